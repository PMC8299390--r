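test_that("presets encode the nucleotide and mutant constraints", {
  expect_equal(condition_preset("CTP", "R149G")$load_rate, 0)
  apo <- condition_preset("apo")
  expect_equal(apo$convert_rate, 0)
  expect_gt(apo$load_rate, 0)
  for (cond in c("CDP", "EDTA")) {
    expect_equal(condition_preset(cond)$convert_rate, 0, info = cond)
  }
  expect_equal(condition_preset("CTP", "R80A")$convert_rate, 0)
  # CTP and its non-hydrolysable analogue behave identically
  a <- condition_preset("CTP")
  b <- condition_preset("CTPgammaS")
  a$condition <- b$condition <- NULL
  expect_identical(a, b)
})

test_that("parS-free DNA recruits no particles", {
  ts <- simulate_parb(condition_preset("CTP", duration = 3, seed = 2),
                      build_substrate("lambda_control"))
  expect_equal(nrow(ts$pos), 0)
  expect_true(all(occupancy_profile(ts)$occupancy_per_bp == 0))
})

test_that("without clamp conversion all binding stays inside parS", {
  map <- build_substrate("13x")
  ts <- simulate_parb(condition_preset("apo", duration = 5, seed = 4), map)
  expect_gt(nrow(ts$pos), 0)
  parS <- map$sites[map$sites$kind == "parS", ]
  visited <- ts$pos[!is.na(ts$pos) & ts$state %in% c(1L, 2L, 3L)]
  inside <- vapply(visited, function(x)
    any(x >= parS$start & x <= parS$end), logical(1))
  expect_true(all(inside))
})

test_that("active roadblocks confine clamps to the parS segment", {
  map <- build_substrate("ecoRI_39x_parS")
  cfg <- condition_preset("CTP", duration = 5, seed = 3,
                          roadblocks_active = TRUE)
  op <- occupancy_profile(simulate_parb(cfg, map), bin = 100)
  rb <- map$sites[map$sites$kind == "roadblock", ]
  protected <- op$end_bp <= rb$start[1] | op$start_bp >= rb$end[2]
  expect_gt(sum(op$occupancy_per_bp[!protected]), 0)
  expect_equal(sum(op$occupancy_per_bp[protected]), 0)
})

test_that("identical config and substrate reproduce identical trajectories", {
  map <- build_substrate("7x")
  cfg <- condition_preset("CTP", duration = 2, seed = 17)
  a <- simulate_parb(cfg, map)
  b <- simulate_parb(cfg, map)
  expect_identical(a$pos, b$pos)
  expect_identical(a$state, b$state)
})

test_that("particle count never exceeds sites plus escaped clamps", {
  map <- build_substrate("13x")
  cfg <- condition_preset("CTP", duration = 5, seed = 8, load_rate = 2)
  ts <- simulate_parb(cfg, map)
  n_sites <- sum(map$sites$kind == "parS")
  for (t in seq_along(ts$times)) {
    on_parS <- sum(ts$state[, t] == 1L, na.rm = TRUE)
    expect_lte(on_parS, n_sites)
  }
  # positions always on the DNA
  expect_true(all(ts$pos[!is.na(ts$pos)] >= 0 &
                    ts$pos[!is.na(ts$pos)] <= map$length))
})

test_that("too-large integration steps are rejected", {
  map <- build_substrate("tpm_1717")  # short molecule
  cfg <- condition_preset("CTP", duration = 1, dt = 0.05, D = 1)
  expect_error(simulate_parb(cfg, map), "dt too large")
})

test_that("clamp displacements follow the diffusion law (analytic oracle)", {
  D <- 0.4
  dt <- 0.005
  ts <- simulate_clamps(500, D, duration = 2.5, dt = dt, seed = 6)
  d_um <- (ts$pos[, -1] - ts$pos[, -ncol(ts$pos)]) * 0.34 / 1000
  m <- length(d_um)
  # mean squared step vs 2 D dt with a 99% normal CI (kurtosis 3)
  expect_lt(abs(mean(d_um^2) - 2 * D * dt),
            2.58 * sqrt(2 / m) * 2 * D * dt)
})

test_that("long-run confined clamps relax to the uniform distribution", {
  # stationary density of reflected Brownian motion in an interval is
  # uniform; chi-square test at alpha = 0.01
  ts <- simulate_clamps(1000, 0.05, duration = 5, dt = 0.01,
                        length_bp = 2000, seed = 9)
  final <- ts$pos[, ncol(ts$pos)]
  tab <- table(cut(final, breaks = seq(0, 2000, by = 200)))
  expect_gt(chisq.test(tab)$p.value, 0.01)
})

test_that("halving dt leaves the ensemble occupancy unchanged within 2%", {
  prof <- function(dt, seed) {
    ts <- simulate_clamps(1000, 0.05, duration = 5, dt = dt,
                          length_bp = 2000, seed = seed)
    occupancy_profile(ts, bin = 200)$occupancy_per_bp
  }
  a <- prof(0.01, 10)
  b <- prof(0.005, 11)
  expect_lt(sqrt(mean((a - b)^2)) / mean(a), 0.02)
})

test_that("occupancy profile integrates to the mean bound-particle count", {
  map <- build_substrate("13x")
  ts <- simulate_parb(condition_preset("CTP", duration = 3, seed = 5), map)
  op <- occupancy_profile(ts, bin = 50)
  bound_per_t <- colSums(!is.na(ts$state) & ts$state %in% c(1L, 2L, 3L))
  expect_equal(sum(op$occupancy_per_bp * (op$end_bp - op$start_bp)),
               mean(bound_per_t))
  # empty set gives an all-zero profile
  empty <- simulate_parb(condition_preset("CTP", "R149G", duration = 1),
                         map)
  expect_true(all(occupancy_profile(empty)$occupancy_per_bp == 0))
})

test_that("trajectory sets round-trip through tidy TSV", {
  map <- build_substrate("7x")
  ts <- simulate_parb(condition_preset("CTP", duration = 3, seed = 3,
                                       load_rate = 2), map)
  df <- as.data.frame(ts)
  expect_gt(nrow(df), 0)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory_set(ts, p)
  back <- read_trajectory_tsv(p)
  expect_equal(back$position_bp, df$position_bp)
  expect_equal(back$state, df$state)
  expect_true(file.exists(paste0(p, ".json")))
})

test_that("absorbing ends remove clamps that slide off the DNA", {
  # high D on a short molecule: clamps reach the ends quickly
  ts <- simulate_clamps(1, 0, duration = 0.1, dt = 0.01, length_bp = 500)
  expect_true(all(ts$state == 2L))
  map <- build_substrate("tpm_1717")
  cfg <- condition_preset("CTP", duration = 20, seed = 12, D = 0.05,
                          dt = 0.002, unbind_rate = 0, bleach_rate = 0,
                          end_behavior = "absorb")
  tsa <- simulate_parb(cfg, map)
  expect_gt(nrow(tsa$pos), 0)
  expect_gt(sum(tsa$state[, ncol(tsa$state)] == 4L, na.rm = TRUE), 0)
})
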