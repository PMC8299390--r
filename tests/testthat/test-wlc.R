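test_that("the force law matches hand-evaluated values and limits", {
  # x/Lc = 0.5, Lp = 50 nm, T = 298 K: (kBT/50) * 1.25
  expect_equal(wlc_force(0.5, 50), kBT_pN_nm(298) / 50 * 1.25,
               tolerance = 1e-12)
  expect_equal(wlc_force(0.5, 50), 0.1029, tolerance = 1e-3)
  # small-extension (entropic spring) limit: F -> (3 kBT / 2 Lp) (x/Lc)
  x <- 1e-4
  expect_equal(wlc_force(x, 50), 1.5 * kBT_pN_nm(298) / 50 * x,
               tolerance = 1e-3)
  expect_error(wlc_force(1.0), "\\[0, 1\\)")
  expect_error(wlc_force(-0.1), "\\[0, 1\\)")
})

test_that("force and extension are mutually inverse and monotone", {
  f <- c(0.01, 0.1, 0.33, 1, 5)
  x <- wlc_extension(f, 50, 2)
  expect_true(all(diff(x) > 0))
  round_trip <- wlc_force(x / 2, 50)
  expect_equal(round_trip, f, tolerance = 1e-6)
  expect_equal(wlc_extension(0, 50, 2), 0)
  # stiffer chains (larger Lp) need less force at the same extension
  expect_lt(wlc_force(0.5, 60), wlc_force(0.5, 40))
  # monotone in x/Lc
  grid <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(wlc_force(grid, 50)) > 0))
})

test_that("noiseless curves recover (Lp, Lc) within 1%", {
  for (par in list(c(40, 1.5), c(50, 2), c(65, 2.72))) {
    fit <- fit_wlc(simulate_force_extension(par[1], par[2]))
    expect_equal(fit$Lp_nm, par[1], tolerance = 0.01)
    expect_equal(fit$Lc_um, par[2], tolerance = 0.01)
  }
})

test_that("2% extension noise keeps the median recovery within 5%", {
  errs <- vapply(1:50, function(s) {
    fit <- fit_wlc(simulate_force_extension(50, 2, noise_frac = 0.02,
                                            seed = s))
    abs(fit$Lc_um / 2 - 1)
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("fitted contour length scales with the data", {
  cv <- simulate_force_extension(50, 2)
  half <- force_extension_curve(cv$force_pN, cv$extension_um * 0.5)
  fit <- fit_wlc(half)
  expect_equal(fit$Lc_um, 1, tolerance = 0.01)
})

test_that("the +/-15% contour filter is inclusive at the boundary", {
  fit <- function(Lc) structure(list(Lp_nm = 50, Lc_um = Lc),
                                class = "wlc_fit")
  expect_true(filter_contour(fit(2), 2))
  expect_true(filter_contour(fit(2.3), 2))    # exactly +15%
  expect_true(filter_contour(fit(1.7), 2))    # exactly -15%
  expect_false(filter_contour(fit(2 * 0.84), 2))  # 16% short
  expect_false(filter_contour(fit(2 * 1.151), 2))
})

test_that("fit acceptance is invariant to point order", {
  cv <- simulate_force_extension(50, 2, noise_frac = 0.01, seed = 3)
  shuffled <- cv[sample(nrow(cv)), ]
  f1 <- fit_wlc(cv)
  f2 <- fit_wlc(shuffled)
  expect_equal(f1$Lc_um, f2$Lc_um, tolerance = 1e-6)
  expect_equal(filter_contour(f1, 2), filter_contour(f2, 2))
})

test_that("equipartition force calibration is exact and linear", {
  expect_equal(force_from_excursions(1000, 1000), kBT_pN_nm(298),
               tolerance = 1e-12)
  expect_equal(force_from_excursions(1000, 2000),
               2 * force_from_excursions(1000, 1000))
  expect_error(force_from_excursions(0, 1000), "> 0")
  # generator round trip: OU bead at a known force recovers it within 10%
  for (f in c(0.33, 1, 4)) {
    tr <- simulate_magnet_bead(f, Lc_um = 2, seed = round(100 * f))
    rec <- force_from_excursions(mean((tr$x_nm - mean(tr$x_nm))^2),
                                 attr(tr, "extension_nm"))
    expect_equal(rec, f, tolerance = 0.1)
  }
})

test_that("condensation metrics report fraction, rate and verdict", {
  naked <- 2
  flat <- simulate_condensation_trace(naked, plateau_fraction = 1,
                                      noise_nm = 5, seed = 11)
  m0 <- condensation_metrics(flat, naked)
  expect_false(m0$condensed)
  expect_lt(abs(m0$condensed_fraction), 0.02)
  dec <- simulate_condensation_trace(naked, rate_per_s = 0.05,
                                     plateau_fraction = 0.3,
                                     noise_nm = 5, seed = 12)
  m1 <- condensation_metrics(dec, naked)
  expect_true(m1$condensed)
  expect_equal(m1$condensed_fraction, 0.7, tolerance = 0.02)
  expect_gt(m1$initial_rate_nm_s, 0)
  expect_error(condensation_metrics(dec[dec$time_s < 50, ], naked),
               "60 s")
})

test_that("naked-DNA controls almost never trip the condensation verdict", {
  hits <- vapply(1:100, function(s) {
    tr <- simulate_condensation_trace(2, plateau_fraction = 1,
                                      noise_nm = 10, seed = s)
    condensation_metrics(tr, 2)$condensed
  }, logical(1))
  expect_gte(mean(!hits), 0.95)
})

test_that("the maximum condensation force tracks the deficit threshold", {
  ref <- structure(list(Lp_nm = 50, Lc_um = 2), class = "wlc_fit")
  naked <- simulate_force_extension(50, 2)
  expect_equal(max_condensation_force(naked, ref), 0)
  cond <- simulate_force_extension(50, 2, condensed_below_pN = 1,
                                   condensed_factor = 0.4)
  f_max <- max_condensation_force(cond, ref)
  expect_equal(f_max, max(cond$force_pN[cond$force_pN < 1]))
  # monotone: a stricter deficit can only lower the answer
  ths <- seq(0.05, 0.55, by = 0.1)
  fs <- vapply(ths, function(th)
    max_condensation_force(cond, ref, deficit_threshold = th), numeric(1))
  expect_true(all(diff(fs) <= 0))
})

test_that("force-extension tables round-trip through TSV", {
  cv <- simulate_force_extension(50, 2, noise_frac = 0.01, seed = 13)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_force_extension(cv, p)
  back <- read_force_extension(p)
  expect_equal(back$force_pN, cv$force_pN)
  expect_equal(back$extension_um, cv$extension_um)
})
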