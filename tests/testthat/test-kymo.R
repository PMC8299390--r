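test_that("peak detection refines, merges and rejects flat lines", {
  expect_equal(nrow(detect_peaks(rep(2, 50), threshold = 5)), 0)
  # a clean Gaussian peak centred between pixels 25 and 26
  x <- 1:50
  line <- 100 * exp(-(x - 25.5)^2 / (2 * 1.06^2))
  pk <- detect_peaks(line, threshold = 5)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$position_px - 25.5), 0.5)
  # two peaks 3 px apart merge under min_separation 5, keeping the brighter
  line2 <- numeric(50)
  line2[20] <- 80
  line2[23] <- 100
  pk2 <- detect_peaks(line2, threshold = 5, min_separation = 5)
  expect_equal(nrow(pk2), 1)
  expect_equal(round(pk2$position_px), 23)
})

test_that("localization error of a rendered emitter stays below half a pixel", {
  set.seed(11)
  ts <- simulate_clamps(1, 0, duration = 10, dt = 0.025,
                        length_bp = 10000, start_bp = 5120)
  k <- render_kymograph(ts, qd_optics())
  true_px <- 5120 * 0.34 / 100  # bp -> nm -> pixels (edges at 0)
  errs <- vapply(seq_len(nrow(k$counts)), function(i) {
    pk <- detect_peaks(k$counts[i, ], threshold = 5)
    pk$position_px[which.max(pk$intensity)] - 0.5 - true_px
  }, numeric(1))
  expect_lt(mean(abs(errs)), 0.5)   # within half a pixel (50 nm) on average
})

test_that("linking keeps persistent peaks and splits across gaps", {
  peaks <- lapply(1:10, function(i)
    data.frame(position_px = 20, intensity = 50))
  tr <- link_tracks(peaks, (0:9) * 0.025, min_length = 2)
  expect_length(tr, 1)
  expect_equal(nrow(tr[[1]]), 10)
  # a one-line dropout with no gap closing yields two tracks
  peaks[[5]] <- data.frame(position_px = numeric(0), intensity = numeric(0))
  tr2 <- link_tracks(peaks, (0:9) * 0.025, min_length = 2)
  expect_length(tr2, 2)
  expect_equal(sort(vapply(tr2, nrow, integer(1))), c(4L, 5L))
})

test_that("two well-separated clamps are recovered as two faithful tracks", {
  set.seed(12)
  ts <- simulate_clamps(2, 0.2, duration = 2.5, dt = 0.005,
                        length_bp = 30000, start_bp = 7500)
  ts$pos[2, ] <- ts$pos[2, ] + 15000  # move the second clamp far away
  k <- render_kymograph(ts, qd_optics())
  tracks <- track_kymograph(k, min_length = 80)
  expect_length(tracks, 2)
  # oracle: ground-truth identities; >= 95% of linked points must lie
  # nearest the trajectory they started on
  for (tr in tracks) {
    idx <- findInterval(tr$time_s + 1e-12, ts$times)
    truth_um <- ts$pos[, idx, drop = FALSE] * 0.34 / 1000
    d1 <- abs(tr$position_um - truth_um[1, ])
    d2 <- abs(tr$position_um - truth_um[2, ])
    owner <- if (mean(d1) < mean(d2)) d1 else d2
    other <- if (mean(d1) < mean(d2)) d2 else d1
    expect_gt(mean(owner < other), 0.95)
  }
})

test_that("compute_msd equals the brute-force double loop at every lag", {
  set.seed(13)
  for (rep in 1:5) {
    tr <- random_trajectory(80)
    msd <- compute_msd(tr, max_lag_fraction = 0.25, clip_s = Inf)
    oracle <- brute_force_msd(tr$position_um, nrow(msd))
    expect_equal(msd$msd_um2, oracle, tolerance = 1e-12)
  }
})

test_that("MSD has the exact closed forms for degenerate motion", {
  t <- (0:99) * 0.025
  still <- data.frame(time_s = t, position_um = rep(1.5, 100))
  expect_true(all(compute_msd(still, clip_s = Inf)$msd_um2 == 0))
  v <- 0.3
  ball <- data.frame(time_s = t, position_um = v * t)
  msd <- compute_msd(ball, clip_s = Inf)
  expect_equal(msd$msd_um2, v^2 * msd$lag_s^2, tolerance = 1e-12)
})

test_that("tracks are clipped to 2.5 s before the MSD", {
  t <- (0:399) * 0.025  # 10 s
  tr <- data.frame(time_s = t, position_um = cumsum(rnorm(400, 0, 0.05)))
  msd <- compute_msd(tr)  # default clip 2.5 s -> 101 points -> 25 lags
  expect_equal(nrow(msd), 25)
  expect_error(compute_msd(tr[1:8, ]), "too short")
})

test_that("the linear fit recovers slope/2 and intercept exactly", {
  lag <- (1:12) * 0.025
  msd <- structure(data.frame(lag_s = lag,
                              msd_um2 = 2 * 0.41 * lag + 0.001,
                              n_pairs = 100 - (1:12)),
                   class = c("msd_curve", "data.frame"))
  est <- fit_diffusion(msd)
  expect_equal(est$D_um2_s, 0.41, tolerance = 1e-12)
  expect_equal(est$offset_um2, 0.001, tolerance = 1e-12)
  flat <- msd
  flat$msd_um2 <- rep(0.02, 12)
  est2 <- fit_diffusion(flat)
  expect_equal(est2$D_um2_s, 0)
  expect_equal(est2$offset_um2, 0.02)
  expect_error(fit_diffusion(msd[1:2, ]), ">= 3")
})

test_that("ensemble statistics behave as mean and SEM", {
  expect_equal(ensemble_D(c(0.3, 0.5)),
               list(mean_D = 0.4, sem_D = 0.1, n = 2))
  expect_equal(ensemble_D(rep(0.4, 10))$sem_D, 0)
  # SEM scales as 1/sqrt(n): 44-track subsets vs the full 177 (resampling)
  set.seed(14)
  Ds <- rnorm(177, 0.41, 0.1)
  full <- ensemble_D(Ds)$sem_D
  sub <- mean(replicate(300, ensemble_D(sample(Ds, 44))$sem_D))
  expect_equal(sub * sqrt(44 / 177), full, tolerance = 0.05)
})

test_that("ground-truth trajectories fit with a vanishing offset", {
  ts <- simulate_clamps(60, 0.4, duration = 2.5, dt = 0.025, seed = 15)
  offs <- vapply(1:60, function(i) {
    tr <- data.frame(time_s = ts$times,
                     position_um = ts$pos[i, ] * 0.34 / 1000)
    fit_diffusion(compute_msd(tr))$offset_um2
  }, numeric(1))
  # noiseless positions: mean offset indistinguishable from zero
  expect_lt(abs(mean(offs)), 3 * sd(offs) / sqrt(60))
})

test_that("mobile/immobile classification follows D and parS position", {
  map <- build_substrate("13x")
  parS_mid <- mean(range(map$sites$start))
  still <- data.frame(time_s = (0:50) * 0.025,
                      position_um = rep(parS_mid * 0.34 / 1000, 51))
  est_still <- list(D_um2_s = 0.01)
  expect_true(is_immobile_at_parS(still, est_still, map))
  away <- still
  away$position_um <- away$position_um + 2
  expect_false(is_immobile_at_parS(away, est_still, map))
  expect_false(is_immobile_at_parS(still, list(D_um2_s = 0.4), map))
})

test_that("profiles quantify parS enhancement between conditions", {
  # with photobleaching on, apo parS sites bleach dark and stay occupied,
  # while CTP-driven conversion keeps freeing sites for fresh (bright)
  # loading and sends clamps onto nsDNA: time-averaged parS intensity is
  # higher under CTP and only CTP populates nsDNA (oracle: occupancy)
  map <- build_substrate("13x")
  mk <- function(cond, seed) {
    cfg <- condition_preset(cond, duration = 20, seed = seed, load_rate = 2)
    simulate_parb(cfg, map)
  }
  ts_ctp <- mk("CTP", 21)
  ts_apo <- mk("apo", 22)
  parS <- map$sites[map$sites$kind == "parS", ]
  win <- c(min(parS$start) - 200, max(parS$end) + 200)
  ns_bins <- function(ts) {
    op <- occupancy_profile(ts, bin = 100)
    sum(op$occupancy_per_bp[op$end_bp < win[1] | op$start_bp > win[2]])
  }
  expect_gt(ns_bins(ts_ctp), 0)   # clamps spread beyond parS
  expect_equal(ns_bins(ts_apo), 0)  # apo never leaves parS
  set.seed(23)
  k_ctp <- render_kymograph(ts_ctp)
  k_apo <- render_kymograph(ts_apo)
  q <- quantify_regions(k_ctp, list(parS = win))
  expect_gt(q$value, 0)
  expect_gt(fold_enhancement(k_ctp, k_apo, win), 1)
  expect_error(quantify_regions(k_ctp, list(off = c(1e6, 2e6))),
               "outside")
})

test_that("uniform images give a flat profile and fold enhancement one", {
  opt <- optics_config()
  img <- structure(list(counts = matrix(7, 21, 40),
                        row_offsets_nm = (-10:10) * 100,
                        pixel_centers_nm = (1:40) * 100 - 50,
                        t0_s = 0, frame_time_s = 0.525, optics = opt),
                   class = "scan_image")
  prof <- extract_profile(img)
  expect_true(all(prof$mean_counts == 7))
  expect_equal(fold_enhancement(img, img, c(2000, 5000)), 1)
})

test_that("bleach decay fits recover the generating rate and floor", {
  t <- seq(0, 30, by = 0.5)
  set.seed(24)
  y <- 2 + 40 * exp(-0.12 * t) + rnorm(length(t), 0, 0.5)
  fit <- fit_bleach_decay(t, y)
  expect_equal(fit$rate_per_s, 0.12, tolerance = 0.1)
  expect_equal(fit$floor, 2, tolerance = 0.5)
})
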