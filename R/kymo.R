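# Kymograph analysis: sub-pixel peak localization, greedy nearest-neighbour
# track linking, time-averaged MSD, Eq. MSD = 2 D t + offset linear fits,
# ensemble statistics, and intensity-profile quantification.

#' Detect emitter peaks in one scan line
#'
#' Local maxima above `threshold` are refined to sub-pixel precision by
#' three-point parabolic interpolation; peaks closer than `min_separation`
#' pixels are merged, keeping the brighter one.
#'
#' @param line Numeric vector of counts for one scan line.
#' @param threshold Minimum peak count; should exceed the expected
#'   background mean.
#' @param min_separation Minimum peak separation in pixels.
#' @return Data frame with `position_px` (sub-pixel, 1-based pixel centres)
#'   and `intensity`; zero rows if nothing is found.
#' @export
detect_peaks <- function(line, threshold, min_separation = 3) {
  n <- length(line)
  empty <- data.frame(position_px = numeric(0), intensity = numeric(0))
  if (n < 3) return(empty)
  i <- 2:(n - 1)
  is_max <- line[i] > line[i - 1] & line[i] >= line[i + 1] &
    line[i] > threshold
  cand <- i[is_max]
  if (!length(cand)) return(empty)
  denom <- line[cand - 1] - 2 * line[cand] + line[cand + 1]
  delta <- ifelse(denom < 0,
                  0.5 * (line[cand - 1] - line[cand + 1]) / denom, 0)
  delta <- pmax(-0.5, pmin(0.5, delta))
  pk <- data.frame(position_px = cand + delta, intensity = line[cand])
  # merge close peaks, brightest first
  pk <- pk[order(-pk$intensity), , drop = FALSE]
  keep <- logical(nrow(pk))
  for (k in seq_len(nrow(pk))) {
    keep[k] <- !any(keep & abs(pk$position_px - pk$position_px[k]) <
                      min_separation)
  }
  pk <- pk[keep, , drop = FALSE]
  pk <- pk[order(pk$position_px), , drop = FALSE]
  rownames(pk) <- NULL
  pk
}

#' Link per-line peaks into trajectories
#'
#' Greedy nearest-neighbour linking between consecutive lines: candidate
#' (track, peak) pairs are assigned in order of increasing distance, links
#' longer than `max_jump_um` are forbidden, unmatched peaks open new
#' tracks, unmatched tracks terminate (no gap closing), and tracks shorter
#' than `min_length` lines are discarded.
#'
#' @param peaks List of data frames as returned by [detect_peaks()], one
#'   per scan line.
#' @param line_times_s Times of the scan lines (s).
#' @param pixel_size_nm Pixel size used to convert pixels to um.
#' @param max_jump_um Maximum displacement between consecutive lines (um).
#' @param min_length Minimum track length (lines).
#' @return List of trajectories, each a data frame with `time_s`,
#'   `position_um`, `intensity`.
#' @export
link_tracks <- function(peaks, line_times_s, pixel_size_nm = 100,
                        max_jump_um = 0.5, min_length = 20) {
  stopifnot(length(peaks) == length(line_times_s), max_jump_um > 0)
  px_um <- pixel_size_nm / 1000
  tracks <- list()       # finished tracks
  act_pos <- numeric(0)  # active track last positions (um)
  act_id <- integer(0)
  open <- list()         # growing tracks by id
  next_id <- 1L
  for (li in seq_along(peaks)) {
    p <- peaks[[li]]
    pos_um <- (p$position_px - 0.5) * px_um
    assigned_pk <- rep(FALSE, length(pos_um))
    matched_tr <- rep(FALSE, length(act_pos))
    if (length(act_pos) && length(pos_um)) {
      dmat <- abs(outer(act_pos, pos_um, "-"))
      ord <- order(dmat)
      for (o in ord) {
        if (dmat[o] > max_jump_um) break
        ti <- (o - 1L) %% length(act_pos) + 1L
        pi <- (o - 1L) %/% length(act_pos) + 1L
        if (matched_tr[ti] || assigned_pk[pi]) next
        matched_tr[ti] <- TRUE
        assigned_pk[pi] <- TRUE
        id <- act_id[ti]
        open[[id]]$time_s <- c(open[[id]]$time_s, line_times_s[li])
        open[[id]]$position_um <- c(open[[id]]$position_um, pos_um[pi])
        open[[id]]$intensity <- c(open[[id]]$intensity, p$intensity[pi])
        act_pos[ti] <- pos_um[pi]
      }
    }
    # close unmatched tracks
    if (any(!matched_tr)) {
      for (ti in which(!matched_tr)) tracks[[length(tracks) + 1L]] <-
          open[[act_id[ti]]]
      act_pos <- act_pos[matched_tr]
      act_id <- act_id[matched_tr]
    }
    # open new tracks for unassigned peaks
    for (pi in which(!assigned_pk)) {
      open[[next_id]] <- list(time_s = line_times_s[li],
                              position_um = pos_um[pi],
                              intensity = p$intensity[pi])
      act_pos <- c(act_pos, pos_um[pi])
      act_id <- c(act_id, next_id)
      next_id <- next_id + 1L
    }
  }
  for (ti in seq_along(act_id)) tracks[[length(tracks) + 1L]] <-
      open[[act_id[ti]]]
  tracks <- Filter(function(tr) length(tr$time_s) >= min_length, tracks)
  lapply(tracks, function(tr) {
    df <- data.frame(time_s = tr$time_s, position_um = tr$position_um,
                     intensity = tr$intensity)
    class(df) <- c("sm_trajectory", "data.frame")
    df
  })
}

#' Track particles in a kymograph
#'
#' Convenience wrapper: [detect_peaks()] on every line followed by
#' [link_tracks()], using the kymograph's own line times and pixel size.
#'
#' @param kymo A `kymograph_image`.
#' @param threshold Peak threshold in counts.
#' @param min_separation Peak merge distance, pixels.
#' @param max_jump_um Linking radius per line, um.
#' @param min_length Minimum track length, lines.
#' @return List of trajectories (see [link_tracks()]).
#' @export
track_kymograph <- function(kymo, threshold = 5, min_separation = 3,
                            max_jump_um = 0.5, min_length = 20) {
  stopifnot(inherits(kymo, "kymograph_image"))
  peaks <- lapply(seq_len(nrow(kymo$counts)), function(i)
    detect_peaks(kymo$counts[i, ], threshold, min_separation))
  link_tracks(peaks, kymo$line_times_s, kymo$optics$pixel_size_nm,
              max_jump_um, min_length)
}

#' Time-averaged mean squared displacement of one trajectory
#'
#' Computes the single-trajectory (time-averaged, overlapping-pair) MSD,
#' `MSD(k dt) = mean_i (x[i+k] - x[i])^2`, for lags up to
#' `max_lag_fraction` of the track length. Tracks are first clipped to
#' `clip_s` seconds to keep the statistical sample comparable across
#' trajectories.
#'
#' @param traj A trajectory data frame with `time_s` and `position_um`.
#' @param max_lag_fraction Largest lag as a fraction of the track length.
#' @param clip_s Clip duration (s); `Inf` disables clipping.
#' @return An `msd_curve` data frame with `lag_s`, `msd_um2`, `n_pairs`.
#' @export
compute_msd <- function(traj, max_lag_fraction = 0.25, clip_s = 2.5) {
  t <- traj$time_s
  x <- traj$position_um
  keep <- t <= t[1] + clip_s + 1e-9
  t <- t[keep]
  x <- x[keep]
  n <- length(x)
  kmax <- floor(max_lag_fraction * n)
  if (kmax < 3) stop("track too short: fewer than 3 usable lags")
  dt <- stats::median(diff(t))
  msd <- vapply(seq_len(kmax), function(k)
    mean((x[(k + 1):n] - x[1:(n - k)])^2), numeric(1))
  out <- data.frame(lag_s = seq_len(kmax) * dt, msd_um2 = msd,
                    n_pairs = n - seq_len(kmax))
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Fit the linear diffusion law MSD = 2 D t + offset
#'
#' Ordinary least squares of MSD against lag time over a window of lag
#' indices. D is half the slope; the intercept is the localization-noise
#' offset (small negative values can occur by noise). The first lag is
#' excluded by the default window to reduce localization-noise bias.
#'
#' @param msd An `msd_curve`.
#' @param lag_window Integer range `c(first, last)` of lag indices to fit.
#' @return A `diffusion_estimate`: list with `D_um2_s`, `offset_um2`,
#'   `lag_window`, `residual_norm`, `n_lags`.
#' @export
fit_diffusion <- function(msd, lag_window = c(2, 10)) {
  stopifnot(inherits(msd, "msd_curve") || is.data.frame(msd))
  idx <- seq_len(nrow(msd))
  sel <- idx >= lag_window[1] & idx <= lag_window[2]
  if (sum(sel) < 3) stop("need >= 3 MSD points in the lag window")
  sub <- msd[sel, , drop = FALSE]
  if (stats::var(sub$lag_s) == 0) stop("singular fit: degenerate lag times")
  fit <- stats::lm(msd_um2 ~ lag_s, data = sub)
  co <- stats::coef(fit)
  structure(list(D_um2_s = unname(co[2]) / 2, offset_um2 = unname(co[1]),
                 lag_window = lag_window,
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 n_lags = sum(sel)),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("<diffusion_estimate> D = %.4g um^2/s, offset = %.3g um^2 (lags %d-%d)\n",
              x$D_um2_s, x$offset_um2, x$lag_window[1], x$lag_window[2]))
  invisible(x)
}

#' Ensemble mean and SEM of per-trajectory diffusion constants
#'
#' Negative per-trajectory estimates are retained (dropping them would bias
#' the ensemble mean upward).
#'
#' @param estimates A numeric vector of D values or a list of
#'   `diffusion_estimate` objects.
#' @return List with `mean_D`, `sem_D`, `n`.
#' @export
ensemble_D <- function(estimates) {
  if (is.list(estimates) && !is.data.frame(estimates))
    estimates <- vapply(estimates, function(e) e$D_um2_s, numeric(1))
  n <- length(estimates)
  if (n < 2) stop("need at least 2 estimates")
  list(mean_D = mean(estimates), sem_D = stats::sd(estimates) / sqrt(n),
       n = n)
}

#' Convert a diffusion constant between um^2/s and bp^2/s
#'
#' @param D_um2_s Diffusion constant in um^2/s.
#' @param rise Rise per base pair in nm.
#' @return Diffusion constant in bp^2/s.
#' @export
D_to_bp2 <- function(D_um2_s, rise = RISE_NM_PER_BP) {
  D_um2_s * 1e6 / rise^2
}

#' Classify a trajectory as mobile or parS-bound (immobile)
#'
#' A track counts as immobile when its fitted D falls below `D_immobile`
#' and its mean position lies within a parS window widened by `margin_nm`.
#'
#' @param traj Trajectory data frame (`time_s`, `position_um`).
#' @param est Its `diffusion_estimate`.
#' @param substrate A `substrate_map`.
#' @param D_immobile Mobility cutoff, um^2/s.
#' @param margin_nm parS window margin (about the optical resolution), nm.
#' @return `TRUE` when immobile/parS-bound.
#' @export
is_immobile_at_parS <- function(traj, est, substrate, D_immobile = 0.05,
                                margin_nm = 250) {
  if (est$D_um2_s >= D_immobile) return(FALSE)
  parS <- substrate$sites[substrate$sites$kind == "parS", , drop = FALSE]
  if (nrow(parS) == 0) return(FALSE)
  pos_nm <- mean(traj$position_um) * 1000
  lo <- parS$start * substrate$rise_per_bp - margin_nm
  hi <- parS$end * substrate$rise_per_bp + margin_nm
  any(pos_nm >= lo & pos_nm <= hi)
}

#' Axial intensity profile of a scan or kymograph
#'
#' For a 2D scan, averages the rows whose transverse offset lies within a
#' band of width `band_width_nm` centred on the DNA axis; for a kymograph,
#' averages all scan lines over time (the band is the scanned line itself).
#'
#' @param image A `scan_image` or `kymograph_image`.
#' @param band_width_nm Band width, nm.
#' @return An `intensity_profile` data frame with `position_um`,
#'   `mean_counts`; the band width is attached as an attribute.
#' @export
extract_profile <- function(image, band_width_nm = 500) {
  if (inherits(image, "scan_image")) {
    rows <- abs(image$row_offsets_nm) <= band_width_nm / 2
    if (!any(rows)) stop("band narrower than one scan row")
    prof <- colMeans(image$counts[rows, , drop = FALSE])
  } else if (inherits(image, "kymograph_image")) {
    prof <- colMeans(image$counts)
  } else stop("image must be a scan_image or kymograph_image")
  out <- data.frame(position_um = image$pixel_centers_nm / 1000,
                    mean_counts = prof)
  attr(out, "band_width_nm") <- band_width_nm
  class(out) <- c("intensity_profile", "data.frame")
  out
}

# background estimate: median of pixels >= 3 sigma transverse off the DNA
# axis for scans; for kymographs (single-line), median of pixels outside
# all quantified windows
.background_estimate <- function(image, windows_um = NULL) {
  if (inherits(image, "scan_image")) {
    sigma <- .psf_sigma(image$optics)
    off <- abs(image$row_offsets_nm) >= 3 * sigma
    if (any(off)) return(stats::median(image$counts[off, ]))
  }
  prof <- colMeans(image$counts)
  pos <- image$pixel_centers_nm / 1000
  out_of <- rep(TRUE, length(pos))
  if (!is.null(windows_um)) {
    for (w in windows_um) out_of <- out_of & !(pos >= w[1] & pos <= w[2])
  }
  if (!any(out_of)) out_of <- rep(TRUE, length(pos))
  stats::median(prof[out_of])
}

#' Quantify mean intensity in substrate regions
#'
#' Maps bp windows to image coordinates through the rise per bp, averages
#' the axial profile inside each window and subtracts a background estimate
#' (the median of pixels at least 3 sigma off the DNA axis for scans).
#'
#' @param image A `scan_image` or `kymograph_image`.
#' @param windows_bp Named list of `c(start, end)` windows in bp.
#' @param rise Rise per base pair, nm.
#' @param band_width_nm Band width for the profile, nm.
#' @return Data frame with `region`, `mean_counts`, `background`, `value`
#'   (background-subtracted mean).
#' @export
quantify_regions <- function(image, windows_bp, rise = RISE_NM_PER_BP,
                             band_width_nm = 500) {
  prof <- extract_profile(image, band_width_nm)
  windows_um <- lapply(windows_bp, function(w) sort(w) * rise / 1000)
  bad <- vapply(windows_um, function(w)
    w[1] > max(prof$position_um) || w[2] < min(prof$position_um), logical(1))
  if (any(bad))
    stop("window(s) outside the imaged field: ",
         paste(names(windows_bp)[bad], collapse = ", "))
  bg <- .background_estimate(image, windows_um)
  vals <- vapply(windows_um, function(w) {
    sel <- prof$position_um >= w[1] & prof$position_um <= w[2]
    mean(prof$mean_counts[sel])
  }, numeric(1))
  nm <- names(windows_bp)
  if (is.null(nm)) nm <- sprintf("region_%d", seq_along(windows_bp))
  data.frame(region = nm, mean_counts = unname(vals), background = bg,
             value = unname(vals) - bg)
}

#' Fold enhancement of a region between two images
#'
#' Ratio of background-subtracted region intensity between two conditions
#' rendered with identical optics (e.g. CTP vs apo).
#'
#' @param image_a,image_b Images for the numerator and denominator.
#' @param window_bp `c(start, end)` window in bp.
#' @param rise Rise per base pair, nm.
#' @return The intensity ratio (a / b).
#' @export
fold_enhancement <- function(image_a, image_b, window_bp,
                             rise = RISE_NM_PER_BP) {
  va <- quantify_regions(image_a, list(w = window_bp), rise)$value
  vb <- quantify_regions(image_b, list(w = window_bp), rise)$value
  if (va == vb) return(1)  # covers the featureless 0/0 case
  va / vb
}

#' Fit a single-exponential photobleaching decay with floor
#'
#' Least-squares fit of `I(t) = floor + amplitude * exp(-rate * t)`.
#'
#' @param times Times (s).
#' @param intensity Region intensity at those times (counts).
#' @return List with `rate_per_s`, `amplitude`, `floor`, `fitted`.
#' @export
fit_bleach_decay <- function(times, intensity) {
  stopifnot(length(times) == length(intensity), length(times) >= 4)
  f0 <- min(intensity)
  a0 <- max(intensity) - f0
  k0 <- 2 / max(diff(range(times)), 1e-9)
  fit <- minpack.lm::nlsLM(
    intensity ~ fl + a * exp(-k * times),
    start = list(fl = f0, a = max(a0, 1e-9), k = k0),
    lower = c(0, 0, 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- stats::coef(fit)
  list(rate_per_s = unname(co["k"]), amplitude = unname(co["a"]),
       floor = unname(co["fl"]), fitted = stats::fitted(fit))
}

#' End-to-end diffusion-constant recovery experiment
#'
#' Simulates `n_tracks` sliding clamps at a known diffusion constant,
#' renders each as a single-emitter kymograph with quantum-dot optics,
#' tracks the kymographs, computes per-track time-averaged MSDs, fits the
#' linear diffusion law and returns the ensemble statistics. This is the
#' full measurement pipeline run against its own ground truth.
#'
#' @param D_true Ground-truth diffusion constant, um^2/s.
#' @param n_tracks Number of trajectories.
#' @param duration,dt Simulated span and sampling step (s).
#' @param length_bp Substrate length (featureless DNA), bp.
#' @param optics Optics used for rendering; defaults to [qd_optics()].
#' @param threshold,max_jump_um,min_length Tracking parameters.
#' @param lag_window MSD fit window (lag indices).
#' @param seed Integer seed.
#' @return List with `D_true`, `estimates` (per-track D), `mean_D`,
#'   `sem_D`, `n`.
#' @export
recover_diffusion <- function(D_true, n_tracks = 210, duration = 2.5,
                              dt = 0.005, length_bp = 48502,
                              optics = qd_optics(), threshold = 5,
                              max_jump_um = 1, min_length = 50,
                              lag_window = c(2, 10), seed = 1L) {
  ts <- simulate_clamps(n_tracks, D_true, duration = duration, dt = dt,
                        length_bp = length_bp, seed = seed)
  Ds <- numeric(0)
  for (i in seq_len(n_tracks)) {
    one <- ts
    one$pos <- ts$pos[i, , drop = FALSE]
    one$state <- ts$state[i, , drop = FALSE]
    one$birth_time <- ts$birth_time[i]
    kymo <- render_kymograph(one, optics)
    tracks <- track_kymograph(kymo, threshold = threshold,
                              max_jump_um = max_jump_um,
                              min_length = min_length)
    if (!length(tracks)) next
    tr <- tracks[[which.max(vapply(tracks, nrow, integer(1)))]]
    est <- try(fit_diffusion(compute_msd(tr), lag_window), silent = TRUE)
    if (!inherits(est, "try-error")) Ds <- c(Ds, est$D_um2_s)
  }
  ens <- ensemble_D(Ds)
  list(D_true = D_true, estimates = Ds, mean_D = ens$mean_D,
       sem_D = ens$sem_D, n = ens$n)
}
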