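# Tethered particle motion: full-trace RMS excursion, drift-suppressed
# sliding-window RMS_tau, condensation detection, and a drifting-bead
# trace generator.

#' Simulate a tethered-bead position trace
#'
#' Per-axis stationary Gaussian process with exponential correlation
#' (Ornstein-Uhlenbeck), optional linear stage drift and an optional step
#' change in excursion amplitude mimicking condensation. In `"auto"` mode
#' the excursion amplitude per axis is the Gaussian-chain estimate
#' `sigma = sqrt(2 Lp Lc / 3)` with persistence length `Lp` and contour
#' length `Lc = tether_bp * rise`; for the 1717 bp tether this gives about
#' 139.5 nm. Drift is applied at 45 degrees so `drift_nm_per_s` is the
#' scalar stage speed.
#'
#' @param tether_bp Tether length, bp.
#' @param excursion_sigma Per-axis excursion SD in nm, or `"auto"`.
#' @param drift_nm_per_s Linear drift speed, nm/s (0 = none).
#' @param step_time_s Time of a condensation step, s (`NULL` = none).
#' @param step_factor Multiplier applied to sigma after the step.
#' @param duration_s Trace duration, s.
#' @param rate_hz Sampling rate, Hz.
#' @param correlation_time_s Correlation time of the bead-tether system, s
#'   (0 gives white noise).
#' @param persistence_nm Persistence length for `"auto"` sigma, nm.
#' @param rise Rise per base pair, nm.
#' @param seed Integer seed.
#' @return A `bead_trace` data frame with `time_s`, `x_nm`, `y_nm`;
#'   the generating parameters are attached as attributes.
#' @export
simulate_bead_trace <- function(tether_bp = 1717, excursion_sigma = "auto",
                                drift_nm_per_s = 0, step_time_s = NULL,
                                step_factor = 0.5, duration_s = 300,
                                rate_hz = 120, correlation_time_s = 0.5,
                                persistence_nm = 50, rise = RISE_NM_PER_BP,
                                seed = 1L) {
  stopifnot(tether_bp > 0, duration_s > 0, rate_hz > 0,
            correlation_time_s >= 0, step_factor >= 0)
  if (identical(excursion_sigma, "auto")) {
    Lc <- tether_bp * rise
    excursion_sigma <- sqrt(2 * persistence_nm * Lc / 3)
  }
  stopifnot(is.numeric(excursion_sigma), excursion_sigma >= 0)
  set.seed(as.integer(seed))
  n <- round(duration_s * rate_hz)
  times <- (seq_len(n) - 1L) / rate_hz
  phi <- if (correlation_time_s > 0)
    exp(-1 / (rate_hz * correlation_time_s)) else 0
  ou_axis <- function() {
    u <- numeric(n)
    u[1] <- stats::rnorm(1)
    innov <- stats::rnorm(n - 1L, 0, sqrt(1 - phi^2))
    for (i in 2:n) u[i] <- phi * u[i - 1L] + innov[i - 1L]
    u
  }
  sigma_t <- rep(excursion_sigma, n)
  if (!is.null(step_time_s)) sigma_t[times >= step_time_s] <-
      excursion_sigma * step_factor
  v <- drift_nm_per_s / sqrt(2)
  out <- data.frame(time_s = times,
                    x_nm = sigma_t * ou_axis() + v * times,
                    y_nm = sigma_t * ou_axis() + v * times)
  attr(out, "sigma_nm") <- excursion_sigma
  attr(out, "rate_hz") <- rate_hz
  attr(out, "correlation_time_s") <- correlation_time_s
  class(out) <- c("bead_trace", "data.frame")
  out
}

.check_uniform <- function(t) {
  d <- diff(t)
  if (length(d) < 1 || any(abs(d - stats::median(d)) > 1e-6 * stats::median(d)))
    stop("trace must be uniformly sampled")
  stats::median(d)
}

#' Full-trace RMS excursion of a tethered bead
#'
#' `RMS = sqrt(mean((x - xbar)^2 + (y - ybar)^2))` with the means taken
#' over the whole trace. Sensitive to slow drift; see [rms_windowed()] for
#' the drift-suppressed estimator.
#'
#' @param trace A `bead_trace` (or data frame with `time_s`, `x_nm`,
#'   `y_nm`), uniformly sampled.
#' @return RMS excursion, nm.
#' @export
rms_full <- function(trace) {
  stopifnot(nrow(trace) >= 2)
  .check_uniform(trace$time_s)
  dx <- trace$x_nm - mean(trace$x_nm)
  dy <- trace$y_nm - mean(trace$y_nm)
  sqrt(mean(dx^2 + dy^2))
}

#' Sliding-window RMS excursion (drift-suppressed)
#'
#' Computes `RMS_tau = sqrt(var_tau(x) + var_tau(y))` in a sliding boxcar
#' window of span `tau` with window-local means, stride one sample. Local
#' mean removal filters out drift slower than the window, at the price of a
#' variance bias when the window is shorter than the bead-tether
#' correlation time; windows shorter than `min_tau_s` are therefore
#' rejected unless explicitly overridden.
#'
#' @param trace A uniformly sampled `bead_trace`.
#' @param tau_s Window span, s.
#' @param min_tau_s Calibration floor for the window, s.
#' @param override Set `TRUE` to proceed (with a warning) below the floor.
#' @return An `rms_series` data frame with `center_s` and `rms_nm`; `tau_s`
#'   is attached as an attribute.
#' @export
rms_windowed <- function(trace, tau_s = 8.3, min_tau_s = 8,
                         override = FALSE) {
  dt <- .check_uniform(trace$time_s)
  if (tau_s < min_tau_s) {
    if (!override)
      stop("tau = ", tau_s, " s is below the ", min_tau_s,
           " s correlation-safe floor; pass override = TRUE to force")
    warning("tau below the ", min_tau_s, " s floor; variance will be biased")
  }
  w <- max(2L, round(tau_s / dt))
  n <- nrow(trace)
  if (w > n) stop("window longer than the trace")
  winvar <- function(z) {
    s1 <- cumsum(c(0, z))
    s2 <- cumsum(c(0, z^2))
    i <- seq_len(n - w + 1L)
    m <- (s1[i + w] - s1[i]) / w
    pmax((s2[i + w] - s2[i]) / w - m^2, 0)
  }
  v <- winvar(trace$x_nm) + winvar(trace$y_nm)
  centers <- trace$time_s[seq_len(n - w + 1L)] + (w - 1L) * dt / 2
  out <- data.frame(center_s = centers, rms_nm = sqrt(v))
  attr(out, "tau_s") <- tau_s
  class(out) <- c("rms_series", "data.frame")
  out
}

#' Mean windowed RMS over the whole experiment
#'
#' @param series An `rms_series` from [rms_windowed()].
#' @return Mean RMS_tau, nm.
#' @export
mean_rms_tau <- function(series) {
  mean(series$rms_nm)
}

#' Detect DNA condensation in a windowed RMS series
#'
#' The tether counts as condensed when RMS_tau falls below
#' `(1 - drop_fraction)` times the baseline (median of the first
#' `baseline_fraction` of the series) and stays there for at least
#' `hold_s` seconds.
#'
#' @param series An `rms_series`.
#' @param drop_fraction Fractional drop defining condensation.
#' @param hold_s Minimum time below threshold, s.
#' @param baseline_fraction Initial fraction of the series used as the
#'   baseline.
#' @return List with `condensed` (logical), `onset_s` (`NA` if not
#'   condensed), `baseline_nm`, `threshold_nm`.
#' @export
detect_condensation <- function(series, drop_fraction = 0.3, hold_s = 20,
                                baseline_fraction = 0.2) {
  n <- nrow(series)
  span <- series$center_s[n] - series$center_s[1]
  if (span < 2 * hold_s) stop("series must span at least 2 x hold_s")
  nb <- max(2L, floor(baseline_fraction * n))
  baseline <- stats::median(series$rms_nm[seq_len(nb)])
  thr <- (1 - drop_fraction) * baseline
  below <- series$rms_nm < thr
  dt <- stats::median(diff(series$center_s))
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths * dt >= hold_s)
  if (length(hit)) {
    list(condensed = TRUE, onset_s = series$center_s[starts[hit[1]]],
         baseline_nm = baseline, threshold_nm = thr)
  } else {
    list(condensed = FALSE, onset_s = NA_real_, baseline_nm = baseline,
         threshold_nm = thr)
  }
}

#' Write / read a bead trace as TSV
#'
#' Columns `time_s`, `x_nm`, `y_nm`; lossless round trip.
#'
#' @param trace A `bead_trace`.
#' @param path File path.
#' @return `write_bead_trace` returns `path` invisibly; `read_bead_trace`
#'   returns a `bead_trace`.
#' @export
write_bead_trace <- function(trace, path) {
  utils::write.table(trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_bead_trace
#' @export
read_bead_trace <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  need <- c("time_s", "x_nm", "y_nm")
  if (!all(need %in% names(df)))
    stop("missing column(s) in ", path, ": ",
         paste(setdiff(need, names(df)), collapse = ", "))
  class(df) <- c("bead_trace", "data.frame")
  df
}
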