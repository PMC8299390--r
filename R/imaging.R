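# Confocal scan / kymograph rendering: Gaussian PSF blur of point emitters
# plus Poisson shot noise, with the acquisition geometry of a dual-trap
# confocal (100 nm pixels, 0.1 ms pixel dwell, ~250 nm FWHM resolution,
# line scans every 25 ms). Emitter positions are frozen at line start; the
# PSF is truncated at +/- 4 sigma.

#' Optics and acquisition configuration
#'
#' @param pixel_size_nm Pixel size along the DNA axis (nm).
#' @param psf_fwhm_nm Point-spread-function full width at half maximum (nm);
#'   must be >= the pixel size.
#' @param photon_rate Detected photon rate per unbleached emitter (counts/s).
#' @param background_rate Background rate (counts/s/pixel).
#' @param line_period_s Time between successive scan lines (s).
#' @param pixel_dwell_s Dwell time per pixel (s).
#' @return An `optics_config` list.
#' @export
optics_config <- function(pixel_size_nm = 100, psf_fwhm_nm = 250,
                          photon_rate = 3e5, background_rate = 1e4,
                          line_period_s = 0.025, pixel_dwell_s = 1e-4) {
  vals <- c(pixel_size_nm, psf_fwhm_nm, photon_rate, background_rate,
            line_period_s, pixel_dwell_s)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all optics parameters must be finite and positive")
  if (psf_fwhm_nm < pixel_size_nm)
    stop("PSF FWHM must be >= pixel size")
  structure(list(pixel_size_nm = pixel_size_nm, psf_fwhm_nm = psf_fwhm_nm,
                 photon_rate = photon_rate,
                 background_rate = background_rate,
                 line_period_s = line_period_s,
                 pixel_dwell_s = pixel_dwell_s),
            class = "optics_config")
}

#' Optics preset for quantum-dot labelled emitters
#'
#' Quantum dots are far brighter than organic dyes and do not photobleach;
#' this preset raises the per-emitter photon rate accordingly and is the
#' natural choice when rendering tracking (diffusion-measurement)
#' experiments.
#'
#' @param ... Overrides passed to [optics_config()].
#' @return An `optics_config`.
#' @export
qd_optics <- function(...) {
  args <- list(...)
  defaults <- list(photon_rate = 1.5e6)
  do.call(optics_config, utils::modifyList(defaults, args))
}

.psf_sigma <- function(optics) optics$psf_fwhm_nm / (2 * sqrt(2 * log(2)))

# Gaussian mass per pixel for each emitter, truncated at +/- 4 sigma.
# edges: pixel edges (nm); returns matrix emitters x pixels
.emitter_masses <- function(x_nm, edges, sigma) {
  np <- length(edges) - 1L
  out <- matrix(0, length(x_nm), np)
  for (i in seq_along(x_nm)) {
    lo <- max(1L, floor((x_nm[i] - 4 * sigma - edges[1]) /
                          (edges[2] - edges[1])) + 1L)
    hi <- min(np, ceiling((x_nm[i] + 4 * sigma - edges[1]) /
                            (edges[2] - edges[1])))
    if (hi < lo) next
    p <- stats::pnorm(edges[lo:(hi + 1L)], x_nm[i], sigma)
    out[i, lo:hi] <- diff(p)
  }
  out
}

# emissive (bound and unbleached) emitter positions (nm) at sample index
.emitters_at <- function(ts, t_idx) {
  on <- !is.na(ts$state[, t_idx]) & ts$state[, t_idx] %in% c(1L, 2L)
  ts$pos[on, t_idx] * ts$substrate$rise_per_bp
}

#' Render a kymograph from a trajectory set
#'
#' Repeated single-line scans along the DNA contour. The expected count in
#' pixel j of a line is `background_rate * dwell` plus, for every emissive
#' emitter, `photon_rate * dwell` times the Gaussian PSF mass falling in
#' that pixel; realized counts are Poisson. Bleached and detached emitters
#' contribute nothing. Emitter positions are frozen at line start (the line
#' period is much longer than the pixel dwell).
#'
#' @param ts A `trajectory_set` sampled at least as finely as the line
#'   period.
#' @param optics An [optics_config()].
#' @param n_lines Number of scan lines; default spans the whole simulation.
#' @return A `kymograph_image`: list with integer count matrix `counts`
#'   (rows = scan lines, cols = position pixels), `line_times_s`,
#'   `pixel_centers_nm` and the optics echo.
#' @export
render_kymograph <- function(ts, optics = optics_config(), n_lines = NULL) {
  stopifnot(inherits(ts, "trajectory_set"), inherits(optics, "optics_config"))
  dt_samp <- ts$times[2] - ts$times[1]
  if (dt_samp > optics$line_period_s + 1e-12)
    stop("trajectory sampling must be at least as fine as the line period")
  t_max <- max(ts$times)
  if (is.null(n_lines)) n_lines <- floor(t_max / optics$line_period_s) + 1L
  line_times <- (seq_len(n_lines) - 1L) * optics$line_period_s
  if (line_times[n_lines] > t_max + 1e-9)
    stop("n_lines exceeds the simulated span")
  L_nm <- ts$substrate$length * ts$substrate$rise_per_bp
  npx <- ceiling(L_nm / optics$pixel_size_nm)
  edges <- (0:npx) * optics$pixel_size_nm
  sigma <- .psf_sigma(optics)
  bg <- optics$background_rate * optics$pixel_dwell_s
  amp <- optics$photon_rate * optics$pixel_dwell_s
  samp_idx <- findInterval(line_times + 1e-12, ts$times)
  counts <- matrix(0L, n_lines, npx)
  for (li in seq_len(n_lines)) {
    x <- .emitters_at(ts, samp_idx[li])
    mu <- rep(bg, npx)
    if (length(x)) {
      mu <- mu + amp * colSums(.emitter_masses(x, edges, sigma))
    }
    counts[li, ] <- stats::rpois(npx, mu)
  }
  structure(list(counts = counts, line_times_s = line_times,
                 pixel_centers_nm = edges[-1] - optics$pixel_size_nm / 2,
                 optics = optics),
            class = "kymograph_image")
}

#' Render a 2D confocal scan frame
#'
#' Scans `n_lines` parallel lines across the DNA axis, one line period per
#' line; rows are transverse offsets from the axis, columns positions along
#' the DNA. The photon model matches [render_kymograph()] with an
#' additional transverse Gaussian factor of the same sigma (emitters sit on
#' the axis). The frame time is `n_lines * line_period_s`.
#'
#' @param ts A `trajectory_set`.
#' @param t0 Frame start time (s), within the simulated span.
#' @param optics An [optics_config()].
#' @param n_lines Number of scan rows (odd keeps the axis centred).
#' @return A `scan_image`: `counts` (rows x pixels), `row_offsets_nm`,
#'   `pixel_centers_nm`, `t0_s`, `frame_time_s`, optics echo.
#' @export
render_scan <- function(ts, t0 = 0, optics = optics_config(), n_lines = 21) {
  stopifnot(inherits(ts, "trajectory_set"), inherits(optics, "optics_config"))
  frame_time <- n_lines * optics$line_period_s
  if (t0 < min(ts$times) || t0 + frame_time > max(ts$times) + 1e-9)
    stop("frame [t0, t0 + n_lines * line_period] outside the simulated span")
  L_nm <- ts$substrate$length * ts$substrate$rise_per_bp
  npx <- ceiling(L_nm / optics$pixel_size_nm)
  edges <- (0:npx) * optics$pixel_size_nm
  sigma <- .psf_sigma(optics)
  px <- optics$pixel_size_nm
  offsets <- (seq_len(n_lines) - (n_lines + 1) / 2) * px
  row_mass <- stats::pnorm(offsets + px / 2, 0, sigma) -
    stats::pnorm(offsets - px / 2, 0, sigma)
  row_mass[abs(offsets) > 4 * sigma] <- 0
  bg <- optics$background_rate * optics$pixel_dwell_s
  amp <- optics$photon_rate * optics$pixel_dwell_s
  counts <- matrix(0L, n_lines, npx)
  for (r in seq_len(n_lines)) {
    t_line <- t0 + (r - 1L) * optics$line_period_s
    x <- .emitters_at(ts, findInterval(t_line + 1e-12, ts$times))
    mu <- rep(bg, npx)
    if (length(x)) {
      mu <- mu + amp * row_mass[r] * colSums(.emitter_masses(x, edges, sigma))
    }
    counts[r, ] <- stats::rpois(npx, mu)
  }
  structure(list(counts = counts, row_offsets_nm = offsets,
                 pixel_centers_nm = edges[-1] - px / 2,
                 t0_s = t0, frame_time_s = frame_time, optics = optics),
            class = "scan_image")
}

#' @export
print.kymograph_image <- function(x, ...) {
  cat(sprintf("<kymograph_image> %d lines x %d px, line period %.3g s\n",
              nrow(x$counts), ncol(x$counts), x$optics$line_period_s))
  invisible(x)
}

#' @export
print.scan_image <- function(x, ...) {
  cat(sprintf("<scan_image> %d rows x %d px, frame %.3g s at t0 = %.3g s\n",
              nrow(x$counts), ncol(x$counts), x$frame_time_s, x$t0_s))
  invisible(x)
}
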