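# Worm-like-chain mechanics for magnetic-tweezers assays: Marko-Siggia
# interpolation force-extension law, two-parameter (Lp, Lc) fitting with a
# deterministic multi-start grid, the +/-15% contour-length quality filter,
# equipartition force calibration from bead excursions, condensation
# time-course metrics, and synthetic generators.

#' Thermal energy kB*T in pN nm
#'
#' @param temperature_K Temperature in kelvin.
#' @return kB*T in pN nm (4.114 pN nm at 298 K).
#' @export
kBT_pN_nm <- function(temperature_K = 298) {
  0.01380649 * temperature_K
}

#' Worm-like-chain force at a relative extension
#'
#' Marko-Siggia interpolation:
#' `F = (kBT / Lp) * (1 / (4 (1 - x/Lc)^2) - 1/4 + x/Lc)`.
#' The enthalpic stretching correction is negligible below 5 pN and is not
#' included.
#'
#' @param x_over_Lc Relative extension in `[0, 1)`.
#' @param Lp_nm Persistence length, nm.
#' @param temperature_K Temperature, K.
#' @return Force in pN.
#' @examples
#' wlc_force(0.5, 50)  # ~0.103 pN at 298 K
#' @export
wlc_force <- function(x_over_Lc, Lp_nm = 50, temperature_K = 298) {
  stopifnot(Lp_nm > 0)
  if (any(x_over_Lc < 0) || any(x_over_Lc >= 1))
    stop("x/Lc must lie in [0, 1)")
  (kBT_pN_nm(temperature_K) / Lp_nm) *
    (0.25 / (1 - x_over_Lc)^2 - 0.25 + x_over_Lc)
}

#' Worm-like-chain extension at a force
#'
#' Numerical inverse of [wlc_force()] by monotone bisection (relative
#' tolerance 1e-9 on x/Lc).
#'
#' @param force_pN Force in pN (>= 0).
#' @param Lp_nm Persistence length, nm.
#' @param Lc_um Contour length, um.
#' @param temperature_K Temperature, K.
#' @return Extension in um.
#' @export
wlc_extension <- function(force_pN, Lp_nm = 50, Lc_um = 1,
                          temperature_K = 298) {
  stopifnot(all(force_pN >= 0), Lp_nm > 0, Lc_um > 0)
  f <- force_pN
  lo <- rep(0, length(f))
  hi <- rep(1 - 1e-12, length(f))
  for (i in 1:60) {  # 2^-60 < the 1e-9 relative tolerance
    mid <- (lo + hi) / 2
    below <- wlc_force(mid, Lp_nm, temperature_K) < f
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  z <- (lo + hi) / 2
  z[f == 0] <- 0
  z * Lc_um
}

#' Construct a force-extension curve object
#'
#' @param force_pN Forces, pN (typically a descending 5 to 0.01 pN ramp).
#' @param extension_um Measured extensions, um (one per force).
#' @param molecule_id Identifier.
#' @param condition Condition label.
#' @return A `force_extension_curve` data frame.
#' @export
force_extension_curve <- function(force_pN, extension_um,
                                  molecule_id = "mol1", condition = "") {
  stopifnot(length(force_pN) == length(extension_um), all(force_pN > 0))
  out <- data.frame(force_pN = force_pN, extension_um = extension_um)
  attr(out, "molecule_id") <- molecule_id
  attr(out, "condition") <- condition
  class(out) <- c("force_extension_curve", "data.frame")
  out
}

#' Fit the worm-like-chain model to a force-extension curve
#'
#' Least squares on extension residuals over (Lp, Lc), using a fixed
#' multi-start grid (Lp in {30, 50, 70} nm, Lc in {0.8, 1.0, 1.2} times
#' the maximum measured extension) so the result is deterministic. Only
#' points at or below 5 pN enter the fit (at least 5 required).
#'
#' @param curve A `force_extension_curve` (or data frame with `force_pN`,
#'   `extension_um`).
#' @param temperature_K Temperature, K.
#' @param max_force_pN Upper force bound for points entering the fit.
#' @return A `wlc_fit`: list with `Lp_nm`, `Lc_um`, `residual_norm`,
#'   `converged`, `accepted` (`NA` until [filter_contour()] is applied).
#' @export
fit_wlc <- function(curve, temperature_K = 298, max_force_pN = 5) {
  sel <- curve$force_pN <= max_force_pN
  if (sum(sel) < 5) stop("need >= 5 points at or below ", max_force_pN, " pN")
  f <- curve$force_pN[sel]
  x <- curve$extension_um[sel]
  resid_fn <- function(par) {
    wlc_extension(f, par[1], par[2], temperature_K) - x
  }
  starts <- expand.grid(Lp = c(30, 50, 70),
                        Lc = c(0.8, 1.0, 1.2) * max(x))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    fit <- try(minpack.lm::nls.lm(
      par = c(starts$Lp[k], starts$Lc[k]), fn = resid_fn,
      lower = c(1, max(x) * 1.0000001),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("WLC fit failed at every grid start")
  structure(list(Lp_nm = best$par[1], Lc_um = best$par[2],
                 residual_norm = sqrt(best$deviance),
                 converged = best$info %in% 1:4,
                 accepted = NA),
            class = "wlc_fit")
}

#' @export
print.wlc_fit <- function(x, ...) {
  cat(sprintf("<wlc_fit> Lp = %.3g nm, Lc = %.4g um (resid %.3g, %s)\n",
              x$Lp_nm, x$Lc_um, x$residual_norm,
              if (isTRUE(x$converged)) "converged" else "not converged"))
  invisible(x)
}

#' Contour-length quality filter
#'
#' Accepts a fit when the fitted contour length lies within a +/- `tol`
#' (default 15%, boundary inclusive) relative band around the expected
#' crystallographic contour length (substrate bp times 0.34 nm/bp).
#'
#' @param fit A `wlc_fit`.
#' @param expected_Lc_um Expected contour length, um.
#' @param tol Relative tolerance.
#' @return Logical: accepted or not.
#' @export
filter_contour <- function(fit, expected_Lc_um, tol = 0.15) {
  stopifnot(expected_Lc_um > 0)
  # inclusive boundary, robust to floating-point representation of 15%
  abs(fit$Lc_um - expected_Lc_um) / expected_Lc_um <= tol + 1e-12
}

#' Force from Brownian bead excursions (equipartition)
#'
#' Inverted-pendulum calibration: `F = kBT * extension / <x^2>`, where
#' `<x^2>` is the transverse mean squared excursion of the bead.
#'
#' @param mean_sq_excursion_nm2 Transverse mean squared excursion, nm^2.
#' @param extension_nm Tether extension, nm.
#' @param temperature_K Temperature, K.
#' @return Force in pN.
#' @export
force_from_excursions <- function(mean_sq_excursion_nm2, extension_nm,
                                  temperature_K = 298) {
  if (mean_sq_excursion_nm2 <= 0) stop("mean squared excursion must be > 0")
  stopifnot(extension_nm > 0)
  kBT_pN_nm(temperature_K) * extension_nm / mean_sq_excursion_nm2
}

#' Condensation metrics from an extension time course
#'
#' Hold-force time course after lowering the force: the condensed fraction
#' is `1 - plateau / naked` (plateau = median extension over the final
#' `hold_s`), the initial rate is minus the least-squares extension slope
#' over the first `rate_window_s`, and the verdict is condensed when the
#' extension deficit exceeds `deficit_threshold` for a sustained `hold_s`.
#' The thresholds are analysis constants, not measured quantities.
#'
#' @param trace Data frame with `time_s` and `extension_um` (>= 60 s).
#' @param naked_extension_um Extension of the naked tether at the hold
#'   force, um.
#' @param deficit_threshold Fractional extension deficit for the verdict.
#' @param hold_s Sustain time, s.
#' @param rate_window_s Window for the initial-rate slope, s.
#' @return List with `condensed_fraction`, `initial_rate_nm_s`,
#'   `condensed`.
#' @export
condensation_metrics <- function(trace, naked_extension_um,
                                 deficit_threshold = 0.25, hold_s = 30,
                                 rate_window_s = 30) {
  stopifnot(naked_extension_um > 0)
  t <- trace$time_s
  ext <- trace$extension_um
  if (max(t) - min(t) < 60) stop("trace must span at least 60 s")
  tail_sel <- t >= max(t) - hold_s
  plateau <- stats::median(ext[tail_sel])
  fraction <- 1 - plateau / naked_extension_um
  head_sel <- t <= min(t) + rate_window_s
  slope <- stats::coef(stats::lm(ext[head_sel] ~ t[head_sel]))[2]
  deficit <- 1 - ext / naked_extension_um
  below <- deficit > deficit_threshold
  dt <- stats::median(diff(t))
  r <- rle(below)
  condensed <- any(r$values & r$lengths * dt >= hold_s)
  list(condensed_fraction = fraction,
       initial_rate_nm_s = -unname(slope) * 1000,
       condensed = condensed)
}

#' Largest force at which protein-bound DNA is condensed
#'
#' Compares a measured force-extension curve against the WLC prediction of
#' a reference (naked-DNA) fit and returns the largest sampled force at
#' which the measured extension falls short of the prediction by more than
#' `deficit_threshold`; 0 when no force qualifies. Raising the threshold
#' can only lower the returned force.
#'
#' @param curve A `force_extension_curve` measured with protein.
#' @param ref_fit The naked-DNA `wlc_fit` of the same molecule.
#' @param deficit_threshold Fractional extension deficit.
#' @param temperature_K Temperature, K.
#' @return Force in pN (0 when never condensed).
#' @export
max_condensation_force <- function(curve, ref_fit, deficit_threshold = 0.25,
                                   temperature_K = 298) {
  stopifnot(length(curve$force_pN) >= 3)
  pred <- wlc_extension(curve$force_pN, ref_fit$Lp_nm, ref_fit$Lc_um,
                        temperature_K)
  qual <- curve$extension_um < (1 - deficit_threshold) * pred
  if (!any(qual)) return(0)
  max(curve$force_pN[qual])
}

#' Synthetic force-extension curve generator
#'
#' Evaluates the WLC at a descending force ramp (default 5 to 0.01 pN),
#' optionally applies multiplicative extension noise, and optionally
#' imposes a phenomenological condensed branch (extension scaled by
#' `condensed_factor` below `condensed_below_pN`). There is no mechanistic
#' condensation model; the condensed branch is a construction for testing
#' detection logic.
#'
#' @param Lp_nm,Lc_um WLC parameters.
#' @param forces_pN Force ladder, pN.
#' @param noise_frac Multiplicative noise SD on extensions.
#' @param condensed_below_pN Force below which the tether is condensed
#'   (`NULL` = naked).
#' @param condensed_factor Extension multiplier on the condensed branch.
#' @param temperature_K Temperature, K.
#' @param seed Integer seed (`NULL` leaves the RNG untouched).
#' @return A `force_extension_curve`.
#' @export
simulate_force_extension <- function(Lp_nm = 50, Lc_um = 2,
                                     forces_pN = NULL, noise_frac = 0,
                                     condensed_below_pN = NULL,
                                     condensed_factor = 0.4,
                                     temperature_K = 298, seed = NULL) {
  if (is.null(forces_pN))
    forces_pN <- exp(seq(log(5), log(0.01), length.out = 25))
  if (!is.null(seed)) set.seed(as.integer(seed))
  ext <- wlc_extension(forces_pN, Lp_nm, Lc_um, temperature_K)
  if (!is.null(condensed_below_pN))
    ext[forces_pN < condensed_below_pN] <-
      ext[forces_pN < condensed_below_pN] * condensed_factor
  if (noise_frac > 0)
    ext <- ext * (1 + stats::rnorm(length(ext), 0, noise_frac))
  force_extension_curve(forces_pN, ext)
}

#' Synthetic condensation time course at a hold force
#'
#' Exponential extension decay towards a plateau with additive Gaussian
#' noise; `plateau_fraction = 1` gives a flat naked-DNA control.
#'
#' @param naked_extension_um Naked-tether extension at the hold force, um.
#' @param rate_per_s Decay rate, 1/s.
#' @param plateau_fraction Final extension as a fraction of naked.
#' @param noise_nm Additive noise SD, nm.
#' @param duration_s,rate_hz Span and sampling rate.
#' @param hold_force_pN Hold force label, pN.
#' @param seed Integer seed.
#' @return Data frame with `time_s`, `extension_um`; hold force attached
#'   as an attribute.
#' @export
simulate_condensation_trace <- function(naked_extension_um,
                                        rate_per_s = 0.05,
                                        plateau_fraction = 0.3,
                                        noise_nm = 10, duration_s = 300,
                                        rate_hz = 10, hold_force_pN = 0.33,
                                        seed = 1L) {
  set.seed(as.integer(seed))
  t <- seq(0, duration_s, by = 1 / rate_hz)
  ext <- naked_extension_um *
    (plateau_fraction + (1 - plateau_fraction) * exp(-rate_per_s * t)) +
    stats::rnorm(length(t), 0, noise_nm / 1000)
  out <- data.frame(time_s = t, extension_um = ext)
  attr(out, "hold_force_pN") <- hold_force_pN
  class(out) <- c("condensation_trace", "data.frame")
  out
}

#' Synthetic transverse bead fluctuations under tension
#'
#' Ornstein-Uhlenbeck transverse position of a magnetically pulled bead:
#' the stationary variance follows equipartition,
#' `<x^2> = kBT * extension / F`, so [force_from_excursions()] applied to
#' the generated trace recovers the force.
#'
#' @param force_pN Applied force, pN.
#' @param Lp_nm,Lc_um WLC parameters fixing the extension at that force.
#' @param duration_s,rate_hz Span and sampling rate.
#' @param correlation_time_s Relaxation time, s.
#' @param temperature_K Temperature, K.
#' @param seed Integer seed.
#' @return Data frame with `time_s`, `x_nm`; the tether extension (nm) is
#'   attached as attribute `extension_nm`.
#' @export
simulate_magnet_bead <- function(force_pN, Lp_nm = 50, Lc_um = 2,
                                 duration_s = 300, rate_hz = 120,
                                 correlation_time_s = 0.05,
                                 temperature_K = 298, seed = 1L) {
  stopifnot(force_pN > 0)
  set.seed(as.integer(seed))
  ext_nm <- wlc_extension(force_pN, Lp_nm, Lc_um, temperature_K) * 1000
  sd_nm <- sqrt(kBT_pN_nm(temperature_K) * ext_nm / force_pN)
  n <- round(duration_s * rate_hz)
  phi <- exp(-1 / (rate_hz * correlation_time_s))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd_nm)
  innov <- stats::rnorm(n - 1L, 0, sd_nm * sqrt(1 - phi^2))
  for (i in 2:n) x[i] <- phi * x[i - 1L] + innov[i - 1L]
  out <- data.frame(time_s = (seq_len(n) - 1L) / rate_hz, x_nm = x)
  attr(out, "extension_nm") <- ext_nm
  out
}

#' Write / read a force-extension curve as TSV
#'
#' @param curve A `force_extension_curve`.
#' @param path File path.
#' @return `write_force_extension` returns `path` invisibly;
#'   `read_force_extension` returns a `force_extension_curve`.
#' @export
write_force_extension <- function(curve, path) {
  utils::write.table(curve, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_force_extension
#' @export
read_force_extension <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  need <- c("force_pN", "extension_um")
  if (!all(need %in% names(df)))
    stop("missing column(s) in ", path, ": ",
         paste(setdiff(need, names(df)), collapse = ", "))
  force_extension_curve(df$force_pN, df$extension_um)
}
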