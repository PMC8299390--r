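# Stochastic simulation of the three-step ParB mechanism: open-clamp
# binding at parS (CTP-independent), CTP-gated conversion to a diffusing
# sliding clamp, 1D Brownian motion along the DNA contour with reflecting
# roadblocks/ends, unbinding, and photobleaching under illumination.
# Fixed-timestep Brownian dynamics; state transitions fire as per-step
# exponential clocks, P = 1 - exp(-rate * dt).

SIM_CONDITIONS <- c("apo", "CTP", "CTPgammaS", "CDP", "EDTA")
SIM_VARIANTS <- c("WT", "R80A", "R149G")

# state codes used in trajectory matrices
STATE_LEVELS <- c("parS_bound", "clamp", "bleached", "detached")

#' Simulation configuration for the ParB clamp simulator
#'
#' Rates are first-order (1/s) except `load_rate`, which applies per vacant
#' parS site. Absolute loading/unbinding rates are free parameters of the
#' model (not measured quantities); defaults are chosen to give stable parS
#' occupancy over tens of seconds with sparse clamps on non-specific DNA.
#'
#' @param condition Nucleotide condition, one of `"apo"`, `"CTP"`,
#'   `"CTPgammaS"`, `"CDP"`, `"EDTA"`.
#' @param variant Protein variant, one of `"WT"`, `"R80A"` (no CTP
#'   binding), `"R149G"` (no parS binding).
#' @param load_rate Loading events per second per vacant parS site.
#' @param convert_rate Open-clamp to sliding-clamp conversion rate (1/s);
#'   requires CTP (or CTPgammaS) and Mg2+.
#' @param D Sliding-clamp diffusion constant, um^2/s.
#' @param unbind_rate Clamp unbinding rate from non-specific DNA (1/s).
#' @param parS_unbind_rate Open-clamp unbinding rate from parS (1/s).
#' @param unload_rate Optional hydrolysis-driven unloading (1/s), acting only
#'   under CTP; 0 by default (hydrolysis is not required for sliding).
#' @param bleach_rate Photobleaching rate under illumination (1/s).
#' @param illumination_start Time (s) at which illumination begins.
#' @param dt Integration step (s).
#' @param duration Simulated time (s).
#' @param seed Integer seed; identical config + substrate reproduce
#'   identical trajectories.
#' @param roadblocks_active Whether bound roadblocks reflect clamps.
#' @param end_behavior `"reflect"` (DNA ends occluded by beads) or
#'   `"absorb"` (free ends: clamps slide off and detach).
#' @return A `sim_config` list.
#' @export
sim_config <- function(condition = "CTP", variant = "WT",
                       load_rate = 0.2, convert_rate = 0.5, D = 0.4,
                       unbind_rate = 0.05, parS_unbind_rate = 0.01,
                       unload_rate = 0, bleach_rate = 0.15,
                       illumination_start = 0, dt = 0.005, duration = 10,
                       seed = 1L, roadblocks_active = FALSE,
                       end_behavior = c("reflect", "absorb")) {
  condition <- match.arg(condition, SIM_CONDITIONS)
  variant <- match.arg(variant, SIM_VARIANTS)
  end_behavior <- match.arg(end_behavior)
  rates <- c(load_rate, convert_rate, unbind_rate, parS_unbind_rate,
             unload_rate, bleach_rate)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rates must be finite and >= 0")
  if (!is.finite(D) || D < 0) stop("D must be >= 0")
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  if (duration <= 0) stop("duration must be > 0")
  structure(list(condition = condition, variant = variant,
                 load_rate = load_rate, convert_rate = convert_rate, D = D,
                 unbind_rate = unbind_rate,
                 parS_unbind_rate = parS_unbind_rate,
                 unload_rate = unload_rate, bleach_rate = bleach_rate,
                 illumination_start = illumination_start, dt = dt,
                 duration = duration, seed = as.integer(seed),
                 roadblocks_active = isTRUE(roadblocks_active),
                 end_behavior = end_behavior),
            class = "sim_config")
}

#' Preset configuration for a nucleotide condition and protein variant
#'
#' Encodes the mechanistic constraints of the model: parS binding does not
#' require CTP, but conversion to a sliding clamp does (and needs Mg2+);
#' CTPgammaS behaves as CTP because hydrolysis is not required; CDP does
#' not bind ParB appreciably. `R149G` cannot bind parS (loading rate 0);
#' `R80A` cannot bind CTP (conversion rate 0).
#'
#' @inheritParams sim_config
#' @param ... Further arguments passed to [sim_config()].
#' @return A `sim_config`.
#' @examples
#' condition_preset("apo")$convert_rate    # 0
#' condition_preset("CTP", "R149G")$load_rate  # 0
#' @export
condition_preset <- function(condition, variant = "WT", ...) {
  cfg <- sim_config(condition = condition, variant = variant, ...)
  if (cfg$variant == "R149G") cfg$load_rate <- 0
  if (cfg$condition %in% c("apo", "CDP", "EDTA") || cfg$variant == "R80A")
    cfg$convert_rate <- 0
  if (cfg$condition != "CTP") cfg$unload_rate <- 0
  cfg
}

# reflect positions into [lo, hi] by folding (triangle wave); exact image
# method for Brownian paths
.reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  y <- ifelse(y > w, 2 * w - y, y)
  lo + y
}

# open segments of the substrate: complement of active roadblock footprints
.open_segments <- function(substrate, roadblocks_active) {
  L <- substrate$length
  rb <- substrate$sites[substrate$sites$kind == "roadblock", , drop = FALSE]
  if (!roadblocks_active || nrow(rb) == 0)
    return(data.frame(lo = 0, hi = L))
  lo <- c(0, rb$end)
  hi <- c(rb$start, L)
  keep <- hi > lo
  data.frame(lo = lo[keep], hi = hi[keep])
}

.sd_step_bp <- function(D, dt, rise) sqrt(2 * D * dt) * 1000 / rise

#' Simulate ParB loading, sliding and unbinding on a substrate
#'
#' Runs the mechanistic model on a [build_substrate()] map. Loading occurs
#' only at vacant parS sites (one open clamp per site); parS-bound ParB is
#' immobile; sliding clamps take Gaussian steps of variance `2 D dt` along
#' the contour; roadblocks (when active) and, by default, the DNA ends
#' reflect; unbinding removes clamps; photobleaching switches bound
#' particles dark after `illumination_start` without stopping their motion.
#'
#' The step size must satisfy `sqrt(2 D dt) <= 5%` of the substrate contour
#' length; violating `dt` is rejected.
#'
#' @param config A [sim_config()].
#' @param substrate A `substrate_map`.
#' @return A `trajectory_set`: list with the substrate, the config echo,
#'   `times` (uniform grid), position matrix `pos` (particles x times, bp),
#'   integer state matrix `state` (same shape; levels
#'   `parS_bound`, `clamp`, `bleached`, `detached`; `NA` before birth) and
#'   `birth_time`.
#' @export
simulate_parb <- function(config, substrate) {
  stopifnot(inherits(config, "sim_config"), inherits(substrate, "substrate_map"))
  rise <- substrate$rise_per_bp
  sd_bp <- .sd_step_bp(config$D, config$dt, rise)
  if (config$D > 0 && sd_bp > 0.05 * substrate$length)
    stop("dt too large: sqrt(2 D dt) exceeds 5% of the contour length")
  set.seed(config$seed)
  dt <- config$dt
  times <- seq(0, config$duration, by = dt)
  nt <- length(times)
  parS <- substrate$sites[substrate$sites$kind == "parS", , drop = FALSE]
  centers <- (parS$start + parS$end) / 2
  ns <- length(centers)
  segs <- .open_segments(substrate, config$roadblocks_active)

  cap <- max(16L, 4L * ns)
  pos <- matrix(NA_real_, cap, nt)
  st <- matrix(NA_integer_, cap, nt)
  loc <- integer(cap)        # 0 unborn, 1 parS-bound, 2 clamp, 3 off
  dark <- logical(cap)
  curpos <- numeric(cap)
  seg_lo <- numeric(cap)
  seg_hi <- numeric(cap)
  birth <- numeric(cap)
  site_of <- integer(cap)
  site_occ <- integer(ns)    # particle id occupying each parS site (0 = vacant)
  np <- 0L

  p_load <- 1 - exp(-config$load_rate * dt)
  r_pb <- config$convert_rate + config$parS_unbind_rate
  p_pb <- 1 - exp(-r_pb * dt)
  p_off <- 1 - exp(-(config$unbind_rate + config$unload_rate) * dt)
  p_bleach <- 1 - exp(-config$bleach_rate * dt)

  grow <- function(n_new) {
    while (np + n_new > cap) {
      cap2 <- 2L * cap
      pos2 <- matrix(NA_real_, cap2, nt); pos2[seq_len(cap), ] <- pos
      st2 <- matrix(NA_integer_, cap2, nt); st2[seq_len(cap), ] <- st
      pos <<- pos2; st <<- st2
      length(loc) <<- cap2; loc[is.na(loc)] <<- 0L
      length(dark) <<- cap2; dark[is.na(dark)] <<- FALSE
      length(curpos) <<- cap2; length(seg_lo) <<- cap2
      length(seg_hi) <<- cap2; length(birth) <<- cap2
      length(site_of) <<- cap2
      cap <<- cap2
    }
  }

  record <- function(t_idx) {
    if (np == 0L) return(invisible())
    idx <- seq_len(np)
    pos[idx, t_idx] <<- curpos[idx]
    code <- ifelse(loc[idx] == 3L, 4L, ifelse(dark[idx], 3L, loc[idx]))
    st[idx, t_idx] <<- code
  }

  record(1L)
  for (t in seq_len(nt - 1L) + 1L) {
    # loading at vacant parS sites
    if (ns > 0 && p_load > 0) {
      vac <- which(site_occ == 0L)
      if (length(vac)) {
        hit <- vac[stats::runif(length(vac)) < p_load]
        if (length(hit)) {
          grow(length(hit))
          ids <- np + seq_along(hit)
          np <- np + length(hit)
          curpos[ids] <- centers[hit]
          loc[ids] <- 1L
          dark[ids] <- FALSE
          birth[ids] <- times[t]
          site_of[ids] <- hit
          site_occ[hit] <- ids
        }
      }
    }
    # parS-bound: convert to clamp or unbind (competing exponentials)
    pb <- which(loc[seq_len(np)] == 1L)
    if (length(pb) && p_pb > 0) {
      ev <- pb[stats::runif(length(pb)) < p_pb]
      if (length(ev)) {
        conv <- stats::runif(length(ev)) < config$convert_rate / r_pb
        site_occ[site_of[ev]] <- 0L
        cv <- ev[conv]
        if (length(cv)) {
          loc[cv] <- 2L
          si <- findInterval(curpos[cv], segs$lo)
          seg_lo[cv] <- segs$lo[si]
          seg_hi[cv] <- segs$hi[si]
        }
        loc[ev[!conv]] <- 3L
      }
    }
    # clamps diffuse (reflected in their open segment) and may unbind
    cl <- which(loc[seq_len(np)] == 2L)
    if (length(cl)) {
      x <- curpos[cl] + stats::rnorm(length(cl), 0, sd_bp)
      if (config$end_behavior == "absorb") {
        at_end_lo <- seg_lo[cl] <= 0 & x < seg_lo[cl]
        at_end_hi <- seg_hi[cl] >= substrate$length & x > seg_hi[cl]
        gone <- at_end_lo | at_end_hi
        x <- .reflect_into(x, seg_lo[cl], seg_hi[cl])
        curpos[cl] <- x
        if (any(gone)) loc[cl[gone]] <- 3L
        cl <- cl[!gone]
      } else {
        curpos[cl] <- .reflect_into(x, seg_lo[cl], seg_hi[cl])
      }
      if (length(cl) && p_off > 0) {
        off <- cl[stats::runif(length(cl)) < p_off]
        loc[off] <- 3L
      }
    }
    # photobleaching of bound particles under illumination
    if (p_bleach > 0 && times[t] >= config$illumination_start) {
      lit <- which(loc[seq_len(np)] %in% c(1L, 2L) & !dark[seq_len(np)])
      if (length(lit)) {
        bl <- lit[stats::runif(length(lit)) < p_bleach]
        dark[bl] <- TRUE
      }
    }
    record(t)
  }

  keep <- seq_len(np)
  structure(list(substrate = substrate, config = config, times = times,
                 pos = pos[keep, , drop = FALSE],
                 state = st[keep, , drop = FALSE],
                 birth_time = birth[keep],
                 state_levels = STATE_LEVELS),
            class = "trajectory_set")
}

#' Simulate an ensemble of freely sliding clamps
#'
#' Ground-truth generator for diffusion-recovery studies: `n` sliding
#' clamps, present from t = 0 at `start_bp` (default: the substrate
#' midpoint), diffusing with constant `D` and no unbinding or bleaching.
#' Reflected Brownian motion is generated exactly by folding a free
#' Brownian path into the interval.
#'
#' @param n Number of clamps.
#' @param D Diffusion constant, um^2/s.
#' @param duration,dt Time span and sampling step (s).
#' @param substrate A `substrate_map`, or `NULL` to use a featureless map of
#'   `length_bp`.
#' @param length_bp Substrate length when `substrate` is `NULL`.
#' @param start_bp Initial position (bp); default midpoint.
#' @param seed Integer seed.
#' @return A `trajectory_set` (all states `"clamp"`).
#' @export
simulate_clamps <- function(n, D, duration = 2.5, dt = 0.005,
                            substrate = NULL, length_bp = 48502,
                            start_bp = NULL, seed = 1L) {
  if (is.null(substrate)) substrate <- .bare_substrate(length_bp)
  L <- substrate$length
  if (is.null(start_bp)) start_bp <- L / 2
  stopifnot(n >= 1, D >= 0, duration > 0, dt > 0,
            start_bp >= 0, start_bp <= L)
  set.seed(as.integer(seed))
  times <- seq(0, duration, by = dt)
  nt <- length(times)
  sd_bp <- .sd_step_bp(D, dt, substrate$rise_per_bp)
  steps <- matrix(stats::rnorm(n * (nt - 1L), 0, sd_bp), n, nt - 1L)
  free <- cbind(rep(start_bp, n),
                start_bp + t(apply(steps, 1, cumsum)))
  pos <- .reflect_into(free, 0, L)
  cfg <- sim_config(D = D, dt = dt, duration = duration, seed = seed,
                    load_rate = 0, convert_rate = 0, unbind_rate = 0,
                    parS_unbind_rate = 0, bleach_rate = 0)
  structure(list(substrate = substrate, config = cfg, times = times,
                 pos = pos,
                 state = matrix(2L, n, nt),
                 birth_time = rep(0, n),
                 state_levels = STATE_LEVELS),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> %d particle(s), %d samples over %.3g s on %s\n",
              nrow(x$pos), length(x$times), max(x$times), x$substrate$name))
  invisible(x)
}

#' Tidy data frame view of a trajectory set
#'
#' @param x A `trajectory_set`.
#' @param ... Unused.
#' @return Data frame with `particle_id`, `time_s`, `position_bp`, `state`,
#'   one row per particle per sample after its birth.
#' @export
as.data.frame.trajectory_set <- function(x, ...) {
  n <- nrow(x$pos)
  if (n == 0) {
    return(data.frame(particle_id = integer(0), time_s = numeric(0),
                      position_bp = numeric(0), state = character(0)))
  }
  out <- data.frame(
    particle_id = rep(seq_len(n), times = length(x$times)),
    time_s = rep(x$times, each = n),
    position_bp = as.vector(x$pos),
    state = x$state_levels[as.vector(x$state)])
  out <- out[!is.na(out$position_bp), , drop = FALSE]
  out <- out[order(out$particle_id, out$time_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean occupancy profile of a trajectory set
#'
#' Bins the DNA in `bin`-bp windows and reports the time-averaged count of
#' bound particles (parS-bound, sliding or bleached-but-bound) per bp, so
#' that `sum(profile * bin)` equals the mean number of bound particles.
#'
#' @param ts A `trajectory_set`.
#' @param bin Bin width in bp (>= 1).
#' @return Data frame with `start_bp`, `end_bp`, `occupancy_per_bp`.
#' @export
occupancy_profile <- function(ts, bin = 50) {
  stopifnot(inherits(ts, "trajectory_set"), bin >= 1)
  L <- ts$substrate$length
  edges <- seq(0, L, by = bin)
  if (edges[length(edges)] < L) edges <- c(edges, L)
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  bound <- !is.na(ts$state) & ts$state %in% c(1L, 2L, 3L)
  if (any(bound)) {
    x <- ts$pos[bound]
    bi <- findInterval(x, edges, rightmost.closed = TRUE)
    bi[bi < 1L] <- 1L
    bi[bi > nb] <- nb
    tab <- tabulate(bi, nbins = nb)
    counts <- tab / length(ts$times)
  }
  widths <- diff(edges)
  data.frame(start_bp = edges[-length(edges)], end_bp = edges[-1],
             occupancy_per_bp = counts / widths)
}

#' Write / read a trajectory set as tidy TSV
#'
#' The TSV has columns `particle_id`, `time_s`, `position_bp`, `state`; a
#' JSON sidecar (`<path>.json`) echoes the configuration and seed.
#'
#' @param ts A `trajectory_set`.
#' @param path File path for the TSV.
#' @return `write_trajectory_set` returns `path` invisibly;
#'   `read_trajectory_tsv` returns the tidy data frame.
#' @export
write_trajectory_set <- function(ts, path) {
  df <- as.data.frame(ts)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- ts$config
  side$substrate_name <- ts$substrate$name
  jsonlite::write_json(unclass(side), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trajectory_set
#' @export
read_trajectory_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(particle_id = "integer",
                                         time_s = "numeric",
                                         position_bp = "numeric",
                                         state = "character"))
  need <- c("particle_id", "time_s", "position_bp", "state")
  if (!all(need %in% names(df)))
    stop("missing column(s) in ", path, ": ",
         paste(setdiff(need, names(df)), collapse = ", "))
  df
}
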