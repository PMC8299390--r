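# End-to-end pipeline binding the three experiment archetypes:
#   ctrap - simulate, render a kymograph, track, MSD, ensemble D
#   mt    - condensation time courses at a hold force vs a naked control
#   tpm   - tethered-bead trace, windowed RMS, condensation verdict
# One root seed drives derived per-stage seeds so each stage is
# independently reproducible.

.derived_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}

#' Default configuration for a pipeline run
#'
#' @param archetype `"ctrap"`, `"mt"` or `"tpm"`.
#' @param substrate Substrate name (see [substrate_names()]).
#' @param condition,variant Passed to [condition_preset()].
#' @param seed Root seed; all stage seeds derive from it.
#' @param outdir Output directory (`NULL` = return results only).
#' @param sim,optics,track,tpm,mt Named lists of stage-parameter overrides.
#' @return A `run_config` list.
#' @export
run_config <- function(archetype = c("ctrap", "mt", "tpm"),
                       substrate = "39x_parS", condition = "CTP",
                       variant = "WT", seed = 1L, outdir = NULL,
                       sim = list(), optics = list(), track = list(),
                       tpm = list(), mt = list()) {
  archetype <- match.arg(archetype)
  if (!substrate %in% substrate_names())
    stop("unknown substrate '", substrate, "'")
  structure(list(archetype = archetype, substrate = substrate,
                 condition = condition, variant = variant,
                 seed = as.integer(seed), outdir = outdir, sim = sim,
                 optics = optics, track = track, tpm = tpm, mt = mt),
            class = "run_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path A `.yaml`/`.yml` or `.json` file with [run_config()] fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is needed to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(run_config, cfg)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

.write_if <- function(outdir, fn) if (!is.null(outdir)) fn()

#' Run one experiment archetype end to end
#'
#' Executes the stages of the chosen archetype in order (simulate, render,
#' analyze), returns a summary list, and, when `outdir` is set, persists
#' every intermediate (trajectories TSV, kymograph ASCII + sidecar, bead
#' traces, JSON summary) so each summary number is recomputable from the
#' files alone. A log of every defaulted parameter is included in the
#' summary. Identical configurations produce identical results.
#'
#' @param config A [run_config()].
#' @return A summary list; archetype-dependent fields (see Details).
#' @details
#' `ctrap`: `n_tracks`, `n_mobile`, `D_mean_um2_s`, `D_sem_um2_s` over the
#' mobile tracks.
#' `mt`: `n_molecules`, `n_condensed`, `condensed_fraction_mean`,
#' `naked_extension_um`.
#' `tpm`: `condensed`, `onset_s`, `mean_rms_tau_nm`, `rms_full_nm`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  map <- .stage("substrate", build_substrate(config$substrate))
  n_parS <- sum(map$sites$kind == "parS")
  preset_args <- utils::modifyList(
    list(condition = config$condition, variant = config$variant,
         seed = .derived_seed(config$seed, 1)),
    config$sim)
  cfg <- .stage("preset", do.call(condition_preset, preset_args))
  licensed <- cfg$load_rate > 0 && cfg$convert_rate > 0

  summary <- switch(
    config$archetype,
    ctrap = {
      # QD-style tracking: bright non-bleaching emitters
      opt <- .stage("optics", do.call(qd_optics, config$optics))
      cfg$bleach_rate <- config$sim$bleach_rate %||% 0
      ts <- .stage("simulate", simulate_parb(cfg, map))
      kymo <- .stage("render", {
        set.seed(.derived_seed(config$seed, 2))
        render_kymograph(ts, opt)
      })
      track_args <- utils::modifyList(
        list(threshold = 5, max_jump_um = 0.5, min_length = 20),
        config$track)
      tracks <- .stage("track", do.call(track_kymograph,
                                        c(list(kymo), track_args)))
      ests <- list()
      mobile <- logical(0)
      for (tr in tracks) {
        est <- try(fit_diffusion(compute_msd(tr)), silent = TRUE)
        if (inherits(est, "try-error")) next
        ests[[length(ests) + 1L]] <- est
        mobile <- c(mobile, !is_immobile_at_parS(tr, est, map))
      }
      Dm <- vapply(ests, function(e) e$D_um2_s, numeric(1))[mobile]
      ens <- if (length(Dm) >= 2) ensemble_D(Dm) else
        list(mean_D = NA_real_, sem_D = NA_real_, n = length(Dm))
      .write_if(outdir, function() {
        write_trajectory_set(ts, file.path(outdir, "trajectories.tsv"))
        write_kymograph(kymo, file.path(outdir, "kymograph.txt"))
      })
      list(archetype = "ctrap", n_tracks = length(tracks),
           n_mobile = sum(mobile), D_mean_um2_s = ens$mean_D,
           D_sem_um2_s = ens$sem_D)
    },
    mt = {
      mt_args <- utils::modifyList(
        list(n_molecules = 6, hold_force_pN = 0.33, rate_per_s = 0.05,
             plateau_fraction = 0.3, noise_nm = 10, duration_s = 300,
             Lp_nm = 50, min_parS = 5), config$mt)
      Lc_um <- map$length * map$rise_per_bp / 1000
      naked <- wlc_extension(mt_args$hold_force_pN, mt_args$Lp_nm, Lc_um)
      # condensation requires licensed clamp loading and enough parS to
      # beat the restraining force (no printed rate law; phenomenological)
      condensing <- licensed && n_parS >= mt_args$min_parS
      res <- lapply(seq_len(mt_args$n_molecules), function(i) {
        tr <- simulate_condensation_trace(
          naked, rate_per_s = mt_args$rate_per_s,
          plateau_fraction = if (condensing) mt_args$plateau_fraction else 1,
          noise_nm = mt_args$noise_nm, duration_s = mt_args$duration_s,
          hold_force_pN = mt_args$hold_force_pN,
          seed = .derived_seed(config$seed, 10 + i))
        .write_if(outdir, function() {
          utils::write.table(tr, file.path(outdir,
                                           sprintf("mt_trace_%02d.tsv", i)),
                             sep = "\t", quote = FALSE, row.names = FALSE)
        })
        condensation_metrics(tr, naked)
      })
      fr <- vapply(res, function(r) r$condensed_fraction, numeric(1))
      list(archetype = "mt", n_molecules = mt_args$n_molecules,
           n_condensed = sum(vapply(res, function(r) r$condensed,
                                    logical(1))),
           condensed_fraction_mean = mean(fr),
           naked_extension_um = naked)
    },
    tpm = {
      tpm_args <- utils::modifyList(
        list(tau_s = 8.3, drift_nm_per_s = 0.5, step_time_s = 120,
             step_factor = 0.5, duration_s = 300, drop_fraction = 0.3,
             hold_s = 20), config$tpm)
      condensing <- licensed && n_parS >= 1
      trace <- simulate_bead_trace(
        tether_bp = map$length, drift_nm_per_s = tpm_args$drift_nm_per_s,
        step_time_s = if (condensing) tpm_args$step_time_s else NULL,
        step_factor = tpm_args$step_factor,
        duration_s = tpm_args$duration_s,
        seed = .derived_seed(config$seed, 20))
      series <- rms_windowed(trace, tpm_args$tau_s)
      verdict <- detect_condensation(series, tpm_args$drop_fraction,
                                     tpm_args$hold_s)
      .write_if(outdir, function() {
        write_bead_trace(trace, file.path(outdir, "bead_trace.tsv"))
      })
      list(archetype = "tpm", condensed = verdict$condensed,
           onset_s = verdict$onset_s,
           mean_rms_tau_nm = mean_rms_tau(series),
           rms_full_nm = rms_full(trace))
    })

  summary$substrate <- config$substrate
  summary$condition <- config$condition
  summary$variant <- config$variant
  summary$seed <- config$seed
  summary$defaults_log <- .defaults_log(config)
  .write_if(outdir, function() {
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(unclass(config), file.path(outdir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  })
  summary
}

# record every stage parameter the user did not set explicitly
.defaults_log <- function(config) {
  all_defaults <- list(
    sim = formals(sim_config), optics = formals(optics_config),
    track = list(threshold = 5, max_jump_um = 0.5, min_length = 20),
    tpm = list(tau_s = 8.3, drift_nm_per_s = 0.5, step_time_s = 120,
               step_factor = 0.5, duration_s = 300),
    mt = list(n_molecules = 6, hold_force_pN = 0.33, rate_per_s = 0.05,
              plateau_fraction = 0.3, noise_nm = 10, duration_s = 300))
  out <- list()
  for (blk in names(all_defaults)) {
    given <- names(config[[blk]])
    defs <- all_defaults[[blk]]
    unset <- setdiff(names(defs), given)
    vals <- lapply(defs[unset], function(v)
      if (is.language(v)) deparse(v) else v)
    out[[blk]] <- vals[!vapply(vals, is.null, logical(1))]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
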