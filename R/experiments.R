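#' Experiment run configuration
#'
#' Named experiments bundle the standard protocols end to end, fully
#' populated with their conventional defaults:
#' \describe{
#'   \item{`fig5b_apparent_motion`}{flicker responses at relative columns -1,
#'     0, +1 and nonlinear response components for the four two-step pairs
#'     (-1 to 0, 0 to -1, 0 to 1, 1 to 0); 450 ms pulses, 472 ms
#'     onset-to-onset.}
#'   \item{`fig5c_temporal_tuning`}{detector-array and tangential PD/ND
#'     amplitudes over a log-spaced 0.1-10 Hz grid (sine grating, wavelength
#'     50 deg, contrast 1), for the full and both ablated model variants.}
#'   \item{`fig5d_direction_tuning`}{array amplitudes for 12 directions
#'     spaced 30 deg apart at 1 Hz, for the three model variants.}
#'   \item{`fig3c_delay`}{PD and ND two-step responses versus onset delay
#'     (0-1.5 s in 59 ms steps, 472 ms pulses).}
#'   \item{`fig3e_pair_map`}{noiseless synthetic detector cell on the
#'     two-ring hexagonal raster: response to simultaneous center + other
#'     column stimulation, normalized to the center-alone response.}
#'   \item{`fig2_rf_synthetic`}{receptive-field mapping on synthetic
#'     calcium recordings (10 cells, T4 ring profile 1/0.5/0.25, noise sd
#'     0.2, 3 repetitions), averaged after alignment and normalization, with
#'     the three hexagonal axis profiles.}
#'   \item{`custom`}{runs the function supplied as `custom_fn(config)`.}
#' }
#'
#' @param experiment one of the names above.
#' @param variant model variant: `"full"`, `"no_enhancement"` or
#'   `"no_suppression"` (experiments that sweep all variants ignore this).
#' @param seed integer random seed (only the synthetic-recording experiments
#'   consume randomness; deterministic experiments record it unchanged).
#' @param out_dir output directory; `NULL` runs in memory without writing.
#' @param ... experiment-specific overrides (e.g. `frequencies_hz`,
#'   `directions_deg`, `onset_delays_s`, `n_cells`, `noise_sd`, `contrast`,
#'   `custom_fn`). Invalid values are rejected with the offending field named.
#' @return An object of class `run_config`.
#' @export
run_config <- function(experiment = c("fig5b_apparent_motion",
                                      "fig5c_temporal_tuning",
                                      "fig5d_direction_tuning",
                                      "fig3c_delay", "fig3e_pair_map",
                                      "fig2_rf_synthetic", "custom"),
                       variant = c("full", "no_enhancement", "no_suppression"),
                       seed = 1, out_dir = NULL, ...) {
  experiment <- match.arg(experiment)
  variant <- match.arg(variant)
  extra <- list(...)
  if (!is.null(extra$contrast) && (extra$contrast < 0 || extra$contrast > 1))
    stop("field `contrast`: must lie in [0, 1] (luminance bounds)")
  if (!is.null(extra$noise_sd) && extra$noise_sd < 0)
    stop("field `noise_sd`: must be nonnegative")
  if (!is.null(extra$n_cells) && extra$n_cells < 1)
    stop("field `n_cells`: must be at least 1")
  structure(list(experiment = experiment, variant = variant,
                 seed = as.integer(seed), out_dir = out_dir, extra = extra),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> %s (variant %s, seed %d)%s\n", x$experiment,
              x$variant, x$seed,
              if (is.null(x$out_dir)) "" else paste0(" -> ", x$out_dir)))
  invisible(x)
}

# resolved-config record written next to every run's outputs
resolve_config <- function(config, defaults) {
  resolved <- utils::modifyList(defaults, config$extra)
  list(experiment = config$experiment, variant = config$variant,
       seed = config$seed, parameters = resolved)
}

#' Run a named experiment end to end
#'
#' Executes the stimulus, front-end, detector and analysis chain (or the
#' synthetic-recording and analysis chain) for the configured experiment.
#' When `out_dir` is set, writes all traces/curves/maps as CSV with JSON
#' sidecars, the resolved configuration as `config.json`, and the numeric
#' summary as `summary.json`; identical configuration and seed reproduce all
#' outputs byte-identically.
#'
#' @param config a [run_config()].
#' @return Invisibly, a result bundle: list with `summary` (named numeric
#'   results) plus experiment-specific artifacts (traces, curves, maps) and
#'   the resolved config.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t_start <- proc.time()[["elapsed"]]
  res <- switch(config$experiment,
                fig5b_apparent_motion = exp_fig5b(config),
                fig5c_temporal_tuning = exp_fig5c(config),
                fig5d_direction_tuning = exp_fig5d(config),
                fig3c_delay = exp_fig3c(config),
                fig3e_pair_map = exp_fig3e(config),
                fig2_rf_synthetic = exp_fig2(config),
                custom = {
                  fn <- config$extra$custom_fn
                  if (!is.function(fn))
                    stop("field `custom_fn`: a custom experiment needs a function")
                  fn(config)
                })
  res$config <- resolve_config(config, res$defaults %||% list())
  res$defaults <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_json_file(res$config, file.path(config$out_dir, "config.json"))
    write_json_file(res$summary, file.path(config$out_dir, "summary.json"))
    if (!is.null(res$write_artifacts)) res$write_artifacts(config$out_dir)
    res$write_artifacts <- NULL
    message(sprintf("[flyemd] %s done in %.1f s -> %s", config$experiment,
                    proc.time()[["elapsed"]] - t_start, config$out_dir))
  }
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

variant_params <- function(variant) ablate_params(detector_params(), variant)

exp_fig5b <- function(config) {
  defaults <- list(pulse_s = 0.45, onset_to_onset_s = 0.472, dt_s = 0.01)
  p <- utils::modifyList(defaults, config$extra)
  params <- variant_params(config$variant)
  pairs <- list(pd_on = c(-1L, 0L), pd_off = c(0L, 1L),
                nd_on = c(1L, 0L), nd_off = c(0L, -1L))
  runs <- lapply(pairs, apparent_motion_nlc, params = params,
                 onset_to_onset_s = p$onset_to_onset_s, pulse_s = p$pulse_s,
                 dt_s = p$dt_s)
  nlc_amp <- vapply(runs, function(r) signed_extremum(r$nlc), numeric(1))
  flick <- runs$pd_on$flicker
  flick[["1"]] <- runs$nd_on$flicker[["1"]]
  summary <- as.list(c(nlc = nlc_amp,
    flicker_peak = vapply(flick[c("-1", "0", "1")], function(tr)
      max(baseline_subtract(tr)$values), numeric(1))))
  list(summary = summary, runs = runs, flicker = flick, defaults = defaults,
       write_artifacts = function(dir) {
         for (nm in names(runs)) {
           write_trace_csv(runs[[nm]]$sequence,
                           file.path(dir, paste0("sequence_", nm, ".csv")))
           write_trace_csv(runs[[nm]]$nlc,
                           file.path(dir, paste0("nlc_", nm, ".csv")))
         }
         for (nm in names(flick))
           write_trace_csv(flick[[nm]],
                           file.path(dir, paste0("flicker_", nm, ".csv")))
       })
}

exp_fig5c <- function(config) {
  defaults <- list(frequencies_hz = 10^seq(-1, 1, length.out = 9))
  p <- utils::modifyList(defaults, config$extra)
  variants <- c("full", "no_enhancement", "no_suppression")
  curves <- list()
  summary <- list()
  for (v in variants) {
    for (st in c("array", "tangential")) {
      cv <- temporal_tuning(variant_params(v), frequencies_hz = p$frequencies_hz,
                            stage = st)
      curves[[paste(v, st, sep = "_")]] <- cv
      if (st == "array")
        summary[[paste0("dsi_1hz_", v)]] <- dsi(
          grating_response(1, 0, "array", params = variant_params(v),
                           measure = "level"),
          grating_response(1, 180, "array", params = variant_params(v),
                           measure = "level"))
      else
        summary[[paste0("tangential_pd_min_", v)]] <- min(cv$pd)
    }
  }
  list(summary = summary, curves = curves, defaults = defaults,
       write_artifacts = function(dir)
         for (nm in names(curves))
           write_curve_csv(curves[[nm]],
                           file.path(dir, paste0("temporal_", nm, ".csv"))))
}

exp_fig5d <- function(config) {
  defaults <- list(directions_deg = seq(0, 330, by = 30), frequency_hz = 1)
  p <- utils::modifyList(defaults, config$extra)
  variants <- c("full", "no_enhancement", "no_suppression")
  curves <- lapply(variants, function(v)
    direction_tuning(variant_params(v), directions_deg = p$directions_deg,
                     frequency_hz = p$frequency_hz))
  names(curves) <- variants
  summary <- lapply(curves, function(cv)
    cv$direction[which.max(cv$amplitude)])
  names(summary) <- paste0("peak_direction_", variants)
  list(summary = summary, curves = curves, defaults = defaults,
       write_artifacts = function(dir)
         for (nm in names(curves))
           write_curve_csv(curves[[nm]],
                           file.path(dir, paste0("direction_", nm, ".csv"))))
}

exp_fig3c <- function(config) {
  defaults <- list(onset_delays_s = seq(0, 1.5, by = 0.059), pulse_s = 0.472)
  p <- utils::modifyList(defaults, config$extra)
  params <- variant_params(config$variant)
  pd <- delay_tuning(params, onset_delays_s = p$onset_delays_s, pair = "PD",
                     pulse_s = p$pulse_s)
  nd <- delay_tuning(params, onset_delays_s = p$onset_delays_s, pair = "ND",
                     pulse_s = p$pulse_s)
  summary <- list(pd_peak_delay_s = pd$delay[which.max(pd$amplitude)],
                  nd_min_nlc = min(nd$nlc))
  list(summary = summary, curves = list(pd = pd, nd = nd),
       defaults = defaults,
       write_artifacts = function(dir) {
         write_curve_csv(pd, file.path(dir, "delay_pd.csv"))
         write_curve_csv(nd, file.path(dir, "delay_nd.csv"))
       })
}

exp_fig3e <- function(config) {
  defaults <- list(duration_s = 0.472, n_rings = 2)
  p <- utils::modifyList(defaults, config$extra)
  raster <- make_hex_raster(p$n_rings)
  rf <- synth_rf(raster, preset = "T4")
  cols <- raster$columns
  others <- cols[!(cols$q == 0 & cols$r == 0), ]
  conds <- c(list(center = hex_protocol(0, 0, duration_s = p$duration_s)),
             lapply(seq_len(nrow(others)), function(i)
               hex_protocol(c(0, others$q[i]), c(0, others$r[i]),
                            duration_s = p$duration_s)))
  names(conds)[-1] <- paste(others$q, others$r, sep = ",")
  rec <- simulate_recording(conds, rf, cell_model = "emd", noise_sd = 0,
                            n_reps = 1, seed = config$seed)
  amps <- recording_amplitudes(rec, measure = "peak")
  ratios <- pair_suppression_map(amps[-1], amps["center"])
  map <- data.frame(others[, c("q", "r", "ring")], ratio = unname(ratios))
  list(summary = list(min_ratio = min(ratios), max_ratio = max(ratios),
                      center_amplitude = unname(amps["center"])),
       map = map, defaults = defaults,
       write_artifacts = function(dir)
         utils::write.csv(map, file.path(dir, "pair_suppression_map.csv"),
                          row.names = FALSE))
}

exp_fig2 <- function(config) {
  defaults <- list(n_cells = 10, noise_sd = 0.2, n_reps = 3, preset = "T4",
                   duration_s = 0.472, measure = "mean")
  p <- utils::modifyList(defaults, config$extra)
  raster <- make_hex_raster(2)
  rf <- synth_rf(raster, preset = p$preset)
  conds <- rf_flicker_conditions(raster, duration_s = p$duration_s)
  amps <- t(vapply(seq_len(p$n_cells), function(cell) {
    rec <- simulate_recording(conds, rf, cell_model = "linear",
                              noise_sd = p$noise_sd, n_reps = p$n_reps,
                              seed = config$seed + 1000 * cell)
    recording_amplitudes(rec, measure = p$measure)
  }, numeric(nrow(raster$columns))))
  map <- rf_map(amps, raster)
  ring_mean <- vapply(0:2, function(k) mean(map$mean[map$ring == k]),
                      numeric(1))
  profiles <- lapply(names(raster$axes), function(ax) axis_profile(map, ax))
  names(profiles) <- names(raster$axes)
  list(summary = list(center_mean = ring_mean[1], ring1_mean = ring_mean[2],
                      ring2_mean = ring_mean[3]),
       map = map, profiles = profiles, defaults = defaults,
       write_artifacts = function(dir) {
         write_rf_map_csv(map, file.path(dir, "rf_map.csv"))
         for (ax in names(profiles))
           utils::write.csv(profiles[[ax]],
                            file.path(dir, paste0("axis_", gsub("-", "", ax),
                                                  ".csv")), row.names = FALSE)
       })
}
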