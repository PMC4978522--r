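#' Hexagonal column raster
#'
#' The neuro-ommatidial lattice in axial coordinates `(q, r)`: all columns
#' within `n_rings` lattice steps of the central column. A raster with
#' `n_rings = 2` has the 19 columnar positions used for receptive-field
#' mapping. The three lattice axes through the center carry anatomical
#' labels: D-V (`q = 0`), DL-VF (`r = 0`) and DF-VL (`q + r = 0`). Columns
#' are listed in row-major order (by `r`, then `q`).
#'
#' @param n_rings number of rings around the center (>= 0).
#' @return An object of class `hex_raster`: list with `columns` (data frame
#'   `q`, `r`, `ring`), `n_rings`, and `axes` (label-to-definition map).
#' @export
make_hex_raster <- function(n_rings = 2) {
  if (n_rings < 0) stop("n_rings must be nonnegative")
  n <- as.integer(n_rings)
  grid <- expand.grid(q = -n:n, r = -n:n)
  grid <- grid[abs(grid$q + grid$r) <= n, , drop = FALSE]
  grid$ring <- pmax(abs(grid$q), abs(grid$r), abs(grid$q + grid$r))
  grid <- grid[order(grid$r, grid$q), , drop = FALSE]
  rownames(grid) <- NULL
  structure(list(columns = grid, n_rings = n,
                 axes = c("D-V" = "q = 0", "DL-VF" = "r = 0",
                          "DF-VL" = "q + r = 0")),
            class = "hex_raster")
}

#' @export
print.hex_raster <- function(x, ...) {
  cat(sprintf("<hex_raster> %d rings, %d columns; axes: %s\n", x$n_rings,
              nrow(x$columns), paste(names(x$axes), collapse = ", ")))
  invisible(x)
}

# lattice distance between axial coordinates
hex_distance <- function(q1, r1, q2, r2) {
  (abs(q1 - q2) + abs(r1 - r2) + abs(q1 + r1 - q2 - r2)) / 2
}

#' Synthetic receptive field on a hex raster
#'
#' Per-column true response amplitudes, parameterized either as explicit ring
#' amplitudes (center, first ring, second ring, ...) or as an isotropic
#' Gaussian over lattice distance with a stated full width at half maximum.
#' Presets: `"T4"` gives rings (1, 0.5, 0.25) — a wide field pooling over the
#' six nearest and twelve next-outer columns; `"L2"` gives (1, 0.3, 0.12) —
#' the narrow single-column field whose residual surround reflects only the
#' Gaussian acceptance angle of the eye's optics.
#'
#' @param raster a [make_hex_raster()].
#' @param preset `"T4"` or `"L2"`, or `NULL` when giving amplitudes directly.
#' @param ring_amplitudes numeric vector of amplitudes by ring (index 1 =
#'   center); rings beyond the vector get 0.
#' @param gaussian_fwhm FWHM of a Gaussian profile in lattice pitches
#'   (amplitude `2^(-4 (d/fwhm)^2)` at lattice distance d).
#' @return An object of class `synthetic_rf`: data frame `q`, `r`, `ring`,
#'   `amplitude` (center maximal), with the ring profile as an attribute.
#' @export
synth_rf <- function(raster, preset = NULL, ring_amplitudes = NULL,
                     gaussian_fwhm = NULL) {
  stopifnot(inherits(raster, "hex_raster"))
  if (!is.null(preset)) {
    ring_amplitudes <- switch(match.arg(preset, c("T4", "L2")),
                              T4 = c(1, 0.5, 0.25),
                              L2 = c(1, 0.3, 0.12))
  }
  rings <- raster$columns$ring
  if (!is.null(ring_amplitudes)) {
    if (any(ring_amplitudes < 0)) stop("ring amplitudes must be nonnegative")
    amp <- ifelse(rings + 1 <= length(ring_amplitudes),
                  ring_amplitudes[pmin(rings + 1, length(ring_amplitudes))], 0)
    profile <- function(d) ifelse(d + 1 <= length(ring_amplitudes),
                                  ring_amplitudes[pmin(d + 1, length(ring_amplitudes))], 0)
  } else if (!is.null(gaussian_fwhm)) {
    if (gaussian_fwhm <= 0) stop("Gaussian FWHM must be positive")
    profile <- function(d) 2^(-4 * (d / gaussian_fwhm)^2)
    amp <- profile(rings)
  } else {
    stop("give a preset, ring_amplitudes, or gaussian_fwhm")
  }
  if (max(amp) != amp[rings == 0]) stop("center amplitude must be maximal")
  structure(
    data.frame(raster$columns, amplitude = amp),
    profile = profile, raster = raster,
    spec = list(ring_amplitudes = ring_amplitudes,
                gaussian_fwhm = gaussian_fwhm),
    class = c("synthetic_rf", "data.frame"))
}

#' Calcium-indicator impulse kernel
#'
#' Phenomenological single-exponential indicator kernel,
#' `h(t) = exp(-t / tau_ca)`, peak-normalized to 1 at t = 0. When applied to
#' a trace ([apply_calcium_kernel()]) the convolution is scaled to unit DC
#' gain, so a sustained unit drive saturates at 1 (reaching the rf amplitude
#' for pulses much longer than `tau_ca_s`).
#'
#' @param tau_ca_s decay time constant in seconds (default 0.3).
#' @return An object of class `calcium_kernel`.
#' @export
calcium_kernel <- function(tau_ca_s = 0.3) {
  stopifnot(tau_ca_s > 0)
  structure(list(tau_ca_s = tau_ca_s), class = "calcium_kernel")
}

#' Convolve a drive trace with the calcium kernel
#'
#' @param x numeric drive trace.
#' @param kernel a [calcium_kernel()].
#' @param dt_s sampling interval in seconds.
#' @return The calcium-filtered trace (unit DC gain).
#' @export
apply_calcium_kernel <- function(x, kernel, dt_s) {
  stopifnot(inherits(kernel, "calcium_kernel"))
  filter_first_order(x, tau_s = kernel$tau_ca_s, dt_s = dt_s, mode = "low")
}

#' Flicker protocol on a hexagonal raster
#'
#' A set of light-pulse events addressed by axial column coordinates.
#'
#' @param q,r axial coordinates of the stimulated column(s).
#' @param onset_s onset times relative to stimulus start (default 0).
#' @param duration_s pulse durations (default 0.472 s).
#' @param amplitude pulse amplitudes in `[0, 1]`.
#' @return An object of class `hex_protocol` (a data frame of events).
#' @export
hex_protocol <- function(q, r, onset_s = 0, duration_s = 0.472, amplitude = 1) {
  ev <- data.frame(q = as.integer(q), r = as.integer(r), onset_s = onset_s,
                   duration_s = duration_s, amplitude = amplitude)
  stopifnot(all(ev$duration_s > 0), all(ev$onset_s >= 0),
            all(ev$amplitude >= 0), all(ev$amplitude <= 1))
  structure(ev, class = c("hex_protocol", "data.frame"))
}

#' One flicker condition per raster column
#'
#' @param raster a [make_hex_raster()].
#' @param duration_s pulse duration (default 0.472 s).
#' @return Named list of single-event [hex_protocol()]s in raster column
#'   order (names `"q,r"`), suitable for [simulate_recording()] followed by
#'   [rf_map()].
#' @export
rf_flicker_conditions <- function(raster, duration_s = 0.472) {
  cols <- raster$columns
  conds <- lapply(seq_len(nrow(cols)), function(i)
    hex_protocol(cols$q[i], cols$r[i], duration_s = duration_s))
  names(conds) <- paste(cols$q, cols$r, sep = ",")
  conds
}

# deterministic per-(condition, repetition) seed derived from the base seed;
# keyed so that adding conditions never reshuffles existing streams
derive_seed <- function(seed, condition_index, repetition) {
  (as.double(seed) * 10007 + condition_index * 131 + repetition) %% 2147483647
}

#' Simulate a synthetic calcium recording
#'
#' Generates repetition-resolved, calcium-like dF/F traces for a set of
#' stimulus conditions on the hexagonal raster, emulating the structure of
#' single-column imaging experiments: a per-column receptive field, a slow
#' indicator kernel, additive Gaussian trial noise, and a small number of
#' repetitions (default 3).
#'
#' Two cell models are available. The `"linear"` cell responds with the sum of
#' rf-weighted stimulus indicators, calcium-filtered — linear in the stimulus
#' by construction. The `"emd"` cell routes the stimulus through the
#' three-arm detector unit centered on the raster center (arms along the D-V
#' axis), with optical cross-talk given by the rf ring profile, then applies
#' the calcium kernel to the baseline-subtracted detector response.
#'
#' Each condition/repetition pair draws its noise from an independent stream
#' keyed by `(condition, repetition)` and the base seed, so runs are
#' bit-identical given the same seed and stable under adding conditions.
#'
#' @param conditions list of [hex_protocol()]s (one recording block each).
#' @param rf a [synth_rf()].
#' @param cell_model `"linear"` or `"emd"`.
#' @param kernel a [calcium_kernel()].
#' @param noise_sd standard deviation of additive Gaussian noise per sample.
#' @param n_reps repetitions per condition (>= 1, default 3).
#' @param seed integer base seed.
#' @param dt_s sampling interval (default 0.01 s).
#' @param pre_s baseline time before stimulus onset (default 1 s).
#' @param post_s time after the last pulse (default 1.5 s).
#' @param params detector parameters for the `"emd"` cell model.
#' @return An object of class `synthetic_recording`: list with `conditions`
#'   (each holding `protocol`, `traces` as an n_reps x time matrix and
#'   `stim_onset_s = pre_s`), `dt_s`, `pre_s` and full generator `provenance`.
#' @export
simulate_recording <- function(conditions, rf,
                               cell_model = c("linear", "emd"),
                               kernel = calcium_kernel(), noise_sd = 0,
                               n_reps = 3, seed = 1, dt_s = 0.01, pre_s = 1,
                               post_s = 1.5, params = detector_params()) {
  cell_model <- match.arg(cell_model)
  stopifnot(inherits(rf, "synthetic_rf"), n_reps >= 1, noise_sd >= 0)
  raster <- attr(rf, "raster")
  profile <- attr(rf, "profile")
  if (is.null(names(conditions)))
    names(conditions) <- sprintf("condition_%02d", seq_along(conditions))
  out <- vector("list", length(conditions))
  names(out) <- names(conditions)
  for (ci in seq_along(conditions)) {
    proto <- conditions[[ci]]
    stopifnot(inherits(proto, "hex_protocol"))
    if (any(hex_distance(proto$q, proto$r, 0, 0) > raster$n_rings))
      stop(sprintf("condition %d stimulates a column outside the raster", ci))
    span <- max(proto$onset_s + proto$duration_s)
    nt <- round((pre_s + span + post_s) / dt_s)
    t <- (seq_len(nt) - 1) * dt_s
    indicator <- function(ev) as.numeric(t >= pre_s + ev$onset_s - 1e-9 &
                                         t < pre_s + ev$onset_s + ev$duration_s - 1e-9)
    clean <- if (cell_model == "linear") {
      drive <- numeric(nt)
      for (k in seq_len(nrow(proto))) {
        a <- rf$amplitude[rf$q == proto$q[k] & rf$r == proto$r[k]]
        drive <- drive + a * proto$amplitude[k] * indicator(proto[k, ])
      }
      apply_calcium_kernel(drive, kernel, dt_s)
    } else {
      arm_r <- c(e = -1, d = 0, s = 1) * params$preferred_sign
      lum <- vapply(arm_r, function(rr) {
        v <- numeric(nt)
        for (k in seq_len(nrow(proto))) {
          w <- profile(hex_distance(proto$q[k], proto$r[k], 0, rr))
          v <- v + w * proto$amplitude[k] * indicator(proto[k, ])
        }
        pmin(v, 1)
      }, numeric(nt))
      l1 <- apply(lum, 2, lamina_l1, dt_s = dt_s)
      u <- baseline_subtract(t4_unit(l1[, "e"], l1[, "d"], l1[, "s"],
                                     params, dt_s = dt_s))
      apply_calcium_kernel(u$values, kernel, dt_s)
    }
    traces <- matrix(NA_real_, nrow = n_reps, ncol = nt)
    for (rep in seq_len(n_reps)) {
      set.seed(derive_seed(seed, ci, rep))
      traces[rep, ] <- clean + stats::rnorm(nt, sd = noise_sd)
    }
    out[[ci]] <- list(protocol = proto, traces = traces, stim_onset_s = pre_s)
  }
  structure(
    list(conditions = out, dt_s = dt_s, pre_s = pre_s,
         provenance = list(cell_model = cell_model, noise_sd = noise_sd,
                           n_reps = n_reps, seed = seed,
                           tau_ca_s = kernel$tau_ca_s,
                           rf = data.frame(q = rf$q, r = rf$r, ring = rf$ring,
                                           amplitude = rf$amplitude),
                           rf_spec = attr(rf, "spec"),
                           n_rings = raster$n_rings,
                           detector = unclass(params)[c("k_e", "k_d", "k_s",
                                                        "dc_term", "tau_lp_s",
                                                        "preferred_sign")],
                           dt_s = dt_s, pre_s = pre_s, post_s = post_s)),
    class = "synthetic_recording")
}

#' @export
print.synthetic_recording <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("<synthetic_recording> %d condition(s) x %d rep(s), %s cell, noise sd %g, seed %g\n",
              length(x$conditions), p$n_reps, p$cell_model, p$noise_sd, p$seed))
  invisible(x)
}

#' Response amplitudes of a synthetic recording
#'
#' Averages repetitions, subtracts the mean over the second before stimulus
#' onset, and quantifies the response over the stimulus epoch of each
#' condition. The `"mean"` measure (default) is unbiased under trial noise;
#' `"peak"` matches the convention used for well-averaged recordings but is
#' biased upward when noise survives averaging.
#'
#' @param recording a [simulate_recording()] result.
#' @param measure `"mean"` or `"peak"`.
#' @return Named numeric vector of amplitudes, one per condition.
#' @export
recording_amplitudes <- function(recording, measure = c("mean", "peak")) {
  measure <- match.arg(measure)
  stopifnot(inherits(recording, "synthetic_recording"))
  vapply(recording$conditions, function(cond) {
    avg <- colMeans(cond$traces)
    tr <- response_trace(avg, dt_s = recording$dt_s)
    on <- cond$stim_onset_s
    epoch <- c(on + min(cond$protocol$onset_s),
               on + max(cond$protocol$onset_s + cond$protocol$duration_s))
    quantify_response(tr, baseline_window = c(on - 1, on),
                      epoch_window = epoch, measure = measure)$value
  }, numeric(1))
}
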