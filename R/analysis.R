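#' Relative fluorescence change (dF/F)
#'
#' Converts a raw fluorescence trace to `(F - F0)/F0`, with `F0` the mean over
#' a baseline window. The conventional baseline window is the second before
#' stimulus onset; for sustained-response cells quantified at luminance
#' off-set (the L2 convention) pass the last second before off-set instead.
#'
#' @param raw_trace a [response_trace()] of raw fluorescence F.
#' @param baseline_window numeric `c(t0, t1)` in seconds on the trace's time
#'   axis; `F0` is the mean of F over `[t0, t1)` and must be positive.
#' @return A [response_trace()] of dF/F with baseline 0.
#' @export
dff <- function(raw_trace, baseline_window) {
  idx <- window_index(raw_trace, baseline_window)
  f0 <- mean(raw_trace$values[idx])
  if (!is.finite(f0) || f0 <= 0)
    stop("baseline fluorescence F0 must be positive")
  response_trace((raw_trace$values - f0) / f0, dt_s = raw_trace$dt_s,
                 baseline_value = 0, label = raw_trace$label)
}

# sample indices of a half-open time window [t0, t1)
window_index <- function(trace, window) {
  stopifnot(length(window) == 2, window[2] > window[1])
  t <- trace_time(trace)
  idx <- which(t >= window[1] - 1e-9 & t < window[2] - 1e-9)
  if (length(idx) == 0) stop("time window contains no samples")
  idx
}

#' Quantify a response amplitude
#'
#' Subtracts the mean over a baseline window and reports the peak (maximum) or
#' mean of the baseline-subtracted trace over a stimulus epoch. Peak is the
#' standard measure for averaged calcium responses; the mean is the unbiased
#' choice for noisy traces and for periodic model responses averaged over
#' whole cycles.
#'
#' @param trace a [response_trace()].
#' @param baseline_window `c(t0, t1)` seconds, or `NULL` to use the trace's
#'   own `baseline_value`.
#' @param epoch_window `c(t0, t1)` seconds; must not overlap the baseline
#'   window.
#' @param measure `"peak"` (default) or `"mean"`.
#' @return An object of class `response_amplitude`: list with `value`,
#'   `measure`, `baseline_window_s`, `epoch_window_s`.
#' @export
quantify_response <- function(trace, baseline_window = NULL, epoch_window,
                              measure = c("peak", "mean")) {
  measure <- match.arg(measure)
  epoch <- window_index(trace, epoch_window)
  if (is.null(baseline_window)) {
    base <- trace$baseline_value
  } else {
    if (baseline_window[2] > epoch_window[1] && epoch_window[2] > baseline_window[1])
      stop("baseline and epoch windows must not overlap")
    base <- mean(trace$values[window_index(trace, baseline_window)])
  }
  v <- trace$values[epoch] - base
  structure(list(value = if (measure == "peak") max(v) else mean(v),
                 measure = measure,
                 baseline_window_s = baseline_window,
                 epoch_window_s = epoch_window),
            class = "response_amplitude")
}

#' @export
print.response_amplitude <- function(x, ...) {
  cat(sprintf("<response_amplitude> %s = %g over [%g, %g) s\n", x$measure,
              x$value, x$epoch_window_s[1], x$epoch_window_s[2]))
  invisible(x)
}

#' Linear expectation of a pulse-sequence response
#'
#' The sum of the single-pulse (flicker) responses, each time-shifted to its
#' onset in the sequence protocol. Flicker traces are baseline-subtracted
#' before shifting and summation; the result is the response a perfectly
#' linear cell would give to the sequence.
#'
#' @param flicker_traces named list of [response_trace()]s, one per stimulated
#'   relative column (names are the integer column positions), each
#'   time-referenced so that t = 0 is its own pulse onset.
#' @param protocol a [pulse_protocol()]; every event column must have a
#'   flicker trace.
#' @param n_out output length in samples; defaults to the longest shifted
#'   trace.
#' @return A [response_trace()] with baseline 0.
#' @export
linear_expectation <- function(flicker_traces, protocol, n_out = NULL) {
  stopifnot(inherits(protocol, "pulse_protocol"), length(flicker_traces) >= 1)
  dt <- flicker_traces[[1]]$dt_s
  shifts <- round(protocol$onset_s / dt)
  keys <- as.character(protocol$column)
  missing <- setdiff(keys, names(flicker_traces))
  if (length(missing) > 0)
    stop("no flicker trace for column(s) ", paste(missing, collapse = ", "))
  if (is.null(n_out))
    n_out <- max(shifts + vapply(flicker_traces[keys], function(tr)
      length(tr$values), integer(1)))
  out <- numeric(n_out)
  for (i in seq_len(nrow(protocol))) {
    tr <- baseline_subtract(flicker_traces[[keys[i]]])
    if (abs(tr$dt_s - dt) > 1e-12) stop("flicker traces must share dt")
    k <- shifts[i]
    m <- min(length(tr$values), n_out - k)
    if (m > 0) out[(k + 1):(k + m)] <- out[(k + 1):(k + m)] + tr$values[1:m]
  }
  response_trace(out, dt_s = dt, baseline_value = 0,
                 label = "linear_expectation")
}

#' Nonlinear response component
#'
#' The measured (or simulated) sequence response minus the linear expectation:
#' positive where the sequence is supralinear (preferred-direction
#' enhancement), negative where it is sublinear (null-direction suppression).
#' Identically zero for any cell that is linear in the stimulus.
#'
#' @param sequence_trace a [response_trace()] of the apparent-motion sequence
#'   response, t = 0 at the first pulse onset.
#' @param flicker_traces,protocol as in [linear_expectation()].
#' @return A baseline-subtracted [response_trace()].
#' @export
nonlinear_component <- function(sequence_trace, flicker_traces, protocol) {
  expect <- linear_expectation(flicker_traces, protocol,
                               n_out = length(sequence_trace$values))
  if (abs(expect$dt_s - sequence_trace$dt_s) > 1e-12)
    stop("sequence and flicker traces must share the same time grid")
  seqv <- baseline_subtract(sequence_trace)
  response_trace(seqv$values - expect$values, dt_s = seqv$dt_s,
                 baseline_value = 0, label = "nonlinear_component")
}

#' Receptive-field map from per-cell column amplitudes
#'
#' Reproduces the standard receptive-field averaging procedure: for each cell,
#' the per-column response amplitudes are translated so the maximum sits at
#' the raster center, normalized by that maximum, then averaged across cells;
#' the per-column dispersion is the SEM (sd / sqrt(n)). Ties for the maximum
#' are broken by the first maximum in row-major raster order (sorted by r,
#' then q, for hexagonal rasters).
#'
#' @param amplitudes matrix of response amplitudes, cells in rows, one column
#'   per raster column in raster order (a single cell may be given as a
#'   vector). All-zero cells are rejected.
#' @param raster a [make_hex_raster()] raster describing the columns.
#' @return An object of class `rf_map`: data frame with columns `q`, `r`,
#'   `ring`, `mean`, `sem`, `n` and the raster as an attribute. After
#'   normalization the center amplitude is exactly 1.
#' @export
rf_map <- function(amplitudes, raster) {
  stopifnot(inherits(raster, "hex_raster"))
  if (is.null(dim(amplitudes))) amplitudes <- matrix(amplitudes, nrow = 1)
  if (ncol(amplitudes) != nrow(raster$columns))
    stop("amplitude columns must match the raster columns")
  ord <- order(raster$columns$r, raster$columns$q)
  coords <- raster$columns[, c("q", "r")]
  key <- paste(coords$q, coords$r)
  acc <- matrix(NA_real_, nrow = nrow(amplitudes), ncol = nrow(coords))
  for (ci in seq_len(nrow(amplitudes))) {
    a <- amplitudes[ci, ]
    if (all(a == 0)) stop(sprintf("cell %d has all-zero amplitudes", ci))
    peak <- ord[which.max(a[ord])]
    shifted_q <- coords$q - coords$q[peak]
    shifted_r <- coords$r - coords$r[peak]
    dest <- match(paste(shifted_q, shifted_r), key)
    keep <- !is.na(dest)
    acc[ci, dest[keep]] <- a[keep] / a[peak]
  }
  n <- colSums(!is.na(acc))
  mu <- colMeans(acc, na.rm = TRUE)
  sem <- apply(acc, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
  })
  structure(
    data.frame(q = coords$q, r = coords$r, ring = raster$columns$ring,
               mean = mu, sem = sem, n = n),
    raster = raster, class = c("rf_map", "data.frame"))
}

#' Axis profile of a receptive-field map
#'
#' Amplitudes of the columns lying on one of the three hexagonal lattice axes
#' through the center, ordered along the axis. The axes carry the anatomical
#' labels D-V (dorsal-ventral), DL-VF (dorso-lateral to ventro-frontal) and
#' DF-VL (dorso-frontal to ventro-lateral).
#'
#' @param map an [rf_map()].
#' @param axis one of `"D-V"`, `"DL-VF"`, `"DF-VL"`.
#' @return Data frame with `position` (signed lattice steps from center),
#'   `mean`, `sem`.
#' @export
axis_profile <- function(map, axis = c("D-V", "DL-VF", "DF-VL")) {
  stopifnot(inherits(map, "rf_map"))
  axis <- match.arg(axis)
  on_axis <- switch(axis,
                    "D-V"   = map$q == 0,
                    "DL-VF" = map$r == 0,
                    "DF-VL" = map$q + map$r == 0)
  pos <- switch(axis,
                "D-V"   = map$r[on_axis],
                "DL-VF" = map$q[on_axis],
                "DF-VL" = map$q[on_axis])
  out <- data.frame(position = pos, mean = map$mean[on_axis],
                    sem = map$sem[on_axis])
  out[order(out$position), , drop = FALSE]
}

#' Paired-stimulation suppression map
#'
#' Ratio of the response to simultaneous stimulation of the center column plus
#' one other column, to the response to the center column alone. A ratio of 1
#' means no interaction, below 1 suppression; the degenerate center-vs-center
#' entry is 1 by convention.
#'
#' @param paired_amplitudes named numeric vector of center+other response
#'   amplitudes, one per "other" column.
#' @param center_alone_amplitude positive response amplitude to the isolated
#'   center stimulus.
#' @param center_id optional name identifying the degenerate center entry.
#' @return Named numeric vector of ratios.
#' @export
pair_suppression_map <- function(paired_amplitudes, center_alone_amplitude,
                                 center_id = NULL) {
  if (!is.finite(center_alone_amplitude) || center_alone_amplitude <= 0)
    stop("center-alone amplitude must be positive")
  ratios <- paired_amplitudes / center_alone_amplitude
  if (!is.null(center_id) && center_id %in% names(ratios))
    ratios[center_id] <- 1
  ratios
}

#' Direction-selectivity index
#'
#' `DSI = (PD - ND) / (PD + ND)` on amplitudes clipped at zero; 1 means a
#' fully direction-selective response, 0 none.
#'
#' @param pd_amplitude,nd_amplitude preferred- and null-direction response
#'   amplitudes.
#' @return A number in `[-1, 1]`.
#' @export
dsi <- function(pd_amplitude, nd_amplitude) {
  pd <- max(0, pd_amplitude)
  nd <- max(0, nd_amplitude)
  if (pd + nd == 0) stop("both amplitudes are zero; DSI undefined")
  (pd - nd) / (pd + nd)
}

#' Normalize a tuning curve to its maximum
#'
#' @param curve a data frame with amplitude columns (any of `pd`, `nd`,
#'   `amplitude`).
#' @return The curve divided by the maximum amplitude across those columns
#'   (maximum of the normalized curve is exactly 1).
#' @export
normalize_curve <- function(curve) {
  cols <- intersect(c("pd", "nd", "amplitude"), names(curve))
  m <- max(unlist(curve[cols]))
  if (m == 0) stop("cannot normalize an all-zero curve")
  curve[cols] <- lapply(curve[cols], function(v) v / m)
  attr(curve, "normalized") <- TRUE
  curve
}
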