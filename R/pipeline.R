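#' Run a pulse protocol through the full model chain
#'
#' Renders the protocol as a movie, samples it onto the column raster, applies
#' the L1 front-end and evaluates the requested detector stage. A settle
#' period of background luminance (default 1.5 s, i.e. >= 5 filter time
#' constants) is prepended so all filters reach their resting state before the
#' first pulse; the returned trace starts at stimulus time 0 with the resting
#' response recorded as its baseline.
#'
#' @param protocol a [pulse_protocol()] with onsets relative to stimulus start.
#' @param params a [detector_params()].
#' @param raster a [linear_raster()].
#' @param stage `"unit"` (single detector at the reference column), `"array"`,
#'   or `"tangential"`.
#' @param reference_column home column of the unit stage and origin of the
#'   protocol's relative positions (default: center of the raster).
#' @param settle_s background settle time prepended before stimulus start.
#' @param post_s trailing background time after the last pulse.
#' @param dt_s simulation time step in seconds.
#' @param dc_mode,background DC convention of the front-end, see [lamina_l1()].
#' @return A [response_trace()] (t = 0 at stimulus start).
#' @export
run_pulse_model <- function(protocol, params = detector_params(),
                            raster = linear_raster(),
                            stage = c("unit", "array", "tangential"),
                            reference_column = (raster$n_columns + 1) %/% 2,
                            settle_s = 1.5, post_s = 1.5, dt_s = 0.01,
                            dc_mode = "mean", background = NULL) {
  stage <- match.arg(stage)
  stopifnot(inherits(protocol, "pulse_protocol"))
  span <- if (nrow(protocol) > 0) max(protocol$onset_s + protocol$duration_s) else 0
  duration <- settle_s + span + post_s
  shifted <- protocol
  shifted$onset_s <- shifted$onset_s + settle_s
  movie <- build_pulse_movie(shifted, raster, duration_s = duration,
                             reference_column = reference_column, dt_s = dt_s)
  l1 <- lamina_l1_columns(sample_columns(movie, raster), dc_mode = dc_mode,
                          background = if (is.null(background))
                            attr(protocol, "background") else background)
  resp <- switch(stage,
    unit = {
      cols <- reference_column + params$offsets
      if (any(cols < 1) || any(cols > raster$n_columns))
        stop("detector arms fall outside the raster")
      t4_unit(l1$values[, cols["e"]], l1$values[, cols["d"]],
              l1$values[, cols["s"]], params, dt_s = l1$dt_s)
    },
    array = t4_array(l1, params),
    tangential = tangential(l1, params))
  keep <- (round(settle_s / dt_s) + 1):length(resp$values)
  response_trace(resp$values[keep], dt_s = dt_s,
                 baseline_value = resp$baseline_value, label = resp$label)
}

#' Single-pulse (flicker) model response
#'
#' @param column relative column position of the pulse.
#' @param pulse_s pulse duration in seconds (default 0.45, the model value).
#' @param amplitude pulse amplitude (default 1).
#' @param total_span_s optional total stimulus span to simulate (so that
#'   flicker and sequence runs share trace length and DC content).
#' @param ... passed to [run_pulse_model()].
#' @inheritParams run_pulse_model
#' @return A [response_trace()] with t = 0 at pulse onset.
#' @export
flicker_response <- function(column, params = detector_params(),
                             pulse_s = 0.45, amplitude = 1,
                             total_span_s = NULL, post_s = 1.5, ...) {
  if (!is.null(total_span_s)) post_s <- post_s + max(0, total_span_s - pulse_s)
  proto <- pulse_protocol(column, onset_s = 0, duration_s = pulse_s,
                          amplitude = amplitude)
  run_pulse_model(proto, params = params, post_s = post_s, ...)
}

#' Apparent-motion sequence and its nonlinear component
#'
#' Runs a two-step (or longer) apparent-motion sequence through the model,
#' runs the matching single-pulse flicker stimuli, and returns the sequence
#' response, the linear expectation (time-shifted flicker sum) and the
#' nonlinear response component. The canonical pairs are `c(-1, 0)`
#' (preferred direction across the enhancing side), `c(1, 0)` (null direction
#' across the suppressing side) and their off-side counterparts `c(0, 1)` and
#' `c(0, -1)`.
#'
#' @param sequence integer vector of relative column positions, stimulated in
#'   order.
#' @param onset_to_onset_s time from one pulse onset to the next (default
#'   0.472 s, the single-column protocol; the LED-arena protocol used 0.4 s).
#' @param pulse_s pulse duration (default 0.45 s).
#' @inheritParams run_pulse_model
#' @param ... passed to [run_pulse_model()].
#' @return List with `sequence` (response trace), `flicker` (named list of
#'   flicker traces), `linear` (linear expectation), `nlc` (nonlinear
#'   component) and `protocol`.
#' @export
apparent_motion_nlc <- function(sequence, params = detector_params(),
                                onset_to_onset_s = 0.472, pulse_s = 0.45,
                                ...) {
  onsets <- (seq_along(sequence) - 1) * onset_to_onset_s
  proto <- pulse_protocol(sequence, onset_s = onsets, duration_s = pulse_s)
  span <- max(onsets) + pulse_s
  seq_tr <- run_pulse_model(proto, params = params, ...)
  flick <- lapply(unique(sequence), flicker_response, params = params,
                  pulse_s = pulse_s, total_span_s = span, ...)
  names(flick) <- as.character(unique(sequence))
  lin <- linear_expectation(flick, proto, n_out = length(seq_tr$values))
  list(sequence = seq_tr, flicker = flick, linear = lin,
       nlc = nonlinear_component(seq_tr, flick, proto), protocol = proto)
}

# signed extremum (value of largest magnitude) of a trace over a time window
signed_extremum <- function(trace, window = NULL) {
  v <- if (is.null(window)) trace$values else trace$values[window_index(trace, window)]
  v[which.max(abs(v))]
}

#' Model response amplitude to a drifting grating
#'
#' Simulates a drifting grating (after a background settle period and a
#' 1 s post-onset transient) and quantifies the baseline-subtracted response
#' of the detector array or the opponent tangential stage over a whole number
#' of grating cycles. The time step is chosen as an integer divisor of the
#' grating period near 10 ms (at least 24 samples per cycle) so the
#' measurement window holds an exact integer number of cycles.
#'
#' @param frequency_hz grating temporal frequency.
#' @param direction_deg motion direction (0 = preferred).
#' @param stage `"array"` or `"tangential"`.
#' @param spec a [grating_spec()] supplying wavelength, contrast, waveform and
#'   mean luminance (its frequency/direction fields are overridden).
#' @param raster a [linear_raster()].
#' @param params a [detector_params()].
#' @param n_cycles number of cycles measured; default covers at least 1 s.
#' @param transient_s post-onset time excluded from the measure (default 1 s).
#' @param settle_s background settle before grating onset (default 1.5 s).
#' @param measure `"mean"` (default) or `"peak"` baseline-subtracted
#'   response, or `"level"`: the raw mean response level over the epoch,
#'   without baseline subtraction. The level is the right currency for
#'   comparing direction selectivity across model variants: the ablated
#'   variants' periodic responses can sit below the resting level in both
#'   directions, so their baseline-subtracted amplitudes clip to zero and a
#'   selectivity index on them is undefined, while the response level is
#'   positive by construction.
#' @param return_trace return the full response trace alongside the amplitude.
#' @return The amplitude (numeric), or a list `(amplitude, trace)` if
#'   `return_trace`.
#' @export
grating_response <- function(frequency_hz, direction_deg = 0,
                             stage = c("array", "tangential"),
                             params = detector_params(),
                             spec = grating_spec(),
                             raster = linear_raster(),
                             n_cycles = NULL, transient_s = 1, settle_s = 1.5,
                             measure = "mean", return_trace = FALSE) {
  stage <- match.arg(stage)
  if (frequency_hz <= 0) stop("temporal frequency must be positive")
  m <- max(24, round(1 / (frequency_hz * 0.01)))  # samples per cycle
  dt <- 1 / (frequency_hz * m)
  if (is.null(n_cycles)) n_cycles <- max(1, ceiling(frequency_hz))
  spec$temporal_frequency_hz <- frequency_hz
  spec$direction_deg <- direction_deg
  grating_s <- transient_s + n_cycles / frequency_hz
  movie <- build_grating_movie(spec, duration_s = grating_s,
                               extent_deg = raster$n_columns * raster$pitch_deg,
                               dt_s = dt)
  n_settle <- round(settle_s / dt)
  vals <- cbind(matrix(spec$mean_luminance, nrow = nrow(movie$values),
                       ncol = n_settle), movie$values)
  l1 <- lamina_l1_columns(sample_columns(stimulus_movie(vals, dt_s = dt), raster))
  resp <- if (stage == "array") t4_array(l1, params) else tangential(l1, params)
  tr <- response_trace(resp$values[(n_settle + 1):length(resp$values)],
                       dt_s = dt, baseline_value = resp$baseline_value,
                       label = sprintf("%s f=%g dir=%g", stage, frequency_hz,
                                       direction_deg))
  amp <- if (measure == "level") {
    mean(tr$values[window_index(tr, c(transient_s, grating_s))])
  } else {
    quantify_response(tr, epoch_window = c(transient_s, grating_s),
                      measure = measure)$value
  }
  if (return_trace) list(amplitude = amp, trace = tr) else amp
}

#' Temporal-frequency tuning curve
#'
#' Preferred- and null-direction grating response amplitudes across a grid of
#' temporal frequencies (default log-spaced 0.1-10 Hz), for the detector
#' array or the tangential stage.
#'
#' @param frequencies_hz frequency grid in Hz.
#' @inheritParams grating_response
#' @param ... passed to [grating_response()].
#' @return A data frame of class `tuning_curve` with columns `frequency`,
#'   `pd`, `nd`.
#' @export
temporal_tuning <- function(params = detector_params(),
                            frequencies_hz = 10^seq(-1, 1, length.out = 9),
                            stage = "array", ...) {
  if (any(frequencies_hz <= 0)) stop("frequencies must be positive")
  pd <- vapply(frequencies_hz, grating_response, numeric(1),
               direction_deg = 0, stage = stage, params = params, ...)
  nd <- vapply(frequencies_hz, grating_response, numeric(1),
               direction_deg = 180, stage = stage, params = params, ...)
  structure(data.frame(frequency = frequencies_hz, pd = pd, nd = nd),
            stage = stage, class = c("tuning_curve", "data.frame"))
}

#' Direction tuning curve
#'
#' Grating response amplitude per motion direction (default the standard 12
#' directions spaced 30 deg apart, at 1 Hz). Directions are projected onto
#' the detector axis via `cos(theta)`, so the curve is symmetric about 0.
#'
#' @param directions_deg vector of motion directions in degrees.
#' @param frequency_hz grating temporal frequency (default 1).
#' @inheritParams grating_response
#' @param ... passed to [grating_response()].
#' @return A data frame of class `tuning_curve` with columns `direction`,
#'   `amplitude`.
#' @export
direction_tuning <- function(params = detector_params(),
                             directions_deg = seq(0, 330, by = 30),
                             frequency_hz = 1, stage = "array", ...) {
  amp <- vapply(directions_deg, function(th)
    grating_response(frequency_hz, direction_deg = th, stage = stage,
                     params = params, ...), numeric(1))
  structure(data.frame(direction = directions_deg, amplitude = amp),
            stage = stage, class = c("tuning_curve", "data.frame"))
}

#' Onset-delay tuning of two-step apparent motion
#'
#' Varies the onset-to-onset delay of a two-pulse apparent-motion pair and
#' quantifies, per delay, the peak baseline-subtracted response over the
#' second-pulse epoch and the signed extremum of the nonlinear component in
#' that epoch. Delay 0 is simultaneous stimulation. Delays are snapped to the
#' simulation grid.
#'
#' @param onset_delays_s delay grid in seconds (default 0-1.5 s in 59 ms
#'   steps, one eighth of the 472 ms pulse).
#' @param pair `"PD"` (columns -1 then 0) or `"ND"` (columns 1 then 0).
#' @param pulse_s pulse duration (default 0.472 s, the single-column
#'   protocol).
#' @param dt_s simulation step (default 1 ms, so 59 ms delays are exact).
#' @inheritParams run_pulse_model
#' @param ... passed to [run_pulse_model()].
#' @return A data frame of class `tuning_curve` with columns `delay`,
#'   `amplitude`, `nlc`.
#' @export
delay_tuning <- function(params = detector_params(),
                         onset_delays_s = seq(0, 1.5, by = 0.059),
                         pair = c("PD", "ND"), pulse_s = 0.472,
                         dt_s = 0.001, ...) {
  pair <- match.arg(pair)
  if (any(onset_delays_s < 0)) stop("onset delays must be nonnegative")
  cols <- if (pair == "PD") c(-1L, 0L) else c(1L, 0L)
  res <- t(vapply(onset_delays_s, function(d) {
    d <- round(d / dt_s) * dt_s
    am <- apparent_motion_nlc(cols, params = params, onset_to_onset_s = d,
                              pulse_s = pulse_s, dt_s = dt_s, ...)
    epoch <- c(d, d + pulse_s)
    c(quantify_response(am$sequence, epoch_window = epoch)$value,
      signed_extremum(am$nlc, epoch))
  }, numeric(2)))
  structure(data.frame(delay = onset_delays_s, amplitude = res[, 1],
                       nlc = res[, 2]),
            pair = pair, class = c("tuning_curve", "data.frame"))
}
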