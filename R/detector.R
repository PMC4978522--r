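#' Detector model parameters
#'
#' Constants of the three-arm motion-detector unit: an enhancing arm E
#' (low-pass filtered, multiplicative) one column to the null side, a direct
#' arm D at the home column, and a suppressing arm S (low-pass filtered,
#' divisive) one column to the preferred side. The unit response is
#' `R = (k_E * LP(E) + dc) * (k_D * D + dc) / (k_S * LP(S) + dc)`.
#'
#' The DC term is added after weighting, so the resting response is
#' `dc^2 / dc = dc` (1.0 with defaults) independent of the weights.
#'
#' @param k_e enhancing weight (default 5).
#' @param k_d direct weight (default 5).
#' @param k_s suppressing weight (default 10).
#' @param dc_term additive constant per arm (default 1.0); also prevents
#'   division by zero and carries the flicker response.
#' @param tau_lp_s low-pass time constant of the E and S arms in seconds
#'   (default 0.25).
#' @param preferred_sign +1 (default) if the preferred direction is +x (E arm
#'   at relative column -1, S at +1), -1 for the mirrored unit.
#' @return An object of class `detector_params` with an `offsets` field giving
#'   the relative column indices of the (E, D, S) arms.
#' @export
detector_params <- function(k_e = 5, k_d = 5, k_s = 10, dc_term = 1,
                            tau_lp_s = 0.25, preferred_sign = 1) {
  stopifnot(k_e >= 0, k_d >= 0, k_s >= 0, dc_term > 0, tau_lp_s > 0,
            preferred_sign %in% c(-1, 1))
  structure(
    list(k_e = k_e, k_d = k_d, k_s = k_s, dc_term = dc_term,
         tau_lp_s = tau_lp_s, preferred_sign = preferred_sign,
         offsets = c(e = -1L, d = 0L, s = 1L) * as.integer(preferred_sign)),
    class = "detector_params")
}

#' @export
print.detector_params <- function(x, ...) {
  cat(sprintf(
    "<detector_params> k_E=%g k_D=%g k_S=%g dc=%g tau_LP=%g s, arms (E,D,S) at %+d,%+d,%+d\n",
    x$k_e, x$k_d, x$k_s, x$dc_term, x$tau_lp_s,
    x$offsets["e"], x$offsets["d"], x$offsets["s"]))
  invisible(x)
}

#' Mirror a detector unit
#'
#' Returns the oppositely tuned unit: same weights, arm offsets negated.
#'
#' @param params a [detector_params()].
#' @return A `detector_params` with `preferred_sign` flipped.
#' @export
mirror_params <- function(params) {
  stopifnot(inherits(params, "detector_params"))
  params$preferred_sign <- -params$preferred_sign
  params$offsets <- -params$offsets
  params
}

#' Ablated model variants
#'
#' The two reduced models are obtained by zeroing one nonlinearity:
#' `"no_enhancement"` sets `k_E = 0` (null-direction suppression only),
#' `"no_suppression"` sets `k_S = 0` (preferred-direction enhancement only).
#'
#' @param params a [detector_params()].
#' @param variant `"full"`, `"no_enhancement"` or `"no_suppression"`.
#' @return A copy of `params` with the corresponding weight zeroed.
#' @export
ablate_params <- function(params,
                          variant = c("full", "no_enhancement", "no_suppression")) {
  stopifnot(inherits(params, "detector_params"))
  variant <- match.arg(variant)
  switch(variant,
         full = params,
         no_enhancement = { params$k_e <- 0; params },
         no_suppression = { params$k_s <- 0; params })
}

#' Response time series
#'
#' A uniformly sampled response trace (model output, dF/F, or a derived
#' quantity) with its resting baseline recorded alongside.
#'
#' @param values numeric vector of response values.
#' @param dt_s sampling interval in seconds.
#' @param baseline_value resting response level (finite).
#' @param label optional character label.
#' @return An object of class `response_trace`.
#' @export
response_trace <- function(values, dt_s, baseline_value = 0, label = "") {
  stopifnot(is.numeric(values), length(values) >= 1, dt_s > 0,
            is.finite(baseline_value))
  structure(list(values = as.numeric(values), dt_s = dt_s,
                 baseline_value = baseline_value, label = label),
            class = "response_trace")
}

#' @export
print.response_trace <- function(x, ...) {
  cat(sprintf("<response_trace>%s %d samples, dt %g s, baseline %g, range [%g, %g]\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$values), x$dt_s, x$baseline_value,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Time axis of a response trace (t = 0 at the first sample)
#' @param trace a [response_trace()].
#' @return Numeric vector of sample times in seconds.
#' @export
trace_time <- function(trace) (seq_along(trace$values) - 1) * trace$dt_s

#' Baseline-subtract a response trace
#' @param trace a [response_trace()].
#' @return The trace with `baseline_value` subtracted and reset to 0.
#' @export
baseline_subtract <- function(trace) {
  trace$values <- trace$values - trace$baseline_value
  trace$baseline_value <- 0
  trace
}

#' Single three-arm detector unit
#'
#' Computes `R(t) = (k_E * LP(E) + dc) * (k_D * D + dc) / (k_S * LP(S) + dc)`
#' from the three L1 input traces, with `LP` the first-order low-pass of time
#' constant `tau_lp_s`. The response is strictly positive for nonnegative
#' inputs (the denominator never drops below `dc_term`). The recorded baseline
#' is the response at the first sample, which equals the resting response
#' whenever the inputs begin at their background steady state (filters are
#' initialized at steady state; experiment runners prepend >= 5 tau of
#' background to guarantee this).
#'
#' @param e_in,d_in,s_in L1 output traces (nonnegative, shared grid) feeding
#'   the enhancing, direct and suppressing arms.
#' @param params a [detector_params()].
#' @param dt_s sampling interval in seconds.
#' @return A [response_trace()] with `baseline_value` set to the rest level.
#' @export
t4_unit <- function(e_in, d_in, s_in, params, dt_s) {
  stopifnot(inherits(params, "detector_params"))
  if (length(e_in) != length(d_in) || length(d_in) != length(s_in))
    stop("the three arm traces must share the same time grid")
  dc <- params$dc_term
  lp_e <- filter_first_order(e_in, params$tau_lp_s, dt_s, mode = "low")
  lp_s <- filter_first_order(s_in, params$tau_lp_s, dt_s, mode = "low")
  r <- (params$k_e * lp_e + dc) * (params$k_d * d_in + dc) /
       (params$k_s * lp_s + dc)
  response_trace(r, dt_s = dt_s, baseline_value = r[1], label = "t4_unit")
}

# home-column indices whose three arms all exist on the raster
array_home_columns <- function(n_columns, params) {
  lo <- 1 - min(params$offsets)
  hi <- n_columns - max(params$offsets)
  if (lo > hi) integer(0) else lo:hi
}

#' Summed response of a detector array
#'
#' One unit per visual column; units whose E, D or S input column falls off
#' the raster edge are omitted (no wraparound). The array response is the sum
#' of unit responses and the array baseline the sum of unit baselines.
#'
#' @param l1_traces a `column_traces` object of L1 outputs (>= 3 columns), as
#'   from [lamina_l1_columns()].
#' @param params a [detector_params()].
#' @return A [response_trace()].
#' @export
t4_array <- function(l1_traces, params) {
  stopifnot(inherits(l1_traces, "column_traces"))
  n <- ncol(l1_traces$values)
  if (n < 3) stop("a detector array needs at least 3 columns")
  homes <- array_home_columns(n, params)
  total <- numeric(nrow(l1_traces$values))
  base <- 0
  for (i in homes) {
    u <- t4_unit(l1_traces$values[, i + params$offsets["e"]],
                 l1_traces$values[, i + params$offsets["d"]],
                 l1_traces$values[, i + params$offsets["s"]],
                 params, dt_s = l1_traces$dt_s)
    total <- total + u$values
    base <- base + u$baseline_value
  }
  response_trace(total, dt_s = l1_traces$dt_s, baseline_value = base,
                 label = "t4_array")
}

#' Opponent tangential-cell stage
#'
#' Model wide-field tangential cell: the baseline-subtracted response of the
#' preferred-direction detector array minus that of the mirrored
#' (oppositely tuned) array. Identical inputs to both arrays — e.g. spatially
#' uniform flicker — give a zero trace.
#'
#' @inheritParams t4_array
#' @return A baseline-subtracted [response_trace()] (baseline 0).
#' @export
tangential <- function(l1_traces, params) {
  pd <- baseline_subtract(t4_array(l1_traces, params))
  nd <- baseline_subtract(t4_array(l1_traces, mirror_params(params)))
  response_trace(pd$values - nd$values, dt_s = pd$dt_s, baseline_value = 0,
                 label = "tangential")
}
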