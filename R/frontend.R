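#' First-order temporal filter
#'
#' Discrete first-order low- or high-pass filter with exact exponential
#' discretization: the low-pass recursion is
#' `y[n] = a * y[n-1] + (1 - a) * x[n]` with `a = exp(-dt/tau)`, equivalent to
#' convolution of a zero-order-hold input with the continuous exponential
#' kernel `exp(-t/tau)/tau`. The high-pass is the complement `x - LP(x)`, so
#' low-pass plus high-pass reconstructs the input exactly.
#'
#' With `init = "steady"` (default) the filter state starts at the first
#' sample, i.e. the input is treated as having been held at `x[1]` for all
#' past time; constant inputs are then exact fixed points. `init = "zero"`
#' starts from an empty state.
#'
#' @param x numeric vector, a uniformly sampled trace.
#' @param tau_s filter time constant in seconds (> 0).
#' @param dt_s sampling interval in seconds; `dt_s > tau_s/5` triggers a
#'   warning (the discretization is exact for piecewise-constant inputs but a
#'   coarse grid under-resolves the signal itself).
#' @param mode `"low"` or `"high"`.
#' @param init `"steady"` (default) or `"zero"`.
#' @return Filtered trace, same length and sampling as `x`.
#' @export
filter_first_order <- function(x, tau_s, dt_s, mode = c("low", "high"),
                               init = c("steady", "zero")) {
  mode <- match.arg(mode)
  init <- match.arg(init)
  if (tau_s <= 0) stop("filter time constant must be positive")
  if (length(x) == 0) stop("cannot filter an empty trace")
  if (dt_s > tau_s / 5)
    warning(sprintf("dt = %g s is coarse relative to tau = %g s (dt > tau/5)",
                    dt_s, tau_s))
  a <- exp(-dt_s / tau_s)
  y0 <- if (init == "steady") x[1] else 0
  lp <- as.numeric(stats::filter((1 - a) * x, a, method = "recursive",
                                 init = y0))
  if (mode == "low") lp else x - lp
}

# column-wise filtering of a time x column matrix
filter_columns <- function(values, tau_s, dt_s, mode = "low") {
  apply(values, 2, filter_first_order, tau_s = tau_s, dt_s = dt_s, mode = mode)
}

#' Lamina L1 front-end transformation
#'
#' The ON-pathway input stage: the local luminance signal is high-pass
#' filtered (first order, tau = 250 ms), a fraction of the DC value is added
#' back, and the result is half-wave rectified at zero:
#' `L1 = max(0, HP(x) + dc_fraction * DC)`.
#'
#' "DC value" defaults to the temporal mean of the input trace
#' (`dc_mode = "mean"`); alternatively a fixed background level can be used
#' (`dc_mode = "background"` with `background` supplied), which pins the
#' resting output at `dc_fraction * background` independently of the stimulus
#' content of the trace.
#'
#' @param x nonnegative luminance trace.
#' @param dt_s sampling interval in seconds.
#' @param dc_fraction fraction of the DC value restored (default 0.1).
#' @param tau_s high-pass time constant in seconds (default 0.25).
#' @param dc_mode `"mean"` (default) or `"background"`.
#' @param background background luminance level, required for
#'   `dc_mode = "background"`.
#' @return Nonnegative trace of the same length.
#' @export
lamina_l1 <- function(x, dt_s, dc_fraction = 0.1, tau_s = 0.25,
                      dc_mode = c("mean", "background"), background = NULL) {
  dc_mode <- match.arg(dc_mode)
  if (any(x < 0)) stop("luminance input must be nonnegative")
  dc <- switch(dc_mode,
               mean = mean(x),
               background = {
                 if (is.null(background))
                   stop("dc_mode = \"background\" requires `background`")
                 background
               })
  hp <- filter_first_order(x, tau_s = tau_s, dt_s = dt_s, mode = "high")
  pmax(0, hp + dc_fraction * dc)
}

#' Apply the L1 front-end to every column trace
#'
#' @param traces a `column_traces` object from [sample_columns()].
#' @param ... passed on to [lamina_l1()].
#' @return A `column_traces` object of L1 output traces.
#' @export
lamina_l1_columns <- function(traces, ...) {
  stopifnot(inherits(traces, "column_traces"))
  out <- traces
  out$values <- apply(traces$values, 2, lamina_l1, dt_s = traces$dt_s, ...)
  out
}
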