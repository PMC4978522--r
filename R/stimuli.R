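#' Space-time luminance movie
#'
#' The common input currency of the model: a dimensionless luminance grid over
#' one spatial dimension (degrees of visual angle) and time (seconds). Spatial
#' samples sit at cell centers, i.e. sample `j` covers
#' `[(j-1)*dx_deg, j*dx_deg)` and is evaluated at `x = (j - 1/2)*dx_deg`; time
#' sample `i` is at `t = (i-1)*dt_s`.
#'
#' @param values numeric matrix, space (rows) by time (columns), all values in
#'   `[0, 1]`.
#' @param dx_deg spatial step in degrees (default 1).
#' @param dt_s temporal step in seconds (default 0.01).
#' @return An object of class `stimulus_movie` with fields `values`, `dx_deg`,
#'   `dt_s`, `extent_deg`, `duration_s`.
#' @export
stimulus_movie <- function(values, dx_deg = 1, dt_s = 0.01) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), dx_deg > 0, dt_s > 0)
  if (anyNA(values) || min(values) < 0 || max(values) > 1)
    stop("movie luminance values must lie in [0, 1]")
  structure(
    list(values = values, dx_deg = dx_deg, dt_s = dt_s,
         extent_deg = nrow(values) * dx_deg,
         duration_s = ncol(values) * dt_s),
    class = "stimulus_movie")
}

#' @export
print.stimulus_movie <- function(x, ...) {
  cat(sprintf("<stimulus_movie> %d x %d (space x time), %g deg x %g s (dx=%g deg, dt=%g s)\n",
              nrow(x$values), ncol(x$values), x$extent_deg, x$duration_s,
              x$dx_deg, x$dt_s))
  invisible(x)
}

# x-coordinates of the spatial samples (cell centers)
movie_x <- function(movie) (seq_len(nrow(movie$values)) - 0.5) * movie$dx_deg

# t-coordinates of the time samples
movie_t <- function(movie) (seq_len(ncol(movie$values)) - 1) * movie$dt_s

#' Linear array of visual columns
#'
#' The model maps the stimulus onto a linear array of visual columns (default
#' 40 columns at 5 degree pitch, covering a 200 degree extent). Column centers
#' are at `(k - 1/2) * pitch_deg`.
#'
#' @param n_columns number of columns (>= 3; default 40).
#' @param pitch_deg inter-column spacing in degrees (default 5).
#' @return An object of class `linear_raster` with `n_columns`, `pitch_deg` and
#'   derived `center_positions_deg`.
#' @export
linear_raster <- function(n_columns = 40, pitch_deg = 5) {
  stopifnot(n_columns >= 3, pitch_deg > 0)
  structure(
    list(n_columns = as.integer(n_columns), pitch_deg = pitch_deg,
         center_positions_deg = (seq_len(n_columns) - 0.5) * pitch_deg),
    class = "linear_raster")
}

#' @export
print.linear_raster <- function(x, ...) {
  cat(sprintf("<linear_raster> %d columns, pitch %g deg, centers %g..%g deg\n",
              x$n_columns, x$pitch_deg, x$center_positions_deg[1],
              x$center_positions_deg[x$n_columns]))
  invisible(x)
}

#' Light-pulse stimulation protocol
#'
#' An ordered list of rectangular luminance pulses delivered to individual
#' visual columns, identified by their integer position relative to a reference
#' column (0 = reference, -1 = null side, +1 = preferred side).
#'
#' @param column integer vector of relative column positions, one per event.
#' @param onset_s pulse onset times in seconds (recycled against `column`).
#' @param duration_s pulse durations in seconds (default 0.45, the model pulse
#'   length; the single-column experimental protocols used 0.472 s).
#' @param amplitude pulse luminance amplitudes in `[0, 1]` (default 1).
#' @param background background luminance in `[0, 1]` (default 0).
#' @return An object of class `pulse_protocol`: a data frame of events (sorted
#'   by onset) with attribute `background`.
#' @export
pulse_protocol <- function(column, onset_s, duration_s = 0.45, amplitude = 1,
                           background = 0) {
  ev <- if (length(column) == 0) {
    data.frame(column = integer(0), onset_s = numeric(0),
               duration_s = numeric(0), amplitude = numeric(0))
  } else {
    data.frame(column = as.integer(column), onset_s = onset_s,
               duration_s = duration_s, amplitude = amplitude)
  }
  stopifnot(all(ev$duration_s > 0), all(ev$amplitude >= 0),
            all(ev$amplitude <= 1), all(ev$onset_s >= 0),
            background >= 0, background <= 1)
  ev <- ev[order(ev$onset_s, ev$column), , drop = FALSE]
  rownames(ev) <- NULL
  structure(ev, background = background,
            class = c("pulse_protocol", "data.frame"))
}

#' @export
print.pulse_protocol <- function(x, ...) {
  cat(sprintf("<pulse_protocol> %d event(s), background %g\n",
              nrow(x), attr(x, "background")))
  print.data.frame(x)
  invisible(x)
}

#' Drifting-grating stimulus specification
#'
#' @param wavelength_deg spatial wavelength lambda in degrees (default 50).
#' @param contrast Michelson contrast in `[0, 1]` (default 1).
#' @param temporal_frequency_hz drift rate in cycles per second (default 1).
#' @param direction_deg motion direction theta in degrees; 0 is motion along
#'   the detector's preferred axis (+x), 180 the reverse. Off-axis directions
#'   are projected onto the 1-D column axis via `cos(theta)` in the spatial
#'   phase, so theta = 90 yields full-field flicker.
#' @param waveform `"sine"` or `"square"` (sign of the sine).
#' @param mean_luminance mean level; default 0.5 so contrast 1 spans `[0, 1]`.
#' @return An object of class `grating_spec`.
#' @export
grating_spec <- function(wavelength_deg = 50, contrast = 1,
                         temporal_frequency_hz = 1, direction_deg = 0,
                         waveform = c("sine", "square"),
                         mean_luminance = 0.5) {
  waveform <- match.arg(waveform)
  if (wavelength_deg <= 0) stop("grating wavelength must be positive")
  if (contrast < 0 || contrast > 1) stop("contrast must lie in [0, 1]")
  lo <- mean_luminance * (1 - contrast)
  hi <- mean_luminance * (1 + contrast)
  if (lo < 0 || hi > 1)
    stop(sprintf(
      "mean %g with contrast %g drives luminance to [%g, %g], outside [0, 1]",
      mean_luminance, contrast, lo, hi))
  structure(
    list(wavelength_deg = wavelength_deg, contrast = contrast,
         temporal_frequency_hz = temporal_frequency_hz,
         direction_deg = direction_deg, waveform = waveform,
         mean_luminance = mean_luminance),
    class = "grating_spec")
}

#' Build a movie from a pulse protocol
#'
#' Renders rectangular single-column light pulses into a space-time luminance
#' movie. Each event occupies the full spatial footprint of its column (one
#' pitch, centered on the column center) during `[onset, onset + duration)`.
#'
#' @param protocol a [pulse_protocol()].
#' @param raster a [linear_raster()].
#' @param duration_s movie duration in seconds.
#' @param reference_column absolute index of the column that relative position
#'   0 refers to; defaults to the central column of the raster.
#' @param dt_s,dx_deg movie resolution (defaults 0.01 s, 1 deg).
#' @return A [stimulus_movie()].
#' @export
build_pulse_movie <- function(protocol, raster, duration_s,
                              reference_column = (raster$n_columns + 1) %/% 2,
                              dt_s = 0.01, dx_deg = 1) {
  stopifnot(inherits(protocol, "pulse_protocol"), inherits(raster, "linear_raster"))
  background <- attr(protocol, "background")
  nx <- round(raster$n_columns * raster$pitch_deg / dx_deg)
  nt <- round(duration_s / dt_s)
  vals <- matrix(background, nrow = nx, ncol = nt)
  x <- (seq_len(nx) - 0.5) * dx_deg
  for (i in seq_len(nrow(protocol))) {
    ev <- protocol[i, ]
    col_abs <- reference_column + ev$column
    if (col_abs < 1 || col_abs > raster$n_columns)
      stop(sprintf("event %d (relative column %d, onset %g s) falls outside the raster",
                   i, ev$column, ev$onset_s))
    if (ev$onset_s + ev$duration_s > duration_s + 1e-9)
      stop(sprintf("event %d (relative column %d, onset %g s) extends past the movie duration %g s",
                   i, ev$column, ev$onset_s, duration_s))
    ctr <- raster$center_positions_deg[col_abs]
    xi <- which(x >= ctr - raster$pitch_deg / 2 & x < ctr + raster$pitch_deg / 2)
    t0 <- round(ev$onset_s / dt_s) + 1
    t1 <- t0 + round(ev$duration_s / dt_s) - 1
    vals[xi, t0:min(t1, nt)] <- ev$amplitude
  }
  stimulus_movie(vals, dx_deg = dx_deg, dt_s = dt_s)
}

#' Build a drifting-grating movie
#'
#' Luminance follows
#' `mean * (1 + contrast * w(2 * pi * (cos(theta) * x / lambda - f * t)))`
#' with `w` the sine (or its sign, for square waves). Motion at theta = 0 is
#' along +x, the preferred axis; theta = 180 reverses it.
#'
#' @param spec a [grating_spec()].
#' @param duration_s movie duration in seconds.
#' @param extent_deg spatial extent in degrees (default 200).
#' @param dt_s,dx_deg movie resolution (defaults 0.01 s, 1 deg). Temporal
#'   frequencies above ~1/(10 dt) need a finer `dt_s` to avoid aliasing.
#' @return A [stimulus_movie()].
#' @export
build_grating_movie <- function(spec, duration_s, extent_deg = 200,
                                dt_s = 0.01, dx_deg = 1) {
  stopifnot(inherits(spec, "grating_spec"))
  nx <- round(extent_deg / dx_deg)
  nt <- round(duration_s / dt_s)
  x <- (seq_len(nx) - 0.5) * dx_deg
  t <- (seq_len(nt) - 1) * dt_s
  # cospi gives exact 0 at 90 deg and exact +-1 on the axis
  phase <- outer(cospi(spec$direction_deg / 180) * x / spec$wavelength_deg,
                 spec$temporal_frequency_hz * t, `-`) * 2 * pi
  w <- sin(phase)
  if (spec$waveform == "square") w <- ifelse(w >= 0, 1, -1)
  vals <- spec$mean_luminance * (1 + spec$contrast * w)
  # guard against round-off just past the closed bounds
  vals[vals < 0 & vals > -1e-12] <- 0
  vals[vals > 1 & vals < 1 + 1e-12] <- 1
  stimulus_movie(vals, dx_deg = dx_deg, dt_s = dt_s)
}

#' Sample a movie onto the column raster
#'
#' Reads out one luminance trace per visual column. The default rule is a
#' point sample at the column center (the sample whose x-coordinate is nearest
#' the center); `method = "boxcar"` instead averages over one pitch around the
#' center.
#'
#' @param movie a [stimulus_movie()].
#' @param raster a [linear_raster()]; must fit within the movie extent.
#' @param method `"point"` (default) or `"boxcar"`.
#' @return An object of class `column_traces`: list with `values` (time x
#'   column matrix), `dt_s`, and `centers_deg`.
#' @export
sample_columns <- function(movie, raster, method = c("point", "boxcar")) {
  method <- match.arg(method)
  stopifnot(inherits(movie, "stimulus_movie"), inherits(raster, "linear_raster"))
  if (raster$n_columns * raster$pitch_deg > movie$extent_deg + 1e-9)
    stop("raster is wider than the movie extent")
  x <- movie_x(movie)
  vals <- vapply(raster$center_positions_deg, function(ctr) {
    if (method == "point") {
      movie$values[which.min(abs(x - ctr)), ]
    } else {
      xi <- which(x >= ctr - raster$pitch_deg / 2 & x < ctr + raster$pitch_deg / 2)
      colMeans(movie$values[xi, , drop = FALSE])
    }
  }, numeric(ncol(movie$values)))
  structure(list(values = vals, dt_s = movie$dt_s,
                 centers_deg = raster$center_positions_deg),
            class = "column_traces")
}

#' @export
print.column_traces <- function(x, ...) {
  cat(sprintf("<column_traces> %d columns x %d time samples, dt %g s\n",
              ncol(x$values), nrow(x$values), x$dt_s))
  invisible(x)
}
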