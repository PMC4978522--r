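# Shared test fixtures and independent oracles (built in code, no stored data).

# Direct-convolution oracle for the first-order low-pass: FFT convolution of
# the input with the exact exponential kernel, plus the contribution of the
# input held at x[1] for all past time (the steady-state initial condition).
# Independent of the recursive implementation path.
conv_lowpass_oracle <- function(x, tau_s, dt_s) {
  n <- length(x)
  a <- exp(-dt_s / tau_s)
  h <- (1 - a) * a^(0:(n - 1))
  full <- stats::convolve(x, rev(h), type = "open")
  full[seq_len(n)] + x[1] * a^(seq_len(n))
}

# random nonnegative smooth-ish luminance-like trace in [0, 1]
random_luminance <- function(n, dt_s) {
  f <- stats::runif(3, 0.2, 2)
  ph <- stats::runif(3, 0, 2 * pi)
  t <- (seq_len(n) - 1) * dt_s
  v <- rowSums(sapply(1:3, function(k) sin(2 * pi * f[k] * t + ph[k])))
  (v - min(v)) / max(1e-12, diff(range(v)))
}

# uniform-luminance column traces (for detector rest/flicker tests)
constant_columns <- function(value, n_time, n_col = 5, dt_s = 0.01) {
  structure(list(values = matrix(value, nrow = n_time, ncol = n_col),
                 dt_s = dt_s,
                 centers_deg = (seq_len(n_col) - 0.5) * 5),
            class = "column_traces")
}

# nonlinear component of a synthetic recording: the sequence condition minus
# the sum of flicker conditions whose events already sit at their sequence
# onsets (zero-amplitude marker events pad all conditions to a common span).
recording_nlc <- function(recording, seq_name, flicker_names) {
  avg <- function(nm) colMeans(recording$conditions[[nm]]$traces)
  s <- avg(seq_name)
  for (nm in flicker_names) s <- s - avg(nm)
  s
}

# random apparent-motion protocol on the hex raster: K events at distinct
# columns, onsets on the sample grid; returns the sequence condition plus one
# flicker condition per event, padded to a common span
random_hex_conditions <- function(raster, dt_s = 0.01) {
  k <- sample(2:4, 1)
  cols <- raster$columns[sample(nrow(raster$columns), k), ]
  onsets <- round(cumsum(c(0, stats::runif(k - 1, 0.1, 0.6))) / dt_s) * dt_s
  dur <- 0.472
  span <- max(onsets) + dur
  # zero-amplitude marker event at the end keeps every condition the same length
  pad <- function(q, r, onset)
    hex_protocol(c(q, 0), c(r, 0), onset_s = c(onset, span - dt_s),
                 duration_s = c(dur, dt_s), amplitude = c(1, 0))
  seq_proto <- hex_protocol(c(cols$q, 0), c(cols$r, 0),
                            onset_s = c(onsets, span - dt_s),
                            duration_s = c(rep(dur, k), dt_s),
                            amplitude = c(rep(1, k), 0))
  conds <- c(list(seq = seq_proto),
             lapply(seq_len(k), function(i) pad(cols$q[i], cols$r[i], onsets[i])))
  names(conds)[-1] <- paste0("flick_", seq_len(k))
  conds
}
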