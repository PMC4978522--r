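test_that("dF/F normalizes by the baseline-window mean", {
  f0 <- 2.5
  raw <- response_trace(c(rep(f0, 100), rep(2 * f0, 50), rep(f0, 50)),
                        dt_s = 0.01)
  out <- dff(raw, baseline_window = c(0, 1))
  expect_equal(out$values[1:100], rep(0, 100))
  expect_equal(out$values[101:150], rep(1, 50))  # doubling -> dF/F = 1

  # a later baseline window (the luminance-offset convention) changes F0
  out2 <- dff(raw, baseline_window = c(1, 1.5))
  expect_equal(out2$values[1], (f0 - 2 * f0) / (2 * f0))

  expect_error(dff(response_trace(rep(0, 10), 0.01), c(0, 0.05)), "positive")
})

test_that("response quantification subtracts baseline and takes peak or mean", {
  tr <- response_trace(c(rep(0.2, 100), 0.2 + 0.7 * sin(pi * (1:100) / 100),
                         rep(0.2, 100)), dt_s = 0.01)
  expect_equal(quantify_response(tr, c(0, 1), c(1, 2))$value, 0.7)
  expect_equal(quantify_response(response_trace(rep(0.3, 200), 0.01),
                                 c(0, 1), c(1, 2))$value, 0)

  # a full cycle centered on baseline: mean ~ 0, peak > 0
  cyc <- response_trace(c(rep(0, 100), sin(2 * pi * (0:99) / 100)), dt_s = 0.01)
  expect_equal(quantify_response(cyc, c(0, 1), c(1, 2), "mean")$value, 0,
               tolerance = 1e-12)
  expect_gt(quantify_response(cyc, c(0, 1), c(1, 2), "peak")$value, 0.9)

  expect_error(quantify_response(tr, c(0, 1.5), c(1, 2)), "overlap")
})

test_that("linear expectation shifts and sums flicker responses", {
  dt <- 0.01
  rect <- function(n0, n1, n = 100)
    response_trace(rep(c(0, 1, 0), c(n0, n1 - n0, n - n1)), dt_s = dt)
  flick <- list("-1" = rect(0, 20), "0" = rect(0, 20))

  # non-overlapping shifts: concatenated rectangles
  proto <- pulse_protocol(c(-1L, 0L), onset_s = c(0, 0.5), duration_s = 0.2)
  lin <- linear_expectation(flick, proto, n_out = 100)
  expect_equal(lin$values, rep(c(1, 0, 1, 0), c(20, 30, 20, 30)))

  # overlapping shifts add pointwise
  proto2 <- pulse_protocol(c(-1L, 0L), onset_s = c(0, 0.1), duration_s = 0.2)
  lin2 <- linear_expectation(flick, proto2, n_out = 100)
  expect_equal(lin2$values, rep(c(1, 2, 1, 0), c(10, 10, 10, 70)))

  # additivity: expectation of a concatenated protocol = sum of expectations
  pa <- pulse_protocol(-1L, 0, duration_s = 0.2)
  pb <- pulse_protocol(0L, 0.5, duration_s = 0.2)
  both <- pulse_protocol(c(-1L, 0L), c(0, 0.5), duration_s = 0.2)
  expect_equal(linear_expectation(flick, both, n_out = 100)$values,
               linear_expectation(flick, pa, n_out = 100)$values +
                 linear_expectation(flick, pb, n_out = 100)$values)

  expect_error(linear_expectation(flick["0"], proto), "no flicker trace.*-1")
})

test_that("the nonlinear component of any linear generator vanishes", {
  set.seed(31)
  dt <- 0.01
  kern <- exp(-(0:199) * dt / 0.3)
  linear_cell <- function(onsets, gains) {
    drive <- numeric(400)
    for (i in seq_along(onsets)) {
      k <- round(onsets[i] / dt)
      drive[(k + 1):(k + 47)] <- drive[(k + 1):(k + 47)] + gains[i]
    }
    response_trace(stats::convolve(drive, rev(kern), type = "open")[1:400],
                   dt_s = dt)
  }
  for (rep in 1:10) {
    k <- sample(2:4, 1)
    cols <- sample(-2:2, k)
    onsets <- round(cumsum(c(0, runif(k - 1, 0.1, 0.8))), 2)
    gains <- runif(k, 0.3, 1)
    proto <- pulse_protocol(cols, onsets, duration_s = 0.47)
    flick <- lapply(seq_len(k), function(i) linear_cell(0, gains[i]))
    names(flick) <- as.character(cols)
    seq_tr <- linear_cell(onsets, gains)
    nlc <- nonlinear_component(seq_tr, flick, proto)
    expect_lt(max(abs(nlc$values)), 1e-9)
  }
})

test_that("receptive-field maps align, normalize and average across cells", {
  raster <- make_hex_raster(2)
  rf <- synth_rf(raster, preset = "T4")

  # single noiseless cell: map equals the ring amplitudes exactly
  m1 <- rf_map(rf$amplitude, raster)
  expect_equal(m1$mean[m1$ring == 0], 1)
  expect_equal(m1$mean[m1$ring == 1], rep(0.5, 6))
  expect_equal(m1$mean[m1$ring == 2], rep(0.25, 12))
  expect_true(all(m1$sem == 0))

  # two cells with shifted peaks and scaled amplitudes: alignment and
  # normalization recover the common shape with zero dispersion at center
  shift_cell <- function(dq, dr, scale) {
    a <- numeric(nrow(raster$columns))
    for (i in seq_len(nrow(raster$columns))) {
      d <- flyemd:::hex_distance(raster$columns$q[i], raster$columns$r[i], dq, dr)
      a[i] <- scale * c(1, 0.5, 0.25, 0, 0)[d + 1]
    }
    a
  }
  cells <- rbind(shift_cell(0, 0, 1), shift_cell(1, 0, 7.3))
  m2 <- rf_map(cells, raster)
  expect_equal(m2$mean[m2$ring == 0], 1)
  expect_equal(m2$mean[m2$ring == 1], rep(0.5, 6))
  # relabeling cells leaves the map unchanged
  expect_equal(rf_map(cells[2:1, ], raster), m2)

  expect_error(rf_map(rbind(rf$amplitude, 0), raster), "all-zero")
})

test_that("axis profiles slice the three hexagonal axes through the center", {
  raster <- make_hex_raster(2)
  m <- rf_map(synth_rf(raster, preset = "T4")$amplitude, raster)
  for (ax in c("D-V", "DL-VF", "DF-VL")) {
    pr <- axis_profile(m, ax)
    expect_equal(pr$mean, c(0.25, 0.5, 1, 0.5, 0.25))
    expect_equal(pr$position, -2:2)
  }
  center_only <- as.numeric(raster$columns$ring == 0)
  pr0 <- axis_profile(rf_map(center_only, raster), "D-V")
  expect_equal(pr0$mean, c(0, 0, 1, 0, 0))
  expect_error(axis_profile(m, "A-P"), "arg")
})

test_that("pair-suppression ratios and the DSI behave at the boundaries", {
  expect_equal(unname(pair_suppression_map(c(a = 3, b = 1), 2)), c(1.5, 0.5))
  expect_equal(unname(pair_suppression_map(c(center = 99, b = 1), 2,
                                           center_id = "center")["center"]), 1)
  # linear noiseless cell: ratios never drop below 1 (pure summation)
  lin_pairs <- c(p1 = 1 + 0.5, p2 = 1 + 0.25)
  expect_true(all(pair_suppression_map(lin_pairs, 1) >= 1))
  expect_error(pair_suppression_map(c(a = 1), 0), "positive")

  expect_equal(dsi(2, 2), 0)
  expect_equal(dsi(3, 0), 1)
  expect_equal(dsi(3, -1), 1)  # negative amplitudes clip at zero
  expect_error(dsi(0, 0), "zero")
})

test_that("tuning-curve normalization pins the maximum at one", {
  cv <- structure(data.frame(frequency = c(1, 2), pd = c(4, 8), nd = c(1, 2)),
                  class = c("tuning_curve", "data.frame"))
  nv <- normalize_curve(cv)
  expect_equal(max(nv$pd, nv$nd), 1)
  expect_equal(nv$nd, c(0.125, 0.25))
})
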