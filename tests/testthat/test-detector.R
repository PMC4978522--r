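test_that("detector unit algebra matches the closed forms", {
  p <- detector_params()
  n <- 300
  # resting inputs: DC terms only, R = dc^2/dc = 1
  u0 <- t4_unit(rep(0, n), rep(0, n), rep(0, n), p, dt_s = 0.01)
  expect_equal(u0$values, rep(1, n))
  expect_equal(u0$baseline_value, 1)
  expect_equal(baseline_subtract(u0)$values, rep(0, n))

  # steady arms at 0.1: (5*0.1+1)^2 / (10*0.1+1) = 1.125
  u1 <- t4_unit(rep(0.1, n), rep(0.1, n), rep(0.1, n), p, dt_s = 0.01)
  expect_equal(u1$values, rep(1.125, n))

  expect_error(t4_unit(rep(0, 10), rep(0, 11), rep(0, 10), p, 0.01),
               "same time grid")
})

test_that("detector response is strictly positive for admissible inputs", {
  set.seed(21)
  p <- detector_params()
  for (i in 1:10) {
    e <- lamina_l1(random_luminance(400, 0.01), 0.01)
    d <- lamina_l1(random_luminance(400, 0.01), 0.01)
    s <- lamina_l1(random_luminance(400, 0.01), 0.01)
    expect_gt(min(t4_unit(e, d, s, p, 0.01)$values), 0)
  }
})

test_that("zero-contrast stimuli produce a constant, baseline-zero response", {
  raster <- linear_raster()
  movie <- build_grating_movie(grating_spec(contrast = 0), duration_s = 2)
  l1 <- lamina_l1_columns(sample_columns(movie, raster))
  arr <- t4_array(l1, detector_params())
  expect_lt(diff(range(arr$values)), 1e-12)
  expect_lt(max(abs(baseline_subtract(arr)$values)), 1e-12)
})

test_that("apparent-motion sequences split into enhancement and suppression", {
  # preferred-direction pair crosses the linear expectation upward,
  # null-direction pair falls below it
  pd <- apparent_motion_nlc(c(-1L, 0L))
  nd <- apparent_motion_nlc(c(1L, 0L))
  expect_gt(max(pd$nlc$values), 0.5)
  expect_lt(min(nd$nlc$values), -0.5)
  # flicker responses at the stimulated positions are reproduced by the
  # linear expectation of the single-event protocol
  single <- pulse_protocol(0L, 0)
  lin <- linear_expectation(pd$flicker["0"], single)
  expect_equal(lin$values,
               baseline_subtract(pd$flicker[["0"]])$values[seq_along(lin$values)])
})

test_that("detector arrays degenerate, mirror and oppose correctly", {
  p <- detector_params()
  # 3-column input: array equals the single unit
  l1_3 <- structure(list(values = matrix(lamina_l1(c(rep(0, 50), rep(1, 45),
                                                     rep(0, 55)), 0.01),
                                         ncol = 3, nrow = 150),
                         dt_s = 0.01, centers_deg = c(2.5, 7.5, 12.5)),
                    class = "column_traces")
  arr <- t4_array(l1_3, p)
  unit <- t4_unit(l1_3$values[, 1], l1_3$values[, 2], l1_3$values[, 3], p, 0.01)
  expect_equal(arr$values, unit$values)

  # spatially uniform flicker: PD and ND arrays are identical, opponent zero
  flick <- constant_columns(0, 200, n_col = 6)
  flick$values[80:120, ] <- 1
  l1u <- lamina_l1_columns(flick)
  expect_equal(t4_array(l1u, p)$values, t4_array(l1u, mirror_params(p))$values)
  expect_equal(tangential(l1u, p)$values, rep(0, 200))

  expect_error(t4_array(constant_columns(0, 10, n_col = 2), p), "3 columns")
})

test_that("a mirrored stimulus through a mirrored detector reproduces the response", {
  raster <- linear_raster()
  proto <- pulse_protocol(c(-1L, 0L), onset_s = c(0, 0.472))
  movie <- build_pulse_movie(proto, raster, duration_s = 2)
  l1 <- lamina_l1_columns(sample_columns(movie, raster))
  mirrored <- l1
  mirrored$values <- l1$values[, rev(seq_len(ncol(l1$values)))]
  p <- detector_params()
  # summation order across units differs, so equality is to round-off
  expect_equal(t4_array(l1, p)$values,
               t4_array(mirrored, mirror_params(p))$values,
               tolerance = 1e-12)
})

test_that("a lone pulse on the suppressing side is not detected as a response", {
  # mean-DC convention: any rebound above rest stays below the 5% detection
  # threshold relative to the direct-arm flicker response
  center <- max(baseline_subtract(flicker_response(0L))$values)
  side <- baseline_subtract(flicker_response(1L))
  expect_lt(max(side$values), 0.05 * center)
  expect_lt(min(side$values), 0)  # the divisive dip is retained in the trace

  # fixed-background DC convention: exactly no positive deflection
  side_bg <- baseline_subtract(flicker_response(1L, dc_mode = "background",
                                                background = 0))
  expect_lte(max(side_bg$values), 1e-9)
})

test_that("ablation zeroes exactly one weight", {
  p <- detector_params()
  expect_equal(ablate_params(p, "no_suppression")$k_s, 0)
  expect_equal(ablate_params(p, "no_suppression")$k_e, 5)
  expect_equal(ablate_params(p, "no_enhancement")$k_e, 0)
  expect_identical(ablate_params(p, "full"), p)
  expect_error(ablate_params(p, "no_dc"), "arg")
})
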