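# Isochromat simulator: closed-form limits, noise, reconstruction identities.

test_that("a 90-degree pulse followed by free decay gives |s| = PD * exp(-t/T2)", {
  ph <- point_phantom(t2 = 100, pd = 0.7)
  spec <- single_line_spec(te = 30, readout_us = 1000, n_columns = 2)
  k <- simulate_kspace(compile_sequence(spec), ph)
  # echo sample (k = 0) sits in column n/2 + 1 and is acquired at TE
  expect_equal(Mod(k$data[1, 2]), 0.7 * exp(-30 / 100), tolerance = 1e-9)
})

test_that("the spin-echo amplitude at TE is immune to uniform off-resonance", {
  spec <- single_line_spec(echo = "SpinEcho", te = 40, tr = 500)
  plan <- compile_sequence(spec)
  amps <- vapply(c(0, 37, 150), function(df) {
    ph <- point_phantom(t2 = 100, pd = 0.7, delta_f = df)
    Mod(simulate_kspace(plan, ph, off_resonance = TRUE)$data[1, 2])
  }, numeric(1))
  expect_equal(amps[1], 0.7 * exp(-40 / 100), tolerance = 1e-9)
  expect_lt(max(abs(amps - amps[1])), 1e-6)
})

test_that("the alternating-phase short-TR steady state matches the iterated recursion", {
  ph <- point_phantom(t1 = 1000, t2 = 100, pd = 1)
  spec <- single_line_spec(te = 4, tr = 8, readout_us = 500, n_columns = 2,
                           n_rows = 64, measurements = 4,
                           prescans = list(count = 8, type = "linear"))
  k <- simulate_kspace(compile_sequence(spec), ph)
  sim <- Mod(k$data[64, 2])      # last acquired line: > 250 TRs of history
  oracle <- bssfp_steady_state_oracle(flip = 90, tr = 8, te = 4,
                                      t1 = 1000, t2 = 100)
  expect_equal(sim, oracle, tolerance = 0.01)
})

test_that("add_noise is deterministic, scale-true, and a no-op at sigma 0", {
  ph <- point_phantom()
  k <- simulate_kspace(compile_sequence(single_line_spec()), ph)
  k$data <- matrix(0i, 64, 64)
  expect_identical(add_noise(k, 0)$data, k$data)
  n1 <- add_noise(k, 1, seed = 11)
  n2 <- add_noise(k, 1, seed = 11)
  expect_identical(n1$data, n2$data)
  expect_equal(stats::sd(Re(n1$data)), 1, tolerance = 0.05)
  expect_equal(stats::sd(Im(n1$data)), 1, tolerance = 0.05)
  expect_error(add_noise(k, -1), "non-negative")
})

test_that("reconstruction places a point source at its spatial position", {
  ph <- point_phantom(xs = -5, ys = 10, t1 = 1e9, t2 = 1e9, fov = c(100, 100))
  spec <- sequence_spec(
    name = "pt", echo_type = "GradientEcho", readout_type = "EPIReadout",
    excitation = list(pulse_type = "hard", angle = 90),
    readout_duration = 500, n_columns = 32, te = 15, tr = 100,
    epi_factor = 32, etl = 1, n_rows = 32, measurements = 1, spoiling = list())
  img <- reconstruct_image(simulate_kspace(compile_sequence(spec), ph))
  pk <- which(img$pixels == max(img$pixels), arr.ind = TRUE)
  expect_equal(unname(pk[1, ]), c(10 + 50 + 1, -5 + 50 + 1))
  expect_equal(dim(img$pixels), c(100, 100))  # 1-mm interpolation of the FOV
  expect_true(all(img$pixels >= 0))
})

test_that("a linear PE phase in k-space shifts the image circularly (shift theorem)", {
  ph <- point_phantom(xs = 0, ys = 0, t1 = 1e9, t2 = 1e9, fov = c(32, 32))
  spec <- sequence_spec(
    name = "pt", echo_type = "GradientEcho", readout_type = "EPIReadout",
    excitation = list(pulse_type = "hard", angle = 90),
    readout_duration = 500, n_columns = 32, te = 15, tr = 100,
    epi_factor = 32, etl = 1, n_rows = 32, measurements = 1, spoiling = list())
  k <- simulate_kspace(compile_sequence(spec), ph)
  base <- reconstruct_image(k)$pixels
  delta <- 7  # mm along PE
  m <- (seq_len(32) - 1 - 16) / 32
  k2 <- k
  k2$data <- k$data * exp(-2i * pi * m * delta * 32 / 32)
  shifted <- reconstruct_image(k2)$pixels
  expect_lt(max(abs(shifted - mrseqopt:::.circshift_rows(base, delta))), 1e-8)
})

test_that("k-space and complex image satisfy Parseval equality without relaxation", {
  ph <- point_phantom(xs = c(-10, 3, 8), ys = c(-4, 0, 11), t1 = 1e12,
                      t2 = 1e12, fov = c(64, 64))
  spec <- sequence_spec(
    name = "p", echo_type = "GradientEcho", readout_type = "EPIReadout",
    excitation = list(pulse_type = "hard", angle = 90),
    readout_duration = 500, n_columns = 16, te = 10, tr = 100,
    epi_factor = 16, etl = 1, n_rows = 16, measurements = 1, spoiling = list())
  k <- simulate_kspace(compile_sequence(spec), ph)
  cimg <- mrseqopt:::.ifft2_centered(k$data, 16, 16)
  # image scale is 1/(n1*n2): the unitary relation carries the n1*n2 factor
  expect_equal(sum(Mod(cimg)^2) * 16 * 16, sum(Mod(k$data)^2),
               tolerance = 1e-8)
})

test_that("EPI with uniform off-resonance shifts the image by the shift-theorem prediction", {
  plain <- make_circular_phantom(list(fov = c(100, 100)))
  offres <- make_circular_phantom(list(fov = c(100, 100),
                                       off_resonance_on = TRUE,
                                       off_resonance = 50))
  spec <- expand_defaults(parse_sequence(
    'define MRI sequence "E" using a "GradientEcho" with "EPIReadout".'))
  spec$measurements <- 1
  plan <- compile_sequence(spec)
  d <- distortion_sensitivity(
    reconstruct_image(simulate_kspace(plan, offres)),
    reconstruct_image(simulate_kspace(plan, plain)),
    plain$masks$evaluation)
  predicted_px <- 50 * plan$echo_spacing / 1000 * 100  # df * esp * FOV_pe
  expect_equal(d, predicted_px / 100)
})

test_that("odd/even-line phase errors create an N/2 ghost growing with the perturbation", {
  sq <- make_square_phantom()
  spec <- expand_defaults(parse_sequence(
    'define MRI sequence "B" using a "GradientEcho" with "LineReadout".'))
  k <- simulate_kspace(compile_sequence(spec), sq, off_resonance = FALSE,
                       motion = FALSE)
  ghosts <- vapply(c(0, 0.15, 0.3, 0.6), function(phi) {
    kp <- k
    odd <- seq(1, nrow(kp$data), by = 2)
    kp$data[odd, ] <- kp$data[odd, ] * exp(1i * phi)
    ghost_level(reconstruct_image(kp), sq$masks$object, sq$masks$ghost)
  }, numeric(1))
  expect_false(is.unsorted(ghosts))
  expect_gt(ghosts[4], ghosts[1] * 2)
})

test_that("motion during multi-shot acquisition degrades the image; none does not", {
  circ_m <- make_circular_phantom(list(motion_on = TRUE,
                                       motion = list(amplitude = 5, period = 4)))
  circ_0 <- make_circular_phantom()
  spec <- expand_defaults(parse_sequence(
    'define MRI sequence "R" using a "SpinEcho" with "LineReadout".'))
  plan <- compile_sequence(spec)
  ref <- reconstruct_image(simulate_kspace(plan, circ_0))
  mov <- reconstruct_image(simulate_kspace(plan, circ_m, motion = TRUE))
  frozen <- reconstruct_image(simulate_kspace(plan, circ_m, motion = FALSE))
  expect_gt(motion_sensitivity(mov, ref, circ_0$masks$evaluation), 0.001)
  expect_equal(motion_sensitivity(frozen, ref, circ_0$masks$evaluation), 0)
})
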