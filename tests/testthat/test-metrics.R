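# Image-quality metrics against constructed images and formula oracles.

test_that("contrast is the ratio of masked means", {
  img <- matrix(1, 10, 10)
  a <- b <- matrix(FALSE, 10, 10)
  a[1:3, 1:3] <- TRUE; b[7:9, 7:9] <- TRUE
  expect_equal(img_contrast(img, a, b), 1)
  img[a] <- 2 * 6; img[b] <- 6
  expect_equal(img_contrast(img, a, b), 2)
  img[a] <- 30; img[b] <- 12
  expect_equal(img_contrast(img, a, b), 2.5)
  img[b] <- 0
  expect_error(img_contrast(img, a, b), "zero mean")
})

test_that("SNR uses the Rayleigh-corrected background and recovers S/sigma", {
  set.seed(42)
  snrs <- replicate(4, {
    sigma <- 3
    noise <- matrix(complex(real = rnorm(64 * 64, 0, sigma),
                            imaginary = rnorm(64 * 64, 0, sigma)), 64, 64)
    img <- Mod(noise)
    tissue <- matrix(FALSE, 64, 64); tissue[1:10, 1:10] <- TRUE
    bg <- matrix(FALSE, 64, 64); bg[33:64, ] <- TRUE
    img[tissue] <- 120                     # known signal S
    img_snr(img, tissue, bg) / (120 / sigma)
  })
  expect_lt(abs(mean(snrs) - 1), 0.1)
  # noiseless degenerate background returns the cap
  flat <- matrix(1, 8, 8)
  m1 <- matrix(FALSE, 8, 8); m1[1:2, ] <- TRUE
  m2 <- matrix(FALSE, 8, 8); m2[7:8, ] <- TRUE
  expect_equal(img_snr(flat, m1, m2), 1e6)
})

test_that("ghost level recovers injected ghost fractions and is monotone", {
  sq <- make_square_phantom()
  base <- sq$reference
  lvl <- vapply(c(0, 0.05, 0.1, 0.3), function(g) {
    img <- base + g * mrseqopt:::.circshift_rows(base, 50)
    ghost_level(img, sq$masks$object, sq$masks$ghost)
  }, numeric(1))
  expect_equal(lvl[1], 0)
  expect_equal(lvl[3], 0.1, tolerance = 0.05)
  expect_false(is.unsorted(lvl))
  expect_error(ghost_level(base, sq$masks$object, sq$masks$object), "disjoint")
})

test_that("sharpness is 1 for affine images of the reference and matches the formula", {
  sq <- make_square_phantom()
  ref <- sq$reference
  msk <- sq$masks$structure
  expect_equal(img_sharpness(ref, msk, ref), 1)
  expect_equal(img_sharpness(3 * ref + 2, msk, ref), 1)
  # blurred image: compare against the longhand correlation formula
  blur <- (ref + mrseqopt:::.circshift_rows(ref, 1) +
             mrseqopt:::.circshift_rows(ref, -1)) / 3
  expect_equal(img_sharpness(blur, msk, ref), pcc_oracle(blur, ref, msk))
  expect_lt(img_sharpness(blur, msk, ref), 1)
  expect_error(img_sharpness(ref, msk, matrix(1, 100, 100)), "constant")
})

test_that("homogeneity drops below 1 when ripple is added in the filled area", {
  sq <- make_square_phantom()
  ref <- sq$reference
  win <- sq$masks$homogeneity
  expect_equal(img_homogeneity(ref, win, ref), 1)
  ripple <- ref
  ripple[win] <- ripple[win] * (1 + 0.2 * sin(seq_len(sum(win))))
  expect_lt(img_homogeneity(ripple, win, ref), 1)
  expect_equal(img_homogeneity(ripple, win, ref), pcc_oracle(ripple, ref, win))
})

test_that("motion sensitivity is zero for pure PE shifts and positive for blur", {
  ci <- make_circular_phantom()
  ref <- ci$reference
  msk <- ci$masks$evaluation
  expect_equal(motion_sensitivity(ref, ref, msk), 0)
  for (d in c(3, 17, 60))
    expect_equal(motion_sensitivity(mrseqopt:::.circshift_rows(ref, d), ref, msk),
                 0, tolerance = 1e-12, label = paste("shift", d))
  blur <- (ref + mrseqopt:::.circshift_rows(ref, 2) +
             mrseqopt:::.circshift_rows(ref, -2)) / 3
  got <- motion_sensitivity(blur, ref, msk)
  expect_gt(got, 0)
  expect_equal(got, 1 - max(shift_scan_oracle(blur, ref, msk)))
})

test_that("distortion sensitivity equals d / n_pe exactly for synthetic shifts", {
  ci <- make_circular_phantom()
  ref <- ci$reference
  msk <- ci$masks$evaluation
  expect_equal(distortion_sensitivity(ref, ref, msk), 0)
  expect_equal(distortion_sensitivity(mrseqopt:::.circshift_rows(ref, 5), ref, msk),
               5 / 100)
  # circular distance: a 95-pixel shift is a 5-pixel shift the other way
  expect_equal(distortion_sensitivity(mrseqopt:::.circshift_rows(ref, 95), ref, msk),
               5 / 100)
})

test_that("PCC metrics and contrasts are invariant to positive image scaling", {
  sq <- make_square_phantom()
  ref <- sq$reference
  blur <- (ref + mrseqopt:::.circshift_rows(ref, 1)) / 2
  for (c_ in c(0.5, 7)) {
    expect_equal(img_sharpness(c_ * blur, sq$masks$structure, ref),
                 img_sharpness(blur, sq$masks$structure, ref))
    expect_equal(img_contrast(c_ * blur, sq$masks$csf, sq$masks$gm),
                 img_contrast(blur, sq$masks$csf, sq$masks$gm))
    expect_equal(ghost_level(c_ * (blur + 0.1 * mrseqopt:::.circshift_rows(blur, 50)),
                             sq$masks$object, sq$masks$ghost),
                 ghost_level(blur + 0.1 * mrseqopt:::.circshift_rows(blur, 50),
                             sq$masks$object, sq$masks$ghost))
  }
})

test_that("compute_metrics assembles the full 12-vector and is deterministic", {
  ph <- fixture_phantoms()
  spec <- expand_defaults(parse_sequence(
    'define MRI sequence "B" using a "GradientEcho" with "LineReadout".'))
  m1 <- simulate_and_score(spec, ph, seed = 99)
  m2 <- simulate_and_score(spec, ph, seed = 99)
  expect_identical(m1, m2)
  expect_named(m1, metric_names())
  expect_true(all(is.finite(m1)))
  expect_equal(m1[["acq_time"]], acquisition_time(spec))
  # missing simulation is reported
  expect_error(compute_metrics(spec, ph$square, ph$circ_plain,
                               list(square = NULL)), "missing simulation")
})
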