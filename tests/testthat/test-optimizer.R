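# Penalty fitness, repair, and the evolutionary core.

.toy_problem <- function() {
  translate_requirement(read_requirement(extdata("req_gwc.mrreq")))
}

test_that("fitness equals the goal prediction when no constraint is violated", {
  pred <- c(cgc = 1, gwc = 1.4, cwc = 1, snr_csf = 40, snr_gm = 35,
            snr_wm = 33, ghost = 0.01, sharpness = 0.9, homogeneity = 0.9,
            motion_sens = 0.01, distortion_sens = 0.01, acq_time = 5000)
  problem <- .toy_problem()
  expect_equal(penalty_fitness(pred, problem), 1.4)
  # goal-only problem: fitness is the goal exactly, empty sums contribute 0
  goal_only <- translate_requirement(parse_requirement(
    'define optimization requirement : maximize "GWC".'))
  expect_equal(penalty_fitness(pred, goal_only), 1.4)
})

test_that("each violated strict constraint subtracts the constant penalty", {
  problem <- .toy_problem()
  cfg <- fitness_config(strict_penalty = 1000)
  pred <- c(cgc = 1, gwc = 1.4, cwc = 1, snr_csf = 40, snr_gm = 25,
            snr_wm = 33, ghost = 0.01, sharpness = 0.9, homogeneity = 0.9,
            motion_sens = 0.01, distortion_sens = 0.01, acq_time = 5000)
  # snr_gm > 30 violated AND snr_gm > snr_wm violated: two penalties
  expect_equal(penalty_fitness(pred, problem, cfg), 1.4 - 2000)
  pred["snr_gm"] <- 34
  expect_equal(penalty_fitness(pred, problem, cfg), 1.4)
})

test_that("artifact avoid-constraints use the exponential penalty in the violation", {
  problem <- .toy_problem()
  cfg <- fitness_config(artifact_factor = 50)
  base <- c(cgc = 1, gwc = 1.4, cwc = 1, snr_csf = 40, snr_gm = 35,
            snr_wm = 33, ghost = 0.05, sharpness = 0.9, homogeneity = 0.9,
            motion_sens = 0.01, distortion_sens = 0.01, acq_time = 5000)
  # at the bound: exp(0) = 1 subtracted
  expect_equal(penalty_fitness(base, problem, cfg), 1.4 - 1)
  base["ghost"] <- 0.06                       # violation 0.01 -> exp(0.5)
  expect_equal(penalty_fitness(base, problem, cfg), 1.4 - exp(0.5))
  base["ghost"] <- 0.08
  f3 <- penalty_fitness(base, problem, cfg)
  expect_lt(f3, 1.4 - exp(0.5))               # strictly increasing penalty
})

test_that("vague non-artifact violations cost a fraction of the goal magnitude", {
  problem <- translate_requirement(read_requirement(extdata("req_snr_csf.mrreq")))
  cfg <- fitness_config(vague_fraction = 0.1)
  pred <- c(cgc = 12, gwc = 1, cwc = 12, snr_csf = 40, snr_gm = 30,
            snr_wm = 30, ghost = 0.01, sharpness = 0.9, homogeneity = 0.9,
            motion_sens = 0.01, distortion_sens = 0.01, acq_time = 5000)
  expect_equal(penalty_fitness(pred, problem, cfg), 40)
  pred["cgc"] <- 5                            # CGC > 10 violated
  expect_equal(penalty_fitness(pred, problem, cfg), 40 - 0.1 * 40)
})

test_that("minimization goals are negated into the maximization form", {
  goal <- translate_requirement(parse_requirement(
    'define optimization requirement : minimize "ghosting".'))
  pred <- c(cgc = 1, gwc = 1, cwc = 1, snr_csf = 1, snr_gm = 1, snr_wm = 1,
            ghost = 0.2, sharpness = 1, homogeneity = 1, motion_sens = 0,
            distortion_sens = 0, acq_time = 100)
  expect_equal(penalty_fitness(pred, goal), -0.2)
})

test_that("repair recovers categoricals by rounding and clamps infeasible timings", {
  grid <- build_grid(sequence_grid_config())
  # the worked infeasible short-TR line-readout candidate: TE/TR 130/4300
  v <- sequence_vector(expand_defaults(parse_sequence(
    'define MRI sequence "B" using a "GradientEcho" with "LineReadout".')))
  v["te"] <- 130; v["tr"] <- 4300; v["measurements"] <- 2
  r <- repair_candidate(v, grid)
  expect_equal(r$te, 17)
  expect_equal(r$tr, 36)
  expect_true(validate_sequence(r)$valid)

  # categorical rounding: refocussing angle 2.7/3 of the way -> spin echo
  v2 <- v; v2["refocussing_angle"] <- 162; v2["epi_factor"] <- 54
  r2 <- repair_candidate(v2, grid)
  expect_equal(r2$echo_type, "SpinEcho")
  expect_equal(r2$readout_type, "EPIReadout")
  expect_equal(r2$epi_factor, 64)

  # an already-valid grid point is unchanged, and repair is idempotent
  for (sp in grid[seq(1, length(grid), by = 13)]) {
    v3 <- sequence_vector(sp)
    expect_equal(sequence_vector(repair_candidate(v3, grid)), v3)
  }
})

test_that("the EA recovers the known optimum of an analytic fitness (3/3 seeds)", {
  f <- function(x) -sum((x - 0.5)^2)
  for (sd in 1:3) {
    r <- evolve_real(f, 12, ea_config(seed = sd))
    expect_lt(max(abs(r$best - 0.5)), 0.05, label = paste("seed", sd))
    expect_false(is.unsorted(r$trace), label = paste("seed", sd))
  }
})

test_that("the EA is deterministic under a fixed seed", {
  f <- function(x) -sum((x - 0.3)^2)
  r1 <- evolve_real(f, 5, ea_config(seed = 4, generations = 30))
  r2 <- evolve_real(f, 5, ea_config(seed = 4, generations = 30))
  expect_identical(r1, r2)
  expect_error(ea_config(pop_size = 1), "pop_size")
})
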