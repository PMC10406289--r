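# Evolutionary search over sequence space with a penalty fitness and a
# nearest-valid-grid repair step.  Candidates carry a real-valued genome in
# [0,1]^10 affinely mapped to the parameter ranges of the training grid;
# categorical structure (echo / readout type) is recovered by rounding during
# repair.

#' Fitness configuration
#'
#' Penalty constants of the constrained fitness: a constant `strict_penalty`
#' per violated strict constraint; a `vague_fraction` of the absolute goal
#' prediction per violated vague constraint; and the exponential artifact
#' penalty `exp(artifact_factor * (prediction - bound))` for violated avoid
#' constraints on ghosting / motion / distortion.  Acquisition-time goals are
#' range-normalized before use so the constant penalties dominate for every
#' goal metric.
#'
#' @param strict_penalty Constant per violated strict constraint.
#' @param vague_fraction Fraction of `|goal|` per violated vague constraint.
#' @param artifact_factor Exponent factor `a` of the artifact penalty.
#' @return List of class `fitness_config`.
#' @export
fitness_config <- function(strict_penalty = 1000, vague_fraction = 0.1,
                           artifact_factor = 50) {
  stopifnot(strict_penalty > 0, vague_fraction > 0, vague_fraction < 1,
            artifact_factor > 0)
  structure(list(strict_penalty = strict_penalty,
                 vague_fraction = vague_fraction,
                 artifact_factor = artifact_factor), class = "fitness_config")
}

#' Evolutionary-algorithm configuration
#'
#' Population 50 and 100 generations by default; line crossover with
#' probability 0.1 (interpolation on the segment between two parents with a
#' small extension), Gaussian mutation with probability 0.9 and step size 0.1
#' of the gene range (annealed geometrically to 5% of the initial step across
#' the generations), elitism plus tournament selection.
#'
#' @param pop_size Population size (>= 2).
#' @param generations Number of generations.
#' @param p_crossover Line-crossover probability.
#' @param p_mutation Per-individual mutation probability.
#' @param step Gaussian mutation step (fraction of gene range).
#' @param elite Number of elites preserved unchanged.
#' @param tournament Tournament size.
#' @param extension Line-crossover extension beyond the segment.
#' @param anneal Final mutation step as a fraction of the initial step.
#' @param seed RNG seed.
#' @return List of class `ea_config`.
#' @export
ea_config <- function(pop_size = 50L, generations = 100L, p_crossover = 0.1,
                      p_mutation = 0.9, step = 0.1, elite = 2L,
                      tournament = 3L, extension = 0.1, anneal = 0.05,
                      seed = 1L) {
  stopifnot(pop_size >= 2, generations >= 1,
            p_crossover >= 0, p_crossover <= 1,
            p_mutation >= 0, p_mutation <= 1)
  structure(list(pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 step = step, elite = as.integer(elite),
                 tournament = as.integer(tournament), extension = extension,
                 anneal = anneal, seed = as.integer(seed)),
            class = "ea_config")
}

#' Repair a decoded candidate onto the valid sequence grid
#'
#' Three steps: (i) categorical recovery — the refocussing angle is rounded to
#' 0 or 180 (gradient vs spin echo) and the EPI factor to the nearest
#' admissible value (1 recovers a line readout), which selects the sequence
#' family; (ii, iii) the whole parameter vector is snapped to the nearest
#' point (per-coordinate range-normalized distance) of that family's
#' validity-filtered grid, which clamps out-of-range timings to the family
#' extremes (an infeasible bSSFP-family TE/TR of 130/4300 ms repairs to the
#' largest grid pair, 17/36 ms).  The result always passes
#' [validate_sequence()] and the operation is idempotent.
#'
#' @param v Named numeric vector (as [sequence_vector()]), possibly
#'   off-grid/invalid.
#' @param grid Precomputed valid grid from [build_grid()] (list of specs), or
#'   a grid configuration list from [sequence_grid_config()].
#' @return A valid [sequence_spec()].
#' @export
repair_candidate <- function(v, grid = sequence_grid_config()) {
  specs <- if (is.list(grid) && length(grid) && inherits(grid[[1]], "sequence_spec"))
    grid else build_grid(grid)
  fams <- vapply(specs, function(s) attr(s, "family"), character(1))
  V <- t(vapply(specs, sequence_vector, numeric(10)))

  # (i) categorical recovery
  echo <- if (abs(v[["refocussing_angle"]] - 180) < abs(v[["refocussing_angle"]]))
    "SpinEcho" else "GradientEcho"
  epi_values <- sort(unique(V[, "epi_factor"]))
  epi <- epi_values[which.min(abs(epi_values - v[["epi_factor"]]))]
  ro <- if (epi > 1) "EPIReadout" else "LineReadout"
  fam <- .family_of(echo, ro)
  sel <- fams == fam
  if (!any(sel)) stop("no valid grid points for family ", fam, call. = FALSE)
  Vf <- V[sel, , drop = FALSE]

  # (ii)+(iii) nearest valid grid point, range-normalized per coordinate
  rng <- apply(Vf, 2, function(col) diff(range(col)))
  rng[rng == 0] <- 1
  z <- sweep(sweep(Vf, 2, v[colnames(Vf)]), 2, rng, "/")
  best <- which.min(rowSums(z^2))
  sp <- specs[sel][[best]]
  sp$name <- "repaired"
  attr(sp, "family") <- fam
  sp
}

#' Penalty fitness of a candidate under an optimization problem
#'
#' `p_goal - sum(strict penalties) - sum(vague penalties)`: the predicted goal
#' metric (negated for minimization goals; acquisition time additionally
#' range-normalized), minus a constant per violated strict constraint, minus a
#' fraction of `|p_goal|` per violated vague constraint — except that violated
#' avoid constraints on the artifact metrics contribute the exponential
#' penalty `exp(a * (prediction - bound))`.  Satisfied constraints contribute
#' nothing.
#'
#' @param pred Named prediction vector over [metric_names()].
#' @param problem An [translate_requirement()] optimization problem.
#' @param cfg A [fitness_config()].
#' @param params Optional named sequence-parameter vector (for strict
#'   constraints on sequence parameters).
#' @param time_range Optional `c(min, max)` acquisition-time range for goal
#'   normalization.
#' @return Scalar fitness (larger is better).
#' @export
penalty_fitness <- function(pred, problem, cfg = fitness_config(),
                            params = NULL, time_range = NULL) {
  goal <- pred[[problem$goal$metric]]
  if (problem$goal$metric == "acq_time" && !is.null(time_range) &&
      diff(time_range) > 0)
    goal <- (goal - time_range[1]) / diff(time_range)
  if (problem$goal$direction == "minimize") goal <- -goal
  fit <- goal

  value_of <- function(name, kind) {
    if (kind == "number") return(name)
    if (kind == "metric") return(pred[[name]])
    if (is.null(params) || !name %in% names(params))
      stop("strict constraint references unknown parameter '", name, "'",
           call. = FALSE)
    params[[name]]
  }
  for (s in problem$strict) {
    lhs <- value_of(s$lhs, s$lhs_kind)
    rhs <- value_of(s$rhs, s$rhs_kind)
    viol <- switch(s$relation,
                   lt = !(lhs < rhs), gt = !(lhs > rhs),
                   eq = abs(lhs - rhs) > 1e-9 * max(1, abs(rhs)))
    if (viol) fit <- fit - cfg$strict_penalty
  }
  for (vg in problem$vague) {
    p <- pred[[vg$metric]]
    viol <- if (vg$relation == "lt") !(p < vg$bound) else !(p > vg$bound)
    if (!viol) next
    fit <- fit - if (vg$artifact)
      exp(cfg$artifact_factor * (p - vg$bound)) else
        cfg$vague_fraction * abs(goal)
  }
  unname(fit)
}

#' Core real-valued evolutionary algorithm
#'
#' Maximizes `fn` over `[0,1]^d` with line crossover, annealed Gaussian
#' mutation, elitism and tournament selection.  `fn` may be vectorized over a
#' matrix of genomes (one row per candidate) via `vectorized = TRUE`.
#'
#' @param fn Fitness function: genome vector -> scalar (or genome matrix ->
#'   vector if `vectorized`).
#' @param d Genome dimension.
#' @param cfg An [ea_config()].
#' @param vectorized Whether `fn` accepts a matrix of genomes.
#' @return List `(best, best_fitness, trace)` where `trace` is the
#'   best-so-far fitness per generation (non-decreasing).
#' @export
evolve_real <- function(fn, d, cfg = ea_config(), vectorized = FALSE) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)
  evalpop <- function(P) {
    if (vectorized) as.numeric(fn(P))
    else apply(P, 1, fn)
  }
  P <- matrix(stats::runif(cfg$pop_size * d), cfg$pop_size, d)
  f <- evalpop(P)
  best_i <- which.max(f)
  best <- P[best_i, ]; best_f <- f[best_i]
  trace <- numeric(cfg$generations)
  decay <- cfg$anneal^(1 / max(cfg$generations - 1, 1))
  sigma <- cfg$step
  for (g in seq_len(cfg$generations)) {
    ord <- order(f, decreasing = TRUE)
    elite_idx <- ord[seq_len(min(cfg$elite, cfg$pop_size))]
    n_child <- cfg$pop_size - length(elite_idx)
    tourn <- function() {
      cand <- sample.int(cfg$pop_size, cfg$tournament, replace = TRUE)
      cand[which.max(f[cand])]
    }
    children <- matrix(0, n_child, d)
    for (c_ in seq_len(n_child)) {
      a <- P[tourn(), ]
      if (stats::runif(1) < cfg$p_crossover) {
        b <- P[tourn(), ]
        u <- stats::runif(1, -cfg$extension, 1 + cfg$extension)
        a <- a + u * (b - a)
      }
      if (stats::runif(1) < cfg$p_mutation)
        a <- a + stats::rnorm(d, 0, sigma)
      children[c_, ] <- pmin(pmax(a, 0), 1)
    }
    P <- rbind(P[elite_idx, , drop = FALSE], children)
    f <- c(f[elite_idx], evalpop(children))
    gi <- which.max(f)
    if (f[gi] > best_f) { best_f <- f[gi]; best <- P[gi, ] }
    trace[g] <- best_f
    sigma <- sigma * decay
  }
  list(best = best, best_fitness = best_f, trace = trace)
}

# genome in [0,1]^10 -> raw parameter vector spanning the grid ranges
.genome_decode <- function(G, lo, hi) {
  raw <- sweep(sweep(G, 2, hi - lo, "*"), 2, lo, "+")
  colnames(raw) <- names(lo)
  raw
}

#' Optimize a sequence for a requirement
#'
#' End-to-end evolutionary optimization: genomes in `[0,1]^10` are decoded to
#' parameter vectors spanning the training-grid ranges, repaired onto the
#' valid grid ([repair_candidate()]), scored by the surrogate predictions
#' under the penalty fitness, and evolved.  Returns the best repaired
#' sequence, its predicted metrics and the best-fitness trace.
#'
#' @param problem An [translate_requirement()] optimization problem.
#' @param models Trained [select_and_validate()] surrogates.
#' @param grid_cfg Grid configuration for decode ranges and repair.
#' @param ea A [ea_config()].
#' @param fit_cfg A [fitness_config()].
#' @return List `(best_spec, best_vector, predicted, fitness, trace)`.
#' @export
optimize_sequence <- function(problem, models, grid_cfg = sequence_grid_config(),
                              ea = ea_config(), fit_cfg = fitness_config()) {
  grid <- build_grid(grid_cfg)
  V <- t(vapply(grid, sequence_vector, numeric(10)))
  lo <- apply(V, 2, min); hi <- apply(V, 2, max)
  time_range <- if (!is.null(models$metric_ranges) &&
                    "acq_time" %in% colnames(models$metric_ranges))
    models$metric_ranges[, "acq_time"] else NULL

  fn <- function(G) {
    reps <- lapply(seq_len(nrow(G)), function(i)
      repair_candidate(.genome_decode(G[i, , drop = FALSE], lo, hi)[1, ], grid))
    Xr <- t(vapply(reps, sequence_vector, numeric(10)))
    pred <- predict_metrics(models, Xr)
    if (!is.matrix(pred)) pred <- matrix(pred, nrow = 1,
                                         dimnames = list(NULL, names(pred)))
    vapply(seq_len(nrow(G)), function(i)
      penalty_fitness(as.list(pred[i, ]), problem, fit_cfg,
                      params = Xr[i, ], time_range = time_range),
      numeric(1))
  }
  res <- evolve_real(fn, ncol(V), ea, vectorized = TRUE)
  best_spec <- repair_candidate(
    .genome_decode(matrix(res$best, 1), lo, hi)[1, ], grid)
  bv <- sequence_vector(best_spec)
  pred <- predict_metrics(models, bv)
  list(best_spec = best_spec, best_vector = bv, predicted = pred,
       fitness = res$best_fitness, trace = res$trace)
}

#' Check the strict constraints of a problem against predictions
#'
#' @param problem Optimization problem.
#' @param pred Named metric predictions.
#' @param params Optional named parameter vector.
#' @return Logical vector, one entry per strict constraint (TRUE =
#'   satisfied).
#' @export
strict_satisfied <- function(problem, pred, params = NULL) {
  vapply(problem$strict, function(s) {
    val <- function(name, kind) {
      if (kind == "number") name
      else if (kind == "metric") pred[[name]]
      else params[[name]]
    }
    lhs <- val(s$lhs, s$lhs_kind); rhs <- val(s$rhs, s$rhs_kind)
    switch(s$relation, lt = lhs < rhs, gt = lhs > rhs,
           eq = abs(lhs - rhs) <= 1e-9 * max(1, abs(rhs)))
  }, logical(1))
}
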