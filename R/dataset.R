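# Training-grid generation and campaign orchestration: the four-family
# parameter grid, the four simulations per sequence, the assembled
# (12-input, 12-output) table and the three-way holdout split.

#' Sequence parameter grid configuration
#'
#' Per-family value lists of the training grid: matrix size, TE/TR (ms), echo
#' train length, EPI factor, readout duration (ms), excitation / refocussing
#' angles (deg), measurements, prescans.  `reduced = TRUE` returns a
#' desk-scale grid (16 x 16 matrices, 1 measurement) that completes a full
#' campaign in well under a minute and is used by the examples and the
#' end-to-end checks.
#'
#' @param reduced Use the reduced desk-scale grid.
#' @return Named list of per-family parameter value lists.
#' @export
sequence_grid_config <- function(reduced = FALSE) {
  if (!reduced) {
    list(
      EPI = list(matrix = c(32, 64), te = c(10, 60, 110),
                 tr = c(100, 1500, 6000), etl = 1, epi_factor = c(16, 32, 64),
                 readout_ms = c(0.4, 0.5), excitation = 90, refocussing = 0,
                 measurements = c(1, 10), prescans = 0),
      `SE-EPI` = list(matrix = c(32, 64), te = c(10, 60, 110),
                      tr = c(100, 1500, 6000), etl = 1,
                      epi_factor = c(16, 32, 64), readout_ms = c(0.4, 0.5),
                      excitation = 90, refocussing = 180,
                      measurements = c(1, 10), prescans = 0),
      bSSFP = list(matrix = c(32, 64), te = c(2, 5, 8, 11, 14, 17),
                   tr = c(4, 12, 20, 28, 36), etl = 1, epi_factor = 1,
                   readout_ms = 2, excitation = 90, refocussing = 0,
                   measurements = c(1, 2), prescans = 8),
      RARE = list(matrix = c(32, 64), te = c(10, 60, 110, 160),
                  tr = c(100, 1500, 6000), etl = c(16, 32, 64), epi_factor = 1,
                  readout_ms = c(1, 1.1), excitation = 90, refocussing = 180,
                  measurements = c(1, 10), prescans = 0)
    )
  } else {
    list(
      EPI = list(matrix = 16, te = c(10, 35, 60, 110), tr = c(100, 1500),
                 etl = 1, epi_factor = c(8, 16), readout_ms = c(0.4, 0.5),
                 excitation = 90, refocussing = 0, measurements = c(1, 3),
                 prescans = 0),
      `SE-EPI` = list(matrix = 16, te = c(10, 35, 60, 110), tr = c(100, 1500),
                      etl = 1, epi_factor = c(8, 16), readout_ms = c(0.4, 0.5),
                      excitation = 90, refocussing = 180,
                      measurements = c(1, 3), prescans = 0),
      bSSFP = list(matrix = 16, te = c(2, 5, 8, 11, 14, 17),
                   tr = c(4, 20, 36), etl = 1, epi_factor = 1, readout_ms = 2,
                   excitation = 90, refocussing = 0, measurements = c(1, 2),
                   prescans = 8),
      RARE = list(matrix = 16, te = c(10, 30, 60, 110), tr = c(100, 1500),
                  etl = c(4, 8), epi_factor = 1, readout_ms = c(1, 1.1),
                  excitation = 90, refocussing = 180, measurements = c(1, 3),
                  prescans = 0)
    )
  }
}

# one grid row (family + numeric parameters) -> sequence_spec
.spec_from_params <- function(family, p) {
  echo <- if (family %in% c("SE-EPI", "RARE")) "SpinEcho" else "GradientEcho"
  ro <- if (family %in% c("EPI", "SE-EPI")) "EPIReadout" else "LineReadout"
  d <- .family_defaults(family)
  sequence_spec(
    name = paste0(family, "-grid"),
    echo_type = echo, readout_type = ro,
    excitation = list(pulse_type = "sincpulse", angle = p[["excitation"]]),
    refocussing = if (echo == "SpinEcho")
      list(pulse_type = "sincpulse", angle = p[["refocussing"]]) else NULL,
    readout_duration = p[["readout_ms"]] * 1000,
    n_columns = p[["matrix"]], n_rows = p[["matrix"]],
    te = p[["te"]], tr = p[["tr"]],
    epi_factor = p[["epi_factor"]], etl = p[["etl"]],
    measurements = p[["measurements"]],
    prescans = if (p[["prescans"]] > 0)
      list(count = p[["prescans"]], type = "linear") else NULL,
    spoiling = d$spoiling
  )
}

#' Build the validity-filtered sequence grid
#'
#' Cartesian product of the per-family parameter values of
#' [sequence_grid_config()], filtered through [validate_sequence()]; every
#' returned spec is valid.  A pure function of its configuration.
#'
#' @param cfg Grid configuration (default full grid).
#' @return List of [sequence_spec()] objects with a `family` attribute each.
#' @export
build_grid <- function(cfg = sequence_grid_config()) {
  specs <- list()
  for (fam in names(cfg)) {
    g <- cfg[[fam]]
    grid <- expand.grid(matrix = g$matrix, te = g$te, tr = g$tr, etl = g$etl,
                        epi_factor = g$epi_factor, readout_ms = g$readout_ms,
                        excitation = g$excitation, refocussing = g$refocussing,
                        measurements = g$measurements, prescans = g$prescans,
                        KEEP.OUT.ATTRS = FALSE)
    for (i in seq_len(nrow(grid))) {
      sp <- .spec_from_params(fam, unlist(grid[i, ]))
      if (validate_sequence(sp)$valid) {
        attr(sp, "family") <- fam
        specs[[length(specs) + 1L]] <- sp
      }
    }
  }
  if (length(specs) == 0) stop("empty grid after validity filtering", call. = FALSE)
  specs
}

#' Numeric input vector of a sequence
#'
#' The ten numeric inputs of the learning problem (matrix, TE, TR, ETL, EPI
#' factor, readout duration in ms, excitation and refocussing angle,
#' measurements, prescans).  The two categorical inputs (echo and readout
#' type) are recoverable from the numeric view: refocussing angle 0 encodes
#' gradient echo and EPI factor 1 encodes a line readout.
#'
#' @param spec A complete [sequence_spec()].
#' @return Named numeric vector of length 10.
#' @export
sequence_vector <- function(spec) {
  c(matrix = spec$n_rows, te = spec$te, tr = spec$tr, etl = spec$etl,
    epi_factor = spec$epi_factor, readout_ms = spec$readout_duration / 1000,
    excitation_angle = spec$excitation$angle,
    refocussing_angle = .refoc_angle(spec),
    measurements = spec$measurements,
    prescans = if (is.null(spec$prescans)) 0 else spec$prescans$count)
}

#' Decode a numeric input vector back into a sequence
#'
#' Inverse of [sequence_vector()] (the categorical fields are recovered from
#' the refocussing angle and EPI factor).  `sequence_vector(vector_to_spec(v))
#' == v` for any vector produced from a valid spec.
#'
#' @param v Named numeric vector as returned by [sequence_vector()].
#' @param name Sequence name for the decoded spec.
#' @return A [sequence_spec()].
#' @export
vector_to_spec <- function(v, name = "decoded") {
  echo <- if (v[["refocussing_angle"]] == 0) "GradientEcho" else "SpinEcho"
  ro <- if (v[["epi_factor"]] > 1) "EPIReadout" else "LineReadout"
  fam <- .family_of(echo, ro)
  d <- .family_defaults(fam)
  sequence_spec(
    name = name, echo_type = echo, readout_type = ro,
    excitation = list(pulse_type = "sincpulse", angle = v[["excitation_angle"]]),
    refocussing = if (echo == "SpinEcho")
      list(pulse_type = "sincpulse", angle = v[["refocussing_angle"]]) else NULL,
    readout_duration = v[["readout_ms"]] * 1000,
    n_columns = v[["matrix"]], n_rows = v[["matrix"]],
    te = v[["te"]], tr = v[["tr"]],
    epi_factor = v[["epi_factor"]], etl = v[["etl"]],
    measurements = v[["measurements"]],
    prescans = if (v[["prescans"]] > 0)
      list(count = v[["prescans"]], type = "linear") else NULL,
    spoiling = d$spoiling
  )
}

#' Run the four simulations for one sequence and score it
#'
#' Square phantom (noiseless + noisy reconstruction for SNR), plain circular
#' phantom, circular with off-resonance, circular with motion; then all
#' twelve metrics.
#'
#' @param spec Valid [sequence_spec()].
#' @param phantoms List with `square`, `circ_plain`, `circ_offres`,
#'   `circ_motion` phantoms (see [campaign_phantoms()]).
#' @param noise_frac Relative noise level for the SNR simulation.
#' @param seed Noise seed.
#' @return Named metric vector (see [metric_names()]).
#' @export
simulate_and_score <- function(spec, phantoms, noise_frac = 0.02, seed = 1234L) {
  plan <- compile_sequence(spec)
  k_sq <- simulate_kspace(plan, phantoms$square, off_resonance = FALSE,
                          motion = FALSE)
  sigma <- noise_sigma_for(k_sq, noise_frac)
  images <- list(
    square = reconstruct_image(k_sq),
    square_noisy = reconstruct_image(add_noise(k_sq, sigma, seed)),
    circ_plain = reconstruct_image(
      simulate_kspace(plan, phantoms$circ_plain, off_resonance = FALSE,
                      motion = FALSE)),
    circ_offres = reconstruct_image(
      simulate_kspace(plan, phantoms$circ_offres, off_resonance = TRUE,
                      motion = FALSE)),
    circ_motion = reconstruct_image(
      simulate_kspace(plan, phantoms$circ_motion, off_resonance = FALSE,
                      motion = TRUE))
  )
  compute_metrics(spec, phantoms$square, phantoms$circ_plain, images)
}

#' Standard campaign phantoms
#'
#' The square phantom and the three circular-phantom variants (plain, uniform
#' off-resonance, repeating linear motion).  The motion period defaults to the
#' duration of one measurement of the sequence at hand, so it is passed per
#' call in [run_campaign()]; here a 1 s period placeholder is used when no
#' period is supplied.
#'
#' @param fov FOV in mm (length 2).
#' @param off_resonance_hz Uniform off-resonance of the distortion phantom.
#' @param motion_amplitude_mm Sawtooth amplitude of the motion phantom.
#' @param motion_period_s Sawtooth period in seconds.
#' @param square_cfg Extra configuration for [make_square_phantom()] (e.g.
#'   `stripe_mm` for coarser structure stripes at low matrix sizes).
#' @return List of four `digital_phantom`s.
#' @export
campaign_phantoms <- function(fov = c(100, 100), off_resonance_hz = 50,
                              motion_amplitude_mm = 5, motion_period_s = 1,
                              square_cfg = list()) {
  list(
    square = make_square_phantom(c(list(fov = fov), square_cfg)),
    circ_plain = make_circular_phantom(list(fov = fov)),
    circ_offres = make_circular_phantom(list(
      fov = fov, off_resonance_on = TRUE, off_resonance = off_resonance_hz)),
    circ_motion = make_circular_phantom(list(
      fov = fov, motion_on = TRUE,
      motion = list(amplitude = motion_amplitude_mm, period = motion_period_s)))
  )
}

#' Run a simulation campaign over a sequence grid
#'
#' Executes the four simulations for every sequence and assembles the training
#' table: ten numeric inputs, the family tag, and the twelve metrics.  The
#' motion-phantom period is set to the duration of one measurement of each
#' sequence.  Failures are recorded (with a warning) and the row excluded.
#'
#' @param specs List of valid specs from [build_grid()].
#' @param fov Imaging/phantom FOV in mm.
#' @param noise_frac Relative noise level for SNR.
#' @param seed Campaign seed (controls per-row noise seeds).
#' @param verbose Print per-row progress.
#' @param square_cfg Extra square-phantom configuration (see
#'   [campaign_phantoms()]).
#' @return `data.frame` of class `training_table`: input columns, `family`,
#'   metric columns.
#' @export
run_campaign <- function(specs, fov = c(100, 100), noise_frac = 0.02,
                         seed = 1L, verbose = FALSE, square_cfg = list()) {
  base <- campaign_phantoms(fov = fov, square_cfg = square_cfg)
  rows <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    ph <- base
    # motion period = one measurement of this sequence
    meas_ms <- sp$tr * .shots_per_meas(sp)
    ph$circ_motion$motion$period <- meas_ms / 1000
    met <- tryCatch(
      simulate_and_score(sp, ph, noise_frac = noise_frac,
                         seed = derive_seed(seed + i, "noise")),
      error = function(e) {
        warning("sequence ", i, " (", attr(sp, "family") %||% "?",
                ") failed: ", conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(met)) next
    rows[[i]] <- data.frame(
      t(sequence_vector(sp)),
      family = attr(sp, "family") %||% .family_of(sp$echo_type, sp$readout_type),
      t(met), check.names = FALSE)
    if (verbose) message(sprintf("[%d/%d] %s done", i, length(specs),
                                 attr(sp, "family") %||% sp$name))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  class(out) <- c("training_table", "data.frame")
  out
}

#' Reduced desk-scale campaign
#'
#' The reduced grid ([sequence_grid_config()] with `reduced = TRUE`) simulated
#' on 50 x 50 mm phantoms with 16 mm-scale structure stripes (so the sharpness
#' target stays resolvable at a 16 x 16 matrix).  Completes in seconds on one
#' CPU; used by the examples and the end-to-end checks.
#'
#' @param seed Campaign seed.
#' @param verbose Print progress.
#' @return A `training_table`.
#' @export
run_reduced_campaign <- function(seed = 1L, verbose = FALSE) {
  specs <- build_grid(sequence_grid_config(reduced = TRUE))
  run_campaign(specs, fov = c(50, 50), seed = seed, verbose = verbose,
               square_cfg = list(stripe_mm = 16))
}

#' Three-way holdout split
#'
#' Uniform random partition of the table rows into train / test / validation
#' sets of 60% / 20% / 20% (within one row of exact proportions), disjoint and
#' exhaustive; deterministic under the seed.
#'
#' @param table A `training_table` (>= 5 rows).
#' @param seed Split seed.
#' @return The table with an added `split` factor column.
#' @export
split_table <- function(table, seed = 1L) {
  n <- nrow(table)
  if (n < 5) stop("need at least 5 rows to split", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(derive_seed(seed, "split"))
  n_train <- round(0.6 * n)
  n_test <- round(0.2 * n)
  lab <- rep("validation", n)
  ord <- sample.int(n)
  lab[ord[seq_len(n_train)]] <- "train"
  lab[ord[n_train + seq_len(n_test)]] <- "test"
  table$split <- factor(lab, levels = c("train", "test", "validation"))
  table
}

#' Write / read a training table as CSV
#'
#' Fixed column order: the ten input names, `family`, the twelve metric names,
#' and `split` when present.
#'
#' @param table A `training_table`.
#' @param path CSV path.
#' @export
write_training_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_training_table
#' @export
read_training_table <- function(path) {
  out <- utils::read.csv(path, check.names = FALSE)
  if ("split" %in% names(out))
    out$split <- factor(out$split, levels = c("train", "test", "validation"))
  class(out) <- c("training_table", "data.frame")
  out
}

.input_names <- function() {
  c("matrix", "te", "tr", "etl", "epi_factor", "readout_ms",
    "excitation_angle", "refocussing_angle", "measurements", "prescans")
}
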