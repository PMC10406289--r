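# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# minimal single-tissue phantom with spins at given positions (no geometry)
point_phantom <- function(xs = 0, ys = 0, t1 = 1000, t2 = 100, pd = 1,
                          delta_f = 0, fov = c(4, 4), label = "T") {
  structure(list(
    fov = fov, spin_density = length(xs) * length(ys) / prod(fov),
    spin_x = xs, spin_y = ys,
    motion = list(pattern = "none", amplitude = 0, period = 1, direction = "pe"),
    label_grid = matrix(label, length(ys), length(xs)),
    tissues = stats::setNames(list(list(t1 = t1, t2 = t2, pd = pd,
                                        delta_f = delta_f)), label),
    masks = list(), reference = matrix(pd, fov[1], fov[2])
  ), class = "digital_phantom")
}

# single-line spec: one excitation, one readout line through k = 0
single_line_spec <- function(echo = "GradientEcho", te = 30, tr = 200,
                             readout_us = 1000, n_columns = 2,
                             measurements = 1, prescans = NULL, n_rows = 1) {
  sequence_spec(
    name = "test", echo_type = echo, readout_type = "LineReadout",
    excitation = list(pulse_type = "hard", angle = 90),
    refocussing = if (echo == "SpinEcho")
      list(pulse_type = "hard", angle = 180) else NULL,
    readout_duration = readout_us, n_columns = n_columns,
    te = te, tr = tr, epi_factor = 1, etl = 1, n_rows = n_rows,
    measurements = measurements, prescans = prescans, spoiling = list())
}

fixture_phantoms <- function() {
  if (is.null(.fixtures$phantoms)) .fixtures$phantoms <- campaign_phantoms()
  .fixtures$phantoms
}

fixture_reduced_table <- function() {
  if (is.null(.fixtures$tab))
    .fixtures$tab <- run_reduced_campaign(seed = 1)
  .fixtures$tab
}

fixture_models <- function() {
  if (is.null(.fixtures$models)) {
    tab <- split_table(fixture_reduced_table(), seed = 1)
    .fixtures$models <- select_and_validate(
      tab, hyperparameter_space(budget = 60), seed = 1)
  }
  .fixtures$models
}

extdata <- function(f) system.file("extdata", f, package = "mrseqopt")
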