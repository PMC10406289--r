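# Requirements and sequence DSL: parsing, defaults, rendering, translation.

test_that("the shipped requirement files parse to the expected goals and constraints", {
  r1 <- read_requirement(extdata("req_gwc.mrreq"))
  expect_equal(r1$goal_direction, "maximize")
  expect_equal(r1$goal_metric, "gwc")
  expect_length(r1$strict_constraints, 3)
  expect_equal(r1$strict_constraints[[1]],
               list(lhs = "snr_gm", lhs_kind = "metric", relation = "gt",
                    rhs = 30, rhs_kind = "number"))
  expect_equal(r1$strict_constraints[[3]]$rhs, "snr_wm")
  expect_equal(r1$strict_constraints[[3]]$rhs_kind, "metric")
  expect_length(r1$vague_constraints, 1)
  expect_equal(r1$vague_constraints[[1]]$kind, "avoid")
  expect_equal(r1$vague_constraints[[1]]$metric, "ghost")

  r2 <- read_requirement(extdata("req_snr_csf.mrreq"))
  expect_equal(r2$goal_metric, "snr_csf")
  expect_length(r2$strict_constraints, 1)
  expect_equal(r2$strict_constraints[[1]]$lhs, "sharpness")
  expect_equal(r2$strict_constraints[[1]]$rhs, 0.85)
  expect_length(r2$vague_constraints, 5)
  expect_equal(vapply(r2$vague_constraints, `[[`, "", "kind"),
               c("avoid", "avoid", "avoid", "aim", "aim"))
  expect_equal(r2$vague_constraints[[4]]$quantifier, "high")
})

test_that("a goal-only requirement has empty constraint lists", {
  r <- parse_requirement('define optimization requirement : maximize "GWC".')
  expect_equal(r$goal_metric, "gwc")
  expect_length(r$strict_constraints, 0)
  expect_length(r$vague_constraints, 0)
  expect_null(r$starting_sequence)
})

test_that("requirement parsing rejects malformed input with location info", {
  expect_error(parse_requirement(""), "empty")
  expect_error(parse_requirement('define optimization requirement : maximize "NOPE".'),
               "unknown acquisition metric")
  expect_error(
    parse_requirement(paste0('define optimization requirement : maximize "GWC".\n',
                             'obey the following constraints:\n',
                             '"SNR_GM" is bigger than 30.')),
    "line 3")
})

test_that("the four shipped default sequences parse and are default-expansion fixed points", {
  files <- c("default_rare.mrseq", "default_se_epi.mrseq",
             "default_epi.mrseq", "default_bssfp.mrseq")
  for (f in files) {
    sp <- read_sequence(extdata(f))
    expect_identical(expand_defaults(sp), sp, label = f)
    expect_true(validate_sequence(sp)$valid, label = f)
  }
  rare <- read_sequence(extdata("default_rare.mrseq"))
  expect_equal(rare$te, 44)
  expect_equal(rare$tr, 500)
  expect_equal(rare$etl, 8)
  expect_equal(rare$n_rows, 64)
  expect_equal(rare$refocussing$angle, 180)
  expect_equal(rare$readout_duration, 2000)
})

test_that("the shipped optimized-solution sequences parse with their printed values", {
  s1 <- read_sequence(extdata("solution_se_epi.mrseq"))
  expect_equal(s1$echo_type, "SpinEcho")
  expect_equal(s1$readout_type, "EPIReadout")
  expect_equal(s1$n_columns, 32)
  expect_equal(s1$epi_factor, 32)
  expect_equal(s1$measurements, 10)
  s2 <- read_sequence(extdata("solution_bssfp.mrseq"))
  expect_equal(s2$te, 17)
  expect_equal(s2$tr, 36)
  expect_equal(s2$prescans$count, 8)
})

test_that("upper-level definitions expand to the family defaults", {
  rare <- expand_defaults(parse_sequence(
    'define MRI sequence "R" using a "SpinEcho" with "LineReadout".'))
  expect_equal(rare$te, 44)
  expect_equal(rare$tr, 500)
  expect_equal(rare$etl, 8)
  expect_equal(rare$readout_duration, 2000)
  expect_equal(rare$measurements, 1)
  epi <- expand_defaults(parse_sequence(
    'define MRI sequence "E" using a "GradientEcho" with "EPIReadout".'))
  expect_equal(epi$te, 35)
  expect_equal(epi$tr, 1000)
  expect_equal(epi$epi_factor, 64)
  expect_equal(epi$measurements, 10)
  expect_null(epi$refocussing)
})

test_that("expand_defaults is idempotent and render/parse round trips", {
  for (f in c("default_rare.mrseq", "default_bssfp.mrseq",
              "solution_se_epi.mrseq", "solution_bssfp.mrseq")) {
    sp <- expand_defaults(read_sequence(extdata(f)))
    expect_identical(expand_defaults(sp), sp, label = f)
    expect_identical(parse_sequence(render_sequence(sp)), sp, label = f)
  }
  # upper level only: everything unset until expansion
  u <- parse_sequence('define MRI sequence "X" using a "GradientEcho" with "EPIReadout".')
  expect_null(u$te)
  expect_null(u$measurements)
  # a spec without additions renders no Add sentences
  sp <- expand_defaults(u)
  sp$spoiling <- list()
  sp$prescans <- NULL
  expect_false(grepl("\nAdd ", render_sequence(sp)))
})

test_that("sequence parsing rejects malformed and contradictory input", {
  expect_error(parse_sequence('define MRI sequence "X" using a "FooEcho" with "LineReadout".'),
               "unknown echo type")
  expect_error(parse_sequence(paste0(
    'define MRI sequence "X" using a "SpinEcho" with "LineReadout".\n',
    "Specify measurements with count 1.\nSpecify measurements with count 2.")),
    "duplicate")
  expect_error(parse_sequence("Specify measurements with count 1."), "keyword 'define'")
})

test_that("requirement translation reproduces the worked numeric constraint sets", {
  p1 <- translate_requirement(read_requirement(extdata("req_gwc.mrreq")))
  expect_equal(p1$goal, list(metric = "gwc", direction = "maximize"))
  expect_length(p1$strict, 3)
  expect_equal(p1$vague[[1]],
               list(metric = "ghost", relation = "lt", bound = 0.05,
                    artifact = TRUE))

  p2 <- translate_requirement(read_requirement(extdata("req_snr_csf.mrreq")))
  expect_equal(p2$strict[[1]]$rhs, 0.85)
  bounds <- vapply(p2$vague, `[[`, numeric(1), "bound")
  expect_equal(bounds, c(0.05, 0.05, 0.05, 10, 10))
  expect_equal(vapply(p2$vague, `[[`, logical(1), "artifact"),
               c(TRUE, TRUE, TRUE, FALSE, FALSE))
  # order preservation: constraint i of the text appears at index i
  mets <- vapply(p2$vague, `[[`, "", "metric")
  expect_equal(mets, c("ghost", "motion_sens", "distortion_sens", "cgc", "cwc"))
})

test_that("translation errors on missing quantifiers and unknown dictionary entries", {
  req <- parse_requirement(paste0('define optimization requirement : maximize "GWC".\n',
                                  'aim for the following :\n  have high "CGC".'))
  req$vague_constraints[[1]]$quantifier <- NULL
  expect_error(translate_requirement(req), "quantifier")
  req2 <- parse_requirement(paste0('define optimization requirement : maximize "GWC".\n',
                                   'aim for the following :\n  avoid "CGC".'))
  expect_error(translate_requirement(req2), "no dictionary bound")
})

test_that("ordinal dictionary bounds are monotone in the quantifier order", {
  d <- ordinal_dictionary()
  for (fam in names(d$bands))
    expect_false(is.unsorted(d$bands[[fam]]$bounds), label = fam)
  expect_lt(d$avoid[["ghost"]], d$allow[["ghost"]])
  # overrides are honoured
  d2 <- ordinal_dictionary(list(avoid = c(ghost = 0.01)))
  expect_equal(d2$avoid[["ghost"]], 0.01)
})

test_that("metric aliases resolve case-insensitively and unknowns error", {
  expect_equal(resolve_metric("Ghosting"), "ghost")
  expect_equal(resolve_metric("GNR"), "snr_gm")
  expect_equal(resolve_metric("acquisition time"), "acq_time")
  expect_error(resolve_metric("blur"), "unknown")
  expect_equal(resolve_metric("blur", error = FALSE), NA_character_)
})
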