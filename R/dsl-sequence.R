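#' Construct a sequence specification
#'
#' A `sequence_spec` is the full parametric description of one Cartesian MRI
#' sequence: echo and readout type, pulses, timing (TE/TR in ms), trajectory
#' (EPI factor, echo train length, matrix), readout duration (in microseconds,
#' the unit of the sequence DSL), measurements, optional prescans and spoiling
#' additions.  Fields left `NULL` are "unset" and are later filled in by
#' [expand_defaults()].  Gradient-echo sequences carry a refocussing angle of 0
#' internally so that the numeric parameter vector is fully defined.
#'
#' @param name Sequence name.
#' @param echo_type `"SpinEcho"` or `"GradientEcho"`.
#' @param readout_type `"LineReadout"` or `"EPIReadout"`.
#' @param excitation List `(pulse_type, angle)`, angle in degrees.
#' @param refocussing List `(pulse_type, angle)`; `NULL` for gradient echo.
#' @param readout_duration ADC duration of one line, microseconds.
#' @param n_columns,n_rows Matrix size (readout and phase-encoding).
#' @param te,tr Echo and repetition time, ms.
#' @param epi_factor Lines per excitation for EPI readouts (1 = line readout).
#' @param etl Echo train length for multi-echo spin echo (1 otherwise).
#' @param measurements Number of repeated measurements.
#' @param prescans List `(count, type)` of steady-state prescans, or `NULL`.
#' @param spoiling List of `(location, type)` spoiling additions; locations are
#'   `"around_refocussing"`, `"after_echotrain"`, `"after_segment"`,
#'   `"around_readout"`.
#' @return Object of class `sequence_spec`.
#' @export
sequence_spec <- function(name = "unnamed", echo_type = NULL, readout_type = NULL,
                          excitation = NULL, refocussing = NULL,
                          readout_duration = NULL, n_columns = NULL,
                          te = NULL, tr = NULL,
                          epi_factor = NULL, etl = NULL, n_rows = NULL,
                          measurements = NULL, prescans = NULL,
                          spoiling = list()) {
  spec <- structure(list(
    name = name, echo_type = echo_type, readout_type = readout_type,
    excitation = excitation, refocussing = refocussing,
    readout_duration = readout_duration, n_columns = n_columns,
    te = te, tr = tr, epi_factor = epi_factor, etl = etl, n_rows = n_rows,
    measurements = measurements, prescans = prescans, spoiling = spoiling
  ), class = "sequence_spec")
  .check_spec_fields(spec)
  spec
}

.check_spec_fields <- function(spec) {
  if (!is.null(spec$echo_type) &&
      !spec$echo_type %in% c("SpinEcho", "GradientEcho"))
    stop("unknown echo type: '", spec$echo_type, "'", call. = FALSE)
  if (!is.null(spec$readout_type) &&
      !spec$readout_type %in% c("LineReadout", "EPIReadout"))
    stop("unknown readout type: '", spec$readout_type, "'", call. = FALSE)
  for (p in list(spec$excitation, spec$refocussing)) {
    if (!is.null(p) && (p$angle < 0 || p$angle >= 360))
      stop("pulse angles must lie in [0, 360)", call. = FALSE)
  }
  invisible(spec)
}

#' @export
print.sequence_spec <- function(x, ...) {
  cat("<sequence_spec>", x$name, "\n")
  cat(render_sequence(expand_defaults(x)))
  invisible(x)
}

.spec_complete <- function(spec) {
  core <- c("echo_type", "readout_type", "excitation", "readout_duration",
            "n_columns", "te", "tr", "epi_factor", "etl", "n_rows",
            "measurements")
  all(!vapply(spec[core], is.null, logical(1))) &&
    (spec$echo_type == "GradientEcho" || !is.null(spec$refocussing))
}

#' Parse sequence-DSL text into a sequence specification
#'
#' The sequence DSL consists of one mandatory upper-level sentence
#' (`define MRI sequence "name" using a "SpinEcho" with "LineReadout".`)
#' followed by optional `Specify` sentences (echo pulses, readout, timing,
#' trajectory, measurements) and `Add` sentences (gradient spoiling,
#' prescans).  Fields not mentioned in the text are left unset; use
#' [expand_defaults()] to fill them with the family defaults.
#'
#' @param text Sequence-DSL text (UTF-8 string).
#' @return A [sequence_spec()].  Parsing a rendered spec returns an identical
#'   spec (round trip).
#' @seealso [render_sequence()], [expand_defaults()], [read_sequence()]
#' @export
parse_sequence <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  cur <- .tok_cursor(.dsl_tokenize(text))
  if (.tk_eof(cur)) stop("empty sequence-DSL text", call. = FALSE)

  # upper-level sentence
  .tk_keyword(cur, "define")
  .tk_keyword(cur, "MRI")
  .tk_keyword(cur, "sequence")
  nm <- .tk_name(cur, "the sequence name in double quotes")
  .tk_keyword(cur, "using")
  .tk_keyword(cur, "a")
  echo <- .tk_name(cur, 'the echo type ("SpinEcho"/"GradientEcho")')
  .tk_keyword(cur, "with")
  ro <- .tk_name(cur, 'the readout type ("LineReadout"/"EPIReadout")')
  .tk_punct(cur, ".")
  spec <- sequence_spec(name = nm, echo_type = echo, readout_type = ro)
  if (echo == "GradientEcho") spec$refocussing <- NULL

  seen <- character()
  while (!.tk_eof(cur)) {
    if (.tk_is_keyword(cur, "Specify")) {
      .tk_next(cur)
      spec <- .parse_specify(cur, spec, seen_env = environment())
    } else if (.tk_is_keyword(cur, "Add")) {
      .tk_next(cur)
      spec <- .parse_addition(cur, spec)
    } else {
      .tk_err(.tk_peek(cur), "'Specify' or 'Add'")
    }
  }
  if (spec$echo_type == "SpinEcho" && !is.null(spec$refocussing) &&
      spec$refocussing$angle == 0)
    stop("spin-echo sequences require a non-zero refocussing angle", call. = FALSE)
  if (spec$echo_type == "GradientEcho" && !is.null(spec$refocussing)) {
    if (spec$refocussing$angle != 0)
      stop("gradient-echo sequences cannot carry a refocussing pulse", call. = FALSE)
    spec$refocussing <- NULL
  }
  spec
}

.mark_seen <- function(seen_env, what) {
  if (what %in% seen_env$seen)
    stop("contradictory duplicate 'Specify ", what, "' block", call. = FALSE)
  seen_env$seen <- c(seen_env$seen, what)
}

.parse_specify <- function(cur, spec, seen_env) {
  kw <- tolower(.tk_word(cur, "a specification kind"))
  if (kw == "echo") {
    .mark_seen(seen_env, "echo")
    .tk_keyword(cur, "as")
    .tk_keyword(cur, "excitation")
    .tk_keyword(cur, "with")
    .tk_keyword(cur, "type")
    ety <- .tk_word(cur, "a pulse type")
    .tk_keyword(cur, "and")
    .tk_keyword(cur, "angle")
    ean <- .tk_number(cur, "the excitation angle")
    spec$excitation <- list(pulse_type = ety, angle = ean)
    # optional ", and refocussing ..." -- a trailing comma directly followed by
    # the next sentence is tolerated (it occurs in shipped sequence files)
    if (.tk_is_punct(cur, ",")) .tk_next(cur)
    if (.tk_is_keyword(cur, "and") && .tk_is_keyword(cur, "refocussing", 1L)) {
      .tk_next(cur); .tk_next(cur)
      .tk_keyword(cur, "with")
      .tk_keyword(cur, "type")
      rty <- .tk_word(cur, "a pulse type")
      .tk_keyword(cur, "and")
      .tk_keyword(cur, "angle")
      ran <- .tk_number(cur, "the refocussing angle")
      spec$refocussing <- list(pulse_type = rty, angle = ran)
      .tk_punct(cur, ".")
    } else if (.tk_is_punct(cur, ".")) {
      .tk_next(cur)
    } else if (!(.tk_is_keyword(cur, c("Specify", "Add")) || .tk_eof(cur))) {
      .tk_err(.tk_peek(cur), "'.' or 'and refocussing'")
    }
  } else if (kw == "readout") {
    .mark_seen(seen_env, "readout")
    .tk_keyword(cur, "with")
    .tk_keyword(cur, "duration")
    spec$readout_duration <- .tk_number(cur, "the readout duration (microseconds)")
    .tk_keyword(cur, "and")
    .tk_keyword(cur, "number-of-columns")
    spec$n_columns <- .tk_number(cur, "the number of columns")
    .tk_punct(cur, ".")
  } else if (kw == "timing") {
    .mark_seen(seen_env, "timing")
    .tk_keyword(cur, "parameters")
    .tk_keyword(cur, "with")
    .tk_keyword(cur, "TE")
    spec$te <- .tk_number(cur, "TE (ms)")
    .tk_keyword(cur, "and")
    .tk_keyword(cur, "TR")
    spec$tr <- .tk_number(cur, "TR (ms)")
    .tk_punct(cur, ".")
  } else if (kw == "trajectory") {
    .mark_seen(seen_env, "trajectory")
    .tk_keyword(cur, "with")
    .tk_keyword(cur, "Epi-Factor")
    spec$epi_factor <- .tk_number(cur, "the EPI factor")
    .tk_keyword(cur, "and")
    .tk_keyword(cur, "ETL")
    spec$etl <- .tk_number(cur, "the echo train length")
    .tk_keyword(cur, "and")
    .tk_keyword(cur, "number-of-rows")
    spec$n_rows <- .tk_number(cur, "the number of rows")
    .tk_punct(cur, ".")
  } else if (kw == "measurements") {
    .mark_seen(seen_env, "measurements")
    .tk_keyword(cur, "with")
    .tk_keyword(cur, "count")
    spec$measurements <- .tk_number(cur, "the number of measurements")
    .tk_punct(cur, ".")
  } else {
    stop("unknown specification kind: '", kw, "'", call. = FALSE)
  }
  spec
}

.parse_addition <- function(cur, spec) {
  if (.tk_is_keyword(cur, "prescans")) {
    .tk_next(cur)
    .tk_keyword(cur, "with")
    .tk_keyword(cur, "count")
    cnt <- .tk_number(cur, "the prescan count")
    ty <- NA_character_
    if (.tk_is_keyword(cur, "and")) {
      .tk_next(cur)
      .tk_keyword(cur, "type")
      ty <- .tk_word(cur, "the prescan ramp type")
    }
    .tk_punct(cur, ".")
    spec$prescans <- list(count = cnt, type = ty)
  } else if (.tk_is_keyword(cur, "gradient")) {
    .tk_next(cur)
    .tk_keyword(cur, "spoiling")
    prep <- .tk_keyword(cur, c("around", "after"))
    where <- tolower(.tk_word(cur, "a spoiling location"))
    loc <- paste0(prep, "_", where)
    if (!loc %in% c("around_refocussing", "after_echotrain",
                    "after_segment", "around_readout"))
      stop("unknown spoiling location: '", prep, " ", where, "'", call. = FALSE)
    ty <- NA_character_
    if (.tk_is_keyword(cur, "of")) {
      .tk_next(cur)
      .tk_keyword(cur, "type")
      ty <- .tk_word(cur, "the spoiling type")
    }
    .tk_punct(cur, ".")
    spec$spoiling <- c(spec$spoiling, list(list(location = loc, type = ty)))
  } else {
    .tk_err(.tk_peek(cur), "'prescans' or 'gradient spoiling'")
  }
  spec
}

# family defaults, matched to the four shipped default sequences
.family_of <- function(echo_type, readout_type) {
  if (echo_type == "SpinEcho" && readout_type == "LineReadout") "RARE"
  else if (echo_type == "SpinEcho" && readout_type == "EPIReadout") "SE-EPI"
  else if (echo_type == "GradientEcho" && readout_type == "EPIReadout") "EPI"
  else "bSSFP"
}

.family_defaults <- function(family) {
  switch(family,
    "RARE" = list(
      excitation = list(pulse_type = "sincpulse", angle = 90),
      refocussing = list(pulse_type = "sincpulse", angle = 180),
      readout_duration = 2000, n_columns = 64, te = 44, tr = 500,
      epi_factor = 1, etl = 8, n_rows = 64, measurements = 1, prescans = NULL,
      spoiling = list(list(location = "around_refocussing", type = "balanced"),
                      list(location = "after_echotrain", type = NA_character_))),
    "SE-EPI" = list(
      excitation = list(pulse_type = "sincpulse", angle = 90),
      refocussing = list(pulse_type = "sincpulse", angle = 180),
      readout_duration = 500, n_columns = 64, te = 50, tr = 1000,
      epi_factor = 64, etl = 1, n_rows = 64, measurements = 10, prescans = NULL,
      spoiling = list(list(location = "around_refocussing", type = "balanced"),
                      list(location = "after_segment", type = NA_character_))),
    "EPI" = list(
      excitation = list(pulse_type = "sincpulse", angle = 90),
      refocussing = NULL,
      readout_duration = 500, n_columns = 64, te = 35, tr = 1000,
      epi_factor = 64, etl = 1, n_rows = 64, measurements = 10, prescans = NULL,
      spoiling = list(list(location = "after_segment", type = NA_character_))),
    "bSSFP" = list(
      excitation = list(pulse_type = "sincpulse", angle = 90),
      refocussing = NULL,
      readout_duration = 2000, n_columns = 64, te = 4, tr = 8,
      epi_factor = 1, etl = 1, n_rows = 64, measurements = 1,
      prescans = list(count = 8, type = "linear"),
      spoiling = list(list(location = "around_readout", type = "balanced"))),
    stop("unknown sequence family: ", family, call. = FALSE))
}

#' Fill unset sequence fields with family defaults
#'
#' Echo type and readout type select one of four sequence families (RARE,
#' SE-EPI, EPI, bSSFP); every unset field is substituted with that family's
#' default value (the values of the shipped default sequences).  The operation
#' is idempotent and leaves fully specified sequences unchanged.
#'
#' @param spec A [sequence_spec()] with at least echo and readout type set.
#' @return A complete `sequence_spec`.
#' @export
expand_defaults <- function(spec) {
  stopifnot(inherits(spec, "sequence_spec"))
  if (is.null(spec$echo_type) || is.null(spec$readout_type))
    stop("echo type and readout type must be set before default expansion",
         call. = FALSE)
  fam <- .family_of(spec$echo_type, spec$readout_type)
  d <- .family_defaults(fam)
  for (f in c("excitation", "readout_duration", "n_columns", "te", "tr",
              "epi_factor", "etl", "n_rows", "measurements")) {
    if (is.null(spec[[f]])) spec[[f]] <- d[[f]]
  }
  if (spec$echo_type == "SpinEcho" && is.null(spec$refocussing))
    spec$refocussing <- d$refocussing
  if (is.null(spec$prescans) && !is.null(d$prescans)) spec$prescans <- d$prescans
  if (length(spec$spoiling) == 0) spec$spoiling <- d$spoiling
  spec
}

# effective refocussing angle (0 encodes gradient echo)
.refoc_angle <- function(spec) {
  if (is.null(spec$refocussing)) 0 else spec$refocussing$angle
}

#' Render a sequence specification as sequence-DSL text
#'
#' Inverse of [parse_sequence()]: `parse_sequence(render_sequence(s))` equals
#' `s` for every complete specification.  Gradient-echo specs emit no
#' refocussing clause; specs without additions emit no `Add` sentences.
#'
#' @param spec A complete [sequence_spec()].
#' @return A single string of sequence-DSL text.
#' @export
render_sequence <- function(spec) {
  stopifnot(inherits(spec, "sequence_spec"))
  if (!.spec_complete(spec))
    stop("cannot render an incomplete sequence spec; use expand_defaults()",
         call. = FALSE)
  out <- c(sprintf('define MRI sequence "%s"\n  using a "%s" with "%s".',
                   spec$name, spec$echo_type, spec$readout_type))
  if (!is.null(spec$prescans)) {
    ps <- spec$prescans
    out <- c(out, sprintf("Add prescans\n  with count %s%s.", .fmt_num(ps$count),
                          if (is.na(ps$type)) "" else paste0(" and type ", ps$type)))
  }
  for (sp in spec$spoiling) {
    loc <- sub("_", " ", sp$location)
    out <- c(out, sprintf("Add gradient spoiling %s%s.", loc,
                          if (is.na(sp$type)) "" else paste0("\n  of type ", sp$type)))
  }
  exc <- sprintf("Specify echo\n  as excitation\n    with type %s and angle %s",
                 spec$excitation$pulse_type, .fmt_num(spec$excitation$angle))
  if (!is.null(spec$refocussing)) {
    exc <- paste0(exc, sprintf(
      ",\n  and refocussing\n    with type %s and angle %s.",
      spec$refocussing$pulse_type, .fmt_num(spec$refocussing$angle)))
  } else {
    exc <- paste0(exc, ".")
  }
  out <- c(out, exc)
  out <- c(out,
    sprintf("Specify readout\n  with duration %s\n  and number-of-columns %s.",
            .fmt_num(spec$readout_duration), .fmt_num(spec$n_columns)),
    sprintf("Specify timing parameters\n  with TE %s\n  and TR %s.",
            .fmt_num(spec$te), .fmt_num(spec$tr)),
    sprintf(paste0("Specify trajectory\n  with Epi-Factor %s\n  and ETL %s",
                   "\n  and number-of-rows %s."),
            .fmt_num(spec$epi_factor), .fmt_num(spec$etl), .fmt_num(spec$n_rows)),
    sprintf("Specify measurements\n  with count %s.", .fmt_num(spec$measurements)))
  paste0(paste(out, collapse = "\n"), "\n")
}

#' Read / write sequence-DSL files
#'
#' Plain-text UTF-8 files, conventionally with extension `.mrseq`.
#'
#' @param path File path.
#' @return `read_sequence()` returns a [sequence_spec()].
#' @export
read_sequence <- function(path) {
  parse_sequence(paste(readLines(path, encoding = "UTF-8", warn = FALSE),
                       collapse = "\n"))
}

#' @rdname read_sequence
#' @param spec A complete [sequence_spec()].
#' @export
write_sequence <- function(spec, path) {
  writeLines(render_sequence(spec), path, useBytes = TRUE)
  invisible(path)
}
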