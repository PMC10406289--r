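#' Parse requirements-DSL text
#'
#' The requirements DSL states an optimization goal plus optional strict and
#' vague constraints:
#'
#' ```
#' define optimization requirement :
#'   maximize "GWC".
#'   obey the following constraints:
#'     "SNR_GM" is higher than 30.
#'     "SNR_GM" is higher than "SNR_WM".
#'   aim for the following :
#'     avoid "ghosting".
#'     have high "CGC".
#' ```
#'
#' Strict constraints relate an acquisition metric or sequence parameter to a
#' number or to another metric/parameter via `is smaller than` / `equals` /
#' `is greater than` (`is higher than` / `is lower than` are accepted
#' synonyms).  Vague constraints are `avoid`/`allow` statements or `have
#' <quantifier>` aims with quantifiers `very low`, `low`, `decent`, `high`,
#' `very high`.  An optional starting sequence can be attached with
#' `using starting sequence : <sequence-DSL text>`.
#'
#' @param text Requirements-DSL text.
#' @return Object of class `requirement_spec` with elements `goal_direction`
#'   (`"minimize"`/`"maximize"`), `goal_metric` (canonical metric name),
#'   `strict_constraints` (list of `(lhs, lhs_kind, relation, rhs, rhs_kind)`
#'   with relations `lt`/`eq`/`gt`), `vague_constraints` (list of
#'   `(kind, metric, quantifier)`), and `starting_sequence` (a
#'   [sequence_spec()] or `NULL`).
#' @seealso [translate_requirement()], [read_requirement()]
#' @export
parse_requirement <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (!nzchar(trimws(text))) stop("empty requirements-DSL text", call. = FALSE)
  cur <- .tok_cursor(.dsl_tokenize(text))

  .tk_keyword(cur, "define")
  .tk_keyword(cur, "optimization")
  .tk_keyword(cur, "requirement")
  .tk_punct(cur, ":")
  dir <- .tk_keyword(cur, c("minimize", "maximize"))
  goal <- resolve_metric(.tk_name(cur, "the goal metric in double quotes"))
  .tk_punct(cur, ".")

  strict <- list()
  vague <- list()
  start_seq <- NULL

  if (.tk_is_keyword(cur, "obey")) {
    .tk_next(cur)
    .tk_keyword(cur, "the")
    .tk_keyword(cur, "following")
    .tk_keyword(cur, "constraints")
    .tk_punct(cur, ":")
    while (!.tk_eof(cur) && .tk_peek(cur)$type == "name") {
      strict <- c(strict, list(.parse_strict(cur)))
    }
  }

  if (.tk_is_keyword(cur, "aim")) {
    .tk_next(cur)
    .tk_keyword(cur, "for")
    .tk_keyword(cur, "the")
    .tk_keyword(cur, "following")
    .tk_punct(cur, ":")
    while (.tk_is_keyword(cur, c("avoid", "allow", "have"))) {
      vague <- c(vague, list(.parse_vague(cur)))
    }
  }

  if (.tk_is_keyword(cur, "using")) {
    .tk_next(cur)
    .tk_keyword(cur, "starting")
    .tk_keyword(cur, "sequence")
    .tk_punct(cur, ":")
    rest <- cur$toks[seq(cur$i, length(cur$toks))]
    # hand the remainder of the raw text to the sequence parser
    first <- rest[[1]]
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
    tail_txt <- c(substring(lines[first$line], first$col),
                  if (first$line < length(lines))
                    lines[seq(first$line + 1L, length(lines))])
    start_seq <- parse_sequence(paste(tail_txt, collapse = "\n"))
    cur$i <- length(cur$toks) + 1L
  }

  if (!.tk_eof(cur)) .tk_err(.tk_peek(cur), "end of requirement")

  structure(list(goal_direction = dir, goal_metric = goal,
                 strict_constraints = strict, vague_constraints = vague,
                 starting_sequence = start_seq),
            class = "requirement_spec")
}

# one side of a strict constraint: quoted metric/param name or a number
.parse_operand <- function(cur) {
  t <- .tk_peek(cur)
  if (!is.null(t) && t$type == "number") {
    return(list(value = .tk_number(cur), kind = "number"))
  }
  nm <- .tk_name(cur, "a quoted metric/parameter name or a number")
  m <- resolve_metric(nm, error = FALSE)
  if (!is.na(m)) return(list(value = m, kind = "metric"))
  p <- .resolve_param(nm)
  if (!is.na(p)) return(list(value = p, kind = "param"))
  stop("unknown metric or sequence parameter: '", nm, "'", call. = FALSE)
}

.parse_strict <- function(cur) {
  lhs <- .parse_operand(cur)
  if (lhs$kind == "number")
    stop("the left-hand side of a strict constraint must be a metric or parameter",
         call. = FALSE)
  rel <- if (.tk_is_keyword(cur, "equals")) {
    .tk_next(cur); "eq"
  } else {
    .tk_keyword(cur, "is")
    w <- .tk_keyword(cur, c("smaller", "greater", "higher", "lower"))
    if (w %in% c("smaller", "lower")) { .tk_keyword(cur, "than"); "lt" }
    else { .tk_keyword(cur, "than"); "gt" }
  }
  rhs <- .parse_operand(cur)
  .tk_punct(cur, ".")
  list(lhs = lhs$value, lhs_kind = lhs$kind, relation = rel,
       rhs = rhs$value, rhs_kind = rhs$kind)
}

.parse_vague <- function(cur) {
  kw <- .tk_keyword(cur, c("avoid", "allow", "have"))
  quant <- NULL
  if (kw == "have") {
    q1 <- .tk_keyword(cur, c("very", "low", "decent", "high"))
    quant <- if (q1 == "very") paste0("very_", .tk_keyword(cur, c("low", "high")))
             else q1
  }
  metric <- resolve_metric(.tk_name(cur, "a quoted metric name"))
  .tk_punct(cur, ".")
  list(kind = c(avoid = "avoid", allow = "allow", have = "aim")[[kw]],
       metric = metric, quantifier = quant)
}

#' @export
print.requirement_spec <- function(x, ...) {
  cat("<requirement_spec>", x$goal_direction, x$goal_metric, "\n")
  cat("  strict constraints:", length(x$strict_constraints), "\n")
  cat("  vague constraints: ", length(x$vague_constraints), "\n")
  invisible(x)
}

#' Read a requirements-DSL file
#'
#' @param path Path to a plain-text `.mrreq` file.
#' @return A `requirement_spec` (see [parse_requirement()]).
#' @export
read_requirement <- function(path) {
  parse_requirement(paste(readLines(path, encoding = "UTF-8", warn = FALSE),
                          collapse = "\n"))
}

#' Ordinal dictionary: vague wording to numeric bounds
#'
#' Maps the DSL's ordinal vocabulary onto numeric constraint bounds per metric
#' family.  `avoid`/`allow` on the artifact metrics (ghost, motion and
#' distortion sensitivity) become upper bounds; `have <quantifier>` aims become
#' lower bounds for contrast, SNR and correlation metrics and upper bounds for
#' artifact metrics and acquisition time.  Bounds are monotone in the
#' quantifier order `very_low < low < decent < high < very_high`.  Every entry
#' can be overridden through `overrides` (or a YAML/JSON file read with
#' [yaml::read_yaml()] / [jsonlite::read_json()] whose structure mirrors the
#' returned list).
#'
#' @param overrides Optional named list merged over the defaults; names are
#'   `avoid`, `allow` (named numeric vectors per metric) and `bands` (named
#'   list per metric family of 5 quantifier bounds).
#' @return Object of class `ordinal_dictionary`.
#' @export
ordinal_dictionary <- function(overrides = NULL) {
  dict <- list(
    # upper bounds triggered by avoid/allow statements (artifact metrics)
    avoid = c(ghost = 0.05, motion_sens = 0.05, distortion_sens = 0.05),
    allow = c(ghost = 0.20, motion_sens = 0.20, distortion_sens = 0.20),
    # quantifier bands very_low/low/decent/high/very_high
    bands = list(
      contrast = list(bounds = c(1, 2, 5, 10, 20), direction = "lower"),
      snr = list(bounds = c(5, 10, 20, 30, 50), direction = "lower"),
      correlation = list(bounds = c(0.5, 0.65, 0.75, 0.85, 0.95),
                         direction = "lower"),
      artifact = list(bounds = c(0.01, 0.05, 0.10, 0.20, 0.50),
                      direction = "upper"),
      time = list(bounds = c(5e3, 1.5e4, 6e4, 1.8e5, 6e5), direction = "upper")
    )
  )
  if (!is.null(overrides)) dict <- utils::modifyList(dict, overrides)
  structure(dict, class = "ordinal_dictionary")
}

.metric_family <- function(metric) {
  switch(metric,
         cgc = , gwc = , cwc = "contrast",
         snr_csf = , snr_gm = , snr_wm = "snr",
         sharpness = , homogeneity = "correlation",
         ghost = , motion_sens = , distortion_sens = "artifact",
         acq_time = "time",
         stop("metric '", metric, "' not covered by the ordinal dictionary",
              call. = FALSE))
}

.artifact_metrics <- function() c("ghost", "motion_sens", "distortion_sens")

#' Translate a requirement into a numeric optimization problem
#'
#' Strict constraints are copied verbatim (metric-number, metric-metric or
#' parameter comparisons).  Vague constraints are mapped to numeric bounds via
#' the [ordinal_dictionary()]: avoidance/allowance statements on artifact
#' metrics become upper bounds, `have <quantifier>` aims become quantifier-band
#' bounds.  Avoid constraints on ghost, motion and distortion are flagged for
#' the exponential artifact penalty of the fitness function.  Constraint order
#' is preserved.
#'
#' @param req A `requirement_spec` from [parse_requirement()].
#' @param dict An [ordinal_dictionary()].
#' @return Object of class `optimization_problem` with `goal` (metric,
#'   direction), `strict` (as in the requirement), `vague` (list of
#'   `(metric, relation, bound, artifact)`), and `artifact_flags`.
#' @export
translate_requirement <- function(req, dict = ordinal_dictionary()) {
  stopifnot(inherits(req, "requirement_spec"))
  quant_idx <- c(very_low = 1L, low = 2L, decent = 3L, high = 4L, very_high = 5L)
  vague <- lapply(req$vague_constraints, function(vc) {
    m <- vc$metric
    if (vc$kind %in% c("avoid", "allow")) {
      tab <- dict[[vc$kind]]
      if (!m %in% names(tab))
        stop("'", vc$kind, "' has no dictionary bound for metric '", m, "'",
             call. = FALSE)
      list(metric = m, relation = "lt", bound = unname(tab[[m]]),
           artifact = vc$kind == "avoid" && m %in% .artifact_metrics())
    } else {
      if (is.null(vc$quantifier))
        stop("aim-kind vague constraint on '", m, "' is missing its quantifier",
             call. = FALSE)
      band <- dict$bands[[.metric_family(m)]]
      b <- band$bounds[[quant_idx[[vc$quantifier]]]]
      list(metric = m,
           relation = if (band$direction == "lower") "gt" else "lt",
           bound = b, artifact = FALSE)
    }
  })
  flags <- unique(vapply(Filter(function(v) v$artifact, vague),
                         function(v) v$metric, character(1)))
  structure(list(
    goal = list(metric = req$goal_metric, direction = req$goal_direction),
    strict = req$strict_constraints,
    vague = vague,
    artifact_flags = flags,
    starting_sequence = req$starting_sequence
  ), class = "optimization_problem")
}

#' @export
print.optimization_problem <- function(x, ...) {
  cat("<optimization_problem>", x$goal$direction, x$goal$metric, "\n")
  for (s in x$strict) {
    cat(sprintf("  strict: %s %s %s\n", s$lhs,
                c(lt = "<", eq = "=", gt = ">")[[s$relation]],
                if (s$rhs_kind == "number") .fmt_num(s$rhs) else s$rhs))
  }
  for (v in x$vague) {
    cat(sprintf("  vague:  %s %s %s%s\n", v$metric,
                c(lt = "<", gt = ">")[[v$relation]], .fmt_num(v$bound),
                if (v$artifact) "  [exp penalty]" else ""))
  }
  invisible(x)
}
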