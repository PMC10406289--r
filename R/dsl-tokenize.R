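# Shared tokenizer for both DSLs.
#
# Statements end with a period; names are double-quoted (case-sensitive);
# keywords are matched case-insensitively; whitespace and newlines are
# insignificant.  Hyphenated keywords ("number-of-columns", "Epi-Factor") are
# single tokens; decimal numbers are not split at the point.

.dsl_tokenize <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) == 0) lines <- ""
  toks <- list()
  pat <- paste0(
    '("([^"]*)")',                        # quoted name
    "|([0-9]+(\\.[0-9]+)?)",              # number
    "|([A-Za-z][A-Za-z0-9_-]*)",          # word (may contain hyphens)
    "|([.,:])"                            # punctuation
  )
  for (ln in seq_along(lines)) {
    s <- lines[[ln]]
    pos <- 1L
    while (pos <= nchar(s)) {
      rest <- substr(s, pos, nchar(s))
      ws <- regmatches(rest, regexpr("^\\s+", rest))
      if (length(ws) == 1) {
        pos <- pos + nchar(ws)
        next
      }
      rest <- substr(s, pos, nchar(s))
      if (!nzchar(rest)) break
      m <- regexpr(pat, rest, perl = TRUE)
      if (m != 1L) {
        stop(sprintf("DSL syntax error at line %d, column %d: unexpected character '%s'",
                     ln, pos, substr(rest, 1, 1)), call. = FALSE)
      }
      tok <- regmatches(rest, m)
      if (startsWith(tok, '"')) {
        type <- "name"; val <- substr(tok, 2, nchar(tok) - 1)
      } else if (grepl("^[0-9]", tok)) {
        type <- "number"; val <- tok
      } else if (tok %in% c(".", ",", ":")) {
        type <- tok; val <- tok
      } else {
        type <- "word"; val <- tok
      }
      toks[[length(toks) + 1L]] <- list(type = type, value = val,
                                        lower = tolower(val), line = ln, col = pos)
      pos <- pos + nchar(tok)
    }
  }
  toks
}

# Minimal cursor over the token list with keyword-oriented helpers.
.tok_cursor <- function(tokens) {
  env <- new.env(parent = emptyenv())
  env$toks <- tokens
  env$i <- 1L
  env
}

.tk_eof <- function(cur) cur$i > length(cur$toks)

.tk_peek <- function(cur, ahead = 0L) {
  j <- cur$i + ahead
  if (j > length(cur$toks)) NULL else cur$toks[[j]]
}

.tk_next <- function(cur) {
  t <- .tk_peek(cur)
  if (is.null(t)) stop("DSL syntax error: unexpected end of input", call. = FALSE)
  cur$i <- cur$i + 1L
  t
}

.tk_err <- function(tok, expected) {
  if (is.null(tok)) {
    stop(sprintf("DSL syntax error: expected %s but input ended", expected),
         call. = FALSE)
  }
  stop(sprintf("DSL syntax error at line %d, column %d: expected %s, found '%s'",
               tok$line, tok$col, expected, tok$value), call. = FALSE)
}

# consume one keyword (case-insensitive); kw may be a vector of alternatives
.tk_keyword <- function(cur, kw) {
  t <- .tk_peek(cur)
  if (is.null(t) || t$type != "word" || !(t$lower %in% tolower(kw)))
    .tk_err(t, paste0("keyword '", paste(kw, collapse = "'/'"), "'"))
  cur$i <- cur$i + 1L
  t$lower
}

.tk_is_keyword <- function(cur, kw, ahead = 0L) {
  t <- .tk_peek(cur, ahead)
  !is.null(t) && t$type == "word" && t$lower %in% tolower(kw)
}

.tk_punct <- function(cur, p) {
  t <- .tk_peek(cur)
  if (is.null(t) || t$type != p) .tk_err(t, paste0("'", p, "'"))
  cur$i <- cur$i + 1L
  invisible(p)
}

.tk_is_punct <- function(cur, p) {
  t <- .tk_peek(cur)
  !is.null(t) && t$type == p
}

.tk_number <- function(cur, what = "a number") {
  t <- .tk_peek(cur)
  if (is.null(t) || t$type != "number") .tk_err(t, what)
  cur$i <- cur$i + 1L
  as.numeric(t$value)
}

.tk_name <- function(cur, what = "a quoted name") {
  t <- .tk_peek(cur)
  if (is.null(t) || t$type != "name") .tk_err(t, what)
  cur$i <- cur$i + 1L
  t$value
}

.tk_word <- function(cur, what = "a word") {
  t <- .tk_peek(cur)
  if (is.null(t) || t$type != "word") .tk_err(t, what)
  cur$i <- cur$i + 1L
  t$value
}
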