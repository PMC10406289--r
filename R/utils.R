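#' Canonical acquisition-metric names
#'
#' The twelve image-quality metrics computed for every simulated sequence, in
#' the fixed column order used throughout the package: three tissue contrasts
#' (CGC = CSF/grey, GWC = grey/white, CWC = CSF/white), three tissue SNR
#' values, the ghosting level, sharpness and homogeneity (both Pearson
#' correlations against the simulated target), motion and distortion
#' sensitivity, and the acquisition time in milliseconds.
#'
#' @return Character vector of length 12.
#' @export
metric_names <- function() {
  c("cgc", "gwc", "cwc",
    "snr_csf", "snr_gm", "snr_wm",
    "ghost", "sharpness", "homogeneity",
    "motion_sens", "distortion_sens", "acq_time")
}

# DSL-facing aliases (case-insensitive) -> canonical metric name.  Includes the
# per-tissue "noise ratio" aliases (CNR/GNR/WNR) used interchangeably with SNR.
.metric_aliases <- function() {
  c(cgc = "cgc", gwc = "gwc", cwc = "cwc",
    snr_csf = "snr_csf", snr_gm = "snr_gm", snr_wm = "snr_wm",
    cnr = "snr_csf", gnr = "snr_gm", wnr = "snr_wm",
    ghost = "ghost", ghosting = "ghost", gl = "ghost",
    sharpness = "sharpness", is_ = "sharpness",
    homogeneity = "homogeneity", hom = "homogeneity",
    motion = "motion_sens", motion_sens = "motion_sens",
    motion_sensitivity = "motion_sens", motion.sens = "motion_sens",
    distortion = "distortion_sens", distortion_sens = "distortion_sens",
    distortion_sensitivity = "distortion_sens", distortion.sens = "distortion_sens",
    time = "acq_time", acq_time = "acq_time", acquisition_time = "acq_time",
    `acquisition time` = "acq_time")
}

#' Resolve a DSL metric name to its canonical identifier
#'
#' @param name Metric name as written in DSL text (case-insensitive; aliases
#'   such as "ghosting", "motion" or "acquisition time" are accepted).
#' @param error Throw an error for unknown names (default) or return `NA`.
#' @return Canonical metric name (one of [metric_names()]), or `NA_character_`.
#' @export
resolve_metric <- function(name, error = TRUE) {
  key <- tolower(gsub("[-\\s]+", "_", trimws(name), perl = TRUE))
  key <- sub("^is$", "is_", key)
  al <- .metric_aliases()
  if (key %in% names(al)) return(unname(al[[key]]))
  if (key %in% metric_names()) return(key)
  if (error) stop("unknown acquisition metric: '", name, "'", call. = FALSE)
  NA_character_
}

# Sequence-parameter names usable on either side of a strict constraint.
.sequence_param_names <- function() {
  c("matrix", "te", "tr", "etl", "epi_factor", "readout_duration",
    "excitation_angle", "refocussing_angle", "measurements", "prescans")
}

.resolve_param <- function(name) {
  key <- tolower(gsub("[-\\s]+", "_", trimws(name), perl = TRUE))
  key <- c(epifactor = "epi_factor", epi_factor = "epi_factor",
           number_of_rows = "matrix", rows = "matrix", matrix = "matrix")[key] %||%
    key
  if (key %in% .sequence_param_names()) key else NA_character_
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Derive per-stage seeds from a single global seed
#'
#' A fixed affine derivation so that pipeline stages (simulation noise, data
#' split, hyperparameter search, evolutionary search) are independently
#' reproducible from one user-facing seed.
#'
#' @param seed Integer global seed.
#' @param stage Stage name.
#' @return Integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage = c("noise", "split", "tune", "ea", "campaign")) {
  stage <- match.arg(stage)
  off <- c(noise = 101L, split = 211L, tune = 307L, ea = 401L, campaign = 503L)[[stage]]
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483587)
}

# circular (wrap-around) shift of a matrix along rows (PE axis) by d pixels
.circshift_rows <- function(m, d) {
  n <- nrow(m)
  d <- ((d %% n) + n) %% n
  if (d == 0) return(m)
  m[c((n - d + 1):n, 1:(n - d)), , drop = FALSE]
}

.is_count <- function(x) length(x) == 1 && is.finite(x) && x >= 1 && x == round(x)

.fmt_num <- function(x) {
  # integer-valued numbers without decimal point, others as-is
  if (is.finite(x) && x == round(x)) format(as.integer(round(x))) else format(x)
}
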