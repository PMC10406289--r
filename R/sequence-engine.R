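# Compilation of a sequence_spec into an executable encoding plan: an RF
# schedule, k-space line ordering with per-line echo times, and spoiling
# events, on one global timeline covering prescans and all measurements.
#
# Timing model (hard-pulse approximation): RF pulses are instantaneous
# rotations with a nominal 1 ms duration reserved in the timing checks; the
# dwell time is readout_duration / n_columns; the EPI/RARE echo spacing allows
# a 0.1 ms gradient ramp between lines.

.PULSE_MS <- 1.0
.RAMP_MS <- 0.1

.ro_ms <- function(spec) spec$readout_duration / 1000

.shots_per_meas <- function(spec) {
  if (spec$readout_type == "EPIReadout") spec$n_rows / spec$epi_factor
  else spec$n_rows / spec$etl
}

# 0-based index of the echo that acquires the k-space centre line, under
# interleaved line ordering (echo e of shot s acquires PE line e*shots + s)
.center_echo <- function(n_rows, shots) floor((n_rows / 2) / shots)

#' Validate physical plausibility of a sequence
#'
#' Checks, at minimum: TE < TR; TE at least the minimal TE implied by the
#' readout duration, echo spacing and nominal pulse durations; matrix
#' divisibility by the EPI factor / echo train length; refocussing presence
#' consistent with the echo type; all counts positive integers; and that the
#' echo train fits within one TR.  A report object is always returned.
#'
#' @param spec A complete [sequence_spec()] (see [expand_defaults()]).
#' @return List with `valid` (logical) and `violations` (list of
#'   `(code, message)`), `valid` iff no violations.
#' @export
validate_sequence <- function(spec) {
  stopifnot(inherits(spec, "sequence_spec"))
  if (!.spec_complete(spec))
    stop("spec incomplete; run expand_defaults() first", call. = FALSE)
  v <- list()
  bad <- function(code, msg) v[[length(v) + 1L]] <<- list(code = code, message = msg)

  for (f in c("n_rows", "n_columns", "epi_factor", "etl", "measurements")) {
    if (!.is_count(spec[[f]]))
      bad("COUNT_NOT_POSITIVE", paste0(f, " must be a positive integer"))
  }
  ps <- if (is.null(spec$prescans)) 0 else spec$prescans$count
  if (!(length(ps) == 1 && is.finite(ps) && ps >= 0 && ps == round(ps)))
    bad("COUNT_NOT_POSITIVE", "prescan count must be a non-negative integer")
  if (!(is.finite(spec$te) && spec$te > 0 && is.finite(spec$tr) && spec$tr > 0))
    bad("TIMING_NOT_POSITIVE", "TE and TR must be positive")
  if (length(v) > 0)
    return(list(valid = FALSE, violations = v))

  if (spec$te >= spec$tr) bad("TE_GE_TR", "TE must be smaller than TR")
  refoc <- .refoc_angle(spec)
  if (spec$echo_type == "SpinEcho" && refoc == 0)
    bad("REFOCUSSING_MISSING", "spin echo requires a refocussing pulse")
  if (spec$echo_type == "GradientEcho" && refoc != 0)
    bad("REFOCUSSING_PRESENT", "gradient echo cannot have a refocussing pulse")

  epi <- spec$readout_type == "EPIReadout"
  if (epi) {
    if (spec$epi_factor < 2)
      bad("EPI_FACTOR_TOO_SMALL", "EPI readout needs epi_factor >= 2")
    if (spec$n_rows %% spec$epi_factor != 0)
      bad("MATRIX_NOT_DIVISIBLE", "n_rows must be a multiple of the EPI factor")
    if (spec$etl != 1)
      bad("ETL_ON_EPI", "echo train length is 1 for EPI readouts")
  } else {
    if (spec$epi_factor != 1)
      bad("EPI_FACTOR_ON_LINE_READOUT", "line readout requires epi_factor = 1")
    if (spec$n_rows %% spec$etl != 0)
      bad("MATRIX_NOT_DIVISIBLE", "n_rows must be a multiple of the ETL")
  }
  if (length(v) > 0) return(list(valid = FALSE, violations = v))

  ro <- .ro_ms(spec)
  shots <- .shots_per_meas(spec)
  fam <- .family_of(spec$echo_type, spec$readout_type)
  if (fam %in% c("EPI", "SE-EPI")) {
    esp <- ro + .RAMP_MS
    ec <- .center_echo(spec$n_rows, shots)
    t_first <- spec$te - ec * esp
    t_last <- spec$te + (spec$epi_factor - 1 - ec) * esp
    floor_t <- if (fam == "SE-EPI") spec$te / 2 + .PULSE_MS / 2 else .PULSE_MS / 2
    if (fam == "SE-EPI" && spec$te / 2 < .PULSE_MS)
      bad("TE_TOO_SHORT", "TE/2 leaves no room for the refocussing pulse")
    if (t_first - ro / 2 < floor_t)
      bad("TE_TOO_SHORT", "TE below the minimal TE of the echo train")
    if (t_last + ro / 2 + .RAMP_MS > spec$tr)
      bad("TRAIN_EXCEEDS_TR", "EPI echo train does not fit within TR")
  } else if (fam == "RARE") {
    ec1 <- .center_echo(spec$n_rows, shots) + 1
    esp <- spec$te / ec1
    if (esp < .PULSE_MS + ro + 2 * .RAMP_MS)
      bad("TE_TOO_SHORT", "echo spacing too short for refocussing pulse and readout")
    if (spec$etl * esp + ro / 2 + .RAMP_MS > spec$tr)
      bad("TRAIN_EXCEEDS_TR", "RARE echo train does not fit within TR")
  } else { # bSSFP
    if (spec$te - ro / 2 < .PULSE_MS / 2)
      bad("TE_TOO_SHORT", "TE below the minimal TE of the readout")
    if (spec$te + ro / 2 + .PULSE_MS / 2 > spec$tr)
      bad("READOUT_EXCEEDS_TR", "readout does not fit within TR")
  }
  list(valid = length(v) == 0, violations = v)
}

#' Total acquisition time of a sequence
#'
#' `TR * shots_per_measurement * measurements + TR * prescans`, in ms.
#'
#' @param spec A complete, valid [sequence_spec()].
#' @return Acquisition time in ms.
#' @export
acquisition_time <- function(spec) {
  rep_ <- validate_sequence(spec)
  if (!rep_$valid)
    stop("invalid sequence: ", rep_$violations[[1]]$message, call. = FALSE)
  ps <- if (is.null(spec$prescans)) 0 else spec$prescans$count
  spec$tr * .shots_per_meas(spec) * spec$measurements + spec$tr * ps
}

#' Compile a sequence into an encoding plan
#'
#' Expands a valid sequence specification into the executable plan used by the
#' simulator: a global RF schedule (prescans, excitations, refocussing
#' pulses), the ordered k-space lines with per-line echo times and readout
#' polarity, and the spoiling events.
#'
#' Conventions: interleaved ascending phase-encoding order (echo `e` of shot
#' `s` acquires PE line `e * shots + s`, line 0 = most negative k); the centre
#' line (index `n_rows/2`, 0-based) is acquired at TE; EPI readouts alternate
#' polarity within the echo train; bSSFP alternates the excitation phase
#' 0/180 degrees (receiver phase follows) and prepends `prescans` RF pulses
#' with linearly ramped flip angles and no ADC.
#'
#' @param spec A complete [sequence_spec()].
#' @return Object of class `encoding_plan`: RF events (`time`, `flip`,
#'   `phase`, `kind`), k-space `lines` (`meas`, `shot`, `pe_index`,
#'   `polarity`, `t_echo`, `t_excite`, `rx_phase`), `spoil_times`, `dwell`
#'   (ms), `echo_spacing`, and the shot/measurement bookkeeping.
#' @export
compile_sequence <- function(spec) {
  rep_ <- validate_sequence(spec)
  if (!rep_$valid) {
    stop("cannot compile invalid sequence: ",
         paste(vapply(rep_$violations, function(x) x$code, character(1)),
               collapse = ", "), call. = FALSE)
  }
  fam <- .family_of(spec$echo_type, spec$readout_type)
  shots <- .shots_per_meas(spec)
  n_meas <- spec$measurements
  prescans <- if (is.null(spec$prescans)) 0L else as.integer(spec$prescans$count)
  ro <- .ro_ms(spec)
  dwell <- ro / spec$n_columns
  alt_phase <- fam == "bSSFP"
  spoil_shot <- any(vapply(spec$spoiling, function(s)
    s$location %in% c("after_echotrain", "after_segment"), logical(1)))

  rf <- list(); lines <- list(); spoil <- numeric()
  exc_count <- 0L

  # prescan ramp: flips approach the nominal angle, no ADC
  ang <- spec$excitation$angle
  for (p in seq_len(prescans)) {
    t0 <- (p - 1) * spec$tr
    ph <- if (alt_phase) 180 * (exc_count %% 2) else 0
    rf[[length(rf) + 1L]] <- list(time = t0, flip = ang * p / (prescans + 1),
                                  phase = ph, kind = "prescan")
    exc_count <- exc_count + 1L
  }

  if (fam %in% c("EPI", "SE-EPI")) {
    esp <- ro + .RAMP_MS
    ec <- .center_echo(spec$n_rows, shots)
  } else if (fam == "RARE") {
    esp <- spec$te / (.center_echo(spec$n_rows, shots) + 1)
  } else {
    esp <- spec$tr
  }
  echoes_per_shot <- if (fam %in% c("EPI", "SE-EPI")) spec$epi_factor
                     else if (fam == "RARE") spec$etl else 1L

  for (m in seq_len(n_meas) - 1L) {
    for (s in seq_len(shots) - 1L) {
      t0 <- (prescans + m * shots + s) * spec$tr
      ph <- if (alt_phase) 180 * (exc_count %% 2) else 0
      rf[[length(rf) + 1L]] <- list(time = t0, flip = ang, phase = ph,
                                    kind = "excitation")
      exc_count <- exc_count + 1L
      if (fam %in% c("SE-EPI", "RARE")) {
        rtimes <- if (fam == "SE-EPI") spec$te / 2
                  else (seq_len(spec$etl) - 0.5) * esp
        for (rt in rtimes) {
          rf[[length(rf) + 1L]] <- list(time = t0 + rt,
                                        flip = spec$refocussing$angle,
                                        phase = 90, kind = "refocussing")
        }
      }
      for (e in seq_len(echoes_per_shot) - 1L) {
        t_echo <- t0 + switch(fam,
          "bSSFP" = spec$te,
          "RARE" = (e + 1) * esp,
          spec$te + (e - .center_echo(spec$n_rows, shots)) * esp)
        pe <- if (fam == "bSSFP") s else e * shots + s
        pol <- if (fam %in% c("EPI", "SE-EPI") && e %% 2 == 1) -1L else 1L
        lines[[length(lines) + 1L]] <- list(
          meas = m, shot = s, pe_index = pe, polarity = pol,
          t_echo = t_echo, t_excite = t0, rx_phase = ph)
      }
      if (spoil_shot) {
        t_end <- max(vapply(lines[seq(length(lines) - echoes_per_shot + 1L,
                                      length(lines))],
                            function(l) l$t_echo, numeric(1))) + ro / 2 + 0.01
        spoil <- c(spoil, t_end)
      }
    }
  }

  structure(list(
    spec = spec, family = fam,
    n_rows = spec$n_rows, n_columns = spec$n_columns,
    dwell = dwell, echo_spacing = esp,
    shots_per_meas = shots, n_measurements = n_meas, prescans = prescans,
    rf_events = do.call(rbind, lapply(rf, as.data.frame)),
    lines = do.call(rbind, lapply(lines, as.data.frame)),
    spoil_times = spoil,
    total_time = acquisition_time(spec)
  ), class = "encoding_plan")
}

#' @export
print.encoding_plan <- function(x, ...) {
  cat("<encoding_plan>", x$family, sprintf("%dx%d", x$n_rows, x$n_columns),
      "|", x$shots_per_meas, "shot(s) x", x$n_measurements, "measurement(s),",
      x$prescans, "prescan(s),", x$total_time, "ms\n")
  invisible(x)
}

#' Serialize an encoding plan to JSON
#'
#' For inspection and debugging; numbers are written unrounded.
#'
#' @param plan An [compile_sequence()] result.
#' @param path Output file path.
#' @export
write_plan_json <- function(plan, path) {
  out <- plan[c("family", "n_rows", "n_columns", "dwell", "echo_spacing",
                "shots_per_meas", "n_measurements", "prescans", "spoil_times",
                "total_time")]
  out$rf_events <- plan$rf_events
  out$lines <- plan$lines
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
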