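# Tissue-level isochromat simulator.
#
# One magnetization vector is tracked per tissue (all spins of a tissue share
# T1/T2/off-resonance, so their magnetization histories coincide); spatial
# encoding is applied analytically as the Fourier phase exp(-i 2 pi k.r) summed
# over the spin positions of each tissue.  For spins on the regular phantom
# sub-grid this sum is a separable matrix product, so each simulation costs a
# few small complex matrix multiplications plus the per-event Bloch updates.
# Rigid translational motion enters as a per-shot linear phase on the
# phase-encoding k coordinate.

# 3x3 rotation for an RF pulse of given flip and phase (degrees):
# Rz(phase) . Rx(flip) . Rz(-phase)
.rf_rotation <- function(flip_deg, phase_deg) {
  a <- flip_deg * pi / 180
  p <- phase_deg * pi / 180
  Rx <- matrix(c(1, 0, 0,
                 0, cos(a), -sin(a),
                 0, sin(a), cos(a)), 3, 3, byrow = TRUE)
  Rz <- function(t) matrix(c(cos(t), -sin(t), 0,
                             sin(t), cos(t), 0,
                             0, 0, 1), 3, 3, byrow = TRUE)
  Rz(p) %*% Rx %*% Rz(-p)
}

# free evolution of (mxy complex, mz) over dt ms with off-resonance df Hz
.relax <- function(mxy, mz, m0, dt, t1, t2, df) {
  if (dt <= 0) return(list(mxy = mxy, mz = mz))
  list(mxy = mxy * exp(-dt / t2) * exp(2i * pi * df * dt / 1000),
       mz = m0 + (mz - m0) * exp(-dt / t1))
}

# acquisition-order sample index of the echo (k = 0) within a line
.echo_sample <- function(n_columns, polarity) {
  if (polarity > 0) n_columns / 2 else n_columns / 2 - 1
}

#' Simulate k-space data for a compiled sequence on a phantom
#'
#' Evolves the magnetization of every tissue through the full RF / relaxation
#' schedule (prescans and all measurements, so steady-state effects are
#' included), samples the transverse magnetization at every ADC time, and
#' applies the spatial encoding analytically.  Spoiling events zero the
#' transverse magnetization.  The k-space of the last measurement is returned.
#'
#' @param plan An [compile_sequence()] encoding plan.
#' @param phantom A [make_square_phantom()] / [make_circular_phantom()] phantom
#'   (FOV must match the intended imaging FOV; k-space is sampled at
#'   `1/FOV` spacing).
#' @param off_resonance Apply the phantom's tissue off-resonance (logical).
#' @param motion Apply the phantom's motion trajectory (logical); spin
#'   positions are frozen within each shot and displaced at each excitation.
#' @return Object of class `kspace`: complex `data` (n_rows x n_columns, rows
#'   indexed by PE line, samples in acquisition order), `polarity` per row,
#'   `dwell` (ms), `pe_fov`/`ro_fov` (mm), `measurement_index`.
#' @export
simulate_kspace <- function(plan, phantom, off_resonance = TRUE, motion = TRUE) {
  stopifnot(inherits(plan, "encoding_plan"), inherits(phantom, "digital_phantom"))
  fov <- phantom$fov
  n_pe <- plan$n_rows; n_ro <- plan$n_columns
  kpe <- (seq_len(n_pe) - 1 - n_pe / 2) / fov[1]
  kro <- (seq_len(n_ro) - 1 - n_ro / 2) / fov[2]

  tnames <- names(phantom$tissues)
  # per-tissue spatial spectra F[[t]][pe, k]
  Ey <- exp(-2i * pi * outer(kpe, phantom$spin_y))
  Ex <- exp(-2i * pi * outer(phantom$spin_x, kro))
  Fsp <- lapply(tnames, function(nm) {
    M <- (phantom$label_grid == nm) * 1
    Ey %*% M %*% Ex
  })
  names(Fsp) <- tnames

  # merged event timeline: RF, spoiling, readout lines (keyed by start time)
  lines <- plan$lines
  j_rel <- lapply(seq_len(nrow(lines)), function(i) {
    pol <- lines$polarity[i]
    (seq_len(n_ro) - 1) - .echo_sample(n_ro, pol)
  })
  line_t0 <- lines$t_echo + vapply(j_rel, min, numeric(1)) * plan$dwell
  ev <- rbind(
    data.frame(time = plan$rf_events$time, type = "rf",
               idx = seq_len(nrow(plan$rf_events))),
    if (length(plan$spoil_times))
      data.frame(time = plan$spoil_times, type = "spoil", idx = 0L),
    data.frame(time = line_t0, type = "line", idx = seq_len(nrow(lines)))
  )
  ev <- ev[order(ev$time, ev$type != "rf"), ]

  traj <- if (motion) phantom$motion else NULL
  has_motion <- !is.null(traj) && traj$pattern != "none"
  data <- matrix(0i, n_pe, n_ro)
  polarity_by_row <- rep(1L, n_pe)
  last_meas <- plan$n_measurements - 1L

  rfmats <- lapply(seq_len(nrow(plan$rf_events)), function(i)
    .rf_rotation(plan$rf_events$flip[i], plan$rf_events$phase[i]))

  for (nm in tnames) {
    ts <- phantom$tissues[[nm]]
    df <- if (off_resonance) ts$delta_f else 0
    m0 <- ts$pd
    mxy <- 0i; mz <- m0; t_cur <- 0
    for (r in seq_len(nrow(ev))) {
      te_v <- ev$time[r]
      if (ev$type[r] == "rf") {
        st <- .relax(mxy, mz, m0, te_v - t_cur, ts$t1, ts$t2, df)
        v <- rfmats[[ev$idx[r]]] %*% c(Re(st$mxy), Im(st$mxy), st$mz)
        mxy <- complex(real = v[1], imaginary = v[2]); mz <- v[3]
        t_cur <- te_v
      } else if (ev$type[r] == "spoil") {
        st <- .relax(mxy, mz, m0, te_v - t_cur, ts$t1, ts$t2, df)
        mxy <- 0i; mz <- st$mz; t_cur <- te_v
      } else {
        i <- ev$idx[r]
        if (lines$meas[i] != last_meas) next
        tsamp <- lines$t_echo[i] + j_rel[[i]] * plan$dwell
        dtv <- tsamp - t_cur
        vals <- mxy * exp(-dtv / ts$t2) * exp(2i * pi * df * dtv / 1000)
        pe <- lines$pe_index[i]
        pol <- lines$polarity[i]
        kcols <- if (pol > 0) seq_len(n_ro) else rev(seq_len(n_ro))
        contrib <- vals * Fsp[[nm]][pe + 1L, kcols]
        if (has_motion) {
          d <- displacement(traj, lines$t_excite[i] / 1000)
          contrib <- contrib * exp(-2i * pi * kpe[pe + 1L] * d)
        }
        if (lines$rx_phase[i] != 0)
          contrib <- contrib * exp(-1i * pi * lines$rx_phase[i] / 180)
        data[pe + 1L, ] <- data[pe + 1L, ] + contrib
        polarity_by_row[pe + 1L] <- pol
      }
    }
  }

  structure(list(data = data, polarity = polarity_by_row,
                 dwell = plan$dwell, pe_fov = fov[1], ro_fov = fov[2],
                 measurement_index = last_meas),
            class = "kspace")
}

#' Add complex Gaussian noise to k-space
#'
#' Independent real and imaginary Gaussian noise of standard deviation `sigma`
#' is added to every sample; deterministic under a fixed seed (the global RNG
#' state is preserved).
#'
#' @param k A `kspace` object.
#' @param sigma Noise standard deviation per channel (`>= 0`).
#' @param seed Integer seed.
#' @return The noisy `kspace`.
#' @export
add_noise <- function(k, sigma, seed = 1234L) {
  stopifnot(inherits(k, "kspace"))
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  if (sigma == 0) return(k)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  n <- length(k$data)
  k$data <- k$data + complex(real = stats::rnorm(n, 0, sigma),
                             imaginary = stats::rnorm(n, 0, sigma))
  k
}

#' Per-channel k-space noise level for a relative image-domain target
#'
#' Returns the complex k-space noise standard deviation such that the
#' image-domain per-channel noise std equals `frac` times the maximum of the
#' noiseless reconstructed magnitude image.
#'
#' @param k Noiseless `kspace`.
#' @param frac Relative noise level (default 0.02).
#' @return Noise std for [add_noise()].
#' @export
noise_sigma_for <- function(k, frac = 0.02) {
  img <- reconstruct_image(k)
  frac * max(img$pixels) * sqrt(length(k$data))
}

# centred zero-padded inverse 2D DFT; input rows/cols are k indices
# -n/2 .. n/2-1 (index 1 = most negative); output pixel p sits at
# -fov/2 + p * (fov/P).  Scaling: 1 / (number of original samples).
.ifft2_centered <- function(K, P1, P2) {
  n1 <- nrow(K); n2 <- ncol(K)
  m1 <- (seq_len(n1) - 1 - n1 / 2)
  m2 <- (seq_len(n2) - 1 - n2 / 2)
  Kp <- K * outer((-1)^m1, (-1)^m2)   # e^{-i pi m} factors for centred pixels
  Z <- matrix(0i, P1, P2)
  r <- ((m1 %% P1) + P1) %% P1 + 1
  cl <- ((m2 %% P2) + P2) %% P2 + 1
  Z[r, cl] <- Kp
  img <- stats::fft(Z, inverse = TRUE) / (n1 * n2)
  img
}

#' Reconstruct a magnitude image from k-space
#'
#' Reverses the sample order of negative-polarity EPI lines, zero-pads the
#' k-space matrix to the field of view at the target pixel size (default
#' 1 x 1 mm) and applies the inverse 2D Fourier transform; the magnitude of
#' the complex image is returned.
#'
#' @param k A `kspace` object.
#' @param pixel_mm Target pixel size in mm.
#' @return Object of class `recon_image` with non-negative `pixels`
#'   (`pe_fov/pixel_mm` rows), the `complex` image, and `pixel_size`.
#' @export
reconstruct_image <- function(k, pixel_mm = 1) {
  stopifnot(inherits(k, "kspace"))
  d <- k$data
  for (r in which(k$polarity < 0)) d[r, ] <- rev(d[r, ])
  P1 <- round(k$pe_fov / pixel_mm)
  P2 <- round(k$ro_fov / pixel_mm)
  if (P1 < nrow(d) || P2 < ncol(d))
    stop("target pixel grid smaller than the acquired matrix", call. = FALSE)
  cimg <- .ifft2_centered(d, P1, P2)
  structure(list(pixels = Mod(cimg), complex = cimg, pixel_size = pixel_mm),
            class = "recon_image")
}

#' Export an image or mask as PNG for visual inspection
#'
#' Magnitude images are normalized to their maximum; logical masks are written
#' as black/white.
#'
#' @param img A `recon_image`, numeric matrix, or logical mask.
#' @param path Output PNG path.
#' @export
write_image_png <- function(img, path) {
  p <- if (inherits(img, "recon_image")) img$pixels else img
  p <- if (is.logical(p)) p * 1 else p / max(p, .Machine$double.eps)
  png::writePNG(pmin(pmax(p, 0), 1), path)
  invisible(path)
}

#' @export
print.kspace <- function(x, ...) {
  cat("<kspace>", nrow(x$data), "x", ncol(x$data), "samples, dwell",
      signif(x$dwell, 3), "ms\n")
  invisible(x)
}

#' @export
print.recon_image <- function(x, ...) {
  cat("<recon_image>", nrow(x$pixels), "x", ncol(x$pixels), "pixels of",
      x$pixel_size, "mm\n")
  invisible(x)
}
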