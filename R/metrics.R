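# The twelve acquisition metrics, computed from reconstructed magnitude images
# and the phantom evaluation masks (all images and masks on the interpolated
# 1 x 1 mm grid).

.as_pixels <- function(img) if (inherits(img, "recon_image")) img$pixels else img

#' Tissue contrast ratio
#'
#' Mean signal intensity over `mask_a` divided by the mean over `mask_b`.
#'
#' @param img Reconstructed image (a `recon_image` or numeric matrix).
#' @param mask_a,mask_b Non-empty logical masks.
#' @return Dimensionless ratio.
#' @export
img_contrast <- function(img, mask_a, mask_b) {
  p <- .as_pixels(img)
  if (!any(mask_a) || !any(mask_b)) stop("empty contrast mask", call. = FALSE)
  den <- mean(p[mask_b])
  if (den <= 0) stop("undefined contrast: zero mean in denominator mask",
                     call. = FALSE)
  mean(p[mask_a]) / den
}

#' Tissue SNR (single-image background method)
#'
#' `mean(img[tissue]) / (sd(img[background]) / 0.655)`: the background standard
#' deviation of a magnitude image underestimates the Gaussian channel noise by
#' the Rayleigh factor 0.655, so the corrected ratio estimates signal over
#' per-channel noise std.  Degenerate noiseless backgrounds return `cap`.
#'
#' @param img Noisy magnitude image.
#' @param tissue_mask,background_mask Non-empty logical masks.
#' @param cap Value returned when the background is (numerically) noise-free.
#' @return SNR estimate.
#' @export
img_snr <- function(img, tissue_mask, background_mask, cap = 1e6) {
  p <- .as_pixels(img)
  if (!any(background_mask)) stop("empty background mask", call. = FALSE)
  s <- stats::sd(p[background_mask])
  m <- mean(p[tissue_mask])
  if (!is.finite(s) || s <= m * 1e-9) return(cap)
  min(m / (s / 0.655), cap)
}

#' Ghosting level
#'
#' Mean intensity over the ghost regions divided by the mean over the object
#' regions; 0 for a ghost-free image, and monotone in the injected ghost
#' amplitude.  (The inverse orientation, object/ghost, can be requested for
#' compatibility with the "target over ghost" reading of the definition.)
#'
#' @param img Magnitude image.
#' @param object_mask,ghost_mask Disjoint non-empty logical masks.
#' @param orientation `"ghost_over_object"` (default, small is good) or
#'   `"object_over_ghost"`.
#' @return Ghosting level.
#' @export
ghost_level <- function(img, object_mask, ghost_mask,
                        orientation = c("ghost_over_object", "object_over_ghost")) {
  orientation <- match.arg(orientation)
  p <- .as_pixels(img)
  if (!any(object_mask) || !any(ghost_mask)) stop("empty mask", call. = FALSE)
  if (any(object_mask & ghost_mask))
    stop("object and ghost masks must be disjoint", call. = FALSE)
  g <- mean(p[ghost_mask]); o <- mean(p[object_mask])
  if (orientation == "ghost_over_object") g / o else o / max(g, .Machine$double.eps)
}

.masked_pcc <- function(a, b, mask) {
  x <- a[mask]; y <- b[mask]
  if (length(x) < 2) stop("mask must contain at least 2 pixels", call. = FALSE)
  if (stats::sd(y) == 0)
    stop("reference is constant over the mask; correlation undefined",
         call. = FALSE)
  if (stats::sd(x) == 0) return(0)
  stats::cor(x, y)
}

#' Image sharpness
#'
#' Pearson correlation between the reconstructed image and the simulated
#' target structure, restricted to the structure mask.  1 for a perfect
#' (affinely scaled) reconstruction; blurring lowers it.
#'
#' @param img Magnitude image.
#' @param structure_mask Logical mask over the structure area (>= 2 pixels).
#' @param reference Ground-truth image (phantom `$reference`).
#' @return Correlation in `[-1, 1]`.
#' @export
img_sharpness <- function(img, structure_mask, reference) {
  .masked_pcc(.as_pixels(img), .as_pixels(reference), structure_mask)
}

#' Signal homogeneity
#'
#' Same Pearson-correlation measure as [img_sharpness()], evaluated over a
#' window covering the filled CSF area including its boundary (the boundary
#' keeps the reference non-constant).  Ripple or shading inside the filled
#' area lowers the value below 1.
#'
#' @inheritParams img_sharpness
#' @param window_mask Logical window over the filled area and boundary.
#' @export
img_homogeneity <- function(img, window_mask, reference) {
  .masked_pcc(.as_pixels(img), .as_pixels(reference), window_mask)
}

# PCC of `moving` circularly shifted by each PE offset vs `reference`
.shift_pcc_scan <- function(moving, reference, mask, n_pe = NULL) {
  mv <- .as_pixels(moving); rf <- .as_pixels(reference)
  if (!any(mask)) stop("empty evaluation mask", call. = FALSE)
  n <- n_pe %||% nrow(mv)
  vapply(seq_len(n) - 1L, function(d)
    .masked_pcc(.circshift_rows(mv, -d), rf, mask), numeric(1))
}

#' Motion sensitivity
#'
#' Applies a series of integer circular shifts along the phase-encoding
#' direction to the motion-corrupted image, computes the Pearson correlation
#' with the reference inside the evaluation area for each shift, and returns
#' one minus the maximum correlation.  A pure (rigid) shift of the object
#' therefore scores 0; blurring or ghosting from intra-scan motion scores > 0.
#'
#' @param motion_img Reconstruction of the motion-corrupted simulation.
#' @param reference_img Reconstruction of the motion-free simulation.
#' @param area_mask Evaluation-area mask (1-mm grid).
#' @param n_pe Number of shifts scanned (defaults to the PE matrix size).
#' @return Value in `[0, 2]`.
#' @export
motion_sensitivity <- function(motion_img, reference_img, area_mask, n_pe = NULL) {
  1 - max(.shift_pcc_scan(motion_img, reference_img, area_mask, n_pe))
}

#' Distortion sensitivity
#'
#' Scans the same shift series as [motion_sensitivity()] but returns the
#' location of the correlation maximum — the apparent displacement of the
#' object — as a fraction of the interpolated matrix size in the
#' phase-encoding direction.  Ties are broken toward the smaller circular
#' distance.
#'
#' @param offres_img Reconstruction of the off-resonance simulation.
#' @inheritParams motion_sensitivity
#' @return Fraction in `[0, 1)`.
#' @export
distortion_sensitivity <- function(offres_img, reference_img, area_mask,
                                   n_pe = NULL) {
  pcc <- .shift_pcc_scan(offres_img, reference_img, area_mask, n_pe)
  n <- length(pcc)
  d <- seq_len(n) - 1L
  dist <- pmin(d, n - d)                      # circular distance
  best <- which(pcc >= max(pcc) - 1e-12)
  dist[best[which.min(dist[best])]] / n
}

#' Compute all twelve acquisition metrics for one sequence
#'
#' Combines the four simulations of the data-generation workflow: the square
#' phantom provides contrasts, SNR (from the noisy reconstruction), ghosting,
#' sharpness and homogeneity; motion sensitivity compares the
#' motion-corrupted and plain circular reconstructions; distortion sensitivity
#' compares the off-resonance and plain circular reconstructions; acquisition
#' time comes from the sequence timing.
#'
#' @param spec A complete, valid [sequence_spec()].
#' @param square,circular The two phantoms.
#' @param images List with reconstructions `square` (noiseless),
#'   `square_noisy`, `circ_plain`, `circ_offres`, `circ_motion`.
#' @return Named numeric vector over [metric_names()].
#' @export
compute_metrics <- function(spec, square, circular, images) {
  need <- c("square", "square_noisy", "circ_plain", "circ_offres", "circ_motion")
  miss <- setdiff(need, names(images))
  if (length(miss)) stop("missing simulation(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  sq <- images$square
  sqn <- images$square_noisy
  m <- square$masks
  res <- c(
    cgc = img_contrast(sq, m$csf, m$gm),
    gwc = img_contrast(sq, m$gm, m$wm),
    cwc = img_contrast(sq, m$csf, m$wm),
    snr_csf = img_snr(sqn, m$csf, m$background),
    snr_gm = img_snr(sqn, m$gm, m$background),
    snr_wm = img_snr(sqn, m$wm, m$background),
    ghost = ghost_level(sq, m$object, m$ghost),
    sharpness = img_sharpness(sq, m$structure, square$reference),
    homogeneity = img_homogeneity(sq, m$homogeneity, square$reference),
    motion_sens = motion_sensitivity(images$circ_motion, images$circ_plain,
                                     circular$masks$evaluation),
    distortion_sens = distortion_sensitivity(images$circ_offres,
                                             images$circ_plain,
                                             circular$masks$evaluation),
    acq_time = acquisition_time(spec)
  )
  res[metric_names()]
}
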