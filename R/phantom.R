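#' Default brain-tissue parameters at 3 T
#'
#' T1/T2 relaxation times (ms), relative proton density and off-resonance (Hz)
#' for cerebrospinal fluid, grey matter and white matter, typical literature
#' values for 3 T brain imaging.  All values are config-overridable.
#'
#' @return Named list of tissue parameter lists `(t1, t2, pd, delta_f)`.
#' @export
tissue_defaults <- function() {
  list(
    CSF = list(t1 = 4000, t2 = 2000, pd = 1.00, delta_f = 0),
    GM  = list(t1 = 1350, t2 = 110,  pd = 0.80, delta_f = 0),
    WM  = list(t1 = 850,  t2 = 80,   pd = 0.65, delta_f = 0)
  )
}

.check_tissue <- function(t, label) {
  if (!(t$t1 > t$t2 && t$t2 > 0))
    stop("tissue '", label, "': need t1 > t2 > 0", call. = FALSE)
  if (t$pd <= 0) stop("tissue '", label, "': proton density must be > 0",
                      call. = FALSE)
  invisible(t)
}

# Pixel-center coordinate along one axis of the 1-mm metric grid:
# pixel p (0-based) sits at -fov/2 + p mm, matching the reconstruction grid.
.pixel_coords <- function(fov) seq(0, fov - 1) - fov / 2

# logical mask on the 1-mm grid from a half-open rectangle [y0,y1) x [x0,x1)
.rect_mask <- function(fov, y0, y1, x0, x1) {
  y <- .pixel_coords(fov[1]); x <- .pixel_coords(fov[2])
  outer(y >= y0 & y < y1, x >= x0 & x < x1, "&")
}

.phantom_base <- function(fov, spin_density, motion = NULL) {
  # spin grid: regular sub-grid with exactly fov_x * fov_y * density spins
  nx <- ny <- NULL
  if (abs(spin_density - 4) < 1e-9) {
    dx <- dy <- 0.5
  } else if (abs(spin_density - 2) < 1e-9) {
    dx <- 0.5; dy <- 1.0
  } else {
    # generic: square sub-grid if the density is a perfect square of 1/d
    d <- 1 / sqrt(spin_density)
    dx <- dy <- d
  }
  nx <- round(fov[2] / dx); ny <- round(fov[1] / dy)
  list(fov = fov, spin_density = spin_density,
       spin_x = (seq_len(nx) - 0.5) * dx - fov[2] / 2,
       spin_y = (seq_len(ny) - 0.5) * dy - fov[1] / 2,
       motion = motion %||% list(pattern = "none", amplitude = 0, period = 1,
                                 direction = "pe"))
}

#' Square training phantom
#'
#' A 100 x 100 mm digital phantom (4 simulated spins/mm^2) containing three
#' 20 x 20 mm tissue squares (CSF, GM, WM) in the upper band, a striped CSF
#' structure section (for the sharpness metric) and a filled CSF block (for the
#' homogeneity metric) in the lower band.  The object is kept within a 48 mm
#' phase-encoding extent so that its N/2-ghost replica never overlaps the
#' object.  Evaluation masks are provided on the 1 x 1 mm image grid: interior
#' tissue masks, the structure mask, the homogeneity window, the object/ghost
#' region pair, and a background (noise) mask.
#'
#' @param cfg Optional list overriding `fov` (mm, length 2), `spin_density`
#'   (spins/mm^2), `tissues` (see [tissue_defaults()]), `stripe_mm` (structure
#'   stripe width).
#' @return Object of class `digital_phantom` with the label grid at spin
#'   resolution, tissue parameters, masks, a ground-truth `reference` image
#'   (proton density on the 1-mm grid) and a motion trajectory (none).
#' @export
make_square_phantom <- function(cfg = list()) {
  fov <- cfg$fov %||% c(100, 100)
  dens <- cfg$spin_density %||% 4
  if (any(fov <= 0) || dens <= 0)
    stop("FOV and spin density must be positive", call. = FALSE)
  tissues <- cfg$tissues %||% tissue_defaults()
  for (nm in names(tissues)) .check_tissue(tissues[[nm]], nm)
  stripe <- cfg$stripe_mm %||% 4

  base <- .phantom_base(fov, dens)
  sy <- base$spin_y; sx <- base$spin_x
  lab <- matrix("background", length(sy), length(sx))

  # geometry scaled with FOV so reduced phantoms keep their proportions
  sc <- fov / 100
  reg <- function(y0, y1, x0, x1) {
    outer(sy >= y0 * sc[1] & sy < y1 * sc[1],
          sx >= x0 * sc[2] & sx < x1 * sc[2], "&")
  }
  # upper band: three tissue squares
  lab[reg(-22, -2, -40, -20)] <- "CSF"
  lab[reg(-22, -2, -10, 10)]  <- "GM"
  lab[reg(-22, -2, 20, 40)]   <- "WM"
  # lower band: striped CSF structure (sharpness target) ...
  str_y <- c(6, 22) * sc[1]; str_x <- c(-40, 0) * sc[2]
  in_str <- outer(sy >= str_y[1] & sy < str_y[2],
                  sx >= str_x[1] & sx < str_x[2], "&")
  stripe_on <- outer(rep(TRUE, length(sy)),
                     ((sx - str_x[1]) %/% (stripe * sc[2])) %% 2 == 0, "&")
  lab[in_str & stripe_on] <- "CSF"
  # ... and a filled CSF block (homogeneity target)
  lab[reg(6, 22, 10, 40)] <- "CSF"

  # masks on the 1-mm image grid; tissue masks eroded 2 mm inside the squares
  msk <- function(y0, y1, x0, x1) {
    .rect_mask(fov, y0 * sc[1], y1 * sc[1], x0 * sc[2], x1 * sc[2])
  }
  er <- 2
  masks <- list(
    csf = msk(-22 + er, -2 - er, -40 + er, -20 - er),
    gm  = msk(-22 + er, -2 - er, -10 + er, 10 - er),
    wm  = msk(-22 + er, -2 - er, 20 + er, 40 - er),
    structure = msk(6, 22, -40, 0),
    homogeneity = msk(6 - 1, 22 + 1, 10 - 1, 40 + 1)
  )
  # object support and its N/2-ghost replica (circular shift by half the PE fov)
  object <- msk(-22, 22, -40, 40)
  ghost <- .circshift_rows(object, as.integer(round(fov[1] / 2)))
  ghost <- ghost & !object
  masks$object <- object
  masks$ghost <- ghost
  # noise-only background: readout-edge bands untouched by object and ghosts
  bgx <- .pixel_coords(fov[2])
  masks$background <- outer(rep(TRUE, fov[1]), abs(bgx) > 43 * sc[2], "&")
  masks$background <- masks$background & !object & !ghost

  structure(c(base, list(
    label_grid = lab, tissues = tissues, masks = masks,
    reference = .reference_image(lab, tissues, base, fov)
  )), class = "digital_phantom")
}

#' Circular motion/distortion phantom
#'
#' A small circular structure (default radius 15 mm, grey-matter parameters)
#' inside a 100 x 100 mm area at 2 simulated spins/mm^2, used to assess motion
#' and distortion sensitivity.  A uniform non-zero off-resonance (default
#' 50 Hz) can be enabled, as can a repeating linear translational motion
#' pattern along the phase-encoding direction.  The evaluation-area mask is a
#' central window covering the structure and its plausible shifted positions.
#'
#' @param cfg Optional list overriding `fov`, `spin_density`, `radius` (mm),
#'   `tissue` (parameter list), `off_resonance` (Hz, used when
#'   `off_resonance_on`), `off_resonance_on` (logical), `motion_on` (logical),
#'   `motion` (list `amplitude` mm, `period` s, `pattern`).
#' @return A `digital_phantom`.
#' @export
make_circular_phantom <- function(cfg = list()) {
  fov <- cfg$fov %||% c(100, 100)
  dens <- cfg$spin_density %||% 2
  if (any(fov <= 0) || dens <= 0)
    stop("FOV and spin density must be positive", call. = FALSE)
  radius <- cfg$radius %||% 15 * min(fov / 100)
  # exact [[ lookups: several config names share prefixes ($ would partial-match)
  tissue <- cfg[["tissue", exact = TRUE]] %||% tissue_defaults()$GM
  off_on <- cfg[["off_resonance_on", exact = TRUE]] %||% FALSE
  tissue$delta_f <- if (off_on)
    (cfg[["off_resonance", exact = TRUE]] %||% 50) else 0
  .check_tissue(tissue, "structure")

  motion_on <- cfg[["motion_on", exact = TRUE]] %||% FALSE
  motion <- if (motion_on) {
    m <- cfg[["motion", exact = TRUE]] %||% list()
    list(pattern = m$pattern %||% "linear_repeating",
         amplitude = m$amplitude %||% 5,
         period = m$period %||% 1,   # seconds; campaign sets one measurement
         direction = "pe")
  } else NULL

  base <- .phantom_base(fov, dens, motion)
  sy <- base$spin_y; sx <- base$spin_x
  lab <- matrix("background", length(sy), length(sx))
  lab[outer(sy^2, sx^2, `+`) <= radius^2] <- "structure"

  y <- .pixel_coords(fov[1]); x <- .pixel_coords(fov[2])
  win <- 0.35 * fov
  masks <- list(
    evaluation = outer(abs(y) <= win[1], abs(x) <= win[2], "&"),
    object = outer(y^2, x^2, `+`) <= radius^2
  )
  structure(c(base, list(
    label_grid = lab, tissues = list(structure = tissue), masks = masks,
    reference = .reference_image(lab, list(structure = tissue), base, fov)
  )), class = "digital_phantom")
}

# ground-truth proton-density image on the 1-mm grid (spin-count weighted)
.reference_image <- function(lab, tissues, base, fov) {
  ref <- matrix(0, fov[1], fov[2])
  py <- pmin(pmax(floor(base$spin_y + fov[1] / 2) + 1L, 1L), fov[1])
  px <- pmin(pmax(floor(base$spin_x + fov[2] / 2) + 1L, 1L), fov[2])
  for (nm in names(tissues)) {
    sel <- which(lab == nm, arr.ind = TRUE)
    if (nrow(sel) == 0) next
    lin <- (px[sel[, 2]] - 1L) * fov[1] + py[sel[, 1]]
    ref <- ref + tissues[[nm]]$pd *
      matrix(tabulate(lin, nbins = fov[1] * fov[2]), fov[1], fov[2])
  }
  ref
}

#' Number of simulated spins in a phantom
#'
#' Always exactly `fov_x * fov_y * spin_density` for the shipped geometries.
#'
#' @param phantom A `digital_phantom`.
#' @return Integer spin count.
#' @export
spin_count <- function(phantom) {
  length(phantom$spin_x) * length(phantom$spin_y)
}

#' Motion displacement at time t
#'
#' Deterministic translational displacement along the phase-encoding axis.
#' `linear_repeating` is a sawtooth ramp from 0 to the amplitude, repeating
#' every period (so `displacement(period) == 0`); `none` is identically zero.
#'
#' @param traj Motion trajectory list `(pattern, amplitude, period)`,
#'   amplitude in mm, period in seconds.
#' @param t Time in seconds (scalar or vector), `t >= 0`.
#' @return Displacement in mm.
#' @export
displacement <- function(traj, t) {
  stopifnot(all(t >= 0))
  if (is.null(traj) || traj$pattern == "none") return(rep(0, length(t)))
  if (traj$pattern != "linear_repeating")
    stop("unknown motion pattern: ", traj$pattern, call. = FALSE)
  frac <- (t / traj$period) %% 1
  traj$amplitude * frac
}

#' @export
print.digital_phantom <- function(x, ...) {
  cat("<digital_phantom>", paste(x$fov, collapse = " x "), "mm,",
      spin_count(x), "spins,", length(x$tissues), "tissue type(s)\n")
  invisible(x)
}
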