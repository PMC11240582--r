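## Synthetic dissected-aorta phantom.
##
## Each axial slice is a filled disc (the whole aorta: TL + flap + FL, no
## separate wall) whose centre may drift sinusoidally along z. A straight
## chord band of configurable thickness, offset and orientation models the
## intimal flap and splits the lumen into two circular segments; the larger
## side is labelled false lumen, the smaller true lumen. The band is left
## as background in the "annotation-style" volume (the flap is not labelled
## at annotation time and must be rediscovered by flap extraction); a
## companion "full-truth" volume labels it 3. All morphometry implied by
## the geometry is available in closed form.

#' Specify a dissection phantom
#'
#' @param n_slices number of axial slices.
#' @param grid_shape in-plane grid size, (rows, cols).
#' @param spacing voxel size in mm, (z, y, x). Default is the reference
#'   CT resampling grid 1.25 x 0.8242 x 0.8242 mm.
#' @param outer_diameter aortic lumen diameter in mm (TL + flap + FL).
#' @param flap_thickness thickness of the intimal-flap chord band, mm.
#' @param flap_offset signed perpendicular displacement of the flap chord
#'   from the lumen centre, mm; 0 puts the flap on a diameter.
#' @param flap_angle in-plane orientation of the chord normal, radians.
#' @param centerline_amplitude amplitude of the sinusoidal in-plane drift
#'   of the tube centre along z, mm; 0 gives a straight tube.
#' @param seed integer seed recorded with the parameters (phantom geometry is
#'   deterministic; the seed pairs the phantom with downstream stochastic
#'   degradation).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_slices = 40L,
                         grid_shape = c(96L, 96L),
                         spacing = c(1.25, 0.8242, 0.8242),
                         outer_diameter = 50,
                         flap_thickness = 2.4,
                         flap_offset = 6,
                         flap_angle = pi / 6,
                         centerline_amplitude = 5,
                         seed = 1L) {
  spec <- structure(list(n_slices = as.integer(n_slices),
                         grid_shape = as.integer(grid_shape),
                         spacing = as.numeric(spacing),
                         outer_diameter = as.numeric(outer_diameter),
                         flap_thickness = as.numeric(flap_thickness),
                         flap_offset = as.numeric(flap_offset),
                         flap_angle = as.numeric(flap_angle),
                         centerline_amplitude = as.numeric(centerline_amplitude),
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(paste0("<phantom_spec> %d slices of %d x %d px, outer %.3g mm, ",
                     "flap %.3g mm at offset %.3g mm, angle %.3g rad, drift %.3g mm\n"),
              x$n_slices, x$grid_shape[1], x$grid_shape[2], x$outer_diameter,
              x$flap_thickness, x$flap_offset, x$flap_angle,
              x$centerline_amplitude))
  invisible(x)
}

validate_phantom_spec <- function(spec) {
  if (spec$n_slices < 1L) stop_validation("n_slices must be >= 1")
  if (any(spec$grid_shape < 4L)) stop_validation("grid_shape too small")
  if (any(!is.finite(spec$spacing)) || any(spec$spacing <= 0))
    stop_validation("spacing components must be strictly positive")
  if (spec$flap_thickness <= 0 || spec$flap_thickness >= spec$outer_diameter)
    stop_validation("flap_thickness must satisfy 0 < flap_thickness < outer_diameter (got %.3g vs %.3g)",
                    spec$flap_thickness, spec$outer_diameter)
  if (abs(spec$flap_offset) + spec$flap_thickness / 2 >= spec$outer_diameter / 2)
    stop_validation("flap band must lie strictly inside the lumen: |flap_offset| + flap_thickness/2 < outer_diameter/2")
  sy <- spec$spacing[2]; sx <- spec$spacing[3]
  half_extent <- min((spec$grid_shape[1] - 1) * sy, (spec$grid_shape[2] - 1) * sx) / 2
  need <- spec$outer_diameter / 2 + abs(spec$centerline_amplitude) +
    2 * max(sy, sx)
  if (need > half_extent)
    stop_validation("outer_diameter plus drift must fit in the grid with >= 2 voxels margin (need %.3g mm half-extent, have %.3g mm)",
                    need, half_extent)
  invisible(spec)
}

## Area of the circular region {s > d} of a disc of radius R, where s is a
## signed chord coordinate. Valid for any d in (-R, R); negative d gives
## the majority segment.
circular_segment_area <- function(d, R) {
  d <- pmin(pmax(d, -R), R)
  R^2 * acos(d / R) - d * sqrt(pmax(R^2 - d^2, 0))
}

## Longest chord of the region {s > d}: the cutting chord itself when the
## region is the minority segment (d >= 0), else the full diameter.
segment_max_chord <- function(d, R) {
  if (d >= 0) 2 * sqrt(max(R^2 - d^2, 0)) else 2 * R
}

#' Generate a dissection phantom volume with analytic ground truth
#'
#' Returns an annotation-style label volume (flap band left as background,
#' mirroring a manual TL/FL annotation), a full-truth volume with the band
#' labelled 3, and the analytic per-slice morphometry implied by the
#' geometry. The smaller circular segment is the true lumen.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `annotation` ([label_volume()], labels
#'   \{0,1,2\}), `full` (labels \{0,1,2,3\}), `truth` (a one-row
#'   `data.frame` of class `phantom_truth` with `aortic_diameter`,
#'   `tl_diameter`, `fl_diameter`, `tl_area`, `fl_area`, `flap_thickness`)
#'   and `spec`.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  nz <- spec$n_slices
  nr <- spec$grid_shape[1]; ncl <- spec$grid_shape[2]
  sz <- spec$spacing[1]; sy <- spec$spacing[2]; sx <- spec$spacing[3]
  R <- spec$outer_diameter / 2
  t2 <- spec$flap_thickness / 2
  off <- spec$flap_offset
  a <- spec$flap_angle
  cy0 <- (nr - 1) / 2 * sy
  cx0 <- (ncl - 1) / 2 * sx
  yc <- (seq_len(nr) - 1) * sy
  xc <- (seq_len(ncl) - 1) * sx

  ## analytic side areas decide which side is TL (the smaller one)
  area_hi <- circular_segment_area(off + t2, R)
  area_lo <- pi * R^2 - circular_segment_area(off - t2, R)
  tl_is_hi <- area_hi <= area_lo

  ann <- array(0L, dim = c(nz, nr, ncl))
  full <- array(0L, dim = c(nz, nr, ncl))
  for (z in seq_len(nz)) {
    cy <- cy0 + spec$centerline_amplitude * sin(2 * pi * (z - 1) / nz)
    cx <- cx0
    dy <- yc - cy
    dx <- xc - cx
    dist2 <- outer(dy^2, dx^2, "+")
    s <- outer(dy * cos(a), dx * sin(a), "+")
    in_disc <- dist2 <= R^2
    hi <- in_disc & (s - off > t2)
    lo <- in_disc & (s - off < -t2)
    band <- in_disc & !hi & !lo
    sl <- matrix(0L, nr, ncl)
    sl[if (tl_is_hi) hi else lo] <- LABEL_TRUE_LUMEN
    sl[if (tl_is_hi) lo else hi] <- LABEL_FALSE_LUMEN
    ann[z, , ] <- sl
    slf <- sl
    slf[band] <- LABEL_FLAP
    full[z, , ] <- slf
  }

  diam_hi <- segment_max_chord(off + t2, R)
  diam_lo <- segment_max_chord(-(off - t2), R)
  truth <- data.frame(
    aortic_diameter = spec$outer_diameter,
    tl_diameter = if (tl_is_hi) diam_hi else diam_lo,
    fl_diameter = if (tl_is_hi) diam_lo else diam_hi,
    tl_area = if (tl_is_hi) area_hi else area_lo,
    fl_area = if (tl_is_hi) area_lo else area_hi,
    flap_thickness = spec$flap_thickness
  )
  class(truth) <- c("phantom_truth", "data.frame")

  annotation <- label_volume(ann, spec$spacing)
  attr(annotation, "outer_diameter") <- spec$outer_diameter
  full_vol <- label_volume(full, spec$spacing)
  attr(full_vol, "outer_diameter") <- spec$outer_diameter
  list(annotation = annotation, full = full_vol, truth = truth, spec = spec)
}

#' Specify prediction degradation
#'
#' Controls how a perfect phantom annotation is turned into an imperfect
#' "predicted" segmentation: random per-slice, per-label boundary
#' dilation/erosion, TL/FL label swaps on boundary voxels, and whole-slice
#' dropout.
#'
#' @param boundary_shift_mm maximum magnitude of the random per-slice,
#'   per-label morphological boundary shift, mm (nonnegative).
#' @param flip_fraction fraction in `[0, 1)` of TL/FL boundary voxels whose
#'   label is swapped between TL and FL.
#' @param dropout_slices number of slices whose prediction is zeroed.
#' @param seed integer seed; the degradation is deterministic given it.
#' @return an object of class `degradation_spec`.
#' @export
degradation_spec <- function(boundary_shift_mm = 0.9,
                             flip_fraction = 0.05,
                             dropout_slices = 0L,
                             seed = 1L) {
  spec <- structure(list(boundary_shift_mm = as.numeric(boundary_shift_mm),
                         flip_fraction = as.numeric(flip_fraction),
                         dropout_slices = as.integer(dropout_slices),
                         seed = as.integer(seed)),
                    class = "degradation_spec")
  validate_degradation_spec(spec)
  spec
}

validate_degradation_spec <- function(spec, outer_diameter = NULL) {
  if (!is.finite(spec$boundary_shift_mm) || spec$boundary_shift_mm < 0)
    stop_validation("boundary_shift_mm must be nonnegative")
  if (!is.finite(spec$flip_fraction) || spec$flip_fraction < 0 ||
      spec$flip_fraction >= 1)
    stop_validation("flip_fraction must lie in [0, 1)")
  if (spec$dropout_slices < 0L)
    stop_validation("dropout_slices must be nonnegative")
  if (!is.null(outer_diameter) && spec$boundary_shift_mm >= outer_diameter / 4)
    stop_validation("boundary_shift_mm (%.3g) must be < outer_diameter/4 (%.3g)",
                    spec$boundary_shift_mm, outer_diameter / 4)
  invisible(spec)
}

#' Degrade a ground-truth segmentation into a synthetic prediction
#'
#' Applies, per slice and per lumen label, a morphological dilation or
#' erosion of random radius up to `boundary_shift_mm`; swaps the labels of
#' a random `flip_fraction` of TL/FL boundary voxels; and zeroes
#' `dropout_slices` randomly chosen slices. With an all-zero spec the
#' output equals the input. Deterministic given `spec$seed`.
#'
#' @param gt a [label_volume()] with labels in \{0, 1, 2\}.
#' @param spec a [degradation_spec()].
#' @return a degraded [label_volume()].
#' @export
degrade_prediction <- function(gt, spec) {
  validate_label_volume(gt)
  validate_degradation_spec(spec, attr(gt, "outer_diameter"))
  if (spec$dropout_slices > dim(gt$voxels)[1])
    stop_validation("dropout_slices (%d) exceeds the number of slices (%d)",
                    spec$dropout_slices, dim(gt$voxels)[1])
  vox <- gt$voxels
  nz <- dim(vox)[1]
  syx <- spacing_yx(gt)
  withr::with_seed(spec$seed, {
    for (z in seq_len(nz)) {
      sl <- vox[z, , ]
      for (lab in sample(c(LABEL_TRUE_LUMEN, LABEL_FALSE_LUMEN))) {
        r <- runif(1, 0, spec$boundary_shift_mm)
        grow <- sample(c(TRUE, FALSE), 1)
        mask <- sl == lab
        if (!any(mask) || r <= 0) next
        if (grow) {
          newmask <- dilate_mm(mask, r, syx)
          sl[newmask] <- lab
        } else {
          newmask <- erode_mm(mask, r, syx)
          sl[mask & !newmask] <- LABEL_BACKGROUND
        }
      }
      if (spec$flip_fraction > 0) {
        tl <- sl == LABEL_TRUE_LUMEN
        fl <- sl == LABEL_FALSE_LUMEN
        boundary <- (tl & !erode4(tl)) | (fl & !erode4(fl))
        cand <- which(boundary)
        k <- round(spec$flip_fraction * length(cand))
        if (k > 0) {
          pick <- sample(cand, k)
          sl[pick] <- ifelse(sl[pick] == LABEL_TRUE_LUMEN,
                             LABEL_FALSE_LUMEN, LABEL_TRUE_LUMEN)
        }
      }
      vox[z, , ] <- sl
    }
    if (spec$dropout_slices > 0L) {
      drop <- sample(nz, spec$dropout_slices)
      vox[drop, , ] <- 0L
    }
  })
  out <- label_volume(vox, gt$spacing)
  attr(out, "outer_diameter") <- attr(gt, "outer_diameter")
  out
}

## 4-connected erosion by one pixel (interior test for boundary detection).
erode4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask
  p[2:(nr + 1L), 2:(nc + 1L)] &
    p[1:nr, 2:(nc + 1L)] & p[3:(nr + 2L), 2:(nc + 1L)] &
    p[2:(nr + 1L), 1:nc] & p[2:(nr + 1L), 3:(nc + 2L)]
}

#' Synthesize a pseudo-CT intensity volume from labels
#'
#' Maps each label to a plausible contrast-CT attenuation level (lumen
#' bright, flap intermediate, background dark) and adds Gaussian noise.
#' Intended for documentation figures only; the analysis path never reads
#' intensities.
#'
#' @param gt a [label_volume()].
#' @param noise_sd Gaussian noise standard deviation in HU (nonnegative).
#' @param levels named numeric vector of attenuation levels in HU for
#'   `background`, `true_lumen`, `false_lumen`, `flap`.
#' @param seed integer seed.
#' @return a numeric 3D array (z, y, x) of intensities in HU.
#' @export
synthesize_intensity <- function(gt, noise_sd = 25,
                                 levels = c(background = -80, true_lumen = 350,
                                            false_lumen = 300, flap = 120),
                                 seed = 1L) {
  validate_label_volume(gt)
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop_validation("noise_sd must be nonnegative")
  lev <- levels[c("background", "true_lumen", "false_lumen", "flap")]
  if (any(is.na(lev)))
    stop_validation("levels must name background, true_lumen, false_lumen, flap")
  img <- array(lev[gt$voxels + 1L], dim = dim(gt$voxels))
  if (noise_sd > 0) {
    img <- img + withr::with_seed(seed, rnorm(length(img), 0, noise_sd))
    dim(img) <- dim(gt$voxels)
  }
  img
}
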