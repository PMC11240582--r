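## Per-slice and per-patient aortic morphology: maximum Feret diameters,
## lumen areas, medial-axis flap thickness, and relative errors of a
## predicted segmentation against ground truth.

#' Maximum Feret diameter of a 2D region
#'
#' Maximum Euclidean distance between any two foreground pixel centres,
#' in mm. Computed exactly: the maximising pair lies on the convex hull
#' of the pixel centres, so the hull is built first and all hull pairs
#' are checked.
#'
#' @param mask 2D logical matrix (y, x), nonempty.
#' @param in_plane_spacing (y, x) pixel size in mm.
#' @return maximum diameter in mm (0 for a single pixel).
#' @export
max_diameter <- function(mask, in_plane_spacing = c(1, 1)) {
  if (!any(mask)) stop_validation("mask has no foreground pixels")
  idx <- which(mask, arr.ind = TRUE)
  pts <- cbind((idx[, 1] - 1) * in_plane_spacing[1],
               (idx[, 2] - 1) * in_plane_spacing[2])
  if (nrow(pts) == 1L) return(0)
  if (nrow(pts) > 3L) {
    h <- tryCatch(grDevices::chull(pts[, 2], pts[, 1]), error = function(e) NULL)
    if (!is.null(h) && length(h) >= 2L) pts <- pts[h, , drop = FALSE]
  }
  d2 <- outer(pts[, 1], pts[, 1], "-")^2 + outer(pts[, 2], pts[, 2], "-")^2
  sqrt(max(d2))
}

#' Area of a 2D region
#'
#' Foreground pixel count times the pixel area.
#'
#' @param mask 2D logical matrix (y, x); an empty mask has area 0.
#' @param in_plane_spacing (y, x) pixel size in mm.
#' @return area in mm^2.
#' @export
region_area <- function(mask, in_plane_spacing = c(1, 1)) {
  sum(mask) * in_plane_spacing[1] * in_plane_spacing[2]
}

#' Mean local thickness of an elongated 2D region
#'
#' Medial-axis width estimator. The region boundary is represented at
#' sub-pixel precision by the midpoints of the pixel edges ("cracks")
#' separating foreground from background. For every pixel of the
#' morphological skeleton the local width is the distance to the nearest
#' boundary midpoint plus the distance to the nearest midpoint on the
#' opposite side of the skeleton; the mean over the skeleton is
#' reported. Measuring both sides separately keeps even-width bands
#' (whose true medial axis falls between pixel rows) unbiased. For a
#' region too thin to carry an interior (single-pixel line) the
#' thickness is one pixel spacing, with a warning.
#'
#' @param flap_mask 2D logical matrix (y, x), nonempty.
#' @param in_plane_spacing (y, x) pixel size in mm.
#' @return mean thickness in mm.
#' @export
mean_thickness <- function(flap_mask, in_plane_spacing = c(1, 1)) {
  if (!any(flap_mask)) stop_validation("flap mask has no foreground pixels")
  px <- mean(in_plane_spacing)
  skel <- thin_mask(flap_mask) & flap_mask
  if (!any(skel)) skel <- flap_mask
  widths <- local_width(flap_mask, skel, in_plane_spacing)
  if (max(widths) <= max(in_plane_spacing) + 1e-9) {
    warning("region is a single-pixel line; thickness reported as one pixel spacing",
            call. = FALSE)
    return(px)
  }
  max(mean(widths), px)
}

## Two-sided local width at the pixels of `at`: distance to the nearest
## boundary crack midpoint, plus distance to the nearest midpoint lying
## in the opposite half-plane. The image border counts as background.
local_width <- function(mask, at, in_plane_spacing) {
  sy <- in_plane_spacing[1]; sx <- in_plane_spacing[2]
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  ## crack midpoints between 4-adjacent fg/bg pairs, in mm (padded frame)
  mids <- list()
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  cells <- which(core, arr.ind = TRUE)
  cy <- (cells[, 1] - 1) * sy; cx <- (cells[, 2] - 1) * sx
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    nb <- !pad[cbind(cells[, 1] + 1L + d[1], cells[, 2] + 1L + d[2])]
    if (!any(nb)) next
    mids[[length(mids) + 1L]] <- cbind(cy[nb] + d[1] * sy / 2,
                                       cx[nb] + d[2] * sx / 2)
  }
  m <- do.call(rbind, mids)
  q <- which(at, arr.ind = TRUE)
  vapply(seq_len(nrow(q)), function(i) {
    py <- (q[i, 1] - 1) * sy; px_ <- (q[i, 2] - 1) * sx
    vy <- m[, 1] - py; vx <- m[, 2] - px_
    dd <- sqrt(vy^2 + vx^2)
    j <- which.min(dd)
    d1 <- dd[j]
    dot <- vy * vy[j] + vx * vx[j]
    opp <- dd[dot < -1e-12]
    d2 <- if (length(opp)) min(opp) else d1
    d1 + d2
  }, numeric(1))
}

## Cross-check width estimator for elongated bands: area / skeleton length.
thickness_area_over_length <- function(flap_mask, in_plane_spacing = c(1, 1)) {
  skel <- thin_mask(flap_mask)
  n <- sum(skel)
  if (n < 2L) return(mean(in_plane_spacing))
  region_area(flap_mask, in_plane_spacing) / (n * mean(in_plane_spacing))
}

#' Morphometry of one processed slice
#'
#' @param regions a `slice_regions` object (see [extract_flap()]) with
#'   all three region masks nonempty.
#' @param z slice index recorded in the output.
#' @return one-row `data.frame`: `z`, `aortic_diameter`, `tl_diameter`,
#'   `fl_diameter` (mm), `tl_area`, `fl_area` (mm^2), `flap_thickness`
#'   (mm).
#' @export
slice_morphometry <- function(regions, z = NA_integer_) {
  sp <- regions$in_plane_spacing
  for (nm in c("tl_mask", "fl_mask", "flap_mask"))
    if (!any(regions[[nm]]))
      stop_validation("region %s is empty on slice %s", nm, as.character(z))
  data.frame(
    z = z,
    aortic_diameter = max_diameter(regions$aorta_mask, sp),
    tl_diameter = max_diameter(regions$tl_mask, sp),
    fl_diameter = max_diameter(regions$fl_mask, sp),
    tl_area = region_area(regions$tl_mask, sp),
    fl_area = region_area(regions$fl_mask, sp),
    flap_thickness = mean_thickness(regions$flap_mask, sp)
  )
}

## slice_regions from a slice of a flap-labelled volume.
regions_from_grid <- function(grid, in_plane_spacing) {
  structure(list(tl_mask = grid == LABEL_TRUE_LUMEN,
                 fl_mask = grid == LABEL_FALSE_LUMEN,
                 flap_mask = grid == LABEL_FLAP,
                 aorta_mask = grid != LABEL_BACKGROUND,
                 in_plane_spacing = in_plane_spacing),
            class = "slice_regions")
}

#' Patient-level morphometry averages
#'
#' Unweighted means of the per-slice morphometry over all slices where
#' the three regions (TL, FL, flap) are present and, if given, the slice
#' index falls in `slice_range` (the configured section of interest,
#' e.g. the ascending aorta). A patient with no passing slice is an
#' exclusion error, mirroring manual exclusion of patients without a
#' usable three-region cross-section.
#'
#' @param x a flap-labelled [label_volume()] (labels \{0,1,2,3\}, e.g.
#'   from [extract_flap_volume()]) or a list of `slice_regions`.
#' @param slice_range optional inclusive `(zmin, zmax)` slice interval.
#' @param patient_id identifier recorded in the output.
#' @return one-row `data.frame` of class `patient_morphometry`:
#'   `patient_id`, `n_slices_used`, and the per-field averages.
#' @export
patient_morphometry <- function(x, slice_range = NULL, patient_id = NA) {
  if (inherits(x, "label_volume")) {
    validate_label_volume(x)
    syx <- spacing_yx(x)
    regions_list <- lapply(seq_len(dim(x$voxels)[1]), function(z)
      regions_from_grid(x$voxels[z, , ], syx))
  } else {
    regions_list <- x
  }
  rows <- list()
  skipped <- list()
  for (z in seq_along(regions_list)) {
    r <- regions_list[[z]]
    if (!is.null(slice_range) && (z < slice_range[1] || z > slice_range[2])) {
      skipped[[length(skipped) + 1L]] <- data.frame(z = z, reason = "outside slice_range")
      next
    }
    if (!any(r$tl_mask) || !any(r$fl_mask) || !any(r$flap_mask)) {
      skipped[[length(skipped) + 1L]] <- data.frame(z = z, reason = "missing region")
      next
    }
    rows[[length(rows) + 1L]] <- slice_morphometry(r, z)
  }
  if (length(rows) == 0L)
    stop(errorCondition(
      sprintf("patient %s excluded: no slice with all three regions in range",
              as.character(patient_id)),
      class = c("taadmorph_exclusion", "taadmorph_error")))
  per_slice <- do.call(rbind, rows)
  fields <- c("aortic_diameter", "tl_diameter", "fl_diameter",
              "tl_area", "fl_area", "flap_thickness")
  out <- cbind(data.frame(patient_id = patient_id,
                          n_slices_used = nrow(per_slice)),
               as.data.frame(as.list(colMeans(per_slice[fields]))))
  class(out) <- c("patient_morphometry", "data.frame")
  attr(out, "per_slice") <- per_slice
  attr(out, "skip_log") <- if (length(skipped)) do.call(rbind, skipped)
    else data.frame(z = integer(), reason = character())
  out
}

#' Relative-error comparison of predicted vs ground-truth morphometry
#'
#' For each morphometric field, reports the across-patient ground-truth
#' and predicted averages and the mean relative error, computed per
#' patient first (`mean_i |pred_i - gt_i| / gt_i`) and then averaged --
#' not as the relative discrepancy of the two averages, which would
#' understate the error whenever per-patient errors have mixed sign.
#'
#' @param gt,pred `data.frame`s of per-patient morphometry (rows from
#'   [patient_morphometry()]) covering the same patients.
#' @return a `data.frame` with columns `field`, `gt_average`,
#'   `pred_average`, `mean_relative_error` (fraction).
#' @export
compare_morphometry <- function(gt, pred) {
  if (!setequal(gt$patient_id, pred$patient_id) ||
      nrow(gt) != nrow(pred))
    stop_validation("ground-truth and predicted tables cover different patients")
  pred <- pred[match(gt$patient_id, pred$patient_id), ]
  fields <- c("aortic_diameter", "tl_diameter", "fl_diameter",
              "tl_area", "fl_area", "flap_thickness")
  rows <- lapply(fields, function(f) {
    g <- gt[[f]]; p <- pred[[f]]
    data.frame(field = f,
               gt_average = mean(g),
               pred_average = mean(p),
               mean_relative_error = mean(abs(p - g) / g))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("morphometry_comparison", "data.frame")
  out
}
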