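## Intimal-flap recovery from TL/FL labels, per slice: contour extraction
## of each lumen, contour evolution over the merged TL+FL region to obtain
## the whole-aorta mask (bridging the inter-lumen gap), and set
## subtraction, so that aorta = TL + FL + flap exactly.
##
## The contour engine is a morphological, region-based evolution on the
## binary label image: the region is initialised from the Euclidean
## closing of the target mask (radius `init_dilation_mm`) and iterated
## with a 3x3 majority filter (a discrete curvature-flow step), anchored
## so it always remains a superset of the input labels. A pure
## morphological-closing engine is available for cross-checking.

#' Contour-evolution parameters
#'
#' @param max_iterations maximum number of evolution iterations.
#' @param smoothing_passes majority-filter passes per iteration
#'   (curvature regularisation strength).
#' @param convergence_window number of consecutive unchanged iterations
#'   required to declare convergence (`max_iterations >=
#'   convergence_window >= 1`).
#' @param init_dilation_mm radius in mm of the Euclidean closing used to
#'   build the initial region; it must exceed half the widest expected
#'   flap gap for the gap to be bridged. Default 3 mm.
#' @param adjacency_required if `TRUE`, residual components not touching
#'   (8-neighbourhood) both TL and FL are discarded as contour-bridging
#'   artifacts rather than flap.
#' @param engine `"active_contour"` (closing-initialised curvature
#'   evolution, default) or `"closing"` (plain Euclidean closing,
#'   debugging/cross-check path).
#' @return an object of class `contour_params`.
#' @export
contour_params <- function(max_iterations = 50L,
                           smoothing_passes = 2L,
                           convergence_window = 3L,
                           init_dilation_mm = 3,
                           adjacency_required = TRUE,
                           engine = c("active_contour", "closing")) {
  engine <- match.arg(engine)
  p <- structure(list(max_iterations = as.integer(max_iterations),
                      smoothing_passes = as.integer(smoothing_passes),
                      convergence_window = as.integer(convergence_window),
                      init_dilation_mm = as.numeric(init_dilation_mm),
                      adjacency_required = isTRUE(adjacency_required),
                      engine = engine),
                 class = "contour_params")
  if (p$convergence_window < 1L || p$max_iterations < p$convergence_window)
    stop_validation("need max_iterations >= convergence_window >= 1")
  if (p$init_dilation_mm < 0)
    stop_validation("init_dilation_mm must be nonnegative")
  p
}

## Curvature-regularised evolution of `init`, constrained to contain
## `anchor`. Returns the mask with attribute "converged".
evolve_region <- function(init, anchor, params) {
  u <- init | anchor
  stable <- 0L
  converged <- FALSE
  for (i in seq_len(params$max_iterations)) {
    v <- if (params$smoothing_passes > 0L)
      majority_smooth(u, params$smoothing_passes) else u
    v <- v | anchor
    if (identical(v, u)) {
      stable <- stable + 1L
      if (stable >= params$convergence_window) { converged <- TRUE; break }
    } else {
      stable <- 0L
    }
    u <- v
  }
  attr(u, "converged") <- converged
  u
}

#' Extract the closed boundary contour of a binary region
#'
#' Evolves a contour over the largest 8-connected component of `mask`
#' (closing-initialised curvature evolution) and returns its closed
#' boundary polygon, traced along pixel edges so the enclosed area equals
#' the region's pixel area. Vertices are ordered counterclockwise in mm
#' coordinates.
#'
#' @param mask 2D logical matrix (y, x) with at least one `TRUE` pixel.
#' @param in_plane_spacing (y, x) pixel size in mm.
#' @param params a [contour_params()].
#' @return an n x 2 matrix of (x, y) vertices in mm, with attribute
#'   `"converged"` (`FALSE`, with a warning, if the evolution hit
#'   `max_iterations` while still changing).
#' @export
extract_region_contour <- function(mask, in_plane_spacing = c(1, 1),
                                   params = contour_params()) {
  if (!any(mask)) stop_validation("mask has no foreground pixels")
  comp <- largest_component(mask)
  if (params$engine == "active_contour") {
    init <- closing_mm(comp, params$init_dilation_mm, in_plane_spacing)
    region <- evolve_region(init, comp, params)
  } else {
    region <- closing_mm(comp, params$init_dilation_mm, in_plane_spacing) | comp
    attr(region, "converged") <- TRUE
  }
  if (!isTRUE(attr(region, "converged")))
    warning("contour evolution did not converge within max_iterations; returning last contour",
            call. = FALSE)
  poly <- mask_boundary_polygon(region, in_plane_spacing)
  attr(poly, "converged") <- isTRUE(attr(region, "converged"))
  poly
}

#' Whole-aorta region from the merged TL + FL labels
#'
#' Treats TL + FL as one labelling region and evolves a contour over it,
#' initialised from the Euclidean closing by `init_dilation_mm`, so the
#' converged region bridges the inter-lumen flap gap. The result is
#' hole-filled and guaranteed to be a superset of TL and FL.
#'
#' @param tl_mask,fl_mask 2D logical matrices (y, x), each nonempty.
#' @param in_plane_spacing (y, x) pixel size in mm.
#' @param params a [contour_params()].
#' @return 2D logical aorta mask.
#' @export
extract_aorta_region <- function(tl_mask, fl_mask,
                                 in_plane_spacing = c(1, 1),
                                 params = contour_params()) {
  if (!any(tl_mask) || !any(fl_mask))
    stop_validation("TL and FL must both be nonempty on this slice")
  lumen <- tl_mask | fl_mask
  init <- closing_mm(lumen, params$init_dilation_mm, in_plane_spacing)
  region <- if (params$engine == "active_contour")
    evolve_region(init, lumen, params) else (init | lumen)
  region <- EBImage::fillHull(region) > 0
  region | lumen
}

#' Flap region by subtraction of the lumens from the aorta
#'
#' The flap is the remaining region after removing TL and FL from the
#' whole-aorta mask. With `adjacency_required`, residual connected
#' components not touching (8-neighbourhood) both TL and FL are
#' discarded. The returned aorta mask is the exact disjoint union
#' TL + FL + flap.
#'
#' @param tl_mask,fl_mask,aorta_mask 2D logical matrices (y, x);
#'   `aorta_mask` must contain TL and FL.
#' @param in_plane_spacing (y, x) pixel size in mm.
#' @param params a [contour_params()].
#' @return an object of class `slice_regions`: list with `tl_mask`,
#'   `fl_mask`, `flap_mask`, `aorta_mask`, `in_plane_spacing`.
#' @export
extract_flap <- function(tl_mask, fl_mask, aorta_mask,
                         in_plane_spacing = c(1, 1),
                         params = contour_params()) {
  if (any((tl_mask | fl_mask) & !aorta_mask))
    stop_validation("aorta_mask must be a superset of TL and FL")
  if (any(tl_mask & fl_mask))
    stop_validation("TL and FL masks overlap")
  flap <- aorta_mask & !tl_mask & !fl_mask
  if (params$adjacency_required && any(flap)) {
    lab <- label8(flap)
    keep <- flap & FALSE
    for (k in seq_len(max(lab))) {
      comp <- lab == k
      halo <- dilate8_1px(comp)
      if (any(halo & tl_mask) && any(halo & fl_mask)) keep <- keep | comp
    }
    flap <- keep
  }
  structure(list(tl_mask = tl_mask, fl_mask = fl_mask, flap_mask = flap,
                 aorta_mask = tl_mask | fl_mask | flap,
                 in_plane_spacing = in_plane_spacing),
            class = "slice_regions")
}

## Per-slice chain: aorta region then subtraction.
slice_flap_chain <- function(grid, in_plane_spacing, params) {
  tl <- grid == LABEL_TRUE_LUMEN
  fl <- grid == LABEL_FALSE_LUMEN
  aorta <- extract_aorta_region(tl, fl, in_plane_spacing, params)
  extract_flap(tl, fl, aorta, in_plane_spacing, params)
}

#' Recover the intimal flap throughout a volume
#'
#' Applies the per-slice extraction chain (merged-lumen contour evolution
#' plus region subtraction) to every slice passing `slice_filter`
#' (default: TL and FL both nonempty). Other slices are copied unchanged
#' and logged. Recovered flap voxels are written as label 3; any label-3
#' voxels already present in the input are ignored and recomputed, which
#' makes the operation idempotent.
#'
#' @param volume a [label_volume()].
#' @param params a [contour_params()].
#' @param slice_filter `NULL` for the default rule, or
#'   `function(grid, z)` returning `TRUE` for slices to process.
#' @return a [label_volume()] with labels \{0,1,2,3\}; attribute
#'   `"skip_log"` is a `data.frame` (columns `z`, `reason`) listing
#'   skipped slices.
#' @export
extract_flap_volume <- function(volume, params = contour_params(),
                                slice_filter = NULL) {
  validate_label_volume(volume)
  syx <- spacing_yx(volume)
  nz <- dim(volume$voxels)[1]
  out <- volume$voxels
  skips <- list()
  for (z in seq_len(nz)) {
    grid <- volume$voxels[z, , ]
    grid[grid == LABEL_FLAP] <- LABEL_BACKGROUND
    has_both <- any(grid == LABEL_TRUE_LUMEN) && any(grid == LABEL_FALSE_LUMEN)
    pass <- if (is.null(slice_filter)) has_both else
      isTRUE(slice_filter(grid, z)) && has_both
    if (!pass) {
      reason <- if (!has_both) "TL or FL empty" else "excluded by slice_filter"
      skips[[length(skips) + 1L]] <- data.frame(z = z, reason = reason)
      next
    }
    regions <- slice_flap_chain(grid, syx, params)
    sl <- matrix(LABEL_BACKGROUND, nrow(grid), ncol(grid))
    sl[regions$tl_mask] <- LABEL_TRUE_LUMEN
    sl[regions$fl_mask] <- LABEL_FALSE_LUMEN
    sl[regions$flap_mask] <- LABEL_FLAP
    out[z, , ] <- sl
  }
  res <- label_volume(out, volume$spacing)
  attr(res, "outer_diameter") <- attr(volume, "outer_diameter")
  attr(res, "skip_log") <- if (length(skips)) do.call(rbind, skips)
    else data.frame(z = integer(), reason = character())
  res
}
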