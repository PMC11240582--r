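## Internal helpers: classed error conditions, exact Euclidean morphology on
## the pixel/voxel lattice, binary smoothing, thinning, boundary polygons.

stop_io <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("taadmorph_io_error", "taadmorph_error")))
}

stop_format <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("taadmorph_format_error", "taadmorph_error")))
}

stop_validation <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("taadmorph_validation_error", "taadmorph_error")))
}

stop_index <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("taadmorph_index_error", "taadmorph_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Euclidean distance transform in physical units
#'
#' Distance (mm) from every grid point to the nearest `TRUE` element of
#' `mask`, computed exactly with the separable lower-envelope algorithm.
#' Spacing is given per axis in the same order as `dim(mask)`, so
#' anisotropic voxels are handled correctly. If `mask` has no `TRUE`
#' element every distance is `+Inf`.
#'
#' @param mask logical matrix or 3D array.
#' @param spacing numeric vector of per-axis sample spacings in mm.
#' @return numeric array of distances with the shape of `mask`.
#' @export
edt_mm <- function(mask, spacing) {
  d <- dim(mask)
  if (is.null(d)) d <- length(mask)
  if (length(spacing) != length(d))
    stop_validation("spacing length (%d) must match mask dimensionality (%d)",
                    length(spacing), length(d))
  out <- sqrt(.edt_sq_cpp(as.logical(mask), as.integer(d), as.numeric(spacing)))
  dim(out) <- d
  out
}

## Morphological operators with true Euclidean disc/ball structuring
## elements of physical radius r (mm), via thresholded distance transforms.
dilate_mm <- function(mask, r, spacing) {
  if (r <= 0) return(mask)
  edt_mm(mask, spacing) <= r + 1e-9
}

erode_mm <- function(mask, r, spacing) {
  if (r <= 0) return(mask)
  !dilate_mm(!mask, r, spacing)
}

closing_mm <- function(mask, r, spacing) {
  erode_mm(dilate_mm(mask, r, spacing), r, spacing)
}

## Count of TRUE values in each pixel's 3x3 neighbourhood (self included),
## zero-padded at the image border.
neighbour_count3 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- as.integer(mask)
  acc <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1)
    acc <- acc + p[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  acc
}

## Majority vote over the 3x3 neighbourhood: a discrete curvature-flow step.
majority_smooth <- function(mask, passes = 1L) {
  for (i in seq_len(passes)) mask <- neighbour_count3(mask) >= 5L
  mask
}

label8 <- function(mask) {
  .label8_cpp(as.logical(mask), as.integer(dim(mask)))
}

largest_component <- function(mask) {
  lab <- label8(mask)
  k <- max(lab)
  if (k <= 1L) return(mask & (lab > 0L))
  counts <- tabulate(lab[lab > 0L], nbins = k)
  lab == which.max(counts)
}

## One-pixel 8-connected dilation (used for adjacency tests).
dilate8_1px <- function(mask) {
  neighbour_count3(mask) >= 1L
}

## Zhang-Suen thinning: reduces a binary region to its one-pixel skeleton.
thin_mask <- function(mask) {
  m <- mask
  nr <- nrow(m); nc <- ncol(m)
  shift <- function(p, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 - dr):min(nr, nr - dr)
    cs <- max(1, 1 - dc):min(nc, nc - dc)
    out[rs, cs] <- p[rs + dr, cs + dc]
    out
  }
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p2 <- shift(m, -1, 0); p3 <- shift(m, -1, 1); p4 <- shift(m, 0, 1)
      p5 <- shift(m, 1, 1);  p6 <- shift(m, 1, 0);  p7 <- shift(m, 1, -1)
      p8 <- shift(m, 0, -1); p9 <- shift(m, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (sub == 1L) {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        m[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

## Closed boundary polygon of the largest 8-connected component of a mask,
## traced along pixel-square edges (the 0.5 iso-contour of the binary
## image), so the enclosed polygon area equals the pixel-count area.
## Returns an n x 2 matrix of (x, y) vertices in mm, counterclockwise.
mask_boundary_polygon <- function(mask, spacing_yx) {
  if (!any(mask)) stop_validation("cannot trace the contour of an empty mask")
  comp <- largest_component(mask)
  comp <- EBImage::fillHull(comp) > 0
  nr <- nrow(comp); nc <- ncol(comp)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- comp
  core <- pad[2:(nr + 1L), 2:(nc + 1L)]
  idx <- function(w) which(w, arr.ind = TRUE)
  ## boundary edges in doubled-corner coordinates: pixel (r, c) (1-based)
  ## has corners (2r-3..2r-1, 2c-3..2c-1) on the doubled 0-based lattice.
  edges <- list()
  add_edges <- function(cells, a_dr, a_dc, b_dr, b_dc) {
    if (nrow(cells) == 0L) return()
    r2 <- 2L * (cells[, 1] - 1L); c2 <- 2L * (cells[, 2] - 1L)
    a <- cbind(r2 + a_dr, c2 + a_dc)
    b <- cbind(r2 + b_dr, c2 + b_dc)
    edges[[length(edges) + 1L]] <<- cbind(a, b)
  }
  up_bg    <- core & !pad[1:nr, 2:(nc + 1L)]
  down_bg  <- core & !pad[3:(nr + 2L), 2:(nc + 1L)]
  left_bg  <- core & !pad[2:(nr + 1L), 1:nc]
  right_bg <- core & !pad[2:(nr + 1L), 3:(nc + 2L)]
  add_edges(idx(up_bg),    -1L, -1L, -1L,  1L)
  add_edges(idx(down_bg),   1L, -1L,  1L,  1L)
  add_edges(idx(left_bg),  -1L, -1L,  1L, -1L)
  add_edges(idx(right_bg), -1L,  1L,  1L,  1L)
  e <- do.call(rbind, edges)
  key <- function(r2, c2) paste(r2, c2)
  k1 <- key(e[, 1], e[, 2]); k2 <- key(e[, 3], e[, 4])
  ## adjacency map vertex -> incident edge indices
  adj <- split(c(seq_len(nrow(e)), seq_len(nrow(e))), c(k1, k2))
  used <- logical(nrow(e))
  start <- 1L
  cur_key <- k1[start]
  first_key <- cur_key
  path <- matrix(NA_integer_, nrow(e) + 1L, 2L)
  path[1L, ] <- e[start, 1:2]
  np <- 1L
  cur_edge <- start
  repeat {
    used[cur_edge] <- TRUE
    nxt_key <- if (key(e[cur_edge, 1], e[cur_edge, 2]) == cur_key)
      key(e[cur_edge, 3], e[cur_edge, 4]) else key(e[cur_edge, 1], e[cur_edge, 2])
    np <- np + 1L
    coords <- as.integer(strsplit(nxt_key, " ")[[1]])
    path[np, ] <- coords
    if (nxt_key == first_key) break
    cand <- adj[[nxt_key]]
    cand <- cand[!used[cand]]
    if (length(cand) == 0L) break
    cur_edge <- cand[1L]
    cur_key <- nxt_key
  }
  path <- path[seq_len(np), , drop = FALSE]
  ## doubled corner lattice -> mm; pixel centre (r, c) sits at
  ## ((r-1) * sy, (c-1) * sx), corners at +/- half spacing.
  y <- path[, 1] / 2 * spacing_yx[1]
  x <- path[, 2] / 2 * spacing_yx[2]
  poly <- cbind(x = x, y = y)
  if (polygon_area_signed(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
  poly
}

## Shoelace signed area; vertices may or may not repeat the first point.
polygon_area_signed <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(0)
  if (all(poly[1, ] == poly[n, ])) { poly <- poly[-n, , drop = FALSE]; n <- n - 1L }
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

polygon_area <- function(poly) abs(polygon_area_signed(poly))
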