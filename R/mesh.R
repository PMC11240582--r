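## Stacking a label volume into a 3D surface: the 0.5 isosurface of the
## binary label mask on the voxel lattice (cuberille surface), i.e. the
## set of voxel faces separating label voxels from the rest. The mesh is
## watertight by construction, its vertices lie on the voxel-corner
## lattice in mm (voxel centres at index x spacing), and its enclosed
## volume equals the voxel count times the voxel volume exactly.

## Voxel pairs that touch only along an edge (a 2x2 checkerboard in some
## axis-aligned plane) would give a non-manifold cuberille surface (four
## faces meeting at one edge). Filling one empty voxel of each such pair
## makes the contact face-connected, so every surface edge is shared by
## exactly two faces. Iterates until no pattern remains.
resolve_diagonal_contacts <- function(mask) {
  d <- dim(mask)
  sub <- function(m, ax, o) {
    idx <- lapply(d, seq_len)
    for (k in 1:2) idx[[ax[k]]] <- seq_len(d[ax[k]] - 1L) + o[k]
    do.call(`[`, c(list(m), idx, list(drop = FALSE)))
  }
  assign_sub <- function(m, ax, o, sel, value) {
    idx <- lapply(d, seq_len)
    for (k in 1:2) idx[[ax[k]]] <- seq_len(d[ax[k]] - 1L) + o[k]
    block <- do.call(`[`, c(list(m), idx, list(drop = FALSE)))
    block[sel] <- value
    do.call(`[<-`, c(list(m), idx, list(block)))
  }
  repeat {
    changed <- FALSE
    for (ax in list(c(1L, 2L), c(1L, 3L), c(2L, 3L))) {
      if (d[ax[1]] < 2L || d[ax[2]] < 2L) next
      a <- sub(mask, ax, c(0L, 0L)); b <- sub(mask, ax, c(1L, 1L))
      cc <- sub(mask, ax, c(1L, 0L)); e <- sub(mask, ax, c(0L, 1L))
      diag1 <- a & b & !cc & !e
      diag2 <- !a & !b & cc & e
      if (any(diag1)) { mask <- assign_sub(mask, ax, c(1L, 0L), diag1, TRUE); changed <- TRUE }
      if (any(diag2)) { mask <- assign_sub(mask, ax, c(0L, 0L), diag2, TRUE); changed <- TRUE }
    }
    if (!changed) break
  }
  mask
}

#' Triangle surface mesh of one label in a volume
#'
#' @param volume a [label_volume()].
#' @param label label code to mesh; must be present.
#' @param smooth_passes optional number of in-plane 3x3 majority passes
#'   applied to the binary mask before meshing (0 = none); smoothing
#'   trades exact voxel fidelity for visual regularity.
#' @return an object of class `surface_mesh`: list with `vertices`
#'   (n x 3 matrix of (x, y, z) mm coordinates), `faces` (m x 3 integer
#'   matrix, outward-oriented), `label`.
#' @export
stack_to_mesh <- function(volume, label, smooth_passes = 0L) {
  validate_label_volume(volume)
  mask <- volume$voxels == label
  if (!any(mask)) stop_validation("label %s not present in volume", label)
  if (smooth_passes > 0L) {
    for (z in seq_len(dim(mask)[1]))
      mask[z, , ] <- majority_smooth(mask[z, , ], smooth_passes)
    if (!any(mask)) stop_validation("smoothing removed all voxels of label %s", label)
  }
  mask <- resolve_diagonal_contacts(mask)
  d <- dim(mask)  # (z, y, x)
  sp <- volume$spacing
  ## pad with background on all sides so outer faces are emitted
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask

  ## for each axis and direction, voxels whose neighbour is background
  quads <- list()
  core_idx <- which(mask, arr.ind = TRUE)  # (z, y, x), 1-based
  neighbour_bg <- function(dz, dy, dx) {
    sub <- cbind(core_idx[, 1] + 1L + dz, core_idx[, 2] + 1L + dy,
                 core_idx[, 3] + 1L + dx)
    !pad[sub]
  }
  ## voxel centre (0-based index) * spacing; corners at centre +/- half
  cz <- (core_idx[, 1] - 1L) * sp[1]
  cy <- (core_idx[, 2] - 1L) * sp[2]
  cx <- (core_idx[, 3] - 1L) * sp[3]
  hz <- sp[1] / 2; hy <- sp[2] / 2; hx <- sp[3] / 2

  ## each face: 4 corners (x, y, z), counterclockwise seen from outside
  face_defs <- list(
    list(dz = -1L, dy = 0L, dx = 0L,  # -z face, normal (0,0,-1)
         corners = list(c(-1, -1, -1), c(-1, 1, -1), c(1, 1, -1), c(1, -1, -1))),
    list(dz = 1L, dy = 0L, dx = 0L,   # +z face, normal (0,0,+1)
         corners = list(c(-1, -1, 1), c(1, -1, 1), c(1, 1, 1), c(-1, 1, 1))),
    list(dz = 0L, dy = -1L, dx = 0L,  # -y face, normal (0,-1,0)
         corners = list(c(-1, -1, -1), c(1, -1, -1), c(1, -1, 1), c(-1, -1, 1))),
    list(dz = 0L, dy = 1L, dx = 0L,   # +y face, normal (0,+1,0)
         corners = list(c(-1, 1, -1), c(-1, 1, 1), c(1, 1, 1), c(1, 1, -1))),
    list(dz = 0L, dy = 0L, dx = -1L,  # -x face, normal (-1,0,0)
         corners = list(c(-1, -1, -1), c(-1, -1, 1), c(-1, 1, 1), c(-1, 1, -1))),
    list(dz = 0L, dy = 0L, dx = 1L,   # +x face, normal (+1,0,0)
         corners = list(c(1, -1, -1), c(1, 1, -1), c(1, 1, 1), c(1, -1, 1)))
  )
  verts <- list()
  tris <- list()
  nv <- 0L
  for (fd in face_defs) {
    sel <- neighbour_bg(fd$dz, fd$dy, fd$dx)
    if (!any(sel)) next
    n <- sum(sel)
    corner_xyz <- lapply(fd$corners, function(s)
      cbind(cx[sel] + s[1] * hx, cy[sel] + s[2] * hy, cz[sel] + s[3] * hz))
    v4 <- do.call(rbind, corner_xyz)            # 4n x 3, corner-major blocks
    i1 <- nv + seq_len(n)
    i2 <- i1 + n; i3 <- i2 + n; i4 <- i3 + n
    verts[[length(verts) + 1L]] <- v4
    tris[[length(tris) + 1L]] <- rbind(cbind(i1, i2, i3), cbind(i1, i3, i4))
    nv <- nv + 4L * n
  }
  v <- do.call(rbind, verts)
  f <- do.call(rbind, tris)
  ## merge duplicate corner vertices (corners are on a half-step lattice)
  ## corners lie on the half-step lattice: 2 * coord / spacing is integral
  key <- paste(round(v[, 1] / hx / 2 * 2), round(v[, 2] / hy / 2 * 2),
               round(v[, 3] / hz / 2 * 2))
  uid <- match(key, unique(key))
  vu <- v[!duplicated(key), , drop = FALSE]
  fu <- matrix(uid[f], ncol = 3)
  colnames(vu) <- c("x", "y", "z")
  structure(list(vertices = vu, faces = fu, label = label),
            class = "surface_mesh")
}

#' Signed enclosed volume of a closed triangle mesh
#'
#' Divergence-theorem sum of signed tetrahedron volumes; positive for an
#' outward-oriented watertight mesh.
#'
#' @param mesh a `surface_mesh`.
#' @return enclosed volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Check that every mesh edge is shared by exactly two faces
#'
#' @param mesh a `surface_mesh`.
#' @return `TRUE` if watertight.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Write a surface mesh as ASCII STL
#'
#' @param mesh a `surface_mesh`.
#' @param path destination `.stl` path.
#' @param name solid name written in the file.
#' @return `path`, invisibly.
#' @export
write_mesh_stl <- function(mesh, path, name = paste0("label_", mesh$label)) {
  if (!dir.exists(dirname(path)))
    stop_io("parent directory does not exist: %s", dirname(path))
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  u <- b - a; w <- c_ - a
  nrm <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
               u[, 3] * w[, 1] - u[, 1] * w[, 3],
               u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  fmt <- paste0(" facet normal %.9g %.9g %.9g\n  outer loop\n",
                "   vertex %.9g %.9g %.9g\n   vertex %.9g %.9g %.9g\n",
                "   vertex %.9g %.9g %.9g\n  endloop\n endfacet")
  writeLines(sprintf(fmt, nrm[, 1], nrm[, 2], nrm[, 3],
                     a[, 1], a[, 2], a[, 3], b[, 1], b[, 2], b[, 3],
                     c_[, 1], c_[, 2], c_[, 3]), con)
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}
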