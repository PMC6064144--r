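#' Named ROI masks aligned to a grid geometry
#'
#' @param rois named list of logical arrays, each with exactly the geometry's
#'   shape.
#' @param geom grid geometry (see [geometry()]).
#' @return a `structure_set`.
#' @export
structure_set <- function(rois = list(), geom) {
  stopifnot(is.list(rois))
  if (length(rois) && is.null(names(rois)))
    stop("structure_set: ROIs must be named")
  for (nm in names(rois)) {
    m <- rois[[nm]]
    if (!is.logical(m) || !identical(as.integer(dim(m)), as.integer(geom$shape)))
      stop(sprintf("structure_set: ROI '%s' does not match the declared shape", nm))
  }
  structure(list(rois = rois, geometry = geom), class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d ROI(s) on %s grid\n", length(x$rois),
              paste(x$geometry$shape, collapse = " x ")))
  for (nm in names(x$rois))
    cat(sprintf("  %-16s %d voxels\n", nm, sum(x$rois[[nm]])))
  invisible(x)
}

#' Fetch one ROI mask, insisting it is non-empty
#'
#' @param structures a [structure_set()].
#' @param name ROI name.
#' @return logical array.
#' @export
roi_mask <- function(structures, name) {
  m <- structures$rois[[name]]
  if (is.null(m)) stop(sprintf("validation error: no ROI named '%s'", name))
  if (!any(m)) stop(sprintf("validation error: ROI '%s' is empty", name))
  m
}

# Even-odd point-in-polygon test, vectorised over points.
# poly: n x 2 matrix of vertices (closed implicitly); px, py: point coords.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterise planar contours into ROI masks
#'
#' Each ROI is a list of closed planar contours parallel to the grid's xy
#' slices. A voxel belongs to the ROI iff its centre lies inside the contour
#' polygon of its slice under the even-odd rule, so holes (a contour inside a
#' contour on the same slice) are carved out, matching RT-STRUCT semantics.
#'
#' @param contours named list; each element is a list of contours, a contour
#'   being `list(points = <n x 2 matrix of (x, y) mm>, z = <slice position mm>)`.
#' @param geom 3-D grid geometry the masks are rasterised onto.
#' @param tol_mm contours are assigned to the nearest slice; a contour farther
#'   than `tol_mm` from every slice triggers a warning and is dropped.
#' @return a [structure_set()] on `geom`.
#' @export
rasterize_contours <- function(contours, geom, tol_mm = NULL) {
  stopifnot(length(geom$shape) == 3)
  if (is.null(tol_mm)) tol_mm <- geom$spacing[3] / 2 + 1e-6
  nx <- geom$shape[1]; ny <- geom$shape[2]; nz <- geom$shape[3]
  xs <- geom$origin[1] + (seq_len(nx) - 1) * geom$spacing[1]
  ys <- geom$origin[2] + (seq_len(ny) - 1) * geom$spacing[2]
  zs <- geom$origin[3] + (seq_len(nz) - 1) * geom$spacing[3]
  px <- rep(xs, times = ny)
  py <- rep(ys, each = nx)
  rois <- list()
  for (nm in names(contours)) {
    mask <- array(FALSE, geom$shape)
    any_hit <- FALSE
    for (ct in contours[[nm]]) {
      poly <- as.matrix(ct$points)
      if (nrow(poly) < 3) next
      dz <- abs(zs - ct$z)
      k <- which.min(dz)
      if (dz[k] > tol_mm) next
      any_hit <- TRUE
      inside <- point_in_polygon(px, py, poly)
      mask[, , k] <- xor(mask[, , k], matrix(inside, nx, ny))
    }
    if (length(contours[[nm]]) && !any_hit)
      warning(sprintf("ROI '%s': no contour lies on a grid slice; mask is empty", nm))
    rois[[nm]] <- mask
  }
  structure_set(rois, geom)
}
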