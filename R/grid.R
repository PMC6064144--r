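#' Axis-aligned scalar grid
#'
#' The basic volumetric container of the package: a 2-D or 3-D scalar field on
#' a regular axis-aligned grid with voxel-centre geometry. The value array is
#' stored x-fastest (`dim = c(nx, ny)` or `c(nx, ny, nz)`); the physical
#' coordinate of voxel `(i, j, k)` (1-based) is
#' `origin + ((i-1)*sx, (j-1)*sy, (k-1)*sz)`, all in millimetres, with
#' `origin` at the centre of the first voxel.
#'
#' @param values numeric array, 2-D or 3-D; all values must be finite.
#' @param origin numeric, physical coordinate (mm) of the centre of the first
#'   voxel; length equal to the array dimensionality.
#' @param spacing numeric, voxel spacing (mm), strictly positive, same length
#'   as `origin`.
#' @param unit character, one of `"Gy"`, `"g/cm3"`, `"HU"`, `"percent"`,
#'   `"dimensionless"`.
#' @return An object of class `scalar_grid`.
#' @examples
#' g <- scalar_grid(array(1, c(4, 4, 4)), spacing = c(3, 3, 3), unit = "Gy")
#' grid_geometry(g)
#' @export
scalar_grid <- function(values, origin = NULL, spacing = NULL,
                        unit = c("dimensionless", "Gy", "g/cm3", "HU", "percent")) {
  unit <- match.arg(unit)
  if (is.null(dim(values))) dim(values) <- length(values)
  nd <- length(dim(values))
  if (!nd %in% c(2L, 3L)) stop("scalar_grid: values must be a 2-D or 3-D array")
  if (is.null(origin)) origin <- rep(0, nd)
  if (is.null(spacing)) spacing <- rep(1, nd)
  origin <- as.numeric(origin); spacing <- as.numeric(spacing)
  if (length(origin) != nd || length(spacing) != nd)
    stop("scalar_grid: origin/spacing length must match array dimensionality")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("scalar_grid: all spacing components must be strictly positive")
  if (any(!is.finite(values)))
    stop("scalar_grid: all values must be finite")
  if (unit %in% c("Gy", "g/cm3") && any(values < 0))
    stop(sprintf("scalar_grid: %s grids must be non-negative", unit))
  structure(list(values = values, origin = origin, spacing = spacing, unit = unit),
            class = "scalar_grid")
}

#' @export
print.scalar_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<scalar_grid> %s  [%s]\n", paste(d, collapse = " x "), x$unit))
  cat(sprintf("  origin  (mm): %s\n", paste(format(x$origin), collapse = ", ")))
  cat(sprintf("  spacing (mm): %s\n", paste(format(x$spacing), collapse = ", ")))
  cat(sprintf("  range: [%g, %g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Grid geometry descriptor
#'
#' @param x a `scalar_grid`, or the components given separately.
#' @return list with `shape`, `origin`, `spacing`.
#' @export
grid_geometry <- function(x) {
  stopifnot(inherits(x, "scalar_grid"))
  list(shape = dim(x$values), origin = x$origin, spacing = x$spacing)
}

#' @rdname grid_geometry
#' @param shape,origin,spacing explicit geometry components (mm).
#' @export
geometry <- function(shape, origin = rep(0, length(shape)),
                     spacing = rep(1, length(shape))) {
  shape <- as.integer(shape)
  stopifnot(length(origin) == length(shape), length(spacing) == length(shape),
            all(spacing > 0), all(shape >= 1))
  list(shape = shape, origin = as.numeric(origin), spacing = as.numeric(spacing))
}

#' Test whether two grids share a geometry
#'
#' @param a,b `scalar_grid` objects.
#' @param tol absolute tolerance (mm) on origin and spacing.
#' @return logical.
#' @export
same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    length(a$origin) == length(b$origin) &&
    all(abs(a$origin - b$origin) <= tol) &&
    all(abs(a$spacing - b$spacing) <= tol)
}

stop_geometry_mismatch <- function(what) {
  stop(sprintf("geometry error: %s must share geometry (resample first)", what),
       call. = FALSE)
}

#' Physical coordinates of all voxel centres
#'
#' @param geom geometry list (see [geometry()]) or a `scalar_grid`.
#' @return numeric matrix, one row per voxel in array (x-fastest) order.
#' @keywords internal
voxel_centers <- function(geom) {
  if (inherits(geom, "scalar_grid")) geom <- grid_geometry(geom)
  axes <- lapply(seq_along(geom$shape), function(d)
    geom$origin[d] + (seq_len(geom$shape[d]) - 1) * geom$spacing[d])
  as.matrix(do.call(expand.grid, axes))
}

# Interpolate a grid at arbitrary physical points.
# pts: n x nd matrix (mm). Points outside the grid extent (beyond the outermost
# voxel centres) get `outside`. Grids are treated with the voxel-centre
# convention throughout.
grid_interp <- function(grid, pts, method = c("trilinear", "nearest"),
                        outside = NA_real_) {
  method <- match.arg(method)
  v <- grid$values
  d <- dim(v)
  nd <- length(d)
  pts <- matrix(as.numeric(pts), ncol = nd)
  n <- nrow(pts)
  # continuous 0-based index along each axis
  u <- sweep(sweep(pts, 2, grid$origin, "-"), 2, grid$spacing, "/")
  eps <- 1e-9
  inside <- rep(TRUE, n)
  for (a in seq_len(nd)) inside <- inside & u[, a] >= -eps & u[, a] <= d[a] - 1 + eps

  out <- rep(outside, n)
  if (!any(inside)) return(out)
  ui <- u[inside, , drop = FALSE]

  if (method == "nearest") {
    idx <- lapply(seq_len(nd), function(a) pmin(pmax(round(ui[, a]), 0), d[a] - 1))
    lin <- idx[[1]]
    mult <- d[1]
    if (nd >= 2) { lin <- lin + mult * idx[[2]]; mult <- mult * d[2] }
    if (nd >= 3) lin <- lin + mult * idx[[3]]
    out[inside] <- v[lin + 1]
    return(out)
  }

  i0 <- list(); fr <- list()
  for (a in seq_len(nd)) {
    f0 <- floor(ui[, a])
    f0 <- pmin(pmax(f0, 0), max(d[a] - 2, 0))  # degenerate axis (size 1) -> 0
    i0[[a]] <- f0
    fr[[a]] <- if (d[a] == 1) rep(0, nrow(ui)) else pmin(pmax(ui[, a] - f0, 0), 1)
  }
  acc <- numeric(nrow(ui))
  corners <- as.matrix(do.call(expand.grid, rep(list(0:1), nd)))
  for (r in seq_len(nrow(corners))) {
    w <- rep(1, nrow(ui))
    lin <- numeric(nrow(ui))
    mult <- 1
    for (a in seq_len(nd)) {
      c_a <- corners[r, a]
      ia <- pmin(i0[[a]] + c_a, d[a] - 1)
      w <- w * (if (c_a == 1) fr[[a]] else 1 - fr[[a]])
      lin <- lin + mult * ia
      mult <- mult * d[a]
    }
    nz <- w > 0
    if (any(nz)) acc[nz] <- acc[nz] + w[nz] * v[lin[nz] + 1]
  }
  out[inside] <- acc
  out
}

#' Resample a grid onto a new geometry
#'
#' Values are interpolated at the target voxel centres; target voxels outside
#' the source extent are filled with 0 and flagged in the `"outside"`
#' attribute (a logical array on the target geometry).
#'
#' @param grid a `scalar_grid`.
#' @param geom target geometry, from [geometry()] or [grid_geometry()].
#' @param interpolation `"trilinear"` (default) or `"nearest"`.
#' @return a `scalar_grid` on the target geometry.
#' @export
resample_to <- function(grid, geom, interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (inherits(geom, "scalar_grid")) geom <- grid_geometry(geom)
  if (any(!is.finite(grid$values)))
    stop("resample_to: source grid contains non-finite values")
  pts <- voxel_centers(geom)
  vals <- grid_interp(grid, pts, method = interpolation, outside = NA_real_)
  outside <- is.na(vals)
  vals[outside] <- 0
  g <- scalar_grid(array(vals, geom$shape), origin = geom$origin,
                   spacing = geom$spacing, unit = grid$unit)
  attr(g, "outside") <- array(outside, geom$shape)
  g
}

#' Extract a planar slice from a 3-D grid
#'
#' Interpolates the volume onto the axis-orthogonal plane at `position_mm`,
#' at the native in-plane spacing. Used e.g. to emulate a planar detector at a
#' fixed depth.
#'
#' @param dose a 3-D `scalar_grid`.
#' @param axis `"x"`, `"y"` or `"z"` (the axis normal to the plane).
#' @param position_mm physical position of the plane along `axis` (mm).
#' @return a 2-D `scalar_grid` over the remaining two axes.
#' @export
extract_plane <- function(dose, axis = c("z", "x", "y"), position_mm) {
  axis <- match.arg(axis)
  a <- match(axis, c("x", "y", "z"))
  d <- dim(dose$values)
  if (length(d) != 3) stop("extract_plane: a 3-D grid is required")
  lo <- dose$origin[a]; hi <- dose$origin[a] + (d[a] - 1) * dose$spacing[a]
  if (position_mm < lo - 1e-9 || position_mm > hi + 1e-9)
    stop(sprintf("geometry error: plane position %g mm outside extent [%g, %g]",
                 position_mm, lo, hi), call. = FALSE)
  keep <- setdiff(1:3, a)
  geom2 <- geometry(d[keep], dose$origin[keep], dose$spacing[keep])
  pts2 <- voxel_centers(geom2)
  pts3 <- matrix(0, nrow(pts2), 3)
  pts3[, keep] <- pts2
  pts3[, a] <- position_mm
  vals <- grid_interp(dose, pts3, method = "trilinear", outside = 0)
  scalar_grid(array(vals, geom2$shape), origin = geom2$origin,
              spacing = geom2$spacing, unit = dose$unit)
}
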