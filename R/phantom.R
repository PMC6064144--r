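#' Geometric primitives for phantom construction
#'
#' Shapes are axis-aligned and defined in physical mm coordinates:
#' `sphere(center, radius)`, `ellipsoid(center, semi_axes)`,
#' `zcylinder(center_xy, radius, z_range)` (axis parallel to z), and
#' `cuboid(lower, upper)`.
#'
#' @param center,center_xy,lower,upper physical coordinates (mm).
#' @param radius,semi_axes,z_range sizes (mm).
#' @param density mass density assigned inside (g/cm3).
#' @param roi optional ROI name; primitives sharing a name are unioned.
#' @return a `phantom_insert`.
#' @name phantom_primitives
NULL

new_insert <- function(type, params, density, roi) {
  stopifnot(is.numeric(density), density >= 0.0012, density <= 3.0)
  structure(c(list(type = type, density = density, roi = roi), params),
            class = "phantom_insert")
}

#' @rdname phantom_primitives
#' @export
sphere <- function(center, radius, density, roi = NULL)
  new_insert("sphere", list(center = center, radius = radius), density, roi)

#' @rdname phantom_primitives
#' @export
ellipsoid <- function(center, semi_axes, density, roi = NULL)
  new_insert("ellipsoid", list(center = center, semi_axes = semi_axes), density, roi)

#' @rdname phantom_primitives
#' @export
zcylinder <- function(center_xy, radius, z_range = c(-Inf, Inf), density, roi = NULL)
  new_insert("zcylinder", list(center_xy = center_xy, radius = radius,
                               z_range = z_range), density, roi)

#' @rdname phantom_primitives
#' @export
cuboid <- function(lower, upper, density, roi = NULL)
  new_insert("box", list(lower = lower, upper = upper), density, roi)

insert_mask <- function(ins, pts) {
  switch(ins$type,
    sphere = rowSums(sweep(pts, 2, ins$center)^2) <= ins$radius^2,
    ellipsoid = rowSums(sweep(sweep(pts, 2, ins$center), 2, ins$semi_axes, "/")^2) <= 1,
    zcylinder = (pts[, 1] - ins$center_xy[1])^2 + (pts[, 2] - ins$center_xy[2])^2 <=
      ins$radius^2 & pts[, 3] >= ins$z_range[1] & pts[, 3] <= ins$z_range[2],
    box = {
      m <- rep(TRUE, nrow(pts))
      for (a in 1:3) m <- m & pts[, a] >= ins$lower[a] & pts[, a] <= ins$upper[a]
      m
    },
    stop(sprintf("unknown insert type '%s'", ins$type)))
}

#' Phantom specification
#'
#' A heterogeneous anatomy stand-in: an elliptical-cylinder body of soft
#' tissue (1.0 g/cm3) surrounded by air, with density inserts (lung 0.26,
#' trabecular bone 1.2, cortical bone 1.85, air cavities 0.0012, ...) applied
#' in order, later inserts overwriting earlier ones. Inserts with an `roi`
#' name also define structure-set masks; the body contributes a `BODY` ROI.
#' The default 3 mm cubic spacing matches a typical Monte Carlo dose grid.
#'
#' @param shape grid shape `(nx, ny, nz)`.
#' @param spacing voxel spacing (mm), default `c(3, 3, 3)`.
#' @param body_semi_axes in-plane semi-axes (mm) of the body ellipse; use
#'   large values to fill the whole grid (e.g. a water tank).
#' @param body_density body density, default 1.0 g/cm3.
#' @param outside_density density outside the body, default air 0.0012.
#' @param inserts list of [phantom_primitives].
#' @param origin grid origin; default centres the grid on (0, 0, 0).
#' @return a `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(40, 40, 16), spacing = c(3, 3, 3),
                         body_semi_axes = c(55, 45),
                         body_density = 1.0, outside_density = 0.0012,
                         inserts = list(), origin = NULL) {
  shape <- as.integer(shape)
  if (is.null(origin)) origin <- -(shape - 1) * spacing / 2
  for (ins in inserts)
    if (!inherits(ins, "phantom_insert")) stop("inserts must be phantom primitives")
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 origin = as.numeric(origin),
                 body_semi_axes = as.numeric(body_semi_axes),
                 body_density = body_density, outside_density = outside_density,
                 inserts = inserts),
            class = "phantom_spec")
}

#' Build the density grid and structure set of a phantom
#'
#' Deterministic: the same spec always yields bit-identical grids. An insert
#' with voxels outside the body is rejected, except when the body fills the
#' grid.
#'
#' @param spec a [phantom_spec()].
#' @return list with `density` (a `scalar_grid`, g/cm3) and `structures`
#'   (a [structure_set()]).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geom <- geometry(spec$shape, spec$origin, spec$spacing)
  pts <- voxel_centers(geom)
  body <- (pts[, 1] / spec$body_semi_axes[1])^2 +
    (pts[, 2] / spec$body_semi_axes[2])^2 <= 1
  rho <- ifelse(body, spec$body_density, spec$outside_density)
  rois <- list(BODY = array(body, spec$shape))
  for (ins in spec$inserts) {
    m <- insert_mask(ins, pts)
    if (!any(m))
      stop(sprintf("validation error: insert%s covers no voxel",
                   if (is.null(ins$roi)) "" else paste0(" '", ins$roi, "'")))
    if (any(m & !body))
      stop(sprintf("validation error: insert%s extends outside the body",
                   if (is.null(ins$roi)) "" else paste0(" '", ins$roi, "'")))
    rho[m] <- ins$density
    if (!is.null(ins$roi)) {
      prev <- rois[[ins$roi]]
      if (is.null(prev)) prev <- array(FALSE, spec$shape)
      rois[[ins$roi]] <- prev | array(m, spec$shape)
    }
  }
  list(density = scalar_grid(array(rho, spec$shape), spec$origin, spec$spacing,
                             "g/cm3"),
       structures = structure_set(rois, geom))
}

#' Treatment-plan specification for the pseudo-IMRT dose generator
#'
#' @param prescription_gy prescription dose (Gy), > 0.
#' @param n_beams number of equally spaced coplanar beams (default 9).
#' @param penumbra_sigma_mm Gaussian penumbra width (mm).
#' @param attenuation_per_mm effective exponential attenuation along depth
#'   (1/mm); 0.004 approximates a 6 MV beam in water.
#' @param aperture_margin_mm field margin beyond the PTV projection (mm).
#' @param mc_noise_percent multiplicative Gaussian noise SD (%) emulating
#'   Monte Carlo statistical uncertainty; default 0 (off).
#' @param seed integer seed for the noise stream.
#' @return a `plan_spec`.
#' @export
plan_spec <- function(prescription_gy, n_beams = 9, penumbra_sigma_mm = 5,
                      attenuation_per_mm = 0.004, aperture_margin_mm = 6,
                      mc_noise_percent = 0, seed = 1) {
  stopifnot(prescription_gy > 0, n_beams >= 1, penumbra_sigma_mm > 0,
            mc_noise_percent >= 0)
  structure(list(prescription_gy = prescription_gy, n_beams = n_beams,
                 penumbra_sigma_mm = penumbra_sigma_mm,
                 attenuation_per_mm = attenuation_per_mm,
                 aperture_margin_mm = aperture_margin_mm,
                 mc_noise_percent = mc_noise_percent, seed = seed),
            class = "plan_spec")
}

# Depth of each point along a beam through the elliptical body cylinder:
# length of the upstream ray segment inside the ellipse.
beam_depth <- function(pts, dir2, semi, body_center = c(0, 0)) {
  qx <- pts[, 1] - body_center[1]; qy <- pts[, 2] - body_center[2]
  A <- semi[1]; B <- semi[2]
  a <- (dir2[1] / A)^2 + (dir2[2] / B)^2
  b <- -2 * (qx * dir2[1] / A^2 + qy * dir2[2] / B^2)
  c0 <- (qx / A)^2 + (qy / B)^2 - 1
  disc <- b^2 - 4 * a * c0
  depth <- numeric(nrow(pts))
  hit <- disc > 0
  s <- sqrt(pmax(disc, 0))
  t1 <- (-b - s) / (2 * a); t2 <- (-b + s) / (2 * a)
  depth[hit] <- pmax(t2[hit], 0) - pmax(t1[hit], 0)
  depth
}

# Flat aperture of half-width a convolved with a Gaussian penumbra.
aperture_profile <- function(l, a, sigma)
  stats::pnorm((a - l) / sigma) + stats::pnorm((a + l) / sigma) - 1

#' Generate a pseudo-IMRT dose-to-medium distribution
#'
#' Superposes `n_beams` equally spaced coplanar beams aimed at the PTV
#' centroid. Each beam is an analytic model — a flat aperture matched to the
#' PTV projection with a Gaussian penumbra, attenuated exponentially with the
#' geometric depth inside the body — not a particle transport simulation: the
#' analysis stages only need realistic conformal dose shapes with known
#' ground truth. The result is normalised so that the PTV's D50% equals the
#' prescription; optional seeded multiplicative Gaussian noise emulates Monte
#' Carlo statistical uncertainty (applied before normalisation).
#'
#' @param phantom a [make_phantom()] result.
#' @param plan a [plan_spec()].
#' @param ptv name of the target ROI (default `"PTV"`).
#' @param spec the [phantom_spec()] the phantom was built from (used for the
#'   body outline); defaults to an outline refit from the BODY mask extents.
#' @return a dose `scalar_grid` (Gy), labelled Dm.
#' @export
make_dose <- function(phantom, plan, ptv = "PTV", spec = NULL) {
  stopifnot(inherits(plan, "plan_spec"))
  mask <- roi_mask(phantom$structures, ptv)
  geom <- phantom$structures$geometry
  pts <- voxel_centers(geom)
  ptv_pts <- pts[as.vector(mask), , drop = FALSE]
  iso <- colMeans(ptv_pts)
  semi <- if (!is.null(spec)) spec$body_semi_axes else {
    body <- pts[as.vector(phantom$structures$rois$BODY), 1:2, drop = FALSE]
    c(max(abs(body[, 1])), max(abs(body[, 2]))) + 1e-6
  }
  a_z <- max(abs(ptv_pts[, 3] - iso[3])) + plan$aperture_margin_mm
  l2 <- pts[, 3] - iso[3]
  total <- numeric(nrow(pts))
  for (b in seq_len(plan$n_beams)) {
    th <- 2 * pi * (b - 1) / plan$n_beams
    d2 <- c(-sin(th), -cos(th))            # direction of travel, toward iso
    e1 <- c(cos(th), -sin(th))             # in-plane lateral axis
    rel <- sweep(pts[, 1:2, drop = FALSE], 2, iso[1:2])
    l1 <- rel %*% e1
    a_1 <- max(abs(sweep(ptv_pts[, 1:2, drop = FALSE], 2, iso[1:2]) %*% e1)) +
      plan$aperture_margin_mm
    depth <- beam_depth(pts[, 1:2, drop = FALSE], d2, semi)
    total <- total +
      aperture_profile(as.numeric(l1), a_1, plan$penumbra_sigma_mm) *
      aperture_profile(l2, a_z, plan$penumbra_sigma_mm) *
      exp(-plan$attenuation_per_mm * depth)
  }
  if (plan$mc_noise_percent > 0)
    total <- total * pmax(with_seed(plan$seed,
      stats::rnorm(length(total), 1, plan$mc_noise_percent / 100)), 0)
  dose <- scalar_grid(array(pmax(total, 0), geom$shape), geom$origin,
                      geom$spacing, "Gy")
  d50 <- d_at_volume(compute_dvh(dose, mask, roi = ptv), 50)
  scalar_grid(dose$values * (plan$prescription_gy / d50), geom$origin,
              geom$spacing, "Gy")
}

#' Perturb a planar dose into a pseudo-measurement
#'
#' Emulates a detector-plane measurement that disagrees with the plan:
#' an in-plane rigid shift (trilinear resampling), a global scale error, then
#' seeded multiplicative Gaussian noise, in that order. With all three at
#' zero the plane is returned unchanged.
#'
#' @param dose_plane 2-D `scalar_grid` (Gy).
#' @param scale_error_percent global scale error (%; 3 means +3%).
#' @param shift_mm length-2 in-plane shift (mm).
#' @param noise_percent multiplicative Gaussian noise SD (%).
#' @param seed integer seed for the noise.
#' @return perturbed 2-D `scalar_grid`.
#' @export
perturb_measurement <- function(dose_plane, scale_error_percent = 0,
                                shift_mm = c(0, 0), noise_percent = 0,
                                seed = 1) {
  stopifnot(length(dim(dose_plane$values)) == 2, length(shift_mm) == 2,
            all(is.finite(dose_plane$values)))
  d <- dim(dose_plane$values)
  extent <- (d - 1) * dose_plane$spacing
  if (any(abs(shift_mm) > extent))
    stop("geometry error: shift exceeds the plane extent")
  vals <- dose_plane$values
  if (any(shift_mm != 0)) {
    pts <- voxel_centers(grid_geometry(dose_plane))
    # field shifted by s: new(x) = old(x - s); off-grid positions clamp to edge
    pts <- sweep(pts, 2, shift_mm, "-")
    for (a in 1:2) {
      lo <- dose_plane$origin[a]
      pts[, a] <- pmin(pmax(pts[, a], lo), lo + extent[a])
    }
    vals <- array(grid_interp(dose_plane, pts, method = "trilinear",
                              outside = 0), d)
  }
  vals <- vals * (1 + scale_error_percent / 100)
  if (noise_percent > 0)
    vals <- vals * pmax(with_seed(seed,
      stats::rnorm(length(vals), 1, noise_percent / 100)), 0)
  scalar_grid(pmax(vals, 0), dose_plane$origin, dose_plane$spacing, "Gy")
}

# Evaluate an expression under a temporary RNG seed, restoring global state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Disease-site phantom presets
#'
#' Four ready-made study conditions mirroring common cohorts:
#' \describe{
#'   \item{`water`}{a homogeneous water tank filling the grid — the null
#'     condition under which Dw and Dm must coincide. Prescription 60 Gy.}
#'   \item{`npc`}{head-like body with cortical bone (1.85 g/cm3) abutting the
#'     target, plus cord and parotid OARs. Prescription 70 Gy, 9 beams.}
#'   \item{`lung`}{thorax with 0.26 g/cm3 lungs, target inside lung, cord and
#'     esophagus OARs. Prescription 65 Gy, 7 beams.}
#'   \item{`bone-met`}{vertebral metastasis: target inside trabecular bone
#'     (1.2 g/cm3) with a cortical shell, cord OAR. Prescription 25 Gy,
#'     7 beams.}
#' }
#'
#' @param preset one of `"water"`, `"npc"`, `"lung"`, `"bone-met"`.
#' @param shape grid shape (default `c(40, 40, 16)` at 3 mm).
#' @return list with `spec` (a [phantom_spec()]) and `plan_defaults`
#'   (prescription and beam count for [plan_spec()]).
#' @export
phantom_preset <- function(preset = c("water", "npc", "lung", "bone-met"),
                           shape = c(40, 40, 16)) {
  preset <- match.arg(preset)
  sp <- switch(preset,
    water = phantom_spec(
      # tank large enough that every voxel is water, with realistic depths
      shape = shape, body_semi_axes = c(200, 200),
      inserts = list(
        sphere(c(0, 0, 0), 13, density = 1.0, roi = "PTV"),
        zcylinder(c(0, 30), 4, density = 1.0, roi = "Cord"))),
    npc = phantom_spec(
      shape = shape, body_semi_axes = c(55, 48),
      inserts = list(
        cuboid(c(-14, 4, -24), c(14, 20, 24), density = 1.85, roi = "Bone"),
        sphere(c(0, -8, 0), 13, density = 1.0, roi = "PTV"),
        zcylinder(c(0, 34), 4, density = 1.0, roi = "Cord"),
        sphere(c(36, 0, 0), 8, density = 1.0, roi = "Parotid"))),
    lung = phantom_spec(
      shape = shape, body_semi_axes = c(58, 45),
      inserts = list(
        zcylinder(c(-28, 0), 17, density = 0.26, roi = "Lungs"),
        zcylinder(c(28, 0), 17, density = 0.26, roi = "Lungs"),
        sphere(c(28, 0, 0), 9, density = 1.0, roi = "PTV"),
        zcylinder(c(0, 30), 4, density = 1.0, roi = "Cord"),
        zcylinder(c(0, 20), 4, density = 1.0, roi = "Esophagus"))),
    `bone-met` = phantom_spec(
      shape = shape, body_semi_axes = c(48, 40),
      inserts = list(
        zcylinder(c(0, 10), 16, density = 1.85, roi = "Bone"),
        zcylinder(c(0, 10), 12, density = 1.2),
        sphere(c(0, 10, 0), 8, density = 1.2, roi = "PTV"),
        zcylinder(c(0, 30), 4, density = 1.0, roi = "Cord"),
        zcylinder(c(-30, -12), 8, density = 0.26, roi = "Lungs"),
        zcylinder(c(30, -12), 8, density = 0.26, roi = "Lungs"))))
  plan_defaults <- switch(preset,
    water = list(prescription_gy = 60, n_beams = 9),
    npc = list(prescription_gy = 70, n_beams = 9),
    lung = list(prescription_gy = 65, n_beams = 7),
    `bone-met` = list(prescription_gy = 25, n_beams = 7))
  list(spec = sp, plan_defaults = plan_defaults, preset = preset)
}
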