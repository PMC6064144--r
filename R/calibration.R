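#' CT-number calibration
#'
#' Couples the scanner's HU to relative electron density (ED) table with a
#' continuous piecewise-linear ED to mass-density mapping, the two-step
#' calibration a Monte Carlo planning system applies before assigning
#' densities to voxels. The HU table must be strictly increasing in HU,
#' non-decreasing in ED, and anchor water at (HU = 0, ED = 1); the density
#' segments must pass through (ED = 1, 1 g/cm3).
#'
#' @param hu_ed two-column data frame or matrix `(HU, ED)`.
#' @param ed_density two-column data frame or matrix `(ED, density g/cm3)`.
#' @return a `ct_calibration`.
#' @export
ct_calibration <- function(hu_ed, ed_density) {
  hu_ed <- as.matrix(hu_ed); ed_density <- as.matrix(ed_density)
  if (nrow(hu_ed) < 2) stop("validation error: HU-to-ED table needs >= 2 points")
  if (any(diff(hu_ed[, 1]) <= 0))
    stop("validation error: HU values must be strictly increasing")
  if (any(diff(hu_ed[, 2]) < 0))
    stop("validation error: ED values must be non-decreasing in HU")
  w <- which(hu_ed[, 1] == 0)
  if (!length(w) || abs(hu_ed[w, 2] - 1) > 1e-9)
    stop("validation error: calibration must anchor water (HU = 0 -> ED = 1)")
  if (nrow(ed_density) < 2 || any(diff(ed_density[, 1]) <= 0))
    stop("validation error: ED-to-density segments must have strictly increasing ED")
  if (any(ed_density[, 2] < 0))
    stop("validation error: mass densities must be non-negative")
  if (min(abs(stats::approx(ed_density[, 1], ed_density[, 2], xout = 1,
                            rule = 2)$y - 1)) > 1e-9)
    stop("validation error: ED-to-density mapping must pass through (1, 1 g/cm3)")
  structure(list(hu_ed = unname(hu_ed), ed_density = unname(ed_density)),
            class = "ct_calibration")
}

#' Default CT calibration
#'
#' A conventional bilinear HU-to-ED curve with knots at (-1000, 0), (0, 1),
#' (1000, 1.55), (3000, 2.5), and an ED-to-density fit that is the identity in
#' the soft-tissue range and steepens for mineralised bone (cortical bone at
#' ED 1.695 mapping to 1.85 g/cm3, ICRU-44-like). Scanner-specific tables
#' should replace it in clinical use.
#'
#' @return a [ct_calibration()].
#' @export
default_ct_calibration <- function() {
  ct_calibration(
    hu_ed = cbind(HU = c(-1000, 0, 1000, 3000),
                  ED = c(0, 1, 1.55, 2.5)),
    ed_density = cbind(ED = c(0, 1, 1.695, 2.5),
                       density = c(0.0012, 1, 1.85, 2.85))
  )
}

piecewise_linear <- function(x, knots_x, knots_y) {
  stats::approx(knots_x, knots_y, xout = as.numeric(x), rule = 2, ties = "ordered")$y
}

#' Convert an HU grid to relative electron density
#'
#' Piecewise-linear interpolation through the calibration table; HU outside
#' the table are clamped to the end values (metal artefacts must not
#' extrapolate to unphysical densities).
#'
#' @param calib a [ct_calibration()].
#' @param hu a `scalar_grid` with unit `"HU"`.
#' @return a dimensionless `scalar_grid` of ED.
#' @export
hu_to_ed <- function(calib, hu) {
  stopifnot(inherits(calib, "ct_calibration"), inherits(hu, "scalar_grid"))
  ed <- piecewise_linear(hu$values, calib$hu_ed[, 1], calib$hu_ed[, 2])
  scalar_grid(array(ed, dim(hu$values)), hu$origin, hu$spacing, "dimensionless")
}

#' Convert an ED grid to mass density
#'
#' @param calib a [ct_calibration()].
#' @param ed dimensionless `scalar_grid` of relative electron density (>= 0).
#' @return a `scalar_grid` in g/cm3.
#' @export
ed_to_density <- function(calib, ed) {
  stopifnot(inherits(calib, "ct_calibration"), inherits(ed, "scalar_grid"))
  if (any(ed$values < 0)) stop("validation error: ED values must be >= 0")
  rho <- piecewise_linear(ed$values, calib$ed_density[, 1], calib$ed_density[, 2])
  scalar_grid(array(pmax(rho, 0), dim(ed$values)), ed$origin, ed$spacing, "g/cm3")
}

#' Density-indexed stopping-power-ratio model
#'
#' A monotone-by-segments piecewise-linear table mapping mass density to the
#' mean unrestricted water-to-medium mass collision stopping-power ratio
#' s_w,med of the Bragg-Gray conversion Dw = Dm * s_w,med. Outside the anchor
#' range the ratio is clamped to the end values. The table must contain the
#' water anchor (1.0 g/cm3, 1.0) exactly, and all ratios must be physically
#' plausible (within [0.9, 1.3]).
#'
#' @param anchors two-column data frame or matrix `(density g/cm3, s_w_med)`,
#'   densities strictly increasing.
#' @return an `spr_model`.
#' @export
spr_model <- function(anchors) {
  anchors <- as.matrix(anchors)
  if (nrow(anchors) < 2 || any(diff(anchors[, 1]) <= 0))
    stop("validation error: SPR anchor densities must be strictly increasing")
  if (any(anchors[, 2] < 0.9) || any(anchors[, 2] > 1.3))
    stop("validation error: SPR values must lie in [0.9, 1.3]")
  w <- which(anchors[, 1] == 1.0)
  if (!length(w) || anchors[w, 2] != 1.0)
    stop("validation error: SPR table must contain the water anchor (1.0, 1.0)")
  structure(list(anchors = unname(anchors)), class = "spr_model")
}

#' Default stopping-power-ratio table
#'
#' Anchors for tissue-like media, taken from unrestricted mass collision
#' stopping-power ratios of water to ICRU-44/46 reference media near 1 MeV:
#' air (0.0012 g/cm3) 1.113, lung (0.26) 0.999, adipose (0.95) 0.986, water
#' (1.00) 1.000, trabecular bone (1.20) 1.034, cortical bone (1.85) 1.118.
#' The ratio stays within a percent of unity for low-density tissue and
#' exceeds 1.10 for cortical bone and air, mirroring the behaviour of the
#' density-based pre-calculated tables used by Monte Carlo planning systems.
#'
#' @return an [spr_model()].
#' @export
default_spr_model <- function() {
  spr_model(cbind(
    density = c(0.0012, 0.26, 0.95, 1.00, 1.20, 1.85),
    s_w_med = c(1.113, 0.999, 0.986, 1.000, 1.034, 1.118)
  ))
}

#' Read an SPR or calibration table from CSV
#'
#' @param path CSV with a header and two numeric columns.
#' @return numeric matrix with the file's two columns.
#' @export
read_table_csv <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2) stop("format error: table CSV must have two columns")
  as.matrix(df[, 1:2])
}

#' Look up s_w,med for a density grid
#'
#' @param model an [spr_model()].
#' @param density `scalar_grid` in g/cm3, values >= 0.
#' @return dimensionless `scalar_grid` of stopping-power ratios.
#' @export
spr_lookup <- function(model, density) {
  stopifnot(inherits(model, "spr_model"), inherits(density, "scalar_grid"))
  if (any(density$values < 0)) stop("validation error: densities must be >= 0")
  s <- piecewise_linear(density$values, model$anchors[, 1], model$anchors[, 2])
  scalar_grid(array(s, dim(density$values)), density$origin, density$spacing,
              "dimensionless")
}

#' Bragg-Gray conversion between dose-to-medium and dose-to-water
#'
#' Applies Dw = Dm * s_w,med voxel-wise (`"m_to_w"`), or divides to invert
#' (`"w_to_m"`). The conversion is purely local: each voxel's dose is scaled
#' by the stopping-power ratio of its own density.
#'
#' @param dose dose `scalar_grid` (Gy).
#' @param density co-registered density `scalar_grid` (g/cm3), same geometry.
#' @param model an [spr_model()].
#' @param direction `"m_to_w"` or `"w_to_m"`.
#' @return dose `scalar_grid` (Gy) on the same geometry.
#' @examples
#' rho <- scalar_grid(array(1, c(4, 4, 4)), unit = "g/cm3")
#' dm <- scalar_grid(array(2, c(4, 4, 4)), unit = "Gy")
#' dw <- convert_dose(dm, rho, default_spr_model())  # identity in water
#' @export
convert_dose <- function(dose, density, model = default_spr_model(),
                         direction = c("m_to_w", "w_to_m")) {
  direction <- match.arg(direction)
  stopifnot(inherits(dose, "scalar_grid"), inherits(density, "scalar_grid"))
  if (!same_geometry(dose, density)) stop_geometry_mismatch("dose and density")
  s <- spr_lookup(model, density)$values
  out <- if (direction == "m_to_w") dose$values * s else dose$values / s
  scalar_grid(out, dose$origin, dose$spacing, "Gy")
}
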