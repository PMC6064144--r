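# Independent oracles and small fixture builders shared across the suite.

# --- independent bilinear interpolation (2-D, voxel-centre convention) ------
oracle_bilinear <- function(vals, origin, spacing, pts) {
  d <- dim(vals)
  ux <- (pts[, 1] - origin[1]) / spacing[1]
  uy <- (pts[, 2] - origin[2]) / spacing[2]
  out <- rep(NA_real_, nrow(pts))
  ok <- ux >= -1e-9 & ux <= d[1] - 1 + 1e-9 & uy >= -1e-9 & uy <= d[2] - 1 + 1e-9
  if (!any(ok)) return(out)
  x <- pmin(pmax(ux[ok], 0), d[1] - 1); y <- pmin(pmax(uy[ok], 0), d[2] - 1)
  i0 <- pmin(floor(x), d[1] - 2); j0 <- pmin(floor(y), d[2] - 2)
  fx <- x - i0; fy <- y - j0
  v00 <- vals[cbind(i0 + 1, j0 + 1)]; v10 <- vals[cbind(i0 + 2, j0 + 1)]
  v01 <- vals[cbind(i0 + 1, j0 + 2)]; v11 <- vals[cbind(i0 + 2, j0 + 2)]
  out[ok] <- v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
    v01 * (1 - fx) * fy + v11 * fx * fy
  out
}

# --- exhaustive fine-grid gamma oracle (2-D, local normalisation) -----------
# Brute force over a dense offset lattice of pitch `step`, scanned in order
# of increasing distance. A voxel whose running minimum is already at or
# below the next offset's pure distance term cannot improve further (any
# candidate there has gamma >= dist/dta), so it drops out — an exact cut,
# not an approximation.
oracle_gamma <- function(reference, evaluated, dd, dta,
                         threshold_percent = 10, step = dta / 50,
                         radius = 2 * dta) {
  refv <- reference$values
  d <- dim(refv)
  thr <- threshold_percent / 100 * max(refv)
  m <- floor(radius / step + 1e-9)
  ax <- step * seq(-m, m)
  offs <- as.matrix(expand.grid(ox = ax, oy = ax))
  dist2 <- rowSums(offs^2)
  keep <- dist2 <= radius^2 + 1e-9
  offs <- offs[keep, , drop = FALSE]; dist2 <- dist2[keep]
  ord <- order(dist2)
  offs <- offs[ord, , drop = FALSE]; dist2 <- dist2[ord]

  sel <- which(refv >= thr & refv > 0)
  ij <- arrayInd(sel, d)
  px <- reference$origin[1] + (ij[, 1] - 1) * reference$spacing[1]
  py <- reference$origin[2] + (ij[, 2] - 1) * reference$spacing[2]
  dr <- refv[sel]
  den <- dd / 100 * dr
  gmin2 <- rep(Inf, length(sel))
  active <- seq_along(sel)
  for (r in seq_len(nrow(offs))) {
    dfrac2 <- dist2[r] / dta^2
    active <- active[gmin2[active] > dfrac2]
    if (!length(active)) break
    ev <- oracle_bilinear(evaluated$values, evaluated$origin,
                          evaluated$spacing,
                          cbind(px[active] + offs[r, 1], py[active] + offs[r, 2]))
    ok <- !is.na(ev)
    if (!any(ok)) next
    g2 <- dfrac2 + ((ev[ok] - dr[active][ok]) / den[active][ok])^2
    tgt <- active[ok]
    imp <- g2 < gmin2[tgt]
    gmin2[tgt[imp]] <- g2[imp]
  }
  gam <- array(NA_real_, d)
  gam[sel] <- sqrt(gmin2)
  gam
}

# --- sort-based DVH quantile oracle -----------------------------------------
# Dx% from sorted samples: smallest dose still covering x% of the volume.
oracle_dx <- function(samples, x_percent) {
  s <- sort(samples, decreasing = TRUE)
  s[ceiling(x_percent / 100 * length(s))]
}

# --- winding-number point-in-polygon oracle ---------------------------------
# Signed-angle accumulation; for simple polygons it agrees with the even-odd
# rule used by the rasteriser.
oracle_inside <- function(px, py, poly) {
  n <- nrow(poly)
  total <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a1 <- atan2(poly[i, 2] - py, poly[i, 1] - px)
    a2 <- atan2(poly[j, 2] - py, poly[j, 1] - px)
    da <- a2 - a1
    if (da > pi) da <- da - 2 * pi
    if (da < -pi) da <- da + 2 * pi
    total <- total + da
  }
  abs(total) > pi
}

# --- fixture builders --------------------------------------------------------
uniform_grid <- function(value, shape = c(20, 20), spacing = 2, unit = "Gy") {
  scalar_grid(array(value, shape), spacing = rep(spacing, length(shape)),
              unit = unit)
}

# Smooth random 2-D dose plane: superposed Gaussian blobs on a floor.
random_smooth_plane <- function(seed, shape = c(30, 30), spacing = 2) {
  set.seed(seed)
  xs <- (seq_len(shape[1]) - 1) * spacing
  ys <- (seq_len(shape[2]) - 1) * spacing
  f <- array(0.3, shape)
  for (b in 1:4) {
    cx <- runif(1, min(xs), max(xs)); cy <- runif(1, min(ys), max(ys))
    amp <- runif(1, 0.5, 2); w <- runif(1, 8, 20)
    f <- f + amp * outer(exp(-(xs - cx)^2 / (2 * w^2)),
                         exp(-(ys - cy)^2 / (2 * w^2)))
  }
  scalar_grid(f, spacing = c(spacing, spacing), unit = "Gy")
}

# A phantom whose PTV sits entirely inside a cortical-bone insert, with
# enough bone margin that DVH sampling never straddles the bone boundary.
bone_ptv_case <- function(rx = 25) {
  spec <- phantom_spec(
    shape = c(32, 32, 14), body_semi_axes = c(44, 40),
    inserts = list(
      sphere(c(0, 0, 0), 18, density = 1.85, roi = "Bone"),
      sphere(c(0, 0, 0), 8, density = 1.85, roi = "PTV")))
  phantom <- make_phantom(spec)
  dm <- make_dose(phantom, plan_spec(rx, n_beams = 7), spec = spec)
  list(phantom = phantom, dm = dm, spec = spec, rx = rx)
}
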