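#' Prescription-normalised dose-difference map
#'
#' Voxel-wise `diff(%) = (Dw - Dm) / Dp * 100`, the plan-subtraction view of
#' the conversion: positive where dose-to-water exceeds dose-to-medium.
#'
#' @param dw,dm dose `scalar_grid`s (Gy) on the same geometry.
#' @param prescription_gy prescription dose Dp (Gy), > 0.
#' @return a `scalar_grid` with unit `"percent"` carrying attribute
#'   `"prescription_gy"`.
#' @export
dose_diff_map <- function(dw, dm, prescription_gy) {
  stopifnot(prescription_gy > 0)
  if (!same_geometry(dw, dm)) stop_geometry_mismatch("Dw and Dm")
  g <- scalar_grid((dw$values - dm$values) / prescription_gy * 100,
                   dw$origin, dw$spacing, "percent")
  attr(g, "prescription_gy") <- prescription_gy
  g
}

#' Gamma-analysis parameters
#'
#' Local-normalisation gamma: the dose-difference criterion is a percentage
#' of the local reference dose, and voxels below the low-dose threshold
#' (a percentage of the reference maximum by default, or of the prescription)
#' are excluded from evaluation and from the passing rate.
#'
#' @param dd_percent dose-difference criterion (% of local reference dose).
#' @param dta_mm distance-to-agreement criterion (mm).
#' @param low_dose_threshold_percent exclusion threshold (default 10).
#' @param threshold_of `"max"` (of the reference distribution, default) or
#'   `"prescription"`; the latter needs `prescription_gy`.
#' @param prescription_gy prescription dose, only for
#'   `threshold_of = "prescription"`.
#' @param search_radius_factor search radius as a multiple of `dta_mm`
#'   (default 2: beyond that the distance term alone gives gamma >= 2, so the
#'   cap cannot change pass/fail).
#' @param interp_step_mm dense-search step for the evaluated dose (default
#'   `dta_mm / 5`); a local refinement at a tenth of this step around the
#'   coarse optimum is applied unless `refine = FALSE`.
#' @param refine logical, apply the sub-step refinement pass.
#' @return a `gamma_params` list.
#' @export
gamma_params <- function(dd_percent, dta_mm, low_dose_threshold_percent = 10,
                         threshold_of = c("max", "prescription"),
                         prescription_gy = NULL,
                         search_radius_factor = 2.0,
                         interp_step_mm = NULL, refine = TRUE) {
  threshold_of <- match.arg(threshold_of)
  stopifnot(dd_percent > 0, dta_mm > 0,
            low_dose_threshold_percent >= 0, low_dose_threshold_percent < 100,
            search_radius_factor > 0)
  if (threshold_of == "prescription" && is.null(prescription_gy))
    stop("usage error: threshold_of = 'prescription' needs `prescription_gy`")
  if (is.null(interp_step_mm)) interp_step_mm <- dta_mm / 5
  structure(list(dd_percent = dd_percent, dta_mm = dta_mm,
                 low_dose_threshold_percent = low_dose_threshold_percent,
                 threshold_of = threshold_of, prescription_gy = prescription_gy,
                 normalization = "local",
                 search_radius_factor = search_radius_factor,
                 interp_step_mm = interp_step_mm, refine = refine),
            class = "gamma_params")
}

# Cell-wise upper bound on the gradient norm of the grid's trilinear
# interpolant: within a cell each gradient component is bounded by the
# steepest edge slope of that cell along the axis. The result is dilated by
# one cell (max filter) so it also bounds points up to one cell away.
interp_lipschitz_cells <- function(grid) {
  v <- grid$values
  d <- dim(v)
  nd <- length(d)
  dc <- pmax(d - 1L, 1L)              # cell-grid shape
  l2 <- array(0, dc)
  for (a in seq_len(nd)) {
    if (d[a] < 2) next
    di <- abs_diff_along(v, a)          # edge slopes along axis a
    for (b in seq_len(nd)[-a]) {
      if (d[b] < 2) next
      di <- pmax_along(di, b)           # max over the cell's parallel edges
    }
    l2 <- l2 + (di / grid$spacing[a])^2
  }
  lip <- sqrt(l2)
  for (b in seq_len(nd)) if (dc[b] > 1) lip <- dilate_along(lip, b)
  list(values = lip, shape = dc)
}

# column minima of a matrix (max.col is C-level, unlike apply)
col_mins <- function(m) {
  tm <- t(m)
  idx <- max.col(-tm, ties.method = "first")
  tm[cbind(seq_len(nrow(tm)), idx)]
}

# |x[i+1] - x[i]| along axis b, reducing that axis by one, dims preserved
abs_diff_along <- function(x, b) {
  d <- dim(x)
  i1 <- lapply(d, seq_len); i2 <- i1
  i1[[b]] <- seq_len(d[b] - 1L); i2[[b]] <- 2:d[b]
  abs(do.call(`[`, c(list(x), i2, drop = FALSE)) -
        do.call(`[`, c(list(x), i1, drop = FALSE)))
}

# pairwise max of an array with itself shifted by one along axis b, reducing
# that axis by one (cell collapse)
pmax_along <- function(x, b) {
  d <- dim(x)
  i1 <- lapply(d, seq_len); i2 <- i1
  i1[[b]] <- seq_len(d[b] - 1L); i2[[b]] <- 2:d[b]
  pmax(do.call(`[`, c(list(x), i1, drop = FALSE)),
       do.call(`[`, c(list(x), i2, drop = FALSE)))
}

# one-cell max dilation along axis b (shape preserved)
dilate_along <- function(x, b) {
  d <- dim(x)
  lo <- lapply(d, seq_len); hi <- lo
  lo[[b]] <- pmax(seq_len(d[b]) - 1L, 1L)
  hi[[b]] <- pmin(seq_len(d[b]) + 1L, d[b])
  pmax(x, do.call(`[`, c(list(x), lo, drop = FALSE)),
       do.call(`[`, c(list(x), hi, drop = FALSE)))
}

# look up the cell-Lipschitz bound at physical points (clamped to the grid)
lip_at <- function(lipcells, grid, pts) {
  d <- lipcells$shape
  u <- sweep(sweep(pts, 2, grid$origin, "-"), 2, grid$spacing, "/")
  lin <- 0; mult <- 1
  for (a in seq_along(d)) {
    ia <- pmin(pmax(floor(u[, a]), 0), d[a] - 1)
    lin <- lin + mult * ia
    mult <- mult * d[a]
  }
  lipcells$values[lin + 1]
}

# Offset lattice, sorted by distance (zero first). `shape = "ball"` trims to
# the search radius; `shape = "box"` keeps the full cube (used to cover a
# coarse cell completely during refinement).
gamma_offsets <- function(nd, step, radius, shape = c("ball", "box")) {
  shape <- match.arg(shape)
  m <- floor(radius / step + 1e-9)
  axis <- step * seq(-m, m)
  offs <- as.matrix(do.call(expand.grid, rep(list(axis), nd)))
  dist2 <- rowSums(offs^2)
  if (shape == "ball") {
    keep <- dist2 <= radius^2 + 1e-9
    offs <- offs[keep, , drop = FALSE]
    dist2 <- dist2[keep]
  }
  ord <- order(dist2)
  list(offsets = unname(offs[ord, , drop = FALSE]), dist2 = dist2[ord])
}

#' Gamma-index map between two dose distributions
#'
#' For every reference voxel at or above the low-dose threshold,
#' `gamma = min over positions r of sqrt((|r - r_ref| / dta)^2 +
#' ((D_eval(r) - D_ref) / (dd/100 * D_ref))^2)`, with the evaluated dose
#' interpolated trilinearly. The minimisation is a dense search on a lattice
#' of step `interp_step_mm` within the search radius, followed by a local
#' refinement (a tenth of the step) around the coarse optimum. Candidate
#' positions outside the evaluated grid's extent are skipped. Works for 2-D
#' planes and 3-D volumes.
#'
#' @param reference,evaluated dose `scalar_grid`s on the same geometry.
#' @param params a [gamma_params()].
#' @return a `gamma_result`: list with `gamma` (array, `NA` where not
#'   evaluated), `evaluated_mask`, `passing_rate` (% of evaluated voxels with
#'   gamma <= 1), `n_evaluated`, `params`, and the grid `geometry`.
#' @export
gamma_map <- function(reference, evaluated, params) {
  stopifnot(inherits(params, "gamma_params"))
  if (!same_geometry(reference, evaluated))
    stop_geometry_mismatch("reference and evaluated")
  refv <- as.numeric(reference$values)
  d <- dim(reference$values)
  nd <- length(d)
  thr_base <- if (params$threshold_of == "max") max(refv) else params$prescription_gy
  thr <- params$low_dose_threshold_percent / 100 * thr_base
  eval_idx <- which(refv >= thr & refv > 0)
  if (!length(eval_idx))
    stop("empty-evaluation error: every reference voxel is below the low-dose threshold")

  pos_all <- voxel_centers(grid_geometry(reference))
  pos <- pos_all[eval_idx, , drop = FALSE]
  ref_e <- refv[eval_idx]
  denom <- params$dd_percent / 100 * ref_e   # local normalisation
  dta <- params$dta_mm
  radius <- params$search_radius_factor * dta
  step <- params$interp_step_mm

  off <- gamma_offsets(nd, step, radius)
  n_off <- nrow(off$offsets)
  n_e <- length(eval_idx)
  gmin2 <- rep(Inf, n_e)
  # offsets are scanned in blocks, nearest first; a voxel whose running
  # minimum is at or below the block's smallest distance term cannot improve
  # there (gamma >= dist/dta), an exact cut
  blk <- 64L
  i0 <- 1L
  while (i0 <= n_off) {
    block <- i0:min(i0 + blk - 1L, n_off)
    nb <- length(block)
    active <- which(gmin2 > off$dist2[block[1]] / dta^2)
    if (!length(active)) break
    na <- length(active)
    p <- pos[rep(active, each = nb), , drop = FALSE] +
      off$offsets[rep(block, na), , drop = FALSE]
    ev <- grid_interp(evaluated, p, method = "trilinear", outside = NA_real_)
    g2 <- off$dist2[rep(block, na)] / dta^2 +
      ((ev - ref_e[rep(active, each = nb)]) / denom[rep(active, each = nb)])^2
    g2[is.na(g2)] <- Inf
    g2min <- col_mins(matrix(g2, nrow = nb))
    gmin2[active] <- pmin(gmin2[active], g2min)
    i0 <- i0 + blk
  }

  if (params$refine) {
    # Second pass: sub-lattice refinement. A coarse cell (half-width s/2
    # around its offset) can only contain a better optimum if the candidate
    # value at its centre, minus the largest possible within-cell change of
    # both gamma terms, undercuts the voxel's current best. The dose-term
    # change is bounded by a cell-local Lipschitz bound on the interpolant.
    halfdiag <- step / 2 * sqrt(nd)
    lipc <- interp_lipschitz_cells(evaluated)
    fine_sub <- if (nd >= 3) 5 else 10   # refinement pitch: step/10 (2-D), step/5 (3-D)
    fine <- gamma_offsets(nd, step / fine_sub, step / 2 + 1e-9, shape = "box")
    nf <- nrow(fine$offsets)
    gcur <- sqrt(gmin2)
    slack_dist <- halfdiag / dta
    i0 <- 1L
    while (i0 <= n_off) {
      block <- i0:min(i0 + blk - 1L, n_off)
      i0 <- i0 + blk
      nb <- length(block)
      dfrac_lo <- sqrt(off$dist2[block[1]]) / dta
      if (dfrac_lo - slack_dist > max(gcur)) break   # sorted by distance
      cand <- which(gcur > 1e-12 & dfrac_lo - slack_dist < gcur)
      if (!length(cand)) next
      na <- length(cand)
      vrep <- rep(cand, each = nb)
      p0 <- pos[vrep, , drop = FALSE] + off$offsets[rep(block, na), , drop = FALSE]
      ev0 <- grid_interp(evaluated, p0, method = "trilinear", outside = NA_real_)
      dfrac_r <- sqrt(off$dist2[rep(block, na)]) / dta
      g0 <- sqrt(dfrac_r^2 + ((ev0 - ref_e[vrep]) / denom[vrep])^2)
      # cells whose centre falls off-grid may still be partly inside the
      # extent: keep them under the distance-only lower bound
      g0[is.na(g0)] <- dfrac_r[is.na(g0)]
      slack <- slack_dist + lip_at(lipc, evaluated, p0) * halfdiag / denom[vrep]
      hits <- which(g0 - slack < gcur[vrep])
      if (!length(hits)) next
      hit_off <- rep(block, na)[hits]
      hit_vox <- vrep[hits]
      # flatten every triggered (voxel, cell) pair's fine lattice into large
      # interpolation batches
      for (part in split(seq_along(hits),
                         ceiling(seq_along(hits) / max(1L, 20000L %/% nf)))) {
        vox <- hit_vox[part]; offr <- hit_off[part]
        nv <- length(vox)
        tot <- fine$offsets[rep(seq_len(nf), nv), , drop = FALSE] +
          off$offsets[rep(offr, each = nf), , drop = FALSE]
        p <- pos[rep(vox, each = nf), , drop = FALSE] + tot
        ev <- grid_interp(evaluated, p, method = "trilinear", outside = NA_real_)
        g2 <- rowSums(tot^2) / dta^2 +
          ((ev - ref_e[rep(vox, each = nf)]) / denom[rep(vox, each = nf)])^2
        g2[is.na(g2)] <- Inf
        pair_min <- col_mins(matrix(g2, nrow = nf))
        upd <- tapply(pair_min, vox, min)
        uv <- as.integer(names(upd))
        imp <- upd < gmin2[uv]
        if (any(imp)) {
          gmin2[uv[imp]] <- upd[imp]
          gcur[uv[imp]] <- sqrt(upd[imp])
        }
      }
    }
  }

  gamma_arr <- array(NA_real_, d)
  gamma_arr[eval_idx] <- sqrt(gmin2)
  passing <- 100 * mean(sqrt(gmin2) <= 1 + 1e-9)
  structure(list(gamma = gamma_arr,
                 evaluated_mask = array(seq_along(refv) %in% eval_idx, d),
                 passing_rate = passing, n_evaluated = n_e,
                 params = params,
                 geometry = geometry(d, reference$origin, reference$spacing)),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %g%%&%g mm (local): passing rate %.1f%% (%d voxels evaluated)\n",
              x$params$dd_percent, x$params$dta_mm, x$passing_rate, x$n_evaluated))
  invisible(x)
}

#' Gamma passing-rate sweep over QA criteria
#'
#' Runs [gamma_map()] once per `(dd, dta)` criterion, e.g. the conventional
#' 3%&3 mm, 2%&2 mm, 1%&1 mm ladder used to probe how passing rates fall as
#' tolerances tighten.
#'
#' @param reference,evaluated dose `scalar_grid`s on the same geometry.
#' @param criteria list of `c(dd_percent, dta_mm)` pairs.
#' @param ... further arguments to [gamma_params()].
#' @return data frame with columns `dd_percent`, `dta_mm`, `passing_rate`,
#'   `n_evaluated`; the full `gamma_result`s are in the `"results"` attribute.
#' @export
gamma_sweep <- function(reference, evaluated,
                        criteria = list(c(3, 3), c(2, 2), c(1, 1)), ...) {
  stopifnot(length(criteria) >= 1)
  results <- lapply(criteria, function(cr)
    gamma_map(reference, evaluated, gamma_params(cr[1], cr[2], ...)))
  tab <- data.frame(
    dd_percent = vapply(criteria, `[`, numeric(1), 1),
    dta_mm = vapply(criteria, `[`, numeric(1), 2),
    passing_rate = vapply(results, `[[`, numeric(1), "passing_rate"),
    n_evaluated = vapply(results, `[[`, numeric(1), "n_evaluated")
  )
  attr(tab, "results") <- results
  tab
}
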