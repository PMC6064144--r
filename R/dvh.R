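#' Cumulative dose-volume histogram
#'
#' The dose is resampled trilinearly onto a cubic grid of pitch `sampling_mm`
#' (default 1 mm) restricted to the ROI's bounding box; the mask follows by
#' nearest-neighbour so binary membership is preserved. The cumulative curve
#' uses a fixed 1 cGy bin width: `cum_volume[b]` is the fraction of ROI volume
#' receiving at least the left edge of bin `b`, so the curve starts at 1,
#' is non-increasing, and ends at 0.
#'
#' @param dose dose `scalar_grid` (Gy).
#' @param mask logical array on the dose geometry (one ROI), or a
#'   [structure_set()] plus `roi`.
#' @param roi ROI name when `mask` is a structure set.
#' @param sampling_mm DVH sampling resolution (mm).
#' @return a `dvh_curve`: list with `bin_edges` (Gy), `cum_volume` (fraction),
#'   `roi_name`, `total_volume_cc`.
#' @export
compute_dvh <- function(dose, mask, roi = NULL, sampling_mm = 1.0) {
  stopifnot(inherits(dose, "scalar_grid"))
  if (inherits(mask, "structure_set")) {
    if (is.null(roi)) stop("compute_dvh: give `roi` when passing a structure_set")
    mask <- roi_mask(mask, roi)
  } else if (is.null(roi)) roi <- "ROI"
  if (!any(mask)) stop(sprintf("validation error: ROI '%s' is empty", roi))
  if (any(!is.finite(dose$values)))
    stop("validation error: dose grid contains non-finite values")

  d <- dim(dose$values)
  idx <- which(mask, arr.ind = TRUE)
  lo <- dose$origin + (apply(idx, 2, min) - 1) * dose$spacing
  hi <- dose$origin + (apply(idx, 2, max) - 1) * dose$spacing
  n_s <- pmax(floor((hi - lo) / sampling_mm) + 1L, 1L)
  geom_s <- geometry(n_s, lo, rep(sampling_mm, 3))

  pts <- voxel_centers(geom_s)
  dvals <- grid_interp(dose, pts, method = "trilinear", outside = 0)
  mgrid <- scalar_grid(array(as.numeric(mask), d), dose$origin, dose$spacing)
  mvals <- grid_interp(mgrid, pts, method = "nearest", outside = 0) >= 0.5
  samples <- dvals[mvals]
  if (!length(samples))
    stop(sprintf("validation error: ROI '%s' vanished at the DVH sampling resolution", roi))

  bin <- 0.01
  n_bins <- floor(max(samples) / bin) + 2L
  edges <- (seq_len(n_bins + 1L) - 1L) * bin
  # fraction receiving >= each left edge
  counts <- vapply(edges, function(e) sum(samples >= e), numeric(1))
  cum <- counts / length(samples)
  structure(list(bin_edges = edges, cum_volume = cum, roi_name = roi,
                 total_volume_cc = length(samples) * sampling_mm^3 / 1000),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> %s: %.2f cc, D50%% = %.2f Gy, max edge %.2f Gy\n",
              x$roi_name, x$total_volume_cc, d_at_volume(x, 50),
              max(x$bin_edges)))
  invisible(x)
}

#' Dose covering x percent of the ROI (Dx%)
#'
#' The minimum dose received by the hottest x% of the ROI volume: the smallest
#' dose d with fractional coverage >= x/100, refined by linear interpolation
#' between the bracketing histogram bin edges. Plateaus resolve to the
#' smallest qualifying dose.
#'
#' @param curve a [compute_dvh()] result.
#' @param x_percent volume percentage in (0, 100].
#' @return dose in Gy.
#' @export
d_at_volume <- function(curve, x_percent) {
  stopifnot(x_percent > 0, x_percent <= 100)
  q <- x_percent / 100
  cum <- curve$cum_volume; edges <- curve$bin_edges
  ok <- which(cum >= q - 1e-12)
  j <- max(ok)                       # last edge still covering q
  if (j == length(cum)) return(edges[j])
  # interpolate within the bin where coverage crosses q
  c0 <- cum[j]; c1 <- cum[j + 1]
  if (c0 <= c1 + 1e-15) return(edges[j])
  frac <- (c0 - q) / (c0 - c1)
  edges[j] + frac * (edges[j + 1] - edges[j])
}

#' Volume receiving at least a dose threshold (VxGy / Vx%)
#'
#' @param curve a [compute_dvh()] result.
#' @param threshold dose threshold; Gy when `percent_of_prescription = FALSE`,
#'   otherwise a percentage of `prescription_gy`.
#' @param percent_of_prescription interpret `threshold` as % of prescription.
#' @param prescription_gy prescription dose (Gy), required in percent mode.
#' @return percent of ROI volume, in [0, 100].
#' @export
v_at_dose <- function(curve, threshold, percent_of_prescription = FALSE,
                      prescription_gy = NULL) {
  stopifnot(threshold >= 0)
  if (percent_of_prescription) {
    if (is.null(prescription_gy))
      stop("usage error: percent-of-prescription thresholds need `prescription_gy`")
    threshold <- threshold / 100 * prescription_gy
  }
  100 * stats::approx(curve$bin_edges, curve$cum_volume, xout = threshold,
                      rule = 2, ties = "ordered")$y
}

#' Mean ROI dose from a DVH curve
#'
#' Integrates the cumulative curve (mean = integral of coverage over dose).
#'
#' @param curve a [compute_dvh()] result.
#' @return mean dose in Gy.
#' @export
dvh_mean <- function(curve) {
  w <- diff(curve$bin_edges)
  sum(w * (curve$cum_volume[-1] + curve$cum_volume[-length(curve$cum_volume)]) / 2)
}

#' Relative Dw-Dm difference of a DVH index
#'
#' `Diff(%) = (value_w - value_m) / value_w * 100`; the sign is preserved, so
#' an index larger under dose-to-medium comes out negative.
#'
#' @param value_w index value from the dose-to-water plan (Gy).
#' @param value_m index value from the dose-to-medium plan (Gy).
#' @return percent difference.
#' @examples
#' diff_percent(74.3, 73.6)  # 0.94
#' @export
diff_percent <- function(value_w, value_m) {
  if (any(value_w <= 0))
    stop("undefined-statistic error: Diff(%) requires value_w > 0")
  (value_w - value_m) / value_w * 100
}

#' Paired cohort comparison of a DVH index
#'
#' Two-sided paired t-test on the per-case differences `value_w - value_m`
#' (p from the Student t distribution with n-1 degrees of freedom), together
#' with the cohort mean and SD of the per-case relative differences, the
#' convention of per-index cohort reporting. When the paired differences have
#' zero variance the t statistic is degenerate; the result is then flagged and
#' p is reported as 0 for a non-zero mean difference or 1 for identical arms.
#'
#' @param value_w,value_m numeric vectors of per-case index values (Gy),
#'   equal length >= 2.
#' @return a `paired_cohort_result`: list with `n`, `mean_w`, `sd_w`,
#'   `mean_m`, `sd_m`, `diff_percent` (per case), `mean_diff_percent`,
#'   `sd_diff_percent`, `t_statistic`, `p_value`, `degenerate`.
#' @export
paired_cohort_test <- function(value_w, value_m) {
  stopifnot(length(value_w) == length(value_m), length(value_w) >= 2,
            all(is.finite(value_w)), all(is.finite(value_m)))
  dp <- diff_percent(value_w, value_m)
  d <- value_w - value_m
  degenerate <- stats::sd(d) < 1e-12 * max(1, mean(abs(c(value_w, value_m))))
  if (degenerate) {
    t_stat <- if (abs(mean(d)) < 1e-12) 0 else sign(mean(d)) * Inf
    p <- if (abs(mean(d)) < 1e-12) 1 else 0
  } else {
    tt <- stats::t.test(value_w, value_m, paired = TRUE)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  structure(list(n = length(d),
                 mean_w = mean(value_w), sd_w = stats::sd(value_w),
                 mean_m = mean(value_m), sd_m = stats::sd(value_m),
                 diff_percent = dp,
                 mean_diff = mean(d), sd_diff = stats::sd(d),
                 mean_diff_percent = mean(dp), sd_diff_percent = stats::sd(dp),
                 # Diff of cohort means, for transparency alongside the
                 # mean-of-per-case convention above
                 diff_of_means_percent = diff_percent(mean(value_w), mean(value_m)),
                 t_statistic = t_stat, p_value = p, degenerate = degenerate),
            class = "paired_cohort_result")
}

#' @export
print.paired_cohort_result <- function(x, ...) {
  cat(sprintf("<paired_cohort_result> n = %d\n", x$n))
  cat(sprintf("  Dw %.2f +/- %.2f   Dm %.2f +/- %.2f\n",
              x$mean_w, x$sd_w, x$mean_m, x$sd_m))
  cat(sprintf("  Diff(%%) %.2f +/- %.2f   t = %.3f, p = %.4g%s\n",
              x$mean_diff_percent, x$sd_diff_percent, x$t_statistic, x$p_value,
              if (x$degenerate) "  [degenerate: zero-variance differences]" else ""))
  invisible(x)
}
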