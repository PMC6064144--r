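#' Assemble a synthetic analysis case
#'
#' Builds the phantom, structures and pseudo-IMRT dose-to-medium grid for one
#' preset + seed, the synthetic stand-in for a patient CT with a Monte Carlo
#' plan.
#'
#' @param preset a [phantom_preset()] name.
#' @param seed integer seed (drives the optional MC-like noise).
#' @param prescription_gy override the preset prescription.
#' @param mc_noise_percent multiplicative noise SD (%) for the dose generator.
#' @param shape grid shape passed to the preset.
#' @return a `dose_case`: list with `id`, `preset`, `density`, `structures`,
#'   `dm`, `prescription_gy`, `seed`.
#' @export
make_case <- function(preset, seed = 1, prescription_gy = NULL,
                      mc_noise_percent = 0, shape = c(40, 40, 16)) {
  ps <- phantom_preset(preset, shape = shape)
  phantom <- make_phantom(ps$spec)
  rx <- prescription_gy %||% ps$plan_defaults$prescription_gy
  plan <- plan_spec(prescription_gy = rx, n_beams = ps$plan_defaults$n_beams,
                    mc_noise_percent = mc_noise_percent, seed = seed)
  dm <- make_dose(phantom, plan, spec = ps$spec)
  structure(list(id = sprintf("%s-%03d", preset, seed), preset = preset,
                 density = phantom$density, structures = phantom$structures,
                 dm = dm, prescription_gy = rx, seed = seed),
            class = "dose_case")
}

index_value <- function(curve, index, prescription_gy) {
  if (index == "mean") return(dvh_mean(curve))
  m <- regmatches(index, regexec("^D([0-9.]+)%$", index))[[1]]
  if (length(m)) return(d_at_volume(curve, as.numeric(m[2])))
  m <- regmatches(index, regexec("^V([0-9.]+)%$", index))[[1]]
  if (length(m)) return(v_at_dose(curve, as.numeric(m[2]),
                                  percent_of_prescription = TRUE,
                                  prescription_gy = prescription_gy))
  m <- regmatches(index, regexec("^V([0-9.]+)Gy$", index))[[1]]
  if (length(m)) return(v_at_dose(curve, as.numeric(m[2])))
  stop(sprintf("usage error: unrecognised index specification '%s'", index))
}

#' Run the full per-case analysis
#'
#' Converts the case's Dm grid to Dw with the density grid and
#' stopping-power-ratio table, computes per-ROI DVH curves and indices for
#' both plans with their relative differences, the prescription-normalised
#' 3-D difference map, and a local-gamma criteria sweep between the two plans
#' on the measurement plane (the axial plane through the target centroid,
#' reference = Dm). Deterministic given the case.
#'
#' @param case a [make_case()] result (or a compatible list).
#' @param spr an [spr_model()].
#' @param indices DVH index specifications (`"D98%"`, `"V100%"`, `"V20Gy"`,
#'   `"mean"`).
#' @param criteria gamma criteria, list of `c(dd_percent, dta_mm)`.
#' @param rois ROI names to analyse; default all but BODY.
#' @param sampling_mm DVH sampling resolution (mm).
#' @return a `case_report`: list with `id`, `dw`, `index_table` (data frame
#'   `roi, index, value_w, value_m, diff_percent`), `diff_map`,
#'   `gamma_table`, `plane_z_mm`.
#' @export
run_case <- function(case, spr = default_spr_model(),
                     indices = c("D98%", "D50%", "D2%", "mean"),
                     criteria = list(c(3, 3), c(2, 2), c(1, 1)),
                     rois = NULL, sampling_mm = 1.0) {
  dw <- convert_dose(case$dm, case$density, spr, "m_to_w")
  if (is.null(rois)) rois <- setdiff(names(case$structures$rois), "BODY")
  rows <- list()
  for (roi in rois) {
    mask <- roi_mask(case$structures, roi)
    cw <- compute_dvh(dw, mask, roi = roi, sampling_mm = sampling_mm)
    cm <- compute_dvh(case$dm, mask, roi = roi, sampling_mm = sampling_mm)
    for (idx in indices) {
      vw <- index_value(cw, idx, case$prescription_gy)
      vm <- index_value(cm, idx, case$prescription_gy)
      rows[[length(rows) + 1L]] <- data.frame(
        roi = roi, index = idx, value_w = vw, value_m = vm,
        diff_percent = if (vw > 0) diff_percent(vw, vm) else NA_real_)
    }
  }
  index_table <- do.call(rbind, rows)
  rownames(index_table) <- NULL
  diff_map <- dose_diff_map(dw, case$dm, case$prescription_gy)
  ptv_pts <- voxel_centers(case$structures$geometry)[
    as.vector(roi_mask(case$structures, "PTV")), , drop = FALSE]
  plane_z <- mean(ptv_pts[, 3])
  ref_plane <- extract_plane(case$dm, "z", plane_z)
  ev_plane <- extract_plane(dw, "z", plane_z)
  gamma_table <- gamma_sweep(ref_plane, ev_plane, criteria)
  structure(list(id = case$id, dw = dw, index_table = index_table,
                 diff_map = diff_map, gamma_table = gamma_table,
                 plane_z_mm = plane_z),
            class = "case_report")
}

#' Run a cohort and aggregate with paired statistics
#'
#' Runs [run_case()] on every case and assembles the cohort tables: per ROI
#' and index, the cohort mean and SD of the Dw and Dm values, the mean and SD
#' of the per-case relative differences (plus the difference of cohort means
#' for transparency), and the paired-t statistic and p-value; per gamma
#' criterion, the mean and SD of the passing rates.
#'
#' @param cases list of >= 2 [make_case()] results.
#' @param ... passed on to [run_case()].
#' @return a `cohort_report`: list with `case_reports`, `index_table`,
#'   `gamma_table`.
#' @export
run_cohort <- function(cases, ...) {
  if (length(cases) < 2) stop("usage error: a cohort needs at least 2 cases")
  reports <- lapply(cases, run_case, ...)
  key <- reports[[1]]$index_table[, c("roi", "index")]
  rows <- list()
  for (r in seq_len(nrow(key))) {
    vw <- vapply(reports, function(rep) rep$index_table$value_w[r], numeric(1))
    vm <- vapply(reports, function(rep) rep$index_table$value_m[r], numeric(1))
    pc <- paired_cohort_test(vw, vm)
    rows[[r]] <- data.frame(
      roi = key$roi[r], index = key$index[r],
      mean_w = pc$mean_w, sd_w = pc$sd_w, mean_m = pc$mean_m, sd_m = pc$sd_m,
      diff_mean = pc$mean_diff_percent, diff_sd = pc$sd_diff_percent,
      diff_of_means = pc$diff_of_means_percent,
      t = pc$t_statistic, p = pc$p_value, degenerate = pc$degenerate)
  }
  index_table <- do.call(rbind, rows)
  rownames(index_table) <- NULL
  g0 <- reports[[1]]$gamma_table
  rates <- sapply(reports, function(rep) rep$gamma_table$passing_rate)
  rates <- matrix(rates, nrow = nrow(g0))
  gamma_table <- data.frame(
    dd_percent = g0$dd_percent, dta_mm = g0$dta_mm,
    mean_passing_rate = apply(rates, 1, mean),
    sd_passing_rate = apply(rates, 1, stats::sd))
  structure(list(case_reports = reports, index_table = index_table,
                 gamma_table = gamma_table),
            class = "cohort_report")
}

#' Write cohort tables to CSV
#'
#' Writes `cohort_table.csv` (per ROI/index paired comparison) and
#' `gamma_table.csv` (per criterion passing-rate summary) into `dir`.
#' Output is deterministic: rerunning the same cohort yields byte-identical
#' files.
#'
#' @param cohort a [run_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_report <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$index_table, file.path(dir, "cohort_table.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$gamma_table, file.path(dir, "gamma_table.csv"),
                   row.names = FALSE)
  invisible(dir)
}
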