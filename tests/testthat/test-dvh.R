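uniform_roi_dose <- function(value = 2.0, shape = c(10, 10, 10)) {
  dose <- scalar_grid(array(value, shape), spacing = c(1, 1, 1), unit = "Gy")
  mask <- array(FALSE, shape); mask[3:8, 3:8, 3:8] <- TRUE
  list(dose = dose, mask = mask)
}

test_that("DVH of a uniform ROI is a step at the uniform dose", {
  u <- uniform_roi_dose(2.0)
  curve <- compute_dvh(u$dose, u$mask)
  expect_equal(curve$cum_volume[1], 1.0)
  expect_true(all(diff(curve$cum_volume) <= 0))
  expect_equal(curve$cum_volume[length(curve$cum_volume)], 0)
  expect_true(all(abs(diff(curve$bin_edges) - 0.01) < 1e-12))
  expect_equal(curve$cum_volume[curve$bin_edges <= 2.0],
               rep(1, sum(curve$bin_edges <= 2.0)))
  expect_equal(curve$cum_volume[curve$bin_edges > 2.0],
               rep(0, sum(curve$bin_edges > 2.0)))
  for (x in c(98, 50, 2))
    expect_equal(d_at_volume(curve, x), 2.0, tolerance = 0.011)
  expect_equal(v_at_dose(curve, 1.0), 100)
  expect_equal(v_at_dose(curve, 2.5), 0)
  expect_equal(dvh_mean(curve), 2.0, tolerance = 0.011)
})

test_that("two-level ROI gives the textbook half-volume curve and quantiles", {
  shape <- c(10, 10, 10)
  vals <- array(1.0, shape); vals[, , 6:10] <- 3.0
  dose <- scalar_grid(vals, spacing = c(1, 1, 1), unit = "Gy")
  mask <- array(TRUE, shape)
  curve <- compute_dvh(dose, mask)
  on_plateau <- curve$bin_edges > 1.0 & curve$bin_edges <= 3.0
  expect_equal(curve$cum_volume[on_plateau], rep(0.5, sum(on_plateau)))
  expect_equal(v_at_dose(curve, 2.0), 50)
  expect_equal(d_at_volume(curve, 75), 1.0, tolerance = 0.011)
  expect_equal(d_at_volume(curve, 25), 3.0, tolerance = 0.011)
  # V in percent-of-prescription mode
  expect_equal(v_at_dose(curve, 100, percent_of_prescription = TRUE,
                         prescription_gy = 2.0), 50)
  expect_error(v_at_dose(curve, 100, percent_of_prescription = TRUE),
               "usage error")
})

test_that("Dx% agrees with the sort-based oracle and orders correctly", {
  set.seed(21)
  for (rep in 1:6) {
    shape <- c(12, 12, 8)
    dose <- scalar_grid(array(runif(prod(shape), 0, 70), shape),
                        spacing = c(1, 1, 1), unit = "Gy")
    mask <- array(runif(prod(shape)) < 0.5, shape)
    if (!any(mask)) next
    curve <- compute_dvh(dose, mask)
    samples <- dose$values[mask]
    for (x in c(98, 75, 50, 25, 2))
      expect_lt(abs(d_at_volume(curve, x) - oracle_dx(samples, x)), 0.0101)
    d98 <- d_at_volume(curve, 98); d50 <- d_at_volume(curve, 50)
    d2 <- d_at_volume(curve, 2)
    expect_true(d98 <= d50 + 1e-12 && d50 <= d2 + 1e-12)
    # quasi-inverse: V(D(x)) >= x minus one bin's volume equivalent
    for (x in c(90, 50, 10))
      expect_gte(v_at_dose(curve, d_at_volume(curve, x)), x - 1)
  }
})

test_that("DVH input contracts are enforced", {
  u <- uniform_roi_dose()
  expect_error(compute_dvh(u$dose, array(FALSE, dim(u$dose$values)), roi = "PTV"),
               "'PTV' is empty")
  ss <- structure_set(list(PTV = u$mask), grid_geometry(u$dose))
  expect_equal(d_at_volume(compute_dvh(u$dose, ss, roi = "PTV"), 50), 2,
               tolerance = 0.011)
})

test_that("the relative-difference statistic matches its printed-table uses", {
  expect_equal(round(diff_percent(74.3, 73.6), 1), 0.9)
  expect_equal(round(diff_percent(78.2, 76.7), 1), 1.9)
  expect_equal(diff_percent(5.5, 5.5), 0)
  expect_lt(diff_percent(2.0, 2.2), 0)  # Dm > Dw comes out negative
  expect_error(diff_percent(0, 1), "undefined-statistic")
})

test_that("paired cohort test matches the textbook formula and flags degeneracy", {
  # constant shift: mean difference 1.0, zero-variance -> degenerate flag
  w <- c(2, 3, 4, 5); m <- c(1, 2, 3, 4)
  r <- paired_cohort_test(w, m)
  expect_equal(r$mean_diff, 1.0)
  expect_equal(r$sd_diff, 0)
  expect_true(r$degenerate)
  expect_equal(r$p_value, 0)
  # identical arms
  r0 <- paired_cohort_test(c(2, 3, 4), c(2, 3, 4))
  expect_true(r0$degenerate)
  expect_equal(r0$t_statistic, 0)
  expect_equal(r0$mean_diff_percent, 0)
  # random pairs against the direct t formula and t CDF
  set.seed(9)
  vw <- runif(10, 60, 80); vm <- vw * (1 + rnorm(10, 0, 0.02))
  r2 <- paired_cohort_test(vw, vm)
  d <- vw - vm
  t_ref <- mean(d) / (sd(d) / sqrt(length(d)))
  p_ref <- 2 * stats::pt(-abs(t_ref), df = length(d) - 1)
  expect_equal(r2$t_statistic, t_ref, tolerance = 1e-9)
  expect_equal(r2$p_value, p_ref, tolerance = 1e-9)
  expect_equal(r2$diff_percent, (vw - vm) / vw * 100, tolerance = 1e-9)
  expect_error(paired_cohort_test(1, 1), "length")
})
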