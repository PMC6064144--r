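test_that("phantom densities follow body/insert geometry", {
  spec <- phantom_spec(shape = c(20, 20, 8), body_semi_axes = c(25, 20))
  ph <- make_phantom(spec)
  body <- ph$structures$rois$BODY
  expect_true(all(ph$density$values[body] == 1.0))
  expect_true(all(ph$density$values[!body] == 0.0012))
  # inserts overwrite in order and land in the structure set
  spec2 <- phantom_spec(shape = c(20, 20, 8), body_semi_axes = c(25, 20),
                        inserts = list(sphere(c(0, 0, 0), 9, 1.85, roi = "Bone"),
                                       sphere(c(0, 0, 0), 5, 1.2, roi = "PTV")))
  ph2 <- make_phantom(spec2)
  expect_equal(sort(unique(as.numeric(ph2$density$values))),
               c(0.0012, 1.0, 1.2, 1.85))
  expect_true(all(ph2$density$values[ph2$structures$rois$PTV] == 1.2))
  # an insert escaping the body is rejected
  spec3 <- phantom_spec(shape = c(20, 20, 8), body_semi_axes = c(25, 20),
                        inserts = list(sphere(c(30, 0, 0), 5, 1.2, roi = "X")))
  expect_error(make_phantom(spec3), "outside the body")
})

test_that("rasterised sphere volume approaches the analytic volume", {
  spec <- phantom_spec(shape = c(40, 40, 40), spacing = c(1, 1, 1),
                       body_semi_axes = c(1e6, 1e6),
                       inserts = list(sphere(c(0, 0, 0), 12, 1.2, roi = "S")))
  ph <- make_phantom(spec)
  vol_voxels <- sum(ph$structures$rois$S)          # 1 mm^3 voxels
  vol_true <- 4 / 3 * pi * 12^3
  expect_lt(abs(vol_voxels - vol_true) / vol_true, 0.02)
})

test_that("phantom and dose generation are deterministic and seed-driven", {
  p1 <- make_phantom(phantom_preset("lung")$spec)
  p2 <- make_phantom(phantom_preset("lung")$spec)
  expect_identical(p1$density$values, p2$density$values)
  expect_identical(p1$structures$rois, p2$structures$rois)
  plan <- plan_spec(65, n_beams = 7, mc_noise_percent = 2, seed = 11)
  d1 <- make_dose(p1, plan)
  d2 <- make_dose(p2, plan)
  expect_identical(d1$values, d2$values)
  d3 <- make_dose(p1, plan_spec(65, n_beams = 7, mc_noise_percent = 2, seed = 12))
  expect_false(identical(d1$values, d3$values))
  # the generator must not disturb the caller's RNG stream
  set.seed(5); before <- runif(3)
  set.seed(5); invisible(make_dose(p1, plan)); after <- runif(3)
  expect_identical(before, after)
})

test_that("pseudo-IMRT dose hits the prescription at the PTV median", {
  for (preset in c("npc", "bone-met")) {
    ps <- phantom_preset(preset)
    ph <- make_phantom(ps$spec)
    plan <- plan_spec(ps$plan_defaults$prescription_gy,
                      n_beams = ps$plan_defaults$n_beams)
    dm <- make_dose(ph, plan, spec = ps$spec)
    expect_true(all(dm$values >= 0))
    d50 <- d_at_volume(compute_dvh(dm, roi_mask(ph$structures, "PTV"),
                                   roi = "PTV"), 50)
    expect_lt(abs(d50 - plan$prescription_gy) / plan$prescription_gy, 0.005)
  }
})

test_that("a single beam through a centred symmetric phantom is mirror-symmetric", {
  spec <- phantom_spec(shape = c(30, 30, 10), body_semi_axes = c(40, 35),
                       inserts = list(sphere(c(0, 0, 0), 10, 1.0, roi = "PTV")))
  ph <- make_phantom(spec)
  dm <- make_dose(ph, plan_spec(60, n_beams = 1), spec = spec)
  v <- dm$values
  nx <- dim(v)[1]
  expect_equal(v, v[nx:1, , , drop = FALSE], tolerance = 1e-9)
})

test_that("measurement perturbation composes shift, scale and noise", {
  plane <- random_smooth_plane(3)
  expect_identical(perturb_measurement(plane)$values, plane$values)
  # pure scale on a uniform plane reproduces the gamma ladder closed form
  uni <- uniform_grid(2.0, c(15, 15))
  meas <- perturb_measurement(uni, scale_error_percent = 3)
  expect_equal(meas$values, uni$values * 1.03, tolerance = 1e-12)
  tab <- gamma_sweep(uni, meas, list(c(3, 3), c(2, 2)))
  expect_equal(tab$passing_rate, c(100, 0))
  # seeded noise is reproducible
  n1 <- perturb_measurement(plane, noise_percent = 2, seed = 4)
  n2 <- perturb_measurement(plane, noise_percent = 2, seed = 4)
  expect_identical(n1$values, n2$values)
  expect_error(perturb_measurement(plane, shift_mm = c(1e4, 0)), "geometry error")
})

test_that("a 2 mm shift of a gradient plane passes a 3 mm DTA criterion", {
  nx <- 40
  xs <- (seq_len(nx) - 1) * 1.0
  prof <- 1 + 4 / (1 + exp(-(xs - 20) / 4))      # sigmoid ramp, flat ends
  ref <- scalar_grid(matrix(prof, nx, 20), spacing = c(1, 1), unit = "Gy")
  meas <- perturb_measurement(ref, shift_mm = c(2, 0))
  res <- gamma_map(ref, meas, gamma_params(3, 3))
  expect_equal(res$passing_rate, 100)
  # and fails when DTA is tighter than the shift
  res1 <- gamma_map(ref, meas, gamma_params(1, 1))
  expect_lt(res1$passing_rate, 100)
})
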