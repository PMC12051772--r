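test_that("plasma-input Logan recovers closed-form VT on noiseless curves", {
  x <- sim_tac(0.1, 0.05)
  inp <- input_function(x$dense$time_min,
                        plasma_input(input_function_params(), x$dense$time_min))
  fit <- logan_vt(x$tac, inp, tstar = 18, vb = 0)
  expect_lt(abs(fit$slope / 2 - 1), 0.03)
  expect_equal(fit$n_points, 15L)  # WCM-32 frames with midpoint >= 18 min
  expect_gt(fit$r2, 0.999)
  # vascular correction: measured = (1-vB) tissue + vB blood, vb=0.05
  mixed <- sim_tac(0.1, 0.05, vB = 0.05)
  fit2 <- logan_vt(mixed$tac, inp, tstar = 18, vb = 0.05)
  expect_lt(abs(fit2$slope / 2 - 1), 0.03)
  # uncorrected fit of the mixed curve lands between and is biased low
  fit3 <- logan_vt(mixed$tac, inp, tstar = 18, vb = 0)
  expect_lt(fit3$slope, fit2$slope)
})

test_that("tissue identical to the input gives VT = 1", {
  s <- standard_schedule("WCM")
  mid <- frame_midpoints(s, "min")
  vals <- plasma_input(input_function_params(), mid)
  fit <- logan_vt(tac(vals, s), input_function(mid, vals), tstar = 18, vb = 0)
  expect_equal(fit$slope, 1, tolerance = 1e-6)
})

test_that("Logan errors on short or nonpositive data", {
  x <- sim_tac(0.1, 0.05)
  inp <- input_function(x$dense$time_min, x$dense$activity)
  expect_error(logan_vt(x$tac, inp, tstar = 89), "fewer than 2 frames")
  bad <- x$tac
  bad$values[30] <- -1
  expect_error(logan_vt(bad, inp, tstar = 18, vb = 0), "nonpositive")
  short <- input_function(seq(0, 10, by = 0.1),
                          plasma_input(input_function_params(),
                                       seq(0, 10, by = 0.1)))
  expect_error(logan_vt(x$tac, short, tstar = 18), "cover the scan")
})

test_that("reference Logan is exact under identity and scaling", {
  x <- sim_tac(0.3, 0.15)
  expect_equal(reference_logan_dvr(x$tac, x$tac)$slope, 1,
               tolerance = 1e-10)
  scaled <- tac(1.3 * x$tac$values, x$schedule)
  expect_equal(reference_logan_dvr(scaled, x$tac)$slope, 1.3,
               tolerance = 1e-6)
  # both curves rescaled together: DVR unchanged (scale invariance)
  a <- tac(5 * x$tac$values, x$schedule)
  b <- tac(5 * 0.8 * x$tac$values, x$schedule)
  expect_equal(reference_logan_dvr(b, a)$slope,
               reference_logan_dvr(tac(0.8 * x$tac$values, x$schedule),
                                   x$tac)$slope,
               tolerance = 1e-10)
  jh <- sim_tac(0.3, 0.15, site = "JHMI")
  expect_error(reference_logan_dvr(x$tac, jh$tac), "share a schedule")
})

test_that("reference Logan recovers the VT ratio of simulated 1T pairs", {
  ref <- sim_tac(0.3, 0.15)            # VT 2.0
  target <- sim_tac(0.39, 0.15)        # VT 2.6, ratio 1.3
  fit <- reference_logan_dvr(target$tac, ref$tac, tstar = 18)
  expect_lt(abs(fit$slope / 1.3 - 1), 0.03)
  # monotonicity: DVR strictly increases with target K1 at fixed k2
  slopes <- vapply(c(0.24, 0.30, 0.36), function(k1)
    reference_logan_dvr(sim_tac(k1, 0.15)$tac, ref$tac)$slope, numeric(1))
  expect_true(all(diff(slopes) > 0))
})

test_that("the optional k2prime term tightens 2T reference fits", {
  ref <- sim_tac(0.3, 0.15)
  target <- sim_tac(0.3, 0.15, k3 = 0.03, k4 = 0.1)  # VT 2.6
  plain <- reference_logan_dvr(target$tac, ref$tac)$slope
  k2p <- reference_logan_dvr(target$tac, ref$tac, k2prime = 0.15)$slope
  expect_lt(abs(k2p - 1.3), abs(plain - 1.3))
})

test_that("DVR parametric maps agree with region-level fits", {
  ph <- quiet_phantom()
  ref <- extract_voi_tac(ph$image, ph$class_masks$gm)
  map <- dvr_parametric_map(ph$image, ref, ph$brain, tstar = 18)
  expect_equal(attr(map, "n_failed"), 0L)
  # uniform GM region against itself: DVR 1 everywhere
  gm_sel <- ph$class_masks$gm$labels > 0
  expect_equal(unname(mean(map[gm_sel])), 1, tolerance = 1e-10)
  # two-region truth: thalamus 1.3, WM 0.95, within 3% (noiseless)
  expect_lt(abs(mean(map[ph$class_masks$thalamus$labels > 0]) / 1.3 - 1), 0.03)
  expect_lt(abs(mean(map[ph$class_masks$wm$labels > 0]) / 0.95 - 1), 0.03)
  # VOI mean of the map matches the fit of the VOI TAC (near-linearity)
  voi_tac <- extract_voi_tac(ph$image, ph$class_masks$thalamus)
  direct <- reference_logan_dvr(voi_tac, ref, tstar = 18)$slope
  expect_lt(abs(mean(map[ph$class_masks$thalamus$labels > 0]) / direct - 1),
            0.01)
})

test_that("VT-ratio DVR is a guarded slope quotient", {
  f1 <- svcaPET:::logan_fit_obj(2.6, 0, 18, 15, 0.99, "Logan VT")
  f2 <- svcaPET:::logan_fit_obj(2.0, 0, 18, 15, 0.99, "Logan VT")
  expect_equal(vt_ratio_dvr(f1, f2), 1.3)
  expect_equal(vt_ratio_dvr(f1, f1), 1)
  bad <- svcaPET:::logan_fit_obj(-1, 0, 18, 15, 0.5, "Logan VT")
  expect_error(vt_ratio_dvr(f1, bad), "> 0")
})
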