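test_that("voxel weights recover exact class members and mixtures", {
  lib <- indep_library()
  w <- fit_voxel_weights(lib$curves[, "gm"], lib)
  expect_gt(w[["gm"]], 0)
  expect_equal(unname(w[c("wm", "thalamus", "blood")]), rep(0, 3),
               tolerance = 1e-8)
  # 50/50 GM-blood mixture recovered to 1e-6
  mix <- 0.5 * lib$curves[, "gm"] + 0.5 * lib$curves[, "blood"]
  w <- fit_voxel_weights(mix, lib)
  expect_equal(unname(w), c(0.5, 0, 0, 0.5), tolerance = 1e-6)
  # negated curve: nonnegativity forces all weights to zero (KKT)
  w <- fit_voxel_weights(-lib$curves[, "gm"], lib)
  expect_equal(unname(w), rep(0, 4), tolerance = 1e-10)
  expect_true(kkt_ok(lib$curves, -lib$curves[, "gm"], w))
  # all-zero TAC is flagged
  w0 <- fit_voxel_weights(rep(0, 32), lib)
  expect_equal(unname(w0), rep(0, 4), ignore_attr = TRUE)
  expect_equal(attr(w0, "flag"), "all-zero")
  expect_error(fit_voxel_weights(rep(0, 5), lib), "library grid")
})

test_that("NNLS solution is optimal on random TACs (KKT + grid-search oracle)", {
  lib <- indep_library()
  L <- lib$curves
  expect_equal(qr(L)$rank, 4L)
  set.seed(31)
  for (rep in 1:20) {
    target <- if (rep <= 10) {
      # random non-negative combinations must be recovered exactly
      w_true <- stats::runif(4, 0, 2) * stats::rbinom(4, 1, 0.7)
      as.vector(L %*% w_true)
    } else {
      stats::rnorm(32, sd = 2)
    }
    w <- fit_voxel_weights(target, lib)
    expect_true(kkt_ok(L, target, w))
    if (rep <= 10) expect_equal(unname(w), w_true, tolerance = 1e-6)
    # coarse simplex-scale grid search cannot beat the NNLS residual
    scale <- sum(abs(w)) + 1
    grid <- as.matrix(expand.grid(s1 = seq(0, scale, length.out = 8),
                                  s2 = seq(0, scale, length.out = 8),
                                  s3 = seq(0, scale, length.out = 8),
                                  s4 = seq(0, scale, length.out = 8)))
    res_grid <- min(colSums((as.vector(target) - L %*% t(grid))^2))
    res_nnls <- sum((target - L %*% w)^2)
    expect_lte(res_nnls, res_grid + 1e-8)
  }
})

test_that("GM ratio is a scale-free share of the weights", {
  w <- c(gm = 1, wm = 0, thalamus = 0, blood = 0)
  expect_equal(gm_ratio(w), 1)
  expect_equal(gm_ratio(c(gm = 0.5, wm = 0.5, thalamus = 0, blood = 0)), 0.5)
  w2 <- c(gm = 0.3, wm = 0.1, thalamus = 0.05, blood = 0.05)
  expect_equal(gm_ratio(17 * w2), gm_ratio(w2))
  z <- gm_ratio(c(gm = 0, wm = 0, thalamus = 0, blood = 0))
  expect_true(is.na(z))
  expect_equal(attr(z, "flag"), "undefined")
  expect_error(gm_ratio(c(gm = -1, wm = 1, thalamus = 0, blood = 0)),
               "non-negative")
})

test_that("noiseless homogeneous phantom yields exactly the GM region", {
  ph <- quiet_phantom()
  lib <- own_library(ph)
  res <- extract_pseudoreference(ph$image, ph$brain, lib)
  expect_identical(res$reference_mask$labels, ph$class_masks$gm$labels)
  expect_equal(res$reference_tac$values,
               extract_voi_tac(ph$image, ph$class_masks$gm)$values)
  expect_equal(res$n_voxels, sum(ph$class_masks$gm$labels))
  expect_equal(res$threshold, 0.9)
  expect_error(extract_pseudoreference(ph$image, ph$brain, lib,
                                       threshold = 1.2), "threshold")
})

test_that("pseudoreference of identical voxels equals any single voxel's TAC", {
  ph <- quiet_phantom()
  lib <- own_library(ph)
  res <- extract_pseudoreference(ph$image, ph$brain, lib)
  one <- which(ph$class_masks$gm$labels > 0, arr.ind = TRUE)[1, , drop = FALSE]
  single <- array(0L, dim(ph$brain$labels)); single[one] <- 1L
  voxel_tac <- extract_voi_tac(ph$image,
                               label_mask(single, ph$brain$voxel_size_mm))
  expect_equal(res$reference_tac$values, voxel_tac$values, tolerance = 1e-12)
})

test_that("an unreachable threshold reports the best observed ratio", {
  ph <- build_phantom(phantom_spec(seed = 8))
  lib <- own_library(ph)
  expect_error(extract_pseudoreference(ph$image, ph$brain, lib,
                                       threshold = 0.9999),
               "max observed")
})

test_that("cross-schedule scans are interpolated onto the library grid", {
  jh <- quiet_phantom(site = "JHMI")
  lib <- own_library(quiet_phantom(site = "WCM"))  # 32-point grid
  res <- extract_pseudoreference(jh$image, jh$brain, lib)
  # in a homogeneous noiseless phantom the GM region still dominates
  sel <- res$reference_mask$labels > 0
  gm <- jh$class_masks$gm$labels > 0
  expect_gt(sum(sel & gm) / sum(sel), 0.99)
})
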