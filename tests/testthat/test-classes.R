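test_that("framewise normalization standardizes within the brain mask", {
  ph <- build_phantom(phantom_spec(seed = 2))
  norm <- normalize_dynamic(ph$image, ph$brain)
  nf <- 32L
  mat <- matrix(norm$data, ncol = nf)
  sel <- as.vector(ph$brain$labels > 0)
  expect_lt(max(abs(colMeans(mat[sel, ]))), 1e-6)
  expect_lt(max(abs(apply(mat[sel, ], 2, stats::sd) - 1)), 1e-6)
  # affine invariance: a*X + b normalizes to the same image
  img2 <- ph$image
  img2$data <- 3.7 * img2$data + 11
  norm2 <- normalize_dynamic(img2, ph$brain)
  expect_equal(norm2$data, norm$data, tolerance = 1e-10)
  # constant frame -> degenerate-frame error
  img3 <- ph$image
  img3$data[, , , 5] <- 1
  expect_error(normalize_dynamic(img3, ph$brain), "degenerate frame")
})

test_that("image-derived blood curve recovers the simulated input with QC", {
  ph <- quiet_phantom()
  curve <- idif_blood_curve(ph$image, ph$carotid)
  expect_equal(curve$values, extract_voi_tac(ph$image, ph$carotid)$values)
  expect_equal(attr(curve, "qc"), "pass")
  # a tissue mask peaks late -> QC warning
  expect_warning(out <- idif_blood_curve(ph$image, ph$class_masks$wm),
                 "early window")
  expect_equal(attr(out, "qc"), "warn")
})

test_that("a one-subject library reproduces that subject's class curves", {
  ph <- quiet_phantom()
  norm <- normalize_dynamic(ph$image, ph$brain)
  grid <- frame_midpoints(ph$image$schedule)
  lib <- build_class_library(list(list(image = norm, masks = ph$class_masks)),
                             target_grid_s = grid)
  for (cl in colnames(lib$curves))
    expect_equal(lib$curves[, cl],
                 extract_voi_tac(norm, ph$class_masks[[cl]])$values,
                 tolerance = 1e-12)
  expect_equal(lib$n_subjects, 1L)
  # averaging two identical subjects changes nothing
  lib2 <- build_class_library(rep(list(list(image = norm,
                                            masks = ph$class_masks)), 2),
                              target_grid_s = grid)
  expect_equal(lib2$curves, lib$curves)
  expect_error(build_class_library(list(list(image = norm,
                                             masks = ph$class_masks["gm"]))),
               "missing a class mask")
})

test_that("mixed-schedule subjects are harmonized by linear interpolation", {
  wcm <- quiet_phantom(site = "WCM")
  jhmi <- quiet_phantom(site = "JHMI")
  subjects <- lapply(list(wcm, jhmi), function(ph)
    list(image = normalize_dynamic(ph$image, ph$brain),
         masks = ph$class_masks))
  grid <- frame_midpoints(standard_schedule("WCM"))
  lib <- build_class_library(subjects, target_grid_s = grid)
  # hand-built oracle: interpolate each subject, then average
  oracle <- sapply(colnames(lib$curves), function(cl) {
    per <- sapply(list(wcm, jhmi), function(ph) {
      v <- extract_voi_tac(normalize_dynamic(ph$image, ph$brain),
                           ph$class_masks[[cl]])$values
      stats::approx(frame_midpoints(ph$image$schedule), v, xout = grid,
                    rule = 2)$y
    })
    rowMeans(per)
  })
  expect_equal(unclass(lib$curves), oracle, tolerance = 1e-12)
})

test_that("library building is invariant to subject order", {
  coh <- simulate_cohort(3, phantom_spec(), seed = 5)
  subs <- lapply(coh, function(s)
    list(image = normalize_dynamic(s$scans$test$image, s$brain),
         masks = s$masks))
  libA <- build_class_library(subs)
  libB <- build_class_library(rev(subs))
  expect_equal(libA$curves, libB$curves, tolerance = 1e-12)
})

test_that("library comparison returns per-class correlation and ANOVA p", {
  ph <- quiet_phantom()
  lib <- own_library(ph)
  cmp <- compare_class_libraries(lib, lib)
  expect_equal(cmp$r, rep(1, 4))
  expect_equal(cmp$anova_p, rep(1, 4), tolerance = 1e-12)
  neg <- lib
  neg$curves <- -neg$curves
  expect_equal(compare_class_libraries(lib, neg)$r, rep(-1, 4))
  # 5-point toy curves against the direct Pearson formula
  a <- c(1, 3, 2, 5, 4); b <- c(2, 2.5, 3, 4.5, 5)
  toyA <- structure(list(time_s = 1:5,
                         curves = matrix(a, 5, 4,
                                         dimnames = list(NULL, colnames(lib$curves))),
                         n_subjects = 1L), class = "class_library")
  toyB <- toyA; toyB$curves[] <- b
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(compare_class_libraries(toyA, toyB)$r, rep(r_hand, 4))
  bad <- lib; bad$time_s <- bad$time_s + 1
  expect_error(compare_class_libraries(lib, bad), "time grid")
})

test_that("class library TSV roundtrips with its metadata", {
  lib <- own_library(quiet_phantom())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_class_library(lib, path)
  back <- read_class_library(path)
  expect_equal(back$curves, lib$curves, tolerance = 1e-9)
  expect_equal(back$n_subjects, 1L)
})
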