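#' Configuration of the end-to-end synthetic study workflows
#'
#' Bundles the knobs shared by the study pipelines: the simulated cohort,
#' the training/benchmark group sizes for the class-library sensitivity
#' analysis, the lesion-scale VOI volume presets, and the quantification
#' constants (equilibration time, blood volume fraction, GM-ratio
#' threshold).
#'
#' @param n_subjects Cohort size (default 12: 6 per site).
#' @param variability Between-subject fractional SD of the kinetic
#'   parameters (default 0.05).
#' @param noise_coefficient Frame-noise coefficient for the study scans
#'   (default 0.25, low-to-moderate relative to real voxelwise PET).
#' @param group_sizes Library sizes to test against the benchmark
#'   (default 7:10).
#' @param benchmark_size Benchmark library size (default 10).
#' @param train_size Library size for validation/test-retest pipelines
#'   (default 7).
#' @param voi_volumes Spherical VOI presets, cm^3 (default
#'   0.29, 0.15, 0.065).
#' @param tstar Logan equilibration time, min (default 18).
#' @param vb Fractional blood volume for plasma-input Logan (default 0.05).
#' @param threshold GM-ratio threshold (default 0.9).
#' @param ms_elevation Fractional thalamic VT increase in the simulated
#'   disease cohort (default 0.15).
#' @param hv_n,ms_n Group sizes for the group-comparison study (6 and 10).
#' @param seed Master seed; every workflow derives its randomness from it.
#' @param phantom Base [phantom_spec()]; its noise coefficient is replaced
#'   by `noise_coefficient`.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_subjects = 12L, variability = 0.05,
                         noise_coefficient = 0.25, group_sizes = 7:10,
                         benchmark_size = 10L, train_size = 7L,
                         voi_volumes = c(0.29, 0.15, 0.065), tstar = 18,
                         vb = 0.05, threshold = 0.9, ms_elevation = 0.15,
                         hv_n = 6L, ms_n = 10L, seed = 1L,
                         phantom = phantom_spec()) {
  if (benchmark_size > n_subjects)
    stop("benchmark size exceeds cohort size", call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("`threshold` must be in (0, 1)", call. = FALSE)
  phantom$noise_coefficient <- noise_coefficient
  structure(list(n_subjects = as.integer(n_subjects),
                 variability = variability,
                 noise_coefficient = noise_coefficient,
                 group_sizes = group_sizes,
                 benchmark_size = as.integer(benchmark_size),
                 train_size = as.integer(train_size),
                 voi_volumes = voi_volumes, tstar = tstar, vb = vb,
                 threshold = threshold, ms_elevation = ms_elevation,
                 hv_n = as.integer(hv_n), ms_n = as.integer(ms_n),
                 seed = as.integer(seed), phantom = phantom),
            class = "study_config")
}

## Attach a framewise-normalized test scan to every subject (cached once).
prepare_cohort <- function(cohort) {
  lapply(cohort, function(s) {
    s$norm <- list(image = normalize_dynamic(s$scans$test$image, s$brain),
                   masks = s$masks)
    s
  })
}

## Site-stratified draw of n subjects (half from WCM, rounding down,
## remainder from JHMI), mirroring the 3 + 4 split used for a group of 7.
draw_group <- function(cohort, n) {
  sites <- vapply(cohort, `[[`, character(1), "site")
  w <- which(sites == "WCM"); j <- which(sites == "JHMI")
  n_w <- min(length(w), floor(n / 2))
  n_j <- n - n_w
  if (n_j > length(j)) { n_j <- length(j); n_w <- n - n_j }
  sort(c(sample(w, n_w), sample(j, n_j)))
}

library_from <- function(cohort, idx, grid) {
  build_class_library(lapply(cohort[idx], `[[`, "norm"), target_grid_s = grid)
}

#' Sensitivity of the kinetic-class library to training-group size
#'
#' Simulates a cohort, builds a benchmark library from
#' `cfg$benchmark_size` subjects, then for each size in `cfg$group_sizes`
#' builds an independently drawn library and compares it to the benchmark
#' (per-class Pearson r and one-way ANOVA p, see
#' [compare_class_libraries()]).
#'
#' @param cfg A [study_config()].
#' @param cohort Optional pre-simulated cohort (reused across workflows).
#' @return `data.frame` with columns `group_size`, `class`, `r`,
#'   `anova_p`; one row per group size x class.
#' @export
run_subject_count_sensitivity <- function(cfg, cohort = NULL) {
  stopifnot(inherits(cfg, "study_config"))
  if (is.null(cohort))
    cohort <- simulate_cohort(cfg$n_subjects, cfg$phantom, cfg$variability,
                              seed = cfg$seed)
  cohort <- prepare_cohort(cohort)
  grid <- frame_midpoints(standard_schedule("WCM"))
  set.seed(cfg$seed + 1L)
  bench <- library_from(cohort, draw_group(cohort, cfg$benchmark_size), grid)
  res <- lapply(cfg$group_sizes, function(n) {
    if (n > length(cohort)) stop("group size exceeds cohort", call. = FALSE)
    lib <- library_from(cohort, draw_group(cohort, n), grid)
    cmp <- compare_class_libraries(lib, bench)
    cbind(group_size = n, cmp)
  })
  do.call(rbind, res)
}

#' Leave-one-out stability of the pseudoreference curve
#'
#' For every subject in turn: build group-`train_size` and
#' group-`benchmark_size` libraries from the remaining subjects, extract
#' the held-out subject's pseudoreference curve under each, and summarize
#' the framewise difference (small-library minus benchmark-library curve)
#' across subjects.
#'
#' @param cfg A [study_config()]; the cohort must have at least
#'   `benchmark_size + 1` subjects.
#' @param cohort Optional pre-simulated cohort.
#' @return List with `curves` (long `data.frame`: subject, library,
#'   time_s, value) and `summary` (`data.frame`: time_s, mean_diff,
#'   sd_diff).
#' @export
run_leave_one_out <- function(cfg, cohort = NULL) {
  stopifnot(inherits(cfg, "study_config"))
  if (cfg$n_subjects < cfg$benchmark_size + 1L)
    stop("cohort too small for leave-one-out at the benchmark size",
         call. = FALSE)
  if (is.null(cohort))
    cohort <- simulate_cohort(cfg$n_subjects, cfg$phantom, cfg$variability,
                              seed = cfg$seed)
  cohort <- prepare_cohort(cohort)
  grid <- frame_midpoints(standard_schedule("WCM"))
  set.seed(cfg$seed + 2L)
  curves <- list(); diffs <- matrix(NA_real_, length(cohort), length(grid))
  for (i in seq_along(cohort)) {
    rest <- cohort[-i]
    lib_s <- library_from(rest, draw_group(rest, cfg$train_size), grid)
    lib_b <- library_from(rest, draw_group(rest, cfg$benchmark_size), grid)
    s <- cohort[[i]]
    ref_s <- extract_pseudoreference(s$scans$test$image, s$brain, lib_s,
                                     cfg$threshold)$reference_tac
    ref_b <- extract_pseudoreference(s$scans$test$image, s$brain, lib_b,
                                     cfg$threshold)$reference_tac
    mid <- frame_midpoints(s$scans$test$image$schedule)
    v_s <- stats::approx(mid, ref_s$values, xout = grid, rule = 2)$y
    v_b <- stats::approx(mid, ref_b$values, xout = grid, rule = 2)$y
    diffs[i, ] <- v_s - v_b
    curves[[i]] <- data.frame(subject = s$id,
                              library = rep(c("train", "benchmark"),
                                            each = length(grid)),
                              time_s = rep(grid, 2L),
                              value = c(v_s, v_b))
  }
  list(curves = do.call(rbind, curves),
       summary = data.frame(time_s = grid,
                            mean_diff = colMeans(diffs),
                            sd_diff = apply(diffs, 2, stats::sd)))
}

## Per-subject DVR routes for one region; input is the subject's plasma
## curve. Returns the three DVR readings.
subject_dvrs <- function(subject, region, ref_tac, cfg) {
  img <- subject$scans$test$image
  target <- extract_voi_tac(img, subject$masks[[region]], 1L)
  gm <- extract_voi_tac(img, subject$masks$gm, 1L)
  inp <- input_function(subject$input$time_min, subject$input$activity)
  svca_dvr <- reference_logan_dvr(target, ref_tac, cfg$tstar)$slope
  vt_voi <- logan_vt(target, inp, cfg$tstar, cfg$vb)
  vt_gm <- logan_vt(gm, inp, cfg$tstar, cfg$vb)
  vt_ref <- logan_vt(ref_tac, inp, cfg$tstar, cfg$vb)
  c(svca_dvr = svca_dvr,
    aif_dvr_gm = vt_ratio_dvr(vt_voi, vt_gm),
    aif_dvr_svca = vt_ratio_dvr(vt_voi, vt_ref))
}

#' Independent validation of SVCA-DVR against plasma-input DVR
#'
#' Splits the cohort into a training group (`train_size` subjects, used
#' only to build the class library) and a disjoint validation group.
#' For each validation subject and region (WM, thalamus) it computes
#' SVCA-DVR (reference Logan against the pseudoreference curve),
#' AIF-DVR(GM) and AIF-DVR(SVCA) (Logan VT ratios), together with the
#' subject's ground-truth DVR, and summarizes agreement (Pearson r,
#' ICC(A,1), Bland-Altman bias). Training/validation disjointness is
#' enforced.
#'
#' @param cfg A [study_config()].
#' @param cohort Optional pre-simulated cohort.
#' @return List with `table` (per subject x region) and `summary` (per
#'   region agreement statistics).
#' @export
run_validation <- function(cfg, cohort = NULL) {
  stopifnot(inherits(cfg, "study_config"))
  if (is.null(cohort))
    cohort <- simulate_cohort(cfg$n_subjects, cfg$phantom, cfg$variability,
                              seed = cfg$seed)
  cohort <- prepare_cohort(cohort)
  grid <- frame_midpoints(standard_schedule("WCM"))
  set.seed(cfg$seed + 3L)
  train <- draw_group(cohort, cfg$train_size)
  valid <- setdiff(seq_along(cohort), train)
  if (length(intersect(train, valid)) > 0L)
    stop("training and validation subjects overlap", call. = FALSE)
  lib <- library_from(cohort, train, grid)

  rows <- list()
  for (i in valid) {
    s <- cohort[[i]]
    ref <- extract_pseudoreference(s$scans$test$image, s$brain, lib,
                                   cfg$threshold)$reference_tac
    for (region in c("wm", "thalamus")) {
      d <- subject_dvrs(s, region, ref, cfg)
      rows[[length(rows) + 1L]] <-
        data.frame(subject = s$id, binder = s$binder, region = region,
                   svca_dvr = d[["svca_dvr"]],
                   aif_dvr_gm = d[["aif_dvr_gm"]],
                   aif_dvr_svca = d[["aif_dvr_svca"]],
                   truth_dvr = s$truth$dvr[[region]])
    }
  }
  tab <- do.call(rbind, rows)
  summ <- lapply(unique(tab$region), function(rg) {
    d <- tab[tab$region == rg, ]
    ba <- bland_altman(d$svca_dvr, d$aif_dvr_gm)
    data.frame(region = rg, n = nrow(d),
               mean_svca_dvr = mean(d$svca_dvr),
               mean_aif_dvr_gm = mean(d$aif_dvr_gm),
               mean_truth_dvr = mean(d$truth_dvr),
               r = stats::cor(d$svca_dvr, d$aif_dvr_gm),
               icc = as.numeric(icc_agreement(cbind(d$svca_dvr, d$aif_dvr_gm))),
               ba_bias = ba$bias)
  })
  list(table = tab, summary = do.call(rbind, summ))
}

#' Test-retest repeatability of SVCA-DVR across VOI sizes
#'
#' Builds the class library from a training group, then for each
#' validation subject with a retest scan computes DVR parametric maps
#' (reference Logan against that scan's pseudoreference curve) for both
#' scans and averages them over the full thalamus and WM regions and over
#' spherical VOIs at the preset volumes (placed at the region centroid,
#' constrained inside the region). Repeatability is summarized with
#' [reliability_report()].
#'
#' @param cfg A [study_config()].
#' @param cohort Optional pre-simulated cohort; must contain retest scans
#'   (`simulate_cohort(..., test_retest = TRUE)`).
#' @return List with `report` (the [reliability_report()] table, one row
#'   per region/VOI) and `values` (per subject x region x scan DVR).
#' @export
run_test_retest <- function(cfg, cohort = NULL) {
  stopifnot(inherits(cfg, "study_config"))
  if (is.null(cohort))
    cohort <- simulate_cohort(cfg$n_subjects, cfg$phantom, cfg$variability,
                              test_retest = TRUE, seed = cfg$seed)
  cohort <- prepare_cohort(cohort)
  grid <- frame_midpoints(standard_schedule("WCM"))
  set.seed(cfg$seed + 4L)
  train <- draw_group(cohort, cfg$train_size)
  valid <- setdiff(seq_along(cohort), train)
  lib <- library_from(cohort, train, grid)

  tr_subjects <- Filter(function(s) !is.null(s$scans$retest), cohort[valid])
  if (length(tr_subjects) == 0L)
    stop("no validation subject has a retest scan", call. = FALSE)

  rows <- list()
  for (s in tr_subjects) {
    vois <- region_vois(s, cfg$voi_volumes)
    for (scan_name in c("test", "retest")) {
      scan <- s$scans[[scan_name]]
      ref <- extract_pseudoreference(scan$image, scan$brain, lib,
                                     cfg$threshold)$reference_tac
      map <- dvr_parametric_map(scan$image, ref, scan$brain, cfg$tstar)
      for (v in vois) {
        sel <- v$mask$labels > 0
        rows[[length(rows) + 1L]] <-
          data.frame(subject = s$id, scan = scan_name, region = v$name,
                     volume_cm3 = v$volume_cm3,
                     dvr = mean(map[sel], na.rm = TRUE))
      }
    }
  }
  vals <- do.call(rbind, rows)
  wide <- merge(vals[vals$scan == "test",
                     c("subject", "region", "volume_cm3", "dvr")],
                vals[vals$scan == "retest", c("subject", "region", "dvr")],
                by = c("subject", "region"), suffixes = c("_test", "_retest"))
  names(wide)[names(wide) == "dvr_test"] <- "test"
  names(wide)[names(wide) == "dvr_retest"] <- "retest"
  list(report = reliability_report(wide), values = vals)
}

## Full-region masks plus centroid-placed spherical VOIs for thalamus/WM.
region_vois <- function(subject, volumes) {
  out <- list()
  for (region in c("thalamus", "wm")) {
    mask <- subject$masks[[region]]
    out[[length(out) + 1L]] <-
      list(name = region, mask = mask,
           volume_cm3 = sum(mask$labels > 0) * voxel_volume_cm3(mask))
    idx <- which(mask$labels > 0, arr.ind = TRUE)
    centroid <- colMeans(idx)
    nearest <- idx[which.min(rowSums(sweep(idx, 2, centroid)^2)), ]
    for (k in seq_along(volumes)) {
      voi <- make_spherical_voi(nearest, volumes[k], mask, within = mask)
      out[[length(out) + 1L]] <-
        list(name = sprintf("%s%d", region, k), mask = voi,
             volume_cm3 = attr(voi, "achieved_cm3"))
    }
  }
  out
}

#' Group comparison: healthy volunteers versus a disease cohort
#'
#' Simulates a healthy cohort and a disease cohort whose thalamic VT is
#' elevated by `cfg$ms_elevation` (modelled by scaling the thalamus K1),
#' quantifies SVCA-DVR per subject for GM, WM and thalamus against a class
#' library built from the main healthy cohort, and tests each region with
#' a Welch t-test.
#'
#' @param cfg A [study_config()].
#' @param cohort Optional pre-simulated healthy training cohort.
#' @return `data.frame` with columns `region`, `mean_HV`, `mean_MS`, `p`.
#' @export
run_group_comparison <- function(cfg, cohort = NULL) {
  stopifnot(inherits(cfg, "study_config"))
  if (cfg$hv_n < 2L || cfg$ms_n < 2L)
    stop("each comparison group needs at least 2 subjects", call. = FALSE)
  if (is.null(cohort))
    cohort <- simulate_cohort(cfg$n_subjects, cfg$phantom, cfg$variability,
                              seed = cfg$seed)
  cohort <- prepare_cohort(cohort)
  grid <- frame_midpoints(standard_schedule("WCM"))
  set.seed(cfg$seed + 5L)
  lib <- library_from(cohort, draw_group(cohort, cfg$train_size), grid)

  ms_spec <- cfg$phantom
  thal <- ms_spec$kinetics$thalamus
  ms_spec$kinetics$thalamus <-
    kinetic_params(thal$K1 * (1 + cfg$ms_elevation), thal$k2, thal$k3,
                   thal$k4, thal$vB)
  hv <- simulate_cohort(cfg$hv_n, cfg$phantom, cfg$variability,
                        group = "HV", seed = cfg$seed + 100L)
  ms <- simulate_cohort(cfg$ms_n, ms_spec, cfg$variability,
                        group = "MS", seed = cfg$seed + 200L)

  dvr_one <- function(s) {
    ref <- extract_pseudoreference(s$scans$test$image, s$brain, lib,
                                   cfg$threshold)$reference_tac
    vapply(c(gm = "gm", wm = "wm", thalamus = "thalamus"), function(region) {
      target <- extract_voi_tac(s$scans$test$image, s$masks[[region]], 1L)
      reference_logan_dvr(target, ref, cfg$tstar)$slope
    }, numeric(1))
  }
  hv_dvr <- t(vapply(hv, dvr_one, numeric(3)))
  ms_dvr <- t(vapply(ms, dvr_one, numeric(3)))
  data.frame(region = colnames(hv_dvr),
             mean_HV = colMeans(hv_dvr),
             mean_MS = colMeans(ms_dvr),
             p = vapply(seq_len(ncol(hv_dvr)), function(j)
               group_compare(hv_dvr[, j], ms_dvr[, j]), numeric(1)),
             row.names = NULL)
}
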