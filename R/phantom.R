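#' Default class kinetics for the digital brain phantom
#'
#' Four kinetic classes drive the phantom: low-binding gray matter (GM,
#' one-tissue, VT = 2.0), white matter (WM, one-tissue, VT = 1.9), the
#' high-binding thalamus (two-tissue, VT = 2.6, i.e. true DVR = 1.3 and
#' 0.95 for thalamus and WM against GM), and blood (voxels carrying the
#' input curve itself). GM perfusion is set about 3-fold higher than WM
#' (K1 = 0.30 vs 0.09 mL/cm^3/min), the gray/white contrast that gives the
#' classes their distinct early-phase shapes. Tissue classes carry a
#' fractional blood volume of 0.05.
#'
#' @return Named list of [kinetic_params()] for `gm`, `wm` and `thalamus`
#'   (the blood class has no tissue kinetics).
#' @export
default_class_kinetics <- function() {
  list(
    gm       = kinetic_params(K1 = 0.30, k2 = 0.15, vB = 0.05),
    wm       = kinetic_params(K1 = 0.09, k2 = 0.09 / 1.9, vB = 0.05),
    thalamus = kinetic_params(K1 = 0.30, k2 = 0.15, k3 = 0.03, k4 = 0.10,
                              vB = 0.05)
  )
}

#' Specification of a digital dynamic PET phantom
#'
#' Describes a block-layout brain phantom: a gray-matter interior with a
#' central white-matter slab, an embedded thalamus block, and a small
#' carotid (blood) column, surrounded by background. Every voxel carries
#' exactly one class label.
#'
#' @param dim Grid dimensions in voxels (default `c(16, 16, 8)`).
#' @param voxel_size_mm Voxel edge lengths, mm (default 2-mm isotropic).
#' @param schedule_site `"WCM"` (32 frames) or `"JHMI"` (30 frames).
#' @param kinetics Named list of per-class [kinetic_params()], as in
#'   [default_class_kinetics()].
#' @param input_params An [input_function_params()].
#' @param noise_coefficient Unitless frame-noise coefficient (see
#'   [add_noise()]). The default 0.25 is low-to-moderate relative to real
#'   voxelwise PET (which sits nearer 0.5-1 in this scaling); 0.05 keeps
#'   every frame's nominal noise SD within 10% of the across-brain signal
#'   SD.
#' @param heterogeneity Fractional SD of smooth within-class kinetic
#'   variation: each tissue voxel's rate constants deviate from its class
#'   values by independent Gaussian factors of this SD (applied via
#'   first-order sensitivity curves). Default 0.1, the scale of regional
#'   perfusion/binding variation within a tissue class; set 0 for
#'   perfectly homogeneous classes.
#' @param seed Optional integer seed for the within-class heterogeneity
#'   pattern (a property of the subject's anatomy) and, when `noise_seed`
#'   is unset, the frame noise.
#' @param noise_seed Optional separate seed for the frame noise. A retest
#'   scan of the same subject keeps `seed` (same anatomy) and changes
#'   `noise_seed` (new counts).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(16L, 16L, 8L), voxel_size_mm = c(2, 2, 2),
                         schedule_site = "WCM",
                         kinetics = default_class_kinetics(),
                         input_params = input_function_params(),
                         noise_coefficient = 0.25, heterogeneity = 0.1,
                         seed = NULL, noise_seed = NULL) {
  if (noise_coefficient < 0)
    stop("`noise_coefficient` must be >= 0", call. = FALSE)
  if (heterogeneity < 0)
    stop("`heterogeneity` must be >= 0", call. = FALSE)
  if (any(dim < 8L))
    stop("phantom grid must be at least 8 voxels per axis", call. = FALSE)
  stopifnot(all(c("gm", "wm", "thalamus") %in% names(kinetics)))
  structure(list(dim = as.integer(dim), voxel_size_mm = voxel_size_mm,
                 schedule_site = schedule_site, kinetics = kinetics,
                 input_params = input_params,
                 noise_coefficient = noise_coefficient,
                 heterogeneity = heterogeneity, seed = seed,
                 noise_seed = noise_seed),
            class = "phantom_spec")
}

## Class label codes used by the phantom.
PHANTOM_CLASSES <- c(gm = 1L, wm = 2L, thalamus = 3L, blood = 4L)

## Block layout: labels 0 background, 1 gm, 2 wm, 3 thalamus, 4 blood.
phantom_labels <- function(dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  lab <- array(0L, dims)
  lab[2:(nx - 1), 2:(ny - 1), 2:(nz - 1)] <- PHANTOM_CLASSES[["gm"]]
  wx <- round(nx * 0.25):round(nx * 0.8)
  wy <- round(ny * 0.25):round(ny * 0.8)
  wz <- 2:(nz - 1)
  lab[wx, wy, wz] <- PHANTOM_CLASSES[["wm"]]
  tx <- round(nx * 0.45):round(nx * 0.7)
  ty <- round(ny * 0.45):round(ny * 0.7)
  lab[tx, ty, wz] <- PHANTOM_CLASSES[["thalamus"]]
  lab[2:3, 2:3, wz] <- PHANTOM_CLASSES[["blood"]]
  lab
}

#' Build a digital dynamic PET phantom
#'
#' Generates the noiseless class TACs from the spec's kinetics (blood-class
#' voxels carry the frame-averaged input curve), assigns them to voxels by
#' class, and adds per-voxel frame noise. The ground-truth VT map holds the
#' closed-form tissue VT per class (1.0 for blood, taken as plasma), so the
#' true DVR of any region is its VT divided by the GM-class VT.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `image` ([dynamic_image()]), `labels`
#'   (all-class [label_mask()]), `class_masks` (named list of binary
#'   [label_mask()]s), `brain` (all labelled voxels), `carotid` (the blood
#'   block), `vt_truth` (3D array), `class_tacs` (noiseless frame values,
#'   one column per class), `input` (dense `data.frame`), and `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  schedule <- standard_schedule(spec$schedule_site)
  t_end <- total_duration(schedule) / 60
  lab <- phantom_labels(spec$dim)

  dense_t <- seq(0, t_end, by = 1 / 60)
  input <- data.frame(time_min = dense_t,
                      activity = plasma_input(spec$input_params, dense_t))

  nf <- n_frames(schedule)
  tissue_classes <- c("gm", "wm", "thalamus")
  class_tacs <- matrix(0, nf, 4,
                       dimnames = list(NULL, names(PHANTOM_CLASSES)))
  vt_class <- c(gm = 0, wm = 0, thalamus = 0, blood = 1)
  sens <- list()  # per-class first-order sensitivity curves and VT gradients
  for (cl in tissue_classes) {
    kp <- spec$kinetics[[cl]]
    f <- tissue_response(input, kp, t_end_min = t_end)
    class_tacs[, cl] <- frame_average(f, schedule)$values
    vt_class[cl] <- attr(f, "vt")
    if (spec$heterogeneity > 0)
      sens[[cl]] <- class_sensitivity(input, kp, schedule, t_end,
                                      class_tacs[, cl])
  }
  blood_f <- stats::approxfun(input$time_min, input$activity, rule = 2)
  class_tacs[, "blood"] <- frame_average(blood_f, schedule)$values

  if (!is.null(spec$seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(spec$seed)
  }

  nvox <- prod(spec$dim)
  vals <- matrix(0, nvox, nf)
  vt_truth <- array(0, spec$dim)
  labv <- as.vector(lab)
  for (cl in names(PHANTOM_CLASSES)) {
    sel <- labv == PHANTOM_CLASSES[[cl]]
    n_c <- sum(sel)
    vals[sel, ] <- matrix(class_tacs[, cl], n_c, nf, byrow = TRUE)
    vt_truth[sel] <- vt_class[[cl]]
    if (spec$heterogeneity > 0 && cl %in% tissue_classes) {
      sc <- sens[[cl]]
      eps <- matrix(stats::rnorm(n_c * nrow(sc$curves), 0, spec$heterogeneity),
                    n_c, nrow(sc$curves))
      vals[sel, ] <- pmax(vals[sel, , drop = FALSE] + eps %*% sc$curves, 0)
      vt_truth[sel] <- vt_truth[sel] + as.vector(eps %*% sc$vt_grad)
    }
  }

  if (spec$noise_coefficient > 0) {
    if (!is.null(spec$noise_seed)) set.seed(spec$noise_seed)
    sd <- noise_sd(vals, schedule, spec$noise_coefficient)
    vals <- vals + matrix(stats::rnorm(length(vals), 0, as.vector(sd)),
                          nvox, nf)
    vals[labv == 0L, ] <- 0  # background stays empty
  }

  image <- dynamic_image(array(vals, c(spec$dim, nf)), spec$voxel_size_mm,
                         schedule)
  masks <- lapply(PHANTOM_CLASSES, function(code)
    label_mask(array(as.integer(lab == code), spec$dim), spec$voxel_size_mm))
  brain <- label_mask(array(as.integer(lab > 0L), spec$dim),
                      spec$voxel_size_mm)
  list(image = image,
       labels = label_mask(lab, spec$voxel_size_mm),
       class_masks = masks,
       brain = brain,
       carotid = masks$blood,
       vt_truth = vt_truth,
       class_tacs = class_tacs,
       input = input,
       spec = spec)
}

## First-order sensitivity of a class TAC and of its VT to fractional
## changes in each rate constant; used to paint smooth within-class
## heterogeneity without one convolution per voxel.
class_sensitivity <- function(input, kp, schedule, t_end, base_tac, h = 0.05) {
  pars <- c("K1", "k2", if (kp$k3 > 0) c("k3", "k4"))
  curves <- t(vapply(pars, function(p) {
    kp2 <- kp
    kp2[[p]] <- kp2[[p]] * (1 + h)
    kp2 <- kinetic_params(kp2$K1, kp2$k2, kp2$k3, kp2$k4, kp2$vB)
    f <- tissue_response(input, kp2, t_end_min = t_end)
    (frame_average(f, schedule)$values - base_tac) / h
  }, numeric(n_frames(schedule))))
  vt <- vt_closed_form(kp)
  bound <- if (kp$k3 > 0) (kp$K1 / kp$k2) * (kp$k3 / kp$k4) else 0
  grads <- c(K1 = vt, k2 = -vt, k3 = bound, k4 = -bound)
  list(curves = curves, vt_grad = grads[pars])
}

#' Ground-truth DVR of one phantom region against the GM class
#'
#' @param phantom Output of [build_phantom()].
#' @param class_name `"gm"`, `"wm"`, `"thalamus"` or `"blood"`.
#' @return Region tissue VT divided by the GM-class VT.
#' @export
true_dvr <- function(phantom, class_name) {
  sel_r <- phantom$labels$labels == PHANTOM_CLASSES[[class_name]]
  sel_g <- phantom$labels$labels == PHANTOM_CLASSES[["gm"]]
  mean(phantom$vt_truth[sel_r]) / mean(phantom$vt_truth[sel_g])
}

#' Simulate a multi-subject cohort of dynamic PET scans
#'
#' Each subject's class kinetic parameters are drawn as
#' `truth * (1 + Normal(0, variability))` independently per class and per
#' rate constant (`vB` fixed). Subjects alternate between the two sites, so
#' half use the 32-frame and half the 30-frame schedule. With
#' `test_retest = TRUE`, WCM subjects receive a second scan with fresh
#' noise and a small kinetic jitter (fractional SD `retest_jitter`),
#' mimicking a same-day retest.
#'
#' @param n_subjects Number of subjects.
#' @param spec A [phantom_spec()] giving the grid, truth kinetics, input
#'   model and noise level shared by the cohort.
#' @param variability Fractional between-subject SD of the rate constants
#'   (default 0.05).
#' @param test_retest Give WCM subjects a retest scan?
#' @param retest_jitter Fractional SD of the test-to-retest kinetic change
#'   (default 0.01).
#' @param group Cohort label stored on every subject (e.g. `"HV"`, `"MS"`).
#' @param build_images Build the full 4D scans? Set `FALSE` to draw only
#'   the per-subject kinetic truth (fast, for parameter-level checks).
#' @param seed Integer seed; the whole cohort is reproducible given
#'   `(spec, seed)`.
#' @return List of subject records, each with `id`, `site`, `binder`,
#'   `group`, `params` (per-class [kinetic_params()]), `truth` (per-class
#'   VT and DVR), and (when built) `scans` (list of `test`/`retest`
#'   phantoms).
#' @export
simulate_cohort <- function(n_subjects, spec = phantom_spec(),
                            variability = 0.05, test_retest = FALSE,
                            retest_jitter = 0.01, group = "HV",
                            build_images = TRUE, seed = 1L) {
  if (variability < 0) stop("`variability` must be >= 0", call. = FALSE)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  sites <- rep(c("WCM", "JHMI"), length.out = n_subjects)
  binders <- rep(c("MAB", "HAB"), length.out = n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    params <- lapply(spec$kinetics, jitter_params, variability)
    truth_vt <- vapply(params, vt_closed_form, numeric(1))
    truth <- list(vt = c(truth_vt, blood = 1),
                  dvr = c(truth_vt / truth_vt[["gm"]], blood = 1 / truth_vt[["gm"]]))
    rec <- list(id = sprintf("%s%02d", group, i), site = sites[i],
                binder = binders[i], group = group, params = params,
                truth = truth)
    if (build_images) {
      sspec <- spec
      sspec$kinetics <- params
      sspec$schedule_site <- if (sites[i] == "WCM") "WCM" else "JHMI"
      sspec$seed <- sample.int(.Machine$integer.max, 1L)
      sspec$noise_seed <- sample.int(.Machine$integer.max, 1L)
      scans <- list(test = build_phantom(sspec))
      if (test_retest && sites[i] == "WCM") {
        rspec <- sspec  # same anatomy seed: heterogeneity is the subject's
        rspec$kinetics <- lapply(params, jitter_params, retest_jitter)
        rspec$noise_seed <- sample.int(.Machine$integer.max, 1L)
        scans$retest <- build_phantom(rspec)
      }
      rec$scans <- scans
      rec$masks <- scans$test$class_masks
      rec$brain <- scans$test$brain
      rec$input <- scans$test$input
    }
    rec
  })
}

## Multiply each rate constant by an independent (1 + Normal(0, sd)) factor,
## floored away from zero; vB is left untouched.
jitter_params <- function(kp, sd) {
  if (sd == 0) return(kp)
  f <- function(x) x * max(1 + stats::rnorm(1, 0, sd), 0.05)
  kinetic_params(K1 = f(kp$K1), k2 = f(kp$k2),
                 k3 = if (kp$k3 > 0) f(kp$k3) else 0,
                 k4 = if (kp$k4 > 0) f(kp$k4) else 0,
                 vB = kp$vB)
}
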