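# Shared fixtures, built in code at test time.

# Deterministic homogeneous phantom: no noise, no within-class heterogeneity,
# so every voxel of a class carries exactly the class curve.
quiet_phantom <- function(seed = 1L, site = "WCM") {
  build_phantom(phantom_spec(schedule_site = site, noise_coefficient = 0,
                             heterogeneity = 0, seed = seed))
}

# Class library built from a phantom's own masks (no inter-subject averaging).
own_library <- function(phantom,
                        grid = frame_midpoints(standard_schedule("WCM"))) {
  norm <- normalize_dynamic(phantom$image, phantom$brain)
  build_class_library(list(list(image = norm, masks = phantom$class_masks)),
                      target_grid_s = grid)
}

# A linearly independent 4-curve library from the raw (unnormalized) class
# kinetics; z-scored full-partition class curves are rank-deficient by
# construction, so solver-recovery oracles need this one.
indep_library <- function(phantom = quiet_phantom()) {
  structure(list(time_s = frame_midpoints(phantom$image$schedule),
                 curves = phantom$class_tacs, n_subjects = 1L),
            class = "class_library")
}

# Noiseless 1T/2T tissue TAC on a schedule, plus the dense input table.
sim_tac <- function(K1, k2, k3 = 0, k4 = 0, vB = 0, site = "WCM",
                    params = input_function_params()) {
  sched <- standard_schedule(site)
  f <- tissue_response(params, kinetic_params(K1, k2, k3, k4, vB),
                       t_end_min = total_duration(sched) / 60)
  list(tac = frame_average(f, sched), dense = attr(f, "grid"),
       vt = attr(f, "vt"), schedule = sched)
}

dense_input <- function(params = input_function_params(), t_end = 90) {
  t <- seq(0, t_end, by = 1 / 60)
  input_function(t, plasma_input(params, t))
}

# Karush-Kuhn-Tucker optimality check for min ||t - L w||, w >= 0:
# gradient g = L'(L w - t); g_i ~ 0 where w_i > 0, g_i >= 0 where w_i = 0.
kkt_ok <- function(L, target, w, tol = 1e-6) {
  g <- crossprod(L, L %*% w - target)
  all(abs(g[w > tol]) < tol * max(1, sum(abs(target)))) &&
    all(g[w <= tol] > -tol * max(1, sum(abs(target))))
}

# The default 12-subject study cohort with retest scans, built once per run.
cached_cohort <- local({
  value <- NULL
  function() {
    if (is.null(value)) {
      cfg <- study_config()
      value <<- simulate_cohort(cfg$n_subjects, cfg$phantom, cfg$variability,
                                test_retest = TRUE, seed = cfg$seed)
    }
    value
  }
})
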