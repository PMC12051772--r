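#' Plasma input function container
#'
#' @param time_min Strictly increasing sample times (min).
#' @param activity Non-negative plasma activity (kBq/mL).
#' @param corrected Logical flag: metabolite- and decay-corrected?
#' @return An object of class `input_function` (also a `data.frame`).
#' @export
input_function <- function(time_min, activity, corrected = TRUE) {
  if (length(time_min) > 1L && any(diff(time_min) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(activity < 0)) stop("activity must be >= 0", call. = FALSE)
  structure(data.frame(time_min = time_min, activity = activity),
            corrected = corrected,
            class = c("input_function", "data.frame"))
}

## Cumulative trapezoid integral of a curve known at frame midpoints,
## with an initial triangle from t = 0 (curve taken as 0 at injection).
cum_integral_from_zero <- function(times_min, values) {
  pracma::cumtrapz(c(0, times_min), c(0, values))[-1L]
}

## Integral of the input curve from 0 to each requested time, by trapezoid
## on the input's own sampling grid, plus the input value at those times.
input_at <- function(input, times_min) {
  t_in <- input$time_min
  a_in <- input$activity
  if (t_in[1] > 0) { t_in <- c(0, t_in); a_in <- c(0, a_in) }
  if (max(t_in) < max(times_min) - 1e-9)
    stop("input function does not cover the scan span", call. = FALSE)
  ci <- pracma::cumtrapz(t_in, a_in)
  list(integral = stats::approx(t_in, ci, xout = times_min)$y,
       value = stats::approx(t_in, a_in, xout = times_min)$y)
}

logan_fit_obj <- function(slope, intercept, tstar, n, r2, method) {
  structure(list(slope = slope, intercept = intercept, tstar = tstar,
                 n_points = n, r2 = r2, method = method),
            class = "logan_fit")
}

#' @export
print.logan_fit <- function(x, ...) {
  cat(sprintf("<logan_fit> %s slope = %.4f (t* = %g min, %d points, R2 = %.4f)\n",
              x$method, x$slope, x$tstar, x$n_points, x$r2))
  invisible(x)
}

ols_line <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- mean((x - mx)^2)
  sxy <- mean((x - mx) * (y - my))
  slope <- sxy / sxx
  ss_res <- sum((y - my - slope * (x - mx))^2)
  ss_tot <- sum((y - my)^2)
  list(slope = slope, intercept = my - slope * mx,
       r2 = if (ss_tot > 0) max(0, 1 - ss_res / ss_tot) else 1)
}

#' Logan graphical analysis with a plasma input (total distribution volume)
#'
#' Regresses the Logan-transformed tissue curve on the transformed input,
#' \deqn{\int_0^t C_T / C_T(t) = V_T \int_0^t C_p / C_T(t) + b,}
#' over frames whose midpoint is at or past the equilibration time `tstar`.
#' The measured tissue curve is first corrected for vascular signal,
#' `C_T = (C_pet - vB * C_blood) / (1 - vB)`, with the plasma input
#' standing in for whole blood unless a blood TAC is supplied. Integrals
#' are trapezoid from injection (t = 0). The slope is VT in mL/cm^3.
#'
#' @param tissue A [tac()] (kBq/mL).
#' @param input An [input_function()] (or `data.frame` with `time_min`,
#'   `activity`) covering the scan span.
#' @param tstar Equilibration time (min), default 18.
#' @param vb Fractional blood volume, default 0.05.
#' @param blood Optional whole-blood [tac()] on the tissue schedule.
#' @return A `logan_fit` with `slope` = VT.
#' @export
logan_vt <- function(tissue, input, tstar = 18, vb = 0.05, blood = NULL) {
  stopifnot(inherits(tissue, "tac"))
  mid <- frame_midpoints(tissue$schedule, "min")
  keep <- mid >= tstar
  if (sum(keep) < 2L)
    stop("fewer than 2 frames past t* = ", tstar, " min", call. = FALSE)
  inp <- input_at(input, mid)
  cpet <- tissue$values
  ct <- if (vb > 0) {
    cb <- if (is.null(blood)) inp$value else blood$values
    (cpet - vb * cb) / (1 - vb)
  } else cpet
  if (any(ct[keep] <= 0))
    stop("nonpositive tissue value past t*; Logan transform undefined",
         call. = FALSE)
  int_ct <- cum_integral_from_zero(mid, ct)
  x <- inp$integral[keep] / ct[keep]
  y <- int_ct[keep] / ct[keep]
  fit <- ols_line(x, y)
  logan_fit_obj(fit$slope, fit$intercept, tstar, sum(keep), fit$r2,
                "Logan VT")
}

#' Reference Logan graphical analysis (distribution volume ratio)
#'
#' Regresses the Logan-transformed target curve on the transformed
#' reference curve over frames with midpoint `>= tstar`; the slope is the
#' DVR. When the reference efflux constant `k2prime` is supplied, the
#' standard `C_ref / k2prime` term is added to the reference integral;
#' by default no such term is used.
#'
#' @param target,reference [tac()] objects on the same schedule.
#' @param tstar Equilibration time (min), default 18.
#' @param k2prime Optional reference-region efflux constant (1/min).
#' @return A `logan_fit` with `slope` = DVR.
#' @export
reference_logan_dvr <- function(target, reference, tstar = 18,
                                k2prime = NULL) {
  stopifnot(inherits(target, "tac"), inherits(reference, "tac"))
  if (n_frames(target$schedule) != n_frames(reference$schedule) ||
      max(abs(frame_midpoints(target$schedule) -
              frame_midpoints(reference$schedule))) > 1e-6)
    stop("target and reference must share a schedule", call. = FALSE)
  mid <- frame_midpoints(target$schedule, "min")
  keep <- mid >= tstar
  if (sum(keep) < 2L)
    stop("fewer than 2 frames past t* = ", tstar, " min", call. = FALSE)
  ct <- target$values
  if (any(ct[keep] <= 0))
    stop("nonpositive target value past t*; Logan transform undefined",
         call. = FALSE)
  int_ct <- cum_integral_from_zero(mid, ct)
  int_ref <- cum_integral_from_zero(mid, reference$values)
  num <- if (is.null(k2prime)) int_ref else int_ref + reference$values / k2prime
  x <- num[keep] / ct[keep]
  y <- int_ct[keep] / ct[keep]
  fit <- ols_line(x, y)
  logan_fit_obj(fit$slope, fit$intercept, tstar, sum(keep), fit$r2,
                "reference Logan DVR")
}

#' Voxelwise DVR parametric map by the reference Logan model
#'
#' Applies [reference_logan_dvr()] independently to every brain voxel
#' (vectorized). Voxels where the transform is undefined (nonpositive
#' values past t*) are set to `NA` and counted in attribute `n_failed`.
#'
#' @param image A [dynamic_image()].
#' @param reference A [tac()] on the image schedule (e.g. the SVCA
#'   pseudoreference curve).
#' @param brain A [label_mask()].
#' @param tstar Equilibration time (min), default 18.
#' @return 3D array of DVR values (`NA` outside the brain and at failed
#'   voxels), with attribute `n_failed`.
#' @export
dvr_parametric_map <- function(image, reference, brain, tstar = 18) {
  check_same_grid(image, brain)
  mid <- frame_midpoints(image$schedule, "min")
  keep <- mid >= tstar
  if (sum(keep) < 2L)
    stop("fewer than 2 frames past t* = ", tstar, " min", call. = FALSE)
  sel <- which(as.vector(brain$labels > 0))
  nf <- n_frames(image$schedule)
  V <- matrix(image$data, ncol = nf)[sel, , drop = FALSE]

  dt <- diff(c(0, mid))
  M <- cbind(0, V)
  inc <- (M[, -ncol(M), drop = FALSE] + M[, -1L, drop = FALSE]) / 2 *
    rep(dt, each = nrow(V))
  int_V <- t(apply(inc, 1, cumsum))
  int_ref <- cum_integral_from_zero(mid, reference$values)

  ok <- rowSums(V[, keep, drop = FALSE] <= 0) == 0L
  Vk <- V[, keep, drop = FALSE]
  X <- rep(int_ref[keep], each = nrow(V)) / Vk
  dim(X) <- dim(Vk)
  Y <- int_V[, keep, drop = FALSE] / Vk
  mx <- rowMeans(X); my <- rowMeans(Y)
  sxx <- rowMeans(X * X) - mx^2
  sxy <- rowMeans(X * Y) - mx * my
  slope <- ifelse(ok & sxx > 0, sxy / sxx, NA_real_)

  out <- array(NA_real_, dim(brain$labels))
  out[sel] <- slope
  attr(out, "n_failed") <- sum(!ok)
  out
}

#' DVR as a ratio of two Logan VT fits
#'
#' `AIF-DVR` style quantification: the plasma-input VT of the target VOI
#' divided by that of a reference (whole GM, or the SVCA pseudoreference).
#'
#' @param vt_target,vt_reference `logan_fit` objects from [logan_vt()].
#' @return Unitless DVR (ratio of slopes).
#' @export
vt_ratio_dvr <- function(vt_target, vt_reference) {
  stopifnot(inherits(vt_target, "logan_fit"),
            inherits(vt_reference, "logan_fit"))
  if (vt_reference$slope <= 0)
    stop("reference VT must be > 0", call. = FALSE)
  if (vt_target$slope <= 0)
    stop("target VT must be > 0", call. = FALSE)
  vt_target$slope / vt_reference$slope
}
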