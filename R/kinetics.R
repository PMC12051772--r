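#' Tri-exponential (Feng-type) plasma input model
#'
#' Parameterizes the metabolite- and decay-corrected plasma curve used to
#' drive the simulator: a linear rise multiplied into the fastest
#' exponential plus two slower washout exponentials,
#' \deqn{C_p(t) = (A_1 t' - A_2 - A_3) e^{-\lambda_1 t'} + A_2 e^{-\lambda_2 t'}
#'   + A_3 e^{-\lambda_3 t'}, \quad t' = t - \mathrm{delay},}
#' and 0 for `t <= delay`. The default coefficients give a bolus-like curve
#' peaking within a minute of arrival and decaying towards zero, with
#' activity in kBq/mL and time in minutes.
#'
#' @param A Length-3 amplitudes: `A[1]` in kBq/mL/min, `A[2:3]` in kBq/mL.
#' @param lambda Length-3 positive rate constants (1/min), fastest first.
#' @param delay Tracer arrival delay (min), `>= 0`.
#' @return An object of class `input_function_params`.
#' @export
input_function_params <- function(A = c(851.1, 21.88, 20.81),
                                  lambda = c(4.1339, 0.01043, 0.1191),
                                  delay = 0.1) {
  if (length(A) != 3L || length(lambda) != 3L)
    stop("`A` and `lambda` must have length 3", call. = FALSE)
  if (any(lambda <= 0)) stop("all rate constants must be > 0", call. = FALSE)
  if (delay < 0) stop("`delay` must be >= 0", call. = FALSE)
  structure(list(A = as.numeric(A), lambda = as.numeric(lambda),
                 delay = as.numeric(delay)),
            class = "input_function_params")
}

#' Evaluate the plasma input model
#'
#' @param params An [input_function_params()].
#' @param times_min Non-negative, strictly increasing sample times (min).
#' @return Numeric vector of plasma activity (kBq/mL), zero up to the delay.
#' @export
plasma_input <- function(params, times_min) {
  if (!inherits(params, "input_function_params"))
    stop("`params` must be input_function_params", call. = FALSE)
  if (any(times_min < 0))
    stop("times must be non-negative", call. = FALSE)
  if (length(times_min) > 1L && any(diff(times_min) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  tp <- times_min - params$delay
  A <- params$A; l <- params$lambda
  v <- (A[1] * tp - A[2] - A[3]) * exp(-l[1] * tp) +
       A[2] * exp(-l[2] * tp) + A[3] * exp(-l[3] * tp)
  v[tp <= 0] <- 0
  pmax(v, 0)
}

#' Compartment-model rate constants for one tissue class
#'
#' One- or two-tissue compartment kinetics. `k3 = k4 = 0` gives the
#' one-tissue model; `k3 > 0` requires `k4 > 0` (reversible binding). The
#' closed-form total distribution volume is
#' `VT = (K1/k2) * (1 + k3/k4)` (or `K1/k2` when `k3 = 0`), and `vB` is the
#' fractional blood volume mixed into the measured signal.
#'
#' @param K1 Plasma-to-tissue influx (mL/cm^3/min), > 0.
#' @param k2 Tissue-to-plasma efflux (1/min), > 0.
#' @param k3,k4 Exchange with the bound compartment (1/min).
#' @param vB Fractional blood volume in `[0, 1)`.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(K1, k2, k3 = 0, k4 = 0, vB = 0) {
  if (K1 <= 0 || k2 <= 0) stop("K1 and k2 must be > 0", call. = FALSE)
  if (k3 < 0 || k4 < 0) stop("k3 and k4 must be >= 0", call. = FALSE)
  if (k3 > 0 && k4 == 0)
    stop("irreversible binding (k3 > 0, k4 = 0) is not supported", call. = FALSE)
  if (vB < 0 || vB >= 1) stop("vB must be in [0, 1)", call. = FALSE)
  structure(list(K1 = K1, k2 = k2, k3 = k3, k4 = k4, vB = vB),
            class = "kinetic_params")
}

#' Closed-form total distribution volume
#' @param kp A [kinetic_params()].
#' @return `VT = (K1/k2) * (1 + k3/k4)` in mL/cm^3 (`K1/k2` when `k3 = 0`).
#' @export
vt_closed_form <- function(kp) {
  if (kp$k3 == 0) kp$K1 / kp$k2 else (kp$K1 / kp$k2) * (1 + kp$k3 / kp$k4)
}

## Impulse response of the 1T/2T compartment system at times t (min).
impulse_response <- function(kp, t) {
  if (kp$k3 == 0 && kp$k4 == 0) return(kp$K1 * exp(-kp$k2 * t))
  b <- kp$k2 + kp$k3 + kp$k4
  disc <- sqrt(b^2 - 4 * kp$k2 * kp$k4)
  a1 <- (b - disc) / 2
  a2 <- (b + disc) / 2
  kp$K1 / (a2 - a1) *
    ((kp$k3 + kp$k4 - a1) * exp(-a1 * t) + (a2 - kp$k3 - kp$k4) * exp(-a2 * t))
}

## Trapezoid-rule discrete convolution of two curves sampled on a uniform
## grid with step dt; returns a vector the length of x.
conv_trapezoid <- function(x, h, dt) {
  n <- length(x)
  full <- stats::convolve(x, rev(h), type = "open")[seq_len(n)]
  dt * (full - 0.5 * (x[1] * h + h[1] * x))
}

#' Simulate a tissue time-activity curve from compartmental kinetics
#'
#' Convolves the plasma input with the 1T/2T compartmental impulse response
#' on a fine internal grid (1-s step) and returns a continuous evaluator.
#' When `kp$vB > 0` the returned curve is the measured mixture
#' `vB * blood + (1 - vB) * tissue`, with the input curve standing in for
#' whole blood unless `blood` is given. The asymptotic Logan slope of the
#' pure tissue curve versus the input equals [vt_closed_form()].
#'
#' @param input Sampled input curve: a `data.frame` with columns `time_min`
#'   and `activity`, or an [input_function_params()] object (evaluated
#'   internally).
#' @param kp A [kinetic_params()].
#' @param t_end_min End of the simulation window (min); defaults to the last
#'   input sample time.
#' @param blood Optional whole-blood `data.frame` (`time_min`, `activity`)
#'   for the `vB` mixture.
#' @return A function `f(t_min)` returning kBq/mL, with attributes `vt`
#'   (closed-form VT) and `grid` (the internal dense samples).
#' @export
tissue_response <- function(input, kp, t_end_min = NULL, blood = NULL) {
  dt <- 1 / 60  # 1-s internal step; shortest frame is 10 s
  if (inherits(input, "input_function_params")) {
    t_end <- if (is.null(t_end_min)) 90 else t_end_min
    tgrid <- seq(0, t_end, by = dt)
    cp <- plasma_input(input, tgrid)
  } else {
    if (!all(c("time_min", "activity") %in% names(input)))
      stop("`input` needs columns time_min and activity", call. = FALSE)
    t_end <- if (is.null(t_end_min)) max(input$time_min) else t_end_min
    tgrid <- seq(0, t_end, by = dt)
    cp <- stats::approx(input$time_min, input$activity, xout = tgrid,
                        yleft = 0, rule = 2)$y
  }
  h <- impulse_response(kp, tgrid)
  ct <- pmax(conv_trapezoid(cp, h, dt), 0)  # clip FFT roundoff at t ~ 0
  if (kp$vB > 0) {
    cb <- if (is.null(blood)) cp else
      stats::approx(blood$time_min, blood$activity, xout = tgrid,
                    yleft = 0, rule = 2)$y
    ct <- kp$vB * cb + (1 - kp$vB) * ct
  }
  f <- stats::approxfun(tgrid, ct, rule = 2)
  attr(f, "vt") <- vt_closed_form(kp)
  attr(f, "grid") <- data.frame(time_min = tgrid, activity = ct)
  f
}

#' Average a continuous curve over the frames of a schedule
#'
#' Each frame value is the time-average of the curve over
#' `[start, start + duration]`, computed by trapezoid quadrature on a 1-s
#' subgrid (exact for linear curves).
#'
#' @param curve Function of time in minutes (e.g. from [tissue_response()]).
#' @param schedule A [frame_schedule()].
#' @return A [tac()].
#' @export
frame_average <- function(curve, schedule) {
  if (!is.function(curve)) stop("`curve` must be a function", call. = FALSE)
  vals <- vapply(seq_len(n_frames(schedule)), function(i) {
    a <- schedule$start_s[i] / 60
    b <- (schedule$start_s[i] + schedule$duration_s[i]) / 60
    ts <- seq(a, b, length.out = max(5L, ceiling(schedule$duration_s[i]) + 1L))
    pracma::trapz(ts, curve(ts)) / (b - a)
  }, numeric(1))
  tac(vals, schedule)
}

#' Add count-statistics-like frame noise to a TAC
#'
#' Independent zero-mean Gaussian noise per frame with
#' `SD = noise_coefficient * sqrt(value / duration_min)`: variance grows
#' with activity and shrinks with frame duration, the usual surrogate for
#' reconstructed-PET frame statistics.
#'
#' @param x A [tac()] with non-negative values.
#' @param noise_coefficient Unitless, `>= 0`.
#' @param seed Optional integer; when given, the RNG state is set locally
#'   and restored, so identical seeds give identical output.
#' @return A [tac()].
#' @export
add_noise <- function(x, noise_coefficient, seed = NULL) {
  if (noise_coefficient < 0)
    stop("`noise_coefficient` must be >= 0", call. = FALSE)
  if (any(x$values < 0))
    stop("TAC must be non-negative before adding noise", call. = FALSE)
  if (noise_coefficient == 0) return(x)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  sd <- noise_sd(x$values, x$schedule, noise_coefficient)
  tac(x$values + stats::rnorm(length(x$values), 0, sd), x$schedule)
}

## Nominal per-frame noise SD for a (vector or matrix of) frame values.
noise_sd <- function(values, schedule, noise_coefficient) {
  dur_min <- schedule$duration_s / 60
  if (is.matrix(values)) dur_min <- rep(dur_min, each = nrow(values))
  noise_coefficient * sqrt(pmax(values, 0) / dur_min)
}
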