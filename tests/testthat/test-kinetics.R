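test_that("plasma input model starts at zero, peaks early, is linear in amplitude", {
  p <- input_function_params()
  expect_equal(plasma_input(p, 0), 0)
  expect_equal(plasma_input(p, c(0, p$delay / 2, p$delay)), rep(0, 3))
  t <- seq(0, 90, by = 0.01)
  v <- plasma_input(p, t)
  expect_true(all(v >= 0))
  # single early peak inside (delay, delay + 3 min), then monotone decay
  peak <- t[which.max(v)]
  expect_gt(peak, p$delay)
  expect_lt(peak, p$delay + 3)
  after <- v[t > peak + 0.5]
  expect_true(all(diff(after) <= 1e-9))
  # linearity: doubling all amplitudes doubles the curve everywhere
  p2 <- input_function_params(A = 2 * p$A, lambda = p$lambda, delay = p$delay)
  expect_equal(plasma_input(p2, t), 2 * v)
  expect_error(plasma_input(p, c(2, 1)), "increasing")
  expect_error(input_function_params(lambda = c(-1, 1, 1)), "> 0")
})

test_that("closed-form VT follows the compartmental identities", {
  expect_equal(vt_closed_form(kinetic_params(0.1, 0.05)), 2)
  expect_equal(vt_closed_form(kinetic_params(0.1, 0.05, k3 = 0.02, k4 = 0.02)), 4)
  expect_error(kinetic_params(0.1, 0.05, k3 = 0.01, k4 = 0), "irreversible")
  expect_error(kinetic_params(0.1, 0.05, vB = 1), "vB")
})

test_that("simulated tissue curves match an independent ODE solution", {
  skip_if_not_installed("deSolve")
  p <- input_function_params()
  kp <- kinetic_params(0.3, 0.15, k3 = 0.03, k4 = 0.10)
  f <- tissue_response(p, kp, t_end_min = 90)
  cp_fun <- stats::approxfun(seq(0, 90, by = 1 / 60),
                             plasma_input(p, seq(0, 90, by = 1 / 60)),
                             rule = 2)
  rhs <- function(t, y, parms) {
    list(c(kp$K1 * cp_fun(t) - (kp$k2 + kp$k3) * y[1] + kp$k4 * y[2],
           kp$k3 * y[1] - kp$k4 * y[2]))
  }
  times <- seq(0, 90, by = 0.25)
  ode <- deSolve::ode(c(0, 0), times, rhs, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  ct_ode <- ode[, 2] + ode[, 3]
  ct_pkg <- f(times)
  big <- ct_ode > 0.01 * max(ct_ode)
  expect_lt(max(abs(ct_pkg[big] - ct_ode[big]) / ct_ode[big]), 0.005)
})

test_that("tissue response is linear in the input and Logan-consistent", {
  p <- input_function_params()
  t <- seq(0, 90, by = 1 / 60)
  inp <- data.frame(time_min = t, activity = plasma_input(p, t))
  kp <- kinetic_params(0.1, 0.05)
  f1 <- tissue_response(inp, kp)
  f2 <- tissue_response(transform(inp, activity = 3 * activity), kp)
  expect_equal(f2(seq(1, 89, by = 1)), 3 * f1(seq(1, 89, by = 1)),
               tolerance = 1e-10)
  # Logan slope versus the input equals closed-form VT within 3% (t* = 18)
  for (kpx in list(kinetic_params(0.1, 0.05),
                   kinetic_params(0.3, 0.15, k3 = 0.03, k4 = 0.1))) {
    fx <- tissue_response(inp, kpx)
    tt <- frame_average(fx, standard_schedule("WCM"))
    fit <- logan_vt(tt, input_function(inp$time_min, inp$activity),
                    tstar = 18, vb = 0)
    expect_lt(abs(fit$slope / vt_closed_form(kpx) - 1), 0.03)
  }
})

test_that("frame averaging is exact for constant/linear curves and accurate for kinetics", {
  s <- standard_schedule("WCM")
  expect_equal(frame_average(function(t) rep(7, length(t)), s)$values,
               rep(7, 32))
  a <- 0.4
  lin <- frame_average(function(t) a * t, s)$values
  expect_equal(lin, a * frame_midpoints(s, "min"), tolerance = 1e-12)
  # 2T curve versus 1e4-point quadrature per frame
  f <- tissue_response(input_function_params(),
                       kinetic_params(0.3, 0.15, k3 = 0.03, k4 = 0.1),
                       t_end_min = 90)
  got <- frame_average(f, s)$values
  oracle <- vapply(seq_len(32), function(i) {
    ts <- seq(s$start_s[i] / 60, (s$start_s[i] + s$duration_s[i]) / 60,
              length.out = 1e4)
    pracma::trapz(ts, f(ts)) / (ts[length(ts)] - ts[1])
  }, numeric(1))
  expect_lt(max(abs(got - oracle) / oracle), 0.001)
})

test_that("frame noise has the nominal count-statistics variance and is seeded", {
  s <- standard_schedule("WCM")
  x <- tac(rep(10, 32), s)
  expect_identical(add_noise(x, 0), x)
  expect_equal(add_noise(x, 0.3, seed = 5), add_noise(x, 0.3, seed = 5))
  expect_false(isTRUE(all.equal(add_noise(x, 0.3, seed = 5)$values,
                                add_noise(x, 0.3, seed = 6)$values)))
  expect_error(add_noise(x, -1), ">= 0")
  # Monte-Carlo moment check on one 30-s frame (frame 10): SD within 3%
  frame <- 10L
  nominal <- 0.3 * sqrt(10 / (s$duration_s[frame] / 60))
  set.seed(99)
  reps <- replicate(1e4, add_noise(x, 0.3)$values[frame])
  expect_lt(abs(stats::sd(reps) / nominal - 1), 0.03)
})
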