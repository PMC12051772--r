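#' Test-retest variability (TRV) and its absolute value
#'
#' `TRV = 100 * (T - RT) / ((T + RT) / 2)`: the signed percent difference
#' between test and retest values normalized by their mean. `atrv()` is its
#' absolute value. Both are vectorized over pairs and invariant to global
#' rescaling.
#'
#' @param t_val,rt_val Test and retest values (same units).
#' @return Percent TRV (signed) or aTRV (non-negative).
#' @export
trv <- function(t_val, rt_val) {
  m <- (t_val + rt_val) / 2
  if (any(m == 0)) stop("pair mean of zero: TRV undefined", call. = FALSE)
  100 * (t_val - rt_val) / m
}

#' @rdname trv
#' @export
atrv <- function(t_val, rt_val) abs(trv(t_val, rt_val))

#' Repeatability coefficient (%RC)
#'
#' The smallest relative change detectable with > 95% probability,
#' \deqn{\%RC = 100 \times 2.77 \times \sqrt{\frac{1}{N} \sum_j
#'   \frac{(T_j - RT_j)^2 / 2}{((T_j + RT_j)/2)^2}},}
#' i.e. 2.77 (= 1.96 sqrt(2)) times the root-mean within-pair relative
#' variance. Scale-free: doubling all measurements leaves it unchanged.
#' Pairs with zero mean are excluded with a warning.
#'
#' @param t_val,rt_val Paired test and retest values.
#' @return Percent repeatability coefficient.
#' @export
reliability_coefficient <- function(t_val, rt_val) {
  stopifnot(length(t_val) == length(rt_val), length(t_val) >= 1L)
  m <- (t_val + rt_val) / 2
  bad <- m == 0
  if (any(bad)) {
    warning(sum(bad), " pair(s) with zero mean excluded from %RC")
    t_val <- t_val[!bad]; rt_val <- rt_val[!bad]; m <- m[!bad]
  }
  if (length(m) == 0L) stop("no valid pairs for %RC", call. = FALSE)
  100 * 2.77 * sqrt(mean(((t_val - rt_val)^2 / 2) / m^2))
}

#' Intraclass correlation coefficient ICC(A,1)
#'
#' Two-way mixed-effects, absolute-agreement, single-measurement ICC
#' (McGraw & Wong A,1), the standard choice for test-retest agreement:
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' from the two-way ANOVA mean squares for rows (subjects), columns
#' (sessions) and error.
#'
#' @param mat Numeric matrix, subjects in rows, sessions/raters in columns
#'   (at least 2 of each).
#' @return ICC value (`<= 1`); `NA` with attribute `flag = "undefined"`
#'   when there is no variance at all.
#' @export
icc_agreement <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2L || k < 2L)
    stop("need at least 2 subjects and 2 sessions", call. = FALSE)
  grand <- mean(mat)
  if (sum((mat - grand)^2) == 0) {
    out <- NA_real_
    attr(out, "flag") <- "undefined"
    return(out)
  }
  row_m <- rowMeans(mat); col_m <- colMeans(mat)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((mat - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Bland-Altman agreement analysis
#'
#' Differences between paired measurements (in percent of the pair mean by
#' default, matching how biases are usually reported for DVR), with the
#' bias (mean difference) and 95% limits of agreement
#' `bias +/- 1.96 * SD(differences)`.
#'
#' @param a,b Paired measurements.
#' @param percent Express differences as `100 * (a - b) / pair mean`?
#'   Default `TRUE`.
#' @return List with `bias`, `lower`, `upper`, `sd`, and the per-pair
#'   `differences` and `means`.
#' @export
bland_altman <- function(a, b, percent = TRUE) {
  stopifnot(length(a) == length(b))
  if (length(a) < 2L) stop("need at least 2 pairs", call. = FALSE)
  m <- (a + b) / 2
  d <- if (percent) 100 * (a - b) / m else a - b
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, lower = bias - 1.96 * s, upper = bias + 1.96 * s,
       sd = s, differences = d, means = m)
}

#' Two-group difference test
#'
#' Welch two-sample t-test p-value. Degenerate input (zero variance in
#' both groups) returns p = 1 for equal means and p ~ 0 otherwise rather
#' than erroring, so it can run inside simulation loops.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @return p-value.
#' @export
group_compare <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  stats::t.test(a, b)$p.value
}

#' Per-region test-retest reliability report
#'
#' Assembles the full repeatability battery for paired measurements grouped
#' by region: test/retest mean and SD, signed TRV and aTRV (mean and SD
#' across subjects), %RC, ICC(A,1), and Bland-Altman bias with limits of
#' agreement (percent mode).
#'
#' @param data `data.frame` with columns `region`, `test`, `retest` (one
#'   row per subject x region), and optionally `volume_cm3`.
#' @return `data.frame`, one row per region.
#' @export
reliability_report <- function(data) {
  stopifnot(all(c("region", "test", "retest") %in% names(data)))
  regions <- unique(data$region)
  rows <- lapply(regions, function(rg) {
    d <- data[data$region == rg, ]
    tv <- trv(d$test, d$retest)
    ba <- if (nrow(d) >= 2) bland_altman(d$test, d$retest) else
      list(bias = NA_real_, lower = NA_real_, upper = NA_real_)
    icc <- if (nrow(d) >= 2) icc_agreement(cbind(d$test, d$retest)) else NA_real_
    data.frame(region = rg,
               volume_cm3 = if ("volume_cm3" %in% names(d)) d$volume_cm3[1] else NA_real_,
               n = nrow(d),
               test_mean = mean(d$test), test_sd = stats::sd(d$test),
               retest_mean = mean(d$retest), retest_sd = stats::sd(d$retest),
               trv_mean = mean(tv), trv_sd = stats::sd(tv),
               atrv_mean = mean(abs(tv)), atrv_sd = stats::sd(abs(tv)),
               rc = reliability_coefficient(d$test, d$retest),
               icc = as.numeric(icc),
               ba_bias = ba$bias, ba_lower = ba$lower, ba_upper = ba$upper)
  })
  do.call(rbind, rows)
}
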