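#' Power of the two-sample pooled t test at a given per-group n
#'
#' Exact power from the noncentral t distribution: with common SD `sd`,
#' detectable difference `delta` and `n` per group, the test statistic is
#' noncentral t with `df = 2n - 2` and noncentrality
#' `delta / (sd * sqrt(2/n))`.
#'
#' @param n per-group sample size (>= 2).
#' @param delta absolute mean difference to detect.
#' @param sd common standard deviation.
#' @param alpha two-sided significance level.
#' @return probability of rejecting at level `alpha`.
#' @export
t_test_power <- function(n, delta, sd, alpha = 0.05) {
  if (n < 2) stop("t_test_power: n must be >= 2")
  df <- 2 * n - 2
  ncp <- abs(delta) / (sd * sqrt(2 / n))
  tc <- qt(1 - alpha / 2, df)
  pt(tc, df, ncp = ncp, lower.tail = FALSE) + pt(-tc, df, ncp = ncp)
}

#' Per-group sample size for a two-arm treatment study
#'
#' Answers the planning question "how many subjects per group to detect a
#' given fractional improvement?": the detectable difference is
#' `improvement * |control_mean - mcao_mean|` (a fraction of the lesion
#' deficit, with control = full recovery), both hypothetical arms share the
#' lesioned group's SD, and `n` is the smallest integer whose exact
#' noncentral-t power reaches `power` at two-sided level `alpha`.
#'
#' `method = "normal"` instead returns the classical closed form
#' `ceiling(2 (z_{1-alpha/2} + z_{power})^2 (sd/delta)^2)`, which slightly
#' underestimates the t-based answer at small n.
#'
#' @param control_mean,mcao_mean group means of the measure (any units).
#' @param mcao_sd standard deviation of the lesioned group (> 0).
#' @param improvement fraction of the deficit the treatment is assumed to
#'   recover, in (0, 1]; e.g. 0.5 or 0.75.
#' @param alpha two-sided significance level.
#' @param power target power.
#' @param method `"t"` (exact noncentral t, default) or `"normal"`.
#' @return integer subjects per group.
#' @export
required_n <- function(control_mean, mcao_mean, mcao_sd,
                       improvement = 0.5, alpha = 0.05, power = 0.80,
                       method = c("t", "normal")) {
  method <- match.arg(method)
  if (mcao_sd <= 0) stop("required_n: mcao_sd must be positive")
  if (improvement <= 0 || improvement > 1)
    stop("required_n: improvement must lie in (0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("required_n: alpha must lie in (0, 1)")
  if (power <= 0 || power >= 1) stop("required_n: power must lie in (0, 1)")
  delta <- improvement * abs(control_mean - mcao_mean)
  if (delta == 0) stop("required_n: zero detectable difference")
  if (method == "normal") {
    zn <- (qnorm(1 - alpha / 2) + qnorm(power))^2
    return(as.integer(ceiling(2 * zn * (mcao_sd / delta)^2)))
  }
  n <- 2L
  while (t_test_power(n, delta, mcao_sd, alpha) < power) {
    n <- n + 1L
    if (n > 1e7) stop("required_n: did not converge (effect too small)")
  }
  n
}
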