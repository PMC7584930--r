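#' Two-sided unstratified log-rank test
#'
#' The significance engine behind every fragility iteration. At each distinct
#' event time \eqn{t} with \eqn{d_t} total events, \eqn{n_t} subjects at risk
#' and \eqn{n_{1t}} at risk in the experimental arm, the test accumulates the
#' observed-minus-expected events in the experimental arm
#' \deqn{O - E = \sum_t \left(d_{1t} - d_t \frac{n_{1t}}{n_t}\right)}
#' and the hypergeometric variance
#' \deqn{V = \sum_t d_t \frac{n_{1t}}{n_t}
#'       \left(1 - \frac{n_{1t}}{n_t}\right) \frac{n_t - d_t}{n_t - 1},}
#' with the convention \eqn{0/0 \to 0} when \eqn{n_t = 1}. The statistic
#' \eqn{(O-E)^2 / V} is referred to a chi-square distribution with 1 df; the
#' reported p value is the upper-tail probability (two-sided test, no
#' continuity correction).
#'
#' Ties follow the standard Mantel-Haenszel accounting: all events at the
#' same time are processed in one risk-set step, and subjects censored at
#' time \eqn{t} are still at risk for events at exactly \eqn{t}.
#'
#' @param data A [survival_dataset()] with both arms non-empty.
#' @return An object of class `logrank_result`: a list with elements
#'   `statistic` (chi-square, 1 df), `p_value`, `observed` and `expected`
#'   (event counts for the experimental arm), `direction` (sign of
#'   observed − expected in the experimental arm, in −1/0/+1), and
#'   `degenerate` (`TRUE` when the dataset has no events, in which case the
#'   statistic is 0 and p is 1).
#' @examples
#' d <- survival_dataset(c(1, 2), c(1, 1), c("experimental", "control"))
#' logrank_test(d)  # statistic 1, p = 0.317
#' @export
logrank_test <- function(data) {
  assert_testable(data)
  lr <- logrank_core(data$time, data$event, data$arm == "experimental")
  structure(lr, class = "logrank_result")
}

# Bare-vector implementation, called thousands of times per fragility
# computation; kept free of data-frame overhead.
logrank_core <- function(time, event, is_exp) {
  ev_t <- time[event == 1L]
  if (length(ev_t) == 0L)
    return(list(statistic = 0, p_value = 1, observed = 0, expected = 0,
                direction = 0L, degenerate = TRUE))
  dt <- sort(unique(ev_t))
  # events per distinct time, overall and in the experimental arm
  idx <- match(ev_t, dt)
  d <- tabulate(idx, nbins = length(dt))
  d1 <- tabulate(idx[is_exp[event == 1L]], nbins = length(dt))
  # at risk at t: everyone with observed time >= t (strict '<' drop-out,
  # so censorings tied with events remain at risk at that time)
  st_all <- sort(time)
  st_exp <- sort(time[is_exp])
  n_at <- length(time) - findInterval(dt, st_all, left.open = TRUE)
  n1_at <- length(st_exp) - findInterval(dt, st_exp, left.open = TRUE)
  frac <- n1_at / n_at
  oe <- sum(d1 - d * frac)
  corr <- ifelse(n_at > 1, (n_at - d) / (n_at - 1), 0)
  v <- sum(d * frac * (1 - frac) * corr)
  if (v <= 0) {
    if (abs(oe) > 1e-9)
      stop("log-rank variance is zero but O-E is not; inconsistent risk sets")
    return(list(statistic = 0, p_value = 1, observed = sum(d1),
                expected = sum(d * frac), direction = 0L, degenerate = FALSE))
  }
  stat <- oe^2 / v
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       observed = sum(d1), expected = sum(d * frac),
       direction = as.integer(sign(oe)), degenerate = FALSE)
}

# p value only, on bare vectors (hot path for fragility iterations)
logrank_p <- function(time, event, is_exp) {
  logrank_core(time, event, is_exp)$p_value
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Two-sided unstratified log-rank test\n"))
  cat(sprintf("  chi-square = %.4g (1 df), p = %.4g\n", x$statistic,
              x$p_value))
  cat(sprintf("  experimental arm: observed %g, expected %.4g events\n",
              x$observed, x$expected))
  if (isTRUE(x$degenerate)) cat("  [degenerate: no events in dataset]\n")
  invisible(x)
}
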