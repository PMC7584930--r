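#' Comparator fragility measure: artificial average-exposure patients
#'
#' Implements the fragility measure for survival data that iteratively adds
#' artificial patients to the experimental arm, each with an event at the
#' mean exposure time of all subjects in the original dataset, until
#' two-sided log-rank significance is lost.
#'
#' This measure is defined only for comparisons that are significant at
#' `alpha`; for a non-significant comparison the value is `NA` (no negative
#' counterpart exists). The mean exposure time is computed once, from the
#' original data over both arms, events and censored records alike; appended
#' artificial patients never change it.
#'
#' @inheritParams compute_sifi
#' @param max_iterations Cap on the number of appended patients; default ten
#'   times the original sample size.
#' @return An object of class `johnson_result`: list with `value`
#'   (nonnegative integer count, or `NA` when the original comparison is not
#'   significant), `mean_exposure`, `p_initial`, `p_trajectory` and
#'   `exhausted`.
#' @export
johnson_fragility <- function(data, alpha = 0.05, max_iterations = NULL) {
  assert_testable(data)
  stopifnot(alpha > 0, alpha < 1)
  if (is.null(max_iterations)) max_iterations <- 10L * nrow(data)
  mean_exposure <- mean(data$time)

  time <- data$time; event <- data$event; is_exp <- data$arm == "experimental"
  p0 <- logrank_p(time, event, is_exp)
  if (p0 >= alpha)
    return(structure(list(value = NA_integer_, mean_exposure = mean_exposure,
                          alpha = alpha, p_initial = p0,
                          p_trajectory = numeric(0), exhausted = FALSE),
                     class = "johnson_result"))
  traj <- numeric(0)
  k <- 0L
  exhausted <- FALSE
  repeat {
    if (k >= max_iterations) { exhausted <- TRUE; break }
    time <- c(time, mean_exposure)
    event <- c(event, 1L)
    is_exp <- c(is_exp, TRUE)
    k <- k + 1L
    p <- logrank_p(time, event, is_exp)
    traj <- c(traj, p)
    if (p >= alpha) break
  }
  structure(list(value = k, mean_exposure = mean_exposure, alpha = alpha,
                 p_initial = p0, p_trajectory = traj, exhausted = exhausted),
            class = "johnson_result")
}

#' @export
print.johnson_result <- function(x, ...) {
  if (is.na(x$value)) {
    cat(sprintf(paste0("Fragility (artificial-patient method): undefined ",
                       "(initial p = %.4g >= alpha = %g)\n"),
                x$p_initial, x$alpha))
  } else {
    cat(sprintf(paste0("Fragility (artificial-patient method) = %d ",
                       "artificial patients at mean exposure %.4g\n"),
                x$value, x$mean_exposure))
    if (x$exhausted) cat("  [exhausted: iteration cap reached]\n")
  }
  invisible(x)
}
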