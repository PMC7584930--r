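#' Index of the best survivor in an arm
#'
#' The best survivor is the subject with the longest observed follow-up time
#' in the arm, regardless of whether the record ends in an event or in
#' censoring. Ties at the maximum time are broken in favour of a censored
#' record over an event (a censored subject at \eqn{t} stochastically
#' dominates one who died at \eqn{t}), then by the lowest original row
#' position.
#'
#' @param data A [survival_dataset()].
#' @param arm `"experimental"` or `"control"`.
#' @return Integer row index into `data`.
#' @export
best_survivor_index <- function(data, arm) {
  idx <- which(data$arm == arm)
  if (length(idx) == 0L) stop("arm '", arm, "' is empty")
  best_idx_core(data$time, data$event, idx)
}

best_idx_core <- function(time, event, idx) {
  if (length(idx) == 0L) return(NA_integer_)
  t <- time[idx]
  cand <- idx[t == max(t)]
  cens <- cand[event[cand] == 0L]
  if (length(cens)) min(cens) else min(cand)
}

#' Index of the worst survivor in an arm
#'
#' The worst survivor is the subject with the earliest observed *event* in
#' the arm (censored records are never the worst survivor). Ties are broken
#' by the lowest original row position.
#'
#' @inheritParams best_survivor_index
#' @return Integer row index into `data`.
#' @export
worst_survivor_index <- function(data, arm) {
  idx <- which(data$arm == arm & data$event == 1L)
  if (length(idx) == 0L)
    stop("arm '", arm, "' has no events; worst survivor undefined")
  worst_idx_core(data$time, idx)
}

worst_idx_core <- function(time, idx) {
  if (length(idx) == 0L) return(NA_integer_)
  t <- time[idx]
  min(idx[t == min(t)])
}

sifi_variants <- c("flip_best", "flip_worst", "clone_best", "clone_worst")

# Donor arm and selector for one iteration step.
#   positive direction = the original comparison is significant and extreme
#   survivors are moved so the experimental arm's relative performance
#   degrades until significance is lost; negative mirrors donor/recipient.
variant_rule <- function(variant, positive, literal_directions) {
  rule <- switch(variant,
    flip_best  = list(sel = "best",  donor = "experimental", clone = FALSE),
    # default flip_worst direction degrades the experimental arm by granting
    # it the control arm's earliest event; literal_directions reproduces the
    # opposite (experimental -> control) movement instead
    flip_worst = if (literal_directions)
        list(sel = "worst", donor = "experimental", clone = FALSE)
      else
        list(sel = "worst", donor = "control", clone = FALSE),
    clone_best  = list(sel = "best",  donor = "experimental", clone = TRUE),
    clone_worst = list(sel = "worst", donor = "control", clone = TRUE),
    stop("unknown variant: ", variant))
  if (!positive)
    rule$donor <- setdiff(c("experimental", "control"), rule$donor)
  rule$recipient <- setdiff(c("experimental", "control"), rule$donor)
  rule
}

#' Survival-inferred fragility index (SIFI)
#'
#' Computes the SIFI of a two-arm comparison: the minimum number of
#' reassignments (or clonings) of extreme survivors between arms that moves
#' the two-sided unstratified log-rank p value across the significance
#' threshold `alpha`.
#'
#' If the comparison is significant (`p < alpha`), subjects are moved in the
#' direction that degrades the experimental arm's relative performance until
#' the first iteration at which `p >= alpha`; the SIFI is `+k`, the number of
#' moves. If the comparison is non-significant, donor and recipient arms are
#' mirrored and moves continue until `p < alpha`; the SIFI is `-k` (the
#' negative SIFI). The selection is recomputed on the current, already
#' modified dataset at every iteration.
#'
#' Variants:
#' \describe{
#'   \item{`flip_best`}{(default) reassign the donor arm's best survivor —
#'     longest follow-up, event or censored — to the other arm.}
#'   \item{`flip_worst`}{reassign the donor arm's earliest event to the other
#'     arm. By default the donor is chosen so the move weakens the
#'     experimental arm's advantage (control to experimental for positive
#'     SIFI); `literal_directions = TRUE` moves experimental to control
#'     instead.}
#'   \item{`clone_best`}{append a copy of the donor arm's best survivor to
#'     the other arm, keeping the original. Each subject is cloned at most
#'     once.}
#'   \item{`clone_worst`}{same, for the donor arm's earliest event.}
#' }
#'
#' @param data A [survival_dataset()].
#' @param alpha Significance threshold, strictly between 0 and 1. Significant
#'   means `p < alpha` strictly; loss of significance means `p >= alpha`.
#' @param variant One of `"flip_best"`, `"flip_worst"`, `"clone_best"`,
#'   `"clone_worst"`.
#' @param max_iterations Cap on iterations; defaults to the number of
#'   subjects. Exceeding it (or exhausting eligible donors) is reported via
#'   the `exhausted` flag, not as an error.
#' @param literal_directions See `flip_worst` above.
#' @return An object of class `sifi_result`: list with `value` (signed
#'   integer; positive iff the original comparison is significant),
#'   `variant`, `alpha`, `p_initial`, `p_trajectory` (one p per iteration,
#'   including the terminal one), `exhausted`, `n_initial`, `n_final` and
#'   `direction` (+1 positive / −1 negative SIFI).
#' @examples
#' set.seed(1)
#' d <- simulate_trial(n = 120, beta = -0.8)
#' compute_sifi(d)
#' @export
compute_sifi <- function(data, alpha = 0.05, variant = "flip_best",
                         max_iterations = NULL, literal_directions = FALSE) {
  assert_testable(data)
  variant <- match.arg(variant, sifi_variants)
  stopifnot(alpha > 0, alpha < 1)
  if (is.null(max_iterations)) max_iterations <- nrow(data)
  stopifnot(max_iterations >= 1)

  time <- data$time; event <- data$event; arm <- data$arm
  p0 <- logrank_p(time, event, arm == "experimental")
  positive <- p0 < alpha
  rule <- variant_rule(variant, positive, literal_directions)
  crossed <- if (positive) function(p) p >= alpha else function(p) p < alpha

  cloned <- rep(FALSE, length(time))   # clone-at-most-once provenance
  traj <- numeric(0)
  k <- 0L
  exhausted <- FALSE
  repeat {
    if (k >= max_iterations) { exhausted <- TRUE; break }
    eligible <- which(arm == rule$donor & !cloned)
    sel <- if (rule$sel == "best") {
      best_idx_core(time, event, eligible)
    } else {
      worst_idx_core(time, eligible[event[eligible] == 1L])
    }
    if (is.na(sel)) { exhausted <- TRUE; break }
    if (rule$clone) {
      cloned[sel] <- TRUE
      time <- c(time, time[sel]); event <- c(event, event[sel])
      arm <- c(arm, rule$recipient); cloned <- c(cloned, TRUE)
    } else {
      arm[sel] <- rule$recipient
    }
    k <- k + 1L
    p <- logrank_p(time, event, arm == "experimental")
    traj <- c(traj, p)
    if (crossed(p)) break
  }
  structure(list(
    value = if (positive) k else -k,
    variant = variant, alpha = alpha,
    p_initial = p0, p_trajectory = traj,
    direction = if (positive) 1L else -1L,
    exhausted = exhausted,
    n_initial = nrow(data), n_final = length(time),
    literal_directions = literal_directions
  ), class = "sifi_result")
}

#' @export
print.sifi_result <- function(x, ...) {
  cat(sprintf("SIFI = %+d  (variant %s, alpha = %g)\n", x$value, x$variant,
              x$alpha))
  cat(sprintf("  initial p = %.4g; terminal p = %.4g after %d iteration(s)\n",
              x$p_initial,
              if (length(x$p_trajectory)) utils::tail(x$p_trajectory, 1)
              else x$p_initial,
              length(x$p_trajectory)))
  if (x$exhausted)
    cat("  [exhausted: donor arm ran out or iteration cap hit before the\n",
        "   p value crossed the threshold]\n", sep = "")
  invisible(x)
}

#' Compute all four SIFI variants
#'
#' Runs [compute_sifi()] independently from the same original dataset for
#' each of the four variants.
#'
#' @inheritParams compute_sifi
#' @return Named list of `sifi_result`, one per variant.
#' @export
sifi_all_variants <- function(data, alpha = 0.05, max_iterations = NULL,
                              literal_directions = FALSE) {
  out <- lapply(sifi_variants, function(v)
    compute_sifi(data, alpha = alpha, variant = v,
                 max_iterations = max_iterations,
                 literal_directions = literal_directions))
  names(out) <- sifi_variants
  out
}
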