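#' Simulate a two-arm Weibull trial
#'
#' Generates a randomized two-arm time-to-event dataset under a Weibull
#' accelerated-failure-time (AFT) model, the standard single-binary-covariate
#' set-up of simple survival-data simulators. With treatment indicator
#' \eqn{x} (1 = experimental, 0 = control), latent event and censoring times
#' are
#' \deqn{T = e^{-(\beta_0 + \beta x)} E^{1/a_e}, \qquad
#'       C = e^{-\beta_{0c}} E'^{1/a_c},}
#' with \eqn{E, E'} independent unit exponentials, i.e. \eqn{T} is Weibull
#' with shape `anc_event` and scale \eqn{e^{-(\beta_0+\beta x)}}. Under this
#' parameterization the model is also proportional-hazards with log hazard
#' ratio \eqn{a_e \beta}: `beta = -1`, `anc_event = 1.5` gives HR
#' \eqn{e^{-1.5} \approx 0.22} favouring the experimental arm, `beta = 0`
#' exchangeable arms.
#'
#' Default location and shape values (`beta0_event = 2.0`,
#' `beta0_cens = 2.01`, `anc_event = 1.5`, `anc_cens = 2`) give two arms of
#' abstract time units with moderate censoring; the observed time is
#' `min(T, C)` and the event indicator is `T <= C`.
#'
#' @param n Total cohort size; must be even (1:1 allocation).
#' @param beta Effect-size coefficient on the treatment indicator.
#' @param anc_event,anc_cens Weibull ancillary (shape) parameters for the
#'   event and censoring distributions; both positive.
#' @param beta0_event,beta0_cens Location parameters of the event and
#'   censoring distributions.
#' @param seed Optional integer seed; the dataset is deterministic given it.
#' @param max_followup Optional administrative cutoff; observation is
#'   truncated (and censored) at this time. Default none.
#' @param label Dataset label.
#' @return A [survival_dataset()] with `n/2` experimental and `n/2` control
#'   subjects.
#' @examples
#' d <- simulate_trial(n = 200, beta = -0.5, seed = 42)
#' logrank_test(d)
#' @export
simulate_trial <- function(n, beta = 0, anc_event = 1.5, anc_cens = 2,
                           beta0_event = 2.0, beta0_cens = 2.01,
                           seed = NULL, max_followup = NULL,
                           label = "simulated trial") {
  if (n < 2 || n %% 2 != 0)
    stop("n must be an even integer >= 2 for exact 1:1 allocation")
  stopifnot(anc_event > 0, anc_cens > 0)
  if (!is.null(seed)) set.seed(seed)
  x <- rep(c(1L, 0L), each = n / 2)
  tt <- stats::rweibull(n, shape = anc_event,
                        scale = exp(-(beta0_event + beta * x)))
  cc <- stats::rweibull(n, shape = anc_cens, scale = exp(-beta0_cens))
  if (!is.null(max_followup)) cc <- pmin(cc, max_followup)
  survival_dataset(time = pmin(tt, cc), event = as.integer(tt <= cc),
                   arm = ifelse(x == 1L, "experimental", "control"),
                   label = label)
}

#' Parameter grid matching the reference simulation study
#'
#' The factorial layout used to map SIFI behaviour over survival-data
#' regimes: cohort sizes 100 to 1200 in steps of 100, censoring shape in
#' \{2, 4, 6, 8, 10\}, effect coefficient from −1 to 0.2 in steps of 0.05,
#' event shape 1.5, locations 2.0 / 2.01 — 1,500 cells; with the default 10
#' replicates per cell, 15,000 datasets.
#'
#' @param reps_per_cell Replicates per cell (default 10).
#' @return A data.frame with one row per (cell, replicate): columns `n`,
#'   `anc_cens`, `beta`, `rep`.
#' @export
reference_grid <- function(reps_per_cell = 10) {
  grid_layout(n = seq(100, 1200, by = 100),
              anc_cens = c(2, 4, 6, 8, 10),
              beta = seq(-1, 0.2, by = 0.05),
              reps_per_cell = reps_per_cell)
}

#' Enumerate a factorial simulation grid
#'
#' @param n,anc_cens,beta Vectors of cohort sizes, censoring shapes and
#'   effect coefficients to cross.
#' @param reps_per_cell Replicates per cell.
#' @return Data.frame with columns `n`, `anc_cens`, `beta`, `rep`, one row
#'   per dataset to simulate.
#' @export
grid_layout <- function(n, anc_cens, beta, reps_per_cell = 1) {
  stopifnot(reps_per_cell >= 1)
  g <- expand.grid(rep = seq_len(reps_per_cell), beta = beta,
                   anc_cens = anc_cens, n = n,
                   KEEP.OUT.ATTRS = FALSE)
  g[, c("n", "anc_cens", "beta", "rep")]
}

# Deterministic per-cell seed: a 31-bit polynomial hash of the cell key, so
# any subset of the grid reproduces independently of the rest.
cell_seed <- function(base_seed, n, anc_cens, beta, rep) {
  key <- sprintf("%d|%d|%.6f|%.6f|%d", as.integer(base_seed), as.integer(n),
                 anc_cens, beta, as.integer(rep))
  h <- 17
  for (v in utf8ToInt(key)) h <- (h * 31 + v) %% 2147483629
  as.integer(h)
}

#' Run a factorial simulation grid
#'
#' Simulates one dataset per grid row with [simulate_trial()], then estimates
#' the hazard ratio by a Cox proportional-hazards fit (Efron tie handling) on
#' the arm indicator, records the censoring percentage and the two-sided
#' log-rank p value, and optionally the flip-best SIFI.
#'
#' Per-row seeds are derived deterministically from `base_seed` and the cell
#' coordinates, so identical inputs give bit-identical output and subsets of
#' the grid are independently reproducible.
#'
#' @param grid Data.frame from [grid_layout()] or [reference_grid()].
#' @param base_seed Integer master seed.
#' @param anc_event,beta0_event,beta0_cens Shared simulation parameters.
#' @param alpha Significance threshold used for the SIFI column.
#' @param compute_sifi Logical; compute the flip-best SIFI per row (the
#'   expensive part — disable for envelope summaries that only need HR,
#'   censoring and p).
#' @return Data.frame: grid columns plus `seed`, `hr`, `pct_censored`, `p`,
#'   `degenerate` and (if requested) `sifi`. Rows with zero events are
#'   retained with `p = 1` and `degenerate = TRUE`.
#' @export
run_grid <- function(grid, base_seed = 1L, anc_event = 1.5,
                     beta0_event = 2.0, beta0_cens = 2.01, alpha = 0.05,
                     compute_sifi = TRUE) {
  stopifnot(all(c("n", "anc_cens", "beta", "rep") %in% names(grid)))
  m <- nrow(grid)
  seed <- integer(m); hr <- numeric(m); pct_cens <- numeric(m)
  p <- numeric(m); degen <- logical(m)
  sifi_v <- if (compute_sifi) integer(m) else NULL
  for (i in seq_len(m)) {
    s <- cell_seed(base_seed, grid$n[i], grid$anc_cens[i], grid$beta[i],
                   grid$rep[i])
    seed[i] <- s
    d <- simulate_trial(n = grid$n[i], beta = grid$beta[i],
                        anc_event = anc_event, anc_cens = grid$anc_cens[i],
                        beta0_event = beta0_event, beta0_cens = beta0_cens,
                        seed = s)
    pct_cens[i] <- 100 * mean(d$event == 0L)
    lr <- logrank_core(d$time, d$event, d$arm == "experimental")
    p[i] <- lr$p_value
    degen[i] <- lr$degenerate
    hr[i] <- if (lr$degenerate) NA_real_ else {
      fit <- survival::coxph(
        survival::Surv(time, event) ~ I(arm == "experimental"),
        data = d, ties = "efron")
      unname(exp(stats::coef(fit)))
    }
    if (compute_sifi)
      sifi_v[i] <- compute_sifi(d, alpha = alpha)$value
  }
  out <- cbind(grid,
               data.frame(seed = seed, hr = hr, pct_censored = pct_cens,
                          p = p, degenerate = degen))
  if (compute_sifi) out$sifi <- sifi_v
  rownames(out) <- NULL
  out
}
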