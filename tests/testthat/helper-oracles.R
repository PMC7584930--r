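# Independent oracles used across the suite. These deliberately avoid the
# package's own log-rank and iteration code paths: p values come from
# survival::survdiff and fragility crossings from from-scratch prefix
# recomputation.

survdiff_p <- function(data) {
  sd <- survival::survdiff(survival::Surv(time, event) ~ arm, data = data)
  stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
}

# One selection + move under the flip variants' deterministic rules.
# positive: degrade the experimental arm (best: exp -> ctl, worst: ctl -> exp);
# negative mirrors the donor arm.
apply_flip <- function(data, variant, positive) {
  donor <- if (variant == "flip_best") {
    if (positive) "experimental" else "control"
  } else {
    if (positive) "control" else "experimental"
  }
  sel <- if (variant == "flip_best") best_survivor_index(data, donor)
         else worst_survivor_index(data, donor)
  data$arm[sel] <- setdiff(c("experimental", "control"), donor)
  data
}

# First-crossing count by from-scratch prefix search: for k = 1, 2, ... apply
# k moves to a fresh copy of the original data and test it with survdiff.
prefix_oracle_flip <- function(data, variant, alpha = 0.05, kmax = nrow(data)) {
  positive <- survdiff_p(data) < alpha
  crossed <- if (positive) function(p) p >= alpha else function(p) p < alpha
  for (k in seq_len(kmax)) {
    cur <- data
    for (j in seq_len(k)) cur <- apply_flip(cur, variant, positive)
    if (crossed(survdiff_p(cur))) return(if (positive) k else -k)
  }
  NA_integer_
}

# Prefix oracle for the artificial-patient comparator: test "original plus k
# artificial experimental events at the original mean time" from scratch.
prefix_oracle_johnson <- function(data, alpha = 0.05, kmax = 10 * nrow(data)) {
  if (survdiff_p(data) >= alpha) return(NA_integer_)
  mexp <- mean(data$time)
  for (k in seq_len(kmax)) {
    extra <- data.frame(time = rep(mexp, k), event = 1L,
                        arm = "experimental")
    cur <- rbind(data.frame(time = data$time, event = data$event,
                            arm = data$arm), extra)
    if (survdiff_p(cur) >= alpha) return(k)
  }
  NA_integer_
}

# Trial-like datasets: Weibull AFT with ~50% censoring, sample sizes and
# effect strengths in the range of the packaged trial table (n 400-600,
# HR about 0.55-0.65). Used for panels where fragility behaviour should
# resemble published oncology trials.
make_trial_like <- function(seed, n = 400, beta = -0.35) {
  simulate_trial(n = n, beta = beta, seed = seed,
                 label = paste0("trial-like-", seed))
}

# Small significant two-arm datasets for fragility panels: exponential event
# times with a strong arm effect, optional uniform censoring.
make_significant <- function(seed, n_per_arm = 60, hr = 3, cens = 0) {
  set.seed(seed)
  t_exp <- stats::rexp(n_per_arm, rate = 1)
  t_ctl <- stats::rexp(n_per_arm, rate = hr)
  time <- c(t_exp, t_ctl)
  event <- rep(1L, 2 * n_per_arm)
  if (cens > 0) {
    cc <- stats::runif(2 * n_per_arm, 0, stats::quantile(time, 1 - cens / 2))
    event <- as.integer(time <= cc)
    time <- pmin(time, cc)
  }
  survival_dataset(time, event,
                   rep(c("experimental", "control"), each = n_per_arm),
                   label = paste0("panel-", seed))
}
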