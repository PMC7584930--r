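# Sample a fitted KM curve and at-risk table from a dataset, per arm, the
# way one would digitize a published figure (exact coordinates, no noise).
digitize <- function(data, curve_times = NULL, risk_times) {
  out_curve <- list(); out_risk <- list()
  for (a in c("experimental", "control")) {
    sub <- data[data$arm == a, ]
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = sub)
    tt <- c(0, fit$time)
    ss <- c(1, fit$surv)
    if (!is.null(curve_times)) {
      keep <- unique(c(0, curve_times[curve_times <= max(tt)]))
      ss <- vapply(keep, function(x) ss[max(which(tt <= x + 1e-12))], 0)
      tt <- keep
    }
    out_curve[[a]] <- data.frame(arm = a, time = tt, survival = ss)
    out_risk[[a]] <- data.frame(
      arm = a, time = risk_times,
      n_risk = vapply(risk_times, function(x) sum(sub$time >= x - 1e-9), 0))
  }
  list(curve = do.call(rbind, out_curve), at_risk = do.call(rbind, out_risk))
}

test_that("a no-censoring step curve inverts exactly", {
  curve <- data.frame(arm = rep(c("experimental", "control"), each = 6),
                      time = rep(0:5, 2),
                      survival = rep(c(1, .8, .6, .4, .2, 0), 2))
  at_risk <- data.frame(arm = c("experimental", "control"), time = 0,
                        n_risk = 5)
  rec <- reconstruct_ipd(curve, at_risk)
  d <- rec$dataset
  for (a in c("experimental", "control")) {
    sub <- d[d$arm == a, ]
    expect_equal(sort(sub$time), 1:5)
    expect_true(all(sub$event == 1L))
  }
  expect_true(all(rec$at_risk$discrepancy == 0))
  expect_true(is.na(rec$summary$median))
})

test_that("inconsistent inputs are rejected", {
  bad_curve <- data.frame(arm = rep(c("experimental", "control"), each = 3),
                          time = rep(c(0, 1, 2), 2),
                          survival = rep(c(1, 0.5, 0.7), 2))
  at_risk <- data.frame(arm = c("experimental", "control"), time = 0,
                        n_risk = 10)
  expect_error(reconstruct_ipd(bad_curve, at_risk), "must not rise")
  good_curve <- data.frame(arm = rep(c("experimental", "control"), each = 3),
                           time = rep(c(0, 1, 2), 2),
                           survival = rep(c(1, 0.7, 0.5), 2))
  bad_risk <- data.frame(arm = rep(c("experimental", "control"), each = 2),
                         time = rep(c(0, 1), 2), n_risk = rep(c(5, 9), 2))
  expect_error(reconstruct_ipd(good_curve, bad_risk), "not increase")
})

test_that("exact step-curve with at-risk at every step round-trips losslessly", {
  d <- simulate_trial(n = 120, beta = -0.6, seed = 31)
  # checkpoints at every digitized point of each arm's own curve
  out_c <- list(); out_r <- list()
  for (a in c("experimental", "control")) {
    sub <- d[d$arm == a, ]
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = sub)
    tt <- c(0, fit$time); ss <- c(1, fit$surv)
    out_c[[a]] <- data.frame(arm = a, time = tt, survival = ss)
    out_r[[a]] <- data.frame(
      arm = a, time = tt,
      n_risk = vapply(tt, function(x) sum(sub$time >= x - 1e-9), 0))
  }
  rec <- reconstruct_ipd(do.call(rbind, out_c), do.call(rbind, out_r))
  expect_true(all(rec$at_risk$discrepancy == 0))
  for (a in c("experimental", "control"))
    expect_equal(sum(rec$dataset$event[rec$dataset$arm == a]),
                 sum(d$event[d$arm == a]))
})

test_that("round-trip from sampled curves preserves the log-rank result", {
  for (seed in c(41, 42)) {
    d <- simulate_trial(n = 200, beta = -0.5, seed = seed)
    tmax <- max(d$time)
    dig <- digitize(d, curve_times = seq(0, tmax, length.out = 100),
                    risk_times = seq(0, tmax * 5 / 6, length.out = 6))
    rec <- reconstruct_ipd(dig$curve, dig$at_risk)
    p_orig <- logrank_test(d)$p_value
    p_rec <- logrank_test(rec$dataset)$p_value
    expect_lt(abs(p_orig - p_rec), 0.01)
    # arm sizes equal the first at-risk counts
    for (a in c("experimental", "control"))
      expect_equal(sum(rec$dataset$arm == a),
                   dig$at_risk$n_risk[dig$at_risk$arm == a &
                                      dig$at_risk$time == 0])
    # reconstructed KM within 0.02 of the input curve at checkpoints where
    # the curve is estimable (>= 20 at risk; below that a single event step
    # already exceeds the band, so pointwise agreement is meaningless)
    for (a in c("experimental", "control")) {
      sub <- rec$dataset[rec$dataset$arm == a, ]
      fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = sub)
      rk <- dig$at_risk[dig$at_risk$arm == a, ]
      for (ckpt in rk$time[rk$n_risk >= 20]) {
        s_in <- dig$curve$survival[dig$curve$arm == a &
                                   dig$curve$time <= ckpt + 1e-9]
        s_in <- s_in[length(s_in)]
        s_out <- c(1, fit$surv)[sum(c(0, fit$time) <= ckpt + 1e-9)]
        expect_lt(abs(s_in - s_out), 0.02)
      }
    }
  }
})

test_that("heavy censoring keeps at-risk discrepancies small", {
  d <- simulate_trial(n = 400, beta = -0.5, anc_cens = 2, seed = 57)
  expect_gt(mean(d$event == 0), 0.4)  # ~50% censored regime
  tmax <- max(d$time)
  dig <- digitize(d, curve_times = seq(0, tmax, length.out = 100),
                  risk_times = seq(0, tmax * 5 / 6, length.out = 6))
  rec <- reconstruct_ipd(dig$curve, dig$at_risk)
  nz <- rec$at_risk$discrepancy[rec$at_risk$discrepancy > 0]
  if (length(nz)) expect_lte(stats::median(nz), 2)
  expect_lt(abs(logrank_test(d)$p_value -
                logrank_test(rec$dataset)$p_value), 0.01)
})

test_that("total-events anchor constrains the final interval", {
  d <- simulate_trial(n = 200, beta = -0.4, seed = 77)
  tmax <- max(d$time)
  dig <- digitize(d, curve_times = seq(0, tmax, length.out = 80),
                  risk_times = seq(0, tmax * 0.7, length.out = 5))
  tot <- c(experimental = sum(d$event[d$arm == "experimental"]),
           control = sum(d$event[d$arm == "control"]))
  rec <- reconstruct_ipd(dig$curve, dig$at_risk, total_events = tot)
  got <- c(experimental = sum(rec$dataset$event[rec$dataset$arm == "experimental"]),
           control = sum(rec$dataset$event[rec$dataset$arm == "control"]))
  expect_true(all(abs(got - tot) <= 2))
})
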