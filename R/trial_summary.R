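#' Read a trial table
#'
#' Reads a CSV of per-trial results with columns
#' `trial,drug_class,tumor,year,n,hr,p,p_is_bound,sifi`. `p_is_bound = 1`
#' marks p values printed as an upper bound (e.g. "<.0001"), stored as the
#' bound itself.
#'
#' The package ships a transcription of a published 49-row table of phase 3
#' immune-checkpoint-inhibitor trials as its reference fixture; see
#' [trial_table()].
#'
#' @param path CSV file path.
#' @return Data.frame with the columns above; `p_is_bound` is logical.
#' @export
read_trial_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("trial", "drug_class", "n", "hr", "p", "p_is_bound", "sifi")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("trial table missing column(s): ", paste(miss, collapse = ", "))
  x$p_is_bound <- as.logical(x$p_is_bound)
  if (any(x$n <= 0)) stop("sample sizes must be positive")
  if (any(x$sifi == 0)) stop("SIFI values are signed and never zero")
  x
}

#' Packaged reference trial table
#'
#' Returns the packaged transcription of the published table of 45 phase 3
#' immune-checkpoint-inhibitor trials (49 two-arm comparisons; trials with
#' three groups or two dosing schedules contribute two rows) with per-trial
#' sample size, hazard ratio, log-rank p value and SIFI.
#'
#' @return Data.frame as from [read_trial_table()].
#' @export
trial_table <- function() {
  read_trial_table(system.file("extdata", "table1.csv", package = "sifi",
                               mustWork = TRUE))
}

#' Aggregate statistics over a trial table
#'
#' Computes the summary statistics used to characterise fragility across a
#' collection of trials: medians and interquartile ranges of sample size,
#' SIFI and |SIFI| (linear-interpolation quantiles, R type 7), the
#' percentage of significant comparisons, the number of comparisons whose
#' |SIFI| is strictly below 1% of the sample size, the Pearson correlation
#' between SIFI and log10 p (excluding bound-only p values), and per-class
#' counts of distinct trials.
#'
#' A p value stored as a bound (`p_is_bound`) counts as significant when the
#' bound is at or below `alpha`.
#'
#' @param table Data.frame as from [read_trial_table()].
#' @param alpha Significance threshold (default 0.05).
#' @return Object of class `trial_summary`: a list with elements
#'   `n_rows`, `median_n`, `iqr_n`, `median_sifi`, `iqr_sifi`,
#'   `median_abs_sifi`, `iqr_abs_sifi`, `n_significant`, `pct_significant`,
#'   `count_below_1pct`, `correlation_log_p` and `class_counts`.
#' @examples
#' summarize_trials(trial_table())
#' @export
summarize_trials <- function(table, alpha = 0.05) {
  if (nrow(table) == 0) stop("empty trial table")
  q <- function(x, p) unname(stats::quantile(x, p, type = 7))
  sig <- ifelse(table$p_is_bound, table$p <= alpha, table$p < alpha)
  exact <- !table$p_is_bound
  corr <- if (sum(exact) >= 3 && stats::sd(table$sifi[exact]) > 0 &&
              stats::sd(log10(table$p[exact])) > 0)
    stats::cor(table$sifi[exact], log10(table$p[exact]))
  else NA_real_
  cls <- vapply(split(table$trial, table$drug_class),
                function(tr) length(unique(tr)), 0L)
  structure(list(
    n_rows = nrow(table),
    median_n = q(table$n, 0.5), iqr_n = q(table$n, c(0.25, 0.75)),
    median_sifi = q(table$sifi, 0.5),
    iqr_sifi = q(table$sifi, c(0.25, 0.75)),
    median_abs_sifi = q(abs(table$sifi), 0.5),
    iqr_abs_sifi = q(abs(table$sifi), c(0.25, 0.75)),
    n_significant = sum(sig),
    pct_significant = 100 * mean(sig),
    count_below_1pct = sum(abs(table$sifi) < 0.01 * table$n),
    correlation_log_p = corr,
    class_counts = cls
  ), class = "trial_summary")
}

#' @export
print.trial_summary <- function(x, ...) {
  cat(sprintf("Trial table summary (%d comparisons)\n", x$n_rows))
  cat(sprintf("  sample size: median %g (IQR %g-%g)\n", x$median_n,
              x$iqr_n[1], x$iqr_n[2]))
  cat(sprintf("  SIFI:        median %g (IQR %g to %g)\n", x$median_sifi,
              x$iqr_sifi[1], x$iqr_sifi[2]))
  cat(sprintf("  |SIFI|:      median %g (IQR %g-%g)\n", x$median_abs_sifi,
              x$iqr_abs_sifi[1], x$iqr_abs_sifi[2]))
  cat(sprintf("  significant: %d (%.0f%%)\n" , x$n_significant,
              x$pct_significant))
  cat(sprintf("  |SIFI| < 1%% of n: %d\n", x$count_below_1pct))
  cat(sprintf("  Pearson r(SIFI, log10 p): %.2f\n", x$correlation_log_p))
  cat("  distinct trials per class:\n")
  for (nm in names(x$class_counts))
    cat(sprintf("    %-12s %d\n", nm, x$class_counts[[nm]]))
  invisible(x)
}

#' Count subjects censored in the first ventile of follow-up
#'
#' Counts the subjects of one arm censored during the first twentieth of the
#' follow-up span, taken as \[0, T/20\] with T the maximum observed time over
#' both arms. Comparing this count with the SIFI shows when the statistical
#' conclusion hinges on fewer patients than were lost to follow-up right
#' after randomization.
#'
#' @param data A [survival_dataset()].
#' @param arm Arm to count in (default `"experimental"`).
#' @return Integer count.
#' @export
censored_in_first_ventile <- function(data, arm = "experimental") {
  if (nrow(data) == 0) stop("empty dataset")
  bound <- max(data$time) / 20
  sum(data$arm == arm & data$event == 0L & data$time <= bound)
}

#' Compare the SIFI of a trial at two follow-up durations
#'
#' Computes the flip-best SIFI for the same comparison published at an
#' earlier and a later follow-up, and reports the difference — the stability
#' diagnostic for fragility over maturing data.
#'
#' @param early,late [survival_dataset()] objects for the two data cuts.
#' @param alpha Significance threshold.
#' @return List with `early`, `late` (both `sifi_result`) and `difference`
#'   (`late$value - early$value`).
#' @export
compare_followups <- function(early, late, alpha = 0.05) {
  e <- compute_sifi(early, alpha = alpha)
  l <- compute_sifi(late, alpha = alpha)
  list(early = e, late = l, difference = l$value - e$value)
}
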