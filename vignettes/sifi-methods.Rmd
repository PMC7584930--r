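---
title: "Survival-inferred fragility: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Survival-inferred fragility: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sifi)
```

## The fragility measure

A two-arm survival comparison is summarised by a two-sided unstratified
log-rank test. The survival-inferred fragility index (SIFI) asks how far
that comparison is from the significance threshold in units of *patients at
the extremes*: the minimum number of reassignments of best survivors (the
subjects with the longest observed follow-up, event or censored) from the
experimental to the control arm after which the p value is no longer below
α. Reassignment is re-evaluated greedily: after every move the test is
recomputed on the modified data and the next best survivor is selected from
the *current* arm membership. For comparisons that start non-significant
the donor and recipient arms are mirrored and iteration continues until the
p value drops below α; the count is reported with a negative sign. The sign
therefore always encodes the initial state — positive means "significant,
and k moves destroy it", negative means "non-significant, and k moves
would rescue it" — and a value of zero cannot occur.

Significance is strict: `p < α` is significant, `p ≥ α` is not. α defaults
to .05 and is configurable: fragility at one threshold is not comparable to
fragility at another, and lower prespecified thresholds (e.g. .0001) give
correspondingly lower indices.

### Variants

Four selection/move combinations are implemented:

| variant       | selected subject            | move                       |
|---------------|-----------------------------|-----------------------------|
| `flip_best`   | longest follow-up in donor  | reassign to the other arm  |
| `flip_worst`  | earliest *event* in donor   | reassign to the other arm  |
| `clone_best`  | longest follow-up in donor  | append a copy to the other arm |
| `clone_worst` | earliest *event* in donor   | append a copy to the other arm |

`flip_best` moves the experimental arm's best survivor to control (positive
direction). For `flip_worst` the donor is chosen so the move degrades the
experimental arm's relative performance, which means taking the control
arm's earliest event and giving it to the experimental arm; the literal
alternative (moving the experimental arm's earliest event to control) only
*improves* the experimental curve, so a positive comparison would never
lose significance — the package still offers it behind
`literal_directions = TRUE`, and the iteration then terminates through the
exhaustion flag rather than a crossing. Clone variants retain the original
subject and append a copy to the opposite arm; each subject is cloned at
most once, otherwise a flat curve could absorb the same clone indefinitely
and the iteration would not terminate.

Ties in best-survivor selection are broken in favour of a censored record
over an event at the same time (a subject censored at *t* has a weakly
better outlook than one who died at *t*), then by original row order; worst
survivors tie-break by row order only. These rules make the algorithm fully
deterministic, which the prefix-search oracle in the test suite relies on.

### Termination and edge cases

Iteration stops at the first crossing, at donor exhaustion (no eligible
subject left — for worst-survivor variants an arm can simply run out of
events), or at `max_iterations` (default: the subject count). Exhaustion is
reported via a flag rather than an error so that batch summaries over many
trials can proceed; the value then records the signed iteration count
reached. The p trajectory — one value per iteration, including the
terminal one — is returned so the crossing contract can be verified
directly.

## The log-rank engine

All iterations use the two-sided unstratified log-rank test with standard
Mantel–Haenszel risk-set accounting: at each distinct event time $t$ with
$d_t$ events, $n_t$ at risk and $n_{1t}$ at risk in the experimental arm,

$$O - E = \sum_t \left( d_{1t} - d_t \frac{n_{1t}}{n_t} \right), \qquad
V = \sum_t d_t \frac{n_{1t}}{n_t}\left(1 - \frac{n_{1t}}{n_t}\right)
\frac{n_t - d_t}{n_t - 1},$$

with $(n_t-d_t)/(n_t-1) := 0$ when $n_t = 1$. The statistic $(O-E)^2/V$ is
referred to $\chi^2_1$; no continuity correction is applied. Subjects
censored at $t$ remain at risk for events at exactly $t$ (ties follow the
convention of the mainstream survival packages, so recomputed p values line
up with published ones). A dataset with no events yields the degenerate
result (statistic 0, p 1, flagged). The implementation works on bare
vectors because it sits in the innermost loop; the test suite checks it to
1e-8 against `survival::survdiff` and against a hand-enumerated two-subject
example (statistic exactly 1, p = 0.3173).

## The artificial-patient comparator

The comparator implemented in `johnson_fragility()` appends patients to the
experimental arm, each with an event at the mean observed time of all
subjects in the *original* data (events and censored alike; the mean is
computed once and never updated), until significance is lost. It is
undefined (`NA`) when the comparison starts non-significant — it has no
negative counterpart. Two properties are worth knowing. First, the method
can fail to terminate: on uncensored data whose mean observed time falls
beyond most control-arm events, each artificial patient *increases* the
evidence against the null (they inflate the experimental risk sets early
and die late), and the p value decreases monotonically; the iteration cap
then reports exhaustion. Second, in realistic censoring regimes it yields
values several-fold larger than the flip-best SIFI, because average
"virtual" patients contribute far less information than the extreme
survivors that anchor the curves.

## The trial simulator

`simulate_trial()` draws latent event and censoring times from Weibull
accelerated-failure-time models with a binary treatment covariate $x$:

$$T = e^{-(\beta_0 + \beta x)}\,E^{1/a_e}, \qquad
C = e^{-\beta_{0c}}\,E'^{1/a_c},$$

with $E, E'$ unit exponentials; observed time is $\min(T, C)$ and the event
indicator $T \le C$. This Weibull AFT family is also proportional-hazards
with $\log \mathrm{HR} = a_e\,\beta$. With the defaults $a_e = 1.5$,
$\beta_0 = 2.0$, $\beta_{0c} = 2.01$ and $\beta \in [-1, 0.2]$ the
theoretical hazard-ratio span is $e^{-1.5} \approx 0.22$ to
$e^{0.3} \approx 1.35$, and empirical Cox estimates on grid cells of 100 to
1200 subjects span roughly 0.11 to 2.1 — the simulator parameterization was
chosen over the alternative scale convention ($\beta_0$ divided by the
shape) precisely because it produces this wide span of realized hazard
ratios; the choice is the single most consequential interpretation in the
simulator and is isolated in one function should a different convention be
needed.

The reference grid crosses 12 cohort sizes (100–1200 by 100, 1:1
allocation), 5 censoring shapes (2, 4, 6, 8, 10) and 25 effect
coefficients (−1 to 0.2 by 0.05), with 10 replicates per cell: 15,000
datasets. Per-row seeds are a 31-bit polynomial hash of
(base seed, n, censoring shape, β, replicate), so any subset of the grid is
reproducible independently and the full grid is bit-identical under a fixed
base seed. Hazard ratios are estimated by a Cox fit with Efron tie
handling; cells with zero events are retained flagged with p = 1.

Under the default regime censoring ranges from roughly 29% to 71% across
the reduced grid used in the acceptance checks (median 50%), overlapping
the 17.5%–50% band of the reference study; censoring is heaviest at the
strongest effects because the prolonged experimental-arm survival runs into
the censoring distribution.

## Kaplan–Meier IPD reconstruction

`reconstruct_ipd()` inverts digitized step-curve coordinates plus a
number-at-risk table into per-subject records, in the spirit of the
established iterative interval-balancing algorithms for this problem.
Within each checkpoint interval the censoring count is solved so that
events computed from the curve drops (rounded against the *reconstructed*
KM, which carries rounding residuals forward) reproduce the next published
at-risk count; censoring times are spread uniformly over the interval and
never spill past its boundary checkpoint. Three cases need care:

- intervals containing no digitized point: the curve is flat, so the whole
  at-risk decline is pure censoring, spread uniformly;
- checkpoints beyond the last digitized point: they carry no event
  information but pin late censoring times, handled as a censoring cascade;
- the final interval: with a per-arm total-event anchor (trial reports
  usually print event counts) the censoring there is solved to match;
  without one, no censoring is assumed before the last digitized time and
  the remaining at-risk subjects are censored there.

When an interval cannot be balanced exactly (rounding makes the fixed
point oscillate by one), the best allocation seen is kept and a warning is
raised. The at-risk table is then *recomputed from the reconstructed data*
and the per-checkpoint absolute discrepancies are reported with their
median and IQR — the fidelity diagnostic used when reconstructing published
trials, where a median discrepancy of a patient or two indicates a faithful
reconstruction.

Properties established by the round-trip tests: noiseless input (every step
digitized, at-risk at every step) inverts exactly with all-zero
discrepancy; with curves sampled at 100 points, 6 checkpoints and ~50%
censoring, at-risk tables reproduce within a discrepancy of 1, log-rank p
values agree to a median of well under 0.01, and the reconstructed KM
tracks the input within ±0.02 at checkpoints with at least 20 subjects at
risk. Below ~20 at risk a single event step already moves the curve by more
than 0.02, so pointwise agreement there is dominated by integer
granularity; likewise individual round-trip p gaps can reach ~0.02 when the
true p sits in the most sensitive mid-range, because the interleaving of
censorings between events inside an interval is genuinely unidentified from
the published inputs. Digitization noise itself is not modelled: input
coordinates are taken as exact.

## The packaged trial table

`trial_table()` ships a 49-row transcription of a published table of phase
3 immune-checkpoint-inhibitor trials (45 trials; three-group trials and
two-schedule trials contribute two comparisons). Conventions that matter
for reproducing its printed aggregates:

- quantiles use linear interpolation between order statistics (R type 7),
  which reproduces the printed medians and IQRs exactly on the sample-size,
  SIFI and |SIFI| columns;
- p values printed as bounds ("<.0001") are stored as the bound with a
  flag; they count as significant when the bound is at or below α and are
  excluded from the Pearson correlation between SIFI and log10 p;
- |SIFI| < 1% of n uses strict inequality;
- per-class trial counts count distinct trial names, not rows.

`censored_in_first_ventile()` counts the experimental-arm subjects censored
in [0, T/20] with T the maximum observed time over both arms — the
follow-up ventile against which the SIFI is compared to flag conclusions
that rest on fewer patients than were lost right after randomization. The
maximum observed time is used as the span because it is available for any
dataset; a reverse-KM follow-up quantile would need the full IPD of the
original report.

## Synthetic panels used in the tests

The variant-ordering and comparator checks run on simulator panels with
n ∈ {400, 500, 600}, β ∈ {−0.3, −0.35, −0.4} and the default censoring
shape — cohort sizes, hazard ratios (≈0.55–0.65) and censoring fractions
(~50%) in the range of the packaged trial table. On 100 significant panel
datasets the flip-best magnitude is the smallest of the four variants in
97–99% of cases and the artificial-patient comparator's median is several
times the flip-best median, mirroring the ordering reported for real
trials. These panels emulate the *scale and censoring pattern* of trial
data, not its clinical structure: there is no accrual period, no
administrative cutoff shared across subjects, and proportional hazards
holds exactly, so passing them demonstrates algorithmic correctness and
the documented orderings, not performance under model misspecification.

Problem sizes throughout the suite (n ≤ 1200 per dataset, 120-dataset
grids, 100-dataset panels, 400 null replicates, 6 reconstruction round
trips) were chosen so the whole suite exercises every code path at
realistic trial scale while remaining quick to run.

## Known limitations

- Only two-arm comparisons: multi-arm trials are analyzed pairwise.
- The unstratified test is a deliberate standardization; stratified or
  weighted log-rank variants used by some original trial analyses are out
  of scope, so recomputed p values can differ slightly from published ones.
- No confidence machinery is attached to the SIFI itself; it is a
  descriptive robustness measure, not an inferential statistic.
- The comparator's exhaustion behaviour (above) means its value is
  undefined-in-practice for some uncensored configurations.
- Reconstruction assumes exact digitized coordinates and uniform censoring
  within intervals; both assumptions are diagnosable through the at-risk
  discrepancy report but not corrected for.
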