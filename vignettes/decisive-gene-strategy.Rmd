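---
title: "The decisive gene strategy: sequential monitoring of candidate-gene meta-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The decisive gene strategy: sequential monitoring of candidate-gene meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgsmeta)
```

## The problem

A candidate-gene literature grows one case-control study at a time. Each
time a new study appears, the natural move is to re-run the meta-analysis
— but re-testing the same hypothesis after every addition inflates the
type I error well beyond the nominal level, and without a sample-size
target there is no way to say when a negative literature is *finished*
rather than merely underpowered. The decisive gene strategy treats the
growing literature for each locus and ethnicity stratum as a sequential
experiment: cumulative pooling supplies a Z-curve over accumulated
subjects, trial sequential analysis supplies a required information size
(RIS) and monitoring/futility boundaries, and a verdict engine reads the
crossing pattern into one of four conclusions — conclusive risk factor,
conclusive protective factor, conclusively unassociated, or inconclusive
with a stated number of subjects still to accumulate.

## The statistical model

**Per-study effect.** Each study's genotype triples are collapsed to a
2x2 minor-vs-major allele table (each subject contributes two alleles).
The effect is the Woolf log odds ratio $y_i = \log(a_i d_i / b_i c_i)$
with variance $v_i = 1/a_i + 1/b_i + 1/c_i + 1/d_i$. When any cell is
zero, 0.5 is added to all four cells (Haldane–Anscombe); the correction
is applied only in that case, which is the least biased of the common
defaults. A study with an entirely empty arm carries no information about
the odds ratio and is rejected.

**Pooling.** Random-effects pooling uses the DerSimonian–Laird moment
estimator: with fixed-effect weights $w_i = 1/v_i$, Cochran's
$Q = \sum w_i (y_i - \hat\mu_F)^2$,
$\hat\tau^2 = \max\{0, (Q - (k-1)) / (\sum w_i - \sum w_i^2/\sum w_i)\}$,
and random-effects weights $1/(v_i + \hat\tau^2)$. Heterogeneity is
summarised by $I^2 = \max\{0, (Q-(k-1))/Q\} \times 100$ and the diversity
$D^2 = 1 - v_F/v_R$, the fraction of the random-model pooled variance due
to between-study variation ($v_F$, $v_R$ are the pooled-estimate
variances under the fixed and random models, so $D^2 \in [0,1)$ always).
DerSimonian–Laird rather than REML matches the estimator sequential
meta-analysis practice was built around; the pooling core is a single
internal function, so swapping the estimator is a local change.
P-values are two-sided normal-theory; no small-$k$ t-correction
(Hartung–Knapp) is applied, because the monitoring boundaries already
operate on the normal Z scale.

**Look order.** Studies are pooled cumulatively in publication order,
one look per added study. Ties in year are broken lexicographically by
`study_id` — the boundaries depend on look order, so the tie-break is
part of the contract, not a cosmetic choice.

## The sequential design

**Required information size.** The control minor-allele frequency
$p_c$ (a design input from a reference panel, never re-estimated per
study) and an assumed allelic odds ratio give the comparator proportion
$p_t = OR \cdot p_c / (1 + p_c(OR - 1))$. The fixed-sample requirement is
the two-proportion normal-approximation size on the allele scale,

$$m = \frac{(z_{1-\alpha/2} + z_{1-\beta})^2 \,
      (p_c(1-p_c) + p_t(1-p_t))}{(p_t - p_c)^2},$$

alleles per group; since each subject contributes two alleles split
across two equal groups, the subject requirement is $\lceil m \rceil$.
Heterogeneity inflates it to the diversity-adjusted
$RIS = \lceil n_{fixed} / (1 - D^2) \rceil$. The default design —
two-sided $\alpha = 0.05$, power $0.80$, assumed OR $1.5$, fixed
$D^2 = 0.80$ — reflects common candidate-gene practice: allelic odds
ratios for complex-disease variants cluster around 1.5, and an 80%
diversity adjustment (a five-fold inflation) is the conservative
convention when the eventual heterogeneity of a literature is unknown.
An `"estimate"` mode instead applies the $D^2$ observed at the final
look; both the mode and the applied value are recorded in the output.

**Accumulated information** is counted in *subjects* (cases plus
controls), not alleles; allele tables are internal. Reported
"accumulated samples" and "remaining samples" are therefore subject
counts.

**Monitoring boundary.** Alpha is released over information fractions
$t$ by the O'Brien–Fleming-type Lan–DeMets spending function
$\alpha^*(t) = 2(1 - \Phi(z_{1-\alpha/2}/\sqrt t))$. For the two-sided
symmetric boundary this form is applied to each side at level $\alpha/2$
— the convention of the published Lan–DeMets tables, which the
implementation reproduces (two equal looks at $\alpha = 0.05$: 2.963,
1.969; five: 4.877, 3.357, 2.680, 2.290, 2.031). Thresholds are solved
by recursive numerical integration of the sequential sub-density in the
independent-increment Brownian representation: the continuation density
is propagated look to look by convolution on a trapezoid grid (512
points per look by default), and each threshold is found by `uniroot` so
the cumulative crossing probability under the null equals the spent
alpha. At the default grid the absolute error on crossing probabilities
is about $10^{-4}$, and the spending account balances to $\alpha$ at
full information within that tolerance. Spending increments smaller than
the crossing probability at $Z = 8$ report a capped threshold of 8
(the overspend is below $10^{-14}$); a single look at $t = 1$ reduces
exactly to the fixed-sample critical value.

**Futility wedge.** Beta is spent by the same O'Brien–Fleming-type form,
evaluated under the design alternative with drift $\theta\sqrt t$ where
$\theta = z_{1-\alpha/2} + z_{1-\beta}$ at full information, with the
same recursive integration (efficacy bound binding). Looks where the
computed wedge value is not positive are reported undefined — too little
information for any futility claim. Because the maximum information is
the *fixed-sample* RIS, matched spending leaves a small gap between the
wedge and the monitoring boundary at $t = 1$; the wedge is closed onto
the monitoring boundary there, as sequential-monitoring software
conventionally draws it. This is inconsequential for verdicts, since
reaching the RIS without a crossing is itself conclusive. For $t < 1$
the wedge lies strictly inside the monitoring band.

**Looks beyond the RIS** share information fraction 1 and keep the
thresholds of the look that reached it; no further alpha is spent there.

## The verdict engine

At the first look where $|Z|$ meets the monitoring threshold (equality
counts as crossing), the locus is a conclusive risk factor if the pooled
log-OR at that look is positive, conclusive protective if negative —
direction always refers to the minor allele as oriented by the design's
MAF reference, and each verdict carries a note saying so. Without a
significance crossing, either entering the futility wedge or reaching
the RIS yields *conclusively unassociated*; the RIS-reached route is
deliberately accepted even if the wedge was never entered, because a
literature that has accumulated its required information without
crossing has answered the question it was sized for. Anything else is
*inconclusive*, with `remaining = RIS - accumulated` subjects still
needed. A stratum that is nominally significant at the final look
($p < \alpha$) without any boundary crossing stays inconclusive — that
is the situation sequential monitoring exists to guard against — but the
verdict records a `nominal_significance` flag so such loci can be
surfaced rather than silently absorbed.

Heterogeneity is labelled by the strict rule $I^2 > 50$ is high
(exactly 50 is low), and verdicts are cross-tabulated against the label
in a 2x4 grid. Ethnicity strata are processed fully independently; no
pooling or borrowing crosses a stratum boundary.

The packaged per-locus summaries of published osteoporosis candidate-gene
meta-analyses (`published_summary()`) carry printed pooled ORs, I² values
and verdict strings for 17 Caucasian and 15 Asian loci. They are display
and classification fixtures: the per-study counts behind them are not
available, so they exercise the labelling, cross-tabulation and report
layers, not the pooling. Published "still need to accumulate" counts are
likewise not comparable to this package's RIS — the published values are
mutually inconsistent at near-identical MAF and I² (e.g. 1395 vs 2625),
so the RIS here is the internally consistent closed form documented
above.

## The synthetic cohort generator

`sim_scenario()` / `simulate_locus()` emulate exactly the statistical
structure the analysis assumes: control genotypes are multinomial draws
from Hardy–Weinberg proportions at the control MAF; each study perturbs
the true log odds ratio by $N(0, \tau^2)$; the case allele frequency is
the comparator-proportion transform of the perturbed OR, and case
genotypes are again Hardy–Weinberg draws. Each study has its own
deterministic substream seed, so the same scenario and seed are
byte-identical and appending studies never reshuffles earlier ones.

Two modelling shortcuts are deliberate. Cases are sampled from HWE at
the transformed allele frequency, although a strong allelic effect
distorts case genotype frequencies away from HWE; at the odds ratios
studied here the distortion is second-order. And the generator includes
no linkage disequilibrium, covariates, population stratification,
genotyping error or publication bias. Passing operating-characteristic
tests therefore show that the sequential machinery controls its errors
when the allele-model assumptions hold — they do not certify behaviour
on real literatures, where confounding and selective publication act
outside the model.

`operating_characteristics()` replicates a scenario, classifies every
replicate, and reports the significance-crossing rate, the naive
look-every-study rate on the same streams (any look with
$|Z| > z_{1-\alpha/2}$), verdict proportions and Monte-Carlo standard
errors. The package's own checks use a null stream of 20 studies of 106
subjects at MAF 0.3 (reaching the RIS of 2110 at the final look; 1000
replicates), where monitored false positives stay near 0.04 while naive
retesting exceeds 0.2, and a strong-effect stream (OR 2, 10 studies of
400) where the crossing rate is essentially 1 and the mean final pooled
log-OR recovers $\log 2$ within Monte-Carlo error. These problem sizes
are large enough that binomial Monte-Carlo error (about 0.007 on a rate
at 1000 replicates) does not mask the effects being measured.

## Degenerate inputs and numerical conventions

* $k = 1$: $Q = 0$, $\tau^2 = 0$, $I^2 = 0$, $D^2 = 0$; the pooled
  result is the study itself.
* $Q = 0$: $I^2$ is defined as 0 rather than 0/0.
* Integer required sizes use an epsilon guard before `ceiling`, so
  $389 / (1 - 0.8)$ is 1945, not the floating-point 1946.
* A study whose control minor-allele estimate exceeds 0.5 conflicts with
  the reference orientation; it is flagged in the log and kept as coded,
  never flipped, so OR direction stays comparable across studies.
* When no reference MAF is configured for a locus, it is estimated once
  from the pooled control arms (clamped to (0, 0.5]) and recorded in the
  design — a pragmatic fallback; a reference-panel MAF is preferred.
* Boundary computation requires strictly increasing fractions; repeated
  fraction-1 looks are deduplicated and share thresholds.

## Limitations

Only the allele model is implemented (no dominant/recessive/trend
alternatives), matching the inheritance-mode convention of the
literature the strategy targets. Only O'Brien–Fleming-type spending is
provided; the spending function is an internal seam where a Pocock or
power-family variant could be added. The DerSimonian–Laird estimator is
known to understate $\tau^2$ uncertainty for very small $k$; verdicts at
$k \le 3$ lean heavily on the boundary machinery rather than the
heterogeneity estimate. And the strategy inherits whatever selection
pressure shaped the underlying literature: sequential monitoring
corrects repeated testing, not publication bias.
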