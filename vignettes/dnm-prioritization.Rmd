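---
title: "Prioritizing risk genes from de novo mutations: model, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing risk genes from de novo mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnmrisk)
```

## The statistical model

`dnmrisk` scores genes for disease association from de novo mutation (DNM)
counts in sequenced parent–offspring trios. Only *extreme* mutations enter
the model: loss-of-function calls (frameshift and non-frameshift indels,
stop-gain, stop-loss, splicing SNVs) and damaging missense calls (D-Mis,
at least 8 of 14 predictor votes). Records are first restricted to rare
coding events — non-exonic calls and variants with population minor allele
frequency at or above 0.001 are removed; synonymous calls are retained at
the filtering stage (they are coding, and they count toward a gene's total
DNM tally) but carry no model evidence.

For gene $i$ and class $c$, with $N$ trios and per-haploid background rate
$\mu_{ic}$, the expected null count is $\lambda_{ic} = 2N\mu_{ic}$.
Under the null $x_{ic} \sim \mathrm{Pois}(\lambda_{ic})$; under the
risk-gene model the relative risk is Gamma-distributed,
$\gamma \sim \Gamma(\bar\gamma_c \beta_c, \beta_c)$, giving a negative
binomial marginal with size $\bar\gamma_c\beta_c$ and success probability
$\beta_c/(\beta_c + \lambda_{ic})$. The class Bayes factor is the ratio of
the two marginals, evaluated in log space so that counts up to at least
$10^4$ cannot overflow; gene evidence multiplies the two class factors.
Two boundary conventions matter in practice: a gene with
$\lambda = 0, x = 0$ carries no evidence (BF $= 1$), while
$\lambda = 0, x > 0$ is rejected as impossible under the null rather than
silently producing an infinite factor.

### Hyperparameters

The priors are deliberately fixed, not estimated:

| parameter | meaning | default |
|---|---|---|
| $\pi$ | prior fraction of risk genes | 0.05 |
| $\bar\gamma_{\mathrm{LoF}}$, $\beta_{\mathrm{LoF}}$ | mean relative risk / dispersion, LoF | 20, 1 |
| $\bar\gamma_{\mathrm{DMis}}$, $\beta_{\mathrm{DMis}}$ | mean relative risk / dispersion, D-Mis | 4.7, 1 |
| $M$ | null simulations per gene | 1000 |

These are conventional values for severe neurodevelopmental cohorts; all
are exposed through `tada_params()`. Moment-style estimation of
$\bar\gamma$ from the data is intentionally out of scope — fixed priors
keep runs reproducible and comparable across rate models.

### Two q-value routes

`bayesian_qvalues()` implements the Bayesian FDR: genes are ranked by
decreasing total Bayes factor and the q at rank $k$ is the running mean of
the posterior null probabilities over the top $k$; ties share the q of the
worst tied rank, so reordering tied genes cannot change any call.
`simulation_pvalues()` instead resamples each gene's null counts $M$ times
and reports $p = (\#\{BF^* \ge BF\} + 1)/(M+1)$, followed by
Benjamini–Hochberg adjustment. Both are computed; which one drives the
consensus is the `q_method` switch.

The simulation route has a resolution floor worth knowing about: the
smallest attainable $p$ is $1/(M+1)$, so after BH adjustment across $m$
genes a q below $t$ requires roughly $m/(M t)$ genes simultaneously at the
floor. With $M = 1000$ and $m = 5000$ genes, $q < 0.1$ is unreachable.
The BH route is therefore intended for candidate subsets (or larger $M$);
genome-wide work should use the Bayesian q, and that is what the
acceptance script's study-scale consensus does.

### Consensus across rate models

Because background rates are model-dependent, the fit runs once per rate
table (conventionally GC-content, sequence-context, methylation and
divergence based). `consensus_call()` labels a gene high-confidence when
its q is below 0.1 under at least `min_sources = 3` models **and** the
gene harbors at least 2 DNMs; a relaxed candidate tier applies the same
source rule at q < 0.3. A gene absent from one model's rate table simply
counts as not significant there. The DNM tally defaults to *all* coding
DNMs including synonymous ones — a gene with one LoF plus one synonymous
call qualifies — because the count expresses recurrence of observation,
not model evidence; `dnm_count = "extreme"` restricts it.

## Calibration, and the prior it depends on

The Bayesian FDR is only a calibrated quantity when $\pi$ matches the true
risk-gene fraction. The package's calibration tests therefore simulate
cohorts at the generator defaults (5000 genes, 1027 trios, 63 planted risk
genes with $\gamma_{\mathrm{LoF}} = 20$, $\gamma_{\mathrm{DMis}} = 4.7$)
and analyze them with $\pi = 63/5000$: the realized false-discovery
proportion among $q < 0.1$ genes then sits at its nominal level (about
0.08–0.13 across seeds, within two binomial standard errors of 0.1), and
cohorts with no planted risk genes yield essentially zero discoveries.
Running the same cohorts with the package default $\pi = 0.05$ — four
times the true fraction — inflates the realized FDP to roughly 0.25–0.31.
The acceptance script reports both numbers side by side
(`fdp_q01_matched_prior`, `fdp_q01_default_prior`) so the prior
sensitivity is visible rather than hidden: when the assumed $\pi$
overstates the truth, Bayesian q-values are anti-conservative in exactly
this proportion.

Sensitivity at this scale is modest by construction: with median
class rates of $10^{-5}$, a risk gene's expected LoF count is
$2 \cdot 1027 \cdot 10^{-5} \cdot 20 \approx 0.4$, so most planted risk
genes contribute zero or one extreme DNM and are statistically invisible.
The recovery test asserts the ordering that matters — sensitivity strictly
above the false-positive rate — rather than an arbitrary absolute level.

## Discreteness and randomized p-values

Count statistics are discrete: in a cohort most genes carry zero extreme
DNMs, so the literal $p = (\#\{BF^* \ge BF\}+1)/(M+1)$ has large atoms
(notably at 1) and is super-uniform under the null. It remains a valid,
conservative p-value — but "uniform under the null" is simply not a
property it can have, and a Kolmogorov–Smirnov test against U(0,1) would
reject it for reasons that have nothing to do with correctness. Both
`simulation_pvalues()` and `permutation_connectivity_test()` therefore
expose `tie_break = "randomized"`, which splits ties uniformly:
$p = (\#\{T^* > T\} + U\,\#\{T^* = T\} + 1)/(M+1)$, $U \sim
\mathrm{U}(0,1)$. The randomized form is exactly discrete-uniform under an
exchangeable null and is what the calibration tests use; the default
(`"none"`) is the conservative counting form, and the tests also assert
that it never falls below the randomized one.

## Network connectivity permutation test

"Is the candidate set unusually connected to the known risk genes?" is
answered by resampling: each of `n_iter` iterations draws a query-sized
gene set uniformly without replacement from the universe (the network's
node set by default) and recounts (a) query genes with at least one edge
to the fixed partner set and (b) qualifying edges. Both conventions for
the empirical p are reported — the plus-one form (primary) and the raw
$r/n$ form, which is what a permutation p of exactly $10^{-5}$ at 100,000
iterations corresponds to. The implementation precomputes each universe
gene's partner-neighbor count, so an iteration costs $O(|query|)$; edges
with both endpoints inside the partner set are tracked separately to avoid
double counting when both land in a sampled query. Correctness is checked
two ways: exhaustive enumeration of all 2-subsets of a 4-gene universe,
and uniformity of p over repeated random queries on an exchangeable
(Erdős–Rényi) graph.

Co-expression networks use the absolute Pearson correlation with the
conventional $|r| > 0.6$ edge rule; PPI edge lists are thinned at load by
a STRING-style combined-score cutoff, default 400 ("medium confidence"),
since published analyses rarely state the exact cutoff used. Whether
candidate–candidate edges count is a flag; the default counts only
query–partner pairs.

## Co-expression modules and eigengenes

Module discovery follows the unsigned WGCNA recipe: adjacency
$a_{ij} = |r_{ij}|^6$ (power 6, the standard unsigned scale-free choice),
topological overlap
$\mathrm{TOM}_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) / (\min(k_i,k_j) + 1 -
a_{ij})$, and average-linkage clustering on $1 - \mathrm{TOM}$. Dynamic
tree cutting is intentionally **not** reimplemented: the cut is either a
fixed module count (default 2) or a fixed height, with clusters below
`min_module_size = 5` left unassigned and surviving modules renumbered by
decreasing size. This is a known limitation — data with an unknown module
number need an externally chosen cut.

A module's eigengene is the first principal component of its
gene-standardized expression (samples as observations), rescaled to unit
variance and signed to correlate nonnegatively with the module's mean
profile, so a global sign flip of the data changes nothing observable.
Trajectories summarize the eigengene per developmental period as mean
± 1.96 SEM — a deliberate, assumption-light band; no loess smoothing.
All samples (every region × period) enter the correlations jointly; no
region averaging is applied before correlation.

## The synthetic data, and what passing tests do not show

The generators produce every input the pipeline reads, with planted
ground truth:

- **Trio DNMs** — per-gene class rates lognormal (median $10^{-5}$,
  log-sd 1), counts Poisson, 63 risk genes at relative risks 20/4.7,
  expanded to variant-level records; decoy rows (synonymous, noncoding,
  common, sub-threshold missense) are exactly the ones the filters remove.
  Four rate tables are lognormal-noise copies (log-sd 0.2) of the truth,
  chosen so the rate models disagree on marginal genes and the 3-of-4 rule
  is genuinely exercised.
- **Expression** — 6 brain regions × 15 ordered periods; module 1 (39
  genes) rises to a peak at 16–19 post-conception weeks then falls to a
  childhood low; module 2 (18 genes) dips through fetal/infant periods and
  recovers toward adulthood; Gaussian noise sd 0.4 around unit-amplitude
  templates gives within-module correlations near 0.75. The default matrix
  contains exactly the 57 module genes: risk genes missing from an
  expression resource drop out of the matrix entirely (as they do in real
  resources), rather than appearing as unpatterned profiles. With a fixed
  two-module cut, added pure-noise genes form their own dendrogram branch
  and wreck recovery of the planted split — a structural property of fixed-k
  cutting worth knowing when choosing `background_genes` and the cut.
- **Networks** — Erdős–Rényi background with optional planted
  query–partner edges; with nothing planted the graph is exchangeable, the
  regime in which permutation p-values must be uniform.
- **Gene sets** — each set draws a stated fraction of members from the
  query set, the rest uniformly.

What the synthetic data deliberately does *not* model: trinucleotide-
context mutation rates, region covariance structure in the brain data,
gene-length confounding between mutation rate and network degree, or
overlap between cohorts. Passing calibration here shows the statistics
are implemented correctly, not that real rate tables are unbiased or that
real expression noise is Gaussian.

## Numerical and edge-case choices

- Bayes factors in log space; `x > 0` with `λ = 0` errors, `x = 0` with
  `λ = 0` is BF 1.
- Simulation-p seeds are derived per gene from the master seed and a hash
  of the gene symbol (kept below $2^{31}$), so results are independent of
  gene order and list composition.
- Odds ratios are cross-product ($ad/bc$) with the Haldane 0.5 correction
  on any empty cell — reported alongside the exact Fisher p, which comes
  from the hypergeometric distribution and is unaffected by the
  correction. Note the corrected OR of a fully disjoint overlap is not
  forced below 1; the table cells are always reported so the direction can
  be read directly.
- Intolerance boundaries follow the conventions exactly: RVIS percentile
  $\le 25$ is intolerant, pLI $> 0.9$ (strict) is extremely intolerant,
  the hot zone is their conjunction.
- The MAF filter is strict: a variant observed at exactly 0.001 is
  removed.
- Multiple-testing correction across a gene-set collection defaults to BH
  (Bonferroni available); within the package BH is `stats::p.adjust`,
  verified in the tests against a brute-force step-up oracle.

## Problem sizes used in the shipped checks

The test-suite and acceptance-script workloads are sized for interactive
runs: 20 cohorts of 5000 genes for FDR calibration, 2000 genes for
p-value uniformity, 60,000 iterations for the enumeration comparison, 200
replicates × 499 iterations for permutation calibration, and 10 seeds for
module recovery. At these sizes the whole acceptance script completes in
well under a minute on one core; the statistics they estimate are the
package's own defaults scaled only in replicate count, never in the
underlying study conditions (trio counts, risk-gene number, rates, noise
levels are the generator defaults throughout).
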