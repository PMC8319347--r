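---
title: "Models and methods behind syntrophevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind syntrophevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(syntrophevo)
```

`syntrophevo` packages the statistical machinery needed to analyse a
laboratory-evolution experiment on an obligate syntrophic coculture: a
sulfate reducer (*Dv*-like partner) that ferments lactate and hands
hydrogen/formate to a methanogen (*Mm*-like partner). Thirteen replicate
cocultures evolve for a thousand generations and are sequenced at
generations 100, 300, 500, 780 and 1000; end-point dilutions, single-cell
genotyping and clonal pairings characterise the evolved communities. Every
analysis in the package runs end to end on synthetic data with known ground
truth, so each estimator can be validated against the quantity it is
supposed to recover.

## Parallel evolution: G-scores, randomization null, Z

For each gene with `O` observed nonsynonymous mutations pooled across
lines and a length-proportional expectation `E = N * L / sum(L)`, the
goodness-of-fit score is

    G = 2 * O * ln(O / E),    G = 0 when O = 0.

The genome-wide statistic is the sum over genes. Its null distribution
comes from re-placing the observed `N` mutations uniformly along the
genome (a gene is hit proportionally to its length; hits in unannotated
sequence score zero) and recomputing the total; with null mean and sd
`(mu, sigma)` the parallelism score is `Z = (G_obs - mu) / sigma`.

Numerical conventions worth stating:

* genes with `0 < O < E` contribute *negative* G — the formula as written;
  only positive excesses indicate parallelism, and ranking uses the signed
  value;
* `observed_gscores()` counts pooled events by default; `per_line_unique`
  counts each gene once per line, matching how "mutated across two or more
  lines" is tallied;
* intergenic calls are excluded from scoring and reported in the
  `excluded` attribute;
* the expectation uses the summed *gene* length as denominator, while the
  null can place hits in intergenic sequence when the catalog declares a
  genome longer than its genes. Synthetic calibration catalogs declare no
  intergenic space, so generator and null coincide exactly.

Calibration of the pipeline is a property of the whole chain: data
generated with all enrichment factors at 1 give `Z` centred at zero
(checked over 50 synthetic datasets of 50 genes and about 100 mutations,
1000 randomizations each). Power has a structural limit that the package
documents rather than hides: a *single* enriched gene raises the total G by
about `2 * O * ln(O/E)`, and at enrichment 5 the ratio `O/E` cannot exceed
about 5, so one gene contributes roughly `3.2 * O` while the null sd itself
grows with `N`. Detecting one planted gene at enrichment 5 with ~10 hits
therefore yields `Z` of order 1, far below the genome-wide signal that many
co-enriched genes produce in real data; the power test accordingly checks
the planted gene's *rank* (it is reliably rank 1 once it reaches 10 hits)
and reports the Z behaviour as measured.

## Longitudinal trajectory statistics

Trajectories are per-line, per-gene frequency series over the sampled
generations. Three numbers operationalise the qualitative patterns:

* **fixation**: the earliest sampled generation from which the frequency
  stays at or above 0.95 (transient excursions do not count);
* **detection**: frequency at or above 0.05, the package's declared bulk
  detection limit (the source experiment never states one; its variant
  filter is 0.20, and 0.05 is a conventional bulk-sequencing floor);
* statistics between two loci count supporting lines: co-occurrence
  (detected together at `k >= 2` common time points by default),
  simultaneous fixation (same fixation generation), nested fixation
  (later-detected locus fixes no later than the earlier one).

Empirical significance uses `P = (s + 1) / (n + 1)`, `s` being null
replicates with an equal-or-stronger (`>=`) statistic. The null keeps the
number of mutated genes per line and the number of lines per gene fixed.
Two mechanisms implement it:

* **swap randomization** of the line-by-gene presence matrix (checkerboard
  swaps; burn-in of 10x the matrix fill, a fresh batch of swap attempts
  between replicates), with each line's observed trajectory summaries
  re-dealt among that line's events — so both margins hold exactly in
  every replicate;
* **placement null** — each gene independently dropped onto a uniformly
  random line subset of its observed size, its trajectory summaries
  travelling with it — used when the matrix admits no checkerboard swap at
  all (with two loci in identical line sets there is nothing to swap), and
  available explicitly via `null = "placement"`.

`exact_association_pvalue()` enumerates the placement space outright and
is the oracle the Monte-Carlo path is tested against (exact value 1/3 on
the canonical 3-line instance). One honest caveat: a counting statistic
over a handful of lines takes few values, so its permutation P is
conservative and lumpy at the 13-line study scale. The uniformity property
is therefore checked where it can actually hold — 150 independent replicate
lines — and users should read P values near 1/13-resolution data as
conservative.

Cross-species sweeps are detected per line from adjacent sampled
generations: the earliest interval `(g1, g2]` in which, in *both*
organisms, some dominant locus set (frequency >= 0.5) crashes below
detection while a disjoint undetected set rises to dominance. No
interpolation is attempted between samples; with ~250-generation spacing
the data cannot distinguish one joint sweep from two rapid sequential
ones, and the detector does not pretend otherwise.

## Single-cell lineage inference

Single-cell genotypes are ternary: 1 (mutation present), 0 (absent),
3 (not enough reads). `build_mutation_matrix()` applies the genotyping
cutoffs — fold coverage >= 8 for a callable state, within-cell frequency
>= 0.80 for presence (the inclusive reading of the two printed
thresholds), and >= 2 presence cells to keep a mutation.

The mutation tree places each mutation at one node of a rooted tree; a
cell attached at a node carries all mutations on its root path. The
likelihood uses the standard single-cell error model with false-positive
rate `fd = 6.04e-5` and allelic dropout `ad = 0.21545` (the second dropout
parameter of the homozygous-aware variant collapses onto `ad` here because
states are binary presence/absence):

    P(obs 1 | true 0) = fd      P(obs 0 | true 1) = ad
    P(obs 0 | true 0) = 1 - fd  P(obs 1 | true 1) = 1 - ad
    state 3 contributes a factor of 1.

Each cell is scored at its best attachment node (`attachment = "max"`,
i.e. ML attachment; `"sum"` averages over nodes under a uniform prior that
includes the root). Inference enumerates every parent vector for up to 7
mutations and returns the global optimum; larger problems use a seeded
Metropolis search over prune-and-reattach and label-swap moves with a
default chain length of 1e5 (the published run length is ambiguous between
9e4 and 9e5 — 1e5 is the package default and a flag). Likelihood ties are
real and frequent (two mutations carried by identical cell sets order
arbitrarily); the tie-break is deterministic (lexicographically smallest
parent vector) and tied label pairs are reported. For tied *trunk*
mutations, `order_trunk_by_generations()` imposes the longitudinal order of
first detection; a tied mutation never seen in bulk data keeps its position
and is flagged as a rare / below-detection lineage.

At the experiment's scale (5 trunk-mutation candidates, ~90 cells) the
true tree is recovered in well over 80% of simulations; recovery degrades
as dropout grows, which the property suite checks directionally.

## Growth kinetics and the dilution assay

OD curves are fitted by bounded Levenberg–Marquardt least squares to the
modified logistic and Gompertz forms parameterised by maximum growth rate
`mu` (OD/h), lag `lambda` (h) and capacity `A` (OD):

    logistic: A / (1 + exp(4*mu*(lambda - t)/A + 2))
    Gompertz: A * exp(-exp(mu*e*(lambda - t)/A + 1))

Starts come from the data (capacity from the maximum OD, rate from the
steepest finite difference, lag from that tangent's intercept), with two
perturbed restarts before declaring non-convergence — which yields
`grew = FALSE` plus a diagnostic, never an error. When no fixed blank
value is supplied the baseline is fitted as a free offset. Model choice is
by small-sample-corrected AIC with ties going to the logistic. A well
"grows" when its OD rises at least 0.05 above baseline for three
consecutive readings (the assay's growth call is a package choice, exposed
as `growth_threshold`).

Dilution plates carry a 1.5-fold series with blank wells; any blank that
grows aborts the analysis as contamination. The minimal permissive density
is the lowest seeding density with at least one growing replicate,
reported with the full per-density growth profile so that two plates one
dilution step apart resolve exactly a 1.5-fold difference.

## Excess over Bliss

Fractional effects of evolved partners come from the 2x2 pairing design
(ancestral/evolved for each species), by default relative to the ancestral
baseline and clamped to [0, 1] with a flag (the mapping from raw rates to
fractions is not fixed by the source experiment; `relative_to_full` is the
alternative). Bliss independence expects
`f_DvMm = f_Dv + f_Mm - f_Dv*f_Mm`, and

    EOB = (f_z - f_DvMm) * 100.

Errors propagate to first order assuming independent measurements (each
pairing grows in its own tube):
`sd(f_DvMm)^2 = (1-f_Mm)^2 sd(f_Dv)^2 + (1-f_Dv)^2 sd(f_Mm)^2`, and a
pairing is called additive within ±2 propagated sd of zero ("EOB ≈ 0" made
operational; the band is a parameter). The first-order sd agrees with
Monte-Carlo propagation to within 5% for fraction sds up to ~0.2, which
the suite verifies.

## The synthetic-data generators

`simulate_lines()` emulates the longitudinal design: per line and
organism, a Poisson number of mutation events (default 8/line) lands on
genes multinomially, proportional to gene length times an enrichment
factor — so enrichment 1 is exactly length-proportional, and planted
parallel genes are ordinary genes with enrichment > 1. Events under
selection (probability 0.5) follow a logistic frequency rise spanning
250–450 generations from their appearance; neutral events persist at a low
level. Noise is frequency-dependent (`sd ∝ sqrt(f(1-f))`) so fixed
mutations stay fixed in sampled data. A planted cross-species sweep forces
a replaced set to fall from ~0.85 to below detection and a novel set to
rise symmetrically across one sampling interval in both organisms.

The other generators mirror their consumers: per-caller call sets apply
per-caller false-negative dropout, binomial false positives over a decoy
site space and Gaussian frequency jitter; single-cell matrices attach
cells uniformly over tree nodes (root included — a root cell simply has no
mutations) and apply the fd/ad/missing model; growth plates grow a well
iff its seeding density reaches the planted permissive minimum, with
truncated-Gaussian OD noise; pairings plant additive, synergistic or
antagonistic deviations from the Bliss expectation on the fractional
scale.

What the generators deliberately do **not** emulate: linkage between
mutations within a clone (events are independent), clonal interference,
sequencing-depth-dependent frequency error, doublets or chromosome-loss
artifacts in single cells, and plasmid loss (one published mutation was
undetectable in single cells for that reason — the model carries no
plasmid state). Passing tests therefore demonstrate that the estimators
recover what the error models describe, not that real data meet those
models.

## Problem sizes and reproducibility

The test and acceptance workloads are sized for a laptop-class single
core: 50 calibration datasets of 50 genes x ~100 mutations with 1000
randomizations each; 100-seed power and recovery studies; permutation
oracles at 1e5 replicates on the enumerable instance and 499 per seed for
the 200-seed uniformity study; exhaustive tree search at 4–5 mutations
against a brute-force oracle. Every stochastic routine takes an explicit
seed, the pipeline derives per-stage seeds deterministically from one
master seed, and a rerun from the manifest's config reproduces every
output byte for byte.
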