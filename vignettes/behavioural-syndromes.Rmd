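---
title: "Methods: from scored trials to a behavioural syndrome network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from scored trials to a behavioural syndrome network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(behavsyn)
```

`behavsyn` implements a complete analysis chain for individual-level
behavioural variation: trial-level scoring of three captive paradigms, a
repeatability gate, collinearity-gated composite axes, a
hormone-behaviour association scan, and a field module for non-invasive
genetics and terrain-aware disturbance exposure. This vignette is the
package's account of the statistical choices, their assumptions, and
their limits.

## Behavioural metrics

The multi-access box (MAB) paradigm yields, per trial, *persistence* (the
union of scored interaction intervals divided by trial duration — scored
video segments can overlap, so intervals are merged before summation to
avoid double counting) and *inverse inhibitory control* (time on
previously learned but now blocked solutions over total exploration
time). One-shot first-exposure measures are *neophobia* (latency to first
contact, right-censored at the trial duration and flagged when the
subject never approaches) and *exploratory diversity* (distinct behaviour
codes). The *learning rate* is the within-phase OLS slope of exploration
duration on trial number, averaged over phases, z-standardized across the
cohort and sign-flipped so higher values mean faster decline. Two
orderings of that standardization are defensible (standardize per phase
then average, or average then standardize); we average first, which
weighs every phase equally within an individual and keeps a single
cohort-level scale. Familiarization trials contribute to task-completion
counts but not to learning-rate slopes (the apparatus is unconstrained
there); a `trials_completed` convention including familiarization is the
default.

The resource depletion test is scored from ordered bowl visits. Six
metrics follow directly from the visit sequence (pick count,
working-memory errors, learned-location visit ratio and stay-duration,
accuracy, locations visited). Two rule-based indices need conventions:
*trials to learn* is the third trial of the first run of three
consecutive trials with at most two picks (capped at 20 trials), and
*delayed fixation trials* (DFT) counts depletion-phase trials elapsed
before the first run of three consecutive trials without a
learned-location visit — so immediate avoidance scores 0 and an
individual that never disengages is censored. In the pipeline, censored
values are set to the phase length (21 and the number of depletion
trials) rather than dropped, keeping non-learners inside the composite
axis instead of silently selecting on the outcome.

The string-pulling criterion is at least 8 successes in each of three
consecutive overlapping 10-trial windows; the deductive reasoning score
(DRS) is the trial at which the third window closes, 151 for
non-learners. Windows move by one trial, so the earliest attainable DRS
is 12. Handedness uses HI = (R − L)/(R + L) and the binomial normal
approximation z = (R − N/2)/√(N/4) with a two-sided 1.96 cutoff
(configurable); the exact binomial test agrees with the z label except in
a narrow band around the cutoff, which the tests document.

## Repeatability

Metrics measured repeatedly are only promoted to individual attributes if
they are significantly repeatable. The model is a Gaussian random
intercept per individual with trial number (and phase, where meaningful)
as fixed effects. The fitter profiles both the fixed effects and the
residual variance out of the (restricted) likelihood, leaving a
one-dimensional optimization over the variance ratio
λ = σ²_ind/σ²_res: a coarse grid on log λ from −12 to 8 (half-unit
steps) brackets the optimum, `optimize()` refines it to 1e-8, and λ = 0
is always evaluated explicitly so boundary solutions are exact rather
than approached. REML is used for reported components, ML for
likelihood-ratio tests — standard practice where the source of a
published ICC is unstated. Because the null `σ²_ind = 0` sits on the
parameter boundary, the LRT p-value uses the 50:50 mixture of χ²₀ and
χ²₁; the naive χ²₁ p is reported alongside since conventions differ.
Confidence intervals are parametric-bootstrap percentiles
(simulate-from-fit, refit by REML); with cohorts of a dozen individuals a
case bootstrap would frequently lose whole individuals, which the
parametric scheme avoids. The suite verifies the fitter against the
balanced one-way ANOVA closed form and against `lme4` on unbalanced data
with covariates, checks near-unbiasedness of the ICC (|bias| < 0.05 at 50
individuals × 10 trials), interval coverage (200 runs × 100 replicates at
30 × 8, true ICC 0.4), and the mixture test's type-I error (1000 null
data sets at nominal 5%).

## Composite axes

Individual mean scores enter a Spearman correlation matrix
(pairwise-complete, so an individual missing one assay still contributes
elsewhere). The collinearity gate places an edge wherever |ρ| > 0.7 and
takes *connected components*: a cluster may legitimately contain a
sub-threshold pair bridged by a shared strong correlate, which is exactly
the structure the packaged study tables show. Components of size ≥ 2 are
summarized by PCA on the (Pearson, by default) correlation matrix of
z-scores, retaining components by the Kaiser rule; scree data are
reported but do not decide retention. Eigenvector sign is arbitrary, so
each named axis carries a fixed orientation rule (reactive: neophobia
loads positive; learning impediment: trials-to-learn positive;
exploratory adaptiveness: accuracy positive). Adequacy is reported as KMO
(from anti-image partial correlations) and Bartlett's sphericity test.
With n ≈ 12 the correlation matrix can be near-singular; no ridge is
applied by default, but a 1e-6 ridge is available, and the adequacy step
falls back to it automatically for degenerate (perfectly collinear)
inputs.

## Associations

Headline tests are identity-link Gaussian GLMs with complete-case n
reported per test. Covariates (sex, age class, body mass) default *off*:
re-deriving the packaged study's printed slopes shows they are
covariate-free simple regressions, and the covariate list is an explicit
argument where wanted. Raw p-values are never altered;
Benjamini-Hochberg adjustment is an optional extra column. The Wilcoxon
signed-rank statistic is reported as W = min(W⁺, W⁻) over mid-ranks —
the convention that matches the packaged tables — with an exact
convolution null for n ≤ 25 without ties and a tie-corrected normal
approximation otherwise. DRS enters hormone models on its raw 1-151
scale. The two-sample t defaults to pooled variance with a Welch option;
neither variant reproduces the packaged study's printed left- vs
right-handed comparison, so that statistic is provided as an operation
but not treated as a reproduction target.

## Field module

Identification power uses the theoretical PID and PID(sib) formulas under
Hardy-Weinberg and locus independence, with expected heterozygosity as
Nei's 1 − Σp² (the unbiased 2n/(2n−1) variant is a switch, since the
estimator behind published tables of this kind is rarely stated). Panels
are selected by descending PIC, taking the smallest prefix with
cumulative PID(sib) below 0.01. Consensus genotyping follows multi-tube
practice: a heterozygote allele needs two replicate observations, a
homozygote three with no competing allele. Sample matching clusters
identical panel genotypes (missing loci ignored, configurable mismatch
tolerance) via graph components; non-clique chains are merged with a
warning because they need human review.

Surface distance to disturbance samples the elevation profile along the
straight planimetric segment. The segment is split into
`ceiling(L/step)` *equal* subdivisions (nominal step 30 m, the native
resolution of the global DEM products this workflow targets): equal
subdivision keeps the actual step at or below the nominal one, samples
both endpoints, and — unlike a fixed step with a trailing partial
segment — makes the distance exactly symmetric in its endpoints, which
the test suite asserts to 1e-9. Elevation is bilinear between cell
centres (nearest-neighbour optional), nodata under a path is an error
naming the chainage, and geographic coordinates are rejected (reproject
first; no geodesic corrections are attempted). The nearest-disturbance
search visits candidates in increasing planimetric order and stops once
the planimetric distance exceeds the best surface distance found — a
sound bound because a profile can never be shorter than its planimetric
projection — with lexicographic (x, y) tie-breaking; tests confirm
pruning never changes the minimum. The packaged wild table carries its
published SSD values as inputs: the study's own profile step and
interpolation rule are unknown, so those distances are not recomputation
targets.

## The synthetic generator

`sim_captive_study()` emulates the captive design at its published scale:
12 individuals, five baseline hormone samples each, a familiarization
trial plus four sequentially blocked problem-solving phases (trials end
at three successes or three straight failures, capped at 10), a 12-20
trial fixed-reward phase with 15 depletion trials, and two 150-trial
string-pulling phases. Two standard-normal latent traits drive the
structure: a coping-style trait `c` (baseline fGCM = 330 + 80·c ng/g,
truncated positive by resampling, spanning roughly the published 165-490
ng/g range; higher neophobia, lower persistence, poorer inhibition,
longer dwelling at the depleted location, less efficient search, a
left-forelimb logit shift of 1.2) and a learning trait `l` (steeper
exploration-duration decline, faster spatial-rule acquisition, quicker
disengagement). Gaussian trial metrics are specified by residual SD,
target ICC and latent loading, with the loading's share of the
among-individual variance checked for feasibility (an impossible
combination is an error stating the implied negative variance). Discrete
metrics arise mechanistically from per-individual search policies, so
their ICCs are emergent rather than dialled. A `couple = FALSE` switch
zeroes every loading for null-structure testing.

What the generator does *not* emulate: temporal drift across the study
months, observer scoring error, sex/age structure in the latent traits,
non-Gaussian metric distributions beyond clipping, or hormonal dynamics
(each individual has one latent hormone level). Passing recovery tests
therefore demonstrates that the pipeline correctly extracts structure of
the assumed form at the study's n, not that real pandas satisfy these
assumptions.

`sim_field_study()` generates Dirichlet allele frequencies (8 loci × 6
alleles), Hardy-Weinberg genotypes shared across each individual's
samples (9 individuals behind 18 samples, one sampled seven times), a
smoothed-Gaussian terrain, and a linear disturbance feature. The
synthetic terrain uses 250 m cells over a 30 km extent — coarser than a
native 30 m DEM — so that surface distances span the home-range
kilometres over which the per-km hormone slopes (+5 between individuals,
−4 within, the opposing-sign structure of interest) are identifiable at
n = 9. Hormone values are built on the *realized* surface distances, so
slope recovery tests the estimation chain, not a geometric
approximation.

## Problem sizes and determinism

All simulations are seeded and reproducible; bundles regenerate
bit-identically from (parameters, seed). The acceptance checks run 200
pipeline seeds at n = 12 for edge-sign recovery, 200 simulations each for
ICC bias and interval coverage, and 1000 for the LRT null — sizes chosen
so each property estimate has a standard error well inside its asserted
band. `scripts/acceptance.R` uses 100 pipeline seeds and 500 LRT
replicates under its command-line seed for the same summaries.

## Known limitations

The fitter covers a single random intercept only (no random slopes, no
link-scale ICCs for binary or count metrics). The published confidence
intervals and PCA loadings of the packaged study depend on unpublished
trial-level data and are represented here only through their orientation
conventions and property-based substitutes. Genotype matching assumes
error-free consensus calls at the matching stage; allelic dropout is
modelled only upstream, in the consensus rules. The terrain module is a
profile sampler, not a least-cost-path engine, by design: it mirrors the
profile-tool workflow its outputs are meant to match.
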