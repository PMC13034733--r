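# behavsyn

Behavioural syndromes, coping styles and stress physiology for wildlife
cohorts, in R.

`behavsyn` is aimed at behavioural ecologists and conservation
physiologists who score individual animals across repeated trials of
several paradigms and want a defensible route from raw scored events to a
trait network: which metrics are repeatable enough to be treated as
individual attributes, how correlated metrics collapse into composite
coping-style axes, and how those axes relate to a physiological stress
proxy (faecal glucocorticoid metabolite concentrations, fGCM, ng/g). A
field companion handles non-invasive genetics (who left which faecal
sample?) and terrain-aware distances to human disturbance, so the same
hormone questions can be asked of wild individuals.

The package ships a worked dataset of 12 captive and 9 wild giant pandas
(*Ailuropoda melanoleuca*) and a synthetic-study generator that emulates
the full design, so every stage is testable end to end without any
external data.

## The statistics at the core

* **Repeatability gate.** Each trial-level metric `y_ij` (individual `i`,
  trial `j`) is fit with a Gaussian random-intercept model
  `y_ij = x_ij'β + b_i + e_ij`, `b_i ~ N(0, σ²_ind)`, `e_ij ~ N(0, σ²_res)`,
  by profiled ML/REML over the variance ratio. Repeatability is the
  intraclass correlation `ICC = σ²_ind / (σ²_ind + σ²_res)`; significance
  comes from a likelihood-ratio test against the fixed-only model with the
  boundary-corrected 50:50 `χ²₀:χ²₁` mixture null, and uncertainty from a
  parametric bootstrap. Only significantly repeatable metrics are averaged
  into individual scores.
* **Collinearity-gated composite axes.** Pairwise Spearman correlations
  among individual scores; variables joined by any `|ρ| > 0.7` edge form
  connected components. Components of two or more variables are summarized
  by correlation-matrix PCA (Kaiser retention, KMO and Bartlett adequacy,
  fixed sign orientation: the *reactive* axis points toward high
  neophobia, *learning impediment* toward more trials-to-learn,
  *exploratory adaptiveness* toward high search accuracy); singletons are
  analysed as they are.
* **Association scan.** Identity-link Gaussian GLMs (`lm`) between axes,
  learning rate, string-pulling trials-to-criterion (DRS) and baseline
  fGCM, plus Wilcoxon signed-rank (`W = min(W⁺, W⁻)`, exact small-sample
  null) and two-sample t tests; results assemble into a signed
  significance network.
* **Field component.** Per-locus `Ho`, `He`, PIC, and probability of
  identity `PID = 2(Σp²)² − Σp⁴` with its sibling variant; PIC-ranked
  panel selection to `PID(sib) < 0.01`; multi-tube consensus genotyping
  and multilocus sample matching. Disturbance exposure is the shortest
  *surface* distance (SSD): elevation profiles are sampled over a DEM by
  bilinear interpolation and summed as `Σ√(Δd² + Δz²)`, with planimetric
  lower-bound pruning over candidate disturbance points. fGCM is then
  regressed on SSD within individuals (≥3 samples) and between individual
  means.

## Worked example

```r
library(behavsyn)

# reanalyse the packaged panda study tables
reproduce_study()
#> Captive association scan (packaged tables):
#>                   response     predictor      beta         p  n
#> 1      learning_impediment learning_rate -1.216374 4.117e-03 11
#> 2                 reactive     fgcm_ng_g  0.010414 5.890e-03 11
#> 3 exploratory_adaptiveness      reactive -0.702365 2.377e-03 11
#> 4 exploratory_adaptiveness     fgcm_ng_g -0.010429 3.002e-05 12
#> 5                drs_cross     fgcm_ng_g  0.205222 7.320e-02 12
#> 6            learning_rate     fgcm_ng_g  0.001814 5.391e-01 11
#>
#> String-pulling phases, signed-rank: W = 23  p = 0.224
#>
#> Wild fGCM ~ surface distance:
#>   within-individual: A: beta = -3.915 (n = 7)
#>   between-individual: beta = 5.035  (n = 9 )
#>
#> Collinearity-gate partitions:
#>   mab: {exploratory_diversity} {neophobia, persistence, inhibitory}
#>   rdt_learning: {pick_count, trials_to_learn, dft} {wme}
#>   rdt_personality: {llvr} {llsd, accuracy} {tlv}
```

Reading this: individuals that learn faster in the problem-solving box
have lower spatial-learning impediment (β = −1.22); higher baseline fGCM
predicts a more reactive coping style (+0.010 per ng/g) and lower
exploratory adaptiveness (−0.010); the cross-configuration string-pulling
score rises with fGCM (0.205 trials per ng/g). In the wild cohort the two
levels disagree in sign — within the repeatedly-sampled individual, fGCM
drops 3.9 ng/g per km farther from disturbance, while across individuals
mean fGCM *rises* 5.0 ng/g per km — the intra/inter contrast the field
design is built to expose.

The same machinery runs on synthetic data with known truth:

```r
bundle <- sim_captive_study(seed = 1)   # 12 individuals, all paradigms
run <- run_captive(bundle)              # metrics -> gate -> axes -> scan
run$associations
autoplot(run$network)

field <- run_field(sim_field_study(seed = 1))
field$panel$pid_sib                     # e.g. 0.0075 over 8 loci
```

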