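Package: behavsyn
Title: Behavioural Syndromes, Coping Styles and Stress Physiology in
    Wildlife
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for quantifying behavioural syndromes
    in captive and wild wildlife cohorts. Scores trial-level behavioural
    event tables from problem-solving, spatial-learning and string-pulling
    paradigms; estimates behavioural repeatability with random-intercept
    mixed models (intraclass correlations, boundary-corrected likelihood
    ratio tests, parametric bootstrap intervals); builds collinearity-gated
    principal-component coping-style axes with KMO/Bartlett adequacy
    checks; and relates composite scores to faecal glucocorticoid
    metabolite (fGCM) concentrations through association scans and network
    summaries. A field companion covers microsatellite individual
    identification (heterozygosity, polymorphic information content,
    probability-of-identity panel selection, multi-tube consensus
    genotyping), terrain-profile shortest surface distance to disturbance
    over a digital elevation model, and intra- versus inter-individual
    hormone-disturbance regressions. A synthetic study generator with a
    latent coping-style trait makes every stage testable without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    lme4,
    patchwork,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
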