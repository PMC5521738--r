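# hmfnet

Identification and analysis of multi-organ gene regulatory networks from
short qPCR expression time courses, for systems biologists studying how
regulatory interactions across organs reorganize between a disease and a
control phenotype.

Expression of gene *g* in organ *r* is modelled by a continuous-time
linear system over all (organ, gene) nodes,

    dE/dt = K E(t)

where the interaction matrix **K** — the Jacobian of the system — carries
the strength, direction and sign of every (possibly indirect) regulatory
influence, with first-order degradation absorbed into the diagonal.
Because the data are short (five sampled ages) and noisy, **K** is not
estimated by differentiating the data.  Instead the package uses the
**Hartley modulating function (HMF) method**: the ODE is multiplied by
basis functions built from the Hartley kernel cas(x) = sin x + cos x that
vanish at both ends of the record, integration by parts eliminates the
derivative, and both sides become frequency-domain inner products
(Hartley spectra, computed in closed form for the piecewise-linear
interpolant of each profile).  Stacking spectra over modulation indices
m = 0, ±1, …, ±M yields a block-diagonal linear regression

    Hbar¹(m ω₀) = Σⱼ Hbar_j(m ω₀) k_ij,     ω₀ = 2π/T

solved per target node by elastic net,

    min_β ‖y − Xβ‖² + λ(α‖β‖₁ + (1−α)‖β‖₂²),

over a grid of m-sets, α and a four-decade λ path.  Candidate models are
ranked by simulating each identified ODE and scoring
J_sim = Σ (ŷ − ȳ)² / (Var(ŷ) + 1e−10), whose variance penalty
disqualifies trivially flat fits.  Downstream analyses cover
median-pseudo-reference (−ΔΔCt) normalization, spline-F permutation
tests for strain-differential dynamics, peak/valley cascade ordering,
added/removed/switched differential-edge calls, signed feed-forward-loop
(adaptation) motifs, graph-topology metrics, and robustness comparison
of near-optimal fits.  A synthetic-data module generates the whole
two-strain study (ground-truth networks, trajectories, replicate Ct
tables with missingness), so every stage is testable without external
data.

## Worked example

Generate a 12-node two-organ study, normalize it, and identify the
network:

```r
library(hmfnet)

model    <- generate_network(n_organs = 3, n_genes = 4, density = 0.15, seed = 1)
truth    <- simulate_truth(model)                    # dE/dt = K_true E at ages 4-16 wk
ct       <- generate_ct_dataset(truth, "disease", replicates = 3,
                                noise_sd = 0.05, seed = 2)
profiles <- scale_profiles(mean_profiles(normalize_ct(ct)))

# regularization contract: at lambda_max the identified network is empty
sys  <- build_regression_system(profiles, "disease", build_m_sets(12, 1)[[1]])
lmax <- lambda_max(sys, alpha = 0.2)
sum(elastic_net_solve(sys, lmax, alpha = 0.2) != 0)
#> [1] 0

fit <- grid_search_identify(profiles, "disease",
                            alpha_grid = c(0.2, 1), n_lambda = 5, n_m_sets = 3)
c(M = fit$best$M, alpha = fit$best$alpha,
  lambda = signif(fit$best$lambda, 3), j_sim = signif(fit$best$j_sim, 3))
#>       M   alpha  lambda   j_sim
#> 9.00000 1.00000 0.00592 0.27700
```

The selected fit (m-set half-width M = 9, lasso, small λ) reproduces the
scaled profiles with J_sim ≈ 0.28, while the all-zero model — flat
simulation, near-zero variance — scores ≈ 2.6 × 10¹¹: the variance
penalty separates real dynamics from the trivial fit by eleven orders of
magnitude.  The strongest identified connections are reported in
`k_<target>_<source>` form:

```r
tab <- coefficient_table(fit$best$K)
head(tab[order(-abs(tab$k)), ], 3)
#>                             name         target         source          k
#>  k_organ01.gene02_organ01.gene04 organ01.gene02 organ01.gene04 -1.7476111
#>  k_organ03.gene02_organ01.gene04 organ03.gene02 organ01.gene04 -0.9130270
#>  k_organ01.gene02_organ02.gene02 organ01.gene02 organ02.gene02  0.7156827
```

i.e. the model calls down-regulation of organ01.gene02 by
organ01.gene04, and so on.  With five sampled ages these coefficients
are stable interaction calls rather than recovered kinetic constants —
the design matrix of each node has effective rank five — so the
analysis validates them by robustness: across near-optimal fits of the
compact study in `analysis/`, filtered coefficients correlate at
Spearman ρ ≥ 0.8 with every sign-table odds ratio infinite (see
`analysis/05_robustness.R` output and the methods vignette).

## The analysis workflow

The numbered drivers under `analysis/` re-run the whole study and write
their tables to `results/`:

| script | stage |
| --- | --- |
| `01_simulate.R` | ground-truth networks (disease = partially rewired control) and replicate Ct tables |
| `02_preprocess.R` | −ΔΔCt normalization, pseudo-reference stability ranks, imputation, scaled profiles |
| `03_dynamics.R` | spline-F permutation tests per (organ, gene), BH-adjusted |
| `04_identify.R` | grid-search HMF identification for both strains |
| `05_robustness.R` | near-optimal fit comparisons, graph-topology metrics |
| `06_patterns_diffnet_motifs.R` | extremum cascades, differential edges, feed-forward loops |

Run them in order from the repository root:
`for s in analysis/0*.R; do Rscript $s; done`

## Package layout

* `R/` — synthetic data, preprocessing, dynamics testing, HMF spectra,
  identification, comparison/topology, patterns, differential network,
  motifs, pipeline orchestration (`run_pipeline()` / `default_config()`)
* `tests/testthat/` — unit, property and end-to-end suites with
  independent brute-force oracles
* `vignettes/hmf-network-identification.Rmd` — the methods vignette:
  model, estimator, numerical conventions, design decisions, and what
  five time points can and cannot identify
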