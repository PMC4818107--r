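# pathbias

Many HER2-amplified (ERBB2+) cancer cell lines are assumed to grow through
PI3K/AKT signalling, yet a substantial fraction depend instead on MAPK/ERK —
and some switch dependence when exposed to the ERBB3 ligand heregulin (HRG).
`pathbias` is an R package for quantifying that dependence from AKT x MEK
inhibitor dose-combination growth experiments, and for finding biomarkers
that predict it. It is aimed at computational biologists analysing
drug-combination response surfaces and pharmacogenomic screens.

## The model

Growth of a treated culture over the 96 h assay is summarised as net
population doublings (PD). With inhibitor concentrations *A* (AKT inhibitor,
uM) and *M* (MEK inhibitor, uM) as surrogates for pathway activity,

    PD(A, M) = mu_max * f1(A, M) - delta_max * f2(A, M)

where `f1` (proliferation) and `f2` (death) are logic gates: the null gate
`K = 1`, an OR gate

    OR(A, M) = s^k / (tau + s^k),   s = w_akt * A + w_erk * M

or an AND gate (product of two single-input Hill terms). All ten variants of
this family (M1–M9 = every (f1, f2) pair over {K, OR, AND}; M10 = separate
single-input Hill terms for proliferation and death) are fitted to each 5 x 6
response surface by particle swarm optimisation and compared by

    AIC = 2 * P + N * log10(MSE),   N = 30 measurements.

The selected OR-gate survival model (M4) yields the **Pathway Bias**

    Bias = (w_akt - w_erk) / (w_akt + w_erk)  in [-1, +1],

+1 meaning purely PI3K/AKT-dependent growth, -1 purely MAPK/ERK-dependent.
Each cell line is fitted with and without heregulin; restart-dispersion 95%
CIs (mean ± 2 SD over independently seeded fits) classify it as PI3K, MAPK,
SWITCH, or UNDETERMINED. Downstream, a logistic model predicts discretized
bias from protein biomarkers (evaluated by leave-one-out cross-validation
against permutation nulls), and biomarker-stratified rank-sum screens with
hypergeometric gene-set enrichment test whether the biomarkers generalise to
external sensitivity data.

## Worked example

```r
library(pathbias)

# fit a surface simulated from a known OR-gate model
m4    <- model_spec("M4")
truth <- m4_params(mu_max = 4, delta_max = 6, w_akt = 5, w_erk = 0.5,
                   k = 1.5, tau = 1)
surf  <- simulate_surface(m4, truth, noise_sd = 0, seed = 1)$surface
fit   <- fit_pso(m4, surf, fit_config(n_restarts = 5, seed = 7))
c(bias = fit$bias, truth = pathway_bias(5, 0.5), mse = fit$mse)
#>         bias        truth          mse
#> 8.181818e-01 8.181818e-01 3.376992e-14
```

The fitted bias 0.818 means growth inhibition is dominated by the AKT
inhibitor axis: a PI3K-dependent line. On the full synthetic panel the
pipeline recovers the generating class structure from the dose-response data
alone:

```r
bundle <- run_pipeline(run_config(seed = 1, fit = fit_config(n_restarts = 5)))
table(sapply(bundle$calls, function(d) d$call))
#> MAPK PI3K SWITCH
#>    9    5      4
bundle$classifier[["3BM"]]$accuracy        # EGFR+ERBB3+CDKN1B classifier
#> [1] 0.8333333
bundle$classifier[["3BM"]]$p_values[["accuracy"]]
#> [1] 0.004975124
```

36 samples (18 lines ± heregulin), of which the three-protein biomarker set
predicts 30 correctly; the permutation p-value says no label-shuffled model
did as well. Enrichment of a canonical five-gene set among screen hits uses
the exact hypergeometric upper tail:

```r
hypergeometric_tail(N = 5711, n = 781, K = 5, r = 4)
#> [1] 0.001547953
```

i.e. finding 4 of 5 canonical PI3K/MAPK nodes among 781 hits out of 5711
tested genes would occur by chance with probability 1.5e-3.

A command-line interface wrapping the same stages
(`simulate | fit | classify | screen | enrich | run`) ships as
`inst/cli/pathbias.R`.

## Further reading

`vignettes/pathway-bias-methods.Rmd` documents the model assumptions,
parameter search space, synthetic-data design and its limitations, and the
numerical conventions (CI clipping, median-tie handling, permutation
p-value estimator).
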