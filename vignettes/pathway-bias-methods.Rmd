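---
title: "Pathway Bias from dose-combination growth surfaces: models, fitting and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway Bias methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathbias)
```

## The problem

HER2-amplified cancer cells route growth signalling through two partially
redundant cascades, PI3K/AKT and MAPK/ERK. Which cascade a given line
actually depends on determines whether an AKT inhibitor or a MEK inhibitor
will stop its growth, and the dependence can be remodelled by
microenvironmental ligands such as heregulin. `pathbias` turns a 5 x 6
matrix of growth measurements under combined AKT/MEK inhibition into a
single interpretable statistic of that dependence, and provides the
statistical machinery to find and validate biomarkers that predict it.

## The growth model and its assumptions

Net growth is modelled as a balance of proliferation and death, each
regulated by pathway activity:

$$\mathrm{PD}(A, M) = \mu_{max}\, f_1(A, M) - \delta_{max}\, f_2(A, M)$$

with PD the population doublings over the 96 h assay and $A$, $M$ the AKT
and MEK inhibitor concentrations in $\mu$M.

Three modelling assumptions matter:

1. **Inhibitor concentration as a pathway-activity surrogate.** No
   mechanistic signalling states are simulated; the model assumes a
   monotone dose–response between inhibitor and pathway activity. This is
   also why no cross-talk or synergy term exists — a line whose response to
   the drug *combination* is strongly super-additive (observed once in the
   emulated panel, for SKOV3) is flagged UNDETERMINED rather than forced
   into a class.
2. **Algebraic observable.** The growth law is a rate equation, but at
   constant inhibitor concentration its exponential solution makes PD over
   a fixed assay window *linear* in the net rate. The assay duration is
   therefore absorbed into $\mu_{max}$ and $\delta_{max}$ (units:
   doublings / 96 h) and no ODE integration is performed.
3. **Verbatim Hill form.** Gates use the denominator $\tau + s^k$, not
   $\tau^k + s^k$; $\tau$ consequently carries units of $(\mu M \cdot
   w)^k$ and absorbs the concentration scale. This matches the printed
   model family rather than the more common EC50 parameterisation, and it
   is why $\tau$ is searched in log space over six decades.

The gate family is closed over $\{K, OR, AND\}$ for $(f_1, f_2)$, giving
models M1–M9 with 2–10 free parameters; the text identifies only two
variants structurally (the OR-gate survival model and the split
proliferation/death variant), so M4 = (K, OR) and M10 are pinned and the
remaining ids simply enumerate the grid (f1 fastest). The catalog exists
for the AIC comparison harness; inference always reads bias off an OR
gate's weights:

$$\mathrm{Bias} = \frac{w_{akt} - w_{erk}}{w_{akt} + w_{erk}} \in [-1, 1].$$

## Parameters, defaults and why

| parameter | default / range | rationale |
|---|---|---|
| AKT dose axis | 0, 1/27, 1/9, 1/3, 1 uM | 3-fold series from 1 uM with untreated control, 5 points |
| MEK dose axis | 0, 10/81 … 10 uM | 3-fold series from 10 uM with control, 6 points; 30 measurements total |
| $\mu_{max}$ bounds | [0, 8] PD | observed surfaces span roughly 0–5 doublings/96 h, with margin |
| $\delta_{max}$ bounds | [0, 12] PD | death can exceed proliferation at saturating dose |
| weights $w$ | $[10^{-2}, 10^2]$, log-searched | scale parameter; only the ratio is identified (bias is scale-invariant) |
| $\tau$ | $[10^{-3}, 10^3]$, log-searched | absorbs dose scale under the verbatim Hill form |
| $k$ | [0.3, 4], linear | Hill coefficients outside this range are biologically implausible |
| PSO | swarm 40, 300 iter, inertia 0.729, c1 = c2 = 1.494 | standard constriction coefficients; the estimation method is stated but not its settings |
| restarts | 100 (tests use 20) | point estimate = best-MSE restart; 95% CI = mean ± 2 SD over restarts |
| ridge $\lambda$ | $10^{-4}$ on slopes | 36 samples with informative features separate; a negligible penalty keeps MLE character while guaranteeing finite coefficients |
| permutations $B$ | 10000 (tests use 1000) | add-one p-value $(1+r)/(1+B)$ avoids zero p-values |
| screen thresholds | $\alpha$ = 0.05 or 0.1, raw | the emulated screens use raw p-value cuts with no FDR correction, by design |

Whether the fitting objective compares PD or fold expansion ($2^{PD}$) is
exposed as `objective_scale` because the source is ambiguous (the fitting
text says fold expansion, the figures are in PD); the default is `"pd"`,
which weights high-kill corners of the surface more evenly — on the fold
scale a difference of one doubling near zero growth contributes far less
than the same difference in an untreated corner.

## Numerical conventions

* **AIC floor.** MSE is floored at $10^{-6}$ before $\log_{10}$, so perfect
  fits to noiseless synthetic surfaces cannot produce $-\infty$.
* **CI clipping.** Bias is bounded, so reported CIs are clipped to
  $[-1, 1]$; the zero-crossing (UNDETERMINED) test uses the unclipped
  bounds. Clipping cannot change zero containment, so the calls are
  unaffected.
* **Model-selection ties** break toward fewer parameters, then
  lexicographic id.
* **Median stratification** drops samples exactly at the median from both
  groups — on small panels this yields unambiguous strata at the cost of a
  few samples. Percentile membership uses linear interpolation between
  order statistics with a strict `>`.
* **Rank-sum flavour.** Exact two-sided p when the combined sample is small
  and tie-free; normal approximation with tie and continuity correction
  otherwise. Hits require `p < alpha` strictly; `alpha >= 1` disables the
  threshold (exact tests can return p = 1, which a strict cut would
  otherwise exclude from an "everything" screen).
* **Accuracy ties.** A predicted bias of exactly 0 (indifferent model) and
  skipped degenerate folds count as errors, in the denominator.
* **Permutation scheme.** The (bias, class) pair is shuffled against fixed
  feature rows; the ±HRG rows of one line permute independently, consistent
  with treating them as independent samples throughout.

## What the synthetic world emulates — and what it does not

`simulate_panel()` generates the default stated world: 18 lines split
5 PI3K : 9 MAPK : 4 SWITCH (largest-remainder apportionment, so the default
counts are exact), each measured ± heregulin for 36 samples, surfaces from
M4 with observation noise SD 0.25 PD, and log-normal protein signals
(base-10 location 3.0, scale 0.3 — arbitrary but Luminex-like: positive and
right-skewed). Class-conditional shifts are +1 log10 for EGFR in
MAPK-dependent lines and +0.7 / +0.5 log10 for ERBB3 / CDKN1B in
PI3K-dependent lines; pAKT, pERK and total proteins are class-independent;
PI3K-pathway mutations occur at 0.8 vs 0.3; breast tissue coincides with
the PI3K and SWITCH classes; MAPK lines proliferate faster
($\mu_{max} \sim U[3,5]$ vs $U[1.5, 3.5]$).

Two design choices deserve emphasis:

* **The SWITCH mechanism is a weight swap.** No mechanism for
  heregulin-induced dependence switching is described in the source, so the
  generator swaps $w_{akt} \leftrightarrow w_{erk}$ between the two
  conditions — the minimal construction that reproduces the phenotype.
* **Biomarkers follow the intrinsic (unstimulated) class.** SWITCH lines
  carry PI3K-like biomarker profiles in both conditions, so their
  stimulated samples are *structurally* mispredictable — the classifier's
  accuracy ceiling on a default panel is 32/36 ≈ 0.89. This mirrors the
  empirical finding that the measured proteins explain intrinsic dependence
  but not the ligand-induced switch. Across generator seeds the
  three-biomarker LOOCV accuracy has median ≈ 0.82.

A green test on this world establishes that the estimator and classifier
recover a known generating structure at realistic noise. It does **not**
establish anything about real Luminex signal magnitudes, real correlation
between replicate antibodies, plate effects, or dose–response shapes
outside the Hill family; the generator draws features independently across
samples given class, which is more favourable than correlated real data.

## Identifiability and known limitations

* With $\delta_{max}$ near zero (or $\tau$ so small that the gate saturates
  across the whole grid) the surface carries little information about the
  weight *ratio*, and the fitted bias is poorly determined. This is the
  dominant failure mode in the parameter-recovery acceptance test and is
  exactly what the restart-dispersion CI is for: such fits produce wide
  CIs and UNDETERMINED calls rather than confident noise.
* The restart CI measures optimizer dispersion, not sampling uncertainty:
  no data resampling is performed (none is described for the emulated
  analysis), so a CI of width zero means a reproducible optimum, not a
  certain parameter.
* PSO is stochastic; identical results require identical seeds. All
  package functions derive their randomness from explicit seed arguments.
* Raw-scale (not log) protein features enter the logistic model by default,
  for fidelity to the normalised-coefficient convention
  ($\beta_i \times$ median signal); with log-normal signals this costs a
  little accuracy relative to a log transform, which is available via the
  panel columns themselves.

## Reduced scales in the shipped tests

The full protocol (100 restarts, $B = 10^4$ permutations) is what the
defaults encode; the test suite and acceptance script run the same code at
20 restarts / $B = 10^3$ (and 2–5 restarts in pure plumbing tests) to stay
inside desk runtime budgets. The reduction is in sampling effort only —
thresholds and generator parameters are untouched.
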