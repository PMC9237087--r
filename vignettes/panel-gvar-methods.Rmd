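---
title: "Panel GVAR models for sessional symptom data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Panel GVAR models for sessional symptom data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelnet)
```

## The model

`panelnet` analyses panels in which many subjects answer the same m
ordinal symptom items (by default the 9 depression and 7 anxiety items of
the PHQ-9 and GAD-7, scored 0–3) at a small number of fixed sessions
(waves), as collected routinely in psychological therapy services. The
core model is a lag-1 panel graphical vector autoregression (panel GVAR):
writing $y_{it}$ for subject $i$'s item vector at wave $t$,

$$y_{it} = \mu + b_i + w_{it}, \qquad
  w_{it} = B\,w_{i,t-1} + \zeta_{it},$$

with

* $\mu$ — item means, held constant across waves (the data are detrended
  first, so wave effects are removed before modelling);
* $b_i \sim N(0, \Sigma_B)$ — stable between-person differences;
* $B$ — the temporal matrix; entry $[j, i]$ is the lag-1 effect of item
  $i$ on item $j$, controlling for all other items (the directed
  *temporal network*; the diagonal holds autoregressions);
* $\zeta_{it} \sim N(0, \Sigma_\zeta)$ — same-wave innovations (the
  *contemporaneous network* after standardising the precision matrix to
  partial correlations).

Both covariance blocks are Gaussian graphical models,
$\Sigma = \Delta (I - \Omega)^{-1} \Delta$, with $\Omega$ a symmetric
partial-correlation matrix and $\Delta$ positive scalings, so zeros in
$\Omega$ are conditional independences. The first wave is not treated as
exogenous: $w_{i1}$ is drawn from the stationary covariance $S_w$ implied
by the temporal structure, the solution of the discrete Lyapunov equation
$S_w = B S_w B^\top + \Sigma_\zeta$ (requiring the spectral radius of $B$
below 1). The model-implied covariance between waves $t \ge s$ is then
$\Sigma_B + B^{t-s} S_w$ — a random-intercept cross-lagged panel
structure. The saturated model has exactly $2m^2 + 2m$ free parameters
($m$ means, $m^2$ temporal effects, and $m(m+1)/2$ per GGM block); with
$K = Wm$ observed variables carrying $K(K+3)/2$ moments, the degrees of
freedom follow. At $m = 16$, $W = 6$ this gives 544 parameters against
4752 moments (df 4208), which `count_free_parameters()` reproduces.

## Estimation

Missing item blocks (monotone dropout is the dominant pattern in therapy
data) are handled by full-information maximum likelihood: each subject
contributes the multivariate-normal density of exactly their observed
wave-item values under the matching sub-matrix of the implied moments.
Internally subjects are grouped by missingness pattern and summarised by
per-pattern means and scatter matrices; the result is contractually
identical to per-subject evaluation (tested to 1e-10), and FIML is valid
when data are missing at random.

Numerical choices worth recording:

* **Positive definiteness.** During optimisation each fully-free GGM
  block is carried as the lower-triangular factor $L$ of its covariance
  ($\Sigma = LL^\top$), an unconstrained parameterisation; estimates are
  re-expressed as $(\Omega, \Delta)$ for reporting. A block with
  structurally-zero partial correlations (a confirmatory adjacency)
  cannot express the zeros in triangular-factor form, so such blocks are
  optimised directly in partial-correlation/log-scaling coordinates with
  a penalty on non-positive-definite $(I - \Omega)$; the fitted optimum
  always lies in the interior.
* **Optimiser.** Quasi-Newton (BFGS) with numerical gradients, relative
  tolerance 1e-12, followed by a restart from the optimum; the converged
  flag also checks the final gradient norm. Starting values are cheap
  consistent estimators: lag-1 least squares on within-person deviations
  for $B$, shrunken subject-mean covariance for the between block, and
  the residual within-wave covariance for the innovations.
* **Stationarity** is checked, not enforced, at the optimum and exposed
  as a flag: a penalty-free likelihood surface avoids distorting
  standard errors near the boundary.
* **Standard errors** come from the inverse observed information,
  obtained by central-difference differentiation of the log-likelihood
  at the optimum in reporting coordinates (step 1e-4 relative; scalings
  on the log scale, back-transformed by the delta method). Edge masks
  use Wald tests at the study convention $\alpha = 10^{-4}$.
* **Saturated model** under missingness: EM for the unstructured
  multivariate normal, iterated to relative log-likelihood change below
  1e-9 (closed-form moments when data are complete). The independence
  baseline factorises per variable and is available in closed form.

Generalizability testing follows the protocol: a confirmatory fit in the
holdout sample with the training significance masks as the adjacency
(the mask family is a design choice — any adjacency is supported), and a
two-group fit with equality constraints, by default sharing all
$2m^2+2m$ parameters (block-level sharing over means, temporal, and the
two GGM blocks is exposed; the printed df of published equality models
cannot be decomposed further from fit tables alone, so "share
everything" is the documented default).

## Fit assessment

`chisquare()` compares the fitted model to the saturated model;
`fit_indices()` adds the incremental battery (NFI, PNFI, TLI, RFI, IFI,
CFI) against the independence baseline, with TLI/RFI deliberately
uncapped (raw arithmetic is reported, as fit tables print it). RMSEA
uses $\sqrt{G\,\max(\chi^2 - df, 0) / (df\,(N - G))}$: the $N - G$
convention and the $\sqrt{G}$ multi-group factor are the pair of
conventions that reproduce published single-group and
equality-constrained values from their printed $\chi^2$, df and N; at
$G = 1$ it is the standard formula. The 95% interval inverts the
noncentral $\chi^2$ distribution in the noncentrality parameter (floored
at zero, so the lower bound is 0 whenever $\chi^2 \le df$).

## Networks and centrality

`extract_networks()` reports the temporal network as raw $B$ entries
(a standardised variant is not the default because the correlation-like
scale of published temporal edges is not pinned down), and the two
partial-correlation networks. Expected Influence sums signed edge
weights excluding the self-loop — In-EI over incoming temporal edges,
Out-EI over outgoing ones — and is z-standardised within each network
across items. Density is the sum of *absolute* edge weights over unique
edges: signed sums can cancel, which would make a dense
mixed-sign network look empty; `signed = TRUE` restores the literal
reading. Network agreement is the Spearman correlation over vectorised
unique edges.

## Per-wave cross-sectional networks

For each wave, an unregularised GGM is selected by stepwise EBIC search:
Spearman correlations (pairwise-complete, average-rank ties; repaired by
nearest-correlation projection when pairwise deletion breaks positive
definiteness), 100 graphical-lasso fits down a log-spaced penalty path
(block coordinate descent, written in-package) to propose candidate
structures, unregularised refits of each candidate (iterative
conditional fitting with structural zeros), and a hill-climb over
single-edge additions/removals until EBIC stops improving. The EBIC
penalty is $-2\ell + k\log n + 4\gamma k\log m$ with $\gamma = 0$ by
default (the ordinary-BIC convention of the stepwise procedure; exposed
as a parameter since published analyses rarely print it). Node
redundancy uses the goldbricker screen: pairs correlated at least 0.5
whose correlation profiles with third items differ significantly (the
dependent-correlation z test with the back-transformed-average Fisher-z
method, $\alpha = 0.01$) in fewer than 25% of comparisons are flagged as
topologically overlapping.

## The synthetic cohort

Because raw clinical panels of this kind are not redistributable, the
package ships a generator whose defaults emulate the study conditions:
16 items over 6 sessions, a dense-but-weak temporal network
(cross-lag density 0.8, mean magnitude 0.03, random signs) with moderate
autocorrelations (mean 0.2), GGM-structured innovations and intercepts
(density 0.5, partial correlations around 0.15), linearly declining
means (−0.1 score units per session, matching gradual symptom
improvement), ordinalisation to 0–3 scores by latent-marginal quartiles
(uniform margins — published item margins are not available to calibrate
against), and monotone dropout after session 3 at hazard 0.15 per
session (mean attended sessions near eight in routine care, and the
≥3-session inclusion rule stays satisfiable by construction). Dropout is
missing at random given wave, so the FIML assumption holds in the
default test bed. Trends enter the means only; variance trends can be
added to exercise the variance-detrending path.

What the generator does *not* emulate: floor effects and skewed item
margins, therapy-type and service heterogeneity, symptom-dependent
dropout, and measurement error. Passing recovery tests on this test bed
therefore demonstrates correctness of the estimator under its own
assumptions, not robustness to clinical data pathologies.

## Validation scale and known limitations

The test suite validates at desk scale, chosen to keep the full run in
minutes: parameter recovery at m = 4, W = 4, n = 2000 (element-wise
correlation of true and estimated temporal matrices ≥ 0.9); χ²
calibration over 200 null replicates at m = 3, W = 3, n = 1000 (mean
within 15% of df = 30), with Wald false-positive rates pooled over the
same replicates; stepwise-EBIC selection checked against exhaustive
enumeration of all 1024 graphs at m = 5 on 50 datasets; and end-to-end
determinism of the pipeline at m = 4. Published edge-level numbers from
clinical samples of ~10^5 patients depend on undeposited data and are
not reproduction targets; the analytic quantities that *are* arithmetic
(parameter counts, df, RMSEA from printed χ²/df/N, its CI) are asserted
exactly.

Limitations: detrending by per-wave standardisation assumes the panel is
wide enough per wave to estimate cell moments; the optimiser's numerical
gradients make the full 16-item, 6-wave fit minutes-slow rather than
seconds-fast; no latent measurement model, time-varying temporal
matrices, more-than-two-group comparisons, or regularised panel
estimation (all deliberately out of scope).
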