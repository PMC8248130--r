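---
title: "Multi-activation survival modelling and equivalent-dose calculation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-activation survival modelling and equivalent-dose calculation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umasurv)
```

## The model

Clonogenic survival curves show a shoulder at low dose and a straight
(exponential) portion at high dose.  The two classical two-parameter
descriptions each fail in one regime: the linear-quadratic (LQ) form
$\ln S = -\alpha D - \beta D^2$ bends ever downward and underestimates
survival beyond the measured range, while the multitarget (MT) asymptote
$S = n e^{-D/D_0}$ overshoots the shoulder ($S > 1$ at low dose).  This
package implements a unified multi-activation (UMA) form that interpolates
both regimes with the same two parameters over the entire dose range:

$$S(D) \;=\; \frac{n}{e^{D/D_0} + n - 1}.$$

At $D = 0$ the denominator equals $n$, so $S = 1$ exactly; at high dose
$S \to n\,e^{-D/D_0}$, the MT straight portion.  $D_0$ (Gy) is the dose
slope of that straight portion; $n$ is the activation (extrapolation)
number, interpretable as the number of radiation-activated cell-death
pathways.  Curves with $0 < n < 1$ have an inverted (negatively curved)
shoulder; $n = 1$ reduces to the pure exponential $S = e^{-D/D_0}$.
Tumours with distinct sub-populations (e.g. a hypoxic fraction) are
handled as weighted mixtures $\sum_k w_k S_k(D)$ with $\sum w_k = 1$.

All evaluation is done in log space,
$\ln S = \ln n - D/D_0 - \mathrm{log1p}\!\big((n-1)e^{-D/D_0}\big)$,
so dose ratios $D/D_0$ up to the double-precision exponent limit
(~700) neither overflow nor lose the $n-1$ correction; this matters
because the derived $\alpha/\beta$ ratios reach $10^{10}$ Gy for
realistic parameters.  Since $e^{D/D_0} + n - 1 \ge n > 0$ for all
$D \ge 0$, no further domain guard is needed even for $n < 1$.

## Derived radiosensitivity quantities

Matching the LQ expansion locally at a working dose $D$ gives
dose-*dependent* coefficients from the derivatives of $\ln S$:

$$\beta(D) = -\tfrac12 \frac{\partial^2 \ln S}{\partial D^2}
 = \frac{(n-1)e^{D/D_0}}{2 D_0^2 \left(e^{D/D_0}+n-1\right)^2},
 \qquad
 \alpha(D) = -\frac{\partial \ln S}{\partial D} + 2\beta D .$$

Their ratio simplifies to
$$\frac{\alpha}{\beta}(D) = \frac{2 D_0\left(e^{D/D_0}+n-1\right)}{n-1} + 2D .$$

A sign-convention note: one sometimes sees this ratio quoted with a
trailing $-2D$; the ratio of the two derivative expressions above gives
$+2D$, and every tabulated value the package reproduces is consistent
with $+2D$, so that is what `uma_alpha_beta_ratio()` implements.  At
$n = 1$ the curvature vanishes: $\beta = 0$, $\alpha = 1/D_0$, and the
ratio is undefined (returned as `NA`, not an error).  For $n < 1$ both
$\beta$ and the ratio are negative.  These are *local* (derivative)
coefficients: $-\alpha(D)D - \beta(D)D^2$ does not reproduce $\ln S(D)$
itself, and the package never uses them for isoeffect arithmetic — they
exist to compare against LQ-derived literature values.

Mixtures have no single well-defined curvature, so the derivative
quantities are exposed for single populations only.

The mean inactivation dose, a one-number radiosensitivity summary, is the
area under the survival curve and has the closed form
$$\mathrm{MID} = \int_0^\infty S(D)\,dD = \frac{n \ln n}{n-1} D_0,$$
with the continuous limit $\mathrm{MID} = D_0$ at $n = 1$.  The unit
tests verify this against adaptive quadrature to $10^{-6}$ relative error
over $D_0 \in [0.5, 7]$ Gy, $n \in [0.2, 60]$.

## Equivalent dose in 2-Gy fractions

Because $\ln S$ contains the dose through a single term, the end survival
of $N$ fractions of $D$ Gy is $S(D)^N$ and the equivalent number of
2-Gy fractions solves $S(2)^{N_2} = S(D)^N$:

$$\mathrm{EQD2} = 2\,N\,
  \frac{\ln n - \ln\!\left(e^{D/D_0}+n-1\right)}
       {\ln n - \ln\!\left(e^{2/D_0}+n-1\right)} .$$

Multi-session schemes sum their per-session equivalents (exact
additivity), and mixed-radiation cases (e.g. alpha-particle treatment of
cells whose reference 2-Gy response was measured with gamma rays) put the
treatment-radiation parameters in the numerator and the
reference-radiation parameters in the denominator
(`params_ref` in `uma_eqd2()`).  Under this model the physical dose
itself plays the role of the biologically effective dose, so no separate
BED is defined; `lq_bed()` exists only on the LQ comparison path, where
$\mathrm{EQD2}_{LQ} = \sum N D\,(1+D/(\alpha/\beta))/(1+2/(\alpha/\beta))$.
For a mixed-cell-population tumour the governing equivalent dose is the
*minimum* per-component EQD2, since the most radioresistant population
dominates the surviving tumour at the end of treatment
(`mixture_eqd2()`).

Three conventions worth making explicit:

* the equivalent fraction number $N_2$ is real-valued and never rounded
  in the library; rounding up to deliverable fractions is offered only by
  the CLI's `--round-up` flag;
* the reference fraction size is configurable (`ref_dose`, default 2 Gy),
  since the algebra is identical for any EQDx;
* negative $\alpha/\beta$ ratios are accepted by `lq_eqd2()` with a
  warning (they arise for inverted-shoulder lines); the only pole is
  $\alpha/\beta = -2$ Gy, where the 2-Gy reference effect vanishes.

## Fitting procedure

`fit_uma()` exploits an exact linearization: if the data follow the model,
$y_i = \ln(n/S_i + 1 - n) = D_i/D_0$ for every point.  The algorithm is:

1. initialize from the two highest-dose points,
   $D_0^{(0)} = -(D_I - D_{I-1})/(\ln S_I - \ln S_{I-1})$ and
   $n^{(0)} = S_{I-1}e^{D_{I-1}/D_0^{(0)}}$;
2. for each candidate $n$ on a deterministic log-spaced grid
   ($n \in [0.05, 200]$, 160 points, plus $n^{(0)}$), solve $D_0$ by a
   through-origin least-squares regression of $y_i$ on $D_i$ — candidates
   making any $n/S_i + 1 - n \le 0$ are infeasible and skipped;
3. select the $n$ minimizing the mean relative residual
   $r = I^{-1}\sum_i |S(D_i) - S_i|/S_i$ subject to $R^2 \ge 0.9$
   (the constraint is dropped with a warning when no candidate meets it);
   golden-section refinement between the neighbouring grid points then
   sharpens the optimum.  Ties in $r$ within $10^{-10}$ break to higher
   $R^2$, then smaller $n$ — everything is deterministic.

$R^2 = 1 - RSS/SSS$ is computed on the linear survival scale, and the
residual index $r$ is compared with the mean relative experimental error
$e = \mathrm{mean}(\Delta S_i/S_i)$ over the points that carry a
replicate SD; a fit is flagged "good" when $R^2 \in [0.9, 1]$ and
$r < e$ (or no SDs exist).  The zero-dose anchor (survival 1, no error
bar) participates in the regression and in $R^2$/$r$, never in $e$.
Point means use the plain replicate average and $\Delta S_i$ the sample
SD ($I'-1$ denominator); the regressions are unweighted, as no weighting
scheme is prescribed for this kind of data.

`fit_lq()` is a zero-intercept OLS of $\ln S$ on $(D, D^2)$, optionally
restricted to a dose range but always scored over all points, so the
high-dose divergence stays visible.  `fit_mt()` regresses $\ln S$ on $D$
over points with $D > 3$ Gy (configurable) and is likewise scored over
all points, exposing its shoulder overshoot.  `fit_uma_mixture()`
minimizes the same $r$ by Nelder–Mead in log-parameter space from three
deterministic starts (a tail/shoulder decomposition plus perturbations of
the single-population fit), with weights fixed equal by default; on exact
two-population data it recovers the generating components to well under
5%.  On the classic irregular-shoulder example — half the cells with
$D_0 = 2.80$ Gy, $n = 1$ and half with $D_0 = 2.70$ Gy, $n = 58$ — the
recovery is numerically exact.

## Fractionation comparison surfaces

`scheme_survival_ratio()` compares two schemes of equal physical dose by
$S(D_a)^{N_a}/S(D_b)^{N_b}$ (log-space evaluation; real exponents
allowed, e.g. $2/1.2$ for twice-daily 1.2-Gy fractions at equal daily
dose).  Values below 1 favour scheme A.  `ratio_grid()` evaluates this
over the $(D_0, n)$ plane; the built-in comparisons are one 10-Gy
fraction vs five 2-Gy fractions, and 1.2-Gy BID vs 2-Gy fractions.  Both
surfaces are identically 1 along $n = 1$ (an exponential curve sees only
total dose).  The hypofractionation surface rises with $D_0$ at fixed
$n > 1$ and has an interior *minimum* across $n$ at fixed $D_0 > 2$ Gy —
the activation number at which a large fraction gains the most control;
the BID surface is below 1 exactly for $n < 1$, increasing in $n$ through
that regime.  Default axis ranges $D_0 \in [0.5, 7]$ Gy,
$n \in [0.2, 20]$ cover the span of the packaged tumour table.

## The packaged tumour table

`tumor_parameter_table()` ships 31 rows of published $(D_0, n)$ values
for human tumour cell lines with a clinically relevant scheme per row and
the reference values of $\alpha$, $\alpha/\beta$ and EQD2 derived from
them, plus the clinical $\alpha/\beta$ convention (3 Gy prostate, 8 Gy
lung and colorectal, 10 Gy otherwise) driving the LQ comparison column.
`recompute_tumor_table()` re-derives every quantity from the closed forms
and flags agreement: $\alpha$ and $\alpha/\beta$ within half a unit in
the second significant figure, EQD2 within 0.1 Gy.  30 of the 31 rows
match; the single mismatch is the merged melanoma entry ("Bell/MelH"),
whose tabulated $\alpha/\beta$ and EQD2 are not self-consistent with its
own tabulated $(D_0, n)$ at those tolerances — it is flagged, not hidden.
Four rows' *LQ* reference values are likewise inconsistent with the
stated clinical ratios (they correspond to $\alpha/\beta = -10$ Gy,
apparently a sign slip in the original tabulation); the package always
recomputes the LQ column from the stated clinical ratio and keeps the
tabulated value only as a reference column.

## Synthetic assay generator

`generate_curve()` emulates a multi-replicate clonogenic assay: replicate
survivals are the model mean times multiplicative lognormal noise
($\sigma$ on the log scale, default 0.1 — a typical relative colony-count
error), clipped to $(0, 1]$, with the zero-dose point emitted as exactly
$(0, 1)$ and no spread.  Defaults (0–12 Gy in 1.5-Gy steps, 3 replicates)
mirror common in-vitro assay designs; recovery studies in the tests use
0–14 Gy in 2-Gy steps (8 dose points).  The generator is seeded and
leaves the caller's RNG stream untouched.  What it does *not* emulate:
Poisson colony-count statistics and plating-efficiency normalization,
dose-rate and repair-kinetics effects, inter-assay batch shifts, or
correlated replicate errors.  Passing recovery tests therefore show that
the estimator inverts its own noise model at realistic noise levels
(median parameter error < 10% at $\sigma = 0.1$ with 3 replicates and 8
dose points), not that every laboratory curve is fit equally well.

## Numerical choices and limitations

* Survival at $D = 0$ is returned as exactly 1 (the log-space expression
  is forced to zero there) so the normalization convention is bitwise.
* The $n$-search grid, refinement bracket and tie-breaks are fixed;
  repeated fits of the same curve are identical.
* `integrate()`-based checks of the MID and the finite-difference checks
  of $\alpha$, $\beta$ use Richardson-extrapolated central differences
  with step $0.01 D_0$; at very large $D/D_0$ the curvature underflows
  faster than any finite-difference oracle can follow, so those checks
  run at $D/D_0 \le 5$.
* The straight-portion approximation $\ln S \approx \ln n - D/D_0$ is
  accurate to $10^{-4}$ once $(n-1)e^{-D/D_0} < 10^{-4}$ — e.g. from
  $D/D_0 \ge 12$ for $n \le 16$, and from $D/D_0 \ge 14$ for $n$ up to
  100.
* No confidence intervals are produced for $(D_0, n)$; the goodness
  indices ($R^2$, $r$ vs $e$) are the intended adequacy summary.
* The model deliberately omits dose-rate, repair-kinetics, repopulation
  and combination-therapy effects, and it says nothing about
  normal-tissue complication; equivalent doses computed here concern
  tumour-cell survival only.

## Problem sizes used in the shipped checks

The test suite's stochastic components are fixed-seed simulations: 200
generated curves for the parameter-recovery study (plus an 80-curve
variant in the end-to-end checks), 8-point dose grids, 3 replicates.
All tabulated-value reproductions are closed-form evaluations and run in
milliseconds.
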