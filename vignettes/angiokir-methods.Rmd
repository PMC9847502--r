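---
title: "Methods: population kinetics, kinome regression, and the synthetic screen"
author: "angiokir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population kinetics, kinome regression, and the synthetic screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angiokir)
```

# The problem

Endothelial cells in a resting vessel sit in G0; a pro-angiogenic growth
factor (FGF2, VEGFA, HGF) both suppresses their low basal apoptosis and
commits a dose-dependent fraction of them to re-enter the cycle, producing a
semi-synchronous wave of division. A time-lapse proliferation assay counts
live nuclei $N(t)$ and cumulative dead cells $M(t)$ per well. Profiled
kinase inhibitors perturb the proliferative response through their
polypharmacology, and the question is which kinases carry the signal from
*any* of the growth factors to the cell cycle. `angiokir` implements the full
analysis chain: rate estimation, kinome regression (KIR), rank-sum
intersection across growth factors, and siRNA-validation statistics, plus a
stochastic screen simulator with known ground truth so every stage can be
verified end to end.

# Population kinetics

The per-capita proliferation rate is defined by $dN/dt = p(t)\,N(t)$ and the
death rate by $dM/dt = D(t)\,N(t)$; the birth rate is $B(t) = p(t) + D(t)$.
With constant $p$ the first equation has the exponential solution
$N(t) = N_0 e^{k_P t}$.

Three estimators are provided:

* **Endpoint estimator** (`estimateRates()`):
  $k_P = \Delta N / (\bar N\,\Delta t)$ and
  $k_D = \Delta M / (\bar N\,\Delta t)$ with
  $\bar N = (N(t_0)+N(t_{end}))/2$, and $k_B = k_P + k_D$ identically.
  On exact exponential data this returns $(2/\Delta t)\tanh(k\Delta t/2)$,
  so its relative bias is bounded by $(k\Delta t)^2/12$ and vanishes as the
  window shrinks. A variant with the endpoint *sum* in the denominator
  (which converges to $k/2$) exists behind `convention = "sum"` purely for
  compatibility with analyses that used the sum form; the endpoint-mean
  reading is the default because it is the one consistent with the
  exponential model. "Average over the experiment" is read as the endpoint
  mean rather than the time-average of all samples, matching the reduction
  of the printed formula to the two endpoints.
* **Exponential fit** (`fitExponential()`): least squares on $\log N$ vs
  $t$; used for the screen because it is robust, requires no numerical
  differentiation, and its $r^2$ flags wells where constant-rate growth is a
  poor description.
* **Smoothed instantaneous rates** (`instantaneousRates()`): counts are
  smoothed with a local-quadratic (Savitzky–Golay) filter — default window
  10 h, i.e. 5 samples at the 2 h imaging interval — with *point-reflected*
  padding at the ends (reflection through the end values preserves linear
  trends, so boundary derivatives are not biased toward zero). Derivatives
  are central differences on the smoothed series; points where smoothed
  $N \le 0$ yield `NA` rather than an error.

The default estimation window runs from growth-factor addition (24 h after
plating) to the end of imaging; trajectories are timestamped in hours since
plating. Wells whose dead-cell series decreases (possible with noisy
counting) are flagged with a warning, not rejected, because dye failure at
high death rates is a known feature of the assay being modelled.

Screen phenotypes are the difference in $k_P$ between each
(inhibitor, dose) condition and the mean of the vehicle-control wells on the
*same plate* and growth factor (`phenotypeTable()`); replicate wells are
combined as the mean of per-well rates. Dead-cell counts are not used in the
screen phenotype: when inhibitors cause massive death the dead-cell stain
undercounts and birth-rate deconvolution becomes unreliable, so the analysis
restricts itself to $k_P$.

# Kinome regression

For one growth factor, row $i$ of the design matrix is the treatment
(inhibitor $j$ at dose $d$) and column $k$ a kinase; the entry is the
fractional inhibition of kinase $k$ under that treatment. Profiles are
measured at a single reference concentration (1 µM by default), and are
mapped to other doses by single-site binding: the dissociation constant is
back-inferred from the profiled residual activity $r$ as
$K_d = c_{ref}\, r/(1-r)$ and inhibition at dose $d$ is $d/(d+K_d)$. This
choice is standard receptor pharmacology, monotone in dose, parameter-free,
and exactly reproduces the profiled point at the reference concentration.
Fractional inhibition (rather than residual activity) is the feature
encoding, so kinases whose inhibition lowers proliferation carry negative
coefficients; rankings use coefficient magnitude.

Kinases are first filtered by an expression table with a cutoff of 1.5
arbitrary units (a kinase exactly at the cutoff is kept; `>=` was chosen
because the filter is meant to *retain* plausibly expressed genes).

The phenotype is regressed on the design by elastic net with mixing weight
$\alpha = 0.15$ and standardized features,
$$\min_{\beta_0,\beta}\ \tfrac{1}{2n}\lVert y-\beta_0-X\beta\rVert^2
  +\lambda\big(\alpha\lVert\beta\rVert_1+\tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2\big),$$
solved by glmnet over a 100-point log-spaced $\lambda$ grid spanning four
decades below the smallest all-zero $\lambda$. $\lambda$ is selected at the
minimum of the 10-fold cross-validated mean squared error (cross-validated,
not training, error — training MSE is trivially minimized at $\lambda = 0$);
folds are assigned by a seeded shuffle so the fit is reproducible. All
(inhibitor, dose) rows are pooled into a single model per growth factor. The
fixed-$\lambda$ solver `enetCoef()` corrects for glmnet's internal response
scaling so that its coefficients minimize the objective exactly as written;
the test suite verifies this against direct numerical minimization by BFGS
on an $\epsilon$-smoothed objective.

Per growth factor, the kinases with non-zero coefficients at the selected
$\lambda$ are ranked by decreasing $|\beta_k|$; `intersectRankSum()` keeps
the kinases selected for *every* growth factor and orders them by the sum of
their per-growth-factor ranks. All ties (equal magnitudes, equal rank sums)
break lexicographically by kinase id, making the output deterministic. Both
coefficient signs are retained: a sign filter is not applied because
positive coefficients (kinases whose inhibition raises proliferation) are
informative too.

# siRNA validation statistics

Knockdown effects are reported as in the validation figure convention: for
each gene and growth factor, the effect is the mean over the three
independent siRNAs of each siRNA's replicate-mean $k_P$ divided by the
no-siRNA control rate, with the s.e.m. taken across the three siRNA means
(`normalizeSirna()`).

Significance is assessed per growth factor by one-way ANOVA over genes plus
control, followed by Dunnett many-to-one comparisons against the control
(`testSirnaEffects()`; a Holm-adjusted Welch fallback is coded and labelled
in the output should the Dunnett fit fail). The unit of analysis is the
replicate well, pooled across a gene's siRNAs. The alternative — using the
three siRNA means as the unit — was evaluated and rejected: means of $n$
wells have variance $\sigma^2/n$ while the control wells enter raw, and that
heteroscedasticity makes the pooled-variance Dunnett procedure
anti-conservative (simulated family-wise error ≈ 0.08 at nominal 0.05),
which robust covariance did not repair. With well-level pooling all groups
share the error variance the ANOVA assumes, the simulated family-wise error
is ≈ 0.05, and a planted 40% rate reduction at four replicates and 10% noise
is detected essentially always.

`receptorSpecificity()` encodes the receptor control experiment: a receptor
knockdown is *specific* when it significantly reduces proliferation under
its cognate growth factor (FGFR1–FGF2, VEGFR2–VEGFA, MET–HGF) and under
none of the others.

# The synthetic screen

The simulator exists so that every downstream stage has a testable ground
truth; its defaults encode the assay it emulates.

* **Design**: 255 cells per 384-plate well; growth factor added 24 h after
  plating; imaging every 2 h for 48 h thereafter; 58 inhibitors at six
  doses (5 µM top, serial 3-fold dilution) × 4 replicates × 3 growth
  factors; 16 DMSO wells per plate; screen growth-factor doses FGF2
  1.25 ng/ml, VEGFA 20 ng/ml, HGF 20 ng/ml (the concentrations stated for
  the validation experiments; the screen's own concentrations are not
  stated anywhere, so these are an assumption).
* **Cell states**: quiescent → committed → (division) and alive → dead.
  At growth-factor addition each quiescent cell commits with probability
  $E_{max}\,c/(c+EC_{50})$, modelling the observation that even saturating
  growth factor drives only a minority of the population through a single
  division ($E_{max} = 0.45$, consistent with ~320 cells producing ~130
  daughters at the highest dose). Committed cells exit G0 after a
  log-normal delay (mean 8 h, sd 4 h) and divide one cycle time later
  (normal, mean 21 h — the measured doubling time in complete medium — sd
  2 h); daughters return to quiescence under a single growth-factor pulse.
  These choices place the first divisions near 29 h post stimulation so the
  population birth rate rises around 20 h and peaks around 30 h, the
  calibration target. Death is a basal apoptotic hazard
  (0.0015 h$^{-1}$), suppressed up to 90% by growth factor, and set to a
  residual non-apoptotic hazard (default 0) by the caspase-inhibitor flag.
* **Inhibitor action**: commitment probability is multiplied by
  $\max(0,\,1-\sum_k w_k\,\mathrm{inh}_k(d))$ where $w_k$ are the
  ground-truth weights — linear in weighted fractional inhibition, matching
  the linearity the regression assumes, so recovery is well-posed. Above a
  weighted-inhibition load of 0.8 a toxicity hazard (0.05 h$^{-1}$) is
  added, emulating the death seen at high inhibitor doses.
* **Dynamics**: discrete-time tau-leap at the imaging interval with
  per-cell state. At a 2 h step, hazards of order $10^{-3}$ h$^{-1}$ and a
  division schedule resolved per cell, the leap error is negligible and a
  full 4000-well screen simulates in seconds. An internal event log of
  births and deaths per interval supports the conservation check
  $N(t)+M(t)-N(0)=\sum\text{births}$.
* **Counting noise** (on by default, off in oracle tests): each cell is
  labelled with probability 0.97 (the labelling efficiency of the nuclear
  marker; an unlabelled cell is consistently invisible, so observed dead
  counts stay monotone) and the observed nuclei count gets a 3%
  multiplicative counting error.
* **Inhibition profiles**: each inhibitor strongly inhibits 12 "hit"
  kinases (residual activity 0.02–0.2 at 1 µM) and leaves the rest nearly
  active (0.8–1.0). Hits are dealt round-robin over shuffled kinase cycles
  so coverage of the panel is even — the real panel was chosen for kinome
  coverage, and ≥ 2 inhibitors per kinase is what makes the kinase, rather
  than the inhibitor, identifiable. Twelve strong targets is typical
  promiscuity for profiled tool compounds.
* **Ground truth**: per growth factor, 5 true kinases (3 shared across all
  growth factors) with weights uniform in 0.4–1, drawn from kinases that
  pass the expression filter and are actually covered by an inhibitor.
* **Direct phenotype generation** (`simulatePhenotypes()`): for regression
  recovery studies the phenotype table is generated straight from the
  linear effect model, $\Delta k_P = -s\min(1,\sum_k w_k\,\mathrm{inh}_k(d))
  + \varepsilon$ with $s = 0.02$ h$^{-1}$ (the magnitude of a typical
  growth-factor-driven rate gain) and noise sd equal to 20% of the largest
  true effect. This isolates the regression from simulator stochasticity;
  the full stochastic route (simulate → rates → phenotypes → KIR) is
  exercised separately.

What the simulator does *not* model: image segmentation, cell motility and
spatial effects, density dependence, receptor-level signalling, knockdown
efficiency of siRNAs, or the dead-cell stain's failure mode under massive
death. Passing tests therefore demonstrate the correctness and calibration
of the analysis chain under the stated generative assumptions, not the
biological conclusions one would draw from real screen data — the original
raw screen data are not publicly deposited, so the real kinase lists are not
recomputable.

# Numerical choices and degenerate inputs

* Rate estimators error on zero-length windows or zero endpoint-mean counts;
  window endpoints must coincide with sampled times.
* `fitExponential()` refuses non-positive counts (log undefined) and fewer
  than 3 points; a constant series has $r^2 = 1$ by convention.
* `fitKir()` returns an empty ranking with a warning when the response has
  zero variance; the null model (all coefficients zero) is reached at the
  top of every $\lambda$ path.
* `inhibitionAtDose()` caps the inferred $K_d$ when residual activity
  approaches 1, so fully-unaffected kinases map to ≈ 0 inhibition at any
  dose.
* Seeds: every stochastic operation takes an explicit seed; screens derive
  per-well child seeds from the screen seed with a fixed 32-bit LCG step, so
  identical seeds give byte-identical outputs.

# Problem sizes used in the verification suite

The test suite and the acceptance script run at the screen's native design
where that is cheap (58 inhibitors × 6 doses × 3 growth factors for the
regression; 200 wells for the calibration of the birth wave; 1000 null and
400 power repeats for the siRNA error rates) and at reduced designs (6–12
kinases, 2–6 inhibitors, 2 replicates) for the end-to-end pipeline checks,
which exercise identical code paths on smaller plates.

# Session info

```{r}
sessionInfo()
```
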