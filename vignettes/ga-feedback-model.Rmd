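---
title: "Modeling gibberellin feedback rewired by a hormone-degraded CAS9 repressor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling gibberellin feedback rewired by a hormone-degraded CAS9 repressor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gahacr)
```

## The biological question

Gibberellins (GA) control plant stature, root elongation and flowering.
Bioactive GA4 is made in the last steps of a biosynthetic chain
(GA12 → GA15 → GA24 → GA9 → GA4, catalyzed by GA20-oxidase for the first
three oxidations and GA3-oxidase for the last), perceived by the GID1
receptor, and acts by triggering degradation of the DELLA repressor: the
GA4·GID1 complex binds DELLA and commits it to proteolysis.  DELLA closes
several feedback loops — it *activates* transcription of the biosynthetic
genes `GA20ox` and `GA3ox` and of the receptor `GID1`, and *represses* its
own transcription — so GA levels are homeostatic: a drop in GA stabilizes
DELLA, which drives more biosynthesis and perception.

A GA-regulated Hormone Activated CAS9-based Repressor (GAHACR) is a
synthetic dCas9–degron–repression-domain fusion.  Targeted to the `GA20ox`
promoter, it adds a *new, tunable line of negative feedback*: the repressor
is degraded through its DELLA-derived degron in a GA-dependent manner, so
low GA means more repressor and stronger repression of biosynthesis.  The
package simulates three regulatory variants of this circuit:

* **wildtype** — no repressor expressed (repressor transcription set to 0);
* **no_degron_cr** — the repressor lacks the GA degron, so its GA-dependent
  degradation constant is 0: an *open-loop* repressor whose abundance is
  set only by expression and basal turnover;
* **gahacr** — the full *closed-loop* repressor.

## The model

The state holds 17 species: the five GA intermediates, mRNA/protein pairs
for GA20ox, GA3ox, GID1 and DELLA, the GA4·GID1 and GA4·GID1·DELLA
complexes, and the repressor mRNA/protein pair (`ga_species()`).  All
equations are deterministic mass-action / Hill kinetics in nondimensional
units (time in hours, concentrations scaled to order one).

**Biosynthesis.** Each oxidation is bilinear in enzyme and substrate,
e.g. $v_1 = k_{20}\,[\mathrm{GA20ox}]\,[\mathrm{GA12}]$; GA12 is supplied
at a constant rate and every intermediate carries a first-order turnover.

**Perception.** GA4 binds GID1 reversibly
($k_\mathrm{bind}, k_\mathrm{unbind}$).  The GA4·GID1 complex captures
DELLA irreversibly at rate
$\delta_\mathrm{DELLA}\,[\mathrm{GA4{\cdot}GID1}]\,[\mathrm{DELLA}]$ into a
ternary complex whose fast turnover returns GA4·GID1 — net, GA-induced
DELLA degradation that is catalytic in the GA4·GID1 complex.

**Transcription.** DELLA activates GA20ox, GA3ox and GID1 through Hill
terms $D^n/(K^n + D^n)$ and represses its own transcription through the
complementary form $K^n/(K^n + D^n)$, with $K = 0.5$, $n = 2$ throughout.

**The repressor.** Its mRNA is produced constitutively at rate `hacr_tx`
(the promoter-strength knob), and its translation, mRNA decay, basal
protein decay and GA-induced degradation use *exactly* the same functional
forms as DELLA's — both equations are emitted by one shared internal
sub-RHS.  The one deliberate asymmetry is the promoter input: DELLA
self-represses while the synthetic cassette is constitutive, which is how
such constructs are actually driven.  For the repressor variants the
target gene's transcription term becomes the repressed Hill form

$$\mathrm{act}(D, R) \;=\; \frac{D^{n}}{K^{n} + D^{n} +
  (\rho\,R)^{h}},$$

with $D$ the DELLA concentration, $R$ the repressor concentration,
$\rho$ = `hacr_repstr` the user-set repression strength and exponent
$h$ = `hacr_rep_exponent` defaulting to 1 — the simplest reading of
"repressor concentration, scaled by a strength constant, added to the Hill
denominator"; the exponent is exposed so steeper repressor cooperativity
can be explored.  `GA20ox` is the default target; `GA3ox` and `GID1`
targeting reuse the same insertion on their transcription terms and are
provided as experimental options.

## Parameters

`default_parameters()` documents the full set.  The choices that matter:

* transcription maxima 1, mRNA decay 1 h⁻¹ (~40 min half-life),
  translation 1, protein decay 0.1 h⁻¹ (~7 h half-life) — common
  magnitudes for all four endogenous transcription units, keeping the
  network's behavior attributable to its topology rather than to
  asymmetric rates;
* Hill thresholds $K = 0.5$ with $n = 2$, placing the steady-state DELLA
  level on the sensitive flank of every feedback;
* GA-induced DELLA degradation $\delta_\mathrm{DELLA} = 5$, fast relative
  to basal decay, so GA perception dominates DELLA turnover — the defining
  property of the pathway;
* the repressor block mimics DELLA constant-for-constant
  (`hacr_tx = della_tx`, …, `hacr_ga_decay = della_ga_decay`), and
  `hacr_repstr = 1`, the log-midpoint of the sweep range below.

With these constants the wildtype settles at GA4 ≈ 1.53 with DELLA
≈ 0.09: GA high, repressor degraded — the expected homeostatic point.

## Numerical methods

* **Integration** (`integrate_model()`): `deSolve::lsoda`, automatic
  stiff/non-stiff switching, defaults `rel_tol = 1e-8`,
  `abs_tol = 1e-10`.  Negative excursions beyond `-abs_tol` are clipped to
  zero with a warning; smaller ones silently (they are within solver
  error).
* **Steady states** (`find_steady_state()`): integrate-then-polish.  The
  transient is integrated in geometrically growing chunks at relaxed
  tolerance until the residual sup-norm falls below a coarse pre-tolerance
  (1e-2); the endpoint then seeds a Levenberg–Marquardt root polish
  (`minpack.lm`).  A polished root is accepted only if it is non-negative,
  its residual is below the certification tolerance (`1e-8`), and it lies
  near the integration endpoint — the proximity guard keeps the polish
  from jumping to a branch the dynamics never reach.  If polishing fails
  the transient is re-integrated at full accuracy to the horizon
  (`t_max = 5000`).  Pure integration (`polish = FALSE`) is kept as an
  independent route and the two are cross-checked in the tests.
  Integration-before-root is deliberate: the system is stiff and the
  integration selects the biologically reached equilibrium.
* **Divergence and failure**: a diverging or non-converging cell yields a
  result flagged `converged = FALSE` (an `NA` cell in sweeps), never an
  exception that aborts a sweep, and never a silent number.
* **Determinism**: everything outside `perturb_parameters()` is
  deterministic; the ensemble generator is seeded and restores the
  caller's RNG state.

## Sweeps and scenarios

`figure1_scenarios()` bundles the three standard runs: the three-variant
time course from the rest state (all concentrations zero — the de-novo
rise of the pathway, with the transgene switching on at $t = 0$), and the
steady-state GA4 surfaces over repression strength × repressor degradation
rate for the no-degron and GAHACR variants.  No published axis ranges
exist for these surfaces, so the package's declared choice is 8 log-spaced
points spanning two decades either side of the default value of each
parameter; the ranges are recorded in each scenario file and in run
metadata.  `sweep_2d()` warm-starts each cell from its left neighbor's
solution (the surface is continuous in the parameters), falling back to
the rest state on failure.  The "expression level" axis referred to in the
variant contrast is `hacr_tx`, the transcription rate — promoter strength
is the knob an experimentalist actually tunes — with translation held at
the DELLA-mimicking default.

## The ensemble harness and what it does (not) show

`perturb_parameters()` draws log-normal multiplicative factors (median 1,
given cv, Hill coefficients fixed) — the natural noise model for
positive-scale rate constants.  `ensemble_robustness()` then re-checks the
two qualitative predictions on every member: monotonicity of the GAHACR
surface (GA4 non-increasing in repression strength, non-decreasing in
degradation rate) and the variant ordering
$\mathrm{GA4}_{wt} \ge \mathrm{GA4}_{gahacr} \ge
\mathrm{GA4}_{nodegron}$.  At cv = 0.2, n = 50 the test suite requires
both satisfied fractions to exceed 0.9 — the predictions are properties
of the feedback topology, not of one lucky constant set.  The generator emulates parameter uncertainty
only: it does not emulate cell-to-cell stochasticity, spatial gradients,
the multi-gene structure of the real `GA20ox` family (the model's GA20ox
is one lumped node), or transcriptome-scale readouts, so passing these
checks says nothing about those aspects of real data.

## A reported discrepancy

On matched expression-level ramps the *no-degron* repressor's GA4 response
is the more nonlinear one at the package's constants (scores ≈ 0.73 vs
≈ 0.12 from `nonlinearity_score()`, 1 − R² of the best straight line),
whereas the variant-contrast narrative expects the closed-loop GAHACR to
be the nonlinear one.  The reversal is robust to linear vs log ramp
spacing and to the ramp span.  Mechanistically it is not absurd: the
open-loop repressor accumulates in proportion to expression, so GA4 falls
hyperbolically through the Hill denominator, while the GAHACR's
GA-dependent degradation self-limits the repressor and flattens the
response.  The package reports both scores and flags the reversal rather
than asserting a direction; with a different constant set (e.g. weaker
DELLA-side feedback) the contrast may flip.

## Worked example

```{r example}
cmp <- compare_variants(default_parameters(), times = seq(0, 200, by = 0.5))
cmp
```

```{r sweep, eval = FALSE}
# steady-state GA4 surface for the closed-loop repressor (takes ~5 s)
sw <- sweep_2d(default_parameters(), "gahacr",
               parameter_axis("hacr_repstr",
                              exp(seq(log(1e-2), log(1e2), length.out = 8))),
               parameter_axis("hacr_ga_decay",
                              exp(seq(log(5e-2), log(5e2), length.out = 8))))
round(sw$values, 3)
```

## Known limitations

* Single-compartment, deterministic ODEs: no tissue structure, transport,
  or stochastic gene expression.
* The constant set is a documented in-package baseline chosen to realize
  the network's qualitative regime (homeostasis with GA-dominated DELLA
  turnover); absolute concentrations are in model units, not nM.
* One lumped GA20ox node stands in for the five-gene family; per-gene
  sgRNA efficiencies are outside the model.
* The repression exponent defaults to 1; cooperative repressor binding
  would need `hacr_rep_exponent > 1`, which is exposed but unexplored.
* Steady-state certification is a residual bound plus reachability by
  integration; formal stability analysis (eigenvalues, bifurcations) is
  out of scope.
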