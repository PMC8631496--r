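---
title: "Parallel-networks modelling of nucleus pulposus cell activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parallel-networks modelling of nucleus pulposus cell activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnDisc)
```

## The modelling problem

Nucleus pulposus (NP) cells in the avascular intervertebral disc live in a
"cocktail" of biochemical stimuli. Nutrition-related stimuli (glucose
concentration, extracellular pH) vary with diffusion distance and disc
degeneration; the pro-inflammatory cytokines IL1β and TNF-α are produced
locally and define four cell states: non-inflamed, IL1β-immunopositive,
TNF-α-immunopositive, and double positive. `pnDisc` estimates, for each
cell state and a given nutrient environment, normalized mRNA-expression
activities for five target genes: aggrecan (Agg), collagen types I and II
(Col-I, Col-II), and the proteases MMP3 and ADAMTS4.

The cell itself is treated as a black box. Each directed
stimulus-to-cell-activity (S-CA) edge carries two quantities:

* a **weighting factor** $\theta_S^{CA}$: the sensitivity of the activity
  to the stimulus *type*, calibrated from the maximal fold-change the
  stimulus was observed to induce;
* a **dose-response value** $x_S^{CA} \in [0,1]$: the sensitivity of the
  activity to the current stimulus *concentration*, given by a continuous
  monotone curve over the physiological range.

## Weighting-factor calibration

An experimental x-fold mRNA change $\epsilon > 0$ (control $= 1$) is first
mapped to the *cellular effort*
$$f(\epsilon) = \begin{cases}\epsilon & \epsilon \ge 1\\ 1/\epsilon & 0 < \epsilon < 1,\end{cases}$$
a symmetric magnitude of up- or down-regulation (no intracellular
mechanism is implied). Efforts are scaled by a constant
$\vartheta = \max f(\epsilon)$ over all significant PN-system edges, so
$\theta_S^{CA} = f(\epsilon)/\vartheta \in (0, 1]$ and exactly one edge
attains 1. Edges whose experimental effect was not statistically
significant are fixed at $\theta = 0.01$, which approximates a linear
coupling between $x$ and the resulting activity. With the shipped tables
the scaling factor is 28.7, attained by the pH→MMP3 edge:

```{r calibrate}
sys <- defaultPNSystem()
scalingFactor(sys)
head(relationships(sys), 10)
```

$\theta$ values are reported at 4 decimals (R's round-half-even), floored
at 0.01 so the PN-system range $0.01 \le \theta \le 1$ always holds; the
inflammation submodel reuses the PN-derived scaling factor, so its
$\theta$ may exceed 1 (pH→IL1β: 2.8223). Significance is an input flag of
the table, never recomputed, and the fold-change column may be empty for
non-significant rows. Likewise the activating/inhibiting sign of each edge
is an input. For the shipped defaults the signs of the significant edges
are assigned from the reported biology: cytokine edges with fold-changes
below 1 (collagen suppression, Agg suppression by IL1β) are inhibiting,
cytokine edges with fold-changes above 1 (protease induction) are
activating, and all nutrient edges are activating with the *direction* of
the effect carried by the dose-response anchors (next section).

## Dose-response curves

Each nutrient edge has a monotone curve $x(c) \in [0,1]$ over the
physiological range (glucose 0–5 mM, pH 6.5–7.4). The exact curve shapes
behind the original study are not recoverable from published material, so
the module defines a reproducible calibration instead: a four-parameter
logistic is fitted to discrete anchor points by Nelder–Mead least squares
(three fixed deterministic starting points, best fit kept) and then
rescaled so the curve spans exactly $[0,1]$ over the range. Anchors must
be monotone after averaging ties; non-monotone sequences are rejected.
Concentrations outside the range clamp to the endpoints (with a warning)
because the PN equation requires $x \in [0,1]$; extrapolation is never
attempted.

The shipped default anchors are the package's own design choice, shaped by
the cited experimental designs: glucose curves rise steeply below
0.5 mM and saturate near 1 mM (glucose levels 0, 0.5, 0.8, 1 and 5 mM
produced no measurable difference between 0.8 and 1 mM), and pH curves
span 6.5–7.4 with a midpoint near 6.95. Edges driven by acidity (MMP3,
ADAMTS4, both cytokine mRNAs) use decreasing anchors — $x$ is the
*strength of the edge's effect*, so it rises as pH falls — while
Agg/Col-I/Col-II use increasing ones. All downstream numbers are therefore
parameter-table-driven; users can override every anchor via
`fitCurveSet()` on their own table.

```{r curves}
curves <- defaultCurves()
evalCurve(curves[["pH:MMP3"]], c(6.5, 6.9349, 7.1, 7.4))
```

## The PN equation

A *network* is the set of S-CA edges converging on one activity for one
cell state (non-inflamed: glucose + pH; single positive: + that cytokine;
double positive: all four stimuli). The activation of activity $CA$ in
state $CS$ is

$$\omega_{CA,CS} = \underbrace{\frac{1+\sum\theta_\alpha}{\sum\theta_\alpha}\cdot
\frac{S_\alpha}{1+S_\alpha}}_{\text{activating term}}
\left(1-\frac{\sum\theta^{CA}_{S,\beta}}{\sum\theta^{CA}_{S,\alpha}+\sum\theta^{CA}_{S,\beta}}\cdot
\frac{1+\sum\theta^{CA}_\beta}{\sum\theta^{CA}_\beta}\cdot
\frac{S_\beta}{1+S_\beta}\right)$$

with $S_\alpha = \sum\theta x$ over the network's activating edges,
$S_\beta$ the analogous inhibiting sum, $\sum\theta_\alpha$ the sum of all
activating weights in the whole PN-system and $\sum\theta^{CA}_\beta$ the
inhibiting weights converging on the same activity regardless of state.
The result is bounded in $[0,1]$ (clamped defensively) and reported at 4
decimals — small persistent differences at the third or fourth decimal are
exactly what slow, cumulative degeneration processes make relevant.

Two readings of "all activating relationships within the PN-system" are
possible: counting each unique (stimulus, activity) edge once, or once per
cell-state network in which it appears. The package defaults to
`unique_edges` (the repetition across state levels is presentational) and
exposes `globalSumMode = "per_state_repeats"` as a config switch; both
paths are tested against an independent transcription of the equation.

Degenerate inputs are made total rather than erroring mid-pipeline: a
network with no activating edge yields $\omega = 0$ with a warning, and an
activity with no inhibiting edge anywhere has a vanishing inhibition term.

```{r profiles}
profileAll(sys, nutrientPreset("early_degenerated"), curves)[1:10, ]
```

The second mode, `thetaMode = "invariant_0.01"`, replaces every weighting
factor by 0.01 before evaluating; comparing the two modes quantifies what
the evidence-based weighting adds. The package asserts the orderings this
comparison must produce (protease elevation under TNF-α, Col-II below Agg,
larger state dispersion with individual weights) rather than exact printed
activities, which depend on the unrecoverable original curve shapes.

## Inflammation submodel

Cytokine mRNA activities $\omega_{IL1\beta}, \omega_{TNF\alpha}$ are
global (not cell-specific) single-network evaluations driven by the
nutrient environment, using the submodel weighting factors (glucose edges
and pH→TNF-α are non-significant, hence 0.01; pH→IL1β is 2.8223). Protein
pools follow per-hour steps
$$P_{t+1} = P_t\,2^{-1/t_{1/2}} + k_{syn}\,\omega$$
with half-lives of 2 h (IL1β) and 1 h (TNF-α); the 1 h step matches the
agent-based clock and the shortest half-life. $k_{syn}$ is not fixed by
any published value; it defaults to 1 in normalized units and is exposed
as an argument. The steady state $k_{syn}\omega/(1-2^{-1/t_{1/2}})$ is the
geometric-series limit and is tested against simulated trajectories.

The percentage of immunopositive cells is an affine map anchored at the
published ranges — IL1β: 10–59 %, TNF-α: 9–36 % — so $\omega = 0$ gives
the non-degenerated floor and $\omega = 1$ the degenerated ceiling. Pure
proportionality through zero would make 0 % reachable, contradicting the
published floors, which is why the affine reading was chosen. A
grade-conditional mapping (separate ranges per degeneration grade) would
be a defensible alternative; the overall-range reading is implemented.

The $x$ values that the inflamed cell-activity networks consume are, by
default, the cytokine protein level normalized by its saturated steady
state (`carrier = "protein"`, numerically equal to $\omega$ once
converged); `carrier = "mRNA"` uses the mRNA activity directly. The two
cytokine submodels are independent — no mutual stimulation — an assumption
the source literature itself flags as revisable.

```{r inflammation}
inflammationState(sys, nutrientPreset("borderline"), curves)
```

## 3D agent-based model

4,000 agents of 10 µm diameter are placed uniformly at random,
non-overlapping (centre distance ≥ 10 µm), in a 1 mm³ cube — an average NP
cell density where cells fill well under 1 % of the volume, so rejection
placement converges in a few repair rounds. 30 agents are drawn as
nucleation points (15 per cytokine, disjoint). Each cytokine's cluster set
then grows independently: at every step the not-yet-positive agent with
the globally shortest Euclidean distance to any positive agent is marked,
until `round(pct/100 * n)` agents are positive. Ties break to the lowest
agent id (a deterministic rule the source text does not specify).
Double-positive cells are the set intersection of the two grown sets — the
"overlapping areas" reading; a geometric-halo alternative is not
implementable from the available description. Domain boundaries are hard
walls; there is no motility, division, death, or cytokine diffusion field
(cluster growth is a phenomenological stand-in for paracrine spread).

Run-to-run variation comes only from placement and nucleation sampling;
given the percentages, the per-cytokine totals are deterministic and only
the overlap varies. `replicateRuns()` runs seeds `base .. base+n-1`
(10 replicates by default) and `summarizeReplicates()` reports means with
t-based 95 % confidence intervals.

```{r abm}
pct <- pctImmunopositiveCells(
  inflammationState(sys, nutrientPreset("optimal"), curves))
runs <- replicateRuns(pct[["IL1B"]], pct[["TNFA"]], n = 400, nRuns = 3,
                      baseSeed = 1, nIl1b = 3, nTnfa = 3)
summarizeReplicates(runs)[c("quantity", "mean", "ciLow", "ciHigh")]
```

## Synthetic fixtures and what passing tests show

`generateFixtureTables()` draws synthetic S-CA tables with fold-changes in
realistic ranges (activating 1.5–30, inhibiting 0.05–0.9, 80 % significant
edges, five monotone anchors per nutrient curve) and computes the expected
calibration output by direct arithmetic inside the generator, so the whole
calibration path is testable against ground truth it did not produce. The
generator emulates the *shape* of the evidence tables, not real biology:
it does not emulate inter-donor variance, measurement error in ΔCt space,
or cross-stimulus interactions, so green tests certify the computational
contract, not predictive accuracy on real NP tissue.

## Numerical choices, problem sizes, limitations

* Rounding: full precision internally; 4 decimals (round-half-even) at
  θ derivation and profile emission.
* Curve fitting: Nelder–Mead, `reltol = 1e-12`, three deterministic
  starts; no random initialization anywhere in the fit.
* The PN-equation implementation is verified against an independent
  scalar transcription at $10^{-12}$ on 10,000 randomized small networks,
  and cluster growth against a brute-force nearest-neighbour rescan at
  400 agents; full-scale runs use 4,000 agents and 10 replicates.
* Exact printed activities (e.g. 0.1266 for Agg, non-inflamed, optimal)
  are *not* reproduced: they depend on original curve shapes that are not
  publicly recoverable. Ordering and bounded-range properties are the
  honest targets; every quantity that *is* recoverable (the full weighting
  factor tables, scaling factor, half-life dynamics, percentage map
  endpoints) is reproduced exactly.
* No mechanical loading, no stimulus cross-effects, no temporal ECM
  accumulation, no spatial cytokine diffusion: the model scope ends at
  per-state activity profiles and cluster geometry.
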