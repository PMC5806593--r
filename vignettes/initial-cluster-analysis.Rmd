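---
title: "Initial-cluster analysis: model, conventions, and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Initial-cluster analysis: model, conventions, and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

The input is an ordered binary track: length $L$, $D$ ones, with the order
carrying the scientific meaning (residues sorted by distance from a focal
point, subjects sorted by an expression level). The question is whether the
ones are concentrated at the start, and if so, which prefix is the cluster.

Two models compete under the minimum description length (MDL) principle,
which prefers the model minimizing $\mathrm{DL}(S\,|\,\mathcal{M}) +
\mathrm{COMP}(\mathcal{M})$, description lengths in bits.

**Null.** A single Bernoulli theory with rate $D/L$:
$\mathrm{DL}(S|H_0) = D\log_2(L/D) + (L-D)\log_2\!\big(L/(L-D)\big)$,
i.e. $L$ times the Bernoulli entropy. One theory, so
$\mathrm{COMP}(H_0)=0$. $D$ is treated as fixed in both models, so its
specification cost cancels and neither model pays for it.

**Cut model.** A cut $x \in \{1,\dots,L-1\}$ splits the track into an
initial segment (length $x$, $D_1$ ones) and a terminal segment (length
$y = L-x$, $D_2 = D - D_1$ ones), each Bernoulli at its maximum-likelihood
rate. The fitted likelihood
$K_x = P_1^{D_1}(1-P_1)^{x-D_1} P_2^{D_2}(1-P_2)^{y-D_2}$ (with $0^0=1$)
is not a distribution over data sets, so it is normalized over all
$\binom{L}{D}$ arrangements (normalized maximum likelihood):
$P_x(S) = K_x(S)/Z$ where grouping arrangements by $D_1$ collapses $Z$ to
at most $D+1$ terms, $Z=\sum_{D_1}\binom{x}{D_1}\binom{y}{D-D_1}K_x(D_1)$.
Only *admissible* cuts compete — those with $D_1/x > D_2/y$, since a
1-dense *terminal* segment has no interpretation in the intended
applications — and $\mathrm{DL}(S|H_1) = -\log_2\max_x P_x(S)$.

**Complexity.** The $L-1$ cut theories are highly correlated; the
effective count comes from the Fisher information of the cut location in a
continuous two-Poisson relaxation, $J_X = (D/2)(1/X^2 + 1/Y^2)$, giving
$I = \tfrac12\sqrt{D/\pi}\sum_{x=1}^{L-1}\sqrt{1/x^2+1/y^2}$, numerically
close to $\sqrt{D/\pi}\,\ln(1.024\,L)$. The admissibility restriction
discards half the theory space, so $\mathrm{COMP}(H_1)=\log_2(I/2)$.

**Flattened prior.** The NML construction is implicitly Bayesian with a
Jeffreys prior $\propto \sqrt{1/x^2+1/y^2}$ over the cut — U-shaped, so
optimal cuts are dragged toward the sequence ends. There being no reason to
expect real cluster boundaries near the ends, the flattened variant
maximizes $R_x = P_x / \sqrt{1/x^2+1/y^2}$ with effective count
$I^* = \sqrt{D/\pi}(L-1)$. This is a heuristic (the package's simulation
experiments are what justify it), and it is the default recommendation for
structure analyses.

**Evidence and p-value.** $\Delta = \mathrm{DL}(S|H_0) -
(\mathrm{DL}(S|H_1) + \mathrm{COMP}(H_1))$ bits; the logistic conversion
$p = 1/(1+2^\Delta)$ makes "cut model preferred $\iff p< 0.5$" literal.
With no admissible cut (no ones, all ones terminal, or $D=L$) the result is
$X=\mathrm{NA}$, $p=1$ — a convention, not an error, so pipelines survive
degenerate tracks.

## Tunable parameters

* `prior` — `"jeffreys"` maximizes $P_x$, `"flattened"` maximizes $R_x$.
  Flattened is the default in the `order` pipeline; Jeffreys retains an
  edge only for true cuts very close to the boundaries.
* `apply_correction` — multiplies the effective theory count by $1-D/L$.
  The Poisson relaxation counts $(D_1,X)$ pairs with $D_1>X$ or $D_2>Y$
  that the discrete problem forbids, roughly a fraction $D/L$ of them, so
  uncorrected p-values are conservative, increasingly so as $D/L$ grows.
  Default `TRUE` in `cluster_test()` (user-facing analyses), and see below
  for the simulation experiments.
* `complexity_method` — `"sum"` (exact $O(L)$ sum, default: no fitted
  constant) or `"closed"` ($\ln(1.024L)$ form; the two agree within 1% for
  $L\ge 50$, which the tests check; the constant 1.024 is taken as given,
  its fitting procedure being unstated in the source material).

## The simulation module and its conventions

`sim_replicates()` generates uniform or boundary-skewed random tracks
(`generate_uniform()`, `generate_skewed()`) and finds each replicate's
optimal cut under both priors in one compiled pass. Two precomputations
make $10^6$ replicates cheap: $\log_2 K_x(D_1)$ and $\log_2 Z(x)$ depend
only on $(L, D, x, D_1)$, never on the arrangement, so they are tabled once
per configuration; the per-replicate scan is then a table lookup per cut.
Generation stays in R (`sample.int`), so reproducibility is exactly R's
seed contract; the compiled scan is cross-checked against the pure-R
`best_cut()` path in the test suite.

The stated world of the experiments (fixed, not tuned):

* Skew recovery: $L=601$, 35 ones uniform in positions 1–200, 40 in
  201–601, $10^5$ replicates (scaled down from the reference $10^6$;
  binomial error at $10^5$ is ≈0.1 percentage point, well inside the
  acceptance slack). Histogram bins of width 30.
* Null histograms: $L=601$, $D=75$, tallying only replicates where the cut
  model is preferred ($p<0.5$); the skewed experiment tallies every
  replicate with an admissible cut, and its threshold *fractions* are over
  all replicates. The reference text is ambiguous on that denominator; the
  all-replicates reading reproduces the printed percentages.
* Calibration: $L=500$, $D=25$, $10^6$ replicates (scaled down from
  $10^8$; the published $\le 33\%/\le 28\%$ deviation bounds at
  $P\le 10^{-3}$ are unreachable at desk scale, so the acceptance suite
  substitutes the property $P^* \le 1.5P$ on $P\in[10^{-3},10^{-2}]$ plus
  "the correction moves $P^*$ toward $P$ on average").

**Where the finite-size correction is applied.** The reference description
introduces the correction only after its simulation section, which reads as
if the printed p-value fractions for the skewed experiment (62.5%/8.6%
Jeffreys, 86.4%/11.4% flattened at thresholds 0.1/0.01) were computed
without it. Empirically they were not: uncorrected, this implementation
gets both 0.1-fractions 5–6 percentage points low, far outside Monte-Carlo
noise, while the corrected complexity reproduces all four within noise.
`sim_pvalue_fractions()` therefore applies the correction by default (and
exposes `apply_correction` so the uncorrected variant remains one flag
away). The cut/D1 recovery percentages involve no p-values and are
unaffected. This also settles the logistic-base question: base-2 log-odds
with $p = 1/(1+2^\Delta)$ reproduces the printed fractions; feeding bits
into a natural-base logistic does not (27.7% instead of 8.6% at the 0.01
threshold, in the same run).

## The structural front end

`order_by_distance()` sorts the residues of a selection by distance from a
focal specification: a literal point `"x,y,z"`, a named atom
`"chain:resnum:atom"`, or a residue centroid `"chain:resnum"`. The
residue-to-focal distance is the **minimum over heavy atoms** by default —
the convention that best matches "how far is this residue from a probe
inserted into the site" — with `atom_mode = "ca"` as the alternative; the
source material does not state its convention, so both are exposed and the
choice genuinely changes orderings (a test pins an example where it flips
the nearest residue). Distances are snapped to $10^{-6}$ Å before sorting
and ties break by (chain, residue number, insertion code), making the
ordering a total order: shuffling input atoms cannot change the track.
When the focal is a residue of the ordered selection itself, that index
residue is dropped from the track (its distance, zero, is not a datum);
a distinguished identifier naming it is reported as unmatched rather than
silently absorbed.

PDB input is parsed with a minimal fixed-column reader (first model, first
alternate location, heavy atoms, waters always excluded, other hetero
groups opt-in) written for this package because no PDB parser is available
in the supported dependency set; it handles exactly the record fields the
ordering needs and nothing else.

## Numerical choices

* All likelihoods in base-2 log space via `lchoose`/log-gamma; $Z$ by
  log-sum-exp. Binomial coefficients at protein scale overflow doubles
  before $L=200$ if materialized.
* $0^0 = 1$ throughout ($0\log 0 = 0$), so degenerate segments cost 0 bits.
* Admissibility and the logistic are computed from integer cross-products
  ($D_1 L > D x$) and a two-branch stable logistic, respectively, so
  neither overflows.
* Ties in the cut scan break toward the smallest $x$ (the source is silent;
  determinism matters more than the choice).
* The flattened score $R_x$ is not a probability (it can exceed 1); only
  differences of its logs enter results.

## What a green test does and does not establish

The synthetic generators emulate exactly the stated world above:
exchangeable placements with fixed counts, hard segment boundaries,
independent replicates. Real residue tracks violate several of these —
distances are correlated along the chain, "distinguished" calls carry
their own error, and a binding site is not a sharp sphere around a focal
atom — so a small p-value certifies surprising prefix density *given the
ordering and the flags*, not the biological story behind them. The
published protein application is deliberately not an acceptance target:
its distinguished-residue sets and distance convention are not printed, so
the front end is validated on synthetic structures where the truth is
known by construction.

## Known limitations

* One cut only: no multi-segment variant, no terminal-dense (two-sided)
  test, no multiple-testing layer across many tracks.
* $D$ is fixed, not estimated; comparing tracks with very different $D$
  compares different nulls.
* The flattened prior and the $1-D/L$ correction are effective heuristics,
  calibrated here by simulation, not theorems; for $D/L$ near 1 the
  corrected complexity degenerates (and is refused at $D=L$).
* The PDB reader is deliberately minimal (no mmCIF, no symmetry mates, no
  multi-model averaging).
* Plotting is left to the caller: reports carry the binned fractions and
  calibration pairs as plain data.
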