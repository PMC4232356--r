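---
title: "Expression-guided flux minimization: model, assumptions, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-guided flux minimization: model, assumptions, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efmin)
```

## The problem

A metabolic network with $n$ reactions and $m$ internal metabolites
constrains steady-state fluxes only up to an $(n - m)$-dimensional
solution space: $S\,r = 0$ with directionality bounds. Picking one flux
vector out of that space requires either measurements or an optimality
principle. Flux balance analysis (FBA) assumes the cell maximizes biomass
production — often right for fast-growing bacteria, demonstrably wrong
for, say, Crabtree-positive yeast pouring carbon into ethanol. This
package implements the complementary principle of *expression-guided flux
minimization*: among all feasible states that sustain at least a
negligible biomass flux, choose the one with the smallest weighted total
flux, where each reaction's weight decreases with the expression of its
associated genes.

$$
\min_r \sum_i w_i\,\lvert r_i\rvert
\quad \text{s.t.} \quad
S r = 0,\;\; r^L \le r \le r^U,\;\; r_B \ge \varepsilon,
\qquad w_i = 1 - g_i .
$$

The biological reading: flux through a reaction requires enzyme, enzyme
is expensive, and the transcriptional state tells us which enzymes the
cell has chosen to pay for. Reactions at the expression maximum
($g_i = 1$) are free; everything else is suppressed in proportion to how
weakly it is expressed; reactions with no associated expression data get
the neutral weight 1.

## From genes to weights

Expression values are mapped onto reactions through GPR Boolean rules:
AND (an enzyme complex — the least-expressed subunit limits) evaluates to
the minimum of its children, OR (isozymes — the strongest suffices) to
the maximum. Two conventions had to be fixed where common usage varies:

* **Operator precedence.** Unparenthesized `A and B or C` parses as
  `(A and B) or C` — AND binds tighter, matching the SBML-fbc convention
  (cross-checked against cobra's parser). Curated models almost always
  parenthesize, so this rarely matters.
* **Missing genes inside a rule.** By default an unmeasured gene is
  simply left out of the min/max, and only a rule with *no* measured leaf
  makes the reaction "missing". This keeps partial data usable. The
  stricter reading — an AND with an unmeasured subunit is unusable — is
  available via `missing_poisons_and = TRUE` in `evaluate_gpr()` /
  `map_expression()`.

After mapping, values are divided by their global maximum (one maximum
across all mapped reactions, not per pathway), so $g_i \in [0, 1]$.
Normalization happens *after* GPR evaluation; the two orders differ only
when mixing platforms, which the package treats as the caller's
preprocessing problem.

## Parameters that matter

| parameter | where | default | meaning |
|---|---|---|---|
| $\varepsilon$ | `efmin_config()` | 0.01 mmol/(gDW·h) | minimum biomass flux |
| `big_bound` | `efmin_config()` | `Inf` | finite stand-in for unbounded fluxes |
| `rmf_threshold` | `gimme_config()` | 0.90 | RMF fraction of FBA max (GIMME) |
| `g_cutoff` | `gimme_config()` | 0.05 | GIMME expression cutoff |
| `bound_scale` | `eflux_config()` | largest finite bound, else 1000 | E-Flux capacity scale |

$\varepsilon$ is *not* a tuning parameter. The constraint set
$\{S r = 0,\ r \ge r^L,\ r \le r^U,\ r_B \ge \varepsilon\}$ is a cone
sliced at $\varepsilon$ when bounds are infinite, so the optimal solution
scales exactly linearly in $\varepsilon$ and any two choices coincide
after normalization to a common reference flux. The suite asserts this
at $\varepsilon \in \{10^{-4}, 10^{-2}, 1\}$ to $10^{-8}$ relative
tolerance. Finite measured bounds (e.g. a fixed glucose uptake) break the
cone argument, which is one reason the default analysis removes
condition-specific bounds (`apply_thermodynamic_bounds()`, optionally
with `reset = TRUE` for models shipping default capacity bounds — both
behaviors are exposed because curated genome-scale models differ in
whether their finite defaults are meaningful).

GIMME's defaults (90% of the FBA biomass maximum, cutoff 0.05) mirror
the values conventionally used when the method is benchmarked, so
comparisons are reproducible in spirit. E-Flux's published description
does not fix the scale of its expression-proportional bounds; bounds are
proportional to $g_i$ with a scale defaulting to the model's largest
finite bound. For irreversible reactions without data E-Flux keeps
$(0, \text{existing ub})$ — the lower-bound treatment for that case is
genuinely ambiguous in the literature, and this is the conservative
choice.

## The linear program and its numerics

The absolute values are linearized with one magnitude variable per
reaction, $t_i \ge r_i$, $t_i \ge -r_i$, objective $\sum w_i t_i$ — half
as many added columns as positive/negative flux splitting, and at any
optimum $t_i = \lvert r_i\rvert$ wherever $w_i > 0$. Reactions with
$w_i = 0$ keep their $t_i$ constrained (so the objective budget used by
variability analysis remains meaningful) but cost nothing, which is what
lets fully expressed reactions carry free flux.

The LPs are solved by an internal dense two-phase simplex with Bland's
rule. This is a deliberate design choice: the package needs exact status
classification — *optimal* / *infeasible* (biomass structurally blocked)
/ *unbounded* (expected for FBA without an uptake limit) — and native
infinite bounds, with problem sizes where pivoting speed is irrelevant.
Free variables are split internally rather than boxed with a big-M
constant. Tolerances: pivot/zero threshold $10^{-9}$; fluxes below
`tolerance` ($10^{-8}$) in the returned solution are snapped to zero. On
feasible bounded instances the simplex is cross-checked in the test
suite against an independent LP implementation (`pracma::linprog`) and,
on networks of up to ten reactions, against brute-force enumeration of
all basic feasible solutions.

Degenerate alternative optima are reported as whatever vertex the
simplex lands on — no lexicographic tie-breaking is imposed. Flux
variability analysis is the sanctioned way to characterize the optimal
face: `run_fva()` re-optimizes each flux under the budget
$\sum_i w_i t_i \le z^\*$ (plus a $10^{-10}$-relative slack so the
optimal vertex itself stays feasible in floating point). On weighted
instances the optimum is generically unique and ranges collapse to
(numerically) zero width; symmetric constructions in the test suite show
the ranges opening up to the full throughput exactly when two routes tie.

## What the synthetic generators emulate — and what they don't

`build_toy_network()` is the canonical nine-reaction illustration: one
uptake, one secreted product, three biomass routes of lengths 1, 2, 3
between the branch metabolite and the biomass precursor. It is small
enough that every optimization can be checked by hand and by exhaustive
vertex enumeration.

`gen_planted_condition()` builds parallel-path networks with a designated
"true" route whose genes sit at expression 1, all others at a baseline
0.2 plus Gaussian noise (sd 0.05 in the acceptance property) *clipped*
to $[0, 1]$ — clipping rather than re-normalizing keeps the planted
ordering intact, since re-normalization would shift every weight whenever
noise exceeded 1. Identity GPRs (one gene per reaction) are used so the
planted signal maps one-to-one onto weights; GPR complexity is exercised
separately by the parser tests. Recovery of the planted active set over
50 seeded conditions is asserted at ≥ 95%.

`build_cycle_fixture()` plants a balanced three-reaction loop on fresh
internal metabolites, deliberately disconnected from the productive
routes: an arc drawn between the toy's own metabolites would open a new
substrate-to-biomass route, and flux on it could then be a legitimate
pathway choice rather than the thermodynamically infeasible circulation
the fixture is meant to isolate. With strictly positive weights the
optimizer must leave the loop at exactly zero.

These generators emulate the *structure* of the benchmark setting —
under-determined networks, partial expression coverage, planted truth —
but not its biology: no GPR redundancy from real isozyme families, no
correlated expression noise, no measurement error on fluxes, and toy
dimensions rather than thousands of reactions. Passing tests therefore
certify the optimization machinery and the statistics, not predictive
accuracy on organisms; the genome-scale workflow (SBML model + measured
expression + measured fluxes) is supported but requires the user's data.

## Meta-statistics

Given a table of per-condition correlation coefficients for several
methods, all values are pooled and converted to percentile scores,
$\text{rank}/N$ ascending with mid-ranks on ties (a `(rank − 0.5)/N`
variant is available via `midpoint = TRUE`; the default is the plain
rank-fraction form). A one-way ANOVA on the scores — mean squares on
$(K-1,\ N-K)$ degrees of freedom — tests whether methods differ at all.
Rank products then ask whether a given method is *consistently* good
across independent tables: rank methods within each table by unrounded
average score (mid-ranks on ties — with two-decimal table values,
three-way ties do occur and mid-ranking them is what makes the published
reference values reproducible), take the geometric mean of the method's
ranks, and compute the exact P value by enumerating all
$\prod_t n_t$ rank tuples of the independent-uniform null. For the
bundled three tables that is 392 tuples, so exhaustive enumeration is
exact and instantaneous; no gamma approximation is needed. With one
table the P value reduces to the closed form $r/n$, which the suite
checks, along with agreement between enumeration and a Monte-Carlo
estimate of the null.

Averaging is done on unrounded column means; ranking from the printed
two-decimal averages instead would leave near-ties unbroken and change
the result. The bundled tables transcribe entries printed as "<0.01" as
0.005 — any value below the next-smallest entry gives identical ranks,
so the choice is inconsequential for every statistic computed here.

## Problem sizes and determinism

All shipped computations are small by construction: the toy and planted
networks have ≤ 13 reactions, FVA solves $2n$ LPs of that size, the
rank-product null has 392 tuples, and the full test suite plus the
acceptance script run in well under a minute on one core. Every
stochastic generator is a pure function of an explicit integer seed
(`with_seed` save/restores the caller's RNG state), so conditions are
reproducible by construction.

## Known limitations

* Quadratic or other nonlinear objectives are out of scope; loop-freeness
  emerges from minimization rather than from explicit loop-law
  constraints, and holds only where weights are strictly positive —
  zero-weight cycles can circulate undetected (FVA exposes them).
* Biomass is the single default required functionality. The `required`
  argument of `solve_efmin()` accepts any set of reactions with minimum
  fluxes, but choosing such sets is condition-specific and left to the
  user.
* The SBML reader is deliberately minimal (Level 3 core + fbc gene
  associations, boundary species via `boundaryCondition`); exotic
  constructs (species conversion factors, initial-assignment bounds) are
  not interpreted.
* The evaluation layer pairs predicted and measured fluxes by reaction
  id; lumped measured reactions (as produced by ¹³C-MFA) need a
  user-supplied mapping before pairing. Whether correlations should use
  signed or absolute fluxes for reversible reactions is unsettled;
  signed is the default.
* The dense simplex is comfortable up to a few thousand columns but is
  not tuned for genome-scale FVA (thousands of reactions × 2 LPs each);
  for that workload, batching or an external solver wrapper would be the
  natural extension behind the same interface.
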