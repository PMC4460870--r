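---
title: "Estimating per-protein amino-acid supply and its role in translation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating per-protein amino-acid supply and its role in translation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aasupply)
```

## The question

Different proteins draw different mixtures of amino acids from the same
metabolic network. Given a genome-scale stoichiometric reconstruction and a
limited substrate uptake, how much amino-acid flux can the network devote to
synthesizing one particular protein while the cell keeps growing? And does
that *supply* — a purely metabolic quantity — predict how efficiently the
protein is translated (protein output per mRNA, ribosomes bound per mRNA)?

`aasupply` implements the full chain: constraint-based supply estimation,
translation-efficiency and ribosome-density summaries from expression
tables, rank-based statistics connecting them, and the amino-acid-starvation
buffering analysis, plus a synthetic-data module that makes every stage
testable against known ground truth.

## The supply model

A stoichiometric model consists of a matrix $S$ (metabolites × reactions),
flux bounds $v_{lb} \le v \le v_{ub}$, and a biomass pseudo-reaction whose
flux is the growth rate $\mu$. All flux-balance computations assume steady
state, $S v = 0$.

Supply estimation is a two-step linear program:

1. **Growth step.** Maximize $v_{\text{biomass}}$ subject to
   $S v = 0$ and the bounds, with the limiting substrate uptake fixed
   (glucose at 10 mmol gDW$^{-1}$ h$^{-1}$ by convention: a lower bound of
   $-10$ on the exchange reaction). The optimum is $\mu$.
2. **Supply step.** Replace the biomass reaction by a *partial-biomass*
   reaction whose amino-acid coefficients are scaled to a basal level
   $\beta$ (default 0.3) with every other coefficient untouched; fix its
   flux at $\mu$; add a protein-specific sink that consumes free amino
   acids in the protein's residue frequencies and produces nothing; and
   maximize the sink flux. That maximum is the protein's amino-acid
   supply, in residue equivalents gDW$^{-1}$ h$^{-1}$.

Fixing the partial biomass at $\mu$ keeps every non-amino-acid growth
demand at the optimal rate while releasing a $1-\beta$ share of amino-acid
biosynthesis; the sink then measures how much of that released capacity the
network can channel into one protein's particular residue mixture. Because
the model is linear, $\beta$ rescales supplies without reordering them —
the package tests this rank invariance explicitly across
$\beta \in \{0.1, 0.3, 0.5, 0.7\}$.

Two choices here were genuinely open:

* **Frequencies, not counts.** The sink uses residue frequencies
  (counts/length), making supply a per-residue rate comparable across
  proteins of different lengths. Raw counts would conflate composition
  with length; rank statistics would agree for equal-length proteomes but
  not across lengths.
* **A pure amino-acid sink.** The sink consumes free amino acids only — no
  ATP/GTP, tRNA or water bookkeeping. Polymerization costs are deliberately
  out of scope: supply isolates the metabolic availability of residues, not
  the energetics of elongation.

### The LP solver

Flux-balance programs are *structurally degenerate*: after shifting
variables to non-negative coordinates the equality right-hand side is
zero wherever lower bounds are zero, so phase-1 bases are degenerate and
alternate optimal flux vectors are generic. The package ships its own
bounded-variable two-phase primal simplex (`R/lp_solver.R`) with Bland's
anti-cycling rule; phase-1 artificial variables are frozen at zero for
phase 2, which also handles redundant mass-balance rows without basis
repair. Tolerances: $10^{-9}$ for pricing/feasibility inside the solver,
$10^{-6}$ for all assertions in tests (standard LP numerics, far below any
biological signal). Only the objective value is contractual — flux vectors
are reported but never asserted, because degeneracy makes them
non-unique. The test suite checks every optimum on small models against a
brute-force vertex-enumeration oracle that shares no code with the solver.

## Sequence covariates

* **Residue frequencies** feed the sink directly; a trailing stop (`*`) is
  stripped, and non-canonical letters are an error in strict mode or
  dropped with a warning otherwise.
* **CAI** is the geometric mean of relative adaptiveness $w$ over a CDS,
  with $w = \text{count}/\max(\text{synonymous counts})$ computed from a
  highly-expressed reference (conventionally ribosomal-protein genes,
  supplied as an id list — no annotation mining). Codons unused in the
  reference get $w = 0.01$ so the geometric mean never collapses. The
  default dialect (`sharp-li`) excludes Met, Trp and stops from the mean,
  since single-codon amino acids carry no usage information; an `emboss`
  dialect keeps Met and Trp for compatibility with that program's
  convention. Both are provided because published CAI values rarely state
  which convention produced them.
* **Gene-start folding energy** covers the window $-4..+38$ relative to
  the translation start (42 nt, no position 0). The package does not
  predict RNA structure: the energy is an input covariate, either from a
  pluggable engine (`rnafold_engine()` shells out to RNAfold when
  available) or a precomputed TSV; a missing energy is a missing value,
  never an abort.

## Expression metrics and filters

TE is protein abundance (ppm) over mRNA level (molecules/cell); RD is
footprint RPKM over mRNA-fragment RPKM, each series replicate-averaged
first. The two mRNA denominators are distinct measurements and are never
substituted for one another.

Reliability filters follow the published thresholds, strictly
interpreted: mRNA level $> 0.5$ molecules/cell for TE; for RD, *both* the
footprint and fragment series need replicate mean $> 1$ and max/min
replicate ratio $< 1.5$. "Variation below 1.5-fold" is read as the max/min
ratio — the simplest metric consistent with the wording — and a
single-replicate series passes vacuously. Filters are applied per series,
not on condition averages (the wording is ambiguous; per-series is the
conservative reading). All filters are idempotent and tested against hand
application on a fixed 10-row table.

## Rank-based statistics

Correlations are Spearman's, with average ranks for ties and a two-sided
t-approximation p-value on $n-2$ degrees of freedom.

The regression model is rank-based: coefficients minimize Jaeckel's
dispersion $D(\beta) = \sum_i a(R(e_i))\, e_i$ with Wilcoxon scores
$a(i) = \sqrt{12}\,(i/(n+1) - 1/2)$, a convex piecewise-linear criterion
robust to outlying responses. For one covariate the minimizer is computed
*exactly* as the weighted median of pairwise slopes (weights
$|x_j - x_i|$); with several covariates the dispersion is minimized
numerically (BFGS on the subgradient, Nelder–Mead polish, multi-start from
the least-squares solution and from zero), and flats are resolved toward
the smallest-norm coefficient vector. The intercept is the residual
median. Per-covariate p-values come from drop-in-dispersion F-tests with
the scale $\tau$ estimated by a Koul–Sievers–McKean window estimator: the
window is the $\delta_n$-quantile of pairwise absolute residual
differences with $\delta_n = \min(0.8,\, 4 n^{-2/5})$ — shrinking in $n$
for consistency — and the usual $\sqrt{n/(n-p-1)}$ degrees-of-freedom
correction. The overall fit is summarized by
$R = \sqrt{1 - D_{\text{full}}/D_{\text{null}}}$, a dispersion-based
analogue of a robust multiple correlation; it is labelled as such in all
output because no standard definition exists for this quantity.

The one-sided Wilcoxon rank-sum test is exact by enumeration of all
$\binom{n_x+n_y}{n_x}$ rank assignments when $n_x + n_y \le 12$ (ties
handled through average ranks) and otherwise uses the normal approximation
with tie correction and continuity correction. Both routes are
cross-checked against each other and against an independent reference
implementation in the tests.

## The starvation buffering analysis

The fold change is the plain ratio RD(starved)/RD(normal). Genes are split
at the supply median: WAAS (well supplied, top half) vs PAAS; with an odd
count WAAS is the larger group, and median ties resolve by stable input
order into WAAS — the published split of 2801 genes into 1401 vs 1400 is
reproduced by this policy, which had to be fixed by choice since the
original does not state which group takes the extra gene. The buffering
test is one-sided (WAAS fold change smaller). RD-increased genes are those
with fold change strictly above 2.0; their mRNA comparison uses the
normal-condition fragment-RPKM mean (which condition the original used is
not stated; normal is the natural baseline and matches the RPKM scale of
the reported medians).

## What the synthetic data emulates — and what it does not

The generator produces every input the pipeline reads, with known planted
structure:

* **Toy metabolic networks**: one substrate, one synthesis reaction per
  amino acid with configurable yield, biomass consuming a stated
  composition. The canonical fixture (two residues, yields 2 and 1,
  uptake 10) has closed-form optima — growth 20/3; supplies 14, 7 and 28/3
  for all-A, all-B and half-half proteins at $\beta = 0.3$ — derived by
  hand before the solver existed, and asserted to $10^{-6}$.
* **Proteomes**: fixed-length (300-residue) sequences with per-protein
  compositions drawn from a Dirichlet distribution whose mean interpolates
  toward the cheapest residue as the bias parameter rises. The Dirichlet
  layer gives proteins genuinely different compositions, hence a spread of
  supplies; length variation is deliberately not modelled.
* **Expression tables**: a Gaussian copula ties TE, RD, mRNA level and
  fragment RPKM to the supply ranks with latent correlation
  $r = 2\sin(\pi\rho_s/6)$, so the *population Spearman* equals the target
  $\rho_s$ exactly — the planted quantity is the same statistic the
  analysis measures, which an additive-noise construction would not
  guarantee. The same target is used for mRNA so that the
  RD-increased-genes comparison has the supply–expression coupling the
  analysis presumes (the original reports exactly such a positive
  supply–mRNA correlation). Observables are lognormal transforms:
  mRNA level $e^{1.5 + z}$ molecules/cell (so ~1–2% of genes fall below the
  0.5 filter), fragment RPKM $e^{3.8 + z}$ (median ≈ 45, the scale of the
  published mRNA medians), RD $e^{0.5 z}$ (median ≈ 1). Protein abundance
  is TE × mRNA and footprint RPKM is RD × fragment RPKM, so the ratios the
  pipeline computes recover the planted values identically when replicate
  noise is off. Replicates carry mean-preserving lognormal noise with
  CV 0.1 — the scale at which a few tenths of a percent of genes trip the
  1.5-fold filter, as in real replicate data.
* **Starvation tables**: gene $i$'s fold change has median
  $1 + \delta\,(1 - p_i)$ with $p_i$ the supply percentile and
  $\delta = 0.2$ by default, times lognormal noise of log-sd 0.25 (the
  generator's own noise-scale choice; the construction only specifies
  "median profile plus noise"). At these defaults the WAAS/PAAS medians
  land near 1.05 vs 1.15, matching the magnitude of the published 1.05 vs
  1.19 without being fitted to it. $\delta = 0$ is the calibration null.

Passing on this synthetic data shows that the pipeline measures what it
claims to measure — it recovers planted correlations, orders group medians
correctly, and rejects at the nominal rate under the null. It does *not*
show that real organisms behave this way: the copula has no biological
covariates (no codon bias confounding, no operon structure, no shared
regulation), noise is lognormal by construction, and the toy networks have
none of the pathway coupling of a genome-scale reconstruction. Conclusions
about real proteomes require the real inputs (a curated model, PaxDb
abundances, ribosome-profiling tables), for which the pipeline's readers
and filters are the interface.

## Problem sizes and determinism

The shipped analysis and the validation suite run at $n = 2000$ genes for
correlation recovery (20 expression seeds over one supply table), 200/2000
genes for the null-calibration/power checks of the buffering test
(200 and 50 seeded replicates), 100 paired replicates at $n = 150$ for the
outlier-robustness comparison, and toy models of at most 10 reactions for
all oracle comparisons — sizes at which every planted effect is resolvable
with comfortable margins while a full run stays in the minutes range on a
single core. Every random draw flows through an explicit integer seed
(`withr::with_seed`; no global state), so reruns are byte-identical, and
the toy-model LP layer is deterministic outright.

## Known limitations

* Supply ignores amino-acid transport and protein degradation as sources,
  exactly as the two-step formulation dictates; it is a biosynthetic
  capacity, not a free-pool concentration.
* The `total_r` of the rank regression is a dispersion-based stand-in for
  a robust multiple correlation, not a standard quantity; compare like
  with like.
* The KSM window estimator of $\tau$ is accurate to a few percent at the
  sample sizes used here but is not the heavy-tail-optimal bandwidth
  choice; p-values from very small fits (n below ~30) should be treated
  as indicative.
* The SBML reader covers Level 3 + FBC as COBRA models use it (species,
  reactions, bound parameters, active objective); it is not a general
  SBML implementation.
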