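# aasupply

Constraint-based estimation of per-protein **amino-acid supply** and its
relationship to **protein translation**, for systems biologists working
with genome-scale metabolic reconstructions and ribosome-profiling
summary data.

Different proteins draw different residue mixtures from the same metabolic
network under the same limited substrate uptake. `aasupply` quantifies, for
each protein, how much amino-acid flux the network can devote to it while
the cell keeps growing, and then asks whether that supply predicts
translation efficiency and ribosome density.

## The method

Given a stoichiometric model (matrix *S*, bounds *v*<sub>lb</sub> ≤ *v* ≤
*v*<sub>ub</sub>, biomass reaction), supply is a two-step linear program at
steady state *S v* = 0:

1. **Growth:** maximize *v*<sub>biomass</sub> under a fixed substrate
   uptake (glucose 10 mmol gDW⁻¹ h⁻¹ by default) → growth rate *μ*.
2. **Supply:** scale the biomass reaction's amino-acid coefficients to a
   basal level *β* (default 0.3, other coefficients unchanged), fix this
   partial-biomass flux at *μ*, add a protein-specific sink consuming free
   amino acids in the protein's residue frequencies, and maximize the sink
   flux. The optimum is the protein's amino-acid supply
   (residue equivalents gDW⁻¹ h⁻¹).

Model linearity makes the supply *ranking* independent of *β*, which the
tests verify. Downstream, the package computes translation efficiency
(TE = protein abundance / mRNA molecules per cell) and ribosome density
(RD = footprint RPKM / mRNA-fragment RPKM, replicate-averaged) with strict
reliability filters (mRNA > 0.5 molecules/cell; both RPKM series with mean
> 1 and < 1.5-fold replicate variation), and relates supply to them with
rank statistics: Spearman correlation, rank-based linear regression
(Jaeckel dispersion with Wilcoxon scores, exact weighted-median solver for
one covariate), and one-sided Wilcoxon rank-sum tests (exact by
enumeration for small samples). The starvation module splits genes at the
supply median (WAAS vs PAAS) and tests whether well-supplied genes buffer
their ribosome-density fold change under amino-acid starvation.

Because every stage needs inputs that normally come from external
databases, the package includes a first-class synthetic-data module: toy
metabolic models with hand-computable optima, Dirichlet-composition
proteomes, and expression/starvation tables whose Spearman structure is
planted exactly via a Gaussian copula. It also ships its own
bounded-variable two-phase simplex (Bland's rule), since flux-balance
programs are too degenerate for the textbook solvers available in a stock
R installation.

## Worked example

The `analysis/` directory is a numbered workflow over the package
(simulate → supply → metrics → correlations → starvation). Running it:

```sh
Rscript analysis/01_simulate.R   # synthetic model/proteome/tables, n = 2000
Rscript analysis/02_supply.R
Rscript analysis/03_metrics.R
Rscript analysis/04_correlations.R
Rscript analysis/05_starvation.R
```

Stage 4 prints (planted Spearman 0.30 between supply and TE/RD/mRNA):

```
Spearman correlations (filtered sets):
  supply ~ te: r = 0.276, p = 6.75e-36, n = 1976
  supply ~ rd: r = 0.284, p = 4.45e-38, n = 1988
  supply ~ mrna_level: r = 0.263, p = 1.6e-32, n = 1976

Rank regression rd ~ supply:
Rank-based regression (Wilcoxon scores), n = 1988
  intercept: -0.12711
  supply             0.080388   p = 1.22e-37
  dispersion-based total R (robust R analogue): 0.1932
```

The correlations recover the planted 0.30 within sampling error after the
reliability filters (n drops from 2000 to 1976/1988), and the regression
confirms supply as a significant predictor of RD. Stage 5 prints the
buffering analysis on the synthetic starvation table (planted buffering
delta 0.2):

```
WAAS vs PAAS: medians 1.058 vs 1.164, n 1000 vs 1000, one-sided p = 3.94e-18
RD-increased vs others: medians 25.68 vs 43.86, n 25 vs 1975, one-sided p = 0.00315
```

Well-supplied genes show the smaller ribosome-density fold change, and the
genes whose RD more than doubles sit at lower mRNA expression — the
planted structure, recovered end to end.

Smaller building blocks are directly usable too:

```r
library(aasupply)
m   <- toy1_model()          # 2 amino acids: A (yield 2), B (yield 1)
mu  <- max_growth(m)         # 6.666667 = 20/3
amino_acid_supply(m, toy_aa_map(m), c(A = 1), beta = 0.3, mu = mu)$supply
#> 14
```

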