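---
title: "Optimum contribution selection with kinship at native alleles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimum contribution selection with kinship at native alleles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nativeocs)
```

## The problem

Local livestock breeds have often been crossed with high-yielding
commercial breeds. The resulting introgression raises measured genetic
diversity while eroding exactly what a conservation program wants to keep:
the breed's own, *native*, gene pool. Classical optimum contribution
selection (OCS) — choosing each candidate's genetic contribution `c_i` to
the next generation so as to maximize genetic gain under a constraint on
mean kinship — is blind to this distinction. Worse, when breeding values
and migrant ancestry are positively correlated (they are, because the
migrant breeds were introduced to lift performance), classical OCS
actively increases the migrant fraction of the genome.

`nativeocs` implements an origin-aware OCS formulation. Every allele in
the pedigree descends from a *founder* (a parentless record), and every
founder is classified native or migrant by a herdbook rule: founders of
the native breed code are native, founders of other breeds are migrant,
and founders of unknown breed are native only if born before a cutoff
year (default 1970). From this classification the package computes, for
every pair of individuals, probabilities about two alleles drawn at a
random locus, one from each individual (with replacement for self-pairs):

* `fA` — the classical kinship: the probability the two alleles are
  identical by descent (IBD);
* `fN` — the probability both alleles descend from native founders;
* `fM` — the probability both descend from migrant founders;
* `Knat` — the probability the alleles are IBD *and* native (IBD copies
  descend from one founder allele, so IBD pairs are never of mixed
  origin);
* `fB = Knat + (1 - fN)` — IBD or at least one migrant allele;
* `fC = Knat + fM` — IBD or both alleles migrant;
* `MC` — each individual's migrant contribution, the expected migrant
  fraction of its genome (founder value 0 or 1, parental average below).

For a contribution vector `c` the offspring generation has mean kinships
`c'fAc`, `c'fBc`, `c'fCc`, mean migrant contribution `c'MC` and mean
breeding value `c'EBV`. The *kinship at native alleles*,

```
fD(c) = 1 - (1 - c'fB c) / (c'fN c)  =  c'Knat c / c'fN c ,
```

is the probability of IBD *conditional* on both alleles being native —
the quantity whose complement is the diversity of native alleles.
Constraining or minimizing `fD` protects the native gene pool itself, not
just the overall pedigree diversity.

## Recursions and their oracles

All four matrices satisfy the tabular half-parent recursion
`f(i,j) = (f(s_i, j) + f(d_i, j)) / 2` over a pedigree sorted parents
first; they differ only in base cases. With `n_i = 1 - MC_i` the expected
native fraction:

| matrix | founder diagonal | founder cross terms | diagonal recursion |
|--------|-----------------|---------------------|--------------------|
| `fA`   | 1/2             | 0                   | `(1 + f(s,d))/2`   |
| `fN`   | `n_i`           | `n_i n_j`           | `(n_i + f(s,d))/2` |
| `fM`   | `m_i`           | `m_i m_j`           | `(m_i + f(s,d))/2` |
| `Knat` | `n_i / 2`       | 0                   | `(n_i + f(s,d))/2` |

The non-zero founder cross terms of `fN` and `fM` reflect that origin,
unlike IBD, is not exclusive to relatives: two unrelated animals can both
carry native alleles. These constructions are validated against two
independent oracles implemented in the package rather than against any
closed-form source: `enumerate_transmissions()` sums over all `2^T`
inheritance patterns of a pedigree with `T` meioses (every probability is
a dyadic rational, represented exactly in doubles), and `gene_drop()`
estimates the same probabilities by Monte-Carlo allele dropping. The test
suite requires exact agreement with enumeration on every fixture within
the 24-meiosis bound and 3-standard-error agreement of gene dropping at
one million replicates on a 50-individual pedigree. Reproducibility of
the gene-drop stream comes from R's seeded Mersenne-Twister
(`withr::with_seed`); a counter-based generator was considered and not
used since a single seeded stream already reproduces bit-identically.

Diagonals use with-replacement sampling, `f(i,i) = (1 + F_i)/2`, on all
four matrices, so that quadratic forms in `c` are offspring-generation
expectations even when an individual is paired with itself by sampling.

## The optimization problems

Contributions satisfy `c >= 0`, each sex sums to 0.5, all female
contributions are forced equal (cows produce few calves), and male
contributions are bounded by 0.5. Optimization is therefore performed
over male contributions only; every quadratic form is expanded into
male-male, male-female and female-female blocks with the fixed female
part absorbed. Scenario names follow a grammar of an objective prefix
(`minfB`, `minfC`, `minfD`, `minMC`, `maxEBV`) and constraint-letter
suffixes (`A`, `B`, `C`, `D`, `MC`, `EBV`), e.g. `maxEBV.A.D.MC`.

The kinship bound comes from a target rate of inbreeding:
`ub.fA = fbar + (1 - fbar) dF` with `dF = 1/(2 Ne)` and `fbar` the mean
candidate kinship (the off-diagonal mean of the candidate `fA` block —
self-kinships are excluded, consistent with descriptive statistics of
kinship *between* candidates). All other bounds are placed a fraction
`lambda` (default 0.3) of the way from their equal-contribution reference
value towards their single-constraint optimum.

The convex scenarios (quadratic PSD objectives and constraints, linear
`MC`/`EBV` bounds) are solved with a log-barrier interior-point method
written for this package: damped Newton steps on the KKT system with the
equality constraint kept explicit, a phase-I stage that minimizes the
maximum constraint violation to find a strictly feasible start or certify
infeasibility, and a geometric barrier schedule down to a duality-gap
tolerance of `1e-8`. Bound feasibility of returned solutions is
re-checked post hoc at `1e-6`, sex sums at `1e-8`. Degenerate bound sets
are reported `infeasible`, never clipped. The `fD` bound is rewritten as
the PSD quadratic `c'fB c + (1 - ub.fD) c'fN c <= 1`, which is convex for
any bound below 1 (an eigenvalue check guards the remaining case).

Minimizing `fD` itself is a ratio of quadratic forms and not convex. It
is solved by Dinkelbach iteration — repeatedly minimizing
`c'Knat c - q c'fN c` and updating `q` to the achieved ratio — with the
concave `-q c'fN c` term linearized around the current iterate
(convex–concave step) so each subproblem is convex, run from several
seeded starts (equal contributions, the classical-kinship minimizer, and
random feasible points). The best fixed point is returned with the honest
status `"local"`; on three-male problems the tests require agreement with
a `1e-3`-resolution simplex grid search.

A sire counts as selected when its contribution reaches `0.00025`, which
absorbs the numerical dust an interior-point method leaves on inactive
coordinates; the reported spread of male contributions includes zeros.

## What the synthetic generator emulates

Since herdbook pedigrees of real breeds are proprietary, the package
ships a generator (`generate_pedigree()`) whose defaults play the role of
the study population. It emulates a small dual-purpose cattle breed:

* 200 native founders born around 1948 (half carrying the herdbook code,
  half relying on the pre-cutoff birth-year rule, so the classification
  path is exercised);
* four discrete 12-year generations; in each, 45% of matings are sired
  by migrant founders drawn from a pool of 40 per wave, producing
  candidate migrant contributions around 0.6–0.7, in the range reported
  for heavily introgressed breeds;
* parents drawn with gamma-distributed usage weights
  (`sire_concentration = 0.1`, `dam_concentration = 2`): a handful of
  popular AI sires dominate each cohort while dam usage is only mildly
  uneven. This is the mechanism that creates real family structure —
  without it, kinship and native-ancestry differences between candidates
  are too homogeneous for contribution optimization to have anything to
  trade;
* a final cohort born 2005–2006 sired by 200 males, which thereby become
  the male selection candidates; 1000 of the 1100 candidate-generation
  females are sampled as dams;
* breeding values `EBV = alpha * MC + noise`, with `alpha` calibrated in
  closed form so the EBV–MC correlation among candidates hits a target of
  0.33 — the positive correlation that makes classical OCS drag migrant
  ancestry upward.

The generator writes breed codes and birth years such that
`classify_origin()` reconstructs the ground-truth founder classification
exactly, which the tests assert. What it does *not* emulate: overlapping
generations, realistic trait architecture or EBV estimation error
structure (EBVs are noisy functions of migrant ancestry only), linkage
(all probabilities are single-locus), and real herdbook quirks such as
recorded-but-wrong parentage. Passing tests on this population therefore
show that the machinery behaves as the theory predicts under a plausible
breeding history — not that any particular real breed would show effects
of the same magnitude.

Problem sizes were chosen so the whole candidate pipeline (about 3,900
pedigree records, 1,200 candidates, 200 male decision variables, a dozen
scenarios) runs in a few minutes on one core.

## Numerical and design choices

* **Phantom founders.** A non-founder with one unknown parent gets a
  phantom founder in that slot, dated `offspring year - G` with `G = 0`
  by default, so the cutoff-year rule classifies the phantom with its
  offspring's cohort; the herdbook classification rule is stated for
  animals, and extending it to missing-parent slots is a package choice.
* **Herdbook purebred status** for candidate eligibility comes from the
  breed code, not from `MC = 0`; herdbook animals routinely carry migrant
  ancestry.
* **EBV normalization** uses the population standard deviation (divisor
  `n`), pooled over both sexes; configurable to `n-1`.
* **Missing-parent sentinels** `""` and `"0"` are both accepted.
* **Ties** in truncation selection are broken by ascending id, making the
  baseline deterministic.
* **`fD` guard.** `fD(c)` is undefined when the offspring generation has
  no native ancestry; the denominator is guarded at `1e-8`.
* **Slack flags** in reports mark a constrained criterion `active` when
  the achieved value is within `1e-5` (ten times the feasibility
  tolerance) of its bound, and `slack` otherwise, separating numerical
  grazing from genuinely non-binding constraints.

## Known limitations

Pedigree-based probabilities are expectations over Mendelian sampling;
genomic (marker-based) kinships and migrant contributions are out of
scope. Only male contributions are optimized — the engine's scenario
grammar has no both-sexes surface. The `fD` scenarios return local optima
by construction; the multi-start heuristic is validated only at toy size.
Mate allocation, multi-generation dynamic optimization and native
effective population size estimation are not implemented.
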