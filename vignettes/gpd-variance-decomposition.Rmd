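---
title: "Conditional moments of V_A under gametic phase disequilibrium: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conditional moments of V_A under gametic phase disequilibrium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpdVA)
```

# The model

The package works with fully homozygous material — inbred or
doubled-haploid (DH) lines — scored 0/2 at biallelic loci (2 = homozygous
for the reference allele). Dominance and epistasis are assumed absent
throughout; this is an explicit modelling assumption, not a simplification
we can relax later, because the quadratic-form algebra below is exact only
for purely additive gene action.

Given a genotype matrix $X$ ($N$ lines $\times$ $L$ QTL) the package
centers with the sample allele frequencies $p_i = \sum_n x_{ni}/(2N)$,
$Z = X - 2\,\mathbf{1}p$, and forms the genotypic covariance matrix
$D = Z^\top Z / N$ with divisor $N$, not $N - 1$. The divisor matters: with
$N$ the diagonal is exactly $d_{ii} = 4p_i(1-p_i)$ and the conditional
expectation of the additive variance is exactly $\mathrm{trace}(D)$; with
$N-1$ every identity below would carry a nuisance factor.

$D$ is partitioned entrywise into its diagonal $V$, the within-chromosome
off-diagonal part $W$ and the between-chromosome part $B$. Off-diagonal
entries $d_{ij} = 4(f_{ij} - p_i p_j)$ are four times the gametic phase
disequilibrium (GPD) between loci $i$ and $j$ ($f_{ij}$ the gamete
frequency — for homozygous lines, lines are their own gametes). $W$ and $B$
are kept as full symmetric matrices, so any sum "over pairs" counts
$(i,j)$ and $(j,i)$ separately and the quadratic form $a^\top W a$ carries
the conventional factor 2 of the covariance component without special
casing.

For a trait with QTL substitution effects $a$ the realized components are
$V_A = a^\top D a$, $V_g = a^\top V a$, $C_w = a^\top W a$,
$C_b = a^\top B a$, summing exactly. Treating $a \sim N(0, I)$ as random
across traits, these are Gaussian quadratic forms, and the standard
identities $E[a^\top M a] = \mathrm{trace}(M)$,
$\mathrm{var}[a^\top M a] = 2\,\mathrm{trace}(M^2)$ and
$\mathrm{cov}(a^\top M_1 a, a^\top M_2 a) = 2\,\mathrm{trace}(M_1 M_2)$
give everything `conditionalMoments()` reports. Two structural facts make
the decomposition clean: $W$ and $B$ have zero diagonals, so
$E[C_w|X] = E[C_b|X] = 0$ exactly; and
$\mathrm{trace}(VW) = \mathrm{trace}(VB) = \mathrm{trace}(WB) = 0$ in this
partition ($V$ diagonal against zero-diagonal matrices; $W$ and $B$ have
disjoint supports), so the component variances add exactly:
$\mathrm{var}[V_A|X] = \mathrm{var}[V_g|X] + \mathrm{var}[C_w|X] +
\mathrm{var}[C_b|X]$.

## Standardized ratios and their bound

The ratios $b_w = C_w/V_g$, $b_b = C_b/V_g$, $b = b_w + b_b$ allow
comparison across scenarios with different $L$ and allele-frequency
spectra. Their moments are first-order (delta-method) approximations —
$E \approx 0$, $\mathrm{var}[b_w|X] \approx 2\,\mathrm{trace}(W^2)/
\mathrm{trace}(V)^2$, etc. — and are documented and tested as
approximations only; the Monte-Carlo path (`monteCarloMoments()`) is the
reference for their quality. The first-order bias of $E[b_w|X]$ vanishes
because $\mathrm{cov}(C_w, V_g) = 2\,\mathrm{trace}(WV) = 0$.

Because $D \succeq 0$, the ratio $b$ is bounded below by $-1$.
`bLowerBound()` computes the exact minimum of
$a^\top(W+B)a / a^\top V a$ as the smallest eigenvalue of
$V^{-1/2}(D - V)V^{-1/2}$ restricted to the polymorphic loci
($d_{ii} > 0$); monomorphic loci are retained in all matrices as zero
rows/columns (stable indexing across generations) but excluded from this
subspace. Equality $b_{\min} = -1$ holds iff $D$ is singular there. A
floating-point guard clips eigenvalues within $10^{-9}$ below $-1$ back to
$-1$. Note the bound constrains $b$ and $b_w$, not $b_b$: when $b_w > 1$,
individual draws can realize $b_b < -1$ (the test suite constructs a
three-coupled-loci/one-repulsed-locus fixture where this happens).

When all sampled QTL are monomorphic ($\mathrm{trace}(V) = 0$) the ratios
are undefined; `realizedComponents()` and `conditionalMoments()` return
flagged `NA`s rather than raising, so scenario aggregation can skip and
count them — relevant for small parent numbers, where a QTL sample can be
entirely fixed.

# The breeding simulator

`meiosis()` generates gametes chromosome-by-chromosome as a Markov walk
over the ordered loci: the walk starts on a random parental haplotype and
switches between adjacent loci at map distance $d$ cM with the Haldane
probability $r = \tfrac12(1 - e^{-2d/100})$. With no crossover
interference this per-interval chain is *exactly* equivalent to sampling a
Poisson crossover process and thresholding — no explicit crossover-count
layer is needed — and it composes correctly over skipped loci
($r_{13} = r_{12} + r_{23} - 2r_{12}r_{23}$, verified by simulation
against the closed form). Chromosome-first loci switch with probability
$\tfrac12$, which both randomizes the starting haplotype and makes
chromosomes assort independently. Genetic positions are continuous cM
floats; there are no physical coordinates anywhere.

The mating designs follow the standard combinatorics: disjoint crosses
(DC, $P/2$ crosses from a random ordering, each parent used once),
factorial (FC, random split into two halves, all $(P/2)^2$ crosses), and
half-diallel (HC, all $P(P-1)/2$ unordered pairs, no selfs). $P = 2$
degenerates to the single biparental cross under every design. Generation
G1 samples each progeny's cross uniformly *with replacement* — interpreted
as uniform-over-crosses per progeny rather than a pre-generated progeny
pool, which matches the expected equal cross sizes and the $P = 2$ case of
$N$ genetically identical F1s. Random mating draws, independently per
offspring, an unordered pair of distinct parents (monoecious without
selfing); whether parents are drawn with or without replacement *across*
the $N$ matings is not fixed by the biology, and the
independent-per-offspring choice is the documented one. DH derivation
takes exactly one gamete per individual. Parents are sampled from the
founder panel without replacement (with replacement would permit selfs in
a half-diallel).

# The synthetic founder generator

`synthAncestral()` emulates the *statistical* structure of real maize
panels, nothing marker-specific: panel size (default 115 lines), 10
chromosomes totalling 1442 cM (maize-like decreasing length profile), a
uniform allele-frequency spectrum on $[0.02, 0.98]$ with a configurable
monomorphic-in-panel fraction, and a target LD decay distance (distance at
which binned mean $r^2$ first falls below 0.1). Two presets encode
realistic panels: `"elite"` (monomorphic fraction 0.049, decay 22.2 cM)
and `"landrace"` (0.163, 21.3 cM).

Mechanically, a pool of `poolSize` (default 24) founder haplotypes gets
distance-decaying allelic association from a latent AR(1) Gaussian copula
(correlation $e^{-d/\rho}$ between adjacent loci) thresholded at
$\Phi^{-1}(q_i)$, so marginal frequencies follow the spectrum while
association decays along the chromosome. Pool columns that come out fixed
despite a polymorphic target frequency have one haplotype flipped — a
minimal distortion concentrated at frequency $1/\text{poolSize}$. Each
line is then a recombinant mosaic of pool haplotypes with exponential
segment lengths (mean `segmentLength`, default twice the target decay).
The copula scale $\rho$ is calibrated by bisection: rather than bisecting
the noisy, stepwise decay-distance statistic itself, the calibration
targets mean $r^2 = 0.1$ in a $\pm 3$ cM window around the target
distance, evaluated under common random numbers — a much smoother function
of $\rho$ with the same crossing point. Realized decay distances scatter
roughly $\pm 3$ cM around the target across seeds; this realization noise
is intrinsic to a 115-line panel, not a calibration error. This
mosaic-of-haplotypes generator was chosen over a coalescent simulation for
determinism and zero external dependencies.

What the generator does *not* emulate: ascertainment of real SNP chips,
population substructure between heterotic groups, selection footprints,
and the empirical site-frequency spectrum of any particular landrace.
Passing tests therefore demonstrate the analytic identities and the
design-driven behaviour of GPD on realistic-scale genomes — they do not
certify numbers conditioned on any real panel.

QTL positions are apportioned to chromosomes proportionally to genetic
length with largest-remainder rounding and sampled uniformly without
replacement within chromosomes (`sampleQtl()`). LD is summarized by
$r^2_{ij} = d_{ij}^2/(d_{ii}d_{jj})$ over within-chromosome pairs of
polymorphic loci — on homozygous lines this equals haplotype $r^2$ — and
the decay distance uses 1 cM bins by default; the binning rule before
thresholding is a package choice (no interpolation), as is returning the
bin midpoint and `Inf` ("beyond map") when the threshold is never
crossed.

# Scenario aggregation and the decay regression

`runScenario()` follows the replication structure of a designed
simulation study: each replication samples parents, simulates
G1..G$k$/G1-DH..G$k$-DH, then draws several QTL-position sets from the
candidate pool (fresh per replication); conditional moments are computed
for every realized QTL genotype matrix and averaged. Standard errors are
reported *across replications* (QTL sets within a replication share a
population and are not independent). Undefined-ratio realizations are
excluded from ratio averages and counted in the output. Full study scale
is 500 replications × 50 QTL sets; the package default (50 × 10) is the
desk-scale profile used by the test suite, where the between-design
contrasts run at L = 250 QTL, N = 250 and P ∈ {4, 8, 16} on panels with
600–1000 candidate loci, and the decay analysis at N ∈ {50, 1000} over
four DH generations.

Per-replication seeds are derived as `seed + replication`, so scenario
runs sharing a master seed draw *identical parent samples* per
replication across mating designs. Between-design comparisons are thereby
paired (common random numbers), which removes the dominant noise source —
which parents were drawn — from contrasts that the designs cannot affect,
such as $E[V_A]$.

For the decay of the between-chromosome component: one generation of
random mating halves $d_{ij}$ of unlinked pairs (large $N$), hence
quarters $\mathrm{var}[b_b|X]$. With finite $N$, sampling regenerates GPD
each generation; the recursion $v_0 = \theta + \omega$,
$v_{r+1} = v_r/4 + \omega$ has closed form
$v_r = \theta/4^r + \omega\,(4 - 4^{-r})/3$ with steady state
$\tfrac43\omega$. The model is linear in $(\theta, \omega)$, so
`decayCurve()` fits exact least squares (`lm`); a negative unbounded
$\hat\omega$ — possible by noise, physically meaningless — is flagged and
a `port`-algorithm `nls` refit constrained to $\omega \ge 0$ is reported,
with the unbounded estimates kept as a diagnostic. G1-DH is $r = 0$.

# Numerical and testing choices

* Monte-Carlo draws default to 10,000 effect vectors; empirical variances
  are compared with $2\,\mathrm{trace}(M^2)$ within 4 standard errors of a
  variance estimate, $\mathrm{SE} = \sqrt{(m_4 - s^4)/n}$.
* Skewness and kurtosis are the standardized third/fourth central moments
  without small-sample bias correction (shape is reported qualitatively).
* Recombination fractions are verified against exact two-sided binomial
  intervals, not normal approximations.
* When successive DH panels are compared to measure the GPD halving, the
  regression denominator subtracts the known sampling variance of
  $\hat d_{ij}$ ($\approx (d_{ii}d_{jj} + d_{ij}^2)/N$) — an
  errors-in-variables correction without which the estimated ratio is
  attenuated by a few tenths of a percent, visible at $N = 20{,}000$.
* Eigen decompositions use the symmetric solver; positive
  semidefiniteness of $D$ is asserted in tests with tolerance
  $10^{-8}\,\mathrm{trace}(D)$.
* All randomness flows through R's global RNG; every exported stochastic
  function accepts a `seed` argument and identical seeds reproduce results
  bit-for-bit.

# Known limitations

* Homozygous material only — no heterozygous genotypic scores, hence no
  Hardy–Weinberg machinery; heterozygous VCF calls are an error by design.
* Additive gene action only; no dominance, epistasis, or selection between
  generations.
* The ratio moments are first-order approximations that degrade when
  $\mathrm{var}[V_g|X]$ is large relative to $E[V_g|X]^2$ (few, or
  low-frequency, QTL).
* The founder generator matches summary structure, not real haplotypes;
  conclusions about any *specific* germplasm require that germplasm's
  genotypes, which can be supplied via `readGenotypeVCF()` /
  `readGenotypeMatrix()`.
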