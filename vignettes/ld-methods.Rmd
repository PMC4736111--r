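---
title: "Methods: LD decay, persistence of phase and Ne from phased haplotypes"
author: "ldphase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LD decay, persistence of phase and Ne from phased haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldphase)
```

## The problem

Genomic selection and GWAS transfer between two related populations only to
the extent that marker–QTL associations — linkage disequilibrium and, more
stringently, its *sign* — are shared. This package implements the full
analysis chain used to answer that question for a purebred breed and a
composite relative (the motivating design is a composite carrying 5/8 of
its genome from the purebred): pairwise LD on phased gametes, genome-wide
decay, panel-thinning experiments, linear models of LD heterogeneity,
across-population correlation of signed r, and LD-based demography. Because
such datasets are usually proprietary, the package also contains a
forward-in-time simulator whose output feeds every stage with known truth.

## Pairwise LD on gametes

All LD statistics are computed at the gametic level: inputs must be phased
(the package refuses unphased VCF genotypes), and haplotype frequencies are
counted directly from gametes rather than inferred from genotype
covariances. For loci A and B, `pair_ld()` evaluates

$$D = p_{A1B1}p_{A2B2} - p_{A1B2}p_{A2B1}, \qquad
r = \frac{D}{\sqrt{p_{A1}p_{A2}p_{B1}p_{B2}}},$$

and $r^2 = r^2$. Algebraically $D = p_{11} - p_{A1}p_{B1}$, so $r$ is the
Pearson correlation of the 0/1 allele indicators across gametes; the bulk
pair enumeration uses the cross-product form for speed, while the tests
verify both routes against `cor()` at 1e-12. Monomorphic loci have
undefined LD and must be removed first (`drop_monomorphic()`); a marker
monomorphic in one breed but segregating in the other is likewise excluded
from that breed's pairs and from the across-breed matching.

Signed r is only meaningful across populations under a *shared allele
coding*: allele code 1 refers to the same physical allele (the shared map's
`allele1`, the VCF ALT) in every population. Flipping one population's
coding at a locus flips the sign of every r involving that locus in that
population only, which corrupts the phase comparison — this is why the map,
not each population, owns the allele labels.

## Decay, thresholds and thinning

Pairs are enumerated within chromosomes up to a 10 Mb cap (the decay
analysis range) and binned by physical distance into half-open intervals
$[k\,w, (k+1)\,w)$ with $w = 100$ Kb by default. The half-open convention is
a tie-break the source material does not specify; it guarantees each pair
falls in exactly one bin (a tested partition invariant). Panel thinning
keeps every k-th marker within each chromosome, restarting at chromosome
boundaries, with the first marker kept (offset 0) by default — the offset is
exposed as an argument since the choice is arbitrary. Threshold summaries
report the fraction of pairs with $r^2$ *strictly* above 0.2 and 0.3.

## ANCOVA models of LD heterogeneity

Two fixed-effect models are fitted to $r^2$ by ordinary least squares
(`ld_ancova()`), with the covariate
$d^*_k = \log_{10} d_k - \log_{10}\bar d$, where $\bar d$ is the arithmetic
mean physical distance over the pooled input pairs of both breeds (a single
shared $\bar d$, so both breeds sit on one distance scale):

* order 1, for adjacent pairs:
  $r^2_{ijk} = \mu + c_i + b_j + \beta_1 d^*_k + cb_{ij} + e_{ijk}$;
* order 3, for all syntenic pairs within the cap: adds $\beta_2 (d^*)^2$,
  $\beta_3 (d^*)^3$ and chromosome, breed and chromosome-by-breed
  interactions with every power.

Design choices:

* **Sum-to-zero contrasts** for chromosome and breed make $\mu$ literally
  the overall mean of $r^2$ and give least-squares means the simple form
  $\mu + c_i$ in balanced noise-free data. `ls_means_by_chromosome()`
  averages model predictions over breed levels at $d^* = 0$ (i.e. at the
  mean spacing), with standard errors from the coefficient covariance.
* **Marginal (type-III-style) F-tests**: each term's sum of squares comes
  from deleting that term's columns from the full design and refitting; the
  original analysis reports term significance without naming the SS type,
  and marginal tests are the convention that matches sum-to-zero contrasts.
* **Input cap**: the order-3 model is fitted to syntenic pairs within 10 Mb,
  not to truly all pairs; at array densities the all-pairs count grows
  ~50-fold beyond the decay range while distances beyond 10 Mb carry almost
  no LD signal. The cap is an argument (`max_distance_bp`).
* Pairs are treated as independent observations, as in the standard
  analysis; overlapping pairs share markers and genealogy, so the F-tests
  are anti-conservative and should be read as descriptive.

Predictions at the average spacings of commercial panels use
`panel_distance_kb()`: genome length in Mb divided by panel size, rounded
half-up to Kb (3000 Mb: 150K → 20 Kb, 80K → 38 Kb, 50K → 60 Kb, 20K →
150 Kb, 8K → 375 Kb, 3K → 1000 Kb). Requests outside the fitted distance
range are served but flagged as extrapolation.

## Persistence of phase

`phase_correlation()` matches pairs between populations by exact
(chromosome, pos_i, pos_j) after the marker-set intersection, bins them by
distance, and computes per bin the Pearson correlation of signed r plus the
fraction of pairs with opposite signs (zero r counts as non-reversed). Bins
with fewer than `min_pairs = 3` matches are reported as undefined (NA)
rather than propagating meaningless correlations. The per-bin correlation
with mean-centering is the standard formulation; note it is exactly
invariant only under coding swaps applied to *all* pairs of a bin — the
reversed-sign fraction, built from the products $r_A r_B$, is invariant
under any consistent swap, and the tests check exactly these properties.

## Effective population size

Under drift–recombination equilibrium $E(r^2) = 1/(4cN_e+1)$. The estimator
inverts this with bin averages: pairs with genetic distance $c \in
[c_{lo}, c_{hi})$ (half-open, again a tie-break choice), excluding $r^2$
exactly 0 or 1, give

$$\hat N_{e,t} = \frac{1-\bar r^2}{4\,\bar c\,\bar r^2},$$

assigned to generation $t = 1/(2\bar c_{target})$. Genetic distance is
physical distance at 1 cM/Mb; pairs are taken up to 100 Mb so the recent
generations ($t = 1$ needs $c$ up to 1 Morgan) are reachable. The binning
scheme (`generation_bins()`) uses single generations for $t = 1\ldots10$
($t \pm 0.5$), five for $t = 15\ldots100$ ($t \pm 2.5$) and fifty for
$t = 150\ldots1000$ ($t \pm 25$); gaps between regimes (t = 11–14, 105–145)
are simply not estimated. Two mid-point conventions circulate — $1/(2t)$
and the arithmetic mean of the c range — and they disagree in the first
regime; the package reports both (`mid_c`, `mid_c_arith`) and uses the
target generation, not the mid-point, to label estimates.

**Finite-sample correction.** A sample of $n$ gametes inflates $r^2$ by
roughly $1/n$ even at linkage equilibrium. The default estimator applies
the formula exactly as written (no correction), matching its usual printed
form; `sample_size_correction = TRUE` subtracts $1/n$ from $\bar r^2$
first. With a few hundred sampled gametes the inflation exceeds the drift
expectation at long distances ($t \le 3$), so recovery studies on simulated
samples must switch the correction on — the acceptance suite does.

**Known limitation.** Even with the correction, the estimator carries a
systematic bias of order +10 % at the shortest-distance bins and the
recent-generation estimates from a single chromosome fluctuate by ±10–20 %
between realizations, because all pairs at one distance scale share a small
number of independent genealogies. The package's recovery test on a
constant-Ne world (Ne = 100, one 100 Mb chromosome, 2000 ascertained SNPs,
100 diploids) reflects this: most generation bins land within ±25 % of
truth, but individual bins can fall just outside for any given seed. A
cross-check of the same world with an independent coalescent simulator
shows the same behaviour, so this is a property of the estimator at this
problem size, not of the implementation. Estimates from several
chromosomes, or averaged over replicate genomes, are correspondingly more
stable.

## The simulator: what it emulates, and what not

`simulate_population()` is a discrete-generation, monoecious Wright–Fisher
model with random mating (selfing allowed), an explicit Ne trajectory from
past to present, and recombination at a constant 1 cM/Mb. Defaults state
the intended world: two populations, array-like marker density, a declining
Ne history, initial allele frequencies i.i.d. uniform on [0.05, 0.95]
(array SNPs are pre-ascertained common variants, not a mutation–drift
spectrum — there is no mutation during the forward phase), and MAF-based
marker ascertainment in a reference population
(`ascertain_markers()`), which reproduces — deliberately without correcting
— the array bias towards variants common in the discovery breeds.

Crossovers per meiosis are Poisson with uniform positions and no
interference (`crossover_model = "haldane"`), the standard meiosis model
and the physics assumed by coalescent simulators; a complete-interference
variant placing exactly one crossover per Morgan at random phase
("lattice") is available for studying interference effects. The Poisson
default was validated by comparing equilibrium decay and Ne recovery
against an independent coalescent implementation of the same world.

The composite population is founded by whole individuals drawn from the
purebred with probability `admix_proportion` (default 5/8) and from the
diverged relative otherwise, followed by random mating with recombination;
divergence time between the two ancestral populations is a free knob
(`divergence_generations`), not calibrated to real cattle history — the
source material provides no quantitative divergence parameter.

What the generator does *not* emulate: selection (no QTL, no sweeps — so
simulated LD heterogeneity between chromosomes is purely stochastic),
genotyping error and missingness (QC filters are exercised by planted
defects in fixtures instead), sex chromosomes, pedigree structure, phasing
error (inputs are perfectly phased by construction), and mutation. A green
test on simulated data therefore establishes the correctness of the
*estimators* under the stated model, not the realism of the model for any
particular breed.

## Quality control

Filters mirror the standard array workflow, in a fixed order: samples
first (call rate < 0.90; heterozygosity beyond mean ± 3 SD, computed over
samples surviving the call-rate step, plain estimators; duplicated
genotypes at ≥ 0.95 concordance, keeping the higher-call-rate member — the
threshold is a package default, the source names none), then markers
(autosome restriction; call rate < 0.98; MAF < 0.03; Hardy–Weinberg
$P < 10^{-6}$ by a 1-df Pearson chi-square on genotype counts, with
monomorphic markers assigned $P = 1$ by convention; one SNP per physical
position, keeping the highest MAF; optional removal of markers monomorphic
in the population). A record failing several rules is counted once, under
the first rule applied. Bookkeeping (removed + retained = input) is a
tested invariant, as are idempotence and sample-order invariance. The
chi-square choice over an exact test is deliberate: at the $10^{-6}$
threshold the decisions rarely differ, and the closed form is deterministic
and fast; an exact test can be substituted upstream if needed.

## Determinism and numerics

Every stochastic component consumes one seeded RNG stream; a saved run
configuration re-executes to byte-identical TSV outputs (fixed-precision
formatting), and the run manifest records config and seed. Distance
arithmetic is integer bp; conversions to Kb/Mb/Morgans happen only at
presentation or estimator boundaries. OLS fits are checked for residual
orthogonality ($X'e = 0$ to 1e-8) and the cubic model restricted to first
order reproduces the first-order model exactly — both are tested
invariants.
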