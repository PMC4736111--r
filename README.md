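# ldphase

Linkage-disequilibrium analysis of phased SNP-array data for related
livestock populations: genome-wide LD decay, marker-panel thinning, ANCOVA
models of LD heterogeneity across chromosomes and breeds, across-population
persistence of linkage phase, and historical effective population size —
plus a forward Wright–Fisher simulator that provides ground truth for all of
it.

The package is aimed at animal-breeding and population-genetics researchers
who work with phased genotypes from two related populations (the motivating
setting is a purebred taurine breed and a composite breed carrying 5/8 of
its genome from the purebred) and want to quantify how far marker–QTL
associations transfer between them, and what the LD landscape implies about
past demography and the marker density needed for genomic selection.

## What it computes

**Pairwise LD from gametes.** For two biallelic loci A and B with allele
frequencies p_A1, p_A2, p_B1, p_B2 and haplotype frequencies p_A1B1 etc.
counted directly on phased gametes,

    D  = p_A1B1 · p_A2B2 − p_A1B2 · p_A2B1
    r  = D / sqrt(p_A1 p_A2 p_B1 p_B2),       r² = r²

(`pair_ld()`, bulk versions `syntenic_pairs()` / `adjacent_pairs()`). r²
equals the squared Pearson correlation of the 0/1 allele indicators across
gametes — the test suite holds the two routes to ≤ 1e−12 of each other.

**Decay, thresholds, thinning.** `bin_by_distance()` summarises r² in
half-open 100 Kb bins up to 10 Mb; `thinning_experiment()` re-derives
adjacent-pair LD after keeping every k-th marker (50 %, 25 %, … 7 % panel
density); `proportion_above()` reports the fraction of pairs with r² above
0.2 / 0.3.

**ANCOVA of LD heterogeneity.** `ld_ancova()` fits, by OLS with sum-to-zero
contrasts,

    r²_ijk = μ + c_i + b_j + β1·d*_k + cb_ij + e_ijk            (order 1)

on adjacent pairs, and an order-3 version with quadratic and cubic powers of
d* and all chromosome/breed interactions on all syntenic pairs, where
d*_k = log10(d_k) − log10(d̄) is the adjusted log distance. Methods:
`summary()` (marginal F-tests), `ls_means_by_chromosome()`, and `predict()`
at the average inter-marker spacings of commercial panels
(`panel_distance_kb()`: 150K → 20 Kb, 80K → 38 Kb, …, 3K → 1000 Kb on a
3000 Mb genome).

**Persistence of phase.** `phase_correlation()` bins marker pairs shared by
the two populations and computes per bin the Pearson correlation R of the
signed r values, together with the fraction of pairs whose r signs disagree.
A shared allele coding across populations (enforced by the common map) is
what makes signed r comparable.

**Effective population size.** From E(r²) = 1/(4cNe + 1), each past
generation t is probed by pairs at genetic distance c = 1/(2t) (1 Mb = 1 cM),
binned per the three-regime scheme of `generation_bins()` (single
generations for t = 1–10, five for 15–100, fifty for 150–1000), and

    Ne_t = (1 − r̄²) / (4 c̄ r̄²)

(`ne_trajectory()`; optional finite-sample correction subtracts
1/n_haplotypes from r̄²).

**Simulator.** `simulate_population()` (discrete Wright–Fisher, Poisson
crossovers at 1 cM/Mb, configurable Ne trajectory), `make_composite()`
(admixture, default 5/8), `ascertain_markers()` (array-style MAF
ascertainment), and `evolve_population()` (divergence experiments).

Standard array QC (`sample_qc()`, `marker_qc()`: call rate, heterozygosity,
duplicates, MAF, Hardy–Weinberg, duplicate positions) and phased-VCF /
plain-text I/O round out the pipeline; `run_full_analysis()` orchestrates
everything and writes deterministic TSV tables.

## Worked example

```r
library(ldphase)
cfg <- run_config(
  sim = sim_config(ne_trajectory = data.frame(generations = c(60, 40),
                                              ne = c(120, 60)),
                   n_sample_individuals = 40, chrom_lengths_bp = c(3e7, 3e7),
                   n_snps_per_chrom = 300, seed = 11),
  divergence_generations = 30, admix_generations = 8, seed = 11)
run <- run_full_analysis(cfg)
print(run)
#> LD analysis run: 2 population(s): H, B
#>  population n_pairs mean_r2  sd_r2 mean_dist_bp pct_r2_gt_0.2 pct_r2_gt_0.3
#>           H     308  0.5290 0.3845       191191         69.81         62.66
#>           B     293  0.5441 0.3895       200979         71.33         62.46
```

Adjacent-pair LD is high because the simulated panel is sparse (~100 Kb
spacing) and the populations small. Phase persistence between the purebred
H and its 5/8 composite B is strong at short range and decays with distance:

```r
head(run$phase_bins[, c("bin_lo_bp", "n_pairs", "R_AB", "reversed_fraction")], 3)
#>   bin_lo_bp n_pairs  R_AB reversed_fraction
#> 1     0e+00     134 0.967            0.0299
#> 2     1e+05     149 0.979            0.0134
#> 3     2e+05     143 0.959            0.0420
```

The LD-based demography recovers the simulated recent size (true final
Ne = 60):

```r
head(subset(as.data.frame(run$ne$H), !is.na(ne)), 3)
#>  t_target n_pairs mean_r2  mean_c    ne
#>         2    2820 0.01772 0.23450 59.11
#>         3    3939 0.02465 0.16936 58.40
#>         4    2894 0.04660 0.12645 40.45
```

(t = 1 needs pairs beyond 33 cM, farther than this toy 30 Mb chromosome
reaches, so its bin is empty and flagged unavailable.)

and predicted r² at commercial-panel spacings falls off with sparser panels:

```r
subset(run$panel_predictions, chrom == "1" & breed == "H",
       c(panel_size, distance_bp, r2_pred))
#>    panel_size distance_bp r2_pred
#> 3      150000       20000   0.686
#> 7       80000       38000   0.669
#> 11      50000       60000   0.643
#> 15      20000      150000   0.565
#> 19       8000      375000   0.459
#> 23      3000      1000000   0.329
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's full pipeline from scratch on a
simulated two-population dataset seeded from the command line and writes a
JSON summary:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The per-stage TSV tables land next to the JSON under `results/tables/`.
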