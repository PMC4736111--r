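# Small programmatic fixtures shared across test files.

# A tiny deterministic haplotype set: n_gametes x n_markers random 0/1 with
# monomorphic columns re-rolled, positions evenly spaced on one chromosome.
random_hapset <- function(n_gametes = 20, n_markers = 10, chrom = "1",
                          spacing_bp = 1e5, seed = 1) {
  set.seed(seed)
  H <- matrix(rbinom(n_gametes * n_markers, 1, runif(n_markers, 0.2, 0.8)),
              nrow = n_gametes, byrow = TRUE)
  for (j in seq_len(n_markers)) {
    while (length(unique(H[, j])) < 2) H[, j] <- rbinom(n_gametes, 1, 0.5)
  }
  map <- marker_map(sprintf("m%03d", seq_len(n_markers)),
                    rep(chrom, n_markers),
                    seq(spacing_bp, by = spacing_bp, length.out = n_markers))
  haplotype_set(H, map, population = "test")
}

# Haplotype set with explicit matrix and positions (possibly multi-chrom).
hapset_from <- function(H, pos, chrom = rep("1", length(pos)), pop = "test") {
  map <- marker_map(sprintf("m%03d", seq_along(pos)), chrom, pos)
  haplotype_set(H, map, population = pop)
}

# Genotype set from a matrix (rows = individuals).
genoset_from <- function(G, pos = seq(1e5, by = 1e5, length.out = ncol(G)),
                         chrom = rep("1", ncol(G))) {
  map <- marker_map(sprintf("m%03d", seq_len(ncol(G))), chrom, pos)
  genotype_set(G, map)
}

# Per-chromosome marker counts laid out like a post-QC bovine 50K panel
# (29 autosomes, ~41.2K SNPs): used for count arithmetic on realistic shapes.
panel_50k_counts <- c(2697, 2197, 2000, 1987, 1732, 2066, 1824, 1958, 1670,
                      1760, 1805, 1342, 1449, 1471, 1374, 1314, 1249, 1036,
                      1058, 1264, 1124, 1021, 838, 1014, 753, 867, 763, 747,
                      827)

# Small constant-Ne simulated population reused by several slow-ish tests;
# computed once per test run.
shared_sim_env <- new.env()
shared_constant_sim <- function() {
  if (is.null(shared_sim_env$pop)) {
    cfg <- sim_config(ne_trajectory = data.frame(generations = 120, ne = 60),
                      n_sample_individuals = 40,
                      chrom_lengths_bp = c(2e7, 2e7),
                      n_snps_per_chrom = 250, seed = 42,
                      crossover_model = "haldane")
    shared_sim_env$pop <- simulate_population(cfg)
  }
  shared_sim_env$pop
}
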