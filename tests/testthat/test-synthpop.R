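test_that("simulation is reproducible bit-exactly and shaped correctly", {
  cfg <- sim_config(ne_trajectory = data.frame(generations = 10, ne = 50),
                    n_sample_individuals = 50, chrom_lengths_bp = 3e7,
                    n_snps_per_chrom = 200, seed = 5)
  h1 <- simulate_population(cfg)
  h2 <- simulate_population(cfg)
  expect_identical(dim(h1), c(100L, 200L))
  expect_identical(h1$haplotypes, h2$haplotypes)
  expect_identical(h1$map, h2$map)
  # a different seed changes the data
  cfg2 <- cfg; cfg2$seed <- 6L
  expect_false(identical(simulate_population(cfg2)$haplotypes, h1$haplotypes))
  expect_error(sim_config(ne_trajectory = data.frame(generations = 5, ne = 1)),
               ">= 2")
  expect_error(sim_config(n_snps_per_chrom = 0), "zero markers")
})

test_that("without recombination every gamete is a founder haplotype", {
  cfg <- sim_config(ne_trajectory = data.frame(generations = 15, ne = 2),
                    n_sample_individuals = 2, chrom_lengths_bp = 1e7,
                    n_snps_per_chrom = 60, recomb_rate_cm_per_mb = 0,
                    seed = 8)
  h <- simulate_population(cfg)
  # reconstruct the founder pool: same seed, zero generations of drift
  cfg0 <- cfg; cfg0$ne_trajectory <- data.frame(generations = 1, ne = 2)
  set.seed(cfg$seed)
  pos <- sort(sample.int(1e7, 60))
  p0 <- runif(60, 0.05, 0.95)
  founders <- matrix(rbinom(4 * 60, 1, rep(p0, each = 4)), nrow = 4)
  founder_str <- apply(founders, 1, paste, collapse = "")
  got <- apply(h$haplotypes, 1, paste, collapse = "")
  expect_true(all(got %in% founder_str))
})

test_that("distant loci in a large population are effectively independent", {
  # 50 cM apart at Ne = 500: expected r2 ~ 1/(4*0.5*500+1), i.e. at the
  # noise floor of 1/n_haplotypes; compare against a permutation oracle
  cfg <- sim_config(ne_trajectory = data.frame(generations = 60, ne = 500),
                    n_sample_individuals = 100, chrom_lengths_bp = 5e7,
                    n_snps_per_chrom = 40, seed = 13)
  h <- drop_monomorphic(simulate_population(cfg))
  pos <- h$map$pos_bp
  far <- which(outer(pos, pos, function(a, b) b - a) >= 4.5e7, arr.ind = TRUE)
  skip_if(nrow(far) < 3)
  obs <- vapply(seq_len(nrow(far)), function(k)
    pair_ld(h$haplotypes[, far[k, 1]], h$haplotypes[, far[k, 2]])$r2,
    numeric(1))
  set.seed(99)
  perm <- replicate(200, {
    k <- sample(nrow(far), 1)
    a <- h$haplotypes[, far[k, 1]]
    b <- sample(h$haplotypes[, far[k, 2]])
    if (length(unique(a)) < 2 || length(unique(b)) < 2) NA_real_
    else pair_ld(a, b)$r2
  })
  # observed mean r2 within a few noise floors of the permutation baseline
  expect_lt(abs(mean(obs) - mean(perm, na.rm = TRUE)),
            4 / n_haplotypes(h))
})

test_that("composite founder sampling follows the admixture proportion", {
  cfg <- sim_config(ne_trajectory = data.frame(generations = 5, ne = 60),
                    n_sample_individuals = 60, chrom_lengths_bp = 1e7,
                    n_snps_per_chrom = 80, seed = 21)
  popA <- simulate_population(cfg, population = "A")
  popB <- evolve_population(popA, n_generations = 20, ne = 60, seed = 22,
                            population = "B")
  # diagnostic marker: fixed 1 in A, fixed 0 in B
  HA <- popA$haplotypes; HA[, 1] <- 1L
  HB <- popB$haplotypes; HB[, 1] <- 0L
  popA <- haplotype_set(HA, popA$map, popA$sample_ids, "A")
  popB <- haplotype_set(HB, popB$map, popB$sample_ids, "B")

  # admix_proportion = 1 -> pure A
  compA <- make_composite(popA, popB, admix_proportion = 1,
                          n_generations_since_admixture = 0L, seed = 1)
  expect_equal(mean(compA$haplotypes[, 1]), 1)

  # admix_proportion = 5/8 -> diagnostic frequency ~ 0.625 (binomial oracle);
  # average over replicates, each drawing 60 founders
  freqs <- vapply(1:12, function(s) {
    cmp <- make_composite(popA, popB, admix_proportion = 0.625,
                          n_generations_since_admixture = 2L, seed = s)
    mean(cmp$haplotypes[, 1])
  }, numeric(1))
  se <- sqrt(0.625 * 0.375 / (60 * length(freqs)))
  expect_lt(abs(mean(freqs) - 0.625), 5 * se)

  # determinism and map check
  c1 <- make_composite(popA, popB, seed = 7)
  c2 <- make_composite(popA, popB, seed = 7)
  expect_identical(c1$haplotypes, c2$haplotypes)
  popC <- subset_markers(popB, 1:40)
  expect_error(make_composite(popA, popC), "identical marker map")
})

test_that("ascertainment filters by reference-population MAF", {
  h <- random_hapset(n_gametes = 40, n_markers = 30, seed = 3)
  expect_identical(ascertain_markers(h, 0)$map, h$map)
  H <- h$haplotypes
  H[, 5] <- c(1L, rep(0L, 39))      # MAF 0.025
  h2 <- haplotype_set(H, h$map, h$sample_ids, "test")
  kept <- ascertain_markers(h2, 0.03)
  expect_false("m005" %in% kept$map$snp_id)
  # allele coding untouched: retained columns identical
  expect_identical(kept$haplotypes,
                   h2$haplotypes[, maf(h2) >= 0.03])
})

test_that("ascertaining on one population lowers the other's MAF spectrum", {
  cfg <- sim_config(ne_trajectory = data.frame(generations = 40, ne = 50),
                    n_sample_individuals = 40, chrom_lengths_bp = 1e7,
                    n_snps_per_chrom = 300, seed = 17)
  popA <- simulate_population(cfg, population = "A")
  popB <- evolve_population(popA, n_generations = 30, ne = 40, seed = 18,
                            population = "B")
  ascB_on_A <- ascertain_markers(popB, 0.1, reference = popA)
  ascB_on_B <- ascertain_markers(popB, 0.1, reference = popB)
  expect_lt(mean(maf(ascB_on_A)), mean(maf(ascB_on_B)))
})

test_that("constant-Ne equilibrium decay tracks 1/(4cNe+1)", {
  h <- ascertain_markers(shared_constant_sim(), 0.05)
  pairs <- syntenic_pairs(h, max_distance_bp = 1e7)
  b <- bin_by_distance(pairs, bin_width_bp = 5e5, max_bp = 1e7)
  b <- b[b$n_pairs >= 20, ]
  mid_c <- morgans_from_bp((b$bin_lo_bp + b$bin_hi_bp) / 2)
  expect_gt(cor(b$mean_r2, expected_r2(mid_c, 60)), 0.9)
})
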