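#' Simulation configuration for the two-population generator
#'
#' Bundles everything the forward Wright-Fisher simulator needs. The defaults
#' emulate the study system the package targets: SNP-array data from a
#' purebred taurine population and a composite population carrying 5/8 of its
#' genome from the purebred, a declining effective population size, ~29
#' autosomes, and array-style ascertainment of common variants. Desk-scale
#' runs use far fewer markers and chromosomes than a real 50K array.
#'
#' @param ne_trajectory data.frame with columns \code{generations} and
#'   \code{ne}, ordered past to present; each row runs the population at that
#'   size for that many generations. Default: a decline from 600 to 150 over
#'   300 generations, the shape typical of intensively selected cattle
#'   breeds.
#' @param n_sample_individuals diploid individuals sampled from the final
#'   generation.
#' @param chrom_lengths_bp chromosome lengths in bp.
#' @param n_snps_per_chrom markers simulated per chromosome (before any
#'   ascertainment).
#' @param recomb_rate_cm_per_mb genetic:physical ratio; 1.0 means
#'   1 Mb = 1 cM, the conversion the downstream Ne estimator assumes.
#' @param crossover_model \code{"haldane"} (default) draws a Poisson number
#'   of crossovers per meiosis with uniform positions (no interference), the
#'   standard meiosis model and the physics the coalescent assumes;
#'   \code{"lattice"} places exactly one crossover per Morgan at a uniformly
#'   random phase (complete interference), making the single-meiosis
#'   recombination fraction exactly equal to the map distance.
#' @param init_freq_range range of the i.i.d. uniform initial allele-1
#'   frequencies; array SNPs are pre-ascertained common variants, hence the
#'   default \code{c(0.05, 0.95)}.
#' @param admix_proportion genome fraction the composite draws from
#'   population A (default 0.625 = 5/8).
#' @param maf_min_ascertainment MAF floor applied by
#'   \code{\link{ascertain_markers}}.
#' @param seed integer; fully determines the simulator output.
#' @return a list of class \code{sim_config}.
#' @export
sim_config <- function(ne_trajectory = data.frame(
                         generations = c(150L, 100L, 50L),
                         ne = c(600L, 300L, 150L)),
                       n_sample_individuals = 50L,
                       chrom_lengths_bp = rep(1e8, 2),
                       n_snps_per_chrom = 400L,
                       recomb_rate_cm_per_mb = 1.0,
                       crossover_model = c("haldane", "lattice"),
                       init_freq_range = c(0.05, 0.95),
                       admix_proportion = 0.625,
                       maf_min_ascertainment = 0.05,
                       seed = 1L) {
  crossover_model <- match.arg(crossover_model)
  ne_trajectory <- as.data.frame(ne_trajectory)
  stopifnot(all(c("generations", "ne") %in% names(ne_trajectory)),
            all(ne_trajectory$generations >= 1))
  if (any(ne_trajectory$ne < 2)) stop("all Ne values must be >= 2")
  if (admix_proportion < 0 || admix_proportion > 1)
    stop("admix_proportion must lie in [0, 1]")
  if (any(n_snps_per_chrom < 1)) stop("zero markers requested")
  structure(list(
    ne_trajectory = ne_trajectory,
    n_sample_individuals = as.integer(n_sample_individuals),
    chrom_lengths_bp = as.numeric(chrom_lengths_bp),
    n_snps_per_chrom = as.integer(n_snps_per_chrom),
    recomb_rate_cm_per_mb = recomb_rate_cm_per_mb,
    crossover_model = crossover_model,
    init_freq_range = init_freq_range,
    admix_proportion = admix_proportion,
    maf_min_ascertainment = maf_min_ascertainment,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Morgans spanned by a chromosome of the given physical length.
.chrom_morgans <- function(length_bp, rate_cm_per_mb) {
  length_bp / 1e6 * rate_cm_per_mb / 100
}

# Crossover breakpoints (in Morgans) for one meiosis.
.crossovers <- function(l_morgans, model) {
  if (model == "haldane") {
    k <- stats::rpois(1L, l_morgans)
    if (k == 0L) return(numeric(0))
    sort(stats::runif(k, 0, l_morgans))
  } else {
    u <- stats::runif(1L)
    if (u >= l_morgans) return(numeric(0))
    seq(u, l_morgans, by = 1)
  }
}

# One gamete from parent haplotype rows a and b at marker map positions
# mpos (Morgans). Start haplotype random; switch at each breakpoint.
.meiosis <- function(a, b, mpos, l_morgans, model) {
  bk <- .crossovers(l_morgans, model)
  start <- stats::runif(1L) < 0.5
  if (length(bk) == 0L) return(if (start) a else b)
  seg <- findInterval(mpos, bk)
  use_b <- (seg + !start) %% 2L == 1L
  out <- a
  out[use_b] <- b[use_b]
  out
}

# Advance a gamete pool (2N x m matrix) by n_gen generations of random-mating
# Wright-Fisher reproduction at size `ne` diploids. Monoecious, selfing
# allowed; each offspring draws two parents uniformly with replacement.
.wf_generations <- function(pool, n_gen, ne, mpos, l_morgans, model) {
  for (g in seq_len(n_gen)) {
    n_parents <- nrow(pool) / 2L
    nxt <- matrix(0L, nrow = 2L * ne, ncol = ncol(pool))
    parents <- sample.int(n_parents, 2L * ne, replace = TRUE)
    for (i in seq_len(2L * ne)) {
      p <- parents[i]
      nxt[i, ] <- .meiosis(pool[2L * p - 1L, ], pool[2L * p, ],
                           mpos, l_morgans, model)
    }
    pool <- nxt
  }
  pool
}

#' Simulate one population forward in time
#'
#' Discrete-generation Wright-Fisher with random mating and recombination.
#' Founders get i.i.d. allele frequencies drawn uniformly from
#' \code{init_freq_range} (no mutation afterwards); the population then runs
#' through the configured Ne trajectory, and \code{n_sample_individuals}
#' diploids are sampled (without replacement) from the final generation.
#' Marker positions are spaced uniformly at random along each chromosome.
#'
#' @param config a \code{\link{sim_config}}.
#' @param population label stored on the result.
#' @return a phased \code{\link{haplotype_set}}.
#' @examples
#' cfg <- sim_config(ne_trajectory = data.frame(generations = 20, ne = 30),
#'                   n_sample_individuals = 10, chrom_lengths_bp = 5e7,
#'                   n_snps_per_chrom = 50, seed = 7)
#' simulate_population(cfg)
#' @export
simulate_population <- function(config, population = "sim") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_chr <- length(config$chrom_lengths_bp)
  n_snps <- rep_len(config$n_snps_per_chrom, n_chr)
  ne0 <- config$ne_trajectory$ne[1]
  if (config$n_sample_individuals > utils::tail(config$ne_trajectory$ne, 1))
    stop("cannot sample more individuals than the final generation holds")
  hap_chunks <- vector("list", n_chr)
  maps <- vector("list", n_chr)
  for (ch in seq_len(n_chr)) {
    len <- config$chrom_lengths_bp[ch]
    m <- n_snps[ch]
    pos <- sort(sample.int(len, m))
    l_mor <- .chrom_morgans(len, config$recomb_rate_cm_per_mb)
    mpos <- pos / 1e6 * config$recomb_rate_cm_per_mb / 100
    p0 <- stats::runif(m, config$init_freq_range[1], config$init_freq_range[2])
    pool <- matrix(stats::rbinom(2L * ne0 * m, 1L, rep(p0, each = 2L * ne0)),
                   nrow = 2L * ne0, ncol = m)
    for (seg in seq_len(nrow(config$ne_trajectory))) {
      pool <- .wf_generations(pool,
                              config$ne_trajectory$generations[seg],
                              config$ne_trajectory$ne[seg],
                              mpos, l_mor, config$crossover_model)
    }
    picked <- sort(sample.int(nrow(pool) / 2L, config$n_sample_individuals))
    rows <- as.vector(rbind(2L * picked - 1L, 2L * picked))
    hap_chunks[[ch]] <- pool[rows, , drop = FALSE]
    maps[[ch]] <- data.frame(
      snp_id = sprintf("chr%d_snp%05d", ch, seq_len(m)),
      chrom = as.character(ch), pos_bp = pos,
      allele1 = "B", allele2 = "A", stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, maps)
  class(map) <- c("marker_map", "data.frame")
  haplotype_set(do.call(cbind, hap_chunks), map, population = population)
}

#' Continue evolving an existing phased population
#'
#' Runs additional Wright-Fisher generations starting from the gametes of
#' \code{h} (used as the founding pool), at constant size \code{ne}, and
#' samples \code{n_sample_individuals} diploids at the end. Useful for
#' creating diverged sister populations from a common base.
#'
#' @param h a \code{\link{haplotype_set}} of founders.
#' @param n_generations generations to run (0 returns a re-sample of h).
#' @param ne constant diploid population size during the run.
#' @param n_sample_individuals diploids sampled at the end (default: ne).
#' @param seed integer seed.
#' @param recomb_rate_cm_per_mb,crossover_model as in \code{\link{sim_config}}.
#' @param population label for the result.
#' @return a phased \code{\link{haplotype_set}}.
#' @export
evolve_population <- function(h, n_generations, ne,
                              n_sample_individuals = ne, seed = 1L,
                              recomb_rate_cm_per_mb = 1.0,
                              crossover_model = c("haldane", "lattice"),
                              population = h$population) {
  crossover_model <- match.arg(crossover_model)
  if (ne < 2) stop("all Ne values must be >= 2")
  set.seed(seed)
  out <- vector("list", 0L)
  chroms <- unique(h$map$chrom)
  chunks <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    idx <- which(h$map$chrom == chroms[i])
    pos <- h$map$pos_bp[idx]
    l_mor <- .chrom_morgans(max(pos), recomb_rate_cm_per_mb)
    mpos <- pos / 1e6 * recomb_rate_cm_per_mb / 100
    pool <- h$haplotypes[, idx, drop = FALSE]
    if (n_generations > 0)
      pool <- .wf_generations(pool, n_generations, ne, mpos, l_mor,
                              crossover_model)
    picked <- sort(sample.int(nrow(pool) / 2L, n_sample_individuals))
    rows <- as.vector(rbind(2L * picked - 1L, 2L * picked))
    chunks[[i]] <- pool[rows, , drop = FALSE]
  }
  haplotype_set(do.call(cbind, chunks), h$map, population = population)
}

#' Create a composite (admixed) population from two parents
#'
#' Founders of the composite are whole individuals drawn from population A
#' with probability \code{admix_proportion} (default 5/8, the nominal
#' purebred contribution to a composite such as the Braford) and from
#' population B otherwise, followed by random mating with recombination for
#' the stated number of generations.
#'
#' @param popA,popB \code{\link{haplotype_set}}s with identical maps.
#' @param admix_proportion probability a founder comes from A.
#' @param n_generations_since_admixture generations of random mating after
#'   founding.
#' @param seed integer seed.
#' @param n_founders diploid size of the composite (default: individuals in
#'   popA).
#' @param n_sample_individuals diploids sampled at the end (default:
#'   n_founders).
#' @param recomb_rate_cm_per_mb,crossover_model as in \code{\link{sim_config}}.
#' @param population label for the result.
#' @return a phased \code{\link{haplotype_set}}.
#' @export
make_composite <- function(popA, popB, admix_proportion = 0.625,
                           n_generations_since_admixture = 5L, seed = 1L,
                           n_founders = nrow(popA$haplotypes) / 2L,
                           n_sample_individuals = n_founders,
                           recomb_rate_cm_per_mb = 1.0,
                           crossover_model = c("haldane", "lattice"),
                           population = "composite") {
  crossover_model <- match.arg(crossover_model)
  if (!identical(popA$map$snp_id, popB$map$snp_id) ||
      !identical(popA$map$pos_bp, popB$map$pos_bp) ||
      !identical(popA$map$chrom, popB$map$chrom))
    stop("popA and popB must share an identical marker map")
  set.seed(seed)
  nA <- nrow(popA$haplotypes) / 2L
  nB <- nrow(popB$haplotypes) / 2L
  from_a <- stats::runif(n_founders) < admix_proportion
  rows <- matrix(0L, nrow = 2L * n_founders, ncol = ncol(popA$haplotypes))
  for (i in seq_len(n_founders)) {
    if (from_a[i]) {
      k <- sample.int(nA, 1L)
      rows[2L * i - 1L, ] <- popA$haplotypes[2L * k - 1L, ]
      rows[2L * i, ] <- popA$haplotypes[2L * k, ]
    } else {
      k <- sample.int(nB, 1L)
      rows[2L * i - 1L, ] <- popB$haplotypes[2L * k - 1L, ]
      rows[2L * i, ] <- popB$haplotypes[2L * k, ]
    }
  }
  founders <- haplotype_set(rows, popA$map, population = population)
  evolve_population(founders, n_generations_since_admixture, ne = n_founders,
                    n_sample_individuals = n_sample_individuals,
                    seed = sample.int(.Machine$integer.max, 1L),
                    recomb_rate_cm_per_mb = recomb_rate_cm_per_mb,
                    crossover_model = crossover_model,
                    population = population)
}

#' Array-style marker ascertainment
#'
#' Retains markers whose MAF in a designated reference population meets the
#' floor, emulating the bias of SNP arrays towards variants informative in
#' the discovery breeds. No correction is attempted; the point is to
#' reproduce the bias so its downstream consequences are visible.
#'
#' @param pop population whose markers are subset.
#' @param maf_min MAF floor in [0, 0.5].
#' @param reference population in which MAF is measured (default: pop
#'   itself); must share pop's map.
#' @return \code{pop} restricted to the ascertained markers.
#' @export
ascertain_markers <- function(pop, maf_min, reference = pop) {
  stopifnot(maf_min >= 0, maf_min <= 0.5)
  keep <- maf(reference) >= maf_min
  subset_markers(pop, keep)
}
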