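#' Configuration of a full analysis run
#'
#' Collects everything \code{\link{run_full_analysis}} needs. Input is
#' either one or two phased populations supplied directly (or as phased-VCF
#' paths), or a simulation recipe: a purebred population plus a composite
#' relative built by admixture (default 5/8 purebred contribution), the
#' study design this package emulates.
#'
#' @param populations list of \code{\link{haplotype_set}}s or phased-VCF
#'   paths, named by population label; \code{NULL} to simulate instead.
#' @param sim a \code{\link{sim_config}} used when \code{populations} is
#'   NULL.
#' @param divergence_generations generations the second ancestral population
#'   drifts away from the first before admixture (simulated runs).
#' @param admix_generations generations of random mating after admixture.
#' @param qc a \code{\link{qc_thresholds}}.
#' @param max_distance_bp pair-distance cap for the decay/model stages.
#' @param ne_max_distance_bp pair-distance cap for the Ne stage.
#' @param bin_width_bp distance bin width.
#' @param keep_every_list thinning factors.
#' @param panel_sizes marker counts of the commercial panels whose average
#'   spacings are used as prediction distances.
#' @param genome_mb genome length used for panel spacing arithmetic.
#' @param sample_size_correction passed to \code{\link{ne_trajectory}}.
#' @param out_dir output directory for TSV tables (NULL = no files).
#' @param seed integer master seed for simulated runs.
#' @return a list of class \code{run_config}.
#' @export
run_config <- function(populations = NULL,
                       sim = sim_config(),
                       divergence_generations = 40L,
                       admix_generations = 10L,
                       qc = qc_thresholds(),
                       max_distance_bp = 1e7,
                       ne_max_distance_bp = 1e8,
                       bin_width_bp = 1e5,
                       keep_every_list = c(1L, 2L, 4L, 5L, 6L, 7L, 14L),
                       panel_sizes = c(150000L, 80000L, 50000L, 20000L,
                                       8000L, 3000L),
                       genome_mb = 3000,
                       sample_size_correction = FALSE,
                       out_dir = NULL,
                       seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

.log_stage <- function(verbose, ...) if (verbose) message("[ldphase] ", ...)

#' Run the full LD analysis pipeline
#'
#' Executes the stages in their methodological order: obtain two phased
#' populations (ingest or simulate) -> per-population QC -> pairwise LD,
#' decay binning and panel thinning -> ANCOVA models of LD heterogeneity
#' with LS means and panel-distance predictions -> persistence of phase ->
#' Ne history. With a single population the phase-persistence stage is
#' skipped with a notice. When \code{out_dir} is set, all result tables are
#' written as deterministic TSVs together with a run manifest.
#'
#' @param config a \code{\link{run_config}}.
#' @param verbose log per-stage counts.
#' @return a list of class \code{ld_run} with elements qc_reports,
#'   populations, adjacent (per-pop pair tables), syntenic, ld_bins,
#'   adjacent_summary, thinning, model_adjacent, model_syntenic, ls_means,
#'   panel_predictions, phase_bins, ne (per-pop trajectories), config.
#' @export
run_full_analysis <- function(config = run_config(), verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))

  # --- stage 0: inputs -------------------------------------------------------
  if (is.null(config$populations)) {
    .log_stage(verbose, "simulating two related populations (seed ",
               config$seed, ")")
    sim <- config$sim
    sim$seed <- config$seed
    ancestral <- simulate_population(sim, population = "A")
    diverged <- evolve_population(
      ancestral, config$divergence_generations,
      ne = max(2L, nrow(ancestral$haplotypes) %/% 2L),
      n_sample_individuals = nrow(ancestral$haplotypes) %/% 2L,
      seed = config$seed + 1L,
      recomb_rate_cm_per_mb = sim$recomb_rate_cm_per_mb,
      crossover_model = sim$crossover_model, population = "Z")
    composite <- make_composite(
      ancestral, diverged, admix_proportion = sim$admix_proportion,
      n_generations_since_admixture = config$admix_generations,
      seed = config$seed + 2L,
      recomb_rate_cm_per_mb = sim$recomb_rate_cm_per_mb,
      crossover_model = sim$crossover_model, population = "B")
    ancestral$population <- "H"
    pops <- list(H = ancestral, B = composite)
    pops <- lapply(pops, function(p)
      ascertain_markers(p, sim$maf_min_ascertainment, reference = pops[[1L]]))
  } else {
    pops <- lapply(seq_along(config$populations), function(i) {
      p <- config$populations[[i]]
      nm <- names(config$populations)[i]
      if (is.character(p)) p <- read_phased_vcf(p, population = nm)
      p$population <- nm
      p
    })
    names(pops) <- names(config$populations)
  }

  # --- stage 1: QC -----------------------------------------------------------
  qc_reports <- list()
  for (nm in names(pops)) {
    g <- as_genotype_set(pops[[nm]])
    autosomes <- unique(g$map$chrom)
    mq <- marker_qc(g, config$qc, autosomes = autosomes,
                    drop_monomorphic = TRUE)
    qc_reports[[nm]] <- mq$report
    keep <- pops[[nm]]$map$snp_id %in% mq$genotypes$map$snp_id
    if (!any(keep)) stop("QC stage removed all markers for population ", nm)
    pops[[nm]] <- subset_markers(pops[[nm]], keep)
    .log_stage(verbose, "QC [", nm, "]: retained ", sum(keep), "/",
               length(keep), " markers")
  }

  # --- stage 2: pairwise LD --------------------------------------------------
  adjacent <- lapply(pops, adjacent_pairs)
  syntenic <- lapply(pops, syntenic_pairs,
                     max_distance_bp = config$max_distance_bp)
  ld_bins <- lapply(syntenic, bin_by_distance,
                    bin_width_bp = config$bin_width_bp,
                    max_bp = config$max_distance_bp)
  adjacent_summary <- do.call(rbind, lapply(names(pops), function(nm) {
    ap <- adjacent[[nm]]
    data.frame(population = nm, n_pairs = nrow(ap),
               mean_r2 = mean(ap$r2), sd_r2 = stats::sd(ap$r2),
               mean_dist_bp = mean(ap$distance_bp),
               pct_r2_gt_0.2 = 100 * proportion_above(ap, 0.2),
               pct_r2_gt_0.3 = 100 * proportion_above(ap, 0.3),
               stringsAsFactors = FALSE)
  }))
  thinning <- do.call(rbind, lapply(names(pops), function(nm) {
    te <- thinning_experiment(pops[[nm]], config$keep_every_list)
    cbind(population = nm, te)
  }))
  .log_stage(verbose, "LD: ",
             paste(vapply(syntenic, nrow, integer(1)), collapse = " + "),
             " syntenic pairs within ", config$max_distance_bp / 1e6, " Mb")

  # --- stage 3: ANCOVA models ------------------------------------------------
  model_adjacent <- model_syntenic <- ls_means <- panel_predictions <- NULL
  n_chrom <- length(unique(pops[[1L]]$map$chrom))
  if (length(pops) >= 2L && n_chrom >= 2L) {
    rec_adj <- do.call(ld_model_records, adjacent[1:2])
    model_adjacent <- ld_ancova(rec_adj, order = 1L)
    ls_means <- ls_means_by_chromosome(model_adjacent)
    rec_syn <- do.call(ld_model_records, syntenic[1:2])
    model_syntenic <- ld_ancova(rec_syn, order = 3L)
    dists_kb <- panel_distance_kb(config$panel_sizes, config$genome_mb)
    grid <- expand.grid(chrom = model_syntenic$chrom_levels,
                        breed = model_syntenic$breed_levels,
                        panel_kb = dists_kb, stringsAsFactors = FALSE)
    panel_predictions <- suppressWarnings(
      predict(model_syntenic, grid$chrom, grid$breed, grid$panel_kb * 1000))
    panel_predictions$panel_size <- rep(config$panel_sizes,
                                        each = nrow(grid) / length(dists_kb))
    .log_stage(verbose, "models: ANCOVA on ", nrow(rec_adj), " adjacent and ",
               nrow(rec_syn), " syntenic pairs")
  } else {
    .log_stage(verbose, "models: skipped (needs 2 populations and >= 2 chromosomes)")
  }

  # --- stage 4: persistence of phase ----------------------------------------
  phase_bins <- NULL
  if (length(pops) >= 2L) {
    phase_bins <- phase_correlation(syntenic[[1L]], syntenic[[2L]],
                                    bin_width_bp = config$bin_width_bp,
                                    max_bp = config$max_distance_bp)
    .log_stage(verbose, "phase: ", sum(phase_bins$n_pairs),
               " matched pairs in ", sum(!is.na(phase_bins$R_AB)),
               " defined bins")
  } else {
    .log_stage(verbose, "phase: skipped (single population)")
  }

  # --- stage 5: Ne history ---------------------------------------------------
  ne <- lapply(pops, function(p) {
    long_pairs <- syntenic_pairs(p, max_distance_bp = config$ne_max_distance_bp)
    ne_trajectory(long_pairs,
                  sample_size_correction = config$sample_size_correction)
  })
  .log_stage(verbose, "Ne: trajectories for ",
             paste(names(pops), collapse = ", "))

  out <- list(qc_reports = qc_reports, populations = pops,
              adjacent = adjacent, syntenic = syntenic, ld_bins = ld_bins,
              adjacent_summary = adjacent_summary, thinning = thinning,
              model_adjacent = model_adjacent,
              model_syntenic = model_syntenic,
              ls_means = ls_means, panel_predictions = panel_predictions,
              phase_bins = phase_bins, ne = ne, config = config)
  class(out) <- "ld_run"

  if (!is.null(config$out_dir)) write_run(out, config$out_dir)
  out
}

#' Write the result bundle of a run as TSV tables plus a manifest
#'
#' @param run an \code{ld_run}.
#' @param out_dir output directory.
#' @return invisible vector of written paths.
#' @export
write_run <- function(run, out_dir) {
  tabs <- list(
    qc_report = do.call(rbind, lapply(names(run$qc_reports), function(nm)
      cbind(population = nm, as.data.frame(run$qc_reports[[nm]])))),
    adjacent_summary = run$adjacent_summary,
    thinning = run$thinning,
    ld_pairs = do.call(rbind, lapply(names(run$syntenic), function(nm)
      cbind(population = nm, as.data.frame(run$syntenic[[nm]])))),
    ld_bins = do.call(rbind, lapply(names(run$ld_bins), function(nm)
      cbind(population = nm, run$ld_bins[[nm]]))),
    ne_trajectory = do.call(rbind, lapply(names(run$ne), function(nm)
      cbind(population = nm, as.data.frame(run$ne[[nm]]))))
  )
  if (!is.null(run$phase_bins)) tabs$phase_bins <- as.data.frame(run$phase_bins)
  if (!is.null(run$ls_means)) tabs$ls_means <- run$ls_means
  if (!is.null(run$panel_predictions)) tabs$panel_predictions <- run$panel_predictions
  paths <- write_tables(tabs, out_dir)
  cfg <- unclass(run$config)
  cfg$out_dir <- NULL   # environmental, not part of the analysis identity
  cfg$populations <- if (is.null(cfg$populations)) NULL else names(cfg$populations)
  cfg$sim <- unclass(cfg$sim)
  cfg$qc <- unclass(cfg$qc)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(package = "ldphase",
         version = as.character(utils::packageVersion("ldphase")),
         seed = cfg$seed, config = cfg),
    manifest_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  md5 <- unname(tools::md5sum(manifest_path))
  cat("config_md5\t", md5, "\n", sep = "",
      file = file.path(out_dir, "manifest.md5"))
  invisible(c(paths, manifest_path))
}

#' @export
print.ld_run <- function(x, ...) {
  cat("LD analysis run: ", length(x$populations), " population(s): ",
      paste(names(x$populations), collapse = ", "), "\n", sep = "")
  print(x$adjacent_summary, row.names = FALSE, digits = 4)
  invisible(x)
}
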