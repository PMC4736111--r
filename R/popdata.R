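#' Marker map
#'
#' A marker map records, for every SNP, its chromosome, 1-based physical
#' position in bp, identifier and the two allele labels. It is the coordinate
#' system every analysis stage shares: inter-marker distances are always
#' \code{pos_bp[j] - pos_bp[i]} with j downstream of i.
#'
#' @param snp_id character vector of marker identifiers.
#' @param chrom chromosome labels (coerced to character); autosomes 1..29 in
#'   the default cattle setting, but any labels are accepted.
#' @param pos_bp integer vector of 1-based physical positions.
#' @param allele1,allele2 allele labels; \code{allele1} is the allele that
#'   haplotype code 1 refers to, consistently across populations.
#' @return A \code{data.frame} of class \code{marker_map}, sorted by
#'   (chrom, pos_bp).
#' @examples
#' marker_map(c("s1", "s2"), c(1, 1), c(100, 2000))
#' @export
marker_map <- function(snp_id, chrom, pos_bp,
                       allele1 = rep("A", length(snp_id)),
                       allele2 = rep("B", length(snp_id))) {
  map <- data.frame(
    snp_id = as.character(snp_id),
    chrom = as.character(chrom),
    pos_bp = as.integer(pos_bp),
    allele1 = as.character(allele1),
    allele2 = as.character(allele2),
    stringsAsFactors = FALSE
  )
  if (any(is.na(map$pos_bp)) || any(map$pos_bp < 1L))
    stop("pos_bp must be positive 1-based integers")
  if (any(map$allele1 == map$allele2))
    stop("allele1 and allele2 must differ for every marker")
  map <- sort_map(map)
  class(map) <- c("marker_map", "data.frame")
  map
}

#' Sort a marker map by (chrom, pos)
#'
#' Stable and idempotent; chromosome labels that look numeric sort
#' numerically (1, 2, ..., 10), others lexicographically after them.
#'
#' @param map a \code{marker_map} or compatible data.frame.
#' @return the sorted map, same class.
#' @export
sort_map <- function(map) {
  num <- suppressWarnings(as.numeric(map$chrom))
  key <- order(is.na(num), num, map$chrom, map$pos_bp)
  map[key, , drop = FALSE]
}

.validate_map <- function(map) {
  stopifnot(is.data.frame(map),
            all(c("snp_id", "chrom", "pos_bp") %in% names(map)))
  by_chr <- split(map$pos_bp, map$chrom)
  if (any(vapply(by_chr, function(p) any(diff(p) <= 0), logical(1))))
    stop("marker positions must be strictly increasing within chromosome")
  invisible(map)
}

#' Phased haplotype set
#'
#' The universal substrate of the package: a matrix of 0/1 alleles with one
#' row per gamete (two per diploid individual) and one column per marker,
#' plus the marker map and sample identifiers. Allele code 1 refers to
#' \code{map$allele1}. LD statistics are computed at this gametic level.
#'
#' @param haplotypes integer/numeric matrix of 0/1, rows = gametes (2 per
#'   individual, consecutive), columns = markers in map order.
#' @param map a \code{\link{marker_map}}.
#' @param sample_ids character vector, one per individual (nrow/2 entries).
#' @param population optional population label (e.g. "H", "B").
#' @return An object of class \code{haplotype_set}.
#' @export
haplotype_set <- function(haplotypes, map, sample_ids = NULL, population = "pop") {
  haplotypes <- as.matrix(haplotypes)
  if (nrow(haplotypes) %% 2L != 0L)
    stop("haplotype row count must be even (two gametes per individual)")
  if (ncol(haplotypes) != nrow(map))
    stop("haplotype column count (", ncol(haplotypes),
         ") does not match map length (", nrow(map), ")")
  if (!all(haplotypes %in% c(0L, 1L)))
    stop("haplotype entries must be 0/1; resolve missingness upstream")
  storage.mode(haplotypes) <- "integer"
  n_ind <- nrow(haplotypes) / 2L
  if (is.null(sample_ids)) sample_ids <- sprintf("ind%04d", seq_len(n_ind))
  if (length(sample_ids) != n_ind)
    stop("sample_ids length must equal the number of individuals")
  .validate_map(map)
  structure(
    list(haplotypes = haplotypes, map = map,
         sample_ids = as.character(sample_ids),
         population = population),
    class = "haplotype_set"
  )
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("Phased haplotype set '", x$population, "': ",
      nrow(x$haplotypes) / 2L, " individuals (",
      nrow(x$haplotypes), " gametes), ",
      ncol(x$haplotypes), " markers on ",
      length(unique(x$map$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' @export
dim.haplotype_set <- function(x) dim(x$haplotypes)

#' Number of gametes (haplotypes) in a set
#' @param h a \code{haplotype_set}.
#' @return integer count of gametes.
#' @export
n_haplotypes <- function(h) nrow(h$haplotypes)

#' Subset markers of a haplotype set
#'
#' Column subsetting that keeps matrix and map in step. Allele coding is
#' never altered: subsetting is the only shape-changing operation.
#'
#' @param h a \code{haplotype_set}.
#' @param idx logical or integer column index into the map.
#' @return a \code{haplotype_set} with the selected markers.
#' @export
subset_markers <- function(h, idx) {
  haplotype_set(h$haplotypes[, idx, drop = FALSE],
                h$map[idx, , drop = FALSE],
                h$sample_ids, h$population)
}

#' Per-marker allele-1 frequency and minor allele frequency
#' @param h a \code{haplotype_set}.
#' @return \code{allele1_freq}: numeric vector of allele-1 frequencies.
#' @export
allele1_freq <- function(h) colMeans(h$haplotypes)

#' @rdname allele1_freq
#' @export
maf <- function(h) {
  p <- colMeans(h$haplotypes)
  pmin(p, 1 - p)
}

#' Drop markers monomorphic in this population
#'
#' LD is undefined at a monomorphic locus, so a population's marker set is
#' restricted to its polymorphic markers before pair enumeration.
#'
#' @param h a \code{haplotype_set}.
#' @return a \code{haplotype_set} without monomorphic columns.
#' @export
drop_monomorphic <- function(h) {
  p <- colMeans(h$haplotypes)
  subset_markers(h, p > 0 & p < 1)
}

#' Collapse phased haplotypes to genotype dosages
#'
#' Sums the two gametes of each individual into a 0/1/2 allele-1 dosage
#' matrix, the substrate of the (pre-phasing) QC stage.
#'
#' @param h a \code{haplotype_set}.
#' @return a \code{\link{genotype_set}}.
#' @export
as_genotype_set <- function(h) {
  n_ind <- nrow(h$haplotypes) / 2L
  g <- h$haplotypes[seq(1L, by = 2L, length.out = n_ind), , drop = FALSE] +
    h$haplotypes[seq(2L, by = 2L, length.out = n_ind), , drop = FALSE]
  genotype_set(g, h$map, h$sample_ids)
}

# ---- phased VCF I/O ---------------------------------------------------------

#' Read a phased VCF into a haplotype set
#'
#' Requires every GT to be phased ("|"-separated) and every site biallelic.
#' Haplotype code 1 is the VCF ALT allele; the map carries CHROM/POS/ID and
#' REF (allele code 0) / ALT (allele code 1). Markers are returned in
#' (chrom, pos) order.
#'
#' @param path path to a VCF (plain text or bgzipped).
#' @param autosomes optional character vector of chromosome labels to keep
#'   (e.g. \code{as.character(1:29)}); \code{NULL} keeps all contigs.
#' @param population population label stored on the result.
#' @return a \code{\link{haplotype_set}}.
#' @export
read_phased_vcf <- function(path, autosomes = NULL, population = "pop") {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_phased_vcf() requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  if (any(n_alt != 1L)) {
    k <- which(n_alt != 1L)[1]
    stop("multiallelic site at ", as.character(GenomeInfoDb::seqnames(rr))[k],
         ":", BiocGenerics::start(rr)[k], "; only biallelic SNPs are supported")
  }
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  bad <- grepl("/", gt, fixed = TRUE)
  dim(bad) <- dim(gt)
  if (any(bad)) {
    k <- which(bad, arr.ind = TRUE)[1L, ]
    stop("unphased genotype '", gt[k[1], k[2]], "' at record ",
         rownames(gt)[k[1]], " sample ", colnames(gt)[k[2]],
         "; phased (\"|\") GT required")
  }
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref_al <- as.character(VariantAnnotation::ref(vcf))
  alt_al <- as.character(unlist(alt))
  ids <- if (is.null(rownames(gt))) sprintf("snp%05d", seq_along(pos)) else rownames(gt)
  if (!is.null(autosomes)) {
    keep <- chrom %in% as.character(autosomes)
    gt <- gt[keep, , drop = FALSE]
    chrom <- chrom[keep]; pos <- pos[keep]
    ref_al <- ref_al[keep]; alt_al <- alt_al[keep]; ids <- ids[keep]
  }
  num <- suppressWarnings(as.numeric(chrom))
  ord <- order(is.na(num), num, chrom, pos)
  map <- data.frame(snp_id = ids[ord], chrom = chrom[ord],
                    pos_bp = as.integer(pos[ord]),
                    allele1 = alt_al[ord], allele2 = ref_al[ord],
                    stringsAsFactors = FALSE)
  class(map) <- c("marker_map", "data.frame")
  gt <- gt[ord, , drop = FALSE]
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  if (any(a1 %in% "." | a2 %in% "."))
    stop("missing alleles in GT; impute before analysis")
  n_ind <- ncol(gt)
  hap <- matrix(0L, nrow = 2L * n_ind, ncol = nrow(gt))
  hap[seq(1L, by = 2L, length.out = n_ind), ] <- t(matrix(as.integer(a1), nrow = nrow(gt)))
  hap[seq(2L, by = 2L, length.out = n_ind), ] <- t(matrix(as.integer(a2), nrow = nrow(gt)))
  haplotype_set(hap, map, sample_ids = colnames(gt), population = population)
}

#' Write a haplotype set as a phased VCF
#'
#' Allele code 0 is written as REF (= \code{map$allele2}) and code 1 as ALT
#' (= \code{map$allele1}), so a write/read round trip is the identity.
#'
#' @param h a \code{\link{haplotype_set}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_phased_vcf <- function(h, path) {
  map <- h$map
  n_ind <- nrow(h$haplotypes) / 2L
  i1 <- seq(1L, by = 2L, length.out = n_ind)
  gt <- matrix(paste0(t(h$haplotypes[i1, , drop = FALSE]), "|",
                      t(h$haplotypes[i1 + 1L, , drop = FALSE])),
               nrow = nrow(map))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(map$chrom)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", h$sample_ids), collapse = "\t")
  ), con)
  body <- cbind(map$chrom, map$pos_bp, map$snp_id, map$allele2, map$allele1,
                ".", "PASS", ".", "GT", gt)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

# ---- plain-text haplotype matrix I/O ---------------------------------------

#' Read a plain-text haplotype matrix plus map TSV
#'
#' The haplotype file holds one row per gamete of whitespace-separated 0/1
#' alleles; the map TSV has columns snp_id, chrom, pos_bp, allele1, allele2.
#'
#' @param hap_path path to the haplotype matrix file.
#' @param map_path path to the map TSV.
#' @param population population label.
#' @return a \code{\link{haplotype_set}}.
#' @export
read_haplotype_table <- function(hap_path, map_path, population = "pop") {
  m <- utils::read.table(map_path, header = TRUE, sep = "\t",
                         colClasses = "character")
  map <- marker_map(m$snp_id, m$chrom, as.integer(m$pos_bp),
                    m$allele1, m$allele2)
  hap <- as.matrix(utils::read.table(hap_path, header = FALSE))
  haplotype_set(hap, map, population = population)
}

#' @rdname read_haplotype_table
#' @param h a \code{haplotype_set} to write.
#' @export
write_haplotype_table <- function(h, hap_path, map_path) {
  utils::write.table(h$haplotypes, hap_path, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(h$map, map_path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(hap_path)
}

# ---- result-table output ----------------------------------------------------

#' Write a result table as deterministic TSV
#'
#' Numeric columns are formatted at fixed precision so repeated runs on the
#' same inputs produce byte-identical files; an empty table yields a
#' header-only file.
#'
#' @param x a data.frame (any stage output).
#' @param path output file path.
#' @param digits decimal places for numeric columns.
#' @return \code{path}, invisibly.
#' @export
write_result_table <- function(x, path, digits = 6L) {
  x <- as.data.frame(x)
  for (j in seq_along(x)) {
    if (is.double(x[[j]]))
      x[[j]] <- sprintf(paste0("%.", digits, "g"), x[[j]])
  }
  utils::write.table(x, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Write the standard result bundle of a pipeline run
#'
#' @param results a named list of data.frames (e.g. ld_pairs, ld_bins,
#'   thinning, phase_bins, ne_trajectory, qc_report).
#' @param out_dir output directory, created if absent.
#' @return invisible character vector of written paths.
#' @export
write_tables <- function(results, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(results)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_result_table(as.data.frame(results[[nm]]), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
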