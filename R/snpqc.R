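#' Genotype set (pre-phasing substrate of QC)
#'
#' Unphased allele-1 dosages 0/1/2 with \code{NA} for missing calls. QC
#' operates here, before phasing, mirroring the usual array workflow.
#'
#' @param genotypes matrix of 0/1/2/NA, rows = individuals, cols = markers.
#' @param map a \code{\link{marker_map}}.
#' @param sample_ids character vector, one per row.
#' @return an object of class \code{genotype_set}.
#' @export
genotype_set <- function(genotypes, map, sample_ids = NULL) {
  genotypes <- as.matrix(genotypes)
  if (ncol(genotypes) != nrow(map))
    stop("genotype column count does not match map length")
  if (!all(genotypes %in% c(0L, 1L, 2L, NA)))
    stop("genotype entries must be 0, 1, 2 or NA")
  storage.mode(genotypes) <- "integer"
  if (is.null(sample_ids)) sample_ids <- sprintf("ind%04d", seq_len(nrow(genotypes)))
  structure(list(genotypes = genotypes, map = map,
                 sample_ids = as.character(sample_ids)),
            class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat("Genotype set: ", nrow(x$genotypes), " samples x ",
      ncol(x$genotypes), " markers; missing rate ",
      sprintf("%.4f", mean(is.na(x$genotypes))), "\n", sep = "")
  invisible(x)
}

#' QC thresholds
#'
#' Defaults are the standard array filter set: samples with call rate < 0.90
#' or autosomal heterozygosity beyond 3 SD of the sample mean, duplicated
#' genotypes; markers off-autosome, call rate < 0.98, MAF < 0.03, or
#' Hardy-Weinberg deviation at P < 1e-6, plus one-per-position resolution.
#'
#' @param sample_call_rate_min minimum sample call rate.
#' @param het_sd_limit allowed heterozygosity deviation in SD units.
#' @param marker_call_rate_min minimum marker call rate.
#' @param maf_min minimum minor allele frequency.
#' @param hwe_p_min minimum HWE p-value.
#' @param duplicate_concordance_min genotype concordance above which two
#'   samples are treated as duplicates.
#' @return a list of class \code{qc_thresholds}.
#' @export
qc_thresholds <- function(sample_call_rate_min = 0.90,
                          het_sd_limit = 3.0,
                          marker_call_rate_min = 0.98,
                          maf_min = 0.03,
                          hwe_p_min = 1e-6,
                          duplicate_concordance_min = 0.95) {
  stopifnot(het_sd_limit > 0)
  structure(list(sample_call_rate_min = sample_call_rate_min,
                 het_sd_limit = het_sd_limit,
                 marker_call_rate_min = marker_call_rate_min,
                 maf_min = maf_min,
                 hwe_p_min = hwe_p_min,
                 duplicate_concordance_min = duplicate_concordance_min),
            class = "qc_thresholds")
}

#' Hardy-Weinberg equilibrium p-value
#'
#' Pearson chi-square goodness of fit with 1 df of the observed genotype
#' counts against the expectation from the sample allele frequency. A
#' monomorphic marker returns p = 1 by convention (no test possible).
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return upper-tail p-value.
#' @examples
#' hwe_pvalue(25, 50, 25)  # exact HWE proportions -> 1
#' hwe_pvalue(50, 0, 50)   # total heterozygote deficit -> ~1.5e-23
#' @export
hwe_pvalue <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  if (n <= 0) stop("at least one called genotype required")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p == 0 || p == 1) return(1)
  expd <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((c(n_AA, n_Aa, n_aa) - expd)^2 / expd)
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

.sample_call_rate <- function(g) rowMeans(!is.na(g))
.marker_call_rate <- function(g) colMeans(!is.na(g))

.sample_het <- function(g) {
  called <- rowSums(!is.na(g))
  het <- rowSums(g == 1L, na.rm = TRUE)
  ifelse(called > 0, het / called, NA_real_)
}

.geno_maf <- function(g) {
  p <- colMeans(g, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Sample-level quality control
#'
#' Applies, in order: (1) call-rate filter; (2) heterozygosity filter —
#' samples whose proportion of heterozygous calls lies beyond
#' mean +/- het_sd_limit * SD, with mean and SD computed over the samples
#' retained after step 1; (3) duplicate detection — among sample pairs with
#' genotype concordance >= the threshold at jointly called markers, the
#' lower-call-rate member is removed. A sample failing several rules is
#' counted once, under the first rule that caught it.
#'
#' @param g a \code{\link{genotype_set}}.
#' @param thr a \code{\link{qc_thresholds}}.
#' @return list with elements \code{genotypes} (filtered
#'   \code{genotype_set}) and \code{report} (a \code{qc_report}).
#' @export
sample_qc <- function(g, thr = qc_thresholds()) {
  stopifnot(inherits(g, "genotype_set"))
  gm <- g$genotypes
  n0 <- nrow(gm)
  removed <- c(call_rate = 0L, heterozygosity = 0L, duplicate = 0L)

  cr <- .sample_call_rate(gm)
  fail_cr <- cr < thr$sample_call_rate_min
  removed["call_rate"] <- sum(fail_cr)
  keep <- which(!fail_cr)

  if (length(keep) < 3L) {
    warning("fewer than 3 samples after call-rate filter; heterozygosity filter skipped")
  } else {
    het <- .sample_het(gm[keep, , drop = FALSE])
    m <- mean(het); s <- stats::sd(het)
    if (is.finite(s) && s > 0) {
      fail_het <- abs(het - m) > thr$het_sd_limit * s
      removed["heterozygosity"] <- sum(fail_het)
      keep <- keep[!fail_het]
    }
  }

  if (length(keep) >= 2L) {
    sub <- gm[keep, , drop = FALSE]
    crk <- cr[keep]
    drop <- logical(length(keep))
    for (i in seq_len(length(keep) - 1L)) {
      if (drop[i]) next
      for (j in (i + 1L):length(keep)) {
        if (drop[j]) next
        both <- !is.na(sub[i, ]) & !is.na(sub[j, ])
        if (!any(both)) next
        conc <- mean(sub[i, both] == sub[j, both])
        if (conc >= thr$duplicate_concordance_min) {
          # remove the lower-call-rate member of the pair
          victim <- if (crk[i] < crk[j]) i else j
          drop[victim] <- TRUE
        }
      }
    }
    removed["duplicate"] <- sum(drop)
    keep <- keep[!drop]
  }

  out <- genotype_set(gm[keep, , drop = FALSE], g$map, g$sample_ids[keep])
  report <- structure(list(axis = "sample", input = n0,
                           removed = removed, retained = length(keep)),
                      class = "qc_report")
  list(genotypes = out, report = report)
}

#' Marker-level quality control
#'
#' Applies, in order: autosome restriction, marker call rate, MAF, HWE,
#' duplicate-position resolution (keeping the highest-MAF SNP at each
#' (chrom, pos)), and optionally removal of markers monomorphic in the set.
#' Sample QC is assumed to have run first.
#'
#' @param g a \code{\link{genotype_set}}.
#' @param thr a \code{\link{qc_thresholds}}.
#' @param autosomes chromosome labels treated as autosomes (default 1..29,
#'   the cattle autosome set); \code{NULL} disables the restriction.
#' @param drop_monomorphic remove markers with MAF 0 after the other filters.
#' @return list with \code{genotypes} and \code{report}, as
#'   \code{\link{sample_qc}}.
#' @export
marker_qc <- function(g, thr = qc_thresholds(),
                      autosomes = as.character(1:29),
                      drop_monomorphic = FALSE) {
  stopifnot(inherits(g, "genotype_set"))
  gm <- g$genotypes
  map <- g$map
  m0 <- ncol(gm)
  removed <- c(non_autosomal = 0L, call_rate = 0L, maf = 0L, hwe = 0L,
               duplicate_position = 0L, monomorphic = 0L)
  keep <- seq_len(m0)

  if (!is.null(autosomes)) {
    ok <- map$chrom[keep] %in% as.character(autosomes)
    removed["non_autosomal"] <- sum(!ok)
    keep <- keep[ok]
  }

  cr <- .marker_call_rate(gm[, keep, drop = FALSE])
  ok <- cr >= thr$marker_call_rate_min
  removed["call_rate"] <- sum(!ok)
  keep <- keep[ok]

  mafs <- .geno_maf(gm[, keep, drop = FALSE])
  ok <- mafs >= thr$maf_min
  removed["maf"] <- sum(!ok)
  keep <- keep[ok]

  if (length(keep)) {
    hwe <- vapply(keep, function(j) {
      x <- gm[, j]
      hwe_pvalue(sum(x == 0L, na.rm = TRUE), sum(x == 1L, na.rm = TRUE),
                 sum(x == 2L, na.rm = TRUE))
    }, numeric(1))
    ok <- hwe >= thr$hwe_p_min
    removed["hwe"] <- sum(!ok)
    keep <- keep[ok]
  }

  if (length(keep)) {
    pos_key <- paste(map$chrom[keep], map$pos_bp[keep], sep = ":")
    if (anyDuplicated(pos_key)) {
      mafs <- .geno_maf(gm[, keep, drop = FALSE])
      # keep the highest-MAF SNP at each physical position
      best <- unlist(lapply(split(seq_along(keep), pos_key), function(ii) {
        ii[which.max(mafs[ii])]
      }), use.names = FALSE)
      removed["duplicate_position"] <- length(keep) - length(best)
      keep <- sort(keep[best])
    }
  }

  if (drop_monomorphic && length(keep)) {
    mafs <- .geno_maf(gm[, keep, drop = FALSE])
    ok <- mafs > 0
    removed["monomorphic"] <- sum(!ok)
    keep <- keep[ok]
  }

  out <- genotype_set(gm[, keep, drop = FALSE],
                      {
                        sub <- map[keep, , drop = FALSE]
                        class(sub) <- c("marker_map", "data.frame")
                        sub
                      },
                      g$sample_ids)
  report <- structure(list(axis = "marker", input = m0,
                           removed = removed, retained = length(keep)),
                      class = "qc_report")
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report (", x$axis, "): input ", x$input, ", retained ",
      x$retained, "\n", sep = "")
  for (nm in names(x$removed))
    cat(sprintf("  removed by %-20s %d\n", paste0(nm, ":"), x$removed[[nm]]))
  invisible(x)
}

#' @export
as.data.frame.qc_report <- function(x, ...) {
  data.frame(axis = x$axis,
             rule = c(names(x$removed), "retained"),
             count = c(unname(x$removed), x$retained),
             stringsAsFactors = FALSE)
}
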