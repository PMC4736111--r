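#' Signed r and r-squared for one marker pair from phased gametes
#'
#' Computes linkage disequilibrium directly from gametic haplotype
#' frequencies. With alleles A1/A2 at the first locus and B1/B2 at the
#' second (code 1 = allele1 of the map),
#' \deqn{D = p_{A1B1} p_{A2B2} - p_{A1B2} p_{A2B1},\qquad
#'       r = D / \sqrt{p_{A1} p_{A2} p_{B1} p_{B2}},\qquad r^2 = r^2.}
#' This equals the squared Pearson correlation of the 0/1 allele indicators
#' across gametes, which the tests use as an independent oracle.
#'
#' @param hapA,hapB 0/1 allele vectors over the same gametes.
#' @return list with \code{r_signed}, \code{r2}, \code{D}, the four
#'   haplotype frequencies and \code{n_haplotypes}.
#' @examples
#' a <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
#' b <- c(1, 1, 1, 1, 0, 1, 1, 0, 0, 0)
#' pair_ld(a, b)$r_signed  # 0.4082...
#' @export
pair_ld <- function(hapA, hapB) {
  stopifnot(length(hapA) == length(hapB))
  n <- length(hapA)
  p_A1 <- mean(hapA)
  p_B1 <- mean(hapB)
  if (p_A1 %in% c(0, 1) || p_B1 %in% c(0, 1))
    stop("undefined LD: monomorphic locus (pre-filter with drop_monomorphic)")
  p_A1B1 <- mean(hapA == 1L & hapB == 1L)
  p_A1B2 <- mean(hapA == 1L & hapB == 0L)
  p_A2B1 <- mean(hapA == 0L & hapB == 1L)
  p_A2B2 <- mean(hapA == 0L & hapB == 0L)
  D <- p_A1B1 * p_A2B2 - p_A1B2 * p_A2B1
  r <- D / sqrt(p_A1 * (1 - p_A1) * p_B1 * (1 - p_B1))
  list(r_signed = r, r2 = r^2, D = D,
       p_A1B1 = p_A1B1, p_A1B2 = p_A1B2, p_A2B1 = p_A2B1, p_A2B2 = p_A2B2,
       n_haplotypes = n)
}

# Vectorised r for all requested column pairs of a 0/1 gamete matrix.
# D = p11 - pA*pB is the frequency-algebra form of the haplotype-product
# difference above.
.pair_r_bulk <- function(H, i_idx, j_idx) {
  n <- nrow(H)
  p <- colMeans(H)
  p11 <- crossprod(H) / n
  D <- p11[cbind(i_idx, j_idx)] - p[i_idx] * p[j_idx]
  denom <- sqrt(p[i_idx] * (1 - p[i_idx]) * p[j_idx] * (1 - p[j_idx]))
  D / denom
}

.pair_table <- function(h, i_glob, j_glob, r) {
  data.frame(
    chrom = h$map$chrom[i_glob],
    snp_i = h$map$snp_id[i_glob],
    snp_j = h$map$snp_id[j_glob],
    pos_i = h$map$pos_bp[i_glob],
    pos_j = h$map$pos_bp[j_glob],
    distance_bp = h$map$pos_bp[j_glob] - h$map$pos_bp[i_glob],
    r_signed = r,
    r2 = r^2,
    stringsAsFactors = FALSE
  )
}

#' All syntenic marker pairs with their LD
#'
#' Enumerates every within-chromosome pair up to \code{max_distance_bp}
#' (10 Mb by default, the range of the decay analysis) and computes signed r
#' and r-squared for each. Monomorphic markers are dropped first. Pairs are
#' ordered by (chrom, pos_i, pos_j).
#'
#' @param h a \code{\link{haplotype_set}}.
#' @param max_distance_bp maximum pair distance in bp; \code{Inf} for all
#'   syntenic pairs.
#' @return data.frame of class \code{pair_ld_table} with one row per pair
#'   and attribute \code{n_haplotypes}.
#' @export
syntenic_pairs <- function(h, max_distance_bp = 1e7) {
  h <- drop_monomorphic(h)
  chroms <- unique(h$map$chrom)
  out <- vector("list", length(chroms))
  for (k in seq_along(chroms)) {
    idx <- which(h$map$chrom == chroms[k])
    m <- length(idx)
    if (m < 2L) next
    pos <- h$map$pos_bp[idx]
    ij <- which(outer(pos, pos, function(a, b) b - a) > 0 &
                  outer(pos, pos, function(a, b) b - a) <= max_distance_bp,
                arr.ind = TRUE)
    if (nrow(ij) == 0L) next
    ij <- ij[order(ij[, 1L], ij[, 2L]), , drop = FALSE]
    r <- .pair_r_bulk(h$haplotypes[, idx, drop = FALSE], ij[, 1L], ij[, 2L])
    out[[k]] <- .pair_table(h, idx[ij[, 1L]], idx[ij[, 2L]], r)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) res <- .pair_table(h, integer(0), integer(0), numeric(0))
  rownames(res) <- NULL
  attr(res, "n_haplotypes") <- nrow(h$haplotypes)
  class(res) <- c("pair_ld_table", "data.frame")
  res
}

#' Adjacent-marker pairs with their LD
#'
#' Consecutive-marker pairs within each chromosome; a chromosome with n
#' markers contributes n - 1 pairs.
#'
#' @inheritParams syntenic_pairs
#' @return data.frame of class \code{pair_ld_table}.
#' @export
adjacent_pairs <- function(h) {
  h <- drop_monomorphic(h)
  chroms <- unique(h$map$chrom)
  out <- vector("list", length(chroms))
  for (k in seq_along(chroms)) {
    idx <- which(h$map$chrom == chroms[k])
    m <- length(idx)
    if (m < 2L) next
    i_loc <- seq_len(m - 1L)
    r <- .pair_r_bulk(h$haplotypes[, idx, drop = FALSE], i_loc, i_loc + 1L)
    out[[k]] <- .pair_table(h, idx[i_loc], idx[i_loc + 1L], r)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) res <- .pair_table(h, integer(0), integer(0), numeric(0))
  rownames(res) <- NULL
  attr(res, "n_haplotypes") <- nrow(h$haplotypes)
  class(res) <- c("pair_ld_table", "data.frame")
  res
}

#' Bin pairs by physical distance and summarise r-squared
#'
#' Half-open bins [k w, (k+1) w) from 0 up to \code{max_bp}; the default is
#' the decay analysis grid of 100 Kb bins up to 10 Mb. Empty bins are
#' reported with n_pairs = 0.
#'
#' @param pairs a \code{pair_ld_table}.
#' @param bin_width_bp bin width in bp.
#' @param max_bp upper end of the binning range.
#' @return data.frame with bin_lo_bp, bin_hi_bp, n_pairs, mean_r2, sd_r2.
#' @export
bin_by_distance <- function(pairs, bin_width_bp = 1e5, max_bp = 1e7) {
  edges <- seq(0, max_bp, by = bin_width_bp)
  n_bins <- length(edges) - 1L
  bin <- findInterval(pairs$distance_bp, edges,
                      rightmost.closed = FALSE, left.open = FALSE)
  inside <- bin >= 1L & bin <= n_bins & pairs$distance_bp < max_bp
  bin <- bin[inside]
  r2 <- pairs$r2[inside]
  n <- tabulate(bin, nbins = n_bins)
  mean_r2 <- rep(NA_real_, n_bins)
  sd_r2 <- rep(NA_real_, n_bins)
  if (length(bin)) {
    sums <- tapply(r2, factor(bin, levels = seq_len(n_bins)), mean)
    sds <- tapply(r2, factor(bin, levels = seq_len(n_bins)), stats::sd)
    mean_r2 <- as.numeric(sums)
    sd_r2 <- as.numeric(sds)
  }
  data.frame(bin_lo_bp = edges[-length(edges)], bin_hi_bp = edges[-1L],
             n_pairs = n, mean_r2 = mean_r2, sd_r2 = sd_r2)
}

#' Fraction of pairs with r-squared above a threshold
#'
#' @param pairs a \code{pair_ld_table} (nonempty).
#' @param threshold r-squared threshold; strictly-greater comparison.
#' @return fraction in [0, 1].
#' @export
proportion_above <- function(pairs, threshold) {
  if (nrow(pairs) == 0L) stop("empty pair list")
  mean(pairs$r2 > threshold)
}

#' Thin a marker panel by regular subsampling
#'
#' Keeps markers at indices offset + 1, offset + 1 + keep_every, ... within
#' each chromosome (thinning restarts at every chromosome), emulating the
#' construction of sparser commercial panels from a dense one.
#'
#' @param h a \code{\link{haplotype_set}}.
#' @param keep_every keep one marker in this many (1 = identity).
#' @param offset 0-based index of the first kept marker per chromosome.
#' @return a thinned \code{haplotype_set}.
#' @export
thin_panel <- function(h, keep_every, offset = 0L) {
  stopifnot(keep_every >= 1L, offset >= 0L)
  counts <- table(h$map$chrom)
  if (keep_every > max(counts))
    stop("keep_every exceeds every chromosome's marker count")
  keep <- unlist(lapply(split(seq_len(nrow(h$map)), h$map$chrom), function(ii) {
    sel <- seq(1L + offset, length(ii), by = keep_every)
    ii[sel[sel <= length(ii)]]
  }), use.names = FALSE)
  subset_markers(h, sort(keep))
}

#' Panel-thinning experiment
#'
#' For each thinning factor, thins the panel, recomputes adjacent-pair LD
#' and summarises: retained marker count and density, mean and SD of
#' adjacent r-squared, mean adjacent distance, and the percentage of
#' adjacent pairs with r-squared above 0.2 and 0.3.
#'
#' @param h a \code{\link{haplotype_set}}.
#' @param keep_every_list integer vector of thinning factors; the default
#'   1, 2, 4, 5, 6, 7, 14 spans 100% down to 7% panel density.
#' @param offset as in \code{\link{thin_panel}}.
#' @return data.frame with one row per density.
#' @export
thinning_experiment <- function(h, keep_every_list = c(1L, 2L, 4L, 5L, 6L, 7L, 14L),
                                offset = 0L) {
  rows <- lapply(keep_every_list, function(k) {
    hk <- thin_panel(h, k, offset)
    ap <- adjacent_pairs(hk)
    data.frame(
      keep_every = k,
      n_markers = nrow(hk$map),
      density_pct = 100 * nrow(hk$map) / nrow(h$map),
      mean_adj_r2 = mean(ap$r2),
      sd_adj_r2 = stats::sd(ap$r2),
      mean_adj_dist_bp = mean(ap$distance_bp),
      pct_r2_gt_0.2 = 100 * proportion_above(ap, 0.2),
      pct_r2_gt_0.3 = 100 * proportion_above(ap, 0.3)
    )
  })
  do.call(rbind, rows)
}
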