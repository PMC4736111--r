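#' Match two populations' LD pair tables on shared marker pairs
#'
#' Inner join on (chrom, pos_i, pos_j). Both tables must have been computed
#' under the shared allele coding of a common map, otherwise signed r is not
#' comparable across populations.
#'
#' @param pairsA,pairsB \code{pair_ld_table}s from the two populations.
#' @return data.frame with chrom, pos_i, pos_j, distance_bp, r_A, r_B.
#' @export
match_pairs <- function(pairsA, pairsB) {
  keyA <- paste(pairsA$chrom, pairsA$pos_i, pairsA$pos_j, sep = ":")
  keyB <- paste(pairsB$chrom, pairsB$pos_i, pairsB$pos_j, sep = ":")
  hit <- match(keyA, keyB)
  sel <- which(!is.na(hit))
  if (length(sel) == 0L) stop("no common markers between the two populations")
  data.frame(
    chrom = pairsA$chrom[sel],
    pos_i = pairsA$pos_i[sel],
    pos_j = pairsA$pos_j[sel],
    distance_bp = pairsA$distance_bp[sel],
    r_A = pairsA$r_signed[sel],
    r_B = pairsB$r_signed[hit[sel]],
    stringsAsFactors = FALSE
  )
}

#' Persistence of linkage phase between two populations
#'
#' Bins matched marker pairs by physical distance and computes, per bin, the
#' Pearson correlation of signed r between the populations
#' \deqn{R_{A,B} = \frac{\sum_p (r_{p(A)} - \bar r_A)(r_{p(B)} - \bar r_B)}
#'   {S_A S_B},}
#' together with the per-population means and SDs of signed r and the
#' fraction of pairs whose r signs disagree. Only marker pairs present in
#' both populations (markers common to both breeds) enter. Bins with fewer
#' than \code{min_pairs} matches are flagged undefined (NA correlation).
#'
#' @param pairsA,pairsB \code{pair_ld_table}s computed under a shared map.
#' @param bin_width_bp,max_bp binning grid (default 100 Kb bins to 10 Mb).
#' @param min_pairs minimum matched pairs for a defined correlation.
#' @return data.frame of class \code{phase_bins}: bin_lo_bp, bin_hi_bp,
#'   n_pairs, R_AB, mean_r_A, mean_r_B, sd_r_A, sd_r_B, reversed_fraction.
#' @export
phase_correlation <- function(pairsA, pairsB, bin_width_bp = 1e5,
                              max_bp = 1e7, min_pairs = 3L) {
  m <- match_pairs(pairsA, pairsB)
  edges <- seq(0, max_bp, by = bin_width_bp)
  n_bins <- length(edges) - 1L
  bin <- findInterval(m$distance_bp, edges)
  inside <- bin >= 1L & bin <= n_bins & m$distance_bp < max_bp
  m <- m[inside, , drop = FALSE]
  bin <- bin[inside]
  out <- data.frame(bin_lo_bp = edges[-length(edges)], bin_hi_bp = edges[-1L],
                    n_pairs = tabulate(bin, nbins = n_bins),
                    R_AB = NA_real_, mean_r_A = NA_real_, mean_r_B = NA_real_,
                    sd_r_A = NA_real_, sd_r_B = NA_real_,
                    reversed_fraction = NA_real_)
  for (b in unique(bin)) {
    sel <- bin == b
    rA <- m$r_A[sel]; rB <- m$r_B[sel]
    out$mean_r_A[b] <- mean(rA)
    out$mean_r_B[b] <- mean(rB)
    out$sd_r_A[b] <- stats::sd(rA)
    out$sd_r_B[b] <- stats::sd(rB)
    out$reversed_fraction[b] <- reversed_sign_fraction(rA, rB)
    if (sum(sel) >= min_pairs && stats::sd(rA) > 0 && stats::sd(rB) > 0)
      out$R_AB[b] <- stats::cor(rA, rB)
  }
  class(out) <- c("phase_bins", "data.frame")
  out
}

#' Fraction of matched pairs with reversed r signs
#'
#' A pair is reversed when the product of its signed r values in the two
#' populations is negative; pairs with r = 0 in either population count as
#' non-reversed.
#'
#' @param rA,rB matched signed-r vectors.
#' @return fraction in [0, 1].
#' @export
reversed_sign_fraction <- function(rA, rB) {
  if (length(rA) == 0L) return(NA_real_)
  mean(rA * rB < 0)
}
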