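#' Generation bins for the Ne history
#'
#' Past generations t are probed through marker pairs at genetic distance
#' c = 1/(2t): long-range LD reflects recent Ne, short-range LD ancient Ne.
#' The binning scheme widens as it moves into the past so each bin keeps
#' enough marker pairs: one-generation bins for t = 1..10 (range t +/- 0.5),
#' five-generation bins for t = 15, 20, ..., 100 (t +/- 2.5), and
#' fifty-generation bins for t = 150, 200, ..., 1000 (t +/- 25). Each
#' generation range maps to a c interval [1/(2 t_hi), 1/(2 t_lo)) Morgans.
#' Two mid-point conventions are reported: \code{mid_c} = 1/(2 t_target) and
#' \code{mid_c_arith} = the arithmetic mean of the c range.
#'
#' @return data.frame with t_target, t_lo, t_hi, c_lo, c_hi, mid_c,
#'   mid_c_arith, ordered by t.
#' @export
generation_bins <- function() {
  t_target <- c(1:10, seq(15, 100, by = 5), seq(150, 1000, by = 50))
  half <- c(rep(0.5, 10), rep(2.5, 18), rep(25, 18))
  t_lo <- t_target - half
  t_hi <- t_target + half
  data.frame(
    t_target = t_target, t_lo = t_lo, t_hi = t_hi,
    c_lo = 1 / (2 * t_hi), c_hi = 1 / (2 * t_lo),
    mid_c = 1 / (2 * t_target),
    mid_c_arith = (1 / (2 * t_hi) + 1 / (2 * t_lo)) / 2
  )
}

#' Physical distance to genetic distance
#'
#' Linear conversion at 1 Mb = 1 cM: c (Morgans) = bp * 1e-8.
#'
#' @param distance_bp physical distance in bp (positive).
#' @return genetic distance in Morgans.
#' @examples
#' morgans_from_bp(1e6)   # 0.01
#' morgans_from_bp(5e4)   # 5e-4
#' @export
morgans_from_bp <- function(distance_bp) {
  stopifnot(all(distance_bp > 0))
  distance_bp * 1e-8
}

#' Ne at one past generation from LD in the matching c range
#'
#' Selects pairs with genetic distance in [c_lo, c_hi) Morgans and
#' 0 < r-squared < 1, averages r-squared and c within the bin, and inverts
#' the drift-recombination equilibrium expectation
#' E(r2) = 1/(4 c Ne + 1):
#' \deqn{\hat N_{e,t} = \frac{1 - \bar r^2}{4 \bar c\, \bar r^2}.}
#'
#' With \code{sample_size_correction}, 1/n_haplotypes is subtracted from the
#' mean r-squared first, removing the finite-sample inflation of r-squared
#' (a sample of n gametes adds ~1/n even at linkage equilibrium). The
#' default is off, matching the estimator as usually printed; switch it on
#' when estimating from modest samples, where the inflation can exceed the
#' drift signal at long distances.
#'
#' @param pairs a \code{pair_ld_table} (compute with a distance cap wide
#'   enough for the bin, up to 100 Mb for recent generations).
#' @param bin one row of \code{\link{generation_bins}}.
#' @param sample_size_correction subtract 1/n_haplotypes from mean r2.
#' @param n_haplotypes gamete count; defaults to the table's attribute.
#' @return one-row data.frame: t_target, n_pairs, mean_r2, mean_c, ne
#'   (NA when the bin is empty or unusable).
#' @export
ne_at_generation <- function(pairs, bin, sample_size_correction = FALSE,
                             n_haplotypes = attr(pairs, "n_haplotypes")) {
  cc <- morgans_from_bp(pairs$distance_bp)
  sel <- cc >= bin$c_lo & cc < bin$c_hi & pairs$r2 > 0 & pairs$r2 < 1
  n <- sum(sel)
  if (n == 0L)
    return(data.frame(t_target = bin$t_target, n_pairs = 0L,
                      mean_r2 = NA_real_, mean_c = NA_real_, ne = NA_real_))
  mr2 <- mean(pairs$r2[sel])
  mc <- mean(cc[sel])
  r2_use <- mr2
  if (sample_size_correction) {
    if (is.null(n_haplotypes))
      stop("n_haplotypes needed for the sample-size correction")
    r2_use <- mr2 - 1 / n_haplotypes
  }
  ne <- if (r2_use > 0 && r2_use < 1) (1 - r2_use) / (4 * mc * r2_use) else NA_real_
  data.frame(t_target = bin$t_target, n_pairs = n, mean_r2 = mr2,
             mean_c = mc, ne = ne)
}

#' Historical effective population size trajectory from LD
#'
#' Applies \code{\link{ne_at_generation}} over the full generation-binning
#' scheme, giving one Ne estimate per past-generation bin.
#'
#' @inheritParams ne_at_generation
#' @param bins generation bins (default \code{\link{generation_bins}()}).
#' @return data.frame of class \code{ne_trajectory}, one row per bin,
#'   ordered by t; rows with no usable pairs carry NA estimates.
#' @export
ne_trajectory <- function(pairs, bins = generation_bins(),
                          sample_size_correction = FALSE,
                          n_haplotypes = attr(pairs, "n_haplotypes")) {
  rows <- lapply(seq_len(nrow(bins)), function(i) {
    ne_at_generation(pairs, bins[i, ], sample_size_correction, n_haplotypes)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ne_trajectory", "data.frame")
  out
}

#' @export
print.ne_trajectory <- function(x, ...) {
  usable <- !is.na(x$ne)
  cat("Ne trajectory over ", nrow(x), " generation bins (",
      sum(usable), " estimable)\n", sep = "")
  if (any(usable)) {
    recent <- x[usable, ][1L, ]
    cat("  most recent estimable generation t = ", recent$t_target,
        ": Ne = ", round(recent$ne), " (", recent$n_pairs, " pairs)\n",
        sep = "")
  }
  print.data.frame(utils::head(x[usable, ], 10L), row.names = FALSE,
                   digits = 4)
  invisible(x)
}

#' @export
plot.ne_trajectory <- function(x, ...) {
  ok <- !is.na(x$ne)
  graphics::plot(x$t_target[ok], x$ne[ok], log = "xy", type = "b", pch = 16,
                 xlab = "generations ago (t)", ylab = expression(hat(N)[e]), ...)
  invisible(x)
}

#' Expected r-squared under drift-recombination equilibrium
#'
#' E(r2) = 1/(4 c Ne + 1); the exact inverse of the estimator in
#' \code{\link{ne_at_generation}}.
#'
#' @param c_morgans genetic distance in Morgans.
#' @param ne effective population size.
#' @return expected r-squared.
#' @export
expected_r2 <- function(c_morgans, ne) 1 / (4 * c_morgans * ne + 1)
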