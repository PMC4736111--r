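#' Build ANCOVA model records from an LD pair table
#'
#' Attaches the response and design variables of the LD-heterogeneity
#' ANCOVA: r-squared as response, chromosome and breed as factors, and the
#' adjusted log distance d* = log10(d) - log10(dbar), where dbar is the mean
#' physical distance over the model's pooled input pairs (shared between
#' breeds, so both are measured on one scale).
#'
#' @param ... named \code{pair_ld_table}s, one per breed; names are the
#'   breed labels (e.g. \code{H = pairsH, B = pairsB}).
#' @param d_bar_bp optional fixed mean distance; by default computed from
#'   the pooled input.
#' @return data.frame with columns r2, chrom, breed, distance_bp, d_star and
#'   attribute \code{d_bar_bp}.
#' @export
ld_model_records <- function(..., d_bar_bp = NULL) {
  tabs <- list(...)
  if (is.null(names(tabs)) || any(names(tabs) == ""))
    stop("pair tables must be named by breed")
  rec <- do.call(rbind, lapply(names(tabs), function(b) {
    tt <- tabs[[b]]
    data.frame(r2 = tt$r2, chrom = as.character(tt$chrom), breed = b,
               distance_bp = tt$distance_bp, stringsAsFactors = FALSE)
  }))
  if (any(rec$distance_bp <= 0)) stop("all pair distances must be positive")
  if (is.null(d_bar_bp)) d_bar_bp <- mean(rec$distance_bp)
  rec$d_star <- log10(rec$distance_bp) - log10(d_bar_bp)
  attr(rec, "d_bar_bp") <- d_bar_bp
  rec
}

#' Fit the LD-heterogeneity analysis of covariance
#'
#' Ordinary least squares on r-squared with sum-to-zero contrasts for
#' chromosome and breed, so the intercept is the overall mean. Two model
#' orders are available:
#' \describe{
#'   \item{order 1 (adjacent-pair model)}{mu + chrom + breed + beta1 d* +
#'     chrom:breed — the model fitted to adjacent marker pairs.}
#'   \item{order 3 (all-syntenic-pair model)}{adds quadratic and cubic
#'     powers of d* and the full set of chromosome, breed and
#'     chromosome-by-breed interactions with every power.}
#' }
#' Marginal (type-III-style) F-tests are computed for each term by removing
#' that term's columns from the full design.
#'
#' @param records output of \code{\link{ld_model_records}}.
#' @param order 1 or 3.
#' @return object of class \code{ld_ancova}: the \code{lm} fit plus the
#'   model order, d_bar and factor levels; methods: \code{print},
#'   \code{summary}, \code{coef}, \code{predict}, \code{residuals},
#'   \code{fitted}, \code{anova}.
#' @export
ld_ancova <- function(records, order = 1L) {
  stopifnot(order %in% c(1L, 3L))
  dat <- data.frame(
    r2 = records$r2,
    chrom = factor(records$chrom),
    breed = factor(records$breed),
    d1 = records$d_star
  )
  if (nlevels(dat$breed) < 2L) stop("both breeds must be present")
  if (nlevels(dat$chrom) < 2L) stop("at least 2 chromosomes required")
  tab <- table(dat$chrom, dat$breed)
  if (any(tab == 0L)) {
    empty <- which(tab == 0L, arr.ind = TRUE)[1L, ]
    stop("rank deficiency: chromosome ", rownames(tab)[empty[1L]],
         " absent in breed ", colnames(tab)[empty[2L]])
  }
  ctr <- list(chrom = "contr.sum", breed = "contr.sum")
  if (order == 1L) {
    fml <- r2 ~ chrom + breed + d1 + chrom:breed
  } else {
    dat$d2 <- dat$d1^2
    dat$d3 <- dat$d1^3
    fml <- r2 ~ chrom * breed * d1 + chrom * breed * d2 + chrom * breed * d3
  }
  fit <- stats::lm(fml, data = dat, contrasts = ctr)
  structure(list(
    fit = fit,
    order = order,
    d_bar_bp = attr(records, "d_bar_bp"),
    chrom_levels = levels(dat$chrom),
    breed_levels = levels(dat$breed),
    distance_range_bp = range(records$distance_bp)
  ), class = "ld_ancova")
}

#' @export
print.ld_ancova <- function(x, ...) {
  cat("LD heterogeneity ANCOVA (order ", x$order, " in d* = log10 d - log10 d_bar)\n",
      "  d_bar = ", format(x$d_bar_bp, big.mark = ","), " bp; ",
      length(x$chrom_levels), " chromosomes x ",
      length(x$breed_levels), " breeds; n = ",
      length(stats::fitted(x$fit)), " pairs\n", sep = "")
  cat("  overall mean r2 (mu): ", signif(stats::coef(x$fit)[1L], 5), "\n", sep = "")
  invisible(x)
}

#' @export
coef.ld_ancova <- function(object, ...) stats::coef(object$fit)

#' @export
residuals.ld_ancova <- function(object, ...) stats::residuals(object$fit)

#' @export
fitted.ld_ancova <- function(object, ...) stats::fitted(object$fit)

#' Marginal F-tests for every model term
#'
#' For each term, refits the model without that term's design columns
#' (leaving all other columns in place) and reports the marginal sum of
#' squares, F statistic and p-value against the full-model residual.
#'
#' @param object an \code{ld_ancova}.
#' @param ... unused.
#' @return data.frame with one row per term.
#' @export
anova.ld_ancova <- function(object, ...) {
  fit <- object$fit
  X <- stats::model.matrix(fit)
  y <- stats::model.response(stats::model.frame(fit))
  asg <- attr(X, "assign")
  terms_lab <- attr(stats::terms(fit), "term.labels")
  rss_full <- sum(stats::residuals(fit)^2)
  df_res <- stats::df.residual(fit)
  rows <- lapply(seq_along(terms_lab), function(t) {
    drop_cols <- which(asg == t)
    red <- stats::lm.fit(X[, -drop_cols, drop = FALSE], y)
    ss <- sum(red$residuals^2) - rss_full
    df <- length(drop_cols)
    Fv <- (ss / df) / (rss_full / df_res)
    data.frame(term = terms_lab[t], df = df, sum_sq = ss, f_value = Fv,
               p_value = stats::pf(Fv, df, df_res, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
summary.ld_ancova <- function(object, ...) {
  out <- list(object = object, anova = anova(object),
              sigma = stats::sigma(object$fit))
  class(out) <- "summary.ld_ancova"
  out
}

#' @export
print.summary.ld_ancova <- function(x, ...) {
  print(x$object)
  cat("  residual SD: ", signif(x$sigma, 5), "\n\nMarginal F-tests:\n", sep = "")
  tab <- x$anova
  tab$sum_sq <- signif(tab$sum_sq, 5)
  tab$f_value <- signif(tab$f_value, 5)
  tab$p_value <- format.pval(tab$p_value, digits = 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Predict r-squared at given chromosome, breed and physical distance
#'
#' Evaluates the fitted chromosome-and-breed-specific polynomial in
#' d* = log10(d) - log10(d_bar) at the requested distances. Distances
#' outside the fitted range are flagged as extrapolation (with a warning).
#'
#' @param object an \code{ld_ancova}.
#' @param chrom,breed,distance_bp vectors (recycled to common length).
#' @param se.fit also return standard errors.
#' @param ... unused.
#' @return data.frame with chrom, breed, distance_bp, r2_pred,
#'   extrapolated (and se if requested).
#' @export
predict.ld_ancova <- function(object, chrom, breed, distance_bp,
                              se.fit = FALSE, ...) {
  n <- max(length(chrom), length(breed), length(distance_bp))
  chrom <- rep_len(as.character(chrom), n)
  breed <- rep_len(as.character(breed), n)
  distance_bp <- rep_len(distance_bp, n)
  d1 <- log10(distance_bp) - log10(object$d_bar_bp)
  nd <- data.frame(
    chrom = factor(chrom, levels = object$chrom_levels),
    breed = factor(breed, levels = object$breed_levels),
    d1 = d1
  )
  if (anyNA(nd$chrom) || anyNA(nd$breed))
    stop("chromosome or breed level not present in the fitted model")
  if (object$order == 3L) { nd$d2 <- d1^2; nd$d3 <- d1^3 }
  extrap <- distance_bp < object$distance_range_bp[1L] |
    distance_bp > object$distance_range_bp[2L]
  if (any(extrap))
    warning("prediction outside the fitted distance range (extrapolation)")
  pr <- stats::predict(object$fit, newdata = nd, se.fit = se.fit)
  out <- data.frame(chrom = chrom, breed = breed, distance_bp = distance_bp,
                    r2_pred = if (se.fit) pr$fit else pr,
                    extrapolated = extrap, stringsAsFactors = FALSE)
  if (se.fit) out$se <- pr$se.fit
  rownames(out) <- NULL
  out
}

#' Least-squares means of r-squared per chromosome
#'
#' Predicted marginal means at d* = 0 (i.e. at the mean inter-marker
#' distance), averaged over breed levels, with standard errors from the
#' fitted coefficient covariance.
#'
#' @param object an \code{ld_ancova}.
#' @return data.frame with chrom, ls_mean, se.
#' @export
ls_means_by_chromosome <- function(object) {
  fit <- object$fit
  V <- stats::vcov(fit)
  beta <- stats::coef(fit)
  grid <- expand.grid(chrom = factor(object$chrom_levels,
                                     levels = object$chrom_levels),
                      breed = factor(object$breed_levels,
                                     levels = object$breed_levels))
  grid$d1 <- 0
  if (object$order == 3L) { grid$d2 <- 0; grid$d3 <- 0 }
  X <- stats::model.matrix(stats::delete.response(stats::terms(fit)), grid,
                           contrasts.arg = fit$contrasts)
  nb <- length(object$breed_levels)
  rows <- lapply(seq_along(object$chrom_levels), function(i) {
    sel <- which(grid$chrom == object$chrom_levels[i])
    a <- colMeans(X[sel, , drop = FALSE])
    est <- sum(a * beta)
    se <- sqrt(drop(t(a) %*% V %*% a))
    data.frame(chrom = object$chrom_levels[i], ls_mean = est, se = se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Average inter-marker distance of a commercial panel
#'
#' Genome length divided by marker count, rounded half-up to integer Kb:
#' e.g. a 3,000 Mb genome over 150,000 markers gives 20 Kb; over 80,000
#' markers, 38 Kb; over 3,000 markers, 1000 Kb.
#'
#' @param n_markers marker count of the panel.
#' @param genome_mb genome length in Mb (default 3000, the bovine genome).
#' @return integer average spacing in Kb.
#' @export
panel_distance_kb <- function(n_markers, genome_mb = 3000) {
  if (any(n_markers <= 0)) stop("n_markers must be positive")
  as.integer(floor(genome_mb * 1000 / n_markers + 0.5))
}
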