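# Construct noise-free records from known sum-to-zero effects so OLS must
# recover them exactly.
make_model_records <- function(n_chrom = 3, beta = c(-0.1, 0, 0),
                               chrom_eff = NULL, breed_eff = 0.02,
                               mu = 0.3, seed = 1, n_per_cell = 25) {
  set.seed(seed)
  if (is.null(chrom_eff)) {
    chrom_eff <- seq(-0.05, 0.05, length.out = n_chrom)
    chrom_eff <- chrom_eff - mean(chrom_eff)
  }
  grid <- expand.grid(chrom = as.character(seq_len(n_chrom)),
                      breed = c("B", "H"), rep = seq_len(n_per_cell),
                      stringsAsFactors = FALSE)
  grid$distance_bp <- round(10^runif(nrow(grid), 4.2, 6.7))
  d_bar <- mean(grid$distance_bp)
  d1 <- log10(grid$distance_bp) - log10(d_bar)
  ci <- chrom_eff[as.integer(grid$chrom)]
  bj <- ifelse(grid$breed == "B", breed_eff, -breed_eff)
  grid$r2 <- mu + ci + bj + beta[1] * d1 + beta[2] * d1^2 + beta[3] * d1^3
  rec <- data.frame(r2 = grid$r2, chrom = grid$chrom, breed = grid$breed,
                    distance_bp = grid$distance_bp,
                    d_star = d1, stringsAsFactors = FALSE)
  attr(rec, "d_bar_bp") <- d_bar
  attr(rec, "truth") <- list(mu = mu, chrom_eff = chrom_eff,
                             breed_eff = breed_eff, beta = beta)
  rec
}

test_that("adjacent-pair ANCOVA recovers generating coefficients exactly", {
  rec <- make_model_records(beta = c(-0.1, 0, 0))
  fit <- ld_ancova(rec, order = 1L)
  truth <- attr(rec, "truth")
  cf <- coef(fit)
  expect_equal(unname(cf["(Intercept)"]), truth$mu, tolerance = 1e-8)
  expect_equal(unname(cf["d1"]), -0.1, tolerance = 1e-8)
  # sum-to-zero chromosome effects: first n-1 coefficients
  expect_equal(unname(cf[c("chrom1", "chrom2")]), truth$chrom_eff[1:2],
               tolerance = 1e-8)
  expect_equal(unname(cf["breed1"]), truth$breed_eff, tolerance = 1e-8)
  # interaction absent from the generating model -> 0
  expect_lt(max(abs(cf[grep("chrom.:breed", names(cf))])), 1e-8)
  expect_lt(max(abs(residuals(fit))), 1e-8)
})

test_that("constant response collapses to mu with all effects zero", {
  rec <- make_model_records(beta = c(0, 0, 0), chrom_eff = rep(0, 3),
                            breed_eff = 0, mu = 0.25)
  fit <- ld_ancova(rec, order = 1L)
  cf <- coef(fit)
  expect_equal(unname(cf["(Intercept)"]), 0.25, tolerance = 1e-10)
  expect_lt(max(abs(cf[-1])), 1e-10)
})

test_that("cubic model recovers a cubic generating surface and nests order 1", {
  rec <- make_model_records(beta = c(-0.12, 0.03, -0.01), seed = 3)
  fit3 <- ld_ancova(rec, order = 3L)
  cf <- coef(fit3)
  expect_equal(unname(cf["d1"]), -0.12, tolerance = 1e-6)
  expect_equal(unname(cf["d2"]), 0.03, tolerance = 1e-6)
  expect_equal(unname(cf["d3"]), -0.01, tolerance = 1e-6)
  expect_lt(max(abs(residuals(fit3))), 1e-6)

  # first-order generating model: order-3 fit finds zero higher terms and
  # reproduces the order-1 predictions
  rec1 <- make_model_records(beta = c(-0.1, 0, 0), seed = 4)
  f1 <- ld_ancova(rec1, order = 1L)
  f3 <- ld_ancova(rec1, order = 3L)
  expect_lt(abs(coef(f3)["d2"]), 1e-8)
  expect_lt(abs(coef(f3)["d3"]), 1e-8)
  grid_d <- c(2e4, 1e5, 5e5, 2e6)
  p1 <- predict(f1, "1", "B", grid_d)
  p3 <- predict(f3, "1", "B", grid_d)
  expect_equal(p3$r2_pred, p1$r2_pred, tolerance = 1e-8)
})

test_that("fits are invariant to record order and to distance rescaling", {
  rec <- make_model_records(beta = c(-0.1, 0, 0), seed = 5)
  set.seed(9); perm <- sample(nrow(rec))
  recp <- rec[perm, ]
  attr(recp, "d_bar_bp") <- attr(rec, "d_bar_bp")
  f1 <- ld_ancova(rec, order = 1L)
  f2 <- ld_ancova(recp, order = 1L)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-10)

  # multiplying all distances by a constant shifts log10(d) and log10(d_bar)
  # equally: d* and hence the fit are unchanged (log-ratio property)
  tabs <- list(B = data.frame(r2 = rec$r2[rec$breed == "B"],
                              chrom = rec$chrom[rec$breed == "B"],
                              distance_bp = rec$distance_bp[rec$breed == "B"]),
               H = data.frame(r2 = rec$r2[rec$breed == "H"],
                              chrom = rec$chrom[rec$breed == "H"],
                              distance_bp = rec$distance_bp[rec$breed == "H"]))
  r_orig <- do.call(ld_model_records, tabs)
  tabs_scaled <- lapply(tabs, function(tt) {
    tt$distance_bp <- tt$distance_bp * 10; tt
  })
  r_scaled <- do.call(ld_model_records, tabs_scaled)
  expect_equal(r_orig$d_star, r_scaled$d_star, tolerance = 1e-12)
  expect_equal(coef(ld_ancova(r_orig)), coef(ld_ancova(r_scaled)),
               tolerance = 1e-10)
})

test_that("residual orthogonality X'e = 0 holds on noisy fits", {
  rec <- make_model_records(seed = 6)
  rec$r2 <- rec$r2 + rnorm(nrow(rec), 0, 0.02)
  for (ord in c(1L, 3L)) {
    fit <- ld_ancova(rec, order = ord)
    X <- model.matrix(fit$fit)
    expect_lt(max(abs(crossprod(X, residuals(fit)))), 1e-8)
  }
})

test_that("LS means equal mu + chrom effect and match a brute-force grid", {
  rec <- make_model_records(beta = c(-0.1, 0, 0), seed = 7)
  truth <- attr(rec, "truth")
  fit <- ld_ancova(rec, order = 1L)
  # zero residual variance triggers base R's "essentially perfect fit" note
  lsm <- suppressWarnings(ls_means_by_chromosome(fit))
  expect_equal(lsm$ls_mean, truth$mu + truth$chrom_eff, tolerance = 1e-8)
  # brute force: predict on the chrom x breed grid at d* = 0 and average
  brute <- vapply(fit$chrom_levels, function(ch) {
    mean(predict(fit, ch, fit$breed_levels,
                 rep(fit$d_bar_bp, 2))$r2_pred)
  }, numeric(1))
  expect_equal(lsm$ls_mean, unname(brute), tolerance = 1e-10)
  # opposite breed effects cancel in the marginal mean by construction
  expect_false(any(is.na(lsm$se)))
})

test_that("rank-deficient designs are rejected with the offending cell named", {
  rec <- make_model_records(seed = 8)
  rec <- rec[!(rec$chrom == "2" & rec$breed == "H"), ]
  attr(rec, "d_bar_bp") <- mean(rec$distance_bp)
  expect_error(ld_ancova(rec), "chromosome 2 absent in breed H")
  rec1 <- make_model_records(seed = 8)
  rec1b <- rec1[rec1$breed == "B", ]
  attr(rec1b, "d_bar_bp") <- mean(rec1b$distance_bp)
  expect_error(ld_ancova(rec1b), "both breeds")
})

test_that("panel spacing arithmetic matches the commercial panel grid", {
  expect_equal(panel_distance_kb(150000), 20L)
  expect_equal(panel_distance_kb(80000), 38L)   # 37.5 rounds half-up
  expect_equal(panel_distance_kb(50000), 60L)
  expect_equal(panel_distance_kb(20000), 150L)
  expect_equal(panel_distance_kb(8000), 375L)
  expect_equal(panel_distance_kb(3000), 1000L)
  expect_error(panel_distance_kb(0), "positive")
})

test_that("predictions evaluate the fitted polynomial and flag extrapolation", {
  rec <- make_model_records(beta = c(-0.12, 0.03, -0.01), seed = 10)
  truth <- attr(rec, "truth")
  fit <- ld_ancova(rec, order = 3L)
  d_bar <- fit$d_bar_bp
  # at d = d_bar, d* = 0: prediction = mu + c_i + b_j (+ zero interaction)
  p <- predict(fit, "1", "B", d_bar)
  expect_equal(p$r2_pred, truth$mu + truth$chrom_eff[1] + truth$breed_eff,
               tolerance = 1e-6)
  # closed-form polynomial at arbitrary distance
  d <- 3e5
  ds <- log10(d) - log10(d_bar)
  closed <- truth$mu + truth$chrom_eff[2] - truth$breed_eff +
    truth$beta[1] * ds + truth$beta[2] * ds^2 + truth$beta[3] * ds^3
  expect_equal(predict(fit, "2", "H", d)$r2_pred, closed, tolerance = 1e-6)
  expect_warning(predict(fit, "1", "B", 1e9), "extrapolation")
  # monotone decay over the panel grid on a monotone generating model
  recm <- make_model_records(beta = c(-0.1, 0, 0), seed = 11)
  fm <- ld_ancova(recm, order = 3L)
  pg <- predict(fm, "1", "B", c(2e4, 3.8e4, 6e4, 1.5e5, 3.75e5, 1e6))
  expect_true(all(diff(pg$r2_pred) < 0))
})
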