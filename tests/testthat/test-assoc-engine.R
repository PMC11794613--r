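test_that("the design matrix standardises, encodes categoricals and reports collinearity", {
  covs <- make_covariates(200, seed = 1)
  des <- design_spec(stats::rnorm(200), covs)
  expect_equal(mean(des$X[, "factor"]), 0, tolerance = 1e-12)
  expect_equal(stats::sd(des$X[, "factor"]), 1, tolerance = 1e-12)
  expect_equal(stats::sd(des$X[, "age"]), 1, tolerance = 1e-12)
  expect_true(all(paste0("PC", 1:10) %in% colnames(des$X)))
  expect_true(any(grepl("^device", colnames(des$X))))
  expect_true(any(grepl("^eye", colnames(des$X))))
  # a covariate duplicating the factor is flagged by name
  covs2 <- covs
  covs2$height <- covs2$age     # exact collinearity after standardisation
  expect_error(design_spec(stats::rnorm(200), covs2), "collinear")
  # missing covariates are dropped and counted
  covs3 <- covs
  covs3$height[1:7] <- NA
  des3 <- design_spec(stats::rnorm(200), covs3)
  expect_equal(des3$n_dropped, 7)
  expect_equal(nrow(des3$X), 193)
})

test_that("mass OLS recovers self-association, planted effects, and stays calibrated", {
  covs <- make_covariates(500, seed = 2)
  restore <- retinagrid:::scoped_seed(3)
  on.exit(restore(), add = TRUE)
  Y <- matrix(stats::rnorm(500 * 200), 500, 200)
  # factor = copy of pixel 1: beta 1 on the standardised scale, p ~ 0
  fac <- Y[, 1]
  des <- design_spec(fac, covs)
  fit <- fit_mass_linear(Y, des)
  expect_equal(fit$beta[1] * stats::sd(fac), stats::sd(fac) * 1,
               tolerance = 0.05)
  expect_lt(fit$p_ord[1], 1e-100)
  # permuted factor on null pixels: p uniform
  fitn <- fit_mass_linear(Y[, -1], design_spec(sample(fac), covs))
  ks <- stats::ks.test(fitn$p_ord, "punif")
  expect_gt(ks$p.value, 0.01)
  # planted annulus effect of 0.3 SD recovered within 0.05 at n = 2000
  covs2 <- make_covariates(2000, seed = 4)
  f2 <- stats::rnorm(2000)
  Y2 <- matrix(stats::rnorm(2000 * 100), 2000, 100)
  Y2[, 1:40] <- Y2[, 1:40] + 0.3 * f2
  fit2 <- fit_mass_linear(Y2, design_spec(f2, covs2))
  expect_lt(abs(mean(fit2$beta[1:40]) - 0.3), 0.05)
  expect_lt(abs(mean(fit2$beta[41:100])), 0.05)
})

test_that("engine output is invariant to joint permutation and equivariant to outcome scaling", {
  covs <- make_covariates(150, seed = 5)
  restore <- retinagrid:::scoped_seed(6)
  on.exit(restore(), add = TRUE)
  Y <- matrix(stats::rnorm(150 * 40), 150, 40)
  fac <- stats::rnorm(150)
  f1 <- fit_mass_linear(Y, design_spec(fac, covs))
  perm <- sample(150)
  f2 <- fit_mass_linear(Y[perm, ], design_spec(fac[perm], covs[perm, ]))
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
  expect_equal(f1$p_ord, f2$p_ord, tolerance = 1e-10)
  f3 <- fit_mass_linear(2 * Y, design_spec(fac, covs))
  expect_equal(f3$beta, 2 * f1$beta, tolerance = 1e-10)
  expect_equal(f3$t_ord, f1$t_ord, tolerance = 1e-10)
})

test_that("variance moderation handles the degenerate, limit, and estimable cases", {
  base <- list(beta = rep(1, 50), se = rep(0.1, 50), sigma2 = rep(2, 50),
               df = 30, t_ord = rep(10, 50), p_ord = rep(0, 50),
               stdev_unscaled = 0.1 / sqrt(2), coef = "factor")
  class(base) <- "mass_fit"
  # all sigma2 identical: shrinkage is a no-op
  m <- moderate_variances(base)
  expect_equal(m$s2_shrunk, base$sigma2, tolerance = 1e-9)
  expect_equal(m$t_mod, base$t_ord)
  # d0 = 0: moderated t equals ordinary t exactly
  restore <- retinagrid:::scoped_seed(7)
  on.exit(restore(), add = TRUE)
  v <- 2 * stats::rf(100, 30, 8)
  fit <- base
  fit$sigma2 <- v
  fit$se <- fit$stdev_unscaled * sqrt(v)
  fit$t_ord <- fit$beta / fit$se
  m0 <- moderate_variances(fit, d0 = 0)
  expect_equal(m0$t_mod, fit$t_ord, tolerance = 1e-12)
  expect_equal(m0$df_total, fit$df)
  # prior recovery from the scaled-F model at 20,000 pixels
  s2 <- 2 * stats::rf(20000, 30, 4)
  fit2 <- base
  fit2$sigma2 <- s2
  fit2$se <- fit2$stdev_unscaled * sqrt(s2)
  m2 <- moderate_variances(fit2)
  expect_lt(abs(m2$d0 - 4) / 4, 0.10)
  expect_lt(abs(m2$s0_2 - 2) / 2, 0.10)
})

test_that("moderated statistics match the reference empirical-Bayes implementation", {
  skip_if_not_installed("limma")
  covs <- make_covariates(120, seed = 8)
  restore <- retinagrid:::scoped_seed(9)
  on.exit(restore(), add = TRUE)
  Y <- matrix(stats::rnorm(120 * 300), 120, 300)
  Y <- sweep(Y, 2, sqrt(2 * stats::rf(300, 94, 6)), `*`)  # heteroskedastic
  des <- design_spec(stats::rnorm(120), covs)
  mod <- moderate_variances(fit_mass_linear(Y, des))
  eb <- limma::eBayes(limma::lmFit(t(Y[des$keep, ]), des$X))
  j <- match("factor", colnames(des$X))
  expect_lt(abs(mod$d0 - eb$df.prior) / eb$df.prior, 0.01)
  expect_lt(abs(mod$s0_2 - eb$s2.prior) / eb$s2.prior, 0.01)
  expect_lt(max(abs(mod$t_mod - eb$t[, j])), 1e-6)
  expect_lt(max(abs(mod$p_mod - eb$p.value[, j])), 1e-8)
})

test_that("p-value adjustment implements the three schemes", {
  expect_equal(adjust_pvalues(0.01, "bonferroni_global"), 0.01)
  p <- matrix(c(0.01, 0.4, 0.03, 1), 2, 2)
  expect_equal(adjust_pvalues(p, "bonferroni_global"),
               matrix(pmin(1, 4 * c(0.01, 0.4, 0.03, 1)), 2, 2))
  # hand BH on (0.01, 0.02, 0.03, 0.04) -> all 0.04
  expect_equal(as.vector(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04),
                                        "bh_global")),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(rep(1, 6), "bh_global"), rep(1, 6))
  # within-factor BH operates column-wise
  pw <- cbind(c(0.01, 0.02), c(0.5, 1))
  aw <- adjust_pvalues(pw, "bh_within_factor")
  expect_equal(aw[, 1], stats::p.adjust(pw[, 1], "BH"))
  expect_equal(aw[, 2], stats::p.adjust(pw[, 2], "BH"))
  expect_error(adjust_pvalues(c(0.01), "bh_within_factor"), "matrix")
  # BH equals the step-up oracle on every ordering of short lists
  restore <- retinagrid:::scoped_seed(10)
  on.exit(restore(), add = TRUE)
  for (i in 1:20) {
    p <- stats::runif(sample(3:8, 1))
    expect_equal(as.vector(adjust_pvalues(p, "bh_global")), oracle_bh(p),
                 tolerance = 1e-12)
  }
})

test_that("factor summaries reduce the per-pixel fields correctly", {
  fit <- list(beta = c(2, 2, -1, 0.5, 3, -2), sigma2 = rep(1, 6), df = 20,
              se = rep(0.1, 6), stdev_unscaled = 0.1, coef = "factor",
              t_ord = rep(1, 6), p_ord = rep(0.5, 6),
              d0 = 4, s0_2 = 1, s2_shrunk = rep(1, 6),
              t_mod = rep(1, 6),
              p_mod = c(1e-6, 1e-5, 0.2, 0.9, 1e-4, 0.8), df_total = 24)
  class(fit) <- c("moderated_fit", "mass_fit")
  s <- summarize_factor(fit, alpha = 0.05)
  padj <- stats::p.adjust(fit$p_mod, "BH")
  expect_equal(s$n_sig, sum(padj < 0.05))
  expect_equal(s$mean_beta_sig, mean(fit$beta[padj < 0.05]))
  expect_equal(s$mean_beta_all, mean(fit$beta))
  expect_equal(s$median_log10p, stats::median(-log10(fit$p_mod)))
  # no significant pixel: summary (ii) missing
  fit$p_mod <- rep(0.9, 6)
  s0 <- summarize_factor(fit, alpha = 0.05)
  expect_equal(s0$n_sig, 0)
  expect_true(is.na(s0$mean_beta_sig))
})

test_that("interaction scans are calibrated under the null and directional when planted", {
  covs <- make_covariates(1500, seed = 11)
  restore <- retinagrid:::scoped_seed(12)
  on.exit(restore(), add = TRUE)
  fac <- stats::rnorm(1500)
  # null: no interaction anywhere; BH at 5% yields few discoveries
  Y0 <- matrix(stats::rnorm(1500 * 150), 1500, 150)
  isc0 <- suppressWarnings(interaction_scan(Y0, fac, covs))
  expect_lte(isc0$n_sig_interaction, 8)
  # planted positive main effect and positive interaction on an annulus
  age_std <- as.numeric(scale(covs$age))
  Y1 <- Y0
  Y1[, 1:60] <- Y1[, 1:60] + 0.4 * fac + 0.35 * fac * age_std
  isc1 <- suppressWarnings(interaction_scan(Y1, fac, covs))
  expect_gt(isc1$n_sig_interaction, 30)
  expect_gt(isc1$sign_agreement, 0.95)
  covs_const <- covs
  covs_const$age <- 50
  expect_error(interaction_scan(Y0, fac, covs_const), "constant")
})

test_that("FPC association uses the same engine and the 1% FDR convention", {
  covs <- make_covariates(400, seed = 13)
  restore <- retinagrid:::scoped_seed(14)
  on.exit(restore(), add = TRUE)
  scores <- matrix(stats::rnorm(400 * 6), 400, 6)
  # factor equal to FPC1 scores: overwhelming signal on component 1
  res <- associate_fpcs(scores, scores[, 1], covs)
  expect_true(res$significant[1])
  expect_lt(res$fit$p_mod[1], 1e-100)
  # engine equivalence: same betas as a 1-pixel mass fit
  fac <- stats::rnorm(400)
  res2 <- associate_fpcs(scores, fac, covs)
  one <- fit_mass_linear(scores[, 2, drop = FALSE], design_spec(fac, covs))
  expect_equal(unname(res2$fit$beta[2]), unname(one$beta[1]),
               tolerance = 1e-12)
  # null factor: about 1% of many components flagged
  big <- matrix(stats::rnorm(400 * 500), 400, 500)
  res3 <- suppressWarnings(associate_fpcs(big, stats::rnorm(400), covs))
  expect_lte(mean(res3$significant), 0.03)
})

test_that("effect-map comparison honours pixel-set modes and correlation variants", {
  m <- stats::rnorm(200)
  expect_equal(compare_effect_maps(m, m), 1)
  expect_equal(compare_effect_maps(m, -m), -1)
  expect_equal(compare_effect_maps(m, m, method = "spearman"), 1)
  sig_a <- c(rep(TRUE, 50), rep(FALSE, 150))
  m2 <- m; m2[!sig_a] <- stats::rnorm(150)
  expect_equal(compare_effect_maps(m, m2, "a_significant", sig_a = sig_a), 1)
  expect_equal(compare_effect_maps(m, m2, "both_significant",
                                   sig_a = sig_a, sig_b = sig_a), 1)
  # independent null maps rarely exceed 4/sqrt(n)
  restore <- retinagrid:::scoped_seed(15)
  on.exit(restore(), add = TRUE)
  exceed <- mean(vapply(1:200, function(i) {
    abs(compare_effect_maps(stats::rnorm(400), stats::rnorm(400))) >
      4 / sqrt(400)
  }, logical(1)))
  expect_lte(exceed, 0.05)
})
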