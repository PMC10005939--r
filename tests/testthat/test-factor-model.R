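# DWLS common-factor fitting, fit statistics, model comparison, Heywood
# correction, and the per-SNP factor GWAS

test_that("exact one-factor structure is recovered to machine precision", {
  cov <- fixture_exact_cov(lambda = c(0.8, 1, 0.6, 0.4), phi = 0.05)
  fit <- fit_common_factor(cov, marker = "trait2")
  expect_lt(max(abs(fit$loadings - c(0.8, 1, 0.6, 0.4))), 1e-6)
  expect_lt(abs(fit$factor_var - 0.05), 1e-6)
  expect_lt(max(abs(fit$residuals - c(0.010, 0.008, 0.012, 0.009))), 1e-6)
  expect_lt(fit$fit_stats$chi2, 1e-8)
  expect_equal(fit$fit_stats$cfi, 1)
  expect_lt(fit$fit_stats$srmr, 1e-7)
  expect_false(fit$heywood_corrected)
  # standardized loading^2 + standardized residual = 1 per indicator
  sig <- fit$factor_var * tcrossprod(fit$loadings) + diag(fit$residuals)
  expect_equal(fit$std_loadings^2 + fit$residuals / diag(sig),
               rep(1, 4), ignore_attr = TRUE)
})

test_that("four-indicator model has df = 2 and AIC = chi2 + 2k", {
  cov <- fixture_exact_cov()
  # perturb off-diagonals off the rank-1 manifold (diagonal shifts would be
  # absorbed by the residual variances)
  cov$S[1, 2] <- cov$S[2, 1] <- cov$S[1, 2] + 2e-3
  cov$S[3, 4] <- cov$S[4, 3] <- cov$S[3, 4] - 1e-3
  fit <- fit_common_factor(cov, marker = "trait2")
  expect_identical(fit$n_free, 8L)
  expect_identical(fit$fit_stats$df, 2L)
  expect_equal(fit$fit_stats$aic, fit$fit_stats$chi2 + 16)
  expect_gt(fit$fit_stats$chi2, 0)
})

test_that("three indicators give a saturated model with chi2 ~ 0", {
  lam <- c(0.9, 1, 0.5)
  S <- 0.04 * tcrossprod(lam) + diag(c(0.02, 0.015, 0.03))
  # asymmetric S perturbation is impossible; any admissible S fits exactly
  S[1, 2] <- S[2, 1] <- S[1, 2] * 1.1
  nms <- paste0("t", 1:3)
  dimnames(S) <- list(nms, nms)
  set.seed(1)
  V <- 1e-5 * diag(6)
  cov <- structure(list(traits = nms, S = S, V = V, intercepts = diag(3),
                        m = NA, n_blocks = NA), class = "cov_struct")
  fit <- fit_common_factor(cov, marker = "t2")
  expect_identical(fit$fit_stats$df, 0L)
  expect_lt(fit$fit_stats$chi2, 1e-6)
})

test_that("Heywood case triggers a bounded refit with a zero residual", {
  cov <- fixture_exact_cov(theta = c(0.010, 0.008, 0.012, -0.004))
  unbounded <- fit_common_factor(cov, marker = "trait2", bound_residuals = FALSE)
  expect_lt(unbounded$residuals[4], 0)
  expect_false(unbounded$heywood_corrected)
  fit <- fit_common_factor(cov, marker = "trait2", bound_residuals = TRUE)
  expect_true(fit$heywood_corrected)
  expect_gte(min(fit$residuals), 0)
  expect_lt(fit$residuals[4], 1e-8)
  # bounded optimum cannot beat the unconstrained one
  expect_gte(fit$objective, unbounded$objective - 1e-12)
})

test_that("standardized quantities are invariant to indicator rescaling", {
  cov <- fixture_exact_cov()
  cov$S[1, 3] <- cov$S[3, 1] <- cov$S[1, 3] + 1e-3
  fit1 <- fit_common_factor(cov, marker = "trait2")
  # unit change on indicator 1: variance x c^2, covariances x c
  cc <- 2.5
  k <- 4
  scale_vec <- rep(1, k); scale_vec[1] <- cc
  D <- diag(scale_vec)
  cov2 <- cov
  cov2$S <- D %*% cov$S %*% D
  dimnames(cov2$S) <- dimnames(cov$S)
  g <- sfactor::vech(tcrossprod(scale_vec))
  cov2$V <- cov$V * outer(g, g)
  fit2 <- fit_common_factor(cov2, marker = "trait2")
  expect_equal(fit2$std_loadings, fit1$std_loadings, tolerance = 1e-6)
  expect_equal(fit2$fit_stats$cfi, fit1$fit_stats$cfi, tolerance = 1e-6)
  expect_equal(fit2$fit_stats$srmr, fit1$fit_stats$srmr, tolerance = 1e-6)
})

test_that("model comparison demands dominance on AIC, SRMR and CFI", {
  mk <- function(aic, srmr, cfi)
    structure(list(fit_stats = list(aic = aic, srmr = srmr, cfi = cfi)),
              class = "factor_fit")
  # headline comparison: lower AIC, lower SRMR, higher CFI wins
  cmp <- compare_models(list(model1 = mk(16.21, 0.024, 1.00),
                             model2 = mk(19.14, 0.025, 0.999)))
  expect_identical(cmp$decision, "model1")
  # identical fits tie
  cmp2 <- compare_models(list(a = mk(10, 0.02, 0.99), b = mk(10, 0.02, 0.99)))
  expect_identical(cmp2$decision, "indeterminate")
  # split criteria: indeterminate with a per-criterion breakdown
  cmp3 <- compare_models(list(a = mk(10, 0.05, 0.99), b = mk(12, 0.02, 0.99)))
  expect_identical(cmp3$decision, "indeterminate")
  expect_identical(unname(cmp3$criterion_winners["aic"]), "a")
  expect_identical(unname(cmp3$criterion_winners["srmr"]), "b")
})

test_that("AIC ordering is invariant to the identification marker", {
  cov <- fixture_exact_cov()
  cov$S[1, 2] <- cov$S[2, 1] <- cov$S[1, 2] + 2e-3
  aics <- vapply(cov$traits, function(mk)
    fit_common_factor(cov, marker = mk)$fit_stats$aic, 0)
  expect_lt(diff(range(aics)), 1e-4)
})

test_that("factor GWAS is exact under proportional effects and calibrated under the null", {
  cov <- fixture_exact_cov()
  fit <- fit_common_factor(cov, marker = "trait2")
  lam <- fit$loadings
  m <- 500
  b_true <- rnorm(m, 0, 0.01)
  n <- 1e5
  traits <- lapply(seq_len(4), function(t) {
    data.frame(snp = paste0("rs", 1:m), a1 = "A", a2 = "G",
               z = sqrt(n) * lam[t] * b_true, n = n,
               beta = lam[t] * b_true, se = 1 / sqrt(n))
  })
  names(traits) <- cov$traits
  g <- factor_gwas(cov, traits, fit, error_cor = NULL)
  expect_lt(max(abs(g$beta - b_true)), 1e-6)

  # null per-trait effects: beta ~ 0, p uniform
  set.seed(5)
  traits0 <- lapply(seq_len(4), function(t) {
    z <- rnorm(m)
    data.frame(snp = paste0("rs", 1:m), a1 = "A", a2 = "G",
               z = z, n = n, beta = z / sqrt(n), se = 1 / sqrt(n))
  })
  names(traits0) <- cov$traits
  g0 <- factor_gwas(cov, traits0, fit, error_cor = NULL)
  expect_lt(abs(mean(g0$p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / m))
  expect_lt(abs(mean(g0$z^2) - 1), 4 * sqrt(2 / m))

  # a variant missing in one trait is skipped and counted
  traits_na <- traits0
  traits_na[[2]]$beta[10] <- NA
  g_na <- factor_gwas(cov, traits_na, fit, error_cor = NULL)
  expect_identical(attr(g_na, "n_skipped"), 1L)
  expect_false("rs10" %in% g_na$snp)
})

test_that("factor GWAS recovers generating factor effects end to end", {
  ld <- fixture_ld(5000)
  ss <- fixture_sumstats(ld, seed = 83, n = 2e5)
  cs <- genetic_covariance(ss, ld, chi2_cap = FALSE)
  fit <- fit_common_factor(cs, marker = 2)
  g <- factor_gwas(cs, ss, fit)
  tm <- true_model(5000, loadings = c(0.9, 1, 0.7, 0.5), residual_h2 = 0.01,
                   factor_h2 = 0.076, pi_c = 0.005, seed = 83)
  beta_f <- attr(simulate_factor_architecture(tm), "beta_factor")
  marg <- sfactor:::ld_convolve(ld, matrix(beta_f))[match(g$snp, ld$variants$snp)]
  expect_gt(cor(g$beta, marg), 0.9)
  # effective N lies within the indicator N range
  expect_true(all(g$n > 0 & g$n <= 4 * 2e5))
})
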