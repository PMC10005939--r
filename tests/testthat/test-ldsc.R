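# LD-score regression: calibration, recovery, multivariable covariance
# consistency, and stratified enrichment

test_that("null simulation: h2 near 0 and intercept near 1", {
  ld <- fixture_ld(20000)
  tm <- true_model(20000, loadings = 1, factor_h2 = 0, pi_c = 0)
  s <- simulate_sumstats(tm, ld, n_per_trait = 1e5, seed = 31)[[1]]
  h <- estimate_h2(s, ld)
  expect_lt(abs(h$h2), 2 * h$se)
  expect_lt(abs(h$intercept - 1), 2 * h$intercept_se)
  expect_gt(h$se, 0)
})

test_that("h2 recovery at the aggregate-trait scale", {
  ld <- fixture_ld(20000)
  tm <- true_model(20000, loadings = 1, factor_h2 = 0.076, pi_c = 0.005,
                   seed = 1)
  s <- simulate_sumstats(tm, ld, n_per_trait = 1.2e5, seed = 1)[[1]]
  h <- estimate_h2(s, ld, chi2_cap = FALSE)
  expect_lt(abs(h$h2 - 0.076), 2 * h$se)
  expect_lt(h$p, 0.05)
})

test_that("rg is symmetric, unity on self, and recovers the generating value", {
  ld <- fixture_ld(8000)
  ss <- fixture_sumstats(ld, seed = 17, n = 1.2e5)
  r12 <- estimate_rg(ss[[1]], ss[[2]], ld, chi2_cap = FALSE)
  r21 <- estimate_rg(ss[[2]], ss[[1]], ld, chi2_cap = FALSE)
  expect_equal(r12$rg, r21$rg, tolerance = 1e-12)
  expect_equal(r12$se, r21$se, tolerance = 1e-12)

  rself <- estimate_rg(ss[[1]], ss[[1]], ld, chi2_cap = FALSE)
  expect_equal(rself$rg, 1)

  # pure-factor traits: population rg = 1
  tm <- true_model(8000, loadings = c(1, 0.8), residual_h2 = 0,
                   factor_h2 = 0.076, pi_c = 0.005, seed = 23)
  pf <- simulate_sumstats(tm, ld, n_per_trait = 1.2e5, seed = 23)
  rpf <- estimate_rg(pf[[1]], pf[[2]], ld, chi2_cap = FALSE)
  expect_lt(abs(rpf$rg - 1), 2 * rpf$se)

  # independent architectures: rg near 0
  tma <- true_model(8000, loadings = 1, factor_h2 = 0.08, pi_c = 0.01, seed = 5)
  tmb <- true_model(8000, loadings = 1, factor_h2 = 0.08, pi_c = 0.01, seed = 6)
  sa <- simulate_sumstats(tma, ld, 1e5, overlap_fraction = 0, seed = 5)[[1]]
  sb <- simulate_sumstats(tmb, ld, 1e5, overlap_fraction = 0, seed = 6)[[1]]
  r0 <- estimate_rg(sa, sb, ld, chi2_cap = FALSE)
  expect_lt(abs(r0$rg), 2 * r0$se)
})

test_that("genetic covariance agrees with the univariate and bivariate fits", {
  ld <- fixture_ld(8000)
  ss <- fixture_sumstats(ld, seed = 41)
  cs <- genetic_covariance(ss, ld, chi2_cap = FALSE)
  k <- 4
  # diagonal equals the univariate estimates on the same blocks
  for (t in seq_len(k)) {
    h <- estimate_h2(ss[[t]], ld, chi2_cap = FALSE)
    expect_equal(cs$S[t, t], h$h2, tolerance = 1e-12)
    # V diagonal matches the univariate squared jackknife SE
    dpos <- sfactor:::vech_diag_pos(k)[t]
    expect_equal(unname(sqrt(diag(cs$V)[dpos])), h$se, tolerance = 1e-10)
  }
  expect_true(isSymmetric(cs$S))
  expect_true(isSymmetric(cs$V, tol = 1e-12))
  expect_identical(dim(cs$V), c(10L, 10L))
  expect_true(all(diag(cs$V) > 0))

  # S converges to lambda lambda' h2_F + diag(residual): within 3 sampling SEs
  truth <- outer(c(0.9, 1, 0.7, 0.5), c(0.9, 1, 0.7, 0.5)) * 0.076 +
    diag(rep(0.01, 4))
  se_mat <- sfactor:::unvech(sqrt(diag(cs$V)), 4)
  expect_true(all(abs(cs$S - truth) < 3 * se_mat))

  # intercept structure: under the null the cross intercepts estimate
  # overlap * pheno_cor cleanly (no slope/intercept trade-off)
  tm0 <- true_model(8000, loadings = c(1, 1, 1, 1), factor_h2 = 0, pi_c = 0)
  ss0 <- simulate_sumstats(tm0, ld, 1.2e5, overlap_fraction = 1,
                           pheno_cor = 0.5, seed = 43)
  cs0 <- genetic_covariance(ss0, ld, chi2_cap = FALSE)
  offdiag <- cs0$intercepts[upper.tri(cs0$intercepts)]
  expect_true(all(abs(offdiag - 0.5) < 0.1))
  expect_true(all(abs(diag(cs0$intercepts) - 1) < 0.1))
})

test_that("stratified regression recovers concentrated enrichment", {
  set.seed(61)
  m <- 20000
  ld <- fixture_ld(m)
  annot <- cbind(base = 1, conserved = as.numeric(seq_len(m) %in%
                   sample.int(m, m * 0.05)))
  ld <- add_annotations(ld, annot)
  # dense architecture with 50% of h2 in the 5% annotation => enrichment 10
  h2 <- 0.1
  beta <- numeric(m)
  in_a <- annot[, "conserved"] == 1
  beta[in_a] <- rnorm(sum(in_a), 0, sqrt(0.5 * h2 / sum(in_a)))
  beta[!in_a] <- rnorm(sum(!in_a), 0, sqrt(0.5 * h2 / sum(!in_a)))
  s <- simulate_sumstats(effects = cbind(t1 = beta), ld = ld,
                         n_per_trait = 1e5, seed = 61)[[1]]
  enr <- stratified_h2(s, ld, chi2_cap = FALSE)
  row <- enr$table[enr$table$annotation == "conserved", ]
  expect_lt(abs(row$enrichment - 10), 2 * row$se)
  expect_equal(enr$table$enrichment[1], 1)   # base enrichment is 1 identically
  expect_equal(enr$table$se[1], 0)

  # an annotation holding no causal signal: enrichment near 0
  annot2 <- cbind(base = 1, empty = as.numeric(seq_len(m) > m * 0.95))
  ld2 <- add_annotations(fixture_ld(m), annot2)
  beta2 <- numeric(m)
  beta2[seq_len(m * 0.95)] <- rnorm(m * 0.95, 0, sqrt(h2 / (m * 0.95)))
  s2 <- simulate_sumstats(effects = cbind(t1 = beta2), ld = ld2,
                          n_per_trait = 1e5, seed = 62)[[1]]
  enr2 <- stratified_h2(s2, ld2, chi2_cap = FALSE)
  row2 <- enr2$table[enr2$table$annotation == "empty", ]
  expect_lt(abs(row2$enrichment), 2 * row2$se)

  # collinear annotations are named in the failure
  ld3 <- add_annotations(fixture_ld(1000),
                         cbind(base = rep(1, 1000), dup = rep(1, 1000)))
  s3 <- simulate_sumstats(effects = cbind(t1 = numeric(1000)), ld = ld3,
                          n_per_trait = 1e4, seed = 63)[[1]]
  expect_error(stratified_h2(s3, ld3), "collinear")
})

test_that("jackknife SEs shrink with panel size", {
  ses <- vapply(c(4000, 16000), function(m) {
    ld <- fixture_ld(m)
    tm <- true_model(m, loadings = 1, factor_h2 = 0.076, pi_c = 0.01, seed = 71)
    s <- simulate_sumstats(tm, ld, 1e5, seed = 71)[[1]]
    estimate_h2(s, ld, chi2_cap = FALSE)$se
  }, 0)
  expect_lt(ses[2], ses[1])
})
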