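# generators: LD references, causal architectures, summary statistics,
# target cohorts, and the ordinal aggregation rule

test_that("LD scores are exact for block AR(1) panels", {
  ld0 <- simulate_ld_blocks(100, 1, 0)
  expect_true(all(ld0$variants$l2 == 1))          # self-correlation only

  ld2 <- simulate_ld_blocks(4, 2, 0.5)
  # 2-SNP AR(1) block: ell = 1 + 0.5^2 for both variants
  expect_equal(ld2$variants$l2, rep(1.25, 4))

  ld <- simulate_ld_blocks(1000, 50, 0.9)
  # brute-force oracle: sum of squared correlations from the realized matrix
  R <- 0.9^abs(outer(1:50, 1:50, "-"))
  expect_equal(ld$variants$l2, rep(rowSums(R^2), 20))
  expect_true(all(ld$variants$l2 >= 1))

  expect_error(simulate_ld_blocks(100, 10, 1.0), "rho")
  expect_error(simulate_ld_blocks(100, 7, 0.5), "divisible")
})

test_that("factor architecture scales effects to the requested heritabilities", {
  expect_error(true_model(1000, loadings = 1, factor_h2 = 0.1, pi_c = 0) |>
                 simulate_factor_architecture(), "unattainable")
  expect_error(true_model(1000, loadings = 2, factor_h2 = 0.5), "exceeds 1")

  # pi_c = 0 with zero heritability: all effects exactly zero
  tm0 <- true_model(1000, loadings = c(1, 1), factor_h2 = 0, pi_c = 0)
  expect_true(all(simulate_factor_architecture(tm0) == 0))

  # pure-factor traits with equal loadings are identical
  tm1 <- true_model(5000, loadings = c(1, 1), residual_h2 = 0,
                    factor_h2 = 0.08, pi_c = 0.01, seed = 3)
  b <- simulate_factor_architecture(tm1)
  expect_identical(b[, 1], b[, 2])

  # binomial oracle for the causal count
  tm2 <- true_model(1e5, loadings = 1, factor_h2 = 0.08, pi_c = 0.01, seed = 5)
  n_causal <- sum(attr(simulate_factor_architecture(tm2), "causal"))
  expect_lt(abs(n_causal - 1000), 3 * sqrt(1e5 * 0.01 * 0.99))

  # expected summed squared factor effects equal factor_h2
  reps <- vapply(1:30, function(r) {
    tm <- true_model(2e4, loadings = 1, factor_h2 = 0.076, pi_c = 0.005,
                     seed = 100 + r)
    sum(attr(simulate_factor_architecture(tm), "beta_factor")^2)
  }, 0)
  expect_lt(abs(mean(reps) - 0.076) / 0.076, 0.1)
})

test_that("summary statistics have the designed mean and error structure", {
  ld <- fixture_ld(4000)
  null_model <- true_model(4000, loadings = c(1, 1), factor_h2 = 0, pi_c = 0)
  ss <- simulate_sumstats(null_model, ld, n_per_trait = 1e5,
                          overlap_fraction = 0, seed = 11)
  # null GWAS: mean chi-square near 1 (MC error ~ sqrt(2/M))
  expect_lt(abs(mean(ss[[1]]$z^2) - 1), 4 * sqrt(2 / 4000))
  # no overlap: cross-trait error correlation near zero at null sites
  expect_lt(abs(cor(ss[[1]]$z, ss[[2]]$z)), 4 / sqrt(4000))
  # full overlap imprints the phenotypic correlation on the errors
  ss2 <- simulate_sumstats(null_model, ld, n_per_trait = 1e5,
                           overlap_fraction = 1, pheno_cor = 0.5, seed = 11)
  expect_lt(abs(cor(ss2[[1]]$z, ss2[[2]]$z) - 0.5), 4 / sqrt(4000))
  # beta/se carry z and n
  expect_equal(ss[[1]]$beta / ss[[1]]$se, ss[[1]]$z)
  expect_equal(ss[[1]]$se, rep(1 / sqrt(1e5), 4000))
})

test_that("null GWAS are calibrated at genome-wide significance", {
  ld <- simulate_ld_blocks(20000, 1, 0)
  tm <- true_model(20000, loadings = 1, factor_h2 = 0, pi_c = 0)
  s <- simulate_sumstats(tm, ld, n_per_trait = 1e5, seed = 2)[[1]]
  p <- 2 * pnorm(-abs(s$z))
  expect_equal(sum(p < 5e-8), 0)   # expected count 1e-3; any hit is a defect
})

test_that("seeded generators are bit-identical and seeds propagate", {
  ld_a <- simulate_ld_blocks(500, 10, c(0.3, 0.8), seed = 9)
  ld_b <- simulate_ld_blocks(500, 10, c(0.3, 0.8), seed = 9)
  expect_identical(ld_a, ld_b)
  tm <- true_model(500, loadings = c(0.9, 1), factor_h2 = 0.05, pi_c = 0.02,
                   seed = 9)
  expect_identical(simulate_sumstats(tm, ld_a, 1e4, seed = 9),
                   simulate_sumstats(tm, ld_b, 1e4, seed = 9))
  co_a <- simulate_target_cohort(50, 200, seed = 9)
  co_b <- simulate_target_cohort(50, 200, seed = 9)
  expect_identical(co_a, co_b)
  co_c <- simulate_target_cohort(50, 200, seed = 10)
  expect_false(identical(co_a$dosage, co_c$dosage))
})

test_that("target cohorts match their generating frequencies and thresholds", {
  co <- simulate_target_cohort(256, 5000, seed = 21)
  expect_true(all(co$dosage >= 0 & co$dosage <= 2))
  af <- colMeans(co$dosage) / 2
  se <- sqrt(co$variants$maf * (1 - co$variants$maf) / (2 * 256))
  expect_gt(mean(abs(af - co$variants$maf) < 4 * se), 0.99)

  all_yes <- simulate_target_cohort(40, 100, thresholds = rep(-Inf, 4), seed = 3)
  expect_true(all(all_yes$items == 1L))
  expect_true(all(aggregate_suicidality(all_yes$items) == 4L))

  expect_error(simulate_target_cohort(10, 10, thresholds = rep(99, 4)),
               "liability")
  co_na <- simulate_target_cohort(200, 50, missing_rate = 0.2, seed = 4)
  expect_true(anyNA(co_na$items))
})

test_that("suicidality aggregation counts endorsements and propagates missing", {
  expect_identical(aggregate_suicidality(c("no", "no", "no", "no")), 0L)
  expect_identical(aggregate_suicidality(c("yes", "yes", "yes", "yes")), 4L)
  expect_identical(aggregate_suicidality(c("yes", "no", "yes", "no")), 2L)
  expect_identical(aggregate_suicidality(c("yes", NA, "yes", "no")), NA_integer_)
  expect_error(aggregate_suicidality(c("yes", "maybe", "no", "no")), "invalid")
  expect_error(aggregate_suicidality(c("yes", "no", "no")), "four items")

  # exhaustive enumeration over the 16 response patterns: the score of a
  # pattern is its number of yes responses, so with independent Bernoulli(p)
  # items the score distribution is Binomial(4, p)
  patterns <- expand.grid(rep(list(c("no", "yes")), 4), stringsAsFactors = FALSE)
  scores <- aggregate_suicidality(as.matrix(patterns))
  expect_identical(scores, rowSums(patterns == "yes") |> as.integer())
  p <- 0.3
  pattern_prob <- apply(patterns == "yes", 1, function(y)
    prod(ifelse(y, p, 1 - p)))
  dist <- tapply(pattern_prob, scores, sum)
  expect_equal(as.numeric(dist), dbinom(0:4, 4, p))
})
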