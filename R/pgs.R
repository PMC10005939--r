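# Polygenic scoring of a target cohort from summary-statistic weights and
# association with binary, ordinal and continuous phenotypes under the
# age/sex-interaction + principal-component covariate model.

#' Compute polygenic scores in a target cohort
#'
#' `score_i = sum_j w_j dosage_ij` over weight variants passing a minor allele
#' frequency filter computed in the target cohort itself (`maf > maf_min`,
#' strict). Weights are harmonized to the cohort's allele coding: a swapped
#' allele pair negates the weight; strand-ambiguous and irreconcilable variants
#' are dropped and counted. Missing dosages are mean-imputed per variant, and
#' the returned scores are mean-centred.
#'
#' @param cohort A `pgs_cohort`.
#' @param weights Data frame with columns `snp`, `a1`, `a2` and an effect
#'   column `w` (or `beta`).
#' @param maf_min Minor-allele-frequency threshold in the target cohort.
#' @return Object of class `pgs_scores`: `score` (length n, centred),
#'   `n_variants_scored`, `n_variants_dropped_maf`, `n_variants_dropped_allele`.
#' @export
compute_pgs <- function(cohort, weights, maf_min = 0.05) {
  stopifnot(inherits(cohort, "pgs_cohort"))
  w_col <- weights$w %||% weights$beta
  if (is.null(w_col)) stopf("weights need a 'w' or 'beta' column")
  idx <- match(weights$snp, cohort$variants$snp)
  present <- !is.na(idx)
  weights <- weights[present, , drop = FALSE]
  w_col <- w_col[present]
  idx <- idx[present]
  ref <- cohort$variants[idx, , drop = FALSE]
  same <- weights$a1 == ref$a1 & weights$a2 == ref$a2
  swap <- weights$a1 == ref$a2 & weights$a2 == ref$a1
  ambig <- is_ambiguous(weights$a1, weights$a2)
  ok_allele <- (same | swap) & !ambig
  w_col[swap] <- -w_col[swap]
  dos <- cohort$dosage[, idx, drop = FALSE]
  af <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  pass_maf <- maf > maf_min
  use <- ok_allele & pass_maf
  n_dropped_maf <- sum(ok_allele & !pass_maf)
  if (!any(use)) stopf("no variants pass harmonization and the MAF filter")
  dos <- dos[, use, drop = FALSE]
  if (anyNA(dos)) {
    mu <- colMeans(dos, na.rm = TRUE)
    for (j in which(colSums(is.na(dos)) > 0)) dos[is.na(dos[, j]), j] <- mu[j]
  }
  score <- as.numeric(dos %*% w_col[use])
  score <- score - mean(score)
  structure(list(score = score,
                 n_variants_scored = sum(use),
                 n_variants_dropped_maf = n_dropped_maf,
                 n_variants_dropped_allele = sum(!ok_allele)),
            class = "pgs_scores")
}

#' @export
print.pgs_scores <- function(x, ...) {
  cat(sprintf("PGS over %d variants (%d dropped by MAF, %d by allele); score SD %.3f\n",
              x$n_variants_scored, x$n_variants_dropped_maf,
              x$n_variants_dropped_allele, stats::sd(x$score)))
  invisible(x)
}

#' Nagelkerke's max-rescaled pseudo R-squared
#'
#' `R2_CS = 1 - exp(2 (l0 - l1) / n)` rescaled by its maximum
#' `1 - exp(2 l0 / n)`.
#'
#' @param loglik_null,loglik_full Log-likelihoods of the nested models
#'   (`loglik_full >= loglik_null`).
#' @param n Number of observations.
#' @return Nagelkerke R-squared in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(loglik_null, loglik_full, n) {
  if (n < 1) stopf("n must be at least 1")
  if (loglik_full < loglik_null - 1e-8)
    stopf("full-model log-likelihood below the null's")
  r2_cs <- 1 - exp(2 * (loglik_null - loglik_full) / n)
  denom <- 1 - exp(2 * loglik_null / n)
  if (denom <= 0) stopf("degenerate null model: Nagelkerke R2 undefined")
  r2_cs / denom
}

# covariate design used throughout: age, age^2, sex:age, sex:age^2, PC1..PC10
pgs_design <- function(covariates) {
  age <- covariates$age
  sex <- covariates$sex
  pcs <- as.matrix(covariates[, grep("^pc", names(covariates)), drop = FALSE])
  X <- cbind(age = age, age2 = age^2, sex_age = sex * age,
             sex_age2 = sex * age^2, pcs)
  qrx <- qr(cbind(1, X))
  if (qrx$rank < ncol(X) + 1L) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):(ncol(X) + 1L)] - 1L]
    stopf("collinear covariate column(s): %s", paste(bad, collapse = ", "))
  }
  X
}

#' Associate a polygenic score with a phenotype
#'
#' Fits the covariate-only and covariate-plus-score models with age, age^2,
#' sex x age, sex x age^2 and ten principal components, after listwise
#' deletion. Binary phenotypes use logistic regression and report the
#' Nagelkerke R-squared increment of adding the score; the ordinal aggregate
#' score (0-4) uses a linear model and reports the incremental adjusted
#' R-squared (with the likelihood-based Nagelkerke increment from the Gaussian
#' fits also reported, since both conventions circulate for ordinal outcomes);
#' continuous phenotypes use a linear model. The p-value is the two-sided Wald
#' test of the score coefficient.
#'
#' @param scores A `pgs_scores` object or numeric vector.
#' @param phenotype Numeric vector: 0/1 (binary), 0-4 integers (ordinal), or
#'   continuous.
#' @param covariates Data frame with `age`, `sex`, `pc1`..`pc10`.
#' @param type `"auto"` detects binary vs ordinal vs continuous; or force one.
#' @return One-row data frame: `type`, `effect`, `se`, `p`, `r2_incremental`
#'   (Nagelkerke for binary, adjusted R2 for ordinal/continuous),
#'   `r2_nagelkerke` (also populated for ordinal), `n`.
#' @export
pgs_association <- function(scores, phenotype, covariates,
                            type = c("auto", "binary", "ordinal", "continuous")) {
  type <- match.arg(type)
  score <- if (inherits(scores, "pgs_scores")) scores$score else as.numeric(scores)
  cc <- stats::complete.cases(score, phenotype, covariates)
  score <- score[cc]; y <- phenotype[cc]
  X <- pgs_design(covariates[cc, , drop = FALSE])
  if (type == "auto") {
    uy <- sort(unique(y))
    type <- if (all(uy %in% 0:1)) "binary"
            else if (all(uy %in% 0:4)) "ordinal" else "continuous"
  }
  n <- length(y)
  if (type == "binary") {
    m0 <- stats::glm(y ~ X, family = stats::binomial())
    m1 <- stats::glm(y ~ score + X, family = stats::binomial())
    mnull <- stats::glm(y ~ 1, family = stats::binomial())
    r2_full <- nagelkerke_r2(as.numeric(stats::logLik(mnull)),
                             as.numeric(stats::logLik(m1)), n)
    r2_cov <- nagelkerke_r2(as.numeric(stats::logLik(mnull)),
                            as.numeric(stats::logLik(m0)), n)
    sm <- summary(m1)$coefficients["score", ]
    out <- data.frame(type = type, effect = sm[1], se = sm[2], p = sm[4],
                      r2_incremental = r2_full - r2_cov,
                      r2_nagelkerke = r2_full - r2_cov, n = n)
  } else {
    m0 <- stats::lm(y ~ X)
    m1 <- stats::lm(y ~ score + X)
    sm <- summary(m1)$coefficients["score", ]
    adj_inc <- summary(m1)$adj.r.squared - summary(m0)$adj.r.squared
    mnull <- stats::lm(y ~ 1)
    r2_nag <- nagelkerke_r2(as.numeric(stats::logLik(mnull)),
                            as.numeric(stats::logLik(m1)), n) -
              nagelkerke_r2(as.numeric(stats::logLik(mnull)),
                            as.numeric(stats::logLik(m0)), n)
    out <- data.frame(type = type, effect = sm[1], se = sm[2], p = sm[4],
                      r2_incremental = adj_inc,
                      r2_nagelkerke = if (type == "ordinal") r2_nag else NA_real_,
                      n = n)
  }
  rownames(out) <- NULL
  out
}

#' Pearson correlation between two polygenic scores
#'
#' @param scores_a,scores_b Equal-length numeric vectors or `pgs_scores`
#'   (`n >= 3`).
#' @return List with `r`, `p`, `n`.
#' @export
score_correlation <- function(scores_a, scores_b) {
  a <- if (inherits(scores_a, "pgs_scores")) scores_a$score else as.numeric(scores_a)
  b <- if (inherits(scores_b, "pgs_scores")) scores_b$score else as.numeric(scores_b)
  if (length(a) != length(b)) stopf("score vectors differ in length")
  if (length(a) < 3) stopf("at least 3 individuals required")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stopf("zero variance in a score vector: correlation undefined")
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(a))
}

#' Select one variant per LD block by association strength
#'
#' Stand-in for external LD-clumping: keeps, within each LD block of the
#' reference, the variant with the smallest p-value (largest `|z|`) in the
#' training statistics.
#'
#' @param s A `sumstats` data frame.
#' @param ld The `ld_reference` defining the blocks.
#' @return The thinned `sumstats` data frame.
#' @export
ld_independent <- function(s, ld) {
  s <- validate_sumstats(s)
  idx <- match(s$snp, ld$variants$snp)
  if (anyNA(idx)) stopf("variants absent from the LD reference")
  block <- ld$variants$block[idx]
  keep <- unlist(lapply(split(seq_len(nrow(s)), block),
                        function(i) i[which.max(abs(s$z[i]))]), use.names = FALSE)
  out <- s[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}
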