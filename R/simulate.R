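# Synthetic-data generators: block LD references, factor-structured causal
# architectures, multi-trait GWAS summary statistics and a small
# individual-level target cohort. Everything downstream of the generators is
# estimation; nothing here is fitted.

#' Specify a generative factor architecture
#'
#' Collects the parameters of the generating model: `n_snps` variants, a single
#' heritable latent factor with SNP-heritability `factor_h2` loading on each
#' trait through `loadings`, per-trait residual genetic variance `residual_h2`,
#' and a point-normal causal architecture in which a proportion `pi_c` of
#' variants carry effects drawn from `Normal(0, sigma2_beta)`.
#'
#' When `sigma2_beta` is omitted it is set to `factor_h2 / (n_snps * pi_c)` so
#' that the summed squared factor effects equal `factor_h2` in expectation.
#'
#' @param n_snps Number of variants M.
#' @param loadings Numeric vector of unstandardized factor loadings, one per trait.
#' @param residual_h2 Per-trait residual genetic variance (recycled to the
#'   number of traits).
#' @param factor_h2 SNP-heritability of the latent factor, in `[0, 1]`.
#' @param pi_c Proportion of causal (non-null) variants, in `[0, 1]`.
#' @param sigma2_beta Per-causal-variant effect variance; derived from
#'   `factor_h2` when `NULL`.
#' @param seed Integer seed; fixed seed implies bit-identical output.
#' @return An object of class `true_model`.
#' @export
true_model <- function(n_snps, loadings, residual_h2 = 0, factor_h2 = 0.076,
                       pi_c = 0.005, sigma2_beta = NULL, seed = 1L) {
  residual_h2 <- rep_len(residual_h2, length(loadings))
  if (pi_c < 0 || pi_c > 1) stopf("pi_c must lie in [0, 1], got %g", pi_c)
  if (factor_h2 < 0 || factor_h2 > 1) stopf("factor_h2 must lie in [0, 1]")
  if (any(residual_h2 < 0 | residual_h2 > 1)) stopf("residual_h2 must lie in [0, 1]")
  total <- loadings^2 * factor_h2 + residual_h2
  if (any(total > 1 + 1e-12))
    stopf("per-trait total genetic variance exceeds 1 (max %.3f)", max(total))
  if (is.null(sigma2_beta))
    sigma2_beta <- if (pi_c > 0) factor_h2 / (n_snps * pi_c) else 0
  structure(list(n_snps = as.integer(n_snps), loadings = as.numeric(loadings),
                 residual_h2 = residual_h2, factor_h2 = factor_h2,
                 pi_c = pi_c, sigma2_beta = sigma2_beta,
                 seed = as.integer(seed)),
            class = "true_model")
}

#' Simulate a block-structured LD reference
#'
#' Variants are arranged in independent blocks of `block_size` with an AR(1)
#' correlation profile: the correlation between variants at within-block
#' distance `d` is `rho^d`, and zero across blocks. LD scores are computed
#' exactly from the generating correlation matrix (sum of squared correlations
#' including the self-correlation), never estimated from genotypes. A vector
#' `rho` is recycled across blocks, giving the between-block LD-score
#' heterogeneity that real panels show (and that LD-score regression needs for
#' leverage).
#'
#' @param n_snps Total number of variants; must be divisible by `block_size`.
#' @param block_size Variants per LD block.
#' @param rho AR(1) neighbour correlation(s), each `|rho| < 1`; recycled over
#'   blocks.
#' @param seed Integer seed (used only for reproducible allele assignment).
#' @return An object of class `ld_reference`: a list with a `variants` data
#'   frame (`chrom`, `snp`, `bp`, `a1`, `a2`, `l2`, `block`), the block
#'   correlation matrix `r_block`, and optional `annotations` / `m_annot`
#'   filled in by [add_annotations()].
#' @export
simulate_ld_blocks <- function(n_snps, block_size = 1L, rho = 0, seed = 1L) {
  if (any(abs(rho) >= 1)) stopf("rho must satisfy |rho| < 1, got %g", max(abs(rho)))
  if (n_snps %% block_size != 0)
    stopf("n_snps (%d) must be divisible by block_size (%d)", n_snps, block_size)
  set.seed(derive_seed(seed, 1L))
  n_blocks <- n_snps %/% block_size
  block_rho <- rep_len(rho, n_blocks)
  d <- abs(outer(seq_len(block_size), seq_len(block_size), "-"))
  uniq <- unique(block_rho)
  r_by_rho <- lapply(uniq, function(r) r^d)
  names(r_by_rho) <- as.character(uniq)
  l2_by_rho <- lapply(r_by_rho, function(R) rowSums(R^2))  # exact ell_j per block
  variants <- data.frame(
    chrom = 1L,
    snp = paste0("rs", seq_len(n_snps)),
    bp = seq_len(n_snps) * 1000L,
    a1 = "A", a2 = "G",
    l2 = unlist(l2_by_rho[as.character(block_rho)], use.names = FALSE),
    block = rep(seq_len(n_blocks), each = block_size),
    stringsAsFactors = FALSE
  )
  structure(list(variants = variants, r_blocks = r_by_rho,
                 block_rho = block_rho,
                 block_size = as.integer(block_size), rho = rho,
                 annotations = NULL, m_annot = NULL),
            class = "ld_reference")
}

# correlation matrix of one block
block_r <- function(ld, b) ld$r_blocks[[as.character(ld$block_rho[b])]]

#' @export
print.ld_reference <- function(x, ...) {
  cat(sprintf("LD reference: %d variants in blocks of %d (AR1 rho: %s)\n",
              nrow(x$variants), x$block_size,
              paste(unique(x$rho), collapse = "/")))
  cat(sprintf("  mean LD score %.3f", mean(x$variants$l2)))
  if (!is.null(x$annotations))
    cat(sprintf("; %d annotations", ncol(x$annotations)))
  cat("\n")
  invisible(x)
}

#' Attach annotations and annotation LD scores to an LD reference
#'
#' Adds a variant-by-annotation membership matrix (the first column must be the
#' all-ones base annotation) and computes per-annotation LD scores exactly from
#' the block correlation matrix: `l2[j, c] = sum_k a[k, c] * r[j, k]^2`.
#'
#' @param ld An `ld_reference`.
#' @param annotations Numeric matrix, variants by annotations; column names are
#'   kept. A base column of ones is prepended when absent.
#' @return The `ld_reference` with `annotations`, `annot_l2` and `m_annot`
#'   (column sums) filled in.
#' @export
add_annotations <- function(ld, annotations) {
  annotations <- as.matrix(annotations)
  if (nrow(annotations) != nrow(ld$variants))
    stopf("annotation matrix has %d rows but reference has %d variants",
          nrow(annotations), nrow(ld$variants))
  if (!all(abs(annotations[, 1] - 1) < 1e-12)) {
    annotations <- cbind(base = 1, annotations)
  }
  if (is.null(colnames(annotations)))
    colnames(annotations) <- c("base", paste0("annot", seq_len(ncol(annotations) - 1L)))
  annot_l2 <- matrix(0, nrow(annotations), ncol(annotations),
                     dimnames = list(NULL, colnames(annotations)))
  for (b in unique(ld$variants$block)) {
    idx <- which(ld$variants$block == b)
    annot_l2[idx, ] <- block_r(ld, b)^2 %*% annotations[idx, , drop = FALSE]
  }
  ld$annotations <- annotations
  ld$annot_l2 <- annot_l2
  ld$m_annot <- colSums(annotations)
  ld
}

#' Draw per-trait causal effect vectors under the factor model
#'
#' Factor effects are point-normal: zero with probability `1 - pi_c`, otherwise
#' `Normal(0, sigma2_beta)`, so the summed squared factor effects equal
#' `factor_h2` in expectation. Trait `t` effects are `loadings[t]` times the
#' factor effects plus an independent point-normal residual vector scaled to
#' `residual_h2[t]`; all traits therefore share the factor's causal loci.
#'
#' @param model A [true_model()].
#' @return Matrix of per-variant per-trait causal effects (variants x traits)
#'   with the factor effect vector in attribute `"beta_factor"` and the causal
#'   indicator in attribute `"causal"`.
#' @export
simulate_factor_architecture <- function(model) {
  stopifnot(inherits(model, "true_model"))
  m <- model$n_snps
  k <- length(model$loadings)
  if (model$pi_c == 0 && (model$factor_h2 > 0 || any(model$residual_h2 > 0)))
    stopf("requested heritability unattainable with pi_c = 0")
  set.seed(derive_seed(model$seed, 2L))
  causal <- stats::runif(m) < model$pi_c
  beta_f <- numeric(m)
  beta_f[causal] <- stats::rnorm(sum(causal), 0, sqrt(model$sigma2_beta))
  beta <- outer(beta_f, model$loadings)
  for (t in seq_len(k)) {
    if (model$residual_h2[t] > 0) {
      sig2_res <- model$residual_h2[t] / (m * model$pi_c)
      causal_res <- stats::runif(m) < model$pi_c
      beta[causal_res, t] <- beta[causal_res, t] +
        stats::rnorm(sum(causal_res), 0, sqrt(sig2_res))
    }
  }
  colnames(beta) <- paste0("trait", seq_len(k))
  attr(beta, "beta_factor") <- beta_f
  attr(beta, "causal") <- causal
  beta
}

# marginal (LD-convolved) effects: R %*% beta, block by block
ld_convolve <- function(ld, beta) {
  beta <- as.matrix(beta)
  out <- beta
  if (ld$block_size > 1L && any(ld$rho != 0)) {
    for (b in unique(ld$variants$block)) {
      idx <- which(ld$variants$block == b)
      out[idx, ] <- block_r(ld, b) %*% beta[idx, , drop = FALSE]
    }
  }
  out
}

#' Simulate GWAS summary statistics for the factor-structured traits
#'
#' Per-trait Z statistics are `Normal(sqrt(N) * (R beta)_j, 1)` where `R` is the
#' block LD correlation. Cross-trait sampling errors are correlated with
#' correlation `overlap_fraction * pheno_cor`, the structure a shared-sample
#' design imprints on the LD-score regression intercepts; shared individuals
#' are not simulated explicitly.
#'
#' @param model A [true_model()]; ignored when `effects` is supplied.
#' @param ld An `ld_reference` with as many variants as `model$n_snps`.
#' @param n_per_trait GWAS sample size per trait (recycled).
#' @param overlap_fraction Fraction of shared samples between trait pairs, in
#'   `[0, 1]`. Defaults to 1 (all items measured in one cohort).
#' @param pheno_cor Phenotypic correlation between trait pairs: scalar or k x k
#'   matrix. Defaults to 0.5.
#' @param effects Optional explicit variants-by-traits causal effect matrix,
#'   bypassing [simulate_factor_architecture()].
#' @param seed Integer seed.
#' @return List of per-trait `sumstats` data frames (columns `snp`, `a1`, `a2`,
#'   `z`, `n`, `beta`, `se`), named after the effect matrix columns.
#' @export
simulate_sumstats <- function(model = NULL, ld, n_per_trait, overlap_fraction = 1,
                              pheno_cor = 0.5, effects = NULL, seed = 1L) {
  if (is.null(effects)) {
    stopifnot(inherits(model, "true_model"))
    if (model$n_snps != nrow(ld$variants))
      stopf("model has %d variants but reference has %d",
            model$n_snps, nrow(ld$variants))
    effects <- simulate_factor_architecture(model)
  }
  effects <- as.matrix(effects)
  if (nrow(effects) != nrow(ld$variants))
    stopf("effect matrix rows (%d) must match reference variants (%d)",
          nrow(effects), nrow(ld$variants))
  m <- nrow(effects); k <- ncol(effects)
  n_per_trait <- rep_len(n_per_trait, k)
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stopf("overlap_fraction must lie in [0, 1]")
  if (is.matrix(pheno_cor)) {
    cmat <- pheno_cor
  } else {
    cmat <- matrix(pheno_cor, k, k); diag(cmat) <- 1
  }
  err_cor <- overlap_fraction * cmat
  diag(err_cor) <- 1
  set.seed(derive_seed(seed, 3L))
  marg <- ld_convolve(ld, effects)
  eps <- MASS::mvrnorm(m, mu = rep(0, k), Sigma = err_cor)
  labels <- colnames(effects) %||% paste0("trait", seq_len(k))
  out <- vector("list", k)
  for (t in seq_len(k)) {
    n <- n_per_trait[t]
    z <- sqrt(n) * marg[, t] + eps[, t]
    out[[t]] <- data.frame(
      snp = ld$variants$snp, a1 = ld$variants$a1, a2 = ld$variants$a2,
      z = z, n = n, beta = z / sqrt(n), se = 1 / sqrt(n),
      stringsAsFactors = FALSE
    )
    class(out[[t]]) <- c("sumstats", "data.frame")
  }
  names(out) <- labels
  out
}

#' Effective sample size for a binary trait
#'
#' `Neff = 4 / (1/n_cases + 1/n_controls)`, the equivalent balanced-design
#' sample size used for case-control GWAS.
#'
#' @param n_cases,n_controls Case and control counts.
#' @return Effective sample size.
#' @export
effective_n <- function(n_cases, n_controls) {
  if (any(n_cases <= 0) || any(n_controls <= 0))
    stopf("case and control counts must be positive")
  4 / (1 / n_cases + 1 / n_controls)
}

#' Simulate an individual-level target cohort for polygenic scoring
#'
#' Dosages are `Binomial(2, maf)` draws at independent variants. Each
#' individual's latent factor combines a standardized genetic score (built from
#' point-normal weights over a causal subset of variants) with Gaussian noise
#' in proportion `factor_h2_liability`; the four binary items are thresholded
#' item liabilities sharing that factor. Covariates (age, sex, ten principal
#' components) are simulated independently of genotype.
#'
#' @param n Individuals.
#' @param m Variants.
#' @param maf_range Range from which allele frequencies are drawn uniformly.
#' @param factor_h2_liability Proportion of factor-liability variance explained
#'   by the genetic score, in `[0, 1]`.
#' @param thresholds Length-4 liability thresholds (standard-normal scale); item
#'   `t` is endorsed when its liability exceeds `thresholds[t]`.
#' @param item_loadings Loadings of the four item liabilities on the factor.
#' @param pi_causal Proportion of variants given non-zero weight.
#' @param missing_rate Probability an item response is missing (encoded `NA`).
#' @param seed Integer seed.
#' @return An object of class `pgs_cohort`: dosage matrix, `variants` data
#'   frame (with generating `maf`), `items` (n x 4, values 0/1/`NA`),
#'   `covariates` data frame, and the generating `weights`.
#' @export
simulate_target_cohort <- function(n, m, maf_range = c(0.05, 0.5),
                                   factor_h2_liability = 0.2,
                                   thresholds = rep(1.0, 4),
                                   item_loadings = rep(0.8, 4),
                                   pi_causal = 0.05, missing_rate = 0,
                                   seed = 1L) {
  if (factor_h2_liability < 0 || factor_h2_liability > 1)
    stopf("factor_h2_liability must lie in [0, 1]")
  if (length(thresholds) != 4L) stopf("exactly four item thresholds required")
  if (any(is.finite(thresholds) & abs(thresholds) > 8))
    stopf("thresholds outside the usable liability range")
  set.seed(derive_seed(seed, 4L))
  maf <- stats::runif(m, maf_range[1], maf_range[2])
  dosage <- matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), n, m)
  variants <- data.frame(snp = paste0("rs", seq_len(m)),
                         a1 = "A", a2 = "G", maf = maf,
                         stringsAsFactors = FALSE)
  colnames(dosage) <- variants$snp
  weights <- numeric(m)
  causal <- stats::runif(m) < pi_causal
  weights[causal] <- stats::rnorm(sum(causal))
  g <- as.numeric(dosage %*% weights)
  g <- if (stats::sd(g) > 0) (g - mean(g)) / stats::sd(g) else g
  f <- sqrt(factor_h2_liability) * g +
    sqrt(1 - factor_h2_liability) * stats::rnorm(n)
  items <- matrix(NA_integer_, n, 4L,
                  dimnames = list(NULL, c("tlnwl", "tsh", "ash", "as")))
  for (t in 1:4) {
    lam <- item_loadings[t]
    liab <- lam * f + sqrt(max(1 - lam^2, 0)) * stats::rnorm(n)
    items[, t] <- as.integer(liab > thresholds[t])
  }
  if (missing_rate > 0) {
    miss <- matrix(stats::runif(n * 4L) < missing_rate, n, 4L)
    items[miss] <- NA_integer_
  }
  covariates <- data.frame(
    age = round(stats::rnorm(n, 56, 8)),
    sex = stats::rbinom(n, 1L, 0.5)
  )
  pcs <- matrix(stats::rnorm(n * 10L), n, 10L,
                dimnames = list(NULL, paste0("pc", 1:10)))
  covariates <- cbind(covariates, as.data.frame(pcs))
  structure(list(dosage = dosage, variants = variants, items = items,
                 covariates = covariates, weights = weights,
                 factor_score = f),
            class = "pgs_cohort")
}

#' @export
print.pgs_cohort <- function(x, ...) {
  cat(sprintf("Target cohort: %d individuals x %d variants; item endorsement %s\n",
              nrow(x$dosage), ncol(x$dosage),
              paste(sprintf("%.2f", colMeans(x$items, na.rm = TRUE)), collapse = "/")))
  invisible(x)
}

#' Aggregate four binary items into an ordinal severity score
#'
#' The aggregate score is the count of endorsed ("yes") items, 0 (none) through
#' 4 (most severe). A missing response to any item makes the aggregate missing:
#' counting only observed items would deflate scores for incomplete responders.
#'
#' @param items A length-4 vector, or an n x 4 matrix/data frame, with values
#'   in `{"yes", "no", NA}` (or `{1, 0, NA}` / logical).
#' @return Integer score(s) in `0:4`, `NA` where any item is missing.
#' @export
aggregate_suicidality <- function(items) {
  if (is.null(dim(items))) items <- matrix(items, nrow = 1L)
  items <- as.matrix(items)
  if (ncol(items) != 4L) stopf("exactly four items required, got %d", ncol(items))
  if (is.character(items)) {
    bad <- !(items %in% c("yes", "no") | is.na(items))
    if (any(bad)) stopf("invalid item value(s): %s",
                        paste(unique(items[bad]), collapse = ", "))
    num <- matrix(as.integer(items == "yes"), nrow(items), 4L)
  } else {
    num <- matrix(as.numeric(items), nrow(items), 4L)
    bad <- !(num %in% c(0, 1) | is.na(num))
    if (any(bad)) stopf("item values must be 0/1/yes/no/NA")
  }
  score <- as.integer(rowSums(num))   # NA propagates through rowSums
  if (length(score) == 1L) score[[1L]] else score
}
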