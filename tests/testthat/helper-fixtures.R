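# shared fixture builders; all simulated in code, nothing on disk

# small heterogeneous-LD reference: the rho mix gives the between-block
# LD-score spread the regression estimators need
fixture_ld <- function(n_snps = 5000, block_size = 50,
                       rho = c(0.2, 0.5, 0.8, 0.95), seed = 1L) {
  simulate_ld_blocks(n_snps, block_size, rho, seed = seed)
}

# four factor-structured indicator GWAS at the default study scale
fixture_sumstats <- function(ld, factor_h2 = 0.076, pi_c = 0.005,
                             loadings = c(0.9, 1, 0.7, 0.5),
                             residual_h2 = 0.01, n = 1.2e5, seed = 1L,
                             overlap_fraction = 1, pheno_cor = 0.5) {
  tm <- true_model(nrow(ld$variants), loadings = loadings,
                   residual_h2 = residual_h2, factor_h2 = factor_h2,
                   pi_c = pi_c, seed = seed)
  simulate_sumstats(tm, ld, n_per_trait = n,
                    overlap_fraction = overlap_fraction,
                    pheno_cor = pheno_cor, seed = seed)
}

# hand-sized sumstats table for IO/filter tests
toy_sumstats <- function(n = 10, z = NULL, nn = NULL, seed = 42L) {
  set.seed(seed)
  data.frame(snp = paste0("rs", seq_len(n)),
             a1 = "A", a2 = "G",
             z = z %||% stats::rnorm(n),
             n = nn %||% rep(1e4, n),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exact one-factor covariance structure and a plausible sampling matrix
fixture_exact_cov <- function(lambda = c(0.8, 1, 0.6, 0.4), phi = 0.05,
                              theta = c(0.010, 0.008, 0.012, 0.009),
                              v_scale = 1e-5) {
  k <- length(lambda)
  S <- phi * tcrossprod(lambda) + diag(theta)
  nms <- paste0("trait", seq_len(k))
  dimnames(S) <- list(nms, nms)
  p <- k * (k + 1) / 2
  set.seed(99L)
  A <- matrix(stats::rnorm(p * p, sd = 0.1), p, p)
  V <- v_scale * (diag(p) + tcrossprod(A))   # positive definite, mildly correlated
  structure(list(traits = nms, S = S, V = V,
                 intercepts = diag(k), m = NA_integer_, n_blocks = NA_integer_),
            class = "cov_struct")
}
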