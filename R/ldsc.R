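# LD-score regression: univariate heritability, bivariate genetic correlation,
# multivariable genetic covariance with block-jackknife sampling covariance,
# and stratified (annotation) partitioning. All estimators share one weighted
# least squares + delete-a-block jackknife engine so the genetic covariance
# diagonal reproduces the univariate fits exactly.

# weighted LS with per-block crossproducts; returns full-sample coefficients
# and the B x p matrix of delete-one-block coefficients
wls_blocks <- function(X, y, w, blocks) {
  p <- ncol(X)
  nb <- max(blocks)
  Xw <- X * w
  A <- crossprod(Xw, X)
  cc <- crossprod(Xw, y)
  A_b <- array(0, c(p, p, nb))
  c_b <- matrix(0, p, nb)
  for (b in seq_len(nb)) {
    idx <- which(blocks == b)
    Xb <- X[idx, , drop = FALSE]
    A_b[, , b] <- crossprod(Xb * w[idx], Xb)
    c_b[, b] <- crossprod(Xb * w[idx], y[idx])
  }
  est <- solve(A, cc)
  del <- matrix(0, nb, p)
  for (b in seq_len(nb)) del[b, ] <- solve(A - A_b[, , b], cc - c_b[, b])
  list(est = drop(est), delete = del, n_blocks = nb)
}

jackknife_se <- function(delete_est) {
  b <- NROW(delete_est)
  if (is.null(dim(delete_est)))
    sqrt((b - 1) / b * sum((delete_est - mean(delete_est))^2))
  else
    sqrt((b - 1) / b * colSums(sweep(delete_est, 2, colMeans(delete_est))^2))
}

# align one sumstats table to the reference variant order
align_to_ld <- function(s, ld) {
  idx <- match(ld$variants$snp, s$snp)
  if (anyNA(idx))
    stopf("%d reference variants missing from the summary statistics; harmonize first",
          sum(is.na(idx)))
  s[idx, , drop = FALSE]
}

# heteroskedasticity x over-counting LDSC regression weights
ldsc_weights <- function(l2, n, h2, m) {
  het <- (1 + n * pmax(h2, 0) * l2 / m)^2
  1 / (pmax(l2, 1) * het)
}

# two-step weighted chi-square-on-ell regression for one trait.
# regressor is N * l2 / M so the slope is h2 itself; intercept free.
ldsc_univariate <- function(z, n, l2, m, blocks, chi2_cap = TRUE) {
  chi2 <- z^2
  keep <- if (chi2_cap) chi2 <= max(80, 0.001 * max(n)) else rep(TRUE, length(z))
  X <- cbind(intercept = 1, h2 = n * l2 / m)[keep, , drop = FALSE]
  y <- chi2[keep]
  bl <- blocks[keep]
  bl <- match(bl, sort(unique(bl)))   # renumber in case a block emptied
  if (stats::var(X[, 2]) == 0) stopf("zero variance in LD scores: singular design")
  f0 <- wls_blocks(X, y, rep(1, length(y)), bl)
  w1 <- ldsc_weights(l2[keep], n[keep], f0$est[2], m)
  f1 <- wls_blocks(X, y, w1, bl)
  w2 <- ldsc_weights(l2[keep], n[keep], f1$est[2], m)
  f2 <- wls_blocks(X, y, w2, bl)
  list(est = f2$est, delete = f2$delete, mean_chi2 = mean(chi2),
       keep = keep, n_blocks = f2$n_blocks)
}

# two-step weighted z1*z2-on-ell regression; slope is rho_g
ldsc_bivariate <- function(z1, n1, z2, n2, l2, m, blocks, h1, h2, keep) {
  X <- cbind(intercept = 1, rhog = sqrt(n1 * n2) * l2 / m)[keep, , drop = FALSE]
  y <- (z1 * z2)[keep]
  bl <- match(blocks[keep], sort(unique(blocks[keep])))
  het1 <- 1 + n1[keep] * pmax(h1, 0) * l2[keep] / m
  het2 <- 1 + n2[keep] * pmax(h2, 0) * l2[keep] / m
  f0 <- wls_blocks(X, y, 1 / (pmax(l2[keep], 1) * het1 * het2), bl)
  expected <- f0$est[1] + X[, 2] * f0$est[2]
  w <- 1 / (pmax(l2[keep], 1) * (het1 * het2 + expected^2))
  wls_blocks(X, y, w, bl)
}

#' Estimate SNP-heritability by LD-score regression
#'
#' Regresses per-variant chi-squared statistics on LD scores under
#' `E[chi2_j] = 1 + N a + (N h2 / M) l_j` with a free intercept, using the
#' standard two-step heteroskedasticity-and-over-counting weights after an
#' initial unweighted pass. Standard errors come from a delete-a-block
#' jackknife over contiguous variant blocks. By default variants with
#' `chi2 > max(80, 0.001 N)` are excluded from the regression (only), the
#' standard guard against single loci of outsized effect; disable it
#' (`chi2_cap = FALSE`) for simulated architectures whose genuine causal
#' variants exceed that bound. Negative point estimates are reported
#' untruncated so downstream difference tests stay unbiased.
#'
#' @param s A `sumstats` data frame covering the reference variants.
#' @param ld An `ld_reference`; its variant count is the M in the model.
#' @param n_blocks Number of jackknife blocks (reduced with a warning if there
#'   are fewer variants).
#' @param chi2_cap Apply the `max(80, 0.001 N)` chi-squared exclusion to the
#'   regression variants.
#' @return Object of class `ldsc_h2`: `h2`, `se`, `intercept`, `intercept_se`,
#'   `mean_chi2`, `p` (two-sided vs `h2 = 0`), `m`, `n_blocks`.
#' @export
estimate_h2 <- function(s, ld, n_blocks = 200, chi2_cap = TRUE) {
  s <- align_to_ld(validate_sumstats(s), ld)
  m <- nrow(ld$variants)
  blocks <- block_assign(m, n_blocks)
  fit <- ldsc_univariate(s$z, s$n, ld$variants$l2, m, blocks, chi2_cap = chi2_cap)
  ses <- jackknife_se(fit$delete)
  h2 <- unname(fit$est[2]); se <- unname(ses[2])
  structure(list(h2 = h2, se = se,
                 intercept = unname(fit$est[1]), intercept_se = unname(ses[1]),
                 mean_chi2 = fit$mean_chi2,
                 p = 2 * stats::pnorm(-abs(h2 / se)),
                 m = m, n_blocks = fit$n_blocks,
                 delete = fit$delete, keep = fit$keep),
            class = "ldsc_h2")
}

#' @export
print.ldsc_h2 <- function(x, ...) {
  cat(sprintf("LDSC h2: %.4f (SE %.4f, p = %.3g); intercept %.4f (SE %.4f); mean chi2 %.3f\n",
              x$h2, x$se, x$p, x$intercept, x$intercept_se, x$mean_chi2))
  invisible(x)
}

#' @export
coef.ldsc_h2 <- function(object, ...) c(h2 = object$h2, intercept = object$intercept)

#' Estimate genetic correlation by cross-trait LD-score regression
#'
#' Regresses the product `z1 * z2` on LD scores; the intercept absorbs sample
#' overlap and the slope estimates the genetic covariance `rho_g`. The genetic
#' correlation is `rg = rho_g / sqrt(h2_1 h2_2)` with the heritabilities
#' estimated on the same variants and jackknife blocks by the same
#' product-regression scheme (so `estimate_rg(s, s)` returns exactly 1), and
#' its standard error is the delete-a-block jackknife of the full ratio. `rg` is unconstrained and
#' can exceed 1 in magnitude by sampling noise. When either heritability point
#' estimate is non-positive the correlation is undefined and the result is
#' returned flagged (`defined = FALSE`) rather than as a silent `NaN`.
#'
#' @inheritParams estimate_h2
#' @param s1,s2 `sumstats` data frames harmonized to the same reference.
#' @return Object of class `ldsc_rg`: `rg`, `se`, `p`, `rho_g`, `rho_g_se`,
#'   `cross_intercept`, `defined`, plus the underlying `ldsc_h2` fits.
#' @export
estimate_rg <- function(s1, s2, ld, n_blocks = 200, chi2_cap = TRUE) {
  s1 <- align_to_ld(validate_sumstats(s1), ld)
  s2 <- align_to_ld(validate_sumstats(s2), ld)
  m <- nrow(ld$variants)
  blocks <- block_assign(m, n_blocks)
  l2 <- ld$variants$l2
  f1 <- ldsc_univariate(s1$z, s1$n, l2, m, blocks, chi2_cap = chi2_cap)
  f2 <- ldsc_univariate(s2$z, s2$n, l2, m, blocks, chi2_cap = chi2_cap)
  keep <- f1$keep & f2$keep
  # all three slopes (h2_1, h2_2, rho_g) from the same product-regression
  # estimator on the shared regression SNPs, so the ratio is self-consistent
  h1_0 <- f1$est[2]; h2_0 <- f2$est[2]
  d1 <- ldsc_bivariate(s1$z, s1$n, s1$z, s1$n, l2, m, blocks, h1_0, h1_0, keep)
  d2 <- ldsc_bivariate(s2$z, s2$n, s2$z, s2$n, l2, m, blocks, h2_0, h2_0, keep)
  fx <- ldsc_bivariate(s1$z, s1$n, s2$z, s2$n, l2, m, blocks, h1_0, h2_0, keep)
  rho_g <- unname(fx$est[2])
  h1 <- unname(d1$est[2]); h2 <- unname(d2$est[2])
  defined <- h1 > 0 && h2 > 0
  rg_del <- fx$delete[, 2] / sqrt(pmax(d1$delete[, 2] * d2$delete[, 2], 1e-12))
  rg <- if (defined) rho_g / sqrt(h1 * h2) else NA_real_
  se <- unname(jackknife_se(rg_del))
  structure(list(rg = rg, se = se,
                 p = if (defined) 2 * stats::pnorm(-abs(rg / se)) else NA_real_,
                 rho_g = rho_g, rho_g_se = unname(jackknife_se(fx$delete[, 2])),
                 cross_intercept = unname(fx$est[1]), defined = defined,
                 h2_1 = h1, h2_2 = h2, n_blocks = fx$n_blocks),
            class = "ldsc_rg")
}

#' @export
print.ldsc_rg <- function(x, ...) {
  if (x$defined)
    cat(sprintf("LDSC rg: %.4f (SE %.4f, p = %.3g); rho_g %.5f; cross-intercept %.4f\n",
                x$rg, x$se, x$p, x$rho_g, x$cross_intercept))
  else
    cat("LDSC rg: undefined (non-positive heritability point estimate)\n")
  invisible(x)
}

#' Multivariable LD-score regression: genetic covariance and sampling matrix
#'
#' Assembles the k x k genetic covariance matrix S from the univariate slopes
#' (diagonal) and pairwise cross-trait slopes (off-diagonal), and the sampling
#' covariance V of `vech(S)` from the joint delete-a-block jackknife of all
#' `k(k+1)/2` estimates computed on shared blocks. The intercept matrix (per-
#' trait on the diagonal, cross-trait off it) is retained for downstream
#' error-correlation handling.
#'
#' @inheritParams estimate_h2
#' @param traits Named list of two or more harmonized `sumstats` data frames.
#' @return Object of class `cov_struct`: `traits` (names), `S`, `V` (with
#'   vech ordering: columns stacked, lower triangle), `intercepts`, `m`,
#'   `n_blocks`.
#' @export
genetic_covariance <- function(traits, ld, n_blocks = 200, chi2_cap = TRUE) {
  if (length(traits) < 2) stopf("at least two traits required")
  k <- length(traits)
  nms <- names(traits) %||% paste0("trait", seq_len(k))
  aligned <- lapply(traits, function(s) align_to_ld(validate_sumstats(s), ld))
  m <- nrow(ld$variants)
  blocks <- block_assign(m, n_blocks)
  l2 <- ld$variants$l2
  uni <- lapply(aligned, function(s)
    ldsc_univariate(s$z, s$n, l2, m, blocks, chi2_cap = chi2_cap))
  keep <- Reduce(`&`, lapply(uni, `[[`, "keep"))
  if (sum(keep) < 2 * n_blocks && sum(keep) < m)
    blocks_k <- block_assign(sum(keep), n_blocks)
  else blocks_k <- match(blocks[keep], sort(unique(blocks[keep])))
  unik <- lapply(aligned, function(s)
    ldsc_univariate(s$z[keep], s$n[keep], l2[keep], m, blocks_k, chi2_cap = FALSE))
  nb <- unik[[1]]$n_blocks
  idx <- vech_index(k)
  p <- nrow(idx)
  est <- numeric(p)
  del <- matrix(0, nb, p)
  intercepts <- matrix(0, k, k, dimnames = list(nms, nms))
  for (e in seq_len(p)) {
    i <- idx[e, "row"]; j <- idx[e, "col"]
    if (i == j) {
      est[e] <- unik[[i]]$est[2]
      del[, e] <- unik[[i]]$delete[, 2]
      intercepts[i, i] <- unik[[i]]$est[1]
    } else {
      si <- aligned[[i]]; sj <- aligned[[j]]
      fx <- ldsc_bivariate(si$z[keep], si$n[keep], sj$z[keep], sj$n[keep],
                           l2[keep], m, blocks_k,
                           unik[[i]]$est[2], unik[[j]]$est[2],
                           rep(TRUE, sum(keep)))
      est[e] <- fx$est[2]
      del[, e] <- fx$delete[, 2]
      intercepts[i, j] <- intercepts[j, i] <- fx$est[1]
    }
  }
  S <- unvech(est, k)
  dimnames(S) <- list(nms, nms)
  V <- jackknife_cov(del)
  lbl <- paste(nms[idx[, "row"]], nms[idx[, "col"]], sep = ":")
  dimnames(V) <- list(lbl, lbl)
  structure(list(traits = nms, S = S, V = V, intercepts = intercepts,
                 m = m, n_blocks = nb),
            class = "cov_struct")
}

#' @export
print.cov_struct <- function(x, ...) {
  cat(sprintf("Genetic covariance (LDSC) over %d traits, M = %d, %d jackknife blocks\n",
              length(x$traits), x$m, x$n_blocks))
  print(round(x$S, 5))
  cat("h2 SEs:", paste(sprintf("%.4f", sqrt(diag(x$V)[vech_diag_pos(length(x$traits))])),
                       collapse = ", "), "\n")
  invisible(x)
}

# positions of the diagonal elements inside the vech ordering
vech_diag_pos <- function(k) {
  idx <- vech_index(k)
  which(idx[, "row"] == idx[, "col"])
}

#' Stratified LD-score regression: annotation enrichment
#'
#' Multiple weighted regression of chi-squared statistics on per-annotation LD
#' scores yields per-annotation effect coefficients tau; the heritability
#' attributed to annotation c is the sum over its member variants of their
#' modelled per-SNP heritability, and enrichment is the ratio of the proportion
#' of heritability to the proportion of variants. The base (all-ones)
#' annotation has enrichment exactly 1 by construction. Standard errors and
#' p-values (vs enrichment = 1) come from the delete-a-block jackknife. The MHC
#' interval is excluded by default when positions are available.
#'
#' @inheritParams estimate_h2
#' @param ld An `ld_reference` with annotations attached ([add_annotations()]).
#' @param exclude_mhc Drop variants in the chr6:25-34 Mb interval.
#' @return Object of class `ldsc_enrichment`: a `table` data frame (annotation,
#'   `m_annot`, `prop_snps`, `prop_h2`, `enrichment`, `se`, `p`), coefficients
#'   `tau`, and the total `h2`.
#' @export
stratified_h2 <- function(s, ld, exclude_mhc = TRUE, n_blocks = 200,
                          chi2_cap = TRUE) {
  if (is.null(ld$annotations)) stopf("reference carries no annotations")
  s <- align_to_ld(validate_sumstats(s), ld)
  A <- ld$annotations
  L <- ld$annot_l2
  l2 <- ld$variants$l2
  keep <- rep(TRUE, nrow(A))
  if (exclude_mhc) keep <- keep & !in_mhc(ld)
  m_annot <- colSums(A[keep, , drop = FALSE])
  m <- sum(keep)
  chi2 <- s$z^2
  cap <- if (chi2_cap) chi2 <= max(80, 0.001 * max(s$n)) else rep(TRUE, length(chi2))
  use <- keep & cap
  X <- cbind(1, s$n[use] * L[use, , drop = FALSE])
  colnames(X) <- c("intercept", colnames(A))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stopf("collinear annotation column(s): %s", paste(bad, collapse = ", "))
  }
  blocks <- block_assign(sum(use), n_blocks)
  h2_agg <- max((mean(chi2[use]) - 1) * m / (mean(s$n[use]) * mean(l2[use])), 0)
  w <- ldsc_weights(l2[use], s$n[use], h2_agg, m)
  fit <- wls_blocks(X, chi2[use], w, blocks)
  tau <- fit$est[-1]
  Ak <- A[keep, , drop = FALSE]
  per_snp <- as.numeric(Ak %*% tau)
  h2_c <- as.numeric(crossprod(Ak, per_snp))
  h2_tot <- h2_c[1]
  enr_from_tau <- function(tauv) {
    h2c <- as.numeric(crossprod(Ak, as.numeric(Ak %*% tauv)))
    (h2c / h2c[1]) / (m_annot / m)
  }
  enr <- enr_from_tau(tau)
  enr_del <- t(apply(fit$delete[, -1, drop = FALSE], 1, enr_from_tau))
  se <- jackknife_se(enr_del)
  pv <- 2 * stats::pnorm(-abs((enr - 1) / se))
  se[1] <- 0; pv[1] <- NA_real_   # base is 1 identically
  tab <- data.frame(annotation = colnames(A), m_annot = m_annot,
                    prop_snps = m_annot / m, prop_h2 = h2_c / h2_tot,
                    enrichment = enr, se = se, p = pv,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, tau = stats::setNames(tau, colnames(A)),
                 h2 = h2_tot, m = m, n_blocks = max(blocks)),
            class = "ldsc_enrichment")
}

#' @export
print.ldsc_enrichment <- function(x, ...) {
  cat(sprintf("Stratified LDSC over %d annotations (total h2 = %.4f)\n",
              nrow(x$table), x$h2))
  print(x$table, digits = 4)
  invisible(x)
}
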