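# Single common-factor model fitted to the LDSC genetic covariance matrix by
# diagonally weighted least squares, with fit statistics, model comparison,
# Heywood-case correction, and the per-SNP common-factor GWAS.

# implied covariance and its Jacobian wrt (free loadings, phi, theta)
implied_sigma <- function(lambda, phi, theta) {
  phi * tcrossprod(lambda) + diag(theta, length(lambda))
}

factor_jacobian <- function(lambda, phi, theta, free_idx) {
  k <- length(lambda)
  idx <- vech_index(k)
  p <- nrow(idx)
  J <- matrix(0, p, length(free_idx) + 1L + k)
  for (e in seq_len(p)) {
    i <- idx[e, "row"]; j <- idx[e, "col"]
    for (a in seq_along(free_idx)) {
      fa <- free_idx[a]
      J[e, a] <- phi * ((i == fa) * lambda[j] + lambda[i] * (j == fa))
    }
    J[e, length(free_idx) + 1L] <- lambda[i] * lambda[j]
    if (i == j) J[e, length(free_idx) + 1L + i] <- 1
  }
  J
}

dwls_objective <- function(par, s_vech, d, k, marker, free_idx) {
  lambda <- numeric(k); lambda[marker] <- 1
  lambda[free_idx] <- par[seq_along(free_idx)]
  phi <- par[length(free_idx) + 1L]
  theta <- par[(length(free_idx) + 2L):length(par)]
  r <- s_vech - vech(implied_sigma(lambda, phi, theta))
  sum(r^2 / d)
}

dwls_gradient <- function(par, s_vech, d, k, marker, free_idx) {
  lambda <- numeric(k); lambda[marker] <- 1
  lambda[free_idx] <- par[seq_along(free_idx)]
  phi <- par[length(free_idx) + 1L]
  theta <- par[(length(free_idx) + 2L):length(par)]
  r <- s_vech - vech(implied_sigma(lambda, phi, theta))
  J <- factor_jacobian(lambda, phi, theta, free_idx)
  as.numeric(-2 * crossprod(J, r / d))
}

#' Fit a single common-factor model by diagonally weighted least squares
#'
#' Minimizes `(vech(S) - vech(Sigma))' diag(V)^-1 (vech(S) - vech(Sigma))` with
#' `Sigma = phi * lambda lambda' + diag(theta)`, identification by fixing the
#' marker indicator's loading to 1 and estimating the factor variance `phi`.
#' The optimizer is quasi-Newton (L-BFGS-B) with the analytic gradient and five
#' random restarts from perturbed starting values. Parameter standard errors
#' use the sandwich estimator with the full sampling covariance V. If any
#' residual variance is negative at the unconstrained optimum (a Heywood case)
#' and `bound_residuals` is set, the model is re-fitted with `theta >= 0`
#' active and flagged `heywood_corrected`. Promax rotation, listed alongside
#' DWLS in this literature, is the identity for a single factor and is applied
#' as an explicit no-op.
#'
#' @param cov A `cov_struct` from [genetic_covariance()] (k >= 3 indicators).
#' @param marker Name (or index) of the indicator whose loading is fixed to 1.
#' @param bound_residuals Re-fit with non-negative residual variances when the
#'   unconstrained optimum is inadmissible.
#' @return Object of class `factor_fit`: `loadings` (unstandardized, marker
#'   fixed at 1), `factor_var`, `residuals` (theta), `std_loadings` and
#'   `std_loading_se`, `par_cov`, `heywood_corrected`, `converged`, `n_free`,
#'   and `fit_stats` from [compute_fit_statistics()].
#' @export
fit_common_factor <- function(cov, marker = 1L, bound_residuals = TRUE) {
  stopifnot(inherits(cov, "cov_struct"))
  k <- length(cov$traits)
  if (k < 3) stopf("at least three indicators required")
  d <- diag(cov$V)
  if (any(d <= 0)) stopf("diagonal of V must be strictly positive")
  if (is.character(marker)) marker <- match(marker, cov$traits)
  if (is.na(marker) || marker < 1 || marker > k) stopf("unknown marker indicator")
  n_free <- 2L * k   # (k-1) loadings + factor variance + k residuals
  p_elems <- k * (k + 1L) / 2L
  if (p_elems < n_free && k > 3)
    stopf("model under-identified: %d free parameters, %d moments", n_free, p_elems)
  free_idx <- setdiff(seq_len(k), marker)
  s_vech <- vech(cov$S)
  run <- function(theta_lower) {
    best <- best_any <- NULL
    set.seed(20260101L)
    for (r in 1:5) {
      jitter <- if (r == 1) 0 else stats::rnorm(n_free, 0, 0.1)
      start <- c(rep(0.5, k - 1L),
                 max(cov$S[marker, marker] * 0.5, 1e-4),
                 pmax(0.5 * diag(cov$S), 1e-4))
      start <- start * exp(jitter)
      lower <- c(rep(-Inf, k - 1L), 1e-10, rep(theta_lower, k))
      opt <- stats::optim(start, dwls_objective, dwls_gradient,
                          s_vech = s_vech, d = d, k = k,
                          marker = marker, free_idx = free_idx,
                          method = "L-BFGS-B", lower = lower,
                          control = list(factr = 10, pgtol = 1e-12,
                                         maxit = 2000L))
      # with factr this tight L-BFGS-B can stop with an abnormal line-search
      # code at a genuine optimum; accept it when the gradient is tiny
      g <- dwls_gradient(opt$par, s_vech, d, k, marker, free_idx)
      opt$grad_ok <- max(abs(g)) < 1e-4 * (1 + abs(opt$value))
      if (is.null(best_any) || opt$value < best_any$value) best_any <- opt
      if ((opt$convergence == 0 || opt$grad_ok) &&
          (is.null(best) || opt$value < best$value)) best <- opt
    }
    best %||% best_any
  }
  opt <- run(-Inf)
  heywood <- FALSE
  theta_hat <- opt$par[(k + 1L):(2L * k)]
  if (bound_residuals && any(theta_hat < 0)) {
    opt <- run(0)
    heywood <- TRUE
  }
  bounded_ok <- heywood && opt$convergence == 0   # KKT point, gradient need not vanish
  if (opt$convergence != 0 && !isTRUE(opt$grad_ok) && !bounded_ok &&
      opt$value > 1e-6)
    stopf("DWLS optimization failed to converge (best objective %.3g)", opt$value)
  lambda <- numeric(k); lambda[marker] <- 1
  lambda[free_idx] <- opt$par[seq_len(k - 1L)]
  phi <- opt$par[k]
  theta <- opt$par[(k + 1L):(2L * k)]
  lambda <- promax_single(lambda)
  # sandwich covariance of the free parameters using the full V
  J <- factor_jacobian(lambda, phi, theta, free_idx)
  W <- 1 / d
  B <- crossprod(J, J * W)
  Binv <- tryCatch(solve(B), error = function(e) MASS::ginv(B))
  meat <- crossprod(J * W, cov$V %*% (J * W))
  par_cov <- Binv %*% meat %*% Binv
  par_names <- c(paste0("lambda_", cov$traits[free_idx]), "phi",
                 paste0("theta_", cov$traits))
  dimnames(par_cov) <- list(par_names, par_names)
  sig_hat <- implied_sigma(lambda, phi, theta)
  std_load <- lambda * sqrt(phi) / sqrt(diag(sig_hat))
  std_se <- std_loading_se(lambda, phi, theta, free_idx, par_cov)
  fit <- structure(list(
    traits = cov$traits, marker = cov$traits[marker],
    loadings = stats::setNames(lambda, cov$traits),
    factor_var = phi,
    residuals = stats::setNames(theta, cov$traits),
    std_loadings = stats::setNames(std_load, cov$traits),
    std_loading_se = stats::setNames(std_se, cov$traits),
    par_cov = par_cov, objective = opt$value,
    heywood_corrected = heywood, converged = TRUE,
    n_free = n_free, df = as.integer(p_elems - n_free)), class = "factor_fit")
  fit$fit_stats <- compute_fit_statistics(fit, cov)
  fit
}

# promax rotation of a one-column loading pattern is the identity; kept as an
# explicit step so the estimation pipeline mirrors the multi-factor convention
promax_single <- function(lambda) lambda

std_loading_se <- function(lambda, phi, theta, free_idx, par_cov) {
  k <- length(lambda)
  par <- c(lambda[free_idx], phi, theta)
  stdfun <- function(p) {
    lam <- lambda; lam[free_idx] <- p[seq_along(free_idx)]
    ph <- p[length(free_idx) + 1L]
    th <- p[(length(free_idx) + 2L):length(p)]
    lam * sqrt(ph) / sqrt(diag(implied_sigma(lam, ph, th)))
  }
  eps <- 1e-6
  G <- matrix(0, k, length(par))
  for (a in seq_along(par)) {
    up <- par; up[a] <- up[a] + eps
    dn <- par; dn[a] <- dn[a] - eps
    G[, a] <- (stdfun(up) - stdfun(dn)) / (2 * eps)
  }
  sqrt(pmax(diag(G %*% par_cov %*% t(G)), 0))
}

#' Model fit statistics for a common-factor fit
#'
#' The model chi-square is the residual-based statistic: the quadratic form of
#' the moment residuals `r = vech(S) - vech(Sigma_hat)` weighted by the
#' generalized inverse of their asymptotic covariance `(I - P) V (I - P)'`,
#' where `P` is the projection induced by the DWLS estimator at the optimum.
#' An exact fit gives 0 and, under a correct model, the statistic is
#' asymptotically chi-squared on `df = k(k+1)/2 - n_free` whatever the fitting
#' weights (the naive form `r' V^-1 r` is inflated above `df` when the
#' estimator is not V-efficient). `AIC = chi2 + 2 n_free`;
#' `CFI = 1 - max(chi2_m - df_m, 0) / max(chi2_i - df_i, chi2_m - df_m, 0)`
#' against an independence model that keeps every indicator heritable but
#' uncorrelated (free variances, zero covariances); SRMR is the root mean
#' square difference between the correlation-standardized observed and implied
#' matrices over the unique elements.
#'
#' @param fit A `factor_fit`.
#' @param cov The `cov_struct` the model was fitted to.
#' @return List with `chi2`, `df`, `p`, `aic`, `cfi`, `srmr`, `chi2_indep`,
#'   `df_indep`, and `v_rank_deficient`.
#' @export
compute_fit_statistics <- function(fit, cov) {
  k <- length(cov$traits)
  p_elems <- k * (k + 1L) / 2L
  sig_hat <- implied_sigma(fit$loadings, fit$factor_var, fit$residuals)
  r <- vech(cov$S) - vech(sig_hat)
  qrv <- qr(cov$V)
  deficient <- qrv$rank < p_elems
  w <- 1 / diag(cov$V)
  resid_chi2 <- function(r, J) {
    # Browne-style residual statistic: weight by the ginv of the residual
    # covariance under the (possibly inefficient) diagonal-weight projection
    P <- J %*% solve(crossprod(J, J * w), t(J * w))
    G <- (diag(p_elems) - P) %*% cov$V %*% t(diag(p_elems) - P)
    max(as.numeric(t(r) %*% MASS::ginv(G) %*% r), 0)
  }
  free_idx <- setdiff(seq_len(k), match(fit$marker, fit$traits))
  J <- factor_jacobian(fit$loadings, fit$factor_var, fit$residuals, free_idx)
  chi2 <- if (deficient && qrv$rank < k) NA_real_ else resid_chi2(r, J)
  df <- as.integer(p_elems - fit$n_free)
  if (df == 0L) chi2 <- if (is.na(chi2)) chi2 else 0
  # independence model: variances free (fitted exactly), covariances zero
  r_i <- vech(cov$S - diag(diag(cov$S)))
  J_i <- diag(p_elems)[, vech_diag_pos(k), drop = FALSE]
  chi2_i <- resid_chi2(r_i, J_i)
  df_i <- as.integer(p_elems - k)
  num <- max(chi2 - df, 0)
  den <- max(chi2_i - df_i, chi2 - df, 0)
  cfi <- if (is.na(chi2)) NA_real_ else if (den == 0) 1 else 1 - num / den
  s_cor <- stats::cov2cor(cov$S)
  sig_cor <- stats::cov2cor(sig_hat)
  dr <- (s_cor - sig_cor)[lower.tri(s_cor, diag = TRUE)]
  srmr <- sqrt(mean(dr^2))
  list(chi2 = chi2, df = df,
       p = if (!is.na(chi2) && df > 0) stats::pchisq(chi2, df, lower.tail = FALSE)
           else NA_real_,
       aic = chi2 + 2 * fit$n_free, cfi = cfi, srmr = srmr,
       chi2_indep = chi2_i, df_indep = df_i, v_rank_deficient = deficient)
}

#' @export
print.factor_fit <- function(x, ...) {
  cat(sprintf("Common factor model (DWLS), marker = %s%s\n", x$marker,
              if (x$heywood_corrected) ", Heywood-corrected" else ""))
  tab <- data.frame(loading = x$loadings, std_loading = x$std_loadings,
                    std_se = x$std_loading_se, residual = x$residuals)
  print(round(tab, 4))
  fs <- x$fit_stats
  cat(sprintf("factor variance %.5f; chi2(%d) = %.3f, p = %.3g, AIC = %.2f, CFI = %.3f, SRMR = %.4f\n",
              x$factor_var, fs$df, fs$chi2, fs$p, fs$aic, fs$cfi, fs$srmr))
  invisible(x)
}

#' @export
coef.factor_fit <- function(object, ...) {
  c(object$loadings, phi = object$factor_var, object$residuals)
}

#' @export
summary.factor_fit <- function(object, ...) {
  out <- list(fit = object, stats = object$fit_stats)
  class(out) <- "summary.factor_fit"
  out
}

#' @export
print.summary.factor_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("independence model: chi2(%d) = %.3f\n",
              x$stats$df_indep, x$stats$chi2_indep))
  invisible(x)
}

#' Compare candidate factor models on AIC, SRMR and CFI
#'
#' A model is declared superior only if it dominates every competitor on all
#' three criteria: lower AIC, lower SRMR, and higher CFI (strictly better on at
#' least one criterion against each competitor). Otherwise the decision is
#' `"indeterminate"` and the per-criterion winners are reported.
#'
#' @param fits List (optionally named) of two or more `factor_fit` objects.
#' @return Object of class `model_comparison`: `decision` (winning model name
#'   or `"indeterminate"`), `table` of criteria, and per-criterion winners.
#' @export
compare_models <- function(fits) {
  if (length(fits) < 2) stopf("at least two fits required")
  nms <- names(fits) %||% paste0("model", seq_along(fits))
  tab <- data.frame(
    model = nms,
    aic = vapply(fits, function(f) f$fit_stats$aic, 0),
    srmr = vapply(fits, function(f) f$fit_stats$srmr, 0),
    cfi = vapply(fits, function(f) f$fit_stats$cfi, 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
  dominates <- function(i, j) {
    better <- c(tab$aic[i] < tab$aic[j], tab$srmr[i] < tab$srmr[j],
                tab$cfi[i] > tab$cfi[j])
    no_worse <- c(tab$aic[i] <= tab$aic[j], tab$srmr[i] <= tab$srmr[j],
                  tab$cfi[i] >= tab$cfi[j])
    all(no_worse) && any(better)
  }
  winner <- NULL
  for (i in seq_along(fits)) {
    if (all(vapply(setdiff(seq_along(fits), i), function(j) dominates(i, j), TRUE)))
      { winner <- nms[i]; break }
  }
  crit_winner <- c(aic = nms[which.min(tab$aic)],
                   srmr = nms[which.min(tab$srmr)],
                   cfi = nms[which.max(tab$cfi)])
  structure(list(decision = winner %||% "indeterminate",
                 table = tab, criterion_winners = crit_winner),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  print(x$table, digits = 4)
  cat("decision:", x$decision, "\n")
  if (x$decision == "indeterminate")
    cat("per-criterion winners:",
        paste(names(x$criterion_winners), x$criterion_winners,
              sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Per-SNP common-factor GWAS
#'
#' For each variant the standardized per-trait effects (`beta = Z / sqrt(N)`)
#' extend the genetic covariance matrix with SNP-indicator covariances; holding
#' the measurement structure at the fitted optimum, the SNP-on-factor
#' regression solves the working model `beta_t = lambda_t * b` by generalized
#' least squares with the per-SNP standard errors (and, optionally, the
#' cross-trait sampling correlation implied by the LDSC intercepts) as the
#' error covariance. Variants missing in any trait are skipped and counted.
#' The per-SNP effective sample size attached to the output is the sum of the
#' indicator sample sizes weighted by squared standardized loadings.
#'
#' @param cov A `cov_struct` (supplies the intercept matrix).
#' @param traits Named list of harmonized `sumstats` data frames in the order
#'   of `cov$traits`.
#' @param fit The baseline `factor_fit`.
#' @param error_cor `"intercepts"` (default) to derive the cross-trait error
#'   correlation from the LDSC cross-intercepts, `NULL`/`"identity"` for
#'   independent errors, or an explicit k x k correlation matrix.
#' @return A `sumstats`-compatible data frame of class `factor_gwas` with
#'   columns `snp`, `a1`, `a2`, `beta`, `se`, `z`, `p`, `n`; the number of
#'   skipped variants is in attribute `"n_skipped"`.
#' @export
factor_gwas <- function(cov, traits, fit, error_cor = "intercepts") {
  k <- length(cov$traits)
  if (length(traits) != k) stopf("expected %d trait tables", k)
  ids <- traits[[1]]$snp
  for (s in traits[-1]) if (!identical(s$snp, ids))
    stopf("trait tables are not aligned; harmonize first")
  lambda <- fit$loadings
  rho <- diag(k)
  if (is.matrix(error_cor)) rho <- error_cor
  else if (identical(error_cor, "intercepts")) {
    ints <- cov$intercepts
    dd <- sqrt(pmax(diag(ints), 1e-8))
    rho <- ints / tcrossprod(dd)
    diag(rho) <- 1
    eig <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
    if (min(eig) < 1e-8) rho <- diag(k)   # fall back when not positive definite
  }
  B <- vapply(traits, function(s) s$beta %||% (s$z / sqrt(s$n)), numeric(length(ids)))
  SE <- vapply(traits, function(s) s$se %||% (1 / sqrt(s$n)), numeric(length(ids)))
  Nmat <- vapply(traits, function(s) s$n, numeric(length(ids)))
  ok <- stats::complete.cases(B) & stats::complete.cases(SE)
  n_skipped <- sum(!ok)
  rho_inv <- solve(rho)
  bvec <- sevec <- rep(NA_real_, length(ids))
  constant_se <- all(apply(SE, 2, function(x) diff(range(x[ok]))) < 1e-12)
  if (constant_se) {
    se0 <- SE[which(ok)[1], ]
    Oinv <- rho_inv / tcrossprod(se0)
    denom <- as.numeric(t(lambda) %*% Oinv %*% lambda)
    bvec[ok] <- as.numeric(B[ok, , drop = FALSE] %*% (Oinv %*% lambda)) / denom
    sevec[ok] <- sqrt(1 / denom)
  } else {
    for (j in which(ok)) {
      Oinv <- rho_inv / tcrossprod(SE[j, ])
      denom <- as.numeric(t(lambda) %*% Oinv %*% lambda)
      bvec[j] <- as.numeric(t(lambda) %*% Oinv %*% B[j, ]) / denom
      sevec[j] <- sqrt(1 / denom)
    }
  }
  w_n <- fit$std_loadings^2
  n_eff <- as.numeric(Nmat %*% w_n)
  out <- data.frame(snp = ids, a1 = traits[[1]]$a1, a2 = traits[[1]]$a2,
                    beta = bvec, se = sevec, z = bvec / sevec,
                    p = 2 * stats::pnorm(-abs(bvec / sevec)),
                    n = n_eff, stringsAsFactors = FALSE)
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("factor_gwas", "sumstats", "data.frame")
  attr(out, "n_skipped") <- n_skipped
  out
}
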