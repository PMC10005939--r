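# Head-to-head comparison layer: difference tests, multiple-testing control,
# genetic-correlation-profile concordance, and the assembled report.

#' Two-sided z-test for a difference of independent estimates
#'
#' `z = (est1 - est2) / sqrt(se1^2 + se2^2)` with a two-sided normal p-value.
#' Independence of the two estimates is assumed; when the underlying GWAS share
#' samples the test is anti-conservative, and a known covariance between the
#' estimates can be supplied to correct the denominator.
#'
#' @param est1,se1,est2,se2 Estimates and their standard errors (`se > 0`).
#' @param covar Optional covariance between the two estimates.
#' @return List with `z` and `p`.
#' @export
zdiff_test <- function(est1, se1, est2, se2, covar = 0) {
  if (se1 <= 0 || se2 <= 0) stopf("standard errors must be positive")
  v <- se1^2 + se2^2 - 2 * covar
  if (v <= 0) stopf("non-positive variance of the difference")
  z <- (est1 - est2) / sqrt(v)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure at level `q`: with ordered p-values `p_(1) <= ... <=
#' p_(m)`, all hypotheses up to the largest `i` with `p_(i) <= i q / m` are
#' flagged. Adjusted p-values follow the standard monotone BH adjustment.
#'
#' @param pvals Vector of p-values in `(0, 1]`.
#' @param q FDR level.
#' @return List with logical `significant` flags and `adjusted` p-values, in
#'   input order; empty input yields empty output.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (!length(pvals)) return(list(significant = logical(0), adjusted = numeric(0)))
  if (any(pvals <= 0 | pvals > 1)) stopf("p-values must lie in (0, 1]")
  m <- length(pvals)
  adjusted <- stats::p.adjust(pvals, method = "BH")
  ord <- order(pvals)
  thr_ok <- pvals[ord] <= seq_len(m) * q / m
  cutoff <- if (any(thr_ok)) pvals[ord][max(which(thr_ok))] else -Inf
  list(significant = pvals <= cutoff, adjusted = adjusted)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param m Number of tests (at least 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (m < 1) stopf("m must be at least 1")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  alpha / m
}

#' Concordance of two genetic-correlation profiles
#'
#' Ordinary least squares of one trait's vector of genetic correlations with a
#' panel of external traits on the other's, with intercept; reports the slope,
#' the single-predictor adjusted R-squared
#' `1 - (1 - R2) (n - 1) / (n - 2)`, and the slope's two-sided p-value.
#'
#' @param rg_response,rg_predictor Equal-length numeric vectors (`n >= 3`).
#' @return List with `slope`, `intercept`, `adj_r2`, `p`, `n`.
#' @export
concordance_regression <- function(rg_response, rg_predictor) {
  if (length(rg_response) != length(rg_predictor)) stopf("vectors differ in length")
  n <- length(rg_response)
  if (n < 3) stopf("at least 3 pairs required")
  if (stats::var(rg_predictor) == 0) stopf("zero variance in the predictor profile")
  fit <- stats::lm(rg_response ~ rg_predictor)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       adj_r2 = sm$adj.r.squared,
       p = sm$coefficients[2, 4], n = n)
}

#' Assemble the comparison report
#'
#' Bundles the component analyses of the aggregate-trait vs latent-factor
#' comparison into one self-describing object: heritability pair with the
#' difference test, the mutual genetic correlation, genetic-correlation
#' profiles with BH-FDR flags, enrichment tables with per-annotation difference
#' tests, mixture fits with projection curves, and the PGS association table.
#' Components may be omitted; the report lists the gaps rather than failing.
#'
#' @param h2_aggregate,h2_factor `ldsc_h2` objects.
#' @param rg `ldsc_rg` between the two trait definitions.
#' @param rg_profiles List with numeric vectors `aggregate` and `factor` of
#'   correlations with a shared external-trait panel, and optionally `p`
#'   (p-values entering the FDR correction).
#' @param enrichment List of `ldsc_enrichment` objects (per method/trait).
#' @param mixtures List with `mixture_fit` elements `aggregate` and `factor`.
#' @param projections List of `projection_curve` objects.
#' @param pgs Data frame of PGS association rows ([pgs_association()]).
#' @param seed Seed recorded for provenance.
#' @return Object of class `comparison_report`.
#' @export
build_report <- function(h2_aggregate = NULL, h2_factor = NULL, rg = NULL,
                         rg_profiles = NULL, enrichment = NULL,
                         mixtures = NULL, projections = NULL, pgs = NULL,
                         seed = NA_integer_) {
  components <- list(h2_aggregate = h2_aggregate, h2_factor = h2_factor,
                     rg = rg, rg_profiles = rg_profiles,
                     enrichment = enrichment, mixtures = mixtures,
                     projections = projections, pgs = pgs)
  missing <- names(components)[vapply(components, is.null, TRUE)]
  out <- list(components = components, missing = missing, seed = seed)
  if (!is.null(h2_aggregate) && !is.null(h2_factor))
    out$h2_difference <- zdiff_test(h2_aggregate$h2, h2_aggregate$se,
                                    h2_factor$h2, h2_factor$se)
  if (!is.null(rg_profiles)) {
    out$concordance <- concordance_regression(rg_profiles$factor,
                                              rg_profiles$aggregate)
    if (!is.null(rg_profiles$p)) out$profile_fdr <- bh_fdr(rg_profiles$p)
  }
  if (!is.null(enrichment) && length(enrichment) >= 2) {
    e1 <- enrichment[[1]]$table; e2 <- enrichment[[2]]$table
    shared <- intersect(e1$annotation, e2$annotation)
    shared <- shared[e1$se[match(shared, e1$annotation)] > 0 &
                     e2$se[match(shared, e2$annotation)] > 0]
    out$enrichment_difference <- do.call(rbind, lapply(shared, function(a) {
      i <- match(a, e1$annotation); j <- match(a, e2$annotation)
      zt <- zdiff_test(e1$enrichment[i], e1$se[i], e2$enrichment[j], e2$se[j])
      data.frame(annotation = a, z = zt$z, p = zt$p, stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(mixtures) && !is.null(mixtures$aggregate) && !is.null(mixtures$factor))
    out$pi_difference <- compare_pi(mixtures$aggregate, mixtures$factor)
  structure(out, class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Aggregate-trait vs latent-factor comparison report\n")
  co <- x$components
  if (!is.null(co$h2_aggregate))
    cat(sprintf("  h2 aggregate: %.4f (SE %.4f)\n", co$h2_aggregate$h2, co$h2_aggregate$se))
  if (!is.null(co$h2_factor))
    cat(sprintf("  h2 factor:    %.4f (SE %.4f)\n", co$h2_factor$h2, co$h2_factor$se))
  if (!is.null(x$h2_difference))
    cat(sprintf("  h2 difference: z = %.3f, p = %.3g\n",
                x$h2_difference$z, x$h2_difference$p))
  if (!is.null(co$rg))
    cat(sprintf("  rg(aggregate, factor) = %.4f (SE %.4f)\n", co$rg$rg, co$rg$se))
  if (!is.null(x$concordance))
    cat(sprintf("  rg-profile concordance: slope %.3f, adj R2 = %.4f, p = %.3g\n",
                x$concordance$slope, x$concordance$adj_r2, x$concordance$p))
  if (!is.null(x$pi_difference))
    cat(sprintf("  pi_c %.4f vs %.4f: p = %.3g\n",
                x$pi_difference$pi_a, x$pi_difference$pi_b, x$pi_difference$p))
  if (length(x$missing))
    cat("  missing components:", paste(x$missing, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a comparison report
#'
#' Writes a machine-readable JSON bundle, a TSV of the headline numbers, and a
#' short markdown rendering.
#'
#' @param report A `comparison_report`.
#' @param json_path,tsv_path,md_path Output paths (any may be `NULL` to skip).
#' @return Invisibly, the list of written paths.
#' @export
write_report <- function(report, json_path = NULL, tsv_path = NULL,
                         md_path = NULL) {
  co <- report$components
  rows <- list()
  add <- function(metric, value) rows[[length(rows) + 1L]] <<-
    data.frame(metric = metric, value = value, stringsAsFactors = FALSE)
  if (!is.null(co$h2_aggregate)) add("h2_aggregate", co$h2_aggregate$h2)
  if (!is.null(co$h2_factor)) add("h2_factor", co$h2_factor$h2)
  if (!is.null(report$h2_difference)) add("h2_diff_p", report$h2_difference$p)
  if (!is.null(co$rg)) add("rg", co$rg$rg)
  if (!is.null(report$concordance)) add("rg_profile_adj_r2", report$concordance$adj_r2)
  if (!is.null(co$mixtures$aggregate)) add("pi_c_aggregate", co$mixtures$aggregate$pi_c)
  if (!is.null(co$mixtures$factor)) add("pi_c_factor", co$mixtures$factor$pi_c)
  if (!is.null(report$pi_difference)) add("pi_diff_p", report$pi_difference$p)
  tab <- do.call(rbind, rows)
  written <- list()
  if (!is.null(tsv_path)) {
    utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
    written$tsv <- tsv_path
  }
  if (!is.null(json_path)) {
    payload <- list(seed = report$seed, missing = report$missing,
                    metrics = stats::setNames(as.list(tab$value), tab$metric))
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
    written$json <- json_path
  }
  if (!is.null(md_path)) {
    lines <- c("# Aggregate trait vs latent factor",
               "", "| metric | value |", "| --- | --- |",
               sprintf("| %s | %.6g |", tab$metric, tab$value))
    if (length(report$missing))
      lines <- c(lines, "",
                 paste("Missing components:",
                       paste(report$missing, collapse = ", ")))
    writeLines(lines, md_path)
    written$md <- md_path
  }
  invisible(written)
}
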