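# Reading, writing, harmonizing and quality-filtering GWAS summary statistics
# and LD-score tables. The on-disk dialects are the whitespace-delimited
# "munged" layout (SNP A1 A2 Z N) and generic TSV with a column map; gzip is
# handled transparently via the file extension.

VALID_ALLELES <- c("A", "C", "G", "T")

validate_sumstats <- function(s) {
  need <- c("snp", "a1", "a2", "z", "n")
  missing_cols <- setdiff(need, names(s))
  if (length(missing_cols))
    stopf("missing required column(s): %s", paste(missing_cols, collapse = ", "))
  if (nrow(s)) {
    if (any(!s$a1 %in% VALID_ALLELES) || any(!s$a2 %in% VALID_ALLELES))
      stopf("alleles must be one of A/C/G/T")
    if (any(s$a1 == s$a2)) stopf("a1 and a2 must differ")
    if (!is.null(s$se) && any(s$se <= 0, na.rm = TRUE)) stopf("se must be positive")
    if (!is.null(s$beta) && !is.null(s$se)) {
      dz <- abs(s$z - s$beta / s$se)
      if (any(dz > 1e-6, na.rm = TRUE))
        stopf("z inconsistent with beta/se (max |z - beta/se| = %.2g)", max(dz))
    }
  }
  class(s) <- unique(c("sumstats", class(s)))
  s
}

#' Read GWAS summary statistics
#'
#' `dialect = "munged"` expects whitespace-delimited columns `SNP A1 A2 Z N`
#' (extra columns are preserved); `dialect = "tsv"` reads a tab-separated table
#' and renames columns through `col_map`, e.g. `c(snp = "rsid", z = "zscore")`.
#' Files ending in `.gz` are decompressed transparently.
#'
#' @param path File path.
#' @param dialect `"munged"` or `"tsv"`.
#' @param col_map Named character vector mapping canonical names (`snp`, `a1`,
#'   `a2`, `z`, `n`, ...) to file column names, for `dialect = "tsv"`.
#' @return A `sumstats` data frame.
#' @export
read_sumstats <- function(path, dialect = c("munged", "tsv"), col_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          sep = if (dialect == "tsv") "\t" else "",
                          check.names = FALSE, colClasses = NA)
  if (dialect == "tsv" && !is.null(col_map)) {
    for (canon in names(col_map)) {
      hit <- match(col_map[[canon]], names(df))
      if (is.na(hit)) stopf("missing required column: %s", col_map[[canon]])
      names(df)[hit] <- canon
    }
  }
  names(df) <- ifelse(tolower(names(df)) %in% c("snp", "a1", "a2", "z", "n",
                                                "beta", "se", "chrom", "pos", "freq"),
                      tolower(names(df)), names(df))
  if (!is.null(df$z) && nrow(df) && !is.numeric(df$z)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$z))))
    stopf("non-numeric Z at line %d", bad[1] + 1L)
  }
  validate_sumstats(df)
}

#' Write GWAS summary statistics
#'
#' Inverse of [read_sumstats()]: `read_sumstats(write_sumstats(x, f), dialect)`
#' reproduces `x` field for field. The munged dialect writes `SNP A1 A2 Z N`
#' plus any extra columns, space-delimited; paths ending `.gz` are compressed.
#'
#' @param s A `sumstats` data frame.
#' @param path Output path.
#' @param dialect `"munged"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(s, path, dialect = c("munged", "tsv")) {
  dialect <- match.arg(dialect)
  df <- as.data.frame(s)
  if (dialect == "munged") {
    lead <- c("snp", "a1", "a2", "z", "n")
    df <- df[, c(lead, setdiff(names(df), lead)), drop = FALSE]
    names(df)[1:5] <- c("SNP", "A1", "A2", "Z", "N")
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = if (dialect == "tsv") "\t" else " ",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an LD-score table
#'
#' Tables follow the `CHR SNP BP L2` layout with optional extra per-annotation
#' LD-score columns.
#'
#' @param path File path.
#' @return Data frame with lower-case `chrom`, `snp`, `bp`, `l2` plus any
#'   annotation columns.
#' @export
read_ldscores <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  names(df)[match(c("CHR", "SNP", "BP", "L2"), names(df), nomatch = 0)] <-
    c("chrom", "snp", "bp", "l2")[c("CHR", "SNP", "BP", "L2") %in% names(df)]
  df
}

#' @rdname read_ldscores
#' @param ld An `ld_reference` (annotation LD-score columns are appended when
#'   present).
#' @export
write_ldscores <- function(ld, path) {
  df <- data.frame(CHR = ld$variants$chrom, SNP = ld$variants$snp,
                   BP = ld$variants$bp, L2 = ld$variants$l2)
  if (!is.null(ld$annot_l2)) df <- cbind(df, as.data.frame(ld$annot_l2))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

is_ambiguous <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize summary statistics against an LD reference
#'
#' Restricts every trait to the variants shared with the reference, matches
#' allele order to the reference (negating Z/beta when the allele pair is
#' swapped), removes strand-ambiguous A/T and C/G variants, and drops —
#' counting, not failing on — variants whose allele pair cannot be reconciled.
#' The output row order is the reference order, identical across traits, and is
#' insensitive to the input row order.
#'
#' @param traits List of `sumstats` data frames (at least one).
#' @param reference An `ld_reference`.
#' @return List with `traits` (aligned `sumstats` list), `reference` (subset to
#'   the common variants) and `dropped` (per-trait counts of ambiguous and
#'   irreconcilable variants).
#' @export
harmonize <- function(traits, reference) {
  if (!length(traits)) stopf("at least one trait required")
  traits <- lapply(traits, validate_sumstats)
  ref <- reference$variants
  common <- ref$snp
  for (s in traits) common <- intersect(common, s$snp)
  dropped <- list()
  keep <- rep(TRUE, length(common))
  aligned <- vector("list", length(traits))
  for (i in seq_along(traits)) {
    s <- traits[[i]][match(common, traits[[i]]$snp), , drop = FALSE]
    r <- ref[match(common, ref$snp), , drop = FALSE]
    ambig <- is_ambiguous(s$a1, s$a2)
    same <- s$a1 == r$a1 & s$a2 == r$a2
    swap <- s$a1 == r$a2 & s$a2 == r$a1
    irrec <- !(same | swap) & !ambig
    dropped[[i]] <- c(ambiguous = sum(ambig), irreconcilable = sum(irrec))
    keep <- keep & !ambig & !irrec
    s$z[swap] <- -s$z[swap]
    if (!is.null(s$beta)) s$beta[swap] <- -s$beta[swap]
    s$a1[swap] <- r$a1[swap]; s$a2[swap] <- r$a2[swap]
    aligned[[i]] <- s
  }
  names(dropped) <- names(traits) %||% paste0("trait", seq_along(traits))
  common_kept <- common[keep]
  ref_keep <- reference
  ridx <- match(common_kept, ref$snp)
  ref_keep$variants <- ref$variants[ridx, , drop = FALSE]
  if (!is.null(reference$annotations)) {
    ref_keep$annotations <- reference$annotations[ridx, , drop = FALSE]
    ref_keep$annot_l2 <- reference$annot_l2[ridx, , drop = FALSE]
    ref_keep$m_annot <- colSums(ref_keep$annotations)
  }
  aligned <- lapply(aligned, function(s) {
    out <- s[keep, , drop = FALSE]
    rownames(out) <- NULL
    validate_sumstats(out)
  })
  names(aligned) <- names(traits)
  list(traits = aligned, reference = ref_keep, dropped = dropped)
}

#' Quality-filter summary statistics for effect-size-distribution modelling
#'
#' Applies, sequentially: (1) restriction to an allow-list of variant ids
#' (HapMap3-style), (2) removal of variants with `z^2 > z2_max` (the boundary
#' value is kept), and (3) removal of variants whose sample size falls below
#' `neff_factor` times the 90th percentile of the post-allow-list sample sizes
#' (linear-interpolation percentile; `>=` keeps). The report tallies each
#' removal cause in that order.
#'
#' @param s A `sumstats` data frame with an `n` column.
#' @param allowlist Character vector of variant ids to keep; `NULL` skips the
#'   allow-list step.
#' @param z2_max Squared-Z cutoff (strict inequality removes).
#' @param neff_factor Multiplier of the 90th sample-size percentile.
#' @return List with the filtered `sumstats` and a `filter_report` containing
#'   `n_input`, `n_removed_not_in_allowlist`, `n_removed_z2`, `n_removed_neff`,
#'   `n_output`.
#' @export
qc_filter <- function(s, allowlist = NULL, z2_max = 80, neff_factor = 0.67) {
  s <- validate_sumstats(s)
  if (is.null(s$n)) stopf("qc_filter requires an n column")
  n_input <- nrow(s)
  if (!is.null(allowlist)) {
    in_allow <- s$snp %in% allowlist
    n_allow <- sum(!in_allow)
    s <- s[in_allow, , drop = FALSE]
  } else n_allow <- 0L
  big_z <- s$z^2 > z2_max
  n_z2 <- sum(big_z)
  s <- s[!big_z, , drop = FALSE]
  if (nrow(s)) {
    thr <- neff_factor * stats::quantile(s$n, 0.9, type = 7, names = FALSE)
    low_n <- s$n < thr
    n_neff <- sum(low_n)
    s <- s[!low_n, , drop = FALSE]
  } else n_neff <- 0L
  if (!nrow(s)) warning("qc_filter removed every variant")
  rownames(s) <- NULL
  report <- structure(list(n_input = n_input,
                           n_removed_not_in_allowlist = n_allow,
                           n_removed_z2 = n_z2,
                           n_removed_neff = n_neff,
                           n_output = nrow(s)),
                      class = "filter_report")
  list(sumstats = validate_sumstats(s), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0("QC filter: %d in -> %d out ",
                     "(allowlist -%d, z2 -%d, sample size -%d)\n"),
              x$n_input, x$n_output, x$n_removed_not_in_allowlist,
              x$n_removed_z2, x$n_removed_neff))
  invisible(x)
}

#' Variants falling in the MHC exclusion interval
#'
#' The major histocompatibility complex (chr6:25-34 Mb) is routinely excluded
#' from LD-score analyses because of its long-range LD. When positions are
#' unavailable an explicit exclusion id list is used instead.
#'
#' @param s A `sumstats` data frame or `ld_reference` variants table.
#' @param chrom,start,end Interval (defaults chr6:25-34 Mb; build is the
#'   caller's choice).
#' @param exclude_ids Optional variant-id exclusion list used when `chrom`/`pos`
#'   columns are absent.
#' @return Logical vector: `TRUE` where the variant should be excluded.
#' @export
in_mhc <- function(s, chrom = 6L, start = 25e6, end = 34e6, exclude_ids = NULL) {
  df <- if (inherits(s, "ld_reference")) s$variants else as.data.frame(s)
  if (!is.null(df$chrom) && !is.null(df$pos %||% df$bp)) {
    pos <- df$pos %||% df$bp
    df$chrom == chrom & pos >= start & pos <= end
  } else if (!is.null(exclude_ids)) {
    df$snp %in% exclude_ids
  } else rep(FALSE, nrow(df))
}
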