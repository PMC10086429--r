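#' @keywords internal
"_PACKAGE"

VALID_ALLELES <- c("A", "C", "G", "T")

SUMSTATS_COLUMNS <- c("snp", "effect_allele", "other_allele",
                      "beta", "se", "pval", "eaf", "n")

#' Construct a GWAS summary-statistics table
#'
#' A `summary_stats` object is a data frame with one row per biallelic SNP and
#' the columns `snp`, `effect_allele`, `other_allele`, `beta`, `se`, `pval`,
#' `eaf`, `n`.  `beta` is the per-effect-allele association with the trait
#' (log-odds for binary traits, SD units for quantitative traits), `se` its
#' standard error, `eaf` the effect-allele frequency (may be `NA`) and `n` the
#' GWAS sample size.  Alleles are uppercased; only single-base A/C/G/T alleles
#' are accepted (biallelic SNPs only, no indels).
#'
#' A missing `pval` is imputed from the two-sided normal tail of `beta/se`.
#'
#' @param df data frame carrying the columns above (extra columns are kept).
#' @param trait_id character label for the trait measured by this GWAS.
#' @param validate run [validate_summary_stats()] (default `TRUE`).
#' @return A `summary_stats` data frame with attribute `trait_id`.
#' @export
#' @examples
#' ss <- summary_stats(data.frame(
#'   snp = c("rs1", "rs2"), effect_allele = c("A", "C"),
#'   other_allele = c("G", "T"), beta = c(0.1, -0.05),
#'   se = c(0.02, 0.01), pval = c(NA, 1e-6), eaf = c(0.3, NA),
#'   n = 10000L), trait_id = "exposure")
summary_stats <- function(df, trait_id = "trait", validate = TRUE) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(setdiff(SUMSTATS_COLUMNS, c("pval", "eaf", "n")),
                          names(df))
  if (length(missing_cols) > 0L) {
    stop("summary statistics are missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(df$pval)) df$pval <- NA_real_
  if (is.null(df$eaf))  df$eaf  <- NA_real_
  if (is.null(df$n))    df$n    <- NA_real_
  df <- df[, c(SUMSTATS_COLUMNS, setdiff(names(df), SUMSTATS_COLUMNS))]
  df$snp <- as.character(df$snp)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele  <- toupper(as.character(df$other_allele))
  for (col in c("beta", "se", "pval", "eaf", "n")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  # impute missing p from the two-sided normal tail of z = beta/se
  miss_p <- is.na(df$pval) & !is.na(df$beta) & !is.na(df$se) & df$se > 0
  df$pval[miss_p] <- 2 * stats::pnorm(-abs(df$beta[miss_p] / df$se[miss_p]))
  rownames(df) <- NULL
  structure(df, trait_id = trait_id,
            class = c("summary_stats", "data.frame")) -> out
  if (validate) validate_summary_stats(out)
  out
}

#' Trait label of a summary-statistics table
#' @param x a `summary_stats` object.
#' @return The `trait_id` attribute.
#' @export
trait_id <- function(x) attr(x, "trait_id", exact = TRUE)

#' Validate a summary-statistics table
#'
#' Checks the structural invariants of the format: unique SNP identifiers,
#' A/C/G/T alleles with `effect_allele != other_allele`, positive standard
#' errors, p-values and allele frequencies inside `[0, 1]`, positive sample
#' sizes.  Violations raise an error naming the offending SNPs.  Where both a
#' p-value and `beta`/`se` are present, disagreement with the two-sided normal
#' p beyond a factor of 2 raises a warning (GWAS rounding makes small
#' discrepancies routine), not an error.
#'
#' @param x a `summary_stats` object.
#' @return `x`, invisibly.
#' @export
validate_summary_stats <- function(x) {
  stopifnot(inherits(x, "summary_stats"))
  fail <- function(msg, ids) {
    stop(msg, ": ", paste(utils::head(unique(ids), 10L), collapse = ", "),
         if (length(unique(ids)) > 10L) ", ..." else "", call. = FALSE)
  }
  dup <- x$snp[duplicated(x$snp)]
  if (length(dup) > 0L) fail("duplicated snp identifiers", dup)
  bad_allele <- !(x$effect_allele %in% VALID_ALLELES) |
    !(x$other_allele %in% VALID_ALLELES)
  if (any(bad_allele)) fail("non-ACGT or multi-base alleles", x$snp[bad_allele])
  same <- x$effect_allele == x$other_allele
  if (any(same)) fail("effect_allele equals other_allele", x$snp[same])
  bad_se <- !is.na(x$se) & x$se <= 0
  if (any(bad_se)) fail("non-positive standard errors", x$snp[bad_se])
  bad_p <- !is.na(x$pval) & (x$pval < 0 | x$pval > 1)
  if (any(bad_p)) fail("p-values outside [0, 1]", x$snp[bad_p])
  bad_eaf <- !is.na(x$eaf) & (x$eaf < 0 | x$eaf > 1)
  if (any(bad_eaf)) fail("allele frequencies outside [0, 1]", x$snp[bad_eaf])
  bad_n <- !is.na(x$n) & x$n <= 0
  if (any(bad_n)) fail("non-positive sample sizes", x$snp[bad_n])
  ok <- !is.na(x$pval) & !is.na(x$beta) & !is.na(x$se) & x$se > 0 & x$pval > 0
  if (any(ok)) {
    pz <- 2 * stats::pnorm(-abs(x$beta[ok] / x$se[ok]))
    off <- pz > 0 & (x$pval[ok] / pz > 2 | pz / x$pval[ok] > 2)
    if (any(off)) {
      warning("p-values inconsistent with beta/se beyond a factor of 2 for: ",
              paste(utils::head(x$snp[ok][off], 10L), collapse = ", "),
              call. = FALSE)
    }
  }
  invisible(x)
}

#' Read a summary-statistics TSV
#'
#' The expected dialect is tab-delimited UTF-8 with a mandatory header and
#' `NA` for missing values; default column names are
#' `snp, effect_allele, other_allele, beta, se, pval, eaf, n`.  Use
#' `column_map` to read files with other headers, e.g.
#' `c(snp = "rsid", beta = "b")` maps file column `rsid` onto `snp`.
#'
#' @param path file path.
#' @param column_map named character vector mapping canonical names to the
#'   file's column names.
#' @param trait_id trait label; defaults to the file name without extension.
#' @return A validated [summary_stats()] object.
#' @export
read_summary_stats <- function(path, column_map = NULL, trait_id = NULL) {
  if (is.null(trait_id)) trait_id <- sub("\\.[^.]*$", "", basename(path))
  # read everything as character: allele columns like "T" must not be
  # type-converted to logical; summary_stats() coerces the numeric fields
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          na.strings = "NA", check.names = FALSE,
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      fcol <- column_map[[canon]]
      if (!fcol %in% names(df)) {
        stop("column_map names absent file column: ", fcol, call. = FALSE)
      }
      names(df)[names(df) == fcol] <- canon
    }
  }
  summary_stats(df, trait_id = trait_id)
}

#' Write a summary-statistics TSV
#'
#' Inverse of [read_summary_stats()]: tab-delimited, header, `NA` for missing.
#' Reading the written file back recovers the record set (floating-point
#' formatting aside).
#'
#' @param x a `summary_stats` object.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path) {
  stopifnot(inherits(x, "summary_stats"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Reconstruct a standard error from a printed confidence interval
#'
#' `se = (upper - lower) / (2 * z)` with `z` the standard-normal quantile at
#' `(1 + level) / 2`.  Used to recover SEs from published tables that print
#' only point estimates and Wald CIs.
#'
#' @param lower,upper CI bounds, `upper > lower`.
#' @param level CI coverage in (0, 1); default 0.95.
#' @return The implied standard error.
#' @export
#' @examples
#' se_from_ci(-0.822, -0.067)  # ~0.1926
se_from_ci <- function(lower, upper, level = 0.95) {
  if (!all(upper > lower)) stop("upper must exceed lower", call. = FALSE)
  if (level <= 0 || level >= 1) stop("level must be in (0,1)", call. = FALSE)
  (upper - lower) / (2 * stats::qnorm((1 + level) / 2))
}

#' Construct an LD description
#'
#' Pairwise LD r-squared for a set of SNPs together with their genomic
#' coordinates, as used by clumping.  The matrix must be symmetric with unit
#' diagonal and entries in `[0, 1]`.
#'
#' @param snp_ids character vector of SNP identifiers (ordered as `r2`).
#' @param r2 square symmetric matrix of pairwise r-squared.
#' @param positions 1-based base-pair positions.
#' @param chrom chromosome label per SNP.
#' @return An `ld_info` list.
#' @export
ld_info <- function(snp_ids, r2, positions, chrom) {
  snp_ids <- as.character(snp_ids)
  r2 <- as.matrix(r2)
  stopifnot(length(snp_ids) == nrow(r2), nrow(r2) == ncol(r2),
            length(positions) == length(snp_ids),
            length(chrom) == length(snp_ids))
  if (any(abs(r2 - t(r2)) > 1e-8)) stop("r2 matrix not symmetric", call. = FALSE)
  if (any(abs(diag(r2) - 1) > 1e-8)) stop("r2 diagonal not 1", call. = FALSE)
  if (any(r2 < -1e-12 | r2 > 1 + 1e-12)) {
    stop("r2 entries outside [0, 1]", call. = FALSE)
  }
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = snp_ids, r2 = r2,
                 positions = as.numeric(positions),
                 chrom = as.character(chrom)),
            class = "ld_info")
}

#' Read an LD matrix TSV
#'
#' Format: tab-delimited with columns `snp`, `chrom`, `pos`, then one column
#' per SNP holding the square r-squared matrix.
#'
#' @param path file path.
#' @return An [ld_info()] object.
#' @export
read_ld_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  snp_ids <- as.character(df$snp)
  ld_info(snp_ids, as.matrix(df[, snp_ids, drop = FALSE]),
          positions = df$pos, chrom = df$chrom)
}

#' Write an LD matrix TSV
#' @param ld an [ld_info()] object.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_ld_matrix <- function(ld, path) {
  stopifnot(inherits(ld, "ld_info"))
  df <- data.frame(snp = ld$snp_ids, chrom = ld$chrom, pos = ld$positions,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(ld$r2, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a proxy-SNP table
#'
#' Tab-delimited columns `target_snp`, `proxy_snp`, `r2`; the offline stand-in
#' for an online LD-proxy lookup.
#'
#' @param path file path.
#' @return Data frame with the three columns.
#' @export
read_proxy_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("target_snp", "proxy_snp", "r2")
  if (!all(need %in% names(df))) {
    stop("proxy table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}
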