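# Instrument selection: p-value thresholding, greedy LD clumping, proxy
# lookup, exclusion lists and instrument-strength metrics.

#' Construct an instrument set
#' @param snp_ids ordered SNP identifiers.
#' @param source_trait trait the instruments were selected for.
#' @param threshold_used p-value cutoff applied.
#' @param provenance per-SNP note (`direct`, `proxy-of:<snp>`, ...).
#' @return An `instrument_set` list.
#' @keywords internal
instrument_set <- function(snp_ids, source_trait, threshold_used,
                           provenance = rep("direct", length(snp_ids))) {
  structure(list(snp_ids = as.character(snp_ids),
                 source_trait = source_trait,
                 threshold_used = threshold_used,
                 provenance = provenance),
            class = "instrument_set")
}

#' Select instruments by association p-value
#'
#' Retains the SNPs with `pval < threshold`, ordered by ascending p-value
#' (ties broken lexicographically by SNP id for determinism).  An empty result
#' is returned with a warning, not an error: downstream stages decide whether
#' to fall back to a more relaxed threshold.
#'
#' @param stats a [summary_stats()] table.
#' @param threshold p-value cutoff in (0, 1); the conventional genome-wide
#'   cutoff is `5e-8`, a relaxed discovery cutoff `5e-5`.
#' @return An `instrument_set`.
#' @export
select_by_pvalue <- function(stats, threshold = 5e-5) {
  stopifnot(inherits(stats, "summary_stats"))
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must be in (0, 1)", call. = FALSE)
  }
  keep <- which(!is.na(stats$pval) & stats$pval < threshold)
  ord <- keep[order(stats$pval[keep], stats$snp[keep])]
  if (length(ord) == 0L) {
    warning("no SNPs pass p < ", format(threshold), " for trait '",
            trait_id(stats), "'", call. = FALSE)
  }
  instrument_set(stats$snp[ord], trait_id(stats), threshold)
}

#' Remove SNPs on an exclusion list
#'
#' Offline surrogate for a pleiotropy web screen: SNPs named in `exclude` are
#' dropped before clumping, with the reason recorded in the provenance.
#'
#' @param instruments an `instrument_set`.
#' @param exclude character vector of SNP ids (or a file of one id per line).
#' @param reason provenance note for the dropped SNPs.
#' @return The filtered `instrument_set`; dropped ids in attribute `dropped`.
#' @export
apply_exclusions <- function(instruments, exclude,
                             reason = "excluded:pleiotropy-screen") {
  stopifnot(inherits(instruments, "instrument_set"))
  if (length(exclude) == 1L && file.exists(exclude)) {
    exclude <- readLines(exclude)
    exclude <- exclude[nzchar(exclude)]
  }
  drop <- instruments$snp_ids %in% exclude
  out <- instrument_set(instruments$snp_ids[!drop],
                        instruments$source_trait,
                        instruments$threshold_used,
                        instruments$provenance[!drop])
  attr(out, "dropped") <- instruments$snp_ids[drop]
  out
}

#' Greedy LD clumping
#'
#' Repeatedly keeps the remaining SNP with the lowest p-value and discards all
#' others on the same chromosome within `window_kb` kilobases that have
#' `r2 >= r2_max` with it.  SNPs absent from the LD description are treated as
#' unlinked and kept.  The operation is idempotent and its output never
#' contains a pair violating the rule.
#'
#' @param candidates an `instrument_set` (ordered by p, as produced by
#'   [select_by_pvalue()]).
#' @param stats the [summary_stats()] the candidates came from (for p-values
#'   and tie-breaking).
#' @param ld an [ld_info()] object, or `NULL` for no LD information.
#' @param r2_max LD threshold; default 0.001.
#' @param window_kb distance window in kb; default 10,000.
#' @return The clumped `instrument_set` (retention order).
#' @export
ld_clump <- function(candidates, stats, ld = NULL, r2_max = 0.001,
                     window_kb = 10000) {
  stopifnot(inherits(candidates, "instrument_set"))
  ids <- candidates$snp_ids
  if (length(ids) <= 1L || is.null(ld)) {
    return(instrument_set(ids, candidates$source_trait,
                          candidates$threshold_used, candidates$provenance))
  }
  p <- stats$pval[match(ids, stats$snp)]
  ord <- order(p, ids)
  ids <- ids[ord]
  in_ld <- match(ids, ld$snp_ids)
  kept <- character(0)
  active <- rep(TRUE, length(ids))
  for (i in seq_along(ids)) {
    if (!active[i]) next
    kept <- c(kept, ids[i])
    if (is.na(in_ld[i])) next               # unknown to panel: unlinked
    for (j in seq_along(ids)) {
      if (!active[j] || j == i || is.na(in_ld[j])) next
      same_chr <- ld$chrom[in_ld[i]] == ld$chrom[in_ld[j]]
      close <- abs(ld$positions[in_ld[i]] - ld$positions[in_ld[j]]) <=
        window_kb * 1000
      if (same_chr && close &&
          ld$r2[in_ld[i], in_ld[j]] >= r2_max) {
        active[j] <- FALSE
      }
    }
    active[i] <- FALSE
  }
  instrument_set(kept, candidates$source_trait, candidates$threshold_used,
                 candidates$provenance[match(kept, candidates$snp_ids)])
}

#' Find an LD proxy for a SNP missing from the outcome GWAS
#'
#' Returns the proxy with the highest r-squared at least `r2_min` among those
#' present in the outcome table, or `NA` if none qualifies.
#'
#' @param missing_snp SNP id absent from the outcome table.
#' @param proxy_table data frame with columns `target_snp`, `proxy_snp`, `r2`
#'   (see [read_proxy_table()]).
#' @param outcome the outcome [summary_stats()].
#' @param r2_min minimum acceptable r-squared; default 0.8.
#' @return The proxy SNP id, or `NA_character_`.
#' @export
find_proxy <- function(missing_snp, proxy_table, outcome, r2_min = 0.8) {
  if (r2_min <= 0 || r2_min > 1) stop("r2_min must be in (0, 1]",
                                      call. = FALSE)
  cand <- proxy_table[proxy_table$target_snp == missing_snp &
                        proxy_table$r2 >= r2_min &
                        proxy_table$proxy_snp %in% outcome$snp, , drop = FALSE]
  if (nrow(cand) == 0L) return(NA_character_)
  cand <- cand[order(-cand$r2, cand$proxy_snp), , drop = FALSE]
  cand$proxy_snp[1L]
}

#' Instrument-strength metrics
#'
#' Per-SNP F-statistic `(beta/se)^2` and explained variance.  Two R-squared
#' formulas are reported: `r2_af = 2*eaf*(1-eaf)*beta^2` (valid for traits on
#' the SD scale when the allele frequency is known) and the frequency-free
#' fallback `r2_f = F / (F + n - 2)`.  The total is the sum of `r2_af` where
#' available, otherwise of `r2_f`.  SNPs with `F < 10` are flagged as weak by
#' the usual rule of thumb.
#'
#' @param exposure the exposure [summary_stats()].
#' @param instruments an `instrument_set` over that table.
#' @return List with the per-SNP data frame (`snp`, `f`, `r2_af`, `r2_f`,
#'   `weak`), `total_r2`, `mean_f` and `n_weak`.
#' @export
instrument_strength <- function(exposure, instruments) {
  idx <- match(instruments$snp_ids, exposure$snp)
  if (anyNA(idx)) {
    stop("instruments absent from exposure table: ",
         paste(instruments$snp_ids[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  b <- exposure$beta[idx]; s <- exposure$se[idx]
  eaf <- exposure$eaf[idx]; n <- exposure$n[idx]
  f <- (b / s)^2
  r2_af <- ifelse(is.na(eaf), NA_real_, 2 * eaf * (1 - eaf) * b^2)
  need_fallback <- is.na(eaf)
  if (any(need_fallback & (is.na(n) | n <= 2))) {
    stop("fallback R^2 needs n > 2 for SNPs lacking allele frequency",
         call. = FALSE)
  }
  r2_f <- ifelse(is.na(n) | n <= 2, NA_real_, f / (f + n - 2))
  per_snp <- data.frame(snp = instruments$snp_ids, f = f,
                        r2_af = r2_af, r2_f = r2_f, weak = f < 10,
                        stringsAsFactors = FALSE)
  total_r2 <- sum(ifelse(is.na(r2_af), r2_f, r2_af))
  list(per_snp = per_snp, total_r2 = total_r2, mean_f = mean(f),
       n_weak = sum(per_snp$weak))
}
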