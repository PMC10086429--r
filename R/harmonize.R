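# Allele harmonization between summary tables: resolve label swaps, strand
# complements, and palindromic (A/T, C/G) SNPs via allele frequency.

comp_allele <- function(a) chartr("ACGT", "TGCA", a)

#' Is an allele pair palindromic?
#'
#' A SNP is palindromic when its two alleles are strand complements of each
#' other ({A,T} or {C,G}), so strand cannot be inferred from the alleles
#' alone.
#'
#' @param a1,a2 allele characters (vectorized).
#' @return Logical vector.
#' @export
is_palindromic <- function(a1, a2) {
  a1 <- toupper(a1); a2 <- toupper(a2)
  a2 == comp_allele(a1)
}

# Align one table's records to a reference orientation.
# ref and oth are row-matched data frames with columns effect_allele,
# other_allele, beta, eaf.  Returns disposition plus the (possibly sign-
# corrected) beta and eaf of `oth` expressed on ref's effect allele.
align_alleles <- function(ref_ea, ref_oa, ref_eaf,
                          oth_ea, oth_oa, oth_beta, oth_eaf,
                          af_ambiguous = c(0.4, 0.6)) {
  n <- length(ref_ea)
  disp <- character(n)
  beta <- oth_beta
  eaf <- oth_eaf
  pal <- is_palindromic(ref_ea, ref_oa)
  for (i in seq_len(n)) {
    ea <- oth_ea[i]; oa <- oth_oa[i]
    if (pal[i]) {
      # palindrome: label match and strand flip are indistinguishable;
      # align labels first, then use allele frequency to infer strand
      if (ea == ref_ea[i] && oa == ref_oa[i]) {
        # aligned as printed
      } else if (ea == ref_oa[i] && oa == ref_ea[i]) {
        beta[i] <- -beta[i]
        eaf[i] <- 1 - eaf[i]
      } else {
        disp[i] <- "removed:incompatible-alleles"
        next
      }
      ambiguous <- is.na(ref_eaf[i]) || is.na(eaf[i]) ||
        (ref_eaf[i] > af_ambiguous[1] && ref_eaf[i] < af_ambiguous[2]) ||
        (eaf[i] > af_ambiguous[1] && eaf[i] < af_ambiguous[2])
      if (ambiguous) {
        disp[i] <- "removed:ambiguous-palindrome"
        next
      }
      if ((ref_eaf[i] < 0.5) != (eaf[i] < 0.5)) {
        # frequencies on opposite sides of 0.5: the tables counted
        # complementary strands; flip the outcome effect
        beta[i] <- -beta[i]
        eaf[i] <- 1 - eaf[i]
        disp[i] <- "flipped"
      } else {
        disp[i] <- "kept"
      }
    } else {
      if (ea == ref_ea[i] && oa == ref_oa[i]) {
        disp[i] <- "kept"
      } else if (ea == ref_oa[i] && oa == ref_ea[i]) {
        beta[i] <- -beta[i]
        eaf[i] <- 1 - eaf[i]
        disp[i] <- "flipped"
      } else if (comp_allele(ea) == ref_ea[i] && comp_allele(oa) == ref_oa[i]) {
        disp[i] <- "kept"                  # strand complement, same order
      } else if (comp_allele(ea) == ref_oa[i] && comp_allele(oa) == ref_ea[i]) {
        beta[i] <- -beta[i]
        eaf[i] <- 1 - eaf[i]
        disp[i] <- "flipped"
      } else {
        disp[i] <- "removed:incompatible-alleles"
      }
    }
  }
  list(disposition = disp, beta = beta, eaf = eaf)
}

#' Harmonize an exposure/outcome pair of summary tables
#'
#' Restricts to the SNPs shared by both tables and aligns the outcome effects
#' to the exposure's effect allele: matching alleles are kept, swapped alleles
#' have the outcome beta negated and frequency complemented, strand-complement
#' records are relabelled then treated the same way, and incompatible allele
#' sets are removed.  Palindromic SNPs are resolved by allele frequency: if
#' both frequencies fall outside `af_ambiguous` they are kept (with a sign
#' flip when the frequencies sit on opposite sides of 0.5); otherwise they are
#' removed as ambiguous, as is any palindrome with a missing frequency.
#'
#' @param exposure,outcome [summary_stats()] tables.
#' @param af_ambiguous open frequency interval within which a palindrome is
#'   unresolvable; default `c(0.4, 0.6)`.
#' @param snps optional subset of SNP ids (e.g. an instrument set) to
#'   harmonize; default is the full intersection.
#' @return A `harmonized_set` data frame with columns `snp`,
#'   `effect_allele`, `other_allele`, `beta_x`, `se_x`, `pval_x`, `eaf_x`,
#'   `beta_y`, `se_y`, `eaf_y`; the per-SNP disposition of every candidate SNP
#'   (including removed ones) is in `attr(, "drop_log")`.
#' @export
harmonize_pair <- function(exposure, outcome, af_ambiguous = c(0.4, 0.6),
                           snps = NULL) {
  stopifnot(inherits(exposure, "summary_stats"),
            inherits(outcome, "summary_stats"))
  shared <- intersect(exposure$snp, outcome$snp)
  if (!is.null(snps)) shared <- intersect(snps, shared)
  if (length(shared) == 0L) stop("no shared SNPs to harmonize", call. = FALSE)
  ex <- exposure[match(shared, exposure$snp), ]
  ou <- outcome[match(shared, outcome$snp), ]
  al <- align_alleles(ex$effect_allele, ex$other_allele, ex$eaf,
                      ou$effect_allele, ou$other_allele, ou$beta, ou$eaf,
                      af_ambiguous)
  keep <- al$disposition %in% c("kept", "flipped")
  h <- data.frame(snp = shared[keep],
                  effect_allele = ex$effect_allele[keep],
                  other_allele = ex$other_allele[keep],
                  beta_x = ex$beta[keep], se_x = ex$se[keep],
                  pval_x = ex$pval[keep], eaf_x = ex$eaf[keep],
                  beta_y = al$beta[keep], se_y = ou$se[keep],
                  eaf_y = al$eaf[keep],
                  stringsAsFactors = FALSE)
  rownames(h) <- NULL
  structure(h,
            drop_log = data.frame(snp = shared, disposition = al$disposition,
                                  stringsAsFactors = FALSE),
            exposure_trait = trait_id(exposure),
            outcome_trait = trait_id(outcome),
            class = c("harmonized_set", "data.frame"))
}

#' Harmonization drop log
#' @param h a `harmonized_set`.
#' @return Data frame of per-SNP dispositions.
#' @export
drop_log <- function(h) attr(h, "drop_log", exact = TRUE)

#' Construct a harmonized set directly from effect vectors
#'
#' Convenience constructor for already-aligned effects (fixtures, reduced
#' problems).  `beta_x`/`se_x` may be matrices with one column per exposure
#' for multivariable analyses.
#'
#' @param beta_x,se_x exposure effects and SEs (vector or matrix).
#' @param beta_y,se_y outcome effects and SEs.
#' @param snp optional SNP ids.
#' @param eaf_x,eaf_y,pval_x optional columns.
#' @param exposure_labels labels for exposure columns when `beta_x` is a
#'   matrix.
#' @return A `harmonized_set`.
#' @export
harmonized_set <- function(beta_x, se_x, beta_y, se_y, snp = NULL,
                           eaf_x = NA_real_, eaf_y = NA_real_,
                           pval_x = NA_real_, exposure_labels = NULL) {
  if (is.matrix(beta_x) && ncol(beta_x) > 1L) {
    if (is.null(exposure_labels)) {
      exposure_labels <- colnames(beta_x)
      if (is.null(exposure_labels)) {
        exposure_labels <- paste0("x", seq_len(ncol(beta_x)))
      }
    }
    J <- nrow(beta_x)
    if (is.null(snp)) snp <- sprintf("snp%03d", seq_len(J))
    h <- data.frame(snp = snp, stringsAsFactors = FALSE)
    for (k in seq_along(exposure_labels)) {
      h[[paste0("beta_x.", exposure_labels[k])]] <- beta_x[, k]
      h[[paste0("se_x.", exposure_labels[k])]] <- se_x[, k]
    }
    h$beta_y <- beta_y
    h$se_y <- se_y
    return(structure(h, exposure_labels = exposure_labels,
                     class = c("harmonized_set", "data.frame")))
  }
  beta_x <- drop(beta_x); se_x <- drop(se_x)
  J <- length(beta_x)
  if (is.null(snp)) snp <- sprintf("snp%03d", seq_len(J))
  structure(data.frame(snp = snp, beta_x = beta_x, se_x = se_x,
                       pval_x = pval_x, eaf_x = eaf_x,
                       beta_y = beta_y, se_y = se_y, eaf_y = eaf_y,
                       stringsAsFactors = FALSE),
            class = c("harmonized_set", "data.frame"))
}

# exposure effect matrix of a harmonized set (1 column in the UVMR case)
exposure_matrix <- function(h) {
  labs <- attr(h, "exposure_labels", exact = TRUE)
  if (is.null(labs)) {
    bx <- matrix(h$beta_x, ncol = 1L,
                 dimnames = list(NULL, attr(h, "exposure_trait") %||% "x"))
    sx <- matrix(h$se_x, ncol = 1L, dimnames = dimnames(bx))
  } else {
    bx <- as.matrix(h[paste0("beta_x.", labs)])
    sx <- as.matrix(h[paste0("se_x.", labs)])
    colnames(bx) <- colnames(sx) <- labs
  }
  list(beta = bx, se = sx)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
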