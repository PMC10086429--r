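# Pipeline orchestration: method decision tree, FDR labelling, effect-scale
# conversion, and the end-to-end analysis driver.

#' Univariable method decision tree
#'
#' Encodes the standard selection rule: a significant MR-Egger intercept
#' (`p < 0.05`) selects MR-Egger; otherwise significant heterogeneity — which
#' requires *both* `p_Q < 0.05` and `I2 > 0.25` — selects random-effects IVW;
#' otherwise fixed-effects IVW.
#'
#' @param egger_intercept_p intercept p-value in `[0, 1]`.
#' @param p_Q heterogeneity p-value in `[0, 1]`.
#' @param I2 heterogeneity I-squared in `[0, 1]`.
#' @return List with `method` (`"mr-egger"` or `"ivw"`) and `effects_model`
#'   (`"random"`/`"fixed"`, `NA` for MR-Egger).
#' @export
choose_uvmr_method <- function(egger_intercept_p, p_Q, I2) {
  stopifnot(egger_intercept_p >= 0, egger_intercept_p <= 1,
            p_Q >= 0, p_Q <= 1, I2 >= 0, I2 <= 1)
  if (egger_intercept_p < 0.05) {
    list(method = "mr-egger", effects_model = NA_character_)
  } else if (p_Q < 0.05 && I2 > 0.25) {
    list(method = "ivw", effects_model = "random")
  } else {
    list(method = "ivw", effects_model = "fixed")
  }
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: `q_i = min_{j >= rank(i)} p_(j) * m / j`,
#' returned in input order.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values.
#' @export
bh_fdr <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = "BH")
}

#' Evidence labels from raw p and FDR q
#'
#' `significant` when `q < cutoff`; `suggestive` when `q >= cutoff` but the
#' raw `p < 0.05`; `null` otherwise.
#'
#' @param pvals raw p-values.
#' @param q_cutoff FDR cutoff; default 0.05.
#' @param qvals optional precomputed q-values ([bh_fdr()] of `pvals` if
#'   omitted).
#' @return Data frame with `raw_p`, `q_value`, `label`.
#' @export
evidence_label <- function(pvals, q_cutoff = 0.05, qvals = bh_fdr(pvals)) {
  label <- ifelse(qvals < q_cutoff, "significant",
                  ifelse(pvals < 0.05, "suggestive", "null"))
  data.frame(raw_p = pvals, q_value = qvals, label = label,
             stringsAsFactors = FALSE)
}

#' Convert log-odds effects to odds ratios
#'
#' Elementwise exponentiation of an effect and its CI, optionally rounded as
#' in report tables (2 decimals).
#'
#' @param beta log-odds effect.
#' @param ci_low,ci_high CI bounds on the log-odds scale.
#' @param digits rounding; `NULL` for none.
#' @return List with `or`, `or_low`, `or_high`.
#' @export
#' @examples
#' beta_to_or(-0.444, -0.822, -0.067)  # OR 0.64 (0.44, 0.94)
beta_to_or <- function(beta, ci_low = NA_real_, ci_high = NA_real_,
                       digits = 2L) {
  out <- list(or = exp(beta), or_low = exp(ci_low), or_high = exp(ci_high))
  if (!is.null(digits)) out <- lapply(out, round, digits = digits)
  out
}

#' Assemble and validate a pipeline configuration
#'
#' Fields: file paths (`exposure`, `mediators`, `outcome`, optional `ld`,
#' `proxies`, `exclude`), thresholds (`p_threshold` 5e-5, `clump_r2` 0.001,
#' `clump_kb` 10000, `proxy_r2_min` 0.8, `af_ambiguous` (0.4, 0.6), `fdr_q`
#' 0.05), the MR-PRESSO settings (`presso` TRUE, `presso_nb_sim` 1000) and a
#' mandatory `seed`.  `config` may be a named list or the path of a JSON file
#' with the same fields.
#'
#' @param config named list or JSON file path.
#' @return Validated config list (class `analysis_config`).
#' @export
analysis_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- list(exposure = NULL, mediators = character(0), outcome = NULL,
                   ld = NULL, proxies = NULL, exclude = NULL,
                   p_threshold = 5e-5, clump_r2 = 0.001, clump_kb = 10000,
                   proxy_r2_min = 0.8, af_ambiguous = c(0.4, 0.6),
                   presso = TRUE, presso_nb_sim = 1000L,
                   fdr_q = 0.05, seed = NULL, out_dir = NULL)
  cfg <- utils::modifyList(defaults, as.list(config))
  with(cfg, {
    stopifnot(p_threshold > 0, p_threshold < 1,
              clump_r2 > 0, clump_r2 <= 1, clump_kb > 0,
              proxy_r2_min > 0, proxy_r2_min <= 1,
              length(af_ambiguous) == 2L, af_ambiguous[1] < af_ambiguous[2],
              fdr_q > 0, fdr_q < 1)
  })
  if (is.null(cfg$seed)) {
    stop("config must set a seed (stochastic methods are seeded)",
         call. = FALSE)
  }
  structure(cfg, class = c("analysis_config", "list"))
}

#' Run the full MR mediation pipeline
#'
#' Orchestrates the complete analysis from one configuration: load tables,
#' select instruments (threshold, exclusion list, clump), harmonize against
#' the outcome (with proxy substitution), remove MR-PRESSO outliers and refit,
#' run the univariable battery with the method decision tree, run
#' per-mediator two-step mediation and the combined parallel-mediator model,
#' attach FDR evidence labels, and (when `out_dir` is set) write result TSVs
#' plus a machine-readable run manifest.  Re-running with the same config and
#' seed reproduces identical outputs.
#'
#' @param config an [analysis_config()] (or list / JSON path coercible to
#'   one).
#' @return List with `uvmr` (battery table with evidence labels), `presso`,
#'   `mediation` (per-mediator table), `combined`, `manifest`.
#' @export
run_pipeline <- function(config) {
  cfg <- analysis_config(config)
  load_tab <- function(x, label) {
    if (inherits(x, "summary_stats")) x else read_summary_stats(x, trait_id = label)
  }
  exposure <- load_tab(cfg$exposure, "exposure")
  outcome <- load_tab(cfg$outcome, "outcome")
  mediators <- list()
  med_in <- cfg$mediators
  if (inherits(med_in, "summary_stats")) med_in <- list(med_in)
  for (i in seq_along(med_in)) {
    mediators[[i]] <- load_tab(med_in[[i]], paste0("mediator", i))
  }
  ld <- if (is.null(cfg$ld)) NULL else if (inherits(cfg$ld, "ld_info")) {
    cfg$ld
  } else read_ld_matrix(cfg$ld)
  proxies <- if (is.null(cfg$proxies)) NULL else if (is.data.frame(cfg$proxies)) {
    cfg$proxies
  } else read_proxy_table(cfg$proxies)

  # --- instrument selection for the exposure ---------------------------
  iv <- select_by_pvalue(exposure, cfg$p_threshold)
  if (!is.null(cfg$exclude)) iv <- apply_exclusions(iv, cfg$exclude)
  iv <- ld_clump(iv, exposure, ld, cfg$clump_r2, cfg$clump_kb)
  if (length(iv$snp_ids) == 0L) {
    stop("stage [instruments]: no instruments survive selection",
         call. = FALSE)
  }
  strength <- instrument_strength(exposure, iv)
  if (strength$n_weak > 0L) {
    warning(strength$n_weak, " instrument(s) have F < 10", call. = FALSE)
  }
  # proxy substitution for instruments absent from the outcome table
  ids <- iv$snp_ids
  proxy_log <- character(0)
  for (i in seq_along(ids)) {
    if (!(ids[i] %in% outcome$snp) && !is.null(proxies)) {
      p <- find_proxy(ids[i], proxies, outcome, cfg$proxy_r2_min)
      if (!is.na(p)) {
        proxy_log <- c(proxy_log, paste0(ids[i], "->", p))
        ids[i] <- p
      }
    }
  }
  h <- harmonize_pair(exposure, outcome, cfg$af_ambiguous, snps = ids)

  # --- MR-PRESSO outlier removal, then refit ---------------------------
  presso <- NULL
  if (isTRUE(cfg$presso) && nrow(h) >= 4L) {
    presso <- mr_presso(h, cfg$presso_nb_sim, seed = cfg$seed)
    if (length(presso$outlier_snp_ids) > 0L) {
      h <- h[!(h$snp %in% presso$outlier_snp_ids), , drop = FALSE]
    }
  }

  # --- univariable battery + decision tree -----------------------------
  uvmr <- uvmr_battery(h, seed = cfg$seed)
  eg <- mr_egger(h)
  ivw <- mr_ivw(h, "auto")
  pick <- choose_uvmr_method(eg$egger_intercept$p, ivw$heterogeneity$p_Q,
                             ivw$heterogeneity$I2)
  primary <- if (pick$method == "mr-egger") eg else
    mr_ivw(h, pick$effects_model)
  uvmr$primary <- uvmr$method == primary$method
  uvmr <- cbind(uvmr, evidence_label(uvmr$pval, cfg$fdr_q))

  # --- mediation -------------------------------------------------------
  med_cfg <- list(p_threshold = cfg$p_threshold, clump_r2 = cfg$clump_r2,
                  clump_kb = cfg$clump_kb, proxy_r2_min = cfg$proxy_r2_min,
                  af_ambiguous = cfg$af_ambiguous, presso = cfg$presso,
                  presso_nb_sim = cfg$presso_nb_sim, seed = cfg$seed,
                  exclude = cfg$exclude, proxy_table = proxies)
  mediation_tab <- NULL
  combined <- NULL
  med_results <- list()
  if (length(mediators) > 0L) {
    rows <- list()
    for (m in mediators) {
      res <- two_step_mediation(exposure, m, outcome, ld, med_cfg)
      med_results[[trait_id(m)]] <- res
      rows[[trait_id(m)]] <- data.frame(
        exposure = trait_id(exposure), mediator = trait_id(m),
        outcome = trait_id(outcome),
        total = res$beta_c, total_low = res$beta_c - 1.96 * res$se_c,
        total_high = res$beta_c + 1.96 * res$se_c,
        beta_a = res$beta_a, beta_b = res$beta_b,
        indirect = res$indirect$estimate,
        indirect_low = res$indirect$ci_low,
        indirect_high = res$indirect$ci_high,
        pval_indirect = res$pval_indirect,
        proportion = res$proportion$estimate,
        proportion_low = res$proportion$ci_low,
        proportion_high = res$proportion$ci_high,
        stringsAsFactors = FALSE)
    }
    mediation_tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    combined <- combined_mediation(exposure, mediators, outcome, ld, med_cfg)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("mrmediate")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    thresholds = cfg[c("p_threshold", "clump_r2", "clump_kb",
                       "proxy_r2_min", "af_ambiguous", "fdr_q",
                       "presso_nb_sim")],
    presso = isTRUE(cfg$presso),
    n_instruments = length(iv$snp_ids),
    instrument_total_r2 = strength$total_r2,
    instrument_mean_f = strength$mean_f,
    proxies_used = proxy_log,
    n_snps_harmonized = nrow(h),
    primary_method = primary$method)

  out <- list(uvmr = uvmr, primary = primary, presso = presso,
              mediation = mediation_tab, mediation_results = med_results,
              combined = combined, harmonized = h,
              instrument_strength = strength, manifest = manifest)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(uvmr, file.path(cfg$out_dir, "uvmr_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(mediation_tab)) {
      utils::write.table(mediation_tab,
                         file.path(cfg$out_dir, "mediation_results.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(drop_log(h),
                       file.path(cfg$out_dir, "harmonization_log.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Published education-esophageal disease mediation estimates
#'
#' The printed point estimates and 95\% CIs of a published two-sample MR
#' mediation analysis of educational attainment (years of education and
#' college completion) on esophageal cancer, Barrett's esophagus and
#' gastro-esophageal reflux disease, with BMI, smoking quantity and major
#' depressive disorder as mediators.  One row per exposure-mediator-outcome
#' triple: total effect `beta_c`, exposure-on-mediator effect `beta_a`,
#' adjusted mediator-on-outcome effect `beta_b` (log-odds scale), the printed
#' mediation effect with CI and p, and the printed proportion mediated (%)
#' with CI.  Used as the desk-scale oracle for [mediate()].
#'
#' @return Data frame with one row per mediation pathway.
#' @export
published_mediation_table <- function() {
  path <- system.file("extdata", "education_esophageal_mediation.tsv",
                      package = "mrmediate")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
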