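# Two-step MR mediation: decompose a total causal effect into indirect
# (through one or more mediators) and direct components, with delta-method
# uncertainty and proportions mediated.

#' Product-method mediation arithmetic with delta-method uncertainty
#'
#' Given the three effect estimates of a two-step MR mediation — `beta_a`
#' (exposure on mediator, univariable MR), `beta_b` (mediator on outcome
#' adjusted for the exposure, multivariable MR) and `beta_c` (total effect,
#' univariable MR) — computes:
#' * the indirect (mediation) effect `beta_a * beta_b` with first-order
#'   delta-method SE `sqrt(beta_a^2 se_b^2 + beta_b^2 se_a^2)` (the
#'   second-order `+ se_a^2 se_b^2` term via `product_var = "second"`),
#' * the direct effect `beta_c - beta_a * beta_b` (so direct + indirect equals
#'   the total exactly),
#' * the proportion mediated `indirect / beta_c`.
#'
#' Two uncertainty conventions for the proportion are provided.  The default
#' `prop_var = "scaled-indirect"` treats the total effect as fixed and scales
#' the indirect effect's CI by `1/|beta_c|` — this is the construction that
#' reproduces published mediation tables of this design.  The full ratio
#' delta-method SE treating numerator and denominator as independent,
#' `sqrt(se_ind^2/beta_c^2 + ind^2 se_c^2/beta_c^4)`, is always reported as
#' `proportion_se_delta` and drives the CI under `prop_var = "delta-ratio"`.
#'
#' @param beta_a,se_a exposure-on-mediator effect and SE.
#' @param beta_b,se_b mediator-on-outcome (exposure-adjusted) effect and SE.
#' @param beta_c,se_c total effect and SE.
#' @param level CI coverage; default 0.95.
#' @param product_var `"first"` (default) or `"second"` order product
#'   variance.
#' @param prop_var `"scaled-indirect"` (default) or `"delta-ratio"` CI for
#'   the proportion mediated.
#' @return A `mediation_result` list with `indirect`, `direct`, `proportion`
#'   (each with `se`, `ci_low`, `ci_high` where defined), and
#'   `pval_indirect`.
#' @export
#' @examples
#' mediate(beta_a = -0.171, se_a = se_from_ci(-0.217, -0.126),
#'         beta_b = 0.408, se_b = se_from_ci(0.102, 0.715),
#'         beta_c = -0.444, se_c = se_from_ci(-0.822, -0.067))
mediate <- function(beta_a, se_a, beta_b, se_b, beta_c, se_c,
                    level = 0.95, product_var = c("first", "second"),
                    prop_var = c("scaled-indirect", "delta-ratio")) {
  product_var <- match.arg(product_var)
  prop_var <- match.arg(prop_var)
  stopifnot(se_a > 0, se_b > 0, se_c > 0)
  z <- stats::qnorm((1 + level) / 2)
  indirect <- beta_a * beta_b
  v_ind <- beta_a^2 * se_b^2 + beta_b^2 * se_a^2
  if (product_var == "second") v_ind <- v_ind + se_a^2 * se_b^2
  se_ind <- sqrt(v_ind)
  p_ind <- 2 * stats::pnorm(-abs(indirect / se_ind))
  direct <- beta_c - indirect
  se_dir <- sqrt(se_c^2 + v_ind)        # independence working assumption
  if (beta_c == 0) {
    prop <- list(estimate = NA_real_, se = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_,
                 note = "total effect is zero: proportion undefined")
    se_prop_delta <- NA_real_
  } else {
    p_est <- indirect / beta_c
    se_prop_delta <- sqrt(v_ind / beta_c^2 +
                            indirect^2 * se_c^2 / beta_c^4)
    if (prop_var == "scaled-indirect") {
      # indirect CI mapped through division by the (fixed) total effect
      bounds <- sort(c((indirect - z * se_ind) / beta_c,
                       (indirect + z * se_ind) / beta_c))
      prop <- list(estimate = p_est, se = se_ind / abs(beta_c),
                   ci_low = bounds[1], ci_high = bounds[2], note = NULL)
    } else {
      prop <- list(estimate = p_est, se = se_prop_delta,
                   ci_low = p_est - z * se_prop_delta,
                   ci_high = p_est + z * se_prop_delta, note = NULL)
    }
  }
  structure(list(
    beta_a = beta_a, se_a = se_a, beta_b = beta_b, se_b = se_b,
    beta_c = beta_c, se_c = se_c,
    indirect = list(estimate = indirect, se = se_ind,
                    ci_low = indirect - z * se_ind,
                    ci_high = indirect + z * se_ind),
    direct = list(estimate = direct, se = se_dir),
    proportion = prop,
    proportion_se_delta = se_prop_delta,
    pval_indirect = p_ind, level = level,
    product_var = product_var, prop_var = prop_var),
    class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Two-step MR mediation\n")
  cat(sprintf("  beta_a %.4f (se %.4f)   beta_b %.4f (se %.4f)   beta_c %.4f (se %.4f)\n",
              x$beta_a, x$se_a, x$beta_b, x$se_b, x$beta_c, x$se_c))
  cat(sprintf("  indirect %.4f [%.4f, %.4f], p = %.3g\n",
              x$indirect$estimate, x$indirect$ci_low, x$indirect$ci_high,
              x$pval_indirect))
  cat(sprintf("  direct   %.4f\n", x$direct$estimate))
  if (!is.na(x$proportion$estimate)) {
    cat(sprintf("  proportion mediated %.2f%% [%.2f%%, %.2f%%]\n",
                100 * x$proportion$estimate, 100 * x$proportion$ci_low,
                100 * x$proportion$ci_high))
  } else {
    cat("  proportion mediated undefined (total effect is zero)\n")
  }
  invisible(x)
}

# run one UVMR stage under the pipeline decision tree, tagged with its stage
uvmr_stage <- function(exposure, outcome, ld, stage, config) {
  tryCatch({
    iv <- select_by_pvalue(exposure, config$p_threshold)
    if (!is.null(config$exclude)) iv <- apply_exclusions(iv, config$exclude)
    iv <- ld_clump(iv, exposure, ld, config$clump_r2, config$clump_kb)
    h <- harmonize_pair(exposure, outcome, config$af_ambiguous,
                        snps = iv$snp_ids)
    if (nrow(h) >= 4L && isTRUE(config$presso)) {
      pr <- mr_presso(h, config$presso_nb_sim, seed = config$seed)
      if (length(pr$outlier_snp_ids) > 0L) {
        h <- h[!(h$snp %in% pr$outlier_snp_ids), , drop = FALSE]
      }
    }
    fit <- if (nrow(h) >= 3L) {
      eg <- mr_egger(h)
      ivw <- mr_ivw(h, "auto")
      pick <- choose_uvmr_method(eg$egger_intercept$p,
                                 ivw$heterogeneity$p_Q,
                                 ivw$heterogeneity$I2)
      if (pick$method == "mr-egger") eg else
        mr_ivw(h, pick$effects_model)
    } else {
      mr_ivw(h, "fixed")
    }
    list(fit = fit, h = h)
  }, error = function(e) {
    stop("stage [", stage, "]: ", conditionMessage(e), call. = FALSE)
  })
}

default_mediation_config <- function(config = list()) {
  defaults <- list(p_threshold = 5e-5, clump_r2 = 0.001, clump_kb = 10000,
                   proxy_r2_min = 0.8, af_ambiguous = c(0.4, 0.6),
                   presso = FALSE, presso_nb_sim = 1000L, seed = 1L,
                   exclude = NULL, proxy_table = NULL)
  utils::modifyList(defaults, config)
}

#' Two-step MR mediation from summary statistics
#'
#' Runs the full two-step procedure: `beta_c` by univariable MR of the
#' exposure on the outcome, `beta_a` by univariable MR of the exposure on the
#' mediator, `beta_b` as the mediator coefficient of the multivariable MR of
#' the outcome on exposure and mediator jointly, then [mediate()].  All
#' intermediate fits are retained in the result.
#'
#' @param exposure,mediator,outcome [summary_stats()] tables.
#' @param ld optional [ld_info()].
#' @param config list overriding the defaults: `p_threshold` (5e-5),
#'   `clump_r2` (0.001), `clump_kb` (10000), `proxy_r2_min` (0.8),
#'   `af_ambiguous` (0.4, 0.6), `presso` (FALSE), `presso_nb_sim`, `seed`,
#'   `exclude`, `proxy_table`, plus the [mediate()] options.
#' @return A `mediation_result` with `$stages` (the UVMR/MVMR fits).
#' @export
two_step_mediation <- function(exposure, mediator, outcome, ld = NULL,
                               config = list()) {
  cfg <- default_mediation_config(config)
  total <- uvmr_stage(exposure, outcome, ld, "total-effect", cfg)
  a <- uvmr_stage(exposure, mediator, ld, "exposure-on-mediator", cfg)
  mv <- tryCatch({
    iv_x <- ld_clump(select_by_pvalue(exposure, cfg$p_threshold), exposure,
                     ld, cfg$clump_r2, cfg$clump_kb)
    iv_m <- ld_clump(select_by_pvalue(mediator, cfg$p_threshold), mediator,
                     ld, cfg$clump_r2, cfg$clump_kb)
    hmv <- build_mv_set(list(exposure, mediator), outcome,
                        list(iv_x, iv_m), ld, cfg$proxy_table,
                        cfg$clump_r2, cfg$clump_kb, cfg$proxy_r2_min,
                        cfg$af_ambiguous)
    mvmr_ivw(hmv)
  }, error = function(e) {
    stop("stage [mediator-on-outcome]: ", conditionMessage(e), call. = FALSE)
  })
  med_label <- trait_id(mediator)
  res <- mediate(beta_a = a$fit$estimate, se_a = a$fit$se,
                 beta_b = unname(mv$estimates[med_label]),
                 se_b = unname(mv$ses[med_label]),
                 beta_c = total$fit$estimate, se_c = total$fit$se,
                 product_var = cfg$product_var %||% "first",
                 prop_var = cfg$prop_var %||% "scaled-indirect")
  res$stages <- list(total = total$fit, exposure_on_mediator = a$fit,
                     mvmr = mv)
  res
}

#' Parallel multi-mediator (combined) mediation
#'
#' One joint multivariable MR of the outcome on the exposure and *all*
#' mediators supplies every `beta_b_i`; each `beta_a_i` comes from
#' univariable MR of the exposure on mediator i.  Per-mediator indirect
#' effects `beta_a_i * beta_b_i` are summed into the combined indirect effect
#' with `se = sqrt(sum(se_ind_i^2))` (independence working assumption), and
#' the combined proportion mediated is computed as in [mediate()].
#'
#' @param exposure exposure [summary_stats()].
#' @param mediators list of mediator [summary_stats()] tables.
#' @param outcome outcome [summary_stats()].
#' @param ld optional [ld_info()].
#' @param config as in [two_step_mediation()].
#' @return A `combined_mediation_result` list: `mediator_labels`,
#'   `per_mediator` (each a [mediate()] result), `combined_indirect`,
#'   `combined_proportion`, `beta_c`, and the joint MVMR fit.
#' @export
combined_mediation <- function(exposure, mediators, outcome, ld = NULL,
                               config = list()) {
  stopifnot(length(mediators) >= 1L)
  cfg <- default_mediation_config(config)
  labels <- vapply(mediators, trait_id, character(1))
  total <- uvmr_stage(exposure, outcome, ld, "total-effect", cfg)
  ivs <- c(list(ld_clump(select_by_pvalue(exposure, cfg$p_threshold),
                         exposure, ld, cfg$clump_r2, cfg$clump_kb)),
           lapply(mediators, function(m) {
             ld_clump(select_by_pvalue(m, cfg$p_threshold), m, ld,
                      cfg$clump_r2, cfg$clump_kb)
           }))
  hmv <- build_mv_set(c(list(exposure), mediators), outcome, ivs, ld,
                      cfg$proxy_table, cfg$clump_r2, cfg$clump_kb,
                      cfg$proxy_r2_min, cfg$af_ambiguous)
  mv <- mvmr_ivw(hmv)
  per <- list()
  for (i in seq_along(mediators)) {
    a <- uvmr_stage(exposure, mediators[[i]], ld,
                    paste0("exposure-on-", labels[i]), cfg)
    per[[labels[i]]] <- mediate(
      beta_a = a$fit$estimate, se_a = a$fit$se,
      beta_b = unname(mv$estimates[labels[i]]),
      se_b = unname(mv$ses[labels[i]]),
      beta_c = total$fit$estimate, se_c = total$fit$se,
      prop_var = cfg$prop_var %||% "scaled-indirect")
  }
  ind <- vapply(per, function(m) m$indirect$estimate, numeric(1))
  se_ind <- vapply(per, function(m) m$indirect$se, numeric(1))
  comb <- sum(ind)
  se_comb <- sqrt(sum(se_ind^2))
  z <- stats::qnorm(0.975)
  bc <- total$fit$estimate
  bounds <- sort(c((comb - z * se_comb) / bc, (comb + z * se_comb) / bc))
  structure(list(
    mediator_labels = labels, per_mediator = per,
    combined_indirect = list(estimate = comb, se = se_comb,
                             ci_low = comb - z * se_comb,
                             ci_high = comb + z * se_comb),
    combined_proportion = list(estimate = comb / bc,
                               se = se_comb / abs(bc),
                               ci_low = bounds[1], ci_high = bounds[2]),
    beta_c = bc, se_c = total$fit$se,
    stages = list(total = total$fit, mvmr = mv)),
    class = "combined_mediation_result")
}
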