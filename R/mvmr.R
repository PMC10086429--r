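# Multivariable MR: joint direct effects of several exposures on an outcome.

mvmr_result <- function(method, labels, estimates, ses, pvals = NULL,
                        Q = NA_real_, df_Q = NA_real_, p_Q = NA_real_,
                        I2 = NA_real_, intercept = NULL, n_snps,
                        extra = list()) {
  if (is.null(pvals)) pvals <- 2 * stats::pnorm(-abs(estimates / ses))
  z <- stats::qnorm(0.975)
  res <- c(list(method = method, exposure_labels = labels,
                estimates = stats::setNames(estimates, labels),
                ses = stats::setNames(ses, labels),
                ci_low = stats::setNames(estimates - z * ses, labels),
                ci_high = stats::setNames(estimates + z * ses, labels),
                pvals = stats::setNames(pvals, labels),
                heterogeneity = list(Q = Q, df = df_Q, p_Q = p_Q, I2 = I2),
                mv_egger_intercept = intercept, n_snps = n_snps),
           extra)
  class(res) <- "mvmr_result"
  res
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat(sprintf("MVMR result [%s], %d SNPs, %d exposures\n", x$method,
              x$n_snps, length(x$exposure_labels)))
  for (k in x$exposure_labels) {
    cat(sprintf("  %s: %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
                k, x$estimates[k], x$ses[k], x$ci_low[k], x$ci_high[k],
                x$pvals[k]))
  }
  invisible(x)
}

# weighted no/with-intercept least squares shared by mvmr_ivw / mvmr_egger
mvmr_wls <- function(X, y, w, intercept = FALSE, labels) {
  D <- if (intercept) cbind(`(intercept)` = 1, X) else X
  qrD <- qr(sqrt(w) * D)
  if (qrD$rank < ncol(D)) {
    bad <- colnames(D)[qrD$pivot[seq.int(qrD$rank + 1L, ncol(D))]]
    stop("rank-deficient exposure design (collinear: ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  }
  coef <- qr.coef(qrD, sqrt(w) * y)
  resid <- y - drop(D %*% coef)
  Q <- sum(w * resid^2)
  df <- nrow(D) - ncol(D)
  xtwx_inv <- chol2inv(chol(crossprod(sqrt(w) * D)))
  sigma2 <- if (df > 0) Q / df else 0
  ses <- sqrt(diag(xtwx_inv)) * sqrt(max(1, sigma2))
  list(coef = coef, ses = ses, Q = Q, df = df,
       p_Q = if (df > 0) stats::pchisq(Q, df, lower.tail = FALSE)
       else NA_real_,
       I2 = if (df > 0 && Q > 0) max(0, (Q - df) / Q) else 0)
}

#' Multivariable IVW
#'
#' Weighted least squares of the outcome effects on the matrix of exposure
#' effects without intercept, weights `1/se_y^2`; each coefficient is the
#' direct effect of that exposure conditional on the others.  SEs carry
#' multiplicative residual scaling bounded below by 1; heterogeneity Q has
#' `n_snps - n_exposures` df.  With a single exposure this reduces exactly to
#' univariable IVW.
#'
#' @param h a (possibly multi-exposure) `harmonized_set`.
#' @return An `mvmr_result`.
#' @export
mvmr_ivw <- function(h) {
  ex <- exposure_matrix(h)
  K <- ncol(ex$beta)
  if (nrow(h) <= K) stop("need more SNPs than exposures", call. = FALSE)
  w <- 1 / h$se_y^2
  fit <- mvmr_wls(ex$beta, h$beta_y, w, intercept = FALSE,
                  labels = colnames(ex$beta))
  mvmr_result("mv-ivw", colnames(ex$beta), unname(fit$coef), fit$ses,
              Q = fit$Q, df_Q = fit$df, p_Q = fit$p_Q, I2 = fit$I2,
              n_snps = nrow(h))
}

#' Multivariable MR-Egger
#'
#' As [mvmr_ivw()] plus an intercept, after orienting every SNP so the first
#' exposure's effects are non-negative; the intercept p-value (t, with
#' `n_snps - n_exposures - 1` df) is the multivariable pleiotropy test.
#'
#' @param h a multi-exposure `harmonized_set`.
#' @return An `mvmr_result` with `mv_egger_intercept`.
#' @export
mvmr_egger <- function(h) {
  ex <- exposure_matrix(h)
  K <- ncol(ex$beta)
  J <- nrow(h)
  if (J <= K + 1L) {
    stop("MVMR-Egger needs more SNPs than exposures + 1", call. = FALSE)
  }
  flip <- sign(ex$beta[, 1])
  flip[flip == 0] <- 1
  X <- ex$beta * flip
  y <- h$beta_y * flip
  w <- 1 / h$se_y^2
  fit <- mvmr_wls(X, y, w, intercept = TRUE, labels = colnames(X))
  df <- fit$df
  int <- unname(fit$coef[1]); int_se <- fit$ses[1]
  int_p <- 2 * stats::pt(-abs(int / int_se), df = df)
  mvmr_result("mv-egger", colnames(ex$beta), unname(fit$coef[-1]),
              fit$ses[-1],
              pvals = 2 * stats::pt(-abs(fit$coef[-1] / fit$ses[-1]), df),
              Q = fit$Q, df_Q = df, p_Q = fit$p_Q, I2 = fit$I2,
              intercept = list(value = int, se = int_se, p = int_p),
              n_snps = J)
}

#' Q-minimizing (heterogeneity-weighted) MVMR
#'
#' Estimates the direct effects by minimizing the heterogeneity statistic
#' \deqn{Q(\theta) = \sum_j \frac{(\beta_{yj} - \sum_k \theta_k
#'   \beta_{xjk})^2}{se_{yj}^2 + \sum_k \theta_k^2 se_{xjk}^2}}
#' whose weights acknowledge the uncertainty of the exposure effects.
#' Numerical minimization starts from the [mvmr_ivw()] fit; confidence
#' intervals come from a seeded nonparametric bootstrap over SNPs.  In the
#' zero-exposure-SE limit the estimate coincides with MVMR-IVW.
#'
#' @param h a `harmonized_set` with exposure SEs available.
#' @param ci_boot bootstrap replicates; default 1000.  0 skips the bootstrap
#'   (SEs reported as `NA`).
#' @param seed RNG seed for the bootstrap.
#' @return An `mvmr_result` (method `"qhet"`) with `q_min`, the attained Q.
#' @export
qhet_mvmr <- function(h, ci_boot = 1000L, seed = 1L) {
  ex <- exposure_matrix(h)
  K <- ncol(ex$beta)
  if (nrow(h) <= K) stop("need more SNPs than exposures", call. = FALSE)
  qfun <- function(theta, X, SX2, y, sy2) {
    denom <- sy2 + drop(SX2 %*% theta^2)
    sum((y - drop(X %*% theta))^2 / denom)
  }
  minimize <- function(X, SX2, y, sy2, start) {
    opt <- stats::optim(start, qfun, X = X, SX2 = SX2, y = y, sy2 = sy2,
                        method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    if (opt$convergence != 0) {
      stop("QHET optimizer failed to converge (code ", opt$convergence,
           "): ", paste(opt$message, collapse = " "), call. = FALSE)
    }
    opt
  }
  X <- ex$beta; SX2 <- ex$se^2
  y <- h$beta_y; sy2 <- h$se_y^2
  start <- unname(mvmr_ivw(h)$estimates)
  opt <- minimize(X, SX2, y, sy2, start)
  est <- opt$par
  ses <- rep(NA_real_, K)
  ci_low <- ci_high <- rep(NA_real_, K)
  if (ci_boot > 0L) {
    boots <- with_seed(seed, {
      vapply(seq_len(ci_boot), function(b) {
        idx <- sample.int(nrow(h), replace = TRUE)
        tryCatch(minimize(X[idx, , drop = FALSE], SX2[idx, , drop = FALSE],
                          y[idx], sy2[idx], est)$par,
                 error = function(e) rep(NA_real_, K))
      }, numeric(K))
    })
    boots <- matrix(boots, nrow = K)
    ses <- apply(boots, 1L, stats::sd, na.rm = TRUE)
    ci_low <- apply(boots, 1L, stats::quantile, 0.025, na.rm = TRUE,
                    names = FALSE)
    ci_high <- apply(boots, 1L, stats::quantile, 0.975, na.rm = TRUE,
                     names = FALSE)
  }
  out <- mvmr_result("qhet", colnames(X), est, ses, n_snps = nrow(h),
                     Q = opt$value, df_Q = nrow(h) - K,
                     extra = list(q_min = opt$value, ci_boot = ci_boot,
                                  seed = seed))
  if (ci_boot > 0L) {
    out$ci_low <- stats::setNames(ci_low, colnames(X))
    out$ci_high <- stats::setNames(ci_high, colnames(X))
  }
  out
}

#' Assemble a multi-exposure harmonized set
#'
#' Takes the union of per-exposure instrument sets, jointly re-clumps it
#' (ranking by the lowest p-value across the contributing GWAS), extracts the
#' union from every exposure table and the outcome table (substituting LD
#' proxies in the outcome where available), and aligns all effect columns to
#' the first exposure's allele orientation.
#'
#' @param exposures list of [summary_stats()] tables (exposure first, then
#'   mediators).
#' @param outcome outcome [summary_stats()].
#' @param instruments list of `instrument_set`s, one per exposure.
#' @param ld optional [ld_info()] for the joint re-clump.
#' @param proxy_table optional proxy table for outcome lookup.
#' @param r2_max,window_kb clumping parameters.
#' @param proxy_r2_min minimum proxy r-squared; default 0.8.
#' @param af_ambiguous palindrome ambiguity interval.
#' @return A multi-exposure `harmonized_set`; per-SNP dispositions in
#'   `attr(, "drop_log")`.
#' @export
build_mv_set <- function(exposures, outcome, instruments, ld = NULL,
                         proxy_table = NULL, r2_max = 0.001,
                         window_kb = 10000, proxy_r2_min = 0.8,
                         af_ambiguous = c(0.4, 0.6)) {
  stopifnot(length(exposures) >= 1L, length(instruments) == length(exposures))
  labels <- vapply(exposures, trait_id, character(1))
  union_ids <- unique(unlist(lapply(instruments, `[[`, "snp_ids")))
  if (length(union_ids) == 0L) stop("empty instrument union", call. = FALSE)
  # joint re-clump ranked by the best p across contributing GWAS
  minp <- vapply(union_ids, function(s) {
    min(vapply(exposures, function(e) {
      p <- e$pval[match(s, e$snp)]
      if (length(p) == 0L || is.na(p)) Inf else p
    }, numeric(1)))
  }, numeric(1))
  pseudo <- summary_stats(data.frame(
    snp = union_ids, effect_allele = "A", other_allele = "G",
    beta = 1, se = 1, pval = pmin(minp, 1), eaf = NA_real_, n = NA_real_,
    stringsAsFactors = FALSE), trait_id = "union", validate = FALSE)
  cl <- ld_clump(instrument_set(union_ids[order(minp, union_ids)], "union",
                                max(minp[is.finite(minp)], 1)),
                 pseudo, ld, r2_max, window_kb)
  ids <- cl$snp_ids
  log <- data.frame(snp = character(0), disposition = character(0),
                    stringsAsFactors = FALSE)
  note <- function(snp, why) {
    log <<- rbind(log, data.frame(snp = snp, disposition = why,
                                  stringsAsFactors = FALSE))
  }
  # outcome availability, with proxy substitution
  out_id <- ids
  for (i in seq_along(ids)) {
    if (!(ids[i] %in% outcome$snp)) {
      proxy <- if (!is.null(proxy_table)) {
        find_proxy(ids[i], proxy_table, outcome, proxy_r2_min)
      } else NA_character_
      if (!is.na(proxy)) {
        note(ids[i], paste0("proxy-of:", proxy))
        out_id[i] <- proxy
      } else {
        note(ids[i], "dropped:absent-from-outcome")
        out_id[i] <- NA_character_
      }
    }
  }
  present_everywhere <- !is.na(out_id) &
    Reduce(`&`, lapply(exposures, function(e) ids %in% e$snp))
  missing_exp <- !is.na(out_id) & !present_everywhere
  if (any(missing_exp)) note(ids[missing_exp], "dropped:absent-from-exposure")
  ids <- ids[present_everywhere]
  out_id <- out_id[present_everywhere]
  if (length(ids) <= length(exposures)) {
    stop("too few SNPs survive the multivariable extraction (",
         length(ids), ")", call. = FALSE)
  }
  ref <- exposures[[1]][match(ids, exposures[[1]]$snp), ]
  h <- data.frame(snp = ids, effect_allele = ref$effect_allele,
                  other_allele = ref$other_allele, stringsAsFactors = FALSE)
  ok <- rep(TRUE, length(ids))
  cols <- list()
  for (k in seq_along(exposures)) {
    tab <- exposures[[k]][match(ids, exposures[[k]]$snp), ]
    al <- align_alleles(ref$effect_allele, ref$other_allele, ref$eaf,
                        tab$effect_allele, tab$other_allele, tab$beta,
                        tab$eaf, af_ambiguous)
    ok <- ok & al$disposition %in% c("kept", "flipped")
    cols[[paste0("beta_x.", labels[k])]] <- al$beta
    cols[[paste0("se_x.", labels[k])]] <- tab$se
  }
  otab <- outcome[match(out_id, outcome$snp), ]
  al_y <- align_alleles(ref$effect_allele, ref$other_allele, ref$eaf,
                        otab$effect_allele, otab$other_allele, otab$beta,
                        otab$eaf, af_ambiguous)
  ok <- ok & al_y$disposition %in% c("kept", "flipped")
  if (any(!ok)) note(ids[!ok], "removed:harmonization")
  h <- cbind(h, as.data.frame(cols, check.names = FALSE))
  h$beta_y <- al_y$beta
  h$se_y <- otab$se
  h <- h[ok, , drop = FALSE]
  rownames(h) <- NULL
  if (nrow(h) <= length(exposures)) {
    stop("too few SNPs survive multivariable harmonization", call. = FALSE)
  }
  structure(h, exposure_labels = labels, drop_log = log,
            class = c("harmonized_set", "data.frame"))
}
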