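# Univariable two-sample MR estimators and sensitivity analyses, all
# operating on a harmonized_set of (beta_x, se_x, beta_y, se_y).

mr_result <- function(method, estimate, se, pval = NULL, n_snps,
                      Q = NA_real_, df_Q = NA_real_, p_Q = NA_real_,
                      I2 = NA_real_, egger_intercept = NULL, notes = NULL,
                      extra = list()) {
  if (is.null(pval)) pval <- 2 * stats::pnorm(-abs(estimate / se))
  z <- stats::qnorm(0.975)
  res <- c(list(method = method, estimate = estimate, se = se,
                ci_low = estimate - z * se, ci_high = estimate + z * se,
                pval = pval, n_snps = n_snps,
                heterogeneity = list(Q = Q, df = df_Q, p_Q = p_Q, I2 = I2),
                egger_intercept = egger_intercept, notes = notes),
           extra)
  class(res) <- "mr_result"
  res
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR result [%s], %d SNPs\n", x$method, x$n_snps))
  cat(sprintf("  estimate %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
              x$estimate, x$se, x$ci_low, x$ci_high, x$pval))
  if (!is.na(x$heterogeneity$Q)) {
    cat(sprintf("  Q = %.3f (df %d, p = %.3g), I2 = %.1f%%\n",
                x$heterogeneity$Q, x$heterogeneity$df, x$heterogeneity$p_Q,
                100 * x$heterogeneity$I2))
  }
  if (!is.null(x$egger_intercept)) {
    cat(sprintf("  intercept %.4f (se %.4f), p = %.3g\n",
                x$egger_intercept$value, x$egger_intercept$se,
                x$egger_intercept$p))
  }
  invisible(x)
}

check_snps <- function(h, min_snps, what) {
  if (nrow(h) < min_snps) {
    stop(what, " needs at least ", min_snps, " SNPs (got ", nrow(h), ")",
         call. = FALSE)
  }
}

#' Per-SNP Wald ratio estimates
#'
#' `ratio = beta_y / beta_x` with first-order SE `se_y / |beta_x|`; the
#' second-order (delta-method) SE
#' `sqrt(se_y^2/beta_x^2 + beta_y^2 se_x^2 / beta_x^4)` is also reported.
#' SNPs with `beta_x == 0` are dropped with a warning.
#'
#' @param h a `harmonized_set`.
#' @param order SE order to place in the `se` column: `"first"` (default) or
#'   `"second"`.
#' @return Data frame with `snp`, `ratio`, `se`, `se_first`, `se_second`.
#' @export
ratio_estimates <- function(h, order = c("first", "second")) {
  order <- match.arg(order)
  zero <- h$beta_x == 0
  if (any(zero)) {
    warning("dropping SNP(s) with zero exposure effect: ",
            paste(h$snp[zero], collapse = ", "), call. = FALSE)
    h <- h[!zero, , drop = FALSE]
  }
  ratio <- h$beta_y / h$beta_x
  se1 <- h$se_y / abs(h$beta_x)
  se2 <- sqrt(h$se_y^2 / h$beta_x^2 + h$beta_y^2 * h$se_x^2 / h$beta_x^4)
  data.frame(snp = h$snp, ratio = ratio,
             se = if (order == "first") se1 else se2,
             se_first = se1, se_second = se2, stringsAsFactors = FALSE)
}

ivw_sums <- function(bx, by, sy) {
  w <- 1 / sy^2
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  est <- sxy / sxx
  list(w = w, est = est, sxx = sxx,
       q_contrib = w * (by - est * bx)^2)
}

#' Inverse-variance weighted estimator
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' through the origin with first-order weights `1/se_y^2` — the IVW
#' combination of Wald ratios.  The fixed-effect SE is
#' `sqrt(1 / sum(beta_x^2/se_y^2))`; the multiplicative random-effects model
#' scales it by `max(1, sqrt(Q/(J-1)))`.  `effects_model = "auto"` picks
#' random effects exactly when the heterogeneity test is significant
#' (`p_Q < 0.05`) *and* `I2 > 0.25`, otherwise fixed.  Cochran's Q and I2 are
#' always reported.  A single SNP degrades to the Wald ratio with a note.
#'
#' @param h a `harmonized_set`.
#' @param effects_model `"fixed"`, `"random"` or `"auto"`.
#' @return An `mr_result`; per-SNP Q contributions in `$q_contrib`.
#' @export
mr_ivw <- function(h, effects_model = c("auto", "fixed", "random")) {
  effects_model <- match.arg(effects_model)
  check_snps(h, 1L, "IVW")
  J <- nrow(h)
  s <- ivw_sums(h$beta_x, h$beta_y, h$se_y)
  se_fixed <- sqrt(1 / s$sxx)
  Q <- sum(s$q_contrib)
  if (J == 1L) {
    return(mr_result("wald-ratio", s$est, se_fixed, n_snps = 1L,
                     notes = "single SNP: Wald ratio",
                     extra = list(q_contrib = s$q_contrib)))
  }
  df <- J - 1L
  p_Q <- stats::pchisq(Q, df, lower.tail = FALSE)
  I2 <- max(0, (Q - df) / Q)
  random <- switch(effects_model,
                   fixed = FALSE,
                   random = TRUE,
                   auto = (p_Q < 0.05 && I2 > 0.25))
  scale <- if (random) max(1, sqrt(Q / df)) else 1
  method <- if (random) "ivw-random" else "ivw-fixed"
  mr_result(method, s$est, se_fixed * scale, n_snps = J,
            Q = Q, df_Q = df, p_Q = p_Q, I2 = I2,
            extra = list(q_contrib = s$q_contrib,
                         effects_model = if (random) "random" else "fixed"))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects *with* an intercept,
#' after orienting every SNP so the exposure effect is non-negative.  The
#' slope is the causal estimate; the intercept estimates average directional
#' pleiotropy and its two-sided p-value (t, J-2 df) is the MR-Egger pleiotropy
#' test.  SEs carry multiplicative residual scaling bounded below by 1.
#'
#' @param h a `harmonized_set` with at least 3 SNPs.
#' @return An `mr_result` with `egger_intercept`.
#' @export
mr_egger <- function(h) {
  check_snps(h, 3L, "MR-Egger")
  J <- nrow(h)
  flip <- sign(h$beta_x)
  flip[flip == 0] <- 1
  bx <- h$beta_x * flip
  by <- h$beta_y * flip
  w <- 1 / h$se_y^2
  fit <- stats::lm(by ~ bx, weights = w)
  # unit-variance coefficient SEs scaled by max(1, residual sd): the
  # multiplicative model never shrinks below the homoscedastic-weight SE
  xtwx_inv <- chol2inv(chol(crossprod(cbind(1, bx) * sqrt(w))))
  Q <- sum(w * stats::residuals(fit)^2)
  sigma2 <- Q / (J - 2L)
  adj <- sqrt(max(1, sigma2))
  est <- unname(stats::coef(fit)["bx"])
  se <- sqrt(xtwx_inv[2, 2]) * adj
  int <- unname(stats::coef(fit)["(Intercept)"])
  int_se <- sqrt(xtwx_inv[1, 1]) * adj
  pt2 <- function(t) 2 * stats::pt(-abs(t), df = J - 2L)
  df <- J - 2L
  mr_result("mr-egger", est, se, pval = pt2(est / se), n_snps = J,
            Q = Q, df_Q = df,
            p_Q = stats::pchisq(Q, df, lower.tail = FALSE),
            I2 = max(0, (Q - df) / Q),
            egger_intercept = list(value = int, se = int_se,
                                   p = pt2(int / int_se)))
}

weighted_median_point <- function(ratio, w) {
  ord <- order(ratio)
  ratio <- ratio[ord]
  w <- w[ord] / sum(w)
  cum <- cumsum(w) - w / 2
  if (cum[1] >= 0.5) return(ratio[1])
  if (cum[length(cum)] <= 0.5) return(ratio[length(ratio)])
  stats::approx(cum, ratio, xout = 0.5, ties = "ordered")$y
}

#' Weighted and penalized weighted median estimators
#'
#' The weighted median of the per-SNP Wald ratios, consistent when at least
#' half the weight comes from valid instruments.  Ratios are ordered and the
#' estimate is the ratio at cumulative (half-open) weight 0.5, interpolating
#' linearly between the two bracketing SNPs at cumulative weights
#' `cumsum(w) - w/2`.  The penalized variant down-weights heterogeneous SNPs:
#' weights are multiplied by `min(1, penalty * q_j)` with `q_j` the upper
#' chi-square(1) tail of SNP j's Q contribution about the unpenalized median.
#' The SE comes from a seeded parametric bootstrap (resampling `beta_x`,
#' `beta_y` from their sampling distributions).
#'
#' @param h a `harmonized_set` with at least 3 SNPs.
#' @param penalized apply the heterogeneity penalty.
#' @param penalty penalty constant; default 20.
#' @param n_boot bootstrap draws for the SE; default 1000.
#' @param seed RNG seed for the bootstrap.
#' @return An `mr_result`.
#' @export
weighted_median_mr <- function(h, penalized = FALSE, penalty = 20,
                               n_boot = 1000L, seed = 1L) {
  check_snps(h, 3L, "weighted median")
  point <- function(bx, by, sy) {
    ratio <- by / bx
    w <- bx^2 / sy^2                     # inverse variance of the ratio
    if (penalized) {
      mid <- weighted_median_point(ratio, w)
      qj <- stats::pchisq(w * (ratio - mid)^2, df = 1, lower.tail = FALSE)
      w <- w * pmin(1, penalty * qj)
    }
    weighted_median_point(ratio, w)
  }
  est <- point(h$beta_x, h$beta_y, h$se_y)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(nrow(h), h$beta_x, h$se_x)
      by <- stats::rnorm(nrow(h), h$beta_y, h$se_y)
      point(bx, by, h$se_y)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  mr_result(if (penalized) "penalized-weighted-median" else "weighted-median",
            est, se, n_snps = nrow(h),
            extra = list(n_boot = n_boot, seed = seed))
}

#' Likelihood-based MR estimator
#'
#' Maximizes the bivariate-normal likelihood in which each SNP has an unknown
#' true exposure effect `xi_j` and all SNPs share a causal slope `theta`:
#' `beta_x_j ~ N(xi_j, se_x_j^2)`, `beta_y_j ~ N(theta * xi_j, se_y_j^2)`.
#' The `xi_j` are profiled out in closed form; `theta` is then maximized by
#' 1-D optimization and its SE taken from the curvature of the profile
#' log-likelihood (the observed information for `theta`).  As `se_x -> 0`
#' the estimate converges to fixed-effect IVW.
#'
#' @param h a `harmonized_set` with at least 2 SNPs.
#' @return An `mr_result`.
#' @export
max_likelihood_mr <- function(h) {
  check_snps(h, 2L, "likelihood-based MR")
  bx <- h$beta_x; sx2 <- h$se_x^2
  by <- h$beta_y; sy2 <- h$se_y^2
  sx2 <- pmax(sx2, 1e-12)
  prof_ll <- function(theta) {
    xi <- (bx / sx2 + theta * by / sy2) / (1 / sx2 + theta^2 / sy2)
    -0.5 * sum((bx - xi)^2 / sx2 + (by - theta * xi)^2 / sy2)
  }
  start <- ivw_sums(bx, by, h$se_y)$est
  width <- 50 * sqrt(1 / ivw_sums(bx, by, h$se_y)$sxx) + abs(start) + 1
  opt <- stats::optimize(prof_ll, interval = c(start - width, start + width),
                         maximum = TRUE, tol = 1e-10)
  est <- opt$maximum
  hstep <- max(1e-6, abs(est) * 1e-4)
  d2 <- (prof_ll(est + hstep) - 2 * prof_ll(est) + prof_ll(est - hstep)) /
    hstep^2
  if (!is.finite(d2) || d2 >= 0) {
    stop("likelihood-based MR failed to attain a maximum (curvature ",
         format(d2), ")", call. = FALSE)
  }
  mr_result("max-likelihood", est, sqrt(-1 / d2), n_snps = nrow(h),
            notes = sprintf("profile optimum, objective %.6g", opt$objective))
}

#' Radial (modified second-order weights) IVW
#'
#' Regression of `ratio_j * sqrt(w_j)` on `sqrt(w_j)` without intercept,
#' where `w_j = beta_x_j^2 / se_y_j^2` are first-order weights.  Numerically
#' identical to first-order IVW; its value is the per-SNP radial Q
#' contributions used for outlier display.
#'
#' @param h a `harmonized_set` with at least 2 SNPs.
#' @return An `mr_result` with per-SNP contributions in `$q_contrib`.
#' @export
radial_ivw <- function(h) {
  check_snps(h, 2L, "radial IVW")
  r <- ratio_estimates(h)
  hh <- h[h$snp %in% r$snp, , drop = FALSE]
  w <- hh$beta_x^2 / hh$se_y^2
  xr <- sqrt(w)
  yr <- r$ratio * xr
  est <- sum(xr * yr) / sum(xr^2)
  se_fixed <- sqrt(1 / sum(xr^2))
  qc <- (yr - est * xr)^2
  Q <- sum(qc)
  df <- length(w) - 1L
  p_Q <- stats::pchisq(Q, df, lower.tail = FALSE)
  mr_result("radial-ivw", est, se_fixed, n_snps = length(w),
            Q = Q, df_Q = df, p_Q = p_Q, I2 = max(0, (Q - df) / Q),
            extra = list(q_contrib = stats::setNames(qc, r$snp)))
}

# leave-one-out IVW estimates via sufficient-statistic downdating
loo_estimates <- function(bx, by, sy) {
  w <- 1 / sy^2
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' MR-PRESSO: residual sum and outlier test
#'
#' Detects horizontally pleiotropic outlier SNPs by comparing the observed
#' residual sum of squares (each SNP's residual about the leave-one-out IVW
#' fit, inverse-variance weighted) against its parametric null distribution
#' simulated from the per-SNP sampling errors.  A per-SNP empirical p with
#' Bonferroni correction flags outliers when the global test is significant;
#' the distortion test compares the outlier-removal shift of the estimate to
#' the shift from removing random subsets of the same size.  Fully seeded.
#'
#' @param h a `harmonized_set` with at least 4 SNPs.
#' @param nb_sim number of simulations (min p is `1/(nb_sim+1)`); default
#'   1000, at least 100.
#' @param seed RNG seed.
#' @param sig significance level for the global and outlier tests (0.05).
#' @return A `presso_result` list: `global_rss_p`, `outlier_snp_ids`,
#'   `outlier_p` (Bonferroni-adjusted), `distortion_p`, `estimate_before`,
#'   `estimate_after` (IVW after outlier removal), `nb_sim`, `seed`.
#' @export
mr_presso <- function(h, nb_sim = 1000L, seed = 1L, sig = 0.05) {
  check_snps(h, 4L, "MR-PRESSO")
  if (nb_sim < 100L) stop("nb_sim must be at least 100", call. = FALSE)
  J <- nrow(h)
  if (J / (nb_sim + 1) >= sig) {
    warning("nb_sim = ", nb_sim, " cannot resolve Bonferroni-adjusted ",
            "outlier p below ", signif(J / (nb_sim + 1), 3),
            " for ", J, " SNPs; increase nb_sim", call. = FALSE)
  }
  bx <- h$beta_x; sx <- h$se_x
  by <- h$beta_y; sy <- h$se_y
  w <- 1 / sy^2
  theta_loo <- loo_estimates(bx, by, sy)
  obs_contrib <- w * (by - theta_loo * bx)^2
  rss_obs <- sum(obs_contrib)
  sims <- with_seed(seed, {
    vapply(seq_len(nb_sim), function(i) {
      bxs <- stats::rnorm(J, bx, sx)
      bys <- stats::rnorm(J, theta_loo * bx, sy)
      tl <- loo_estimates(bxs, bys, sy)
      w * (bys - tl * bxs)^2
    }, numeric(J))
  })                                      # J x nb_sim matrix
  rss_sim <- colSums(sims)
  global_p <- (1 + sum(rss_sim >= rss_obs)) / (nb_sim + 1)
  p_snp <- (1 + rowSums(sims >= obs_contrib)) / (nb_sim + 1)
  p_adj <- pmin(1, p_snp * J)
  outliers <- if (global_p < sig) h$snp[p_adj < sig] else character(0)
  before <- mr_ivw(h, "fixed")$estimate
  after <- before
  distortion_p <- NA_real_
  if (length(outliers) > 0L && length(outliers) < J - 1L) {
    keep <- !(h$snp %in% outliers)
    after <- mr_ivw(h[keep, , drop = FALSE], "fixed")$estimate
    obs_shift <- abs(before - after)
    shifts <- with_seed(derive_seed(seed, 9L), {
      vapply(seq_len(nb_sim), function(i) {
        drop_i <- sample.int(J, length(outliers))
        abs(before - ivw_sums(bx[-drop_i], by[-drop_i], sy[-drop_i])$est)
      }, numeric(1))
    })
    distortion_p <- (1 + sum(shifts >= obs_shift)) / (nb_sim + 1)
  }
  structure(list(global_rss_p = global_p, outlier_snp_ids = outliers,
                 outlier_p = stats::setNames(p_adj, h$snp),
                 distortion_p = distortion_p,
                 estimate_before = before, estimate_after = after,
                 nb_sim = nb_sim, seed = seed),
            class = "presso_result")
}

#' Leave-one-out IVW sensitivity analysis
#'
#' One fixed-effect IVW fit per omitted SNP, plus the all-SNP fit in the last
#' row (`snp = "(all)"`).
#'
#' @param h a `harmonized_set` with at least 3 SNPs.
#' @return Data frame with `snp` (the omitted SNP), `estimate`, `se`.
#' @export
leave_one_out <- function(h) {
  check_snps(h, 3L, "leave-one-out")
  J <- nrow(h)
  rows <- lapply(seq_len(J), function(j) {
    fit <- mr_ivw(h[-j, , drop = FALSE], "fixed")
    data.frame(snp = h$snp[j], estimate = fit$estimate, se = fit$se,
               stringsAsFactors = FALSE)
  })
  all_fit <- mr_ivw(h, "fixed")
  rbind(do.call(rbind, rows),
        data.frame(snp = "(all)", estimate = all_fit$estimate,
                   se = all_fit$se, stringsAsFactors = FALSE))
}

# I2_GX: weak-instrument (regression-dilution) statistic on exposure effects
i2_gx <- function(bx, sx) {
  w <- 1 / sx^2
  bbar <- sum(w * bx) / sum(w)
  q_gx <- sum(w * (bx - bbar)^2)
  J <- length(bx)
  max(0, (q_gx - (J - 1)) / q_gx)
}

#' SIMEX-corrected MR-Egger slope
#'
#' Simulation-extrapolation correction for the regression dilution of the
#' Egger slope under weak instruments (low `I2_GX`): for each `lambda` in the
#' grid, noise `N(0, lambda * se_x^2)` is added to the exposure effects `B`
#' times and the Egger fit repeated; the mean slope (and intercept) is then
#' extrapolated quadratically to `lambda = -1`, the no-measurement-error
#' limit.  With `se_x = 0` the corrected estimate equals the naive one.
#'
#' @param h a `harmonized_set` with at least 3 SNPs.
#' @param lambdas grid of added-noise multipliers; default `seq(0, 2, 0.25)`.
#' @param B refits per grid point; default 200.
#' @param seed RNG seed.
#' @return An `mr_result` (method `"egger-simex"`) with `I2_GX` and the naive
#'   Egger fit in `$naive`; SE extrapolated on the same grid.
#' @export
egger_simex <- function(h, lambdas = seq(0, 2, by = 0.25), B = 200L,
                        seed = 1L) {
  check_snps(h, 3L, "SIMEX")
  naive <- mr_egger(h)
  if (all(h$se_x == 0)) {
    out <- naive
    out$method <- "egger-simex"
    out$notes <- "se_x all zero: no dilution, corrected = naive"
    out$I2_GX <- 1
    out$naive <- naive
    return(out)
  }
  i2gx <- i2_gx(abs(h$beta_x), h$se_x)
  notes <- NULL
  if (is.finite(i2gx) && i2gx >= 0.9) {
    notes <- "I2_GX >= 0.9: SIMEX correction negligible"
  }
  fits <- with_seed(seed, {
    sapply(lambdas, function(l) {
      if (l == 0) {
        c(naive$estimate, naive$se)
      } else {
        reps <- vapply(seq_len(B), function(b) {
          hh <- h
          hh$beta_x <- h$beta_x + stats::rnorm(nrow(h), 0, sqrt(l) * h$se_x)
          fit <- mr_egger(hh)
          c(fit$estimate, fit$se)
        }, numeric(2))
        rowMeans(reps)
      }
    })
  })
  extrap <- function(y) {
    fit <- stats::lm(y ~ lambdas + I(lambdas^2))
    unname(stats::predict(fit, data.frame(lambdas = -1)))
  }
  est <- extrap(fits[1, ])
  se <- max(extrap(fits[2, ]), 1e-12)
  out <- mr_result("egger-simex", est, se, n_snps = nrow(h), notes = notes)
  out$I2_GX <- i2gx
  out$naive <- naive
  out$lambdas <- lambdas
  out
}

#' Run the standard univariable MR battery
#'
#' Convenience wrapper returning a tidy table over the requested methods.
#'
#' @param h a `harmonized_set`.
#' @param methods subset of `c("ivw", "egger", "wmedian", "pwmedian", "ml",
#'   "radial")`.
#' @param seed seed for the stochastic methods.
#' @return Data frame with columns `method`, `estimate`, `se`, `ci_low`,
#'   `ci_high`, `pval`, `n_snps`, `Q`, `p_Q`, `I2`, `intercept`,
#'   `intercept_p`.
#' @export
uvmr_battery <- function(h, methods = c("ivw", "egger", "wmedian",
                                        "pwmedian", "ml", "radial"),
                         seed = 1L) {
  fits <- list()
  for (m in methods) {
    fits[[m]] <- switch(
      m,
      ivw = mr_ivw(h),
      egger = mr_egger(h),
      wmedian = weighted_median_mr(h, seed = seed),
      pwmedian = weighted_median_mr(h, penalized = TRUE, seed = seed),
      ml = max_likelihood_mr(h),
      radial = radial_ivw(h),
      stop("unknown method: ", m, call. = FALSE))
  }
  do.call(rbind, lapply(fits, function(f) {
    data.frame(method = f$method, estimate = f$estimate, se = f$se,
               ci_low = f$ci_low, ci_high = f$ci_high, pval = f$pval,
               n_snps = f$n_snps, Q = f$heterogeneity$Q,
               p_Q = f$heterogeneity$p_Q, I2 = f$heterogeneity$I2,
               intercept = if (is.null(f$egger_intercept)) NA_real_
               else f$egger_intercept$value,
               intercept_p = if (is.null(f$egger_intercept)) NA_real_
               else f$egger_intercept$p,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
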