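mv_h <- function(J = 30, theta = c(0.3, -0.2), se_y = 0.05, noise = 0,
                 seed = 1) {
  set.seed(seed)
  X <- cbind(x1 = runif(J, -0.5, 0.5), x2 = runif(J, -0.5, 0.5))
  y <- drop(X %*% theta) + rnorm(J, 0, noise)
  harmonized_set(beta_x = X, se_x = matrix(0.02, J, 2),
                 beta_y = y, se_y = rep(se_y, J))
}

test_that("single-exposure MVMR reduces to univariable estimators", {
  h <- sim_h(J = 25, seed = 1, pleio_sd = 0.02)
  mv <- mvmr_ivw(h)
  uv <- mr_ivw(h, "fixed")
  expect_lt(abs(unname(mv$estimates[1]) - uv$estimate), 1e-8)
  mve <- mvmr_egger(h)
  uve <- mr_egger(h)
  expect_lt(abs(unname(mve$estimates[1]) - uve$estimate), 1e-8)
  expect_lt(abs(mve$mv_egger_intercept$value - uve$egger_intercept$value),
            1e-8)
  expect_equal(mve$ses[[1]], uve$se, tolerance = 1e-8)
})

test_that("exact multi-exposure relation is recovered with zero residual", {
  h <- mv_h(theta = c(0.3, -0.2))
  fit <- mvmr_ivw(h)
  expect_equal(unname(fit$estimates), c(0.3, -0.2), tolerance = 1e-10)
  expect_equal(fit$heterogeneity$Q, 0, tolerance = 1e-16)
})

test_that("MVMR-Egger finds a constant offset added after orientation", {
  h <- mv_h(theta = c(0.3, -0.2), noise = 0.01, seed = 3)
  flip <- sign(h$beta_x.x1)
  h$beta_y <- h$beta_y + 0.05 * flip   # +0.05 in oriented space
  fit <- mvmr_egger(h)
  expect_lt(abs(fit$mv_egger_intercept$value - 0.05), 0.02)
  noint <- mv_h(theta = c(0.3, -0.2), noise = 0.01, seed = 4)
  fit0 <- mvmr_egger(noint)
  expect_lt(abs(fit0$mv_egger_intercept$value),
            3 * fit0$mv_egger_intercept$se)
  expect_equal(unname(fit0$estimates), unname(mvmr_ivw(noint)$estimates),
               tolerance = 0.05)
})

test_that("exposure permutation permutes estimates identically", {
  h <- mv_h(noise = 0.02, seed = 5)
  hp <- harmonized_set(
    beta_x = cbind(x2 = h$beta_x.x2, x1 = h$beta_x.x1),
    se_x = matrix(0.02, nrow(h), 2), beta_y = h$beta_y, se_y = h$se_y)
  f1 <- mvmr_ivw(h); f2 <- mvmr_ivw(hp)
  expect_equal(unname(f2$estimates[c("x1", "x2")]),
               unname(f1$estimates[c("x1", "x2")]), tolerance = 1e-12)
})

test_that("rank deficiency is reported with the collinear exposures", {
  J <- 20
  set.seed(6)
  x1 <- runif(J)
  h <- harmonized_set(beta_x = cbind(a = x1, b = 2 * x1),
                      se_x = matrix(0.02, J, 2),
                      beta_y = 0.3 * x1, se_y = rep(0.05, J))
  expect_error(mvmr_ivw(h), "collinear")
})

test_that("QHET: IVW limit, exact fit, and minimization dominance", {
  h0 <- mv_h(noise = 0.02, seed = 7)
  h0$se_x.x1 <- h0$se_x.x2 <- rep(0, nrow(h0))
  q0 <- qhet_mvmr(h0, ci_boot = 0)
  ivw0 <- mvmr_ivw(h0)
  expect_equal(unname(q0$estimates), unname(ivw0$estimates),
               tolerance = 1e-5)
  hx <- mv_h(noise = 0)
  qx <- qhet_mvmr(hx, ci_boot = 0)
  expect_equal(qx$q_min, 0, tolerance = 1e-10)
  expect_equal(unname(qx$estimates), c(0.3, -0.2), tolerance = 1e-5)
  # Q at the minimizer never exceeds Q at the IVW start
  hh <- mv_h(noise = 0.1, seed = 8)
  qfun <- function(theta, h) {
    X <- cbind(h$beta_x.x1, h$beta_x.x2)
    S <- cbind(h$se_x.x1, h$se_x.x2)^2
    sum((h$beta_y - drop(X %*% theta))^2 / (h$se_y^2 + drop(S %*% theta^2)))
  }
  qh <- qhet_mvmr(hh, ci_boot = 50, seed = 2)
  expect_lte(qh$q_min, qfun(unname(mvmr_ivw(hh)$estimates), hh) + 1e-8)
  expect_false(any(is.na(qh$ses)))
})

test_that("build_mv_set unions, de-duplicates, re-clumps and harmonizes", {
  mk <- function(snp, beta, pval, trait, ea = "A", oa = "G") {
    summary_stats(data.frame(
      snp = snp, effect_allele = ea, other_allele = oa, beta = beta,
      se = 0.02, pval = pval, eaf = 0.3, n = 1e5,
      stringsAsFactors = FALSE), trait_id = trait, validate = FALSE)
  }
  x1 <- mk(c("a", "b", "c", "d"), 0.1, c(1e-9, 1e-9, 0.5, 0.5), "x1")
  x2 <- mk(c("a", "b", "c", "d"), 0.1, c(0.5, 0.5, 1e-9, 1e-7), "x2")
  y <- mk(c("a", "b", "c", "d"), 0.05, 0.5, "y")
  iv1 <- select_by_pvalue(x1, 5e-5)
  iv2 <- select_by_pvalue(x2, 5e-5)
  # disjoint instruments: union is the concatenation
  h <- build_mv_set(list(x1, x2), y, list(iv1, iv2))
  expect_setequal(h$snp, c("a", "b", "c", "d"))
  # shared SNP appears once
  iv2b <- select_by_pvalue(mk(c("a", "c"), 0.1, c(1e-8, 1e-9), "x2"), 5e-5)
  h2 <- build_mv_set(list(x1, x2), y, list(iv1, iv2b))
  expect_equal(sum(h2$snp == "a"), 1L)
  # joint re-clump under LD keeps the lower-p member of a linked pair
  ld <- toy_ld(c("b", "d"), matrix(c(1, 0.5, 0.5, 1), 2))
  h3 <- build_mv_set(list(x1, x2), y, list(iv1, iv2), ld = ld,
                     r2_max = 0.001)
  expect_true("b" %in% h3$snp)   # p 1e-9 beats d's 1e-7
  expect_false("d" %in% h3$snp)
})

test_that("MVMR recovers mediator and direct effects from synthetic data", {
  tr <- sim_truth(J = 60, n_per_trait = 8000, palindromic_frac = 0,
                  seed = 31)
  tabs <- simulate_two_sample(tr)
  iv_x <- select_by_pvalue(tabs$exposure, 5e-5)
  iv_m <- select_by_pvalue(tabs$mediator, 5e-5)
  h <- build_mv_set(list(tabs$exposure, tabs$mediator), tabs$outcome,
                    list(iv_x, iv_m))
  fit <- mvmr_ivw(h)
  expect_lt(abs(fit$estimates[["exposure"]] - tr$theta_d),
            4 * fit$ses[["exposure"]])
  expect_lt(abs(fit$estimates[["mediator"]] - tr$beta_m),
            4 * fit$ses[["mediator"]])
})
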