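test_that("Wald ratios: point, sign, and both SE orders", {
  h <- harmonized_set(beta_x = c(0.5, -0.5), se_x = 0.05,
                      beta_y = c(0.2, 0.2), se_y = 0.1)
  r <- ratio_estimates(h)
  expect_equal(r$ratio, c(0.4, -0.4))
  expect_equal(r$se_first, c(0.2, 0.2))
  # delta method: sqrt(se_y^2/bx^2 + by^2 se_x^2 / bx^4)
  expect_equal(r$se_second,
               rep(sqrt(0.1^2 / 0.25 + 0.04 * 0.0025 / 0.0625), 2))
  h0 <- harmonized_set(beta_x = c(0.5, 0), se_x = 0.05,
                       beta_y = c(0.2, 0.2), se_y = 0.1)
  expect_warning(r0 <- ratio_estimates(h0), "zero exposure effect")
  expect_equal(nrow(r0), 1L)
})

test_that("IVW equals the hand-computed WLS oracle", {
  h <- harmonized_set(beta_x = c(1, 1, 2), se_x = 1e-4,
                      beta_y = c(0.2, 0.4, 0.6), se_y = 0.1)
  fit <- mr_ivw(h, "fixed")
  expect_equal(fit$estimate, 1.8 / 6, tolerance = 1e-12)
  expect_equal(fit$se, 0.1 / sqrt(6), tolerance = 1e-12)
  expect_equal(fit$se, 0.0408, tolerance = 1e-3)
  # exact-fit data: zero heterogeneity
  hx <- harmonized_set(beta_x = c(1, 2, 3), se_x = 1e-4,
                       beta_y = 0.4 * c(1, 2, 3), se_y = 0.1)
  fx <- mr_ivw(hx)
  expect_equal(fx$estimate, 0.4, tolerance = 1e-12)
  expect_equal(fx$heterogeneity$Q, 0, tolerance = 1e-20)
  expect_equal(fx$heterogeneity$I2, 0)
})

test_that("random-effects scaling and the auto rule", {
  h <- sim_h(J = 40, theta = 0.4, se_y = 0.02, pleio_sd = 0.2, seed = 2)
  fixed <- mr_ivw(h, "fixed")
  rand <- mr_ivw(h, "random")
  expect_equal(rand$estimate, fixed$estimate)
  expect_equal(rand$se,
               fixed$se * max(1, sqrt(fixed$heterogeneity$Q / (40 - 1))))
  auto <- mr_ivw(h, "auto")
  hetero <- fixed$heterogeneity$p_Q < 0.05 && fixed$heterogeneity$I2 > 0.25
  expect_equal(auto$method, if (hetero) "ivw-random" else "ivw-fixed")
})

test_that("Q contributions add to Q, standard and radial", {
  h <- sim_h(J = 25, seed = 3, pleio_sd = 0.05)
  ivw <- mr_ivw(h)
  expect_equal(sum(ivw$q_contrib), ivw$heterogeneity$Q, tolerance = 1e-10)
  rad <- radial_ivw(h)
  expect_equal(sum(rad$q_contrib), rad$heterogeneity$Q, tolerance = 1e-10)
})

test_that("MR-Egger recovers an exact linear relation with intercept", {
  bx <- seq(0.1, 1, length.out = 8)
  h <- harmonized_set(beta_x = bx, se_x = 1e-4,
                      beta_y = 0.1 + 0.3 * bx, se_y = 0.1)
  fit <- mr_egger(h)
  expect_equal(fit$estimate, 0.3, tolerance = 1e-10)
  expect_equal(fit$egger_intercept$value, 0.1, tolerance = 1e-10)
  expect_equal(fit$heterogeneity$Q, 0, tolerance = 1e-18)
  expect_error(mr_egger(h[1:2, ]), "at least 3")
})

test_that("directional pleiotropy shows up in the Egger intercept", {
  h <- sim_h(J = 300, theta = 0.4, se_y = 0.01, pleio_mean = 0.05,
             pleio_sd = 0.01, seed = 5)
  fit <- mr_egger(h)
  expect_lt(abs(fit$egger_intercept$value - 0.05),
            4 * fit$egger_intercept$se)
  expect_lt(fit$egger_intercept$p, 0.05)
})

test_that("weighted median: hand cases and outlier resistance", {
  h3 <- harmonized_set(beta_x = c(1, 1, 1), se_x = 1e-4,
                       beta_y = c(1, 2, 3), se_y = 1)
  expect_equal(weighted_median_mr(h3, n_boot = 50)$estimate, 2)
  # one gross outlier among 20 concordant SNPs
  set.seed(6)
  bx <- runif(20, 0.2, 0.5)
  by <- 0.4 * bx
  by[20] <- 0.4 * bx[20] + 1.5
  h <- harmonized_set(beta_x = bx, se_x = 0.01, beta_y = by, se_y = 0.05)
  wm <- weighted_median_mr(h, seed = 1)
  ivw <- mr_ivw(h, "fixed")
  expect_lt(abs(wm$estimate - 0.4), 2 * wm$se)
  expect_gt(abs(ivw$estimate - 0.4), abs(wm$estimate - 0.4))
  # penalized variant shrinks the outlier's influence further
  pwm <- weighted_median_mr(h, penalized = TRUE, seed = 1)
  expect_lt(abs(pwm$estimate - 0.4), 2 * pwm$se)
  # bootstrap SE is reproducible given the seed
  expect_identical(weighted_median_mr(h, seed = 9)$se,
                   weighted_median_mr(h, seed = 9)$se)
})

test_that("likelihood-based MR: IVW limit and exact fit", {
  h <- harmonized_set(beta_x = c(1, 1, 2), se_x = 1e-8,
                      beta_y = c(0.2, 0.4, 0.6), se_y = 0.1)
  ml <- max_likelihood_mr(h)
  ivw <- mr_ivw(h, "fixed")
  expect_lt(abs(ml$estimate - ivw$estimate), 1e-6)
  hx <- harmonized_set(beta_x = c(1, 2, 3), se_x = 0.05,
                       beta_y = 0.4 * c(1, 2, 3), se_y = 0.1)
  expect_equal(max_likelihood_mr(hx)$estimate, 0.4, tolerance = 1e-6)
})

test_that("radial IVW is algebraically first-order IVW", {
  for (s in 1:5) {
    h <- sim_h(J = 20, seed = s, pleio_sd = 0.03)
    expect_lt(abs(radial_ivw(h)$estimate - mr_ivw(h, "fixed")$estimate),
              1e-10)
  }
  # an injected outlier owns the largest radial Q contribution
  h <- sim_h(J = 20, seed = 9, se_y = 0.02)
  h$beta_y[7] <- h$beta_y[7] + 10 * h$se_y[7]
  rad <- radial_ivw(h)
  expect_equal(unname(which.max(rad$q_contrib)), 7L)
})

test_that("leave-one-out returns J+1 rows and isolates an outlier", {
  h <- sim_h(J = 12, seed = 10, se_y = 0.02)
  loo <- leave_one_out(h)
  expect_equal(nrow(loo), 13L)
  expect_equal(loo$snp[13], "(all)")
  # homogeneous data: all estimates agree closely
  expect_lt(diff(range(loo$estimate)), 6 * loo$se[13])
  h$beta_y[4] <- h$beta_y[4] + 12 * h$se_y[4]
  loo2 <- leave_one_out(h)
  all_est <- loo2$estimate[13]
  dev <- abs(loo2$estimate[1:12] - all_est)
  expect_equal(which.max(dev), 4L)
})

test_that("MR-PRESSO: consistency, sensitivity, and seeding", {
  h <- sim_h(J = 20, seed = 11, se_y = 0.02)
  h$beta_y[5] <- h$beta_y[5] + 10 * h$se_y[5]
  pr <- mr_presso(h, nb_sim = 1000, seed = 3)
  expect_true("snp005" %in% pr$outlier_snp_ids)
  keep <- !(h$snp %in% pr$outlier_snp_ids)
  expect_equal(pr$estimate_after,
               mr_ivw(h[keep, , drop = FALSE], "fixed")$estimate,
               tolerance = 1e-12)
  expect_lt(pr$global_rss_p, 0.05)
  # bit-reproducible given the seed
  pr2 <- mr_presso(h, nb_sim = 1000, seed = 3)
  expect_identical(pr$global_rss_p, pr2$global_rss_p)
  expect_identical(pr$outlier_snp_ids, pr2$outlier_snp_ids)
  expect_error(mr_presso(h, nb_sim = 50), "at least 100")
  expect_error(mr_presso(h[1:3, ]), "at least 4")
})

test_that("SIMEX: no dilution means no correction; I2_GX is reported", {
  h <- harmonized_set(beta_x = seq(0.2, 1, length.out = 10), se_x = 0,
                      beta_y = 0.1 + 0.3 * seq(0.2, 1, length.out = 10),
                      se_y = 0.1)
  sx <- egger_simex(h, B = 20, seed = 1)
  naive <- mr_egger(h)
  expect_equal(sx$estimate, naive$estimate)
  expect_equal(sx$I2_GX, 1)
  h2 <- sim_h(J = 30, seed = 12, se_x = 0.1, se_y = 0.05)
  sx2 <- egger_simex(h2, B = 30, seed = 2)
  expect_true(sx2$I2_GX >= 0 && sx2$I2_GX <= 1)
  expect_identical(egger_simex(h2, B = 30, seed = 2)$estimate, sx2$estimate)
})

test_that("scale equivariance and orientation invariance", {
  h <- sim_h(J = 15, seed = 13, pleio_sd = 0.02)
  c_ <- 2.5
  hc <- h; hc$beta_y <- c_ * h$beta_y; hc$se_y <- c_ * h$se_y
  for (f in list(function(x) mr_ivw(x, "fixed"), mr_egger, radial_ivw)) {
    f1 <- f(h); f2 <- f(hc)
    expect_equal(f2$estimate, c_ * f1$estimate, tolerance = 1e-10)
    expect_equal(f2$se, c_ * f1$se, tolerance = 1e-10)
  }
  ml1 <- max_likelihood_mr(h); ml2 <- max_likelihood_mr(hc)
  expect_equal(ml2$estimate, c_ * ml1$estimate, tolerance = 1e-5)
  expect_equal(ml2$se, c_ * ml1$se, tolerance = 1e-3)
  # flipping any SNP's joint orientation leaves estimates unchanged
  set.seed(1)
  flip <- sample(c(1, -1), 15, replace = TRUE)
  hf <- h; hf$beta_x <- flip * h$beta_x; hf$beta_y <- flip * h$beta_y
  expect_equal(mr_ivw(hf, "fixed")$estimate, mr_ivw(h, "fixed")$estimate,
               tolerance = 1e-12)
  expect_equal(radial_ivw(hf)$estimate, radial_ivw(h)$estimate,
               tolerance = 1e-12)
  expect_equal(max_likelihood_mr(hf)$estimate,
               max_likelihood_mr(h)$estimate, tolerance = 1e-8)
  expect_equal(weighted_median_mr(hf, seed = 5)$estimate,
               weighted_median_mr(h, seed = 5)$estimate, tolerance = 1e-12)
})
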