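test_that("mediate: null path, accounting identity, scale invariance", {
  m0 <- mediate(0, 0.01, 0.4, 0.05, -0.4, 0.05)
  expect_equal(m0$indirect$estimate, 0)
  expect_equal(m0$direct$estimate, -0.4)
  expect_equal(m0$proportion$estimate, 0)
  set.seed(2)
  for (i in 1:25) {
    a <- rnorm(1); b <- rnorm(1); cc <- rnorm(1)
    if (cc == 0) next
    m <- mediate(a, 0.05, b, 0.05, cc, 0.05)
    expect_equal(m$direct$estimate + m$indirect$estimate, cc,
                 tolerance = 1e-15)
    expect_equal(m$proportion$estimate * cc, m$indirect$estimate,
                 tolerance = 1e-12)
    # rescaling the mediator's units leaves indirect and proportion fixed
    k <- runif(1, 0.5, 3)
    mk <- mediate(a * k, 0.05 * k, b / k, 0.05 / k, cc, 0.05)
    expect_equal(mk$indirect$estimate, m$indirect$estimate,
                 tolerance = 1e-12)
    expect_equal(mk$proportion$estimate, m$proportion$estimate,
                 tolerance = 1e-12)
  }
})

test_that("zero total effect leaves the proportion undefined with a note", {
  m <- mediate(0.1, 0.02, 0.2, 0.02, 0, 0.05)
  expect_true(is.na(m$proportion$estimate))
  expect_match(m$proportion$note, "zero")
  expect_equal(m$direct$estimate, -m$indirect$estimate)
})

test_that("first- and second-order product variances are ordered", {
  m1 <- mediate(-0.2, 0.05, 0.3, 0.04, -0.4, 0.05)
  m2 <- mediate(-0.2, 0.05, 0.3, 0.04, -0.4, 0.05, product_var = "second")
  expect_equal(m2$indirect$se^2 - m1$indirect$se^2, 0.05^2 * 0.04^2,
               tolerance = 1e-12)
  expect_gt(m2$indirect$se, m1$indirect$se)
})

test_that("proportion CI conventions: scaled indirect vs delta ratio", {
  m <- mediate(-0.232, se_from_ci(-0.321, -0.143),
               0.102, se_from_ci(0.069, 0.134),
               -0.473, se_from_ci(-0.546, -0.400))
  # scaled-indirect: bounds are the indirect CI divided by beta_c
  expect_equal(m$proportion$ci_low, m$indirect$ci_high / -0.473,
               tolerance = 1e-12)
  md <- mediate(-0.232, se_from_ci(-0.321, -0.143),
                0.102, se_from_ci(0.069, 0.134),
                -0.473, se_from_ci(-0.546, -0.400),
                prop_var = "delta-ratio")
  expect_equal(md$proportion$se, md$proportion_se_delta)
  expect_gt(md$proportion$se, 0)
  # both conventions share the point estimate
  expect_equal(md$proportion$estimate, m$proportion$estimate)
})

test_that("two-step mediation recovers a synthetic truth end to end", {
  tr <- sim_truth(J = 60, n_per_trait = 8000, palindromic_frac = 0,
                  seed = 17)
  tabs <- simulate_two_sample(tr)
  res <- two_step_mediation(tabs$exposure, tabs$mediator, tabs$outcome)
  expect_lt(abs(res$beta_c - tr$theta_total), 4 * res$se_c)
  expect_lt(abs(res$beta_a - tr$alpha), 4 * res$se_a)
  expect_lt(abs(res$beta_b - tr$beta_m), 4 * res$se_b)
  expect_equal(res$direct$estimate + res$indirect$estimate, res$beta_c,
               tolerance = 1e-12)
  expect_s3_class(res$stages$mvmr, "mvmr_result")
})

test_that("stage failures are tagged with the stage name", {
  tr <- sim_truth(J = 20, n_per_trait = 1000, seed = 19)
  tabs <- simulate_two_sample(tr)
  other <- summary_stats(data.frame(
    snp = "zz1", effect_allele = "A", other_allele = "G", beta = 1,
    se = 0.01, eaf = 0.3, n = 100, stringsAsFactors = FALSE),
    trait_id = "unrelated")
  expect_error(
    suppressWarnings(two_step_mediation(tabs$exposure, tabs$mediator, other)),
    "total-effect")
})

test_that("combined mediation with one mediator equals the two-step result", {
  tr <- sim_truth(J = 50, n_per_trait = 6000, palindromic_frac = 0,
                  seed = 23)
  tabs <- simulate_two_sample(tr)
  single <- two_step_mediation(tabs$exposure, tabs$mediator, tabs$outcome)
  comb <- combined_mediation(tabs$exposure, list(tabs$mediator),
                             tabs$outcome)
  expect_equal(comb$combined_indirect$estimate, single$indirect$estimate,
               tolerance = 1e-10)
  expect_equal(comb$combined_proportion$estimate,
               single$proportion$estimate, tolerance = 1e-10)
  expect_equal(comb$beta_c, single$beta_c, tolerance = 1e-12)
})

test_that("a duplicated mediator trips the collinearity guard", {
  tr <- sim_truth(J = 40, n_per_trait = 4000, palindromic_frac = 0,
                  seed = 29)
  tabs <- simulate_two_sample(tr)
  m2 <- tabs$mediator
  attr(m2, "trait_id") <- "mediator-copy"
  expect_error(
    combined_mediation(tabs$exposure, list(tabs$mediator, m2),
                       tabs$outcome),
    "collinear")
})
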