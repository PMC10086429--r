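mk_stats <- function(snp, pval, chrom = NULL, pos = NULL) {
  summary_stats(data.frame(
    snp = snp, effect_allele = "A", other_allele = "G",
    beta = 0.1, se = 0.1 / sqrt(qchisq(pval, 1, lower.tail = FALSE)),
    pval = pval, eaf = 0.3, n = 1e5, stringsAsFactors = FALSE),
    trait_id = "x", validate = FALSE)
}

test_that("p-value thresholding retains exactly the passing SNPs, ordered", {
  ss <- mk_stats(c("a", "b", "c"), c(1e-9, 1e-6, 0.2))
  expect_equal(select_by_pvalue(ss, 5e-8)$snp_ids, "a")
  expect_equal(select_by_pvalue(ss, 5e-5)$snp_ids, c("a", "b"))
  expect_warning(out <- select_by_pvalue(ss, 1e-12), "no SNPs")
  expect_length(out$snp_ids, 0)
})

test_that("null SNPs pass the relaxed threshold at the binomial rate", {
  # 2000 uniform p-values: expected passes at 5e-5 is 0.1
  set.seed(1)
  counts <- vapply(1:50, function(i) {
    ss <- mk_stats(sprintf("s%04d", 1:2000), runif(2000))
    length(suppressWarnings(select_by_pvalue(ss, 5e-5))$snp_ids)
  }, numeric(1))
  expect_lt(mean(counts), 0.5)  # mean ~ 0.1, generous ceiling
})

test_that("greedy clumping keeps the lowest-p SNP of a linked pair", {
  ss <- mk_stats(c("a", "b"), c(1e-10, 1e-8))
  ld_hi <- toy_ld(c("a", "b"), matrix(c(1, .9, .9, 1), 2))
  ld_lo <- toy_ld(c("a", "b"), matrix(c(1, 5e-4, 5e-4, 1), 2))
  cand <- select_by_pvalue(ss, 1e-4)
  expect_equal(ld_clump(cand, ss, ld_hi)$snp_ids, "a")
  expect_equal(sort(ld_clump(cand, ss, ld_lo)$snp_ids), c("a", "b"))
})

test_that("clumping matches an independently coded greedy oracle", {
  # oracle: scan SNPs by ascending p, keep one iff compatible with all kept
  oracle <- function(ids, p, ld, r2_max, window_kb) {
    ord <- order(p, ids)
    kept <- character(0)
    for (s in ids[ord]) {
      ok <- TRUE
      for (k in kept) {
        same <- ld$chrom[match(s, ld$snp_ids)] == ld$chrom[match(k, ld$snp_ids)]
        close <- abs(ld$positions[match(s, ld$snp_ids)] -
                       ld$positions[match(k, ld$snp_ids)]) <= window_kb * 1000
        if (same && close && ld$r2[s, k] >= r2_max) ok <- FALSE
      }
      if (ok) kept <- c(kept, s)
    }
    kept
  }
  set.seed(7)
  for (rep in 1:20) {
    n <- 5
    ids <- letters[1:n]
    p <- runif(n, 1e-12, 1e-6)
    m <- matrix(runif(n * n), n)
    m <- (m + t(m)) / 2 * 0.5
    diag(m) <- 1
    ld <- toy_ld(ids, m)
    ss <- mk_stats(ids, p)
    got <- ld_clump(select_by_pvalue(ss, 1e-4), ss, ld, r2_max = 0.1)
    expect_equal(sort(got$snp_ids), sort(oracle(ids, p, ld, 0.1, 10000)))
    # idempotence
    again <- ld_clump(got, ss, ld, r2_max = 0.1)
    expect_equal(again$snp_ids, got$snp_ids)
    # no violating pair survives
    for (i in got$snp_ids) for (j in got$snp_ids) {
      if (i != j) expect_lt(ld$r2[i, j], 0.1)
    }
  }
})

test_that("SNPs outside the distance window or LD panel are kept", {
  ss <- mk_stats(c("a", "b"), c(1e-10, 1e-8))
  far <- toy_ld(c("a", "b"), matrix(c(1, .9, .9, 1), 2),
                pos = c(0, 2e7))  # 20,000 kb apart
  expect_equal(sort(ld_clump(select_by_pvalue(ss, 1e-4), ss, far)$snp_ids),
               c("a", "b"))
  panel_missing <- toy_ld("a", matrix(1, 1, 1))
  expect_equal(sort(ld_clump(select_by_pvalue(ss, 1e-4), ss,
                             panel_missing)$snp_ids),
               c("a", "b"))
})

test_that("proxy lookup returns the best qualifying proxy in the outcome", {
  outcome <- mk_stats(c("p1", "p2"), c(0.5, 0.5))
  tab <- data.frame(target_snp = c("s1", "s1"), proxy_snp = c("p1", "p2"),
                    r2 = c(0.95, 0.85))
  expect_equal(find_proxy("s1", tab, outcome), "p1")
  outcome2 <- mk_stats("p2", 0.5)
  expect_equal(find_proxy("s1", tab, outcome2), "p2")
  weak <- data.frame(target_snp = "s1", proxy_snp = "p1", r2 = 0.7)
  expect_true(is.na(find_proxy("s1", weak, outcome)))
})

test_that("instrument strength reports F and both R-squared formulas", {
  ss <- summary_stats(data.frame(
    snp = c("a", "b"), effect_allele = "A", other_allele = "G",
    beta = 0.1, se = 0.02, eaf = c(0.5, NA), n = 293723,
    stringsAsFactors = FALSE), trait_id = "x", validate = FALSE)
  iv <- select_by_pvalue(ss, 1e-4)   # both SNPs pass (z = 5)
  iv$snp_ids <- c("a", "b")
  st <- instrument_strength(ss, iv)
  expect_equal(st$per_snp$f, c(25, 25))
  expect_equal(st$per_snp$r2_af[1], 2 * 0.5 * 0.5 * 0.01)
  expect_equal(st$per_snp$r2_f[2], 25 / (25 + 293723 - 2), tolerance = 1e-10)
  expect_equal(st$per_snp$r2_f[2], 8.51e-5, tolerance = 1e-3)
  expect_false(any(st$per_snp$weak))
  expect_equal(st$total_r2, st$per_snp$r2_af[1] + st$per_snp$r2_f[2])
})

test_that("exclusion lists drop SNPs before clumping with provenance", {
  ss <- mk_stats(c("a", "b", "c"), c(1e-9, 1e-8, 1e-7))
  iv <- select_by_pvalue(ss, 1e-4)
  out <- apply_exclusions(iv, c("b"))
  expect_equal(out$snp_ids, c("a", "c"))
  expect_equal(attr(out, "dropped"), "b")
})
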