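# Shared fixture builders.  All randomness is seeded at the call site.

# small well-formed summary table
toy_sumstats <- function(trait = "x") {
  summary_stats(data.frame(
    snp = c("rs1", "rs2", "rs3"),
    effect_allele = c("A", "C", "G"),
    other_allele = c("G", "T", "A"),
    beta = c(0.10, -0.05, 0.02),
    se = c(0.02, 0.01, 0.015),
    pval = c(2 * pnorm(-5), 2 * pnorm(-5), 2 * pnorm(-4 / 3)),
    eaf = c(0.30, 0.55, NA),
    n = 10000,
    stringsAsFactors = FALSE), trait_id = trait)
}

# summary-level simulated harmonized set: J SNPs with true slope theta,
# optional per-SNP pleiotropic intercepts alpha_j
sim_h <- function(J = 30, theta = 0.4, se_x = 0.02, se_y = 0.05,
                  pleio_mean = 0, pleio_sd = 0, seed = 1) {
  set.seed(seed)
  # positive instrument effects: directional pleiotropy is defined relative
  # to the oriented exposure effect, so mixed signs would cancel it
  xi <- runif(J, 0.1, 0.5)
  alpha <- if (pleio_sd > 0 || pleio_mean != 0) {
    rnorm(J, pleio_mean, pleio_sd)
  } else rep(0, J)
  bx <- rnorm(J, xi, se_x)
  by <- rnorm(J, theta * xi + alpha, se_y)
  harmonized_set(beta_x = bx, se_x = rep(se_x, J),
                 beta_y = by, se_y = rep(se_y, J))
}

# deterministic LD panel over a given set of SNPs
toy_ld <- function(snp_ids, r2_mat, pos = NULL, chrom = NULL) {
  n <- length(snp_ids)
  if (is.null(pos)) pos <- seq_len(n) * 1000
  if (is.null(chrom)) chrom <- rep("1", n)
  ld_info(snp_ids, r2_mat, pos, chrom)
}

expect_close <- function(x, y, tol) expect_lt(max(abs(x - y)), tol)
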