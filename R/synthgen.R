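# Synthetic GWAS generator: a linear structural model with known mediation
# structure (exposure X -> mediator M -> outcome Y, plus a direct X -> Y path
# and an optional shared confounder), from which two-sample summary statistics
# are computed on disjoint subsamples.

#' Run code with a temporary RNG seed
#'
#' Evaluates `code` after `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package internals never perturb user-level
#' reproducibility.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# deterministic sub-seed derivation, kept below 2^31 - 1
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483629 + 1)
}

#' Define the generating truth of a synthetic mediation dataset
#'
#' The structural model is linear with no interactions:
#' \deqn{X = G\gamma + cU + \epsilon_x}
#' \deqn{M = \alpha X + G\kappa + cU + \epsilon_m}
#' \deqn{Y = \theta_d X + \beta_m M + G\pi + cU + \epsilon_y}
#' with genotypes `G` (dosages 0/1/2), standard-normal noise and confounder
#' `U`.  The true total effect of X on Y is `theta_d + alpha * beta_m` and the
#' true proportion mediated is `alpha * beta_m / theta_total`.
#'
#' Defaults describe a scaled-down but well-powered two-sample setting: 100
#' SNPs of which half are direct instruments for the exposure and half for the
#' mediator, each explaining about `per_snp_r2` (1\%) of its trait's variance
#' so that discovery at `p < 5e-5` on `n = 20,000` individuals carries
#' negligible winner's-curse attenuation; minor-allele frequencies uniform on
#' (0.1, 0.5); no pleiotropy (`pi = 0`); modest shared confounding; 20\% of
#' SNPs assigned palindromic (A/T or C/G) allele pairs and half of the outcome
#' rows emitted with swapped allele labels so that harmonization is exercised.
#'
#' @param J number of SNPs.
#' @param n_per_trait GWAS sample size per trait (disjoint subsamples).
#' @param alpha effect of exposure on mediator.
#' @param beta_m effect of mediator on outcome.
#' @param theta_d direct effect of exposure on outcome.
#' @param per_snp_r2 variance of its trait explained by each direct instrument.
#' @param exposure_frac fraction of SNPs that are exposure instruments (the
#'   rest are mediator instruments).
#' @param pi_mean,pi_sd mean and SD of per-SNP direct (pleiotropic) effects on
#'   the outcome; both 0 disables pleiotropy.
#' @param confounder_load loading `c` of the shared confounder on all traits.
#' @param maf optional vector of minor-allele frequencies (drawn if `NULL`).
#' @param gamma,kappa,pi optional explicit per-SNP effect vectors overriding
#'   the defaults derived from `per_snp_r2`.
#' @param palindromic_frac fraction of SNPs given A/T or C/G alleles.
#' @param flip_frac fraction of outcome rows emitted with swapped allele
#'   labels (and correspondingly negated betas).
#' @param ld_blocks optional list with elements `size` and `r2`: SNPs are
#'   grouped into consecutive blocks of `size` with constant pairwise LD `r2`.
#'   `NULL` means all SNPs independent.
#' @param overlap_frac fraction of the outcome subsample shared with the
#'   exposure subsample (0 = strict two-sample design).
#' @param binary_outcome emit a case-control outcome by thresholding a
#'   logistic liability instead of the continuous Y.
#' @param seed integer seed fixing every random choice, including the
#'   dataset-level allele assignments and flips.
#' @return A `sim_truth` list with all realized parameter vectors plus
#'   `theta_total` and `prop_mediated`.
#' @export
sim_truth <- function(J = 100L, n_per_trait = 20000L,
                      alpha = -0.17, beta_m = 0.41, theta_d = -0.37,
                      per_snp_r2 = 0.01, exposure_frac = 0.5,
                      pi_mean = 0, pi_sd = 0, confounder_load = 0.3,
                      maf = NULL, gamma = NULL, kappa = NULL, pi = NULL,
                      palindromic_frac = 0.2, flip_frac = 0.5,
                      ld_blocks = NULL, overlap_frac = 0,
                      binary_outcome = FALSE, seed = 1L) {
  if (J <= 0 || n_per_trait <= 0) {
    stop("J and n_per_trait must be positive", call. = FALSE)
  }
  stopifnot(is.finite(alpha), is.finite(beta_m), is.finite(theta_d))
  with_seed(derive_seed(seed, 1L), {
    if (is.null(maf)) maf <- stats::runif(J, 0.1, 0.5)
    if (any(maf <= 0 | maf > 0.5)) stop("maf must lie in (0, 0.5]",
                                        call. = FALSE)
    n_exp <- round(J * exposure_frac)
    exposure_snps <- seq_len(n_exp)
    mediator_snps <- setdiff(seq_len(J), exposure_snps)
    # normally distributed per-SNP effects (mean explained variance
    # per_snp_r2): GWAS effect sizes are dispersed, and a spread of
    # instrument strengths keeps the Egger design well conditioned
    if (is.null(gamma)) {
      gamma <- numeric(J)
      gamma[exposure_snps] <- stats::rnorm(n_exp) *
        sqrt(per_snp_r2 / (2 * maf[exposure_snps] * (1 - maf[exposure_snps])))
    }
    if (is.null(kappa)) {
      kappa <- numeric(J)
      kappa[mediator_snps] <- stats::rnorm(length(mediator_snps)) *
        sqrt(per_snp_r2 / (2 * maf[mediator_snps] * (1 - maf[mediator_snps])))
    }
    if (is.null(pi)) {
      pi <- if (pi_sd > 0 || pi_mean != 0) {
        stats::rnorm(J, pi_mean, pi_sd)
      } else numeric(J)
    }
    # allele assignment: palindromic SNPs get A/T or C/G pairs
    n_pal <- round(J * palindromic_frac)
    pal_idx <- if (n_pal > 0) sort(sample.int(J, n_pal)) else integer(0)
    a1 <- a2 <- character(J)
    pal_pairs <- list(c("A", "T"), c("C", "G"))
    npal_pairs <- list(c("A", "G"), c("A", "C"), c("C", "T"), c("G", "T"))
    for (j in seq_len(J)) {
      pair <- if (j %in% pal_idx) pal_pairs[[sample.int(2L, 1L)]]
      else npal_pairs[[sample.int(4L, 1L)]]
      if (stats::runif(1) < 0.5) pair <- rev(pair)
      a1[j] <- pair[1]; a2[j] <- pair[2]
    }
    n_flip <- round(J * flip_frac)
    flip_idx <- if (n_flip > 0) sort(sample.int(J, n_flip)) else integer(0)
    snp_ids <- sprintf("rs%05d", seq_len(J))
    # genomic coordinates: blocks are contiguous and close; distinct blocks
    # are placed far apart so the clumping window separates them
    if (is.null(ld_blocks)) {
      block_id <- seq_len(J)
      block_r2 <- 0
    } else {
      block_id <- rep(seq_len(ceiling(J / ld_blocks$size)),
                      each = ld_blocks$size)[seq_len(J)]
      block_r2 <- ld_blocks$r2
    }
    pos <- block_id * 2e7 + stats::ave(rep(1, J), block_id, FUN = seq_along) *
      1000
    truth <- list(
      J = as.integer(J), n_per_trait = as.integer(n_per_trait),
      alpha = alpha, beta_m = beta_m, theta_d = theta_d,
      gamma = gamma, kappa = kappa, pi = pi,
      confounder_load = confounder_load, maf = maf,
      snp_ids = snp_ids, effect_allele = a1, other_allele = a2,
      palindromic_snps = snp_ids[pal_idx], flip_snps = snp_ids[flip_idx],
      palindromic_frac = palindromic_frac, flip_frac = flip_frac,
      block_id = block_id, block_r2 = block_r2,
      positions = pos, chrom = rep("1", J),
      overlap_frac = overlap_frac, binary_outcome = binary_outcome,
      theta_total = theta_d + alpha * beta_m,
      prop_mediated = if (theta_d + alpha * beta_m != 0) {
        alpha * beta_m / (theta_d + alpha * beta_m)
      } else NA_real_,
      seed = as.integer(seed))
    class(truth) <- "sim_truth"
    truth
  })
}

# latent-normal haplotype draw: one binary allele indicator per haplotype,
# with within-block correlation of the latent normals inducing LD
draw_genotypes <- function(n, truth) {
  J <- truth$J
  g <- matrix(0L, n, J)
  for (b in unique(truth$block_id)) {
    idx <- which(truth$block_id == b)
    k <- length(idx)
    for (hap in 1:2) {
      if (k == 1L || truth$block_r2 <= 0) {
        z <- matrix(stats::rnorm(n * k), n, k)
      } else {
        r <- sqrt(truth$block_r2)        # latent correlation, nominal
        shared <- stats::rnorm(n)
        z <- sqrt(r) * matrix(shared, n, k) +
          sqrt(1 - r) * matrix(stats::rnorm(n * k), n, k)
      }
      thr <- stats::qnorm(truth$maf[idx])
      g[, idx] <- g[, idx] + (z < matrix(thr, n, k, byrow = TRUE))
    }
  }
  colnames(g) <- truth$snp_ids
  g
}

#' Simulate an individual-level cohort under a `sim_truth`
#'
#' Draws genotypes (dosages 0/1/2, allele frequency `maf`, within-block LD via
#' a latent-normal copula) and generates exposure, mediator and outcome traits
#' under the linear structural model of [sim_truth()].
#'
#' @param truth a [sim_truth()] object.
#' @param n_total total number of individuals; defaults to
#'   `3 * n_per_trait` so three disjoint GWAS subsamples are available.
#' @param seed RNG seed; defaults to a sub-seed derived from `truth$seed`.
#' @return List with matrix `G` and vectors `X`, `M`, `Y` (and `Y_bin` when
#'   `truth$binary_outcome`), plus the seed used.
#' @export
simulate_cohort <- function(truth, n_total = 3L * truth$n_per_trait,
                            seed = derive_seed(truth$seed, 2L)) {
  stopifnot(inherits(truth, "sim_truth"))
  if (n_total <= 0) stop("n_total must be positive", call. = FALSE)
  with_seed(seed, {
    n <- n_total
    G <- draw_genotypes(n, truth)
    U <- stats::rnorm(n)
    c_ <- truth$confounder_load
    X <- drop(G %*% truth$gamma) + c_ * U + stats::rnorm(n)
    M <- truth$alpha * X + drop(G %*% truth$kappa) + c_ * U + stats::rnorm(n)
    Y <- truth$theta_d * X + truth$beta_m * M + drop(G %*% truth$pi) +
      c_ * U + stats::rnorm(n)
    out <- list(G = G, X = X, M = M, Y = Y, seed = seed)
    if (isTRUE(truth$binary_outcome)) {
      # logistic liability: Y acts as the linear predictor around its mean
      p <- stats::plogis(Y - mean(Y))
      out$Y_bin <- stats::rbinom(n, 1L, p)
    }
    out
  })
}

#' Per-SNP GWAS on a simulated cohort
#'
#' Simple linear regression of the trait on each SNP's dosage over the given
#' subsample, yielding a [summary_stats()] table (beta, se, two-sided p,
#' effect-allele frequency, n).  Monomorphic SNPs in the subsample are dropped
#' with a warning.
#'
#' @param cohort result of [simulate_cohort()].
#' @param truth the generating [sim_truth()] (provides allele labels).
#' @param trait one of `"X"`, `"M"`, `"Y"` (or `"Y_bin"`).
#' @param subsample integer indices of the individuals to use.
#' @param trait_id label for the resulting table.
#' @return A [summary_stats()] object.
#' @export
compute_gwas_summary <- function(cohort, truth, trait = c("X", "M", "Y",
                                                          "Y_bin"),
                                 subsample, trait_id = NULL) {
  trait <- match.arg(trait)
  if (length(subsample) == 0L) stop("empty subsample", call. = FALSE)
  if (is.null(trait_id)) trait_id <- trait
  g <- cohort$G[subsample, , drop = FALSE]
  y <- cohort[[trait]][subsample]
  n <- length(y)
  gbar <- colMeans(g)
  gc_ <- sweep(g, 2L, gbar)
  yc <- y - mean(y)
  sxx <- colSums(gc_^2)
  sxy <- drop(crossprod(gc_, yc))
  keep <- sxx > 0
  if (!all(keep)) {
    warning("dropping monomorphic SNP(s) in subsample: ",
            paste(truth$snp_ids[!keep], collapse = ", "), call. = FALSE)
  }
  beta <- sxy[keep] / sxx[keep]
  syy <- sum(yc^2)
  sse <- pmax(syy - beta * sxy[keep], 0)
  se <- sqrt(sse / ((n - 2) * sxx[keep]))
  # normal rather than t reference: GWAS summary exports report the
  # Wald/normal p, and at these n the difference only shows in deep tails
  pval <- 2 * stats::pnorm(-abs(beta / se))
  summary_stats(data.frame(
    snp = truth$snp_ids[keep],
    effect_allele = truth$effect_allele[keep],
    other_allele = truth$other_allele[keep],
    beta = beta, se = se, pval = pval,
    eaf = gbar[keep] / 2, n = n,
    stringsAsFactors = FALSE), trait_id = trait_id)
}

# swap allele labels on selected rows of a summary table (the emitted beta
# then refers to the former other allele: negate beta, complement eaf)
apply_label_flips <- function(ss, flip_snps) {
  i <- ss$snp %in% flip_snps
  ea <- ss$effect_allele[i]
  ss$effect_allele[i] <- ss$other_allele[i]
  ss$other_allele[i] <- ea
  ss$beta[i] <- -ss$beta[i]
  ss$eaf[i] <- 1 - ss$eaf[i]
  ss
}

# stated (nominal) LD matrix of a truth: block-diagonal constant r2
truth_ld <- function(truth) {
  r2 <- outer(truth$block_id, truth$block_id,
              function(a, b) ifelse(a == b, truth$block_r2, 0))
  diag(r2) <- 1
  ld_info(truth$snp_ids, r2, truth$positions, truth$chrom)
}

#' Generate a complete two-sample GWAS file bundle
#'
#' Simulates a cohort, computes exposure/mediator/outcome GWAS on disjoint
#' subsamples (unless `overlap_frac > 0`), applies the truth's allele-label
#' flips to the outcome table and writes the full bundle: three summary TSVs,
#' an LD matrix, a proxy table (within-block pairs), and the truth as JSON.
#' The bundle is byte-identical across calls with the same truth.
#'
#' @param truth a [sim_truth()] object.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory tables and the file paths.
#' @export
make_dataset <- function(truth, out_dir) {
  stopifnot(inherits(truth, "sim_truth"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- simulate_two_sample(truth)
  out_tab <- apply_label_flips(tabs$outcome, truth$flip_snps)
  ld <- truth_ld(truth)
  # proxy table: within-block partners (excluding self), best-r2 first
  prox <- do.call(rbind, lapply(unique(truth$block_id), function(b) {
    idx <- which(truth$block_id == b)
    if (length(idx) < 2L) return(NULL)
    pairs <- expand.grid(target_snp = truth$snp_ids[idx],
                         proxy_snp = truth$snp_ids[idx],
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$target_snp != pairs$proxy_snp, ]
    pairs$r2 <- truth$block_r2
    pairs
  }))
  if (is.null(prox)) {
    prox <- data.frame(target_snp = character(0), proxy_snp = character(0),
                       r2 = numeric(0))
  }
  paths <- list(
    exposure = file.path(out_dir, "exposure.tsv"),
    mediator = file.path(out_dir, "mediator.tsv"),
    outcome = file.path(out_dir, "outcome.tsv"),
    ld = file.path(out_dir, "ld_matrix.tsv"),
    proxies = file.path(out_dir, "proxies.tsv"),
    truth = file.path(out_dir, "truth.json"))
  write_summary_stats(tabs$exposure, paths$exposure)
  write_summary_stats(tabs$mediator, paths$mediator)
  write_summary_stats(out_tab, paths$outcome)
  write_ld_matrix(ld, paths$ld)
  utils::write.table(prox, paths$proxies, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(unclass(truth), paths$truth, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(exposure = tabs$exposure, mediator = tabs$mediator,
                 outcome = out_tab, outcome_unflipped = tabs$outcome,
                 ld = ld, proxies = prox, truth = truth, paths = paths))
}

#' Two-sample summary tables for a truth (no file output)
#'
#' Convenience wrapper: simulates the cohort and returns exposure, mediator
#' and outcome [summary_stats()] computed on disjoint subsamples (overlap
#' between exposure and outcome samples controlled by `truth$overlap_frac`).
#' Allele labels are left unflipped; see [make_dataset()] for the full bundle.
#'
#' @param truth a [sim_truth()] object.
#' @return List of three `summary_stats` tables.
#' @export
simulate_two_sample <- function(truth) {
  n <- truth$n_per_trait
  cohort <- simulate_cohort(truth)
  idx_x <- seq_len(n)
  idx_m <- n + seq_len(n)
  n_overlap <- floor(truth$overlap_frac * n)
  idx_y <- c(seq_len(n_overlap), 2L * n + seq_len(n - n_overlap))
  ytrait <- if (isTRUE(truth$binary_outcome)) "Y_bin" else "Y"
  list(exposure = compute_gwas_summary(cohort, truth, "X", idx_x, "exposure"),
       mediator = compute_gwas_summary(cohort, truth, "M", idx_m, "mediator"),
       outcome = compute_gwas_summary(cohort, truth, ytrait, idx_y, "outcome"))
}
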