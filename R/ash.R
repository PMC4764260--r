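# Joint genotyping and allele-specific hypersensitivity (ASH) from
# allelic read counts.  Per sample, a sequencing error rate eps and a
# beta-binomial concentration M (large M = little overdispersion) are
# estimated by maximising the marginal likelihood over latent genotypes
# with Hardy-Weinberg priors; heterozygous sites are then tested for
# allelic imbalance with a beta-binomial likelihood-ratio test of
# rho = 0.5.

#' Beta-binomial mass
#'
#' Mean parameterisation: `prob` is the expected success fraction and `M`
#' the concentration (`alpha = prob * M`, `beta = (1 - prob) * M`).
#'
#' @param k,n successes and trials.
#' @param prob mean success probability in (0, 1).
#' @param M concentration > 0.
#' @param log return log mass?
#' @return (log) probability mass.
#' @export
dbetabinom <- function(k, n, prob, M, log = FALSE) {
  a <- prob * M
  b <- (1 - prob) * M
  out <- lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b)
  if (log) out else exp(out)
}

# Per-genotype log-likelihoods of the reference read count.
# RR: Binom(n, 1 - eps); AA: Binom(n, eps); RA: BetaBinom(n, 1/2, M).
genotype_logliks <- function(n_ref, n, eps, M) {
  cbind(
    RR = dbinom(n_ref, n, 1 - eps, log = TRUE),
    RA = dbetabinom(n_ref, n, 0.5, M, log = TRUE),
    AA = dbinom(n_ref, n, eps, log = TRUE)
  )
}

hw_log_priors <- function(af) {
  af <- pmin(pmax(af, 1e-6), 1 - 1e-6)
  log(cbind(RR = (1 - af)^2, RA = 2 * af * (1 - af), AA = af^2))
}

marginal_loglik <- function(n_ref, n, af, eps, M) {
  ll <- genotype_logliks(n_ref, n, eps, M) + hw_log_priors(af)
  m <- apply(ll, 1, max)
  sum(m + log(rowSums(exp(ll - m))))
}

#' Fit the per-sample genotyping/ASH model
#'
#' Estimates the sequencing error rate `eps` and the het-site
#' beta-binomial concentration `M` by coordinate-ascent maximisation of
#' the genotype-marginalised likelihood with Hardy-Weinberg priors at the
#' population allele frequency.
#'
#' @param counts tibble with n_ref, n_alt and af columns (one row per
#'   SNP); rows below `cov_min` total coverage are ignored for fitting.
#' @param eps_bounds,M_bounds box constraints for the two parameters.
#' @param min_snps minimum usable SNPs (default 500).
#' @param cov_min minimum coverage for a SNP to inform the fit.
#' @param max_rounds coordinate-ascent rounds.
#' @return object of class `ash_model` with `eps`, `M`, `log_lik`,
#'   `n_used`.
#' @export
fit_sample_model <- function(counts, eps_bounds = c(1e-4, 0.1),
                             M_bounds = c(1, 1e6), min_snps = 500,
                             cov_min = 5, max_rounds = 20) {
  stopifnot(all(c("n_ref", "n_alt", "af") %in% names(counts)))
  n <- counts$n_ref + counts$n_alt
  use <- n >= cov_min & is.finite(counts$af)
  if (sum(use) < min_snps) {
    stop_footvar(sprintf("%d SNPs with coverage >= %d < min_snps = %d",
                         sum(use), cov_min, min_snps),
                 "footvar_insufficient_data")
  }
  n_ref <- counts$n_ref[use]
  nn <- n[use]
  af <- counts$af[use]

  eps <- 0.01
  M <- 100
  ll_old <- -Inf
  for (round in seq_len(max_rounds)) {
    eps <- optimize(function(e) marginal_loglik(n_ref, nn, af, e, M),
                    interval = eps_bounds, maximum = TRUE)$maximum
    opt_m <- optimize(function(lm) marginal_loglik(n_ref, nn, af, eps, exp(lm)),
                      interval = log(M_bounds), maximum = TRUE)
    M <- exp(opt_m$maximum)
    ll <- opt_m$objective
    if (abs(ll - ll_old) < 1e-6) break
    ll_old <- ll
  }
  # No detectable overdispersion: the likelihood is flat up to the cap
  if (marginal_loglik(n_ref, nn, af, eps, M_bounds[2]) >= ll - 1e-4) {
    M <- M_bounds[2]
  }
  # Degenerate all-homozygous data cannot constrain M
  post <- genotype_posteriors_matrix(n_ref, nn, af, eps, M)
  if (sum(post[, "RA"]) < 1) {
    M <- M_bounds[2]
    warn("no heterozygous evidence: concentration M set to its upper bound")
  }
  structure(list(eps = eps, M = M, log_lik = ll, n_used = length(n_ref),
                 eps_bounds = eps_bounds, M_bounds = M_bounds),
            class = "ash_model")
}

#' @export
print.ash_model <- function(x, ...) {
  cat(sprintf("<ash_model> eps = %.4g, M = %.4g (fit on %d SNPs)\n",
              x$eps, x$M, x$n_used))
  invisible(x)
}

#' @method glance ash_model
#' @export
glance.ash_model <- function(x, ...) {
  tibble::tibble(eps = x$eps, M = x$M, log_lik = x$log_lik, n_used = x$n_used)
}

genotype_posteriors_matrix <- function(n_ref, n, af, eps, M) {
  ll <- genotype_logliks(n_ref, n, eps, M) + hw_log_priors(af)
  m <- apply(ll, 1, max)
  p <- exp(ll - m)
  p / rowSums(p)
}

#' Genotype posteriors at each SNP
#'
#' Bayes over {RR, RA, AA} with Hardy-Weinberg priors at the population
#' allele frequency; an hSNP is called when the RA posterior exceeds
#' `gt_cut`.  Zero-coverage SNPs return the prior.
#'
#' @param counts tibble with n_ref, n_alt, af.
#' @param model a fitted [fit_sample_model()] object.
#' @param gt_cut heterozygote posterior call threshold (default 0.99).
#' @return `counts` with p_RR, p_RA, p_AA, genotype (argmax) and
#'   `is_het` (p_RA > gt_cut) columns.
#' @export
genotype_posteriors <- function(counts, model, gt_cut = 0.99) {
  n <- counts$n_ref + counts$n_alt
  post <- genotype_posteriors_matrix(counts$n_ref, n, counts$af,
                                     model$eps, model$M)
  counts |>
    dplyr::mutate(
      p_RR = as.numeric(post[, "RR"]), p_RA = as.numeric(post[, "RA"]),
      p_AA = as.numeric(post[, "AA"]),
      genotype = c("RR", "RA", "AA")[max.col(post)],
      is_het = .data$p_RA > gt_cut
    )
}

# Error-corrected reference-read probability at a het site with allelic
# ratio rho: reads follow rho shrunk toward 1/2 by the error rate.
effective_ref_prob <- function(rho, eps) rho * (1 - 2 * eps) + eps

bb_rho_loglik <- function(rho, k, n, eps, M) {
  dbetabinom(k, n, effective_ref_prob(rho, eps), M, log = TRUE)
}

# Exact two-sided null tail of the balanced beta-binomial, with the
# mid-p correction for discreteness: half the boundary mass is counted.
# The LRT of rho = 0.5 is monotone in |k - n/2| at fixed n, so this is
# the exact finite-sample version of the likelihood-ratio ordering.
bb_midp <- function(k, n, M) {
  ks <- 0:n
  pmf <- dbetabinom(ks, n, 0.5, M)
  d <- abs(ks - n / 2)
  dobs <- abs(k - n / 2)
  sum(pmf[d > dobs + 1e-9]) + 0.5 * sum(pmf[abs(d - dobs) <= 1e-9])
}

#' Test heterozygous SNPs for allele-specific hypersensitivity
#'
#' At each called het with total coverage >= `min_cov` and minor allele
#' frequency > `min_maf`, the reference-allele ratio rho is estimated by
#' beta-binomial maximum likelihood (error-corrected) and tested against
#' rho = 0.5.  Two p-values are reported: `p_value`, the exact two-sided
#' beta-binomial null tail with the mid-p correction for discreteness
#' (calibrated: approximately uniform under the null, the version used
#' for FDR control downstream), and `p_lrt`, the likelihood-ratio
#' statistic referred to chi-square(1) (exactly 1 at perfect balance,
#' but carrying a discreteness atom there).  Filtered SNPs are kept with
#' an NA p-value and a recorded reason.
#'
#' @param counts tibble with chrom, pos0 (optional), n_ref, n_alt, af.
#' @param model fitted [fit_sample_model()].
#' @param gt_cut het call threshold.
#' @param min_cov minimum ref+alt coverage for testing (default 10).
#' @param min_maf minimum population MAF (default 0.05).
#' @param assume_het treat every row as an RA-called heterozygote (for
#'   externally genotyped input); default FALSE.
#' @return tibble: input columns plus genotype posteriors, rho_hat,
#'   p_value, p_lrt, filter_reason (NA when tested).
#' @export
ash_test <- function(counts, model, gt_cut = 0.99, min_cov = 10,
                     min_maf = 0.05, assume_het = FALSE) {
  gt <- genotype_posteriors(counts, model, gt_cut)
  if (assume_het) gt$is_het <- TRUE
  n <- gt$n_ref + gt$n_alt
  maf <- pmin(gt$af, 1 - gt$af)
  reason <- dplyr::case_when(
    !gt$is_het ~ "not_het",
    n < min_cov ~ "coverage_lt_10",
    maf <= min_maf ~ "maf_le_0.05",
    TRUE ~ NA_character_
  )
  test_idx <- which(is.na(reason))
  rho_hat <- rep(NA_real_, nrow(gt))
  p_value <- rep(NA_real_, nrow(gt))
  p_lrt <- rep(NA_real_, nrow(gt))
  eps <- model$eps
  M <- model$M
  for (i in test_idx) {
    k <- gt$n_ref[i]
    ni <- n[i]
    p_value[i] <- bb_midp(k, ni, M)
    if (k * 2L == ni) {                       # perfectly balanced
      rho_hat[i] <- 0.5
      p_lrt[i] <- 1
      next
    }
    opt <- optimize(bb_rho_loglik, interval = c(1e-6, 1 - 1e-6),
                    maximum = TRUE, k = k, n = ni, eps = eps, M = M)
    ll0 <- bb_rho_loglik(0.5, k, ni, eps, M)
    lrt <- max(0, 2 * (opt$objective - ll0))
    rho_hat[i] <- opt$maximum
    p_lrt[i] <- pchisq(lrt, df = 1, lower.tail = FALSE)
  }
  dplyr::mutate(gt, rho_hat = rho_hat, p_value = p_value, p_lrt = p_lrt,
                filter_reason = reason)
}

#' Sample-level quality control
#'
#' Advisory checks on a fitted sample: the beta-binomial concentration
#' must not indicate gross overdispersion (`M >= m_min`); the mode of the
#' het-site allelic ratio must sit near 1/2 (`|mode - 0.5| <= rho_tol`,
#' guarding against chromosomal abnormalities such as 3:1 copy-number
#' skews); and the all-SNP allelic-ratio histogram must show the
#' expected three-peak structure (near 0, 1/2, and 1).
#'
#' @param model fitted [fit_sample_model()].
#' @param counts tibble with n_ref, n_alt, af (the genotyped SNPs).
#' @param m_min minimum acceptable concentration (default 20).
#' @param rho_tol maximum het-mode deviation from 0.5 (default 0.1).
#' @param trimodality_min minimum trimodality score: the smallest, over
#'   the three expected peak regions, of the region's peak density
#'   relative to the overall maximum (default 0.02).
#' @return one-row tibble with pass flag, reasons, and the diagnostics.
#' @export
sample_qc <- function(model, counts, m_min = 20, rho_tol = 0.1,
                      trimodality_min = 0.02) {
  gt <- genotype_posteriors(counts, model)
  n <- gt$n_ref + gt$n_alt
  ok <- n > 0
  rho_all <- gt$n_ref[ok] / n[ok]
  het <- gt$is_het[ok]

  reasons <- character(0)
  if (model$M < m_min) reasons <- c(reasons, "overdispersion")

  het_mode <- NA_real_
  if (sum(het) >= 10) {
    d <- density(rho_all[het], from = 0, to = 1, n = 512)
    het_mode <- d$x[which.max(d$y)]
    if (abs(het_mode - 0.5) > rho_tol) {
      reasons <- c(reasons, "rho mode deviation")
    }
  }

  d_all <- density(rho_all, from = 0, to = 1, n = 512)
  region_peak <- function(lo, hi) max(d_all$y[d_all$x >= lo & d_all$x <= hi])
  tri <- min(region_peak(0, 0.2), region_peak(0.4, 0.6), region_peak(0.8, 1)) /
    max(d_all$y)
  if (tri < trimodality_min) reasons <- c(reasons, "missing rho peak")

  tibble::tibble(
    pass = length(reasons) == 0,
    reasons = paste(reasons, collapse = "; "),
    eps = model$eps, M = model$M,
    het_rho_mode = het_mode, trimodality = tri
  )
}
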