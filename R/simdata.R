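# Synthetic-data generators with known truth for every pipeline input:
# genomes with planted motif instances, footprint-shaped cut-count
# matrices, allelic read counts with tunable imbalance coupling, and
# divergence/polymorphism site sets under neutral, positive and
# purifying regimes.  All generators are deterministic under `seed`.

#' Default example PWM (a 10-bp asymmetric, informative motif)
#'
#' Built once from fixed counts; informative enough that single-base
#' substitutions at its strong columns shift the prior log odds by > 3
#' under the default simulation prior.
#'
#' @param pseudocount smoothing for the probability matrix.
#' @return a `pwm`.
#' @export
example_pwm <- function(pseudocount = 1) {
  counts <- matrix(c(
    # A    C    G    T  (one column per line)
    394,   2,   2,   2,
      2, 394,   2,   2,
      2,   2, 394,   2,
    388,   4,   4,   4,
      2,   4,   2, 392,
    160, 100,  80,  60,
      4, 392,   2,   2,
    392,   4,   2,   2,
      2,   2, 394,   2,
     60, 140, 120,  80
  ), nrow = 4)
  new_pwm(counts, motif_id = "SIM_M1", pseudocount = pseudocount)
}

#' Simulate a genome with planted motif instances
#'
#' Draws an i.i.d. background sequence and plants `n_sites`
#' non-overlapping draws from the PWM at random positions and strands.
#'
#' @param genome_length total contig length (bp).
#' @param pwm motif model whose probability columns generate the planted
#'   instances.
#' @param n_sites number of planted instances.
#' @param chrom contig name.
#' @param min_gap minimum gap between planted sites (default 2 x width,
#'   so cut windows do not collide).
#' @param seed RNG seed (deterministic output).
#' @return list with `sequence` (named character), `sites` (truth tibble
#'   with chrom, start, end, strand, sequence, score) and `pwm`.
#' @export
simulate_genome <- function(genome_length = 1e5, pwm = example_pwm(),
                            n_sites = 200, chrom = "chrSim", min_gap = NULL,
                            seed = 1) {
  check_seed(seed)
  w <- pwm_width(pwm)
  min_gap <- min_gap %||% (2L * w)
  slot <- w + min_gap
  if (n_sites * slot > genome_length) {
    stop_footvar("motif density too high to place sites without overlap",
                 "footvar_config")
  }
  sm <- pwm_log_odds(pwm)
  with_seed_or_not(seed, {
    bg <- sample(DNA_BASES, genome_length, replace = TRUE, prob = pwm$background)
    if (n_sites == 0) {
      return(list(
        sequence = setNames(paste(bg, collapse = ""), chrom),
        sites = tibble::tibble(chrom = character(), start = integer(),
                               end = integer(), strand = character(),
                               sequence = character(), score = numeric(),
                               motif_id = character()),
        pwm = pwm
      ))
    }
    # one site per equal-width bin, at a random offset, guarantees no overlap
    bin <- floor(genome_length / n_sites)
    starts0 <- (seq_len(n_sites) - 1L) * bin +
      sample.int(bin - slot, n_sites, replace = TRUE)
    strands <- sample(c("+", "-"), n_sites, replace = TRUE)
    motif_seq <- vapply(seq_len(n_sites), function(i) {
      paste(DNA_BASES[apply(pwm$probs, 2, function(p)
        sample.int(4, 1, prob = p))], collapse = "")
    }, character(1))
    planted <- ifelse(strands == "+", motif_seq, revcomp(motif_seq))
    for (i in seq_len(n_sites)) {
      bg[(starts0[i] + 1):(starts0[i] + w)] <-
        strsplit(planted[i], "", fixed = TRUE)[[1]]
    }
    sites <- tibble::tibble(
      chrom = chrom, start = as.integer(starts0),
      end = as.integer(starts0 + w), strand = strands,
      sequence = motif_seq,
      score = unname(vapply(motif_seq, score_sequence, numeric(1), sm = sm)),
      motif_id = pwm$motif_id
    )
    list(sequence = setNames(paste(bg, collapse = ""), chrom),
         sites = sites, pwm = pwm)
  })
}

#' Footprint-shaped spatial cut profile
#'
#' Baseline cleavage in the flanks, depletion over the motif (the
#' footprint), and strand-asymmetric shoulders at the motif edges
#' (elevated 5' shoulder on the forward strand, 3' on the reverse).
#' Normalised over both strands.
#'
#' @param width motif width.
#' @param flank flanking bases per side (default 100).
#' @param depletion relative cleavage inside the footprint.
#' @param shoulder relative cleavage at the edge shoulders.
#' @param shoulder_width shoulder extent in bp.
#' @return probability vector of length `2 * (width + 2 * flank)`.
#' @export
footprint_profile <- function(width, flank = 100, depletion = 0.15,
                              shoulder = 3, shoulder_width = 5) {
  window <- width + 2L * flank
  motif <- (flank + 1):(flank + width)
  base <- rep(1, window)
  base[motif] <- depletion
  fwd <- base
  rev_ <- base
  sh_f <- max(1, flank - shoulder_width + 1):flank
  sh_r <- (flank + width + 1):min(window, flank + width + shoulder_width)
  fwd[sh_f] <- shoulder
  rev_[sh_r] <- shoulder
  lam <- c(fwd, rev_)
  lam / sum(lam)
}

#' Simulate a cut-count matrix from the mixture model
#'
#' Bound states are drawn with `P(bound) = sigma(beta0 + beta1 * S)`;
#' bound rows draw a NB(mu1, size1) total spread over the footprint
#' profile, unbound rows a NB(mu0, size0) total spread uniformly.
#'
#' @param scores per-site PWM scores (from a truth table or scan).
#' @param beta logistic prior `(beta0, beta1)`.
#' @param width,flank window geometry.
#' @param lambda spatial profile (default [footprint_profile()]).
#' @param mu1,size1,mu0,size0 NB read-total parameters per component.
#' @param seed RNG seed.
#' @return list with `cuts` (a [new_cut_matrix()]) and `truth` tibble
#'   (site_id, score, prior, bound, total).
#' @export
simulate_cut_matrix <- function(scores, beta = c(-9, 0.8), width = 10,
                                flank = 100, lambda = NULL, mu1 = 100,
                                size1 = 4, mu0 = 10, size0 = 2, seed = 1) {
  check_seed(seed)
  window <- width + 2L * flank
  J <- 2L * window
  lambda <- lambda %||% footprint_profile(width, flank)
  if (length(lambda) != J) {
    stop_footvar("lambda must have 2 * (width + 2 * flank) entries",
                 "footvar_config")
  }
  n <- length(scores)
  with_seed_or_not(seed, {
    prior <- sigmoid(beta[1] + beta[2] * scores)
    bound <- rbinom(n, 1, prior) == 1
    totals <- integer(n)
    totals[bound] <- rnbinom(sum(bound), size = size1, mu = mu1)
    totals[!bound] <- rnbinom(sum(!bound), size = size0, mu = mu0)
    counts <- matrix(0L, n, J)
    if (any(bound)) {
      counts[bound, ] <- t(vapply(totals[bound], function(R)
        rmultinom(1, R, lambda)[, 1], integer(J)))
    }
    if (any(!bound)) {
      counts[!bound, ] <- t(vapply(totals[!bound], function(R)
        rmultinom(1, R, rep(1 / J, J))[, 1], integer(J)))
    }
    ids <- paste0("site_", seq_len(n))
    list(
      cuts = new_cut_matrix(counts, site_ids = ids, window = window,
                            flank = flank),
      truth = tibble::tibble(site_id = ids, score = scores, prior = prior,
                             bound = bound, total = totals),
      lambda = lambda, beta = beta
    )
  })
}

# Beta-binomial draw with mean `prob` and concentration M.
rbetabinom <- function(n, size, prob, M) {
  rbinom(n, size, rbeta(n, prob * M, (1 - prob) * M))
}

# Left-truncated NB: resample values below `min` (true truncation).
rnbinom_trunc <- function(n, mu, size, min = 1) {
  x <- rnbinom(n, size = size, mu = mu)
  bad <- which(x < min)
  guard <- 0
  while (length(bad) > 0 && guard < 1000) {
    x[bad] <- rnbinom(length(bad), size = size, mu = mu)
    bad <- bad[x[bad] < min]
    guard <- guard + 1
  }
  x[x < min] <- min
  x
}

#' Simulate allelic read counts at heterozygous SNPs
#'
#' The true reference-allele ratio is coupled to the predicted binding
#' difference: `rho = 0.5 - a + 2a * sigma(kappa * delta)` where `delta`
#' is the per-SNP difference in prior log odds (ell_ref - ell_alt), so
#' `kappa = 0` gives the global null rho = 0.5 and large kappa pushes
#' rho towards `0.5 +/- amplitude` in the predicted direction.  Reads
#' follow a beta-binomial with error-corrected mean and concentration M;
#' coverage follows a left-truncated NB.
#'
#' @param delta per-SNP difference in prior log odds (length = n SNPs).
#' @param kappa coupling strength (0 = null).
#' @param M beta-binomial concentration.
#' @param eps sequencing error rate.
#' @param coverage_mu,coverage_size,coverage_min truncated-NB coverage law.
#' @param amplitude maximum deviation `a` of rho from 0.5 (default 0.4).
#' @param af population allele frequencies (recycled; default 0.25).
#' @param chrom,start0 coordinates assigned to the SNPs.
#' @param seed RNG seed.
#' @return tibble with chrom, pos0, ref, alt, n_ref, n_alt, n_other, af,
#'   delta and the true `rho`.
#' @export
simulate_allele_counts <- function(delta, kappa = 0, M = 50, eps = 0.01,
                                   coverage_mu = 100, coverage_size = 5,
                                   coverage_min = 10, amplitude = 0.4,
                                   af = 0.25, chrom = "chrSim",
                                   start0 = 1000L, seed = 1) {
  check_seed(seed)
  n <- length(delta)
  with_seed_or_not(seed, {
    rho <- 0.5 - amplitude + 2 * amplitude * sigmoid(kappa * delta)
    cov <- rnbinom_trunc(n, coverage_mu, coverage_size, coverage_min)
    p_eff <- effective_ref_prob(rho, eps)
    n_ref <- rbetabinom(n, cov, p_eff, M)
    tibble::tibble(
      chrom = chrom,
      pos0 = as.integer(start0 + seq_len(n) * 10L),
      ref = sample(DNA_BASES, n, replace = TRUE),
      alt = NA_character_,
      n_ref = n_ref, n_alt = cov - n_ref, n_other = 0L,
      af = rep_len(af, n), delta = delta, rho = rho
    ) |>
      dplyr::mutate(alt = purrr::map_chr(.data$ref, function(r)
        sample(setdiff(DNA_BASES, r), 1)))
  })
}

#' Simulate a genotyping sample (all three genotypes)
#'
#' Genotypes drawn from Hardy-Weinberg at each SNP's allele frequency;
#' read counts follow the genotyping model (RR: Binom(1 - eps), AA:
#' Binom(eps), RA: BetaBinom(1/2, M)).  Used to test the sample-model
#' fit and QC.
#'
#' @param n_snps number of SNPs.
#' @param eps,M true error rate and concentration.
#' @param coverage_mu,coverage_size,coverage_min coverage law.
#' @param af_alpha,af_beta Beta law for population allele frequencies.
#' @param het_rho reference ratio at het sites (0.5 = diploid balance;
#'   e.g. 0.75 mimics a 3:1 copy-number skew).
#' @param seed RNG seed.
#' @return tibble with n_ref, n_alt, n_other, af and the true genotype.
#' @export
simulate_sample_counts <- function(n_snps = 5000, eps = 0.01, M = 50,
                                   coverage_mu = 30, coverage_size = 3,
                                   coverage_min = 5, af_alpha = 1,
                                   af_beta = 1, het_rho = 0.5, seed = 1) {
  check_seed(seed)
  with_seed_or_not(seed, {
    af <- rbeta(n_snps, af_alpha, af_beta)
    af <- pmin(pmax(af, 0.05), 0.95)
    g <- vapply(af, function(a)
      sample.int(3, 1, prob = c((1 - a)^2, 2 * a * (1 - a), a^2)), integer(1))
    cov <- rnbinom_trunc(n_snps, coverage_mu, coverage_size, coverage_min)
    n_ref <- integer(n_snps)
    rr <- g == 1; ra <- g == 2; aa <- g == 3
    n_ref[rr] <- rbinom(sum(rr), cov[rr], 1 - eps)
    n_ref[ra] <- rbetabinom(sum(ra), cov[ra],
                            effective_ref_prob(het_rho, eps), M)
    n_ref[aa] <- rbinom(sum(aa), cov[aa], eps)
    tibble::tibble(
      chrom = "chrSim", pos0 = seq_len(n_snps) * 10L,
      n_ref = n_ref, n_alt = cov - n_ref, n_other = 0L, af = af,
      genotype_true = c("RR", "RA", "AA")[g]
    )
  })
}

#' Simulate divergence and polymorphism at binding sites
#'
#' For each motif, sites are fixed interspecies differences (divergent),
#' within-species polymorphisms, or unchanged.  The functional fraction
#' among divergent vs polymorphic changes is set by the regime: neutral
#' equalises them, positive inflates fixed-functional changes, purifying
#' depletes them and skews the polymorphic functional DAF towards rare
#' alleles.  Changed sites carry realising sequences: the substitution is
#' chosen from the motif's score matrix so that `|beta1 * dS|` matches
#' the intended class, so [classify_divergence()] and the effect-SNP rule
#' recover the truth.
#'
#' @param n_motifs motifs to simulate (each gets a fresh PWM draw of the
#'   example motif's sites).
#' @param sites_per_motif binding sites per motif.
#' @param regime `"neutral"`, `"positive"` or `"purifying"`.
#' @param pwm motif model (shared across motifs).
#' @param beta logistic prior coefficients.
#' @param p_divergent,p_polymorphic per-site probabilities of a fixed
#'   difference / polymorphism (the rest stay identical).
#' @param f_poly functional fraction among polymorphic changes.
#' @param f_div_neutral,f_div_positive,f_div_purifying functional
#'   fraction among fixed differences per regime.
#' @param seed RNG seed.
#' @return list with `sites` (per-site tibble: motif_id, sequence,
#'   ortholog_seq, alt allele columns, true class, daf) and `beta`, `sm`.
#' @export
simulate_divergence <- function(n_motifs = 20, sites_per_motif = 200,
                                regime = c("neutral", "positive", "purifying"),
                                pwm = example_pwm(), beta = c(-6, 1),
                                p_divergent = 0.3, p_polymorphic = 0.3,
                                f_poly = 0.3, f_div_neutral = 0.3,
                                f_div_positive = 0.6, f_div_purifying = 0.1,
                                seed = 1) {
  regime <- match.arg(regime)
  check_seed(seed)
  sm <- pwm_log_odds(pwm)
  w <- sm$width
  f_div <- switch(regime, neutral = f_div_neutral,
                  positive = f_div_positive, purifying = f_div_purifying)

  # Catalogue all single-base substitutions of the consensus-ish draws by
  # their |beta1 * dS| so classes are realisable by construction.
  with_seed_or_not(seed, {
    per_site <- function(motif) {
      n <- sites_per_motif
      seqs <- vapply(seq_len(n), function(i)
        codes_to_seq(apply(pwm$probs, 2, function(p)
          sample.int(4, 1, prob = p))), character(1))
      type <- sample(c("divergent", "polymorphic", "identical"), n,
                     replace = TRUE,
                     prob = c(p_divergent, p_polymorphic,
                              1 - p_divergent - p_polymorphic))
      functional <- rep(NA, n)
      functional[type == "divergent"] <-
        runif(sum(type == "divergent")) < f_div
      functional[type == "polymorphic"] <-
        runif(sum(type == "polymorphic")) < f_poly
      changed <- type != "identical"
      mut <- purrr::map(seq_len(n), function(i) {
        if (!changed[i]) return(list(seq2 = NA_character_, ok = TRUE))
        pick_substitution(seqs[i], sm, beta, functional[i])
      })
      ok <- vapply(mut, function(m) m$ok, logical(1))
      seq2 <- vapply(mut, function(m) m$seq2, character(1))
      daf <- rep(NA_real_, n)
      pol <- type == "polymorphic" & ok
      # neutral-ish SFS for silent; purifying skews functional DAF rare
      daf[pol & !functional] <- rbeta(sum(pol & !functional), 0.4, 2)
      a_fun <- if (regime == "purifying") 0.2 else 0.4
      daf[pol & functional] <- rbeta(sum(pol & functional), a_fun,
                                     if (regime == "purifying") 4 else 2)
      tibble::tibble(
        motif_id = motif, sequence = seqs, type = type,
        functional = functional, realised = ok,
        ortholog_seq = ifelse(type == "divergent", seq2, NA_character_),
        alt_seq = ifelse(type == "polymorphic", seq2, NA_character_),
        daf = pmin(pmax(daf, 1e-4), 1 - 1e-4)
      )
    }
    sites <- purrr::list_rbind(
      purrr::map(paste0("SIM_M", seq_len(n_motifs)), per_site))
    list(sites = sites, beta = beta, sm = sm, regime = regime)
  })
}

# Choose a single-base substitution whose |beta1 * dS| is >= 3
# (functional) or < 3 (silent); returns the mutated sequence.
pick_substitution <- function(sequence, sm, beta, functional,
                              ln_fold_threshold = 3) {
  codes <- seq_to_codes(sequence)
  s0 <- sum(sm$scores[cbind(codes, seq_len(sm$width))])
  cand <- expand.grid(j = seq_len(sm$width), b = 1:4)
  cand <- cand[codes[cand$j] != cand$b, ]
  d <- abs(beta[2] * (sm$scores[cbind(cand$b, cand$j)] -
                        sm$scores[cbind(codes[cand$j], cand$j)]))
  keep <- if (functional) d >= ln_fold_threshold else
    d < ln_fold_threshold & d > 1e-9
  if (!any(keep)) return(list(seq2 = NA_character_, ok = FALSE))
  pick <- sample(which(keep), 1)
  codes2 <- codes
  codes2[cand$j[pick]] <- cand$b[pick]
  list(seq2 = codes_to_seq(codes2), ok = TRUE)
}
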