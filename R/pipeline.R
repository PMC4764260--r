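# End-to-end driver and configuration.  The pipeline mirrors the
# two-step analysis: simulate (or load) inputs, scan, fit the footprint
# mixture, recalibrate, rescan at the prior floor, annotate SNPs,
# test ASH with partitioned FDR, and score motif-wise selection.

default_config <- function() {
  list(
    # thresholds (documented defaults; every printed rule of the method)
    posterior_cutoff = 0.99,   # footprint / recalibration posterior
    z_cutoff = 5,              # TF activity (strict >)
    prior_min = 0.10,          # step-2 rescan prior floor
    ln_fold_threshold = 3,     # effect-SNP rule (e^3 ~ 20-fold odds)
    min_cov = 10,              # ASH coverage filter
    min_maf = 0.05,            # ASH MAF filter
    q_cut = 0.20,              # ASH discovery FDR
    min_hsnp = 100,            # motif enrichment inclusion rule (> 100)
    mk_pseudocount = 0.5,      # Haldane correction
    mk_min_sites = 100,
    recal_min_sites = 100,
    # simulation scale
    genome_length = 2e5,
    n_sites = 400,
    width = 10, flank = 50,
    beta_true = c(-9, 0.8),
    mu1 = 100, size1 = 4, mu0 = 10, size0 = 2,
    n_snps = 2000, kappa = 2, M = 50, eps = 0.01,
    n_motifs_mk = 20, sites_per_motif = 200, regime = "neutral",
    sample_id = "simSample",
    seed = 1
  )
}

#' Read a pipeline configuration
#'
#' YAML file of scalar overrides on top of the documented defaults;
#' unknown keys are rejected so every threshold stays auditable.
#'
#' @param path YAML path, or NULL for pure defaults.
#' @param overrides named list applied after the file.
#' @return named list of configuration values.
#' @export
read_pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  user <- if (!is.null(path)) yaml::read_yaml(path) else list()
  user <- utils::modifyList(user, overrides)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop_footvar(paste("unknown config keys:", paste(unknown, collapse = ", ")),
                 "footvar_config")
  }
  utils::modifyList(cfg, user)
}

#' Run the full pipeline on simulated inputs
#'
#' Simulates a genome with planted motif instances, cut-count data,
#' allelic read counts coupled to the predicted binding difference, and
#' a divergence site set; then runs scan, mixture fit, recalibration,
#' SNP annotation, ASH with partitioned FDR, and the MK selection score.
#' All stage outputs are returned; when `out_dir` is given the standard
#' files (match BED, catalog, fit, counts, tables) are written there.
#'
#' @param config from [read_pipeline_config()].
#' @param out_dir optional output directory.
#' @param quiet suppress per-stage count logging.
#' @return named list of stage results, including the Fig-1D-style
#'   nested category funnel.
#' @export
run_pipeline <- function(config = read_pipeline_config(), out_dir = NULL,
                         quiet = FALSE) {
  log_ <- function(...) if (!quiet) inform(sprintf(...))
  seed <- config$seed

  ## --- inputs (simulated with truth) ---
  genome <- simulate_genome(config$genome_length, n_sites = config$n_sites,
                            seed = seed)
  pwm <- genome$pwm
  sm <- pwm_log_odds(pwm)
  sim_cm <- simulate_cut_matrix(genome$sites$score, beta = config$beta_true,
                                width = config$width, flank = config$flank,
                                mu1 = config$mu1, size1 = config$size1,
                                mu0 = config$mu0, size0 = config$size0,
                                seed = seed + 1)
  log_("simulated %d sites on a %g bp genome", config$n_sites,
       config$genome_length)

  ## --- step 1: fit + recalibrate ---
  fit <- fit_centipede(sim_cm$cuts, genome$sites$score,
                       min_sites = min(config$n_sites, 500))
  act <- activity_zscore(fit, config$z_cutoff)
  log_("mixture fit: Z = %.1f (%s)", act$z,
       if (act$is_active) "active" else "inactive")
  sites_post <- dplyr::mutate(genome$sites,
                              site_id = fit$site_ids,
                              posterior = fit$posteriors)
  recal <- tryCatch(
    recalibrate_pwm(sites_post, config$posterior_cutoff,
                    min_sites = config$recal_min_sites,
                    motif_id = paste0(pwm$motif_id, "_recal")),
    footvar_insufficient_data = function(e) {
      warn(conditionMessage(e))
      pwm
    })

  ## --- step 2: rescan at the prior floor + annotate SNPs ---
  sm2 <- pwm_log_odds(recal)
  thr <- prior_threshold_score(fit$beta, config$prior_min)
  rescan <- scan_sequence(genome$sequence, sm2, thr)
  log_("rescan at prior >= %.0f%%: %d matches (score >= %.2f)",
       100 * config$prior_min, nrow(rescan), thr)

  variants <- simulate_footprint_variants(sites_post, fit, seed = seed + 2)
  ann <- annotate_snps(variants, dplyr::mutate(genome$sites,
                                               site_id = fit$site_ids),
                       sm, fit = fit, sample_id = config$sample_id,
                       ln_fold_threshold = config$ln_fold_threshold)
  ann <- resolve_overlaps(ann)
  footprints <- dplyr::filter(sites_post,
                              .data$posterior > config$posterior_cutoff)
  dhs <- tibble::tibble(chrom = genome$sites$chrom[1], start = 0L,
                        end = as.integer(config$genome_length))
  nested <- nest_categories(ann, footprints, dhs)
  funnel <- category_funnel(nested)
  log_("SNP funnel: dhs %d > footprint %d > effect %d > switch %d",
       funnel$n[1], funnel$n[2], funnel$n[3], funnel$n[4])

  ## --- ASH: genotyping model, test, partitioned FDR ---
  ash_in <- simulate_allele_counts(
    delta = ann$log_ratio[seq_len(min(nrow(ann), config$n_snps))],
    kappa = config$kappa, M = config$M, eps = config$eps,
    seed = seed + 3)
  sample_counts <- simulate_sample_counts(max(500, config$n_snps),
                                          eps = config$eps, M = config$M,
                                          seed = seed + 4)
  model <- fit_sample_model(sample_counts)
  qc <- sample_qc(model, sample_counts)
  ash <- ash_test(ash_in, model, min_cov = config$min_cov,
                  min_maf = config$min_maf)
  ash$partition <- ifelse(abs(ash$delta) >= config$ln_fold_threshold,
                          "effect", "footprint_only")
  fdr <- partitioned_fdr(ash, q_cut = config$q_cut)
  log_("ASH: %d tested, %d discoveries at q < %.2f",
       sum(!is.na(fdr$p_value)), sum(fdr$ash_discovery), config$q_cut)

  ## --- selection ---
  div <- simulate_divergence(config$n_motifs_mk, config$sites_per_motif,
                             regime = config$regime, seed = seed + 5)
  mk_sites <- classify_divergence_sites(div)
  mk_counts <- mk_count_sites(mk_sites)
  mk <- mk_selection_score(mk_counts, config$mk_pseudocount,
                           config$mk_min_sites)
  log_("MK selection: %d motifs scored, mean score %.3f",
       nrow(mk), mean(mk$score))

  res <- list(
    config = config, genome = genome, fit = fit, activity = act,
    recalibrated_pwm = recal, rescan = rescan, annotations = ann,
    nested = nested, funnel = funnel, ash_model = model, qc = qc,
    ash = fdr, partition_summary = partition_summary(fdr, config$q_cut),
    mk_counts = mk_counts, mk = mk
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(genome$sequence, file.path(out_dir, "genome.fa"))
    write_match_bed(rescan, file.path(out_dir, "matches.bed"))
    write_cut_matrix(sim_cm$cuts, file.path(out_dir, "cuts.tsv"))
    write_centipede_fit(fit, file.path(out_dir, "centipede_fit.txt"))
    write_pwm(recal, file.path(out_dir, "recalibrated_pwm.txt"))
    write_catalog(ann, file.path(out_dir, "snp_catalog.tsv"))
    write_allele_counts(ash_in, file.path(out_dir, "allele_counts.tsv"))
    readr::write_tsv(fdr, file.path(out_dir, "ash_results.tsv"))
    readr::write_tsv(mk, file.path(out_dir, "mk_scores.tsv"))
    log_("outputs written to %s", out_dir)
  }
  invisible(res)
}

# Plant one SNP inside each motif instance (for the simulated pipeline).
simulate_footprint_variants <- function(sites, fit, seed = 1) {
  with_seed_or_not(seed, {
    off <- sample.int(sites$end[1] - sites$start[1],
                      nrow(sites), replace = TRUE) - 1L
    pos0 <- sites$start + off
    ref_fwd <- purrr::map2_chr(sites$sequence, off + 1L, function(s, j) {
      substr(s, j, j)
    })
    # sequence column is strand-resolved; recover the forward-strand base
    minus <- sites$strand == "-"
    j_minus <- nchar(sites$sequence[minus]) - off[minus]
    ref_fwd[minus] <- chartr("ACGT", "TGCA",
                             substr(sites$sequence[minus], j_minus, j_minus))
    alt <- purrr::map_chr(ref_fwd, function(r)
      sample(setdiff(DNA_BASES, r), 1))
    tibble::tibble(chrom = sites$chrom, pos0 = pos0, ref = ref_fwd,
                   alt = alt)
  })
}

# Classify every simulated divergence site through the sequence models.
classify_divergence_sites <- function(div) {
  sites <- div$sites
  sm <- div$sm
  beta <- div$beta
  d_idx <- which(sites$type == "divergent" & sites$realised)
  p_idx <- which(sites$type == "polymorphic" & sites$realised)
  sites$divergence_class <- NA_character_
  if (length(d_idx)) {
    sites$divergence_class[d_idx] <- classify_divergence(
      sites$sequence[d_idx], sites$ortholog_seq[d_idx], sm, beta)
  }
  sites$category <- NA_character_
  if (length(p_idx)) {
    ell1 <- beta[1] + beta[2] *
      unname(vapply(sites$sequence[p_idx], score_sequence, numeric(1), sm = sm))
    ell2 <- beta[1] + beta[2] *
      unname(vapply(sites$alt_seq[p_idx], score_sequence, numeric(1), sm = sm))
    sites$category[p_idx] <- classify_category(ell1, ell2)
  }
  sites
}

#' Command-line dispatch
#'
#' Thin wrapper used by the installed `inst/cli/footvar.R` script.
#' Subcommands: `simulate` (write simulated inputs), `pipeline` (full
#' run), `version`.  Options: `--config <yaml>`, `--out <dir>`,
#' `--seed <int>`, `--quiet`.
#'
#' @param argv character vector of arguments (default from the command
#'   line).
#' @return exit status, invisibly (0 on success).
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0 || argv[1] %in% c("-h", "--help")) {
    cat("usage: footvar <simulate|pipeline|version> [--config yaml]",
        "[--out dir] [--seed int] [--quiet]\n")
    return(invisible(0L))
  }
  cmd <- argv[1]
  opts <- argv[-1]
  get_opt <- function(flag, default = NULL) {
    i <- which(opts == flag)
    if (length(i) && i[1] < length(opts)) opts[i[1] + 1] else default
  }
  quiet <- "--quiet" %in% opts
  if (cmd == "version") {
    cat("footvar", as.character(utils::packageVersion("footvar")), "\n")
    return(invisible(0L))
  }
  if (!cmd %in% c("simulate", "pipeline")) {
    cat("unknown subcommand:", cmd, "\n")
    return(invisible(1L))
  }
  overrides <- list()
  seed <- get_opt("--seed")
  if (!is.null(seed)) overrides$seed <- as.integer(seed)
  cfg <- read_pipeline_config(get_opt("--config"), overrides)
  out <- get_opt("--out", "footvar_out")
  if (cmd == "simulate") {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    genome <- simulate_genome(cfg$genome_length, n_sites = cfg$n_sites,
                              seed = cfg$seed)
    sim_cm <- simulate_cut_matrix(genome$sites$score, beta = cfg$beta_true,
                                  width = cfg$width, flank = cfg$flank,
                                  seed = cfg$seed + 1)
    write_fasta(genome$sequence, file.path(out, "genome.fa"))
    write_bed(genome$sites, file.path(out, "sites.bed"))
    write_cut_matrix(sim_cm$cuts, file.path(out, "cuts.tsv"))
    if (!quiet) inform(sprintf("simulated inputs written to %s", out))
    return(invisible(0L))
  }
  run_pipeline(cfg, out_dir = out, quiet = quiet)
  invisible(0L)
}
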