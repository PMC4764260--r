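# Allele-aware annotation of SNPs inside motif matches: per-allele prior
# log odds from the logistic sequence prior, effect-/switch-SNP
# classification, overlap resolution and the catalog writer.

#' Classify a SNP by its per-allele prior log odds
#'
#' effect: the prior log odds of binding differ by at least
#' `ln_fold_threshold` between alleles (default 3, i.e. a >= e^3 ~ 20-fold
#' change in prior odds); switch: an effect-SNP whose prior log odds are
#' `>= 0` for one allele and `<= 0` for the other (boundary 0 counts for
#' both signs); otherwise footprint.
#'
#' @param ell_ref,ell_alt prior log odds of binding per allele (vectors).
#' @param ln_fold_threshold natural-log-odds difference calling an effect.
#' @return character vector in `c("footprint", "effect", "switch")`.
#' @export
classify_category <- function(ell_ref, ell_alt, ln_fold_threshold = 3) {
  stopifnot(length(ell_ref) == length(ell_alt))
  delta <- abs(ell_ref - ell_alt)
  effect <- is.finite(delta) & delta >= ln_fold_threshold
  flips <- (ell_ref >= 0 & ell_alt <= 0) | (ell_ref <= 0 & ell_alt >= 0)
  dplyr::case_when(
    effect & flips ~ "switch",
    effect ~ "effect",
    TRUE ~ "footprint"
  )
}

#' Annotate SNPs falling inside motif matches
#'
#' Overlap-joins variants with matches, substitutes each allele into the
#' motif, and converts the two scores into per-allele prior log odds
#' `ell = beta0 + beta1 * S`.  The site likelihood ratio is taken from
#' the fitted model when given.
#'
#' @param variants tibble with chrom, pos0 (0-based), ref, alt.
#' @param matches tibble from [scan_sequence()]; a `site_id` column (or
#'   row order) links matches to `fit` sites.
#' @param sm score matrix used for the matches.
#' @param beta length-2 logistic prior coefficients; defaults to
#'   `fit$beta`.
#' @param fit optional `centipede_fit` supplying per-site posteriors and
#'   likelihood ratios.
#' @param sample_id cell type / sample label stored in the catalog.
#' @param ln_fold_threshold passed to [classify_category()].
#' @return tibble, one row per (SNP, match) pair, with score_ref/score_alt,
#'   ell_ref/ell_alt, delta (absolute), log_ratio (signed ref - alt),
#'   category, lik_ratio, posterior.
#' @export
annotate_snps <- function(variants, matches, sm, beta = NULL, fit = NULL,
                          sample_id = "sample", ln_fold_threshold = 3) {
  beta <- unname(beta %||% fit$beta)
  if (is.null(beta)) stop_footvar("supply `beta` or `fit`", "footvar_input")
  if (nrow(matches) == 0 || nrow(variants) == 0) {
    return(empty_annotation_tbl())
  }
  if (!"site_id" %in% names(matches)) {
    matches$site_id <- paste0("site_", seq_len(nrow(matches)))
  }
  ov <- overlap_join(variants, matches)
  if (nrow(ov) == 0) return(empty_annotation_tbl())

  ov <- score_alleles(ov, sm)
  ov <- dplyr::mutate(
    ov,
    ell_ref = beta[1] + beta[2] * .data$score_ref,
    ell_alt = beta[1] + beta[2] * .data$score_alt,
    delta = abs(.data$ell_ref - .data$ell_alt),
    log_ratio = .data$ell_ref - .data$ell_alt,
    category = classify_category(.data$ell_ref, .data$ell_alt, ln_fold_threshold),
    sample_id = sample_id
  )
  if (!is.null(fit)) {
    site_tbl <- posterior_binding(fit)
    ov <- dplyr::left_join(ov, site_tbl, by = "site_id")
    ov <- dplyr::rename(ov, lik_ratio = "log_lik_ratio")
  } else {
    ov$lik_ratio <- NA_real_
    ov$posterior <- NA_real_
  }
  dplyr::select(ov, "chrom", "pos0", "ref", "alt", "motif_id", "site_id",
                "sample_id", "score_ref", "score_alt", "ell_ref", "ell_alt",
                "delta", "log_ratio", "category", "lik_ratio", "posterior")
}

empty_annotation_tbl <- function() {
  tibble::tibble(
    chrom = character(), pos0 = integer(), ref = character(),
    alt = character(), motif_id = character(), site_id = character(),
    sample_id = character(), score_ref = numeric(), score_alt = numeric(),
    ell_ref = numeric(), ell_alt = numeric(), delta = numeric(),
    log_ratio = numeric(), category = character(), lik_ratio = numeric(),
    posterior = numeric()
  )
}

# Overlap join of point variants (pos0) against half-open match intervals,
# via GenomicRanges.
overlap_join <- function(variants, matches) {
  vr <- GenomicRanges::GRanges(
    variants$chrom,
    IRanges::IRanges(start = variants$pos0 + 1, width = 1)
  )
  mr <- GenomicRanges::GRanges(
    matches$chrom,
    IRanges::IRanges(start = matches$start + 1, end = matches$end)
  )
  hits <- GenomicRanges::findOverlaps(vr, mr)
  v <- variants[S4Vectors::queryHits(hits), , drop = FALSE]
  m <- matches[S4Vectors::subjectHits(hits), , drop = FALSE]
  m <- dplyr::select(m, -dplyr::any_of("chrom"))
  dplyr::bind_cols(v, m)
}

#' Keep one annotation per SNP across overlapping motifs
#'
#' Where a SNP lies in several predicted binding sites, the motif with
#' the greatest CENTIPEDE likelihood ratio is retained (the factor most
#' likely to be bound); exact ties break deterministically by
#' lexicographic motif_id.
#'
#' @param annotations tibble from [annotate_snps()] (any number of motifs
#'   and samples bound together).
#' @return tibble with one row per (chrom, pos0, ref, alt, sample_id).
#' @export
resolve_overlaps <- function(annotations) {
  if (nrow(annotations) == 0) {
    stop_footvar("no annotations to resolve", "footvar_input")
  }
  annotations |>
    dplyr::group_by(.data$chrom, .data$pos0, .data$ref, .data$alt,
                    .data$sample_id) |>
    dplyr::arrange(dplyr::desc(.data$lik_ratio), .data$motif_id,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

CATALOG_COLS <- c("chrom", "start", "end", "motif_id", "log_ratio",
                  "ell_ref", "ell_alt", "sample_id")

#' Write the SNP catalog (8-column TSV)
#'
#' Columns: 1-3 BED-formatted SNP position (0-based half-open), 4 motif
#' ID, 5 signed difference between the per-allele prior log odds
#' (ref - alt), 6 prior log odds for the reference allele, 7 for the
#' alternate allele, 8 cell type.
#'
#' @param annotations resolved annotation tibble.
#' @param path output TSV path.
#' @param digits decimal places for the numeric columns.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(annotations, path, digits = 6) {
  df <- tibble::tibble(
    chrom = annotations$chrom,
    start = annotations$pos0,
    end = annotations$pos0 + 1L,
    motif_id = annotations$motif_id,
    log_ratio = round(annotations$log_ratio, digits),
    ell_ref = round(annotations$ell_ref, digits),
    ell_alt = round(annotations$ell_alt, digits),
    sample_id = annotations$sample_id
  )
  header <- c(
    "# SNP catalog; coordinates 0-based half-open (BED)",
    paste0("# columns: ", paste(CATALOG_COLS, collapse = "\t"))
  )
  writeLines(header, path)
  readr::write_tsv(df, path, append = TRUE, col_names = FALSE)
  invisible(path)
}

#' Read a SNP catalog written by [write_catalog()]
#' @param path TSV path.
#' @return tibble with the catalog columns plus `pos0`.
#' @export
read_catalog <- function(path) {
  df <- readr::read_tsv(
    path, comment = "#", col_names = CATALOG_COLS,
    col_types = readr::cols(
      chrom = "c", start = "i", end = "i", motif_id = "c",
      log_ratio = "d", ell_ref = "d", ell_alt = "d", sample_id = "c"
    ),
    progress = FALSE
  )
  dplyr::mutate(df, pos0 = .data$start)
}

#' Nest SNPs into dhs > footprint > effect > switch categories
#'
#' Labels each SNP with the deepest applicable category: inside a DHS
#' region; additionally inside a footprint; an effect-SNP; a switch-SNP.
#' SNPs in a footprint that fall outside every DHS region are kept (with
#' a warning) and labelled by their footprint-level category.
#'
#' @param snps tibble with chrom, pos0 and (for footprint SNPs) the
#'   `category` column from [annotate_snps()].
#' @param footprints tibble of footprint intervals (chrom, start, end).
#' @param dhs tibble of DHS intervals (chrom, start, end).
#' @return `snps` with `nested_category` (`none`, `dhs`, `footprint`,
#'   `effect`, `switch`) plus a `counts` attribute holding the funnel.
#' @export
nest_categories <- function(snps, footprints, dhs) {
  in_region <- function(region_tbl) {
    if (is.null(region_tbl) || nrow(region_tbl) == 0) {
      return(rep(FALSE, nrow(snps)))
    }
    vr <- GenomicRanges::GRanges(
      snps$chrom, IRanges::IRanges(snps$pos0 + 1, width = 1))
    rr <- GenomicRanges::GRanges(
      region_tbl$chrom,
      IRanges::IRanges(region_tbl$start + 1, region_tbl$end))
    GenomicRanges::countOverlaps(vr, rr) > 0
  }
  in_dhs <- in_region(dhs)
  in_fp <- in_region(footprints)
  if (any(in_fp & !in_dhs)) {
    warn(sprintf("%d footprint SNP(s) fall outside every DHS region",
                 sum(in_fp & !in_dhs)))
  }
  cat_col <- if ("category" %in% names(snps)) snps$category else
    rep("footprint", nrow(snps))
  nested <- dplyr::case_when(
    in_fp & cat_col == "switch" ~ "switch",
    in_fp & cat_col == "effect" ~ "effect",
    in_fp ~ "footprint",
    in_dhs ~ "dhs",
    TRUE ~ "none"
  )
  out <- dplyr::mutate(snps, nested_category = nested)
  counts <- tibble::tibble(
    category = c("dhs", "footprint", "effect", "switch"),
    n = c(sum(in_dhs | in_fp),
          sum(nested %in% c("footprint", "effect", "switch")),
          sum(nested %in% c("effect", "switch")),
          sum(nested == "switch"))
  )
  attr(out, "counts") <- counts
  out
}

#' Category funnel counts from a nested annotation table
#' @param nested output of [nest_categories()].
#' @return tibble of cumulative counts per nested category.
#' @export
category_funnel <- function(nested) {
  attr(nested, "counts")
}
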