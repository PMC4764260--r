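# Motif-wise selection signals on TF binding sites: a modified
# McDonald-Kreitman contrast of functional vs silent changes among fixed
# interspecies differences and within-species polymorphisms, plus the
# derived-allele-frequency (DAF) spectrum enrichment.

#' Classify an orthologous binding site by divergence class
#'
#' Compares the strand-resolved human motif sequence with its ortholog.
#' Identical sequences are `identical`; otherwise the site is
#' `divergent_functional` when the prior log odds of binding change by at
#' least `ln_fold_threshold` between species (`|beta1 * (S_human -
#' S_ortholog)|`, analogous to effect-SNPs, i.e. a >= 20-fold change),
#' else `divergent_silent`.
#'
#' @param sequence,ortholog_seq strand-resolved motif sequences of equal
#'   length (vectors recycle).
#' @param sm score matrix for the motif.
#' @param beta logistic prior coefficients `(beta0, beta1)`.
#' @param ln_fold_threshold natural-log-odds threshold (default 3).
#' @return character vector in `c("identical", "divergent_functional",
#'   "divergent_silent")`; NA with a warning count attribute for length
#'   mismatches (alignment failures are dropped, not scored).
#' @export
classify_divergence <- function(sequence, ortholog_seq, sm, beta,
                                ln_fold_threshold = 3) {
  n <- max(length(sequence), length(ortholog_seq))
  sequence <- rep_len(toupper(sequence), n)
  ortholog_seq <- rep_len(toupper(ortholog_seq), n)
  out <- rep(NA_character_, n)
  bad <- nchar(sequence) != nchar(ortholog_seq) |
    nchar(ortholog_seq) != sm$width
  if (any(bad)) {
    warn(sprintf("%d ortholog sequence(s) misaligned; dropped", sum(bad)))
  }
  same <- !bad & sequence == ortholog_seq
  out[same] <- "identical"
  idx <- which(!bad & !same)
  if (length(idx)) {
    d <- vapply(idx, function(i) {
      abs(beta[2] * (score_sequence(sm, sequence[i]) -
                       score_sequence(sm, ortholog_seq[i])))
    }, numeric(1))
    out[idx] <- ifelse(d >= ln_fold_threshold,
                       "divergent_functional", "divergent_silent")
  }
  out
}

#' Modified McDonald-Kreitman selection score per motif
#'
#' `score = log2((D_f + ps) / (D_s + ps)) - log2((P_f + ps) / (P_s + ps))`
#' with Haldane pseudocount `ps`: positive scores indicate an excess of
#' fixed functional changes (suggestive of positive selection), negative
#' scores an excess of functional polymorphism (suggestive of weak
#' purifying selection).  Each motif's 2x2 table also gets a Fisher
#' exact p-value and a Benjamini-Hochberg q-value across motifs.
#'
#' @param counts tibble with motif_id, D_f, D_s, P_f, P_s (divergent /
#'   polymorphic x functional / silent site counts).
#' @param pseudocount Haldane correction (default 0.5).
#' @param min_sites motifs with fewer total classified sites are dropped
#'   (default 100).
#' @return tibble with score, fisher_p, q (BH) per retained motif.
#' @export
mk_selection_score <- function(counts, pseudocount = 0.5, min_sites = 100) {
  stopifnot(all(c("motif_id", "D_f", "D_s", "P_f", "P_s") %in% names(counts)))
  cols <- c("D_f", "D_s", "P_f", "P_s")
  if (any(as.matrix(counts[cols]) < 0)) {
    stop_footvar("negative MK counts", "footvar_input")
  }
  total <- rowSums(counts[cols])
  kept <- counts[total >= min_sites & total > 0, , drop = FALSE]
  if (nrow(kept) == 0) {
    stop_footvar("no motif has enough classified sites", "footvar_insufficient_data")
  }
  ps <- pseudocount
  kept |>
    dplyr::mutate(
      score = log2((.data$D_f + ps) / (.data$D_s + ps)) -
        log2((.data$P_f + ps) / (.data$P_s + ps)),
      fisher_p = purrr::pmap_dbl(
        list(.data$D_f, .data$D_s, .data$P_f, .data$P_s),
        function(df_, ds_, pf_, ps_) {
          fisher.test(matrix(c(df_, ds_, pf_, ps_), 2, 2))$p.value
        }),
      q = p.adjust(.data$fisher_p, method = "BH")
    )
}

#' DAF x selection-score enrichment table
#'
#' Bins SNPs jointly by derived allele frequency and motif selection
#' score; each cell's enrichment is the observed joint proportion over
#' the product of the two marginal proportions (1 = independence).
#' Cells in an empty row or column are NA, not an error.
#'
#' @param snps tibble with `daf` in (0, 1) and `score` (the motif's
#'   selection score for the site's motif).
#' @param daf_breaks,score_breaks bin edges (passed to [cut()]).
#' @return object of class `daf_table` with `counts`, `joint`,
#'   `enrichment` matrices (DAF bins x score bins).
#' @export
daf_enrichment <- function(snps,
                           daf_breaks = c(0, 0.01, 0.05, 0.2, 0.5, 1),
                           score_breaks = c(-Inf, -0.5, 0, 0.5, Inf)) {
  stopifnot(all(c("daf", "score") %in% names(snps)))
  if (any(snps$daf <= 0 | snps$daf >= 1, na.rm = TRUE)) {
    stop_footvar("DAF must lie strictly in (0, 1)", "footvar_input")
  }
  daf_bin <- cut(snps$daf, daf_breaks, include.lowest = TRUE)
  score_bin <- cut(snps$score, score_breaks, include.lowest = TRUE)
  counts <- table(daf_bin, score_bin)
  n <- sum(counts)
  joint <- counts / n
  row_m <- rowSums(joint)
  col_m <- colSums(joint)
  expected <- outer(row_m, col_m)
  enrichment <- matrix(NA_real_, nrow(joint), ncol(joint),
                       dimnames = dimnames(joint))
  ok <- expected > 0
  enrichment[ok] <- joint[ok] / expected[ok]
  structure(list(counts = unclass(counts), joint = unclass(joint),
                 enrichment = enrichment, n = n),
            class = "daf_table")
}

#' @export
print.daf_table <- function(x, ...) {
  cat("<daf_table> ", x$n, " SNPs; enrichment (obs / expected):\n", sep = "")
  print(round(x$enrichment, 3))
  invisible(x)
}

#' Plot a DAF enrichment table
#' @param object a [daf_enrichment()] result.
#' @param ... unused.
#' @return a ggplot tile map of log2 enrichments.
#' @method autoplot daf_table
#' @export
autoplot.daf_table <- function(object, ...) {
  df <- as.data.frame(as.table(object$enrichment))
  names(df) <- c("daf_bin", "score_bin", "enrichment")
  ggplot(df, aes(x = .data$score_bin, y = .data$daf_bin,
                 fill = log2(.data$enrichment))) +
    geom_tile() +
    scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                         midpoint = 0, na.value = "grey80") +
    labs(x = "selection score bin", y = "DAF bin",
         fill = "log2 obs/exp") +
    theme_minimal()
}

#' Tabulate MK counts from classified binding sites
#'
#' Aggregates per-site divergence / polymorphism classes into the 2x2
#' counts per motif expected by [mk_selection_score()].  Divergent sites
#' carry `divergence_class` from [classify_divergence()]; polymorphic
#' sites carry a SNP `category` from [classify_category()] (effect or
#' switch = functional, footprint = silent).
#'
#' @param sites tibble with motif_id, and per site either
#'   `divergence_class` or `category` (NA for the other).
#' @return tibble with motif_id, D_f, D_s, P_f, P_s.
#' @export
mk_count_sites <- function(sites) {
  stopifnot("motif_id" %in% names(sites))
  div <- sites$divergence_class %||% rep(NA_character_, nrow(sites))
  pol <- sites$category %||% rep(NA_character_, nrow(sites))
  tibble::tibble(
    motif_id = sites$motif_id,
    D_f = !is.na(div) & div == "divergent_functional",
    D_s = !is.na(div) & div == "divergent_silent",
    P_f = is.na(div) & !is.na(pol) & pol %in% c("effect", "switch"),
    P_s = is.na(div) & !is.na(pol) & pol == "footprint"
  ) |>
    dplyr::group_by(.data$motif_id) |>
    dplyr::summarise(dplyr::across(c("D_f", "D_s", "P_f", "P_s"), sum),
                     .groups = "drop")
}
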