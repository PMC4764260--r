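#' Scan a sequence for motif matches on both strands
#'
#' Slides the log-odds matrix over every window of the sequence and its
#' reverse complement and keeps windows scoring at least `min_score`.
#' Minus-strand windows are scored on the reverse complement of the
#' genomic window; the `sequence` column is always strand-resolved (reads
#' 5'->3' on the matching strand).  Windows containing N are skipped.
#'
#' @param sequence character scalar (genomic, forward strand) or a named
#'   character vector of several contigs.
#' @param sm a [pwm_log_odds()] score matrix.
#' @param min_score minimum match score kept (natural-log odds).
#' @param chrom contig name used when `sequence` is unnamed.
#' @return tibble with columns chrom, start (0-based), end (exclusive),
#'   strand, score, sequence, motif_id, sorted by (chrom, start, strand).
#' @export
scan_sequence <- function(sequence, sm, min_score, chrom = "seq1") {
  stopifnot(inherits(sm, "score_matrix"))
  if (!is.finite(min_score)) {
    if (is.infinite(min_score) && min_score > 0) {
      return(empty_match_tbl(sm$motif_id))
    }
    min_score <- -Inf
  }
  if (is.null(names(sequence))) names(sequence) <- c(chrom, paste0(chrom, "_", seq_along(sequence)))[seq_along(sequence)]
  out <- purrr::map(names(sequence), function(chr) {
    scan_one_contig(sequence[[chr]], sm, min_score, chr)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) return(empty_match_tbl(sm$motif_id))
  dplyr::arrange(res, .data$chrom, .data$start, .data$strand)
}

empty_match_tbl <- function(motif_id) {
  tibble::tibble(chrom = character(), start = integer(), end = integer(),
                 strand = character(), score = numeric(),
                 sequence = character(), motif_id = character())
}

scan_one_contig <- function(sequence, sm, min_score, chrom) {
  w <- sm$width
  codes <- seq_to_codes(sequence)
  n_win <- length(codes) - w + 1
  if (n_win < 1) return(empty_match_tbl(sm$motif_id))

  window_scores <- function(S) {
    acc <- numeric(n_win)
    for (j in seq_len(w)) {
      acc <- acc + S[cbind(codes[seq_len(n_win) + j - 1L], j)]
    }
    acc
  }
  fwd <- window_scores(sm$scores)
  rev_ <- window_scores(revcomp_score_matrix(sm)$scores)

  keep_f <- which(!is.na(fwd) & fwd >= min_score)
  keep_r <- which(!is.na(rev_) & rev_ >= min_score)
  if (length(keep_f) + length(keep_r) == 0) return(empty_match_tbl(sm$motif_id))

  win_seq <- function(i) substr(sequence, i, i + w - 1)
  f_tbl <- tibble::tibble(
    chrom = chrom, start = keep_f - 1L, end = keep_f + w - 1L,
    strand = "+", score = fwd[keep_f],
    sequence = toupper(vapply(keep_f, win_seq, character(1))),
    motif_id = sm$motif_id
  )
  r_tbl <- tibble::tibble(
    chrom = chrom, start = keep_r - 1L, end = keep_r + w - 1L,
    strand = "-", score = rev_[keep_r],
    sequence = revcomp(toupper(vapply(keep_r, win_seq, character(1)))),
    motif_id = sm$motif_id
  )
  dplyr::bind_rows(f_tbl, r_tbl)
}

#' Score an allele substituted into a motif match
#'
#' Substitutes `allele` (given on the genome forward strand) at 0-based
#' genomic position `pos0` inside the match and returns the new match
#' score.  For minus-strand matches the base is complemented and the
#' motif column mirrored.  Substituting the base already present returns
#' the match score unchanged.
#'
#' @param match one-row data frame (or list) with start, end, strand,
#'   score, sequence as produced by [scan_sequence()].
#' @param sm the score matrix the match was scored with.
#' @param pos0 0-based genomic position of the variant.
#' @param allele single base A/C/G/T on the forward strand.
#' @return numeric score of the match with the allele substituted.
#' @export
score_allele <- function(match, sm, pos0, allele) {
  if (is.data.frame(match)) match <- as.list(match[1, ])
  offset <- pos0 - match$start
  if (is.na(offset) || offset < 0 || offset >= sm$width) {
    stop_footvar("variant position outside the motif match", "footvar_out_of_window")
  }
  allele <- toupper(allele)
  if (!allele %in% DNA_BASES) {
    stop_footvar("allele must be a single A/C/G/T base", "footvar_bad_allele")
  }
  if (match$strand == "+") {
    col <- offset + 1L
    base_new <- allele
  } else {
    col <- sm$width - offset
    base_new <- chartr("ACGT", "TGCA", allele)
  }
  base_old <- substr(match$sequence, col, col)
  unname(match$score - sm$scores[base_old, col] + sm$scores[base_new, col])
}

#' Per-allele scores for a table of (match, variant) pairs
#'
#' Vectorised convenience over [score_allele()]: every row must carry the
#' match fields plus `pos0`, `ref`, `alt` (forward-strand alleles).
#'
#' @param df data frame of match rows joined with variants.
#' @param sm score matrix.
#' @return `df` with `score_ref` and `score_alt` columns added.
#' @export
score_alleles <- function(df, sm) {
  stopifnot(all(c("start", "strand", "sequence", "score", "pos0", "ref", "alt")
                %in% names(df)))
  sub_one <- function(start, strand, sequence, score, pos0, allele) {
    score_allele(list(start = start, strand = strand, sequence = sequence,
                      score = score), sm, pos0, allele)
  }
  df$score_ref <- purrr::pmap_dbl(
    list(df$start, df$strand, df$sequence, df$score, df$pos0, df$ref), sub_one)
  df$score_alt <- purrr::pmap_dbl(
    list(df$start, df$strand, df$sequence, df$score, df$pos0, df$alt), sub_one)
  df
}

#' Recalibrate a PWM from footprinted motif matches
#'
#' Rebuilds the count matrix from the strand-resolved sequences of all
#' matches whose footprint posterior exceeds `posterior_cutoff`, mirroring
#' the recalibration of active motifs from sites with a DNase-seq
#' footprint (posterior > 0.99).
#'
#' @param sites data frame with columns `sequence` (strand-resolved, all
#'   of motif width) and `posterior`.
#' @param posterior_cutoff sites above this footprint posterior are used.
#' @param pseudocount,background passed to [new_pwm()].
#' @param min_sites minimum number of passing sites required.
#' @param motif_id identifier for the recalibrated model.
#' @return a `pwm` built from the passing-site base frequencies.
#' @export
recalibrate_pwm <- function(sites, posterior_cutoff = 0.99, pseudocount = 1,
                            background = rep(0.25, 4), min_sites = 100,
                            motif_id = "recalibrated") {
  stopifnot(all(c("sequence", "posterior") %in% names(sites)))
  pass <- sites$sequence[sites$posterior > posterior_cutoff]
  if (length(pass) < min_sites) {
    stop_footvar(
      sprintf("only %d sites pass posterior > %g (min_sites = %d); keeping seed PWM",
              length(pass), posterior_cutoff, min_sites),
      "footvar_insufficient_data"
    )
  }
  w <- unique(nchar(pass))
  if (length(w) != 1) {
    stop_footvar("passing sequences differ in length", "footvar_format")
  }
  mat <- do.call(rbind, strsplit(toupper(pass), "", fixed = TRUE))
  counts <- vapply(seq_len(w), function(j) {
    tabulate(match(mat[, j], DNA_BASES), nbins = 4)
  }, numeric(4))
  new_pwm(counts, motif_id = motif_id, pseudocount = pseudocount,
          background = background)
}

#' PWM score threshold implied by a prior probability floor
#'
#' Inverts the logistic sequence prior: returns the score `S*` with
#' `beta0 + beta1 * S* = logit(prior_min)`, the rescan threshold
#' corresponding to a prior probability of binding of `prior_min`
#' (default 10%).
#'
#' @param beta length-2 numeric `(beta0, beta1)` from the logistic prior.
#' @param prior_min prior probability floor in (0, 1).
#' @return numeric score threshold.
#' @export
prior_threshold_score <- function(beta, prior_min = 0.10) {
  stopifnot(length(beta) == 2, prior_min > 0, prior_min < 1)
  if (!is.finite(beta[2]) || beta[2] <= 0) {
    stop_footvar(
      "beta1 <= 0: the sequence prior is non-informative, no threshold exists",
      "footvar_noninformative_prior"
    )
  }
  unname((logit(prior_min) - beta[1]) / beta[2])
}
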