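#' Position weight matrix (PWM) objects
#'
#' A `pwm` holds a base x position count matrix together with the
#' pseudocount-smoothed probability matrix and the background base
#' frequencies.  Columns of `probs` always sum to one; with a positive
#' pseudocount every cell is strictly positive, so log-odds scores are
#' finite.
#'
#' @param counts 4 x width numeric matrix of non-negative counts, rows in
#'   A, C, G, T order.
#' @param motif_id character identifier.
#' @param pseudocount non-negative smoothing constant added to every cell.
#' @param background length-4 base frequency vector (A, C, G, T), summing
#'   to 1.  Default uniform.
#' @return An object of class `pwm` with fields `motif_id`, `counts`,
#'   `probs`, `pseudocount`, `background`.
#' @export
new_pwm <- function(counts, motif_id = "motif", pseudocount = 1,
                    background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) {
    stop_footvar("PWM counts must have 4 rows (A, C, G, T)", "footvar_format")
  }
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop_footvar("PWM counts must be finite and non-negative", "footvar_format")
  }
  if (pseudocount < 0) {
    stop_footvar("pseudocount must be >= 0", "footvar_format")
  }
  if (length(background) != 4 || any(background <= 0)) {
    stop_footvar("background must be 4 positive frequencies", "footvar_format")
  }
  background <- background / sum(background)
  tot <- colSums(counts) + 4 * pseudocount
  if (any(tot == 0)) {
    stop_footvar(
      "all-zero PWM column with pseudocount 0 is degenerate",
      "footvar_degenerate_column"
    )
  }
  probs <- sweep(counts + pseudocount, 2, tot, "/")
  rownames(counts) <- rownames(probs) <- DNA_BASES
  structure(
    list(motif_id = motif_id, counts = counts, probs = probs,
         pseudocount = pseudocount, background = background),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$motif_id, ": ", ncol(x$counts), " positions, pseudocount ",
      x$pseudocount, "\n", sep = "")
  cat("consensus:", pwm_consensus(x), "\n")
  invisible(x)
}

#' Consensus sequence (highest-probability base per column)
#' @param pwm a [new_pwm()] object.
#' @return character scalar.
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$probs, 2, which.max)], collapse = "")
}

#' Width (number of positions) of a PWM or score matrix
#' @param x a `pwm` or `score_matrix`.
#' @return integer width.
#' @export
pwm_width <- function(x) {
  if (inherits(x, "score_matrix")) x$width else ncol(x$counts)
}

#' Parse a PWM record in JASPAR or TRANSFAC count dialect
#'
#' Accepts a single motif record as text.  Dialects are auto-detected:
#' JASPAR rows look like `A [ 4 19 0 ]` (optionally preceded by a `>`
#' header); TRANSFAC blocks have a `PO`/`P0` header with A C G T columns
#' and numbered position rows; a bare numeric matrix is interpreted as
#' base-rows if it has 4 rows, base-columns if it has 4 columns.
#'
#' @param text character scalar or vector of lines holding one record.
#' @param pseudocount,background passed to [new_pwm()].
#' @param motif_id identifier override; default taken from the record
#'   header when present.
#' @return a [new_pwm()] object whose `probs` obey
#'   `(counts + pseudocount) / (colSums(counts) + 4 * pseudocount)`.
#' @export
parse_pwm <- function(text, pseudocount = 1, background = rep(0.25, 4),
                      motif_id = NULL) {
  lines <- if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") & lines != "//" &
                   !grepl("^XX$", lines)]
  if (length(lines) == 0) stop_footvar("empty PWM record", "footvar_format")

  id <- motif_id
  header <- grepl("^>", lines)
  if (any(header)) {
    if (is.null(id)) {
      id <- strsplit(sub("^>\\s*", "", lines[which(header)[1]]), "\\s+")[[1]][1]
    }
    lines <- lines[!header]
  }

  base_row <- grepl("^[ACGTacgt]\\b", lines) | grepl("^[ACGTacgt]\\s*\\[", lines)
  po_row <- grepl("^(PO|P0)\\b", lines)

  if (sum(base_row) == 4) {
    # JASPAR-style: one row per base, in any order
    parsed <- lapply(lines[base_row], function(l) {
      base <- toupper(substr(l, 1, 1))
      nums <- gsub("[\\[\\]]", " ", sub("^[ACGTacgt]", "", l), perl = TRUE)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(nums), "\\s+")[[1]]))
      if (anyNA(vals)) stop_footvar("non-numeric PWM entry", "footvar_format")
      list(base = base, vals = vals)
    })
    lens <- vapply(parsed, function(p) length(p$vals), integer(1))
    if (length(unique(lens)) != 1) {
      stop_footvar("ragged PWM matrix: base rows differ in length", "footvar_format")
    }
    counts <- matrix(0, 4, lens[1], dimnames = list(DNA_BASES, NULL))
    for (p in parsed) counts[p$base, ] <- p$vals
  } else if (any(po_row) || !any(base_row)) {
    # TRANSFAC-style (position rows, A C G T columns) or bare matrix
    if (any(po_row)) {
      hdr <- strsplit(lines[which(po_row)[1]], "\\s+")[[1]][-1]
      col_order <- match(DNA_BASES, toupper(hdr))
      if (anyNA(col_order)) stop_footvar("TRANSFAC header lacks A C G T", "footvar_format")
      lines <- lines[-seq_len(which(po_row)[1])]
    } else {
      col_order <- 1:4
    }
    lines <- lines[!grepl("^[A-Za-z]{2}", lines)]  # drop ID/BF-style tag lines
    rows <- lapply(lines, function(l) {
      toks <- strsplit(l, "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(toks))
      vals[!is.na(vals)]
    })
    rows <- rows[vapply(rows, length, integer(1)) > 0]
    if (length(rows) == 0) stop_footvar("no numeric PWM rows found", "footvar_format")
    lens <- vapply(rows, length, integer(1))
    if (length(unique(lens)) != 1) {
      stop_footvar("ragged PWM matrix", "footvar_format")
    }
    m <- do.call(rbind, rows)
    if (ncol(m) == 5) m <- m[, -1, drop = FALSE]  # numbered position rows
    if (ncol(m) == 4) {
      counts <- t(m[, col_order, drop = FALSE])
    } else if (nrow(m) == 4) {
      counts <- m
    } else {
      stop_footvar("PWM matrix must have 4 base rows or 4 base columns",
                   "footvar_format")
    }
    rownames(counts) <- DNA_BASES
  } else {
    stop_footvar("unrecognised PWM dialect", "footvar_format")
  }

  new_pwm(counts, motif_id = id %||% "motif", pseudocount = pseudocount,
          background = background)
}

#' Read all PWM records from a file
#'
#' Splits a multi-record JASPAR (`>`-delimited) or TRANSFAC (`//`-delimited)
#' file and parses each record.
#'
#' @param path file path.
#' @inheritParams parse_pwm
#' @return named list of `pwm` objects.
#' @export
read_pwms <- function(path, pseudocount = 1, background = rep(0.25, 4)) {
  lines <- readLines(path)
  if (any(grepl("^>", lines))) {
    idx <- cumsum(grepl("^>", lines))
    recs <- split(lines[idx > 0], idx[idx > 0])
  } else {
    idx <- cumsum(c(TRUE, head(lines, -1) == "//"))
    recs <- split(lines, idx)
  }
  pwms <- lapply(recs, parse_pwm, pseudocount = pseudocount,
                 background = background)
  names(pwms) <- vapply(pwms, function(p) p$motif_id, character(1))
  pwms
}

#' Write a PWM as JASPAR-style text
#'
#' @param pwm a `pwm` object.
#' @param path optional file; when NULL the text is returned invisibly.
#' @return character vector of lines, invisibly.
#' @export
write_pwm <- function(pwm, path = NULL) {
  fmt <- function(v) paste(format(v, trim = TRUE, scientific = FALSE), collapse = " ")
  lines <- c(
    paste0(">", pwm$motif_id),
    vapply(seq_along(DNA_BASES), function(b) {
      paste0(DNA_BASES[b], " [ ", fmt(pwm$counts[b, ]), " ]")
    }, character(1))
  )
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Log-odds score matrix of a PWM
#'
#' Per-cell natural-log odds of each base against the background:
#' `scores[b, j] = ln(probs[b, j] / background[b])`.  The maximal
#' attainable match score is the column-wise maximum sum.
#'
#' @param pwm a `pwm` with strictly positive probabilities.
#' @return an object of class `score_matrix` with fields `motif_id`,
#'   `scores` (4 x width), `width`, `background`.
#' @export
pwm_log_odds <- function(pwm) {
  if (any(pwm$probs <= 0)) {
    stop_footvar(
      "zero probability cell: log-odds undefined (use pseudocount > 0)",
      "footvar_undefined_score"
    )
  }
  scores <- log(pwm$probs / pwm$background)
  structure(
    list(motif_id = pwm$motif_id, scores = scores, width = ncol(scores),
         background = pwm$background),
    class = "score_matrix"
  )
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("<score_matrix> ", x$motif_id, ": width ", x$width,
      ", max score ", round(sum(apply(x$scores, 2, max)), 3), "\n", sep = "")
  invisible(x)
}

# Reverse-complemented score matrix: scoring the forward strand with it
# equals scoring the reverse complement with the original.
revcomp_score_matrix <- function(sm) {
  s <- sm$scores[4:1, sm$width:1, drop = FALSE]
  rownames(s) <- DNA_BASES
  out <- sm
  out$scores <- s
  out
}

#' Score a single sequence against a score matrix
#'
#' @param sm a `score_matrix`.
#' @param sequence character scalar of length `sm$width` over A/C/G/T.
#' @return numeric score (sum of per-column log odds).
#' @export
score_sequence <- function(sm, sequence) {
  codes <- seq_to_codes(sequence)
  if (length(codes) != sm$width) {
    stop_footvar("sequence length must equal motif width", "footvar_format")
  }
  if (anyNA(codes)) return(NA_real_)
  sum(sm$scores[cbind(codes, seq_len(sm$width))])
}
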