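# Readers and writers for the standard formats.  Internal coordinates
# are 0-based half-open; VCF input is converted from 1-based on read.
# Every file this package writes carries a `#` comment line declaring
# its coordinate convention.

COORD_COMMENT <- "# coords: 0-based half-open"

#' Read FASTA sequences
#' @param path FASTA file (optionally gzipped).
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write FASTA sequences
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a VCF of SNPs
#'
#' Positions are converted to 0-based (`pos0 = POS - 1`); multi-allelic
#' records are decomposed into one biallelic row per alternate allele.
#' `AF` and `AA` INFO fields are extracted when present.
#'
#' @param path VCF path (plain or bgzip).
#' @return tibble with chrom, pos0, id, ref, alt, af, aa.
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) {
    fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  }
  fx <- as.data.frame(fx, stringsAsFactors = FALSE)
  info_field <- function(key) {
    val <- vcfR::extract.info(v, element = key)
    if (is.null(val)) rep(NA_character_, nrow(fx)) else val
  }
  out <- tibble::tibble(
    chrom = fx$CHROM,
    pos0 = as.integer(fx$POS) - 1L,
    id = fx$ID,
    ref = toupper(fx$REF),
    alt = toupper(fx$ALT),
    af = unname(suppressWarnings(as.numeric(info_field("AF")))),
    aa = unname(toupper(info_field("AA")))
  )
  tidyr::separate_longer_delim(out, "alt", delim = ",")
}

#' Write a minimal SNP VCF
#'
#' @param variants tibble with chrom, pos0, ref, alt and optional id,
#'   af, aa columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path) {
  id <- variants[["id"]] %||% rep(".", nrow(variants))
  info <- rep(".", nrow(variants))
  has_af <- !is.null(variants[["af"]])
  has_aa <- !is.null(variants[["aa"]])
  if (has_af || has_aa) {
    info <- purrr::map_chr(seq_len(nrow(variants)), function(i) {
      parts <- character(0)
      if (has_af && is.finite(variants$af[i])) {
        parts <- c(parts, sprintf("AF=%g", variants$af[i]))
      }
      if (has_aa && !is.na(variants$aa[i])) {
        parts <- c(parts, paste0("AA=", variants$aa[i]))
      }
      if (length(parts)) paste(parts, collapse = ";") else "."
    })
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele frequency\">",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t%s",
                  variants$chrom, variants$pos0 + 1L, id,
                  variants$ref, variants$alt, info)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a BED file (0-based half-open)
#'
#' Plain 3-6 column BED; `#`, `track` and `browser` lines are skipped.
#'
#' @param path BED path (optionally gzipped).
#' @return tibble with chrom, start, end and, when present, name,
#'   score, strand.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- min(lengths(fields))
  get <- function(i) vapply(fields, `[[`, character(1), i)
  out <- tibble::tibble(
    chrom = get(1),
    start = as.integer(get(2)),
    end = as.integer(get(3))
  )
  if (ncol >= 4) out$name <- get(4)
  if (ncol >= 5) out$score <- suppressWarnings(as.numeric(get(5)))
  if (ncol >= 6) out$strand <- get(6)
  out
}

#' Write intervals as BED
#'
#' @param df tibble with chrom, start, end and optional name, score,
#'   strand columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(df))
  writeLines(COORD_COMMENT, path)
  readr::write_tsv(df[cols], path, append = TRUE, col_names = FALSE)
  invisible(path)
}

#' Write motif matches as 6-column BED
#'
#' Scores are stored as `round(score * 100)` in the BED score column.
#'
#' @param matches tibble from [scan_sequence()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_match_bed <- function(matches, path) {
  df <- tibble::tibble(
    chrom = matches$chrom, start = matches$start, end = matches$end,
    name = matches$motif_id,
    score = as.integer(round(matches$score * 100)),
    strand = matches$strand
  )
  write_bed(df, path)
}

#' Write a cut-count matrix as TSV
#'
#' Header row: site_id then F0..F(w-1), R0..R(w-1) positions.
#'
#' @param cm a [new_cut_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cut_matrix <- function(cm, path) {
  w <- cm$window
  df <- tibble::as_tibble(cm$counts, .name_repair = "minimal")
  names(df) <- c(paste0("F", seq_len(w) - 1L), paste0("R", seq_len(w) - 1L))
  df <- dplyr::bind_cols(tibble::tibble(site_id = cm$site_ids), df)
  writeLines(c(COORD_COMMENT,
               sprintf("# window=%d flank=%s", w, cm$flank)), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a cut-count matrix TSV written by [write_cut_matrix()]
#' @param path TSV path.
#' @return a `cut_matrix`.
#' @export
read_cut_matrix <- function(path) {
  hdr <- readLines(path, n = 5)
  flank <- NA_integer_
  m <- regmatches(hdr, regexpr("flank=([0-9]+)", hdr))
  if (length(m)) flank <- as.integer(sub("flank=", "", m[1]))
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  counts <- as.matrix(df[, -1])
  new_cut_matrix(counts, site_ids = df$site_id, window = ncol(counts) / 2,
                 flank = flank)
}

#' Read an allelic count table
#'
#' TSV with columns chrom, pos1 (1-based), ref, alt, n_ref, n_alt,
#' n_other, af; positions are converted to 0-based.
#'
#' @param path TSV path.
#' @return tibble with pos0 and the count columns.
#' @export
read_allele_counts <- function(path) {
  df <- readr::read_tsv(
    path, comment = "#",
    col_names = c("chrom", "pos1", "ref", "alt", "n_ref", "n_alt",
                  "n_other", "af"),
    col_types = "cicciiid", progress = FALSE)
  dplyr::mutate(df, pos0 = .data$pos1 - 1L, pos1 = NULL)
}

#' Write an allelic count table (1-based positions)
#' @param counts tibble with chrom, pos0, ref, alt, n_ref, n_alt,
#'   n_other, af.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_allele_counts <- function(counts, path) {
  df <- tibble::tibble(
    chrom = counts$chrom, pos1 = counts$pos0 + 1L,
    ref = counts$ref, alt = counts$alt,
    n_ref = counts$n_ref, n_alt = counts$n_alt,
    n_other = counts$n_other %||% 0L, af = counts$af
  )
  writeLines("# coords: 1-based positions (pos1)", path)
  readr::write_tsv(df, path, append = TRUE, col_names = FALSE)
  invisible(path)
}

#' Serialise a centipede fit as flat key-value text
#' @param fit a `centipede_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_centipede_fit <- function(fit, path) {
  num <- function(x) paste(format(x, digits = 10), collapse = ",")
  lines <- c(
    COORD_COMMENT,
    paste0("beta0=", num(fit$beta[1])),
    paste0("beta1=", num(fit$beta[2])),
    paste0("beta1_se=", num(fit$beta_se[2])),
    paste0("z_score=", num(fit$z_score)),
    paste0("mu_bound=", num(fit$nb_bound[["mu"]])),
    paste0("size_bound=", num(fit$nb_bound[["size"]])),
    paste0("mu_unbound=", num(fit$nb_unbound[["mu"]])),
    paste0("size_unbound=", num(fit$nb_unbound[["size"]])),
    paste0("converged=", fit$converged),
    paste0("n_iter=", fit$n_iter),
    paste0("lambda=", num(fit$lambda_fp))
  )
  writeLines(lines, path)
  invisible(path)
}
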