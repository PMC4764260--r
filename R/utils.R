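# Shared numeric and sequence helpers.  All scores and log odds in this
# package are natural-log; coordinates are 0-based half-open internally.

DNA_BASES <- c("A", "C", "G", "T")

sigmoid <- stats::plogis
logit <- stats::qlogis

#' Numerically stable log(exp(a) + exp(b)) for vectors
#' @noRd
log_add <- function(a, b) {
  m <- pmax(a, b)
  # both -Inf -> -Inf without NaN
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of sequences over A/C/G/T/N.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

# Integer codes 1..4 for A,C,G,T; NA for anything else (N etc.)
seq_to_codes <- function(sequence) {
  match(strsplit(toupper(sequence), "", fixed = TRUE)[[1]], DNA_BASES)
}

codes_to_seq <- function(codes) {
  paste(DNA_BASES[codes], collapse = "")
}

stop_footvar <- function(msg, class) {
  rlang::abort(msg, class = c(class, "footvar_error"))
}

check_seed <- function(seed) {
  if (!is.null(seed) && (!is.numeric(seed) || length(seed) != 1 || is.na(seed))) {
    stop_footvar("`seed` must be a single number or NULL", "footvar_bad_seed")
  }
  seed
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream;
# seed = NULL uses the current stream.
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed) %% .Machine$integer.max, expr)
}
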