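# Independent oracles used across the suite.  These deliberately avoid
# the package's vectorised code paths: naive loops and exact enumeration
# only.

# All-windows, both-strands scan by direct per-window rescoring.
naive_scan <- function(sequence, sm, min_score) {
  w <- sm$width
  L <- nchar(sequence)
  rows <- list()
  if (L >= w) {
    for (i in 1:(L - w + 1)) {
      win <- toupper(substr(sequence, i, i + w - 1))
      if (grepl("[^ACGT]", win)) next
      s_f <- score_sequence(sm, win)
      s_r <- score_sequence(sm, revcomp(win))
      if (!is.na(s_f) && s_f >= min_score) {
        rows[[length(rows) + 1]] <- data.frame(
          start = i - 1L, strand = "+", score = s_f, sequence = win)
      }
      if (!is.na(s_r) && s_r >= min_score) {
        rows[[length(rows) + 1]] <- data.frame(
          start = i - 1L, strand = "-", score = s_r, sequence = revcomp(win))
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(), strand = character(),
                      score = numeric(), sequence = character()))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$strand), ]
}

# Exact distribution of the match score of a random background window:
# dynamic programme over columns, merging duplicate sums.
score_dist_dp <- function(sm, background = rep(0.25, 4), digits = 9) {
  dist <- data.frame(s = 0, p = 1)
  for (j in seq_len(sm$width)) {
    cross <- do.call(rbind, lapply(1:4, function(b) {
      data.frame(s = dist$s + sm$scores[b, j], p = dist$p * background[b])
    }))
    key <- round(cross$s, digits)
    dist <- aggregate(p ~ key, cross, sum)
    names(dist) <- c("s", "p")
  }
  dist
}

# P(background window scores >= t), exact.
prob_score_ge <- function(sm, t, background = rep(0.25, 4)) {
  d <- score_dist_dp(sm, background)
  sum(d$p[d$s >= t - 1e-9])
}

# Rank-based AUROC of a score against binary labels.
auroc <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label)
  n0 <- sum(!label)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# A 4-column matrix strongly favouring the non-palindromic consensus ACGG.
toy_pwm <- function() {
  counts <- matrix(2, 4, 4)
  counts[cbind(c(1, 2, 3, 3), 1:4)] <- 94
  new_pwm(counts, motif_id = "TOY_ACGG", pseudocount = 0)
}

# A palindromic variant (consensus ACGT, its own reverse complement).
palindrome_pwm <- function() {
  counts <- matrix(2, 4, 4)
  counts[cbind(1:4, 1:4)] <- 94
  new_pwm(counts, motif_id = "TOY_ACGT", pseudocount = 0)
}

# O(n^2) reference step-up q-value transform.
reference_qvalues <- function(p, pi0) {
  n <- length(p)
  o <- order(p)
  q_sorted <- numeric(n)
  for (i in seq_len(n)) {
    q_sorted[i] <- min(1, min(pi0 * n * p[o][i:n] / (i:n)))
  }
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# Direct beta-binomial sampler (kept independent of the package internals).
rbetabinom_t <- function(n, size, prob, M) {
  rbinom(n, size, rbeta(n, prob * M, (1 - prob) * M))
}

# Brute-force nearest-TSS distance.
brute_tss <- function(snps, tss) {
  vapply(seq_len(nrow(snps)), function(i) {
    tp <- tss$pos0[tss$chrom == snps$chrom[i]]
    if (length(tp) == 0) return(NA_real_)
    min(abs(tp - snps$pos0[i]))
  }, numeric(1))
}
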