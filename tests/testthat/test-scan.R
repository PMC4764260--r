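test_that("scan matches the naive all-windows oracle exactly", {
  sm <- pwm_log_odds(example_pwm())
  set.seed(11)
  seqs <- c(
    paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE), collapse = ""),
    paste(sample(c("A", "C", "G", "T", "N"), 500, replace = TRUE,
                 prob = c(rep(0.24, 4), 0.04)), collapse = "")
  )
  for (s in seqs) {
    for (thr in c(-5, 0, 5)) {
      got <- scan_sequence(s, sm, thr)
      want <- naive_scan(s, sm, thr)
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$start, want$start)
      expect_equal(got$strand, want$strand)
      expect_equal(got$score, want$score, tolerance = 1e-12)
      expect_equal(got$sequence, want$sequence)
    }
  }
})

test_that("scanning is reverse-complement equivariant", {
  sm <- pwm_log_odds(example_pwm())
  set.seed(12)
  s <- paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE), collapse = "")
  a <- scan_sequence(s, sm, 0)
  b <- scan_sequence(revcomp(s), sm, 0)
  expect_equal(nrow(a), nrow(b))
  # mirrored coordinates, flipped strands, identical score multiset
  L <- nchar(s)
  a_m <- a[order(a$start, a$strand), ]
  b_m <- b[order(L - b$end, b$strand), ]
  expect_equal(sort(a$score), sort(b$score), tolerance = 1e-12)
  expect_equal(a_m$start, L - b_m$end)
  expect_equal(a_m$strand, chartr("+-", "-+", b_m$strand))
})

test_that("toy matrix finds the planted site and its reverse complement", {
  sm <- pwm_log_odds(toy_pwm())
  max_s <- sum(apply(sm$scores, 2, max))
  hit <- scan_sequence("TTACGGTT", sm, max_s - 1e-6)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$start, 2L)
  expect_equal(hit$strand, "+")
  expect_equal(hit$sequence, "ACGG")

  rc <- scan_sequence(revcomp("TTACGGTT"), sm, max_s - 1e-6)
  expect_equal(nrow(rc), 1)
  expect_equal(rc$strand, "-")
  expect_equal(rc$score, hit$score)
})

test_that("degenerate scans return empty tibbles, not errors", {
  sm <- pwm_log_odds(toy_pwm())
  expect_equal(nrow(scan_sequence("ACGTACGT", sm, Inf)), 0)   # vacuous threshold
  expect_equal(nrow(scan_sequence("ACG", sm, -100)), 0)       # shorter than width
  expect_equal(nrow(scan_sequence("ANGT", sm, -100)), 0)      # N window skipped
  # palindromic consensus: both strands of the same window are reported
  smp <- pwm_log_odds(palindrome_pwm())
  both <- scan_sequence("NACGTN", smp, sum(apply(smp$scores, 2, max)) - 1e-6)
  expect_equal(nrow(both), 2)
  expect_setequal(both$strand, c("+", "-"))
})

test_that("score_allele is exact substitution arithmetic", {
  sm <- pwm_log_odds(example_pwm())
  set.seed(13)
  s <- paste(sample(c("A", "C", "G", "T"), 800, replace = TRUE), collapse = "")
  m <- scan_sequence(s, sm, 0)
  expect_gt(nrow(m), 2)
  for (i in seq_len(min(nrow(m), 20))) {
    row <- m[i, ]
    for (off in c(0L, 5L, 9L)) {
      pos0 <- row$start + off
      genome_ref <- substr(s, pos0 + 1, pos0 + 1)
      # reference substitution returns the match score exactly
      expect_equal(score_allele(row, sm, pos0, genome_ref), row$score,
                   tolerance = 1e-12)
      # any substitution equals full re-scoring of the mutated window
      for (alt in setdiff(c("A", "C", "G", "T"), genome_ref)) {
        mut <- s
        substr(mut, pos0 + 1, pos0 + 1) <- alt
        win <- substr(mut, row$start + 1, row$end)
        want <- if (row$strand == "+") score_sequence(sm, win) else
          score_sequence(sm, revcomp(win))
        expect_equal(score_allele(row, sm, pos0, alt), want, tolerance = 1e-12)
      }
    }
  }
})

test_that("score_allele arithmetic on a designed column", {
  # column with s(A) = 1.2, s(C) = -0.8: A -> C drops the score by 2
  probs <- exp(c(1.2, -0.8, -2, -2)) * 0.25
  counts <- matrix(probs / sum(probs) * 100, 4, 1)
  sm <- pwm_log_odds(new_pwm(counts, pseudocount = 0))
  shift <- unname(sm$scores["A", 1] - sm$scores["C", 1])
  m <- list(start = 10L, end = 11L, strand = "+",
            score = unname(sm$scores["A", 1]), sequence = "A")
  expect_equal(score_allele(m, sm, 10L, "C"), m$score - shift)
})

test_that("score_allele validates the variant and allele", {
  sm <- pwm_log_odds(toy_pwm())
  m <- list(start = 5L, end = 9L, strand = "+", score = 1, sequence = "ACGT")
  expect_error(score_allele(m, sm, 4L, "A"), class = "footvar_out_of_window")
  expect_error(score_allele(m, sm, 9L, "A"), class = "footvar_out_of_window")
  expect_error(score_allele(m, sm, 6L, "N"), class = "footvar_bad_allele")
})

test_that("recalibration recovers the generating PWM from sampled sites", {
  pwm <- example_pwm()
  set.seed(14)
  n <- 5000
  seqs <- vapply(seq_len(n), function(i) {
    paste(c("A", "C", "G", "T")[apply(pwm$probs, 2, function(p)
      sample.int(4, 1, prob = p))], collapse = "")
  }, character(1))
  sites <- tibble::tibble(sequence = seqs, posterior = 1)
  recal <- recalibrate_pwm(sites, pseudocount = 1, motif_id = "R")
  expect_lt(max(abs(recal$probs - pwm$probs)), 0.02)
})

test_that("recalibration handles degenerate and insufficient inputs", {
  sites <- tibble::tibble(sequence = rep("ACGT", 500), posterior = 1)
  recal <- recalibrate_pwm(sites, pseudocount = 0, motif_id = "D")
  expect_equal(unname(recal$probs[cbind(1:4, 1:4)]), rep(1, 4))

  few <- tibble::tibble(sequence = rep("ACGT", 200),
                        posterior = rep(c(1, 0), c(50, 150)))
  expect_error(recalibrate_pwm(few, posterior_cutoff = 0.99, min_sites = 100),
               class = "footvar_insufficient_data")
  expect_no_error(r2 <- recalibrate_pwm(few, min_sites = 50,
                                        posterior_cutoff = 0.5))
})

test_that("recalibration is stable at its own fixed point", {
  # resampling from a recalibrated model and recalibrating again moves
  # the PWM less and less: from a heavily smoothed start the KL to the
  # next iterate shrinks to sampling noise
  pwm <- example_pwm()
  set.seed(15)
  kl <- function(a, b) sum(a$probs * log(a$probs / b$probs))
  smoothed <- new_pwm(0.3 * pwm$counts + 0.7 * 100, pseudocount = 1)
  cur <- smoothed
  divs <- numeric(3)
  for (it in 1:3) {
    seqs <- vapply(seq_len(3000), function(i) {
      paste(c("A", "C", "G", "T")[apply(cur$probs, 2, function(p)
        sample.int(4, 1, prob = p))], collapse = "")
    }, character(1))
    nxt <- recalibrate_pwm(tibble::tibble(sequence = seqs, posterior = 1),
                           pseudocount = 1, motif_id = "it")
    divs[it] <- kl(cur, nxt)
    cur <- nxt
  }
  expect_lt(divs[3], 0.02)
  expect_lt(divs[3], divs[1] + 0.01)
})

test_that("prior threshold inverts the logistic prior", {
  expect_equal(prior_threshold_score(c(-6, 0.5), 0.1),
               (qlogis(0.1) + 6) / 0.5, tolerance = 1e-9)
  expect_equal(prior_threshold_score(c(-6, 0.5), 0.1), 7.60555, tolerance = 1e-4)
  expect_equal(prior_threshold_score(c(0, 2), 0.5), 0)
  expect_error(prior_threshold_score(c(0, 0), 0.1),
               class = "footvar_noninformative_prior")
  expect_error(prior_threshold_score(c(0, -1), 0.1),
               class = "footvar_noninformative_prior")
})
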