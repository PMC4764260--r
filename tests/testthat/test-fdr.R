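test_that("pi0 estimation tracks the null fraction", {
  withr::with_seed(51, {
    p_null <- runif(10000)
    expect_gte(storey_pi0(p_null), 0.95)
    expect_lte(storey_pi0(p_null), 1.0)
    # pure signal
    expect_lt(storey_pi0(rep(1e-6, 1000)), 0.05)
    # 70/30 null/signal mixture
    p_mix <- c(runif(7000), rbeta(3000, 0.15, 8))
    expect_lt(abs(storey_pi0(p_mix) - 0.7), 0.03)
  })
  expect_error(storey_pi0(runif(50)), class = "footvar_insufficient_data")
  expect_error(storey_pi0(c(0, runif(200))), class = "footvar_input")
})

test_that("q-values match the reference step-up transform", {
  expect_equal(qvalues(0.05, pi0 = 1), 0.05)          # n = 1
  # ties share a q-value
  q <- qvalues(c(0.01, 0.01, 0.5), pi0 = 1)
  expect_equal(q[1], q[2])
  # cross-check against the O(n^2) reference on random input
  withr::with_seed(52, {
    p <- c(runif(800), rbeta(200, 0.2, 8))
    for (pi0 in c(1, 0.7)) {
      expect_equal(qvalues(p, pi0), reference_qvalues(p, pi0),
                   tolerance = 1e-12)
    }
  })
  # monotone in p, and discovery counts nest across thresholds
  p <- sort(runif(500))
  q <- qvalues(p, 0.9)
  expect_true(all(diff(q) >= -1e-12))
  expect_lte(sum(q < 0.2), sum(q < 0.5))
})

test_that("partitioned FDR adjusts within each annotation separately", {
  withr::with_seed(53, {
    df <- tibble::tibble(
      p_value = c(rbeta(300, 0.1, 10), runif(300), runif(300)),
      partition = rep(c("effect", "footprint_only", "dhs_only"), each = 300)
    )
  })
  res <- partitioned_fdr(df)
  s <- partition_summary(res)
  eff <- s[s$partition == "effect", ]
  # signal concentrated in the effect partition drives its discoveries
  expect_gt(eff$n_discoveries, 200)
  expect_lte(sum(s$n_discoveries) - eff$n_discoveries, 3)
  expect_lt(eff$pi0, 0.4)

  # identical p-vector in two partitions with different pi0 gives different q
  p_shared <- runif(200, 0.001, 0.05)
  df2 <- tibble::tibble(
    p_value = c(p_shared, p_shared, runif(400)),
    partition = rep(c("a", "b", "b"), c(200, 200, 400))
  )
  res2 <- suppressWarnings(partitioned_fdr(df2, min_n = 100))
  qa <- res2$q_value[res2$partition == "a"]
  qb <- res2$q_value[res2$partition == "b"][1:200]
  expect_false(isTRUE(all.equal(qa, qb)))

  # NA p-values (untested SNPs) are carried through, not dropped
  df3 <- tibble::tibble(p_value = c(runif(150), NA, NA),
                        partition = "only")
  res3 <- partitioned_fdr(df3)
  expect_true(all(is.na(res3$q_value[151:152])))
  expect_false(any(res3$ash_discovery[151:152]))
})

test_that("motif enrichment ratios are anchored and filtered correctly", {
  df <- tibble::tibble(
    motif_id = c("at_global", "double", "small", "boundary"),
    n_hsnp = c(1000L, 1000L, 99L, 100L),
    n_ash = c(100L, 200L, 99L, 10L)
  )
  res <- ash_enrichment_ratio(df, min_hsnp = 100)
  # motifs at or below the hSNP floor are excluded (> 100 rule)
  expect_setequal(res$motif_id, c("at_global", "double"))
  global <- sum(df$n_ash) / sum(df$n_hsnp)
  expect_equal(res$ratio[res$motif_id == "at_global"], 0.1 / global)
  expect_equal(res$ratio[res$motif_id == "double"], 0.2 / global)
  expect_true(all(res$ci_lo <= res$ratio & res$ratio <= res$ci_hi))
  expect_error(
    ash_enrichment_ratio(tibble::tibble(motif_id = "m", n_hsnp = 200L,
                                        n_ash = 0L)),
    class = "footvar_input")
})

test_that("enrichment ratios are unbiased under the null", {
  withr::with_seed(54, {
    n_h <- rep(500L, 50)
    n_a <- rbinom(50, n_h, 0.1)
    df <- tibble::tibble(motif_id = paste0("m", 1:50), n_hsnp = n_h,
                         n_ash = n_a)
    res <- ash_enrichment_ratio(df)
    expect_lt(abs(mean(res$ratio) - 1), 0.05)
    expect_lt(mean(res$status != "ns"), 0.1)
  })
})

test_that("the effect regression recovers known coefficients", {
  withr::with_seed(55, {
    n <- 8000
    rec <- tibble::tibble(
      C = rnorm(n), F = runif(n, 0, 0.5), T = rexp(n, 1 / 2e4),
      N = rpois(n, 5) + 1, P = rnorm(n)
    )
    truth <- c(`(Intercept)` = -1, C = 0.5, F = -2, T = -2e-5, N = -0.05,
               P = 0.3)
    eta <- truth[1] + as.matrix(rec) %*% truth[-1]
    rec$E <- rbinom(n, 1, plogis(eta))
  })
  fit <- effect_logistic_regression(rec)
  for (i in seq_len(nrow(fit))) {
    expect_lt(abs(fit$estimate[i] - truth[[fit$term[i]]]),
              1.96 * fit$std_error[i] + 1e-8)
  }
  expect_error(effect_logistic_regression(dplyr::mutate(rec, E = 1)),
               class = "footvar_degenerate_data")
  expect_error(effect_logistic_regression(rec[1:20, ]),
               class = "footvar_insufficient_data")
})

test_that("separation triggers the ridge fallback with a warning", {
  rec <- tibble::tibble(C = c(rnorm(40, -3), rnorm(40, 3)),
                        E = rep(0:1, each = 40))
  expect_warning(fit <- effect_logistic_regression(rec), "separation")
  expect_true(all(is.finite(fit$estimate)))
})

test_that("Fisher enrichment wraps the exact hypergeometric test", {
  sym <- fisher_enrichment(matrix(10, 2, 2))
  expect_equal(sym$odds_ratio, 1, tolerance = 1e-9)
  expect_equal(sym$p_value, 1)

  skew <- fisher_enrichment(matrix(c(20, 5, 5, 20), 2, 2))
  expect_lt(skew$p_value, 0.001)
  # exact two-sided hypergeometric enumeration oracle
  m <- matrix(c(20, 5, 5, 20), 2, 2)
  probs <- dhyper(0:25, 25, 25, 25)
  p_exact <- sum(probs[probs <= dhyper(20, 25, 25, 25) * (1 + 1e-7)])
  expect_equal(skew$p_value, p_exact, tolerance = 1e-9)
  # swapping rows inverts the odds ratio, keeps p
  swapped <- fisher_enrichment(matrix(c(5, 20, 20, 5), 2, 2))
  expect_equal(swapped$odds_ratio, 1 / skew$odds_ratio, tolerance = 1e-6)
  expect_equal(swapped$p_value, skew$p_value)
  # zero margin: OR undefined
  zm <- fisher_enrichment(matrix(c(0, 0, 5, 10), 2, 2, byrow = TRUE))
  expect_false(zm$or_defined)
})

test_that("the exact binomial tail matches pbinom and its anchors", {
  expect_equal(binomial_validation_test(10, 21, 0.05),
               pbinom(9, 21, 0.05, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(binomial_validation_test(0, 30, 0.1), 1)
  expect_equal(binomial_validation_test(21, 21, 0.05), 0.05^21,
               tolerance = 1e-12)
  withr::with_seed(56, {
    for (i in 1:20) {
      n <- sample(5:60, 1)
      k <- sample(0:n, 1)
      p0 <- runif(1, 0.01, 0.8)
      expect_equal(binomial_validation_test(k, n, p0),
                   pbinom(k - 1, n, p0, lower.tail = FALSE),
                   tolerance = 1e-11)
    }
  })
})

test_that("TSS distances agree with brute force and handle edge cases", {
  tss <- tibble::tibble(chrom = "chr1", pos0 = c(1000L, 5000L))
  snps <- tibble::tibble(chrom = c("chr1", "chr1", "chr1", "chr2"),
                         pos0 = c(1000L, 1500L, 4800L, 7L))
  d <- tss_distance(snps, tss)
  expect_equal(d[1], 0)          # exactly at a TSS
  expect_equal(d[2], 500)        # nearest of the two
  expect_equal(d[3], 200)
  expect_true(is.na(d[4]))       # chromosome without any TSS

  withr::with_seed(57, {
    snps2 <- tibble::tibble(chrom = sample(c("c1", "c2"), 1000, TRUE),
                            pos0 = sample.int(1e6, 1000))
    tss2 <- tibble::tibble(chrom = sample(c("c1", "c2"), 300, TRUE),
                           pos0 = sample.int(1e6, 300))
  })
  expect_equal(tss_distance(snps2, tss2), brute_tss(snps2, tss2))
})
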