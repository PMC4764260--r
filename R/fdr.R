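# Partitioned FDR over ASH p-values (Storey pi0 + q-values), motif-wise
# ASH enrichment ratios, the binding-effect logistic regression, and the
# generic enrichment tests.

#' Storey estimate of the null proportion pi0
#'
#' `pi0_hat(lambda) = #{p > lambda} / (n (1 - lambda))` over the lambda
#' grid, smoothed by a cubic polynomial and evaluated at the largest
#' lambda, clipped to [0, 1].
#'
#' @param pvalues p-values in (0, 1].
#' @param lambda_grid tuning grid (default 0.05 to 0.95 by 0.05).
#' @param min_n minimum number of p-values (default 100).
#' @return pi0 estimate in [0, 1].
#' @export
storey_pi0 <- function(pvalues, lambda_grid = seq(0.05, 0.95, by = 0.05),
                       min_n = 100) {
  pvalues <- pvalues[!is.na(pvalues)]
  n <- length(pvalues)
  if (n < min_n) {
    stop_footvar(sprintf(
      "only %d p-values (< %d): too few to estimate pi0, consider fixing pi0 = 1",
      n, min_n), "footvar_insufficient_data")
  }
  if (any(pvalues <= 0 | pvalues > 1)) {
    stop_footvar("p-values must lie in (0, 1]", "footvar_input")
  }
  pi0_l <- vapply(lambda_grid,
                  function(l) mean(pvalues > l) / (1 - l), numeric(1))
  fit <- lm(pi0_l ~ poly(lambda_grid, 3))
  pi0 <- predict(fit, newdata = data.frame(lambda_grid = max(lambda_grid)))
  min(max(unname(pi0), 0), 1)
}

#' Storey q-values from p-values and pi0
#'
#' Step-up transform `q_(i) = min_{j >= i} pi0 * n * p_(j) / j`, capped
#' at 1 and returned in the input order (ties share a q-value).
#'
#' @param pvalues p-values in (0, 1].
#' @param pi0 null proportion (default 1, the BH special case).
#' @return q-values aligned with `pvalues`.
#' @export
qvalues <- function(pvalues, pi0 = 1) {
  n <- length(pvalues)
  o <- order(pvalues)
  raw <- pi0 * n * pvalues[o] / seq_len(n)
  q_sorted <- pmin(rev(cummin(rev(raw))), 1)
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

#' Partitioned FDR over disjoint annotation categories
#'
#' Applies [storey_pi0()] and [qvalues()] within each partition
#' independently (SNP categories carry different prior expectations of
#' being functional, so multiple testing is re-adjusted per annotation).
#' An ASH discovery is a SNP with q < `q_cut` in any partition.
#'
#' @param df tibble with a `p_value` column and a `partition` label
#'   column; NA p-values are carried through untested.
#' @param q_cut discovery threshold (default 0.20).
#' @param min_n passed to [storey_pi0()]; partitions smaller than this
#'   fall back to pi0 = 1 with a warning.
#' @return `df` with `pi0` and `q_value` columns plus an `ash_discovery`
#'   flag; partition summaries via [partition_summary()].
#' @export
partitioned_fdr <- function(df, q_cut = 0.20, min_n = 100) {
  stopifnot(all(c("p_value", "partition") %in% names(df)))
  parts <- split(seq_len(nrow(df)), df$partition)
  pi0_v <- rep(NA_real_, nrow(df))
  q_v <- rep(NA_real_, nrow(df))
  for (lab in names(parts)) {
    idx <- parts[[lab]]
    p <- df$p_value[idx]
    tested <- which(!is.na(p))
    if (length(tested) == 0) {
      warn(sprintf("partition '%s' has no tested p-values; skipped", lab))
      next
    }
    pi0 <- tryCatch(storey_pi0(p[tested], min_n = min_n),
                    footvar_insufficient_data = function(e) {
                      warn(sprintf("partition '%s': %s", lab, conditionMessage(e)))
                      1
                    })
    pi0_v[idx] <- pi0
    q_v[idx[tested]] <- qvalues(p[tested], pi0)
  }
  dplyr::mutate(df, pi0 = pi0_v, q_value = q_v,
                ash_discovery = !is.na(q_v) & q_v < q_cut)
}

#' Per-partition summary of a partitioned FDR run
#' @param df output of [partitioned_fdr()].
#' @param q_cut discovery threshold used in the summary.
#' @return tibble with partition, n tested, pi0, discoveries.
#' @export
partition_summary <- function(df, q_cut = 0.20) {
  df |>
    dplyr::group_by(.data$partition) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_tested = sum(!is.na(.data$p_value)),
      pi0 = dplyr::first(.data$pi0),
      n_discoveries = sum(.data$q_value < q_cut, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Motif-wise ASH enrichment ratios
#'
#' For each motif with more than `min_hsnp` hSNPs, the fraction of
#' ASH-hSNPs over hSNPs relative to the average fraction across all
#' motifs, with a two-sided binomial test against the global rate and a
#' 95% Wilson interval on the motif proportion (divided by the global
#' rate).
#'
#' @param df tibble with motif_id, n_hsnp, n_ash.
#' @param min_hsnp motifs with `n_hsnp <= min_hsnp` are excluded
#'   (default 100).
#' @param p_cut flag threshold for enrichment/depletion (default 0.01).
#' @return tibble with ratio, ci_lo, ci_hi, p, and a status flag in
#'   `c("enriched", "depleted", "ns")`.
#' @export
ash_enrichment_ratio <- function(df, min_hsnp = 100, p_cut = 0.01) {
  stopifnot(all(c("motif_id", "n_hsnp", "n_ash") %in% names(df)))
  if (any(df$n_ash > df$n_hsnp)) {
    stop_footvar("n_ash cannot exceed n_hsnp", "footvar_input")
  }
  global <- sum(df$n_ash) / sum(df$n_hsnp)
  if (global == 0) stop_footvar("global ASH rate is zero", "footvar_input")
  kept <- dplyr::filter(df, .data$n_hsnp > min_hsnp)
  wilson <- function(k, n, z = qnorm(0.975)) {
    p <- k / n
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    c(lo = max(0, centre - half), hi = min(1, centre + half))
  }
  kept |>
    dplyr::mutate(
      ratio = (.data$n_ash / .data$n_hsnp) / global,
      p = purrr::map2_dbl(.data$n_ash, .data$n_hsnp,
                          ~ binom.test(.x, .y, p = global)$p.value),
      ci_lo = purrr::map2_dbl(.data$n_ash, .data$n_hsnp,
                              ~ wilson(.x, .y)[["lo"]] / global),
      ci_hi = purrr::map2_dbl(.data$n_ash, .data$n_hsnp,
                              ~ wilson(.x, .y)[["hi"]] / global),
      status = dplyr::case_when(
        .data$p < p_cut & .data$ratio > 1 ~ "enriched",
        .data$p < p_cut & .data$ratio < 1 ~ "depleted",
        TRUE ~ "ns"
      )
    )
}

#' Plot motif-wise ASH enrichment ratios
#' @param object output of [ash_enrichment_ratio()].
#' @param ... unused.
#' @return a ggplot of log2 ratios with 95% intervals.
#' @export
plot_ash_enrichment <- function(object, ...) {
  df <- dplyr::arrange(object, .data$ratio)
  df$motif_id <- factor(df$motif_id, levels = df$motif_id)
  ggplot(df, aes(x = log2(.data$ratio), y = .data$motif_id,
                 colour = .data$status)) +
    geom_point() +
    geom_errorbar(aes(xmin = log2(.data$ci_lo), xmax = log2(.data$ci_hi)),
                  width = 0.2) +
    geom_hline(xintercept = 0, linetype = 2, colour = "grey50") +
    labs(x = "log2 ASH enrichment ratio", y = NULL) +
    theme_minimal()
}

#' Logistic regression of effect status on SNP features
#'
#' Fits `logit(E) ~ C + F + T + N + P` by maximum likelihood: C the
#' footprint likelihood ratio (without the sequence model), F the minor
#' allele frequency, T the absolute TSS distance, N the number of active
#' tissues, P the conservation score.  Any subset of the covariates
#' present in `records` is used.  Perfect separation triggers a
#' ridge-stabilised IRLS refit with a warning.
#'
#' @param records tibble with binary `E` and covariate columns among
#'   C, F, T, N, P.
#' @param ridge penalty used by the separation fallback.
#' @return tibble of term, estimate, std_error, statistic, p_value.
#' @export
effect_logistic_regression <- function(records, ridge = 1e-4) {
  stopifnot("E" %in% names(records))
  covars <- intersect(c("C", "F", "T", "N", "P"), names(records))
  if (length(covars) == 0) stop_footvar("no covariates found", "footvar_input")
  if (length(unique(records$E)) < 2) {
    stop_footvar("degenerate response: E is constant", "footvar_degenerate_data")
  }
  n_par <- length(covars) + 1
  if (nrow(records) < 10 * n_par) {
    stop_footvar("need >= 10 records per parameter", "footvar_insufficient_data")
  }
  form <- stats::as.formula(paste("E ~", paste(covars, collapse = " + ")))
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(form, family = binomial(), data = records),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|algorithm did not converge",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (separated || !fit$converged) {
    warn("separation detected: refitting with a ridge-stabilised IRLS")
    X <- stats::model.matrix(form, records)
    y <- records$E
    beta <- rep(0, ncol(X))
    for (i in 1:100) {
      p <- sigmoid(drop(X %*% beta))
      W <- pmax(p * (1 - p), 1e-10)
      H <- crossprod(X, X * W) + diag(ridge, ncol(X))
      step <- solve(H, crossprod(X, y - p) - ridge * beta)
      beta <- beta + step
      if (max(abs(step)) < 1e-8) break
    }
    p <- sigmoid(drop(X %*% beta))
    V <- solve(crossprod(X, X * pmax(p * (1 - p), 1e-10)) + diag(ridge, ncol(X)))
    se <- sqrt(diag(V))
    est <- beta
    terms <- colnames(X)
  } else {
    s <- summary(fit)$coefficients
    terms <- rownames(s)
    est <- s[, 1]
    se <- s[, 2]
  }
  z <- est / se
  tibble::tibble(
    term = terms, estimate = unname(est), std_error = unname(se),
    statistic = unname(z), p_value = 2 * stats::pnorm(-abs(unname(z)))
  )
}

#' Fisher's exact enrichment test on a 2x2 table
#'
#' @param tbl 2x2 matrix of non-negative counts.
#' @return tibble with odds_ratio (conditional MLE), ci_lo, ci_hi,
#'   p_value, and `or_defined` (FALSE when a margin is zero).
#' @export
fisher_enrichment <- function(tbl) {
  tbl <- as.matrix(tbl)
  stopifnot(all(dim(tbl) == c(2, 2)), all(tbl >= 0))
  zero_margin <- any(rowSums(tbl) == 0) || any(colSums(tbl) == 0)
  ft <- fisher.test(tbl)
  tibble::tibble(
    odds_ratio = if (zero_margin) NA_real_ else unname(ft$estimate),
    ci_lo = if (zero_margin) NA_real_ else ft$conf.int[1],
    ci_hi = if (zero_margin) NA_real_ else ft$conf.int[2],
    p_value = ft$p.value,
    or_defined = !zero_margin
  )
}

#' Exact one-sided binomial validation test
#'
#' `P(X >= k | X ~ Binom(n, p0))` by exact summation of the binomial
#' mass; used to compare an observed validation rate with a chance rate.
#'
#' @param k observed successes.
#' @param n trials.
#' @param p0 null success probability.
#' @return upper-tail probability.
#' @export
binomial_validation_test <- function(k, n, p0) {
  stopifnot(k >= 0, k <= n, p0 > 0, p0 < 1)
  if (k == 0) return(1)
  sum(dbinom(k:n, n, p0))
}

#' Absolute distance to the nearest transcription start site
#'
#' @param snps tibble with chrom, pos0.
#' @param tss tibble with chrom and either pos0 or start (TSS point,
#'   0-based).
#' @return numeric vector of distances aligned with `snps` (NA when the
#'   chromosome has no TSS).
#' @export
tss_distance <- function(snps, tss) {
  tss_pos <- if ("pos0" %in% names(tss)) tss$pos0 else tss$start
  tss_by_chrom <- split(tss_pos, tss$chrom)
  out <- rep(NA_real_, nrow(snps))
  for (chr in unique(snps$chrom)) {
    tp <- sort(tss_by_chrom[[chr]])
    if (is.null(tp) || length(tp) == 0) next
    idx <- which(snps$chrom == chr)
    pos <- snps$pos0[idx]
    right <- findInterval(pos, tp)
    d_left <- ifelse(right >= 1, pos - tp[pmax(right, 1)], Inf)
    d_right <- ifelse(right < length(tp), tp[pmin(right + 1, length(tp))] - pos, Inf)
    out[idx] <- pmin(abs(d_left), abs(d_right))
  }
  out
}
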