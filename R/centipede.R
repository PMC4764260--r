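# Two-component mixture model for DNase-seq cut-start profiles at motif
# matches.  Bound sites: total reads R ~ NegBin(mu1, r1) and positions
# x | R ~ Multinomial(lambda) with a footprint-shaped lambda; unbound
# sites: R ~ NegBin(mu0, r0) and a uniform spatial profile.  The mixing
# prior is logistic in the PWM match score S: P(bound) = sigma(b0 + b1 S).
# Fitting is by EM; the TF-activity Z statistic is the Wald z of b1.

#' Construct a cut-count matrix
#'
#' @param counts sites x (2 * window) non-negative integer matrix: forward
#'   strand positions first, then reverse-strand positions.
#' @param site_ids row identifiers (default `site_1 ...`).
#' @param window positions per strand (motif width + 2 * flank).
#' @param flank flanking bases on each side of the motif.
#' @return object of class `cut_matrix`.
#' @export
new_cut_matrix <- function(counts, site_ids = NULL, window = ncol(counts) / 2,
                           flank = NA_integer_) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 2 * window) {
    stop_footvar("cut matrix must have 2 * window columns", "footvar_format")
  }
  if (any(counts < 0)) stop_footvar("negative cut counts", "footvar_input")
  site_ids <- site_ids %||% paste0("site_", seq_len(nrow(counts)))
  rownames(counts) <- site_ids
  structure(list(site_ids = site_ids, counts = counts,
                 window = as.integer(window), flank = flank),
            class = "cut_matrix")
}

#' @export
print.cut_matrix <- function(x, ...) {
  cat("<cut_matrix> ", nrow(x$counts), " sites x ", ncol(x$counts),
      " positions (window ", x$window, "/strand)\n", sep = "")
  invisible(x)
}

cut_counts <- function(cm) {
  if (inherits(cm, "cut_matrix")) cm$counts else as.matrix(cm)
}

# log NB mass with (mean, size) parameterisation, guarded for mu = 0
lognb <- function(x, mu, size) {
  dnbinom(x, size = size, mu = max(mu, 1e-12), log = TRUE)
}

# Posterior-weighted NB maximum likelihood: mean in closed form, size by
# 1-D search on the log scale.
fit_weighted_nb <- function(R, w, size_bounds = c(1e-3, 1e6)) {
  sw <- sum(w)
  if (sw <= 0) return(c(mu = mean(R), size = size_bounds[2]))
  mu <- sum(w * R) / sw
  obj <- function(ls) sum(w * lognb(R, mu, exp(ls)))
  opt <- optimize(obj, interval = log(size_bounds), maximum = TRUE)
  c(mu = mu, size = exp(opt$maximum))
}

# Weighted logistic regression of fractional responses on the PWM score;
# returns coefficients and Wald standard errors from the final IRLS weights.
fit_score_logistic <- function(rho, scores) {
  X <- cbind(1, scores)
  fit <- suppressWarnings(
    glm.fit(X, rho, family = quasibinomial(), intercept = FALSE)
  )
  beta <- unname(coef(fit))
  if (anyNA(beta)) {           # collinear design (e.g. constant scores)
    beta[is.na(beta)] <- 0
    return(list(beta = beta, se = c(Inf, Inf)))
  }
  p <- fit$fitted.values
  W <- pmax(p * (1 - p), 1e-12)
  se <- tryCatch({
    V <- solve(crossprod(X, X * W))
    sqrt(diag(V))
  }, error = function(e) c(Inf, Inf))
  list(beta = beta, se = unname(se))
}

#' Component log-likelihoods of one site's cut profile
#'
#' Evaluates `ln f_bound` and `ln f_unbound` for a single site: each is
#' the NB log mass of the read total plus the multinomial log mass of the
#' positional counts (footprint profile for bound, uniform for unbound).
#' Computed fully in log space; finite for any non-negative counts.
#'
#' @param x length `2 * window` non-negative count vector.
#' @param fit a [fit_centipede()] object (or any list with `lambda_fp`,
#'   `nb_bound`, `nb_unbound`).
#' @return named numeric `c(ln_bound, ln_unbound)`.
#' @export
component_loglik <- function(x, fit) {
  if (any(x < 0)) stop_footvar("negative counts", "footvar_input")
  J <- length(fit$lambda_fp)
  if (length(x) != J) stop_footvar("count vector length != 2 * window", "footvar_input")
  R <- sum(x)
  mult_const <- lgamma(R + 1) - sum(lgamma(x + 1))
  ln_b <- lognb(R, fit$nb_bound[["mu"]], fit$nb_bound[["size"]]) +
    mult_const + sum(x * log(fit$lambda_fp))
  ln_u <- lognb(R, fit$nb_unbound[["mu"]], fit$nb_unbound[["size"]]) +
    mult_const + R * log(1 / J)
  c(ln_bound = ln_b, ln_unbound = ln_u)
}

#' Fit the footprint mixture model by EM
#'
#' Alternates an E-step, `rho_l = sigma(eta_l + Delta_l)` with
#' `eta_l = beta0 + beta1 * S_l` and `Delta_l` the bound/unbound
#' log-likelihood ratio, with M-steps for the footprint profile
#' (posterior-weighted counts plus a total smoothing mass `lambda_eps`
#' spread uniformly), the two NB read-total components (weighted MLE,
#' size on a bounded log scale), and the logistic score prior (IRLS).
#' Iterates until the relative change in observed-data log-likelihood
#' falls below `tol` or `max_iter` is reached.  The bound component is
#' kept as the higher-mean one by swapping labels if needed.
#'
#' @param cuts a [new_cut_matrix()] or plain sites x (2 * window) matrix.
#' @param pwm_scores per-site PWM match scores aligned with the rows.
#' @param max_iter,tol EM stopping controls.
#' @param min_sites minimum number of sites (default 500).
#' @param lambda_eps total smoothing pseudo-mass for the profile.
#' @param size_bounds NB size search bounds.
#' @return object of class `centipede_fit` with the footprint profile
#'   `lambda_fp`, NB parameters, logistic prior `beta` and `beta_se`,
#'   per-site `posteriors` and `log_lik_ratio`, activity `z_score`,
#'   convergence flag and log-likelihood trace.
#' @export
fit_centipede <- function(cuts, pwm_scores, max_iter = 200, tol = 1e-6,
                          min_sites = 500, lambda_eps = 0.5,
                          size_bounds = c(1e-3, 1e6)) {
  counts <- cut_counts(cuts)
  n <- nrow(counts)
  J <- ncol(counts)
  if (n < min_sites) {
    stop_footvar(sprintf("%d sites < min_sites = %d", n, min_sites),
                 "footvar_insufficient_data")
  }
  if (length(pwm_scores) != n) {
    stop_footvar("pwm_scores must align with cut-matrix rows", "footvar_input")
  }
  if (any(counts < 0)) stop_footvar("negative cut counts", "footvar_input")
  R <- rowSums(counts)
  if (all(R == 0)) {
    stop_footvar("all cut counts are zero: nothing to fit", "footvar_degenerate_data")
  }
  mult_const <- lgamma(R + 1) - rowSums(lgamma(counts + 1))
  log_unif_term <- R * log(1 / J)

  # Initialisation: high-score sites presumed bound; prior at the 10% floor.
  q90 <- quantile(pwm_scores, 0.9, names = FALSE)
  rho <- ifelse(pwm_scores >= q90, 0.9, 0.1)
  beta <- c(logit(0.1), 0)
  beta_se <- c(NA_real_, NA_real_)

  ll_old <- -Inf
  ll_trace <- numeric(0)
  converged <- FALSE
  swapped <- FALSE
  lambda <- rep(1 / J, J)
  nb1 <- nb0 <- c(mu = mean(R), size = 10)

  for (iter in seq_len(max_iter)) {
    ## ---- M-step ----
    mu_b <- sum(rho * R) / max(sum(rho), 1e-12)
    mu_u <- sum((1 - rho) * R) / max(sum(1 - rho), 1e-12)
    if (mu_b < mu_u) {            # label-switching guard
      rho <- 1 - rho
      swapped <- TRUE
      ll_old <- -Inf              # relabeling restarts the monotone run
    }
    lam_raw <- colSums(rho * counts) + lambda_eps / J
    lambda <- lam_raw / sum(lam_raw)
    nb1 <- fit_weighted_nb(R, rho, size_bounds)
    nb0 <- fit_weighted_nb(R, 1 - rho, size_bounds)
    bfit <- fit_score_logistic(rho, pwm_scores)
    beta <- bfit$beta
    beta_se <- bfit$se

    ## ---- E-step ----
    eta <- beta[1] + beta[2] * pwm_scores
    ln_fb <- lognb(R, nb1[["mu"]], nb1[["size"]]) + mult_const +
      drop(counts %*% log(lambda))
    ln_fu <- lognb(R, nb0[["mu"]], nb0[["size"]]) + mult_const + log_unif_term
    delta <- ln_fb - ln_fu
    rho <- sigmoid(eta + delta)

    ll <- sum(log_add(plogis(eta, log.p = TRUE) + ln_fb,
                      plogis(-eta, log.p = TRUE) + ln_fu))
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old)) {
      if (ll < ll_old - 1e-8) {
        warn(sprintf("EM log-likelihood decreased at iteration %d (%.3g)",
                     iter, ll - ll_old))
      }
      if (abs(ll - ll_old) / (abs(ll_old) + 1e-8) < tol) {
        converged <- TRUE
        break
      }
    }
    ll_old <- ll
  }
  if (!converged) {
    warn(sprintf("EM did not converge in %d iterations", max_iter))
  }

  eta <- beta[1] + beta[2] * pwm_scores
  z <- unname(beta[2] / beta_se[2])
  capped <- !is.finite(beta_se[2]) || beta_se[2] == 0
  if (capped) z <- sign(beta[2]) * Inf

  structure(list(
    lambda_fp = lambda,
    nb_bound = nb1, nb_unbound = nb0,
    beta = beta, beta_se = beta_se,
    posteriors = as.numeric(rho),
    log_lik_ratio = as.numeric(delta),
    prior_log_odds = as.numeric(eta),
    pwm_scores = as.numeric(pwm_scores),
    z_score = z, z_capped = capped,
    converged = converged, n_iter = length(ll_trace),
    log_lik = ll_trace, n_sites = n, window = J / 2,
    site_ids = rownames(counts) %||% paste0("site_", seq_len(n)),
    label_swapped = swapped
  ), class = "centipede_fit")
}

#' @export
print.centipede_fit <- function(x, ...) {
  cat("<centipede_fit> ", x$n_sites, " sites, window ", x$window, "/strand\n",
      sep = "")
  cat(sprintf("  beta = (%.3f, %.3f), Z = %.2f%s\n", x$beta[1], x$beta[2],
              x$z_score, if (x$z_score > 5) " (active)" else ""))
  cat(sprintf("  NB bound mu = %.1f, unbound mu = %.1f; %s in %d iterations\n",
              x$nb_bound[["mu"]], x$nb_unbound[["mu"]],
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Posterior probability of binding and likelihood ratio per site
#'
#' @param fit a `centipede_fit`.
#' @param sites site indices (default all).
#' @return tibble with site_id, posterior, log_lik_ratio.
#' @export
posterior_binding <- function(fit, sites = NULL) {
  sites <- sites %||% seq_len(fit$n_sites)
  tibble::tibble(
    site_id = fit$site_ids[sites],
    posterior = fit$posteriors[sites],
    log_lik_ratio = fit$log_lik_ratio[sites]
  )
}

#' TF-activity Z statistic of a fit
#'
#' `z = beta1 / se(beta1)` from the final weighted logistic prior fit; a
#' sample-motif pair is called active when `z > 5` (strictly).
#'
#' @param fit a `centipede_fit`.
#' @param z_cutoff activity threshold (default 5).
#' @return list with `z`, `is_active`, and `capped` (TRUE when the
#'   standard error was undefined, e.g. under separation).
#' @export
activity_zscore <- function(fit, z_cutoff = 5) {
  list(z = fit$z_score, is_active = isTRUE(fit$z_score > z_cutoff),
       capped = fit$z_capped)
}

#' @method tidy centipede_fit
#' @export
tidy.centipede_fit <- function(x, ...) {
  tibble::tibble(
    site_id = x$site_ids,
    pwm_score = x$pwm_scores,
    prior_log_odds = x$prior_log_odds,
    log_lik_ratio = x$log_lik_ratio,
    posterior = x$posteriors
  )
}

#' @method glance centipede_fit
#' @export
glance.centipede_fit <- function(x, ...) {
  tibble::tibble(
    n_sites = x$n_sites, beta0 = x$beta[1], beta1 = x$beta[2],
    beta1_se = x$beta_se[2], z_score = x$z_score,
    mu_bound = x$nb_bound[["mu"]], size_bound = x$nb_bound[["size"]],
    mu_unbound = x$nb_unbound[["mu"]], size_unbound = x$nb_unbound[["size"]],
    log_lik = tail(x$log_lik, 1), n_iter = x$n_iter, converged = x$converged
  )
}

#' Plot the fitted footprint profile
#'
#' Cut-start probability per window position, split by strand; the dip
#' over the motif is the footprint.
#'
#' @param object a `centipede_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot centipede_fit
#' @export
autoplot.centipede_fit <- function(object, ...) {
  w <- object$window
  df <- tibble::tibble(
    position = rep(seq_len(w), 2),
    strand = rep(c("forward", "reverse"), each = w),
    probability = object$lambda_fp
  )
  ggplot(df, aes(x = .data$position, y = .data$probability,
                 colour = .data$strand)) +
    geom_line() +
    labs(x = "window position", y = "cut-start probability",
         title = "Footprint profile (lambda)") +
    theme_minimal()
}
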