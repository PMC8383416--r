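# True-m6A thresholding.
#
# Modified-base callers assign most adenosines a non-trivial m6A
# probability, so the raw per-base probability distribution is bimodal: a
# noise peak shared with an unmethylated control, and a signal peak from
# genuinely accessible DNA. A two-component Gaussian mixture fitted to the
# raw probabilities separates the two; the cutoff is the posterior
# crossover between the components.

#' Fit a two-component Gaussian mixture to m6A probabilities
#'
#' Plain EM on the untransformed probabilities in \[0, 1\] (densities are
#' not truncated; boundary leakage is accepted). Components are relabeled so
#' the means ascend: component 1 is the noise peak, component 2 the signal
#' peak. Initialization is deterministic — means at the 25th/75th
#' percentiles, equal weights, both SDs at half the inter-quartile spread —
#' so the fit is reproducible regardless of `seed` (kept for interface
#' stability).
#'
#' A fit is flagged degenerate (not converged, no cutoff) when the means end
#' up closer than 0.02 or either weight drops below 0.01.
#'
#' @param probs Numeric vector of probabilities in \[0, 1\]; at least 100
#'   values required.
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Convergence tolerance on the log-likelihood improvement
#'   (default 1e-6).
#' @param seed Unused (initialization is deterministic); accepted for
#'   interface stability.
#' @return A `mixture_fit`: list with `weights`, `means`, `sds`, `cutoff`,
#'   `loglik`, `n_iter`, `converged`, `diagnostic`, `n`.
#' @export
fit_probability_mixture <- function(probs, max_iter = 500, tol = 1e-6,
                                    seed = NULL) {
  probs <- as.numeric(probs)
  if (length(probs) < 100L) {
    stop("fit_probability_mixture: need at least 100 values, got ",
         length(probs))
  }
  if (any(!is.finite(probs) | probs < 0 | probs > 1)) {
    stop("fit_probability_mixture: probabilities must lie in [0, 1]")
  }
  x <- probs
  if (sd(x) == 0) {
    return(.mixture_fit(c(0.5, 0.5), rep(x[1], 2), c(0, 0), NA_real_,
                        NA_real_, 0L, FALSE, "all values identical",
                        length(x)))
  }
  q <- unname(quantile(x, c(0.25, 0.75)))
  mu <- q
  sdev <- rep(max((q[2] - q[1]) / 2, 1e-3), 2)
  w <- c(0.5, 0.5)
  ll_prev <- -Inf; ll <- -Inf; it <- 0L; converged <- FALSE
  for (it in seq_len(max_iter)) {
    la <- log(w[1]) + dnorm(x, mu[1], sdev[1], log = TRUE)
    lb <- log(w[2]) + dnorm(x, mu[2], sdev[2], log = TRUE)
    m <- pmax(la, lb)
    ll <- sum(m + log(exp(la - m) + exp(lb - m)))
    # EM guarantee: the log-likelihood never decreases
    if (ll < ll_prev - 1e-8) {
      stop(sprintf("EM log-likelihood decreased at iteration %d (%.6f -> %.6f)",
                   it, ll_prev, ll))
    }
    if (is.finite(ll_prev) && ll - ll_prev < tol) { converged <- TRUE; break }
    ll_prev <- ll
    r2 <- 1 / (1 + exp(la - lb))
    n2 <- sum(r2); n1 <- length(x) - n2
    w <- c(n1, n2) / length(x)
    mu <- c(sum((1 - r2) * x) / n1, sum(r2 * x) / n2)
    sdev <- sqrt(c(sum((1 - r2) * (x - mu[1])^2) / n1,
                   sum(r2 * (x - mu[2])^2) / n2))
    sdev <- pmax(sdev, 1e-4)
  }
  if (mu[1] > mu[2]) { mu <- rev(mu); sdev <- rev(sdev); w <- rev(w) }
  if (abs(mu[2] - mu[1]) < 0.02 || min(w) < 0.01) {
    return(.mixture_fit(w, mu, sdev, NA_real_, ll, it, FALSE,
                        sprintf("degenerate fit (means %.3f/%.3f, weights %.3f/%.3f)",
                                mu[1], mu[2], w[1], w[2]),
                        length(x)))
  }
  fit <- .mixture_fit(w, mu, sdev, NA_real_, ll, it, converged, NA_character_,
                      length(x))
  fit$cutoff <- crossover_cutoff(fit)
  fit
}

.mixture_fit <- function(weights, means, sds, cutoff, loglik, n_iter,
                         converged, diagnostic, n) {
  structure(list(weights = weights, means = means, sds = sds, cutoff = cutoff,
                 loglik = loglik, n_iter = n_iter, converged = converged,
                 diagnostic = diagnostic, n = n),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(paste0("<mixture_fit> n=%d  noise N(%.3f, %.3f^2) w=%.3f  ",
                     "signal N(%.3f, %.3f^2) w=%.3f\n  cutoff=%s  loglik=%.2f  ",
                     "iter=%d  converged=%s%s\n"),
              x$n, x$means[1], x$sds[1], x$weights[1],
              x$means[2], x$sds[2], x$weights[2],
              ifelse(is.na(x$cutoff), "NA", sprintf("%.4f", x$cutoff)),
              x$loglik, x$n_iter, x$converged,
              ifelse(is.na(x$diagnostic), "", paste0("  [", x$diagnostic, "]"))))
  invisible(x)
}

#' Posterior-crossover cutoff of a mixture fit
#'
#' The smallest probability between the two component means at which the
#' signal component's weighted density reaches the noise component's
#' (posterior crossover), located on a fine grid and refined with
#' [stats::uniroot()] to well below 1e-4. With equal weights and equal SDs
#' this is the midpoint of the means.
#'
#' @param fit A converged `mixture_fit`.
#' @return The cutoff probability.
#' @export
crossover_cutoff <- function(fit) {
  if (!isTRUE(fit$converged)) {
    stop("crossover_cutoff: mixture fit did not converge",
         if (!is.na(fit$diagnostic)) paste0(" (", fit$diagnostic, ")") else "")
  }
  m1 <- fit$means[1]; m2 <- fit$means[2]
  g <- function(x) {
    (log(fit$weights[2]) + dnorm(x, m2, fit$sds[2], log = TRUE)) -
      (log(fit$weights[1]) + dnorm(x, m1, fit$sds[1], log = TRUE))
  }
  grid <- seq(m1, m2, length.out = 4097L)
  gv <- g(grid)
  if (gv[1] >= 0) {
    stop("crossover_cutoff: signal component already dominates at the noise mean")
  }
  idx <- which(gv >= 0)
  if (length(idx) == 0L) {
    stop("crossover_cutoff: no crossover between the component means")
  }
  i <- idx[1]
  uniroot(g, lower = grid[i - 1L], upper = grid[i], tol = 1e-8)$root
}

#' Sensitivity and specificity of a cutoff against a control
#'
#' Specificity is the fraction of control (unmethylated-sample) values below
#' the cutoff. Sensitivity is the fraction of treated values assigned to the
#' signal component (posterior > 0.5 under `fit`) that reach the cutoff.
#'
#' @param fit A converged `mixture_fit` (defines the posterior assignment).
#' @param treated_probs Probabilities from the methyltransferase-treated
#'   sample.
#' @param control_probs Probabilities from the untreated control.
#' @param cutoff Threshold to evaluate (default `fit$cutoff`).
#' @return List with `sensitivity`, `specificity`, `cutoff`.
#' @export
evaluate_cutoff <- function(fit, treated_probs, control_probs,
                            cutoff = fit$cutoff) {
  if (length(treated_probs) == 0L || length(control_probs) == 0L) {
    stop("evaluate_cutoff: treated and control sets must be nonempty")
  }
  stopifnot(is.finite(cutoff))
  post <- posterior_signal(fit, treated_probs)
  pos <- treated_probs[post > 0.5]
  sens <- if (length(pos)) mean(pos >= cutoff) else NA_real_
  spec <- mean(control_probs < cutoff)
  list(sensitivity = sens, specificity = spec, cutoff = cutoff)
}

#' Posterior probability of the signal component
#'
#' @param fit A `mixture_fit`.
#' @param probs Probabilities to score.
#' @return Numeric vector of posteriors in \[0, 1\].
#' @export
posterior_signal <- function(fit, probs) {
  la <- log(fit$weights[1]) + dnorm(probs, fit$means[1], fit$sds[1], log = TRUE)
  lb <- log(fit$weights[2]) + dnorm(probs, fit$means[2], fit$sds[2], log = TRUE)
  1 / (1 + exp(la - lb))
}

#' Binarize per-read m6A calls at a probability cutoff
#'
#' A call is methylated iff its probability is strictly above the cutoff
#' (a probability exactly at the cutoff is unmethylated), so the methylated
#' count is non-increasing in the cutoff.
#'
#' @param calls Mod-call table (see [read_modcall_table()]).
#' @param cutoff Probability cutoff in (0, 1); default 0.53.
#' @return The calls with an added logical column `methylated`.
#' @export
binarize_calls <- function(calls, cutoff = 0.53) {
  stopifnot(is.numeric(cutoff), cutoff > 0, cutoff < 1)
  calls <- data.table::as.data.table(calls)
  calls$methylated <- calls$prob > cutoff
  calls[]
}

#' Serialize a mixture fit (plus optional evaluation) to JSON
#'
#' @param fit A `mixture_fit`.
#' @param path Output path.
#' @param evaluation Optional result of [evaluate_cutoff()].
#' @return `path`, invisibly.
#' @export
write_mixture_report <- function(fit, path, evaluation = NULL) {
  rep <- unclass(fit)
  rep$diagnostic <- if (is.na(rep$diagnostic)) NULL else rep$diagnostic
  if (!is.null(evaluation)) rep$evaluation <- evaluation
  write_json_report(rep, path)
}
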