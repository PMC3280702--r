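## S3 methods for the fitted hmm_glm model.

#' @export
print.hmm_glm <- function(x, ...) {
  cat("Two-state HMM with history-dependent Poisson-GLM emissions\n")
  cat(sprintf("  onset hazard rho = %.4g, horizon M = %d, lag order L = %d\n",
              x$rho, x$M, x$L))
  cat(sprintf("  quantizer: %d uniform bins on [%.4g, %.4g]\n",
              x$quantizer$n_bins, min(x$quantizer$bin_edges),
              max(x$quantizer$bin_edges)))
  cat(sprintf("  nonictal: alpha = %.4f; ictal: alpha = %.4f\n",
              x$theta0$alpha, x$theta1$alpha))
  if (!is.null(x$band)) print(x$band)
  invisible(x)
}

#' @export
summary.hmm_glm <- function(object, ...) {
  se <- function(th) if (is.null(th$cov)) rep(NA_real_, th$L + 1L)
    else sqrt(diag(th$cov))
  tab <- function(th, state) {
    est <- c(th$alpha, th$betas)
    s <- se(th)
    data.frame(state = state,
               parameter = c("alpha", if (th$L > 0) paste0("beta", seq_len(th$L))),
               estimate = est,
               lo95 = est - 1.96 * s,
               hi95 = est + 1.96 * s)
  }
  out <- list(coefficients = rbind(tab(object$theta0, "nonictal"),
                                   tab(object$theta1, "ictal")),
              rho = object$rho, M = object$M, L = object$L,
              loglik = logLik(object))
  class(out) <- "summary.hmm_glm"
  out
}

#' @export
print.summary.hmm_glm <- function(x, ...) {
  cat(sprintf("Two-state HMM-GLM (rho = %.4g, L = %d, M = %d)\n", x$rho, x$L, x$M))
  print(x$coefficients, row.names = FALSE, digits = 4)
  if (!is.na(x$loglik))
    cat(sprintf("emission log-likelihood (training): %.2f\n", as.numeric(x$loglik)))
  invisible(x)
}

#' @export
coef.hmm_glm <- function(object, ...) {
  nm <- c("alpha", if (object$L > 0) paste0("beta", seq_len(object$L)))
  m <- rbind(nonictal = c(object$theta0$alpha, object$theta0$betas),
             ictal = c(object$theta1$alpha, object$theta1$betas))
  colnames(m) <- nm
  m
}

#' @export
logLik.hmm_glm <- function(object, ...) {
  ll <- object$theta0$loglik + object$theta1$loglik
  if (is.null(ll) || length(ll) == 0L) ll <- NA_real_
  structure(ll, df = 2 * (object$L + 1) + 1, class = "logLik")
}

#' @export
simulate.hmm_glm <- function(object, nsim = 1, seed = NULL, n_steps = 1000, ...) {
  if (is.null(seed)) seed <- sample.int(1e6, 1)
  out <- lapply(seq_len(nsim), function(i)
    simulate_hmm_glm(object, n_steps, seed = seed + i - 1L))
  if (nsim == 1) out[[1]] else out
}

#' One-step-ahead conditional intensities
#'
#' For each stage of a count series, the state-conditional Poisson rates
#' `lambda_0` and `lambda_1` implied by the model and the observed history
#' (padded at the start).
#'
#' @param object An `hmm_glm`.
#' @param newdata Integer vector of quantized counts (codes).
#' @param ... Unused.
#' @return Data frame with columns `lambda0`, `lambda1`.
#' @export
predict.hmm_glm <- function(object, newdata, ...) {
  counts <- as.integer(newdata)
  pad <- history_pad(object)
  L <- object$L
  n <- length(counts)
  l0 <- l1 <- numeric(n)
  for (i in seq_len(n)) {
    avail <- if (L > 0L && i > 1L) counts[(i - 1L):max(1L, i - L)] else integer(0)
    history <- c(avail, rep(pad, max(0L, L - length(avail))))
    l0[i] <- exp(glm_log_rate(object$theta0, history))
    l1[i] <- exp(glm_log_rate(object$theta1, history))
  }
  data.frame(lambda0 = l0, lambda1 = l1)
}

#' @export
residuals.hmm_glm <- function(object, type = c("pearson", "deviance"), ...) {
  type <- match.arg(type)
  tr <- object$training
  if (is.null(tr)) stop("model carries no training data")
  lam <- predict(object, tr$counts)
  mu <- ifelse(tr$states == 0L, lam$lambda0, lam$lambda1)
  y <- tr$counts
  if (type == "pearson") (y - mu) / sqrt(mu)
  else sign(y - mu) * sqrt(2 * (ifelse(y > 0, y * log(y / mu), 0) - (y - mu)))
}

#' @export
plot.svd_statistic <- function(x, ...) {
  graphics::plot(x$k_s, x$sigma1, type = "l", xlab = "time (s)",
                 ylab = expression(sigma[1]),
                 main = "Largest singular value of the connectivity matrix", ...)
  invisible(x)
}
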