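## Bayesian information-state filter: the posterior probability pi_k that
## the hidden state is ictal given all observations up to stage k.

LOG_LR_CLIP <- 50        # likelihood ratios clipped to [e^-50, e^50]
PI_CLIP <- 1e-12         # pi kept inside [PI_CLIP, 1 - PI_CLIP]

#' Initial information state
#'
#' Posterior probability of the ictal state after the very first
#' observation: `pi_0 = q1(z0) (1 - p0) / (q0(z0) p0 + q1(z0) (1 - p0))`,
#' where `p0 = P0[1]` is the prior probability of starting nonictal and the
#' state-conditional probabilities `q_x(z0)` are evaluated with the padded
#' (empty) history.
#'
#' @param model An `hmm_glm`.
#' @param z0 First observation (real).
#' @return Probability in `[0, 1]`.
#' @export
initial_pi <- function(model, z0) {
  stopifnot(inherits(model, "hmm_glm"))
  pad <- rep(history_pad(model), max(model$L, 1L))
  p0 <- model$P0[1]
  q0 <- emission_probability(model, 0, z0, pad)
  q1 <- emission_probability(model, 1, z0, pad)
  den <- q0 * p0 + q1 * (1 - p0)
  if (den <= 0) stop("degenerate likelihood: both emission terms vanish at z0")
  q1 * (1 - p0) / den
}

#' Likelihood ratio of one observation
#'
#' `L_k = q1(z | H_k) / q0(z | H_k)`, computed in the log domain and clipped
#' to `[exp(-50), exp(50)]` so long quiescent stretches can never produce a
#' hard zero or overflow.
#'
#' @inheritParams emission_probability
#' @param z Raw observation.
#' @param history Integer codes, most recent first, length >= L.
#' @return Nonnegative likelihood ratio.
#' @export
likelihood_ratio <- function(model, z, history) {
  n <- quantize(model$quantizer, z)
  l0 <- glm_log_rate(model$theta0, history)
  l1 <- glm_log_rate(model$theta1, history)
  loglr <- stats::dpois(n, exp(l1), log = TRUE) -
           stats::dpois(n, exp(l0), log = TRUE)
  if (!is.finite(loglr)) loglr <- sign(l1 - l0) * LOG_LR_CLIP
  exp(max(min(loglr, LOG_LR_CLIP), -LOG_LR_CLIP))
}

#' One-step information-state update
#'
#' The recursive posterior update
#' `pi' = L (pi + (1 - pi) rho) / ((1 - pi)(1 - rho) + L (pi + (1 - pi) rho))`
#' combining the geometric onset prior (hazard `rho`) with the evidence in
#' the likelihood ratio `L`. With `L = 1` it reduces to pure prior drift
#' `pi' = pi + (1 - pi) rho`; it is strictly increasing in `L` and absorbs
#' at `pi = 1`.
#'
#' @param pi Current posterior, in `[0, 1]`.
#' @param L Likelihood ratio, nonnegative.
#' @param rho Onset hazard, in `[0, 1]`.
#' @return Updated posterior in `[0, 1]`.
#' @export
update_pi <- function(pi, L, rho) {
  num <- L * (pi + (1 - pi) * rho)
  den <- (1 - pi) * (1 - rho) + num
  if (den <= 0) {
    warning("information-state denominator underflow; saturating")
    return(if (num > 0) 1 else 0)
  }
  num / den
}

#' Filter a full observation series
#'
#' Runs the information-state recursion over a series of raw observations:
#' [initial_pi()] at stage 0 and after every restart, [update_pi()]
#' elsewhere. The history buffer of quantized codes is kept across restarts
#' (the physical signal is continuous) unless `reset_history = TRUE`;
#' stages with insufficient history are padded with the nonictal stationary
#' code. `pi` is clipped to `[1e-12, 1 - 1e-12]` between updates so the
#' recursion stays responsive after long quiescent periods.
#'
#' @param model An `hmm_glm`.
#' @param observations Numeric vector, one raw observation per stage
#'   (stages k = 0, 1, ... map to indices 1, 2, ...).
#' @param restarts Integer vector of 1-based indices at which the filter
#'   re-initializes (terminate-and-restart stages).
#' @param reset_history Also clear the observation history at restarts?
#' @return Object of class `info_trajectory`: list with `pi`,
#'   `likelihood_ratios` (`NA` at initialization stages), `restart_indices`,
#'   and the quantized `counts`.
#' @export
filter_series <- function(model, observations, restarts = integer(0),
                          reset_history = FALSE) {
  stopifnot(inherits(model, "hmm_glm"))
  n <- length(observations)
  if (n == 0L) stop("empty observation series")
  counts <- quantize(model$quantizer, observations)
  pad <- history_pad(model)
  L <- model$L
  pi <- numeric(n)
  lr <- rep(NA_real_, n)
  restart_set <- sort(unique(c(1L, as.integer(restarts))))
  seg_start <- 1L
  for (i in seq_len(n)) {
    if (i %in% restart_set) {
      pi[i] <- initial_pi(model, observations[i])
      seg_start <- i
    } else {
      hist_lo <- if (reset_history) seg_start else 1L
      avail <- if (L > 0L && i - 1L >= hist_lo)
        counts[(i - 1L):max(hist_lo, i - L)] else integer(0)
      history <- c(avail, rep(pad, max(0L, L - length(avail))))
      lr[i] <- likelihood_ratio(model, observations[i], history)
      pi[i] <- update_pi(pi[i - 1L], lr[i], model$rho)
    }
    pi[i] <- min(max(pi[i], PI_CLIP), 1 - PI_CLIP)
  }
  structure(list(pi = pi, likelihood_ratios = lr,
                 restart_indices = setdiff(restart_set, 1L),
                 counts = counts),
            class = "info_trajectory")
}

#' @export
print.info_trajectory <- function(x, ...) {
  cat(sprintf("information-state trajectory: %d stages, %d restart(s), pi range [%.3g, %.3g]\n",
              length(x$pi), length(x$restart_indices), min(x$pi), max(x$pi)))
  invisible(x)
}

#' Write an information-state trajectory to CSV
#'
#' Columns: `k_s` (0-based stage), `pi`, `L_k`, `restarted_flag`.
#' @param x An `info_trajectory`.
#' @param path Output file path.
#' @export
write_trajectory <- function(x, path) {
  stopifnot(inherits(x, "info_trajectory"))
  n <- length(x$pi)
  df <- data.frame(k_s = seq_len(n) - 1L, pi = x$pi, L_k = x$likelihood_ratios,
                   restarted_flag = as.integer(seq_len(n) %in% x$restart_indices))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
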