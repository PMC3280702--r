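#' Uniform quantizer for the detection statistic
#'
#' Maps the real-valued detection statistic to integer codes 0 ... n_bins-1
#' with uniform-width bins spanning the range of the training values.
#' Out-of-range values clip to the end bins, so the code domain is always
#' finite — a requirement for the Poisson observation model and the
#' finite-alphabet dynamic program.
#'
#' @param training_values Finite numeric vector used to anchor the range.
#' @param n_bins Number of bins (codes), at least 2. Default 50.
#' @return Object of class `quantizer`: list with `bin_edges`
#'   (length `n_bins + 1`) and `n_bins`.
#' @export
build_quantizer <- function(training_values, n_bins = 50) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  v <- training_values[is.finite(training_values)]
  if (length(v) < 2L || !all(is.finite(range(v))))
    stop("training values must contain at least two finite numbers")
  r <- range(v)
  if (r[1] == r[2]) stop("degenerate range: training values are constant")
  structure(list(bin_edges = seq(r[1], r[2], length.out = n_bins + 1L),
                 n_bins = as.integer(n_bins)),
            class = "quantizer")
}

#' Apply a quantizer
#'
#' @param q A `quantizer`.
#' @param z Numeric vector of observations.
#' @return Integer codes in `0:(q$n_bins - 1)`; monotone in `z`, clipping
#'   below/above range to the first/last bin.
#' @export
quantize <- function(q, z) {
  stopifnot(inherits(q, "quantizer"))
  code <- findInterval(z, q$bin_edges, rightmost.closed = TRUE) - 1L
  pmin(pmax(code, 0L), q$n_bins - 1L)
}

## Lagged design matrix: row k has counts[k-1], ..., counts[k-L].
## Rows 1..L are dropped (insufficient history).
lag_design <- function(counts, L) {
  n <- length(counts)
  if (L == 0L) return(matrix(numeric(0), nrow = n, ncol = 0))
  X <- matrix(NA_real_, n, L)
  for (j in seq_len(L)) X[(j + 1L):n, j] <- counts[1L:(n - j)]
  X
}

## Ridge-stabilised Poisson IRLS, used when stats::glm fails on a
## degenerate design. Penalty excludes the intercept.
ridge_poisson_irls <- function(X, y, lambda = 1e-6, maxit = 100, tol = 1e-10) {
  Xi <- cbind(1, X)
  p <- ncol(Xi)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  beta <- c(log(mean(y) + 0.5), rep(0, p - 1L))
  for (it in seq_len(maxit)) {
    eta <- drop(Xi %*% beta)
    mu <- exp(pmin(eta, 30))
    W <- mu
    z <- eta + (y - mu) / pmax(mu, 1e-12)
    XtW <- t(Xi * W)
    H <- XtW %*% Xi + pen
    beta_new <- drop(solve(H, XtW %*% z))
    if (max(abs(beta_new - beta)) < tol) { beta <- beta_new; break }
    beta <- beta_new
  }
  eta <- drop(Xi %*% beta)
  mu <- exp(eta)
  list(coefficients = beta,
       vcov = solve(t(Xi * mu) %*% Xi + pen),
       loglik = sum(stats::dpois(y, mu, log = TRUE)),
       converged = TRUE)
}

#' Fit a history-dependent Poisson GLM to a count sequence
#'
#' Maximum-likelihood fit of the log-linear autoregressive count model
#' `log lambda_k = alpha + sum_j beta_j * n_{k-j}`, j = 1..L, where `n_k`
#' are quantized observations. The first `L` observations serve only as
#' history. Fitting uses iteratively reweighted least squares
#' ([stats::glm()] with a Poisson family); on rank-deficient or
#' non-converged designs a ridge-penalised IRLS (lambda = 1e-6) takes over.
#'
#' @param counts Nonnegative integer vector.
#' @param L Number of history lags (L >= 0).
#' @return Object of class `glm_params`: list with `alpha`, `betas`
#'   (length L), `L`, `cov` (parameter covariance, for 95% confidence
#'   bounds), `loglik`, `n_used`.
#' @examples
#' fit_glm(rep(3L, 100), L = 0)   # alpha = log 3
#' @export
fit_glm <- function(counts, L = 15L) {
  L <- as.integer(L)
  counts <- as.integer(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  n <- length(counts)
  if (n <= L + (L + 1L)) stop("sequence too short for L = ", L)
  X <- lag_design(counts, L)
  keep <- seq_len(n) > L
  y <- counts[keep]
  Xk <- X[keep, , drop = FALSE]
  fit <- tryCatch({
    if (L == 0L) {
      g <- stats::glm(y ~ 1, family = stats::poisson())
    } else {
      g <- stats::glm(y ~ Xk, family = stats::poisson())
    }
    if (!g$converged || anyNA(stats::coef(g))) stop("glm did not converge")
    list(coefficients = unname(stats::coef(g)),
         vcov = unname(stats::vcov(g)),
         loglik = sum(stats::dpois(y, stats::fitted(g), log = TRUE)))
  }, error = function(e) {
    ridge_poisson_irls(Xk, y)
  })
  structure(list(alpha = fit$coefficients[1],
                 betas = if (L > 0L) fit$coefficients[-1] else numeric(0),
                 L = L,
                 cov = fit$vcov,
                 loglik = fit$loglik,
                 n_used = length(y)),
            class = "glm_params")
}

#' @export
print.glm_params <- function(x, ...) {
  cat(sprintf("Poisson history GLM: alpha = %.4f, L = %d lag(s), loglik = %.2f\n",
              x$alpha, x$L, x$loglik))
  if (x$L > 0) {
    cat("betas:", paste(sprintf("%.4f", x$betas), collapse = " "), "\n")
  }
  invisible(x)
}

#' Select the GLM lag order by AIC
#'
#' Fits the history GLM for each candidate lag on a common effective sample
#' (history truncated at the largest candidate so log-likelihoods are
#' comparable) and returns the lag minimizing
#' `AIC = 2 (L + 1) - 2 loglik`. Ties break toward the smaller lag.
#'
#' @param counts Nonnegative integer vector.
#' @param candidate_Ls Integer vector of candidate lag orders.
#' @return The selected lag (integer). The AIC table is attached as
#'   attribute `"aic"`.
#' @export
select_lag_by_aic <- function(counts, candidate_Ls) {
  if (length(candidate_Ls) == 0L) stop("empty candidate list")
  candidate_Ls <- sort(unique(as.integer(candidate_Ls)))
  Lmax <- max(candidate_Ls)
  n <- length(counts)
  if (n <= Lmax + Lmax + 1L) stop("sequence too short for the largest candidate lag")
  aic <- vapply(candidate_Ls, function(L) {
    ## common response window: drop the first Lmax observations
    X <- lag_design(counts, L)
    keep <- seq_len(n) > Lmax
    y <- counts[keep]
    Xk <- X[keep, , drop = FALSE]
    g <- tryCatch({
      gg <- if (L == 0L) stats::glm(y ~ 1, family = stats::poisson())
            else stats::glm(y ~ Xk, family = stats::poisson())
      sum(stats::dpois(y, stats::fitted(gg), log = TRUE))
    }, error = function(e) ridge_poisson_irls(Xk, y)$loglik)
    2 * (L + 1) - 2 * g
  }, numeric(1))
  sel <- candidate_Ls[which.min(aic)]   # which.min takes the first = smallest L
  attr(sel, "aic") <- stats::setNames(aic, candidate_Ls)
  sel
}

#' Maximum-likelihood estimate of the onset hazard rho
#'
#' For the two-state chain with absorbing ictal state, the transition
#' probability rho has the closed-form MLE
#' (number of observed 0 to 1 transitions) / (number of steps spent in state
#' 0 that have a successor). Multiple training sequences pool counts.
#'
#' @param state_labels A 0/1 vector, or a list of such vectors (one per
#'   training sequence; each starts in state 0).
#' @return `rho_hat` in `[0, 1]`. Warns if no transition was observed.
#' @examples
#' estimate_rho(c(0, 0, 0, 1))   # 1/3
#' @export
estimate_rho <- function(state_labels) {
  if (!is.list(state_labels)) state_labels <- list(state_labels)
  trans <- 0L; at_risk <- 0L
  for (s in state_labels) {
    s <- as.integer(s)
    if (!all(s %in% c(0L, 1L))) stop("state labels must be 0/1")
    if (length(s) < 2L) next
    from0 <- s[-length(s)] == 0L
    at_risk <- at_risk + sum(from0)
    trans <- trans + sum(from0 & s[-1L] == 1L)
  }
  if (at_risk == 0L) stop("no time spent in state 0: rho is not estimable")
  if (trans == 0L) warning("no 0->1 transition observed; rho_hat = 0")
  trans / at_risk
}

## Log rate of the history GLM at one stage. history[j] = n_{k-j}.
glm_log_rate <- function(theta, history) {
  L <- theta$L
  if (L == 0L) return(theta$alpha)
  if (length(history) < L) stop("history shorter than the lag order")
  theta$alpha + sum(theta$betas * history[seq_len(L)])
}

#' State-conditional emission probability
#'
#' Probability of observing `z` in hidden state `state`, given the history
#' of quantized observations: the Poisson pmf at code `Q(z)` with rate
#' `exp(alpha_x + sum_j beta_{x,j} n_{k-j})`.
#'
#' @param model An `hmm_glm` model.
#' @param state 0 (nonictal) or 1 (ictal).
#' @param z Raw observation (real); quantized internally.
#' @param history Integer vector of previous codes, most recent first
#'   (`history[j]` is the code j stages back). Must have length >= L.
#' @return Probability in (0, 1].
#' @export
emission_probability <- function(model, state, z, history) {
  stopifnot(inherits(model, "hmm_glm"), state %in% c(0, 1))
  theta <- if (state == 0) model$theta0 else model$theta1
  lam <- exp(glm_log_rate(theta, history))
  stats::dpois(quantize(model$quantizer, z), lam)
}

#' Construct a two-state HMM-GLM observation model
#'
#' Assembles the full model triple: initial distribution `P0`, transition
#' matrix `[[1-rho, rho], [0, 1]]` (the ictal state absorbs within a
#' monitoring run), and per-state history-dependent Poisson-GLM emission
#' laws. Use [fit_hmm_glm()] to estimate one from data; this constructor
#' serves simulation studies and hand-specified models.
#'
#' @param rho Onset hazard, in `[0, 1]`.
#' @param theta0,theta1 `glm_params` (or lists with `alpha`, `betas`, `L`)
#'   for the nonictal and ictal states. Must share the same lag order.
#' @param quantizer A `quantizer`.
#' @param P0 Initial state distribution, default `c(1, 0)` (monitoring
#'   starts nonictal).
#' @param M Detection horizon in stages (seconds).
#' @param band Optional `band_spec` recording the frequency band used.
#' @param training Optional list with `counts` and `states` retained from
#'   fitting (used for history-marginalized policy synthesis).
#' @return Object of class `hmm_glm`.
#' @export
hmm_glm_model <- function(rho, theta0, theta1, quantizer,
                          P0 = c(1, 0), M = 3600L, band = NULL,
                          training = NULL) {
  as_theta <- function(th) {
    if (inherits(th, "glm_params")) return(th)
    structure(list(alpha = th$alpha,
                   betas = if (is.null(th$betas)) numeric(0) else th$betas,
                   L = length(if (is.null(th$betas)) numeric(0) else th$betas),
                   cov = th$cov %||% NULL,
                   loglik = th$loglik %||% NA_real_,
                   n_used = th$n_used %||% NA_integer_),
              class = "glm_params")
  }
  theta0 <- as_theta(theta0); theta1 <- as_theta(theta1)
  if (theta0$L != theta1$L) stop("theta0 and theta1 must share the lag order L")
  if (!(rho >= 0 && rho <= 1)) stop("rho must lie in [0, 1]")
  if (length(P0) != 2L || abs(sum(P0) - 1) > 1e-12 || any(P0 < 0))
    stop("P0 must be a 2-vector probability distribution")
  if (M < 1) stop("M must be >= 1")
  structure(list(rho = rho,
                 P0 = P0,
                 Sigma = matrix(c(1 - rho, 0, rho, 1), 2, 2),
                 quantizer = quantizer,
                 theta0 = theta0, theta1 = theta1,
                 L = theta0$L,
                 M = as.integer(M),
                 band = band,
                 training = training),
            class = "hmm_glm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## History pad code for stages with insufficient history: the integer
## nearest the nonictal stationary mean exp(alpha_0), clipped to the code
## domain.
history_pad <- function(model) {
  pad <- round(exp(model$theta0$alpha))
  as.integer(min(max(pad, 0), model$quantizer$n_bins - 1L))
}

#' Fit the two-state HMM-GLM to a labeled statistic series
#'
#' Training protocol: the quantizer is anchored on the full training series;
#' the nonictal parameters Theta_0 are fitted on stages labeled 0 and the
#' ictal parameters Theta_1 on stages labeled 1 (each stage keeps its true
#' preceding history from the continuous series, so short ictal epochs still
#' contribute); the onset hazard rho comes from the labeled transitions.
#' Optionally the lag order is selected by AIC on the nonictal stretch.
#'
#' @param z Numeric vector: the detection statistic (e.g. sigma1), one value
#'   per second.
#' @param states 0/1 vector of the same length: ictal annotation per stage.
#' @param L Lag order (default 15).
#' @param n_bins Quantizer bins (default 50).
#' @param candidate_L Optional integer vector; when given, L is selected by
#'   [select_lag_by_aic()] on the nonictal data.
#' @param M Detection horizon in stages; default the mean inter-onset
#'   interval of the annotations (or `length(z)` when fewer than two onsets).
#' @param rho Optional fixed hazard; default estimated from `states`.
#' @return A fitted `hmm_glm` model.
#' @export
fit_hmm_glm <- function(z, states, L = 15L, n_bins = 50L,
                        candidate_L = NULL, M = NULL, rho = NULL) {
  stopifnot(length(z) == length(states))
  states <- as.integer(states)
  q <- build_quantizer(z, n_bins)
  counts <- quantize(q, z)
  if (!is.null(candidate_L)) {
    L <- as.integer(select_lag_by_aic(counts[states == 0L], candidate_L))
  }
  L <- as.integer(L)
  n <- length(counts)
  X <- lag_design(counts, L)
  usable <- seq_len(n) > L
  fit_state <- function(s) {
    rows <- which(usable & states == s)
    if (length(rows) <= L + 2L)
      stop("too few stages labeled ", s, " to fit Theta_", s)
    y <- counts[rows]
    Xk <- X[rows, , drop = FALSE]
    fit <- tryCatch({
      g <- if (L == 0L) stats::glm(y ~ 1, family = stats::poisson())
           else stats::glm(y ~ Xk, family = stats::poisson())
      if (!g$converged || anyNA(stats::coef(g))) stop("glm did not converge")
      list(coefficients = unname(stats::coef(g)), vcov = unname(stats::vcov(g)),
           loglik = sum(stats::dpois(y, stats::fitted(g), log = TRUE)))
    }, error = function(e) ridge_poisson_irls(Xk, y))
    structure(list(alpha = fit$coefficients[1],
                   betas = if (L > 0L) fit$coefficients[-1] else numeric(0),
                   L = L, cov = fit$vcov, loglik = fit$loglik,
                   n_used = length(y)),
              class = "glm_params")
  }
  theta0 <- fit_state(0L)
  theta1 <- fit_state(1L)
  if (is.null(rho)) rho <- estimate_rho(states)
  if (is.null(M)) {
    onsets <- which(diff(states) == 1L)
    M <- if (length(onsets) >= 2L) round(mean(diff(onsets))) else length(z)
  }
  hmm_glm_model(rho, theta0, theta1, q, M = M,
                training = list(counts = counts, states = states))
}

## History-marginalized emission pmf per state over the full code alphabet.
## Used by policy synthesis: the exact DP over history-dependent emissions is
## exponential in L, so the dynamic program sees, per state, the average
## one-step predictive Poisson pmf over training histories (or, without
## training data, the pmf at the self-consistent fixed-point rate
## lambda = exp(alpha + sum(beta) * lambda)). Poisson tail mass beyond the
## top code is lumped into the top code, keeping the alphabet finite.
marginal_emission_pmf <- function(model) {
  B <- model$quantizer$n_bins
  codes <- 0:(B - 1L)
  state_rates <- function(theta, s) {
    tr <- model$training
    if (!is.null(tr)) {
      rows <- which(seq_along(tr$counts) > model$L & tr$states == s)
      if (length(rows) > 0L) {
        X <- lag_design(tr$counts, model$L)
        eta <- theta$alpha + if (model$L > 0L)
          drop(X[rows, , drop = FALSE] %*% theta$betas) else 0
        return(exp(pmin(eta, 30)))
      }
    }
    ## fixed-point rate of the self-exciting recursion
    lam <- exp(theta$alpha)
    for (i in 1:200) {
      lam_new <- exp(pmin(theta$alpha + sum(theta$betas) * lam, 30))
      if (abs(lam_new - lam) < 1e-12) { lam <- lam_new; break }
      lam <- lam_new
    }
    lam
  }
  pmf_for <- function(theta, s) {
    lams <- state_rates(theta, s)
    p <- rowMeans(vapply(lams, function(l) stats::dpois(codes, l), numeric(B)))
    p[B] <- p[B] + max(0, 1 - sum(p))   # lump the tail into the top code
    p / sum(p)
  }
  rbind(q0 = pmf_for(model$theta0, 0L), q1 = pmf_for(model$theta1, 1L))
}

#' Select the frequency band maximizing ictal/nonictal model separation
#'
#' For each candidate band, computes the sigma1 series of the training
#' record, fits the two-state model, and measures the distance between the
#' ictal and nonictal GLM parameter vectors; the band with the largest
#' distance wins. The distance is the Euclidean norm of the standardized
#' parameter difference, `sqrt(sum(((theta1 - theta0) / se)^2))` with
#' `se = sqrt(se0^2 + se1^2)` per coordinate (a Wald-type contrast).
#'
#' @param training_record A `multichannel_record` with ictal annotations.
#' @param bands List of [band_spec()] candidates.
#' @param L,n_bins Model settings passed to [fit_hmm_glm()].
#' @param min_nonictal_s Required nonictal training duration in seconds
#'   (default 3 h); lower it for short synthetic records.
#' @return The winning `band_spec`, with the per-band distances attached as
#'   attribute `"distance"`.
#' @export
select_band <- function(training_record, bands, L = 15L, n_bins = 50L,
                        min_nonictal_s = 10800) {
  stopifnot(inherits(training_record, "multichannel_record"))
  ann <- training_record$annotations
  if (is.null(ann) || nrow(ann) == 0L)
    stop("training record has no ictal annotations")
  if (length(bands) == 1L) return(bands[[1]])
  dur <- ncol(training_record$samples) / training_record$rate
  nonictal_s <- dur - sum(ann$offset_s - ann$onset_s)
  if (nonictal_s < min_nonictal_s)
    stop("insufficient nonictal training data: ", round(nonictal_s),
         " s < ", min_nonictal_s, " s")
  dist <- vapply(bands, function(b) {
    ss <- svd_statistic(connectivity_series(training_record, b))
    st <- stage_states(ann, ss$k_s)
    m <- fit_hmm_glm(ss$sigma1, st, L = L, n_bins = n_bins)
    d0 <- c(m$theta0$alpha, m$theta0$betas)
    d1 <- c(m$theta1$alpha, m$theta1$betas)
    se <- sqrt(pmax(diag(m$theta0$cov) + diag(m$theta1$cov), 1e-12))
    sqrt(sum(((d1 - d0) / se)^2))
  }, numeric(1))
  best <- bands[[which.max(dist)]]
  attr(best, "distance") <- stats::setNames(
    dist, vapply(bands, function(b) b$name, character(1)))
  best
}

#' Per-stage state labels from annotation intervals
#'
#' Expands onset/offset annotation intervals into the 0/1 label per stage
#' second used for model fitting: stage `k` is ictal when
#' `onset_s <= k < offset_s` for some annotated event.
#'
#' @param annotations Data frame with `onset_s`, `offset_s` (or `NULL`).
#' @param k_s Numeric vector of stage times in seconds.
#' @return Integer 0/1 vector parallel to `k_s`.
#' @export
stage_states <- function(annotations, k_s) {
  st <- integer(length(k_s))
  if (is.null(annotations) || nrow(annotations) == 0L) return(st)
  for (i in seq_len(nrow(annotations))) {
    st[k_s >= annotations$onset_s[i] & k_s < annotations$offset_s[i]] <- 1L
  }
  st
}

#' Serialize / restore a fitted model as JSON
#'
#' The document stores rho, P0, quantizer bin edges, lag order, per-state
#' alpha/betas, the horizon M and the band. Training counts are not stored.
#'
#' @param model An `hmm_glm`.
#' @param path File path.
#' @return `write_model`: the path, invisibly. `read_model`: the model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "hmm_glm"))
  doc <- list(rho = model$rho, P0 = model$P0,
              bin_edges = model$quantizer$bin_edges,
              L = model$L, M = model$M,
              alpha0 = model$theta0$alpha, betas0 = model$theta0$betas,
              alpha1 = model$theta1$alpha, betas1 = model$theta1$betas,
              band = if (is.null(model$band)) NULL else
                list(name = model$band$name, lb = model$band$lb, ub = model$band$ub))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  q <- structure(list(bin_edges = doc$bin_edges,
                      n_bins = length(doc$bin_edges) - 1L),
                 class = "quantizer")
  band <- if (!is.null(doc$band)) {
    if (doc$band$name == "custom") band_spec("custom", doc$band$lb, doc$band$ub)
    else band_spec(doc$band$name)
  }
  hmm_glm_model(doc$rho,
                list(alpha = doc$alpha0, betas = doc$betas0),
                list(alpha = doc$alpha1, betas = doc$betas1),
                q, P0 = doc$P0, M = doc$M, band = band)
}
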