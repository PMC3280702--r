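## Quickest-detection policy: per-stage costs, dynamic-programming backward
## induction over a discretized information state, and the online detector
## with terminate-and-restart.

#' Expected elapsed delay given the change already occurred
#'
#' Under the geometric onset prior `P(T = t) = (1 - rho)^(t-1) rho`, the
#' expected elapsed delay at stage `k` conditional on the onset having
#' occurred, `E[k - T | T <= k]`. Grows without bound in `k`: the longer a
#' true onset has been missed, the costlier another stage of waiting — this
#' is what drives the detection threshold down over time.
#'
#' @param k Stage (vectorized), `k >= 0`; the value at `k = 0` (empty
#'   conditioning support) is 0.
#' @param rho Onset hazard in (0, 1).
#' @return `E[k - T | T <= k]`, same length as `k`.
#' @examples
#' expected_delay_given_past(1, 0.5)   # 0
#' expected_delay_given_past(2, 0.5)   # 2/3
#' @export
expected_delay_given_past <- function(k, rho) {
  if (!(rho > 0 && rho < 1)) stop("rho must lie strictly in (0, 1)")
  q <- 1 - rho
  qk <- exp(k * log(q))
  den <- 1 - qk
  ET <- (1 - qk * (1 + k * rho)) / (rho * den)   # E[T | T <= k]
  out <- k - ET
  out[k < 1] <- 0
  pmax(out, 0)
}

#' Expected residual time to the change
#'
#' Mean remaining time until onset when stopping before it, under the
#' memoryless geometric prior: `1 / rho`.
#'
#' @param rho Onset hazard in (0, 1].
#' @return `1 / rho`.
#' @export
expected_time_to_change <- function(rho) {
  if (!(rho > 0 && rho <= 1)) stop("rho must lie in (0, 1]")
  1 / rho
}

#' Cost specification for the quickest-detection policy
#'
#' The per-stage cost weighs expected detection delay (weight `gamma`,
#' incurred while continuing after a true onset) against the expected
#' prematurity of a false alarm (weight `1 - gamma`, incurred when stopping
#' before the onset). `gamma` near 1 punishes delay and yields a hair
#' trigger; near 0 it punishes false positives and the policy never fires
#' before the horizon.
#'
#' @param gamma Delay weight in `[0, 1]`; default 0.3 (false positives
#'   penalized more than delay).
#' @param delay_exponent 1 (linear delay cost, default) or 2 (squared).
#' @param horizon_M Detection horizon in stages; `NULL` defers to the model.
#' @param rho Onset hazard of the change prior; `NULL` defers to the model.
#' @return Object of class `cost_spec`.
#' @export
cost_spec <- function(gamma = 0.3, delay_exponent = 1, horizon_M = NULL,
                      rho = NULL) {
  if (!(gamma >= 0 && gamma <= 1)) stop("gamma must lie in [0, 1]")
  if (!delay_exponent %in% c(1, 2)) stop("delay_exponent must be 1 or 2")
  if (!is.null(horizon_M) && horizon_M < 2) stop("horizon_M must be >= 2")
  structure(list(gamma = gamma, delay_exponent = delay_exponent,
                 horizon_M = horizon_M, rho = rho),
            class = "cost_spec")
}

resolve_cost <- function(cost, model) {
  if (is.null(cost$horizon_M)) cost$horizon_M <- model$M
  if (is.null(cost$rho)) cost$rho <- model$rho
  if (!(cost$rho > 0 && cost$rho < 1))
    stop("policy synthesis requires rho strictly inside (0, 1)")
  cost
}

#' Cost per stage
#'
#' `G_k(pi, u)`: continuing (`u = 0`) costs
#' `gamma * D(k)^e * pi` with `D(k)` the expected elapsed delay given a past
#' onset; stopping (`u = 1`) costs
#' `(1 - gamma) * (1 / rho) * (1 - pi)`, the false-positive penalty scaled
#' by the expected time the alarm anticipates the change.
#'
#' @param pi Information state in `[0, 1]`.
#' @param u Decision: 0 continue, 1 stop.
#' @param k Stage index (0-based).
#' @param cost A [cost_spec()] with `rho` set.
#' @return Nonnegative stage cost.
#' @export
stage_cost <- function(pi, u, k, cost) {
  stopifnot(inherits(cost, "cost_spec"), !is.null(cost$rho))
  if (u == 0) {
    cost$gamma * expected_delay_given_past(k, cost$rho)^cost$delay_exponent * pi
  } else if (u == 1) {
    (1 - cost$gamma) * expected_time_to_change(cost$rho) * (1 - pi)
  } else 0
}

## Marginalized symbol machinery shared by grid DP and exact DP.
## Returns q0/q1 pmfs over the code alphabet and the clipped likelihood
## ratio per symbol.
policy_emissions <- function(model) {
  qbar <- marginal_emission_pmf(model)
  q0 <- pmax(qbar["q0", ], 1e-300)
  q1 <- pmax(qbar["q1", ], 1e-300)
  Lr <- pmin(pmax(q1 / q0, exp(-LOG_LR_CLIP)), exp(LOG_LR_CLIP))
  list(q0 = q0, q1 = q1, Lr = Lr)
}

#' Synthesize the adaptive detection threshold by dynamic programming
#'
#' Backward induction from the horizon: `J_M(pi)` is the forced-stop cost
#' `(1 - gamma) (1 / rho) (1 - pi)`; at earlier stages
#' `J_k(pi) = min(stop cost, continue cost + E[J_(k+1)(Phi(pi, z))])`, the
#' expectation running over the next quantized symbol under the pi-mixture
#' of the state-conditional, history-marginalized emission laws. The
#' per-stage threshold `F_k` is the smallest grid point at which stopping is
#' optimal; online detection fires at the first stage with `pi_k > F_k`
#' (strict, so ties continue). The threshold falls (non-monotonically) as
#' `k` approaches the horizon.
#'
#' @param model A fitted `hmm_glm`.
#' @param cost A [cost_spec()]; horizon and hazard default to the model's.
#' @param pi_grid_size Number of uniform grid points on `[0, 1]`
#'   (default 1001); `J` is linearly interpolated inside the expectation.
#' @param keep_values Retain the full value table `J` (grid x stages)?
#' @return Object of class `qd_policy`: list with `pi_grid`, `F` (length
#'   `M`, thresholds for stages 0 ... M-1), `cost`, `J0` (value at stage 0
#'   as a function of the grid), optionally `value_table`, and
#'   `nonconvex_stages` (stages where the stop region was not a clean upper
#'   interval on the grid, flagged by a warning).
#' @export
synthesize_policy <- function(model, cost = cost_spec(), pi_grid_size = 1001,
                              keep_values = FALSE) {
  stopifnot(inherits(model, "hmm_glm"))
  cost <- resolve_cost(cost, model)
  if (pi_grid_size < 101) stop("pi_grid_size must be >= 101")
  M <- as.integer(cost$horizon_M)
  rho <- cost$rho
  gam <- cost$gamma
  em <- policy_emissions(model)
  B <- length(em$Lr)
  g <- seq(0, 1, length.out = pi_grid_size)
  G <- pi_grid_size
  h <- g[2] - g[1]
  pi1 <- g + (1 - g) * rho                    # predicted state-1 prob
  ## per-symbol transition of the grid and predictive probability
  PN <- ILO <- W <- P <- matrix(0, G, B)
  for (b in seq_len(B)) {
    num <- em$Lr[b] * pi1
    den <- (1 - g) * (1 - rho) + num
    pn <- num / den
    pn <- pmin(pmax(pn, 0), 1)
    ilo <- pmin(findInterval(pn, g), G - 1L)
    PN[, b] <- pn
    ILO[, b] <- ilo
    W[, b] <- (g[ilo + 1L] - pn) / h          # weight on the lower grid point
    P[, b] <- pi1 * em$q1[b] + (1 - pi1) * em$q0[b]
  }
  ILO <- matrix(as.integer(ILO), G, B)
  WHI <- 1 - W
  Dk <- expected_delay_given_past(0:(M - 1L), rho)^cost$delay_exponent
  stop_cost <- (1 - gam) * (1 / rho) * (1 - g)
  Jnext <- stop_cost                           # forced decision at the horizon
  Fk <- numeric(M)
  value_table <- if (keep_values) matrix(NA_real_, G, M + 1L) else NULL
  if (keep_values) value_table[, M + 1L] <- Jnext
  nonconvex <- integer(0)
  for (k in (M - 1L):0L) {
    EJ <- rowSums(P * (W * Jnext[ILO] + WHI * Jnext[ILO + 1L]))
    cont <- gam * Dk[k + 1L] * g + EJ
    opt_stop <- stop_cost <= cont
    first <- which(opt_stop)[1]
    Fk[k + 1L] <- if (is.na(first)) 1 else g[first]
    if (!is.na(first) && any(!opt_stop[first:G])) nonconvex <- c(nonconvex, k)
    Jnext <- pmin(stop_cost, cont)
    if (keep_values) value_table[, k + 1L] <- Jnext
  }
  if (length(nonconvex) > 0L)
    warning("stop region not an upper interval on the grid at stage(s) ",
            paste(utils::head(nonconvex, 5), collapse = ", "),
            "; consider a finer pi grid")
  structure(list(pi_grid = g, F = Fk, cost = cost, J0 = Jnext,
                 value_table = value_table, n_symbols = B,
                 nonconvex_stages = nonconvex),
            class = "qd_policy")
}

#' Exact dynamic-programming value of the optimal stopping problem
#'
#' Grid-free evaluation of the optimal expected cost by direct recursion on
#' the information state: exact posterior propagation through the filter
#' update at every reachable observation prefix, no discretization or
#' interpolation. Cost is exponential in the horizon (alphabet^M), so this
#' is for small instances — model validation and the dynamic-programming
#' cross-checks. Stopping is allowed at stages 0 ... M-1 with ties resolved
#' toward stopping; the horizon forces the stop cost.
#'
#' @param model An `hmm_glm` (history-free emissions, i.e. `L = 0`, make
#'   the marginalized emission laws exact).
#' @param cost A [cost_spec()].
#' @return List with `J0` (total expected cost, including the expectation
#'   over the first observation) and `value(k, pi)`, the cost-to-go
#'   function usable for inspection.
#' @export
qd_value_exact <- function(model, cost = cost_spec()) {
  stopifnot(inherits(model, "hmm_glm"))
  cost <- resolve_cost(cost, model)
  M <- as.integer(cost$horizon_M)
  rho <- cost$rho; gam <- cost$gamma
  em <- policy_emissions(model)
  B <- length(em$Lr)
  Dk <- expected_delay_given_past(0:(M - 1L), rho)^cost$delay_exponent
  stopc <- function(pi) (1 - gam) * (1 / rho) * (1 - pi)
  value <- function(k, pi) {
    if (k == M) return(stopc(pi))
    pi1 <- pi + (1 - pi) * rho
    cont <- gam * Dk[k + 1L] * pi
    for (b in seq_len(B)) {
      pn <- em$Lr[b] * pi1 / ((1 - pi) * (1 - rho) + em$Lr[b] * pi1)
      pb <- pi1 * em$q1[b] + (1 - pi1) * em$q0[b]
      cont <- cont + pb * value(k + 1L, pn)
    }
    min(stopc(pi), cont)
  }
  ## expectation over the first observation from the prior P0
  p0 <- model$P0[1]
  J0 <- 0
  for (b in seq_len(B)) {
    pb <- p0 * em$q0[b] + (1 - p0) * em$q1[b]
    pi0 <- em$q1[b] * (1 - p0) / (em$q0[b] * p0 + em$q1[b] * (1 - p0))
    J0 <- J0 + pb * value(0L, pi0)
  }
  list(J0 = J0, value = value)
}

#' First stage at which stopping is optimal, per observation sequence
#'
#' Replays a fixed quantized observation sequence through the exact
#' (grid-free) dynamic program and reports the first stage whose stop cost
#' is no larger than its continue cost (ties stop). `NA` if continuing is
#' optimal at every stage before the horizon.
#'
#' @param model An `hmm_glm` with history-free emissions.
#' @param cost A [cost_spec()].
#' @param codes Integer vector of quantized symbols (stages 0, 1, ...).
#' @return 0-based stage index or `NA`.
#' @export
qd_optimal_stop_stage <- function(model, cost, codes) {
  cost <- resolve_cost(cost, model)
  M <- as.integer(cost$horizon_M)
  rho <- cost$rho; gam <- cost$gamma
  em <- policy_emissions(model)
  B <- length(em$Lr)
  Dk <- expected_delay_given_past(0:(M - 1L), rho)^cost$delay_exponent
  stopc <- function(pi) (1 - gam) * (1 / rho) * (1 - pi)
  cont_value <- function(k, pi) {
    if (k == M) return(stopc(pi))
    pi1 <- pi + (1 - pi) * rho
    cont <- gam * Dk[k + 1L] * pi
    for (b in seq_len(B)) {
      pn <- em$Lr[b] * pi1 / ((1 - pi) * (1 - rho) + em$Lr[b] * pi1)
      pb <- pi1 * em$q1[b] + (1 - pi1) * em$q0[b]
      cont <- cont + pb * min(stopc(pn), cont_value(k + 1L, pn))
    }
    cont
  }
  p0 <- model$P0[1]
  b0 <- codes[1] + 1L
  pi <- em$q1[b0] * (1 - p0) / (em$q0[b0] * p0 + em$q1[b0] * (1 - p0))
  for (k in 0:(min(M, length(codes)) - 1L)) {
    if (k > 0L) {
      b <- codes[k + 1L] + 1L
      pi1 <- pi + (1 - pi) * rho
      pi <- em$Lr[b] * pi1 / ((1 - pi) * (1 - rho) + em$Lr[b] * pi1)
    }
    if (k < M && stopc(pi) <= cont_value(k, pi)) return(k)
  }
  NA_integer_
}

#' @export
print.qd_policy <- function(x, ...) {
  cat(sprintf("quickest-detection policy: M = %d stages, gamma = %.3g, rho = %.3g\n",
              length(x$F), x$cost$gamma, x$cost$rho))
  cat(sprintf("threshold range [%.4g, %.4g] over %d-point pi grid, %d symbols\n",
              min(x$F), max(x$F), length(x$pi_grid), x$n_symbols))
  invisible(x)
}

#' @export
plot.qd_policy <- function(x, ...) {
  graphics::plot(seq_along(x$F) - 1L, x$F, type = "l", xlab = "stage k (s)",
                 ylab = expression(F[k]), ylim = c(0, 1),
                 main = "Adaptive detection threshold", ...)
  invisible(x)
}

## Shared online loop: filter pi, compare to a per-segment-stage threshold,
## emit detections with terminate-and-restart. After a detection the
## detector re-arms once (i) the refractory time has elapsed and (ii) pi
## has dropped back below the current threshold (renewal-style hysteresis:
## a persisting alarm condition is one event, not a train of them).
## threshold_at(s) gives the threshold for 0-based segment stage s.
run_pi_detector <- function(model, observations, threshold_at,
                            refractory_s = 60, min_stage = 1L) {
  n <- length(observations)
  counts <- quantize(model$quantizer, observations)
  pad <- history_pad(model)
  L <- model$L
  pi <- numeric(n); lr <- rep(NA_real_, n)
  restarts <- integer(0)
  det_stage <- integer(0); det_pi <- numeric(0)
  seg <- 0L            # 0-based stage within the current segment
  refract_until <- -Inf
  armed <- TRUE
  for (i in seq_len(n)) {
    k <- i - 1L        # global 0-based stage = seconds
    if (i == 1L || seg == 0L) {
      pi[i] <- initial_pi(model, observations[i])
      if (i > 1L) restarts <- c(restarts, i)
    } else {
      avail <- counts[(i - 1L):max(1L, i - L)]
      history <- if (L > 0L) c(avail, rep(pad, max(0L, L - length(avail))))
                 else integer(0)
      lr[i] <- likelihood_ratio(model, observations[i], history)
      pi[i] <- update_pi(pi[i - 1L], lr[i], model$rho)
    }
    pi[i] <- min(max(pi[i], PI_CLIP), 1 - PI_CLIP)
    thr <- threshold_at(seg)
    if (!armed && k >= refract_until && pi[i] <= thr) armed <- TRUE
    fired <- armed && seg >= min_stage && k >= refract_until && pi[i] > thr
    if (fired) {
      det_stage <- c(det_stage, k)
      det_pi <- c(det_pi, pi[i])
      refract_until <- k + refractory_s
      armed <- FALSE
      seg <- 0L        # terminate & restart at the next stage
    } else {
      seg <- seg + 1L
    }
  }
  traj <- structure(list(pi = pi, likelihood_ratios = lr,
                         restart_indices = restarts, counts = counts),
                    class = "info_trajectory")
  list(stage = det_stage, pi_at_detection = det_pi, trajectory = traj)
}

#' Run the quickest-detection policy online
#'
#' Filters the information state over the observation series, fires a
#' detection at the first segment stage `0 < s < M` with
#' `pi > F_s` (strict), then terminates and restarts: the filter and the
#' stage clock reset at the next stage and detections are suppressed for
#' `refractory_s` seconds. Segments outliving the horizon keep monitoring
#' with the threshold held at its final-stage value.
#'
#' @param model A fitted `hmm_glm`.
#' @param policy A `qd_policy` from [synthesize_policy()].
#' @param observations Numeric vector, one raw observation per second.
#' @param refractory_s Refractory period after each detection (default 60).
#' @return Object of class `qd_detection`: list with `detections`
#'   (data.frame `stage`, `time_s`, `pi`), `trajectory`
#'   (`info_trajectory`), and `policy_id`.
#' @export
run_qd <- function(model, policy, observations, refractory_s = 60) {
  stopifnot(inherits(policy, "qd_policy"))
  M <- length(policy$F)
  if (M < 2) stop("policy horizon must be >= 2")
  res <- run_pi_detector(model, observations,
                         threshold_at = function(s) policy$F[min(s, M - 1L) + 1L],
                         refractory_s = refractory_s, min_stage = 1L)
  structure(list(detections = data.frame(stage = res$stage,
                                         time_s = as.numeric(res$stage),
                                         pi = res$pi_at_detection),
                 trajectory = res$trajectory,
                 policy_id = sprintf("qd_gamma%.3g", policy$cost$gamma)),
            class = "qd_detection")
}

#' @export
print.qd_detection <- function(x, ...) {
  cat(sprintf("%s: %d detection(s) over %d stages\n", x$policy_id,
              nrow(x$detections), length(x$trajectory$pi)))
  if (nrow(x$detections) > 0)
    cat("at t =", paste(x$detections$time_s, collapse = ", "), "s\n")
  invisible(x)
}

#' Write detections to CSV
#'
#' Columns: `t_s`, `pi`, `policy_id`.
#' @param x A `qd_detection`.
#' @param path Output file path.
#' @export
write_detections <- function(x, path) {
  stopifnot(inherits(x, "qd_detection"))
  df <- data.frame(t_s = x$detections$time_s, pi = x$detections$pi,
                   policy_id = rep(x$policy_id, nrow(x$detections)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize / restore a threshold policy as JSON
#'
#' @param policy A `qd_policy`.
#' @param path File path.
#' @export
write_policy <- function(policy, path) {
  stopifnot(inherits(policy, "qd_policy"))
  doc <- list(pi_grid = policy$pi_grid, F = policy$F,
              gamma = policy$cost$gamma,
              delay_exponent = policy$cost$delay_exponent,
              horizon_M = policy$cost$horizon_M, rho = policy$cost$rho,
              n_symbols = policy$n_symbols)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_policy
#' @export
read_policy <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(pi_grid = doc$pi_grid, F = doc$F,
                 cost = cost_spec(doc$gamma, doc$delay_exponent,
                                  doc$horizon_M, doc$rho),
                 J0 = NULL, value_table = NULL, n_symbols = doc$n_symbols,
                 nonconvex_stages = integer(0)),
            class = "qd_policy")
}
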