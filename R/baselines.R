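## Baseline detectors and the evaluation protocol.

#' Bayesian-estimator baseline detector
#'
#' Classic change-point baseline: fire at the first stage of each monitoring
#' segment where the information state exceeds 0.5,
#' `T_BE = min(k > 0 | pi_k > 0.5)`, with the same terminate-and-restart and
#' refractory machinery as the quickest-detection policy.
#'
#' @param model A fitted `hmm_glm`.
#' @param observations Numeric vector, one raw observation per second.
#' @param threshold Fixed posterior threshold (default 0.5).
#' @param refractory_s Refractory period after each detection (default 60).
#' @return A `qd_detection` object (`policy_id = "be"`).
#' @export
bayes_detector <- function(model, observations, threshold = 0.5,
                           refractory_s = 60) {
  res <- run_pi_detector(model, observations,
                         threshold_at = function(s) threshold,
                         refractory_s = refractory_s, min_stage = 1L)
  structure(list(detections = data.frame(stage = res$stage,
                                         time_s = as.numeric(res$stage),
                                         pi = res$pi_at_detection),
                 trajectory = res$trajectory, policy_id = "be"),
            class = "qd_detection")
}

#' Heuristic-threshold baseline detector
#'
#' Thresholds the raw statistic at `hbar = mean + 3 * sd` of the nonictal
#' training stretch (sample standard deviation, n-1 denominator). Fires at
#' the first stage of each segment with `z_k > hbar`; after a detection the
#' detector re-arms once the refractory period has elapsed and `z` has
#' dropped back below the threshold (the same renewal hysteresis as the
#' posterior-based detectors).
#'
#' @param z Numeric vector: the test statistic series.
#' @param training_z Numeric vector: nonictal training values of the same
#'   statistic.
#' @param refractory_s Refractory period in seconds (default 60).
#' @return A `qd_detection`-like object with `detections`, `hbar`,
#'   `policy_id = "ht"`.
#' @export
heuristic_detector <- function(z, training_z, refractory_s = 60) {
  if (length(training_z) == 0L) stop("empty training sequence")
  s <- stats::sd(training_z)
  if (!is.finite(s) || s == 0) {
    warning("degenerate threshold: training data has zero variance")
    s <- 0
  }
  hbar <- mean(training_z) + 3 * s
  det <- integer(0)
  refract_until <- -Inf
  armed <- TRUE
  for (i in seq_along(z)) {
    k <- i - 1L
    if (!armed && k >= refract_until && z[i] <= hbar) armed <- TRUE
    if (armed && k >= refract_until && z[i] > hbar) {
      det <- c(det, k)
      refract_until <- k + refractory_s
      armed <- FALSE
    }
  }
  structure(list(detections = data.frame(stage = det,
                                         time_s = as.numeric(det),
                                         pi = rep(NA_real_, length(det))),
                 hbar = hbar, policy_id = "ht"),
            class = "qd_detection")
}

#' Score detections against annotated onsets
#'
#' Greedy one-to-one matching in detection-time order: a detection with an
#' unmatched onset within `tolerance_s` seconds (either side) is a true
#' positive, carrying the signed delay `detection - onset` (negative =
#' anticipation); otherwise it is a false positive. Onsets left unmatched
#' are false negatives. The combined delay summary is the mean of absolute
#' delays. The false-positive rate is FP per analyzed hour, the analyzed
#' span excluding annotated ictal intervals (and, optionally, refractory
#' time after each detection).
#'
#' @param detections Sorted numeric vector of detection times (s).
#' @param onsets Sorted numeric vector of annotated onset times (s).
#' @param tolerance_s Matching tolerance (default 20 s).
#' @param duration_s Total analyzed duration in seconds (for the FP rate);
#'   `NA` rate if omitted.
#' @param ictal_s Total annotated ictal time to exclude from the analyzed
#'   span (default 0).
#' @param refractory_s Per-detection refractory time to exclude (default 0).
#' @return Object of class `detection_report`: `tp`, `fp`, `fn`, `delays`
#'   (signed, per matched onset), `sensitivity`, `fpr_per_h`,
#'   `mean_abs_delay_s`, `detections`, `onsets`.
#' @examples
#' score_detections(c(105), c(100), duration_s = 3600)  # TP, delay +5 s
#' @export
score_detections <- function(detections, onsets, tolerance_s = 20,
                             duration_s = NULL, ictal_s = 0,
                             refractory_s = 0) {
  if (is.unsorted(detections) || is.unsorted(onsets))
    stop("detections and onsets must be sorted")
  matched_onset <- rep(FALSE, length(onsets))
  is_tp <- rep(FALSE, length(detections))
  delays <- rep(NA_real_, length(onsets))
  for (i in seq_along(detections)) {
    d <- abs(onsets - detections[i])
    d[matched_onset] <- Inf
    if (length(d) > 0 && min(d) <= tolerance_s) {
      j <- which.min(d)
      matched_onset[j] <- TRUE
      is_tp[i] <- TRUE
      delays[j] <- detections[i] - onsets[j]
    }
  }
  tp <- sum(is_tp); fp <- sum(!is_tp); fn <- sum(!matched_onset)
  analyzed_h <- if (is.null(duration_s)) NA_real_ else
    max(duration_s - ictal_s - refractory_s * length(detections), 0) / 3600
  structure(list(tp = tp, fp = fp, fn = fn,
                 delays = delays[matched_onset],
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 fpr_per_h = if (is.finite(analyzed_h) && analyzed_h > 0)
                   fp / analyzed_h else NA_real_,
                 mean_abs_delay_s = if (tp > 0)
                   mean(abs(delays[matched_onset])) else NA_real_,
                 analyzed_h = analyzed_h,
                 detections = detections, onsets = onsets),
            class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d | sensitivity %.3f | FPR %s FP/h | mean |delay| %s s\n",
              x$tp, x$fp, x$fn, x$sensitivity,
              ifelse(is.na(x$fpr_per_h), "NA", sprintf("%.2f", x$fpr_per_h)),
              ifelse(is.na(x$mean_abs_delay_s), "NA",
                     sprintf("%.1f", x$mean_abs_delay_s))))
  invisible(x)
}

## Pool several per-run reports into one (counts add; delays concatenate;
## analyzed hours add).
pool_reports <- function(reports) {
  tp <- sum(vapply(reports, `[[`, 0, "tp"))
  fp <- sum(vapply(reports, `[[`, 0, "fp"))
  fn <- sum(vapply(reports, `[[`, 0, "fn"))
  delays <- unlist(lapply(reports, `[[`, "delays"))
  ah <- sum(vapply(reports, `[[`, 0, "analyzed_h"))
  structure(list(tp = tp, fp = fp, fn = fn, delays = delays,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 fpr_per_h = if (is.finite(ah) && ah > 0) fp / ah else NA_real_,
                 mean_abs_delay_s = if (length(delays) > 0)
                   mean(abs(delays)) else NA_real_,
                 analyzed_h = ah,
                 detections = NULL, onsets = NULL),
            class = "detection_report")
}

#' Delay / false-positive trade-off across the cost weight gamma
#'
#' Re-synthesizes the quickest-detection policy for each value of `gamma`,
#' runs it over the observation runs, and scores each against the annotated
#' onsets, tracing the delay-versus-false-positive trade-off curve.
#'
#' @param model A fitted `hmm_glm`.
#' @param cost_template A [cost_spec()] supplying delay exponent, horizon
#'   and hazard; its `gamma` is overridden per grid point.
#' @param observations A numeric vector, or a list of vectors (one per
#'   independent run).
#' @param onsets Numeric vector of onset times, or a list parallel to
#'   `observations`.
#' @param gamma_grid Gamma values; default `c(0.01, 0.1, 0.3, 0.5, 0.9, 0.999)`.
#' @param refractory_s Refractory period (default 60).
#' @param tolerance_s Scoring tolerance (default 20).
#' @param ictal_s Ictal seconds excluded from the analyzed span, per run.
#' @param pi_grid_size Grid size for [synthesize_policy()].
#' @return Object of class `gamma_sweep`: list with `summary` (data.frame
#'   `gamma`, `tp`, `fp`, `fn`, `sensitivity`, `fpr_per_h`,
#'   `delay_mean_abs_s`) and `reports` (one pooled `detection_report` per
#'   gamma).
#' @export
gamma_sweep <- function(model, cost_template, observations, onsets,
                        gamma_grid = c(0.01, 0.1, 0.3, 0.5, 0.9, 0.999),
                        refractory_s = 60, tolerance_s = 20, ictal_s = 0,
                        pi_grid_size = 1001) {
  if (any(gamma_grid < 0 | gamma_grid > 1)) stop("gamma grid must lie in [0, 1]")
  if (!is.list(observations)) observations <- list(observations)
  if (!is.list(onsets)) onsets <- rep(list(onsets), length(observations))
  stopifnot(length(observations) == length(onsets))
  reports <- vector("list", length(gamma_grid))
  for (gi in seq_along(gamma_grid)) {
    cost <- cost_template
    cost$gamma <- gamma_grid[gi]
    policy <- synthesize_policy(model, cost, pi_grid_size = pi_grid_size)
    per_run <- lapply(seq_along(observations), function(r) {
      det <- run_qd(model, policy, observations[[r]], refractory_s)
      score_detections(det$detections$time_s, sort(onsets[[r]]),
                       tolerance_s = tolerance_s,
                       duration_s = length(observations[[r]]),
                       ictal_s = ictal_s)
    })
    reports[[gi]] <- pool_reports(per_run)
  }
  summary <- data.frame(
    gamma = gamma_grid,
    tp = vapply(reports, `[[`, 0, "tp"),
    fp = vapply(reports, `[[`, 0, "fp"),
    fn = vapply(reports, `[[`, 0, "fn"),
    sensitivity = vapply(reports, `[[`, 0, "sensitivity"),
    fpr_per_h = vapply(reports, `[[`, 0, "fpr_per_h"),
    delay_mean_abs_s = vapply(reports, `[[`, 0, "mean_abs_delay_s"))
  structure(list(summary = summary, reports = reports), class = "gamma_sweep")
}

#' @export
print.gamma_sweep <- function(x, ...) {
  cat("gamma sensitivity sweep:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' @export
plot.gamma_sweep <- function(x, ...) {
  s <- x$summary
  graphics::plot(s$fpr_per_h, s$delay_mean_abs_s, type = "b",
                 xlab = "false positives per hour", ylab = "mean |delay| (s)",
                 main = "Delay / false-positive trade-off", ...)
  graphics::text(s$fpr_per_h, s$delay_mean_abs_s,
                 labels = sprintf("%.3g", s$gamma), pos = 3, cex = 0.8)
  invisible(x)
}

#' Write a detection report (or sweep summary) to disk
#'
#' Reports go to a JSON summary plus a CSV of per-event delays; sweeps to a
#' tidy CSV (`gamma`, `delay_mean_abs_s`, `fpr_per_h`, `sensitivity`).
#'
#' @param x A `detection_report` or `gamma_sweep`.
#' @param path Output path (`.json` for reports, `.csv` for sweeps).
#' @export
write_report <- function(x, path) {
  if (inherits(x, "gamma_sweep")) {
    utils::write.csv(x$summary[, c("gamma", "delay_mean_abs_s",
                                   "fpr_per_h", "sensitivity")],
                     path, row.names = FALSE)
  } else if (inherits(x, "detection_report")) {
    jsonlite::write_json(list(tp = x$tp, fp = x$fp, fn = x$fn,
                              sensitivity = x$sensitivity,
                              fpr_per_h = x$fpr_per_h,
                              mean_abs_delay_s = x$mean_abs_delay_s,
                              delays = x$delays),
                         path, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported object")
  invisible(path)
}
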