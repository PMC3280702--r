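## End-to-end orchestration over files: simulate -> fit -> detect ->
## evaluate. Thin wrappers over the package functions, used by the
## command-line script in inst/scripts/qdetect.R.

#' Run configuration for the file pipeline
#'
#' Collects paths and analysis settings. Defaults mirror the published
#' protocol: 5-s window / 1-s slide, lag candidates including 15, 20-s
#' scoring tolerance, posterior threshold 0.5 for the Bayesian baseline.
#'
#' @param out_dir Output directory.
#' @param record,annotations,model,policy Optional input file paths.
#' @param band A [band_spec()] (default beta) or list of candidates for
#'   band selection.
#' @param n_bins Quantizer bins (default 50).
#' @param L_candidates Lag-order candidates for AIC selection (default 15,
#'   i.e. fixed).
#' @param gamma Cost weight (default 0.3).
#' @param M Horizon; `NULL` = from data.
#' @param refractory_s Refractory period (default 60).
#' @param tolerance_s Scoring tolerance (default 20).
#' @param rate Sampling rate of delimited records (Hz).
#' @param seed Integer seed.
#' @return Object of class `run_config`.
#' @export
run_config <- function(out_dir, record = NULL, annotations = NULL,
                       model = NULL, policy = NULL,
                       band = band_spec("beta"), n_bins = 50,
                       L_candidates = 15L, gamma = 0.3, M = NULL,
                       refractory_s = 60, tolerance_s = 20, rate = 250,
                       seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

write_provenance <- function(config, out_dir, stage) {
  plain <- lapply(unclass(config), function(x)
    if (inherits(x, "band_spec")) unclass(x) else x)
  tmp <- tempfile(); on.exit(unlink(tmp))
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(
    list(stage = stage,
         config = plain,
         config_md5 = unname(tools::md5sum(tmp)),
         seed = config$seed,
         package_version = as.character(utils::packageVersion("qdetect")),
         r_version = R.version.string,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    file.path(out_dir, paste0("provenance_", stage, ".json")),
    auto_unbox = TRUE, digits = NA, null = "null")
}

#' Pipeline stages over files
#'
#' `pipeline_simulate` writes a surrogate record (`record.tsv`), its
#' annotations (`annotations.csv`) and the ground-truth per-second state
#' series (`states.csv`). `pipeline_fit` computes the sigma1 series, fits
#' the HMM-GLM and writes `model.json` (plus `sigma1.csv`).
#' `pipeline_detect` synthesizes (or loads) the policy and writes the QD,
#' BE and HT detection streams. `pipeline_evaluate` scores all streams
#' against the annotations and writes `report_<id>.json` plus an optional
#' gamma-sweep CSV. Every stage drops a provenance JSON (config + md5 +
#' seed + versions) in the output directory, and the whole chain is
#' deterministic under the config seed.
#'
#' @param config A [run_config()].
#' @param sim A [sim_config()] for the surrogate recording.
#' @return Invisibly, the paths written.
#' @export
pipeline_simulate <- function(config, sim = sim_config(seed = config$seed)) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  rec <- simulate_record(sim)
  p1 <- file.path(config$out_dir, "record.tsv")
  p2 <- file.path(config$out_dir, "annotations.csv")
  write_record(rec, p1, p2)
  ks <- seq_len(floor(ncol(rec$samples) / rec$rate))
  st <- stage_states(rec$annotations, ks)
  p3 <- file.path(config$out_dir, "states.csv")
  utils::write.csv(data.frame(k_s = ks, state = st), p3, row.names = FALSE)
  write_provenance(config, config$out_dir, "simulate")
  invisible(c(p1, p2, p3))
}

#' @rdname pipeline_simulate
#' @export
pipeline_fit <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  rec <- read_record(config$record, config$rate, config$annotations)
  band <- config$band
  if (is.list(band) && !inherits(band, "band_spec")) {
    band <- if (length(band) == 1L) band[[1L]]
      else select_band(rec, band, L = max(config$L_candidates),
                       n_bins = config$n_bins, min_nonictal_s = 0)
  }
  ss <- svd_statistic(connectivity_series(rec, band))
  st <- stage_states(rec$annotations, ss$k_s)
  cand <- config$L_candidates
  model <- fit_hmm_glm(ss$sigma1, st,
                       L = max(cand),
                       candidate_L = if (length(cand) > 1L) cand else NULL,
                       n_bins = config$n_bins, M = config$M)
  model$band <- band
  p1 <- file.path(config$out_dir, "sigma1.csv")
  write_svd_statistic(ss, p1)
  p2 <- file.path(config$out_dir, "model.json")
  write_model(model, p2)
  write_provenance(config, config$out_dir, "fit")
  invisible(c(p1, p2))
}

#' @rdname pipeline_simulate
#' @param z Numeric observation series; default read from
#'   `<out_dir>/sigma1.csv`.
#' @export
pipeline_detect <- function(config, z = NULL) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- read_model(config$model)
  if (is.null(z)) {
    z <- utils::read.csv(file.path(config$out_dir, "sigma1.csv"))$sigma1
  }
  policy <- if (!is.null(config$policy)) read_policy(config$policy)
    else synthesize_policy(model, cost_spec(gamma = config$gamma,
                                            horizon_M = config$M))
  if (length(policy$F) != policy$cost$horizon_M)
    stop("policy/horizon mismatch")
  paths <- character(0)
  qd <- run_qd(model, policy, z, config$refractory_s)
  be <- bayes_detector(model, z, refractory_s = config$refractory_s)
  tr_nonictal <- z[seq_len(min(length(z), 3 * 3600))]
  ht <- heuristic_detector(z, tr_nonictal, refractory_s = config$refractory_s)
  for (d in list(qd, be, ht)) {
    p <- file.path(config$out_dir, paste0("detections_", d$policy_id, ".csv"))
    write_detections(d, p)
    paths <- c(paths, p)
  }
  pp <- file.path(config$out_dir, "policy.json")
  write_policy(policy, pp)
  pt <- file.path(config$out_dir, "trajectory.csv")
  write_trajectory(qd$trajectory, pt)
  write_provenance(config, config$out_dir, "detect")
  invisible(c(paths, pp, pt))
}

#' @rdname pipeline_simulate
#' @param sweep Also run [gamma_sweep()] and write `sweep.csv`?
#' @export
pipeline_evaluate <- function(config, sweep = FALSE) {
  ann <- utils::read.csv(config$annotations)
  if (nrow(ann) == 0L) stop("annotation file has no events")
  onsets <- sort(ann$onset_s)
  ictal_s <- sum(ann$offset_s - ann$onset_s)
  paths <- character(0)
  z <- utils::read.csv(file.path(config$out_dir, "sigma1.csv"))$sigma1
  for (id in c("qd", "be", "ht")) {
    f <- file.path(config$out_dir,
                   paste0("detections_",
                          if (id == "qd") sprintf("qd_gamma%.3g", config$gamma)
                          else id, ".csv"))
    if (!file.exists(f)) next
    det <- utils::read.csv(f)
    rep_ <- score_detections(sort(det$t_s), onsets,
                             tolerance_s = config$tolerance_s,
                             duration_s = length(z), ictal_s = ictal_s)
    p <- file.path(config$out_dir, paste0("report_", id, ".json"))
    write_report(rep_, p)
    paths <- c(paths, p)
  }
  if (sweep) {
    model <- read_model(config$model)
    sw <- gamma_sweep(model, cost_spec(horizon_M = config$M), z, onsets,
                      refractory_s = config$refractory_s,
                      tolerance_s = config$tolerance_s, ictal_s = ictal_s)
    p <- file.path(config$out_dir, "sweep.csv")
    write_report(sw, p)
    paths <- c(paths, p)
  }
  write_provenance(config, config$out_dir, "evaluate")
  invisible(paths)
}
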