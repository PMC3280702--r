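# Quantizer, Poisson history GLM, hazard estimation, band selection.

test_that("uniform quantizer maps endpoints, interior and out-of-range values", {
  q <- build_quantizer(c(0, 10), n_bins = 10)
  expect_equal(quantize(q, 0), 0L)
  expect_equal(quantize(q, 10), 9L)
  expect_equal(quantize(q, -5), 0L)   # clips below range
  expect_equal(quantize(q, 99), 9L)   # clips above range
  # brute-force linear-scan oracle over random values
  set.seed(3)
  z <- runif(200, -2, 12)
  scan <- vapply(z, function(v) {
    b <- 0L
    for (j in seq_len(q$n_bins)) {
      if (v >= q$bin_edges[j]) b <- j - 1L
    }
    b
  }, integer(1))
  expect_identical(quantize(q, z), scan)
  expect_equal(quantize(q, 4.99), 4L)
  # monotone
  zs <- sort(z)
  expect_true(all(diff(quantize(q, zs)) >= 0))
  expect_error(build_quantizer(rep(2, 5), 10), "constant")
  expect_error(build_quantizer(c(0, 1), 1), "n_bins")
})

test_that("intercept-only GLM recovers log of the mean exactly", {
  fit <- fit_glm(rep(3L, 100), L = 0)
  expect_equal(fit$alpha, log(3), tolerance = 1e-8)
  expect_length(fit$betas, 0)
})

test_that("GLM recovers simulated parameters within confidence bounds", {
  m <- hmm_glm_model(0, list(alpha = 0.5, betas = 0.05),
                     list(alpha = 0.5, betas = 0.05),
                     unit_quantizer(50), M = 10)
  sim <- simulate_hmm_glm(m, 20000, seed = 8)
  fit <- fit_glm(sim$counts, L = 1)
  se <- sqrt(diag(fit$cov))
  expect_lt(abs(fit$alpha - 0.5), 1.96 * se[1])
  expect_lt(abs(fit$betas[1] - 0.05), 1.96 * se[2])
})

test_that("AIC lag selection: singleton, null data, and true-lag power", {
  counts <- simulate_hmm_glm(toy_lag_model(rho = 0), 3000, seed = 2)$counts
  expect_equal(as.integer(select_lag_by_aic(counts, 15L)), 15L)
  # beta = 0 data: smallest lag wins in large samples
  m0 <- toy_model(alpha0 = log(3), alpha1 = log(3), rho = 0, n_bins = 30)
  null_counts <- simulate_hmm_glm(m0, 50000, seed = 5)$counts
  expect_equal(as.integer(select_lag_by_aic(null_counts, 0:3)), 0L)
  # strong true lag-2 structure: selected L >= 2 in most seeds
  m2 <- hmm_glm_model(0, list(alpha = log(1.5), betas = c(0.08, 0.06)),
                      list(alpha = log(1.5), betas = c(0.08, 0.06)),
                      unit_quantizer(40), M = 10)
  hits <- 0
  for (s in 1:20) {
    cts <- simulate_hmm_glm(m2, 4000, seed = 300 + s)$counts
    if (select_lag_by_aic(cts, 0:4) >= 2) hits <- hits + 1
  }
  expect_gte(hits, 18)
  expect_error(select_lag_by_aic(counts, integer(0)), "empty")
})

test_that("log-likelihood is non-decreasing in the lag order (nested fits)", {
  counts <- simulate_hmm_glm(toy_lag_model(rho = 0), 5000, seed = 9)$counts
  sel <- select_lag_by_aic(counts, 0:5)
  aic <- attr(sel, "aic")
  loglik <- (2 * (0:5 + 1) - aic) / 2
  expect_true(all(diff(loglik) >= -1e-6))
})

test_that("hazard MLE: closed form, boundary, and simulation recovery", {
  expect_equal(estimate_rho(c(0, 0, 0, 1)), 1 / 3)
  expect_warning(r0 <- estimate_rho(c(0, 0, 0, 0)), "no 0->1")
  expect_equal(r0, 0)
  expect_error(estimate_rho(c(1, 1)), "not estimable")
  expect_error(estimate_rho(c(0, 2, 0)), "0/1")
  # pooled MLE across 1000 simulated chains, true rho = 0.01
  m <- toy_lag_model(rho = 0.01)
  chains <- lapply(1:1000, function(s)
    simulate_hmm_glm(m, 300, seed = 5000 + s)$states)
  rho_hat <- estimate_rho(chains)
  expect_lt(abs(rho_hat - 0.01) / 0.01, 0.2)
})

test_that("emission probabilities follow the Poisson law and normalize", {
  m <- toy_model(alpha0 = 0, alpha1 = log(4), n_bins = 20)
  expect_equal(emission_probability(m, 0, 0.5, integer(0)), exp(-1))
  # identical parameter vectors make the states indistinguishable
  m_eq <- toy_model(alpha0 = log(2), alpha1 = log(2))
  for (z in c(0.2, 1.3, 2.9))
    expect_equal(emission_probability(m_eq, 0, z, integer(0)),
                 emission_probability(m_eq, 1, z, integer(0)))
  # q1/q0 for lambda 2 vs 4 at count 3: 2^3 e^{-2}
  m24 <- toy_model(alpha0 = log(2), alpha1 = log(4), n_bins = 10)
  expect_equal(emission_probability(m24, 1, 3.5, integer(0)) /
                 emission_probability(m24, 0, 3.5, integer(0)),
               8 * exp(-2), tolerance = 1e-12)
  # sums to 1 over the count support (tail bound)
  lam <- exp(0.7)
  tot <- sum(dpois(0:200, lam))
  expect_equal(tot, 1, tolerance = 1e-12)
  ml <- hmm_glm_model(0.1, list(alpha = 0.7, betas = 0.05),
                      list(alpha = 1, betas = 0.02), unit_quantizer(50), M = 10)
  hist <- c(3L, 1L)
  probs <- vapply(0:200, function(n)
    emission_probability(ml, 0, n + 0.5, hist), numeric(1))
  expect_equal(sum(probs), 1, tolerance = 1e-10)
})

test_that("fitting the full model recovers the generating parameters", {
  m <- example_hmm_glm(rho = 0.002, M = 2000L)
  # several runs with events, pooled into one labeled series
  states <- integer(6000)
  states[1001:1300] <- 1L; states[3001:3300] <- 1L; states[5001:5300] <- 1L
  sim <- simulate_hmm_glm(m, 6000, seed = 17, states = states)
  fit <- fit_hmm_glm(as.numeric(sim$counts), sim$states, L = 1, n_bins = 30)
  expect_equal(fit$theta0$alpha, log(3), tolerance = 0.1)
  expect_equal(fit$theta1$alpha, log(8), tolerance = 0.2)
  expect_equal(fit$theta0$betas[1], 0.05, tolerance = 0.05)
  # rho MLE: 3 transitions over ~5700 nonictal steps
  expect_equal(fit$rho, 3 / sum(states[-length(states)] == 0), tolerance = 1e-9)
  # parameter error shrinks with more data (median over seeds)
  err_at <- function(n) {
    e <- vapply(1:5, function(s) {
      st <- integer(n); st[(n / 2):(n / 2 + 299)] <- 1L
      sm <- simulate_hmm_glm(m, n, seed = 40 + s, states = st)
      f <- fit_hmm_glm(as.numeric(sm$counts), sm$states, L = 1, n_bins = 30)
      abs(f$theta0$alpha - log(3))
    }, numeric(1))
    median(e)
  }
  expect_lt(err_at(8000), err_at(1200))
})

test_that("model survives a JSON round trip", {
  m <- example_hmm_glm()
  m$band <- band_spec("theta")
  d <- withr::local_tempdir()
  write_model(m, file.path(d, "model.json"))
  back <- read_model(file.path(d, "model.json"))
  expect_equal(back$rho, m$rho)
  expect_equal(back$theta0$alpha, m$theta0$alpha)
  expect_equal(back$theta1$betas, m$theta1$betas)
  expect_equal(back$quantizer$bin_edges, m$quantizer$bin_edges)
  expect_equal(back$M, m$M)
  expect_equal(back$band$lb, 4)
})

test_that("band selection finds the band containing the ictal drive", {
  ann <- data.frame(onset_s = c(60, 150), offset_s = c(90, 180))
  bands <- list(band_spec("theta"), band_spec("alpha"), band_spec("beta"))
  mk <- function(freq, seed) simulate_record(
    sim_config(n_channels = 4, duration_s = 240, rate = 64,
               nonictal_coupling = 0.15, ictal_coupling = 1.6,
               drive_freq_hz = freq, noise_sd = 1,
               annotations = ann, seed = seed))
  sel_beta <- select_band(mk(20, 31), bands, L = 2, n_bins = 20,
                          min_nonictal_s = 0)
  expect_equal(sel_beta$name, "beta")
  sel_theta <- select_band(mk(5, 32), bands, L = 2, n_bins = 20,
                           min_nonictal_s = 0)
  expect_equal(sel_theta$name, "theta")
  # singleton candidate list returned unchanged
  expect_equal(select_band(mk(20, 33), list(band_spec("alpha")))$name, "alpha")
  no_ann <- simulate_record(sim_config(n_channels = 2, duration_s = 30,
                                       rate = 64, seed = 3,
                                       annotations = data.frame(onset_s = numeric(0),
                                                                offset_s = numeric(0))))
  expect_error(select_band(no_ann, bands), "annotations")
})

test_that("model summary and methods expose the fitted structure", {
  m <- example_hmm_glm()
  cf <- coef(m)
  expect_equal(dim(cf), c(2, 2))
  expect_equal(cf["nonictal", "alpha"], log(3))
  expect_equal(cf["ictal", "beta1"], 0.03)
  expect_output(print(m), "hazard")
  sim <- simulate(m, seed = 12, n_steps = 50)
  expect_s3_class(sim, "labeled_counts")
  pr <- predict(m, c(3L, 5L, 2L))
  expect_equal(pr$lambda0[2], exp(log(3) + 0.05 * 3))
  expect_equal(pr$lambda1[3], exp(log(8) + 0.03 * 5))
})
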