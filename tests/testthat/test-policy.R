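# Stage costs, dynamic-programming threshold synthesis, online detection.

test_that("expected delay under the truncated geometric prior", {
  expect_equal(expected_delay_given_past(1, 0.5), 0)
  expect_equal(expected_delay_given_past(2, 0.5), 2 / 3)
  # brute-force sum oracle over random (k, rho)
  set.seed(6)
  for (i in 1:20) {
    k <- sample(1:200, 1); rho <- runif(1, 0.01, 0.6)
    t <- 1:k; w <- (1 - rho)^(t - 1) * rho
    expect_equal(expected_delay_given_past(k, rho), sum((k - t) * w) / sum(w),
                 tolerance = 1e-9)
  }
  expect_error(expected_delay_given_past(5, 0), "rho")
})

test_that("expected residual time to change is the geometric mean waiting time", {
  expect_equal(expected_time_to_change(0.1), 10)
  expect_equal(expected_time_to_change(1), 1)
  expect_equal(expected_time_to_change(0.5), 2)
  # memorylessness, by Monte Carlo
  set.seed(2)
  expect_equal(mean(rgeom(40000, 0.1) + 1), 10, tolerance = 0.05)
  expect_error(expected_time_to_change(0), "rho")
})

test_that("stage costs vanish in the no-loss corners and scale as specified", {
  cs <- cost_spec(gamma = 0.5, horizon_M = 10, rho = 0.1)
  expect_equal(stage_cost(0, 0, 5, cs), 0)   # surely nonictal, continuing free
  expect_equal(stage_cost(1, 1, 5, cs), 0)   # surely ictal, stopping free
  expect_equal(stage_cost(0.4, 1, 3, cs), 0.5 * 10 * 0.6)
  expect_equal(stage_cost(0.7, 0, 4, cs),
               0.5 * expected_delay_given_past(4, 0.1) * 0.7)
  cs2 <- cost_spec(gamma = 0.5, delay_exponent = 2, horizon_M = 10, rho = 0.1)
  expect_equal(stage_cost(0.7, 0, 4, cs2),
               0.5 * expected_delay_given_past(4, 0.1)^2 * 0.7)
})

test_that("degenerate cost weights give the degenerate policies", {
  m <- toy_lag_model(rho = 0.01, M = 40)
  p1 <- synthesize_policy(m, cost_spec(gamma = 1), pi_grid_size = 201)
  expect_true(all(p1$F == 0))                    # stop everywhere
  p0 <- synthesize_policy(m, cost_spec(gamma = 0), pi_grid_size = 201)
  expect_true(all(p0$F == 1))                    # never stop before M
  z <- as.numeric(simulate_hmm_glm(m, 40, seed = 3)$counts)
  det1 <- run_qd(m, p1, z)
  expect_equal(det1$detections$stage[1], 1L)     # fires at the first stage
  det0 <- run_qd(m, p0, z)
  expect_equal(nrow(det0$detections), 0L)        # never fires
})

test_that("value table is sandwiched and thresholds respect their limits", {
  m <- toy_model(alpha0 = log(1.5), alpha1 = log(5), rho = 0.08, M = 12)
  cs <- cost_spec(gamma = 0.4)
  pol <- synthesize_policy(m, cs, pi_grid_size = 201, keep_values = TRUE)
  g <- pol$pi_grid
  cs <- qdetect:::resolve_cost(cs, m)
  stopc <- (1 - 0.4) * (1 / 0.08) * (1 - g)
  for (k in 0:12) {
    J <- pol$value_table[, k + 1]
    expect_true(all(J >= -1e-12))
    expect_true(all(J <= stopc + 1e-9))
  }
  # never-stop value: forward recursion on the same grid, independent code
  em <- qdetect:::policy_emissions(m)
  Jns <- stopc
  for (k in 11:0) {
    pi1 <- g + (1 - g) * 0.08
    EJ <- numeric(length(g))
    for (b in seq_along(em$Lr)) {
      pn <- em$Lr[b] * pi1 / ((1 - g) * (1 - 0.08) + em$Lr[b] * pi1)
      EJ <- EJ + (pi1 * em$q1[b] + (1 - pi1) * em$q0[b]) *
        approx(g, Jns, xout = pmin(pmax(pn, 0), 1))$y
    }
    Jns <- 0.4 * expected_delay_given_past(k, 0.08)^1 * g * (k >= 1) + EJ
    expect_true(all(pol$value_table[, k + 1] <= Jns + 1e-9))
  }
  # thresholds live on [0, 1] and the policy object prints
  expect_true(all(pol$F >= 0 & pol$F <= 1))
  expect_output(print(pol), "quickest-detection")
})

test_that("grid DP agrees with the exact recursion at grid resolution", {
  m <- toy_model(alpha0 = log(1.2), alpha1 = log(3.5), rho = 0.1,
                 p0 = 0.9, M = 5)
  cs <- cost_spec(gamma = 0.35)
  ex <- qd_value_exact(m, cs)
  pol <- synthesize_policy(m, cs, pi_grid_size = 4001, keep_values = TRUE)
  # J_0 from the grid table, averaged over the first observation like the
  # exact version
  em <- qdetect:::policy_emissions(m)
  J0_grid <- 0
  for (b in seq_along(em$Lr)) {
    pb <- 0.9 * em$q0[b] + 0.1 * em$q1[b]
    pi0 <- em$q1[b] * 0.1 / (em$q0[b] * 0.9 + em$q1[b] * 0.1)
    J0_grid <- J0_grid + pb * approx(pol$pi_grid, pol$value_table[, 1],
                                     xout = pi0)$y
  }
  expect_equal(J0_grid, ex$J0, tolerance = 1e-5)
})

test_that("online detection is consistent with the threshold rule", {
  m <- toy_lag_model(rho = 0.005, M = 300)
  pol <- synthesize_policy(m, cost_spec(gamma = 0.3), pi_grid_size = 501)
  states <- c(integer(150), rep(1L, 60), integer(90))
  for (s in 1:15) {
    z <- as.numeric(simulate_hmm_glm(m, 300, seed = 880 + s,
                                     states = states)$counts)
    det <- run_qd(m, pol, z)
    tr <- det$trajectory
    if (nrow(det$detections) > 0) {
      first <- det$detections$stage[1]
      # never earlier than the first stage at which pi exceeds the
      # policy's minimum threshold
      min_cross <- which(tr$pi > min(pol$F))[1] - 1L
      expect_gte(first, min_cross)
      # at the detection stage pi exceeded the stage threshold
      expect_gt(det$detections$pi[1], min(pol$F))
    }
  }
})

test_that("a single switch is detected once, promptly, at the default weight", {
  # rare-event hazard: the onset prior mass stays spread over the horizon
  m <- toy_lag_model(rho = 5e-4, M = 600)
  pol <- synthesize_policy(m, cost_spec(gamma = 0.3), pi_grid_size = 501)
  ok <- 0
  for (s in 1:100) {
    states <- c(integer(300), rep(1L, 60), integer(240))
    gain <- rep(1, 600); gain[361:600] <- c(seq(0.3, 1, length.out = 120),
                                            rep(1, 120))
    z <- as.numeric(simulate_hmm_glm(m, 600, seed = 4000 + s,
                                     states = states, rate_gain = gain)$counts)
    det <- run_qd(m, pol, z)
    dets <- det$detections$stage
    if (length(dets) == 1 && dets >= 300 && dets <= 320) ok <- ok + 1
  }
  expect_gte(ok, 95)
})

test_that("unreachable thresholds never fire and horizons are validated", {
  m <- toy_lag_model(M = 50)
  pol1 <- constant_policy(1, 50)
  z <- as.numeric(simulate_hmm_glm(m, 50, seed = 6)$counts)
  expect_equal(nrow(run_qd(m, pol1, z)$detections), 0L)
  expect_error(run_qd(m, constant_policy(0.5, 1), z), "horizon")
  expect_error(synthesize_policy(m, cost_spec(gamma = 0.3), pi_grid_size = 50),
               "pi_grid_size")
})

test_that("policies survive a JSON round trip", {
  m <- toy_lag_model(rho = 0.01, M = 30)
  pol <- synthesize_policy(m, cost_spec(gamma = 0.25), pi_grid_size = 201)
  d <- withr::local_tempdir()
  write_policy(pol, file.path(d, "pol.json"))
  back <- read_policy(file.path(d, "pol.json"))
  expect_equal(back$F, pol$F, tolerance = 1e-12)
  expect_equal(back$cost$gamma, 0.25)
  expect_equal(back$cost$horizon_M, 30)
})
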