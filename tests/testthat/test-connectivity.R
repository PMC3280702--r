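# Cross-power connectivity matrices and the SVD statistic.

# Independent brute-force Welch cross-spectrum: plain loops over segments,
# frequencies and channel pairs, with the same estimator definition
# (1-s Hann, 50% overlap, one-sided density, trapezoidal band integral).
brute_band_crosspower <- function(window, rate, lb, ub) {
  n_ch <- nrow(window); n <- ncol(window)
  nfft <- rate
  starts <- seq(1, n - nfft + 1, by = nfft %/% 2)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nfft) / (nfft + 1)))
  freqs <- (0:(nfft %/% 2)) * rate / nfft
  nf <- length(freqs)
  S <- array(0 + 0i, c(n_ch, n_ch, nf))
  for (s in starts) {
    X <- matrix(0 + 0i, nf, n_ch)
    for (c in seq_len(n_ch)) {
      seg <- window[c, s:(s + nfft - 1)]
      seg <- (seg - mean(seg)) * w
      for (fi in seq_len(nf)) {   # naive DFT
        X[fi, c] <- sum(seg * exp(-2i * pi * (fi - 1) * (0:(nfft - 1)) / nfft))
      }
    }
    for (i in seq_len(n_ch)) for (j in seq_len(n_ch))
      S[i, j, ] <- S[i, j, ] + X[, i] * Conj(X[, j])
  }
  S <- S / (length(starts) * rate * sum(w^2))
  dbl <- rep(2, nf); dbl[1] <- 1; if (nfft %% 2 == 0) dbl[nf] <- 1
  sel <- which(freqs >= lb & freqs <= ub)
  df <- freqs[2] - freqs[1]
  tw <- rep(df, length(sel)); tw[1] <- df / 2; tw[length(sel)] <- df / 2
  A <- matrix(0 + 0i, n_ch, n_ch)
  for (ii in seq_along(sel)) A <- A + tw[ii] * S[, , sel[ii]] * dbl[sel[ii]]
  Mod(A)
}

test_that("band presets match the conventional iEEG bands", {
  b <- band_spec("beta")
  expect_equal(c(b$lb, b$ub), c(13, 30))
  expect_equal(c(band_spec("theta")$lb, band_spec("theta")$ub), c(4, 7))
  expect_equal(c(band_spec("alpha")$lb, band_spec("alpha")$ub), c(8, 13))
  expect_error(band_spec("custom"), "lb and ub")
  expect_error(band_spec("custom", 10, 5), "lb < ub")
})

test_that("band cross-power matches a brute-force DFT cross-periodogram", {
  rate <- 64
  tt <- (0:(5 * rate - 1)) / rate
  # pure 20 Hz sinusoid on both channels, plus a mixed random case
  win1 <- rbind(sin(2 * pi * 20 * tt), sin(2 * pi * 20 * tt))
  set.seed(5)
  win2 <- rbind(sin(2 * pi * 20 * tt) + rnorm(length(tt), sd = 0.3),
                0.5 * sin(2 * pi * 20 * tt + 0.7) + rnorm(length(tt), sd = 0.3),
                rnorm(length(tt)))
  band <- band_spec("custom", 15, 25)
  for (win in list(win1, win2)) {
    A <- band_crosspower(win, rate, band)
    B <- brute_band_crosspower(win, rate, 15, 25)
    expect_equal(A, (B + t(B)) / 2, tolerance = 1e-10)
  }
})

test_that("two identical channels give a rank-1 matrix with equal entries", {
  rate <- 64
  tt <- (0:(5 * rate - 1)) / rate
  x <- sin(2 * pi * 20 * tt) + 0.2 * sin(2 * pi * 17 * tt)
  A <- band_crosspower(rbind(x, x), rate, band_spec("custom", 14, 26))
  expect_equal(A[1, 1], A[1, 2])
  expect_equal(A[1, 1], A[2, 2])
  s <- svd(A)$d
  expect_lt(s[2] / s[1], 1e-10)
})

test_that("input validation: short windows, NaN samples, Nyquist", {
  rate <- 64
  expect_error(band_crosspower(matrix(rnorm(32), 1), rate, band_spec("beta")),
               "sub-segment")
  bad <- matrix(rnorm(5 * rate * 2), 2)
  bad[1, 7] <- NaN
  expect_error(band_crosspower(bad, rate, band_spec("beta")), "non-finite|NA")
  expect_error(band_crosspower(matrix(rnorm(5 * rate), 1), rate,
                               band_spec("custom", 20, 40)), "Nyquist")
})

test_that("a 10-s record yields 6 matrices and a 5-s minimum is enforced", {
  rec <- simulate_record(sim_config(n_channels = 2, duration_s = 10,
                                    rate = 64, seed = 3,
                                    annotations = data.frame(onset_s = numeric(0),
                                                             offset_s = numeric(0))))
  cs <- connectivity_series(rec, band_spec("beta"))
  expect_length(cs$matrices, 6)
  expect_equal(cs$k_s, 5:10)
  short <- multichannel_record(matrix(rnorm(2 * 4 * 64), 2), 64)
  expect_error(connectivity_series(short, band_spec("beta")), "shorter")
})

test_that("a coupling step at t = 30 s appears within the straddling window", {
  ann <- data.frame(onset_s = 30, offset_s = 60)
  rec <- simulate_record(sim_config(n_channels = 4, duration_s = 60, rate = 64,
                                    nonictal_coupling = 0.1, ictal_coupling = 2,
                                    noise_sd = 0.5, annotations = ann, seed = 9))
  ss <- svd_statistic(connectivity_series(rec, band_spec("beta")))
  pre <- ss$sigma1[ss$k_s <= 30]    # windows entirely before the step
  post <- ss$sigma1[ss$k_s >= 35]   # windows entirely after it
  expect_gt(min(post), max(pre))
  mid <- ss$sigma1[ss$k_s %in% 31:34]
  expect_true(all(mid > min(pre) - 1e-12 & mid < max(post) + 1e-12))
})

test_that("svd_statistic handles closed-form cases", {
  s <- svd_statistic(list(diag(3)))
  expect_equal(s$sigma1, 1)
  s2 <- svd_statistic(list(matrix(c(2, 1, 1, 2), 2)))
  expect_equal(s2$sigma1, 3)
  expect_equal(abs(s2$v1[, 1]), rep(1 / sqrt(2), 2))
  expect_gt(s2$v1[which.max(abs(s2$v1[, 1])), 1], 0)  # sign convention
  expect_error(svd_statistic(list(matrix(c(1, NA, 1, 1), 2))), "non-finite")
})

test_that("one strengthened connection drops the effective rank", {
  # three nodes, comparable weak links vs one dominant link
  weak <- matrix(c(1, .3, .25, .3, 1, .2, .25, .2, 1), 3)
  strong <- weak; strong[1, 2] <- strong[2, 1] <- 6
  sv_w <- svd(weak)$d
  sv_s <- svd(strong)$d
  expect_lt(sv_s[3] / sv_s[1], sv_w[3] / sv_w[1])
  expect_gt(sv_s[1], sv_w[1])   # amplification increases
})

test_that("spectral invariants hold on random connectivity series", {
  set.seed(21)
  rec <- simulate_record(sim_config(n_channels = 5, duration_s = 15, rate = 64,
                                    seed = 77,
                                    annotations = data.frame(onset_s = 5,
                                                             offset_s = 9)))
  cs <- connectivity_series(rec, band_spec("beta"))
  ss <- svd_statistic(cs, keep_all = TRUE)
  for (i in seq_along(cs$matrices)) {
    A <- cs$matrices[[i]]
    # Frobenius conservation
    expect_equal(sum(ss$all_singular_values[, i]^2), sum(A^2),
                 tolerance = 1e-12)
    # spectral norm bounds the largest entry
    expect_gte(ss$sigma1[i], max(A) - 1e-12)
    expect_equal(sqrt(sum(ss$v1[, i]^2)), 1, tolerance = 1e-12)
  }
  # channel permutation: sigma1 invariant, v1 permuted identically
  perm <- c(3, 1, 5, 2, 4)
  rec_p <- multichannel_record(rec$samples[perm, ], rec$rate,
                               annotations = rec$annotations)
  ss_p <- svd_statistic(connectivity_series(rec_p, band_spec("beta")))
  expect_equal(ss_p$sigma1, ss$sigma1, tolerance = 1e-9)
  expect_equal(ss_p$v1[, 4], ss$v1[perm, 4], tolerance = 1e-6)
  # amplitude scaling: A and sigma1 scale as c^2
  rec_s <- multichannel_record(2 * rec$samples, rec$rate,
                               annotations = rec$annotations)
  cs_s <- connectivity_series(rec_s, band_spec("beta"))
  expect_equal(cs_s$matrices[[1]], 4 * cs$matrices[[1]], tolerance = 1e-10)
  expect_equal(svd_statistic(cs_s)$sigma1, 4 * ss$sigma1, tolerance = 1e-9)
})
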