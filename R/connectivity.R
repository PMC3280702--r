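#' Frequency band specification
#'
#' Builds a frequency band for the band-limited cross-power connectivity
#' matrix. Presets follow the conventional iEEG bands: theta 4--7 Hz,
#' alpha 8--13 Hz, beta 13--30 Hz.
#'
#' @param name One of `"theta"`, `"alpha"`, `"beta"`, `"custom"`.
#' @param lb,ub Lower/upper band edge in Hz; required (and only allowed)
#'   for `name = "custom"`.
#' @return An object of class `band_spec` with fields `name`, `lb`, `ub`.
#' @examples
#' band_spec("beta")
#' band_spec("custom", 35, 45)
#' @export
band_spec <- function(name = c("theta", "alpha", "beta", "custom"),
                      lb = NULL, ub = NULL) {
  name <- match.arg(name)
  presets <- list(theta = c(4, 7), alpha = c(8, 13), beta = c(13, 30))
  if (name == "custom") {
    if (is.null(lb) || is.null(ub))
      stop("custom band requires lb and ub")
  } else {
    if (!is.null(lb) || !is.null(ub))
      stop("preset bands fix lb and ub; use name = 'custom'")
    lb <- presets[[name]][1]
    ub <- presets[[name]][2]
  }
  if (!(is.finite(lb) && is.finite(ub) && lb > 0 && lb < ub))
    stop("band edges must satisfy 0 < lb < ub")
  structure(list(name = name, lb = lb, ub = ub), class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("frequency band '%s': %.6g-%.6g Hz\n", x$name, x$lb, x$ub))
  invisible(x)
}

## Welch cross-spectral matrix of a channels x samples window.
## Sub-windows: seg_s-second Hann tapers, 50% overlap. Returns a list with
## freq (Hz, one-sided) and S, an n_ch x n_ch x n_freq complex array of
## cross-spectral densities (power per Hz, one-sided scaling).
welch_cross_spectra <- function(window, rate, seg_s = 1) {
  if (!is.matrix(window)) window <- matrix(window, nrow = 1)
  if (anyNA(window) || !all(is.finite(window)))
    stop("window contains NA or non-finite samples")
  n_ch <- nrow(window)
  n_samp <- ncol(window)
  nfft <- round(seg_s * rate)
  if (n_samp < nfft)
    stop("window shorter than one spectral sub-segment (", nfft, " samples)")
  step <- nfft %/% 2L
  starts <- seq(1L, n_samp - nfft + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nfft) / (nfft + 1)))  # Hann taper
  U <- sum(w^2)
  n_freq <- nfft %/% 2L + 1L
  S <- array(0 + 0i, dim = c(n_ch, n_ch, n_freq))
  for (s in starts) {
    seg <- window[, s:(s + nfft - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)                 # demean per sub-segment
    X <- stats::mvfft(t(seg * rep(w, each = n_ch)))[seq_len(n_freq), , drop = FALSE]
    for (f in seq_len(n_freq)) {
      xf <- X[f, ]
      S[, , f] <- S[, , f] + outer(xf, Conj(xf))
    }
  }
  S <- S / (length(starts) * rate * U)
  ## one-sided: double all bins except DC and (for even nfft) Nyquist
  dbl <- rep(2, n_freq); dbl[1] <- 1
  if (nfft %% 2L == 0L) dbl[n_freq] <- 1
  for (f in seq_len(n_freq)) S[, , f] <- S[, , f] * dbl[f]
  list(freq = (seq_len(n_freq) - 1L) * rate / nfft, S = S)
}

#' Band-integrated cross-power connectivity matrix
#'
#' Computes the connectivity matrix A of one analysis window: for every
#' channel pair (i, j), `A[i, j]` is the magnitude of the cross-power
#' spectral density integrated over the requested frequency band,
#' `A[i,j] = | \int_{lb}^{ub} P_ij(w) dw |`. Cross-spectra are estimated by
#' Welch averaging (1-s Hann sub-windows, 50% overlap) and integrated by the
#' trapezoidal rule over FFT bins whose centres fall inside `[lb, ub]`
#' (inclusive). The diagonal holds band-limited auto-power. Taking the
#' magnitude of the (complex) band-integrated cross-spectrum makes A
#' symmetric, real and nonnegative by construction.
#'
#' @param window Numeric matrix, channels x samples.
#' @param rate Sampling rate in Hz.
#' @param band A [band_spec()].
#' @param quantity `"magnitude"` (default) or `"real"`: how the complex
#'   band-integrated cross-spectrum is reduced to a real edge weight.
#' @return Symmetric nonnegative n_channels x n_channels matrix.
#' @export
band_crosspower <- function(window, rate, band, quantity = c("magnitude", "real")) {
  quantity <- match.arg(quantity)
  stopifnot(inherits(band, "band_spec"))
  if (band$ub >= rate / 2)
    stop("band upper edge must be below the Nyquist frequency")
  cs <- welch_cross_spectra(window, rate)
  sel <- which(cs$freq >= band$lb & cs$freq <= band$ub)
  if (length(sel) < 2L)
    stop("band too narrow for the spectral resolution: fewer than 2 FFT bins")
  df <- cs$freq[2] - cs$freq[1]
  ## trapezoidal weights over the selected bins
  tw <- rep(df, length(sel)); tw[1] <- df / 2; tw[length(sel)] <- df / 2
  n_ch <- dim(cs$S)[1]
  A <- matrix(0 + 0i, n_ch, n_ch)
  for (idx in seq_along(sel)) A <- A + tw[idx] * cs$S[, , sel[idx]]
  A <- if (quantity == "magnitude") Mod(A) else pmax(Re(A), 0)
  (A + t(A)) / 2     # exact symmetry against rounding
}

#' Sliding-window connectivity matrix series
#'
#' Computes one connectivity matrix per whole second of the recording from a
#' 5-second sliding window with a 1-second slide. The matrix indexed by
#' second `k` uses the samples in `(k-5, k]` seconds, so a detector reading
#' the series at stage k uses no future data. A recording of `floor(d)`
#' seconds yields `floor(d) - 4` matrices, indexed k = 5, 6, ....
#'
#' @param record A `multichannel_record` (see [simulate_record()]).
#' @param band A [band_spec()].
#' @param window_s,slide_s Window and slide length in seconds.
#' @param quantity Passed to [band_crosspower()].
#' @return An object of class `connectivity_series`: list with `matrices`
#'   (list of symmetric matrices), `k_s` (right-edge second of each window),
#'   `band`, `window_s`, `slide_s`.
#' @export
connectivity_series <- function(record, band, window_s = 5, slide_s = 1,
                                quantity = "magnitude") {
  stopifnot(inherits(record, "multichannel_record"))
  dur <- ncol(record$samples) / record$rate
  if (dur < window_s)
    stop("record shorter than one analysis window (", window_s, " s)")
  rate <- record$rate
  ks <- seq(window_s, floor(dur), by = slide_s)
  mats <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    idx <- (round((k - window_s) * rate) + 1L):round(k * rate)
    mats[[i]] <- band_crosspower(record$samples[, idx, drop = FALSE],
                                 rate, band, quantity)
  }
  structure(list(matrices = mats, k_s = ks, band = band,
                 window_s = window_s, slide_s = slide_s),
            class = "connectivity_series")
}

#' Largest singular value and vector of each connectivity matrix
#'
#' Tracks the time-varying complexity of the multichannel network by the
#' singular value decomposition of each connectivity matrix A(k). The
#' largest singular value sigma1(k) is the detection statistic; its singular
#' vector v1(k) points at the dominant coupling direction. For the symmetric
#' nonnegative-definite matrices produced by [band_crosspower()] the singular
#' values coincide with the eigenvalue magnitudes. The sign of v1 is fixed by
#' making its largest-magnitude component positive.
#'
#' @param series A `connectivity_series`, or a plain list of square matrices.
#' @param keep_all Keep the full singular spectra (`all_singular_values`)?
#' @return Object of class `svd_statistic`: list with `sigma1` (numeric
#'   vector), `v1` (matrix, one unit-norm column per window), `k_s`, and
#'   optionally `all_singular_values` (matrix, one column per window).
#' @export
svd_statistic <- function(series, keep_all = FALSE) {
  mats <- if (inherits(series, "connectivity_series")) series$matrices else series
  k_s <- if (inherits(series, "connectivity_series")) series$k_s else seq_along(mats)
  n <- length(mats)
  if (n == 0L) stop("empty matrix series")
  p <- nrow(mats[[1]])
  sigma1 <- numeric(n)
  v1 <- matrix(NA_real_, p, n)
  allsv <- if (keep_all) matrix(NA_real_, p, n) else NULL
  for (i in seq_len(n)) {
    A <- mats[[i]]
    if (!all(is.finite(A))) stop("non-finite entries in connectivity matrix ", i)
    s <- svd(A)
    sigma1[i] <- s$d[1]
    v <- s$v[, 1]
    j <- which.max(abs(v))
    if (v[j] < 0) v <- -v
    v1[, i] <- v
    if (keep_all) allsv[, i] <- s$d
  }
  structure(list(sigma1 = sigma1, v1 = v1, k_s = k_s,
                 all_singular_values = allsv),
            class = "svd_statistic")
}

#' Write a sigma1/v1 series to CSV
#'
#' Columns: `k_s`, `sigma1`, `v1_1` ... `v1_n`.
#' @param x An `svd_statistic`.
#' @param path Output file path.
#' @export
write_svd_statistic <- function(x, path) {
  stopifnot(inherits(x, "svd_statistic"))
  df <- data.frame(k_s = x$k_s, sigma1 = x$sigma1, t(x$v1))
  names(df)[-(1:2)] <- paste0("v1_", seq_len(nrow(x$v1)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
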