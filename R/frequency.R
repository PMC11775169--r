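## Frequency-domain features of the TSNIT signal. Signals are demeaned before
## spectral analysis so the DC level (overall thickness) stays a spatial
## feature and the spectra capture the double-hump shape. Frequencies are in
## cycles per revolution of the scan circle for the whole profile (bin index
## k of an n-sample periodogram = k cycles over the analysed window).

new_psd <- function(frequencies, power, method, normalization) {
  stopifnot(length(frequencies) == length(power), all(power >= -1e-12),
            all(diff(frequencies) > 0), frequencies[1] == 0)
  structure(list(frequencies = frequencies, power = pmax(0, power),
                 method = method, normalization = normalization),
            class = "psd")
}

#' @export
print.psd <- function(x, ...) {
  cat("<psd> ", x$method, ", ", length(x$power), " bins, total power ",
      format(sum(x$power)), "\n", sep = "")
  invisible(x)
}

#' One-sided periodogram PSD
#'
#' The signal is demeaned first; the one-sided periodogram is normalised so
#' that the summed power equals the mean square of the demeaned signal
#' (Parseval). A pure tone of amplitude A therefore carries total power
#' A^2/2, concentrated at its frequency bin.
#'
#' @param signal Numeric vector, length >= 8.
#' @param demean Remove the mean first (default `TRUE`; the detail-band
#'   summaries keep the DC bin since wavelet coefficients carry no
#'   meaningful offset to remove).
#' @return A `psd` object with frequency bins `0 .. floor(n/2)` (cycles per
#'   analysed window).
#' @export
periodogram_psd <- function(signal, demean = TRUE) {
  x <- as.numeric(signal)
  n <- length(x)
  if (n < 8L) stop("signal must have at least 8 samples")
  if (demean) x <- x - mean(x)
  X <- stats::fft(x)
  half <- floor(n / 2)
  p2 <- Mod(X)^2 / n^2                 # two-sided, sums to mean square
  p1 <- p2[1:(half + 1)]
  dbl <- 2:(half + if (n %% 2 == 0) 0 else 1)  # bins with a mirror image
  p1[dbl] <- 2 * p1[dbl]
  new_psd(0:half, p1, "periodogram", "sum = mean square (Parseval)")
}

hann_window <- function(m) 0.5 * (1 - cos(2 * pi * (0:(m - 1)) / m))

#' Welch-averaged PSD
#'
#' Averaged modified periodograms of overlapping windowed segments, with
#' coherent-gain compensation (division by `sum(w)^2`) so that a single
#' full-length rectangular segment reproduces [periodogram_psd()] exactly.
#'
#' @param signal Numeric vector (demeaned internally).
#' @param seg_len Segment length (default 64; must not exceed the signal).
#' @param overlap_frac Fractional overlap between segments (default 0.5).
#' @param window `"hann"` (default) or `"rect"`.
#' @return A `psd` object with frequency bins `0 .. seg_len/2` (cycles per
#'   segment window).
#' @export
welch_psd <- function(signal, seg_len = 64L, overlap_frac = 0.5,
                      window = c("hann", "rect")) {
  x <- as.numeric(signal)
  n <- length(x)
  seg_len <- as.integer(seg_len)
  if (seg_len > n) stop("seg_len exceeds signal length")
  if (seg_len < 8L) stop("seg_len must be >= 8")
  window <- match.arg(window)
  x <- x - mean(x)
  w <- if (window == "hann") hann_window(seg_len) else rep(1, seg_len)
  step <- max(1L, as.integer(round(seg_len * (1 - overlap_frac))))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  half <- floor(seg_len / 2)
  dbl <- 2:(half + if (seg_len %% 2 == 0) 0 else 1)
  acc <- numeric(half + 1)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)] * w
    p2 <- Mod(stats::fft(seg))^2 / sum(w)^2
    p1 <- p2[1:(half + 1)]
    p1[dbl] <- 2 * p1[dbl]
    acc <- acc + p1
  }
  new_psd(0:half, acc / length(starts), "welch",
          sprintf("%s window, seg_len %d, overlap %.2f",
                  window, seg_len, overlap_frac))
}

## db4 analysis filters (8-tap Daubechies, 4 vanishing moments),
## standard published coefficients; hi is the quadrature mirror of lo.
DB4_DEC_LO <- c(-0.010597401785069032, 0.0328830116668852,
                0.030841381835560764, -0.18703481171909309,
                -0.027983769416859854, 0.6308807679298589,
                0.7148465705529157, 0.2303778133088965)
DB4_DEC_HI <- rev(DB4_DEC_LO) * (-1)^(seq_along(DB4_DEC_LO) - 1)

## One periodized DWT analysis step: circular filter + dyadic downsample.
## Periodization keeps the transform orthogonal, so energy is conserved
## exactly across levels.
dwt_step <- function(x, filt) {
  n <- length(x)
  L <- length(filt)
  out <- numeric(n / 2)
  for (k in seq_len(n / 2)) {
    idx <- ((2 * k - 1) + seq_len(L) - 2) %% n + 1   # x[2k-1 .. 2k-2+L] circular
    out[k] <- sum(filt * x[idx])
  }
  out
}

#' Discrete-wavelet detail-band powers of a signal
#'
#' Periodized db4 multilevel decomposition; for each detail level 1..
#' `max_level` the periodogram of the detail coefficients is summarised by
#' its total and peak power.
#'
#' @param signal Numeric vector; length must be a multiple of
#'   `2^max_level` and at least `2^max_level * 8`.
#' @param max_level Deepest decomposition level (default 4).
#' @return data.frame with columns `level`, `total_power`, `peak_power`.
#' @export
dwt_band_powers <- function(signal, max_level = 4L) {
  x <- as.numeric(signal)
  max_level <- as.integer(max_level)
  if (length(x) %% 2^max_level != 0 || length(x) / 2^max_level < 8L)
    stop("signal too short for ", max_level, " decomposition levels")
  out <- data.frame(level = seq_len(max_level), total_power = NA_real_,
                    peak_power = NA_real_)
  approx_coef <- x
  for (lev in seq_len(max_level)) {
    detail <- dwt_step(approx_coef, DB4_DEC_HI)
    approx_coef <- dwt_step(approx_coef, DB4_DEC_LO)
    if (sum(detail^2) == 0) {
      out$total_power[lev] <- 0; out$peak_power[lev] <- 0
    } else {
      p <- periodogram_psd(detail, demean = FALSE)
      out$total_power[lev] <- sum(p$power)
      out$peak_power[lev] <- max(p$power)
    }
  }
  attr(out, "approx_energy") <- sum(approx_coef^2)
  out
}

#' Slope of the PSD harmonics
#'
#' Least-squares slope of `log10(power at k * fundamental)` against the
#' harmonic index k = 1..`n_harmonics`. The double-hump TSNIT morphology has
#' a fundamental of 2 cycles per revolution. Powers are floored at machine
#' epsilon before taking logs.
#'
#' @param psd A `psd` object.
#' @param fundamental Fundamental frequency in the PSD's bin units
#'   (default 2).
#' @param n_harmonics Number of harmonics fitted (default 5).
#' @return Slope (log10 power per harmonic).
#' @export
harmonic_slope <- function(psd, fundamental = 2, n_harmonics = 5L) {
  freqs <- fundamental * seq_len(n_harmonics)
  idx <- match(freqs, psd$frequencies)
  ok <- !is.na(idx)
  if (sum(ok) < 2L) stop("fewer than 2 harmonics fall inside the PSD range")
  k <- seq_len(n_harmonics)[ok]
  y <- log10(pmax(psd$power[idx[ok]], .Machine$double.eps))
  unname(stats::coef(stats::lm(y ~ k))[2])
}

#' Normalised spectral entropy
#'
#' Shannon entropy of the PSD normalised to a probability distribution,
#' divided by `log(number of bins)`: 0 for a single occupied bin, 1 for a
#' flat spectrum.
#'
#' @param psd A `psd` object with positive total power.
#' @return Value in \[0, 1\].
#' @export
spectral_entropy <- function(psd) {
  p <- psd$power
  if (sum(p) <= 0) stop("zero PSD has no spectral entropy")
  p <- p / sum(p)
  h <- -sum(ifelse(p > 0, p * log(p), 0))
  h / log(length(p))
}

psd_summaries <- function(psd) {
  pk <- which.max(psd$power)
  c(total = sum(psd$power), peak = psd$power[pk],
    peakfreq = psd$frequencies[pk], mean = mean(psd$power),
    sd = stats::sd(psd$power))
}

#' Extract the 64 frequency-domain features of one TSNIT profile
#'
#' For each of five signals (whole profile and the four 64-sample quadrant
#' slices) and two PSD estimators (periodogram; Welch with segment length 64
#' for the whole signal and 32 for quadrants, 50% overlap, Hann window), the
#' five summaries total power, peak power, peak frequency, mean power and
#' power sd (50 features); total and peak detail power at db4 DWT levels 1-4
#' of the whole signal (8); the harmonic slope of each signal's periodogram
#' (5); and the normalised spectral entropy of the whole-signal periodogram
#' (1).
#'
#' @param tsnit Numeric vector of 256 samples, or `NULL`/`NA` for an
#'   artefact-masked profile (returns 64 missing values).
#' @return Named numeric vector of exactly 64 features in catalog order.
#' @export
extract_frequency <- function(tsnit) {
  nm <- frequency_feature_names()
  out <- stats::setNames(rep(NA_real_, length(nm)), nm)
  if (is.null(tsnit) || !all(is.finite(as.numeric(tsnit)))) return(out)
  x <- as_tsnit(tsnit)
  segs <- list(whole = x, t = x[1:64], s = x[65:128],
               n = x[129:192], i = x[193:256])
  for (sg in names(segs)) {
    sig <- segs[[sg]]
    if (stats::sd(sig) == 0) next      # degenerate slice: leave NA
    pg <- periodogram_psd(sig)
    wl <- welch_psd(sig, seg_len = if (sg == "whole") 64L else 32L)
    out[paste("psd", sg, "pgram",
              c("total", "peak", "peakfreq", "mean", "sd"), sep = "_")] <-
      psd_summaries(pg)
    out[paste("psd", sg, "welch",
              c("total", "peak", "peakfreq", "mean", "sd"), sep = "_")] <-
      psd_summaries(wl)
    out[paste0("hslope_", sg)] <- harmonic_slope(pg)
    if (sg == "whole") out["spectral_entropy"] <- spectral_entropy(pg)
  }
  if (stats::sd(x) > 0) {
    bp <- dwt_band_powers(x - mean(x))
    out[paste0("dwt_l", bp$level, "_total")] <- bp$total_power
    out[paste0("dwt_l", bp$level, "_peak")] <- bp$peak_power
  }
  out
}
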