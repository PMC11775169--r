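## Spatial-domain features of the 256-point TSNIT profile plus GC-IPL and
## macular pass-throughs: 67 features in the default catalog.

as_tsnit <- function(x) {
  x <- as.numeric(x)
  if (length(x) != TSNIT_LEN)
    stop("TSNIT profile must have exactly ", TSNIT_LEN, " samples")
  if (any(!is.finite(x)) || any(x < 0))
    stop("TSNIT samples must be finite and >= 0")
  x
}

#' Quadrant means of a TSNIT profile
#'
#' Temporal, superior, nasal and inferior thickness, computed as the means of
#' the first, second, third and fourth blocks of 64 samples of the
#' temporal-start TSNIT ordering.
#'
#' @param tsnit Numeric vector of 256 thickness samples (um).
#' @return Named vector `c(T=, S=, N=, I=)`.
#' @export
quadrant_means <- function(tsnit) {
  x <- as_tsnit(tsnit)
  stats::setNames(vapply(0:3, function(q) mean(x[(64 * q + 1):(64 * q + 64)]),
                         0.0),
                  c("T", "S", "N", "I"))
}

## Sample-to-clock-hour maps. Sector m (m = 0..11) covers samples
## [round(256 m/12), round(256 (m+1)/12)). The anchoring puts clocks 11/12/1
## in the superior quadrant and 5/6/7 in the inferior quadrant for a right
## eye; the left-eye labels are the anatomical mirror (2<->10, 3<->9, ...).
clock_hours_for <- function(laterality) {
  od <- c(8, 9, 10, 11, 12, 1, 2, 3, 4, 5, 6, 7)
  switch(laterality,
         OD = od,
         OS = ifelse((12 - od) %% 12 == 0, 12, (12 - od) %% 12),
         stop("laterality must be 'OD' or 'OS'"))
}

#' Clock-hour sector means of a TSNIT profile
#'
#' Splits the 256 samples into 12 contiguous 30-degree sectors and labels
#' them with anatomical clock hours for the given eye, so that clock 11 falls
#' in the superior quadrant and clocks 6-7 in the inferior quadrant for both
#' lateralities.
#'
#' @inheritParams quadrant_means
#' @param laterality `"OD"` (right) or `"OS"` (left).
#' @return Named vector `clock_1 .. clock_12` (um).
#' @export
clock_hour_means <- function(tsnit, laterality = "OD") {
  x <- as_tsnit(tsnit)
  bounds <- round(TSNIT_LEN * (0:12) / 12)
  sector_means <- vapply(1:12, function(m)
    mean(x[(bounds[m] + 1):bounds[m + 1]]), 0.0)
  hours <- clock_hours_for(laterality)
  out <- numeric(12)
  out[hours] <- sector_means
  stats::setNames(out, paste0("clock_", 1:12))
}

moments_of <- function(x) {
  n <- length(x)
  m <- mean(x)
  s2 <- sum((x - m)^2) / n              # population variance
  sdv <- stats::sd(x)                   # sample sd, reported as "sd"
  if (s2 <= .Machine$double.eps * max(1, m^2)) {
    skew <- 0; kurt <- 0                # degenerate segment convention
  } else {
    skew <- sum((x - m)^3) / n / s2^1.5
    kurt <- sum((x - m)^4) / n / s2^2   # non-excess: normal -> 3
  }
  c(mean = m, median = stats::median(x), sd = sdv, skew = skew, kurt = kurt)
}

#' Distributional statistics of the TSNIT profile and its quadrants
#'
#' Mean, median, standard deviation, skewness and kurtosis of the whole
#' profile and of each 64-sample quadrant (25 values). Skewness and kurtosis
#' are the population-normalised standardised third and fourth central
#' moments (kurtosis non-excess, normal = 3); zero-variance segments report
#' both as 0.
#'
#' @inheritParams quadrant_means
#' @return Named vector of 25 values (`tsnit_<segment>_<statistic>`).
#' @export
tsnit_statistics <- function(tsnit) {
  x <- as_tsnit(tsnit)
  segs <- list(whole = x, t = x[1:64], s = x[65:128],
               n = x[129:192], i = x[193:256])
  out <- unlist(lapply(names(segs), function(nm)
    stats::setNames(moments_of(segs[[nm]]),
                    paste0("tsnit_", nm, "_",
                           c("mean", "median", "sd", "skew", "kurt")))))
  out
}

#' Information-theoretic features of the TSNIT profile
#'
#' Shannon entropy (bits) of the 16-equal-width-bin normalised thickness
#' histogram over \[min, max\]; the discrete Fisher information measure
#' `sum_i (p[i+1] - p[i])^2 / p[i]` over the same histogram (terms with
#' `p[i] = 0` skipped); and the signal-to-noise ratio `mean/sd`.
#'
#' @inheritParams quadrant_means
#' @param bins Number of histogram bins (default 16).
#' @return Named vector `c(entropy=, fisher=, snr=)`; a constant profile has
#'   entropy 0, Fisher measure 0 and `snr = Inf`.
#' @export
information_features <- function(tsnit, bins = 16L) {
  x <- as_tsnit(tsnit)
  if (diff(range(x)) == 0) {
    return(c(entropy = 0, fisher = 0, snr = Inf))
  }
  breaks <- seq(min(x), max(x), length.out = bins + 1L)
  cnt <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                               all.inside = TRUE), nbins = bins)
  p <- cnt / sum(cnt)
  entropy <- -sum(ifelse(p > 0, p * log2(p), 0))
  d <- diff(p)
  keep <- p[-length(p)] > 0
  fisher <- sum(d[keep]^2 / p[-length(p)][keep])
  snr <- if (stats::sd(x) == 0) Inf else mean(x) / stats::sd(x)
  c(entropy = entropy, fisher = fisher, snr = snr)
}

#' Inter-eye RNFL symmetry
#'
#' `100 * max(0, r)` where `r` is the Pearson correlation between the two
#' fellow-eye profiles. Because each eye's TSNIT ordering starts at its own
#' temporal side, index-aligned profiles are already anatomically mirrored,
#' so no re-indexing is applied. This is a documented stand-in for the
#' device's (unpublished) symmetry definition; device-exported values take
#' precedence in [extract_spatial()].
#'
#' @param od_tsnit,os_tsnit The fellow-eye profiles (256 samples each).
#' @return Percent in \[0, 100\], or `NA` if either profile has zero variance.
#' @export
rnfl_symmetry <- function(od_tsnit, os_tsnit) {
  a <- as_tsnit(od_tsnit); b <- as_tsnit(os_tsnit)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  100 * max(0, stats::cor(a, b))
}

#' Extract the 67 spatial-domain features of one eye record
#'
#' Emits the default spatial catalog: 46 RNFL features (average, inter-eye
#' symmetry, 4 quadrants, 12 clock hours, 25 TSNIT statistics, 3
#' information-theoretic features), 8 GC-IPL and 13 macular pass-throughs.
#' Device-exported summary values take precedence over recomputation from the
#' raw profile; artefact-masked groups emit missing values.
#'
#' @param record One cohort row (data.frame of one row in the canonical
#'   schema).
#' @param fellow_record Optional fellow-eye row, used to compute RNFL
#'   symmetry when the device value is absent.
#' @return Named numeric vector of exactly 67 features in catalog order.
#' @export
extract_spatial <- function(record, fellow_record = NULL) {
  record <- as.data.frame(record)
  if (nrow(record) != 1L) stop("record must be a single row")
  out <- stats::setNames(rep(NA_real_, 67L), spatial_feature_names())
  tvals <- as.numeric(record[1, tsnit_cols()])
  has_tsnit <- all(is.finite(tvals))
  rn <- rnfl_summary_cols()
  dev <- stats::setNames(as.numeric(record[1, rn]), rn)
  if (!has_tsnit && all(is.na(dev)) &&
      all(is.na(as.numeric(record[1, gcipl_cols()]))) &&
      all(is.na(as.numeric(record[1, mac_cols()]))))
    stop("record has no usable parameter group")
  if (has_tsnit) {
    computed <- c(rnfl_average = mean(tvals),
                  rnfl_symmetry = NA_real_,
                  stats::setNames(unname(quadrant_means(tvals)),
                                  c("rnfl_quad_t", "rnfl_quad_s",
                                    "rnfl_quad_n", "rnfl_quad_i")),
                  stats::setNames(unname(clock_hour_means(tvals,
                                                          record$eye[1])),
                                  paste0("rnfl_clock_", 1:12)))
    if (!is.null(fellow_record)) {
      fv <- as.numeric(as.data.frame(fellow_record)[1, tsnit_cols()])
      if (all(is.finite(fv)))
        computed["rnfl_symmetry"] <- rnfl_symmetry(tvals, fv)
    }
    out[rn] <- ifelse(is.na(dev), computed[rn], dev)
    st <- tsnit_statistics(tvals)
    out[names(st)] <- st
    info <- information_features(tvals)
    out[c("tsnit_entropy", "tsnit_fisher", "tsnit_snr")] <- info
  } else {
    out[rn] <- dev
  }
  out[gcipl_cols()] <- as.numeric(record[1, gcipl_cols()])
  out[mac_cols()] <- as.numeric(record[1, mac_cols()])
  out
}
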