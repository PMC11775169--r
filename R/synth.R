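## Seeded generator of stage-conditioned synthetic eyes. The TSNIT profile is
## modelled as a baseline plus two Gaussian bumps (the superior and inferior
## "double hump"), attenuated with disease severity, with additive Gaussian
## measurement noise. GC-IPL and macular summaries are affine in the eye's
## mean TSNIT thickness plus noise, so cross-parameter correlation exists for
## chained-equation imputation to exploit.

#' Specification of a synthetic cohort
#'
#' Defaults emulate a reference clinical cohort's class structure (334 normal eyes from
#' paired-eye patients; 86 early, 72 moderate, 37 MD-advanced and 73
#' CFD-advanced glaucomatous eyes, one eye per glaucoma patient), Mills-band
#' mean deviations, severity-attenuated double-hump TSNIT morphology and a
#' 3.65% per-parameter-group artefact rate.
#'
#' @param counts Named integer vector of eye counts per stage label.
#' @param baseline Baseline (temporal/nasal floor) thickness, um.
#' @param hump_amplitude Named vector, peak height of the superior and
#'   inferior humps above baseline, um.
#' @param hump_sd Gaussian bump scale in samples (bump width ~ 2*sd).
#' @param attenuation Named per-stage fraction in [0,1] by which disease
#'   shrinks the humps.
#' @param noise_sd Per-sample measurement noise, um.
#' @param inter_eye_sd Per-patient inter-eye jitter of bump parameters, um.
#' @param md_bands Named list of c(lo, hi) dB intervals per stage; each band
#'   must be consistent with the Mills partition for its label.
#' @param artefact_rate Probability a parameter group is artefact-masked.
#' @param seed Integer seed for [generate_cohort()].
#' @return A validated `synth_spec` list.
#' @export
synth_spec <- function(counts = c(NORMAL = 334, EARLY = 86, MODERATE = 72,
                                  ADVANCED_MD = 37, ADVANCED_CFD = 73),
                       baseline = 65,
                       hump_amplitude = c(superior = 70, inferior = 78),
                       hump_sd = 15,
                       attenuation = c(NORMAL = 0, EARLY = 0.25,
                                       MODERATE = 0.45, ADVANCED_MD = 0.65,
                                       ADVANCED_CFD = 0.60),
                       noise_sd = 6,
                       inter_eye_sd = 4,
                       md_bands = list(NORMAL = c(-2, 2),
                                       EARLY = c(-5.9, -0.1),
                                       MODERATE = c(-11.9, -6.0),
                                       ADVANCED_MD = c(-20, -12),
                                       ADVANCED_CFD = c(-10, -3)),
                       artefact_rate = 0.0365,
                       seed = 20260101L) {
  counts <- counts[STAGE_LEVELS]
  names(counts) <- STAGE_LEVELS
  counts[is.na(counts)] <- 0L
  stopifnot(all(counts >= 0),
            all(attenuation >= 0 & attenuation <= 1),
            artefact_rate >= 0, artefact_rate < 1,
            baseline >= 0, hump_sd > 0, noise_sd >= 0)
  ## Mills consistency of the MD bands
  chk <- function(stage, ok) {
    b <- md_bands[[stage]]
    if (!is.null(b) && !all(ok(b))) stop("md band for ", stage,
                                         " violates the Mills partition")
  }
  chk("EARLY", function(b) b > -6 & b < 0)
  chk("MODERATE", function(b) b > -12 & b <= -6)
  chk("ADVANCED_MD", function(b) b <= -12)
  chk("ADVANCED_CFD", function(b) b > -12)
  structure(list(counts = as.integer(counts) |> stats::setNames(STAGE_LEVELS),
                 baseline = baseline, hump_amplitude = hump_amplitude,
                 hump_sd = hump_sd, attenuation = attenuation,
                 noise_sd = noise_sd, inter_eye_sd = inter_eye_sd,
                 md_bands = md_bands, artefact_rate = artefact_rate,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

## Noise-free double-hump shape; superior hump centred in samples 64-127,
## inferior hump centred in samples 192-255 (0-based TSNIT indexing).
tsnit_shape <- function(spec, amp_s, amp_i, atten) {
  i <- 0:(TSNIT_LEN - 1L)
  spec$baseline +
    amp_s * (1 - atten) * exp(-(i - 96)^2 / (2 * spec$hump_sd^2)) +
    amp_i * (1 - atten) * exp(-(i - 224)^2 / (2 * spec$hump_sd^2))
}

#' Generate one synthetic TSNIT profile
#'
#' Draws from the current RNG state; wrap in `set.seed()` (or use
#' [generate_cohort()]) for reproducibility.
#'
#' @param stage Stage label (one of the five cohort labels).
#' @param spec A [synth_spec()].
#' @return Numeric vector of 256 thickness samples (um), clipped at 0.
#' @export
generate_tsnit <- function(stage, spec = synth_spec()) {
  stopifnot(stage %in% STAGE_LEVELS)
  mu <- tsnit_shape(spec, spec$hump_amplitude[["superior"]],
                    spec$hump_amplitude[["inferior"]],
                    spec$attenuation[[stage]])
  pmax(0, mu + stats::rnorm(TSNIT_LEN, 0, spec$noise_sd))
}

## GC-IPL / macular summaries as affine functions of mean TSNIT + noise.
gcipl_from_tsnit <- function(mean_tsnit) {
  avg <- 20 + 0.70 * mean_tsnit + stats::rnorm(1, 0, 2.5)
  sec_names <- setdiff(gcipl_cols(), c("gcipl_average", "gcipl_minimum"))
  sectors <- avg + c(-2, 1, -1, 0, 2, 1) + stats::rnorm(6, 0, 2)
  out <- c(avg, min(sectors) - abs(stats::rnorm(1, 1, 0.5)), sectors)
  stats::setNames(pmax(0, out), gcipl_cols())
}

mac_from_tsnit <- function(mean_tsnit) {
  cube_avg <- 230 + 0.60 * mean_tsnit + stats::rnorm(1, 0, 4)
  central <- cube_avg - 25 + stats::rnorm(1, 0, 4)
  inner <- cube_avg + 20 + c(2, 1, -1, -2) + stats::rnorm(4, 0, 3)
  outer <- cube_avg - 5 + c(1, 2, -2, -1) + stats::rnorm(4, 0, 3)
  vol <- cube_avg * 0.036 + stats::rnorm(1, 0, 0.05)   # ~10 mm^3 cube volume
  foveal <- central - 20 + stats::rnorm(1, 0, 3)
  cmin <- central - 8 - abs(stats::rnorm(1, 2, 1))
  out <- c(central, inner, outer, cube_avg, vol, foveal, cmin)
  stats::setNames(pmax(0, out), mac_cols())
}

#' Generate a seeded synthetic cohort
#'
#' Honours the per-stage eye counts of `spec`: normal patients contribute
#' both eyes, glaucoma patients one eye each (with an unrecorded fellow eye
#' generated internally so inter-eye RNFL symmetry can be computed). Mean
#' deviation is drawn uniformly within the stage's Mills band, GC-IPL and
#' macular summaries are correlated with mean TSNIT thickness, and each
#' parameter group is artefact-masked i.i.d. at `artefact_rate` (resampled in
#' the rare event all three groups of an eye are hit, since such eyes were
#' excluded by the inclusion criteria).
#'
#' @param spec A [synth_spec()].
#' @return An `oct_cohort`.
#' @examples
#' coh <- generate_cohort(synth_spec(counts = c(NORMAL = 8, EARLY = 4,
#'   MODERATE = 4, ADVANCED_MD = 4, ADVANCED_CFD = 0), seed = 1))
#' table(coh$label)
#' @export
generate_cohort <- function(spec = synth_spec()) {
  with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  rows <- list()
  pid <- 0L
  for (stage in STAGE_LEVELS) {
    n_eyes <- spec$counts[[stage]]
    if (n_eyes == 0L) next
    paired <- stage == "NORMAL"
    while (n_eyes > 0L) {
      pid <- pid + 1L
      patient <- sprintf("P%04d", pid)
      record_both <- paired && n_eyes >= 2L
      ## per-patient bump parameters with inter-eye jitter applied per eye
      amp_s <- spec$hump_amplitude[["superior"]] + stats::rnorm(1, 0, 5)
      amp_i <- spec$hump_amplitude[["inferior"]] + stats::rnorm(1, 0, 5)
      att <- spec$attenuation[[stage]]
      ## asymmetric disease: the fellow (or second) eye is attenuated by a
      ## random fraction of the index-eye attenuation, so inter-eye symmetry
      ## degrades with severity
      att2 <- if (stage == "NORMAL") att else att * stats::runif(1, 0.1, 0.7)
      jit <- function() stats::rnorm(TSNIT_LEN, 0, spec$inter_eye_sd)
      i <- 0:(TSNIT_LEN - 1L)
      prof1 <- pmax(0, tsnit_shape(spec, amp_s, amp_i, att) +
                      stats::rnorm(TSNIT_LEN, 0, spec$noise_sd) + jit())
      prof2 <- pmax(0, tsnit_shape(spec, amp_s, amp_i, att2) +
                      stats::rnorm(TSNIT_LEN, 0, spec$noise_sd) + jit())
      sym <- rnfl_symmetry(prof1, prof2)
      lat1 <- if (record_both) "OD" else sample(c("OD", "OS"), 1L)
      eyes <- if (record_both) list(c("OD", 1), c("OS", 2)) else
        list(c(lat1, 1))
      for (e in eyes) {
        prof <- if (e[[2]] == 1) prof1 else prof2
        band <- spec$md_bands[[stage]]
        md <- stats::runif(1, band[1], band[2])
        row <- make_eye_row(patient, e[[1]], stage, md,
                            cfd = stage == "ADVANCED_CFD",
                            prof = prof, sym = sym)
        ## artefact mask per parameter group, redrawn if all three are hit
        repeat {
          mask <- stats::runif(3) < spec$artefact_rate
          if (!all(mask)) break
        }
        for (g in PARAM_GROUPS[mask]) row[group_cols(g)] <- NA_real_
        rows[[length(rows) + 1L]] <- row
        n_eyes <- n_eyes - 1L
      }
    }
  }
  df <- do.call(rbind, rows)
  validate_cohort(df)
  new_cohort(df, provenance = sprintf("synthetic (seed %d)", spec$seed))
}

make_eye_row <- function(patient, eye, stage, md, cfd, prof, sym) {
  qm <- quadrant_means(prof)
  cm <- clock_hour_means(prof, eye)
  df <- data.frame(patient_id = patient, eye = eye, label = stage,
                   md_db = md, cfd_flag = cfd, stringsAsFactors = FALSE)
  df[tsnit_cols()] <- as.list(prof)
  df[["rnfl_average"]] <- mean(prof)
  df[["rnfl_symmetry"]] <- sym
  df[c("rnfl_quad_t", "rnfl_quad_s", "rnfl_quad_n", "rnfl_quad_i")] <-
    as.list(unname(qm))
  df[paste0("rnfl_clock_", 1:12)] <- as.list(unname(cm))
  df[gcipl_cols()] <- as.list(unname(gcipl_from_tsnit(mean(prof))))
  df[mac_cols()] <- as.list(unname(mac_from_tsnit(mean(prof))))
  df[cohort_cols()]
}
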