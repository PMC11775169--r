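test_that("quadrant means are the four 64-sample block averages", {
  expect_equal(unname(quadrant_means(rep(100, 256))), rep(100, 4))
  blocks <- c(rep(70, 64), rep(120, 64), rep(80, 64), rep(110, 64))
  expect_equal(quadrant_means(blocks),
               c(T = 70, S = 120, N = 80, I = 110))
  x <- random_profile(3)
  oracle <- vapply(0:3, function(q) sum(x[(64 * q + 1):(64 * q + 64)]) / 64,
                   0.0)
  expect_equal(unname(quadrant_means(x)), oracle, tolerance = 1e-12)
})

test_that("clock-hour sectors partition the profile and conserve the total", {
  x <- random_profile(4)
  cm <- clock_hour_means(x, "OD")
  expect_length(cm, 12L)
  expect_equal(unname(clock_hour_means(rep(55, 256), "OS")), rep(55, 12))
  bounds <- round(256 * (0:12) / 12)
  counts <- diff(bounds)
  hours <- glocr:::clock_hours_for("OD")
  ## sum of sector_count * sector_mean over sectors = sum of all samples
  expect_equal(sum(counts * cm[paste0("clock_", hours)]), sum(x),
               tolerance = 1e-9)
})

test_that("clock labels mirror between lateralities (2<->10, 3<->9, ...)", {
  x <- random_profile(5)
  od <- clock_hour_means(x, "OD")
  os <- clock_hour_means(x, "OS")
  mirror <- function(h) ifelse((12 - h) %% 12 == 0, 12, (12 - h) %% 12)
  for (h in 1:12)
    expect_equal(unname(od[paste0("clock_", h)]),
                 unname(os[paste0("clock_", mirror(h))]))
  ## anatomical anchoring: clock 11 lies in the superior quadrant, clocks
  ## 6 and 7 in the inferior quadrant, for both eyes
  sup <- c(rep(0, 64), rep(100, 64), rep(0, 128))
  inf <- c(rep(0, 192), rep(100, 64))
  for (lat in c("OD", "OS")) {
    expect_gt(clock_hour_means(sup, lat)[["clock_11"]], 50)
    expect_gt(clock_hour_means(inf, lat)[["clock_6"]], 99)
    expect_gt(clock_hour_means(inf, lat)[["clock_7"]], 99)
  }
})

test_that("TSNIT statistics match independent moment computation", {
  ## degenerate rule
  st <- tsnit_statistics(rep(80, 256))
  expect_equal(unname(st["tsnit_whole_mean"]), 80)
  expect_equal(unname(st["tsnit_whole_median"]), 80)
  expect_equal(unname(st[c("tsnit_whole_sd", "tsnit_whole_skew",
                           "tsnit_whole_kurt")]), c(0, 0, 0))
  ## symmetric two-level signal has zero skewness
  two <- rep(c(60, 100), 128)
  expect_equal(unname(tsnit_statistics(two)["tsnit_whole_skew"]), 0)
  ## arbitrary vector against brute-force population moments
  x <- random_profile(6)
  st <- tsnit_statistics(x)
  expect_length(st, 25L)
  for (seg in list(c("whole", 1, 256), c("t", 1, 64), c("s", 65, 128),
                   c("n", 129, 192), c("i", 193, 256))) {
    v <- x[as.integer(seg[2]):as.integer(seg[3])]
    m2 <- mean((v - mean(v))^2)
    expect_equal(unname(st[paste0("tsnit_", seg[1], "_mean")]), mean(v))
    expect_equal(unname(st[paste0("tsnit_", seg[1], "_median")]), median(v))
    expect_equal(unname(st[paste0("tsnit_", seg[1], "_sd")]), sd(v))
    expect_equal(unname(st[paste0("tsnit_", seg[1], "_skew")]),
                 mean((v - mean(v))^3) / m2^1.5, tolerance = 1e-12)
    expect_equal(unname(st[paste0("tsnit_", seg[1], "_kurt")]),
                 mean((v - mean(v))^4) / m2^2, tolerance = 1e-12)
  }
})

test_that("information features follow the 16-bin histogram definitions", {
  ## constant profile: single occupied bin
  info <- information_features(rep(70, 256))
  expect_equal(unname(info[c("entropy", "fisher")]), c(0, 0))
  expect_equal(unname(info["snr"]), Inf)
  ## exactly uniform 16-bin histogram: entropy = 4 bits, Fisher measure 0
  u <- rep(seq(0, 15) * 10 + 5, each = 16)
  info <- information_features(u)
  expect_equal(unname(info["entropy"]), 4)
  expect_equal(unname(info["fisher"]), 0)
  ## arbitrary signal against an independent histogram recomputation
  x <- random_profile(7)
  info <- information_features(x)
  h <- hist(x, breaks = seq(min(x), max(x), length.out = 17),
            include.lowest = TRUE, plot = FALSE)
  p <- h$counts / sum(h$counts)
  expect_equal(unname(info["entropy"]),
               -sum(p[p > 0] * log2(p[p > 0])), tolerance = 1e-12)
  fis <- 0
  for (i in 1:15) if (p[i] > 0) fis <- fis + (p[i + 1] - p[i])^2 / p[i]
  expect_equal(unname(info["fisher"]), fis, tolerance = 1e-12)
  expect_equal(unname(info["snr"]), mean(x) / sd(x), tolerance = 1e-12)
})

test_that("RNFL symmetry is a clamped fellow-eye correlation", {
  x <- random_profile(8)
  expect_equal(rnfl_symmetry(x, x), 100)
  ## anti-correlated constructed pair clamps to 0
  y <- max(x) + min(x) - x
  expect_equal(rnfl_symmetry(x, y), 0)
  ## jittered fellow eyes equal the independent correlation oracle
  set.seed(9)
  z <- pmax(0, x + rnorm(256, 0, 5))
  expect_equal(rnfl_symmetry(x, z), 100 * cor(x, z), tolerance = 1e-12)
  ## symmetric in arguments, invariant to common affine rescaling
  expect_equal(rnfl_symmetry(x, z), rnfl_symmetry(z, x))
  expect_equal(rnfl_symmetry(2 * x + 10, 2 * z + 10), rnfl_symmetry(x, z),
               tolerance = 1e-9)
  expect_true(is.na(rnfl_symmetry(rep(5, 256), x)))
})

test_that("extract_spatial emits the 67-name catalog with masks and precedence", {
  coh <- as.data.frame(small_cohort())
  full <- coh[rowSums(artefact_mask(small_cohort())) == 0, ][1, ]
  sp <- extract_spatial(full)
  expect_identical(names(sp), glocr:::spatial_feature_names())
  expect_length(sp, 67L)
  expect_true(all(is.finite(sp)))
  ## masked GC-IPL group propagates as 8 missing entries
  masked <- full
  masked[glocr:::gcipl_cols()] <- NA_real_
  sp2 <- extract_spatial(masked)
  expect_equal(sum(is.na(sp2)), 8L)
  expect_true(all(is.na(sp2[glocr:::gcipl_cols()])))
  ## device-provided summary overrides recomputation
  dev <- full
  dev$rnfl_average <- 999
  expect_equal(unname(extract_spatial(dev)["rnfl_average"]), 999)
  ## a record with no usable group errors
  empty <- full
  empty[c(glocr:::tsnit_cols(), glocr:::rnfl_summary_cols(),
          glocr:::gcipl_cols(), glocr:::mac_cols())] <- NA_real_
  expect_error(extract_spatial(empty), "no usable")
})

test_that("fellow-eye symmetry is recomputed only when the device value is absent", {
  coh <- as.data.frame(small_cohort())
  norm <- coh[coh$label == "NORMAL", ]
  pid <- norm$patient_id[duplicated(norm$patient_id)][1]
  a <- norm[norm$patient_id == pid & norm$eye == "OD", ]
  b <- norm[norm$patient_id == pid & norm$eye == "OS", ]
  a$rnfl_symmetry <- NA_real_
  sp <- extract_spatial(a, b)
  expect_equal(unname(sp["rnfl_symmetry"]),
               rnfl_symmetry(as.numeric(a[1, glocr:::tsnit_cols()]),
                             as.numeric(b[1, glocr:::tsnit_cols()])))
})
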