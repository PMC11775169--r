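test_that("likelihood bins are left-closed on the documented edges", {
  expect_identical(likelihood_bins(0), "very low")
  expect_identical(likelihood_bins(0.09), "very low")
  expect_identical(likelihood_bins(0.10), "low")
  expect_identical(likelihood_bins(0.25), "intermediate")  # left-closed
  expect_identical(likelihood_bins(0.50), "high")
  expect_identical(likelihood_bins(0.75), "very high")
  expect_identical(likelihood_bins(1), "very high")
  expect_error(likelihood_bins(1.2), "0, 1")
})

test_that("the major/minor priority rule scores as specified", {
  g <- synthetic_gloc(cutoff = 70)   # prob(v) = 1 - v/100
  feats <- names(g$entries)
  ## all three majors beyond their cut-offs with probabilities .90/.80/.85;
  ## minors on the normal side
  inp <- setNames(rep(90, 9), feats)
  inp[glocr:::GLOC_MAJOR] <- c(10, 20, 15)
  r <- gloc_score(g, inp)
  expect_equal(r$likelihood, 0.85, tolerance = 1e-12)
  expect_identical(r$path, "major")
  expect_true(r$binary_call)           # glaucoma at the 0.25 threshold
  expect_identical(r$category, "very high")
  ## majors not all fulfilled, all minors fulfilled with mean prob 0.40
  inp2 <- setNames(rep(60, 9), feats)  # minors at 60 -> prob 0.40 each
  inp2[glocr:::GLOC_MAJOR] <- c(10, 20, 80)   # third major unfulfilled
  r2 <- gloc_score(g, inp2)
  expect_equal(r2$likelihood, 0.40, tolerance = 1e-12)
  expect_identical(r2$path, "minor")
  ## nothing fulfilled: combined mean of all nine
  inp3 <- setNames(rep(90, 9), feats)  # every prob 0.10
  r3 <- gloc_score(g, inp3)
  expect_identical(r3$path, "combined")
  expect_equal(r3$likelihood, 0.10, tolerance = 1e-12)
  expect_false(r3$binary_call)         # healthy-typical inputs -> normal
  ## path consistency: major path implies every major beyond its cut-off
  expect_true(all(r$fulfilled[glocr:::GLOC_MAJOR]))
  expect_false(all(r2$fulfilled[glocr:::GLOC_MAJOR]))
})

test_that("missing inputs are boundary-neutral and flagged partial", {
  g <- synthetic_gloc()
  inp <- setNames(rep(90, 9), names(g$entries))
  inp <- inp[-1]                        # drop one major
  r <- gloc_score(g, inp)
  expect_true(r$partial_input)
  ## the missing feature contributes its cut-off probability (0.5 here)
  expect_equal(unname(r$probabilities[glocr:::GLOC_MAJOR[1]]), 0.5,
               tolerance = 1e-12)
})

test_that("lookups interpolate linearly and clamp at the grid ends", {
  g <- synthetic_gloc()
  e <- g$entries[[1]]
  expect_equal(glocr:::gloc_lookup(e, 25), 0.75, tolerance = 1e-12)
  expect_equal(glocr:::gloc_lookup(e, -10), 1)    # clamped
  expect_equal(glocr:::gloc_lookup(e, 250), 0)
})

test_that("build_gloc stores monotone curves with finite cut-offs", {
  set.seed(61)
  feats <- c(glocr:::GLOC_MAJOR, glocr:::GLOC_MINOR)
  X <- matrix(runif(9 * 150, 40, 120), 150, 9,
              dimnames = list(NULL, feats))
  ## monotone synthetic model: risk rises as every feature falls
  w <- setNames(rep(-0.03, 9), feats)
  pf <- function(M) plogis(as.matrix(M)[, feats, drop = FALSE] %*% w + 21)
  g <- build_gloc(pf, X)
  expect_s3_class(g, "gloc")
  expect_length(g$entries, 9L)
  for (e in g$entries) {
    expect_true(is.finite(e$cutoff))
    expect_false(e$cutoff_fallback)
    expect_true(all(diff(e$prob) <= 1e-12))       # decreasing lookup
  }
  ## the curve-crossing worked example propagates into the stored cut-off
  curve <- structure(list(feature = "rnfl_quad_i", grid = c(70, 72),
                          pdp = c(0.6, 0.4), n_background = 1),
                     class = "pdp_curve")
  expect_equal(as.numeric(estimate_cutoff(curve, 0.5)), 71)
  ## missing feature in the reference matrix is a build error
  expect_error(build_gloc(pf, X[, -1]), "lacks")
  expect_error(build_gloc(pf, X, major = glocr:::GLOC_MAJOR,
                          minor = glocr:::GLOC_MINOR[-1]), "9 features")
})

test_that("likelihood is monotone within a fixed decision path", {
  g <- synthetic_gloc()
  feats <- names(g$entries)
  set.seed(62)
  for (rep_i in 1:20) {
    inp <- setNames(runif(9, 0, 100), feats)
    f <- sample(feats, 1)
    grid <- seq(100, 0, length.out = 15)
    res <- lapply(grid, function(v) { x <- inp; x[f] <- v; gloc_score(g, x) })
    lik <- vapply(res, `[[`, 0.0, "likelihood")
    path <- vapply(res, `[[`, "", "path")
    ## as the input falls, per-feature probability rises; within any run of
    ## constant path the likelihood never decreases
    same <- path[-length(path)] == path[-1]
    expect_true(all(diff(lik)[same] >= -1e-12))
  }
})

test_that("the priority rule is discontinuous at path switches", {
  ## documented property: when the last major criterion crosses its cut-off
  ## while the minors are deeply glaucomatous, the likelihood drops from the
  ## minor-group mean to the (lower) major-group mean
  g <- synthetic_gloc()
  inp <- setNames(rep(5, 9), names(g$entries))   # minors deeply abnormal
  inp[glocr:::GLOC_MAJOR] <- c(49, 49, 51)       # one major unfulfilled
  before <- gloc_score(g, inp)
  inp[glocr:::GLOC_MAJOR[3]] <- 49               # now all majors fulfilled
  after <- gloc_score(g, inp)
  expect_identical(before$path, "minor")
  expect_identical(after$path, "major")
  expect_lt(after$likelihood, before$likelihood)
})

test_that("threshold trade-off is monotone on a fixed cohort", {
  g <- synthetic_gloc()
  set.seed(63)
  feats <- names(g$entries)
  X <- matrix(runif(9 * 120, 0, 100), 120, 9, dimnames = list(NULL, feats))
  lik <- predict(g, X)
  pos <- lik > median(lik)
  ths <- seq(0, 1, by = 0.1)
  sens <- vapply(ths, function(t) sum(lik > t & pos) / sum(pos), 0.0)
  spc <- vapply(ths, function(t) sum(lik <= t & !pos) / sum(!pos), 0.0)
  expect_true(all(diff(sens) <= 1e-12))
  expect_true(all(diff(spc) >= -1e-12))
  ## degenerate thresholds from the validation harness
  v0 <- validate_gloc(g, X, rep(c("NORMAL", "EARLY"), 60),
                      md_db = runif(120, -20, 2), threshold = 0)
  expect_equal(unname(v0$operating_point["sensitivity"]), 1)
  v1 <- validate_gloc(g, X, rep(c("NORMAL", "EARLY"), 60),
                      md_db = runif(120, -20, 2), threshold = 1)
  expect_equal(unname(v1$operating_point["specificity"]), 1)
})

test_that("gloc JSON round-trips", {
  g <- synthetic_gloc()
  p <- withr::local_tempfile(fileext = ".json")
  write_gloc(g, p)
  g2 <- read_gloc(p)
  inp <- setNames(runif(9, 0, 100), names(g$entries))
  expect_equal(gloc_score(g2, inp)$likelihood, gloc_score(g, inp)$likelihood,
               tolerance = 1e-12)
  expect_equal(g2$entries[[1]]$cutoff, g$entries[[1]]$cutoff)
})
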