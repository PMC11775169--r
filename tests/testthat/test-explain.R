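test_that("exact Shapley values satisfy the dummy and efficiency axioms", {
  set.seed(51)
  bg <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("x", 1:4)))
  x <- c(x1 = 2, x2 = 1, x3 = 0.5, x4 = -1)
  ## model using only x1: phi1 = f(x) - E[f], others exactly 0
  f1 <- function(M) as.matrix(M)[, "x1"]
  at <- shapley_values(f1, bg, x, mode = "exact")
  expect_equal(unname(at$phi["x1"]), 2 - mean(bg[, "x1"]), tolerance = 1e-9)
  expect_equal(unname(at$phi[c("x2", "x3", "x4")]), rep(0, 3),
               tolerance = 1e-12)
  expect_lt(abs(sum(at$phi) + at$base_value - at$fx), 1e-9)
  ## additive model: phi_i = x_i - mean(background_i)
  fa <- function(M) rowSums(as.matrix(M))
  ata <- shapley_values(fa, bg, x, mode = "exact")
  expect_equal(unname(ata$phi), unname(x - colMeans(bg)), tolerance = 1e-9)
  expect_error(shapley_values(fa, bg[0, ], x, mode = "exact"), "empty")
})

test_that("exchangeable features receive equal exact Shapley values", {
  bg <- matrix(rep(c(0, 1), each = 8), 8, 2,
               dimnames = list(NULL, c("p", "q")))
  bg[, 2] <- bg[, 1]                       # identical background columns
  f <- function(M) as.matrix(M)[, "p"] * as.matrix(M)[, "q"]
  at <- shapley_values(f, bg, c(p = 1, q = 1), mode = "exact")
  expect_equal(unname(at$phi["p"]), unname(at$phi["q"]), tolerance = 1e-9)
})

test_that("sampled Shapley converges to the exact enumeration", {
  set.seed(52)
  m <- 5
  bg <- matrix(rnorm(40 * m), 40, m, dimnames = list(NULL, paste0("x", 1:m)))
  x <- setNames(rnorm(m), paste0("x", 1:m))
  ## interaction model (additive models are exact after one permutation)
  f <- function(M) {
    M <- as.matrix(M)
    plogis(M[, 1] * M[, 2] + 0.5 * M[, 3] - M[, 4]^2 + 0.2 * M[, 5])
  }
  exact <- shapley_values(f, bg, x, mode = "exact")$phi
  err <- vapply(c(50L, 2000L), function(np)
    max(abs(shapley_values(f, bg, x, mode = "sampled", n_perm = np,
                           seed = 3)$phi - exact)), 0.0)
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.02)
})

test_that("global ranking orders by mean absolute attribution", {
  A <- rbind(c(a = 0.1, b = 0.9, c = -0.2),
             c(a = -0.1, b = -0.8, c = 0.1))
  r <- global_rank(A)
  expect_identical(r$feature[1], "b")
  ## all-zero attributions preserve catalog (column) order
  r0 <- global_rank(matrix(0, 3, 3, dimnames = list(NULL, c("a", "b", "c"))))
  expect_identical(r0$feature, c("a", "b", "c"))
  ## rank stable under sample duplication
  expect_identical(global_rank(rbind(A, A))$feature, r$feature)
  ## per-class means present when classes given
  rc <- global_rank(A, classes = c("g", "n"))
  expect_true(all(c("mean_abs_g", "mean_abs_n") %in% names(rc)))
  expect_error(global_rank(A[0, , drop = FALSE]), "empty")
})

test_that("dependence data pairs values with attributions row-by-row", {
  set.seed(53)
  X <- matrix(runif(200, 40, 100), 100, 2,
              dimnames = list(NULL, c("thk", "oth")))
  ## monotone model: risk falls as thickness rises; crossover at the centre
  f <- function(M) plogis(-(as.matrix(M)[, "thk"] - 70) / 5)
  A <- t(vapply(seq_len(nrow(X)), function(r)
    shapley_values(f, X, X[r, ], mode = "exact")$phi, numeric(2)))
  colnames(A) <- colnames(X)
  dd <- dependence_data(A, X, "thk")
  expect_equal(nrow(dd), nrow(X))
  ## sign of phi changes exactly once along the sorted feature axis
  sgn <- sign(dd$phi[order(dd$value)])
  sgn <- sgn[sgn != 0]
  expect_equal(sum(diff(sgn) != 0), 1L)
  ## feature the model ignores -> all-zero attribution column
  expect_true(all(abs(A[, "oth"]) < 1e-12))
  expect_error(dependence_data(A, X, "nope"), "unknown feature")
})

test_that("PDP is exactly the columnwise mean of ICE", {
  set.seed(54)
  X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  f <- function(M) plogis(as.matrix(M)[, "a"] + 0.5 * as.matrix(M)[, "b"])
  pc <- pdp_ice(f, X, "a", grid_size = 21)
  expect_equal(pc$pdp, colMeans(pc$ice), tolerance = 1e-12)
  expect_true(all(diff(pc$grid) > 0))
  expect_true(all(pc$pdp >= 0 & pc$pdp <= 1))
  ## unused feature: flat PDP at the mean prediction
  pflat <- pdp_ice(f, X, "c", grid_size = 11)
  expect_lt(diff(range(pflat$pdp)), 1e-12)
  expect_equal(pflat$pdp[1], mean(f(X)), tolerance = 1e-12)
  ## clipped-linear model in one feature reproduces the line
  g <- function(M) pmin(1, pmax(0, 0.5 + 0.1 * as.matrix(M)[, "a"]))
  pl <- pdp_ice(g, X, "a", grid_size = 7)
  expect_equal(pl$pdp, pmin(1, pmax(0, 0.5 + 0.1 * pl$grid)),
               tolerance = 1e-12)
  ## constant feature collapses to a single-point grid
  Xc <- X; Xc[, "a"] <- 5
  expect_length(pdp_ice(f, Xc, "a")$grid, 1L)
  expect_error(pdp_ice(f, X[0, , drop = FALSE], "a"), "non-empty")
})

test_that("two-way PDP surfaces decompose additively and stay bounded", {
  set.seed(55)
  X <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  f <- function(M) plogis(0.8 * as.matrix(M)[, "a"] -
                            0.6 * as.matrix(M)[, "b"])
  ## linear link version for exact additivity of the surface
  flin <- function(M) 0.3 * as.matrix(M)[, "a"] + 0.1 * as.matrix(M)[, "b"]
  tw <- two_way_pdp(flin, X, "a", "b", grid_size = 9)
  pa <- pdp_ice(flin, X, "a", grid_size = 9)$pdp
  pb <- pdp_ice(flin, X, "b", grid_size = 9)$pdp
  const <- mean(flin(X))
  expect_equal(tw$surface, outer(pa, pb, `+`) - const, tolerance = 1e-12)
  ## probabilities stay in [0, 1]; unused second feature gives a constant axis
  tw2 <- two_way_pdp(f, X, "a", "b", grid_size = 5)
  expect_true(all(tw2$surface >= 0 & tw2$surface <= 1))
  fa_only <- function(M) plogis(as.matrix(M)[, "a"])
  tw3 <- two_way_pdp(fa_only, X, "a", "b", grid_size = 5)
  expect_lt(max(apply(tw3$surface, 1, function(r) diff(range(r)))), 1e-12)
})

test_that("cut-off estimation interpolates the first boundary crossing", {
  mk <- function(grid, pdp) structure(list(feature = "f", grid = grid,
                                           pdp = pdp, n_background = 1),
                                      class = "pdp_curve")
  ## the worked example: 0.6 @ 70 and 0.4 @ 72 with boundary 0.5 -> 71.0
  expect_equal(as.numeric(estimate_cutoff(mk(c(70, 72), c(0.6, 0.4)))), 71)
  ## curve entirely above the boundary -> none
  expect_true(is.na(estimate_cutoff(mk(1:5, rep(0.8, 5)))))
  ## wiggly curve: first crossing from the high-risk (falling) side wins,
  ## the remainder is logged
  wig <- mk(c(0, 1, 2, 3, 4), c(0.9, 0.4, 0.7, 0.3, 0.2))
  cut <- estimate_cutoff(wig)
  expect_equal(as.numeric(cut), 0.8)
  expect_length(attr(cut, "other_crossings"), 2L)
  ## rising-risk direction scans from the right
  ris <- mk(c(0, 1, 2), c(0.2, 0.4, 0.9))
  expect_equal(as.numeric(estimate_cutoff(ris, direction = "rising")), 1.2,
               tolerance = 1e-12)
  expect_error(estimate_cutoff(mk(1:3, c(0.2, NA, 0.8))), "non-finite")
})
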