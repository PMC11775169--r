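## Model-agnostic explanations: Shapley attributions (exact subset
## enumeration and permutation sampling), global mean-|phi| ranking,
## dependence data, partial-dependence / ICE curves, two-way PDP surfaces and
## decision-boundary cut-off estimation. Coalition values use marginal
## (interventional) expectations over a background sample, the same Monte
## Carlo treatment the partial-dependence estimator applies.

## value of a set of coalitions (bitmask rows) for instance x over background
coalition_values <- function(predict_fn, background, x, masks) {
  m <- length(x)
  nb <- nrow(background)
  big <- background[rep(seq_len(nb), times = length(masks)), , drop = FALSE]
  for (j in seq_len(m)) {
    in_S <- bitwAnd(masks, bitwShiftL(1L, j - 1L)) != 0L
    rows_on <- rep(in_S, each = nb)
    big[rows_on, j] <- x[j]
  }
  p <- predict_fn(big)
  stopifnot(length(p) == nrow(big))
  colMeans(matrix(p, nrow = nb))
}

#' Shapley-value attribution of one prediction
#'
#' Distributes `predict_fn(x) - E[predict_fn]` over the features by the
#' Shapley combinatorial weights: exact mode enumerates every feature subset
#' S and weights the marginal contributions `val(S u {i}) - val(S)` by
#' `|S|! (m - |S| - 1)! / m!`; sampled mode averages marginal contributions
#' along random feature permutations and converges to the same values. The
#' coalition value `val(S)` is the mean prediction with features in S pinned
#' to `x` and the rest marginalised over the background rows.
#'
#' @param predict_fn Function taking a feature matrix (same columns as
#'   `background_X`) and returning positive-class probabilities.
#' @param background_X Background sample for the marginal expectations
#'   (subsample ~200 rows for speed).
#' @param x Named numeric vector, the instance to explain.
#' @param mode `"exact"` (feature count <= 15) or `"sampled"`.
#' @param n_perm Number of permutations in sampled mode (default 200).
#' @param seed Integer seed (sampled mode).
#' @return An `attribution`: `phi` (named), `base_value` `E[f]`, `fx`
#'   `f(x)`; exact mode satisfies `sum(phi) + base_value = fx` to 1e-9.
#' @export
shapley_values <- function(predict_fn, background_X, x,
                           mode = c("exact", "sampled"), n_perm = 200L,
                           seed = 1L) {
  mode <- match.arg(mode)
  background_X <- as.matrix(background_X)
  if (nrow(background_X) == 0L) stop("empty background")
  m <- length(x)
  stopifnot(m == ncol(background_X))
  nms <- names(x) %||% colnames(background_X)
  if (mode == "exact") {
    if (m > 15L) stop("exact mode supports at most 15 features")
    masks <- 0:(2^m - 1L)
    val <- coalition_values(predict_fn, background_X, x, masks)
    phi <- numeric(m)
    sizes <- vapply(masks, function(s) sum(bitwAnd(s, 2^(0:(m - 1))) != 0),
                    0)
    lw <- lgamma(0:m + 1)                # log factorials
    for (j in seq_len(m)) {
      bit <- bitwShiftL(1L, j - 1L)
      without <- masks[bitwAnd(masks, bit) == 0L]
      s <- sizes[without + 1L]
      w <- exp(lw[s + 1] + lw[m - s] - lw[m + 1])
      phi[j] <- sum(w * (val[bitwOr(without, bit) + 1L] -
                           val[without + 1L]))
    }
    base <- val[1L]
  } else {
    phi <- numeric(m)
    base <- mean(predict_fn(background_X))
    with_seed(seed, {
      for (p in seq_len(n_perm)) {
        perm <- sample.int(m)
        masks <- integer(m + 1L)
        for (step in seq_len(m))
          masks[step + 1L] <- bitwOr(masks[step],
                                     bitwShiftL(1L, perm[step] - 1L))
        val <- coalition_values(predict_fn, background_X, x, masks)
        phi[perm] <- phi[perm] + diff(val)
      }
    })
    phi <- phi / n_perm
  }
  fx <- as.numeric(predict_fn(matrix(x, nrow = 1,
                                     dimnames = list(NULL, nms))))
  structure(list(phi = stats::setNames(phi, nms), base_value = base,
                 fx = fx, mode = mode),
            class = "attribution")
}

#' @export
print.attribution <- function(x, ...) {
  cat("<attribution> base ", format(x$base_value), " -> f(x) ",
      format(x$fx), " (", x$mode, ")\n", sep = "")
  print(round(sort(x$phi, decreasing = TRUE), 4))
  invisible(x)
}

#' Global feature ranking from an attribution matrix
#'
#' Mean absolute Shapley value per feature, sorted descending (ties keep
#' column order).
#'
#' @param attribution_matrix Matrix of per-sample phi vectors (rows =
#'   samples, named columns).
#' @param classes Optional per-row class labels; adds per-class means.
#' @return data.frame `feature`, `mean_abs` (and per-class columns), ordered
#'   by pooled importance.
#' @export
global_rank <- function(attribution_matrix, classes = NULL) {
  A <- as.matrix(attribution_matrix)
  if (nrow(A) == 0L) stop("empty attribution matrix")
  pooled <- colMeans(abs(A))
  out <- data.frame(feature = colnames(A), mean_abs = pooled,
                    row.names = NULL)
  if (!is.null(classes)) {
    for (lv in unique(classes))
      out[[paste0("mean_abs_", lv)]] <-
        colMeans(abs(A[classes == lv, , drop = FALSE]))
  }
  out[order(-out$mean_abs), , drop = FALSE]
}

#' Dependence-plot data with interaction colouring
#'
#' Per-sample triples (feature value, phi, interaction feature value); the
#' automatic interaction pick maximises the absolute correlation between the
#' candidate feature and the residuals of phi after removing the main trend
#' on the plotted feature.
#'
#' @param attribution_matrix Per-sample phi matrix.
#' @param X Feature-value matrix aligned with it.
#' @param feature Feature to plot.
#' @param interaction_feature Colour feature, or `NULL` for automatic.
#' @return data.frame `value`, `phi`, `colour_value` with the chosen
#'   interaction feature as an attribute.
#' @export
dependence_data <- function(attribution_matrix, X, feature,
                            interaction_feature = NULL) {
  A <- as.matrix(attribution_matrix); X <- as.matrix(X)
  if (!feature %in% colnames(A)) stop("unknown feature: ", feature)
  v <- X[, feature]; phi <- A[, feature]
  if (is.null(interaction_feature)) {
    res <- stats::residuals(stats::lm(phi ~ v))
    cand <- setdiff(colnames(X), feature)
    cors <- vapply(cand, function(cn) {
      if (stats::sd(X[, cn]) == 0) return(0)
      abs(stats::cor(X[, cn], res))
    }, 0.0)
    interaction_feature <- cand[which.max(cors)]
  }
  out <- data.frame(value = v, phi = phi,
                    colour_value = X[, interaction_feature])
  attr(out, "interaction_feature") <- interaction_feature
  out
}

#' Partial-dependence and ICE curves of one feature
#'
#' The PDP value at grid point v is the mean prediction over the data with
#' the feature pinned to v (the Monte Carlo estimate of the partial
#' dependence function); ICE rows are the per-sample curves and the PDP is
#' exactly their columnwise mean.
#'
#' @param predict_fn Prediction function over a feature matrix.
#' @param X Training/background feature matrix (non-empty).
#' @param feature Feature of interest.
#' @param grid_size Number of grid points spanning the observed range
#'   (default 50; a constant feature yields a single-point grid).
#' @param with_ice Keep the per-sample ICE matrix.
#' @return A `pdp_curve`: `feature`, `grid`, `pdp`, optional `ice`
#'   (samples x grid), `n_background`.
#' @export
pdp_ice <- function(predict_fn, X, feature, grid_size = 50L,
                    with_ice = TRUE) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("X must be non-empty")
  v <- X[, feature]
  grid <- if (diff(range(v)) == 0) v[1L] else
    seq(min(v), max(v), length.out = grid_size)
  ice <- matrix(NA_real_, nrow(X), length(grid))
  for (gi in seq_along(grid)) {
    Xg <- X
    Xg[, feature] <- grid[gi]
    ice[, gi] <- predict_fn(Xg)
  }
  structure(list(feature = feature, grid = grid, pdp = colMeans(ice),
                 ice = if (with_ice) ice, n_background = nrow(X)),
            class = "pdp_curve")
}

#' @export
print.pdp_curve <- function(x, ...) {
  cat("<pdp_curve> ", x$feature, ": ", length(x$grid), " grid points in [",
      format(min(x$grid)), ", ", format(max(x$grid)), "], pdp range [",
      format(min(x$pdp)), ", ", format(max(x$pdp)), "]\n", sep = "")
  invisible(x)
}

#' Two-way partial-dependence surface
#'
#' @param predict_fn Prediction function over a feature matrix.
#' @param X Background feature matrix.
#' @param feature_a,feature_b The two features.
#' @param grid_size Grid points per axis (default 20).
#' @return List with `grid_a`, `grid_b` and the `surface` matrix
#'   (`length(grid_a)` x `length(grid_b)`) of mean predictions.
#' @export
two_way_pdp <- function(predict_fn, X, feature_a, feature_b,
                        grid_size = 20L) {
  X <- as.matrix(X)
  mk <- function(f) {
    v <- X[, f]
    if (diff(range(v)) == 0) v[1L] else
      seq(min(v), max(v), length.out = grid_size)
  }
  ga <- mk(feature_a); gb <- mk(feature_b)
  surface <- matrix(NA_real_, length(ga), length(gb))
  for (i in seq_along(ga)) for (j in seq_along(gb)) {
    Xg <- X
    Xg[, feature_a] <- ga[i]
    Xg[, feature_b] <- gb[j]
    surface[i, j] <- mean(predict_fn(Xg))
  }
  list(grid_a = ga, grid_b = gb, surface = surface,
       feature_a = feature_a, feature_b = feature_b)
}

#' Decision-boundary cut-off of a PDP curve
#'
#' Intersects the curve with a horizontal decision boundary and returns the
#' feature value at the first crossing encountered moving from the high-risk
#' side (linear interpolation between the bracketing grid points). With
#' `direction = "falling"` the predicted risk falls as the feature rises
#' (thickness- or symmetry-like features: the high-risk side is the low end,
#' so the scan runs left to right); `"rising"` scans from the right.
#'
#' @param pdp_curve A `pdp_curve`.
#' @param boundary_probability Decision boundary (default 0.5).
#' @param direction `"falling"` or `"rising"`.
#' @return The cut-off value with any additional crossings attached as the
#'   `other_crossings` attribute, or `NA` if the curve never crosses.
#' @export
estimate_cutoff <- function(pdp_curve, boundary_probability = 0.5,
                            direction = c("falling", "rising")) {
  direction <- match.arg(direction)
  g <- pdp_curve$grid; p <- pdp_curve$pdp
  if (any(!is.finite(p))) stop("non-finite PDP curve")
  if (length(g) < 2L) return(NA_real_)
  d <- p - boundary_probability
  cross <- which(d[-length(d)] * d[-1L] < 0 | d[-length(d)] == 0)
  if (length(cross) == 0L) {
    if (d[length(d)] == 0) cross <- length(g) - 1L else return(NA_real_)
  }
  cuts <- vapply(cross, function(i) {
    if (d[i] == 0) return(g[i])
    g[i] + (g[i + 1L] - g[i]) * (0 - d[i]) / (d[i + 1L] - d[i])
  }, 0.0)
  if (direction == "rising") cuts <- rev(cuts)
  structure(cuts[1L], other_crossings = cuts[-1L])
}
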