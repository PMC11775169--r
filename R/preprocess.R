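## Preprocessing: chained-equation imputation of artefact-masked feature
## groups, minority-interpolation oversampling, and per-model feature
## scaling. Imputation and oversampling are excluded from feature selection
## and explainability inputs; the pipeline enforces the ordering.

#' Impute missing feature cells by chained linear regressions
#'
#' Deterministic multiple-imputation-by-chained-equations style completion:
#' cells are initialised at column means, then columns are revisited in
#' increasing-missingness order, each regressed on all other columns over its
#' observed rows, until the largest absolute cell change drops below `tol` or
#' `max_iter` sweeps. Observed cells are never altered. A single completed
#' dataset is returned (the downstream classifiers consume one completed
#' matrix; pooled multiple-completion inference is out of scope).
#'
#' @param X Numeric matrix (rows = eyes, columns = features); every column
#'   needs >= 2 observed values.
#' @param max_iter Maximum sweeps (default 10).
#' @param tol Convergence threshold on the max absolute cell change
#'   (default 1e-3).
#' @return List with `completed` (matrix) and `report` (an
#'   `imputation_report`: iterations, per-iteration max deltas, imputed cell
#'   coordinates).
#' @export
mice_impute <- function(X, max_iter = 10L, tol = 1e-3) {
  X <- as.matrix(X)
  miss <- is.na(X)
  if (any(colSums(!miss) < 2L))
    stop("column ", colnames(X)[which(colSums(!miss) < 2L)[1L]],
         " has fewer than 2 observed values")
  filled <- X
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) filled[miss[, j], j] <- mu[j]
  order_j <- order(colSums(miss))
  order_j <- order_j[colSums(miss)[order_j] > 0]
  deltas <- numeric(0)
  models <- list()
  iter <- 0L
  if (length(order_j)) {
    for (iter in seq_len(max_iter)) {
      delta <- 0
      for (j in order_j) {
        obs <- !miss[, j]
        fit <- stats::lm.fit(cbind(1, filled[obs, -j, drop = FALSE]),
                             filled[obs, j])
        beta <- fit$coefficients
        beta[is.na(beta)] <- 0          # collinear predictors drop out
        pred <- cbind(1, filled[miss[, j], -j, drop = FALSE]) %*% beta
        delta <- max(delta, max(abs(pred - filled[miss[, j], j])))
        filled[miss[, j], j] <- pred
        models[[colnames(X)[j] %||% as.character(j)]] <- beta
      }
      deltas <- c(deltas, delta)
      if (delta < tol) break
    }
  }
  report <- structure(
    list(iterations = iter, deltas = deltas,
         imputed = which(miss, arr.ind = TRUE),
         n_imputed = sum(miss)),
    class = "imputation_report")
  structure(list(completed = filled, report = report, models = models,
                 columns = colnames(X)),
            class = "mice_fit")
}

#' Apply a fitted imputation to new rows
#'
#' Fills missing cells of `newX` using the final chained-regression models of
#' a [mice_impute()] fit (predictors initialised at the training column
#' means), so no statistic of the new rows leaks into the completion.
#'
#' @param fit A `mice_fit`.
#' @param newX Numeric matrix with the same columns as the training matrix.
#' @return Completed matrix.
#' @export
mice_apply <- function(fit, newX) {
  newX <- as.matrix(newX)
  stopifnot(identical(colnames(newX), fit$columns))
  miss <- is.na(newX)
  if (!any(miss)) return(newX)
  mu <- colMeans(fit$completed)
  filled <- newX
  for (j in seq_len(ncol(newX))) filled[miss[, j], j] <- mu[j]
  for (j in which(colSums(miss) > 0)) {
    beta <- fit$models[[fit$columns[j] %||% as.character(j)]]
    if (is.null(beta)) next             # column fully observed in training
    pred <- cbind(1, filled[miss[, j], -j, drop = FALSE]) %*% beta
    filled[miss[, j], j] <- pred
  }
  filled
}

#' @export
print.imputation_report <- function(x, ...) {
  cat("<imputation_report> ", x$n_imputed, " cells imputed in ",
      x$iterations, " sweep(s)\n", sep = "")
  invisible(x)
}

#' Balance classes by minority interpolation (SMOTE)
#'
#' Upsamples the minority class to the majority count: each synthetic point
#' is `x_i + lambda * (x_nn - x_i)` with `lambda ~ U(0,1)` and `x_nn` one of
#' the `k_neighbors` nearest minority neighbours of a randomly drawn minority
#' point `x_i`. Original rows are preserved verbatim.
#'
#' @param X Numeric matrix.
#' @param y Binary class labels (factor or character).
#' @param k_neighbors Neighbourhood size (default 5); the minority class must
#'   exceed it.
#' @param seed Integer seed.
#' @return List with the augmented `X`, `y`, and `synthetic` (logical flag
#'   per output row).
#' @export
smote_oversample <- function(X, y, k_neighbors = 5L, seed = 1L) {
  X <- as.matrix(X)
  y <- as.character(y)
  tab <- sort(table(y))
  if (length(tab) != 2L) stop("smote_oversample expects exactly 2 classes")
  n_new <- unname(tab[2L] - tab[1L])
  if (n_new == 0L)
    return(list(X = X, y = y, synthetic = rep(FALSE, nrow(X))))
  minority <- names(tab)[1L]
  mi <- which(y == minority)
  if (length(mi) <= k_neighbors)
    stop("minority class (", length(mi),
         ") must exceed k_neighbors (", k_neighbors, ")")
  Xm <- X[mi, , drop = FALSE]
  D <- as.matrix(stats::dist(Xm))
  diag(D) <- Inf
  nn <- t(apply(D, 1L, function(d) order(d)[seq_len(k_neighbors)]))
  synth <- with_seed(seed, {
    base_i <- sample(seq_len(nrow(Xm)), n_new, replace = TRUE)
    nb_i <- nn[cbind(base_i, sample.int(k_neighbors, n_new, replace = TRUE))]
    lambda <- stats::runif(n_new)
    Xm[base_i, , drop = FALSE] +
      lambda * (Xm[nb_i, , drop = FALSE] - Xm[base_i, , drop = FALSE])
  })
  list(X = rbind(X, synth),
       y = c(y, rep(minority, n_new)),
       synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, n_new)))
}

#' Fit-on-train feature scaling
#'
#' Scaling parameters are fitted on the training split only and applied to
#' both splits: `minmax` maps training columns onto \[0,1\] (apply-set values
#' outside the training range are not clipped), `standard` to mean 0 / sd 1,
#' `none` passes through. The model binding is min-max for KNN,
#' standardisation for SVM and none for random forests.
#'
#' @param X_train,X_apply Numeric matrices with identical columns (`X_apply`
#'   may be `NULL`).
#' @param method `"minmax"`, `"standard"` or `"none"`.
#' @return List with `train`, `apply` and the fitted `params`.
#' @export
scale_features <- function(X_train, X_apply = NULL,
                           method = c("minmax", "standard", "none")) {
  method <- match.arg(method)
  X_train <- as.matrix(X_train)
  if (method == "none") {
    return(list(train = X_train, apply = X_apply,
                params = list(method = "none")))
  }
  if (method == "minmax") {
    lo <- apply(X_train, 2L, min); hi <- apply(X_train, 2L, max)
    rng <- hi - lo
    flat <- rng == 0
    rng[flat] <- 1                       # zero-range column maps to 0
    tr <- function(M) sweep(sweep(as.matrix(M), 2L, lo), 2L, rng, "/")
    params <- list(method = "minmax", lo = lo, hi = hi, flat = flat)
  } else {
    mu <- colMeans(X_train)
    sdev <- apply(X_train, 2L, stats::sd)
    flat <- sdev == 0
    sdev[flat] <- 1
    tr <- function(M) sweep(sweep(as.matrix(M), 2L, mu), 2L, sdev, "/")
    params <- list(method = "standard", mu = mu, sd = sdev, flat = flat)
  }
  list(train = tr(X_train),
       apply = if (!is.null(X_apply)) tr(X_apply),
       params = params)
}
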