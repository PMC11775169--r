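## Tuned KNN / RBF-SVM / random-forest staging classifiers with patient-level
## cross-validation and the sensitivity/specificity/accuracy/AUC/F1 battery.
## Probability scores: RF uses the tree vote fraction, SVM Platt-type
## calibration fitted on the training folds, KNN the neighbour vote fraction.

#' Classifier specification
#'
#' @param kind `"KNN"`, `"SVM_RBF"` or `"RF"`.
#' @param grid Hyperparameter grid (data.frame, one row per candidate),
#'   ordered simple to complex; defaults: k = 1..40 for KNN; C in
#'   \{0.1, 1, 10, 100\} x gamma in \{0.001, 0.01, 0.1\} for SVM;
#'   100 trees x max depth \{3, 6, unlimited\} for RF.
#' @param seed Integer seed.
#' @return A `model_spec`.
#' @export
model_spec <- function(kind = c("KNN", "SVM_RBF", "RF"), grid = NULL,
                       seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(grid)) {
    grid <- switch(kind,
      KNN = data.frame(k = 1:40),
      SVM_RBF = expand.grid(gamma = c(0.001, 0.01, 0.1),
                            C = c(0.1, 1, 10, 100))[, c("C", "gamma")],
      RF = data.frame(ntree = 100, max_depth = c(3, 6, Inf)))
  }
  if (kind == "KNN" && (any(grid$k < 1) || any(grid$k > 40)))
    stop("KNN grid must keep k within [1, 40]")
  scaling <- switch(kind, KNN = "minmax", SVM_RBF = "standard", RF = "none")
  structure(list(kind = kind, grid = grid, scaling = scaling,
                 seed = as.integer(seed)),
            class = "model_spec")
}

#' Fit a classifier at fixed hyperparameters
#'
#' Fits the model kind of `spec` on an (already scaled, per the spec's
#' binding) training matrix with a given hyperparameter row — typically the
#' output of [tune()]. KNN stores its training set and classifies lazily.
#'
#' @param spec A [model_spec()].
#' @param hp One-row data.frame of hyperparameters (a row of `spec$grid`).
#' @param X Training feature matrix.
#' @param y Binary labels (second factor level = positive class).
#' @return A `glocr_model` for [predict_prob()].
#' @export
fit_model <- function(spec, hp, X, y) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  stopifnot(nlevels(y) == 2L)
  model <- switch(spec$kind,
    KNN = list(train = X, y = y, k = hp$k),
    SVM_RBF = e1071::svm(x = X, y = y, kernel = "radial",
                         cost = hp$C, gamma = hp$gamma,
                         probability = TRUE, scale = FALSE),
    RF = {
      ## depth d ~ 2^d terminal nodes; cap at n so small folds stay valid
      maxnodes <- if (is.finite(hp$max_depth))
        min(2^hp$max_depth, nrow(X)) else NULL
      randomForest::randomForest(X, y, ntree = hp$ntree,
                                 maxnodes = maxnodes)
    })
  structure(list(kind = spec$kind, model = model, levels = levels(y),
                 hp = hp, features = colnames(X)),
            class = "glocr_model")
}

#' Positive-class probability of a fitted classifier
#'
#' @param object A fitted `glocr_model`.
#' @param newX Matrix of rows to score.
#' @param positive Class treated as positive (default: second factor level).
#' @param ... unused.
#' @return Numeric vector of probabilities.
#' @export
predict_prob <- function(object, newX, positive = NULL, ...) {
  newX <- as.matrix(newX)
  positive <- positive %||% object$levels[2L]
  switch(object$kind,
    KNN = {
      pr <- class::knn(object$model$train, newX, object$model$y,
                       k = object$model$k, prob = TRUE)
      win <- attr(pr, "prob")
      ifelse(as.character(pr) == positive, win, 1 - win)
    },
    SVM_RBF = {
      p <- attr(stats::predict(object$model, newX, probability = TRUE),
                "probabilities")
      p[, positive]
    },
    RF = stats::predict(object$model, newX, type = "prob")[, positive])
}

#' Grid-search hyperparameter tuning
#'
#' Exhaustive search over the spec's grid maximising mean cross-validated
#' accuracy on stratified row folds of the (already scaled) training data;
#' ties break toward the simpler model, i.e. the earlier grid row.
#'
#' @param spec A [model_spec()].
#' @param X Scaled training matrix.
#' @param y Binary labels.
#' @param folds Inner fold count (default 3).
#' @param seed Integer seed.
#' @return List with `hp` (chosen row), `accuracy`, and the full
#'   `grid_accuracy` vector.
#' @export
tune <- function(spec, X, y, folds = 3L, seed = 1L) {
  if (nrow(spec$grid) == 0L) stop("empty hyperparameter grid")
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  fold_id <- with_seed(seed, stratified_row_folds(y, folds))
  accs <- vapply(seq_len(nrow(spec$grid)), function(gi) {
    hp <- spec$grid[gi, , drop = FALSE]
    correct <- 0L
    for (fd in seq_len(folds)) {
      tr <- fold_id != fd
      if (length(unique(y[tr])) < 2L) next
      m <- with_seed(seed + 1000L * gi + fd,
                     fit_model(spec, hp, X[tr, , drop = FALSE], y[tr]))
      pr <- with_seed(seed + 1000L * gi + fd,
                      predict_prob(m, X[!tr, , drop = FALSE]))
      pred <- ifelse(pr > 0.5, levels(y)[2L], levels(y)[1L])
      correct <- correct + sum(pred == y[!tr])
    }
    correct / length(y)
  }, 0.0)
  best <- which.max(accs)               # first max = simplest
  list(hp = spec$grid[best, , drop = FALSE], accuracy = accs[best],
       grid_accuracy = accs)
}

#' Classification metrics of probability scores
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy, F1
#' (harmonic mean of precision and sensitivity at the threshold) and AUC by
#' the trapezoid rule over the empirical ROC (tie-corrected rank form).
#'
#' @param scores Positive-class probabilities.
#' @param labels Logical (or coercible) truth, `TRUE` = positive.
#' @param threshold Classification threshold (default 0.5).
#' @return Named vector `sensitivity, specificity, accuracy, auc, f1`.
#'   Single-class inputs yield `NA` for the undefined entries, with a
#'   warning.
#' @export
evaluate <- function(scores, labels, threshold = 0.5) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  pos <- sum(labels); neg <- sum(!labels)
  if (pos == 0L || neg == 0L)
    warning("single-class labels: some metrics undefined")
  pred <- scores > threshold
  tp <- sum(pred & labels); fn <- sum(!pred & labels)
  tn <- sum(!pred & !labels); fp <- sum(pred & !labels)
  sens <- if (pos) tp / (tp + fn) else NA_real_
  spec <- if (neg) tn / (tn + fp) else NA_real_
  acc <- (tp + tn) / length(labels)
  prec <- if (tp + fp) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sens) && (prec + sens) > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  auc <- if (pos && neg) {
    r <- rank(scores)                   # midranks = trapezoid under ties
    (sum(r[labels]) - pos * (pos + 1) / 2) / (pos * neg)
  } else NA_real_
  c(sensitivity = sens, specificity = spec, accuracy = acc,
    auc = auc, f1 = f1)
}

binary_problems <- function(y, scheme) {
  y <- as.character(y)
  classes <- unique(y)
  switch(scheme,
    binary = {
      stopifnot(length(classes) == 2L)
      pos <- setdiff(classes, "NORMAL")
      if (length(pos) != 1L) pos <- classes[2L]
      list(list(name = paste0(pos, "_vs_", setdiff(classes, pos)),
                rows = seq_along(y), positive = pos))
    },
    OvR = lapply(classes, function(lv)
      list(name = paste0(lv, "_vs_rest"), rows = seq_along(y),
           positive = lv)),
    OvO = {
      stopifnot("NORMAL" %in% classes)
      stages <- setdiff(classes, "NORMAL")
      lapply(stages, function(lv)
        list(name = paste0(lv, "_vs_NORMAL"),
             rows = which(y %in% c(lv, "NORMAL")), positive = lv))
    },
    stop("unknown scheme: ", scheme))
}

#' Patient-level cross-validated evaluation
#'
#' Evaluates a classifier specification over patient-level folds, with
#' imputation, oversampling and scaling all fitted inside each training fold
#' (no leakage), under three schemes: `binary` (glaucoma vs normal), `OvR`
#' (each class against all others) and `OvO` (each glaucoma stage against
#' normal only). `repeats > 1` reshuffles the folds (five-times five-fold
#' style). Aggregates report mean, sd, standard error `sd/sqrt(n_folds)` and
#' the 95% CI `mean +/- 1.96 SE` clipped to \[0, 1\].
#'
#' @param spec A [model_spec()].
#' @param X Feature matrix (may contain NA if `impute = TRUE`).
#' @param y Stage labels per row.
#' @param patient_ids Patient identifier per row (both eyes of a patient
#'   always share a fold).
#' @param k Fold count (default 5).
#' @param scheme `"binary"`, `"OvR"` or `"OvO"`.
#' @param repeats Number of reshuffled repetitions (default 1).
#' @param smote Oversample the minority class inside training folds.
#' @param impute Impute missing cells by [mice_impute()] inside training
#'   folds (otherwise complete-case rows only).
#' @param tune_folds Inner folds for hyperparameter tuning.
#' @param seed Integer seed governing folds, oversampling and model fits.
#' @return A named list of `metric_report` objects, one per binary problem.
#' @export
cross_validate <- function(spec, X, y, patient_ids, k = 5L,
                           scheme = c("binary", "OvR", "OvO"),
                           repeats = 1L, smote = TRUE, impute = TRUE,
                           tune_folds = 3L, seed = 1L) {
  scheme <- match.arg(scheme)
  X <- as.matrix(X)
  y <- as.character(y)
  stopifnot(nrow(X) == length(y), length(patient_ids) == length(y))
  problems <- binary_problems(y, scheme)
  reports <- list()
  for (pb in problems) {
    rows <- pb$rows
    Xp <- X[rows, , drop = FALSE]
    yp <- y[rows]
    pid <- patient_ids[rows]
    ybin <- factor(ifelse(yp == pb$positive, pb$positive, "OTHER"),
                   levels = c("OTHER", pb$positive))
    per_fold <- list()
    hps <- list()
    for (rep_i in seq_len(repeats)) {
      fold_id <- patient_folds_for(pid, yp, k, seed + 7000L * (rep_i - 1L))
      for (fd in seq_len(k)) {
        tr <- which(fold_id != fd); te <- which(fold_id == fd)
        if (length(unique(ybin[tr])) < 2L || length(te) == 0L) next
        Xtr <- Xp[tr, , drop = FALSE]; Xte <- Xp[te, , drop = FALSE]
        ytr <- ybin[tr]; yte <- ybin[te]
        if (anyNA(Xtr) || anyNA(Xte)) {
          if (impute) {
            fit <- mice_impute(Xtr)
            Xtr <- fit$completed
            Xte <- mice_apply(fit, Xte)
          } else {
            keep_tr <- stats::complete.cases(Xtr)
            keep_te <- stats::complete.cases(Xte)
            Xtr <- Xtr[keep_tr, , drop = FALSE]; ytr <- ytr[keep_tr]
            Xte <- Xte[keep_te, , drop = FALSE]; yte <- yte[keep_te]
          }
        }
        if (smote && length(unique(ytr)) == 2L &&
            length(table(ytr)) == 2L && diff(range(table(ytr))) > 0 &&
            min(table(ytr)) > 5L) {
          sm <- smote_oversample(Xtr, as.character(ytr), seed = seed + fd)
          Xtr <- sm$X
          ytr <- factor(sm$y, levels = levels(ybin))
        }
        sc <- scale_features(Xtr, Xte, method = spec$scaling)
        tuned <- tune(spec, sc$train, ytr, folds = tune_folds,
                      seed = seed + 100L * fd)
        model <- with_seed(seed + 100L * fd,
                           fit_model(spec, tuned$hp, sc$train, ytr))
        pr <- with_seed(seed + 100L * fd,
                        predict_prob(model, sc$apply,
                                     positive = pb$positive))
        met <- evaluate(pr, yte == pb$positive)
        per_fold[[length(per_fold) + 1L]] <-
          data.frame(repeat_i = rep_i, fold = fd, t(met))
        hps[[length(hps) + 1L]] <- tuned$hp
      }
    }
    pf <- do.call(rbind, per_fold)
    reports[[pb$name]] <- new_metric_report(pf, scheme, pb$name, hps)
  }
  reports
}

## build patient-level folds from per-row patient ids + labels
patient_folds_for <- function(patient_ids, labels, k, seed) {
  pats <- unique(patient_ids)
  plab <- labels[match(pats, patient_ids)]
  folds <- integer(length(pats))
  names(folds) <- pats
  with_seed(seed, {
    nxt <- 0L
    for (lv in unique(plab)) {
      idx <- which(plab == lv)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- ((nxt + seq_along(idx) - 1L) %% k) + 1L
      nxt <- (nxt + length(idx)) %% k
    }
  })
  unname(folds[patient_ids])
}

new_metric_report <- function(per_fold, scheme, problem, hps) {
  metrics <- c("sensitivity", "specificity", "accuracy", "auc", "f1")
  agg <- do.call(rbind, lapply(metrics, function(m) {
    v <- per_fold[[m]]
    v <- v[!is.na(v)]
    mu <- mean(v); sdv <- stats::sd(v); se <- sdv / sqrt(length(v))
    data.frame(metric = m, mean = mu, sd = sdv, se = se,
               ci_lo = max(0, mu - 1.96 * se),
               ci_hi = min(1, mu + 1.96 * se))
  }))
  structure(list(per_fold = per_fold, aggregate = agg, scheme = scheme,
                 problem = problem, hyperparameters = hps),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 3, ...) {
  cat("<metric_report> ", x$problem, " (", x$scheme, "), ",
      nrow(x$per_fold), " fold evaluations\n", sep = "")
  agg <- x$aggregate
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-12s %.*f +/- %.*f (95%% CI %.*f-%.*f)\n",
                agg$metric[i], digits, agg$mean[i], digits, agg$sd[i],
                digits, agg$ci_lo[i], digits, agg$ci_hi[i]))
  invisible(x)
}
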