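## Filter-based feature selection: one-way ANOVA F scores, Pearson
## correlation pruning at |r| > 0.98, and a wrapper-validated K-best curve
## with the binding F >= 30 cut-off.

#' One-way ANOVA F score per feature
#'
#' `F = (SSB/(g-1)) / (SSW/(n-g))` of each column against the class labels,
#' with missing cells excluded per feature. A feature with distinct group
#' means but zero within-group variance scores `Inf` (sorts first).
#'
#' @param X Numeric matrix (rows = samples).
#' @param y Class labels (>= 2 classes, each with >= 2 samples).
#' @return Named numeric vector of F scores (>= 0).
#' @export
anova_f <- function(X, y) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (length(unique(y)) < 2L) stop("need at least 2 classes")
  apply(X, 2L, function(x) {
    ok <- !is.na(x)
    xi <- x[ok]; yi <- y[ok]
    g <- unique(yi)
    if (length(g) < 2L || length(xi) - length(g) < 1L) return(NA_real_)
    grand <- mean(xi)
    ssb <- 0; ssw <- 0
    for (lv in g) {
      v <- xi[yi == lv]
      ssb <- ssb + length(v) * (mean(v) - grand)^2
      ssw <- ssw + sum((v - mean(v))^2)
    }
    if (ssw == 0) return(if (ssb > 0) Inf else 0)
    (ssb / (length(g) - 1)) / (ssw / (length(xi) - length(g)))
  })
}

#' Prune highly correlated features
#'
#' Builds the graph whose edges are feature pairs with `|r| >` the threshold
#' (Pearson, pairwise-complete observations) and keeps, within each connected
#' component, only the feature with the highest F score (ties broken by
#' column order). Constant columns have undefined correlation and are
#' retained, flagged.
#'
#' @param X Numeric matrix.
#' @param f_scores Named F scores covering all columns (e.g. [anova_f()]).
#' @param r_threshold Correlation threshold (default 0.98).
#' @return List with `retained` (character), `pruned` (data.frame of kept /
#'   dropped / r), and `flagged_constant`.
#' @export
correlation_prune <- function(X, f_scores, r_threshold = 0.98) {
  X <- as.matrix(X)
  nms <- colnames(X)
  stopifnot(!is.null(nms), all(nms %in% names(f_scores)))
  f <- f_scores[nms]
  suppressWarnings(R <- stats::cor(X, use = "pairwise.complete.obs"))
  constant <- apply(X, 2L, function(x) stats::sd(x, na.rm = TRUE) == 0)
  R[is.na(R)] <- 0
  adj <- abs(R) > r_threshold
  diag(adj) <- FALSE
  ## connected components by breadth-first search
  comp <- rep(NA_integer_, ncol(X))
  cid <- 0L
  for (s in seq_len(ncol(X))) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  keep <- logical(ncol(X))
  prune_log <- list()
  for (cc in unique(comp)) {
    members <- which(comp == cc)
    fi <- f[members]
    fi[is.na(fi)] <- -Inf
    best <- members[which.max(fi)]      # which.max: first max = column order
    keep[best] <- TRUE
    dropped <- setdiff(members, best)
    if (length(dropped))
      prune_log[[length(prune_log) + 1L]] <- data.frame(
        kept = nms[best], dropped = nms[dropped],
        r = R[best, dropped], row.names = NULL)
  }
  list(retained = nms[keep],
       pruned = if (length(prune_log)) do.call(rbind, prune_log)
                else data.frame(kept = character(0), dropped = character(0),
                                r = numeric(0)),
       flagged_constant = nms[constant])
}

#' Wrapper-validated K-best feature selection with an F cut-off
#'
#' Ranks the retained features by F score (descending), records the
#' cross-validated accuracy of a random-forest wrapper for increasing
#' prefixes K (an advisory curve), and selects every retained feature whose F
#' score meets the cut-off — the binding rule. The cut-off can alternatively
#' be given as a fraction of the top F score via `f_cutoff_frac`.
#'
#' @param X Numeric matrix (no missing cells among `retained` columns, or
#'   rows with missing cells are dropped for the wrapper).
#' @param y Class labels.
#' @param retained Character vector of candidate features (e.g. from
#'   [correlation_prune()]).
#' @param f_scores Named F scores.
#' @param folds Wrapper CV folds (default 5).
#' @param f_cutoff Absolute F cut-off (default 30).
#' @param f_cutoff_frac Optional fraction of the maximum F, overriding
#'   `f_cutoff` (e.g. 0.06).
#' @param seed Integer seed for fold shuffling and the forest.
#' @param curve_points Maximum number of prefix sizes evaluated for the
#'   advisory curve.
#' @return A `selection_result`: ranked names, selected names, F scores, the
#'   prune log is not repeated here, and the accuracy-vs-K curve.
#' @export
wrapped_select <- function(X, y, retained, f_scores, folds = 5L,
                           f_cutoff = 30, f_cutoff_frac = NULL, seed = 1L,
                           curve_points = 20L) {
  stopifnot(length(retained) > 0L)
  f <- f_scores[retained]
  ord <- order(-f)                       # ties: earlier catalog order first
  ranked <- retained[ord]
  f_ranked <- f[ord]
  if (!is.null(f_cutoff_frac)) f_cutoff <- f_cutoff_frac * max(f_ranked)
  selected <- ranked[f_ranked >= f_cutoff]
  if (length(selected) == 0L)
    stop("no feature reaches the F cut-off of ", format(f_cutoff))
  ## advisory wrapper curve
  Xr <- as.matrix(X)[, ranked, drop = FALSE]
  cc <- stats::complete.cases(Xr)
  Xr <- Xr[cc, , drop = FALSE]
  yr <- factor(as.character(y)[cc])
  ks <- unique(round(seq(1, length(ranked),
                         length.out = min(curve_points, length(ranked)))))
  fold_id <- with_seed(seed, stratified_row_folds(yr, folds))
  acc <- vapply(ks, function(k) {
    correct <- 0L
    for (fd in seq_len(folds)) {
      tr <- fold_id != fd
      rf <- with_seed(seed + fd, randomForest::randomForest(
        Xr[tr, seq_len(k), drop = FALSE], yr[tr], ntree = 100))
      pred <- stats::predict(rf, Xr[!tr, seq_len(k), drop = FALSE])
      correct <- correct + sum(pred == yr[!tr])
    }
    correct / length(yr)
  }, 0.0)
  structure(list(ranked = ranked, f_scores = f_ranked,
                 selected = selected, f_cutoff = f_cutoff,
                 curve = data.frame(k = ks, accuracy = acc)),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> ", length(x$selected), " of ", length(x$ranked),
      " features selected (F >= ", format(x$f_cutoff), ")\n", sep = "")
  cat("  top: ", paste(utils::head(x$ranked, 5L), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

## Stratified row-level folds (used by wrappers and tuning; patient-level
## folds for the outer evaluation come from patient_level_folds()).
stratified_row_folds <- function(y, k) {
  y <- as.character(y)
  fold <- integer(length(y))
  nxt <- 0L
  for (lv in unique(y)) {
    idx <- which(y == lv)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((nxt + seq_along(idx) - 1L) %% k) + 1L
    nxt <- (nxt + length(idx)) %% k
  }
  fold
}
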