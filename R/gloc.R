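## The glaucoma likelihood calculator (GLOC): per-feature PDP lookup curves
## and decision-boundary cut-offs grouped into major criteria (RNFL symmetry,
## inferior and superior quadrant thickness) and minor criteria (four GC-IPL
## sectors, average RNFL and average GC-IPL), combined into a likelihood
## score, a five-bin verbal scale and a binary call at the 0.25 threshold.

GLOC_MAJOR <- c("rnfl_symmetry", "rnfl_quad_i", "rnfl_quad_s")
GLOC_MINOR <- c("gcipl_inferotemporal", "gcipl_superotemporal",
                "gcipl_inferior", "gcipl_superior",
                "rnfl_average", "gcipl_average")

DEFAULT_BIN_EDGES <- c(0, 0.10, 0.25, 0.50, 0.75, 1)
BIN_LABELS <- c("very low", "low", "intermediate", "high", "very high")

#' Build a glaucoma likelihood calculator from a fitted model
#'
#' For each of the nine explainable spatial features, stores its one-way
#' partial-dependence lookup curve ([pdp_ice()]) and the decision-boundary
#' cut-off ([estimate_cutoff()], falling-risk direction: lower thickness or
#' symmetry means higher risk). A feature whose curve never crosses the
#' boundary falls back to the curve midpoint, flagged.
#'
#' @param model_predict Function mapping a 9-column feature matrix to
#'   glaucoma probabilities.
#' @param X_reference Reference (training) matrix containing all nine
#'   features; PDPs are averaged over it.
#' @param major,minor Feature-name groups (defaults: the three SHAP-top RNFL
#'   features; the six supporting GC-IPL/average features).
#' @param boundary Decision-boundary probability (default 0.5).
#' @param threshold Binary likelihood threshold (default 0.25).
#' @param bin_edges Five-bin verbal-scale edges.
#' @param grid_size PDP grid resolution.
#' @param quorum `"all"` (default) or an integer: how many criteria of a
#'   group must be fulfilled for the group to decide.
#' @return A `gloc` specification.
#' @export
build_gloc <- function(model_predict, X_reference, major = GLOC_MAJOR,
                       minor = GLOC_MINOR, boundary = 0.5,
                       threshold = 0.25, bin_edges = DEFAULT_BIN_EDGES,
                       grid_size = 50L, quorum = "all") {
  X_reference <- as.matrix(X_reference)
  feats <- c(major, minor)
  if (length(feats) != 9L || anyDuplicated(feats))
    stop("major and minor sets must be disjoint and total 9 features")
  missing_f <- setdiff(feats, colnames(X_reference))
  if (length(missing_f))
    stop("X_reference lacks feature(s): ", paste(missing_f, collapse = ", "))
  stopifnot(threshold > 0, threshold < 1)
  entries <- lapply(feats, function(f) {
    curve <- pdp_ice(model_predict, X_reference, f, grid_size = grid_size,
                     with_ice = FALSE)
    ## the stored lookup is the monotone-decreasing (isotonic) projection of
    ## the PDP: the risk direction is declared a priori, and projecting out
    ## estimation wiggle keeps the calculator monotone in each input and
    ## gives a unique boundary crossing
    if (length(curve$grid) > 1L)
      curve$pdp <- -stats::isoreg(curve$grid, -curve$pdp)$yf
    cut <- estimate_cutoff(curve, boundary, direction = "falling")
    fallback <- is.na(cut)
    if (fallback) cut <- mean(range(curve$grid))
    list(feature = f, grid = curve$grid, prob = curve$pdp,
         cutoff = unname(cut), direction = "falling",
         cutoff_fallback = fallback)
  })
  names(entries) <- feats
  structure(list(entries = entries, major = major, minor = minor,
                 boundary = boundary, threshold = threshold,
                 bin_edges = bin_edges, quorum = quorum),
            class = "gloc")
}

gloc_lookup <- function(entry, value) {
  ## linear interpolation on the PDP lookup curve, clamped at the grid ends
  if (length(entry$grid) == 1L) return(entry$prob[1L])
  stats::approx(entry$grid, entry$prob, xout = value, rule = 2)$y
}

#' Verbal likelihood category
#'
#' Left-closed bins over the default edges 0.10 / 0.25 / 0.50 / 0.75: very
#' low, low, intermediate, high, very high.
#'
#' @param likelihood Value in \[0, 1\].
#' @param bin_edges Bin edges (length 6, increasing, spanning \[0, 1\]).
#' @return Category string.
#' @export
likelihood_bins <- function(likelihood, bin_edges = DEFAULT_BIN_EDGES) {
  if (!is.finite(likelihood) || likelihood < 0 || likelihood > 1)
    stop("likelihood must lie in [0, 1]")
  idx <- findInterval(likelihood, bin_edges, rightmost.closed = TRUE)
  BIN_LABELS[idx]
}

#' Score one eye with the likelihood calculator
#'
#' Each feature value is converted to a glaucoma probability by linear
#' interpolation on its PDP lookup curve; a criterion is fulfilled when the
#' value lies on the glaucomatous (low) side of its cut-off. If all (or the
#' configured quorum of) major criteria are fulfilled, the likelihood is the
#' mean of the major probabilities; failing that, if all minor criteria are
#' fulfilled, the mean of the minor probabilities; otherwise the mean of all
#' nine. Missing inputs contribute their cut-off (boundary-neutral)
#' probability and flag the result as partial.
#'
#' @param spec A `gloc` from [build_gloc()].
#' @param inputs Named vector/list of the nine feature values.
#' @return A `gloc_result`: `likelihood`, `path` (major / minor / combined),
#'   `category`, `binary_call`, per-feature probabilities and fulfilment.
#' @export
gloc_score <- function(spec, inputs) {
  inputs <- unlist(inputs)
  feats <- names(spec$entries)
  vals <- stats::setNames(rep(NA_real_, 9L), feats)
  vals[intersect(feats, names(inputs))] <-
    inputs[intersect(feats, names(inputs))]
  partial <- any(!is.finite(vals))
  prob <- numeric(9L); fulfilled <- logical(9L)
  names(prob) <- names(fulfilled) <- feats
  for (f in feats) {
    e <- spec$entries[[f]]
    if (is.finite(vals[f])) {
      prob[f] <- gloc_lookup(e, vals[f])
      fulfilled[f] <- vals[f] <= e$cutoff    # glaucomatous = low side
    } else {
      prob[f] <- gloc_lookup(e, e$cutoff)    # neutral at the boundary
      fulfilled[f] <- FALSE
    }
  }
  need <- function(group) if (identical(spec$quorum, "all"))
    length(group) else min(spec$quorum, length(group))
  if (sum(fulfilled[spec$major]) >= need(spec$major)) {
    likelihood <- mean(prob[spec$major]); path <- "major"
  } else if (sum(fulfilled[spec$minor]) >= need(spec$minor)) {
    likelihood <- mean(prob[spec$minor]); path <- "minor"
  } else {
    likelihood <- mean(prob); path <- "combined"
  }
  structure(list(likelihood = likelihood, path = path,
                 probabilities = prob, fulfilled = fulfilled,
                 category = likelihood_bins(likelihood, spec$bin_edges),
                 binary_call = likelihood > spec$threshold,
                 partial_input = partial),
            class = "gloc_result")
}

#' @export
print.gloc <- function(x, ...) {
  cat("<gloc> 9-feature likelihood calculator, threshold ",
      x$threshold, "\n", sep = "")
  for (f in names(x$entries)) {
    e <- x$entries[[f]]
    cat(sprintf("  %-22s cut-off %8.2f%s [%s]\n", f, e$cutoff,
                if (e$cutoff_fallback) " (fallback)" else "",
                if (f %in% x$major) "major" else "minor"))
  }
  invisible(x)
}

#' @export
print.gloc_result <- function(x, ...) {
  cat(sprintf("<gloc_result> likelihood %.1f%% (%s) via %s criteria -> %s%s\n",
              100 * x$likelihood, x$category, x$path,
              if (x$binary_call) "glaucoma" else "normal",
              if (x$partial_input) " [partial input]" else ""))
  invisible(x)
}

#' Score a cohort-level predictor convenience method
#'
#' @param object A `gloc`.
#' @param newdata Matrix or data.frame of feature values (columns named by
#'   the nine features), one row per eye.
#' @param ... unused.
#' @return Numeric vector of likelihoods.
#' @export
predict.gloc <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  vapply(seq_len(nrow(newdata)), function(r)
    gloc_score(object, newdata[r, ])$likelihood, 0.0)
}

#' Validate a likelihood calculator against a labelled cohort
#'
#' Computes the (mean deviation, likelihood) scatter, the operating point
#' (sensitivity / specificity / accuracy treating every glaucomatous stage
#' as positive) at the spec's threshold, the Spearman rank correlation
#' between MD and likelihood, and optionally the Pearson correlation between
#' the likelihood and a reference model's predicted probabilities.
#'
#' @param spec A `gloc`.
#' @param features Matrix of the nine feature values per eye.
#' @param labels Stage labels per eye.
#' @param md_db Mean deviation per eye (dB).
#' @param reference_probs Optional reference-model probabilities.
#' @param threshold Operating threshold (default: the spec's).
#' @return List with `scatter` (md, likelihood, label), `operating_point`,
#'   `spearman_md`, and `reference_correlation` when supplied.
#' @export
validate_gloc <- function(spec, features, labels, md_db,
                          reference_probs = NULL, threshold = NULL) {
  threshold <- threshold %||% spec$threshold
  labels <- as.character(labels)
  if (!length(labels) || all(is.na(labels))) stop("no labelled rows")
  lik <- predict(spec, features)
  pos <- labels != "NORMAL"
  pred <- lik > threshold
  op <- c(sensitivity = sum(pred & pos) / sum(pos),
          specificity = sum(!pred & !pos) / sum(!pos),
          accuracy = mean(pred == pos))
  out <- list(scatter = data.frame(md_db = md_db, likelihood = lik,
                                   label = labels),
              operating_point = op,
              threshold = threshold,
              spearman_md = suppressWarnings(
                stats::cor(md_db, lik, method = "spearman",
                           use = "complete.obs")))
  if (!is.null(reference_probs))
    out$reference_correlation <- stats::cor(lik, reference_probs)
  out
}

#' Serialise / load a likelihood calculator as JSON
#'
#' @param spec A `gloc`.
#' @param path JSON file path.
#' @export
write_gloc <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_gloc
#' @export
read_gloc <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$entries <- lapply(obj$entries, function(e) {
    e$grid <- as.numeric(e$grid); e$prob <- as.numeric(e$prob); e
  })
  obj$bin_edges <- as.numeric(obj$bin_edges)
  structure(obj, class = "gloc")
}
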