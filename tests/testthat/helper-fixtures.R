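## Shared fixtures, built in code. The small cohort is cached per session so
## independent test files do not pay for regeneration.

.fixture_env <- new.env(parent = emptyenv())

small_spec <- function(seed = 421L) {
  synth_spec(counts = c(NORMAL = 30, EARLY = 14, MODERATE = 12,
                        ADVANCED_MD = 12, ADVANCED_CFD = 6),
             seed = seed)
}

small_cohort <- function() {
  if (is.null(.fixture_env$cohort))
    .fixture_env$cohort <- generate_cohort(small_spec())
  .fixture_env$cohort
}

small_features <- function() {
  if (is.null(.fixture_env$features))
    .fixture_env$features <- extract_features(small_cohort())
  .fixture_env$features
}

## deterministic pseudo-random profile helper
random_profile <- function(seed = 1L, baseline = 80, sd = 10) {
  set.seed(seed)
  pmax(0, baseline + rnorm(256, 0, sd))
}

## linear probability model over named feature columns, clipped to [0, 1]
linear_prob_fn <- function(weights, intercept = 0) {
  function(M) {
    M <- as.matrix(M)
    pmin(1, pmax(0, intercept +
                   as.vector(M[, names(weights), drop = FALSE] %*% weights)))
  }
}

## synthetic 9-feature likelihood-calculator spec with identical decreasing
## lookup curves prob(v) = 1 - v/100 on [0, 100] and cut-off 50
synthetic_gloc <- function(cutoff = 50, threshold = 0.25) {
  feats <- c(glocr:::GLOC_MAJOR, glocr:::GLOC_MINOR)
  entries <- lapply(feats, function(f)
    list(feature = f, grid = seq(0, 100), prob = seq(1, 0, by = -0.01),
         cutoff = cutoff, direction = "falling", cutoff_fallback = FALSE))
  names(entries) <- feats
  structure(list(entries = entries, major = glocr:::GLOC_MAJOR,
                 minor = glocr:::GLOC_MINOR, boundary = 0.5,
                 threshold = threshold,
                 bin_edges = c(0, 0.10, 0.25, 0.50, 0.75, 1),
                 quorum = "all"),
            class = "gloc")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
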