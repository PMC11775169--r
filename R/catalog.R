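## Default feature catalog: 67 spatial + 64 frequency = 131 named features.
## The composition is a documented reconstruction from the device analyses
## (RNFL / GC-IPL / macular) that totals exactly 67 + 64; it is versioned and
## swappable via JSON so an alternative enumeration can be dropped in.

CATALOG_VERSION <- "glocr-catalog-1"

spatial_feature_names <- function() {
  stats5 <- c("mean", "median", "sd", "skew", "kurt")
  segs <- c("whole", "t", "s", "n", "i")
  c(rnfl_summary_cols(),                                   # 18
    as.vector(t(outer(segs, stats5,
                      function(a, b) paste0("tsnit_", a, "_", b)))),  # 25
    "tsnit_entropy", "tsnit_fisher", "tsnit_snr",          # 3
    gcipl_cols(),                                          # 8
    mac_cols())                                            # 13
}

frequency_feature_names <- function() {
  segs <- c("whole", "t", "s", "n", "i")
  methods <- c("pgram", "welch")
  summaries <- c("total", "peak", "peakfreq", "mean", "sd")
  psd <- unlist(lapply(segs, function(sg)
    unlist(lapply(methods, function(m)
      paste("psd", sg, m, summaries, sep = "_")))))        # 50
  dwt <- as.vector(t(outer(1:4, c("total", "peak"),
                           function(l, s) paste0("dwt_l", l, "_", s))))  # 8
  c(psd, dwt, paste0("hslope_", segs), "spectral_entropy") # 5 + 1
}

#' The default 131-feature catalog
#'
#' Enumerates the 67 spatial-domain and 64 frequency-domain features the
#' extraction stages emit, each tagged with its domain and source parameter
#' group (RNFL, GC-IPL or macular).
#'
#' @return data.frame with columns `name`, `domain` (`"spatial"` /
#'   `"frequency"`) and `group` (`"RNFL"`, `"GCIPL"`, `"MAC"`), carrying a
#'   `version` attribute.
#' @examples
#' table(default_catalog()$domain)
#' @export
default_catalog <- function() {
  sn <- spatial_feature_names()
  fn <- frequency_feature_names()
  grp <- function(nms) ifelse(grepl("^gcipl_", nms), "GCIPL",
                       ifelse(grepl("^mac_", nms), "MAC", "RNFL"))
  cat <- data.frame(
    name = c(sn, fn),
    domain = c(rep("spatial", length(sn)), rep("frequency", length(fn))),
    group = c(grp(sn), rep("RNFL", length(fn))),
    stringsAsFactors = FALSE)
  stopifnot(!anyDuplicated(cat$name),
            sum(cat$domain == "spatial") == 67L,
            sum(cat$domain == "frequency") == 64L)
  attr(cat, "version") <- CATALOG_VERSION
  cat
}

#' Write / read a feature catalog as JSON
#'
#' @param catalog A catalog data.frame as returned by [default_catalog()].
#' @param path JSON file path.
#' @export
write_catalog <- function(catalog, path) {
  jsonlite::write_json(
    list(version = attr(catalog, "version") %||% "custom",
         features = catalog),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cat <- as.data.frame(obj$features, stringsAsFactors = FALSE)
  attr(cat, "version") <- obj$version
  cat
}

`%||%` <- function(a, b) if (is.null(a)) b else a
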