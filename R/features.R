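#' Extract the full 131-feature matrix of a cohort
#'
#' Runs [extract_spatial()] and [extract_frequency()] on every eye, using the
#' fellow eye on record (same patient, other laterality) for inter-eye
#' symmetry when the device value is absent.
#'
#' @param cohort An `oct_cohort`.
#' @param catalog Feature catalog (default [default_catalog()]).
#' @return Numeric matrix, one row per eye, columns in catalog order, with a
#'   `catalog_version` attribute; row names are `patient_id:eye`.
#' @export
extract_features <- function(cohort, catalog = default_catalog()) {
  df <- as.data.frame(cohort)
  n <- nrow(df)
  X <- matrix(NA_real_, n, nrow(catalog),
              dimnames = list(paste(df$patient_id, df$eye, sep = ":"),
                              catalog$name))
  for (r in seq_len(n)) {
    fellow_idx <- which(df$patient_id == df$patient_id[r] &
                          df$eye != df$eye[r])
    fellow <- if (length(fellow_idx)) df[fellow_idx[1L], ] else NULL
    sp <- extract_spatial(df[r, ], fellow)
    tvals <- as.numeric(df[r, tsnit_cols()])
    fr <- extract_frequency(if (all(is.finite(tvals))) tvals else NULL)
    vals <- c(sp, fr)
    X[r, ] <- vals[colnames(X)]
  }
  attr(X, "catalog_version") <- attr(catalog, "version")
  X
}

#' Feature labels for a cohort
#'
#' @param cohort An `oct_cohort`.
#' @param collapse_glaucoma If `TRUE`, all glaucomatous stages are collapsed
#'   to `"GLAUCOMA"` for overall diagnosis.
#' @return Character vector of labels, one per eye.
#' @export
cohort_labels <- function(cohort, collapse_glaucoma = FALSE) {
  lab <- as.data.frame(cohort)$label
  if (collapse_glaucoma) lab[lab != "NORMAL" & !is.na(lab)] <- "GLAUCOMA"
  lab
}
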