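## Canonical per-eye record schema. A cohort is a data.frame with one row per
## eye; missing measurements are NA and whole parameter groups flagged as
## artefact are NA across the group.

STAGE_LEVELS <- c("NORMAL", "EARLY", "MODERATE", "ADVANCED_MD", "ADVANCED_CFD")

TSNIT_LEN <- 256L

tsnit_cols <- function() sprintf("t%03d", 0:(TSNIT_LEN - 1L))

rnfl_summary_cols <- function() {
  c("rnfl_average", "rnfl_symmetry",
    "rnfl_quad_t", "rnfl_quad_s", "rnfl_quad_n", "rnfl_quad_i",
    paste0("rnfl_clock_", 1:12))
}

gcipl_cols <- function() {
  c("gcipl_average", "gcipl_minimum",
    "gcipl_superotemporal", "gcipl_superior", "gcipl_superonasal",
    "gcipl_inferonasal", "gcipl_inferior", "gcipl_inferotemporal")
}

mac_cols <- function() {
  c("mac_central",
    "mac_inner_superior", "mac_inner_nasal", "mac_inner_inferior",
    "mac_inner_temporal",
    "mac_outer_superior", "mac_outer_nasal", "mac_outer_inferior",
    "mac_outer_temporal",
    "mac_cube_average", "mac_cube_volume", "mac_center_foveal",
    "mac_center_min")
}

cohort_cols <- function() {
  c("patient_id", "eye", "label", "md_db", "cfd_flag",
    tsnit_cols(), rnfl_summary_cols(), gcipl_cols(), mac_cols())
}

## Parameter groups used for artefact masking: an artefact on a scan protocol
## wipes out every measurement the protocol produces.
PARAM_GROUPS <- c("RNFL", "GCIPL", "MAC")

group_cols <- function(group) {
  switch(group,
    RNFL  = c(tsnit_cols(), rnfl_summary_cols()),
    GCIPL = gcipl_cols(),
    MAC   = mac_cols(),
    stop("unknown parameter group: ", group))
}

## Run expr with a temporary RNG state so seeded helpers do not disturb the
## caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Assign a glaucoma severity stage from the visual-field mean deviation
#'
#' Applies the Mills mean-deviation (MD) staging bands to an eye already
#' diagnosed as glaucomatous: early for MD above -6 dB, moderate for
#' -12 dB < MD <= -6 dB, advanced for MD <= -12 dB. An eye whose MD does not
#' meet the advanced criterion can still be staged advanced through an
#' explicit central-field-defect (CFD) flag; MD alone never produces the
#' CFD-based label. Normal eyes are a clinician-assigned input label and are
#' never derived from MD.
#'
#' @param md_db Visual-field mean deviation in dB (finite scalar; more
#'   negative is worse).
#' @param cfd_flag Logical; `TRUE` if a central field defect was adjudicated.
#' @return One of `"EARLY"`, `"MODERATE"`, `"ADVANCED_MD"`, `"ADVANCED_CFD"`.
#' @examples
#' stage_from_md(-3)    # "EARLY"
#' stage_from_md(-6)    # "MODERATE" (boundary included)
#' stage_from_md(-12)   # "ADVANCED_MD"
#' stage_from_md(-8, cfd_flag = TRUE)  # "ADVANCED_CFD"
#' @export
stage_from_md <- function(md_db, cfd_flag = FALSE) {
  if (!is.numeric(md_db) || length(md_db) != 1L || !is.finite(md_db))
    stop("md_db must be a single finite number")
  if (md_db <= -12) return("ADVANCED_MD")
  if (isTRUE(cfd_flag)) return("ADVANCED_CFD")
  if (md_db <= -6) return("MODERATE")
  "EARLY"
}

new_cohort <- function(df, provenance = "unspecified") {
  rownames(df) <- NULL
  structure(df, class = c("oct_cohort", "data.frame"),
            provenance = provenance)
}

validate_cohort <- function(df) {
  missing_cols <- setdiff(cohort_cols(), names(df))
  if (length(missing_cols))
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0L) return(invisible(df))
  if (!all(df$eye %in% c("OD", "OS")))
    stop("eye must be 'OD' or 'OS'")
  key <- paste(df$patient_id, df$eye)
  if (anyDuplicated(key))
    stop("duplicate (patient_id, eye) pair: ", key[duplicated(key)][1L])
  bad_label <- !is.na(df$label) & !(df$label %in% STAGE_LEVELS)
  if (any(bad_label))
    stop("unknown label string: ", df$label[bad_label][1L])
  tm <- as.matrix(df[tsnit_cols()])
  if (any(tm[is.finite(tm)] < 0))
    stop("TSNIT thickness values must be >= 0")
  sym <- df$rnfl_symmetry
  if (any(!is.na(sym) & (sym < 0 | sym > 100)))
    stop("rnfl_symmetry must lie in [0, 100]")
  ## every row must carry at least one artefact-free parameter group
  has_any <- rep(FALSE, nrow(df))
  for (g in PARAM_GROUPS) {
    gm <- as.matrix(df[group_cols(g)])
    has_any <- has_any | rowSums(!is.na(gm)) > 0
  }
  if (!all(has_any))
    stop("row ", which(!has_any)[1L],
         " has no artefact-free parameter group")
  invisible(df)
}

#' Read a per-eye OCT cohort from CSV
#'
#' One row per eye. The 256-point TSNIT profile may be stored either as
#' columns `t000..t255` or as a single quoted `tsnit` column of
#' semicolon-joined values; both dialects are accepted and canonicalised to
#' the 256-column form. Empty cells are missing measurements; a fully missing
#' parameter group (RNFL / GC-IPL / macular) is the artefact mask.
#'
#' @param path CSV file path.
#' @return An `oct_cohort` (a data.frame, one row per eye).
#' @seealso [write_cohort()], [artefact_mask()]
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character"))
  if (nrow(df) > 0L && "tsnit" %in% names(df) &&
      !all(tsnit_cols() %in% names(df))) {
    parts <- strsplit(as.character(df$tsnit), ";", fixed = TRUE)
    lens <- lengths(parts)
    empty <- is.na(df$tsnit) | !nzchar(trimws(as.character(df$tsnit)))
    if (any(!empty & lens != TSNIT_LEN))
      stop("TSNIT field must contain exactly ", TSNIT_LEN,
           " values; row ", which(!empty & lens != TSNIT_LEN)[1L],
           " has ", lens[!empty & lens != TSNIT_LEN][1L])
    tm <- matrix(NA_real_, nrow(df), TSNIT_LEN,
                 dimnames = list(NULL, tsnit_cols()))
    for (i in which(!empty)) tm[i, ] <- as.numeric(parts[[i]])
    df$tsnit <- NULL
    df <- cbind(df, as.data.frame(tm))
  }
  if (nrow(df) == 0L) {
    ## header-only file: build an empty canonical frame
    for (cn in setdiff(cohort_cols(), names(df)))
      df[[cn]] <- if (cn %in% c("patient_id", "eye", "label")) character(0)
                  else if (cn == "cfd_flag") logical(0) else numeric(0)
  } else {
    tsn <- intersect(tsnit_cols(), names(df))
    if (length(tsn) && length(tsn) != TSNIT_LEN)
      stop("expected ", TSNIT_LEN, " TSNIT columns, found ", length(tsn))
    for (cn in setdiff(cohort_cols(), names(df)))
      df[[cn]] <- if (cn == "cfd_flag") FALSE else NA_real_
    df$cfd_flag <- !is.na(df$cfd_flag) & as.logical(df$cfd_flag)
    df$label <- as.character(df$label)
    df$label[!is.na(df$label) & !nzchar(df$label)] <- NA_character_
  }
  df <- df[cohort_cols()]
  validate_cohort(df)
  new_cohort(df, provenance = path)
}

#' Write a cohort to canonical CSV
#'
#' The canonical form uses `t000..t255` TSNIT columns; `write_cohort()`
#' followed by [read_cohort()] is the identity on canonical cohorts.
#'
#' @param cohort An `oct_cohort`.
#' @param path Output CSV path.
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  df <- as.data.frame(cohort)[cohort_cols()]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Artefact mask of a cohort
#'
#' @param cohort An `oct_cohort`.
#' @return Logical matrix, rows = eyes, columns = parameter groups
#'   (`RNFL`, `GCIPL`, `MAC`); `TRUE` where the whole group is missing.
#' @export
artefact_mask <- function(cohort) {
  m <- sapply(PARAM_GROUPS, function(g) {
    gm <- as.matrix(as.data.frame(cohort)[group_cols(g)])
    rowSums(!is.na(gm)) == 0
  })
  if (nrow(cohort) == 1L) m <- matrix(m, 1L, dimnames = list(NULL, PARAM_GROUPS))
  m
}

#' Patient-level cross-validation folds
#'
#' Partitions patients (never single eyes) into `k` folds so both eyes of a
#' patient always share a fold, stratified by the patient's stage label where
#' possible, with fold sizes differing by at most one patient. Deterministic
#' for a fixed seed.
#'
#' @param cohort An `oct_cohort`.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return A `fold_assignment`: list with `k`, `seed` and `folds`, a named
#'   integer vector mapping `patient_id` to fold index.
#' @export
patient_level_folds <- function(cohort, k = 5L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  df <- as.data.frame(cohort)
  pats <- unique(df$patient_id)
  if (length(pats) < k) stop("fewer patients (", length(pats),
                             ") than folds (", k, ")")
  ## patient-level label = label of the first eye on record
  plab <- df$label[match(pats, df$patient_id)]
  plab[is.na(plab)] <- "<unlabelled>"
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
  structure(list(k = k, seed = as.integer(seed), folds = folds),
            class = "fold_assignment")
}

#' Per-row fold indices for a cohort
#'
#' @param cohort An `oct_cohort`.
#' @param fa A `fold_assignment` from [patient_level_folds()].
#' @return Integer vector of fold indices, one per cohort row.
#' @export
record_folds <- function(cohort, fa) {
  unname(fa$folds[as.data.frame(cohort)$patient_id])
}

#' @export
print.oct_cohort <- function(x, ...) {
  df <- as.data.frame(x)
  cat("<oct_cohort> ", nrow(df), " eyes, ",
      length(unique(df$patient_id)), " patients\n", sep = "")
  if (nrow(df)) {
    tab <- table(factor(df$label, levels = STAGE_LEVELS), useNA = "ifany")
    cat("  labels: ", paste(names(tab), tab, sep = "=", collapse = " "),
        "\n", sep = "")
    cat("  artefact-masked groups: ", sum(artefact_mask(x)), "\n", sep = "")
  }
  invisible(x)
}
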