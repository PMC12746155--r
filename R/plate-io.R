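#' Assemble and validate a plate dataset
#'
#' A plate dataset bundles a plate map (one row per well), a long-format
#' feature table (one detected ion per row) and, optionally, MS/MS spectra.
#' This is the canonical in-memory container every screening stage consumes.
#'
#' @param features Data frame with columns `well`, `mz` (Da/charge, > 0),
#'   `rt` (minutes, >= 0), `intensity` (counts, >= 0) and optionally `ms2_id`
#'   referencing a spectrum in `ms2`.
#' @param plate_map Data frame with columns `well`, `role`
#'   (`"elicitor"` or `"control"`; `"vehicle-control"` is accepted as a
#'   synonym of `"control"`), `elicitor` (identifier, `NA` for controls),
#'   `concentration_uM` (>= 0; 0 only for controls) and `replicate`
#'   (integer >= 1).
#' @param ms2 Optional long-format spectra: columns `spectrum_id`,
#'   `precursor_mz`, `fragment_mz`, `rel_intensity`. Fragments must lie below
#'   `precursor_mz + 1.5` Da.
#' @param metadata Optional list (instrument polarity, generation seed, ...).
#'   Polarity defaults to `"positive"`.
#' @param require_control Require at least one control well (default `TRUE`;
#'   screening stages always need one).
#' @return An object of class `"plate_dataset"`.
#' @export
plate_dataset <- function(features, plate_map, ms2 = NULL, metadata = list(),
                          require_control = TRUE) {
  plate_map <- .validate_plate_map(plate_map, require_control)
  features <- .validate_features(features, plate_map, ms2)
  if (!is.null(ms2)) ms2 <- .validate_ms2(ms2)
  if (is.null(metadata$polarity)) metadata$polarity <- "positive"
  structure(list(features = features, plate_map = plate_map, ms2 = ms2,
                 metadata = metadata),
            class = "plate_dataset")
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("missing-column error: ", what, " lacks mandatory column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
}

.validate_plate_map <- function(pm, require_control = TRUE) {
  if (!is.data.frame(pm)) stop("plate map must be a data frame")
  .require_columns(pm, c("well", "role", "elicitor", "concentration_uM",
                         "replicate"), "plate map")
  pm$well <- as.character(pm$well)
  pm$role <- ifelse(pm$role == "vehicle-control", "control",
                    as.character(pm$role))
  pm$elicitor <- as.character(pm$elicitor)
  if (anyDuplicated(pm$well))
    stop("duplicate well id(s) in plate map")
  if (!all(pm$role %in% c("elicitor", "control")))
    stop("plate map role must be 'elicitor' or 'control'")
  ctrl <- pm$role == "control"
  if (require_control && !any(ctrl))
    stop("no-control error: dataset has no vehicle-control wells")
  if (any(!is.na(pm$elicitor[ctrl]) & nzchar(pm$elicitor[ctrl])))
    stop("control wells must not carry an elicitor id")
  if (any(is.na(pm$elicitor[!ctrl]) | !nzchar(pm$elicitor[!ctrl])))
    stop("elicitor wells must carry an elicitor id")
  if (any(pm$concentration_uM < 0))
    stop("concentrations must be >= 0")
  if (any(pm$concentration_uM[!ctrl] == 0))
    stop("concentration 0 is only valid for control wells")
  if (any(pm$replicate < 1 | pm$replicate != round(pm$replicate)))
    stop("replicate index must be an integer >= 1")
  pm
}

.validate_features <- function(ft, pm, ms2 = NULL) {
  if (!is.data.frame(ft)) stop("feature table must be a data frame")
  .require_columns(ft, c("well", "mz", "rt", "intensity"), "feature table")
  ft$well <- as.character(ft$well)
  if (nrow(ft)) {
    if (any(ft$mz <= 0)) stop("feature m/z must be positive")
    if (any(ft$rt < 0)) stop("feature retention time must be >= 0")
    if (any(ft$intensity < 0)) stop("feature intensity must be >= 0")
    unknown <- setdiff(unique(ft$well), pm$well)
    if (length(unknown))
      stop("unknown-well error: feature table references well(s) ",
           paste(head(unknown, 5), collapse = ", "),
           " absent from the plate map")
  }
  if (!"ms2_id" %in% names(ft)) ft$ms2_id <- rep(NA_character_, nrow(ft))
  ft$ms2_id <- as.character(ft$ms2_id)
  if (!is.null(ms2) && nrow(ft)) {
    ref <- ft$ms2_id[!is.na(ft$ms2_id)]
    missing <- setdiff(ref, unique(as.character(ms2$spectrum_id)))
    if (length(missing))
      stop("feature table references unknown MS/MS spectrum id(s): ",
           paste(head(missing, 5), collapse = ", "))
  }
  ft
}

.validate_ms2 <- function(ms2) {
  if (!is.data.frame(ms2)) stop("ms2 table must be a data frame")
  .require_columns(ms2, c("spectrum_id", "precursor_mz", "fragment_mz",
                          "rel_intensity"), "ms2 table")
  ms2$spectrum_id <- as.character(ms2$spectrum_id)
  if (!nrow(ms2)) stop("ms2 table must be non-empty when supplied")
  if (any(ms2$rel_intensity < 0)) stop("fragment intensities must be >= 0")
  if (any(ms2$fragment_mz >= ms2$precursor_mz + 1.5))
    stop("fragment m/z must be below precursor m/z + 1.5 Da")
  ms2
}

#' @export
print.plate_dataset <- function(x, ...) {
  nw <- nrow(x$plate_map)
  nc <- sum(x$plate_map$role == "control")
  cat(sprintf("plate_dataset: %d wells (%d control), %d features%s\n",
              nw, nc, nrow(x$features),
              if (!is.null(x$ms2))
                sprintf(", %d MS/MS spectra",
                        length(unique(x$ms2$spectrum_id))) else ""))
  invisible(x)
}

# full-precision numeric formatting so that CSV round-trips are exact
.fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g", width = 1)
  out[is.na(x)] <- NA
  gsub(" ", "", out)
}

.write_csv_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- .fmt_num(out[[j]])
  write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
}

#' Read a plate dataset from CSV files
#'
#' Reads a long-format feature table and a plate map (and optionally MS/MS
#' spectra) written by [write_feature_table()] or produced externally, and
#' validates them into a [plate_dataset()]. Row order is irrelevant.
#'
#' @param features_path CSV with columns `well, mz, rt, intensity[, ms2_id]`.
#' @param plate_map_path CSV with columns
#'   `well, role, elicitor, concentration_uM, replicate`.
#' @param ms2_path Optional CSV with columns
#'   `spectrum_id, precursor_mz, fragment_mz, rel_intensity`.
#' @param require_control Passed to [plate_dataset()].
#' @return A `plate_dataset`.
#' @export
read_feature_table <- function(features_path, plate_map_path,
                               ms2_path = NULL, require_control = TRUE) {
  ft <- read.csv(features_path, stringsAsFactors = FALSE)
  pm <- read.csv(plate_map_path, stringsAsFactors = FALSE)
  ms2 <- NULL
  if (!is.null(ms2_path) && file.exists(ms2_path)) {
    ms2 <- read.csv(ms2_path, stringsAsFactors = FALSE)
    if (!nrow(ms2)) ms2 <- NULL
  }
  if ("ms2_id" %in% names(ft)) {
    ft$ms2_id <- as.character(ft$ms2_id)
    ft$ms2_id[!is.na(ft$ms2_id) & !nzchar(ft$ms2_id)] <- NA_character_
  }
  if (!is.null(pm$elicitor)) {
    pm$elicitor <- as.character(pm$elicitor)
    pm$elicitor[!is.na(pm$elicitor) & !nzchar(pm$elicitor)] <- NA_character_
  }
  plate_dataset(ft, pm, ms2 = ms2, require_control = require_control)
}

#' Write a plate dataset to CSV files
#'
#' Writes `features.csv`, `plate_map.csv` and (when spectra are present)
#' `ms2.csv` into a directory, with deterministic column order and row sort
#' (features by well, rt, mz), so identical datasets always serialize to
#' identical bytes.
#'
#' @param dataset A [plate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the file paths written.
#' @export
write_feature_table <- function(dataset, dir) {
  if (!inherits(dataset, "plate_dataset"))
    stop("`dataset` must be a plate_dataset")
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory '", dir, "'")
  ft <- dataset$features[, c("well", "mz", "rt", "intensity", "ms2_id")]
  ft <- ft[order(ft$well, ft$rt, ft$mz), , drop = FALSE]
  pm <- dataset$plate_map[, c("well", "role", "elicitor", "concentration_uM",
                              "replicate")]
  pm <- pm[order(pm$well), , drop = FALSE]
  paths <- c(features = file.path(dir, "features.csv"),
             plate_map = file.path(dir, "plate_map.csv"))
  .write_csv_exact(ft, paths["features"])
  .write_csv_exact(pm, paths["plate_map"])
  if (!is.null(dataset$ms2)) {
    ms2 <- dataset$ms2[, c("spectrum_id", "precursor_mz", "fragment_mz",
                           "rel_intensity")]
    ms2 <- ms2[order(ms2$spectrum_id, ms2$fragment_mz), , drop = FALSE]
    paths["ms2"] <- file.path(dir, "ms2.csv")
    .write_csv_exact(ms2, paths["ms2"])
  }
  invisible(paths)
}
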