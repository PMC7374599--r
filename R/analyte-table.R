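#' Construct an analyte table
#'
#' The central data container of the package: a samples-by-analytes matrix of
#' concentrations together with per-sample metadata, per-analyte metadata and
#' an optional below-limit-of-detection (LOD) mask. Cells flagged in
#' `lod_mask` hold `NA` until [impute_lod()] replaces them.
#'
#' @param values numeric matrix, samples in rows (rownames = sample IDs),
#'   analytes in columns (colnames = analyte IDs).
#' @param sample_meta data.frame with one row per sample; must contain
#'   columns `sample_id`, `subject_id`, `group`, `time_week`, `compartment`.
#'   BAL tables additionally carry `total_protein`.
#' @param analyte_meta data.frame with columns `analyte_id` and `compartment`
#'   (one row per column of `values`); may carry `min_detectable` for LOD
#'   imputation. Defaults to a single-compartment frame inferred from
#'   `sample_meta`.
#' @param lod_mask logical matrix of the same dimension as `values`, `TRUE`
#'   where the measurement fell below the detection limit. Default: all
#'   `FALSE`.
#'
#' @return An object of class `analyte_table`.
#' @export
analyte_table <- function(values, sample_meta, analyte_meta = NULL,
                          lod_mask = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have sample rownames and analyte colnames")
  required <- c("sample_id", "subject_id", "group", "time_week", "compartment")
  missing_cols <- setdiff(required, names(sample_meta))
  if (length(missing_cols))
    stop("sample_meta lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(sample_meta) != nrow(values))
    stop("sample_meta has ", nrow(sample_meta), " rows but values has ",
         nrow(values), " samples")
  if (anyDuplicated(sample_meta$sample_id))
    stop("duplicate sample IDs in metadata")
  if (!identical(as.character(sample_meta$sample_id), rownames(values)))
    stop("sample_meta$sample_id must match rownames(values) in order")
  if (is.null(analyte_meta)) {
    analyte_meta <- data.frame(
      analyte_id = colnames(values),
      compartment = sample_meta$compartment[1],
      stringsAsFactors = FALSE
    )
  }
  if (!identical(as.character(analyte_meta$analyte_id), colnames(values)))
    stop("analyte_meta$analyte_id must match colnames(values) in order")
  dup <- duplicated(paste(analyte_meta$compartment, analyte_meta$analyte_id))
  if (any(dup))
    stop("duplicate analyte IDs within a compartment: ",
         paste(unique(analyte_meta$analyte_id[dup]), collapse = ", "))
  if (is.null(lod_mask)) {
    lod_mask <- matrix(FALSE, nrow(values), ncol(values),
                       dimnames = dimnames(values))
  }
  if (!identical(dim(lod_mask), dim(values)))
    stop("lod_mask dimensions must match values")
  structure(
    list(values = values, sample_meta = sample_meta,
         analyte_meta = analyte_meta, lod_mask = lod_mask),
    class = "analyte_table"
  )
}

#' @export
print.analyte_table <- function(x, ...) {
  cat(sprintf("analyte_table: %d samples x %d analytes\n",
              nrow(x$values), ncol(x$values)))
  cat(sprintf("  compartment(s): %s; time week(s): %s\n",
              paste(unique(x$analyte_meta$compartment), collapse = ", "),
              paste(unique(x$sample_meta$time_week), collapse = ", ")))
  grp <- table(x$sample_meta$group)
  cat("  groups:", paste(sprintf("%s=%d", names(grp), grp), collapse = ", "),
      "\n")
  n_lod <- sum(x$lod_mask)
  if (n_lod > 0) cat(sprintf("  %d cell(s) below LOD\n", n_lod))
  invisible(x)
}

#' @export
dim.analyte_table <- function(x) dim(x$values)

# Subset an analyte table by sample and/or analyte index, keeping the
# metadata aligned.
#' Subset an analyte table
#'
#' @param table an [analyte_table()].
#' @param samples row index (logical, integer or sample-ID character vector).
#' @param analytes column index (logical, integer or analyte-ID character
#'   vector).
#' @return The subsetted `analyte_table`.
#' @export
subset_table <- function(table, samples = NULL, analytes = NULL) {
  stopifnot(inherits(table, "analyte_table"))
  if (is.null(samples)) samples <- seq_len(nrow(table$values))
  if (is.null(analytes)) analytes <- seq_len(ncol(table$values))
  if (is.character(samples)) samples <- match(samples, rownames(table$values))
  if (is.character(analytes)) {
    idx <- match(analytes, colnames(table$values))
    if (anyNA(idx))
      stop("analyte(s) not present: ",
           paste(analytes[is.na(idx)], collapse = ", "))
    analytes <- idx
  }
  analyte_table(
    values = table$values[samples, analytes, drop = FALSE],
    sample_meta = table$sample_meta[samples, , drop = FALSE],
    analyte_meta = table$analyte_meta[analytes, , drop = FALSE],
    lod_mask = table$lod_mask[samples, analytes, drop = FALSE]
  )
}

# The token written in place of censored values in exported tables.
LOD_SENTINEL <- "<LOD"

#' Read a delimited analyte table with its metadata
#'
#' Parses a concentration table (first column sample ID, remaining columns
#' analytes) plus a sample metadata table. Cells equal to the sentinel token
#' `"<LOD"` are flagged in the LOD mask and held as `NA` pending imputation.
#' Tab- or comma-delimited files are detected from the extension (`.csv` =
#' comma, otherwise tab).
#'
#' @param path path to the concentration table.
#' @param meta_path path to the sample metadata table (columns `sample_id`,
#'   `subject_id`, `group`, `time_week`, `compartment`, optionally
#'   `total_protein`).
#' @param analyte_meta_path optional path to an analyte metadata table
#'   (columns `analyte_id`, `compartment`, optionally `min_detectable`).
#' @return An [analyte_table()].
#' @export
read_analyte_table <- function(path, meta_path, analyte_meta_path = NULL) {
  raw <- .read_delim_auto(path, colClasses = "character")
  if (ncol(raw) < 2) stop("table must have a sample-ID column and >= 1 analyte")
  ids <- raw[[1]]
  if (anyDuplicated(ids))
    stop("duplicate sample IDs in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cells <- as.matrix(raw[, -1, drop = FALSE])
  rownames(cells) <- ids
  mask <- cells == LOD_SENTINEL
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells),
                                 dimnames = dimnames(cells)))
  bad <- which(is.na(vals) & !mask & cells != "NA", arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-numeric value '%s' at row %s, column %s of %s",
                 cells[bad[1, 1], bad[1, 2]], rownames(cells)[bad[1, 1]],
                 colnames(cells)[bad[1, 2]], path))
  vals[mask] <- NA_real_

  meta <- .read_delim_auto(meta_path)
  meta$sample_id <- as.character(meta$sample_id)
  extra_meta <- setdiff(meta$sample_id, ids)
  if (length(extra_meta))
    stop("metadata row(s) without matching sample row: ",
         paste(extra_meta, collapse = ", "))
  extra_rows <- setdiff(ids, meta$sample_id)
  if (length(extra_rows))
    stop("sample row(s) without metadata: ",
         paste(extra_rows, collapse = ", "))
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL

  analyte_meta <- NULL
  if (!is.null(analyte_meta_path)) {
    am <- .read_delim_auto(analyte_meta_path)
    am$analyte_id <- as.character(am$analyte_id)
    am <- am[match(colnames(vals), am$analyte_id), , drop = FALSE]
    if (anyNA(am$analyte_id))
      stop("analyte metadata is missing entries for some table columns")
    rownames(am) <- NULL
    analyte_meta <- am
  }
  analyte_table(vals, meta, analyte_meta, mask)
}

.read_delim_auto <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  read.delim(path, sep = sep, stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}
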