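#' Impute below-LOD cells at half the global minimum detectable concentration
#'
#' Every cell flagged below the limit of detection is replaced by one half of
#' the lowest minimum detectable concentration across *all* analytes (a single
#' global floor, not a per-analyte one), the convention used for multiplexed
#' immunoassay panels where one shared standard-curve floor is reported.
#'
#' @param table an [analyte_table()] with its `lod_mask` set.
#' @param min_detectable named numeric vector of per-analyte minimum
#'   detectable concentrations. Defaults to the `min_detectable` column of
#'   `analyte_meta` when present.
#' @return The table with all masked cells imputed; the mask is retained so
#'   the provenance of imputed values is not lost.
#' @export
impute_lod <- function(table, min_detectable = NULL) {
  stopifnot(inherits(table, "analyte_table"))
  if (!any(table$lod_mask)) return(table)
  if (is.null(min_detectable)) {
    if (!"min_detectable" %in% names(table$analyte_meta))
      stop("masked cells present but no `min_detectable` supplied")
    min_detectable <- setNames(table$analyte_meta$min_detectable,
                               table$analyte_meta$analyte_id)
  }
  if (!all(is.finite(min_detectable)) || any(min_detectable <= 0))
    stop("`min_detectable` must be positive and finite")
  fill <- 0.5 * min(min_detectable)
  table$values[table$lod_mask] <- fill
  table
}

#' Normalise BAL concentrations to per-sample total protein
#'
#' Divides each bronchoalveolar-lavage (BAL) measurement by the sample's
#' total protein concentration, converting raw assay units into
#' analyte-per-total-protein units. Dilution of lavage fluid varies strongly
#' between procedures, so raw BAL values are not comparable across samples
#' without this correction.
#'
#' @param table a BAL [analyte_table()].
#' @param totals named numeric vector of per-sample total protein values;
#'   defaults to the `total_protein` column of `sample_meta`.
#' @return The normalised table.
#' @export
normalize_total_protein <- function(table, totals = NULL) {
  stopifnot(inherits(table, "analyte_table"))
  if (!all(table$analyte_meta$compartment == "bal"))
    stop("compartment mismatch: total-protein normalisation applies to BAL tables only")
  if (is.null(totals)) {
    if (!"total_protein" %in% names(table$sample_meta))
      stop("no `totals` supplied and no total_protein column in sample_meta")
    totals <- setNames(table$sample_meta$total_protein,
                       table$sample_meta$sample_id)
  }
  totals <- totals[rownames(table$values)]
  if (anyNA(totals))
    stop("missing total protein for sample(s): ",
         paste(rownames(table$values)[is.na(totals)], collapse = ", "))
  if (any(totals <= 0)) stop("total protein values must be > 0")
  table$values <- table$values / totals
  table
}

#' Merge blood and BAL tables at a shared time point
#'
#' Restricts both tables to the subjects present in each (matched by subject
#' ID) and concatenates the analyte columns. Analyte identifiers that occur
#' in both compartments are kept distinct by a compartment-qualified prefix.
#' After merging, analytes from both compartments are treated identically by
#' downstream scaling.
#'
#' @param blood,bal [analyte_table()] objects at the same time point.
#' @return The merged `analyte_table` (compartment tag `"blood+bal"` in the
#'   sample metadata; per-analyte compartments preserved in `analyte_meta`).
#' @export
merge_compartments <- function(blood, bal) {
  stopifnot(inherits(blood, "analyte_table"), inherits(bal, "analyte_table"))
  tw_b <- unique(blood$sample_meta$time_week)
  tw_l <- unique(bal$sample_meta$time_week)
  if (!identical(tw_b, tw_l))
    stop("tables are at different time points (", tw_b, " vs ", tw_l, ")")
  shared <- intersect(blood$sample_meta$subject_id, bal$sample_meta$subject_id)
  if (length(shared) == 0) stop("no subjects shared between compartments")
  bi <- match(shared, blood$sample_meta$subject_id)
  li <- match(shared, bal$sample_meta$subject_id)
  b <- subset_table(blood, samples = bi)
  l <- subset_table(bal, samples = li)
  clash <- intersect(colnames(b$values), colnames(l$values))
  if (length(clash)) {
    rename <- function(tab) {
      hit <- colnames(tab$values) %in% clash
      new <- paste(tab$analyte_meta$compartment[hit],
                   colnames(tab$values)[hit], sep = ".")
      colnames(tab$values)[hit] <- new
      colnames(tab$lod_mask)[hit] <- new
      tab$analyte_meta$analyte_id[hit] <- new
      tab
    }
    b <- rename(b)
    l <- rename(l)
  }
  meta <- b$sample_meta
  meta$compartment <- "blood+bal"
  meta$sample_id <- paste0(meta$subject_id, "_w", meta$time_week, "_merged")
  values <- cbind(b$values, l$values)
  rownames(values) <- meta$sample_id
  mask <- cbind(b$lod_mask, l$lod_mask)
  rownames(mask) <- meta$sample_id
  analyte_table(values, meta,
                rbind(b$analyte_meta[, c("analyte_id", "compartment")],
                      l$analyte_meta[, c("analyte_id", "compartment")]),
                mask)
}

#' Autoscale (mean-centre and unit-variance scale) each analyte
#'
#' @param table an [analyte_table()] or plain numeric matrix with no missing
#'   values.
#' @param on_zero_variance `"error"` (default) aborts listing the offending
#'   analytes; `"drop"` removes them with a warning.
#' @return A list with elements `table` (scaled data, same class as the
#'   input) and `params`, a `scaling_params` object (`means`, `sds`) for
#'   applying the identical transform to held-out data via
#'   [apply_scaling()]. Standard deviations use the n-1 denominator.
#' @export
autoscale <- function(table, on_zero_variance = c("error", "drop")) {
  on_zero_variance <- match.arg(on_zero_variance)
  x <- if (inherits(table, "analyte_table")) table$values else table
  if (anyNA(x)) stop("missing values present; impute before autoscaling")
  mu <- colMeans(x)
  sds <- apply(x, 2, sd)
  zero <- sds < .Machine$double.eps^0.5
  if (any(zero)) {
    if (on_zero_variance == "error")
      stop("zero-variance analyte(s): ",
           paste(colnames(x)[zero], collapse = ", "))
    warning("dropping zero-variance analyte(s): ",
            paste(colnames(x)[zero], collapse = ", "))
    keep <- !zero
    if (inherits(table, "analyte_table")) {
      table <- subset_table(table, analytes = which(keep))
      x <- table$values
    } else {
      x <- x[, keep, drop = FALSE]
    }
    mu <- mu[keep]
    sds <- sds[keep]
  }
  scaled <- sweep(sweep(x, 2, mu, "-"), 2, sds, "/")
  params <- structure(list(means = mu, sds = sds), class = "scaling_params")
  if (inherits(table, "analyte_table")) {
    table$values <- scaled
    list(table = table, params = params)
  } else {
    list(table = scaled, params = params)
  }
}

#' Apply previously fitted scaling parameters to new data
#'
#' Used to scale held-out cross-validation folds with the calibration fold's
#' means and standard deviations, so no information leaks from test samples.
#'
#' @param table an [analyte_table()] or matrix whose columns match `params`.
#' @param params a `scaling_params` object from [autoscale()].
#' @return The scaled table/matrix.
#' @export
apply_scaling <- function(table, params) {
  stopifnot(inherits(params, "scaling_params"))
  x <- if (inherits(table, "analyte_table")) table$values else table
  nm <- names(params$means)
  missing_cols <- setdiff(nm, colnames(x))
  if (length(missing_cols))
    stop("data lack analyte(s) required by scaling params: ",
         paste(missing_cols, collapse = ", "))
  x <- x[, nm, drop = FALSE]
  scaled <- sweep(sweep(x, 2, params$means, "-"), 2, params$sds, "/")
  if (inherits(table, "analyte_table")) {
    table <- subset_table(table, analytes = nm)
    table$values <- scaled
    table
  } else {
    scaled
  }
}
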