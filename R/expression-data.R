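#' Expression time-course dataset
#'
#' Container for a probe-by-sample expression matrix together with per-sample
#' collection metadata for the two hair-growth cycles (the second natural
#' cycle and the depilation-induced cycle). Values may be on the linear or
#' the log2 scale; several downstream stages are scale-specific (periodicity
#' detection works on log2 values, the two-population mixture model requires
#' the linear scale) and refuse the wrong scale rather than converting
#' silently.
#'
#' @param values numeric matrix, probes in rows and samples in columns.
#'   Row names are taken as probe ids when `probe_ids` is missing.
#' @param sample_info data frame with one row per sample column, containing at
#'   least `sample_id`, `cycle` (one of `"natural"`, `"induced"`) and `day`
#'   (numeric collection day: postnatal day for the natural cycle, days after
#'   depilation for the induced cycle). An optional `merged_day` column is
#'   carried along (normally filled by [merge_cycles()]).
#' @param scale `"linear"` or `"log2"`.
#' @param probe_ids optional character vector of unique probe labels.
#'
#' @return An object of class `expr_dataset`: a list with elements `values`,
#'   `samples` (the metadata data frame) and `scale`.
#' @seealso [read_expression()], [merge_cycles()], [convert_scale()]
#' @export
expression_dataset <- function(values, sample_info,
                               scale = c("log2", "linear"),
                               probe_ids = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(probe_ids)) rownames(values) <- probe_ids
  if (is.null(rownames(values)))
    rownames(values) <- paste0("probe_", seq_len(nrow(values)))
  if (anyDuplicated(rownames(values)))
    stop_hw("duplicate probe ids", class = "hairwave_validation_error")
  if (!is.data.frame(sample_info))
    stop_hw("sample_info must be a data frame",
            class = "hairwave_schema_error")
  required <- c("sample_id", "cycle", "day")
  missing_cols <- setdiff(required, names(sample_info))
  if (length(missing_cols))
    stop_hw("sample_info lacks column(s): ",
            paste(missing_cols, collapse = ", "),
            class = "hairwave_schema_error")
  if (nrow(sample_info) != ncol(values))
    stop_hw("sample_info rows (", nrow(sample_info),
            ") do not match sample columns (", ncol(values), ")",
            class = "hairwave_schema_error")
  sample_info$sample_id <- as.character(sample_info$sample_id)
  if (anyDuplicated(sample_info$sample_id))
    stop_hw("duplicate sample ids", class = "hairwave_validation_error")
  if (!all(sample_info$cycle %in% c("natural", "induced")))
    stop_hw("cycle must be 'natural' or 'induced'",
            class = "hairwave_validation_error")
  sample_info$day <- as.numeric(sample_info$day)
  if (is.null(colnames(values))) {
    colnames(values) <- sample_info$sample_id
  } else if (!identical(colnames(values), sample_info$sample_id)) {
    if (!setequal(colnames(values), sample_info$sample_id))
      stop_hw("sample ids in matrix and metadata differ",
              class = "hairwave_schema_error")
    sample_info <- sample_info[match(colnames(values),
                                     sample_info$sample_id), , drop = FALSE]
    rownames(sample_info) <- NULL
  }
  if (scale == "linear" && any(values < 0, na.rm = TRUE))
    stop_hw("negative values on the linear scale",
            class = "hairwave_validation_error")
  if (!"merged_day" %in% names(sample_info))
    sample_info$merged_day <- NA_real_
  structure(list(values = values, samples = sample_info, scale = scale),
            class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf("<expr_dataset> %d probes x %d samples [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  cycles: %s\n",
              paste(sprintf("%s (%d)", names(table(x$samples$cycle)),
                            table(x$samples$cycle)), collapse = ", ")))
  if (all(is.na(x$samples$merged_day))) {
    cat("  merged_day: not set (run merge_cycles())\n")
  } else {
    cat(sprintf("  merged days: %s\n",
                paste(format(sort(unique(x$samples$merged_day))),
                      collapse = " ")))
  }
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$values)

#' Read an expression matrix and its sample metadata
#'
#' The matrix file is tab-separated with a `probe_id` first column and one
#' column per sample; the metadata file is tab-separated with columns
#' `sample_id`, `cycle`, `day` (and optionally `merged_day`). Metadata rows
#' are aligned to the matrix column order; a mismatch in the sample id sets
#' is a schema error.
#'
#' @param matrix_path,metadata_path paths to the two TSV files.
#' @inheritParams expression_dataset
#' @return An [expression_dataset()].
#' @export
read_expression <- function(matrix_path, metadata_path,
                            scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  mat <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(mat)[1] != "probe_id")
    stop_hw("matrix file must have 'probe_id' as its first column",
            class = "hairwave_schema_error")
  values <- as.matrix(mat[, -1, drop = FALSE])
  rownames(values) <- mat$probe_id
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE)
  expression_dataset(values, meta, scale = scale)
}

#' Write an expression dataset to TSV files
#'
#' Inverse of [read_expression()]: values are written with full precision
#' (15 significant digits) so a read/write round trip reproduces the dataset.
#'
#' @param ds an [expression_dataset()].
#' @param matrix_path,metadata_path output paths.
#' @return `ds`, invisibly.
#' @export
write_expression <- function(ds, matrix_path, metadata_path) {
  stopifnot(inherits(ds, "expr_dataset"))
  df <- data.frame(probe_id = rownames(ds$values),
                   signif(ds$values, 15), check.names = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- ds$samples
  if (all(is.na(meta$merged_day))) meta$merged_day <- NULL
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(ds)
}

#' Induced-to-natural day mapping of the two hair cycles
#'
#' The depilation-induced cycle is sampled on its own clock; to pool it with
#' the natural second cycle, induced collection days are mapped to
#' morphologically equivalent postnatal days of the natural cycle. The
#' default is the published skin-morphology correspondence:
#' induced days 3, 5, 8, 12, 17 map to natural days 24, 25, 27, 29, 37.
#'
#' @param induced_days,natural_days parallel numeric vectors defining the
#'   correspondence. Induced days must be unique and natural-equivalent days
#'   strictly increasing with them.
#' @return A named numeric vector (names = induced days) of class `time_map`.
#' @export
hair_time_map <- function(induced_days = c(3, 5, 8, 12, 17),
                          natural_days = c(24, 25, 27, 29, 37)) {
  if (length(induced_days) != length(natural_days))
    stop_hw("induced and natural day vectors differ in length",
            class = "hairwave_validation_error")
  o <- order(induced_days)
  induced_days <- induced_days[o]; natural_days <- natural_days[o]
  if (anyDuplicated(induced_days))
    stop_hw("duplicate induced days in time map",
            class = "hairwave_validation_error")
  if (length(natural_days) > 1 && any(diff(natural_days) <= 0))
    stop_hw("natural-equivalent days must increase strictly with induced days",
            class = "hairwave_validation_error")
  structure(stats::setNames(natural_days, induced_days), class = "time_map")
}

#' Merge the natural and induced cycles onto one time axis
#'
#' Fills `merged_day` for every sample: natural samples keep their postnatal
#' day, induced samples get the natural-equivalent day from the time map.
#' Samples are re-ordered by ascending merged day, natural before induced on
#' ties, which fixes downstream regression design matrices. The operation is
#' idempotent and leaves the values untouched.
#'
#' @param ds an [expression_dataset()].
#' @param map a [hair_time_map()].
#' @return The dataset with `merged_day` set and samples sorted.
#' @export
merge_cycles <- function(ds, map = hair_time_map()) {
  stopifnot(inherits(ds, "expr_dataset"))
  s <- ds$samples
  merged <- s$day
  ind <- s$cycle == "induced"
  if (any(ind)) {
    key <- as.character(s$day[ind])
    hit <- match(key, names(map))
    if (anyNA(hit))
      stop_hw("induced day(s) absent from time map: ",
              paste(unique(key[is.na(hit)]), collapse = ", "),
              class = "hairwave_mapping_error")
    merged[ind] <- unname(map[hit])
  }
  s$merged_day <- merged
  o <- order(merged, ind)  # natural (FALSE) sorts before induced on ties
  ds$samples <- s[o, , drop = FALSE]
  rownames(ds$samples) <- NULL
  ds$values <- ds$values[, o, drop = FALSE]
  ds
}

#' Display normalizations for expression heat maps
#'
#' `zero_one` rescales a vector to `[0, 1]` via `(x - min) / (max - min)`;
#' `frac_max` divides by the maximum, preserving relative fold change. Both
#' are display conveniences only and are never used in any statistical
#' computation.
#'
#' @param x numeric vector.
#' @param scheme `"zero_one"` or `"frac_max"`.
#' @return The normalized vector.
#' @export
normalize_for_viz <- function(x, scheme = c("zero_one", "frac_max")) {
  scheme <- match.arg(scheme)
  if (scheme == "zero_one") {
    r <- range(x)
    if (diff(r) == 0)
      stop_hw("constant vector cannot be 0-1 normalized",
              class = "hairwave_degenerate_error")
    (x - r[1]) / diff(r)
  } else {
    m <- max(x)
    if (m <= 0)
      stop_hw("frac_max requires a positive maximum",
              class = "hairwave_degenerate_error")
    x / m
  }
}

#' Convert an expression dataset between linear and log2 scales
#'
#' Conversions are explicit; no stage converts behind the caller's back.
#' `log2` of a linear dataset uses `log2(x + offset)` with a small offset to
#' guard exact zeros.
#'
#' @param ds an [expression_dataset()].
#' @param to target scale.
#' @param offset additive guard used only for linear -> log2.
#' @return The converted dataset.
#' @export
convert_scale <- function(ds, to = c("log2", "linear"), offset = 0) {
  to <- match.arg(to)
  stopifnot(inherits(ds, "expr_dataset"))
  if (ds$scale == to) return(ds)
  ds$values <- if (to == "log2") log2(ds$values + offset) else 2^ds$values
  ds$scale <- to
  ds
}
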