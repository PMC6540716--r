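# Feature-table container, TSV I/O, the two feature filters
# (blank-contaminant and singleton removal) and binarization to the
# presence/absence matrix that every downstream statistic consumes.

#' Construct a feature table
#'
#' Bundles a nonnegative samples-by-features intensity matrix with per-sample
#' metadata (species, growth form, plot, region, sample type exudate/blank)
#' and a provenance record of applied filters.
#'
#' @param intensities numeric matrix, samples in rows (row names = sample
#'   ids), features in columns (column names = feature ids).
#' @param metadata data.frame with columns `sample_id`, `species`, `plot`,
#'   `sample_type` (values `exudate`/`blank`); `growth_form` and `region`
#'   are carried along when present.
#' @param provenance list of filter records (internal use).
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(intensities, metadata, provenance = list()) {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop("`intensities` must be a numeric matrix", call. = FALSE)
  }
  required <- c("sample_id", "species", "plot", "sample_type")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols)) {
    stop("schema error: metadata lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyNA(intensities) || any(intensities < 0)) {
    stop("data error: intensities must be nonnegative and non-missing",
         call. = FALSE)
  }
  if (is.null(rownames(intensities)) || is.null(colnames(intensities))) {
    stop("`intensities` needs sample ids as row names and feature ids as column names",
         call. = FALSE)
  }
  if (anyDuplicated(colnames(intensities))) {
    stop("data error: feature ids must be unique", call. = FALSE)
  }
  extra <- setdiff(rownames(intensities), metadata$sample_id)
  if (length(extra)) {
    stop("schema error: samples missing from metadata: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  if (!all(metadata$sample_type %in% c("exudate", "blank"))) {
    stop("schema error: sample_type must be 'exudate' or 'blank'", call. = FALSE)
  }
  metadata <- metadata[match(rownames(intensities), metadata$sample_id), ,
                       drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(intensities = intensities, metadata = metadata,
                 provenance = provenance),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  nb <- sum(x$metadata$sample_type == "blank")
  cat(sprintf("Feature table: %d samples (%d blanks) x %d features\n",
              nrow(x$intensities), nb, ncol(x$intensities)))
  if (length(x$provenance)) {
    cat("Filters applied:\n")
    for (p in x$provenance) {
      cat(sprintf("  - %s (%s): removed %d features\n", p$filter,
                  paste(names(p$params), unlist(p$params), sep = "=",
                        collapse = ", "),
                  length(p$removed)))
    }
  }
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' Read a feature table and its sample metadata from TSV
#'
#' Expects the intensity matrix as a TSV with feature ids in the first
#' column (features in rows, samples in columns, the common export layout)
#' or sample ids in the first column (samples in rows); orientation is
#' resolved against the metadata sample ids. Sample ids must match between
#' the two files; mismatches are reported by name.
#'
#' @param matrix_path path to the intensity TSV.
#' @param metadata_path path to the metadata TSV (columns sample_id,
#'   species, plot, sample_type, optionally growth_form, region).
#' @return a [feature_table()].
#' @export
read_feature_table <- function(matrix_path, metadata_path) {
  for (p in c(matrix_path, metadata_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  raw <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  meta <- utils::read.delim(metadata_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(meta)) {
    stop("schema error: metadata lacks column(s): sample_id", call. = FALSE)
  }
  ids <- raw[[1]]
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  samples_in_rows <- mean(ids %in% meta$sample_id) >=
    mean(colnames(m) %in% meta$sample_id)
  if (!samples_in_rows) m <- t(m)
  missing_meta <- setdiff(rownames(m), meta$sample_id)
  if (length(missing_meta)) {
    stop("sample ids absent from metadata: ",
         paste(missing_meta, collapse = ", "), call. = FALSE)
  }
  missing_mat <- setdiff(meta$sample_id, rownames(m))
  if (length(missing_mat)) {
    stop("metadata sample ids absent from matrix: ",
         paste(missing_mat, collapse = ", "), call. = FALSE)
  }
  feature_table(m, meta)
}

#' Write a feature table to TSV (matrix + metadata)
#'
#' @param table a `feature_table`.
#' @param matrix_path,metadata_path output paths. The matrix is written
#'   samples-in-rows with a leading `sample_id` column.
#' @return invisibly, the paths.
#' @export
write_feature_table <- function(table, matrix_path, metadata_path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(sample_id = rownames(table$intensities),
                   table$intensities, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(table$metadata, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(c(matrix_path, metadata_path))
}

.occurrence <- function(intensities, presence_threshold = 0) {
  colSums(intensities > presence_threshold)
}

#' Remove features prevalent in water controls
#'
#' Drops every feature detected in at least `blank_fraction` of the blank
#' (water-control) samples — the boundary is inclusive, so with four blanks
#' a feature seen in two of them is removed. Blank samples themselves remain
#' in the table until [to_presence_absence()] drops them.
#'
#' @param table a `feature_table` containing at least one blank sample.
#' @param blank_fraction prevalence threshold in blanks (default 0.5).
#' @param presence_threshold intensity strictly above which a feature counts
#'   as present (default 0).
#' @param by_region filter within each region separately and remove the
#'   union (default FALSE: blanks pooled across regions).
#' @return the filtered `feature_table`, with the filter recorded in
#'   `$provenance`.
#' @export
filter_blank_features <- function(table, blank_fraction = 0.5,
                                  presence_threshold = 0,
                                  by_region = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  stopifnot_scalar_number(blank_fraction, "blank_fraction", 0, 1)
  is_blank <- table$metadata$sample_type == "blank"
  if (!any(is_blank)) {
    stop("blank filter not applicable: table contains no blank samples",
         call. = FALSE)
  }
  drop <- if (by_region && "region" %in% names(table$metadata)) {
    regions <- unique(table$metadata$region[is_blank])
    Reduce(`|`, lapply(regions, function(r) {
      sel <- is_blank & table$metadata$region == r
      .occurrence(table$intensities[sel, , drop = FALSE],
                  presence_threshold) >= blank_fraction * sum(sel)
    }))
  } else {
    .occurrence(table$intensities[is_blank, , drop = FALSE],
                presence_threshold) >= blank_fraction * sum(is_blank)
  }
  removed <- colnames(table$intensities)[drop]
  feature_table(
    table$intensities[, !drop, drop = FALSE], table$metadata,
    c(table$provenance,
      list(list(filter = "blank",
                params = list(blank_fraction = blank_fraction,
                              presence_threshold = presence_threshold,
                              by_region = by_region),
                removed = removed)))
  )
}

#' Remove features that occur only once
#'
#' Drops features whose total occurrence count across all exudate samples is
#' at most one. Blank samples do not contribute to the count (a different
#' sample population); set `exudates_only = FALSE` to count over all samples.
#'
#' @param table a `feature_table`.
#' @param presence_threshold intensity strictly above which a feature counts
#'   as present.
#' @param exudates_only count occurrences over exudate samples only
#'   (default TRUE).
#' @return the filtered `feature_table` with provenance updated. Applying
#'   the filter twice is a no-op.
#' @export
filter_singletons <- function(table, presence_threshold = 0,
                              exudates_only = TRUE) {
  stopifnot(inherits(table, "feature_table"))
  sel <- if (exudates_only) table$metadata$sample_type == "exudate" else
    rep(TRUE, nrow(table$intensities))
  occ <- .occurrence(table$intensities[sel, , drop = FALSE],
                     presence_threshold)
  drop <- occ <= 1L
  removed <- colnames(table$intensities)[drop]
  feature_table(
    table$intensities[, !drop, drop = FALSE], table$metadata,
    c(table$provenance,
      list(list(filter = "singleton",
                params = list(presence_threshold = presence_threshold,
                              exudates_only = exudates_only),
                removed = removed)))
  )
}

#' Binarize a feature table to a presence/absence matrix
#'
#' Converts intensities to 0/1 (present iff intensity strictly above
#' `presence_threshold`) and drops blank samples: the result is the
#' samples-by-features binary matrix on which all community statistics
#' operate. Row and column labels are preserved; the provenance of the
#' source table plus the binarization parameters is attached as the
#' `"provenance"` attribute.
#'
#' @param table a `feature_table`.
#' @param presence_threshold intensity threshold (strict inequality;
#'   default 0).
#' @return integer matrix of class `pa_matrix` (exudate samples x features,
#'   entries 0/1).
#' @export
to_presence_absence <- function(table, presence_threshold = 0) {
  stopifnot(inherits(table, "feature_table"))
  keep <- table$metadata$sample_type == "exudate"
  m <- (table$intensities[keep, , drop = FALSE] > presence_threshold) * 1L
  storage.mode(m) <- "integer"
  structure(m,
            provenance = c(table$provenance,
                           list(list(filter = "binarize",
                                     params = list(
                                       presence_threshold = presence_threshold),
                                     removed = character()))),
            metadata = table$metadata[keep, , drop = FALSE],
            class = c("pa_matrix", "matrix", "array"))
}

#' Sample metadata of a presence/absence matrix
#'
#' @param pa a `pa_matrix`.
#' @return the per-sample metadata data.frame carried through binarization.
#' @export
pa_metadata <- function(pa) {
  stopifnot(inherits(pa, "pa_matrix"))
  attr(pa, "metadata")
}
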