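#' Construct a single labeled view
#'
#' A view is one feature matrix (samples x features) from one data source,
#' e.g. gene-level copy number, methylation, or expression measured on a
#' common set of samples.
#'
#' @param matrix Numeric matrix, samples in rows, features in columns.
#' @param name Character scalar naming the view.
#' @param feature_names Character vector of unique feature names; defaults to
#'   the matrix column names.
#' @param sample_ids Optional character vector of unique sample identifiers;
#'   defaults to the matrix row names when present.
#' @return An object of class `mv_view`.
#' @export
mv_view <- function(matrix, name = "view", feature_names = colnames(matrix),
                    sample_ids = rownames(matrix)) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) == 0L) stop("a view must have at least one sample (row)")
  if (is.null(feature_names)) {
    feature_names <- sprintf("f%0*d", nchar(ncol(matrix)), seq_len(ncol(matrix)))
  }
  feature_names <- as.character(feature_names)
  if (length(feature_names) != ncol(matrix)) {
    stop("feature_names length must equal the number of columns")
  }
  if (anyDuplicated(feature_names)) {
    stop("duplicate feature names within view '", name, "'")
  }
  if (!is.null(sample_ids)) {
    sample_ids <- as.character(sample_ids)
    if (length(sample_ids) != nrow(matrix)) {
      stop("sample_ids length must equal the number of rows")
    }
    if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  }
  storage.mode(matrix) <- "double"
  colnames(matrix) <- feature_names
  rownames(matrix) <- sample_ids
  structure(
    list(name = name, matrix = matrix, feature_names = feature_names,
         sample_ids = sample_ids),
    class = "mv_view"
  )
}

#' @export
print.mv_view <- function(x, ...) {
  cat(sprintf("<mv_view '%s': %d samples x %d features>\n",
              x$name, nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' @export
dim.mv_view <- function(x) dim(x$matrix)

#' Construct a labeled multi-view dataset
#'
#' Bundles one or more views that share the same samples (in the same row
#' order) with a binary outcome label per sample.
#'
#' @param views List of [mv_view] objects, all with the same number of rows.
#' @param labels Binary (0/1) label vector, one per sample, or `NULL` for
#'   unlabeled data (supervised operations will refuse it).
#' @param sample_ids Optional character vector of sample identifiers.
#' @return An object of class `mv_dataset`.
#' @export
mv_dataset <- function(views, labels = NULL, sample_ids = NULL) {
  if (inherits(views, "mv_view")) views <- list(views)
  if (length(views) < 1L) stop("need at least one view")
  if (!all(vapply(views, inherits, logical(1), "mv_view"))) {
    stop("all views must be mv_view objects")
  }
  m <- nrow(views[[1L]]$matrix)
  if (!all(vapply(views, function(v) nrow(v$matrix), integer(1)) == m)) {
    stop("all views must have the same number of samples")
  }
  nm <- vapply(views, function(v) v$name, character(1))
  if (anyDuplicated(nm)) stop("view names must be unique")
  names(views) <- nm
  if (!is.null(labels)) {
    labels <- validate_binary_labels(labels, m)
  }
  if (is.null(sample_ids) && !is.null(views[[1L]]$sample_ids)) {
    sample_ids <- views[[1L]]$sample_ids
  }
  structure(
    list(views = views, labels = labels, sample_ids = sample_ids),
    class = "mv_dataset"
  )
}

validate_binary_labels <- function(labels, m = length(labels)) {
  labels <- as.integer(labels)
  if (length(labels) != m) stop("labels length must equal the number of samples")
  if (anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop("labels must be binary (0/1)")
  }
  labels
}

require_both_classes <- function(labels) {
  if (is.null(labels)) stop("this operation requires labels")
  if (length(unique(labels)) < 2L) {
    stop("labels must contain both classes")
  }
  invisible(labels)
}

#' @export
print.mv_dataset <- function(x, ...) {
  cat(sprintf("<mv_dataset: %d views, %d samples%s>\n",
              length(x$views), n_samples(x),
              if (is.null(x$labels)) ", unlabeled"
              else sprintf(", %d positives", sum(x$labels))))
  for (v in x$views) {
    cat(sprintf("  %s: %d features\n", v$name, ncol(v$matrix)))
  }
  invisible(x)
}

#' Number of samples in a dataset or view
#' @param x An `mv_dataset` or `mv_view`.
#' @return Integer sample count.
#' @export
n_samples <- function(x) {
  if (inherits(x, "mv_view")) nrow(x$matrix) else nrow(x$views[[1L]]$matrix)
}

#' Restrict a multi-view dataset to a subset of samples
#'
#' @param mvd An `mv_dataset`.
#' @param idx Integer or logical row index.
#' @return An `mv_dataset` over the selected samples, labels subset in step.
#' @export
subset_samples <- function(mvd, idx) {
  views <- lapply(mvd$views, function(v) {
    mv_view(v$matrix[idx, , drop = FALSE], name = v$name,
            feature_names = v$feature_names,
            sample_ids = if (is.null(v$sample_ids)) NULL else v$sample_ids[idx])
  })
  mv_dataset(views,
             labels = if (is.null(mvd$labels)) NULL else mvd$labels[idx],
             sample_ids = if (is.null(mvd$sample_ids)) NULL else mvd$sample_ids[idx])
}

#' Read one view from a delimited text table
#'
#' The table must carry a header row of feature names. Labels can live in a
#' named column of the same table or in a separate single-column file (one
#' value per sample, header optional). Non-numeric cells become `NA` and are
#' handled downstream by [drop_missing_features()].
#'
#' @param path Path to the delimited file.
#' @param delimiter Field delimiter, default comma.
#' @param labels Either the name of a label column in the table, a path to a
#'   label file, or `NULL` for an unlabeled view.
#' @param sample_id_column Name of a column holding sample identifiers, or
#'   `NULL` if there is none.
#' @param name View name; defaults to the file name without extension.
#' @return A list with elements `view` (an [mv_view]) and `labels` (integer
#'   vector or `NULL`).
#' @export
read_view <- function(path, delimiter = ",", labels = NULL,
                      sample_id_column = NULL, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  tab <- utils::read.table(path, sep = delimiter, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  sample_ids <- NULL
  if (!is.null(sample_id_column)) {
    if (!sample_id_column %in% names(tab)) {
      stop("sample id column '", sample_id_column, "' not found")
    }
    sample_ids <- tab[[sample_id_column]]
    tab[[sample_id_column]] <- NULL
  }
  y <- NULL
  if (!is.null(labels)) {
    if (length(labels) == 1L && labels %in% names(tab)) {
      raw <- tab[[labels]]
      tab[[labels]] <- NULL
    } else if (length(labels) == 1L && file.exists(labels)) {
      raw <- utils::read.table(labels, header = FALSE,
                               stringsAsFactors = FALSE)[[1L]]
      if (length(raw) == nrow(tab) + 1L && is.na(suppressWarnings(as.numeric(raw[1L])))) {
        raw <- raw[-1L]  # tolerate a header line
      }
    } else {
      stop("labels must name a column of the table or an existing file")
    }
    yv <- suppressWarnings(as.numeric(raw))
    if (anyNA(yv) || !all(yv %in% c(0, 1))) {
      stop("labels must be binary (0/1); got: ",
           paste(utils::head(unique(raw)), collapse = ", "))
    }
    y <- as.integer(yv)
    if (length(y) != nrow(tab)) stop("label count does not match sample count")
  }
  mat <- vapply(tab, function(col) suppressWarnings(as.numeric(col)),
                numeric(nrow(tab)))
  if (nrow(tab) == 1L) mat <- matrix(mat, nrow = 1L, dimnames = list(NULL, names(tab)))
  list(view = mv_view(mat, name = name, feature_names = names(tab),
                      sample_ids = sample_ids),
       labels = y)
}

#' Write a view to a delimited text table
#'
#' @param view An `mv_view`.
#' @param path Output path.
#' @param delimiter Field delimiter.
#' @return `path`, invisibly.
#' @export
write_view <- function(view, path, delimiter = ",") {
  df <- as.data.frame(view$matrix, check.names = FALSE)
  if (!is.null(view$sample_ids)) {
    df <- cbind(sample_id = view$sample_ids, df)
  }
  utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Align several views on their common samples
#'
#' Multi-omics sources rarely cover identical patient sets; only samples
#' present in every view (and, when given, in the label vector) are retained.
#' The output sample order is the lexicographic sort of the shared ids so the
#' result does not depend on input order.
#'
#' @param views List of `mv_view` objects, each carrying sample ids.
#' @param labels Optional named vector of binary labels (names = sample ids).
#' @return An `mv_dataset` over the intersection of sample ids, with an
#'   attribute `"dropped"` giving per-view counts of discarded samples.
#' @export
align_views <- function(views, labels = NULL) {
  if (inherits(views, "mv_view")) views <- list(views)
  ids <- lapply(views, function(v) {
    if (is.null(v$sample_ids)) stop("view '", v$name, "' has no sample ids")
    v$sample_ids
  })
  common <- Reduce(intersect, ids)
  if (!is.null(labels)) {
    if (is.null(names(labels))) stop("labels must be named by sample id")
    common <- intersect(common, names(labels))
  }
  if (length(common) == 0L) stop("no samples shared by all views")
  common <- sort(common)
  dropped <- vapply(views, function(v) length(v$sample_ids) - length(common),
                    integer(1))
  names(dropped) <- vapply(views, function(v) v$name, character(1))
  aligned <- lapply(views, function(v) {
    ix <- match(common, v$sample_ids)
    mv_view(v$matrix[ix, , drop = FALSE], name = v$name,
            feature_names = v$feature_names, sample_ids = common)
  })
  y <- if (is.null(labels)) NULL else validate_binary_labels(labels[common])
  out <- mv_dataset(aligned, labels = y, sample_ids = common)
  attr(out, "dropped") <- dropped
  out
}

#' Drop features containing missing values
#'
#' @param view An `mv_view`.
#' @return The view restricted to columns with no missing entries. Warns when
#'   nothing survives.
#' @export
drop_missing_features <- function(view) {
  keep <- !apply(is.na(view$matrix), 2L, any)
  if (!any(keep)) warning("all features contain missing values; empty view")
  mv_view(view$matrix[, keep, drop = FALSE], name = view$name,
          feature_names = view$feature_names[keep],
          sample_ids = view$sample_ids)
}

#' Rescale values to the unit interval
#'
#' Applies `(x - min) / (max - min)` along the chosen axis. Constant slices
#' map to all zeros (so a later variance filter removes them cleanly) rather
#' than `NaN`.
#'
#' @param view An `mv_view` with no missing values.
#' @param axis `"per_feature"` (default) rescales each column; `"per_sample"`
#'   rescales each row.
#' @return The rescaled view.
#' @export
rescale_unit_interval <- function(view, axis = c("per_feature", "per_sample")) {
  axis <- match.arg(axis)
  if (anyNA(view$matrix)) stop("rescaling requires complete data; run drop_missing_features first")
  scale01 <- function(x) {
    r <- range(x)
    if (r[1L] == r[2L]) return(rep(0, length(x)))
    (x - r[1L]) / (r[2L] - r[1L])
  }
  m <- if (axis == "per_feature") {
    apply(view$matrix, 2L, scale01)
  } else {
    t(apply(view$matrix, 1L, scale01))
  }
  if (nrow(view$matrix) == 1L && axis == "per_feature") {
    m <- matrix(m, nrow = 1L)
  }
  dimnames(m) <- dimnames(view$matrix)
  mv_view(m, name = view$name, feature_names = view$feature_names,
          sample_ids = view$sample_ids)
}

#' Remove low-variance features
#'
#' Keeps the columns whose population variance (divisor `m`) is at least
#' `threshold`; features with variance strictly below it are removed.
#'
#' @param view An `mv_view`.
#' @param threshold Variance cutoff, default 0.02 (tuned to data already
#'   rescaled to the unit interval).
#' @return The filtered view.
#' @export
variance_filter <- function(view, threshold = 0.02) {
  if (anyNA(view$matrix)) stop("variance filter requires complete data")
  m <- nrow(view$matrix)
  mu <- colMeans(view$matrix)
  v <- colMeans(view$matrix^2) - mu^2
  v <- pmax(v, 0)  # guard tiny negative rounding
  keep <- v >= threshold
  mv_view(view$matrix[, keep, drop = FALSE], name = view$name,
          feature_names = view$feature_names[keep],
          sample_ids = view$sample_ids)
}

#' Standard preprocessing pipeline for one view
#'
#' Drops features with missing values, rescales to the unit interval and
#' removes low-variance features, in that order.
#'
#' @inheritParams rescale_unit_interval
#' @inheritParams variance_filter
#' @return The preprocessed view.
#' @export
preprocess_view <- function(view, axis = "per_feature", threshold = 0.02) {
  variance_filter(rescale_unit_interval(drop_missing_features(view),
                                        axis = axis),
                  threshold = threshold)
}

#' Binary survival labels from follow-up time and vital status
#'
#' Samples surviving at least `cutoff` years are long-term survivors (1).
#' Samples with shorter follow-up are short-term survivors (0) only when
#' deceased (vital status 0); living samples censored before the cutoff are
#' uninformative and are excluded.
#'
#' @param times Survival/follow-up time in years.
#' @param vital_status 0 = deceased, 1 = alive at last follow-up.
#' @param cutoff Years separating long- from short-term survival, default 3.
#' @return A list with `labels` (integer, `NA` where excluded) and `keep`
#'   (logical inclusion mask).
#' @export
label_survival <- function(times, vital_status, cutoff = 3) {
  if (length(times) != length(vital_status)) {
    stop("times and vital_status must have the same length")
  }
  if (any(times < 0, na.rm = TRUE)) stop("negative survival times")
  lab <- rep(NA_integer_, length(times))
  lab[times >= cutoff] <- 1L
  lab[times < cutoff & vital_status == 0] <- 0L
  list(labels = lab, keep = !is.na(lab))
}

#' Construct a selection result
#'
#' Records, for a multi-view selection, which feature indices were chosen in
#' each view and the global order in which they were picked.
#'
#' @param selection_order Data frame with integer columns `view` and
#'   `feature`, one row per selection step in order.
#' @param n_views Number of views the selection is over.
#' @param view_names Optional view names.
#' @param feature_names Optional list (per view) of feature name vectors used
#'   to attach names to indices.
#' @return An object of class `selection_result` with fields
#'   `per_view_indices` (list of integer vectors) and `selection_order`.
#' @export
selection_result <- function(selection_order, n_views,
                             view_names = NULL, feature_names = NULL) {
  stopifnot(is.data.frame(selection_order),
            all(c("view", "feature") %in% names(selection_order)))
  so <- selection_order[, c("view", "feature")]
  so$view <- as.integer(so$view)
  so$feature <- as.integer(so$feature)
  key <- paste(so$view, so$feature)
  if (anyDuplicated(key)) stop("a feature was selected twice")
  per_view <- lapply(seq_len(n_views), function(t) so$feature[so$view == t])
  if (!is.null(view_names)) names(per_view) <- view_names
  structure(
    list(per_view_indices = per_view, selection_order = so,
         view_names = view_names, feature_names = feature_names),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result: %d features over %d views>\n",
              nrow(x$selection_order), length(x$per_view_indices)))
  for (t in seq_along(x$per_view_indices)) {
    nm <- if (!is.null(x$view_names)) x$view_names[t] else paste0("view", t)
    cat(sprintf("  %s: %s\n", nm,
                paste(x$per_view_indices[[t]], collapse = ", ")))
  }
  invisible(x)
}

#' @export
length.selection_result <- function(x) nrow(x$selection_order)

#' Selected feature names per view
#'
#' @param selection A `selection_result` whose `feature_names` field is set.
#' @return Named list mapping view name to selected feature names, in
#'   selection order within each view.
#' @export
selected_feature_names <- function(selection) {
  if (is.null(selection$feature_names)) {
    stop("selection carries no feature names")
  }
  out <- lapply(seq_along(selection$per_view_indices), function(t) {
    selection$feature_names[[t]][selection$per_view_indices[[t]]]
  })
  names(out) <- selection$view_names %||%
    paste0("view", seq_along(selection$per_view_indices))
  out
}

#' Serialize a selection to JSON
#'
#' Writes the standard `{view_name: [feature_name, ...]}` document.
#'
#' @param selection A `selection_result` carrying feature names.
#' @param path Output path; `NULL` returns the JSON string.
#' @return The JSON string, invisibly when written to a file.
#' @export
selection_to_json <- function(selection, path = NULL) {
  doc <- selected_feature_names(selection)
  js <- jsonlite::toJSON(doc, auto_unbox = FALSE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
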