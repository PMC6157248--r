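# Registry of Stage-I / Stage-II filter kinds. A filter fit function takes
# (view, labels, params, seed) and returns the selected feature indices of
# that view; multi-view Stage-II kinds instead take an mv_dataset and return
# a selection_result.
.filter_registry <- new.env(parent = emptyenv())

#' Register a custom view-specific filter kind
#'
#' @param name Filter kind name.
#' @param fit_fun Function `(view, labels, params, seed)` returning an
#'   integer vector of selected feature indices.
#' @return `name`, invisibly.
#' @export
register_filter <- function(name, fit_fun) {
  stopifnot(is.character(name), is.function(fit_fun))
  assign(name, fit_fun, envir = .filter_registry)
  invisible(name)
}

#' Declare a filter for the two-stage pipeline
#'
#' @param kind One of `"all_filter"` (pass everything through),
#'   `"embedded_l1"` (see [embedded_sparse_filter()]), `"mrmr"`
#'   ([mrmr_select()]), `"mrmr_mv"` ([mrmr_mv_select()], Stage II only), or
#'   a name registered via [register_filter()].
#' @param params Named list of parameters forwarded to the filter
#'   (e.g. `k`, `f`, `exponent`, `p`, `strength`, `top_n`).
#' @param enabled Gate signal: a disabled Stage-I filter passes no data to
#'   Stage II (its view is effectively deleted).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(kind, params = list(), enabled = TRUE) {
  builtin <- c("all_filter", "embedded_l1", "mrmr", "mrmr_mv", "chain")
  if (!kind %in% builtin && !exists(kind, envir = .filter_registry)) {
    stop("unknown filter kind '", kind, "'")
  }
  structure(list(kind = kind, params = params, enabled = isTRUE(enabled)),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec %s%s%s>\n", x$kind,
              if (length(x$params)) paste0("(", paste(names(x$params),
                vapply(x$params, function(p) paste(format(p), collapse = ","),
                       character(1)), sep = "=", collapse = ", "), ")") else "",
              if (x$enabled) "" else " [disabled]"))
  invisible(x)
}

# fit a single-view filter spec -> integer indices into the view's columns
fit_single_view_filter <- function(spec, view, labels, seed = NULL) {
  pr <- spec$params
  switch(spec$kind,
    all_filter = seq_len(ncol(view$matrix)),
    embedded_l1 = embedded_sparse_filter(
      view, labels,
      strength = pr$strength %||% 1e-4,
      top_n = pr$top_n %||% 100L
    ),
    mrmr = mrmr_select(view, labels,
                       k = pr$k %||% stop("mrmr filter needs params$k"),
                       f = pr$f %||% "f_stat",
                       exponent = pr$exponent %||% 2,
                       bins = pr$bins %||% 10L)$per_view_indices[[1L]],
    mrmr_mv = stop("mrmr_mv is a multi-view filter; use it as Stage II"),
    chain = {
      # apply sub-filters sequentially within the view
      idx <- seq_len(ncol(view$matrix))
      for (sub in pr$filters) {
        if (length(idx) == 0L) break
        subview <- mv_view(view$matrix[, idx, drop = FALSE], name = view$name,
                           feature_names = view$feature_names[idx],
                           sample_ids = view$sample_ids)
        k_sub <- sub$params$k
        if (!is.null(k_sub) && sub$kind == "mrmr" && k_sub > length(idx)) {
          sub$params$k <- length(idx)  # chained selector cannot exceed input
        }
        idx <- idx[fit_single_view_filter(sub, subview, labels, seed = seed)]
      }
      idx
    },
    get(spec$kind, envir = .filter_registry)(view, labels, pr, seed)
  )
}

#' L1-embedded sparse linear filter
#'
#' Fits an L1-penalized linear classifier (lasso logistic model, via glmnet)
#' at a fixed regularization strength and ranks features by the absolute
#' value of their coefficients, nonzero coefficients first. Returns the top
#' `top_n` feature indices; when fewer coefficients are nonzero than
#' `top_n`, the ranking falls back to coefficient magnitude over all
#' features (zeros keep their original column order).
#'
#' @param view An [mv_view] or numeric matrix.
#' @param labels Binary 0/1 labels with both classes present.
#' @param strength L1 regularization strength (glmnet `lambda`),
#'   default 1e-4.
#' @param top_n Number of features to return, default 100.
#' @return Integer vector of at most `top_n` feature indices, ranked.
#' @export
embedded_sparse_filter <- function(view, labels, strength = 1e-4,
                                   top_n = 100L) {
  X <- if (inherits(view, "mv_view")) view$matrix else as.matrix(view)
  labels <- validate_binary_labels(labels, nrow(X))
  require_both_classes(labels)
  n <- ncol(X)
  top_n <- min(as.integer(top_n), n)
  if (n == 1L) return(1L)
  fit <- glmnet::glmnet(X, factor(labels), family = "binomial",
                        alpha = 1, lambda = strength, standardize = TRUE)
  coefs <- abs(as.numeric(fit$beta))
  ord <- order(-coefs, seq_len(n))  # magnitude desc, index asc on ties
  ord[seq_len(top_n)]
}

#' Assemble a two-stage feature selection pipeline
#'
#' Stage I holds one gated view-specific filter per view; a disabled filter
#' passes no data downstream. Stage II holds a single filter applied either
#' to the concatenation of the surviving views (single-view kinds) or to the
#' surviving multi-view data as such (`"mrmr_mv"`).
#'
#' @param stage1 A single `filter_spec` recycled over all views, or a list
#'   with one `filter_spec` per view.
#' @param stage2 A `filter_spec`.
#' @return An object of class `two_stage_pipeline` (unfitted).
#' @export
two_stage_pipeline <- function(stage1 = filter_spec("all_filter"),
                               stage2 = filter_spec("all_filter")) {
  if (inherits(stage1, "filter_spec")) stage1 <- list(stage1)
  stopifnot(all(vapply(stage1, inherits, logical(1), "filter_spec")),
            inherits(stage2, "filter_spec"))
  structure(list(stage1 = stage1, stage2 = stage2, fitted_state = NULL),
            class = "two_stage_pipeline")
}

#' @export
print.two_stage_pipeline <- function(x, ...) {
  cat("<two_stage_pipeline", if (is.null(x$fitted_state)) "(unfitted)>" else "(fitted)>", "\n")
  invisible(x)
}

expand_stage1 <- function(pipeline, v) {
  s1 <- pipeline$stage1
  if (length(s1) == 1L && v > 1L) s1 <- rep(s1, v)
  if (length(s1) != v) {
    stop("stage1 must have one filter per view (", v, " views)")
  }
  s1
}

#' Fit the two-stage pipeline on a labeled multi-view dataset
#'
#' Training mode: every enabled Stage-I filter learns its feature subset
#' from its own view; Stage II then learns the final selection from the
#' filtered (concatenated or multi-view) data. The learned state is a pure
#' per-view list of selected feature names, so applying the fitted pipeline
#' is a column projection.
#'
#' @param pipeline A [two_stage_pipeline()].
#' @param mvd A labeled [mv_dataset].
#' @param seed Optional seed forwarded to stochastic Stage-II filters
#'   (the multi-view schedule).
#' @return The fitted pipeline; `fitted_state` holds `stage1_features`,
#'   `selected` (per-view feature names) and the Stage-II
#'   `selection` object.
#' @export
fit_pipeline <- function(pipeline, mvd, seed = NULL) {
  stopifnot(inherits(pipeline, "two_stage_pipeline"),
            inherits(mvd, "mv_dataset"))
  require_both_classes(mvd$labels)
  v <- length(mvd$views)
  s1 <- expand_stage1(pipeline, v)
  enabled <- vapply(s1, function(s) s$enabled, logical(1))
  if (!any(enabled)) stop("all Stage-I filters are disabled")

  stage1_features <- stats::setNames(vector("list", v), names(mvd$views))
  kept_views <- list()
  for (t in seq_len(v)) {
    if (!enabled[t]) next
    idx <- sort(fit_single_view_filter(s1[[t]], mvd$views[[t]], mvd$labels,
                                       seed = seed))
    stage1_features[[t]] <- mvd$views[[t]]$feature_names[idx]
    kept_views[[length(kept_views) + 1L]] <- mv_view(
      mvd$views[[t]]$matrix[, idx, drop = FALSE],
      name = mvd$views[[t]]$name,
      feature_names = mvd$views[[t]]$feature_names[idx],
      sample_ids = mvd$views[[t]]$sample_ids
    )
  }
  filtered <- mv_dataset(kept_views, labels = mvd$labels,
                         sample_ids = mvd$sample_ids)

  s2 <- pipeline$stage2
  if (s2$kind == "mrmr_mv") {
    pr <- s2$params
    sel <- mrmr_mv_select(filtered,
                          k = pr$k %||% stop("mrmr_mv filter needs params$k"),
                          p = pr[["p"]], f = pr[["f"]] %||% "f_stat",
                          exponent = pr$exponent %||% 2,
                          bins = pr$bins %||% 10L, seed = seed)
    selected <- selected_feature_names(sel)
  } else {
    # single-view Stage II on the concatenation; names prefixed with the
    # view name to stay unique across sources sharing gene symbols
    concat <- concat_views(filtered)
    idx <- fit_single_view_filter(s2, concat$view, mvd$labels, seed = seed)
    sel <- selection_result(data.frame(view = 1L, feature = as.integer(idx)),
                            n_views = 1L, view_names = concat$view$name,
                            feature_names = list(concat$view$feature_names))
    picked <- concat$origin[idx, , drop = FALSE]
    selected <- lapply(seq_along(filtered$views), function(t) {
      filtered$views[[t]]$feature_names[picked$feature[picked$view == t]]
    })
    names(selected) <- names(filtered$views)
  }
  # every input view appears in the manifest; gated-off or unselected views
  # carry an empty feature list
  full <- stats::setNames(vector("list", v), names(mvd$views))
  for (nm in names(full)) full[[nm]] <- selected[[nm]] %||% character(0)
  pipeline$fitted_state <- list(stage1_features = stage1_features,
                                selected = full, selection = sel)
  pipeline
}

# concatenate a multi-view dataset into one view with view-prefixed names;
# origin maps concatenated columns back to (view, feature) of the input
concat_views <- function(mvd) {
  mats <- lapply(mvd$views, function(v) v$matrix)
  names_pref <- unlist(lapply(mvd$views, function(v) {
    paste(v$name, v$feature_names, sep = ".")
  }), use.names = FALSE)
  sizes <- vapply(mvd$views, function(v) ncol(v$matrix), integer(1))
  origin <- data.frame(view = rep(seq_along(sizes), sizes),
                       feature = unlist(lapply(sizes, seq_len), use.names = FALSE))
  X <- do.call(cbind, mats)
  colnames(X) <- names_pref
  list(view = mv_view(X, name = "concat", feature_names = names_pref,
                      sample_ids = mvd$sample_ids),
       origin = origin)
}

#' Apply a fitted pipeline to (new) data
#'
#' Test mode: a pure column projection, keyed by feature name, onto the
#' selection learned by [fit_pipeline()]. No re-learning happens. Views that
#' contributed no selected feature are dropped from the output.
#'
#' @param pipeline A fitted [two_stage_pipeline()].
#' @param mvd An [mv_dataset] whose views contain (at least) the selected
#'   feature names.
#' @return The reduced `mv_dataset`.
#' @export
transform_pipeline <- function(pipeline, mvd) {
  st <- pipeline$fitted_state
  if (is.null(st)) stop("pipeline is not fitted")
  out_views <- list()
  for (nm in names(st$selected)) {
    feats <- st$selected[[nm]]
    if (length(feats) == 0L) next
    if (!nm %in% names(mvd$views)) stop("view '", nm, "' missing from input")
    vw <- mvd$views[[nm]]
    ix <- match(feats, vw$feature_names)
    if (anyNA(ix)) {
      stop("view '", nm, "' is missing selected feature(s): ",
           paste(feats[is.na(ix)], collapse = ", "))
    }
    out_views[[length(out_views) + 1L]] <- mv_view(
      vw$matrix[, ix, drop = FALSE], name = nm, feature_names = feats,
      sample_ids = vw$sample_ids)
  }
  if (length(out_views) == 0L) stop("fitted selection is empty")
  mv_dataset(out_views, labels = mvd$labels, sample_ids = mvd$sample_ids)
}

#' Serialize a fitted pipeline's selection manifest
#'
#' @param pipeline A fitted pipeline.
#' @param path Output path; `NULL` returns the JSON string.
#' @return JSON `{view_name: [feature_name, ...]}`.
#' @export
pipeline_manifest <- function(pipeline, path = NULL) {
  st <- pipeline$fitted_state
  if (is.null(st)) stop("pipeline is not fitted")
  js <- jsonlite::toJSON(st$selected, auto_unbox = FALSE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
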