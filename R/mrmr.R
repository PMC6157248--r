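#' Greedy MRMR score of a candidate feature
#'
#' The criterion balances relevance to the outcome against redundancy with
#' the already-selected set `S`:
#' \deqn{f(x_j, y) - \frac{1}{|S|^e} \sum_{l \in S} g(x_j, x_l)}
#' with the redundancy divisor exponent `e = 2` by default; `e = 1` gives the
#' classical mean-redundancy variant.
#'
#' @param view An [mv_view] (or bare numeric matrix).
#' @param labels Binary 0/1 labels.
#' @param j Candidate feature index (must not already be selected).
#' @param selected Integer vector of already-selected feature indices,
#'   length >= 1.
#' @param f Relevance function name (see [relevance_scores()]).
#' @param exponent Redundancy divisor exponent, 1 or 2.
#' @param bins Bin count for the mutual-information relevance.
#' @param relevance_cache Optional precomputed relevance vector over all
#'   features, used instead of recomputation.
#' @return The scalar greedy criterion value (may be negative).
#' @export
mrmr_score <- function(view, labels, j, selected, f = "f_stat",
                       exponent = 2, bins = 10L, relevance_cache = NULL) {
  X <- if (inherits(view, "mv_view")) view$matrix else as.matrix(view)
  if (length(selected) < 1L) stop("selected set must be non-empty")
  if (j %in% selected) stop("candidate ", j, " is already selected")
  rel <- if (!is.null(relevance_cache)) {
    relevance_cache[j]
  } else if (f == "cfm") {
    cfm_relevance(X[, j], labels, pool = X, bins = bins)
  } else {
    relevance(X[, j], labels, method = f, bins = bins)
  }
  red <- sum(vapply(selected, function(l) abs_pearson(X[, j], X[, l]),
                    numeric(1)))
  rel - red / length(selected)^exponent
}

#' Single-view greedy MRMR feature selection
#'
#' Selects `k` features from one view: the first is the feature with maximal
#' relevance to the labels; each subsequent pick maximizes [mrmr_score()]
#' over the remaining candidates. Ties at the argmax go to the lowest feature
#' index, and selection continues even when all remaining scores are
#' negative (the only stopping rule is `k`).
#'
#' @param view An [mv_view] or numeric matrix (samples x features).
#' @param labels Binary 0/1 labels with both classes present.
#' @param k Number of features to select, `1 <= k <=` feature count.
#' @param f Relevance function name; for `"cfm"` the normalization pool is
#'   the view's full feature set, fixed for the whole run.
#' @param exponent Redundancy divisor exponent (2 as in the printed
#'   criterion; 1 for the classical variant).
#' @param bins Bin count for the mutual-information relevance.
#' @param use_cache Precompute relevance scores and accumulate redundancy
#'   sums incrementally (default). `FALSE` recomputes every term from
#'   scratch at every step; the selection is identical either way.
#' @return A [selection_result] over this single view.
#' @export
mrmr_select <- function(view, labels, k, f = "f_stat", exponent = 2,
                        bins = 10L, use_cache = TRUE) {
  v <- if (inherits(view, "mv_view")) view else mv_view(as.matrix(view))
  X <- v$matrix
  n <- ncol(X)
  labels <- validate_binary_labels(labels, nrow(X))
  require_both_classes(labels)
  if (k < 1L) stop("k must be positive")
  if (k > n) stop("k = ", k, " exceeds the number of features (", n, ")")

  rel <- relevance_scores(X, labels, method = f, bins = bins)
  selected <- integer(0)
  if (use_cache) {
    red_sum <- numeric(n)  # sum over selected of g(x_j, x_l), per candidate j
    for (step in seq_len(k)) {
      score <- if (step == 1L) rel else rel - red_sum / length(selected)^exponent
      score[selected] <- -Inf
      pick <- which.max(score)
      selected <- c(selected, pick)
      if (step < k) red_sum <- red_sum + abs_pearson_cols(X, X[, pick])
    }
  } else {
    for (step in seq_len(k)) {
      cand <- setdiff(seq_len(n), selected)
      score <- if (step == 1L) {
        rel[cand]
      } else {
        vapply(cand, function(j) {
          mrmr_score(v, labels, j, selected, f = f, exponent = exponent,
                     bins = bins, relevance_cache = rel)
        }, numeric(1))
      }
      selected <- c(selected, cand[which.max(score)])
    }
  }
  selection_result(data.frame(view = 1L, feature = selected),
                   n_views = 1L, view_names = v$name,
                   feature_names = list(v$feature_names))
}
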