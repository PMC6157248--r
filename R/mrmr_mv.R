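#' View-importance sampling distribution
#'
#' Validates a probability vector `P = (p_1 ... p_v)` giving each view's
#' prior chance of contributing the next selected feature.
#'
#' @param p Numeric vector of nonnegative probabilities summing to 1
#'   (within 1e-9).
#' @return The validated numeric vector.
#' @export
view_distribution <- function(p) {
  p <- as.numeric(p)
  if (length(p) < 1L) stop("P must have at least one entry")
  if (any(p < 0)) stop("P must be nonnegative")
  if (abs(sum(p) - 1) > 1e-9) stop("P must sum to 1 (got ", sum(p), ")")
  p
}

#' Sample a view schedule
#'
#' Draws `k - 1` view indices with replacement from the categorical
#' distribution `P`. The schedule covers selection steps 2..k; the first
#' selection is the globally most relevant feature and is not drawn from `P`.
#'
#' @param p View sampling distribution (see [view_distribution()]).
#' @param k Total number of features to be selected (>= 1).
#' @param seed Optional integer seed making the draw reproducible without
#'   touching the global RNG state.
#' @return Integer vector of `k - 1` view indices (possibly empty).
#' @export
sample_view_schedule <- function(p, k, seed = NULL) {
  p <- view_distribution(p)
  if (k < 1L) stop("k must be positive")
  if (k == 1L) return(integer(0))
  draw <- function() sample.int(length(p), k - 1L, replace = TRUE, prob = p)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Globally most relevant feature across all views
#'
#' @param mvd A labeled [mv_dataset].
#' @param f Relevance function name.
#' @param bins Bin count for the mutual-information relevance.
#' @param relevance_cache Optional list of per-view relevance vectors.
#' @return Integer vector `c(view, feature)`; ties go to the lowest view
#'   index, then the lowest feature index.
#' @export
global_max_relevance <- function(mvd, f = "f_stat", bins = 10L,
                                 relevance_cache = NULL) {
  if (all(vapply(mvd$views, function(v) ncol(v$matrix), integer(1)) == 0L)) {
    stop("all views are empty")
  }
  rel <- relevance_cache %||% relevance_by_view(mvd, method = f, bins = bins)
  best <- c(NA_integer_, NA_integer_); best_val <- -Inf
  for (t in seq_along(rel)) {
    if (length(rel[[t]]) == 0L) next
    j <- which.max(rel[[t]])
    if (rel[[t]][j] > best_val) {  # strict: earlier views win ties
      best_val <- rel[[t]][j]
      best <- c(t, j)
    }
  }
  best
}

#' Multi-view greedy MRMR feature selection
#'
#' Extends the greedy MRMR criterion to several views. A schedule of `k - 1`
#' views is sampled with replacement from the view-importance distribution
#' `P`; the first selection is the globally most relevant feature across all
#' views (regardless of `P`); each subsequent step picks, from the scheduled
#' view's remaining candidates, the feature maximizing
#' \deqn{f(x_j, y) - \frac{1}{|S_{all}|^e} \sum_{l \in S_{all}} g(x_j, x_l)}
#' where \eqn{S_{all}} is the union of selections from every view so far —
#' the redundancy penalty therefore acts across views, which lets the
#' algorithm keep complementary features and discard cross-view copies.
#'
#' When a scheduled view has no candidates left, that step's view is redrawn
#' from `P` restricted (and renormalized) to views with remaining
#' candidates, so exactly `k` features are always returned when the dataset
#' has at least `k` features in total.
#'
#' @param mvd A labeled [mv_dataset].
#' @param k Total number of features to select.
#' @param p View sampling distribution; default uniform across views.
#' @param f Relevance function name; for `"cfm"` normalization spans the
#'   union of all views' features, so scores are comparable across views.
#' @param exponent Redundancy divisor exponent (default 2, as printed in the
#'   single-view criterion).
#' @param seed Integer seed determining the schedule; selection is
#'   deterministic given the schedule.
#' @param schedule Optional explicit schedule (integer vector, length
#'   `k - 1`) overriding sampling.
#' @param bins Bin count for the mutual-information relevance.
#' @param zero_redundancy If `TRUE`, the redundancy term is dropped
#'   (pure per-view relevance ranking under the same schedule) — useful for
#'   ablation comparisons.
#' @return A [selection_result]; attribute `"schedule"` holds the sampled
#'   schedule and `"schedule_used"` the views actually drawn after any
#'   exhaustion fallbacks.
#' @export
mrmr_mv_select <- function(mvd, k, p = NULL, f = "f_stat", exponent = 2,
                           seed = NULL, schedule = NULL, bins = 10L,
                           zero_redundancy = FALSE) {
  stopifnot(inherits(mvd, "mv_dataset"))
  require_both_classes(mvd$labels)
  v <- length(mvd$views)
  sizes <- vapply(mvd$views, function(vw) ncol(vw$matrix), integer(1))
  if (k < 1L) stop("k must be positive")
  if (k > sum(sizes)) {
    stop("k = ", k, " exceeds the total number of features (", sum(sizes), ")")
  }
  p <- if (is.null(p)) rep(1 / v, v) else view_distribution(p)
  if (length(p) != v) stop("P must have one probability per view")

  rng <- if (is.null(seed)) NULL else seed
  if (is.null(schedule)) {
    schedule <- sample_view_schedule(p, k, seed = rng)
  } else {
    schedule <- as.integer(schedule)
    if (length(schedule) != k - 1L) stop("schedule must have k - 1 entries")
    if (any(schedule < 1L | schedule > v)) stop("schedule entries out of range")
  }

  rel <- relevance_by_view(mvd, method = f, bins = bins)
  # per-view accumulated redundancy of each candidate against S_all
  red_sum <- lapply(sizes, numeric)
  n_sel <- integer(v)
  order_view <- integer(k); order_feat <- integer(k)
  selected <- lapply(sizes, function(n) logical(n))

  add_pick <- function(t, j, step) {
    selected[[t]][j] <<- TRUE
    n_sel[t] <<- n_sel[t] + 1L
    order_view[step] <<- t; order_feat[step] <<- j
    if (step < k && !zero_redundancy) {
      xl <- mvd$views[[t]]$matrix[, j]
      for (u in seq_len(v)) {
        red_sum[[u]] <<- red_sum[[u]] + abs_pearson_cols(mvd$views[[u]]$matrix, xl)
      }
    }
  }

  first <- global_max_relevance(mvd, f = f, relevance_cache = rel)
  add_pick(first[1L], first[2L], 1L)

  schedule_used <- integer(k - 1L)
  # exhaustion fallback: redraw from P restricted to views with candidates,
  # on a seed-derived stream so runs stay reproducible
  fallback_i <- 0L
  redraw <- function(open_views) {
    fallback_i <<- fallback_i + 1L
    probs <- p[open_views]
    if (sum(probs) == 0) probs <- rep(1, length(open_views))
    pick <- function() open_views[sample.int(length(open_views), 1L, prob = probs)]
    if (is.null(rng)) pick() else withr::with_seed(rng + fallback_i, pick())
  }

  for (step in seq_len(k - 1L)) {
    t <- schedule[step]
    if (n_sel[t] >= sizes[t]) {
      open <- which(n_sel < sizes)
      t <- if (length(open) == 1L) open else redraw(open)
    }
    schedule_used[step] <- t
    total_sel <- sum(n_sel)
    score <- rel[[t]]
    if (!zero_redundancy) score <- score - red_sum[[t]] / total_sel^exponent
    score[selected[[t]]] <- -Inf
    add_pick(t, which.max(score), step + 1L)
  }

  out <- selection_result(
    data.frame(view = order_view, feature = order_feat),
    n_views = v, view_names = names(mvd$views),
    feature_names = lapply(mvd$views, function(vw) vw$feature_names)
  )
  attr(out, "schedule") <- schedule
  attr(out, "schedule_used") <- schedule_used
  out
}
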