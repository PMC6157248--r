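#' Absolute Pearson correlation between two features
#'
#' The redundancy measure used by the greedy selection criterion: similarity
#' of two feature vectors as `|r|` in `[0, 1]`. A constant vector carries no
#' signal, so its redundancy with anything is defined as 0 rather than `NaN`.
#'
#' @param a,b Numeric vectors of equal length (>= 2).
#' @return `|Pearson r|`, a number in `[0, 1]`.
#' @export
abs_pearson <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (length(a) < 2L) stop("need at least two samples")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  min(abs(stats::cor(a, b)), 1)
}

# |cor| of every column of X against vector b; zero-variance columns (or b) -> 0
abs_pearson_cols <- function(X, b) {
  if (stats::sd(b) == 0) return(rep(0, ncol(X)))
  sds <- apply(X, 2L, stats::sd)
  r <- rep(0, ncol(X))
  ok <- sds > 0
  if (any(ok)) {
    r[ok] <- abs(as.vector(stats::cor(X[, ok, drop = FALSE], b)))
  }
  pmin(r, 1)
}

#' Univariate relevance of features for a binary outcome
#'
#' Scores every column of `X` against the labels with one of the field's
#' standard filter statistics:
#'
#' * `chi2` — the one-feature chi-squared statistic for nonnegative data:
#'   per-class column sums are compared with the totals expected under label
#'   independence, \eqn{\sum_c (O_c - E_c)^2 / E_c}.
#' * `f_stat` — the one-way ANOVA F statistic between the two class groups.
#'   Perfectly separated features (zero within-class variance) score `Inf`.
#' * `mutual_information` — a deterministic plug-in estimate: the feature is
#'   discretized into `bins` equal-width bins over its observed range and the
#'   discrete mutual information with the labels is computed in nats.
#' * `cfm` — the consensus of the three: each statistic is min-max normalized
#'   to `[0, 1]` across the candidate pool (the columns of `X`), then
#'   averaged with equal weights.
#'
#' @param X Numeric matrix (samples x features), complete; nonnegative when
#'   `method = "chi2"`.
#' @param y Binary 0/1 labels with both classes present.
#' @param method One of `"chi2"`, `"f_stat"`, `"mutual_information"`, `"cfm"`.
#' @param bins Bin count for the mutual-information estimator.
#' @return Numeric vector of nonnegative scores, one per column.
#' @export
relevance_scores <- function(X, y,
                             method = c("f_stat", "chi2",
                                        "mutual_information", "cfm"),
                             bins = 10L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  y <- validate_binary_labels(y, nrow(X))
  require_both_classes(y)
  if (anyNA(X)) stop("relevance requires complete data")
  out <- switch(method,
    chi2 = chi2_scores(X, y),
    f_stat = f_stat_scores(X, y),
    mutual_information = mi_scores(X, y, bins = bins),
    cfm = cfm_scores(X, y, bins = bins)
  )
  unname(out)
}

#' Relevance of a single feature
#'
#' Convenience wrapper around [relevance_scores()] for one feature vector.
#' The `cfm` consensus needs a candidate pool to normalize against; pass it
#' via `pool` (see [cfm_relevance()]).
#'
#' @param x Numeric feature vector.
#' @param y Binary labels.
#' @inheritParams relevance_scores
#' @return A single nonnegative score.
#' @export
relevance <- function(x, y, method = c("f_stat", "chi2", "mutual_information"),
                      bins = 10L) {
  method <- match.arg(method)
  relevance_scores(matrix(x, ncol = 1L), y, method = method, bins = bins)[1L]
}

chi2_scores <- function(X, y) {
  if (any(X < 0)) stop("chi2 relevance requires nonnegative feature values")
  obs1 <- colSums(X[y == 1L, , drop = FALSE])
  obs0 <- colSums(X[y == 0L, , drop = FALSE])
  tot <- obs0 + obs1
  p1 <- mean(y)
  exp1 <- tot * p1
  exp0 <- tot * (1 - p1)
  out <- rep(0, ncol(X))
  nz <- tot > 0
  out[nz] <- (obs1[nz] - exp1[nz])^2 / exp1[nz] +
    (obs0[nz] - exp0[nz])^2 / exp0[nz]
  out
}

f_stat_scores <- function(X, y) {
  m <- nrow(X)
  if (m < 3L) stop("F statistic needs at least 3 samples")
  i1 <- y == 1L
  n1 <- sum(i1); n0 <- m - n1
  mu1 <- colMeans(X[i1, , drop = FALSE])
  mu0 <- colMeans(X[!i1, , drop = FALSE])
  mu <- colMeans(X)
  ssb <- n1 * (mu1 - mu)^2 + n0 * (mu0 - mu)^2
  ssw <- colSums((X - rep(mu, each = m) -
                    outer(as.numeric(i1), mu1 - mu) -
                    outer(as.numeric(!i1), mu0 - mu))^2)
  out <- numeric(ncol(X))
  sep <- ssw <= .Machine$double.eps * pmax(ssb, 1)
  out[!sep] <- (ssb[!sep] / 1) / (ssw[!sep] / (m - 2))
  out[sep & ssb > 0] <- Inf     # perfectly separated feature
  out[sep & ssb <= 0] <- 0      # constant feature
  out
}

# equal-width binning over the observed range, then discrete MI in nats
mi_scores <- function(X, y, bins = 10L) {
  bins <- as.integer(bins)
  if (bins < 2L) stop("need at least 2 bins")
  m <- nrow(X)
  py <- c(mean(y == 0L), mean(y == 1L))
  apply(X, 2L, function(x) {
    r <- range(x)
    if (r[1L] == r[2L]) return(0)
    b <- pmin(floor((x - r[1L]) / (r[2L] - r[1L]) * bins) + 1L, bins)
    mi <- 0
    for (cl in 0:1) {
      idx <- y == cl
      for (bb in unique(b)) {
        pxy <- sum(b == bb & idx) / m
        if (pxy > 0) {
          px <- sum(b == bb) / m
          mi <- mi + pxy * log(pxy / (px * py[cl + 1L]))
        }
      }
    }
    max(mi, 0)
  })
}

cfm_scores <- function(X, y, bins = 10L) {
  if (ncol(X) < 2L) stop("cfm needs a candidate pool of at least 2 features")
  comp <- cbind(chi2_scores(X, y), f_stat_scores(X, y), mi_scores(X, y, bins))
  norm <- apply(comp, 2L, minmax01)
  rowMeans(norm)
}

# min-max to [0,1]; Inf (perfect separation) pins to the top, constant -> 0
minmax01 <- function(s) {
  fin <- is.finite(s)
  if (!any(fin)) return(rep(1, length(s)))
  hi <- max(s[fin]); lo <- min(s[fin])
  out <- if (hi == lo) rep(0, length(s)) else (s - lo) / (hi - lo)
  out[!fin] <- 1
  pmin(pmax(out, 0), 1)
}

#' Consensus (CFM) relevance of one feature against a candidate pool
#'
#' Averages the min-max-normalized chi-squared, F and mutual-information
#' statistics, where normalization bounds come from the candidate pool.
#'
#' @param x Feature vector to score.
#' @param y Binary labels.
#' @param pool Matrix of candidate features defining the normalization range;
#'   needs at least two columns.
#' @param bins Bin count for the mutual-information component.
#' @return Consensus score in `[0, 1]` (values outside the pool's range are
#'   clipped).
#' @export
cfm_relevance <- function(x, y, pool, bins = 10L) {
  pool <- as.matrix(pool)
  if (ncol(pool) < 2L) stop("cfm needs a candidate pool of at least 2 features")
  y <- validate_binary_labels(y, length(x))
  require_both_classes(y)
  comp_pool <- cbind(chi2_scores(pool, y), f_stat_scores(pool, y),
                     mi_scores(pool, y, bins))
  xm <- matrix(x, ncol = 1L)
  comp_x <- c(chi2_scores(xm, y), f_stat_scores(xm, y), mi_scores(xm, y, bins))
  vals <- vapply(1:3, function(i) {
    s <- comp_pool[, i]
    fin <- is.finite(s)
    if (!any(fin)) return(1)
    hi <- max(s[fin]); lo <- min(s[fin])
    if (!is.finite(comp_x[i])) return(1)
    if (hi == lo) return(0)
    min(max((comp_x[i] - lo) / (hi - lo), 0), 1)
  }, numeric(1))
  mean(vals)
}

# Relevance of every feature in every view, as a list of vectors.
# The cfm pool is the union of all candidate features across views, so the
# consensus scores are commensurable between views.
relevance_by_view <- function(mvd, method, bins = 10L) {
  if (method == "cfm") {
    Xall <- do.call(cbind, lapply(mvd$views, function(v) v$matrix))
    all_scores <- relevance_scores(Xall, mvd$labels, method = "cfm", bins = bins)
    sizes <- vapply(mvd$views, function(v) ncol(v$matrix), integer(1))
    split(all_scores, rep(seq_along(sizes), sizes))
  } else {
    lapply(mvd$views, function(v) {
      relevance_scores(v$matrix, mvd$labels, method = method, bins = bins)
    })
  }
}
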