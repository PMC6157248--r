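# Independent scoring oracles: everything here recomputes scores from
# scratch with base R / stats building blocks (lm/anova, cut + entropies,
# scalar cor) and never calls the package's cached selection paths.

oracle_abs_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  abs(stats::cor(a, b))
}

oracle_relevance <- function(x, y, f = "f_stat", bins = 10L) {
  if (f == "f_stat") {
    if (stats::sd(x) == 0) return(0)
    a <- stats::anova(stats::lm(x ~ factor(y)))
    fv <- a[["F value"]][1L]
    if (!is.finite(fv)) Inf else fv
  } else if (f == "chi2") {
    o1 <- sum(x[y == 1]); o0 <- sum(x[y == 0]); tot <- o0 + o1
    if (tot == 0) return(0)
    p1 <- mean(y)
    (o1 - tot * p1)^2 / (tot * p1) + (o0 - tot * (1 - p1))^2 / (tot * (1 - p1))
  } else if (f == "mutual_information") {
    r <- range(x)
    if (r[1L] == r[2L]) return(0)
    br <- seq(r[1L], r[2L], length.out = bins + 1L)
    b <- cut(x, br, right = FALSE, include.lowest = TRUE, labels = FALSE)
    H <- function(tab) {
      p <- as.numeric(tab) / length(x)
      p <- p[p > 0]
      -sum(p * log(p))
    }
    max(H(table(b)) + H(table(y)) - H(table(b, y)), 0)
  } else {
    stop("no oracle for relevance '", f, "'")
  }
}

# from-scratch greedy single-view MRMR (no caching, re-scores everything)
oracle_mrmr <- function(X, y, k, f = "f_stat", exponent = 2) {
  n <- ncol(X)
  rel <- vapply(seq_len(n), function(j) oracle_relevance(X[, j], y, f),
                numeric(1))
  S <- integer(0)
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(n), S)
    sc <- vapply(cand, function(j) {
      if (length(S) == 0L) return(rel[j])
      red <- sum(vapply(S, function(l) oracle_abs_cor(X[, j], X[, l]),
                        numeric(1)))
      rel[j] - red / length(S)^exponent
    }, numeric(1))
    S <- c(S, cand[which.max(sc)])
  }
  S
}

# from-scratch replay of the multi-view greedy selection for a given schedule
oracle_mrmr_mv <- function(Xs, y, k, schedule, f = "f_stat", exponent = 2) {
  v <- length(Xs)
  rel <- lapply(Xs, function(X) {
    vapply(seq_len(ncol(X)), function(j) oracle_relevance(X[, j], y, f),
           numeric(1))
  })
  sel <- lapply(Xs, function(X) integer(0))
  # first pick: global argmax, earliest view then earliest feature on ties
  best <- c(1L, 1L); best_val <- -Inf
  for (t in seq_len(v)) {
    j <- which.max(rel[[t]])
    if (rel[[t]][j] > best_val) { best_val <- rel[[t]][j]; best <- c(t, j) }
  }
  sel[[best[1L]]] <- best[2L]
  ord <- list(best)
  for (step in seq_len(k - 1L)) {
    t <- schedule[step]
    cand <- setdiff(seq_len(ncol(Xs[[t]])), sel[[t]])
    all_sel <- do.call(rbind, lapply(seq_len(v), function(u) {
      if (length(sel[[u]]) == 0L) NULL else cbind(u, sel[[u]])
    }))
    sc <- vapply(cand, function(j) {
      red <- sum(apply(all_sel, 1L, function(rw) {
        oracle_abs_cor(Xs[[t]][, j], Xs[[rw[1L]]][, rw[2L]])
      }))
      rel[[t]][j] - red / nrow(all_sel)^exponent
    }, numeric(1))
    pick <- cand[which.max(sc)]
    sel[[t]] <- c(sel[[t]], pick)
    ord[[length(ord) + 1L]] <- c(t, pick)
  }
  list(per_view = sel, order = do.call(rbind, ord))
}

# random labeled view fixture on [0, 1] (chi2-safe)
random_fixture <- function(m, n, seed, signal = 0) {
  withr::with_seed(seed, {
    y <- sample(rep_len(0:1, m))
    X <- matrix(stats::runif(m * n), m, n)
    if (signal > 0) {
      ns <- max(1L, n %/% 3L)
      X[, seq_len(ns)] <- X[, seq_len(ns)] + signal * y
      X <- apply(X, 2L, function(x) (x - min(x)) / (max(x) - min(x)))
    }
    list(X = X, y = y)
  })
}

# orthonormal columns (centered, unit sd) for building exact correlations
orthonormal_cols <- function(m, p, seed = 42) {
  withr::with_seed(seed, {
    Z <- matrix(stats::rnorm(m * p), m, p)
    Z <- scale(Z, center = TRUE, scale = FALSE)
    Q <- qr.Q(qr(Z))
    Q <- scale(Q, center = TRUE, scale = FALSE)  # re-center after QR
    apply(Q, 2L, function(x) x / stats::sd(x))
  })
}

# two-view fixture with an exact cross-view copy of view 1's top feature
# plus an independent informative feature in view 2
planted_duplicate_fixture <- function(m = 80, seed = 5) {
  withr::with_seed(seed, {
    y <- sample(rep_len(0:1, m))
    top <- y + stats::rnorm(m, sd = 0.3)   # strongest signal
    ind <- y + stats::rnorm(m, sd = 0.45)  # informative, independent noise
    v1 <- cbind(top = top, n1 = stats::rnorm(m), n2 = stats::rnorm(m))
    v2 <- cbind(copy = top, ind = ind)
    mv_dataset(list(mv_view(v1, "v1"), mv_view(v2, "v2")), labels = y)
  })
}
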