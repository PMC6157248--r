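#' Cross-validation protocol
#'
#' @param n_folds Folds per repetition (default 5).
#' @param n_repeats Repetitions with re-randomized folds (default 10).
#' @param stratified Preserve class proportions within folds (default TRUE).
#' @param seed Base seed; repetition `r` uses fold seed `seed + r`, so the
#'   splits are reproducible and shared between strategies evaluated under
#'   the same protocol.
#' @param fold_ids Optional pre-computed splits: a list with one integer
#'   fold-id vector per repetition, overriding the seeded assignment (used
#'   e.g. to hold a split fixed while perturbing the data).
#' @return An object of class `cv_protocol`.
#' @export
cv_protocol <- function(n_folds = 5L, n_repeats = 10L, stratified = TRUE,
                        seed = NULL, fold_ids = NULL) {
  stopifnot(n_folds >= 2L, n_repeats >= 1L)
  if (!is.null(fold_ids) && length(fold_ids) != n_repeats) {
    stop("fold_ids needs one fold vector per repetition")
  }
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats),
                 stratified = isTRUE(stratified), seed = seed,
                 fold_ids = fold_ids),
            class = "cv_protocol")
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of `k` folds. Under stratification each
#' class's samples are spread as evenly as possible, so per-fold class
#' counts differ by at most one.
#'
#' @param y Binary labels.
#' @param k Number of folds.
#' @param seed Optional seed.
#' @param stratified Stratify by class (default TRUE).
#' @return Integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(y, k, seed = NULL, stratified = TRUE) {
  assign_folds <- function() {
    fold <- integer(length(y))
    if (!stratified) return(sample(rep_len(seq_len(k), length(y))))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  }
  if (is.null(seed)) assign_folds() else withr::with_seed(seed, assign_folds())
}

#' Area under the ROC curve
#'
#' The Mann-Whitney rank form: the probability that a uniformly chosen
#' positive sample outscores a uniformly chosen negative one, with ties
#' counted half.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Binary 0/1 labels, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- validate_binary_labels(labels, length(scores))
  require_both_classes(labels)
  n1 <- sum(labels == 1L)
  n0 <- length(labels) - n1
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Elementwise average of two prediction score vectors
#'
#' The late-fusion ensemble rule: unweighted mean of the two models'
#' per-sample scores.
#'
#' @param p1,p2 Numeric score vectors of equal length.
#' @return The averaged vector.
#' @export
ensemble_average <- function(p1, p2) {
  if (length(p1) != length(p2)) stop("score vectors must have equal length")
  (p1 + p2) / 2
}

#' Construct a classifier for the evaluation harness
#'
#' The harness only needs `fit(X, y, seed)` and `predict_prob(model, X)`.
#' Shipped defaults mirror common survival-classification choices:
#' `"l1"` — L1-regularized logistic regression (glmnet, fixed lambda);
#' `"logistic"` — unpenalized logistic regression; `"rf"` — probability
#' random forest, 500 trees (requires ranger); `"xgb"` — gradient boosting,
#' 500 rounds (requires xgboost). Any list with the same two functions and
#' a `name` works in their place.
#'
#' @param name Learner name.
#' @param params Named list of overrides (`lambda`, `num_trees`, `nrounds`,
#'   `eta`, ...).
#' @return A learner object (list with `name`, `fit`, `predict_prob`).
#' @export
make_learner <- function(name = c("l1", "logistic", "rf", "xgb"),
                         params = list()) {
  name <- match.arg(name)
  learner <- switch(name,
    l1 = list(
      fit = function(X, y, seed = NULL) {
        if (ncol(X) < 2L) {
          df <- data.frame(y = y, X)
          return(list(kind = "glm",
                      model = suppressWarnings(
                        stats::glm(y ~ ., data = df, family = stats::binomial()))))
        }
        list(kind = "glmnet",
             model = glmnet::glmnet(X, factor(y), family = "binomial",
                                    alpha = 1,
                                    lambda = params$lambda %||% 0.01))
      },
      predict_prob = function(model, X) {
        if (model$kind == "glm") {
          as.numeric(stats::predict(model$model,
                                    newdata = data.frame(X),
                                    type = "response"))
        } else {
          as.numeric(stats::predict(model$model, newx = X,
                                    type = "response"))
        }
      }
    ),
    logistic = list(
      fit = function(X, y, seed = NULL) {
        df <- data.frame(y = y, X)
        suppressWarnings(stats::glm(y ~ ., data = df,
                                    family = stats::binomial()))
      },
      predict_prob = function(model, X) {
        as.numeric(stats::predict(model, newdata = data.frame(X),
                                  type = "response"))
      }
    ),
    rf = list(
      fit = function(X, y, seed = NULL) {
        if (!requireNamespace("ranger", quietly = TRUE)) {
          stop("the 'rf' learner requires the ranger package")
        }
        ranger::ranger(x = as.data.frame(X), y = factor(y, levels = 0:1),
                       probability = TRUE,
                       num.trees = params$num_trees %||% 500L,
                       seed = seed %||% 1L, num.threads = 1L)
      },
      predict_prob = function(model, X) {
        stats::predict(model, data = as.data.frame(X),
                       num.threads = 1L)$predictions[, "1"]
      }
    ),
    xgb = list(
      fit = function(X, y, seed = NULL) {
        if (!requireNamespace("xgboost", quietly = TRUE)) {
          stop("the 'xgb' learner requires the xgboost package")
        }
        set.seed(seed %||% 1L)
        xgboost::xgboost(data = X, label = y,
                         nrounds = params$nrounds %||% 500L,
                         params = list(objective = "binary:logistic",
                                       eta = params$eta %||% 0.3,
                                       nthread = 1L),
                         verbose = 0)
      },
      predict_prob = function(model, X) {
        as.numeric(stats::predict(model, newdata = X))
      }
    )
  )
  c(list(name = name), learner)
}

# flatten the views of a (reduced) dataset into one model matrix
dataset_matrix <- function(mvd) {
  X <- do.call(cbind, lapply(mvd$views, function(v) {
    m <- v$matrix
    colnames(m) <- paste(v$name, v$feature_names, sep = ".")
    m
  }))
  X
}

#' Repeated stratified cross-validation of a selection pipeline
#'
#' For every repetition and fold, the pipeline (feature selection) and the
#' learner are fitted on the training folds only and scored on the held-out
#' fold by AUC — selection always happens inside the fold, so no information
#' leaks from the test samples.
#'
#' @param mvd A labeled [mv_dataset].
#' @param pipeline An unfitted [two_stage_pipeline()].
#' @param learner A learner from [make_learner()] (or a compatible list).
#' @param protocol A [cv_protocol()].
#' @param strategy Label recorded in the result.
#' @return An object of class `strategy_result`: `aucs` (data frame with
#'   `rep`, `fold`, `auc`), `mean_auc`, `predictions` (per rep x fold:
#'   held-out indices and scores) and `selections` (per rep x fold fitted
#'   feature names).
#' @export
repeated_cv <- function(mvd, pipeline, learner, protocol = cv_protocol(),
                        strategy = "model") {
  stopifnot(inherits(mvd, "mv_dataset"), inherits(protocol, "cv_protocol"))
  y <- require_both_classes(mvd$labels)
  base_seed <- protocol$seed
  rows <- list(); preds <- list(); sels <- list()
  for (r in seq_len(protocol$n_repeats)) {
    fold <- protocol$fold_ids[[r]] %||%
      stratified_folds(y, protocol$n_folds,
                       seed = if (is.null(base_seed)) NULL else base_seed + r,
                       stratified = protocol$stratified)
    for (fo in seq_len(protocol$n_folds)) {
      te <- which(fold == fo); tr <- which(fold != fo)
      if (length(unique(y[te])) < 2L || length(unique(y[tr])) < 2L) {
        stop("protocol error: a fold is missing a class")
      }
      pseed <- if (is.null(base_seed)) NULL else base_seed + 1000L * r + fo
      fitted <- fit_pipeline(pipeline, subset_samples(mvd, tr), seed = pseed)
      Xtr <- dataset_matrix(transform_pipeline(fitted, subset_samples(mvd, tr)))
      Xte <- dataset_matrix(transform_pipeline(fitted, subset_samples(mvd, te)))
      model <- learner$fit(Xtr, y[tr], seed = pseed)
      sc <- learner$predict_prob(model, Xte)
      key <- sprintf("r%d_f%d", r, fo)
      rows[[key]] <- data.frame(rep = r, fold = fo,
                                auc = auc_score(sc, y[te]))
      preds[[key]] <- list(rep = r, fold = fo, test_idx = te, scores = sc)
      sels[[key]] <- fitted$fitted_state$selected
    }
  }
  aucs <- do.call(rbind, rows)
  rownames(aucs) <- NULL
  structure(list(strategy = strategy, aucs = aucs,
                 mean_auc = mean(aucs$auc), predictions = preds,
                 selections = sels, protocol = protocol),
            class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("<strategy_result '%s': mean AUC %.3f over %d folds>\n",
              x$strategy, x$mean_auc, nrow(x$aucs)))
  invisible(x)
}

# ensemble of two strategy_results evaluated on identical folds
ensemble_result <- function(res1, res2, y, strategy = "Ensemble") {
  stopifnot(identical(names(res1$predictions), names(res2$predictions)))
  rows <- lapply(names(res1$predictions), function(key) {
    a <- res1$predictions[[key]]; b <- res2$predictions[[key]]
    stopifnot(identical(a$test_idx, b$test_idx))
    avg <- ensemble_average(a$scores, b$scores)
    data.frame(rep = a$rep, fold = a$fold,
               auc = auc_score(avg, y[a$test_idx]))
  })
  aucs <- do.call(rbind, rows)
  structure(list(strategy = strategy, aucs = aucs, mean_auc = mean(aucs$auc),
                 predictions = NULL, selections = NULL,
                 protocol = res1$protocol),
            class = "strategy_result")
}

# pipelines implementing the benchmark strategies
strategy_pipelines <- function(mvd, k, stage1, f, exponent, bins, p) {
  v <- length(mvd$views)
  nm <- names(mvd$views)
  mrmr_params <- list(k = k, f = f, exponent = exponent, bins = bins)
  out <- list()
  for (t in seq_len(v)) {
    s1 <- lapply(seq_len(v), function(u) {
      sp <- stage1; sp$enabled <- (u == t); sp
    })
    out[[paste0("SV_", nm[t])]] <- two_stage_pipeline(
      s1, filter_spec("mrmr", mrmr_params))
  }
  if (v >= 2L) {
    out$SV_C <- two_stage_pipeline(stage1, filter_spec("mrmr", mrmr_params))
    out$SV_S <- two_stage_pipeline(
      filter_spec("chain", list(filters = list(stage1,
                                               filter_spec("mrmr", mrmr_params)))),
      filter_spec("all_filter"))
    out$MV <- two_stage_pipeline(
      stage1, filter_spec("mrmr_mv", c(mrmr_params, list(p = p))))
  } else {
    # with one view every strategy reduces to the single per-view model
    out$SV_C <- out$SV_S <- out$MV <- out[[paste0("SV_", nm[1L])]]
  }
  out
}

#' Benchmark single-view, concatenation, union, multi-view and ensemble
#' modelling strategies
#'
#' Runs, for every `k` and learner, under one shared set of CV splits:
#' per-view models (`SV_<view>`: greedy MRMR restricted to one view);
#' `SV_C`: MRMR on the concatenation of all views; `SV_S`: MRMR applied to
#' each view separately (k features per view) then the union; `MV`:
#' multi-view MRMR; `Ensemble`: prediction averaging of the best per-view
#' model and the MV model. With a single view all strategies coincide with
#' the per-view model.
#'
#' @param mvd A labeled [mv_dataset].
#' @param k_grid Integer vector of selection sizes.
#' @param learners Character vector of learner names (see [make_learner()])
#'   or a list of learner objects.
#' @param protocol A [cv_protocol()]; its seed fixes the shared folds.
#' @param stage1 Stage-I `filter_spec` applied per view before selection
#'   (default pass-through).
#' @param f Relevance function name.
#' @param exponent Redundancy divisor exponent.
#' @param bins Mutual-information bin count.
#' @param p View sampling distribution for the MV strategy (default
#'   uniform).
#' @param strategies Optional subset of strategy labels to run.
#' @return A list with `results` — a tidy data frame
#'   `(strategy, learner, k, rep, fold, auc)` — and `summary`, the mean AUC
#'   per `(strategy, learner, k)`.
#' @export
strategy_suite <- function(mvd, k_grid, learners = "l1",
                           protocol = cv_protocol(),
                           stage1 = filter_spec("all_filter"),
                           f = "f_stat", exponent = 2, bins = 10L, p = NULL,
                           strategies = NULL) {
  stopifnot(inherits(mvd, "mv_dataset"))
  if (is.character(learners)) {
    learners <- lapply(learners, make_learner)
  }
  y <- mvd$labels
  all_rows <- list()
  for (k in k_grid) {
    pipes <- strategy_pipelines(mvd, k, stage1, f, exponent, bins, p)
    per_view_names <- grep("^SV_(?!C$|S$)", names(pipes), perl = TRUE,
                           value = TRUE)
    needed <- if (is.null(strategies)) {
      names(pipes)
    } else {
      nd <- intersect(strategies, names(pipes))
      if ("Ensemble" %in% strategies) nd <- union(nd, c("MV", per_view_names))
      nd
    }
    for (lrn in learners) {
      res <- list()
      for (snm in intersect(names(pipes), needed)) {
        res[[snm]] <- repeated_cv(mvd, pipes[[snm]], lrn, protocol,
                                  strategy = snm)
      }
      sv_names <- intersect(per_view_names, names(res))
      if (length(sv_names) > 0L && "MV" %in% names(res) &&
          (is.null(strategies) || "Ensemble" %in% strategies)) {
        best_sv <- sv_names[which.max(vapply(res[sv_names],
                                             function(r) r$mean_auc,
                                             numeric(1)))]
        res$Ensemble <- ensemble_result(res[[best_sv]], res$MV, y)
      }
      for (snm in names(res)) {
        if (!is.null(strategies) && !snm %in% strategies) next
        df <- res[[snm]]$aucs
        df$strategy <- snm; df$learner <- lrn$name; df$k <- k
        all_rows[[paste(snm, lrn$name, k)]] <- df
      }
    }
  }
  results <- do.call(rbind, all_rows)
  rownames(results) <- NULL
  results <- results[, c("strategy", "learner", "k", "rep", "fold", "auc")]
  summary <- stats::aggregate(auc ~ strategy + learner + k, results, mean)
  names(summary)[names(summary) == "auc"] <- "mean_auc"
  list(results = results, summary = summary)
}

#' Percent relative range
#'
#' Spread statistic used for the sensitivity analysis:
#' `100 * (max - min) / mean`.
#'
#' @param x Numeric vector.
#' @return The percent relative range of `x`.
#' @export
percent_relative_range <- function(x) {
  100 * (max(x) - min(x)) / mean(x)
}

#' Sensitivity of the multi-view model to the view sampling distribution
#'
#' For a two-view dataset, evaluates the MV model at each
#' `P = (p1, 1 - p1)` on a grid of `p1` values and summarizes, per `k`, the
#' spread of the resulting mean AUCs as the percent relative range. Small
#' values mean the model barely cares how selection effort is split across
#' the views.
#'
#' @param mvd A labeled two-view [mv_dataset].
#' @param k_grid Integer vector of selection sizes.
#' @param p1_grid Grid of first-view probabilities, default `seq(0, 1, 0.1)`.
#' @param learner A learner object or name.
#' @param protocol A [cv_protocol()].
#' @inheritParams strategy_suite
#' @return Data frame `(k, percent_relative_range)`; attribute `"aucs"`
#'   holds the k x p1 matrix of mean AUCs.
#' @export
p_sensitivity <- function(mvd, k_grid, p1_grid = seq(0, 1, by = 0.1),
                          learner = "l1", protocol = cv_protocol(),
                          stage1 = filter_spec("all_filter"),
                          f = "f_stat", exponent = 2, bins = 10L) {
  if (length(mvd$views) != 2L) stop("P sensitivity is defined for two views")
  if (is.character(learner)) learner <- make_learner(learner)
  auc_mat <- matrix(NA_real_, length(k_grid), length(p1_grid),
                    dimnames = list(paste0("k", k_grid), paste0("p", p1_grid)))
  for (ki in seq_along(k_grid)) {
    for (pi in seq_along(p1_grid)) {
      pipe <- two_stage_pipeline(
        stage1,
        filter_spec("mrmr_mv", list(k = k_grid[ki], f = f,
                                    exponent = exponent, bins = bins,
                                    p = c(p1_grid[pi], 1 - p1_grid[pi]))))
      auc_mat[ki, pi] <- repeated_cv(mvd, pipe, learner, protocol)$mean_auc
    }
  }
  out <- data.frame(k = k_grid,
                    percent_relative_range = unname(
                      apply(auc_mat, 1L, percent_relative_range)))
  attr(out, "aucs") <- auc_mat
  out
}
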