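make_two_view_data <- function(m = 60, n = 8, seed = 61, signal = 1) {
  withr::with_seed(seed, {
    y <- sample(rep_len(0:1, m))
    mk <- function(nm) {
      X <- matrix(runif(m * n), m, n)
      X[, 1] <- (X[, 1] + signal * y) / (1 + signal)
      mv_view(X, nm, feature_names = paste0(nm, "_f", seq_len(n)))
    }
    mv_dataset(list(mk("cna"), mk("rna")), labels = y)
  })
}

test_that("the all-pass pipeline is the identity", {
  mvd <- make_two_view_data()
  fit <- fit_pipeline(two_stage_pipeline(), mvd)
  expect_equal(fit$fitted_state$selected,
               lapply(mvd$views, function(v) v$feature_names))
  red <- transform_pipeline(fit, mvd)
  expect_equal(lapply(red$views, function(v) v$matrix),
               lapply(mvd$views, function(v) v$matrix))
})

test_that("disabling a view's gate passes only the other view downstream", {
  mvd <- make_two_view_data()
  pipe <- two_stage_pipeline(list(filter_spec("all_filter", enabled = TRUE),
                                  filter_spec("all_filter", enabled = FALSE)),
                             filter_spec("all_filter"))
  fit <- fit_pipeline(pipe, mvd)
  expect_equal(fit$fitted_state$selected$cna, mvd$views$cna$feature_names)
  expect_equal(fit$fitted_state$selected$rna, character(0))
  expect_equal(names(transform_pipeline(fit, mvd)$views), "cna")
  # all gates closed is a configuration error
  expect_error(fit_pipeline(two_stage_pipeline(
    filter_spec("all_filter", enabled = FALSE)), mvd), "disabled")
})

test_that("gate law: disabling a view equals deleting it", {
  mvd <- make_two_view_data()
  deleted <- mv_dataset(mvd$views["cna"], labels = mvd$labels)
  pipe_gated <- two_stage_pipeline(
    list(filter_spec("all_filter"), filter_spec("all_filter", enabled = FALSE)),
    filter_spec("mrmr", list(k = 3)))
  pipe_plain <- two_stage_pipeline(filter_spec("all_filter"),
                                   filter_spec("mrmr", list(k = 3)))
  f1 <- fit_pipeline(pipe_gated, mvd)
  f2 <- fit_pipeline(pipe_plain, deleted)
  expect_equal(f1$fitted_state$selected$cna, f2$fitted_state$selected$cna)
})

test_that("stage composition: embedded top-n then multi-view selection", {
  mvd <- make_two_view_data(m = 80, n = 12)
  pipe <- two_stage_pipeline(
    filter_spec("embedded_l1", list(strength = 1e-3, top_n = 6)),
    filter_spec("mrmr_mv", list(k = 5)))
  fit <- fit_pipeline(pipe, mvd, seed = 3)
  sel <- fit$fitted_state$selected
  expect_equal(sum(lengths(sel)), 5L)
  # the final picks come from the stage-I survivors
  s1 <- fit$fitted_state$stage1_features
  expect_true(all(sel$cna %in% s1$cna) && all(sel$rna %in% s1$rna))
  expect_equal(lengths(s1), c(cna = 6L, rna = 6L))
  # equivalent to composing the two modules by hand
  by_hand_idx <- lapply(mvd$views, function(v) {
    sort(embedded_sparse_filter(v, mvd$labels, strength = 1e-3, top_n = 6))
  })
  sub <- mv_dataset(lapply(names(mvd$views), function(nm) {
    v <- mvd$views[[nm]]
    mv_view(v$matrix[, by_hand_idx[[nm]], drop = FALSE], nm,
            feature_names = v$feature_names[by_hand_idx[[nm]]])
  }), labels = mvd$labels)
  by_hand <- selected_feature_names(mrmr_mv_select(sub, k = 5, seed = 3))
  expect_equal(sel, by_hand, ignore_attr = TRUE)
})

test_that("transform is a pure name-keyed projection", {
  mvd <- make_two_view_data()
  pipe <- two_stage_pipeline(filter_spec("all_filter"),
                             filter_spec("mrmr", list(k = 4)))
  fit <- fit_pipeline(pipe, mvd)
  red1 <- transform_pipeline(fit, mvd)
  # idempotence: transforming the reduced data again changes nothing
  red2 <- transform_pipeline(fit, red1)
  expect_equal(lapply(red2$views, function(v) v$matrix),
               lapply(red1$views, function(v) v$matrix))
  # permuted column order projects to the same features by name
  perm <- mv_dataset(lapply(mvd$views, function(v) {
    ix <- rev(seq_len(ncol(v$matrix)))
    mv_view(v$matrix[, ix], v$name, feature_names = v$feature_names[ix])
  }), labels = mvd$labels)
  red3 <- transform_pipeline(fit, perm)
  expect_equal(lapply(red3$views, function(v) v$matrix),
               lapply(red1$views, function(v) v$matrix))
  # a missing selected feature is an error
  broken <- mv_dataset(lapply(mvd$views, function(v) {
    keep <- setdiff(v$feature_names, fit$fitted_state$selected[[v$name]][1])
    mv_view(v$matrix[, keep, drop = FALSE], v$name, feature_names = keep)
  }), labels = mvd$labels)
  expect_error(transform_pipeline(fit, broken), "missing")
  expect_error(transform_pipeline(two_stage_pipeline(), mvd), "not fitted")
})

test_that("single-view and multi-view Stage II agree on one view", {
  fx <- random_fixture(m = 50, n = 9, seed = 63, signal = 0.8)
  mvd <- mv_dataset(mv_view(fx$X, "v", feature_names = paste0("f", 1:9)),
                    labels = fx$y)
  sv <- fit_pipeline(two_stage_pipeline(stage2 = filter_spec("mrmr", list(k = 4))),
                     mvd)
  mv <- fit_pipeline(two_stage_pipeline(stage2 = filter_spec("mrmr_mv", list(k = 4))),
                     mvd, seed = 1)
  expect_equal(sv$fitted_state$selected, mv$fitted_state$selected,
               ignore_attr = TRUE)
})

test_that("embedded sparse filter ranks a separable feature first", {
  withr::with_seed(64, {
    m <- 80
    y <- sample(rep_len(0:1, m))
    X <- matrix(rnorm(m * 5), m, 5)
    X[, 3] <- y * 2 - 1 + rnorm(m, sd = 0.05)  # y is recoverable from f3
  })
  idx <- embedded_sparse_filter(X, y, strength = 1e-2, top_n = 5)
  expect_equal(idx[1], 3L)
  expect_setequal(idx, 1:5)  # top_n = all returns everything, ranked
  # heavy penalty shrinks all coefficients away; ranking falls back to
  # magnitude (here: all zero -> original order) with the right count
  idx2 <- embedded_sparse_filter(X, y, strength = 50, top_n = 2)
  expect_length(idx2, 2L)
  expect_error(embedded_sparse_filter(X, rep(1, m), top_n = 2),
               "both classes")
})

test_that("custom filter kinds are registerable by name", {
  register_filter("first_two", function(view, labels, params, seed) 1:2)
  mvd <- make_two_view_data()
  fit <- fit_pipeline(two_stage_pipeline(filter_spec("first_two"),
                                         filter_spec("all_filter")), mvd)
  expect_equal(fit$fitted_state$selected$cna, c("cna_f1", "cna_f2"))
  expect_error(filter_spec("unheard_of"), "unknown filter kind")
})

test_that("pipeline manifests serialize the per-view selection", {
  mvd <- make_two_view_data()
  pipe <- two_stage_pipeline(filter_spec("all_filter"),
                             filter_spec("mrmr", list(k = 3)))
  fit <- fit_pipeline(pipe, mvd)
  doc <- jsonlite::fromJSON(pipeline_manifest(fit))
  expect_setequal(names(doc), c("cna", "rna"))
  expect_equal(sum(lengths(doc)), 3L)
})
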