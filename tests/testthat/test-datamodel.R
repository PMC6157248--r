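test_that("read_view parses a delimited table with labels from a file", {
  d <- withr::local_tempdir()
  writeLines(c("g1,g2", "0.1,0.5", "0.2,0.6", "0.3,0.7"),
             file.path(d, "view.csv"))
  writeLines(c("0", "1", "1"), file.path(d, "labels.txt"))
  out <- read_view(file.path(d, "view.csv"),
                   labels = file.path(d, "labels.txt"))
  expect_s3_class(out$view, "mv_view")
  expect_equal(dim(out$view), c(3L, 2L))
  expect_equal(out$view$feature_names, c("g1", "g2"))
  expect_equal(out$labels, c(0L, 1L, 1L))
  expect_equal(out$view$matrix[, "g2"], c(0.5, 0.6, 0.7))
})

test_that("read_view marks non-numeric and empty cells as missing", {
  d <- withr::local_tempdir()
  writeLines(c("g1,g2", "0.1,", "0.2,0.6", "bad,0.7"),
             file.path(d, "view.csv"))
  out <- read_view(file.path(d, "view.csv"))
  expect_true(is.na(out$view$matrix[1, 2]))
  expect_true(is.na(out$view$matrix[3, 1]))
  expect_equal(sum(is.na(out$view$matrix)), 2L)
})

test_that("read_view rejects missing files and non-binary labels", {
  d <- withr::local_tempdir()
  expect_error(read_view(file.path(d, "nope.csv")), "not found")
  writeLines(c("g1,y", "0.1,0", "0.2,2"), file.path(d, "bad.csv"))
  expect_error(read_view(file.path(d, "bad.csv"), labels = "y"), "binary")
})

test_that("read_view/write_view round-trip preserves the matrix", {
  d <- withr::local_tempdir()
  v <- mv_view(matrix(round(runif(12), 6), 4, 3,
                      dimnames = list(NULL, c("a", "b", "c"))),
               name = "v", sample_ids = paste0("s", 1:4))
  write_view(v, file.path(d, "v.csv"))
  back <- read_view(file.path(d, "v.csv"), sample_id_column = "sample_id")
  expect_equal(back$view$matrix, v$matrix, ignore_attr = TRUE)
  expect_equal(back$view$sample_ids, v$sample_ids)
})

test_that("align_views keeps the sorted intersection of sample ids", {
  mk <- function(ids, nm) {
    mv_view(matrix(seq_along(ids), ncol = 1,
                   dimnames = list(NULL, "f1")),
            name = nm, sample_ids = ids)
  }
  out <- align_views(list(mk(c("A", "B", "C"), "v1"),
                          mk(c("D", "C", "B"), "v2")))
  expect_equal(out$sample_ids, c("B", "C"))
  expect_equal(attr(out, "dropped"), c(v1 = 1L, v2 = 1L))
  # rows really are the matching samples, in the same order in both views
  expect_equal(unname(out$views$v1$matrix[, 1]), c(2, 3))
  expect_equal(unname(out$views$v2$matrix[, 1]), c(3, 2))

  same <- align_views(list(mk(c("B", "A"), "v1"), mk(c("A", "B"), "v2")))
  expect_equal(same$sample_ids, c("A", "B"))
  expect_equal(attr(same, "dropped"), c(v1 = 0L, v2 = 0L))

  expect_error(align_views(list(mk(c("A"), "v1"), mk(c("B"), "v2"))),
               "no samples")
})

test_that("drop_missing_features removes exactly the incomplete columns", {
  X <- cbind(a = c(1, 2, 3), b = c(1, NA, 3))
  v <- drop_missing_features(mv_view(X))
  expect_equal(v$feature_names, "a")
  complete <- mv_view(cbind(a = 1:3, b = 4:6))
  expect_equal(drop_missing_features(complete)$matrix, complete$matrix)
  allna <- mv_view(cbind(a = c(1, NA), b = c(NA, 2)))
  expect_warning(out <- drop_missing_features(allna), "all features")
  expect_equal(ncol(out$matrix), 0L)
})

test_that("rescale_unit_interval maps slices affinely onto [0,1]", {
  v <- mv_view(cbind(a = c(2, 4, 6), b = c(5, 5, 5), c = c(0, 0.25, 1)))
  r <- rescale_unit_interval(v)
  expect_equal(r$matrix[, "a"], c(0, 0.5, 1))
  expect_equal(r$matrix[, "b"], c(0, 0, 0))  # constant slice -> zeros
  expect_equal(r$matrix[, "c"], c(0, 0.25, 1))  # full-range data unchanged
  # idempotence on full-range per-feature scaling
  expect_equal(rescale_unit_interval(r)$matrix, r$matrix)
  # per-sample axis rescales rows instead
  rs <- rescale_unit_interval(mv_view(rbind(c(2, 4, 6))), axis = "per_sample")
  expect_equal(as.numeric(rs$matrix), c(0, 0.5, 1))
})

test_that("variance_filter removes strictly-below-threshold features", {
  m <- 10
  x_exact <- rep(c(0, 2 * sqrt(0.02)), m / 2)  # population variance 0.02
  expect_equal(mean(x_exact^2) - mean(x_exact)^2, 0.02)
  v <- mv_view(cbind(const = rep(1, m), boundary = x_exact,
                     wide = seq(0, 1, length.out = m)))
  out <- variance_filter(v, threshold = 0.02)
  expect_equal(out$feature_names, c("boundary", "wide"))
  # threshold 0 keeps everything
  expect_equal(variance_filter(v, threshold = 0)$feature_names,
               v$feature_names)
})

test_that("label_survival follows the 3-year rule table", {
  out <- label_survival(times = c(4.0, 1.5, 1.5, 3.0, 0.5),
                        vital_status = c(1, 0, 1, 0, 0))
  expect_equal(out$labels, c(1L, 0L, NA, 1L, 0L))
  expect_equal(out$keep, c(TRUE, TRUE, FALSE, TRUE, TRUE))
  # exhaustive rule-table check against an enumerated oracle
  grid <- expand.grid(time = c(0, 1, 2.9, 3, 3.1, 10), status = 0:1)
  got <- label_survival(grid$time, grid$status)$labels
  want <- ifelse(grid$time >= 3, 1L,
                 ifelse(grid$status == 0, 0L, NA_integer_))
  expect_equal(got, want)
  expect_error(label_survival(-1, 0), "negative")
  expect_error(label_survival(c(1, 2), 0), "length")
})

test_that("preprocessing pipeline composes and is idempotent on its output", {
  withr::with_seed(3, {
    X <- matrix(runif(60, 0, 5), 12, 5)
    X[2, 3] <- NA
    X[, 5] <- 2  # constant: killed by the variance filter after rescaling
  })
  v <- mv_view(X, name = "v")
  p1 <- preprocess_view(v)
  expect_equal(ncol(p1$matrix), 3L)
  expect_true(all(p1$matrix >= 0 & p1$matrix <= 1))
  p2 <- preprocess_view(p1)
  expect_equal(p2$matrix, p1$matrix)
})

test_that("dataset constructors enforce their invariants", {
  v1 <- mv_view(matrix(1:6, 3, 2), "v1")
  expect_error(mv_view(matrix(1:6, 3, 2), feature_names = c("a", "a")),
               "duplicate")
  expect_error(mv_dataset(list(v1, mv_view(matrix(1:4, 2, 2), "v2"))),
               "same number of samples")
  expect_error(mv_dataset(v1, labels = c(0, 1, 2)), "binary")
  expect_error(selection_result(data.frame(view = c(1, 1),
                                           feature = c(2, 2)), 1),
               "twice")
})

test_that("selection results serialize to the per-view JSON document", {
  sel <- selection_result(data.frame(view = c(2L, 1L, 2L),
                                     feature = c(3L, 1L, 1L)),
                          n_views = 2L, view_names = c("cna", "rna"),
                          feature_names = list(c("a", "b"),
                                               c("x", "y", "z")))
  expect_equal(length(sel), 3L)
  expect_equal(sel$per_view_indices, list(cna = 1L, rna = c(3L, 1L)))
  doc <- jsonlite::fromJSON(selection_to_json(sel))
  expect_equal(doc, list(cna = "a", rna = c("z", "x")))
})
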