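#' Specification of a synthetic labeled multi-view dataset
#'
#' Describes a controllable stand-in for a multi-omics cohort: each view
#' carries a block of planted class-associated ("relevant") features, noisy
#' within-view copies of those features, cross-view copies shared with the
#' next view, and bulk class-independent noise, with a binary outcome.
#'
#' Defaults emulate the structure of a modest two-source tumor cohort:
#' 300 samples, two views of 200 features each with 10 relevant features per
#' view, a mildly unbalanced outcome (59% positives, the long-term-survivor
#' fraction typical of 3-year survival labels), and a standardized mean
#' shift (effect size) of 1 between classes in the relevant features.
#'
#' @param m Number of samples.
#' @param v Number of views.
#' @param n_per_view Features per view (scalar or length-`v`).
#' @param n_relevant Planted relevant features per view.
#' @param n_redundant_within Noisy within-view copies of relevant features
#'   per view (correlation `rho_within` with their originals).
#' @param n_cross_pairs Cross-view copy pairs: for each view `t < v`,
#'   this many of its relevant features are copied (at correlation
#'   `rho_cross`) into view `t + 1`.
#' @param class_balance Fraction of positive labels, in (0, 1).
#' @param effect_size Between-class mean shift of relevant features, in
#'   units of `noise_sd`.
#' @param noise_sd Within-class standard deviation of all features.
#' @param rho_within,rho_cross Target absolute Pearson correlation of
#'   within-view / cross-view copies with their originals, in (0, 1].
#' @param complementary If `TRUE`, relevant features are view-specific
#'   (each view's block is independent signal, so no single view carries
#'   the whole outcome) — this is the default and the interesting regime
#'   for multi-view selection.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(m = 300L, v = 2L, n_per_view = 200L,
                           n_relevant = 10L, n_redundant_within = 0L,
                           n_cross_pairs = 0L, class_balance = 0.59,
                           effect_size = 1.0, noise_sd = 1.0,
                           rho_within = 0.8, rho_cross = 0.95,
                           complementary = TRUE) {
  n_per_view <- rep_len(as.integer(n_per_view), v)
  spec <- list(m = as.integer(m), v = as.integer(v), n_per_view = n_per_view,
               n_relevant = as.integer(n_relevant),
               n_redundant_within = as.integer(n_redundant_within),
               n_cross_pairs = as.integer(n_cross_pairs),
               class_balance = class_balance, effect_size = effect_size,
               noise_sd = noise_sd, rho_within = rho_within,
               rho_cross = rho_cross, complementary = isTRUE(complementary))
  if (spec$m < 4L) stop("need at least 4 samples")
  if (spec$v < 1L) stop("need at least one view")
  if (spec$class_balance <= 0 || spec$class_balance >= 1) {
    stop("class_balance must be in (0, 1)")
  }
  if (spec$rho_within <= 0 || spec$rho_within > 1 ||
      spec$rho_cross <= 0 || spec$rho_cross > 1) {
    stop("copy correlations must be in (0, 1]")
  }
  occupied <- spec$n_relevant + spec$n_redundant_within + spec$n_cross_pairs
  if (any(occupied > spec$n_per_view)) {
    stop("planted feature counts exceed the per-view feature budget")
  }
  if (spec$n_cross_pairs > spec$n_relevant) {
    stop("cannot copy more relevant features across views than exist")
  }
  if (spec$n_relevant == 0L && spec$n_redundant_within > 0L) {
    stop("within-view copies need relevant features to copy")
  }
  structure(spec, class = "synthetic_spec")
}

#' Generate a synthetic labeled multi-view dataset
#'
#' Labels are Bernoulli draws at the requested balance (re-drawn in the rare
#' event of a single-class vector). Relevant features are class-conditional
#' Gaussians with mean shift `effect_size * noise_sd`; copies are their
#' originals plus fresh Gaussian noise with
#' `sd = sd(original) * sqrt(1 / rho^2 - 1)`, which targets the requested
#' correlation exactly in expectation; noise features are class-independent
#' Gaussians. Every feature is finally rescaled to the unit interval
#' (rescaling does not change correlations or class separation ordering).
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return A list with `dataset` (an [mv_dataset]) and `truth`, the ground
#'   truth holding `relevant` (per-view index vectors) and `redundancy_map`
#'   (data frame of original/copy pairs, within and across views).
#' @export
generate_multiview <- function(spec = synthetic_spec(), seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  gen <- function() {
    y <- stats::rbinom(spec$m, 1L, spec$class_balance)
    tries <- 0L
    while (length(unique(y)) < 2L && tries < 100L) {
      y <- stats::rbinom(spec$m, 1L, spec$class_balance)
      tries <- tries + 1L
    }
    shift <- spec$effect_size * spec$noise_sd
    views <- vector("list", spec$v)
    relevant <- vector("list", spec$v)
    rmap <- data.frame(view_orig = integer(0), feature_orig = integer(0),
                       view_copy = integer(0), feature_copy = integer(0),
                       kind = character(0))
    relevant_mats <- vector("list", spec$v)

    for (t in seq_len(spec$v)) {
      n <- spec$n_per_view[t]
      X <- matrix(stats::rnorm(spec$m * n, sd = spec$noise_sd), spec$m, n)
      nrel <- spec$n_relevant
      rel_idx <- seq_len(nrel)
      if (nrel > 0L) {
        # complementary: independent per-view signal; otherwise every view
        # expresses the same latent signal features
        X[, rel_idx] <- X[, rel_idx] + outer(as.numeric(y), rep(shift, nrel))
        if (!spec$complementary && t > 1L) {
          X[, rel_idx] <- relevant_mats[[1L]] +
            matrix(stats::rnorm(spec$m * nrel, sd = spec$noise_sd), spec$m, nrel)
        }
      }
      relevant_mats[[t]] <- X[, rel_idx, drop = FALSE]
      relevant[[t]] <- rel_idx
      pos <- nrel
      if (spec$n_redundant_within > 0L) {
        for (ci in seq_len(spec$n_redundant_within)) {
          src <- rel_idx[((ci - 1L) %% nrel) + 1L]
          pos <- pos + 1L
          sd_n <- stats::sd(X[, src]) * sqrt(1 / spec$rho_within^2 - 1)
          X[, pos] <- X[, src] + stats::rnorm(spec$m, sd = sd_n)
          rmap <- rbind(rmap, data.frame(view_orig = t, feature_orig = src,
                                         view_copy = t, feature_copy = pos,
                                         kind = "within"))
        }
      }
      nm <- c(sprintf("rel%02d", rel_idx),
              if (spec$n_redundant_within > 0L)
                sprintf("wred%02d", seq_len(spec$n_redundant_within)),
              sprintf("noise%03d", seq_len(n - pos)))
      views[[t]] <- list(X = X, names = nm, next_pos = pos)
    }
    # cross-view copies: view t's first relevant features copied into t+1
    if (spec$n_cross_pairs > 0L && spec$v > 1L) {
      for (t in seq_len(spec$v - 1L)) {
        tgt <- t + 1L
        for (ci in seq_len(spec$n_cross_pairs)) {
          src <- relevant[[t]][ci]
          pos <- views[[tgt]]$next_pos + 1L
          views[[tgt]]$next_pos <- pos
          x0 <- views[[t]]$X[, src]
          sd_n <- stats::sd(x0) * sqrt(1 / spec$rho_cross^2 - 1)
          views[[tgt]]$X[, pos] <- x0 + stats::rnorm(spec$m, sd = sd_n)
          views[[tgt]]$names[pos] <- sprintf("xred%02d", ci)
          rmap <- rbind(rmap, data.frame(view_orig = t, feature_orig = src,
                                         view_copy = tgt, feature_copy = pos,
                                         kind = "cross"))
        }
      }
    }
    mv_views <- lapply(seq_len(spec$v), function(t) {
      vw <- mv_view(views[[t]]$X, name = paste0("view", t),
                    feature_names = views[[t]]$names,
                    sample_ids = sprintf("s%04d", seq_len(spec$m)))
      rescale_unit_interval(vw, axis = "per_feature")
    })
    list(dataset = mv_dataset(mv_views, labels = y),
         truth = structure(list(relevant = relevant, redundancy_map = rmap),
                           class = "mv_ground_truth"))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Redundancy-aware recovery of planted signal
#'
#' Scores a selection against the generator's ground truth. Each planted
#' relevant feature is one "signal"; a selected copy (within- or cross-view)
#' counts as recovering its original, but an original and its own copy
#' together still count once.
#'
#' @param selection A [selection_result] over the generated dataset.
#' @param truth The `truth` component returned by [generate_multiview()].
#' @return A list with `precision` (fraction of selected features that map
#'   to some planted signal; 0 when nothing is relevant) and `recall`
#'   (fraction of planted signals recovered; 1 when nothing is relevant).
#' @export
recovery_score <- function(selection, truth) {
  sig_id <- function(view, feature) paste(view, feature, sep = ":")
  signals <- unlist(lapply(seq_along(truth$relevant), function(t) {
    if (length(truth$relevant[[t]]) == 0L) character(0)
    else sig_id(t, truth$relevant[[t]])
  }), use.names = FALSE)
  rm <- truth$redundancy_map
  copy_key <- sig_id(rm$view_copy, rm$feature_copy)
  copy_val <- sig_id(rm$view_orig, rm$feature_orig)
  canon <- function(key) {
    # follow copy -> original links (cross copies may chain through views)
    seen <- character(0)
    while (key %in% copy_key && !key %in% seen) {
      seen <- c(seen, key)
      key <- copy_val[match(key, copy_key)]
    }
    key
  }
  so <- selection$selection_order
  sel_keys <- vapply(seq_len(nrow(so)),
                     function(i) canon(sig_id(so$view[i], so$feature[i])),
                     character(1))
  hits <- sel_keys %in% signals
  precision <- if (nrow(so) == 0L || length(signals) == 0L) 0
               else mean(hits)
  recall <- if (length(signals) == 0L) 1
            else length(unique(sel_keys[hits])) / length(signals)
  list(precision = precision, recall = recall)
}
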