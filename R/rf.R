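#' Random-forest configuration
#'
#' The ensemble protocol: `n_trees` binary classification trees, each grown
#' on a bag of `floor(bag_fraction * n)` training samples drawn *without*
#' replacement and restricted to `features_per_tree` features drawn without
#' replacement — features are fixed per tree, not re-drawn per split. Votes
#' for a training sample are aggregated only over trees whose bag excluded it
#' (out-of-bag evaluation).
#'
#' @param n_trees number of trees (default 1000).
#' @param bag_fraction fraction of training samples per bag (default 0.66).
#' @param features_per_tree features per tree (default 3).
#' @param vote_threshold a sample is called positive when its positive vote
#'   fraction strictly exceeds this (default 0.5; ties are conservative,
#'   i.e. negative).
#' @param seed RNG seed making bags, feature subsets and permutation
#'   importance reproducible.
#' @return an object of class `forest_config`.
#' @export
forest_config <- function(n_trees = 1000L, bag_fraction = 0.66,
                          features_per_tree = 3L, vote_threshold = 0.5,
                          seed = 1L) {
  stopifnot(bag_fraction > 0, bag_fraction < 1, features_per_tree >= 1)
  structure(list(n_trees = as.integer(n_trees), bag_fraction = bag_fraction,
                 features_per_tree = as.integer(features_per_tree),
                 vote_threshold = vote_threshold, seed = as.integer(seed)),
            class = "forest_config")
}

rpart_ctrl <- function() {
  rpart::rpart.control(minsplit = 2L, minbucket = 1L, cp = 0, xval = 0L,
                       maxcompete = 0L, maxsurrogate = 0L, usesurrogate = 0L)
}

as_label_factor <- function(y) {
  if (is.logical(y)) return(factor(y, levels = c(FALSE, TRUE), labels = c("neg", "pos")))
  if (is.factor(y) || is.character(y)) {
    y <- as.character(y)
    if (!all(y %in% c("negative", "positive"))) {
      stop("labels must be logical or 'positive'/'negative'")
    }
    return(factor(y == "positive", levels = c(FALSE, TRUE), labels = c("neg", "pos")))
  }
  stop("unsupported label type")
}

#' Train the random forest on a labeled feature matrix
#'
#' Per-tree CART models are fit with `rpart` (Gini splits, grown to purity,
#' no pruning); the bagging, out-of-bag vote aggregation, confusion matrix
#' and permutation importance protocol are implemented here.
#'
#' @param x data frame or matrix of feature columns (rows = precursors).
#' @param y labels: logical (TRUE = miRNA) or "positive"/"negative".
#' @param cfg a [forest_config()].
#' @return an object of class `mirforge_rf` with elements `trees` (each a
#'   list of `fit`, `feats`, `bag`), `oob_votes` (per-sample positive vote
#'   fraction), `oob_predicted`, `oob_accuracy`, `confusion`
#'   (tp/fp/tn/fn and per-class error rates), `feature_names`, `config`.
#' @export
rf_train <- function(x, y, cfg = forest_config()) {
  x <- as.data.frame(x)
  yf <- as_label_factor(y)
  if (length(unique(yf)) < 2L) stop("training data must contain both classes")
  n <- nrow(x); p <- ncol(x)
  stopifnot(n == length(yf), cfg$features_per_tree <= p)
  if (min(table(yf)) < 10L) warning("fewer than 10 training samples in a class")
  bag_size <- max(2L, floor(cfg$bag_fraction * n))
  trees <- vector("list", cfg$n_trees)
  votes_pos <- numeric(n); votes_all <- numeric(n)
  with_seed(cfg$seed, {
    for (t in seq_len(cfg$n_trees)) {
      bag <- sort(sample.int(n, bag_size))
      feats <- sort(sample.int(p, cfg$features_per_tree))
      d <- data.frame(.y = yf[bag], x[bag, feats, drop = FALSE], check.names = FALSE)
      fit <- rpart::rpart(.y ~ ., data = d, method = "class", control = rpart_ctrl())
      trees[[t]] <- list(fit = fit, feats = feats, bag = bag)
      oob <- setdiff(seq_len(n), bag)
      pr <- predict(fit, x[oob, feats, drop = FALSE], type = "class")
      votes_pos[oob] <- votes_pos[oob] + (pr == "pos")
      votes_all[oob] <- votes_all[oob] + 1
    }
  })
  if (any(votes_all == 0)) {
    warning("some training samples were never out of bag; increase n_trees")
  }
  frac <- ifelse(votes_all > 0, votes_pos / votes_all, NA_real_)
  pred_pos <- !is.na(frac) & frac > cfg$vote_threshold
  actual_pos <- yf == "pos"
  confusion <- list(
    tp = sum(pred_pos & actual_pos), fp = sum(pred_pos & !actual_pos),
    tn = sum(!pred_pos & !actual_pos), fn = sum(!pred_pos & actual_pos))
  confusion$class_error_pos <- confusion$fn / max(1L, sum(actual_pos))
  confusion$class_error_neg <- confusion$fp / max(1L, sum(!actual_pos))
  structure(list(
    trees = trees, feature_names = colnames(x),
    oob_votes = frac, oob_predicted = pred_pos,
    oob_accuracy = mean(pred_pos == actual_pos),
    confusion = confusion, labels = actual_pos, config = cfg),
    class = "mirforge_rf")
}

#' @export
print.mirforge_rf <- function(x, ...) {
  cat("Random forest:", length(x$trees), "trees,",
      x$config$features_per_tree, "features/tree\n")
  cat(sprintf("OOB accuracy: %.3f\n", x$oob_accuracy))
  cm <- x$confusion
  cat(sprintf("confusion: tp=%d fp=%d tn=%d fn=%d\n", cm$tp, cm$fp, cm$tn, cm$fn))
  invisible(x)
}

#' Permutation feature importance (mean decrease in OOB accuracy)
#'
#' For every tree using a feature, the feature's values are permuted among
#' that tree's out-of-bag samples and the drop in per-tree OOB accuracy is
#' recorded; the importance is the mean drop over those trees.
#'
#' @param model a trained [rf_train()] model.
#' @param x the training feature matrix.
#' @param y the training labels.
#' @return data frame with `feature`, `mean_decrease`, `rank`, sorted by
#'   decreasing importance.
#' @export
rf_importance <- function(model, x, y) {
  x <- as.data.frame(x)
  yf <- as_label_factor(y)
  p <- ncol(x)
  dec_sum <- numeric(p); dec_n <- integer(p)
  with_seed(model$config$seed + 104729L, {
    for (tr in model$trees) {
      oob <- setdiff(seq_len(nrow(x)), tr$bag)
      if (length(oob) < 2) next
      xo <- x[oob, tr$feats, drop = FALSE]
      base <- mean(predict(tr$fit, xo, type = "class") == yf[oob])
      for (f in tr$feats) {
        xp <- xo
        col <- match(f, tr$feats)
        xp[[col]] <- xp[sample.int(nrow(xp)), col]
        acc <- mean(predict(tr$fit, xp, type = "class") == yf[oob])
        dec_sum[f] <- dec_sum[f] + (base - acc)
        dec_n[f] <- dec_n[f] + 1L
      }
    }
  })
  md <- ifelse(dec_n > 0, dec_sum / dec_n, 0)
  out <- data.frame(feature = colnames(x), mean_decrease = md,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$mean_decrease), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Classify new candidates with a trained forest
#'
#' @param model a trained [rf_train()] model.
#' @param newx feature matrix with the same columns as the training matrix.
#' @return data frame with `vote_fraction` (fraction of trees voting
#'   positive) and `predicted` (logical; strict majority above the vote
#'   threshold).
#' @export
rf_classify <- function(model, newx) {
  newx <- as.data.frame(newx)
  if (!identical(colnames(newx), model$feature_names)) {
    stop("feature columns do not match the training matrix")
  }
  n <- nrow(newx)
  if (n == 0) {
    return(data.frame(vote_fraction = numeric(0), predicted = logical(0)))
  }
  votes <- numeric(n)
  for (tr in model$trees) {
    votes <- votes + (predict(tr$fit, newx[, tr$feats, drop = FALSE],
                              type = "class") == "pos")
  }
  frac <- votes / length(model$trees)
  data.frame(vote_fraction = frac,
             predicted = frac > model$config$vote_threshold)
}
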