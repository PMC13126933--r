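# run code under a local RNG state so callers' streams are untouched
with_seed_ <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Classification metrics from confusion counts
#'
#' Specificity `TN/(TN+FP)`, recall `TP/(TP+FN)`, precision `TP/(TP+FP)`,
#' `F1 = 2 pr re / (pr + re)` and accuracy; rates with a zero denominator
#' propagate as `NA`.
#'
#' @param TP,FP,TN,FN Confusion counts.
#' @return A one-row tibble with the counts and rates.
#' @export
metrics_from_counts <- function(TP, FP, TN, FN) {
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- rate(TP, TP + FP)
  recall <- rate(TP, TP + FN)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else 2 * precision * recall / (precision + recall)
  tibble::tibble(
    TP = TP, FP = FP, TN = TN, FN = FN,
    specificity = rate(TN, TN + FP), recall = recall,
    precision = precision, F1 = f1,
    accuracy = rate(TP + TN, TP + FP + TN + FN))
}

#' Stratified validation split
#'
#' Holds out a class-stratified validation fraction never used for
#' learning (or model selection) afterwards.
#'
#' @param data Labeled tibble with a `class` column (exactly two levels)
#'   and feature columns.
#' @param validation_fraction Held-out fraction (default 0.1).
#' @param seed Integer seed; the split is a pure function of it.
#' @return A list with tibbles `train` and `validation`.
#' @export
split_validation <- function(data, validation_fraction = 0.1, seed = 1L) {
  stopifnot("class" %in% names(data))
  if (nrow(data) < 10L) stop("need at least 10 examples to split")
  classes <- unique(data$class)
  if (length(classes) < 2L) stop("both classes must be present")
  with_seed_(seed, {
    hold <- unlist(lapply(classes, function(cl) {
      idx <- which(data$class == cl)
      sample(idx, round(length(idx) * validation_fraction))
    }))
    list(train = data[-hold, , drop = FALSE],
         validation = data[hold, , drop = FALSE])
  })
}

# ---- CART tree with Gini impurity (classifier backend) ----
# No tree/forest package ships in the target image, so the forest backend
# lives here: bootstrap-bagged binary CART trees with per-node feature
# subsampling and mean-decrease-in-impurity importances.

# grow one tree on X[idx,]; returns flat node table + raw importance
grow_tree <- function(X, y, idx, mtry, max_depth, min_leaf) {
  p <- ncol(X)
  nodes <- list()
  importance <- numeric(p)
  new_node <- function() length(nodes) + 1L

  build <- function(idx, depth) {
    n <- length(idx)
    pos <- sum(y[idx])
    id <- new_node()
    nodes[[id]] <<- list(feature = NA_integer_, threshold = NA_real_,
                         left = NA_integer_, right = NA_integer_,
                         prob = pos / n)
    if (depth >= max_depth || n < 2L * min_leaf || pos == 0L || pos == n) {
      return(id)
    }
    # parent impurity mass: n * gini = n - (pos^2 + neg^2)/n
    imp_parent <- n - (pos^2 + (n - pos)^2) / n
    feats <- sample.int(p, mtry)
    best <- list(gain = 1e-12, feature = NA_integer_, threshold = NA_real_)
    for (f in feats) {
      x <- X[idx, f]
      o <- order(x)
      xs <- x[o]
      ys <- y[idx][o]
      cut_ok <- which(xs[-n] < xs[-1L])
      cut_ok <- cut_ok[cut_ok >= min_leaf & (n - cut_ok) >= min_leaf]
      if (length(cut_ok) == 0L) next
      cpos <- cumsum(ys)
      nl <- cut_ok
      pl <- cpos[cut_ok]
      nr <- n - nl
      pr <- sum(ys) - pl
      imp_children <- (nl - (pl^2 + (nl - pl)^2) / nl) +
        (nr - (pr^2 + (nr - pr)^2) / nr)
      gain <- imp_parent - imp_children
      b <- which.max(gain)
      if (gain[b] > best$gain) {
        best <- list(gain = gain[b], feature = f,
                     threshold = (xs[cut_ok[b]] + xs[cut_ok[b] + 1L]) / 2)
      }
    }
    if (is.na(best$feature)) return(id)
    importance[best$feature] <<- importance[best$feature] + best$gain
    go_left <- X[idx, best$feature] <= best$threshold
    left_id <- build(idx[go_left], depth + 1L)
    right_id <- build(idx[!go_left], depth + 1L)
    nodes[[id]]$feature <<- best$feature
    nodes[[id]]$threshold <<- best$threshold
    nodes[[id]]$left <<- left_id
    nodes[[id]]$right <<- right_id
    id
  }
  build(idx, 0L)
  list(nodes = nodes, importance = importance)
}

predict_tree <- function(tree, X) {
  n <- nrow(X)
  out <- numeric(n)
  for (i in seq_len(n)) {
    node <- 1L
    repeat {
      nd <- tree$nodes[[node]]
      if (is.na(nd$feature)) {
        out[i] <- nd$prob
        break
      }
      node <- if (X[i, nd$feature] <= nd$threshold) nd$left else nd$right
    }
  }
  out
}

#' Random-forest hyperparameters
#'
#' @param n_estimators Number of trees (default 500).
#' @param max_depth Maximum tree depth (default 10).
#' @param min_samples_leaf Minimum examples per leaf (default 5).
#' @param mtry Features tried per split (default `floor(sqrt(p))`,
#'   resolved at fit time when `NULL`).
#' @return A named list of class `rf_hyperparams`.
#' @export
rf_hyperparams <- function(n_estimators = 500L, max_depth = 10L,
                           min_samples_leaf = 5L, mtry = NULL) {
  stopifnot(n_estimators > 0, max_depth > 0, min_samples_leaf > 0)
  structure(list(n_estimators = as.integer(n_estimators),
                 max_depth = as.integer(max_depth),
                 min_samples_leaf = as.integer(min_samples_leaf),
                 mtry = mtry), class = "rf_hyperparams")
}

# labeled tibble -> list(X matrix, y 0/1, positive level, feature names)
design_matrix <- function(data, positive = "solenoid") {
  stopifnot("class" %in% names(data))
  feats <- setdiff(names(data), c("protein_id", "class"))
  X <- as.matrix(data[feats])
  storage.mode(X) <- "double"
  y <- as.integer(data$class == positive)
  if (all(y == 1L) || all(y == 0L)) stop("both classes must be present")
  list(X = X, y = y, positive = positive, features = feats)
}

#' Train the random-forest classifier
#'
#' Bootstrap-bagged Gini CART trees with per-node feature subsampling.
#' With a `grid`, a stratified 5-fold cross-validated grid search selects
#' the best hyperparameter combination (highest mean CV accuracy) before
#' the final fit on all training data.
#'
#' @param data Labeled tibble: `class` column (positive level
#'   `"solenoid"`), optional `protein_id`, remaining columns numeric
#'   features.
#' @param hyperparams An [rf_hyperparams()] object.
#' @param grid Optional named list of hyperparameter vectors to search.
#' @param seed Integer seed; training is a pure function of it.
#' @param positive Positive class label (default `"solenoid"`).
#' @return An object of class `rf_model` with elements `trees`,
#'   `importance` (61-entry mean decrease in impurity, sums to 1),
#'   `features`, `hyperparams`, `seed`, `descriptor_version`.
#' @export
train_rf <- function(data, hyperparams = rf_hyperparams(), grid = NULL,
                     seed = 1L, positive = "solenoid") {
  dm <- design_matrix(data, positive)
  if (!is.null(grid)) {
    hyperparams <- with_seed_(seed + 7L,
                             grid_search_cv(dm, hyperparams, grid))
  }
  mtry <- hyperparams$mtry %||% max(1L, floor(sqrt(ncol(dm$X))))
  n <- nrow(dm$X)
  fits <- with_seed_(seed, {
    purrr::map(seq_len(hyperparams$n_estimators), function(b) {
      boot <- sample.int(n, n, replace = TRUE)
      grow_tree(dm$X, dm$y, boot, mtry = mtry,
                max_depth = hyperparams$max_depth,
                min_leaf = hyperparams$min_samples_leaf)
    })
  })
  imp_per_tree <- vapply(fits, function(f) {
    s <- sum(f$importance)
    if (s > 0) f$importance / s else rep(0, length(f$importance))
  }, numeric(ncol(dm$X)))
  importance <- rowMeans(imp_per_tree)
  if (sum(importance) > 0) importance <- importance / sum(importance)
  names(importance) <- dm$features
  structure(list(trees = lapply(fits, `[[`, "nodes"),
                 importance = importance, features = dm$features,
                 positive = dm$positive, hyperparams = hyperparams,
                 seed = seed, descriptor_version = DESCRIPTOR_VERSION),
            class = "rf_model")
}

# stratified k-fold CV over a hyperparameter grid; best mean accuracy
grid_search_cv <- function(dm, base, grid, k = 5L) {
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  folds <- integer(length(dm$y))
  for (cl in unique(dm$y)) {
    idx <- sample(which(dm$y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  acc <- vapply(seq_len(nrow(combos)), function(i) {
    hp <- utils::modifyList(unclass(base), as.list(combos[i, , drop = FALSE]))
    mtry <- hp$mtry %||% max(1L, floor(sqrt(ncol(dm$X))))
    mean(vapply(seq_len(k), function(fold) {
      tr <- which(folds != fold)
      te <- which(folds == fold)
      fits <- purrr::map(seq_len(hp$n_estimators), function(b) {
        boot <- sample(tr, length(tr), replace = TRUE)
        grow_tree(dm$X, dm$y, boot, mtry, hp$max_depth, hp$min_samples_leaf)
      })
      Xte <- dm$X[te, , drop = FALSE]
      prob <- rowMeans(vapply(fits, function(f) predict_tree(f, Xte),
                              numeric(length(te))))
      mean((prob >= 0.5) == (dm$y[te] == 1L))
    }, numeric(1)))
  }, numeric(1))
  best <- as.list(combos[which.max(acc), , drop = FALSE])
  do.call(rf_hyperparams, utils::modifyList(
    unclass(base)[c("n_estimators", "max_depth", "min_samples_leaf", "mtry")],
    best))
}

#' Predict classes with a trained forest
#'
#' @param object An `rf_model`.
#' @param new_data Tibble with the model's feature columns (extra columns
#'   such as `protein_id` are ignored).
#' @param type `"class"` (default) or `"prob"` (mean leaf positive
#'   fraction over trees).
#' @param ... Unused.
#' @return Logical vector (positive class) or numeric probabilities.
#' @export
predict.rf_model <- function(object, new_data, type = c("class", "prob"),
                             ...) {
  type <- match.arg(type)
  X <- as.matrix(new_data[object$features])
  storage.mode(X) <- "double"
  prob <- rowMeans(vapply(object$trees, function(nodes) {
    predict_tree(list(nodes = nodes), X)
  }, numeric(nrow(X))))
  if (type == "prob") prob else prob >= 0.5
}

#' Evaluate a classifier on a labeled set
#'
#' @param model An `rf_model`.
#' @param data Labeled tibble (as in [train_rf()]).
#' @return A one-row metrics tibble (see [metrics_from_counts()]).
#' @export
evaluate_rf <- function(model, data) {
  pred <- predict(model, data)
  truth <- data$class == model$positive
  metrics_from_counts(TP = sum(pred & truth), FP = sum(pred & !truth),
                      TN = sum(!pred & !truth), FN = sum(!pred & truth))
}

#' Ensemble detection with a retention quorum
#'
#' Trains `n_runs` forests, each with its own seed and a fresh stratified
#' re-subsample of the training pool, predicts the probe proteins with
#' each, and retains a probe when it is predicted positive in at least
#' `retention` of the runs (`>=`, "at least 90% of the iterations").
#'
#' @param train_pool Labeled tibble (as in [train_rf()]).
#' @param probes Tibble of probe descriptors (feature columns plus
#'   `protein_id`).
#' @param n_runs Number of independent trainings (default 1000).
#' @param retention Retention fraction (default 0.9).
#' @param subsample Fraction of the pool drawn (stratified, without
#'   replacement) for each run (default 0.9).
#' @param hyperparams An [rf_hyperparams()] object.
#' @param seed Base seed; run `r` uses `seed + r`.
#' @return A tibble `protein_id`, `retrieval_count`, `retained`, with
#'   attributes `n_runs` and `retention`.
#' @export
ensemble_detect <- function(train_pool, probes, n_runs = 1000L,
                            retention = 0.9, subsample = 0.9,
                            hyperparams = rf_hyperparams(), seed = 1L) {
  counts <- integer(nrow(probes))
  for (r in seq_len(n_runs)) {
    sub <- with_seed_(seed + r, {
      idx <- unlist(lapply(unique(train_pool$class), function(cl) {
        i <- which(train_pool$class == cl)
        sample(i, max(1L, round(length(i) * subsample)))
      }))
      train_pool[idx, , drop = FALSE]
    })
    model <- train_rf(sub, hyperparams, seed = seed + r)
    counts <- counts + as.integer(predict(model, probes))
  }
  retention_verdict(probes$protein_id, counts, n_runs, retention)
}

#' Apply the retention rule to retrieval counts
#'
#' Exposed separately so the quorum boundary (`count / n_runs >=
#' retention`) is testable without 1000 trainings.
#'
#' @param protein_id Probe ids.
#' @param retrieval_count Positive predictions per probe.
#' @param n_runs Total runs.
#' @param retention Retention fraction (default 0.9).
#' @return A tibble `protein_id`, `retrieval_count`, `retained`.
#' @export
retention_verdict <- function(protein_id, retrieval_count, n_runs,
                              retention = 0.9) {
  out <- tibble::tibble(protein_id = protein_id,
                        retrieval_count = as.integer(retrieval_count),
                        retained = retrieval_count / n_runs >= retention)
  attr(out, "n_runs") <- n_runs
  attr(out, "retention") <- retention
  out
}

#' Feature importances ranked by mean decrease in impurity
#'
#' @param model An `rf_model`.
#' @return A tibble `feature`, `importance`, descending (ties keep
#'   feature order); importances sum to 1.
#' @export
rank_feature_importance <- function(model) {
  imp <- model$importance
  o <- order(-imp)
  tibble::tibble(feature = names(imp)[o], importance = unname(imp[o]))
}

#' @export
print.rf_model <- function(x, ...) {
  cat("Random forest: ", length(x$trees), " trees, ",
      length(x$features), " features (descriptor ",
      x$descriptor_version, ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Tidy a random-forest model into its importance table
#' @param x An `rf_model`.
#' @param ... Unused.
#' @return The ranked importance tibble (see [rank_feature_importance()]).
#' @export
tidy.rf_model <- function(x, ...) rank_feature_importance(x)

#' One-row summary of a random-forest model
#' @inheritParams tidy.rf_model
#' @return A one-row tibble of the fitted configuration.
#' @export
glance.rf_model <- function(x, ...) {
  tibble::tibble(n_trees = length(x$trees), n_features = length(x$features),
                 max_depth = x$hyperparams$max_depth,
                 min_samples_leaf = x$hyperparams$min_samples_leaf,
                 seed = x$seed, descriptor_version = x$descriptor_version)
}
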