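#' Bin the 0-100 health score into four classes
#'
#' Class 1: score <= 20; class 2: 20 < score <= 40; class 3: 40 < score
#' <= 60; class 4: score > 60 (right-closed boundaries).
#'
#' @param score numeric vector in [0, 100].
#' @return Integer class vector in \{1, 2, 3, 4\}.
#' @export
bin_health <- function(score) {
  as.integer(cut(score, breaks = c(-Inf, 20, 40, 60, Inf), right = TRUE,
                 labels = FALSE))
}

# Shannon entropy (base 2) of a class vector
entropy2 <- function(y) {
  p <- table(y) / length(y)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information gain of a candidate binary partition
#'
#' H(y) - sum_g (n_g / n) H(y_g) in bits, for the two groups induced by
#' \code{left} (a logical vector).
#'
#' @param y class labels.
#' @param left logical vector defining the left branch.
#' @return Information gain in bits.
#' @export
information_gain <- function(y, left) {
  n <- length(y)
  nl <- sum(left)
  if (nl == 0 || nl == n) return(0)
  entropy2(y) - nl / n * entropy2(y[left]) -
    (n - nl) / n * entropy2(y[!left])
}

# best binary level-set split of one categorical feature; returns NULL
# when no admissible split exists
best_split_feature <- function(x, y, min_leaf) {
  levs <- sort(unique(x))
  L <- length(levs)
  if (L < 2) return(NULL)
  best <- NULL
  # enumerate proper subsets containing the first level (complement
  # symmetry; the full set is excluded), in deterministic order
  for (mask in 0:(2^(L - 1) - 2)) {
    inset <- c(TRUE, as.logical(bitwAnd(mask, 2^(seq_len(L - 1) - 1)) > 0))
    left <- x %in% levs[inset]
    if (sum(left) < min_leaf || sum(!left) < min_leaf) next
    g <- information_gain(y, left)
    if (is.null(best) || g > best$gain + 1e-12) {
      best <- list(gain = g, levels_left = levs[inset], left = left)
    }
  }
  best
}

grow_node <- function(X, y, depth, max_depth, min_leaf, features, mtry) {
  leaf <- function() {
    tab <- tabulate(y, nbins = max(4, max(y)))
    list(leaf = TRUE, class = which.max(tab), n = length(y),
         dist = tab)
  }
  if (depth >= max_depth || length(y) < 2 * min_leaf ||
      length(unique(y)) == 1) {
    return(leaf())
  }
  cand <- if (mtry < length(features)) sample(features, mtry) else features
  cand <- sort(cand)
  best <- NULL
  for (f in cand) {
    s <- best_split_feature(X[[f]], y, min_leaf)
    if (!is.null(s) && (is.null(best) || s$gain > best$gain + 1e-12)) {
      best <- c(s, feature = f)
    }
  }
  if (is.null(best) || best$gain <= 1e-12) return(leaf())
  left <- best$left
  list(leaf = FALSE, feature = best$feature,
       levels_left = best$levels_left, gain = best$gain, n = length(y),
       left = grow_node(X[left, , drop = FALSE], y[left], depth + 1,
                        max_depth, min_leaf, features, mtry),
       right = grow_node(X[!left, , drop = FALSE], y[!left], depth + 1,
                         max_depth, min_leaf, features, mtry))
}

#' Grow a single information-gain decision tree
#'
#' Recursive binary splits on level sets of categorical features,
#' maximising the entropy-based information gain; growth stops at
#' \code{max_depth}, when a child would fall under \code{min_leaf} rows,
#' or when no split improves the gain. Leaf labels are majority classes
#' with ties broken toward the lowest class index. All randomness (the
#' per-split feature subsample when \code{mtry} < p) is governed by
#' \code{seed}.
#'
#' @param X data frame of categorical/ordinal features.
#' @param y integer class labels (1-based).
#' @param max_depth maximum tree depth (default 4).
#' @param min_leaf minimum rows per leaf (default 20).
#' @param feature_subset optional character vector restricting the
#'   candidate features.
#' @param mtry number of features sampled per split (default: all).
#' @param seed integer seed.
#' @return Object of class \code{"ig_tree"}.
#' @export
grow_tree <- function(X, y, max_depth = 4, min_leaf = 20,
                      feature_subset = NULL, mtry = NULL, seed = 1L) {
  X <- as.data.frame(X)
  if (!nrow(X) || !ncol(X)) stop("empty feature matrix")
  stopifnot(length(y) == nrow(X))
  features <- if (is.null(feature_subset)) names(X) else feature_subset
  if (is.null(mtry)) mtry <- length(features)
  set.seed(seed)
  structure(list(root = grow_node(X, as.integer(y), 0L, max_depth,
                                  min_leaf, features, mtry),
                 features = features),
            class = "ig_tree")
}

predict_node <- function(node, X, idx, out) {
  if (node$leaf) {
    out[idx] <- node$class
    return(out)
  }
  go_left <- X[[node$feature]][idx] %in% node$levels_left
  if (any(go_left)) out <- predict_node(node$left, X, idx[go_left], out)
  if (any(!go_left)) out <- predict_node(node$right, X, idx[!go_left], out)
  out
}

#' @export
predict.ig_tree <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  predict_node(object$root, newdata, seq_len(nrow(newdata)),
               integer(nrow(newdata)))
}

#' Bagged forest of information-gain trees
#'
#' Bootstrap row resampling plus per-split random feature subsets;
#' prediction by majority vote (ties toward the lowest class index).
#' Out-of-bag predictions are retained for accuracy and permutation
#' importance.
#'
#' @param X data frame of categorical features.
#' @param y integer class labels.
#' @param n_trees number of trees (default 500).
#' @param mtry features sampled per split (default ceiling(sqrt(p))).
#' @param max_depth,min_leaf tree controls.
#' @param seed integer seed.
#' @param identity_bootstrap if TRUE every tree sees the full sample
#'   (test hook: with \code{n_trees = 1} the forest equals a single
#'   tree).
#' @return Object of class \code{"ig_forest"} with trees, bootstrap
#'   index lists, OOB votes and OOB accuracy.
#' @export
bagged_forest <- function(X, y, n_trees = 500, mtry = NULL,
                          max_depth = 4, min_leaf = 20, seed = 1L,
                          identity_bootstrap = FALSE) {
  X <- as.data.frame(X)
  y <- as.integer(y)
  n <- nrow(X)
  p <- ncol(X)
  if (is.null(mtry)) mtry <- ceiling(sqrt(p))
  set.seed(seed)
  tree_seeds <- sample.int(.Machine$integer.max, n_trees)
  trees <- vector("list", n_trees)
  inbag <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    rows <- if (identity_bootstrap) seq_len(n) else {
      set.seed(tree_seeds[t])
      sample(n, n, replace = TRUE)
    }
    trees[[t]] <- grow_tree(X[rows, , drop = FALSE], y[rows],
                            max_depth = max_depth, min_leaf = min_leaf,
                            mtry = mtry, seed = tree_seeds[t])
    inbag[[t]] <- rows
  }
  forest <- structure(list(trees = trees, inbag = inbag, n = n,
                           classes = sort(unique(y)), mtry = mtry,
                           X_names = names(X)),
                      class = "ig_forest")
  forest$oob_pred <- oob_predict(forest, X)
  forest$oob_accuracy <- mean(forest$oob_pred == y, na.rm = TRUE)
  forest
}

# OOB prediction, optionally with one feature's column permuted
oob_predict <- function(forest, X, permute_feature = NULL, perm = NULL) {
  n <- forest$n
  n_class <- max(forest$classes)
  counts <- matrix(0L, n, n_class)
  Xp <- X
  if (!is.null(permute_feature)) Xp[[permute_feature]] <- X[[permute_feature]][perm]
  for (t in seq_along(forest$trees)) {
    oob <- setdiff(seq_len(n), unique(forest$inbag[[t]]))
    if (!length(oob)) next
    pr <- predict_node(forest$trees[[t]]$root, Xp, oob, integer(n))
    counts[cbind(oob, pr[oob])] <- counts[cbind(oob, pr[oob])] + 1L
  }
  pred <- max.col(counts, ties.method = "first")
  pred[rowSums(counts) == 0] <- NA_integer_
  pred
}

#' @export
predict.ig_forest <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  n_class <- max(object$classes)
  counts <- matrix(0L, nrow(newdata), n_class)
  for (tr in object$trees) {
    pr <- predict(tr, newdata)
    counts[cbind(seq_len(nrow(newdata)), pr)] <-
      counts[cbind(seq_len(nrow(newdata)), pr)] + 1L
  }
  max.col(counts, ties.method = "first")
}

#' Stratified k-fold cross-validated accuracy
#'
#' Splits rows into k folds stratified by class, trains the supplied
#' builder on each training part and returns the mean held-out accuracy.
#'
#' @param builder function(X, y) returning an object with a
#'   \code{predict(object, newdata)} method.
#' @param X data frame of features.
#' @param y class labels.
#' @param k number of folds (default 10; \code{k = n} gives
#'   leave-one-out).
#' @param seed integer seed for the fold assignment.
#' @return Mean held-out accuracy (scalar), with per-fold accuracies as
#'   attribute \code{"folds"}.
#' @export
cv_accuracy <- function(builder, X, y, k = 10, seed = 1L) {
  X <- as.data.frame(X)
  n <- nrow(X)
  stopifnot(k >= 2, k <= n)
  set.seed(seed)
  fold <- integer(n)
  if (k == n) {
    fold <- sample(n)                  # leave-one-out
  } else {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  }
  used <- sort(unique(fold))
  accs <- vapply(used, function(f) {
    te <- which(fold == f)
    fit <- builder(X[-te, , drop = FALSE], y[-te])
    mean(predict(fit, X[te, , drop = FALSE]) == y[te])
  }, numeric(1))
  structure(mean(accs), folds = accs)
}

#' Permutation importance (mean decrease in accuracy)
#'
#' For each feature, MDA = 100 x (baseline OOB accuracy - mean OOB
#' accuracy with that feature's column permuted), averaged over
#' \code{n_perm} permutations. A feature unused by every tree scores
#' ~ 0.
#'
#' @param forest an \code{"ig_forest"}.
#' @param X,y the training data.
#' @param n_perm permutations per feature (default 10).
#' @param seed integer seed.
#' @return Data frame (feature, mda) sorted by decreasing MDA.
#' @export
mda_importance <- function(forest, X, y, n_perm = 10, seed = 1L) {
  X <- as.data.frame(X)
  y <- as.integer(y)
  set.seed(seed)
  base_acc <- forest$oob_accuracy
  mda <- vapply(names(X), function(f) {
    accs <- vapply(seq_len(n_perm), function(r) {
      perm <- sample(forest$n)
      mean(oob_predict(forest, X, permute_feature = f, perm = perm) == y,
           na.rm = TRUE)
    }, numeric(1))
    100 * (base_acc - mean(accs))
  }, numeric(1))
  out <- data.frame(feature = names(X), mda = unname(mda), row.names = NULL)
  out[order(-out$mda), ]
}

# enumerate root-to-leaf paths of a tree as condition lists
tree_paths <- function(node, conds = list()) {
  if (node$leaf) {
    return(list(list(conditions = conds, class = node$class)))
  }
  lc <- c(conds, list(list(feature = node$feature, op = "in",
                           levels = node$levels_left)))
  rc <- c(conds, list(list(feature = node$feature, op = "not_in",
                           levels = node$levels_left)))
  c(tree_paths(node$left, lc), tree_paths(node$right, rc))
}

match_conditions <- function(conds, X) {
  sel <- rep(TRUE, nrow(X))
  for (cn in conds) {
    inset <- X[[cn$feature]] %in% cn$levels
    sel <- sel & if (cn$op == "in") inset else !inset
  }
  sel
}

#' Extract pattern rules from an ensemble of decision trees
#'
#' Grows \code{n_trees} seeded trees, each on a bootstrap sample with a
#' random feature subset, enumerates every root-to-leaf path as a
#' conjunction of level-set conditions, scores each path's accuracy
#' (fraction of matched rows falling in the predicted class) on the full
#' sample (or out-of-bag rows only), and keeps paths with accuracy at
#' least \code{min_accuracy}.
#'
#' @param X data frame of categorical features.
#' @param y integer class labels.
#' @param n_trees number of trees (default 100).
#' @param min_accuracy rule-confidence threshold (default 0.40; 0.25 is
#'   the accuracy of a random classifier over four balanced classes).
#' @param feature_fraction fraction of features available to each tree
#'   (default 2/3).
#' @param max_depth,min_leaf tree controls.
#' @param evaluate \code{"full"} (default) scores rules on the full
#'   sample; \code{"oob"} on each tree's out-of-bag rows.
#' @param seed integer seed.
#' @return List of \code{"pattern_rule"} objects: conditions (ordered
#'   root-to-leaf), predicted class, support and accuracy.
#' @export
extract_patterns <- function(X, y, n_trees = 100, min_accuracy = 0.40,
                             feature_fraction = 2 / 3, max_depth = 4,
                             min_leaf = 20, evaluate = c("full", "oob"),
                             seed = 1L) {
  evaluate <- match.arg(evaluate)
  X <- as.data.frame(X)
  y <- as.integer(y)
  n <- nrow(X)
  p <- ncol(X)
  set.seed(seed)
  tree_seeds <- sample.int(.Machine$integer.max, n_trees)
  rules <- list()
  for (t in seq_len(n_trees)) {
    set.seed(tree_seeds[t])
    rows <- sample(n, n, replace = TRUE)
    feats <- sample(names(X), max(2, ceiling(feature_fraction * p)))
    tr <- grow_tree(X[rows, , drop = FALSE], y[rows],
                    max_depth = max_depth, min_leaf = min_leaf,
                    feature_subset = feats, seed = tree_seeds[t])
    eval_rows <- if (evaluate == "full") seq_len(n) else {
      setdiff(seq_len(n), unique(rows))
    }
    if (!length(eval_rows)) next
    for (path in tree_paths(tr$root)) {
      sel <- match_conditions(path$conditions, X[eval_rows, , drop = FALSE])
      support <- sum(sel)
      if (support == 0) next
      acc <- mean(y[eval_rows][sel] == path$class)
      if (acc >= min_accuracy) {
        rules[[length(rules) + 1]] <- structure(
          list(conditions = path$conditions, class = path$class,
               support = support, accuracy = acc, tree = t),
          class = "pattern_rule")
      }
    }
  }
  rules
}

#' Select the most accurate patterns per class
#'
#' Per predicted class, sorts rules by accuracy (ties broken toward
#' larger support, then fewer conditions) and keeps the top
#' \code{per_class}; also counts, per feature, the number of selected
#' patterns whose conditions mention it.
#'
#' @param rules list of \code{"pattern_rule"} (from
#'   \code{\link{extract_patterns}}).
#' @param per_class rules kept per class (default 5).
#' @return List with \code{selected} (list of rules) and
#'   \code{factor_counts} (named integer vector over features).
#' @export
top_patterns <- function(rules, per_class = 5) {
  if (!length(rules)) return(list(selected = list(),
                                  factor_counts = integer()))
  cls <- vapply(rules, `[[`, integer(1), "class")
  selected <- list()
  for (cl in sort(unique(cls))) {
    sub <- rules[cls == cl]
    ord <- order(-vapply(sub, function(r) as.numeric(r$accuracy), numeric(1)),
                 -vapply(sub, function(r) as.numeric(r$support), numeric(1)),
                 vapply(sub, function(r) length(r$conditions), integer(1)))
    selected <- c(selected, sub[ord[seq_len(min(per_class, length(sub)))]])
  }
  feats <- unlist(lapply(selected, function(r) {
    unique(vapply(r$conditions, `[[`, character(1), "feature"))
  }))
  counts <- sort(table(feats), decreasing = TRUE)
  list(selected = selected,
       factor_counts = setNames(as.integer(counts), names(counts)))
}

#' @export
format.pattern_rule <- function(x, ...) {
  conds <- vapply(x$conditions, function(cn) {
    paste0(cn$feature, if (cn$op == "in") " in {" else " not in {",
           paste(cn$levels, collapse = ","), "}")
  }, character(1))
  sprintf("IF %s THEN class %d (support %d, accuracy %.2f)",
          if (length(conds)) paste(conds, collapse = " AND ") else "TRUE",
          x$class, x$support, x$accuracy)
}

#' @export
print.pattern_rule <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
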