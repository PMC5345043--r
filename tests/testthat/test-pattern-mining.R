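test_that("health-score binning follows the right-closed cutpoints", {
  expect_equal(bin_health(c(20, 20.01, 40, 60, 0, 100, 60.01)),
               c(1L, 2L, 2L, 3L, 1L, 4L, 4L))
  # monotone: higher score never maps to a lower class
  s <- sort(runif(200, 0, 100))
  expect_true(all(diff(bin_health(s)) >= 0))
})

test_that("information gain matches hand-computed entropy arithmetic", {
  # printed 8-row toy: y = (1,1,1,1,2,2,2,2), split 6|2 rows
  y <- c(1, 1, 1, 1, 2, 2, 2, 2)
  left <- c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  # H(y) = 1 bit; H(left) = -(4/6)log2(4/6)-(2/6)log2(2/6); H(right) = 0
  h_left <- -(4 / 6) * log2(4 / 6) - (2 / 6) * log2(2 / 6)
  want <- 1 - (6 / 8) * h_left
  expect_equal(information_gain(y, left), want, tolerance = 1e-12)
  # degenerate splits carry no gain
  expect_equal(information_gain(y, rep(TRUE, 8)), 0)
})

test_that("trees solve pure and XOR-style problems exactly", {
  # pure response: single leaf
  X <- data.frame(a = factor(rep(c("x", "y"), 10)))
  t0 <- grow_tree(X, rep(2L, 20), min_leaf = 1)
  expect_true(t0$root$leaf)
  expect_equal(t0$root$class, 2L)

  # near-XOR over two binary features (slightly unbalanced cells so the
  # greedy root split carries positive gain): depth-2, accuracy 1
  g <- expand.grid(a = c("0", "1"), b = c("0", "1"))
  X2 <- g[rep(1:4, times = c(10, 12, 11, 13)), ]
  y2 <- as.integer(xor(X2$a == "1", X2$b == "1")) + 1L
  t2 <- grow_tree(X2, y2, max_depth = 3, min_leaf = 1)
  expect_false(t2$root$leaf)
  expect_false(t2$root$left$leaf)
  expect_equal(predict(t2, X2), y2)

  expect_error(grow_tree(data.frame(), 1:3), "empty")

  # leaf ties break toward the lowest class index
  X3 <- data.frame(a = factor(rep("x", 4)))
  t3 <- grow_tree(X3, c(3L, 3L, 1L, 1L), min_leaf = 1)
  expect_equal(t3$root$class, 1L)
})

test_that("information-gain splits agree with an rpart oracle on a toy", {
  skip_if_not_installed("rpart")
  set.seed(12)
  n <- 400
  X <- data.frame(a = factor(sample(c("lo", "hi"), n, TRUE)),
                  b = factor(sample(c("p", "q", "r"), n, TRUE)))
  y <- ifelse(X$a == "hi", 1L, 2L)
  y[sample(n, 40)] <- 3L              # noise
  tr <- grow_tree(X, y, max_depth = 1, min_leaf = 5)
  or <- rpart::rpart(factor(y) ~ a + b, data = X,
                     parms = list(split = "information"),
                     control = rpart::rpart.control(maxdepth = 1,
                                                    minbucket = 5, cp = 0))
  # both should split on the informative feature
  expect_equal(tr$root$feature, "a")
  expect_equal(as.character(or$frame$var[1]), "a")
})

test_that("bagged forest reduces to a single tree under the test hook", {
  set.seed(13)
  X <- data.frame(a = factor(sample(letters[1:3], 200, TRUE)),
                  b = factor(sample(letters[4:5], 200, TRUE)))
  y <- as.integer(X$a)
  f1 <- bagged_forest(X, y, n_trees = 1, mtry = 2, min_leaf = 5,
                      identity_bootstrap = TRUE, seed = 3)
  expect_equal(predict(f1, X), predict(f1$trees[[1]], X))
  # seed determinism
  f2 <- bagged_forest(X, y, n_trees = 5, seed = 9)
  f3 <- bagged_forest(X, y, n_trees = 5, seed = 9)
  expect_equal(predict(f2, X), predict(f3, X))
  expect_equal(f2$oob_accuracy, f3$oob_accuracy)
})

test_that("OOB accuracy tracks 10-fold CV accuracy", {
  set.seed(14)
  n <- 600
  X <- data.frame(a = factor(sample(c("0", "1"), n, TRUE)),
                  b = factor(sample(c("0", "1", "2"), n, TRUE)),
                  c = factor(sample(c("u", "v"), n, TRUE)))
  y <- 1L + (X$a == "1") + (X$b == "2")
  y <- as.integer(y)
  forest <- bagged_forest(X, y, n_trees = 60, min_leaf = 10, seed = 5)
  cv <- cv_accuracy(function(Xt, yt) {
    bagged_forest(Xt, yt, n_trees = 60, min_leaf = 10, seed = 5)
  }, X, y, k = 10, seed = 5)
  expect_lt(abs(forest$oob_accuracy - cv), 0.05)
})

test_that("cross-validated accuracy has the right baselines", {
  set.seed(15)
  n <- 400
  X <- data.frame(a = factor(sample(c("0", "1"), n, TRUE)))
  y <- rep(1:4, each = n / 4)
  # constant-majority classifier: accuracy equals the majority share
  const_builder <- function(Xt, yt) {
    cls <- which.max(tabulate(yt, 4))
    structure(list(cls = cls), class = "const_clf")
  }
  assign("predict.const_clf",
         function(object, newdata, ...) rep(object$cls, nrow(newdata)),
         envir = globalenv())
  on.exit(rm("predict.const_clf", envir = globalenv()), add = TRUE)
  acc <- cv_accuracy(const_builder, X, y, k = 10, seed = 2)
  expect_lt(abs(acc - 0.25), 0.02)
  # k = n: leave-one-out runs and stays near the same baseline
  y2 <- rep(1:2, each = 20)
  X2 <- data.frame(a = factor(rep(c("0", "1"), 20)))
  acc_loo <- cv_accuracy(const_builder, X2, y2, k = 40, seed = 2)
  expect_true(acc_loo >= 0 && acc_loo <= 1)
})

test_that("permutation importance isolates the informative feature", {
  set.seed(16)
  n <- 500
  X <- data.frame(signal = factor(sample(c("lo", "mid", "hi"), n, TRUE)),
                  noise1 = factor(sample(c("a", "b"), n, TRUE)),
                  noise2 = factor(sample(c("x", "y", "z"), n, TRUE)))
  y <- as.integer(X$signal)
  forest <- bagged_forest(X, y, n_trees = 50, min_leaf = 10, seed = 7)
  imp <- mda_importance(forest, X, y, n_perm = 5, seed = 7)
  expect_equal(imp$feature[1], "signal")
  expect_gt(imp$mda[1], 20)
  # label-independent features sit near zero
  expect_lt(max(abs(imp$mda[imp$feature != "signal"])), 5)
  # ranking stable across seeds
  imp2 <- mda_importance(forest, X, y, n_perm = 5, seed = 8)
  expect_equal(imp2$feature[1], "signal")
})

test_that("pattern extraction matches a brute-force row filter", {
  set.seed(17)
  n <- 300
  X <- data.frame(a = factor(sample(c("0", "1"), n, TRUE)),
                  b = factor(sample(c("p", "q"), n, TRUE)))
  y <- 1L + (X$a == "1") * 2L          # classes 1 and 3
  y <- as.integer(y)
  rules <- extract_patterns(X, y, n_trees = 10, min_accuracy = 0,
                            min_leaf = 10, seed = 21)
  expect_gt(length(rules), 0)
  for (r in rules[seq_len(min(10, length(rules)))]) {
    sel <- rep(TRUE, n)
    for (cn in r$conditions) {
      hit <- X[[cn$feature]] %in% cn$levels
      sel <- sel & (if (cn$op == "in") hit else !hit)
    }
    expect_equal(sum(sel), r$support)
    expect_equal(mean(y[sel] == r$class), r$accuracy)
  }
  # a perfect-signal rule set passes the 40% filter
  rules40 <- extract_patterns(X, y, n_trees = 10, min_accuracy = 0.4,
                              min_leaf = 10, seed = 21)
  expect_true(all(vapply(rules40, `[[`, numeric(1), "accuracy") >= 0.4))
  # single-leaf tree yields an unconditional rule at the class share
  y_const <- rep(c(1L, 2L), c(250, 50))
  r_const <- extract_patterns(X, y_const, n_trees = 2, min_accuracy = 0,
                              max_depth = 0, seed = 3)
  expect_true(all(lengths(lapply(r_const, `[[`, "conditions")) == 0))
  expect_true(all(abs(vapply(r_const, `[[`, numeric(1), "accuracy") -
                        mean(y_const == 1)) < 0.1))
})

test_that("top-pattern selection keeps five per class and counts factors", {
  mk_rule <- function(cl, acc, sup, feats) {
    structure(list(conditions = lapply(feats, function(f) {
      list(feature = f, op = "in", levels = "x")
    }), class = cl, support = sup, accuracy = acc), class = "pattern_rule")
  }
  rules <- c(
    lapply(1:8, function(i) mk_rule(1L, 0.4 + i / 100, 50, "act")),
    lapply(1:6, function(i) mk_rule(2L, 0.5, 10 * i, c("act", "wealth"))),
    lapply(1:5, function(i) mk_rule(3L, 0.6, 30, "falls")),
    lapply(1:7, function(i) mk_rule(4L, 0.9 - i / 50, 5, "age"))
  )
  top <- top_patterns(rules, per_class = 5)
  expect_length(top$selected, 20)
  cls <- vapply(top$selected, `[[`, integer(1), "class")
  expect_equal(as.integer(table(cls)), rep(5L, 4))
  # factor counts recount correctly
  expect_equal(unname(top$factor_counts["act"]), 10L)
  expect_equal(unname(top$factor_counts["wealth"]), 5L)
  # class-2 ties broken toward larger support
  sel2 <- top$selected[cls == 2L]
  expect_equal(vapply(sel2, `[[`, numeric(1), "support"),
               c(60, 50, 40, 30, 20))
})
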