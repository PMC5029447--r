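test_that("entropy matches closed-form values in bits", {
  expect_equal(entropy(c(5, 5)), 1.0)
  expect_equal(entropy(c(10, 0)), 0.0)
  expect_equal(entropy(c(1, 1, 1, 1)), 2.0)
  expect_equal(entropy(c(3, 1)), -0.75 * log2(0.75) - 0.25 * log2(0.25))
  expect_error(entropy(c(0, 0)), "zero")
  expect_error(entropy(c(-1, 2)), "nonnegative")
})

test_that("best_split maximizes information gain, verified by exhaustive enumeration", {
  # one perfectly separating position: gain equals the parent entropy
  x <- cbind(N1 = c("A", "A", "C", "C"), N2 = c("A", "C", "A", "C"))
  s <- best_split(x, c("a", "a", "b", "b"))
  expect_equal(s$position, "N1")
  expect_equal(s$gain, 1.0)

  # identical feature rows with mixed labels: no split
  x2 <- matrix("A", 4, 2, dimnames = list(NULL, c("N1", "N2")))
  expect_null(best_split(x2, c("a", "a", "b", "b")))

  # random tables: gain matches the brute-force oracle over all
  # (position, subset) candidates, and the chosen split is among the argmax
  set.seed(101)
  for (i in 1:50) {
    rt <- random_table(n = sample(6:25, 1), p = sample(1:4, 1),
                       ncat = sample(2:5, 1), nclass = sample(2:4, 1))
    oracle <- brute_force_splits(rt$x, rt$labels)
    got <- best_split(rt$x, rt$labels)
    if (oracle$gain <= 1e-9) {
      expect_null(got)
    } else {
      expect_equal(got$gain, oracle$gain, tolerance = 1e-9)
      hit <- any(vapply(oracle$argmax, function(a)
        identical(a$position, got$position) &&
          setequal(a$left, got$left_categories) ||
          identical(a$position, got$position) &&
          setequal(setdiff(sort(unique(rt$x[, got$position])), a$left),
                   got$left_categories), TRUE))
      expect_true(hit)
    }
  }
})

test_that("a 6-row two-position toy picks the higher-gain position", {
  x <- cbind(N1 = c("A", "A", "A", "C", "C", "C"),
             N2 = c("A", "A", "C", "C", "G", "G"))
  y <- c("a", "a", "a", "b", "b", "a")
  oracle <- brute_force_splits(x, y)
  s <- best_split(x, y)
  expect_equal(s$gain, oracle$gain, tolerance = 1e-9)
  expect_equal(s$position, oracle$argmax[[1]]$position)
})

test_that("fully grown trees hit the unique-row majority bound exactly", {
  # perfectly separable toy
  x <- cbind(N1 = c("A", "C", "G", "U"), N2 = rep("A", 4))
  m <- fit_tree(x, c("a", "b", "c", "d"))
  expect_equal(m$resub_accuracy, 1.0)
  expect_equal(predict(m, x), c("a", "b", "c", "d"))

  # irreducible impurity: identical rows, different labels
  x2 <- matrix("A", 2, 1, dimnames = list(NULL, "N1"))
  m2 <- fit_tree(x2, c("a", "b"))
  expect_equal(length(m2$nodes$split_col), 1L)  # a single leaf
  expect_equal(m2$resub_accuracy, 0.5)

  # XOR-like zero-gain plateau still gets fully resolved
  x3 <- cbind(N1 = c("A", "A", "C", "C"), N2 = c("A", "C", "A", "C"))
  y3 <- c("a", "b", "b", "a")
  m3 <- fit_tree(x3, y3)
  expect_equal(m3$resub_accuracy, 1.0)

  set.seed(202)
  for (i in 1:60) {
    rt <- random_table(n = sample(5:40, 1), p = sample(1:4, 1),
                       ncat = sample(2:5, 1), nclass = sample(2:5, 1))
    m <- fit_tree(rt$x, rt$labels)
    expect_equal(m$resub_accuracy,
                 unique_row_majority_bound(rt$x, rt$labels))
    expect_equal(mean(predict(m, rt$x) == rt$labels), m$resub_accuracy)
  }
})

test_that("accuracy is non-decreasing as feature columns are appended", {
  set.seed(303)
  for (i in 1:10) {
    rt <- random_table(n = 30, p = 5, ncat = 3, nclass = 4)
    accs <- vapply(1:5, function(k)
      fit_tree(rt$x[, 1:k, drop = FALSE], rt$labels)$resub_accuracy, 0)
    expect_true(all(diff(accs) >= -1e-12))
  }
})

test_that("fit_tree is invariant to row order and to column order", {
  set.seed(404)
  rt <- random_table(n = 25, p = 3, ncat = 4, nclass = 3)
  m <- fit_tree(rt$x, rt$labels)
  perm <- sample(25)
  m_rows <- fit_tree(rt$x[perm, ], rt$labels[perm])
  expect_equal(m_rows$resub_accuracy, m$resub_accuracy)
  expect_equal(predict(m_rows, rt$x), predict(m, rt$x))
  m_cols <- fit_tree(rt$x[, c(2, 3, 1)], rt$labels)
  expect_equal(m_cols$resub_accuracy, m$resub_accuracy)
})

test_that("prediction routes unseen categories to the larger training child", {
  # N1 = A (6 rows, class a) vs C (4 rows, class b); G unseen in training
  x <- cbind(N1 = rep(c("A", "C"), c(6, 4)))
  colnames(x) <- "N1"
  y <- rep(c("a", "b"), c(6, 4))
  m <- fit_tree(x, y)
  out <- predict(m, cbind(N1 = c("G", "A", "C")))
  expect_equal(out[2:3], c("a", "b"))
  expect_equal(out[1], "a")  # larger side had 6 training rows
  expect_equal(predict(m, x[0, , drop = FALSE]), character(0))
  expect_error(predict(m, matrix("A", 1, 1, dimnames = list(NULL, "N9"))),
               "missing feature column")
})

test_that("identification accuracy is the exact-match fraction", {
  expect_equal(identification_accuracy(c("a", "b"), c("a", "b")), 1.0)
  expect_equal(identification_accuracy(c("a", "b"), c("b", "a")), 0.0)
  expect_equal(identification_accuracy(rep("a", 4), c("a", "a", "a", "b")),
               0.75)
  expect_error(identification_accuracy("a", c("a", "b")), "length mismatch")
})

test_that("tree rules serialize to a readable JSON-able rule list", {
  x <- cbind(N73 = c("C", "C", "G", "U"), N22 = c("A", "A", "A", "C"))
  m <- fit_tree(x, c("His", "His", "Tyr", "Tyr"))
  rules <- tree_rules(m)
  expect_equal(sum(rules$n), 4L)
  expect_setequal(rules$class, c("His", "Tyr"))
  expect_true(any(grepl("N73", rules$rule)))
  expect_silent(jsonlite::toJSON(rules))
})

test_that("resubstitution accuracy agrees with an independent tree learner on separable data", {
  skip_if_not_installed("rpart")
  set.seed(505)
  g <- generate_dataset(synth_spec(n_species = 4, genes_per_aa = c(2L, 2L),
                                   seed = 17))
  tab <- extract_features(prepare_records(g$records),
                          g$truth$planted$position)
  ours <- fit_tree(tab)
  df <- data.frame(y = factor(tab$labels),
                   as.data.frame(unclass(as.data.frame(tab$x)),
                                 stringsAsFactors = TRUE))
  rp <- rpart::rpart(y ~ ., df, method = "class",
                     control = rpart::rpart.control(minsplit = 2,
                                                    minbucket = 1, cp = 0,
                                                    xval = 0))
  rp_acc <- mean(predict(rp, df, type = "class") == df$y)
  expect_equal(ours$resub_accuracy, 1.0)
  expect_equal(rp_acc, 1.0)
})
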