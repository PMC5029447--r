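test_that("Cramer's V reproduces the printed histidine discriminator-base value", {
  # 86 of 86 His tRNAs carry C at N73; 3 of 3850 non-His tRNAs do
  his <- matrix(c(86, 3, 0, 3847), 2,
                dimnames = list(c("C", "not C"), c("His", "other")))
  v <- cramers_v(his)
  expect_equal(round(v, 2), 0.98)
  expect_equal(v, 0.9826, tolerance = 1e-4)
})

test_that("Cramer's V hits its endpoints and equals |phi| on 2x2 tables", {
  expect_equal(cramers_v(matrix(c(7, 0, 0, 12), 2)), 1.0)
  expect_equal(cramers_v(matrix(10, 2, 2)), 0.0)
  expect_error(cramers_v(matrix(c(5, 0, 5, 0), 2)), "degenerate")
  set.seed(8)
  for (i in 1:20) {
    m <- matrix(rpois(4, 20) + 1, 2, 2)
    a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
    phi <- abs(a * d - b * c) /
      sqrt((a + b) * (c + d) * (a + c) * (b + d))
    expect_equal(cramers_v(m), phi, tolerance = 1e-12)
  }
})

test_that("Cramer's V is invariant to row/column permutation and transposition", {
  set.seed(9)
  m <- matrix(rpois(12, 15) + 1, 3, 4)
  v <- cramers_v(m)
  expect_equal(cramers_v(m[c(2, 3, 1), c(4, 1, 3, 2)]), v)
  expect_equal(cramers_v(t(m)), v)
})

test_that("single-position rule statistics reproduce the His worked example", {
  # rebuild the printed counts as a feature table: 86 His with C at N73,
  # 3 non-His with C, 3847 non-His without C
  states <- rep(c("C", "C", "G"), c(86, 3, 3847))
  labels <- rep(c("His", "other", "other"), c(86, 3, 3847))
  tab <- toy_table(matrix(states, dimnames = list(NULL, "N73")), labels)
  st <- single_rule_stats(tab, "His", "N73", "C")
  expect_equal(st$sensitivity, 1.0)
  expect_equal(st$ppv, 86 / 89)
  expect_equal(round(st$ppv, 2), 0.97)
  expect_equal(round(st$cramers_v, 2), 0.98)
  # unspecified nucleotide: the best state is found automatically
  st2 <- single_rule_stats(tab, "His", "N73")
  expect_equal(st2$nucleotide, "C")
  expect_error(single_rule_stats(tab, "His", "N73", "U"), "never observed")
})

test_that("sensitivity and PPV match brute-force confusion counts on random tables", {
  set.seed(10)
  for (i in 1:25) {
    rt <- random_table(n = 50, p = 1, ncat = 4, nclass = 3)
    tab <- toy_table(rt$x, rt$labels)
    aa <- sample(unique(rt$labels), 1)
    nt <- sample(unique(rt$x[, 1]), 1)
    st <- single_rule_stats(tab, aa, "N1", nt)
    tp <- sum(rt$x[, 1] == nt & rt$labels == aa)
    fp <- sum(rt$x[, 1] == nt & rt$labels != aa)
    fn <- sum(rt$x[, 1] != nt & rt$labels == aa)
    expect_equal(st$sensitivity, tp / (tp + fn))
    if (tp + fp > 0) expect_equal(st$ppv, tp / (tp + fp))
    else expect_true(st$undefined)
  }
})

test_that("degenerate rules are flagged, not silently zeroed", {
  tab <- toy_table(matrix(c("C", "C", "G", "G"), dimnames = list(NULL, "N1")),
                   c("a", "a", "a", "a"))
  st <- single_rule_stats(tab, "a", "N1", "C")
  expect_equal(st$ppv, 1.0)  # target class occupies all rows
  expect_equal(st$sensitivity, 0.5)
})

test_that("the screen grid covers every class x position with planted signal standing out", {
  g <- generate_dataset(synth_spec(n_species = 6, genes_per_aa = c(2L, 2L),
                                   seed = 33))
  tab <- extract_features(prepare_records(g$records))
  grid <- screen_positions(tab)
  expect_equal(dim(grid), c(20L, 43L))
  expect_setequal(rownames(grid), unique(tab$labels))
  # a constant position is flagged missing, not an error
  const_tab <- toy_table(cbind(N9 = rep("G", 10),
                               N73 = rep(c("C", "G"), 5)),
                         rep(c("His", "Tyr"), 5))
  cg <- screen_positions(const_tab)
  expect_true(all(is.na(cg[, "N9"])))
  expect_equal(cg["His", "N73"], 1.0)
  # His marker: the planted position with the His-pair difference carries
  # more signal for His than any background position
  planted <- g$truth$planted$position
  background <- setdiff(colnames(grid), planted)
  expect_gt(max(grid["His", planted]), max(grid["His", background]))
  expect_true(all(grid[!is.na(grid)] >= 0 & grid[!is.na(grid)] <= 1))
})

test_that("minimal one-vs-rest models stop at the target and report the X0 baseline", {
  # single-position code: His alone carries C at N73
  n <- 200
  set.seed(12)
  x <- cbind(N73 = c(rep("C", 10), sample(c("A", "G", "U"), n - 10, TRUE)),
             N22 = sample(c("A", "C", "G", "U"), n, TRUE))
  labels <- rep(c("His", "rest_aa"), c(10, n - 10))
  tab <- toy_table(x, labels)
  mm <- per_aa_minimal_model(tab, "His")
  expect_equal(mm$k, 1L)
  expect_equal(mm$positions, "N73")
  expect_true(mm$met)
  expect_equal(mm$x0, 190 / 200)
  # target 0 is already met by the baseline
  mm0 <- per_aa_minimal_model(tab, "His", target_accuracy = 0)
  expect_equal(mm0$k, 0L)
  expect_true(mm0$met)
})

test_that("conjunctive two-position codes need k = 2, verified by exhaustive search", {
  # target has A at N3 AND A at N7; each alone is shared with non-targets
  set.seed(14)
  n_t <- 30; n_o <- 120
  # non-targets draw (N3, N7) from {(A,C), (C,A), (C,C)}: each marker state
  # occurs alone among non-targets, the conjunction never does
  pick <- sample(1:3, n_o, TRUE)
  x <- rbind(
    cbind(N3 = rep("A", n_t), N5 = sample(c("A", "C"), n_t, TRUE),
          N7 = rep("A", n_t)),
    cbind(N3 = c("A", "C", "C")[pick],
          N5 = sample(c("A", "C"), n_o, TRUE),
          N7 = c("C", "A", "C")[pick]))
  labels <- rep(c("Trp", "rest_aa"), c(n_t, n_o))
  tab <- toy_table(x, labels)
  # oracle: no single position reaches accuracy 1, the pair does
  one_pos_best <- max(vapply(tab$positions, function(p)
    subset_accuracy(tab, p), 0))
  expect_lt(one_pos_best, 1)
  expect_equal(subset_accuracy(tab, c("N3", "N7")), 1)
  mm <- per_aa_minimal_model(tab, "Trp", target_accuracy = 1)
  expect_equal(mm$k, 2L)
  expect_setequal(mm$positions, c("N3", "N7"))
})

test_that("per-amino-acid f-CV scores a universal code perfectly in both directions", {
  g <- generate_dataset(synth_spec(n_species = 6, genes_per_aa = c(2L, 2L),
                                   seed = 44))
  tab <- extract_features(prepare_records(g$records))
  res <- per_aa_f_cv(tab, "His")
  expect_equal(res$directions$accuracy, c(1.0, 1.0))
  expect_equal(res$mean_accuracy, 1.0)
  # an amino acid absent from one phylum is an error
  tab2 <- tab
  drop <- !(tab$labels == "Trp" & tab$phylum == "Phy2")
  tab2 <- feature_table(tab$x[drop, ], tab$labels[drop], tab$species[drop],
                        tab$phylum[drop])
  expect_error(per_aa_f_cv(tab2, "Trp"), "absent from phylum")
})
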