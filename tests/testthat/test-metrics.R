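test_that("confusion counts are exact on constructed masks", {
  G <- array(0L, c(10, 10, 1)); G[1:8, 1, 1] <- 1L
  P <- array(0L, c(10, 10, 1)); P[3:10, 1, 1] <- 1L   # 6 shared, 2 extra
  cc <- confusion_counts(P, G)
  expect_identical(c(cc$TP, cc$FP, cc$FN, cc$TN), c(6L, 2L, 2L, 90L))
  expect_identical(cc$TP + cc$FP + cc$FN + cc$TN, 100L)
  cc2 <- confusion_counts(G, G)
  expect_identical(c(cc2$TP, cc2$FP, cc2$FN, cc2$TN), c(8L, 0L, 0L, 92L))
  disj <- array(0L, c(10, 10, 1)); disj[1, 10, 1] <- 1L
  expect_identical(confusion_counts(disj, G)$TP, 0L)
  expect_error(confusion_counts(array(0, c(2, 2)), array(0, c(3, 3))), "grids")
})

test_that("the six metrics match hand arithmetic on the toy counts", {
  row <- compute_metrics(list(TP = 6L, FP = 2L, FN = 2L, TN = 90L))
  expect_equal(row$dice, 0.75)
  expect_equal(row$vop, 0.75)
  expect_equal(row$vor, 0.25)
  expect_equal(row$precision, 0.75)
  expect_equal(row$jaccard, 0.6)
  expect_equal(row$specificity, 90 / 92)
  ## algebraic identity dice = 2 vop / (1 + vop + vor)
  expect_equal(2 * row$vop / (1 + row$vop + row$vor), row$dice)
  perfect <- compute_metrics(list(TP = 5L, FP = 0L, FN = 0L, TN = 95L))
  expect_equal(c(perfect$dice, perfect$vop, perfect$vor, perfect$jaccard),
               c(1, 1, 0, 1))
  ## empty reference: sentinels, not zeros
  empty <- compute_metrics(list(TP = 0L, FP = 3L, FN = 0L, TN = 97L))
  expect_true(is.na(empty$dice) && is.na(empty$vop) && is.na(empty$vor))
  expect_false(is.na(empty$specificity))
})

test_that("metrics agree with a brute-force voxel loop on random masks", {
  set.seed(42)
  for (rep in 1:20) {
    mp <- random_mask_pair(8L)
    bf <- brute_force_metrics(mp$P, mp$G)
    row <- compute_metrics(confusion_counts(mp$P, mp$G))
    for (cl in c("dice", "vop", "vor", "specificity", "precision", "jaccard"))
      expect_equal(row[[cl]], bf[[cl]], tolerance = 1e-12)
  }
})

test_that("dice and jaccard are symmetric; VOR vanishes iff P is inside G", {
  set.seed(13)
  for (rep in 1:10) {
    mp <- random_mask_pair(6L)
    a <- compute_metrics(confusion_counts(mp$P, mp$G))
    b <- compute_metrics(confusion_counts(mp$G, mp$P))
    expect_equal(a$dice, b$dice)
    expect_equal(a$jaccard, b$jaccard)
    expect_gte(a$vor, 0)
    expect_identical(a$vor == 0, all(mp$P <= mp$G))
  }
})

test_that("aggregation uses sample sd and excludes sentinel rows", {
  rows <- data.frame(subject = c("a", "b"), tract = "t",
                     dice = c(0.7, 0.9), vop = c(1, 1), vor = c(0, 0),
                     specificity = c(1, 1), precision = c(1, 1),
                     jaccard = c(0.5, 0.7))
  ag <- aggregate_metrics(rows)
  expect_equal(ag$dice_mean, 0.8)
  expect_equal(ag$dice_sd, sd(c(0.7, 0.9)))
  expect_equal(ag$dice_sd, 0.1414, tolerance = 1e-3)
  rows2 <- rbind(rows, data.frame(subject = "c", tract = "t", dice = NA,
                                  vop = NA, vor = NA, specificity = 1,
                                  precision = NA, jaccard = NA))
  ag2 <- aggregate_metrics(rows2)
  expect_equal(ag2$dice_mean, 0.8)
  expect_identical(ag2$dice_n_excluded, 1L)
  expect_identical(ag2$specificity_n_excluded, 0L)
  expect_error(aggregate_metrics(rows[0, ]), "rows")
  one <- aggregate_metrics(rows[1, ])
  expect_equal(one$dice_mean, 0.7)
  expect_equal(one$dice_sd, 0)
})

test_that("Wilcoxon comparison handles exact, degenerate and large cases", {
  ## all-positive differences over 6 pairs: exact two-sided p = 2/64
  a <- c(0.9, 0.8, 0.85, 0.7, 0.95, 0.75)
  b <- a - c(0.05, 0.02, 0.04, 0.01, 0.03, 0.06)
  cm <- compare_methods(a, b)
  expect_equal(cm$p_raw, 2 / 64)
  expect_identical(cm$n_effective, 6L)
  ## identical methods: p = 1 by convention
  cm0 <- compare_methods(a, a)
  expect_equal(cm0$p_raw, 1)
  expect_identical(cm0$n_effective, 0L)
  ## Bonferroni caps at 1
  expect_equal(compare_methods(a, b, n_comparisons = 72L)$p_bonferroni, 1)
  expect_equal(compare_methods(a, b, n_comparisons = 2L)$p_bonferroni, 2 * 2 / 64)
  ## large-sample normal path stays a valid p-value
  set.seed(20)
  x <- runif(40); y <- x + rnorm(40, 0.05, 0.02)
  big <- compare_methods(x, y, n_comparisons = 3L)
  expect_true(big$p_raw > 0 && big$p_raw < 1e-3)
  expect_error(compare_methods(1:3, 1:4), "length")
})
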