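test_that("balanced trials undersample, split 90/10 and are reproducible", {
  pos <- sprintf("p%03d", 1:155); neg <- sprintf("n%03d", 1:164)
  tr <- make_balanced_trials(pos, neg, n_trials = 20, seed = 42)
  expect_length(tr, 20)
  for (s in tr[1:5]) {
    neg_used <- c(s$train_neg, s$test_neg)
    expect_length(neg_used, 155)                       # 155 of 164 sampled
    expect_length(s$test_pos, ceiling(0.1 * 155))      # = 16
    expect_length(s$train_pos, 155 - 16)
    expect_equal(length(s$train_pos), length(s$train_neg))  # balanced
    expect_length(intersect(s$train_pos, s$test_pos), 0)
    expect_length(intersect(s$train_neg, s$test_neg), 0)
  }
  # distinct trials draw distinct negative subsets (w.h.p.)
  expect_false(identical(sort(c(tr[[1]]$train_neg, tr[[1]]$test_neg)),
                         sort(c(tr[[2]]$train_neg, tr[[2]]$test_neg))))
  # determinism from the master seed
  tr2 <- make_balanced_trials(pos, neg, n_trials = 20, seed = 42)
  expect_identical(tr, tr2)
  # equal classes: undersampling is a no-op
  tr3 <- make_balanced_trials(pos[1:10], neg[1:10], n_trials = 3, seed = 1)
  expect_setequal(c(tr3[[1]]$train_neg, tr3[[1]]$test_neg), neg[1:10])
  expect_error(make_balanced_trials(character(), neg, 5), "non-empty")
})

test_that("rfe_rank puts planted informative features on top", {
  # 2 informative + 8 pure-noise features, strong separation
  hits <- 0
  for (rep in 1:10) {
    d <- dilisvm:::with_seed(rep, {
      x <- matrix(rnorm(200 * 10), 200,
                  dimnames = list(NULL, sprintf("F%02d", 1:10)))
      y <- rep(c("pos", "neg"), each = 100)
      x[, 1] <- x[, 1] + ifelse(y == "pos", 1.5, -1.5)
      x[, 2] <- x[, 2] + ifelse(y == "pos", 1.5, -1.5)
      list(x = scale(x), y = y)
    })
    rk <- rfe_rank(d$x, d$y, cost = 1, schedule = c(10, 5, 2),
                   positive_level = "pos")
    if (setequal(rk[1:2], c("F01", "F02"))) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("rfe_rank handles degenerate and duplicated-feature cases", {
  d <- separable_xy(n_per = 25, p = 1, gap = 3, seed = 5)
  expect_equal(rfe_rank(d$x, d$labels, positive_level = "pos"), "F01")

  # a duplicated informative feature: both copies outrank the noise
  d2 <- dilisvm:::with_seed(9, {
    x <- matrix(rnorm(200 * 8), 200,
                dimnames = list(NULL, sprintf("F%02d", 1:8)))
    y <- rep(c("pos", "neg"), each = 100)
    x[, 1] <- x[, 1] + ifelse(y == "pos", 2, -2)
    x[, 2] <- x[, 1] + rnorm(200, sd = 0.05)  # near-copy
    list(x = scale(x), y = y)
  })
  rk <- rfe_rank(d2$x, d2$y, schedule = c(8, 4, 2), positive_level = "pos")
  expect_setequal(rk[1:2], c("F01", "F02"))

  expect_warning(rfe_rank(d2$x, d2$y, schedule = c(20, 8, 2),
                          positive_level = "pos"), "truncated")
})

test_that("roc_auc matches the Mann-Whitney statistic with ties", {
  truth <- c("pos", "pos", "neg", "neg", "pos")
  prob <- c(0.9, 0.7, 0.7, 0.2, 0.4)
  # pairwise enumeration over the 6 (pos, neg) pairs: 4 wins + 1 tie
  expect_equal(roc_auc(truth, prob), (4 + 0.5) / 6)
  expect_true(is.na(roc_auc(rep("pos", 3), c(0.1, 0.2, 0.3))))
})

test_that("confusion metrics obey their definitions and identities", {
  truth <- rep(c("pos", "neg"), each = 4)
  prob <- c(0.9, 0.8, 0.3, 0.2, 0.7, 0.4, 0.3, 0.1)
  m <- confusion_metrics(truth, prob, 0.5)
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 0.75)
  expect_equal(m$sensitivity + m$fnr, 1)
  expect_equal(m$specificity + m$fpr, 1)
  expect_equal(m$accuracy, 5 / 8)
  expect_equal(m$ppv, 2 / 3)
  # threshold 0 calls every nonzero probability positive
  expect_equal(confusion_metrics(truth, prob, 0)$sensitivity, 1)
  # no predicted positives -> PPV is missing, not zero
  expect_true(is.na(confusion_metrics(truth, prob, 0.95)$ppv))
  expect_error(confusion_metrics(character(), numeric(), 0.5), "empty")
})

test_that("fit_trial achieves the separable limit and flags degenerate sets", {
  d <- separable_xy(n_per = 40, p = 10, gap = 5, seed = 21)
  tr <- make_balanced_trials(names(d$labels)[d$labels == "pos"],
                             names(d$labels)[d$labels == "neg"],
                             n_trials = 3, seed = 7)
  r <- fit_trial(tr[[1]], d$x, d$labels, list(cost = 1, top = 5))
  expect_equal(r$metrics$auc, 1.0)
  expect_equal(r$metrics$sensitivity, 1.0)
  expect_equal(r$metrics$specificity, 1.0)
  expect_length(r$selected_features, 5)
  expect_equal(r$metrics$fnr, 1 - r$metrics$sensitivity)

  # single-class held-out set is flagged, not averaged
  bad <- tr[[1]]
  bad$test_neg <- character(0)
  rb <- fit_trial(bad, d$x, d$labels, list(cost = 1, top = 5))
  expect_true(rb$flagged)
  expect_true(is.na(rb$metrics$auc))
})

test_that("grid_search averages cells, picks the argmax and breaks ties", {
  d <- separable_xy(n_per = 30, p = 12, gap = 4, seed = 13)
  pos <- names(d$labels)[d$labels == "pos"]
  neg <- names(d$labels)[d$labels == "neg"]
  tr <- make_balanced_trials(pos, neg, n_trials = 5, seed = 2)
  g <- grid_search(tr, d$x, d$labels, cost_grid = 1, top_grid = 4)
  expect_equal(g$best_params, list(cost = 1, top = 4, kernel = "linear"))
  expect_equal(nrow(g$grid), 1)
  expect_equal(g$grid$n_trials_used, 5)
  # separable data: ties on AUC = 1 resolve to the smallest top, then cost
  g2 <- grid_search(tr, d$x, d$labels, cost_grid = c(1, 10),
                    top_grid = c(4, 8))
  expect_equal(g2$best_params$top, 4)
  expect_equal(g2$best_params$cost, 1)
  expect_equal(nrow(g2$grid), 4)
  # every cell's averaged metrics respect the probability identities
  expect_true(all(abs(g2$grid$sensitivity + g2$grid$fnr - 1) < 1e-12))
  expect_true(all(abs(g2$grid$specificity + g2$grid$fpr - 1) < 1e-12))
})
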