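# ROC/AUC computation and classifier evaluation within and across cohorts.

test_that("AUC matches hand-computable concordance cases", {
  expect_equal(auc_mannwhitney(c(0.9, 0.8, 0.1, 0.2),
                               c("case", "case", "control", "control")), 1)
  # pairs: (.9>.5) (.9>.1) (.3<.5) (.3>.1) -> 3/4
  expect_equal(auc_mannwhitney(c(0.9, 0.3, 0.5, 0.1),
                               c("case", "case", "control", "control")),
               0.75)
  expect_equal(auc_mannwhitney(rep(0.4, 6),
                               rep(c("case", "control"), 3)), 0.5)
})

test_that("trapezoidal ROC integration equals the Mann-Whitney identity", {
  for (s in 1:50) {
    withr::with_seed(s, {
      n <- sample(10:60, 1)
      scores <- if (s %% 2) rnorm(n) else sample(seq(0, 1, 0.1), n, TRUE)
      labels <- sample(c("case", "control"), n, TRUE)
    })
    if (length(unique(labels)) < 2) next
    roc <- roc_points(scores, labels)
    expect_lt(abs(auc_trapezoid(roc) - auc_mannwhitney(scores, labels)),
              1e-12)
    # independent pairwise-loop oracle
    expect_equal(auc_mannwhitney(scores, labels),
                 oracle_pairwise_auc(scores, labels))
  }
})

test_that("ROC points are monotone from (0,0) to (1,1)", {
  withr::with_seed(4, {
    scores <- rnorm(40); labels <- sample(c("case", "control"), 40, TRUE)
  })
  roc <- roc_points(scores, labels)
  expect_equal(unlist(roc[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(roc[nrow(roc), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
})

test_that("label inversion maps AUC to its complement exactly", {
  withr::with_seed(11, {
    scores <- rnorm(50)
    labels <- sample(c("case", "control"), 50, TRUE)
  })
  a <- auc_mannwhitney(scores, labels, positive = "case")
  b <- auc_mannwhitney(scores, labels, positive = "control")
  expect_equal(a, 1 - b, tolerance = 1e-12)
})

test_that("AUC agrees with pROC on a random score set", {
  withr::with_seed(21, {
    scores <- rnorm(60)
    labels <- sample(c("case", "control"), 60, TRUE)
  })
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, levels =
    c("control", "case"), direction = "<", quiet = TRUE)))
  expect_equal(auc_mannwhitney(scores, labels), ref, tolerance = 1e-12)
})

test_that("training is deterministic, separable data gives zero OOB error", {
  toy <- make_separable(seed = 31)
  m1 <- train_classifier(toy$x, toy$y, panel = "g001", ntree = 300L,
                         seed = 3)
  m2 <- train_classifier(toy$x, toy$y, panel = "g001", ntree = 300L,
                         seed = 3)
  expect_identical(predict(m1), predict(m2))
  expect_equal(unname(tail(m1$rf$err.rate[, "OOB"], 1)), 0)
  rep <- evaluate_classifier(m1, mode = "within")
  expect_equal(rep$auc, 1)
  expect_error(train_classifier(toy$x, toy$y, panel = character()),
               "empty")
  expect_error(train_classifier(toy$x, toy$y, panel = "nope"), "missing")
})

test_that("shuffled labels give a near-chance out-of-bag accuracy", {
  toy <- make_separable(n = 60L, seed = 41)
  y_perm <- withr::with_seed(42, sample(toy$y))
  m <- train_classifier(toy$x, y_perm, panel = colnames(toy$x)[1:5],
                        ntree = 400L, seed = 4)
  acc <- 1 - unname(tail(m$rf$err.rate[, "OOB"], 1))
  expect_gte(acc, 0.3)
  expect_lte(acc, 0.7)
})

test_that("transfer evaluation requires both classes and panel columns", {
  toy <- make_separable(seed = 51)
  m <- train_classifier(toy$x, toy$y, panel = "g001", seed = 5)
  expect_error(evaluate_classifier(m, toy$x[, -1, drop = FALSE],
                                   toy$y, mode = "transfer"), "panel")
  expect_error(evaluate_classifier(m, toy$x, rep("case", nrow(toy$x)),
                                   mode = "transfer"), "single class")
})

test_that("specificity_suite handles self-contrasts and unknown cohorts", {
  toy <- make_separable(seed = 61)
  m <- train_classifier(toy$x, toy$y, panel = "g001", seed = 6)
  reps <- specificity_suite(m, list(disc = toy$x),
                            list(c("disc", "disc")))
  expect_s3_class(reps$disc_vs_disc, "classifier_report")
  expect_equal(reps$disc_vs_disc$mode, "within")
  expect_error(specificity_suite(m, list(disc = toy$x),
                                 list(c("disc", "ghost"))), "ghost")
})
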