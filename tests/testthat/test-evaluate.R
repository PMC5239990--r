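test_that("confusion counts match direct enumeration", {
  cm <- confusion(rep(c("p", "n"), c(10, 5)), rep(c("p", "n"), c(10, 5)), "p")
  expect_equal(unclass(cm)[c("TP", "FN", "FP", "TN")],
               list(TP = 10, FN = 0, FP = 0, TN = 5))

  cm2 <- confusion(c("p", "n", "n"), c("p", "p", "p"), "p")
  expect_equal(cm2$FN, 0)
  expect_equal(cm2$TN, 0)

  withr::with_seed(4, {
    actual <- sample(c("p", "n"), 20, TRUE)
    predicted <- sample(c("p", "n"), 20, TRUE)
  })
  cm3 <- confusion(actual, predicted, "p")
  brute <- table(actual, predicted)
  expect_equal(cm3$TP, brute["p", "p"], ignore_attr = TRUE)
  expect_equal(cm3$FN, brute["p", "n"], ignore_attr = TRUE)
  expect_equal(cm3$FP, brute["n", "p"], ignore_attr = TRUE)
  expect_equal(cm3$TN, brute["n", "n"], ignore_attr = TRUE)
  expect_error(confusion(actual, predicted[-1], "p"), "equal-length")
})

test_that("metrics follow the percentage formulas with NA for empty strata", {
  cm <- structure(list(TP = 28, FN = 2, FP = 3, TN = 17),
                  class = "confusion_matrix")
  m <- metrics(cm)
  expect_equal(m$sensitivity, 100 * 28 / 30)
  expect_equal(round(m$sensitivity, 2), 93.33)
  expect_equal(m$specificity, 85)
  expect_equal(m$accuracy, 90)

  perfect <- structure(list(TP = 50, FN = 0, FP = 0, TN = 50),
                       class = "confusion_matrix")
  expect_equal(unlist(metrics(perfect)), c(sensitivity = 100,
                                           specificity = 100, accuracy = 100))

  no_neg <- structure(list(TP = 5, FN = 1, FP = 0, TN = 0),
                      class = "confusion_matrix")
  expect_true(is.na(metrics(no_neg)$specificity))
  expect_false(is.na(metrics(no_neg)$sensitivity))
})

test_that("accuracy is the prevalence-weighted mean of Sn and Sp", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      cm <- structure(as.list(stats::setNames(sample(1:30, 4, TRUE),
                                              c("TP", "FN", "FP", "TN"))),
                      class = "confusion_matrix")
    })
    m <- metrics(cm)
    pos <- cm$TP + cm$FN
    neg <- cm$FP + cm$TN
    expect_equal(m$accuracy,
                 (pos * m$sensitivity + neg * m$specificity) / (pos + neg))
  }
})

test_that("70/30 split is exhaustive, reproducible and stratified", {
  tab <- make_statlog_like(270, seed = 2)
  sp <- split_70_30(tab, seed = 1)
  expect_equal(nrow(sp$train), 189)
  expect_equal(nrow(sp$test), 81)

  sp2 <- split_70_30(tab, seed = 1)
  expect_identical(as.data.frame(sp$test), as.data.frame(sp2$test))

  global <- prop.table(table(tab$class))
  for (seed in 1:20) {
    spi <- split_70_30(tab, seed = seed)
    test_counts <- table(spi$test$class)
    expected <- global * 81
    expect_true(all(abs(test_counts - expected) <= 1))
    expect_equal(nrow(spi$train) + nrow(spi$test), 270)
  }
})

test_that("jackknife aggregates one prediction per object", {
  # memorizing trainer: exact-match lookup, majority fallback
  memorizer <- function(train) {
    key <- do.call(paste, as.data.frame(train)[condition_attributes(train)])
    list(key = key, label = as.character(train[[decision_attribute(train)]]))
  }
  lookup <- function(model, newdata) {
    k <- do.call(paste, as.data.frame(newdata)[condition_attributes(newdata)])
    hit <- match(k, model$key)
    ifelse(is.na(hit), names(which.max(table(model$label))), model$label[hit])
  }
  g <- make_table(n_objects = 20, seed = 3)
  dup <- decision_table(rbind(as.data.frame(g$table), as.data.frame(g$table)),
                        "d", kinds = attribute_kinds(g$table), positive = "c1")
  jk <- jackknife(dup, memorizer, lookup)
  expect_equal(jk$metrics$accuracy, 100)
  expect_equal(jk$confusion$TP + jk$confusion$FN + jk$confusion$FP +
                 jk$confusion$TN, nrow(dup))

  # two objects with opposite classes: majority trainer misses both
  two <- decision_table(data.frame(a = c(0, 1), d = c("n", "p")), "d",
                        positive = "p")
  majority <- function(train) as.character(train$d[1])
  jk2 <- jackknife(two, majority, function(m, d) m)
  expect_equal(jk2$metrics$accuracy, 0)
})

test_that("ROC handles perfect, constant and random scores", {
  perfect <- roc(c(0.9, 0.8, 0.2, 0.1), c("p", "p", "n", "n"), "p")
  expect_equal(perfect$auc, 1)

  flat <- roc(rep(0.5, 6), c("p", "p", "p", "n", "n", "n"), "p")
  expect_equal(flat$auc, 0.5)
  expect_equal(nrow(flat$points), 2)  # single tie-grouped step

  withr::with_seed(8, {
    scores <- round(runif(30), 1)  # coarse scores force ties
    actual <- sample(c("p", "n"), 30, TRUE)
  })
  rc <- roc(scores, actual, "p")
  # pairwise-comparison oracle
  sp <- scores[actual == "p"]
  sn <- scores[actual == "n"]
  pairs <- expand.grid(sp = sp, sn = sn)
  oracle <- mean((pairs$sp > pairs$sn) + 0.5 * (pairs$sp == pairs$sn))
  expect_equal(rc$auc, oracle, tolerance = 1e-12)

  expect_error(roc(1:3, c("p", "p", "p"), "p"), "both classes")
})

test_that("ROC curve is monotone from (0,0) to (1,1) and transform-invariant", {
  withr::with_seed(12, {
    scores <- rnorm(40)
    actual <- sample(c("p", "n"), 40, TRUE)
  })
  rc <- roc(scores, actual, "p")
  expect_equal(rc$points$fpr[1], 0)
  expect_equal(rc$points$tpr[1], 0)
  expect_equal(utils::tail(rc$points$fpr, 1), 1)
  expect_equal(utils::tail(rc$points$tpr, 1), 1)
  expect_true(all(diff(rc$points$fpr) >= 0))
  expect_true(all(diff(rc$points$tpr) >= 0))

  rc2 <- roc(exp(3 * scores), actual, "p")
  expect_equal(rc2$auc, rc$auc)
  expect_equal(rc2$points$fpr, rc$points$fpr)
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(3, {
    scores <- rnorm(60)
    actual <- sample(c("p", "n"), 60, TRUE)
  })
  rc <- roc(scores, actual, "p")
  ref <- pROC::auc(pROC::roc(response = actual, predictor = scores,
                             levels = c("n", "p"), direction = "<",
                             quiet = TRUE))
  expect_equal(rc$auc, as.numeric(ref), tolerance = 1e-12)
})
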