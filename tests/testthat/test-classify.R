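# independent gain-ratio oracle for a categorical split (uniform weights)
gain_ratio_oracle <- function(v, y) {
  ent <- function(labels) {
    p <- table(labels) / length(labels)
    -sum(p * log2(p))
  }
  H <- ent(y)
  cond <- sum(vapply(split(seq_along(v), v), function(idx) {
    length(idx) / length(v) * ent(y[idx])
  }, numeric(1)))
  gain <- H - cond
  si <- ent(v)
  c(gain = gain, ratio = if (si > 0) gain / si else NA_real_)
}

test_that("a class-determining attribute yields zero training error", {
  tab <- decision_table(
    data.frame(a = c("x", "x", "y", "y"), z = c(0, 1, 0, 1),
               d = c("n", "n", "p", "p"), stringsAsFactors = FALSE),
    "d", positive = "p"
  )
  tr <- train_tree(tab)
  expect_equal(predict(tr, tab), as.character(tab$d))
  expect_equal(tr$root$attribute, "a")
})

test_that("the chosen split maximizes the gain ratio among high-gain attributes", {
  tab <- decision_table(
    data.frame(
      a = c("x", "x", "y", "y", "x", "y"),
      b = c("u", "v", "u", "v", "w", "w"),
      d = c("n", "n", "p", "p", "n", "p"),
      stringsAsFactors = FALSE
    ),
    "d", positive = "p"
  )
  oracle <- rbind(a = gain_ratio_oracle(tab$a, tab$d),
                  b = gain_ratio_oracle(tab$b, tab$d))
  cand <- rownames(oracle)[oracle[, "gain"] >= mean(oracle[, "gain"])]
  best <- cand[which.max(oracle[cand, "ratio"])]
  tr <- train_tree(tab, control = tree_control(min_leaf = 1))
  expect_equal(tr$root$attribute, best)
})

test_that("numeric splits pick the best threshold at a midpoint", {
  tab <- decision_table(
    data.frame(a = c(1, 2, 3, 10, 11, 12), d = rep(c("n", "p"), each = 3)),
    "d", kinds = c(a = "real"), positive = "p"
  )
  tr <- train_tree(tab)
  expect_equal(tr$root$threshold, 6.5)
  expect_equal(predict(tr, tab), as.character(tab$d))
})

test_that("tree induction ignores overall weight scale", {
  g <- make_table(n_objects = 50, flip_noise = 0.1, seed = 5)
  t1 <- train_tree(g$table, instance_weights = rep(1, 50))
  t2 <- train_tree(g$table, instance_weights = rep(2, 50))
  expect_identical(t1, t2)
})

test_that("duplicating instances with halved weights leaves the tree unchanged", {
  g <- make_table(n_objects = 40, flip_noise = 0.1, seed = 6)
  ctrl <- tree_control(min_leaf = 0)
  t1 <- train_tree(g$table, control = ctrl)
  dbl <- decision_table(rbind(as.data.frame(g$table), as.data.frame(g$table)),
                        "d", kinds = attribute_kinds(g$table), positive = "c1")
  t2 <- train_tree(dbl, instance_weights = rep(0.5, nrow(dbl)), control = ctrl)
  probe <- random_table(60, length(condition_attributes(g$table)), seed = 60)
  names(probe)[seq_along(condition_attributes(g$table))] <-
    condition_attributes(g$table)
  expect_identical(predict(t1, probe), predict(t2, probe))
  expect_identical(rfrs:::tree_size(t1$root), rfrs:::tree_size(t2$root))
})

test_that("mixed labels on identical rows give a majority leaf, no error", {
  tab <- decision_table(
    data.frame(a = c(0, 0, 0), d = c("p", "p", "n")), "d", positive = "p"
  )
  tr <- train_tree(tab)
  expect_true(tr$root$leaf)
  expect_equal(tr$root$label, "p")
})

test_that("unseen categories route to the heaviest child", {
  tab <- decision_table(
    data.frame(a = c("x", "x", "x", "y", "y"), d = c("n", "n", "n", "p", "p"),
               stringsAsFactors = FALSE),
    "d", positive = "p"
  )
  tr <- train_tree(tab, control = tree_control(min_leaf = 1))
  newdata <- data.frame(a = "z", stringsAsFactors = FALSE)
  expect_equal(predict(tr, newdata), "n")  # "x" child carries more weight
})

test_that("boosting accepts k rounds, renormalizes weights, is deterministic", {
  g <- make_table(n_objects = 80, flip_noise = 0.15, seed = 9)
  b1 <- boost(g$table, k = 10, seed = 3)
  b2 <- boost(g$table, k = 10, seed = 3)
  expect_identical(predict(b1, g$table, type = "score"),
                   predict(b2, g$table, type = "score"))
  expect_equal(sum(b1$final_weights), 1)
  expect_lte(b1$n_effective, b1$n_requested)
  expect_true(all(tidy(b1)$vote >= 0))
  expect_error(boost(g$table, k = 0), "positive")
})

test_that("separable data gives an error-free first round and perfect votes", {
  tab <- decision_table(
    data.frame(a = rep(c("x", "y"), each = 5),
               d = rep(c("n", "p"), each = 5), stringsAsFactors = FALSE),
    "d", positive = "p"
  )
  b <- boost(tab, k = 3)
  single <- train_tree(tab)
  expect_equal(predict(b, tab), predict(single, tab))
  expect_equal(abs(predict_score(b, tab)), rep(1, 10))
})

test_that("ensemble training accuracy is at least the single tree's", {
  wins <- 0
  for (seed in 1:8) {
    g <- make_table(n_objects = 60, n_relevant = 2, n_noise = 3,
                    flip_noise = 0.2, seed = seed)
    single <- train_tree(g$table)
    ens <- boost(g$table, k = 15, seed = seed)
    acc_s <- mean(predict(single, g$table) == g$table$d)
    acc_e <- mean(predict(ens, g$table) == g$table$d)
    if (acc_e >= acc_s) wins <- wins + 1
  }
  expect_gte(wins, 7)
})

test_that("scores are vote-normalized and tie to the positive class", {
  pos_tab <- decision_table(data.frame(a = c(0, 1), d = c("p", "p")), "d",
                            kinds = c(a = "nominal"), positive = "p")
  # leaves always predicting one class, assembled into a hand-built ensemble
  leaf_tree <- function(label) {
    tab <- decision_table(
      data.frame(a = c(0, 1), d = rep(label, 2)), "d", kinds = c(a = "nominal")
    )
    tr <- train_tree(tab)
    tr$classes <- c("n", "p")
    tr
  }
  all_pos <- structure(
    list(members = list(list(tree = leaf_tree("p"), vote = 1),
                        list(tree = leaf_tree("p"), vote = 2)),
         n_requested = 2, n_effective = 2, classes = c("n", "p"),
         positive = "p", decision = "d"),
    class = "boosted_ensemble"
  )
  newdata <- data.frame(a = c(0, 1))
  expect_equal(predict_score(all_pos, newdata), c(1, 1))

  split_vote <- all_pos
  split_vote$members <- list(list(tree = leaf_tree("p"), vote = 1),
                             list(tree = leaf_tree("n"), vote = 1))
  s <- predict_score(split_vote, newdata)
  expect_equal(s, c(0, 0))
  expect_equal(predict(split_vote, newdata), c("p", "p"))
})
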