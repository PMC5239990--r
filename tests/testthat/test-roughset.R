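# independent partition oracle: group rows by pasted values
partition_oracle <- function(tab, P) {
  key <- do.call(paste, c(as.data.frame(tab)[P], sep = "|"))
  unname(lapply(split(seq_len(nrow(tab)), key), sort))
}

test_that("indiscernibility groups objects with identical value tuples", {
  tab <- five_object_table()
  blocks <- indiscernibility(tab, "p")
  expect_equal(blocks, list(1:2, 3:5))

  distinct <- decision_table(
    data.frame(a = 1:5, b = c(0, 0, 1, 1, 0), d = c(0, 1, 0, 1, 0)), "d",
    kinds = c(a = "nominal", b = "nominal")
  )
  expect_length(indiscernibility(distinct, c("a", "b")), 5)
  expect_message(indiscernibility(tab, character(0)), "single block")
})

test_that("adding attributes only refines the partition", {
  for (seed in 1:20) {
    tab <- random_table(15, 4, seed = seed)
    p1 <- indiscernibility(tab, c("x1", "x2"))
    p2 <- indiscernibility(tab, c("x1", "x2", "x3"))
    # each finer block sits inside exactly one coarser block
    for (b in p2) {
      containing <- Filter(function(cb) all(b %in% cb), p1)
      expect_length(containing, 1)
    }
    expect_equal(sort(unlist(p2)), seq_len(nrow(tab)))
  }
})

test_that("approximations bracket the target set", {
  tab <- five_object_table()
  n <- nrow(tab)
  full <- approximations(tab, "p", seq_len(n))
  expect_equal(full$lower, seq_len(n))
  expect_equal(full$upper, seq_len(n))

  empty <- approximations(tab, "p", integer(0))
  expect_length(empty$lower, 0)
  expect_length(empty$upper, 0)

  mid <- approximations(tab, "p", 2:5)
  expect_equal(mid$lower, 3:5)
  expect_equal(mid$upper, 1:5)

  for (seed in 1:10) {
    rt <- random_table(12, 3, seed = seed)
    X <- withr::with_seed(seed, sample(12, 5))
    ap <- approximations(rt, c("x1", "x2"), X)
    expect_true(all(ap$lower %in% X))
    expect_true(all(X %in% ap$upper))
  }
})

test_that("positive region and dependency follow the block purity rule", {
  tab <- five_object_table()
  expect_equal(positive_region(tab, "p"), 3:5)
  expect_equal(dependency(tab, "p"), 0.6)

  const <- decision_table(data.frame(a = c(0, 1, 0), d = c(1, 1, 1)), "d")
  expect_equal(positive_region(const, "a"), 1:3)

  # consistent table: full condition set gives the whole universe
  g <- make_table(n_objects = 25, seed = 6)
  expect_equal(dependency(g$table, condition_attributes(g$table)), 1)
})

test_that("duplicated attributes add no dependency", {
  g <- make_table(n_objects = 30, n_relevant = 2, n_redundant = 1,
                  n_noise = 1, seed = 8)
  tab <- g$table
  expect_equal(dependency(tab, c("a1", "a2")),
               dependency(tab, c("a1", "a1_dup1", "a2")))
  expect_equal(significance(tab, c("a1", "a1_dup1", "a2"), a = "a1"), 0)
})

test_that("significance equals the dependency drop and is non-negative", {
  expect_error(significance(five_object_table(), "p", a = "q"), "not a member")
  for (seed in 1:20) {
    tab <- random_table(12, 4, seed = seed)
    P <- c("x1", "x2", "x3")
    for (a in P) {
      s <- significance(tab, P, a = a)
      expect_equal(s, dependency(tab, P) - dependency(tab, setdiff(P, a)))
      expect_gte(s, 0)
    }
  }
})

test_that("single determining attribute has significance 1 - r_empty", {
  tab <- decision_table(data.frame(a = c(0, 0, 1, 1), d = c("x", "x", "y", "y")),
                        "d")
  r_empty <- if (length(unique(tab$d)) == 1) 1 else 0
  expect_equal(significance(tab, "a", a = "a"), 1 - r_empty)
})

test_that("exhaustive reduct scan finds the planted minimal subsets", {
  g <- make_table(n_objects = 40, n_relevant = 2, n_redundant = 1,
                  n_noise = 2, flip_noise = 0, seed = 3)
  bf <- all_reducts_bruteforce(g$table)
  expect_true(same_reduct_family(bf$reducts, g$reducts))
  expect_equal(bf$baseline_dependency, 1)

  # a single determining attribute plus pure noise gives a unique reduct
  withr::with_seed(21, {
    df <- data.frame(a = rep(0:1, each = 10),
                     z1 = sample(0:2, 20, TRUE), z2 = sample(0:2, 20, TRUE))
    df$d <- c("n", "p")[df$a + 1]
  })
  solo <- decision_table(df, "d", positive = "p")
  bf2 <- all_reducts_bruteforce(solo)
  expect_true(same_reduct_family(bf2$reducts, list("a")))

  # the full condition set always preserves itself
  for (seed in 1:5) {
    rt <- random_table(10, 3, seed = seed)
    expect_gt(length(all_reducts_bruteforce(rt)$reducts), 0)
  }

  wide <- random_table(5, 16, seed = 1)
  expect_error(all_reducts_bruteforce(wide), "refusing")
})

test_that("GA reducts are exact reducts: contained in brute force, minimal", {
  for (seed in 1:25) {
    g <- make_table(
      n_objects = 25 + (seed %% 3) * 5,
      n_relevant = 1 + (seed %% 3), n_redundant = seed %% 2,
      n_noise = 2, n_levels = 2 + (seed %% 2),
      flip_noise = if (seed %% 2 == 0) 0 else 0.1, seed = seed
    )
    tab <- g$table
    bf <- all_reducts_bruteforce(tab)
    w <- withr::with_seed(seed, stats::setNames(
      runif(length(condition_attributes(tab))), condition_attributes(tab)
    ))
    ga <- ga_reduct_search(tab, w, ga_params(population = 20, generations = 15,
                                             seed = seed))
    expect_gt(length(ga$reducts), 0)
    bf_keys <- vapply(bf$reducts, function(r) paste(sort(r), collapse = ","),
                      character(1))
    for (r in ga$reducts) {
      expect_true(paste(sort(r), collapse = ",") %in% bf_keys)
      # drop-one minimality
      full_dep <- bf$baseline_dependency
      expect_equal(dependency(tab, r), full_dep)
      if (length(r) > 1) {
        for (a in r) {
          expect_lt(dependency(tab, setdiff(r, a)), full_dep)
        }
      }
    }
  }
})

test_that("GA search recovers a unique planted reduct and is deterministic", {
  withr::with_seed(17, {
    df <- data.frame(a = sample(0:1, 40, TRUE))
    for (j in 1:7) df[[paste0("z", j)]] <- sample(0:1, 40, TRUE)
    df$d <- c("n", "p")[df$a + 1]
  })
  tab <- decision_table(df, "d", positive = "p")
  w <- stats::setNames(c(0.5, runif(7, 0, 0.1)), condition_attributes(tab))
  ga1 <- ga_reduct_search(tab, w, ga_params(seed = 2))
  expect_true(same_reduct_family(ga1$reducts, list("a")))
  ga2 <- ga_reduct_search(tab, w, ga_params(seed = 2))
  expect_identical(ga1$reducts, ga2$reducts)
})

test_that("GA search rejects a decision independent of the conditions", {
  tab <- decision_table(
    data.frame(a = c(0, 0, 1, 1), d = c("x", "y", "x", "y")), "d"
  )
  w <- c(a = 0.5)
  expect_error(ga_reduct_search(tab, w), "independent")
})
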