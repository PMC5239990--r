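# small constructed tables used across test files

# 5 objects, one attribute (0,0,1,1,1), decision (0,1,1,1,1)
five_object_table <- function() {
  decision_table(
    data.frame(p = c(0, 0, 1, 1, 1), d = c(0, 1, 1, 1, 1)),
    decision = "d", kinds = c(p = "nominal"), positive = "1"
  )
}

# toy table for the missing-value diff examples: class "+" instances with
# known A have values (y, y, y, x); class "-" has values (y, x)
toy_missing_table <- function() {
  decision_table(
    data.frame(
      A = c("y", "y", "y", "x", NA, NA, "y", "x", NA),
      B = c("u", "v", "u", "v", "u", "v", "u", "v", "u"),
      d = c("+", "+", "+", "+", "+", "+", "-", "-", "-"),
      stringsAsFactors = FALSE
    ),
    decision = "d", kinds = c(A = "nominal", B = "nominal"), positive = "+"
  )
}

# random small categorical table (for property-style loops)
random_table <- function(n_objects, n_attrs, n_levels = 3, seed = 1) {
  withr::with_seed(seed, {
    df <- as.data.frame(matrix(
      sample.int(n_levels, n_objects * n_attrs, replace = TRUE) - 1L,
      nrow = n_objects
    ))
    names(df) <- paste0("x", seq_len(n_attrs))
    df$d <- sample(c("c0", "c1"), n_objects, replace = TRUE)
  })
  if (length(unique(df$d)) < 2) df$d[1] <- setdiff(c("c0", "c1"), df$d[1])
  decision_table(df, decision = "d",
                 kinds = stats::setNames(rep("nominal", n_attrs),
                                         paste0("x", seq_len(n_attrs))),
                 positive = "c1")
}

# published ReliefF weight table for the 13 Statlog heart attributes
statlog_published_weights <- function() {
  c(C2 = 0.172, C13 = 0.147, C7 = 0.126, C12 = 0.122, C9 = 0.106,
    C3 = 0.098, C11 = 0.057, C10 = 0.046, C8 = 0.042, C4 = 0.032,
    C1 = 0.028, C6 = 0.014, C5 = 0.011)
}

# set-of-sets comparison helper
same_reduct_family <- function(a, b) {
  norm <- function(l) sort(vapply(l, function(r) paste(sort(r), collapse = ","),
                                  character(1)))
  identical(norm(a), norm(b))
}
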