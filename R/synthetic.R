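#' Synthetic decision table with planted reduct structure
#'
#' Generates a categorical decision table in which the minimal reducts are
#' known by construction. Relevant attributes `a1..aR` determine the class
#' through a deterministic rule over their value tuples: a parity rule (label
#' = sum of relevant codes mod 2, so every relevant attribute matters in
#' every context), optionally perturbed by `flip_noise` — each tuple's class
#' is flipped with that probability, producing rules that deviate from parity
#' while the label stays a deterministic function of the relevant attributes,
#' so the table remains consistent and the rough-set machinery applies.
#' (Per-row label noise would make identical tuples carry conflicting labels
#' and collapse the positive region, which is why the noise acts on the rule.)
#' Perturbations that would make the rule constant or drop a relevant
#' attribute entirely are rejected and redrawn. Redundant attributes are
#' value-permuted copies of designated relevant attributes and therefore
#' induce identical partitions. Noise attributes are drawn independently of
#' the class. For every relevant attribute a *witness pair* of objects is
#' planted — identical everywhere except on that attribute (and its copies)
#' and differing in class under the rule — so any attribute subset missing a
#' whole duplicate group leaves a contradiction. The ground-truth minimal
#' reducts are therefore exactly the transversals picking one representative
#' per duplicate group.
#'
#' @param n_objects Number of objects (witness pairs included in the count).
#' @param n_relevant Number of relevant attributes (>= 1).
#' @param n_redundant Number of permuted copies, assigned to relevant
#'   attributes in round-robin order.
#' @param n_noise Number of class-independent attributes.
#' @param n_levels Levels per attribute (2–4; default 3).
#' @param flip_noise Per-tuple rule-perturbation probability, in `[0, 0.5)`.
#' @param seed Integer seed; the same seed reproduces the same table.
#' @return List with `table` (a [decision_table()]), `reducts` (the
#'   ground-truth minimal reducts, list of character vectors), and `roles`
#'   (named character vector: relevant/redundant/noise).
#' @export
make_table <- function(n_objects = 60L, n_relevant = 2L, n_redundant = 1L,
                       n_noise = 2L, n_levels = 3L, flip_noise = 0,
                       seed = 1L) {
  stopifnot(n_relevant >= 1L, flip_noise >= 0, flip_noise < 0.5,
            n_levels >= 2L, n_levels <= 4L,
            n_objects >= 2L * n_relevant + 2L)
  rel_names <- paste0("a", seq_len(n_relevant))
  dup_of <- rep(seq_len(n_relevant), length.out = n_redundant)
  dup_names <- character(n_redundant)
  counts <- integer(n_relevant)
  for (j in seq_len(n_redundant)) {
    counts[dup_of[j]] <- counts[dup_of[j]] + 1L
    dup_names[j] <- paste0("a", dup_of[j], "_dup", counts[dup_of[j]])
  }
  noise_names <- if (n_noise > 0) paste0("z", seq_len(n_noise)) else character(0)

  withr::with_seed(seed, {
    # label rule over the full relevant-tuple space
    tuples <- as.matrix(expand.grid(rep(list(0:(n_levels - 1L)), n_relevant)))
    rule <- label_rule(tuples, flip_noise, n_relevant)
    tuple_key <- tuples %*% n_levels^(seq_len(n_relevant) - 1L)

    n_base <- n_objects - 2L * n_relevant
    rel <- matrix(sample.int(n_levels, n_base * n_relevant, replace = TRUE) - 1L,
                  nrow = n_base, ncol = n_relevant)
    noise <- if (n_noise > 0) {
      matrix(sample.int(n_levels, n_base * n_noise, replace = TRUE) - 1L,
             nrow = n_base, ncol = n_noise)
    } else NULL
    # witness pairs: rows identical except on one relevant attribute, with
    # classes differing under the rule (such a pair exists for every
    # attribute by the rejection step in label_rule)
    for (r in seq_len(n_relevant)) {
      pair <- witness_pair(tuples, rule, r)
      rel <- rbind(rel, tuples[pair[1], ], tuples[pair[2], ])
      if (n_noise > 0) {
        zrow <- sample.int(n_levels, n_noise, replace = TRUE) - 1L
        noise <- rbind(noise, zrow, zrow)
      }
    }
    label <- rule[match(rel %*% n_levels^(seq_len(n_relevant) - 1L), tuple_key)]
    # permuted copies: bijective relabeling of the source attribute
    dup <- if (n_redundant > 0) {
      vapply(seq_len(n_redundant), function(j) {
        perm <- sample.int(n_levels) - 1L
        perm[rel[, dup_of[j]] + 1L]
      }, integer(nrow(rel)))
    } else NULL

    df <- as.data.frame(cbind(rel, dup, noise))
    names(df) <- c(rel_names, dup_names, noise_names)
    df$d <- c("c0", "c1")[label + 1L]
  })

  kinds <- stats::setNames(
    rep("nominal", length(rel_names) + length(dup_names) + length(noise_names)),
    c(rel_names, dup_names, noise_names)
  )
  tab <- decision_table(df, decision = "d", kinds = kinds, positive = "c1")

  groups <- lapply(seq_len(n_relevant), function(r) {
    c(rel_names[r], dup_names[dup_of == r])
  })
  reducts <- apply(expand.grid(groups, stringsAsFactors = FALSE), 1,
                   function(row) unname(unlist(row)), simplify = FALSE)
  roles <- c(
    stats::setNames(rep("relevant", n_relevant), rel_names),
    stats::setNames(rep("redundant", length(dup_names)), dup_names),
    stats::setNames(rep("noise", length(noise_names)), noise_names)
  )
  list(table = tab, reducts = reducts, roles = roles)
}

# parity labels over the tuple rows, perturbed per tuple with prob
# flip_noise; redrawn until the rule is non-constant and every coordinate
# still matters (has a witness pair)
label_rule <- function(tuples, flip_noise, n_relevant) {
  parity <- rowSums(tuples) %% 2L
  repeat {
    rule <- parity
    if (flip_noise > 0) {
      flip <- stats::runif(nrow(tuples)) < flip_noise
      rule[flip] <- 1L - rule[flip]
    }
    if (length(unique(rule)) < 2L) next
    ok <- all(vapply(seq_len(n_relevant), function(r) {
      !is.null(tryCatch(witness_pair(tuples, rule, r), error = function(e) NULL))
    }, logical(1)))
    if (ok) return(rule)
  }
}

# indices of two tuples differing only in coordinate r, with different labels
witness_pair <- function(tuples, rule, r) {
  other <- tuples[, -r, drop = FALSE]
  key <- apply(other, 1, paste, collapse = ",")
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) < 2L) next
    for (i in idx) for (j in idx) {
      if (i < j && rule[i] != rule[j]) return(c(i, j))
    }
  }
  stop("no witness pair for coordinate ", r, call. = FALSE)
}

#' Mask condition-attribute cells at random
#'
#' Each condition cell is independently set to missing with probability
#' `rate`; the decision column is never masked.
#'
#' @param x A [decision_table()].
#' @param rate Masking probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return The masked `decision_table`.
#' @export
inject_missing <- function(x, rate, seed = 1L) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(x)
  df <- as.data.frame(x, stringsAsFactors = FALSE)
  cond <- condition_attributes(x)
  withr::with_seed(seed, {
    for (a in cond) {
      mask <- stats::runif(nrow(df)) < rate
      df[[a]][mask] <- NA
    }
  })
  decision_table(df, decision = decision_attribute(x),
                 kinds = attribute_kinds(x), domains = attribute_domains(x),
                 positive = positive_class(x))
}

# Published marginal summaries of the Statlog (Heart) features used by the
# synthetic generator: real attributes get a moment-matched scaled Beta on
# the published domain (sample mean/sd match the published mean/sd exactly
# in expectation); categorical attributes get plausible level frequencies.
statlog_real_moments <- list(
  C1 = c(mean = 54, sd = 9),
  C4 = c(mean = 131.344, sd = 17.862),
  C5 = c(mean = 249.659, sd = 51.686),
  C8 = c(mean = 149.678, sd = 23.1666),
  C10 = c(mean = 1.05, sd = 1.145)
)

statlog_cat_probs <- list(
  C2 = c(`0` = 0.32, `1` = 0.68),
  C3 = c(`1` = 0.07, `2` = 0.16, `3` = 0.29, `4` = 0.48),
  C6 = c(`0` = 0.85, `1` = 0.15),
  C7 = c(`0` = 0.48, `1` = 0.04, `2` = 0.48),
  C9 = c(`0` = 0.67, `1` = 0.33),
  C11 = c(`1` = 0.48, `2` = 0.46, `3` = 0.06),
  C12 = c(`0` = 0.55, `1` = 0.2, `2` = 0.15, `3` = 0.1),
  C13 = c(`3` = 0.56, `6` = 0.05, `7` = 0.39)
)

#' Synthetic table with the Statlog (Heart) schema
#'
#' Draws `n` instances with the 13-attribute heart-disease schema: real
#' attributes from scaled Beta distributions moment-matched to the published
#' marginal means and standard deviations on the published domains,
#' categorical attributes from plausible level frequencies, and a
#' presence/absence class from a logistic rule over the clinically
#' informative attributes (sex, thal, chest-pain type, exercise angina,
#' vessel count, ECG, ST depression, ST slope). Only marginals and kinds are
#' emulated, not the full joint distribution of the real data.
#'
#' @param n Number of instances (>= 10).
#' @param seed Integer seed.
#' @return A [decision_table()] round-trip compatible with the
#'   [read_statlog()] schema.
#' @export
make_statlog_like <- function(n = 270L, seed = 1L) {
  stopifnot(n >= 10L)
  withr::with_seed(seed, {
    df <- tibble::tibble(.rows = n)
    for (a in paste0("C", 1:13)) {
      if (a %in% names(statlog_real_moments)) {
        mo <- statlog_real_moments[[a]]
        dom <- statlog_domains[[a]]
        m <- (mo[["mean"]] - dom[1]) / (dom[2] - dom[1])
        v <- (mo[["sd"]] / (dom[2] - dom[1]))^2
        ab <- m * (1 - m) / v - 1
        vals <- dom[1] + (dom[2] - dom[1]) * stats::rbeta(n, m * ab, (1 - m) * ab)
        df[[a]] <- round(vals, 1)
      } else {
        p <- statlog_cat_probs[[a]]
        df[[a]] <- as.numeric(sample(names(p), n, replace = TRUE, prob = p))
      }
    }
    z8 <- (df$C8 - 149.678) / 23.1666
    z10 <- (df$C10 - 1.05) / 1.145
    # effect scale chosen so the rule's irreducible (Bayes) accuracy sits
    # near 0.88, comparable to what published classifiers reach on the
    # real heart data, with ~43% disease prevalence
    eta <- 3.2 * (1.2 * df$C2 + 1.1 * (df$C13 == 7) + 0.9 * (df$C3 == 4) +
                    0.8 * df$C9 + 0.8 * (df$C12 > 0) + 0.5 * (df$C7 == 2) +
                    0.5 * z10 + 0.4 * (df$C11 == 2) - 0.4 * z8)
    p_presence <- stats::plogis(eta - mean(eta) - 0.8)
    df$class <- ifelse(stats::runif(n) < p_presence, "presence", "absence")
  })
  if (length(unique(df$class)) < 2L) {
    df$class[1] <- setdiff(c("absence", "presence"), df$class[1])
  }
  decision_table(df, decision = "class", kinds = statlog_kinds,
                 domains = statlog_domains, positive = "presence")
}
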