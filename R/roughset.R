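#' Indiscernibility partition
#'
#' Groups objects that carry identical values on every attribute of `P`; the
#' resulting equivalence classes partition the universe. A missing value is
#' its own category (two objects both missing an attribute are indiscernible
#' on it).
#'
#' @param x A [decision_table()] (categorical attributes; discretize first).
#' @param P Character vector of attribute names. An empty `P` gives the
#'   single-block partition.
#' @return A list of integer vectors (row indices), the equivalence classes,
#'   each sorted, ordered by first member.
#' @export
indiscernibility <- function(x, P) {
  if (!length(P)) {
    message("empty attribute set: universe-wide single block")
    return(list(seq_len(nrow(x))))
  }
  ids <- partition_ids(x, P)
  blocks <- split(seq_len(nrow(x)), ids)
  blocks <- lapply(blocks, sort)
  names(blocks) <- NULL
  blocks[order(vapply(blocks, `[`, integer(1), 1L))]
}

# integer group ids per row for the value tuples on attribute set P
partition_ids <- function(x, P) {
  key <- do.call(paste, c(lapply(P, function(a) {
    v <- as.character(x[[a]])
    v[is.na(v)] <- "\r<NA>"
    v
  }), sep = "\x1f"))
  match(key, unique(key))
}

#' Lower and upper approximations of an object set
#'
#' The lower approximation is the union of equivalence classes wholly inside
#' `X`; the upper approximation the union of classes meeting `X`. Always
#' `lower` \eqn{\subseteq} `X` \eqn{\subseteq} `upper`.
#'
#' @inheritParams indiscernibility
#' @param X Integer vector of row indices (the target object set).
#' @return List with sorted integer vectors `lower` and `upper`.
#' @export
approximations <- function(x, P, X) {
  blocks <- indiscernibility(x, P)
  inX <- logical(nrow(x))
  inX[X] <- TRUE
  lower <- integer(0)
  upper <- integer(0)
  for (b in blocks) {
    hit <- inX[b]
    if (all(hit)) lower <- c(lower, b)
    if (any(hit)) upper <- c(upper, b)
  }
  list(lower = sort(lower), upper = sort(upper))
}

#' Positive region of Q with respect to P
#'
#' The set of objects that can be classified with certainty into the classes
#' of `Q` using only the attributes in `P`: the union over the `Q`-classes of
#' their lower approximations under `P`.
#'
#' @inheritParams indiscernibility
#' @param Q Character vector of attribute names, typically the decision
#'   attribute.
#' @return Sorted integer vector of row indices.
#' @export
positive_region <- function(x, P, Q = decision_attribute(x)) {
  pid <- if (length(P)) partition_ids(x, P) else rep(1L, nrow(x))
  qid <- partition_ids(x, Q)
  pure <- pure_blocks(pid, qid)
  sort(which(pure[pid]))
}

# logical per block id (1..max(pid)): does the block hold a single Q-class?
pure_blocks <- function(pid, qid) {
  nb <- max(pid)
  combo <- as.numeric(pid) * (max(qid) + 1) + qid
  firsts <- !duplicated(combo)
  nclass <- tabulate(pid[firsts], nbins = nb)
  nclass == 1L
}

#' Dependency degree of Q on P
#'
#' The fraction of the universe inside the positive region,
#' `|pos_P(Q)| / |U|`, in `[0, 1]`. A value of 1 means `Q` is fully
#' determined by `P`. Counts are exact integers; the ratio is formed once at
#' the end.
#'
#' @inheritParams positive_region
#' @return A number in `[0, 1]`.
#' @export
dependency <- function(x, P, Q = decision_attribute(x)) {
  length(positive_region(x, P, Q)) / nrow(x)
}

#' Significance of an attribute within a subset
#'
#' The drop in dependency caused by removing `a` from `P`:
#' `r_P(Q) - r_(P \ a)(Q)`. Non-negative, because removing an attribute can
#' only coarsen the partition.
#'
#' @inheritParams positive_region
#' @param a An attribute name, a member of `P`.
#' @return A non-negative number.
#' @export
significance <- function(x, P, Q = decision_attribute(x), a) {
  if (!a %in% P) stop("attribute '", a, "' is not a member of P", call. = FALSE)
  dependency(x, P, Q) - dependency(x, setdiff(P, a), Q)
}

# ---- fast positive-region counting used by reduct search -------------------

# Encode the table once: 0-based integer codes per condition attribute plus
# decision codes. Dependency of any attribute subset then reduces to integer
# key hashing, no data-frame work per evaluation.
encode_table <- function(x) {
  cond <- condition_attributes(x)
  M <- vapply(cond, function(a) {
    v <- as.character(x[[a]])
    v[is.na(v)] <- "\r<NA>"
    match(v, unique(v)) - 1L
  }, integer(nrow(x)))
  if (is.null(dim(M))) M <- matrix(M, ncol = length(cond))
  colnames(M) <- cond
  d <- as.character(x[[decision_attribute(x)]])
  list(M = M, levels = apply(M, 2, max) + 1,
       d = match(d, unique(d)), n = nrow(x))
}

# count of objects in the positive region for the attribute subset `sel`
pos_count <- function(enc, sel) {
  n <- enc$n
  if (!length(sel)) {
    return(if (length(unique(enc$d)) == 1L) n else 0L)
  }
  lv <- enc$levels[sel]
  if (prod(lv) < 2^52) {
    strides <- cumprod(c(1, lv[-length(lv)]))
    key <- as.vector(enc$M[, sel, drop = FALSE] %*% strides)
  } else {
    key <- do.call(paste, c(asplit(enc$M[, sel, drop = FALSE], 2), sep = "\x1f"))
  }
  f <- match(key, unique(key))
  nb <- max(f)
  combo <- f * (max(enc$d) + 1) + enc$d
  firsts <- !duplicated(combo)
  nclass <- tabulate(f[firsts], nbins = nb)
  sizes <- tabulate(f, nbins = nb)
  sum(sizes[nclass == 1L])
}

#' Exhaustive reduct enumeration (test oracle)
#'
#' Scans every non-empty subset of the condition attributes, keeps those whose
#' dependency on the decision equals the full set's dependency, and filters to
#' the subset-minimal ones. Exponential in the attribute count, so refused
#' above `max_attributes`; finding reducts in general is NP-hard and this
#' routine exists as an exact oracle for small tables.
#'
#' @param x A discretized [decision_table()].
#' @param max_attributes Refusal threshold (default 15).
#' @return A `reduct_set`: list with `reducts` (list of character vectors) and
#'   `baseline_dependency`.
#' @export
all_reducts_bruteforce <- function(x, max_attributes = 15L) {
  cond <- condition_attributes(x)
  m <- length(cond)
  if (m > max_attributes) {
    stop("refusing exhaustive scan over ", m, " attributes (limit ",
         max_attributes, ")", call. = FALSE)
  }
  enc <- encode_table(x)
  full <- pos_count(enc, cond)
  kept <- list()
  for (size in seq_len(m)) {
    for (idx in utils::combn(m, size, simplify = FALSE)) {
      sub <- cond[idx]
      if (any(vapply(kept, function(r) all(r %in% sub), logical(1)))) next
      if (pos_count(enc, sub) == full) kept[[length(kept) + 1L]] <- sub
    }
  }
  new_reduct_set(kept, full / enc$n)
}

new_reduct_set <- function(reducts, baseline) {
  structure(list(reducts = reducts, baseline_dependency = baseline),
            class = "reduct_set")
}

#' @export
print.reduct_set <- function(x, ...) {
  cat("Reduct set:", length(x$reducts), "reduct(s), baseline dependency",
      signif(x$baseline_dependency, 6), "\n")
  for (r in x$reducts) cat("  {", paste(r, collapse = ", "), "}\n")
  invisible(x)
}

#' Tidy a reduct set
#'
#' @param x A `reduct_set`.
#' @param ... Unused.
#' @return Tibble with `reduct` (comma-joined label), `size` and `attributes`
#'   (list-column), ordered by size.
#' @export
tidy.reduct_set <- function(x, ...) {
  tibble::tibble(
    reduct = vapply(x$reducts, paste, character(1), collapse = ","),
    size = lengths(x$reducts),
    attributes = x$reducts
  ) |> dplyr::arrange(.data$size, .data$reduct)
}

#' GA search parameters
#'
#' @param population Population size (>= 2).
#' @param generations Number of generations.
#' @param crossover Uniform-crossover probability per pair.
#' @param mutation Per-bit flip probability.
#' @param parsimony Weight of the subset-size penalty in the fitness
#'   (`lambda`).
#' @param init_bias Length-2 clip bounds for the weight-derived initial
#'   per-bit inclusion probabilities.
#' @param tournament Tournament size for selection.
#' @param seed Integer seed; the search is deterministic given it.
#' @return A `ga_params` list.
#' @export
ga_params <- function(population = 50L, generations = 100L, crossover = 0.6,
                      mutation = 0.02, parsimony = 0.1,
                      init_bias = c(0.1, 0.9), tournament = 2L, seed = 1L) {
  stopifnot(population >= 2L, generations >= 1L,
            crossover >= 0, crossover <= 1, mutation >= 0, mutation <= 1,
            length(init_bias) == 2L, init_bias[1] <= init_bias[2])
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 crossover = crossover, mutation = mutation,
                 parsimony = parsimony, init_bias = init_bias,
                 tournament = as.integer(tournament),
                 seed = as.integer(seed)),
            class = "ga_params")
}

#' Weight-guided genetic search for rough-set reducts
#'
#' Searches for minimal attribute subsets that preserve the full condition
#' set's dependency on the decision. Chromosomes are inclusion bitmasks over
#' the condition attributes. The initial population is biased by the ReliefF
#' weights: each bit is switched on with probability equal to the min–max
#' normalized weight, clipped to `init_bias`, so highly ranked attributes
#' enter the search more often. Fitness is the dependency ratio minus a
#' parsimony penalty, with dependency-preserving subsets strictly dominating
#' all others. Every preserving subset met in any generation is reduced to
#' minimality by repeatedly dropping the lowest-weight attribute whose
#' removal keeps the dependency intact; the distinct minimal subsets are
#' accumulated, superset-filtered and returned.
#'
#' @param x A discretized [decision_table()].
#' @param weights A `relieff_weights` object or named numeric vector covering
#'   every condition attribute.
#' @param params A [ga_params()] list.
#' @return A `reduct_set`. Every member passes the drop-one minimality check.
#' @export
ga_reduct_search <- function(x, weights, params = ga_params()) {
  cond <- condition_attributes(x)
  w <- if (inherits(weights, "relieff_weights")) weights$weights else weights
  if (!all(cond %in% names(w))) {
    stop("weights must cover every condition attribute", call. = FALSE)
  }
  w <- w[cond]
  enc <- encode_table(x)
  m <- length(cond)
  full <- pos_count(enc, cond)
  if (full == 0L) stop("decision independent of conditions", call. = FALSE)

  wn <- if (diff(range(w)) > 0) (w - min(w)) / diff(range(w)) else rep(0.5, m)
  p_init <- pmin(pmax(wn, params$init_bias[1]), params$init_bias[2])
  drop_order <- order(w)  # lowest weight tried first during minimization

  found <- new.env(parent = emptyenv())
  minimize <- function(mask) {
    sel <- which(mask)
    repeat {
      dropped <- FALSE
      for (i in drop_order) {
        if (!(i %in% sel) || length(sel) == 1L) next
        cand <- setdiff(sel, i)
        if (pos_count(enc, cond[cand]) == full) {
          sel <- cand
          dropped <- TRUE
          break
        }
      }
      if (!dropped) break
    }
    key <- paste(sort(sel), collapse = ",")
    if (is.null(found[[key]])) found[[key]] <- sort(sel)
    invisible(NULL)
  }

  fitness <- function(mask) {
    sel <- cond[mask]
    pc <- pos_count(enc, sel)
    base <- pc / full - params$parsimony * sum(mask) / m
    if (pc == full) {
      minimize(mask)
      base + 1
    } else {
      base
    }
  }

  top <- which.max(w)
  withr::with_seed(params$seed, {
    pop <- matrix(
      stats::runif(params$population * m) < rep(p_init, each = params$population),
      nrow = params$population
    )
    # the full mask is always evaluated, so at least one reduct (a minimized
    # version of the whole condition set) is guaranteed
    pop[1, ] <- TRUE
    pop <- repair_pop(pop, top)
    fit <- apply(pop, 1, fitness)
    for (gen in seq_len(params$generations)) {
      elite <- pop[which.max(fit), ]
      newpop <- matrix(FALSE, params$population, m)
      newpop[1, ] <- elite
      i <- 2L
      while (i <= params$population) {
        p1 <- pop[tournament_pick(fit, params$tournament), ]
        p2 <- pop[tournament_pick(fit, params$tournament), ]
        if (stats::runif(1) < params$crossover) {
          swap <- stats::runif(m) < 0.5
          c1 <- ifelse(swap, p2, p1)
          c2 <- ifelse(swap, p1, p2)
        } else {
          c1 <- p1; c2 <- p2
        }
        newpop[i, ] <- c1
        if (i + 1L <= params$population) newpop[i + 1L, ] <- c2
        i <- i + 2L
      }
      flips <- matrix(stats::runif(params$population * m) < params$mutation,
                      params$population, m)
      flips[1, ] <- FALSE  # elite untouched
      newpop <- xor(newpop, flips)
      pop <- repair_pop(newpop, top)
      fit <- apply(pop, 1, fitness)
    }
  })

  reducts <- lapply(ls(found), function(k) cond[found[[k]]])
  reducts <- superset_filter(reducts)
  ord <- order(lengths(reducts),
               vapply(reducts, paste, character(1), collapse = ","))
  new_reduct_set(reducts[ord], full / enc$n)
}

# an empty chromosome is repaired by activating the top-weight attribute
repair_pop <- function(pop, top) {
  empty <- rowSums(pop) == 0
  if (any(empty)) pop[empty, top] <- TRUE
  pop
}

tournament_pick <- function(fit, size) {
  cand <- sample.int(length(fit), size, replace = TRUE)
  cand[which.max(fit[cand])]
}

superset_filter <- function(reducts) {
  if (length(reducts) < 2L) return(reducts)
  keep <- rep(TRUE, length(reducts))
  for (i in seq_along(reducts)) {
    for (j in seq_along(reducts)) {
      if (i != j && keep[i] && keep[j] &&
          all(reducts[[j]] %in% reducts[[i]]) &&
          length(reducts[[j]]) < length(reducts[[i]])) {
        keep[i] <- FALSE
      }
    }
  }
  reducts[keep]
}
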