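#' Per-attribute dissimilarity between two instances
#'
#' The `diff` function underlying ReliefF, always in `[0, 1]`. For categorical
#' (nominal/ordered/binary) attributes with both values known it is 0 on
#' equality and 1 otherwise; for real attributes it is the absolute difference
#' scaled by the attribute's value range. Missing values are handled
#' probabilistically through class-conditional relative frequencies: if one
#' instance is missing the value, the dissimilarity is one minus the
#' probability of the other instance's value given the missing instance's
#' class; if both are missing, it is one minus the sum over the attribute's
#' values of the product of the two class-conditional probabilities.
#'
#' @param x A [decision_table()].
#' @param attribute A condition-attribute name.
#' @param i,j Row indices of the two instances.
#' @return A dissimilarity in `[0, 1]`.
#' @export
relieff_diff <- function(x, attribute, i, j) {
  freqs <- class_value_freqs(x)
  relieff_diff_impl(x, attribute, i, j, freqs)
}

relieff_diff_impl <- function(x, attribute, i, j, freqs) {
  v1 <- x[[attribute]][i]
  v2 <- x[[attribute]][j]
  kinds <- attribute_kinds(x)
  if (!is.na(v1) && !is.na(v2)) {
    if (kinds[[attribute]] == "real") {
      rng <- attr_range(x, attribute)
      if (rng <= 0) return(0)
      return(abs(v1 - v2) / rng)
    }
    return(as.numeric(v1 != v2))
  }
  d <- x[[decision_attribute(x)]]
  f <- freqs[[attribute]]
  if (is.na(v1) && is.na(v2)) {
    p1 <- f[[as.character(d[i])]]
    p2 <- f[[as.character(d[j])]]
    vals <- union(names(p1), names(p2))
    s <- sum(vapply(vals, function(v) {
      p_of(p1, v) * p_of(p2, v)
    }, numeric(1)))
    return(1 - s)
  }
  # exactly one missing: condition on the missing instance's class
  if (is.na(v1)) {
    1 - p_of(f[[as.character(d[i])]], as.character(v2))
  } else {
    1 - p_of(f[[as.character(d[j])]], as.character(v1))
  }
}

p_of <- function(freq, value) {
  if (is.null(freq) || !value %in% names(freq)) 0 else unname(freq[[value]])
}

attr_range <- function(x, a) {
  if (isTRUE(attr(x, "use_domain_range"))) {
    dom <- attribute_domains(x)[[a]]
    if (length(dom) == 2L && !anyNA(dom)) return(dom[2] - dom[1])
  }
  v <- x[[a]][!is.na(x[[a]])]
  if (length(v) < 2L) 0 else diff(range(v))
}

# class-conditional relative frequencies of observed values, per attribute
class_value_freqs <- function(x) {
  d <- as.character(x[[decision_attribute(x)]])
  cond <- condition_attributes(x)
  out <- lapply(cond, function(a) {
    v <- as.character(x[[a]])
    keep <- !is.na(x[[a]])
    tapply(v[keep], d[keep], function(vv) {
      tab <- table(vv)
      as.numeric(tab) |> stats::setNames(names(tab)) |> (\(t) t / sum(t))()
    }, simplify = FALSE)
  })
  names(out) <- cond
  out
}

# Full n x n diff matrix for one attribute (vectorized known-known path,
# per-pair fallback where a missing value is involved).
diff_matrix <- function(x, a, freqs) {
  v <- x[[a]]
  n <- length(v)
  kinds <- attribute_kinds(x)
  if (kinds[[a]] == "real") {
    rng <- attr_range(x, a)
    D <- if (rng <= 0) matrix(0, n, n) else abs(outer(v, v, `-`)) / rng
  } else {
    D <- 1 - outer(v, v, `==`) * 1
  }
  miss <- which(is.na(v))
  if (length(miss)) {
    for (i in miss) {
      for (j in seq_len(n)) {
        D[i, j] <- relieff_diff_impl(x, a, i, j, freqs)
        D[j, i] <- D[i, j]
      }
    }
  }
  diag(D) <- 0
  D
}

#' ReliefF attribute weights
#'
#' Estimates a quality weight in `[-1, 1]` for every condition attribute.
#' For each anchor instance the algorithm finds its `k` nearest neighbours of
#' the same class (hits) and, for every other class, its `k` nearest
#' neighbours of that class (misses), nearness being the Manhattan sum of
#' per-attribute dissimilarities ([relieff_diff()]); neighbours tied in
#' distance at the k-th rank contribute fractionally, which makes the
#' estimate invariant under object reordering. Each attribute's weight
#' is decreased by the average hit dissimilarity and increased by the
#' class-prior-weighted average miss dissimilarity (miss class `c` weighted by
#' `P(c) / (1 - P(class(anchor)))`), averaged over anchors. A weight near zero
#' marks an attribute carrying no class information; strongly positive weights
#' mark attributes that separate the classes.
#'
#' @param x A [decision_table()]; needs at least two classes.
#' @param k_neighbors Number of nearest hits/misses per class (default 10).
#'   Truncated per class when a class has fewer members.
#' @param n_samples Number of anchor instances sampled without replacement;
#'   `NULL` (default) uses every instance as an anchor, which is deterministic.
#' @param seed Integer seed used when `n_samples` is given.
#' @param normalize If `TRUE` (default) real-attribute dissimilarities are
#'   scaled by the observed value range; if `FALSE`, by the declared domain
#'   width.
#' @return A `relieff_weights` object: list with `weights` (named numeric),
#'   `k_neighbors`, `n_anchors`, `seed`. Has [tidy()][generics::tidy],
#'   `glance()` and `autoplot()` methods.
#' @export
relieff_weights <- function(x, k_neighbors = 10L, n_samples = NULL,
                            seed = 1L, normalize = TRUE) {
  d <- as.character(x[[decision_attribute(x)]])
  classes <- unique(d)
  if (length(classes) < 2L) {
    stop("weights undefined for one class", call. = FALSE)
  }
  cond <- condition_attributes(x)
  n <- nrow(x)
  if (!normalize) attr(x, "use_domain_range") <- TRUE
  freqs <- class_value_freqs(x)
  D <- lapply(cond, function(a) diff_matrix(x, a, freqs))
  names(D) <- cond
  dist <- Reduce(`+`, D)

  anchors <- if (is.null(n_samples)) {
    seq_len(n)
  } else {
    withr::with_seed(seed, sample.int(n, min(n_samples, n)))
  }
  prior <- table(d) / n
  W <- stats::setNames(numeric(length(cond)), cond)
  m <- length(anchors)
  idx_by_class <- split(seq_len(n), d)

  for (i in anchors) {
    y <- d[i]
    for (cl in classes) {
      pool <- setdiff(idx_by_class[[cl]], i)
      if (!length(pool)) next
      k_use <- min(k_neighbors, length(pool))
      # distance-tied neighbours at the k-th rank enter with fractional
      # weight, so the estimate is invariant under object reordering
      dv <- dist[i, pool]
      kth <- sort(dv)[k_use]
      lt <- dv < kth
      eq <- dv == kth
      w_eq <- (k_use - sum(lt)) / sum(eq)
      coef <- if (cl == y) -1 else prior[[cl]] / (1 - prior[[y]])
      for (a in cond) {
        da <- D[[a]][i, pool]
        avg <- (sum(da[lt]) + w_eq * sum(da[eq])) / k_use
        W[[a]] <- W[[a]] + coef * avg / m
      }
    }
  }
  structure(
    list(weights = W, k_neighbors = as.integer(k_neighbors),
         n_anchors = m, seed = as.integer(seed)),
    class = "relieff_weights"
  )
}

#' @export
print.relieff_weights <- function(x, ...) {
  cat("ReliefF weights (k =", x$k_neighbors, ",", x$n_anchors, "anchors)\n")
  print(round(sort(x$weights, decreasing = TRUE), 4))
  invisible(x)
}

#' Tidy a ReliefF weight vector
#'
#' @param x A `relieff_weights` object.
#' @param delta Optional selection threshold; adds a `selected` column
#'   (`weight > delta`, strict).
#' @param ... Unused.
#' @return A tibble with columns `attribute`, `weight`, `rank` and optionally
#'   `selected`, ordered by decreasing weight.
#' @export
tidy.relieff_weights <- function(x, delta = NULL, ...) {
  out <- tibble::tibble(
    attribute = names(x$weights),
    weight = unname(x$weights)
  ) |>
    dplyr::arrange(dplyr::desc(.data$weight)) |>
    dplyr::mutate(rank = dplyr::row_number())
  if (!is.null(delta)) out$selected <- out$weight > delta
  out
}

#' @export
glance.relieff_weights <- function(x, ...) {
  tibble::tibble(
    k_neighbors = x$k_neighbors,
    n_anchors = x$n_anchors,
    n_attributes = length(x$weights),
    max_weight = max(x$weights),
    min_weight = min(x$weights)
  )
}

#' Plot ReliefF weights as a ranked bar chart
#'
#' @param object A `relieff_weights` object.
#' @param delta Optional threshold drawn as a dashed line and used to colour
#'   selected attributes.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.relieff_weights <- function(object, delta = NULL, ...) {
  df <- tidy.relieff_weights(object, delta = delta)
  df$attribute <- stats::reorder(df$attribute, df$weight)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$attribute, y = .data$weight)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "ReliefF weight")
  if (!is.null(delta)) {
    p <- p +
      ggplot2::geom_col(ggplot2::aes(fill = .data$selected)) +
      ggplot2::geom_hline(yintercept = delta, linetype = "dashed") +
      ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                            `FALSE` = "grey70"),
                                 name = "selected")
  } else {
    p <- p + ggplot2::geom_col(fill = "steelblue")
  }
  p
}

#' Select attributes whose weight exceeds a threshold
#'
#' Keeps exactly the attributes with weight strictly greater than `delta`.
#'
#' @param weights A `relieff_weights` object or a named numeric vector.
#' @param delta Selection threshold (default 0.02).
#' @return Character vector of selected attribute names (in decreasing weight
#'   order). Warns and returns `character(0)` when nothing clears the
#'   threshold.
#' @export
select_features <- function(weights, delta = 0.02) {
  w <- if (inherits(weights, "relieff_weights")) weights$weights else weights
  stopifnot(is.numeric(w), !is.null(names(w)))
  keep <- w[w > delta]
  if (!length(keep)) {
    warning("no attribute weight exceeds delta = ", delta, call. = FALSE)
    return(character(0))
  }
  names(sort(keep, decreasing = TRUE))
}
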