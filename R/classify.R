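#' Tree induction parameters
#'
#' @param min_leaf Minimum total instance weight per branch, in units of whole
#'   instances (default 2, the classic C4.5 minimum-cases setting).
#' @param max_depth Depth limit (default unlimited).
#' @param pruning Apply pessimistic (confidence-bound) error pruning after
#'   growing. Off by default: boosting prefers low-bias base learners.
#' @param cf Confidence factor for pruning (default 0.25).
#' @return A `tree_control` list.
#' @export
tree_control <- function(min_leaf = 2, max_depth = Inf, pruning = FALSE,
                         cf = 0.25) {
  structure(list(min_leaf = min_leaf, max_depth = max_depth,
                 pruning = pruning, cf = cf), class = "tree_control")
}

w_entropy <- function(w_by_class) {
  p <- w_by_class[w_by_class > 0] / sum(w_by_class)
  -sum(p * log2(p))
}

#' Train a C4.5-style decision tree
#'
#' Greedy recursive partitioning on weighted instances. At each node the
#' split maximizing the weighted gain ratio is chosen among attributes whose
#' information gain is at least the average gain of the candidates (the C4.5
#' pre-filter). Nominal and binary attributes split multiway, one child per
#' observed category; real and ordered attributes take the best binary
#' threshold among midpoints of consecutive distinct values. Growth stops on
#' pure nodes, when node weight falls below `min_leaf`, at `max_depth`, or
#' when no split yields positive gain. Leaf labels are the weighted majority;
#' ties go to the class more prevalent in the full training set, then to the
#' lexicographically lower label. Instances missing the split value are
#' excluded from that split's evaluation (gain scaled by the known-weight
#' fraction) and routed to the heaviest child when the tree is applied.
#'
#' @param x A [decision_table()].
#' @param instance_weights Non-negative per-object weights, not all zero;
#'   default uniform. Rescaled internally so they sum to the object count,
#'   making induction invariant under overall weight scaling.
#' @param control A [tree_control()] list.
#' @return A `c45_tree` object with a [predict()] method returning class
#'   labels.
#' @export
train_tree <- function(x, instance_weights = NULL, control = tree_control()) {
  n <- nrow(x)
  if (is.null(instance_weights)) instance_weights <- rep(1, n)
  stopifnot(length(instance_weights) == n, all(instance_weights >= 0),
            sum(instance_weights) > 0)
  w <- instance_weights * n / sum(instance_weights)
  y <- as.character(x[[decision_attribute(x)]])
  classes <- sort(unique(y))
  overall <- vapply(classes, function(cl) sum(w[y == cl]), numeric(1))
  kinds <- attribute_kinds(x)
  cond <- condition_attributes(x)
  cols <- lapply(cond, function(a) x[[a]])
  names(cols) <- cond

  node <- grow_node(cols, y, w, cond, kinds, classes, overall, depth = 0L,
                    control = control)
  if (control$pruning) node <- prune_node(node, control$cf)
  structure(list(root = node, classes = classes, kinds = kinds,
                 decision = decision_attribute(x), overall = overall),
            class = "c45_tree")
}

class_weights <- function(y, w, classes) {
  vapply(classes, function(cl) sum(w[y == cl]), numeric(1))
}

majority_label <- function(wc, overall, classes) {
  top <- which(wc == max(wc))
  if (length(top) > 1L) {
    # tie: prefer class more prevalent overall, then lower label
    top <- top[order(-overall[top], classes[top])]
  }
  classes[top[1]]
}

make_leaf <- function(y, w, classes, overall) {
  wc <- class_weights(y, w, classes)
  prob <- if (sum(wc) > 0) wc / sum(wc) else rep(1 / length(classes), length(classes))
  list(leaf = TRUE, label = majority_label(wc, overall, classes),
       prob = stats::setNames(prob, classes), weight = sum(w),
       error_weight = sum(w) - max(wc))
}

grow_node <- function(cols, y, w, cond, kinds, classes, overall, depth,
                      control) {
  wc <- class_weights(y, w, classes)
  if (sum(wc > 0) <= 1L || sum(w) < control$min_leaf ||
      depth >= control$max_depth) {
    return(make_leaf(y, w, classes, overall))
  }
  cand <- lapply(cond, function(a) {
    best_split(cols[[a]], y, w, kinds[[a]], classes, control$min_leaf)
  })
  names(cand) <- cond
  gains <- vapply(cand, function(s) if (is.null(s)) -Inf else s$gain, numeric(1))
  ok <- is.finite(gains) & gains > 1e-12
  if (!any(ok)) return(make_leaf(y, w, classes, overall))
  thresh <- mean(gains[ok])
  pool <- names(gains)[ok & gains >= thresh - 1e-12]
  ratios <- vapply(pool, function(a) cand[[a]]$gain_ratio, numeric(1))
  a_star <- pool[which.max(ratios)]
  sp <- cand[[a_star]]

  v <- cols[[a_star]]
  known <- !is.na(v)
  if (sp$type == "nominal") {
    cats <- sp$categories
    children <- vector("list", length(cats))
    names(children) <- cats
    child_w <- numeric(length(cats))
    for (ci in seq_along(cats)) {
      sel <- known & as.character(v) == cats[ci]
      child_w[ci] <- sum(w[sel])
      children[[ci]] <- grow_node(
        lapply(cols, function(col) col[sel]), y[sel], w[sel],
        cond, kinds, classes, overall, depth + 1L, control
      )
    }
    list(leaf = FALSE, attribute = a_star, type = "nominal",
         children = children, child_weights = stats::setNames(child_w, cats),
         majority_child = cats[which.max(child_w)],
         fallback = make_leaf(y, w, classes, overall))
  } else {
    selL <- known & v <= sp$threshold
    selR <- known & v > sp$threshold
    left <- grow_node(lapply(cols, function(col) col[selL]), y[selL], w[selL],
                      cond, kinds, classes, overall, depth + 1L, control)
    right <- grow_node(lapply(cols, function(col) col[selR]), y[selR], w[selR],
                       cond, kinds, classes, overall, depth + 1L, control)
    list(leaf = FALSE, attribute = a_star, type = "threshold",
         threshold = sp$threshold, children = list(left = left, right = right),
         child_weights = c(left = sum(w[selL]), right = sum(w[selR])),
         majority_child = if (sum(w[selL]) >= sum(w[selR])) "left" else "right",
         fallback = make_leaf(y, w, classes, overall))
  }
}

# best weighted gain-ratio split for one attribute; NULL when no valid split
best_split <- function(v, y, w, kind, classes, min_leaf) {
  known <- !is.na(v)
  Wk <- sum(w[known])
  W <- sum(w)
  if (Wk <= 0) return(NULL)
  yk <- y[known]; wk <- w[known]; vk <- v[known]
  H <- w_entropy(class_weights(yk, wk, classes))

  if (kind %in% c("nominal", "binary")) {
    vs <- as.character(vk)
    cats <- sort(unique(vs))
    if (length(cats) < 2L) return(NULL)
    CW <- vapply(classes, function(cl) wk * (yk == cl),
                 numeric(length(wk)))
    if (is.null(dim(CW))) CW <- matrix(CW, nrow = length(wk))
    M <- rowsum(CW, vs)  # category x class weight totals
    M <- M[cats, , drop = FALSE]
    wt <- rowSums(M)
    if (sum(wt >= min_leaf) < 2L) return(NULL)
    gain_known <- H - sum(wt * row_entropy(M)) / Wk
    gain <- (Wk / W) * gain_known
    si <- w_entropy(wt)
    if (si <= 0) return(NULL)
    list(type = "nominal", categories = cats, gain = gain,
         gain_ratio = gain / si)
  } else {
    ord <- order(vk)
    vs <- vk[ord]; ys <- yk[ord]; ws <- wk[ord]
    nk <- length(vs)
    if (nk < 2L || vs[1] == vs[nk]) return(NULL)
    # cumulative class-weight sums give every left-side distribution at once
    cw <- vapply(classes, function(cl) cumsum(ws * (ys == cl)),
                 numeric(nk))
    if (is.null(dim(cw))) cw <- matrix(cw, nrow = nk)
    pos <- which(vs[-nk] != vs[-1])  # candidate boundaries
    if (!length(pos)) return(NULL)
    L <- cw[pos, , drop = FALSE]
    tot <- cw[nk, ]
    R <- matrix(tot, nrow(L), ncol(L), byrow = TRUE) - L
    wl <- rowSums(L); wr <- rowSums(R)
    ok <- wl >= min_leaf & wr >= min_leaf
    if (!any(ok)) return(NULL)
    gain_known <- H - (wl * row_entropy(L) + wr * row_entropy(R)) / Wk
    gain <- (Wk / W) * gain_known
    si <- row_entropy(cbind(wl, wr))
    ok <- ok & si > 0
    if (!any(ok)) return(NULL)
    gain[!ok] <- -Inf
    i <- which.max(gain)  # ties resolve to the lowest threshold
    list(type = "threshold", threshold = (vs[pos[i]] + vs[pos[i] + 1L]) / 2,
         gain = gain[i], gain_ratio = gain[i] / si[i])
  }
}

# entropy of each row of a non-negative weight matrix
row_entropy <- function(M) {
  s <- rowSums(M)
  P <- M / (s + (s <= 0))
  -rowSums(P * log2(P + (P <= 0)))
}

# C4.5 pessimistic pruning: collapse a subtree when the upper confidence
# bound on its leaf-ified error is no worse than the sum over its branches
prune_node <- function(node, cf) {
  if (node$leaf) return(node)
  node$children <- lapply(node$children, prune_node, cf = cf)
  subtree_err <- sum(vapply(node$children, ucb_error, numeric(1), cf = cf))
  leaf <- node$fallback
  if (ucb_error(leaf, cf) <= subtree_err + 1e-12) leaf else node
}

ucb_error <- function(node, cf) {
  if (node$leaf) {
    n <- node$weight
    if (n <= 0) return(0)
    e <- node$error_weight
    n * stats::qbeta(1 - cf, e + 1, pmax(n - e, 0) + 1e-9)
  } else {
    sum(vapply(node$children, ucb_error, numeric(1), cf = cf))
  }
}

route <- function(node, cols, i) {
  while (!node$leaf) {
    v <- cols[[node$attribute]][i]
    node <- if (node$type == "nominal") {
      key <- if (is.na(v)) NA_character_ else as.character(v)
      if (!is.na(key) && key %in% names(node$children)) {
        node$children[[key]]
      } else {
        node$children[[node$majority_child]]
      }
    } else {
      if (is.na(v)) {
        node$children[[node$majority_child]]
      } else if (v <= node$threshold) {
        node$children$left
      } else {
        node$children$right
      }
    }
  }
  node
}

#' Predict with a C4.5-style tree
#'
#' @param object A `c45_tree`.
#' @param newdata A data frame (or `decision_table`) of instances.
#' @param type `"class"` for labels, `"prob"` for the leaf class-probability
#'   matrix.
#' @param ... Unused.
#' @return Character vector of labels or a numeric matrix of probabilities.
#' @export
predict.c45_tree <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  cols <- as.list(as.data.frame(newdata, stringsAsFactors = FALSE))
  leaves <- lapply(seq_len(nrow(newdata)), function(i) {
    route(object$root, cols, i)
  })
  if (type == "class") {
    vapply(leaves, `[[`, character(1), "label")
  } else {
    do.call(rbind, lapply(leaves, `[[`, "prob"))
  }
}

#' @export
print.c45_tree <- function(x, ...) {
  cat("C4.5-style tree,", tree_size(x$root), "leaves\n")
  invisible(x)
}

tree_size <- function(node) {
  if (node$leaf) 1L else sum(vapply(node$children, tree_size, integer(1)))
}

#' Boosted ensemble of C4.5-style trees
#'
#' AdaBoost.M1 by reweighting on a binary decision table. Instance weights
#' start uniform; each round trains a tree on the current weights and
#' measures its weighted error `eps`. A round with `eps = 0` receives a
#' capped vote weight and the weights reset to uniform; a round with
#' `eps >= 0.5` is discarded and the weights reset; otherwise the vote weight
#' is `0.5 * log((1 - eps) / eps)`, misclassified instances are up-weighted
#' by `exp(vote)`, the rest down-weighted, and the weights renormalized.
#' Reweighting (the default) is fully deterministic; `resample = TRUE`
#' draws a weighted bootstrap sample each round instead, using `seed`.
#'
#' @param x A binary-decision [decision_table()].
#' @param k Number of boosting rounds requested (>= 1).
#' @param seed Integer seed (used only in resampling mode).
#' @param control A [tree_control()] for the base trees.
#' @param resample Use weighted resampling instead of reweighting.
#' @param vote_cap Vote weight assigned to an error-free round (default 10).
#' @return A `boosted_ensemble`: members (tree + vote weight), `n_requested`,
#'   `n_effective`, the positive class, the final (renormalized) instance
#'   weights and training metadata. Has
#'   [predict()], `tidy()` and `glance()` methods.
#' @export
boost <- function(x, k, seed = 1L, control = tree_control(),
                  resample = FALSE, vote_cap = 10) {
  if (!is.numeric(k) || k < 1L) stop("k must be a positive integer", call. = FALSE)
  k <- as.integer(k)
  y <- as.character(x[[decision_attribute(x)]])
  classes <- sort(unique(y))
  if (length(classes) != 2L) {
    stop("boosting requires a binary decision attribute", call. = FALSE)
  }
  n <- nrow(x)
  w <- rep(1 / n, n)
  members <- list()
  withr::with_seed(seed, {
    for (round in seq_len(k)) {
      xw <- if (resample) {
        idx <- sample.int(n, n, replace = TRUE, prob = w)
        list(tab = dt_keep_rows(x, idx), w = rep(1 / n, n), idx = idx)
      } else {
        list(tab = x, w = w, idx = seq_len(n))
      }
      tree <- train_tree(xw$tab, instance_weights = xw$w, control = control)
      pred <- predict.c45_tree(tree, x)
      wrong <- pred != y
      eps <- sum(w[wrong])
      if (eps <= 0) {
        members[[length(members) + 1L]] <- list(tree = tree, vote = vote_cap)
        w <- rep(1 / n, n)
      } else if (eps >= 0.5) {
        w <- rep(1 / n, n)  # round discarded
      } else {
        vote <- 0.5 * log((1 - eps) / eps)
        members[[length(members) + 1L]] <- list(tree = tree, vote = vote)
        w <- w * exp(ifelse(wrong, vote, -vote))
        w <- w / sum(w)
      }
    }
  })
  structure(
    list(members = members, n_requested = k, n_effective = length(members),
         classes = classes, positive = positive_class(x),
         decision = decision_attribute(x), final_weights = w),
    class = "boosted_ensemble"
  )
}

#' Ensemble score and class prediction
#'
#' The score is the vote-weighted average of per-tree votes, `+1` for the
#' positive class and `-1` otherwise, normalized by the total vote weight,
#' so it lies in `[-1, 1]`. The predicted class is the sign of the score;
#' a zero score ties to the positive class.
#'
#' @param model A non-empty `boosted_ensemble`.
#' @param newdata Data frame of instances.
#' @return Numeric scores in `[-1, 1]`.
#' @export
predict_score <- function(model, newdata) {
  stopifnot(inherits(model, "boosted_ensemble"))
  if (!length(model$members)) stop("ensemble has no members", call. = FALSE)
  votes <- vapply(model$members, `[[`, numeric(1), "vote")
  preds <- vapply(model$members, function(mb) {
    ifelse(predict.c45_tree(mb$tree, newdata) == model$positive, 1, -1)
  }, numeric(nrow(newdata)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = nrow(newdata))
  as.vector(preds %*% votes) / sum(votes)
}

#' @rdname predict_score
#' @param object A `boosted_ensemble`.
#' @param type `"class"` or `"score"`.
#' @param ... Unused.
#' @export
predict.boosted_ensemble <- function(object, newdata,
                                     type = c("class", "score"), ...) {
  type <- match.arg(type)
  s <- predict_score(object, newdata)
  if (type == "score") return(s)
  negative <- setdiff(object$classes, object$positive)
  ifelse(s >= 0, object$positive, negative)
}

#' @export
print.boosted_ensemble <- function(x, ...) {
  cat("Boosted ensemble:", x$n_effective, "of", x$n_requested,
      "rounds accepted; positive class =", x$positive, "\n")
  invisible(x)
}

#' @export
tidy.boosted_ensemble <- function(x, ...) {
  tibble::tibble(
    round = seq_along(x$members),
    vote = vapply(x$members, `[[`, numeric(1), "vote"),
    leaves = vapply(x$members, function(mb) tree_size(mb$tree$root), integer(1))
  )
}

#' @export
glance.boosted_ensemble <- function(x, ...) {
  tibble::tibble(
    n_requested = x$n_requested,
    n_effective = x$n_effective,
    total_vote = sum(vapply(x$members, `[[`, numeric(1), "vote"))
  )
}
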