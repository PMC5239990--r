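#' Confusion matrix for binary classification
#'
#' Counts with the disease-present convention: TP are positives predicted
#' positive, FN positives predicted negative, FP negatives predicted
#' positive, TN negatives predicted negative.
#'
#' @param actual,predicted Equal-length label vectors.
#' @param positive The positive-class label.
#' @return A `confusion_matrix`: list with integer `TP`, `FN`, `FP`, `TN`.
#' @export
confusion <- function(actual, predicted, positive) {
  if (length(actual) != length(predicted) || !length(actual)) {
    stop("`actual` and `predicted` must be equal-length, non-empty", call. = FALSE)
  }
  a <- actual == positive
  p <- predicted == positive
  structure(list(
    TP = sum(a & p), FN = sum(a & !p), FP = sum(!a & p), TN = sum(!a & !p)
  ), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2, byrow = TRUE,
              dimnames = list(c("actual +", "actual -"),
                              c("pred +", "pred -")))
  print(m)
  invisible(x)
}

#' Sensitivity, specificity and accuracy
#'
#' `Sn = TP / (TP + FN)`, `Sp = TN / (FP + TN)`,
#' `Acc = (TP + TN) / (TP + TN + FP + FN)`, each as a percentage. A metric
#' with an empty denominator is undefined and reported as `NA`, never as 0.
#'
#' @param cm A [confusion()] matrix.
#' @return A tibble with `sensitivity`, `specificity`, `accuracy` (percent).
#' @export
metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  pos <- cm$TP + cm$FN
  neg <- cm$FP + cm$TN
  tot <- pos + neg
  tibble::tibble(
    sensitivity = if (pos > 0) 100 * cm$TP / pos else NA_real_,
    specificity = if (neg > 0) 100 * cm$TN / neg else NA_real_,
    accuracy = if (tot > 0) 100 * (cm$TP + cm$TN) / tot else NA_real_
  )
}

#' Stratified 70/30 train/test split
#'
#' The test set holds `round(0.3 * n)` objects; in stratified mode (default)
#' each class contributes proportionally (largest-remainder rounding), so
#' test class proportions stay within one object of the global proportions.
#'
#' @param x A [decision_table()].
#' @param seed Integer seed; the same seed reproduces the same split.
#' @param stratified Stratify by decision class (default `TRUE`).
#' @return List with `train` and `test` decision tables (disjoint,
#'   exhaustive).
#' @export
split_70_30 <- function(x, seed = 1L, stratified = TRUE) {
  n <- nrow(x)
  n_test <- round(0.3 * n)
  test_idx <- withr::with_seed(seed, {
    if (!stratified) {
      sample.int(n, n_test)
    } else {
      d <- as.character(x[[decision_attribute(x)]])
      groups <- split(seq_len(n), d)
      quota <- vapply(groups, function(g) 0.3 * length(g), numeric(1))
      base <- floor(quota)
      rem <- n_test - sum(base)
      if (rem > 0) {
        extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
      } else if (rem < 0) {
        cut <- order(quota - base)[seq_len(-rem)]
        base[cut] <- pmax(base[cut] - 1, 0)
      }
      unlist(lapply(seq_along(groups), function(i) {
        sample(groups[[i]], base[i])
      }), use.names = FALSE)
    }
  })
  list(train = dt_keep_rows(x, -sort(test_idx)),
       test = dt_keep_rows(x, sort(test_idx)))
}

#' Jackknife (leave-one-out) evaluation
#'
#' Each object is predicted by a model trained on the remaining objects; the
#' confusion matrix aggregates all `n` predictions, so its total equals the
#' universe size.
#'
#' @param x A [decision_table()] with at least 2 objects.
#' @param trainer Function `(decision_table) -> model`.
#' @param predictor Function `(model, newdata) -> label vector`; defaults to
#'   [predict()].
#' @return List with `confusion` (a [confusion()] matrix), `metrics` (a
#'   [metrics()] tibble) and `predictions`.
#' @export
jackknife <- function(x, trainer, predictor = function(m, d) predict(m, d)) {
  n <- nrow(x)
  stopifnot(n >= 2L)
  y <- as.character(x[[decision_attribute(x)]])
  preds <- character(n)
  for (i in seq_len(n)) {
    model <- tryCatch(trainer(dt_keep_rows(x, -i)), error = function(e) {
      stop("trainer failed on fold ", i, ": ", conditionMessage(e),
           call. = FALSE)
    })
    preds[i] <- predictor(model, dt_keep_rows(x, i))
  }
  cm <- confusion(y, preds, positive_class(x))
  list(confusion = cm, metrics = metrics(cm), predictions = preds)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the distinct scores in descending order, grouping tied scores into
#' a single step, and accumulates (false-positive-rate, true-positive-rate)
#' points from `(0, 0)` to `(1, 1)`. The AUC is the trapezoid-rule area,
#' which equals the probability that a random positive outscores a random
#' negative (ties counted half).
#'
#' @param scores Numeric classifier scores (larger = more positive).
#' @param actual Label vector.
#' @param positive Positive-class label.
#' @return A `roc_curve`: list with `points` (tibble `fpr`, `tpr`,
#'   `threshold`) and `auc`. Has an `autoplot()` method.
#' @export
roc <- function(scores, actual, positive) {
  stopifnot(length(scores) == length(actual))
  is_pos <- actual == positive
  P <- sum(is_pos); N <- sum(!is_pos)
  if (P == 0 || N == 0) stop("both classes must be present", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yp <- is_pos[ord]
  # group tied scores into single steps
  grp_end <- c(which(diff(s) != 0), length(s))
  tp <- cumsum(yp)[grp_end]
  fp <- (grp_end - cumsum(yp)[grp_end])
  pts <- tibble::tibble(
    fpr = c(0, fp / N),
    tpr = c(0, tp / P),
    threshold = c(Inf, s[grp_end])
  )
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("ROC curve:", nrow(x$points), "points, AUC =", signif(x$auc, 6), "\n")
  invisible(x)
}

#' Plot a ROC curve
#'
#' @param object A `roc_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC (AUC = %.3f)", object$auc)
    )
}
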