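#' Fit an equal-interval binning specification
#'
#' Rough-set reduction needs categorical data, so continuous condition
#' attributes are binned first. For an attribute with observed (non-missing)
#' minimum `m` and maximum `M`, `n_bins` equal-width intervals give cut points
#' at `m + i * (M - m) / n_bins` for `i = 1 .. n_bins - 1`. A constant
#' attribute yields a single-bin spec with no cut points.
#'
#' @param x A [decision_table()].
#' @param n_bins Number of bins (>= 2).
#' @param attributes Attributes to bin; defaults to all real-kind condition
#'   attributes.
#' @return A `binning_spec`: a named list of ascending cut-point vectors.
#' @examples
#' dt <- decision_table(data.frame(a = c(29, 50, 77), d = c(0, 1, 1)), "d")
#' fit_equal_interval(dt, n_bins = 4)
#' @export
fit_equal_interval <- function(x, n_bins = 4L,
                               attributes = real_attributes(x)) {
  stopifnot(n_bins >= 2L)
  kinds <- attribute_kinds(x)
  bad <- attributes[kinds[attributes] != "real"]
  if (length(bad)) {
    stop("equal-interval binning applies to real attributes only: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cuts <- lapply(attributes, function(a) {
    v <- x[[a]][!is.na(x[[a]])]
    if (!length(v)) stop("attribute ", a, " has no observed values", call. = FALSE)
    m <- min(v); M <- max(v)
    if (m == M) return(numeric(0))
    m + seq_len(n_bins - 1L) * (M - m) / n_bins
  })
  names(cuts) <- attributes
  structure(list(cut_points = cuts, n_bins = as.integer(n_bins)),
            class = "binning_spec")
}

#' @export
print.binning_spec <- function(x, ...) {
  cat("Equal-interval binning spec (", x$n_bins, " bins):\n", sep = "")
  for (a in names(x$cut_points)) {
    cat("  ", a, ": cuts at ",
        paste(signif(x$cut_points[[a]], 5), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @rdname fit_equal_interval
#' @export
real_attributes <- function(x) {
  kinds <- attribute_kinds(x)
  names(kinds)[kinds == "real"]
}

#' Apply a fitted binning specification
#'
#' Binned attributes become ordered-kind with integer codes `0 .. n_bins - 1`.
#' Assignment is right-closed: a value `v` maps to the smallest bin `i` with
#' `v <= cut_i`, so a value exactly at a cut point falls in the lower bin.
#' Values outside the fitted range (possible when the spec was fitted on a
#' training split) are clipped to the first or last bin. Missing values stay
#' missing; attributes absent from the spec are untouched.
#'
#' @param x A [decision_table()].
#' @param spec A `binning_spec` from [fit_equal_interval()].
#' @return The binned `decision_table`.
#' @export
apply_binning <- function(x, spec) {
  stopifnot(inherits(spec, "binning_spec"))
  df <- as.data.frame(x, stringsAsFactors = FALSE)
  kinds <- attribute_kinds(x)
  domains <- attribute_domains(x)
  for (a in names(spec$cut_points)) {
    if (!a %in% names(df)) stop("spec attribute ", a, " not in table", call. = FALSE)
    cuts <- spec$cut_points[[a]]
    v <- df[[a]]
    code <- if (!length(cuts)) {
      ifelse(is.na(v), NA_integer_, 0L)
    } else {
      # right-closed: count of cut points strictly below v; clips automatically
      as.integer(rowSums(outer(v, cuts, FUN = ">")))
    }
    df[[a]] <- code
    kinds[[a]] <- "ordered"
    domains[[a]] <- 0:(length(cuts))
  }
  decision_table(df, decision = decision_attribute(x), kinds = kinds,
                 domains = domains, positive = positive_class(x))
}

#' Discretize a decision table in one step
#'
#' Convenience wrapper: [fit_equal_interval()] on all real attributes followed
#' by [apply_binning()].
#'
#' @inheritParams fit_equal_interval
#' @return A binned `decision_table`.
#' @export
discretize_table <- function(x, n_bins = 4L, attributes = real_attributes(x)) {
  if (!length(attributes)) return(x)
  apply_binning(x, fit_equal_interval(x, n_bins, attributes))
}
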