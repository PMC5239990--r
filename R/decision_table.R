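#' Construct a decision table
#'
#' A decision table is the basic container of the package: a tibble of labeled
#' instances whose columns are *condition attributes* plus one *decision
#' attribute* (the class). Each condition attribute carries a kind tag —
#' `"real"`, `"nominal"`, `"ordered"` or `"binary"` — and a value domain
#' (observed range for real attributes, level set otherwise). Missing values
#' are represented by `NA`; the decision column must be complete.
#'
#' @param data A data frame of instances (one row per object).
#' @param decision Name of the decision column (a string).
#' @param kinds Named character vector mapping condition-attribute names to one
#'   of `"real"`, `"nominal"`, `"ordered"`, `"binary"`. Attributes not named
#'   are inferred: numeric columns with more than 6 distinct values are
#'   `"real"`, two-valued columns `"binary"`, everything else `"nominal"`.
#' @param domains Optional named list of per-attribute domains (length-2
#'   numeric range for real attributes, a vector of levels otherwise). Missing
#'   entries are inferred from the observed non-missing values.
#' @param positive For a two-class decision, the label treated as the positive
#'   class when computing sensitivity/specificity. Defaults to the last level.
#'
#' @return A `decision_table`: a tibble with attributes `decision`, `kinds`,
#'   `domains` and `positive`.
#' @examples
#' dt <- decision_table(
#'   data.frame(a = c(0, 0, 1, 1), d = c("n", "n", "y", "y")),
#'   decision = "d"
#' )
#' condition_attributes(dt)
#' @export
decision_table <- function(data, decision, kinds = NULL, domains = NULL,
                           positive = NULL) {
  stopifnot(is.data.frame(data))
  data <- tibble::as_tibble(data)
  if (!is.character(decision) || length(decision) != 1L ||
      !decision %in% names(data)) {
    stop("`decision` must name a column of `data`", call. = FALSE)
  }
  if (nrow(data) < 1L) stop("decision table needs at least one object", call. = FALSE)
  if (anyDuplicated(names(data))) stop("attribute names must be unique", call. = FALSE)
  if (anyNA(data[[decision]])) {
    stop("decision attribute must have no missing values", call. = FALSE)
  }
  cond <- setdiff(names(data), decision)
  if (length(cond) < 1L) stop("at least one condition attribute is required", call. = FALSE)

  kinds <- infer_kinds(data, cond, kinds)
  domains <- infer_domains(data, cond, kinds, domains)
  check_domains(data, cond, kinds, domains)

  dlev <- sort(unique(as.character(data[[decision]])))
  if (is.null(positive)) positive <- dlev[length(dlev)]

  structure(
    data,
    class = c("decision_table", class(tibble::tibble()))
  ) |>
    set_dt_attrs(decision = decision, kinds = kinds, domains = domains,
                 positive = as.character(positive))
}

set_dt_attrs <- function(x, decision, kinds, domains, positive) {
  attr(x, "decision") <- decision
  attr(x, "kinds") <- kinds
  attr(x, "domains") <- domains
  attr(x, "positive") <- positive
  x
}

infer_kinds <- function(data, cond, kinds) {
  out <- character(length(cond))
  names(out) <- cond
  for (a in cond) {
    if (!is.null(kinds) && a %in% names(kinds)) {
      k <- kinds[[a]]
      if (!k %in% c("real", "nominal", "ordered", "binary")) {
        stop("unknown kind '", k, "' for attribute ", a, call. = FALSE)
      }
      out[[a]] <- k
    } else {
      v <- data[[a]][!is.na(data[[a]])]
      nu <- length(unique(v))
      out[[a]] <-
        if (is.numeric(v) && nu > 6L) "real"
        else if (nu == 2L) "binary"
        else "nominal"
    }
  }
  out
}

infer_domains <- function(data, cond, kinds, domains) {
  out <- vector("list", length(cond))
  names(out) <- cond
  for (a in cond) {
    if (!is.null(domains) && a %in% names(domains)) {
      out[[a]] <- domains[[a]]
    } else {
      v <- data[[a]][!is.na(data[[a]])]
      out[[a]] <- if (kinds[[a]] == "real") {
        if (length(v)) range(v) else c(NA_real_, NA_real_)
      } else {
        sort(unique(v))
      }
    }
  }
  out
}

check_domains <- function(data, cond, kinds, domains) {
  for (a in cond) {
    v <- data[[a]][!is.na(data[[a]])]
    if (!length(v)) next
    dom <- domains[[a]]
    ok <- if (kinds[[a]] == "real") {
      all(v >= dom[1] & v <= dom[2])
    } else {
      all(v %in% dom)
    }
    if (!ok) {
      stop("attribute ", a, " has values outside its declared domain", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Accessors for decision-table metadata
#'
#' @param x A `decision_table`.
#' @return `condition_attributes()` returns the condition-attribute names;
#'   `decision_attribute()` the decision column name; `attribute_kinds()` the
#'   named kind vector; `attribute_domains()` the named domain list;
#'   `positive_class()` the positive decision label.
#' @export
condition_attributes <- function(x) {
  setdiff(names(x), attr(x, "decision"))
}

#' @rdname condition_attributes
#' @export
decision_attribute <- function(x) attr(x, "decision")

#' @rdname condition_attributes
#' @export
attribute_kinds <- function(x) attr(x, "kinds")

#' @rdname condition_attributes
#' @export
attribute_domains <- function(x) attr(x, "domains")

#' @rdname condition_attributes
#' @export
positive_class <- function(x) attr(x, "positive")

#' @export
print.decision_table <- function(x, ...) {
  cat(sprintf(
    "# A decision table: %d objects, %d condition attributes, decision '%s'\n",
    nrow(x), length(condition_attributes(x)), decision_attribute(x)
  ))
  NextMethod()
}

# Rebuild a decision_table after row subsetting (metadata is row-independent).
dt_keep_rows <- function(x, idx) {
  out <- tibble::as_tibble(as.data.frame(x, stringsAsFactors = FALSE))[idx, , drop = FALSE]
  structure(out, class = c("decision_table", class(tibble::tibble()))) |>
    set_dt_attrs(attr(x, "decision"), attr(x, "kinds"), attr(x, "domains"),
                 attr(x, "positive"))
}

# Statlog (Heart) schema: 13 condition attributes C1..C13 plus a 1/2 class
# label. Kinds follow the published feature table; the vessel count C12 is
# treated as ordered-discrete (domain 0..3) rather than binned.
statlog_kinds <- c(
  C1 = "real", C2 = "binary", C3 = "nominal", C4 = "real", C5 = "real",
  C6 = "binary", C7 = "nominal", C8 = "real", C9 = "binary", C10 = "real",
  C11 = "ordered", C12 = "ordered", C13 = "nominal"
)

statlog_domains <- list(
  C1 = c(29, 77), C2 = c(0, 1), C3 = 1:4, C4 = c(94, 200), C5 = c(126, 564),
  C6 = c(0, 1), C7 = 0:2, C8 = c(71, 202), C9 = c(0, 1), C10 = c(0, 6.2),
  C11 = 1:3, C12 = 0:3, C13 = c(3, 6, 7)
)

#' Read a Statlog (Heart)-format flat file
#'
#' Reads the UCI Statlog (Heart) layout: 14 whitespace- or comma-separated
#' fields per row, the first 13 being the condition attributes `C1`..`C13`
#' and the last the class label (`1` = absence, `2` = presence of disease).
#' Attribute kinds follow the published schema (real: C1, C4, C5, C8, C10;
#' binary: C2, C6, C9; nominal: C3, C7, C13; ordered: C11, C12).
#'
#' @param path Path to the flat file.
#' @return A [decision_table()] with decision column `class` holding
#'   `"absence"`/`"presence"`; `"presence"` is the positive class.
#' @export
read_statlog <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("parse error: file '", path, "' is empty", call. = FALSE)
  rows <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(trimws(lines[[i]]), "[,[:space:]]+")[[1]]
    if (length(fields) != 14L) {
      stop("parse error at line ", i, ": expected 14 fields, found ",
           length(fields), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) {
      stop("parse error at line ", i, ": non-numeric field", call. = FALSE)
    }
    vals
  })
  m <- do.call(rbind, rows)
  colnames(m) <- c(paste0("C", 1:13), "class")
  df <- tibble::as_tibble(as.data.frame(m))
  if (!all(df$class %in% c(1, 2))) {
    bad <- which(!df$class %in% c(1, 2))[1]
    stop("validation error at line ", bad, ": unknown class label ",
         df$class[bad], call. = FALSE)
  }
  df$class <- c("absence", "presence")[df$class]
  decision_table(df, decision = "class", kinds = statlog_kinds,
                 domains = statlog_domains, positive = "presence")
}

#' Read a decision table from a generic CSV file
#'
#' @param path Path to a CSV file with a header row.
#' @param decision Name of the decision column.
#' @param kinds Optional named kind map, as in [decision_table()].
#' @param missing_token String encoding a missing value (default `"?"`).
#' @param positive Optional positive class label.
#' @return A [decision_table()]; cells equal to `missing_token` become `NA`.
#' @export
read_csv_table <- function(path, decision, kinds = NULL, missing_token = "?",
                           positive = NULL) {
  df <- readr::read_csv(path, na = c(missing_token, "NA", ""),
                        show_col_types = FALSE)
  if (!decision %in% names(df)) {
    stop("decision column '", decision, "' not found", call. = FALSE)
  }
  if (anyNA(df[[decision]])) {
    stop("validation error: decision column contains missing values", call. = FALSE)
  }
  decision_table(df, decision = decision, kinds = kinds, positive = positive)
}

#' Write a decision table to CSV (with a schema sidecar)
#'
#' Writes the values as plain CSV and, unless `schema = NULL`, a small JSON
#' sidecar recording the decision column, kinds, domains and positive class so
#' that [read_decision_table()] can reconstruct the table exactly.
#'
#' @param x A `decision_table`.
#' @param path Output CSV path.
#' @param schema Path for the JSON schema sidecar (default `<path>.schema.json`).
#' @param missing_token Token written for `NA` cells.
#' @return `x`, invisibly.
#' @export
write_decision_table <- function(x, path, schema = paste0(path, ".schema.json"),
                                 missing_token = "?") {
  df <- as.data.frame(x, stringsAsFactors = FALSE)
  out <- df
  out[] <- lapply(out, function(col) {
    col <- as.character(col)
    col[is.na(col)] <- missing_token
    col
  })
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  if (!is.null(schema)) {
    jsonlite::write_json(
      list(
        decision = decision_attribute(x),
        positive = positive_class(x),
        kinds = as.list(attribute_kinds(x)),
        domains = attribute_domains(x),
        missing_token = missing_token
      ),
      schema, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(x)
}

#' Read back a decision table written by [write_decision_table()]
#'
#' @param path CSV path.
#' @param schema Schema sidecar path.
#' @return A `decision_table` identical to the one written.
#' @export
read_decision_table <- function(path, schema = paste0(path, ".schema.json")) {
  sc <- jsonlite::read_json(schema, simplifyVector = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = sc$missing_token,
                        check.names = FALSE)
  kinds <- unlist(sc$kinds)
  # restore numeric typing for columns whose domain is numeric
  for (a in names(kinds)) {
    if (is.numeric(sc$domains[[a]]) && !is.numeric(df[[a]])) {
      df[[a]] <- as.numeric(df[[a]])
    }
  }
  decision_table(df, decision = sc$decision, kinds = kinds,
                 domains = sc$domains, positive = sc$positive)
}

#' Per-attribute summary of a decision table
#'
#' Mean and standard deviation (over non-missing values) for real attributes;
#' category counts for the rest.
#'
#' @param x A `decision_table`.
#' @return A tibble with one row per condition attribute: `attribute`, `kind`,
#'   `n_missing`, `mean`, `sd` (real attributes, `NA` otherwise) and `levels`
#'   (a `"value:count"` string for categorical attributes).
#' @export
summarize_attributes <- function(x) {
  cond <- condition_attributes(x)
  kinds <- attribute_kinds(x)
  purrr::map_dfr(cond, function(a) {
    v <- x[[a]]
    obs <- v[!is.na(v)]
    if (kinds[[a]] == "real") {
      tibble::tibble(
        attribute = a, kind = kinds[[a]], n_missing = sum(is.na(v)),
        mean = mean(obs),
        sd = if (length(obs) < 2L) 0 else stats::sd(obs),
        levels = NA_character_
      )
    } else {
      tab <- table(obs)
      tibble::tibble(
        attribute = a, kind = kinds[[a]], n_missing = sum(is.na(v)),
        mean = NA_real_, sd = NA_real_,
        levels = paste(sprintf("%s:%d", names(tab), as.integer(tab)),
                       collapse = ", ")
      )
    }
  })
}
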