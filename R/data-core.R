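#' Validate and coerce item-response data
#'
#' All analysis functions in mokkenscale accept a data frame (or matrix) of
#' integer item scores, one row per respondent and one column per item, with
#' `NA` marking a missing response. `as_item_matrix()` is the single
#' validation gate they all pass through: it checks column names are unique,
#' entries are non-negative integers, and (optionally) that the data are
#' complete and every item varies.
#'
#' Scores are shifted internally so that every item's minimum observed (or
#' declared) category is 0; the shift is recorded in the `"score_shift"`
#' attribute. Shifting leaves every statistic in the package unchanged
#' (covariances, restscores and conditional proportions depend on scores only
#' through differences and means), so inputs coded 1..m+1 are handled
#' transparently.
#'
#' @param data data frame or matrix of integer item scores.
#' @param complete require no missing entries (`TRUE` for every coefficient
#'   and diagnostic; listwise-delete first with [drop_incomplete()]).
#' @param min_items minimum number of item columns.
#' @param require_variance error if any item has a single observed category.
#' @return integer matrix with item labels as column names and attributes
#'   `n_categories` (per-item number of categories m+1, from the observed
#'   range after shifting) and `score_shift` (per-item amount subtracted).
#' @keywords internal
as_item_matrix <- function(data, complete = TRUE, min_items = 2L,
                           require_variance = FALSE) {
  if (is.data.frame(data)) {
    non_num <- !vapply(data, is.numeric, logical(1))
    if (any(non_num)) {
      abort(paste0("item columns must be numeric; not numeric: ",
                   paste(names(data)[non_num], collapse = ", ")))
    }
    x <- as.matrix(data)
  } else if (is.matrix(data)) {
    x <- data
    if (is.null(colnames(x))) colnames(x) <- paste0("item", seq_len(ncol(x)))
  } else {
    abort("`data` must be a data frame or matrix of item scores")
  }
  storage.mode(x) <- "double"
  if (ncol(x) < min_items) {
    abort(sprintf("need at least %d items, got %d", min_items, ncol(x)))
  }
  if (nrow(x) < 1L) abort("`data` has no respondents (0 rows)")
  if (anyDuplicated(colnames(x))) {
    abort(paste0("duplicate item labels: ",
                 paste(unique(colnames(x)[duplicated(colnames(x))]),
                       collapse = ", ")))
  }
  bad <- which(!is.na(x) & (x != round(x) | x < 0))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(x))
    abort(sprintf(
      "item scores must be non-negative integers; first offender: row %d, item '%s' (value %g)",
      rc[1L], colnames(x)[rc[2L]], x[bad[1L]]))
  }
  if (complete && anyNA(x)) {
    abort(sprintf(
      "%d missing entries present; apply drop_incomplete() (listwise deletion) first",
      sum(is.na(x))))
  }
  shift <- suppressWarnings(apply(x, 2L, function(col) min(col, na.rm = TRUE)))
  shift[!is.finite(shift)] <- 0
  x <- sweep(x, 2L, shift)
  ncat <- apply(x, 2L, function(col) {
    if (all(is.na(col))) 1L else as.integer(max(col, na.rm = TRUE)) + 1L
  })
  if (require_variance) {
    const <- vapply(seq_len(ncol(x)), function(j) {
      v <- x[!is.na(x[, j]), j]
      length(unique(v)) < 2L
    }, logical(1))
    if (any(const)) {
      abort(paste0("zero-variance item(s): ",
                   paste(colnames(x)[const], collapse = ", "),
                   " (maximum covariance is 0, scalability undefined)"))
    }
  }
  storage.mode(x) <- "integer"
  attr(x, "n_categories") <- ncat
  attr(x, "score_shift") <- shift
  x
}

#' Read item-response data from a delimited text file
#'
#' Reads a headered CSV/TSV of integer category scores (one column per item,
#' one row per respondent) into a tibble, mapping a configurable missing-value
#' token to `NA`. Parsing is strict: any non-integer, non-missing cell is an
#' error naming the offending row and column.
#'
#' @param path path to the delimited file.
#' @param missing_code token(s) representing a missing response
#'   (default `"NA"`).
#' @param delimiter field delimiter; `","` (default) or `"\t"`.
#' @return tibble of integer item scores with `NA` for missing entries.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("a,b,c", "0,1,1", "1,NA,0"), tf)
#' read_item_data(tf)
#' @export
read_item_data <- function(path, missing_code = "NA", delimiter = ",") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- read.table(path, header = TRUE, sep = delimiter,
                    colClasses = "character", check.names = FALSE,
                    na.strings = character(), strip.white = TRUE)
  if (ncol(raw) < 2L) {
    abort(sprintf("need at least 2 item columns, found %d in %s",
                  ncol(raw), path))
  }
  if (anyDuplicated(names(raw))) {
    abort(paste0("duplicate item labels in header: ",
                 paste(unique(names(raw)[duplicated(names(raw))]),
                       collapse = ", ")))
  }
  parsed <- lapply(names(raw), function(lbl) {
    cell <- raw[[lbl]]
    out <- rep(NA_integer_, length(cell))
    miss <- cell %in% missing_code | cell == ""
    num <- suppressWarnings(as.numeric(cell[!miss]))
    ok <- !is.na(num) & num == round(num)
    if (!all(ok)) {
      row <- which(!miss)[which(!ok)[1L]]
      abort(sprintf("cannot parse cell as integer at row %d, column '%s': '%s'",
                    row, lbl, cell[row]))
    }
    out[!miss] <- as.integer(num)
    out
  })
  names(parsed) <- names(raw)
  out <- tibble::as_tibble(parsed)
  inform(sprintf("read %d respondents x %d items from %s (%.1f%% missing)",
                 nrow(out), ncol(out), basename(path),
                 100 * mean(is.na(as.matrix(out)))))
  out
}

#' Write item-response data to a delimited text file
#'
#' Round-trip companion to [read_item_data()]: same dialect, same missing
#' token.
#'
#' @inheritParams read_item_data
#' @param data data frame of integer item scores.
#' @return `path`, invisibly.
#' @export
write_item_data <- function(data, path, missing_code = "NA", delimiter = ",") {
  x <- as_item_matrix(data, complete = FALSE, min_items = 1L)
  # undo the internal 0-base shift so the file shows the original coding
  x <- sweep(matrix(as.double(x), nrow(x), dimnames = dimnames(x)),
             2L, -attr(x, "score_shift"))
  out <- as.data.frame(x)
  write.table(out, path, sep = delimiter, na = missing_code[1L],
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Recode item scores
#'
#' Applies per-item (or shared) score mappings, e.g. the traditional binary
#' scoring of four-category GHQ responses, 1-2-3-4 -> 0-0-1-1. Missing entries
#' are left untouched. Every non-missing observed code must be covered by the
#' map; unmapped codes are an error listing the offenders.
#'
#' @param data data frame of integer item scores.
#' @param map either a single named mapping applied to every item, or a named
#'   list of such mappings keyed by item label (items absent from the list are
#'   left as-is). A mapping is a named numeric vector, names = observed codes,
#'   values = analysis scores, e.g. `c("1" = 0, "2" = 0, "3" = 1, "4" = 1)`.
#' @return tibble of recoded integer scores.
#' @examples
#' ghq <- c("1" = 0, "2" = 0, "3" = 1, "4" = 1)
#' recode_items(data.frame(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1)), ghq)
#' @export
recode_items <- function(data, map) {
  if (!is.data.frame(data)) data <- tibble::as_tibble(as.data.frame(data))
  per_item <- if (is.list(map)) map else stats::setNames(
    rep(list(map), ncol(data)), names(data))
  if (is.list(map)) {
    unknown <- setdiff(names(map), names(data))
    if (length(unknown)) {
      abort(paste0("recode map names items not in the data: ",
                   paste(unknown, collapse = ", ")))
    }
  }
  out <- data
  for (lbl in names(per_item)) {
    m <- per_item[[lbl]]
    if (is.null(names(m))) abort("each mapping must be a named vector (names = observed codes)")
    col <- data[[lbl]]
    obs <- unique(col[!is.na(col)])
    unmapped <- setdiff(as.character(obs), names(m))
    if (length(unmapped)) {
      abort(sprintf("item '%s' contains codes not covered by the map: %s",
                    lbl, paste(sort(unmapped), collapse = ", ")))
    }
    new <- col
    new[!is.na(col)] <- unname(m[as.character(col[!is.na(col)])])
    out[[lbl]] <- as.integer(new)
  }
  tibble::as_tibble(out)
}

#' Drop respondents with any missing response (listwise deletion)
#'
#' All coefficients and diagnostics in the package assume a complete
#' rectangle; this is the one supported missing-data treatment.
#'
#' @param data data frame of integer item scores with `NA` for missing.
#' @return tibble containing only complete rows.
#' @export
drop_incomplete <- function(data) {
  if (!is.data.frame(data)) data <- tibble::as_tibble(as.data.frame(data))
  keep <- stats::complete.cases(data)
  if (!any(keep)) abort("every respondent has at least one missing response; no data left")
  if (!all(keep)) {
    inform(sprintf("listwise deletion: dropped %d of %d respondents",
                   sum(!keep), length(keep)))
  }
  tibble::as_tibble(data[keep, , drop = FALSE])
}

#' Read a recode map from a YAML config file
#'
#' The file maps item labels to `from: to` pairs, e.g.
#' ```yaml
#' anxious: {1: 0, 2: 0, 3: 1, 4: 1}
#' ```
#' A top-level key `all` supplies a default mapping for every item.
#'
#' @param path YAML file path.
#' @return named list of named numeric vectors, suitable for [recode_items()]
#'   (or a single vector if only `all` is given).
#' @export
read_recode_map <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("reading YAML recode maps requires the 'yaml' package")
  }
  raw <- yaml::read_yaml(path)
  as_map <- function(x) {
    v <- vapply(x, as.numeric, numeric(1))
    stats::setNames(v, names(x))
  }
  if (identical(names(raw), "all")) return(as_map(raw$all))
  lapply(raw, as_map)
}
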