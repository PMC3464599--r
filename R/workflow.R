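#' Run the full Mokken scale analysis workflow
#'
#' Composes the analysis steps in the standard order on one item set:
#' Step 1, dimensionality — scalability coefficients ([coef_h()]) and,
#' optionally, automated scale search ([aisp()]); Step 2, manifest
#' monotonicity ([check_monotonicity()]); Step 3, invariant item ordering
#' ([check_iio()], with backward removal via [backward_select_iio()] when
#' `backward = TRUE`); and finally total-score reliability ([ms_rho()],
#' which also reports Cronbach's alpha). Each step is the exported function
#' itself, so running the steps individually with the same settings
#' reproduces the bundle's numbers exactly.
#'
#' @inheritParams coef_h
#' @param lowerbound aisp lower bound on H_i (used when `run_aisp = TRUE`).
#' @param run_aisp also partition the pool with [aisp()] (Step 1b).
#' @param minvi_monotonicity,minvi_iio minimum violation sizes for Steps 2
#'   and 3 (per item step).
#' @param minsize minimum restscore-group size; `NULL` = [default_minsize()].
#' @param alpha significance level used throughout.
#' @param backward run backward item removal in Step 3.
#' @return object of class `"mokken_workflow"`: list with `scalability`,
#'   `partition` (or `NULL`), `monotonicity`, `iio`, `reliability`,
#'   `settings`. `glance()` returns the one-row headline summary.
#' @examples
#' bank <- logistic_items(locations = seq(-1.5, 1.5, length.out = 6),
#'                        discriminations = 1.8)
#' d <- sim_responses(bank, n = 800, seed = 11)
#' wf <- run_scale_analysis(d)
#' glance(wf)
#' @export
run_scale_analysis <- function(data, lowerbound = 0.3, run_aisp = FALSE,
                               minvi_monotonicity = 0.03, minvi_iio = 0.03,
                               minsize = NULL, alpha = 0.05,
                               backward = TRUE) {
  x <- as_item_matrix(data, complete = TRUE, min_items = 3L,
                      require_variance = TRUE)
  if (is.null(minsize)) minsize <- default_minsize(nrow(x))
  step_or_abort <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("[", label, "] ", conditionMessage(e)))
    })
  }
  scal <- step_or_abort("step 1: scalability", coef_h(data))
  part <- if (run_aisp) {
    step_or_abort("step 1b: aisp",
                  aisp(data, lowerbound = lowerbound, alpha = alpha))
  }
  mono <- step_or_abort(
    "step 2: monotonicity",
    check_monotonicity(data, minvi = minvi_monotonicity, minsize = minsize,
                       alpha = alpha))
  iio <- step_or_abort(
    "step 3: IIO",
    if (backward) {
      backward_select_iio(data, minvi = minvi_iio, minsize = minsize,
                          alpha = alpha)
    } else {
      check_iio(data, minvi = minvi_iio, minsize = minsize, alpha = alpha)
    })
  rel <- step_or_abort("reliability", ms_rho(data))
  out <- list(scalability = scal, partition = part, monotonicity = mono,
              iio = iio, reliability = rel,
              settings = list(lowerbound = lowerbound, minsize = minsize,
                              minvi_monotonicity = minvi_monotonicity,
                              minvi_iio = minvi_iio, alpha = alpha,
                              backward = backward, n = nrow(x),
                              k = ncol(x)))
  class(out) <- "mokken_workflow"
  out
}

#' @export
print.mokken_workflow <- function(x, ...) {
  s <- x$settings
  cat(sprintf("Mokken scale analysis workflow (N = %d, k = %d, minsize = %d, alpha = %.2f)\n",
              s$n, s$k, s$minsize, s$alpha))
  cat("\n== Step 1: scalability ==\n"); print(x$scalability)
  if (!is.null(x$partition)) {
    cat("\n== Step 1b: automated item selection ==\n"); print(x$partition)
  }
  cat("\n== Step 2: monotonicity ==\n"); print(x$monotonicity)
  cat("\n== Step 3: invariant item ordering ==\n"); print(x$iio)
  cat("\n== Reliability ==\n"); print(x$reliability)
  invisible(x)
}

#' @rdname run_scale_analysis
#' @param x a `"mokken_workflow"` object.
#' @param ... unused.
#' @export
glance.mokken_workflow <- function(x, ...) {
  tibble::tibble(
    h = x$scalability$h,
    h_class = as.character(x$scalability$classification),
    mono_zsig = sum(x$monotonicity$items$zsig),
    iio_tsig = sum(x$iio$items$tsig),
    iio_removed = length(x$iio$removed %||% character()),
    ht = as.numeric(x$iio$ht_final %||% x$iio$ht),
    rho_ms = x$reliability$rho_ms,
    cronbach_alpha = x$reliability$cronbach_alpha,
    n = x$settings$n, n_items = x$settings$k)
}

#' Render a result as fixed-width text or TSV
#'
#' One rendering gate for every report type: `style = "text"` prints the
#' object's formatted table (what `print()` shows), `style = "tsv"` emits
#' the tidy table as tab-separated values. Counts that other software shows
#' as blanks are always printed as zeros.
#'
#' @param result a result object from this package (`scalability_h`,
#'   `scale_partition`, `monotonicity_report`, `iio_report`,
#'   `reliability_result`, `mokken_workflow`).
#' @param style `"text"` or `"tsv"`.
#' @return character vector of lines, invisibly printable.
#' @export
render_table <- function(result, style = c("text", "tsv")) {
  style <- match.arg(style)
  if (style == "text") {
    return(utils::capture.output(print(result)))
  }
  tb <- if (inherits(result, "reliability_result") ||
            inherits(result, "mokken_workflow")) {
    glance(result)
  } else {
    tidy(result)
  }
  c(paste(names(tb), collapse = "\t"),
    apply(tb, 1L, function(r) paste(trimws(unname(r)), collapse = "\t")))
}
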