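#' Automated item selection into Mokken scales (aisp)
#'
#' Partitions an item pool into unidimensional Mokken scales with the
#' classical bottom-up search. A scale is seeded with the best available item
#' pair — largest H_ij among pairs that are significantly positive (per
#' [test_hij_positive()]) and reach the lower bound `c` — and then grown
#' greedily: at each step the admissible unselected item that maximises the
#' scale's H is added, where admissible means (a) H_ij significantly positive
#' with every selected item and (b) after the tentative addition every
#' member's within-scale H_i is still >= `c`. When no item qualifies, the
#' scale is closed and a new one is seeded from the remaining pool; items
#' never placed are reported as unscalable (scale 0).
#'
#' Condition (b) is deliberately checked for *all* members (not only the
#' candidate) so every reported scale is guaranteed to pass a post-hoc
#' [coef_h()] check at the chosen bound.
#'
#' Ties on scale H are broken by the larger total maximum covariance with the
#' already-selected items, then by pool order, making the search
#' deterministic.
#'
#' @inheritParams coef_h
#' @param lowerbound lower bound `c` on within-scale item H_i (default 0.3,
#'   the conventional unidimensionality threshold); `0 <= c < 1`.
#' @param alpha per-comparison significance level for the positivity screen.
#' @param strategy search strategy; only `"normal"` (the bottom-up search
#'   above) is implemented. Other tokens are accepted with a warning and fall
#'   back to `"normal"`.
#' @return object of class `"scale_partition"`: list with `assignment`
#'   (tibble: item, scale id — 0 = unscalable — and within-scale H_i),
#'   `scales` (list of `"scalability_h"` objects, one per scale),
#'   `lowerbound`, `alpha`.
#' @examples
#' set.seed(7)
#' bank <- logistic_items(locations = c(-1, 0, 1, -1, 0, 1),
#'                        discriminations = 2)
#' d <- sim_responses(bank, n = 500, seed = 7)
#' aisp(d, lowerbound = 0.3)
#' @export
aisp <- function(data, lowerbound = 0.3, alpha = 0.05, strategy = "normal") {
  stopifnot(lowerbound >= 0, lowerbound < 1, alpha > 0, alpha < 1)
  if (!identical(strategy, "normal")) {
    warn(sprintf("strategy '%s' is not implemented; using 'normal'", strategy))
  }
  x <- as_item_matrix(data, complete = TRUE)
  k <- ncol(x)
  n <- nrow(x)
  cv <- crossprod(x) / n - tcrossprod(colMeans(x))
  cm <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      cm[i, j] <- cm[j, i] <- covmax_counts(tabulate0(x[, i]), tabulate0(x[, j]))
    }
  }
  hij <- ifelse(cm > 0, cv / cm, NA_real_)
  sig <- h_pair_tests(x)$p < alpha
  sig[is.na(sig)] <- FALSE

  pool <- seq_len(k)
  assignment <- integer(k)
  scale_id <- 0L

  repeat {
    # admissible seed pairs: significantly positive and H_ij >= lower bound
    best <- NULL
    for (i in pool) for (j in pool) {
      if (j <= i || !sig[i, j]) next
      if (is.na(hij[i, j]) || hij[i, j] < max(lowerbound, 1e-12)) next
      if (is.null(best) || hij[i, j] > hij[best[1L], best[2L]]) best <- c(i, j)
    }
    if (is.null(best)) break
    scale_id <- scale_id + 1L
    members <- best
    pool <- setdiff(pool, members)
    repeat {
      cand <- pool[vapply(pool, function(c_) all(sig[c_, members]), logical(1))]
      if (!length(cand)) break
      stats_c <- lapply(cand, function(c_) {
        sub <- h_from_matrix(x[, c(members, c_), drop = FALSE])
        list(ok = all(sub$hi >= lowerbound - 1e-12), h = sub$h,
             tie = sum(cm[c_, members]))
      })
      ok <- vapply(stats_c, `[[`, logical(1), "ok")
      if (!any(ok)) break
      hs <- vapply(stats_c, `[[`, numeric(1), "h")
      ties <- vapply(stats_c, `[[`, numeric(1), "tie")
      hs[!ok] <- -Inf
      pick <- which(hs >= max(hs) - 1e-12)
      if (length(pick) > 1L) pick <- pick[order(-ties[pick], cand[pick])]
      chosen <- cand[pick[1L]]
      members <- c(members, chosen)
      pool <- setdiff(pool, chosen)
    }
    assignment[members] <- scale_id
  }

  scales <- lapply(seq_len(scale_id), function(s) {
    coef_h(tibble::as_tibble(as.data.frame(x[, assignment == s, drop = FALSE])))
  })
  hi_within <- rep(NA_real_, k)
  for (s in seq_len(scale_id)) hi_within[assignment == s] <- scales[[s]]$hi
  out <- list(
    assignment = tibble::tibble(item = colnames(x), scale = assignment,
                                hi_within = hi_within),
    scales = scales, lowerbound = lowerbound, alpha = alpha, n = n)
  class(out) <- "scale_partition"
  out
}

#' Sweep the aisp lower bound over a grid of cutoffs
#'
#' Runs [aisp()] at each cutoff (ascending) to show how an item pool
#' fragments as the homogeneity demand rises — the recommended exploration
#' strategy of starting at c = 0.3 and raising it in steps of 0.05.
#'
#' @inheritParams aisp
#' @param cutoffs ascending numeric vector of lower bounds.
#' @return tibble with one row per item x cutoff: `lowerbound`, `item`,
#'   `scale` (0 = unscalable), `hi_within`; the per-cutoff
#'   `"scale_partition"` objects are attached as attribute `"partitions"`.
#' @export
cutoff_sweep <- function(data, cutoffs = seq(0.3, 0.55, by = 0.05),
                         alpha = 0.05) {
  if (!length(cutoffs)) {
    return(tibble::tibble(lowerbound = numeric(), item = character(),
                          scale = integer(), hi_within = numeric()))
  }
  if (is.unsorted(cutoffs)) abort("`cutoffs` must be ascending")
  parts <- lapply(cutoffs, function(c_) aisp(data, lowerbound = c_, alpha = alpha))
  out <- purrr::map2_dfr(parts, cutoffs, function(p, c_) {
    dplyr::mutate(p$assignment, lowerbound = c_, .before = 1L)
  })
  attr(out, "partitions") <- stats::setNames(parts, format(cutoffs))
  out
}

#' @export
print.scale_partition <- function(x, digits = 2, ...) {
  ns <- length(x$scales)
  cat(sprintf("aisp partition (lower bound %.2f, alpha %.2f, N = %d): %d scale(s), %d unscalable item(s)\n",
              x$lowerbound, x$alpha, x$n, ns, sum(x$assignment$scale == 0L)))
  for (s in seq_len(ns)) {
    cat(sprintf("\nScale %d:\n", s))
    df <- as.data.frame(x$scales[[s]]$items)
    df$mean <- round(df$mean, digits); df$hi <- round(df$hi, digits)
    names(df) <- c("Label", "Mean", "ItemH")
    print(df, row.names = FALSE)
    cat(sprintf("Scale H = %.*f\n", digits, x$scales[[s]]$h))
  }
  un <- x$assignment$item[x$assignment$scale == 0L]
  if (length(un)) cat("\nUnscalable:", paste(un, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname aisp
#' @param x,object a `"scale_partition"` object.
#' @param ... unused.
#' @export
tidy.scale_partition <- function(x, ...) x$assignment

#' @rdname aisp
#' @export
glance.scale_partition <- function(x, ...) {
  tibble::tibble(
    n_scales = length(x$scales),
    n_unscalable = sum(x$assignment$scale == 0L),
    largest_scale = if (length(x$scales)) max(table(x$assignment$scale[x$assignment$scale > 0L])) else 0L,
    lowerbound = x$lowerbound, alpha = x$alpha, n = x$n)
}

#' @rdname aisp
#' @export
autoplot.scale_partition <- function(object, ...) {
  df <- object$assignment
  df$item <- factor(df$item, levels = df$item)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$item, y = .data$hi_within,
                                   fill = factor(.data$scale))) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = object$lowerbound, linetype = 2) +
    ggplot2::labs(x = NULL, y = "within-scale H_i", fill = "scale",
                  title = sprintf("aisp at lower bound %.2f", object$lowerbound)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
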