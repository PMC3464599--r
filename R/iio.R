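#' Check invariant item ordering (manifest IIO, MIIO)
#'
#' Under invariant item ordering the items keep one difficulty order at
#' every level of the latent trait. The manifest check orders items by
#' overall mean and, for each item pair, compares the two conditional item
#' means within restscore groups (restscore = total over all *other* items,
#' excluding both members of the pair; groups built with the usual minsize
#' merging). If the overall order says item `a` is harder than item `b`
#' (lower mean), then within every group the conditional mean of `a` should
#' not exceed that of `b`: a reversal of at least `minvi * m` (with `m` the
#' number of item steps, so `minvi` is a per-step threshold; for binary
#' items just `minvi`) counts as a violation for both items, and every
#' violation is tested with a one-sided paired t-test on the within-group
#' score differences. Pairs with tied overall means have no expected order
#' and are skipped entirely (coincident response functions are permitted
#' under the model).
#'
#' @inheritParams check_monotonicity
#' @param method only `"MIIO"` is implemented.
#' @param minvi minimum reversal per item step counted as a violation
#'   (default 0.03).
#' @param compute_ht also compute H^T of the item set (set `FALSE` to skip
#'   the one moderately expensive step when only violation counts are
#'   needed, as the backward-removal iterations do).
#' @return object of class `"iio_report"`: `items` (tibble: item, mean, hi,
#'   ac, vi, tsig), `pairs` (per group-level comparison detail), `ht`
#'   (H^T of the item set, with classification attribute), `settings`.
#' @examples
#' bank <- logistic_items(locations = seq(-1.5, 1.5, length.out = 6),
#'                        discriminations = 1.5)
#' d <- sim_responses(bank, n = 1000, seed = 3)
#' check_iio(d)
#' @export
check_iio <- function(data, method = "MIIO", minvi = 0.03, minsize = NULL,
                      alpha = 0.05, compute_ht = TRUE) {
  if (!identical(toupper(method), "MIIO")) {
    abort(sprintf("method '%s' is not implemented; use method = \"MIIO\"", method))
  }
  x <- as_item_matrix(data, complete = TRUE, min_items = 3L,
                      require_variance = TRUE)
  n <- nrow(x)
  k <- ncol(x)
  if (is.null(minsize)) minsize <- default_minsize(n)
  stopifnot(minvi >= 0, alpha > 0, alpha < 1)
  hi <- h_from_matrix(x)$hi
  means <- colMeans(x)
  total <- rowSums(x)
  ac <- vi <- tsig <- stats::setNames(integer(k), colnames(x))
  pair_rows <- list()
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      if (means[i] == means[j]) next  # no expected order: pair skipped
      a <- if (means[i] < means[j]) i else j  # harder item (lower mean)
      b <- if (means[i] < means[j]) j else i
      m_steps <- max(attr(x, "n_categories")[c(i, j)]) - 1L
      thr <- minvi * m_steps
      rest <- total - x[, i] - x[, j]
      grp <- restscore_groups(rest, minsize)
      r_ <- nrow(grp$summary)
      if (r_ < 1L) abort("restscore grouping failed")
      for (g in seq_len(r_)) {
        sel <- grp$group == g
        d <- x[sel, a] - x[sel, b]
        diff_g <- mean(d)
        ac[a] <- ac[a] + 1L; ac[b] <- ac[b] + 1L
        violated <- diff_g > 0 & diff_g >= thr
        t_stat <- NA_real_
        significant <- FALSE
        if (violated) {
          vi[a] <- vi[a] + 1L; vi[b] <- vi[b] + 1L
          sd_d <- stats::sd(d)
          if (is.na(sd_d) || sd_d == 0) {
            significant <- TRUE          # deterministic reversal
            t_stat <- Inf
          } else {
            t_stat <- diff_g / (sd_d / sqrt(length(d)))
            significant <- pt(t_stat, df = length(d) - 1L,
                              lower.tail = FALSE) < alpha
          }
          if (significant) { tsig[a] <- tsig[a] + 1L; tsig[b] <- tsig[b] + 1L }
        }
        pair_rows[[length(pair_rows) + 1L]] <- tibble::tibble(
          item_hard = colnames(x)[a], item_easy = colnames(x)[b],
          group = g, n = sum(sel),
          mean_hard = mean(x[sel, a]), mean_easy = mean(x[sel, b]),
          reversal = diff_g, violation = violated, t = t_stat,
          significant = significant)
      }
    }
  }
  items <- tibble::tibble(item = colnames(x),
                          mean = means + attr(x, "score_shift"),
                          hi = unname(hi), ac = unname(ac), vi = unname(vi),
                          tsig = unname(tsig))
  out <- list(items = items, pairs = dplyr::bind_rows(pair_rows),
              ht = if (compute_ht) coef_ht(as.data.frame(x)),
              settings = list(method = "MIIO", minvi = minvi,
                              minsize = minsize, alpha = alpha, n = n))
  class(out) <- "iio_report"
  out
}

#' Non-intersection check for dichotomous items
#'
#' For binary items non-intersection of the item characteristic curves is
#' exactly what guarantees an invariant item ordering, and the manifest
#' check is the MIIO computation specialised to 0/1 scores (restscore-group
#' comparison of endorsement proportions). Provided as its own entry point
#' so the dichotomous workflow reads as in the methodology; non-binary input
#' is an error directing to [check_iio()].
#'
#' @inheritParams check_iio
#' @return an `"iio_report"`, as [check_iio()].
#' @export
check_nonintersection <- function(data, minvi = 0.03, minsize = NULL,
                                  alpha = 0.05) {
  x <- as_item_matrix(data, complete = TRUE, min_items = 3L)
  if (any(attr(x, "n_categories") > 2L)) {
    abort("check_nonintersection() is for dichotomous items only; use check_iio(method = \"MIIO\") for polytomous data")
  }
  check_iio(data, method = "MIIO", minvi = minvi, minsize = minsize,
            alpha = alpha)
}

#' Backward item removal until invariant item ordering holds
#'
#' Repeatedly runs the MIIO check and removes the single item with the most
#' significant violations; on ties the item with the lowest scalability
#' H_i (within the current item set) is removed. Iteration stops when no
#' significant violations remain, or with a warning when fewer than three
#' items would be left. The trace mirrors the conventional report: one
#' column per step holding each item's significant-violation count, `NA`
#' once the item has been removed.
#'
#' @inheritParams check_iio
#' @return an `"iio_report"` for the *final* item set, with extra elements
#'   `removal` (tibble: item, step_1, step_2, ... significant-violation
#'   counts, `NA` = removed), `removed` (labels in removal order) and
#'   `ht_final` (H^T of the surviving set, classification attached).
#' @export
backward_select_iio <- function(data, minvi = 0.03, minsize = NULL,
                                alpha = 0.05) {
  if (!is.data.frame(data)) data <- tibble::as_tibble(as.data.frame(data))
  all_items <- names(data)
  keep <- all_items
  removed <- character()
  trace <- list()
  rep_now <- NULL
  repeat {
    rep_now <- check_iio(data[keep], minvi = minvi, minsize = minsize,
                         alpha = alpha, compute_ht = FALSE)
    step_col <- stats::setNames(rep(NA_integer_, length(all_items)), all_items)
    step_col[rep_now$items$item] <- rep_now$items$tsig
    trace[[length(trace) + 1L]] <- step_col
    if (max(rep_now$items$tsig) == 0L) break
    if (length(keep) <= 3L) {
      warn("significant IIO violations remain but only 3 items are left; stopping removal")
      break
    }
    worst <- rep_now$items[rep_now$items$tsig == max(rep_now$items$tsig), ]
    drop_item <- worst$item[which.min(worst$hi)]  # tie -> lowest scalability
    removed <- c(removed, drop_item)
    keep <- setdiff(keep, drop_item)
  }
  trace_tbl <- tibble::tibble(item = all_items)
  for (s in seq_along(trace)) trace_tbl[[paste0("step_", s)]] <- unname(trace[[s]])
  rep_now$removal <- trace_tbl
  rep_now$removed <- removed
  rep_now$ht <- rep_now$ht_final <- coef_ht(data[keep])
  rep_now
}

#' @export
print.iio_report <- function(x, digits = 2, ...) {
  s <- x$settings
  cat(sprintf("IIO check, method %s (N = %d, minsize = %d, minvi = %.2f, alpha = %.2f)\n\n",
              s$method, s$n, s$minsize, s$minvi, s$alpha))
  df <- as.data.frame(x$items[, c("item", "mean", "ac", "vi", "tsig")])
  df$mean <- round(df$mean, digits)
  names(df) <- c("Label", "Mean", "#ac", "#vi", "#tsig")
  print(df, row.names = FALSE)
  if (!is.null(x$ht)) {
    cat(sprintf("\nH^T = %.2f (%s)\n", as.numeric(x$ht),
                as.character(attr(x$ht, "classification"))))
  }
  if (!is.null(x$removal)) {
    cat("\nBackward removal trace (significant violations; NA = removed):\n")
    print(as.data.frame(x$removal), row.names = FALSE)
    if (length(x$removed)) {
      cat("Removed:", paste(x$removed, collapse = ", "), "\n")
    } else {
      cat("No items removed.\n")
    }
    cat(sprintf("H^T of final item set = %.2f (%s)\n", as.numeric(x$ht_final),
                as.character(attr(x$ht_final, "classification"))))
  }
  invisible(x)
}

#' @rdname check_iio
#' @param x,object an `"iio_report"` object.
#' @param ... unused.
#' @export
tidy.iio_report <- function(x, ...) x$items

#' @rdname check_iio
#' @export
glance.iio_report <- function(x, ...) {
  ht <- if (is.null(x$ht)) NA_real_ else as.numeric(x$ht)
  tibble::tibble(n_items = nrow(x$items), total_ac = sum(x$items$ac),
                 total_vi = sum(x$items$vi), total_tsig = sum(x$items$tsig),
                 ht = ht,
                 n_removed = length(x$removed %||% character()),
                 ht_final = if (is.null(x$ht_final)) ht else as.numeric(x$ht_final))
}

#' @rdname check_iio
#' @export
autoplot.iio_report <- function(object, ...) {
  df <- object$items
  df$item <- factor(df$item, levels = df$item[order(df$mean)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$item)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$vi), fill = "grey75") +
    ggplot2::geom_col(ggplot2::aes(y = .data$tsig), fill = "firebrick") +
    ggplot2::labs(x = "item (ordered by overall mean)",
                  y = "#violations (grey) and #significant (red)",
                  title = if (is.null(object$ht)) "MIIO violations" else
                    sprintf("MIIO violations; H^T = %.2f",
                            as.numeric(object$ht))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
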