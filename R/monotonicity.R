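#' Default minimum restscore-group size
#'
#' The conventional sample-size-dependent default: `N/10` when N > 500,
#' `N/5` when 250 < N <= 500, and `N/3` but at least 50 when N <= 250
#' (all truncated to integers). Small groups give unstable proportion
#' estimates; too large a minimum leaves too few groups to assess
#' monotonicity at all.
#'
#' @param n sample size (N >= 1).
#' @return integer minimum group size.
#' @examples
#' default_minsize(773) # 77
#' default_minsize(300) # 60
#' default_minsize(100) # 50
#' @export
default_minsize <- function(n) {
  stopifnot(length(n) == 1L, n >= 1)
  if (n > 500) as.integer(n %/% 10)
  else if (n > 250) as.integer(n %/% 5)
  else max(as.integer(n %/% 3), 50L)
}

#' Group respondents by restscore
#'
#' Buckets a vector of restscores (total score over all items except the
#' focal item, or except a focal pair) into ordered groups of at least
#' `minsize` respondents: walking from the lowest restscore upwards,
#' adjacent score values are joined until the group reaches `minsize`; an
#' undersized final group is merged into its left neighbour.
#'
#' @param rest integer vector of restscores.
#' @param minsize minimum group size (>= 1).
#' @return list with `group` (per-respondent group index, 1 = lowest
#'   restscores) and `summary` (tibble: group, lo, hi, n).
#' @export
restscore_groups <- function(rest, minsize) {
  stopifnot(minsize >= 1)
  tab <- table(rest)
  vals <- as.integer(names(tab))
  cnt <- as.integer(tab)
  grp_of_val <- integer(length(vals))
  g <- 1L
  acc <- 0L
  for (i in seq_along(vals)) {
    grp_of_val[i] <- g
    acc <- acc + cnt[i]
    if (acc >= minsize && i < length(vals)) {
      g <- g + 1L
      acc <- 0L
    }
  }
  if (acc < minsize && acc > 0L && g > 1L) {
    # undersized last group: merge into its left neighbour
    grp_of_val[grp_of_val == g] <- g - 1L
  }
  group <- grp_of_val[match(rest, vals)]
  gid <- sort(unique(grp_of_val))
  summary <- tibble::tibble(
    group = seq_along(gid),
    lo = vapply(gid, function(g) min(vals[grp_of_val == g]), integer(1)),
    hi = vapply(gid, function(g) max(vals[grp_of_val == g]), integer(1)),
    n = vapply(gid, function(g) sum(cnt[grp_of_val == g]), integer(1)))
  list(group = match(group, gid), summary = summary)
}

#' Compare ordered-group endorsement proportions for monotonicity
#'
#' The elementary comparison behind [check_monotonicity()], exposed for
#' audit: given per-group endorsement proportions of one item step (groups
#' ordered by increasing restscore) and group sizes, every ordered pair
#' `r < s` is an active comparison; a decrease `p_r - p_s >= minvi` (and
#' `> 0`) is a violation, and each violation is tested with a one-sided
#' pooled two-proportion z-test.
#'
#' @param props endorsement proportion per group, lowest restscore first.
#' @param ns group sizes.
#' @param minvi minimum decrease counted as a violation (default 0.03).
#' @param alpha significance level for the z-test.
#' @return tibble with one row per active comparison: `group_lo`, `group_hi`,
#'   `p_lo`, `p_hi`, `decrease`, `violation`, `z`, `significant`.
#' @export
compare_group_proportions <- function(props, ns, minvi = 0.03, alpha = 0.05) {
  stopifnot(length(props) == length(ns), minvi >= 0)
  r_ <- length(props)
  if (r_ < 2L) {
    return(tibble::tibble(group_lo = integer(), group_hi = integer(),
                          p_lo = numeric(), p_hi = numeric(),
                          decrease = numeric(), violation = logical(),
                          z = numeric(), significant = logical()))
  }
  idx <- which(upper.tri(diag(r_)), arr.ind = TRUE)
  lo <- idx[, 1L]; hi <- idx[, 2L]
  dec <- props[lo] - props[hi]
  viol <- dec > 0 & dec >= minvi
  z <- rep(NA_real_, length(dec))
  if (any(viol)) {
    pp <- (props[lo] * ns[lo] + props[hi] * ns[hi]) / (ns[lo] + ns[hi])
    se <- sqrt(pp * (1 - pp) * (1 / ns[lo] + 1 / ns[hi]))
    z[viol] <- dec[viol] / se[viol]
  }
  tibble::tibble(group_lo = lo, group_hi = hi,
                 p_lo = props[lo], p_hi = props[hi], decrease = dec,
                 violation = viol, z = z,
                 significant = !is.na(z) & pnorm(z, lower.tail = FALSE) < alpha)
}

#' Check manifest monotonicity of item (step) response functions
#'
#' For each item, respondents are grouped by restscore (sum score over the
#' other items) and, for every item step `s` (the event of scoring `>= s`;
#' a dichotomous item has one step), the endorsement proportions across
#' ordered restscore groups are compared pairwise. Under monotone item
#' response functions the proportions should be non-decreasing; a decrease
#' of at least `minvi` is counted as a violation (#vi), each violation is
#' z-tested (#zsig counts the significant ones), and #ac counts all active
#' comparisons: `R(R-1)/2` per step for `R` groups.
#'
#' The `crit` column is a composite severity score in the tradition of MSP
#' software, computed only when #vi > 0:
#' `50(0.3 - Hi) + sqrt(vi) + 100 vi/ac + 100 maxvi + 10 sqrt(sumvi) +
#'  1000 sumvi/ac + 5 zmax + 10 sqrt(zsum) + 100 zsum/ac`.
#' Its exact form is not canonical; values below 40 are conventionally read
#' as "no serious violation", and all components are returned so any other
#' rule can be applied.
#'
#' @inheritParams coef_h
#' @param minvi minimum decrease of an item step response function counted
#'   as a violation (default 0.03).
#' @param minsize minimum restscore-group size; `NULL` (default) applies
#'   [default_minsize()] to the sample size.
#' @param alpha significance level for the per-violation z-tests.
#' @return object of class `"monotonicity_report"`: list with `items`
#'   (tibble: item, hi, ac, vi, zsig, maxvi, sumvi, zmax, zsum, crit),
#'   `comparisons` (per-comparison detail), `plotdata` (tibble: item, step,
#'   group, lo, hi, n, prop — enough to redraw the monotonicity plots),
#'   `settings`. `tidy()` returns the item table, `autoplot()` the
#'   item-step curves against restscore group.
#' @examples
#' bank <- logistic_items(locations = seq(-1.5, 1.5, length.out = 6),
#'                        discriminations = 1.5)
#' d <- sim_responses(bank, n = 1000, seed = 42)
#' check_monotonicity(d)
#' @export
check_monotonicity <- function(data, minvi = 0.03, minsize = NULL,
                               alpha = 0.05) {
  x <- as_item_matrix(data, complete = TRUE, min_items = 3L,
                      require_variance = TRUE)
  n <- nrow(x)
  k <- ncol(x)
  if (is.null(minsize)) minsize <- default_minsize(n)
  hi <- h_from_matrix(x)$hi
  total <- rowSums(x)
  items <- vector("list", k)
  comps <- vector("list", k)
  plotdata <- vector("list", k)
  for (i in seq_len(k)) {
    rest <- total - x[, i]
    grp <- restscore_groups(rest, minsize)
    r_ <- nrow(grp$summary)
    if (r_ < 2L) {
      abort(sprintf(
        "item '%s': only %d restscore group(s) of size >= %d can be formed; monotonicity cannot be assessed (reduce minsize)",
        colnames(x)[i], r_, minsize))
    }
    m_i <- attr(x, "n_categories")[i] - 1L
    ns <- grp$summary$n
    step_rows <- vector("list", m_i)
    pd <- vector("list", m_i)
    for (s in seq_len(m_i)) {
      props <- vapply(seq_len(r_),
                      function(g) mean(x[grp$group == g, i] >= s), numeric(1))
      cmp <- compare_group_proportions(props, ns, minvi = minvi, alpha = alpha)
      cmp$step <- s
      step_rows[[s]] <- cmp
      pd[[s]] <- tibble::tibble(step = s, group = seq_len(r_),
                                lo = grp$summary$lo, hi = grp$summary$hi,
                                n = ns, prop = props)
    }
    cmp_i <- dplyr::bind_rows(step_rows)
    cmp_i$item <- colnames(x)[i]
    comps[[i]] <- cmp_i
    pd_i <- dplyr::bind_rows(pd)
    pd_i$item <- colnames(x)[i]
    plotdata[[i]] <- pd_i
    vi_rows <- cmp_i[cmp_i$violation, , drop = FALSE]
    items[[i]] <- tibble::tibble(
      item = colnames(x)[i], hi = unname(hi[i]),
      ac = nrow(cmp_i), vi = nrow(vi_rows),
      zsig = sum(vi_rows$significant),
      maxvi = if (nrow(vi_rows)) max(vi_rows$decrease) else 0,
      sumvi = sum(vi_rows$decrease),
      zmax = if (nrow(vi_rows)) max(vi_rows$z) else 0,
      zsum = sum(vi_rows$z))
  }
  items <- dplyr::bind_rows(items)
  items$crit <- crit_statistic(items)
  out <- list(items = items,
              comparisons = dplyr::bind_rows(comps),
              plotdata = dplyr::relocate(dplyr::bind_rows(plotdata), "item"),
              settings = list(minvi = minvi, minsize = minsize, alpha = alpha,
                              n = n))
  class(out) <- "monotonicity_report"
  out
}

# MSP-style composite severity; 0 when no violation
crit_statistic <- function(it) {
  ifelse(it$vi == 0, 0,
         50 * (0.3 - it$hi) + sqrt(it$vi) + 100 * it$vi / it$ac +
           100 * it$maxvi + 10 * sqrt(it$sumvi) + 1000 * it$sumvi / it$ac +
           5 * it$zmax + 10 * sqrt(it$zsum) + 100 * it$zsum / it$ac)
}

#' Extract plot-ready monotonicity series
#'
#' Per item and item step: ordered restscore-group label, size and
#' endorsement proportion — the series behind a monotonicity plot.
#'
#' @param report a `"monotonicity_report"`.
#' @return tibble: item, step, group, label (`"lo-hi"` restscore range),
#'   n, prop.
#' @export
monotonicity_plotdata <- function(report) {
  stopifnot(inherits(report, "monotonicity_report"))
  pd <- report$plotdata
  pd$label <- ifelse(pd$lo == pd$hi, as.character(pd$lo),
                     paste0(pd$lo, "-", pd$hi))
  pd[, c("item", "step", "group", "label", "n", "prop")]
}

#' @export
print.monotonicity_report <- function(x, digits = 2, ...) {
  s <- x$settings
  cat(sprintf("Monotonicity check (N = %d, minsize = %d, minvi = %.2f, alpha = %.2f)\n\n",
              s$n, s$minsize, s$minvi, s$alpha))
  df <- as.data.frame(x$items[, c("item", "hi", "ac", "vi", "zsig", "crit")])
  df$hi <- round(df$hi, digits)
  df$crit <- round(df$crit)
  names(df) <- c("Label", "ItemH", "#ac", "#vi", "#zsig", "crit")
  print(df, row.names = FALSE)
  invisible(x)
}

#' @rdname check_monotonicity
#' @param x,object a `"monotonicity_report"` object.
#' @param ... unused.
#' @export
tidy.monotonicity_report <- function(x, ...) x$items

#' @rdname check_monotonicity
#' @export
glance.monotonicity_report <- function(x, ...) {
  tibble::tibble(n_items = nrow(x$items), total_ac = sum(x$items$ac),
                 total_vi = sum(x$items$vi), total_zsig = sum(x$items$zsig),
                 max_crit = max(x$items$crit),
                 minsize = x$settings$minsize, minvi = x$settings$minvi)
}

#' @rdname check_monotonicity
#' @export
autoplot.monotonicity_report <- function(object, ...) {
  pd <- monotonicity_plotdata(object)
  pd$label <- factor(pd$label, levels = unique(pd$label[order(pd$group)]))
  ggplot2::ggplot(pd, ggplot2::aes(x = .data$group, y = .data$prop,
                                   colour = factor(.data$step),
                                   group = .data$step)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.6) +
    ggplot2::scale_size_area(max_size = 3) +
    ggplot2::facet_wrap(~item) +
    ggplot2::labs(x = "restscore group (low to high)",
                  y = "P(score >= step)", colour = "item step", size = "n",
                  title = "Item step response functions by restscore group") +
    ggplot2::theme_minimal()
}
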