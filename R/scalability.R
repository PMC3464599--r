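#' Loevinger scalability coefficients
#'
#' For a pair of items with scores \eqn{X_i, X_j}, the pairwise scalability
#' coefficient is
#' \deqn{H_{ij} = \mathrm{Cov}(X_i, X_j) / \mathrm{Cov}_{\max}(X_i, X_j),}
#' where the denominator is the largest covariance attainable by any joint
#' distribution with the observed marginals (reached by the comonotonic,
#' Guttman-ordered coupling of the two score distributions). Item and scale
#' coefficients are the corresponding ratios of sums:
#' \deqn{H_i = \sum_{j \ne i} \mathrm{Cov}(X_i,X_j) / \sum_{j \ne i}
#'   \mathrm{Cov}_{\max}(X_i,X_j), \qquad
#'   H = \sum_{i<j} \mathrm{Cov}(X_i,X_j) / \sum_{i<j}
#'   \mathrm{Cov}_{\max}(X_i,X_j).}
#' Under the monotone homogeneity model all three lie in \[0, 1\]; H = 1 is
#' error-free (Guttman) cumulative data and H = 0 means no linear association
#' among the items. Rule-of-thumb interpretation of the scale coefficient:
#' H < 0.3 unscalable, 0.3 <= H < 0.4 weak, 0.4 <= H < 0.5 medium,
#' H >= 0.5 strong.
#'
#' Both covariance and maximum covariance use the population divisor N; only
#' their ratio enters any coefficient, so the choice is immaterial as long as
#' it is consistent.
#'
#' @param data data frame (or matrix) of integer item scores, complete
#'   (no `NA`; see [drop_incomplete()]), k >= 2 items, no zero-variance item.
#' @return `coef_h()` returns an object of class `"scalability_h"`: a list
#'   with elements `hij` (k x k symmetric matrix, `NA` diagonal), `hi`
#'   (named vector), `h` (scalar), `classification`, `items` (tibble of
#'   label, mean, Hi), `cov` / `covmax` (the audit matrices) and `n`.
#'   `tidy()` gives the per-item table, `glance()` the one-row scale summary.
#' @examples
#' d <- sim_guttman(c(5, 5, 5, 5), n_items = 3)
#' coef_h(d)$h  # exactly 1 on cumulative error-free data
#' @seealso [coef_ht()] for the transposed-matrix coefficient,
#'   [aisp()] for scale construction from an item pool.
#' @export
coef_h <- function(data) {
  x <- as_item_matrix(data, complete = TRUE, require_variance = TRUE)
  res <- h_from_matrix(x)
  res$items <- tibble::tibble(
    item = colnames(x),
    mean = colMeans(x) + attr(x, "score_shift"),
    hi = res$hi
  )
  res$n <- nrow(x)
  res$classification <- classify_h(res$h)
  class(res) <- "scalability_h"
  res
}

# core H computation on a validated integer matrix. The covariance uses the
# same E[XY] - E[X]E[Y] arithmetic as the comonotone maximum, so cov <= covmax
# holds exactly (both E[XY] terms are exact integer sums) and Guttman data
# gives H_ij identically 1.
h_from_matrix <- function(x) {
  k <- ncol(x)
  n <- nrow(x)
  mu <- colMeans(x)
  cv <- crossprod(x) / n - tcrossprod(mu)
  cm <- matrix(0, k, k, dimnames = dimnames(cv))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      cm[i, j] <- cm[j, i] <- covmax_counts(tabulate0(x[, i]), tabulate0(x[, j]))
    }
  }
  diag(cv) <- NA_real_
  diag(cm) <- NA_real_
  hij <- cv / cm
  num_i <- rowSums(cv, na.rm = TRUE)
  den_i <- rowSums(cm, na.rm = TRUE)
  if (any(den_i <= 0)) {
    abort(paste0("item(s) with zero total maximum covariance: ",
                 paste(colnames(x)[den_i <= 0], collapse = ", ")))
  }
  list(hij = hij, hi = stats::setNames(num_i / den_i, colnames(x)),
       h = sum(cv[upper.tri(cv)]) / sum(cm[upper.tri(cm)]),
       cov = cv, covmax = cm)
}

# counts over scores 0..max (index 1 = score 0)
tabulate0 <- function(v) tabulate(v + 1L, nbins = max(v) + 1L)

#' Sample covariance of two item-score columns (population divisor)
#'
#' @param x,y equal-length complete numeric score vectors.
#' @return `sum((x - mean(x)) * (y - mean(y))) / length(x)`.
#' @keywords internal
#' @export
pair_covariance <- function(x, y) {
  if (length(x) != length(y)) abort("score columns differ in length")
  if (length(x) < 2L) abort("need at least 2 respondents")
  mean(x * y) - mean(x) * mean(y)
}

#' Maximum covariance given two marginal score distributions
#'
#' The Frechet upper bound on the covariance over all joint distributions
#' with the given marginals, attained by the comonotonic coupling: sort both
#' score distributions and pair them off rank by rank (for binary items this
#' is `min(p_i, p_j) - p_i * p_j` times nothing further; in count form,
#' the Guttman-ordered cross table).
#'
#' @param x_marginals,y_marginals count (or weight) vectors over scores
#'   `0..m`, element 1 = score 0; must have equal totals.
#' @return maximum covariance, population divisor (>= 0).
#' @keywords internal
#' @export
pair_covmax <- function(x_marginals, y_marginals) {
  if (abs(sum(x_marginals) - sum(y_marginals)) > 1e-8) {
    abort("marginal totals differ")
  }
  covmax_counts(x_marginals, y_marginals)
}

covmax_counts <- function(fx, fy) {
  n <- sum(fx)
  sx <- seq_along(fx) - 1
  sy <- seq_along(fy) - 1
  # comonotone walk: pair off the two sorted score distributions
  i <- 1L; j <- 1L
  rx <- fx[1L]; ry <- fy[1L]
  exy <- 0
  while (i <= length(fx) && j <= length(fy)) {
    t <- min(rx, ry)
    exy <- exy + t * sx[i] * sy[j]
    rx <- rx - t; ry <- ry - t
    if (rx <= 1e-12) { i <- i + 1L; rx <- if (i <= length(fx)) fx[i] else 0 }
    if (ry <= 1e-12) { j <- j + 1L; ry <- if (j <= length(fy)) fy[j] else 0 }
  }
  max(0, exy / n - (sum(fx * sx) / n) * (sum(fy * sy) / n))
}

classify_h <- function(h) {
  cut(h, breaks = c(-Inf, 0.3, 0.4, 0.5, Inf), right = FALSE,
      labels = c("unscalable", "weak", "medium", "strong"))
}

classify_ht <- function(ht) {
  cut(ht, breaks = c(-Inf, 0.3, 0.4, 0.5, Inf), right = FALSE,
      labels = c("too inaccurate", "somewhat low accuracy",
                 "medium accuracy", "sufficient accuracy"))
}

#' Scalability of the transposed data matrix (H^T)
#'
#' Computes the H coefficient with the roles of respondents and items
#' exchanged: instead of asking how well the items order the respondents,
#' H^T summarises how accurately the scale orders the *items* across
#' respondents, the manifest counterpart of invariant item ordering.
#' Interpretation bands: H^T < 0.3 too inaccurate to be useful,
#' 0.3-0.4 somewhat low, 0.4-0.5 medium, >= 0.5 sufficient accuracy.
#'
#' Respondent pairs in which either respondent has a constant response
#' pattern contribute zero to both the covariance and the maximum-covariance
#' sums, so they drop out of the ratio; the coefficient is undefined (an
#' error) only if *all* respondents are constant or identical. Computation
#' aggregates identical response patterns, so cost grows with the number of
#' distinct patterns, not with N^2.
#'
#' @inheritParams coef_h
#' @return scalar H^T with attribute `"classification"`.
#' @examples
#' d <- sim_guttman(c(4, 4, 4, 4, 4, 4), n_items = 5)
#' coef_ht(d)  # 1 on error-free Guttman data
#' @export
coef_ht <- function(data) {
  x <- as_item_matrix(data, complete = TRUE, min_items = 3L)
  pat <- apply(x, 1L, paste, collapse = "\r")
  first <- !duplicated(pat)
  u <- x[first, , drop = FALSE]              # distinct patterns (P x k)
  w <- tabulate(match(pat, pat[first]))      # pattern multiplicities
  k <- ncol(u)
  us <- t(apply(u, 1L, sort))                # row-sorted: comonotone pairing
  m <- rowMeans(u)
  cvm <- tcrossprod(u) / k - outer(m, m)       # pattern-pair covariances
  cmm <- tcrossprod(us) / k - outer(m, m)      # pattern-pair covmax
  cmm[cmm < 0] <- 0
  # sum over all unordered respondent pairs = (w'Mw - sum w^2 diag)/2 + within-pattern pairs
  pair_sum <- function(M) {
    (drop(t(w) %*% M %*% w) - sum(w^2 * diag(M))) / 2 + sum(choose(w, 2) * diag(M))
  }
  den <- pair_sum(cmm)
  if (den <= 1e-12) {
    abort("H^T undefined: all respondents have identical or constant response patterns")
  }
  ht <- pair_sum(cvm) / den
  attr(ht, "classification") <- classify_ht(ht)
  ht
}

#' One-sided tests that pairwise scalability exceeds zero
#'
#' Because `Covmax > 0` for any two non-constant items, `H_ij > 0` is
#' equivalent to a positive inter-item covariance; the test used here is the
#' large-sample normal approximation for the item-pair Pearson correlation,
#' `z = r * sqrt(N - 1)`, one-sided. The construction is deliberately
#' isolated so an alternative (e.g. a permutation test) can be swapped in.
#' Pairs involving a constant item have undefined H_ij and are flagged,
#' not tested.
#'
#' @inheritParams coef_h
#' @param alpha per-comparison significance level (default 0.05).
#' @return tibble with one row per item pair: `item_i`, `item_j`, `hij`,
#'   `z`, `p_value`, `significant`, `small_sample` (N < 30).
#' @export
test_hij_positive <- function(data, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  x <- as_item_matrix(data, complete = TRUE)
  n <- nrow(x)
  k <- ncol(x)
  sds <- apply(x, 2L, stats::sd)
  res <- h_pair_tests(x)
  hij <- matrix(NA_real_, k, k)
  nz <- sds > 0
  if (sum(nz) >= 2L) {
    sub <- h_from_matrix(x[, nz, drop = FALSE])
    hij[nz, nz] <- sub$hij
  }
  idx <- which(upper.tri(res$z), arr.ind = TRUE)
  tibble::tibble(
    item_i = colnames(x)[idx[, 1L]],
    item_j = colnames(x)[idx[, 2L]],
    hij = hij[idx],
    z = res$z[idx],
    p_value = res$p[idx],
    significant = !is.na(res$p[idx]) & res$p[idx] < alpha,
    small_sample = n < 30L
  )
}

# z and p matrices for H_ij > 0; NA where a member of the pair is constant
h_pair_tests <- function(x) {
  n <- nrow(x)
  sds <- apply(x, 2L, stats::sd)
  r <- suppressWarnings(stats::cor(x))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  z <- r * sqrt(n - 1)
  diag(z) <- NA_real_
  list(z = z, p = pnorm(z, lower.tail = FALSE))
}

#' @export
print.scalability_h <- function(x, digits = 2, ...) {
  cat("Loevinger scalability (N =", x$n, ")\n\n")
  df <- as.data.frame(x$items)
  df$mean <- round(df$mean, digits)
  df$hi <- round(df$hi, digits)
  names(df) <- c("Label", "Mean", "ItemH")
  print(df, row.names = FALSE)
  cat(sprintf("\nScale H = %.*f (%s scale)\n", digits, x$h,
              as.character(x$classification)))
  invisible(x)
}

#' @rdname coef_h
#' @param x a `"scalability_h"` object.
#' @param ... unused.
#' @export
tidy.scalability_h <- function(x, ...) x$items

#' @rdname coef_h
#' @export
glance.scalability_h <- function(x, ...) {
  tibble::tibble(h = x$h, classification = as.character(x$classification),
                 n_items = length(x$hi), n = x$n,
                 hi_min = min(x$hi), hi_max = max(x$hi))
}

#' @rdname coef_h
#' @param object a `"scalability_h"` object.
#' @export
autoplot.scalability_h <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object$hij, rownames = "item_i"),
    -"item_i", names_to = "item_j", values_to = "hij")
  df$item_i <- factor(df$item_i, levels = rownames(object$hij))
  df$item_j <- factor(df$item_j, levels = rownames(object$hij))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$item_j, y = .data$item_i,
                                   fill = .data$hij)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(is.na(.data$hij), "", sprintf("%.2f", .data$hij))),
      size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0.3,
                                  na.value = "grey90", limits = c(NA, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "H_ij",
                  title = sprintf("Pairwise scalability (scale H = %.2f)",
                                  object$h)) +
    ggplot2::theme_minimal()
}
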