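#' Cronbach's alpha
#'
#' `k/(k-1) * (1 - sum(item variances) / variance(total score))`. Reported
#' for comparison with [ms_rho()]: under the model assumptions alpha is a
#' lower bound on (and in practice underestimates) the total-score
#' reliability.
#'
#' @inheritParams coef_h
#' @return scalar alpha (<= 1).
#' @export
cronbach_alpha <- function(data) {
  x <- as_item_matrix(data, complete = TRUE, min_items = 2L)
  k <- ncol(x)
  vt <- var(rowSums(x))
  if (vt == 0) abort("total score has zero variance; alpha undefined")
  k / (k - 1) * (1 - sum(apply(x, 2L, var)) / vt)
}

#' Molenaar-Sijtsma total-score reliability (Rho)
#'
#' Estimates the reliability of the total score as the correlation between
#' two hypothetical parallel administrations: the probability of giving the
#' same responses twice. All observable between-item joint proportions enter
#' directly; the unobservable within-item terms (the "same response twice"
#' proportions, i.e. the diagonal of the popularity-ordered joint-positive
#' matrix and, for polytomous items, all within-item step pairs) are filled
#' in by interpolation along popularity-ordered neighbouring item steps —
#' a construction justified by non-intersecting response functions, which is
#' why the double monotonicity diagnostics ([check_monotonicity()],
#' [check_iio()]) should be run and pass before this estimate is
#' interpreted; a note to that effect is attached.
#'
#' The interpolation scheme (isolated in one internal function for audit) is,
#' for a target unobservable joint proportion of steps `a` (more popular) and
#' `b`, with `A`/`B` steps of *other* items more popular than `a` / less
#' popular than `b`: the multiplicative interior rule
#' `P[A,b] P[a,B] / P[A,B]`; at the popular extreme the ratio rule
#' `P[a,B] p_b / p_B`; at the unpopular extreme the complementary ratio rule
#' applied to negative responses. All three are exact on deterministic
#' cumulative (Guttman) data and on independent items, and each is refined
#' by first-order Richardson extrapolation against the same rule at the
#' next-farther neighbours, cancelling the leading smoothness bias under
#' double monotonicity. Estimates are clipped to the feasible range
#' `[p_a p_b, min(p_a, p_b)]`.
#'
#' @inheritParams coef_h
#' @param data complete item scores, k >= 3 items.
#' @return object of class `"reliability_result"`: list with `rho_ms`,
#'   `cronbach_alpha`, `n`, `k`, `notes`.
#' @examples
#' d <- sim_guttman(rep(8, 6), n_items = 5)
#' ms_rho(d)$rho_ms  # 1: deterministic responses are perfectly repeatable
#' @export
ms_rho <- function(data) {
  x <- as_item_matrix(data, complete = TRUE, min_items = 3L,
                      require_variance = TRUE)
  n <- nrow(x)
  k <- ncol(x)
  ncat <- attr(x, "n_categories")
  # step indicator matrix: one 0/1 column per item step (score >= s)
  cols <- list()
  step_item <- integer()
  for (i in seq_len(k)) {
    for (s in seq_len(ncat[i] - 1L)) {
      cols[[length(cols) + 1L]] <- as.numeric(x[, i] >= s)
      step_item <- c(step_item, i)
    }
  }
  y <- do.call(cbind, cols)
  p <- colMeans(y)
  keep <- p > 0 & p < 1                      # constant steps carry no variance
  y <- y[, keep, drop = FALSE]
  step_item <- step_item[keep]
  p <- p[keep]
  if (length(unique(step_item)) < 3L) {
    abort("Molenaar-Sijtsma rho needs at least 3 items with non-degenerate steps")
  }
  ord <- order(p, decreasing = TRUE)         # popularity order
  y <- y[, ord, drop = FALSE]
  step_item <- step_item[ord]
  p <- p[ord]
  pp <- crossprod(y) / n                     # joint positive proportions
  est <- pp
  ks <- length(p)
  for (a in seq_len(ks)) {
    for (b in a:ks) {
      if (step_item[a] != step_item[b]) next
      est[a, b] <- est[b, a] <- interpolate_joint(pp, p, step_item, a, b)
    }
  }
  cov_parallel <- sum(est - outer(p, p))
  var_total <- var(rowSums(y)) * (n - 1) / n
  rho <- min(max(cov_parallel / var_total, 0), 1)
  out <- list(
    rho_ms = rho,
    cronbach_alpha = if (k >= 2) cronbach_alpha(data) else NA_real_,
    n = n, k = k,
    notes = paste("rho assumes non-intersecting item (step) response",
                  "functions; run check_monotonicity() and check_iio()",
                  "before interpreting it."))
  class(out) <- "reliability_result"
  out
}

# Estimate the unobservable joint-positive proportion of steps a, b of the
# same item (a at least as popular as b) from popularity-ordered neighbouring
# steps of *other* items. Three elementary rules, each exact on deterministic
# Guttman data and on independent items:
#   interior       m(A,B) = P[A,b] P[a,B] / P[A,B]   (A above a, B below b)
#   popular end    r(B)   = P[a,B] p_b / p_B
#   unpopular end  c(A)   = complement-ratio rule on negative responses
# and each is refined by first-order Richardson extrapolation against the
# same rule evaluated at the next-farther neighbours, which cancels the
# leading smoothness bias under double monotonicity. Estimates are clipped
# to [p_a p_b, min(p_a, p_b)].
interpolate_joint <- function(pp, p, step_item, a, b) {
  own <- step_item[a]
  above <- rev(which(step_item != own & seq_along(p) < a))  # nearest first
  below <- which(step_item != own & seq_along(p) > b)
  m_rule <- function(A, B) pp[A, b] * pp[a, B] / pp[A, B]
  r_rule <- function(B) pp[a, B] * p[b] / p[B]
  c_rule <- function(A) {
    nu <- (1 - p[A] - p[b] + pp[A, b]) * (1 - p[a]) / (1 - p[A])
    nu - 1 + p[a] + p[b]
  }
  finite <- function(x) length(x) == 1L && is.finite(x)
  e <- NA_real_
  if (length(above) && length(below)) {
    m1 <- m_rule(above[1L], below[1L])
    if (finite(m1)) {
      e <- m1
      if (length(above) >= 2L && length(below) >= 2L) {
        m2 <- m_rule(above[2L], below[2L])
        if (finite(m2)) e <- (4 * m1 - m2) / 3
      } else if (length(below) >= 2L) {
        m2 <- m_rule(above[1L], below[2L])
        if (finite(m2)) e <- 2 * m1 - m2
      } else if (length(above) >= 2L) {
        m2 <- m_rule(above[2L], below[1L])
        if (finite(m2)) e <- 2 * m1 - m2
      }
    }
  }
  if (!finite(e) && length(below)) {
    r1 <- r_rule(below[1L])
    if (finite(r1)) {
      e <- r1
      if (length(below) >= 2L) {
        r2 <- r_rule(below[2L])
        if (finite(r2)) e <- 2 * r1 - r2
      }
    }
  }
  if (!finite(e) && length(above)) {
    c1 <- c_rule(above[1L])
    if (finite(c1)) {
      e <- c1
      if (length(above) >= 2L) {
        c2 <- c_rule(above[2L])
        if (finite(c2)) e <- 2 * c1 - c2
      }
    }
  }
  if (!finite(e)) {
    abort("cannot interpolate joint proportions: no usable item steps from other items")
  }
  min(max(e, p[a] * p[b]), min(p[a], p[b]))
}

#' @export
print.reliability_result <- function(x, digits = 3, ...) {
  cat(sprintf("Total-score reliability (N = %d, k = %d items)\n", x$n, x$k))
  cat(sprintf("  Molenaar-Sijtsma Rho: %.*f\n", digits, x$rho_ms))
  cat(sprintf("  Cronbach's alpha:     %.*f\n", digits, x$cronbach_alpha))
  cat("Note:", x$notes, "\n")
  invisible(x)
}

#' @rdname ms_rho
#' @param x a `"reliability_result"` object.
#' @param ... unused.
#' @export
glance.reliability_result <- function(x, ...) {
  tibble::tibble(rho_ms = x$rho_ms, cronbach_alpha = x$cronbach_alpha,
                 n = x$n, n_items = x$k)
}
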