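#' Build an item bank for simulation
#'
#' An item bank is a tibble with one row per item describing its (step)
#' response function over a standard-normal latent trait:
#' * `logistic` — graded-response style cumulative logistic steps,
#'   `P(X >= s | theta) = plogis(a (theta - b_s))` with ordered thresholds
#'   `b_1 < ... < b_m`; monotone by construction, and an equal-discrimination
#'   set is non-intersecting (invariant item ordering holds).
#' * `step` — deterministic Guttman steps, `P(X >= s | theta) = 1(theta >= b_s)`.
#' * `unimodal` — a binary item whose response probability rises then falls,
#'   `P = height * exp(-a^2 (theta - b)^2 / 2)`: a deliberate monotonicity
#'   violation.
#' * `table` — constant step probabilities independent of theta (no
#'   association with the trait or with other items).
#'
#' @param kind character vector of kinds (recycled).
#' @param location list of numeric threshold vectors (one per item; for
#'   `table`, the step probabilities, non-increasing), or a numeric vector
#'   for one-step (binary) items.
#' @param discrimination numeric slope `a >= 0` (recycled; unused by `step`
#'   and `table`).
#' @param height peak probability for `unimodal` items (recycled,
#'   default 0.85).
#' @param labels item labels (default `item01`, `item02`, ...).
#' @return tibble of class `"item_bank"` with columns `item`, `kind`,
#'   `location` (list), `discrimination`, `height`, `n_cat`.
#' @export
item_bank <- function(kind, location, discrimination = 1, height = 0.85,
                      labels = NULL) {
  if (!is.list(location)) location <- as.list(location)
  k <- length(location)
  kind <- rep_len(kind, k)
  discrimination <- rep_len(discrimination, k)
  height <- rep_len(height, k)
  stopifnot(all(kind %in% c("logistic", "step", "unimodal", "table")),
            all(discrimination >= 0),
            all(height > 0 & height <= 1))
  for (i in seq_len(k)) {
    loc <- location[[i]]
    if (kind[i] %in% c("logistic", "step") && is.unsorted(loc, strictly = FALSE)) {
      abort(sprintf("item %d: step thresholds must be non-decreasing", i))
    }
    if (kind[i] == "table" &&
        (any(loc < 0 | loc > 1) || is.unsorted(rev(loc)))) {
      abort(sprintf("item %d: 'table' locations are step probabilities, in [0,1] and non-increasing", i))
    }
    if (kind[i] == "unimodal" && length(loc) != 1L) {
      abort(sprintf("item %d: 'unimodal' items are binary (single location)", i))
    }
  }
  labels <- labels %||% sprintf("item%02d", seq_len(k))
  stopifnot(length(labels) == k, !anyDuplicated(labels))
  out <- tibble::tibble(item = labels, kind = kind, location = location,
                        discrimination = discrimination, height = height,
                        n_cat = lengths(location) + 1L)
  class(out) <- c("item_bank", class(out))
  out
}

#' @rdname item_bank
#' @param locations for `logistic_items()`: numeric vector of locations
#'   (binary items) or list/matrix of ordered thresholds (polytomous).
#' @param discriminations common or per-item slopes.
#' @param n_cat number of response categories; when > 2 and `locations` is a
#'   vector, thresholds are spread 1 unit apart around each location.
#' @export
logistic_items <- function(locations, discriminations = 1, n_cat = 2,
                           labels = NULL) {
  if (is.matrix(locations)) {
    loc <- lapply(seq_len(nrow(locations)), function(i) sort(locations[i, ]))
  } else if (is.list(locations)) {
    loc <- lapply(locations, sort)
  } else if (n_cat > 2) {
    off <- seq(-1, 1, length.out = n_cat - 1L)
    loc <- lapply(locations, function(b) b + off)
  } else {
    loc <- as.list(locations)
  }
  item_bank("logistic", loc, discrimination = discriminations, labels = labels)
}

# P(X >= s | theta) for one bank row: length(theta) x m matrix
step_probs <- function(bank, i, theta) {
  loc <- bank$location[[i]]
  a <- bank$discrimination[i]
  out <- switch(bank$kind[i],
    logistic = vapply(loc, function(b) plogis(a * (theta - b)),
                      numeric(length(theta))),
    step = vapply(loc, function(b) as.numeric(theta >= b),
                  numeric(length(theta))),
    unimodal = bank$height[i] * exp(-a^2 * (theta - loc)^2 / 2),
    table = rep(loc, each = length(theta)))
  matrix(out, nrow = length(theta))
}

#' Simulate item responses from an item bank
#'
#' Draws a latent trait value per respondent (standard normal unless `theta`
#' is supplied) and then, conditionally on theta, each item's response
#' independently (local independence by construction): with cumulative step
#' probabilities `P(X >= s | theta)` non-increasing in `s`, a single uniform
#' per item-respondent yields `X = #\{s : u <= P(X >= s)\}`. The seed fully
#' determines the output.
#'
#' @param bank an [item_bank()].
#' @param n number of respondents.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param theta optional vector of latent trait values (length `n`).
#' @return tibble of integer scores, one column per item.
#' @export
sim_responses <- function(bank, n, seed = NULL, theta = NULL) {
  stopifnot(inherits(bank, "item_bank"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  theta <- theta %||% rnorm(n)
  stopifnot(length(theta) == n)
  k <- nrow(bank)
  out <- matrix(0L, n, k, dimnames = list(NULL, bank$item))
  for (i in seq_len(k)) {
    pr <- step_probs(bank, i, theta)
    if (any(pr < -1e-9 | pr > 1 + 1e-9)) abort("invalid step probabilities")
    u <- runif(n)
    out[, i] <- as.integer(rowSums(u <= pr))
  }
  tibble::as_tibble(out)
}

#' Deterministic Guttman (cumulative scalogram) data
#'
#' Builds error-free cumulative response patterns: a respondent who endorses
#' the s-th hardest item endorses all easier ones, so the only patterns are
#' the triangular ones `00..0`, `10..0`, `110..0`, ..., `11..1`. The scale
#' H of such data is exactly 1.
#'
#' @param pattern_counts numeric vector of length `n_items + 1`: respondent
#'   counts for the patterns with 0, 1, ..., `n_items` endorsements.
#' @param n_items number of items (default `length(pattern_counts) - 1`).
#' @return tibble of 0/1 scores (`n_items` columns).
#' @examples
#' sim_guttman(rep(10, 6), n_items = 5)
#' @export
sim_guttman <- function(pattern_counts, n_items = length(pattern_counts) - 1L) {
  stopifnot(all(pattern_counts >= 0), n_items >= 2L,
            length(pattern_counts) == n_items + 1L)
  if (sum(pattern_counts > 0) < 2L) {
    abort("all respondents share one pattern: every item is constant (zero variance)")
  }
  scores <- rep(seq_along(pattern_counts) - 1L, times = pattern_counts)
  out <- vapply(seq_len(n_items), function(i) as.integer(scores >= i),
                integer(length(scores)))
  colnames(out) <- sprintf("item%02d", seq_len(n_items))
  tibble::as_tibble(out)
}

#' Make two binary logistic items cross at a chosen trait value
#'
#' Modifies items `i` and `j` of a bank so their response curves intersect
#' at `crossing_point` (both pass through probability 1/2 there) with
#' clearly different slopes — the canonical violation of non-intersection /
#' invariant item ordering. A crossing point outside +/- 3 SD of the trait
#' distribution is allowed but triggers a low-power warning, since almost no
#' respondents sit on the far side of the crossing.
#'
#' @param bank an [item_bank()] of binary `logistic` items (at positions
#'   `i`, `j` at least).
#' @param i,j distinct item positions.
#' @param crossing_point trait value where the two curves cross.
#' @param discriminations length-2 slopes for items `i` and `j`; must
#'   differ.
#' @return the modified item bank.
#' @export
inject_crossing_pair <- function(bank, i, j, crossing_point = 0,
                                 discriminations = c(2.5, 0.8)) {
  stopifnot(inherits(bank, "item_bank"))
  if (i == j) abort("`i` and `j` must be distinct items")
  for (idx in c(i, j)) {
    if (bank$kind[idx] != "logistic" || bank$n_cat[idx] != 2L) {
      abort("crossing injection requires binary logistic items")
    }
  }
  if (discriminations[1L] == discriminations[2L]) {
    abort("equal discriminations cannot cross")
  }
  if (abs(crossing_point) > 3) {
    warn("crossing point beyond +/-3 SD of the trait: the curves are ordered for nearly all respondents, expect low detection power")
  }
  bank$location[[i]] <- crossing_point
  bank$location[[j]] <- crossing_point
  bank$discrimination[i] <- discriminations[1L]
  bank$discrimination[j] <- discriminations[2L]
  bank
}

# normal quadrature grid for population quantities
theta_grid <- function(lim = 8, step = 0.005) {
  th <- seq(-lim, lim, by = step)
  w <- dnorm(th)
  list(theta = th, w = w / sum(w))
}

#' Population scalability coefficients of an item bank
#'
#' Computes H_ij, H_i and H at the population level by numerical
#' integration over the standard-normal trait: step probabilities give the
#' exact inter-item covariances and category marginals, and the maximum
#' covariances come from the comonotonic coupling of the marginal category
#' distributions. Sample coefficients from [sim_responses()] converge to
#' these values.
#'
#' @param bank an [item_bank()].
#' @param grid quadrature grid over the trait, as produced by the internal
#'   default (standard normal weights on an equally spaced grid).
#' @return list with `hij`, `hi`, `h`.
#' @export
population_h <- function(bank, grid = theta_grid()) {
  k <- nrow(bank)
  stopifnot(k >= 2L)
  pr <- lapply(seq_len(k), function(i) step_probs(bank, i, grid$theta))
  ex <- vapply(pr, function(m) sum(grid$w * rowSums(m)), numeric(1))
  # category probabilities per item (marginal over theta)
  catp <- lapply(pr, function(m) {
    cum <- cbind(1, m)                        # P(X >= 0) = 1
    marg <- colSums(grid$w * cum)
    -diff(c(marg, 0))                         # P(X = c), c = 0..m
  })
  cv <- cm <- matrix(0, k, k, dimnames = list(bank$item, bank$item))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      exy <- sum(grid$w * rowSums(pr[[i]]) * rowSums(pr[[j]]))
      cv[i, j] <- cv[j, i] <- exy - ex[i] * ex[j]
      cm[i, j] <- cm[j, i] <- covmax_counts(catp[[i]], catp[[j]])
    }
  }
  diag(cv) <- diag(cm) <- NA_real_
  list(hij = cv / cm,
       hi = rowSums(cv, na.rm = TRUE) / rowSums(cm, na.rm = TRUE),
       h = sum(cv[upper.tri(cv)]) / sum(cm[upper.tri(cm)]))
}

#' Population total-score reliability of an item bank
#'
#' True reliability `Var(E[X+ | theta]) / Var(X+)` by numerical integration:
#' the target that [ms_rho()] estimates and that parallel-replication
#' simulation approximates.
#'
#' @inheritParams population_h
#' @return scalar reliability in \[0, 1\].
#' @export
population_reliability <- function(bank, grid = theta_grid()) {
  k <- nrow(bank)
  pr <- lapply(seq_len(k), function(i) step_probs(bank, i, grid$theta))
  tmean <- Reduce(`+`, lapply(pr, rowSums))          # E[X+ | theta]
  var_true <- sum(grid$w * tmean^2) - sum(grid$w * tmean)^2
  cond_var <- Reduce(`+`, lapply(pr, function(m) {
    cum <- cbind(1, m)
    cats <- -t(apply(cbind(cum, 0), 1L, diff))       # P(X = c | theta)
    sc <- seq_len(ncol(cats)) - 1
    colSums(t(cats) * sc^2) - colSums(t(cats) * sc)^2
  }))
  var_total <- var_true + sum(grid$w * cond_var)
  var_true / var_total
}
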