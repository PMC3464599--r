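# Independent oracles and shared fixture builders. The covmax/H oracle works
# by exhaustive enumeration of all contingency tables with fixed margins and
# never calls the package's comonotone-coupling code path.

# all allocations of total n into boxes with capacities cap
enum_compositions <- function(n, cap) {
  if (length(cap) == 1L) {
    if (n <= cap) return(list(n)) else return(list())
  }
  out <- list()
  for (first in 0:min(n, cap[1L])) {
    for (rest in enum_compositions(n - first, cap[-1L])) {
      out[[length(out) + 1L]] <- c(first, rest)
    }
  }
  out
}

# maximum of sum n_ab * a * b over all tables with row margins rmar (row
# scores row_offset, row_offset+1, ...) and column margins cmar (scores
# 0..length-1), by brute-force enumeration
enum_max_exy_score <- function(rmar, cmar, row_offset) {
  cscores <- seq_along(cmar) - 1L
  if (length(rmar) == 1L) {
    # single remaining row: forced allocation equals remaining column margins
    return(row_offset * sum(cmar * cscores))
  }
  best <- -Inf
  for (row1 in enum_compositions(rmar[1L], cmar)) {
    contrib <- row_offset * sum(row1 * cscores)
    sub <- enum_max_exy_score(rmar[-1L], cmar - row1, row_offset + 1L)
    best <- max(best, contrib + sub)
  }
  best
}

oracle_covmax <- function(fx, fy) {
  n <- sum(fx)
  exy <- enum_max_exy_score(fx, fy, row_offset = 0L)
  ex <- sum(fx * (seq_along(fx) - 1L)) / n
  ey <- sum(fy * (seq_along(fy) - 1L)) / n
  exy / n - ex * ey
}

# brute-force scalability coefficients built on the enumeration oracle
oracle_h <- function(x) {
  x <- as.matrix(x)
  k <- ncol(x)
  n <- nrow(x)
  covp <- function(a, b) mean(a * b) - mean(a) * mean(b)
  tab <- function(v, m) tabulate(v + 1L, nbins = m + 1L)
  mmax <- max(x)
  num <- den <- matrix(0, k, k)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      num[i, j] <- num[j, i] <- covp(x[, i], x[, j])
      den[i, j] <- den[j, i] <- oracle_covmax(tab(x[, i], mmax), tab(x[, j], mmax))
    }
  }
  list(hij = ifelse(den > 0, num / den, NA_real_),
       hi = rowSums(num) / rowSums(den),
       h = sum(num[upper.tri(num)]) / sum(den[upper.tri(den)]))
}

# random small complete item matrix with every column non-constant
random_small_matrix <- function(k, m, n) {
  repeat {
    x <- matrix(sample(0:m, n * k, replace = TRUE), n, k,
                dimnames = list(NULL, paste0("i", seq_len(k))))
    if (all(apply(x, 2L, function(v) length(unique(v)) > 1L))) return(x)
  }
}

# canonical double-monotone bank: 6 equal-discrimination binary items with
# spread locations (the package's stock well-behaved scale)
dmm_bank <- function(k = 6, disc = 2, n_cat = 2) {
  logistic_items(seq(-1.5, 1.5, length.out = k), discriminations = disc,
                 n_cat = n_cat)
}

# deterministic 4-item binary data containing every response pattern,
# so each item's restscore takes all values 0..3 (4 groups at minsize 1)
all_patterns_4 <- function(copies = 5) {
  g <- expand.grid(a = 0:1, b = 0:1, c = 0:1, d = 0:1)
  tibble::as_tibble(g[rep(seq_len(nrow(g)), copies), ])
}

# parallel-replication reliability oracle: same theta, two administrations
parallel_oracle <- function(bank, n, theta) {
  d1 <- sim_responses(bank, n, theta = theta)
  d2 <- sim_responses(bank, n, theta = theta)
  stats::cor(rowSums(d1), rowSums(d2))
}
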