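test_that("pairwise covariance and maximum covariance match hand values", {
  expect_equal(pair_covariance(c(0, 0, 1, 1), c(0, 0, 1, 1)), 0.25)
  expect_equal(pair_covariance(c(0, 1), c(1, 0)), -0.25)
  expect_equal(pair_covariance(rep(1, 5), c(0, 1, 0, 1, 0)), 0)
  expect_error(pair_covariance(c(0, 1), c(0, 1, 1)), "length")

  # binary margins 3/10 and 5/10 positives: covmax = 0.3 * (1 - 0.5)
  expect_equal(pair_covmax(c(7, 3), c(5, 5)), 0.15)
  expect_equal(pair_covmax(c(5, 5), c(5, 5)), 0.25)
  expect_equal(pair_covmax(c(10, 0), c(5, 5)), 0)
  expect_error(pair_covmax(c(7, 3), c(5, 6)), "totals differ")
})

test_that("covmax equals the exhaustive-enumeration oracle on assorted marginals", {
  set.seed(41)
  for (rep in 1:40) {
    n_cat_x <- sample(2:3, 1)
    n_cat_y <- sample(2:3, 1)
    n <- sample(4:12, 1)
    fx <- as.vector(stats::rmultinom(1, n, rep(1, n_cat_x)))
    fy <- as.vector(stats::rmultinom(1, n, rep(1, n_cat_y)))
    expect_equal(pair_covmax(fx, fy), oracle_covmax(fx, fy),
                 tolerance = 1e-12)
  }
})

test_that("error-free Guttman data has H = 1 with all pairwise coefficients 1", {
  d <- sim_guttman(c(7, 3, 9, 4), n_items = 3)
  res <- coef_h(d)
  expect_equal(res$h, 1)
  expect_equal(unname(res$hi), rep(1, 3))
  expect_true(all(res$hij[upper.tri(res$hij)] == 1))
  expect_equal(as.character(res$classification), "strong")
})

test_that("independent items give scale H near zero", {
  bank <- item_bank("table", location = list(0.2, 0.4, 0.6))
  d <- sim_responses(bank, 20000, seed = 17)
  expect_lt(abs(coef_h(d)$h), 0.03)
})

test_that("zero-variance items are an error naming the item", {
  d <- tibble::tibble(a = c(0L, 1L, 0L, 1L), flat = c(1L, 1L, 1L, 1L))
  expect_error(coef_h(d), "flat")
})

test_that("coef_h equals the brute-force oracle on random small instances", {
  set.seed(99)
  for (rep in 1:60) {
    k <- sample(2:4, 1)
    m <- sample(1:2, 1)
    n <- sample(4:12, 1)
    x <- random_small_matrix(k, m, n)
    got <- coef_h(x)
    want <- oracle_h(x)
    expect_equal(got$h, want$h, tolerance = 1e-10)
    expect_equal(unname(got$hi), want$hi, tolerance = 1e-10)
  }
})

test_that("H is invariant to respondent shuffling and coherent under item permutation", {
  set.seed(5)
  x <- random_small_matrix(4, 2, 40)
  base <- coef_h(x)
  shuf <- coef_h(x[sample(nrow(x)), ])
  expect_equal(shuf$h, base$h)
  expect_equal(shuf$hi, base$hi)

  perm <- c(3, 1, 4, 2)
  permuted <- coef_h(x[, perm])
  expect_equal(permuted$h, base$h)
  expect_equal(unname(permuted$hi), unname(base$hi[perm]))
  expect_equal(unname(permuted$hij), unname(base$hij[perm, perm]))
})

test_that("reversing all item scorings leaves H unchanged", {
  set.seed(8)
  for (rep in 1:10) {
    x <- random_small_matrix(3, 2, 30)
    expect_equal(coef_h(max(x) - x)$h, coef_h(x)$h, tolerance = 1e-12)
  }
})

test_that("scale H lies between the smallest and largest item H (mediant property)", {
  set.seed(21)
  for (rep in 1:20) {
    x <- random_small_matrix(sample(3:5, 1), 1, 30)
    res <- coef_h(x)
    expect_gte(res$h, min(res$hi) - 1e-12)
    expect_lte(res$h, max(res$hi) + 1e-12)
  }
})

test_that("strength classification follows the 0.3/0.4/0.5 bands", {
  expect_equal(as.character(mokkenscale:::classify_h(c(0.1, 0.31, 0.45, 0.7))),
               c("unscalable", "weak", "medium", "strong"))
  expect_equal(as.character(mokkenscale:::classify_ht(c(0.2, 0.31, 0.45, 0.7))),
               c("too inaccurate", "somewhat low accuracy",
                 "medium accuracy", "sufficient accuracy"))
})

test_that("H^T is 1 on Guttman data and near 0 for exchangeable items", {
  d <- sim_guttman(rep(10, 6), n_items = 5)
  ht <- coef_ht(d)
  expect_equal(as.numeric(ht), 1)

  # identical marginals, independent responses: items interchangeable,
  # no item ordering to recover
  bank <- item_bank("table", location = list(0.5, 0.5, 0.5, 0.5, 0.5, 0.5))
  di <- sim_responses(bank, 4000, seed = 23)
  expect_lt(abs(as.numeric(coef_ht(di))), 0.05)

  allsame <- tibble::tibble(a = rep(0L:1L, 4), b = rep(0L:1L, 4),
                            c = rep(0L:1L, 4))
  expect_error(coef_ht(allsame), "H\\^T undefined")
})

test_that("H^T agrees with a direct transpose computation on small data", {
  set.seed(12)
  x <- random_small_matrix(5, 1, 9)
  # drop constant-row respondents, then coefficients on the transpose
  keep <- apply(x, 1L, function(r) length(unique(r)) > 1L)
  xt <- t(x[keep, , drop = FALSE])
  colnames(xt) <- paste0("r", seq_len(ncol(xt)))
  want <- oracle_h(xt)
  expect_equal(as.numeric(coef_ht(x)), want$h, tolerance = 1e-10)
})

test_that("positivity screen rejects for associated pairs and respects alpha for null pairs", {
  bank <- dmm_bank()
  d <- sim_responses(bank, 1000, seed = 31)
  tt <- test_hij_positive(d)
  expect_true(all(tt$significant))
  expect_false(any(tt$small_sample))

  # independent pair: rejection rate across replications stays near alpha
  set.seed(77)
  rejections <- vapply(1:100, function(i) {
    d0 <- tibble::tibble(a = sample(0:1, 400, TRUE), b = sample(0:1, 400, TRUE))
    test_hij_positive(d0)$significant[1L]
  }, logical(1))
  expect_lte(mean(rejections), 0.12)

  tiny <- test_hij_positive(tibble::tibble(a = c(0L, 1L, 1L), b = c(0L, 0L, 1L)))
  expect_true(all(tiny$small_sample))
})
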