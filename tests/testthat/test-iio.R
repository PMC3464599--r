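test_that("equal-discrimination (non-intersecting) items show no significant IIO violations", {
  d <- sim_responses(dmm_bank(), 2000, seed = 71)
  r <- check_iio(d)
  expect_true(all(r$items$tsig == 0))
  expect_true(all(r$items$vi <= r$items$ac))
  expect_true(all(r$items$tsig <= r$items$vi))
})

test_that("a crossing pair is flagged for both members", {
  bank <- inject_crossing_pair(dmm_bank(), 3, 4, crossing_point = 0)
  d <- sim_responses(bank, 4000, seed = 81)
  r <- check_iio(d)
  expect_gte(r$items$tsig[3], 1L)
  expect_gte(r$items$tsig[4], 1L)
})

test_that("coincident response functions produce no violations (ties skipped)", {
  set.seed(14)
  v <- sample(0:1, 60, replace = TRUE)
  d <- tibble::tibble(a = v, b = v, c = v)
  r <- check_iio(d, compute_ht = FALSE)   # H^T undefined for identical items
  expect_true(all(r$items$ac == 0))
  expect_true(all(r$items$vi == 0))
  expect_equal(nrow(r$pairs), 0L)
})

test_that("active comparisons never grow when an item is removed", {
  d <- sim_responses(dmm_bank(k = 7, disc = 1.5), 1200, seed = 44)
  full <- check_iio(d, compute_ht = FALSE)
  sub <- check_iio(d[, -7], compute_ht = FALSE)
  shared <- sub$items$item
  expect_true(all(sub$items$ac <=
                    full$items$ac[match(shared, full$items$item)]))
})

test_that("backward removal eliminates planted crossing items and reaches a fixed point", {
  bank <- logistic_items(c(seq(-1.6, 1.6, length.out = 6), -0.5, 0.5),
                         discriminations = c(rep(2.2, 6), 0.6, 0.6),
                         labels = c(sprintf("ok%d", 1:6), "bad1", "bad2"))
  d <- sim_responses(bank, 3000, seed = 91)
  bs <- backward_select_iio(d)
  expect_true(all(c("bad1", "bad2") %in% bs$removed))
  # fixed point: the final set re-checks clean
  survivors <- setdiff(names(d), bs$removed)
  again <- check_iio(d[survivors], compute_ht = FALSE)
  expect_equal(max(again$items$tsig), 0L)
  # trace shape: one column per step, removed items NA afterwards
  expect_equal(ncol(bs$removal) - 1L, length(bs$removed) + 1L)
  first_removed <- bs$removed[1L]
  expect_false(is.na(bs$removal$step_1[bs$removal$item == first_removed]))
  expect_true(is.na(bs$removal$step_2[bs$removal$item == first_removed]))
  expect_true(length(bs$removed) <= ncol(d) - 2L)
  expect_s3_class(attr(bs$ht_final, "classification"), "factor")
})

test_that("IIO-clean data passes backward selection untouched", {
  d <- sim_responses(dmm_bank(), 1500, seed = 101)
  bs <- backward_select_iio(d)
  expect_length(bs$removed, 0L)
  expect_equal(ncol(bs$removal), 2L)  # item column + single step
  expect_equal(as.numeric(bs$ht_final), as.numeric(bs$ht))
})

test_that("ties in violation counts remove the item with the lowest scalability", {
  # a single crossing pair gives both members identical violation counts,
  # so the tie-break (lower within-set H_i) decides which one goes
  bank <- inject_crossing_pair(dmm_bank(), 3, 4, crossing_point = 0,
                               discriminations = c(2.6, 1.4))
  d <- sim_responses(bank, 3000, seed = 111)
  r <- check_iio(d, compute_ht = FALSE)
  expect_equal(r$items$tsig[3], r$items$tsig[4])  # violations shared
  expect_gte(r$items$tsig[3], 1L)
  bs <- backward_select_iio(d)
  flat <- which.min(r$items$hi[c(3, 4)])          # the flat item scales worse
  expect_equal(bs$removed[1L], r$items$item[c(3, 4)][flat])
})

test_that("the dichotomous non-intersection check is the binary MIIO", {
  d <- sim_responses(dmm_bank(), 800, seed = 121)
  a <- check_nonintersection(d)
  b <- check_iio(d)
  expect_equal(a$items, b$items)
  poly <- sim_responses(dmm_bank(k = 4, n_cat = 4), 500, seed = 5)
  expect_error(check_nonintersection(poly), "dichotomous")
})

test_that("reversals are measured against restscore groups excluding both items", {
  d <- sim_responses(dmm_bank(), 700, seed = 131)
  r <- check_iio(d)
  # group sizes per pair partition the full sample
  sizes <- tapply(r$pairs$n, paste(r$pairs$item_hard, r$pairs$item_easy),
                  sum)
  expect_true(all(sizes == nrow(d)))
  expect_s3_class(tidy(r), "tbl_df")
  expect_equal(glance(r)$n_items, 6L)
})
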