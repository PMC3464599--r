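test_that("default minsize follows the sample-size rule", {
  expect_equal(default_minsize(773), 77L)   # N/10 branch
  expect_equal(default_minsize(300), 60L)   # N/5 branch
  expect_equal(default_minsize(100), 50L)   # N/3 floored at 50
  expect_equal(default_minsize(249), 83L)
  expect_equal(default_minsize(5000), 500L)
})

test_that("restscore grouping merges undersized groups and respects minsize", {
  rest <- rep(0:5, c(30, 10, 25, 40, 5, 20))
  g <- restscore_groups(rest, minsize = 30)
  expect_true(all(g$summary$n >= 30))
  expect_equal(sum(g$summary$n), length(rest))
  # groups are ordered, disjoint restscore ranges
  expect_true(all(diff(g$summary$lo) > 0))
  expect_true(all(g$summary$hi >= g$summary$lo))
  expect_true(all(g$summary$lo[-1] > g$summary$hi[-nrow(g$summary)]))
  # per-respondent assignment matches the summary
  expect_equal(as.vector(table(g$group)), g$summary$n)

  # minsize 1: one group per observed value
  g1 <- restscore_groups(rest, minsize = 1)
  expect_equal(nrow(g1$summary), 6L)

  # a single shared restscore gives a single group
  gs <- restscore_groups(rep(3L, 100), minsize = 10)
  expect_equal(nrow(gs$summary), 1L)
})

test_that("group-proportion comparisons count violations per the minvi rule", {
  props <- c(0.2, 0.5, 0.45, 0.9)
  ns <- rep(120, 4)
  cmp <- compare_group_proportions(props, ns, minvi = 0.03)
  expect_equal(nrow(cmp), 6L)              # 4*3/2 active comparisons
  expect_equal(sum(cmp$violation), 1L)     # only the 0.5 -> 0.45 dip
  expect_equal(cmp$decrease[cmp$violation], 0.05)

  # a larger minvi absorbs the dip
  cmp2 <- compare_group_proportions(props, ns, minvi = 0.06)
  expect_equal(sum(cmp2$violation), 0L)

  # equalities are not violations even at minvi = 0
  cmp3 <- compare_group_proportions(c(0.3, 0.3, 0.6), rep(50, 3), minvi = 0)
  expect_equal(sum(cmp3$violation), 0L)
})

test_that("deterministic cumulative data shows no monotonicity violations at any minvi", {
  d <- sim_guttman(c(12, 9, 11, 8, 10, 7), n_items = 5)
  for (mv in c(0, 0.03, 0.1)) {
    rep_ <- check_monotonicity(d, minvi = mv, minsize = 5)
    expect_true(all(rep_$items$vi == 0))
    expect_true(all(rep_$items$crit == 0))
  }
})

test_that("active comparisons equal R(R-1)/2 per dichotomous item", {
  d <- all_patterns_4(copies = 5)
  rep_ <- check_monotonicity(d, minsize = 1)
  # every item's restscore over the other three items takes values 0..3
  expect_equal(rep_$items$ac, rep(6L, 4))
  # and in general #ac matches the realized group count
  bank <- dmm_bank()
  ds <- sim_responses(bank, 1500, seed = 61)
  rep2 <- check_monotonicity(ds)
  groups_per_item <- tapply(rep2$plotdata$group, rep2$plotdata$item,
                            function(g) length(unique(g)))
  r_i <- as.vector(groups_per_item[rep2$items$item])
  expect_equal(rep2$items$ac, as.integer(r_i * (r_i - 1) / 2))
})

test_that("polytomous items accumulate comparisons per item step", {
  bank <- dmm_bank(k = 4, disc = 1.5, n_cat = 3)
  d <- sim_responses(bank, 1200, seed = 19)
  rep_ <- check_monotonicity(d)
  per_step <- dplyr::count(rep_$comparisons, item, step)
  totals <- tapply(per_step$n, per_step$item, sum)
  expect_equal(rep_$items$ac, as.integer(totals[rep_$items$item]),
               ignore_attr = TRUE)
  expect_true(all(per_step$n >= 1))
})

test_that("violation counts are monotone in minvi and ordered #zsig <= #vi <= #ac", {
  bank <- dmm_bank(disc = 0.8)
  d <- sim_responses(bank, 300, seed = 7)   # small N: sampling dips expected
  gr <- seq(0, 0.1, by = 0.02)
  vis <- vapply(gr, function(mv) {
    r <- check_monotonicity(d, minvi = mv, minsize = 40)
    expect_true(all(r$items$zsig <= r$items$vi))
    expect_true(all(r$items$vi <= r$items$ac))
    sum(r$items$vi)
  }, numeric(1))
  expect_true(all(diff(vis) <= 0))
})

test_that("well-behaved items are rarely flagged; an injected unimodal item is caught", {
  # type-I behaviour under the monotone homogeneity model
  flagged <- 0L; total <- 0L
  for (s in 1:40) {
    d <- sim_responses(dmm_bank(), 2000, seed = 500 + s)
    r <- check_monotonicity(d)
    flagged <- flagged + sum(r$items$zsig > 0)
    total <- total + nrow(r$items)
  }
  expect_lte(flagged / total, 0.10)

  # power: rise-then-fall response function
  hits <- vapply(1:15, function(s) {
    bank <- dmm_bank()
    bank$kind[4] <- "unimodal"; bank$location[[4]] <- 0
    bank$discrimination[4] <- 1
    d <- sim_responses(bank, 2000, seed = 900 + s)
    check_monotonicity(d)$items$zsig[4] >= 1
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("grouping failures raise actionable errors", {
  # constant restscores: a single group, monotonicity unassessable
  expect_error(suppressMessages(check_monotonicity(tibble::tibble(
    a = rep(c(0L, 1L), 30), b = rep(c(0L, 1L), 30), c = rep(c(1L, 0L), 30)
  ), minsize = 60)), "restscore group")
})

test_that("plot data is sufficient to redraw the response curves", {
  d <- sim_responses(dmm_bank(), 1000, seed = 3)
  r <- check_monotonicity(d)
  pd <- monotonicity_plotdata(r)
  expect_named(pd, c("item", "step", "group", "label", "n", "prop"))
  expect_true(all(pd$prop >= 0 & pd$prop <= 1))
  # weighted group proportions reproduce each item's overall mean
  agg <- tapply(seq_len(nrow(pd)), pd$item,
                function(i) sum(pd$prop[i] * pd$n[i]) / sum(pd$n[i]))
  expect_equal(as.vector(agg[colnames(d)]), unname(colMeans(d)),
               tolerance = 1e-12)
  expect_s3_class(autoplot(r), "ggplot")
  expect_s3_class(tidy(r), "tbl_df")
})
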