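test_that("percent agreement is the (weighted) mean credit over fully-rated items", {
  expect_equal(percent_agreement(c(1, 1, 2, 1), c(1, 1, 2, 2)), 0.75)
  # quadratic: (1 + 8/9 + 1 + 5/9) / 4
  expect_equal(
    percent_agreement(c(1, 1, 4, 2), c(1, 2, 4, 4),
                      weights = "quadratic", categories = 1:4),
    31 / 36
  )
  expect_equal(percent_agreement(c("A", "B"), c("A", "B"),
                                 weights = "quadratic"), 1)
  # pairwise deletion
  expect_equal(percent_agreement(c(1, NA, 2), c(1, 2, NA)), 1)
  expect_error(percent_agreement(c(NA, NA), c(1, 2)), class = "rih_no_pairs")
})

test_that("AC1 on the 4-item hand example matches the spelled-out formula", {
  r1 <- c(1, 1, 2, 1)
  r2 <- c(1, 1, 2, 2)
  est <- gwet_ac(r1, r2, weights = "identity")
  expect_equal(est$pa, 0.75)
  expect_equal(est$pe, 0.46875)
  expect_equal(est$coefficient, 9 / 17, tolerance = 1e-12)
  expect_equal(est$coefficient, reference_ac1(r1, r2, 2), tolerance = 1e-12)
})

test_that("perfect agreement on mixed categories gives coefficient 1, SE 0, CI [1,1], p n/a", {
  x <- c("A", "B", "C", "D", "A", "B", "A", "C")
  est <- gwet_ac(x, x, weights = "quadratic", categories = c("A", "B", "C", "D"))
  expect_equal(est$pa, 1)
  expect_equal(est$coefficient, 1)
  expect_equal(est$se, 0)
  expect_equal(c(est$ci_low, est$ci_high), c(1, 1))
  expect_true(is.na(est$p_value))
  expect_equal(est$benchmark, "Almost perfect")
})

test_that("single-category saturation still yields coefficient 1 with zero chance term", {
  est <- gwet_ac(rep(1, 10), rep(1, 10), weights = "identity", categories = 1:2)
  expect_equal(est$pe, 0) # pi = (1, 0): no chance-agreement mass
  expect_equal(est$coefficient, 1)
})

test_that("pa = 1 forces coefficient 1 for any valid weight scheme", {
  withr::with_seed(41, {
    for (i in 1:10) {
      q <- sample(2:5, 1)
      x <- sample(seq_len(q), 20, replace = TRUE)
      for (w in list("identity", "quadratic")) {
        expect_equal(gwet_ac(x, x, weights = w, categories = seq_len(q))$coefficient, 1)
      }
    }
  })
})

test_that("AC1 is invariant under category relabelling; AC2 under order reversal", {
  withr::with_seed(42, {
    tb <- simulate_rating_pair(30, 4, c(0.4, 0.3, 0.2, 0.1), 0.7)
    perm <- sample(4)
    ac1 <- gwet_ac(tb$rater_1, tb$rater_2, weights = "identity",
                   categories = 1:4)$coefficient
    ac1_perm <- gwet_ac(perm[tb$rater_1], perm[tb$rater_2],
                        weights = "identity", categories = 1:4)$coefficient
    expect_equal(ac1, ac1_perm)

    ac2 <- gwet_ac(tb$rater_1, tb$rater_2, weights = "quadratic",
                   categories = 1:4)$coefficient
    ac2_rev <- gwet_ac(5L - tb$rater_1, 5L - tb$rater_2,
                       weights = "quadratic", categories = 1:4)$coefficient
    expect_equal(ac2, ac2_rev)
  })
})

test_that("quadratic-weighted pa dominates identity pa, and pe stays in [0, 1]", {
  withr::with_seed(43, {
    for (i in 1:25) {
      m <- as.vector(prop.table(runif(4) + 0.1))
      tb <- simulate_rating_pair(20, 4, m, runif(1))
      pa_id <- percent_agreement(tb$rater_1, tb$rater_2,
                                 weights = "identity", categories = 1:4)
      pa_qd <- percent_agreement(tb$rater_1, tb$rater_2,
                                 weights = "quadratic", categories = 1:4)
      expect_gte(pa_qd, pa_id)
      est <- gwet_ac(tb$rater_1, tb$rater_2, weights = "quadratic",
                     categories = 1:4)
      expect_gte(est$pe, 0)
      expect_lte(est$pe, 1)
      expect_lte(est$coefficient, 1)
      expect_lte(est$ci_low, est$coefficient)
      expect_gte(est$ci_high, est$coefficient)
    }
  })
})

test_that("the linearized SE tracks the delete-one jackknife", {
  withr::with_seed(44, {
    for (i in 1:20) {
      tb <- simulate_rating_pair(25, 4, c(0.4, 0.3, 0.2, 0.1),
                                 runif(1, 0.4, 0.8))
      est <- gwet_ac(tb$rater_1, tb$rater_2, weights = "quadratic",
                     categories = 1:4)
      sj <- jackknife_se_ac(tb$rater_1, tb$rater_2, "quadratic", 1:4)
      if (sj == 0) {
        expect_equal(est$se, 0)
      } else {
        expect_lt(abs(est$se - sj) / sj, 0.10)
      }
    }
  })
})

test_that("duplicating every item shrinks the SE by about 1/sqrt(2)", {
  withr::with_seed(45, {
    ratios <- replicate(10, {
      tb <- simulate_rating_pair(25, 4, c(0.4, 0.3, 0.2, 0.1), 0.6)
      one <- gwet_ac(tb$rater_1, tb$rater_2, weights = "quadratic",
                     categories = 1:4)$se
      two <- gwet_ac(rep(tb$rater_1, 2), rep(tb$rater_2, 2),
                     weights = "quadratic", categories = 1:4)$se
      two / one
    })
    # exact finite-n ratio is sqrt((n-1)/(2n-1)); 1/sqrt(2) asymptotically
    expect_true(all(abs(ratios - 1 / sqrt(2)) < 0.03))
  })
})

test_that("the long-format front end reproduces the vector interface per attribute", {
  withr::with_seed(46, {
    tb1 <- simulate_rating_pair(25, 4, c(0.4, 0.3, 0.2, 0.1), 0.7)
    tb2 <- simulate_rating_pair(25, 4, c(0.25, 0.25, 0.25, 0.25), 0.9,
                                missing_rate = 0.2)
  })
  long <- dplyr::bind_rows(pair_to_long(tb1, "attr_one"),
                           pair_to_long(tb2, "attr_two"))
  res <- rih_agreement(long, weights = "quadratic", categories = 1:4)
  expect_equal(nrow(res), 2)
  direct <- gwet_ac(tb2$rater_1, tb2$rater_2, weights = "quadratic",
                    categories = 1:4)
  row2 <- res[res$attribute == "attr_two", ]
  expect_equal(row2$coefficient, direct$coefficient)
  expect_equal(row2$n_used, direct$n_used)
  expect_equal(row2$n_used, sum(!is.na(tb2$rater_1) & !is.na(tb2$rater_2)))
  expect_error(rih_agreement(dplyr::mutate(long, rater_id = "only_one")),
               "exactly 2 raters")
})

test_that("glance and autoplot summarise an agreement table", {
  withr::with_seed(47, tb <- simulate_rating_pair(25, 4, rep(0.25, 4), 0.8))
  res <- rih_agreement(pair_to_long(tb, "demo"), weights = "quadratic",
                       categories = 1:4)
  g <- glance(res)
  expect_equal(g$n_scales, 1)
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(autoplot(rih_rate(table4_scorecards())), "ggplot")
})
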