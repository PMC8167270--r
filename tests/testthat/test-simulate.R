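test_that("simulation is reproducible from its seed and leaves the RNG alone", {
  a <- simulate_rating_pair(25, seed = 123)
  b <- simulate_rating_pair(25, seed = 123)
  expect_identical(a, b)
  c <- simulate_rating_pair(25, seed = 124)
  expect_false(identical(a, c))

  withr::with_seed(1, before <- runif(1))
  withr::with_seed(1, {
    simulate_rating_pair(25, seed = 99)
    after <- runif(1)
  })
  expect_identical(before, after)

  s1 <- simulate_scorecards(n = 4, seed = 7)
  s2 <- simulate_scorecards(n = 4, seed = 7)
  expect_identical(s1, s2)
})

test_that("full designed agreement copies rater 1 exactly", {
  tb <- simulate_rating_pair(40, agreement_prob = 1, seed = 5)
  expect_identical(tb$rater_1, tb$rater_2)
  expect_equal(percent_agreement(tb$rater_1, tb$rater_2, categories = 1:4), 1)
})

test_that("independent redraw at zero agreement matches the collision probability", {
  # q = 2, uniform marginal: expected identity pa = sum(m^2) = 0.5
  withr::with_seed(61, {
    pa <- replicate(300, {
      tb <- simulate_rating_pair(50, q = 2, marginal = c(0.5, 0.5),
                                 agreement_prob = 0,
                                 disagreement_model = "independent_redraw")
      percent_agreement(tb$rater_1, tb$rater_2, categories = 1:2)
    })
  })
  mcse <- sd(pa) / sqrt(length(pa))
  expect_lt(abs(mean(pa) - 0.5), 3 * mcse + 1e-12)
})

test_that("empirical weighted agreement matches its analytic expectation", {
  for (model in c("adjacent_category", "independent_redraw")) {
    m <- c(0.4, 0.3, 0.2, 0.1)
    exp_pa <- expected_pair_agreement(4, m, 0.7, model, "quadratic")$pa
    withr::with_seed(62, {
      pa <- replicate(500, {
        tb <- simulate_rating_pair(25, 4, m, 0.7, model)
        percent_agreement(tb$rater_1, tb$rater_2, weights = "quadratic",
                          categories = 1:4)
      })
    })
    mcse <- sd(pa) / sqrt(length(pa))
    expect_lt(abs(mean(pa) - exp_pa), 2 * mcse)
  }
})

test_that("adjacent-category disagreements move exactly one rank, reflected at edges", {
  tb <- simulate_rating_pair(500, 4, agreement_prob = 0,
                             disagreement_model = "adjacent_category",
                             seed = 63)
  d <- abs(tb$rater_1 - tb$rater_2)
  expect_true(all(d == 1))
})

test_that("cell and item masking deliver the designed complete-pair count", {
  withr::with_seed(64, {
    n_used_cell <- replicate(300, {
      tb <- simulate_rating_pair(25, missing_rate = 0.5, missing_mode = "cell")
      sum(!is.na(tb$rater_1) & !is.na(tb$rater_2))
    })
    n_used_item <- replicate(300, {
      tb <- simulate_rating_pair(25, missing_rate = 0.5, missing_mode = "item")
      sum(!is.na(tb$rater_1) & !is.na(tb$rater_2))
    })
  })
  # independent masks: 25 * 0.25; joint masks: 25 * 0.5
  expect_lt(abs(mean(n_used_cell) - 25 * 0.25), 3 * sd(n_used_cell) / sqrt(300))
  expect_lt(abs(mean(n_used_item) - 25 * 0.5), 3 * sd(n_used_item) / sqrt(300))
})

test_that("mean estimated AC2 increases with the designed agreement", {
  m <- c(0.4, 0.3, 0.2, 0.1)
  means <- sapply(c(0.5, 0.75, 0.95), function(a) {
    withr::with_seed(65, {
      mean(replicate(120, {
        tb <- simulate_rating_pair(25, 4, m, a)
        gwet_ac(tb$rater_1, tb$rater_2, weights = "quadratic",
                categories = 1:4)$coefficient
      }))
    })
  })
  expect_true(all(diff(means) > 0))
})

test_that("simulated scorecards recover their design marginals at scale", {
  sc <- simulate_scorecards(n = 4000, seed = 66)
  s <- rih_summarize(sc)
  target <- default_grade_marginals()
  for (attr_id in rownames(target)) {
    got <- s$grades[s$grades$attribute == attr_id, ]
    got <- got$pct[match(c("A", "B", "C", "D"), got$grade)]
    expect_true(all(abs(got - 100 * target[attr_id, ]) <= 3),
                label = paste("marginals recovered for", attr_id))
  }
  # missingness recovered too
  details <- attr(suppressWarnings(rih_rate(sc)), "details")
  miss <- tapply(is.na(details$grade), details$attribute, mean)
  expect_true(all(abs(miss[names(default_missing_rates())] -
                        default_missing_rates()) < 0.03))
})

test_that("degenerate scorecard designs behave as their parameters dictate", {
  all_a <- default_grade_marginals()
  all_a[] <- 0
  all_a[, "A"] <- 1
  sc <- simulate_scorecards(n = 5, grade_marginals = all_a,
                            missing_rates = rep(0, 9), seed = 67)
  r <- rih_rate(sc)
  expect_true(all(r$overall_score == 5.0))

  forced <- default_missing_rates()
  forced[c("elsis", "frugality", "eco_responsibility")] <- 1
  forced[setdiff(names(forced), c("elsis", "frugality", "eco_responsibility"))] <- 0
  sc3 <- simulate_scorecards(n = 5, missing_rates = forced, seed = 68)
  r3 <- rih_rate(sc3)
  expect_true(all(r3$n_documented == 6))
  expect_true(all(r3$meaningful == FALSE))
})

test_that("invalid designs are rejected", {
  expect_error(simulate_rating_pair(marginal = c(0.5, 0.6, 0, 0)), "sum to 1")
  expect_error(simulate_rating_pair(agreement_prob = 1.2), "probability")
  expect_error(simulate_rating_pair(missing_rate = -0.1), "probability")
  expect_error(simulate_scorecards(missing_rates = rep(0.1, 3)),
               "one entry per attribute")
})
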