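test_that("overall_score averages documented attributes and rounds half-up to 1 decimal", {
  pts <- table4_points()
  expect_equal(overall_score(pts$innovation_1), 4.6) # 41/9
  expect_equal(overall_score(pts$innovation_2), 3.6) # 32/9
  expect_equal(overall_score(pts$innovation_3), 2.3) # 16/7 over 7 documented
  expect_equal(overall_score(c(2, 2.1)), 2.1)        # 2.05 rounds up
  expect_error(overall_score(rep(NA_real_, 9)), class = "rih_no_score")
})

test_that("overall_score is permutation-invariant and unaffected by where the gaps sit", {
  withr::with_seed(11, {
    for (i in 1:20) {
      p <- sample(c(5, 4, 2, 1), 9, replace = TRUE)
      p[sample(9, sample(0:2, 1))] <- NA
      if (all(is.na(p))) next
      expect_equal(overall_score(sample(p)), overall_score(p))
    }
  })
})

test_that("the four intervals partition every 1-decimal score in [1, 5]", {
  scores <- seq(1, 5, by = 0.1)
  labels <- classify_interval(scores)
  expect_false(anyNA(labels))
  expect_equal(classify_interval(4.6), "Almost all RIH features are present")
  expect_equal(classify_interval(2.3), "Few RIH features are present")
  expect_equal(classify_interval(1.0), "Almost no RIH features are present")
  expect_equal(classify_interval(2.0), "Almost no RIH features are present")
  expect_equal(classify_interval(2.05), "Few RIH features are present")
  # each score maps to exactly one label, and bands are contiguous
  expect_equal(rle(labels)$values, rih_config()$interval_labels)
  expect_error(classify_interval(5.2), "out of range")
  expect_error(classify_interval(0.9), "out of range")
})

test_that("rate() reproduces the published example scorecards end to end", {
  r <- rih_rate(table4_scorecards())
  r <- r[match(paste0("innovation_", 1:3), r$innovation_id), ]
  expect_equal(r$overall_score, c(4.6, 3.6, 2.3))
  expect_equal(r$interval, c("Almost all RIH features are present",
                             "Many RIH features are present",
                             "Few RIH features are present"))
  expect_equal(r$n_documented, c(9L, 9L, 7L))
  expect_true(all(r$availability_sufficient))
  # innovation 3: 7 documented attributes, still meaningful given quality >= 2
  expect_true(r$meaningful[3])
})

test_that("availability component: at least 7 of 9 attributes must carry a grade", {
  grades <- rep("A", 9)
  grades[1:3] <- NA
  r6 <- suppressWarnings(rih_rate(scorecard("six", grades, sources = rep(3, 9))))
  expect_equal(r6$n_documented, 6L)
  expect_false(r6$availability_sufficient)
  expect_false(r6$meaningful) # regardless of score or quality

  grades[3] <- "A"
  r7 <- suppressWarnings(rih_rate(scorecard("seven", grades, sources = rep(3, 9))))
  expect_equal(r7$n_documented, 7L)
  expect_true(r7$availability_sufficient)
})

test_that("quality component thresholds at a mean source score of 2, boundary inclusive", {
  srcs <- c(3, 2, 2, 1, 2, 2, 2, 2, 2) # mean 18/9 = 2.0
  r <- rih_rate(scorecard("edge", rep("A", 9), sources = srcs))
  expect_equal(r$quality_mean, 2.0)
  expect_true(r$quality_sufficient)

  low <- rih_rate(scorecard("low", rep("A", 9), sources = rep(1, 9)))
  expect_equal(low$quality_mean, 1.0)
  expect_false(low$quality_sufficient)
  expect_false(low$meaningful)

  high <- rih_rate(scorecard("high", rep("A", 9), sources = rep(3, 9)))
  expect_equal(high$quality_mean, 3.0)
  expect_true(high$meaningful)
})

test_that("graded-but-unsourced attributes count toward availability, not quality", {
  srcs <- c(3, 3, 3, 3, NA, NA, NA, NA, NA)
  expect_warning(r <- rih_rate(scorecard("part", rep("B", 9), sources = srcs)),
                 "excluded from the quality mean")
  expect_equal(r$n_documented, 9L)
  expect_equal(r$quality_mean, 3.0)

  w <- capture_warnings(none <- rih_rate(scorecard("unsourced", rep("B", 9))))
  expect_match(w, "quality not assessable", all = FALSE)
  expect_true(is.na(none$quality_mean))
  expect_true(is.na(none$meaningful)) # availability ok, quality unknowable
})

test_that("all-A and all-D scorecards hit the scale endpoints", {
  top <- rih_rate(scorecard("top", rep("A", 9), sources = rep(3, 9)))
  expect_equal(top$overall_score, 5.0)
  expect_equal(top$interval, "Almost all RIH features are present")
  bottom <- rih_rate(scorecard("bottom", rep("D", 9), sources = rep(3, 9)))
  expect_equal(bottom$overall_score, 1.0)
  expect_equal(bottom$interval, "Almost no RIH features are present")
})

test_that("documenting one more attribute never breaks meaningfulness through availability", {
  withr::with_seed(21, {
    for (i in 1:20) {
      grades <- sample(c("A", "B", "C", "D"), 9, replace = TRUE)
      grades[sample(9, sample(0:3, 1))] <- NA
      srcs <- ifelse(is.na(grades), NA, 3L)
      before <- suppressWarnings(rih_rate(scorecard("x", grades, sources = srcs)))
      gap <- which(is.na(grades))
      if (length(gap) == 0) next
      grades2 <- grades
      grades2[gap[1]] <- "C"
      srcs2 <- ifelse(is.na(grades2), NA, 3L)
      after <- suppressWarnings(rih_rate(scorecard("x", grades2, sources = srcs2)))
      if (isTRUE(before$meaningful)) expect_true(after$meaningful)
    }
  })
})

test_that("excluded-at-screening innovations are still rated, with the outcome flagged", {
  sc <- scorecard("excluded", rep("B", 9), sources = rep(3, 9),
                  screening = c("yes", "yes", "yes", "no"))
  r <- rih_rate(sc)
  expect_false(r$proceed)
  expect_equal(r$overall_score, 4.0)
})

test_that("non-canonical configurations are flagged", {
  cfg <- rih_config(availability_threshold = 5)
  expect_false(cfg$canonical)
  r <- rih_rate(table4_scorecards(), config = cfg)
  expect_false(attr(r, "canonical"))
  expect_output(print(r), "NON-CANONICAL")
})
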