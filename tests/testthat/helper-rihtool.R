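# Attribute point rows of the three published example innovations
# (canonical attribute order; NA = undocumented).
table4_points <- function() {
  list(
    innovation_1 = c(4, 4, 5, 4, 5, 5, 5, 4, 5),
    innovation_2 = c(5, 2, 5, 2, 5, 5, 2, 4, 2),
    innovation_3 = c(5, 1, NA, 2, 4, 1, NA, 1, 2)
  )
}

table4_scorecards <- function(source_type = 3L) {
  pts <- table4_points()
  dplyr::bind_rows(lapply(names(pts), function(id) {
    p <- pts[[id]]
    scorecard(id, points_to_grade(p),
              sources = ifelse(is.na(p), NA_integer_, source_type))
  }))
}

# Delete-one jackknife SE of the AC coefficient: an independent variance
# route over the same point estimator.
jackknife_se_ac <- function(r1, r2, weights, categories) {
  n <- length(r1)
  th <- vapply(seq_len(n), function(i) {
    gwet_ac(r1[-i], r2[-i], weights = weights,
            categories = categories)$coefficient
  }, numeric(1))
  sqrt((n - 1) / n * sum((th - mean(th))^2))
}

# Independent spelled-out AC1 for two raters, identity weights: raw
# proportion of exact matches, chance term from the mean category shares.
reference_ac1 <- function(r1, r2, q) {
  n <- length(r1)
  pa <- sum(r1 == r2) / n
  pik <- vapply(seq_len(q), function(k) (sum(r1 == k) + sum(r2 == k)) / (2 * n),
                numeric(1))
  pe <- sum(pik * (1 - pik)) / (q - 1)
  (pa - pe) / (1 - pe)
}
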