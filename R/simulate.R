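#' Simulate a two-rater ratings table with designed agreement
#'
#' Emulates a two-rater reliability study: the first rater draws each
#' item's category i.i.d. from `marginal`; with probability
#' `agreement_prob` the second rater copies the first, otherwise they
#' disagree according to `disagreement_model` — `"adjacent_category"`
#' steps one rank up or down with equal probability (reflected at the scale
#' edges; raters plausibly err by one level on an ordinal scale) and
#' `"independent_redraw"` draws afresh from `marginal` (so an accidental
#' match remains possible; the natural model for nominal answers). Cells
#' can then be masked at random, either independently per cell or per item
#' (both raters missing, as when no information exists for an innovation).
#'
#' @param n_items Number of items (innovations).
#' @param q Number of ordered categories.
#' @param marginal Probability vector of length `q` for rater 1's draws.
#' @param agreement_prob Probability that rater 2 copies rater 1.
#' @param disagreement_model `"adjacent_category"` or
#'   `"independent_redraw"`.
#' @param missing_rate Masking probability.
#' @param missing_mode `"cell"` (each rating masked independently) or
#'   `"item"` (both ratings of an item masked together).
#' @param seed Optional integer seed; the draw is fully reproducible from
#'   it and the calling RNG state is left untouched.
#' @return A tibble `item_id`, `rater_1`, `rater_2` of integer category
#'   ranks with `NA` for masked cells, with the category count in
#'   `attr(, "q")`.
#' @examples
#' simulate_rating_pair(n_items = 5, agreement_prob = 1, seed = 1)
#' @export
simulate_rating_pair <- function(n_items = 25, q = 4,
                                 marginal = rep(1 / q, q),
                                 agreement_prob = 0.8,
                                 disagreement_model = c("adjacent_category",
                                                        "independent_redraw"),
                                 missing_rate = 0,
                                 missing_mode = c("cell", "item"),
                                 seed = NULL) {
  disagreement_model <- match.arg(disagreement_model)
  missing_mode <- match.arg(missing_mode)
  .check_q(q)
  .check_prob_vector(marginal, q, "marginal")
  .check_prob(agreement_prob, "agreement_prob")
  .check_prob(missing_rate, "missing_rate")
  if (n_items < 1) abort("`n_items` must be at least 1")
  if (!is.null(seed)) {
    old_rng <- snapshot_rng()
    on.exit(restore_rng(old_rng), add = TRUE)
    set.seed(seed)
  }

  r1 <- sample.int(q, n_items, replace = TRUE, prob = marginal)
  copy <- stats::runif(n_items) < agreement_prob
  r2 <- r1
  redo <- which(!copy)
  if (length(redo) > 0) {
    if (disagreement_model == "independent_redraw") {
      r2[redo] <- sample.int(q, length(redo), replace = TRUE, prob = marginal)
    } else {
      step <- sample(c(-1L, 1L), length(redo), replace = TRUE)
      moved <- r1[redo] + step
      moved[moved == 0L] <- 2L
      moved[moved == q + 1L] <- q - 1L
      r2[redo] <- moved
    }
  }

  if (missing_rate > 0) {
    if (missing_mode == "item") {
      gone <- stats::runif(n_items) < missing_rate
      r1[gone] <- NA_integer_
      r2[gone] <- NA_integer_
    } else {
      r1[stats::runif(n_items) < missing_rate] <- NA_integer_
      r2[stats::runif(n_items) < missing_rate] <- NA_integer_
    }
  }

  structure(tibble(item_id = paste0("item_", seq_len(n_items)),
                   rater_1 = r1, rater_2 = r2),
            q = q)
}

#' Analytic agreement expectations under the pair generator
#'
#' Computes, from the generator's design parameters, the population values
#' of the weighted percent agreement, the chance agreement and the AC
#' coefficient — the quantities [simulate_rating_pair()] plus [gwet_ac()]
#' estimate. With `order = 2` and a sample size `n`, a delta-method
#' second-order term (from the exact item-level moments of the generator)
#' is added to the coefficient, giving the expectation of the *estimator*
#' at that sample size: the plug-in population coefficient plus its
#' `O(1/n)` small-sample bias.
#'
#' @inheritParams simulate_rating_pair
#' @param weights `"identity"`, `"quadratic"` or a weight matrix.
#' @param order `1` for the population (plug-in) value, `2` to include the
#'   `O(1/n)` bias of the estimator.
#' @param n Sample size at which to evaluate the `order = 2` expectation.
#' @return A list with `pa`, `pe`, `coefficient` and (for `order = 2`)
#'   `bias`.
#' @examples
#' expected_pair_agreement(q = 4, agreement_prob = 0.8,
#'                         weights = "quadratic")
#' @export
expected_pair_agreement <- function(q = 4, marginal = rep(1 / q, q),
                                    agreement_prob = 0.8,
                                    disagreement_model = c("adjacent_category",
                                                           "independent_redraw"),
                                    weights = "quadratic",
                                    order = 1, n = NULL) {
  disagreement_model <- match.arg(disagreement_model)
  .check_q(q)
  .check_prob_vector(marginal, q, "marginal")
  .check_prob(agreement_prob, "agreement_prob")
  W <- resolve_weights(weights, q)

  # disagreement kernel D[k, l] = P(rater 2 = l | rater 1 = k, no copy)
  D <- matrix(0, q, q)
  if (disagreement_model == "independent_redraw") {
    D <- matrix(marginal, q, q, byrow = TRUE)
  } else {
    for (k in seq_len(q)) {
      lo <- if (k == 1) 2L else k - 1L
      hi <- if (k == q) q - 1L else k + 1L
      D[k, lo] <- D[k, lo] + 0.5
      D[k, hi] <- D[k, hi] + 0.5
    }
  }
  # joint distribution of the pair
  cond <- agreement_prob * diag(q) + (1 - agreement_prob) * D
  P <- diag(marginal) %*% cond

  tw <- sum(W)
  cc <- tw / (q * (q - 1))
  pa <- sum(P * W)
  p2 <- colSums(P)
  pik <- (marginal + p2) / 2
  pe <- cc * sum(pik * (1 - pik))
  coef <- (pa - pe) / (1 - pe)
  out <- list(pa = pa, pe = pe, coefficient = coef)

  if (order == 2) {
    if (is.null(n)) abort("`n` is required for the order-2 expectation")
    # exact item-level moments of (w_i, t_i1..t_iq), t_ik in {0, 1/2, 1}
    cells <- expand.grid(k = seq_len(q), l = seq_len(q))
    pr <- P[cbind(cells$k, cells$l)]
    wv <- W[cbind(cells$k, cells$l)]
    tmat <- matrix(0, nrow(cells), q)
    for (m in seq_len(q)) {
      tmat[, m] <- ((cells$k == m) + (cells$l == m)) / 2
    }
    cov_wt <- colSums(pr * wv * tmat) - pa * pik
    cov_tt <- t(tmat) %*% (pr * tmat) - outer(pik, pik)
    g <- 1 - pe
    pe_k <- cc * (1 - 2 * pik)           # d pe / d pi_k
    # bias = sum_k f_{pa,pi_k} Cov(pa^, pi^_k)
    #      + 1/2 sum_{k,l} f_{pi_k,pi_l} Cov(pi^_k, pi^_l), all over n
    f_pa_pik <- pe_k / g^2
    f_pik_pil <- (-2 * (1 - pa) / g^3) * outer(pe_k, pe_k) +
      (-(1 - pa) / g^2) * (-2 * cc) * diag(q)
    bias <- (sum(f_pa_pik * cov_wt) + 0.5 * sum(f_pik_pil * cov_tt)) / n
    out$bias <- bias
    out$coefficient <- coef + bias
  }
  out
}

#' Simulate a sample of scorecards
#'
#' Draws complete scorecards — screening answers, attribute grades and
#' best-source types — from per-attribute marginal distributions, with
#' per-attribute missingness. The defaults emulate the composition of a
#' published 25-innovation validation sample: grade marginals and
#' missingness follow its observed per-attribute distributions (e.g.
#' health relevance ~ 84/4/4/8% over A-D with no missingness;
#' eco-responsibility documented for only 44% of innovations), screening
#' answers follow its include/exclude rates, and the source-quality
#' marginal is set so that roughly a third of samples reach the quality
#' threshold.
#'
#' @param n Number of scorecards.
#' @param grade_marginals 9 x 4 matrix (rows = attributes in canonical
#'   order, columns = grades A-D) of grade probabilities given documented.
#' @param source_marginals 9 x 3 matrix of best-source-type probabilities
#'   (types 1-3) given documented.
#' @param missing_rates Length-9 probability an attribute is undocumented.
#' @param screening_rates Named length-4 probability of a "yes" answer to
#'   each screening criterion.
#' @param region Region stamped on the scorecards.
#' @param seed Optional integer seed (reproducible, RNG state preserved).
#' @return A long scorecard tibble covering `n` innovations.
#' @examples
#' sc <- simulate_scorecards(n = 5, seed = 7)
#' rih_rate(sc)
#' @export
simulate_scorecards <- function(n = 25,
                                grade_marginals = default_grade_marginals(),
                                source_marginals = default_source_marginals(),
                                missing_rates = default_missing_rates(),
                                screening_rates = c(
                                  determinants_of_health = 1,
                                  innovativeness = 1,
                                  unavailability = 0.12,
                                  corporate_social_irresponsibility = 0.12
                                ),
                                region = "synthetic",
                                seed = NULL) {
  attrs <- .attribute_ids()
  crits <- .criterion_ids()
  grade_marginals <- .check_marginal_matrix(grade_marginals, 4, "grade_marginals")
  source_marginals <- .check_marginal_matrix(source_marginals, 3, "source_marginals")
  if (length(missing_rates) != length(attrs)) {
    abort("`missing_rates` must have one entry per attribute")
  }
  for (p in missing_rates) .check_prob(p, "missing_rates")
  for (p in screening_rates) .check_prob(p, "screening_rates")
  if (!setequal(names(screening_rates), crits)) {
    abort("`screening_rates` must be named by the 4 screening criteria")
  }
  if (!is.null(seed)) {
    old_rng <- snapshot_rng()
    on.exit(restore_rng(old_rng), add = TRUE)
    set.seed(seed)
  }

  grades_letters <- c("A", "B", "C", "D")
  purrr::map_dfr(seq_len(n), function(i) {
    answers <- map_chr(crits, function(cr) {
      if (stats::runif(1) < screening_rates[[cr]]) "yes" else "no"
    })
    documented <- stats::runif(length(attrs)) >= missing_rates
    grades <- rep(NA_character_, length(attrs))
    sources <- rep(NA_integer_, length(attrs))
    for (a in which(documented)) {
      grades[a] <- sample(grades_letters, 1, prob = grade_marginals[a, ])
      sources[a] <- sample(1:3, 1, prob = source_marginals[a, ])
    }
    scorecard(sprintf("sim_%03d", i),
              grades = setNames(grades, attrs),
              sources = setNames(sources, attrs),
              screening = setNames(answers, crits),
              region = region)
  })
}

#' Default simulation marginals
#'
#' Per-attribute grade distributions, missingness and best-source
#' distributions used by [simulate_scorecards()]; see that help page for
#' what they emulate.
#'
#' @return `default_grade_marginals()`: a 9 x 4 matrix of grade
#'   probabilities; `default_missing_rates()`: a named length-9 vector;
#'   `default_source_marginals()`: a 9 x 3 matrix.
#' @export
default_grade_marginals <- function() {
  counts <- rbind(
    health_relevance = c(21, 1, 1, 2),
    elsis = c(1, 4, 16, 1),
    health_inequalities = c(10, 6, 2, 2),
    inclusiveness = c(2, 4, 13, 2),
    responsiveness = c(18, 2, 1, 1),
    level_intensity_of_care = c(15, 2, 5, 1),
    frugality = c(11, 8, 3, 0),
    business_model = c(7, 5, 5, 4),
    eco_responsibility = c(3, 1, 7, 0)
  )
  colnames(counts) <- c("A", "B", "C", "D")
  sweep(counts, 1, rowSums(counts), `/`)
}

#' @rdname default_grade_marginals
#' @export
default_missing_rates <- function() {
  c(health_relevance = 0, elsis = 3, health_inequalities = 5,
    inclusiveness = 4, responsiveness = 3, level_intensity_of_care = 2,
    frugality = 3, business_model = 4, eco_responsibility = 14) / 25
}

#' @rdname default_grade_marginals
#' @export
default_source_marginals <- function() {
  m <- matrix(rep(c(0.40, 0.30, 0.30), each = 9), nrow = 9,
              dimnames = list(.attribute_ids(), 1:3))
  m
}

.check_prob <- function(p, what) {
  if (length(p) != 1 || is.na(p) || p < 0 || p > 1) {
    abort(paste0("`", what, "` must be a probability in [0, 1]"))
  }
}

.check_prob_vector <- function(p, len, what) {
  if (length(p) != len || anyNA(p) || any(p < 0)) {
    abort(paste0("`", what, "` must be ", len, " non-negative probabilities"))
  }
  if (abs(sum(p) - 1) > 1e-8) {
    abort(paste0("`", what, "` must sum to 1"))
  }
}

.check_marginal_matrix <- function(m, ncols, what) {
  m <- as.matrix(m)
  if (nrow(m) != length(.attribute_ids()) || ncol(m) != ncols) {
    abort(paste0("`", what, "` must be ", length(.attribute_ids()),
                 " x ", ncols))
  }
  for (i in seq_len(nrow(m))) .check_prob_vector(m[i, ], ncols, what)
  m
}
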