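#' Agreement weight matrices over ordered categories
#'
#' Chance-corrected agreement coefficients generalise from nominal to
#' ordinal scales through a symmetric weight matrix `w[k, l]` giving the
#' partial credit earned when one rater chooses category `k` and the other
#' `l`. Identity weights (`w = 1` iff `k == l`) recover the unweighted
#' nominal-scale statistics (AC1); quadratic weights
#' `w[k, l] = 1 - ((k - l) / (q - 1))^2` give near-miss disagreements most
#' of the credit and are the conventional choice for ordinal Likert-type
#' grades (AC2).
#'
#' @param q Number of ordered categories (at least 2).
#' @return A `q` by `q` numeric matrix with unit diagonal, symmetric,
#'   entries in `[0, 1]`.
#' @examples
#' quadratic_weights(4)
#' identity_weights(2)
#' @export
quadratic_weights <- function(q) {
  .check_q(q)
  k <- seq_len(q)
  d <- outer(k, k, `-`) / (q - 1)
  w <- 1 - d^2
  dimnames(w) <- list(k, k)
  w
}

#' @rdname quadratic_weights
#' @export
identity_weights <- function(q) {
  .check_q(q)
  w <- diag(q)
  dimnames(w) <- list(seq_len(q), seq_len(q))
  w
}

.check_q <- function(q) {
  if (length(q) != 1 || is.na(q) || q < 2 || q != as.integer(q)) {
    abort("`q` must be a single integer >= 2")
  }
}

# accept "identity" / "quadratic" / a user matrix; validate the matrix
resolve_weights <- function(weights, q) {
  if (is.character(weights)) {
    weights <- match.arg(weights, c("identity", "quadratic"))
    return(switch(weights,
                  identity = identity_weights(q),
                  quadratic = quadratic_weights(q)))
  }
  w <- as.matrix(weights)
  if (nrow(w) != q || ncol(w) != q) {
    abort(sprintf("weight matrix must be %d x %d for these categories", q, q))
  }
  if (!isTRUE(all.equal(w, t(w)))) abort("weight matrix must be symmetric")
  if (!isTRUE(all.equal(unname(diag(w)), rep(1, q)))) {
    abort("weight matrix must have a unit diagonal")
  }
  if (any(w < -1e-12 | w > 1 + 1e-12)) {
    abort("weights must lie in [0, 1]")
  }
  w
}
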