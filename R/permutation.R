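#' Empirical permutation P value
#'
#' Add-one empirical P: `(1 + #\{null >= observed\}) / (1 + B)`. Ties count
#' toward the numerator and the value can never be 0; the smallest
#' attainable P with `B` permutations is `1 / (B + 1)`.
#'
#' @param observed observed first canonical correlation.
#' @param null_rhos numeric vector of null-distribution values.
#' @return P value in `[1/(B+1), 1]`.
#' @examples
#' empirical_p(0.9, runif(1000, 0, 0.6)) # 1/1001 when observed tops them all
#' @export
empirical_p <- function(observed, null_rhos) {
  if (length(null_rhos) < 1) abort_input("null distribution is empty")
  (1 + sum(null_rhos >= observed)) / (1 + length(null_rhos))
}

#' Permutation null distribution for the first canonical correlation
#'
#' Breaks the occasion-level linkage between the two blocks by shuffling one
#' block across occasions, refitting the CCA each time, and recording the
#' first canonical correlation. Two schemes:
#' \describe{
#'   \item{`within_column`}{each column of the shuffled block is
#'     independently re-ordered across occasions. This also destroys the
#'     within-block correlation structure of that block and is the more
#'     liberal null.}
#'   \item{`row_shuffle`}{whole rows are re-ordered jointly, preserving the
#'     shuffled block's internal correlations; the more conservative null.}
#' }
#' The default (`within_column` on the `y` block) matches shuffling values
#' within the columns of one block. Each of the `B` iterations draws its
#' permutation from a deterministically derived substream, so results do not
#' depend on execution order.
#'
#' @param A_x,A_y occasion blocks as in [fit_pcca()].
#' @param B number of permutations (default 1000).
#' @param scheme `"within_column"` or `"row_shuffle"`.
#' @param shuffled_block `"y"` (default) or `"x"`.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param ridge passed to [fit_pcca()].
#' @return an object of class `permutation_null`: list with `null_rhos`
#'   (length `B`), `observed`, `p_value`, `B`, `scheme`, `shuffled_block`,
#'   `seed`.
#' @examples
#' set.seed(7)
#' A_x <- matrix(rnorm(27 * 6), 27)
#' A_y <- matrix(rnorm(27 * 5), 27)
#' pn <- permute_null(A_x, A_y, B = 99, seed = 1)
#' pn$p_value
#' @export
permute_null <- function(A_x, A_y, B = 1000,
                         scheme = c("within_column", "row_shuffle"),
                         shuffled_block = c("y", "x"),
                         seed = NULL, ridge = 0) {
  scheme <- match.arg(scheme)
  shuffled_block <- match.arg(shuffled_block)
  if (!is_count(B) || B < 1) abort_input("B must be a positive integer")
  A_x <- as_occasion_values(A_x)
  A_y <- as_occasion_values(A_y)

  observed <- fit_pcca(A_x, A_y, ridge = ridge)$rho[1]
  n <- nrow(A_x)
  seeds <- derive_seeds(seed %||% sample.int(.Machine$integer.max - 1L, 1), B)

  target <- if (shuffled_block == "y") A_y else A_x
  null_rhos <- numeric(B)
  for (b in seq_len(B)) {
    perm <- with_seed(seeds[b], {
      if (scheme == "within_column") {
        apply(target, 2, sample, size = n)
      } else {
        target[sample.int(n), , drop = FALSE]
      }
    })
    null_rhos[b] <- if (shuffled_block == "y") {
      fit_pcca(A_x, perm, ridge = ridge)$rho[1]
    } else {
      fit_pcca(perm, A_y, ridge = ridge)$rho[1]
    }
  }

  structure(list(
    null_rhos = null_rhos,
    observed = observed,
    p_value = empirical_p(observed, null_rhos),
    B = B, scheme = scheme, shuffled_block = shuffled_block,
    seed = seed
  ), class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat(sprintf(
    "permutation null: B = %d (%s, block %s)\n  observed r = %.3f, P = %.4g\n",
    x$B, x$scheme, x$shuffled_block, x$observed, x$p_value))
  invisible(x)
}

#' Null-distribution histogram data
#'
#' Bins the permutation null so the histogram can be drawn (or exported)
#' without a plotting dependency.
#'
#' @param pn a `permutation_null` object.
#' @param breaks passed to [graphics::hist()] logic via [base::cut()]; a
#'   single bin count (default 30).
#' @return a tibble with `bin_low`, `bin_high`, `count`.
#' @export
null_histogram <- function(pn, breaks = 30) {
  stopifnot(inherits(pn, "permutation_null"))
  edges <- seq(0, max(1, max(pn$null_rhos)), length.out = breaks + 1)
  idx <- cut(pn$null_rhos, edges, include.lowest = TRUE, labels = FALSE)
  tibble::tibble(
    bin_low = edges[-length(edges)],
    bin_high = edges[-1],
    count = tabulate(idx, nbins = breaks)
  )
}
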