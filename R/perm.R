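#' Difference in mean weekly reports
#'
#' The pre/post comparison statistic: \eqn{\Delta =} mean(post) -
#' mean(pre), in reports per week.  Negative values are declines.
#'
#' @param pre_counts,post_counts non-empty numeric vectors of weekly
#'   counts.
#' @return the difference in means \eqn{\Delta}.
#' @examples
#' diff_in_means(c(5, 7), c(2, 4))  # -3
#' @export
diff_in_means <- function(pre_counts, post_counts) {
  if (!length(pre_counts) || !length(post_counts))
    stop("both groups must be non-empty")
  mean(post_counts) - mean(pre_counts)
}

#' Permutation test of the pre/post difference in means
#'
#' Pools the two groups and relabels into groups of the original sizes.
#' When the number of distinct relabelings \eqn{\binom{n}{n_{pre}}} is at
#' most \code{n_perm} the null distribution is enumerated exactly and
#' \eqn{p} is the exact tail fraction; otherwise \code{n_perm} random
#' relabelings are drawn and the add-one estimate
#' \eqn{p = (1 + \#\{|\Delta^*| \ge |\Delta_{obs}|\})/(n_{perm} + 1)}
#' is used (one-sided variants drop the absolute values), which can
#' never report \eqn{p = 0}.
#'
#' @param pre_counts,post_counts weekly count vectors (combined length
#'   at least 2).
#' @param n_perm number of random relabelings (default 10000).
#' @param seed optional integer seed for reproducibility.
#' @param sidedness \code{"two_sided"} (default), \code{"greater"} or
#'   \code{"less"}.
#' @param method \code{"auto"} (exact when feasible, the default),
#'   \code{"exact"} (error if infeasible at \code{n_perm}), or
#'   \code{"sample"} (always Monte Carlo; useful for cross-checking the
#'   sampled path against enumeration).
#' @return object of class \code{"perm_result"}: list with
#'   \code{delta_obs}, \code{p_value}, \code{n_perm} (relabelings
#'   actually used), \code{exact} (logical), \code{seed},
#'   \code{sidedness}.
#' @examples
#' permutation_test(c(0, 1), c(5, 6))$p_value  # exact: 2/6
#' @export
permutation_test <- function(pre_counts, post_counts, n_perm = 10000,
                             seed = NULL, sidedness = c("two_sided",
                                                        "greater", "less"),
                             method = c("auto", "exact", "sample")) {
  sidedness <- match.arg(sidedness)
  method <- match.arg(method)
  n1 <- length(pre_counts)
  n2 <- length(post_counts)
  if (n1 + n2 < 2L || n1 < 1L || n2 < 1L)
    stop("need at least one observation per group")
  pooled <- c(pre_counts, post_counts)
  d_obs <- diff_in_means(pre_counts, post_counts)

  res <- function(p, nperm, exact) {
    structure(list(delta_obs = d_obs, p_value = p, n_perm = nperm,
                   exact = exact, seed = seed, sidedness = sidedness),
              class = "perm_result")
  }
  if (length(unique(pooled)) == 1L) {
    warning("degenerate pooled data (all values equal); p = 1 by convention")
    return(res(1, 0L, TRUE))
  }

  tot <- sum(pooled)
  n <- n1 + n2
  # delta* is determined by the sum s of the relabeled pre group:
  # delta* = (tot - s)/n2 - s/n1
  delta_from_pre_sum <- function(s) (tot - s) / n2 - s / n1
  tail_prob <- function(deltas, denom_add) {
    eps <- 1e-12 * max(1, abs(d_obs))
    hits <- switch(sidedness,
                   two_sided = sum(abs(deltas) >= abs(d_obs) - eps),
                   greater = sum(deltas >= d_obs - eps),
                   less = sum(deltas <= d_obs + eps))
    (hits + denom_add) / (length(deltas) + denom_add)
  }

  n_distinct <- choose(n, n1)
  if (method == "exact" && !(is.finite(n_distinct) && n_distinct <= n_perm))
    stop("exact enumeration infeasible: choose(", n, ", ", n1,
         ") exceeds n_perm")
  if (method != "sample" && is.finite(n_distinct) && n_distinct <= n_perm) {
    idx <- utils::combn(n, n1)
    sums <- colSums(matrix(pooled[idx], nrow = n1))
    p <- tail_prob(delta_from_pre_sum(sums), denom_add = 0)
    return(res(p, as.integer(n_distinct), TRUE))
  }

  if (!is.null(seed)) set.seed(seed)
  sums <- vapply(seq_len(n_perm),
                 function(b) sum(pooled[sample.int(n, n1)]), numeric(1))
  p <- tail_prob(delta_from_pre_sum(sums), denom_add = 1)
  res(p, as.integer(n_perm), FALSE)
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("Permutation test (%s, %s %d relabelings)\n",
              x$sidedness, if (x$exact) "exact," else "N =", x$n_perm))
  cat(sprintf("  delta (post - pre mean): %.4f\n", x$delta_obs))
  cat(sprintf("  p-value: %.4g\n", x$p_value))
  invisible(x)
}
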