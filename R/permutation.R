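#' @name permutation_tests
#' @title Permutation tests for small tissue cohorts
#'
#' @description Three two-sided permutation tests tailored to cohorts of a
#' handful of animals, where exact enumeration is cheap: a paired sign-flip
#' test on within-animal differences, a correlation test permuting one
#' variable against the other, and a difference-in-means test reshuffling
#' group labels. Each test enumerates the complete null set when feasible
#' (reported as `method = "exhaustive"`, with an exact rational p-value that
#' includes the identity arrangement) and otherwise Monte-Carlo samples the
#' null with the add-one correction `p = (k + 1) / (B + 1)`. Ties between a
#' permuted and the observed statistic count toward the numerator.
#'
#' @return An object of class `permutation_result`: list with
#'   `statistic_observed`, `p_value`, `n_permutations_used`, `method`
#'   (`"exhaustive"` or `"monte_carlo"`), and `seed` (Monte Carlo only).
NULL

perm_result <- function(stat, p, n_used, method, seed = NULL) {
  structure(list(statistic_observed = stat, p_value = p,
                 n_permutations_used = n_used, method = method, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation test (%s, %d permutations): statistic = %.4g, p = %.4g\n",
              x$method, x$n_permutations_used, x$statistic_observed, x$p_value))
  invisible(x)
}

# tolerance used when counting permuted |statistic| >= |observed|
.tie_tol <- function(obs) 1e-12 * max(1, abs(obs))

#' Paired sign-flip permutation test
#'
#' Tests whether paired differences are centred at zero. The statistic is the
#' mean difference; the null distribution flips each difference's sign
#' independently. All `2^n` sign patterns are enumerated when `2^n <= 2^20`.
#'
#' @param differences numeric vector of paired differences (n >= 1).
#' @param n_permutations Monte-Carlo sample size B (default 10000).
#' @param seed seed for the Monte-Carlo branch.
#' @param method `"auto"` (exhaustive when feasible), or force
#'   `"exhaustive"` / `"monte_carlo"`.
#' @rdname permutation_tests
#' @export
#' @examples
#' paired_signflip_test(rep(1, 7))$p_value  # 2 / 2^7
paired_signflip_test <- function(differences, n_permutations = 10000, seed = NULL,
                                 method = c("auto", "exhaustive", "monte_carlo")) {
  method <- match.arg(method)
  n <- length(differences)
  if (n == 0) stop_radecol("empty differences", "radecol_empty_result_error")
  obs <- mean(differences)
  tol <- .tie_tol(obs)
  if (method != "monte_carlo" && 2^n <= 2^20) {
    total <- 2^n
    count <- 0
    chunk <- 2^16
    for (start in seq(0, total - 1, by = chunk)) {
      idx <- start:min(start + chunk - 1, total - 1)
      signs <- vapply(seq_len(n) - 1L,
                      function(j) ifelse(bitwAnd(idx, bitwShiftL(1, j)) > 0, 1, -1),
                      numeric(length(idx)))
      stats <- as.vector(signs %*% differences) / n
      count <- count + sum(abs(stats) >= abs(obs) - tol)
    }
    return(perm_result(obs, count / total, total, "exhaustive"))
  }
  if (!is.null(seed)) set.seed(seed)
  B <- n_permutations
  signs <- matrix(sample(c(-1, 1), B * n, replace = TRUE), B, n)
  stats <- as.vector(signs %*% differences) / n
  k <- sum(abs(stats) >= abs(obs) - tol)
  perm_result(obs, (k + 1) / (B + 1), B, "monte_carlo", seed)
}

# all permutations of 1..n as an n! x n integer matrix (n <= 9 practical)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    others <- seq_len(n)[-i]
    cbind(rep.int(i, nrow(sub)), matrix(others[sub], nrow(sub)))
  }))
}

#' Permutation correlation test
#'
#' Tests association between two continuous variables. The statistic is the
#' Pearson correlation; the null permutes `y` against a fixed `x`. All `n!`
#' orderings are enumerated when `n! <= 1e6`.
#'
#' @param x,y paired numeric vectors (n >= 3, nonzero variance).
#' @rdname permutation_tests
#' @export
perm_corr_test <- function(x, y, n_permutations = 10000, seed = NULL,
                           method = c("auto", "exhaustive", "monte_carlo")) {
  method <- match.arg(method)
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3) stop_radecol("need at least 3 pairs", "radecol_empty_result_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_radecol("zero variance in x or y", "radecol_degenerate_error")
  obs <- stats::cor(x, y)
  tol <- .tie_tol(obs)
  xc <- x - mean(x)
  denom <- (n - 1) * stats::sd(x) * stats::sd(y)
  if (method != "monte_carlo" && factorial(n) <= 1e6) {
    perms <- all_permutations(n)
    rs <- as.vector(matrix(y[perms], nrow(perms)) %*% xc) / denom
    count <- sum(abs(rs) >= abs(obs) - tol)
    return(perm_result(obs, count / nrow(perms), nrow(perms), "exhaustive"))
  }
  if (!is.null(seed)) set.seed(seed)
  B <- n_permutations
  rs <- vapply(seq_len(B), function(b) sum(y[sample.int(n)] * xc), 0) / denom
  k <- sum(abs(rs) >= abs(obs) - tol)
  perm_result(obs, (k + 1) / (B + 1), B, "monte_carlo", seed)
}

#' Permutation difference-in-means test
#'
#' Tests a location difference between two groups. The statistic is
#' `mean(a) - mean(b)`; the null reshuffles group labels preserving group
#' sizes. All `C(n, n_a)` assignments are enumerated when that count is
#' at most `1e6`.
#'
#' @param group_a,group_b numeric vectors (both non-empty).
#' @rdname permutation_tests
#' @export
perm_meandiff_test <- function(group_a, group_b, n_permutations = 10000, seed = NULL,
                               method = c("auto", "exhaustive", "monte_carlo")) {
  method <- match.arg(method)
  na <- length(group_a); nb <- length(group_b)
  if (na == 0 || nb == 0)
    stop_radecol("both groups must be non-empty", "radecol_empty_result_error")
  z <- c(group_a, group_b); n <- na + nb
  obs <- mean(group_a) - mean(group_b)
  tol <- .tie_tol(obs)
  tot <- sum(z)
  if (method != "monte_carlo" && choose(n, na) <= 1e6) {
    idx <- utils::combn(n, na)
    sumA <- colSums(matrix(z[idx], nrow = na))
    stats <- sumA / na - (tot - sumA) / nb
    count <- sum(abs(stats) >= abs(obs) - tol)
    return(perm_result(obs, count / ncol(idx), ncol(idx), "exhaustive"))
  }
  if (!is.null(seed)) set.seed(seed)
  B <- n_permutations
  sumA <- vapply(seq_len(B), function(b) sum(z[sample.int(n, na)]), 0)
  stats <- sumA / na - (tot - sumA) / nb
  k <- sum(abs(stats) >= abs(obs) - tol)
  perm_result(obs, (k + 1) / (B + 1), B, "monte_carlo", seed)
}
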