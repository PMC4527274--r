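#' Site-pattern counts for a three-sequence alignment
#'
#' Columns containing any gap are eliminated first (complete deletion),
#' then every retained column falls in exactly one category: identical
#' in all three sequences, a unique difference in sequence A, B or C
#' (the other two agree), or divergent in all three. The five counts
#' sum to the retained column count.
#'
#' @param block An alignment tibble of exactly 3 members; rows are
#'   taken as sequences A, B, C in order.
#' @return A one-row tibble of class `trio_counts`: `identical`,
#'   `unique_a`, `unique_b`, `unique_c`, `divergent_all`,
#'   `total_sites`.
#' @export
trio_counts <- function(block) {
  if (nrow(block) != 3) {
    abort(sprintf("The relative rate test needs exactly 3 sequences, got %d.",
                  nrow(block)), class = "cblkit_arity_error")
  }
  mat <- alignment_matrix(block)
  keep <- colSums(mat == "-") == 0
  mat <- mat[, keep, drop = FALSE]
  a <- mat[1, ]; b <- mat[2, ]; c <- mat[3, ]
  identical_all <- a == b & b == c
  div_all <- a != b & b != c & a != c
  ua <- b == c & a != b
  ub <- a == c & a != b
  uc <- a == b & a != c
  out <- tibble::tibble(
    identical = sum(identical_all),
    unique_a = sum(ua),
    unique_b = sum(ub),
    unique_c = sum(uc),
    divergent_all = sum(div_all),
    total_sites = ncol(mat)
  )
  class(out) <- c("trio_counts", class(out))
  out
}

#' Upper-tail chi-square probability
#'
#' @param x Non-negative statistic value(s).
#' @param df Degrees of freedom (default 1).
#' @return `P(X >= x)` for a chi-square variable with `df` degrees of
#'   freedom; 1 at `x = 0`, strictly decreasing.
#' @export
chi2_upper_tail <- function(x, df = 1) {
  if (any(x < 0)) {
    abort("Chi-square statistic must be non-negative.",
          class = "cblkit_domain_error")
  }
  pchisq(x, df = df, lower.tail = FALSE)
}

#' Tajima's relative rate test
#'
#' Tests equality of substitution rates in two lineages A and B against
#' an outgroup C: with `m_a` sites changed only in A and `m_b` only in
#' B, the statistic `(m_a - m_b)^2 / (m_a + m_b)` is chi-square with 1
#' degree of freedom under rate equality.
#'
#' @param counts A `trio_counts` row (or anything with `unique_a` and
#'   `unique_b` fields).
#' @return An object of class `cbl_rrt` with fields `unique_a`,
#'   `unique_b`, `chi2`, `df` (1) and `p`; see [tidy()] / [glance()].
#' @export
relative_rate_test <- function(counts) {
  ua <- counts$unique_a
  ub <- counts$unique_b
  if (ua + ub == 0) {
    abort("Relative rate test is undefined when neither lineage has a unique difference.",
          class = "cblkit_undefined_test_error")
  }
  chi2 <- (ua - ub)^2 / (ua + ub)
  structure(
    list(unique_a = ua, unique_b = ub, chi2 = chi2, df = 1L,
         p = chi2_upper_tail(chi2, 1)),
    class = "cbl_rrt")
}

#' @export
print.cbl_rrt <- function(x, ...) {
  cat("Tajima's relative rate test\n")
  cat(sprintf("  unique differences: A = %d, B = %d\n",
              x$unique_a, x$unique_b))
  cat(sprintf("  chi-square = %.2f (df = 1), p = %.5f\n", x$chi2, x$p))
  invisible(x)
}

#' @rdname relative_rate_test
#' @param x A `cbl_rrt` object.
#' @param ... Unused.
#' @export
tidy.cbl_rrt <- function(x, ...) {
  tibble::tibble(unique_a = x$unique_a, unique_b = x$unique_b,
                 statistic = x$chi2, df = x$df, p.value = x$p)
}

#' @rdname relative_rate_test
#' @export
glance.cbl_rrt <- function(x, ...) tidy.cbl_rrt(x)

harmonic_sums <- function(m) {
  i <- seq_len(m - 1)
  list(a1 = sum(1 / i), a2 = sum(1 / i^2))
}

#' Watterson's per-site diversity estimate
#'
#' `theta = (S / n) / a1` where `a1` is the harmonic sum over `m - 1`
#' sequences, computed by direct summation.
#'
#' @param m Number of sequences (>= 2).
#' @param S Number of segregating sites.
#' @param n Total number of sites (>= 1).
#' @return Per-site theta.
#' @examples
#' watterson_theta(m = 327, S = 153, n = 153)
#' @export
watterson_theta <- function(m, S, n) {
  if (m < 2 || n < 1) abort("Need m >= 2 sequences and n >= 1 sites.")
  if (S > n) {
    abort("More segregating sites than sites.",
          class = "cblkit_inconsistency_error")
  }
  (S / n) / harmonic_sums(m)$a1
}

#' Tajima's D test of neutrality
#'
#' Computes the D statistic from the classical constants: with
#' `a1 = sum(1/i)`, `a2 = sum(1/i^2)` for `i` in `1..m-1`,
#' `b1 = (m+1)/(3(m-1))`, `b2 = 2(m^2+m+3)/(9m(m-1))`,
#' `c1 = b1 - 1/a1`, `c2 = b2 - (m+2)/(a1 m) + a2/a1^2`,
#' `e1 = c1/a1`, `e2 = c2/(a1^2+a2)`, the statistic is
#' `D = (pi n - S/a1) / sqrt(e1 S + e2 S (S-1))`. D > 0 indicates an
#' excess of intermediate-frequency variants (balancing selection /
#' population contraction), D < 0 an excess of rare variants.
#'
#' @param m Number of sequences (>= 4).
#' @param n Number of sites.
#' @param S Number of segregating sites (>= 1).
#' @param pi Per-site diversity (average pairwise difference per site).
#' @return An object of class `cbl_tajima_d` holding the inputs, all
#'   constants, `theta_per_site = (S/n)/a1`, `k_total = pi * n` and
#'   `D`; see [tidy()] / [glance()].
#' @examples
#' tajima_d(m = 327, n = 153, S = 153, pi = 0.385669)
#' @export
tajima_d <- function(m, n, S, pi) {
  if (m < 4) abort("Tajima's D needs at least 4 sequences.")
  if (S < 1) abort("Tajima's D needs at least one segregating site.")
  if (S > n) {
    abort("More segregating sites than sites.",
          class = "cblkit_inconsistency_error")
  }
  h <- harmonic_sums(m)
  a1 <- h$a1; a2 <- h$a2
  b1 <- (m + 1) / (3 * (m - 1))
  b2 <- 2 * (m^2 + m + 3) / (9 * m * (m - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (m + 2) / (a1 * m) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  var_term <- e1 * S + e2 * S * (S - 1)
  if (var_term <= 0) {
    abort("Degenerate variance term in Tajima's D.",
          class = "cblkit_degenerate_variance_error")
  }
  k_total <- pi * n
  D <- (k_total - S / a1) / sqrt(var_term)
  structure(
    list(m = m, n = n, S = S, pi = pi,
         a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
         e1 = e1, e2 = e2,
         ps = S / n, theta_per_site = (S / n) / a1,
         k_total = k_total, D = D),
    class = "cbl_tajima_d")
}

#' @export
print.cbl_tajima_d <- function(x, ...) {
  cat("Tajima's test of neutrality\n")
  cat(sprintf("  m = %d sequences, n = %d sites, S = %d, pi = %.6f\n",
              x$m, x$n, x$S, x$pi))
  cat(sprintf("  theta (per site) = %.6f, D = %.6f\n",
              x$theta_per_site, x$D))
  invisible(x)
}

#' @rdname tajima_d
#' @param x A `cbl_tajima_d` object.
#' @param ... Unused.
#' @export
tidy.cbl_tajima_d <- function(x, ...) {
  terms <- c("a1", "a2", "b1", "b2", "c1", "c2", "e1", "e2",
             "ps", "theta_per_site", "k_total", "D")
  tibble::tibble(term = terms,
                 estimate = vapply(terms, function(t) x[[t]], numeric(1)))
}

#' @rdname tajima_d
#' @export
glance.cbl_tajima_d <- function(x, ...) {
  tibble::tibble(m = x$m, n = x$n, S = x$S, pi = x$pi,
                 theta_per_site = x$theta_per_site, D = x$D)
}

#' Pairwise diversity, segregating sites and effective length
#'
#' Columns with less than `min_coverage` non-gap fraction are removed;
#' on the retained columns, diversity is the average over all
#' `m(m-1)/2` sequence pairs of the per-pair mismatch fraction
#' (computed over positions where both members are ungapped), and `S`
#' counts retained columns with two or more residue states.
#'
#' @param block An alignment tibble (>= 2 members).
#' @param min_coverage Minimum per-column non-gap fraction (default
#'   0.95, i.e. fewer than 5 percent gaps allowed at any position).
#' @return A one-row tibble: `m`, `n_effective`, `S`, `pi`.
#' @export
pairwise_diversity <- function(block, min_coverage = 0.95) {
  mat <- alignment_matrix(block)
  m <- nrow(mat)
  cov <- colMeans(mat != "-")
  mat <- mat[, cov >= min_coverage, drop = FALSE]
  n_eff <- ncol(mat)
  if (n_eff == 0) {
    abort("No columns pass the coverage filter.",
          class = "cblkit_empty_alignment_error")
  }
  S <- sum(apply(mat, 2, function(col) {
    length(unique(col[col != "-"])) >= 2
  }))
  pair_fracs <- c()
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      both <- mat[i, ] != "-" & mat[j, ] != "-"
      if (any(both)) {
        pair_fracs <- c(pair_fracs,
                        mean(mat[i, both] != mat[j, both]))
      }
    }
  }
  tibble::tibble(m = m, n_effective = n_eff, S = S,
                 pi = mean(pair_fracs))
}

#' Tajima's neutrality test straight from an alignment
#'
#' Convenience wrapper: [pairwise_diversity()] then [tajima_d()].
#'
#' @inheritParams pairwise_diversity
#' @return A `cbl_tajima_d` object.
#' @export
tajima_test <- function(block, min_coverage = 0.95) {
  d <- pairwise_diversity(block, min_coverage)
  tajima_d(m = d$m, n = d$n_effective, S = d$S, pi = d$pi)
}
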