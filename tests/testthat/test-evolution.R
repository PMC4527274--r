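test_that("trio site patterns partition retained columns", {
  b1 <- protein_records(c("a", "b", "c"), rep("AAA", 3), aligned = TRUE)
  t1 <- trio_counts(b1)
  expect_equal(t1$identical, 3)
  expect_equal(t1$unique_a + t1$unique_b + t1$unique_c +
                 t1$divergent_all, 0)

  b2 <- protein_records(c("a", "b", "c"), c("DAG", "EAG", "DAG"),
                        aligned = TRUE)
  t2 <- trio_counts(b2)
  expect_equal(t2$unique_b, 1)
  expect_equal(t2$identical, 2)

  # gapped columns are eliminated before counting
  b3 <- protein_records(c("a", "b", "c"), c("D-G", "E-G", "DAG"),
                        aligned = TRUE)
  t3 <- trio_counts(b3)
  expect_equal(t3$total_sites, 2)

  expect_error(
    trio_counts(protein_records(c("a", "b"), c("AA", "AA"),
                                aligned = TRUE)),
    class = "cblkit_arity_error")

  # planted-pattern recovery across random specs
  set.seed(77)
  for (rep in 1:40) {
    spec <- list(ua = sample(0:20, 1), ub = sample(0:20, 1),
                 uc = sample(0:20, 1), id = sample(1:50, 1),
                 div = sample(0:10, 1))
    trio <- simulate_trio(spec$ua, spec$ub, spec$uc, spec$id,
                          spec$div, seed = rep)
    counts <- trio_counts(trio)
    expect_equal(counts$unique_a, spec$ua)
    expect_equal(counts$unique_b, spec$ub)
    expect_equal(counts$unique_c, spec$uc)
    expect_equal(counts$identical, spec$id)
    expect_equal(counts$divergent_all, spec$div)
    expect_equal(counts$total_sites,
                 spec$ua + spec$ub + spec$uc + spec$id + spec$div)
  }
})

test_that("relative rate test reproduces the published trio statistics", {
  configs <- list(c(1, 10), c(4, 18), c(36, 16))
  chi2_expected <- c(7.36, 8.91, 7.69)
  p_expected <- c(0.00666, 0.00284, 0.00555)
  for (i in 1:3) {
    r <- relative_rate_test(list(unique_a = configs[[i]][1],
                                 unique_b = configs[[i]][2]))
    expect_equal(round(r$chi2, 2), chi2_expected[i])
    expect_equal(round(r$p, 5), p_expected[i])
    expect_equal(r$df, 1L)
    # symmetry under swapping lineages A and B
    r_swap <- relative_rate_test(list(unique_a = configs[[i]][2],
                                      unique_b = configs[[i]][1]))
    expect_equal(r_swap$chi2, r$chi2)
    expect_equal(r_swap$p, r$p)
  }
  r0 <- relative_rate_test(list(unique_a = 5, unique_b = 5))
  expect_equal(r0$chi2, 0)
  expect_equal(r0$p, 1)
  expect_error(relative_rate_test(list(unique_a = 0, unique_b = 0)),
               class = "cblkit_undefined_test_error")

  td <- tidy(relative_rate_test(list(unique_a = 1, unique_b = 10)))
  expect_equal(td$statistic, 81 / 11)
  expect_named(td, c("unique_a", "unique_b", "statistic", "df",
                     "p.value"))
})

test_that("chi-square upper tail matches numeric integration of the density", {
  expect_equal(chi2_upper_tail(0), 1)
  expect_equal(round(chi2_upper_tail(8.91), 5), 0.00284)
  expect_error(chi2_upper_tail(-1), class = "cblkit_domain_error")
  dens <- function(x) exp(-x / 2) / sqrt(2 * base::pi * x)
  for (x in c(0.5, 1, 3.84, 7.36)) {
    numeric_tail <- stats::integrate(dens, x, Inf, rel.tol = 1e-10)$value
    expect_equal(chi2_upper_tail(x), numeric_tail, tolerance = 1e-8)
  }
  expect_lt(abs(chi2_upper_tail(3.84) - 0.05), 1e-3)
  xs <- seq(0, 10, 0.5)
  expect_true(all(diff(chi2_upper_tail(xs)) < 0))
})

test_that("Watterson's theta uses direct harmonic summation", {
  expect_equal(round(watterson_theta(327, 153, 153), 6), 0.157093)
  expect_equal(watterson_theta(10, 0, 100), 0)
  expect_equal(watterson_theta(2, 7, 100), 7 / 100)
  expect_error(watterson_theta(10, 101, 100),
               class = "cblkit_inconsistency_error")
})

test_that("Tajima's D matches published values and an independent oracle", {
  td <- tajima_d(m = 327, n = 153, S = 153, pi = 0.385669)
  expect_lt(abs(td$D - 4.4137), 0.001)
  expect_equal(round(td$theta_per_site, 6), 0.157093)
  expect_equal(round(td$ps, 6), 1)

  # numerator-null case: pi * n = S / a1 exactly
  a1 <- sum(1 / (1:19))
  td0 <- tajima_d(m = 20, n = 100, S = 30, pi = (30 / a1) / 100)
  expect_equal(td0$D, 0)

  # independent from-scratch constant computation
  set.seed(5)
  for (rep in 1:20) {
    m <- sample(4:400, 1); n <- sample(50:500, 1)
    S <- sample(1:n, 1); pi <- runif(1, 0, 0.5)
    expect_equal(tajima_d(m, n, S, pi)$D, oracle_tajima_d(m, n, S, pi),
                 tolerance = 1e-12)
  }

  # D strictly increases in pi, all else fixed
  ds <- vapply(seq(0.05, 0.5, 0.05),
               function(p) tajima_d(20, 100, 40, p)$D, numeric(1))
  expect_true(all(diff(ds) > 0))

  # harmonic sums match direct summation over a wide m range
  for (m in c(4, 10, 100, 1000, 10000)) {
    h <- cblkit:::harmonic_sums(m)
    expect_equal(h$a1, sum(1 / seq_len(m - 1)), tolerance = 1e-14)
    expect_equal(h$a2, sum(1 / seq_len(m - 1)^2), tolerance = 1e-14)
  }

  g <- glance(td)
  expect_equal(g$D, td$D)
  expect_equal(nrow(tidy(td)), 12)
})

test_that("pairwise diversity equals the exhaustive pair loop", {
  two_same <- protein_records(c("a", "b"), c("MKTV", "MKTV"),
                              aligned = TRUE)
  d0 <- pairwise_diversity(two_same)
  expect_equal(d0$pi, 0)
  expect_equal(d0$S, 0)

  d1 <- pairwise_diversity(
    protein_records(c("a", "b"), c("AD", "AE"), aligned = TRUE))
  expect_equal(d1$pi, 0.5)
  expect_equal(d1$S, 1)
  expect_equal(d1$n_effective, 2)

  for (seed in 1:10) {
    sim <- simulate_alignment(m = 10, n = 50, S = sample(0:50, 1),
                              seed = seed)
    if (sim$truth$S == 0) next
    d <- pairwise_diversity(sim$block)
    mat <- matrix(unlist(strsplit(sim$block$sequence, "")),
                  nrow = 10, byrow = TRUE)
    expect_equal(d$pi, oracle_pairwise_pi(mat), tolerance = 1e-12)
    expect_equal(d$pi, sim$truth$pi, tolerance = 1e-12)
    expect_equal(d$S, sim$truth$S)
  }

  # coverage filter: a column with 2 of 20 gapped members (90%) drops
  set.seed(4)
  base <- replicate(20, random_protein(10))
  mat <- matrix(unlist(strsplit(base, "")), nrow = 20, byrow = TRUE)
  mat[1:2, 5] <- "-"
  block <- protein_records(paste0("s", 1:20),
                           apply(mat, 1, paste, collapse = ""),
                           aligned = TRUE)
  d <- pairwise_diversity(block, min_coverage = 0.95)
  expect_equal(d$n_effective, 9)

  all_gap <- protein_records(c("a", "b"), c("--", "--"), aligned = TRUE)
  expect_error(pairwise_diversity(all_gap),
               class = "cblkit_empty_alignment_error")
})

test_that("tajima_test wraps diversity and the D computation coherently", {
  sim <- simulate_alignment(m = 20, n = 100, S = 40, seed = 9)
  td <- tajima_test(sim$block)
  direct <- tajima_d(m = 20, n = 100, S = 40, pi = sim$truth$pi)
  expect_equal(td$D, direct$D, tolerance = 1e-12)
})
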