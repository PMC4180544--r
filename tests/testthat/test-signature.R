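test_that("d and s match hand-evaluated values on 3-sample vectors", {
  high <- matrix(c(1, 2, 3), 1); low <- matrix(c(0, 1, 2), 1)
  st <- relative_difference(high, low, s0 = 0)
  s_hand <- sqrt((1 / (3 * 2)) * (2 + 2))  # SS_H = SS_L = 2
  expect_equal(st$s, s_hand, tolerance = 1e-12)
  expect_equal(st$d, 1 / s_hand, tolerance = 1e-12)
  st2 <- relative_difference(high, low, s0 = 0.18350)
  expect_equal(st2$d, 1 / (s_hand + 0.18350), tolerance = 1e-12)
  # identical groups: d exactly 0
  st3 <- relative_difference(high, high, s0 = 0)
  expect_identical(st3$d, 0)
})

test_that("with s0 = 0 the statistic equals the pooled-SE two-sample t", {
  set.seed(71)
  for (N in c(3, 8, 26)) {
    high <- matrix(rnorm(20 * N), 20); low <- matrix(rnorm(20 * N), 20)
    st <- relative_difference(high, low, s0 = 0)
    for (g in c(1, 7, 20)) {
      tt <- t.test(high[g, ], low[g, ], var.equal = TRUE)
      expect_equal(st$d[g], unname(tt$statistic), tolerance = 1e-10)
    }
  }
})

test_that("d is antisymmetric under group swap; guards fire", {
  set.seed(73)
  high <- matrix(rnorm(30), 5); low <- matrix(rnorm(30), 5)
  expect_equal(relative_difference(high, low)$d,
               -relative_difference(low, high)$d, tolerance = 1e-14)
  expect_error(relative_difference(high, low[, 1:5]), "equal group sizes")
  expect_error(relative_difference(high[, 1, drop = FALSE],
                                   low[, 1, drop = FALSE]), "at least 2")
  # zero scatter and zero s0 flagged as degenerate
  h <- matrix(rep(1, 6), 2); l <- matrix(rep(0, 6), 2)
  st <- relative_difference(h, l, s0 = 0)
  expect_true(all(st$degenerate))
  expect_true(all(is.infinite(st$d)))
})

test_that("the s0 schedule is non-increasing in the scatter", {
  hn <- hetero_null(n_genes = 500, N = 10, seed = 75)
  sched <- fit_s0_schedule(hn$high, hn$low)
  st <- relative_difference(hn$high, hn$low, s0 = sched)
  o <- order(st$s)
  expect_true(all(diff(st$s0[o]) <= 1e-12))
  expect_equal(st$s0[which.max(st$s)], 0, tolerance = 1e-12)
})

test_that("the fitted schedule stabilizes heteroscedastic d and is idle on homoscedastic data", {
  decile_cv <- function(st) {
    dec <- cut(rank(st$s) / length(st$s), seq(0, 1, 0.1),
               include.lowest = TRUE, labels = FALSE)
    med <- tapply(abs(st$d), dec, median)
    sd(med) / mean(med)
  }
  hn <- hetero_null(n_genes = 2000, N = 26, seed = 77)
  sched <- fit_s0_schedule(hn$high, hn$low)
  cv_fit <- decile_cv(relative_difference(hn$high, hn$low, s0 = sched))
  cv_zero <- decile_cv(relative_difference(hn$high, hn$low, s0 = 0))
  expect_lt(cv_fit, cv_zero)
  expect_gt(sched$s0_max, 0)

  # homoscedastic null: nothing to stabilize, criterion flat near s0 = 0
  set.seed(79)
  high <- matrix(rnorm(1000 * 26), 1000); low <- matrix(rnorm(1000 * 26), 1000)
  sched0 <- fit_s0_schedule(high, low)
  st0 <- relative_difference(high, low, s0 = 0)
  expect_lt(sched0$criterion, decile_cv(st0) * 1.25)
})

test_that("spread of d in the lowest scatter decile shrinks as s0_max grows", {
  hn <- hetero_null(n_genes = 1000, N = 15, seed = 81)
  s <- statresp:::gene_scatter(hn$high, hn$low)
  low_dec <- s <= quantile(s, 0.1)
  Fh <- ecdf(s)
  spread <- vapply(quantile(s, c(0, 0.05, 0.1, 0.2)), function(s0m) {
    d <- (rowMeans(hn$high) - rowMeans(hn$low)) / (s + s0m * (1 - Fh(s)))
    sd(d[low_dec])
  }, numeric(1))
  expect_true(all(diff(spread) < 0))
})

test_that("pooled permutation p-values hit the formula floor and respect relabeling", {
  set.seed(83)
  high <- matrix(rnorm(50 * 8), 50); low <- matrix(rnorm(50 * 8), 50)
  high[1, ] <- high[1, ] + 50  # |d| beyond every sampled permuted value
  st <- permutation_pvalues(high, low, schedule = 0, n_perm = 200, seed = 3)
  n_tot <- attr(st, "n_perm_used") * nrow(high)
  expect_equal(st$p_perm[1], 1 / (1 + n_tot), tolerance = 1e-14)
  expect_identical(st$rank[1], 1L)

  # N = 4 per group: all 70 balanced splits are enumerated, so the null is
  # exact and relabeling invariance holds to machine precision
  h4 <- matrix(rnorm(50 * 4), 50); l4 <- matrix(rnorm(50 * 4), 50)
  st4 <- permutation_pvalues(h4, l4, schedule = 0, n_perm = 200, seed = 3)
  st4b <- permutation_pvalues(h4[, c(3, 1, 2, 4)], l4, schedule = 0,
                              n_perm = 200, seed = 99)
  expect_equal(st4b$p_perm, st4$p_perm, tolerance = 1e-14)
})

test_that("tiny groups trigger exhaustive enumeration of balanced splits", {
  set.seed(85)
  high <- matrix(rnorm(10 * 2), 10); low <- matrix(rnorm(10 * 2), 10)
  st <- permutation_pvalues(high, low, n_perm = 500, seed = 5)
  expect_identical(attr(st, "n_perm_used"), 6L)  # choose(4, 2)
})

test_that("per-gene pooling gives coarser p-values on the per-gene grid", {
  set.seed(87)
  high <- matrix(rnorm(30 * 6), 30); low <- matrix(rnorm(30 * 6), 30)
  st <- permutation_pvalues(high, low, n_perm = 100, pooling = "per_gene",
                            seed = 7)
  n_used <- attr(st, "n_perm_used")
  expect_true(all(abs(st$p_perm * (1 + n_used) -
                        round(st$p_perm * (1 + n_used))) < 1e-9))
})

test_that("signature selection ranks planted genes first", {
  sg <- shifted_groups(n_genes = 300, n_shift = 25, N = 12, delta = 1.5,
                       seed = 89)
  st <- permutation_pvalues(sg$high, sg$low,
                            schedule = fit_s0_schedule(sg$high, sg$low),
                            n_perm = 200, seed = 9)
  top <- select_signature(st, n_select = 25)
  expect_gte(length(intersect(top$gene, sg$shifted)), 20)
  expect_true(all(top$direction[top$d > 0] == "up_in_high"))
  # n_select = n_genes returns every gene exactly once
  all_g <- select_signature(st, n_select = 300)
  expect_setequal(all_g$gene, st$gene)
})

test_that("hypergeometric enrichment matches a brute-force tail sum", {
  # independent oracle: exact tail sum over log-binomials
  tail_sum <- function(k, nq, nr, nu) {
    i <- k:min(nq, nr)
    sum(exp(lchoose(nr, i) + lchoose(nu - nr, nq - i) - lchoose(nu, nq)))
  }
  universe <- sprintf("g%05d", 1:20000)
  ref <- universe[1:3170]
  query <- c(universe[1:48], universe[10001:10052])  # overlap 48 of 100
  res <- overlap_enrichment(query, ref, universe)
  expect_identical(res$overlap, 48L)
  expect_equal(res$p_value, tail_sum(48, 100, 3170, 20000),
               tolerance = 1e-12)
  # disjoint query: observing >= 0 overlaps is certain
  res0 <- overlap_enrichment(universe[5001:5010], universe[1:10], universe)
  expect_identical(res0$p_value, 1)
  # full containment is the most extreme configuration of its size
  res_full <- overlap_enrichment(universe[1:10], universe[1:100], universe)
  res_part <- overlap_enrichment(c(universe[1:9], universe[200]),
                                 universe[1:100], universe)
  expect_lt(res_full$p_value, res_part$p_value)
  expect_error(overlap_enrichment("a", "a", character()), "empty universe")
})
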