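# Independent direct-formula oracle for purity/entropy, written against the
# contingency table from first principles (loops, no shared code).
oracle_quality <- function(assignments, labels) {
  n <- length(assignments)
  cl <- unique(assignments); cs <- unique(labels)
  purity <- 0; entropy <- 0
  for (i in cl) {
    in_i <- assignments == i
    n_i <- sum(in_i)
    best <- 0
    for (j in cs) {
      nij <- sum(in_i & labels == j)
      if (nij > best) best <- nij
      if (nij > 0) entropy <- entropy - nij * log2(nij / n_i)
    }
    purity <- purity + best
  }
  list(purity = purity / n, entropy = entropy / (n * log2(length(cs))))
}

test_that("purity and entropy match exhaustive enumeration for small n", {
  for (l in 2:3) {
    n <- 6L
    labels <- rep(seq_len(l), length.out = n)
    # all k^n assignments for k = 2 and k = 3
    for (k in 2:3) {
      grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
      for (r in seq(1, nrow(grid), by = 7)) {  # stride: still hundreds of cases
        a <- as.integer(grid[r, ])
        q <- cluster_quality(a, labels)
        o <- oracle_quality(a, labels)
        expect_equal(q$purity, o$purity, tolerance = 1e-12)
        expect_equal(q$entropy, o$entropy, tolerance = 1e-12)
      }
    }
  }
})

test_that("purity and entropy reproduce hand-computed cases", {
  # perfect 2x2 match
  q <- cluster_quality(rep(1:2, each = 4), rep(c("A", "B"), each = 4))
  expect_identical(q$purity, 1)
  expect_identical(q$entropy, 0)
  # one cluster holding 4+4 of two classes: purity 1/2, entropy 1
  q <- cluster_quality(rep(1, 8), rep(c("A", "B"), each = 4))
  expect_identical(q$purity, 0.5)
  expect_identical(q$entropy, 1)
  # clusters {3A, 1B} and {0A, 4B}
  q <- cluster_quality(c(1, 1, 1, 1, 2, 2, 2, 2),
                       c("A", "A", "A", "B", "B", "B", "B", "B"))
  expect_identical(q$purity, 7 / 8)
})

test_that("purity is invariant under cluster relabeling, entropy under class relabeling", {
  set.seed(51)
  for (rep_ in 1:20) {
    a <- sample(1:3, 12, replace = TRUE)
    lab <- sample(c("x", "y"), 12, replace = TRUE)
    if (length(unique(lab)) < 2) next
    perm <- sample(3)
    q1 <- cluster_quality(a, lab)
    q2 <- cluster_quality(perm[a], lab)
    expect_equal(q1$purity, q2$purity, tolerance = 1e-14)
    q3 <- cluster_quality(a, c(x = "y", y = "x")[lab])
    expect_equal(q1$entropy, q3$entropy, tolerance = 1e-14)
  }
  expect_error(cluster_quality(1:4, rep("A", 4)), "single true class")
})

test_that("the 1 - P transform maps standardized values through the normal CDF", {
  set.seed(53)
  m <- matrix(rnorm(30 * 21), 30,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:21)))
  m <- t(scale(t(m)))  # per-gene mean 0, sd 1
  attr(m, "state") <- "fully_normalized"
  a <- nonnegativize(m)
  expect_true(all(a > 0 & a < 1))
  # a value at the gene mean maps to 1/2
  m2 <- m; m2[1, 1] <- mean(m2[1, -1])
  m2[1, ] <- (m2[1, ] - mean(m2[1, ])) / sd(m2[1, ])
  z <- (m2[1, 1] - mean(m2[1, ])) / sd(m2[1, ])
  attr(m2, "state") <- "fully_normalized"
  expect_equal(unname(nonnegativize(m2)[1, 1]), pnorm(z), tolerance = 1e-12)
  # z = 1.645 maps near 0.95
  i <- which.min(abs(m[2, ] - 1.645))
  m[2, i] <- 1.645
  m[2, ] <- (m[2, ] - mean(m[2, ])) / sd(m[2, ])
  a2 <- nonnegativize(m)
  expect_equal(unname(a2[2, i]), pnorm(m[2, i]), tolerance = 1e-12)
  # monotone within each gene
  for (g in 1:5) {
    o <- order(m[g, ])
    expect_true(all(diff(a[g, o]) > 0))
  }
  # raw input is rejected
  raw <- matrix(runif(10), 2); attr(raw, "state") <- "raw"
  expect_error(nonnegativize(raw), "fully normalized")
})

test_that("an exact non-negative rank-2 matrix is recovered", {
  set.seed(55)
  W0 <- matrix(runif(60 * 2), 60, 2)
  H0 <- matrix(runif(2 * 20), 2, 20)
  A <- W0 %*% H0
  fit <- nmf_factorize(A, k = 2, n_runs = 10, seed = 3)
  expect_lt(fit$reconstruction_error / sqrt(sum(A^2)), 1e-6)
  expect_true(all(fit$W >= 0) && all(fit$H >= 0))
})

test_that("the reconstruction error trace is non-increasing", {
  set.seed(57)
  A <- matrix(runif(200 * 52), 200, 52)
  for (k in c(2, 4)) {
    fit <- nmf_factorize(A, k = k, n_runs = 2, max_iter = 300, seed = 5)
    tr <- fit$trace
    expect_true(all(diff(tr) <= 1e-10 * tr[-length(tr)]))
  }
})

test_that("k = 1 assigns every sample to one cluster", {
  set.seed(59)
  A <- matrix(runif(30 * 10), 30, 10,
              dimnames = list(NULL, sprintf("s%02d", 1:10)))
  fit <- nmf_factorize(A, k = 1, n_runs = 3, seed = 7)
  expect_true(all(fit$assignments == 1L))
  # rank-1 oracle: leading right singular vector (non-negative for A >= 0)
  expect_gt(abs(cor(fit$H[1, ], svd(A)$v[, 1])), 0.999)
})

test_that("planted two-block data are clustered correctly", {
  bl <- block_matrix(seed = 61)
  fit <- nmf_factorize(bl$A, k = 2, n_runs = 5, seed = 9)
  q <- cluster_quality(fit$assignments, bl$labels)
  expect_identical(q$purity, 1)
  # agrees with an independent clustering oracle (k-means on columns)
  km <- kmeans(t(bl$A), centers = 2, nstart = 10)
  expect_identical(cluster_quality(km$cluster, fit$assignments)$purity, 1)
})

test_that("consensus diagnostics separate stable from unstable ranks", {
  bl <- block_matrix(n_genes = 40, n_per_group = 8, seed = 63)
  cons <- consensus_diagnostics(bl$A, ranks = 2:4, n_runs = 15,
                                max_iter = 500, seed = 11)
  # all runs agree at k = 2 on clean blocks: binary consensus, dispersion 1
  C2 <- cons$k2$consensus
  expect_true(all(C2 %in% c(0, 1)))
  expect_equal(cons$k2$dispersion, 1, tolerance = 1e-12)
  # the planted rank is the most stable
  expect_gt(cons$k2$cophenetic_correlation,
            max(cons$k3$cophenetic_correlation,
                cons$k4$cophenetic_correlation) - 1e-8)
  expect_gt(cons$k2$dispersion, cons$k3$dispersion - 1e-8)
  expect_error(consensus_diagnostics(bl$A, ranks = 2, n_runs = 1), "n_runs")
})

test_that("random data give a diffuse consensus at k = 2", {
  set.seed(65)
  A <- matrix(runif(40 * 16), 40, 16,
              dimnames = list(NULL, sprintf("s%02d", 1:16)))
  cons <- consensus_diagnostics(A, ranks = 2, n_runs = 25, max_iter = 300,
                                seed = 13)
  off_diag <- cons$k2$consensus[upper.tri(cons$k2$consensus)]
  expect_lt(cons$k2$dispersion, 0.9)
  expect_gt(mean(off_diag > 0.05 & off_diag < 0.95), 0.2)
})

test_that("tail selection finds pure tails in a strong cohort and not in a null", {
  co <- strong_cohort(seed = 67, n_samples = 120)
  pr <- prep_cohort(co)
  sel <- select_tail_subset(pr$expression, pr$responses,
                            N_grid = c(20L, 30L, 40L),
                            n_genes_preselect = 200L, n_random_sets = 10L,
                            n_runs = 5L, max_iter = 500L, seed = 15L)
  expect_true(all(sel$curve$purity_true >= 0.9))
  expect_true(all(sel$curve$purity_true > sel$curve$purity_random))
  expect_identical(sel$chosen_n, 40L)
  expect_length(sel$high_ids, 20L)
  expect_length(intersect(sel$high_ids, sel$low_ids), 0L)
  # high tail really is the top of the response distribution
  expect_true(all(pr$responses[sel$high_ids] >
                    max(pr$responses[sel$low_ids])))

  con <- null_cohort(seed = 69, n_samples = 120)
  prn <- prep_cohort(con)
  seln <- suppressWarnings(select_tail_subset(
    prn$expression, prn$responses, N_grid = c(20L, 30L),
    n_genes_preselect = 150L, n_random_sets = 10L, n_runs = 5L,
    max_iter = 500L, seed = 17L))
  # exchangeable under the null: the two purities share a distribution, so
  # their grid means agree up to single-realization noise
  expect_lt(abs(mean(seln$curve$purity_true) -
                  mean(seln$curve$purity_random)), 0.25)
})
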