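test_that("rank AUC behaves like the Mann-Whitney statistic", {
  # positives (5, 3) vs negatives (1, 2, 4, 0): 7 of 8 pairs won
  sc <- c(5, 3, 1, 2, 4, 0); lab <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  expect_equal(rank_auc(sc, lab), 0.875, tolerance = 1e-12)
  # invariant under strictly monotone transforms of the scores
  expect_identical(rank_auc(exp(3 * sc) - 1, lab), rank_auc(sc, lab))
  expect_identical(rank_auc(rank(sc), lab), rank_auc(sc, lab))
  # perfect separation
  expect_identical(rank_auc(c(1, 2, 3, 4), c(F, F, T, T)), 1)
  # ties count a half
  expect_equal(rank_auc(c(1, 1), c(TRUE, FALSE)), 0.5, tolerance = 1e-12)
  expect_error(rank_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
  skip_if_not_installed("pROC")
  set.seed(93)
  s <- rnorm(60); l <- rbinom(60, 1, 0.5) == 1
  expect_equal(rank_auc(s, l),
               as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("separable clusters are classified; XOR needs the RBF kernel", {
  set.seed(95)
  tr <- rbind(matrix(rnorm(40, -3, .5), 20, 2),
              matrix(rnorm(40, 3, .5), 20, 2))
  y <- factor(rep(c("a", "b"), each = 20))
  sc <- svm_train_predict(tr, y, rbind(c(-3, -3), c(3, 3)), "classify")
  expect_true(sc[1] < 0 && sc[2] > 0)

  # XOR pattern is not linearly separable, yet RBF fits it (points on the
  # axes are excluded: they are ambiguous for any smooth classifier)
  n <- 300
  X <- matrix(runif(2 * n, -1, 1), n, 2)
  X <- X[abs(X[, 1] * X[, 2]) > 0.05, ]
  xr <- factor(X[, 1] * X[, 2] > 0)
  scores <- svm_train_predict(X, xr, X, "classify")
  acc <- mean((scores > 0) == (xr == levels(xr)[2]))
  expect_gt(acc, 0.95)
  # while the best linear separator hovers near chance
  lin <- glm((xr == levels(xr)[2]) ~ X, family = binomial)
  acc_lin <- mean((fitted(lin) > 0.5) == (xr == levels(xr)[2]))
  expect_gt(acc - acc_lin, 0.25)
})

test_that("regression on constant targets stays inside the epsilon tube", {
  set.seed(97)
  X <- matrix(rnorm(60), 20, 3)
  pred <- svm_train_predict(X, rep(5, 20), X, "regress")
  expect_true(all(abs(pred - 5) < 0.1 + 1e-8))
})

test_that("standardization statistics come from the training split only", {
  set.seed(99)
  train <- matrix(rnorm(40), 20, 2)
  test <- matrix(rnorm(10, 50, 1), 5, 2)  # held-out outliers
  std <- statresp:::standardize_train_test(train, test)
  expect_equal(unname(colMeans(std$train)), c(0, 0), tolerance = 1e-12)
  # the outlier fold must NOT be centered: full-data statistics would be
  expect_true(all(std$test > 10))
  expect_equal(unname(std$test[1, 1]),
               (test[1, 1] - mean(train[, 1])) / sd(train[, 1]),
               tolerance = 1e-12)
})

test_that("null features give chance AUC; a separating feature gives 1", {
  set.seed(101)
  X <- matrix(rnorm(80 * 5), 80)
  y <- rep(c(TRUE, FALSE), 40)
  res <- repeated_holdout_auc(X, y, cv_scheme(60, seed = 1))
  expect_lt(abs(res$mean - 0.5), 0.06)
  Xs <- cbind(X, ifelse(y, 1, 0) + rnorm(80, 0, 0.01))
  res1 <- repeated_holdout_auc(Xs, y, cv_scheme(20, seed = 2))
  expect_identical(res1$mean, 1)
})

test_that("the Monte-Carlo SE shrinks like 1/sqrt(repeats)", {
  set.seed(103)
  X <- matrix(rnorm(60 * 4), 60)
  y <- X[, 1] + rnorm(60) > 0
  r100 <- repeated_holdout_auc(X, y, cv_scheme(100, seed = 3))
  r400 <- repeated_holdout_auc(X, y, cv_scheme(400, seed = 4))
  ratio <- r100$se / r400$se
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 2.8)
})

test_that("tail fraction 1 reduces to a median split of the cohort", {
  co <- strong_cohort(seed = 105, n_samples = 60)
  pr <- prep_cohort(co)
  X <- t(pr$expression[co$truth$signature_genes, names(pr$responses)])
  sw <- tail_sweep(X, pr$responses, fractions = 1, cv_scheme(15, seed = 5))
  ordered <- names(sort(pr$responses, decreasing = TRUE))
  lab <- rownames(X) %in% ordered[1:30]
  direct <- repeated_holdout_auc(X[c(ordered[1:30], rev(ordered)[1:30]), ],
                                 rep(c(TRUE, FALSE), each = 30),
                                 cv_scheme(15, seed = 5 + 1))
  expect_equal(sw$auc, direct$mean, tolerance = 1e-12)
  expect_identical(sw$n, 60L)
  # fractions leaving fewer than 4 samples per tail are skipped
  expect_warning(sw2 <- tail_sweep(X, pr$responses,
                                   fractions = c(0.05, 1),
                                   cv_scheme(5, seed = 7)), "skipped")
  expect_identical(nrow(sw2), 1L)
})

test_that("explained variance recovers exact signal and rejects noise", {
  set.seed(107)
  X <- matrix(rnorm(150 * 2), 150)
  y_exact <- 2 * X[, 2]
  ev <- explained_variance(X, y_exact, cv_scheme(40, seed = 9))
  expect_gt(ev$mean, 95)
  y_noise <- rnorm(150)
  evn <- explained_variance(X, y_noise, cv_scheme(60, seed = 11))
  expect_lt(evn$mean, 5)
  expect_gte(evn$mean, 0)
})

test_that("label permutation is a global negative control", {
  co <- strong_cohort(seed = 109, n_samples = 80)
  pr <- prep_cohort(co)
  X <- t(pr$expression[co$truth$signature_genes, names(pr$responses)])
  y <- unname(pr$responses)
  ev_true <- explained_variance(X, y, cv_scheme(40, seed = 13))
  set.seed(15)
  ev_perm <- explained_variance(X, sample(y), cv_scheme(40, seed = 17))
  expect_gt(ev_true$mean, 20)
  expect_lt(ev_perm$mean, 8)
})

test_that("comparison report tabulates deltas against the baseline", {
  r1 <- structure(list(metric = "explained_variance", mean = 12, se = 1,
                       per_repeat = numeric(), n = 10),
                  class = "eval_result")
  r2 <- structure(list(metric = "explained_variance", mean = 15, se = 1,
                       per_repeat = numeric(), n = 10),
                  class = "eval_result")
  tab <- model_comparison_report(list(sg = r1, all = r2), baseline = "sg")
  expect_identical(tab$model, c("sg", "all"))
  expect_equal(tab$delta_vs_sg, c(0, 3), tolerance = 1e-12)
  expect_error(model_comparison_report(list(sg = r1), baseline = "zz"))
})
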