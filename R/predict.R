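#' Repeated-holdout evaluation scheme
#'
#' @param n_repeats Number of independent train/test splits (default 1000).
#' @param holdout_fraction Fraction of samples held out per repeat
#'   (default 0.1, i.e. a 90/10 split).
#' @param seed Master seed; per-repeat split seeds derive from it.
#' @return Object of class `cv_scheme`.
#' @export
cv_scheme <- function(n_repeats = 1000L, holdout_fraction = 0.1, seed = 1L) {
  stopifnot(holdout_fraction > 0, holdout_fraction < 1, n_repeats >= 1L)
  structure(list(n_repeats = as.integer(n_repeats),
                 holdout_fraction = holdout_fraction,
                 seed = as.integer(seed)),
            class = "cv_scheme")
}

## Standardize train columns; apply the same (train-derived) transform to
## test. Constant training features are dropped (with warning at the caller's
## discretion via attribute).
standardize_train_test <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2L, stats::sd)
  keep <- sdv > 0
  tr <- sweep(sweep(train[, keep, drop = FALSE], 2L, mu[keep]), 2L,
              sdv[keep], "/")
  te <- sweep(sweep(test[, keep, drop = FALSE], 2L, mu[keep]), 2L,
              sdv[keep], "/")
  list(train = tr, test = te, dropped = colnames(train)[!keep])
}

## Gaussian kernel bandwidth by the median heuristic: kernlab's rbfdot is
## exp(-sigma ||x - y||^2), so sigma = 1 / median pairwise squared distance.
median_heuristic_sigma <- function(X, max_points = 200L) {
  n <- nrow(X)
  idx <- if (n > max_points) seq(1L, n, length.out = max_points) else seq_len(n)
  d2 <- stats::dist(X[idx, , drop = FALSE])^2
  med <- stats::median(d2[d2 > 0])
  if (!is.finite(med) || med == 0) 1 else 1 / med
}

#' Train an RBF-SVM and predict on held-out samples
#'
#' Fits a soft-margin SVM classifier (`C-svc`, returning signed decision
#' scores) or an epsilon-insensitive SVM regressor (`eps-svr`) with the
#' Gaussian kernel `k(x, y) = exp(-gamma ||x - y||^2)`, `gamma` set by the
#' median-pairwise-squared-distance heuristic on the training data. Features
#' are standardized with training-set statistics only; constant training
#' features are dropped with a warning. Default cost `C = 1` and epsilon
#' `0.1` (regression). The optimizer is `kernlab::ksvm`.
#'
#' @param train_x,train_y Training features (samples x features) and
#'   targets: a 2-level factor / binary vector (classification) or numeric
#'   (regression).
#' @param test_x Held-out feature matrix.
#' @param mode `"classify"` or `"regress"`.
#' @param cost,epsilon SVM cost and (regression) epsilon-tube width.
#' @return Numeric vector: decision scores (classification) or predicted
#'   values (regression) for the rows of `test_x`.
#' @export
svm_train_predict <- function(train_x, train_y, test_x,
                              mode = c("classify", "regress"),
                              cost = 1, epsilon = 0.1) {
  mode <- match.arg(mode)
  if (mode == "classify") {
    train_y <- factor(train_y)
    if (nlevels(train_y) < 2L) stop("single-class training set")
  }
  std <- standardize_train_test(train_x, test_x)
  if (length(std$dropped))
    warning("constant training feature(s) dropped: ",
            paste(std$dropped, collapse = ", "))
  if (ncol(std$train) == 0L) stop("no informative features left")
  sigma <- median_heuristic_sigma(std$train)
  kern <- kernlab::rbfdot(sigma = sigma)
  if (mode == "classify") {
    fit <- kernlab::ksvm(std$train, train_y, type = "C-svc", kernel = kern,
                         C = cost, scaled = FALSE)
    sc <- kernlab::predict(fit, std$test, type = "decision")[, 1]
    ## orient scores so larger = more likely the SECOND factor level
    if (levels(train_y)[2] != fit@lev[2]) sc <- -sc
    sc
  } else {
    ## standardize the target with training statistics so the epsilon tube
    ## is on the unit-variance scale; back-transform the predictions
    y <- as.numeric(train_y)
    mu_y <- mean(y); sd_y <- stats::sd(y)
    ## constant target: every point sits inside the epsilon tube
    if (sd_y == 0) return(rep(mu_y, nrow(std$test)))
    fit <- kernlab::ksvm(std$train, (y - mu_y) / sd_y, type = "eps-svr",
                         kernel = kern, C = cost, epsilon = epsilon,
                         scaled = FALSE)
    as.numeric(kernlab::predict(fit, std$test)) * sd_y + mu_y
  }
}

#' Area under the ROC curve by the rank formulation
#'
#' Mann-Whitney AUC with tie correction: the probability that a random
#' positive's score exceeds a random negative's (ties count 1/2).
#'
#' @param scores Numeric decision scores, larger = more positive.
#' @param labels Logical/0-1 vector of true classes (TRUE = positive).
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes required for AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## One stratified holdout split: per class, round(frac * n_class) test
## samples (at least 1). Returns test indices.
stratified_test_idx <- function(labels, frac) {
  idx <- unlist(lapply(split(seq_along(labels), labels), function(cls) {
    k <- max(1L, round(frac * length(cls)))
    sample(cls, k)
  }), use.names = FALSE)
  sort(idx)
}

#' Mean AUC under repeated stratified holdout
#'
#' Per repeat: a stratified random split holds out `holdout_fraction` of each
#' class, an RBF-SVM classifier is trained on the rest, and the held-out
#' samples' decision scores give a rank AUC. Reported is the mean AUC across
#' repeats with its Monte-Carlo standard error. Repeats whose held-out fold
#' is single-class (impossible under the stratified draw, kept as a guard)
#' are resampled.
#'
#' @param features Samples x features matrix.
#' @param labels Logical/0-1 vector (TRUE = positive class), length
#'   `nrow(features)`.
#' @param scheme A [cv_scheme()].
#' @return Object of class `eval_result`: `metric = "auc"`, `mean`, `se`,
#'   `per_repeat`, `n`.
#' @export
repeated_holdout_auc <- function(features, labels, scheme = cv_scheme()) {
  labels <- as.logical(labels)
  stopifnot(length(labels) == nrow(features))
  if (!any(labels) || all(labels)) stop("both classes required")
  set.seed(scheme$seed)
  aucs <- numeric(scheme$n_repeats)
  for (r in seq_len(scheme$n_repeats)) {
    repeat {
      te <- stratified_test_idx(labels, scheme$holdout_fraction)
      if (length(unique(labels[te])) == 2L &&
          length(unique(labels[-te])) == 2L) break
    }
    sc <- suppressWarnings(
      svm_train_predict(features[-te, , drop = FALSE],
                        factor(labels[-te], levels = c(FALSE, TRUE)),
                        features[te, , drop = FALSE], mode = "classify"))
    aucs[r] <- rank_auc(sc, labels[te])
  }
  structure(list(metric = "auc", mean = mean(aucs),
                 se = stats::sd(aucs) / sqrt(length(aucs)),
                 per_repeat = aucs, n = nrow(features)),
            class = "eval_result")
}

#' AUC as a function of the response-tail fraction
#'
#' For each fraction `f`, the top `f/2` of responders are labeled high and
#' the bottom `f/2` low, and [repeated_holdout_auc()] is run on that subset.
#' Fractions whose tails would hold fewer than 4 samples each are skipped
#' with a warning. At `f = 1` this reduces to a median split of the whole
#' cohort.
#'
#' @param features Samples x features matrix (all samples).
#' @param responses Named numeric vector of adjusted responses, names
#'   matching `rownames(features)`.
#' @param fractions Tail fractions to evaluate (default `seq(0.1, 1, 0.05)`).
#' @param scheme A [cv_scheme()].
#' @return Data frame: `fraction`, `n`, `auc`, `auc_se`.
#' @export
tail_sweep <- function(features, responses,
                       fractions = seq(0.10, 1, by = 0.05),
                       scheme = cv_scheme()) {
  stopifnot(all(fractions > 0), all(fractions <= 1),
            !is.null(rownames(features)),
            all(names(responses) %in% rownames(features)))
  ordered <- order_by_response(responses)
  m <- length(ordered)
  rows <- lapply(seq_along(fractions), function(fi) {
    f <- fractions[fi]
    half <- as.integer(floor(f * m / 2))
    if (half < 4L) {
      warning("fraction ", f, " leaves tails of ", half,
              " samples; skipped")
      return(NULL)
    }
    high <- ordered[seq_len(half)]
    low <- rev(ordered)[seq_len(half)]
    ids <- c(high, low)
    sub_scheme <- cv_scheme(scheme$n_repeats, scheme$holdout_fraction,
                            seed = scheme$seed + fi)
    res <- repeated_holdout_auc(
      features[ids, , drop = FALSE],
      rownames(features[ids, , drop = FALSE]) %in% high,
      sub_scheme)
    data.frame(fraction = f, n = 2L * half, auc = res$mean,
               auc_se = res$se)
  })
  do.call(rbind, rows)
}

#' Cross-validated explained variance of a regression model
#'
#' Per repeat: a random 90/10 split, an RBF-SVM regressor trained on 90%,
#' and the *directional* squared Pearson correlation between held-out
#' predictions and observed responses — `sign(r) * r^2`, so folds where the
#' predictions are anti-correlated with the truth count against the model
#' rather than accruing spurious positive variance (plain `r^2` has a
#' `1/(n_test - 1)` positive bias on pure noise). The explained variance is
#' the mean across repeats, floored at zero, reported as a percentage. The
#' alternative definition `1 - SSE/SST` on the held-out fold is reported
#' alongside.
#'
#' @param features Samples x features matrix.
#' @param responses Numeric responses, length `nrow(features)` (names, if
#'   present, must match the rownames).
#' @param scheme A [cv_scheme()].
#' @return Object of class `eval_result`: `metric = "explained_variance"`,
#'   `mean` (percent, squared-correlation definition), `se`, `mean_r2_sse`
#'   (percent, `1 - SSE/SST` definition, not floored per repeat),
#'   `per_repeat`, `n`.
#' @export
explained_variance <- function(features, responses, scheme = cv_scheme()) {
  stopifnot(nrow(features) == length(responses), nrow(features) >= 30L)
  if (!is.null(names(responses)) && !is.null(rownames(features)))
    stopifnot(identical(names(responses), rownames(features)))
  set.seed(scheme$seed)
  n <- nrow(features)
  r2 <- numeric(scheme$n_repeats)
  r2_sse <- numeric(scheme$n_repeats)
  for (r in seq_len(scheme$n_repeats)) {
    repeat {
      te <- sort(sample.int(n, max(2L, round(scheme$holdout_fraction * n))))
      if (stats::sd(responses[te]) > 0) break
    }
    pred <- suppressWarnings(
      svm_train_predict(features[-te, , drop = FALSE], responses[-te],
                        features[te, , drop = FALSE], mode = "regress"))
    r2[r] <- if (stats::sd(pred) == 0) 0 else {
      rho <- stats::cor(pred, responses[te])
      sign(rho) * rho^2
    }
    r2_sse[r] <- 1 - sum((responses[te] - pred)^2) /
      sum((responses[te] - mean(responses[te]))^2)
  }
  structure(list(metric = "explained_variance",
                 mean = max(0, mean(r2)) * 100,
                 se = stats::sd(r2) / sqrt(length(r2)) * 100,
                 mean_r2_sse = mean(r2_sse) * 100,
                 per_repeat = r2, n = n),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  if (x$metric == "auc")
    cat(sprintf("AUC %.3f (SE %.3f) over %d repeats, n = %d\n",
                x$mean, x$se, length(x$per_repeat), x$n))
  else
    cat(sprintf(
      "explained variance %.1f%% (SE %.1f) [1-SSE/SST: %.1f%%], n = %d\n",
      x$mean, x$se, x$mean_r2_sse, x$n))
  invisible(x)
}

#' Side-by-side comparison of model evaluation results
#'
#' @param results Named list of `eval_result` objects (a common metric).
#' @param baseline Optional name of the baseline model for the delta column.
#' @return Data frame: `model`, `metric`, `value`, `se`, and `delta_vs_<b>`
#'   when a baseline is given.
#' @export
model_comparison_report <- function(results, baseline = NULL) {
  stopifnot(length(results) >= 1L)
  tab <- data.frame(
    model = names(results),
    metric = vapply(results, `[[`, character(1), "metric"),
    value = vapply(results, `[[`, numeric(1), "mean"),
    se = vapply(results, `[[`, numeric(1), "se"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!is.null(baseline)) {
    stopifnot(baseline %in% tab$model)
    tab[[paste0("delta_vs_", baseline)]] <-
      tab$value - tab$value[tab$model == baseline]
  }
  tab
}
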