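#' Relative LDLC change on the log scale
#'
#' The response phenotype: `log(mean of the two post-treatment LDLC visits) -
#' log(mean of the two pre-treatment visits)` (natural log). Duplicate visits
#' are averaged first to damp technical variation; the relative (log) change
#' is used because absolute LDLC change is strongly correlated with baseline.
#'
#' @param ldlc_pre,ldlc_post Numeric vectors of visit-level LDLC values
#'   (mg/dL), two visits each (any length >= 1 is accepted and averaged).
#' @return The log change, a dimensionless scalar.
#' @export
compute_log_change <- function(ldlc_pre, ldlc_post) {
  if (any(!is.finite(ldlc_pre)) || any(!is.finite(ldlc_post)) ||
      any(ldlc_pre <= 0) || any(ldlc_post <= 0))
    stop("LDLC visit values must be positive and finite")
  log(mean(ldlc_post)) - log(mean(ldlc_pre))
}

#' Derive the response phenotype table
#'
#' Applies [compute_log_change()] per sample, optionally excluding smokers
#' beforehand.
#'
#' @param phenotypes Phenotype data frame as produced by [simulate_cohort()] /
#'   [read_phenotypes()].
#' @param exclude_smokers Drop samples flagged as smokers before analysis.
#' @return The phenotype data frame, filtered, with a `log_change` column.
#' @export
derive_response <- function(phenotypes, exclude_smokers = TRUE) {
  ph <- phenotypes
  if (exclude_smokers && any(ph$smoker)) ph <- ph[!ph$smoker, , drop = FALSE]
  ph$log_change <- vapply(seq_len(nrow(ph)), function(i) {
    compute_log_change(c(ph$ldlc_pre1[i], ph$ldlc_pre2[i]),
                       c(ph$ldlc_post1[i], ph$ldlc_post2[i]))
  }, numeric(1))
  rownames(ph) <- NULL
  ph
}

#' Screen candidate covariates and adjust the response
#'
#' Each candidate covariate is tested one at a time by simple linear
#' regression of `log_change` on it; covariates whose slope is significant at
#' `alpha` are retained and the response is residualized on all retained
#' covariates jointly. With nothing retained the adjusted response is the
#' centered log change. Constant covariates are excluded with a warning.
#'
#' @param phenotypes Data frame with a `log_change` column (see
#'   [derive_response()]).
#' @param candidates Character vector of covariate column names to screen
#'   (default `c("age", "sex", "bmi")`).
#' @param alpha Significance level for retaining a covariate.
#' @return A list with `kept` (character vector of retained covariates),
#'   `p_values` (named, one per screened candidate), and `phenotypes` (input
#'   with an `adjusted_change` column).
#' @export
screen_and_adjust_covariates <- function(phenotypes,
                                         candidates = c("age", "sex", "bmi"),
                                         alpha = 0.05) {
  stopifnot("log_change" %in% names(phenotypes))
  miss <- setdiff(candidates, names(phenotypes))
  if (length(miss))
    stop("candidate covariate(s) not in phenotype table: ",
         paste(miss, collapse = ", "))
  if (nrow(phenotypes) < length(candidates) + 3L)
    stop("too few samples to screen covariates")
  y <- phenotypes$log_change
  pvals <- vapply(candidates, function(nm) {
    x <- as.numeric(phenotypes[[nm]])
    if (stats::sd(x) == 0) {
      warning("covariate '", nm, "' is constant; excluded from screening")
      return(NA_real_)
    }
    stats::coef(summary(stats::lm(y ~ x)))[2, 4]
  }, numeric(1))
  kept <- candidates[!is.na(pvals) & pvals < alpha]
  if (length(kept)) {
    X <- as.data.frame(lapply(phenotypes[kept], as.numeric))
    fit <- stats::lm(y ~ ., data = X)
    phenotypes$adjusted_change <- unname(stats::residuals(fit))
  } else {
    phenotypes$adjusted_change <- y - mean(y)
  }
  list(kept = kept, p_values = pvals, phenotypes = phenotypes)
}

## rank-based inverse-normal transform with Blom offset, rows of a matrix
inverse_normal_rows <- function(m) {
  n <- ncol(m)
  out <- t(apply(m, 1L, function(x) {
    if (stats::sd(x) == 0) return(rep(0, n))
    stats::qnorm((rank(x, ties.method = "average") - 3 / 8) / (n + 1 / 4))
  }))
  dimnames(out) <- dimnames(m)
  out
}

#' Normalize an expression matrix
#'
#' Four-step normalization of an array expression matrix:
#' 1. each array (column) is quantile-transformed onto the average empirical
#'    distribution across arrays (via [limma::normalizeQuantiles()]);
#' 2. each gene (row) is quantile-normalized across samples — implemented as
#'    a rank-based inverse-normal transform with Blom offset
#'    `(r - 3/8)/(n + 1/4)`;
#' 3. each gene is residualized on the supplied batch/technical covariates;
#' 4. the inverse-normal transform is applied again.
#' The output therefore has, per gene, mean ~0 and SD ~1 and is a monotone
#' function of the post-adjustment ranks. All-constant genes map to zero
#' vectors with a warning.
#'
#' @param matrix_ Gene x sample numeric matrix with `state` attribute
#'   `"raw"`.
#' @param batch_covariates Data frame (or NULL) of per-sample technical
#'   covariates, rows aligned with the matrix columns; factors allowed.
#' @return The normalized matrix, `state` attribute `"fully_normalized"`.
#' @export
normalize_expression <- function(matrix_, batch_covariates = NULL) {
  st <- attr(matrix_, "state")
  if (!is.null(st) && st == "fully_normalized")
    stop("matrix is already fully normalized")
  if (any(!is.finite(matrix_))) stop("expression matrix has missing values")
  const <- apply(matrix_, 1L, stats::sd) == 0
  if (any(const))
    warning(sum(const), " all-constant gene(s) map to zero vectors")

  m1 <- limma::normalizeQuantiles(matrix_)
  m2 <- inverse_normal_rows(m1)
  if (!is.null(batch_covariates)) {
    stopifnot(nrow(batch_covariates) == ncol(matrix_))
    mm <- stats::model.matrix(~ ., data = as.data.frame(batch_covariates))
    fit <- stats::lm.fit(mm, t(m2))
    m3 <- t(fit$residuals)
  } else {
    m3 <- m2
  }
  out <- inverse_normal_rows(m3)
  out[const, ] <- 0
  dimnames(out) <- dimnames(matrix_)
  attr(out, "state") <- "fully_normalized"
  out
}
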