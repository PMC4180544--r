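#' Map a normalized expression matrix into (0, 1) for NMF
#'
#' NMF requires a non-negative data matrix. Each entry is replaced by one
#' minus its upper-tail normal P value — equivalently the standard normal CDF
#' of the per-gene standardized value — so entries lie in (0, 1) and preserve
#' the within-gene ordering. Entries are clipped to `[eps, 1 - eps]`.
#'
#' @param matrix_ Gene x sample matrix, `state` attribute
#'   `"fully_normalized"` (per gene approximately standard normal).
#' @param eps Clipping bound away from 0 and 1.
#' @return Matrix of the same shape with entries in (0, 1) and attribute
#'   `provenance = "one_minus_p"`.
#' @export
nonnegativize <- function(matrix_, eps = 1e-12) {
  st <- attr(matrix_, "state")
  if (is.null(st) || st != "fully_normalized")
    stop("nonnegativize() expects a fully normalized matrix ",
         "(state = 'fully_normalized')")
  sds <- apply(matrix_, 1L, stats::sd)
  mus <- rowMeans(matrix_)
  z <- (matrix_ - mus) / ifelse(sds > 0, sds, 1)
  a <- stats::pnorm(z)
  a[a < eps] <- eps
  a[a > 1 - eps] <- 1 - eps
  dimnames(a) <- dimnames(matrix_)
  attr(a, "provenance") <- "one_minus_p"
  a
}

frob <- function(m) sqrt(sum(m * m))

## One multiplicative-update (Lee-Seung, Frobenius loss) NMF run.
nmf_run <- function(A, k, max_iter, tol, seed) {
  set.seed(seed)
  n <- nrow(A); m <- ncol(A)
  sc <- mean(A)
  W <- matrix(stats::runif(n * k), n, k) * sc
  H <- matrix(stats::runif(k * m), k, m) * sc
  eps <- .Machine$double.eps
  err <- numeric(0)
  e_prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, A) / (crossprod(W) %*% H + eps))
    W <- W * (A %*% t(H) / (W %*% tcrossprod(H) + eps))
    e <- frob(A - W %*% H)
    err <- c(err, e)
    if (is.finite(e_prev) && abs(e_prev - e) < tol * max(e_prev, eps)) {
      converged <- TRUE
      break
    }
    e_prev <- e
  }
  list(W = W, H = H, error = err[length(err)], trace = err,
       converged = converged)
}

#' Non-negative matrix factorization with multiplicative updates
#'
#' Factorizes a non-negative matrix `A` (genes x samples) into `W %*% H` with
#' non-negative factors using Lee-Seung multiplicative updates under the
#' Frobenius objective. Because the objective is non-convex and the random
#' initialization matters, `n_runs` restarts are performed (per-run seeds
#' derived from `seed`) and the run with the smallest reconstruction error is
#' returned. Samples are assigned to clusters by the argmax over rows of `H`
#' in their column.
#'
#' @param A Non-negative numeric matrix (see [nonnegativize()]).
#' @param k Factorization rank (number of clusters), `>= 1`.
#' @param n_runs Number of random restarts; the best fit is kept.
#' @param max_iter Maximum update iterations per run.
#' @param tol Relative change in reconstruction error declaring convergence.
#' @param seed Master seed; run seeds are `seed + 1 ... seed + n_runs`.
#' @return An object of class `nmf_fit`: list with `W`, `H`, `k`,
#'   `reconstruction_error`, `assignments` (named integer vector in `1..k`),
#'   `trace` (error per iteration of the best run), and `converged` (FALSE
#'   triggers a warning).
#' @export
nmf_factorize <- function(A, k, n_runs = 30L, max_iter = 2000L,
                          tol = 1e-6, seed = 1L) {
  stopifnot(is.matrix(A), all(A >= 0), k >= 1L, n_runs >= 1L)
  best <- NULL
  for (r in seq_len(n_runs)) {
    fit <- nmf_run(A, k, max_iter, tol, seed = seed + r)
    if (is.null(best) || fit$error < best$error) best <- fit
  }
  if (!best$converged)
    warning("NMF did not converge within ", max_iter,
            " iterations; returning best iterate")
  assignments <- max.col(t(best$H), ties.method = "first")
  names(assignments) <- colnames(A)
  out <- list(W = best$W, H = best$H, k = as.integer(k),
              reconstruction_error = best$error,
              assignments = assignments, trace = best$trace,
              converged = best$converged)
  class(out) <- "nmf_fit"
  out
}

#' Cluster purity and entropy against known class labels
#'
#' Purity is `(1/n) * sum_i max_j n_i^j` where `n_i^j` counts samples of true
#' class `j` in cluster `i`; entropy is
#' `-(1/(n log2 l)) * sum_i sum_j n_i^j log2(n_i^j / n_i)` with `l` true
#' classes and `n_i` the size of cluster `i` (empty counts contribute 0).
#' Purity 1 and entropy 0 mean perfect clustering.
#'
#' @param assignments Cluster index per sample (any label set).
#' @param labels True class label per sample, same order; at least two
#'   distinct classes are required for entropy.
#' @return List of class `cluster_quality`: `purity`, `entropy`, `n`, `l`,
#'   and the contingency `counts` (cluster x class).
#' @export
cluster_quality <- function(assignments, labels) {
  stopifnot(length(assignments) == length(labels))
  n <- length(assignments)
  counts <- table(cluster = assignments, class = labels)
  l <- ncol(counts)
  if (l < 2L) stop("entropy undefined with a single true class")
  purity <- sum(apply(counts, 1L, max)) / n
  n_i <- rowSums(counts)
  terms <- counts * log2(sweep(counts, 1L, n_i, "/"))
  terms[counts == 0] <- 0
  entropy <- -sum(terms) / (n * log2(l))
  structure(list(purity = purity, entropy = entropy, n = n, l = l,
                 counts = counts),
            class = "cluster_quality")
}

#' Consensus-clustering diagnostics across NMF ranks
#'
#' For each candidate rank `k`, runs `n_runs` independently seeded NMF fits
#' (single initialization each), records the connectivity matrix (entry 1 iff
#' two samples share a cluster), and averages them into a consensus matrix
#' `C`. Rank stability is summarized by the cophenetic correlation (Pearson
#' correlation between the `1 - C` distances and the cophenetic distances of
#' their average-linkage dendrogram) and the dispersion
#' `(1/m^2) * sum_ij 4 (C_ij - 1/2)^2`, which is 1 exactly when all runs
#' agree.
#'
#' @param A Non-negative matrix (see [nonnegativize()]).
#' @param ranks Integer vector of candidate ranks, each in `2..(m-1)`.
#' @param n_runs Connectivity matrices averaged per rank (`>= 2`).
#' @param max_iter,tol Per-run NMF controls.
#' @param seed Master seed.
#' @return List (one element per rank) of class `consensus_summary` entries:
#'   `k`, `consensus` (m x m), `cophenetic_correlation`, `dispersion`.
#' @export
consensus_diagnostics <- function(A, ranks = 2:5, n_runs = 50L,
                                  max_iter = 2000L, tol = 1e-6, seed = 1L) {
  m <- ncol(A)
  stopifnot(all(ranks >= 2L), all(ranks <= m - 1L))
  if (n_runs < 2L) stop("consensus diagnostics need n_runs >= 2")
  out <- lapply(seq_along(ranks), function(ri) {
    k <- ranks[ri]
    C <- matrix(0, m, m)
    for (r in seq_len(n_runs)) {
      fit <- nmf_run(A, k, max_iter, tol,
                     seed = seed + 10000L * ri + r)
      a <- max.col(t(fit$H), ties.method = "first")
      C <- C + outer(a, a, "==")
    }
    C <- C / n_runs
    dimnames(C) <- list(colnames(A), colnames(A))
    d <- stats::as.dist(1 - C)
    coph <- if (stats::sd(d) == 0) NA_real_ else {
      hc <- stats::hclust(d, method = "average")
      stats::cor(d, stats::cophenetic(hc))
    }
    structure(list(k = k, consensus = C,
                   cophenetic_correlation = coph,
                   dispersion = mean(4 * (C - 0.5)^2)),
              class = "consensus_summary")
  })
  names(out) <- paste0("k", ranks)
  out
}

## Sample ids ordered by decreasing response; ties broken by sample id so
## tail selection is reproducible.
order_by_response <- function(responses) {
  ids <- names(responses)
  ids[order(-responses, ids)]
}

## Pick the `n_genes` genes with largest |mean(high) - mean(low)|.
preselect_genes <- function(expression, high_ids, low_ids, n_genes) {
  dif <- abs(rowMeans(expression[, high_ids, drop = FALSE]) -
               rowMeans(expression[, low_ids, drop = FALSE]))
  ord <- order(-dif, rownames(expression))
  rownames(expression)[ord[seq_len(min(n_genes, nrow(expression)))]]
}

## Standardize-per-gene + CDF transform of an expression submatrix, keeping
## the fully_normalized contract local to the subset.
subset_nonneg <- function(expression, sample_ids, gene_ids) {
  sub <- expression[gene_ids, sample_ids, drop = FALSE]
  attr(sub, "state") <- "fully_normalized"
  nonnegativize(sub)
}

#' Select extreme-responder tails by NMF cluster purity
#'
#' Implements the tail-size search: for each even subset size `N` in
#' `N_grid`, take the `N/2` highest and `N/2` lowest responders, preselect
#' the `n_genes_preselect` genes with the greatest absolute mean difference
#' between those groups, transform to (0,1) via [nonnegativize()], cluster at
#' rank 2 by [nmf_factorize()], and score purity against the true high/low
#' labels. A random baseline repeats the identical procedure on
#' `n_random_sets` random draws of `N` samples split into two arbitrary
#' pseudo-groups. The chosen `N` is the largest with
#' `purity_true >= purity_cutoff` (maximizing sample size subject to clean
#' separation); if none qualifies the argmax-purity `N` is returned with a
#' warning.
#'
#' @param expression Fully normalized gene x sample matrix.
#' @param responses Named numeric vector of adjusted response values, names
#'   matching expression columns.
#' @param N_grid Even subset sizes to scan (default `seq(20, 80, 2)`).
#' @param n_genes_preselect Genes kept per subset (default 2000).
#' @param n_random_sets Random baseline draws per `N` (default 500).
#' @param purity_cutoff Minimum acceptable purity (default 0.9).
#' @param n_runs NMF restarts per factorization (default 500).
#' @param max_iter,tol NMF controls.
#' @param seed Master seed.
#' @return List of class `tail_selection`: `chosen_n`, `high_ids`,
#'   `low_ids`, and `curve` — a data frame with columns `N`, `purity_true`,
#'   `purity_random`, `entropy_true`, `entropy_random`.
#' @export
select_tail_subset <- function(expression, responses,
                               N_grid = seq(20L, 80L, 2L),
                               n_genes_preselect = 2000L,
                               n_random_sets = 500L,
                               purity_cutoff = 0.9,
                               n_runs = 500L, max_iter = 2000L,
                               tol = 1e-6, seed = 1L) {
  stopifnot(!is.null(names(responses)),
            all(names(responses) %in% colnames(expression)),
            all(N_grid %% 2L == 0L), all(N_grid <= length(responses)))
  ordered <- order_by_response(responses)
  m <- length(ordered)

  eval_subset <- function(high_ids, low_ids, sub_seed) {
    genes <- preselect_genes(expression, high_ids, low_ids,
                             n_genes_preselect)
    A <- subset_nonneg(expression, c(high_ids, low_ids), genes)
    fit <- suppressWarnings(
      nmf_factorize(A, k = 2L, n_runs = n_runs, max_iter = max_iter,
                    tol = tol, seed = sub_seed))
    labels <- rep(c("high", "low"), c(length(high_ids), length(low_ids)))
    cluster_quality(fit$assignments, labels)
  }

  curve <- lapply(seq_along(N_grid), function(ni) {
    N <- N_grid[ni]
    half <- N %/% 2L
    high_ids <- ordered[seq_len(half)]
    low_ids <- rev(ordered)[seq_len(half)]
    q_true <- eval_subset(high_ids, low_ids, seed + 1000L * ni)

    set.seed(seed + 500000L + ni)
    rnd <- replicate(n_random_sets, sample(colnames(expression), N),
                     simplify = FALSE)
    q_rand <- lapply(seq_along(rnd), function(ri) {
      ids <- rnd[[ri]]
      eval_subset(ids[seq_len(half)], ids[half + seq_len(half)],
                  seed + 1000L * ni + 100000L + ri)
    })
    data.frame(
      N = N,
      purity_true = q_true$purity,
      purity_random = mean(vapply(q_rand, `[[`, numeric(1), "purity")),
      entropy_true = q_true$entropy,
      entropy_random = mean(vapply(q_rand, `[[`, numeric(1), "entropy"))
    )
  })
  curve <- do.call(rbind, curve)

  ok <- curve$N[curve$purity_true >= purity_cutoff]
  if (length(ok)) {
    chosen <- max(ok)
  } else {
    chosen <- curve$N[which.max(curve$purity_true)]
    warning("no subset size reached purity ", purity_cutoff,
            "; returning the argmax-purity N = ", chosen)
  }
  half <- chosen %/% 2L
  structure(list(chosen_n = chosen,
                 high_ids = ordered[seq_len(half)],
                 low_ids = rev(ordered)[seq_len(half)],
                 curve = curve),
            class = "tail_selection")
}
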