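## Gene-specific scatter for two equal-size groups:
##   s(i) = sqrt( (1/(N(N-1))) * (SS_high(i) + SS_low(i)) )
## i.e. the pooled standard error of the mean difference for equal N.
gene_scatter <- function(high, low) {
  N <- ncol(high)
  ssh <- rowSums((high - rowMeans(high))^2)
  ssl <- rowSums((low - rowMeans(low))^2)
  sqrt((ssh + ssl) / (N * (N - 1)))
}

#' Relative-difference statistic between high and low responders
#'
#' For each gene computes the moderated t-like statistic
#' `d(i) = (xbar_H(i) - xbar_L(i)) / (s(i) + s0(i))`, where `s(i)` is the
#' gene-specific scatter `sqrt((SS_H + SS_L) / (N (N - 1)))` (the pooled
#' standard error of the group mean difference, equal group sizes `N`), and
#' `s0(i)` is an additive fudge value stabilizing the denominator — either a
#' single constant or a per-gene schedule from [fit_s0_schedule()].
#'
#' @param high,low Gene x sample matrices for the two groups; equal numbers
#'   of columns (`N >= 2`) and identical gene rows required.
#' @param s0 Either a non-negative scalar (default 0) or an `s0_schedule`
#'   object.
#' @return Data frame of class `signature_stats`: `gene`, `xbar_H`,
#'   `xbar_L`, `s`, `s0`, `d`. Genes with `s + s0 == 0` get `d = +/-Inf`
#'   (0 when the numerator is also 0) and are flagged in a `degenerate`
#'   column.
#' @export
relative_difference <- function(high, low, s0 = 0) {
  stopifnot(is.matrix(high), is.matrix(low),
            nrow(high) == nrow(low))
  if (ncol(high) != ncol(low))
    stop("equal group sizes required (scatter assumes equal N)")
  if (ncol(high) < 2L) stop("need at least 2 samples per group")
  if (any(!is.finite(high)) || any(!is.finite(low)))
    stop("missing values not allowed")
  s <- gene_scatter(high, low)
  s0_vec <- if (inherits(s0, "s0_schedule")) s0_values(s0, s)
            else rep(as.numeric(s0), nrow(high))
  stopifnot(all(s0_vec >= 0))
  num <- rowMeans(high) - rowMeans(low)
  den <- s + s0_vec
  d <- ifelse(den > 0, num / den, ifelse(num == 0, 0, sign(num) * Inf))
  out <- data.frame(
    gene = if (is.null(rownames(high))) sprintf("g%d", seq_len(nrow(high)))
           else rownames(high),
    xbar_H = rowMeans(high), xbar_L = rowMeans(low),
    s = s, s0 = s0_vec, d = d,
    degenerate = den == 0,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("signature_stats", "data.frame")
  out
}

## Evaluate a fitted schedule at scatter values s: s0(i) = s0_max (1 - F(s)),
## with F the empirical CDF frozen at fit time. Non-increasing in s.
s0_values <- function(schedule, s) {
  schedule$s0_max * (1 - schedule$ecdf(s))
}

## CV (sd/mean) of the per-s-decile median |d| for a candidate s0_max.
s0_criterion <- function(num, s, s0_max, Fhat, deciles) {
  d <- num / (s + s0_max * (1 - Fhat))
  med <- tapply(abs(d), deciles, stats::median)
  if (mean(med) == 0) return(Inf)
  stats::sd(med) / mean(med)
}

#' Fit a scatter-dependent fudge-factor schedule
#'
#' The constant-`s0` moderated statistic can remain heteroscedastic: genes
#' with small scatter `s(i)` show inflated spread of `d(i)`. This schedule
#' lets the fudge value start at `s0_max` for the smallest-scatter genes and
#' decay linearly in the percentile rank of `s(i)` to 0 for the largest:
#' `s0(i) = s0_max * (1 - Fhat(s(i)))`, with `Fhat` the empirical CDF of the
#' scatter values. `s0_max` is tuned over a grid of percentiles of the `s`
#' distribution (default 0th-20th) by minimizing the coefficient of
#' variation, across deciles of `s`, of the decile-median `|d|` — flat
#' `|d|`-spread across the scatter range is the stabilization target.
#'
#' @param high,low Gene x sample matrices as in [relative_difference()].
#' @param grid_probs Percentile grid for the `s0_max` candidates.
#' @return Object of class `s0_schedule`: `s0_max`, `ecdf` (frozen empirical
#'   CDF of `s`), `criterion` (achieved CV), `grid` (data frame of candidate
#'   `s0_max` and criterion values).
#' @export
fit_s0_schedule <- function(high, low, grid_probs = seq(0, 0.20, by = 0.025)) {
  stopifnot(nrow(high) >= 100L)
  s <- gene_scatter(high, low)
  num <- rowMeans(high) - rowMeans(low)
  if (stats::sd(s) == 0) {
    warning("degenerate scatter distribution (all equal); constant s0")
    Fh <- stats::ecdf(s)
    sched <- structure(list(s0_max = 0, ecdf = Fh, criterion = NA_real_,
                            grid = data.frame(s0_max = 0,
                                              criterion = NA_real_)),
                       class = "s0_schedule")
    return(sched)
  }
  Fh <- stats::ecdf(s)
  Fhat <- Fh(s)
  deciles <- cut(Fhat, breaks = seq(0, 1, 0.1), include.lowest = TRUE,
                 labels = FALSE)
  cand <- unname(stats::quantile(s, probs = grid_probs, type = 7))
  crit <- vapply(cand, function(s0m)
    s0_criterion(num, s, s0m, Fhat, deciles), numeric(1))
  best <- which.min(crit)
  structure(list(s0_max = cand[best], ecdf = Fh, criterion = crit[best],
                 grid = data.frame(s0_max = cand, criterion = crit)),
            class = "s0_schedule")
}

## All balanced splits of 1..(2N) into a high-set of size N (complement low),
## as a list of index vectors; used when exhaustive enumeration is cheaper
## than sampling.
balanced_splits <- function(two_n) {
  N <- two_n %/% 2L
  splits <- utils::combn(two_n, N, simplify = FALSE)
  splits
}

#' Permutation p-values for the relative-difference statistic
#'
#' Recomputes `d` under `n_perm` balanced relabelings of the pooled `2N`
#' samples (`N` per group), keeping the fitted `s0` schedule fixed, and
#' assigns two-sided p-values from `|d|`. With `pooling = "pooled"` (default)
#' all permuted statistics across genes form one null distribution:
#' `p(i) = (1 + #\{(p, g): |d_p(g)| >= |d(i)|\}) / (1 + n_perm * n_genes)` —
#' finer resolution than the per-gene null, which is available as
#' `pooling = "per_gene"`. When fewer distinct balanced splits exist than
#' `n_perm`, all of them are enumerated instead of sampled.
#'
#' @param high,low Gene x sample matrices as in [relative_difference()].
#' @param schedule An `s0_schedule`, or a non-negative constant.
#' @param n_perm Number of permutations (`>= 100` recommended; default 1000).
#' @param pooling `"pooled"` or `"per_gene"`.
#' @param seed Seed for the permutation draw.
#' @return The [relative_difference()] data frame with columns `p_perm` and
#'   `rank` appended (rank 1 = most significant; ties broken by descending
#'   `|d|`, then gene id).
#' @export
permutation_pvalues <- function(high, low, schedule = 0, n_perm = 1000L,
                                pooling = c("pooled", "per_gene"),
                                seed = 1L) {
  pooling <- match.arg(pooling)
  obs <- relative_difference(high, low, s0 = schedule)
  N <- ncol(high)
  two_n <- 2L * N
  pooled_mat <- cbind(high, low)
  s <- obs$s
  s0_vec <- obs$s0

  n_exhaustive <- choose(two_n, N)
  if (n_exhaustive <= n_perm) {
    splits <- balanced_splits(two_n)
  } else {
    set.seed(seed)
    splits <- replicate(n_perm, sample.int(two_n, N), simplify = FALSE)
  }
  n_used <- length(splits)

  perm_d <- vapply(splits, function(hi_idx) {
    h <- pooled_mat[, hi_idx, drop = FALSE]
    l <- pooled_mat[, -hi_idx, drop = FALSE]
    num <- rowMeans(h) - rowMeans(l)
    sc <- gene_scatter(h, l)
    num / (sc + s0_vec)
  }, numeric(nrow(high)))

  abs_obs <- abs(obs$d)
  if (pooling == "pooled") {
    vabs <- sort(abs(as.vector(perm_d)))
    n_tot <- length(vabs)
    cnt <- n_tot - findInterval(abs_obs, vabs, left.open = TRUE)
    p <- (1 + cnt) / (1 + n_tot)
  } else {
    p <- vapply(seq_len(nrow(high)), function(i)
      (1 + sum(abs(perm_d[i, ]) >= abs_obs[i])) / (1 + n_used),
      numeric(1))
  }
  obs$p_perm <- p
  ord <- order(p, -abs_obs, obs$gene)
  obs$rank <- integer(nrow(obs))
  obs$rank[ord] <- seq_len(nrow(obs))
  attr(obs, "n_perm_used") <- n_used
  attr(obs, "pooling") <- pooling
  obs
}

#' Select the top signature genes
#'
#' Ranks genes by ascending permutation p-value (ties broken by descending
#' `|d|`, then gene id) and returns the first `n_select`, annotated with the
#' direction of differential expression.
#'
#' @param stats_ Output of [permutation_pvalues()].
#' @param n_select Number of genes to select (default 100).
#' @return Data frame with `gene`, `d`, `p_perm`, `rank`, `direction`
#'   (`"up_in_high"` / `"up_in_low"`), ordered by rank.
#' @export
select_signature <- function(stats_, n_select = 100L) {
  stopifnot(all(c("p_perm", "rank") %in% names(stats_)),
            n_select <= nrow(stats_))
  ord <- stats_[order(stats_$rank), , drop = FALSE]
  top <- ord[seq_len(n_select), , drop = FALSE]
  top$direction <- ifelse(top$d >= 0, "up_in_high", "up_in_low")
  rownames(top) <- NULL
  top[, c("gene", "xbar_H", "xbar_L", "s", "s0", "d", "p_perm", "rank",
          "direction")]
}

#' Hypergeometric overlap enrichment of two gene sets
#'
#' Upper-tail hypergeometric probability of observing at least the given
#' overlap between a query set and a reference set drawn from a common
#' universe — used e.g. to ask whether signature genes are enriched among
#' genes co-expressed with a pathway marker.
#'
#' @param query,reference Character vectors of gene ids, both subsets of
#'   `universe`.
#' @param universe Character vector: the gene universe.
#' @return List: `overlap`, `p_value` (P[overlap >= observed]), and the set
#'   sizes.
#' @export
overlap_enrichment <- function(query, reference, universe) {
  if (length(universe) == 0L) stop("empty universe")
  query <- unique(query); reference <- unique(reference)
  universe <- unique(universe)
  if (!all(query %in% universe) || !all(reference %in% universe))
    stop("query and reference must be subsets of the universe")
  k <- length(intersect(query, reference))
  p <- stats::phyper(k - 1, length(reference),
                     length(universe) - length(reference),
                     length(query), lower.tail = FALSE)
  list(overlap = k, p_value = p, n_query = length(query),
       n_reference = length(reference), n_universe = length(universe))
}

#' Signature discovery on selected tails, end to end
#'
#' Convenience wrapper: given the normalized expression matrix and the
#' high/low tail sample ids, fits the `s0` schedule, computes permutation
#' p-values, and selects the top `n_select` signature genes.
#'
#' @param expression Fully normalized gene x sample matrix.
#' @param high_ids,low_ids Sample ids of the two tails (equal sizes).
#' @param n_perm,n_select,pooling,seed Passed through to
#'   [permutation_pvalues()] / [select_signature()].
#' @param use_s0_schedule Fit the varying-`s0` schedule (TRUE, default) or
#'   use `s0 = 0` (the unmoderated statistic).
#' @return List: `signature` (the selected-genes data frame), `stats` (full
#'   per-gene table), `schedule` (the fitted `s0_schedule` or NULL).
#' @export
discover_signature <- function(expression, high_ids, low_ids,
                               n_perm = 1000L, n_select = 100L,
                               pooling = "pooled", use_s0_schedule = TRUE,
                               seed = 1L) {
  high <- expression[, high_ids, drop = FALSE]
  low <- expression[, low_ids, drop = FALSE]
  schedule <- if (use_s0_schedule) fit_s0_schedule(high, low) else 0
  st <- permutation_pvalues(high, low, schedule = schedule, n_perm = n_perm,
                            pooling = pooling, seed = seed)
  list(signature = select_signature(st, n_select = n_select),
       stats = st,
       schedule = if (use_s0_schedule) schedule else NULL)
}
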