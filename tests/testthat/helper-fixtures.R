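# Shared fixtures built in code at test time.

# Small cohort with a strong planted signal: fast enough for unit tests,
# strong enough that tail clustering and signature recovery are clean.
strong_cohort <- function(seed = 42L, n_samples = 120L) {
  simulate_cohort(sim_config(
    n_samples = n_samples, n_genes = 400L, n_signature = 40L,
    n_eqtl_genes = 10L, eqtl_r2 = 0.9, n_gwas_snps = 4L,
    trait_r2_expression = 0.6, trait_r2_snps = 0.05,
    age_effect = 0.01, batch_sd = 0.2, seed = seed))
}

# Exchangeable null: no planted effects at all.
null_cohort <- function(seed = 7L, n_samples = 100L, n_genes = 300L) {
  simulate_cohort(sim_config(
    n_samples = n_samples, n_genes = n_genes, n_signature = 10L,
    n_eqtl_genes = 0L, n_gwas_snps = 1L,
    trait_r2_expression = 0, trait_r2_snps = 0, age_effect = 0,
    batch_sd = 0, seed = seed))
}

# Normalized expression + adjusted responses for a cohort.
prep_cohort <- function(cohort) {
  ph <- derive_response(cohort$phenotypes)
  adj <- screen_and_adjust_covariates(ph)
  norm <- normalize_expression(
    cohort$expression,
    data.frame(batch = factor(cohort$truth$batch)))
  list(expression = norm,
       responses = stats::setNames(adj$phenotypes$adjusted_change,
                                   adj$phenotypes$sample_id),
       phenotypes = adj$phenotypes)
}

# Two-group matrix with a planted mean shift in the first `n_shift` genes.
shifted_groups <- function(n_genes = 200L, n_shift = 20L, N = 10L,
                           delta = 2, seed = 1L) {
  set.seed(seed)
  high <- matrix(rnorm(n_genes * N), n_genes,
                 dimnames = list(sprintf("g%03d", seq_len(n_genes)), NULL))
  low <- matrix(rnorm(n_genes * N), n_genes,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)), NULL))
  high[seq_len(n_shift), ] <- high[seq_len(n_shift), ] + delta
  list(high = high, low = low,
       shifted = sprintf("g%03d", seq_len(n_shift)))
}

# Heteroscedastic null for the fudge-factor tests: within-group scatter
# varies across genes, and genes destined for the lowest scatter quartile
# carry an extra random between-group shift that inflates var(d) ~4x there.
hetero_null <- function(n_genes = 2000L, N = 26L, seed = 1L) {
  set.seed(seed)
  sigma <- exp(seq(log(0.2), log(2), length.out = n_genes))
  low_q <- sigma <= quantile(sigma, 0.25)
  shift <- rnorm(n_genes, 0, ifelse(low_q, sqrt(3) * sigma * sqrt(2 / N), 0))
  high <- matrix(rnorm(n_genes * N, 0, sigma), n_genes) + shift
  low <- matrix(rnorm(n_genes * N, 0, sigma), n_genes)
  rownames(high) <- rownames(low) <- sprintf("g%04d", seq_len(n_genes))
  list(high = high, low = low, sigma = sigma)
}

# Rank-2 plus block structure: two sample groups with distinct non-negative
# expression profiles (for NMF recovery tests).
block_matrix <- function(n_genes = 60L, n_per_group = 10L, seed = 1L) {
  set.seed(seed)
  w1 <- runif(n_genes, 0, 1); w1[seq_len(n_genes / 2)] <- w1[seq_len(n_genes / 2)] + 2
  w2 <- runif(n_genes, 0, 1); w2[(n_genes / 2 + 1):n_genes] <- w2[(n_genes / 2 + 1):n_genes] + 2
  A <- cbind(
    sapply(seq_len(n_per_group), function(i) w1 * runif(1, 0.8, 1.2)),
    sapply(seq_len(n_per_group), function(i) w2 * runif(1, 0.8, 1.2)))
  colnames(A) <- sprintf("s%02d", seq_len(2L * n_per_group))
  list(A = A, labels = rep(c(1L, 2L), each = n_per_group))
}
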