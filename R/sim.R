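#' Configuration for a synthetic statin-response cohort
#'
#' Defines the data-generating conditions for [simulate_cohort()]: cohort and
#' gene-panel sizes, how much response variance the planted signature genes and
#' trait SNPs carry, how strongly cis-eQTLs drive signature-gene expression,
#' and the nuisance structure (array batches, visit-level LDLC measurement
#' noise, an age effect).
#'
#' Variance fractions `trait_r2_expression` and `trait_r2_snps` refer to the
#' age-independent part of the latent response, which has unit variance by
#' construction; the age term (`age_effect` per year, ages uniform on 30-75)
#' adds variance on top and is removed again downstream by covariate
#' adjustment. Defaults mirror a cohort of 372 non-smoking statin trial
#' participants: a 100-gene signature carrying 12.3% of response variance, 36
#' of those genes driven by a strong cis-eQTL, and 7 genome-wide-significant
#' trait SNPs carrying a further 2.7%.
#'
#' @param n_samples Number of individuals.
#' @param n_genes Number of genes on the expression panel.
#' @param n_signature Number of planted signature genes (first genes in the
#'   panel); two thirds are up-regulated in high responders, one third down.
#' @param n_eqtl_genes Number of signature genes (a prefix of the signature)
#'   whose expression is partly driven by a cis-eQTL SNP.
#' @param eqtl_r2 Fraction of each eQTL gene's pre-batch expression variance
#'   explained by its SNP dosage, in `[0, 1]`.
#' @param n_gwas_snps Number of independent trait-associated SNPs.
#' @param trait_r2_expression Fraction of latent response variance carried by
#'   signature-gene expression.
#' @param trait_r2_snps Fraction of latent response variance carried by the
#'   GWAS SNPs. `trait_r2_expression + trait_r2_snps` must be `< 1`.
#' @param age_effect Latent-response slope per year of age.
#' @param maf_range Length-2 numeric, minor allele frequency range in
#'   `(0, 0.5]`; each SNP's MAF is drawn uniformly from it.
#' @param signature_cor Fraction of each signature gene's (non-eQTL)
#'   expression variance carried by a shared latent module factor, in
#'   `[0, 1)`. Signature genes in real cohorts are co-regulated (e.g. by
#'   intracellular cholesterol state), not independent; the module factor
#'   reproduces that block correlation, with up- and down-regulated genes
#'   loading with opposite signs.
#' @param n_batches Number of array batches (samples assigned round-robin).
#' @param batch_sd SD of per-gene, per-batch expression offsets.
#' @param noise_sd SD scale of per-gene expression (eQTL + residual core).
#' @param visit_cv Coefficient of variation of a single LDLC visit
#'   measurement (multiplicative lognormal noise per visit).
#' @param response_mean,response_sd Location/scale mapping the unit-variance
#'   latent response onto the log LDLC-change scale (defaults emulate a mean
#'   ~43% LDLC reduction with realistic between-subject spread).
#' @param smoker_frac Fraction of smokers among samples (smokers get no
#'   response shift; they exist to exercise the exclusion filter).
#' @param seed Integer seed making the cohort reproducible.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()], [write_cohort()]
#' @export
sim_config <- function(n_samples = 372L,
                       n_genes = 2000L,
                       n_signature = 100L,
                       n_eqtl_genes = 36L,
                       eqtl_r2 = 0.9,
                       n_gwas_snps = 7L,
                       trait_r2_expression = 0.123,
                       trait_r2_snps = 0.027,
                       age_effect = 0.014,
                       signature_cor = 0.5,
                       maf_range = c(0.1, 0.5),
                       n_batches = 4L,
                       batch_sd = 0.3,
                       noise_sd = 1,
                       visit_cv = 0.05,
                       response_mean = -0.56,
                       response_sd = 0.2,
                       smoker_frac = 0,
                       seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    n_signature = as.integer(n_signature),
    n_eqtl_genes = as.integer(n_eqtl_genes), eqtl_r2 = eqtl_r2,
    n_gwas_snps = as.integer(n_gwas_snps),
    trait_r2_expression = trait_r2_expression,
    trait_r2_snps = trait_r2_snps, age_effect = age_effect,
    signature_cor = signature_cor,
    maf_range = maf_range, n_batches = as.integer(n_batches),
    batch_sd = batch_sd, noise_sd = noise_sd, visit_cv = visit_cv,
    response_mean = response_mean, response_sd = response_sd,
    smoker_frac = smoker_frac, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  for (nm in c("n_samples", "n_genes", "n_signature", "n_batches")) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] < 1L)
      stop(sprintf("'%s' must be a positive count", nm))
  }
  if (cfg$n_eqtl_genes < 0L || cfg$n_gwas_snps < 0L)
    stop("'n_eqtl_genes' and 'n_gwas_snps' must be non-negative counts")
  if (cfg$n_eqtl_genes > cfg$n_signature)
    stop("'n_eqtl_genes' must not exceed 'n_signature'")
  if (cfg$n_signature > cfg$n_genes)
    stop("'n_signature' must not exceed 'n_genes'")
  if (cfg$eqtl_r2 < 0 || cfg$eqtl_r2 > 1)
    stop("'eqtl_r2' must lie in [0, 1]")
  if (cfg$signature_cor < 0 || cfg$signature_cor >= 1)
    stop("'signature_cor' must lie in [0, 1)")
  if (cfg$trait_r2_expression < 0 || cfg$trait_r2_snps < 0 ||
      cfg$trait_r2_expression + cfg$trait_r2_snps >= 1)
    stop("infeasible variance fractions: trait_r2_expression + ",
         "trait_r2_snps must be < 1, both non-negative")
  if (length(cfg$maf_range) != 2L || any(cfg$maf_range <= 0) ||
      any(cfg$maf_range > 0.5) || cfg$maf_range[1] > cfg$maf_range[2])
    stop("'maf_range' must be an increasing pair within (0, 0.5]")
  if (cfg$visit_cv < 0 || cfg$batch_sd < 0 || cfg$noise_sd < 0)
    stop("noise parameters must be non-negative")
  invisible(cfg)
}

## Center a vector and rescale to an exact empirical SD (0 allowed).
rescale_sd <- function(x, sd_target) {
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s == 0) return(rep(0, length(x)))
  x / s * sd_target
}

## Residualize x on the columns of `basis` (plus intercept), then rescale to
## an exact empirical SD. Gram-Schmidt for the response components: sampling
## covariance between components would otherwise distort the realized
## variance fractions by O(1/sqrt(n)).
orth_rescale <- function(x, basis, sd_target) {
  if (length(basis) && stats::sd(x) > 0) {
    bm <- do.call(cbind, basis)
    keep <- apply(bm, 2L, stats::sd) > 0
    if (any(keep))
      x <- stats::lm.fit(cbind(1, bm[, keep, drop = FALSE]), x)$residuals
  }
  rescale_sd(x, sd_target)
}

#' Simulate a synthetic statin-response cohort
#'
#' Generates expression, genotype, and phenotype data with the statistical
#' structure the downstream analysis assumes: Hardy-Weinberg genotype dosages
#' (`Binomial(2, maf)`), signature genes whose pre-batch expression is a
#' mixture of a standardized cis-eQTL dosage (weight `sqrt(eqtl_r2)`) and
#' Gaussian residual, array batch offsets, and a latent response that is a
#' weighted sum of signature-gene expression cores, GWAS SNP dosages, an age
#' term, and residual noise. Component weights are rescaled so the *realized*
#' variance fractions equal the configured ones exactly. The latent response
#' is mapped affinely onto the log LDLC-change scale and back-transformed into
#' two pre- and two post-treatment LDLC visit values with multiplicative
#' lognormal visit noise, so that `log(mean post) - log(mean pre)` recovers
#' the latent response (up to that affine map) plus measurement noise.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `sim_cohort`: a list with elements
#'   `expression` (gene x sample matrix, `state` attribute `"raw"`),
#'   `genotypes` (SNP x sample dosage matrix, values in `[0, 2]`),
#'   `phenotypes` (data frame with per-visit LDLC values and covariates),
#'   `truth` (planted signature genes with directions and weights, eQTL
#'   gene-SNP pairs with effects, GWAS SNP weights, per-sample latent
#'   response, batch assignments), and `config`.
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n  <- config$n_samples
  ng <- config$n_genes
  ns <- config$n_signature
  ne <- config$n_eqtl_genes

  gene_ids   <- sprintf("gene%04d", seq_len(ng))
  sample_ids <- sprintf("S%04d", seq_len(n))
  eqtl_snps  <- if (ne > 0L) sprintf("rsE%04d", seq_len(ne)) else character()
  gwas_snps  <- if (config$n_gwas_snps > 0L)
    sprintf("rsG%04d", seq_len(config$n_gwas_snps)) else character()
  snp_ids <- c(eqtl_snps, gwas_snps)

  ## genotypes under Hardy-Weinberg
  n_snps <- length(snp_ids)
  maf <- stats::runif(n_snps, config$maf_range[1], config$maf_range[2])
  G <- matrix(stats::rbinom(n_snps * n, 2L, rep(maf, each = n)),
              nrow = n_snps, ncol = n, byrow = TRUE,
              dimnames = list(snp_ids, sample_ids))
  storage.mode(G) <- "double"  # dosages may be fractional downstream

  ## covariates
  age <- stats::runif(n, 30, 75)
  sex <- stats::rbinom(n, 1L, 0.5)
  bmi <- stats::rnorm(n, 27.7, 5.3)
  smoker <- stats::rbinom(n, 1L, config$smoker_frac) == 1L
  batch <- rep_len(seq_len(config$n_batches), n)

  ## expression cores: unit-variance pre-batch mixtures of (a) the gene's
  ## cis-eQTL dosage (eQTL genes only), (b) a latent co-expression module
  ## factor shared by all signature genes (up-regulated genes load +, down
  ## -), and (c) gene-specific noise
  n_up <- ceiling(2 / 3 * ns)
  direction <- rep(c(1, -1), c(n_up, ns - n_up))
  module <- stats::rnorm(n)
  core <- matrix(stats::rnorm(ng * n), nrow = ng,
                 dimnames = list(gene_ids, sample_ids))
  rho <- config$signature_cor
  for (g in seq_len(ns)) {
    shared <- sqrt(rho) * direction[g] * module +
      sqrt(1 - rho) * core[g, ]
    if (g <= ne && stats::sd(G[eqtl_snps[g], ]) > 0) {
      z <- G[eqtl_snps[g], ]
      z <- (z - mean(z)) / stats::sd(z)
      core[g, ] <- sqrt(config$eqtl_r2) * z +
        sqrt(1 - config$eqtl_r2) * shared
    } else {
      core[g, ] <- shared
    }
  }
  batch_off <- matrix(stats::rnorm(ng * config$n_batches, 0, config$batch_sd),
                      nrow = ng)
  expr <- config$noise_sd * core + batch_off[, batch, drop = FALSE]
  dimnames(expr) <- list(gene_ids, sample_ids)
  attr(expr, "state") <- "raw"

  ## latent response: signature expression + GWAS SNPs + age + residual,
  ## each component centered and rescaled to its exact variance share
  w <- direction * (0.5 + stats::runif(ns))
  age_comp <- config$age_effect * (age - mean(age))
  expr_comp <- as.vector(crossprod(core[seq_len(ns), , drop = FALSE], w))
  expr_comp <- orth_rescale(expr_comp, list(age_comp),
                            sqrt(config$trait_r2_expression))

  if (config$n_gwas_snps > 0L) {
    v <- sample(c(-1, 1), config$n_gwas_snps, replace = TRUE) *
      (0.5 + stats::runif(config$n_gwas_snps))
    snp_comp <- as.vector(crossprod(G[gwas_snps, , drop = FALSE], v))
  } else {
    v <- numeric()
    snp_comp <- numeric(n)
  }
  snp_comp <- orth_rescale(snp_comp, list(age_comp, expr_comp),
                           sqrt(config$trait_r2_snps))

  resid <- orth_rescale(stats::rnorm(n),
                        list(age_comp, expr_comp, snp_comp),
                        sqrt(1 - config$trait_r2_expression -
                               config$trait_r2_snps))
  latent <- expr_comp + snp_comp + age_comp + resid

  ## back-transform to visit-level LDLC (mg/dL)
  log_change <- config$response_mean + config$response_sd * latent
  sdlog <- sqrt(log(1 + config$visit_cv^2))
  pre_base  <- pmax(stats::rnorm(n, 132, 28), 50)
  post_base <- pre_base * exp(log_change)
  visit <- function(base) base * exp(stats::rnorm(n, 0, sdlog))
  phen <- data.frame(
    sample_id = sample_ids,
    ldlc_pre1 = visit(pre_base),  ldlc_pre2 = visit(pre_base),
    ldlc_post1 = visit(post_base), ldlc_post2 = visit(post_base),
    age = age, sex = sex, bmi = bmi, smoker = smoker, batch = batch,
    stringsAsFactors = FALSE
  )

  truth <- list(
    signature_genes = gene_ids[seq_len(ns)],
    direction = stats::setNames(direction, gene_ids[seq_len(ns)]),
    weights = stats::setNames(w, gene_ids[seq_len(ns)]),
    eqtl = data.frame(gene = gene_ids[seq_len2(ne)],
                      snp = eqtl_snps,
                      effect = rep(sqrt(config$eqtl_r2), ne),
                      maf = maf[seq_len2(ne)],
                      stringsAsFactors = FALSE),
    gwas = data.frame(snp = gwas_snps, weight = v,
                      maf = if (n_snps > 0L) maf[ne + seq_len(config$n_gwas_snps)]
                            else numeric(),
                      stringsAsFactors = FALSE),
    latent_response = stats::setNames(latent, sample_ids),
    components = list(expression = stats::setNames(expr_comp, sample_ids),
                      snps = stats::setNames(snp_comp, sample_ids),
                      age = stats::setNames(age_comp, sample_ids),
                      module = stats::setNames(module, sample_ids)),
    response_scale = c(mean = config$response_mean, sd = config$response_sd),
    batch = stats::setNames(batch, sample_ids)
  )

  out <- list(expression = expr, genotypes = G, phenotypes = phen,
              truth = truth, config = config)
  class(out) <- "sim_cohort"
  out
}

## seq_len that tolerates 0 without surprises (used for truth tables)
seq_len2 <- function(k) if (k > 0L) seq_len(k) else integer()

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "sim_cohort: %d samples, %d genes (%d signature, %d with eQTL), %d SNPs\n",
    ncol(x$expression), nrow(x$expression), x$config$n_signature,
    x$config$n_eqtl_genes, nrow(x$genotypes)))
  invisible(x)
}

#' eQTL association table for a simulated cohort
#'
#' Builds the gene-SNP association table the feature-assembly stage consumes,
#' by measuring each planted eQTL pair's association p-value on the simulated
#' data (linear regression of expression on dosage) and adding one decoy SNP
#' per eQTL gene (a random trait-unrelated SNP whose p-value is likewise
#' measured, hence approximately uniform) so the significance filter has
#' something to reject.
#'
#' @param cohort A `sim_cohort`.
#' @return Data frame with columns `gene`, `snp`, `p_value`, `source`.
#' @export
eqtl_table_from_truth <- function(cohort) {
  stopifnot(inherits(cohort, "sim_cohort"))
  tr <- cohort$truth$eqtl
  if (nrow(tr) == 0L)
    return(data.frame(gene = character(), snp = character(),
                      p_value = numeric(), source = character(),
                      stringsAsFactors = FALSE))
  assoc_p <- function(gene, snp) {
    x <- cohort$genotypes[snp, ]
    y <- cohort$expression[gene, ]
    if (stats::sd(x) == 0) return(1)
    stats::summary.lm(stats::lm(y ~ x))$coefficients[2, 4]
  }
  true_p <- mapply(assoc_p, tr$gene, tr$snp)
  ## decoys: pair each eQTL gene with some other SNP
  snp_pool <- rownames(cohort$genotypes)
  decoy_snp <- snp_pool[(match(tr$snp, snp_pool) %% length(snp_pool)) + 1L]
  decoy_p <- mapply(assoc_p, tr$gene, decoy_snp)
  out <- rbind(
    data.frame(gene = tr$gene, snp = tr$snp, p_value = unname(true_p),
               source = "synthetic_true", stringsAsFactors = FALSE),
    data.frame(gene = tr$gene, snp = decoy_snp, p_value = unname(decoy_p),
               source = "synthetic_decoy", stringsAsFactors = FALSE)
  )
  out[out$p_value <= 0, "p_value"] <- .Machine$double.xmin
  out
}
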