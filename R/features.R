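#' Pick each signature gene's best eQTL SNP
#'
#' Filters an eQTL association table to signature genes with
#' `p_value < p_threshold` and keeps, per gene, the most strongly associated
#' SNP (smallest p; ties broken by lexicographically smallest SNP id). Genes
#' with no qualifying eQTL are simply absent from the map.
#'
#' @param eqtls Data frame with columns `gene`, `snp`, `p_value` (see
#'   [read_eqtl_table()]).
#' @param signature Character vector of signature gene ids.
#' @param p_threshold Association significance threshold (default `5e-8`,
#'   genome-wide significance).
#' @return Named character vector: `names` are covered genes, values their
#'   best SNP. Empty (with a warning) when no gene passes.
#' @export
select_best_eqtls <- function(eqtls, signature, p_threshold = 5e-8) {
  stopifnot(all(c("gene", "snp", "p_value") %in% names(eqtls)),
            nrow(eqtls) > 0L)
  hit <- eqtls[eqtls$gene %in% signature & eqtls$p_value < p_threshold, ,
               drop = FALSE]
  if (nrow(hit) == 0L) {
    warning("no signature gene has an eQTL at p < ", p_threshold)
    return(stats::setNames(character(), character()))
  }
  hit <- hit[order(hit$gene, hit$p_value, hit$snp), , drop = FALSE]
  best <- hit[!duplicated(hit$gene), , drop = FALSE]
  stats::setNames(best$snp, best$gene)
}

#' Specify a named feature model
#'
#' A feature model is an ordered list of components, each an expression
#' feature (a gene), an eQTL genotype feature (a SNP standing in for a
#' gene), or a GWAS SNP feature. Canned variants of the study's models are
#' built by [canned_feature_specs()].
#'
#' @param name Model label.
#' @param expression_genes Gene ids entering as expression levels.
#' @param eqtl_map Named character vector gene -> SNP; these SNP dosages
#'   enter as features (names record which signature gene each covers).
#' @param gwas_snps SNP ids entering as trait-associated genotype features.
#' @return Object of class `feature_spec`.
#' @export
feature_spec <- function(name, expression_genes = character(),
                         eqtl_map = character(), gwas_snps = character()) {
  ids <- c(paste0("expr:", expression_genes),
           paste0("eqtl:", unname(eqtl_map)),
           paste0("gwas:", gwas_snps))
  if (anyDuplicated(ids))
    stop("duplicate feature ids in model '", name, "'")
  structure(list(name = name,
                 expression_genes = expression_genes,
                 eqtl_map = eqtl_map,
                 gwas_snps = gwas_snps),
            class = "feature_spec")
}

#' Canned feature models for the study's comparisons
#'
#' Builds the standard model set given a signature, an eQTL best-SNP map and
#' a GWAS SNP list:
#' * `sg` — all signature genes as expression features;
#' * `eqtl_only` — only the best eQTL SNP dosages of the covered genes;
#' * `sg_plus_eqtl` — combined: every signature gene's expression, plus the
#'   eQTL dosage for covered genes (covered genes contribute both);
#' * `substitution` — eQTL dosages *replace* expression for covered genes
#'   (uncovered genes keep their expression feature);
#' * `gwas_only`, `sg_plus_gwas`, `all_features` — analogous with the GWAS
#'   SNPs.
#'
#' @param signature Character vector of signature gene ids.
#' @param eqtl_map Named character vector gene -> SNP (see
#'   [select_best_eqtls()]).
#' @param gwas_snps Character vector of GWAS SNP ids.
#' @return Named list of `feature_spec` objects.
#' @export
canned_feature_specs <- function(signature, eqtl_map = character(),
                                 gwas_snps = character()) {
  covered <- names(eqtl_map)
  uncovered <- setdiff(signature, covered)
  specs <- list(
    sg = feature_spec("sg", expression_genes = signature),
    eqtl_only = feature_spec("eqtl_only", eqtl_map = eqtl_map),
    sg_plus_eqtl = feature_spec("sg_plus_eqtl",
                                expression_genes = signature,
                                eqtl_map = eqtl_map),
    substitution = feature_spec("substitution",
                                expression_genes = uncovered,
                                eqtl_map = eqtl_map),
    gwas_only = feature_spec("gwas_only", gwas_snps = gwas_snps),
    sg_plus_gwas = feature_spec("sg_plus_gwas",
                                expression_genes = signature,
                                gwas_snps = gwas_snps),
    all_features = feature_spec("all_features",
                                expression_genes = signature,
                                eqtl_map = eqtl_map,
                                gwas_snps = gwas_snps)
  )
  specs
}

#' Assemble a sample-by-feature matrix for a model
#'
#' Pulls expression rows and genotype dosage rows for the spec's components
#' into one numeric matrix (samples in rows, features in columns, column
#' order: expression, then eQTL dosages, then GWAS dosages, each in spec
#' order). Missing dosage entries are imputed with the feature mean computed
#' over the requested samples; standardization is deliberately *not* done
#' here — the prediction stage standardizes with training-set statistics
#' only, so information cannot leak across CV splits.
#'
#' @param spec A `feature_spec`.
#' @param expression Gene x sample matrix.
#' @param genotypes SNP x sample dosage matrix (may be NULL if the spec has
#'   no genotype features).
#' @param samples Sample ids (must exist in every source used).
#' @return Numeric samples x features matrix; feature columns are named
#'   `expr:<gene>`, `eqtl:<snp>`, `gwas:<snp>`.
#' @export
assemble_features <- function(spec, expression, genotypes = NULL, samples) {
  stopifnot(inherits(spec, "feature_spec"))
  miss_e <- setdiff(spec$expression_genes, rownames(expression))
  if (length(miss_e))
    stop("feature(s) absent from expression matrix: ",
         paste(miss_e, collapse = ", "))
  snp_feats <- c(unname(spec$eqtl_map), spec$gwas_snps)
  if (length(snp_feats)) {
    if (is.null(genotypes)) stop("spec needs genotypes but none supplied")
    miss_s <- setdiff(snp_feats, rownames(genotypes))
    if (length(miss_s))
      stop("feature(s) absent from genotype matrix: ",
           paste(miss_s, collapse = ", "))
  }
  bad <- setdiff(samples, colnames(expression))
  if (length(spec$expression_genes) && length(bad))
    stop("sample(s) absent from expression matrix: ",
         paste(bad, collapse = ", "))

  blocks <- list()
  if (length(spec$expression_genes))
    blocks$expr <- t(expression[spec$expression_genes, samples,
                                drop = FALSE])
  if (length(snp_feats)) {
    g <- t(genotypes[snp_feats, samples, drop = FALSE])
    if (anyNA(g)) {
      for (j in seq_len(ncol(g))) {
        nas <- is.na(g[, j])
        if (any(nas)) g[nas, j] <- mean(g[!nas, j])
      }
    }
    blocks$geno <- g
  }
  X <- do.call(cbind, blocks)
  colnames(X) <- c(
    if (length(spec$expression_genes)) paste0("expr:", spec$expression_genes),
    if (length(spec$eqtl_map)) paste0("eqtl:", unname(spec$eqtl_map)),
    if (length(spec$gwas_snps)) paste0("gwas:", spec$gwas_snps))
  rownames(X) <- samples
  X
}
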