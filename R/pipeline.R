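#' Pipeline configuration
#'
#' Bundles the input paths and every stage parameter, with defaults at the
#' study's operating values: 2,000 preselected genes, 500 NMF runs, 500
#' random baseline sets, purity cutoff 0.9, 1,000 permutations, a 100-gene
#' signature, eQTL threshold `5e-8`, 1,000 CV repeats, and tail fractions
#' from 10% in 5% steps. Any of these can be dialed down for smaller
#' problems.
#'
#' @param expression,phenotypes,genotypes,eqtl,gwas Input file paths
#'   (genotypes/eqtl/gwas may be NULL to skip genotype-based models).
#' @param out_dir Output directory.
#' @param exclude_smokers,alpha Covariate stage controls.
#' @param N_grid,n_genes_preselect,n_random_sets,purity_cutoff,nmf_runs Tail
#'   selection controls.
#' @param n_perm,n_select Signature stage controls.
#' @param eqtl_p eQTL significance threshold.
#' @param cv_repeats,holdout_fraction,fractions Prediction stage controls.
#' @param seed Master seed for every stochastic stage.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, phenotypes, genotypes = NULL,
                            eqtl = NULL, gwas = NULL, out_dir,
                            exclude_smokers = TRUE, alpha = 0.05,
                            N_grid = seq(20L, 80L, 2L),
                            n_genes_preselect = 2000L,
                            n_random_sets = 500L, purity_cutoff = 0.9,
                            nmf_runs = 500L,
                            n_perm = 1000L, n_select = 100L,
                            eqtl_p = 5e-8,
                            cv_repeats = 1000L, holdout_fraction = 0.1,
                            fractions = seq(0.10, 1, 0.05),
                            seed = 1L) {
  cfg <- list(
    expression = expression, phenotypes = phenotypes, genotypes = genotypes,
    eqtl = eqtl, gwas = gwas, out_dir = out_dir,
    exclude_smokers = exclude_smokers, alpha = alpha, N_grid = N_grid,
    n_genes_preselect = n_genes_preselect, n_random_sets = n_random_sets,
    purity_cutoff = purity_cutoff, nmf_runs = nmf_runs, n_perm = n_perm,
    n_select = n_select, eqtl_p = eqtl_p, cv_repeats = cv_repeats,
    holdout_fraction = holdout_fraction, fractions = fractions, seed = seed)
  if (cfg$n_select < 1L) stop("signature size must be a positive count")
  if (cfg$purity_cutoff < 0 || cfg$purity_cutoff > 1)
    stop("purity cutoff must lie in [0, 1]")
  for (f in c("expression", "phenotypes"))
    if (!file.exists(cfg[[f]])) stop("input not readable: ", cfg[[f]])
  class(cfg) <- "pipeline_config"
  cfg
}

write_tsv_generic <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    rows <- vapply(seq_len(nrow(df)), function(i) {
      paste(vapply(df[i, , drop = FALSE], function(v) {
        if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
      }, character(1)), collapse = "\t")
    }, character(1))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: (1) preprocessing — response derivation, covariate
#' screening/adjustment, expression normalization; (2) extreme-tail
#' selection by NMF purity; (3) signature-gene discovery with the varying-s0
#' permutation statistic; (4) feature assembly for the canned model set; (5)
#' SVM evaluation — AUC tail sweep for the signature model and
#' cross-validated explained variance per model. Writes stage outputs as TSV
#' and a JSON manifest recording package version, parameters, seeds, input
#' checksums, and output files; the manifest contains no timestamps, so a
#' rerun under an identical config is byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, the manifest (a list). Side effect: files under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[statresp] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  out <- function(f) file.path(config$out_dir, f)
  manifest <- list(
    package = "statresp",
    version = as.character(utils::packageVersion("statresp")),
    seed = config$seed,
    parameters = config[setdiff(names(config),
                                c("expression", "phenotypes", "genotypes",
                                  "eqtl", "gwas", "out_dir"))],
    inputs = list(), stages = list(), outputs = character()
  )
  for (f in c("expression", "phenotypes", "genotypes", "eqtl", "gwas")) {
    if (!is.null(config[[f]]))
      manifest$inputs[[f]] <- list(
        path = config[[f]],
        md5 = unname(tools::md5sum(config[[f]])))
  }

  ## stage 1: preprocess
  say("stage preprocess")
  prep <- stage("preprocess", {
    expr_raw <- read_expression(config$expression)
    phen <- read_phenotypes(config$phenotypes)
    phen <- derive_response(phen, exclude_smokers = config$exclude_smokers)
    adj <- screen_and_adjust_covariates(phen, alpha = config$alpha)
    expr_raw <- expr_raw[, adj$phenotypes$sample_id, drop = FALSE]
    attr(expr_raw, "state") <- "raw"
    ## technical covariates known to the arrays: batch surrogate = none in
    ## file inputs, so normalize without residualization unless a batch
    ## column is present in the phenotype table
    batch_cov <- NULL
    if ("batch" %in% names(adj$phenotypes))
      batch_cov <- data.frame(batch = factor(adj$phenotypes$batch))
    norm <- normalize_expression(expr_raw, batch_cov)
    list(phenotypes = adj$phenotypes, kept = adj$kept, expression = norm)
  })
  responses <- stats::setNames(prep$phenotypes$adjusted_change,
                               prep$phenotypes$sample_id)
  write_tsv_generic(prep$phenotypes, out("phenotypes_adjusted.tsv"))
  write_matrix_tsv(prep$expression, out("expression_normalized.tsv"),
                   "gene_id")
  manifest$stages$preprocess <- list(
    n_samples = length(responses), kept_covariates = prep$kept)

  ## stage 2: tail selection
  say("stage select_tails")
  tails <- stage("select_tails", {
    grid <- config$N_grid[config$N_grid <= length(responses)]
    select_tail_subset(prep$expression, responses, N_grid = grid,
                       n_genes_preselect = config$n_genes_preselect,
                       n_random_sets = config$n_random_sets,
                       purity_cutoff = config$purity_cutoff,
                       n_runs = config$nmf_runs, seed = config$seed)
  })
  write_tsv_generic(tails$curve, out("purity_curve.tsv"))
  write_tsv_generic(data.frame(sample_id = c(tails$high_ids, tails$low_ids),
                               group = rep(c("high", "low"),
                                           each = length(tails$high_ids))),
                    out("selected_tails.tsv"))
  manifest$stages$select_tails <- list(chosen_n = tails$chosen_n)

  ## stage 3: signature discovery
  say("stage signature")
  sig <- stage("signature", {
    discover_signature(prep$expression, tails$high_ids, tails$low_ids,
                       n_perm = config$n_perm, n_select = config$n_select,
                       seed = config$seed)
  })
  write_tsv_generic(sig$signature, out("signature.tsv"))
  manifest$stages$signature <- list(
    n_select = config$n_select,
    s0_max = if (is.null(sig$schedule)) 0 else sig$schedule$s0_max,
    n_up_in_high = sum(sig$signature$direction == "up_in_high"))

  ## stage 4: feature assembly
  say("stage assemble")
  asm <- stage("assemble", {
    genotypes <- if (!is.null(config$genotypes))
      read_genotypes(config$genotypes) else NULL
    eqtl_map <- character()
    gwas_snps <- character()
    if (!is.null(config$eqtl) && !is.null(genotypes)) {
      eq <- read_eqtl_table(config$eqtl)
      eqtl_map <- suppressWarnings(
        select_best_eqtls(eq, sig$signature$gene, config$eqtl_p))
    }
    if (!is.null(config$gwas) && !is.null(genotypes)) {
      gw <- utils::read.delim(config$gwas, stringsAsFactors = FALSE)
      gwas_snps <- intersect(gw$snp, rownames(genotypes))
    }
    specs <- canned_feature_specs(sig$signature$gene, eqtl_map, gwas_snps)
    keep <- vapply(specs, function(sp)
      length(sp$expression_genes) + length(sp$eqtl_map) +
        length(sp$gwas_snps) > 0, logical(1))
    specs <- specs[keep]
    mats <- lapply(specs, assemble_features, expression = prep$expression,
                   genotypes = genotypes, samples = names(responses))
    list(specs = specs, mats = mats, eqtl_map = eqtl_map,
         gwas_snps = gwas_snps)
  })
  manifest$stages$assemble <- list(
    models = names(asm$specs),
    n_eqtl_covered = length(asm$eqtl_map),
    n_gwas = length(asm$gwas_snps))

  ## stage 5: prediction / evaluation
  say("stage predict")
  pred <- stage("predict", {
    scheme <- cv_scheme(config$cv_repeats, config$holdout_fraction,
                        seed = config$seed)
    sweep_tab <- suppressWarnings(
      tail_sweep(asm$mats$sg, responses, fractions = config$fractions,
                 scheme = scheme))
    ev <- lapply(seq_along(asm$mats), function(i)
      explained_variance(asm$mats[[i]], unname(responses),
                         cv_scheme(config$cv_repeats,
                                   config$holdout_fraction,
                                   seed = config$seed + i)))
    names(ev) <- names(asm$mats)
    list(sweep = sweep_tab, ev = ev)
  })
  write_tsv_generic(pred$sweep, out("auc_tail_sweep.tsv"))
  ev_tab <- model_comparison_report(pred$ev, baseline = "sg")
  write_tsv_generic(ev_tab, out("explained_variance.tsv"))
  manifest$stages$predict <- list(
    auc_max = max(pred$sweep$auc),
    auc_max_fraction = pred$sweep$fraction[which.max(pred$sweep$auc)],
    explained_variance_pct = stats::setNames(
      as.list(ev_tab$value), ev_tab$model))

  manifest$outputs <- basename(c(
    out("phenotypes_adjusted.tsv"), out("expression_normalized.tsv"),
    out("purity_curve.tsv"), out("selected_tails.tsv"),
    out("signature.tsv"), out("auc_tail_sweep.tsv"),
    out("explained_variance.tsv")))
  manifest_json <- jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                    digits = NA, pretty = TRUE, null = "null")
  con <- file(out("manifest.json"), open = "wb")
  writeLines(manifest_json, con)
  close(con)
  say("done: ", config$out_dir)
  invisible(manifest)
}
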