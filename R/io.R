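## File formats
##
## Canonical interchange is tab-separated text with an explicit header
## contract:
##   expression TSV: first column `gene_id`, remaining columns one per sample.
##   genotype TSV:   first column `snp_id`, dosage floats in [0, 2].
##   phenotype TSV:  columns sample_id, ldlc_pre1, ldlc_pre2, ldlc_post1,
##                   ldlc_post2, age, sex, bmi, smoker.
##   eQTL TSV:       columns gene, snp, p_value, source.
## Numeric cells are written with "%.17g" so matrices round-trip to machine
## precision and regeneration under a fixed seed is byte-identical.

write_matrix_tsv <- function(mat, path, id_col) {
  con <- file(path, open = "wb")  # binary: LF endings on every platform
  on.exit(close(con))
  writeLines(paste(c(id_col, colnames(mat)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], sprintf("%.17g", mat[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

read_matrix_tsv <- function(path, id_col, what) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || names(df)[1] != id_col)
    stop(sprintf("%s: expected first column '%s', found '%s'",
                 what, id_col, names(df)[1]))
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop(sprintf("%s: duplicated id '%s'", what, ids[duplicated(ids)][1]))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    stop(sprintf("%s: non-numeric values in column '%s'",
                 what, names(df)[-1][bad]))
  }
  rownames(m) <- ids
  storage.mode(m) <- "double"
  m
}

#' Read an expression matrix from TSV
#'
#' @param path Path to a tab-delimited file, first column `gene_id`, one
#'   column per sample.
#' @param state Normalization state to stamp on the matrix (`"raw"` for
#'   freshly simulated/measured data).
#' @return Numeric gene x sample matrix with a `state` attribute.
#' @export
read_expression <- function(path, state = "raw") {
  m <- read_matrix_tsv(path, "gene_id", "expression matrix")
  attr(m, "state") <- state
  m
}

#' Read a genotype dosage matrix (TSV or VCF)
#'
#' TSV input must have first column `snp_id` and per-sample dosage columns.
#' Files ending in `.vcf` are parsed as VCF 4.2 and dosages taken from the
#' `DS` FORMAT field (requires the `vcfR` package).
#'
#' @param path Path to the genotype file.
#' @return Numeric SNP x sample matrix with entries in `[0, 2]`.
#' @export
read_genotypes <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("reading VCF genotypes requires the 'vcfR' package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    if (is.null(ds)) stop("VCF has no DS (dosage) FORMAT field")
    storage.mode(ds) <- "double"
    m <- ds
  } else {
    m <- read_matrix_tsv(path, "snp_id", "genotype matrix")
  }
  if (any(m < 0 | m > 2, na.rm = TRUE))
    stop("genotype dosages must lie in [0, 2]")
  m
}

#' Read a phenotype table from TSV
#'
#' @param path Path to a tab-delimited file with columns `sample_id`,
#'   `ldlc_pre1`, `ldlc_pre2`, `ldlc_post1`, `ldlc_post2`, `age`, `sex`,
#'   `bmi`, `smoker`.
#' @return Data frame keyed by `sample_id`.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "ldlc_pre1", "ldlc_pre2", "ldlc_post1",
            "ldlc_post2", "age", "sex", "bmi", "smoker")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("phenotype table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("phenotype table: duplicated sample_id '",
         df$sample_id[duplicated(df$sample_id)][1], "'")
  df$smoker <- as.logical(df$smoker)
  df
}

#' Read an eQTL association table from TSV
#'
#' @param path Path to a tab-delimited file with columns `gene`, `snp`,
#'   `p_value` and optionally `source`.
#' @return Data frame of eQTL records with `p_value` validated in `(0, 1]`.
#' @export
read_eqtl_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "snp", "p_value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("eQTL table missing column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(df$p_value) || any(df$p_value <= 0 | df$p_value > 1))
    stop("eQTL p_value must be numeric in (0, 1]")
  if (is.null(df$source)) df$source <- NA_character_
  df
}

write_phenotypes_tsv <- function(phen, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(phen), collapse = "\t"), con)
  rows <- vapply(seq_len(nrow(phen)), function(i) {
    cells <- vapply(names(phen), function(nm) {
      v <- phen[[nm]][i]
      if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
    }, character(1))
    paste(cells, collapse = "\t")
  }, character(1))
  writeLines(rows, con)
  invisible(path)
}

write_vcf_ds <- function(G, maf_ref, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of ALT allele\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(G)), collapse = "\t")), con)
  body <- vapply(seq_len(nrow(G)), function(i) {
    paste(c("1", as.character(i * 1000L), rownames(G)[i], "A", "G", ".",
            "PASS", ".", "DS", sprintf("%.17g", G[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Write a simulated cohort to a directory of plain-text files
#'
#' Emits `expression.tsv`, `genotypes.tsv`, `phenotypes.tsv`, an eQTL
#' association table `eqtl.tsv` (measured on the simulated data, see
#' [eqtl_table_from_truth()]), a GWAS SNP list `gwas_snps.tsv`, a structured
#' truth manifest `truth.json`, and optionally `genotypes.vcf` (VCF 4.2 with
#' a `DS` dosage FORMAT field). Output is byte-identical for identical
#' cohorts and round-trips losslessly through the package readers.
#'
#' @param cohort A `sim_cohort` from [simulate_cohort()].
#' @param directory Output directory (created if absent).
#' @param vcf Also write the genotypes as VCF 4.2 with DS dosages.
#' @return Invisibly, a named character vector of the files written.
#' @export
write_cohort <- function(cohort, directory, vcf = FALSE) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(directory, f)
  files <- c(expression = p("expression.tsv"), genotypes = p("genotypes.tsv"),
             phenotypes = p("phenotypes.tsv"), eqtl = p("eqtl.tsv"),
             gwas = p("gwas_snps.tsv"), truth = p("truth.json"))
  write_matrix_tsv(cohort$expression, files["expression"], "gene_id")
  write_matrix_tsv(cohort$genotypes, files["genotypes"], "snp_id")
  write_phenotypes_tsv(cohort$phenotypes, files["phenotypes"])

  eq <- eqtl_table_from_truth(cohort)
  con <- file(files["eqtl"], open = "wb"); on.exit(close(con), add = TRUE)
  writeLines(c("gene\tsnp\tp_value\tsource",
               if (nrow(eq)) sprintf("%s\t%s\t%.17g\t%s", eq$gene, eq$snp,
                                     eq$p_value, eq$source)), con)

  con2 <- file(files["gwas"], open = "wb"); on.exit(close(con2), add = TRUE)
  gw <- cohort$truth$gwas
  writeLines(c("snp\tannotation",
               if (nrow(gw)) sprintf("%s\ttrait_associated", gw$snp)), con2)

  truth_json <- jsonlite::toJSON(cohort$truth, digits = NA, auto_unbox = TRUE,
                                 dataframe = "columns")
  writeLines(truth_json, con3 <- file(files["truth"], open = "wb"))
  close(con3)

  if (vcf) {
    files <- c(files, vcf = p("genotypes.vcf"))
    write_vcf_ds(cohort$genotypes, NULL, files["vcf"])
  }
  invisible(files)
}
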