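# Plain-text interchange: genes x samples count TSVs with a TSS sidecar,
# dosage TSVs with variant metadata, clinical TSVs, eQTL summary-statistic
# TSVs (the cross-cohort exchange format for two-sample MR), and JSON
# manifests / ground-truth sidecars.

#' Write / read an expression matrix as TSV with a TSS sidecar
#'
#' @param E an [expr_matrix()].
#' @param path output TSV (genes x samples; first column `gene_id`).
#' @param tss_path sidecar TSV with `gene_id`, `chrom`, `tss` (1-based).
#' @export
write_expression_tsv <- function(E, path, tss_path) {
  df <- data.frame(gene_id = rownames(E$values), E$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(E$gene_meta, tss_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @param scale_flag scale of the stored values.
#' @export
read_expression_tsv <- function(path, tss_path, scale_flag = "raw") {
  df <- utils::read.delim(path, check.names = FALSE)
  V <- as.matrix(df[, -1, drop = FALSE])
  rownames(V) <- df$gene_id
  meta <- utils::read.delim(tss_path)
  expr_matrix(V, meta, scale_flag)
}

#' Write / read a genotype dosage matrix as TSV
#'
#' Samples in rows; the variant metadata is stored in a sidecar TSV.
#'
#' @param G a [geno_matrix()].
#' @param path dosage TSV (first column `sample_id`).
#' @param meta_path variant metadata TSV.
#' @export
write_dosage_tsv <- function(G, path, meta_path) {
  df <- data.frame(sample_id = rownames(G$dosages), G$dosages,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(G$variant_meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path, meta_path) {
  df <- utils::read.delim(path, check.names = FALSE)
  D <- as.matrix(df[, -1, drop = FALSE])
  rownames(D) <- df$sample_id
  geno_matrix(D, utils::read.delim(meta_path))
}

#' Write / read a clinical table as TSV
#'
#' @param clinical validated clinical data.frame.
#' @param path output TSV.
#' @export
write_clinical_tsv <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_clinical_tsv
#' @export
read_clinical_tsv <- function(path) {
  validate_clinical(utils::read.delim(path))
}

#' Write eQTL summary statistics (cross-cohort exchange format)
#'
#' The TSV consumed by the two-sample MR stage: `gene_id`, `variant_id`,
#' `chrom`, `pos`, `beta`, `se`, `p_nominal`.
#'
#' @param eqtls data.frame from [map_cis_eqtl()].
#' @param path output TSV.
#' @export
write_eqtl_tsv <- function(eqtls, path) {
  utils::write.table(
    eqtls[, c("gene_id", "variant_id", "chrom", "pos", "beta", "se",
              "p_nominal")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eqtl_tsv
#' @export
read_eqtl_tsv <- function(path) utils::read.delim(path)

#' Write a run manifest or ground truth as JSON
#'
#' @param x manifest list (or `ground_truth`).
#' @param path output JSON path.
#' @export
write_manifest_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
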