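#' @keywords internal
"_PACKAGE"

# Lightweight S3 containers. Matrices carry their metadata as attributes so
# every stage can be run and inspected interactively; validators are strict
# so contract violations surface at the module boundary, not deep in a fit.

#' Construct an expression matrix
#'
#' A genes x samples matrix tagged with per-gene TSS coordinates and a scale
#' flag. The scale flag tracks the only admissible processing order:
#' `raw` -> `uq_normalized` -> `log2`.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene ids) and colnames (sample ids).
#' @param gene_meta data.frame with columns `gene_id`, `chrom`, `tss`
#'   (1-based position), one row per gene of `values`.
#' @param scale_flag one of `"raw"`, `"uq_normalized"`, `"log2"`.
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, gene_meta, scale_flag = c("raw", "uq_normalized", "log2")) {
  scale_flag <- match.arg(scale_flag)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (scale_flag == "raw" && any(values < 0)) stop("negative values on raw scale")
  gene_meta <- as.data.frame(gene_meta)
  need <- c("gene_id", "chrom", "tss")
  if (!all(need %in% names(gene_meta)))
    stop("gene_meta needs columns: ", paste(need, collapse = ", "))
  if (!setequal(gene_meta$gene_id, rownames(values)))
    stop("gene_meta does not match the matrix genes")
  gene_meta <- gene_meta[match(rownames(values), gene_meta$gene_id), , drop = FALSE]
  rownames(gene_meta) <- NULL
  structure(list(values = values, gene_meta = gene_meta, scale_flag = scale_flag),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$scale_flag))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Construct a genotype dosage matrix
#'
#' Samples x variants dosages in \[0, 2\] with variant metadata (chromosome,
#' position, effect/other allele, empirical MAF).
#'
#' @param dosages numeric matrix, samples in rows, variants in columns, with
#'   sample rownames and variant colnames.
#' @param variant_meta data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `maf`.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosages, variant_meta) {
  stopifnot(is.matrix(dosages), is.numeric(dosages))
  if (is.null(rownames(dosages)) || is.null(colnames(dosages)))
    stop("dosage matrix needs sample rownames and variant colnames")
  if (any(dosages < 0 | dosages > 2)) stop("dosages must lie in [0, 2]")
  variant_meta <- as.data.frame(variant_meta)
  need <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele", "maf")
  if (!all(need %in% names(variant_meta)))
    stop("variant_meta needs columns: ", paste(need, collapse = ", "))
  if (!setequal(variant_meta$variant_id, colnames(dosages)))
    stop("variant_meta does not match the matrix variants")
  variant_meta <- variant_meta[match(colnames(dosages), variant_meta$variant_id), , drop = FALSE]
  rownames(variant_meta) <- NULL
  structure(list(dosages = dosages, variant_meta = variant_meta), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d variants (MAF %.3f-%.3f)\n",
              nrow(x$dosages), ncol(x$dosages),
              min(x$variant_meta$maf), max(x$variant_meta$maf)))
  invisible(x)
}

#' Validate a clinical table
#'
#' Checks that a clinical data.frame carries the columns the survival models
#' need and that they are well formed. Aborts naming the first missing column.
#'
#' @param clinical data.frame with at least `sample_id`, `os_time`,
#'   `os_event`, `arm`.
#' @param required character vector of required column names.
#' @return The table, invisibly, with `arm` as character.
#' @export
validate_clinical <- function(clinical,
                              required = c("sample_id", "os_time", "os_event", "arm")) {
  clinical <- as.data.frame(clinical)
  missing <- setdiff(required, names(clinical))
  if (length(missing))
    stop("clinical table is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(clinical$sample_id)) stop("duplicate sample_id in clinical table")
  if (any(clinical$os_time <= 0)) stop("os_time must be positive")
  if (!all(clinical$os_event %in% c(0, 1))) stop("os_event must be 0/1")
  clinical$arm <- as.character(clinical$arm)
  invisible(clinical)
}

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library calls never perturb user code.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

# Deterministic 32-bit sub-seed from a base seed and a string label, so that
# per-gene permutation streams are reproducible under any scheduling order.
derive_seed <- function(seed, label) {
  h <- 0
  for (k in utf8ToInt(as.character(label))) h <- (h * 31 + k) %% 2147483647L
  as.integer((as.double(seed) * 2654435761 + h) %% 2147483647L)
}
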