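# Preprocessing and QC for RNA-seq counts: sample-level filters, gene
# filters, upper-quartile normalization, log2 transform, chromosome-Y sex
# inference, immune-cell abundance enrichment, and PCA.
#
# The admissible order is enforced through the expression scale flag:
# raw -> uq_normalized -> log2. Calling a step out of order is an error.

require_scale <- function(E, scale) {
  if (!inherits(E, "expr_matrix")) stop("not an expr_matrix")
  if (E$scale_flag != scale)
    stop(sprintf("operation requires scale '%s' but matrix is '%s' (pipeline order: raw -> uq_normalized -> log2)",
                 scale, E$scale_flag))
  invisible(E)
}

#' Remove low-quality and duplicated samples
#'
#' Sample-level QC, applied before gene filtering: drops samples with more
#' than 50 percent zero-count genes, and reports (and drops) duplicated
#' samples. Duplication is flagged by exact sample-id duplication or by
#' near-identical expression (Pearson correlation >= `dup_cor`); both
#' criteria are recorded in the report.
#'
#' @param E raw-scale [expr_matrix()].
#' @param max_zero_frac samples with a higher zero fraction are removed.
#' @param dup_cor correlation threshold flagging an expression duplicate.
#' @return list with `E` (filtered) and `report` (removed sample ids and the
#'   triggering rule).
#' @export
filter_samples <- function(E, max_zero_frac = 0.5, dup_cor = 0.999) {
  require_scale(E, "raw")
  zf <- colMeans(E$values == 0)
  drop_zero <- colnames(E$values)[zf > max_zero_frac]
  keep <- setdiff(colnames(E$values), drop_zero)
  V <- E$values[, keep, drop = FALSE]
  dup <- character(0)
  if (ncol(V) > 1) {
    cc <- suppressWarnings(stats::cor(log2(V + 1)))
    cc[upper.tri(cc, diag = TRUE)] <- 0
    pairs <- which(cc >= dup_cor, arr.ind = TRUE)
    if (nrow(pairs)) dup <- unique(colnames(V)[pairs[, "row"]])  # keep the earlier sample
  }
  keep <- setdiff(keep, dup)
  report <- data.frame(
    sample_id = c(drop_zero, dup),
    rule = c(rep("zero_fraction_gt_0.5", length(drop_zero)),
             rep(sprintf("expression_duplicate_cor_ge_%g", dup_cor), length(dup))),
    stringsAsFactors = FALSE)
  list(E = expr_matrix(E$values[, keep, drop = FALSE], E$gene_meta, "raw"),
       report = report)
}

#' Filter lowly expressed / invariant genes
#'
#' Retains genes whose across-sample standard deviation is at least `sd_min`
#' and whose zero-count fraction is at most `max_zero_frac` (genes with
#' *more than* 30 percent zeros are excluded; the boundary gene is kept).
#' The SD is evaluated on `log2(count + 1)` by default, where a threshold of
#' 0.5 is meaningful; set `sd_scale = "raw"` to evaluate it on counts.
#'
#' @param E raw-scale [expr_matrix()].
#' @param sd_min minimum across-sample SD (genes below are excluded,
#'   strictly: SD < 0.5 removed, SD = 0.5 kept).
#' @param max_zero_frac maximum tolerated zero fraction (strictly greater
#'   is removed).
#' @param sd_scale `"log2"` (default) or `"raw"`: scale on which the SD
#'   threshold is evaluated.
#' @return raw-scale [expr_matrix()] with the retained genes, order
#'   preserved; attribute `qc` lists removed genes and the triggering rule.
#' @export
filter_genes <- function(E, sd_min = 0.5, max_zero_frac = 0.30,
                         sd_scale = c("log2", "raw")) {
  require_scale(E, "raw")
  sd_scale <- match.arg(sd_scale)
  V <- E$values
  M <- if (sd_scale == "log2") log2(V + 1) else V
  sds <- apply(M, 1, stats::sd)
  zf <- rowMeans(V == 0)
  keep <- sds >= sd_min & zf <= max_zero_frac
  if (!any(keep)) stop("gene filtering removed every gene")
  removed <- data.frame(
    gene_id = rownames(V)[!keep],
    rule = ifelse(sds[!keep] < sd_min, sprintf("sd_lt_%g", sd_min),
                  sprintf("zero_fraction_gt_%g", max_zero_frac)),
    stringsAsFactors = FALSE)
  out <- expr_matrix(V[keep, , drop = FALSE],
                     E$gene_meta[keep, , drop = FALSE], "raw")
  attr(out, "qc") <- removed
  out
}

#' Upper-quartile normalization
#'
#' Divides each sample by its 75th percentile of nonzero counts (linear
#' interpolation, `stats::quantile` type 7) and rescales by the across-sample
#' mean of those percentiles, so the normalized values stay on a count-like
#' scale. After the operation every sample has the same 75th percentile of
#' nonzero values.
#'
#' @param E raw-scale [expr_matrix()]; every sample must have a nonzero count.
#' @return [expr_matrix()] with `scale_flag = "uq_normalized"`; the
#'   per-sample quartiles used are stored in attribute `uq`.
#' @export
upper_quartile_normalize <- function(E) {
  require_scale(E, "raw")
  V <- E$values
  uq <- apply(V, 2, function(x) {
    nz <- x[x > 0]
    if (!length(nz)) stop("sample with all-zero counts: cannot normalize")
    stats::quantile(nz, 0.75, names = FALSE)
  })
  W <- sweep(V, 2, uq / mean(uq), "/")
  out <- expr_matrix(W, E$gene_meta, "uq_normalized")
  attr(out, "uq") <- uq
  out
}

#' Log2 transform
#'
#' `value -> log2(value + 1)`; requires upper-quartile-normalized input.
#'
#' @param E [expr_matrix()] with `scale_flag = "uq_normalized"`.
#' @return [expr_matrix()] on the log2 scale.
#' @export
log2_transform <- function(E) {
  require_scale(E, "uq_normalized")
  if (any(E$values < 0)) stop("negative input to log2 transform")
  expr_matrix(log2(E$values + 1), E$gene_meta, "log2")
}

#' Infer genetic sex from chromosome-Y expression
#'
#' 2-means clustering of samples on the expression of chromosome-Y genes;
#' the cluster with the higher mean chrY expression is labeled male. Returns
#' inferred labels and the mismatches against the reported ones.
#'
#' @param E log2-scale [expr_matrix()].
#' @param chrY_genes character vector of chrY gene ids present in `E`.
#' @param reported 0/1 vector of reported labels (1 = male), one per sample.
#' @return list with `inferred` (0/1 per sample), `mismatches` (sample ids),
#'   and `n_mismatch`.
#' @export
infer_genetic_sex <- function(E, chrY_genes, reported) {
  require_scale(E, "log2")
  chrY_genes <- intersect(chrY_genes, rownames(E$values))
  if (length(chrY_genes) < 2) stop("need at least 2 chrY genes present")
  X <- t(E$values[chrY_genes, , drop = FALSE])
  if (nrow(X) < 2) stop("need at least 2 samples to form 2 clusters")
  if (all(apply(X, 2, stats::sd) < 1e-12))
    stop("degenerate clustering: all chrY expression constant")
  km <- stats::kmeans(X, centers = 2, nstart = 10)
  male_cluster <- which.max(tapply(rowMeans(X), km$cluster, mean))
  inferred <- as.integer(km$cluster == male_cluster)
  names(inferred) <- rownames(X)
  stopifnot(length(reported) == length(inferred))
  mism <- rownames(X)[inferred != reported]
  list(inferred = inferred, mismatches = mism, n_mismatch = length(mism))
}

#' Select enriched immune cell types
#'
#' A cell type is enriched when at most 30 percent of its abundance scores
#' are zero and its standard deviation is strictly greater than `sd_min`
#' (a type with SD exactly 0.12 is excluded).
#'
#' @param A samples x cell-types abundance matrix or data.frame (scores in
#'   \[0, 1\]).
#' @param max_zero_frac maximum zero fraction.
#' @param sd_min SD threshold (strict).
#' @return character vector of enriched cell-type names (may be empty, with
#'   a warning).
#' @export
filter_cell_abundance <- function(A, max_zero_frac = 0.30, sd_min = 0.12) {
  A <- as.matrix(A)
  if (any(A < 0 | A > 1)) stop("abundances must lie in [0, 1]")
  zf <- colMeans(A == 0)
  sds <- apply(A, 2, stats::sd)
  keep <- zf <= max_zero_frac & sds > sd_min
  if (!any(keep)) warning("no enriched cell types at the configured thresholds")
  colnames(A)[keep]
}

#' Principal components of the expression matrix
#'
#' PCA of the samples x genes matrix after per-gene centering, for batch and
#' stratification QC. The sign of each component is fixed so that its
#' largest-magnitude gene loading is positive.
#'
#' @param E log2-scale [expr_matrix()].
#' @param k number of components, `k < min(genes, samples)`.
#' @return list with `scores` (samples x k), `explained` (variance shares),
#'   `sdev`.
#' @export
pca_qc <- function(E, k = 2) {
  require_scale(E, "log2")
  X <- t(E$values)
  if (k >= min(dim(X))) stop("k must be < min(genes, samples)")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation[, seq_len(k), drop = FALSE], 2,
                function(v) sign(v[which.max(abs(v))]))
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, "*")
  list(scores = scores,
       explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
       sdev = pc$sdev[seq_len(k)])
}

#' Run the full preprocessing pipeline
#'
#' sample QC -> gene filter -> upper-quartile normalization -> log2, with a
#' QC report of every removed gene and sample and the rule that removed it.
#'
#' @param E raw-scale [expr_matrix()].
#' @param sd_min,max_zero_frac gene-filter thresholds (see [filter_genes()]).
#' @return list with `E` (log2 scale), `report` (list of data.frames), and
#'   `counts` (genes/samples before and after each step).
#' @export
preprocess_expression <- function(E, sd_min = 0.5, max_zero_frac = 0.30) {
  s <- filter_samples(E)
  g <- filter_genes(s$E, sd_min = sd_min, max_zero_frac = max_zero_frac)
  out <- log2_transform(upper_quartile_normalize(g))
  list(E = out,
       report = list(samples_removed = s$report, genes_removed = attr(g, "qc")),
       counts = data.frame(
         stage = c("input", "sample_qc", "gene_filter"),
         genes = c(nrow(E$values), nrow(s$E$values), nrow(out$values)),
         samples = c(ncol(E$values), ncol(s$E$values), ncol(out$values))))
}
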