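# Consensus-molecular-subtype enrichment of causal genes: median
# dichotomization into beneficial / non-beneficial expression and the
# strictly-greater-than-70% per-subtype enrichment rule.

#' Dichotomize a gene's expression into beneficial / non-beneficial
#'
#' Samples strictly above the all-sample median are "high"; a sample exactly
#' at the median is assigned to the "low" side (documented convention).
#' `direction` is the sign of the gene's causal effect on the hazard:
#' `-1` (higher expression lowers the hazard, i.e. protective) maps high
#' expression to "beneficial"; `+1` maps low expression to "beneficial".
#'
#' @param E log2-scale [expr_matrix()].
#' @param gene_id gene to dichotomize.
#' @param direction -1 or +1, sign of the hazard effect from the MR stage.
#' @return factor per sample with levels `beneficial`, `non_beneficial`.
#' @export
dichotomize <- function(E, gene_id, direction) {
  require_scale(E, "log2")
  if (!gene_id %in% rownames(E$values)) stop("unknown gene: ", gene_id)
  if (!direction %in% c(-1, 1)) stop("direction must be -1 or +1")
  x <- E$values[gene_id, ]
  if (stats::sd(x) < 1e-12) stop("zero expression variance for ", gene_id)
  high <- x > stats::median(x)
  beneficial <- if (direction == -1) high else !high
  factor(ifelse(beneficial, "beneficial", "non_beneficial"),
         levels = c("beneficial", "non_beneficial"))
}

#' Subtype enrichment of a dichotomized gene
#'
#' Per subtype, the rate of beneficial and non-beneficial samples; a
#' (subtype, category) pair is enriched when its rate strictly exceeds
#' `threshold` (a rate of exactly 0.70 is not enriched). Subtypes with no
#' samples are omitted with a warning.
#'
#' @param categories factor from [dichotomize()], named or aligned with
#'   `subtype_labels`.
#' @param subtype_labels character vector of CMS labels per sample.
#' @param threshold enrichment rate threshold (strict; default 0.70).
#' @return data.frame with `subtype`, `category`, `rate`, `enriched`,
#'   `n_subtype`.
#' @export
enrichment <- function(categories, subtype_labels, threshold = 0.70) {
  stopifnot(length(categories) == length(subtype_labels))
  if (anyNA(subtype_labels)) stop("every sample needs a subtype label")
  subtypes <- paste0("CMS", 1:4)
  absent <- setdiff(unique(subtype_labels), subtypes)
  if (length(absent)) stop("unknown subtype label(s): ",
                           paste(absent, collapse = ", "))
  empty <- setdiff(subtypes, unique(subtype_labels))
  if (length(empty))
    warning("omitting empty subtype(s): ", paste(empty, collapse = ", "))
  rows <- list()
  for (s in intersect(subtypes, unique(subtype_labels))) {
    cc <- categories[subtype_labels == s]
    n <- length(cc)
    for (cat in levels(categories)) {
      r <- mean(cc == cat)
      rows[[length(rows) + 1L]] <- data.frame(
        subtype = s, category = cat, rate = r,
        enriched = r > threshold, n_subtype = n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Subtype enrichment for a set of causal genes
#'
#' @param E log2-scale [expr_matrix()].
#' @param mr_results data.frame with `gene_id` and `direction` (one row per
#'   causal gene).
#' @param subtype_labels CMS label per sample of `E` (aligned to columns).
#' @param threshold enrichment threshold.
#' @return data.frame with one row per gene x subtype x category.
#' @export
enrich_causal_genes <- function(E, mr_results, subtype_labels,
                                threshold = 0.70) {
  rows <- lapply(seq_len(nrow(mr_results)), function(i) {
    g <- mr_results$gene_id[i]
    cats <- dichotomize(E, g, mr_results$direction[i])
    cbind(gene_id = g, enrichment(cats, subtype_labels, threshold))
  })
  do.call(rbind, rows)
}
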