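# End-to-end orchestration: the discovery run (preprocess -> eQTL -> screen
# -> pleiotropy -> prune -> one-sample MR -> subtype enrichment) and the
# validation run (allele harmonization -> two-sample prediction -> two-sample
# MR), each returning a manifest recording every threshold, seed and filter
# count.

#' Analysis configuration
#'
#' Every threshold of the workflow in one audited place; defaults are the
#' published ones.
#'
#' @param gene_sd_min,gene_max_zero_frac expression gene filters.
#' @param abundance_sd_min,abundance_max_zero_frac immune-abundance filters.
#' @param cis_window cis window in bp.
#' @param maf_min minimum minor allele frequency.
#' @param egene_alpha gene-level eQTL threshold.
#' @param screen_alpha gene-OS screen threshold.
#' @param pleiotropy_alpha per-variant Cox exclusion threshold.
#' @param r2_threshold LD pruning threshold.
#' @param mr_alpha causal/replication significance threshold.
#' @param enrich_threshold subtype enrichment rate threshold.
#' @param k_clusters number of gene clusters for the screen.
#' @param n_perm eQTL permutations.
#' @param seed global seed.
#' @param arms the two monotherapy arms analyzed.
#' @return list of class `run_config`.
#' @export
run_config <- function(gene_sd_min = 0.5, gene_max_zero_frac = 0.30,
                       abundance_sd_min = 0.12, abundance_max_zero_frac = 0.30,
                       cis_window = 1e6, maf_min = 0.05,
                       egene_alpha = 0.05, screen_alpha = 0.1,
                       pleiotropy_alpha = 1e-4, r2_threshold = 0.1,
                       mr_alpha = 0.05, enrich_threshold = 0.70,
                       k_clusters = 4, n_perm = 10000, seed = 1L,
                       arms = c("bevacizumab", "cetuximab")) {
  structure(as.list(environment()), class = "run_config")
}

#' Discovery-cohort run
#'
#' Executes the one-sample pipeline on in-memory inputs: preprocessing,
#' cis-eQTL mapping with permutation gene-level p-values, gene clustering,
#' the arm-specific additive-hazard screen, the Cox pleiotropy screen, LD
#' pruning, genetic prediction of expression, the one-sample MR causal test,
#' and subtype enrichment of the causal genes.
#'
#' @param E raw-scale [expr_matrix()].
#' @param G a [geno_matrix()].
#' @param clinical clinical table (validated; must carry `cms` for the
#'   enrichment stage, or enrichment is skipped).
#' @param abundances optional samples x cell-type abundance table.
#' @param cfg a [run_config()].
#' @return list with `manifest`, the per-stage outputs (`prep`, `eqtl`,
#'   `gene_level`, `egenes`, `clusters`, `screen`, `pleiotropy`, `ivsets`,
#'   `predictions`, `mr`, `causal`, `enrichment`).
#' @export
run_discovery <- function(E, G, clinical, abundances = NULL,
                          cfg = run_config()) {
  clinical <- validate_clinical(
    clinical, required = c("sample_id", "os_time", "os_event", "arm",
                           "age", "gender", "braf_v600e", "all_ras"))
  manifest <- list(config = unclass(cfg),
                   counts = list(genes_in = nrow(E$values),
                                 samples_in = ncol(E$values),
                                 variants_in = ncol(G$dosages)))

  prep <- preprocess_expression(E, sd_min = cfg$gene_sd_min,
                                max_zero_frac = cfg$gene_max_zero_frac)
  El <- prep$E
  manifest$counts$genes_after_filter <- nrow(El$values)
  manifest$counts$samples_after_qc <- ncol(El$values)

  enriched_cells <- NULL
  Cextra <- NULL
  if (!is.null(abundances)) {
    enriched_cells <- filter_cell_abundance(
      abundances, max_zero_frac = cfg$abundance_max_zero_frac,
      sd_min = cfg$abundance_sd_min)
    if (length(enriched_cells))
      Cextra <- as.matrix(abundances)[, enriched_cells, drop = FALSE]
    manifest$counts$enriched_cell_types <- length(enriched_cells)
  }

  # eQTL covariates: clinical + enriched abundances
  samples <- intersect(colnames(El$values), clinical$sample_id)
  cl_o <- clinical[match(samples, clinical$sample_id), , drop = FALSE]
  Ceqtl <- screen_covariates(cl_o, if (is.null(Cextra)) NULL else
    Cextra[match(samples, rownames(Cextra)), , drop = FALSE])
  rownames(Ceqtl) <- samples

  eqtls <- map_cis_eqtl(El, G, Ceqtl, window = cfg$cis_window)
  gene_level <- permute_all_genes(El, G, Ceqtl, window = cfg$cis_window,
                                  n_perm = cfg$n_perm, seed = cfg$seed,
                                  genes = unique(eqtls$gene_id))
  egenes <- select_egenes(gene_level, alpha = cfg$egene_alpha)
  manifest$counts$genes_with_cis_variants <- length(unique(eqtls$gene_id))
  manifest$counts$egenes <- length(egenes)
  if (!length(egenes)) stop("stage eqtl: no eGenes at alpha = ", cfg$egene_alpha)

  Eg <- expr_matrix(El$values[egenes, , drop = FALSE],
                    El$gene_meta[match(egenes, El$gene_meta$gene_id), ,
                                 drop = FALSE], "log2")
  clusters <- cluster_genes(Eg, k = min(cfg$k_clusters, length(egenes)),
                            seed = cfg$seed)

  screen <- do.call(rbind, lapply(cfg$arms, function(a)
    screen_gene_os(Eg, clinical, Cextra, clusters, arm = a,
                   alpha = cfg$screen_alpha)))
  screened <- unique(screen$gene_id[screen$selected])
  manifest$counts$screen_selected <-
    stats::setNames(lapply(cfg$arms, function(a)
      sum(screen$selected[screen$arm == a])), cfg$arms)
  if (!length(screened)) {
    manifest$counts$causal <- 0L
    return(list(manifest = manifest, prep = prep, eqtl = eqtls,
                gene_level = gene_level, egenes = egenes,
                clusters = clusters, screen = screen, pleiotropy = NULL,
                ivsets = NULL, predictions = NULL, mr = NULL,
                causal = NULL, enrichment = NULL))
  }

  candidate_ivs <- unique(eqtls$variant_id[eqtls$gene_id %in% screened])
  pc1 <- pca_qc(El, k = 1)$scores
  ps <- pleiotropy_screen(G, clinical, C = pc1, candidate_ivs,
                          alpha = cfg$pleiotropy_alpha)
  manifest$counts$ivs_candidate <- length(candidate_ivs)
  manifest$counts$ivs_excluded_pleiotropy <- length(ps$excluded)

  ivsets <- list()
  for (g in screened) {
    eg <- eqtls[eqtls$gene_id == g &
                  !(eqtls$variant_id %in% ps$excluded), , drop = FALSE]
    if (!nrow(eg)) next
    ivsets[[g]] <- prune_ivs(eg, G, r2_threshold = cfg$r2_threshold)
  }
  manifest$counts$genes_with_ivs <- length(ivsets)
  if (!length(ivsets)) stop("stage prune: every screened gene lost all IVs")

  predictions <- do.call(cbind, lapply(ivsets, predict_expression_one_sample,
                                       G = G))
  colnames(predictions) <- names(ivsets)

  mr <- do.call(rbind, lapply(cfg$arms, function(a) {
    genes_a <- intersect(colnames(predictions),
                         screen$gene_id[screen$arm == a & screen$selected])
    if (!length(genes_a)) return(NULL)
    r <- one_sample_mr(predictions[, genes_a, drop = FALSE], clinical,
                       Cextra, arm = a, alpha_mr = cfg$mr_alpha)
    r$n_ivs <- vapply(r$gene_id, function(g) nrow(ivsets[[g]]$ivs), integer(1))
    r
  }))
  causal <- if (is.null(mr)) NULL else mr[mr$significant, , drop = FALSE]
  manifest$counts$causal <- if (is.null(causal)) 0L else nrow(causal)

  enr <- NULL
  if (!is.null(causal) && nrow(causal) && "cms" %in% names(clinical)) {
    cms <- clinical$cms[match(colnames(El$values), clinical$sample_id)]
    enr <- enrich_causal_genes(El, causal, cms,
                               threshold = cfg$enrich_threshold)
  }

  list(manifest = manifest, prep = prep, eqtl = eqtls,
       gene_level = gene_level, egenes = egenes, clusters = clusters,
       screen = screen, pleiotropy = ps, ivsets = ivsets,
       predictions = predictions, mr = mr, causal = causal,
       enrichment = enr)
}

#' Harmonize validation dosages to the discovery effect alleles
#'
#' Variants whose effect/other alleles are swapped relative to the discovery
#' metadata are recoded as `2 - dosage`; an allele pair matching neither
#' orientation aborts, listing the variants.
#'
#' @param G_validation validation [geno_matrix()].
#' @param discovery_meta discovery `variant_meta` data.frame.
#' @return harmonized [geno_matrix()].
#' @export
harmonize_alleles <- function(G_validation, discovery_meta) {
  vm <- G_validation$variant_meta
  dm <- discovery_meta[match(vm$variant_id, discovery_meta$variant_id), ,
                       drop = FALSE]
  same <- vm$effect_allele == dm$effect_allele & vm$other_allele == dm$other_allele
  flip <- vm$effect_allele == dm$other_allele & vm$other_allele == dm$effect_allele
  bad <- vm$variant_id[!(same | flip) & !is.na(dm$variant_id)]
  if (length(bad)) stop("allele mismatch between cohorts for: ",
                        paste(bad, collapse = ", "))
  D <- G_validation$dosages
  if (any(flip)) {
    D[, flip] <- 2 - D[, flip]
    vm$effect_allele[flip] <- dm$effect_allele[flip]
    vm$other_allele[flip] <- dm$other_allele[flip]
    vm$maf[flip] <- pmin(colMeans(D[, flip, drop = FALSE]) / 2,
                         1 - colMeans(D[, flip, drop = FALSE]) / 2)
  }
  geno_matrix(D, vm)
}

#' Validation-cohort run (two-sample MR)
#'
#' Harmonizes alleles, predicts expression of the discovery causal genes in
#' the genotype-only cohort via the discovery joint least-squares fit, and
#' runs the arm-specific replication test. The validation cohort has no
#' RNA-seq, so only the clinical covariates enter the model.
#'
#' @param discovery output of [run_discovery()].
#' @param E_discovery the discovery log2 [expr_matrix()]
#'   (`discovery$prep$E`), source of the measured expression `g`.
#' @param G_discovery,G_validation the two cohorts' genotypes.
#' @param clinical_validation validation clinical table.
#' @param cfg a [run_config()].
#' @return list with `manifest`, `predictions`, `replication`.
#' @export
run_validation <- function(discovery, E_discovery, G_discovery, G_validation,
                           clinical_validation, cfg = run_config()) {
  clinical_validation <- validate_clinical(
    clinical_validation, required = c("sample_id", "os_time", "os_event",
                                      "arm", "age", "gender"))
  causal <- discovery$causal
  manifest <- list(config = unclass(cfg),
                   counts = list(n_validation = nrow(clinical_validation),
                                 causal_genes_in = if (is.null(causal)) 0L
                                 else length(unique(causal$gene_id))))
  if (is.null(causal) || !nrow(causal))
    return(list(manifest = manifest, predictions = NULL,
                replication = data.frame()))

  Gv <- harmonize_alleles(G_validation, G_discovery$variant_meta)
  genes <- unique(causal$gene_id)
  preds <- do.call(cbind, lapply(genes, function(g) {
    gexp <- stats::setNames(E_discovery$values[g, ],
                            colnames(E_discovery$values))
    predict_expression_two_sample(discovery$ivsets[[g]], G_discovery, gexp, Gv)
  }))
  colnames(preds) <- genes

  repl <- do.call(rbind, lapply(cfg$arms, function(a) {
    genes_a <- unique(causal$gene_id[causal$arm == a])
    if (!length(genes_a)) return(NULL)
    dirs <- stats::setNames(causal$direction[match(genes_a, causal$gene_id)],
                            genes_a)
    two_sample_mr(preds[, genes_a, drop = FALSE], clinical_validation,
                  C = NULL, arm = a, alpha = cfg$mr_alpha,
                  one_sample_directions = dirs)
  }))
  manifest$counts$replicated <- sum(repl$replicated)
  list(manifest = manifest, predictions = preds, replication = repl)
}
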