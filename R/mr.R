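# The causal pipeline: gene clustering, additive-hazard screening per arm,
# per-variant Cox pleiotropy screen, LD pruning of instruments, genetic
# prediction of expression, and the one- and two-sample MR causal tests.

#' Cluster genes by expression profile
#'
#' k-means on per-gene standardized expression profiles (genes as points,
#' samples as dimensions), used to keep the multivariable survival screens
#' small enough to avoid overfitting.
#'
#' @param E log2-scale [expr_matrix()].
#' @param k number of clusters (default 4).
#' @param seed RNG seed (k-means is deterministic given it).
#' @param nstart random restarts.
#' @return named integer vector, gene -> cluster id in 1..k.
#' @export
cluster_genes <- function(E, k = 4, seed = 1L, nstart = 10) {
  require_scale(E, "log2")
  X <- E$values
  if (k > nrow(X)) stop("k cannot exceed the number of genes")
  if (k == nrow(X))
    return(stats::setNames(seq_len(nrow(X)), rownames(X)))  # singletons
  sds <- apply(X, 1, stats::sd)
  Xs <- (X - rowMeans(X)) / ifelse(sds < 1e-12, 1, sds)
  cl <- with_seed(derive_seed(seed, "kmeans"),
                  stats::kmeans(Xs, centers = k, nstart = nstart, iter.max = 50))
  stats::setNames(cl$cluster, rownames(X))
}

# Build the numeric covariate design used by the survival screens: clinical
# covariates plus optional immune abundances / principal components.
# Zero-variance columns are dropped (they are collinear with the intercept).
screen_covariates <- function(clinical, extra = NULL,
                              cols = c("age", "gender", "braf_v600e", "all_ras")) {
  have <- intersect(cols, names(clinical))
  M <- as.matrix(clinical[, have, drop = FALSE])
  storage.mode(M) <- "double"
  if (!is.null(extra)) M <- cbind(M, as.matrix(extra))
  keep <- apply(M, 2, function(x) stats::sd(x) > 1e-12)
  M[, keep, drop = FALSE]
}

#' Screen genes for association with overall survival
#'
#' Per cluster and per treatment arm, one multivariable Aalen additive-hazard
#' fit including all of the cluster's genes plus the clinical covariates;
#' genes with a per-gene p-value strictly below `alpha` pass the screen.
#' A cluster larger than `events / 5` triggers an overfitting warning and is
#' automatically sub-split.
#'
#' @param E log2-scale [expr_matrix()].
#' @param clinical validated clinical table with `arm`.
#' @param C optional extra covariate matrix (e.g. enriched immune
#'   abundances), rows aligned to `clinical$sample_id`.
#' @param clusters gene -> cluster map from [cluster_genes()].
#' @param arm treatment arm to subset to.
#' @param alpha screening threshold (strict; default 0.1).
#' @param min_events floor on the arm's event count.
#' @return data.frame (stage = "screen") with `gene_id`, `arm`, `p_value`,
#'   `direction`, `selected`.
#' @export
screen_gene_os <- function(E, clinical, C = NULL, clusters, arm,
                           alpha = 0.1, min_events = 20) {
  require_scale(E, "log2")
  clinical <- validate_clinical(clinical)
  idx <- clinical$arm == arm
  sub <- clinical[idx, , drop = FALSE]
  n_events <- sum(sub$os_event)
  if (n_events < min_events)
    stop(sprintf("arm '%s' has %d events, below the floor of %d", arm,
                 n_events, min_events))
  samples <- intersect(sub$sample_id, colnames(E$values))
  sub <- sub[match(samples, sub$sample_id), , drop = FALSE]
  Cc <- screen_covariates(sub, if (is.null(C)) NULL else
    as.matrix(C)[match(samples, rownames(as.matrix(C))), , drop = FALSE])
  out <- list()
  for (cl in sort(unique(clusters))) {
    genes <- names(clusters)[clusters == cl]
    genes <- intersect(genes, rownames(E$values))
    if (!length(genes)) next
    cap <- max(1L, floor(n_events / 5))
    chunks <- if (length(genes) > cap) {
      warning(sprintf("cluster %s has %d genes > events/5 = %d: sub-splitting",
                      cl, length(genes), cap))
      split(genes, ceiling(seq_along(genes) / cap))
    } else list(genes)
    for (ch in chunks) {
      Xg <- t(E$values[ch, samples, drop = FALSE])
      design <- cbind(`(Intercept)` = 1, Xg, Cc)
      fit <- fit_aalen(design, sub$os_time, sub$os_event)
      for (g in ch) {
        tt <- aalen_test(fit, g)
        out[[length(out) + 1L]] <- data.frame(
          gene_id = g, arm = arm, stage = "screen",
          p_value = tt$p, direction = tt$direction,
          selected = tt$p < alpha, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-variant Cox pleiotropy screen
#'
#' A survival GWAS on the candidate instruments, both arms pooled: each
#' variant's dosage is fit in a Cox proportional-hazards model with the
#' screen covariates (gender, age, tumor location, all-RAS and KRAS status,
#' first expression PC where available). Variants with Wald p strictly below
#' `alpha` are excluded as pleiotropic; non-converging fits are excluded
#' conservatively and logged.
#'
#' @param G a [geno_matrix()].
#' @param clinical validated clinical table (both arms).
#' @param C optional extra covariate matrix (e.g. first principal component),
#'   rows aligned to sample ids.
#' @param candidate_ivs character vector of variant ids to screen.
#' @param alpha exclusion threshold (strict; default 1e-4: a variant at
#'   exactly 1e-4 is retained).
#' @return list with `excluded` (variant ids), `p` (named per-variant Wald
#'   p), `n_nonconverged`.
#' @export
pleiotropy_screen <- function(G, clinical, C = NULL, candidate_ivs,
                              alpha = 1e-4) {
  clinical <- validate_clinical(clinical)
  miss <- setdiff(candidate_ivs, colnames(G$dosages))
  if (length(miss)) stop("candidate variants absent from G: ",
                         paste(miss, collapse = ", "))
  samples <- intersect(clinical$sample_id, rownames(G$dosages))
  if (!is.null(C)) samples <- intersect(samples, rownames(as.matrix(C)))
  cl <- clinical[match(samples, clinical$sample_id), , drop = FALSE]
  base <- screen_covariates(cl, extra = NULL,
                            cols = c("gender", "age", "all_ras", "kras"))
  if ("tumor_location" %in% names(cl))
    base <- cbind(base, tumor_location = as.integer(factor(cl$tumor_location)) - 1)
  if (!is.null(C))
    base <- cbind(base, as.matrix(C)[match(samples, rownames(as.matrix(C))), ,
                                     drop = FALSE])
  keep_cols <- apply(base, 2, function(x) stats::sd(x) > 1e-12)
  base <- base[, keep_cols, drop = FALSE]
  pvals <- rep(NA_real_, length(candidate_ivs))
  names(pvals) <- candidate_ivs
  nonconv <- 0L
  for (v in candidate_ivs) {
    d <- G$dosages[samples, v]
    if (stats::sd(d) < 1e-12) { nonconv <- nonconv + 1L; next }
    fit <- fit_coxph(cbind(dosage = d, base), cl$os_time, cl$os_event)
    if (!fit$converged) { nonconv <- nonconv + 1L; next }
    pvals[v] <- fit$wald_p["dosage"]
  }
  excluded <- names(pvals)[is.na(pvals) | pvals < alpha]
  list(excluded = excluded, p = pvals, n_nonconverged = nonconv)
}

#' Prune a gene's instruments by LD clustering
#'
#' Complete-linkage hierarchical clustering of the gene's surviving
#' instruments on distance `1 - r^2`, cut so that every within-cluster pair
#' has `r^2 > 0.1`; one proxy per cluster, the variant with the smallest
#' eQTL nominal p-value. The proxies' marginal eQTL slopes form the weight
#' vector W.
#'
#' @param eqtls data.frame of [map_cis_eqtl()] rows for one gene.
#' @param G a [geno_matrix()] carrying the variants.
#' @param r2_threshold within-cluster LD threshold (default 0.1).
#' @return list of class `iv_set`: `gene_id`, `ivs` (data.frame variant_id,
#'   weight, p_nominal), `clusters` (variant -> cluster id).
#' @export
prune_ivs <- function(eqtls, G, r2_threshold = 0.1) {
  if (is.null(eqtls) || !nrow(eqtls)) stop("empty IV list")
  stopifnot(length(unique(eqtls$gene_id)) == 1)
  vars <- eqtls$variant_id
  miss <- setdiff(vars, colnames(G$dosages))
  if (length(miss)) stop("variants absent from G: ", paste(miss, collapse = ", "))
  if (length(vars) == 1) {
    cl <- stats::setNames(1L, vars)
  } else {
    r2 <- stats::cor(G$dosages[, vars, drop = FALSE])^2
    d <- stats::as.dist(1 - r2)
    hc <- stats::hclust(d, method = "complete")
    # merge only when every pairwise r^2 strictly exceeds the threshold,
    # i.e. complete-linkage height strictly below 1 - r2_threshold
    cl <- stats::cutree(hc, h = (1 - r2_threshold) * (1 - 1e-9))
  }
  proxies <- vapply(split(vars, cl[vars]), function(vs) {
    ps <- eqtls$p_nominal[match(vs, eqtls$variant_id)]
    vs[which.min(ps)]
  }, character(1))
  sel <- eqtls[match(proxies, eqtls$variant_id), , drop = FALSE]
  structure(list(gene_id = eqtls$gene_id[1],
                 ivs = data.frame(variant_id = sel$variant_id,
                                  weight = sel$beta,
                                  p_nominal = sel$p_nominal,
                                  stringsAsFactors = FALSE),
                 clusters = cl),
            class = "iv_set")
}

#' Predict expression from genotypes (one-sample MR)
#'
#' `g_hat = Q W`: the cohort's dosage matrix over the gene's proxies times
#' the marginal eQTL weights.
#'
#' @param ivset an `iv_set` from [prune_ivs()].
#' @param G a [geno_matrix()] containing all proxies.
#' @return named numeric vector, one predicted value per sample.
#' @export
predict_expression_one_sample <- function(ivset, G) {
  vars <- ivset$ivs$variant_id
  miss <- setdiff(vars, colnames(G$dosages))
  if (length(miss)) stop("missing variant(s) in cohort: ",
                         paste(miss, collapse = ", "))
  Q <- G$dosages[, vars, drop = FALSE]
  stats::setNames(as.vector(Q %*% ivset$ivs$weight), rownames(Q))
}

#' One-sample MR causal test
#'
#' Per treatment arm, a multivariable Aalen additive-hazard fit including
#' all genetically predicted expressions plus the clinical covariates; each
#' gene's causal p-value and effect direction come from the aggregated
#' increment test. Collinear predictions are dropped (later gene dropped,
#' logged in the result's `dropped` attribute).
#'
#' @param predictions samples x genes matrix of predicted expression (rows
#'   named by sample id).
#' @param clinical validated clinical table.
#' @param C optional extra covariate matrix.
#' @param arm treatment arm.
#' @param alpha_mr significance threshold (default 0.05).
#' @return data.frame (stage = "one_sample") with `gene_id`, `arm`,
#'   `p_value`, `direction`, `significant`, `n_ivs` left NA for the caller.
#' @export
one_sample_mr <- function(predictions, clinical, C = NULL, arm,
                          alpha_mr = 0.05) {
  clinical <- validate_clinical(clinical)
  P <- as.matrix(predictions)
  sub <- clinical[clinical$arm == arm, , drop = FALSE]
  samples <- intersect(sub$sample_id, rownames(P))
  sub <- sub[match(samples, sub$sample_id), , drop = FALSE]
  P <- P[samples, , drop = FALSE]
  # collinearity guard: scan genes in order, dropping any gene whose
  # prediction is linearly dependent on the earlier ones (later gene loses)
  keep <- character(0)
  dropped <- character(0)
  base <- matrix(1, nrow(P), 1)
  for (g in colnames(P)) {
    cand <- cbind(base, P[, g])
    if (qr(cand)$rank == ncol(cand)) {
      keep <- c(keep, g); base <- cand
    } else dropped <- c(dropped, g)
  }
  P <- P[, keep, drop = FALSE]
  if (!ncol(P) || any(apply(P, 2, stats::sd) < 1e-12))
    stop("constant predicted expression: no variance to test")
  Cc <- screen_covariates(sub, if (is.null(C)) NULL else
    as.matrix(C)[match(samples, rownames(as.matrix(C))), , drop = FALSE])
  design <- cbind(`(Intercept)` = 1, P, Cc)
  fit <- fit_aalen(design, sub$os_time, sub$os_event)
  res <- do.call(rbind, lapply(keep, function(g) {
    tt <- aalen_test(fit, g)
    data.frame(gene_id = g, arm = arm, stage = "one_sample",
               p_value = tt$p, direction = tt$direction,
               significant = tt$p < alpha_mr, stringsAsFactors = FALSE)
  }))
  attr(res, "dropped") <- dropped
  rownames(res) <- NULL
  res
}

#' Predict expression in a genotype-only cohort (two-sample MR)
#'
#' `g_hat* = Q* (Q'Q)^{-1} Q' g`: a joint least-squares fit of the measured
#' expression on the proxy dosages in the discovery cohort, applied to the
#' validation cohort's dosages. A singular Gram matrix falls back to a ridge
#' solve with penalty `1e-8 * trace(Q'Q) / p`, logged via attribute.
#'
#' @param ivset an `iv_set` (defines the proxies).
#' @param G_discovery discovery [geno_matrix()].
#' @param g_discovery measured (log2) expression of the gene in the
#'   discovery cohort, named by sample id.
#' @param G_validation validation [geno_matrix()] (alleles harmonized).
#' @param center when `TRUE` (the default, used by the pipeline) the
#'   projection is computed on mean-centered variables: dosages are centered
#'   at their discovery means (the same means applied to the validation
#'   cohort) and expression at its discovery mean, which is added back to
#'   the predictions. The projection formula presumes centered variables;
#'   on raw dosages the mean expression level dominates the weights.
#'   `center = FALSE` applies the formula literally.
#' @return named numeric vector of predicted expression per validation
#'   sample; attribute `joint_weights` carries the fitted coefficients and
#'   `ridge` flags the fallback.
#' @export
predict_expression_two_sample <- function(ivset, G_discovery, g_discovery,
                                          G_validation, center = TRUE) {
  vars <- ivset$ivs$variant_id
  for (G in list(G_discovery, G_validation)) {
    miss <- setdiff(vars, colnames(G$dosages))
    if (length(miss)) stop("missing variant(s): ", paste(miss, collapse = ", "))
  }
  samples <- intersect(names(g_discovery), rownames(G_discovery$dosages))
  Q <- G_discovery$dosages[samples, vars, drop = FALSE]
  g <- g_discovery[samples]
  Qv <- G_validation$dosages[, vars, drop = FALSE]
  gbar <- 0
  if (center) {
    mu <- colMeans(Q)
    Q <- sweep(Q, 2, mu)
    Qv <- sweep(Qv, 2, mu)
    gbar <- mean(g)
    g <- g - gbar
  }
  M <- crossprod(Q)
  ridge <- FALSE
  if (rcond(M) < 1e-12) {
    ridge <- TRUE
    M <- M + diag(1e-8 * sum(diag(M)) / ncol(M), ncol(M))
  }
  w <- solve(M, crossprod(Q, g))
  out <- stats::setNames(as.vector(Qv %*% w) + gbar, rownames(Qv))
  attr(out, "joint_weights") <- stats::setNames(as.vector(w), vars)
  attr(out, "ridge") <- ridge
  out
}

#' Two-sample MR replication test
#'
#' Arm-specific multivariable Aalen fit of overall survival on the predicted
#' expressions in the validation cohort plus clinical covariates. A gene
#' replicates when its p-value is below `alpha` and its direction is
#' concordant with the one-sample result.
#'
#' @param predictions samples x genes matrix of `g_hat*` values.
#' @param clinical validated validation clinical table.
#' @param C optional extra covariates.
#' @param arm treatment arm.
#' @param alpha replication threshold (default 0.05).
#' @param one_sample_directions named vector gene -> direction from the
#'   one-sample stage (optional; concordance is NA without it).
#' @return data.frame (stage = "two_sample") with `gene_id`, `arm`,
#'   `p_value`, `direction`, `replicated`.
#' @export
two_sample_mr <- function(predictions, clinical, C = NULL, arm,
                          alpha = 0.05, one_sample_directions = NULL) {
  res <- one_sample_mr(predictions, clinical, C, arm, alpha_mr = alpha)
  res$stage <- "two_sample"
  conc <- if (is.null(one_sample_directions)) NA else
    res$direction == one_sample_directions[res$gene_id]
  res$replicated <- res$significant & (is.na(conc) | conc)
  if (!is.null(one_sample_directions)) res$concordant <- conc
  res
}
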