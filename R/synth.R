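# Synthetic-data generator: LD-blocked genotypes, negative-binomial
# expression with planted cis-eQTLs, arm-specific additive-hazard survival,
# and consensus-molecular-subtype labels, all with queryable ground truth.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic cohort generator. Defaults emulate a
#' randomized two-arm oncology trial with mature follow-up: a baseline hazard
#' of 0.1 events per month (median OS about 7 months times the covariate
#' load), light independent censoring giving roughly 80 percent observed
#' deaths, common variants (MAF 0.1-0.5), and cis-eQTL effects sized so that
#' two causal instruments per gene predict expression with R-squared near
#' 0.2.
#'
#' @param n_discovery,n_validation samples in the discovery (genotype +
#'   RNA-seq + survival) and validation (genotype + survival only) cohorts.
#' @param n_genes number of genes.
#' @param snps_per_gene cis variants simulated per gene (one LD block each).
#' @param ld_block_rho latent Gaussian correlation within an LD block,
#'   in \[0, 1).
#' @param maf_range allele-frequency range; the lower bound must exceed 0.05
#'   (common-variant filter).
#' @param eqtl_effect_sd SD of planted eQTL effects on the log mean.
#' @param n_causal_ivs_per_gene number of variants per gene with nonzero
#'   eQTL effect.
#' @param baseline_hazard baseline hazard rate per month (lambda0 > 0).
#' @param causal_effects data.frame with columns `gene`, `arm`, `alpha`:
#'   additive hazard slope per clipped SD of expression, in the given arm.
#' @param censoring_rate rate of the independent exponential censoring.
#' @param nb_dispersion negative-binomial size (shape) parameter; counts
#'   approach Poisson as it grows.
#' @param hazard_x_clip expression (and age) z-scores entering the hazard are
#'   clipped at +/- this many SDs so additivity cannot drive the hazard
#'   negative; the generator still verifies positivity row by row.
#' @param cms_proportions length-4 vector of subtype proportions (CMS1-4).
#' @param cms_shift named list: gene id -> length-4 numeric vector of
#'   log2-mean shifts per subtype, applied before count generation.
#' @param pleiotropic_variants data.frame with columns `variant`, `beta`:
#'   direct log-hazard effects used by the Cox pleiotropy screen fixture
#'   (these act through a proportional-hazards term on top of the additive
#'   model).
#' @param seed integer seed; identical configs give bit-identical cohorts.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_discovery = 300,
                       n_validation = 600,
                       n_genes = 6,
                       snps_per_gene = 4,
                       ld_block_rho = 0.6,
                       maf_range = c(0.1, 0.5),
                       eqtl_effect_sd = 0.18,
                       n_causal_ivs_per_gene = 2,
                       baseline_hazard = 0.1,
                       causal_effects = NULL,
                       censoring_rate = 0.025,
                       nb_dispersion = 4,
                       hazard_x_clip = 1.5,
                       cms_proportions = c(0.25, 0.25, 0.25, 0.25),
                       cms_shift = NULL,
                       pleiotropic_variants = NULL,
                       seed = 1L) {
  cfg <- list(n_discovery = n_discovery, n_validation = n_validation,
              n_genes = n_genes, snps_per_gene = snps_per_gene,
              ld_block_rho = ld_block_rho, maf_range = maf_range,
              eqtl_effect_sd = eqtl_effect_sd,
              n_causal_ivs_per_gene = n_causal_ivs_per_gene,
              baseline_hazard = baseline_hazard,
              causal_effects = causal_effects,
              censoring_rate = censoring_rate,
              nb_dispersion = nb_dispersion,
              hazard_x_clip = hazard_x_clip,
              cms_proportions = cms_proportions,
              cms_shift = cms_shift,
              pleiotropic_variants = pleiotropic_variants,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_discovery, cfg$n_validation, cfg$n_genes,
              cfg$snps_per_gene, cfg$n_causal_ivs_per_gene)
  if (any(counts <= 0)) stop("all counts must be > 0")
  if (cfg$ld_block_rho < 0 || cfg$ld_block_rho >= 1)
    stop("ld_block_rho must lie in [0, 1)")
  if (cfg$maf_range[1] <= 0.05)
    stop("maf_range lower bound must exceed 0.05 (common-variant filter)")
  if (cfg$maf_range[2] > 0.5) stop("maf_range upper bound must be <= 0.5")
  if (cfg$baseline_hazard <= 0) stop("baseline_hazard must be > 0")
  if (cfg$censoring_rate < 0) stop("censoring_rate must be >= 0")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (cfg$n_causal_ivs_per_gene > cfg$snps_per_gene)
    stop("n_causal_ivs_per_gene cannot exceed snps_per_gene")
  if (!is.null(cfg$causal_effects)) {
    ce <- cfg$causal_effects
    stopifnot(all(c("gene", "arm", "alpha") %in% names(ce)))
    # worst case: every hazard covariate at its clip simultaneously
    worst <- cfg$baseline_hazard -
      sum(abs(ce$alpha)) * cfg$hazard_x_clip - 0.05 * cfg$baseline_hazard * cfg$hazard_x_clip
    if (worst <= 0)
      stop("config rejected: lambda0 + x'alpha can go non-positive at the ",
           "clip boundary; reduce |alpha| or raise baseline_hazard")
  }
  invisible(cfg)
}

#' Simulate LD-blocked genotype dosages
#'
#' Variants come in per-gene LD blocks generated from a Gaussian copula with
#' exchangeable latent correlation `ld_block_rho`; each of the two allele
#' copies is thresholded at the allele frequency, so dosages are in
#' \{0, 1, 2\} and in Hardy-Weinberg proportions marginally. Variants whose
#' empirical MAF falls below 0.05 are resampled.
#'
#' @param cfg a [sim_config()].
#' @param n number of samples (defaults to `cfg$n_discovery`).
#' @param sample_prefix prefix for generated sample ids.
#' @param seed RNG seed (defaults to `cfg$seed`).
#' @return A [geno_matrix()]; gene `i`'s block sits on chromosome 1 at
#'   positions near `i * 2e6`, so cis windows of adjacent genes are disjoint.
#' @export
simulate_genotypes <- function(cfg, n = cfg$n_discovery,
                               sample_prefix = "S", seed = cfg$seed) {
  m_block <- cfg$snps_per_gene
  n_blocks <- cfg$n_genes
  # population allele frequencies depend on the config seed only, so that
  # discovery and validation cohorts are samples from one population
  mafs <- with_seed(derive_seed(cfg$seed, "pop_mafs"),
                    stats::runif(n_blocks * m_block,
                                 cfg$maf_range[1], cfg$maf_range[2]))
  with_seed(seed, {
    doses <- matrix(0, n, n_blocks * m_block)
    for (b in seq_len(n_blocks)) {
      idx <- (b - 1L) * m_block + seq_len(m_block)
      doses[, idx] <- sample_ld_block(n, mafs[idx], cfg$ld_block_rho)
      # MAF floor: resample columns that drifted under 0.05 empirically
      for (tries in 1:50) {
        emp <- colMeans(doses[, idx, drop = FALSE]) / 2
        emp_maf <- pmin(emp, 1 - emp)
        low <- which(emp_maf < 0.05)
        if (!length(low)) break
        redraw <- sample_ld_block(n, mafs[idx], cfg$ld_block_rho)
        doses[, idx[low]] <- redraw[, low, drop = FALSE]
      }
    }
    ids <- sprintf("rs%d_%d", rep(seq_len(n_blocks), each = m_block),
                   rep(seq_len(m_block), n_blocks))
    rownames(doses) <- sprintf("%s%04d", sample_prefix, seq_len(n))
    colnames(doses) <- ids
    emp <- colMeans(doses) / 2
    meta <- data.frame(
      variant_id = ids,
      chrom = "chr1",
      pos = rep(seq_len(n_blocks), each = m_block) * 2000000L +
        rep(seq_len(m_block), n_blocks) * 1000L,
      effect_allele = "A", other_allele = "G",
      maf = pmin(emp, 1 - emp))
    geno_matrix(doses, meta)
  })
}

# One LD block: two independent haploid copies from a latent exchangeable
# Gaussian; allele present where the latent variable is below qnorm(maf).
sample_ld_block <- function(n, mafs, rho) {
  m <- length(mafs)
  thr <- stats::qnorm(mafs)
  hap <- function() {
    shared <- stats::rnorm(n)
    z <- sqrt(rho) * shared + sqrt(1 - rho) * matrix(stats::rnorm(n * m), n, m)
    sweep(z, 2, thr, "<") + 0
  }
  hap() + hap()
}

#' Ground truth for a simulated cohort
#'
#' Draws the eQTL architecture implied by a config: which variants of each
#' gene's cis block carry effects and their signed sizes, plus the causal
#' gene-arm pairs and any pleiotropic variants.
#'
#' @param cfg a [sim_config()].
#' @param G the discovery [geno_matrix()] (defines variant ids and TSS grid).
#' @return A list of class `ground_truth` with `eqtl_map` (gene ->
#'   data.frame(variant, beta)), `causal_gene_arm_pairs`,
#'   `pleiotropic_variants`, and `gene_meta` (gene TSS annotation).
#' @export
make_ground_truth <- function(cfg, G) {
  genes <- sprintf("gene%02d", seq_len(cfg$n_genes))
  with_seed(derive_seed(cfg$seed, "truth"), {
    eqtl_map <- list()
    for (i in seq_len(cfg$n_genes)) {
      block <- G$variant_meta$variant_id[(i - 1L) * cfg$snps_per_gene +
                                           seq_len(cfg$snps_per_gene)]
      hit <- sample(block, cfg$n_causal_ivs_per_gene)
      eqtl_map[[genes[i]]] <- data.frame(
        variant = hit,
        beta = stats::rnorm(length(hit), 0, cfg$eqtl_effect_sd) +
          2.5 * cfg$eqtl_effect_sd * sign(stats::rnorm(length(hit))),  # keep effects off zero
        stringsAsFactors = FALSE)
    }
    gene_meta <- data.frame(
      gene_id = genes, chrom = "chr1",
      tss = seq_len(cfg$n_genes) * 2000000L)
    pv <- cfg$pleiotropic_variants
    if (!is.null(pv)) {
      all_eqtl <- unlist(lapply(eqtl_map, `[[`, "variant"))
      bad <- setdiff(pv$variant, all_eqtl)
      if (length(bad))
        stop("pleiotropic variants must be eQTL variants: ",
             paste(bad, collapse = ", "))
    }
    ce <- cfg$causal_effects
    if (!is.null(ce) && !all(ce$gene %in% genes))
      stop("causal_effects names unknown genes")
    structure(list(eqtl_map = eqtl_map,
                   causal_gene_arm_pairs = ce,
                   pleiotropic_variants = pv,
                   gene_meta = gene_meta),
              class = "ground_truth")
  })
}

#' Simulate covariates and subtype labels
#'
#' Age, gender, BRAF-V600E and all-RAS mutation statuses, tumor location,
#' and a CMS label drawn from the configured proportions.
#'
#' @param cfg a [sim_config()].
#' @param n number of samples.
#' @param sample_ids sample identifiers.
#' @param seed RNG seed.
#' @return data.frame of per-sample covariates (gender coded 0/1).
#' @export
simulate_covariates <- function(cfg, n, sample_ids, seed = cfg$seed) {
  with_seed(derive_seed(seed, "covars"), {
    cms <- assign_subtypes(n, cfg$cms_proportions)
    data.frame(
      sample_id = sample_ids,
      age = round(stats::rnorm(n, 60, 10)),
      gender = stats::rbinom(n, 1, 0.5),
      braf_v600e = stats::rbinom(n, 1, 0.08),
      all_ras = stats::rbinom(n, 1, 0.45),
      kras = stats::rbinom(n, 1, 0.4),
      tumor_location = sample(c("left", "right"), n, replace = TRUE),
      cms = cms,
      stringsAsFactors = FALSE)
  })
}

# Subtype labels from requested proportions; errors if a requested subtype
# comes out empty (degenerate for downstream enrichment rates).
assign_subtypes <- function(n, proportions) {
  stopifnot(length(proportions) == 4, all(proportions >= 0), sum(proportions) > 0)
  labels <- paste0("CMS", 1:4)
  cms <- sample(labels, n, replace = TRUE, prob = proportions)
  want <- labels[proportions > 0]
  empty <- setdiff(want, unique(cms))
  if (length(empty))
    stop("empty subtype under requested proportions: ",
         paste(empty, collapse = ", "))
  cms
}

#' Simulate negative-binomial expression counts
#'
#' Counts are drawn per gene from a negative binomial whose log mean is
#' `intercept + sum(beta * dosage) + gamma' covariates + subtype shift`;
#' genes without planted eQTLs have all betas zero. The dispersion parameter
#' is the NB size, so counts approach Poisson as it grows.
#'
#' @param G a [geno_matrix()].
#' @param truth a [make_ground_truth()] object.
#' @param covariates data.frame from [simulate_covariates()] (or NULL).
#' @param cfg a [sim_config()].
#' @param seed RNG seed.
#' @return A raw-scale [expr_matrix()] (genes x samples).
#' @export
simulate_expression <- function(G, truth, covariates = NULL, cfg,
                                seed = cfg$seed) {
  n <- nrow(G$dosages)
  genes <- truth$gene_meta$gene_id
  with_seed(derive_seed(seed, "expr"), {
    counts <- matrix(0L, length(genes), n,
                     dimnames = list(genes, rownames(G$dosages)))
    for (i in seq_along(genes)) {
      g <- genes[i]
      eta <- rep(log(500), n)  # baseline mean ~500 counts
      em <- truth$eqtl_map[[g]]
      if (!is.null(em) && nrow(em)) {
        miss <- setdiff(em$variant, colnames(G$dosages))
        if (length(miss))
          stop("unknown variant id in eqtl_map: ", paste(miss, collapse = ", "))
        eta <- eta + as.vector(G$dosages[, em$variant, drop = FALSE] %*% em$beta)
      }
      if (!is.null(covariates)) {
        # mild covariate load on expression: age and gender
        eta <- eta + 0.004 * (covariates$age - 60) + 0.05 * covariates$gender
        sh <- cfg$cms_shift[[g]]
        if (!is.null(sh)) {
          idx <- match(covariates$cms, paste0("CMS", 1:4))
          eta <- eta + sh[idx] * log(2)  # shifts specified on the log2 scale
        }
      }
      counts[i, ] <- stats::rnbinom(n, size = cfg$nb_dispersion, mu = exp(eta))
    }
    if (!is.null(cfg$cms_shift)) {
      bad <- setdiff(names(cfg$cms_shift), genes)
      if (length(bad)) stop("cms_shift names genes absent from the cohort: ",
                            paste(bad, collapse = ", "))
    }
    expr_matrix(counts, truth$gene_meta, "raw")
  })
}

#' Subtype labels for an expression cohort
#'
#' Thin wrapper that validates a subtype shift rule against the genes of an
#' expression matrix and returns the per-sample labels used when the counts
#' were generated. Shifts are applied inside [simulate_expression()] (before
#' count generation), so planted enrichment rates are recoverable.
#'
#' @param E an [expr_matrix()].
#' @param rule named list: gene -> length-4 shift vector (log2 scale).
#' @param covariates the covariate table holding the `cms` labels.
#' @return character vector of labels, one per sample.
#' @export
simulate_cms <- function(E, rule, covariates) {
  bad <- setdiff(names(rule), rownames(E$values))
  if (length(bad)) stop("rule names genes absent from E: ",
                        paste(bad, collapse = ", "))
  stats::setNames(covariates$cms, covariates$sample_id)
}

#' Simulate survival under an arm-specific additive hazard
#'
#' Event times follow `h(t) = lambda0 + x' alpha(t)` with `x` holding the
#' clipped expression z-scores of the causal genes (arm-specific slopes) and
#' a mild age term; `alpha` constant in time by default (exponential
#' inversion), or piecewise-constant on a stated grid (piecewise-exponential
#' inversion). Independent exponential censoring; arms assigned 1:1.
#'
#' @param G a discovery [geno_matrix()] (sample ids; also used for
#'   pleiotropic direct effects if planted).
#' @param E the raw [expr_matrix()] for the same samples (NULL for a
#'   genotype-only cohort, in which case causal effects act through the
#'   genetic predictor of expression).
#' @param truth a [make_ground_truth()] object.
#' @param covariates data.frame from [simulate_covariates()].
#' @param cfg a [sim_config()].
#' @param seed RNG seed.
#' @param alpha_breaks optional increasing time grid for piecewise-constant
#'   effects; `alpha_mult` gives the per-interval multiplier of each slope.
#' @param alpha_mult numeric vector, one multiplier per interval of
#'   `alpha_breaks` (length `length(alpha_breaks) + 1`).
#' @return A validated clinical data.frame (`sample_id`, `os_time`,
#'   `os_event`, `arm`, covariates, `cms`).
#' @export
simulate_survival <- function(G, E, truth, covariates, cfg, seed = cfg$seed,
                              alpha_breaks = NULL, alpha_mult = NULL) {
  n <- nrow(G$dosages)
  ids <- rownames(G$dosages)
  with_seed(derive_seed(seed, "surv"), {
    arm <- sample(c("bevacizumab", "cetuximab"), n, replace = TRUE)
    lin <- hazard_linear_predictor(G, E, truth, covariates, arm, cfg)
    rate <- cfg$baseline_hazard + lin
    if (any(rate <= 0))
      stop("negative or zero hazard for sample ", ids[which(rate <= 0)[1]],
           " (h = ", signif(min(rate), 4), ")")
    if (is.null(alpha_breaks)) {
      tt <- stats::rexp(n, rate)
    } else {
      stopifnot(length(alpha_mult) == length(alpha_breaks) + 1)
      tt <- piecewise_exp_sample(cfg$baseline_hazard, lin, alpha_breaks, alpha_mult)
    }
    if (cfg$censoring_rate > 0) {
      cc <- stats::rexp(n, cfg$censoring_rate)
    } else {
      cc <- rep(Inf, n)
    }
    out <- data.frame(sample_id = ids,
                      os_time = pmin(tt, cc),
                      os_event = as.integer(tt <= cc),
                      arm = arm,
                      stringsAsFactors = FALSE)
    out <- cbind(out, covariates[match(ids, covariates$sample_id),
                                 setdiff(names(covariates), "sample_id"),
                                 drop = FALSE])
    rownames(out) <- NULL
    validate_clinical(out)
    out
  })
}

# Additive linear predictor x' alpha for every sample. Causal expression
# effects use the clipped z-score of log2(count+1) (or of the genetic value
# Q beta for genotype-only cohorts); planted pleiotropic variants add a
# direct per-dosage term.
hazard_linear_predictor <- function(G, E, truth, covariates, arm, cfg) {
  n <- nrow(G$dosages)
  lin <- rep(0, n)
  clip <- cfg$hazard_x_clip
  zclip <- function(x) {
    s <- stats::sd(x)
    if (s < 1e-12) return(rep(0, length(x)))
    pmin(pmax((x - mean(x)) / s, -clip), clip)
  }
  ce <- truth$causal_gene_arm_pairs
  if (!is.null(ce)) {
    for (r in seq_len(nrow(ce))) {
      g <- ce$gene[r]
      if (!is.null(E)) {
        x <- zclip(log2(E$values[g, ] + 1))
      } else {
        em <- truth$eqtl_map[[g]]
        x <- zclip(as.vector(G$dosages[, em$variant, drop = FALSE] %*% em$beta))
      }
      lin <- lin + ifelse(arm == ce$arm[r], ce$alpha[r] * x, 0)
    }
  }
  # mild prognostic age effect, clipped like expression
  lin <- lin + 0.05 * cfg$baseline_hazard * zclip(covariates$age)
  pv <- truth$pleiotropic_variants
  if (!is.null(pv)) {
    for (r in seq_len(nrow(pv))) {
      d <- G$dosages[, pv$variant[r]]
      # direct variant effect expressed additively, centered
      lin <- lin + pv$beta[r] * cfg$baseline_hazard * (d - mean(d))
    }
  }
  lin
}

# Exact inversion sampling for h(t) = lambda0 * mult(t) + lin * mult(t) on a
# piecewise-constant grid: cumulative hazard is piecewise linear, inverted
# segment by segment.
piecewise_exp_sample <- function(lambda0, lin, breaks, mult) {
  n <- length(lin)
  u <- stats::rexp(n)  # target cumulative hazard
  edges <- c(0, breaks, Inf)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (k in seq_along(mult)) {
      rate <- (lambda0 + lin[i]) * mult[k]
      if (rate <= 0) stop("negative hazard for sample ", i, " in interval ", k)
      width <- edges[k + 1] - edges[k]
      if (acc + rate * width >= u[i]) {
        out[i] <- edges[k] + (u[i] - acc) / rate
        break
      }
      acc <- acc + rate * width
      if (k == length(mult)) out[i] <- edges[k + 1]  # unreachable (Inf width)
    }
  }
  out
}

#' Simulate a complete two-cohort study
#'
#' Convenience wrapper producing discovery and validation cohorts plus the
#' ground truth: genotypes, expression (discovery only), covariates with
#' subtype labels, and survival for both cohorts.
#'
#' @param cfg a [sim_config()].
#' @return list with `truth`, `discovery` (list: G, E, covariates, clinical)
#'   and `validation` (list: G, covariates, clinical).
#' @export
simulate_study <- function(cfg) {
  G_d <- simulate_genotypes(cfg, n = cfg$n_discovery, sample_prefix = "D",
                            seed = cfg$seed)
  truth <- make_ground_truth(cfg, G_d)
  cov_d <- simulate_covariates(cfg, cfg$n_discovery, rownames(G_d$dosages),
                               seed = cfg$seed)
  E_d <- simulate_expression(G_d, truth, cov_d, cfg, seed = cfg$seed)
  clin_d <- simulate_survival(G_d, E_d, truth, cov_d, cfg, seed = cfg$seed)
  G_v <- simulate_genotypes(cfg, n = cfg$n_validation, sample_prefix = "V",
                            seed = derive_seed(cfg$seed, "validation"))
  cov_v <- simulate_covariates(cfg, cfg$n_validation, rownames(G_v$dosages),
                               seed = derive_seed(cfg$seed, "validation"))
  clin_v <- simulate_survival(G_v, NULL, truth, cov_v, cfg,
                              seed = derive_seed(cfg$seed, "validation"))
  list(truth = truth,
       discovery = list(G = G_d, E = E_d, covariates = cov_d, clinical = clin_d),
       validation = list(G = G_v, covariates = cov_v, clinical = clin_v))
}
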