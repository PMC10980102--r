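# Synthetic-cohort generator: genotypes, expression, survival, subtypes.

test_that("independent variants have near-zero pairwise r2 and symmetric dosage mean", {
  cfg <- sim_config(n_discovery = 10000, n_genes = 2, snps_per_gene = 5,
                    ld_block_rho = 0, maf_range = c(0.49, 0.5), seed = 42)
  G <- simulate_genotypes(cfg)
  # inter-variant r2 across the two independent blocks
  r2 <- cor(G$dosages)^2
  off <- r2[upper.tri(r2)]
  expect_lt(mean(off), 0.001 + 3 / 10000)
  # maf ~ 0.5 gives mean dosage ~ 1
  expect_true(all(abs(colMeans(G$dosages) - 1) < 0.03))
})

test_that("within-block dosage r2 matches a brute-force two-locus copula oracle", {
  # oracle: sample two loci directly from the latent exchangeable Gaussian
  # copula (independent of the generator's code path)
  rho <- 0.8; maf <- c(0.3, 0.4); n <- 10000
  set.seed(99)
  hap_pair <- function() {
    s <- rnorm(n)
    z1 <- sqrt(rho) * s + sqrt(1 - rho) * rnorm(n)
    z2 <- sqrt(rho) * s + sqrt(1 - rho) * rnorm(n)
    cbind(z1 < qnorm(maf[1]), z2 < qnorm(maf[2])) + 0
  }
  d_or <- hap_pair() + hap_pair()
  oracle_r2 <- cor(d_or[, 1], d_or[, 2])^2

  cfg <- sim_config(n_discovery = 10000, n_genes = 1, snps_per_gene = 5,
                    ld_block_rho = 0.8, maf_range = c(0.2, 0.45), seed = 7)
  G <- simulate_genotypes(cfg)
  r2 <- cor(G$dosages)^2
  mean_r2 <- mean(r2[upper.tri(r2)])
  expect_lt(abs(mean_r2 - oracle_r2), 0.1)
})

test_that("no emitted variant violates the MAF floor, and configs enforce it", {
  cfg <- sim_config(n_discovery = 150, n_genes = 4, maf_range = c(0.06, 0.12),
                    seed = 3)
  G <- simulate_genotypes(cfg)
  emp <- colMeans(G$dosages) / 2
  expect_true(all(pmin(emp, 1 - emp) >= 0.05))
  expect_error(sim_config(maf_range = c(0.05, 0.3)), "exceed 0.05")
})

test_that("generator is bit-reproducible under a fixed config", {
  cfg <- sim_config(n_discovery = 80, n_validation = 60, seed = 5)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$discovery$G$dosages, s2$discovery$G$dosages)
  expect_identical(s1$discovery$E$values, s2$discovery$E$values)
  expect_identical(s1$discovery$clinical, s2$discovery$clinical)
  expect_identical(s1$validation$clinical, s2$validation$clinical)
})

test_that("null eQTL genes show no dosage-expression slope; planted effects match the NB mean ratio", {
  # null case: genes without planted eQTLs, slope CI covers 0 for most genes
  cfg <- sim_config(n_discovery = 400, n_genes = 8, seed = 21)
  G <- simulate_genotypes(cfg)
  truth <- make_ground_truth(cfg, G)
  truth$eqtl_map <- lapply(truth$eqtl_map, function(x) x[0, ])  # wipe effects
  E <- simulate_expression(G, truth, NULL, cfg, seed = 21)
  covered <- vapply(seq_len(8), function(i) {
    d <- G$dosages[, (i - 1) * 4 + 1]
    fit <- lm(log2(E$values[i, ] + 1) ~ d)
    ci <- confint(fit)[2, ]
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.5)   # 95% CIs, 8 genes: >= half must cover

  # near-Poisson limit: mean ratio between dosage-2 and dosage-0 ~ exp(2 beta)
  cfg2 <- sim_config(n_discovery = 8000, n_genes = 1, snps_per_gene = 1,
                     n_causal_ivs_per_gene = 1, ld_block_rho = 0,
                     nb_dispersion = 1e6, maf_range = c(0.4, 0.5), seed = 8)
  G2 <- simulate_genotypes(cfg2)
  tr2 <- make_ground_truth(cfg2, G2)
  beta <- 0.5
  tr2$eqtl_map[[1]] <- data.frame(variant = colnames(G2$dosages)[1], beta = beta)
  E2 <- simulate_expression(G2, tr2, NULL, cfg2, seed = 8)
  d <- G2$dosages[, 1]
  m2 <- mean(E2$values[1, d == 2]); m0 <- mean(E2$values[1, d == 0])
  expect_lt(abs(m2 / m0 - exp(2 * beta)) / exp(2 * beta), 0.1)

  # exchangeability: constant dosage, no covariates -> two halves same law
  cfg3 <- sim_config(n_discovery = 600, n_genes = 1, seed = 13)
  G3 <- simulate_genotypes(cfg3, seed = 13)
  tr3 <- make_ground_truth(cfg3, G3)
  tr3$eqtl_map[[1]] <- tr3$eqtl_map[[1]][0, ]
  E3 <- simulate_expression(G3, tr3, NULL, cfg3, seed = 13)
  x <- E3$values[1, ]
  ks <- suppressWarnings(ks.test(x[1:300], x[301:600]))
  expect_gt(ks$p.value, 0.01)
})

test_that("expression generation rejects unknown eQTL variant ids", {
  cfg <- sim_config(n_discovery = 50, n_genes = 2, seed = 1)
  G <- simulate_genotypes(cfg)
  truth <- make_ground_truth(cfg, G)
  truth$eqtl_map[[1]]$variant[1] <- "rs_nonexistent"
  expect_error(simulate_expression(G, truth, NULL, cfg), "unknown variant")
})

test_that("survival sampling matches closed forms and the Nelson-Aalen hazard-ratio oracle", {
  # alpha = 0, no censoring: exponential(lambda0); KM median ~ ln2/lambda0
  cfg <- sim_config(n_discovery = 5000, n_genes = 1, baseline_hazard = 0.1,
                    censoring_rate = 0, seed = 17)
  G <- simulate_genotypes(cfg)
  truth <- make_ground_truth(cfg, G)
  cov <- simulate_covariates(cfg, 5000, rownames(G$dosages), seed = 17)
  cov$age <- 60  # silence the prognostic age term: pure exponential
  clin <- simulate_survival(G, NULL, truth, cov, cfg, seed = 17)
  expect_true(all(clin$os_event == 1))
  km_med <- median(clin$os_time)
  expect_lt(abs(km_med - log(2) / 0.1) / (log(2) / 0.1), 0.07)

  # binary covariate with constant additive effect: cumulative-hazard ratio
  # matches (lambda0 + alpha) / lambda0 via a Nelson-Aalen oracle per group
  lam0 <- 0.1; alp <- 0.08; n <- 6000
  set.seed(31)
  grp <- rep(0:1, each = n / 2)
  tt <- rexp(n, lam0 + alp * grp)
  na0 <- nelson_aalen_oracle(tt[grp == 0], rep(1, n / 2))
  na1 <- nelson_aalen_oracle(tt[grp == 1], rep(1, n / 2))
  tq <- quantile(tt, 0.5)
  H0 <- max(na0$cumhaz[na0$times <= tq]); H1 <- max(na1$cumhaz[na1$times <= tq])
  expect_lt(abs(H1 / H0 - (lam0 + alp) / lam0), 0.15)
})

test_that("negative hazard is a hard failure naming the offending sample", {
  cfg <- sim_config(n_discovery = 100, n_genes = 2, seed = 2,
                    baseline_hazard = 0.1)
  G <- simulate_genotypes(cfg)
  truth <- make_ground_truth(cfg, G)
  cov <- simulate_covariates(cfg, 100, rownames(G$dosages), seed = 2)
  E <- simulate_expression(G, truth, cov, cfg, seed = 2)
  # inject an inadmissible effect directly into the truth object
  truth$causal_gene_arm_pairs <- data.frame(gene = "gene01",
                                            arm = "bevacizumab", alpha = 0.2)
  expect_error(simulate_survival(G, E, truth, cov, cfg, seed = 2),
               "negative or zero hazard for sample")
  # and the config constructor rejects it upfront
  expect_error(
    sim_config(causal_effects = data.frame(gene = "gene01",
                                           arm = "bevacizumab", alpha = 0.2)),
    "config rejected")
})

test_that("piecewise-constant effects sample by exact piecewise-exponential inversion", {
  cfg <- sim_config(n_discovery = 4000, n_genes = 1, baseline_hazard = 0.2,
                    censoring_rate = 0, seed = 23)
  G <- simulate_genotypes(cfg)
  truth <- make_ground_truth(cfg, G)
  truth$causal_gene_arm_pairs <- NULL
  cov <- simulate_covariates(cfg, 4000, rownames(G$dosages), seed = 23)
  cov$age <- 60
  # hazard 0.2 on [0,2), 0.4 afterwards; survival at t has closed form
  clin <- simulate_survival(G, NULL, truth, cov, cfg, seed = 23,
                            alpha_breaks = 2, alpha_mult = c(1, 2))
  S_emp <- mean(clin$os_time > 4)
  S_true <- exp(-(0.2 * 2 + 0.4 * 2))
  expect_lt(abs(S_emp - S_true), 0.03)
})

test_that("subtype labels follow requested proportions and planted shifts raise above-median rates", {
  # degenerate proportions give a single label
  cfg1 <- sim_config(n_discovery = 50, cms_proportions = c(1, 0, 0, 0), seed = 4)
  cov1 <- simulate_covariates(cfg1, 50, sprintf("s%02d", 1:50), seed = 4)
  expect_true(all(cov1$cms == "CMS1"))

  # zero shift: above-median rates per subtype ~ 50%
  cfg2 <- sim_config(n_discovery = 800, n_genes = 2, seed = 6)
  G2 <- simulate_genotypes(cfg2)
  tr2 <- make_ground_truth(cfg2, G2)
  cov2 <- simulate_covariates(cfg2, 800, rownames(G2$dosages), seed = 6)
  E2 <- simulate_expression(G2, tr2, cov2, cfg2, seed = 6)
  x <- log2(E2$values[1, ] + 1)
  above <- x > median(x)
  rates <- tapply(above, cov2$cms, mean)
  expect_true(all(abs(rates - 0.5) < 0.12))

  # large planted shift in CMS1: above-median rate > 70%, in line with a
  # two-group normal-shift oracle on the log2 scale
  delta <- 2
  cfg3 <- sim_config(n_discovery = 800, n_genes = 2, seed = 9,
                     cms_shift = list(gene01 = c(delta, 0, 0, 0)))
  G3 <- simulate_genotypes(cfg3)
  tr3 <- make_ground_truth(cfg3, G3)
  cov3 <- simulate_covariates(cfg3, 800, rownames(G3$dosages), seed = 9)
  E3 <- simulate_expression(G3, tr3, cov3, cfg3, seed = 9)
  y <- log2(E3$values["gene01", ] + 1)
  r1 <- mean(y[cov3$cms == "CMS1"] > median(y))
  # oracle: mixture median m solves .25 Phi(delta/s - m/s) + .75 Phi(-m/s) = .5
  s <- sd(y[cov3$cms != "CMS1"])
  m <- uniroot(function(m) 0.25 * pnorm((delta - m) / s) + 0.75 * pnorm(-m / s) - 0.5,
               c(-1, delta))$root
  oracle_rate <- pnorm((delta - m) / s)
  expect_gt(r1, 0.70)
  expect_lt(abs(r1 - oracle_rate), 0.15)

  # requested-but-empty subtype errors
  expect_error(
    simulate_covariates(
      sim_config(n_discovery = 3, cms_proportions = c(0.997, 0.001, 0.001, 0.001),
                 seed = 11),
      3, c("a", "b", "c")),
    "empty subtype")
})

test_that("ground truth is queryable and internally consistent", {
  cfg <- sim_config(n_discovery = 60, seed = 12,
                    causal_effects = data.frame(gene = "gene02",
                                                arm = "cetuximab", alpha = 0.05))
  st <- simulate_study(cfg)
  tr <- st$truth
  # every causal gene has at least one eQTL
  for (g in tr$causal_gene_arm_pairs$gene)
    expect_gte(nrow(tr$eqtl_map[[g]]), 1)
  # eQTL variants lie within 1 Mb of the gene TSS
  for (g in names(tr$eqtl_map)) {
    vm <- st$discovery$G$variant_meta
    tss <- tr$gene_meta$tss[tr$gene_meta$gene_id == g]
    pos <- vm$pos[match(tr$eqtl_map[[g]]$variant, vm$variant_id)]
    expect_true(all(abs(pos - tss) <= 1e6))
  }
})
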