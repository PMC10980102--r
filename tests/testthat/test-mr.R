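# Gene clustering, survival screens, IV pruning, prediction, one- and
# two-sample MR.

test_that("gene clustering recovers separable groups and is seed-deterministic", {
  set.seed(6)
  n <- 40
  centers <- rbind(c(rep(5, n / 2), rep(0, n / 2)),
                   c(rep(0, n / 2), rep(5, n / 2)),
                   rep(c(5, 0), n / 2),
                   rep(c(0, 5), n / 2))
  V <- centers[rep(1:4, each = 5), ] + matrix(rnorm(20 * n, 0, 0.2), 20, n)
  E <- toy_expr(V, scale_flag = "log2")
  cl <- cluster_genes(E, k = 4, seed = 3)
  truth <- rep(1:4, each = 5)
  # partitions agree up to label permutation
  expect_equal(length(unique(paste(cl, truth))), 4)
  # determinism
  expect_identical(cl, cluster_genes(E, k = 4, seed = 3))
  # k = number of genes: singletons
  cl_all <- cluster_genes(E, k = 20, seed = 3)
  expect_equal(length(unique(cl_all)), 20)
  expect_error(cluster_genes(E, k = 21), "cannot exceed")
  # within-cluster SSE beats random partitions
  Xs <- t(scale(t(V)))
  sse <- function(part) sum(vapply(split(seq_len(20), part), function(i)
    sum(scale(Xs[i, , drop = FALSE], scale = FALSE)^2), numeric(1)))
  sse_km <- sse(cl)
  set.seed(10)
  sse_rand <- replicate(100, sse(sample(1:4, 20, replace = TRUE)))
  expect_true(all(sse_km <= sse_rand))
})

test_that("the gene-OS screen finds planted arm-specific effects and respects the floor", {
  hits <- vapply(1:20, function(s) {
    cfg <- sim_config(n_discovery = 600, seed = s,
                      causal_effects = data.frame(gene = "gene02",
                                                  arm = "bevacizumab",
                                                  alpha = 0.06))
    st <- simulate_study(cfg)
    El <- log2_transform(upper_quartile_normalize(st$discovery$E))
    cl <- cluster_genes(El, k = 2, seed = s)
    sc <- screen_gene_os(El, st$discovery$clinical, NULL, cl,
                         arm = "bevacizumab")
    sc$selected[sc$gene_id == "gene02"]
  }, logical(1))
  expect_gte(mean(hits), 0.8)

  # events floor: tiny arm errors out
  cfg <- sim_config(n_discovery = 30, seed = 1)
  st <- simulate_study(cfg)
  El <- log2_transform(upper_quartile_normalize(st$discovery$E))
  cl <- cluster_genes(El, k = 2, seed = 1)
  expect_error(screen_gene_os(El, st$discovery$clinical, NULL, cl,
                              arm = "bevacizumab", min_events = 100),
               "below the floor")
})

test_that("screen and causal thresholds are strict at the boundary", {
  cfg <- sim_config(n_discovery = 400, seed = 2)
  st <- simulate_study(cfg)
  El <- log2_transform(upper_quartile_normalize(st$discovery$E))
  cl <- cluster_genes(El, k = 2, seed = 2)
  sc <- screen_gene_os(El, st$discovery$clinical, NULL, cl, arm = "cetuximab")
  # re-screen with alpha set to an observed p: that gene must NOT be selected
  p_obs <- sc$p_value[1]
  sc2 <- screen_gene_os(El, st$discovery$clinical, NULL, cl,
                        arm = "cetuximab", alpha = p_obs)
  expect_false(sc2$selected[sc2$gene_id == sc$gene_id[1]])
})

test_that("the pleiotropy screen keeps null variants and is strict at its threshold", {
  cfg <- sim_config(n_discovery = 500, seed = 4)
  st <- simulate_study(cfg)
  cand <- colnames(st$discovery$G$dosages)[1:8]
  ps <- pleiotropy_screen(st$discovery$G, st$discovery$clinical,
                          candidate_ivs = cand)
  # null variants: none should fall under 1e-4 here
  expect_length(ps$excluded, 0)
  # exactly-at-threshold is retained: set alpha to an observed p
  p1 <- ps$p[1]
  ps2 <- pleiotropy_screen(st$discovery$G, st$discovery$clinical,
                           candidate_ivs = cand, alpha = p1)
  expect_false(names(p1) %in% ps2$excluded)
  # a planted strong direct effect is excluded
  cfg2 <- sim_config(n_discovery = 800, seed = 5)
  G2 <- simulate_genotypes(cfg2, seed = 5)
  tr2 <- make_ground_truth(cfg2, G2)
  pv <- tr2$eqtl_map[["gene01"]]$variant[1]
  tr2$pleiotropic_variants <- data.frame(variant = pv, beta = 0.8)
  cov2 <- simulate_covariates(cfg2, 800, rownames(G2$dosages), seed = 5)
  clin2 <- simulate_survival(G2, NULL, tr2, cov2, cfg2, seed = 5)
  ps3 <- pleiotropy_screen(G2, clin2, candidate_ivs = pv)
  expect_true(pv %in% ps3$excluded)
})

test_that("IV pruning clusters by LD with strict r2 rule and picks best-p proxies", {
  # single IV: the set is itself
  eq1 <- data.frame(gene_id = "g", variant_id = "a", beta = 0.5,
                    p_nominal = 0.01)
  set.seed(3)
  G1 <- toy_geno(matrix(rbinom(50, 2, 0.4), 50, 1))
  colnames(G1$dosages) <- "a"; G1$variant_meta$variant_id <- "a"
  iv1 <- prune_ivs(eq1, G1)
  expect_equal(iv1$ivs$variant_id, "a")
  expect_equal(iv1$ivs$weight, 0.5)

  # 3 variants with r2(A,B) high, r2 with C low: clusters {A,B},{C}
  set.seed(9)
  n <- 400
  A <- rbinom(n, 2, 0.5)
  B <- A; flip <- sample(n, 60); B[flip] <- rbinom(60, 2, 0.5)   # high LD
  C <- rbinom(n, 2, 0.5)                                         # independent
  d <- cbind(a = A, b = B, c = C)
  G <- toy_geno(d)
  colnames(G$dosages) <- c("a", "b", "c"); G$variant_meta$variant_id <- c("a", "b", "c")
  r2 <- cor(d)^2
  expect_gt(r2["a", "b"], 0.1); expect_lt(r2["a", "c"], 0.1)
  eq <- data.frame(gene_id = "g", variant_id = c("a", "b", "c"),
                   beta = c(0.3, 0.6, -0.2),
                   p_nominal = c(0.02, 0.001, 0.5))
  iv <- prune_ivs(eq, G)
  expect_setequal(iv$ivs$variant_id, c("b", "c"))   # b beats a on p
  # all pairwise r2 below the threshold: every variant its own proxy
  set.seed(21)
  d2 <- matrix(rbinom(n * 3, 2, 0.5), n, 3)
  G2 <- toy_geno(d2)
  eq2 <- data.frame(gene_id = "g", variant_id = colnames(G2$dosages),
                    beta = 1:3 / 10, p_nominal = c(0.1, 0.2, 0.3))
  iv2 <- prune_ivs(eq2, G2)
  expect_setequal(iv2$ivs$variant_id, colnames(G2$dosages))
  expect_error(prune_ivs(eq2[0, ], G2), "empty IV list")
})

test_that("one-sample prediction is the dosage-weight product", {
  Q <- matrix(c(0, 1, 2, 1, 2, 0), 3, 2,
              dimnames = list(paste0("s", 1:3), c("va", "vb")))
  G <- toy_geno(Q)
  ivset <- structure(list(gene_id = "g",
                          ivs = data.frame(variant_id = c("va", "vb"),
                                           weight = c(0.5, -1),
                                           p_nominal = c(0.01, 0.02))),
                     class = "iv_set")
  # hand product: [0,1,2] * 0.5 + [1,2,0] * (-1) = [-1, -1.5, 1]
  expect_equal(unname(predict_expression_one_sample(ivset, G)),
               c(-1, -1.5, 1))
  ivset$ivs$weight <- c(0, 0)
  expect_true(all(predict_expression_one_sample(ivset, G) == 0))
  ivset$ivs <- data.frame(variant_id = "va", weight = 1, p_nominal = 0.01)
  expect_equal(unname(predict_expression_one_sample(ivset, G)),
               unname(Q[, "va"]))
  ivset$ivs$variant_id <- "missing"
  expect_error(predict_expression_one_sample(ivset, G), "missing variant")
})

test_that("two-sample prediction satisfies the projection identities and a pseudoinverse oracle", {
  set.seed(13)
  Q <- matrix(c(1, 0, 2, 1, 1, 1, 0, 2), 4, 2,
              dimnames = list(paste0("d", 1:4), c("va", "vb")))
  Qv <- matrix(c(2, 1, 0, 0, 1, 2), 3, 2,
               dimnames = list(paste0("v", 1:3), c("va", "vb")))
  Gd <- toy_geno(Q); Gv <- toy_geno(Qv)
  g <- c(1.2, -0.4, 2.2, 0.8); names(g) <- rownames(Q)
  ivset <- structure(list(gene_id = "g",
                          ivs = data.frame(variant_id = c("va", "vb"),
                                           weight = c(1, 1),
                                           p_nominal = c(0.1, 0.1))),
                     class = "iv_set")
  # literal formula vs brute-force pseudoinverse
  gh <- predict_expression_two_sample(ivset, Gd, g, Gv, center = FALSE)
  oracle <- Qv %*% (MASS::ginv(Q) %*% g)
  expect_lt(max(abs(gh - oracle)), 1e-10)
  # Q* = Q reproduces the OLS fitted values (hat-matrix idempotence)
  gh_self <- predict_expression_two_sample(ivset, Gd, g, Gd, center = FALSE)
  fitted <- Q %*% solve(crossprod(Q), crossprod(Q, g))
  expect_lt(max(abs(gh_self - fitted)), 1e-10)
  # g orthogonal to col(Q) predicts exactly zero
  g_orth <- as.vector((diag(4) - Q %*% solve(crossprod(Q), t(Q))) %*% rnorm(4))
  names(g_orth) <- rownames(Q)
  gh0 <- predict_expression_two_sample(ivset, Gd, g_orth, Gv, center = FALSE)
  expect_lt(max(abs(gh0)), 1e-10)
  # collinear proxies trigger the logged ridge fallback instead of failing
  Qc <- cbind(va = Q[, 1], vb = Q[, 1])
  rownames(Qc) <- rownames(Q)
  Gc <- toy_geno(Qc)
  ghr <- predict_expression_two_sample(ivset, Gc, g, Gc, center = FALSE)
  expect_true(attr(ghr, "ridge"))
  expect_true(all(is.finite(ghr)))
})

test_that("one-sample MR holds its level without instruments and under confounding", {
  # expression affects hazard but instruments are null: MR finds nothing
  set.seed(71)
  rej_noinstr <- mean(replicate(60, {
    n <- 300
    d <- matrix(rbinom(n * 2, 2, 0.3), n, 2)          # null instruments
    expr <- rnorm(n)                                   # true exposure
    tt <- rexp(n, 0.1 + 0.03 * pmin(pmax(expr, -1.5), 1.5))
    clin <- toy_clinical(tt, rep(1L, n), arm = "bevacizumab",
                         ids = sprintf("s%02d", 1:n))
    ghat <- d %*% c(0.4, -0.3)                         # prediction from noise
    rownames(ghat) <- clin$sample_id; colnames(ghat) <- "g1"
    r <- one_sample_mr(ghat, clin, NULL, "bevacizumab")
    r$significant
  }))
  expect_lt(rej_noinstr, 0.15)

  # classic confounding: U drives expression and hazard, no causal path;
  # the naive screen rejects far above level, MR stays near it
  set.seed(72)
  out <- replicate(60, {
    n <- 300
    U <- rnorm(n)
    d <- rbinom(n, 2, 0.4)
    expr <- 0.5 * d + U + rnorm(n, 0, 0.5)             # valid instrument
    tt <- rexp(n, 0.12 + 0.04 * pmin(pmax(U, -2), 2))  # hazard via U only
    clin <- toy_clinical(tt, rep(1L, n), arm = "bevacizumab",
                         ids = sprintf("s%03d", 1:n))
    naive <- fit_aalen(cbind(1, expr = scale(expr)[, 1]), tt, rep(1L, n))
    p_naive <- aalen_test(naive, "expr")$p
    ghat <- matrix(0.5 * d, ncol = 1,
                   dimnames = list(clin$sample_id, "g1"))
    r <- one_sample_mr(ghat, clin, NULL, "bevacizumab")
    c(naive = p_naive < 0.05, mr = r$significant)
  })
  expect_gt(mean(out["naive", ]), 0.4)    # association screen misled
  expect_lt(mean(out["mr", ]), 0.15)      # MR protected by the instrument
})

test_that("constant predictions and collinear predictions are handled as specified", {
  n <- 100
  set.seed(2)
  tt <- rexp(n, 0.1)
  clin <- toy_clinical(tt, rep(1L, n), arm = "cetuximab",
                       ids = sprintf("s%03d", 1:n))
  pc <- matrix(1, n, 1, dimnames = list(clin$sample_id, "g1"))
  expect_error(one_sample_mr(pc, clin, NULL, "cetuximab"), "constant")
  # second gene collinear with the first: dropped, first retained
  g1 <- rnorm(n)
  P <- cbind(g1 = g1, g2 = 2 * g1)
  rownames(P) <- clin$sample_id
  r <- one_sample_mr(P, clin, NULL, "cetuximab")
  expect_identical(r$gene_id, "g1")
  expect_identical(attr(r, "dropped"), "g2")
})

test_that("allele recoding with matching weight flips leaves predictions and p-values unchanged", {
  cfg <- sim_config(n_discovery = 300, seed = 30,
                    causal_effects = data.frame(gene = "gene01",
                                                arm = "bevacizumab",
                                                alpha = 0.05))
  st <- simulate_study(cfg)
  El <- log2_transform(upper_quartile_normalize(st$discovery$E))
  eq <- map_cis_eqtl(El, st$discovery$G)
  iv <- prune_ivs(eq[eq$gene_id == "gene01", ], st$discovery$G)
  gh <- predict_expression_one_sample(iv, st$discovery$G)
  # flip every proxy's dosage coding and the weight sign
  Gf <- st$discovery$G
  Gf$dosages[, iv$ivs$variant_id] <- 2 - Gf$dosages[, iv$ivs$variant_id]
  ivf <- iv; ivf$ivs$weight <- -iv$ivs$weight
  ghf <- predict_expression_one_sample(ivf, Gf)
  # identical up to an additive constant
  expect_lt(max(abs((gh - mean(gh)) - (ghf - mean(ghf)))), 1e-10)
  # and the MR p-value is untouched
  P1 <- matrix(gh, ncol = 1, dimnames = list(names(gh), "gene01"))
  P2 <- matrix(ghf, ncol = 1, dimnames = list(names(ghf), "gene01"))
  r1 <- one_sample_mr(P1, st$discovery$clinical, NULL, "bevacizumab")
  r2 <- one_sample_mr(P2, st$discovery$clinical, NULL, "bevacizumab")
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-9)
})
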