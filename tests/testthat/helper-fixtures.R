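# Shared fixture builders. Everything is generated in code; no stored data.

# genes x samples expression matrix with trivial TSS metadata
toy_expr <- function(values, scale_flag = "raw", chrom = "chr1",
                     tss = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  if (is.null(tss)) tss <- seq_len(nrow(values)) * 2000000L
  expr_matrix(values,
              data.frame(gene_id = rownames(values), chrom = chrom, tss = tss),
              scale_flag)
}

# samples x variants dosage matrix with trivial metadata
toy_geno <- function(dosages, chrom = "chr1", pos = NULL) {
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("s%02d", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- sprintf("v%02d", seq_len(ncol(dosages)))
  if (is.null(pos)) pos <- seq_len(ncol(dosages)) * 1000L
  emp <- colMeans(dosages) / 2
  geno_matrix(dosages,
              data.frame(variant_id = colnames(dosages), chrom = chrom,
                         pos = pos, effect_allele = "A", other_allele = "G",
                         maf = pmin(emp, 1 - emp)))
}

# minimal clinical table
toy_clinical <- function(time, event, arm = "bevacizumab", ids = NULL,
                         extra = NULL) {
  n <- length(time)
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(n))
  cl <- data.frame(sample_id = ids, os_time = time, os_event = event,
                   arm = rep_len(arm, n),
                   age = rep(60, n), gender = rep_len(c(0, 1), n),
                   braf_v600e = 0, all_ras = rep_len(c(0, 1, 0), n),
                   stringsAsFactors = FALSE)
  if (!is.null(extra)) cl <- cbind(cl, extra)
  cl
}

# independent per-event-time least-squares oracle for the Aalen increments:
# at each distinct event time solve (X_r' X_r)^{-1} X_r' dN by a dense solve
# over the explicitly constructed at-risk set; event times whose at-risk
# Gram matrix is numerically singular (outside the identifiable range) are
# omitted, mirroring the estimator's documented rule
aalen_increment_oracle <- function(X, time, event, rcond_tol = 1e-10) {
  ev <- sort(unique(time[event == 1]))
  rows <- lapply(ev, function(tk) {
    risk <- which(time >= tk)
    Xr <- X[risk, , drop = FALSE]
    M <- crossprod(Xr)
    if (rcond(M) < rcond_tol) return(NULL)
    dN <- as.numeric(time[risk] == tk & event[risk] == 1)
    list(time = tk, dB = as.vector(solve(M, crossprod(Xr, dN))))
  })
  rows <- Filter(Negate(is.null), rows)
  list(times = vapply(rows, `[[`, numeric(1), "time"),
       dB = do.call(rbind, lapply(rows, `[[`, "dB")))
}

# Nelson-Aalen estimator computed directly from its definition
nelson_aalen_oracle <- function(time, event) {
  ev <- sort(unique(time[event == 1]))
  dA <- vapply(ev, function(tk)
    sum(time == tk & event == 1) / sum(time >= tk), numeric(1))
  list(times = ev, cumhaz = cumsum(dA))
}

# brute-force Breslow partial log-likelihood for a single covariate
cox_loglik_oracle <- function(beta, x, time, event) {
  ord <- order(time)
  x <- x[ord]; time <- time[ord]; event <- event[ord]
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}
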