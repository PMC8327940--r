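# Independent brute-force oracles, written as literal transliterations of
# the definitions so they share no code path with the package internals.

# TMM factor for one sample against a reference: enumerate M/A values,
# drop the trimmed tails by explicit sorting, take the precision-weighted
# mean of the survivors.
oracle_tmm_pair <- function(obs, ref, n_obs, n_ref,
                            trim_m = 0.30, trim_a = 0.05) {
  keep0 <- which(obs > 0 & ref > 0)
  M <- A <- V <- numeric(0)
  for (g in keep0) {
    po <- obs[g] / n_obs
    pr <- ref[g] / n_ref
    M <- c(M, log2(po / pr))
    A <- c(A, (log2(po) + log2(pr)) / 2)
    V <- c(V, (n_obs - obs[g]) / (n_obs * obs[g]) +
              (n_ref - ref[g]) / (n_ref * ref[g]))
  }
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  rm_ <- rank(M, ties.method = "first")
  ra_ <- rank(A, ties.method = "first")
  surv <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
  num <- den <- 0
  for (i in which(surv)) {
    num <- num + M[i] / V[i]
    den <- den + 1 / V[i]
  }
  2^(num / den)
}

oracle_tmm <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  lib <- colSums(counts)
  q75 <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts)))
    q75[j] <- quantile(counts[, j], probs = 0.75, names = FALSE) / lib[j]
  ref <- which.min(abs(q75 - mean(q75)))
  f <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts)))
    f[j] <- oracle_tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref],
                            trim_m, trim_a)
  f / exp(mean(log(f)))
}

# Literal Benjamini-Hochberg step-up: q_(i) = min_{j >= i} p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cands <- numeric(0)
    for (j in i:m) cands <- c(cands, p[o[j]] * m / j)
    q_sorted[i] <- min(1, min(cands))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Direct normal-equations evaluation of an (optionally weighted) gene-wise
# linear model and contrast.
oracle_wls <- function(y, X, w, cvec) {
  W <- diag(w)
  XtWX <- t(X) %*% W %*% X
  inv <- solve(XtWX)
  beta <- inv %*% t(X) %*% W %*% y
  r <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(w * r^2) / df
  list(estimate = drop(t(cvec) %*% beta),
       s2 = s2,
       v = drop(t(cvec) %*% inv %*% cvec),
       t_ordinary = drop(t(cvec) %*% beta) / sqrt(s2 * drop(t(cvec) %*% inv %*% cvec)),
       df = df)
}

# Small deterministic fixture: counts with one spiked gene so the TMM trim
# sets are non-trivial.
spiked_fixture <- function(seed = 101, n_genes = 20, n_samples = 3) {
  set.seed(seed)
  m <- matrix(rnbinom(n_genes * n_samples, mu = exp(runif(n_genes * n_samples, 3, 7)),
                      size = 10), n_genes, n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%d", seq_len(n_samples))))
  m[1, 1] <- m[1, 1] * 40  # spike
  m
}

# Balanced two-line sample sheet used across tests.
toy_design <- function(per_cell = 2) {
  grid <- expand.grid(line_type = c("control", "resistant"),
                      treatment = c("unsprayed", "sprayed"),
                      timepoint = c(8, 32), replicate = seq_len(per_cell),
                      stringsAsFactors = FALSE)
  grid$sample <- sprintf("s%02d", seq_len(nrow(grid)))
  sample_design(grid[, c("sample", "line_type", "treatment", "timepoint",
                         "replicate")])
}

# dge_result-shaped table for classify tests.
fake_dge <- function(gene, lfc, fdr, contrast = NULL) {
  structure(data.frame(gene = gene, log2_fc = lfc, ave_expr = 0,
                       t = lfc, p_value = fdr, fdr = fdr,
                       stringsAsFactors = FALSE),
            class = c("dge_result", "data.frame"), contrast = contrast)
}
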