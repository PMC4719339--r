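# Independent oracles used to cross-check the implementation. Each oracle
# deliberately takes a different computational route from the package code.

# textbook Pearson correlation: explicit sums, one probe at a time
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  if (den == 0) return(NA_real_)
  num / den
}

# eigenvalue share via the gene-by-gene covariance matrix (p x p route)
eigen_oracle_gene_space <- function(x) {
  xc <- x - rowMeans(x)
  cv <- tcrossprod(xc)            # gene x gene cross-product
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  100 * max(ev) / sum(ev)
}

# eigenvalue share via singular values
eigen_oracle_svd <- function(x) {
  xc <- x - rowMeans(x)
  d <- svd(xc, nu = 0, nv = 0)$d
  100 * d[1]^2 / sum(d^2)
}

# Mann-Whitney U via the rank-sum identity (midranks), two-sided exact p by
# explicit enumeration of group assignments
mw_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  idx_all <- utils::combn(n1 + n2, n1)
  devs <- apply(idx_all, 2, function(i) abs(u_of(i) - mu))
  list(U = u_obs, p = mean(devs >= abs(u_obs - mu) - 1e-9))
}

# upper hypergeometric tail by complete enumeration of draws (small N only)
hyper_enum_oracle <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2, function(d) sum(d <= K))
  mean(hits >= k)
}

# pooled-variance two-sample t from first principles
t_oracle <- function(x1, x0) {
  n1 <- length(x1); n0 <- length(x0)
  sp2 <- ((n1 - 1) * var(x1) + (n0 - 1) * var(x0)) / (n1 + n0 - 2)
  tt <- (mean(x1) - mean(x0)) / sqrt(sp2 * (1 / n1 + 1 / n0))
  list(t = tt, p = 2 * pt(-abs(tt), n1 + n0 - 2))
}

# Kruskal-Wallis permutation p: permute pooled ranks across fixed group
# sizes and recompute the rank-sum form of H (tie correction is constant
# under permutation, so comparing uncorrected H is exact)
kw_perm_oracle <- function(groups, n_perm = 1e4, seed = 1) {
  ns <- lengths(groups)
  values <- unlist(groups, use.names = FALSE)
  r <- rank(values)
  nn <- length(r)
  h_of <- function(rr) {
    ends <- cumsum(ns)
    starts <- c(1, head(ends, -1) + 1)
    rs <- mapply(function(s, e) sum(rr[s:e]), starts, ends)
    12 / (nn * (nn + 1)) * sum(rs^2 / ns) - 3 * (nn + 1)
  }
  h_obs <- h_of(r)
  set.seed(seed)
  h_null <- replicate(n_perm, h_of(sample(r)))
  mean(h_null >= h_obs - 1e-12)
}

# a tiny deterministic expression matrix with named dims
toy_expr <- function(values, probes, samples) {
  matrix(values, nrow = length(probes), ncol = length(samples),
         dimnames = list(probes, samples))
}
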