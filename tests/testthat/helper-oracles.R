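# Independent oracles: deliberately naive re-derivations used only to check
# the package's implementations. None of them share code with R/.

# upper-tail hypergeometric P(X >= q) by explicit enumeration of point masses
oracle_hyper_upper <- function(q, K, N, k) {
  xs <- seq(max(0L, q), min(K, k))
  if (q > min(K, k)) return(0)
  sum(vapply(xs, function(x) {
    choose(K, x) * choose(N - K, k - x)
  }, numeric(1))) / choose(N, k)
}

# quadratic-time BH step-up: adjusted_(i) = min_{j >= i} min(1, K p_(j) / j)
oracle_bh <- function(p) {
  K <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(K)
  for (i in seq_len(K)) {
    adj[i] <- min(1, min(K * ps[i:K] / (i:K)))
  }
  out <- numeric(K)
  out[o] <- adj
  out
}

# Kendall's W via the mean pairwise Spearman identity, valid without ties:
# W = ((m - 1) * mean_rho + 1) / m, an independent route to the rank-sum form
oracle_kendall_w_spearman <- function(pmat) {
  m <- ncol(pmat)
  ranks <- apply(pmat, 2, rank)
  rho <- stats::cor(ranks)
  ((m - 1) * mean(rho[upper.tri(rho)]) + 1) / m
}

# textbook tie-corrected Kruskal-Wallis H from joint ranks
oracle_kruskal_h <- function(groups) {
  vals <- unlist(groups, use.names = FALSE)
  N <- length(vals)
  r <- rank(vals)
  gid <- rep(seq_along(groups), lengths(groups))
  H <- 12 / (N * (N + 1)) *
    sum(vapply(split(r, gid), function(g) {
      length(g) * (mean(g) - (N + 1) / 2)^2
    }, numeric(1)))
  tt <- table(vals)
  C <- 1 - sum(tt^3 - tt) / (N^3 - N)
  H / C
}

# full running-sum walk for the GSEA enrichment score
oracle_gsea_es <- function(ranked_stats, members, p_exp = 1) {
  hit <- names(ranked_stats) %in% members
  w <- abs(ranked_stats)^p_exp
  NR <- sum(w[hit])
  Nh <- sum(hit)
  N <- length(ranked_stats)
  inc <- if (NR > 0) w / NR else rep(1 / Nh, N)
  step <- ifelse(hit, inc, -1 / (N - Nh))
  run <- cumsum(step)
  run[which(abs(run) >= max(abs(run)) - 1e-12)[1L]]
}

# literal ECDF walk for the per-sample ssGSEA score
oracle_ssgsea_score <- function(expr, members, tau) {
  N <- length(expr)
  ord <- order(expr, decreasing = TRUE)
  genes <- names(expr)[ord]
  rank_value <- N:1
  hit <- genes %in% members
  w_in <- rank_value^tau * hit
  p_in <- cumsum(w_in) / sum(w_in)
  p_out <- cumsum(!hit) / (N - sum(hit))
  sum(p_in - p_out)
}

# small labelled dataset from an explicit matrix
make_ds <- function(values, condition) {
  expression_dataset(as.matrix(values), condition)
}

# random dataset: iid normal noise around a baseline, no signal
random_null_ds <- function(n_genes, n_ctrl, n_case, seed, sd = 1) {
  set.seed(seed)
  v <- matrix(rnorm(n_genes * (n_ctrl + n_case), mean = 7, sd = sd),
              nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n_ctrl + n_case))))
  expression_dataset(v, rep(c("control", "case"), c(n_ctrl, n_case)))
}

# dataset where a chosen subset of genes is unambiguously differentially
# expressed (huge shift, tiny noise) and the rest is pure noise
de_spiked_ds <- function(n_genes, de_genes, n_per_group = 5, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  v <- matrix(rnorm(n_genes * n, 7, 0.3), nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%03d", seq_len(n))))
  cond <- rep(c("control", "case"), each = n_per_group)
  v[de_genes, cond == "case"] <- v[de_genes, cond == "case"] + 10
  expression_dataset(v, cond)
}
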