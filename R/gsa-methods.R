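# ---- result containers ------------------------------------------------------

#' Construct a GSA result vector
#'
#' Per-set p-values aligned to the gene set database order: the k-th entry
#' always refers to the k-th gene set. Raw p-values come from a method;
#' adjusted p-values are filled by [gsa_adjust()].
#'
#' @param method_name Registry name of the method.
#' @param set_names Set names in database order.
#' @param raw_p Raw p-values in [0,1], one per set.
#' @param adjusted_p BH-adjusted p-values (or NA before adjustment).
#' @param flagged Logical vector marking sets whose p was set to 1 by
#'   convention (no member present in the background, or a degenerate score).
#' @return Object of class \code{GSAResultVector}.
#' @export
gsa_result <- function(method_name, set_names, raw_p,
                       adjusted_p = rep(NA_real_, length(raw_p)),
                       flagged = rep(FALSE, length(raw_p))) {
  stopifnot(length(raw_p) == length(set_names),
            length(adjusted_p) == length(raw_p))
  if (any(raw_p < 0 | raw_p > 1, na.rm = TRUE)) stop("raw p-values outside [0,1]")
  structure(list(method_name = method_name,
                 set_names = as.character(set_names),
                 raw_p = as.numeric(raw_p),
                 adjusted_p = as.numeric(adjusted_p),
                 flagged = flagged),
            class = "GSAResultVector")
}

#' @export
print.GSAResultVector <- function(x, ...) {
  cat(sprintf("GSAResultVector [%s]: %d sets, %d with adjusted p < 0.05\n",
              x$method_name, length(x$raw_p),
              sum(x$adjusted_p < 0.05, na.rm = TRUE)))
  invisible(x)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin, validated wrapper around \code{stats::p.adjust(method = "BH")}; used
#' uniformly on every method's raw p-values so all methods are compared under
#' the same multiplicity control.
#'
#' @param raw_p Numeric vector of p-values in [0,1].
#' @return Adjusted p-values in input order.
#' @export
adjust_bh <- function(raw_p) {
  if (any(is.na(raw_p)) || any(raw_p < 0 | raw_p > 1)) {
    stop("p-values must lie in [0,1]")
  }
  stats::p.adjust(raw_p, method = "BH")
}

#' Fill a result vector's adjusted p-values
#'
#' @param result A \code{GSAResultVector} with raw p-values.
#' @return The result with \code{adjusted_p} populated via [adjust_bh()].
#' @export
gsa_adjust <- function(result) {
  stopifnot(inherits(result, "GSAResultVector"))
  result$adjusted_p <- adjust_bh(result$raw_p)
  result
}

#' Call differentially enriched gene sets
#'
#' A set is called significant when its adjusted p-value is strictly below
#' alpha.
#'
#' @param result A \code{GSAResultVector} with adjusted p-values.
#' @param alpha Significance level (default 0.05).
#' @return Object of class \code{EnrichedCall}: elements \code{significant}
#'   (character vector of set names) and \code{alpha}.
#' @export
call_enriched <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "GSAResultVector"))
  if (any(is.na(result$adjusted_p))) stop("adjusted p-values not populated; run gsa_adjust() first")
  structure(list(significant = result$set_names[result$adjusted_p < alpha],
                 alpha = alpha),
            class = "EnrichedCall")
}

.as_expr <- function(x) {
  if (inherits(x, "ReplicateDataset")) x$data
  else if (inherits(x, "ExpressionDataset")) x
  else stop("expected an ExpressionDataset or ReplicateDataset")
}

# ---- gene-level statistics --------------------------------------------------

#' Per-gene Welch two-sample statistics
#'
#' Welch's unequal-variance t statistic (case minus control), its two-sided
#' p-value, and the raw mean difference on the log2 scale, per gene. A gene
#' whose values are constant and equal in both groups gets t = 0, p = 1.
#'
#' @param x An \code{ExpressionDataset} or \code{ReplicateDataset} with at
#'   least 2 samples per group.
#' @return data.frame with columns \code{gene_id}, \code{t}, \code{p},
#'   \code{effect}.
#' @export
gene_level_stats <- function(x) {
  ds <- .as_expr(x)
  ctrl <- ds$values[, ds$condition == "control", drop = FALSE]
  case <- ds$values[, ds$condition == "case", drop = FALSE]
  if (ncol(ctrl) < 2L || ncol(case) < 2L) {
    stop("each group needs at least 2 samples (got ", ncol(ctrl),
         " control, ", ncol(case), " case)")
  }
  .welch_rows(case, ctrl)
}

# vectorized Welch t over matrix rows; a is the "case" side
.welch_rows <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  diff <- ma - mb
  t <- diff / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t), df)
  zero <- se2 == 0
  if (any(zero)) {
    t[zero] <- ifelse(diff[zero] == 0, 0, sign(diff[zero]) * Inf)
    p[zero] <- ifelse(diff[zero] == 0, 1, 0)
  }
  data.frame(gene_id = rownames(a), t = unname(t), p = unname(p),
             effect = unname(diff))
}

# two-sided two-sample Welch t-test p for per-sample scores, guarded against
# degenerate (constant) score vectors
.score_t_p <- function(case_scores, ctrl_scores) {
  if (stats::var(c(case_scores, ctrl_scores)) < 1e-24) return(1)
  if (stats::var(case_scores) + stats::var(ctrl_scores) < 1e-24) {
    return(if (abs(mean(case_scores) - mean(ctrl_scores)) < 1e-12) 1 else 0)
  }
  stats::t.test(case_scores, ctrl_scores)$p.value
}

# ---- ORA --------------------------------------------------------------------

#' Over-representation analysis (hypergeometric)
#'
#' Genes with BH-adjusted Welch p below \code{de_threshold} form the
#' differentially expressed (DE) list; the background is every gene in the
#' dataset. Each set's raw p is the upper-tail hypergeometric probability of
#' observing at least the achieved overlap between the DE list and the set's
#' members present in the background.
#'
#' @inheritParams gene_level_stats
#' @param db A \code{GeneSetDatabase}.
#' @param de_threshold Adjusted gene-level p cutoff defining the DE list
#'   (default 0.05).
#' @return \code{GSAResultVector} with raw p-values only.
#' @export
ora_analyze <- function(x, db, de_threshold = 0.05) {
  ds <- .as_expr(x)
  bg <- gene_ids(ds)
  if (length(bg) == 0L) stop("empty background")
  gls <- gene_level_stats(ds)
  de <- gls$gene_id[adjust_bh(gls$p) < de_threshold]
  N <- length(bg); k <- length(de)
  raw <- vapply(db$sets, function(mem) {
    K <- sum(mem %in% bg)
    if (K == 0L) return(1)
    q <- sum(mem %in% de)
    stats::phyper(q - 1L, K, N - K, k, lower.tail = FALSE)
  }, numeric(1))
  flagged <- vapply(db$sets, function(mem) sum(mem %in% bg) == 0L, logical(1))
  gsa_result("ora", set_names(db), unname(raw), flagged = unname(flagged))
}

# ---- PAGE -------------------------------------------------------------------

#' Parametric analysis of gene set enrichment (PAGE)
#'
#' Z-test on the set mean of per-gene effects (case minus control mean
#' difference): with mu and delta the mean and standard deviation of all
#' genes' effects, and Sm the mean effect over the set's m members present in
#' the background, Z = (Sm - mu) * sqrt(m) / delta with a two-sided normal
#' p-value.
#'
#' @inheritParams ora_analyze
#' @return \code{GSAResultVector} with raw p-values only.
#' @export
page_analyze <- function(x, db) {
  ds <- .as_expr(x)
  gls <- gene_level_stats(ds)
  eff <- stats::setNames(gls$effect, gls$gene_id)
  mu <- mean(eff)
  delta <- stats::sd(eff)
  if (!is.finite(delta) || delta == 0) stop("degenerate gene-level effects")
  raw <- numeric(n_sets(db)); flagged <- logical(n_sets(db))
  for (i in seq_len(n_sets(db))) {
    mem <- intersect(db$sets[[i]], names(eff))
    m <- length(mem)
    if (m == 0L) { raw[i] <- 1; flagged[i] <- TRUE; next }
    z <- (mean(eff[mem]) - mu) * sqrt(m) / delta
    raw[i] <- 2 * stats::pnorm(-abs(z))
  }
  gsa_result("page", set_names(db), raw, flagged = flagged)
}

# ---- PLAGE ------------------------------------------------------------------

#' Pathway-level analysis of gene expression (PLAGE)
#'
#' Each set's activity per sample is its metagene: the first right-singular
#' vector of the set's standardized (row mean 0, sd 1) member-by-sample
#' submatrix. The raw p is a two-sided two-sample t-test of metagene values,
#' case versus control; the metagene's arbitrary sign cannot affect it.
#' Member genes with zero variance contribute a zero row.
#'
#' @inheritParams ora_analyze
#' @return \code{GSAResultVector} with raw p-values only.
#' @export
plage_analyze <- function(x, db) {
  ds <- .as_expr(x)
  is_case <- ds$condition == "case"
  if (sum(is_case) < 2L || sum(!is_case) < 2L) stop("each group needs at least 2 samples")
  bg <- gene_ids(ds)
  raw <- numeric(n_sets(db)); flagged <- logical(n_sets(db))
  for (i in seq_len(n_sets(db))) {
    mem <- intersect(db$sets[[i]], bg)
    if (length(mem) == 0L) { raw[i] <- 1; flagged[i] <- TRUE; next }
    sub <- ds$values[mem, , drop = FALSE]
    mu <- rowMeans(sub)
    sdv <- apply(sub, 1L, stats::sd)
    z <- (sub - mu) / ifelse(sdv > 0, sdv, 1)
    z[sdv == 0, ] <- 0
    if (all(z == 0)) { raw[i] <- 1; flagged[i] <- TRUE; next }
    meta <- svd(z, nu = 0, nv = 1)$v[, 1L]
    raw[i] <- .score_t_p(meta[is_case], meta[!is_case])
  }
  gsa_result("plage", set_names(db), raw, flagged = flagged)
}

# ---- ssGSEA -----------------------------------------------------------------

# per-sample ssGSEA score in closed form: with rank values r = N..1 down the
# sorted list, the summed ECDF difference equals
#   sum_hit r^(tau+1) / sum_hit r^tau  -  sum_miss r / (N - k)
.ssgsea_sample_score <- function(rank_values_of_members, N, k, tau) {
  r <- rank_values_of_members
  sum(r^(tau + 1)) / sum(r^tau) - (N * (N + 1) / 2 - sum(r)) / (N - k)
}

#' Single-sample GSEA (ssGSEA)
#'
#' Per sample, genes are ranked by expression (descending; the top gene has
#' rank value N). A set's score in that sample is the summed difference
#' between the rank-weighted in-set cumulative (weights rank^tau,
#' normalized) and the uniform out-of-set cumulative, walked down the full
#' ranking. Per set, the raw p is a two-sided two-sample t-test of the
#' per-sample scores, case versus control.
#'
#' @inheritParams ora_analyze
#' @param tau Rank-weight exponent (default 0.25).
#' @return \code{GSAResultVector} with raw p-values only.
#' @export
ssgsea_analyze <- function(x, db, tau = 0.25) {
  ds <- .as_expr(x)
  is_case <- ds$condition == "case"
  if (sum(is_case) < 2L || sum(!is_case) < 2L) stop("each group needs at least 2 samples")
  bg <- gene_ids(ds)
  N <- length(bg)
  members <- lapply(db$sets, function(mem) which(bg %in% mem))
  if (any(lengths(members) == N)) {
    stop("a gene set covers the entire background; out-of-set ECDF undefined")
  }
  n_samp <- ncol(ds$values)
  scores <- matrix(0, n_sets(db), n_samp)
  for (s in seq_len(n_samp)) {
    ord <- order(ds$values[, s], decreasing = TRUE)
    rank_value <- integer(N)
    rank_value[ord] <- N:1
    for (i in seq_len(n_sets(db))) {
      rows <- members[[i]]
      if (length(rows) == 0L) next
      scores[i, s] <- .ssgsea_sample_score(rank_value[rows], N,
                                           length(rows), tau)
    }
  }
  raw <- numeric(n_sets(db)); flagged <- logical(n_sets(db))
  for (i in seq_len(n_sets(db))) {
    if (length(members[[i]]) == 0L) { raw[i] <- 1; flagged[i] <- TRUE; next }
    raw[i] <- .score_t_p(scores[i, is_case], scores[i, !is_case])
  }
  res <- gsa_result("ssgsea", set_names(db), raw, flagged = flagged)
  attr(res, "scores") <- scores
  res
}

# ---- GSEA enrichment score --------------------------------------------------

# ES from hit positions in a ranked list: the running sum is piecewise linear
# between hits, so its extremes sit immediately before or after a hit.
# w_all: |stat|^p_exp down the ranked list; hit_pos: sorted hit positions.
.gsea_es_core <- function(w_all, hit_pos, N) {
  k <- length(hit_pos)
  wh <- w_all[hit_pos]
  NR <- sum(wh)
  H <- if (NR > 0) cumsum(wh) / NR else seq_len(k) / k
  miss_step <- (hit_pos - seq_len(k)) / (N - k)
  before <- c(0, H[-k]) - miss_step
  after <- H - miss_step
  cand <- as.numeric(rbind(before, after))  # interleaved, in list order
  # signed maximum deviation; on a (near-)exact magnitude tie the earliest
  # position in the ranked list wins, robust to floating-point noise
  cand[which(abs(cand) >= max(abs(cand)) - 1e-12)[1L]]
}

#' GSEA enrichment score
#'
#' Weighted Kolmogorov-Smirnov-like running sum over a ranked gene list:
#' member hits add |stat|^p_exp normalized by the total hit weight, misses
#' subtract 1/(N - N_hits); the enrichment score is the signed maximum
#' deviation from zero.
#'
#' @param ranked_stats Named numeric vector of per-gene ranking statistics,
#'   sorted in the ranking order (descending).
#' @param members Character vector of member gene ids; must intersect the
#'   ranked genes and must not cover all of them.
#' @param p_exp Weight exponent (default 1; 0 gives the unweighted
#'   Kolmogorov-Smirnov form).
#' @return The enrichment score, a single number in [-1, 1].
#' @export
gsea_es <- function(ranked_stats, members, p_exp = 1) {
  genes <- names(ranked_stats)
  if (is.null(genes)) stop("ranked_stats must be named by gene id")
  hit <- genes %in% members
  if (!any(hit)) stop("no member of the set appears in the ranked list")
  if (all(hit)) stop("gene set covers the entire ranked list")
  .gsea_es_core(abs(ranked_stats)^p_exp, which(hit), length(genes))
}

.ranked_stats <- function(gls) {
  ord <- order(gls$t, decreasing = TRUE)  # stable: ties keep input gene order
  stats::setNames(gls$t[ord], gls$gene_id[ord])
}

# ---- GSEA, gene-permutation null --------------------------------------------

#' GSEA with gene-permutation null (GSEA-G)
#'
#' Genes are ranked by the Welch t statistic; each set's observed enrichment
#' score is compared with the scores of random same-size gene subsets. The
#' raw p uses the add-one estimator
#' \eqn{(1 + \#\{|ES_{null}| \ge |ES_{obs}|\}) / (1 + n_{perm})}, so it is
#' never zero. Permutations are shared across sets of equal size.
#'
#' @inheritParams ora_analyze
#' @param n_perm Number of random gene subsets per set size (default 1000).
#' @param seed Integer seed for the permutation draws.
#' @param p_exp Hit-weight exponent passed to the enrichment score.
#' @return \code{GSAResultVector} with raw p-values only.
#' @export
gsea_gene_perm_analyze <- function(x, db, n_perm = 1000L, seed = 1L, p_exp = 1) {
  ds <- .as_expr(x)
  gls <- gene_level_stats(ds)
  ranked <- .ranked_stats(gls)
  w <- abs(ranked)^p_exp
  N <- length(ranked)
  pos_of <- stats::setNames(seq_len(N), names(ranked))
  sizes <- vapply(db$sets, function(mem) sum(mem %in% names(ranked)), integer(1))
  if (any(sizes == N)) stop("a gene set covers the entire ranked list")
  obs <- rep(NA_real_, n_sets(db))
  for (i in seq_len(n_sets(db))) {
    if (sizes[i] == 0L) next
    hp <- sort(unname(pos_of[intersect(db$sets[[i]], names(ranked))]))
    obs[i] <- .gsea_es_core(w, hp, N)
  }
  set.seed(seed)
  null_by_size <- list()
  for (k in sort(unique(sizes[sizes > 0L]))) {
    null_by_size[[as.character(k)]] <- vapply(seq_len(n_perm), function(j) {
      .gsea_es_core(w, sort(sample.int(N, k)), N)
    }, numeric(1))
  }
  raw <- numeric(n_sets(db)); flagged <- sizes == 0L
  for (i in seq_len(n_sets(db))) {
    if (flagged[i]) { raw[i] <- 1; next }
    nulls <- null_by_size[[as.character(sizes[i])]]
    raw[i] <- (1 + sum(abs(nulls) >= abs(obs[i]))) / (1 + n_perm)
  }
  res <- gsa_result("gsea_g", set_names(db), raw, flagged = unname(flagged))
  attr(res, "es") <- obs
  res
}

# ---- GSEA, sample-permutation null ------------------------------------------

#' Enumerate balanced relabellings of a 2n-sample replicate
#'
#' All ways of choosing n of the 2n samples as pseudo-controls; there are
#' C(2n, n) of them, and the identity labelling is one. With n = 3 this
#' yields the 20 distinct permutations that bound the sample-permutation
#' p-value away from anything below 1/20.
#'
#' @param n Samples per group.
#' @return Integer matrix, one column per relabelling, rows the chosen
#'   pseudo-control positions in 1..2n.
#' @export
balanced_relabellings <- function(n) {
  stopifnot(n >= 1)
  utils::combn(2L * n, n)
}

#' GSEA with sample-permutation null (GSEA-S)
#'
#' The gene ranking is recomputed under permuted group labels (balanced
#' relabellings choosing n of the 2n samples as pseudo-controls). When the
#' number of relabellings C(2n, n) does not exceed \code{exhaustive_cap} and
#' mode is \code{"exhaustive_if_small"}, all of them are enumerated and the
#' identity labelling is part of the null, so the smallest attainable p is
#' 1/C(2n, n) — 0.05 at n = 3, which is why this method cannot call anything
#' significant at very small sample sizes. Otherwise a Monte Carlo null of
#' \code{n_perm} random relabellings with the add-one estimator is used.
#'
#' @inheritParams gsea_gene_perm_analyze
#' @param mode \code{"exhaustive_if_small"} (default) or
#'   \code{"monte_carlo"}.
#' @param exhaustive_cap Largest permutation count enumerated exhaustively
#'   (default 5000).
#' @return \code{GSAResultVector} with raw p-values only; attribute
#'   \code{n_permutations} records the null size used.
#' @export
gsea_sample_perm_analyze <- function(x, db, n_perm = 1000L,
                                     mode = c("exhaustive_if_small", "monte_carlo"),
                                     seed = 1L, exhaustive_cap = 5000L,
                                     p_exp = 1) {
  mode <- match.arg(mode)
  ds <- .as_expr(x)
  nc <- n_control(ds); nt <- n_case(ds)
  if (nc != nt) stop("sample permutation requires a balanced replicate")
  n <- nc
  if (n < 2L) stop("need at least 2 samples per group")
  V <- ds$values
  bg <- gene_ids(ds)
  N <- length(bg)
  members <- lapply(db$sets, function(mem) which(bg %in% mem))
  if (any(lengths(members) == N)) stop("a gene set covers the entire ranked list")

  es_under <- function(ctrl_cols) {
    case_cols <- setdiff(seq_len(2L * n), ctrl_cols)
    gls <- .welch_rows(V[, case_cols, drop = FALSE], V[, ctrl_cols, drop = FALSE])
    ord <- order(gls$t, decreasing = TRUE)
    pos <- integer(N); pos[ord] <- seq_len(N)
    w <- abs(gls$t[ord])^p_exp
    vapply(members, function(rows) {
      if (length(rows) == 0L) return(NA_real_)
      .gsea_es_core(w, sort(pos[rows]), N)
    }, numeric(1))
  }

  identity_ctrl <- which(ds$condition == "control")
  obs <- es_under(identity_ctrl)

  total <- choose(2L * n, n)
  exhaustive <- mode == "exhaustive_if_small" && total <= exhaustive_cap
  if (exhaustive) {
    perms <- balanced_relabellings(n)
    null_es <- matrix(apply(perms, 2L, es_under), nrow = n_sets(db))
    ge <- rowSums(abs(null_es) >= abs(obs), na.rm = FALSE)
    raw <- ge / ncol(perms)
    n_null <- ncol(perms)
  } else {
    set.seed(seed)
    null_es <- vapply(seq_len(n_perm), function(j) {
      es_under(sample.int(2L * n, n))
    }, numeric(n_sets(db)))
    null_es <- matrix(null_es, nrow = n_sets(db))
    ge <- rowSums(abs(null_es) >= abs(obs))
    raw <- (1 + ge) / (1 + n_perm)
    n_null <- n_perm
  }
  flagged <- lengths(members) == 0L
  raw[flagged] <- 1
  res <- gsa_result("gsea_s", set_names(db), raw, flagged = unname(flagged))
  attr(res, "n_permutations") <- n_null
  attr(res, "exhaustive") <- exhaustive
  attr(res, "es") <- obs
  res
}

# ---- method registry --------------------------------------------------------

.gsa_registry <- new.env(parent = emptyenv())

#' Register a GSA method
#'
#' A method is a function \code{(x, db, ...) -> GSAResultVector} returning
#' raw p-values aligned to the database order; the framework applies the same
#' BH adjustment and alpha call to every method.
#'
#' @param name Registry key.
#' @param fun Method function.
#' @export
register_gsa_method <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(name, fun, envir = .gsa_registry)
  invisible(name)
}

#' @rdname register_gsa_method
#' @export
gsa_methods_available <- function() sort(ls(.gsa_registry))

#' Run one registered GSA method end-to-end
#'
#' Applies the method, BH-adjusts its raw p-values, and calls enrichment at
#' alpha, so every method passes through the identical significance pipeline.
#'
#' @inheritParams ora_analyze
#' @param method Registry name (see [gsa_methods_available()]).
#' @param alpha Significance level for the call (default 0.05).
#' @param ... Passed to the method function.
#' @return List with elements \code{result} (adjusted
#'   \code{GSAResultVector}) and \code{call} (\code{EnrichedCall}).
#' @export
run_gsa <- function(x, db, method, alpha = 0.05, ...) {
  if (!exists(method, envir = .gsa_registry, inherits = FALSE)) {
    stop("unknown GSA method '", method, "'; available: ",
         paste(gsa_methods_available(), collapse = ", "))
  }
  fun <- get(method, envir = .gsa_registry, inherits = FALSE)
  res <- gsa_adjust(fun(x, db, ...))
  list(result = res, call = call_enriched(res, alpha))
}

#' Wrap an external executable as a GSA method
#'
#' Plugin contract for methods not built in: the executable is invoked as
#' \code{command <expression.tsv> <sets.gmt> <out.tsv>}, where the expression
#' file carries an in-file condition line, and must write a two-column TSV
#' (\code{set_name}, \code{raw_p}) with a header. Sets the executable omits
#' get raw p = 1 (flagged). Register the returned function with
#' [register_gsa_method()] to use it in sweeps; its output is BH-adjusted
#' exactly like the built-ins.
#'
#' @param command Path to the executable.
#' @param method_name Name recorded in the result vectors.
#' @return A method function \code{(x, db, ...) -> GSAResultVector}.
#' @export
make_external_gsa_method <- function(command, method_name = basename(command)) {
  force(command); force(method_name)
  function(x, db, ...) {
    ds <- .as_expr(x)
    dir <- tempfile("gsa_ext_")
    dir.create(dir)
    on.exit(unlink(dir, recursive = TRUE))
    expr_path <- file.path(dir, "expression.tsv")
    gmt_path <- file.path(dir, "sets.gmt")
    out_path <- file.path(dir, "result.tsv")
    write_expression(ds, expr_path)
    write_gmt(db, gmt_path)
    status <- system2(command, c(expr_path, gmt_path, out_path))
    if (status != 0) stop("external GSA method '", method_name,
                          "' exited with status ", status)
    tab <- utils::read.delim(out_path, header = TRUE)
    p <- stats::setNames(as.numeric(tab$raw_p), tab$set_name)
    raw <- p[set_names(db)]
    flagged <- is.na(raw)
    raw[flagged] <- 1
    gsa_result(method_name, set_names(db), unname(raw),
               flagged = unname(flagged))
  }
}

# built-ins: spec'd registry keys
register_gsa_method("ora", ora_analyze)
register_gsa_method("page", page_analyze)
register_gsa_method("plage", plage_analyze)
register_gsa_method("ssgsea", ssgsea_analyze)
register_gsa_method("gsea_g", gsea_gene_perm_analyze)
register_gsa_method("gsea_s", gsea_sample_perm_analyze)
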