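# ---- Jaccard overlap --------------------------------------------------------

#' Jaccard overlap score between two significant-set calls
#'
#' |A n B| / |A u B|; 0 is no agreement, 1 complete agreement. The 0/0 case
#' (both calls empty) is undefined in the raw formula and is scored as
#' \code{empty_value}, default 0: a method that reports nothing has
#' demonstrated no reproducible finding, so all-empty replicate pairs count
#' as no agreement — this keeps methods that are powerless at small sample
#' sizes from appearing maximally reproducible there. Set
#' \code{empty_value = 1} to treat two empty reports as complete agreement
#' instead; the convention's influence is auditable by counting empty calls.
#'
#' @param a,b Character vectors (or \code{EnrichedCall}s) of significant set
#'   names.
#' @param empty_value Score assigned when both calls are empty (default 0).
#' @return A number in [0, 1]; symmetric in its arguments.
#' @export
jaccard_overlap <- function(a, b, empty_value = 0) {
  if (inherits(a, "EnrichedCall")) a <- a$significant
  if (inherits(b, "EnrichedCall")) b <- b$significant
  u <- length(union(a, b))
  if (u == 0L) return(empty_value)
  length(intersect(a, b)) / u
}

# ---- overlap matrices and multisets -----------------------------------------

#' Build the pairwise overlap matrix for m same-size replicates
#'
#' Upper-triangular m x m matrix: entry (i, j), i < j, is the Jaccard
#' overlap between the significant calls of replicates i and j; the diagonal
#' is fixed at 1 as a visual reference; the lower triangle is NA. Symmetry
#' means only m(m-1)/2 scores are computed.
#'
#' @param calls List of m \code{EnrichedCall}s (same method, same size).
#' @param method_name,n Optional provenance recorded as attributes.
#' @return Object of class \code{OverlapMatrix} (a numeric matrix with
#'   attributes \code{method} and \code{n}).
#' @export
build_overlap_matrix <- function(calls, method_name = NULL, n = NULL) {
  m <- length(calls)
  if (m < 2L) stop("need at least 2 replicate calls, got ", m)
  sig <- lapply(calls, function(cl) if (inherits(cl, "EnrichedCall")) cl$significant else cl)
  mat <- matrix(NA_real_, m, m)
  diag(mat) <- 1
  for (i in seq_len(m - 1L)) {
    for (j in seq(i + 1L, m)) {
      mat[i, j] <- jaccard_overlap(sig[[i]], sig[[j]])
    }
  }
  structure(mat, method = method_name, n = n, class = c("OverlapMatrix", "matrix"))
}

#' Pairwise overlap multiset (all upper-triangle scores)
#'
#' Flattens the strict upper triangle of the overlap matrix into a multiset
#' of m(m-1)/2 scores, repetition preserved.
#'
#' @inheritParams build_overlap_matrix
#' @return Object of class \code{OverlapMultiset} with \code{kind =
#'   "pairwise"}: a numeric vector with provenance attributes.
#' @export
pairwise_overlap_multiset <- function(calls, method_name = NULL, n = NULL) {
  mat <- build_overlap_matrix(calls, method_name, n)
  vals <- t(mat)[lower.tri(mat)]   # upper triangle in row-major (i, j) order
  structure(vals, method = method_name, n = n, kind = "pairwise",
            class = "OverlapMultiset")
}

#' Replicate-versus-whole overlap multiset
#'
#' The m overlaps between each replicate's significant call and the call
#' obtained by the same method on the full original dataset; high values
#' suggest the smaller size already reproduces the whole-dataset result.
#'
#' @inheritParams build_overlap_matrix
#' @param whole_call \code{EnrichedCall} from the same method on the full
#'   dataset.
#' @return Object of class \code{OverlapMultiset} with \code{kind =
#'   "vs_whole"}: a numeric vector of length m.
#' @export
vs_whole_overlap_multiset <- function(calls, whole_call, method_name = NULL, n = NULL) {
  vals <- vapply(calls, jaccard_overlap, numeric(1), b = whole_call)
  structure(vals, method = method_name, n = n, kind = "vs_whole",
            class = "OverlapMultiset")
}

#' @export
print.OverlapMultiset <- function(x, ...) {
  cat(sprintf("OverlapMultiset [%s%s]: %d scores, mean %.3f\n",
              attr(x, "kind"),
              if (!is.null(attr(x, "n"))) paste0(", 2x", attr(x, "n")) else "",
              length(x), mean(unclass(x))))
  invisible(x)
}

# ---- Kendall's coefficient of concordance -----------------------------------

#' Kendall's W over replicate rankings of significant gene sets
#'
#' Measures agreement in the \emph{order} of gene sets across the m
#' replicates: the item universe U is the union of sets called significant
#' in at least one replicate; every replicate then ranks all of U by its
#' adjusted p-values (ascending, mid-ranks for ties — every set always has
#' an adjusted p, so no imputation is needed). W uses the tie-corrected
#' formula \eqn{W = 12 S / (m^2 (k^3 - k) - m \sum T)} with S the sum of
#' squared deviations of the per-item rank sums from their mean, k = |U|,
#' and T the usual per-replicate tie correction \eqn{\sum (t^3 - t)}.
#'
#' @param results List of m \code{GSAResultVector}s with adjusted p-values.
#' @param calls Matching list of m \code{EnrichedCall}s.
#' @return Object of class \code{ConcordanceResult}: \code{W} in [0,1] (NA
#'   with \code{defined = FALSE} when |U| < 2), \code{n_items = |U|},
#'   provenance fields.
#' @export
kendalls_w <- function(results, calls) {
  m <- length(results)
  stopifnot(m >= 2L, length(calls) == m)
  U <- sort(unique(unlist(lapply(calls, function(cl) cl$significant))))
  method <- results[[1L]]$method_name
  if (length(U) < 2L) {
    return(structure(list(method_name = method, W = NA_real_,
                          n_items = length(U), defined = FALSE),
                     class = "ConcordanceResult"))
  }
  k <- length(U)
  ranks <- vapply(results, function(res) {
    p <- stats::setNames(res$adjusted_p, res$set_names)[U]
    rank(p, ties.method = "average")
  }, numeric(k))                      # k x m
  R <- rowSums(ranks)
  S <- sum((R - mean(R))^2)
  Tsum <- sum(apply(ranks, 2L, function(r) {
    t <- table(r)
    sum(t^3 - t)
  }))
  denom <- m^2 * (k^3 - k) - m * Tsum
  W <- if (denom <= 0) NA_real_ else 12 * S / denom
  structure(list(method_name = method, W = W, n_items = k,
                 defined = is.finite(W)),
            class = "ConcordanceResult")
}

#' @export
print.ConcordanceResult <- function(x, ...) {
  cat(sprintf("Kendall's W [%s]: %s over %d gene sets\n", x$method_name,
              if (x$defined) sprintf("%.3f", x$W) else "undefined", x$n_items))
  invisible(x)
}

# ---- Kruskal-Wallis across sample sizes -------------------------------------

#' Kruskal-Wallis test of overlap scores across sample sizes
#'
#' Tests whether the pairwise overlap multisets of one method differ across
#' sample sizes, via the tie-corrected Kruskal-Wallis H with a chi-square
#' p-value on (#groups - 1) degrees of freedom. If every score is identical
#' in all groups the statistic is degenerate and reported as H = 0, p = 1.
#'
#' @param multisets Named list (one element per sample size) of numeric
#'   overlap-score vectors.
#' @return List with \code{H}, \code{p}, \code{df}, and \code{degenerate}.
#' @export
kruskal_wallis_across_sizes <- function(multisets) {
  stopifnot(length(multisets) >= 2L, all(lengths(multisets) > 0L))
  values <- unlist(lapply(multisets, as.numeric), use.names = FALSE)
  groups <- factor(rep(seq_along(multisets), lengths(multisets)))
  if (length(unique(values)) == 1L) {
    return(list(H = 0, p = 1, df = length(multisets) - 1L, degenerate = TRUE))
  }
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter), degenerate = FALSE)
}

# ---- specificity / count summaries ------------------------------------------

.mean_count_summary <- function(calls_by_n, method_name) {
  stopifnot(length(calls_by_n) >= 1L)
  n_vals <- as.integer(names(calls_by_n))
  if (anyNA(n_vals)) stop("calls_by_n must be named by the per-group size n")
  means <- vapply(calls_by_n, function(calls) {
    mean(vapply(calls, function(cl) length(cl$significant), numeric(1)))
  }, numeric(1))
  data.frame(method = method_name, n = n_vals, mean_count = unname(means))
}

#' False-positive summary of a control-control experiment
#'
#' In control-control replicates there is no genuine signal, so every
#' significant call is a false positive; this reports the mean count of
#' significant gene sets per sample size.
#'
#' @param calls_by_n Named list (name = n) of lists of \code{EnrichedCall}s
#'   from control-control replicates.
#' @param method_name Method label for the output.
#' @return data.frame with columns \code{method}, \code{n},
#'   \code{mean_count}; class \code{SpecificitySummary}.
#' @export
false_positive_summary <- function(calls_by_n, method_name = "") {
  out <- .mean_count_summary(calls_by_n, method_name)
  class(out) <- c("SpecificitySummary", class(out))
  out
}

#' Mean enriched-set count of a case-control experiment
#'
#' Same arithmetic as [false_positive_summary()] applied to case-control
#' replicates: the mean number of gene sets called differentially enriched
#' per sample size, bounded above by the database size.
#'
#' @inheritParams false_positive_summary
#' @return data.frame with columns \code{method}, \code{n},
#'   \code{mean_count}.
#' @export
enriched_count_summary <- function(calls_by_n, method_name = "") {
  .mean_count_summary(calls_by_n, method_name)
}
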