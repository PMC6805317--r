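# Deterministic per-replicate seed: a small multiplicative-congruential mix of
# (root_seed, mode, n, replicate index). Stable, so adding sample sizes or
# replicates never perturbs earlier draws; always in [1, 2^31 - 2].
derive_seed <- function(root_seed, mode, n, index) {
  mode_code <- match(mode, c("case_control", "control_control"))
  if (is.na(mode_code)) stop("unknown mode: ", mode)
  x <- as.double(root_seed) %% 2147483647
  for (v in c(mode_code, n, index)) {
    x <- (x * 48271 + v * 9973 + 12345) %% 2147483647
  }
  as.integer(x) + 1L
}

.replicate_dataset <- function(parent, n, mode, ctrl_idx, case_idx, seed) {
  sids <- sample_ids(parent)
  sel <- c(ctrl_idx, case_idx)
  vals <- parent$values[, sel, drop = FALSE]
  # replicate-local labels; in control-control mode these are pseudo-labels
  cond <- rep(c("control", "case"), c(n, n))
  # disambiguate column names when the same parent sample could recur across
  # replicates; within one replicate indices are unique so names stay unique
  colnames(vals) <- sids[sel]
  structure(list(parent_id = attr(parent, "dataset_id") %||% "parent",
                 n = as.integer(n), mode = mode,
                 control_indices = as.integer(ctrl_idx),
                 case_indices = as.integer(case_idx),
                 seed = as.integer(seed),
                 data = expression_dataset(vals, cond)),
            class = "ReplicateDataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ReplicateDataset <- function(x, ...) {
  cat(sprintf("ReplicateDataset: 2 x %d (%s mode, seed %d)\n",
              x$n, x$mode, x$seed))
  invisible(x)
}

#' Draw one balanced case-control replicate dataset
#'
#' Randomly selects n of the parent's controls and n of its cases, each
#' without replacement, producing a balanced 2 x n dataset whose labels are
#' the parent labels of the chosen samples. Requires n strictly below both
#' group sizes.
#'
#' @param parent An \code{ExpressionDataset} with both conditions present.
#' @param n Samples per group.
#' @param seed Integer seed making the draw reproducible.
#' @return A \code{ReplicateDataset}: parent sample positions per group,
#'   the seed, and the materialized \code{ExpressionDataset}.
#' @export
draw_case_control_replicate <- function(parent, n, seed) {
  stopifnot(inherits(parent, "ExpressionDataset"))
  nc <- n_control(parent); nt <- n_case(parent)
  if (n >= nc) stop("n = ", n, " must be < n_C = ", nc)
  if (n >= nt) stop("n = ", n, " must be < n_T = ", nt)
  set.seed(seed)
  ctrl_pool <- which(parent$condition == "control")
  case_pool <- which(parent$condition == "case")
  ctrl_idx <- sort(sample(ctrl_pool, n))
  case_idx <- sort(sample(case_pool, n))
  .replicate_dataset(parent, n, "case_control", ctrl_idx, case_idx, seed)
}

#' Draw one control-control (null) replicate dataset
#'
#' Selects 2n distinct parent \emph{controls} without replacement; the first
#' n are relabelled control and the remaining n case. Because both pseudo
#' groups are genuine controls, any gene set later called significant is a
#' false positive. Requires n < n_C / 2.
#'
#' @inheritParams draw_case_control_replicate
#' @return A \code{ReplicateDataset} with pseudo-labels.
#' @export
draw_control_control_replicate <- function(parent, n, seed) {
  stopifnot(inherits(parent, "ExpressionDataset"))
  nc <- n_control(parent)
  if (n >= nc / 2) stop("n = ", n, " must be < n_C/2 = ", nc / 2)
  set.seed(seed)
  ctrl_pool <- which(parent$condition == "control")
  sel <- sample(ctrl_pool, 2L * n)
  .replicate_dataset(parent, n, "control_control",
                     sel[seq_len(n)], sel[n + seq_len(n)], seed)
}

#' Generate a series of m replicate datasets of one size
#'
#' Repeats the draw m times with per-replicate seeds derived
#' deterministically from \code{root_seed}; a parent sample may appear in
#' several replicates but never twice within one. Replicates are not forced
#' to be mutually distinct (collisions are detectable from the recorded
#' indices and seeds).
#'
#' @inheritParams draw_case_control_replicate
#' @param m Number of replicates (>= 1).
#' @param mode \code{"case_control"} or \code{"control_control"}.
#' @param root_seed Integer root seed for the series.
#' @return List of m \code{ReplicateDataset} objects.
#' @export
generate_replicate_series <- function(parent, n, m, mode = c("case_control", "control_control"),
                                      root_seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(m >= 1)
  draw <- switch(mode,
                 case_control = draw_case_control_replicate,
                 control_control = draw_control_control_replicate)
  lapply(seq_len(m), function(i) {
    draw(parent, n, derive_seed(root_seed, mode, n, i))
  })
}

#' Write a replicate-series manifest as TSV
#'
#' One row per replicate: index, n, mode, seed, and the comma-joined parent
#' sample ids of each group, enough to reconstruct every draw exactly.
#'
#' @param reps List of \code{ReplicateDataset} (one series).
#' @param parent The parent \code{ExpressionDataset}.
#' @param path Output path.
#' @export
write_replicate_manifest <- function(reps, parent, path) {
  sids <- sample_ids(parent)
  df <- data.frame(
    replicate_index = seq_along(reps),
    n = vapply(reps, `[[`, integer(1), "n"),
    mode = vapply(reps, `[[`, character(1), "mode"),
    seed = vapply(reps, `[[`, integer(1), "seed"),
    control_samples = vapply(reps, function(r)
      paste(sids[r$control_indices], collapse = ","), character(1)),
    case_samples = vapply(reps, function(r)
      paste(sids[r$case_indices], collapse = ","), character(1)))
  .write_tsv(df, path)
}
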