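#' Construct an expression dataset
#'
#' The core container of the package: a genes x samples matrix of normalized
#' log2-scale intensities together with a two-level condition label
#' (\code{"control"} / \code{"case"}) per sample. Downstream code refers to the
#' number of controls as \code{n_C} and the number of cases as \code{n_T}.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Rownames
#'   are gene identifiers, colnames are sample identifiers; both must be
#'   unique and non-empty.
#' @param condition Character or factor vector of length \code{ncol(values)}
#'   with values in \code{c("control", "case")}. If named, names must match
#'   the sample ids (order is taken from the matrix).
#' @return An object of class \code{ExpressionDataset}: a list with elements
#'   \code{values} (the matrix) and \code{condition} (a factor with levels
#'   \code{control}, \code{case} named by sample id).
#' @export
expression_dataset <- function(values, condition) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || any(gid == "")) stop("values must have gene ids as rownames")
  if (is.null(sid) || any(sid == "")) stop("values must have sample ids as colnames")
  if (anyDuplicated(gid)) {
    stop("duplicate gene id: ", gid[duplicated(gid)][1L])
  }
  if (anyDuplicated(sid)) {
    stop("duplicate sample id: ", sid[duplicated(sid)][1L])
  }
  if (length(condition) != ncol(values)) {
    stop("condition must have one label per sample")
  }
  if (!is.null(names(condition))) {
    if (!setequal(names(condition), sid)) {
      missing <- setdiff(sid, names(condition))
      stop("no condition label for sample(s): ", paste(missing, collapse = ", "))
    }
    condition <- condition[sid]
  }
  condition <- as.character(condition)
  bad <- setdiff(unique(condition), c("control", "case"))
  if (length(bad)) {
    stop("condition labels must be 'control' or 'case'; found: ",
         paste(bad, collapse = ", "))
  }
  condition <- factor(condition, levels = c("control", "case"))
  names(condition) <- sid
  structure(list(values = values, condition = condition),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d genes x %d samples (%d control, %d case)\n",
              nrow(x$values), ncol(x$values), n_control(x), n_case(x)))
  invisible(x)
}

#' @rdname expression_dataset
#' @param x An \code{ExpressionDataset}.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname expression_dataset
#' @export
sample_ids <- function(x) colnames(x$values)

#' @rdname expression_dataset
#' @export
n_control <- function(x) sum(x$condition == "control")

#' @rdname expression_dataset
#' @export
n_case <- function(x) sum(x$condition == "case")

#' Construct a gene set database
#'
#' An ordered collection of named gene sets. Order matters: the k-th entry
#' defines "the k-th gene set" and fixes the position of every method's
#' p-value vector.
#'
#' @param sets Named list of character vectors (member gene ids). Names must
#'   be unique, members non-empty; duplicate members within a set are
#'   silently de-duplicated.
#' @return Object of class \code{GeneSetDatabase}, a list with element
#'   \code{sets}.
#' @export
gene_set_database <- function(sets) {
  if (!is.list(sets)) stop("sets must be a list of character vectors")
  nm <- names(sets)
  if (length(sets) > 0 && (is.null(nm) || any(nm == ""))) {
    stop("every gene set must be named")
  }
  if (anyDuplicated(nm)) {
    stop("duplicate set name: ", nm[duplicated(nm)][1L])
  }
  sets <- lapply(sets, function(m) unique(as.character(m)))
  if (any(lengths(sets) == 0)) {
    stop("empty gene set: ", nm[lengths(sets) == 0][1L])
  }
  structure(list(sets = sets), class = "GeneSetDatabase")
}

#' @export
print.GeneSetDatabase <- function(x, ...) {
  cat(sprintf("GeneSetDatabase: %d sets (median size %s)\n", length(x$sets),
              if (length(x$sets)) stats::median(lengths(x$sets)) else NA))
  invisible(x)
}

#' @rdname gene_set_database
#' @param x A \code{GeneSetDatabase}.
#' @export
set_names <- function(x) names(x$sets)

#' @rdname gene_set_database
#' @export
n_sets <- function(x) length(x$sets)

#' Filter a gene set database by set size
#'
#' Optional size filter; no filtering is applied anywhere by default because
#' published tools disagree on their default size windows.
#'
#' @param db A \code{GeneSetDatabase}.
#' @param min_size,max_size Inclusive bounds on member count.
#' @return A filtered \code{GeneSetDatabase} (order preserved).
#' @export
filter_gene_sets <- function(db, min_size = 1L, max_size = Inf) {
  keep <- lengths(db$sets) >= min_size & lengths(db$sets) <= max_size
  gene_set_database(db$sets[keep])
}

#' Construct a probe-level expression table
#'
#' Holds probe-level intensities plus a (possibly many-to-one) probe-to-gene
#' map; probes absent from the map are treated as unannotated.
#'
#' @param values Numeric matrix, probes in rows (unique rownames), samples in
#'   columns.
#' @param probe_to_gene Named character vector mapping probe id to gene id.
#'   Every name must be a probe id of \code{values}.
#' @return Object of class \code{ProbeTable}.
#' @export
probe_table <- function(values, probe_to_gene) {
  values <- as.matrix(values)
  pid <- rownames(values)
  if (is.null(pid) || anyDuplicated(pid)) stop("values must have unique probe ids as rownames")
  if (length(probe_to_gene)) {
    if (is.null(names(probe_to_gene)) || any(names(probe_to_gene) == "")) {
      stop("probe_to_gene must be named by probe id")
    }
    unknown <- setdiff(names(probe_to_gene), pid)
    if (length(unknown)) stop("probe_to_gene refers to unknown probe(s): ",
                              paste(unknown, collapse = ", "))
  }
  ptg <- stats::setNames(as.character(probe_to_gene), names(probe_to_gene))
  structure(list(values = values, probe_to_gene = ptg), class = "ProbeTable")
}

#' Collapse probes to genes by the max-mean rule
#'
#' When several probes map to one gene, retain the probe whose mean intensity
#' across all samples is maximal; ties go to the probe that appears first in
#' the input. Unmapped probes are dropped.
#'
#' @param probes A \code{ProbeTable}.
#' @return Numeric matrix with one row per distinct mapped gene (rownames are
#'   gene ids), columns as in the input. Row order follows first appearance
#'   of each gene in the probe table.
#' @export
collapse_probes_maxmean <- function(probes) {
  stopifnot(inherits(probes, "ProbeTable"))
  map <- probes$probe_to_gene
  if (length(map) == 0) stop("no mapped probes")
  mapped <- names(map)
  vals <- probes$values[mapped, , drop = FALSE]
  means <- rowMeans(vals)
  genes <- unique(unname(map))
  pick <- vapply(genes, function(g) {
    idx <- which(map == g)
    # which.max returns the first maximum, giving the input-order tie-break
    idx[which.max(means[idx])]
  }, integer(1))
  out <- vals[pick, , drop = FALSE]
  rownames(out) <- genes
  out
}
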