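#' Read a tab-separated expression matrix
#'
#' Expected layout: header row \code{gene_id<TAB>sample1<TAB>sample2...},
#' optionally followed by a second header line whose first field is
#' \code{condition} carrying the per-sample labels, then one gene per row.
#' Values must be numeric (normalized, log2 scale; no normalization is
#' performed here).
#'
#' @param path Path to the TSV file.
#' @param label_spec Per-sample condition labels, one of: a named character
#'   vector (names = sample ids, values in control/case); a two-column
#'   data.frame \code{(sample_id, condition)}; a path to a two-column TSV of
#'   the same shape; or \code{NULL} to require the in-file \code{condition}
#'   line.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path, label_spec = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1L) stop("empty expression file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < 2L) stop("expression header must contain at least one sample id")
  sids <- header[-1L]
  body_start <- 2L
  cond_inline <- NULL
  if (length(fields) >= 2L && identical(fields[[2L]][1L], "condition")) {
    cond_line <- fields[[2L]]
    if (length(cond_line) != length(header)) {
      stop("condition line must have one label per sample")
    }
    cond_inline <- stats::setNames(cond_line[-1L], sids)
    body_start <- 3L
  }
  body <- fields[seq_along(fields) >= body_start]
  gid <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(gid)) {
    stop("duplicate gene id: ", gid[duplicated(gid)][1L])
  }
  nlens <- lengths(body)
  if (any(nlens != length(header))) {
    bad <- which(nlens != length(header))[1L]
    stop("row ", bad + body_start - 1L, " has ", nlens[bad] - 1L,
         " values; expected ", length(sids))
  }
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(sids),
                 dimnames = list(gid, sids))
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1L]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      stop("non-numeric value at gene '", gid[i], "', sample '", sids[j],
           "': '", body[[i]][j + 1L], "'")
    }
    vals[i, ] <- v
  }

  cond <- .resolve_labels(label_spec, cond_inline, sids)
  expression_dataset(vals, cond)
}

.resolve_labels <- function(label_spec, cond_inline, sids) {
  if (is.null(label_spec)) {
    if (is.null(cond_inline)) {
      stop("no condition labels: supply label_spec or an in-file 'condition' line")
    }
    return(cond_inline)
  }
  if (is.character(label_spec) && length(label_spec) == 1L &&
      is.null(names(label_spec)) && file.exists(label_spec)) {
    tab <- utils::read.delim(label_spec, header = TRUE, colClasses = "character")
    label_spec <- stats::setNames(tab[[2L]], tab[[1L]])
  }
  if (is.data.frame(label_spec)) {
    label_spec <- stats::setNames(as.character(label_spec[[2L]]),
                                  as.character(label_spec[[1L]]))
  }
  missing <- setdiff(sids, names(label_spec))
  if (length(missing)) {
    stop("no condition label for sample(s): ", paste(missing, collapse = ", "))
  }
  label_spec[sids]
}

#' Write an expression dataset as TSV
#'
#' Inverse of [read_expression()]: writes the header row, a \code{condition}
#' line, and one gene per row. Values are serialized with 17 significant
#' digits so a read/write round trip reproduces the matrix bit-exactly.
#'
#' @param x An \code{ExpressionDataset}.
#' @param path Output path.
#' @param condition_line Write the in-file condition line (default TRUE).
#' @return \code{path}, invisibly.
#' @export
write_expression <- function(x, path, condition_line = TRUE) {
  stopifnot(inherits(x, "ExpressionDataset"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("gene_id", sample_ids(x)), collapse = "\t"), con)
  if (condition_line) {
    writeLines(paste(c("condition", as.character(x$condition)), collapse = "\t"), con)
  }
  num <- apply(x$values, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(paste(gene_ids(x), num, sep = "\t"), con)
  invisible(path)
}

#' Read a GMT gene set file
#'
#' Standard MSigDB-style format: one set per line,
#' \code{name<TAB>description<TAB>member1<TAB>member2...}. The description is
#' discarded; duplicate members within a line are de-duplicated; file order
#' is preserved and defines each set's index.
#'
#' @param path Path to the GMT file.
#' @return A [gene_set_database()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(gene_set_database(list()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short)) {
    stop("GMT line ", which(short)[1L], " has fewer than 3 fields")
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate set name: ", nm[duplicated(nm)][1L])
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  gene_set_database(sets)
}

#' Write a gene set database as GMT
#'
#' @param db A \code{GeneSetDatabase}.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions
#'   (default \code{"na"}).
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(db, path, descriptions = NULL) {
  stopifnot(inherits(db, "GeneSetDatabase"))
  if (is.null(descriptions)) descriptions <- rep("na", n_sets(db))
  members <- vapply(db$sets, paste, character(1), collapse = "\t")
  writeLines(paste(set_names(db), descriptions, members, sep = "\t"), path)
  invisible(path)
}

# Shared TSV writer: deterministic, header row, full numeric precision.
.write_tsv <- function(df, path) {
  is_num <- vapply(df, is.double, logical(1))
  df[is_num] <- lapply(df[is_num], function(v) sprintf("%.17g", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
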