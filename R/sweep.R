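#' Configuration of a full reproducibility sweep
#'
#' Bundles everything one experiment needs: the parent dataset, the gene set
#' database, the methods to benchmark, the sample sizes and replicate count,
#' the significance level, the experiment modes, the root seed and the
#' output directory. Defaults mirror the standard design: n from 3 to 20,
#' m = 10 replicates per size, alpha = 0.05.
#'
#' @param dataset \code{ExpressionDataset} (or path to an expression TSV
#'   carrying an in-file condition line).
#' @param database \code{GeneSetDatabase} (or path to a GMT file).
#' @param methods Character vector of registry names (see
#'   [gsa_methods_available()]).
#' @param n_values Per-group sample sizes to sweep.
#' @param m Replicates per size (>= 2).
#' @param alpha Significance level.
#' @param modes Subset of \code{c("case_control", "control_control")}.
#' @param root_seed Integer root seed for every random draw.
#' @param outdir Output directory (created if absent).
#' @param method_args Optional named list: per-method extra arguments.
#' @return Object of class \code{SweepConfig}.
#' @export
sweep_config <- function(dataset, database, methods = "ora",
                         n_values = 3:20, m = 10L, alpha = 0.05,
                         modes = "case_control", root_seed = 1L,
                         outdir = tempfile("gsarep_sweep_"),
                         method_args = list()) {
  if (is.character(dataset)) dataset <- read_expression(dataset)
  if (is.character(database)) database <- read_gmt(database)
  stopifnot(inherits(dataset, "ExpressionDataset"),
            inherits(database, "GeneSetDatabase"),
            length(n_values) >= 1L, m >= 2L,
            all(modes %in% c("case_control", "control_control")))
  unknown <- setdiff(methods, gsa_methods_available())
  if (length(unknown)) stop("unregistered method(s): ", paste(unknown, collapse = ", "))
  structure(list(dataset = dataset, database = database, methods = methods,
                 n_values = as.integer(n_values), m = as.integer(m),
                 alpha = alpha, modes = modes,
                 root_seed = as.integer(root_seed), outdir = outdir,
                 method_args = method_args),
            class = "SweepConfig")
}

.write_result_tsv <- function(result, call, path) {
  df <- data.frame(set_name = result$set_names,
                   raw_p = result$raw_p,
                   adjusted_p = result$adjusted_p,
                   significant = as.integer(result$set_names %in% call$significant))
  .write_tsv(df, path)
}

.analyze_replicate <- function(cfg, method, rep, coord) {
  args <- c(list(x = rep, db = cfg$database, method = method,
                 alpha = cfg$alpha),
            cfg$method_args[[method]] %||% list())
  tryCatch(do.call(run_gsa, args),
           error = function(e) stop("sweep failed at ", coord, ": ",
                                    conditionMessage(e), call. = FALSE))
}

#' Run the full reproducibility / specificity sweep
#'
#' For every (mode, method, sample size): draws m replicate datasets,
#' applies the method, BH-adjusts, calls significance at alpha, and writes
#' replicate manifests, per-replicate result tables, overlap matrices and
#' multisets, Kendall's W, the Kruskal-Wallis test across sizes, mean-count
#' (case-control) or false-positive (control-control) summaries, the four
#' standard figures, and a machine-readable JSON manifest. Each method is
#' also applied once to the whole dataset for the replicate-versus-whole
#' overlaps (case-control mode). Given the same configuration and seed the
#' output files are byte-identical across runs.
#'
#' @param cfg A [sweep_config()].
#' @param figures Render figures as well as tables (default TRUE).
#' @return The output directory path, invisibly.
#' @export
run_sweep <- function(cfg, figures = TRUE) {
  stopifnot(inherits(cfg, "SweepConfig"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  ds <- cfg$dataset; db <- cfg$database

  manifest <- list(methods = cfg$methods, n_values = cfg$n_values,
                   m = cfg$m, alpha = cfg$alpha, modes = cfg$modes,
                   root_seed = cfg$root_seed,
                   n_genes = length(gene_ids(ds)),
                   n_control = n_control(ds), n_case = n_case(ds),
                   n_sets = n_sets(db),
                   package_version = as.character(utils::packageVersion("gsarep")))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  overlap_rows <- list(); multiset_rows <- list(); conc_rows <- list()
  kw_rows <- list(); count_rows <- list()

  for (mode in cfg$modes) {
    for (method in cfg$methods) {
      whole <- NULL
      if (mode == "case_control") {
        whole <- .analyze_replicate(cfg, method, ds,
                                    sprintf("(%s, %s, whole dataset)", mode, method))
      }
      mdir <- file.path(cfg$outdir, mode, method)
      dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
      if (!is.null(whole)) {
        .write_result_tsv(whole$result, whole$call,
                          file.path(mdir, "whole_dataset.tsv"))
      }
      calls_by_n <- list()
      mats <- list()
      pair_ms <- list(); whole_ms <- list()
      for (n in cfg$n_values) {
        message(sprintf("[gsarep] %s / %s / n=%d", mode, method, n))
        reps <- generate_replicate_series(ds, n, cfg$m, mode, cfg$root_seed)
        write_replicate_manifest(reps, ds,
                                 file.path(mdir, sprintf("replicates_n%02d.tsv", n)))
        runs <- lapply(seq_along(reps), function(i) {
          out <- .analyze_replicate(cfg, method, reps[[i]],
                                    sprintf("(%s, %s, n=%d, replicate %d)",
                                            mode, method, n, i))
          .write_result_tsv(out$result, out$call,
                            file.path(mdir, sprintf("result_n%02d_rep%02d.tsv", n, i)))
          out
        })
        calls <- lapply(runs, `[[`, "call")
        results <- lapply(runs, `[[`, "result")
        calls_by_n[[as.character(n)]] <- calls

        mat <- build_overlap_matrix(calls, method, n)
        mats[[as.character(n)]] <- mat
        idx <- which(!is.na(mat) & upper.tri(mat), arr.ind = TRUE)
        overlap_rows[[length(overlap_rows) + 1L]] <-
          data.frame(mode = mode, method = method, n = n,
                     i = idx[, 1L], j = idx[, 2L], overlap = mat[idx])

        pm <- pairwise_overlap_multiset(calls, method, n)
        pair_ms[[as.character(n)]] <- pm
        multiset_rows[[length(multiset_rows) + 1L]] <-
          data.frame(mode = mode, method = method, n = n, kind = "pairwise",
                     value = as.numeric(pm))
        if (!is.null(whole)) {
          wm <- vs_whole_overlap_multiset(calls, whole$call, method, n)
          whole_ms[[as.character(n)]] <- wm
          multiset_rows[[length(multiset_rows) + 1L]] <-
            data.frame(mode = mode, method = method, n = n, kind = "vs_whole",
                       value = as.numeric(wm))
        }

        cw <- kendalls_w(results, calls)
        conc_rows[[length(conc_rows) + 1L]] <-
          data.frame(mode = mode, method = method, n = n,
                     W = if (cw$defined) cw$W else NA_real_,
                     n_items = cw$n_items)
      }

      kw <- kruskal_wallis_across_sizes(lapply(pair_ms, as.numeric))
      kw_rows[[length(kw_rows) + 1L]] <-
        data.frame(mode = mode, method = method, H = kw$H, p = kw$p,
                   degenerate = kw$degenerate)

      summary_df <- if (mode == "control_control") {
        false_positive_summary(calls_by_n, method)
      } else {
        enriched_count_summary(calls_by_n, method)
      }
      summary_df <- data.frame(mode = mode, summary_df)
      count_rows[[length(count_rows) + 1L]] <- summary_df

      if (figures && length(mats) >= 1L) {
        render_pine_plot(mats, file.path(mdir, "pine_plot.png"),
                         title = sprintf("%s (%s)", method, mode))
        if (!is.null(whole) && length(whole_ms)) {
          render_overlap_boxplots(pair_ms, whole_ms,
                                  file.path(mdir, "overlap_boxplots.png"),
                                  title = method)
        }
      }
    }
  }

  .write_tsv(do.call(rbind, overlap_rows),
             file.path(cfg$outdir, "overlap_matrices.tsv"))
  .write_tsv(do.call(rbind, multiset_rows),
             file.path(cfg$outdir, "overlap_multisets.tsv"))
  conc <- do.call(rbind, conc_rows)
  .write_tsv(conc, file.path(cfg$outdir, "concordance.tsv"))
  .write_tsv(do.call(rbind, kw_rows),
             file.path(cfg$outdir, "kruskal_wallis.tsv"))
  counts <- do.call(rbind, count_rows)
  .write_tsv(counts, file.path(cfg$outdir, "mean_counts.tsv"))

  if (figures) {
    cc <- conc[conc$mode == "case_control", , drop = FALSE]
    if (nrow(cc) && any(!is.na(cc$W))) {
      render_concordance_plot(cc, file.path(cfg$outdir, "concordance.png"))
    }
    ccnt <- counts[counts$mode == "case_control", , drop = FALSE]
    if (nrow(ccnt)) {
      render_count_plot(ccnt, n_sets(db), file.path(cfg$outdir, "mean_counts.png"))
    }
  }
  invisible(cfg$outdir)
}
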