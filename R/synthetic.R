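#' Configuration for the synthetic expression generator
#'
#' The generator emulates a normalized, log2-scale two-condition microarray
#' study: per-gene baselines drawn uniformly from a typical log-intensity
#' window, Gaussian gene-level noise, optional within-gene-set correlation
#' induced by one shared latent factor per set, and a constant mean shift
#' applied to (a fraction of) the member genes of designated "truly enriched"
#' sets in case samples only.
#'
#' Defaults describe a desk-scale study: 1000 genes, 30 controls + 30 cases,
#' 100 gene sets of 10-50 members, 10% of sets truly enriched with a 1.5
#' log2-unit shift in all their members, within-set correlation 0.1, noise
#' SD 0.4 (a typical post-RMA within-condition standard deviation for
#' expressed genes), baselines in [4, 10].
#'
#' @param n_genes,n_controls,n_cases,n_sets Positive integers.
#' @param set_size_range Integer interval \code{c(lo, hi)}, \code{lo >= 1},
#'   \code{hi <= n_genes}.
#' @param frac_enriched Fraction in [0,1] of sets designated truly enriched.
#' @param effect_size Log2-scale mean shift added to shifted genes in case
#'   samples.
#' @param frac_members_shifted Fraction in (0,1] of each enriched set's
#'   members that receive the shift.
#' @param rho Within-set correlation in [0,1) from the shared latent factor.
#' @param noise_sd Standard deviation of the independent gene-level noise.
#' @param baseline_mean_range Interval for the uniform per-gene baseline.
#' @param seed Integer root seed; the whole output is a deterministic
#'   function of the configuration.
#' @return Object of class \code{SyntheticConfig} (a validated list).
#' @export
synthetic_config <- function(n_genes = 1000L, n_controls = 30L, n_cases = 30L,
                             n_sets = 100L, set_size_range = c(10L, 50L),
                             frac_enriched = 0.1, effect_size = 1.5,
                             frac_members_shifted = 1, rho = 0.1,
                             noise_sd = 0.4, baseline_mean_range = c(4, 10),
                             seed = 1L) {
  stopifnot(n_genes >= 1, n_controls >= 1, n_cases >= 1, n_sets >= 1,
            length(set_size_range) == 2L, set_size_range[1] >= 1,
            frac_enriched >= 0, frac_enriched <= 1,
            frac_members_shifted > 0, frac_members_shifted <= 1,
            rho >= 0, rho < 1, noise_sd > 0,
            length(baseline_mean_range) == 2L,
            baseline_mean_range[1] <= baseline_mean_range[2])
  if (set_size_range[2] > n_genes) {
    stop("infeasible set sizes: max set size ", set_size_range[2],
         " exceeds n_genes = ", n_genes)
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_controls = as.integer(n_controls),
                 n_cases = as.integer(n_cases),
                 n_sets = as.integer(n_sets),
                 set_size_range = as.integer(set_size_range),
                 frac_enriched = frac_enriched,
                 effect_size = effect_size,
                 frac_members_shifted = frac_members_shifted,
                 rho = rho, noise_sd = noise_sd,
                 baseline_mean_range = baseline_mean_range,
                 seed = as.integer(seed)),
            class = "SyntheticConfig")
}

#' Generate a synthetic case-control dataset with known enrichment truth
#'
#' Model for gene g, sample s:
#' \deqn{x_{gs} = b_g + \sqrt{\rho}\, L_{set(g),s} + \sqrt{1-\rho}\,\sigma\,\epsilon_{gs} + \Delta_{gs}}
#' with baseline \eqn{b_g \sim U(lo, hi)}, one standard-normal latent factor
#' L per (gene set, sample), independent standard-normal noise
#' \eqn{\epsilon}, and \eqn{\Delta_{gs}} equal to \code{effect_size} iff s is
#' a case and g is a shifted member of a truly enriched set. Genes belonging
#' to several sets take the latent factor of their first containing set;
#' genes in no set get independent noise only. Gene sets are drawn by
#' sampling members without replacement per set.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements \code{dataset} (an
#'   \code{ExpressionDataset}), \code{database} (a \code{GeneSetDatabase})
#'   and \code{truth} (class \code{SyntheticTruth}: character vectors
#'   \code{enriched_set_names} and \code{shifted_genes}).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  cfg <- config
  set.seed(cfg$seed)
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  samples <- c(sprintf("ctrl%03d", seq_len(cfg$n_controls)),
               sprintf("case%03d", seq_len(cfg$n_cases)))
  cond <- rep(c("control", "case"), c(cfg$n_controls, cfg$n_cases))
  n_samp <- length(samples)

  sizes <- sample(seq(cfg$set_size_range[1], cfg$set_size_range[2]),
                  cfg$n_sets, replace = TRUE)
  sets <- lapply(sizes, function(k) sample(genes, k))
  names(sets) <- sprintf("set%03d", seq_len(cfg$n_sets))
  db <- gene_set_database(sets)

  n_enr <- round(cfg$frac_enriched * cfg$n_sets)
  enriched <- if (n_enr > 0) sample(names(sets), n_enr) else character(0)
  # keep database order in the truth record
  enriched <- names(sets)[names(sets) %in% enriched]
  shifted <- character(0)
  for (nm in enriched) {
    mem <- sets[[nm]]
    k <- max(1L, ceiling(cfg$frac_members_shifted * length(mem)))
    shifted <- union(shifted, sample(mem, k))
  }

  # first containing set per gene drives the shared latent factor
  first_set <- rep(NA_integer_, cfg$n_genes)
  names(first_set) <- genes
  for (i in seq_along(sets)) {
    mem <- sets[[i]]
    unset <- mem[is.na(first_set[mem])]
    first_set[unset] <- i
  }

  b <- stats::runif(cfg$n_genes, cfg$baseline_mean_range[1],
                    cfg$baseline_mean_range[2])
  L <- matrix(stats::rnorm(cfg$n_sets * n_samp), cfg$n_sets, n_samp)
  eps <- matrix(stats::rnorm(cfg$n_genes * n_samp), cfg$n_genes, n_samp)

  vals <- b + sqrt(1 - cfg$rho) * cfg$noise_sd * eps
  in_set <- !is.na(first_set)
  if (cfg$rho > 0 && any(in_set)) {
    vals[in_set, ] <- vals[in_set, ] +
      sqrt(cfg$rho) * L[first_set[in_set], , drop = FALSE]
  }
  if (cfg$effect_size != 0 && length(shifted)) {
    vals[genes %in% shifted, cond == "case"] <-
      vals[genes %in% shifted, cond == "case"] + cfg$effect_size
  }
  dimnames(vals) <- list(genes, samples)

  truth <- structure(list(enriched_set_names = enriched,
                          shifted_genes = sort(shifted)),
                     class = "SyntheticTruth")
  list(dataset = expression_dataset(vals, cond), database = db, truth = truth)
}

#' Generate a pure-null dataset (control pool)
#'
#' Identical to [generate_dataset()] but with the effect size forced to zero
#' and every sample labelled \code{control}, so the output is a homogeneous
#' pool suitable as the parent of control-control replicates; any downstream
#' significant call is a false positive by construction.
#'
#' @inheritParams generate_dataset
#' @return As [generate_dataset()]; \code{truth$enriched_set_names} is empty
#'   and the dataset has \code{n_controls + n_cases} controls, zero cases.
#' @export
generate_null_dataset <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  cfg <- config
  cfg$effect_size <- 0
  cfg$frac_enriched <- 0
  out <- generate_dataset(cfg)
  v <- out$dataset$values
  out$dataset <- expression_dataset(v, rep("control", ncol(v)))
  out$truth <- structure(list(enriched_set_names = character(0),
                              shifted_genes = character(0)),
                         class = "SyntheticTruth")
  out
}

#' Write the enrichment truth as TSV
#'
#' @param truth A \code{SyntheticTruth}.
#' @param db The matching \code{GeneSetDatabase}.
#' @param path Output path; columns \code{set_name}, \code{is_enriched}.
#' @export
write_truth <- function(truth, db, path) {
  df <- data.frame(set_name = set_names(db),
                   is_enriched = as.integer(set_names(db) %in%
                                            truth$enriched_set_names))
  .write_tsv(df, path)
}
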