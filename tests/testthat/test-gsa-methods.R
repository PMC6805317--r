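test_that("gene-level Welch statistics match the textbook computation", {
  v <- rbind(flat = c(2, 2, 2, 2, 2, 2),
             up   = c(1, 2, 3, 4, 5, 6))
  colnames(v) <- paste0("s", 1:6)
  ds <- make_ds(v, rep(c("control", "case"), each = 3))
  gls <- gene_level_stats(ds)
  expect_equal(gls$t[gls$gene_id == "flat"], 0)
  expect_equal(gls$p[gls$gene_id == "flat"], 1)

  tt <- t.test(c(4, 5, 6), c(1, 2, 3))   # independent Welch oracle
  expect_equal(gls$t[gls$gene_id == "up"], unname(tt$statistic))
  expect_equal(gls$p[gls$gene_id == "up"], tt$p.value)
  expect_equal(gls$effect[gls$gene_id == "up"], 3)

  swapped <- make_ds(v, rep(c("case", "control"), each = 3))
  gls2 <- gene_level_stats(swapped)
  expect_equal(gls2$t, -gls$t)
  expect_equal(gls2$p, gls$p)

  expect_error(gene_level_stats(make_ds(v[, 1:3], c("control", "case", "case"))),
               "at least 2 samples")
})

test_that("ORA equals brute-force hypergeometric enumeration on small backgrounds", {
  de <- sprintf("g%03d", 1:8)                 # 8 DE genes in a 20-gene background
  ds <- de_spiked_ds(20, de, n_per_group = 5, seed = 42)
  gls <- gene_level_stats(ds)
  expect_identical(gls$gene_id[adjust_bh(gls$p) < 0.05], de)

  set.seed(7)
  sets <- c(list(fourhit = c(de[1:4], "g015")),   # overlap 4 of 5
            lapply(1:20, function(i) sample(gene_ids(ds), sample(3:10, 1))))
  names(sets) <- c("fourhit", paste0("rand", 1:20))
  db <- gene_set_database(sets)
  res <- ora_analyze(ds, db)
  expect_identical(res$set_names, set_names(db))
  for (i in seq_along(sets)) {
    q <- length(intersect(sets[[i]], de))
    expect_equal(res$raw_p[i], oracle_hyper_upper(q, length(sets[[i]]), 20, 8),
                 info = names(sets)[i])
  }
  # the spec'd worked case: mass at overlaps {4, 5}
  expect_equal(res$raw_p[1],
               oracle_hyper_upper(4, 5, 20, 8))

  # empty DE list: upper tail at zero overlap is 1 for every set
  null_ds <- random_null_ds(20, 5, 5, seed = 3)
  res0 <- ora_analyze(null_ds, db)
  expect_true(all(res0$raw_p == 1))

  # DE list == background: overlap is forced, p = 1
  all_ds <- de_spiked_ds(12, sprintf("g%03d", 1:12), n_per_group = 4, seed = 5)
  db1 <- gene_set_database(list(inside = sprintf("g%03d", 1:5)))
  expect_equal(ora_analyze(all_ds, db1)$raw_p, 1)
})

test_that("PAGE z-statistic follows its closed form", {
  ds <- random_null_ds(50, 6, 6, seed = 13)
  db <- gene_set_database(list(
    all = gene_ids(ds),                       # Sm == mu, so Z = 0, p = 1
    some = gene_ids(ds)[c(2, 9, 17, 30)]))
  res <- page_analyze(ds, db)
  expect_equal(res$raw_p[1], 1)

  gls <- gene_level_stats(ds)
  eff <- stats::setNames(gls$effect, gls$gene_id)
  z <- (mean(eff[db$sets$some]) - mean(eff)) * sqrt(4) / sd(eff)
  expect_equal(res$raw_p[2], 2 * pnorm(-abs(z)))

  # negating every sample's label negates effects and keeps p
  flipped <- make_ds(ds$values, ifelse(ds$condition == "case", "control", "case"))
  res2 <- page_analyze(flipped, db)
  expect_equal(res2$raw_p, res$raw_p)

  const <- make_ds(matrix(5, 3, 8, dimnames = list(paste0("g", 1:3), paste0("s", 1:8))),
                   rep(c("control", "case"), each = 4))
  expect_error(page_analyze(const, db), "degenerate")
})

test_that("PLAGE metagene reduces to the standardized gene for singleton sets", {
  ds <- random_null_ds(30, 5, 5, seed = 21)
  g <- gene_ids(ds)[7]
  db <- gene_set_database(list(single = g,
                               dup = c(g)))
  res <- plage_analyze(ds, db)
  zrow <- scale(ds$values[g, ])[, 1]
  tt <- t.test(zrow[ds$condition == "case"], zrow[ds$condition == "control"])
  expect_equal(res$raw_p[1], tt$p.value)

  # metagene sign is arbitrary: flipping the expression sign leaves p unchanged
  neg <- make_ds(-ds$values, as.character(ds$condition))
  expect_equal(plage_analyze(neg, db)$raw_p, res$raw_p)

  # set with no member in the background: p = 1, flagged
  db2 <- gene_set_database(list(absent = c("nope1", "nope2")))
  r2 <- plage_analyze(ds, db2)
  expect_equal(r2$raw_p, 1)
  expect_true(r2$flagged)
})

test_that("ssGSEA closed-form scores equal the brute-force ECDF walk", {
  ds <- random_null_ds(10, 3, 3, seed = 33)
  set.seed(4)
  sets <- lapply(1:6, function(i) sample(gene_ids(ds), sample(2:5, 1)))
  names(sets) <- paste0("S", 1:6)
  db <- gene_set_database(sets)
  for (tau in c(0.25, 0)) {
    res <- ssgsea_analyze(ds, db, tau = tau)
    scores <- attr(res, "scores")
    for (i in seq_along(sets)) {
      for (s in seq_len(ncol(ds$values))) {
        expect_equal(scores[i, s],
                     oracle_ssgsea_score(ds$values[, s], sets[[i]], tau),
                     info = sprintf("set %d sample %d tau %g", i, s, tau))
      }
    }
  }

  # members occupying the top |set| ranks attain the maximal score: compare
  # against enumeration of every possible 3-member placement in one sample
  expr <- stats::setNames(sort(rnorm(10), decreasing = TRUE), paste0("g", 1:10))
  top <- names(expr)[1:3]
  all_scores <- combn(names(expr), 3, function(mm) {
    oracle_ssgsea_score(expr, mm, 0.25)
  })
  expect_equal(oracle_ssgsea_score(expr, top, 0.25), max(all_scores))

  expect_error(ssgsea_analyze(ds, gene_set_database(list(all = gene_ids(ds)))),
               "entire background")

  # identical columns: constant scores, guarded p = 1
  cds <- make_ds(matrix(rep(1:8, 6), nrow = 8,
                        dimnames = list(paste0("g", 1:8), paste0("s", 1:6))),
                 rep(c("control", "case"), each = 3))
  rc <- ssgsea_analyze(cds, gene_set_database(list(S = c("g2", "g5"))))
  expect_equal(rc$raw_p, 1)
})

test_that("enrichment score matches the running-sum walk and its extreme cases", {
  # single member at rank 1: hit weight normalizes to 1 before any miss
  st <- stats::setNames(seq(5, 1), paste0("g", 1:5))
  expect_equal(gsea_es(st, "g1"), 1)

  # single member at the last rank: extreme negative, equal to the oracle
  expect_equal(gsea_es(st, "g5"), oracle_gsea_es(st, "g5"))
  expect_lt(gsea_es(st, "g5"), 0)

  # scale invariance at p_exp = 1
  expect_equal(gsea_es(st * 2, c("g2", "g4")), gsea_es(st, c("g2", "g4")))

  expect_error(gsea_es(st, paste0("g", 1:5)), "entire ranked list")
  expect_error(gsea_es(st, "absent"), "no member")

  # property: candidate-point shortcut equals the full running sum
  set.seed(66)
  for (i in 1:50) {
    N <- sample(4:10, 1)
    stats_i <- stats::setNames(sort(rnorm(N), decreasing = TRUE), paste0("g", 1:N))
    k <- sample(1:(N - 1), 1)
    mem <- sample(names(stats_i), k)
    for (p_exp in c(0, 1, 1.5)) {
      expect_equal(gsea_es(stats_i, mem, p_exp),
                   oracle_gsea_es(stats_i, mem, p_exp))
    }
  }
})

test_that("gene-permutation GSEA p-values respect the add-one floor and the seed", {
  de <- sprintf("g%03d", 1:10)
  ds <- de_spiked_ds(60, de, n_per_group = 4, seed = 9)
  db <- gene_set_database(list(hot = de[1:6],
                               cold = sprintf("g%03d", 40:45)))
  res <- gsea_gene_perm_analyze(ds, db, n_perm = 19, seed = 1)
  expect_equal(min(res$raw_p), 1 / 20)         # smallest attainable with 19 perms
  expect_true(all(res$raw_p >= 1 / 20))

  res2 <- gsea_gene_perm_analyze(ds, db, n_perm = 19, seed = 1)
  expect_identical(res$raw_p, res2$raw_p)

  # random sets on null data: p approximately uniform at the tail
  nds <- random_null_ds(300, 5, 5, seed = 10)
  set.seed(11)
  rsets <- lapply(1:200, function(i) sample(gene_ids(nds), 15))
  names(rsets) <- paste0("R", 1:200)
  rres <- gsea_gene_perm_analyze(nds, gene_set_database(rsets),
                                 n_perm = 200, seed = 12)
  frac <- mean(rres$raw_p < 0.1)
  expect_gte(frac, 0.05)
  expect_lte(frac, 0.16)
})

test_that("sample-permutation GSEA enumerates balanced relabellings exhaustively", {
  expect_equal(ncol(balanced_relabellings(3)), 20)  # C(6, 3)
  expect_equal(ncol(balanced_relabellings(4)), 70)

  de <- sprintf("g%03d", 1:10)
  ds <- de_spiked_ds(50, de, n_per_group = 3, seed = 15)
  db <- gene_set_database(list(hot = de[1:6],
                               cold = sprintf("g%03d", 30:35)))
  res <- gsea_sample_perm_analyze(ds, db)
  expect_true(attr(res, "exhaustive"))
  expect_equal(attr(res, "n_permutations"), 20)
  # p-values live on the 1/20 grid and never drop below 1/20
  expect_true(all(abs(res$raw_p * 20 - round(res$raw_p * 20)) < 1e-12))
  # the estimator's granularity: nothing below 1/20 is representable
  expect_gte(min(res$raw_p), 0.05)
  # the spiked set sits at the floor up to the complement relabelling, whose
  # mirrored statistic matches |ES| under the undirected comparison
  expect_lte(res$raw_p[1], 2 / 20)

  # Monte Carlo branch with the add-one estimator
  mc <- gsea_sample_perm_analyze(ds, db, n_perm = 50, mode = "monte_carlo",
                                 seed = 3)
  expect_true(all(mc$raw_p >= 1 / 51))
  expect_error(gsea_sample_perm_analyze(random_null_ds(10, 4, 5, 1), db),
               "balanced")
})

test_that("BH adjustment matches the quadratic step-up oracle", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.42), 0.42)
  expect_error(adjust_bh(c(0.5, 1.2)), "0,1")
  expect_error(adjust_bh(c(0.5, -0.1)), "0,1")

  set.seed(3)
  for (i in 1:20) {
    K <- sample(1:50, 1)
    p <- round(runif(K), sample(1:4, 1))   # rounding provokes ties
    adj <- adjust_bh(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("enrichment calls use a strict alpha threshold", {
  res <- gsa_result("demo", c("a", "b", "c"), c(0.01, 0.02, 0.1),
                    adjusted_p = c(0.049, 0.05, 0.2))
  expect_identical(call_enriched(res, 0.05)$significant, "a")
  expect_identical(call_enriched(res, 1)$significant, c("a", "b", "c"))

  res1 <- gsa_result("demo", c("a", "b"), c(1, 1), adjusted_p = c(1, 1))
  expect_length(call_enriched(res1, 0.05)$significant, 0)
  expect_length(call_enriched(res1, 1)$significant, 0)  # adjusted exactly 1 excluded
})

test_that("every method reports one p per database set, in database order", {
  sim <- generate_dataset(synthetic_config(n_genes = 120, n_controls = 6,
                                           n_cases = 6, n_sets = 12,
                                           set_size_range = c(4, 10), seed = 19))
  rep <- draw_case_control_replicate(sim$dataset, 4, 5)
  for (meth in c("ora", "page", "plage", "ssgsea")) {
    out <- run_gsa(rep, sim$database, meth)
    expect_identical(out$result$set_names, set_names(sim$database))
    expect_true(all(out$result$raw_p >= 0 & out$result$raw_p <= 1))
    expect_true(all(out$result$adjusted_p >= out$result$raw_p - 1e-15))
  }
  out <- run_gsa(rep, sim$database, "gsea_g", n_perm = 100, seed = 2)
  expect_identical(out$result$set_names, set_names(sim$database))
  expect_error(run_gsa(rep, sim$database, "nope"), "unknown GSA method")
})

test_that("external executables plug in through the method contract", {
  skip_on_os("windows")
  sh <- withr::local_tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh",
               'printf "set_name\\traw_p\\n" > "$3"',
               'cut -f1 "$2" | while read nm; do printf "%s\\t0.04\\n" "$nm" >> "$3"; done'),
             sh)
  Sys.chmod(sh, "0755")
  register_gsa_method("fixed04", make_external_gsa_method(sh, "fixed04"))
  ds <- random_null_ds(10, 3, 3, seed = 2)
  db <- gene_set_database(list(A = c("g001", "g002"), B = c("g003")))
  out <- run_gsa(ds, db, "fixed04")
  expect_equal(out$result$raw_p, c(0.04, 0.04))
  expect_equal(out$result$adjusted_p, c(0.04, 0.04))   # BH applied like built-ins
  expect_identical(out$call$significant, c("A", "B"))
})
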