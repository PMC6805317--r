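call_of <- function(sig) structure(list(significant = sig, alpha = 0.05),
                                   class = "EnrichedCall")

test_that("Jaccard overlap follows its contract including the empty convention", {
  expect_equal(jaccard_overlap(c("A", "B"), c("A", "B")), 1)
  expect_equal(jaccard_overlap(c("A"), c("B")), 0)
  expect_equal(jaccard_overlap(c("A", "B"), c("B", "C")), 1 / 3)
  expect_equal(jaccard_overlap(character(0), "A"), 0)
  expect_equal(jaccard_overlap(call_of("A"), call_of(c("A", "B"))), 0.5)

  # the undefined 0/0 case: no-finding pairs score 0 by default so powerless
  # analyses do not look reproducible; the agreement convention is opt-in
  expect_equal(jaccard_overlap(character(0), character(0)), 0)
  expect_equal(jaccard_overlap(character(0), character(0), empty_value = 1), 1)

  set.seed(2)
  for (i in 1:20) {
    a <- sample(LETTERS, sample(0:6, 1))
    b <- sample(LETTERS, sample(0:6, 1))
    expect_equal(jaccard_overlap(a, b), jaccard_overlap(b, a))
    expect_gte(jaccard_overlap(a, b), 0)
    expect_lte(jaccard_overlap(a, b), 1)
    expect_equal(jaccard_overlap(a, b) == 1,
                 setequal(a, b) && length(a) > 0)
  }
})

test_that("overlap matrices are upper-triangular with unit diagonal", {
  calls <- replicate(10, call_of(c("X", "Y")), simplify = FALSE)
  mat <- build_overlap_matrix(calls, "demo", 5)
  expect_equal(dim(mat), c(10, 10))
  expect_true(all(diag(mat) == 1))
  expect_equal(sum(!is.na(mat) & upper.tri(mat)), 45)   # m(m-1)/2, m = 10
  expect_true(all(mat[upper.tri(mat)] == 1))
  expect_true(all(is.na(mat[lower.tri(mat)])))
  expect_error(build_overlap_matrix(calls[1]), "at least 2")
})

test_that("pairwise multisets flatten the upper triangle with repetition", {
  calls <- list(call_of("A"), call_of("A"), call_of("B"))
  pm <- pairwise_overlap_multiset(calls, "demo", 3)
  expect_equal(as.numeric(pm), c(1, 0, 0))
  expect_equal(attr(pm, "kind"), "pairwise")

  for (m in c(2, 5, 8)) {
    calls_m <- replicate(m, call_of(sample(LETTERS, 3)), simplify = FALSE)
    expect_length(pairwise_overlap_multiset(calls_m), m * (m - 1) / 2)
  }
})

test_that("versus-whole multisets hold one score per replicate", {
  calls <- list(call_of("A"), call_of(c("A", "B")))
  wm <- vs_whole_overlap_multiset(calls, call_of("A"), "demo", 3)
  expect_equal(as.numeric(wm), c(1, 0.5))
  expect_equal(attr(wm, "kind"), "vs_whole")

  # all-empty replicate calls against an empty whole-dataset call: no
  # demonstrated agreement under the default convention
  empties <- replicate(4, call_of(character(0)), simplify = FALSE)
  expect_equal(as.numeric(vs_whole_overlap_multiset(empties, call_of(character(0)))),
               rep(0, 4))
})

test_that("Kendall's W is 1 for identical rankings and 0 for reversed pairs", {
  mk_res <- function(p) gsa_result("demo", paste0("S", seq_along(p)), p,
                                   adjusted_p = p)
  p1 <- c(0.01, 0.02, 0.03, 0.2, 0.9)
  res_same <- list(mk_res(p1), mk_res(p1 * 0.5), mk_res(p1 * 0.9))
  calls_same <- replicate(3, call_of(paste0("S", 1:3)), simplify = FALSE)
  w1 <- kendalls_w(res_same, calls_same)
  expect_equal(w1$W, 1)
  expect_equal(w1$n_items, 3)

  p2 <- c(0.03, 0.02, 0.01, 0.2, 0.9)     # exactly reversed over S1..S3
  w0 <- kendalls_w(list(mk_res(p1), mk_res(p2)), calls_same[1:2])
  expect_equal(w0$W, 0)

  wu <- kendalls_w(res_same[1:2], list(call_of("S1"), call_of("S1")))
  expect_false(wu$defined)
  expect_true(is.na(wu$W))
})

test_that("Kendall's W agrees with an independent concordance implementation", {
  skip_if_not_installed("vegan")
  set.seed(12)
  for (i in 1:10) {
    m <- sample(3:6, 1); k <- sample(3:8, 1)
    p <- matrix(round(runif(m * k), 2), nrow = k)  # rounding provokes ties
    res <- lapply(seq_len(m), function(j) {
      gsa_result("demo", paste0("S", 1:k), p[, j], adjusted_p = p[, j])
    })
    calls <- replicate(m, call_of(paste0("S", 1:k)), simplify = FALSE)
    ours <- kendalls_w(res, calls)$W
    ref <- unname(vegan::kendall.global(p)$Concordance_analysis["W", 1])
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("Kruskal-Wallis across sizes matches the textbook rank computation", {
  deg <- kruskal_wallis_across_sizes(list(a = c(0.5, 0.5), b = c(0.5, 0.5)))
  expect_equal(deg$H, 0)
  expect_equal(deg$p, 1)
  expect_true(deg$degenerate)

  g <- list(n3 = c(1, 2, 3), n5 = c(4, 5, 6))
  kw <- kruskal_wallis_across_sizes(g)
  expect_equal(kw$H, oracle_kruskal_h(g))
  expect_equal(kw$df, 1)

  perm <- kruskal_wallis_across_sizes(rev(g))
  expect_equal(perm$H, kw$H)

  set.seed(9)
  for (i in 1:10) {
    gs <- lapply(1:sample(2:4, 1), function(j) round(runif(sample(2:8, 1)), 1))
    names(gs) <- paste0("g", seq_along(gs))
    if (length(unique(unlist(gs))) == 1) next
    got <- kruskal_wallis_across_sizes(gs)
    expect_equal(got$H, oracle_kruskal_h(gs), tolerance = 1e-12)
    expect_equal(got$p, stats::pchisq(got$H, got$df, lower.tail = FALSE))
  }
})

test_that("false-positive and count summaries average significant-set counts", {
  calls_by_n <- list(
    "3" = list(call_of(character(0)), call_of(c("A", "B", "C", "D"))),
    "5" = list(call_of(character(0)), call_of(character(0))))
  fp <- false_positive_summary(calls_by_n, "demo")
  expect_s3_class(fp, "SpecificitySummary")
  expect_equal(fp$mean_count[fp$n == 3], 2)   # mean of 0 and 4
  expect_equal(fp$mean_count[fp$n == 5], 0)

  ec <- enriched_count_summary(calls_by_n, "demo")
  expect_equal(ec$mean_count, fp$mean_count)  # shared kernel
  expect_true(all(ec$mean_count >= 0))
})
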