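test_that("EBM calibration recovers Fisher under independence and collapse under dependence", {
  set.seed(41)
  p1 <- runif(1e4)
  p2 <- runif(1e4)
  ind <- calibrate_ebm(p1, p2, "independent")
  expect_equal(ind$scale_factor, 1, tolerance = 0.05)
  expect_equal(ind$dof, 4, tolerance = 0.05)
  expect_equal(ind$rho, 0, tolerance = 0.05)
  dep <- calibrate_ebm(p1, p1, "dependent")
  expect_equal(dep$scale_factor, 2, tolerance = 0.1)
  expect_equal(dep$dof, 2, tolerance = 0.1)
  expect_equal(dep$rho, 1, tolerance = 1e-6)
  # mean preservation: c * f = 4 exactly, by construction
  expect_equal(ind$scale_factor * ind$dof, 4)
  expect_equal(dep$scale_factor * dep$dof, 4)
  expect_error(calibrate_ebm(runif(5), runif(5)), "at least 10")
  expect_error(calibrate_ebm(rep(0.5, 20), runif(20)), "degenerate")
  expect_error(calibrate_ebm(c(runif(19), 0), runif(20)), "\\(0, 1\\]")
})

test_that("EBM parameters round-trip through their JSON sidecar", {
  params <- ebm_params(1.3, 4 / 1.3, rho = 0.25, source_label = "cohortX",
                       n_pairs = 120L)
  p <- withr::local_tempfile(fileext = ".json")
  write_ebm_params(params, p)
  back <- read_ebm_params(p)
  expect_equal(back$scale_factor, params$scale_factor)
  expect_equal(back$dof, params$dof)
  expect_equal(back$rho, 0.25)
  expect_equal(back$source_label, "cohortX")
})

test_that("combination matches Fisher's closed form at (c, f) = (1, 4)", {
  fisher <- ebm_params(1, 4)
  grid <- expand.grid(p1 = c(0.001, 0.01, 0.1, 0.5, 0.9, 1),
                      p2 = c(0.005, 0.05, 0.3, 0.7, 1))
  for (i in seq_len(nrow(grid))) {
    x <- -2 * log(grid$p1[i]) - 2 * log(grid$p2[i])
    closed <- exp(-x / 2) * (1 + x / 2)  # chi-square(4) survival function
    expect_equal(combine_pvalues(grid$p1[i], grid$p2[i], fisher), closed,
                 tolerance = 1e-12)
  }
  expect_equal(combine_pvalues(0.1, 0.1, fisher), 0.05605, tolerance = 1e-4)
  expect_equal(combine_pvalues(1, 1, fisher), 1)
})

test_that("perfect dependence collapses the combination to the single p-value", {
  collapse <- ebm_params(2, 2)
  for (p in c(1e-8, 1e-4, 0.01, 0.3, 0.77, 1)) {
    expect_equal(combine_pvalues(p, p, collapse), p, tolerance = 1e-12)
  }
})

test_that("combination is monotone in both inputs and rejects invalid p", {
  params <- ebm_params(1.4, 4 / 1.4)
  ps <- c(0.001, 0.01, 0.1, 0.5, 1)
  for (fixed in c(0.05, 0.6)) {
    along1 <- combine_pvalues(ps, fixed, params)
    along2 <- combine_pvalues(fixed, ps, params)
    expect_false(is.unsorted(along1))
    expect_false(is.unsorted(along2))
  }
  expect_error(combine_pvalues(0, 0.5, params), "\\(0, 1\\]")
  expect_error(combine_pvalues(0.5, 1.5, params), "\\(0, 1\\]")
})

test_that("score and tier respect the published boundaries inclusively", {
  expect_equal(simpheny_score(1), 0)
  expect_equal(simpheny_score(1e-3), 3)
  expect_equal(simpheny_score(10^-4.5), 4.5)
  expect_equal(assign_tier(simpheny_score(10^-4.5)), "high")
  expect_equal(assign_tier(simpheny_score(10^-2.5)), "medium")
  expect_equal(assign_tier(4.5), "high")
  expect_equal(assign_tier(4.4999), "medium")
  expect_equal(assign_tier(2.5), "medium")
  expect_equal(assign_tier(2.4999), "low")
  expect_equal(assign_tier(0), "low")
  expect_error(assign_tier(-1), "non-negative")
  expect_error(simpheny_score(0), "\\(0, 1\\]")
})

test_that("gene score averages the two best matches and respects bounds", {
  expect_equal(gene_score(3.2), 3.2)
  expect_equal(gene_score(c(6, 4, 1)), 5)
  expect_equal(gene_score(c(2, 2, 2)), 2)
  expect_error(gene_score(numeric(0)), "no match scores")
  set.seed(51)
  for (i in 1:20) {
    x <- runif(sample(1:6, 1), 0, 10)
    gs <- gene_score(x)
    expect_equal(gs, gene_score(x[sample(length(x))]))  # permutation-invariant
    expect_gte(gs, min(x))
    expect_lte(gs, max(x))
  }
})

test_that("BH adjustment follows the hand step-up rule", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  # hand step-up with cumulative minimum, order preserved
  p <- c(0.30, 0.01, 0.04, 0.90)
  m <- length(p)
  o <- order(p)
  hand <- rev(cummin(rev(p[o] * m / seq_len(m))))[order(o)]
  expect_equal(bh_adjust(p), pmin(hand, 1))
  sorted <- sort(runif(20))
  expect_false(is.unsorted(bh_adjust(sorted)))
  expect_error(bh_adjust(c(0.1, 0)), "\\(0, 1\\]")
})

test_that("gene ranking applies the two-best rule then sorts with alphabetical ties", {
  m <- data.frame(
    query_id = "q",
    gene = c("G1", "G1", "G2"),
    simpheny_score = c(6, 4, 5.5),
    stringsAsFactors = FALSE
  )
  r <- rank_genes(m)
  expect_equal(r$gene, c("G2", "G1"))
  expect_equal(r$gene_score, c(5.5, 5.0))
  expect_equal(r$rank, 1:2)
  expect_equal(r$n_matches, c(1L, 2L))
  tie <- data.frame(query_id = "q", gene = c("B", "A"),
                    simpheny_score = c(3, 3), stringsAsFactors = FALSE)
  rt <- rank_genes(tie)
  expect_equal(rt$gene, c("A", "B"))
  expect_equal(rt$rank, 1:2)
  single <- rank_genes(data.frame(query_id = "q", gene = "G",
                                  simpheny_score = 2.2))
  expect_equal(single$rank, 1L)
  expect_equal(single$gene_score, 2.2)
  bad <- data.frame(query_id = c("a", "b"), gene = "G", simpheny_score = 1)
  expect_error(rank_genes(bad), "single query")
})
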