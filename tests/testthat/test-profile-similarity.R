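test_that("fractional ranks average over ties and sum to n(n+1)/2", {
  expect_equal(fractional_ranks(c(10, 20, 30)), c(1, 2, 3))
  expect_equal(fractional_ranks(c(5, 5, 9)), c(1.5, 1.5, 3))
  expect_equal(fractional_ranks(c(7, 7, 7)), c(2, 2, 2))
  expect_error(fractional_ranks(numeric()), "empty")
  set.seed(301)
  for (i in 1:50) {
    x <- sample(1:5, sample(2:30, 1), replace = TRUE)
    expect_equal(sum(fractional_ranks(x)), length(x) * (length(x) + 1) / 2)
  }
})

test_that("spearman_rho matches hand-checked values and flags degeneracy", {
  expect_equal(spearman_rho(c(3, 1, 4, 1, 5), c(3, 1, 4, 1, 5)), 1.0)
  expect_equal(spearman_rho(c(1, 2, 3), c(3, 1, 2)), -0.5)
  rho <- spearman_rho(c(1, 2, 3), c(7, 7, 7))
  expect_true(is.na(rho))
  expect_equal(attr(rho, "reason"), "constant input")
  expect_error(spearman_rho(1:3, 1:4), "length")
  expect_error(spearman_rho(1, 2), "at least 2")
})

test_that("spearman_rho obeys symmetry, monotone invariance and antisymmetry", {
  set.seed(302)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    x <- rnorm(n); y <- sample(1:6, n, replace = TRUE)
    expect_equal(spearman_rho(x, y), spearman_rho(y, x))
    expect_equal(spearman_rho(x, x), 1)
    # strictly increasing transform of x leaves the ranks unchanged
    expect_equal(spearman_rho(exp(x) + 3, y), spearman_rho(x, y))
    expect_equal(spearman_rho(x, -x), -1)
  }
})

test_that("spearman_rho agrees with stats::cor's spearman on tied data", {
  set.seed(303)
  for (i in 1:200) {
    n <- sample(2:50, 1)
    x <- sample(0:8, n, replace = TRUE)
    y <- sample(0:8, n, replace = TRUE)
    ref <- suppressWarnings(stats::cor(x, y, method = "spearman"))
    got <- spearman_rho(x, y)
    if (is.na(ref)) expect_true(is.na(got))
    else expect_equal(as.numeric(got), ref, tolerance = 1e-12)
  }
})

test_that("linear resampling hits the stated interpolation points", {
  expect_equal(resample_to_length(c(0, 2, 4), 3), c(0, 2, 4))
  expect_equal(resample_to_length(c(0, 4), 3), c(0, 2, 4))
  expect_equal(resample_to_length(rep(1, 4), 7), rep(1, 7))
  expect_error(resample_to_length(c(1, 2), 1), "target_len")
  expect_error(resample_to_length(3, 5), "at least 2")
})

make_pair_fixture <- function(shift = 6000L, strand_b = "+") {
  # gene B's locus is an exact translated copy of gene A's landscape
  ga <- gene_model("A", "c1", "+", 1200, 2500)
  gb <- gene_model("B", "c1", strand_b, 1200 + shift, 2500 + shift)
  set.seed(42)
  s <- sample(200:2400, 300, replace = TRUE)
  e <- s + sample(120:170, 300, replace = TRUE)
  frags <- fragment_set(rep("c1", 600), c(s, s + shift), c(e, e + shift))
  list(ga = ga, gb = gb, frags = frags)
}

test_that("a translated identical landscape yields rho = 1 in both regions", {
  fx <- make_pair_fixture()
  res <- compare_paralog_pair(fx$ga, fx$gb, fx$frags)
  expect_s3_class(res, "pair_similarity")
  expect_equal(res$promoter_rho, 1.0)
  expect_equal(res$coding_rho, 1.0)
  expect_false(res$resampled)
  expect_equal(res$promoter_n, 1000L)
  expect_equal(res$coding_n, 1300L)
})

test_that("a gene compared against itself gives rho = 1", {
  fx <- make_pair_fixture()
  res <- compare_paralog_pair(fx$ga, fx$ga, fx$frags)
  expect_equal(res$promoter_rho, 1.0)
  expect_equal(res$coding_rho, 1.0)
})

test_that("a fragment-free locus propagates an explicit undefined rho", {
  fx <- make_pair_fixture()
  gb_empty <- gene_model("Bempty", "c1", "+", 50000, 51300)
  res <- compare_paralog_pair(fx$ga, gb_empty, fx$frags)
  expect_true(is.na(res$promoter_rho))
  expect_true(is.na(res$coding_rho))
  expect_equal(res$promoter_reason, "constant profile")
  expect_equal(res$coding_reason, "constant profile")
})

test_that("unequal coding lengths are reconciled per the length policy", {
  fx <- make_pair_fixture()
  gb_short <- gene_model("Bshort", "c1", "+", 7200, 8100)  # 900 vs 1300 bp
  res <- compare_paralog_pair(fx$ga, gb_short, fx$frags)
  expect_true(res$resampled)
  expect_equal(res$coding_n, 900L)
  expect_equal(res$promoter_n, 1000L)   # promoters never resampled
  trunc <- compare_paralog_pair(fx$ga, gb_short, fx$frags,
                                length_policy = "truncate_min")
  expect_false(trunc$resampled)
  expect_equal(trunc$coding_n, 900L)
})

test_that("pair comparison is invariant under mirroring the genome", {
  fx <- make_pair_fixture(strand_b = "-")
  res <- compare_paralog_pair(fx$ga, fx$gb, fx$frags)
  pivot <- max(fx$frags$end, fx$gb$end) + 2000L
  mres <- compare_paralog_pair(mirror_gene(fx$ga, pivot),
                               mirror_gene(fx$gb, pivot),
                               mirror_fragments(fx$frags, pivot))
  expect_equal(mres, res)
})
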