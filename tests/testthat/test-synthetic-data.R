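test_that("architecture constructor enforces weight and jitter bounds", {
  expect_error(nuc_architecture(0L, 1.2), "weights")
  expect_error(nuc_architecture(0L, 0.5, jitter_sd = -1), "jitter")
  arch <- nuc_architecture(c(-500L, 80L), c(0.9, 0.5), jitter_sd = c(5, 10))
  expect_equal(nrow(arch$dyads), 2L)
})

test_that("degenerate noise settings give identical fragments on one dyad", {
  arch <- nuc_architecture(100L, 1, jitter_sd = 0, fragment_len_mean = 147,
                           fragment_len_sd = 0, background_rate = 0)
  gene <- gene_model("g", "c1", "+", 2000, 3300)
  cfg <- sim_config(seed = 5, depth = 5L)
  frags <- simulate_fragments(arch, gene, cfg)
  expect_gt(nrow(frags), 0L)
  expect_equal(length(unique(frags$start)), 1L)
  expect_true(all(frags$end - frags$start == 147L))
  # dyad offset 100 on + strand -> genomic center 2100
  expect_equal(frags$start[1] + 73L, 2100L)
})

test_that("zero dyads and zero background give an empty fragment set", {
  arch <- nuc_architecture(integer(), numeric(), background_rate = 0)
  gene <- gene_model("g", "c1", "+", 2000, 3300)
  expect_equal(nrow(simulate_fragments(arch, gene, sim_config(1))), 0L)
})

test_that("fragment simulation is byte-deterministic given the seed", {
  gene <- gene_model("g", "c1", "-", 3000, 4300)
  cfg <- sim_config(seed = 99, depth = 30L)
  set.seed(7); arch <- random_nuc_architecture(-1000, 1300, background_rate = 0.01)
  f1 <- tempfile(); f2 <- tempfile()
  write_fragments_bed(simulate_fragments(arch, gene, cfg), f1)
  write_fragments_bed(simulate_fragments(arch, gene, cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("fragments per dyad match depth x weight in expectation", {
  arch <- nuc_architecture(200L, 0.8, jitter_sd = 0, background_rate = 0)
  gene <- gene_model("g", "c1", "+", 2000, 3300)
  n <- vapply(1:200, function(s)
    nrow(simulate_fragments(arch, gene, sim_config(seed = s, depth = 50L))),
    numeric(1))
  expect_lt(abs(mean(n) - 50 * 0.8) / (50 * 0.8), 0.05)
})

test_that("paralog pair loci are disjoint and the shared flags drive rho", {
  sim <- make_paralog_pair(sim_config(seed = 11))
  # no fragment touches both genes' windows (promoter + coding)
  a_hi <- sim$gene_a$end
  b_lo <- sim$gene_b$start
  expect_true(all(sim$fragments$end <= b_lo | sim$fragments$start >= a_hi))
  res <- compare_paralog_pair(sim$gene_a, sim$gene_b, sim$fragments)
  expect_gt(res$coding_rho, res$promoter_rho)

  both <- make_paralog_pair(sim_config(seed = 11), promoter_shared = TRUE,
                            coding_shared = TRUE)
  rboth <- compare_paralog_pair(both$gene_a, both$gene_b, both$fragments)
  expect_gt(rboth$promoter_rho, 0.5)
  expect_gt(rboth$coding_rho, 0.5)
})

test_that("promoter occupancy boost raises promoter over coding occupancy", {
  for (s in 1:3) {
    sim <- make_paralog_pair(sim_config(seed = s, promoter_occupancy_boost = 1.5))
    for (g in list(sim$gene_a, sim$gene_b)) {
      prom <- compute_occupancy(sim$fragments, promoter_interval(g, 1000))
      cod <- compute_occupancy(sim$fragments, coding_interval(g))
      expect_gt(mean(prom$counts), mean(cod$counts))
    }
  }
})

test_that("gene tree simulation is deterministic and validates species", {
  s1 <- simulate_gene_tree(8, 2, seed = 123)
  s2 <- simulate_gene_tree(8, 2, seed = 123)
  expect_identical(s1$newick, s2$newick)
  expect_error(simulate_gene_tree(4, "sp99", seed = 1), "unknown species")
  expect_error(simulate_gene_tree(3, 4, seed = 1), "more duplications")
})

test_that("planted duplications are recovered exactly, repeats included", {
  zero <- simulate_gene_tree(6, 0, seed = 9)
  expect_equal(label_duplications(zero$tree)$n_duplications, 0L)
  expect_equal(nrow(sister_paralog_pairs(zero$tree)), 0L)

  one <- simulate_gene_tree(5, "sp01", seed = 2)
  expect_equal(label_duplications(one$tree)$n_duplications, 1L)
  expect_equal(sister_paralog_pairs(one$tree)$species, "sp01")

  # nested events in one species: both grafts count as duplications
  nested <- simulate_gene_tree(5, c("sp02", "sp02"), seed = 3)
  expect_equal(label_duplications(nested$tree)$n_duplications, 2L)
  got <- sister_paralog_pairs(nested$tree)
  expect_equal(got[order(got$species, got$gene_a),
                   c("species", "gene_a", "gene_b")],
               nested$planted_pairs, ignore_attr = TRUE)
})
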