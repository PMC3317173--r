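test_that("BED reading keeps coordinates and rejects malformed lines", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("track name=frags", "c1\t0\t147\tfrag1\t0\t+"), bed)
  fs <- read_fragments_bed(bed)
  expect_equal(nrow(fs), 1L)
  expect_equal(fs$end - fs$start, 147L)

  writeLines(character(), bed)
  expect_equal(nrow(read_fragments_bed(bed)), 0L)

  writeLines("c1\t5\t5", bed)
  expect_error(read_fragments_bed(bed), "line 1")
  writeLines(c("c1\t0\t10", "c1\tx\t10"), bed)
  expect_error(read_fragments_bed(bed), "line 2")
})

test_that("coverage counts match the worked example and reverse on -", {
  fs <- fragment_set(c("c", "c"), c(0, 3), c(5, 8))
  int_plus <- genomic_interval("c", 0, 10, "+", "coding")
  prof <- compute_occupancy(fs, int_plus, gene_id = "g")
  expect_equal(prof$counts, c(1L, 1L, 1L, 2L, 2L, 1L, 1L, 1L, 0L, 0L))
  int_minus <- genomic_interval("c", 0, 10, "-", "coding")
  expect_equal(compute_occupancy(fs, int_minus)$counts,
               rev(prof$counts))
})

test_that("empty and missing-chromosome inputs give zero profiles", {
  int <- genomic_interval("c9", 0, 20, "+", "coding")
  expect_equal(compute_occupancy(fragment_set(), int)$counts, integer(20))
  fs <- fragment_set("c1", 0, 10)
  expect_warning(prof <- compute_occupancy(fs, int), "c9")
  expect_equal(sum(prof$counts), 0L)
})

test_that("dyad mode counts fragment midpoints with the lower-middle tie rule", {
  # length 4 fragment [0,4): central positions 1 and 2, tie -> 1
  fs <- fragment_set(c("c", "c"), c(0, 10), c(4, 15))  # mids 1 and 12
  int <- genomic_interval("c", 0, 20, "+", "coding")
  prof <- compute_occupancy(fs, int, mode = "dyad")
  expect_equal(which(prof$counts == 1L) - 1L, c(1L, 12L))
  expect_equal(sum(prof$counts), 2L)
  # a midpoint outside the interval is not counted
  int2 <- genomic_interval("c", 0, 5, "+", "coding")
  expect_equal(sum(compute_occupancy(fs, int2, mode = "dyad")$counts), 1L)
})

test_that("occupancy agrees with the brute-force oracle on random instances", {
  set.seed(202)
  for (i in 1:150) {
    fs <- random_fragments(sample(0:12, 1), span = 60L)
    start <- sample(0:40, 1); end <- start + sample.int(20, 1)
    strand <- sample(c("+", "-"), 1)
    int <- genomic_interval("c1", start, end, strand, "coding")
    for (mode in c("coverage", "dyad")) {
      expected <- oracle_occupancy(fs, "c1", start, end, mode)
      if (strand == "-") expected <- rev(expected)
      expect_equal(compute_occupancy(fs, int, mode = mode)$counts, expected)
    }
  }
})

test_that("adding a fragment never decreases any count", {
  set.seed(203)
  int <- genomic_interval("c1", 5, 45, "+", "coding")
  fs <- random_fragments(10, span = 60L)
  base <- compute_occupancy(fs, int)$counts
  grown <- fragment_set(c(fs$chrom, "c1"), c(fs$start, 20), c(fs$end, 40))
  expect_true(all(compute_occupancy(grown, int)$counts >= base))
})

test_that("bedGraph output merges runs and round-trips the counts", {
  fs <- fragment_set(c("c", "c"), c(100, 100), c(102, 102))
  int <- genomic_interval("c", 100, 103, "+", "coding")
  prof <- compute_occupancy(fs, int)
  path <- tempfile(fileext = ".bedGraph")
  write_profile_bedgraph(prof, path)
  expect_equal(readLines(path), c("c\t100\t102\t2", "c\t102\t103\t0"))
  expect_equal(paranuc:::.expand_bedgraph(path), prof$counts)

  # all-zero profile collapses to a single run
  zero <- compute_occupancy(fragment_set(), int)
  write_profile_bedgraph(zero, path)
  expect_equal(readLines(path), "c\t100\t103\t0")

  # minus-strand profiles are written back in genomic order
  set.seed(204)
  fsr <- random_fragments(15, span = 80L)
  intm <- genomic_interval("c1", 10, 60, "-", "coding")
  profm <- compute_occupancy(fsr, intm)
  write_profile_bedgraph(profm, path)
  expect_equal(paranuc:::.expand_bedgraph(path), rev(profm$counts))
})

test_that("fragment length filter keeps the mononucleosome-sized range", {
  fs <- fragment_set(rep("c", 3), c(0, 0, 0), c(100, 147, 200))
  kept <- filter_fragment_length(fs, 120, 180)
  expect_equal(kept$end, 147L)
})
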