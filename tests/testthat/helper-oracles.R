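# Independent oracles and small utilities used across the test files.
# These deliberately avoid the package's own code paths (and, for the rank
# correlation, base rank()/cor()) so they can arbitrate.

# Per-position fragment overlap / midpoint counts by exhaustive looping.
oracle_occupancy <- function(frags, chrom, start, end, mode = "coverage") {
  width <- end - start
  counts <- integer(width)
  for (i in seq_len(nrow(frags))) {
    if (frags$chrom[i] != chrom) next
    fs <- frags$start[i]; fe <- frags$end[i]
    if (mode == "coverage") {
      for (pos in seq.int(start, end - 1L)) {
        if (pos >= fs && pos < fe) counts[pos - start + 1L] <- counts[pos - start + 1L] + 1L
      }
    } else {
      mid <- fs + (fe - fs - 1L) %/% 2L
      if (mid >= start && mid < end) counts[mid - start + 1L] <- counts[mid - start + 1L] + 1L
    }
  }
  counts
}

# Spearman for tie-free data via the classical 6*sum(d^2) closed form.
oracle_spearman_noties <- function(x, y) {
  n <- length(x)
  rx <- vapply(x, function(v) sum(x <= v), numeric(1))
  ry <- vapply(y, function(v) sum(y <= v), numeric(1))
  1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
}

# Tie-aware Spearman: average ranks computed by counting, Pearson by the
# raw-sum formula. No rank(), no cor().
oracle_spearman_ties <- function(x, y) {
  avg_rank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  }
  a <- avg_rank(x); b <- avg_rank(y)
  n <- length(a)
  num <- n * sum(a * b) - sum(a) * sum(b)
  den <- sqrt((n * sum(a^2) - sum(a)^2) * (n * sum(b^2) - sum(b)^2))
  if (den == 0) return(NA_real_)
  num / den
}

# All permutations of a vector (n <= 7 or so).
all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_permutations(v[-i])) out[[length(out) + 1L]] <- c(v[[i]], rest)
  }
  out
}

# Reflect a gene / fragment set about pivot P (position x -> P - x, so the
# half-open interval [s, e) maps to [P - e, P - s)) and flip strands.
mirror_gene <- function(gene, pivot) {
  gene_model(gene$gene_id, gene$chrom,
             if (gene$strand == "+") "-" else "+",
             start = pivot - gene$end, end = pivot - gene$start,
             species = gene$species)
}

mirror_fragments <- function(frags, pivot) {
  if (nrow(frags) == 0L) return(fragment_set())
  fragment_set(frags$chrom, pivot - frags$end, pivot - frags$start)
}

# Random small fragment set on one chromosome, coordinates in [0, span).
random_fragments <- function(n, span = 100L, chrom = "c1") {
  if (n == 0L) return(fragment_set())
  s <- sample.int(span - 1L, n, replace = TRUE) - 1L
  len <- sample.int(20L, n, replace = TRUE)
  fragment_set(rep(chrom, n), s, pmin(s + len, span))
}
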