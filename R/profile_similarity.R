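#' Fractional (tie-averaged) ranks
#'
#' Ranks 1..n with tied values receiving the mean of the ranks they span,
#' so that `sum(fractional_ranks(x)) == n * (n + 1) / 2` always holds.
#'
#' @param values numeric vector, length >= 1, no missing values.
#' @return numeric rank vector of the same length.
#' @export
fractional_ranks <- function(values) {
  if (length(values) < 1L)
    stop("fractional_ranks: empty input", call. = FALSE)
  if (anyNA(values))
    stop("fractional_ranks: missing values not allowed", call. = FALSE)
  rank(values, ties.method = "average")
}

#' Spearman rank correlation (tie-aware)
#'
#' Defined as the Pearson product-moment correlation of the fractional
#' ranks of `x` and `y` — the definition that remains correct under ties
#' (the 6*sum(d^2) shortcut does not). When either input is constant the
#' correlation is undefined and `NA` is returned with a `"reason"`
#' attribute, never a fabricated 0.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return the correlation in `[-1, 1]`, or `NA` (attribute `reason =
#'   "constant input"`) when either vector has zero rank variance.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y))
    stop("spearman_rho: length mismatch (", length(x), " vs ", length(y), ")",
         call. = FALSE)
  if (length(x) < 2L)
    stop("spearman_rho: need at least 2 observations", call. = FALSE)
  rx <- fractional_ranks(x)
  ry <- fractional_ranks(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    return(structure(NA_real_, reason = "constant input"))
  stats::cor(rx, ry)
}

#' Linearly resample a profile to a target length
#'
#' Evaluates the piecewise-linear interpolant of `counts` at `target_len`
#' equally spaced points spanning the original index range (endpoints
#' included). Used to reconcile coding regions of unequal length before
#' rank correlation; a rank-based comparison is unaffected by the positive
#' local averaging this introduces.
#'
#' @param counts numeric vector, length >= 2.
#' @param target_len integer >= 2.
#' @return numeric vector of length `target_len`; identical to `counts`
#'   when `target_len == length(counts)`.
#' @export
resample_to_length <- function(counts, target_len) {
  target_len <- as.integer(target_len)
  if (is.na(target_len) || target_len < 2L)
    stop("resample_to_length: target_len must be >= 2", call. = FALSE)
  if (length(counts) < 2L)
    stop("resample_to_length: need at least 2 points", call. = FALSE)
  if (target_len == length(counts)) return(as.numeric(counts))
  stats::approx(x = seq_along(counts), y = counts, n = target_len)$y
}

# Reconcile two oriented count vectors to a common length per policy.
# Returns list(a, b, n, resampled).
.reconcile_lengths <- function(a, b, policy) {
  if (length(a) == length(b))
    return(list(a = as.numeric(a), b = as.numeric(b), n = length(a),
                resampled = FALSE))
  n <- min(length(a), length(b))
  if (policy == "truncate_min") {
    list(a = as.numeric(a[seq_len(n)]), b = as.numeric(b[seq_len(n)]),
         n = n, resampled = FALSE)
  } else {
    list(a = if (length(a) == n) as.numeric(a) else resample_to_length(a, n),
         b = if (length(b) == n) as.numeric(b) else resample_to_length(b, n),
         n = n, resampled = TRUE)
  }
}

#' Compare the nucleosome profiles of a paralog pair
#'
#' Builds oriented promoter and coding occupancy profiles for both genes
#' from the same fragment set and computes the Spearman rank correlation of
#' each region pair. Promoter windows are equal-length by construction
#' (barring boundary truncation); coding regions of unequal length are
#' reconciled by `length_policy`: `"resample_min"` linearly interpolates
#' the longer profile onto the shorter one's point count, `"truncate_min"`
#' keeps the 5'-most common-length prefix of both.
#'
#' @param gene_a,gene_b [gene_model] objects.
#' @param frags a [fragment_set] covering both loci.
#' @param upstream_len promoter window length in bases (default 1000).
#' @param mode occupancy counting mode, `"coverage"` or `"dyad"`.
#' @param length_policy `"resample_min"` (default) or `"truncate_min"`.
#' @return an object of class `pair_similarity` with fields `gene_a`,
#'   `gene_b`, `promoter_rho`, `coding_rho`, `promoter_n`, `coding_n`,
#'   `resampled`, `mode`, `length_policy`, and per-region `*_reason`
#'   strings explaining any undefined correlation.
#' @export
compare_paralog_pair <- function(gene_a, gene_b, frags, upstream_len = 1000L,
                                 mode = c("coverage", "dyad"),
                                 length_policy = c("resample_min",
                                                   "truncate_min")) {
  mode <- match.arg(mode)
  length_policy <- match.arg(length_policy)
  stopifnot(inherits(gene_a, "gene_model"), inherits(gene_b, "gene_model"))

  region_rho <- function(region) {
    make <- function(g) {
      int <- if (region == "promoter")
        promoter_interval(g, upstream_len) else coding_interval(g)
      compute_occupancy(frags, int, mode = mode, gene_id = g$gene_id)
    }
    pa <- make(gene_a); pb <- make(gene_b)
    rec <- .reconcile_lengths(pa$counts, pb$counts, length_policy)
    rho <- spearman_rho(rec$a, rec$b)
    reason <- if (is.na(rho)) "constant profile" else NA_character_
    list(rho = as.numeric(rho), n = rec$n, resampled = rec$resampled,
         reason = reason)
  }

  prom <- region_rho("promoter")
  cod <- region_rho("coding")
  structure(
    list(gene_a = gene_a$gene_id, gene_b = gene_b$gene_id,
         promoter_rho = prom$rho, coding_rho = cod$rho,
         promoter_n = prom$n, coding_n = cod$n,
         resampled = prom$resampled || cod$resampled,
         mode = mode, length_policy = length_policy,
         promoter_reason = prom$reason, coding_reason = cod$reason),
    class = "pair_similarity")
}

.fmt_rho <- function(rho) if (is.na(rho)) "NA" else sprintf("%.6f", rho)

#' @export
print.pair_similarity <- function(x, ...) {
  cat(sprintf("<pair_similarity> %s vs %s  (mode=%s, policy=%s%s)\n",
              x$gene_a, x$gene_b, x$mode, x$length_policy,
              if (x$resampled) ", resampled" else ""))
  cat(sprintf("  promoter rho = %s  (n = %d)%s\n", .fmt_rho(x$promoter_rho),
              x$promoter_n,
              if (is.na(x$promoter_rho)) paste0("  [", x$promoter_reason, "]") else ""))
  cat(sprintf("  coding   rho = %s  (n = %d)%s\n", .fmt_rho(x$coding_rho),
              x$coding_n,
              if (is.na(x$coding_rho)) paste0("  [", x$coding_reason, "]") else ""))
  invisible(x)
}

#' @export
as.data.frame.pair_similarity <- function(x, ...) {
  data.frame(
    gene_a = x$gene_a, gene_b = x$gene_b,
    region = c("promoter", "coding"),
    rho = c(x$promoter_rho, x$coding_rho),
    n = c(x$promoter_n, x$coding_n),
    resampled = x$resampled, mode = x$mode, policy = x$length_policy,
    reason = c(x$promoter_reason, x$coding_reason),
    stringsAsFactors = FALSE)
}
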