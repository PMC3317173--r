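#' Nucleosomal fragment set
#'
#' A collection of mapped nucleosomal DNA fragment intervals on named
#' sequences, stored 0-based half-open (the BED convention).
#'
#' @param chrom character vector of sequence names.
#' @param start,end integer vectors, 0-based half-open; `start < end`
#'   elementwise.
#' @return a data frame of class `fragment_set` with columns
#'   `chrom`, `start`, `end`.
#' @export
fragment_set <- function(chrom = character(), start = integer(),
                         end = integer()) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  start <- as.integer(start); end <- as.integer(end)
  if (any(is.na(start) | is.na(end)))
    stop("fragment_set: non-integer coordinates", call. = FALSE)
  if (any(start < 0L)) stop("fragment_set: negative start", call. = FALSE)
  if (any(end <= start))
    stop("fragment_set: every fragment must satisfy start < end", call. = FALSE)
  structure(data.frame(chrom = as.character(chrom), start = start, end = end,
                       stringsAsFactors = FALSE),
            class = c("fragment_set", "data.frame"))
}

#' Read nucleosomal fragments from a BED file
#'
#' Accepts BED3+ (extra columns ignored); `track`, `browser` and `#` lines
#' are skipped. Coordinates are 0-based half-open and are kept as read.
#'
#' @param path path to the BED file.
#' @return a [fragment_set].
#' @export
read_fragments_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b|\\s*$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) return(fragment_set())
  chrom <- character(length(idx)); s <- integer(length(idx)); e <- integer(length(idx))
  for (k in seq_along(idx)) {
    i <- idx[[k]]
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("BED parse error at line ", i, ": expected >= 3 columns", call. = FALSE)
    si <- suppressWarnings(as.integer(f[[2]]))
    ei <- suppressWarnings(as.integer(f[[3]]))
    if (is.na(si) || is.na(ei))
      stop("BED parse error at line ", i, ": non-integer coordinates", call. = FALSE)
    if (si >= ei)
      stop("BED parse error at line ", i, ": start (", si,
           ") must be < end (", ei, ")", call. = FALSE)
    chrom[[k]] <- f[[1]]; s[[k]] <- si; e[[k]] <- ei
  }
  fragment_set(chrom, s, e)
}

#' Write a fragment set as BED3
#'
#' Fragments are written sorted by (chrom, start, end) so identical sets
#' always serialize to identical bytes.
#'
#' @param frags a [fragment_set].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fragments_bed <- function(frags, path) {
  stopifnot(inherits(frags, "fragment_set"))
  o <- order(frags$chrom, frags$start, frags$end)
  writeLines(sprintf("%s\t%d\t%d", frags$chrom[o], frags$start[o],
                     frags$end[o]), path)
  invisible(path)
}

#' Keep fragments within a length range
#'
#' Convenience filter for mononucleosome-sized fragments (e.g. 120-180 bp
#' for MNase-style data). No filter is applied by default anywhere in the
#' pipeline.
#'
#' @param frags a [fragment_set].
#' @param min_len,max_len inclusive length bounds.
#' @return the filtered [fragment_set].
#' @export
filter_fragment_length <- function(frags, min_len = 120L, max_len = 180L) {
  stopifnot(inherits(frags, "fragment_set"))
  len <- frags$end - frags$start
  out <- frags[len >= min_len & len <= max_len, , drop = FALSE]
  class(out) <- c("fragment_set", "data.frame")
  out
}

# 0-based midpoint of a fragment; even lengths tie to the lower of the two
# central positions.
.fragment_midpoints <- function(start, end) {
  start + (end - start - 1L) %/% 2L
}

#' Per-nucleotide occupancy profile over a gene region
#'
#' Counts, for every nucleotide of `interval`, the nucleosomal fragments
#' overlapping that position (`mode = "coverage"`) or centered at it
#' (`mode = "dyad"`; even-length fragments tie to the lower central
#' position). The resulting vector is oriented to the gene: index 1 is the
#' 5'-most position of the region in gene orientation, so the vector is
#' reversed for `-` strand intervals. Overlap is half-open: a fragment
#' ending exactly at a position does not cover it.
#'
#' @param frags a [fragment_set].
#' @param interval a [genomic_interval] (from [promoter_interval] or
#'   [coding_interval]).
#' @param mode `"coverage"` (default) or `"dyad"`.
#' @param gene_id identifier recorded in the profile.
#' @return an object of class `occupancy_profile` with fields `gene_id`,
#'   `region_label`, `counts` (oriented integer vector), `interval`, `mode`.
#' @export
compute_occupancy <- function(frags, interval, mode = c("coverage", "dyad"),
                              gene_id = NA_character_) {
  mode <- match.arg(mode)
  stopifnot(inherits(frags, "fragment_set"), inherits(interval, "genomic_interval"))
  width <- interval_width(interval)
  on_chrom <- frags$chrom == interval$chrom
  if (nrow(frags) > 0L && !any(on_chrom))
    warning("no fragments on sequence ", dQuote(interval$chrom),
            "; returning an all-zero profile", call. = FALSE)
  fr <- frags[on_chrom, , drop = FALSE]
  counts <- if (mode == "coverage") {
    ov <- fr$start < interval$end & fr$end > interval$start
    fr <- fr[ov, , drop = FALSE]
    if (nrow(fr) == 0L) integer(width) else {
      # clip to the interval and shift to 1-based window coordinates
      ir <- IRanges::IRanges(
        start = pmax(fr$start, interval$start) - interval$start + 1L,
        end = pmin(fr$end, interval$end) - interval$start)
      as.integer(IRanges::coverage(ir, width = width))
    }
  } else {
    mids <- .fragment_midpoints(fr$start, fr$end)
    inside <- mids >= interval$start & mids < interval$end
    tabulate(mids[inside] - interval$start + 1L, nbins = width)
  }
  if (interval$strand == "-") counts <- rev(counts)
  structure(
    list(gene_id = gene_id, region_label = interval$label,
         counts = as.integer(counts), interval = interval, mode = mode),
    class = "occupancy_profile")
}

#' @export
print.occupancy_profile <- function(x, ...) {
  cat(sprintf(
    "<occupancy_profile> %s %s  %s:%d-%d (%s)  mode=%s  n=%d  total=%d\n",
    x$gene_id, x$region_label, x$interval$chrom, x$interval$start,
    x$interval$end, x$interval$strand, x$mode, length(x$counts),
    sum(x$counts)))
  invisible(x)
}

#' Write an occupancy profile as bedGraph
#'
#' Counts are written in genomic (unoriented) coordinates; runs of equal
#' counts are merged into single bedGraph records.
#'
#' @param profile an `occupancy_profile` from [compute_occupancy].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_profile_bedgraph <- function(profile, path) {
  stopifnot(inherits(profile, "occupancy_profile"))
  counts <- profile$counts
  if (profile$interval$strand == "-") counts <- rev(counts)  # back to genomic order
  r <- rle(counts)
  ends <- profile$interval$start + cumsum(r$lengths)
  starts <- ends - r$lengths
  writeLines(sprintf("%s\t%d\t%d\t%d", profile$interval$chrom, starts, ends,
                     r$values), path)
  invisible(path)
}

# Re-expand a bedGraph written by write_profile_bedgraph into the per-base
# genomic-order count vector (used for round-trip checks).
.expand_bedgraph <- function(path) {
  bg <- utils::read.table(path, sep = "\t",
                          col.names = c("chrom", "start", "end", "count"))
  rep(bg$count, times = bg$end - bg$start)
}
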