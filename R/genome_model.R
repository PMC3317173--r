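#' Gene coordinate model
#'
#' A `gene_model` stores one gene's genomic span in 0-based half-open
#' coordinates, together with its strand, chromosome and optional species.
#' `start`/`end` are always the lower/upper genomic coordinates of the span
#' between the translational start and end sites; for a `-` strand gene the
#' translational start therefore sits at genomic position `end - 1`.
#'
#' @param gene_id character gene identifier.
#' @param chrom character chromosome / contig name (nonempty).
#' @param strand `"+"` or `"-"`.
#' @param start 0-based inclusive lower coordinate of the coding span.
#' @param end 0-based exclusive upper coordinate of the coding span.
#' @param species optional species label (default `NA`).
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, start, end, species = NA_character_) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L, nzchar(gene_id))
  if (!is.character(chrom) || length(chrom) != 1L || !nzchar(chrom))
    stop("gene_model: 'chrom' must be a nonempty string", call. = FALSE)
  if (!strand %in% c("+", "-"))
    stop("gene_model: strand must be '+' or '-', got ", dQuote(strand), call. = FALSE)
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L)
    stop("gene_model: coordinates must be non-negative integers", call. = FALSE)
  if (end <= start)
    stop("gene_model: end (", end, ") must exceed start (", start, ") for gene ",
         gene_id, call. = FALSE)
  structure(
    list(gene_id = gene_id, species = as.character(species), chrom = chrom,
         strand = strand, start = start, end = end),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s  %s:%d-%d (%s)%s\n", x$gene_id, x$chrom,
              x$start, x$end, x$strand,
              if (is.na(x$species)) "" else paste0("  species=", x$species)))
  invisible(x)
}

#' Genomic interval record
#'
#' Plain coordinate carrier for extracted gene regions, 0-based half-open.
#'
#' @param chrom chromosome name.
#' @param start,end 0-based half-open bounds, `start < end`.
#' @param strand `"+"` or `"-"` (orientation of the owning gene).
#' @param label `"promoter"` or `"coding"`.
#' @param truncated logical; `TRUE` when the interval was clipped at a
#'   sequence boundary.
#' @return an object of class `genomic_interval`.
#' @export
genomic_interval <- function(chrom, start, end, strand, label,
                             truncated = FALSE) {
  start <- as.integer(start); end <- as.integer(end)
  if (end <= start)
    stop("genomic_interval: empty interval [", start, ", ", end, ")", call. = FALSE)
  if (!strand %in% c("+", "-")) stop("genomic_interval: bad strand", call. = FALSE)
  if (!label %in% c("promoter", "coding"))
    stop("genomic_interval: label must be 'promoter' or 'coding'", call. = FALSE)
  structure(
    list(chrom = chrom, start = start, end = end, strand = strand,
         label = label, truncated = isTRUE(truncated)),
    class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<genomic_interval> %s:%d-%d (%s) %s%s\n", x$chrom, x$start,
              x$end, x$strand, x$label,
              if (x$truncated) " [truncated]" else ""))
  invisible(x)
}

#' Width of a genomic interval
#' @param interval a `genomic_interval`.
#' @return integer number of bases spanned.
#' @export
interval_width <- function(interval) interval$end - interval$start

#' Read gene models from a TSV or GFF3 annotation
#'
#' TSV input has columns gene_id, chrom, strand, start, end (1-based
#' inclusive, tab- or space-separated) and optionally a sixth species column;
#' lines starting with `#` are skipped. GFF3 input is parsed with
#' \code{rtracklayer::readGFF}; one feature row of `feature_type` per gene is
#' expected (multiple rows sharing an identifier, e.g. CDS parts, are merged
#' to their enclosing span). All coordinates are converted to the internal
#' 0-based half-open convention.
#'
#' @param path file path to the annotation.
#' @param format `"tsv"` or `"gff3"`.
#' @param gene_id_attr GFF3 attribute holding the gene identifier
#'   (default `"ID"`).
#' @param feature_type GFF3 feature type to use (default `"gene"`).
#' @return a named list of [gene_model] objects.
#' @export
read_gene_table <- function(path, format = c("tsv", "gff3"),
                            gene_id_attr = "ID", feature_type = "gene") {
  format <- match.arg(format)
  genes <- if (format == "tsv") {
    .read_gene_tsv(path)
  } else {
    .read_gene_gff3(path, gene_id_attr = gene_id_attr,
                    feature_type = feature_type)
  }
  if (anyDuplicated(names(genes)))
    stop("duplicated gene_id in ", path, ": ",
         paste(unique(names(genes)[duplicated(names(genes))]), collapse = ", "),
         call. = FALSE)
  genes
}

.read_gene_tsv <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  out <- list()
  for (i in which(keep)) {
    f <- strsplit(trimws(lines[[i]]), "[ \t]+")[[1]]
    if (length(f) < 5L)
      stop("gene TSV parse error at line ", i, ": expected >= 5 columns, got ",
           length(f), call. = FALSE)
    start1 <- suppressWarnings(as.integer(f[[4]]))
    end1 <- suppressWarnings(as.integer(f[[5]]))
    if (is.na(start1) || is.na(end1))
      stop("gene TSV parse error at line ", i,
           ": non-integer coordinates", call. = FALSE)
    g <- tryCatch(
      gene_model(f[[1]], f[[2]], f[[3]], start = start1 - 1L, end = end1,
                 species = if (length(f) >= 6L) f[[6]] else NA_character_),
      error = function(e) stop("gene TSV validation error at line ", i, ": ",
                               conditionMessage(e), call. = FALSE))
    out[[g$gene_id]] <- g
  }
  out
}

.read_gene_gff3 <- function(path, gene_id_attr = "ID", feature_type = "gene") {
  gff <- rtracklayer::readGFF(path)
  gff <- as.data.frame(gff)
  rows <- gff[gff$type == feature_type, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("no '", feature_type, "' features found in ", path, call. = FALSE)
  if (!gene_id_attr %in% names(rows))
    stop("GFF3 attribute ", dQuote(gene_id_attr), " not present in ", path,
         call. = FALSE)
  ids <- as.character(rows[[gene_id_attr]])
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("GFF3 rows with missing ", dQuote(gene_id_attr), " attribute in ",
         path, call. = FALSE)
  out <- list()
  for (id in unique(ids)) {
    r <- rows[ids == id, , drop = FALSE]
    strand <- unique(as.character(r$strand))
    if (length(strand) != 1L || !strand %in% c("+", "-"))
      stop("GFF3 gene ", id, ": strand must be a single '+' or '-'",
           call. = FALSE)
    chrom <- unique(as.character(r$seqid))
    if (length(chrom) != 1L)
      stop("GFF3 gene ", id, ": features on multiple sequences", call. = FALSE)
    # GFF3 is 1-based inclusive; merged span of all parts sharing the id
    out[[id]] <- gene_model(id, chrom, strand,
                            start = min(r$start) - 1L, end = max(r$end))
  }
  out
}

#' Promoter window of a gene
#'
#' The promoter is the `upstream_len` bases immediately upstream of the
#' translational start site, on the gene's own strand: for a `+` strand gene
#' the window `[start - upstream_len, start)`, for a `-` strand gene
#' `[end, end + upstream_len)`. A window running off the start of the
#' sequence (or past `chrom_len`, when known) is kept as the clipped
#' remainder with `truncated = TRUE`.
#'
#' @param gene a [gene_model].
#' @param upstream_len window length in bases (default 1000).
#' @param chrom_len optional sequence length used to clip the upstream window
#'   of `-` strand genes.
#' @return a [genomic_interval] labelled `"promoter"`.
#' @export
promoter_interval <- function(gene, upstream_len = 1000L, chrom_len = NULL) {
  stopifnot(inherits(gene, "gene_model"))
  upstream_len <- as.integer(upstream_len)
  if (is.na(upstream_len) || upstream_len < 1L)
    stop("promoter_interval: upstream_len must be >= 1", call. = FALSE)
  if (gene$strand == "+") {
    lo <- gene$start - upstream_len; hi <- gene$start
  } else {
    lo <- gene$end; hi <- gene$end + upstream_len
  }
  trunc <- FALSE
  if (lo < 0L) { lo <- 0L; trunc <- TRUE }
  if (!is.null(chrom_len) && hi > chrom_len) { hi <- as.integer(chrom_len); trunc <- TRUE }
  if (hi <= lo)
    stop("promoter_interval: region of gene ", gene$gene_id,
         " is empty after truncation at the sequence boundary", call. = FALSE)
  genomic_interval(gene$chrom, lo, hi, gene$strand, "promoter", truncated = trunc)
}

#' Coding window of a gene
#'
#' The full genomic span between the translational start and end sites.
#' Introns, where present, are not excised: the comparison operates on the
#' genomic window (a warning is emitted when `has_introns` is set).
#'
#' @param gene a [gene_model].
#' @param has_introns set `TRUE` to acknowledge (with a warning) that the
#'   span contains introns which will be included.
#' @return a [genomic_interval] labelled `"coding"`.
#' @export
coding_interval <- function(gene, has_introns = FALSE) {
  stopifnot(inherits(gene, "gene_model"))
  if (isTRUE(has_introns))
    warning("coding_interval: genomic span of ", gene$gene_id,
            " includes introns; they are not excised", call. = FALSE)
  genomic_interval(gene$chrom, gene$start, gene$end, gene$strand, "coding")
}
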