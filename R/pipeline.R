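#' @keywords internal
.validation_error <- function(...) {
  stop(structure(class = c("paranuc_validation_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null", na = "string")
  invisible(path)
}

# Round-trippable rho representation: 6 decimal places, "NA" when undefined.
.json_rho <- function(rho) if (is.na(rho)) "NA" else round(rho, 6)

.write_manifest <- function(outdir, command, params, inputs = character(),
                            seed = NA) {
  checksums <- if (length(inputs) > 0)
    as.list(tools::md5sum(inputs)) else list()
  .write_json(
    list(command = command, parameters = params, input_md5 = checksums,
         seed = seed,
         tool = paste0("paranuc ", as.character(utils::packageVersion("paranuc"))),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")),
    file.path(outdir, "manifest.json"))
}

.ensure_outdir <- function(outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  outdir
}

.get_gene <- function(genes, id) {
  if (!id %in% names(genes))
    .validation_error("gene ", dQuote(id), " not found in the annotation")
  genes[[id]]
}

#' Pipeline step: occupancy profile of one gene region
#'
#' Reads fragments (BED) and genes (TSV or GFF3), computes the oriented
#' occupancy profile of one gene's promoter or coding region, and writes
#' `occupancy.bedGraph` plus an `occupancy.json` metadata sidecar and a
#' run manifest to `outdir`.
#'
#' @param bed path to the fragment BED file.
#' @param genes path to the gene annotation.
#' @param gene_id gene to profile.
#' @param region `"promoter"` or `"coding"`.
#' @param mode occupancy mode, `"coverage"` or `"dyad"`.
#' @param upstream_len promoter window length (default 1000).
#' @param outdir output directory (created if absent).
#' @param genes_format annotation format, `"tsv"` or `"gff3"`.
#' @return the `occupancy_profile`, invisibly.
#' @export
run_occupancy <- function(bed, genes, gene_id,
                          region = c("promoter", "coding"),
                          mode = c("coverage", "dyad"), upstream_len = 1000L,
                          outdir = ".", genes_format = c("tsv", "gff3")) {
  region <- match.arg(region); mode <- match.arg(mode)
  genes_format <- match.arg(genes_format)
  .ensure_outdir(outdir)
  frags <- read_fragments_bed(bed)
  gtab <- read_gene_table(genes, format = genes_format)
  g <- .get_gene(gtab, gene_id)
  int <- if (region == "promoter") promoter_interval(g, upstream_len)
         else coding_interval(g)
  prof <- compute_occupancy(frags, int, mode = mode, gene_id = gene_id)
  write_profile_bedgraph(prof, file.path(outdir, "occupancy.bedGraph"))
  .write_json(
    list(gene_id = gene_id, region = region, mode = mode,
         interval = list(chrom = int$chrom, start = int$start, end = int$end,
                         strand = int$strand, truncated = int$truncated),
         n_positions = length(prof$counts), total_count = sum(prof$counts)),
    file.path(outdir, "occupancy.json"))
  .write_manifest(outdir, "occupancy",
                  list(gene_id = gene_id, region = region, mode = mode,
                       upstream_len = as.integer(upstream_len)),
                  inputs = c(bed, genes))
  invisible(prof)
}

#' Pipeline step: compare a paralog pair
#'
#' Reads fragments and genes, runs [compare_paralog_pair] on the named
#' genes, and writes `pair_similarity.tsv`, `pair_similarity.json` and a
#' run manifest to `outdir`. Correlations are serialized with 6 decimal
#' places; an undefined correlation is written as the literal `NA` with
#' its reason.
#'
#' @inheritParams run_occupancy
#' @param gene_a,gene_b the two gene ids to compare.
#' @param length_policy `"resample_min"` or `"truncate_min"`.
#' @return the `pair_similarity`, invisibly.
#' @export
run_compare_pair <- function(bed, genes, gene_a, gene_b, upstream_len = 1000L,
                             mode = c("coverage", "dyad"),
                             length_policy = c("resample_min", "truncate_min"),
                             outdir = ".", genes_format = c("tsv", "gff3")) {
  mode <- match.arg(mode); length_policy <- match.arg(length_policy)
  genes_format <- match.arg(genes_format)
  .ensure_outdir(outdir)
  frags <- read_fragments_bed(bed)
  gtab <- read_gene_table(genes, format = genes_format)
  res <- compare_paralog_pair(.get_gene(gtab, gene_a), .get_gene(gtab, gene_b),
                              frags, upstream_len = upstream_len, mode = mode,
                              length_policy = length_policy)
  df <- as.data.frame(res)
  df$rho <- vapply(df$rho, .fmt_rho, character(1))
  df$reason[is.na(df$reason)] <- ""
  utils::write.table(df, file.path(outdir, "pair_similarity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .write_json(
    list(gene_a = res$gene_a, gene_b = res$gene_b,
         promoter_rho = .json_rho(res$promoter_rho),
         coding_rho = .json_rho(res$coding_rho),
         promoter_n = res$promoter_n, coding_n = res$coding_n,
         promoter_reason = res$promoter_reason,
         coding_reason = res$coding_reason,
         resampled = res$resampled, mode = res$mode,
         length_policy = res$length_policy),
    file.path(outdir, "pair_similarity.json"))
  .write_manifest(outdir, "compare-pair",
                  list(gene_a = gene_a, gene_b = gene_b,
                       upstream_len = as.integer(upstream_len), mode = mode,
                       length_policy = length_policy),
                  inputs = c(bed, genes))
  invisible(res)
}

#' Pipeline step: duplication report for a gene tree
#'
#' Parses a species-labeled Newick gene tree, runs [label_duplications]
#' and [sister_paralog_pairs], and writes `dup_report.json`,
#' `copy_number.tsv` and a run manifest to `outdir`.
#'
#' @param newick path to (or literal string of) the Newick tree.
#' @param delimiter,species_field tip label parsing rule (see
#'   [parse_newick_genetree]).
#' @param clade_filter optional character vector of species restricting
#'   the copy-number table written to `copy_number.tsv`.
#' @param outdir output directory.
#' @return the `duplication_report`, invisibly.
#' @export
run_tree_dups <- function(newick, delimiter = "|", species_field = 1L,
                          clade_filter = NULL, outdir = ".") {
  .ensure_outdir(outdir)
  tree <- tryCatch(
    parse_newick_genetree(newick, delimiter = delimiter,
                          species_field = species_field),
    error = function(e) .validation_error(conditionMessage(e)))
  rep <- label_duplications(tree)
  pairs <- sister_paralog_pairs(tree)
  ct <- copy_number_table(tree, clade_filter = clade_filter)
  utils::write.table(
    data.frame(species = names(ct), n_copies = as.integer(ct)),
    file.path(outdir, "copy_number.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  .write_json(
    list(n_tips = length(tree$species),
         n_species = length(unique(tree$species)),
         n_multi_copy = rep$n_multi_copy,
         n_duplications = rep$n_duplications,
         duplication_nodes = rep$duplication_nodes,
         sister_paralog_pairs = pairs[, c("species", "gene_a", "gene_b")],
         copy_table = as.list(rep$copy_table)),
    file.path(outdir, "dup_report.json"))
  inputs <- if (file.exists(newick)) newick else character()
  .write_manifest(outdir, "tree-dups",
                  list(delimiter = delimiter,
                       species_field = as.integer(species_field)),
                  inputs = inputs)
  invisible(rep)
}

#' Pipeline step: generate a synthetic data set
#'
#' Drives the synthetic-data generators from one flat configuration (YAML
#' or JSON file, or an R list) and writes the exact formats the pipeline
#' reads: `fragments.bed`, `genes.tsv`, `genetree.nwk`, a `truth.json`
#' recording the planted ground truth, and a run manifest. Recognised
#' configuration keys (all optional except `seed`): `seed`, `depth`,
#' `upstream_len`, `promoter_occupancy_boost`, `coding_len`,
#' `coding_shared`, `promoter_shared`, `background_rate`, `jitter_sd`,
#' `n_species`, `n_duplications`.
#'
#' @param config path to a YAML/JSON config file, or a named list.
#' @param outdir output directory.
#' @return a list with the `paralog_sim` and `genetree_sim` objects,
#'   invisibly.
#' @export
run_simulate <- function(config, outdir = ".") {
  .ensure_outdir(outdir)
  cfg_in <- if (is.character(config)) {
    if (grepl("\\.json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  } else config
  if (is.null(cfg_in$seed))
    .validation_error("simulate config must provide a seed")
  pick <- function(key, default) if (is.null(cfg_in[[key]])) default else cfg_in[[key]]

  cfg <- sim_config(
    seed = cfg_in$seed, depth = pick("depth", 100L),
    upstream_len = pick("upstream_len", 1000L),
    promoter_occupancy_boost = pick("promoter_occupancy_boost", 1.5),
    coding_len = pick("coding_len", 1300L))
  pair <- make_paralog_pair(
    cfg, coding_shared = pick("coding_shared", TRUE),
    promoter_shared = pick("promoter_shared", FALSE),
    background_rate = pick("background_rate", 0.02),
    jitter_sd = pick("jitter_sd", 10))
  tree_sim <- simulate_gene_tree(
    n_species = pick("n_species", 12L),
    duplications = pick("n_duplications", 3L),
    seed = .derive_seeds(cfg$seed, 7L)[[7]])

  write_fragments_bed(pair$fragments, file.path(outdir, "fragments.bed"))
  gene_row <- function(g) sprintf("%s\t%s\t%s\t%d\t%d\t%s", g$gene_id, g$chrom,
                                  g$strand, g$start + 1L, g$end, g$species)
  writeLines(c("#gene_id\tchrom\tstrand\tstart\tend\tspecies",
               gene_row(pair$gene_a), gene_row(pair$gene_b)),
             file.path(outdir, "genes.tsv"))
  writeLines(tree_sim$newick, file.path(outdir, "genetree.nwk"))
  .write_json(
    list(config = cfg_in,
         paralog_pair = list(coding_shared = pair$truth$coding_shared,
                             promoter_shared = pair$truth$promoter_shared),
         gene_tree = list(n_species = length(tree_sim$species),
                          n_duplications = tree_sim$n_duplications,
                          planted_pairs = tree_sim$planted_pairs)),
    file.path(outdir, "truth.json"))
  .write_manifest(outdir, "simulate", cfg_in, seed = cfg$seed)
  invisible(list(pair = pair, tree = tree_sim))
}
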