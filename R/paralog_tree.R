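#' Parse a species-labeled gene tree from Newick
#'
#' Tip labels encode the species per `delimiter`/`species_field`
#' (default `"Species|gene"`), or a `species_map` overrides label parsing
#' entirely. Branch lengths and support values, if present, are carried on
#' the underlying `phylo` object but ignored by all downstream operations.
#'
#' @param x a Newick string (recognised by a `(` ... `;` shape) or a file
#'   path.
#' @param delimiter label field separator (default `"|"`).
#' @param species_field 1-based index of the species field in the split
#'   label (default 1).
#' @param species_map optional named character vector mapping full tip
#'   labels to species; when given, the whole label is kept as the gene id.
#' @return an object of class `gene_tree`: the `phylo` tree plus `species`
#'   and `gene_id` vectors named by tip label.
#' @export
parse_newick_genetree <- function(x, delimiter = "|", species_field = 1L,
                                  species_map = NULL) {
  phy <- if (grepl("\\(", x[1]) && grepl(";", x[1])) {
    ape::read.tree(text = x)
  } else {
    ape::read.tree(file = x)
  }
  if (is.null(phy)) stop("could not parse Newick input", call. = FALSE)
  if (ape::Ntip(phy) < 2L)
    stop("gene tree must have at least 2 tips", call. = FALSE)
  if (!ape::is.rooted(phy))
    stop("gene tree is unrooted (basal multifurcation); ",
         "root it before duplication analysis", call. = FALSE)
  labels <- phy$tip.label
  dup <- labels[duplicated(labels)]
  if (length(dup) > 0L)
    stop("duplicate tip labels: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  if (!is.null(species_map)) {
    missing <- setdiff(labels, names(species_map))
    if (length(missing) > 0L)
      stop("species_map lacks entries for tips: ",
           paste(missing, collapse = ", "), call. = FALSE)
    species <- unname(species_map[labels])
    gene_id <- labels
  } else {
    parts <- strsplit(labels, delimiter, fixed = TRUE)
    bad <- lengths(parts) < 2L
    if (any(bad))
      stop("tip label(s) without species delimiter ", dQuote(delimiter),
           ": ", paste(labels[bad], collapse = ", "), call. = FALSE)
    species <- vapply(parts, function(p) p[[species_field]], character(1))
    gene_id <- vapply(parts, function(p)
      paste(p[-species_field], collapse = delimiter), character(1))
  }
  if (any(!nzchar(species)))
    stop("empty species in tip label(s): ",
         paste(labels[!nzchar(species)], collapse = ", "), call. = FALSE)
  names(species) <- labels
  names(gene_id) <- labels
  structure(list(phylo = phy, species = species, gene_id = gene_id),
            class = "gene_tree")
}

#' @export
print.gene_tree <- function(x, ...) {
  cat(sprintf("<gene_tree> %d tips, %d species, %d internal nodes\n",
              ape::Ntip(x$phylo), length(unique(x$species)),
              x$phylo$Nnode))
  invisible(x)
}

#' Per-species gene copy number
#'
#' Counts tips per species, optionally restricted to a set of species
#' (e.g. one subphylum's members).
#'
#' @param tree a [parse_newick_genetree] result.
#' @param clade_filter optional character vector of species to keep.
#' @return a named integer vector, species -> tip count, sorted by species
#'   name. Species in `clade_filter` absent from the tree are dropped.
#' @export
copy_number_table <- function(tree, clade_filter = NULL) {
  stopifnot(inherits(tree, "gene_tree"))
  sp <- tree$species
  if (!is.null(clade_filter)) sp <- sp[sp %in% clade_filter]
  if (length(sp) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(sp)
  stats::setNames(as.integer(tab), names(tab))
}

# Species set below every node, indexed by ape node number.
.node_species_sets <- function(tree) {
  phy <- tree$phylo
  ntip <- ape::Ntip(phy)
  sets <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$species[[phy$tip.label[[i]]]]
  edge <- stats::reorder(phy, order = "postorder")$edge
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1]; ch <- edge[k, 2]
    sets[[p]] <- union(sets[[p]], sets[[ch]])
  }
  sets
}

#' Flag duplication nodes by species overlap
#'
#' An internal node is called a duplication when the species sets of at
#' least two of its child subtrees intersect — the minimal formalization of
#' reading duplications off a species-labeled gene tree, and exact when no
#' gene loss has occurred. Multifurcations are allowed; overlap is tested
#' across all children jointly.
#'
#' @param tree a [parse_newick_genetree] result (rooted).
#' @return an object of class `duplication_report` with fields
#'   `copy_table` (as [copy_number_table]), `n_multi_copy` (species with
#'   >= 2 copies), `duplication_nodes` (ape node ids), `n_duplications`.
#' @export
label_duplications <- function(tree) {
  stopifnot(inherits(tree, "gene_tree"))
  phy <- tree$phylo
  ntip <- ape::Ntip(phy)
  sets <- .node_species_sets(tree)
  internal <- ntip + seq_len(phy$Nnode)
  dup_nodes <- integer(0)
  for (node in internal) {
    children <- phy$edge[phy$edge[, 1] == node, 2]
    child_sets <- sets[children]
    # some pair of children overlaps iff the concatenation has repeats
    all_sp <- unlist(child_sets, use.names = FALSE)
    if (length(all_sp) > length(unique(all_sp)))
      dup_nodes <- c(dup_nodes, node)
  }
  ct <- copy_number_table(tree)
  structure(
    list(copy_table = ct, n_multi_copy = sum(ct >= 2L),
         duplication_nodes = dup_nodes,
         n_duplications = length(dup_nodes)),
    class = "duplication_report")
}

#' @export
print.duplication_report <- function(x, ...) {
  cat(sprintf("<duplication_report> %d species, %d with >= 2 copies, %d duplication node(s)\n",
              length(x$copy_table), x$n_multi_copy, x$n_duplications))
  invisible(x)
}

#' Within-species sister paralog pairs
#'
#' Lists cherries (two-tip internal nodes) whose tips share a species —
#' the topological pattern of a duplication younger than any speciation
#' below it, e.g. a within-species paralog pair sitting as mutual closest
#' relatives.
#'
#' @param tree a [parse_newick_genetree] result.
#' @return a data frame with columns `species`, `gene_a`, `gene_b`, `node`
#'   (ape node id); zero rows when no such cherry exists.
#' @export
sister_paralog_pairs <- function(tree) {
  stopifnot(inherits(tree, "gene_tree"))
  phy <- tree$phylo
  ntip <- ape::Ntip(phy)
  out <- list()
  for (node in ntip + seq_len(phy$Nnode)) {
    children <- phy$edge[phy$edge[, 1] == node, 2]
    if (length(children) == 2L && all(children <= ntip)) {
      labs <- phy$tip.label[children]
      sp <- tree$species[labs]
      if (sp[[1]] == sp[[2]]) {
        genes <- sort(unname(tree$gene_id[labs]))
        out[[length(out) + 1L]] <- data.frame(
          species = sp[[1]], gene_a = genes[[1]], gene_b = genes[[2]],
          node = node, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(species = character(), gene_a = character(),
                      gene_b = character(), node = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
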