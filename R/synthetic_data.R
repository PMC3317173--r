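#' Nucleosome architecture of a locus
#'
#' The generative description of a nucleosome landscape around one gene:
#' a set of dyad positions given as offsets relative to the translational
#' start site (negative offsets lie in the promoter), each with an
#' occupancy weight and a positional jitter, plus a fragment-length model
#' and a uniform background rate.
#'
#' @param offsets integer dyad offsets relative to the translational start
#'   (bp; negative = upstream/promoter side).
#' @param weights per-dyad occupancy weights in (0, 1].
#' @param jitter_sd per-dyad dyad-position jitter (bp standard deviation,
#'   >= 0); recycled if scalar.
#' @param fragment_len_mean,fragment_len_sd normal fragment-length model;
#'   defaults 147 +/- 10 bp, the canonical mononucleosomal DNA length.
#' @param background_rate expected uniform background fragments per bp of
#'   locus (>= 0).
#' @return an object of class `nuc_architecture`.
#' @export
nuc_architecture <- function(offsets, weights, jitter_sd = 10,
                             fragment_len_mean = 147, fragment_len_sd = 10,
                             background_rate = 0) {
  stopifnot(length(offsets) == length(weights))
  if (length(weights) > 0 && (any(weights <= 0) || any(weights > 1)))
    stop("nuc_architecture: weights must lie in (0, 1]", call. = FALSE)
  jitter_sd <- rep_len(as.numeric(jitter_sd), length(offsets))
  if (length(jitter_sd) > 0 && any(jitter_sd < 0))
    stop("nuc_architecture: jitter_sd must be >= 0", call. = FALSE)
  if (fragment_len_mean <= 0)
    stop("nuc_architecture: fragment_len_mean must be > 0", call. = FALSE)
  if (background_rate < 0)
    stop("nuc_architecture: background_rate must be >= 0", call. = FALSE)
  structure(
    list(dyads = data.frame(offset = as.integer(offsets),
                            weight = as.numeric(weights),
                            jitter_sd = jitter_sd),
         fragment_len_mean = fragment_len_mean,
         fragment_len_sd = fragment_len_sd,
         background_rate = background_rate),
    class = "nuc_architecture")
}

#' Draw a random phased nucleosome architecture
#'
#' Places dyads over the offset window `[from, to)` on a regular grid with
#' a random phase, adds a small per-dyad positional scatter, and draws
#' per-dyad occupancy weights uniformly from `weight_range`. The default
#' 165 bp spacing approximates the nucleosome repeat length of budding
#' yeast. Draws from the current RNG state; seed before calling for
#' reproducibility.
#'
#' @param from,to offset window relative to the translational start
#'   (half-open; use negative `from`/`to` for a promoter architecture).
#' @param spacing mean dyad-to-dyad distance in bp (default 165).
#' @param jitter_sd per-dyad sampling jitter passed to [nuc_architecture].
#' @param weight_range range of per-dyad occupancy weights.
#' @param placement_sd scatter (bp sd) of each dyad around its grid point.
#' @param ... forwarded to [nuc_architecture] (fragment length model,
#'   background rate).
#' @return a `nuc_architecture`.
#' @export
random_nuc_architecture <- function(from, to, spacing = 165, jitter_sd = 10,
                                    weight_range = c(0.3, 1),
                                    placement_sd = 15, ...) {
  stopifnot(to > from)
  phase <- stats::runif(1, 0, spacing)
  grid <- seq(from + phase, to - 1, by = spacing)
  offsets <- round(grid + stats::rnorm(length(grid), 0, placement_sd))
  offsets <- pmin(pmax(offsets, from), to - 1L)
  weights <- stats::runif(length(grid), weight_range[[1]], weight_range[[2]])
  nuc_architecture(offsets, weights, jitter_sd = jitter_sd, ...)
}

#' Simulation configuration
#'
#' @param seed integer seed; every random draw in the generators flows
#'   from it.
#' @param depth expected fragment count per unit-weight dyad (default 100).
#' @param upstream_len promoter window length in bases (default 1000).
#' @param promoter_occupancy_boost multiplicative factor (>= 1) applied to
#'   the sampling rate of dyads at negative offsets, emulating promoters
#'   attracting more mapped nucleosomes than coding regions (default 1.5).
#' @param coding_len simulated coding-span length in bp (default 1300,
#'   about the span of a yeast homocitrate synthase gene).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed, depth = 100L, upstream_len = 1000L,
                       promoter_occupancy_boost = 1.5, coding_len = 1300L) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("sim_config: seed must be an integer", call. = FALSE)
  if (depth < 1L) stop("sim_config: depth must be >= 1", call. = FALSE)
  if (promoter_occupancy_boost < 1)
    stop("sim_config: promoter_occupancy_boost must be >= 1", call. = FALSE)
  structure(
    list(seed = seed, depth = as.integer(depth),
         upstream_len = as.integer(upstream_len),
         promoter_occupancy_boost = promoter_occupancy_boost,
         coding_len = as.integer(coding_len)),
    class = "sim_config")
}

# Derive k child seeds from one parent seed, all < 2^31.
.derive_seeds <- function(seed, k) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

# Genomic 0-based position of an offset relative to the translational start.
.offset_to_genomic <- function(gene, offset) {
  if (gene$strand == "+") gene$start + offset else (gene$end - 1L) - offset
}

#' Simulate nucleosomal fragments at a gene locus
#'
#' For each dyad of `arch`, draws `Poisson(depth * weight)` fragments
#' (times `promoter_occupancy_boost` for dyads at negative offsets), each
#' centered at the dyad plus normal jitter with length drawn from the
#' architecture's fragment-length model (clamped >= 50 bp), plus a uniform
#' Poisson background over the locus window (promoter plus coding span).
#' Offsets are translated to genomic coordinates through the gene's strand.
#' Fully deterministic given `cfg$seed`.
#'
#' @param arch a [nuc_architecture].
#' @param gene a [gene_model] locating the architecture on the genome.
#' @param cfg a [sim_config].
#' @return a [fragment_set], sorted by coordinate.
#' @export
simulate_fragments <- function(arch, gene, cfg) {
  stopifnot(inherits(arch, "nuc_architecture"), inherits(gene, "gene_model"),
            inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  starts <- integer(0); ends <- integer(0)

  draw_lengths <- function(n) {
    pmax(50L, as.integer(round(stats::rnorm(n, arch$fragment_len_mean,
                                            arch$fragment_len_sd))))
  }
  add <- function(centers, lens) {
    s <- as.integer(round(centers)) - (lens - 1L) %/% 2L
    e <- s + lens
    keep <- s >= 0L
    starts <<- c(starts, s[keep]); ends <<- c(ends, e[keep])
  }

  for (i in seq_len(nrow(arch$dyads))) {
    d <- arch$dyads[i, ]
    rate <- cfg$depth * d$weight *
      if (d$offset < 0L) cfg$promoter_occupancy_boost else 1
    n <- stats::rpois(1, rate)
    if (n == 0L) next
    centers <- .offset_to_genomic(gene, d$offset) +
      stats::rnorm(n, 0, d$jitter_sd)
    add(centers, draw_lengths(n))
  }

  if (arch$background_rate > 0) {
    win_lo <- if (gene$strand == "+") gene$start - cfg$upstream_len else gene$start
    win_hi <- if (gene$strand == "+") gene$end else gene$end + cfg$upstream_len
    win_lo <- max(0L, win_lo)
    nbg <- stats::rpois(1, arch$background_rate * (win_hi - win_lo))
    if (nbg > 0L)
      add(stats::runif(nbg, win_lo, win_hi), draw_lengths(nbg))
  }

  if (length(starts) == 0L) return(fragment_set())
  o <- order(starts, ends)
  fragment_set(rep(gene$chrom, length(starts)), starts[o], ends[o])
}

# Merge the dyad tables of two architectures (fragment-length model and
# background taken from the first).
.combine_architectures <- function(a, b) {
  nuc_architecture(
    c(a$dyads$offset, b$dyads$offset), c(a$dyads$weight, b$dyads$weight),
    jitter_sd = c(a$dyads$jitter_sd, b$dyads$jitter_sd),
    fragment_len_mean = a$fragment_len_mean,
    fragment_len_sd = a$fragment_len_sd,
    background_rate = a$background_rate)
}

#' Simulate a paralog pair with controllable profile similarity
#'
#' Places two genes on disjoint loci of one synthetic chromosome (gene A on
#' the `+` strand, gene B on the `-` strand) and populates each locus with
#' nucleosomal fragments. The promoter and coding nucleosome architectures
#' are controlled independently: a *shared* region uses the same
#' architecture at both loci (only sampling noise differs, so its profiles
#' correlate), an unshared region gets an independent random architecture
#' at each locus. The defaults — coding shared, promoter independent —
#' plant the pattern of paralogs with conserved coding-region nucleosome
#' organisation but diverged promoter organisation.
#'
#' @param cfg a [sim_config]; all randomness derives from `cfg$seed`.
#' @param coding_shared,promoter_shared logicals selecting which region's
#'   architecture the two loci share (defaults `TRUE`/`FALSE`).
#' @param background_rate uniform background fragments per bp
#'   (default 0.02).
#' @param jitter_sd dyad jitter in bp (default 10).
#' @param gap bases separating the two loci (default 3000).
#' @param chrom chromosome name for both loci.
#' @return a list of class `paralog_sim`: `gene_a`, `gene_b`
#'   ([gene_model]s), `fragments` (combined [fragment_set]) and `truth`
#'   (shared flags and derived seeds).
#' @export
make_paralog_pair <- function(cfg, coding_shared = TRUE,
                              promoter_shared = FALSE,
                              background_rate = 0.02, jitter_sd = 10,
                              gap = 3000L, chrom = "chrS") {
  stopifnot(inherits(cfg, "sim_config"))
  sub <- .derive_seeds(cfg$seed, 6L)

  a_start <- cfg$upstream_len + 500L
  gene_a <- gene_model("geneA", chrom, "+", a_start, a_start + cfg$coding_len,
                       species = "synth")
  b_start <- gene_a$end + as.integer(gap)
  gene_b <- gene_model("geneB", chrom, "-", b_start, b_start + cfg$coding_len,
                       species = "synth")

  draw <- function(seed, from, to) {
    set.seed(seed)
    random_nuc_architecture(from, to, jitter_sd = jitter_sd,
                            background_rate = background_rate)
  }
  prom_a <- draw(sub[[1]], -cfg$upstream_len, 0L)
  cod_a <- draw(sub[[2]], 0L, cfg$coding_len)
  prom_b <- if (promoter_shared) prom_a else draw(sub[[3]], -cfg$upstream_len, 0L)
  cod_b <- if (coding_shared) cod_a else draw(sub[[4]], 0L, cfg$coding_len)

  cfg_a <- cfg; cfg_a$seed <- sub[[5]]
  cfg_b <- cfg; cfg_b$seed <- sub[[6]]
  frags_a <- simulate_fragments(.combine_architectures(prom_a, cod_a),
                                gene_a, cfg_a)
  frags_b <- simulate_fragments(.combine_architectures(prom_b, cod_b),
                                gene_b, cfg_b)
  frags <- fragment_set(c(frags_a$chrom, frags_b$chrom),
                        c(frags_a$start, frags_b$start),
                        c(frags_a$end, frags_b$end))
  structure(
    list(gene_a = gene_a, gene_b = gene_b, fragments = frags,
         truth = list(coding_shared = coding_shared,
                      promoter_shared = promoter_shared,
                      seed = cfg$seed, derived_seeds = sub)),
    class = "paralog_sim")
}

# ---- gene tree simulation ------------------------------------------------

# Random rooted binary topology over ids, as nested pairlists of leaf ids.
.random_topology <- function(ids) {
  if (length(ids) == 1L) return(ids[[1]])
  k <- sample.int(length(ids) - 1L, 1L)
  pick <- sample(seq_along(ids), k)
  list(.random_topology(ids[pick]), .random_topology(ids[-pick]))
}

.collect_tips <- function(node) {
  if (!is.list(node)) return(node)
  c(.collect_tips(node[[1]]), .collect_tips(node[[2]]))
}

# Replace leaf `id` with a cherry of two new leaf ids.
.split_tip <- function(node, id, new_ids) {
  if (!is.list(node)) {
    if (node == id) return(list(new_ids[[1]], new_ids[[2]]))
    return(node)
  }
  list(.split_tip(node[[1]], id, new_ids), .split_tip(node[[2]], id, new_ids))
}

.topology_to_newick <- function(node, labels) {
  if (!is.list(node)) return(labels[[node]])
  paste0("(", .topology_to_newick(node[[1]], labels), ",",
         .topology_to_newick(node[[2]], labels), ")")
}

#' Simulate a species-labeled gene tree with planted duplications
#'
#' Builds a random rooted binary topology over `n_species` single-copy
#' tips, then plants each requested duplication by replacing one tip of
#' the chosen species with a within-species cherry (no gene losses). Under
#' this no-loss model the species-overlap criterion is exact, so the
#' planted event count is the ground truth for [label_duplications] and
#' the surviving within-species cherries for [sister_paralog_pairs].
#'
#' @param n_species number of species (>= 2); tips are labeled
#'   `sp01 ... spNN`.
#' @param duplications either a single count (that many distinct species
#'   are chosen at random) or a character vector of species names, one
#'   event per entry (repeats allowed: a later event may split a copy
#'   created by an earlier one).
#' @param seed integer seed; the same seed reproduces the identical Newick
#'   string.
#' @return a list of class `genetree_sim`: `tree` (a parsed `gene_tree`),
#'   `newick`, `species`, `n_duplications` (number of planted events) and
#'   `planted_pairs` (data frame of the within-species cherries present in
#'   the final tree: columns `species`, `gene_a`, `gene_b`).
#' @export
simulate_gene_tree <- function(n_species, duplications = 0L, seed = 1L) {
  n_species <- as.integer(n_species)
  if (n_species < 2L) stop("simulate_gene_tree: need >= 2 species", call. = FALSE)
  species <- sprintf("sp%02d", seq_len(n_species))
  set.seed(as.integer(seed))

  if (is.numeric(duplications)) {
    d <- as.integer(duplications)
    if (d > n_species)
      stop("simulate_gene_tree: more duplications than species; ",
           "pass a species vector to plant repeats", call. = FALSE)
    dup_species <- if (d > 0L) sample(species, d) else character(0)
  } else {
    dup_species <- as.character(duplications)
    unknown <- setdiff(dup_species, species)
    if (length(unknown) > 0L)
      stop("simulate_gene_tree: duplication requested for unknown species: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }

  # tip registry; ids index into it
  tip_species <- species
  topo <- .random_topology(seq_len(n_species))
  splits <- list()           # each: list(parent, child1, child2)
  split_parents <- integer(0)

  for (sp in dup_species) {
    candidates <- which(tip_species == sp & !(seq_along(tip_species) %in% split_parents))
    target <- if (length(candidates) == 1L) candidates else sample(candidates, 1L)
    new_ids <- length(tip_species) + c(1L, 2L)
    tip_species <- c(tip_species, sp, sp)
    topo <- .split_tip(topo, target, new_ids)
    splits[[length(splits) + 1L]] <- list(parent = target, children = new_ids)
    split_parents <- c(split_parents, target)
  }

  # gene ids per species in left-to-right tip order
  order_ids <- .collect_tips(topo)
  gene_no <- integer(length(tip_species))
  counter <- stats::setNames(integer(length(species)), species)
  for (id in order_ids) {
    sp <- tip_species[[id]]
    counter[[sp]] <- counter[[sp]] + 1L
    gene_no[[id]] <- counter[[sp]]
  }
  labels <- sprintf("%s|g%d", tip_species, gene_no)

  newick <- paste0(.topology_to_newick(topo, labels), ";")
  tree <- parse_newick_genetree(newick)

  # surviving cherries: splits whose both children were never split again
  pairs <- do.call(rbind, lapply(splits, function(s) {
    if (any(s$children %in% split_parents)) return(NULL)
    genes <- sort(sprintf("g%d", gene_no[s$children]))
    data.frame(species = tip_species[[s$children[[1]]]],
               gene_a = genes[[1]], gene_b = genes[[2]],
               stringsAsFactors = FALSE)
  }))
  if (is.null(pairs))
    pairs <- data.frame(species = character(), gene_a = character(),
                        gene_b = character(), stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$species, pairs$gene_a), , drop = FALSE]
  rownames(pairs) <- NULL

  structure(
    list(tree = tree, newick = newick, species = species,
         n_duplications = length(dup_species), planted_pairs = pairs),
    class = "genetree_sim")
}
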