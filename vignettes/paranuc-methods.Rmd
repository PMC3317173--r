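---
title: "Methods: comparing nucleosome profiles of paralogs and counting duplications"
author: "paranuc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing nucleosome profiles of paralogs and counting duplications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paranuc)
```

## The question

When a gene duplicates, its two copies may keep the same enzymatic role yet
drift apart in regulation. Chromatin organisation offers a sequence-independent
readout of that drift: nucleosome positions over a promoter constrain where
regulators can bind, so paralogs whose coding regions carry near-identical
nucleosome profiles but whose promoters do not are good candidates for
divergent regulatory control. The budding-yeast homocitrate synthase pair
*LYS20*/*LYS21* is the motivating case: two adjacent-in-function copies of the
first enzyme of the α-aminoadipate lysine pathway, repeatedly duplicated
across ascomycetous yeasts. `paranuc` packages the two computations behind
that style of analysis: (1) per-nucleotide occupancy profiles and their rank
correlation between paralogs, and (2) copy-number and duplication accounting
on a species-labeled gene tree.

## Regions and coordinates

All internal coordinates are 0-based half-open, matching BED fragments; GFF3
and TSV annotations (1-based inclusive) are converted on read. Two windows are
extracted per gene, strand-aware:

* **promoter** — the `upstream_len` bases immediately upstream of the
  translational start site. `upstream_len` is a parameter (bases, default
  1000), not a constant. A window running off the sequence start is kept as
  the clipped remainder and flagged `truncated` rather than erroring, so toy
  contigs degrade gracefully.
* **coding** — the genomic span between the translational start and end
  sites. Introns are *not* excised: the comparison is between genomic
  windows (the motivating yeast genes are intronless), and a warning is
  available when the caller knows introns are present.

Both windows are oriented so index 1 is the gene's 5′-most position; on the
`-` strand the genomic count vector is reversed. No masking is applied when a
promoter window overlaps a neighboring gene; with a 1000-base window in a
compact genome this can happen, and callers who care should filter gene pairs
beforehand.

## Occupancy profiles

For fragments F and window W, `coverage` mode sets
`counts[i] = #{f in F : f overlaps position W[i]}` with half-open overlap (a
fragment ending exactly at a position does not cover it); `dyad` mode counts
a fragment only at its midpoint, tying even lengths to the lower of the two
central positions. Coverage is the default: "mapping numbers per nucleotide
position" from fragment data is most directly fragment coverage, and the
choice is recorded in every output's metadata so a dyad-based rerun is one
flag away. Counts stay raw integers — the downstream statistic is rank-based
and invariant to positive depth scaling, so depth normalisation would add a
parameter without changing any result. An optional 120–180 bp fragment-length
filter is provided for MNase-style data but is off by default.

The per-base counting itself is delegated to `IRanges::coverage()`; the test
suite holds it to an exhaustive position-by-fragment loop on ~1000 random
instances.

## Rank correlation

Profiles are compared with the tie-aware Spearman coefficient: the Pearson
correlation of fractional (tie-averaged) ranks. Count vectors are full of
ties, and the classical `1 − 6Σd²/(n(n²−1))` shortcut is exact only without
ties, so it is used solely as a test oracle on tie-free permutations. When
either profile is constant (e.g. a locus with no fragments) the correlation
is undefined and is reported as an explicit `NA` with a reason string —
returning 0 would fabricate a similarity statement. No p-values are attached:
neighbouring positions of an occupancy profile are strongly autocorrelated,
so nominal correlation tests would be anticonservative; the package reports
effect sizes only.

Promoter windows are equal-length by construction and are never resampled.
Coding spans differ in length between paralogs; the default `resample_min`
policy linearly interpolates the longer profile onto the shorter one's point
count (monotone transformations of position, so rank structure is preserved
up to local averaging), with `truncate_min` (keep the 5′-most common prefix)
available when interpolation is undesirable. The policy used is recorded in
the result.

## Tree accounting

Gene trees arrive as rooted Newick with `Species|gene` tip labels (delimiter
and field configurable; a tip→species sidecar map overrides parsing). An
internal node is called a **duplication** iff the species sets of at least
two of its child subtrees intersect — the species-overlap criterion. With no
gene loss this is exact; with losses it undercounts, and no reconciliation
against a species tree is attempted (a deliberate limitation: reconciliation
needs a trusted species tree, which this analysis does not assume).
Multifurcations are allowed; overlap is tested jointly across all children.
Within-species cherries are additionally reported as sister paralog pairs —
the topological pattern of two copies that are each other's closest
relatives. Branch lengths and supports are carried but never used.

## Synthetic data: what it emulates, and what it does not

The generator emulates a mononucleosomal fragment map of a gene locus: dyads
placed on a ~165 bp grid (the yeast nucleosome repeat length) with a random
phase and ±15 bp placement scatter; per-dyad occupancy weights uniform on
(0.3, 1]; fragments of length 147 ± 10 bp (clamped ≥ 50) centered on the
dyad plus Gaussian jitter (default sd 10 bp); a uniform background of 0.02
fragments/bp; and an expected `depth × weight` fragments per dyad (Poisson,
default depth 100). Dyads at negative offsets (the promoter side) are sampled
at 1.5× rate by default (`promoter_occupancy_boost`), reproducing the
qualitative observation that promoters of these genes attract more mapped
nucleosomes than coding spans. Simulated genes use a 1300 bp coding span —
about the span of a yeast homocitrate synthase gene — with the two paralogs
given equal spans by default, on opposite strands of disjoint loci so that
orientation handling is always exercised.

`make_paralog_pair` controls similarity region by region: a *shared* region
reuses one architecture at both loci (profiles then differ only by sampling
noise), an unshared region draws an independent architecture per locus. The
defaults — coding shared, promoter independent — are the planted analogue of
conserved coding-region organisation with diverged promoters.

The generator does **not** model sequence-dependent nucleosome affinity,
MNase digestion bias, linker-length heterogeneity within a locus, duplicate
reads, or read-level errors. Passing tests therefore demonstrate that the
pipeline recovers planted truths under idealised sampling noise — not that
any particular biological pair diverged; on real data the absolute ρ values
additionally depend on digestion conditions and map resolution, which is one
reason published values for specific gene pairs are not targets here.

Tree simulation plants each duplication by replacing one tip of a chosen
species with a within-species cherry, without losses, which makes the
species-overlap criterion provably exact on simulated trees and gives a
clean ground truth (`n_duplications`, surviving cherries). Duplication
requests are a species vector (or a count, drawing distinct species); a
richer clade selector was considered and dropped — with cherry-grafting and
no losses, the species name alone determines the event. Repeated events in
one species nest: both grafts remain duplication nodes, but only the final
cherry survives as a sister pair, and the returned truth accounts for that.

All generators are deterministic given the seed; derived sub-seeds (for the
two loci, the architectures, the tree) are drawn once from the master seed so
outputs are byte-identical across reruns.

## Numerical and design choices

* Ranks come from base `rank(ties.method = "average")`; ρ from
  `stats::cor` on the rank vectors. The test oracles (closed form; an
  independently coded Pearson-of-average-ranks using neither `rank` nor
  `cor`) agree to 1e−12.
* Linear resampling uses `stats::approx` at `target_len` equally spaced
  points including both endpoints, so `target_len = n` is the identity.
* bedGraph output merges runs of equal counts and is written in genomic
  (unoriented) coordinates; re-expansion is the exact inverse.
* Serialized ρ values carry 6 decimal places; undefined ρ is the literal
  string `NA` plus a reason field, in both TSV and JSON.
* Pipeline steps write one `manifest.json` per output directory (command,
  parameters, input MD5 checksums, seed, version, timestamp); manifests are
  the only non-reproducible bytes, so byte-level comparisons exclude them.

## Problem sizes used by the test suite

The suite verifies the correlation against its oracles on all permutations
of up to 6 distinct values plus 1000 random tied vectors; occupancy
conservation on 1000 random fragment/interval instances; mirror-invariance
of the pair comparison on 50 simulated pairs; the shared-coding /
independent-promoter recovery on 20 seeded pairs at depth 100 (median coding
ρ ≥ 0.7, median promoter ρ ≤ 0.4, coding > promoter in ≥ 18/20); exact
duplication recovery on 100 simulated trees of 5–30 species with 0–5 planted
events; window arithmetic on 1000 random gene models; and a byte-for-byte
golden rerun of the simulate → compare → tree pipeline. These sizes keep the
whole suite around a minute on one core while leaving the Monte-Carlo margins
comfortable.

## Known limitations

* Species-overlap undercounts duplications when losses have pruned one copy
  from every species below a node.
* The promoter window is a fixed upstream length, not a measured regulatory
  region; overlapping upstream genes are not masked.
* Unequal-length reconciliation by interpolation slightly smooths the longer
  profile; with grossly different spans (`> 2×`) `truncate_min` is the more
  honest comparison.
* ρ between real paralog profiles depends on the fragment-counting mode and
  length policy chosen; results should always be reported together with
  those settings (the output records them).
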