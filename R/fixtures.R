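# Bundled reference dataset: published dictyostelid 18S rDNA summaries.
# dicty16_*  — 16 cultured isolates: taxonomy and pairwise distance tables
#              (proportion of differing sites, and K2P).
# dicty214_* — 214-sample / 44-species delimitation summary: per-species
#              verdicts and group memberships for a distance-based (ASAP)
#              and a tree-based (bPTP) delimitation, monophyly calls for an
#              ML phylogeny, expanded per-sample partitions, and a
#              *synthetic* tree topology consistent with the monophyly
#              column (the original inference output is not distributed).

bg_extdata <- function(file) {
  path <- system.file("extdata", file, package = "barcodegap",
                      mustWork = TRUE)
  path
}

#' Taxonomy of the 16 cultured reference isolates
#'
#' Four-rank taxonomy (3 genera, 2 orders) for the bundled 16-isolate
#' distance tables. Unnamed isolates are keyed one species per distinct
#' informal label; isolates sharing a haplotype under the same label share
#' a species key.
#'
#' @return Taxonomy data frame (see [read_taxonomy()]).
#' @export
dicty16_taxonomy <- function() read_taxonomy(bg_extdata("dicty16_taxonomy.tsv"))

#' Pairwise distance table of the 16 cultured reference isolates
#'
#' @param model `"k2p"` or `"p_distance"` — which published triangle to
#'   load (the source table prints the proportion of differing sites above
#'   its diagonal and the K2P distance below).
#' @return A `dist_matrix`.
#' @export
dicty16_distances <- function(model = c("k2p", "p_distance")) {
  model <- match.arg(model)
  file <- if (model == "k2p") "dicty16_k2p.tsv" else "dicty16_pdist.tsv"
  read_distance_matrix(bg_extdata(file), model = model)
}

#' Per-species delimitation summary for the 214-sample reference set
#'
#' One row per multi-sample species (44 rows, 214 samples): sample count,
#' the published pattern (`MONO`/`MERGE`/`SPLIT`/`multi-SPLIT`) and
#' occupied groups under a distance-based (ASAP) and a tree-based (bPTP)
#' delimitation, and the monophyly verdict (with bootstrap support) on the
#' published ML phylogeny.
#'
#' @return Data frame with columns `species`, `genus`, `n_samples`,
#'   `asap_pattern`, `asap_groups`, `ml_topology`, `ml_support`,
#'   `bptp_pattern`, `bptp_groups`.
#' @export
dicty214_summary <- function() {
  tab <- read_delim_auto(bg_extdata("dicty214_summary.tsv"))
  tab$n_samples <- as.integer(tab$n_samples)
  tab$ml_support <- suppressWarnings(as.numeric(tab$ml_support))
  tab
}

#' Taxonomy for the 214-sample reference set
#' @return Taxonomy data frame (44 species over 9 genera).
#' @export
dicty214_taxonomy <- function() read_taxonomy(bg_extdata("dicty214_taxonomy.tsv"))

#' Reference delimitation partitions (214 samples)
#'
#' Per-sample group assignments expanded from the published per-species
#' group memberships: a species' samples are spread round-robin over its
#' printed groups (the published patterns depend only on the occupied
#' group sets and their cross-species sharing, which the expansion
#' preserves).
#'
#' @param method `"asap"` (48 groups) or `"bptp"` (27 groups).
#' @return Partition data frame (see [read_partition()]).
#' @export
dicty214_partition <- function(method = c("asap", "bptp")) {
  method <- match.arg(method)
  read_partition(bg_extdata(paste0("dicty214_", method, ".tsv")))
}

#' Synthetic tree consistent with the reference monophyly calls
#'
#' A constructed rooted topology over the 214 samples plus an outgroup tip
#' (`Acanthamoeba_castellanii`) in which exactly the species recorded as
#' monophyletic in [dicty214_summary()] form pure clades. It reproduces the
#' published per-species monophyly verdicts and success rates, not the
#' published branching order or branch lengths.
#'
#' @return A rooted `phylo` with 215 tips.
#' @export
dicty214_tree <- function() read_newick(bg_extdata("dicty214_ml_synthetic.nwk"))
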