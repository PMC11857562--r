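# Synthetic-data generator: taxonomies, trees whose tip-pair path lengths
# realize three nested divergence scales (intraspecific, within-genus
# interspecific, between-genus), and alignments evolved along those trees
# under the K80 model. Everything is deterministic under the config seed.

#' Simulation configuration
#'
#' Defaults emulate a multi-genus 18S rDNA-like survey: short sequences of
#' `seq_length` sites, shallow intraspecific divergence, an order of
#' magnitude more within-genus interspecific divergence, and deep
#' between-genus divergence (expected K2P distances `d_intra` <
#' `d_inter_species` < `d_inter_genus`). `kappa` is the
#' transition/transversion *rate* ratio of the K80 model.
#'
#' `samples_per_species` may be a single count, a vector recycled over
#' species, or `"tableshape"` to replay the bundled 214-sample reference
#' imbalance (44 species, 2–29 samples each; see [dicty214_summary()]),
#' in which case `n_genera`/`species_per_genus` are taken from that table.
#'
#' @param n_genera Number of genera.
#' @param species_per_genus Species per genus (scalar or per-genus vector).
#' @param samples_per_species Samples per species (scalar, per-species
#'   vector, or `"tableshape"`).
#' @param seq_length Alignment length in sites.
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param d_intra,d_inter_species,d_inter_genus Expected K2P tip-pair
#'   distances within species, between congeneric species, and between
#'   genera.
#' @param seed Integer seed; fully determines every output.
#' @param allow_overlap Permit `d_inter_species < d_intra` (or
#'   `d_inter_genus < d_inter_species`) for overlap scenarios; the
#'   corresponding stem branches are clamped at zero, so the smaller scale
#'   collapses onto the larger.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genera = 9, species_per_genus = 5,
                       samples_per_species = 3, seq_length = 1800,
                       kappa = 2, d_intra = 0.002, d_inter_species = 0.012,
                       d_inter_genus = 0.28, seed = 1,
                       allow_overlap = FALSE) {
  stopifnot(kappa > 0, seq_length >= 1, d_intra >= 0,
            d_inter_species >= 0, d_inter_genus >= 0)
  if (!allow_overlap &&
      (d_inter_species < d_intra || d_inter_genus < d_inter_species))
    stop("divergence scales must be nested (d_intra <= d_inter_species <= ",
         "d_inter_genus) unless allow_overlap = TRUE")
  structure(list(n_genera = n_genera, species_per_genus = species_per_genus,
                 samples_per_species = samples_per_species,
                 seq_length = as.integer(seq_length), kappa = kappa,
                 d_intra = d_intra, d_inter_species = d_inter_species,
                 d_inter_genus = d_inter_genus, seed = as.integer(seed),
                 allow_overlap = allow_overlap),
            class = "sim_config")
}

sim_layout <- function(config) {
  if (identical(config$samples_per_species, "tableshape")) {
    ref <- dicty214_summary()
    genera <- unique(ref$genus)
    return(data.frame(genus = ref$genus, species = ref$species,
                      n_samples = ref$n_samples, stringsAsFactors = FALSE))
  }
  stopifnot(config$n_genera >= 1)
  spg <- rep_len(config$species_per_genus, config$n_genera)
  if (any(spg < 1)) stop("non-positive species_per_genus")
  genus <- rep(sprintf("g%02d", seq_len(config$n_genera)), spg)
  species <- unlist(lapply(seq_len(config$n_genera), function(g)
    sprintf("g%02d_s%02d", g, seq_len(spg[g]))))
  nspp <- rep_len(config$samples_per_species, length(species))
  if (any(nspp < 1)) stop("non-positive samples_per_species")
  data.frame(genus = genus, species = species, n_samples = as.integer(nspp),
             stringsAsFactors = FALSE)
}

#' Simulate a taxonomy and its true partition
#'
#' Sample ids encode genus/species indices (`g01_s02_i03`), or sanitized
#' species names under the `"tableshape"` layout. The true partition
#' assigns each sample its species as group id.
#'
#' @param config A [sim_config()].
#' @return List with `taxonomy` (data frame `sample_id`, `species`,
#'   `genus`, `family`, `order`) and `partition` (data frame `sample_id`,
#'   `group_id`). Family/order are synthetic: one family per genus,
#'   genera split into two orders.
#' @export
simulate_taxonomy <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  layout <- sim_layout(config)
  rows <- lapply(seq_len(nrow(layout)), function(k) {
    n <- layout$n_samples[k]
    base <- gsub("[^A-Za-z0-9_]+", "_", layout$species[k])
    data.frame(sample_id = sprintf("%s_i%02d", base, seq_len(n)),
               species = layout$species[k], genus = layout$genus[k],
               stringsAsFactors = FALSE)
  })
  tax <- do.call(rbind, rows)
  genera <- unique(tax$genus)
  fam <- stats::setNames(paste0(genera, "_fam"), genera)
  ord <- stats::setNames(
    paste0("order", 1 + (match(genera, genera) - 1) %% 2), genera)
  tax$family <- unname(fam[tax$genus])
  tax$order <- unname(ord[tax$genus])
  list(taxonomy = tax,
       partition = data.frame(sample_id = tax$sample_id,
                              group_id = tax$species,
                              stringsAsFactors = FALSE))
}

#' Simulate a tree realizing the configured divergence scales
#'
#' Builds a rooted tree in which every tip-pair path length equals its
#' class's target exactly: conspecific tips hang as a star of branches
#' `d_intra/2` from their species node; species nodes hang
#' `(d_inter_species - d_intra)/2` below their genus node; genus nodes
#' hang `(d_inter_genus - d_inter_species)/2` below the root. With
#' `allow_overlap` the stem lengths are clamped at zero.
#'
#' @param taxonomy Taxonomy data frame from [simulate_taxonomy()].
#' @param config The matching [sim_config()].
#' @return A rooted `phylo` with branch lengths in expected-substitution
#'   units.
#' @export
simulate_tree <- function(taxonomy, config) {
  stopifnot(inherits(config, "sim_config"))
  s_stem <- (config$d_inter_species - config$d_intra) / 2
  g_stem <- (config$d_inter_genus - config$d_inter_species) / 2
  if (config$allow_overlap) {
    s_stem <- max(0, s_stem); g_stem <- max(0, g_stem)
  }
  tip_len <- config$d_intra / 2
  fmt <- function(x) sprintf("%.10g", x)
  species_clade <- function(s, stem) {
    tips <- taxonomy$sample_id[taxonomy$species == s]
    if (length(tips) == 1L)
      sprintf("%s:%s", tips, fmt(tip_len + stem))
    else
      sprintf("(%s):%s",
              paste(sprintf("%s:%s", tips, fmt(tip_len)), collapse = ","),
              fmt(stem))
  }
  genus_clades <- vapply(unique(taxonomy$genus), function(g) {
    sp <- unique(taxonomy$species[taxonomy$genus == g])
    if (length(sp) == 1L)  # lone species absorbs the genus stem
      species_clade(sp, s_stem + g_stem)
    else
      sprintf("(%s):%s",
              paste(vapply(sp, species_clade, character(1), stem = s_stem),
                    collapse = ","),
              fmt(g_stem))
  }, character(1))
  # join genera in a zero-length ladder so the root is binary (rooted in
  # the ape sense) without changing any tip-pair path length
  txt <- if (length(genus_clades) == 1L) {
    paste0("(", genus_clades[[1]], ");")
  } else {
    backbone <- Reduce(function(a, b) sprintf("(%s,%s):0", a, b),
                       genus_clades)
    paste0(sub(":0$", "", backbone), ";")
  }
  ape::read.tree(text = txt)
}

# K80 transition-probability matrix for branch length d (expected
# substitutions per site) and ts/tv rate ratio kappa. States A,C,G,T.
k80_pmatrix <- function(d, kappa) {
  if (d < 0) stop("negative branch length: ", d)
  beta <- 1 / (kappa + 2)        # normalized so total rate = 1
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * d)
  e2 <- exp(-2 * (alpha + beta) * d)
  p_same <- 0.25 + 0.25 * e1 + 0.5 * e2
  p_ts   <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv   <- 0.25 - 0.25 * e1    # each of the two transversion targets
  #      A       C      G      T
  m <- rbind(
    c(p_same, p_tv, p_ts, p_tv),   # from A
    c(p_tv, p_same, p_tv, p_ts),   # from C
    c(p_ts, p_tv, p_same, p_tv),   # from G
    c(p_tv, p_ts, p_tv, p_same))   # from T
  dimnames(m) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  m
}

#' Evolve an alignment along a tree under K80
#'
#' The root sequence is uniform over A/C/G/T; each site evolves
#' independently down the tree under the K80 rate matrix with
#' transition/transversion rate ratio `config$kappa`, branch lengths in
#' expected-substitution units. Output is byte-identical for identical
#' configs (the RNG is seeded from `config$seed`).
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param config A [sim_config()] supplying `seq_length`, `kappa`, `seed`.
#' @return Data frame with `sample_id` and `sequence` (tip order of the
#'   tree).
#' @export
evolve_alignment <- function(tree, config) {
  stopifnot(inherits(tree, "phylo"), inherits(config, "sim_config"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  L <- config$seq_length
  nt <- c("A", "C", "G", "T")
  old <- .Random.seed_get()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  n_tip <- ape::Ntip(tree)
  root <- n_tip + 1L
  states <- vector("list", n_tip + tree$Nnode)
  states[[root]] <- sample.int(4L, L, replace = TRUE)
  # preorder: parents before children
  ordered <- ape::reorder.phylo(tree, "cladewise")
  edges <- ordered$edge
  lens <- ordered$edge.length
  for (k in seq_len(nrow(edges))) {
    parent <- edges[k, 1]; child <- edges[k, 2]
    P <- k80_pmatrix(lens[k], config$kappa)
    ps <- states[[parent]]
    cs <- integer(L)
    for (s in 1:4) {
      at <- which(ps == s)
      if (length(at))
        cs[at] <- sample.int(4L, length(at), replace = TRUE, prob = P[s, ])
    }
    states[[child]] <- cs
  }
  seqs <- vapply(seq_len(n_tip), function(i)
    paste(nt[states[[i]]], collapse = ""), character(1))
  data.frame(sample_id = tree$tip.label, sequence = seqs,
             stringsAsFactors = FALSE)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: taxonomy + true partition + tree + alignment.
#'
#' @param config A [sim_config()].
#' @return List with `taxonomy`, `partition` (truth), `tree`, `records`
#'   (alignment) and `config`.
#' @export
simulate_dataset <- function(config) {
  tx <- simulate_taxonomy(config)
  tree <- simulate_tree(tx$taxonomy, config)
  records <- evolve_alignment(tree, config)
  list(taxonomy = tx$taxonomy, partition = tx$partition, tree = tree,
       records = records, config = config)
}

#' Single-linkage threshold clustering of a distance matrix
#'
#' Groups samples into the connected components of the graph joining pairs
#' at distance `<= threshold` (single linkage). At `threshold = 0` this is
#' haplotype collapsing; at a threshold above the largest distance it is
#' one group. A simple distance-based delimiter that lets the scoring
#' pipeline run end to end without external tools.
#'
#' @param dm A `dist_matrix`. Undefined pairs are treated as unlinked.
#' @param threshold Non-negative distance threshold.
#' @return Partition data frame (`sample_id`, `group_id`), group ids
#'   `"c1"`, `"c2"`, ... in order of first appearance.
#' @export
threshold_cluster <- function(dm, threshold) {
  stopifnot(inherits(dm, "dist_matrix"), threshold >= 0)
  m <- dm$values
  m[is.na(m)] <- Inf
  ids <- rownames(m)
  if (length(ids) == 1L) {
    cl <- 1L
  } else {
    cl <- stats::cutree(stats::hclust(stats::as.dist(m), method = "single"),
                        h = threshold)
  }
  first <- !duplicated(cl)
  relabel <- stats::setNames(seq_len(sum(first)), cl[first])
  data.frame(sample_id = ids,
             group_id = sprintf("c%d", relabel[as.character(cl)]),
             stringsAsFactors = FALSE)
}
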