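# Score species-delimitation partitions and rooted trees against a
# reference taxonomy: per-species MONO/MERGE/SPLIT/multi-SPLIT verdicts,
# plain and sample-weighted success rates.

partition_as_vector <- function(partition) {
  stats::setNames(as.character(partition$group_id),
                  as.character(partition$sample_id))
}

#' Classify one species' delimitation outcome
#'
#' Compares the groups occupied by a species' samples with the species
#' composition of those groups:
#' * `MONO` — one group, containing only this species;
#' * `MERGE` — one group, shared with at least one other species;
#' * `SPLIT` — two or more groups, every one pure (only this species);
#' * `multi-SPLIT` — two or more groups, at least one shared with another
#'   species.
#'
#' Only species with at least two samples are scored; group sharing is
#' judged against *all* samples in the partition (including samples of
#' unscored species).
#'
#' @param partition Partition data frame (`sample_id`, `group_id`), see
#'   [read_partition()].
#' @param taxonomy Taxonomy covering every sample in the partition.
#' @param species Species label to classify.
#' @return List: `species`, `n_samples`, `groups` (character vector of
#'   occupied group ids), `pattern` (one of `"MONO"`, `"MERGE"`, `"SPLIT"`,
#'   `"multi-SPLIT"`).
#' @export
classify_species <- function(partition, taxonomy, species) {
  grp <- partition_as_vector(partition)
  tax_sp <- stats::setNames(taxonomy$species, taxonomy$sample_id)
  samples <- names(grp)[tax_sp[names(grp)] == species]
  samples <- samples[!is.na(samples)]
  if (!length(samples))
    stop("species not present in partition: ", species)
  if (length(samples) < 2L)
    stop("species '", species, "' has a single sample; singletons are not scored")
  groups <- unique(unname(grp[samples]))
  # a group is shared if any sample of a different species occupies it
  shared <- vapply(groups, function(g) {
    members <- names(grp)[grp == g]
    any(tax_sp[members] != species, na.rm = TRUE)
  }, logical(1))
  pattern <- if (length(groups) == 1L) {
    if (shared[1L]) "MERGE" else "MONO"
  } else {
    if (any(shared)) "multi-SPLIT" else "SPLIT"
  }
  list(species = species, n_samples = length(samples),
       groups = sort(groups), pattern = pattern)
}

#' Score a delimitation partition against the taxonomy
#'
#' Applies [classify_species()] to every species with at least two samples
#' and aggregates: the success rate is the percentage of scored species
#' classified `MONO`; the weighted success rate is the percentage of scored
#' *samples* belonging to `MONO` species. `n_groups` counts distinct group
#' ids over scored samples only.
#'
#' @inheritParams classify_species
#' @return List of class `delim_report`: `per_species` (data frame
#'   `species`, `n_samples`, `pattern`, `groups`), `n_species_scored`,
#'   `n_samples_scored`, `n_groups`, `success_rate`,
#'   `weighted_success_rate` (percentages).
#' @export
score_partition <- function(partition, taxonomy) {
  grp <- partition_as_vector(partition)
  tax_sp <- stats::setNames(taxonomy$species, taxonomy$sample_id)
  if (any(is.na(tax_sp[names(grp)])))
    stop("partition sample(s) missing from taxonomy: ",
         paste(names(grp)[is.na(tax_sp[names(grp)])], collapse = ", "))
  counts <- table(tax_sp[names(grp)])
  scored_species <- names(counts)[counts >= 2L]
  if (!length(scored_species)) {
    warning("no species with >= 2 samples; empty delimitation report")
    return(structure(list(per_species = data.frame(),
                          n_species_scored = 0L, n_samples_scored = 0L,
                          n_groups = 0L, success_rate = NA_real_,
                          weighted_success_rate = NA_real_),
                     class = "delim_report"))
  }
  res <- lapply(scored_species, classify_species,
                partition = partition, taxonomy = taxonomy)
  per_species <- data.frame(
    species = vapply(res, `[[`, character(1), "species"),
    n_samples = vapply(res, `[[`, integer(1), "n_samples"),
    pattern = vapply(res, `[[`, character(1), "pattern"),
    groups = vapply(res, function(r) paste(r$groups, collapse = ", "),
                    character(1)),
    stringsAsFactors = FALSE)
  scored_samples <- names(grp)[tax_sp[names(grp)] %in% scored_species]
  mono <- per_species$pattern == "MONO"
  structure(list(
    per_species = per_species,
    n_species_scored = nrow(per_species),
    n_samples_scored = length(scored_samples),
    n_groups = length(unique(unname(grp[scored_samples]))),
    success_rate = 100 * sum(mono) / nrow(per_species),
    weighted_success_rate =
      100 * sum(per_species$n_samples[mono]) / length(scored_samples)),
    class = "delim_report")
}

#' @export
print.delim_report <- function(x, ...) {
  cat("Delimitation report:", x$n_species_scored, "species /",
      x$n_samples_scored, "samples in", x$n_groups, "groups\n")
  if (x$n_species_scored > 0) {
    print(table(x$per_species$pattern))
    cat(sprintf("success rate: %.2f%%  weighted: %.2f%%\n",
                x$success_rate, x$weighted_success_rate))
  }
  invisible(x)
}

#' Is a species monophyletic on a rooted tree?
#'
#' True iff the smallest clade (MRCA subtree) containing all the species'
#' tips contains no tip of any other sample. The outgroup tip (used to root
#' the tree if supplied) never counts as a member of any species.
#'
#' @param tree A rooted `phylo` object (or any `phylo` if `outgroup_tip`
#'   is given, in which case the tree is rooted on that tip first).
#' @param taxonomy Taxonomy mapping tip labels to species.
#' @param species Species label to test.
#' @param outgroup_tip Optional tip label to root the tree on; it is
#'   dropped from membership checks.
#' @return Logical scalar.
#' @export
is_species_monophyletic <- function(tree, taxonomy, species,
                                    outgroup_tip = NULL) {
  tree <- rooted_tree(tree, outgroup_tip)
  tax_sp <- stats::setNames(taxonomy$species, taxonomy$sample_id)
  tips <- tree$tip.label[!is.na(tax_sp[tree$tip.label]) &
                         tax_sp[tree$tip.label] == species]
  wanted <- taxonomy$sample_id[taxonomy$species == species]
  wanted <- setdiff(wanted, outgroup_tip)
  missing <- setdiff(wanted, tree$tip.label)
  if (length(missing))
    stop("tip(s) of species '", species, "' missing from tree: ",
         paste(missing, collapse = ", "))
  if (length(tips) == 1L) return(TRUE)
  mrca <- ape::getMRCA(tree, tips)
  clade_tips <- tree$tip.label[phangorn::Descendants(tree, mrca, "tips")[[1]]]
  clade_tips <- setdiff(clade_tips, outgroup_tip)
  setequal(clade_tips, tips)
}

rooted_tree <- function(tree, outgroup_tip = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!is.null(outgroup_tip)) {
    if (!outgroup_tip %in% tree$tip.label)
      stop("outgroup tip not in tree: ", outgroup_tip)
    tree <- ape::root(tree, outgroup = outgroup_tip, resolve.root = TRUE)
  } else if (!ape::is.rooted(tree)) {
    stop("tree is unrooted; supply outgroup_tip")
  }
  tree
}

#' Score a rooted tree by species monophyly
#'
#' For every species with at least two tips, tests monophyly via
#' [is_species_monophyletic()] and reports a `delim_report` whose patterns
#' are restricted to `MONO` / `non-MONO`. The success rate is the
#' percentage of monophyletic multi-sample species; the weighted analogue
#' counts samples of monophyletic species.
#'
#' @inheritParams is_species_monophyletic
#' @return A `delim_report` (see [score_partition()]); `n_groups` is `NA`
#'   (trees carry no delimitation groups), and `per_species$groups` is
#'   empty.
#' @export
score_tree <- function(tree, taxonomy, outgroup_tip = NULL) {
  tree <- rooted_tree(tree, outgroup_tip)
  tax_sp <- stats::setNames(taxonomy$species, taxonomy$sample_id)
  tips <- setdiff(tree$tip.label, outgroup_tip)
  known <- tips[!is.na(tax_sp[tips])]
  counts <- table(tax_sp[known])
  scored_species <- names(counts)[counts >= 2L]
  if (!length(scored_species)) {
    warning("no species with >= 2 tips; empty report")
    return(structure(list(per_species = data.frame(),
                          n_species_scored = 0L, n_samples_scored = 0L,
                          n_groups = NA_integer_, success_rate = NA_real_,
                          weighted_success_rate = NA_real_),
                     class = "delim_report"))
  }
  mono <- vapply(scored_species, function(sp)
    is_species_monophyletic(tree, taxonomy, sp, outgroup_tip = outgroup_tip),
    logical(1))
  n_samp <- as.integer(counts[scored_species])
  per_species <- data.frame(
    species = scored_species,
    n_samples = n_samp,
    pattern = ifelse(mono, "MONO", "non-MONO"),
    groups = "",
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(
    per_species = per_species,
    n_species_scored = length(scored_species),
    n_samples_scored = sum(n_samp),
    n_groups = NA_integer_,
    success_rate = 100 * sum(mono) / length(scored_species),
    weighted_success_rate = 100 * sum(n_samp[mono]) / sum(n_samp)),
    class = "delim_report")
}
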