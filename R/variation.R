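# Categorize pairwise distances by taxonomic relationship and compare the
# classes with rank tests.

#' Classify every sample pair by taxonomic relationship
#'
#' Each defined pair gets exactly one (finest) class:
#' * `intraspecific` — same species label (this takes precedence: samples
#'   sharing a species but recorded under different genera are still
#'   intraspecific, with a consistency warning);
#' * `within_genus` — same genus, different species;
#' * `between_genus` — different genus, same order (or order rank absent);
#' * `between_order` — different genus and different order.
#'
#' `between_order` pairs are a subset of the different-genus pairs; use
#' [summarize_classes()] to aggregate them back into an inclusive
#' between-genus class.
#'
#' @param dm A `dist_matrix`.
#' @param taxonomy Taxonomy data frame (see [read_taxonomy()]) covering
#'   every sample in `dm`.
#' @return Data frame with columns `sample_i`, `sample_j`, `class`
#'   (factor), `distance`. Undefined (`NA`) distances are kept and flagged
#'   so callers can report them; summaries drop them.
#' @export
classify_pairs <- function(dm, taxonomy) {
  stopifnot(inherits(dm, "dist_matrix"))
  ids <- rownames(dm$values)
  missing <- setdiff(ids, taxonomy$sample_id)
  if (length(missing))
    stop("sample(s) missing from taxonomy: ", paste(missing, collapse = ", "))
  tax <- taxonomy[match(ids, taxonomy$sample_id), ]
  has_order <- !all(is.na(tax$order))
  n <- length(ids)
  idx <- which(upper.tri(dm$values), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  same_sp <- tax$species[i] == tax$species[j]
  same_gen <- tax$genus[i] == tax$genus[j]
  if (any(same_sp & !same_gen))
    warning("same-species pair(s) recorded under different genera; ",
            "classified intraspecific")
  cls <- ifelse(same_sp, "intraspecific",
         ifelse(same_gen, "within_genus", "between_genus"))
  if (has_order) {
    same_ord <- tax$order[i] == tax$order[j]
    cls[!same_sp & !same_gen & !is.na(same_ord) & !same_ord] <- "between_order"
  }
  data.frame(
    sample_i = ids[i], sample_j = ids[j],
    class = factor(cls, levels = c("intraspecific", "within_genus",
                                   "between_genus", "between_order")),
    distance = dm$values[idx],
    stringsAsFactors = FALSE)
}

#' Summarize distance classes
#'
#' Per-class count, mean, min and max over defined distances. With
#' `levels = 2` the interspecific side is the two-way split used for
#' violin-plot style comparisons: `within_genus` vs `between_genus`, the
#' latter including cross-order pairs. With `levels = 3` the summary also
#' reports `between_order` (different order) as a separate row while
#' `between_genus` still covers *all* different-genus pairs, so those two
#' rows overlap by construction — this matches how three-level distance
#' averages are conventionally quoted.
#'
#' @param pairs Output of [classify_pairs()].
#' @param levels 2 or 3 (see Details).
#' @return Data frame with columns `class`, `n`, `mean`, `min`, `max`.
#'   Empty classes are absent, not zero-filled.
#' @export
summarize_classes <- function(pairs, levels = 2) {
  stopifnot(levels %in% c(2, 3))
  pairs <- pairs[!is.na(pairs$distance), ]
  cls <- as.character(pairs$class)
  grp <- list(
    intraspecific = pairs$distance[cls == "intraspecific"],
    within_genus  = pairs$distance[cls == "within_genus"],
    between_genus = pairs$distance[cls %in% c("between_genus",
                                              "between_order")])
  if (levels == 3) {
    if (!any(cls == "between_order"))
      stop("three-level summary requested but no between_order pairs; ",
           "is the order rank present in the taxonomy?")
    grp$between_order <- pairs$distance[cls == "between_order"]
  }
  grp <- grp[vapply(grp, length, integer(1)) > 0]
  out <- data.frame(
    class = names(grp),
    n = vapply(grp, length, integer(1)),
    mean = vapply(grp, mean, numeric(1)),
    min = vapply(grp, min, numeric(1)),
    max = vapply(grp, max, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  out
}

#' Compare distance classes with rank tests
#'
#' Kruskal–Wallis rank-sum test across the classes plus pairwise Wilcoxon
#' rank-sum tests with Holm-adjusted p-values. Pairwise distance
#' observations are treated as independent, as is conventional for
#' barcoding studies; this pseudo-replicates samples, so a note to that
#' effect accompanies the report.
#'
#' @param pairs Output of [classify_pairs()].
#' @param two_way Collapse `between_order` into `between_genus` before
#'   testing (default `TRUE`, the two-way interspecific split).
#' @return List with elements `global` (`htest` from
#'   [stats::kruskal.test()]), `pairwise` (`pairwise.htest`, Holm
#'   adjustment), `n` (per-class counts) and `note`.
#' @export
compare_classes <- function(pairs, two_way = TRUE) {
  pairs <- pairs[!is.na(pairs$distance), ]
  cls <- as.character(pairs$class)
  if (two_way) cls[cls == "between_order"] <- "between_genus"
  cls <- factor(cls)
  counts <- table(cls)
  if (length(counts) < 2L) stop("need at least 2 non-empty classes")
  if (any(counts < 2L)) stop("every class needs at least 2 pairs")
  x <- pairs$distance
  degenerate <- length(unique(x)) == 1L
  if (degenerate)
    warning("all distances tied; p-value reported as 1")
  global <- if (degenerate) {
    structure(list(statistic = c(`Kruskal-Wallis chi-squared` = 0),
                   parameter = c(df = length(counts) - 1),
                   p.value = 1,
                   method = "Kruskal-Wallis rank sum test (degenerate: all tied)",
                   data.name = "distance by class"),
              class = "htest")
  } else {
    stats::kruskal.test(x, cls)
  }
  pairwise <- if (degenerate) NULL else
    stats::pairwise.wilcox.test(x, cls, p.adjust.method = "holm",
                                exact = FALSE)
  list(global = global,
       pairwise = pairwise,
       adjust_method = "holm",
       n = as.vector(counts, mode = "integer") |>
         stats::setNames(names(counts)),
       note = paste("pairwise distances are treated as independent",
                    "observations (pseudo-replication caveat)"))
}
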