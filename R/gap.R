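# Per-sample barcoding-gap statistics and per-genus aggregation.

#' Per-sample barcoding gap
#'
#' For every sample whose species has at least two samples, computes
#' `max_conspecific` (largest defined distance to a same-species sample),
#' `min_nonconspecific` (smallest defined distance to any other-species
#' sample, across *all* other species including other genera) and
#' `gap = min_nonconspecific - max_conspecific`. A positive gap means the
#' nearest non-conspecific lies beyond the farthest conspecific, so a
#' distance threshold can separate the species.
#'
#' Singleton species have no conspecific distance; by default their samples
#' are excluded (and logged via a message). `singleton_zero = TRUE` instead
#' scores them with `max_conspecific = 0`, the convention of some barcoding
#' toolkits — rejected as the default here because it biases gaps upward.
#'
#' @param dm A `dist_matrix` (typically K2P).
#' @param taxonomy Taxonomy covering every sample in `dm`.
#' @param singleton_zero Include singleton species with
#'   `max_conspecific = 0` (default `FALSE`).
#' @param within_genus_only Restrict the non-conspecific minimum to samples
#'   of the same genus (default `FALSE`: all other species compete).
#' @return Data frame with one row per scored sample: `sample_id`,
#'   `species`, `genus`, `max_conspecific`, `min_nonconspecific`, `gap`,
#'   `singleton` (logical flag). Samples whose distances are all undefined
#'   get `NA` values.
#' @export
gap_per_sample <- function(dm, taxonomy, singleton_zero = FALSE,
                           within_genus_only = FALSE) {
  stopifnot(inherits(dm, "dist_matrix"))
  ids <- rownames(dm$values)
  missing <- setdiff(ids, taxonomy$sample_id)
  if (length(missing))
    stop("sample(s) missing from taxonomy: ", paste(missing, collapse = ", "))
  tax <- taxonomy[match(ids, taxonomy$sample_id), ]
  if (length(unique(tax$species)) < 2L)
    stop("need at least 2 species for barcoding-gap analysis")
  sp_counts <- table(tax$species)
  singleton <- sp_counts[tax$species] == 1L
  if (any(singleton) && !singleton_zero)
    message(sum(singleton), " singleton-species sample(s) excluded from ",
            "gap records: ", paste(ids[singleton], collapse = ", "))
  rows <- lapply(seq_along(ids), function(i) {
    if (singleton[i] && !singleton_zero) return(NULL)
    con <- which(tax$species == tax$species[i]); con <- setdiff(con, i)
    noncon <- which(tax$species != tax$species[i])
    if (within_genus_only) noncon <- noncon[tax$genus[noncon] == tax$genus[i]]
    d_con <- dm$values[i, con]; d_con <- d_con[!is.na(d_con)]
    d_non <- dm$values[i, noncon]; d_non <- d_non[!is.na(d_non)]
    max_con <- if (singleton[i]) 0 else if (length(d_con)) max(d_con) else NA_real_
    min_non <- if (length(d_non)) min(d_non) else NA_real_
    data.frame(sample_id = ids[i], species = tax$species[i],
               genus = tax$genus[i],
               max_conspecific = max_con, min_nonconspecific = min_non,
               gap = min_non - max_con, singleton = unname(singleton[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(is.na(out$gap)))
    warning(sum(is.na(out$gap)), " sample(s) with undefined gap ",
            "(all relevant distances undefined)")
  out
}

#' Aggregate barcoding gaps by genus and test against zero
#'
#' Per genus: sample count, mean gap, its sign, and the p-value of a
#' one-sample location test of the gaps against zero — Wilcoxon signed-rank
#' by default, with a plain rank-sum alternative (`method = "rank_sum"`,
#' i.e. a two-sample Wilcoxon of the gaps against a zero vector) for parity
#' with pipelines that used that reading. A Kruskal–Wallis test across
#' genera is attached as an attribute.
#'
#' @param records Output of [gap_per_sample()].
#' @param method `"signed_rank"` (default) or `"rank_sum"`.
#' @return Data frame `genus`, `n`, `mean_gap`, `positive` (mean > 0),
#'   `p_value` (`NA` with a note when a genus has a single record), with
#'   attribute `kruskal` holding the across-genus test (`htest`, or `NULL`
#'   if fewer than 2 genera).
#' @export
gaps_by_genus <- function(records, method = c("signed_rank", "rank_sum")) {
  method <- match.arg(method)
  records <- records[!is.na(records$gap), ]
  if (!nrow(records)) stop("no defined gap records")
  split_gaps <- split(records$gap, records$genus)
  rows <- lapply(names(split_gaps), function(g) {
    x <- split_gaps[[g]]
    p <- if (length(x) < 2L) NA_real_
    else if (all(x == 0)) 1
    else if (method == "signed_rank")
      suppressWarnings(stats::wilcox.test(x, mu = 0, exact = FALSE)$p.value)
    else
      suppressWarnings(stats::wilcox.test(x, rep(0, length(x)),
                                          exact = FALSE)$p.value)
    data.frame(genus = g, n = length(x), mean_gap = mean(x),
               positive = mean(x) > 0, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(is.na(out$p_value)))
    message("genus/genera with a single gap record: test skipped (p = NA)")
  kw <- if (length(split_gaps) >= 2L &&
            length(unique(records$gap)) > 1L)
    stats::kruskal.test(records$gap, factor(records$genus))
  else NULL
  attr(out, "kruskal") <- kw
  attr(out, "method") <- method
  out
}
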