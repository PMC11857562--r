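# Pairwise distances: proportion of differences and Kimura 2-parameter,
# both under pairwise deletion (per pair, drop sites where either sequence
# is a gap or any code outside A/C/G/T).

#' Count comparable sites, transitions and transversions for one pair
#'
#' Applies pairwise deletion: any alignment column where either sequence
#' carries a gap or an ambiguity code (anything outside `A`, `C`, `G`, `T`)
#' is excluded from the comparison. Transitions are `A<->G` and `C<->T`;
#' every other mismatch is a transversion.
#'
#' @param seq_a,seq_b Aligned DNA strings of equal length.
#' @return Named integer vector with elements `n_compared`,
#'   `n_transitions`, `n_transversions`. `n_compared == 0` signals that no
#'   site was comparable (distances are then undefined).
#' @examples
#' site_counts("ACGT", "GCGA")  # one transition, one transversion
#' @export
site_counts <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) != length(b))
    stop("sequences have unequal lengths (", length(a), " vs ", length(b), ")")
  acgt <- c("A", "C", "G", "T")
  keep <- a %in% acgt & b %in% acgt
  a <- a[keep]; b <- b[keep]
  diff <- a != b
  purine <- c("A", "G")
  is_ts <- diff & ((a %in% purine) == (b %in% purine))
  c(n_compared = length(a),
    n_transitions = sum(is_ts),
    n_transversions = sum(diff & !is_ts))
}

# Closed-form K2P from transition/transversion proportions. Returns NA when
# the logarithm arguments are non-positive (saturation) or when P, Q are NA.
k2p_from_pq <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  out <- ifelse(is.na(w1) | w1 <= 0 | w2 <= 0, NA_real_,
                -0.5 * log(w1 * sqrt(w2)))
  # guard -0 and tiny negatives from floating point at P = Q = 0
  ifelse(!is.na(out) & out < 0 & out > -1e-12, 0, out)
}

#' Kimura 2-parameter distance between two aligned sequences
#'
#' `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))` with `P` and `Q` the
#' proportions of transition and transversion sites among comparable sites
#' (pairwise deletion, see [site_counts()]).
#'
#' @inheritParams site_counts
#' @return The distance, or `NA` with a warning when the distance is
#'   undefined (no comparable sites, or saturation making a logarithm
#'   argument non-positive).
#' @examples
#' k2p("ACGT", "ACGT")  # 0
#' @export
k2p <- function(seq_a, seq_b) {
  cnt <- site_counts(seq_a, seq_b)
  if (cnt[["n_compared"]] == 0L) {
    warning("no comparable sites; K2P distance undefined")
    return(NA_real_)
  }
  d <- k2p_from_pq(cnt[["n_transitions"]] / cnt[["n_compared"]],
                   cnt[["n_transversions"]] / cnt[["n_compared"]])
  if (is.na(d)) warning("K2P distance undefined (saturated pair)")
  d
}

#' Proportion of differing sites between two aligned sequences
#'
#' @inheritParams site_counts
#' @return `(n_transitions + n_transversions) / n_compared`, in `[0, 1]`;
#'   `NA` with a warning when no site is comparable.
#' @export
p_distance <- function(seq_a, seq_b) {
  cnt <- site_counts(seq_a, seq_b)
  if (cnt[["n_compared"]] == 0L) {
    warning("no comparable sites; p-distance undefined")
    return(NA_real_)
  }
  (cnt[["n_transitions"]] + cnt[["n_transversions"]]) / cnt[["n_compared"]]
}

new_dist_matrix <- function(values, model, sites = NULL) {
  stopifnot(is.matrix(values), identical(rownames(values), colnames(values)))
  diag(values) <- 0
  structure(list(values = values, sites = sites, model = model),
            class = "dist_matrix")
}

#' @export
print.dist_matrix <- function(x, ...) {
  n <- nrow(x$values)
  und <- sum(is.na(x$values[upper.tri(x$values)]))
  cat("dist_matrix:", n, "samples, model =", x$model,
      if (und) paste0("(", und, " undefined pair", if (und > 1) "s", ")"),
      "\n")
  invisible(x)
}

#' Build a pairwise distance matrix from aligned records
#'
#' Computes all pairwise distances under the chosen model with pairwise
#' deletion. Undefined pairs (no comparable sites, or K2P saturation) are
#' stored as `NA` and counted in a warning rather than dropped silently.
#'
#' @param records Data frame with `sample_id` and `sequence` columns
#'   (aligned, equal lengths), e.g. from [read_alignment()].
#' @param model `"k2p"` or `"p_distance"`.
#' @return A `dist_matrix` object: list with `values` (symmetric numeric
#'   matrix, zero diagonal), `sites` (symmetric matrix of comparable-site
#'   counts) and `model`.
#' @export
build_distance_matrix <- function(records, model = c("k2p", "p_distance")) {
  model <- match.arg(model)
  n <- nrow(records)
  if (n < 2L) stop("need at least 2 records to build a distance matrix")
  lens <- nchar(records$sequence)
  if (length(unique(lens)) > 1L) stop("records are not aligned (unequal lengths)")
  ids <- records$sample_id
  if (anyDuplicated(ids)) stop("duplicate sample ids")
  # integer-encode once: 1..4 = A,C,G,T; 0 = excluded under pairwise deletion
  enc <- lapply(records$sequence, function(s) {
    ch <- strsplit(toupper(s), "")[[1]]
    match(ch, c("A", "C", "G", "T"), nomatch = 0L)
  })
  vals <- matrix(0, n, n, dimnames = list(ids, ids))
  sites <- matrix(0L, n, n, dimnames = list(ids, ids))
  diag(sites) <- lens[1L]
  for (i in seq_len(n - 1L)) {
    ei <- enc[[i]]
    for (j in seq.int(i + 1L, n)) {
      ej <- enc[[j]]
      keep <- ei > 0L & ej > 0L
      nc <- sum(keep)
      sites[i, j] <- sites[j, i] <- nc
      if (nc == 0L) { vals[i, j] <- vals[j, i] <- NA_real_; next }
      ai <- ei[keep]; aj <- ej[keep]
      diffs <- ai != aj
      # purines encode to odd (A=1, G=3), pyrimidines to even (C=2, T=4)
      ts <- sum(diffs & (ai %% 2L == aj %% 2L))
      tv <- sum(diffs) - ts
      d <- if (model == "k2p") k2p_from_pq(ts / nc, tv / nc)
           else (ts + tv) / nc
      vals[i, j] <- vals[j, i] <- d
    }
  }
  und <- sum(is.na(vals[upper.tri(vals)]))
  if (und > 0)
    warning(und, " pair(s) with undefined ", model, " distance (flagged NA)")
  new_dist_matrix(vals, model = model, sites = sites)
}

#' Collapse samples into haplotype classes
#'
#' Haplotypes are the connected components of the graph joining sample
#' pairs at distance exactly zero. Under pairwise deletion zero distance
#' need not be transitive (masked sites can hide differences); components
#' still partition the samples, and a warning flags any class containing a
#' pair at positive distance.
#'
#' @param dm A `dist_matrix` (any model; only the zero-distance relation is
#'   used). Undefined (`NA`) pairs are treated as non-zero.
#' @return A list of character vectors of sample ids, one per haplotype
#'   class, ordered by first appearance.
#' @export
collapse_haplotypes <- function(dm) {
  stopifnot(inherits(dm, "dist_matrix"))
  m <- dm$values
  m[is.na(m)] <- Inf
  n <- nrow(m)
  if (n == 1L) return(list(rownames(m)))
  cl <- stats::cutree(stats::hclust(stats::as.dist(m), method = "single"),
                      h = 0)
  classes <- split(rownames(m), cl)
  classes <- classes[order(vapply(classes, function(s)
    min(match(s, rownames(m))), integer(1)))]
  names(classes) <- NULL
  for (s in classes) {
    if (length(s) > 1L && any(m[s, s][upper.tri(m[s, s])] > 0))
      warning("zero-distance relation non-transitive within class {",
              paste(s, collapse = ", "), "}")
  }
  classes
}
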