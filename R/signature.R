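# Genus (or other clade) assignment by diagnostic signature columns of an
# alignment: columns fixed for one state within a group and absent from
# every other group.

IUPAC_EXPAND <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

alignment_matrix <- function(records) {
  lens <- nchar(records$sequence)
  if (length(unique(lens)) > 1L) stop("records are not aligned")
  m <- do.call(rbind, strsplit(toupper(records$sequence), ""))
  rownames(m) <- records$sample_id
  m
}

#' Derive diagnostic signatures for groups of aligned sequences
#'
#' Scans every alignment column for *fully diagnostic* sites of each group:
#' columns where all members of the group carry one identical unambiguous
#' state (`A`/`C`/`G`/`T`) that appears in no sequence of any other group.
#' Each group's diagnostic columns and their states are assembled into a
#' signature; groups without any diagnostic column are reported as
#' unresolvable (empty signature).
#'
#' @param records Aligned records (data frame with `sample_id`,
#'   `sequence`) carrying the grouping column.
#' @param group Character vector of group labels, one per record (e.g. the
#'   genus column of a taxonomy joined to the records).
#' @param min_match_fraction Default match threshold stored on each
#'   signature; 1 treats signatures as fixed differences.
#' @return A list of signatures, each a list with `clade_label`, `columns`
#'   (1-based alignment positions, strictly increasing), `motif` (string
#'   over those columns) and `min_match_fraction`. Unresolvable groups have
#'   `columns = integer(0)` and `motif = ""`.
#' @export
derive_signatures <- function(records, group, min_match_fraction = 1) {
  stopifnot(length(group) == nrow(records),
            min_match_fraction > 0, min_match_fraction <= 1)
  groups <- unique(group)
  if (length(groups) < 2L) stop("need at least 2 groups to derive signatures")
  m <- alignment_matrix(records)
  acgt <- c("A", "C", "G", "T")
  sigs <- lapply(groups, function(g) {
    inside <- m[group == g, , drop = FALSE]
    outside <- m[group != g, , drop = FALSE]
    fixed_state <- apply(inside, 2, function(col) {
      u <- unique(col)
      if (length(u) == 1L && u %in% acgt) u else NA_character_
    })
    absent_outside <- vapply(seq_len(ncol(m)), function(j) {
      !is.na(fixed_state[j]) && !fixed_state[j] %in% outside[, j]
    }, logical(1))
    cols <- which(absent_outside)
    list(clade_label = g,
         columns = cols,
         motif = paste(fixed_state[cols], collapse = ""),
         min_match_fraction = min_match_fraction)
  })
  unresolved <- vapply(sigs, function(s) length(s$columns) == 0L, logical(1))
  if (any(unresolved))
    warning("group(s) without any fully diagnostic column: ",
            paste(groups[unresolved], collapse = ", "))
  sigs
}

#' Classify a query sequence by signature match
#'
#' The query must already be aligned to the reference coordinate system
#' (same length as the alignment the signatures were derived from). For
#' each signature the match fraction is the share of signature columns
#' where the query base is unambiguous and consistent with the motif state
#' (gaps and ambiguity codes in the query count as mismatches; IUPAC codes
#' in the motif are expanded). The best label is the signature with the
#' highest fraction at or above its threshold; ties yield an `"ambiguous"`
#' verdict listing all tied labels, and no qualifying signature yields
#' `"unclassified"`.
#'
#' @param query A single-row record (data frame with `sequence`) or a
#'   character string, aligned to reference coordinates.
#' @param signatures List of signatures from [derive_signatures()] or
#'   [read_signatures()].
#' @param alignment_length Expected alignment length (optional check).
#' @return List: `verdict` (a clade label, `"ambiguous"` or
#'   `"unclassified"`), `labels` (best label(s)), `report` (data frame
#'   `clade_label`, `n_columns`, `n_match`, `fraction`, `pass`).
#' @export
classify_query <- function(query, signatures, alignment_length = NULL) {
  seq <- if (is.data.frame(query)) query$sequence[1L] else query
  ch <- strsplit(toupper(seq), "")[[1]]
  if (!is.null(alignment_length) && length(ch) != alignment_length)
    stop("query length ", length(ch), " != alignment length ",
         alignment_length)
  rows <- lapply(signatures, function(s) {
    if (!length(s$columns))
      return(data.frame(clade_label = s$clade_label, n_columns = 0L,
                        n_match = 0L, fraction = NA_real_, pass = FALSE,
                        stringsAsFactors = FALSE))
    if (max(s$columns) > length(ch))
      stop("signature for '", s$clade_label, "' exceeds query length")
    q <- ch[s$columns]
    motif <- strsplit(toupper(s$motif), "")[[1]]
    ok <- mapply(function(qb, mb) {
      qb %in% c("A", "C", "G", "T") &&
        qb %in% (IUPAC_EXPAND[[mb]] %||% character())
    }, q, motif)
    frac <- mean(ok)
    data.frame(clade_label = s$clade_label, n_columns = length(s$columns),
               n_match = sum(ok), fraction = frac,
               pass = frac >= s$min_match_fraction,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  passing <- report[report$pass, , drop = FALSE]
  if (!nrow(passing)) {
    verdict <- "unclassified"; labels <- character()
  } else {
    best <- passing[passing$fraction == max(passing$fraction), , drop = FALSE]
    labels <- best$clade_label
    verdict <- if (nrow(best) > 1L) "ambiguous" else labels
  }
  list(verdict = verdict, labels = labels, report = report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a signature configuration file
#'
#' Delimited text with columns `clade_label`, `columns` (comma-separated
#' 1-based positions and `start-end` ranges), `motif` and `threshold`.
#'
#' @param path Path to the config file.
#' @return List of signatures as in [derive_signatures()].
#' @export
read_signatures <- function(path) {
  tab <- read_delim_auto(path)
  need <- c("clade_label", "columns", "motif", "threshold")
  if (!all(need %in% names(tab)))
    stop("signature config must have columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i) {
    cols <- parse_ranges(tab$columns[i])
    motif <- toupper(tab$motif[i])
    if (length(cols) != nchar(motif))
      stop("row ", i, ": motif length ", nchar(motif),
           " != number of columns ", length(cols))
    if (is.unsorted(cols, strictly = TRUE))
      stop("row ", i, ": columns must be strictly increasing")
    list(clade_label = tab$clade_label[i], columns = cols, motif = motif,
         min_match_fraction = as.numeric(tab$threshold[i]))
  })
}

#' Write signatures to a configuration file (TSV)
#' @param signatures List of signatures.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signatures <- function(signatures, path) {
  tab <- data.frame(
    clade_label = vapply(signatures, `[[`, character(1), "clade_label"),
    columns = vapply(signatures, function(s) format_ranges(s$columns),
                     character(1)),
    motif = vapply(signatures, `[[`, character(1), "motif"),
    threshold = vapply(signatures, `[[`, numeric(1), "min_match_fraction"),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

parse_ranges <- function(x) {
  parts <- trimws(strsplit(x, ",")[[1]])
  unlist(lapply(parts, function(p) {
    if (grepl("-", p)) {
      ab <- as.integer(strsplit(p, "-")[[1]])
      seq.int(ab[1], ab[2])
    } else as.integer(p)
  }))
}

format_ranges <- function(cols) {
  if (!length(cols)) return("")
  breaks <- c(0, which(diff(cols) != 1), length(cols))
  paste(vapply(seq_len(length(breaks) - 1L), function(k) {
    run <- cols[(breaks[k] + 1L):breaks[k + 1L]]
    if (length(run) == 1L) as.character(run)
    else paste0(run[1L], "-", run[length(run)])
  }, character(1)), collapse = ",")
}
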