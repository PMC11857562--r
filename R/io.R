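# IUPAC nucleotide alphabet accepted in alignments ('-' for gaps, 'U' is
# normalized to 'T' on read).
IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")

#' Read an aligned FASTA file
#'
#' Reads a multiple-sequence alignment from FASTA text. Sequences are
#' uppercased, `U` is normalized to `T`, and the file order is preserved.
#' All records must have equal length (the file must already be aligned);
#' the alphabet is IUPAC nucleotide codes plus `-`.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `sample_id` and `sequence`, one row per
#'   record. Taxonomy columns are not set; join with [read_taxonomy()].
#' @seealso [write_alignment()], [read_taxonomy()]
#' @export
read_alignment <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0L || !any(nzchar(readLines(path, warn = FALSE)))) {
    warning("empty FASTA file: ", path)
    return(data.frame(sample_id = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  dna <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                            whole.header = TRUE)
  ids <- trimws(names(dna))
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(vapply(dna, as.character, character(1)))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    bad <- which(lens != lens[1L])[1L]
    stop("unequal sequence lengths: record ", bad, " ('", ids[bad],
         "') has length ", lens[bad], ", expected ", lens[1L])
  }
  bad_chars <- setdiff(unique(strsplit(paste(seqs, collapse = ""), "")[[1]]),
                       c(IUPAC_CHARS, "?"))
  if (length(bad_chars))
    stop("non-IUPAC characters in alignment: ",
         paste(bad_chars, collapse = ", "))
  data.frame(sample_id = unname(ids), sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write an alignment to FASTA
#'
#' @param records Data frame with `sample_id` and `sequence` columns, as
#'   returned by [read_alignment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(records, path) {
  stopifnot(is.data.frame(records),
            all(c("sample_id", "sequence") %in% names(records)))
  lines <- as.vector(rbind(paste0(">", records$sample_id), records$sequence))
  writeLines(lines, path)
  invisible(path)
}

#' Read a taxonomy table
#'
#' Reads a delimited text file (TSV or CSV, autodetected from the header
#' line) mapping samples to a four-rank taxonomy. Columns `sample_id`,
#' `species` and `genus` are required; `family` and `order` are optional
#' and stored as `NA` when absent. Extra columns are ignored.
#'
#' @param path Path to the table.
#' @return Data frame with columns `sample_id`, `species`, `genus`,
#'   `family`, `order`.
#' @export
read_taxonomy <- function(path) {
  tab <- read_delim_auto(path)
  required <- c("sample_id", "species", "genus")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("taxonomy table missing required column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample_id in taxonomy: ",
         paste(unique(tab$sample_id[duplicated(tab$sample_id)]),
               collapse = ", "))
  if (any(!nzchar(tab$species) | is.na(tab$species)))
    stop("empty species label for sample(s): ",
         paste(tab$sample_id[!nzchar(tab$species) | is.na(tab$species)],
               collapse = ", "))
  for (opt in c("family", "order"))
    if (!opt %in% names(tab)) tab[[opt]] <- NA_character_
  tab[, c("sample_id", "species", "genus", "family", "order")]
}

#' Write a taxonomy table as TSV
#' @param taxonomy Data frame from [read_taxonomy()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy <- function(taxonomy, path) {
  utils::write.table(taxonomy, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a species-delimitation partition
#'
#' Reads a two-column delimited file (`sample_id`, `group_id`) assigning
#' every sample to exactly one delimitation group. This is the transcription
#' format for the outputs of delimitation tools such as ASAP or bPTP. Group
#' ids are opaque labels: they carry no ordering semantics.
#'
#' @param path Path to the table.
#' @return Data frame with character columns `sample_id` and `group_id`.
#' @export
read_partition <- function(path) {
  tab <- read_delim_auto(path)
  if (!all(c("sample_id", "group_id") %in% names(tab)))
    stop("partition table must have columns sample_id and group_id")
  if (anyDuplicated(tab$sample_id))
    stop("sample listed twice in partition: ",
         paste(unique(tab$sample_id[duplicated(tab$sample_id)]),
               collapse = ", "))
  data.frame(sample_id = as.character(tab$sample_id),
             group_id = as.character(tab$group_id),
             stringsAsFactors = FALSE)
}

#' Write a partition as TSV
#' @param partition Data frame from [read_partition()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  utils::write.table(partition[, c("sample_id", "group_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted newick tree
#'
#' Parses a newick file into an [ape::read.tree()] `phylo` object after a
#' syntax precheck that reports the position of unbalanced parentheses.
#' Internal node labels are kept (they usually carry support values).
#'
#' @param path Path to a newick file.
#' @return A `phylo` object.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- cumsum((strsplit(txt, "")[[1]] == "(") -
                  (strsplit(txt, "")[[1]] == ")"))
  if (any(depth < 0))
    stop("newick parse error: unbalanced ')' at character ",
         which(depth < 0)[1L])
  if (utils::tail(depth, 1L) != 0)
    stop("newick parse error: ", utils::tail(depth, 1L),
         " unclosed '(' at end of input")
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("newick parse error in ", path)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  tree
}

#' Write a tree as newick
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a square distance matrix from TSV
#'
#' Reads a tab-separated square matrix whose first row and column hold
#' sample ids. Empty and `NA` cells become undefined distances.
#'
#' @param path Path to the TSV file.
#' @param model Distance model the values were computed under
#'   (`"k2p"` or `"p_distance"`); stored as metadata.
#' @return A `dist_matrix` object (see [build_distance_matrix()]).
#' @export
read_distance_matrix <- function(path, model = c("k2p", "p_distance")) {
  model <- match.arg(model)
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    stop("distance matrix must be square with matching row/column ids")
  new_dist_matrix(m, model = model)
}

#' Write a distance matrix as square TSV
#' @param dm A `dist_matrix` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "dist_matrix"))
  tab <- data.frame(sample_id = rownames(dm$values), dm$values,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Detect the delimiter (tab or comma) from the header line and read the
# whole table as character.
read_delim_auto <- function(path) {
  stopifnot(file.exists(path))
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, sep = sep, header = TRUE, quote = "\"",
                    colClasses = "character", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
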