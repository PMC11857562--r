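# Shared helpers: independent brute-force oracles and tiny builders.

# Per-position classifier used as an oracle for site_counts(): explicit
# if/else over every alignment column.
brute_site_counts <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- 0L; ts <- 0L; tv <- 0L
  for (k in seq_along(av)) {
    x <- av[k]; y <- bv[k]
    if (!(x %in% c("A", "C", "G", "T")) || !(y %in% c("A", "C", "G", "T")))
      next
    n <- n + 1L
    if (x == y) next
    if ((x == "A" && y == "G") || (x == "G" && y == "A") ||
        (x == "C" && y == "T") || (x == "T" && y == "C")) ts <- ts + 1L
    else tv <- tv + 1L
  }
  c(n_compared = n, n_transitions = ts, n_transversions = tv)
}

# All set partitions of seq_len(n) as lists of integer blocks (restricted
# growth strings).
all_set_partitions <- function(n) {
  out <- list()
  rec <- function(assign, k, m) {
    if (k > n) {
      out[[length(out) + 1L]] <<- split(seq_len(n), assign)
      return(invisible())
    }
    for (g in seq_len(m + 1L)) {
      assign[k] <- g
      rec(assign, k + 1L, max(m, g))
    }
  }
  rec(integer(n), 1L, 0L)
  out
}

# Direct transcription of the four pattern invariants, used as the oracle
# for classify_species(): group_of = named group vector, species_of =
# named species vector.
brute_pattern <- function(group_of, species_of, sp) {
  mine <- names(species_of)[species_of == sp]
  groups <- unique(group_of[mine])
  pure <- vapply(groups, function(g) {
    members <- names(group_of)[group_of == g]
    all(species_of[members] == sp)
  }, logical(1))
  if (length(groups) == 1L) {
    if (pure[1L]) "MONO" else "MERGE"
  } else if (all(pure)) "SPLIT" else "multi-SPLIT"
}

make_records <- function(ids, seqs)
  data.frame(sample_id = ids, sequence = seqs, stringsAsFactors = FALSE)

make_taxonomy <- function(ids, species, genus,
                          family = NA_character_, order = NA_character_)
  data.frame(sample_id = ids, species = species, genus = genus,
             family = family, order = order, stringsAsFactors = FALSE)
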