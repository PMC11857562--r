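# Builds the plain-text reference fixtures under inst/extdata/ from the
# published summary tables (entered cell-by-cell below) and constructs the
# synthetic monophyly-consistent tree. Run from the package root:
#   Rscript data-raw/make_fixtures.R
# Re-running is deterministic.

out <- "inst/extdata"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## ---- 16-isolate taxonomy -------------------------------------------------

tax16 <- data.frame(
  sample_id = c("Dpur", "Ddis", "TH11C", "TH18CC", "TH14B_Delta", "TH8C",
                "TH11CW", "TH14B", "Csub", "Cpse", "TH18B", "TH19B",
                "TH20A", "Cbhu", "Cpro", "TH20C"),
  species = c("Dictyostelium purpureum", "Dictyostelium discoideum",
              "Dictyostelium sp. TH11C", "Dictyostelium sp. TH11C",
              "Raperostelium sp. TH14B (Delta)", "Raperostelium sp. TH8C",
              "Raperostelium sp. TH14B", "Raperostelium sp. TH14B",
              "Cavenderia subdiscoidea", "Cavenderia pseudoaureostipes",
              "Cavenderia ungulata", "Cavenderia helicoidea",
              "Cavenderia protumula", "Cavenderia bhumiboliana",
              "Cavenderia protodigitata", "Cavenderia parvibrachiata"),
  genus = c(rep("Dictyostelium", 4), rep("Raperostelium", 4),
            rep("Cavenderia", 8)),
  family = c(rep("Dictyosteliaceae", 4), rep("Raperosteliaceae", 4),
             rep("Cavenderiaceae", 8)),
  order = c(rep("Dictyosteliales", 8), rep("Acytosteliales", 8)),
  stringsAsFactors = FALSE)
write.table(tax16, file.path(out, "dicty16_taxonomy.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

## ---- 16x16 distance tables ----------------------------------------------
# Published combined table: proportion of differing sites above the
# diagonal, K2P distance below. Rows in published order.

ids <- tax16$sample_id
raw <- rbind(
  c(  NA, 0.047, 0.042, 0.042, 0.115, 0.114, 0.105, 0.105, 0.254, 0.254, 0.253, 0.253, 0.253, 0.253, 0.253, 0.251),
  c(0.048,   NA, 0.034, 0.034, 0.110, 0.111, 0.113, 0.113, 0.257, 0.255, 0.254, 0.254, 0.254, 0.254, 0.254, 0.254),
  c(0.043, 0.035,   NA, 0.000, 0.111, 0.111, 0.111, 0.111, 0.258, 0.257, 0.257, 0.257, 0.257, 0.257, 0.257, 0.255),
  c(0.043, 0.035, 0.000,   NA, 0.111, 0.111, 0.111, 0.111, 0.258, 0.257, 0.257, 0.257, 0.257, 0.257, 0.257, 0.255),
  c(0.126, 0.119, 0.121, 0.121,   NA, 0.005, 0.038, 0.038, 0.262, 0.264, 0.263, 0.263, 0.263, 0.263, 0.263, 0.262),
  c(0.125, 0.120, 0.120, 0.120, 0.005,   NA, 0.041, 0.041, 0.261, 0.265, 0.263, 0.263, 0.263, 0.263, 0.263, 0.262),
  c(0.114, 0.123, 0.120, 0.120, 0.039, 0.042,   NA, 0.000, 0.262, 0.263, 0.264, 0.264, 0.264, 0.264, 0.264, 0.263),
  c(0.114, 0.123, 0.120, 0.120, 0.039, 0.042, 0.000,   NA, 0.262, 0.263, 0.264, 0.264, 0.264, 0.264, 0.264, 0.263),
  c(0.313, 0.318, 0.320, 0.320, 0.325, 0.324, 0.325, 0.325,   NA, 0.009, 0.006, 0.006, 0.006, 0.006, 0.006, 0.007),
  c(0.313, 0.316, 0.318, 0.318, 0.328, 0.330, 0.327, 0.327, 0.009,   NA, 0.006, 0.006, 0.006, 0.006, 0.006, 0.006),
  c(0.312, 0.313, 0.318, 0.318, 0.326, 0.326, 0.328, 0.328, 0.006, 0.006,   NA, 0.000, 0.000, 0.000, 0.000, 0.002),
  c(0.312, 0.313, 0.318, 0.318, 0.326, 0.326, 0.328, 0.328, 0.006, 0.006, 0.000,   NA, 0.000, 0.000, 0.000, 0.002),
  c(0.312, 0.313, 0.318, 0.318, 0.326, 0.326, 0.328, 0.328, 0.006, 0.006, 0.000, 0.000,   NA, 0.000, 0.000, 0.002),
  c(0.312, 0.313, 0.318, 0.318, 0.326, 0.326, 0.328, 0.328, 0.006, 0.006, 0.000, 0.000, 0.000,   NA, 0.000, 0.002),
  c(0.312, 0.313, 0.318, 0.318, 0.326, 0.326, 0.328, 0.328, 0.006, 0.006, 0.000, 0.000, 0.000, 0.000,   NA, 0.002),
  c(0.309, 0.313, 0.315, 0.315, 0.325, 0.325, 0.327, 0.327, 0.007, 0.006, 0.002, 0.002, 0.002, 0.002, 0.002,   NA))
dimnames(raw) <- list(ids, ids)

pdist <- raw; pdist[lower.tri(pdist)] <- t(raw)[lower.tri(raw)]  # upper tri
k2p   <- raw; k2p[upper.tri(k2p)]     <- t(raw)[upper.tri(raw)]  # lower tri
diag(pdist) <- 0; diag(k2p) <- 0
stopifnot(isSymmetric(pdist), isSymmetric(k2p))

write_square <- function(m, file) {
  tab <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  write.table(tab, file.path(out, file), sep = "\t", quote = FALSE,
              row.names = FALSE)
}
write_square(pdist, "dicty16_pdist.tsv")
write_square(k2p, "dicty16_k2p.tsv")

## ---- 214-sample / 44-species delimitation summary ------------------------
# species | n | ASAP pattern | ASAP groups | ML topology | support |
# bPTP pattern | bPTP groups   (group ranges expanded)

rows <- list(
  c("Dictyostelium ammophilum",      2, "MERGE",       "6",                       "MONO",     "98",  "MERGE",       "7"),
  c("Dictyostelium brefeldianum",    2, "MERGE",       "5",                       "non-MONO", "NA",  "MERGE",       "7"),
  c("Dictyostelium chordatum",       2, "MONO",        "8",                       "MONO",     "100", "MERGE",       "7"),
  c("Dictyostelium clavatum",        2, "MERGE",       "6",                       "non-MONO", "NA",  "MERGE",       "7"),
  c("Dictyostelium dimigraformum",   2, "MONO",        "4",                       "MONO",     "99",  "MERGE",       "7"),
  c("Dictyostelium discoideum",     17, "SPLIT",       "1,2",                     "non-MONO", "NA",  "MERGE",       "7"),
  c("Dictyostelium firmibasis",      4, "MONO",        "3",                       "MONO",     "100", "MERGE",       "7"),
  c("Dictyostelium giganteum",       4, "MONO",        "9",                       "MONO",     "92",  "MERGE",       "7"),
  c("Dictyostelium leptosomopsis",   3, "MERGE",       "5",                       "non-MONO", "NA",  "MERGE",       "7"),
  c("Dictyostelium longosporum",     2, "MERGE",       "6",                       "non-MONO", "NA",  "MERGE",       "7"),
  c("Dictyostelium macrocephalum",   2, "multi-SPLIT", "6,11",                    "non-MONO", "NA",  "MERGE",       "7"),
  c("Dictyostelium mucoroides",      8, "multi-SPLIT", "5,6,7",                   "non-MONO", "NA",  "MERGE",       "7"),
  c("Dictyostelium multiforme",      2, "MERGE",       "6",                       "non-MONO", "NA",  "MERGE",       "7"),
  c("Dictyostelium purpureum",      23, "SPLIT",       "12,13,14",                "MONO",     "81",  "MERGE",       "7"),
  c("Dictyostelium septentrionalis", 2, "MONO",        "10",                      "MONO",     "93",  "MERGE",       "7"),
  c("Dictyostelium sphaerocephalum", 6, "multi-SPLIT", "6,11",                    "non-MONO", "NA",  "MERGE",       "7"),
  c("Polysphondylium patagonicum",   2, "MERGE",       "15",                      "non-MONO", "NA",  "MERGE",       "8"),
  c("Polysphondylium violaceum",     9, "MERGE",       "15",                      "non-MONO", "NA",  "MERGE",       "8"),
  c("Raperostelium minutum",         4, "MONO",        "16",                      "MONO",     "100", "SPLIT",       "20,24,25"),
  c("Raperostelium tenue",           3, "SPLIT",       "17,18",                   "non-MONO", "NA",  "SPLIT",       "11,12"),
  c("Coremiostelium polycephalum",   5, "SPLIT",       "19,20,21,22",             "MONO",     "87",  "SPLIT",       "13,21,22,23"),
  c("Synstelium polycarpum",         2, "SPLIT",       "23,24",                   "MONO",     "100", "SPLIT",       "18,19"),
  c("Rostrostelium ellipticum",      2, "MONO",        "34",                      "MONO",     "100", "MONO",        "4"),
  c("Acytostelium amazonicum",       2, "SPLIT",       "35,36",                   "MONO",     "100", "SPLIT",       "5,6"),
  c("Acytostelium leptosomum",       2, "SPLIT",       "37,38",                   "MONO",     "99",  "SPLIT",       "2,3"),
  c("Cavenderia aureostipes",       29, "multi-SPLIT", "39,40,41,42,44,45",       "non-MONO", "NA",  "MERGE",       "1"),
  c("Cavenderia bhumiboliana",       2, "MERGE",       "45",                      "non-MONO", "NA",  "MERGE",       "1"),
  c("Cavenderia cf. aureostipes",   19, "multi-SPLIT", "39,40,43,44,45,46,47,48", "non-MONO", "NA",  "MERGE",       "1"),
  c("Cavenderia fasciculata",        8, "multi-SPLIT", "44,48",                   "non-MONO", "NA",  "MERGE",       "1"),
  c("Cavenderia helicoidea",         2, "MERGE",       "45",                      "non-MONO", "NA",  "MERGE",       "1"),
  c("Cavenderia parvibrachiata",     3, "MERGE",       "45",                      "MONO",     "88",  "MERGE",       "1"),
  c("Cavenderia protodigitata",      2, "MERGE",       "45",                      "non-MONO", "NA",  "MERGE",       "1"),
  c("Cavenderia protumula",          2, "MERGE",       "45",                      "non-MONO", "NA",  "MERGE",       "1"),
  c("Cavenderia pseudoaureostipes",  2, "MERGE",       "45",                      "MONO",     "100", "MERGE",       "1"),
  c("Cavenderia subdiscoidea",       2, "MERGE",       "42",                      "MONO",     "98",  "MERGE",       "1"),
  c("Cavenderia ungulata",           2, "MERGE",       "45",                      "non-MONO", "NA",  "MERGE",       "1"),
  c("Heterostelium asymetricum",     2, "MONO",        "29",                      "MONO",     "100", "MONO",        "17"),
  c("Heterostelium boreale",         2, "MONO",        "30",                      "MONO",     "100", "SPLIT",       "26,27"),
  c("Heterostelium candidum",        3, "multi-SPLIT", "25,32",                   "non-MONO", "NA",  "multi-SPLIT", "10,14"),
  c("Heterostelium colligatum",      3, "MERGE",       "33",                      "non-MONO", "NA",  "MERGE",       "15"),
  c("Heterostelium oculare",         2, "MONO",        "31",                      "MONO",     "100", "MONO",        "9"),
  c("Heterostelium pallidum",       10, "multi-SPLIT", "25,26",                   "non-MONO", "NA",  "multi-SPLIT", "10,16"),
  c("Heterostelium tenuissimum",     3, "multi-SPLIT", "26,27,28",                "non-MONO", "NA",  "MERGE",       "16"),
  c("Heterostelium tikalense",       2, "MERGE",       "33",                      "non-MONO", "NA",  "MERGE",       "15"))

summ <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
names(summ) <- c("species", "n_samples", "asap_pattern", "asap_groups",
                 "ml_topology", "ml_support", "bptp_pattern", "bptp_groups")
summ$n_samples <- as.integer(summ$n_samples)
summ$genus <- vapply(strsplit(summ$species, " "), `[`, character(1), 1)
summ <- summ[, c("species", "genus", "n_samples", "asap_pattern",
                 "asap_groups", "ml_topology", "ml_support", "bptp_pattern",
                 "bptp_groups")]
stopifnot(nrow(summ) == 44, sum(summ$n_samples) == 214)
write.table(summ, file.path(out, "dicty214_summary.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

## ---- expanded taxonomy and partitions ------------------------------------

sample_ids <- function(species, n)
  sprintf("%s_%02d", gsub("[^A-Za-z0-9]+", "_", species), seq_len(n))

tax214 <- do.call(rbind, lapply(seq_len(nrow(summ)), function(i)
  data.frame(sample_id = sample_ids(summ$species[i], summ$n_samples[i]),
             species = summ$species[i], genus = summ$genus[i],
             stringsAsFactors = FALSE)))
write.table(tax214, file.path(out, "dicty214_taxonomy.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# Spread each species' samples over its printed groups: the first |G|
# samples take one group each, the remainder stay in the last group.
expand_partition <- function(groups_col) {
  do.call(rbind, lapply(seq_len(nrow(summ)), function(i) {
    g <- trimws(strsplit(summ[[groups_col]][i], ",")[[1]])
    n <- summ$n_samples[i]
    stopifnot(n >= length(g))
    data.frame(sample_id = sample_ids(summ$species[i], n),
               group_id = g[pmin(seq_len(n), length(g))],
               stringsAsFactors = FALSE)
  }))
}
asap <- expand_partition("asap_groups")
bptp <- expand_partition("bptp_groups")
stopifnot(length(unique(asap$group_id)) == 48,
          length(unique(bptp$group_id)) == 27)
write.table(asap, file.path(out, "dicty214_asap.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(bptp, file.path(out, "dicty214_bptp.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

## ---- synthetic monophyly-consistent tree ---------------------------------
# MONO species become pure clades; the non-MONO species of each genus are
# interleaved round-robin in a caterpillar so none of them is monophyletic.
# A genus whose only non-MONO species has no sibling to tangle with gets a
# MONO clade nested inside that species' span instead.

clade <- function(parts) {
  if (length(parts) == 1L) parts else
    sprintf("(%s)", paste(parts, collapse = ","))
}
caterpillar <- function(tips) Reduce(function(a, b) sprintf("(%s,%s)", a, b),
                                     tips)

genus_clade <- function(g) {
  sub <- summ[summ$genus == g, ]
  mono <- sub$species[sub$ml_topology == "MONO"]
  nonmono <- sub$species[sub$ml_topology != "MONO"]
  mono_clades <- vapply(mono, function(s)
    clade(sample_ids(s, sub$n_samples[sub$species == s])), character(1))
  if (length(nonmono) == 0L) {
    return(clade(unname(mono_clades)))
  }
  if (length(nonmono) == 1L) {
    stopifnot(length(mono) >= 1L)  # need something to break the clade with
    tips <- sample_ids(nonmono, sub$n_samples[sub$species == nonmono])
    tangle <- sprintf("(%s,(%s,%s))", tips[1L], mono_clades[[1L]],
                      clade(tips[-1L]))
    rest <- mono_clades[-1L]
    return(clade(c(unname(rest), tangle)))
  }
  # round-robin interleave the non-MONO species' samples
  per_sp <- lapply(nonmono, function(s)
    sample_ids(s, sub$n_samples[sub$species == s]))
  ord <- character(0)
  while (any(lengths(per_sp) > 0)) {
    for (k in seq_along(per_sp)) {
      if (length(per_sp[[k]])) {
        ord <- c(ord, per_sp[[k]][1L])
        per_sp[[k]] <- per_sp[[k]][-1L]
      }
    }
  }
  clade(c(unname(mono_clades), caterpillar(ord)))
}

genera <- unique(summ$genus)
newick <- sprintf("(Acanthamoeba_castellanii,(%s));",
                  paste(vapply(genera, genus_clade, character(1)),
                        collapse = ","))
writeLines(newick, file.path(out, "dicty214_ml_synthetic.nwk"))

## ---- verify the fixtures against the published numbers -------------------

if (requireNamespace("pkgload", quietly = TRUE)) {
  pkgload::load_all(".", quiet = TRUE)
  rep_asap <- score_partition(dicty214_partition("asap"), dicty214_taxonomy())
  rep_bptp <- score_partition(dicty214_partition("bptp"), dicty214_taxonomy())
  rep_tree <- score_tree(dicty214_tree(), dicty214_taxonomy(),
                         outgroup_tip = "Acanthamoeba_castellanii")
  stopifnot(
    abs(rep_asap$success_rate - 22.73) < 0.01,
    abs(rep_asap$weighted_success_rate - 12.15) < 0.01,
    rep_asap$n_groups == 48,
    abs(rep_bptp$success_rate - 6.82) < 0.01,
    abs(rep_bptp$weighted_success_rate - 2.80) < 0.01,
    rep_bptp$n_groups == 27,
    sum(rep_tree$per_species$pattern == "MONO") == 19,
    abs(rep_tree$success_rate - 43.18) < 0.01)
  message("fixture verification passed")
}
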