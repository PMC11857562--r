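test_that("per-species verdicts follow the pattern definitions", {
  asap <- dicty214_partition("asap")
  tax <- dicty214_taxonomy()
  d_split <- classify_species(asap, tax, "Dictyostelium discoideum")
  expect_equal(d_split$pattern, "SPLIT")
  expect_equal(d_split$groups, c("1", "2"))
  d_merge <- classify_species(asap, tax, "Dictyostelium ammophilum")
  expect_equal(d_merge$pattern, "MERGE")
  expect_equal(d_merge$groups, "6")
  d_multi <- classify_species(asap, tax, "Dictyostelium macrocephalum")
  expect_equal(d_multi$pattern, "multi-SPLIT")
  expect_setequal(d_multi$groups, c("11", "6"))
  d_mono <- classify_species(asap, tax, "Dictyostelium chordatum")
  expect_equal(d_mono$pattern, "MONO")
  expect_error(classify_species(asap, tax, "No such species"), "not present")
})

test_that("every published per-species pattern is reproduced", {
  summ <- dicty214_summary()
  tax <- dicty214_taxonomy()
  for (method in c("asap", "bptp")) {
    part <- dicty214_partition(method)
    col <- paste0(method, "_pattern")
    got <- vapply(summ$species, function(sp)
      classify_species(part, tax, sp)$pattern, character(1))
    expect_equal(unname(got), summ[[col]],
                 label = paste(method, "patterns"))
  }
})

test_that("verdicts agree with an exhaustive brute-force oracle", {
  # all set partitions of up to 6 samples over up to 3 species
  for (n in 2:6) {
    species_of <- stats::setNames(
      paste0("sp", rep_len(1:3, n)), paste0("s", seq_len(n)))
    tax <- make_taxonomy(names(species_of), unname(species_of), "G")
    parts <- all_set_partitions(n)
    for (p in parts) {
      group_of <- stats::setNames(rep(seq_along(p), lengths(p)),
                                  paste0("s", unlist(p)))
      part_df <- data.frame(sample_id = names(group_of),
                            group_id = as.character(group_of))
      counts <- table(species_of)
      for (sp in names(counts)[counts >= 2]) {
        expect_equal(
          classify_species(part_df, tax, sp)$pattern,
          brute_pattern(stats::setNames(as.character(group_of),
                                        names(group_of)),
                        species_of, sp),
          label = sprintf("n=%d partition=%s species=%s", n,
                          paste(group_of, collapse = ""), sp))
      }
    }
  }
})

test_that("partition scoring reproduces the published success rates", {
  tax <- dicty214_taxonomy()
  asap <- score_partition(dicty214_partition("asap"), tax)
  expect_equal(asap$n_species_scored, 44L)
  expect_equal(asap$n_samples_scored, 214L)
  expect_equal(asap$n_groups, 48L)
  expect_equal(sum(asap$per_species$pattern == "MONO"), 10L)
  expect_equal(round(asap$success_rate, 2), 22.73)
  expect_equal(round(asap$weighted_success_rate, 2), 12.15)
  bptp <- score_partition(dicty214_partition("bptp"), tax)
  expect_equal(bptp$n_groups, 27L)
  expect_equal(round(bptp$success_rate, 2), 6.82)
  expect_equal(round(bptp$weighted_success_rate, 2), 2.80)
})

test_that("the true partition scores a perfect rate", {
  tax <- dicty214_taxonomy()
  truth <- data.frame(sample_id = tax$sample_id, group_id = tax$species)
  rep <- score_partition(truth, tax)
  expect_equal(rep$success_rate, 100)
  expect_equal(rep$weighted_success_rate, 100)
  expect_equal(rep$n_groups, 44L)
})

test_that("permuting group ids leaves every report invariant", {
  set.seed(5)
  tax <- dicty214_taxonomy()
  part <- dicty214_partition("asap")
  ids <- unique(part$group_id)
  remap <- stats::setNames(sample(sprintf("z%02d", seq_along(ids))), ids)
  part2 <- part
  part2$group_id <- unname(remap[part$group_id])
  r1 <- score_partition(part, tax)
  r2 <- score_partition(part2, tax)
  expect_equal(r2$per_species$pattern, r1$per_species$pattern)
  expect_equal(r2$success_rate, r1$success_rate)
  expect_equal(r2$weighted_success_rate, r1$weighted_success_rate)
  expect_equal(r2$n_groups, r1$n_groups)
})

test_that("weighted success equals plain success under equal sample counts", {
  tax <- make_taxonomy(paste0("s", 1:6),
                       rep(c("spA", "spB", "spC"), each = 2), "G")
  part <- data.frame(sample_id = paste0("s", 1:6),
                     group_id = c("1", "1", "2", "2", "2", "2"))
  rep <- score_partition(part, tax)
  expect_equal(rep$success_rate, rep$weighted_success_rate)
  expect_lte(rep$weighted_success_rate, 100)
})

test_that("monophyly uses MRCA purity on rooted trees", {
  tax <- make_taxonomy(c("a1", "a2", "b1", "c1"),
                       c("A", "A", "B", "C"), "G")
  t1 <- ape::read.tree(text = "((a1,a2),b1);")
  expect_true(is_species_monophyletic(t1, tax, "A"))
  t2 <- ape::read.tree(text = "((a1,b1),a2);")
  expect_false(is_species_monophyletic(t2, tax, "A"))
  t3 <- ape::read.tree(text = "((a1,(a2,b1)),c1);")
  expect_false(is_species_monophyletic(t3, tax, "A", outgroup_tip = "c1"))
  expect_error(
    is_species_monophyletic(ape::read.tree(text = "((a1,b1),c1);"), tax, "A"),
    "missing from tree")
  expect_error(
    is_species_monophyletic(t1, tax, "A", outgroup_tip = "zz"),
    "outgroup")
  # unrooted trees are rejected without an outgroup
  t4 <- ape::read.tree(text = "(a1,a2,b1,c1);")
  expect_error(is_species_monophyletic(t4, tax, "A"), "unrooted")
})

test_that("monophyly agrees with the ape reference implementation", {
  set.seed(77)
  for (r in 1:20) {
    tree <- ape::rtree(12)
    tax <- make_taxonomy(tree$tip.label,
                         paste0("sp", sample(1:4, 12, replace = TRUE)), "G")
    for (sp in unique(tax$species)) {
      tips <- tax$sample_id[tax$species == sp]
      if (length(tips) < 2) next
      expect_equal(is_species_monophyletic(tree, tax, sp),
                   ape::is.monophyletic(tree, tips),
                   label = paste("rep", r, sp))
    }
  }
})

test_that("tree scoring reproduces the published monophyly summary", {
  rep <- score_tree(dicty214_tree(), dicty214_taxonomy(),
                    outgroup_tip = "Acanthamoeba_castellanii")
  expect_equal(rep$n_species_scored, 44L)
  expect_equal(sum(rep$per_species$pattern == "MONO"), 19L)
  expect_equal(round(rep$success_rate, 2), 43.18)
  # every per-species monophyly call matches the published column
  summ <- dicty214_summary()
  got <- rep$per_species$pattern[match(summ$species,
                                       rep$per_species$species)]
  expect_equal(got, summ$ml_topology)
})

test_that("tree scoring handles perfect and broken sorting", {
  cfg <- sim_config(n_genera = 2, species_per_genus = 2,
                    samples_per_species = 3, seq_length = 100,
                    d_intra = 0.01, d_inter_species = 0.05,
                    d_inter_genus = 0.2, seed = 2)
  sim <- simulate_dataset(cfg)
  expect_equal(score_tree(sim$tree, sim$taxonomy)$success_rate, 100)
  # break one species across two clades
  broken <- ape::read.tree(text = paste0(
    "((g01_s01_i01,(g01_s02_i01,g01_s02_i02)),",
    "(g01_s01_i02,g01_s02_i03));"))
  tax <- sim$taxonomy[sim$taxonomy$sample_id %in% broken$tip.label, ]
  rep <- score_tree(broken, tax)
  expect_equal(rep$per_species$pattern[rep$per_species$species == "g01_s01"],
               "non-MONO")
})
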