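test_that("taxonomy simulation lays out genera, species and samples", {
  cfg <- sim_config(n_genera = 2, species_per_genus = 2,
                    samples_per_species = 2, seed = 1)
  tx <- simulate_taxonomy(cfg)
  expect_equal(nrow(tx$taxonomy), 8L)
  expect_equal(length(unique(tx$partition$group_id)), 4L)
  expect_equal(anyDuplicated(tx$taxonomy$sample_id), 0L)
  expect_error(sim_config(species_per_genus = 0) |> simulate_taxonomy())
})

test_that("the tableshape layout replays the reference imbalance", {
  cfg <- sim_config(samples_per_species = "tableshape", seed = 1)
  tx <- simulate_taxonomy(cfg)
  expect_equal(nrow(tx$taxonomy), 214L)
  expect_equal(length(unique(tx$taxonomy$species)), 44L)
  expect_equal(length(unique(tx$taxonomy$genus)), 9L)
})

test_that("all-singleton layouts give an empty delimitation report", {
  cfg <- sim_config(n_genera = 2, species_per_genus = 2,
                    samples_per_species = 1, seed = 1)
  tx <- simulate_taxonomy(cfg)
  expect_warning(rep <- score_partition(tx$partition, tx$taxonomy),
                 "no species")
  expect_equal(rep$n_species_scored, 0L)
})

test_that("simulated trees realize the configured divergence scales exactly", {
  cfg <- sim_config(n_genera = 3, species_per_genus = c(1, 2, 4),
                    samples_per_species = c(3, 1, 2, 2, 2, 1, 4),
                    seq_length = 10, d_intra = 0.004,
                    d_inter_species = 0.04, d_inter_genus = 0.3, seed = 9)
  tx <- simulate_taxonomy(cfg)
  tree <- simulate_tree(tx$taxonomy, cfg)
  expect_true(ape::is.rooted(tree))
  pd <- ape::cophenetic.phylo(tree)
  tax <- tx$taxonomy[match(rownames(pd), tx$taxonomy$sample_id), ]
  for (i in seq_len(nrow(pd) - 1)) for (j in seq.int(i + 1, nrow(pd))) {
    target <- if (tax$species[i] == tax$species[j]) cfg$d_intra
      else if (tax$genus[i] == tax$genus[j]) cfg$d_inter_species
      else cfg$d_inter_genus
    expect_equal(pd[i, j], target, tolerance = 1e-10)
  }
})

test_that("single-species star trees put all tips at the intra distance", {
  cfg <- sim_config(n_genera = 1, species_per_genus = 1,
                    samples_per_species = 3, d_intra = 0.01,
                    d_inter_species = 0.01, d_inter_genus = 0.01, seed = 1)
  tx <- simulate_taxonomy(cfg)
  pd <- ape::cophenetic.phylo(simulate_tree(tx$taxonomy, cfg))
  expect_true(all(abs(pd[upper.tri(pd)] - 0.01) < 1e-12))
})

test_that("sequence evolution is deterministic and seed-sensitive", {
  cfg <- sim_config(n_genera = 2, species_per_genus = 2,
                    samples_per_species = 2, seq_length = 400, seed = 123)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_alignment(s1$records, f1)
  write_alignment(s2$records, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  cfg3 <- sim_config(n_genera = 2, species_per_genus = 2,
                     samples_per_species = 2, seq_length = 400, seed = 124)
  expect_false(identical(simulate_dataset(cfg3)$records, s1$records))
  # the simulator must not disturb the caller's RNG stream
  set.seed(55); before <- runif(1)
  set.seed(55); invisible(simulate_dataset(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("a zero-length tree yields identical sequences", {
  cfg <- sim_config(n_genera = 1, species_per_genus = 1,
                    samples_per_species = 4, seq_length = 200,
                    d_intra = 0, d_inter_species = 0, d_inter_genus = 0,
                    seed = 6)
  sim <- simulate_dataset(cfg)
  expect_equal(length(unique(sim$records$sequence)), 1L)
})

test_that("huge kappa suppresses transversions on short branches", {
  for (s in 1:10) {
    cfg <- sim_config(n_genera = 1, species_per_genus = 1,
                      samples_per_species = 2, seq_length = 10000,
                      kappa = 1e6, d_intra = 0.01, d_inter_species = 0.01,
                      d_inter_genus = 0.01, seed = 3000 + s)
    sim <- simulate_dataset(cfg)
    cnt <- site_counts(sim$records$sequence[1], sim$records$sequence[2])
    expect_equal(unname(cnt["n_transversions"]), 0L)
    expect_gt(cnt[["n_transitions"]], 0L)
  }
})

test_that("per-class mean distances recover the generating scales", {
  targets <- c(intra = 0.005, wtg = 0.05, btg = 0.25)
  reps <- 20
  means <- matrix(NA_real_, reps, 3, dimnames = list(NULL, names(targets)))
  for (r in seq_len(reps)) {
    cfg <- sim_config(n_genera = 2, species_per_genus = 2,
                      samples_per_species = 2, seq_length = 5000,
                      d_intra = targets["intra"],
                      d_inter_species = targets["wtg"],
                      d_inter_genus = targets["btg"], seed = 5000 + r)
    sim <- simulate_dataset(cfg)
    dm <- build_distance_matrix(sim$records, "k2p")
    pairs <- classify_pairs(dm, sim$taxonomy)
    s <- summarize_classes(pairs, levels = 2)
    means[r, ] <- s$mean[match(c("intraspecific", "within_genus",
                                 "between_genus"), s$class)]
  }
  for (k in 1:3) {
    se <- stats::sd(means[, k]) / sqrt(reps)
    expect_lt(abs(mean(means[, k]) - targets[k]), 3 * se + 1e-4)
  }
})

test_that("threshold clustering matches its definitions at the extremes", {
  cfg <- sim_config(n_genera = 2, species_per_genus = 2,
                    samples_per_species = 3, seq_length = 600,
                    d_intra = 0.01, d_inter_species = 0.08,
                    d_inter_genus = 0.25, seed = 14)
  sim <- simulate_dataset(cfg)
  dm <- build_distance_matrix(sim$records, "p_distance")
  # threshold 0 reproduces haplotype classes
  p0 <- threshold_cluster(dm, 0)
  hap <- collapse_haplotypes(dm)
  expect_equal(length(unique(p0$group_id)), length(hap))
  # threshold above the maximum joins everything
  pmax <- threshold_cluster(dm, max(dm$values) + 0.01)
  expect_equal(length(unique(pmax$group_id)), 1L)
})

test_that("a separated simulation passes the whole pipeline perfectly", {
  cfg <- sim_config(n_genera = 3, species_per_genus = 3,
                    samples_per_species = 3, seq_length = 1500,
                    d_intra = 0.005, d_inter_species = 0.05,
                    d_inter_genus = 0.3, seed = 42)
  sim <- simulate_dataset(cfg)
  dm <- build_distance_matrix(sim$records, "k2p")
  pairs <- classify_pairs(dm, sim$taxonomy)
  max_intra <- max(pairs$distance[pairs$class == "intraspecific"])
  min_inter <- min(pairs$distance[pairs$class != "intraspecific"])
  expect_lt(max_intra, min_inter)  # precondition for the guarantees below
  gp <- gap_per_sample(dm, sim$taxonomy)
  expect_true(all(gp$gap > 0))
  for (thr in c(mean(c(max_intra, min_inter)), max_intra + 1e-6,
                min_inter - 1e-6)) {
    rep <- score_partition(threshold_cluster(dm, thr), sim$taxonomy)
    expect_equal(rep$success_rate, 100)
  }
  expect_equal(score_tree(sim$tree, sim$taxonomy)$success_rate, 100)
})

test_that("overlapping divergences break delimitation qualitatively", {
  cfg <- sim_config(n_genera = 2, species_per_genus = 4,
                    samples_per_species = 4, seq_length = 1200,
                    d_intra = 0.02, d_inter_species = 0.005,
                    d_inter_genus = 0.3, seed = 5, allow_overlap = TRUE)
  sim <- simulate_dataset(cfg)
  dm <- build_distance_matrix(sim$records, "k2p")
  gp <- gap_per_sample(dm, sim$taxonomy)
  expect_true(any(gp$gap < 0))
  rep <- score_partition(threshold_cluster(dm, 0.02), sim$taxonomy)
  expect_true(any(rep$per_species$pattern %in% c("MERGE", "multi-SPLIT")))
  expect_lt(rep$success_rate, 100)
})

test_that("nested divergence scales are enforced unless overlap is allowed", {
  expect_error(sim_config(d_intra = 0.05, d_inter_species = 0.01),
               "allow_overlap")
  expect_silent(sim_config(d_intra = 0.05, d_inter_species = 0.01,
                           d_inter_genus = 0.3, allow_overlap = TRUE))
})
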