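#!/usr/bin/env Rscript
# Generates the synthetic survey used by the downstream scripts: a
# three-genus taxonomy with nested divergence scales, the generating tree,
# the K80-evolved alignment, and the true partition.

library(barcodegap)
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(n_genera = 3, species_per_genus = 3,
                  samples_per_species = 3, seq_length = 1500,
                  d_intra = 0.005, d_inter_species = 0.05,
                  d_inter_genus = 0.3, seed = 42)
sim <- simulate_dataset(cfg)

write_alignment(sim$records, "results/synthetic.fasta")
write_taxonomy(sim$taxonomy, "results/synthetic_taxonomy.tsv")
write_partition(sim$partition, "results/synthetic_true_partition.tsv")
write_newick(sim$tree, "results/synthetic_tree.nwk")

message("simulated ", nrow(sim$records), " sequences of ",
        cfg$seq_length, " sites: ",
        length(unique(sim$taxonomy$species)), " species in ",
        length(unique(sim$taxonomy$genus)), " genera")
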