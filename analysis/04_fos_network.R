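#!/usr/bin/env Rscript
# The c-Fos functional-connectivity stage on synthetic density tables with
# planted structure: normalization against a control group, Spearman
# matrices, the three confidence-tier graphs (rho >= 0.51 / 0.64 / 0.73 at
# n = 15), degree/betweenness hubs with leave-one-out robustness, and Markov
# clustering at inflation 2.1.
# Finds: the three planted co-activation modules are recovered as clusters,
# and the planted hub is the unique region passing the 80th-percentile
# degree + betweenness conjunction in all three tiers.

suppressPackageStartupMessages(library(seqnav))
dir.create("results", showWarnings = FALSE)
regions <- fos_regions()

# --- raw counts and normalization -------------------------------------
raw_exp <- generate_fos_table(fos_spec(n_subjects = 15, blocks = list(
  list(regions = regions[1:11], rho = 0.85),
  list(regions = regions[12:22], rho = 0.85),
  list(regions = regions[23:33], rho = 0.85)), group = "exploitation",
  seed = 1))
raw_ctl <- generate_fos_table(fos_spec(n_subjects = 15,
                                       group = "swim-control", seed = 2))
combined <- combine_fos(raw_exp$table, raw_ctl$table)
norm <- normalize_density(combined, "swim-control")
write_fos(norm, "results/fos_normalized.csv")

# --- tier graphs and clustering on the exploitation group -------------
tiers <- build_tier_graphs(norm, "exploitation")
cl <- mcl_clusters(tiers$main, inflation = 2.1)
cat("clusters found:", length(unique(cl)), "\n")
print(split(names(cl), cl))

# --- planted-hub fixture ----------------------------------------------
hub_spec <- fos_spec(
  n_subjects = 15,
  blocks = list(list(regions = regions[1:10], rho = 0.45),
                list(regions = regions[11:16], rho = 0.74)),
  hub = list(region = regions[34], blocks = 1, rho = 0.72), seed = 1)
gh <- suppressWarnings(generate_fos_table(hub_spec))
htiers <- build_tier_graphs(gh$table)
hubs <- identify_hubs(htiers)
print(hubs)
loo <- leave_one_out_hubs(gh$table)
cat("leave-one-out hub frequency of", regions[34], ":",
    loo$hub_count[loo$region == regions[34]], "/ 15\n")

export_graph(htiers$main, "results/hub_network_edges.tsv",
             "results/hub_network.graphml", hubs = hubs$hubs,
             clusters = mcl_clusters(htiers$main))
write.table(loo, "results/hub_loo_frequency.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote results/fos_normalized.csv, hub_network_*, hub_loo_frequency.tsv\n")
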