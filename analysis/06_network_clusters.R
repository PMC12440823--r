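#!/usr/bin/env Rscript
# Stage 6: network-level view of interaction changes. The proteome's
# proteins are organized into a synthetic complex catalogue (cliques plus
# sparse cross-complex edges); marker-hit proteins from stage 5 seed a
# personalized PageRank (damping 0.9), the top 40% of scores induce the
# working subnetwork, walktrap (4 steps) clusters it, clusters with at
# least 4 subunits are kept and named by the complex holding most changing
# markers, and a second (mutant) condition is compared cluster by cluster.

suppressMessages(library(flipms))
seed <- 42

proteome <- read_proteome_fasta("results/proteome_synthetic.fasta")
hit_proteins <- readLines("results/hit_proteins.txt")

# synthetic complex catalogue over the simulated proteome
set.seed(seed + 20)
sizes <- c(6, 6, 5, 5, 4, 4, 4, 4, 3, 3)
net0 <- simulate_complex_network(sizes, n_bridge_edges = 8, seed = seed + 21)
id_map <- setNames(proteome$protein_id[seq_len(sum(sizes))],
                   sort(unique(net0$complexes$protein_id)))
complexes <- transform(net0$complexes, protein_id = id_map[protein_id])
edges <- data.frame(from = id_map[net0$edges$from],
                    to = id_map[net0$edges$to], stringsAsFactors = FALSE)
network <- build_network(complexes, extra_edges = edges)

seeds <- intersect(hit_proteins, igraph::V(network$graph)$name)
cat(sprintf("network: %d proteins, %d edges; %d of %d hit proteins present\n",
            igraph::vcount(network$graph), igraph::ecount(network$graph),
            length(seeds), length(hit_proteins)))

scores <- personalized_pagerank(network, seeds, damping = 0.9)
sub <- top_quantile_subnetwork(network, scores, keep_fraction = 0.40)
membership <- walktrap_clusters(sub, steps = 4)
clusters <- filter_and_name(membership, network,
                            changed_proteins = seeds, min_size = 4)

# mutant comparison: the mutant changes a subset of the wild-type markers
hits <- read.delim("results/marker_hits.tsv", stringsAsFactors = FALSE)
hits$region_id <- paste(hits$protein_id, hits$marker_start,
                        hits$marker_end)
set.seed(seed + 22)
mut <- hits[sample(nrow(hits), max(1, nrow(hits) %/% 2)), ]
cmp <- compare_conditions(clusters, hits, mut)
write.table(cmp, "results/network_clusters.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("subnetwork: %d proteins; %d clusters of >= 4 subunits\n",
            igraph::vcount(sub), nrow(clusters)))
for (i in seq_len(nrow(cmp)))
  cat(sprintf("  cluster %s (%d members, %d changing): %s [%s]\n",
              cmp$name[i], cmp$size[i], cmp$n_changing[i],
              cmp$changing_members[i], cmp$delta[i]))
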