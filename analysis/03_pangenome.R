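#!/usr/bin/env Rscript
# Stage 3 — the pangenome: minbit graph, MCL orthogroups, classes, ordering.
#
# All-vs-all protein alignment across the population catalogs, minbit 0.5
# edge filter, MCL at inflation 10, core/singleton/clade-specific classing,
# Ward ordering of frequency vectors, and the average-linkage ANI tree over
# population genomes (Newick).

library(metapang)

st1 <- readRDS("results/01_state.rds")
st2 <- readRDS("results/02_state.rds")

message("building protein similarity graph over ",
        nrow(st2$catalogs), " catalog proteins")
graph <- build_graph(st2$catalogs)
message("  edges kept at minbit 0.5: ", nrow(graph$edges))
write_tsv(graph$edges, "results/graph_edges.tsv")

mcl <- mcl_cluster(graph)
message("MCL (inflation 10): ", length(mcl$clusters), " orthogroups, ",
        "converged in ", mcl$iterations, " iterations")
og <- orthogroup_table(mcl, graph)
write_tsv(og$table, "results/orthogroups.tsv")
write_profile_tsv(og$presence, "results/og_presence.tsv",
                  id_col = "orthogroup_id")

subclade_map <- data.frame(
  population_id = unique(st2$partition$population_id))
truth <- setNames(st1$community$truth$genome_subclade$subclade,
                  st1$community$truth$genome_subclade$genome_id)
subclade_map$group <- truth[st2$partition$genome_id[
  match(subclade_map$population_id, st2$partition$population_id)]]
classes <- classify_orthogroups(og, subclade_map)
write_tsv(classes$classes, "results/og_classes.tsv")
write_tsv(classes$sharing, "results/og_sharing.tsv")
message("orthogroup classes:")
print(table(classes$classes$class))

pani <- popgenome_ani(st2$ani, st2$partition)
tree <- order_genomes_by_ani(pani)
writeLines(tree$newick, "results/populations.nwk")
message("population tree: ", tree$newick)

saveRDS(list(graph = graph, mcl = mcl, og = og, classes = classes,
             pop_ani = pani, tree = tree), "results/03_state.rds")
message("wrote orthogroups, classes, sharing counts and the Newick tree")
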