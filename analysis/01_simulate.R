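#!/usr/bin/env Rscript
# Stage 1 — simulate the study community.
#
# Builds the default depth-stratified community: 4 subclades x 3 genomes
# (~430 genes), subclades ~98% ANI inside and ~75% across, Gaussian depth
# zonation over 7 depths (25-1000 m), genomes degraded to 54% completeness,
# and 20,000 single-end 100-bp reads per depth at 1% error. Writes genomes,
# genes, truth tables and per-sample FASTQ under results/community/.

library(metapang)

design <- community_design(rng_seed = 42)
dir.create("results", showWarnings = FALSE)

message("evolving ", design$n_subclades * design$genomes_per_subclade,
        " genomes in ", design$n_subclades, " subclades")
community <- evolve_genomes(design)
message("  gene records: ", nrow(community$genes))

community <- apply_incompleteness(community, design$completeness_fraction)
message("degraded to ", design$completeness_fraction * 100,
        "% completeness; ", length(community$truth$dropped),
        " genes dropped")

write_community(community, "results/community")

message("sampling ", design$reads_per_sample, " reads at each of ",
        length(design$depth_grid), " depths")
read_sets <- sample_reads(community)
write_reads(read_sets, "results/reads")

saveRDS(list(design = design, community = community,
             read_sets = read_sets), "results/01_state.rds")
message("wrote results/community/ and results/reads/")
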