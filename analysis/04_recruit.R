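#!/usr/bin/env Rscript
# Stage 4 — metagenomic read recruitment and coverage profiles.
#
# Maps every sample's reads onto the pooled gene catalog (accepted at 80%
# identity over 70% of the read, best hit only) and derives mean per-base
# coverage per gene, per orthogroup and per population genome across the
# depth gradient. Populations without any mapped read would be discarded
# here (locally-irrelevant rule).

library(metapang)

st1 <- readRDS("results/01_state.rds")
st2 <- readRDS("results/02_state.rds")
st3 <- readRDS("results/03_state.rds")

catalog <- setNames(st2$catalogs$seq_nt, st2$catalogs$gene_id)
assignments <- list()
for (sid in names(st1$read_sets$reads)) {
  asg <- recruit_reads(st1$read_sets$reads[[sid]], catalog)
  message(sid, ": ", nrow(asg), " reads accepted, ",
          attr(asg, "n_unassigned"), " unassigned")
  assignments[[sid]] <- asg
}

gene_cov <- coverage_per_gene(assignments, catalog,
                              st1$read_sets$metadata)
write_profile_tsv(gene_cov, "results/coverage_genes.tsv",
                  id_col = "gene_id")

og_cov <- aggregate_coverage(gene_cov,
                             setNames(st3$og$table$orthogroup_id,
                                      st3$og$table$gene_id))
write_profile_tsv(og_cov, "results/coverage_orthogroups.tsv",
                  id_col = "orthogroup_id")

pop_cov <- aggregate_coverage(gene_cov,
                              setNames(st2$catalogs$population_id,
                                       st2$catalogs$gene_id))
write_profile_tsv(pop_cov, "results/coverage_populations.tsv",
                  id_col = "population_id")
message("population coverage by depth:")
print(round(unclass(pop_cov), 2))

kept <- filter_locally_relevant(st2$populations, pop_cov)
removed <- attr(kept, "removed")
message(if (length(removed) == 0) "all populations locally relevant"
        else paste("discarded:", paste(removed, collapse = ", ")))

saveRDS(list(assignments = assignments, gene_cov = gene_cov,
             og_cov = og_cov, pop_cov = pop_cov,
             populations = kept), "results/04_state.rds")
message("wrote coverage profiles")
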