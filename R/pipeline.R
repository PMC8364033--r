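#' Run the full metapangenomic pipeline on a synthetic community
#'
#' Executes the stages in dependency order: community simulation (evolve,
#' degrade to the design's completeness, sample stratified reads), pairwise
#' genome ANI, population binning at the 95% boundary, pooled gene-catalog
#' dereplication per population, population-level ANI ordering tree, protein
#' similarity graph + MCL orthogroups + frequency classification, read
#' recruitment and coverage profiles (gene, orthogroup, population),
#' locally-relevant filtering, and ecotype delineation; pathway profiling
#' runs when an annotation table is supplied. Every stage writes TSV/FASTA
#' outputs under \code{outdir} plus a JSON manifest with parameters and
#' md5 checksums of every file; reruns with an identical design and seed are
#' byte-identical.
#'
#' @param design a \code{\link{community_design}}.
#' @param config a \code{\link{threshold_config}}.
#' @param outdir output directory.
#' @param linkage population clustering linkage ("single" or "complete").
#' @param annotation optional data.frame (gene_id, pathway).
#' @param scheme a \code{\link{scoring_scheme}}.
#' @return invisibly, a list with every intermediate result and
#'   \code{manifest} (the manifest path).
#' @export
run_pipeline <- function(design = community_design(),
                         config = threshold_config(),
                         outdir, linkage = "single", annotation = NULL,
                         scheme = scoring_scheme()) {
  t0 <- Sys.time()
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(msg) message(format(Sys.time(), "%H:%M:%S"),
                                 " [pipeline] ", msg)

  stage("simulating community")
  community <- evolve_genomes(design)
  community <- apply_incompleteness(community,
                                    design$completeness_fraction)
  write_community(community, file.path(outdir, "community"))
  read_sets <- sample_reads(community)
  write_reads(read_sets, file.path(outdir, "reads"))

  stage("computing genome ANI")
  ani <- ani_matrix(community$genomes, config, scheme)
  write_profile_tsv(unclass(ani), file.path(outdir, "ani_genomes.tsv"),
                    id_col = "genome_id")

  stage(paste0("binning populations (", linkage, " linkage at ",
               config$ani_population_threshold, "%)"))
  partition <- cluster_populations(ani, linkage,
                                   config$ani_population_threshold)
  write_tsv(partition, file.path(outdir, "populations.tsv"))

  stage("building dereplicated gene catalogs")
  populations <- build_population_genomes(partition, community$genes,
                                          config, scheme)
  catalogs <- catalog_table(populations)
  write_fasta(setNames(catalogs$seq_nt, catalogs$gene_id),
              file.path(outdir, "catalog.fna"))
  member_maps <- do.call(rbind, lapply(populations, function(p)
    cbind(population_id = p$population_id, p$member_map)))
  write_tsv(member_maps, file.path(outdir, "catalog_members.tsv"))

  stage("pangenome graph + MCL orthogroups")
  graph <- build_graph(catalogs, config, scheme)
  write_tsv(graph$edges, file.path(outdir, "graph_edges.tsv"))
  mcl <- mcl_cluster(graph, config$mcl_inflation, config)
  og <- orthogroup_table(mcl, graph)
  write_tsv(og$table, file.path(outdir, "orthogroups.tsv"))
  write_profile_tsv(og$presence, file.path(outdir, "og_presence.tsv"),
                    id_col = "orthogroup_id")

  stage("population ANI ordering tree")
  pani <- popgenome_ani(ani, partition)
  tree <- order_genomes_by_ani(pani)
  writeLines(tree$newick, file.path(outdir, "populations.nwk"))

  stage("recruiting reads")
  assignments <- lapply(read_sets$reads, function(df)
    recruit_reads(df, setNames(catalogs$seq_nt, catalogs$gene_id),
                  config, scheme))
  gene_cov <- coverage_per_gene(assignments,
                                setNames(catalogs$seq_nt,
                                         catalogs$gene_id),
                                read_sets$metadata)
  write_profile_tsv(gene_cov, file.path(outdir, "coverage_genes.tsv"),
                    id_col = "gene_id")
  og_of_gene <- setNames(og$table$orthogroup_id, og$table$gene_id)
  og_cov <- aggregate_coverage(gene_cov, og_of_gene)
  write_profile_tsv(og_cov, file.path(outdir, "coverage_orthogroups.tsv"),
                    id_col = "orthogroup_id")
  pop_of_gene <- setNames(catalogs$population_id, catalogs$gene_id)
  pop_cov <- aggregate_coverage(gene_cov, pop_of_gene)
  write_profile_tsv(pop_cov, file.path(outdir, "coverage_populations.tsv"),
                    id_col = "population_id")

  stage("filtering locally relevant populations")
  populations <- filter_locally_relevant(populations, pop_cov)
  keep <- names(populations)
  pop_cov_kept <- pop_cov[keep, , drop = FALSE]
  attr(pop_cov_kept, "samples") <- attr(pop_cov, "samples")
  class(pop_cov_kept) <- class(pop_cov)

  stage("delineating ecotypes")
  tree_kept <- order_genomes_by_ani(pani[keep, keep, drop = FALSE])
  classes <- classify_orthogroups(og)
  write_tsv(classes$classes, file.path(outdir, "og_classes.tsv"))
  ecotypes <- delineate_ecotypes(tree_kept, pop_cov_kept)
  write_tsv(ecotypes$map, file.path(outdir, "ecotypes.tsv"))
  write_profile_tsv(ecotypes$profiles,
                    file.path(outdir, "ecotype_profiles.tsv"),
                    id_col = "ecotype_id")

  pathways <- NULL
  if (!is.null(annotation)) {
    stage("pathway profiles")
    # lift annotations of dereplicated-away genes onto their representative
    rep_of <- setNames(member_maps$representative_id, member_maps$gene_id)
    ann <- annotation
    hit <- ann$gene_id %in% names(rep_of)
    ann$gene_id[hit] <- unname(rep_of[ann$gene_id[hit]])
    ann <- unique(ann)
    pathways <- pathway_profiles(og_cov, ann, og$table)
    write_profile_tsv(pathways$profiles,
                      file.path(outdir, "pathway_profiles.tsv"),
                      id_col = "pathway")
  }

  stage("writing manifest")
  manifest_path <- write_manifest(outdir, design, config, linkage, t0)
  stage("done")
  invisible(list(community = community, read_sets = read_sets, ani = ani,
                 partition = partition, populations = populations,
                 catalogs = catalogs, graph = graph, mcl = mcl, og = og,
                 classes = classes, pop_ani = pani, tree = tree,
                 assignments = assignments, gene_coverage = gene_cov,
                 og_coverage = og_cov, population_coverage = pop_cov,
                 ecotypes = ecotypes, pathways = pathways,
                 manifest = manifest_path))
}

# JSON manifest: parameters plus md5 checksum of every produced file.
# Timestamps are excluded so identical runs are byte-identical.
write_manifest <- function(outdir, design, config, linkage, t0) {
  files <- sort(list.files(outdir, recursive = TRUE, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  sums <- tools::md5sum(file.path(outdir, files))
  manifest <- list(
    design = design[setdiff(names(design), "abundance_profiles")],
    abundance_profiles = design$abundance_profiles,
    thresholds = unclass(config),
    linkage = linkage,
    outputs = data.frame(file = files, md5 = unname(sums),
                         stringsAsFactors = FALSE))
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
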