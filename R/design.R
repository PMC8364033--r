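#' Design of a synthetic stratified community
#'
#' Describes the planted structure the generator realizes: subclades of
#' genomes at controlled intra/inter pairwise divergence, a core /
#' subclade-specific / singleton gene repertoire, unimodal (Gaussian)
#' depth-abundance curves per subclade, read sampling parameters and
#' per-genome completeness. Divergence parameters are target \emph{pairwise}
#' substitution fractions: each branch from a shared ancestor receives half.
#'
#' Defaults emulate a depth-stratified marine community sampled at seven
#' depths (25-1000 m): four subclades of three genomes, ~36 genes per genome
#' (~430 gene records overall), 2% divergence within subclades (ANI ~98%,
#' so subclades collapse into population genomes at the 95% boundary) and
#' a nominal 30% between subclades (realized ANI ~75-77% after repeated-hit
#' collisions, below the 80% subclade boundary so the ANI tree resolves
#' them), 100 bp single-end reads at 1% substitution
#' error, and a genome completeness fraction of 0.54 mirroring typical
#' incomplete SAG/MAG collections.
#'
#' @param n_subclades number of subclades.
#' @param genomes_per_subclade genomes per subclade.
#' @param n_core_genes orthofamilies present in every genome.
#' @param n_subclade_genes_per_subclade orthofamilies private to each subclade
#'   (present in all its genomes).
#' @param n_singleton_genes_per_genome genes private to each genome.
#' @param gene_length_mean,gene_length_sd gene length distribution in bp
#'   (rounded to codons, floor 300 bp).
#' @param intra_subclade_divergence pairwise substitution fraction within a
#'   subclade, in [0, 0.05].
#' @param inter_subclade_divergence pairwise substitution fraction between
#'   subclades, in (0.05, 0.35]; must exceed the intra value or 95% ANI
#'   binning is ill-posed.
#' @param depth_grid ordered sample depths in meters.
#' @param abundance_profiles data.frame with columns subclade, peak_depth,
#'   width, amplitude (Gaussian in depth). NULL spreads peaks evenly over the
#'   depth grid with unit amplitude.
#' @param read_length read length in bp.
#' @param reads_per_sample reads drawn per depth sample.
#' @param read_error_rate per-base substitution probability.
#' @param completeness_fraction fraction of genes retained per genome, (0, 1].
#' @param contigs_per_genome contigs the shared gene backbone is split into
#'   (singletons always sit on one extra contig).
#' @param spacer_length intergenic spacer length in bp.
#' @param rng_seed integer master seed.
#' @return object of class \code{community_design}.
#' @export
community_design <- function(n_subclades = 4L, genomes_per_subclade = 3L,
                             n_core_genes = 25L,
                             n_subclade_genes_per_subclade = 8L,
                             n_singleton_genes_per_genome = 3L,
                             gene_length_mean = 900, gene_length_sd = 150,
                             intra_subclade_divergence = 0.02,
                             inter_subclade_divergence = 0.30,
                             depth_grid = c(25, 75, 125, 200, 500, 770, 1000),
                             abundance_profiles = NULL,
                             read_length = 100L, reads_per_sample = 20000L,
                             read_error_rate = 0.01,
                             completeness_fraction = 0.54,
                             contigs_per_genome = 3L, spacer_length = 25L,
                             rng_seed = 1L) {
  if (intra_subclade_divergence < 0 || intra_subclade_divergence > 0.05)
    stop("intra_subclade_divergence must be in [0, 0.05]")
  if (inter_subclade_divergence <= 0.05 || inter_subclade_divergence > 0.35)
    stop("inter_subclade_divergence must be in (0.05, 0.35]")
  if (intra_subclade_divergence >= inter_subclade_divergence)
    stop("intra_subclade_divergence must be smaller than ",
         "inter_subclade_divergence (95% ANI binning is ill-posed otherwise)")
  if (completeness_fraction <= 0 || completeness_fraction > 1)
    stop("completeness_fraction must be in (0, 1]")
  if (is.unsorted(depth_grid, strictly = TRUE))
    stop("depth_grid must be strictly increasing")
  if (n_subclades < 1 || genomes_per_subclade < 1)
    stop("need at least one subclade with one genome")
  if (is.null(abundance_profiles)) {
    idx <- unique(round(seq(1, length(depth_grid), length.out = n_subclades)))
    if (length(idx) < n_subclades)
      stop("depth_grid too small to place ", n_subclades, " subclade peaks; ",
           "supply abundance_profiles explicitly")
    peaks <- depth_grid[idx]
    gaps <- diff(depth_grid)
    width <- if (length(gaps) == 0) {
      pmax(depth_grid / 2, 25)
    } else {
      vapply(idx, function(i) {
        near <- gaps[max(1, i - 1):min(length(gaps), i)]
        mean(near) / 1.5
      }, numeric(1))
    }
    abundance_profiles <- data.frame(
      subclade = subclade_ids(n_subclades),
      peak_depth = peaks, width = width, amplitude = 1)
  } else {
    abundance_profiles <- as.data.frame(abundance_profiles)
    need <- c("subclade", "peak_depth", "width", "amplitude")
    if (!all(need %in% names(abundance_profiles)))
      stop("abundance_profiles needs columns ", paste(need, collapse = ", "))
    if (!setequal(abundance_profiles$subclade, subclade_ids(n_subclades)))
      stop("abundance_profiles must cover exactly subclades ",
           paste(subclade_ids(n_subclades), collapse = ", "))
    if (any(abundance_profiles$amplitude < 0) ||
        any(abundance_profiles$width <= 0))
      stop("abundance amplitudes must be non-negative and widths positive")
  }
  design <- list(n_subclades = as.integer(n_subclades),
                 genomes_per_subclade = as.integer(genomes_per_subclade),
                 n_core_genes = as.integer(n_core_genes),
                 n_subclade_genes_per_subclade =
                   as.integer(n_subclade_genes_per_subclade),
                 n_singleton_genes_per_genome =
                   as.integer(n_singleton_genes_per_genome),
                 gene_length_mean = gene_length_mean,
                 gene_length_sd = gene_length_sd,
                 intra_subclade_divergence = intra_subclade_divergence,
                 inter_subclade_divergence = inter_subclade_divergence,
                 depth_grid = depth_grid,
                 abundance_profiles = abundance_profiles,
                 read_length = as.integer(read_length),
                 reads_per_sample = as.integer(reads_per_sample),
                 read_error_rate = read_error_rate,
                 completeness_fraction = completeness_fraction,
                 contigs_per_genome = as.integer(contigs_per_genome),
                 spacer_length = as.integer(spacer_length),
                 rng_seed = as.integer(rng_seed))
  class(design) <- "community_design"
  design
}

subclade_ids <- function(n) paste0("S", LETTERS[seq_len(n)])

#' Subclade abundance at given depths
#'
#' Evaluates the design's Gaussian depth-abundance curve
#' \code{amplitude * exp(-(d - peak)^2 / (2 * width^2))} for one subclade.
#'
#' @param design a \code{\link{community_design}}.
#' @param subclade subclade id (e.g. "SA").
#' @param depths numeric depths in meters.
#' @return numeric abundance values (non-negative).
#' @export
abundance_at <- function(design, subclade, depths = design$depth_grid) {
  p <- design$abundance_profiles
  row <- p[p$subclade == subclade, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown subclade: ", subclade)
  row$amplitude * exp(-(depths - row$peak_depth)^2 / (2 * row$width^2))
}

#' Threshold configuration for the inference chain
#'
#' Houses every numeric decision threshold: the 95% ANI population boundary,
#' CD-HIT-style dereplication thresholds (95% identity over >= 90% of the
#' shorter gene), the minbit edge filter (0.5), the MCL inflation (10), read
#' recruitment acceptance (80% identity, 70% read coverage) and the
#' fragment-ANI parameters (1020 bp fragments accepted at >= 30% identity and
#' >= 70% fragment coverage).
#'
#' @param ani_population_threshold percent ANI for population delineation.
#' @param derep_identity percent identity for gene dereplication.
#' @param derep_coverage fraction of the shorter gene the alignment must cover.
#' @param minbit minbit edge filter threshold in [0, 1].
#' @param mcl_inflation MCL inflation (> 1).
#' @param recruit_identity percent identity for read acceptance.
#' @param recruit_coverage fraction of the read the alignment must cover.
#' @param ani_fragment_length fragment size in bp.
#' @param fragment_accept_identity percent identity to accept a fragment.
#' @param fragment_accept_coverage fragment coverage to accept a fragment.
#' @param mcl_pruning,mcl_tol,mcl_max_iter MCL numerical controls.
#' @return object of class \code{threshold_config}.
#' @export
threshold_config <- function(ani_population_threshold = 95,
                             derep_identity = 95, derep_coverage = 0.90,
                             minbit = 0.5, mcl_inflation = 10,
                             recruit_identity = 80, recruit_coverage = 0.70,
                             ani_fragment_length = 1020L,
                             fragment_accept_identity = 30,
                             fragment_accept_coverage = 0.70,
                             mcl_pruning = 1e-5, mcl_tol = 1e-8,
                             mcl_max_iter = 200L) {
  pct <- c(ani_population_threshold, derep_identity, recruit_identity,
           fragment_accept_identity)
  if (any(pct <= 0) || any(pct > 100))
    stop("percentage thresholds must be in (0, 100]")
  frac <- c(derep_coverage, recruit_coverage, fragment_accept_coverage)
  if (any(frac <= 0) || any(frac > 1))
    stop("coverage fractions must be in (0, 1]")
  if (minbit < 0 || minbit > 1) stop("minbit must be in [0, 1]")
  if (mcl_inflation <= 1) stop("mcl_inflation must be > 1")
  structure(list(ani_population_threshold = ani_population_threshold,
                 derep_identity = derep_identity,
                 derep_coverage = derep_coverage,
                 minbit = minbit, mcl_inflation = mcl_inflation,
                 recruit_identity = recruit_identity,
                 recruit_coverage = recruit_coverage,
                 ani_fragment_length = as.integer(ani_fragment_length),
                 fragment_accept_identity = fragment_accept_identity,
                 fragment_accept_coverage = fragment_accept_coverage,
                 mcl_pruning = mcl_pruning, mcl_tol = mcl_tol,
                 mcl_max_iter = as.integer(mcl_max_iter)),
            class = "threshold_config")
}
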