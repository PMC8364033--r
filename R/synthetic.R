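SENSE_CODONS <- {
  b <- c("T", "C", "A", "G")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}
STOP_CODONS <- c("TAA", "TAG", "TGA")

random_gene <- function(len_bp) {
  n_codon <- len_bp / 3L
  paste0("ATG", paste(sample(SENSE_CODONS, n_codon - 1L, replace = TRUE),
                      collapse = ""))
}

random_spacer <- function(len_bp) {
  paste(sample(c("A", "C", "G", "T"), len_bp, replace = TRUE), collapse = "")
}

# Synonymous alternative bases per codon and codon position (stop codons
# excluded as source and target). Built once from the standard code.
.syn_cache <- new.env(parent = emptyenv())
syn_alts <- function() {
  if (is.null(.syn_cache$tab)) {
    gc_tab <- Biostrings::GENETIC_CODE
    bases <- c("A", "C", "G", "T")
    tab <- list()
    for (cod in names(gc_tab)) {
      if (gc_tab[[cod]] == "*") next
      per_pos <- vector("list", 3)
      for (p in 1:3) {
        alts <- character()
        for (b in setdiff(bases, substring(cod, p, p))) {
          alt <- cod
          substring(alt, p, p) <- b
          if (gc_tab[[alt]] == gc_tab[[cod]]) alts <- c(alts, b)
        }
        per_pos[[p]] <- alts
      }
      tab[[cod]] <- per_pos
    }
    .syn_cache$tab <- tab
  }
  .syn_cache$tab
}

# Apply exactly n_subs substitutions at distinct positions. coding = TRUE
# protects the start codon, rejects replacements creating in-frame stop
# codons, and directs a fraction syn_frac of the substitutions to
# synonymous changes (one per codon), emulating purifying selection: genes
# then diverge faster in nucleotide identity than in protein identity, as
# conserved core genes do. Spacer (coding = FALSE) substitutions are
# unconstrained and uniform.
mutate_seq <- function(seq, n_subs, coding = TRUE, syn_frac = 0.7) {
  if (n_subs <= 0L) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(ch)
  bases <- c("A", "C", "G", "T")
  used <- integer()
  if (coding) {
    syn_tab <- syn_alts()
    n_syn <- round(syn_frac * n_subs)
    if (n_syn > 0) {
      starts <- seq(4L, L - 2L, by = 3L) # codons after the start codon
      starts <- starts[sample.int(length(starts))]
      done <- 0L
      for (cs in starts) {
        if (done >= n_syn) break
        cod <- paste(ch[cs:(cs + 2L)], collapse = "")
        alts <- syn_tab[[cod]]
        if (is.null(alts)) next
        pos_ok <- which(lengths(alts) > 0)
        if (length(pos_ok) == 0) next
        off <- if (length(pos_ok) == 1L) pos_ok else sample(pos_ok, 1L)
        a <- alts[[off]]
        ch[cs + off - 1L] <- if (length(a) == 1L) a else sample(a, 1L)
        used <- c(used, cs + off - 1L)
        done <- done + 1L
      }
    }
    n_rest <- n_subs - length(used)
    eligible <- setdiff(4:L, used)
    pos <- sample(eligible, min(n_rest, length(eligible)))
    for (p in pos) {
      alts <- setdiff(bases, ch[p])
      cod_start <- p - (p - 1L) %% 3L
      ok <- vapply(alts, function(b) {
        cod <- ch[cod_start:(cod_start + 2L)]
        cod[p - cod_start + 1L] <- b
        !(paste(cod, collapse = "") %in% STOP_CODONS)
      }, logical(1))
      alts <- alts[ok]
      ch[p] <- if (length(alts) == 1L) alts else sample(alts, 1L)
    }
  } else {
    pos <- sample.int(L, min(n_subs, L))
    for (p in pos) {
      alts <- setdiff(bases, ch[p])
      ch[p] <- sample(alts, 1L)
    }
  }
  paste(ch, collapse = "")
}

n_subs_for <- function(len, pairwise_divergence) {
  as.integer(round(len * pairwise_divergence / 2))
}

#' Evolve a synthetic community of genomes with planted truth
#'
#' Realizes a \code{\link{community_design}}: ancestral core orthofamilies are
#' generated once; each subclade ancestor derives by applying half the
#' inter-subclade pairwise divergence; each genome derives from its subclade
#' ancestor by half the intra-subclade pairwise divergence.
#' Subclade-specific orthofamilies are generated at the subclade ancestor and
#' singletons per genome. Genes are concatenated with inherited intergenic
#' spacers (mutated at the same rates) into contigs; the shared backbone
#' (core + subclade genes, colinear within a subclade) is split across
#' \code{contigs_per_genome} contigs and singletons sit on one extra contig.
#' Proteins are standard-genetic-code translations; internal stop codons are
#' avoided by construction. Deterministic given \code{design$rng_seed}.
#'
#' @param design a \code{\link{community_design}}.
#' @return object of class \code{community}: list with \code{design},
#'   \code{genomes} (per genome, a named character vector of contigs),
#'   \code{genes} (data.frame: gene_id, genome_id, family_id, class,
#'   contig_id, start, end, length, seq_nt, seq_aa), and \code{truth} (genome
#'   to subclade map, family class map, subclade to ecotype map, abundance
#'   curves, dropped genes).
#' @export
evolve_genomes <- function(design) {
  stopifnot(inherits(design, "community_design"))
  set.seed(substream_seed(design$rng_seed, "evolve"))
  subclades <- subclade_ids(design$n_subclades)

  gene_len <- function(n) {
    raw <- rnorm(n, design$gene_length_mean, design$gene_length_sd)
    pmax(300L, as.integer(round(raw / 3)) * 3L)
  }

  # --- ancestral core repertoire -------------------------------------
  n_core <- design$n_core_genes
  core_ids <- sprintf("Fc%03d", seq_len(n_core))
  core_len <- gene_len(n_core)
  core_seq <- vapply(core_len, random_gene, character(1))
  core_spacer <- vapply(rep(design$spacer_length, n_core + 1L),
                        random_spacer, character(1))

  d_inter <- design$inter_subclade_divergence
  d_intra <- design$intra_subclade_divergence

  fam_rows <- data.frame(family_id = core_ids, class = "core",
                         owner = NA_character_, stringsAsFactors = FALSE)
  genomes <- list()
  gene_rows <- list()
  genome_subclade <- list()

  for (sc in subclades) {
    # subclade ancestor: mutated core + private subclade families
    sc_core_seq <- vapply(core_seq, function(s)
      mutate_seq(s, n_subs_for(nchar(s), d_inter)), character(1))
    sc_core_spacer <- vapply(core_spacer, function(s)
      mutate_seq(s, n_subs_for(nchar(s), d_inter), coding = FALSE),
      character(1))
    n_sub <- design$n_subclade_genes_per_subclade
    sub_ids <- if (n_sub > 0) sprintf("Fs%s%02d", sub("^S", "", sc),
                                      seq_len(n_sub)) else character()
    sub_len <- gene_len(n_sub)
    sub_seq <- vapply(sub_len, random_gene, character(1))
    sub_spacer <- vapply(rep(design$spacer_length, n_sub),
                         random_spacer, character(1))
    if (n_sub > 0)
      fam_rows <- rbind(fam_rows, data.frame(
        family_id = sub_ids, class = "subclade", owner = sc,
        stringsAsFactors = FALSE))

    for (g in seq_len(design$genomes_per_subclade)) {
      genome_id <- sprintf("%sg%d", sc, g)
      genome_subclade[[genome_id]] <- sc
      shared_fam <- c(core_ids, sub_ids)
      shared_seq <- vapply(c(sc_core_seq, sub_seq), function(s)
        mutate_seq(s, n_subs_for(nchar(s), d_intra)), character(1))
      shared_spacer <- vapply(c(sc_core_spacer, sub_spacer), function(s)
        mutate_seq(s, n_subs_for(nchar(s), d_intra), coding = FALSE),
        character(1))
      # spacer i+1 follows gene i; spacer 1 leads the backbone
      n_single <- design$n_singleton_genes_per_genome
      single_ids <- if (n_single > 0)
        sprintf("Fx%s%02d", genome_id, seq_len(n_single)) else character()
      single_len <- gene_len(n_single)
      single_seq <- vapply(single_len, random_gene, character(1))
      single_spacer <- vapply(rep(design$spacer_length, n_single + 1L),
                              random_spacer, character(1))
      if (n_single > 0)
        fam_rows <- rbind(fam_rows, data.frame(
          family_id = single_ids, class = "singleton", owner = genome_id,
          stringsAsFactors = FALSE))

      # split shared backbone into contigs
      n_shared <- length(shared_fam)
      chunk <- sort(rep_len(seq_len(design$contigs_per_genome), n_shared))
      built <- build_contigs(genome_id, shared_fam, shared_seq,
                             shared_spacer, chunk,
                             single_ids, single_seq, single_spacer)
      genomes[[genome_id]] <- built$contigs
      rows <- built$genes
      rows$class <- fam_rows$class[match(rows$family_id, fam_rows$family_id)]
      gene_rows[[genome_id]] <- rows
    }
  }

  genes <- do.call(rbind, gene_rows)
  rownames(genes) <- NULL
  genes$seq_aa <- unname(translate_genes(setNames(genes$seq_nt,
                                                  genes$gene_id)))
  truth <- list(
    genome_subclade = data.frame(
      genome_id = names(genome_subclade),
      subclade = unlist(genome_subclade, use.names = FALSE),
      stringsAsFactors = FALSE),
    family_class = fam_rows,
    subclade_ecotype = truth_ecotypes(design),
    abundance = design$abundance_profiles,
    dropped = character())
  structure(list(design = design, genomes = genomes, genes = genes,
                 truth = truth),
            class = "community")
}

# Assemble contigs from ordered genes and spacers; spacer[i] precedes
# gene[i] and spacer[n+1] closes the backbone. Returns contig strings plus
# per-gene coordinates (1-based inclusive).
build_contigs <- function(genome_id, shared_fam, shared_seq, shared_spacer,
                          chunk, single_ids, single_seq, single_spacer) {
  contigs <- character()
  rows <- list()
  n_shared <- length(shared_fam)
  for (ci in unique(chunk)) {
    idx <- which(chunk == ci)
    contig_id <- sprintf("%s_c%d", genome_id, ci)
    parts <- character()
    pos <- 0L
    for (i in idx) {
      sp <- shared_spacer[i]
      parts <- c(parts, sp, shared_seq[i])
      start <- pos + nchar(sp) + 1L
      end <- start + nchar(shared_seq[i]) - 1L
      pos <- end
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = paste0(genome_id, ".", shared_fam[i]),
        genome_id = genome_id, family_id = shared_fam[i],
        class = NA_character_, contig_id = contig_id,
        start = start, end = end, length = nchar(shared_seq[i]),
        seq_nt = shared_seq[i],
        spacer = sp, stringsAsFactors = FALSE)
    }
    if (max(idx) == n_shared) parts <- c(parts, shared_spacer[n_shared + 1L])
    contigs[contig_id] <- paste(parts, collapse = "")
  }
  if (length(single_ids) > 0) {
    contig_id <- sprintf("%s_cx", genome_id)
    parts <- character()
    pos <- 0L
    for (i in seq_along(single_ids)) {
      sp <- single_spacer[i]
      parts <- c(parts, sp, single_seq[i])
      start <- pos + nchar(sp) + 1L
      end <- start + nchar(single_seq[i]) - 1L
      pos <- end
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = paste0(genome_id, ".", single_ids[i]),
        genome_id = genome_id, family_id = single_ids[i],
        class = NA_character_, contig_id = contig_id,
        start = start, end = end, length = nchar(single_seq[i]),
        seq_nt = single_seq[i],
        spacer = sp, stringsAsFactors = FALSE)
    }
    parts <- c(parts, single_spacer[length(single_ids) + 1L])
    contigs[contig_id] <- paste(parts, collapse = "")
  }
  list(contigs = contigs, genes = do.call(rbind, rows))
}

# Truth ecotypes: subclades sharing one abundance peak depth form one ecotype,
# labeled shallow-first.
truth_ecotypes <- function(design) {
  p <- design$abundance_profiles
  peaks <- sort(unique(p$peak_depth))
  data.frame(subclade = p$subclade,
             ecotype = paste0("E", match(p$peak_depth, peaks)),
             peak_depth = p$peak_depth, stringsAsFactors = FALSE)
}

#' Exact sequence identity between two genomes from planted truth
#'
#' Alignment-free truth: compares, position by position, the gene sequences
#' of every orthofamily present in both genomes (substitution-only evolution
#' keeps family members colinear). Spacers evolve at the same rates as genes,
#' so this is an unbiased estimate of whole-genome identity.
#'
#' @param community a \code{community}.
#' @param genome_a,genome_b genome ids.
#' @return percent identity over shared orthofamilies.
#' @export
truth_identity <- function(community, genome_a, genome_b) {
  g <- community$genes
  a <- g[g$genome_id == genome_a, ]
  b <- g[g$genome_id == genome_b, ]
  fams <- intersect(a$family_id, b$family_id)
  if (length(fams) == 0) return(NA_real_)
  tot <- 0; same <- 0
  for (f in fams) {
    sa <- a$seq_nt[a$family_id == f]
    sb <- b$seq_nt[b$family_id == f]
    ca <- strsplit(sa, "", fixed = TRUE)[[1]]
    cb <- strsplit(sb, "", fixed = TRUE)[[1]]
    stopifnot(length(ca) == length(cb))
    tot <- tot + length(ca)
    same <- same + sum(ca == cb)
  }
  100 * same / tot
}

#' Mutate every contig of a genome by an exact substitution fraction
#'
#' Utility for divergence calibration: applies exactly
#' \code{round(divergence * length)} substitutions at distinct positions of
#' each contig (no codon protection) so the realized Hamming divergence is
#' known exactly.
#'
#' @param genome named character vector of contigs.
#' @param divergence substitution fraction in [0, 1].
#' @param rng_seed integer seed.
#' @return list with \code{genome} (mutated contigs) and
#'   \code{applied_divergence} (realized substitution fraction).
#' @export
mutate_genome <- function(genome, divergence, rng_seed = 1L) {
  set.seed(substream_seed(rng_seed, "mutate_genome"))
  n_tot <- 0L; len_tot <- 0L
  out <- vapply(genome, function(s) {
    n <- as.integer(round(nchar(s) * divergence))
    n_tot <<- n_tot + n; len_tot <<- len_tot + nchar(s)
    mutate_seq(s, n, coding = FALSE)
  }, character(1))
  names(out) <- names(genome)
  list(genome = out, applied_divergence = n_tot / len_tot)
}

#' Degrade genomes to a target completeness
#'
#' Each genome retains a uniformly sampled subset of exactly
#' \code{round(completeness_fraction * n_genes)} genes (at least one);
#' contigs are reassembled from the retained genes and their spacers, and
#' contigs left without genes are dropped. The truth tables record which
#' genes were removed. \code{completeness_fraction = 1} returns the input
#' unchanged.
#'
#' @param community a \code{community}.
#' @param completeness_fraction fraction in (0, 1].
#' @param rng_seed integer seed.
#' @return a degraded \code{community}.
#' @export
apply_incompleteness <- function(community, completeness_fraction,
                                 rng_seed = community$design$rng_seed) {
  if (completeness_fraction <= 0 || completeness_fraction > 1)
    stop("completeness_fraction must be in (0, 1]")
  if (completeness_fraction == 1) return(community)
  set.seed(substream_seed(rng_seed, "incompleteness"))
  genes <- community$genes
  keep_ids <- character()
  for (gid in names(community$genomes)) {
    idx <- which(genes$genome_id == gid)
    n_keep <- max(1L, as.integer(round(completeness_fraction * length(idx))))
    keep_ids <- c(keep_ids, genes$gene_id[sort(sample(idx, n_keep))])
  }
  dropped <- setdiff(genes$gene_id, keep_ids)
  kept <- genes[genes$gene_id %in% keep_ids, ]
  # reassemble contigs: retained genes in original order, each preceded by
  # its spacer
  new_genomes <- list()
  new_rows <- list()
  for (gid in names(community$genomes)) {
    sub <- kept[kept$genome_id == gid, ]
    contigs <- character()
    for (cid in unique(sub$contig_id)) {
      cg <- sub[sub$contig_id == cid, ]
      cg <- cg[order(cg$start), ]
      pos <- 0L
      parts <- character()
      for (i in seq_len(nrow(cg))) {
        parts <- c(parts, cg$spacer[i], cg$seq_nt[i])
        start <- pos + nchar(cg$spacer[i]) + 1L
        end <- start + cg$length[i] - 1L
        pos <- end
        cg$start[i] <- start; cg$end[i] <- end
      }
      contigs[cid] <- paste(parts, collapse = "")
      new_rows[[paste(gid, cid)]] <- cg
    }
    new_genomes[[gid]] <- contigs
  }
  out <- community
  out$genomes <- new_genomes
  out$genes <- do.call(rbind, new_rows)
  rownames(out$genes) <- NULL
  out$truth$dropped <- union(community$truth$dropped, dropped)
  out
}

#' Sample stratified single-end reads with known origins
#'
#' For each depth in the design's grid, draws reads from genomes with
#' probability proportional to the genome's subclade abundance at that depth
#' times its total length; start positions are uniform (per contig,
#' proportional to the number of valid starts), strands equiprobable, and
#' per-base substitution errors applied at \code{read_error_rate}. The origin
#' genome, contig, start, strand and gene (the gene overlapping the read
#' midpoint, NA for intergenic reads) are recorded per read.
#'
#' @param community a \code{community}.
#' @param design defaults to the community's design.
#' @param rng_seed integer seed (defaults to the design seed).
#' @return list with \code{reads} (one data.frame per sample: read_id, seq,
#'   genome_id, contig_id, start, strand, gene_id, n_errors) and
#'   \code{metadata} (sample_id, depth_m, date).
#' @export
sample_reads <- function(community, design = community$design,
                         rng_seed = design$rng_seed) {
  set.seed(substream_seed(rng_seed, "reads"))
  rl <- design$read_length
  genome_ids <- names(community$genomes)
  sc_of <- setNames(community$truth$genome_subclade$subclade,
                    community$truth$genome_subclade$genome_id)
  glen <- vapply(community$genomes, function(g) sum(nchar(g)), numeric(1))
  samples <- list()
  meta <- list()
  for (d in design$depth_grid) {
    sample_id <- sprintf("D%04d", d)
    ab <- vapply(genome_ids, function(g)
      abundance_at(design, sc_of[[g]], d), numeric(1))
    w <- ab * glen[genome_ids]
    if (sum(w) <= 0)
      stop("total abundance at depth ", d, " m is zero")
    counts <- as.vector(stats::rmultinom(1, design$reads_per_sample,
                                         w / sum(w)))
    rows <- list()
    for (gi in seq_along(genome_ids)) {
      n <- counts[gi]
      if (n == 0) next
      gid <- genome_ids[gi]
      contigs <- community$genomes[[gid]]
      valid <- pmax(0L, nchar(contigs) - rl + 1L)
      if (sum(valid) == 0) stop("genome ", gid, " shorter than read length")
      ci <- sample.int(length(contigs), n, replace = TRUE,
                       prob = valid / sum(valid))
      start <- vapply(ci, function(i) sample.int(valid[i], 1L), integer(1))
      seqs <- substring(contigs[ci], start, start + rl - 1L)
      strand <- sample(c("+", "-"), n, replace = TRUE)
      flip <- strand == "-"
      if (any(flip)) seqs[flip] <- revcomp(seqs[flip])
      n_err <- rbinom(n, rl, design$read_error_rate)
      if (any(n_err > 0)) {
        for (i in which(n_err > 0)) {
          ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
          pos <- sample.int(rl, n_err[i])
          for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                                 ch[p]), 1L)
          seqs[i] <- paste(ch, collapse = "")
        }
      }
      gtab <- community$genes[community$genes$genome_id == gid, ]
      mid <- start + rl %/% 2L
      gene_id <- rep(NA_character_, n)
      for (cid in unique(names(contigs)[ci])) {
        gsub <- gtab[gtab$contig_id == cid, ]
        if (nrow(gsub) == 0) next
        gsub <- gsub[order(gsub$start), ]
        sel <- which(names(contigs)[ci] == cid)
        k <- findInterval(mid[sel], gsub$start)
        hit <- k >= 1 & mid[sel] <= gsub$end[pmax(k, 1L)]
        gene_id[sel[hit]] <- gsub$gene_id[k[hit]]
      }
      rows[[gid]] <- data.frame(
        seq = seqs, genome_id = gid, contig_id = names(contigs)[ci],
        start = start, strand = strand, gene_id = gene_id,
        n_errors = n_err, stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    rownames(df) <- NULL
    df <- cbind(read_id = sprintf("%s_r%06d", sample_id, seq_len(nrow(df))),
                df, stringsAsFactors = FALSE)
    samples[[sample_id]] <- df
    meta[[sample_id]] <- data.frame(sample_id = sample_id, depth_m = d,
                                    date = NA_character_,
                                    stringsAsFactors = FALSE)
  }
  list(reads = samples, metadata = do.call(rbind, c(meta,
                                                    make.row.names = FALSE)))
}
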