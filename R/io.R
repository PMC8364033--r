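#' Write a headered TSV (UTF-8, tab-delimited, "." for missing)
#' @param df data.frame.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a headered TSV written by \code{\link{write_tsv}}
#' @param path input file.
#' @return data.frame ("." restored to NA).
#' @export
read_tsv_file <- function(path) {
  read.table(path, sep = "\t", header = TRUE, na.strings = ".",
             stringsAsFactors = FALSE, check.names = FALSE,
             comment.char = "", quote = "")
}

#' Write a coverage matrix as TSV with an entity id column
#' @param profile matrix entities x samples.
#' @param path output file.
#' @param id_col name of the id column.
#' @return invisibly, the path.
#' @export
write_profile_tsv <- function(profile, path, id_col = "entity_id") {
  df <- data.frame(rownames(profile), unclass(profile),
                   check.names = FALSE, stringsAsFactors = FALSE,
                   row.names = NULL)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

#' Read a coverage TSV back into a matrix
#' @param path input file.
#' @return numeric matrix with entity ids as rownames.
#' @export
read_profile_tsv <- function(path) {
  df <- read_tsv_file(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @param width line wrap width.
#' @return invisibly, the path.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a (possibly wrapped, CRLF-tolerant) FASTA file
#' @param path input file.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  setNames(gsub("\r", "", as.character(x)), names(x))
}

#' Write reads to FASTQ with constant quality
#' @param seqs named character vector of reads.
#' @param path output file.
#' @param quality_char Phred+33 quality character applied to every base.
#' @return invisibly, the path.
#' @export
write_fastq <- function(seqs, path, quality_char = "I") {
  x <- Biostrings::DNAStringSet(seqs)
  q <- Biostrings::BStringSet(strrep(quality_char, nchar(seqs)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Validates record structure; a record whose quality length differs from
#' its sequence length raises an error naming the record.
#'
#' @param path input file.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  lines <- gsub("\r$", "", readLines(path))
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 4 != 0)
    stop("malformed FASTQ (", path, "): line count not a multiple of 4")
  ids <- lines[seq(1, length(lines), by = 4)]
  seqs <- lines[seq(2, length(lines), by = 4)]
  plus <- lines[seq(3, length(lines), by = 4)]
  quals <- lines[seq(4, length(lines), by = 4)]
  bad <- which(!startsWith(ids, "@") | !startsWith(plus, "+"))
  if (length(bad) > 0)
    stop("malformed FASTQ (", path, ") at record ", bad[1],
         " (line ", (bad[1] - 1) * 4 + 1, ")")
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad) > 0)
    stop("FASTQ (", path, ") record ", bad[1],
         ": sequence and quality lengths differ")
  setNames(seqs, sub("^@", "", sub("\\s.*$", "", ids)))
}

#' Write a community's genomes, genes and truth tables to disk
#'
#' Produces one genome FASTA per genome under \code{genomes/}, gene
#' nucleotide and protein FASTA, a gene map TSV, and the truth tables
#' (genome to subclade, family classes, subclade to ecotype, abundance
#' curves, dropped genes).
#'
#' @param community a \code{community}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_community <- function(community, dir) {
  dir.create(file.path(dir, "genomes"), recursive = TRUE,
             showWarnings = FALSE)
  for (gid in names(community$genomes))
    write_fasta(community$genomes[[gid]],
                file.path(dir, "genomes", paste0(gid, ".fasta")))
  g <- community$genes
  write_fasta(setNames(g$seq_nt, g$gene_id), file.path(dir, "genes.fna"))
  write_fasta(setNames(g$seq_aa, g$gene_id), file.path(dir, "genes.faa"))
  write_tsv(g[, c("gene_id", "genome_id", "family_id", "class",
                  "contig_id", "start", "end", "length")],
            file.path(dir, "gene_map.tsv"))
  write_tsv(community$truth$genome_subclade,
            file.path(dir, "truth_genome_subclade.tsv"))
  write_tsv(community$truth$family_class,
            file.path(dir, "truth_family_class.tsv"))
  write_tsv(community$truth$subclade_ecotype,
            file.path(dir, "truth_subclade_ecotype.tsv"))
  write_tsv(community$truth$abundance,
            file.path(dir, "truth_abundance.tsv"))
  write_tsv(data.frame(gene_id = community$truth$dropped,
                       stringsAsFactors = FALSE),
            file.path(dir, "truth_dropped_genes.tsv"))
  invisible(dir)
}

#' Write sampled reads as per-sample FASTQ plus metadata and origins
#' @param read_sets result of \code{\link{sample_reads}}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_reads <- function(read_sets, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in names(read_sets$reads)) {
    df <- read_sets$reads[[sid]]
    write_fastq(setNames(df$seq, df$read_id),
                file.path(dir, paste0(sid, ".fastq")))
    write_tsv(df[, c("read_id", "genome_id", "contig_id", "start",
                     "strand", "gene_id")],
              file.path(dir, paste0(sid, "_origins.tsv")))
  }
  write_tsv(read_sets$metadata, file.path(dir, "sample_metadata.tsv"))
  invisible(dir)
}
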