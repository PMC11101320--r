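#' Write sequences to FASTA
#'
#' 60-column wrapped FASTA, uppercase ACGT.
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file.
#' @return named character vector (uppercased).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  # keep only the first whitespace-delimited token of each header
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write reads to FASTQ (Phred+33)
#'
#' Quality is constant (`"I"`, Q40) since the simulator records errors in the
#' sequence itself rather than modelling per-base qualities.
#'
#' @param reads data.frame with columns `read_id` and `seq`
#'   (as returned by [simulate_reads()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "seq") %in% names(reads)))
  qual <- vapply(nchar(reads$seq), function(n) strrep("I", n), character(1))
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$seq, "+", qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ file.
#' @return data.frame with columns `read_id`, `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(read_id = sub("\\s.*$", "", names(x)),
             seq = as.character(x), stringsAsFactors = FALSE)
}

#' Write intervals as BED6
#'
#' @param df data.frame with columns `contig_id`, `start`, `end`, `name`, and
#'   optionally `score`, `strand`. Coordinates 0-based half-open (BED native).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  stopifnot(all(c("contig_id", "start", "end", "name") %in% names(df)))
  score <- if ("score" %in% names(df)) df$score else 0
  strand <- if ("strand" %in% names(df)) df$strand else "+"
  out <- data.frame(df$contig_id, df$start, df$end, df$name, score, strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file (first six columns)
#'
#' @param path BED file.
#' @return data.frame with `contig_id`, `start`, `end`, `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[seq_len(min(6, ncol(df)))] <-
    c("contig_id", "start", "end", "name", "score", "strand")[seq_len(min(6, ncol(df)))]
  df
}

#' Write gene annotations as GFF3
#'
#' @param genes data.frame with `contig_id`, `start`, `end` (0-based half-open),
#'   `gene_id`, optionally `strand`.
#' @param path output file.
#' @param source value for the GFF source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path, source = "haplophaser") {
  strand <- if ("strand" %in% names(genes)) genes$strand else "+"
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$contig_id, source, genes$start + 1L,
                     genes$end, strand, genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' Write a data.frame as a headered TSV
#'
#' @param df data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a headered TSV
#'
#' @param path file.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
}
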