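#' Assembly summary statistics
#'
#' Total length, contig count, longest and mean contig, N50, GC fraction and
#' ambiguous-base count. GC is computed over ACGT bases only; Ns are excluded
#' from the denominator and reported separately as `n_count`.
#'
#' @param x named character vector of contig sequences, or path to a FASTA
#'   file.
#' @return one-row data.frame: `total_length_bp`, `n_contigs`, `longest_bp`,
#'   `mean_length_bp`, `n50_bp`, `gc_fraction`, `n_count`.
#' @export
assembly_stats <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) x <- read_fasta(x)
  if (length(x) == 0) stop("empty assembly")
  dss <- Biostrings::DNAStringSet(x)
  lens <- Biostrings::width(dss)
  af <- Biostrings::alphabetFrequency(dss, baseOnly = TRUE)
  acgt <- colSums(af[, c("A", "C", "G", "T"), drop = FALSE])
  data.frame(total_length_bp = sum(lens),
             n_contigs = length(lens),
             longest_bp = max(lens),
             mean_length_bp = sum(lens) / length(lens),
             n50_bp = n50(lens),
             gc_fraction = sum(acgt[c("C", "G")]) / sum(acgt),
             n_count = sum(lens) - sum(acgt))
}

variant_feature_types <- c("SNP", "INS", "DEL", "DUP", "INV", "TRANS", "HDR",
                           "TR", "NOTAL", "SYN", "HEMI")

#' Genes affected by structural variation
#'
#' Flags every gene overlapping (by at least `min_overlap_bp`) a variant
#' feature of the selected types, and reports the affected fraction. The
#' default type set (translocations, inversions, duplications, unaligned
#' regions) corresponds to the structural-variant classes usually counted in
#' haplotype comparisons.
#'
#' @param genes data.frame with `contig_id`, `start`, `end`, `gene_id`
#'   (0-based half-open).
#' @param variants data.frame with `contig_id`, `start`, `end`, `type`.
#' @param types variant types to count.
#' @param min_overlap_bp minimum overlap (default 1 bp).
#' @return list with `per_gene` (gene_id, affected flag) and
#'   `fraction_affected`.
#' @export
gene_variant_overlap <- function(genes, variants,
                                 types = c("TRANS", "INV", "DUP", "NOTAL"),
                                 min_overlap_bp = 1) {
  unknown <- setdiff(types, variant_feature_types)
  if (length(unknown)) {
    stop("unknown variant feature type(s): ", paste(unknown, collapse = ", "))
  }
  v <- variants[variants$type %in% types, , drop = FALSE]
  if (nrow(genes) == 0) {
    return(list(per_gene = data.frame(gene_id = character(0),
                                      affected = logical(0)),
                fraction_affected = NaN))
  }
  if (nrow(v) == 0) {
    return(list(per_gene = data.frame(gene_id = genes$gene_id,
                                      affected = FALSE),
                fraction_affected = 0))
  }
  gr_g <- GenomicRanges::GRanges(genes$contig_id,
                                 IRanges::IRanges(genes$start + 1, genes$end))
  gr_v <- GenomicRanges::GRanges(v$contig_id,
                                 IRanges::IRanges(v$start + 1, v$end))
  hit <- GenomicRanges::countOverlaps(gr_g, gr_v,
                                      minoverlap = min_overlap_bp) > 0
  list(per_gene = data.frame(gene_id = genes$gene_id, affected = hit,
                             stringsAsFactors = FALSE),
       fraction_affected = mean(hit))
}
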