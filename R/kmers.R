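#' Canonical k-mer set of a sequence collection
#'
#' Extracts all overlapping k-mers from the given sequences and stores each in
#' canonical form (the lexicographic minimum of the k-mer and its reverse
#' complement), so that a sequence and its reverse complement yield identical
#' sets. Exact sets are kept (no sketching): the intended scale is desk-size
#' genomes and read sets.
#'
#' @param seqs character vector of ACGT sequences (a named assembly vector or
#'   read sequences).
#' @param k odd k-mer size; 21 is the conventional choice for trio k-mer
#'   analyses of ~0.5 Gb plant genomes.
#' @param source_label free-text provenance label.
#' @return an object of class `kmer_set` with fields `k`, `kmers` (sorted
#'   unique canonical k-mers) and `source_label`.
#' @export
kmer_set <- function(seqs, k = 21, source_label = "") {
  stopifnot(k >= 3, k %% 2 == 1)
  km <- as.character(unlist(lapply(seqs, function(s) canonical_kmers(s, k)$kmer),
                            use.names = FALSE))
  structure(list(k = as.integer(k),
                 kmers = sort(unique(km), method = "radix"),
                 source_label = source_label),
            class = "kmer_set")
}

#' @export
print.kmer_set <- function(x, ...) {
  cat(sprintf("kmer_set: %d canonical %d-mers%s\n", length(x$kmers), x$k,
              if (nzchar(x$source_label)) paste0(" [", x$source_label, "]") else ""))
  invisible(x)
}

# All k-mers of one sequence with 0-based leftmost positions and canonical
# keys. The reverse complement of every k-mer is read out of the reverse
# complement of the whole sequence (one Biostrings call) so the scan stays
# vectorised. Positions whose k-mer contains a non-ACGT character are dropped.
canonical_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(data.frame(pos = integer(0), kmer = character(0)))
  clean <- !grepl("[^ACGT]", seq)
  starts <- seq_len(n - k + 1)
  km <- substring(seq, starts, starts + k - 1)
  if (!clean) {
    ok <- !grepl("[^ACGT]", km)
    starts <- starts[ok]; km <- km[ok]
    if (length(km) == 0) {
      return(data.frame(pos = integer(0), kmer = character(0)))
    }
  }
  rcseq <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(gsub("[^ACGT]", "A", seq))))
  rstarts <- n - k + 2L - starts
  rkm <- substring(rcseq, rstarts, rstarts + k - 1)
  canon <- km
  w <- rkm < km
  canon[w] <- rkm[w]
  data.frame(pos = starts - 1L, kmer = canon, stringsAsFactors = FALSE)
}

#' Extract parental-specific k-mers (hap-mers)
#'
#' Hap-mers are k-mers private to one parent: present in that parent's set and
#' absent from the other's. When a child k-mer set is supplied the hap-mers are
#' additionally intersected with it, keeping only inherited markers (useful
#' when the parental sets come from raw reads and carry sequencing-error
#' k-mers).
#'
#' @param parent1,parent2 [kmer_set] objects for the two parents.
#' @param child optional [kmer_set] of the child; `NULL` for the pure set
#'   difference.
#' @return list with `P1` and `P2` hap-mer [kmer_set]s (disjoint by
#'   construction).
#' @export
extract_hapmers <- function(parent1, parent2, child = NULL) {
  stopifnot(inherits(parent1, "kmer_set"), inherits(parent2, "kmer_set"))
  if (parent1$k != parent2$k) stop("parental k-mer sets have different k")
  if (!is.null(child) && child$k != parent1$k) {
    stop("child k-mer set has different k")
  }
  h1 <- setdiff(parent1$kmers, parent2$kmers)
  h2 <- setdiff(parent2$kmers, parent1$kmers)
  if (!is.null(child)) {
    h1 <- intersect(h1, child$kmers)
    h2 <- intersect(h2, child$kmers)
  }
  list(P1 = structure(list(k = parent1$k, kmers = sort(h1),
                           source_label = "hapmers_P1"), class = "kmer_set"),
       P2 = structure(list(k = parent1$k, kmers = sort(h2),
                           source_label = "hapmers_P2"), class = "kmer_set"))
}

#' Assign a read to a parental haplotype by hap-mer counts
#'
#' Counts the read's canonical k-mers found in each parental hap-mer set and
#' assigns the read to the parent with the larger count; ties (including 0-0)
#' are left unassigned for reproducibility.
#'
#' @param read_sequence character scalar.
#' @param hapmers_P1,hapmers_P2 [kmer_set]s of parental hap-mers.
#' @return list with `assignment` (`"P1"`, `"P2"` or `"unassigned"`),
#'   `count_P1`, `count_P2`.
#' @export
bin_read <- function(read_sequence, hapmers_P1, hapmers_P2) {
  k <- hapmers_P1$k
  stopifnot(k == hapmers_P2$k)
  if (nchar(read_sequence) < k) {
    warning("read shorter than k; left unassigned")
    return(list(assignment = "unassigned", count_P1 = 0L, count_P2 = 0L))
  }
  km <- canonical_kmers(read_sequence, k)$kmer
  c1 <- sum(km %in% hapmers_P1$kmers)
  c2 <- sum(km %in% hapmers_P2$kmers)
  assignment <- if (c1 > c2) "P1" else if (c2 > c1) "P2" else "unassigned"
  list(assignment = assignment, count_P1 = c1, count_P2 = c2)
}

#' Bin a set of reads
#'
#' Vectorised driver for [bin_read()].
#'
#' @param reads data.frame with `read_id` and `seq` columns (e.g. from
#'   [simulate_reads()]).
#' @param hapmers_P1,hapmers_P2 parental hap-mer [kmer_set]s.
#' @return data.frame with `read_id`, `assignment`, `count_P1`, `count_P2`.
#' @export
bin_reads <- function(reads, hapmers_P1, hapmers_P2) {
  res <- lapply(reads$seq, bin_read, hapmers_P1 = hapmers_P1,
                hapmers_P2 = hapmers_P2)
  data.frame(read_id = reads$read_id,
             assignment = vapply(res, `[[`, character(1), "assignment"),
             count_P1 = vapply(res, function(r) as.integer(r$count_P1), integer(1)),
             count_P2 = vapply(res, function(r) as.integer(r$count_P2), integer(1)),
             stringsAsFactors = FALSE)
}

#' Annotate parental markers along assembly contigs
#'
#' Scans every contig for k-mers belonging to either parental hap-mer set and
#' records each hit as a marker at its leftmost base (0-based). Contigs without
#' any marker are retained with empty tracks, because downstream deduplication
#' rules need to distinguish "no markers" from "all markers switched".
#'
#' @param contigs named character vector of contig sequences.
#' @param hapmers_P1,hapmers_P2 parental hap-mer [kmer_set]s.
#' @return named list of `marker_track` objects, one per contig, each with
#'   fields `contig_id`, `pos` (0-based, strictly increasing), `parent`
#'   (`"P1"`/`"P2"`), `contig_length`.
#' @export
annotate_markers <- function(contigs, hapmers_P1, hapmers_P2) {
  stopifnot(hapmers_P1$k == hapmers_P2$k)
  k <- hapmers_P1$k
  tracks <- lapply(names(contigs), function(id) {
    km <- canonical_kmers(contigs[[id]], k)
    in1 <- km$kmer %in% hapmers_P1$kmers
    in2 <- km$kmer %in% hapmers_P2$kmers
    hit <- in1 | in2
    marker_track(contig_id = id,
                 pos = km$pos[hit],
                 parent = ifelse(in1[hit], "P1", "P2"),
                 contig_length = nchar(contigs[[id]]))
  })
  names(tracks) <- names(contigs)
  tracks
}

#' Construct a marker track
#'
#' @param contig_id contig name.
#' @param pos 0-based marker positions, strictly increasing.
#' @param parent parent-of-origin per marker, `"P1"` or `"P2"`.
#' @param contig_length contig length in bp.
#' @return `marker_track` object.
#' @export
marker_track <- function(contig_id, pos, parent, contig_length) {
  pos <- as.integer(pos)
  parent <- as.character(parent)
  stopifnot(length(pos) == length(parent),
            all(parent %in% c("P1", "P2")),
            !is.unsorted(pos, strictly = TRUE) || length(pos) <= 1,
            all(pos >= 0), all(pos < contig_length))
  structure(list(contig_id = contig_id, pos = pos, parent = parent,
                 contig_length = as.integer(contig_length)),
            class = "marker_track")
}

#' @export
print.marker_track <- function(x, ...) {
  cat(sprintf("marker_track %s: %d markers (%d P1, %d P2) over %d bp\n",
              x$contig_id, length(x$pos), sum(x$parent == "P1"),
              sum(x$parent == "P2"), x$contig_length))
  invisible(x)
}

#' Hap-mer completeness of an assembly
#'
#' Fraction of each parent's hap-mers present in the assembly k-mer set. An
#' assembly representing one haplotype faithfully should contain close to all
#' of its own parent's hap-mers and close to none of the other's.
#'
#' @param assembly_kmers [kmer_set] of the assembly.
#' @param hapmers_P1,hapmers_P2 parental hap-mer [kmer_set]s.
#' @return list with `P1` and `P2` fractions in `[0, 1]`; `NA` (with a
#'   warning) when the corresponding hap-mer set is empty.
#' @export
hapmer_completeness <- function(assembly_kmers, hapmers_P1, hapmers_P2) {
  stopifnot(assembly_kmers$k == hapmers_P1$k, hapmers_P1$k == hapmers_P2$k)
  frac <- function(h) {
    if (length(h$kmers) == 0) {
      warning("empty hap-mer set; completeness undefined")
      return(NA_real_)
    }
    mean(h$kmers %in% assembly_kmers$kmers)
  }
  list(P1 = frac(hapmers_P1), P2 = frac(hapmers_P2))
}

#' Consensus quality (QV) from assembly-only k-mers
#'
#' K-mers found in the assembly but never in the read set are taken as
#' evidence of consensus errors. With a fraction `p = n_only / n_total` of
#' erroneous assembly k-mers, the per-base error rate is
#' `E = 1 - (1 - p)^(1/k)` (a base error corrupts up to k overlapping k-mers)
#' and `QV = -10 log10(E)`.
#'
#' @param n_assembly_only_kmers number of assembly k-mers absent from the reads.
#' @param n_total_assembly_kmers total assembly k-mers (> 0).
#' @param k k-mer size.
#' @return list with `error_rate` and `qv` (`Inf` when the error rate is 0).
#' @export
qv_from_kmers <- function(n_assembly_only_kmers, n_total_assembly_kmers, k = 21) {
  if (n_total_assembly_kmers <= 0) stop("total assembly k-mers must be > 0")
  if (n_assembly_only_kmers < 0 ||
      n_assembly_only_kmers > n_total_assembly_kmers) {
    stop("assembly-only k-mer count outside [0, total]")
  }
  p <- n_assembly_only_kmers / n_total_assembly_kmers
  e <- 1 - (1 - p)^(1 / k)
  list(error_rate = e, qv = if (e == 0) Inf else -10 * log10(e))
}

#' QV for a given per-base error rate
#'
#' The closed-form companion of [qv_from_kmers()]: `QV = -10 log10(E)`.
#'
#' @param error_rate per-base consensus error rate.
#' @return QV (Phred-scaled), `Inf` at 0.
#' @export
qv_from_error_rate <- function(error_rate) {
  stopifnot(error_rate >= 0, error_rate <= 1)
  if (error_rate == 0) Inf else -10 * log10(error_rate)
}
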