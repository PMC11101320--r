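#' Read a PAF alignment file (minimap2 dialect)
#'
#' Parses the 12 mandatory PAF columns plus the per-alignment divergence tag:
#' `de:f:` (gap-compressed per-base divergence, emitted with base-level
#' alignment and the more accurate of the two) when present, else `dv:f:`
#' (approximate divergence). Records carrying neither fall back to
#' `1 - n_matches / block_len`.
#'
#' @param path PAF file.
#' @return data.frame of alignment records with columns `query_id`, `query_len`,
#'   `q_start`, `q_end`, `strand`, `target_id`, `target_len`, `t_start`,
#'   `t_end`, `n_matches`, `block_len`, `mapq`, `divergence`. Coordinates are
#'   0-based half-open as in the PAF spec.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_paf())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  core <- t(vapply(fields, function(f) f[1:12], character(12)))
  dv <- vapply(fields, function(f) {
    tags <- f[-(1:12)]
    de <- grep("^de:f:", tags, value = TRUE)
    if (length(de)) return(as.numeric(sub("^de:f:", "", de[1])))
    tag <- grep("^dv:f:", tags, value = TRUE)
    if (length(tag)) as.numeric(sub("^dv:f:", "", tag[1])) else NA_real_
  }, numeric(1))
  out <- data.frame(
    query_id = core[, 1],
    query_len = as.numeric(core[, 2]),
    q_start = as.numeric(core[, 3]),
    q_end = as.numeric(core[, 4]),
    strand = core[, 5],
    target_id = core[, 6],
    target_len = as.numeric(core[, 7]),
    t_start = as.numeric(core[, 8]),
    t_end = as.numeric(core[, 9]),
    n_matches = as.numeric(core[, 10]),
    block_len = as.numeric(core[, 11]),
    mapq = as.numeric(core[, 12]),
    stringsAsFactors = FALSE
  )
  out$divergence <- ifelse(is.na(dv), 1 - out$n_matches / out$block_len, dv)
  validate_paf(out)
  out
}

#' Write alignment records as PAF
#'
#' Emits the 12 mandatory columns plus a `dv:f:` tag.
#'
#' @param paf data.frame as returned by [read_paf()] / [paf_record()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_paf <- function(paf, path) {
  if (nrow(paf) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d\tdv:f:%.6f",
                   paf$query_id, as.integer(paf$query_len),
                   as.integer(paf$q_start), as.integer(paf$q_end), paf$strand,
                   paf$target_id, as.integer(paf$target_len),
                   as.integer(paf$t_start), as.integer(paf$t_end),
                   as.integer(paf$n_matches), as.integer(paf$block_len),
                   as.integer(paf$mapq), paf$divergence)
  writeLines(lines, path)
  invisible(path)
}

#' Construct alignment records in memory
#'
#' Convenience constructor for PAF-style records (used by the synthetic-data
#' generators and tests).
#'
#' @param query_id,query_len,q_start,q_end query contig, its length and 0-based
#'   half-open aligned interval.
#' @param strand `"+"` or `"-"`.
#' @param target_id,target_len,t_start,t_end target-side equivalents.
#' @param divergence per-alignment divergence (the `dv` value).
#' @param n_matches number of matching bases; defaults to
#'   `round(block_len * (1 - divergence))`.
#' @param block_len alignment block length; defaults to the target span.
#' @param mapq mapping quality.
#' @return data.frame of alignment records.
#' @export
paf_record <- function(query_id, query_len, q_start, q_end, strand,
                       target_id, target_len, t_start, t_end,
                       divergence, block_len = NULL, n_matches = NULL,
                       mapq = 60) {
  block_len <- block_len %||% (t_end - t_start)
  n_matches <- n_matches %||% round(block_len * (1 - divergence))
  out <- data.frame(query_id = query_id, query_len = query_len,
                    q_start = q_start, q_end = q_end, strand = strand,
                    target_id = target_id, target_len = target_len,
                    t_start = t_start, t_end = t_end,
                    n_matches = n_matches, block_len = block_len,
                    mapq = mapq, divergence = divergence,
                    stringsAsFactors = FALSE)
  validate_paf(out)
  out
}

empty_paf <- function() {
  data.frame(query_id = character(0), query_len = numeric(0),
             q_start = numeric(0), q_end = numeric(0), strand = character(0),
             target_id = character(0), target_len = numeric(0),
             t_start = numeric(0), t_end = numeric(0),
             n_matches = numeric(0), block_len = numeric(0),
             mapq = numeric(0), divergence = numeric(0),
             stringsAsFactors = FALSE)
}

validate_paf <- function(paf) {
  stopifnot(all(paf$q_start >= 0), all(paf$q_end <= paf$query_len),
            all(paf$q_start < paf$q_end),
            all(paf$t_start >= 0), all(paf$t_end <= paf$target_len),
            all(paf$t_start < paf$t_end),
            all(paf$divergence >= 0), all(paf$divergence <= 1))
  invisible(paf)
}

#' Align two FASTA files with minimap2 and read the PAF
#'
#' Thin wrapper around the `minimap2` executable (must be on `PATH`), used for
#' whole-assembly cross-haplotype alignment (`preset = "asm5"` mirrors
#' assembly-to-assembly alignment of closely related haplotypes). Base-level
#' alignment (`-c`) is requested so every record carries the gap-compressed
#' divergence tag `de:f:`.
#'
#' @param query_fasta,target_fasta FASTA paths.
#' @param preset minimap2 `-x` preset.
#' @param extra_args further command-line arguments.
#' @return alignment records as from [read_paf()].
#' @export
align_paf <- function(query_fasta, target_fasta, preset = "asm5",
                      extra_args = character(0)) {
  if (Sys.which("minimap2") == "") {
    stop("minimap2 executable not found on PATH")
  }
  out <- tempfile(fileext = ".paf")
  on.exit(unlink(out), add = TRUE)
  status <- system2("minimap2",
                    c("-c", "-x", preset, "--secondary=no", extra_args,
                      shQuote(target_fasta), shQuote(query_fasta)),
                    stdout = out, stderr = FALSE)
  if (status != 0) stop("minimap2 failed with status ", status)
  read_paf(out)
}

#' Read a BUSCO full-table TSV
#'
#' Expects a tab-separated table (comment lines starting with `#` ignored) with
#' columns busco_id, status, sequence, start, end as written by BUSCO's
#' `full_table.tsv`. 1-based inclusive coordinates are converted to 0-based
#' half-open.
#'
#' @param path file.
#' @return data.frame of gene hits: `contig_id`, `start`, `end`, `gene_id`,
#'   `status` (`"single"` or `"duplicated"`, lower-cased from BUSCO's
#'   Complete/Duplicated vocabulary; Missing/Fragmented rows are dropped).
#' @export
read_busco_table <- function(path) {
  lines <- grep("^#", readLines(path), invert = TRUE, value = TRUE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(fields, function(f) f[2] %in% c("Complete", "Duplicated"),
                 logical(1))
  fields <- fields[keep]
  if (length(fields) == 0) {
    return(data.frame(contig_id = character(0), start = numeric(0),
                      end = numeric(0), gene_id = character(0),
                      status = character(0), stringsAsFactors = FALSE))
  }
  data.frame(
    contig_id = vapply(fields, `[`, character(1), 3),
    start = as.numeric(vapply(fields, `[`, character(1), 4)) - 1,
    end = as.numeric(vapply(fields, `[`, character(1), 5)),
    gene_id = vapply(fields, `[`, character(1), 1),
    status = ifelse(vapply(fields, `[`, character(1), 2) == "Duplicated",
                    "duplicated", "single"),
    stringsAsFactors = FALSE
  )
}
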