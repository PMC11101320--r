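#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are deterministic without leaking global state.
#'
#' @param seed integer seed.
#' @param code expression.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Simulate a diploid genome with recorded truth
#'
#' Generates one haplotype (`hap1`) of random ACGT sequence split into
#' contigs, places non-overlapping genes, and derives the second haplotype
#' (`hap2`) by applying sampled variants: SNPs and short (1-10 bp) indels at
#' the requested per-base rates, larger structural variants (tandem DUP, DEL,
#' INV; lengths log-uniform on `sv_length_range`, placed in intergenic space),
#' and hemizygous gene deletions (the gene interval removed from `hap2`). The
#' default SNP and indel densities (one per 147 nt and one per 1458 nt) mirror
#' the inter-haplotype divergence typical of a highly heterozygous clonally
#' propagated grapevine cultivar. Every applied variant is recorded in `hap1`
#' coordinates; `hap2` gene coordinates are lifted through the edits.
#'
#' SNPs and indels are excluded from SV and hemizygous-gene intervals so that
#' each recorded variant is independently observable in the output sequences.
#'
#' @param length_bp total hap1 length (>= 10 kb), split evenly across contigs.
#' @param n_contigs number of contigs.
#' @param snp_rate,indel_rate per-base event rates in `[0, 1)`.
#' @param n_svs number of structural variants.
#' @param n_genes number of genes to place (non-overlapping, intergenic gap
#'   >= 200 bp).
#' @param hemizygous_fraction fraction of genes deleted from hap2
#'   (`round(hemizygous_fraction * n_genes)` genes).
#' @param gene_length gene length in bp.
#' @param sv_length_range SV length range (log-uniform sampling; lengths are
#'   truncated to the largest available intergenic gap).
#' @param seed integer seed (required).
#' @return object of class `diploid_truth`: named `hap1`/`hap2` sequence
#'   vectors, `variants` (hap, contig_id, start, end, type, len_bp; 0-based
#'   half-open, hap1 coordinates), `genes` (hap1 annotation), `genes_hap2`
#'   (lifted, hemizygous genes absent), `hemizygous_genes`, `seed`.
#' @export
simulate_diploid <- function(length_bp = 120000, n_contigs = 8,
                             snp_rate = 1 / 147, indel_rate = 1 / 1458,
                             n_svs = 2, n_genes = 24,
                             hemizygous_fraction = 0.1, gene_length = 1500,
                             sv_length_range = c(1000, 20000), seed) {
  stopifnot(length_bp >= 10000, n_contigs >= 1,
            snp_rate >= 0, snp_rate < 1, indel_rate >= 0, indel_rate < 1,
            hemizygous_fraction >= 0, hemizygous_fraction <= 1,
            !missing(seed))
  with_seed(seed, {
    base_len <- length_bp %/% n_contigs
    lens <- rep(base_len, n_contigs)
    lens[seq_len(length_bp %% n_contigs)] <- base_len + 1L
    ids <- sprintf("contig%02d", seq_len(n_contigs))
    hap1 <- vapply(lens, random_dna, character(1))
    names(hap1) <- ids

    genes <- place_genes(ids, lens, n_genes, gene_length, gap = 200)
    n_hemi <- round(hemizygous_fraction * n_genes)
    hemi <- if (n_hemi > 0) sample(genes$gene_id, n_hemi) else character(0)

    variants <- list()
    edits <- stats::setNames(vector("list", n_contigs), ids)

    # hemizygous deletions: the gene interval excised from hap2
    for (g in which(genes$gene_id %in% hemi)) {
      cid <- genes$contig_id[g]
      s <- genes$start[g]; e <- genes$end[g]
      edits[[cid]] <- rbind(edits[[cid]],
                            data.frame(s = s, e = e, repl = "",
                                       type = "HEMI", stringsAsFactors = FALSE))
      variants[[length(variants) + 1L]] <-
        data.frame(hap = "hap2", contig_id = cid, start = s, end = e,
                   type = "HEMI", len_bp = e - s, stringsAsFactors = FALSE)
    }

    # structural variants in intergenic space
    blocked <- lapply(ids, function(cid) {
      gi <- genes[genes$contig_id == cid, , drop = FALSE]
      cbind(start = gi$start, end = gi$end)
    })
    names(blocked) <- ids
    if (n_svs > 0) {
      margin <- 50
      for (i in seq_len(n_svs)) {
        gaps <- free_gaps(blocked, lens, ids)
        gaps <- gaps[gaps$end - gaps$start >= sv_length_range[1] + 2 * margin, ,
                     drop = FALSE]
        if (nrow(gaps) == 0) {
          stop("infeasible SV placement: no intergenic gap of at least ",
               sv_length_range[1], " bp left")
        }
        gi <- sample.int(nrow(gaps), 1,
                         prob = gaps$end - gaps$start)
        gap_len <- gaps$end[gi] - gaps$start[gi] - 2 * margin
        len <- round(10^stats::runif(1, log10(sv_length_range[1]),
                                     log10(sv_length_range[2])))
        len <- min(len, gap_len)
        off <- sample.int(gap_len - len + 1L, 1) - 1L
        s <- gaps$start[gi] + margin + off
        e <- s + len
        cid <- gaps$contig_id[gi]
        type <- sample(c("DUP", "DEL", "INV"), 1)
        seq1 <- substr(hap1[[cid]], s + 1, e)
        ed <- switch(type,
                     DEL = data.frame(s = s, e = e, repl = "", type = "DEL",
                                      stringsAsFactors = FALSE),
                     DUP = data.frame(s = e, e = e, repl = seq1, type = "DUP",
                                      stringsAsFactors = FALSE),
                     INV = data.frame(s = s, e = e, repl = revcomp(seq1),
                                      type = "INV", stringsAsFactors = FALSE))
        edits[[cid]] <- rbind(edits[[cid]], ed)
        blocked[[cid]] <- rbind(blocked[[cid]], cbind(start = s, end = e))
        variants[[length(variants) + 1L]] <-
          data.frame(hap = "hap2", contig_id = cid, start = s, end = e,
                     type = type, len_bp = e - s, stringsAsFactors = FALSE)
      }
    }

    # SNPs and short indels outside blocked (SV + hemizygous) intervals
    bases <- c("A", "C", "G", "T")
    for (cid in ids) {
      L <- lens[match(cid, ids)]
      occupied <- rep(FALSE, L)
      bl_var <- variants_on(variants, cid, c("DEL", "DUP", "INV", "HEMI"))
      for (r in seq_len(nrow(bl_var))) {
        occupied[(bl_var$start[r] + 1):bl_var$end[r]] <- TRUE
      }
      n_snp <- stats::rbinom(1, L, snp_rate)
      avail <- which(!occupied)
      n_snp <- min(n_snp, length(avail))
      snp_pos <- sort(sample(avail, n_snp))
      occupied[snp_pos] <- TRUE
      if (n_snp > 0) {
        ref <- substring(hap1[[cid]], snp_pos, snp_pos)
        alt <- bases[((match(ref, bases) - 1L +
                         sample.int(3, n_snp, replace = TRUE)) %% 4L) + 1L]
        edits[[cid]] <- rbind(edits[[cid]],
                              data.frame(s = snp_pos - 1L, e = snp_pos,
                                         repl = alt, type = "SNP",
                                         stringsAsFactors = FALSE))
        variants[[length(variants) + 1L]] <-
          data.frame(hap = "hap2", contig_id = cid, start = snp_pos - 1L,
                     end = snp_pos, type = "SNP", len_bp = 1L,
                     stringsAsFactors = FALSE)
      }
      n_indel <- stats::rbinom(1, L, indel_rate)
      indel_anchor <- sort(sample(which(!occupied), min(n_indel, sum(!occupied))))
      last_end <- -1L
      iv_s <- integer(0); iv_e <- integer(0); iv_repl <- character(0)
      iv_type <- character(0); iv_len <- integer(0)
      for (p in indel_anchor) {
        len <- sample.int(10, 1)
        ins <- stats::runif(1) < 0.5
        if (ins) {
          if (p - 1L <= last_end) next
          iv_s <- c(iv_s, p - 1L); iv_e <- c(iv_e, p - 1L)
          iv_repl <- c(iv_repl, random_dna(len))
          iv_type <- c(iv_type, "INS"); iv_len <- c(iv_len, len)
          last_end <- p - 1L
        } else {
          e <- min(p - 1L + len, L)
          if (p - 1L <= last_end || any(occupied[p:e])) next
          iv_s <- c(iv_s, p - 1L); iv_e <- c(iv_e, e)
          iv_repl <- c(iv_repl, ""); iv_type <- c(iv_type, "DEL")
          iv_len <- c(iv_len, e - (p - 1L))
          occupied[p:e] <- TRUE
          last_end <- e
        }
      }
      if (length(iv_s) > 0) {
        edits[[cid]] <- rbind(edits[[cid]],
                              data.frame(s = iv_s, e = iv_e, repl = iv_repl,
                                         type = ifelse(iv_type == "DEL",
                                                       "DELS", iv_type),
                                         stringsAsFactors = FALSE))
        variants[[length(variants) + 1L]] <-
          data.frame(hap = "hap2", contig_id = cid, start = iv_s,
                     end = ifelse(iv_type == "INS", iv_s + 1L, iv_e),
                     type = iv_type, len_bp = iv_len, stringsAsFactors = FALSE)
      }
    }

    hap2 <- vapply(ids, function(cid) {
      apply_edits(hap1[[cid]], edits[[cid]])
    }, character(1))
    names(hap2) <- ids

    genes_hap2 <- genes[!genes$gene_id %in% hemi, , drop = FALSE]
    if (nrow(genes_hap2) > 0) {
      lifted <- t(vapply(seq_len(nrow(genes_hap2)), function(i) {
        cid <- genes_hap2$contig_id[i]
        c(lift_coord(genes_hap2$start[i], edits[[cid]]),
          lift_coord(genes_hap2$end[i], edits[[cid]]))
      }, numeric(2)))
      genes_hap2$start <- as.integer(lifted[, 1])
      genes_hap2$end <- as.integer(lifted[, 2])
    }

    variants <- if (length(variants)) do.call(rbind, variants) else
      data.frame(hap = character(0), contig_id = character(0),
                 start = integer(0), end = integer(0), type = character(0),
                 len_bp = integer(0), stringsAsFactors = FALSE)
    structure(list(hap1 = hap1, hap2 = hap2, variants = variants,
                   genes = genes, genes_hap2 = genes_hap2,
                   hemizygous_genes = hemi, edits = edits, seed = seed),
              class = "diploid_truth")
  })
}

variants_on <- function(variants, cid, types) {
  if (length(variants) == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  v <- do.call(rbind, variants)
  v[v$contig_id == cid & v$type %in% types, , drop = FALSE]
}

place_genes <- function(ids, lens, n_genes, gene_length, gap = 200) {
  if (n_genes == 0) {
    return(data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), gene_id = character(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  # distribute proportionally to contig length
  alloc <- floor(n_genes * lens / sum(lens))
  while (sum(alloc) < n_genes) {
    i <- which.max(lens / (alloc + 1))
    alloc[i] <- alloc[i] + 1L
  }
  out <- list()
  gid <- 0L
  for (i in seq_along(ids)) {
    nc <- alloc[i]
    if (nc == 0) next
    extra <- lens[i] - nc * (gene_length + gap) - gap
    if (extra < 0) {
      stop("infeasible gene placement: contig ", ids[i], " too short for ",
           nc, " genes of ", gene_length, " bp")
    }
    offs <- sort(sample.int(extra + 1L, nc, replace = TRUE) - 1L)
    starts <- gap + (seq_len(nc) - 1L) * (gene_length + gap) + offs
    out[[i]] <- data.frame(
      contig_id = ids[i], start = as.integer(starts),
      end = as.integer(starts + gene_length),
      gene_id = sprintf("gene%04d", gid + seq_len(nc)),
      strand = sample(c("+", "-"), nc, replace = TRUE),
      stringsAsFactors = FALSE)
    gid <- gid + nc
  }
  do.call(rbind, out)
}

free_gaps <- function(blocked, lens, ids) {
  out <- list()
  for (i in seq_along(ids)) {
    bl <- merge_intervals(blocked[[ids[i]]])
    starts <- c(0, bl[, "end"])
    ends <- c(bl[, "start"], lens[i])
    keep <- ends > starts
    out[[i]] <- data.frame(contig_id = ids[i], start = starts[keep],
                           end = ends[keep], stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# apply 0-based half-open edits (columns s, e, repl), sorted by s, to a sequence
apply_edits <- function(seq, edits) {
  if (is.null(edits) || nrow(edits) == 0) return(seq)
  edits <- edits[order(edits$s, edits$e), , drop = FALSE]
  pieces <- character(0)
  cursor <- 0L
  for (i in seq_len(nrow(edits))) {
    s <- edits$s[i]; e <- edits$e[i]
    if (s < cursor) stop("overlapping edits")  # generator guarantees spacing
    pieces <- c(pieces, substr(seq, cursor + 1, s), edits$repl[i])
    cursor <- e
  }
  pieces <- c(pieces, substr(seq, cursor + 1, nchar(seq)))
  paste(pieces, collapse = "")
}

# lift a hap1 coordinate through the edit list: cumulative length deltas of
# edits entirely left of the coordinate; a coordinate inside an edit span maps
# to the corresponding offset within the replacement (clamped for deletions)
lift_coord <- function(x, edits) {
  if (is.null(edits) || nrow(edits) == 0) return(x)
  left <- edits$e <= x
  delta <- sum(nchar(edits$repl[left]) - (edits$e[left] - edits$s[left]))
  inside <- which(edits$s < x & x < edits$e)
  if (length(inside) == 1) {
    i <- inside
    return(edits$s[i] + delta + min(x - edits$s[i], nchar(edits$repl[i])))
  }
  x + delta
}

#' Per-contig inter-haplotype divergence from recorded variants
#'
#' Approximate gap-compressed per-base divergence of the homologous `hap2`
#' contig relative to `hap1`: SNP and short-indel event counts divided by
#' contig length, matching the convention of aligner divergence tags (an
#' indel counts once regardless of length). Structural and hemizygous
#' intervals are excluded, as aligners report them as separate events rather
#' than base-level divergence.
#'
#' @param truth a [simulate_diploid()] result.
#' @param contig_id contig name.
#' @return divergence fraction.
#' @export
contig_divergence <- function(truth, contig_id) {
  v <- truth$variants
  v <- v[v$contig_id == contig_id & v$type %in% c("SNP", "INS", "DEL") &
           v$len_bp <= 50, , drop = FALSE]
  nrow(v) / nchar(truth$hap1[[contig_id]])
}

#' Simulate reads with recorded haplotype-of-origin
#'
#' Samples reads uniformly along the given sequences (contigs chosen with
#' probability proportional to length, start positions uniform, strand
#' random), with optional uniform substitution errors. The truth is encoded in
#' the read name as `readNNNNNN|hap=H|contig|start`, so binning accuracy can
#' be scored without side tables.
#'
#' @param seqs named character vector of source sequences.
#' @param read_length_mean mean read length (lengths are normal with 10 % CV,
#'   clamped to `[50, contig length]`).
#' @param coverage target fold-coverage; mutually exclusive with `n_reads`.
#' @param n_reads explicit read count.
#' @param error_rate per-base substitution probability.
#' @param hap haplotype label recorded in read names (e.g. `1` or `2`).
#' @param seed integer seed (required).
#' @return data.frame with `read_id`, `seq`, `hap`, `contig_id`, `start`
#'   (0-based on the source), `strand`.
#' @export
simulate_reads <- function(seqs, read_length_mean = 1000, coverage = NULL,
                           n_reads = NULL, error_rate = 0, hap = 1, seed) {
  stopifnot(!missing(seed), error_rate >= 0, error_rate < 1)
  lens <- nchar(seqs)
  if (read_length_mean > max(lens)) {
    stop("read length exceeds every contig length")
  }
  if (is.null(n_reads)) {
    if (is.null(coverage) || coverage <= 0) stop("coverage must be > 0")
    n_reads <- ceiling(coverage * sum(lens) / read_length_mean)
  }
  with_seed(seed, {
    idx <- sample.int(length(seqs), n_reads, replace = TRUE, prob = lens)
    rl <- pmax(50L, round(stats::rnorm(n_reads, read_length_mean,
                                       0.1 * read_length_mean)))
    rl <- pmin(rl, lens[idx])
    start <- vapply(seq_len(n_reads), function(i) {
      sample.int(lens[idx[i]] - rl[i] + 1L, 1) - 1L
    }, integer(1))
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    seqv <- substring(seqs[idx], start + 1, start + rl)
    nerr <- stats::rbinom(n_reads, rl, error_rate)
    for (i in which(nerr > 0)) {
      s <- strsplit(seqv[i], "")[[1]]
      at <- sample.int(length(s), nerr[i])
      s[at] <- vapply(s[at], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                      character(1))
      seqv[i] <- paste(s, collapse = "")
    }
    flip <- strand == "-"
    if (any(flip)) {
      seqv[flip] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(seqv[flip])))
    }
    data.frame(
      read_id = sprintf("read%06d|hap=%s|%s|%d", seq_len(n_reads), hap,
                        names(seqs)[idx], start),
      seq = seqv, hap = as.character(hap), contig_id = names(seqs)[idx],
      start = start, strand = strand, stringsAsFactors = FALSE)
  })
}
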