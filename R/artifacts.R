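#' Inject assembly artifacts into a synthetic diploid
#'
#' Builds a pair of artifact-laden draft assemblies from a [simulate_diploid()]
#' truth, emulating the contamination modes a haplotype-aware deduplication
#' pass must correct:
#'
#' * `switched` — a full contig of the other haplotype added to the assembly
#'   (its correctly-assigned homolog remains present);
#' * `leaked_duplicate` — the other haplotype's copy of a region already
#'   present in this assembly, spliced onto the end of another contig of the
#'   same assembly (an artifactual haplotype duplication leaked to the wrong
#'   haplophase);
#' * `partial_switch` — an interval of a contig replaced by the homologous
#'   other-haplotype segment (a switch without any same-assembly duplication;
#'   the corrected pipeline is expected to keep it, mirroring the
#'   likely-homozygous-region rule).
#'
#' Each artifact affects a distinct contig; truth labels record the affected
#' interval. Gene hits (for the ordered-duplicate rule) are maintained through
#' every injection.
#'
#' @param truth a [simulate_diploid()] result (needs enough contigs and genes:
#'   every leak needs a source contig carrying `genes_per_leak` non-hemizygous
#'   genes and a distinct host contig).
#' @param n_switched,n_leaked,n_partial artifact counts per assembly.
#' @param genes_per_leak genes spanned by each leaked duplication.
#' @param leak_flank flank (bp) added around the leaked gene block.
#' @param partial_frac fraction of the host contig replaced in a partial
#'   switch.
#' @param seed integer seed (required).
#' @return list with `A` and `B`, each an `artifact_assembly`: `contigs`
#'   (named sequences), `truth_labels` (contig_id, label, start, end),
#'   `gene_hits` (contig_id, start, end, gene_id, status), `artifacts`
#'   (construction metadata used by the synthetic aligners),
#'   `expected_parent` (`"P1"` for A, `"P2"` for B).
#' @export
inject_artifacts <- function(truth, n_switched = 1, n_leaked = 1,
                             n_partial = 1, genes_per_leak = 2,
                             leak_flank = 1000, partial_frac = 0.35, seed) {
  stopifnot(inherits(truth, "diploid_truth"), !missing(seed))
  with_seed(seed, {
    A <- build_artifact_side(truth, side = "A", n_switched, n_leaked,
                             n_partial, genes_per_leak, leak_flank,
                             partial_frac)
    B <- build_artifact_side(truth, side = "B", n_switched, n_leaked,
                             n_partial, genes_per_leak, leak_flank,
                             partial_frac)
    list(A = A, B = B)
  })
}

# hap1 -> hap2 coordinate lift for one contig of the truth
lift12 <- function(truth, cid, x) {
  vapply(x, lift_coord, numeric(1), edits = truth$edits[[cid]])
}

build_artifact_side <- function(truth, side, n_switched, n_leaked, n_partial,
                                genes_per_leak, leak_flank, partial_frac) {
  own_is_h1 <- side == "A"
  own_seq <- if (own_is_h1) truth$hap1 else truth$hap2
  other_seq <- if (own_is_h1) truth$hap2 else truth$hap1
  own_genes <- if (own_is_h1) truth$genes else truth$genes_hap2
  ids <- names(own_seq)

  # candidate leak sources: contigs with >= genes_per_leak consecutive
  # non-hemizygous genes (present on both haplotypes)
  shared_genes <- truth$genes[!truth$genes$gene_id %in% truth$hemizygous_genes, ,
                              drop = FALSE]
  per_contig <- table(shared_genes$contig_id)
  src_pool <- names(per_contig)[per_contig >= genes_per_leak]

  need <- n_switched + 2 * n_leaked + n_partial
  if (need > length(ids)) stop("not enough contigs for the requested artifacts")

  taken <- character(0)
  pick <- function(pool, n) {
    pool <- setdiff(pool, taken)
    if (length(pool) < n) stop("not enough contigs for the requested artifacts")
    got <- if (n > 0) sample(pool, n) else character(0)
    taken <<- c(taken, got)
    got
  }
  src_ids <- pick(src_pool, n_leaked)
  host_ids <- pick(ids, n_leaked)
  partial_ids <- pick(ids, n_partial)
  donor_ids <- pick(ids, n_switched)

  contigs <- own_seq
  hits <- own_genes[, c("contig_id", "start", "end", "gene_id")]
  if (!own_is_h1 && nrow(hits) > 0) {
    # own coordinates for side B are hap2 coordinates (already lifted)
    hits <- truth$genes_hap2[, c("contig_id", "start", "end", "gene_id")]
  }
  labels <- data.frame(contig_id = ids, label = "clean",
                       start = NA_integer_, end = NA_integer_,
                       stringsAsFactors = FALSE)
  meta <- list()

  # helper: other-haplotype segment homologous to hap1 interval [s, t) of cid
  other_segment <- function(cid, s, t) {
    if (own_is_h1) {
      st <- lift12(truth, cid, c(s, t))
      substr(other_seq[[cid]], st[1] + 1, st[2])
    } else {
      substr(other_seq[[cid]], s + 1, t)
    }
  }
  own_coord <- function(cid, x) {           # hap1 coord -> own coord
    if (own_is_h1) x else lift12(truth, cid, x)
  }

  # switched contigs: full other-haplotype contig added alongside its homolog
  for (cid in donor_ids) {
    sw_id <- paste0(cid, "_sw")
    contigs[[sw_id]] <- other_seq[[cid]]
    labels <- rbind(labels, data.frame(contig_id = sw_id, label = "switched",
                                       start = NA_integer_, end = NA_integer_,
                                       stringsAsFactors = FALSE))
    # the donor carries the other haplotype's gene complement (same ids)
    g <- shared_genes[shared_genes$contig_id == cid, , drop = FALSE]
    if (nrow(g) > 0) {
      gs <- if (own_is_h1) {
        o <- truth$genes_hap2[truth$genes_hap2$gene_id %in% g$gene_id, ,
                              drop = FALSE]
        data.frame(contig_id = sw_id, start = o$start, end = o$end,
                   gene_id = o$gene_id, stringsAsFactors = FALSE)
      } else {
        data.frame(contig_id = sw_id, start = g$start, end = g$end,
                   gene_id = g$gene_id, stringsAsFactors = FALSE)
      }
      hits <- rbind(hits, gs)
    }
    meta[[length(meta) + 1L]] <- list(kind = "switched", contig_id = sw_id,
                                      base_contig = cid)
  }

  # leaked duplications: other-hap copy of a gene block appended to a host
  for (i in seq_len(n_leaked)) {
    src <- src_ids[i]; host <- host_ids[i]
    g <- shared_genes[shared_genes$contig_id == src, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    first <- sample.int(nrow(g) - genes_per_leak + 1L, 1)
    block <- g[first:(first + genes_per_leak - 1L), , drop = FALSE]
    s1 <- max(0L, block$start[1] - leak_flank)                 # hap1 coords
    t1 <- min(nchar(truth$hap1[[src]]), block$end[nrow(block)] + leak_flank)
    seg <- other_segment(src, s1, t1)
    off <- nchar(contigs[[host]])
    contigs[[host]] <- paste0(contigs[[host]], seg)
    labels$label[labels$contig_id == host] <- "leaked_duplicate"
    labels$start[labels$contig_id == host] <- off
    labels$end[labels$contig_id == host] <- off + nchar(seg)
    # gene copies land at offset positions inside the segment
    seg_origin <- if (own_is_h1) lift12(truth, src, s1) else s1
    gpos <- if (own_is_h1) {
      o <- truth$genes_hap2[match(block$gene_id, truth$genes_hap2$gene_id), ,
                            drop = FALSE]
      cbind(o$start, o$end)
    } else cbind(block$start, block$end)
    hits <- rbind(hits, data.frame(contig_id = host,
                                   start = off + (gpos[, 1] - seg_origin),
                                   end = off + (gpos[, 2] - seg_origin),
                                   gene_id = block$gene_id,
                                   stringsAsFactors = FALSE))
    meta[[length(meta) + 1L]] <-
      list(kind = "leaked_duplicate", contig_id = host,
           start = off, end = off + nchar(seg), src_contig = src,
           src_start_h1 = s1, src_end_h1 = t1)
  }

  # partial switches: an interval replaced by its other-haplotype homolog;
  # chosen to avoid hemizygous genes so the gene complement is conserved
  for (cid in partial_ids) {
    L1 <- nchar(truth$hap1[[cid]])
    span <- round(partial_frac * L1)
    hemi_iv <- truth$genes[truth$genes$contig_id == cid &
                             truth$genes$gene_id %in% truth$hemizygous_genes, ,
                           drop = FALSE]
    s1 <- NA
    for (try in 1:50) {
      cand <- sample.int(L1 - span, 1)
      if (nrow(hemi_iv) == 0 ||
          all(cand + span <= hemi_iv$start | cand >= hemi_iv$end)) {
        s1 <- cand
        break
      }
    }
    if (is.na(s1)) stop("could not place partial switch clear of hemizygous genes")
    t1 <- s1 + span
    seg <- other_segment(cid, s1, t1)
    so <- own_coord(cid, s1); to <- own_coord(cid, t1)  # own coords
    old <- contigs[[cid]]
    contigs[[cid]] <- paste0(substr(old, 1, so), seg,
                             substr(old, to + 1, nchar(old)))
    delta <- nchar(seg) - (to - so)
    labels$label[labels$contig_id == cid] <- "partial_switch"
    labels$start[labels$contig_id == cid] <- so
    labels$end[labels$contig_id == cid] <- so + nchar(seg)
    # shift/remap gene hits on this contig
    on_c <- hits$contig_id == cid
    inside <- on_c & hits$start >= so & hits$end <= to
    after <- on_c & hits$start >= to
    seg_origin <- if (own_is_h1) lift12(truth, cid, s1) else s1
    if (any(inside)) {
      gsrc <- if (own_is_h1) {
        o <- truth$genes_hap2[match(hits$gene_id[inside],
                                    truth$genes_hap2$gene_id), , drop = FALSE]
        cbind(o$start, o$end)
      } else {
        o <- truth$genes[match(hits$gene_id[inside], truth$genes$gene_id), ,
                         drop = FALSE]
        cbind(o$start, o$end)
      }
      hits$start[inside] <- so + (gsrc[, 1] - seg_origin)
      hits$end[inside] <- so + (gsrc[, 2] - seg_origin)
    }
    hits$start[after] <- hits$start[after] + delta
    hits$end[after] <- hits$end[after] + delta
    meta[[length(meta) + 1L]] <-
      list(kind = "partial_switch", contig_id = cid, start = so,
           end = so + nchar(seg), src_start_h1 = s1, src_end_h1 = t1)
  }

  hits <- mark_duplicated(hits)
  structure(list(contigs = contigs, truth_labels = labels, gene_hits = hits,
                 artifacts = meta,
                 expected_parent = if (own_is_h1) "P1" else "P2",
                 side = side),
            class = "artifact_assembly")
}

#' @export
print.artifact_assembly <- function(x, ...) {
  cat(sprintf("artifact_assembly (%s, expected %s): %d contigs, %d gene hits\n",
              x$side, x$expected_parent, length(x$contigs), nrow(x$gene_hits)))
  print(table(x$truth_labels$label))
  invisible(x)
}

#' Mark duplicated gene hits
#'
#' Sets `status` to `"duplicated"` for gene ids occurring more than once in
#' the hit table, `"single"` otherwise.
#'
#' @param hits data.frame with at least `gene_id`.
#' @return `hits` with a `status` column.
#' @export
mark_duplicated <- function(hits) {
  n <- table(hits$gene_id)
  hits$status <- ifelse(n[hits$gene_id] > 1, "duplicated", "single")
  hits
}

#' Synthetic cross-haplotype alignment records
#'
#' Emulates the PAF a whole-assembly aligner would produce when mapping one
#' artifact assembly onto the other, using the recorded truth: homologous own
#' segments align at the inter-haplotype divergence of their contig, while
#' switched/leaked/partially-switched material (which is the other haplotype's
#' sequence) aligns at near-zero divergence.
#'
#' @param art_query,art_target `artifact_assembly` objects (opposite sides).
#' @param truth the [simulate_diploid()] truth both were built from.
#' @param residual_dv divergence reported for identical-haplotype matches.
#' @return PAF-style alignment records ([read_paf()] layout).
#' @export
synthetic_cross_hap_paf <- function(art_query, art_target, truth,
                                    residual_dv = 2e-4) {
  stopifnot(art_query$side != art_target$side)
  q_is_h1 <- art_query$side == "A"
  tlen <- nchar(art_target$contigs)
  recs <- list()
  add <- function(qid, qs, qe, tid, ts, te, dv) {
    if (!tid %in% names(tlen)) return()
    te <- min(te, tlen[[tid]])
    if (te - ts < 50 || qe - qs < 50) return()
    recs[[length(recs) + 1L]] <<-
      paf_record(query_id = qid, query_len = nchar(art_query$contigs[[qid]]),
                 q_start = qs, q_end = qe, strand = "+",
                 target_id = tid, target_len = tlen[[tid]],
                 t_start = ts, t_end = te, divergence = dv)
  }
  # homologous coordinates of hap1 interval [s,t) on each side
  h_coord <- function(cid, x, on_h1) if (on_h1) x else lift12(truth, cid, x)

  for (qid in names(art_query$contigs)) {
    lab <- art_query$truth_labels[art_query$truth_labels$contig_id == qid, ]
    base <- sub("_sw$", "", qid)
    dv_own <- max(contig_divergence(truth, base), 1e-3)
    L1 <- nchar(truth$hap1[[base]])
    if (lab$label == "switched") {
      # other-hap contig: near-identical to its source in the target assembly
      add(qid, 0, nchar(art_query$contigs[[qid]]), base,
          0, h_coord(base, L1, on_h1 = !q_is_h1), residual_dv)
    } else if (lab$label == "leaked_duplicate") {
      own_len <- lab$start  # leaked segment was appended at the end
      add(qid, 0, own_len, base, 0, h_coord(base, L1, on_h1 = !q_is_h1), dv_own)
      m <- Filter(function(a) a$kind == "leaked_duplicate" &&
                    a$contig_id == qid, art_query$artifacts)[[1]]
      ts <- h_coord(m$src_contig, m$src_start_h1, on_h1 = !q_is_h1)
      te <- h_coord(m$src_contig, m$src_end_h1, on_h1 = !q_is_h1)
      add(qid, lab$start, lab$end, m$src_contig, ts, te, residual_dv)
    } else if (lab$label == "partial_switch") {
      m <- Filter(function(a) a$kind == "partial_switch" &&
                    a$contig_id == qid, art_query$artifacts)[[1]]
      s1 <- m$src_start_h1; t1 <- m$src_end_h1
      ts <- h_coord(base, s1, on_h1 = !q_is_h1)
      te <- h_coord(base, t1, on_h1 = !q_is_h1)
      add(qid, 0, lab$start, base, 0, ts, dv_own)
      add(qid, lab$start, lab$end, base, ts, te, residual_dv)
      add(qid, lab$end, nchar(art_query$contigs[[qid]]), base, te,
          h_coord(base, L1, on_h1 = !q_is_h1), dv_own)
    } else {
      add(qid, 0, nchar(art_query$contigs[[qid]]), base,
          0, h_coord(base, L1, on_h1 = !q_is_h1), dv_own)
    }
  }
  if (length(recs) == 0) empty_paf() else do.call(rbind, recs)
}

#' Synthetic same-haplophase alignment records onto candidate contigs
#'
#' Emulates aligning the remaining contigs of one assembly onto candidate
#' duplicate contigs of the same assembly: each switched contig is covered by
#' its correctly-assigned homolog, and each leaked block by its source region.
#'
#' @param art an `artifact_assembly`.
#' @param truth the originating [simulate_diploid()] truth.
#' @return PAF-style alignment records.
#' @export
synthetic_same_hap_paf <- function(art, truth) {
  recs <- list()
  lens <- nchar(art$contigs)
  for (m in art$artifacts) {
    if (m$kind == "switched") {
      base <- m$base_contig
      if (!base %in% names(lens)) next
      dv <- max(contig_divergence(truth, base), 1e-3)
      recs[[length(recs) + 1L]] <-
        paf_record(query_id = base, query_len = lens[[base]],
                   q_start = 0, q_end = min(lens[[base]], lens[[m$contig_id]]),
                   strand = "+", target_id = m$contig_id,
                   target_len = lens[[m$contig_id]],
                   t_start = 0, t_end = lens[[m$contig_id]], divergence = dv)
    } else if (m$kind == "leaked_duplicate") {
      src <- m$src_contig
      dv <- max(contig_divergence(truth, src), 1e-3)
      recs[[length(recs) + 1L]] <-
        paf_record(query_id = src, query_len = lens[[src]],
                   q_start = m$src_start_h1,
                   q_end = min(m$src_end_h1, lens[[src]]),
                   strand = "+", target_id = m$contig_id,
                   target_len = lens[[m$contig_id]],
                   t_start = m$start, t_end = m$end, divergence = dv)
    }
  }
  if (length(recs) == 0) empty_paf() else do.call(rbind, recs)
}
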