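#' Remove contigs switched all along their length
#'
#' A contig whose markers are exclusively opposite-parent, with no marker of
#' its own haplotype, is a whole-contig haplotype switch and is removed. A
#' minimum marker count guards against acting on essentially unmarkered
#' sequence (the rule is undefined there).
#'
#' @param tracks list of [marker_track]s for the assembly.
#' @param expected_parent the parent this assembly is supposed to represent
#'   (`"P1"` or `"P2"`).
#' @param min_markers minimum markers required before the rule can fire.
#' @return decision data.frame: `contig_id`, `action` (`keep`/`remove`),
#'   `rule`, `trim_start`, `trim_end` (NA), `n_markers`, `opp_fraction`.
#' @export
remove_switched_contigs <- function(tracks, expected_parent,
                                    min_markers = 10) {
  stopifnot(expected_parent %in% c("P1", "P2"))
  rows <- lapply(tracks, function(tr) {
    n <- length(tr$pos)
    opp <- if (n == 0) 0 else mean(tr$parent != expected_parent)
    remove <- n >= min_markers && opp == 1
    data.frame(contig_id = tr$contig_id,
               action = if (remove) "remove" else "keep",
               rule = "switched_contig",
               trim_start = NA_real_, trim_end = NA_real_,
               n_markers = n, opp_fraction = opp, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Length-weighted average alignment divergence per contig
#'
#' Summarises cross-haplotype alignments into one `avg_dv` value per query
#' contig: the block-length-weighted mean of the per-alignment `dv` values
#' (an unweighted mean is available for comparison). Contigs with no
#' alignment, or zero total block length, are absent from the result.
#'
#' @param alignments alignment records ([read_paf()] layout), queries being
#'   the contigs of interest.
#' @param weighted weight by alignment block length (default) or plain mean.
#' @return named numeric vector of average divergences.
#' @export
contig_avg_divergence <- function(alignments, weighted = TRUE) {
  if (nrow(alignments) == 0) return(stats::setNames(numeric(0), character(0)))
  split_dv <- split(alignments[, c("divergence", "block_len")],
                    alignments$query_id)
  out <- vapply(split_dv, function(d) {
    if (sum(d$block_len) == 0) return(NA_real_)
    if (weighted) sum(d$divergence * d$block_len) / sum(d$block_len)
    else mean(d$divergence)
  }, numeric(1))
  bad <- is.na(out)
  if (any(bad)) {
    message("omitting ", sum(bad), " contig(s) with zero aligned bases")
    out <- out[!bad]
  }
  out
}

#' Flag cross-haplotype duplicate candidates
#'
#' Contigs whose average divergence to the other haplophase falls below the
#' threshold look like copies of the other haplotype rather than true
#' homologous sequence (true homologs diverge at the inter-haplotype rate).
#'
#' @param avg_dv named vector from [contig_avg_divergence()].
#' @param threshold strict upper bound on `avg_dv` (default 0.005).
#' @return character vector of flagged contig ids.
#' @export
flag_cross_hap_candidates <- function(avg_dv, threshold = 0.005) {
  stopifnot(threshold > 0, threshold < 1)
  names(avg_dv)[avg_dv < threshold]
}

#' Coverage-based removal of duplicate candidates
#'
#' A flagged candidate covered by the *other* contigs of its own haplophase
#' (breadth of coverage > 70 % with depth >= 1, and mean depth > 0.7) is a
#' duplicate and is removed; both inequalities are strict. Breadth is the
#' fraction of candidate bases inside the union of aligned target intervals;
#' mean depth is total aligned span divided by candidate length.
#'
#' @param candidates character vector of candidate contig ids.
#' @param alignments records of same-haplophase contigs aligned onto the
#'   candidates (candidates are targets; self-alignments are ignored).
#' @param contig_lengths named lengths of the candidate contigs (fallback when
#'   a candidate has no alignment record).
#' @param breadth_min,depth_min strict lower bounds.
#' @return decision data.frame (`action` `remove`/`keep`, rule
#'   `cross_hap_coverage`, evidence columns `breadth`, `mean_depth`).
#' @export
coverage_removal <- function(candidates, alignments, contig_lengths = NULL,
                             breadth_min = 0.7, depth_min = 0.7) {
  rows <- lapply(candidates, function(cid) {
    al <- alignments[alignments$target_id == cid &
                       alignments$query_id != cid, , drop = FALSE]
    len <- if (nrow(al) > 0) al$target_len[1] else contig_lengths[[cid]] %||% NA
    if (nrow(al) == 0) {
      breadth <- 0; mean_depth <- 0
    } else {
      cov <- IRanges::reduce(IRanges::IRanges(start = al$t_start + 1,
                                              end = al$t_end))
      breadth <- sum(IRanges::width(cov)) / len
      mean_depth <- sum(al$t_end - al$t_start) / len
    }
    remove <- breadth > breadth_min && mean_depth > depth_min
    data.frame(contig_id = cid, action = if (remove) "remove" else "keep",
               rule = "cross_hap_coverage",
               trim_start = NA_real_, trim_end = NA_real_,
               breadth = breadth, mean_depth = mean_depth,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig_id = character(0), action = character(0),
               rule = character(0), trim_start = numeric(0),
               trim_end = numeric(0), breadth = numeric(0),
               mean_depth = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Find ordered duplicated-gene chains within one haplophase
#'
#' Searches the duplicated gene hits of one assembly for pairs of regions
#' carrying at least `min_chain` duplicated genes with pairwise-distinct ids
#' in the same order. Non-duplicated genes may intervene inside either region;
#' an unmatched duplicated gene breaks the chain. Chains contained in a longer
#' chain are not reported again.
#'
#' @param hits gene hits (`contig_id`, `start`, `end`, `gene_id`, `status`),
#'   e.g. from [read_busco_table()] or [mark_duplicated()].
#' @param min_chain minimum chain length (>= 2).
#' @return data.frame of chain pairs: `contig_a`, `a_start`, `a_end`,
#'   `contig_b`, `b_start`, `b_end`, `n_genes`, `genes` (comma-separated id
#'   sequence). Region A is the leftmost occurrence.
#' @export
find_ordered_duplicates <- function(hits, min_chain = 2) {
  stopifnot(min_chain >= 2)
  dup <- hits[hits$status == "duplicated", , drop = FALSE]
  empty <- data.frame(contig_a = character(0), a_start = numeric(0),
                      a_end = numeric(0), contig_b = character(0),
                      b_start = numeric(0), b_end = numeric(0),
                      n_genes = integer(0), genes = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(dup) < 2 * min_chain) return(empty)
  dup <- dup[order(dup$contig_id, dup$start), , drop = FALSE]
  dup$occ <- seq_len(nrow(dup))
  # successor of each occurrence along its contig (next duplicated hit)
  nxt <- integer(nrow(dup))
  for (i in seq_len(nrow(dup))) {
    nxt[i] <- if (i < nrow(dup) && dup$contig_id[i + 1] == dup$contig_id[i])
      i + 1L else NA_integer_
  }
  used <- matrix(FALSE, nrow(dup), nrow(dup))
  chains <- list()
  for (i in seq_len(nrow(dup))) {
    for (j in seq_len(nrow(dup))) {
      if (j <= i || dup$gene_id[i] != dup$gene_id[j]) next
      if (used[i, j]) next
      a <- i; b <- j
      chain_a <- a; chain_b <- b; ids <- dup$gene_id[i]
      repeat {
        na <- nxt[a]; nb <- nxt[b]
        if (is.na(na) || is.na(nb) || nb == na) break
        if (dup$gene_id[na] != dup$gene_id[nb]) break
        if (dup$gene_id[na] %in% ids) break
        a <- na; b <- nb
        chain_a <- c(chain_a, a); chain_b <- c(chain_b, b)
        ids <- c(ids, dup$gene_id[a])
        used[a, b] <- TRUE
      }
      used[i, j] <- TRUE
      if (length(ids) >= min_chain) {
        chains[[length(chains) + 1L]] <- data.frame(
          contig_a = dup$contig_id[chain_a[1]],
          a_start = min(dup$start[chain_a]), a_end = max(dup$end[chain_a]),
          contig_b = dup$contig_id[chain_b[1]],
          b_start = min(dup$start[chain_b]), b_end = max(dup$end[chain_b]),
          n_genes = length(ids), genes = paste(ids, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(chains) == 0) return(empty)
  do.call(rbind, chains)
}

#' Excise the switched copy of ordered duplicated-gene chains
#'
#' For each chain pair, the region whose markers are majority opposite-parent
#' is the artifactual copy leaked from the other haplotype and is trimmed
#' (over the chain's bounding interval); the correctly-assigned copy is kept.
#' If neither region is switch-flagged the duplication is taken as a likely
#' homozygous region and both copies are kept. If both are flagged, the one
#' with the higher opposite-marker fraction is trimmed; exact ties keep both
#' and are reported.
#'
#' @param chains chain pairs from [find_ordered_duplicates()].
#' @param tracks list of [marker_track]s for the assembly.
#' @param expected_parent the assembly's own parent (`"P1"`/`"P2"`).
#' @return decision data.frame with `trim` rows (rule `busco_ordered_block`)
#'   and `keep` rows for audited-but-kept chains; `opp_frac_a`, `opp_frac_b`
#'   evidence columns.
#' @export
busco_ordered_dedup <- function(chains, tracks, expected_parent) {
  opp_frac <- function(cid, s, e) {
    tr <- tracks[[cid]]
    if (is.null(tr)) return(NA_real_)
    sel <- tr$pos >= s & tr$pos < e
    if (!any(sel)) return(NA_real_)    # unmarkered region: not switch-flagged
    mean(tr$parent[sel] != expected_parent)
  }
  rows <- lapply(seq_len(nrow(chains)), function(i) {
    ch <- chains[i, ]
    fa <- opp_frac(ch$contig_a, ch$a_start, ch$a_end)
    fb <- opp_frac(ch$contig_b, ch$b_start, ch$b_end)
    flag_a <- !is.na(fa) && fa > 0.5
    flag_b <- !is.na(fb) && fb > 0.5
    mk <- function(action, cid, s, e) {
      data.frame(contig_id = cid, action = action,
                 rule = "busco_ordered_block",
                 trim_start = if (action == "trim") s else NA_real_,
                 trim_end = if (action == "trim") e else NA_real_,
                 opp_frac_a = fa, opp_frac_b = fb, genes = ch$genes,
                 stringsAsFactors = FALSE)
    }
    if (flag_a && flag_b) {
      if (fa > fb) return(mk("trim", ch$contig_a, ch$a_start, ch$a_end))
      if (fb > fa) return(mk("trim", ch$contig_b, ch$b_start, ch$b_end))
      return(mk("keep", ch$contig_a, NA, NA))   # tie: keep both, report
    }
    if (flag_a) return(mk("trim", ch$contig_a, ch$a_start, ch$a_end))
    if (flag_b) return(mk("trim", ch$contig_b, ch$b_start, ch$b_end))
    mk("keep", ch$contig_a, NA, NA)             # homozygous-region rule
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig_id = character(0), action = character(0),
               rule = character(0), trim_start = numeric(0),
               trim_end = numeric(0), opp_frac_a = numeric(0),
               opp_frac_b = numeric(0), genes = character(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Apply deduplication decisions to an assembly
#'
#' Drops removed contigs, excises merged trim intervals (pieces re-emitted
#' with `_p<i>` suffixes), and drops resulting pieces shorter than
#' `min_piece`. Output order is input order, then piece index.
#'
#' @param contigs named character vector of contig sequences.
#' @param decisions decision data.frame (rows with `action` `keep` are
#'   ignored; `trim` rows may repeat per contig and overlapping intervals are
#'   merged).
#' @param min_piece minimum piece length retained after excision.
#' @return list with `contigs` (corrected assembly), `log` (per-contig action
#'   summary) and `accounting` (input/output base bookkeeping: removed bases,
#'   trimmed bases, dropped small-piece bases).
#' @export
apply_decisions <- function(contigs, decisions, min_piece = 20000) {
  bad <- setdiff(decisions$contig_id, names(contigs))
  if (length(bad)) stop("decisions reference unknown contigs: ",
                        paste(bad, collapse = ", "))
  removed <- unique(decisions$contig_id[decisions$action == "remove"])
  out <- list()
  log <- list()
  removed_bases <- 0; trimmed_bases <- 0; dropped_bases <- 0
  for (cid in names(contigs)) {
    L <- nchar(contigs[[cid]])
    if (cid %in% removed) {
      removed_bases <- removed_bases + L
      log[[length(log) + 1L]] <- data.frame(contig_id = cid, action = "remove",
                                            detail = "", stringsAsFactors = FALSE)
      next
    }
    tr <- decisions[decisions$contig_id == cid & decisions$action == "trim", ,
                    drop = FALSE]
    if (nrow(tr) == 0) {
      out[[cid]] <- contigs[[cid]]
      next
    }
    iv <- merge_intervals(cbind(pmax(0, tr$trim_start),
                                pmin(L, tr$trim_end)))
    trimmed_bases <- trimmed_bases + sum(iv[, "end"] - iv[, "start"])
    keep_start <- c(0, iv[, "end"])
    keep_end <- c(iv[, "start"], L)
    pieces <- which(keep_end > keep_start)
    pi <- 0L
    for (p in pieces) {
      piece <- substr(contigs[[cid]], keep_start[p] + 1, keep_end[p])
      if (nchar(piece) < min_piece) {
        dropped_bases <- dropped_bases + nchar(piece)
        log[[length(log) + 1L]] <-
          data.frame(contig_id = cid, action = "drop_small_piece",
                     detail = sprintf("%d-%d", keep_start[p], keep_end[p]),
                     stringsAsFactors = FALSE)
        next
      }
      pi <- pi + 1L
      out[[sprintf("%s_p%d", cid, pi)]] <- piece
    }
    log[[length(log) + 1L]] <-
      data.frame(contig_id = cid, action = "trim",
                 detail = paste(sprintf("%d-%d", iv[, "start"], iv[, "end"]),
                                collapse = ";"),
                 stringsAsFactors = FALSE)
  }
  list(contigs = unlist(out),
       log = if (length(log)) do.call(rbind, log) else
         data.frame(contig_id = character(0), action = character(0),
                    detail = character(0), stringsAsFactors = FALSE),
       accounting = list(input_bases = sum(nchar(contigs)),
                         output_bases = sum(nchar(unlist(out) %||% character(0))),
                         removed_bases = removed_bases,
                         trimmed_bases = trimmed_bases,
                         dropped_small_piece_bases = dropped_bases))
}

#' Full haplotype-aware deduplication pass
#'
#' Runs the three rules in the curation order: (1) whole-contig switched
#' removal from marker tracks; (2) cross-haplotype divergence flagging plus
#' same-haplophase coverage removal; (3) ordered duplicated-gene chain
#' excision of switch-flagged copies; then applies all decisions.
#'
#' @param contigs named character vector: the assembly to deduplicate.
#' @param tracks [marker_track]s for the assembly (against its own parents).
#' @param expected_parent the assembly's parent (`"P1"`/`"P2"`).
#' @param cross_paf alignments of this assembly onto the other haplophase.
#' @param same_paf same-haplophase alignments onto duplicate candidates.
#' @param gene_hits gene hit table for the ordered-duplicate rule.
#' @param dv_threshold strict `avg_dv` bound for candidate flagging.
#' @param breadth_min,depth_min coverage-rule bounds.
#' @param min_markers guard for the switched-contig rule.
#' @param min_chain minimum ordered-duplicate chain length.
#' @param min_piece minimum retained piece length.
#' @param coverage_first run the coverage stage before the marker stage
#'   (order-equivalence checks).
#' @return list with `decisions` (all rule rows), `corrected` (the
#'   [apply_decisions()] result) and `avg_dv`.
#' @export
dedup_pipeline <- function(contigs, tracks, expected_parent, cross_paf,
                           same_paf, gene_hits, dv_threshold = 0.005,
                           breadth_min = 0.7, depth_min = 0.7,
                           min_markers = 10, min_chain = 2,
                           min_piece = 20000, coverage_first = FALSE) {
  run_marker <- function(live) {
    d <- remove_switched_contigs(tracks[live], expected_parent, min_markers)
    d
  }
  run_coverage <- function(live) {
    paf <- cross_paf[cross_paf$query_id %in% live, , drop = FALSE]
    avg_dv <- contig_avg_divergence(paf)
    cand <- flag_cross_hap_candidates(avg_dv, dv_threshold)
    sp <- same_paf[same_paf$target_id %in% live &
                     same_paf$query_id %in% live, , drop = FALSE]
    coverage_removal(cand, sp, contig_lengths = nchar(contigs),
                     breadth_min = breadth_min, depth_min = depth_min)
  }
  live <- names(contigs)
  if (coverage_first) {
    d1 <- run_coverage(live)
    live <- setdiff(live, d1$contig_id[d1$action == "remove"])
    d2 <- run_marker(live)
    live <- setdiff(live, d2$contig_id[d2$action == "remove"])
  } else {
    d1 <- run_marker(live)
    live <- setdiff(live, d1$contig_id[d1$action == "remove"])
    d2 <- run_coverage(live)
    live <- setdiff(live, d2$contig_id[d2$action == "remove"])
  }
  hits <- gene_hits[gene_hits$contig_id %in% live, , drop = FALSE]
  hits <- mark_duplicated(hits)
  chains <- find_ordered_duplicates(hits, min_chain = min_chain)
  d3 <- busco_ordered_dedup(chains, tracks, expected_parent)
  cols <- c("contig_id", "action", "rule", "trim_start", "trim_end")
  ensure <- function(d) {
    d$trim_start <- d$trim_start %||% NA_real_
    d[, cols, drop = FALSE]
  }
  decisions <- rbind(ensure(d1), ensure(d2), ensure(d3))
  corrected <- apply_decisions(contigs, decisions, min_piece = min_piece)
  list(decisions = decisions, corrected = corrected,
       detail = list(marker = d1, coverage = d2, busco = d3, chains = chains))
}
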