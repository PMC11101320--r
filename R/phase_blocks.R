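#' Partition a marker track into phase blocks
#'
#' A phase block is a maximal run of markers inherited from the same parent,
#' tolerating occasional opposite-parent markers (counted as switches) as long
#' as two bounds hold: at most `max_switches` opposite markers within any
#' `window_bp` span, and an opposite-marker fraction within the block of at
#' most `switch_rate`. The defaults (100 switches in a 20 kb range, 0.5 %
#' switch rate) are the conventional trio-evaluation settings.
#'
#' The scan is greedy left-to-right: the block parent is the parent of its
#' first marker; both bounds are re-checked after every marker, and the first
#' violated bound terminates the block at the last non-violating marker. The
#' following block starts at the violating (opposite-parent) marker. This
#' yields the minimal, leftmost segmentation among all segmentations whose
#' block prefixes satisfy the bounds.
#'
#' @param track a [marker_track].
#' @param max_switches maximum opposite-parent markers tolerated in any
#'   `window_bp` span of a block.
#' @param window_bp window size in bp for the switch-count bound.
#' @param switch_rate maximum opposite-marker fraction within a block.
#' @return data.frame of blocks with columns `contig_id`, `start_idx`,
#'   `end_idx` (1-based marker indices), `start_pos`, `end_pos` (0-based
#'   positions of the first/last marker), `parent`, `n_markers`, `n_switched`,
#'   `span_bp`. Zero rows for an empty track.
#' @export
find_phase_blocks <- function(track, max_switches = 100, window_bp = 20000,
                              switch_rate = 0.005) {
  stopifnot(inherits(track, "marker_track"),
            max_switches >= 0, window_bp > 0,
            switch_rate >= 0, switch_rate <= 1)
  n <- length(track$pos)
  empty <- data.frame(contig_id = character(0), start_idx = integer(0),
                      end_idx = integer(0), start_pos = integer(0),
                      end_pos = integer(0), parent = character(0),
                      n_markers = integer(0), n_switched = integer(0),
                      span_bp = integer(0), stringsAsFactors = FALSE)
  if (n == 0) return(empty)

  pos <- track$pos
  parent <- track$parent
  blocks <- list()
  start <- 1L
  block_parent <- parent[1]
  opp_pos <- integer(0)  # positions of tolerated opposite markers in block

  close_block <- function(start, end) {
    n_mark <- end - start + 1L
    n_sw <- sum(parent[start:end] != parent[start])
    data.frame(contig_id = track$contig_id, start_idx = start, end_idx = end,
               start_pos = pos[start], end_pos = pos[end],
               parent = parent[start], n_markers = n_mark, n_switched = n_sw,
               span_bp = pos[end] - pos[start] + 1L, stringsAsFactors = FALSE)
  }

  i <- 2L
  while (i <= n) {
    if (parent[i] == block_parent) {
      i <- i + 1L
      next
    }
    # tentative addition of an opposite-parent marker
    cand_opp <- c(opp_pos, pos[i])
    in_window <- sum(cand_opp > pos[i] - window_bp)
    frac <- length(cand_opp) / (i - start + 1L)
    if (in_window > max_switches || frac > switch_rate) {
      blocks[[length(blocks) + 1L]] <- close_block(start, i - 1L)
      start <- i
      block_parent <- parent[i]
      opp_pos <- integer(0)
    } else {
      opp_pos <- cand_opp
    }
    i <- i + 1L
  }
  blocks[[length(blocks) + 1L]] <- close_block(start, n)
  do.call(rbind, blocks)
}

#' Phase blocks for a whole assembly
#'
#' Runs [find_phase_blocks()] on every marker track of an assembly and binds
#' the results.
#'
#' @param tracks list of [marker_track]s (e.g. from [annotate_markers()]).
#' @param ... passed to [find_phase_blocks()].
#' @return data.frame of blocks across all contigs.
#' @export
phase_blocks_assembly <- function(tracks, ...) {
  do.call(rbind, lapply(tracks, find_phase_blocks, ...))
}

#' Switch-error report for one haplophase
#'
#' Aggregates phase blocks into the standard phasing-evaluation summary: block
#' count, total bases in blocks, block N50, switched and total marker counts,
#' and the switch error rate (switched / total markers).
#'
#' @param blocks data.frame of blocks (from [phase_blocks_assembly()] or
#'   [find_phase_blocks()]).
#' @param label haplophase label for the report row.
#' @return one-row data.frame with columns `haplophase`, `n_blocks`,
#'   `total_bases_in_blocks`, `block_n50_bp`, `n_switched_markers`,
#'   `n_total_markers`, `switch_error_rate` (fraction; `NaN` with
#'   `rate_defined = FALSE` when there are no markers) and
#'   `switch_error_percent` (formatted at 3 decimals, half-up).
#' @export
switch_report <- function(blocks, label = "assembly") {
  n_total <- sum(blocks$n_markers)
  n_switched <- sum(blocks$n_switched)
  rate <- switch_error_rate(n_switched, n_total)
  data.frame(haplophase = label,
             n_blocks = nrow(blocks),
             total_bases_in_blocks = sum(blocks$span_bp),
             block_n50_bp = n50(blocks$span_bp),
             n_switched_markers = n_switched,
             n_total_markers = n_total,
             switch_error_rate = rate,
             rate_defined = n_total > 0,
             switch_error_percent = format_percent(rate, digits = 3),
             stringsAsFactors = FALSE)
}

#' Switch error rate from marker counts
#'
#' @param n_switched number of switched (opposite-parent) markers.
#' @param n_total total number of markers.
#' @return fraction `n_switched / n_total`; `NaN` when `n_total` is 0.
#' @export
switch_error_rate <- function(n_switched, n_total) {
  stopifnot(n_switched >= 0, n_total >= 0, n_switched <= max(n_total, 0))
  if (n_total == 0) return(NaN)
  n_switched / n_total
}
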