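#' Score dedup decisions against artifact truth labels
#'
#' The expected curation of each truth label is: `switched` contigs are
#' removed; `leaked_duplicate` intervals are trimmed (interval boundaries
#' within `tol_bp` of the injected block); `clean` and `partial_switch`
#' contigs are kept untouched (a partial switch has no same-assembly
#' duplicate, so the engine treats it as a putative homozygous region).
#' Precision is the fraction of emitted remove/trim decisions matching an
#' expected one; recall is the fraction of expected remove/trim actions
#' emitted.
#'
#' @param decisions decision data.frame (e.g. `dedup_pipeline()$decisions`).
#' @param art the `artifact_assembly` the decisions were computed for.
#' @param tol_bp tolerance on trim-interval boundaries.
#' @return list with `precision`, `recall`, `tp`, `fp`, `fn` and the
#'   `expected` table.
#' @export
dedup_truth_eval <- function(decisions, art, tol_bp = 5000) {
  labels <- art$truth_labels
  expected <- labels[labels$label %in% c("switched", "leaked_duplicate"), ,
                     drop = FALSE]
  acted <- decisions[decisions$action %in% c("remove", "trim"), , drop = FALSE]
  # merge trim rows per contig for interval comparison
  matched_exp <- rep(FALSE, nrow(expected))
  fp <- 0L
  for (i in seq_len(nrow(acted))) {
    d <- acted[i, ]
    j <- which(expected$contig_id == d$contig_id)
    ok <- FALSE
    if (length(j) == 1) {
      if (expected$label[j] == "switched" && d$action == "remove") {
        ok <- TRUE
      } else if (expected$label[j] == "leaked_duplicate" &&
                 d$action == "trim" &&
                 abs(d$trim_start - expected$start[j]) <= tol_bp &&
                 abs(d$trim_end - expected$end[j]) <= tol_bp) {
        ok <- TRUE
      }
    }
    if (ok) matched_exp[j] <- TRUE else fp <- fp + 1L
  }
  tp <- sum(matched_exp)
  fn <- nrow(expected) - tp
  n_acted_contigs <- length(unique(acted$contig_id))
  precision <- if (nrow(acted) == 0) 1 else
    sum(unique(acted$contig_id) %in% expected$contig_id[matched_exp]) /
      n_acted_contigs
  recall <- if (nrow(expected) == 0) 1 else tp / nrow(expected)
  list(precision = precision, recall = recall, tp = tp, fp = fp, fn = fn,
       expected = expected)
}
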