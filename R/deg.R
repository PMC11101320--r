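#' Filter a differential-expression table into DEG sets
#'
#' A gene is differentially expressed iff its FDR-adjusted p-value is strictly
#' below `alpha` and its absolute log2 fold change is at least `min_abs_lfc`
#' (the standard strict-p / non-strict-LFC convention). Records with missing
#' adjusted p are excluded and counted in the QC report.
#'
#' @param table data.frame with columns `gene_id`, `log2FoldChange`, `padj`.
#' @param alpha adjusted-p threshold (strict `<`).
#' @param min_abs_lfc minimum |log2 fold change| (non-strict `>=`).
#' @return list with `deg` (the DEG rows), `up`, `down` (gene id vectors) and
#'   `qc` (`n_input`, `n_missing_padj`, `n_deg`).
#' @export
filter_degs <- function(table, alpha = 0.01, min_abs_lfc = 1.0) {
  stopifnot(alpha > 0, min_abs_lfc > 0,
            all(c("gene_id", "log2FoldChange", "padj") %in% names(table)))
  missing_p <- is.na(table$padj)
  t2 <- table[!missing_p, , drop = FALSE]
  is_deg <- t2$padj < alpha & abs(t2$log2FoldChange) >= min_abs_lfc
  deg <- t2[is_deg, , drop = FALSE]
  list(deg = deg,
       up = deg$gene_id[deg$log2FoldChange > 0],
       down = deg$gene_id[deg$log2FoldChange < 0],
       qc = list(n_input = nrow(table), n_missing_padj = sum(missing_p),
                 n_deg = nrow(deg)))
}

#' Construct an ortholog map
#'
#' One-to-one ortholog pairs between two references, plus the genes of each
#' reference with no counterpart.
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b` (one-to-one).
#' @param unmapped_a,unmapped_b character vectors of counterpart-less genes.
#' @return `ortholog_map` object.
#' @export
ortholog_map <- function(pairs, unmapped_a = character(0),
                         unmapped_b = character(0)) {
  stopifnot(!anyDuplicated(pairs$gene_a), !anyDuplicated(pairs$gene_b),
            !any(unmapped_a %in% pairs$gene_a),
            !any(unmapped_b %in% pairs$gene_b))
  structure(list(pairs = pairs[, c("gene_a", "gene_b")],
                 unmapped_a = unmapped_a, unmapped_b = unmapped_b),
            class = "ortholog_map")
}

#' @export
print.ortholog_map <- function(x, ...) {
  cat(sprintf("ortholog_map: %d pairs, %d unmapped in A, %d unmapped in B\n",
              nrow(x$pairs), length(x$unmapped_a), length(x$unmapped_b)))
  invisible(x)
}

#' Simulate an ortholog map between two haplophase annotations
#'
#' @param n_genes_a,n_genes_b annotated gene counts per reference.
#' @param n_unmapped_a,n_unmapped_b minimum genes without a counterpart. Real
#'   annotation pairs are rarely 1-1 consistent; when the implied paired
#'   counts `n_genes - n_unmapped` differ, the surplus genes of the larger
#'   side are also left unmapped.
#' @param seed integer seed.
#' @param prefix_a,prefix_b gene id prefixes.
#' @return `ortholog_map` (unmapped genes are a random subset of each side).
#' @export
simulate_ortholog_map <- function(n_genes_a, n_genes_b = n_genes_a,
                                  n_unmapped_a = 0, n_unmapped_b = 0,
                                  seed, prefix_a = "MbP", prefix_b = "MbM") {
  n_pairs <- min(n_genes_a - n_unmapped_a, n_genes_b - n_unmapped_b)
  if (n_pairs < 0) stop("more unmapped genes than genes")
  with_seed(seed, {
    ga <- sprintf("%s_g%05d", prefix_a, seq_len(n_genes_a))
    gb <- sprintf("%s_g%05d", prefix_b, seq_len(n_genes_b))
    ua <- if (n_genes_a - n_pairs > 0) sample(ga, n_genes_a - n_pairs)
          else character(0)
    ub <- if (n_genes_b - n_pairs > 0) sample(gb, n_genes_b - n_pairs)
          else character(0)
    ortholog_map(data.frame(gene_a = setdiff(ga, ua), gene_b = setdiff(gb, ub),
                            stringsAsFactors = FALSE),
                 unmapped_a = ua, unmapped_b = ub)
  })
}

#' Simulate a pair of dual-reference differential-expression tables
#'
#' Generates one DEG table per haplophase reference over the genes of an
#' [ortholog_map], planting ground-truth effect categories: shared DEGs
#' (same-sign effects beyond threshold in both tables), reference-specific
#' DEGs (effect in one table only), and ortholog-lacking DEGs among each
#' side's unmapped genes (either fixed counts or, with `p_deg_no_ortholog`,
#' an independent per-gene probability — the stochastic mode used for
#' enrichment power studies). All other genes get sub-threshold statistics.
#'
#' @param map an [ortholog_map].
#' @param n_deg_shared planted shared DEG pairs.
#' @param n_deg_specific_a,n_deg_specific_b planted single-reference DEGs
#'   (ortholog exists, effect in one reference only).
#' @param n_deg_no_ortholog_a,n_deg_no_ortholog_b planted DEGs among unmapped
#'   genes.
#' @param p_deg_no_ortholog if non-NULL, overrides the fixed unmapped-DEG
#'   counts: every unmapped gene becomes a DEG independently with this
#'   probability.
#' @param shared_core optional persistent shared DEGs: a character vector of
#'   reference-A gene ids, or a data.frame with columns `gene_a` and `sign`,
#'   forced into the shared DEG set (counted inside `n_deg_shared`). Passing
#'   the same core to several comparisons plants consistently detected DEGs.
#' @param lfc_effect planted |log2 fold change| scale; DEG magnitudes are
#'   `lfc_effect * U(0.75, 1.25)` with random common sign, so `lfc_effect = 0`
#'   plants nothing that survives an |LFC| >= 1 filter.
#' @param alpha significance level the planted DEGs must beat (their padj is
#'   `U(0, 0.9 alpha)`).
#' @param comparison_label label recorded with the truth.
#' @param seed integer seed.
#' @return list with `table_a`, `table_b` (gene_id, log2FoldChange, padj) and
#'   `truth` (gene_a, gene_b, category, sign).
#' @export
simulate_deg_tables <- function(map, n_deg_shared = 200,
                                n_deg_specific_a = 40, n_deg_specific_b = 40,
                                n_deg_no_ortholog_a = 0,
                                n_deg_no_ortholog_b = 0,
                                p_deg_no_ortholog = NULL,
                                shared_core = NULL,
                                lfc_effect = 2, alpha = 0.01,
                                comparison_label = "cmp", seed) {
  stopifnot(inherits(map, "ortholog_map"))
  n_pairs <- nrow(map$pairs)
  if (n_deg_shared + n_deg_specific_a + n_deg_specific_b > n_pairs) {
    stop("more planted DEGs than ortholog pairs")
  }
  core_sign <- NULL
  if (!is.null(shared_core)) {
    core_ids <- if (is.data.frame(shared_core)) shared_core$gene_a
                else shared_core
    if (is.data.frame(shared_core)) core_sign <- shared_core$sign
    i_core <- match(core_ids, map$pairs$gene_a)
    if (anyNA(i_core)) stop("shared_core genes missing from the ortholog map")
    if (length(i_core) > n_deg_shared) {
      stop("shared_core larger than n_deg_shared")
    }
  } else {
    i_core <- integer(0)
  }
  with_seed(seed, {
    idx <- c(i_core, sample(setdiff(seq_len(n_pairs), i_core)))
    i_shared <- idx[seq_len(n_deg_shared)]
    i_spec_a <- idx[n_deg_shared + seq_len(n_deg_specific_a)]
    i_spec_b <- idx[n_deg_shared + n_deg_specific_a + seq_len(n_deg_specific_b)]
    pick_unmapped <- function(pool, n_fixed) {
      if (!is.null(p_deg_no_ortholog)) {
        pool[stats::runif(length(pool)) < p_deg_no_ortholog]
      } else if (n_fixed > 0) sample(pool, n_fixed) else character(0)
    }
    deg_um_a <- pick_unmapped(map$unmapped_a, n_deg_no_ortholog_a)
    deg_um_b <- pick_unmapped(map$unmapped_b, n_deg_no_ortholog_b)

    genes_a <- c(map$pairs$gene_a, map$unmapped_a)
    genes_b <- c(map$pairs$gene_b, map$unmapped_b)
    null_row <- function(n) {
      data.frame(log2FoldChange = stats::runif(n, -0.8, 0.8),
                 padj = stats::runif(n, min(1, 2 * alpha), 1))
    }
    deg_row <- function(n, sign) {
      data.frame(log2FoldChange = sign * lfc_effect * stats::runif(n, 0.75, 1.25),
                 padj = stats::runif(n, 0, 0.9 * alpha))
    }
    ta <- cbind(gene_id = genes_a, null_row(length(genes_a)),
                stringsAsFactors = FALSE)
    tb <- cbind(gene_id = genes_b, null_row(length(genes_b)),
                stringsAsFactors = FALSE)
    set_rows <- function(tab, ids, sign) {
      at <- match(ids, tab$gene_id)
      tab[at, c("log2FoldChange", "padj")] <- deg_row(length(ids), sign)
      tab
    }
    sign_shared <- sample(c(-1, 1), n_deg_shared, replace = TRUE)
    if (!is.null(core_sign)) sign_shared[seq_along(core_sign)] <- core_sign
    sign_spec_a <- sample(c(-1, 1), n_deg_specific_a, replace = TRUE)
    sign_spec_b <- sample(c(-1, 1), n_deg_specific_b, replace = TRUE)
    sign_um_a <- sample(c(-1, 1), length(deg_um_a), replace = TRUE)
    sign_um_b <- sample(c(-1, 1), length(deg_um_b), replace = TRUE)
    # shared DEGs share a sign but draw magnitude/padj per table
    ta <- set_rows(ta, map$pairs$gene_a[i_shared], sign_shared)
    tb <- set_rows(tb, map$pairs$gene_b[i_shared], sign_shared)
    ta <- set_rows(ta, map$pairs$gene_a[i_spec_a], sign_spec_a)
    tb <- set_rows(tb, map$pairs$gene_b[i_spec_b], sign_spec_b)
    ta <- set_rows(ta, deg_um_a, sign_um_a)
    tb <- set_rows(tb, deg_um_b, sign_um_b)

    truth <- rbind(
      if (length(i_shared))
        data.frame(gene_a = map$pairs$gene_a[i_shared],
                   gene_b = map$pairs$gene_b[i_shared],
                   category = "shared", sign = sign_shared,
                   stringsAsFactors = FALSE),
      if (length(i_spec_a))
        data.frame(gene_a = map$pairs$gene_a[i_spec_a],
                   gene_b = map$pairs$gene_b[i_spec_a],
                   category = "specific_a", sign = sign_spec_a,
                   stringsAsFactors = FALSE),
      if (length(i_spec_b))
        data.frame(gene_a = map$pairs$gene_a[i_spec_b],
                   gene_b = map$pairs$gene_b[i_spec_b],
                   category = "specific_b", sign = sign_spec_b,
                   stringsAsFactors = FALSE),
      if (length(deg_um_a)) data.frame(gene_a = deg_um_a, gene_b = NA,
                                       category = "no_ortholog_a",
                                       sign = sign_um_a,
                                       stringsAsFactors = FALSE),
      if (length(deg_um_b)) data.frame(gene_a = NA, gene_b = deg_um_b,
                                       category = "no_ortholog_b",
                                       sign = sign_um_b,
                                       stringsAsFactors = FALSE))
    list(table_a = ta, table_b = tb, truth = truth,
         comparison_label = comparison_label)
  })
}

#' Intersect DEG sets across the two haplophase references
#'
#' Joins the DEG calls of the two references through the ortholog map and
#' partitions each reference's DEGs into: `shared` (both references, same
#' direction), `discordant` (both, opposite directions), `a_specific` /
#' `b_specific` (ortholog exists but is not DEG in the other reference) and
#' `a_no_ortholog` / `b_no_ortholog` (no counterpart annotated).
#'
#' @param degs_a,degs_b DEG tables (rows of [filter_degs()]`$deg`) for the
#'   same comparison against references A and B.
#' @param map an [ortholog_map] covering both gene sets.
#' @return list with `shared` and `discordant` (data.frames gene_a, gene_b,
#'   lfc_a, lfc_b), `a_specific`, `b_specific`, `a_no_ortholog`,
#'   `b_no_ortholog` (gene id vectors).
#' @export
cross_reference_intersection <- function(degs_a, degs_b, map) {
  stopifnot(inherits(map, "ortholog_map"))
  a2b <- stats::setNames(map$pairs$gene_b, map$pairs$gene_a)
  known_a <- c(map$pairs$gene_a, map$unmapped_a)
  known_b <- c(map$pairs$gene_b, map$unmapped_b)
  if (!all(degs_a$gene_id %in% known_a)) {
    stop("DEG table A contains genes absent from the ortholog map")
  }
  if (!all(degs_b$gene_id %in% known_b)) {
    stop("DEG table B contains genes absent from the ortholog map")
  }
  lfc_a <- stats::setNames(degs_a$log2FoldChange, degs_a$gene_id)
  lfc_b <- stats::setNames(degs_b$log2FoldChange, degs_b$gene_id)

  a_no_orth <- intersect(degs_a$gene_id, map$unmapped_a)
  b_no_orth <- intersect(degs_b$gene_id, map$unmapped_b)
  a_paired <- setdiff(degs_a$gene_id, a_no_orth)
  b_paired <- setdiff(degs_b$gene_id, b_no_orth)
  both <- a_paired[a2b[a_paired] %in% b_paired]
  same_sign <- sign(lfc_a[both]) == sign(lfc_b[a2b[both]])
  shared <- data.frame(gene_a = both[same_sign],
                       gene_b = unname(a2b[both[same_sign]]),
                       lfc_a = unname(lfc_a[both[same_sign]]),
                       lfc_b = unname(lfc_b[a2b[both[same_sign]]]),
                       stringsAsFactors = FALSE)
  discordant <- data.frame(gene_a = both[!same_sign],
                           gene_b = unname(a2b[both[!same_sign]]),
                           lfc_a = unname(lfc_a[both[!same_sign]]),
                           lfc_b = unname(lfc_b[a2b[both[!same_sign]]]),
                           stringsAsFactors = FALSE)
  list(shared = shared, discordant = discordant,
       a_specific = setdiff(a_paired, both),
       b_specific = setdiff(b_paired, a2b[both]),
       a_no_ortholog = a_no_orth, b_no_ortholog = b_no_orth)
}

#' DEGs consistently detected across comparisons
#'
#' Intersects per-comparison shared-DEG sets (genes detected with both
#' references) and records the per-comparison effect sign.
#'
#' @param shared_list named list of `shared` data.frames from
#'   [cross_reference_intersection()], one per comparison.
#' @return data.frame with `gene_a`, `gene_b`, one sign column per
#'   comparison, and `sign_consistent`.
#' @export
consistent_degs <- function(shared_list) {
  stopifnot(length(shared_list) >= 2)
  common <- Reduce(intersect, lapply(shared_list, `[[`, "gene_a"))
  if (length(common) == 0) {
    out <- data.frame(gene_a = character(0), gene_b = character(0))
    for (nm in names(shared_list)) out[[paste0("sign_", nm)]] <- numeric(0)
    out$sign_consistent <- logical(0)
    return(out)
  }
  first <- shared_list[[1]]
  out <- data.frame(gene_a = common,
                    gene_b = first$gene_b[match(common, first$gene_a)],
                    stringsAsFactors = FALSE)
  signs <- sapply(shared_list, function(s) {
    sign(s$lfc_a[match(common, s$gene_a)])
  })
  signs <- matrix(signs, nrow = length(common),
                  dimnames = list(NULL, names(shared_list)))
  for (nm in colnames(signs)) out[[paste0("sign_", nm)]] <- signs[, nm]
  out$sign_consistent <- apply(signs, 1, function(r) length(unique(r)) == 1)
  out
}

#' Unmapped-gene fraction of an annotation
#'
#' @param n_unmapped genes without a counterpart in the other reference.
#' @param n_annotated total annotated genes (> 0).
#' @return list with `fraction` and `percent` (half-up, 1 decimal).
#' @export
unmapped_fraction <- function(n_unmapped, n_annotated) {
  stopifnot(n_annotated > 0, n_unmapped >= 0, n_unmapped <= n_annotated)
  f <- n_unmapped / n_annotated
  list(fraction = f, percent = round_half_up(100 * f, 1))
}

# conditional hypergeometric Fisher p for table (a b / c d); two-sided uses
# the minimum-likelihood convention with the customary 1 + 1e-7 tie guard
fisher_p <- function(a, b, c, d,
                     alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  xs <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(xs, c1, n - c1, r1)
  obs <- probs[match(a, xs)]
  switch(alternative,
         two.sided = sum(probs[probs <= obs * (1 + 1e-7)]),
         greater = sum(probs[xs >= a]),
         less = sum(probs[xs <= a]))
}

#' Fisher's exact enrichment of ortholog-lacking genes among DEGs
#'
#' Tests whether DEGs lacking an annotated ortholog in the other haplophase
#' (candidate hemizygous genes) are over- or under-represented relative to
#' the genome-wide unmapped-gene rate, via Fisher's exact test on the 2x2
#' table `a = deg_no_ortholog`, `b = deg_total - a`,
#' `c = genome_unmapped - a`, `d = genome_total - genome_unmapped - b`.
#'
#' @param deg_no_ortholog DEGs without an ortholog.
#' @param deg_total all DEGs.
#' @param genome_unmapped genome-wide ortholog-lacking genes.
#' @param genome_total annotated genes.
#' @param sidedness `"two.sided"` (default), `"greater"` or `"less"`.
#' @return list: `contingency` (a, b, c, d), `odds_ratio` (sample ad/bc,
#'   `Inf` when bc = 0), `p_value`, `sidedness`, `direction`
#'   (`"over"`/`"under"`/`"none"` by comparing DEG vs background rates).
#' @export
hemizygosity_enrichment <- function(deg_no_ortholog, deg_total,
                                    genome_unmapped, genome_total,
                                    sidedness = "two.sided") {
  a <- deg_no_ortholog
  b <- deg_total - a
  c <- genome_unmapped - a
  d <- genome_total - genome_unmapped - b
  if (any(c(a, b, c, d) < 0)) stop("negative contingency cell")
  p <- fisher_p(a, b, c, d, alternative = sidedness)
  or <- if (b * c == 0) Inf else (a * d) / (b * c)
  rate_deg <- if (a + b > 0) a / (a + b) else NaN
  rate_bg <- if (c + d > 0) c / (c + d) else NaN
  direction <- if (is.nan(rate_deg) || is.nan(rate_bg) ||
                   rate_deg == rate_bg) "none"
               else if (rate_deg > rate_bg) "over" else "under"
  list(contingency = c(a = a, b = b, c = c, d = d),
       odds_ratio = or, p_value = p, sidedness = sidedness,
       direction = direction)
}
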