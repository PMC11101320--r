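# Shared fixtures, built once per test run and cached. Desk-scale study
# conditions: 120 kb diploid over 8 contigs, SNPs every 147 nt, indels every
# 1458 nt, 24 genes (10 % hemizygous), 2 SVs.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (!exists(name, envir = .fx_cache)) {
    assign(name, builder(), envir = .fx_cache)
  }
  get(name, envir = .fx_cache)
}

fx_truth <- function() {
  fx("truth", function() {
    simulate_diploid(length_bp = 120000, n_contigs = 8, n_svs = 2,
                     n_genes = 24, hemizygous_fraction = 0.1, seed = 101)
  })
}

fx_hapmers <- function() {
  fx("hapmers", function() {
    tr <- fx_truth()
    extract_hapmers(kmer_set(tr$hap1, 21, "hap1"),
                    kmer_set(tr$hap2, 21, "hap2"))
  })
}

fx_artifacts <- function() {
  fx("artifacts", function() {
    inject_artifacts(fx_truth(), n_switched = 1, n_leaked = 1, n_partial = 1,
                     seed = 202)
  })
}

# one full dedup run (side A) reused by several tests
fx_dedup_run <- function() {
  fx("dedup_run", function() {
    tr <- fx_truth(); hm <- fx_hapmers(); art <- fx_artifacts()
    tracks <- annotate_markers(art$A$contigs, hm$P1, hm$P2)
    res <- dedup_pipeline(art$A$contigs, tracks, "P1",
                          synthetic_cross_hap_paf(art$A, art$B, tr),
                          synthetic_same_hap_paf(art$A, tr),
                          art$A$gene_hits, min_piece = 2000)
    list(tracks = tracks, res = res)
  })
}

# run the whole dedup pass for one side of an artifact pair
run_dedup_side <- function(tr, art, side, hm, ...) {
  X <- art[[side]]
  Y <- art[[setdiff(c("A", "B"), side)]]
  tracks <- annotate_markers(X$contigs, hm$P1, hm$P2)
  dedup_pipeline(X$contigs, tracks, X$expected_parent,
                 synthetic_cross_hap_paf(X, Y, tr),
                 synthetic_same_hap_paf(X, tr),
                 X$gene_hits, min_piece = 2000, ...)
}
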