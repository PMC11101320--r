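test_that("fully switched contigs are removed, others kept", {
  t_all_opp <- marker_track("sw", seq(0, 1990, 10), rep("P2", 200), 2000)
  t_one_own <- marker_track("mix", seq(0, 1990, 10),
                            c(rep("P2", 199), "P1"), 2000)
  t_few <- marker_track("few", c(0, 10, 20), rep("P2", 3), 2000)
  d <- remove_switched_contigs(list(t_all_opp, t_one_own, t_few), "P1")
  expect_equal(d$action[d$contig_id == "sw"], "remove")
  expect_equal(d$action[d$contig_id == "mix"], "keep")   # "no matches" is strict
  expect_equal(d$action[d$contig_id == "few"], "keep")   # min_markers guard
  d2 <- remove_switched_contigs(list(t_few), "P1", min_markers = 3)
  expect_equal(d2$action, "remove")
})

test_that("average divergence is a block-length-weighted mean", {
  paf <- rbind(
    paf_record("q1", 1000, 0, 100, "+", "t", 5000, 0, 100, divergence = 0.002,
               block_len = 100),
    paf_record("q1", 1000, 100, 400, "+", "t", 5000, 100, 400,
               divergence = 0.010, block_len = 300),
    paf_record("q2", 1000, 0, 500, "+", "t", 5000, 0, 500, divergence = 0.004))
  avg <- contig_avg_divergence(paf)
  expect_equal(avg[["q1"]], 0.008)
  expect_equal(avg[["q2"]], 0.004)
  expect_equal(contig_avg_divergence(paf, weighted = FALSE)[["q1"]], 0.006)
  expect_length(contig_avg_divergence(paf[0, ]), 0)
})

test_that("candidate flagging uses a strict divergence threshold", {
  avg <- c(a = 0.004, b = 0.005, c = 0.0049999, d = 0.2)
  expect_setequal(flag_cross_hap_candidates(avg), c("a", "c"))
  expect_length(flag_cross_hap_candidates(numeric(0)), 0)
})

test_that("coverage removal applies strict breadth and depth bounds", {
  # union 750 of 1000 (breadth .75), total span 800 (depth .8) -> remove
  paf <- rbind(
    paf_record("q1", 2000, 0, 500, "+", "cand", 1000, 0, 500, 0.002),
    paf_record("q2", 2000, 0, 250, "+", "cand", 1000, 450, 700, 0.002),
    paf_record("q3", 2000, 0, 50, "+", "cand", 1000, 700, 750, 0.002))
  d <- coverage_removal("cand", paf)
  expect_equal(d$action, "remove")
  expect_equal(d$breadth, 0.75)
  expect_equal(d$mean_depth, 0.8)

  # breadth exactly 0.70 -> keep (strict >)
  paf2 <- paf_record("q1", 2000, 0, 700, "+", "cand", 1000, 0, 700, 0.002,
                     block_len = 900)
  paf2 <- rbind(paf2, paf_record("q2", 2000, 0, 100, "+", "cand", 1000, 100,
                                 200, 0.002))
  d2 <- coverage_removal("cand", paf2)
  expect_equal(d2$breadth, 0.70)
  expect_equal(d2$action, "keep")

  # no alignments -> keep
  d3 <- coverage_removal("lone", paf[0, ], contig_lengths = c(lone = 500))
  expect_equal(d3$action, "keep")
  # self-alignments are ignored
  d4 <- coverage_removal("cand",
                         paf_record("cand", 1000, 0, 1000, "+", "cand", 1000,
                                    0, 1000, 0))
  expect_equal(d4$action, "keep")
})

test_that("ordered duplicate chains require same order and distinct ids", {
  mk <- function(cid, ids, at = seq_along(ids)) {
    data.frame(contig_id = cid, start = at * 1000, end = at * 1000 + 500,
               gene_id = ids, status = "duplicated", stringsAsFactors = FALSE)
  }
  same <- rbind(mk("X", c("g1", "g2", "g3")), mk("Y", c("g1", "g2", "g3")))
  ch <- find_ordered_duplicates(same)
  expect_equal(nrow(ch), 1)
  expect_equal(ch$n_genes, 3)
  expect_equal(ch$genes, "g1,g2,g3")

  flipped <- rbind(mk("X", c("g1", "g2")), mk("Y", c("g2", "g1")))
  expect_equal(nrow(find_ordered_duplicates(flipped)), 0)

  same_id <- mk("X", c("g1", "g1"))
  expect_equal(nrow(find_ordered_duplicates(same_id)), 0)

  # intervening non-duplicated genes do not break the chain
  with_single <- rbind(mk("X", c("g1", "g2")),
                       data.frame(contig_id = "X", start = 1500, end = 1600,
                                  gene_id = "s1", status = "single"),
                       mk("Y", c("g1", "g2")))
  expect_equal(nrow(find_ordered_duplicates(with_single)), 1)
})

test_that("the switched copy of a duplicated chain is trimmed", {
  chains <- data.frame(contig_a = "A", a_start = 1000, a_end = 6000,
                       contig_b = "B", b_start = 2000, b_end = 7000,
                       n_genes = 2L, genes = "g1,g2",
                       stringsAsFactors = FALSE)
  tracks <- list(
    A = marker_track("A", seq(0, 9990, 10), rep("P1", 1000), 10000),
    B = marker_track("B", seq(0, 9990, 10),
                     c(rep("P1", 100), rep("P2", 900)), 10000))
  d <- busco_ordered_dedup(chains, tracks, "P1")
  expect_equal(d$action, "trim")
  expect_equal(d$contig_id, "B")
  expect_equal(c(d$trim_start, d$trim_end), c(2000, 7000))

  # neither region switched: likely homozygous, keep both
  tracks$B <- marker_track("B", seq(0, 9990, 10), rep("P1", 1000), 10000)
  expect_equal(busco_ordered_dedup(chains, tracks, "P1")$action, "keep")

  # a region without markers is not switch-flagged
  tracks$B <- marker_track("B", c(9500L), "P2", 10000)
  expect_equal(busco_ordered_dedup(chains, tracks, "P1")$action, "keep")
})

test_that("decision application excises, renames and accounts for bases", {
  contigs <- c(big = strrep("A", 100000))
  dec <- data.frame(contig_id = "big", action = "trim", rule = "r",
                    trim_start = 40000, trim_end = 60000)
  out <- apply_decisions(contigs, dec, min_piece = 20000)
  expect_equal(names(out$contigs), c("big_p1", "big_p2"))
  expect_equal(unname(nchar(out$contigs)), c(40000, 40000))
  acc <- out$accounting
  expect_equal(acc$output_bases,
               acc$input_bases - acc$removed_bases - acc$trimmed_bases -
                 acc$dropped_small_piece_bases)

  # remnant below min_piece is dropped entirely
  dec2 <- data.frame(contig_id = "big", action = "trim", rule = "r",
                     trim_start = 0, trim_end = 95000)
  out2 <- apply_decisions(contigs, dec2, min_piece = 20000)
  expect_length(out2$contigs, 0)
  expect_equal(out2$accounting$dropped_small_piece_bases, 5000)

  # no decisions: identity
  out3 <- apply_decisions(contigs, dec[0, ])
  expect_identical(out3$contigs, contigs)

  # overlapping trims from different rules merge before excision
  dec4 <- rbind(dec, data.frame(contig_id = "big", action = "trim", rule = "r2",
                                trim_start = 55000, trim_end = 70000))
  out4 <- apply_decisions(contigs, dec4, min_piece = 20000)
  expect_equal(out4$accounting$trimmed_bases, 30000)

  expect_error(apply_decisions(contigs,
                               data.frame(contig_id = "ghost",
                                          action = "remove", rule = "r",
                                          trim_start = NA, trim_end = NA)),
               "unknown contigs")
})

test_that("PAF records survive a write/read round trip, with dv fallback", {
  paf <- rbind(paf_record("q", 1000, 10, 900, "+", "t", 2000, 100, 990,
                          divergence = 0.0123),
               paf_record("q2", 500, 0, 400, "-", "t", 2000, 0, 400,
                          divergence = 0.005))
  tmp <- withr::local_tempfile(fileext = ".paf")
  write_paf(paf, tmp)
  back <- read_paf(tmp)
  expect_equal(back$divergence, paf$divergence, tolerance = 1e-6)
  expect_equal(back$q_start, paf$q_start)
  expect_equal(back$target_len, paf$target_len)

  # no dv tag: divergence falls back to 1 - matches/block_len
  writeLines("q\t100\t0\t90\t+\tt\t200\t0\t90\t72\t90\t60", tmp)
  fb <- read_paf(tmp)
  expect_equal(fb$divergence, 1 - 72 / 90)
})

test_that("minimap2 cross-haplotype alignments carry the expected divergence", {
  tr <- fx_truth()
  tmp <- withr::local_tempdir()
  q <- file.path(tmp, "h1.fa"); t <- file.path(tmp, "h2.fa")
  write_fasta(tr$hap1, q)
  write_fasta(tr$hap2, t)
  paf <- align_paf(q, t, preset = "asm5")
  expect_gt(nrow(paf), 0)
  avg <- contig_avg_divergence(paf)
  # homologous haplotype contigs diverge at roughly the simulated rate
  # (SNPs + short indels ~ 1 %), far above the duplicate-flagging threshold
  expect_true(all(avg > 0.003 & avg < 0.05))
  expect_length(flag_cross_hap_candidates(avg), 0)
  # and a contig aligned to itself is near-identical
  self <- align_paf(q, q, preset = "asm5")
  selfavg <- contig_avg_divergence(
    self[self$query_id == self$target_id, , drop = FALSE])
  expect_true(all(selfavg < 0.001))
})

test_that("the dedup pass recovers injected artifacts exactly", {
  tr <- fx_truth()
  hm <- fx_hapmers()
  art <- fx_artifacts()
  for (side in c("A", "B")) {
    res <- run_dedup_side(tr, art, side, hm)
    ev <- dedup_truth_eval(res$decisions, art[[side]])
    expect_equal(ev$precision, 1)
    expect_equal(ev$recall, 1)
  }
})

test_that("marker-first and coverage-first orders agree on the final bases", {
  tr <- fx_truth()
  hm <- fx_hapmers()
  art <- fx_artifacts()
  a <- run_dedup_side(tr, art, "A", hm, coverage_first = FALSE)
  b <- run_dedup_side(tr, art, "A", hm, coverage_first = TRUE)
  expect_identical(sort(names(a$corrected$contigs)),
                   sort(names(b$corrected$contigs)))
  expect_identical(a$corrected$contigs[sort(names(a$corrected$contigs))],
                   b$corrected$contigs[sort(names(b$corrected$contigs))])
})

test_that("dedup is idempotent on artifact-free assemblies", {
  tr <- fx_truth()
  hm <- fx_hapmers()
  art0 <- inject_artifacts(tr, 0, 0, 0, seed = 77)
  res <- run_dedup_side(tr, art0, "A", hm)
  expect_equal(sum(res$decisions$action != "keep"), 0)
  expect_identical(res$corrected$contigs, art0$A$contigs)
  # a second pass over the output changes nothing either
  again <- run_dedup_side(tr, art0, "A", hm)
  expect_identical(again$corrected$contigs, res$corrected$contigs)
})

test_that("base conservation holds through decision application", {
  run <- fx_dedup_run()
  acc <- run$res$corrected$accounting
  expect_equal(acc$output_bases,
               acc$input_bases - acc$removed_bases - acc$trimmed_bases -
                 acc$dropped_small_piece_bases)
})

test_that("BUSCO full tables parse into 0-based gene hits", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# BUSCO version is: 5.x",
               "g1\tComplete\tctg1\t101\t200\t+\tscore",
               "g2\tDuplicated\tctg1\t301\t400\t+\tscore",
               "g2\tDuplicated\tctg2\t11\t110\t-\tscore",
               "g3\tMissing",
               "g4\tFragmented\tctg2\t1\t50\t+\tscore"), tmp)
  hits <- read_busco_table(tmp)
  expect_equal(nrow(hits), 3)
  expect_equal(hits$start[1], 100)
  expect_equal(hits$end[1], 200)
  expect_setequal(hits$status, c("single", "duplicated"))
})
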