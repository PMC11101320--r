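toy_map <- function() {
  ortholog_map(data.frame(gene_a = c("a1", "a2", "a3"),
                          gene_b = c("b1", "b2", "b3")),
               unmapped_a = "a9", unmapped_b = "b9")
}

deg_tab <- function(ids, lfc, padj) {
  data.frame(gene_id = ids, log2FoldChange = lfc, padj = padj,
             stringsAsFactors = FALSE)
}

test_that("DEG filtering uses strict p and non-strict LFC thresholds", {
  tab <- deg_tab(c("g1", "g2", "g3", "g4", "g5"),
                 c(-1.2, 2, 1.0, 0.99, 5),
                 c(0.005, 0.01, 0.0099, 0.001, NA))
  f <- filter_degs(tab)
  expect_setequal(f$deg$gene_id, c("g1", "g3"))   # g2 fails strict p
  expect_equal(f$down, "g1")
  expect_equal(f$up, "g3")
  expect_equal(f$qc$n_missing_padj, 1)
  expect_equal(f$qc$n_input, 5)
})

test_that("planted shared DEGs are recovered exactly by the filter", {
  map <- simulate_ortholog_map(500, 500, 25, 25, seed = 61)
  sim <- simulate_deg_tables(map, n_deg_shared = 20, n_deg_specific_a = 0,
                             n_deg_specific_b = 0, seed = 62)
  fa <- filter_degs(sim$table_a)
  fb <- filter_degs(sim$table_b)
  planted <- sim$truth$gene_a[sim$truth$category == "shared"]
  expect_setequal(fa$deg$gene_id, planted)
  expect_equal(nrow(fb$deg), 20)

  flat <- simulate_deg_tables(map, n_deg_shared = 20, lfc_effect = 0,
                              seed = 63)
  expect_equal(nrow(filter_degs(flat$table_a)$deg), 0)
})

test_that("cross-reference intersection categorises DEG pairs", {
  map <- toy_map()
  degs_a <- deg_tab(c("a1", "a2", "a3", "a9"), c(2, 2, 1.5, -3),
                    rep(0.001, 4))
  degs_b <- deg_tab(c("b1", "b2"), c(1.5, -2), rep(0.001, 2))
  x <- cross_reference_intersection(degs_a, degs_b, map)
  expect_equal(x$shared$gene_a, "a1")           # same sign both refs
  expect_equal(x$discordant$gene_a, "a2")       # opposite signs
  expect_equal(x$a_specific, "a3")              # ortholog exists, B not DEG
  expect_equal(x$a_no_ortholog, "a9")           # unmapped gene
  expect_length(x$b_specific, 0)
  # partition: every DEG of A in exactly one category
  cats <- c(x$shared$gene_a, x$discordant$gene_a, x$a_specific,
            x$a_no_ortholog)
  expect_setequal(cats, degs_a$gene_id)
  expect_equal(anyDuplicated(cats), 0)
})

test_that("a DEG gene unknown to the map is an error", {
  expect_error(cross_reference_intersection(
    deg_tab("mystery", 2, 0.001), deg_tab(character(0), numeric(0),
                                          numeric(0)), toy_map()),
    "absent from the ortholog map")
})

test_that("swapping references mirrors the intersection output", {
  map <- simulate_ortholog_map(300, 300, 15, 15, seed = 71)
  sim <- simulate_deg_tables(map, n_deg_shared = 30, n_deg_specific_a = 10,
                             n_deg_specific_b = 5, n_deg_no_ortholog_a = 3,
                             n_deg_no_ortholog_b = 2, seed = 72)
  fa <- filter_degs(sim$table_a)$deg
  fb <- filter_degs(sim$table_b)$deg
  fwd <- cross_reference_intersection(fa, fb, map)
  swapped_map <- ortholog_map(
    data.frame(gene_a = map$pairs$gene_b, gene_b = map$pairs$gene_a),
    unmapped_a = map$unmapped_b, unmapped_b = map$unmapped_a)
  rev <- cross_reference_intersection(fb, fa, swapped_map)
  expect_setequal(rev$shared$gene_b, fwd$shared$gene_a)
  expect_setequal(rev$discordant$gene_b, fwd$discordant$gene_a)
  expect_setequal(rev$a_specific, fwd$b_specific)
  expect_setequal(rev$b_no_ortholog, fwd$a_no_ortholog)
})

test_that("planted categories are recovered through the intersection", {
  map <- simulate_ortholog_map(800, 800, 40, 40, seed = 81)
  sim <- simulate_deg_tables(map, n_deg_shared = 50, n_deg_specific_a = 12,
                             n_deg_specific_b = 8, n_deg_no_ortholog_a = 5,
                             seed = 82)
  x <- cross_reference_intersection(filter_degs(sim$table_a)$deg,
                                    filter_degs(sim$table_b)$deg, map)
  tt <- sim$truth
  expect_setequal(x$shared$gene_a, tt$gene_a[tt$category == "shared"])
  expect_setequal(x$a_specific, tt$gene_a[tt$category == "specific_a"])
  expect_setequal(x$b_specific, tt$gene_b[tt$category == "specific_b"])
  expect_setequal(x$a_no_ortholog, tt$gene_a[tt$category == "no_ortholog_a"])
  expect_equal(nrow(x$discordant), 0)
})

test_that("consistent DEGs are the intersection across comparisons", {
  mk_shared <- function(genes, lfc) {
    data.frame(gene_a = genes, gene_b = toupper(genes), lfc_a = lfc,
               lfc_b = lfc, stringsAsFactors = FALSE)
  }
  out <- consistent_degs(list(c1 = mk_shared(c("a", "b", "c"), c(1, 1, -2)),
                              c2 = mk_shared(c("b", "c"), c(1, -1)),
                              c3 = mk_shared(c("c"), c(-3))))
  expect_equal(out$gene_a, "c")
  expect_true(out$sign_consistent)

  empty <- consistent_degs(list(c1 = mk_shared(c("a"), 1),
                                c2 = mk_shared(character(0), numeric(0))))
  expect_equal(nrow(empty), 0)

  flip <- consistent_degs(list(c1 = mk_shared("a", 1),
                               c2 = mk_shared("a", -1)))
  expect_false(flip$sign_consistent)
})

test_that("a planted always-DEG core is recovered across three comparisons", {
  map <- simulate_ortholog_map(600, 600, 30, 30, seed = 111)
  core <- data.frame(gene_a = map$pairs$gene_a[1:15],
                     sign = rep(c(-1, 1), length.out = 15))
  shared <- list()
  for (i in 1:3) {
    sim <- simulate_deg_tables(map, n_deg_shared = 40 + 5 * i,
                               n_deg_specific_a = 10, n_deg_specific_b = 10,
                               shared_core = core, seed = 120 + i)
    shared[[paste0("cmp", i)]] <- cross_reference_intersection(
      filter_degs(sim$table_a)$deg, filter_degs(sim$table_b)$deg, map)$shared
  }
  cons <- consistent_degs(shared)
  # the random extra shared DEGs differ between comparisons; only the core
  # survives every intersection (a chance triple overlap is possible but the
  # planted core must be present and sign-consistent)
  expect_true(all(core$gene_a %in% cons$gene_a))
  core_rows <- cons[cons$gene_a %in% core$gene_a, ]
  expect_true(all(core_rows$sign_consistent))
  expect_equal(core_rows$sign_cmp1,
               core$sign[match(core_rows$gene_a, core$gene_a)])
})

test_that("unmapped-gene percentages print at one decimal, half-up", {
  expect_equal(unmapped_fraction(1915, 35463)$percent, 5.4)
  expect_equal(unmapped_fraction(2296, 35739)$percent, 6.4)
  expect_equal(unmapped_fraction(0, 100)$percent, 0)
  expect_equal(unmapped_fraction(1, 1600)$percent, 0.1)  # 0.0625 % rounds up
  expect_error(unmapped_fraction(5, 0))
})

test_that("enrichment builds the documented contingency table", {
  e <- hemizygosity_enrichment(5, 10, 10, 100)
  expect_equal(unname(e$contingency), c(5, 5, 5, 85))
  expect_equal(e$odds_ratio, 17)
  expect_equal(e$direction, "over")
  expect_equal(e$p_value, oracle_fisher(5, 5, 5, 85), tolerance = 1e-12)

  flat <- hemizygosity_enrichment(10, 100, 100, 1000)
  expect_equal(flat$odds_ratio, 1)
  expect_equal(flat$direction, "none")

  extreme <- hemizygosity_enrichment(10, 10, 10, 200)
  expect_equal(extreme$direction, "over")
  expect_identical(extreme$odds_ratio, Inf)
  expect_lt(extreme$p_value, 1e-6)

  expect_error(hemizygosity_enrichment(5, 4, 10, 100), "negative")
})

test_that("the exact test agrees with stats::fisher.test", {
  set.seed(91)
  for (i in 1:50) {
    tab <- matrix(sample(0:25, 4, replace = TRUE), 2)
    p2 <- haplophaser:::fisher_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    expect_equal(p2, stats::fisher.test(tab)$p.value, tolerance = 1e-10)
    pg <- haplophaser:::fisher_p(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2],
                                 alternative = "greater")
    expect_equal(pg, stats::fisher.test(tab, alternative = "greater")$p.value,
                 tolerance = 1e-10)
  }
})
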