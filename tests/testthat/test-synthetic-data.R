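test_that("SNP counts follow the requested binomial rate", {
  tr <- simulate_diploid(length_bp = 50000, n_contigs = 2, snp_rate = 1 / 147,
                         indel_rate = 0, n_svs = 0, n_genes = 0,
                         hemizygous_fraction = 0, seed = 7)
  n_snp <- sum(tr$variants$type == "SNP")
  mu <- 50000 / 147
  sigma <- sqrt(50000 * (1 / 147) * (1 - 1 / 147))
  expect_lt(abs(n_snp - mu), 3 * sigma)
})

test_that("empirical variant rates converge at 1 Mb", {
  tr <- simulate_diploid(length_bp = 1e6, n_contigs = 4, n_svs = 0,
                         n_genes = 0, hemizygous_fraction = 0, seed = 11)
  for (spec in list(c(1 / 147, "SNP"), c(1 / 1458, "INS|DEL"))) {
    rate <- as.numeric(spec[1])
    n <- sum(grepl(spec[2], tr$variants$type))
    expect_lt(abs(n - 1e6 * rate), 3 * sqrt(1e6 * rate * (1 - rate)))
  }
})

test_that("zero variation yields identical haplotypes", {
  tr <- simulate_diploid(length_bp = 20000, n_contigs = 2, snp_rate = 0,
                         indel_rate = 0, n_svs = 0, n_genes = 4,
                         hemizygous_fraction = 0, seed = 3)
  expect_identical(tr$hap1, tr$hap2)
  expect_equal(nrow(tr$variants), 0)
})

test_that("hemizygous genes are counted and single-haplotype by construction", {
  tr <- simulate_diploid(length_bp = 200000, n_contigs = 8, n_svs = 0,
                         n_genes = 50, hemizygous_fraction = 0.1, seed = 9)
  expect_length(tr$hemizygous_genes, 5)
  expect_true(all(tr$hemizygous_genes %in% tr$genes$gene_id))
  expect_false(any(tr$hemizygous_genes %in% tr$genes_hap2$gene_id))
  # and the gene sequence is really absent from hap2
  g <- tr$genes[tr$genes$gene_id == tr$hemizygous_genes[1], ]
  gene_seq <- substr(tr$hap1[[g$contig_id]], g$start + 1, g$end)
  expect_false(grepl(gene_seq, tr$hap2[[g$contig_id]], fixed = TRUE))
})

test_that("generators are deterministic given the seed", {
  a <- simulate_diploid(length_bp = 30000, n_contigs = 2, seed = 5, n_genes = 6)
  b <- simulate_diploid(length_bp = 30000, n_contigs = 2, seed = 5, n_genes = 6)
  expect_identical(a, b)
  r1 <- simulate_reads(a$hap1, 500, coverage = 2, seed = 8)
  r2 <- simulate_reads(a$hap1, 500, coverage = 2, seed = 8)
  expect_identical(r1, r2)
})

test_that("variant intervals stay within contig bounds", {
  tr <- fx_truth()
  lens <- nchar(tr$hap1)
  expect_true(all(tr$variants$start >= 0))
  expect_true(all(tr$variants$end <= lens[tr$variants$contig_id]))
  expect_true(all(tr$variants$end > tr$variants$start))
})

test_that("infeasible gene placement raises an explicit error", {
  expect_error(simulate_diploid(length_bp = 10000, n_contigs = 1,
                                n_genes = 50, gene_length = 1500,
                                n_svs = 0, seed = 1),
               "infeasible gene placement")
})

test_that("read sampling hits the coverage target", {
  seqs <- c(c1 = strrep("ACGT", 25000))  # 100 kb
  reads <- simulate_reads(seqs, read_length_mean = 1000, coverage = 10,
                          seed = 4)
  expect_lt(abs(sum(nchar(reads$seq)) - 1e6) / 1e6, 0.05)
})

test_that("error-free reads are exact substrings; names encode the truth", {
  tr <- fx_truth()
  reads <- simulate_reads(tr$hap1, 800, n_reads = 30, error_rate = 0, seed = 6)
  for (i in seq_len(nrow(reads))) {
    src <- substr(tr$hap1[[reads$contig_id[i]]], reads$start[i] + 1,
                  reads$start[i] + nchar(reads$seq[i]))
    obs <- reads$seq[i]
    if (reads$strand[i] == "-") {
      obs <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(obs)))
    }
    expect_identical(obs, src)
  }
  expect_true(all(grepl("^read\\d+\\|hap=1\\|contig\\d+\\|\\d+$",
                        reads$read_id)))
})

test_that("substitution errors land at the requested rate", {
  seqs <- c(c1 = strrep("ACGTT", 4000))
  reads <- simulate_reads(seqs, read_length_mean = 1000, n_reads = 40,
                          error_rate = 0.1, seed = 12)
  fwd <- reads[reads$strand == "+", ]
  mism <- vapply(seq_len(nrow(fwd)), function(i) {
    src <- substr(seqs[[1]], fwd$start[i] + 1, fwd$start[i] + nchar(fwd$seq[i]))
    sum(utf8ToInt(src) != utf8ToInt(fwd$seq[i]))
  }, numeric(1))
  rate <- sum(mism) / sum(nchar(fwd$seq))
  expect_lt(abs(rate - 0.1), 3 * sqrt(0.1 * 0.9 / sum(nchar(fwd$seq))))
})

test_that("reads longer than every contig are rejected", {
  expect_error(simulate_reads(c(a = strrep("A", 400)), read_length_mean = 1000,
                              coverage = 1, seed = 1),
               "exceeds every contig")
})

test_that("artifact injection produces the requested labels", {
  art <- fx_artifacts()
  for (side in c("A", "B")) {
    lab <- art[[side]]$truth_labels
    expect_equal(sum(lab$label == "switched"), 1)
    expect_equal(sum(lab$label == "leaked_duplicate"), 1)
    expect_equal(sum(lab$label == "partial_switch"), 1)
    iv <- lab[lab$label != "clean" & !is.na(lab$start), ]
    expect_true(all(iv$end > iv$start))
  }
  none <- inject_artifacts(fx_truth(), 0, 0, 0, seed = 5)
  expect_true(all(none$A$truth_labels$label == "clean"))
  expect_identical(none$A$contigs, fx_truth()$hap1)
})

test_that("a leaked block is near-identical to its other-haplotype source", {
  tr <- fx_truth()
  art <- fx_artifacts()
  m <- Filter(function(a) a$kind == "leaked_duplicate", art$A$artifacts)[[1]]
  leaked <- substr(art$A$contigs[[m$contig_id]], m$start + 1, m$end)
  st <- haplophaser:::lift12(tr, m$src_contig, c(m$src_start_h1, m$src_end_h1))
  src2 <- substr(tr$hap2[[m$src_contig]], st[1] + 1, st[2])
  expect_identical(leaked, src2)  # built from hap2, so exact
  # and it diverges from its own-haplotype counterpart at the inter-hap rate
  src1 <- substr(tr$hap1[[m$src_contig]], m$src_start_h1 + 1, m$src_end_h1)
  expect_false(identical(leaked, src1))
})

test_that("FASTA/FASTQ/BED/TSV round trips preserve the data", {
  tr <- simulate_diploid(length_bp = 20000, n_contigs = 2, seed = 21,
                         n_genes = 4, n_svs = 0)
  tmp <- withr::local_tempdir()
  fa <- file.path(tmp, "h1.fa")
  write_fasta(tr$hap1, fa)
  expect_identical(read_fasta(fa), tr$hap1)
  reads <- simulate_reads(tr$hap1, 300, n_reads = 10, seed = 22)
  fq <- file.path(tmp, "reads.fq")
  write_fastq(reads, fq)
  back <- read_fastq(fq)
  expect_identical(back$read_id, reads$read_id)
  expect_identical(back$seq, reads$seq)
  bed <- file.path(tmp, "genes.bed")
  write_bed(data.frame(contig_id = tr$genes$contig_id, start = tr$genes$start,
                       end = tr$genes$end, name = tr$genes$gene_id), bed)
  bb <- read_bed(bed)
  expect_equal(bb$start, tr$genes$start)
  expect_equal(bb$name, tr$genes$gene_id)
  tsv <- file.path(tmp, "var.tsv")
  write_tsv(tr$variants, tsv)
  expect_equal(read_tsv(tsv), tr$variants)
})
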