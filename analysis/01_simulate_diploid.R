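#!/usr/bin/env Rscript
# Stage 1: build the synthetic diploid study system.
#
# Generates a two-haplotype genome at the divergence of a highly heterozygous
# clonal grapevine cultivar (SNP every 147 nt, indel every 1458 nt), with
# genes, structural variants and hemizygous gene deletions recorded as ground
# truth, and writes the sequences and annotations other stages consume.

library(haplophaser)

dir.create("results", showWarnings = FALSE)
seed <- 101

truth <- simulate_diploid(length_bp = 120000, n_contigs = 8,
                          snp_rate = 1 / 147, indel_rate = 1 / 1458,
                          n_svs = 2, n_genes = 24, hemizygous_fraction = 0.1,
                          seed = seed)

write_fasta(truth$hap1, "results/hap1.fa")
write_fasta(truth$hap2, "results/hap2.fa")
write_gff3(truth$genes, "results/genes_hap1.gff3")
write_gff3(truth$genes_hap2, "results/genes_hap2.gff3")
write_tsv(truth$variants, "results/variants.tsv")
write_bed(data.frame(contig_id = truth$genes$contig_id,
                     start = truth$genes$start, end = truth$genes$end,
                     name = truth$genes$gene_id),
          "results/genes_hap1.bed")

counts <- table(truth$variants$type)
message("simulated diploid: ", sum(nchar(truth$hap1)), " bp hap1, ",
        sum(nchar(truth$hap2)), " bp hap2")
message("variants: ", paste(names(counts), counts, sep = "=", collapse = ", "))
message("hemizygous genes: ", paste(truth$hemizygous_genes, collapse = ", "))
message("observed SNP spacing: 1/",
        round(sum(nchar(truth$hap1)) / sum(truth$variants$type == "SNP")),
        " nt (target 1/147)")

# later stages regenerate the truth from the recorded seed
write_tsv(data.frame(parameter = c("length_bp", "n_contigs", "snp_rate",
                                   "indel_rate", "n_svs", "n_genes",
                                   "hemizygous_fraction", "seed"),
                     value = c(120000, 8, 1 / 147, 1 / 1458, 2, 24, 0.1,
                               seed)),
          "results/simulation_parameters.tsv")
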