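#!/usr/bin/env Rscript
# Duplication, tandem-array and collinearity analysis of the toy
# genome, plus promoter extraction and scanning for the planted motif.

suppressMessages(library(sodscan))

loci <- read_gff3("results/data/genes.gff3")
proteins <- read_fasta("results/data/genome_proteins.fasta")
genome <- read_fasta("results/data/genome.fasta", type = "dna")
hp <- read.delim("results/data/homolog_pairs.tsv")
truth <- read.delim("results/data/genome_truth.tsv")

chrA <- loci$gene_id[loci$chrom == "chrA"]
dp <- duplicate_pairs(proteins[chrA], loci)
write.table(dp, "results/duplicate_pairs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sum(dp$is_duplicate), "duplicate pairs under the 70/70 rule\n")

arr <- tandem_arrays(dp, loci)
write.table(arr, "results/tandem_arrays.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("tandem arrays:", nrow(arr), "- members:",
    if (nrow(arr)) arr$member_gene_ids else "none", "\n")
planted <- truth$entity_id[!is.na(truth$planted_array_id)]
cat("planted array recovered:",
    nrow(arr) == 1 && setequal(strsplit(arr$member_gene_ids, ",")[[1]],
                               planted), "\n")

cb <- collinear_blocks(hp, loci, loci, min_block = 3)
write.table(cb, "results/collinear_blocks.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("collinear blocks:", nrow(cb), "; anchors in largest:",
    if (nrow(cb)) max(cb$n_anchors) else 0, "\n")

prom <- extract_promoters(genome, loci, length = 2000)
model <- pwm_from_instances(rep("TTGACGTCAATT", 4), motif_id = "planted_tf")
hits <- scan_promoters(prom, list(model), score_fraction = 0.9)
write.table(hits$counts, "results/promoter_hits.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("promoters with >= 1 planted-motif hit:",
    sum(tapply(hits$counts$n_hits, hits$counts$gene_id, sum) > 0), "of",
    nrow(prom), "\n")
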