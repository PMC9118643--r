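#!/usr/bin/env Rscript
# Generate the synthetic study inputs: a five-group SOD protein family,
# a toy genome with a planted tandem array and a collinear partner
# chromosome, and a count matrix with planted stress effects.  All
# downstream drivers read from results/data/.

suppressMessages(library(sodscan))
seed <- 1L
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

fam <- make_protein_family(n_per_group = 10, background_mut_rate = 0.05,
                           seed = seed)
write_fasta(fam$proteins, "results/data/family_proteins.fasta")
write.table(fam$truth, "results/data/family_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("family:", length(fam$proteins), "proteins across",
    length(unique(fam$truth$planted_group)), "planted groups\n")

g <- make_genome(arrays = list(list(size = 3, spacing_bp = 10000,
                                    intervening = 0)),
                 decoys = 8, collinear_partner = TRUE, shared_genes = 8,
                 seed = seed,
                 promoter_motif = list(consensus = "TTGACGTCAATT",
                                       offset = 500))
write_fasta(as.character(g$genome), "results/data/genome.fasta", type = "dna")
write_fasta(g$proteins, "results/data/genome_proteins.fasta")
write_gff3(g$loci, "results/data/genes.gff3")
write.table(g$truth, "results/data/genome_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(g$homolog_pairs, "results/data/homolog_pairs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("genome:", nrow(g$loci), "genes on",
    length(unique(g$loci$chrom)), "chromosomes; one planted 3-gene array\n")

mc <- make_counts(n_genes = 200, conditions = c("control", "vibrio"),
                  n_rep = 3,
                  planted_fold = data.frame(
                    gene_id = sprintf("gene_%04d", 1:10),
                    condition = "vibrio", fold = 4),
                  dispersion = 0.04, baseline_meanlog = log(500),
                  baseline_sdlog = 0.5, seed = seed + 1)
write.table(data.frame(gene_id = rownames(mc$em$counts), mc$em$counts),
            "results/data/counts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(mc$em$design, "results/data/design.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(gene_id = rownames(mc$em$counts),
                       length_bp = mc$em$gene_length_bp),
            "results/data/gene_lengths.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(mc$truth, "results/data/counts_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("counts:", nrow(mc$em$counts), "genes x", ncol(mc$em$counts),
    "samples; 10 genes planted at 4-fold under vibrio\n")
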