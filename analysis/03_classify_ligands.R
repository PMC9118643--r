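#!/usr/bin/env Rscript
# Map conserved metal-ligand residues for every candidate domain and
# assign the five functional groups; score recovery against the
# generator truth.

suppressMessages(library(sodscan))

proteins <- read_fasta("results/data/family_proteins.fasta")
truth <- read.delim("results/data/family_truth.tsv")

scan <- scan_proteome(proteins, sod_config())
calls <- classify_proteome(scan, proteins)
write.table(calls, "results/classification.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(attr(calls, "profiles"), "results/ligand_profiles.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("group calls:\n")
print(table(calls$group))

rec <- recover_knockouts(truth, calls)
write.table(rec$per_group, "results/classification_recovery.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("per-group recall:\n")
print(rec$per_group)
cat("reference self-mapping conserves",
    map_ligands(ligand_reference("CuZn")$ref_seq)$n_total,
    "of 7 Cu/Zn ligand positions\n")
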