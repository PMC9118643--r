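#!/usr/bin/env Rscript
# Identify SOD candidates in the synthetic family by reference-domain
# scanning and compute their physicochemical profiles.

suppressMessages(library(sodscan))
dir.create("results", showWarnings = FALSE)

proteins <- read_fasta("results/data/family_proteins.fasta")
truth <- read.delim("results/data/family_truth.tsv")

scan <- scan_proteome(proteins, sod_config())
write.table(scan$architectures, "results/architectures.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sodscan:::hits_to_bed(scan$hits), "results/domain_hits.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("scanned", length(proteins), "proteins;",
    length(scan$candidates), "candidates\n")
cat("sensitivity on planted SODs:",
    mean(truth$entity_id %in% scan$candidates), "\n")
cat("family calls:\n")
print(table(scan$architectures$family_call))

phys <- physchem_profile(proteins[scan$candidates])
write.table(phys, "results/physchem.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("physicochemical profile ranges: MW",
    round(min(phys$mw_da)), "-", round(max(phys$mw_da)), "Da, pI",
    min(phys$pi), "-", max(phys$pi), "\n")
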