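# Published reference inputs (not bundled)

Two acceptance checks run against published *Crassostrea gigas* sequences
that are not redistributed with the package.  To enable them, place the
following files here before installing:

- `oyster_sod_accessions.fasta` — protein translations of the NCBI
  accessions `XM_034479061.1`, `XM_011436741.3` and `NM_001308918.1`,
  with record ids `cg_XM_034479061.1`, `cg_XM_011436741.3` and
  `cg_NM_001308918.1`.  For example:

      efetch -db nuccore -id XM_034479061.1 -format fasta_cds_aa

- `cgigas_proteome_longest_isoform.fasta` — the protein set of assembly
  GCA_902806645.1 reduced to the longest isoform per locus.

Without these files the corresponding checks fail (they are never
skipped); all other checks are self-contained.
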