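# sodscan

Genome-wide characterisation of superoxide dismutase (SOD) gene
families, for comparative genomicists working on invertebrate — in
particular bivalve — genomes, where the Cu/Zn-SOD family is expanded
and many members have lost catalytic metal ligands.

SODs convert superoxide (O2·−) into H2O2 and O2 using a metal
cofactor.  Two animal families exist: Cu/Zn-SODs (Pfam Sod_Cu fold)
and Fe/Mn-SODs.  Family membership does not predict enzyme activity;
conservation of the metal-coordinating residues does.  `sodscan`
implements the complete desk-side analysis of such a family:

* **Identification** — iterative best-hit-then-mask local alignment
  (Smith–Waterman, BLOSUM62, 11/1) of embedded Cu/Zn and Fe/Mn
  reference domains, with Karlin–Altschul significance
  `E = K·m·n·e^(−λS)` (λ = 0.267, K = 0.041) at the threshold
  E ≤ 1e−10.  Multi-domain proteins report up to four Sod_Cu copies.
* **Physicochemical profile** — length, average-mass MW, Bjellqvist
  pI, Guruprasad instability index, Ikai aliphatic index,
  Kyte–Doolittle GRAVY, on the ProtParam scale.
* **Conserved-ligand classification** — global alignment (10/0.5) onto
  the family reference; strict residue identity at the 4 Cu + 3 Zn
  ligand columns (or His-His-Asp-His + His-Tyr-Gln for Mn) yields five
  functional groups: `MnSOD`, `CuZn_active`, `Cu_only`, `Zn_only`,
  `metal_free`.
* **Genome context** — the 70/70 duplication rule (aligned coverage of
  the longer sequence > 0.70 AND aligned-column identity > 0.70),
  tandem arrays (≤ 5 intervening genes, array span ≤ 100 kb), and
  MCScanX-like collinear blocks via longest monotone anchor chains.
* **Motifs and promoters** — log-odds PWM construction from instance
  sets, non-overlapping motif scanning with combination strings
  (e.g. `1-3-2`), 2000-bp promoter extraction and double-strand PWM
  scanning.
* **Expression** — FPKM/TPM, log2 heat values, fold changes, and
  response calls by one-way ANOVA followed by Duncan's multiple range
  test at P < 0.05.
* **Phylogeny** — neighbor joining on Poisson-corrected distances with
  column-resampling bootstrap and supported-clade cutting.
* **Synthetic data** — generators for all of the above with
  machine-readable truth tables (planted ligand knockouts, tandem
  arrays, collinear segments, promoter sites, expression effects).

The repository is organised as an analysis: `analysis/01_simulate.R`
through `analysis/06_phylogeny.R` narrate the workflow over synthetic
data and write tables under `results/`; every computation they perform
is an exported package function.

## Worked example

```r
library(sodscan)

fam  <- make_protein_family(n_per_group = 2, background_mut_rate = 0.05,
                            seed = 42)
scan <- scan_proteome(fam$proteins)
head(scan$architectures, 4)
#>       protein_id   ordered_domains n_sod_cu family_call
#> 1       mnsod_01 SOD_FE_N-SOD_FE_C        0 MnFe_family
#> 2       mnsod_02 SOD_FE_N-SOD_FE_C        0 MnFe_family
#> 3 cuzn_active_01            SOD_CU        1 CuZn_family
#> 4 cuzn_active_02            SOD_CU        1 CuZn_family

calls <- classify_proteome(scan, fam$proteins)
head(calls[, c("protein_id", "group")], 6)
#>       protein_id       group
#> 1       mnsod_01       MnSOD
#> 2       mnsod_02       MnSOD
#> 3 cuzn_active_01 CuZn_active
#> 4 cuzn_active_02 CuZn_active
#> 5     cu_only_01     Cu_only
#> 6     cu_only_02     Cu_only

physchem_profile(fam$proteins[1:2])
#>   protein_id length_aa   pi    mw_da instability aliphatic      gravy
#> 1   mnsod_01       222 6.82 25026.53    41.36216  86.53153 -0.3558559
#> 2   mnsod_02       222 8.87 24937.51    35.73198  86.62162 -0.3702703
```

Ten proteins were generated, two per functional group; the scanner
assigns every one to its family (Fe/Mn proteins hit both halves of the
Fe/Mn fold, Cu/Zn proteins hit Sod_Cu), and the ligand classifier
recovers each planted group from the conservation pattern alone.  The
profile table mirrors the usual ProtParam report: the two Mn-SOD
homologs are ~25 kDa with near-neutral-to-basic pI and negative GRAVY
(soluble, slightly hydrophilic), and an instability index above 40
flags the first as predicted-unstable in vitro.

`run_pipeline()` chains the stages over FASTA/GFF3/TSV inputs and
writes one TSV per stage plus a log; outputs are byte-identical across
reruns with the same inputs, configuration and seed.

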