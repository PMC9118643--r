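---
title: "Methods: SOD gene-family identification, classification and response calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SOD gene-family identification, classification and response calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sodscan)
```

# Scope and model

Superoxide dismutases (SODs) are the metalloenzymes that convert the
superoxide anion into peroxide and oxygen.  Two families occur in
animals: Cu/Zn-SODs (the Pfam Sod_Cu fold) and Fe/Mn-SODs.  In marine
bivalves the Cu/Zn family is strongly expanded and many members have
lost one or both catalytic metals, so family membership alone does not
predict enzyme activity — the conservation of the metal-coordinating
residues does.  `sodscan` implements the full desk-side analysis of such
a family: candidate identification, physicochemical profiling,
conserved-ligand classification into five functional groups, genomic
duplication context, motif/promoter annotation, expression response
calling, and a light phylogeny — with a synthetic-data module that
generates inputs with known truth so every step is testable end to end.

The package is organised as an analysis: the numbered drivers under
`analysis/` narrate the workflow over synthetic data and write their
tables under `results/`, while all computation lives in exported
functions so the test suite and `scripts/acceptance.R` exercise the same
code paths.

# Candidate identification

BLAST/HMMER identification against Pfam models is replaced by one
embedded-reference scanner: `scan_domains()` aligns each of three
reference domains (`SOD_CU`, human SOD1-derived; `SOD_FE_N`/`SOD_FE_C`,
the two halves of the human SOD2 fold) locally against the protein
(Smith–Waterman, BLOSUM62, gap open 11 / extend 1) and converts raw
scores to Karlin–Altschul E-values, `E = K m n exp(-lambda S)`, with
fixed gapped-BLOSUM62 constants `lambda = 0.267`, `K = 0.041`.  The two
thresholds of the published criterion (a significant search hit *and* a
significant domain hit, both at E ≤ 1e-10) collapse to one test because
they are identical.  Scanning is iterative best-hit-then-mask: the best
hit below threshold is recorded, its span masked completely (later hits
may not overlap it at all), and the search repeats on the remaining
segments, which is what lets multi-domain proteins report up to four
Sod_Cu copies.  Choices a user may care about:

* `evalue_threshold` (default 1e-10) — the published identification
  cutoff.
* `min_hit_len` (40 alignment columns) — suppresses spurious micro-hits
  in the segments left over after masking; the source analysis is
  silent on this, so it is exposed.
* `min_protein_len` (100 aa) — the "partial coding sequences were
  filtered" rule with no published length; exposed rather than asserted.
* Karlin–Altschul constants are deliberately fixed, not re-estimated
  per query: the scanner is meant to be deterministic and auditable,
  and the decision boundary at 1e-10 is extremely insensitive to small
  parameter changes at these score magnitudes.

# Physicochemical profile

`physchem_profile()` reproduces the standard sequence-only descriptors
on the scale of the ProtParam service: molecular weight from ExPASy
*average* residue masses plus one water (reported in daltons — the
published table is headed kDa but prints dalton-scale numbers);
isoelectric point by bisection (to < 0.005 pH units) of the
Henderson–Hasselbalch net charge under the Bjellqvist pKa set (one free
N- and C-terminus, K/R/H positive, D/E/C/Y negative); the Guruprasad
instability index from the embedded dipeptide weight table; the Ikai
aliphatic index; and Kyte–Doolittle GRAVY.  The ambiguity letter X is
excluded from every sum with a warning; lengths are reported including
X.  Note the pI model is the plain Bjellqvist set; ProtParam's
positional pKa refinements for termini-adjacent residues are not
replicated, which can shift pI by a few hundredths on short sequences.

# Conserved-ligand classification

`map_ligands()` aligns a candidate domain globally
(Needleman–Wunsch, BLOSUM62, 10/0.5) to the family reference and asks,
for each annotated ligand column, whether the aligned query column
carries *exactly* the expected residue — a substitution or gap counts
as loss, matching the biological reading that any ligand loss
compromises catalysis.  The references are configuration data derived
from the curated metal-binding annotations of human SOD1/SOD2: 4 Cu
histidines and 3 Zn positions (His, His, Asp) for Cu/Zn — the
His bridging both metals is assigned to the Cu set so the total is the
canonical 7 conserved ligands — and His-His-Asp-His (metal linkage)
plus His-Tyr-Gln (active centre) for Mn.  Published accounts
occasionally say "8" ligands for Mn-SOD while enumerating these 7; the
registry defaults to the enumerated 7 and does not invent an eighth.

`classify_sod()` turns per-domain counts into the five functional
groups: `CuZn_active` (4/4 Cu and 3/3 Zn), `Cu_only`, `Zn_only`,
`metal_free`, and `MnSOD` (all 7 Mn positions conserved).  A
multi-domain protein takes the best label of its domains under the
priority `CuZn_active > Cu_only > Zn_only > metal_free`.  Because
Fe/Mn-SOD splits over two reference domains, Fe/Mn-family candidates
are profiled once against the full-length reference rather than per
hit.

# Genome context

`duplicate_pairs()` applies the 70/70 rule: a pair is a duplicate when
aligned coverage of the *longer* sequence exceeds `dup_coverage` and
aligned-column identity exceeds `dup_identity` (both strictly, both
default 0.70).  "Similarity" is implemented as column identity with
gaps excluded; a `similarity_mode = "positive"` switch reports the
BLOSUM62-positive fraction instead, since the published criterion's
wording is ambiguous between the two.

`tandem_arrays()` connects duplicate pairs on the same chromosome
separated by at most `tandem_max_intervening = 5` genes (gene rank is a
dense per-chromosome ordering by start, ties by end then id); connected
components whose genomic *span* fits within `tandem_window_bp =
100000` are arrays.  The window is applied to the array span — the
published rule ("five or fewer genes in 100-kb") does not say whether
the 100 kb is measured between starts, midpoints or over the span, and
the span reading is the conservative one that also rejects chains whose
ends drift apart.

`collinear_blocks()` is a deliberately small MCScanX-like step: within
each chromosome pair it repeatedly extracts the longest strictly
monotone chain of homologous anchor pairs (longest-increasing-
subsequence on rank pairs, both orientations), greedily and without
anchor reuse, keeping chains of at least `min_block = 3` anchors.  The
default is below the classical 5 because the intended inputs are small
gene families, not whole genomes; block-level statistical scoring is
out of scope.

# Motifs and promoters

De-novo motif discovery is a published tool's job; scanning is the
reusable computation.  `pwm_from_instances()` builds log2-odds PWMs
from aligned instances (counts + pseudocount over a background,
uniform by default); `scan_motifs()` reports the best non-overlapping
matches per model above `score_fraction` of the model's maximum score
(greedy by score, ties leftmost) and derives the dash-joined
motif-combination string (e.g. `"1-3-2"`) from match order.
`extract_promoters()` takes the `promoter_len_bp = 2000` bases upstream
of the gene 5' end, strand-corrected and flagged when truncated at a
contig edge; the anchor is the gene-feature 5' end, which equals the
translation start when gene models are CDS-anchored.
`scan_promoters()` scans both strands, so a palindromic site counts
once per strand; transcription-factor family labels are user-supplied
metadata, not a database lookup.

# Expression response calling

`fpkm()` and `tpm()` are the standard normalisations (`TPM` columns sum
to 1e6 by construction).  `anova_duncan()` runs, per gene, a
fixed-effects one-way ANOVA on `log2(x + 1)` abundances (the heat-map
scale; a flag disables the transform) and, when `P < alpha = 0.05`,
Duncan's multiple range test: condition means are sorted and a range of
`p` means is homogeneous when its extremes differ by less than
`q(1 - (1-alpha)^(p-1), p, df) * sqrt(MSE / n_h)` with `n_h` the
harmonic mean group size; maximal homogeneous ranges receive letters,
and a condition is called `up`/`down` against the control only when the
two share no letter.  With two groups this collapses exactly to a
pooled-variance t test, which the suite uses as an algebraic oracle.

Two practical caveats are documented rather than hidden: TPM is
compositional, so strong genuine effects induce opposite apparent
shifts in the remaining genes (the analysis driver demonstrates this on
synthetic data); and the Duncan letters are a display of stepwise
decisions, not simultaneous confidence statements.

# Phylogeny

`nj_tree()` is canonical neighbor joining (via ape) on Poisson-corrected
distances `d = -ln(max(identity, 0.001))` from global alignments.  This
deliberately replaces maximum-likelihood inference: it is exact on
additive distances (a property the suite verifies on 50 random trees),
fast, and fully deterministic, but its clade structure on real data is
a qualitative stand-in, not a reproduction of an ML topology.
`align_family()` is a reference-anchored multiple alignment (every
sequence aligned to the longest one; insertions relative to the anchor
are dropped) — adequate for column-resampling bootstrap on a homologous
family, inadequate for distant outgroups.  `bootstrap_support()`
resamples columns, rebuilds the NJ tree per replicate and reports
percent bipartition support; `cut_clades()` returns the *maximal*
subtrees whose subtending edge reaches the support threshold, everything
else as singletons.

# Synthetic data: what it emulates and what it does not

`make_protein_family()` plants the five functional groups by mutating
ligand positions to alanine (chemically inert, alignment-stable) on the
family templates and adding background substitutions drawn from
BLOSUM62-conditional probabilities, never touching ligand columns
except as instructed; multi-domain proteins are concatemers of
independently mutated domain copies.  `make_genome()` lays out tandem
arrays (low-divergence template copies) and shuffled-composition decoys
on a toy chromosome, optionally with a partner chromosome sharing an
ordered gene subset and a planted promoter motif at a fixed upstream
offset.  `make_counts()` draws negative-binomial counts with log-normal
per-gene baselines, log-normal library factors and planted per-condition
folds.  Every entity carries exactly one truth row and regeneration from
the same seed is byte-identical.

Defaults mirror the study conditions the pipeline targets: 10 proteins
per group at 5% background divergence; a 3-gene array within a 100-kb
window among unrelated decoys; 3 replicates per condition with
dispersion 0.04 — a count CV of about 0.2 once baselines are high
enough (the drivers use log-normal baselines around 500 counts for
that reason) — and 4-fold planted effects.  What the generator does
*not* emulate: real intergenic sequence composition, splice isoforms,
correlated gene-gene expression, GC or length biases in counting, and
sequence families more divergent than BLOSUM62-style substitution.
Passing the recovery suites therefore demonstrates the correctness of
the decision rules, not field performance on diverged real proteomes.

# Numerical and degenerate-input choices

* Alignments come from `Biostrings::pairwiseAlignment`; a length-L gap
  costs `open + L*ext` (BLAST convention).  The test suite checks local
  scores against an independent affine-gap DP oracle.
* Coordinates are 1-based inclusive everywhere inside R (the
  R/Bioconductor convention); exported domain-hit tables use BED-like
  0-based half-open starts.
* X scores 0 against everything in alignments and is excluded from
  physicochemical sums with a warning.
* Ties: registry order breaks equal E-values in scanning; leftmost
  position breaks equal motif-match scores; rank (start, then end, then
  id) totally orders genes.
* Degenerate inputs error early and by name: empty FASTA, duplicate
  ids, start > end, unknown strand, chromosomes absent from the genome,
  conditions with fewer than 2 replicates, all-zero TPM columns.
  All-constant expression vectors short-circuit to `F = 0, P = 1`.
* Identity is floored at 0.001 before the Poisson log so distances stay
  finite.

# Problem sizes

The suites and the acceptance script run at desk scale, chosen to keep
every stochastic check well-powered while the whole battery stays fast:
50-protein families (10 per group), 20-protein decoy sets, 1000-shuffle
E-value null, 100-seed random-scan null, 2000-gene ANOVA null, 200-gene
planted-effect matrices, 100-replicate bootstraps, and 50 random trees
for the NJ exactness property.

# Known limitations

* The scanner's E-values are approximate (fixed Karlin–Altschul
  constants); the 1e-10 decision boundary is robust to this, but the
  absolute E-values should not be compared with BLAST output digit for
  digit.
* Ligand mapping depends on the global alignment being in register
  around the ligand columns; at background divergence far beyond the
  tested 30% the alignment, and with it the classification, degrades.
* The reference-anchored alignment under-represents insertions relative
  to the anchor; bootstrap supports for very gappy families will be
  conservative.
* Checks that require published accession sequences (the printed
  descriptor table, the human-SOD1 similarity bound, the 13-candidate
  proteome count) run only when those sequences are placed under
  `inst/extdata/real/` as described there; they are never skipped and
  fail loudly when absent.
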