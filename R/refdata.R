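# Embedded reference domain and ligand data.
#
# The Cu/Zn reference is derived from human SOD1 (UniProt P00441,
# canonical, initiator Met included); the Fe/Mn references are the N- and
# C-terminal halves of human SOD2 (UniProt P04179, precursor numbering).
# Ligand coordinates follow the curated metal-binding annotations of those
# entries; the histidine bridging the Cu and Zn sites is assigned to the
# Cu set only, so the Cu/Zn family carries 4 Cu + 3 Zn = 7 conserved
# ligand positions.  These sequences and coordinates are configuration
# data: classification is always relative to this registry.

.sod1_seq <- paste0(
  "MATKAVCVLKGDGPVQGIINFEQKESNGPVKVWGSIKGLTEGLHGFHVHEFGDNTAGCTSAGPHFN",
  "PLSRKHGGPKDEERHVGDLGNVTADKDGVADVSIEDSVISLSGDHCIIGRTLVVHEKADDLGKGGN",
  "EESTKTGNAGSRLACGVIGIAQ")

.sod2_seq <- paste0(
  "MLSRAVCGTSRQLAPALGYLGSRQKHSLPDLPYDYGALEPHINAQIMQLHHSKHHAAYVNNLNVTE",
  "EKYQEALAKGDVTAQIALQPALKFNGGGHINHSIFWTNLSPNGGGEPKGELLEAIKRDFGSFDKFK",
  "EKLTAVSVGVQGSGWGWLGFNKERGHLQIAACPNQDPLQGTTGLIPLLGIDVWEHAYYLQYKNVRP",
  "DYLKAIWNVINWENVTERYMACKK")

#' Reference SOD domain registry
#'
#' Returns the embedded reference domains used by [scan_domains()]:
#' `SOD_CU` (the Cu/Zn-SOD domain, human SOD1-derived, ~150 aa),
#' `SOD_FE_N` and `SOD_FE_C` (N- and C-terminal halves of the Fe/Mn-SOD
#' fold, human SOD2-derived).
#'
#' @return A named list of reference domains, each a list with elements
#'   `name`, `seq` and `source_note`.
#' @export
#' @examples
#' names(sod_domain_registry())
sod_domain_registry <- function() {
  list(
    SOD_CU = list(
      name = "SOD_CU", seq = .sod1_seq,
      source_note = "Cu/Zn-SOD domain, derived from human SOD1"),
    SOD_FE_N = list(
      name = "SOD_FE_N", seq = substr(.sod2_seq, 25, 114),
      source_note = "Fe/Mn-SOD alpha-hairpin domain, human SOD2 residues 25-114"),
    SOD_FE_C = list(
      name = "SOD_FE_C", seq = substr(.sod2_seq, 115, 222),
      source_note = "Fe/Mn-SOD C-terminal domain, human SOD2 residues 115-222")
  )
}

#' Reference metal-ligand coordinates
#'
#' Ligand positions are 1-based indices into `ref_seq`.  For the `CuZn`
#' family the reference carries 4 Cu-coordinating histidines and 3
#' Zn-coordinating positions (His, His, Asp); the bridging His belongs to
#' the Cu set, giving 7 distinct conserved-ligand columns.  For the `MnFe`
#' family the reference carries the 4 Mn-linkage positions
#' (His-His-Asp-His) and 3 active-centre positions (His-Tyr-Gln).
#'
#' @param family `"CuZn"` or `"MnFe"`.
#' @return A list with `family`, `ref_seq`, and named position/residue
#'   sets (`cu`, `zn` or `mn`, `conf`), each a list with integer
#'   `positions` and character `residues`.
#' @export
#' @examples
#' ligand_reference("CuZn")$cu$positions
ligand_reference <- function(family = c("CuZn", "MnFe")) {
  family <- match.arg(family)
  if (family == "CuZn") {
    ref <- list(
      family = "CuZn", ref_seq = .sod1_seq,
      cu = list(positions = c(47L, 49L, 64L, 121L),
                residues  = c("H", "H", "H", "H")),
      zn = list(positions = c(72L, 81L, 84L),
                residues  = c("H", "H", "D")))
  } else {
    ref <- list(
      family = "MnFe", ref_seq = .sod2_seq,
      mn = list(positions = c(50L, 98L, 183L, 187L),
                residues  = c("H", "H", "D", "H")),
      conf = list(positions = c(54L, 58L, 167L),
                  residues  = c("H", "Y", "Q")))
  }
  # registry self-check: annotated residues must be present in ref_seq
  for (set in ref[setdiff(names(ref), c("family", "ref_seq"))]) {
    got <- substring(ref$ref_seq, set$positions, set$positions)
    stopifnot(identical(got, set$residues))
  }
  ref
}

# all ligand positions of a reference, in increasing order
ligand_positions <- function(ref) {
  sets <- ref[setdiff(names(ref), c("family", "ref_seq"))]
  sort(unlist(lapply(sets, `[[`, "positions"), use.names = FALSE))
}
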