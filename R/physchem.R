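# Physicochemical descriptors computed from sequence alone, on the
# scale reported by the ExPASy ProtParam service: average-isotopic
# molecular weight, Bjellqvist isoelectric point, Guruprasad instability
# index, Ikai aliphatic index and Kyte-Doolittle GRAVY.
#
# The ambiguity letter X is excluded from every sum (with a warning);
# reported lengths include X.

drop_x <- function(seq, what) {
  if (grepl("X", seq, fixed = TRUE)) {
    warning("excluding X residues from ", what, " calculation")
    seq <- gsub("X", "", seq, fixed = TRUE)
  }
  seq
}

aa_counts <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  tab <- table(factor(ch, levels = .aa_letters))
  as.vector(tab, mode = "integer") |> setNames(.aa_letters)
}

#' Molecular weight (average isotopic)
#'
#' Sum of ExPASy average residue masses plus one water (18.01524 Da).
#'
#' @param seq Amino-acid string.
#' @return Molecular weight in daltons.
#' @export
#' @examples
#' molecular_weight("G")  # 75.07
molecular_weight <- function(seq) {
  seq <- drop_x(check_aa(seq), "molecular weight")
  if (!nzchar(seq)) stop("empty sequence after removing X")
  sum(aa_counts(seq) * .aa_mass) + .water_mass
}

# net charge at a given pH under the Bjellqvist model
net_charge <- function(counts, pH) {
  pos_n <- c(Nterm = 1, K = counts[["K"]], R = counts[["R"]], H = counts[["H"]])
  neg_n <- c(Cterm = 1, D = counts[["D"]], E = counts[["E"]],
             C = counts[["C"]], Y = counts[["Y"]])
  sum(pos_n / (1 + 10^(pH - .pka_pos))) - sum(neg_n / (1 + 10^(.pka_neg - pH)))
}

#' Isoelectric point
#'
#' pH at which the net charge of the polypeptide is zero under
#' Henderson-Hasselbalch terms for one free N-terminus, K, R, H
#' (positive) and one free C-terminus, D, E, C, Y (negative), using the
#' Bjellqvist pKa set.  Solved by bisection on `[0, 14]` to better than
#' 0.005 pH units.
#'
#' @param seq Amino-acid string.
#' @return The isoelectric point in pH units.
#' @export
isoelectric_point <- function(seq) {
  seq <- drop_x(check_aa(seq), "pI")
  if (!nzchar(seq)) stop("empty sequence after removing X")
  counts <- aa_counts(seq)
  lo <- 0; hi <- 14
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (net_charge(counts, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Instability index
#'
#' `II = (10 / L) * sum(DIWV(x_i, x_{i+1}))` over the L - 1 adjacent
#' dipeptides, with the Guruprasad dipeptide instability weight values.
#' Values above 40 predict an unstable protein in vitro.
#'
#' @param seq Amino-acid string of length >= 2 (after removing X).
#' @return The instability index (dimensionless).
#' @export
instability_index <- function(seq) {
  seq <- drop_x(check_aa(seq), "instability index")
  L <- nchar(seq)
  if (L < 2) stop("instability index needs at least 2 residues")
  ch <- strsplit(seq, "")[[1]]
  10 / L * sum(.diwv[cbind(ch[-L], ch[-1])])
}

#' Aliphatic index
#'
#' `AI = X(Ala) + 2.9 X(Val) + 3.9 (X(Ile) + X(Leu))` with `X(.)` the
#' mole percent of the residue.
#'
#' @param seq Amino-acid string.
#' @return The aliphatic index (dimensionless).
#' @export
#' @examples
#' aliphatic_index("AAAA")  # 100
aliphatic_index <- function(seq) {
  seq <- drop_x(check_aa(seq), "aliphatic index")
  if (!nzchar(seq)) stop("empty sequence after removing X")
  x <- aa_counts(seq) / nchar(seq) * 100
  x[["A"]] + 2.9 * x[["V"]] + 3.9 * (x[["I"]] + x[["L"]])
}

#' Grand average of hydropathicity (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over all residues.
#'
#' @param seq Amino-acid string.
#' @return The GRAVY value.
#' @export
#' @examples
#' gravy("V")  # 4.2
gravy <- function(seq) {
  seq <- drop_x(check_aa(seq), "GRAVY")
  if (!nzchar(seq)) stop("empty sequence after removing X")
  mean(.aa_kd[strsplit(seq, "")[[1]]])
}

#' Physicochemical profile of a protein collection
#'
#' @param proteins An `AAStringSet` or named character vector.
#' @return A `data.frame` with one row per protein: `protein_id`,
#'   `length_aa` (including X), `pi`, `mw_da`, `instability`,
#'   `aliphatic`, `gravy`, mirroring the usual ProtParam report order.
#' @export
physchem_profile <- function(proteins) {
  prot <- as_protein_set(proteins)
  rows <- lapply(names(prot), function(id) {
    s <- prot[[id]]
    data.frame(protein_id = id, length_aa = nchar(s),
               pi = round(isoelectric_point(s), 2),
               mw_da = molecular_weight(s),
               instability = instability_index(s),
               aliphatic = aliphatic_index(s),
               gravy = gravy(s), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
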