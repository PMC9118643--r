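# Conserved metal-ligand mapping and five-group functional
# classification.
#
# A candidate domain is aligned globally to the family reference and
# each annotated ligand column is checked for strict residue identity
# (a substitution or gap at the column counts as lost).  Cu/Zn-family
# domains are then labelled CuZn_active (4/4 Cu and 3/3 Zn), Cu_only,
# Zn_only or metal_free; Fe/Mn-family proteins are MnSOD only when all
# Mn-linkage and active-centre positions are conserved.

#' Map conserved ligand residues of a domain
#'
#' Globally aligns `domain_seq` to the family reference (BLOSUM62, gap
#' open 10, extension 0.5) and reports, for every annotated ligand
#' position of the reference, whether the aligned query column carries
#' exactly the expected residue.
#'
#' @param domain_seq Amino-acid string of the candidate domain
#'   (length >= 40).
#' @param ref A [ligand_reference()].
#' @return A list with `family`, logical `conserved` named by reference
#'   position, per-set counts (`n_cu`, `n_zn` for CuZn; `n_mn`, `n_conf`
#'   for MnFe) and `n_total`.
#' @export
#' @examples
#' ref <- ligand_reference("CuZn")
#' map_ligands(ref$ref_seq, ref)$n_total  # 7
map_ligands <- function(domain_seq, ref = ligand_reference("CuZn")) {
  domain_seq <- check_aa(domain_seq)
  if (nchar(domain_seq) < 40) stop("domain sequence shorter than 40 aa")
  al <- global_align(domain_seq, ref$ref_seq)
  q <- strsplit(al$q_aln, "")[[1]]
  t <- strsplit(al$t_aln, "")[[1]]
  if (all(q == "-") || all(t == "-")) stop("degenerate alignment")
  # reference position of each alignment column (the aligned views
  # exclude terminal gaps, hence the t_start offset)
  ref_pos_of_col <- al$t_start - 1L + cumsum(t != "-")
  ref_pos_of_col[t == "-"] <- NA_integer_
  sets <- ref[setdiff(names(ref), c("family", "ref_seq"))]
  conserved <- logical(0)
  counts <- integer(length(sets)); names(counts) <- names(sets)
  for (sn in names(sets)) {
    set <- sets[[sn]]
    ok <- vapply(seq_along(set$positions), function(i) {
      col <- match(set$positions[i], ref_pos_of_col)
      !is.na(col) && q[col] == set$residues[i]
    }, logical(1))
    names(ok) <- paste0(sn, set$positions)
    conserved <- c(conserved, ok)
    counts[sn] <- sum(ok)
  }
  out <- list(family = ref$family, conserved = conserved,
              n_total = sum(conserved))
  for (sn in names(counts)) out[[paste0("n_", sn)]] <- unname(counts[sn])
  out
}

#' Ligand columns spanned by a peptide aligned into the reference
#'
#' Aligns a short peptide (for example a conserved motif consensus) into
#' the family reference, the whole peptide against the best-matching
#' reference region, and counts the annotated ligand columns that fall
#' within the aligned reference span.
#'
#' @param peptide Amino-acid string.
#' @param ref A [ligand_reference()].
#' @return Integer count of ligand columns inside the span, with the
#'   span as attribute `span` (reference coordinates, 1-based inclusive).
#' @export
motif_ligand_span <- function(peptide, ref = ligand_reference("CuZn")) {
  al <- global_align(check_aa(peptide), ref$ref_seq, type = "global-local")
  span <- c(al$t_start, al$t_end)
  n <- sum(ligand_positions(ref) >= span[1] & ligand_positions(ref) <= span[2])
  structure(n, span = span)
}

# label one Cu/Zn domain profile
.cuzn_label <- function(profile) {
  cu_ok <- profile$n_cu == 4L
  zn_ok <- profile$n_zn == 3L
  if (cu_ok && zn_ok) "CuZn_active"
  else if (cu_ok) "Cu_only"
  else if (zn_ok) "Zn_only"
  else "metal_free"
}

#' Classify a protein into the five functional groups
#'
#' Protein-level groups are `MnSOD`, `CuZn_active`, `Cu_only`,
#' `Zn_only` and `metal_free`.  For Cu/Zn-family proteins every domain
#' is labelled from its ligand profile and the protein takes the best
#' label under the priority `CuZn_active > Cu_only > Zn_only >
#' metal_free`.  Fe/Mn-family proteins are `MnSOD` exactly when all
#' Mn-linkage and active-centre positions are conserved.
#'
#' @param architecture One-row architecture `data.frame` from
#'   [scan_domains()] (fields `protein_id`, `family_call`).
#' @param profiles A list of ligand profiles from [map_ligands()], one
#'   per domain, in domain order.
#' @return A list with `protein_id`, `group`, `per_domain_groups`
#'   (character vector) and a human-readable `rationale`.
#' @export
classify_sod <- function(architecture, profiles) {
  if (length(profiles) == 0) stop("no ligand profiles supplied")
  id <- architecture$protein_id
  if (architecture$family_call == "MnFe_family") {
    p <- profiles[[1]]
    all_ok <- p$n_mn == 4L && p$n_conf == 3L
    group <- if (all_ok) "MnSOD" else "metal_free"
    return(list(protein_id = id, group = group,
                per_domain_groups = group,
                rationale = sprintf("MnFe family: %d/4 Mn linkage, %d/3 active-centre positions conserved",
                                    p$n_mn, p$n_conf)))
  }
  labels <- vapply(profiles, .cuzn_label, character(1))
  priority <- c(CuZn_active = 1, Cu_only = 2, Zn_only = 3, metal_free = 4)
  group <- names(priority)[min(priority[labels])]
  counts <- vapply(profiles, function(p) sprintf("%d/4 Cu, %d/3 Zn", p$n_cu, p$n_zn),
                   character(1))
  list(protein_id = id, group = group, per_domain_groups = unname(labels),
       rationale = paste0("CuZn family: per-domain ligands [",
                          paste(counts, collapse = "; "), "]"))
}

#' Classify a scanned protein collection
#'
#' Runs [map_ligands()] on every domain hit of every candidate and
#' [classify_sod()] on the profiles.
#'
#' @param scan Result of [scan_proteome()].
#' @param proteins The scanned `AAStringSet`/named character vector.
#' @return A `data.frame`: `protein_id`, `domain_index`, `n_cu`, `n_zn`
#'   (or Mn counts), `group`, `rationale`; one row per protein with
#'   per-domain counts collapsed into `rationale`, plus per-domain rows
#'   in attribute `profiles`.
#' @export
classify_proteome <- function(scan, proteins) {
  prot <- as_protein_set(proteins)
  refs <- list(CuZn_family = ligand_reference("CuZn"),
               MnFe_family = ligand_reference("MnFe"))
  arch <- scan$architectures
  rows <- list(); prow <- list()
  for (i in seq_len(nrow(arch))) {
    if (arch$family_call[i] == "none") next
    id <- arch$protein_id[i]
    ref <- refs[[arch$family_call[i]]]
    hits <- scan$hits[scan$hits$protein_id == id, , drop = FALSE]
    if (arch$family_call[i] == "MnFe_family") {
      # the Fe/Mn fold is split over two reference domains; profile the
      # whole protein against the full-length reference once
      profs <- list(map_ligands(prot[[id]], ref))
    } else {
      hits <- hits[hits$domain_name == "SOD_CU", , drop = FALSE]
      profs <- lapply(seq_len(nrow(hits)), function(k)
        map_ligands(substr(prot[[id]], hits$start[k], hits$end[k]), ref))
    }
    cls <- classify_sod(arch[i, ], profs)
    rows[[id]] <- data.frame(protein_id = id, group = cls$group,
                             rationale = cls$rationale,
                             stringsAsFactors = FALSE)
    prow[[id]] <- do.call(rbind, lapply(seq_along(profs), function(k) {
      p <- profs[[k]]
      data.frame(protein_id = id, domain_index = k,
                 n_cu = if (!is.null(p$n_cu)) p$n_cu else NA_integer_,
                 n_zn = if (!is.null(p$n_zn)) p$n_zn else NA_integer_,
                 n_total = p$n_total,
                 domain_group = cls$per_domain_groups[k],
                 stringsAsFactors = FALSE)
    }))
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(protein_id = character(), group = character(),
                      rationale = character())
  rownames(out) <- NULL
  attr(out, "profiles") <- do.call(rbind, prow)
  out
}

#' Confusion summary of classification against generator truth
#'
#' @param truth `data.frame` with `entity_id` and `planted_group`.
#' @param calls `data.frame` with `protein_id` and `group` (as from
#'   [classify_proteome()]).
#' @return A list with the confusion `table` (planted x called) and a
#'   per-group `data.frame` of `precision` and `recall`.
#' @export
recover_knockouts <- function(truth, calls) {
  missing <- setdiff(truth$entity_id, calls$protein_id)
  if (length(missing) > 0)
    stop("truth ids absent from calls: ", paste(missing, collapse = ", "))
  called <- calls$group[match(truth$entity_id, calls$protein_id)]
  groups <- sort(unique(c(truth$planted_group, called)))
  tab <- table(factor(truth$planted_group, groups), factor(called, groups))
  per <- data.frame(group = groups,
                    precision = vapply(groups, function(g) {
                      d <- sum(tab[, g]); if (d == 0) NA_real_ else tab[g, g] / d
                    }, numeric(1)),
                    recall = vapply(groups, function(g) {
                      d <- sum(tab[g, ]); if (d == 0) NA_real_ else tab[g, g] / d
                    }, numeric(1)))
  rownames(per) <- NULL
  list(table = tab, per_group = per)
}
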