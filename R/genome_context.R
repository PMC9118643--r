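# Duplicated gene pairs, tandem arrays and collinear blocks from gene
# coordinates plus pairwise protein alignment.
#
# Duplication follows the 70/70 rule: aligned coverage of the longer
# sequence above dup_coverage AND aligned-column identity above
# dup_identity (both strict).  "Similarity" is implemented as column
# identity over aligned columns (gaps excluded); similarity_mode =
# "positive" switches to the BLOSUM62-positive fraction.

#' Evaluate all protein pairs under the 70/70 duplication rule
#'
#' Every unordered pair is aligned globally (BLOSUM62, 10/0.5);
#' `coverage` is the number of aligned columns (both residues) divided
#' by the longer sequence length, `identity` the identical fraction of
#' aligned columns.
#'
#' @param proteins An `AAStringSet` or named character vector.
#' @param loci Locus `data.frame`; every protein id must appear in
#'   `loci$gene_id`.
#' @param config A [sod_config()].
#' @return A `data.frame`: `gene_a`, `gene_b`, `coverage`, `identity`,
#'   `similarity` (per `similarity_mode`), `is_duplicate`.
#' @export
duplicate_pairs <- function(proteins, loci, config = sod_config()) {
  prot <- as_protein_set(proteins)
  missing <- setdiff(names(prot), loci$gene_id)
  if (length(missing) > 0)
    stop("proteins without a locus: ", paste(missing, collapse = ", "))
  ids <- names(prot)
  if (length(ids) < 2)
    return(data.frame(gene_a = character(), gene_b = character(),
                      coverage = numeric(), identity = numeric(),
                      similarity = numeric(), is_duplicate = logical()))
  pairs <- combn(ids, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    al <- global_align(prot[[a]], prot[[b]])
    st <- aln_column_stats(al)
    coverage <- st$n_aligned / max(nchar(prot[[a]]), nchar(prot[[b]]))
    sim <- if (config$similarity_mode == "positive") st$positive else st$identity
    data.frame(gene_a = a, gene_b = b, coverage = coverage,
               identity = st$identity, similarity = sim,
               is_duplicate = coverage > config$dup_coverage &
                 sim > config$dup_identity,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cluster duplicate pairs into tandem arrays
#'
#' Builds a graph whose edges are duplicate pairs on the same
#' chromosome separated by at most `tandem_max_intervening` genes (by
#' rank); connected components whose genomic span does not exceed
#' `tandem_window_bp` are tandem arrays of size >= 2.
#'
#' @param dup_pairs Output of [duplicate_pairs()].
#' @param loci Ranked locus `data.frame`.
#' @param config A [sod_config()].
#' @return A `data.frame`: `array_id`, `chrom`, `member_gene_ids`
#'   (comma-joined in rank order), `n_members`, `span_bp`.
#' @export
tandem_arrays <- function(dup_pairs, loci, config = sod_config()) {
  empty <- data.frame(array_id = character(), chrom = character(),
                      member_gene_ids = character(), n_members = integer(),
                      span_bp = integer())
  dp <- dup_pairs[dup_pairs$is_duplicate, , drop = FALSE]
  if (nrow(dp) == 0) return(empty)
  li <- loci[match(dp$gene_a, loci$gene_id), ]
  lj <- loci[match(dp$gene_b, loci$gene_id), ]
  same <- li$chrom == lj$chrom
  interv <- abs(li$rank - lj$rank) - 1L
  edge <- same & interv <= config$tandem_max_intervening
  dp <- dp[edge, , drop = FALSE]
  if (nrow(dp) == 0) return(empty)
  g <- igraph::graph_from_data_frame(dp[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  rows <- list()
  for (cid in seq_len(comp$no)) {
    members <- names(comp$membership)[comp$membership == cid]
    ml <- loci[match(members, loci$gene_id), ]
    span <- max(ml$end) - min(ml$start) + 1L
    if (span > config$tandem_window_bp) next
    members <- members[order(ml$rank)]
    rows[[length(rows) + 1L]] <- data.frame(
      array_id = sprintf("%s_array_%d", ml$chrom[1], length(rows) + 1L),
      chrom = ml$chrom[1],
      member_gene_ids = paste(members, collapse = ","),
      n_members = length(members), span_bp = span,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty)
  do.call(rbind, rows)
}

# longest strictly-monotone chain (increasing ra; rb increasing when
# orientation "same", decreasing when "inverted"); O(n^2) DP
.longest_chain <- function(ra, rb, orientation) {
  n <- length(ra)
  if (orientation == "inverted") rb <- -rb
  best <- rep(1L, n); prev <- rep(0L, n)
  ord <- order(ra, rb)
  ra <- ra[ord]; rb <- rb[ord]
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (ra[j] < ra[i] && rb[j] < rb[i] && best[j] + 1L > best[i]) {
        best[i] <- best[j] + 1L
        prev[i] <- j
      }
    }
  }
  i <- which.max(best)
  chain <- integer(0)
  while (i > 0) { chain <- c(i, chain); i <- prev[i] }
  ord[chain]
}

#' Detect collinear blocks between two genomes
#'
#' For each chromosome pair, repeatedly extracts the longest
#' strictly-monotone chain of homologous anchor pairs (by gene rank on
#' both chromosomes; both orientations tried), greedily and without
#' anchor reuse, keeping chains of at least `min_block` anchors.
#'
#' @param homolog_pairs `data.frame` with `gene_a`, `gene_b` (ids in
#'   `loci_a` and `loci_b` respectively).
#' @param loci_a,loci_b Ranked locus tables of the two genomes.
#' @param min_block Minimum anchors per block (default 3; small
#'   fixture genomes warrant less than the classical 5).
#' @return A `data.frame`: `block_id`, `chrom_a`, `chrom_b`,
#'   `orientation` (`same`/`inverted`), `n_anchors`, `anchors`
#'   (comma-joined `gene_a|gene_b` in chain order).
#' @export
collinear_blocks <- function(homolog_pairs, loci_a, loci_b, min_block = 3L) {
  empty <- data.frame(block_id = character(), chrom_a = character(),
                      chrom_b = character(), orientation = character(),
                      n_anchors = integer(), anchors = character())
  if (nrow(homolog_pairs) == 0) return(empty)
  hp <- homolog_pairs
  ia <- match(hp$gene_a, loci_a$gene_id)
  ib <- match(hp$gene_b, loci_b$gene_id)
  if (anyNA(ia) || anyNA(ib)) stop("homolog pair gene absent from loci")
  hp$chrom_a <- loci_a$chrom[ia]; hp$rank_a <- loci_a$rank[ia]
  hp$chrom_b <- loci_b$chrom[ib]; hp$rank_b <- loci_b$rank[ib]
  rows <- list()
  for (key in unique(paste(hp$chrom_a, hp$chrom_b))) {
    sub <- hp[paste(hp$chrom_a, hp$chrom_b) == key, , drop = FALSE]
    used <- rep(FALSE, nrow(sub))
    repeat {
      avail <- which(!used)
      if (length(avail) < min_block) break
      ch_same <- .longest_chain(sub$rank_a[avail], sub$rank_b[avail], "same")
      ch_inv <- .longest_chain(sub$rank_a[avail], sub$rank_b[avail], "inverted")
      if (length(ch_same) >= length(ch_inv)) {
        chain <- avail[ch_same]; orientation <- "same"
      } else {
        chain <- avail[ch_inv]; orientation <- "inverted"
      }
      if (length(chain) < min_block) break
      used[chain] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(
        block_id = sprintf("block_%d", length(rows) + 1L),
        chrom_a = sub$chrom_a[1], chrom_b = sub$chrom_b[1],
        orientation = orientation, n_anchors = length(chain),
        anchors = paste(sprintf("%s|%s", sub$gene_a[chain],
                                sub$gene_b[chain]), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty)
  do.call(rbind, rows)
}
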