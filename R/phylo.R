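# Distance-based phylogeny with bootstrap support and clade cutting.
#
# Tree building is neighbor-joining (ape::nj) on Poisson-corrected
# p-distances from global alignments.  This is a deliberate desk-scale
# stand-in for maximum-likelihood inference: clade labels are
# qualitative, and only properties NJ guarantees (exactness on additive
# distances, reproducible supports) are contract-bound.

#' Poisson-corrected protein distance
#'
#' Global alignment of the two sequences; `d = -ln(max(identity,
#' floor))` with identity taken over aligned columns (gaps excluded).
#'
#' @param a,b Amino-acid strings.
#' @param floor Lower bound on identity before the log (default 1e-3),
#'   avoiding infinite distances.
#' @return Non-negative distance; 0 for identical sequences.
#' @export
protein_distance <- function(a, b, floor = 1e-3) {
  st <- aln_column_stats(global_align(a, b))
  if (st$n_aligned == 0) stop("degenerate alignment: no aligned columns")
  -log(max(st$identity, floor))
}

#' All-pairs distance matrix
#'
#' @param proteins An `AAStringSet` or named character vector (>= 2).
#' @param floor Passed to [protein_distance()].
#' @return Symmetric distance matrix with zero diagonal.  Triangle
#'   violations are tolerated (NJ handles them) but reported via the
#'   `triangle_violations` attribute.
#' @export
distance_matrix <- function(proteins, floor = 1e-3) {
  prot <- as_protein_set(proteins)
  ids <- names(prot)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- protein_distance(prot[[i]], prot[[j]], floor)
  }
  viol <- 0L
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n))
    if (d[i, j] > d[i, k] + d[k, j] + 1e-9) viol <- viol + 1L
  attr(d, "triangle_violations") <- viol
  d
}

#' Neighbor-joining tree
#'
#' Canonical NJ via [ape::nj()]; on additive distances it reconstructs
#' the generating topology and branch lengths exactly.
#'
#' @param d Symmetric distance matrix (>= 3 taxa).
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa")
  ape::nj(d)
}

#' Reference-anchored multiple alignment
#'
#' Aligns every sequence globally to an anchor (the longest sequence by
#' default) and stacks the columns of the anchor, dropping insertions
#' relative to it.  A simple deterministic multiple alignment adequate
#' for column-resampling bootstrap on homologous families; positions
#' inserted relative to the anchor are not represented.
#'
#' @param proteins An `AAStringSet` or named character vector.
#' @param anchor Optional id of the anchor sequence.
#' @return Character matrix (taxa x anchor columns, gaps as `-`).
#' @export
align_family <- function(proteins, anchor = NULL) {
  prot <- as_protein_set(proteins)
  if (is.null(anchor)) anchor <- names(prot)[which.max(nchar(prot))]
  ref <- prot[[anchor]]
  L <- nchar(ref)
  mat <- matrix("-", length(prot), L, dimnames = list(names(prot), NULL))
  for (id in names(prot)) {
    if (id == anchor) { mat[id, ] <- strsplit(ref, "")[[1]]; next }
    al <- global_align(prot[[id]], ref)
    q <- strsplit(al$q_aln, "")[[1]]
    t <- strsplit(al$t_aln, "")[[1]]
    refpos <- al$t_start - 1L + cumsum(t != "-")
    keep <- t != "-"
    mat[id, refpos[keep]] <- q[keep]
  }
  mat
}

# distances from alignment columns; pairs share the columns where both
# are residues
dist_from_alignment <- function(mat, floor = 1e-3) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    both <- mat[i, ] != "-" & mat[j, ] != "-"
    ident <- if (sum(both) == 0) floor else mean(mat[i, both] == mat[j, both])
    d[i, j] <- d[j, i] <- -log(max(ident, floor))
  }
  d
}

# NJ tree straight from an alignment matrix (bootstrap workhorse)
tree_from_alignment <- function(mat, floor = 1e-3) {
  nj_tree(dist_from_alignment(mat, floor))
}

#' Bootstrap supports by column resampling
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree
#' per replicate, and records for every internal edge of the base tree
#' the percentage of replicates containing its bipartition
#' (via [ape::boot.phylo()]).
#'
#' @param mat Alignment matrix from [align_family()].
#' @param n_reps Number of replicates (>= 1).
#' @param seed RNG seed; same seed, same supports.
#' @param floor Identity floor for distances.
#' @return The base `phylo` tree with `node.label` set to integer
#'   percent supports (root label empty).
#' @export
bootstrap_support <- function(mat, n_reps = 100L, seed = 1L, floor = 1e-3) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  base <- tree_from_alignment(mat, floor)
  set.seed(seed)
  counts <- ape::boot.phylo(base, mat,
                            function(m) tree_from_alignment(m, floor),
                            B = n_reps, rooted = FALSE, quiet = TRUE)
  supports <- round(100 * counts / n_reps)
  base$node.label <- as.character(supports)
  base$node.label[1] <- ""   # root of the unrooted representation
  base
}

#' Cut a supported tree into clades
#'
#' Maximal subtrees whose subtending edge has support at or above the
#' threshold become clades; every remaining taxon is a singleton clade.
#'
#' @param tree A `phylo` with `node.label` percent supports.
#' @param min_support Support threshold in `[0, 100]`; values above 100
#'   force all singletons.
#' @return Named character vector mapping taxon to clade id
#'   (`"clade_1"`, ... for multi-member clades, `"singleton_<taxon>"`
#'   otherwise).
#' @export
cut_clades <- function(tree, min_support = 50) {
  ntip <- length(tree$tip.label)
  support_of <- function(node) {
    lab <- tree$node.label[node - ntip]
    if (is.na(lab) || lab == "") -Inf else as.numeric(lab)
  }
  children <- split(tree$edge[, 2], tree$edge[, 1])
  tips_under <- function(node) {
    if (node <= ntip) return(node)
    unlist(lapply(children[[as.character(node)]], tips_under))
  }
  clades <- list()
  walk <- function(node, root) {
    if (node <= ntip) return(invisible())
    if (!root && support_of(node) >= min_support) {
      clades[[length(clades) + 1L]] <<- tree$tip.label[tips_under(node)]
      return(invisible())
    }
    for (ch in children[[as.character(node)]]) walk(ch, FALSE)
  }
  walk(ntip + 1L, TRUE)
  out <- setNames(rep(NA_character_, ntip), tree$tip.label)
  for (ci in seq_along(clades)) out[clades[[ci]]] <- sprintf("clade_%d", ci)
  single <- is.na(out)
  out[single] <- paste0("singleton_", names(out)[single])
  out
}
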