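# Synthetic-data generators with machine-readable truth tables.
#
# Generators draw from the embedded references: group-defining ligand
# knockouts are ligand -> Ala (chemically inert, alignment-stable);
# background substitutions avoid ligand columns and are drawn from
# BLOSUM62-conditional substitution probabilities so divergence stays
# alignable.  Every generated entity carries exactly one truth row and
# regeneration from (seed, params) is byte-identical.

.sod_groups <- c("MnSOD", "CuZn_active", "Cu_only", "Zn_only", "metal_free")

# substitution distribution p(b | a) proportional to 2^(S(a,b)/2), b != a
.blosum_sub_probs <- function() {
  if (is.null(the_cache$subprobs)) {
    m <- sod_submat()[.aa_letters, .aa_letters]
    p <- 2^(m / 2)
    diag(p) <- 0
    the_cache$subprobs <- sweep(p, 1, rowSums(p), "/")
  }
  the_cache$subprobs
}

mutate_background <- function(seq, rate, protect = integer(0)) {
  ch <- strsplit(seq, "")[[1]]
  editable <- setdiff(which(ch %in% .aa_letters), protect)
  hit <- editable[runif(length(editable)) < rate]
  probs <- .blosum_sub_probs()
  for (i in hit) ch[i] <- sample(.aa_letters, 1, prob = probs[ch[i], ])
  paste(ch, collapse = "")
}

knockout_positions <- function(group, ref) {
  switch(group,
    CuZn_active = integer(0),
    Cu_only = ref$zn$positions,
    Zn_only = ref$cu$positions,
    metal_free = c(ref$cu$positions, ref$zn$positions),
    MnSOD = integer(0))
}

#' Generate a synthetic SOD protein family with planted groups
#'
#' Starts from the embedded Cu/Zn and Fe/Mn templates.  Each of the
#' five functional groups receives `n_per_group` proteins: the
#' group-defining ligand positions are mutated to Ala and background
#' substitutions are applied everywhere else at `background_mut_rate`.
#' Cu/Zn-family members can be emitted as concatemers of
#' `domain_copies` domain copies (multi-domain SODs).
#'
#' @param n_per_group Proteins per group.
#' @param background_mut_rate Per-site substitution rate in `[0, 0.3]`.
#' @param seed RNG seed.
#' @param groups Subset of the five group labels (default all).
#' @param domain_copies Number of concatenated domain copies for
#'   Cu/Zn-family proteins (1, 2 or 4).
#' @return A list with `proteins` (`AAStringSet`) and `truth`
#'   (`data.frame`: `entity_id`, `planted_group`, `planted_knockouts`,
#'   `n_domains`, `seed`).
#' @export
make_protein_family <- function(n_per_group = 10L, background_mut_rate = 0.05,
                                seed = 1L, groups = .sod_groups,
                                domain_copies = 1L) {
  if (background_mut_rate < 0 || background_mut_rate > 0.3)
    stop("background_mut_rate must be in [0, 0.3]")
  stopifnot(all(groups %in% .sod_groups), domain_copies %in% c(1L, 2L, 4L))
  set.seed(seed)
  cuzn <- ligand_reference("CuZn")
  mnfe <- ligand_reference("MnFe")
  seqs <- character(0); truth <- list()
  for (g in groups) {
    ref <- if (g == "MnSOD") mnfe else cuzn
    protect <- ligand_positions(ref)
    ko <- knockout_positions(g, ref)
    for (i in seq_len(n_per_group)) {
      tmpl <- strsplit(ref$ref_seq, "")[[1]]
      tmpl[ko] <- "A"
      base <- paste(tmpl, collapse = "")
      copies <- if (g == "MnSOD") 1L else domain_copies
      dom <- vapply(seq_len(copies), function(.)
        mutate_background(base, background_mut_rate, protect), character(1))
      id <- sprintf("%s_%02d", tolower(g), i)
      seqs[id] <- paste(dom, collapse = "")
      truth[[id]] <- data.frame(
        entity_id = id, planted_group = g,
        planted_knockouts = paste(ko, collapse = ","),
        n_domains = copies, seed = seed, stringsAsFactors = FALSE)
    }
  }
  list(proteins = AAStringSet(seqs),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Generate a multi-domain Cu/Zn concatemer
#'
#' Concatenates `n_copies` independently mutated copies of the Cu/Zn
#' reference domain (ligand columns protected).
#'
#' @param n_copies Number of domain copies.
#' @param mut_rate Background substitution rate.
#' @param seed RNG seed.
#' @return A single amino-acid string.
#' @export
make_domain_concatemer <- function(n_copies = 4L, mut_rate = 0.15, seed = 7L) {
  set.seed(seed)
  ref <- ligand_reference("CuZn")
  protect <- ligand_positions(ref)
  paste(vapply(seq_len(n_copies), function(.)
    mutate_background(ref$ref_seq, mut_rate, protect), character(1)),
    collapse = "")
}

random_dna <- function(n) paste(sample(.dna_letters, n, TRUE), collapse = "")

#' Generate a toy genome with planted tandem arrays and decoys
#'
#' Genes are laid out left to right on one chromosome: each array
#' contributes `size` homologous genes (low-divergence copies of the
#' Cu/Zn template) separated by `spacing_bp` and by `intervening` decoy
#' genes; remaining decoys (shuffled-composition non-homologs) follow at
#' `decoy_gap_bp` intervals, so they never satisfy the tandem window.
#' Optionally a second chromosome carries a shared ordered subset of the
#' genes for collinearity tests, and a promoter motif can be planted
#' upstream of every gene.
#'
#' @param arrays List of array specs, each
#'   `list(size =, spacing_bp =, intervening =)`.
#' @param decoys Number of trailing decoy genes.
#' @param collinear_partner Emit a partner chromosome (`"chrB"`) with
#'   `shared_genes` genes in the same (or shuffled) order; homologs are
#'   exact sequence copies with ids suffixed `"_b"`.
#' @param shared_genes Number of genes shared with the partner.
#' @param shuffle_partner Shuffle the partner gene order (for negative
#'   collinearity tests).
#' @param gene_len Gene length in bp.
#' @param decoy_gap_bp Intergenic gap between decoy genes.
#' @param array_mut_rate Divergence between array members.
#' @param promoter_motif Optional `list(consensus =, offset =)`: the
#'   consensus is written `offset` bp upstream of every gene 5' end.
#' @param seed RNG seed.
#' @return A list: `genome` (`DNAStringSet`), `loci`, `proteins`
#'   (`AAStringSet`, one per gene), `homolog_pairs`
#'   (`data.frame(gene_a, gene_b)` when a partner exists), `truth`
#'   (per-gene `data.frame`: `entity_id`, `planted_array_id`,
#'   `is_decoy`, `planted_site_start` when a motif was planted).
#' @export
make_genome <- function(arrays = list(list(size = 3L, spacing_bp = 10000L,
                                           intervening = 0L)),
                        decoys = 10L, collinear_partner = FALSE,
                        shared_genes = 8L, shuffle_partner = FALSE,
                        gene_len = 900L, decoy_gap_bp = 150000L,
                        array_mut_rate = 0.03, promoter_motif = NULL,
                        seed = 1L) {
  if (any(vapply(arrays, function(a) a$size < 2L, logical(1))))
    stop("array size must be >= 2")
  set.seed(seed)
  ref <- ligand_reference("CuZn")
  protect <- ligand_positions(ref)
  tmpl_ch <- strsplit(ref$ref_seq, "")[[1]]

  genes <- list()  # ordered along the chromosome
  decoy_pool <- decoys
  decoy_i <- 0L
  new_decoy <- function() {
    decoy_i <<- decoy_i + 1L
    list(id = sprintf("decoy_%02d", decoy_i),
         prot = paste(sample(tmpl_ch), collapse = ""),
         array = NA_character_, gap = NA_integer_)
  }
  for (ai in seq_along(arrays)) {
    sp <- arrays[[ai]]
    aid <- sprintf("array_%d", ai)
    for (m in seq_len(sp$size)) {
      genes[[length(genes) + 1L]] <- list(
        id = sprintf("%s_g%d", aid, m),
        prot = mutate_background(ref$ref_seq, array_mut_rate, protect),
        array = aid, gap = if (m == 1L) NA_integer_ else sp$spacing_bp)
      if (m < sp$size && sp$intervening > 0L) {
        for (d in seq_len(sp$intervening)) {
          if (decoy_pool <= 0L) stop("not enough decoys for intervening slots")
          dec <- new_decoy(); dec$gap <- sp$spacing_bp
          genes[[length(genes) + 1L]] <- dec
          decoy_pool <- decoy_pool - 1L
        }
      }
    }
  }
  while (decoy_pool > 0L) {
    dec <- new_decoy(); dec$gap <- decoy_gap_bp
    genes[[length(genes) + 1L]] <- dec
    decoy_pool <- decoy_pool - 1L
  }

  build_chrom <- function(gene_list, chrom) {
    pos <- 5000L
    loci <- list(); pieces <- character(0); cursor <- 1L
    sites <- setNames(rep(NA_integer_, length(gene_list)),
                      vapply(gene_list, `[[`, character(1), "id"))
    chrom_seq_len <- 0L
    for (gi in seq_along(gene_list)) {
      g <- gene_list[[gi]]
      if (gi > 1L) pos <- pos + if (is.na(g$gap)) decoy_gap_bp else g$gap
      loci[[gi]] <- data.frame(gene_id = g$id, chrom = chrom,
                               start = pos, end = pos + gene_len - 1L,
                               strand = "+", stringsAsFactors = FALSE)
      pos <- pos + gene_len
    }
    loci <- do.call(rbind, loci)
    total <- max(loci$end) + 5000L
    seq <- sample(.dna_letters, total, TRUE)
    if (!is.null(promoter_motif)) {
      cons <- strsplit(toupper(promoter_motif$consensus), "")[[1]]
      for (gi in seq_len(nrow(loci))) {
        s <- loci$start[gi] - promoter_motif$offset
        if (s >= 1L) {
          seq[s:(s + length(cons) - 1L)] <- cons
          sites[loci$gene_id[gi]] <- s
        }
      }
    }
    list(seq = paste(seq, collapse = ""), loci = loci, sites = sites)
  }

  chrA <- build_chrom(genes, "chrA")
  genome <- c(chrA = chrA$seq)
  loci <- chrA$loci
  proteins <- setNames(vapply(genes, `[[`, character(1), "prot"),
                       vapply(genes, `[[`, character(1), "id"))
  homolog_pairs <- NULL
  sites <- chrA$sites
  if (collinear_partner) {
    idx <- seq_len(min(shared_genes, length(genes)))
    partner <- genes[idx]
    if (shuffle_partner) partner <- partner[sample(length(partner))]
    partner <- lapply(partner, function(g) {
      g2 <- g; g2$id <- paste0(g$id, "_b"); g2$gap <- 20000L; g2
    })
    chrB <- build_chrom(partner, "chrB")
    genome <- c(genome, chrB = chrB$seq)
    loci <- rbind(loci, chrB$loci)
    proteins <- c(proteins,
                  setNames(vapply(partner, `[[`, character(1), "prot"),
                           vapply(partner, `[[`, character(1), "id")))
    homolog_pairs <- data.frame(
      gene_a = vapply(genes[idx], `[[`, character(1), "id"),
      gene_b = paste0(vapply(genes[idx], `[[`, character(1), "id"), "_b"),
      stringsAsFactors = FALSE)
    sites <- c(sites, chrB$sites)
  }
  loci <- rank_loci(loci)
  truth <- data.frame(
    entity_id = vapply(genes, `[[`, character(1), "id"),
    planted_array_id = vapply(genes, `[[`, character(1), "array"),
    is_decoy = grepl("^decoy", vapply(genes, `[[`, character(1), "id")),
    seed = seed, stringsAsFactors = FALSE)
  if (!is.null(promoter_motif))
    truth$planted_site_start <- unname(sites[truth$entity_id])
  list(genome = DNAStringSet(genome), loci = loci,
       proteins = AAStringSet(proteins), homolog_pairs = homolog_pairs,
       truth = truth)
}

#' Generate a count matrix with planted condition effects
#'
#' Negative-binomial counts: per-gene baselines are log-normal, means
#' are baseline x planted fold x a log-normal per-sample library factor,
#' dispersion is constant.
#'
#' @param n_genes Number of genes.
#' @param conditions Condition labels; the first is the control.
#' @param n_rep Replicates per condition (>= 2).
#' @param planted_fold Optional `data.frame(gene_id, condition, fold)`.
#' @param dispersion NB dispersion (1/size); variance =
#'   `mu + dispersion * mu^2`.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline
#'   parameters.
#' @param libsize_sdlog Spread of the per-sample library factor.
#' @param seed RNG seed.
#' @return A list: `em` (an [expression_matrix()]), `truth`
#'   (`data.frame`: `entity_id`, `condition`, `planted_fold`).
#' @export
make_counts <- function(n_genes = 200L,
                        conditions = c("control", "treated"),
                        n_rep = 3L, planted_fold = NULL,
                        dispersion = 0.05,
                        baseline_meanlog = log(100), baseline_sdlog = 1,
                        libsize_sdlog = 0.15, seed = 1L) {
  if (n_rep < 2) stop("need at least 2 replicates per condition")
  if (dispersion <= 0) stop("dispersion must be positive")
  set.seed(seed)
  gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
  samples <- as.vector(t(outer(conditions, seq_len(n_rep),
                               function(c, r) paste0(c, "_", r))))
  design <- data.frame(sample = samples,
                       condition = rep(conditions, each = n_rep),
                       stringsAsFactors = FALSE)
  baseline <- rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
  lens <- sample(500:3000, n_genes, TRUE)
  libfac <- rlnorm(length(samples), 0, libsize_sdlog)
  fold <- matrix(1, n_genes, length(conditions),
                 dimnames = list(gene_ids, conditions))
  if (!is.null(planted_fold)) {
    for (r in seq_len(nrow(planted_fold)))
      fold[planted_fold$gene_id[r], planted_fold$condition[r]] <-
        planted_fold$fold[r]
  }
  mu <- baseline * fold[, design$condition, drop = FALSE]
  mu <- sweep(mu, 2, libfac, "*")
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   n_genes, length(samples),
                   dimnames = list(gene_ids, samples))
  truth <- do.call(rbind, lapply(conditions, function(cc)
    data.frame(entity_id = gene_ids, condition = cc,
               planted_fold = fold[, cc], stringsAsFactors = FALSE)))
  rownames(truth) <- NULL
  list(em = expression_matrix(counts, lens, design), truth = truth)
}
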