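toy_loci <- function(ids, chrom = "chr1", start0 = 1000L, gap = 5000L,
                     len = 900L) {
  start <- start0 + (seq_along(ids) - 1L) * gap
  rank_loci(data.frame(gene_id = ids, chrom = chrom, start = start,
                       end = start + len - 1L, strand = "+"))
}

test_that("the 70/70 duplication rule behaves at its boundaries", {
  set.seed(17)
  s <- random_protein(200)
  loci <- toy_loci(c("a", "b", "frag", "big"))
  big <- random_protein(400)
  prots <- c(a = s, b = s, frag = substr(big, 50, 199), big = big)
  dp <- duplicate_pairs(prots, loci)
  ab <- dp[dp$gene_a == "a" & dp$gene_b == "b", ]
  expect_equal(ab$coverage, 1)
  expect_equal(ab$identity, 1)
  expect_true(ab$is_duplicate)
  # 150-aa identical fragment of a 400-aa gene: coverage 0.375, excluded
  fb <- dp[dp$gene_a == "frag" & dp$gene_b == "big", ]
  expect_equal(fb$coverage, 150 / 400)
  expect_equal(fb$identity, 1)
  expect_false(fb$is_duplicate)
  # symmetry: reversing the input order flips nothing
  dp2 <- duplicate_pairs(prots[c(2, 1, 4, 3)], loci)
  m <- merge(dp, dp2, by = c("gene_a", "gene_b"))
  expect_equal(m$is_duplicate.x, m$is_duplicate.y)
  expect_equal(m$identity.x, m$identity.y)

  expect_error(duplicate_pairs(c(orphan = s), loci), "orphan")
})

test_that("a diverged pair engineered below 70% identity is excluded", {
  set.seed(17)
  tmpl <- ligand_reference("CuZn")$ref_seq
  a <- sodscan:::mutate_background(tmpl, 0.25)
  b <- sodscan:::mutate_background(tmpl, 0.25)
  loci <- toy_loci(c("a", "b"))
  dp <- duplicate_pairs(c(a = a, b = b), loci)
  expect_lt(dp$identity, 0.7)
  expect_false(dp$is_duplicate)
})

test_that("tandem rule: intervening-gene and window clauses both bind", {
  s <- random_protein(150)
  # three adjacent duplicates within 30 kb: one array of 3
  loci <- toy_loci(c("g1", "g2", "g3"), gap = 10000L)
  dp <- duplicate_pairs(c(g1 = s, g2 = s, g3 = s), loci)
  arr <- tandem_arrays(dp, loci)
  expect_equal(nrow(arr), 1L)
  expect_equal(arr$n_members, 3L)
  expect_equal(arr$member_gene_ids, "g1,g2,g3")
  expect_lte(arr$span_bp, 100000L)

  # 6 intervening genes: boundary 5 vs 6 excludes the pair
  ids <- c("d1", paste0("f", 1:6), "d2")
  loci6 <- toy_loci(ids, gap = 2000L)
  prots6 <- setNames(c(s, vapply(1:6, function(i) random_protein(150),
                                 character(1)), s), ids)
  dp6 <- duplicate_pairs(prots6, loci6)
  expect_true(any(dp6$is_duplicate))
  expect_equal(nrow(tandem_arrays(dp6, loci6)), 0L)
  # with 5 intervening genes the same pair forms an array
  loci5 <- toy_loci(ids[-2], gap = 2000L)
  dp5 <- duplicate_pairs(prots6[ids[-2]], loci5)
  expect_equal(nrow(tandem_arrays(dp5, loci5)), 1L)

  # 120 kb apart with 2 intervening genes: window clause excludes it
  idsw <- c("w1", "x1", "x2", "w2")
  lociw <- toy_loci(idsw, gap = 40000L)
  protsw <- setNames(c(s, random_protein(150), random_protein(150), s), idsw)
  dpw <- duplicate_pairs(protsw, lociw)
  expect_true(any(dpw$is_duplicate))
  expect_equal(nrow(tandem_arrays(dpw, lociw)), 0L)
})

test_that("every tandem member participates in a qualifying duplicate pair", {
  g <- make_genome(arrays = list(list(size = 3, spacing_bp = 10000,
                                      intervening = 1)),
                   decoys = 8, seed = 23)
  dp <- duplicate_pairs(g$proteins, g$loci)
  arr <- tandem_arrays(dp, g$loci)
  expect_equal(nrow(arr), 1L)
  members <- strsplit(arr$member_gene_ids, ",")[[1]]
  expect_setequal(members,
                  g$truth$entity_id[g$truth$planted_array_id %in% "array_1"])
  dup <- dp[dp$is_duplicate, ]
  for (m in members)
    expect_true(m %in% c(dup$gene_a, dup$gene_b))
})

test_that("collinear blocks recover shared order, orientation and maxima", {
  g <- make_genome(arrays = list(list(size = 2, spacing_bp = 10000,
                                      intervening = 0)),
                   decoys = 8, collinear_partner = TRUE, shared_genes = 8,
                   seed = 29)
  cb <- collinear_blocks(g$homolog_pairs, g$loci, g$loci, min_block = 3)
  expect_equal(nrow(cb), 1L)
  expect_equal(cb$n_anchors, 8L)
  expect_equal(cb$orientation, "same")

  # reversed partner order: inverted orientation
  hp_rev <- g$homolog_pairs
  hp_rev$gene_b <- rev(hp_rev$gene_b)
  cb_rev <- collinear_blocks(hp_rev, g$loci, g$loci, min_block = 3)
  expect_equal(cb_rev$orientation, "inverted")
  expect_equal(cb_rev$n_anchors, 8L)
})

test_that("blocks on shuffled orders match the exhaustive chain oracle", {
  g <- make_genome(arrays = list(list(size = 2, spacing_bp = 10000,
                                      intervening = 0)),
                   decoys = 8, collinear_partner = TRUE, shared_genes = 10,
                   shuffle_partner = TRUE, seed = 19)
  la <- g$loci[g$loci$chrom == "chrA", ]
  lb <- g$loci[g$loci$chrom == "chrB", ]
  hp <- g$homolog_pairs
  ra <- la$rank[match(hp$gene_a, la$gene_id)]
  rb <- lb$rank[match(hp$gene_b, lb$gene_id)]
  cb <- collinear_blocks(hp, g$loci, g$loci, min_block = 4)
  sizes <- greedy_blocks_oracle(ra, rb, min_block = 4)
  expect_equal(nrow(cb), length(sizes))
  if (nrow(cb) > 0) {
    expect_equal(sort(cb$n_anchors, decreasing = TRUE),
                 sort(sizes, decreasing = TRUE))
    expect_equal(max(cb$n_anchors), max_chain_oracle(ra, rb))
    # maximality: no block extendable by an unused anchor
    used <- unlist(lapply(strsplit(cb$anchors, ","), function(x)
      sub("\\|.*", "", x)))
    unused <- setdiff(hp$gene_a, used)
    for (bi in seq_len(nrow(cb))) {
      anchors <- strsplit(cb$anchors[bi], ",")[[1]]
      ga <- sub("\\|.*", "", anchors)
      cra <- ra[match(ga, hp$gene_a)]
      crb <- rb[match(ga, hp$gene_a)]
      dir <- if (cb$orientation[bi] == "same") 1 else -1
      for (u in unused) {
        ua <- ra[match(u, hp$gene_a)]; ub <- rb[match(u, hp$gene_a)]
        ext <- c(cra, ua); exb <- c(crb, ub)
        o <- order(ext)
        mono <- all(diff(ext[o]) > 0) && all(dir * diff(exb[o]) > 0)
        expect_false(mono)
      }
    }
  }
})
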