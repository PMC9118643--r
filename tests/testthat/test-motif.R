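test_that("PWMs from instances match a direct count-table oracle", {
  ins <- c("ACGT", "ACGA", "ACTA", "TCGA")
  model <- pwm_from_instances(ins, pseudocount = 0.1, motif_id = "m")
  # independent count construction
  letters4 <- c("A", "C", "G", "T")
  ch <- do.call(rbind, strsplit(ins, ""))
  for (j in 1:4) {
    counts <- table(factor(ch[, j], letters4)) + 0.1
    expected <- log2((counts / sum(counts)) / 0.25)
    expect_equal(unname(model$pwm[j, ]), unname(as.numeric(expected)))
  }
  expect_equal(model$alphabet, "dna")

  ident <- pwm_from_instances(rep("MKVLAG", 5), pseudocount = 0.1)
  expect_equal(ident$consensus, "MKVLAG")
  # the consensus letter scores maximal at every column
  expect_equal(apply(ident$pwm, 1, which.max),
               match(strsplit("MKVLAG", "")[[1]], colnames(ident$pwm)))

  sym <- pwm_from_instances(c("AC", "AG"), pseudocount = 0.1)
  expect_equal(unname(sym$pwm[2, "C"]), unname(sym$pwm[2, "G"]))
  expect_error(pwm_from_instances(c("AC", "ACG")), "equal lengths")
  expect_error(pwm_from_instances("AC"), "at least 2")
})

test_that("motif scanning finds planted instances and builds combination strings", {
  set.seed(77)
  m1 <- pwm_from_instances(rep("WWHHWWHH", 4), motif_id = "1")
  m2 <- pwm_from_instances(rep("CCKKCCKK", 4), motif_id = "2")
  m3 <- pwm_from_instances(rep("FFDDFFDD", 4), motif_id = "3")
  spacer <- function(n) strrep("G", n)
  seq <- paste0(spacer(5), "WWHHWWHH", spacer(6), "FFDDFFDD", spacer(4),
                "CCKKCCKK", spacer(3))
  res <- scan_motifs(seq, list(m1, m2, m3), score_fraction = 0.9)
  expect_equal(res$combination, "1-3-2")
  expect_equal(res$matches$start[res$matches$motif_id == "1"], 6L)

  expect_equal(scan_motifs(seq, list())$combination, "")
  expect_error(scan_motifs(seq, list(m1), score_fraction = 0), "score_fraction")

  # shift equivariance: prepending k background letters shifts all starts
  shifted <- scan_motifs(paste0(spacer(9), seq), list(m1, m2, m3), 0.9)
  expect_equal(shifted$matches$start, res$matches$start + 9L)
  expect_equal(shifted$combination, res$combination)
})

test_that("promoter extraction windows and strand handling are exact", {
  set.seed(13)
  contig <- random_dna_seq(10000)
  genome <- c(chr1 = contig)
  loci <- data.frame(gene_id = c("plus", "minus", "edge"),
                     chrom = "chr1",
                     start = c(3001L, 6001L, 500L),
                     end = c(4000L, 7000L, 1400L),
                     strand = c("+", "-", "+"))
  pr <- extract_promoters(genome, loci, length = 2000)
  expect_equal(pr$seq[1], substr(contig, 1001, 3000))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(contig, 7001, 9000))))
  expect_equal(pr$seq[2], rc)
  expect_false(pr$truncated[1])
  expect_true(pr$truncated[3])
  expect_equal(nchar(pr$seq[3]), 499L)
  expect_error(extract_promoters(genome,
                                 transform(loci, chrom = "chrX"), 2000),
               "absent")
})

test_that("promoter scanning counts planted sites on both strands", {
  model <- pwm_from_instances(rep("TTGACGTT", 4), motif_id = "tf1")
  site <- "TTGACGTT"
  spacer <- function(n) strrep("A", n)
  prom <- data.frame(gene_id = "g1",
                     seq = paste0(spacer(10), site, spacer(10), site,
                                  spacer(10), site, spacer(10)))
  res <- scan_promoters(prom, list(model), score_fraction = 0.95)
  expect_equal(res$counts$n_hits, 3L)

  # a palindromic site is seen once per strand
  pal_model <- pwm_from_instances(rep("GAATTC", 4), motif_id = "pal")
  pal <- data.frame(gene_id = "g2",
                    seq = paste0(spacer(12), "GAATTC", spacer(12)))
  res_pal <- scan_promoters(pal, list(pal_model), score_fraction = 0.95)
  expect_equal(res_pal$counts$n_hits, 2L)

  prot_model <- pwm_from_instances(rep("MKVLAG", 3), motif_id = "p")
  expect_error(scan_promoters(prom, list(prot_model)), "DNA")

  # family aggregation
  fam <- scan_promoters(prom, list(model), 0.95, families = c(tf1 = "bZIP"))
  expect_equal(fam$family_counts$n_hits, 3L)
  expect_equal(fam$family_counts$family, "bZIP")
})

test_that("random promoters rarely score at a stringent threshold", {
  set.seed(13)
  model <- pwm_from_instances(c("TTGACGTCAATT", "TTGACGTCAATT",
                                "TTGACGTCAATT", "TTGACGTCAATA"),
                              motif_id = "strict")
  zero_hits <- vapply(1:200, function(i) {
    prom <- data.frame(gene_id = "g", seq = random_dna_seq(500))
    sum(scan_promoters(prom, list(model), score_fraction = 0.9)$counts$n_hits)
  }, numeric(1))
  expect_gte(mean(zero_hits == 0), 0.95)
})

test_that("planted promoter sites round-trip through genome extraction", {
  g <- make_genome(arrays = list(list(size = 2, spacing_bp = 8000,
                                      intervening = 0)),
                   decoys = 3, seed = 21,
                   promoter_motif = list(consensus = "TTGACGTCAATT",
                                         offset = 500))
  pr <- extract_promoters(g$genome, g$loci, length = 2000)
  planted <- g$truth[!is.na(g$truth$planted_site_start), ]
  for (i in seq_len(nrow(planted))) {
    row <- pr[pr$gene_id == planted$entity_id[i], ]
    # site planted offset bp upstream: promoter coordinates recover it
    rel <- planted$planted_site_start[i] - row$start + 1L
    expect_equal(substr(row$seq, rel, rel + 11L), "TTGACGTCAATT")
  }
})
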