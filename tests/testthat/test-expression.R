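toy_em <- function(counts, lens = NULL, conditions = NULL,
                   library_size = NULL) {
  if (is.null(lens)) lens <- rep(1000L, nrow(counts))
  if (is.null(conditions)) conditions <- rep("c1", ncol(counts))
  design <- data.frame(sample = colnames(counts), condition = conditions)
  if (is.null(library_size)) library_size <- colSums(counts)
  expression_matrix(counts, lens, design, library_size)
}

test_that("FPKM follows the plug-in formula and its invariances", {
  m <- matrix(100L, 1, 1, dimnames = list("g", "s1"))
  em <- toy_em(m, lens = 1000L, library_size = c(s1 = 1e6))
  expect_equal(unname(fpkm(em)[1, 1]), 100)

  set.seed(9)
  counts <- matrix(rpois(60, 50), 10, 6,
                   dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  lens <- sample(500:2000, 10)
  em <- toy_em(counts, lens)
  # direct-formula oracle
  oracle <- counts * 1e9 /
    outer(lens, colSums(counts), function(l, n) l * n)
  expect_equal(fpkm(em), oracle, tolerance = 1e-9)
  # doubling counts and library sizes leaves FPKM unchanged
  em2 <- toy_em(counts * 2L, lens, library_size = 2 * colSums(counts))
  expect_equal(fpkm(em2), fpkm(em), tolerance = 1e-12)
  expect_error(fpkm(toy_em(m, library_size = c(s1 = 0))), "zero library")
})

test_that("TPM columns sum to one million and rescale FPKM", {
  m <- matrix(7L, 1, 2, dimnames = list("g", c("s1", "s2")))
  expect_equal(unname(tpm(toy_em(m))[1, ]), c(1e6, 1e6))

  set.seed(10)
  counts <- matrix(rpois(80, 30), 10, 8,
                   dimnames = list(paste0("g", 1:10), paste0("s", 1:8)))
  em <- toy_em(counts, sample(500:2000, 10))
  tp <- tpm(em)
  expect_equal(unname(colSums(tp)), rep(1e6, 8), tolerance = 1e-6)
  # TPM equals FPKM rescaled per sample to 1e6
  fp <- fpkm(em)
  rescaled <- sweep(fp, 2, colSums(fp), "/") * 1e6
  expect_equal(tp, rescaled, tolerance = 1e-9)

  zero <- counts; zero[, 3] <- 0L
  expect_error(tpm(toy_em(zero)), "s3")
})

test_that("heat values and fold changes follow their closed forms", {
  expect_equal(heat_values(matrix(c(0, 1, 1023))), matrix(c(0, 1, 10)),
               tolerance = 1e-3)
  expect_error(heat_values(matrix(-1)), "negative")

  ab <- matrix(c(1, 1, 1, 3, 3, 3), 1, dimnames = list("g", paste0("s", 1:6)))
  design <- data.frame(sample = paste0("s", 1:6),
                       condition = rep(c("control", "stress"), each = 3))
  fc <- fold_change(ab, design, "control")
  expect_equal(unname(fc["g", ]), c(1, 2))
  same <- fold_change(ab * 0 + 5, design, "control")
  expect_equal(unname(same["g", "stress"]), 1)
})

test_that("constant genes give F = 0, P = 1 and no direction", {
  ab <- matrix(5, 2, 6, dimnames = list(c("g1", "g2"), paste0("s", 1:6)))
  design <- data.frame(sample = paste0("s", 1:6),
                       condition = rep(c("a", "b", "c"), each = 2))
  calls <- anova_duncan(ab, design, control = "a")
  expect_equal(calls$f_stat, c(0, 0))
  expect_equal(calls$p_value, c(1, 1))
  expect_true(all(calls$dir.b == "none" & calls$dir.c == "none"))
  # replicate guard
  bad <- data.frame(sample = paste0("s", 1:6),
                    condition = c("a", "a", "a", "a", "a", "b"))
  expect_error(anova_duncan(ab, bad, "a"), "fewer than 2")
})

test_that("two-group Duncan calls collapse to the pooled-variance t test", {
  set.seed(41)
  n_genes <- 200
  ab <- matrix(rnorm(n_genes * 6, 8), n_genes, 6,
               dimnames = list(paste0("g", 1:n_genes), paste0("s", 1:6)))
  design <- data.frame(sample = paste0("s", 1:6),
                       condition = rep(c("control", "treat"), each = 3))
  calls <- anova_duncan(ab, design, "control", log2_transform = FALSE)
  for (g in seq_len(n_genes)) {
    tt <- t.test(ab[g, 4:6], ab[g, 1:3], var.equal = TRUE)
    expect_equal(calls$p_value[g], tt$p.value, tolerance = 1e-9)
    expected_dir <- if (tt$p.value < 0.05) {
      if (tt$estimate[1] > tt$estimate[2]) "up" else "down"
    } else "none"
    expect_equal(calls$dir.treat[g], expected_dir, info = paste("gene", g))
  }
})

test_that("Duncan letters are a valid partition display of the means", {
  set.seed(43)
  # one gene, 4 well-separated groups plus 2 close ones
  design <- data.frame(sample = paste0("s", 1:12),
                       condition = rep(c("a", "b", "c", "d"), each = 3))
  y <- c(rnorm(3, 0, 0.3), rnorm(3, 0.2, 0.3), rnorm(3, 4, 0.3),
         rnorm(3, 8, 0.3))
  ab <- matrix(y, 1, 12, dimnames = list("g", paste0("s", 1:12)))
  calls <- anova_duncan(ab, design, "a", log2_transform = FALSE)
  expect_true(calls$significant)
  letters_by_cond <- unlist(calls[1, grep("^letter\\.", names(calls))])
  names(letters_by_cond) <- sub("letter\\.", "", names(letters_by_cond))
  means <- tapply(y, design$condition, mean)
  mse <- sum((y - means[design$condition])^2) / (12 - 4)
  # conditions sharing a letter must differ by less than the span-2
  # critical range upper bound; disjoint letters by more than span-k range
  for (c1 in names(means)) for (c2 in names(means)) {
    if (c1 >= c2) next
    shared <- any(strsplit(letters_by_cond[c1], "")[[1]] %in%
                  strsplit(letters_by_cond[c2], "")[[1]])
    diffm <- abs(means[c1] - means[c2])
    r2 <- qtukey(0.95, 2, 8) * sqrt(mse / 3)
    rk <- qtukey((1 - 0.05)^(4 - 1), 4, 8) * sqrt(mse / 3)
    if (!shared) expect_gt(diffm, r2)
    if (shared) expect_lt(diffm, rk)
  }
  # a and b are close: same letter; d far from everything: unique letter
  expect_true(any(strsplit(letters_by_cond["a"], "")[[1]] %in%
                  strsplit(letters_by_cond["b"], "")[[1]]))
  expect_false(any(strsplit(letters_by_cond["d"], "")[[1]] %in%
                   unlist(strsplit(letters_by_cond[c("a", "b", "c")], ""))))
})

test_that("planted four-fold effects are recovered with high sensitivity", {
  # study condition: n = 3 per group at a count CV of about 0.2, i.e.
  # dispersion 0.04 with baselines high enough that shot noise is minor
  planted <- data.frame(gene_id = sprintf("gene_%04d", 1:10),
                        condition = "stress", fold = 4)
  mc <- make_counts(n_genes = 200, conditions = c("control", "stress"),
                    n_rep = 3, planted_fold = planted, dispersion = 0.04,
                    baseline_meanlog = log(500), baseline_sdlog = 0.5,
                    seed = 29)
  calls <- anova_duncan(tpm(mc$em), mc$em$design, "control")
  hit <- calls$dir.stress[1:10] == "up" & calls$significant[1:10]
  expect_gte(mean(hit), 0.9)
})
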