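test_that("protein distance is a Poisson-corrected identity with closed form", {
  a <- "ACDEFGHIKL"
  b <- "ACDEFGHIRV"   # 2 mismatches in 10 -> p = 0.2
  expect_equal(protein_distance(a, a), 0)
  expect_equal(protein_distance(a, b), -log(0.8), tolerance = 1e-6)
  expect_equal(protein_distance(a, b), protein_distance(b, a))
  expect_equal(round(protein_distance(a, b), 4), 0.2231)
})

test_that("neighbor joining is exact on additive distances", {
  # fixed 4-taxon tree
  tr <- ape::read.tree(text = "((t1:0.10,t2:0.20):0.05,t3:0.30,t4:0.15);")
  d <- ape::cophenetic.phylo(tr)
  est <- nj_tree(d)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(est)), 0,
               ignore_attr = TRUE)
  expect_equal(sort(est$edge.length), sort(tr$edge.length), tolerance = 1e-9)

  # 3 taxa: three-point closed form
  d3 <- matrix(c(0, 0.3, 0.5, 0.3, 0, 0.6, 0.5, 0.6, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(d3)
  lens <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(unname(lens["a"]), (0.3 + 0.5 - 0.6) / 2, tolerance = 1e-9)
  expect_equal(unname(lens["b"]), (0.3 + 0.6 - 0.5) / 2, tolerance = 1e-9)
  expect_equal(unname(lens["c"]), (0.5 + 0.6 - 0.3) / 2, tolerance = 1e-9)
  expect_error(nj_tree(d3[1:2, 1:2]), "at least 3")

  # property: 50 random 6-10 leaf trees, NJ reconstructs each exactly
  set.seed(37)
  for (i in 1:50) {
    n <- sample(6:10, 1)
    tr <- ape::rtree(n)
    est <- nj_tree(ape::cophenetic.phylo(tr))
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(est)), 0,
                 ignore_attr = TRUE, info = paste("tree", i))
  }
})

test_that("tree topology is invariant to taxon input order", {
  set.seed(39)
  prots <- setNames(vapply(1:6, function(i) random_protein(80), character(1)),
                    paste0("t", 1:6))
  # make them related: mutate one base sequence
  base <- random_protein(120)
  prots <- vapply(1:6, function(i) sodscan:::mutate_background(base, 0.05 * i),
                  character(1))
  names(prots) <- paste0("t", 1:6)
  t1 <- nj_tree(distance_matrix(prots))
  t2 <- nj_tree(distance_matrix(prots[c(4, 2, 6, 1, 3, 5)]))
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
               ignore_attr = TRUE)
})

test_that("bootstrap fully supports the split between two planted families", {
  fam <- make_protein_family(n_per_group = 5, background_mut_rate = 0.08,
                             seed = 31, groups = c("CuZn_active", "MnSOD"))
  mat <- align_family(fam$proteins)
  tree <- bootstrap_support(mat, n_reps = 100, seed = 31)
  cuzn <- fam$truth$entity_id[fam$truth$planted_group == "CuZn_active"]
  # find the internal edge whose tip set is exactly one family
  ntip <- length(tree$tip.label)
  found <- FALSE
  for (node in (ntip + 2):(ntip + tree$Nnode)) {
    tips <- tree$tip.label[unlist(ape::prop.part(tree)[node - ntip])]
    if (setequal(tips, cuzn) || setequal(tips, setdiff(tree$tip.label, cuzn))) {
      expect_equal(as.numeric(tree$node.label[node - ntip]), 100)
      found <- TRUE
    }
  }
  expect_true(found)
  # determinism: same seed, same supports
  tree2 <- bootstrap_support(mat, n_reps = 100, seed = 31)
  expect_identical(tree$node.label, tree2$node.label)
  # single replicate: supports are 0 or 100
  t1 <- bootstrap_support(mat, n_reps = 1, seed = 4)
  sup <- as.numeric(t1$node.label[-1])
  expect_true(all(sup %in% c(0, 100)))
  expect_error(bootstrap_support(mat, n_reps = 0), "n_reps")
})

test_that("clade cutting takes maximal supported subtrees", {
  # star tree: no internal edges, all singletons
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  star$node.label <- ""
  cl <- cut_clades(star, 50)
  expect_true(all(grepl("^singleton_", cl)))

  # fully supported 5-leaf caterpillar: the maximal qualifying subtree
  # under the root swallows the deepest four leaves
  cat5 <- ape::read.tree(text = "(a:1,(b:1,(c:1,(d:1,e:1)100:1)100:1)100:1);")
  cl5 <- cut_clades(cat5, 50)
  expect_equal(unname(cl5["a"]), "singleton_a")
  expect_equal(length(unique(cl5[c("b", "c", "d", "e")])), 1L)
  expect_match(unname(cl5["b"]), "^clade_")

  # impossible threshold: everything singleton
  cl101 <- cut_clades(cat5, 101)
  expect_true(all(grepl("^singleton_", cl101)))
})
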