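test_that("UPGMA reproduces hand-worked merges", {
  # two leaves at distance 2 -> root at height 1
  d2 <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- upgma(d2)
  expect_equal(sort(ape::node.depth.edgelength(t2$phylo)[1:2]), c(1, 1))

  # (A,B) merge at height 1, C joins at height 2
  d3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- upgma(d3)
  coph <- ape::cophenetic.phylo(t3$phylo)
  expect_equal(coph["A", "B"], 2)
  expect_equal(coph["A", "C"], 4)
  expect_equal(coph["B", "C"], 4)

  expect_error(upgma(matrix(c(0, 1, 2, 0), 2)), "symmetric")
  expect_error(upgma(matrix(c(0, -1, -1, 0), 2)), "non-negative")
})

test_that("UPGMA equals the naive oracle and is ultrametric", {
  set.seed(41)
  for (rep in 1:6) {
    n <- sample(4:8, 1)
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.1, 2)
    d <- d + t(d)
    dimnames(d) <- list(paste0("L", 1:n), paste0("L", 1:n))
    tr <- upgma(d)
    expect_true(ape::is.ultrametric(tr$phylo, tol = 1e-8))
    coph <- ape::cophenetic.phylo(tr$phylo)[rownames(d), colnames(d)]
    expect_equal(coph, upgma_cophenetic_oracle(d), tolerance = 1e-9)
  }
})

test_that("UPGMA reconstructs ultrametric inputs exactly", {
  for (seed in 1:8) {
    n <- 4 + (seed %% 5)
    d <- random_ultrametric(n, seed)
    tr <- upgma(d)
    coph <- ape::cophenetic.phylo(tr$phylo)[rownames(d), colnames(d)]
    expect_equal(coph, d, tolerance = 1e-9)
  }
})

test_that("Newick serialization round-trips", {
  d2 <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(to_newick(upgma(d2)), "(A:1,B:1);")

  set.seed(19)
  for (i in 1:25) {
    phy <- ape::rtree(sample(3:12, 1))
    tr <- parse_newick(ape::write.tree(phy))
    expect_true(ape::all.equal.phylo(tr$phylo, phy,
                                     use.edge.length = TRUE))
    rt <- parse_newick(to_newick(tr))
    expect_true(ape::all.equal.phylo(rt$phylo, phy,
                                     use.edge.length = TRUE))
  }

  expect_error(parse_newick("((A:1,B:1);"), "position|unclosed")
  expect_error(parse_newick("(A:1,B:1)"), "';'")
})

test_that("cluster cutting yields k monophyletic clusters", {
  d <- random_ultrametric(12, 4)
  tr <- upgma(d)
  expect_equal(unname(unique(cut_clusters(tr, 1))), 1L)
  expect_equal(sort(unname(cut_clusters(tr, 12))), 1:12)
  expect_error(cut_clusters(tr, 0), "k must be")
  expect_error(cut_clusters(tr, 13), "k must be")

  for (k in c(2, 3, 5)) {
    cl <- cut_clusters(tr, k)
    expect_equal(length(unique(cl)), k)
    # monophyly: each cluster's leaves form a complete subtree
    phy <- tr$phylo
    for (cc in unique(cl)) {
      leaves <- names(cl)[cl == cc]
      if (length(leaves) > 1) {
        mrca <- ape::getMRCA(phy, leaves)
        sub <- ape::extract.clade(phy, mrca)
        expect_setequal(sub$tip.label, leaves)
      }
    }
  }

  # the same cut works on a parsed tree without merge structure
  tr2 <- parse_newick(to_newick(tr))
  partition_sig <- function(cl)
    sort(vapply(split(names(cl), as.integer(cl)),
                function(x) paste(sort(x), collapse = ","), ""))
  for (k in c(3, 5))
    expect_equal(unname(partition_sig(cut_clusters(tr, k))),
                 unname(partition_sig(cut_clusters(tr2, k))))
})

test_that("clade and supergroup recovery on the planted tree fixture", {
  fx <- plant_paper_fixtures(seed = 2)
  tr <- upgma(fx$tree$dm)
  cl <- cut_clusters(tr, 10)
  # recovered clusters equal the planted clades (up to relabelling)
  expect_equal(length(unique(cl)), 10)
  tab <- table(cl, fx$tree$clades[names(cl)])
  expect_true(all(rowSums(tab > 0) == 1))

  sg <- supergroup_clusters(tr, cl, groups = 4)
  expect_equal(length(unique(sg)), 4)
  leaf_group <- sg[as.character(as.integer(cl))]
  tab2 <- table(leaf_group, fx$tree$supergroups[names(cl)])
  expect_true(all(rowSums(tab2 > 0) == 1))

  # groups == k puts each cluster in its own supergroup
  cl4 <- cut_clusters(tr, 4)
  expect_equal(length(unique(supergroup_clusters(tr, cl4, 4))), 4)
  expect_error(supergroup_clusters(tr, cl4, 5), "exceeds")

  # two groups form unions of adjacent clusters
  sg2 <- supergroup_clusters(tr, cl, groups = 2)
  expect_equal(length(unique(sg2)), 2)
})

test_that("cluster composition conserves counts and computes the median", {
  planted <- c(0, 0, 0.22, 0.03, 0.04, 0.04, 0.05, 0.05, 0.01, 0.04)
  size <- 100
  acc <- sprintf("A%04d", seq_len(10 * size))
  cl <- rep(1:10, each = size)
  ont <- unlist(lapply(planted, function(f)
    c(rep("D-amino acid dehydrogenase", round(f * size)),
      rep("FAD-binding oxidoreductase", size - round(f * size)))))
  rec <- make_records(acc, residues = rep("ACDE", length(acc)),
                      ontology = ont, tax_class = rep(c("a", "b"),
                                                      length.out = length(acc)))
  asg <- make_assignment(cl, acc)
  comp <- cluster_composition(asg, rec)
  expect_equal(unname(comp$focal_fraction), planted)
  expect_equal(comp$focal_median, stats::median(planted))
  expect_equal(unname(rowSums(comp$class_counts)), rep(size, 10))
  expect_equal(sum(comp$subtype_counts), length(acc))

  # single cluster, single class -> 100%
  one <- cluster_composition(make_assignment(rep(1, 4), sprintf("B%d", 1:4)),
                             make_records(sprintf("B%d", 1:4),
                                          tax_class = "a-proteobacteria"))
  expect_equal(unname(one$class_counts[1, 1]), 4)

  expect_error(cluster_composition(make_assignment(1, "nope"), rec),
               "no record")
})

test_that("representative selection covers clusters and subtypes deterministically", {
  set.seed(61)
  subtypes <- c("FAD-binding oxidoreductase", "D-amino acid dehydrogenase",
                "amino acid oxidase", "cytochrome C4", "dadA1", "Gox",
                "Dehydrogenase", "dependent oxidoreductase",
                "ketopantoate reductase", "pyridine nucleotide", "other")
  acc <- sprintf("R%04d", 1:150)
  rec <- make_records(acc, residues = rep("ACDE", 150),
                      ontology = sample(subtypes, 150, replace = TRUE))
  asg <- make_assignment(rep(1:10, 15), acc)
  sel <- select_representatives(rec, asg, n = 120, seed = 7,
                                reference = "R0001")
  expect_equal(nrow(sel), 120)
  expect_true("R0001" %in% sel$accession)
  expect_setequal(unique(asg[sel$accession]), 1:10)
  expect_setequal(unique(sel$ontology_grouped), unique(rec$ontology_grouped))

  sel2 <- select_representatives(rec, asg, n = 120, seed = 7,
                                 reference = "R0001")
  expect_identical(sel$accession, sel2$accession)
  expect_error(select_representatives(rec, asg, n = 5), "infeasible")
})
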