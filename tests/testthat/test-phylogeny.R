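test_that("p-distance and Dayhoff correction follow their definitions", {
  aln <- c(a = "AAAA", b = "AAAV")
  d <- distance_matrix(aln)
  expect_equal(d["a", "b"], 0.25)
  expect_equal(diag(d), c(a = 0, b = 0))
  dd <- distance_matrix(aln, correction = "dayhoff")
  expect_equal(dd["a", "b"], -log(1 - 0.25 - 0.2 * 0.25^2))
  expect_equal(distance_matrix(c(a = "KWGH", b = "KWGH"))["a", "b"], 0)
  expect_error(distance_matrix(c(a = "--AA", b = "GG--")), "shared")
})

test_that("p-distance matches a brute-force column-count oracle", {
  set.seed(51)
  aas <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-")
  aln <- setNames(replicate(5, paste(sample(aas, 60, replace = TRUE,
                                            prob = c(rep(1, 20), 4)),
                                     collapse = "")), paste0("t", 1:5))
  d <- distance_matrix(aln)
  for (i in 1:4) {
    for (j in (i + 1):5) {
      x <- strsplit(aln[[i]], "")[[1]]
      y <- strsplit(aln[[j]], "")[[1]]
      sh <- x != "-" & y != "-"
      expect_equal(d[i, j], sum(sh & x != y) / sum(sh))
    }
  }
})

test_that("NJ recovers the generating quartet and handles 3 taxa exactly", {
  # additive matrix from ((A,B),(C,D)) with internal branch 0.3
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  bl <- c(A = 0.1, B = 0.2, C = 0.15, D = 0.25)
  for (i in LETTERS[1:4]) {
    for (j in LETTERS[1:4]) {
      if (i == j) next
      d[i, j] <- bl[i] + bl[j] +
        (0.3 * (length(unique(c(i, j) %in% c("A", "B"))) == 2))
    }
  }
  tr <- nj_tree(d)
  want <- ape::read.tree(text = "((A,B),(C,D));")
  expect_true(same_topology(tr, want))
  # 3 taxa: closed-form branch lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  t3 <- nj_tree(d3)
  bl3 <- setNames(t3$edge.length[match(1:3, t3$edge[, 2])], t3$tip.label)
  expect_equal(bl3[["a"]], (3 + 4 - 5) / 2)
  expect_equal(bl3[["b"]], (3 + 5 - 4) / 2)
  expect_equal(bl3[["c"]], (4 + 5 - 3) / 2)
})

test_that("NJ recovers the true topology for random additive 5-taxon
          matrices, verified against exhaustive enumeration", {
  set.seed(53)
  hits_true <- 0L
  hits_oracle <- 0L
  n <- 100
  for (r in seq_len(n)) {
    gen <- random_additive_5taxa()
    tr <- nj_tree(gen$d)
    if (same_topology(tr, gen$tree)) hits_true <- hits_true + 1L
    best <- oracle_best_topology(gen$d)
    if (same_topology(tr, best)) hits_oracle <- hits_oracle + 1L
  }
  expect_equal(hits_true, n)
  expect_equal(hits_oracle, n)
})

test_that("NJ topology equals UPGMA topology on an ultrametric matrix", {
  set.seed(55)
  for (r in 1:10) {
    tr <- ape::rcoal(6, tip.label = paste0("u", 1:6))  # ultrametric
    d <- as.matrix(ape::cophenetic.phylo(tr))
    nj <- nj_tree(d)
    up <- ape::as.phylo(stats::hclust(as.dist(d), method = "average"))
    expect_true(same_topology(nj, up))
  }
})

test_that("bootstrap supports are seeded, reproducible, and sane", {
  set.seed(57)
  # two well-separated clusters of sequences
  base1 <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 120,
                        replace = TRUE), collapse = "")
  base2 <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 120,
                        replace = TRUE), collapse = "")
  mut <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    at <- sample(length(v), k)
    for (i in at) v[i] <- sample(setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                  "")[[1]], v[i]), 1)
    paste(v, collapse = "")
  }
  aln <- c(a1 = mut(base1, 3), a2 = mut(base1, 3), a3 = mut(base1, 3),
           b1 = mut(base2, 3), b2 = mut(base2, 3), b3 = mut(base2, 3))
  t1 <- bootstrap_nj(aln, n_reps = 200, seed = 111)
  t2 <- bootstrap_nj(aln, n_reps = 200, seed = 111)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_identical(attr(t1, "boot_support"), attr(t2, "boot_support"))
  # the a-vs-b bipartition should be maximally supported
  expect_gte(max(attr(t1, "boot_support")), 95)
  # single replicate yields supports in {0, 100}
  t3 <- bootstrap_nj(aln, n_reps = 1, seed = 5)
  expect_true(all(attr(t3, "boot_support") %in% c(0, 100)))
})

test_that("orthology calls follow the cherry-then-minimal-clade rules", {
  # two clean cherries
  tr <- ape::read.tree(text = "((Tm1,Tc1),(Tm2,Tc2));")
  oc <- call_orthologs(tr)
  expect_equal(sum(vapply(oc$calls, function(x) x$type == "pair", TRUE)), 2)
  expect_length(oc$unpaired, 0)
  # cherry precedence inside a nested mixed clade
  tr2 <- ape::root(ape::read.tree(text = "((Tm1,(Tm2,Tc1)),(Tm3,Tm4));"),
                   outgroup = "Tm4", resolve.root = TRUE)
  oc2 <- call_orthologs(tr2)
  types <- vapply(oc2$calls, `[[`, "", "type")
  expect_equal(types, "pair")
  expect_setequal(oc2$calls[[1]]$members, c("Tm2", "Tc1"))
  expect_true("Tm1" %in% oc2$unpaired)
  # species-pure subtree: all unpaired
  tr3 <- ape::read.tree(text = "((Tm1,Tm2),(Tm3,(Tm4,Tm5)));")
  oc3 <- call_orthologs(tr3)
  expect_length(oc3$calls, 0)
  expect_setequal(oc3$unpaired, paste0("Tm", 1:5))
  # a 3-leaf mixed clade that is not a cherry becomes a group
  tr4 <- ape::read.tree(text = "(((Tm1,Tm2),Tc1),(Tm3,Tc3));")
  oc4 <- call_orthologs(tr4)
  types4 <- vapply(oc4$calls, `[[`, "", "type")
  expect_setequal(types4, c("pair", "group"))
  grp <- oc4$calls[[which(types4 == "group")]]
  expect_setequal(grp$members, c("Tm1", "Tm2", "Tc1"))
})

test_that("no leaf appears in two orthology calls", {
  set.seed(59)
  for (r in 1:20) {
    tr <- ape::rtree(12, tip.label = sample(c(paste0("Tm", 1:6),
                                              paste0("Tc", 1:6))))
    oc <- call_orthologs(tr)
    members <- unlist(lapply(oc$calls, `[[`, "members"))
    expect_equal(anyDuplicated(members), 0)
    expect_length(intersect(members, oc$unpaired), 0)
  }
})

test_that("ortholog pairs recover the generator's partner truth", {
  panel <- reference_panel()
  spec <- gene_family_spec(n_clusters = 4, genes_per_cluster = 5,
                           substitution_rate = 0.2, ortholog_fraction = 0.8,
                           seed = 61)
  sim <- generate_gene_families(spec, panel)
  prot <- setNames(sub("^M", "", sim$proteins), names(sim$proteins))
  aln <- papcat:::progressive_msa(prot)
  aseq <- setNames(apply(aln, 1, paste, collapse = ""), rownames(aln))
  tree <- bootstrap_nj(aseq, n_reps = 50, seed = 111)
  tree <- ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE)
  oc <- call_orthologs(tree)
  truth <- setNames(sim$truth$ortholog_partner, sim$truth$gene_id)
  ok <- 0L
  if (!is.null(oc$pairs)) {
    for (k in seq_len(nrow(oc$pairs))) {
      if (identical(truth[[oc$pairs[k, 1]]], oc$pairs[k, 2])) ok <- ok + 1L
    }
    precision <- ok / nrow(oc$pairs)
    expect_gte(precision, 0.9)
  } else {
    fail("no ortholog pairs called")
  }
})
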