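# Alignment identity distances, UPGMA clustering, Newick serialization.

test_that("global alignment identity handles the degenerate extremes", {
  expect_equal(global_align_identity("AAAA", "AAAA"), 1)
  expect_equal(global_align_identity("AAAA", "TTTT"), 0)
  expect_error(global_align_identity("", "A"), "non-empty")
})

test_that("alignment score matches a brute-force oracle on short sequences", {
  res <- global_align_identity("GATTACA", "GCATGC", return_alignment = TRUE)
  expect_equal(res$score, oracle_align_score("GATTACA", "GCATGC"))
  set.seed(41)
  for (i in 1:15) {
    a <- random_peptide(sample(2:8, 1), c("A", "C", "G", "T"))
    b <- random_peptide(sample(2:8, 1), c("A", "C", "G", "T"))
    res <- global_align_identity(a, b, return_alignment = TRUE)
    expect_equal(res$score, oracle_align_score(a, b))
    # the traceback alignment is a valid alignment achieving that score
    al <- strsplit(res$alignment, "")
    expect_equal(paste(al[[1]][al[[1]] != "-"], collapse = ""), a)
    expect_equal(paste(al[[2]][al[[2]] != "-"], collapse = ""), b)
    cols <- cbind(al[[1]], al[[2]])
    colscore <- sum(ifelse(cols[, 1] == "-" | cols[, 2] == "-", -1,
                           ifelse(cols[, 1] == cols[, 2], 1, 0)))
    expect_equal(colscore, res$score)
    expect_equal(res$identity,
                 sum(cols[, 1] == cols[, 2] & cols[, 1] != "-") / nrow(cols))
  }
})

test_that("alignment score agrees with Biostrings pairwise alignment", {
  set.seed(42)
  for (i in 1:10) {
    a <- random_peptide(sample(5:30, 1))
    b <- random_peptide(sample(5:30, 1))
    letters_used <- unique(strsplit(paste0(a, b), "")[[1]])
    sub <- matrix(0, length(letters_used), length(letters_used),
                  dimnames = list(letters_used, letters_used))
    diag(sub) <- 1
    ref <- Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = sub,
      gapOpening = 0, gapExtension = 1, scoreOnly = TRUE)
    expect_equal(global_align_identity(a, b,
                                       return_alignment = TRUE)$score, ref)
  }
})

test_that("distance matrix is symmetric, bounded and rejects duplicates", {
  set.seed(43)
  seqs <- setNames(vapply(1:8, function(i) random_peptide(sample(5:15, 1)),
                          character(1)), paste0("s", 1:8))
  D <- distance_matrix(seqs)
  expect_equal(D, t(D))
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(unname(diag(D)), rep(0, 8))
  expect_error(distance_matrix(setNames(c("AA", "CC"), c("x", "x"))),
               "duplicate")
  expect_error(distance_matrix(c(a = "AA")), "at least 2")
})

test_that("UPGMA reproduces the textbook three-leaf tree", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- upgma(D)
  expect_equal(to_newick(tree), "((A:1,B:1):1,C:2);")
  expect_equal(unname(cut_groups(tree, 2)), c(1L, 1L, 2L))
  expect_equal(unname(cut_groups(tree, 1)), c(1L, 1L, 1L))
  expect_equal(length(unique(cut_groups(tree, 3))), 3L)
  expect_error(cut_groups(tree, 4), "k must be")
  # two leaves: root joins both at d/2
  D2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(to_newick(upgma(D2)), "(x:1.5,y:1.5);")
  expect_error(upgma(matrix(c(0, 1, 2, 0), 2,
                            dimnames = list(c("a", "b"), c("a", "b")))),
               "symmetric")
})

test_that("UPGMA trees are ultrametric and match hclust average linkage", {
  set.seed(44)
  for (i in 1:60) {
    D <- random_distance_matrix(6)
    tree <- upgma(D)
    # ultrametric: all root-to-leaf path lengths equal the root height
    cop <- tree_cophenetic(tree)
    expect_equal(max(cop), 2 * max(tree$node_height), tolerance = 1e-9)
    # independent oracle: classic average-linkage clustering
    ref <- stats::hclust(stats::as.dist(D), method = "average")
    expect_equal(cop[rownames(D), rownames(D)],
                 as.matrix(stats::cophenetic(ref))[rownames(D), rownames(D)],
                 tolerance = 1e-9)
    # heights non-decreasing toward the root
    expect_true(all(diff(tree$merge_distance) >= -1e-12))
  }
})

test_that("leaf label permutation yields an isomorphic tree", {
  set.seed(45)
  D <- random_distance_matrix(7)
  perm <- sample(7)
  Dp <- D[perm, perm]
  c1 <- tree_cophenetic(upgma(D))
  c2 <- tree_cophenetic(upgma(Dp))
  expect_equal(c1[rownames(D), rownames(D)],
               c2[rownames(D), rownames(D)], tolerance = 1e-9)
})

test_that("Newick output round-trips through an independent parser", {
  set.seed(46)
  for (i in 1:10) {
    D <- random_distance_matrix(sample(4:8, 1))
    tree <- upgma(D)
    ph <- ape::read.tree(text = to_newick(tree))
    expect_setequal(ph$tip.label, rownames(D))
    ref <- as.matrix(ape::cophenetic.phylo(ph))
    expect_equal(ref[rownames(D), rownames(D)],
                 tree_cophenetic(tree)[rownames(D), rownames(D)],
                 tolerance = 1e-9)
  }
})
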