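test_that("p-distance matches hand values and the oracle", {
  aln <- c(a = "ACDEF", b = "ACDFF", c = "AC-EF")
  d <- p_distance_matrix(aln)
  expect_equal(unname(d["a", "b"]), 1 / 5)
  expect_equal(unname(d["a", "c"]), 0)          # gapped site dropped pairwise
  expect_equal(unname(d["b", "c"]), 1 / 4)
  dc <- p_distance_matrix(aln, gap_mode = "complete_deletion")
  expect_equal(unname(dc["a", "b"]), 1 / 4)

  # property: random alignments agree with the independent oracle
  set.seed(7)
  for (r in 1:10) {
    seqs <- vapply(1:4, function(i)
      paste(sample(c("A", "C", "D", "E", "-"), 30, replace = TRUE),
            collapse = ""), character(1))
    names(seqs) <- paste0("t", 1:4)
    d <- p_distance_matrix(seqs)
    for (i in 1:3) for (j in (i + 1):4)
      expect_equal(unname(d[i, j]), oracle_pdist(seqs[i], seqs[j]))
  }
})

test_that("NJ recovers additive matrices exactly", {
  # handcrafted additive matrix: tree ((a:2,b:3),(c:4,d:5)) with a total
  # internal path of 1 between the two cherries
  D <- matrix(c(0, 5, 7, 8,
                5, 0, 8, 9,
                7, 8, 0, 9,
                8, 9, 0, 0), 4, 4)
  D[4, 3] <- D[3, 4] <- 9
  dimnames(D) <- list(letters[1:4], letters[1:4])
  tr <- nj_tree(D)
  expect_equal(max(abs(stats::cophenetic(tr)[letters[1:4], letters[1:4]] - D)),
               0, tolerance = 1e-9)
  expect_true(ape::is.monophyletic(tr, c("a", "b")))

  # property: distances from random trees are recovered exactly
  set.seed(11)
  for (r in 1:5) {
    gen <- ape::rtree(8)
    gen$edge.length <- stats::runif(nrow(gen$edge), 0.05, 1)
    D2 <- stats::cophenetic(gen)
    rec <- nj_tree(D2)
    expect_equal(max(abs(stats::cophenetic(rec)[rownames(D2), colnames(D2)] -
                           D2)), 0, tolerance = 1e-9)
  }
  expect_error(nj_tree(matrix(0, 2, 2)), "dimnames")
})

test_that("bootstrap supports are deterministic and saturate on clean splits", {
  # two well-separated blocks: every informative column supports the split
  aln <- c(a = paste(rep("A", 40), collapse = ""),
           b = paste(rep("A", 40), collapse = ""),
           c = paste(rep("W", 40), collapse = ""),
           d = paste(rep("W", 40), collapse = ""))
  aln["b"] <- sub("A$", "C", aln["b"])
  aln["d"] <- sub("W$", "Y", aln["d"])
  t1 <- bootstrap_supports(aln, n_reps = 50, seed = 5)
  t2 <- bootstrap_supports(aln, n_reps = 50, seed = 5)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  sup <- suppressWarnings(as.numeric(t1$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))
  expect_error(bootstrap_supports(aln, n_reps = 10), "seed")
})

test_that("subgroup assignment anchors on references", {
  # (q1 with refA) and (q2 with refB); q3 sits outside both reference clades
  txt <- "(((q1:0.1,refA:0.1)90:0.2,(q2:0.1,refB:0.1)80:0.2)60:0.1,(q3:0.4,out:0.4)30:0.1);"
  tree <- ape::read.tree(text = txt)
  labels <- c(refA = "RLK-Pelle_LRR-I", refB = "RLK-Pelle_LRR-II-1")
  asg <- assign_subgroups(tree, labels, min_support = 50)
  asg <- asg[order(asg$gene_id), ]
  expect_identical(asg$subgroup[asg$gene_id == "q1"], "RLK-Pelle_LRR-I")
  expect_identical(asg$subgroup[asg$gene_id == "q2"], "RLK-Pelle_LRR-II-1")
  expect_identical(asg$status[asg$gene_id == "q1"], "assigned")
  expect_gte(asg$support[asg$gene_id == "q1"], 50)
  expect_error(assign_subgroups(tree, c(refA = "madeup")), "madeup")
})

test_that("conflicting reference clades are skipped to larger clean ones", {
  # smallest clade holding q mixes refA and refB labels -> must climb to the
  # clade that also contains refC, whose references... still conflict, so q
  # ends unclassified; q2 near a clean pair gets its label.
  txt <- "(((q:0.1,(refA:0.1,refB:0.1)99:0.1)99:0.1,refC:0.3)99:0.1,(q2:0.1,refD:0.1)99:0.3);"
  tree <- ape::read.tree(text = txt)
  labels <- c(refA = "RLK-Pelle_LRR-I", refB = "RLK-Pelle_LRR-II-1",
              refC = "RLK-Pelle_LRR-I", refD = "RLK-Pelle_LRR-V")
  asg <- assign_subgroups(tree, labels, min_support = 50)
  expect_identical(asg$subgroup[asg$gene_id == "q2"], "RLK-Pelle_LRR-V")
  # for q: smallest containing clade {q, refA, refB} conflicts; next larger
  # {q, refA, refB, refC} still conflicts; complement-side clades containing
  # q also conflict -> unclassified
  expect_identical(asg$status[asg$gene_id == "q"], "unclassified")
  expect_true(is.na(asg$subgroup[asg$gene_id == "q"]))
})
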