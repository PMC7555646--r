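make_hits <- function(gene, acc, class, evalue, s, e) {
  data.frame(gene_id = gene, domain_acc = acc, domain_class = class,
             evalue = evalue, env_start = s, env_end = e,
             stringsAsFactors = FALSE)
}

test_that("E-value screening is strictly less-than at the boundary", {
  h <- make_hits("g", "PF00560", "LRR",
                 c(9.99e-4, 1e-3, 1.01e-3), c(1, 50, 100), c(30, 80, 130))
  kept <- filter_domain_hits(h, e_max = 1e-3)
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$evalue, 9.99e-4)
  expect_identical(nrow(filter_domain_hits(h[0, ], 1e-3)), 0L)
})

test_that("overlapping LRR envelopes merge before counting", {
  # three raw LRR hits, two of which overlap -> 2 merged; kinase counted raw
  h <- rbind(make_hits("g", "PF00560", "LRR", 1e-10, 20, 45),
             make_hits("g", "PF13855", "LRR", 1e-9, 40, 60),
             make_hits("g", "PF00560", "LRR", 1e-8, 120, 145),
             make_hits("g", "PF00069", "kinase", 1e-12, 160, 290))
  arc <- call_architecture("g", h, paste(rep("M", 300), collapse = ""))
  expect_identical(arc$n_lrr, 2L)
  expect_identical(arc$n_kinase, 1L)
  expect_true(arc$is_family)
  expect_identical(arc$protein_length, 300L)

  # touching envelopes (45 / 46..) also merge under IRanges adjacency rules?
  # 45 and 46 are adjacent: reduce() merges by default -> count 1
  h2 <- rbind(make_hits("g", "PF00560", "LRR", 1e-10, 20, 45),
              make_hits("g", "PF13855", "LRR", 1e-9, 46, 70))
  arc2 <- call_architecture("g", h2, "MMM")
  expect_identical(arc2$n_lrr, 1L)
  expect_false(arc2$is_family)
})

test_that("architecture rule requires both LRR and kinase", {
  lrr_only <- make_hits("a", "PF00560", "LRR", 1e-10, 20, 45)
  kin_only <- make_hits("b", "PF00069", "kinase", 1e-10, 160, 290)
  expect_false(call_architecture("a", lrr_only, "MAA")$is_family)
  expect_false(call_architecture("b", kin_only, "MAA")$is_family)
  expect_false(call_architecture("c", lrr_only[0, ], "MAA")$is_family)
  expect_error(call_architecture("a", kin_only, "MAA"), "other genes")
  expect_error(call_architecture("a", lrr_only, NULL), "missing")
})

test_that("candidate merging is symmetric with correct provenance", {
  hits <- rbind(make_hits("g1", "PF00560", "LRR", 1e-10, 20, 45),
                make_hits("g1", "PF00069", "kinase", 1e-10, 160, 290),
                make_hits("g2", "PF00560", "LRR", 1e-10, 20, 45),
                make_hits("g2", "PF00069", "kinase", 1e-10, 160, 290),
                make_hits("g3", "PF00560", "LRR", 1e-10, 20, 45))
  prots <- stats::setNames(rep(paste(rep("A", 10), collapse = ""), 3),
                           c("g1", "g2", "g3"))
  calls <- call_architectures(c("g1", "g2", "g3"), hits, prots)
  fam <- merge_candidates(c("g1", "g2"), c("g2", "g3"), calls)
  expect_identical(fam$members$gene_id, c("g1", "g2"))
  expect_identical(fam$members$provenance, c("hmm_search", "both"))
  expect_identical(fam$removed$gene_id, "g3")
  expect_identical(fam$removed$reason, "architecture")

  # symmetry: swapping the two input sets flips provenance consistently
  fam2 <- merge_candidates(c("g2", "g3"), c("g1", "g2"), calls)
  expect_identical(fam2$members$gene_id, fam$members$gene_id)
  expect_identical(fam2$members$provenance, c("rescue", "both"))
  expect_error(merge_candidates("g9", character(0), calls), "g9")
})

test_that("tree pruning removes members far from every reference", {
  # handcrafted tree: m1 near ref (0.3), m2 far from ref (1.4)
  tree <- ape::read.tree(text = "((m1:0.1,ref_a:0.2):0.05,(m2:0.7,x:0.1):0.6);")
  members <- data.frame(gene_id = c("m1", "m2"), n_lrr = 2L, n_kinase = 1L,
                        protein_length = 300L, provenance = "hmm_search",
                        stringsAsFactors = FALSE)
  fam <- structure(list(members = members,
                        removed = data.frame(gene_id = character(),
                                             reason = character(),
                                             detail = character())),
                   class = "family_set")
  pd <- stats::cophenetic(tree)
  expect_lt(pd["m1", "ref_a"], 1)
  expect_gt(pd["m2", "ref_a"], 1)
  pruned <- prune_by_tree(fam, tree, "ref_a", max_dist = 1.0)
  expect_identical(pruned$members$gene_id, "m1")
  expect_identical(pruned$removed$reason, "tree_distance")
  expect_match(pruned$removed$detail, "1\\.55")
  expect_error(prune_by_tree(fam, tree, "nope"), "no reference leaves")
  s <- summarize_family(pruned)
  expect_identical(s$n_members, 1L)
  expect_identical(s$n_multi_kinase, 0L)
})
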