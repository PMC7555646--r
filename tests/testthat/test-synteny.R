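fake_annotation <- function(genes) {
  if (is.null(genes$strand)) genes$strand <- "+"
  structure(list(genes = genes), class = "genome_annotation")
}

gene_df <- function(ids, chrom, start, end, strand = "+") {
  data.frame(gene_id = ids, chrom = chrom, start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

test_that("tandem clustering honors the 200-kb boundary inclusively", {
  g <- gene_df(c("a", "b", "c"), "chr1",
               start = c(1000, 204000, 500000),
               end = c(4000, 207000, 503000))
  # a->b end-to-start gap = 204000 - 4000 = 200000 (inclusive: linked)
  # b->c gap = 500000 - 207000 = 293000 (broken)
  ann <- fake_annotation(g)
  cl <- detect_tandem_clusters(c("a", "b", "c"), ann)
  expect_length(cl, 1L)
  expect_identical(cl[[1]]$members, c("a", "b"))
  expect_identical(cl[[1]]$n_pairs, 1L)

  # one bp over the line: no cluster
  g2 <- g; g2$start[2] <- 204001
  expect_length(detect_tandem_clusters(c("a", "b", "c"),
                                       fake_annotation(g2)), 0L)
})

test_that("distance conventions and scaffold handling behave", {
  g <- gene_df(c("a", "b"), "chr1", c(1000, 150000), c(120000, 160000))
  ann <- fake_annotation(g)
  # end-to-start: 150000 - 120000 = 30000 -> linked
  expect_length(detect_tandem_clusters(c("a", "b"), ann), 1L)
  # start-to-start: 149000 < 200000 -> also linked; stretch starts apart
  g3 <- g; g3$start[2] <- 210000; g3$end[2] <- 220000
  expect_length(detect_tandem_clusters(c("a", "b"), fake_annotation(g3),
                                       mode = "start_to_start"), 0L)
  expect_length(detect_tandem_clusters(c("a", "b"), fake_annotation(g3),
                                       mode = "end_to_start"), 1L)

  gs <- gene_df(c("a", "b"), "scaffold_7", c(1000, 2000), c(1500, 2500))
  expect_message(cl <- detect_tandem_clusters(c("a", "b"),
                                              fake_annotation(gs)),
                 "unplaced")
  expect_length(cl, 0L)
})

test_that("tandem clustering is order-invariant and matches the oracle", {
  set.seed(23)
  for (r in 1:8) {
    n <- 12L
    # non-overlapping genes with random inter-gene gaps straddling 200 kb
    gaps <- sample(c(1000, 50000, 150000, 199999, 200000, 200001, 400000),
                   n, replace = TRUE)
    len <- sample(2000:6000, n, replace = TRUE)
    start <- cumsum(c(1000, gaps[-1] + len[-n]))
    g <- gene_df(sprintf("g%02d", 1:n), "chr1", start, start + len - 1)
    ann <- fake_annotation(g)
    ids <- g$gene_id
    cl1 <- detect_tandem_clusters(ids, ann)
    cl2 <- detect_tandem_clusters(sample(ids), ann)
    expect_identical(cl1, cl2)
    want <- oracle_tandem(g)
    expect_length(cl1, length(want))
    for (k in seq_along(cl1))
      expect_identical(cl1[[k]]$members, want[[k]]$members)
  }
  clusters <- list(list(members = letters[1:3]), list(members = letters[4:8]))
  expect_identical(tandem_pair_count(clusters), 6L)
  expect_identical(tandem_pair_count(clusters, "all_pairs"), 13L)
})

test_that("anchor chaining matches the exhaustive oracle", {
  set.seed(31)
  for (r in 1:12) {
    n <- 8L
    a <- data.frame(rank_a = sample(1:30, n), rank_b = sample(1:30, n),
                    score = round(stats::runif(n, 100, 500)))
    for (ori in c("same", "inverted")) {
      got <- lrrfam:::.best_chain(a, ori, max_rank_gap = 25L)
      want <- oracle_best_chain(a, ori, max_rank_gap = 25L)
      expect_identical(got$length, want$len)
      expect_equal(got$score, want$score)
    }
  }
})

test_that("collinear blocks require min_anchors and strict monotonicity", {
  # 30 genes per chromosome; plant a 4-anchor same-orientation block and a
  # stray 2-anchor pair that must not form a block
  mk <- function(ch) gene_df(sprintf("%s_g%02d", ch, 1:30), ch,
                             seq(1000, by = 10000, length.out = 30),
                             seq(3000, by = 10000, length.out = 30))
  ann <- fake_annotation(rbind(mk("chr1"), mk("chr2")))
  anchors <- data.frame(
    gene_a = c("chr1_g05", "chr1_g08", "chr1_g11", "chr1_g14",
               "chr1_g25", "chr1_g02"),
    gene_b = c("chr2_g10", "chr2_g13", "chr2_g16", "chr2_g19",
               "chr2_g02", "chr2_g28"),
    score = c(400, 380, 390, 410, 300, 310), stringsAsFactors = FALSE)
  bl <- detect_collinear_blocks(anchors, ann, min_anchors = 3L)
  expect_length(bl, 1L)
  expect_identical(nrow(bl[[1]]$anchors), 4L)
  expect_identical(bl[[1]]$orientation, "same")
  expect_identical(bl[[1]]$anchors$gene_a,
                   c("chr1_g05", "chr1_g08", "chr1_g11", "chr1_g14"))
  expect_true(all(diff(bl[[1]]$anchors$rank_b) > 0))

  # inverted orientation is detected too
  anchors_inv <- data.frame(
    gene_a = c("chr1_g05", "chr1_g08", "chr1_g11"),
    gene_b = c("chr2_g19", "chr2_g16", "chr2_g13"),
    score = 400, stringsAsFactors = FALSE)
  bl2 <- detect_collinear_blocks(anchors_inv, ann, min_anchors = 3L)
  expect_length(bl2, 1L)
  expect_identical(bl2[[1]]$orientation, "inverted")

  # a rank gap beyond the ceiling severs the chain
  anchors_gap <- data.frame(
    gene_a = c("chr1_g01", "chr1_g02", "chr1_g30"),
    gene_b = c("chr2_g01", "chr2_g02", "chr2_g30"),
    score = 400, stringsAsFactors = FALSE)
  expect_length(detect_collinear_blocks(anchors_gap, ann, min_anchors = 3L,
                                        max_rank_gap = 25L), 0L)
})

test_that("BED and link output use correct coordinate conventions", {
  g <- gene_df(c("a", "b"), "chr1", c(1001, 5001), c(2000, 6000),
               strand = c("+", "-"))
  ann <- fake_annotation(g)
  tmp <- withr::local_tempfile(fileext = ".bed")
  write_family_bed(c("a", "b"), ann, tmp)
  lines <- readLines(tmp)
  expect_identical(lines[1], "chr1\t1000\t2000\ta\t0\t+")
  expect_identical(lines[2], "chr1\t5000\t6000\tb\t0\t-")
})
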