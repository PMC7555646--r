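test_that("exon counts come from the primary transcript", {
  tmp <- withr::local_tempfile(fileext = ".gff3")
  write_tiny_gff(tmp)
  ann <- read_gff3(tmp)
  ec <- exon_counts(ann, c("gA", "gB"))
  expect_identical(ec, c(gA = 2L, gB = 1L))
  expect_error(exon_counts(ann, "ghost"), "ghost")
})

test_that("subgroup statistics match hand-computed values", {
  counts <- c(g1 = 4L, g2 = 4L, g3 = 4L, g4 = 5L,
              h1 = 1L, h2 = 2L, h3 = 2L,
              k1 = 6L, k2 = 7L, k3 = 7L, k4 = 7L, k5 = 7L, k6 = 7L,
              solo = 12L)
  lab <- c(g1 = "A", g2 = "A", g3 = "A", g4 = "A",
           h1 = "B", h2 = "B", h3 = "B",
           k1 = "C", k2 = "C", k3 = "C", k4 = "C", k5 = "C", k6 = "C",
           solo = "D")
  st <- subgroup_stats(counts, lab)
  row <- function(s) st[st$subgroup == s, ]
  expect_equal(row("A")$mean_exons, 4.25)
  expect_equal(row("A")$sd_exons, 0.5)                    # sd({4,4,4,5})
  expect_equal(row("B")$sd_exons, sd(c(1, 2, 2)))
  expect_equal(round(row("B")$sd_exons, 2), 0.58)
  expect_equal(round(row("C")$sd_exons, 2), 0.41)         # sd({6,7x5})
  expect_equal(row("C")$max_exons, 7L)
  expect_equal(row("C")$min_exons, 6L)
  expect_equal(row("D")$sd_exons, 0)                      # single-gene group
  expect_equal(row("Total")$n_genes, 14L)
  expect_true(is.na(row("Total")$mean_exons))
})

test_that("unassigned genes are excluded with a message", {
  counts <- c(a = 2L, b = 3L, c = 9L)
  asg <- data.frame(gene_id = c("a", "b", "c"),
                    subgroup = c("X", "X", NA),
                    support = c(90, 90, NA),
                    status = c("assigned", "assigned", "unclassified"),
                    stringsAsFactors = FALSE)
  expect_message(st <- subgroup_stats(counts, asg), "1 gene")
  expect_identical(st$n_genes[st$subgroup == "Total"], 2L)
  expect_equal(st$mean_exons[st$subgroup == "X"], 2.5)
})
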