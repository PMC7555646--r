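tiny_genome <- function() {
  set.seed(3)
  chr <- paste(sample(c("A", "C", "G", "T"), 6000, replace = TRUE),
               collapse = "")
  Biostrings::DNAStringSet(c(chr1 = chr))
}

tiny_ann <- function(genes) {
  structure(list(genes = genes,
                 transcripts = data.frame(tx_id = character(),
                                          gene_id = character(),
                                          is_primary = logical()),
                 exons = data.frame(), cds = data.frame(),
                 chrom_lengths = c(chr1 = 6000)),
            class = "genome_annotation")
}

test_that("upstream extraction respects strand and boundaries", {
  genome <- tiny_genome()
  chr <- as.character(genome[[1]])
  genes <- data.frame(gene_id = c("plus", "minus", "edge", "origin"),
                      chrom = "chr1",
                      start = c(3001, 100, 300, 1),
                      end = c(3500, 600, 350, 50),
                      strand = c("+", "-", "+", "+"),
                      stringsAsFactors = FALSE)
  ann <- tiny_ann(genes)

  up <- extract_upstream(genome, ann, "plus", length = 500, anchor = "gene")
  expect_identical(as.character(up[[1]]), substr(chr, 2501, 3000))
  expect_identical(attr(up, "strand"), "+")

  um <- extract_upstream(genome, ann, "minus", length = 500, anchor = "gene")
  want <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(chr, 601, 1100))))
  expect_identical(as.character(um[[1]]), want)

  expect_warning(ue <- extract_upstream(genome, ann, "edge", length = 500,
                                        anchor = "gene"),
                 "truncated")
  expect_identical(as.character(ue[[1]]), substr(chr, 1, 299))

  # gene starting at position 1: nothing upstream at all, no warning
  uo <- extract_upstream(genome, ann, "origin", length = 500, anchor = "gene")
  expect_identical(nchar(as.character(uo[[1]])), 0L)
  expect_error(extract_upstream(genome, ann, "ghost"), "not found")
})

test_that("element scanning agrees with the naive oracle", {
  lib <- cis_element_library()
  set.seed(13)
  for (r in 1:6) {
    seq <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                 collapse = "")
    got <- scan_elements(seq, lib)
    want <- oracle_scan(seq, lib)
    rownames(got) <- NULL
    expect_equal(got, want)
  }
})

test_that("palindromes count once and minus-strand hits are found", {
  lib <- data.frame(name = c("G-box", "W-box"),
                    pattern = c("CACGTG", "TTGACY"),
                    both_strands = TRUE, stringsAsFactors = FALSE)
  # CACGTG is its own reverse complement: one locus, one hit
  h <- scan_elements("AAACACGTGAAA", lib)
  expect_identical(nrow(h[h$motif == "G-box", ]), 1L)
  expect_identical(h$offset[h$motif == "G-box"], 4L)

  # W-box on the minus strand only: revcomp(TTGACC) = GGTCAA present
  h2 <- scan_elements("AAAGGTCAAAAA", lib)
  wb <- h2[h2$motif == "W-box", ]
  expect_identical(nrow(wb), 1L)
  expect_identical(wb$strand, "-")
  expect_identical(wb$offset, 4L)
})

test_that("count table tallies per gene with zero rows preserved", {
  lib <- cis_element_library()
  hits <- list(
    g1 = scan_elements("AAACACGTGAAACACGTGAA", lib),
    g2 = data.frame(motif = character(), offset = integer(),
                    strand = character(), stringsAsFactors = FALSE))
  tab <- element_count_table(hits, lib)
  expect_identical(dim(tab), c(2L, nrow(lib)))
  expect_identical(tab["g1", "G-box"], 2L)
  expect_identical(sum(tab["g2", ]), 0L)
  # every CACGTG is also an ACGTG match for ABRE
  expect_gte(tab["g1", "ABRE"], 2L)
})
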