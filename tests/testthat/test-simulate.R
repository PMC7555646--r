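codons_of <- function(seq) {
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

test_that("evolve_cds hits its divergence targets under NG86", {
  set.seed(61)
  anc <- oracle_random_cds(300)
  ev <- evolve_cds(anc, target_ks = 0.3, omega = 0.2, seed = 7)
  expect_false(any(codons_of(ev$cds) %in% c("TAA", "TAG", "TGA")))

  aln <- structure(list(a = codons_of(anc), b = codons_of(ev$cds),
                        gene_a = "anc", gene_b = "mut"),
                   class = "codon_alignment")
  res <- ng86_kaks(aln)
  expect_lt(abs(res$ks - 0.3), 0.03)
  expect_lt(abs(res$ka - 0.06), 0.02)
  expect_lt(abs(res$ratio - 0.2), 0.05)

  # at most one change per codon: differing codons == record rows
  n_diff <- sum(codons_of(anc) != codons_of(ev$cds))
  expect_identical(n_diff, nrow(ev$record))
  expect_true(all(ev$record$type %in% c("syn", "nonsyn")))

  # deterministic given a seed, and the RNG stream is left untouched
  before <- .Random.seed
  ev2 <- evolve_cds(anc, target_ks = 0.3, omega = 0.2, seed = 7)
  expect_identical(ev$cds, ev2$cds)
  expect_identical(before, .Random.seed)

  ev0 <- evolve_cds(anc, target_ks = 0, omega = 0.2)
  expect_identical(ev0$cds, anc)
  expect_identical(nrow(ev0$record), 0L)
})

test_that("the generator is deterministic given its seed", {
  b1 <- default_bundle()
  dir2 <- withr::local_tempdir()
  b2 <- simulate_genome(sim_config(seed = 101), dir2, self_check = FALSE)
  files <- c("genome.fa", "genes.gff3", "proteins.fa", "cds.fa",
             "domains.tsv", "rescue_ids.txt", "reference_proteins.fa",
             "reference_labels.tsv", "tissues.tsv", "infection.tsv",
             "ct.tsv", file.path("truth", "genes.tsv"),
             file.path("truth", "family.tsv"),
             file.path("truth", "promoters.tsv"),
             file.path("truth", "expression.tsv"))
  for (f in files) {
    expect_identical(readLines(file.path(b1$dir, f)),
                     readLines(file.path(dir2, f)))
  }
})

test_that("the planted composition matches the configuration", {
  b <- default_bundle()
  tr <- b$truth
  cfg <- b$config
  fam <- tr$family
  expect_identical(nrow(fam), sum(cfg$subgroup_sizes))
  expect_identical(as.integer(table(fam$subgroup)[names(cfg$subgroup_sizes)]),
                   as.integer(cfg$subgroup_sizes))
  expect_identical(sum(fam$rescue_only), as.integer(cfg$n_rescue_only))
  expect_identical(sum(fam$multi_kinase), as.integer(cfg$n_multi_kinase))
  expect_identical(sum(tr$genes$role == "background"),
                   as.integer(cfg$n_background))
  # tandem truth mirrors the plan: cluster sizes and exact gap geometry
  sizes <- vapply(cfg$tandem, `[[`, integer(1), "n")
  expect_identical(as.integer(table(tr$tandem$cluster_id)[paste0("td",
                                                    seq_along(sizes))]),
                   as.integer(sizes))
  g <- tr$genes
  for (ti in seq_along(cfg$tandem)) {
    ids <- tr$tandem$gene_id[tr$tandem$cluster_id == paste0("td", ti)]
    pos <- g[match(ids, g$gene_id), ]
    expect_equal(unname(pos$start[-1] - pos$end[-length(ids)]),
                 unname(cfg$tandem[[ti]]$gaps))
  }
})

test_that("the near-miss pair stays apart and unclustered", {
  b <- default_bundle()
  tr <- b$truth
  nm <- b$config$near_miss[[1]]
  g <- tr$genes[tr$genes$role == "family" &
                  tr$genes$subgroup == nm$subgroup &
                  tr$genes$chrom == paste0("chr", nm$chrom), ]
  expect_gte(nrow(g), 2L)
  g <- g[order(g$start), ]
  gaps <- g$start[-1] - g$end[-nrow(g)]
  expect_true(all(gaps > 200000))
  expect_true(nm$gap %in% gaps)
  # none of these genes belong to any planted or detectable cluster
  expect_false(any(g$gene_id %in% tr$tandem$gene_id))
  ann <- read_gff3(b$paths$gff)
  cl <- detect_tandem_clusters(tr$family$gene_id, ann)
  in_cluster <- unlist(lapply(cl, `[[`, "members"))
  expect_false(any(g$gene_id %in% in_cluster))
})

test_that("impossible plans fail fast with clear errors", {
  expect_error(sim_config(seed = 1, subgroup_sizes = c(bogus = 2L)),
               "unknown subgroup")
  cfg <- sim_config(seed = 1)
  cfg$tandem[[1]]$n <- 30L
  cfg$tandem[[1]]$gaps <- rep(1000, 29)
  expect_error(simulate_genome(cfg, withr::local_tempdir()),
               "subgroup budget")
  cfg2 <- sim_config(seed = 1, chrom_len = 3e5)
  expect_error(simulate_genome(cfg2, withr::local_tempdir()),
               "capacity|fit")
})
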