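#' Run the full LRR-RLK family characterization pipeline
#'
#' Chains the analysis stages end to end from input files: candidate
#' identification (HMM-style domain screen at `e_max`, similarity-rescue
#' union, LRR+kinase architecture rule), reference-anchored phylogenetic
#' classification (p-distance neighbor-joining with bootstrap supports,
#' distance pruning), gene-structure statistics, tandem and segmental
#' duplication detection, NG86 Ka/Ks dating of duplicate pairs, promoter
#' cis-element scanning, and (when expression inputs are provided)
#' tissue-specificity and infection-time-course peak calls. Stage tables
#' are written to `out_dir` together with a plain-text report.
#'
#' Segmental-duplication chaining is restricted to inter-chromosomal
#' anchor pairs; intra-chromosomal duplications are handled by the tandem
#' step. Classification and Ka/Ks assume family proteins of equal length
#' (indel-free families); supply pre-aligned sequences otherwise.
#'
#' @param paths Named list of input files (`genome`, `gff`, `proteins`,
#'   `cds`, `domains`, `ref_proteins`, `ref_labels`; optional `rescue`,
#'   `tissues`, `infection`), or a `sim_bundle` from [simulate_genome()].
#' @param out_dir Output directory for stage tables and the report.
#' @param e_max Domain screen E-value ceiling (strict `<`; default 1e-3).
#' @param prune_dist Patristic-distance pruning ceiling (default 1.0).
#' @param n_boot Bootstrap replicates for subgroup supports (default 100;
#'   published surveys use 1000, reduce-for-runtime is a reporting choice
#'   only).
#' @param min_support Minimum support for anchoring clades (default 50).
#' @param boot_seed Seed for the bootstrap resampling (default 1).
#' @param kaks A [kaks_config()].
#' @param promoter_length Upstream window length in bp (default 2000).
#' @param baseline_condition Baseline for peak calls; defaults to the first
#'   condition of the infection matrix.
#' @param verbose Emit stage messages (default TRUE).
#' @return List with the per-stage results (`family`, `tree`,
#'   `assignments`, `exon_stats`, `clusters`, `blocks`, `kaks`, `ks_hist`,
#'   `promoter_counts`, `promoter_hits`, `specificity`, `peaks`,
#'   `summary`).
#' @export
run_pipeline <- function(paths, out_dir,
                         e_max = 1e-3, prune_dist = 1.0,
                         n_boot = 100L, min_support = 50, boot_seed = 1L,
                         kaks = kaks_config(), promoter_length = 2000L,
                         baseline_condition = NULL, verbose = TRUE) {
  if (inherits(paths, "sim_bundle")) paths <- paths$paths
  need <- c("genome", "gff", "proteins", "cds", "domains",
            "ref_proteins", "ref_labels")
  miss <- setdiff(need, names(paths))
  if (length(miss)) stop("missing input path: ", miss[1L])
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(...)

  ## stage 1: identification -------------------------------------------
  say("[identify] screening domain hits")
  proteins <- read_fasta(paths$proteins, "protein")
  cds_all <- read_fasta(paths$cds, "dna")
  hits <- read_domain_hits(paths$domains)
  strong <- filter_domain_hits(hits, e_max)
  hmm_set <- sort(unique(strong$gene_id[strong$domain_class == "LRR"]))
  rescue <- if (!is.null(paths$rescue) && file.exists(paths$rescue)) {
    readLines(paths$rescue, warn = FALSE)
  } else character(0)
  candidates <- union(hmm_set, rescue)
  calls <- call_architectures(candidates, hits, proteins)
  family <- merge_candidates(hmm_set, rescue, calls)
  say(sprintf("[identify] %d candidates -> %d members, %d removed",
              length(candidates), nrow(family$members), nrow(family$removed)))

  ## stage 2: phylogeny and classification ------------------------------
  say("[classify] building neighbor-joining tree")
  refs <- read_fasta(paths$ref_proteins, "protein")
  lab_tab <- utils::read.table(paths$ref_labels, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  ref_labels <- stats::setNames(lab_tab$subgroup, lab_tab$leaf)
  make_aln <- function(ids) c(proteins[ids], refs)
  tree0 <- nj_tree(p_distance_matrix(make_aln(family$members$gene_id)))
  family <- prune_by_tree(family, tree0, names(refs), prune_dist)
  member_ids <- family$members$gene_id
  if (length(member_ids) < 2L) stop("fewer than 2 family members survive")
  aln <- make_aln(member_ids)
  tree <- bootstrap_supports(aln, n_reps = n_boot, seed = boot_seed)
  assignments <- assign_subgroups(tree, ref_labels, min_support)
  say(sprintf("[classify] %d/%d members assigned",
              sum(assignments$status == "assigned"), nrow(assignments)))

  ## stage 3: gene structure --------------------------------------------
  ann <- read_gff3(paths$gff)
  counts <- exon_counts(ann, member_ids)
  ex_stats <- subgroup_stats(counts, assignments)

  ## stage 4: duplication and synteny -----------------------------------
  say("[duplication] tandem clusters and collinear blocks")
  clusters <- detect_tandem_clusters(member_ids, ann)
  anchors <- find_anchor_pairs(proteins[member_ids])
  chrom_of <- stats::setNames(ann$genes$chrom, ann$genes$gene_id)
  inter <- anchors[chrom_of[anchors$gene_a] != chrom_of[anchors$gene_b], ,
                   drop = FALSE]
  blocks <- detect_collinear_blocks(inter, ann)

  ## stage 5: Ka/Ks dating ------------------------------------------------
  pair_list <- list()
  for (cl in clusters) {
    mm <- cl$members
    for (i in seq_len(length(mm) - 1L))
      pair_list[[length(pair_list) + 1L]] <-
        c(mm[i], mm[i + 1L], "tandem")
  }
  for (bi in seq_along(blocks)) {
    a <- blocks[[bi]]$anchors
    for (i in seq_len(nrow(a)))
      pair_list[[length(pair_list) + 1L]] <-
        c(a$gene_a[i], a$gene_b[i], "segmental")
  }
  kaks_tab <- NULL
  if (length(pair_list)) {
    rows <- lapply(pair_list, function(pr) {
      ca <- codon_align(proteins[[pr[1]]], proteins[[pr[2]]],
                        cds_all[[pr[1]]], cds_all[[pr[2]]],
                        gene_a = pr[1], gene_b = pr[2])
      out <- ng86_kaks(ca, kaks)
      out$pair_type <- pr[3]
      out
    })
    kaks_tab <- do.call(rbind, rows)
  }
  ks_hist <- ks_histogram(if (is.null(kaks_tab)) numeric(0) else kaks_tab$ks,
                          kaks$bin_width)

  ## stage 6: promoter elements -------------------------------------------
  say("[promoter] scanning upstream regions")
  genome <- read_fasta(paths$genome, "dna")
  lib <- cis_element_library()
  promoter_hits <- lapply(stats::setNames(member_ids, member_ids),
                          function(id) {
    scan_elements(extract_upstream(genome, ann, id, promoter_length), lib)
  })
  promoter_counts <- element_count_table(promoter_hits, lib)

  ## stage 7: expression (optional) ----------------------------------------
  specificity <- NULL; peaks <- NULL
  if (!is.null(paths$tissues) && file.exists(paths$tissues)) {
    cm <- replicate_means(read_expression_tsv(paths$tissues))
    specificity <- specificity_calls(cm)
  } else say("[expression] no tissue matrix supplied; skipping")
  if (!is.null(paths$infection) && file.exists(paths$infection)) {
    icm <- replicate_means(read_expression_tsv(paths$infection))
    base <- baseline_condition %||% colnames(icm)[1L]
    peaks <- peak_time_calls(icm, baseline = base)
  } else say("[expression] no infection matrix supplied; skipping")

  ## outputs ----------------------------------------------------------------
  .write_tsv(family$members, file.path(out_dir, "family_members.tsv"))
  .write_tsv(family$removed, file.path(out_dir, "family_removed.tsv"))
  .write_tsv(assignments, file.path(out_dir, "subgroup_assignments.tsv"))
  .write_tsv(ex_stats, file.path(out_dir, "exon_stats.tsv"))
  cl_tab <- if (length(clusters)) do.call(rbind, lapply(seq_along(clusters),
    function(i) data.frame(cluster = i, chrom = clusters[[i]]$chrom,
                           member_index = seq_along(clusters[[i]]$members),
                           gene_id = clusters[[i]]$members,
                           stringsAsFactors = FALSE)))
    else data.frame(cluster = integer(), chrom = character(),
                    member_index = integer(), gene_id = character())
  .write_tsv(cl_tab, file.path(out_dir, "tandem_clusters.tsv"))
  bl_tab <- if (length(blocks)) do.call(rbind, lapply(seq_along(blocks),
    function(i) data.frame(block = i, chrom_a = blocks[[i]]$chrom_a,
                           chrom_b = blocks[[i]]$chrom_b,
                           orientation = blocks[[i]]$orientation,
                           gene_a = blocks[[i]]$anchors$gene_a,
                           gene_b = blocks[[i]]$anchors$gene_b,
                           score = blocks[[i]]$anchors$score,
                           stringsAsFactors = FALSE)))
    else data.frame(block = integer(), chrom_a = character(),
                    chrom_b = character(), orientation = character(),
                    gene_a = character(), gene_b = character(),
                    score = numeric())
  .write_tsv(bl_tab, file.path(out_dir, "collinear_blocks.tsv"))
  if (!is.null(kaks_tab))
    .write_tsv(kaks_tab, file.path(out_dir, "kaks_pairs.tsv"))
  .write_tsv(ks_hist, file.path(out_dir, "ks_histogram.tsv"))
  pc <- data.frame(gene_id = rownames(promoter_counts), promoter_counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(pc, file.path(out_dir, "promoter_counts.tsv"))
  if (!is.null(specificity))
    .write_tsv(specificity, file.path(out_dir, "specificity_calls.tsv"))
  if (!is.null(peaks))
    .write_tsv(peaks, file.path(out_dir, "peak_calls.tsv"))
  ape::write.tree(tree, file.path(out_dir, "family_tree.nwk"))

  fam_summary <- summarize_family(family)
  report <- c(
    sprintf("family members: %d", fam_summary$n_members),
    sprintf("protein length range: %d-%d aa (mean %.1f)",
            fam_summary$length_min, fam_summary$length_max,
            fam_summary$length_mean),
    sprintf("members with two or more kinase domains: %d",
            fam_summary$n_multi_kinase),
    sprintf("members assigned to subgroups: %d / %d",
            sum(assignments$status == "assigned"), nrow(assignments)),
    sprintf("tandem clusters: %d (%d duplicate pairs, largest %d genes)",
            length(clusters), tandem_pair_count(clusters),
            if (length(clusters))
              max(vapply(clusters, function(x) length(x$members), integer(1)))
            else 0L),
    sprintf("collinear blocks: %d (%d anchor pairs)", length(blocks),
            if (length(blocks))
              sum(vapply(blocks, function(b) nrow(b$anchors), integer(1)))
            else 0L),
    if (!is.null(kaks_tab))
      sprintf("duplicate pairs dated: %d (mean Ks %.3f, mean Ka/Ks %.3f)",
              nrow(kaks_tab), mean(kaks_tab$ks, na.rm = TRUE),
              mean(kaks_tab$ratio, na.rm = TRUE)),
    sprintf("promoter elements found: %d occurrences of %d element types",
            sum(promoter_counts), sum(colSums(promoter_counts) > 0)),
    if (!is.null(specificity))
      sprintf("tissue-specific members: %d",
              sum(specificity$mode == "specific")),
    if (!is.null(peaks))
      sprintf("infection-responsive members (fold >= 2 over baseline): %d",
              sum(peaks$called)))
  writeLines(report, file.path(out_dir, "report.txt"))
  say(paste0("[done] results in ", out_dir))

  list(family = family, tree = tree, assignments = assignments,
       exon_stats = ex_stats, clusters = cl_tab, blocks = bl_tab,
       raw_clusters = clusters, raw_blocks = blocks,
       kaks = kaks_tab, ks_hist = ks_hist,
       promoter_counts = promoter_counts, promoter_hits = promoter_hits,
       specificity = specificity, peaks = peaks, summary = report)
}
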