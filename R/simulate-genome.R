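# Synthetic genome and expression bundle realizing a sim_config plan.
#
# Layout strategy: each chromosome is a sequence of "units" (tandem
# clusters, segmental-block anchor runs, near-miss pairs, isolated family
# genes) separated by filler background genes plus a terminal gap that
# keeps any two family genes of different units more than 200 kb apart, so
# the planted tandem clusters are exactly the clusters the 200-kb rule
# recovers. Filler runs are short (2-4 genes), keeping anchor rank gaps
# inside segmental units far below the chaining limit. Subgroups are
# assigned so that, outside the planted segmental blocks, no two
# chromosomes share a subgroup: within-subgroup protein similarity is the
# only source of alignment anchors, hence the planted blocks are the only
# chainable inter-chromosomal anchor sets.

.FAM_EXON_BASE <- c("RLK-Pelle_LRR-XI-1" = 2L, "RLK-Pelle_LRR-XII" = 3L,
                    "RLK-Pelle_LRR-III-1" = 2L, "RLK-Pelle_LRR-I" = 13L,
                    "RLK-Pelle_LRR-II-1" = 11L, "RLK-Pelle_LRR-VIII" = 14L,
                    "RLK-Pelle_LRR-IV" = 4L, "RLK-Pelle_LRR-V" = 14L)

.PLANT_MOTIFS <- c("W-box", "MBS", "P-box", "LTR", "GARE-motif", "AuxRR-core")

.IUPAC_SETS <- list(A = "A", C = "C", G = "G", T = "T",
                    R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"),
                    W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                    B = c("C", "G", "T"), D = c("A", "G", "T"),
                    H = c("A", "C", "T"), V = c("A", "C", "G"),
                    N = c("A", "C", "G", "T"))

.BASES <- c("A", "C", "G", "T")

# sample k elements from x without the scalar-x pitfall of sample()
.pick <- function(x, k) x[sample.int(length(x), k)]

.iupac_instance <- function(pattern) {
  paste(vapply(strsplit(pattern, "")[[1]],
               function(ch) .pick(.IUPAC_SETS[[ch]], 1L), character(1)),
        collapse = "")
}

# Random intron/exon decomposition of a CDS plus a strand.
.gene_model <- function(cds, n_exons) {
  exon_len <- split_exon_lengths(nchar(cds), n_exons)
  intron_len <- if (n_exons > 1L) sample(100:400, n_exons - 1L, replace = TRUE)
                else integer(0)
  list(exon_len = exon_len, intron_len = intron_len,
       strand = .pick(c("+", "-"), 1L),
       span = sum(exon_len) + sum(intron_len))
}

# Build one promoter window: random background with every library motif
# scrubbed out, then planted instances of `plant_names` motifs at known
# offsets; the final window is accepted only when a full library scan
# returns exactly the planted occurrences.
.make_promoter_window <- function(len, library, plant_names, max_tries = 40L) {
  widths <- nchar(library$pattern)
  for (try_i in seq_len(max_tries)) {
    w <- sample(.BASES, len, replace = TRUE)
    clean <- FALSE
    for (iter in 1:100) {
      hits <- scan_elements(paste(w, collapse = ""), library)
      if (nrow(hits) == 0L) { clean <- TRUE; break }
      for (r in seq_len(nrow(hits))) {
        wd <- widths[match(hits$motif[r], library$name)]
        w[hits$offset[r]:(hits$offset[r] + wd - 1L)] <-
          sample(.BASES, wd, replace = TRUE)
      }
    }
    if (!clean) next
    counts <- sample(0:2, length(plant_names), replace = TRUE)
    while (sum(counts) < 2L) counts <- sample(0:2, length(plant_names),
                                              replace = TRUE)
    total <- sum(counts)
    grid <- seq(3L, len - 12L, by = 15L)
    offs <- sort(.pick(grid, total))
    motifs <- rep(plant_names, counts)
    motifs <- .pick(motifs, length(motifs))   # shuffle across positions
    for (j in seq_len(total)) {
      inst <- .iupac_instance(library$pattern[match(motifs[j], library$name)])
      w[offs[j]:(offs[j] + nchar(inst) - 1L)] <- strsplit(inst, "")[[1]]
    }
    expected <- data.frame(motif = motifs, offset = offs,
                           strand = rep("+", total), stringsAsFactors = FALSE)
    expected <- expected[order(expected$motif, expected$offset), , drop = FALSE]
    rownames(expected) <- NULL
    seq_str <- paste(w, collapse = "")
    got <- scan_elements(seq_str, library)
    rownames(got) <- NULL
    if (identical(got, expected)) return(list(seq = seq_str, truth = expected))
  }
  stop("could not realize a clean promoter window")
}

#' Generate a synthetic genome bundle with known ground truth
#'
#' Realizes the plan in a [sim_config()]: chromosome FASTA, GFF3 gene
#' models, per-gene proteins and CDS, a domain hit table, a rescue
#' candidate list, reference proteins with subgroup labels, planted
#' promoter elements, simulated expression matrices, and a `truth/`
#' directory of TSVs recording every planted fact. All randomness comes
#' from `cfg$seed`; two calls with the same config produce byte-identical
#' output. A read-back self-check (annotation, sequences, domain calls,
#' promoter scans) runs before returning unless disabled.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param self_check Verify the written bundle against the truth tables
#'   using the package's own readers (default TRUE).
#' @return A `sim_bundle`: list with `dir`, `paths` (named file paths),
#'   `truth` (named list of data frames) and `config`.
#' @export
simulate_genome <- function(cfg, out_dir, self_check = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
  with_seed(cfg$seed, .simulate_genome_impl(cfg, out_dir, self_check))
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf("sim_bundle in %s: %d genes (%d family) on %d chromosomes\n",
              x$dir, nrow(x$truth$genes),
              sum(x$truth$genes$role == "family"),
              x$config$n_chrom))
  invisible(x)
}

.simulate_genome_impl <- function(cfg, out_dir, self_check) {
  lib <- cis_element_library()
  labels <- names(cfg$subgroup_sizes)

  ## ---- family plan expansion ----------------------------------------
  fam <- list()
  used <- stats::setNames(integer(length(labels)), labels)
  new_member <- function(subgroup, chrom, unit, role, gap_within = NA_real_,
                         parent = NA_character_, ks = cfg$within_ks,
                         cluster_id = NA_character_, block_id = NA_integer_,
                         pair_idx = NA_integer_, side = NA_character_) {
    if (!subgroup %in% labels) stop("plan uses unknown subgroup: ", subgroup)
    used[subgroup] <<- used[subgroup] + 1L
    if (used[subgroup] > cfg$subgroup_sizes[subgroup])
      stop("family plan exceeds subgroup budget: ", subgroup)
    key <- sprintf("fam%03d", length(fam) + 1L)
    fam[[key]] <<- list(key = key, subgroup = subgroup, chrom = chrom,
                        unit = unit, role = role, gap_within = gap_within,
                        parent = parent, ks = ks, cluster_id = cluster_id,
                        block_id = block_id, pair_idx = pair_idx, side = side)
    key
  }
  for (ti in seq_along(cfg$tandem)) {
    td <- cfg$tandem[[ti]]
    if (length(td$gaps) != td$n - 1L)
      stop("tandem cluster ", ti, ": need n-1 gaps")
    if (any(td$gaps > 200000))
      stop("tandem cluster ", ti, ": planned gap exceeds 200 kb")
    prev <- NA_character_
    for (j in seq_len(td$n)) {
      prev <- new_member(td$subgroup, td$chrom, paste0("td", ti), "tandem",
                         gap_within = if (j > 1L) td$gaps[j - 1L] else NA_real_,
                         parent = prev,
                         ks = if (j > 1L) td$ks else cfg$within_ks,
                         cluster_id = paste0("td", ti), pair_idx = j)
    }
  }
  for (bi in seq_along(cfg$segmental)) {
    bl <- cfg$segmental[[bi]]
    for (j in seq_along(bl$subgroups)) {
      src <- new_member(bl$subgroups[j], bl$chrom_a, paste0("seg", bi, "src"),
                        "segmental", block_id = bi, pair_idx = j, side = "a")
      new_member(bl$subgroups[j], bl$chrom_b, paste0("seg", bi, "dup"),
                 "segmental", parent = src, ks = bl$ks,
                 block_id = bi, pair_idx = j, side = "b")
    }
  }
  for (ni in seq_along(cfg$near_miss)) {
    nm <- cfg$near_miss[[ni]]
    if (nm$gap <= 200000) stop("near-miss gap must exceed 200 kb")
    new_member(nm$subgroup, nm$chrom, paste0("nm", ni), "near_miss")
    new_member(nm$subgroup, nm$chrom, paste0("nm", ni), "near_miss",
               gap_within = nm$gap)
  }
  # leftover members: isolated genes on the subgroup's home chromosome
  home <- stats::setNames(rep(NA_integer_, length(labels)), labels)
  for (td in cfg$tandem) if (is.na(home[td$subgroup])) home[td$subgroup] <- td$chrom
  for (nm in cfg$near_miss) if (is.na(home[nm$subgroup])) home[nm$subgroup] <- nm$chrom
  fi <- 0L
  for (s in labels) {
    for (j in seq_len(max(0L, cfg$subgroup_sizes[s] - used[s]))) {
      fi <- fi + 1L
      ch <- if (!is.na(home[s])) home[s] else ((fi - 1L) %% cfg$n_chrom) + 1L
      new_member(s, ch, paste0("free", fi), "free")
    }
  }

  ## ---- coding sequences ---------------------------------------------
  anc <- lapply(stats::setNames(labels, labels),
                function(s) random_cds(cfg$protein_len))
  cds <- list()
  for (m in fam) {
    base <- if (is.na(m$parent)) anc[[m$subgroup]] else cds[[m$parent]]
    cds[[m$key]] <- evolve_cds(base, m$ks, cfg$omega)$cds
  }
  ref_cds <- lapply(anc, function(a) evolve_cds(a, cfg$ref_ks, cfg$omega)$cds)

  models <- list()
  for (m in fam) {
    base_n <- .FAM_EXON_BASE[m$subgroup]
    if (is.na(base_n)) base_n <- 4L
    n_ex <- max(1L, base_n + .pick(c(-1L, 0L, 0L, 1L), 1L))
    models[[m$key]] <- .gene_model(cds[[m$key]], n_ex)
  }
  out_keys <- character(0)
  if (cfg$n_outliers > 0L) {
    for (k in seq_len(cfg$n_outliers)) {
      key <- sprintf("out%02d", k)
      out_keys <- c(out_keys, key)
      cds[[key]] <- random_cds(cfg$protein_len)
      models[[key]] <- .gene_model(cds[[key]], .pick(2:4, 1L))
    }
  }

  bg <- list()
  next_bg <- function() {
    if (length(bg) >= cfg$n_background)
      stop("background gene budget exhausted during layout; raise n_background")
    key <- sprintf("bg%03d", length(bg) + 1L)
    cdsb <- random_cds(.pick(120:400, 1L))
    bg[[key]] <<- list(key = key, cds = cdsb,
                       model = .gene_model(cdsb, .pick(1:5, 1L)))
    key
  }

  ## ---- placement ------------------------------------------------------
  placed <- list()
  order_on <- stats::setNames(vector("list", cfg$n_chrom),
                              paste0("chr", seq_len(cfg$n_chrom)))
  pos_final <- numeric(cfg$n_chrom)
  cap <- cfg$chrom_len - 2200   # keep room for the last promoter window
  fam_chrom <- vapply(fam, `[[`, integer(1), "chrom")
  fam_unit <- vapply(fam, `[[`, character(1), "unit")
  out_chrom <- if (length(out_keys))
    stats::setNames(((seq_along(out_keys) - 1L) %% cfg$n_chrom) + 1L, out_keys)
  else integer(0)

  for (ch_idx in seq_len(cfg$n_chrom)) {
    chrom <- paste0("chr", ch_idx)
    pos <- 0; last_fam_end <- NA_real_
    put <- function(key, model, gap) {
      start <- pos + gap
      end <- start + model$span - 1
      if (end > cap)
        stop("chromosome capacity exceeded on ", chrom,
             "; extend chrom_len or shrink the plan")
      placed[[key]] <<- list(chrom = chrom, start = as.integer(start),
                             end = as.integer(end))
      order_on[[chrom]] <<- c(order_on[[chrom]], key)
      pos <<- end
    }
    put_bg <- function() {
      k <- next_bg()
      put(k, bg[[k]]$model, .pick(9000:12000, 1L))
    }
    sep_gap <- function() {
      # filler genes plus a terminal gap guaranteeing > 200 kb between
      # family genes of different units (and bounded anchor rank gaps)
      if (is.na(last_fam_end)) return(.pick(3000:8000, 1L))
      for (f in seq_len(.pick(2:4, 1L))) put_bg()
      max(205000 - (pos - last_fam_end), 2600) + .pick(0:5000, 1L)
    }
    for (i in 1:6) put_bg()
    units <- unique(fam_unit[fam_chrom == ch_idx])
    for (u in units) {
      keys <- names(fam)[fam_chrom == ch_idx & fam_unit == u]
      for (k in keys) {
        m <- fam[[k]]
        gap <- if (!is.na(m$gap_within)) m$gap_within else sep_gap()
        put(k, models[[k]], gap)
        last_fam_end <- placed[[k]]$end
      }
    }
    for (k in names(out_chrom)[out_chrom == ch_idx]) {
      put(k, models[[k]], sep_gap())
      last_fam_end <- placed[[k]]$end
    }
    pos_final[ch_idx] <- pos
  }
  while (length(bg) < cfg$n_background) {
    space <- cap - pos_final
    ch_idx <- which.max(space)
    k <- next_bg()
    gap <- .pick(9000:12000, 1L)
    start <- pos_final[ch_idx] + gap
    end <- start + bg[[k]]$model$span - 1
    if (end > cap)
      stop("cannot fit all background genes; extend chrom_len")
    chrom <- paste0("chr", ch_idx)
    placed[[k]] <- list(chrom = chrom, start = as.integer(start),
                        end = as.integer(end))
    order_on[[chrom]] <- c(order_on[[chrom]], k)
    pos_final[ch_idx] <- end
  }

  ## ---- gene ids and master records ------------------------------------
  id_of <- character(0)
  for (ch_idx in seq_len(cfg$n_chrom)) {
    keys <- order_on[[paste0("chr", ch_idx)]]
    starts <- vapply(placed[keys], `[[`, integer(1), "start")
    keys <- keys[order(starts)]
    id_of[keys] <- sprintf("mt%dg%05d", ch_idx, 10L * seq_along(keys))
  }

  genes <- list()
  for (key in names(placed)) {
    model <- if (startsWith(key, "bg")) bg[[key]]$model else models[[key]]
    cds_k <- if (startsWith(key, "bg")) bg[[key]]$cds else cds[[key]]
    n_ex <- length(model$exon_len)
    ex_start <- placed[[key]]$start +
      cumsum(c(0L, model$exon_len[-n_ex] + model$intron_len))
    ex_end <- ex_start + model$exon_len - 1L
    role <- if (startsWith(key, "bg")) "background"
            else if (startsWith(key, "out")) "outlier" else "family"
    genes[[key]] <- list(key = key, id = id_of[[key]],
                         chrom = placed[[key]]$chrom,
                         strand = model$strand,
                         start = placed[[key]]$start, end = placed[[key]]$end,
                         exon_start = as.integer(ex_start),
                         exon_end = as.integer(ex_end),
                         cds = cds_k, role = role,
                         subgroup = if (role == "family") fam[[key]]$subgroup
                                    else NA_character_)
  }
  fam_ids <- stats::setNames(id_of[names(fam)], names(fam))

  ## ---- chromosome sequences -------------------------------------------
  chrom_seq <- lapply(seq_len(cfg$n_chrom),
                      function(i) sample(.BASES, cfg$chrom_len, replace = TRUE))
  names(chrom_seq) <- paste0("chr", seq_len(cfg$n_chrom))
  for (g in genes) {
    chars <- strsplit(if (g$strand == "+") g$cds else revcomp_chr(g$cds), "")[[1]]
    off <- 0L
    for (e in seq_along(g$exon_start)) {
      len_e <- g$exon_end[e] - g$exon_start[e] + 1L
      chrom_seq[[g$chrom]][g$exon_start[e]:g$exon_end[e]] <-
        chars[(off + 1L):(off + len_e)]
      off <- off + len_e
    }
  }

  ## ---- promoters: scrub-and-plant -------------------------------------
  promoter_truth <- list()
  for (key in names(fam)) {
    g <- genes[[key]]
    pw <- .make_promoter_window(2000L, lib, .PLANT_MOTIFS)
    if (g$strand == "+") {
      stopifnot(g$start - 2000L >= 1L)
      chrom_seq[[g$chrom]][(g$start - 2000L):(g$start - 1L)] <-
        strsplit(pw$seq, "")[[1]]
    } else {
      stopifnot(g$end + 2000L <= cfg$chrom_len)
      chrom_seq[[g$chrom]][(g$end + 1L):(g$end + 2000L)] <-
        strsplit(revcomp_chr(pw$seq), "")[[1]]
    }
    tr <- pw$truth
    tr$gene_id <- g$id
    promoter_truth[[key]] <- tr[, c("gene_id", "motif", "offset", "strand")]
  }
  promoter_truth <- do.call(rbind, promoter_truth)
  rownames(promoter_truth) <- NULL

  ## ---- domain hits and candidate sets ----------------------------------
  classes <- default_domain_classes()
  lrr_accs <- names(classes)[classes == "LRR"]
  kin_accs <- names(classes)[classes == "kinase"]
  rescue_keys <- .pick(names(fam), cfg$n_rescue_only)
  multi_keys <- .pick(names(fam), cfg$n_multi_kinase)
  hit_rows <- list()
  add_hit <- function(id, acc, ev, s, e) {
    hit_rows[[length(hit_rows) + 1L]] <<-
      sprintf("%s\t%s\t%.3e\t%d\t%d", id, acc, ev, s, e)
  }
  fam_domains <- list()
  emit_family_hits <- function(id, weak_lrr) {
    n_env <- .pick(1:3, 1L)
    lrr_ev <- function() if (weak_lrr) stats::runif(1, 0.002, 0.05)
                         else 10^-stats::runif(1, 5, 30)
    for (i in seq_len(n_env)) {
      acc <- .pick(lrr_accs, 1L)
      acc_out <- if (stats::runif(1) < 0.15)
        paste0(acc, ".", .pick(1:30, 1L)) else acc
      add_hit(id, acc_out, lrr_ev(), 20L + 50L * (i - 1L), 45L + 50L * (i - 1L))
    }
    if (n_env >= 2L && stats::runif(1) < 0.3)
      add_hit(id, .pick(lrr_accs, 1L), lrr_ev(), 22L, 40L)
    n_env
  }
  for (key in names(fam)) {
    id <- fam_ids[[key]]
    n_lrr <- emit_family_hits(id, key %in% rescue_keys)
    if (key %in% multi_keys) {
      add_hit(id, "PF00069", 10^-stats::runif(1, 10, 40), 160L, 220L)
      add_hit(id, "PF07714", 10^-stats::runif(1, 10, 40), 230L, 290L)
      n_kin <- 2L
    } else {
      add_hit(id, .pick(kin_accs, 1L), 10^-stats::runif(1, 10, 40), 160L, 290L)
      n_kin <- 1L
    }
    fam_domains[[key]] <- c(n_lrr = n_lrr, n_kinase = n_kin)
  }
  for (key in out_keys) {
    id <- id_of[[key]]
    add_hit(id, .pick(lrr_accs, 1L), 10^-stats::runif(1, 5, 30), 20L, 45L)
    add_hit(id, .pick(lrr_accs, 1L), 10^-stats::runif(1, 5, 30), 70L, 95L)
    add_hit(id, .pick(kin_accs, 1L), 10^-stats::runif(1, 10, 40), 160L, 290L)
  }
  bg_keys <- names(bg)
  if (length(bg_keys) < 45L)
    stop("need at least 45 background genes for the decoy role plan")
  perm <- .pick(bg_keys, length(bg_keys))
  bg_role <- stats::setNames(rep("plain", length(bg_keys)), bg_keys)
  bg_role[perm[1:30]] <- "lrr_only"
  bg_role[perm[31:38]] <- "kinase_only"
  bg_role[perm[39:40]] <- "decoy_rescue"
  bg_role[perm[41:45]] <- "other_hit"
  for (key in bg_keys) {
    id <- id_of[[key]]
    switch(bg_role[[key]],
      lrr_only = {
        n <- .pick(1:2, 1L)
        for (i in seq_len(n))
          add_hit(id, .pick(lrr_accs, 1L), 10^-stats::runif(1, 6, 12),
                  c(30L, 80L)[i], c(60L, 110L)[i])
      },
      kinase_only = add_hit(id, .pick(kin_accs, 1L),
                            10^-stats::runif(1, 6, 12), 40L, 110L),
      decoy_rescue = add_hit(id, .pick(kin_accs, 1L),
                             10^-stats::runif(1, 6, 12), 40L, 110L),
      other_hit = add_hit(id, "PF99999", 1e-4, 10L, 50L),
      plain = NULL)
  }
  rescue_ids <- sort(c(unname(fam_ids[rescue_keys]),
                       unname(id_of[perm[39:40]])))

  ## ---- truth tables ----------------------------------------------------
  ord_ids <- unname(sort(id_of))
  gene_truth <- do.call(rbind, lapply(genes[order(id_of[names(genes)])],
    function(g) data.frame(
      gene_id = g$id, chrom = g$chrom, strand = g$strand,
      start = g$start, end = g$end, role = g$role,
      subrole = if (g$role == "family") fam[[g$key]]$role
                else if (g$role == "outlier") "outlier"
                else bg_role[[g$key]],
      subgroup = ifelse(is.na(g$subgroup), "", g$subgroup),
      n_exons = length(g$exon_start),
      cds_length = nchar(g$cds),
      protein_length = nchar(g$cds) / 3L,
      stringsAsFactors = FALSE)))
  rownames(gene_truth) <- NULL

  family_truth <- do.call(rbind, lapply(names(fam), function(key) data.frame(
    gene_id = fam_ids[[key]], subgroup = fam[[key]]$subgroup,
    provenance = if (key %in% rescue_keys) "rescue" else "hmm_search",
    n_lrr = unname(fam_domains[[key]]["n_lrr"]),
    n_kinase = unname(fam_domains[[key]]["n_kinase"]),
    rescue_only = key %in% rescue_keys,
    multi_kinase = key %in% multi_keys,
    stringsAsFactors = FALSE)))
  family_truth <- family_truth[order(family_truth$gene_id), , drop = FALSE]
  rownames(family_truth) <- NULL

  tandem_truth <- list(); tandem_pairs <- list()
  for (ti in seq_along(cfg$tandem)) {
    keys <- names(fam)[vapply(fam, function(m)
      identical(m$cluster_id, paste0("td", ti)), logical(1))]
    ids <- unname(fam_ids[keys])
    tandem_truth[[ti]] <- data.frame(
      cluster_id = paste0("td", ti), chrom = paste0("chr", cfg$tandem[[ti]]$chrom),
      member_index = seq_along(ids), gene_id = ids, stringsAsFactors = FALSE)
    tandem_pairs[[ti]] <- data.frame(
      gene_a = ids[-length(ids)], gene_b = ids[-1L],
      target_ks = cfg$tandem[[ti]]$ks, stringsAsFactors = FALSE)
  }
  tandem_truth <- do.call(rbind, tandem_truth)
  tandem_pairs <- do.call(rbind, tandem_pairs)

  seg_truth <- list()
  for (bi in seq_along(cfg$segmental)) {
    bl <- cfg$segmental[[bi]]
    for (j in seq_along(bl$subgroups)) {
      src <- names(fam)[vapply(fam, function(m)
        identical(m$block_id, bi) && identical(m$pair_idx, j) &&
          identical(m$side, "a"), logical(1))]
      dup <- names(fam)[vapply(fam, function(m)
        identical(m$block_id, bi) && identical(m$pair_idx, j) &&
          identical(m$side, "b"), logical(1))]
      seg_truth[[length(seg_truth) + 1L]] <- data.frame(
        block_id = bi, pair_index = j,
        gene_a = unname(fam_ids[src]), gene_b = unname(fam_ids[dup]),
        chrom_a = paste0("chr", bl$chrom_a), chrom_b = paste0("chr", bl$chrom_b),
        target_ks = bl$ks, target_ka = bl$ks * cfg$omega,
        subgroup = bl$subgroups[j], stringsAsFactors = FALSE)
    }
  }
  seg_truth <- do.call(rbind, seg_truth)

  ref_truth <- data.frame(
    leaf = paste0("ref_", sub("^RLK-Pelle_LRR-", "", labels)),
    subgroup = labels, stringsAsFactors = FALSE)

  ## ---- write files -----------------------------------------------------
  p <- function(...) file.path(out_dir, ...)
  paths <- list(genome = p("genome.fa"), gff = p("genes.gff3"),
                proteins = p("proteins.fa"), cds = p("cds.fa"),
                domains = p("domains.tsv"), rescue = p("rescue_ids.txt"),
                ref_proteins = p("reference_proteins.fa"),
                ref_labels = p("reference_labels.tsv"),
                tissues = p("tissues.tsv"), infection = p("infection.tsv"),
                ct = p("ct.tsv"), truth_dir = p("truth"))

  genome_set <- Biostrings::DNAStringSet(
    vapply(chrom_seq, paste, character(1), collapse = ""))
  write_fasta(genome_set, paths$genome)

  cds_by_id <- stats::setNames(
    vapply(genes, `[[`, character(1), "cds"),
    vapply(genes, `[[`, character(1), "id"))
  cds_by_id <- cds_by_id[ord_ids]
  cds_set <- Biostrings::DNAStringSet(cds_by_id)
  write_fasta(cds_set, paths$cds)
  prot_set <- Biostrings::AAStringSet(
    vapply(as.character(Biostrings::translate(cds_set)), identity, character(1)))
  names(prot_set) <- names(cds_set)
  write_fasta(prot_set, paths$proteins)

  writeLines(.gff3_lines(genes, cfg), paths$gff)
  writeLines(c("# gene\taccession\tevalue\tenv_start\tenv_end",
               unlist(hit_rows)), paths$domains)
  writeLines(rescue_ids, paths$rescue)

  ref_set <- Biostrings::AAStringSet(as.character(Biostrings::translate(
    Biostrings::DNAStringSet(unlist(ref_cds[labels])))))
  names(ref_set) <- ref_truth$leaf
  write_fasta(ref_set, paths$ref_proteins)
  .write_tsv(ref_truth, paths$ref_labels)

  expr <- .simulate_expression_impl(cfg, unname(sort(fam_ids)), paths)

  truth <- list(genes = gene_truth, family = family_truth,
                tandem = tandem_truth, tandem_pairs = tandem_pairs,
                segmental = seg_truth, promoters = promoter_truth,
                references = ref_truth, expression = expr$truth,
                qpcr = expr$qpcr)
  .write_tsv(gene_truth, p("truth", "genes.tsv"))
  .write_tsv(family_truth, p("truth", "family.tsv"))
  .write_tsv(tandem_truth, p("truth", "tandem.tsv"))
  .write_tsv(tandem_pairs, p("truth", "tandem_pairs.tsv"))
  .write_tsv(seg_truth, p("truth", "segmental.tsv"))
  .write_tsv(promoter_truth, p("truth", "promoters.tsv"))
  .write_tsv(ref_truth, p("truth", "references.tsv"))
  .write_tsv(expr$truth, p("truth", "expression.tsv"))
  .write_tsv(expr$qpcr, p("truth", "qpcr.tsv"))

  bundle <- structure(list(dir = out_dir, paths = paths, truth = truth,
                           config = cfg), class = "sim_bundle")
  if (self_check) .sim_self_check(bundle)
  bundle
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

# Hand-rolled GFF3 emitter: gene -> mRNA (flagged primary) -> exon/CDS,
# CDS phase computed in transcript orientation.
.gff3_lines <- function(genes, cfg) {
  header <- c("##gff-version 3",
              sprintf("##sequence-region chr%d 1 %d",
                      seq_len(cfg$n_chrom), as.integer(cfg$chrom_len)))
  ids <- vapply(genes, `[[`, character(1), "id")
  ord <- order(vapply(genes, `[[`, character(1), "chrom"),
               vapply(genes, `[[`, integer(1), "start"))
  body <- lapply(genes[ord], function(g) {
    tx <- paste0(g$id, ".1")
    n <- length(g$exon_start)
    lens <- g$exon_end - g$exon_start + 1L
    tx_order <- if (g$strand == "+") seq_len(n) else rev(seq_len(n))
    phase <- integer(n)
    cum <- 0L
    for (e in tx_order) {
      phase[e] <- (3L - cum %% 3L) %% 3L
      cum <- cum + lens[e]
    }
    c(sprintf("%s\tlrrsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$chrom, g$start, g$end, g$strand, g$id),
      sprintf("%s\tlrrsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s;primary=true",
              g$chrom, g$start, g$end, g$strand, tx, g$id),
      sprintf("%s\tlrrsim\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
              g$chrom, g$exon_start, g$exon_end, g$strand, tx,
              seq_len(n), tx),
      sprintf("%s\tlrrsim\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s",
              g$chrom, g$exon_start, g$exon_end, g$strand, phase, tx, tx))
  })
  c(header, unlist(body))
}

# Splice a gene's CDS back out of the genome using the annotation.
.splice_cds <- function(genome, annotation, gene_id) {
  g <- annotation$genes[annotation$genes$gene_id == gene_id, , drop = FALSE]
  cd <- select_primary_transcript(annotation, gene_id)$cds
  chunks <- vapply(seq_len(nrow(cd)), function(i)
    as.character(Biostrings::subseq(genome[[g$chrom]], cd$start[i], cd$end[i])),
    character(1))
  s <- paste(chunks, collapse = "")
  if (g$strand == "-") s <- revcomp_chr(s)
  s
}

# Read the written bundle back with the package's own parsers and verify
# it against the truth tables.
.sim_self_check <- function(bundle) {
  tr <- bundle$truth
  ann <- read_gff3(bundle$paths$gff)
  if (nrow(ann$genes) != nrow(tr$genes))
    stop("self-check: gene count mismatch")
  genome <- read_fasta(bundle$paths$genome, "dna")
  if (!all(Biostrings::width(genome) == bundle$config$chrom_len))
    stop("self-check: chromosome length mismatch")
  prot <- read_fasta(bundle$paths$proteins, "protein")
  if (!all(Biostrings::width(prot)[match(tr$genes$gene_id, names(prot))] ==
           tr$genes$protein_length))
    stop("self-check: protein length mismatch")
  cds <- read_fasta(bundle$paths$cds, "dna")

  fam_ids <- tr$family$gene_id
  ec <- exon_counts(ann, fam_ids)
  want <- tr$genes$n_exons[match(fam_ids, tr$genes$gene_id)]
  if (!all(unname(ec[fam_ids]) == want))
    stop("self-check: family exon count mismatch")

  check_ids <- c(fam_ids, utils::head(tr$genes$gene_id[tr$genes$role ==
                                                       "background"], 5L))
  for (id in check_ids) {
    if (.splice_cds(genome, ann, id) != as.character(cds[[id]]))
      stop("self-check: spliced CDS mismatch for ", id)
  }

  hits <- read_domain_hits(bundle$paths$domains)
  strong <- filter_domain_hits(hits)
  hmm_set <- sort(unique(strong$gene_id[strong$domain_class == "LRR"]))
  want_hmm <- sort(unique(c(
    tr$family$gene_id[!tr$family$rescue_only],
    tr$genes$gene_id[tr$genes$subrole %in% c("lrr_only", "outlier")])))
  if (!identical(hmm_set, want_hmm))
    stop("self-check: HMM candidate set mismatch")
  calls <- call_architectures(tr$family$gene_id, hits, prot)
  if (!all(calls$is_family) ||
      !all(calls$n_lrr == tr$family$n_lrr) ||
      !all(calls$n_kinase == tr$family$n_kinase))
    stop("self-check: family architecture call mismatch")
  decoys <- tr$genes$gene_id[tr$genes$subrole %in%
                             c("lrr_only", "kinase_only", "decoy_rescue")]
  dcalls <- call_architectures(decoys, hits, prot)
  if (any(dcalls$is_family))
    stop("self-check: decoy passes the architecture rule")

  lib <- cis_element_library()
  for (id in fam_ids) {
    got <- scan_elements(extract_upstream(genome, ann, id), lib)
    rownames(got) <- NULL
    want_p <- tr$promoters[tr$promoters$gene_id == id,
                           c("motif", "offset", "strand"), drop = FALSE]
    want_p <- want_p[order(want_p$motif, want_p$offset), , drop = FALSE]
    rownames(want_p) <- NULL
    if (!identical(got, want_p))
      stop("self-check: promoter scan mismatch for ", id)
  }
  invisible(TRUE)
}
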