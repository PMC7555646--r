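#' All-vs-all protein anchor pairs by local alignment
#'
#' Aligns every protein pair with affine-gap Smith-Waterman (BLOSUM62, gap
#' opening 10, extension 0.5) and keeps pairs whose local score reaches
#' `min_score`. This plays the role of the self-vs-self BLASTp step that
#' feeds collinearity detection: duplicated family genes score far above
#' unrelated proteins, which stay below the default threshold. Pair ids are
#' stored in canonical (lexicographic) order.
#'
#' @param proteins Named `AAStringSet` with at least 2 sequences.
#' @param min_score Minimum local alignment score (default 100).
#' @param gap_opening,gap_extension Affine gap penalties.
#' @return Data frame `gene_a`, `gene_b`, `score`, sorted by decreasing
#'   score.
#' @export
find_anchor_pairs <- function(proteins, min_score = 100,
                              gap_opening = 10, gap_extension = 0.5) {
  if (length(proteins) < 2L) stop("need at least 2 proteins")
  ids <- names(proteins)
  res <- list()
  for (i in seq_len(length(proteins) - 1L)) {
    rest <- proteins[seq.int(i + 1L, length(proteins))]
    sc <- Biostrings::pairwiseAlignment(
      pattern = rest, subject = proteins[[i]], type = "local",
      substitutionMatrix = "BLOSUM62",
      gapOpening = gap_opening, gapExtension = gap_extension,
      scoreOnly = TRUE)
    keep <- sc >= min_score
    if (any(keep)) {
      a <- pmin(ids[i], names(rest)[keep])
      b <- pmax(ids[i], names(rest)[keep])
      res[[length(res) + 1L]] <- data.frame(gene_a = a, gene_b = b,
                                            score = sc[keep],
                                            stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L)
    return(data.frame(gene_a = character(), gene_b = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  out[order(-out$score, out$gene_a, out$gene_b), , drop = FALSE]
}

#' Detect tandem-duplication clusters (200-kb rule)
#'
#' Family genes on one chromosome form a tandem cluster when two or more of
#' them are chained by single linkage with consecutive inter-gene distance
#' at most `max_gap` (default 200 kb). Distance is measured end-to-start of
#' consecutive genes by default (`"end_to_start"`); `"start_to_start"` is
#' available as an alternative convention. Genes on unplaced scaffolds
#' (chromosome name matching `scaffold_pattern`) are skipped with a
#' message. Clustering is invariant to the input order of `family_ids`.
#'
#' @param family_ids Character vector of family gene ids.
#' @param annotation A `genome_annotation`.
#' @param max_gap Maximum inter-gene distance in bp (default 200000).
#' @param mode Distance convention.
#' @param scaffold_pattern Regex marking unplaced sequences.
#' @return List of clusters; each is a list with `chrom`, `members`
#'   (ordered by position), `span` (first start to last end), `n_pairs`
#'   (`length(members) - 1`).
#' @export
detect_tandem_clusters <- function(family_ids, annotation, max_gap = 200000,
                                   mode = c("end_to_start", "start_to_start"),
                                   scaffold_pattern = "^(scaffold|contig)") {
  mode <- match.arg(mode)
  g <- annotation$genes[annotation$genes$gene_id %in% family_ids, , drop = FALSE]
  unplaced <- grepl(scaffold_pattern, g$chrom)
  if (any(unplaced))
    message(sum(unplaced), " family gene(s) on unplaced scaffolds skipped")
  g <- g[!unplaced, , drop = FALSE]
  clusters <- list()
  for (chrom in sort(unique(g$chrom))) {
    cg <- g[g$chrom == chrom, , drop = FALSE]
    cg <- cg[order(cg$start, cg$gene_id), , drop = FALSE]
    if (nrow(cg) < 2L) next
    gap <- if (mode == "end_to_start") {
      cg$start[-1L] - cg$end[-nrow(cg)]
    } else {
      cg$start[-1L] - cg$start[-nrow(cg)]
    }
    brk <- c(0L, cumsum(gap > max_gap))
    for (b in unique(brk)) {
      idx <- which(brk == b)
      if (length(idx) < 2L) next
      clusters[[length(clusters) + 1L]] <- list(
        chrom = chrom,
        members = cg$gene_id[idx],
        span = max(cg$end[idx]) - min(cg$start[idx]) + 1L,
        n_pairs = length(idx) - 1L)
    }
  }
  clusters
}

#' Count tandem-duplication gene pairs
#'
#' @param clusters Output of [detect_tandem_clusters()].
#' @param convention `"consecutive"` (a k-gene cluster contributes k-1
#'   pairs, the default) or `"all_pairs"` (k choose 2).
#' @return Integer pair count.
#' @export
tandem_pair_count <- function(clusters, convention = c("consecutive", "all_pairs")) {
  convention <- match.arg(convention)
  if (length(clusters) == 0L) return(0L)
  sizes <- vapply(clusters, function(cl) length(cl$members), integer(1))
  as.integer(sum(if (convention == "consecutive") sizes - 1L
                 else sizes * (sizes - 1L) / 2))
}

# Gene rank lookup: position index among all genes on each chromosome.
gene_ranks <- function(annotation) {
  g <- annotation$genes
  rank <- integer(nrow(g))
  for (chrom in unique(g$chrom)) {
    k <- g$chrom == chrom
    rank[k] <- rank(g$start[k], ties.method = "first")
  }
  data.frame(gene_id = g$gene_id, chrom = g$chrom, rank = rank,
             stringsAsFactors = FALSE)
}

# Longest monotonic anchor chain by dynamic programming in rank space.
# a: data frame with rank_a, rank_b, score. Returns indices of best chain
# (ties by higher total score), for one orientation.
.best_chain <- function(a, orientation, max_rank_gap) {
  m <- nrow(a)
  ord <- order(a$rank_a, if (orientation == "same") a$rank_b else -a$rank_b)
  ra <- a$rank_a[ord]; rb <- a$rank_b[ord]; sc <- a$score[ord]
  len <- rep(1L, m); tot <- sc; prev <- rep(NA_integer_, m)
  for (j in seq_len(m)) {
    for (i in seq_len(j - 1L)) {
      ok_a <- ra[j] > ra[i] && ra[j] - ra[i] <= max_rank_gap
      ok_b <- if (orientation == "same") {
        rb[j] > rb[i] && rb[j] - rb[i] <= max_rank_gap
      } else {
        rb[j] < rb[i] && rb[i] - rb[j] <= max_rank_gap
      }
      if (ok_a && ok_b) {
        cand_len <- len[i] + 1L
        cand_tot <- tot[i] + sc[j]
        if (cand_len > len[j] || (cand_len == len[j] && cand_tot > tot[j])) {
          len[j] <- cand_len; tot[j] <- cand_tot; prev[j] <- i
        }
      }
    }
  }
  best <- which.max(len + tot / (sum(sc) + 1))   # length first, score tiebreak
  chain <- integer(0)
  k <- best
  while (!is.na(k)) { chain <- c(k, chain); k <- prev[k] }
  list(idx = ord[chain], length = len[best], score = tot[best])
}

# Shared chaining core over anchors annotated with chrom/rank on both sides.
.chain_blocks <- function(anchors, min_anchors, max_rank_gap) {
  blocks <- list()
  if (nrow(anchors) == 0L) return(blocks)
  anchors$pair_key <- paste(anchors$chrom_a, anchors$chrom_b, sep = "~")
  for (key in unique(anchors$pair_key)) {
    pool <- anchors[anchors$pair_key == key, , drop = FALSE]
    repeat {
      if (nrow(pool) < min_anchors) break
      same <- .best_chain(pool, "same", max_rank_gap)
      inv <- .best_chain(pool, "inverted", max_rank_gap)
      pick <- if (same$length > inv$length ||
                  (same$length == inv$length && same$score >= inv$score)) {
        list(res = same, orientation = "same")
      } else list(res = inv, orientation = "inverted")
      if (pick$res$length < min_anchors) break
      chain <- pool[pick$res$idx, , drop = FALSE]
      blocks[[length(blocks) + 1L]] <- list(
        chrom_a = chain$chrom_a[1L], chrom_b = chain$chrom_b[1L],
        anchors = chain[, c("gene_a", "gene_b", "rank_a", "rank_b", "score")],
        orientation = pick$orientation,
        chain_score = sum(chain$score))
      pool <- pool[-pick$res$idx, , drop = FALSE]
    }
  }
  # post-hoc invariant: strict monotonicity on both rank sequences
  for (b in blocks) {
    da <- diff(b$anchors$rank_a); db <- diff(b$anchors$rank_b)
    stopifnot(all(da > 0), all(db > 0) || all(db < 0))
  }
  blocks
}

#' Detect collinear (segmental duplication) blocks within one genome
#'
#' Anchors (homologous gene pairs) are grouped by chromosome pair and
#' chained by dynamic programming in rank space: a block is a maximal run
#' of anchors whose gene ranks are strictly monotonic on both chromosomes
#' (increasing/increasing = `same` orientation, increasing/decreasing =
#' `inverted`) with per-step rank gaps at most `max_rank_gap`. The best
#' chain is extracted greedily, its anchors removed, and chaining repeats;
#' chains shorter than `min_anchors` are discarded.
#'
#' @param anchors Data frame `gene_a`, `gene_b`, `score` (see
#'   [find_anchor_pairs()]).
#' @param annotation A `genome_annotation` providing chromosome and rank
#'   for every anchor gene.
#' @param min_anchors Minimum anchors per block (default 3).
#' @param max_rank_gap Maximum per-step rank gap (default 25).
#' @return List of blocks (`chrom_a`, `chrom_b`, `anchors`, `orientation`,
#'   `chain_score`).
#' @export
detect_collinear_blocks <- function(anchors, annotation, min_anchors = 3L,
                                    max_rank_gap = 25L) {
  rk <- gene_ranks(annotation)
  look <- function(g, what) {
    i <- match(g, rk$gene_id)
    if (anyNA(i)) stop("anchor gene absent from annotation: ", g[which(is.na(i))[1L]])
    rk[[what]][i]
  }
  if (nrow(anchors) == 0L) return(list())
  a <- data.frame(gene_a = anchors$gene_a, gene_b = anchors$gene_b,
                  score = anchors$score,
                  chrom_a = look(anchors$gene_a, "chrom"),
                  rank_a = look(anchors$gene_a, "rank"),
                  chrom_b = look(anchors$gene_b, "chrom"),
                  rank_b = look(anchors$gene_b, "rank"),
                  stringsAsFactors = FALSE)
  # canonicalize chromosome pair orientation
  flip <- a$chrom_a > a$chrom_b
  a[flip, c("gene_a", "gene_b", "chrom_a", "chrom_b", "rank_a", "rank_b")] <-
    a[flip, c("gene_b", "gene_a", "chrom_b", "chrom_a", "rank_b", "rank_a")]
  .chain_blocks(a, min_anchors, max_rank_gap)
}

#' Cross-species synteny blocks
#'
#' As [detect_collinear_blocks()], with `gene_a` looked up in `annot_a` and
#' `gene_b` in `annot_b`.
#'
#' @param annot_a,annot_b `genome_annotation` objects for the two genomes.
#' @param anchors Data frame `gene_a` (genome A), `gene_b` (genome B),
#'   `score`.
#' @param min_anchors,max_rank_gap See [detect_collinear_blocks()].
#' @return List of blocks.
#' @export
cross_species_synteny <- function(annot_a, annot_b, anchors,
                                  min_anchors = 3L, max_rank_gap = 25L) {
  if (nrow(anchors) == 0L) return(list())
  rka <- gene_ranks(annot_a); rkb <- gene_ranks(annot_b)
  ia <- match(anchors$gene_a, rka$gene_id)
  ib <- match(anchors$gene_b, rkb$gene_id)
  if (anyNA(ia)) stop("anchor gene absent from annotation: ",
                      anchors$gene_a[which(is.na(ia))[1L]])
  if (anyNA(ib)) stop("anchor gene absent from annotation: ",
                      anchors$gene_b[which(is.na(ib))[1L]])
  a <- data.frame(gene_a = anchors$gene_a, gene_b = anchors$gene_b,
                  score = anchors$score,
                  chrom_a = rka$chrom[ia], rank_a = rka$rank[ia],
                  chrom_b = rkb$chrom[ib], rank_b = rkb$rank[ib],
                  stringsAsFactors = FALSE)
  .chain_blocks(a, min_anchors, max_rank_gap)
}

#' Chromosome map of family genes
#'
#' @param annotation A `genome_annotation`.
#' @param family_ids Character vector of family gene ids (may be empty).
#' @param clusters Optional tandem clusters from [detect_tandem_clusters()].
#' @param scaffold_pattern Regex marking unplaced sequences.
#' @return List with `counts` (per-chromosome family gene counts),
#'   `positions` (gene, chrom, midpoint), `clusters` (chrom, span bounds),
#'   and `unplaced` (gene ids on scaffolds or absent from the annotation).
#' @export
chromosome_map <- function(annotation, family_ids, clusters = NULL,
                           scaffold_pattern = "^(scaffold|contig)") {
  g <- annotation$genes[match(family_ids, annotation$genes$gene_id), , drop = FALSE]
  absent <- family_ids[is.na(g$gene_id)]
  g <- g[!is.na(g$gene_id), , drop = FALSE]
  unpl <- grepl(scaffold_pattern, g$chrom)
  positions <- data.frame(gene_id = g$gene_id[!unpl], chrom = g$chrom[!unpl],
                          midpoint = (g$start[!unpl] + g$end[!unpl]) / 2,
                          stringsAsFactors = FALSE)
  counts <- if (nrow(positions)) table(positions$chrom) else table(character(0))
  cl <- if (length(clusters)) {
    data.frame(chrom = vapply(clusters, `[[`, character(1), "chrom"),
               n_members = vapply(clusters, function(x) length(x$members), integer(1)),
               span = vapply(clusters, `[[`, numeric(1), "span"),
               stringsAsFactors = FALSE)
  } else data.frame(chrom = character(), n_members = integer(), span = numeric())
  list(counts = counts, positions = positions, clusters = cl,
       unplaced = c(absent, g$gene_id[unpl]))
}

#' Write a Circos-style link file for synteny blocks
#'
#' One line per block: `chrom_a start_a end_a chrom_b start_b end_b`, where
#' the spans cover the first to last anchor gene on each side.
#'
#' @param blocks List of blocks.
#' @param annotation A `genome_annotation` (for anchor coordinates).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_links <- function(blocks, annotation, path) {
  g <- annotation$genes
  rows <- lapply(blocks, function(b) {
    ga <- g[match(b$anchors$gene_a, g$gene_id), ]
    gb <- g[match(b$anchors$gene_b, g$gene_id), ]
    sprintf("%s\t%d\t%d\t%s\t%d\t%d", b$chrom_a, min(ga$start), max(ga$end),
            b$chrom_b, min(gb$start), max(gb$end))
  })
  writeLines(unlist(rows), path)
  invisible(path)
}

#' Write family gene positions as BED
#'
#' BED uses 0-based half-open coordinates; conversion happens here.
#'
#' @param family_ids Gene ids.
#' @param annotation A `genome_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_family_bed <- function(family_ids, annotation, path) {
  g <- annotation$genes[match(family_ids, annotation$genes$gene_id), , drop = FALSE]
  g <- g[!is.na(g$gene_id), , drop = FALSE]
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", g$chrom, g$start - 1L, g$end,
                     g$gene_id, g$strand), path)
  invisible(path)
}
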