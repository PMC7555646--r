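#' Exon counts of family genes
#'
#' Counts exon intervals on the primary transcript of each gene (see
#' [select_primary_transcript()]).
#'
#' @param annotation A `genome_annotation`.
#' @param gene_ids Character vector of gene ids (all must be annotated).
#' @return Named integer vector gene -> exon count.
#' @export
exon_counts <- function(annotation, gene_ids) {
  absent <- setdiff(gene_ids, annotation$genes$gene_id)
  if (length(absent)) stop("gene missing from annotation: ", absent[1L])
  vapply(gene_ids, function(g) {
    nrow(select_primary_transcript(annotation, g)$exons)
  }, integer(1))
}

#' Per-subgroup exon-count statistics
#'
#' Summarizes exon counts per subgroup in the format of published
#' gene-structure tables: gene number, maximum, minimum, mean and sample
#' standard deviation (n-1 denominator; 0 for single-gene subgroups), plus
#' a `Total` row giving the assigned-gene count. Mean and SD are returned
#' at full precision; round to 2 decimals for display.
#'
#' @param counts Named integer vector from [exon_counts()].
#' @param assignments Data frame from [assign_subgroups()] (columns
#'   `gene_id`, `subgroup`, `status`), or a named character vector
#'   gene -> subgroup. Unclassified genes are excluded with a message.
#' @return Data frame `subgroup`, `n_genes`, `max_exons`, `min_exons`,
#'   `mean_exons`, `sd_exons`.
#' @export
subgroup_stats <- function(counts, assignments) {
  if (is.data.frame(assignments)) {
    keep <- assignments$status == "assigned"
    lab <- stats::setNames(assignments$subgroup[keep], assignments$gene_id[keep])
  } else {
    lab <- assignments[!is.na(assignments)]
  }
  n_dropped <- sum(!names(counts) %in% names(lab))
  if (n_dropped > 0)
    message(n_dropped, " gene(s) without subgroup assignment excluded")
  counts <- counts[names(counts) %in% names(lab)]
  lab <- lab[names(counts)]
  groups <- unique(lab)
  rows <- lapply(groups, function(g) {
    x <- counts[lab == g]
    data.frame(subgroup = g, n_genes = length(x),
               max_exons = max(x), min_exons = min(x),
               mean_exons = mean(x),
               sd_exons = if (length(x) > 1L) stats::sd(x) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$subgroup), , drop = FALSE]
  total <- data.frame(subgroup = "Total", n_genes = sum(out$n_genes),
                      max_exons = NA_integer_, min_exons = NA_integer_,
                      mean_exons = NA_real_, sd_exons = NA_real_,
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  rbind(out, total)
}
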