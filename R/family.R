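#' Screen domain hits by E-value
#'
#' Keeps hits whose full-sequence E-value is strictly less than `e_max`
#' (default 0.001, the screening threshold used for HMM candidate sets).
#' Input order is preserved; an empty result is allowed.
#'
#' @param hits Domain hit data frame from [read_domain_hits()].
#' @param e_max Positive E-value ceiling; comparison is strict (`<`).
#' @return The surviving rows of `hits`.
#' @export
filter_domain_hits <- function(hits, e_max = 1e-3) {
  stopifnot(is.numeric(e_max), e_max > 0)
  hits[hits$evalue < e_max, , drop = FALSE]
}

# Count LRR hits after merging overlapping envelopes, so that overlapping
# matches from different LRR-clan profiles on the same residues count once.
merged_lrr_count <- function(hits) {
  lrr <- hits[hits$domain_class == "LRR", , drop = FALSE]
  if (nrow(lrr) == 0L) return(0L)
  length(IRanges::reduce(IRanges::IRanges(lrr$env_start, lrr$env_end)))
}

#' Call the LRR+kinase domain architecture of one gene
#'
#' A candidate is a family member when its protein carries at least one LRR
#' domain and at least one kinase domain. LRR hits whose envelopes overlap
#' (matches of different LRR-clan profiles to the same residues) are merged
#' before counting; kinase hits are counted as-is, so receptor kinases with
#' two kinase domains report `n_kinase = 2`.
#'
#' @param gene_id Gene identifier.
#' @param hits Domain hits; all rows must belong to `gene_id`.
#' @param protein The gene's protein sequence (character, `AAString`, or a
#'   single-element `AAStringSet`). Required; used for `protein_length`.
#' @return A one-row data frame: `gene_id`, `n_lrr`, `n_kinase`,
#'   `is_family`, `protein_length`.
#' @export
call_architecture <- function(gene_id, hits, protein) {
  if (missing(protein) || is.null(protein))
    stop("protein sequence missing for gene ", gene_id)
  if (methods::is(protein, "XStringSet")) protein <- protein[[1L]]
  plen <- nchar(as.character(protein))
  if (nrow(hits) && any(hits$gene_id != gene_id))
    stop("hits contain rows for other genes than ", gene_id)
  n_lrr <- merged_lrr_count(hits)
  n_kinase <- sum(hits$domain_class == "kinase")
  data.frame(gene_id = gene_id, n_lrr = n_lrr, n_kinase = n_kinase,
             is_family = n_lrr >= 1L && n_kinase >= 1L,
             protein_length = plen, stringsAsFactors = FALSE)
}

#' Architecture calls for a set of genes
#'
#' Convenience wrapper applying [call_architecture()] to every id in
#' `gene_ids`, pairing each with its hits and protein.
#'
#' @param gene_ids Character vector of gene ids.
#' @param hits Domain hit data frame (any genes; subset per id).
#' @param proteins Named `AAStringSet` (or named character vector) holding a
#'   protein per gene id.
#' @return Data frame with one row per gene.
#' @export
call_architectures <- function(gene_ids, hits, proteins) {
  rows <- lapply(gene_ids, function(g) {
    if (!g %in% names(proteins)) stop("protein sequence missing for gene ", g)
    call_architecture(g, hits[hits$gene_id == g, , drop = FALSE], proteins[g])
  })
  do.call(rbind, rows)
}

#' Merge HMM-screen and similarity-rescue candidate sets into a family
#'
#' Takes the union of the HMM candidate set and the rescue candidate set,
#' keeps the genes whose architecture call satisfies the LRR+kinase rule,
#' and records per-member provenance (`hmm_search`, `rescue`, or `both`).
#' Candidates failing the architecture rule are listed in `removed` with
#' reason `"architecture"`. The operation is symmetric in its two input
#' sets and orders members deterministically by gene id.
#'
#' @param hmm_set,rescue_set Character vectors of candidate gene ids.
#' @param calls Architecture call data frame covering every candidate
#'   (see [call_architectures()]).
#' @return A `family_set`: list with data frames `members` (`gene_id`,
#'   `n_lrr`, `n_kinase`, `protein_length`, `provenance`) and `removed`
#'   (`gene_id`, `reason`, `detail`).
#' @export
merge_candidates <- function(hmm_set, rescue_set, calls) {
  ids <- sort(union(hmm_set, rescue_set))
  miss <- ids[!ids %in% calls$gene_id]
  if (length(miss)) stop("no architecture call for candidate: ", miss[1L])
  calls <- calls[match(ids, calls$gene_id), , drop = FALSE]
  prov <- ifelse(ids %in% hmm_set & ids %in% rescue_set, "both",
                 ifelse(ids %in% hmm_set, "hmm_search", "rescue"))
  keep <- calls$is_family
  members <- data.frame(gene_id = ids[keep],
                        n_lrr = calls$n_lrr[keep],
                        n_kinase = calls$n_kinase[keep],
                        protein_length = calls$protein_length[keep],
                        provenance = prov[keep],
                        stringsAsFactors = FALSE)
  removed <- data.frame(gene_id = ids[!keep],
                        reason = rep("architecture", sum(!keep)),
                        detail = sprintf("n_lrr=%d n_kinase=%d",
                                         calls$n_lrr[!keep], calls$n_kinase[!keep]),
                        stringsAsFactors = FALSE)
  structure(list(members = members, removed = removed), class = "family_set")
}

#' @export
print.family_set <- function(x, ...) {
  cat(sprintf("family_set: %d members, %d removed\n",
              nrow(x$members), nrow(x$removed)))
  invisible(x)
}

#' Prune family members distant from all reference sequences on a tree
#'
#' Mirrors the manual curation step in which candidate sequences falling far
#' from every known family reference on the phylogeny are discarded as
#' likely false positives. A member is pruned when its patristic distance to
#' the nearest labeled reference leaf exceeds `max_dist`.
#'
#' @param family A `family_set`.
#' @param tree An [ape::phylo] containing every member and at least one
#'   reference leaf.
#' @param references Character vector of reference leaf names.
#' @param max_dist Patristic-distance ceiling in substitutions per site
#'   (default 1.0).
#' @return The pruned `family_set`; removals appended to `removed` with
#'   reason `"tree_distance"` and the observed distance in `detail`.
#' @export
prune_by_tree <- function(family, tree, references, max_dist = 1.0) {
  stopifnot(inherits(family, "family_set"), inherits(tree, "phylo"))
  references <- intersect(references, tree$tip.label)
  if (length(references) == 0L) stop("tree contains no reference leaves")
  absent <- setdiff(family$members$gene_id, tree$tip.label)
  if (length(absent)) stop("family member absent from tree: ", absent[1L])
  pd <- stats::cophenetic(tree)
  nearest <- apply(pd[family$members$gene_id, references, drop = FALSE], 1L, min)
  drop <- nearest > max_dist
  if (any(drop)) {
    removed <- data.frame(gene_id = family$members$gene_id[drop],
                          reason = "tree_distance",
                          detail = sprintf("nearest_reference=%.4f", nearest[drop]),
                          stringsAsFactors = FALSE)
    family$removed <- rbind(family$removed, removed)
    family$members <- family$members[!drop, , drop = FALSE]
  }
  family
}

#' Summarize a confirmed family
#'
#' @param family A non-empty `family_set`.
#' @return List with `n_members`, `length_min`, `length_max`, `length_mean`,
#'   and `n_multi_kinase` (members with two or more kinase domains).
#' @export
summarize_family <- function(family) {
  stopifnot(inherits(family, "family_set"))
  m <- family$members
  if (nrow(m) == 0L) stop("family is empty")
  list(n_members = nrow(m),
       length_min = min(m$protein_length),
       length_max = max(m$protein_length),
       length_mean = mean(m$protein_length),
       n_multi_kinase = sum(m$n_kinase >= 2L))
}
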