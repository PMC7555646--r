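#' Pairwise p-distance matrix from an aligned protein set
#'
#' The p-distance between two aligned sequences is the proportion of
#' compared sites at which they differ (amino-acid differences per site).
#' Under `pairwise_deletion` a site is compared when neither member of the
#' pair is gapped; under `complete_deletion` columns gapped in any row are
#' removed first.
#'
#' @param alignment Named `AAStringSet` or named character vector of
#'   equal-length aligned sequences (at least 2).
#' @param gap_mode `"pairwise_deletion"` (default) or `"complete_deletion"`.
#' @return Symmetric numeric matrix with taxa as dimnames; values in
#'   \[0, 1\], zero diagonal.
#' @export
p_distance_matrix <- function(alignment,
                              gap_mode = c("pairwise_deletion", "complete_deletion")) {
  gap_mode <- match.arg(gap_mode)
  m <- alignment_matrix(alignment)
  if (nrow(m) < 2L) stop("need at least 2 taxa")
  gap <- m == "-" | m == "."
  if (gap_mode == "complete_deletion") {
    keep <- colSums(gap) == 0L
    m <- m[, keep, drop = FALSE]
    gap <- gap[, keep, drop = FALSE]
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ok <- !gap[i, ] & !gap[j, ]
      nc <- sum(ok)
      if (nc == 0L)
        stop(sprintf("no comparable sites between '%s' and '%s'",
                     rownames(m)[i], rownames(m)[j]))
      d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / nc
    }
  }
  d
}

# Coerce an alignment to a character matrix (taxa x columns), validating
# equal lengths and presence of names.
alignment_matrix <- function(alignment) {
  if (methods::is(alignment, "XStringSet")) {
    seqs <- as.character(alignment)
  } else {
    seqs <- as.character(alignment)
    names(seqs) <- names(alignment)
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("alignment sequences must be named")
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("alignment rows have unequal lengths")
  if (w == 0L) stop("alignment has zero columns")
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- names(seqs)
  m
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: at each step the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)` is joined, with
#' ties broken by the smallest `(i, j)` pair in current taxon order, and
#' pendant branch lengths assigned by the two-point formulas. Negative
#' branch lengths are clamped to zero. On an additive distance matrix the
#' generating tree is recovered exactly (topology and branch lengths).
#'
#' @param D Symmetric non-negative distance matrix with taxon dimnames.
#' @return An unrooted [ape::phylo] (trifurcating root representation; a
#'   two-taxon input yields a single split edge).
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (is.null(rownames(D))) stop("distance matrix needs taxon dimnames")
  if (any(D < 0)) stop("distance matrix has negative entries")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix is not symmetric")
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 taxa")
  fmt <- function(x) sprintf("%.15g", max(x, 0))
  labels <- rownames(D)
  nodes <- labels
  while (length(nodes) > 3L) {
    n <- length(nodes)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q == qmin, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    bi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (n - 2))
    bj <- D[i, j] - bi
    newnode <- sprintf("(%s:%s,%s:%s)", nodes[i], fmt(bi), nodes[j], fmt(bj))
    dk <- (D[i, -c(i, j)] + D[j, -c(i, j)] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D <- D[keep, keep, drop = FALSE]
    D <- rbind(cbind(D, dk), c(dk, 0))
    nodes <- c(nodes[keep], newnode)
    rownames(D) <- colnames(D) <- NULL
  }
  newick <- if (length(nodes) == 2L) {
    d <- D[1L, 2L]
    sprintf("(%s:%s,%s:%s);", nodes[1L], fmt(d / 2), nodes[2L], fmt(d / 2))
  } else {
    a <- (D[1L, 2L] + D[1L, 3L] - D[2L, 3L]) / 2
    b <- (D[1L, 2L] + D[2L, 3L] - D[1L, 3L]) / 2
    c3 <- (D[1L, 3L] + D[2L, 3L] - D[1L, 2L]) / 2
    sprintf("(%s:%s,%s:%s,%s:%s);",
            nodes[1L], fmt(a), nodes[2L], fmt(b), nodes[3L], fmt(c3))
  }
  ape::read.tree(text = newick)
}

# Canonical bipartition keys of a tree's internal edges. Each key is the
# sorted leaf set on the side NOT containing the alphabetically first leaf,
# collapsed with "|"; trivial (pendant) splits are excluded.
split_keys <- function(tree) {
  tips <- tree$tip.label
  anchor <- sort(tips)[1L]
  pp <- ape::prop.part(tree)
  keys <- character(0)
  for (k in seq_along(pp)) {
    side <- tips[pp[[k]]]
    if (length(side) == length(tips)) next   # root "split"
    if (anchor %in% side) side <- setdiff(tips, side)
    if (length(side) <= 1L || length(side) >= length(tips) - 1L) next
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the NJ tree from the full alignment, then resamples alignment
#' columns with replacement `n_reps` times; the support of each internal
#' edge is the percentage of replicate trees containing the same
#' bipartition. Deterministic given `seed`.
#'
#' @param alignment Named aligned sequences (see [p_distance_matrix()]).
#' @param n_reps Number of bootstrap replicates (>= 1; published surveys
#'   typically use 1000).
#' @param seed Integer RNG seed (required).
#' @param gap_mode Passed to [p_distance_matrix()].
#' @return The NJ [ape::phylo] with `node.label` holding integer support
#'   percentages (root label empty).
#' @export
bootstrap_supports <- function(alignment, n_reps = 1000L, seed,
                               gap_mode = "pairwise_deletion") {
  stopifnot(n_reps >= 1L)
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  m <- alignment_matrix(alignment)
  if (ncol(m) < 1L) stop("alignment has no columns")
  to_named <- function(mm) stats::setNames(apply(mm, 1L, paste, collapse = ""),
                                           rownames(mm))
  tree <- nj_tree(p_distance_matrix(to_named(m), gap_mode))
  keys <- split_keys(tree)
  hit <- stats::setNames(numeric(length(keys)), keys)
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      rep_tree <- nj_tree(p_distance_matrix(to_named(m[, cols, drop = FALSE]),
                                            gap_mode))
      rk <- split_keys(rep_tree)
      present <- keys %in% rk
      hit[present] <- hit[present] + 1
    }
  })
  support <- round(100 * hit / n_reps)
  # attach supports as internal node labels in ape convention
  tips <- tree$tip.label
  anchor <- sort(tips)[1L]
  pp <- ape::prop.part(tree)
  labs <- character(tree$Nnode)
  for (k in seq_along(pp)) {
    side <- tips[pp[[k]]]
    if (length(side) == length(tips)) { labs[k] <- ""; next }
    if (anchor %in% side) side <- setdiff(tips, side)
    key <- paste(sort(side), collapse = "|")
    labs[k] <- if (key %in% names(support)) as.character(support[[key]]) else ""
  }
  tree$node.label <- labs
  tree
}

#' Assign family members to reference-anchored subgroups
#'
#' Each unlabeled leaf receives the subgroup label of the smallest clade
#' (either side of a tree bipartition whose support passes `min_support`)
#' that contains the leaf together with at least one reference leaf, and
#' whose references all carry one label. Leaves for which no such clade
#' exists are reported `unclassified`. Labels must come from the packaged
#' 24-subgroup vocabulary ([lrr_subgroup_labels()]).
#'
#' @param tree An [ape::phylo], optionally with bootstrap `node.label`s
#'   (edges without a numeric label always pass the support filter).
#' @param reference_labels Named character vector: reference leaf name ->
#'   subgroup label.
#' @param min_support Minimum bootstrap percentage for an anchoring clade
#'   (default 50).
#' @return Data frame `gene_id`, `subgroup`, `support`, `status`.
#' @export
assign_subgroups <- function(tree, reference_labels, min_support = 50) {
  stopifnot(inherits(tree, "phylo"))
  refs <- intersect(names(reference_labels), tree$tip.label)
  if (length(refs) == 0L) stop("tree contains no reference leaves")
  bad <- setdiff(unique(reference_labels), lrr_subgroup_labels())
  if (length(bad)) stop("unknown subgroup label: ", bad[1L])
  tips <- tree$tip.label
  pp <- ape::prop.part(tree)
  labs <- tree$node.label
  clades <- list()
  supports <- numeric(0)
  add <- function(side, sup) {
    clades[[length(clades) + 1L]] <<- side
    supports[length(supports) + 1L] <<- sup
  }
  for (k in seq_along(pp)) {
    side <- tips[pp[[k]]]
    if (length(side) == length(tips)) next
    sup <- if (is.null(labs) || k > length(labs) || !nzchar(labs[k]) ||
               is.na(suppressWarnings(as.numeric(labs[k])))) NA_real_
           else as.numeric(labs[k])
    if (!is.na(sup) && sup < min_support) next
    add(side, sup)
    add(setdiff(tips, side), sup)
  }
  sizes <- lengths(clades)
  ord <- order(sizes)
  queries <- setdiff(tips, refs)
  res <- lapply(queries, function(q) {
    for (k in ord) {
      side <- clades[[k]]
      if (!q %in% side) next
      r <- intersect(side, refs)
      if (length(r) == 0L) next
      lab <- unique(unname(reference_labels[r]))
      if (length(lab) == 1L) {
        return(data.frame(gene_id = q, subgroup = lab,
                          support = supports[k], status = "assigned",
                          stringsAsFactors = FALSE))
      }
      # conflicting references in this clade: try the next larger one
    }
    data.frame(gene_id = q, subgroup = NA_character_, support = NA_real_,
               status = "unclassified", stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
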