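#' Average replicates into a condensed condition matrix
#'
#' @param em An [expression_matrix()].
#' @return Numeric matrix genes x conditions (arithmetic replicate means),
#'   conditions in order of first appearance.
#' @export
replicate_means <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  conds <- unique(em$samples$condition)
  out <- vapply(conds, function(cn) {
    cols <- em$samples$condition == cn
    if (!any(cols)) stop("condition without replicates: ", cn)
    rowMeans(em$values[, cols, drop = FALSE])
  }, numeric(nrow(em$values)))
  if (nrow(em$values) == 1L) out <- matrix(out, nrow = 1L,
                                           dimnames = list(rownames(em$values), conds))
  out
}

# Tissue-specificity score tau of one non-negative profile:
# sum_i (1 - x_i / x_max) / (N - 1); 0 for uniform, 1 for single-condition
# expression.
tau_score <- function(x) {
  xmax <- max(x)
  if (xmax == 0) return(NA_real_)
  sum(1 - x / xmax) / (length(x) - 1L)
}

#' Call tissue-specific and highly expressed genes
#'
#' A gene is called `specific` when its tau specificity score reaches
#' `tau_min` and the conditions within `fold_min` of the row maximum (the
#' called set) stand at least `fold_min`-fold above every other condition.
#' A gene failing the tau criterion is called `high` when its top condition
#' still exceeds `fold_min` times the row median (broad but biased
#' expression); otherwise `none`. All-zero rows get `none` with NA tau.
#'
#' @param cm Condensed matrix from [replicate_means()] (>= 2 conditions).
#' @param tau_min Minimum tau for a specific call (default 0.8).
#' @param fold_min Fold threshold (default 2).
#' @return Data frame `gene_id`, `tau`, `mode`, `called_conditions`
#'   (comma-separated, empty unless specific/high).
#' @export
specificity_calls <- function(cm, tau_min = 0.8, fold_min = 2) {
  stopifnot(ncol(cm) >= 2L)
  conds <- colnames(cm)
  rows <- lapply(seq_len(nrow(cm)), function(i) {
    x <- cm[i, ]
    tau <- tau_score(x)
    if (is.na(tau)) {
      return(data.frame(gene_id = rownames(cm)[i], tau = NA_real_,
                        mode = "none", called_conditions = "",
                        stringsAsFactors = FALSE))
    }
    xmax <- max(x)
    called <- x >= xmax / fold_min
    outside <- x[!called]
    sep_ok <- length(outside) == 0L || xmax >= fold_min * max(outside)
    if (tau >= tau_min && sep_ok) {
      mode <- "specific"
      cc <- paste(conds[called], collapse = ",")
    } else if (xmax >= fold_min * stats::median(x)) {
      mode <- "high"
      cc <- conds[which.max(x)]
    } else {
      mode <- "none"
      cc <- ""
    }
    data.frame(gene_id = rownames(cm)[i], tau = tau, mode = mode,
               called_conditions = cc, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Parse "genotype:time" condition labels.
parse_gt <- function(conds) {
  parts <- strsplit(conds, ":", fixed = TRUE)
  data.frame(condition = conds,
             genotype = vapply(parts, `[[`, character(1), 1L),
             time = as.numeric(vapply(parts, `[[`, character(1), 2L)),
             stringsAsFactors = FALSE)
}

#' Call expression peaks across a genotype-by-time course
#'
#' Condition labels must follow the `"genotype:time"` convention (time in
#' hours). The peak is the condition attaining the row maximum (ties go to
#' the earliest time, then to genotype order); a gene is `called` when its
#' peak mean reaches `fold_min` times the baseline condition mean. A zero
#' baseline with a nonzero peak yields infinite fold and a call.
#'
#' @param cm Condensed matrix from [replicate_means()] over
#'   genotype-by-time conditions.
#' @param baseline Baseline condition label (e.g. `"A17:0"`).
#' @param fold_min Fold-over-baseline threshold (default 2).
#' @param genotype_order Optional genotype preference for ties; defaults to
#'   order of first appearance in the columns.
#' @return Data frame `gene_id`, `peak_condition`, `genotype`, `time`,
#'   `fold_over_baseline`, `called`.
#' @export
peak_time_calls <- function(cm, baseline, fold_min = 2, genotype_order = NULL) {
  if (!baseline %in% colnames(cm)) stop("baseline condition not found: ", baseline)
  meta <- parse_gt(colnames(cm))
  if (is.null(genotype_order)) genotype_order <- unique(meta$genotype)
  gt_rank <- match(meta$genotype, genotype_order)
  rows <- lapply(seq_len(nrow(cm)), function(i) {
    x <- cm[i, ]
    xmax <- max(x)
    at_max <- which(x == xmax)
    pick <- at_max[order(meta$time[at_max], gt_rank[at_max])][1L]
    base <- x[[baseline]]
    fold <- if (base == 0) { if (xmax > 0) Inf else 0 } else xmax / base
    data.frame(gene_id = rownames(cm)[i],
               peak_condition = meta$condition[pick],
               genotype = meta$genotype[pick], time = meta$time[pick],
               fold_over_baseline = fold,
               called = fold >= fold_min && xmax > 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Deterministic heatmap leaf order by hierarchical clustering
#'
#' Rows are transformed (`log2(x+1)` by default, or row z-scores), then
#' clustered with average linkage on Euclidean distances. A constant matrix
#' (all pairwise distances zero) returns the input order, as do matrices
#' with fewer than 3 rows.
#'
#' @param cm Condensed expression matrix (>= 2 genes).
#' @param transform `"log2p1"` or `"zscore_row"`.
#' @return Character vector of gene ids in leaf order.
#' @export
heatmap_order <- function(cm, transform = c("log2p1", "zscore_row")) {
  transform <- match.arg(transform)
  stopifnot(nrow(cm) >= 2L)
  m <- switch(transform,
    log2p1 = log2(cm + 1),
    zscore_row = t(apply(cm, 1L, function(x) {
      s <- stats::sd(x)
      if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
    })))
  if (nrow(cm) == 2L) return(rownames(cm))
  d <- stats::dist(m)
  if (all(d == 0)) return(rownames(cm))
  hc <- stats::hclust(d, method = "average")
  rownames(cm)[hc$order]
}

#' Relative expression by the 2^-ddCt method
#'
#' For each target gene and sample, `dCt = Ct_target - Ct_reference` is
#' computed per replicate (replicates paired by index), `ddCt` subtracts
#' the mean dCt of the calibrator sample, and relative expression is
#' `2^-ddCt`. Per-sample replicate means and standard deviations of the
#' relative expression are reported.
#'
#' @param ct Data frame with columns `gene_id`, `sample_id`, `replicate`,
#'   `ct`.
#' @param reference_gene Normalizer gene id (must be measured in every
#'   sample in which a target is measured).
#' @param calibrator_sample Sample id whose mean dCt defines ddCt = 0.
#' @return Data frame `gene_id`, `sample_id`, `rel_expr` (mean of
#'   `2^-ddCt` over replicates), `rel_sd`, `n_reps`.
#' @export
delta_delta_ct <- function(ct, reference_gene, calibrator_sample) {
  need <- c("gene_id", "sample_id", "replicate", "ct")
  if (!all(need %in% names(ct))) stop("ct table needs columns: ",
                                      paste(need, collapse = ", "))
  ref <- ct[ct$gene_id == reference_gene, , drop = FALSE]
  if (nrow(ref) == 0L) stop("reference gene not in table: ", reference_gene)
  targets <- setdiff(unique(ct$gene_id), reference_gene)
  if (!calibrator_sample %in% ct$sample_id)
    stop("calibrator sample not in table: ", calibrator_sample)
  rows <- list()
  for (g in targets) {
    tg <- ct[ct$gene_id == g, , drop = FALSE]
    dct <- lapply(unique(tg$sample_id), function(s) {
      t_s <- tg[tg$sample_id == s, , drop = FALSE]
      r_s <- ref[ref$sample_id == s, , drop = FALSE]
      if (nrow(r_s) == 0L)
        stop("reference gene Ct missing for sample ", s)
      i <- match(t_s$replicate, r_s$replicate)
      if (anyNA(i)) stop("reference gene Ct missing for sample ", s,
                         " replicate ", t_s$replicate[which(is.na(i))[1L]])
      data.frame(sample_id = s, dct = t_s$ct - r_s$ct[i],
                 stringsAsFactors = FALSE)
    })
    dct <- do.call(rbind, dct)
    cal <- dct$dct[dct$sample_id == calibrator_sample]
    if (length(cal) == 0L)
      stop("calibrator sample has no measurements for gene ", g)
    ddct0 <- mean(cal)
    for (s in unique(dct$sample_id)) {
      rel <- 2^(-(dct$dct[dct$sample_id == s] - ddct0))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, sample_id = s, rel_expr = mean(rel),
        rel_sd = if (length(rel) > 1L) stats::sd(rel) else 0,
        n_reps = length(rel), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
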