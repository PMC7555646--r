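#' Simulate expression matrices with planted calls
#'
#' Generates the two expression datasets of the default bundle for a set of
#' family genes: a tissue atlas (replicated, with a planted
#' root/nodule-specific subset) and a genotype-by-time rhizobial-infection
#' course (with planted peak sets, most genes peaking in the
#' hyper-nodulating mutant at 12 h), plus a small qPCR Ct table whose
#' planted relative-expression ratios are recoverable by
#' [delta_delta_ct()]. Planted set sizes come from `cfg$expression`.
#'
#' @param cfg A [sim_config()].
#' @param gene_ids Family gene ids to simulate.
#' @param out_dir Optional directory; when given, `tissues.tsv`,
#'   `infection.tsv` and `ct.tsv` are written there.
#' @param seed Seed (defaults to `cfg$seed`); pass NULL to draw from the
#'   current stream.
#' @return List with `tissues` and `infection` ([expression_matrix()]
#'   objects), `ct` (data frame), `truth` and `qpcr` (planted-call tables).
#' @export
simulate_expression <- function(cfg, gene_ids, out_dir = NULL,
                                seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  paths <- if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    list(tissues = file.path(out_dir, "tissues.tsv"),
         infection = file.path(out_dir, "infection.tsv"),
         ct = file.path(out_dir, "ct.tsv"))
  } else NULL
  with_seed(seed, .simulate_expression_impl(cfg, gene_ids, paths))
}

.simulate_expression_impl <- function(cfg, gene_ids, paths = NULL) {
  ex <- cfg$expression
  n <- length(gene_ids)
  if (n < ex$n_peak12 + ex$n_peak48)
    stop("expression plan needs more genes than available")
  peak12 <- .pick(gene_ids, ex$n_peak12)
  rest <- setdiff(gene_ids, peak12)
  peak48 <- .pick(rest, ex$n_peak48)
  rest <- setdiff(rest, peak48)
  n_out <- ex$n_specific - ex$n_double_positive
  if (length(rest) < n_out || n_out < 0L)
    stop("expression plan cannot realize the specific set sizes")
  specific <- c(.pick(peak12, ex$n_double_positive), .pick(rest, n_out))

  nr <- ex$n_reps
  reps <- function(mean_vec) {
    vals <- rep(mean_vec, each = nr) +
      stats::rnorm(length(mean_vec) * nr, 0, ex$noise_sd)
    pmax(vals, 0)
  }
  base <- exp(stats::rnorm(n, log(30), 0.3))
  names(base) <- gene_ids

  ## tissue atlas
  tconds <- ex$tissues
  tmeans <- matrix(0, n, length(tconds), dimnames = list(gene_ids, tconds))
  for (g in gene_ids) {
    if (g %in% specific) {
      m <- base[g] * stats::runif(length(tconds), 0.9, 1.1)
      hi <- match(ex$specific_conditions, tconds)
      if (anyNA(hi)) stop("specific_conditions must be tissue labels")
      m[hi] <- base[g] * ex$fold * stats::runif(length(hi), 0.95, 1.05)
    } else {
      m <- base[g] * stats::runif(length(tconds), 0.8, 1.2)
    }
    tmeans[g, ] <- m
  }
  tvals <- t(apply(tmeans, 1L, reps))
  tissues <- expression_matrix(tvals, rep(tconds, each = nr),
                               rep(seq_len(nr), times = length(tconds)))

  ## infection time course
  iconds <- as.vector(vapply(ex$genotypes, function(gt)
    paste(gt, ex$times, sep = ":"), character(length(ex$times))))
  for (cond in c(ex$peak12_condition, ex$peak48_condition))
    if (!cond %in% iconds) stop("planned peak condition absent: ", cond)
  imeans <- matrix(0, n, length(iconds), dimnames = list(gene_ids, iconds))
  for (g in gene_ids) {
    m <- base[g] * stats::runif(length(iconds), 0.8, 1.2)
    if (g %in% peak12)
      m[match(ex$peak12_condition, iconds)] <- base[g] * ex$fold
    if (g %in% peak48)
      m[match(ex$peak48_condition, iconds)] <- base[g] * ex$fold
    imeans[g, ] <- m
  }
  ivals <- t(apply(imeans, 1L, reps))
  infection <- expression_matrix(ivals, rep(iconds, each = nr),
                                 rep(seq_len(nr), times = length(iconds)))

  truth <- data.frame(
    gene_id = gene_ids,
    specific = gene_ids %in% specific,
    specific_conditions = ifelse(gene_ids %in% specific,
                                 paste(ex$specific_conditions, collapse = ","),
                                 ""),
    peak_condition = ifelse(gene_ids %in% peak12, ex$peak12_condition,
                            ifelse(gene_ids %in% peak48,
                                   ex$peak48_condition, "")),
    peak_called = gene_ids %in% c(peak12, peak48),
    stringsAsFactors = FALSE)

  ## qPCR Ct table for a handful of peaking genes
  baseline <- paste0(ex$genotypes[1L], ":", ex$times[1L])
  qgenes <- .pick(peak12, min(4L, length(peak12)))
  qsamples <- unique(c(baseline, ex$peak12_condition, ex$peak48_condition))
  ref_id <- "norm_ref"
  ct_rows <- list(); q_rows <- list()
  for (s in qsamples) {
    ref_ct <- 20 + stats::rnorm(nr, 0, 0.05)
    for (r in seq_len(nr)) {
      ct_rows[[length(ct_rows) + 1L]] <- data.frame(
        gene_id = ref_id, sample_id = s, replicate = r, ct = ref_ct[r],
        stringsAsFactors = FALSE)
    }
    for (g in qgenes) {
      rel <- imeans[g, s] / imeans[g, baseline]
      q_rows[[length(q_rows) + 1L]] <- data.frame(
        gene_id = g, sample_id = s, true_rel = rel, stringsAsFactors = FALSE)
      for (r in seq_len(nr)) {
        ct_rows[[length(ct_rows) + 1L]] <- data.frame(
          gene_id = g, sample_id = s, replicate = r,
          ct = ref_ct[r] + 5 - log2(rel) + stats::rnorm(1, 0, 0.05),
          stringsAsFactors = FALSE)
      }
    }
  }
  ct <- do.call(rbind, ct_rows)
  qpcr <- do.call(rbind, q_rows)

  if (!is.null(paths)) {
    write_expression_tsv(tissues, paths$tissues)
    write_expression_tsv(infection, paths$infection)
    .write_tsv(ct, paths$ct)
  }
  list(tissues = tissues, infection = infection, ct = ct,
       truth = truth, qpcr = qpcr)
}
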