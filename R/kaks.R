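STOP_CODONS <- c("TAA", "TAG", "TGA")

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("U", "T", names(gc))
  gc
}

split_codons <- function(seq) {
  seq <- toupper(as.character(seq))
  if (nchar(seq) %% 3 != 0) stop("sequence length not divisible by 3")
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

#' Back-translate a pairwise protein alignment to a codon alignment
#'
#' Maps every aligned amino-acid column to its source codon and drops
#' columns gapped in either row, yielding a gap-free in-frame codon
#' alignment ready for Ka/Ks estimation. The CDS must be the exact coding
#' sequence of the ungapped protein (terminal stop trimmed beforehand).
#'
#' @param prot_a,prot_b Aligned protein sequences (equal length, gaps `-`).
#' @param cds_a,cds_b Corresponding coding sequences (character,
#'   `DNAString`, or single-element `DNAStringSet`).
#' @param gene_a,gene_b Optional ids used in messages and results.
#' @return A `codon_alignment`: list with codon strings `a`, `b` (equal
#'   length, no gaps, no internal stops) and the gene ids.
#' @export
codon_align <- function(prot_a, prot_b, cds_a, cds_b,
                        gene_a = "seq_a", gene_b = "seq_b") {
  as_chr <- function(x) {
    if (methods::is(x, "XStringSet")) x <- x[[1L]]
    toupper(as.character(x))
  }
  pa <- as_chr(prot_a); pb <- as_chr(prot_b)
  ca <- as_chr(cds_a); cb <- as_chr(cds_b)
  if (nchar(pa) != nchar(pb)) stop("aligned proteins have unequal lengths")
  ungap <- function(p) gsub("-", "", p, fixed = TRUE)
  if (nchar(ca) != 3L * nchar(ungap(pa)))
    stop("CDS length of ", gene_a, " does not match its ungapped protein")
  if (nchar(cb) != 3L * nchar(ungap(pb)))
    stop("CDS length of ", gene_b, " does not match its ungapped protein")
  cod_a <- split_codons(ca); cod_b <- split_codons(cb)
  cols_a <- strsplit(pa, "")[[1]]; cols_b <- strsplit(pb, "")[[1]]
  ia <- ib <- 0L
  keep_a <- keep_b <- character(0)
  for (k in seq_along(cols_a)) {
    ga <- cols_a[k] == "-"; gb <- cols_b[k] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (!ga && !gb) {
      keep_a <- c(keep_a, cod_a[ia])
      keep_b <- c(keep_b, cod_b[ib])
    }
  }
  if (length(keep_a) == 0L) stop("no ungapped codon columns remain")
  if (any(keep_a %in% STOP_CODONS)) stop("internal stop codon in ", gene_a)
  if (any(keep_b %in% STOP_CODONS)) stop("internal stop codon in ", gene_b)
  # ambiguity codes are dropped pairwise before counting
  amb <- grepl("[^ACGT]", keep_a) | grepl("[^ACGT]", keep_b)
  keep_a <- keep_a[!amb]; keep_b <- keep_b[!amb]
  if (length(keep_a) == 0L) stop("no unambiguous codon columns remain")
  structure(list(a = keep_a, b = keep_b, gene_a = gene_a, gene_b = gene_b),
            class = "codon_alignment")
}

# Synonymous/nonsynonymous site fractions of one codon: for each position,
# the fraction of the 3 single-nucleotide changes that preserve the amino
# acid. Changes creating stop codons count as nonsynonymous sites, so
# s + n = 3 for every sense codon.
ng86_codon_sites <- function(codon, gc = codon_table()) {
  nts <- c("A", "C", "G", "T")
  aa <- gc[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (nt in setdiff(nts, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- nt
      if (!mut %in% STOP_CODONS && gc[[mut]] == aa) s <- s + 1 / 3
    }
  }
  c(syn = s, nonsyn = 3 - s)
}

# Average synonymous/nonsynonymous substitution counts between two codons,
# over all minimal mutational pathways (orderings of the differing
# positions). Pathways passing through stop codons are excluded; if every
# pathway is excluded, all pathways are used as a fallback.
ng86_codon_diffs <- function(ca, cb, gc = codon_table(), exclude_stop_paths = TRUE) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- if (k == 1L) list(pos) else {
    if (k == 2L) list(pos, rev(pos)) else {
      out <- list()
      for (p1 in pos) for (p2 in setdiff(pos, p1))
        out[[length(out) + 1L]] <- c(p1, p2, setdiff(pos, c(p1, p2)))
      out
    }
  }
  tally <- function(order_pos) {
    cur <- ca
    sd <- nd <- 0
    for (p in order_pos) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (nxt %in% STOP_CODONS) return(NULL)
      if (gc[[cur]] == gc[[nxt]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  paths <- lapply(perms, tally)
  if (exclude_stop_paths) {
    ok <- !vapply(paths, is.null, logical(1))
    if (any(ok)) paths <- paths[ok]
    else paths <- lapply(perms, function(o) {  # fallback: allow stop intermediates
      cur <- ca; sd <- nd <- 0
      for (p in o) {
        nxt <- cur
        substr(nxt, p, p) <- substr(cb, p, p)
        if (gc[[cur]] == gc[[nxt]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    })
  }
  mat <- do.call(rbind, paths)
  c(syn = mean(mat[, 1L]), nonsyn = mean(mat[, 2L]))
}

jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 3 / 4) return(NA_real_)   # saturated
  -3 / 4 * log(1 - 4 / 3 * p)
}

#' Nei-Gojobori (NG86) Ka/Ks for a codon alignment
#'
#' Computes synonymous and nonsynonymous site counts per codon by
#' single-mutation enumeration (averaged over the two sequences),
#' substitution counts by equal-weight averaging over all minimal
#' mutational pathways between differing codons (pathways through stop
#' codons excluded), and applies the Jukes-Cantor correction
#' `d = -(3/4) ln(1 - (4/3) p)` to both proportions. A proportion at or
#' above 3/4 is flagged saturated and the corresponding rate (and any
#' quantity derived from it) is undefined.
#'
#' @param aln A [codon_align()] result.
#' @param cfg A [kaks_config()].
#' @return A `kaks_result`: one-row data frame with `gene_a`, `gene_b`,
#'   `ka`, `ks`, `ratio`, `selection`, `t_mya`, `saturated`, plus the site
#'   and difference counts `S`, `N`, `sd`, `nd`.
#' @export
ng86_kaks <- function(aln, cfg = kaks_config()) {
  stopifnot(inherits(aln, "codon_alignment"))
  gc <- codon_table()
  sites_a <- vapply(aln$a, ng86_codon_sites, numeric(2), gc = gc)
  sites_b <- vapply(aln$b, ng86_codon_sites, numeric(2), gc = gc)
  S <- (sum(sites_a["syn", ]) + sum(sites_b["syn", ])) / 2
  N <- (sum(sites_a["nonsyn", ]) + sum(sites_b["nonsyn", ])) / 2
  diffs <- mapply(function(x, y) ng86_codon_diffs(x, y, gc, cfg$exclude_stop_paths),
                  aln$a, aln$b)
  sd_ <- sum(diffs["syn", ]); nd_ <- sum(diffs["nonsyn", ])
  pS <- sd_ / S; pN <- nd_ / N
  ks <- jc_correct(pS); ka <- jc_correct(pN)
  saturated <- pS >= 3 / 4 || pN >= 3 / 4
  ratio <- if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_
  res <- data.frame(gene_a = aln$gene_a, gene_b = aln$gene_b,
                    ka = ka, ks = ks, ratio = ratio,
                    selection = classify_selection(ratio, cfg$neutral_band),
                    t_mya = divergence_time(ks, cfg$gamma),
                    saturated = saturated,
                    S = S, N = N, sd = sd_, nd = nd_,
                    stringsAsFactors = FALSE)
  class(res) <- c("kaks_result", class(res))
  res
}

#' Ka/Ks analysis configuration
#'
#' @param gamma Clock rate in substitutions per site per year; the default
#'   1.5e-8 is the divergence rate commonly used for nuclear genes of
#'   dicotyledonous plants.
#' @param neutral_band Half-width of the neutral zone around ratio 1
#'   (default 0: strict inequalities).
#' @param bin_width Histogram bin width (default 0.1).
#' @param exclude_stop_paths Exclude mutational pathways through stop
#'   codons (default TRUE).
#' @return A list of class `kaks_config`.
#' @export
kaks_config <- function(gamma = 1.5e-8, neutral_band = 0, bin_width = 0.1,
                        exclude_stop_paths = TRUE) {
  stopifnot(gamma > 0, neutral_band >= 0, bin_width > 0)
  structure(list(gamma = gamma, neutral_band = neutral_band,
                 bin_width = bin_width,
                 exclude_stop_paths = exclude_stop_paths),
            class = "kaks_config")
}

#' Classify selection from a Ka/Ks ratio
#'
#' Ratio below `1 - band` indicates negative/purifying selection, above
#' `1 + band` positive/Darwinian selection, and values in the band (exactly
#' 1 by default) a neutral mutation pattern.
#'
#' @param ratio Ka/Ks ratio (NA when undefined).
#' @param neutral_band Half-width of the neutral zone (default 0).
#' @return `"purifying"`, `"neutral"`, `"positive"`, or `"undefined"`.
#' @export
classify_selection <- function(ratio, neutral_band = 0) {
  vapply(ratio, function(r) {
    if (is.na(r)) "undefined"
    else if (r < 1 - neutral_band) "purifying"
    else if (r > 1 + neutral_band) "positive"
    else "neutral"
  }, character(1))
}

#' Date a duplication from synonymous divergence
#'
#' `T = Ks / (2 gamma)`, reported in million years (MYA).
#'
#' @param ks Synonymous substitutions per synonymous site (NA when
#'   saturated/undefined).
#' @param gamma Clock rate in substitutions per site per year.
#' @return Divergence time in MYA (NA when `ks` is NA).
#' @export
divergence_time <- function(ks, gamma = 1.5e-8) {
  stopifnot(gamma > 0)
  ifelse(is.na(ks), NA_real_, ks / (2 * gamma) / 1e6)
}

#' Half-open histogram of Ka/Ks or divergence-time values
#'
#' Bins are `[k w, (k+1) w)`; a value exactly on an edge falls in the upper
#' bin. NA values (saturated pairs) are dropped with a message.
#'
#' @param values Numeric vector (non-negative).
#' @param bin_width Bin width (default 0.1).
#' @return Data frame `bin_start`, `bin_end`, `count`; empty for empty
#'   input. Counts sum to the number of non-NA values.
#' @export
ks_histogram <- function(values, bin_width = 0.1) {
  stopifnot(bin_width > 0)
  if (anyNA(values)) {
    message(sum(is.na(values)), " undefined value(s) dropped from histogram")
    values <- values[!is.na(values)]
  }
  if (length(values) == 0L)
    return(data.frame(bin_start = numeric(), bin_end = numeric(),
                      count = integer()))
  # small tolerance so that edge values (e.g. 0.3 / 0.1) land in the upper bin
  idx <- floor(values / bin_width + 1e-9)
  tab <- table(idx)
  ix <- as.integer(names(tab))
  data.frame(bin_start = ix * bin_width, bin_end = (ix + 1) * bin_width,
             count = as.integer(tab))
}
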