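#' Extract the upstream promoter region of a gene
#'
#' Returns the `length` bp immediately upstream of the gene, oriented so
#' that position 1 is the farthest point from the gene and the last
#' position abuts it. For a plus-strand gene starting at s this is genomic
#' `[s - length, s - 1]` read forward; for a minus-strand gene ending at e
#' it is the reverse complement of genomic `[e + 1, e + length]`. Regions
#' are truncated (with a warning) at chromosome boundaries; a gene starting
#' at position 1 on the plus strand yields a zero-length sequence.
#'
#' By default the region is anchored at the translation start (first CDS
#' base of the primary transcript) when CDS features are annotated;
#' set `anchor = "gene"` to anchor at the gene feature boundary.
#'
#' @param genome Named `DNAStringSet` of chromosome sequences.
#' @param annotation A `genome_annotation`.
#' @param gene_id Gene identifier.
#' @param length Upstream length in bp (default 2000).
#' @param anchor `"cds"` (default; falls back to the gene boundary when no
#'   CDS is annotated) or `"gene"`.
#' @return A `DNAStringSet` of length 1 named after the gene, with
#'   attributes `chrom`, `genomic_start`, `genomic_end`, `strand` recording
#'   the forward-strand interval it came from.
#' @export
extract_upstream <- function(genome, annotation, gene_id, length = 2000L,
                             anchor = c("cds", "gene")) {
  anchor <- match.arg(anchor)
  g <- annotation$genes[annotation$genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) == 0L) stop("gene not found: ", gene_id)
  if (!g$chrom %in% names(genome)) stop("chromosome not in genome: ", g$chrom)
  chrom_seq <- genome[[g$chrom]]
  clen <- Biostrings::nchar(chrom_seq)
  astart <- g$start; aend <- g$end
  if (anchor == "cds") {
    cd <- select_primary_transcript(annotation, gene_id)$cds
    if (nrow(cd)) { astart <- min(cd$start); aend <- max(cd$end) }
  }
  if (g$strand == "+") {
    to <- astart - 1L
    from <- astart - length
    if (from < 1L) {
      if (to >= 1L) warning("promoter of ", gene_id, " truncated at chromosome start")
      from <- 1L
    }
    if (to < from) {
      out <- Biostrings::DNAStringSet("")
    } else {
      out <- Biostrings::DNAStringSet(Biostrings::subseq(chrom_seq, from, to))
    }
    gs <- from; ge <- to
  } else {
    from <- aend + 1L
    to <- aend + length
    if (to > clen) {
      if (from <= clen) warning("promoter of ", gene_id, " truncated at chromosome end")
      to <- clen
    }
    if (to < from) {
      out <- Biostrings::DNAStringSet("")
    } else {
      out <- Biostrings::DNAStringSet(
        Biostrings::reverseComplement(Biostrings::subseq(chrom_seq, from, to)))
    }
    gs <- from; ge <- to
  }
  names(out) <- gene_id
  attr(out, "chrom") <- g$chrom
  attr(out, "genomic_start") <- gs
  attr(out, "genomic_end") <- ge
  attr(out, "strand") <- g$strand
  out
}

# All match offsets of an IUPAC pattern in a sequence (plus strand of the
# given sequence). Overlapping occurrences are all reported.
iupac_match_starts <- function(pattern, seq) {
  hits <- Biostrings::matchPattern(Biostrings::DNAString(pattern),
                                   Biostrings::DNAString(seq),
                                   fixed = FALSE)
  Biostrings::start(hits)
}

#' Scan a promoter against a cis-element motif library
#'
#' Reports every occurrence of every IUPAC consensus pattern. Motifs with
#' `both_strands = TRUE` are also matched against the reverse complement of
#' the promoter (reported with strand `-` at the corresponding plus-strand
#' offset); a palindromic match at one locus is counted once.
#'
#' @param promoter A single sequence (character, `DNAString`, or
#'   single-element `DNAStringSet`); position 1 is the farthest point from
#'   the gene, as produced by [extract_upstream()].
#' @param library Motif data frame (`name`, `pattern`, `both_strands`);
#'   default [cis_element_library()].
#' @return Data frame `motif`, `offset` (1-based start in the promoter),
#'   `strand`.
#' @export
scan_elements <- function(promoter, library = cis_element_library()) {
  if (nrow(library) == 0L) stop("motif library is empty")
  if (methods::is(promoter, "XStringSet")) promoter <- promoter[[1L]]
  seq <- toupper(as.character(promoter))
  n <- nchar(seq)
  out <- list()
  for (k in seq_len(nrow(library))) {
    pat <- toupper(library$pattern[k])
    w <- nchar(pat)
    if (n < w) next
    plus <- iupac_match_starts(pat, seq)
    minus <- integer(0)
    if (isTRUE(library$both_strands[k])) {
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(pat)))
      minus <- iupac_match_starts(rc, seq)
      minus <- setdiff(minus, plus)   # palindromic matches counted once
    }
    if (length(plus) || length(minus)) {
      out[[length(out) + 1L]] <- data.frame(
        motif = library$name[k],
        offset = c(plus, minus),
        strand = c(rep("+", length(plus)), rep("-", length(minus))),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(motif = character(), offset = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$motif, res$offset), , drop = FALSE]
}

#' Per-gene cis-element count matrix
#'
#' @param hits_per_gene Named list: gene id -> [scan_elements()] data frame.
#' @param library Motif library defining the column order.
#' @return Integer matrix genes x elements; column sums give family-wide
#'   tallies. All-zero for genes without hits.
#' @export
element_count_table <- function(hits_per_gene, library = cis_element_library()) {
  genes <- names(hits_per_gene)
  mat <- matrix(0L, nrow = length(genes), ncol = nrow(library),
                dimnames = list(genes, library$name))
  for (g in genes) {
    h <- hits_per_gene[[g]]
    if (is.null(h) || nrow(h) == 0L) next
    tab <- table(h$motif)
    mat[g, names(tab)] <- as.integer(tab)
  }
  mat
}
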