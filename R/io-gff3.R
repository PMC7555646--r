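#' Read a GFF3 gene annotation
#'
#' Parses a GFF3 file (gene/mRNA/exon/CDS features linked through `Parent`
#' attributes) into a `genome_annotation` object: plain data frames of genes,
#' transcripts, exons and CDS segments plus per-chromosome lengths. All
#' coordinates stay 1-based inclusive, the GFF3 convention, and minus-strand
#' features keep their forward-strand coordinates.
#'
#' Chromosome lengths are taken from `##sequence-region` pragmas when
#' present; otherwise the maximum feature end per chromosome is used and a
#' warning is issued.
#'
#' @param path Path to a GFF3 file.
#' @return A `genome_annotation`: a list with data frames `genes`
#'   (`gene_id`, `chrom`, `strand`, `start`, `end`), `transcripts` (`tx_id`,
#'   `gene_id`, `is_primary`), `exons` and `cds` (`tx_id`, `start`, `end`),
#'   and a named numeric vector `chrom_lengths`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  id <- as.character(mc$ID)
  parent <- if ("Parent" %in% names(mc)) {
    vapply(mc$Parent, function(p) if (length(p)) as.character(p[1L]) else NA_character_,
           character(1))
  } else rep(NA_character_, length(gr))

  is_gene <- type == "gene"
  genes <- data.frame(
    gene_id = id[is_gene],
    chrom = as.character(GenomicRanges::seqnames(gr))[is_gene],
    strand = as.character(GenomicRanges::strand(gr))[is_gene],
    start = GenomicRanges::start(gr)[is_gene],
    end = GenomicRanges::end(gr)[is_gene],
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene id: ", genes$gene_id[duplicated(genes$gene_id)][1L])
  }

  is_tx <- type %in% c("mRNA", "transcript")
  primary_attr <- if ("primary" %in% names(mc)) as.character(mc$primary) else
    rep(NA_character_, length(gr))
  transcripts <- data.frame(
    tx_id = id[is_tx],
    gene_id = parent[is_tx],
    is_primary = !is.na(primary_attr[is_tx]) &
      tolower(primary_attr[is_tx]) %in% c("true", "1", "yes"),
    stringsAsFactors = FALSE
  )
  orphan <- transcripts$tx_id[is.na(transcripts$gene_id) |
                              !transcripts$gene_id %in% genes$gene_id]
  if (length(orphan)) stop("orphan mRNA (no gene parent): ", orphan[1L])

  seg_frame <- function(which_type) {
    k <- type == which_type
    data.frame(
      tx_id = parent[k],
      start = GenomicRanges::start(gr)[k],
      end = GenomicRanges::end(gr)[k],
      stringsAsFactors = FALSE
    )
  }
  exons <- seg_frame("exon")
  cds <- seg_frame("CDS")
  bad_parent <- exons$tx_id[!exons$tx_id %in% transcripts$tx_id]
  if (length(bad_parent)) stop("exon with unknown parent transcript: ", bad_parent[1L])

  # exon containment within the parent gene span
  tx2gene <- stats::setNames(transcripts$gene_id, transcripts$tx_id)
  gspan <- genes[match(tx2gene[exons$tx_id], genes$gene_id), , drop = FALSE]
  out <- exons$start < gspan$start | exons$end > gspan$end
  if (any(out)) {
    stop(sprintf("exon [%d,%d] of transcript '%s' lies outside its gene span",
                 exons$start[which(out)[1L]], exons$end[which(out)[1L]],
                 exons$tx_id[which(out)[1L]]))
  }

  pragmas <- grep("^##sequence-region", readLines(path, warn = FALSE), value = TRUE)
  if (length(pragmas)) {
    parts <- strsplit(trimws(pragmas), "\\s+")
    chrom_lengths <- stats::setNames(
      vapply(parts, function(p) as.numeric(p[4L]), numeric(1)),
      vapply(parts, function(p) p[2L], character(1))
    )
  } else {
    warning("no ##sequence-region pragmas; chromosome lengths set to max feature end")
    chrom_lengths <- tapply(GenomicRanges::end(gr),
                            as.character(GenomicRanges::seqnames(gr)), max)
    chrom_lengths <- stats::setNames(as.numeric(chrom_lengths), names(chrom_lengths))
  }

  structure(list(genes = genes, transcripts = transcripts, exons = exons,
                 cds = cds, chrom_lengths = chrom_lengths),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d genes, %d transcripts on %d sequences\n",
              nrow(x$genes), nrow(x$transcripts), length(x$chrom_lengths)))
  invisible(x)
}

#' Select the primary transcript of a gene
#'
#' Gene models list one transcript per splice form; downstream analyses use
#' a single representative. The representative is the transcript flagged
#' primary in the annotation; failing that, the one with the longest total
#' CDS; remaining ties go to the lexicographically smallest transcript id.
#'
#' @param annotation A `genome_annotation`.
#' @param gene_id Gene identifier.
#' @return A list with `tx_id`, `is_primary`, and data frames `exons` and
#'   `cds` (sorted by start).
#' @export
select_primary_transcript <- function(annotation, gene_id) {
  stopifnot(inherits(annotation, "genome_annotation"))
  tx <- annotation$transcripts[annotation$transcripts$gene_id == gene_id, , drop = FALSE]
  if (nrow(tx) == 0L) stop("gene has no transcripts: ", gene_id)
  pick <- if (any(tx$is_primary)) {
    tx$tx_id[tx$is_primary][1L]
  } else {
    cds_len <- vapply(tx$tx_id, function(t) {
      seg <- annotation$cds[annotation$cds$tx_id == t, , drop = FALSE]
      if (nrow(seg) == 0L) 0L else sum(seg$end - seg$start + 1L)
    }, integer(1))
    best <- tx$tx_id[cds_len == max(cds_len)]
    sort(best)[1L]
  }
  ex <- annotation$exons[annotation$exons$tx_id == pick, , drop = FALSE]
  cd <- annotation$cds[annotation$cds$tx_id == pick, , drop = FALSE]
  list(tx_id = pick,
       is_primary = tx$is_primary[tx$tx_id == pick],
       exons = ex[order(ex$start), , drop = FALSE],
       cds = cd[order(cd$start), , drop = FALSE])
}
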