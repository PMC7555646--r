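#' Read a FASTA file into a validated sequence set
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that enforces the
#' contracts the rest of the toolkit relies on: the file must contain at
#' least one record, identifiers (the first whitespace-delimited token of
#' each header) must be unique, and every residue must belong to the IUPAC
#' alphabet of the declared sequence type.
#'
#' @param path Path to a FASTA file.
#' @param alphabet Either `"dna"` or `"protein"`; selects the IUPAC alphabet
#'   used for validation and the returned container class.
#' @return A [Biostrings::DNAStringSet] or [Biostrings::AAStringSet] with one
#'   element per record, in file order.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">g1", "ATG"), tf)
#' read_fasta(tf, "dna")
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(x))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id: ", dup[1L])
  names(x) <- ids
  legal <- if (alphabet == "dna") {
    c(strsplit("ACGTRYSWKMBDHVN", "")[[1]], "-", ".")
  } else {
    c(strsplit("ACDEFGHIKLMNPQRSTVWYBXZJUO", "")[[1]], "-", ".", "*")
  }
  for (i in seq_along(x)) {
    chars <- strsplit(toupper(as.character(x[[i]])), "")[[1]]
    bad <- which(!chars %in% legal)
    if (length(bad)) {
      stop(sprintf("illegal %s residue '%s' in record '%s' at position %d",
                   alphabet, chars[bad[1L]], ids[i], bad[1L]))
    }
  }
  if (alphabet == "dna") Biostrings::DNAStringSet(x) else Biostrings::AAStringSet(x)
}

#' Write sequences to FASTA
#'
#' @param x A named `XStringSet` (or named character vector).
#' @param path Output path.
#' @param width Line-wrap width in characters (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (is.character(x)) x <- Biostrings::BStringSet(x)
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == ""))
    stop("all records must be named")
  Biostrings::writeXStringSet(x, filepath = path, width = as.integer(width))
  invisible(path)
}
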