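#' Packaged domain accession to class map
#'
#' The identification cascade needs to know which Pfam accessions count as
#' LRR domains and which as kinase domains. The packaged map covers the five
#' leucine-rich-repeat clan profiles used to search the genome (LRR1
#' PF00560, LRR5 PF13306, LRR6 PF13516, LRR8 PF13855, LRRNT-2 PF08263) and
#' the two protein-kinase profiles (Pkinase PF00069, PK_Tyr_Ser-Thr
#' PF07714). Users can supply their own map to [read_domain_hits()].
#'
#' @return Named character vector mapping accession to class
#'   (`"LRR"`/`"kinase"`).
#' @export
default_domain_classes <- function() {
  path <- system.file("extdata", "domain_classes.tsv", package = "lrrfam",
                      mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stats::setNames(tab$class, tab$accession)
}

#' Strip a Pfam accession version suffix
#'
#' `PF00560.31 -> PF00560`; idempotent on unversioned accessions.
#'
#' @param acc Character vector of accessions.
#' @return Accessions without version suffixes.
#' @export
normalize_accession <- function(acc) sub("\\.\\d+$", "", acc)

#' Read a domain hit table (hmmscan domtblout-like)
#'
#' Reads a whitespace-delimited table with at least five columns: target
#' gene id, domain accession, full-sequence E-value, envelope start and
#' envelope end (1-based amino-acid positions). Lines starting with `#` are
#' skipped; extra columns are ignored. Accession version suffixes are
#' normalized away and each hit is classified as LRR, kinase or other via
#' the accession map.
#'
#' @param path Path to the table.
#' @param class_map Named character vector mapping accession to class;
#'   defaults to [default_domain_classes()]. Accessions absent from the map
#'   get class `"other"`.
#' @return Data frame with columns `gene_id`, `domain_acc`, `evalue`,
#'   `env_start`, `env_end`, `domain_class`.
#' @export
read_domain_hits <- function(path, class_map = default_domain_classes()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(data.frame(gene_id = character(), domain_acc = character(),
                      evalue = numeric(), env_start = integer(),
                      env_end = integer(), domain_class = character(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(idx, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 5L) stop("unparseable domain hit row at line ", i,
                             ": expected >= 5 fields")
    ev <- suppressWarnings(as.numeric(f[3L]))
    s <- suppressWarnings(as.integer(f[4L]))
    e <- suppressWarnings(as.integer(f[5L]))
    if (is.na(ev) || is.na(s) || is.na(e))
      stop("unparseable domain hit row at line ", i, ": non-numeric field")
    if (ev < 0) stop("negative E-value at line ", i)
    if (s > e) stop("envelope start > end at line ", i)
    list(gene_id = f[1L], domain_acc = normalize_accession(f[2L]),
         evalue = ev, env_start = s, env_end = e)
  })
  hits <- data.frame(
    gene_id = vapply(rows, `[[`, character(1), "gene_id"),
    domain_acc = vapply(rows, `[[`, character(1), "domain_acc"),
    evalue = vapply(rows, `[[`, numeric(1), "evalue"),
    env_start = vapply(rows, `[[`, integer(1), "env_start"),
    env_end = vapply(rows, `[[`, integer(1), "env_end"),
    stringsAsFactors = FALSE
  )
  cls <- unname(class_map[hits$domain_acc])
  cls[is.na(cls)] <- "other"
  hits$domain_class <- cls
  hits
}
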