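#' Reference LRR-RLK subgroup table
#'
#' The 24 canonical RLK-Pelle LRR subgroups used for phylogeny-anchored
#' classification, with published family sizes in Arabidopsis thaliana,
#' Medicago truncatula and soybean. Row `Total numbers` is excluded; use
#' `colSums` for the per-species totals (225 / 329 / 467).
#'
#' @return Data frame with columns `subgroup`, `arabidopsis`, `medicago`,
#'   `soybean`.
#' @export
lrr_subgroup_table <- function() {
  path <- system.file("extdata", "lrr_rlk_subgroups.tsv", package = "lrrfam",
                      mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' The 24 canonical subgroup labels
#'
#' @return Character vector of subgroup labels
#'   (`RLK-Pelle_LRR-I` ... `RLK-Pelle_LRR-XV`).
#' @export
lrr_subgroup_labels <- function() lrr_subgroup_table()$subgroup

#' Packaged promoter cis-element motif library
#'
#' Twenty regulatory elements commonly scanned in plant promoter surveys
#' (hormone-responsive, stress-responsive and core elements), each given as
#' an IUPAC nucleotide consensus and a flag for double-stranded scanning.
#' The consensus strings are literature approximations of the PlantCARE
#' element definitions, packaged as an editable TSV; replace the library to
#' use site-specific definitions.
#'
#' @return Data frame with columns `name`, `pattern`, `both_strands`.
#' @export
cis_element_library <- function() {
  path <- system.file("extdata", "cis_elements.tsv", package = "lrrfam",
                      mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  tab$both_strands <- as.logical(tab$both_strands)
  tab
}
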