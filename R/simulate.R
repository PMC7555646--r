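#' Configuration for the synthetic genome and expression generator
#'
#' Builds the default simulation plan: a 3-chromosome genome carrying 160
#' background genes and a 40-member planted LRR-RLK family spread over 8 of
#' the 24 canonical subgroups, with three tandem clusters (3+5+2 genes at
#' inter-gene distances well inside the 200-kb rule), one deliberately
#' near-miss pair 250 kb apart, two collinear segmental blocks (4 and 3
#' duplicate pairs evolved to Ks 0.6 and 0.45, Ka/Ks 0.2), planted promoter
#' elements, and tissue / rhizobial-infection expression with planted
#' specific and peaking gene sets. Every stochastic choice flows from
#' `seed`.
#'
#' @param seed Integer seed (mandatory).
#' @param n_chrom,chrom_len Number and length (bp) of chromosomes.
#' @param n_background Number of background genes.
#' @param subgroup_sizes Named integer vector: planted family members per
#'   subgroup (names from [lrr_subgroup_labels()]).
#' @param protein_len Family protein length (aa); family sequences are
#'   generated indel-free so family alignment is trivial.
#' @param within_ks,omega Divergence of members from their subgroup
#'   ancestor (synonymous target and Ka/Ks).
#' @param ref_ks Divergence of the reference (anchor) sequence of each
#'   subgroup.
#' @param n_rescue_only Family members given LRR hit E-values above the
#'   HMM screen threshold, recoverable only through the rescue set.
#' @param n_multi_kinase Family members given two kinase domain hits.
#' @param n_outliers Divergent decoy genes carrying family-like domain
#'   hits but unrelated sequence (default 0; pruned by the tree step when
#'   planted).
#' @param tandem,segmental,near_miss Duplication plans (see source for the
#'   list structure).
#' @param expression Expression plan (condition sets, planted gene set
#'   sizes, folds, replicate noise SD).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_chrom = 3L,
                       chrom_len = 3e6,
                       n_background = 160L,
                       subgroup_sizes = c("RLK-Pelle_LRR-XI-1" = 10L,
                                          "RLK-Pelle_LRR-XII" = 8L,
                                          "RLK-Pelle_LRR-III-1" = 6L,
                                          "RLK-Pelle_LRR-I" = 4L,
                                          "RLK-Pelle_LRR-II-1" = 4L,
                                          "RLK-Pelle_LRR-VIII" = 4L,
                                          "RLK-Pelle_LRR-IV" = 2L,
                                          "RLK-Pelle_LRR-V" = 2L),
                       protein_len = 300L,
                       within_ks = 0.3, omega = 0.2, ref_ks = 0.15,
                       n_rescue_only = 6L, n_multi_kinase = 2L,
                       n_outliers = 0L,
                       tandem = list(
                         list(chrom = 1L, subgroup = "RLK-Pelle_LRR-XI-1",
                              n = 3L, gaps = c(30000, 80000), ks = 0.15),
                         list(chrom = 2L, subgroup = "RLK-Pelle_LRR-XII",
                              n = 5L, gaps = c(20000, 40000, 60000, 150000),
                              ks = 0.15),
                         list(chrom = 3L, subgroup = "RLK-Pelle_LRR-I",
                              n = 2L, gaps = 100000, ks = 0.15)),
                       segmental = list(
                         list(chrom_a = 1L, chrom_b = 2L,
                              subgroups = c("RLK-Pelle_LRR-III-1",
                                            "RLK-Pelle_LRR-III-1",
                                            "RLK-Pelle_LRR-III-1",
                                            "RLK-Pelle_LRR-IV"),
                              ks = 0.6),
                         list(chrom_a = 2L, chrom_b = 3L,
                              subgroups = c("RLK-Pelle_LRR-II-1",
                                            "RLK-Pelle_LRR-V",
                                            "RLK-Pelle_LRR-II-1"),
                              ks = 0.45)),
                       near_miss = list(
                         list(chrom = 3L, subgroup = "RLK-Pelle_LRR-VIII",
                              gap = 250000)),
                       expression = list(
                         tissues = c("flower", "leaf", "root", "petiole",
                                     "pod", "seedling", "stem", "veg_bud",
                                     "root_tip", "nodule_4d", "nodule_10d",
                                     "nodule_14d"),
                         genotypes = c("A17", "nfp", "lyk3", "skl"),
                         times = c(0, 0.5, 1, 3, 6, 12, 24, 36, 48),
                         n_reps = 3L, noise_sd = 0.5,
                         specific_conditions = c("root", "nodule_14d"),
                         n_specific = 8L,
                         peak12_condition = "skl:12", n_peak12 = 36L,
                         peak48_condition = "skl:48", n_peak48 = 2L,
                         n_double_positive = 6L,
                         fold = 20)) {
  if (missing(seed)) stop("a seed is required")
  bad <- setdiff(names(subgroup_sizes), lrr_subgroup_labels())
  if (length(bad)) stop("unknown subgroup in plan: ", bad[1L])
  structure(list(seed = as.integer(seed), n_chrom = n_chrom,
                 chrom_len = chrom_len, n_background = n_background,
                 subgroup_sizes = subgroup_sizes, protein_len = protein_len,
                 within_ks = within_ks, omega = omega, ref_ks = ref_ks,
                 n_rescue_only = n_rescue_only,
                 n_multi_kinase = n_multi_kinase, n_outliers = n_outliers,
                 tandem = tandem, segmental = segmental,
                 near_miss = near_miss, expression = expression),
            class = "sim_config")
}

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))

random_cds <- function(n_codons) {
  paste(sample(SENSE_CODONS, n_codons, replace = TRUE), collapse = "")
}

#' Evolve a coding sequence to a target synonymous divergence
#'
#' Introduces point substitutions into `ancestor` so that the pair
#' (ancestor, mutant) diverges by `target_ks` synonymous substitutions per
#' synonymous site and `omega * target_ks` nonsynonymous substitutions per
#' nonsynonymous site under the Jukes-Cantor model assumed by the NG86
#' estimator. Site counts follow the NG86 convention; the number of
#' differing positions realizes the JC-expected proportion
#' `p = 3/4 (1 - exp(-4/3 d))` for each class, with at most one change per
#' codon so realized difference counts are exact. Substitutions that would
#' create stop codons are never drawn.
#'
#' @param ancestor CDS (character or `DNAString`), length divisible by 3,
#'   no internal stops.
#' @param target_ks Target synonymous divergence (>= 0).
#' @param omega Target Ka/Ks ratio (>= 0).
#' @param seed Optional integer seed; NULL draws from the current stream.
#' @return List with `cds` (mutated sequence) and `record` (data frame of
#'   realized substitutions: codon index, position, from, to, type).
#' @export
evolve_cds <- function(ancestor, target_ks, omega = 0.2, seed = NULL) {
  stopifnot(target_ks >= 0, omega >= 0)
  if (methods::is(ancestor, "XString")) ancestor <- as.character(ancestor)
  cod <- split_codons(ancestor)
  if (any(cod %in% STOP_CODONS)) stop("ancestor contains internal stop codons")
  empty_rec <- data.frame(codon = integer(), pos = integer(),
                          from = character(), to = character(),
                          type = character(), stringsAsFactors = FALSE)
  if (target_ks == 0 && omega * target_ks == 0) {
    return(list(cds = ancestor, record = empty_rec))
  }
  gc <- codon_table()
  sites <- vapply(cod, ng86_codon_sites, numeric(2), gc = gc)
  S <- sum(sites["syn", ]); N <- sum(sites["nonsyn", ])
  jc_forward <- function(d) 3 / 4 * (1 - exp(-4 / 3 * d))
  n_syn <- round(jc_forward(target_ks) * S)
  n_non <- round(jc_forward(omega * target_ks) * N)
  # single-nucleotide changes available per codon, by class
  options_for <- function(codon, type) {
    nts <- c("A", "C", "G", "T")
    out <- list()
    for (pos in 1:3) {
      for (nt in setdiff(nts, substr(codon, pos, pos))) {
        mut <- codon
        substr(mut, pos, pos) <- nt
        if (mut %in% STOP_CODONS) next
        syn <- gc[[mut]] == gc[[codon]]
        if ((type == "syn") == syn) out[[length(out) + 1L]] <- c(pos, nt)
      }
    }
    out
  }
  with_seed(seed, {
    has_syn <- vapply(cod, function(cd) length(options_for(cd, "syn")) > 0,
                      logical(1))
    has_non <- vapply(cod, function(cd) length(options_for(cd, "nonsyn")) > 0,
                      logical(1))
    rec <- empty_rec
    used <- logical(length(cod))
    draw <- function(type, n_changes, eligible) {
      for (k in seq_len(n_changes)) {
        avail <- which(eligible & !used)
        if (length(avail) == 0L)
          stop("divergence target unreachable on this sequence length")
        i <- if (length(avail) == 1L) avail else sample(avail, 1L)
        opt <- options_for(cod[i], type)
        o <- opt[[sample.int(length(opt), 1L)]]
        from <- substr(cod[i], as.integer(o[1]), as.integer(o[1]))
        mut <- cod[i]
        substr(mut, as.integer(o[1]), as.integer(o[1])) <- o[2]
        cod[i] <<- mut
        used[i] <<- TRUE
        rec <<- rbind(rec, data.frame(codon = i, pos = as.integer(o[1]),
                                      from = from, to = o[2], type = type,
                                      stringsAsFactors = FALSE))
      }
    }
    draw("syn", n_syn, has_syn)
    draw("nonsyn", n_non, has_non)
    list(cds = paste(cod, collapse = ""), record = rec)
  })
}

# Split a CDS of len nucleotides into n_exons chunks of >= min_len each.
split_exon_lengths <- function(len, n_exons, min_len = 30L) {
  if (n_exons * min_len > len) stop("too many exons for CDS length")
  extra <- len - n_exons * min_len
  if (n_exons == 1L) return(len)
  cuts <- sort(sample.int(extra + 1L, n_exons - 1L, replace = TRUE) - 1L)
  as.integer(min_len + diff(c(0L, cuts, extra)))
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
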