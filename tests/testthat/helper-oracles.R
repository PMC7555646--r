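# Independent reference implementations ("oracles") used to cross-check the
# package's algorithms through a structurally different route.

.ORACLE_GC <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("U", "T", names(gc))
  gc
})
.ORACLE_STOPS <- c("TAA", "TAG", "TGA")

# --- NG86 oracle ------------------------------------------------------

# Synonymous site count of one codon, by explicit enumeration over a
# 3x3 mutation grid (matrix route, unlike the package's per-position loop).
oracle_syn_sites <- function(codon) {
  nt <- c("A", "C", "G", "T")
  cod <- strsplit(codon, "")[[1]]
  muts <- expand.grid(pos = 1:3, to = nt, stringsAsFactors = FALSE)
  muts <- muts[muts$to != cod[muts$pos], , drop = FALSE]
  syn <- mapply(function(p, b) {
    m <- cod; m[p] <- b; ms <- paste(m, collapse = "")
    !(ms %in% .ORACLE_STOPS) && .ORACLE_GC[[ms]] == .ORACLE_GC[[codon]]
  }, muts$pos, muts$to)
  sum(syn) / 3
}

# All orderings of a set (n <= 3 here).
oracle_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# Average syn/nonsyn differences between two codons over minimal pathways,
# excluding stop-passing pathways (falling back to all when none survive).
oracle_codon_diffs <- function(ca, cb) {
  a <- strsplit(ca, "")[[1]]; b <- strsplit(cb, "")[[1]]
  pos <- which(a != b)
  if (length(pos) == 0L) return(c(0, 0))
  walk <- function(order_pos, allow_stop) {
    cur <- a; s <- 0; n <- 0
    for (p in order_pos) {
      nxt <- cur; nxt[p] <- b[p]
      cs <- paste(cur, collapse = ""); ns <- paste(nxt, collapse = "")
      if (ns %in% .ORACLE_STOPS && !allow_stop) return(NULL)
      if (.ORACLE_GC[[cs]] == .ORACLE_GC[[ns]]) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    c(s, n)
  }
  res <- Filter(Negate(is.null), lapply(oracle_perms(pos), walk,
                                        allow_stop = FALSE))
  if (length(res) == 0L)
    res <- lapply(oracle_perms(pos), walk, allow_stop = TRUE)
  colMeans(do.call(rbind, res))
}

# Full NG86 Ka/Ks of two equal-length gap-free codon vectors.
oracle_ng86 <- function(cod_a, cod_b) {
  Sa <- sum(vapply(cod_a, oracle_syn_sites, numeric(1)))
  Sb <- sum(vapply(cod_b, oracle_syn_sites, numeric(1)))
  S <- (Sa + Sb) / 2
  N <- 3 * length(cod_a) - S
  d <- mapply(oracle_codon_diffs, cod_a, cod_b)
  sd_ <- sum(d[1, ]); nd_ <- sum(d[2, ])
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 / 3 * p)
  list(S = S, N = N, sd = sd_, nd = nd_,
       ks = jc(sd_ / S), ka = jc(nd_ / N))
}

# --- promoter scan oracle ---------------------------------------------

.ORACLE_IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
                      R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"),
                      W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                      B = c("C", "G", "T"), D = c("A", "G", "T"),
                      H = c("A", "C", "T"), V = c("A", "C", "G"),
                      N = c("A", "C", "G", "T"))

# Naive per-position IUPAC matcher on the plus strand.
oracle_match <- function(pattern, seq) {
  p <- strsplit(toupper(pattern), "")[[1]]
  s <- strsplit(toupper(seq), "")[[1]]
  w <- length(p); n <- length(s)
  if (n < w) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(n - w + 1L)) {
    ok <- TRUE
    for (j in seq_len(w)) {
      if (!(s[i + j - 1L] %in% .ORACLE_IUPAC[[p[j]]])) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, i)
  }
  hits
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B",
            N = "N")
  paste(rev(comp[strsplit(toupper(x), "")[[1]]]), collapse = "")
}

# Full library scan mirroring scan_elements semantics.
oracle_scan <- function(seq, library) {
  out <- list()
  for (k in seq_len(nrow(library))) {
    plus <- oracle_match(library$pattern[k], seq)
    minus <- integer(0)
    if (isTRUE(library$both_strands[k])) {
      minus <- oracle_match(oracle_revcomp(library$pattern[k]), seq)
      minus <- setdiff(minus, plus)
    }
    if (length(plus) || length(minus)) {
      out[[length(out) + 1L]] <- data.frame(
        motif = library$name[k], offset = c(plus, minus),
        strand = c(rep("+", length(plus)), rep("-", length(minus))),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(motif = character(), offset = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$motif, res$offset), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# --- tandem clustering oracle -----------------------------------------

# Brute-force single-linkage by transitive closure of the pairwise
# <= max_gap relation (any pair, not just consecutive genes).
oracle_tandem <- function(genes, max_gap = 200000) {
  # genes: data.frame gene_id, chrom, start, end
  clusters <- list()
  for (ch in unique(genes$chrom)) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    g <- g[order(g$start, g$gene_id), , drop = FALSE]
    n <- nrow(g)
    if (n < 2L) next
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      d <- max(g$start[j], g$start[i]) - min(g$end[i], g$end[j])
      adj[i, j] <- d <= max_gap
    }
    seen <- logical(n)
    for (i in seq_len(n)) {
      if (seen[i]) next
      comp <- i
      repeat {
        grow <- which(apply(adj[comp, , drop = FALSE], 2, any) & !seq_len(n) %in% comp)
        if (!length(grow)) break
        comp <- sort(c(comp, grow))
      }
      seen[comp] <- TRUE
      if (length(comp) >= 2L)
        clusters[[length(clusters) + 1L]] <- list(chrom = ch,
                                                  members = g$gene_id[comp])
    }
  }
  clusters
}

# --- chain oracle ------------------------------------------------------

# Exhaustive longest (then highest-scoring) monotonic chain by DFS.
oracle_best_chain <- function(a, orientation, max_rank_gap) {
  n <- nrow(a)
  best <- list(len = 0L, score = -Inf)
  step_ok <- function(i, j) {
    ok_a <- a$rank_a[j] > a$rank_a[i] &&
      a$rank_a[j] - a$rank_a[i] <= max_rank_gap
    ok_b <- if (orientation == "same") {
      a$rank_b[j] > a$rank_b[i] && a$rank_b[j] - a$rank_b[i] <= max_rank_gap
    } else {
      a$rank_b[j] < a$rank_b[i] && a$rank_b[i] - a$rank_b[j] <= max_rank_gap
    }
    ok_a && ok_b
  }
  dfs <- function(chain, score) {
    if (length(chain) > best$len ||
        (length(chain) == best$len && score > best$score)) {
      best <<- list(len = length(chain), score = score, chain = chain)
    }
    last <- chain[length(chain)]
    for (j in seq_len(n)) {
      if (j %in% chain) next
      if (step_ok(last, j)) dfs(c(chain, j), score + a$score[j])
    }
  }
  for (i in seq_len(n)) dfs(i, a$score[i])
  best
}

# --- p-distance oracle --------------------------------------------------

oracle_pdist <- function(sa, sb) {
  a <- strsplit(sa, "")[[1]]; b <- strsplit(sb, "")[[1]]
  keep <- !(a %in% c("-", ".")) & !(b %in% c("-", "."))
  sum(a[keep] != b[keep]) / sum(keep)
}

# Random sense-codon CDS for oracle tests (uses the session RNG).
oracle_random_cds <- function(n_codons) {
  sense <- setdiff(names(.ORACLE_GC), .ORACLE_STOPS)
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}
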