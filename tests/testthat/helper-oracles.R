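# Independent oracles and fixture builders used across the suite.

# --- brute-force affine-gap Smith-Waterman (Gotoh), scores only -----------
# Gap of length L costs open + L * ext, matching the package's scheme.
sw_score_oracle <- function(a, b, match = 2, mismatch = -3,
                            open = 5, ext = 2) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (a[i] == b[j]) match else mismatch
      M[i + 1, j + 1] <- max(0, max(M[i, j], Ix[i, j], Iy[i, j]) + s)
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, Ix[i, j + 1] - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Iy[i + 1, j] - ext)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# --- NG86 pathway enumeration, written independently of the package -------
# Explicit order lists per k (1, 2, 3 differing positions); averages the
# per-step synonymous/nonsynonymous counts over pathways that avoid stop
# codons; splits equally if every pathway is blocked.
ORACLE_GC <- local({
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("U", "T", names(gc))
  gc
})
ORACLE_STOPS <- c("TAA", "TAG", "TGA")

ng86_diff_oracle <- function(c1, c2) {
  x <- strsplit(c1, "")[[1]]; y <- strsplit(c2, "")[[1]]
  pos <- which(x != y)
  k <- length(pos)
  if (k == 0) return(c(Nd = 0, Sd = 0))
  orders <- switch(as.character(k),
    "1" = list(pos),
    "2" = list(pos, rev(pos)),
    "3" = list(pos[c(1, 2, 3)], pos[c(1, 3, 2)], pos[c(2, 1, 3)],
               pos[c(2, 3, 1)], pos[c(3, 1, 2)], pos[c(3, 2, 1)])
  )
  tallies <- lapply(orders, function(ord) {
    cur <- x; nd <- 0; sd <- 0
    for (p in ord) {
      prev <- paste(cur, collapse = "")
      cur[p] <- y[p]
      nxt <- paste(cur, collapse = "")
      if (nxt %in% ORACLE_STOPS) return(NULL)
      if (ORACLE_GC[[prev]] == ORACLE_GC[[nxt]]) sd <- sd + 1 else nd <- nd + 1
    }
    c(nd, sd)
  })
  ok <- !vapply(tallies, is.null, logical(1))
  if (!any(ok)) return(c(Nd = k / 2, Sd = k / 2))
  avg <- Reduce(`+`, tallies[ok]) / sum(ok)
  c(Nd = avg[1], Sd = avg[2])
}

# Synonymous site fraction of one codon by neighbor enumeration.
ng86_site_oracle <- function(codon) {
  nt <- strsplit(codon, "")[[1]]
  s <- 0
  for (p in 1:3) {
    neigh <- vapply(setdiff(c("A", "C", "G", "T"), nt[p]), function(a) {
      z <- nt; z[p] <- a; paste(z, collapse = "")
    }, character(1))
    keep <- !(neigh %in% ORACLE_STOPS)
    if (!any(keep)) next
    s <- s + sum(ORACLE_GC[neigh[keep]] == ORACLE_GC[[codon]]) / sum(keep)
  }
  s
}

# --- fixture builders ------------------------------------------------------
random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

random_valid_cds <- function(n_codons, seed = 1) {
  withr::with_seed(seed, {
    sense <- setdiff(names(ORACLE_GC)[ORACLE_GC != "*"], character(0))
    paste(c("ATG", sample(sense, n_codons - 2, TRUE), "TAA"), collapse = "")
  })
}

# Minimal hand-built catalog; genes tiled along one or more chromosomes.
toy_catalog <- function(n_genes, chrom = "chrA", species = "spX",
                        family = integer(0), cds = NULL, gap = 5000,
                        start0 = 1000, span = 2000, ids = NULL) {
  if (is.null(cds)) cds <- vapply(seq_len(n_genes), function(i)
    random_valid_cds(120, seed = 1000 + i), character(1))
  starts <- start0 + (seq_len(n_genes) - 1) * (span + gap)
  tibble::tibble(
    species = species,
    gene_id = if (is.null(ids)) sprintf("%s.g%03d", species, seq_len(n_genes)) else ids,
    chrom = chrom, locus = seq_len(n_genes),
    start = starts, end = starts + span - 1, strand = "+",
    exon_count = 1L,
    is_family = seq_len(n_genes) %in% family,
    cds = cds,
    protein = vapply(cds, duphist::translate_cds, character(1), USE.NAMES = FALSE)
  )
}

sense_codon_list <- function() {
  setdiff(names(ORACLE_GC)[ORACLE_GC != "*"], character(0))
}

# Two family genes on one chromosome with configurable gap geometry.
two_gene_catalog <- function(start_a, end_a, start_b, end_b,
                             intervening = 0, intervening_family = 0,
                             chrom_b = NULL) {
  n_int <- intervening + intervening_family
  fam_flags <- c(TRUE, rep(c(FALSE, TRUE),
                           c(intervening, intervening_family)), TRUE)
  gap_lo <- end_a; gap_hi <- start_b
  int_starts <- if (n_int > 0) {
    round(seq(gap_lo + 10, gap_hi - 200, length.out = n_int))
  } else numeric(0)
  cds1 <- random_valid_cds(120, seed = 1)
  prot1 <- translate_cds(cds1)
  tibble::tibble(
    species = "sp",
    gene_id = c("gA", sprintf("int%02d", seq_len(n_int)), "gB"),
    chrom = c("chr1", rep("chr1", n_int),
              if (is.null(chrom_b)) "chr1" else chrom_b),
    locus = NA_integer_,
    start = c(start_a, int_starts, start_b),
    end = c(end_a, int_starts + 100, end_b),
    strand = "+", exon_count = 1L,
    is_family = fam_flags,
    cds = cds1, protein = prot1
  )
}
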