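# Homology search and paralog/ortholog calling. Pairwise local alignment is
# full dynamic programming with BLASTN-like affine-gap scoring; identity is
# computed over all alignment columns, gaps included.

#' Scoring scheme for nucleotide local alignment
#'
#' BLASTN-like defaults: match +2, mismatch -3, gap open 5, gap extend 2,
#' and a reporting floor of score >= 50 for [all_vs_all()]. Ambiguity codes
#' score as mismatches.
#'
#' @param match,mismatch Substitution scores.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param score_floor Minimum score for a hit to be reported.
#' @return A `homology_scoring` list.
#' @export
homology_scoring <- function(match = 2, mismatch = -3, gap_open = 5,
                             gap_extend = 2, score_floor = 50) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend >= 0)
  letters <- c(NUCS, "M", "R", "W", "S", "Y", "K", "V", "H", "D", "B", "N")
  mat <- matrix(mismatch, length(letters), length(letters),
                dimnames = list(letters, letters))
  mat[cbind(NUCS, NUCS)] <- match
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, score_floor = score_floor,
                 matrix = mat),
            class = "homology_scoring")
}

check_nucleotide <- function(seq, name) {
  bad <- gsub("[ACGTMRWSYKVHDBN]", "", toupper(seq))
  if (nchar(bad) > 0) {
    stop(name, " contains non-nucleotide characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ""), call. = FALSE)
  }
  invisible(TRUE)
}

hit_from_alignment <- function(pa, qlen) {
  p <- as.character(Biostrings::pattern(pa))
  s <- as.character(Biostrings::subject(pa))
  cols <- nchar(p)
  ident <- sum(strsplit(p, "")[[1]] == strsplit(s, "")[[1]])
  tibble::tibble(
    identity = 100 * ident / cols,
    aligned_length = cols,
    score = Biostrings::score(pa),
    query_coverage = (nchar(gsub("-", "", p))) / qlen
  )
}

#' Best local alignment of two nucleotide sequences
#'
#' Full-DP affine-gap Smith-Waterman under a [homology_scoring()] scheme.
#' Identity is identical columns over total alignment columns (gap columns
#' included) as a percentage; `aligned_length` is the total alignment
#' columns.
#'
#' @param seq_a,seq_b Non-empty nucleotide sequences.
#' @param scoring A [homology_scoring()].
#' @return One-row tibble: `identity`, `aligned_length`, `score`,
#'   `query_coverage` (aligned fraction of `seq_a`).
#' @export
local_align <- function(seq_a, seq_b, scoring = homology_scoring()) {
  stopifnot(nchar(seq_a) > 0, nchar(seq_b) > 0)
  check_nucleotide(seq_a, "seq_a"); check_nucleotide(seq_b, "seq_b")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(seq_a)), Biostrings::DNAString(toupper(seq_b)),
    type = "local", substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend
  )
  hit_from_alignment(pa, nchar(seq_a))
}

# Align one query against a set of subjects in one vectorized call.
local_align_set <- function(query, subjects, scoring) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(toupper(subjects)),
    Biostrings::DNAString(toupper(query)),
    type = "local", substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend
  )
  # pattern = subjects here; identity/length are orientation-symmetric
  p <- as.character(Biostrings::pattern(pa))
  s <- as.character(Biostrings::subject(pa))
  cols <- nchar(p)
  ident <- mapply(function(x, y) sum(strsplit(x, "")[[1]] == strsplit(y, "")[[1]]),
                  p, s, USE.NAMES = FALSE)
  tibble::tibble(
    identity = 100 * ident / cols,
    aligned_length = cols,
    score = Biostrings::score(pa),
    query_coverage = nchar(gsub("-", "", s)) / nchar(query)
  )
}

#' All-vs-all homology search
#'
#' Computes the best local alignment for every unordered gene pair (within
#' one catalog) or every cross pair (between two catalogs) and reports hits
#' passing the scoring floor. Self-hits are excluded; each unordered pair is
#' recorded once.
#'
#' @param catalog_a A gene catalog (or any data frame with `gene_id`,
#'   `species`, `cds`).
#' @param catalog_b Optional second catalog for a cross-species search.
#' @param genes_a,genes_b Optional gene-id subsets to restrict the search.
#' @param scoring A [homology_scoring()].
#' @param cache Optional environment caching alignments across calls (keyed
#'   by unordered id pair).
#' @return Hits tibble: `query`, `subject`, `species_q`, `species_s`,
#'   `identity`, `aligned_length`, `score`, `query_coverage`.
#' @export
all_vs_all <- function(catalog_a, catalog_b = NULL, genes_a = NULL,
                       genes_b = NULL, scoring = homology_scoring(),
                       cache = NULL) {
  a <- if (is.null(genes_a)) catalog_a else
    catalog_a[catalog_a$gene_id %in% genes_a, ]
  within <- is.null(catalog_b)
  b <- if (within) a else if (is.null(genes_b)) catalog_b else
    catalog_b[catalog_b$gene_id %in% genes_b, ]
  pairs <- if (within) {
    if (nrow(a) < 2L) return(empty_hits())
    idx <- utils::combn(nrow(a), 2L)
    tibble::tibble(i = idx[1, ], j = idx[2, ])
  } else {
    if (nrow(a) == 0L || nrow(b) == 0L) return(empty_hits())
    tidyr::expand_grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
  }
  pairs <- pairs[ (if (within) a$gene_id[pairs$j] else b$gene_id[pairs$j]) !=
                    a$gene_id[pairs$i], ]
  if (nrow(pairs) == 0L) return(empty_hits())
  bi <- if (within) a else b
  res <- aligned_pairs(a$gene_id[pairs$i], a$cds[pairs$i],
                       bi$gene_id[pairs$j], bi$cds[pairs$j], scoring, cache)
  hits <- dplyr::bind_cols(
    tibble::tibble(query = a$gene_id[pairs$i], subject = bi$gene_id[pairs$j],
                   species_q = a$species[pairs$i],
                   species_s = bi$species[pairs$j]),
    res
  )
  hits[hits$score >= scoring$score_floor, ]
}

empty_hits <- function() {
  tibble::tibble(query = character(), subject = character(),
                 species_q = character(), species_s = character(),
                 identity = numeric(), aligned_length = integer(),
                 score = numeric(), query_coverage = numeric())
}

# Align id/cds vectors pairwise, grouping by query for vectorized calls and
# consulting/filling the cache.
aligned_pairs <- function(ids_a, cds_a, ids_b, cds_b, scoring, cache = NULL) {
  n <- length(ids_a)
  out <- vector("list", n)
  todo <- rep(TRUE, n)
  keys <- character(n)
  if (!is.null(cache)) {
    keys <- paste(pmin(ids_a, ids_b), pmax(ids_a, ids_b), sep = "\r")
    for (i in seq_len(n)) {
      hit <- cache[[keys[i]]]
      if (!is.null(hit)) { out[[i]] <- hit; todo[i] <- FALSE }
    }
  }
  if (any(todo)) {
    for (q in unique(ids_a[todo])) {
      sel <- which(todo & ids_a == q)
      res <- local_align_set(cds_a[sel[1]], cds_b[sel], scoring)
      for (k in seq_along(sel)) {
        hit <- res[k, ]
        out[[sel[k]]] <- hit
        if (!is.null(cache)) cache[[keys[sel[k]]]] <- hit
      }
    }
  }
  dplyr::bind_rows(out)
}

canonical_pairs <- function(gene_a, gene_b) {
  tibble::tibble(gene_a = pmin(gene_a, gene_b), gene_b = pmax(gene_a, gene_b))
}

#' Call paralog pairs from within-species hits
#'
#' A hit is a paralog pair when identity exceeds 40 percent (strict) and the
#' alignment covers more than 300 bp (strict). Pairs are canonicalized
#' (gene_a < gene_b).
#'
#' @param hits Hits from a single-species [all_vs_all()].
#' @param min_identity,min_aligned_length Strict thresholds.
#' @return Tibble of pairs with their alignment evidence.
#' @export
call_paralogs <- function(hits, min_identity = 40, min_aligned_length = 300) {
  if (nrow(hits) && length(unique(c(hits$species_q, hits$species_s))) > 1L) {
    stop("call_paralogs() requires hits from a single species", call. = FALSE)
  }
  kept <- hits[hits$identity > min_identity &
                 hits$aligned_length > min_aligned_length, ]
  dplyr::bind_cols(
    canonical_pairs(kept$query, kept$subject),
    kept[c("species_q", "identity", "aligned_length", "score")]
  ) |>
    dplyr::rename(species = "species_q") |>
    dplyr::distinct(.data$gene_a, .data$gene_b, .keep_all = TRUE) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
}

#' Call ortholog pairs by reciprocal best hit
#'
#' A cross-species pair (a, b) is an ortholog pair when b is a's best hit, a
#' is b's best hit, and both alignments span at least 300 columns. Best-hit
#' ties are broken by higher identity, then lexicographic gene id.
#'
#' @param hits Cross-species hits (symmetric; from [all_vs_all()] with two
#'   catalogs). A second directional table may be supplied as `hits_ba` and
#'   is appended.
#' @param hits_ba Optional reverse-direction hits.
#' @param min_aligned_length Inclusive threshold on alignment columns.
#' @return Tibble of ortholog pairs with evidence.
#' @export
call_orthologs <- function(hits, hits_ba = NULL, min_aligned_length = 300) {
  if (!is.null(hits_ba)) hits <- dplyr::bind_rows(hits, hits_ba)
  if (nrow(hits) == 0L) {
    return(tibble::tibble(gene_a = character(), gene_b = character(),
                          species_a = character(), species_b = character(),
                          identity = numeric(), aligned_length = integer(),
                          score = numeric()))
  }
  if (any(hits$species_q == hits$species_s)) {
    stop("call_orthologs() requires cross-species hits", call. = FALSE)
  }
  # symmetric edge list: one row per direction
  edges <- dplyr::bind_rows(
    hits[c("query", "subject", "species_q", "species_s",
           "identity", "aligned_length", "score")],
    dplyr::rename(hits[c("subject", "query", "species_s", "species_q",
                         "identity", "aligned_length", "score")],
                  query = "subject", subject = "query",
                  species_q = "species_s", species_s = "species_q")
  ) |> dplyr::distinct(.data$query, .data$subject, .keep_all = TRUE)
  best <- edges |>
    dplyr::group_by(.data$query) |>
    dplyr::arrange(dplyr::desc(.data$score), dplyr::desc(.data$identity),
                   .data$subject, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  mutual <- dplyr::inner_join(
    best, best,
    by = c(query = "subject", subject = "query"),
    suffix = c("", ".rev")
  )
  mutual <- mutual[mutual$query < mutual$subject &
                     mutual$aligned_length >= min_aligned_length &
                     mutual$aligned_length.rev >= min_aligned_length, ]
  tibble::tibble(
    gene_a = mutual$query, gene_b = mutual$subject,
    species_a = mutual$species_q, species_b = mutual$species_s,
    identity = mutual$identity, aligned_length = mutual$aligned_length,
    score = mutual$score
  ) |> dplyr::arrange(.data$gene_a, .data$gene_b)
}
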