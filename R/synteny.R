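# Microsynteny block detection, tandem-duplication classification, synteny
# quality, and grouping of collinear segments into ancestral loci.
#
# A duplicated-region call requires that two family members are homologous
# and that at least `min_flank_matches` of the k upstream/downstream
# neighboring genes on each side also form homologous pairs (one-to-one).

#' Flanking window of a gene
#'
#' Up to `k` genes on each side of `gene_id` in chromosome order, truncated
#' at chromosome ends; the anchor itself is excluded.
#'
#' @param catalog A gene catalog.
#' @param gene_id Anchor gene.
#' @param k Window half-width in genes.
#' @return List with `upstream` and `downstream` gene-id vectors.
#' @export
flanking_window <- function(catalog, gene_id, k = 50) {
  catalog <- as_gene_catalog(catalog)
  g <- catalog_gene(catalog, gene_id)
  chrom <- catalog[catalog$chrom == g$chrom, ]
  i <- which(chrom$gene_id == gene_id)
  list(
    upstream = chrom$gene_id[seq_len(i - 1L)] |> utils::tail(k),
    downstream = chrom$gene_id[seq(i + 1L, length.out = min(k, nrow(chrom) - i))]
  )
}

#' Synteny quality of a block
#'
#' Twice the number of matched genes (anchor pair included) divided by the
#' total number of genes in both segments, as a percentage.
#'
#' @param matches Matched gene pairs including the anchor pair.
#' @param size_a,size_b Genes in each segment (anchor + window genes
#'   present).
#' @return Percentage in \[0, 100\].
#' @export
synteny_quality <- function(matches, size_a, size_b) {
  stopifnot(size_a >= 1, size_b >= 1)
  200 * matches / (size_a + size_b)
}

# Greedy best-score one-to-one matching of flank genes under the homology
# edge table. Edges are ranked by score, then identity, then ids.
greedy_flank_matching <- function(window_a, window_b, edges) {
  if (nrow(edges) == 0L) return(edges[0, ])
  sel <- (edges$query %in% window_a & edges$subject %in% window_b) |
    (edges$query %in% window_b & edges$subject %in% window_a)
  edges <- edges[sel, ]
  if (nrow(edges) == 0L) return(edges)
  flip <- !(edges$query %in% window_a)
  tmp <- edges$query[flip]
  edges$query[flip] <- edges$subject[flip]
  edges$subject[flip] <- tmp
  edges <- edges[order(-edges$score, -edges$identity,
                       edges$query, edges$subject), ]
  used_a <- character(0); used_b <- character(0)
  keep <- logical(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    if (edges$query[i] %in% used_a || edges$subject[i] %in% used_b) next
    keep[i] <- TRUE
    used_a <- c(used_a, edges$query[i])
    used_b <- c(used_b, edges$subject[i])
  }
  edges[keep, ]
}

#' Test one anchor pair for a shared syntenic block
#'
#' Flank matches are a greedy one-to-one matching between the two flanking
#' windows under the supplied homology hits (filtered at the relaxed flank
#' thresholds); a block is emitted iff the matching has at least
#' `min_flank_matches` pairs.
#'
#' @param catalog_a,catalog_b Catalogs holding the two anchors (the same
#'   catalog for a within-species test).
#' @param gene_a,gene_b Anchor gene ids (family members, already known
#'   homologous).
#' @param hits Homology hits covering the two flanking windows.
#' @param k Window half-width.
#' @param min_flank_matches Minimum one-to-one flank matches.
#' @param flank_min_identity,flank_min_len Relaxed thresholds applied to
#'   flank-gene hits.
#' @return One-row block tibble, or `NULL` when the threshold is not met.
#'   Columns: anchors, species, `match_count`, `segment_size_a/b`, `quality`,
#'   and a `flank_matches` list-column of matched pairs.
#' @export
detect_block <- function(catalog_a, catalog_b, gene_a, gene_b, hits,
                         k = 50, min_flank_matches = 3,
                         flank_min_identity = 40, flank_min_len = 150) {
  stopifnot(gene_a != gene_b)
  wa <- flanking_window(catalog_a, gene_a, k)
  wb <- flanking_window(catalog_b, gene_b, k)
  window_a <- c(wa$upstream, wa$downstream)
  window_b <- c(wb$upstream, wb$downstream)
  window_b <- setdiff(window_b, gene_a)
  window_a <- setdiff(window_a, gene_b)
  edges <- hits[hits$identity > flank_min_identity &
                  hits$aligned_length > flank_min_len, ]
  matched <- greedy_flank_matching(window_a, window_b, edges)
  if (nrow(matched) < min_flank_matches) return(NULL)
  size_a <- 1L + length(window_a)
  size_b <- 1L + length(window_b)
  sa <- catalog_gene(catalog_a, gene_a)$species
  sb <- catalog_gene(catalog_b, gene_b)$species
  tibble::tibble(
    anchor_a = gene_a, anchor_b = gene_b,
    species_a = sa, species_b = sb,
    match_count = nrow(matched),
    segment_size_a = size_a, segment_size_b = size_b,
    quality = synteny_quality(nrow(matched) + 1L, size_a, size_b),
    flank_matches = list(tibble::tibble(gene_a = matched$query,
                                        gene_b = matched$subject))
  )
}

#' Detect syntenic blocks for all family anchor pairs
#'
#' Anchor candidates are family gene pairs passing the paralog thresholds
#' (identity > 40, alignment > 300 bp). Flank homology is computed lazily:
#' only genes inside the two windows of a candidate anchor pair are aligned,
#' with results cached across anchors.
#'
#' @param catalog_a A gene catalog; `catalog_b = NULL` searches within it,
#'   otherwise across the two species.
#' @param catalog_b Optional second catalog.
#' @param k,min_flank_matches,flank_min_identity,flank_min_len See
#'   [detect_block()].
#' @param scoring A [homology_scoring()].
#' @param anchor_min_identity,anchor_min_len Strict anchor thresholds.
#' @param cache Optional alignment cache environment (shared across calls).
#' @return List with `blocks` (tibble of emitted blocks), `anchors`
#'   (candidate anchor pairs with evidence) and `hits` (all alignments
#'   computed, anchor and flank).
#' @export
find_synteny_blocks <- function(catalog_a, catalog_b = NULL, k = 50,
                                min_flank_matches = 3,
                                scoring = homology_scoring(),
                                anchor_min_identity = 40,
                                anchor_min_len = 300,
                                flank_min_identity = 40, flank_min_len = 150,
                                cache = NULL) {
  catalog_a <- as_gene_catalog(catalog_a)
  within <- is.null(catalog_b)
  catalog_b <- if (within) catalog_a else as_gene_catalog(catalog_b)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  fam_a <- catalog_a$gene_id[catalog_a$is_family]
  fam_b <- catalog_b$gene_id[catalog_b$is_family]
  fam_hits <- all_vs_all(catalog_a, if (within) NULL else catalog_b,
                         genes_a = fam_a, genes_b = fam_b,
                         scoring = scoring, cache = cache)
  anchors <- fam_hits[fam_hits$identity > anchor_min_identity &
                        fam_hits$aligned_length > anchor_min_len, ]
  all_hits <- list(fam_hits)
  blocks <- list()
  for (i in seq_len(nrow(anchors))) {
    ga <- anchors$query[i]; gb <- anchors$subject[i]
    wa <- flanking_window(catalog_a, ga, k)
    wb <- flanking_window(catalog_b, gb, k)
    window_a <- setdiff(c(wa$upstream, wa$downstream), gb)
    window_b <- setdiff(c(wb$upstream, wb$downstream), ga)
    if (length(window_a) && length(window_b)) {
      flank_hits <- all_vs_all(catalog_a, catalog_b,
                               genes_a = window_a, genes_b = window_b,
                               scoring = scoring, cache = cache)
      all_hits[[length(all_hits) + 1L]] <- flank_hits
    }
    hits_i <- dplyr::distinct(dplyr::bind_rows(all_hits),
                              .data$query, .data$subject, .keep_all = TRUE)
    b <- detect_block(catalog_a, catalog_b, ga, gb, hits_i, k = k,
                      min_flank_matches = min_flank_matches,
                      flank_min_identity = flank_min_identity,
                      flank_min_len = flank_min_len)
    if (!is.null(b)) blocks[[length(blocks) + 1L]] <- b
  }
  list(
    blocks = if (length(blocks)) dplyr::bind_rows(blocks) else empty_blocks(),
    anchors = anchors,
    hits = dplyr::distinct(dplyr::bind_rows(all_hits),
                           .data$query, .data$subject, .keep_all = TRUE)
  )
}

empty_blocks <- function() {
  tibble::tibble(anchor_a = character(), anchor_b = character(),
                 species_a = character(), species_b = character(),
                 match_count = integer(), segment_size_a = integer(),
                 segment_size_b = integer(), quality = numeric(),
                 flank_matches = list())
}

#' Cross-species microsynteny
#'
#' [find_synteny_blocks()] applied across two distinct species; blocks carry
#' both species tags.
#'
#' @inheritParams find_synteny_blocks
#' @return As [find_synteny_blocks()].
#' @export
cross_species_synteny <- function(catalog_a, catalog_b, k = 50,
                                  min_flank_matches = 3, ...) {
  if (identical(catalog_a$species[1], catalog_b$species[1])) {
    stop("cross_species_synteny() requires two distinct species",
         call. = FALSE)
  }
  find_synteny_blocks(catalog_a, catalog_b, k = k,
                      min_flank_matches = min_flank_matches, ...)
}

#' Tandem-duplication test for a gene pair
#'
#' True iff both genes are family members on the same chromosome, their
#' nearest span boundaries are within `max_gap_bp` (60 kb), and at most
#' `max_intervening_loci` (5) non-family gene loci lie strictly between
#' them. Intervening genes of the focal family extend the tandem cluster
#' rather than counting toward the limit.
#'
#' @param catalog A gene catalog.
#' @param gene_a,gene_b Gene ids.
#' @param max_gap_bp Nearest-boundary distance limit in bp.
#' @param max_intervening_loci Limit on non-family loci strictly between the
#'   spans.
#' @return Logical scalar; symmetric in the gene arguments.
#' @export
tandem_test <- function(catalog, gene_a, gene_b, max_gap_bp = 60000,
                        max_intervening_loci = 5) {
  catalog <- as_gene_catalog(catalog)
  a <- catalog_gene(catalog, gene_a)
  b <- catalog_gene(catalog, gene_b)
  if (!(a$is_family && b$is_family)) return(FALSE)
  if (a$chrom != b$chrom) return(FALSE)
  lo <- if (a$start <= b$start) a else b
  hi <- if (a$start <= b$start) b else a
  gap <- max(0L, hi$start - lo$end)
  if (gap > max_gap_bp) return(FALSE)
  between <- catalog$chrom == a$chrom &
    catalog$start > lo$end & catalog$end < hi$start &
    !catalog$is_family
  sum(between) <= max_intervening_loci
}

#' Maximal tandem clusters of a catalog
#'
#' All same-chromosome family pairs are tested with [tandem_test()] and
#' passing pairs are merged transitively into maximal chains.
#'
#' @inheritParams tandem_test
#' @return List with `pairs` (tibble of passing pairs) and `clusters`
#'   (tibble gene_id/cluster).
#' @export
tandem_clusters <- function(catalog, max_gap_bp = 60000,
                            max_intervening_loci = 5) {
  catalog <- as_gene_catalog(catalog)
  fam <- catalog[catalog$is_family, ]
  pairs <- list()
  for (chrom in unique(fam$chrom)) {
    ids <- fam$gene_id[fam$chrom == chrom]
    if (length(ids) < 2L) next
    idx <- utils::combn(ids, 2L)
    for (p in seq_len(ncol(idx))) {
      if (tandem_test(catalog, idx[1, p], idx[2, p], max_gap_bp,
                      max_intervening_loci)) {
        pairs[[length(pairs) + 1L]] <- canonical_pairs(idx[1, p], idx[2, p])
      }
    }
  }
  pairs <- if (length(pairs)) dplyr::bind_rows(pairs) else
    tibble::tibble(gene_a = character(), gene_b = character())
  clusters <- if (nrow(pairs)) {
    g <- igraph::graph_from_data_frame(pairs, directed = FALSE)
    comp <- igraph::components(g)
    tibble::tibble(gene_id = names(comp$membership),
                   cluster = as.integer(comp$membership)) |>
      dplyr::arrange(.data$cluster, .data$gene_id)
  } else {
    tibble::tibble(gene_id = character(), cluster = integer())
  }
  list(pairs = pairs, clusters = clusters)
}

#' Group collinear segments into ancestral loci
#'
#' Builds the graph whose edges are block anchor pairs and returns its
#' connected components, ordered by size (descending) then smallest gene id,
#' labeled "A", "B", ... The result is invariant to block input order.
#'
#' @param blocks A blocks tibble (within- and/or cross-species), or a list
#'   of them.
#' @param catalogs Optional combined catalog used to attach species tags.
#' @return Tibble: `group`, `gene_id`, `species` (NA when unknown).
#' @export
ancestral_groups <- function(blocks, catalogs = NULL) {
  if (is.list(blocks) && !is.data.frame(blocks)) {
    blocks <- dplyr::bind_rows(blocks)
  }
  if (nrow(blocks) == 0L) {
    return(tibble::tibble(group = character(), gene_id = character(),
                          species = character()))
  }
  edges <- tibble::tibble(from = blocks$anchor_a, to = blocks$anchor_b) |>
    dplyr::arrange(.data$from, .data$to)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  ord <- order(-vapply(members, length, integer(1)),
               vapply(members, min, character(1)))
  members <- members[ord]
  labels <- group_labels(length(members))
  sp <- if (!is.null(catalogs)) {
    stats::setNames(catalogs$species, catalogs$gene_id)
  } else NULL
  purrr::map2(seq_along(members), members, function(i, ids) {
    tibble::tibble(group = labels[i], gene_id = sort(ids))
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(
      species = if (is.null(sp)) NA_character_ else unname(sp[.data$gene_id])
    )
}

# "A".."Z", then "AA", "AB", ...
group_labels <- function(n) {
  if (n <= 26L) return(LETTERS[seq_len(n)])
  extra <- n - 26L
  c(LETTERS,
    paste0(LETTERS[ceiling(seq_len(extra) / 26)],
           LETTERS[((seq_len(extra) - 1L) %% 26L) + 1L]))
}
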