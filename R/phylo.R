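# Protein distance matrices, neighbor-joining trees with bootstrap support,
# and per-subfamily mean genetic distances.

#' Multiple protein alignment
#'
#' Sequences of equal length are returned as-is (the simulator's homologs
#' are colinear). Otherwise the mafft command-line aligner is invoked.
#'
#' @param proteins Named character vector of protein sequences.
#' @return Named character vector of gapped sequences of equal width.
#' @export
align_proteins <- function(proteins) {
  stopifnot(length(proteins) >= 2, !is.null(names(proteins)))
  if (length(unique(nchar(proteins))) == 1L) return(proteins)
  if (Sys.which("mafft") == "") {
    stop("sequences differ in length and mafft is not on the PATH",
         call. = FALSE)
  }
  infile <- tempfile(fileext = ".fasta")
  outfile <- tempfile(fileext = ".fasta")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(proteins), infile)
  status <- system2("mafft", c("--auto", "--quiet", "--anysymbol", infile),
                    stdout = outfile)
  if (status != 0) stop("mafft failed with status ", status, call. = FALSE)
  aln <- Biostrings::readAAStringSet(outfile)
  out <- toupper(as.character(aln))
  names(out) <- names(aln)
  out[names(proteins)]
}

#' Pairwise protein distance matrix
#'
#' p-distance (mismatched columns over compared columns, pairwise gap
#' deletion) or its Poisson correction `-log(1 - p)`.
#'
#' @param proteins Named character vector; either pre-aligned (equal widths,
#'   `-` gaps) or ungapped equal-length sequences.
#' @param model `"p_distance"` (default) or `"poisson"`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
protein_distance_matrix <- function(proteins,
                                    model = c("p_distance", "poisson")) {
  model <- match.arg(model)
  stopifnot(length(proteins) >= 3)
  aligned <- align_proteins(proteins)
  chars <- t(vapply(aligned, function(s) strsplit(s, "")[[1]],
                    character(nchar(aligned[1]))))
  n <- nrow(chars)
  d <- matrix(0, n, n, dimnames = list(names(proteins), names(proteins)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      ok <- chars[i, ] != "-" & chars[j, ] != "-"
      if (!any(ok)) {
        stop("all-gap pair: ", names(proteins)[i], " vs ",
             names(proteins)[j], call. = FALSE)
      }
      p <- mean(chars[i, ok] != chars[j, ok])
      d[i, j] <- d[j, i] <- if (model == "poisson") -log(1 - p) else p
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard NJ agglomeration (Q-matrix criterion) on a symmetric distance
#' matrix; additive distances are recovered exactly. Negative branch-length
#' estimates are clamped to zero, recorded in the `clamped` attribute.
#'
#' @param d Symmetric distance matrix with >= 3 labeled taxa.
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("need at least 3 taxa", call. = FALSE)
  if (!isSymmetric(unname(d), tol = 1e-8)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  tree <- ape::nj(d)
  n_neg <- sum(tree$edge.length < 0)
  if (n_neg > 0) tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "clamped") <- n_neg
  tree
}

#' Neighbor-joining tree with bootstrap support
#'
#' Alignment columns are resampled with replacement `n_replicates` times;
#' support for each internal edge of the full-data NJ tree is the percentage
#' of replicate trees containing the same bipartition, stored in
#' `node.label`.
#'
#' @param proteins Aligned (or equal-length) named protein sequences.
#' @param n_replicates Bootstrap replicates; 0 returns the tree without
#'   supports.
#' @param seed Integer seed.
#' @param model Distance model, see [protein_distance_matrix()].
#' @return A `phylo` tree; internal nodes carry support in \[0, 100\].
#' @export
bootstrap_support <- function(proteins, n_replicates = 1000, seed = 1,
                              model = "p_distance") {
  aligned <- align_proteins(proteins)
  base <- neighbor_joining(protein_distance_matrix(aligned, model))
  if (n_replicates == 0) return(base)
  ncol_aln <- nchar(aligned[1])
  chars <- vapply(aligned, function(s) strsplit(s, "")[[1]],
                  character(ncol_aln))
  trees <- withr::with_seed(seed, {
    lapply(seq_len(n_replicates), function(r) {
      cols <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
      boot <- apply(chars[cols, , drop = FALSE], 2, paste, collapse = "")
      neighbor_joining(protein_distance_matrix(boot, model))
    })
  })
  counts <- ape::prop.clades(base, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0
  base$node.label <- round(100 * counts / n_replicates, 1)
  base
}

#' Mean within-subfamily genetic distance
#'
#' Mean over all unordered within-subfamily pairs of the distance matrix.
#' Subfamilies with fewer than two members get `NA` and are flagged.
#'
#' @param d Distance matrix from [protein_distance_matrix()].
#' @param membership Named character vector mapping gene id to subfamily.
#' @return Tibble: `subfamily`, `n_members`, `n_pairs`, `mean_distance`.
#' @export
clade_mean_distance <- function(d, membership) {
  stopifnot(all(rownames(d) %in% names(membership)))
  subs <- sort(unique(membership[rownames(d)]))
  purrr::map(subs, function(sf) {
    ids <- intersect(rownames(d), names(membership)[membership == sf])
    n <- length(ids)
    md <- if (n >= 2) mean(d[ids, ids][upper.tri(diag(n))]) else NA_real_
    tibble::tibble(subfamily = sf, n_members = n,
                   n_pairs = n * (n - 1) / 2, mean_distance = md)
  }) |> dplyr::bind_rows()
}
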