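# Ka/Ks estimation: protein-guided codon alignment, NG86 counting with
# equal-weight pathway averaging, Jukes-Cantor correction, and
# selection-regime classification.

#' Build a codon alignment from two equal-length homologous CDSs
#'
#' Convenience constructor for CDS pairs that are already colinear (no
#' indels), e.g. simulator output. Terminal stop codons are dropped.
#'
#' @param cds_a,cds_b Coding sequences of equal codon length.
#' @return A `duphist_codon_alignment`: list with `codons_a`, `codons_b`,
#'   `dropped_codon_count`.
#' @export
codon_alignment <- function(cds_a, cds_b) {
  a <- sense_codon_vector(cds_a, "cds_a")
  b <- sense_codon_vector(cds_b, "cds_b")
  if (length(a) != length(b)) {
    stop("CDSs differ in codon length; align proteins first ",
         "(see backtranslate_to_codon_alignment())", call. = FALSE)
  }
  new_codon_alignment(a, b, 0L)
}

new_codon_alignment <- function(codons_a, codons_b, dropped) {
  structure(
    list(codons_a = codons_a, codons_b = codons_b,
         dropped_codon_count = as.integer(dropped)),
    class = "duphist_codon_alignment"
  )
}

#' @export
print.duphist_codon_alignment <- function(x, ...) {
  cat("<codon alignment>", length(x$codons_a), "codon columns,",
      x$dropped_codon_count, "gapped columns dropped\n")
  invisible(x)
}

#' Global pairwise protein alignment
#'
#' Needleman-Wunsch global alignment with BLOSUM62 scoring and affine gaps
#' (open 10, extend 1), used to guide codon alignment of a CDS pair.
#'
#' @param prot_a,prot_b Ungapped protein sequences.
#' @return List with gapped strings `a` and `b` (equal width).
#' @export
align_protein_pair <- function(prot_a, prot_b) {
  stopifnot(nchar(prot_a) > 0, nchar(prot_b) > 0)
  blosum62 <- get_blosum62()
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(prot_a), Biostrings::AAString(prot_b),
    type = "global", substitutionMatrix = blosum62,
    gapOpening = 10, gapExtension = 1
  )
  list(a = as.character(Biostrings::pattern(pa)),
       b = as.character(Biostrings::subject(pa)))
}

get_blosum62 <- function() {
  m <- .duphist_env$blosum62
  if (is.null(m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    .duphist_env$blosum62 <- m
  }
  m
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each aligned amino-acid column is mapped back to its source codons.
#' Columns with a gap in either sequence are dropped and counted.
#'
#' @param prot_aln_a,prot_aln_b Gapped protein strings of equal width (use
#'   [align_protein_pair()]), whose ungapped sequences translate exactly from
#'   the CDSs.
#' @param cds_a,cds_b The source coding sequences (terminal stop allowed).
#' @return A `duphist_codon_alignment`.
#' @export
backtranslate_to_codon_alignment <- function(prot_aln_a, prot_aln_b,
                                             cds_a, cds_b) {
  if (nchar(prot_aln_a) != nchar(prot_aln_b)) {
    stop("aligned protein strings differ in width", call. = FALSE)
  }
  cols_a <- strsplit(prot_aln_a, "")[[1]]
  cols_b <- strsplit(prot_aln_b, "")[[1]]
  codons_a <- sense_codon_vector(cds_a, "cds_a")
  codons_b <- sense_codon_vector(cds_b, "cds_b")
  check_backtranslation(cols_a, codons_a, "a")
  check_backtranslation(cols_b, codons_b, "b")
  ia <- cumsum(cols_a != "-")
  ib <- cumsum(cols_b != "-")
  keep <- cols_a != "-" & cols_b != "-"
  new_codon_alignment(codons_a[ia[keep]], codons_b[ib[keep]], sum(!keep))
}

check_backtranslation <- function(cols, codons, which) {
  res <- cols[cols != "-"]
  if (length(res) != length(codons)) {
    stop("protein alignment ", which, " has ", length(res),
         " residues but CDS has ", length(codons), " codons", call. = FALSE)
  }
  aa <- unname(genetic_code()[codons])
  if (!identical(aa, res)) {
    stop("protein alignment ", which, " does not match the translation of its CDS",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' NG86 difference counts over a codon alignment
#'
#' @param alignment A `duphist_codon_alignment`.
#' @return Named numeric vector `c(Nd = , Sd = )`.
#' @export
ng86_differences <- function(alignment) {
  stopifnot(inherits(alignment, "duphist_codon_alignment"))
  tabs <- ng86_diff_tables()
  sense <- rownames(tabs$Nd)
  ia <- match(alignment$codons_a, sense)
  ib <- match(alignment$codons_b, sense)
  if (anyNA(ia) || anyNA(ib)) stop("non-sense codon in alignment", call. = FALSE)
  idx <- cbind(ia, ib)
  c(Nd = sum(tabs$Nd[idx]), Sd = sum(tabs$Sd[idx]))
}

#' Ka, Ks and omega for one codon alignment (NG86 + Jukes-Cantor)
#'
#' Sites are averaged between the two sequences; differences use
#' equal-weight pathway averaging with stop pathways excluded. Proportions
#' are corrected with the Jukes-Cantor formula `-3/4 * log(1 - 4p/3)`.
#' `Ks` is reported as `NA` with `saturated = TRUE` when `pS >= 3/4` (and
#' likewise for `Ka`/`pN`); `omega = Ka/Ks` is `NA` unless `Ks > 0`.
#'
#' @param alignment A `duphist_codon_alignment`, or a CDS (then `cds_b` must
#'   be given and the pair is aligned via the protein alignment).
#' @param cds_b Optional second CDS when `alignment` is a CDS.
#' @return One-row tibble: `n_codons`, `N`, `S`, `Nd`, `Sd`, `pN`, `pS`,
#'   `Ka`, `Ks`, `omega`, `saturated`, `regime`.
#' @export
compute_kaks <- function(alignment, cds_b = NULL) {
  if (!inherits(alignment, "duphist_codon_alignment")) {
    stopifnot(!is.null(cds_b))
    prot_a <- translate_cds(alignment)
    prot_b <- translate_cds(cds_b)
    aln <- align_protein_pair(prot_a, prot_b)
    alignment <- backtranslate_to_codon_alignment(aln$a, aln$b, alignment, cds_b)
  }
  L <- length(alignment$codons_a)
  if (L == 0L) stop("codon alignment has zero columns", call. = FALSE)
  sites_a <- ng86_sites(alignment$codons_a)
  sites_b <- ng86_sites(alignment$codons_b)
  N <- (sites_a[["N"]] + sites_b[["N"]]) / 2
  S <- (sites_a[["S"]] + sites_b[["S"]]) / 2
  d <- ng86_differences(alignment)
  pN <- d[["Nd"]] / N
  pS <- d[["Sd"]] / S
  Ka <- jukes_cantor(pN)
  Ks <- jukes_cantor(pS)
  saturated <- is.na(Ka) || is.na(Ks)
  omega <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  tibble::tibble(
    n_codons = L, N = N, S = S, Nd = d[["Nd"]], Sd = d[["Sd"]],
    pN = pN, pS = pS, Ka = Ka, Ks = Ks, omega = omega,
    saturated = saturated, regime = classify_selection(omega)
  )
}

jukes_cantor <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Classify the selection regime from omega
#'
#' omega < 0.5 is strong purifying selection, 0.5 <= omega < 1 relaxed
#' purifying, omega = 1 (tolerance 1e-9) neutral, omega > 1 positive;
#' undefined omega gives "undefined".
#'
#' @param omega Numeric vector of Ka/Ks ratios (NA allowed), or a
#'   [compute_kaks()] result row.
#' @return Character vector of regimes.
#' @export
classify_selection <- function(omega) {
  if (is.data.frame(omega)) omega <- omega$omega
  dplyr::case_when(
    is.na(omega) ~ "undefined",
    abs(omega - 1) <= 1e-9 ~ "neutral",
    omega > 1 ~ "positive",
    omega >= 0.5 ~ "relaxed_purifying",
    TRUE ~ "strong_purifying"
  )
}

#' Ka/Ks table for a set of gene pairs
#'
#' Runs the protein-guided codon alignment and NG86 estimator over each pair,
#' mirroring a per-pair Ka/Ks results table.
#'
#' @param pairs Data frame with columns `gene_a`, `gene_b`.
#' @param catalog A gene catalog (see [build_ancestral_genome()]) or any data
#'   frame with `gene_id` and `cds` columns covering all genes in `pairs`.
#' @return `pairs` with the [compute_kaks()] columns appended.
#' @export
kaks_table <- function(pairs, catalog) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(pairs)))
  cds <- stats::setNames(catalog$cds, catalog$gene_id)
  missing <- setdiff(unique(c(pairs$gene_a, pairs$gene_b)), names(cds))
  if (length(missing)) {
    stop("genes absent from catalog: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  res <- purrr::map2(pairs$gene_a, pairs$gene_b, function(a, b) {
    compute_kaks(cds[[a]], cds_b = cds[[b]])
  })
  dplyr::bind_cols(
    tibble::as_tibble(pairs[c("gene_a", "gene_b")]),
    dplyr::bind_rows(res)
  )
}
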