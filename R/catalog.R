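# Gene catalogs: the tabular container used throughout the package.
# A catalog is a tibble with one row per gene locus, ordered by chromosome
# and start coordinate:
#   species, gene_id, chrom, locus (index within chromosome), start, end,
#   strand, exon_count, is_family, cds, protein

CATALOG_COLS <- c("species", "gene_id", "chrom", "locus", "start", "end",
                  "strand", "exon_count", "is_family", "cds", "protein")

#' Validate and normalize a gene catalog
#'
#' Checks column presence, unique gene ids, positive 1-based coordinates,
#' and non-overlapping ordered gene spans within each chromosome, then
#' re-derives the per-chromosome locus index.
#'
#' @param catalog A data frame with the catalog columns.
#' @return The catalog as a tibble, ordered by (chrom, start).
#' @export
as_gene_catalog <- function(catalog) {
  missing <- setdiff(setdiff(CATALOG_COLS, "locus"), names(catalog))
  if (length(missing)) {
    stop("catalog lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  catalog <- tibble::as_tibble(catalog)
  if (anyDuplicated(catalog$gene_id)) {
    stop("duplicate gene ids in catalog", call. = FALSE)
  }
  if (any(catalog$start < 1) || any(catalog$end < catalog$start)) {
    stop("catalog has invalid coordinates (need 1 <= start <= end)",
         call. = FALSE)
  }
  catalog <- dplyr::arrange(catalog, .data$chrom, .data$start)
  overlaps <- catalog |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(
      bad = any(dplyr::lead(.data$start) <= .data$end, na.rm = TRUE),
      .groups = "drop"
    )
  if (any(overlaps$bad)) {
    stop("overlapping gene spans on chromosome(s): ",
         paste(overlaps$chrom[overlaps$bad], collapse = ", "), call. = FALSE)
  }
  catalog |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(locus = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(CATALOG_COLS))
}

catalog_gene <- function(catalog, gene_id) {
  row <- catalog[catalog$gene_id == gene_id, ]
  if (nrow(row) == 0L) stop("unknown gene id: ", gene_id, call. = FALSE)
  row
}

#' Write a catalog as FASTA + GFF3 + truth table
#'
#' Writes `<prefix>.cds.fasta`, `<prefix>.protein.fasta`,
#' `<prefix>.gff3` (gene, mRNA and exon/CDS features, 1-based inclusive)
#' and, when `truth` is supplied, `<prefix>.truth.tsv`. The export
#' round-trips: [import_catalog()] on the prefix reproduces the catalog.
#'
#' @param catalog A gene catalog.
#' @param out_prefix Path prefix for the output files.
#' @param truth Optional truth-record tibble (see [apply_wgd()]).
#' @return Invisibly, the paths written.
#' @export
export_catalog <- function(catalog, out_prefix, truth = NULL) {
  catalog <- as_gene_catalog(catalog)
  dir <- dirname(out_prefix)
  if (!dir.exists(dir)) stop("output directory does not exist: ", dir, call. = FALSE)
  paths <- c(
    cds = paste0(out_prefix, ".cds.fasta"),
    protein = paste0(out_prefix, ".protein.fasta"),
    gff3 = paste0(out_prefix, ".gff3")
  )
  cds <- Biostrings::DNAStringSet(stats::setNames(catalog$cds, catalog$gene_id))
  Biostrings::writeXStringSet(cds, paths[["cds"]])
  prot <- Biostrings::AAStringSet(stats::setNames(catalog$protein, catalog$gene_id))
  Biostrings::writeXStringSet(prot, paths[["protein"]])
  rtracklayer::export(catalog_to_granges(catalog), paths[["gff3"]], format = "gff3")
  if (!is.null(truth)) {
    paths <- c(paths, truth = paste0(out_prefix, ".truth.tsv"))
    readr::write_tsv(truth, paths[["truth"]])
  }
  invisible(paths)
}

catalog_to_granges <- function(catalog) {
  feats <- purrr::pmap(catalog, function(species, gene_id, chrom, locus, start,
                                         end, strand, exon_count, is_family,
                                         cds, protein) {
    ex <- exon_layout(start, nchar(cds), exon_count)
    sizes <- ex$end - ex$start + 1L
    phase <- c(0L, cumsum(sizes)[-exon_count]) %% 3L
    phase <- (3L - phase) %% 3L
    tibble::tibble(
      chrom = chrom,
      start = c(start, start, ex$start, ex$start),
      end = c(end, end, ex$end, ex$end),
      strand = strand,
      phase = c(NA, NA, rep(NA, exon_count), phase),
      type = c("gene", "mRNA", rep("exon", exon_count), rep("CDS", exon_count)),
      ID = c(gene_id, paste0(gene_id, ".mRNA"), rep(NA_character_, 2L * exon_count)),
      Parent = c(NA_character_, gene_id, rep(paste0(gene_id, ".mRNA"), 2L * exon_count)),
      species = c(species, rep(NA_character_, 1L + 2L * exon_count)),
      family = c(as.character(as.integer(is_family)),
                 rep(NA_character_, 1L + 2L * exon_count))
    )
  })
  feats <- dplyr::bind_rows(feats)
  GenomicRanges::GRanges(
    seqnames = feats$chrom,
    ranges = IRanges::IRanges(feats$start, feats$end),
    strand = feats$strand,
    type = feats$type, phase = feats$phase,
    ID = feats$ID, Parent = feats$Parent,
    species = feats$species, family = feats$family
  )
}

# Split a CDS of cds_bp over exon_count exons with fixed-size introns between
# them; returns exon start/end vectors. The gene span is
# cds_bp + (exon_count - 1) * intron_bp.
exon_layout <- function(gene_start, cds_bp, exon_count, intron_bp = 100L) {
  base <- cds_bp %/% exon_count
  sizes <- rep(base, exon_count)
  extra <- cds_bp - base * exon_count
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  starts <- gene_start + cumsum(c(0L, sizes[-exon_count] + intron_bp))
  list(start = starts, end = starts + sizes - 1L)
}

gene_span_bp <- function(cds_bp, exon_count, intron_bp = 100L) {
  cds_bp + (exon_count - 1L) * intron_bp
}

#' Re-import a catalog written by [export_catalog()]
#'
#' @param out_prefix The prefix passed to [export_catalog()].
#' @return A gene catalog tibble.
#' @export
import_catalog <- function(out_prefix) {
  gff <- rtracklayer::import(paste0(out_prefix, ".gff3"))
  cds <- Biostrings::readDNAStringSet(paste0(out_prefix, ".cds.fasta"))
  prot <- Biostrings::readAAStringSet(paste0(out_prefix, ".protein.fasta"))
  md <- S4Vectors::mcols(gff)
  genes <- which(md$type == "gene")
  exon_parent <- unlist(md$Parent[md$type == "exon"])
  exon_counts <- table(sub("\\.mRNA$", "", exon_parent))
  ids <- md$ID[genes]
  tibble::tibble(
    species = md$species[genes],
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gff)[genes]),
    locus = NA_integer_,
    start = GenomicRanges::start(gff)[genes],
    end = GenomicRanges::end(gff)[genes],
    strand = as.character(GenomicRanges::strand(gff)[genes]),
    exon_count = as.integer(exon_counts[ids]),
    is_family = md$family[genes] == "1",
    cds = unname(as.character(cds[ids])),
    protein = unname(as.character(prot[ids]))
  ) |>
    as_gene_catalog()
}
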