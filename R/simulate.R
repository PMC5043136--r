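# Synthetic-genome simulator: multi-chromosome gene catalogs with a focal
# gene family among background genes, plus planted whole-genome, tandem and
# speciation events at controlled synonymous divergence (Ks) and omega.
# Every event is logged in a truth table so downstream callers can be scored
# against ground truth.

#' Simulation configuration
#'
#' @param n_chromosomes,genes_per_chromosome,family_founder_count Counts
#'   (all >= 1).
#' @param gene_length_codons Length-2 sampling range for gene length in
#'   codons including the stop codon; the minimum must be >= 110 so every
#'   CDS exceeds 300 bp and is callable by the paralog rule.
#' @param family_gene_length_codons Optional separate length range for the
#'   family founder genes (real gene families are often much longer than the
#'   background average; e.g. lipoxygenase ORFs run ~2.4-2.8 kb). Defaults
#'   to `gene_length_codons`.
#' @param intergenic_gap_bp Length-2 sampling range for the gap between
#'   consecutive gene spans.
#' @param exon_count_range Length-2 sampling range for exons per gene.
#' @param species Species tag used as the gene-id prefix.
#' @param random_strand Draw each gene's strand at random instead of the
#'   all-plus default (the calling rules are strand-agnostic).
#' @param seed Integer seed; fully determines the genome.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 3, genes_per_chromosome = 50,
                       family_founder_count = 2,
                       gene_length_codons = c(120, 200),
                       family_gene_length_codons = NULL,
                       intergenic_gap_bp = c(2000, 8000),
                       exon_count_range = c(5, 11),
                       species = "anc", random_strand = FALSE, seed = 1) {
  if (is.null(family_gene_length_codons)) {
    family_gene_length_codons <- gene_length_codons
  }
  stopifnot(
    n_chromosomes >= 1, genes_per_chromosome >= 1, family_founder_count >= 1,
    length(gene_length_codons) == 2, length(intergenic_gap_bp) == 2,
    length(exon_count_range) == 2, length(family_gene_length_codons) == 2,
    gene_length_codons[1] <= gene_length_codons[2],
    family_gene_length_codons[1] <= family_gene_length_codons[2],
    intergenic_gap_bp[1] <= intergenic_gap_bp[2]
  )
  if (gene_length_codons[1] < 110 || family_gene_length_codons[1] < 110) {
    stop("gene_length_codons minimum must be >= 110 (CDS > 300 bp)",
         call. = FALSE)
  }
  if (family_founder_count > n_chromosomes * genes_per_chromosome) {
    stop("family_founder_count exceeds the total number of genes",
         call. = FALSE)
  }
  structure(
    list(n_chromosomes = as.integer(n_chromosomes),
         genes_per_chromosome = as.integer(genes_per_chromosome),
         family_founder_count = as.integer(family_founder_count),
         gene_length_codons = as.integer(gene_length_codons),
         family_gene_length_codons = as.integer(family_gene_length_codons),
         intergenic_gap_bp = as.integer(intergenic_gap_bp),
         exon_count_range = as.integer(exon_count_range),
         species = species, random_strand = isTRUE(random_strand),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# uniform integer draw from [lo, hi]; safe when lo == hi (unlike sample())
sample_range <- function(range) {
  range[1] + sample.int(range[2] - range[1] + 1L, 1L) - 1L
}

random_cds <- function(n_codons) {
  internal <- sample(sense_codons(), n_codons - 2L, replace = TRUE)
  paste(c("ATG", internal, sample(STOP_CODONS, 1L)), collapse = "")
}

#' Generate an ancestral genome
#'
#' Genes are laid out in order on each chromosome with uniform intergenic
#' gaps; every CDS starts with ATG, ends with a stop codon and has no
#' internal stops. `family_founder_count` genes are flagged as members of the
#' focal family, placed on distinct chromosomes where possible.
#'
#' @param config A [sim_config()].
#' @return A gene catalog tibble (see [as_gene_catalog()]).
#' @export
build_ancestral_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n_total <- config$n_chromosomes * config$genes_per_chromosome
    founder_chrom <- rep(seq_len(config$n_chromosomes),
                         length.out = config$family_founder_count)
    founder_idx <- lapply(seq_len(config$n_chromosomes), function(ch) {
      n_here <- sum(founder_chrom == ch)
      if (n_here == 0L) return(integer(0))
      sort(sample(config$genes_per_chromosome, n_here))
    })
    rows <- list()
    for (ch in seq_len(config$n_chromosomes)) {
      pos <- 0L
      for (g in seq_len(config$genes_per_chromosome)) {
        fam <- g %in% founder_idx[[ch]]
        len_range <- if (fam) config$family_gene_length_codons else
          config$gene_length_codons
        n_codons <- sample_range(len_range)
        exon_count <- sample_range(config$exon_count_range)
        cds <- random_cds(n_codons)
        gap <- sample_range(config$intergenic_gap_bp)
        start <- pos + gap
        span <- gene_span_bp(nchar(cds), exon_count)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          species = config$species,
          gene_id = sprintf("%s.c%02dg%03d", config$species, ch, g),
          chrom = sprintf("%s_chr%02d", config$species, ch),
          locus = g,
          start = start, end = start + span - 1L,
          strand = if (config$random_strand) sample(c("+", "-"), 1L) else "+",
          exon_count = exon_count,
          is_family = fam,
          cds = cds, protein = translate_cds(cds)
        )
        pos <- start + span - 1L
      }
    }
    as_gene_catalog(dplyr::bind_rows(rows))
  })
}

#' Evolve one CDS to a target synonymous divergence and omega
#'
#' A codon-substitution process: single-nucleotide changes are proposed at
#' uniform random positions; synonymous proposals are always accepted,
#' nonsynonymous proposals are accepted with probability `target_omega`, and
#' proposals creating a stop codon are rejected. The number of synonymous
#' substitutions to accumulate is drawn as Poisson with mean
#' `target_ks * S`, where S is the NG86 synonymous site count of the input,
#' so the NG86 estimator recovers `target_ks` approximately unbiasedly at
#' low divergence and the realized Ka/Ks ratio is `target_omega`.
#'
#' @param cds Valid coding sequence (terminal stop kept fixed).
#' @param target_ks Expected synonymous substitutions per synonymous site
#'   (>= 0).
#' @param target_omega Nonsynonymous/synonymous rate ratio (>= 0).
#' @param seed Integer seed.
#' @return The mutated coding sequence (same length, no stops introduced).
#' @export
evolve_cds_pair <- function(cds, target_ks, target_omega, seed) {
  stopifnot(target_ks >= 0, target_omega >= 0)
  codons <- codon_split(cds)
  stop_tail <- character(0)
  if (length(codons) && codons[length(codons)] %in% STOP_CODONS) {
    stop_tail <- codons[length(codons)]
    codons <- codons[-length(codons)]
  }
  if (!all(codons %in% sense_codons())) {
    stop("invalid or internal-stop codon in CDS", call. = FALSE)
  }
  if (target_ks == 0 && target_omega == 0) return(cds)
  gc <- genetic_code()
  L <- length(codons)
  withr::with_seed(seed, {
    S <- sum(ng86_site_table()[codons])
    n_syn <- stats::rpois(1L, target_ks * S)
    if (n_syn == 0L) {
      cds
    } else {
    syn_done <- 0L
    max_prop <- 5000L + 200L * n_syn
    nprop <- 0L
    while (syn_done < n_syn && nprop < max_prop) {
      m <- 512L
      ci <- sample.int(L, m, replace = TRUE)
      pos <- sample.int(3L, m, replace = TRUE)
      alt <- sample.int(3L, m, replace = TRUE)
      u <- stats::runif(m)
      for (j in seq_len(m)) {
        nprop <- nprop + 1L
        old <- codons[ci[j]]
        nt <- substr(old, pos[j], pos[j])
        new_nt <- setdiff(NUCS, nt)[alt[j]]
        new <- old
        substr(new, pos[j], pos[j]) <- new_nt
        if (new %in% STOP_CODONS) next
        if (gc[[new]] == gc[[old]]) {
          codons[ci[j]] <- new
          syn_done <- syn_done + 1L
          if (syn_done >= n_syn) break
        } else if (u[j] <= target_omega) {
          codons[ci[j]] <- new
        }
      }
    }
    if (syn_done < n_syn) {
      stop("substitution process did not converge (target_ks too large?)",
           call. = FALSE)
    }
    paste(c(codons, stop_tail), collapse = "")
    }
  })
}

new_truth <- function(event_kind = character(), parent_gene = character(),
                      child_gene = character(), target_ks = numeric(),
                      target_omega = numeric(), era_label = character()) {
  tibble::tibble(event_kind = event_kind, parent_gene = parent_gene,
                 child_gene = child_gene, target_ks = target_ks,
                 target_omega = target_omega, era_label = era_label)
}

# Derive per-gene integer seeds reproducibly from one seed.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Plant a whole-genome duplication
#'
#' Every chromosome is duplicated as a new chromosome preserving gene order
#' and coordinates; each duplicate gene is independently retained with
#' probability `retention_rate` (otherwise recorded as a loss) and retained
#' duplicates are diverged from their parents via [evolve_cds_pair()] at
#' `target_ks`.
#'
#' @param catalog A gene catalog.
#' @param target_ks,target_omega Divergence targets for retained duplicates.
#' @param retention_rate Per-duplicate retention probability in \[0, 1\].
#' @param era_label Label stored in the truth records (e.g. `"gamma"`,
#'   `"recent"`); also used to suffix duplicate gene ids and chromosomes.
#' @param seed Integer seed.
#' @return List with elements `catalog` (the expanded catalog) and `truth`
#'   (one `wgd` record per retained duplicate, one `loss` record per deleted
#'   one).
#' @export
apply_wgd <- function(catalog, target_ks, retention_rate, era_label, seed,
                      target_omega = 0.2) {
  stopifnot(retention_rate >= 0, retention_rate <= 1)
  catalog <- as_gene_catalog(catalog)
  n <- nrow(catalog)
  seeds <- derive_seeds(seed, n + 1L)
  retained <- withr::with_seed(seeds[n + 1L],
                               stats::runif(n) < retention_rate)
  dup <- catalog
  dup$chrom <- paste0(catalog$chrom, "_", era_label)
  dup$gene_id <- paste0(catalog$gene_id, "-", era_label)
  truth <- new_truth(
    event_kind = ifelse(retained, "wgd", "loss"),
    parent_gene = catalog$gene_id,
    child_gene = ifelse(retained, dup$gene_id, ""),
    target_ks = ifelse(retained, target_ks, NA_real_),
    target_omega = ifelse(retained, target_omega, NA_real_),
    era_label = era_label
  )
  dup <- dup[retained, ]
  if (nrow(dup)) {
    dup$cds <- purrr::map_chr(which(retained), function(i) {
      evolve_cds_pair(catalog$cds[i], target_ks, target_omega, seeds[i])
    })
    dup$protein <- purrr::map_chr(dup$cds, translate_cds)
  }
  list(catalog = as_gene_catalog(dplyr::bind_rows(catalog, dup)),
       truth = truth)
}

#' Plant a tandem array
#'
#' Inserts `copies` diverged duplicates downstream of `gene_id`. Consecutive
#' array members (the source gene, then each copy) are separated by a
#' nearest-boundary gap of `gap_bp`, with `intervening_loci` background
#' (non-family) genes placed inside each gap. Downstream genes on the
#' chromosome are shifted so spans stay ordered and non-overlapping.
#'
#' @param catalog A gene catalog.
#' @param gene_id Gene to duplicate (must exist).
#' @param copies Number of tandem copies (>= 1).
#' @param gap_bp Nearest-boundary distance between consecutive array members.
#' @param intervening_loci Background genes inserted between consecutive
#'   members.
#' @param target_ks,target_omega Divergence targets for the copies.
#' @param seed Integer seed.
#' @return List with `catalog` and `truth` (kind `tandem`).
#' @export
apply_tandem_array <- function(catalog, gene_id, copies, gap_bp = 12000,
                               intervening_loci = 0, target_ks = 0.05,
                               seed = 1, target_omega = 0.2) {
  stopifnot(copies >= 1, gap_bp >= 1, intervening_loci >= 0)
  catalog <- as_gene_catalog(catalog)
  src <- catalog_gene(catalog, gene_id)
  seeds <- derive_seeds(seed, copies + 1L)
  bg_codons <- 110L
  bg_exons <- 5L
  bg_span <- gene_span_bp(3L * bg_codons, bg_exons)
  if (intervening_loci > 0) {
    need <- intervening_loci * (bg_span + 2L)
    if (need >= gap_bp) {
      stop("gap_bp too small to host ", intervening_loci,
           " intervening loci (need > ", need, " bp)", call. = FALSE)
    }
  }
  inserted <- list()
  prev_end <- src$end
  bg_counter <- 0L
  withr::with_seed(seeds[copies + 1L], {
    for (i in seq_len(copies)) {
      if (intervening_loci > 0) {
        slot <- gap_bp %/% (intervening_loci + 1L)
        for (k in seq_len(intervening_loci)) {
          bg_counter <- bg_counter + 1L
          bstart <- prev_end + (k - 1L) * slot +
            max(1L, (slot - bg_span) %/% 2L)
          bcds <- random_cds(bg_codons)
          inserted[[length(inserted) + 1L]] <- tibble::tibble(
            species = src$species,
            gene_id = paste0(gene_id, "-bg", bg_counter),
            chrom = src$chrom, locus = NA_integer_,
            start = bstart, end = bstart + bg_span - 1L, strand = "+",
            exon_count = bg_exons, is_family = FALSE,
            cds = bcds, protein = translate_cds(bcds)
          )
        }
      }
      cstart <- prev_end + gap_bp
      span <- src$end - src$start + 1L
      ccds <- evolve_cds_pair(src$cds, target_ks, target_omega, seeds[i])
      inserted[[length(inserted) + 1L]] <- tibble::tibble(
        species = src$species,
        gene_id = paste0(gene_id, "-t", i),
        chrom = src$chrom, locus = NA_integer_,
        start = cstart, end = cstart + span - 1L, strand = src$strand,
        exon_count = src$exon_count, is_family = src$is_family,
        cds = ccds, protein = translate_cds(ccds)
      )
      prev_end <- cstart + span - 1L
    }
  })
  inserted <- dplyr::bind_rows(inserted)
  shift <- max(inserted$end) - src$end + 2L
  downstream <- catalog$chrom == src$chrom & catalog$start > src$end
  catalog$start[downstream] <- catalog$start[downstream] + shift
  catalog$end[downstream] <- catalog$end[downstream] + shift
  truth <- new_truth(
    event_kind = "tandem",
    parent_gene = gene_id,
    child_gene = paste0(gene_id, "-t", seq_len(copies)),
    target_ks = target_ks, target_omega = target_omega,
    era_label = "tandem"
  )
  list(catalog = as_gene_catalog(dplyr::bind_rows(catalog, inserted)),
       truth = truth)
}

#' Delete genes from a catalog
#'
#' Models gene loss directly on the current catalog — including ancestral
#' (pre-duplication) loci, for simulating ancient loss events. Coordinates
#' of the remaining genes are untouched (a lost locus leaves a gap).
#'
#' @param catalog A gene catalog.
#' @param gene_ids Genes to delete; or use `rate` to sample them.
#' @param rate Per-gene deletion probability (used when `gene_ids` is NULL).
#' @param seed Integer seed (only used with `rate`).
#' @return List with `catalog` and `truth` (records of kind `loss`).
#' @export
apply_gene_loss <- function(catalog, gene_ids = NULL, rate = NULL,
                            seed = 1) {
  catalog <- as_gene_catalog(catalog)
  if (is.null(gene_ids)) {
    stopifnot(!is.null(rate), rate >= 0, rate <= 1)
    drop <- withr::with_seed(seed, stats::runif(nrow(catalog)) < rate)
    gene_ids <- catalog$gene_id[drop]
  } else {
    missing <- setdiff(gene_ids, catalog$gene_id)
    if (length(missing)) {
      stop("unknown gene id(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  truth <- new_truth(
    event_kind = rep("loss", length(gene_ids)),
    parent_gene = gene_ids, child_gene = rep("", length(gene_ids)),
    target_ks = rep(NA_real_, length(gene_ids)),
    target_omega = rep(NA_real_, length(gene_ids)),
    era_label = rep("loss", length(gene_ids))
  )
  list(catalog = catalog[!(catalog$gene_id %in% gene_ids), ],
       truth = truth)
}

#' Derive a daughter species from a catalog
#'
#' Returns a copy of the catalog carrying a new species tag (gene ids are
#' re-prefixed, keeping the locus core so the one-to-one ortholog map is the
#' shared core id) with every CDS diverged by `target_ks`.
#'
#' @param catalog A gene catalog.
#' @param species New species tag.
#' @param target_ks,target_omega Divergence applied to every gene.
#' @param seed Integer seed.
#' @return The daughter catalog.
#' @export
apply_speciation <- function(catalog, species, target_ks, seed,
                             target_omega = 0.2) {
  catalog <- as_gene_catalog(catalog)
  n <- nrow(catalog)
  seeds <- derive_seeds(seed, n)
  out <- catalog
  core <- sub("^[^.]*\\.", "", catalog$gene_id)
  out$gene_id <- paste0(species, ".", core)
  out$species <- species
  out$chrom <- sub(paste0("^", catalog$species[1]), species, catalog$chrom)
  out$cds <- purrr::map_chr(seq_len(n), function(i) {
    evolve_cds_pair(catalog$cds[i], target_ks, target_omega, seeds[i])
  })
  out$protein <- purrr::map_chr(out$cds, translate_cds)
  as_gene_catalog(out)
}

#' Gene-id core shared by orthologs in simulated clades
#'
#' @param gene_id Character vector of simulator gene ids.
#' @return The id with its species prefix removed.
#' @export
gene_core <- function(gene_id) sub("^[^.]*\\.", "", gene_id)
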