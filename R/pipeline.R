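# End-to-end orchestration: simulate a clade with planted events, run
# homology -> Ka/Ks -> synteny -> dating -> retention -> phylogeny, and
# format the result tables.

#' Simulate a four-species clade with planted duplication events
#'
#' The flagship study design: an ancestral genome carrying the focal family,
#' a shared ancient whole-genome event (triplication-era analogue) at high
#' Ks, speciation into four lineages, one recent whole-genome duplication in
#' the second lineage, and one tandem array in the third. All events are
#' logged with their target Ks so detection and dating can be scored
#' against truth.
#'
#' @param seed Integer seed; fully determines the clade.
#' @param species Four species tags.
#' @param n_chromosomes,genes_per_chromosome,family_founder_count,gene_length_codons,family_gene_length_codons
#'   Passed to [sim_config()].
#' @param gamma_ks,gamma_retention Shared ancient event parameters.
#' @param speciation_ks Per-lineage divergence at the radiation.
#' @param recent_ks,recent_retention Recent WGD (second species).
#' @param tandem_gap_bp Tandem array gap (third species).
#' @return A `duphist_sim` list: `catalogs` (named list), `catalog`
#'   (combined tibble), `truth`, `era` ([era_config()]), `species`.
#' @export
simulate_rosid_clade <- function(seed = 1,
                                 species = c("ath", "ptr", "vvi", "cpa"),
                                 n_chromosomes = 2, genes_per_chromosome = 20,
                                 family_founder_count = 2,
                                 gene_length_codons = c(110, 150),
                                 family_gene_length_codons = c(780, 880),
                                 gamma_ks = 1.5, gamma_retention = 0.8,
                                 speciation_ks = 0.05,
                                 recent_ks = 0.3, recent_retention = 0.8,
                                 tandem_gap_bp = 12000) {
  stopifnot(length(species) == 4)
  s <- derive_seeds(seed, 8L)
  cfg <- sim_config(n_chromosomes = n_chromosomes,
                    genes_per_chromosome = genes_per_chromosome,
                    family_founder_count = family_founder_count,
                    gene_length_codons = gene_length_codons,
                    family_gene_length_codons = family_gene_length_codons,
                    species = "anc", seed = s[1])
  anc <- build_ancestral_genome(cfg)
  gamma <- apply_wgd(anc, target_ks = gamma_ks,
                     retention_rate = gamma_retention,
                     era_label = "gamma", seed = s[2])
  catalogs <- lapply(seq_len(4), function(i) {
    apply_speciation(gamma$catalog, species[i], target_ks = speciation_ks,
                     seed = s[2 + i])
  })
  names(catalogs) <- species
  truth <- list(dplyr::mutate(gamma$truth, scope = "ancestral"))
  recent <- apply_wgd(catalogs[[2]], target_ks = recent_ks,
                      retention_rate = recent_retention,
                      era_label = "recent", seed = s[7])
  catalogs[[2]] <- recent$catalog
  truth[[2]] <- dplyr::mutate(recent$truth, scope = species[2])
  fam3 <- catalogs[[3]]$gene_id[catalogs[[3]]$is_family][1]
  tnd <- apply_tandem_array(catalogs[[3]], fam3, copies = 1,
                            gap_bp = tandem_gap_bp, intervening_loci = 0,
                            target_ks = 0.05, seed = s[8])
  catalogs[[3]] <- tnd$catalog
  truth[[3]] <- dplyr::mutate(tnd$truth, scope = species[3])
  era <- era_config(
    species = c(species, species[2]),
    era = c(rep("gamma", 4), "recent"),
    ref_ks = c(rep(gamma_ks, 4), recent_ks),
    ks_lo = c(rep(1.0, 4), 0.02),
    ks_hi = c(rep(2.4, 4), 0.7),
    multiplier = c(rep(1, 4), 2)
  )
  structure(
    list(catalogs = catalogs,
         catalog = dplyr::bind_rows(catalogs),
         truth = dplyr::bind_rows(truth),
         era = era, species = species,
         ancestor = anc),
    class = "duphist_sim"
  )
}

#' Planted segmental (WGD) family pairs of a simulated clade
#'
#' Translates the truth records into the per-species gene pairs a synteny
#' caller should recover: for the shared ancient event, each retained
#' family duplicate yields one pair per descendant species; for a
#' species-specific event, pairs are local to that species.
#'
#' @param sim A `duphist_sim`.
#' @return Tibble: `species`, `gene_a`, `gene_b`, `era`, `target_ks`.
#' @export
planted_family_pairs <- function(sim) {
  fam_anc <- sim$ancestor$gene_id[sim$ancestor$is_family]
  rows <- list()
  anc_events <- sim$truth[sim$truth$scope == "ancestral" &
                            sim$truth$event_kind == "wgd" &
                            sim$truth$parent_gene %in% fam_anc, ]
  for (sp in sim$species) {
    ids <- sim$catalogs[[sp]]$gene_id
    for (i in seq_len(nrow(anc_events))) {
      a <- paste0(sp, ".", gene_core(anc_events$parent_gene[i]))
      b <- paste0(sp, ".", gene_core(anc_events$child_gene[i]))
      if (a %in% ids && b %in% ids) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          species = sp, gene_a = min(a, b), gene_b = max(a, b),
          era = anc_events$era_label[i],
          target_ks = anc_events$target_ks[i]
        )
      }
    }
  }
  fam_by_sp <- stats::setNames(
    lapply(sim$catalogs, function(x) x$gene_id[x$is_family]), sim$species)
  local <- sim$truth[sim$truth$scope != "ancestral" &
                       sim$truth$event_kind == "wgd", ]
  local <- local[local$parent_gene %in% unlist(fam_by_sp), ]
  if (nrow(local)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      species = local$scope,
      gene_a = pmin(local$parent_gene, local$child_gene),
      gene_b = pmax(local$parent_gene, local$child_gene),
      era = local$era_label, target_ks = local$target_ks
    )
  }
  dplyr::bind_rows(rows)
}

#' Score planted-event recovery of a simulated clade
#'
#' Runs within-species block detection, tandem classification and block
#' dating on every species of a simulated clade and scores the result
#' against the planted truth: the fraction of planted segmental (WGD)
#' family pairs recovered as blocks, the fraction of planted tandem pairs
#' classified tandem (and not segmental-only), and the era-assignment
#' accuracy over recovered planted blocks.
#'
#' @param sim A `duphist_sim` from [simulate_rosid_clade()].
#' @param k Flanking window half-width.
#' @param min_flank_matches Block emission threshold.
#' @return One-row tibble: `n_planted_segmental`, `n_recovered`,
#'   `segmental_recall`, `n_planted_tandem`, `tandem_accuracy`,
#'   `n_era_assigned`, `era_accuracy`.
#' @export
evaluate_planted_recovery <- function(sim, k = 6, min_flank_matches = 3) {
  stopifnot(inherits(sim, "duphist_sim"))
  planted <- planted_family_pairs(sim)
  blocks <- list(); tandem <- list()
  for (sp in sim$species) {
    cat_sp <- sim$catalogs[[sp]]
    fs <- find_synteny_blocks(cat_sp, k = k,
                              min_flank_matches = min_flank_matches)
    blocks[[sp]] <- date_blocks(fs$blocks, cat_sp, sim$era)
    tandem[[sp]] <- tandem_clusters(cat_sp)$pairs
  }
  blocks <- dplyr::bind_rows(blocks)
  tandem <- dplyr::bind_rows(tandem)
  bkey <- if (nrow(blocks)) {
    paste(pmin(blocks$anchor_a, blocks$anchor_b),
          pmax(blocks$anchor_a, blocks$anchor_b))
  } else character(0)
  tkey <- if (nrow(tandem)) paste(tandem$gene_a, tandem$gene_b) else character(0)
  pkey <- paste(planted$gene_a, planted$gene_b)
  recovered <- pkey %in% bkey
  # era accuracy over recovered planted blocks
  era_of_block <- stats::setNames(blocks$era, bkey)
  era_ok <- planted$era[recovered] == era_of_block[pkey[recovered]]
  # planted tandem pairs: classified tandem (precedence over segmental)
  truth_tandem <- sim$truth[sim$truth$event_kind == "tandem", ]
  tandem_planted_key <- paste(
    pmin(truth_tandem$parent_gene, truth_tandem$child_gene),
    pmax(truth_tandem$parent_gene, truth_tandem$child_gene)
  )
  tibble::tibble(
    n_planted_segmental = nrow(planted),
    n_recovered = sum(recovered),
    segmental_recall = mean(recovered),
    n_planted_tandem = length(tandem_planted_key),
    tandem_accuracy = mean(tandem_planted_key %in% tkey),
    n_era_assigned = sum(recovered),
    era_accuracy = if (any(recovered)) mean(era_ok) else NA_real_
  )
}

validate_thresholds <- function(min_identity, min_aligned_length, k,
                                min_flank_matches, tandem_kb,
                                tandem_max_loci) {
  if (!(min_identity > 0 && min_identity <= 100)) {
    stop("identity threshold must be in (0, 100]", call. = FALSE)
  }
  stopifnot(min_aligned_length > 0, k >= 1, min_flank_matches >= 1,
            tandem_kb > 0, tandem_max_loci >= 0)
  invisible(TRUE)
}

#' Run the full duplication-history pipeline
#'
#' Per species: family homology search, paralog calling, tandem clustering,
#' within-species block detection, Ka/Ks estimation and block dating.
#' Across species: reciprocal-best-hit ortholog calling and cross-species
#' block detection. Finally: ancestral grouping, the retention matrix,
#' multiplicity ratios and an NJ tree of the family proteins.
#'
#' @param catalogs Named list of gene catalogs (one per species) or a
#'   `duphist_sim`.
#' @param era A [era_config()] covering every species (taken from the sim
#'   when a `duphist_sim` is given).
#' @param k Flanking window half-width in genes.
#' @param min_flank_matches Minimum one-to-one flank matches for a block.
#' @param min_identity,min_aligned_length Paralog-calling thresholds.
#' @param tandem_kb,tandem_max_loci Tandem rule parameters (kb, loci).
#' @param benchmark_species Species normalizing the multiplicity ratios;
#'   defaults to the first species whose slot count is 1.
#' @param bootstrap_replicates NJ bootstrap replicates (0 disables).
#' @param seed Seed for the bootstrap.
#' @return A `duphist_run` list of result tibbles.
#' @export
run_pipeline <- function(catalogs, era = NULL, k = 50, min_flank_matches = 3,
                         min_identity = 40, min_aligned_length = 300,
                         tandem_kb = 60, tandem_max_loci = 5,
                         benchmark_species = NULL,
                         bootstrap_replicates = 100, seed = 1) {
  if (inherits(catalogs, "duphist_sim")) {
    if (is.null(era)) era <- catalogs$era
    catalogs <- catalogs$catalogs
  }
  stopifnot(is.list(catalogs), !is.null(names(catalogs)), !is.null(era))
  validate_thresholds(min_identity, min_aligned_length, k, min_flank_matches,
                      tandem_kb, tandem_max_loci)
  species <- names(catalogs)
  era <- era[era$species %in% species, ]
  if (nrow(era) == 0L) stop("era config covers none of the species",
                            call. = FALSE)
  catalogs <- lapply(catalogs, as_gene_catalog)
  combined <- dplyr::bind_rows(catalogs)
  per_species <- lapply(species, function(sp) {
    cat_sp <- catalogs[[sp]]
    cache <- new.env(parent = emptyenv())
    fam <- cat_sp$gene_id[cat_sp$is_family]
    fam_hits <- all_vs_all(cat_sp, genes_a = fam, cache = cache)
    paralogs <- call_paralogs(fam_hits, min_identity = min_identity,
                              min_aligned_length = min_aligned_length)
    fs <- find_synteny_blocks(cat_sp, k = k,
                              min_flank_matches = min_flank_matches,
                              anchor_min_identity = min_identity,
                              anchor_min_len = min_aligned_length,
                              cache = cache)
    tnd <- tandem_clusters(cat_sp, max_gap_bp = tandem_kb * 1000,
                           max_intervening_loci = tandem_max_loci)
    kaks <- if (nrow(paralogs)) kaks_table(paralogs, cat_sp) else NULL
    dated <- date_blocks(fs$blocks, cat_sp, era, kaks_tbl = kaks)
    list(species = sp, paralogs = paralogs, kaks = kaks, blocks = dated,
         tandem = tnd)
  })
  names(per_species) <- species
  cross <- list(); orthologs <- list()
  for (i in seq_along(species)[-length(species)]) {
    for (j in seq((i + 1), length(species))) {
      ca <- catalogs[[i]]; cb <- catalogs[[j]]
      cache <- new.env(parent = emptyenv())
      hits <- all_vs_all(ca, cb, genes_a = ca$gene_id[ca$is_family],
                         genes_b = cb$gene_id[cb$is_family], cache = cache)
      orthologs[[length(orthologs) + 1L]] <-
        call_orthologs(hits, min_aligned_length = min_aligned_length)
      cs <- cross_species_synteny(ca, cb, k = k,
                                  min_flank_matches = min_flank_matches,
                                  anchor_min_identity = min_identity,
                                  anchor_min_len = min_aligned_length,
                                  cache = cache)
      cross[[length(cross) + 1L]] <- cs$blocks
    }
  }
  orthologs <- dplyr::bind_rows(orthologs)
  cross_blocks <- if (length(cross)) dplyr::bind_rows(cross) else empty_blocks()
  within_blocks <- dplyr::bind_rows(lapply(per_species, `[[`, "blocks"))
  # tandem precedence: a pair that satisfies the tandem rule is classified
  # tandem even when it also sits on a block
  tandem_pairs <- dplyr::bind_rows(
    lapply(per_species, function(x) x$tandem$pairs))
  classification <- classify_family_pairs(per_species, tandem_pairs)
  groups <- ancestral_groups(
    dplyr::bind_rows(
      if (nrow(within_blocks)) within_blocks[names(empty_blocks())] else NULL,
      if (nrow(cross_blocks)) cross_blocks[names(empty_blocks())] else NULL
    ),
    combined
  )
  retention <- build_retention_matrix(groups, combined, era)
  if (is.null(benchmark_species)) {
    slots <- species_slots(era)
    benchmark_species <- names(slots)[slots == min(slots)][1]
  }
  fam_counts <- vapply(catalogs, function(x) sum(x$is_family), numeric(1))
  multiplicity <- expected_multiplicity_check(
    retention, era, benchmark_species = benchmark_species,
    family_counts = fam_counts
  )
  fam_prot <- stats::setNames(combined$protein, combined$gene_id)[
    combined$is_family]
  tree <- NULL; subfamily_distance <- NULL
  if (length(fam_prot) >= 3) {
    aligned <- align_proteins(fam_prot)
    tree <- bootstrap_support(aligned, n_replicates = bootstrap_replicates,
                              seed = seed)
    membership <- founder_membership(names(fam_prot))
    d <- protein_distance_matrix(aligned)
    subfamily_distance <- clade_mean_distance(d, membership)
  }
  structure(
    list(species = species, catalogs = catalogs,
         paralogs = dplyr::bind_rows(lapply(per_species, `[[`, "paralogs")),
         orthologs = orthologs,
         kaks = dplyr::bind_rows(lapply(per_species, function(x) x$kaks)),
         blocks_within = within_blocks, blocks_cross = cross_blocks,
         tandem_pairs = tandem_pairs,
         tandem_clusters = dplyr::bind_rows(
           lapply(per_species, function(x) {
             dplyr::mutate(x$tandem$clusters, species = x$species)
           })),
         classification = classification,
         groups = groups, retention = retention,
         multiplicity = multiplicity,
         tree = tree, subfamily_distance = subfamily_distance,
         era = era, benchmark_species = benchmark_species),
    class = "duphist_run"
  )
}

# Founder-lineage membership of simulator family genes: the core id with
# event suffixes stripped (e.g. "sp1.c01g003-gamma" -> "c01g003").
founder_membership <- function(gene_ids) {
  stats::setNames(sub("-.*$", "", gene_core(gene_ids)), gene_ids)
}

classify_family_pairs <- function(per_species, tandem_pairs) {
  rows <- lapply(per_species, function(x) {
    if (nrow(x$blocks) == 0L && nrow(x$paralogs) == 0L) return(NULL)
    seg <- if (nrow(x$blocks)) {
      dplyr::mutate(canonical_pairs(x$blocks$anchor_a, x$blocks$anchor_b),
                    species = x$species, on_block = TRUE)
    } else NULL
    par <- if (nrow(x$paralogs)) {
      dplyr::mutate(x$paralogs[c("gene_a", "gene_b", "species")],
                    on_block = FALSE)
    } else NULL
    dplyr::bind_rows(seg, par) |>
      dplyr::group_by(.data$gene_a, .data$gene_b, .data$species) |>
      dplyr::summarise(on_block = any(.data$on_block), .groups = "drop")
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble::tibble(gene_a = character(), gene_b = character(),
                          species = character(), class = character()))
  }
  tkey <- paste(tandem_pairs$gene_a, tandem_pairs$gene_b)
  out$class <- dplyr::case_when(
    paste(out$gene_a, out$gene_b) %in% tkey ~ "tandem",
    out$on_block ~ "segmental",
    TRUE ~ "unclassified"
  )
  dplyr::select(out, -"on_block") |>
    dplyr::arrange(.data$species, .data$gene_a, .data$gene_b)
}

#' Table-1-style gene inventory
#'
#' Gene id, chromosome, coordinates, protein length and ORF length, where
#' ORF length is 3 x (protein length + 1) bp (coding codons plus the stop).
#'
#' @param catalog A gene catalog or combined catalog.
#' @return Tibble.
#' @export
format_gene_inventory <- function(catalog) {
  catalog <- as_gene_catalog(catalog)
  tibble::tibble(
    species = catalog$species,
    gene = catalog$gene_id,
    chrom = catalog$chrom,
    coordinates = paste0(catalog$start, "-", catalog$end),
    protein_length = nchar(catalog$protein),
    orf_length = 3L * (nchar(catalog$protein) + 1L),
    family_member = catalog$is_family
  )
}

#' Table-2-style dated duplicate pairs
#'
#' Within-species block anchors with their pairwise Ka, Ks and the block
#' median Ks plus assigned era.
#'
#' @param run A `duphist_run`.
#' @return Tibble: species, gene_a, gene_b, Ka, Ks, block_median_ks, era.
#' @export
format_dated_pairs <- function(run) {
  stopifnot(inherits(run, "duphist_run"))
  blocks <- run$blocks_within
  if (nrow(blocks) == 0L) {
    return(tibble::tibble(species = character(), gene_a = character(),
                          gene_b = character(), Ka = numeric(),
                          Ks = numeric(), block_median_ks = numeric(),
                          era = character()))
  }
  anchors <- dplyr::bind_cols(
    canonical_pairs(blocks$anchor_a, blocks$anchor_b),
    blocks[c("species_a", "median_ks", "era")]
  )
  kk <- run$kaks
  if (!is.null(kk) && nrow(kk)) {
    anchors <- dplyr::left_join(anchors, kk[c("gene_a", "gene_b", "Ka", "Ks")],
                                by = c("gene_a", "gene_b"))
  } else {
    anchors$Ka <- NA_real_; anchors$Ks <- NA_real_
  }
  tibble::tibble(
    species = anchors$species_a, gene_a = anchors$gene_a,
    gene_b = anchors$gene_b, Ka = anchors$Ka, Ks = anchors$Ks,
    block_median_ks = anchors$median_ks, era = anchors$era
  )
}

#' Table-3-style synteny-quality matrix
#'
#' Mean cross-species block quality per species pair, laid out as a
#' lower-triangular matrix; pairs without blocks are blank, not zero.
#'
#' @param run A `duphist_run`.
#' @return Tibble with one row per species (except the first) and one
#'   column per species (except the last).
#' @export
format_quality_matrix <- function(run) {
  stopifnot(inherits(run, "duphist_run"))
  species <- run$species
  cb <- run$blocks_cross
  means <- if (nrow(cb)) {
    dplyr::bind_cols(
      tibble::tibble(sp_a = pmin(cb$species_a, cb$species_b),
                     sp_b = pmax(cb$species_a, cb$species_b)),
      quality = cb$quality
    ) |>
      dplyr::group_by(.data$sp_a, .data$sp_b) |>
      dplyr::summarise(quality = mean(.data$quality), .groups = "drop")
  } else {
    tibble::tibble(sp_a = character(), sp_b = character(),
                   quality = numeric())
  }
  rows <- species[-1]
  cols <- species[-length(species)]
  out <- tibble::tibble(species = rows)
  for (cc in cols) {
    out[[cc]] <- unname(vapply(rows, function(rr) {
      if (match(rr, species) <= match(cc, species)) return("")
      m <- means$quality[(means$sp_a == min(rr, cc) &
                            means$sp_b == max(rr, cc))]
      if (length(m) == 0L) "" else sprintf("%.2f%%", m)
    }, character(1)))
  }
  out
}
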