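# Dating syntenic blocks by median Ks against per-species duplication-era
# reference intervals, and assembling the ancestral-locus retention matrix.

#' Duplication-era configuration
#'
#' One row per (species, era): a reference median Ks, the Ks interval
#' assigned to the era, and the copy-number multiplier the event contributes
#' (2 for a whole-genome duplication; 1 for the benchmark event a clade-wide
#' analysis is normalized to). Intervals must not overlap within a species
#' and must contain their reference value.
#'
#' @param species,era Character vectors.
#' @param ref_ks Reference median Ks of the era.
#' @param ks_lo,ks_hi Interval bounds (lo < hi).
#' @param multiplier Copy-number multiplier (>= 1).
#' @return A validated `duphist_era_config` tibble.
#' @export
era_config <- function(species, era, ref_ks, ks_lo, ks_hi, multiplier = 2) {
  cfg <- tibble::tibble(species = species, era = era, ref_ks = ref_ks,
                        ks_lo = ks_lo, ks_hi = ks_hi,
                        multiplier = as.numeric(multiplier))
  stopifnot(all(cfg$ks_lo < cfg$ks_hi),
            all(cfg$ref_ks >= cfg$ks_lo & cfg$ref_ks <= cfg$ks_hi),
            all(cfg$multiplier >= 1))
  overlap <- cfg |>
    dplyr::group_by(.data$species) |>
    dplyr::arrange(.data$ks_lo, .by_group = TRUE) |>
    dplyr::summarise(bad = any(dplyr::lead(.data$ks_lo) < .data$ks_hi,
                               na.rm = TRUE), .groups = "drop")
  if (any(overlap$bad)) {
    stop("overlapping Ks intervals within species: ",
         paste(overlap$species[overlap$bad], collapse = ", "), call. = FALSE)
  }
  class(cfg) <- c("duphist_era_config", class(cfg))
  cfg
}

#' Default era configuration for a rosid-like four-species clade
#'
#' Reference medians follow the literature values for an
#' Arabidopsis/Populus/Vitis/Carica-like clade: a shared ancient
#' triplication (gamma; medians 2.00, 1.54, 1.22, 1.76 respectively), the
#' alpha duplication in the Arabidopsis-like lineage (0.86, with beta merged
#' into the gamma interval as the two are nearly indistinguishable by Ks)
#' and the recent salicoid duplication in the Populus-like lineage (0.27,
#' observed range 0.27-0.5 padded to [0.1, 0.6]). The gamma event is the
#' benchmark (multiplier 1), giving post-gamma slot multiplicities 4:2:1:1.
#'
#' @param species Names of the four lineages, in
#'   Arabidopsis/Populus/Vitis/Carica-like order.
#' @return A `duphist_era_config`.
#' @export
default_rosid_era_config <- function(species = c("ath", "ptr", "vvi", "cpa")) {
  stopifnot(length(species) == 4)
  era_config(
    species = c(species[1], species[1], species[2], species[2],
                species[3], species[4]),
    era = c("alpha", "beta_gamma", "p", "gamma", "gamma", "gamma"),
    ref_ks = c(0.86, 2.00, 0.27, 1.54, 1.22, 1.76),
    ks_lo = c(0.5, 1.3, 0.1, 1.2, 0.8, 0.8),
    ks_hi = c(1.3, 2.6, 0.6, 2.6, 2.2, 2.6),
    multiplier = c(2, 2, 2, 1, 1, 1)
  )
}

#' Per-species duplicate-slot counts implied by an era configuration
#'
#' The product of the era multipliers: the number of copies of one ancestral
#' (benchmark-era) locus expected in each genome.
#'
#' @param config A [era_config()].
#' @return Named numeric vector of slots per species.
#' @export
species_slots <- function(config) {
  out <- config |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(slots = prod(.data$multiplier), .groups = "drop")
  stats::setNames(out$slots, out$species)
}

#' Median Ks of a block
#'
#' The median of the defined Ks values over the anchor pair and flank pairs;
#' saturated (undefined) Ks values are excluded.
#'
#' @param ks Numeric Ks values (NA = saturated/undefined).
#' @return List with `median_ks` (NA if no defined value) and `n_pairs`
#'   contributing.
#' @export
block_median_ks <- function(ks) {
  ks <- ks[!is.na(ks)]
  list(median_ks = if (length(ks)) stats::median(ks) else NA_real_,
       n_pairs = length(ks))
}

#' Assign a duplication era from a block median Ks
#'
#' Pure interval lookup in the era configuration; values outside every
#' interval give "unassigned" (never silently dropped).
#'
#' @param median_ks Numeric vector of block median Ks values.
#' @param species Species tag(s), recycled.
#' @param config A [era_config()].
#' @return Character vector of era labels.
#' @export
assign_event_era <- function(median_ks, species, config) {
  n <- max(length(median_ks), length(species))
  median_ks <- rep_len(median_ks, n)
  species <- rep_len(species, n)
  unknown <- setdiff(unique(species), config$species)
  if (length(unknown)) {
    stop("species absent from era config: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  vapply(seq_len(n), function(i) {
    if (is.na(median_ks[i])) return("unassigned")
    rows <- config[config$species == species[i] &
                     config$ks_lo <= median_ks[i] &
                     median_ks[i] <= config$ks_hi, ]
    if (nrow(rows)) rows$era[1] else "unassigned"
  }, character(1))
}

#' Date syntenic blocks by median Ks
#'
#' For each block, Ks values of the anchor pair and all flank pairs are
#' computed (or looked up in `kaks_tbl`), the median taken over defined
#' values, and an era assigned for within-species blocks via
#' [assign_event_era()]; cross-species blocks keep era NA.
#'
#' @param blocks A blocks tibble from [find_synteny_blocks()].
#' @param catalog Combined catalog with `gene_id`, `cds` (used for pairs not
#'   present in `kaks_tbl`).
#' @param config A [era_config()].
#' @param kaks_tbl Optional precomputed [kaks_table()] rows.
#' @return `blocks` with `median_ks`, `n_ks_pairs`, `era` columns (the
#'   `flank_matches` list-column is retained).
#' @export
date_blocks <- function(blocks, catalog, config, kaks_tbl = NULL) {
  if (nrow(blocks) == 0L) {
    return(dplyr::mutate(blocks, median_ks = numeric(0),
                         n_ks_pairs = integer(0), era = character(0)))
  }
  all_pairs <- purrr::map2(seq_len(nrow(blocks)), blocks$flank_matches,
                           function(i, fm) {
    dplyr::bind_rows(
      canonical_pairs(blocks$anchor_a[i], blocks$anchor_b[i]),
      canonical_pairs(fm$gene_a, fm$gene_b)
    )
  })
  need <- dplyr::distinct(dplyr::bind_rows(all_pairs))
  if (!is.null(kaks_tbl)) {
    have <- canonical_pairs(kaks_tbl$gene_a, kaks_tbl$gene_b)
    have$Ks <- kaks_tbl$Ks
    need <- dplyr::anti_join(need, have, by = c("gene_a", "gene_b"))
  } else {
    have <- tibble::tibble(gene_a = character(), gene_b = character(),
                           Ks = numeric())
  }
  if (nrow(need)) {
    computed <- kaks_table(need, catalog)
    have <- dplyr::bind_rows(have,
                             computed[c("gene_a", "gene_b", "Ks")])
  }
  ks_of <- stats::setNames(have$Ks, paste(have$gene_a, have$gene_b))
  dated <- purrr::map(all_pairs, function(p) {
    block_median_ks(unname(ks_of[paste(p$gene_a, p$gene_b)]))
  })
  blocks$median_ks <- vapply(dated, `[[`, numeric(1), "median_ks")
  blocks$n_ks_pairs <- vapply(dated, `[[`, integer(1), "n_pairs")
  blocks$era <- ifelse(
    blocks$species_a == blocks$species_b,
    assign_event_era(blocks$median_ks, blocks$species_a, config),
    NA_character_
  )
  blocks
}

#' Build the ancestral-locus retention matrix
#'
#' One row per ancestral group; per species, `1 + extra` duplicate slots
#' where the slot count is the product of that species' era multipliers
#' ([species_slots()]). Slots are filled with the group's retained family
#' genes; group members that are not family members are recorded as
#' sub-functionalized ("N" loci); unfilled slots are lost. When a group
#' holds more genes of one species than slots (e.g. tandem expansion), the
#' extra genes share the last slot.
#'
#' @param groups Output of [ancestral_groups()] (with species filled in).
#' @param catalogs Combined catalog (for family flags).
#' @param config A [era_config()] covering every species.
#' @return Long tibble of class `duphist_retention`: `group`, `species`,
#'   `slot`, `status` (retained/subfunctionalized/lost), `genes`.
#' @export
build_retention_matrix <- function(groups, catalogs, config) {
  slots <- species_slots(config)
  fam <- stats::setNames(catalogs$is_family, catalogs$gene_id)
  dup <- groups$gene_id[duplicated(groups$gene_id)]
  if (length(dup)) {
    stop("gene(s) assigned to more than one group: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  cells <- tidyr::expand_grid(
    group = unique(groups$group),
    species = names(slots)
  )
  rows <- purrr::pmap(cells, function(group, species) {
    n_slots <- as.integer(slots[[species]])
    members <- groups$gene_id[groups$group == group &
                                groups$species == species]
    retained <- members[fam[members] %in% TRUE]
    subfun <- setdiff(members, retained)
    entries <- c(
      purrr::map_chr(retained, identity),
      purrr::map_chr(subfun, \(g) paste0("N:", g))
    )
    status <- c(rep("retained", length(retained)),
                rep("subfunctionalized", length(subfun)))
    if (length(entries) > n_slots) {
      # overflow: extras share the last slot
      entries <- c(entries[seq_len(n_slots - 1L)],
                   paste(entries[seq(n_slots, length(entries))],
                         collapse = ","))
      status <- c(status[seq_len(n_slots - 1L)],
                  if (any(status[seq(n_slots, length(status))] == "retained"))
                    "retained" else "subfunctionalized")
    }
    n_fill <- length(entries)
    tibble::tibble(
      group = group, species = species, slot = seq_len(n_slots),
      status = c(status, rep("lost", n_slots - n_fill)),
      genes = c(entries, rep(NA_character_, n_slots - n_fill))
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("duphist_retention", class(out))
  out
}

#' Observed vs expected copy multiplicity per species
#'
#' Reports, per species, the observed retained gene count, the expected
#' count under the era multiplicities (groups x slots), their ratio, and
#' count ratios normalized to a benchmark species.
#'
#' @param matrix A `duphist_retention` from [build_retention_matrix()].
#' @param config The [era_config()] used to build it.
#' @param benchmark_species Species whose count normalizes the ratios.
#' @param family_counts Optional named vector of family sizes to use as the
#'   observed counts instead of the matrix's retained genes (the ratio a
#'   whole-family census reports).
#' @return Tibble: `species`, `observed`, `expected`, `obs_exp_ratio`,
#'   `count_ratio` (observed / observed\[benchmark\]), `expected_ratio`
#'   (slots / slots\[benchmark\]).
#' @export
expected_multiplicity_check <- function(matrix, config, benchmark_species,
                                        family_counts = NULL) {
  slots <- species_slots(config)
  n_groups <- length(unique(matrix$group))
  observed <- if (!is.null(family_counts)) {
    family_counts[names(slots)]
  } else {
    retained <- matrix[matrix$status == "retained", ]
    vapply(names(slots), function(sp) {
      genes <- unlist(strsplit(retained$genes[retained$species == sp], ","))
      length(unique(genes))
    }, numeric(1))
  }
  stopifnot(benchmark_species %in% names(slots))
  obs_bench <- as.numeric(observed[[benchmark_species]])
  slots_bench <- as.numeric(slots[[benchmark_species]])
  obs_num <- as.numeric(observed)
  exp_num <- n_groups * as.numeric(slots)
  tibble::tibble(
    species = names(slots),
    observed = obs_num,
    expected = exp_num,
    obs_exp_ratio = obs_num / exp_num,
    count_ratio = obs_num / obs_bench,
    expected_ratio = as.numeric(slots) / slots_bench
  )
}
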