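# Median-Ks dating, era assignment, retention matrix, multiplicity ratios.

test_that("era configuration validates intervals", {
  expect_error(era_config("sp", c("x", "y"), c(0.3, 0.5), c(0.1, 0.4),
                          c(0.6, 0.9)), "overlap")
  expect_error(era_config("sp", "x", ref_ks = 0.9, ks_lo = 0.1, ks_hi = 0.6))
  cfg <- default_rosid_era_config()
  expect_s3_class(cfg, "duphist_era_config")
  expect_equal(unname(species_slots(cfg)[c("ath", "ptr", "vvi", "cpa")]),
               c(4, 2, 1, 1))
})

test_that("era assignment is an interval lookup with literature anchors", {
  cfg <- default_rosid_era_config()
  expect_equal(assign_event_era(0.41, "ptr", cfg), "p")
  expect_equal(assign_event_era(2.28, "ptr", cfg), "gamma")
  expect_equal(assign_event_era(0.91, "ath", cfg), "alpha")
  expect_equal(assign_event_era(1.22, "vvi", cfg), "gamma")
  expect_equal(assign_event_era(1.76, "cpa", cfg), "gamma")
  # outside every interval: reported unassigned, never dropped
  expect_equal(assign_event_era(0.05, "ath", cfg), "unassigned")
  expect_equal(assign_event_era(NA_real_, "ath", cfg), "unassigned")
  expect_error(assign_event_era(0.5, "zz", cfg), "absent")
  # vectorized + pure: same input, same answer
  expect_equal(assign_event_era(c(0.41, 0.41), "ptr", cfg), c("p", "p"))
})

test_that("block median Ks is the median of defined values", {
  expect_equal(block_median_ks(c(0.2, 0.3, 0.4))$median_ks, 0.3)
  expect_equal(block_median_ks(c(0.2, 0.4))$median_ks, 0.3)
  r <- block_median_ks(c(0.2, NA, 0.4, NA))
  expect_equal(r$median_ks, 0.3)
  expect_equal(r$n_pairs, 2)
  und <- block_median_ks(c(NA_real_, NA_real_))
  expect_true(is.na(und$median_ks))
  expect_equal(und$n_pairs, 0)
  # permutation invariant, bounded by the contributing values
  v <- c(0.9, 0.1, 0.5, 0.3)
  expect_equal(block_median_ks(v)$median_ks,
               block_median_ks(rev(v))$median_ks)
  expect_gte(block_median_ks(v)$median_ks, min(v))
  expect_lte(block_median_ks(v)$median_ks, max(v))
})

test_that("dated simulated WGD blocks recover the planted era", {
  cfg <- sim_config(n_chromosomes = 1, genes_per_chromosome = 12,
                    family_founder_count = 1,
                    gene_length_codons = c(120, 160), seed = 81)
  cat <- build_ancestral_genome(cfg)
  w <- apply_wgd(cat, target_ks = 0.3, retention_rate = 1,
                 era_label = "recent", seed = 5)
  fs <- find_synteny_blocks(w$catalog, k = 8)
  era <- era_config(species = c("anc", "anc"), era = c("recent", "old"),
                    ref_ks = c(0.3, 1.5), ks_lo = c(0.05, 1.0),
                    ks_hi = c(0.7, 2.2), multiplier = c(2, 1))
  dated <- date_blocks(fs$blocks, w$catalog, era)
  fam <- cat$gene_id[cat$is_family]
  planted <- dated[dated$anchor_a %in% fam | dated$anchor_b %in% fam, ]
  expect_gte(nrow(planted), 1)
  expect_true(all(planted$era == "recent"))
  expect_true(all(planted$median_ks > 0.2 & planted$median_ks < 0.4))
  expect_true(all(planted$n_ks_pairs >= 3))
})

test_that("retention matrix fills slots, codes N loci, conserves cells", {
  era <- era_config(species = c("sp1", "sp1", "sp2"),
                    era = c("bench", "wgd1", "bench"),
                    ref_ks = c(1.5, 0.3, 1.5), ks_lo = c(1, 0.1, 1),
                    ks_hi = c(2, 0.7, 2), multiplier = c(1, 2, 1))
  catalogs <- tibble::tibble(
    gene_id = c("sp1.a", "sp1.a2", "sp1.b", "sp2.a", "sp2.x"),
    species = c("sp1", "sp1", "sp1", "sp2", "sp2"),
    is_family = c(TRUE, TRUE, TRUE, TRUE, FALSE)
  )
  groups <- tibble::tibble(
    group = c("A", "A", "A", "A", "B"),
    gene_id = c("sp1.a", "sp1.a2", "sp2.a", "sp2.x", "sp1.b"),
    species = c("sp1", "sp1", "sp2", "sp2", "sp1")
  )
  m <- build_retention_matrix(groups, catalogs, era)
  # sp1 has 2 slots, sp2 has 1; two groups -> 2 * (2 + 1) cells
  expect_equal(nrow(m), 6)
  a_sp1 <- m[m$group == "A" & m$species == "sp1", ]
  expect_equal(sort(a_sp1$genes), c("sp1.a", "sp1.a2"))
  expect_true(all(a_sp1$status == "retained"))
  # non-family collinear locus rendered as subfunctionalized with N code;
  # overflow genes share the single sp2 slot
  a_sp2 <- m[m$group == "A" & m$species == "sp2", ]
  expect_equal(a_sp2$genes, "sp2.a,N:sp2.x")
  b_sp2 <- m[m$group == "B" & m$species == "sp2", ]
  expect_equal(b_sp2$status, "lost")
  expect_equal(sum(m$status %in% c("retained", "subfunctionalized", "lost")),
               nrow(m))
  expect_error(
    build_retention_matrix(
      dplyr::bind_rows(groups, groups[1, ] |> dplyr::mutate(group = "B")),
      catalogs, era),
    "more than one group")
})

test_that("lost-cell fraction tracks the retention rate", {
  # groups built directly from planted truth (no detection noise)
  lost_frac <- vapply(1:20, function(s) {
    cfg <- sim_config(n_chromosomes = 1, genes_per_chromosome = 40,
                      family_founder_count = 40,
                      gene_length_codons = c(110, 112), seed = 900 + s)
    cat <- build_ancestral_genome(cfg)
    w <- apply_wgd(cat, 0.01, 0.5, "wgd1", seed = s)
    truth <- w$truth
    # one group per ancestral gene: the parent, plus its child when kept
    kept <- truth[truth$event_kind == "wgd", ]
    groups <- dplyr::bind_rows(
      tibble::tibble(group = truth$parent_gene,
                     gene_id = truth$parent_gene, species = "anc"),
      tibble::tibble(group = kept$parent_gene,
                     gene_id = kept$child_gene, species = "anc")
    )
    era <- era_config(c("anc", "anc"), c("bench", "wgd1"),
                      ref_ks = c(1.5, 0.01), ks_lo = c(1, 0.001),
                      ks_hi = c(2, 0.7), multiplier = c(1, 2))
    m <- build_retention_matrix(groups, w$catalog, era)
    mean(m$status == "lost")
  }, numeric(1))
  # each group: 2 slots, parent fills one, child kept w.p. 0.5
  expect_lt(abs(mean(lost_frac) - 0.25), 3 * sqrt(0.25 * 0.75 / (40 * 20)))
})

test_that("multiplicity ratios reproduce the census arithmetic", {
  era <- default_rosid_era_config()
  m <- tibble::tibble(group = "A", species = "vvi", slot = 1L,
                      status = "retained", genes = "x")
  class(m) <- c("duphist_retention", class(m))
  counts <- c(ath = 6, ptr = 20, vvi = 13, cpa = 11)
  rep <- expected_multiplicity_check(m, era, benchmark_species = "vvi",
                                     family_counts = counts)
  got <- stats::setNames(round(rep$count_ratio, 2), rep$species)
  expect_equal(got[["ath"]], 0.46)
  expect_equal(got[["ptr"]], 1.54)
  expect_equal(got[["cpa"]], 0.85)
  expect_equal(got[["vvi"]], 1)
  expect_equal(stats::setNames(rep$expected_ratio, rep$species)[
    c("ath", "ptr", "vvi", "cpa")], c(ath = 4, ptr = 2, vvi = 1, cpa = 1))
})

test_that("a lossless duplication gives observed/expected of one", {
  era <- era_config(c("s1", "s1", "s2"), c("bench", "w", "bench"),
                    ref_ks = c(1, 0.2, 1), ks_lo = c(0.8, 0.05, 0.8),
                    ks_hi = c(1.5, 0.6, 1.5), multiplier = c(1, 2, 1))
  groups <- tibble::tibble(
    group = rep(c("A", "B"), each = 3),
    gene_id = c("s1.a", "s1.a-w", "s2.a", "s1.b", "s1.b-w", "s2.b"),
    species = rep(c("s1", "s1", "s2"), 2)
  )
  catalogs <- tibble::tibble(gene_id = groups$gene_id,
                             species = groups$species, is_family = TRUE)
  m <- build_retention_matrix(groups, catalogs, era)
  rep <- expected_multiplicity_check(m, era, benchmark_species = "s2")
  expect_equal(rep$obs_exp_ratio, c(1, 1))
})
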