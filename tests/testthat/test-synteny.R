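# Microsynteny detection, tandem rule, quality, ancestral grouping.

test_that("flanking windows truncate at chromosome ends", {
  cfg <- sim_config(n_chromosomes = 1, genes_per_chromosome = 200,
                    family_founder_count = 1,
                    gene_length_codons = c(110, 112), seed = 3)
  cat <- build_ancestral_genome(cfg)
  first <- cat$gene_id[1]
  w <- flanking_window(cat, first, k = 50)
  expect_length(w$upstream, 0)
  expect_length(w$downstream, 50)
  mid <- cat$gene_id[100]
  w <- flanking_window(cat, mid, k = 50)
  expect_length(w$upstream, 50)
  expect_length(w$downstream, 50)
  w <- flanking_window(cat, cat$gene_id[3], k = 2)
  expect_equal(w$upstream, cat$gene_id[1:2])
  expect_equal(w$downstream, cat$gene_id[4:5])
  expect_error(flanking_window(cat, "missing"), "unknown gene")
})

test_that("synteny quality follows the closed form", {
  expect_equal(synteny_quality(10, 10, 10), 100)
  expect_equal(synteny_quality(5, 10, 12), 100 * 10 / 22, tolerance = 1e-9)
  expect_equal(round(synteny_quality(5, 10, 12), 2), 45.45)
  expect_equal(synteny_quality(7, 7, 7), 100)
})

test_that("tandem rule accepts the printed neighbor-pair geometry", {
  # spans taken from a published family inventory: two family genes
  # 12.3 kb apart on one supercontig with no intervening loci
  cat <- two_gene_catalog(1216903, 1220688, 1233011, 1236967)
  expect_true(tandem_test(cat, "gA", "gB"))
  expect_true(tandem_test(cat, "gB", "gA"))  # symmetric
})

test_that("tandem rule enforces distance and intervening-locus limits", {
  far <- two_gene_catalog(1000, 3000, 64001, 66000)  # 61 kb gap
  expect_false(tandem_test(far, "gA", "gB"))
  at_limit <- two_gene_catalog(1000, 3000, 62999, 65000)  # just under 60 kb
  expect_true(tandem_test(at_limit, "gA", "gB"))
  six <- two_gene_catalog(1000, 3000, 43000, 45000, intervening = 6)
  expect_false(tandem_test(six, "gA", "gB"))
  five <- two_gene_catalog(1000, 3000, 43000, 45000, intervening = 5)
  expect_true(tandem_test(five, "gA", "gB"))
  # family members between the pair do not count toward the limit
  mixed <- two_gene_catalog(1000, 3000, 43000, 45000, intervening = 5,
                            intervening_family = 2)
  expect_true(tandem_test(mixed, "gA", "gB"))
  other_chrom <- two_gene_catalog(1000, 3000, 5000, 7000, chrom_b = "chr2")
  expect_false(tandem_test(other_chrom, "gA", "gB"))
})

test_that("tandem clusters merge transitively into maximal chains", {
  cfg <- sim_config(n_chromosomes = 1, genes_per_chromosome = 6,
                    family_founder_count = 1, seed = 9)
  cat <- build_ancestral_genome(cfg)
  fam <- cat$gene_id[cat$is_family][1]
  arr <- apply_tandem_array(cat, fam, copies = 3, gap_bp = 15000, seed = 2)
  tc <- tandem_clusters(arr$catalog)
  expect_equal(length(unique(tc$clusters$cluster)), 1)
  expect_setequal(tc$clusters$gene_id,
                  c(fam, paste0(fam, "-t", 1:3)))
})

test_that("block emission needs three one-to-one flank matches", {
  # two chromosomes of 8 genes; anchors at position 4; synthetic homology
  mk_chrom <- function(tag) {
    cat <- toy_catalog(8, chrom = paste0("chr", tag), species = "sp",
                       family = 4,
                       ids = sprintf("%s.g%d", tag, 1:8))
    cat
  }
  cat <- dplyr::bind_rows(mk_chrom("L"), mk_chrom("R")) |> as_gene_catalog()
  mk_hits <- function(pairs) {
    tibble::tibble(query = pairs$q, subject = pairs$s, species_q = "sp",
                   species_s = "sp", identity = 80,
                   aligned_length = 400, score = 300, query_coverage = 1)
  }
  three <- mk_hits(data.frame(q = c("L.g1", "L.g2", "L.g6"),
                              s = c("R.g1", "R.g2", "R.g6")))
  b <- detect_block(cat, cat, "L.g4", "R.g4", three, k = 5)
  expect_false(is.null(b))
  expect_equal(b$match_count, 3)
  expect_equal(b$segment_size_a, 8)   # 3 up + 4 down + anchor
  two <- mk_hits(data.frame(q = c("L.g1", "L.g2"), s = c("R.g1", "R.g2")))
  expect_null(detect_block(cat, cat, "L.g4", "R.g4", two, k = 5))
  # one repetitive flank gene cannot satisfy the rule alone
  rep_hits <- mk_hits(data.frame(q = c("L.g1", "L.g1", "L.g1"),
                                 s = c("R.g1", "R.g2", "R.g3")))
  expect_null(detect_block(cat, cat, "L.g4", "R.g4", rep_hits, k = 5))
})

test_that("flank thresholds gate the matching", {
  cat <- dplyr::bind_rows(
    toy_catalog(5, chrom = "chrL", ids = sprintf("L.g%d", 1:5), family = 3),
    toy_catalog(5, chrom = "chrR", ids = sprintf("R.g%d", 1:5), family = 3)
  ) |> as_gene_catalog()
  weak <- tibble::tibble(query = c("L.g1", "L.g2", "L.g4"),
                         subject = c("R.g1", "R.g2", "R.g4"),
                         species_q = "spX", species_s = "spX",
                         identity = c(80, 39, 80),
                         aligned_length = c(400, 400, 150),
                         score = 300, query_coverage = 1)
  # identity 39 <= 40 and length 150 <= 150 both fail the relaxed floor
  expect_null(detect_block(cat, cat, "L.g3", "R.g3", weak, k = 2,
                           min_flank_matches = 2))
})

test_that("a fresh WGD yields blocks at every family pair", {
  cfg <- sim_config(n_chromosomes = 1, genes_per_chromosome = 12,
                    family_founder_count = 2,
                    gene_length_codons = c(120, 160), seed = 71)
  cat <- build_ancestral_genome(cfg)
  w <- apply_wgd(cat, target_ks = 0.1, retention_rate = 1,
                 era_label = "e", seed = 1)
  fs <- find_synteny_blocks(w$catalog, k = 8)
  fam <- cat$gene_id[cat$is_family]
  keys <- paste(fam, paste0(fam, "-e"))
  expect_true(all(keys %in% paste(fs$blocks$anchor_a, fs$blocks$anchor_b)))
  planted <- fs$blocks[paste(fs$blocks$anchor_a, fs$blocks$anchor_b)
                       %in% keys, ]
  # flanks are untouched copies: every window gene matches its duplicate
  expect_equal(planted$match_count, planted$segment_size_a - 1L)
  expect_true(all(planted$quality <= 100))
  expect_true(all(planted$match_count >= 3))
})

test_that("ancestral groups are connected components with stable labels", {
  mk_blocks <- function(edges) {
    tibble::tibble(anchor_a = edges$a, anchor_b = edges$b,
                   species_a = "x", species_b = "y",
                   match_count = 5L, segment_size_a = 10L,
                   segment_size_b = 10L, quality = 50,
                   flank_matches = list(tibble::tibble()))
  }
  # a published six-member cross-species group, as anchor edges
  edges <- data.frame(
    a = c("At3", "At3", "Pt5", "Vv8", "At3"),
    b = c("Pt5", "Pt6", "Vv8", "Cp3", "At6")
  )
  g <- ancestral_groups(mk_blocks(edges))
  expect_equal(unique(g$group), "A")
  expect_setequal(g$gene_id, c("At3", "At6", "Pt5", "Pt6", "Vv8", "Cp3"))
  # two components: larger first, then smallest gene id
  edges2 <- data.frame(a = c("z1", "a1", "a1"), b = c("z2", "a2", "a3"))
  g2 <- ancestral_groups(mk_blocks(edges2))
  expect_equal(g2$group[g2$gene_id == "a1"], "A")
  expect_equal(g2$group[g2$gene_id == "z1"], "B")
  # invariant to block order
  shuffled <- mk_blocks(edges2[c(3, 1, 2), ])
  expect_equal(ancestral_groups(shuffled), g2)
  expect_equal(nrow(ancestral_groups(mk_blocks(edges)[0, ])), 0)
})
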