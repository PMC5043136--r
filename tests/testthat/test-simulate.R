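# Synthetic-genome simulator: determinism, coordinate sanity, planted-event
# bookkeeping, and divergence calibration.

test_that("config validation enforces the invariants", {
  expect_error(sim_config(gene_length_codons = c(100, 200)), ">= 110")
  expect_error(sim_config(n_chromosomes = 1, genes_per_chromosome = 3,
                          family_founder_count = 4), "exceeds")
  expect_s3_class(sim_config(seed = 3), "sim_config")
})

test_that("ancestral genome has the configured shape and valid CDSs", {
  cfg <- sim_config(n_chromosomes = 3, genes_per_chromosome = 200,
                    family_founder_count = 4, seed = 1)
  cat <- build_ancestral_genome(cfg)
  expect_equal(nrow(cat), 600)
  expect_equal(sum(cat$is_family), 4)
  # founders spread over distinct chromosomes where possible
  expect_gte(length(unique(cat$chrom[cat$is_family])), 3)
  # every CDS: ATG start, stop end, clean translation (oracle: Biostrings)
  expect_true(all(substr(cat$cds, 1, 3) == "ATG"))
  last <- substr(cat$cds, nchar(cat$cds) - 2, nchar(cat$cds))
  expect_true(all(last %in% c("TAA", "TAG", "TGA")))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(cat$cds)))
  expect_true(all(substr(aa, 1, nchar(aa) - 1) == cat$protein))
  expect_false(any(grepl("\\*", cat$protein)))
  # coordinates ordered and non-overlapping within chromosomes
  by_chr <- split(cat, cat$chrom)
  for (b in by_chr) {
    expect_true(all(diff(b$start) > 0))
    expect_true(all(b$start[-1] > b$end[-nrow(b)]))
  }
  expect_true(all(cat$start >= 1))
})

test_that("identical config and seed give byte-identical exports", {
  cfg <- sim_config(n_chromosomes = 1, genes_per_chromosome = 10,
                    family_founder_count = 1, seed = 7)
  c1 <- build_ancestral_genome(cfg)
  c2 <- build_ancestral_genome(cfg)
  expect_identical(c1, c2)
  d <- withr::local_tempdir()
  export_catalog(c1, file.path(d, "a"))
  export_catalog(c2, file.path(d, "b"))
  for (ext in c(".cds.fasta", ".protein.fasta", ".gff3")) {
    expect_identical(readLines(file.path(d, paste0("a", ext))),
                     readLines(file.path(d, paste0("b", ext))))
  }
})

test_that("export round-trips through FASTA/GFF3 and counts exons", {
  cfg <- sim_config(n_chromosomes = 2, genes_per_chromosome = 6,
                    family_founder_count = 2, exon_count_range = c(9, 9),
                    seed = 21)
  cat <- build_ancestral_genome(cfg)
  d <- withr::local_tempdir()
  export_catalog(cat, file.path(d, "g"))
  gff <- readLines(file.path(d, "g.gff3"))
  genes <- grep("\tgene\t", gff)
  expect_length(genes, 12)
  first_gene <- cat$gene_id[1]
  exon_lines <- grep(paste0("\texon\t.*Parent=", first_gene, ".mRNA"), gff)
  expect_length(exon_lines, 9)
  back <- import_catalog(file.path(d, "g"))
  expect_equal(as.data.frame(back), as.data.frame(cat))
})

test_that("zero target divergence leaves the sequence untouched", {
  cds <- random_valid_cds(150, seed = 3)
  expect_identical(evolve_cds_pair(cds, 0, 0.2, seed = 1), cds)
})

test_that("evolution preserves length and never creates stops", {
  cds <- random_valid_cds(200, seed = 9)
  for (s in 1:10) {
    mut <- evolve_cds_pair(cds, 0.8, 0.5, seed = s)
    expect_equal(nchar(mut), nchar(cds))
    expect_no_error(translate_cds(mut))
  }
  expect_error(evolve_cds_pair("ATGNNNTAA", 0.1, 0.2, 1), "invalid")
})

test_that("realized synonymous divergence is calibrated to the target", {
  cds <- random_valid_cds(500, seed = 13)
  est <- vapply(1:30, function(s) {
    mut <- evolve_cds_pair(cds, 0.3, 0.2, seed = s)
    compute_kaks(codon_alignment(cds, mut))$Ks
  }, numeric(1))
  # binomial-scale tolerance at n = 30 replicates
  expect_gt(mean(est), 0.25)
  expect_lt(mean(est), 0.35)
})

test_that("neutral evolution gives omega near one", {
  cds <- random_valid_cds(700, seed = 17)
  om <- vapply(1:15, function(s) {
    mut <- evolve_cds_pair(cds, 0.3, 1.0, seed = s)
    compute_kaks(codon_alignment(cds, mut))$omega
  }, numeric(1))
  expect_gt(mean(om), 0.9)
  expect_lt(mean(om), 1.1)
})

test_that("whole-genome duplication respects retention bookkeeping", {
  cfg <- sim_config(n_chromosomes = 2, genes_per_chromosome = 10,
                    family_founder_count = 2, gene_length_codons = c(110, 120),
                    seed = 31)
  cat <- build_ancestral_genome(cfg)
  # retention 1, Ks 0: exact doubling, identical children
  full <- apply_wgd(cat, target_ks = 0, retention_rate = 1,
                    era_label = "e", seed = 1)
  expect_equal(nrow(full$catalog), 2 * nrow(cat))
  kids <- full$catalog[grepl("-e$", full$catalog$gene_id), ]
  expect_identical(kids$cds,
                   cat$cds[match(sub("-e$", "", kids$gene_id), cat$gene_id)])
  expect_true(all(full$truth$event_kind == "wgd"))
  # retention 0: unchanged catalog, all losses
  none <- apply_wgd(cat, target_ks = 0.1, retention_rate = 0,
                    era_label = "e", seed = 2)
  expect_equal(none$catalog, cat)
  expect_true(all(none$truth$event_kind == "loss"))
  expect_true(all(none$truth$child_gene == ""))
  # event conservation: genes out = genes in + retained records
  half <- apply_wgd(cat, target_ks = 0.05, retention_rate = 0.5,
                    era_label = "e", seed = 3)
  expect_equal(nrow(half$catalog),
               nrow(cat) + sum(half$truth$event_kind == "wgd"))
})

test_that("mean retained duplicates follow the binomial expectation", {
  cfg <- sim_config(n_chromosomes = 1, genes_per_chromosome = 200,
                    family_founder_count = 1,
                    gene_length_codons = c(110, 115), seed = 41)
  cat <- build_ancestral_genome(cfg)
  retained <- vapply(1:20, function(s) {
    sum(apply_wgd(cat, 0.02, 0.5, "e", seed = s)$truth$event_kind == "wgd")
  }, numeric(1))
  expect_lt(abs(mean(retained) - 100), 3 * sqrt(200 * 0.25))
})

test_that("tandem arrays land inside the tandem rule geometry", {
  cfg <- sim_config(n_chromosomes = 1, genes_per_chromosome = 10,
                    family_founder_count = 1, seed = 51)
  cat <- build_ancestral_genome(cfg)
  fam <- cat$gene_id[cat$is_family][1]
  near <- apply_tandem_array(cat, fam, copies = 1, gap_bp = 12000,
                             intervening_loci = 0, seed = 1)
  expect_true(tandem_test(near$catalog, fam, paste0(fam, "-t1")))
  far <- apply_tandem_array(cat, fam, copies = 1, gap_bp = 61000,
                            intervening_loci = 0, seed = 1)
  expect_false(tandem_test(far$catalog, fam, paste0(fam, "-t1")))
  trio <- apply_tandem_array(cat, fam, copies = 3, gap_bp = 9000, seed = 2)
  gained <- setdiff(trio$catalog$gene_id, cat$gene_id)
  fam_gained <- trio$catalog[trio$catalog$gene_id %in% gained &
                               trio$catalog$is_family, ]
  expect_equal(nrow(fam_gained), 3)
  expect_equal(unique(fam_gained$chrom), cat$chrom[cat$gene_id == fam])
  expect_error(apply_tandem_array(cat, "nope", 1), "unknown gene")
})

test_that("gene loss can target ancestral loci and logs truth records", {
  cfg <- sim_config(n_chromosomes = 1, genes_per_chromosome = 10,
                    family_founder_count = 1, seed = 55)
  cat <- build_ancestral_genome(cfg)
  byid <- apply_gene_loss(cat, gene_ids = cat$gene_id[2:3])
  expect_equal(nrow(byid$catalog), 8)
  expect_equal(byid$truth$event_kind, rep("loss", 2))
  expect_error(apply_gene_loss(cat, gene_ids = "nope"), "unknown gene")
  byrate <- apply_gene_loss(cat, rate = 0.5, seed = 4)
  expect_equal(nrow(byrate$catalog) + nrow(byrate$truth), 10)
  expect_identical(apply_gene_loss(cat, rate = 0.5, seed = 4)$catalog,
                   byrate$catalog)
})

test_that("random-strand genomes draw both strands", {
  cfg <- sim_config(n_chromosomes = 1, genes_per_chromosome = 40,
                    family_founder_count = 1, random_strand = TRUE,
                    gene_length_codons = c(110, 112), seed = 66)
  cat <- build_ancestral_genome(cfg)
  expect_setequal(unique(cat$strand), c("+", "-"))
})

test_that("speciation preserves the one-to-one ortholog core map", {
  cfg <- sim_config(n_chromosomes = 1, genes_per_chromosome = 8,
                    family_founder_count = 1, seed = 61)
  cat <- build_ancestral_genome(cfg)
  sp <- apply_speciation(cat, "neo", target_ks = 0.2, seed = 5)
  expect_equal(sp$species, rep("neo", 8))
  expect_identical(gene_core(sp$gene_id), gene_core(cat$gene_id))
  expect_false(any(sp$cds == cat$cds))
})
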