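test_that("simulation is byte-identical per seed and validates on re-read", {
  cfg <- simulation_config(n_genes = 8, seed = 123)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_bundle(cfg, dir = d1)
  simulate_bundle(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # every generated file validates against its reader
  genome <- read_fasta(file.path(d1, "genome.fa"))
  catalog <- read_gtf(file.path(d1, "annotation.gtf"))
  expect_gt(nrow(catalog), 0)
  expect_true(all(c("base", "addition") %in%
                    read_tsv(file.path(d1, "catalogs.tsv"))$catalog))
  expect_gt(nrow(read_peptide_evidence(file.path(d1, "evidence.tsv"))), 0)
  expect_gt(nrow(read_deg(file.path(d1, "deg.tsv"))), 0)
  expect_gt(length(read_gene_list(file.path(d1, "curated.tsv"))), 0)
  # the GTF genome pair is translatable
  db <- translate_catalog(genome, catalog)
  expect_gt(nrow(db), 0)
})

test_that("n_genes = 0 gives empty outputs", {
  cfg <- simulation_config(n_genes = 0, seed = 5)
  sim <- simulate_genome_annotation(cfg)
  expect_length(sim$genome, 0L)
  expect_equal(nrow(sim$catalog), 0L)
  cats <- simulate_long_read_catalogs(sim$truth, cfg)
  expect_length(cats$base, 0L)
})

test_that("translate flags exactly the transcripts with engineered stops", {
  cfg <- simulation_config(n_genes = 20, ptc_fraction = 0.3, seed = 202,
                           isoforms_per_gene = c(3L, 4L))
  sim <- simulate_genome_annotation(cfg)
  f <- translation_features(translate_catalog(sim$genome, sim$catalog))
  tt <- sim$truth$transcripts
  m <- merge(f, tt, by = "transcript_id")
  expect_true(all(m$is_coding))
  expect_identical(m$is_ptc.x, m$is_ptc.y)
  expect_identical(m$protein_seq.x, m$protein_seq.y)
  # every engineered-PTC transcript is flagged; some exist at this mix
  expect_gt(sum(tt$ptc_engineered), 0)
  expect_true(all(m[m$ptc_engineered, "is_ptc.x"]))
})

test_that("catalog construction respects overlap and novelty settings", {
  cfg <- simulation_config(n_genes = 10, seed = 7, catalog_overlap = 1,
                           novel_fraction = 0)
  sim <- simulate_genome_annotation(cfg)
  cats <- simulate_long_read_catalogs(sim$truth, cfg)
  expect_identical(cats$base, cats$addition)
  # after translation + merge, no novel entries
  full <- translate_catalog(sim$genome, sim$catalog)
  pick <- function(ids, lbl) {
    sub <- transcript_catalog(
      data.table::as.data.table(sim$catalog)[transcript_id %in% ids],
      lbl)
    remove_redundant(translate_catalog(sim$genome, sub, label = lbl))$db
  }
  base_db <- pick(cats$base, "base")
  add_db <- pick(cats$addition, "addition")
  expect_equal(nrow(novel_entries(add_db, base_db)), 0L)
})

test_that("UTR-only novelties add transcripts but no proteoforms", {
  mix <- c(exon_skip = 0, intron_retention = 0, alt5 = 0, alt3 = 0,
           utr_only = 1)
  cfg <- simulation_config(n_genes = 10, seed = 11, as_event_mix = mix,
                           isoforms_per_gene = c(3L, 3L),
                           catalog_overlap = 1, novel_fraction = 1)
  sim <- simulate_genome_annotation(cfg)
  cats <- simulate_long_read_catalogs(sim$truth, cfg)
  novel_tx <- setdiff(cats$addition, cats$base)
  tt <- sim$truth$transcripts
  # only primaries and utr_only variants exist; novel transcripts ahoy
  if (length(novel_tx)) {
    sub <- function(ids, lbl) remove_redundant(translate_catalog(
      sim$genome,
      transcript_catalog(
        data.table::as.data.table(sim$catalog)[transcript_id %in% ids],
        lbl), label = lbl))$db
    base_db <- sub(cats$base, "base")
    add_db <- sub(cats$addition, "addition")
    expect_equal(nrow(novel_entries(add_db, base_db)), 0L)
  }
  # ground truth agrees: every variant duplicates its primary's protein
  expect_true(all(tt[, uniqueN(protein_seq), by = gene_id]$V1 == 1L))
})

test_that("merged database size matches the truth's unique-sequence count", {
  cfg <- simulation_config(n_genes = 12, seed = 17)
  sim <- simulate_genome_annotation(cfg)
  cats <- simulate_long_read_catalogs(sim$truth, cfg)
  tt <- sim$truth$transcripts
  sub <- function(ids, lbl) remove_redundant(translate_catalog(
    sim$genome,
    transcript_catalog(
      data.table::as.data.table(sim$catalog)[transcript_id %in% ids], lbl),
    label = lbl))$db
  merged <- merge_databases(sub(cats$base, "base"),
                            sub(cats$addition, "addition"))
  union_ids <- union(cats$base, cats$addition)
  expect_equal(nrow(merged),
               length(unique(tt[transcript_id %in% union_ids,
                                protein_seq])))
})

test_that("peptide evidence respects noise and detection settings", {
  cfg <- simulation_config(n_genes = 6, seed = 23, noise_peptides = 5,
                           detect_prob = 1,
                           peptides_per_proteoform = Inf)
  sim <- simulate_genome_annotation(cfg)
  tt <- sim$truth$transcripts
  db <- remove_redundant(protein_db(data.table::data.table(
    accession = tt$transcript_id, gene_id = tt$gene_id,
    protein_seq = tt$protein_seq), "truth"))$db
  ev <- simulate_peptide_evidence(db, cfg)
  expect_equal(sum(ev$peptide_truth$is_noise), 5L)
  idx <- build_peptide_index(db, digest_params())
  r <- identify_proteoforms(ev$evidence, idx, db)
  # exactly the noise peptides fail to match
  expect_setequal(r$unmatched_peptides,
                  ev$peptide_truth[is_noise == TRUE, peptide])
  # noise = 0 -> no unmatched peptides
  cfg0 <- simulation_config(n_genes = 6, seed = 23, noise_peptides = 0,
                            detect_prob = 1,
                            peptides_per_proteoform = Inf)
  ev0 <- simulate_peptide_evidence(db, cfg0)
  r0 <- identify_proteoforms(ev0$evidence, idx, db)
  expect_length(r0$unmatched_peptides, 0L)
})

test_that("DEG simulation matches its recorded truth exactly", {
  cfg <- simulation_config(n_genes = 30, seed = 31,
                           frac_differential = 0.4)
  sim <- simulate_genome_annotation(cfg)
  degsim <- simulate_deg_table(sim$truth, cfg)
  expect_setequal(filter_deg(degsim$deg), degsim$differential)
  # boundary configs
  cfg0 <- simulation_config(n_genes = 10, seed = 3, frac_differential = 0)
  sim0 <- simulate_genome_annotation(cfg0)
  expect_length(filter_deg(simulate_deg_table(sim0$truth, cfg0)$deg), 0L)
  cfg1 <- simulation_config(n_genes = 10, seed = 3, frac_differential = 1)
  expect_setequal(filter_deg(simulate_deg_table(sim0$truth, cfg1)$deg),
                  unique(sim0$truth$transcripts$gene_id))
})

test_that("infeasible configurations are rejected", {
  expect_error(simulation_config(as_event_mix = c(exon_skip = 1)),
               "as_event_mix")
  expect_error(simulation_config(ptc_fraction = 1.5), "\\[0, 1\\]")
  expect_error(simulation_config(isoforms_per_gene = c(3L, 2L)),
               "isoforms_per_gene")
})
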