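one_tx <- function(starts, ends, strand = "+", chrom = "c",
                   tid = "t", gid = "g") {
  transcript_catalog(data.frame(transcript_id = tid, gene_id = gid,
                                chrom = chrom, start = starts, end = ends,
                                strand = strand))
}

test_that("spliced_sequence slices exons and honours strand", {
  g <- c(c = "AAACCCGGGTTT")
  expect_identical(spliced_sequence(g, one_tx(c(0, 6), c(3, 9))), "AAAGGG")
  expect_identical(spliced_sequence(g, one_tx(c(0, 6), c(3, 9), "-")),
                   "CCCTTT")
  expect_identical(spliced_sequence(g, one_tx(0, 12)), g[["c"]])
  expect_error(spliced_sequence(g, one_tx(0, 3, chrom = "zz")),
               "not found")
  expect_error(spliced_sequence(g, one_tx(0, 99)), "out of bounds")
})

test_that("find_orf selects the longest ATG-initiated ORF, ties 5'-most", {
  p1 <- translation_params(min_orf_aa = 1)
  o <- find_orf("ATGAAATGA", p1)
  expect_equal(list(o$protein_seq, o$cds_start, o$cds_end),
               list("MK", 0L, 9L))
  expect_false(find_orf("CCCCCC", p1)$is_coding)
  o2 <- find_orf("ATGAAATAAATGAAAAAATAG", p1)  # 3 aa beats 2 aa
  expect_equal(list(o2$protein_seq, o2$cds_start, o2$cds_end),
               list("MKK", 9L, 21L))
  # tie between two 2-aa ORFs resolves to the 5'-most start
  o3 <- find_orf("ATGAAATGAATGAAATGA", p1)
  expect_equal(o3$cds_start, 0L)
  # run-off ORFs (no in-frame stop) are non-coding
  expect_false(find_orf("ATGAAAAAA", p1)$is_coding)
  # N codons translate to X
  o4 <- find_orf("ATGANATAG", p1)
  expect_equal(o4$protein_seq, "MX")
})

test_that("find_orf agrees with the exhaustive ATG-scan oracle", {
  set.seed(101)
  p <- translation_params(min_orf_aa = 5)
  for (i in 1:60) {
    seq <- random_dna(300)
    got <- find_orf(seq, p)
    exp <- oracle_orf(seq, 5)
    if (is.null(exp)) {
      expect_false(got$is_coding)
    } else {
      expect_equal(got$cds_start, exp$cds_start)
      expect_equal(got$cds_end, exp$cds_end)
      expect_equal(nchar(got$protein_seq), exp$naa)
    }
  }
})

test_that("translation is frame-consistent with the genetic code", {
  set.seed(5)
  for (i in 1:20) {
    seq <- random_dna(600)
    o <- find_orf(seq, translation_params(min_orf_aa = 5))
    if (!o$is_coding) next
    cds <- substr(seq, o$cds_start + 1, o$cds_end)
    aa <- Biostrings::translate(Biostrings::DNAString(cds))
    expect_identical(paste0(o$protein_seq, "*"), as.character(aa))
    expect_equal((o$cds_end - o$cds_start) %% 3, 0)
    expect_equal(o$utr5_len, o$cds_start)
    expect_equal(o$utr3_len, nchar(seq) - o$cds_end)
  }
})

test_that("classify_nmd applies the junction distance and UTR rules", {
  p <- translation_params(min_orf_aa = 1, ptc_junction_nt = 50,
                          long_utr3_nt = 350)
  # single-exon: never PTC
  g <- c(c = paste0("ATGAAATAG", strrep("C", 400)))
  t1 <- one_tx(0, 409)
  o1 <- classify_nmd(t1, find_orf(spliced_sequence(g, t1), p), p)
  expect_false(o1$is_ptc)
  expect_true(o1$is_long_utr3)     # utr3 = 400 > 350
  expect_true(o1$nmd_candidate)

  # two exons: stop ends 60 nt upstream of the junction -> PTC
  # exon1 = ATG AAA TAG + 60 nt, exon2 = 100 nt
  e1 <- paste0("ATGAAATAG", strrep("C", 60))
  g2 <- c(c = paste0(e1, strrep("G", 10), strrep("T", 100)))
  t2 <- one_tx(c(0, 79), c(69, 179))
  o2 <- classify_nmd(t2, find_orf(spliced_sequence(g2, t2), p), p)
  expect_true(o2$is_ptc)

  # stop 10 nt upstream of the junction: below the 50-nt rule
  e1b <- paste0("ATGAAATAG", strrep("C", 10))
  g3 <- c(c = paste0(e1b, strrep("G", 10), strrep("T", 400)))
  t3 <- one_tx(c(0, 29), c(19, 429))
  o3 <- classify_nmd(t3, find_orf(spliced_sequence(g3, t3), p), p)
  expect_false(o3$is_ptc)
  expect_true(o3$is_long_utr3)     # utr3 = 410 > 350
  expect_true(o3$nmd_candidate)

  expect_error(classify_nmd(t1, find_orf("CCC", p), p), "non-coding")
})

test_that("strand symmetry: mirrored gene gives identical proteins", {
  set.seed(21)
  cfg <- simulation_config(n_genes = 6, seed = 77)
  sim <- simulate_genome_annotation(cfg)
  db_fwd <- translate_catalog(sim$genome, sim$catalog)
  # mirror: reverse-complement every chromosome and flip all coordinates
  glen <- nchar(sim$genome)
  mirror <- setNames(as.character(revcomp_vec(sim$genome)), names(sim$genome))
  cc <- data.table::as.data.table(sim$catalog)
  cc[, `:=`(start2 = glen[chrom] - end, end2 = glen[chrom] - start,
            strand = ifelse(strand == "+", "-", "+"))]
  cc[, `:=`(start = start2, end = end2, start2 = NULL, end2 = NULL)]
  db_rev <- translate_catalog(mirror, transcript_catalog(cc))
  expect_identical(db_fwd$protein_seq, db_rev$protein_seq)
  expect_identical(db_fwd$is_ptc, db_rev$is_ptc)
})

test_that("UTR-only isoform variants produce identical proteins", {
  cfg <- simulation_config(n_genes = 15, seed = 31,
                           isoforms_per_gene = c(3L, 3L))
  sim <- simulate_genome_annotation(cfg)
  f <- translation_features(translate_catalog(sim$genome, sim$catalog))
  tt <- sim$truth$transcripts
  utr <- tt[event == "utr_only"]
  expect_gt(nrow(utr), 0)
  for (i in seq_len(nrow(utr))) {
    prim <- paste0(utr$gene_id[i], ".1")
    expect_identical(f[transcript_id == utr$transcript_id[i], protein_seq],
                     f[transcript_id == prim, protein_seq])
  }
})

test_that("gene-level start harmonization follows the plurality rule", {
  p <- translation_params(min_orf_aa = 2, start_harmonization = TRUE)
  # one gene, 3 single-exon isoforms on +; two start at genomic 0 (ATG...),
  # the third contains position 0 but its own longest ORF starts at 6
  chrom <- paste0("ATGCCCATGAAAAAAAAAAAATAG", strrep("C", 10))
  g <- c(c = chrom)
  cat <- transcript_catalog(data.frame(
    transcript_id = c("t1", "t2", "t3"), gene_id = "g", chrom = "c",
    start = 0L, end = c(24L, 27L, 34L), strand = "+"))
  db_h <- translate_catalog(g, cat, p)
  f <- translation_features(db_h)
  # plurality start is genomic 0 for t1/t2 only if their own ORF starts
  # there; verify all three agree after harmonization
  expect_equal(length(unique(f$cds_start)), 1L)

  # single isoform: harmonization changes nothing
  cat1 <- transcript_catalog(data.frame(
    transcript_id = "t1", gene_id = "g", chrom = "c",
    start = 0L, end = 24L, strand = "+"))
  f_on <- translation_features(translate_catalog(g, cat1, p))
  p_off <- translation_params(min_orf_aa = 2, start_harmonization = FALSE)
  f_off <- translation_features(translate_catalog(g, cat1, p_off))
  expect_equal(f_on$cds_start, f_off$cds_start)
})

test_that("isoform lacking the plurality start position keeps its own ORF", {
  p <- translation_params(min_orf_aa = 2)
  # t1,t2 cover genomic 0 (ATG at 0); t3 starts at 6 and cannot see it
  chrom <- paste0("ATGAAACCCATGAAAAAATAG", strrep("T", 6))
  g <- c(c = chrom)
  cat <- transcript_catalog(data.frame(
    transcript_id = c("t1", "t2", "t3"), gene_id = "g", chrom = "c",
    start = c(0L, 0L, 9L), end = c(27L, 26L, 27L), strand = "+"))
  f <- translation_features(translate_catalog(g, cat, p))
  # t3's transcript starts at genomic 9; its ORF begins at its own ATG
  expect_equal(f[transcript_id == "t3", cds_start], 0L)
  expect_true(all(f$is_coding))
})

test_that("translate_catalog reports non-coding transcripts but excludes them", {
  g <- c(c = paste0("ATG", strrep("AAA", 40), "TAG", strrep("C", 30)))
  cat <- transcript_catalog(data.frame(
    transcript_id = c("cod", "nc"), gene_id = c("g1", "g2"), chrom = "c",
    start = c(0L, 126L), end = c(126L, 156L), strand = "+"))
  db <- translate_catalog(g, cat, translation_params(min_orf_aa = 10))
  expect_identical(db$accession, "cod")
  f <- translation_features(db)
  expect_equal(nrow(f), 2L)
  expect_identical(f[transcript_id == "nc", is_coding], FALSE)
  # empty catalog -> empty database
  empty <- translate_catalog(g, transcript_catalog(
    data.frame(transcript_id = character(0), gene_id = character(0),
               chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0))))
  expect_equal(nrow(empty), 0L)
})
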