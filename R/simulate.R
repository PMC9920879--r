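## Seeded synthetic data: toy genome + annotation with controlled
## alternative splicing, two partially overlapping transcript catalogs
## (base-like vs addition-like long-read sources), peptide evidence
## sampled from true proteoforms, DEG tables, and a curated gene list --
## with ground truth recorded for recovery testing.
##
## Construction trick: all UTR, intron and CDS filler sequence is drawn
## from {C,G,T} only.  ATG and every stop codon contain an A, so the only
## start codon in a transcript is the engineered one and the only stops
## are the engineered ones (the final TAG, and a TAG planted at offset 15
## of the first intron that premature-termination variants capture either
## by retaining the intron or by an 18-nt donor extension of exon 1).
## TAG is used for every engineered stop because, unlike TAA/TGA, it
## cannot seed a spurious ATG with adjacent A-free sequence.  This makes
## ORF and PTC ground truth exact by construction.

#' Synthetic-world configuration
#'
#' @param n_genes number of genes (default 50)
#' @param isoforms_per_gene integer range (min, max) of isoforms per gene,
#'   primary included
#' @param as_event_mix named proportions over the variant event types
#'   exon_skip, intron_retention, alt5, alt3, utr_only (must sum to 1)
#' @param ptc_fraction fraction of non-UTR-only variants engineered to
#'   carry an in-frame premature stop upstream of the last junction
#' @param catalog_overlap fraction of the base catalog shared by the
#'   addition catalog
#' @param novel_fraction fraction of non-base transcripts included in the
#'   addition catalog as novel isoforms
#' @param peptides_per_proteoform peptides sampled per proteoform when
#'   generating evidence (`Inf` = every digest peptide)
#' @param noise_peptides number of non-database decoy peptides appended
#' @param detect_prob detection probability per sampled peptide
#' @param frac_differential fraction of genes simulated as differential
#' @param lfc_scale scale of the extra |log2FC| above the 1.5 cut for
#'   differential genes
#' @param curated_fraction fraction of genes placed on the curated list
#' @param seed master seed; every sub-generator derives its own stream
#' @return a `simulation_config` list
#' @export
simulation_config <- function(n_genes = 50L,
                              isoforms_per_gene = c(2L, 4L),
                              as_event_mix = c(exon_skip = 0.25,
                                               intron_retention = 0.20,
                                               alt5 = 0.15, alt3 = 0.15,
                                               utr_only = 0.25),
                              ptc_fraction = 0.2,
                              catalog_overlap = 0.7,
                              novel_fraction = 0.5,
                              peptides_per_proteoform = 5,
                              noise_peptides = 10L,
                              detect_prob = 0.8,
                              frac_differential = 0.3,
                              lfc_scale = 1.0,
                              curated_fraction = 0.25,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              isoforms_per_gene = as.integer(isoforms_per_gene),
              as_event_mix = as_event_mix,
              ptc_fraction = ptc_fraction,
              catalog_overlap = catalog_overlap,
              novel_fraction = novel_fraction,
              peptides_per_proteoform = peptides_per_proteoform,
              noise_peptides = as.integer(noise_peptides),
              detect_prob = detect_prob,
              frac_differential = frac_differential,
              lfc_scale = lfc_scale,
              curated_fraction = curated_fraction,
              seed = as.integer(seed))
  ev <- c("exon_skip", "intron_retention", "alt5", "alt3", "utr_only")
  if (!setequal(names(cfg$as_event_mix), ev))
    stopf("as_event_mix must name exactly: %s", paste(ev, collapse = ", "))
  if (abs(sum(cfg$as_event_mix) - 1) > 1e-8)
    stopf("as_event_mix proportions must sum to 1")
  probs <- c(cfg$ptc_fraction, cfg$catalog_overlap, cfg$novel_fraction,
             cfg$detect_prob, cfg$frac_differential, cfg$curated_fraction)
  if (any(probs < 0 | probs > 1))
    stopf("fractions and probabilities must lie in [0, 1]")
  if (cfg$n_genes < 0L) stopf("n_genes must be >= 0")
  if (length(cfg$isoforms_per_gene) != 2L ||
      cfg$isoforms_per_gene[1] < 1L ||
      cfg$isoforms_per_gene[1] > cfg$isoforms_per_gene[2])
    stopf("isoforms_per_gene must be a valid (min, max) range with min >= 1")
  structure(cfg, class = "simulation_config")
}

## random string over an alphabet
rand_string <- function(n, alphabet) {
  if (n == 0L) return("")
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

afree <- function(n) rand_string(n, c("C", "G", "T"))

## TAG offset (0-based) inside the first intron of every gene
PTC_TAG_OFFSET <- 15L
PTC_DONOR_EXT <- 18L

## structural plan and sense-space sequence of one gene locus
build_gene_locus <- function() {
  n_exons <- sample1(4:6)
  utr5 <- sample1(20:50)
  cds1 <- 3L * sample1(40:60)
  mids <- 3L * sample(15:30, n_exons - 2L, replace = TRUE)
  cds_last <- 3L * sample1(12:25)
  utr3 <- sample1(60:150)
  utr3_ext <- 60L
  intron_lens <- 3L * sample(25:50, n_exons - 1L, replace = TRUE)
  introns <- vapply(seq_len(n_exons - 1L), function(i) {
    s <- afree(intron_lens[i])
    if (i == 1L)   # plant the premature-stop TAG in intron 1, in frame 0
      s <- paste0(substr(s, 1L, PTC_TAG_OFFSET), "TAG",
                  substr(s, PTC_TAG_OFFSET + 4L, nchar(s)))
    s
  }, character(1))
  exon_seqs <- c(paste0(afree(utr5), "ATG", afree(cds1)),
                 vapply(mids, afree, character(1)),
                 paste0(afree(cds_last), "TAG", afree(utr3)))
  pieces <- character(0)
  starts <- integer(n_exons); ends <- integer(n_exons)
  pos <- 0L
  for (i in seq_len(n_exons)) {
    starts[i] <- pos
    pieces <- c(pieces, exon_seqs[i])
    pos <- pos + nchar(exon_seqs[i])
    ends[i] <- pos
    if (i < n_exons) {
      pieces <- c(pieces, introns[i])
      pos <- pos + nchar(introns[i])
    }
  }
  pieces <- c(pieces, afree(utr3_ext))
  list(seq = paste(pieces, collapse = ""), n_exons = n_exons,
       utr5 = utr5, utr3 = utr3, utr3_ext = utr3_ext,
       exon_starts = starts, exon_ends = ends)
}

## sense-space exon intervals of one isoform given its event
variant_exons <- function(loc, event) {
  s <- loc$exon_starts; e <- loc$exon_ends
  n <- loc$n_exons
  if (event == "exon_skip") {
    drop <- sample1(2:(n - 1L))
    s <- s[-drop]; e <- e[-drop]
  } else if (event == "intron_retention") {
    e[1] <- e[2]; s <- s[-2]; e <- e[-2]
  } else if (event == "alt5") {
    i <- sample1(2:(n - 2L))
    ext <- 3L * sample1(1:3)
    e[i] <- e[i] + ext          # donor extension into an A-free intron
  } else if (event == "alt3") {
    i <- sample1(2:(n - 2L))
    ext <- 3L * sample1(1:3)
    s[i + 1L] <- s[i + 1L] - ext  # acceptor extension into the intron tail
  } else if (event == "utr_only") {
    deltas <- 3L * c(-8:-1, 1:20)
    new3 <- loc$utr3 + deltas
    ok <- deltas[new3 >= 21L & new3 <= loc$utr3 + loc$utr3_ext]
    e[n] <- e[n] + sample1(ok)
  } else if (event != "primary") stopf("unknown event: %s", event)
  list(start = s, end = e)
}

## truth bookkeeping for one isoform from its sense-space slice: walk
## codons from the known ATG to the first stop (independent of the
## package's genomic/strand translation machinery)
truth_annotate <- function(loc, ex, ptc_junction_nt = 50L) {
  spliced <- paste(substring(loc$seq, ex$start + 1L, ex$end), collapse = "")
  codons <- split_codons(substr(spliced, loc$utr5 + 1L, nchar(spliced)))
  stop_at <- which(codons %in% STOP_CODONS)[1]
  protein <- paste(translate_codons(codons[seq_len(stop_at - 1L)]),
                   collapse = "")
  stop_end <- loc$utr5 + 3L * stop_at          # tx coord, exclusive
  lens <- ex$end - ex$start
  j <- if (length(lens) >= 2L) sum(lens) - lens[length(lens)] else NA_integer_
  list(protein = protein,
       is_ptc = !is.na(j) && (j - stop_end) >= ptc_junction_nt,
       utr3_len = nchar(spliced) - stop_end,
       tx_len = nchar(spliced))
}

#' Simulate a toy genome and multi-isoform annotation with ground truth
#'
#' Genes carry 4-6 exons; variants are drawn from the configured
#' alternative-splicing event mix.  UTR-only variants are protein-identical
#' to their primary by construction; the configured fraction of non-UTR
#' variants is engineered to contain an in-frame premature stop at least
#' `ptc_junction_nt` upstream of the last junction.  Deterministic per
#' seed.
#'
#' @param cfg a [simulation_config()]
#' @param ptc_junction_nt PTC distance rule used for the recorded ground
#'   truth (match the translation parameters you will run with)
#' @return list with `genome` (named character), `catalog`
#'   (a [transcript_catalog()]), and `truth` (list: `transcripts`
#'   data.table and the config)
#' @export
simulate_genome_annotation <- function(cfg = simulation_config(),
                                       ptc_junction_nt = 50L) {
  if (cfg$n_genes == 0L)
    return(list(genome = character(0),
                catalog = transcript_catalog(empty_exon_table(), "all"),
                truth = list(transcripts = empty_truth_table(),
                             config = cfg)))
  with_seed(derive_seed(cfg$seed, 1L), {
    plans <- lapply(seq_len(cfg$n_genes), function(i) {
      loc <- build_gene_locus()
      n_iso <- sample1(cfg$isoforms_per_gene[1]:cfg$isoforms_per_gene[2])
      events <- c("primary",
                  if (n_iso > 1L)
                    sample(names(cfg$as_event_mix), n_iso - 1L,
                           replace = TRUE, prob = cfg$as_event_mix))
      list(loc = loc, events = events, gene_id = sprintf("G%04d", i),
           chrom = if (i %% 2L) "chr1" else "chr2",
           strand = if (((i - 1L) %/% 2L) %% 2L) "-" else "+")
    })
    ## engineer premature stops into a fraction of the eligible variants
    elig <- rbindlist(lapply(seq_along(plans), function(g) {
      ev <- plans[[g]]$events
      k <- which(!ev %in% c("primary", "utr_only", "intron_retention"))
      if (length(k)) data.table(g = g, k = k) else NULL
    }))
    ptc_rows <- integer(0)
    if (!is.null(elig) && nrow(elig)) {
      n_ptc <- round(cfg$ptc_fraction * nrow(elig))
      ptc_rows <- if (n_ptc > 0L) sample(nrow(elig), n_ptc) else integer(0)
    }
    ptc_engineered <- lapply(plans, function(p) logical(length(p$events)))
    for (r in ptc_rows)
      ptc_engineered[[elig$g[r]]][elig$k[r]] <- TRUE

    exon_rows <- list(); truth_rows <- list()
    chrom_pieces <- list(chr1 = character(0), chr2 = character(0))
    chrom_pos <- c(chr1 = 0L, chr2 = 0L)
    for (g in seq_along(plans)) {
      p <- plans[[g]]; loc <- p$loc
      filler <- rand_string(100L, c("A", "C", "G", "T"))
      locus_start <- chrom_pos[[p$chrom]] + 100L
      locus_len <- nchar(loc$seq)
      locus_seq <- if (p$strand == "-") revcomp(loc$seq) else loc$seq
      chrom_pieces[[p$chrom]] <- c(chrom_pieces[[p$chrom]], filler,
                                   locus_seq)
      chrom_pos[[p$chrom]] <- locus_start + locus_len
      for (v in seq_along(p$events)) {
        ev <- p$events[v]
        ex <- variant_exons(loc, ev)
        if (ptc_engineered[[g]][v]) ex$end[1] <- ex$end[1] + PTC_DONOR_EXT
        ann <- truth_annotate(loc, ex, ptc_junction_nt)
        tid <- sprintf("%s.%d", p$gene_id, v)
        gs <- if (p$strand == "-") locus_start + (locus_len - ex$end)
              else locus_start + ex$start
        ge <- if (p$strand == "-") locus_start + (locus_len - ex$start)
              else locus_start + ex$end
        o <- order(gs)
        exon_rows[[length(exon_rows) + 1L]] <- data.table(
          transcript_id = tid, gene_id = p$gene_id, chrom = p$chrom,
          start = gs[o], end = ge[o], strand = p$strand)
        truth_rows[[length(truth_rows) + 1L]] <- data.table(
          transcript_id = tid, gene_id = p$gene_id, event = ev,
          ptc_engineered = ptc_engineered[[g]][v],
          protein_seq = ann$protein, is_ptc = ann$is_ptc,
          utr3_len = ann$utr3_len, tx_len = ann$tx_len,
          n_exons = length(ex$start))
      }
    }
    genome <- vapply(chrom_pieces, paste, character(1), collapse = "")
    genome <- genome[nzchar(genome)]
    truth <- rbindlist(truth_rows)
    truth[, duplicate_class := paste(gene_id,
                                     match(protein_seq,
                                           unique(protein_seq)), sep = ":")]
    list(genome = genome,
         catalog = transcript_catalog(rbindlist(exon_rows), "all"),
         truth = list(transcripts = truth, config = cfg))
  })
}

empty_truth_table <- function() {
  data.table(transcript_id = character(0), gene_id = character(0),
             event = character(0), ptc_engineered = logical(0),
             protein_seq = character(0), is_ptc = logical(0),
             utr3_len = integer(0), tx_len = integer(0),
             n_exons = integer(0), duplicate_class = character(0))
}

#' Split the simulated isoforms into two overlapping source catalogs
#'
#' The base catalog contains every gene's primary isoform plus roughly
#' half of the variants; the addition catalog shares `catalog_overlap` of
#' the base and adds `novel_fraction` of the remaining (non-base)
#' transcripts, so a merge exercises both duplicate and novel outcomes.
#'
#' @param truth output `truth` of [simulate_genome_annotation()]
#' @param cfg the [simulation_config()]
#' @return list of two character vectors: `base`, `addition`
#' @export
simulate_long_read_catalogs <- function(truth, cfg) {
  tt <- truth$transcripts
  if (!nrow(tt)) return(list(base = character(0), addition = character(0)))
  with_seed(derive_seed(cfg$seed, 2L), {
    primaries <- tt[event == "primary", transcript_id]
    variants <- tt[event != "primary", transcript_id]
    in_base <- c(primaries,
                 if (length(variants))
                   variants[runif(length(variants)) < 0.5])
    base <- tt$transcript_id[tt$transcript_id %in% in_base]  # stable order
    rest <- setdiff(tt$transcript_id, base)
    n_shared <- round(cfg$catalog_overlap * length(base))
    shared <- if (n_shared > 0L) sort(sample(base, n_shared)) else character(0)
    n_novel <- round(cfg$novel_fraction * length(rest))
    novel <- if (n_novel > 0L) sort(sample(rest, n_novel)) else character(0)
    addition <- tt$transcript_id[tt$transcript_id %in% c(shared, novel)]
    list(base = base, addition = addition)
  })
}

#' Sample peptide evidence from a proteoform database
#'
#' For every proteoform, up to `peptides_per_proteoform` digest peptides
#' are sampled, each detected with probability `detect_prob`.  Noise
#' peptides are rejection-sampled against the whole database digest so
#' they are guaranteed not to match.  Deterministic per seed.
#'
#' @param db the searched [protein_db()] (deduplicated)
#' @param cfg the [simulation_config()]
#' @param params [digest_params()] used for sampling and the rejection
#'   check
#' @return list: `evidence` (data.table with column peptide) and
#'   `peptide_truth` (peptide, accession of first sampled source,
#'   is_noise)
#' @export
simulate_peptide_evidence <- function(db, cfg, params = digest_params()) {
  with_seed(derive_seed(cfg$seed, 3L), {
    rows <- lapply(seq_len(nrow(db)), function(i) {
      peps <- digest(db$protein_seq[i], params)
      if (!length(peps)) return(NULL)
      k <- min(cfg$peptides_per_proteoform, length(peps))
      sampled <- sample(peps, k)
      detected <- sampled[runif(k) <= cfg$detect_prob]
      if (!length(detected)) return(NULL)
      data.table(peptide = detected, accession = db$accession[i],
                 is_noise = FALSE)
    })
    tr <- rbindlist(rows)
    if (is.null(tr) || !nrow(tr))
      tr <- data.table(peptide = character(0), accession = character(0),
                       is_noise = logical(0))
    tr <- tr[!duplicated(peptide)]
    if (cfg$noise_peptides > 0L) {
      index <- build_peptide_index(db, params)
      aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
      noise <- character(0)
      while (length(noise) < cfg$noise_peptides) {
        cand <- rand_string(sample1(8:15), aa20)
        key <- peptide_key(cand, params)
        if (!key %in% index$entries$peptide && !cand %in% noise &&
            !key %in% peptide_key(tr$peptide, params))
          noise <- c(noise, cand)
      }
      tr <- rbind(tr, data.table(peptide = noise, accession = NA_character_,
                                 is_noise = TRUE))
    }
    list(evidence = data.table(peptide = tr$peptide), peptide_truth = tr)
  })
}

#' Simulate a differential-expression table with known truth
#'
#' Differential genes draw |log2FC| strictly above 1.5 with adjusted p
#' below 0.05; every other gene fails at least one of the two cuts.
#'
#' @param truth output `truth` of [simulate_genome_annotation()]
#' @param cfg the [simulation_config()]
#' @return list: `deg` (data.table gene_id, log2fc, padj) and
#'   `differential` (character vector, the true DEG set)
#' @export
simulate_deg_table <- function(truth, cfg) {
  genes <- unique(truth$transcripts$gene_id)
  n <- length(genes)
  if (!n) return(list(deg = data.table(gene_id = character(0),
                                       log2fc = numeric(0),
                                       padj = numeric(0)),
                      differential = character(0)))
  with_seed(derive_seed(cfg$seed, 4L), {
    n_diff <- round(cfg$frac_differential * n)
    diff_genes <- if (n_diff > 0L) sort(sample(genes, n_diff))
                  else character(0)
    deg <- data.table(gene_id = genes, log2fc = 0, padj = 1)
    is_d <- deg$gene_id %in% diff_genes
    k <- sum(is_d)
    if (k) {
      deg[is_d, log2fc := sample(c(-1, 1), k, TRUE) *
            (1.5 + 0.01 + rexp(k, rate = 1 / cfg$lfc_scale))]
      deg[is_d, padj := runif(k, 1e-8, 0.049)]
    }
    m <- sum(!is_d)
    if (m) {
      mode <- sample(1:3, m, TRUE)   # which cut(s) each non-DEG fails
      lfc <- ifelse(mode != 2L, runif(m, -1.45, 1.45),
                    sample(c(-1, 1), m, TRUE) * runif(m, 1.6, 4))
      pj <- ifelse(mode != 1L, runif(m, 0.051, 1), runif(m, 1e-8, 0.049))
      deg[!is_d, `:=`(log2fc = lfc, padj = pj)]
    }
    list(deg = deg[], differential = diff_genes)
  })
}

#' Simulate a curated gene list (leaf-senescence-list stand-in)
#'
#' @param truth output `truth` of [simulate_genome_annotation()]
#' @param cfg the [simulation_config()]
#' @return character vector of curated gene IDs
#' @export
simulate_curated_list <- function(truth, cfg) {
  with_seed(derive_seed(cfg$seed, 5L), {
    genes <- unique(truth$transcripts$gene_id)
    k <- round(cfg$curated_fraction * length(genes))
    if (k > 0L) sort(sample(genes, k)) else character(0)
  })
}

#' Generate every pipeline input from one seed
#'
#' Runs all sub-generators and, when `dir` is given, writes genome.fa,
#' annotation.gtf, catalogs.tsv, evidence.tsv, deg.tsv, curated.tsv and
#' truth.json.  Peptide evidence is sampled from the deduplicated true
#' proteoforms of the union of the two catalogs.
#'
#' @param cfg a [simulation_config()]
#' @param dir optional output directory
#' @param params [digest_params()] for evidence sampling
#' @param ptc_junction_nt PTC rule distance recorded in ground truth
#' @return list: genome, catalog, truth, catalogs, evidence,
#'   peptide_truth, deg, differential, curated (and `dir` if written)
#' @export
simulate_bundle <- function(cfg = simulation_config(), dir = NULL,
                            params = digest_params(),
                            ptc_junction_nt = 50L) {
  sim <- simulate_genome_annotation(cfg, ptc_junction_nt)
  catalogs <- simulate_long_read_catalogs(sim$truth, cfg)
  tt <- sim$truth$transcripts
  in_union <- tt[transcript_id %in% c(catalogs$base, catalogs$addition)]
  ev_db <- if (nrow(in_union)) {
    remove_redundant(protein_db(data.table(
      accession = in_union$transcript_id, gene_id = in_union$gene_id,
      protein_seq = in_union$protein_seq), "truth_union"))$db
  } else protein_db(NULL, "truth_union")
  evidence <- simulate_peptide_evidence(ev_db, cfg, params)
  degsim <- simulate_deg_table(sim$truth, cfg)
  curated <- simulate_curated_list(sim$truth, cfg)
  out <- list(genome = sim$genome, catalog = sim$catalog,
              truth = sim$truth, catalogs = catalogs,
              evidence = evidence$evidence,
              peptide_truth = evidence$peptide_truth,
              deg = degsim$deg, differential = degsim$differential,
              curated = curated)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    if (length(sim$genome)) write_fasta(sim$genome,
                                        file.path(dir, "genome.fa"))
    else writeLines(character(0), file.path(dir, "genome.fa"))
    write_gtf(sim$catalog, file.path(dir, "annotation.gtf"))
    write_tsv(rbind(
      data.table(transcript_id = catalogs$base, catalog = "base"),
      data.table(transcript_id = catalogs$addition, catalog = "addition")),
      file.path(dir, "catalogs.tsv"))
    write_tsv(evidence$evidence, file.path(dir, "evidence.tsv"))
    write_tsv(degsim$deg, file.path(dir, "deg.tsv"))
    write_tsv(data.table(gene_id = curated), file.path(dir, "curated.tsv"))
    jsonlite::write_json(
      list(transcripts = sim$truth$transcripts,
           catalogs = catalogs,
           peptide_truth = evidence$peptide_truth,
           differential = degsim$differential,
           curated = curated,
           seed = cfg$seed),
      file.path(dir, "truth.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
    out$dir <- dir
  }
  out
}
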