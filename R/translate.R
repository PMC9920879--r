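## Splice-aware translation of transcript models into proteoforms:
## spliced sequence extraction, longest-ORF selection, gene-level start
## harmonization, and PTC / long-3'UTR NMD-feature classification.

#' Translation parameters
#'
#' @param min_orf_aa minimum protein length in residues for an ORF to be
#'   considered coding (default 30)
#' @param ptc_junction_nt a stop ending at least this many nucleotides
#'   upstream of the last exon-exon junction marks a premature termination
#'   codon (default 50, the canonical NMD rule)
#' @param long_utr3_nt a 3'UTR longer than this flags the long-3'UTR NMD
#'   feature (default 350)
#' @param start_harmonization harmonize start codons across isoforms of a
#'   gene (default TRUE)
#' @return a `translation_params` list
#' @export
translation_params <- function(min_orf_aa = 30L, ptc_junction_nt = 50L,
                               long_utr3_nt = 350L,
                               start_harmonization = TRUE) {
  p <- list(min_orf_aa = as.integer(min_orf_aa),
            ptc_junction_nt = as.integer(ptc_junction_nt),
            long_utr3_nt = as.integer(long_utr3_nt),
            start_harmonization = isTRUE(start_harmonization))
  if (p$min_orf_aa < 1L || p$ptc_junction_nt < 1L || p$long_utr3_nt < 1L)
    stopf("translation thresholds must be positive")
  structure(p, class = "translation_params")
}

#' Extract the mature (spliced) transcript sequence
#'
#' Exon substrings are concatenated in genomic order; minus-strand models
#' are reverse-complemented so the result always reads 5' to 3'.
#'
#' @param genome named character vector of chromosome sequences
#' @param t exon rows of one transcript (a [transcript_catalog()] subset)
#' @return the mature transcript sequence (character scalar)
#' @export
spliced_sequence <- function(genome, t) {
  chrom <- t$chrom[1]
  if (!chrom %in% names(genome))
    stopf("chromosome \"%s\" not found in genome", chrom)
  clen <- nchar(genome[[chrom]])
  if (any(t$end > clen))
    stopf("exon out of bounds on %s: end %d > length %d", chrom,
          max(t$end), clen)
  o <- order(t$start)
  s <- paste(substring(genome[[chrom]], t$start[o] + 1L, t$end[o]),
             collapse = "")
  if (t$strand[1] == "-") revcomp(s) else s
}

## ORF annotation rows share this shape; NA protein marks non-coding
orf_na <- function(transcript_id = NA_character_) {
  data.table(transcript_id = transcript_id, is_coding = FALSE,
             cds_start = NA_integer_, cds_end = NA_integer_,
             protein_seq = NA_character_, utr5_len = NA_integer_,
             utr3_len = NA_integer_, is_ptc = NA, is_long_utr3 = NA,
             nmd_candidate = NA)
}

## all stop positions (0-based) in tx_seq; non-overlap is safe because no
## stop codon starts with the 2nd or 3rd base of another stop
stop_positions <- function(tx_seq) {
  m <- gregexpr("TAA|TAG|TGA", tx_seq)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

## ORF beginning at 0-based position p, ending at first in-frame stop;
## NULL if no stop or protein shorter than min_orf_aa
orf_from_start <- function(tx_seq, p, min_orf_aa,
                           stops = stop_positions(tx_seq)) {
  inframe <- stops[stops >= p + 3L & (stops - p) %% 3L == 0L]
  if (!length(inframe)) return(NULL)
  q <- inframe[1]
  naa <- (q - p) %/% 3L
  if (naa < min_orf_aa) return(NULL)
  list(cds_start = p, cds_end = q + 3L, n_aa = naa)
}

#' Find the open reading frame of a transcript sequence
#'
#' Among all ORFs that begin at an ATG and end at the first in-frame stop
#' downstream, the longest protein wins; ties go to the 5'-most start.
#' ORFs shorter than `min_orf_aa` or lacking an in-frame stop (run-off)
#' are discarded; if none survive the transcript is non-coding.  Codons
#' containing N translate to X.
#'
#' @param tx_seq mature transcript sequence over \{A,C,G,T,N\}
#' @param params [translation_params()]
#' @return one-row data.table with cds coordinates (0-based half-open,
#'   `cds_end` includes the stop codon), `protein_seq` (stop excluded),
#'   UTR lengths and `is_coding`; NMD flags are left NA for [classify_nmd()]
#' @export
find_orf <- function(tx_seq, params = translation_params()) {
  tx_seq <- toupper(tx_seq)
  ann <- orf_na()
  m <- gregexpr("ATG", tx_seq, fixed = TRUE)[[1]]
  if (m[1] == -1L) return(ann)
  starts <- as.integer(m) - 1L
  stops <- stop_positions(tx_seq)
  best <- NULL
  for (p in starts) {
    o <- orf_from_start(tx_seq, p, params$min_orf_aa, stops)
    if (!is.null(o) && (is.null(best) || o$n_aa > best$n_aa))
      best <- o  # starts scanned 5'->3', so ties keep the earlier start
  }
  if (is.null(best)) return(ann)
  annotate_cds(tx_seq, best$cds_start, best$cds_end)
}

## fill an ORF annotation row from cds coordinates
annotate_cds <- function(tx_seq, cds_start, cds_end,
                         transcript_id = NA_character_) {
  codons <- split_codons(substr(tx_seq, cds_start + 1L, cds_end - 3L))
  data.table(transcript_id = transcript_id, is_coding = TRUE,
             cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
             protein_seq = paste(translate_codons(codons), collapse = ""),
             utr5_len = as.integer(cds_start),
             utr3_len = as.integer(nchar(tx_seq) - cds_end),
             is_ptc = NA, is_long_utr3 = NA, nmd_candidate = NA)
}

## map a transcript offset (0-based) to its genomic position, honouring
## strand; t is one transcript's exon rows sorted by genomic start
tx_to_genomic <- function(t, off) {
  lens <- t$end - t$start
  if (t$strand[1] == "-") {
    lens <- rev(lens); starts <- rev(t$start); ends <- rev(t$end)
    cum <- cumsum(lens)
    i <- which(off < cum)[1]
    prev <- if (i == 1L) 0L else cum[i - 1L]
    ends[i] - 1L - (off - prev)
  } else {
    cum <- cumsum(lens)
    i <- which(off < cum)[1]
    prev <- if (i == 1L) 0L else cum[i - 1L]
    t$start[i] + (off - prev)
  }
}

## inverse of tx_to_genomic; NA when gpos is not exonic
genomic_to_tx <- function(t, gpos) {
  i <- which(gpos >= t$start & gpos < t$end)
  if (!length(i)) return(NA_integer_)
  lens <- t$end - t$start
  if (t$strand[1] == "-") {
    after <- which(t$start > t$start[i])
    offset_into <- t$end[i] - 1L - gpos
    sum(lens[after]) + offset_into
  } else {
    before <- which(t$start < t$start[i])
    sum(lens[before]) + (gpos - t$start[i])
  }
}

## transcript coordinate of the last exon-exon junction (start of the last
## exon in transcript order); NA for single-exon models
last_junction_tx <- function(t) {
  if (nrow(t) < 2L) return(NA_integer_)
  lens <- t$end - t$start
  if (t$strand[1] == "-") lens <- rev(lens)
  sum(lens) - lens[length(lens)]
}

#' Classify NMD-related coding features of a translated transcript
#'
#' A stop is a premature termination codon (PTC) when the transcript has
#' at least two exons and the stop codon's last base lies at least
#' `ptc_junction_nt` nucleotides upstream of the last exon-exon junction
#' in transcript coordinates.  A 3'UTR longer than `long_utr3_nt` flags
#' the long-3'UTR feature.  Either feature marks an NMD candidate.
#'
#' @param t exon rows of the transcript
#' @param orf one-row ORF annotation from [find_orf()] (must be coding)
#' @param params [translation_params()]
#' @return the annotation row with `is_ptc`, `is_long_utr3`,
#'   `nmd_candidate` set
#' @export
classify_nmd <- function(t, orf, params = translation_params()) {
  if (!isTRUE(orf$is_coding))
    stopf("classify_nmd called on a non-coding ORF annotation")
  orf <- copy(orf)
  j <- last_junction_tx(t)
  orf[, is_ptc := !is.na(j) && (j - cds_end) >= params$ptc_junction_nt]
  orf[, is_long_utr3 := utr3_len > params$long_utr3_nt]
  orf[, nmd_candidate := is_ptc | is_long_utr3]
  orf[]
}

#' Harmonize start codons across the isoforms of one gene
#'
#' Computes each coding isoform's start-codon genomic position and takes
#' the plurality position (ties broken 5'-most on the coding strand) as
#' the gene-level start.  Any isoform whose exon chain contains that
#' position, where the position initiates an ATG in the spliced sequence
#' with a downstream in-frame stop meeting `min_orf_aa`, is re-annotated
#' to start there; all other isoforms keep their own ORF.
#'
#' @param models list of exon tables, named by transcript_id (one gene)
#' @param orfs data.table of ORF annotations for those transcripts
#' @param tx_seqs named character vector of mature transcript sequences
#' @param params [translation_params()]
#' @return the `orfs` table, adjusted
#' @export
harmonize_gene_starts <- function(models, orfs, tx_seqs,
                                  params = translation_params()) {
  coding <- orfs[is_coding == TRUE]
  if (nrow(coding) < 2L) return(orfs)
  gpos <- vapply(seq_len(nrow(coding)), function(i) {
    tx_to_genomic(models[[coding$transcript_id[i]]], coding$cds_start[i])
  }, integer(1))
  tab <- table(gpos)
  cand <- as.integer(names(tab)[tab == max(tab)])
  strand <- models[[coding$transcript_id[1]]]$strand[1]
  g <- if (strand == "-") max(cand) else min(cand)
  out <- copy(orfs)
  for (i in seq_len(nrow(out))) {
    tid <- out$transcript_id[i]
    t <- models[[tid]]
    off <- genomic_to_tx(t, g)
    if (is.na(off)) next
    seq <- tx_seqs[[tid]]
    if (substr(seq, off + 1L, off + 3L) != "ATG") next
    o <- orf_from_start(seq, off, params$min_orf_aa)
    if (is.null(o)) next
    repl <- annotate_cds(seq, o$cds_start, o$cds_end, transcript_id = tid)
    for (col in names(out)) set(out, i, col, repl[[col]])
  }
  out
}

#' Translate a transcript catalog into a proteoform database
#'
#' Per transcript: spliced sequence, ORF selection, optional gene-level
#' start harmonization, then PTC / long-3'UTR classification.  Non-coding
#' transcripts are excluded from the database but reported in the feature
#' table attached as attribute `"features"` (see [translation_features()]).
#' The proteoform accession is the transcript accession; the family is the
#' gene; the source is the catalog label.
#'
#' @param genome named character vector of chromosome sequences
#' @param catalog a [transcript_catalog()]
#' @param params [translation_params()]
#' @param label database / source label (defaults to the catalog's source)
#' @return a [protein_db()] with one entry per coding transcript
#' @export
translate_catalog <- function(genome, catalog,
                              params = translation_params(),
                              label = NULL) {
  label <- label %||% (if (nrow(catalog)) catalog$source[1] else "db")
  if (!nrow(catalog)) {
    db <- protein_db(NULL, label)
    setattr(db, "features", empty_features_table())
    return(db)
  }
  tids <- unique(catalog$transcript_id)
  models <- split(as.data.table(catalog), by = "transcript_id",
                  sorted = FALSE)
  models <- models[tids]
  tx_seqs <- vapply(models, function(t) spliced_sequence(genome, t),
                    character(1))
  orfs <- rbindlist(lapply(tids, function(tid) {
    ann <- find_orf(tx_seqs[[tid]], params)
    ann[, transcript_id := tid]
    ann
  }))
  gene_of <- vapply(models, function(t) t$gene_id[1], character(1))
  if (params$start_harmonization) {
    orfs <- rbindlist(lapply(split(seq_along(tids), gene_of[tids]),
                             function(idx) {
      harmonize_gene_starts(models[idx], orfs[idx], tx_seqs[idx], params)
    }))
    orfs <- orfs[match(tids, transcript_id)]
  }
  for (i in seq_len(nrow(orfs))) {
    if (isTRUE(orfs$is_coding[i])) {
      repl <- classify_nmd(models[[orfs$transcript_id[i]]], orfs[i], params)
      for (col in names(orfs)) set(orfs, i, col, repl[[col]])
    }
  }
  features <- copy(orfs)
  features[, gene_id := gene_of[transcript_id]]
  setcolorder(features, c("transcript_id", "gene_id", "is_coding"))
  coding <- features[is_coding == TRUE]
  db <- protein_db(data.table(
    accession = coding$transcript_id,
    gene_id = coding$gene_id,
    protein_seq = coding$protein_seq,
    sources = rep(list(label), nrow(coding)),
    transcript_ids = as.list(coding$transcript_id),
    is_ptc = coding$is_ptc), label)
  setattr(db, "features", features[])
  db
}

empty_features_table <- function() {
  f <- orf_na()[0]
  f[, gene_id := character(0)]
  setcolorder(f, c("transcript_id", "gene_id", "is_coding"))
  f[]
}

#' Per-transcript coding feature table of a translated catalog
#'
#' Columns: transcript_id, gene_id, is_coding, cds_start, cds_end,
#' protein_seq, utr5_len, utr3_len, is_ptc, is_long_utr3, nmd_candidate.
#'
#' @param db a [protein_db()] produced by [translate_catalog()]
#' @return a data.table (all transcripts, coding or not)
#' @export
translation_features <- function(db) {
  f <- attr(db, "features")
  if (is.null(f)) stopf("database has no attached feature table")
  f
}
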