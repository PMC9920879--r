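## I/O for the formats the pipeline touches: FASTA, GTF 2.2, the protein
## FASTA header dialect, and TSV tables.  Internal coordinates are 0-based
## half-open; GTF I/O converts from/to 1-based inclusive.

#' Read a FASTA file into a named character vector
#'
#' Wrapped sequence lines are concatenated; the record ID is the first
#' whitespace-delimited token of the header; sequences are upper-cased.
#' Record order is preserved.
#'
#' @param path path to a FASTA file
#' @return named character vector of uppercase sequences
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids)))
    stopf("FASTA format error: record with empty ID in %s", path)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stopf("FASTA format error: duplicate ID \"%s\"", dup[1])
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs)))
    stopf("FASTA format error: empty sequence for ID \"%s\"",
          ids[!nzchar(seqs)][1])
  names(seqs) <- ids
  seqs
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs named character vector
#' @param path output file
#' @param width line wrap width (columns)
#' @return `path`, invisibly
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Construct a transcript catalog from exon intervals
#'
#' A transcript catalog is a `data.table` (class `transcript_catalog`) with
#' one row per exon: `transcript_id`, `gene_id`, `chrom`, `start`, `end`
#' (0-based half-open), `strand`, `source`.  Exons of one transcript must
#' share chrom and strand, be non-overlapping, and are stored sorted by
#' genomic start regardless of strand.
#'
#' @param exons data.frame-like with the columns above (`source` optional)
#' @param source catalog label applied when `exons` lacks a source column
#' @return a `transcript_catalog`
#' @export
transcript_catalog <- function(exons, source = "catalog") {
  dt <- as.data.table(exons)
  req <- c("transcript_id", "gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(req, names(dt))
  if (length(miss)) stopf("missing catalog columns: %s",
                          paste(miss, collapse = ", "))
  if (!"source" %in% names(dt)) dt[, source := source]
  if (nrow(dt)) {
    if (any(dt$start < 0L) || any(dt$start >= dt$end))
      stopf("invalid exon interval: require 0 <= start < end")
    if (!all(dt$strand %in% c("+", "-")))
      stopf("strand must be '+' or '-'")
    setorder(dt, transcript_id, start)
    bad <- dt[, .(ok = uniqueN(chrom) == 1L && uniqueN(strand) == 1L &&
                    uniqueN(gene_id) == 1L &&
                    (.N == 1L || all(start[-1] >= end[-.N]))),
              by = transcript_id][ok == FALSE]
    if (nrow(bad))
      stopf("transcript model error (overlapping exons or mixed chrom/strand/gene): %s",
            bad$transcript_id[1])
  }
  setattr(dt, "class", c("transcript_catalog", class(data.table())))
  dt[]
}

#' Read transcript models from a GTF file
#'
#' Only `exon` features are interpreted; any CDS features in the input are
#' ignored because the pipeline computes its own CDS.  GTF coordinates
#' (1-based inclusive) are converted to the internal 0-based half-open
#' convention.  Exons are grouped by `transcript_id` and stored sorted by
#' genomic start on both strands.
#'
#' @param path path to a GTF 2.2 file
#' @param source catalog label recorded on every model
#' @return a [transcript_catalog()]
#' @export
read_gtf <- function(path, source = "catalog") {
  if (!file.exists(path)) stopf("GTF file not found: %s", path)
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  if (!length(keep)) return(transcript_catalog(empty_exon_table(), source))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L))
    stopf("GTF parse error at line %d: expected 9 tab-separated fields",
          keep[which(nf < 9L)[1]])
  feat <- vapply(fields, `[`, character(1), 3L)
  ex <- which(feat == "exon")
  if (!length(ex)) return(transcript_catalog(empty_exon_table(), source))
  f <- fields[ex]
  lineno <- keep[ex]
  attr_str <- vapply(f, `[`, character(1), 9L)
  tid <- gtf_attr(attr_str, "transcript_id")
  gid <- gtf_attr(attr_str, "gene_id")
  if (anyNA(tid))
    stopf("GTF parse error at line %d: exon lacks transcript_id",
          lineno[which(is.na(tid))[1]])
  if (anyNA(gid))
    stopf("GTF parse error at line %d: exon lacks gene_id",
          lineno[which(is.na(gid))[1]])
  start1 <- suppressWarnings(as.integer(vapply(f, `[`, character(1), 4L)))
  end1 <- suppressWarnings(as.integer(vapply(f, `[`, character(1), 5L)))
  if (anyNA(start1) || anyNA(end1))
    stopf("GTF parse error: non-numeric coordinates near line %d",
          lineno[which(is.na(start1) | is.na(end1))[1]])
  dt <- data.table(
    transcript_id = tid, gene_id = gid,
    chrom = vapply(f, `[`, character(1), 1L),
    start = start1 - 1L, end = end1,
    strand = vapply(f, `[`, character(1), 7L))
  transcript_catalog(dt, source)
}

gtf_attr <- function(attr_str, key) {
  pat <- paste0(key, " \"([^\"]*)\"")
  m <- regmatches(attr_str, regexpr(pat, attr_str))
  out <- rep(NA_character_, length(attr_str))
  hit <- grepl(pat, attr_str)
  out[hit] <- sub(pat, "\\1", m)
  out
}

empty_exon_table <- function() {
  data.table(transcript_id = character(0), gene_id = character(0),
             chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0))
}

#' Write a transcript catalog as GTF 2.2
#'
#' Internal 0-based half-open exon coordinates are converted back to
#' 1-based inclusive.  The round trip `read_gtf(write_gtf(x))` restores
#' coordinates exactly.
#'
#' @param catalog a [transcript_catalog()]
#' @param path output file
#' @param feature_source value for the GTF source column
#' @return `path`, invisibly
#' @export
write_gtf <- function(catalog, path, feature_source = "proteodrift") {
  lines <- if (nrow(catalog)) {
    sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
            catalog$chrom, feature_source, catalog$start + 1L, catalog$end,
            catalog$strand, catalog$gene_id, catalog$transcript_id)
  } else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Construct a proteoform database
#'
#' A protein database is a `data.table` (class `protein_db`) with one row
#' per proteoform: `accession`, `gene_id`, `protein_seq`, `sources` (list
#' column of catalog labels), `transcript_ids` (list column of contributing
#' transcript accessions) and `is_ptc`.  Accessions must be unique; after
#' [remove_redundant()] sequences are unique too.
#'
#' @param entries data.frame-like with at least accession, gene_id,
#'   protein_seq; sources/transcript_ids/is_ptc are defaulted when absent
#' @param label database label
#' @return a `protein_db`
#' @export
protein_db <- function(entries = NULL, label = "db") {
  dt <- if (is.null(entries)) {
    data.table(accession = character(0), gene_id = character(0),
               protein_seq = character(0), sources = list(),
               transcript_ids = list(), is_ptc = logical(0))
  } else as.data.table(entries)
  if (nrow(dt)) {
    if (!all(c("accession", "gene_id", "protein_seq") %in% names(dt)))
      stopf("protein_db requires accession, gene_id, protein_seq")
    if (!"sources" %in% names(dt)) dt[, sources := list(list(label))]
    if (!"transcript_ids" %in% names(dt))
      dt[, transcript_ids := as.list(accession)]
    if (!"is_ptc" %in% names(dt)) dt[, is_ptc := FALSE]
    if (anyDuplicated(dt$accession))
      stopf("protein_db invariant violated: duplicate accession \"%s\"",
            dt$accession[duplicated(dt$accession)][1])
    if (any(!nzchar(dt$protein_seq)))
      stopf("protein_db invariant violated: empty protein sequence")
    if (any(lengths(dt$sources) == 0L))
      stopf("protein_db invariant violated: empty source set")
  }
  setcolorder(dt, c("accession", "gene_id", "protein_seq", "sources",
                    "transcript_ids", "is_ptc"))
  setattr(dt, "class", c("protein_db", class(data.table())))
  setattr(dt, "label", label)
  dt[]
}

#' @export
print.protein_db <- function(x, ...) {
  cat(sprintf("<protein_db '%s': %d proteoforms, %d families>\n",
              attr(x, "label") %||% "db", nrow(x),
              uniqueN(x$gene_id)))
  if (nrow(x)) print(as.data.table(x)[, .(accession, gene_id,
                                          len = nchar(protein_seq),
                                          is_ptc)], topn = 5)
  invisible(x)
}

#' Database label accessor
#' @param db a [protein_db()]
#' @return the label string
#' @export
db_label <- function(db) attr(db, "label") %||% "db"

#' Write a proteoform database as protein FASTA
#'
#' Header dialect: `>ACC gene=GENE src=S1[,S2] ptc=0|1`.  Records are
#' written in database order, 60-column wrapped.
#'
#' @param db a [protein_db()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_protein_fasta <- function(db, path) {
  headers <- sprintf("%s gene=%s src=%s ptc=%d", db$accession, db$gene_id,
                     vapply(db$sources, paste, character(1), collapse = ","),
                     as.integer(db$is_ptc))
  seqs <- db$protein_seq
  names(seqs) <- headers
  if (!nrow(db)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  write_fasta(seqs, path, width = 60L)
  invisible(path)
}

#' Read a protein FASTA written in the package header dialect
#'
#' Contributing transcript IDs are not serialized in the header; on read
#' they are re-seeded with the accession (the translation stage uses the
#' transcript accession as the proteoform accession).
#'
#' @param path protein FASTA path
#' @param label database label to attach
#' @return a [protein_db()]
#' @export
read_protein_fasta <- function(path, label = "db") {
  if (!file.exists(path)) stopf("protein FASTA not found: %s", path)
  if (file.size(path) == 0L) return(protein_db(NULL, label))
  set <- Biostrings::readBStringSet(path)
  hdr <- names(set)
  acc <- vapply(strsplit(hdr, " ", fixed = TRUE), `[`, character(1), 1L)
  gene <- gtf_field(hdr, "gene")
  src <- gtf_field(hdr, "src")
  ptc <- gtf_field(hdr, "ptc")
  if (anyNA(gene) || anyNA(src) || anyNA(ptc))
    stopf("protein FASTA header not in '>ACC gene=.. src=.. ptc=..' dialect: %s",
          hdr[which(is.na(gene) | is.na(src) | is.na(ptc))[1]])
  protein_db(data.table(
    accession = acc, gene_id = gene,
    protein_seq = toupper(as.character(set)),
    sources = strsplit(src, ",", fixed = TRUE),
    transcript_ids = as.list(acc),
    is_ptc = ptc == "1"), label)
}

gtf_field <- function(hdr, key) {
  pat <- paste0(".*\\b", key, "=([^ ]+).*")
  out <- rep(NA_character_, length(hdr))
  hit <- grepl(paste0("\\b", key, "="), hdr)
  out[hit] <- sub(pat, "\\1", hdr[hit])
  out
}

#' Read a TSV table
#'
#' Package-wide TSV dialect: tab-separated, `#`-prefixed comment lines,
#' header row required.
#'
#' @param path file path
#' @return a data.table
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stopf("TSV file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) stopf("TSV file has no header row: %s", path)
  fread(text = paste(lines, collapse = "\n"), sep = "\t", header = TRUE,
        data.table = TRUE)
}

#' Write a TSV table
#' @param x data.frame-like
#' @param path output file
#' @return `path`, invisibly
#' @export
write_tsv <- function(x, path) {
  fwrite(x, path, sep = "\t", quote = FALSE)
  invisible(path)
}
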