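## In silico tryptic digestion, peptide -> proteoform indexing, uniqueness
## classification, and cross-database uniqueness drift.

#' Digestion parameters
#'
#' Defaults mirror common search-engine settings for fully tryptic
#' searches: up to 2 missed cleavages, peptide length 7-50.  `equate_il`
#' canonicalizes isoleucine to leucine in peptide keys (isobaric residues
#' that MS cannot distinguish); it is off by default because search engines
#' report I/L-resolved sequences, but it changes uniqueness counts
#' materially and is therefore exposed.
#'
#' @param missed_cleavages maximum internal uncut K/R sites (default 2)
#' @param min_len minimum peptide length (default 7)
#' @param max_len maximum peptide length (default 50)
#' @param equate_il treat I and L as identical in peptide keys
#' @return a `digest_params` list
#' @export
digest_params <- function(missed_cleavages = 2L, min_len = 7L,
                          max_len = 50L, equate_il = FALSE) {
  p <- list(missed_cleavages = as.integer(missed_cleavages),
            min_len = as.integer(min_len), max_len = as.integer(max_len),
            equate_il = isTRUE(equate_il))
  if (p$missed_cleavages < 0L) stopf("missed_cleavages must be >= 0")
  if (p$min_len > p$max_len) stopf("min_len must be <= max_len")
  structure(p, class = "digest_params")
}

same_digest_params <- function(a, b) {
  identical(unclass(a), unclass(b))
}

#' Tryptic digest of one protein sequence
#'
#' Cleaves C-terminal to K or R except when the next residue is P; includes
#' peptides with up to `missed_cleavages` internal uncut sites; applies the
#' length filter; collapses duplicate peptides within the protein, keeping
#' first (N-terminal-most) occurrence order.
#'
#' @param protein_seq amino-acid string
#' @param params [digest_params()]
#' @return character vector of peptides
#' @export
digest <- function(protein_seq, params = digest_params()) {
  if (!nzchar(protein_seq)) stopf("cannot digest an empty sequence")
  aa <- strsplit(protein_seq, "", fixed = TRUE)[[1]]
  n <- length(aa)
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | aa[pmin(cut_after + 1L, n)] != "P"]
  bounds <- unique(c(0L, cut_after, n))   # fragment boundaries, sorted
  nfrag <- length(bounds) - 1L
  peps <- character(0)
  for (i in seq_len(nfrag)) {
    jmax <- min(nfrag, i + params$missed_cleavages)
    for (j in i:jmax) {
      len <- bounds[j + 1L] - bounds[i]
      if (len >= params$min_len && len <= params$max_len)
        peps <- c(peps, substr(protein_seq, bounds[i] + 1L, bounds[j + 1L]))
    }
  }
  unique(peps)
}

peptide_key <- function(peptides, params) {
  if (params$equate_il) chartr("I", "L", peptides) else peptides
}

#' Build a peptide -> proteoform index for a database
#'
#' @param db a deduplicated [protein_db()]
#' @param params [digest_params()]
#' @return a `peptide_index`: list with `db_label`, `params`, and `entries`
#'   (data.table keyed by `peptide` with a list column `accessions`)
#' @export
build_peptide_index <- function(db, params = digest_params()) {
  assert_nonredundant(db, "indexed")
  pairs <- if (nrow(db)) {
    rbindlist(lapply(seq_len(nrow(db)), function(i) {
      peps <- digest(db$protein_seq[i], params)
      if (!length(peps)) return(NULL)
      data.table(peptide = peptide_key(peps, params),
                 accession = db$accession[i])
    }))
  } else data.table(peptide = character(0), accession = character(0))
  entries <- if (nrow(pairs)) {
    unique(pairs)[, .(accessions = list(accession)), by = peptide]
  } else data.table(peptide = character(0), accessions = list())
  setkey(entries, peptide)
  structure(list(db_label = db_label(db), params = params,
                 entries = entries),
            class = "peptide_index")
}

#' @export
print.peptide_index <- function(x, ...) {
  cat(sprintf("<peptide_index of '%s': %d peptides (missed=%d, len %d-%d%s)>\n",
              x$db_label, nrow(x$entries), x$params$missed_cleavages,
              x$params$min_len, x$params$max_len,
              if (x$params$equate_il) ", I=L" else ""))
  invisible(x)
}

#' Classify every indexed peptide's uniqueness
#'
#' `proteoform_unique`: maps to exactly one proteoform accession;
#' `family_unique`: maps to several accessions that all share one gene;
#' `shared`: maps across genes.
#'
#' @param index a [build_peptide_index()] result
#' @param db the database the index was built from
#' @return data.table: peptide, n_proteoforms, accessions (list), class
#' @export
classify_uniqueness <- function(index, db) {
  ent <- index$entries
  known <- unlist(ent$accessions)
  missing <- setdiff(known, db$accession)
  if (length(missing))
    stopf("index references accession \"%s\" absent from the database",
          missing[1])
  gene_of <- stats::setNames(db$gene_id, db$accession)
  out <- data.table(peptide = ent$peptide,
                    n_proteoforms = lengths(ent$accessions),
                    accessions = ent$accessions)
  out[, class := vapply(accessions, function(a) {
    if (length(a) == 1L) "proteoform_unique"
    else if (uniqueN(gene_of[a]) == 1L) "family_unique"
    else "shared"
  }, character(1))]
  out[]
}

#' Cross-database uniqueness drift of proteoform-unique peptides
#'
#' For every peptide that is proteoform-unique in index A: `retained` if it
#' still maps to exactly one accession in B, `lost` if it maps to two or
#' more (the sharers are listed), `absent` if B's digest does not contain
#' it.  This is the mechanism by which growing a database strips formerly
#' unambiguous proteoforms of their identifiability.
#'
#' @param index_a,index_b [build_peptide_index()] results built with the
#'   same digestion parameters
#' @return data.table sorted by peptide: peptide, former_unique_to,
#'   sharers_in_b (list), status
#' @export
uniqueness_drift <- function(index_a, index_b) {
  if (!same_digest_params(index_a$params, index_b$params))
    stopf("uniqueness_drift requires identical digestion parameters")
  ea <- index_a$entries[lengths(accessions) == 1L]
  if (!nrow(ea))
    return(data.table(peptide = character(0),
                      former_unique_to = character(0),
                      sharers_in_b = list(), status = character(0)))
  hit <- index_b$entries[ea$peptide]   # keyed join on peptide
  out <- data.table(
    peptide = ea$peptide,
    former_unique_to = vapply(ea$accessions, `[`, character(1), 1L),
    sharers_in_b = hit$accessions)
  out[, status := ifelse(vapply(sharers_in_b, function(x)
    length(x) == 0L || all(is.na(x)), logical(1)), "absent",
    ifelse(lengths(sharers_in_b) == 1L, "retained", "lost"))]
  out[status == "absent", sharers_in_b := list(list(character(0)))]
  setorder(out, peptide)
  out[]
}

#' Write a classified peptide index as TSV
#'
#' Columns: peptide, n_proteoforms, `;`-joined accessions, class.  The
#' database label and digestion parameters are stored in `#`-prefixed
#' header comments so the file round-trips through
#' [read_peptide_index_tsv()].
#'
#' @param index a `peptide_index`
#' @param db the source database (for uniqueness classes)
#' @param path output file
#' @return `path`, invisibly
#' @export
write_peptide_index_tsv <- function(index, db, path) {
  cls <- classify_uniqueness(index, db)
  hdr <- c(sprintf("# db_label=%s", index$db_label),
           sprintf("# missed_cleavages=%d", index$params$missed_cleavages),
           sprintf("# min_len=%d", index$params$min_len),
           sprintf("# max_len=%d", index$params$max_len),
           sprintf("# equate_il=%d", as.integer(index$params$equate_il)))
  body <- data.table(peptide = cls$peptide,
                     n_proteoforms = cls$n_proteoforms,
                     accessions = vapply(cls$accessions, paste, character(1),
                                         collapse = ";"),
                     class = cls$class)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(names(body), collapse = "\t"), con)
  if (nrow(body))
    writeLines(do.call(paste, c(body, sep = "\t")), con)
  invisible(path)
}

#' Read a peptide index TSV written by [write_peptide_index_tsv()]
#'
#' @param path index TSV path
#' @return a `peptide_index` (classification columns are recomputable)
#' @export
read_peptide_index_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "# ")]
  kv <- strsplit(sub("^# ", "", hdr), "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                          vapply(kv, `[`, character(1), 1L))
  params <- digest_params(as.integer(meta[["missed_cleavages"]]),
                          as.integer(meta[["min_len"]]),
                          as.integer(meta[["max_len"]]),
                          meta[["equate_il"]] == "1")
  tab <- read_tsv(path)
  entries <- data.table(peptide = as.character(tab$peptide),
                        accessions = strsplit(as.character(tab$accessions),
                                              ";", fixed = TRUE))
  setkey(entries, peptide)
  structure(list(db_label = meta[["db_label"]], params = params,
                 entries = entries),
            class = "peptide_index")
}
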