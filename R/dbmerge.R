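## Exact-sequence redundancy removal and hybrid merging of proteoform
## databases with base-accession precedence and provenance tracking.

#' Remove exact-sequence redundancy from a proteoform database
#'
#' Among entries with identical protein sequence the first in database
#' order is kept; the collapsed entries' transcript IDs and source labels
#' are folded into the survivor.  Redundancy means exact full-length
#' identity; no substring or near-identity collapsing.
#'
#' @param db a [protein_db()]
#' @return list with `db` (non-redundant, first-occurrence order) and
#'   `collapse_map` (named character vector: removed accession -> survivor)
#' @export
remove_redundant <- function(db) {
  if (!nrow(db))
    return(list(db = db, collapse_map = stats::setNames(character(0),
                                                        character(0))))
  first <- !duplicated(db$protein_seq)
  survivor_of <- db$accession[first][match(db$protein_seq,
                                           db$protein_seq[first])]
  keep <- as.data.table(db)[, .(
    accession = accession[1], gene_id = gene_id[1],
    sources = list(unique(unlist(sources))),
    transcript_ids = list(unique(unlist(transcript_ids))),
    is_ptc = is_ptc[1]), by = protein_seq]
  ## by = protein_seq preserves first-occurrence order in data.table
  setcolorder(keep, c("accession", "gene_id", "protein_seq", "sources",
                      "transcript_ids", "is_ptc"))
  removed <- !first
  list(db = protein_db(keep, db_label(db)),
       collapse_map = stats::setNames(survivor_of[removed],
                                      db$accession[removed]))
}

assert_nonredundant <- function(db, what) {
  if (anyDuplicated(db$protein_seq))
    stopf("%s database is not deduplicated; run remove_redundant() first",
          what)
}

#' Merge two proteoform databases with base-accession precedence
#'
#' Output is the base entries followed by those addition entries whose
#' sequence is absent from the base.  For sequences present in both, the
#' base accession (and gene assignment) is kept and the addition's source
#' labels and transcript IDs are appended to the surviving entry, so
#' `nrow(merged) == nrow(base) + nrow(novel_entries(addition, base))`.
#' Gene-assignment conflicts for identical sequences are resolved in favour
#' of the base and recorded in attribute `"gene_conflicts"`.
#'
#' @param base the precedence database (accessions win on duplicates)
#' @param addition the appended database
#' @param label label of the merged database
#' @return a [protein_db()]
#' @export
merge_databases <- function(base, addition,
                            label = paste(db_label(base), db_label(addition),
                                          sep = "_")) {
  assert_nonredundant(base, "base")
  assert_nonredundant(addition, "addition")
  clash <- intersect(base$accession, addition$accession)
  if (length(clash)) {
    same <- addition$protein_seq[match(clash, addition$accession)] ==
      base$protein_seq[match(clash, base$accession)]
    if (any(!same))
      stopf(paste0("accession \"%s\" names different sequences in the two",
                   " databases; namespace the catalogs before merging"),
            clash[!same][1])
  }
  out <- copy(as.data.table(base))
  hit <- match(addition$protein_seq, base$protein_seq)
  dup <- which(!is.na(hit))
  conflicts <- data.table(accession = character(0),
                          base_gene = character(0),
                          addition_gene = character(0))
  for (i in dup) {
    j <- hit[i]
    set(out, j, "sources",
        list(list(unique(c(out$sources[[j]], addition$sources[[i]])))))
    set(out, j, "transcript_ids",
        list(list(unique(c(out$transcript_ids[[j]],
                           addition$transcript_ids[[i]])))))
    if (addition$gene_id[i] != out$gene_id[j])
      conflicts <- rbind(conflicts, data.table(
        accession = out$accession[j], base_gene = out$gene_id[j],
        addition_gene = addition$gene_id[i]))
  }
  novel <- as.data.table(addition)[is.na(hit)]
  merged <- protein_db(rbind(out, novel), label)
  setattr(merged, "gene_conflicts", conflicts)
  merged
}

#' Addition entries whose sequence is absent from the base database
#'
#' @param addition a deduplicated [protein_db()]
#' @param base a deduplicated [protein_db()]
#' @return a [protein_db()] of the novel entries, in addition order
#' @export
novel_entries <- function(addition, base) {
  assert_nonredundant(base, "base")
  assert_nonredundant(addition, "addition")
  protein_db(as.data.table(addition)[!protein_seq %in% base$protein_seq],
             paste0(db_label(addition), "_novel"))
}

#' Merge report table
#'
#' One row per merged entry: accession, gene, `;`-joined sources, and a
#' 0/1 novelty flag (absent from the base database).
#'
#' @param merged output of [merge_databases()]
#' @param base the base database used in the merge
#' @return a data.table
#' @export
merge_report <- function(merged, base) {
  data.table(accession = merged$accession, gene = merged$gene_id,
             sources = vapply(merged$sources, paste, character(1),
                              collapse = ","),
             novel = as.integer(!merged$protein_seq %in% base$protein_seq))
}
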