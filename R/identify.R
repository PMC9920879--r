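## From post-FDR peptide evidence to identified protein families,
## unambiguous proteoforms (>= 1 unique peptide) and greedy parsimony
## groups.  Evidence is assumed already FDR-filtered upstream.

#' Read a peptide evidence table
#'
#' TSV with columns `peptide` and optionally `score`, `sample`.
#'
#' @param path evidence TSV path
#' @return data.table of evidence
#' @export
read_peptide_evidence <- function(path) {
  tab <- read_tsv(path)
  if (!"peptide" %in% names(tab))
    stopf("evidence table lacks a 'peptide' column: %s", path)
  tab[, peptide := toupper(as.character(peptide))]
  if (any(!nzchar(tab$peptide))) stopf("evidence contains empty peptides")
  tab[]
}

as_evidence_peptides <- function(evidence) {
  p <- if (is.character(evidence)) evidence else evidence[["peptide"]]
  if (is.null(p)) stopf("evidence must be a character vector or have a 'peptide' column")
  unique(toupper(p))
}

## split evidence into matched/unmatched against an index; peptide keys
## respect the index's I/L canonicalization
match_evidence <- function(evidence, index) {
  peps <- as_evidence_peptides(evidence)
  keys <- peptide_key(peps, index$params)
  hit <- keys %in% index$entries$peptide
  list(matched = unique(keys[hit]), unmatched = peps[!hit])
}

#' Protein families identified by peptide evidence
#'
#' The union of gene IDs of all proteoforms hit by any matched peptide.
#' Unmatched peptides are reported by [identify_proteoforms()], never an
#' error: peptides failing to match a database are themselves a finding
#' when databases are compared.
#'
#' @param evidence character vector of peptides or a table with a
#'   `peptide` column
#' @param index [build_peptide_index()] of `db`
#' @param db the [protein_db()] the index was built from
#' @return character vector of gene IDs (sorted)
#' @export
identify_families <- function(evidence, index, db) {
  m <- match_evidence(evidence, index)
  accs <- unique(unlist(index$entries[m$matched]$accessions))
  sort(unique(db$gene_id[match(accs, db$accession)]))
}

#' Proteoforms identified with at least one unique peptide
#'
#' A proteoform is unambiguously identified when at least one matched
#' peptide maps to it and to no other proteoform in the database.
#'
#' @inheritParams identify_families
#' @return character vector of accessions (sorted)
#' @export
identify_unambiguous_proteoforms <- function(evidence, index, db) {
  m <- match_evidence(evidence, index)
  ent <- index$entries[m$matched]
  uniq <- ent[lengths(accessions) == 1L]
  sort(unique(as.character(unlist(uniq$accessions))))
}

#' Greedy parsimony proteoform groups
#'
#' Greedy set cover over the matched peptides: repeatedly select the
#' proteoform covering the most still-uncovered matched peptides (ties:
#' more proteoform-unique matched peptides, then lexicographic accession).
#' Proteoforms whose matched peptide set is a subset of a selected
#' representative's set become members of its group (first such group in
#' selection order); matched proteoforms subset of no representative are
#' left ungrouped.
#'
#' @inheritParams identify_families
#' @return data.table: representative, members (list), covered_peptides
#'   (list)
#' @export
parsimony_groups <- function(evidence, index, db) {
  m <- match_evidence(evidence, index)
  groups <- data.table(representative = character(0), members = list(),
                       covered_peptides = list())
  if (!length(m$matched)) return(groups)
  ent <- index$entries[m$matched]
  setkey(ent, peptide)
  pairs <- data.table(peptide = rep(ent$peptide, lengths(ent$accessions)),
                      accession = unlist(ent$accessions))
  pep_of <- split(pairs$peptide, pairs$accession)
  n_unique <- vapply(pep_of, function(p) {
    sum(lengths(ent[p]$accessions) == 1L)
  }, integer(1))
  accs <- sort(names(pep_of))     # lexicographic final tie-break
  uncovered <- ent$peptide
  reps <- character(0)
  while (length(uncovered)) {
    gain <- vapply(accs, function(a) sum(pep_of[[a]] %in% uncovered),
                   integer(1))
    best <- max(gain)
    cand <- accs[gain == best]
    if (length(cand) > 1L)
      cand <- cand[order(-n_unique[cand], cand)]
    pick <- cand[1]
    reps <- c(reps, pick)
    uncovered <- setdiff(uncovered, pep_of[[pick]])
    accs <- setdiff(accs, pick)
  }
  assigned <- character(0)
  out <- lapply(reps, function(r) {
    rset <- pep_of[[r]]
    cand <- setdiff(names(pep_of), c(reps, assigned))
    sub <- cand[vapply(cand, function(a) all(pep_of[[a]] %in% rset),
                       logical(1))]
    assigned <<- c(assigned, sub)
    data.table(representative = r, members = list(sort(c(r, sub))),
               covered_peptides = list(sort(rset)))
  })
  rbindlist(out)
}

#' Full identification analysis of a peptide evidence set
#'
#' @inheritParams identify_families
#' @return an `identification_result`: list with `matched_peptides`,
#'   `unmatched_peptides`, `identified_families`,
#'   `unambiguous_proteoforms`, `groups`, and `db_label`
#' @export
identify_proteoforms <- function(evidence, index, db) {
  m <- match_evidence(evidence, index)
  structure(list(
    matched_peptides = sort(m$matched),
    unmatched_peptides = sort(m$unmatched),
    identified_families = identify_families(evidence, index, db),
    unambiguous_proteoforms =
      identify_unambiguous_proteoforms(evidence, index, db),
    groups = parsimony_groups(evidence, index, db),
    db_label = db_label(db)), class = "identification_result")
}

#' @export
print.identification_result <- function(x, ...) {
  cat(sprintf(paste0("<identification vs '%s': %d matched / %d unmatched",
                     " peptides, %d families, %d unambiguous proteoforms,",
                     " %d groups>\n"),
              x$db_label, length(x$matched_peptides),
              length(x$unmatched_peptides), length(x$identified_families),
              length(x$unambiguous_proteoforms), nrow(x$groups)))
  invisible(x)
}

#' Write identification result tables
#'
#' Writes families.tsv, proteoforms.tsv, groups.tsv and unmatched.tsv into
#' a directory, plus result.json with the full result.
#'
#' @param result an `identification_result`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_identification_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(data.table(gene_id = result$identified_families),
            file.path(dir, "families.tsv"))
  write_tsv(data.table(accession = result$unambiguous_proteoforms),
            file.path(dir, "proteoforms.tsv"))
  g <- result$groups
  write_tsv(data.table(
    representative = g$representative,
    members = vapply(g$members, paste, character(1), collapse = ";"),
    covered_peptides = vapply(g$covered_peptides, paste, character(1),
                              collapse = ";")),
    file.path(dir, "groups.tsv"))
  write_tsv(data.table(peptide = result$unmatched_peptides),
            file.path(dir, "unmatched.tsv"))
  jsonlite::write_json(
    list(db_label = result$db_label,
         matched_peptides = result$matched_peptides,
         unmatched_peptides = result$unmatched_peptides,
         identified_families = result$identified_families,
         unambiguous_proteoforms = result$unambiguous_proteoforms,
         groups = lapply(seq_len(nrow(g)), function(i) list(
           representative = g$representative[i],
           members = g$members[[i]],
           covered_peptides = g$covered_peptides[[i]]))),
    file.path(dir, "result.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
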