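## Database and identification statistics: counts and proteoforms-per-
## family ratios, multi-set overlap (Venn/UpSet) tables, DEG filtering,
## and the DEG x long-read proteoform x curated-gene-list intersections.

#' Proteoforms-per-family presentation ratio
#'
#' Rounded half-up to one decimal, the convention used for headline
#' database statistics; `NA` when there are no families.
#'
#' @param n_proteoforms proteoform count
#' @param n_families family count
#' @return a number with one decimal, or NA
#' @export
proteoforms_per_family <- function(n_proteoforms, n_families) {
  if (n_families == 0) return(NA_real_)
  round_half_up(n_proteoforms / n_families, 1L)
}

#' Headline statistics of a proteoform database
#'
#' @param db a deduplicated [protein_db()]
#' @param n_transcripts transcript count of the source catalog (the
#'   database itself only retains coding, non-redundant entries)
#' @return one-row data.table: label, n_transcripts, n_proteoforms,
#'   n_families, proteoforms_per_family (1-decimal presentation) and
#'   proteoforms_per_family_raw (full precision)
#' @export
database_stats <- function(db, n_transcripts = NA_integer_) {
  assert_nonredundant(db, "reported")
  n_p <- nrow(db)
  n_f <- uniqueN(db$gene_id)
  data.table(label = db_label(db),
             n_transcripts = as.integer(n_transcripts),
             n_proteoforms = n_p, n_families = n_f,
             proteoforms_per_family = proteoforms_per_family(n_p, n_f),
             proteoforms_per_family_raw =
               if (n_f == 0) NA_real_ else n_p / n_f)
}

#' Exclusive-region overlap table of named sets
#'
#' For k labeled sets, counts every non-empty exclusive region (the cells
#' of a Venn diagram / bars of an UpSet plot).  Region counts sum to the
#' size of the union.
#'
#' @param named_sets named list of 2-4 character vectors
#' @return data.table: region (labels joined with `&`), degree, count,
#'   members (list)
#' @export
set_overlaps <- function(named_sets) {
  if (length(named_sets) < 2L || length(named_sets) > 4L)
    stopf("set_overlaps expects 2-4 named sets")
  if (is.null(names(named_sets)) || any(!nzchar(names(named_sets))))
    stopf("sets must be named")
  sets <- lapply(named_sets, unique)
  u <- unique(unlist(sets))
  mask <- vapply(sets, function(s) u %in% s, logical(length(u)))
  if (length(u) == 1L) mask <- matrix(mask, nrow = 1L,
                                      dimnames = list(NULL, names(sets)))
  region <- apply(mask, 1L, function(r)
    paste(names(sets)[r], collapse = "&"))
  spl <- split(u, region)
  out <- data.table(region = names(spl),
                    degree = vapply(strsplit(names(spl), "&", fixed = TRUE),
                                    length, integer(1)),
                    count = lengths(spl),
                    members = lapply(spl, sort))
  setorder(out, -degree, region)
  out[]
}

#' Overlap table of 2-4 proteoform databases
#'
#' Family mode compares gene IDs; proteoform mode compares protein
#' sequences, because accession spaces differ across database releases.
#'
#' @param dbs named list of [protein_db()] objects (names default to
#'   database labels)
#' @param mode `"families"` or `"proteoform_sequences"`
#' @return a [set_overlaps()] table
#' @export
db_overlaps <- function(dbs, mode = c("families", "proteoform_sequences")) {
  mode <- match.arg(mode)
  if (is.null(names(dbs)))
    names(dbs) <- vapply(dbs, db_label, character(1))
  sets <- lapply(dbs, function(d)
    if (mode == "families") unique(d$gene_id) else unique(d$protein_seq))
  set_overlaps(sets)
}

#' Read a DEG table (gene_id, log2fc, padj)
#'
#' @param path TSV path
#' @return data.table validated row by row
#' @export
read_deg <- function(path) {
  tab <- read_tsv(path)
  req <- c("gene_id", "log2fc", "padj")
  if (!all(req %in% names(tab)))
    stopf("DEG table must have columns gene_id, log2fc, padj: %s", path)
  validate_deg(tab)
  tab[]
}

validate_deg <- function(tab) {
  bad <- which(!is.finite(tab$log2fc) | !is.finite(tab$padj) |
                 tab$padj < 0 | tab$padj > 1)
  if (length(bad))
    stopf("malformed DEG row %d: log2fc must be finite and padj in [0,1]",
          bad[1])
  invisible(tab)
}

#' Filter differentially expressed genes
#'
#' Strict inequalities, as conventionally printed: |log2FC| > `lfc_cut`
#' AND adjusted p < `padj_cut`.
#'
#' @param table data.frame-like with gene_id, log2fc, padj
#' @param lfc_cut absolute log2 fold-change cut (default 1.5)
#' @param padj_cut adjusted p-value cut (default 0.05)
#' @return character vector of differential gene IDs
#' @export
filter_deg <- function(table, lfc_cut = 1.5, padj_cut = 0.05) {
  tab <- as.data.table(table)
  validate_deg(tab)
  tab[abs(log2fc) > lfc_cut & padj < padj_cut, as.character(gene_id)]
}

#' Read a one-column gene list (curated-list stand-in)
#'
#' @param path TSV path with a `gene_id` column
#' @return character vector of gene IDs
#' @export
read_gene_list <- function(path) {
  tab <- read_tsv(path)
  if (!"gene_id" %in% names(tab))
    stopf("gene list must have a gene_id column: %s", path)
  unique(as.character(tab$gene_id))
}

#' Tiered DEG x long-read proteoform x curated-list intersection
#'
#' Tier 1: DEG genes for which at least one unambiguously identified
#' proteoform carries a long-read source label.  Tier 2: the subset of
#' those proteoforms novel to the long-read sources (all source labels
#' within `long_read_sources`, i.e. absent from the base catalog).
#' Tier 3: tier-2 genes that are also in the curated gene list.  The
#' complementary view (`curated_novel_proteoforms`) lists identified
#' novel long-read proteoforms whose gene is curated regardless of DEG
#' status.
#'
#' @param deg_genes character vector of differential gene IDs
#' @param result an `identification_result` against `db`
#' @param db the searched [protein_db()]
#' @param long_read_sources source labels counting as long-read evidence
#' @param curated_genes curated gene list (character vector)
#' @return list with tier1_genes, tier2_proteoforms, tier2_genes,
#'   tier3_genes, curated_novel_proteoforms, and a `counts` vector
#' @export
intersect_deg_proteoforms <- function(deg_genes, result, db,
                                      long_read_sources, curated_genes) {
  idx <- match(result$unambiguous_proteoforms, db$accession)
  ident <- data.table(accession = result$unambiguous_proteoforms,
                      gene_id = db$gene_id[idx],
                      sources = db$sources[idx])
  ident[, long_read := vapply(sources, function(s)
    length(intersect(s, long_read_sources)) > 0L, logical(1))]
  ident[, novel := vapply(sources, function(s)
    all(s %in% long_read_sources), logical(1))]
  tier1 <- ident[long_read == TRUE & gene_id %in% deg_genes]
  tier1_genes <- sort(unique(tier1$gene_id))
  tier2 <- tier1[novel == TRUE]
  tier2_genes <- sort(unique(tier2$gene_id))
  tier3_genes <- sort(intersect(tier2_genes, curated_genes))
  complement <- ident[novel == TRUE & gene_id %in% curated_genes]
  list(tier1_genes = tier1_genes,
       tier2_proteoforms = sort(tier2$accession),
       tier2_genes = tier2_genes,
       tier3_genes = tier3_genes,
       curated_novel_proteoforms = sort(complement$accession),
       counts = c(tier1 = length(tier1_genes),
                  tier2 = length(unique(tier2$accession)),
                  tier3 = length(tier3_genes),
                  curated_novel = length(unique(complement$accession))))
}
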