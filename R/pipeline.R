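## End-to-end orchestration: translate both catalogs -> dedup -> merge ->
## index per database -> identify per database -> uniqueness drift ->
## stats / overlaps -> DEG intersection.  Every intermediate is persisted;
## results go to files, logs to stderr, so runs compose in shell pipelines.

#' Assemble a pipeline run configuration
#'
#' @param genome_fasta genome FASTA path
#' @param gtf transcript annotation (GTF) covering both catalogs
#' @param catalogs_tsv TSV with columns transcript_id, catalog; catalog
#'   values must match `labels`
#' @param evidence_tsv peptide evidence TSV (column `peptide`)
#' @param out_dir output directory
#' @param labels catalog labels, base (precedence) first
#' @param deg_tsv optional DEG table (gene_id, log2fc, padj)
#' @param curated_tsv optional one-column curated gene list
#' @param translation [translation_params()]
#' @param digestion [digest_params()]
#' @param lfc_cut,padj_cut DEG thresholds (strict inequalities)
#' @return a `run_config` list
#' @export
run_config <- function(genome_fasta, gtf, catalogs_tsv, evidence_tsv,
                       out_dir, labels = c("base", "addition"),
                       deg_tsv = NULL, curated_tsv = NULL,
                       translation = translation_params(),
                       digestion = digest_params(),
                       lfc_cut = 1.5, padj_cut = 0.05) {
  if (length(labels) != 2L)
    stopf("labels must give exactly two catalog labels, base first")
  structure(list(genome_fasta = genome_fasta, gtf = gtf,
                 catalogs_tsv = catalogs_tsv, evidence_tsv = evidence_tsv,
                 out_dir = out_dir, labels = labels, deg_tsv = deg_tsv,
                 curated_tsv = curated_tsv, translation = translation,
                 digestion = digestion, lfc_cut = lfc_cut,
                 padj_cut = padj_cut),
            class = "run_config")
}

#' Read a pipeline run configuration from JSON
#'
#' Recognised keys mirror the arguments of [run_config()]; parameter
#' blocks `translation` and `digestion` are nested objects.
#'
#' @param path JSON file
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- do.call(translation_params, as.list(j$translation %||% list()))
  dg <- do.call(digest_params, as.list(j$digestion %||% list()))
  run_config(genome_fasta = j$genome_fasta, gtf = j$gtf,
             catalogs_tsv = j$catalogs_tsv, evidence_tsv = j$evidence_tsv,
             out_dir = j$out_dir,
             labels = j$labels %||% c("base", "addition"),
             deg_tsv = j$deg_tsv, curated_tsv = j$curated_tsv,
             translation = tr, digestion = dg,
             lfc_cut = j$lfc_cut %||% 1.5, padj_cut = j$padj_cut %||% 0.05)
}

log_msg <- function(...) message("[proteodrift] ", sprintf(...))

#' Run the full pipeline
#'
#' Stages, in fixed order: read inputs; translate base and addition
#' catalogs; remove redundancy within each; merge with base-accession
#' precedence; build peptide indexes for base and merged databases;
#' identify against both; compute uniqueness drift base -> merged;
#' database statistics and overlaps; optional DEG filtering and tiered
#' intersection.  All intermediates are written under `cfg$out_dir`; a
#' machine-readable run report (JSON + returned list) summarises counts.
#' Re-running on identical inputs reproduces identical outputs.
#'
#' @param cfg a [run_config()]
#' @return the run report, invisibly
#' @export
run_pipeline <- function(cfg) {
  for (f in c("genome_fasta", "gtf", "catalogs_tsv", "evidence_tsv")) {
    if (!file.exists(cfg[[f]]))
      stopf("run aborted before any stage: missing %s file %s", f, cfg[[f]])
  }
  for (f in c("deg_tsv", "curated_tsv")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stopf("run aborted before any stage: missing %s file %s", f, cfg[[f]])
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    log_msg("stage %s", name)
    tryCatch(expr, error = function(e)
      stopf("stage %s failed: %s", name, conditionMessage(e)))
  }
  genome <- stage("read_genome", read_fasta(cfg$genome_fasta))
  catalog <- stage("read_gtf", read_gtf(cfg$gtf))
  memb <- stage("read_catalogs", read_tsv(cfg$catalogs_tsv))
  if (!all(c("transcript_id", "catalog") %in% names(memb)))
    stopf("catalogs TSV needs columns transcript_id, catalog")
  bad <- setdiff(unique(memb$catalog), cfg$labels)
  if (length(bad))
    stopf("catalog label \"%s\" not declared in run config", bad[1])
  evidence <- stage("read_evidence", read_peptide_evidence(cfg$evidence_tsv))

  sub_catalog <- function(lbl) {
    ids <- memb[catalog == lbl, transcript_id]
    cc <- as.data.table(catalog)[transcript_id %in% ids]
    cc[, source := lbl]
    transcript_catalog(cc, lbl)
  }
  dbs_raw <- lapply(cfg$labels, function(lbl)
    stage(paste0("translate_", lbl),
          translate_catalog(genome, sub_catalog(lbl), cfg$translation, lbl)))
  names(dbs_raw) <- cfg$labels
  dedup <- lapply(cfg$labels, function(lbl) {
    d <- stage(paste0("dedup_", lbl), remove_redundant(dbs_raw[[lbl]]))
    write_protein_fasta(d$db, file.path(cfg$out_dir,
                                        paste0(lbl, ".nr.fa")))
    write_tsv(data.table(removed = names(d$collapse_map),
                         kept = unname(d$collapse_map)),
              file.path(cfg$out_dir, paste0(lbl, ".collapse.tsv")))
    write_tsv(translation_features(dbs_raw[[lbl]]),
              file.path(cfg$out_dir, paste0(lbl, ".features.tsv")))
    d$db
  })
  names(dedup) <- cfg$labels
  base_db <- dedup[[1]]; add_db <- dedup[[2]]
  merged <- stage("merge", merge_databases(base_db, add_db))
  write_protein_fasta(merged, file.path(cfg$out_dir, "merged.nr.fa"))
  write_tsv(merge_report(merged, base_db),
            file.path(cfg$out_dir, "merge_report.tsv"))

  searched <- list(base_db, merged)
  names(searched) <- c(db_label(base_db), db_label(merged))
  indexes <- lapply(names(searched), function(lbl) {
    idx <- stage(paste0("index_", lbl),
                 build_peptide_index(searched[[lbl]], cfg$digestion))
    write_peptide_index_tsv(idx, searched[[lbl]],
                            file.path(cfg$out_dir,
                                      paste0("index_", lbl, ".tsv")))
    idx
  })
  names(indexes) <- names(searched)
  results <- lapply(names(searched), function(lbl) {
    r <- stage(paste0("identify_", lbl),
               identify_proteoforms(evidence, indexes[[lbl]],
                                    searched[[lbl]]))
    write_identification_result(r, file.path(cfg$out_dir,
                                             paste0("identify_", lbl)))
    r
  })
  names(results) <- names(searched)

  drift <- stage("drift", uniqueness_drift(indexes[[1]], indexes[[2]]))
  drift_out <- data.table(peptide = drift$peptide,
                          former_unique_to = drift$former_unique_to,
                          sharers_in_b = vapply(drift$sharers_in_b, paste,
                                                character(1),
                                                collapse = ";"),
                          status = drift$status)
  write_tsv(drift_out, file.path(cfg$out_dir, "drift.tsv"))

  n_tx <- vapply(cfg$labels, function(lbl)
    length(unique(memb[catalog == lbl, transcript_id])), integer(1))
  stats <- rbind(database_stats(base_db, n_tx[1]),
                 database_stats(add_db, n_tx[2]),
                 database_stats(merged, length(unique(memb$transcript_id))))
  write_tsv(stats, file.path(cfg$out_dir, "stats.tsv"))
  overlaps <- db_overlaps(list(base_db, merged),
                          mode = "proteoform_sequences")
  write_tsv(overlaps[, .(region, degree, count)],
            file.path(cfg$out_dir, "overlaps.tsv"))

  tiers <- NULL
  if (!is.null(cfg$deg_tsv)) {
    deg_genes <- stage("filter_deg",
                       filter_deg(read_deg(cfg$deg_tsv), cfg$lfc_cut,
                                  cfg$padj_cut))
    curated <- if (!is.null(cfg$curated_tsv))
      read_gene_list(cfg$curated_tsv) else character(0)
    tiers <- stage("intersect",
                   intersect_deg_proteoforms(
                     deg_genes, results[[2]], merged,
                     long_read_sources = cfg$labels[2],
                     curated_genes = curated))
    write_tsv(data.table(tier = names(tiers$counts),
                         count = as.integer(tiers$counts)),
              file.path(cfg$out_dir, "tiers.tsv"))
  }

  report <- list(
    labels = cfg$labels,
    params = list(translation = unclass(cfg$translation),
                  digestion = unclass(cfg$digestion),
                  lfc_cut = cfg$lfc_cut, padj_cut = cfg$padj_cut),
    n_transcripts = as.list(stats$n_transcripts),
    n_proteoforms = as.list(stats$n_proteoforms),
    n_families = as.list(stats$n_families),
    merged_size_identity =
      nrow(merged) == nrow(base_db) + nrow(novel_entries(add_db, base_db)),
    identification = lapply(results, function(r) list(
      matched = length(r$matched_peptides),
      unmatched = length(r$unmatched_peptides),
      families = length(r$identified_families),
      unambiguous = length(r$unambiguous_proteoforms),
      groups = nrow(r$groups))),
    drift = as.list(table(drift$status)),
    tiers = if (!is.null(tiers)) as.list(tiers$counts),
    files = list.files(cfg$out_dir, recursive = TRUE))
  jsonlite::write_json(report, file.path(cfg$out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_msg("run complete: %d files in %s", length(report$files), cfg$out_dir)
  invisible(report)
}
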