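# Independent oracles used to freeze expected values and for
# property-style equivalence tests.  These deliberately use different
# algorithms from the package implementations.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

revcomp_vec <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1))
}

# Brute-force tryptic digestion: enumerate all cleavage-compliant
# boundary pairs and count internal sites, rather than joining
# consecutive fragments.
oracle_digest <- function(seq, missed = 0, min_len = 1, max_len = 10000) {
  aa <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(aa)
  sites <- which(aa %in% c("K", "R"))
  sites <- sites[sites == n | aa[pmin(sites + 1L, n)] != "P"]
  starts <- unique(c(1L, sites + 1L))
  starts <- starts[starts <= n]
  ends <- unique(c(sites, n))
  out <- character(0)
  for (i in starts) {
    for (j in ends) {
      if (j < i) next
      len <- j - i + 1L
      if (len < min_len || len > max_len) next
      internal <- sum(sites >= i & sites < j)
      if (internal <= missed) out <- c(out, substr(seq, i, j))
    }
  }
  unique(out)
}

# Exhaustive ATG scan: every ATG, walk codons to the first stop.
oracle_orf <- function(seq, min_aa = 1) {
  n <- nchar(seq)
  best <- NULL
  m <- gregexpr("ATG", seq, fixed = TRUE)[[1]]
  if (m[1] == -1L) return(NULL)
  for (p in as.integer(m) - 1L) {
    q <- p + 3L
    stop_at <- NA_integer_
    while (q + 3L <= n) {
      if (substr(seq, q + 1L, q + 3L) %in% c("TAA", "TAG", "TGA")) {
        stop_at <- q
        break
      }
      q <- q + 3L
    }
    if (!is.na(stop_at)) {
      naa <- (stop_at - p) %/% 3L
      if (naa >= min_aa && (is.null(best) || naa > best$naa))
        best <- list(cds_start = p, cds_end = stop_at + 3L, naa = naa)
    }
  }
  best
}

# Exhaustive minimum set cover size (<= 12 sets).
oracle_min_cover_size <- function(sets, universe) {
  accs <- names(sets)
  for (k in seq_along(accs)) {
    for (cmb in utils::combn(accs, k, simplify = FALSE)) {
      if (all(universe %in% unlist(sets[cmb]))) return(k)
    }
  }
  NA_integer_
}

# Brute-force peptide -> accession index via per-protein oracle digestion.
oracle_index <- function(db, missed = 0, min_len = 1, max_len = 10000,
                         equate_il = FALSE) {
  env <- new.env()
  for (i in seq_len(nrow(db))) {
    peps <- oracle_digest(db$protein_seq[i], missed, min_len, max_len)
    if (equate_il) peps <- chartr("I", "L", peps)
    for (p in unique(peps)) {
      env[[p]] <- c(if (!is.null(env[[p]])) env[[p]], db$accession[i])
    }
  }
  out <- as.list(env)
  lapply(out, unique)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small hand-built database for example-level tests.
toy_db <- function(acc, seq, gene = NULL, src = "base", label = "db") {
  protein_db(data.table::data.table(
    accession = acc, gene_id = gene %||% paste0("g_", acc),
    protein_seq = seq,
    sources = as.list(rep(src, length.out = length(acc))),
    transcript_ids = as.list(acc),
    is_ptc = FALSE), label)
}

# Random toy proteoform database; a fraction of entries duplicate an
# earlier sequence so redundancy removal has work to do.
random_db <- function(n, label = "db", dup_frac = 0.3, prefix = "P",
                      len_range = c(20L, 60L)) {
  seqs <- character(n)
  for (i in seq_len(n)) {
    seqs[i] <- if (i > 1 && runif(1) < dup_frac) {
      seqs[[sample.int(i - 1L, 1L)]]
    } else random_protein(sample(seq(len_range[1], len_range[2]), 1L))
  }
  protein_db(data.table::data.table(
    accession = sprintf("%s%03d", prefix, seq_len(n)),
    gene_id = sprintf("G%02d", sample.int(max(1L, n %/% 2L), n,
                                          replace = TRUE)),
    protein_seq = seqs), label)
}
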