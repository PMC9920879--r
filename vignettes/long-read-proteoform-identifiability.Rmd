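---
title: "Long-read proteogenomic databases and proteoform identifiability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Long-read proteogenomic databases and proteoform identifiability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Bottom-up proteomics identifies proteins by matching acquired spectra
against theoretical spectra derived from in silico digestion of a protein
database: a proteoform absent from the database is unidentifiable, so
richer transcript catalogs — in particular long-read isoform sequencing
(PacBio Iso-Seq, Oxford Nanopore direct RNA sequencing) — promise better
proteoform coverage. But database growth has a countervailing cost.  A
proteoform is *unambiguously identified* only when at least one observed
peptide maps to it and to no other database entry.  Adding isoforms of the
same gene floods the database with near-identical sequences that share
tryptic peptides; peptides that used to be unique lose that status, and
formerly identifiable proteoforms silently drop out.  This package
implements the full workflow in which that trade-off arises — building
proteoform databases from transcript models, merging catalogs, digesting,
and re-identifying — together with the *uniqueness drift* analysis that
makes the mechanism explicit, and a seeded synthetic world in which every
step can be checked against ground truth.

## From transcript models to proteoforms

A transcript model is an exon chain on a genome (internally 0-based
half-open; GTF I/O converts from/to the standard 1-based inclusive
convention; storage is strand-agnostic and genomically sorted).
`spliced_sequence()` concatenates exon substrings and reverse-complements
minus-strand models, yielding the mature transcript 5'→3'.

**ORF selection.** `find_orf()` considers every ORF that starts at an ATG
and ends at the first in-frame stop downstream, discards ORFs shorter
than `min_orf_aa` (default 30 aa, a conventional filter) or lacking an
in-frame stop (run-off ORFs cannot be assigned stop-dependent features,
so they are treated as non-coding), and keeps the longest protein,
breaking ties toward the 5'-most start.  The translation tool the
original workflow used performs gene-level start selection on top of
per-transcript translation; its exact rules are not published, so this
package states its own: `harmonize_gene_starts()` takes the plurality of
start-codon genomic positions across a gene's coding isoforms (ties
resolved 5'-most on the coding strand) and re-annotates any isoform whose
exon chain contains that position, provided the position initiates an ATG
with a viable in-frame stop in that isoform's spliced sequence.  Isoforms
that cannot accommodate the gene-level start keep their own ORF.  Codons
containing N translate to X.

**PTC / NMD features.** `classify_nmd()` applies the canonical 50-nt
rule: a stop whose last base lies at least `ptc_junction_nt` (default
50) nucleotides upstream of the last exon–exon junction, in transcript
coordinates, is a premature termination codon; single-exon transcripts
can never carry one.  A 3'UTR longer than `long_utr3_nt` (default
350 nt) flags the long-3'UTR feature; either feature marks the transcript
as a nonsense-mediated-decay candidate.  Both thresholds are field
conventions, not values fitted to data, and both are configurable.

## Redundancy and hybrid merging

Isoforms that differ only in their UTRs translate to identical proteins,
so databases are collapsed to exact full-length sequence identity
(`remove_redundant()`); no substring or near-identity clustering is
attempted, matching the semantics of the rmdup-style tools used for this
purpose.  The first entry in database order survives and absorbs the
collapsed entries' transcript IDs and source labels.

`merge_databases(base, addition)` appends to the base only those addition
entries whose sequence the base lacks.  For sequences present in both,
the base accession (and gene assignment) wins and the addition's
provenance is folded in — encoding the precedence convention by which a
hybrid database keeps the reference catalog's accessions.  The accounting
identity `|merge(A,B)| = |A| + |novel(B,A)|` is tested property-style and
re-verified at run time by the pipeline.  Gene-assignment conflicts
between releases for an identical sequence are resolved in favour of the
base and logged on the result (`attr(, "gene_conflicts")`).

## Digestion, uniqueness, drift

`digest()` implements the classical tryptic rule — cleave C-terminal to
K or R except before P — with up to `missed_cleavages` (default 2)
internal uncut sites and a 7–50 residue length window, mirroring common
search-engine defaults; the originating study only states that default
search settings were used, so these are documented as conventions.
`equate_il` optionally canonicalizes I→L in peptide keys: the isobaric
pair is indistinguishable by mass spectrometry, and the choice changes
uniqueness counts materially; it defaults to off because search engines
report I/L-resolved sequences.

`build_peptide_index()` inverts digestion over a database;
`classify_uniqueness()` labels each peptide `proteoform_unique`
(one accession), `family_unique` (several accessions, one gene) or
`shared`.  `uniqueness_drift(index_A, index_B)` then reports, for every
peptide proteoform-unique in A, whether it is `retained`, `lost` (with
the sharer set in B) or `absent` in B.  Growing a database can only
shrink a fixed proteoform's unique-peptide count — the monotonicity that
drives identification losses — and this is tested over random growth
steps as well as on a constructed inflated-family fixture.

## Identification and parsimony

Evidence is a post-FDR peptide list; the package does no rescoring.
Peptides that fail to match the database are reported, never an error —
cross-database non-identification is itself a finding.  Identified
protein families are the union of genes hit by matched peptides;
unambiguous proteoforms are those with at least one matched
proteoform-unique peptide.  `parsimony_groups()` performs greedy set
cover (Occam's razor) over matched peptides: repeatedly select the
proteoform covering the most uncovered peptides, breaking ties by more
unique peptides, then lexicographic accession, so output is fully
deterministic.  Proteoforms whose matched peptides are a subset of a
representative's join its group; matched proteoforms subsumed by no
single representative stay ungrouped.  Abundance-aware inference is out
of scope.

## Reporting

`database_stats()` reports proteoform and family counts and the
proteoforms-per-family ratio, rounded half-up to one decimal for
presentation (the raw ratio is retained).  `set_overlaps()` /
`db_overlaps()` produce exclusive-region tables (Venn/UpSet input);
proteoform overlaps compare sequences, not accessions, because accession
spaces differ across database releases.  `filter_deg()` applies strict
cuts |log2FC| > 1.5 and adjusted p < 0.05, exactly as conventionally
printed.  `intersect_deg_proteoforms()` builds the tiered report:
differential genes with long-read-supported identified proteoforms
(tier 1), the subset novel to the long-read source (tier 2), those also
on a curated gene list (tier 3), plus the complementary list of curated
novel proteoforms regardless of differential status.

## The synthetic world

`simulate_bundle()` generates, from one master seed (each sub-generator
derives an independent stream, so adding a generator perturbs nothing
else), every input the pipeline consumes.  Design choices:

* **Codon-level construction.** All filler sequence — UTRs, introns,
  CDS interiors — is drawn from {C,G,T} only.  Since ATG and all three
  stop codons contain an A, the only start codon in any transcript is the
  engineered one and the only stops are the engineered ones, in every
  frame.  ORF and PTC ground truth is therefore exact by construction,
  not approximated.  TAG is used for every engineered stop: adjacent to
  A-free sequence it is the one stop codon that cannot seed a spurious
  ATG.
* **Gene anatomy.** 4–6 exons; 5'UTRs of 20–50 nt; first-exon CDS of
  120–180 nt so that premature stops can sit both 30 codons into the
  protein and 50 nt upstream of the last junction; middle exons with
  codon-aligned lengths so skipping and 3n splice-site shifts preserve
  frame; 3'UTRs of 60–150 nt with a 60-nt extension region for UTR-only
  variants.  Genes alternate chromosomes and strands.
* **Events.** Variants draw from exon skipping, intron retention,
  alternative donor/acceptor shifts and UTR-only 3' changes (default mix
  0.25/0.20/0.15/0.15/0.25).  UTR-only variants are protein-identical to
  their primary by construction.  A TAG is planted in frame at offset 15
  of every first intron; premature-stop transcripts arise either by
  retaining that intron or, for the engineered `ptc_fraction` (default
  0.2) of non-UTR variants, by an 18-nt donor extension of exon 1 that
  captures the planted stop.  Recorded PTC truth is computed by explicit
  junction arithmetic, independent of the package's classifier.
* **Catalogs.** The base catalog holds every primary isoform plus about
  half the variants; the addition shares `catalog_overlap` (default 0.7)
  of the base and contributes `novel_fraction` (default 0.5) of the
  remaining transcripts, so merging exercises both duplicate-collapse and
  novel-append paths.
* **Evidence.** Up to `peptides_per_proteoform` digest peptides per
  proteoform, each detected with `detect_prob` (defaults 5 and 0.8; the
  truth-recovery tests use exhaustive sampling with perfect detection,
  where the identifiable set is exactly computable).  Noise peptides are
  rejection-sampled against the full database digest, so they are
  guaranteed unmatched.  When comparing identification across databases
  of different sizes, evidence should be sampled from a proteome
  contained in every compared database (e.g. the primary proteoforms):
  with the detectable proteome fixed, growing the database provably
  never decreases identified families and never increases unambiguous
  proteoforms — the trade-off of interest — whereas evidence from
  proteins missing from the smaller database conflates that effect with
  plain database incompleteness.
* **DEG table.** A `frac_differential` share of genes receives
  |log2FC| > 1.5 and adjusted p < 0.05; every other gene is constructed
  to fail at least one cut, so threshold filtering recovers the truth set
  exactly.

What a green synthetic test does **not** establish: the generator makes
no attempt to model sequencing error, incomplete splicing, expression
levels, spectral quality, FDR behaviour of real search engines, or
homology between genes (protein sequences of different genes are
essentially never identical).  Synthetic results validate the algebra and
the algorithms, not instrument- or search-engine-level behaviour.

## Numerical and degenerate-input choices

* Presentation ratios round half away from zero (half-up) to one decimal;
  raw ratios are retained in machine output.  The ratio is NA for an
  empty family set.
* All tie-breaks (ORF start, greedy cover, group membership) are total
  orders, so every result is deterministic for fixed input.
* Degenerate inputs translate to empty results rather than errors where
  the contract allows it: empty catalogs give empty databases, empty
  evidence gives empty identification sets; contract violations
  (non-deduplicated inputs to merge, mismatched digestion parameters in
  drift, classification of non-coding ORFs) raise immediately.
* Seeds derived from the master seed stay below 2^31.

## Known limitations

* Redundancy removal is exact-identity only; near-identical proteoforms
  (the release-to-release sequence refinements that real catalogs show)
  are deliberately left distinct.
* The start-harmonization rule is this package's stated stand-in for an
  unpublished algorithm; results can differ from the original tool's
  output at genes where isoform-specific starts dominate.
* Parsimony grouping approximates minimum set cover greedily; it is
  validated against the exhaustive optimum only on small instances and
  makes no claim of matching any specific search suite's inference.
* Peptide keys are unmodified sequences: modified peptides, semi-tryptic
  search spaces and decoy generation are out of scope.
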