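---
title: "Frameshift neoantigen discovery from coding microsatellites: methods"
author: "msneoforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frameshift neoantigen discovery from coding microsatellites: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msneoforge)
```

## Background and model

Mismatch-repair–deficient tumors accumulate insertions and deletions in
microsatellites — tandem repeats of 1–5 bp motifs. When such an indel falls
in a coding sequence and its size is not divisible by three, the downstream
reading frame shifts and the ribosome produces a protein tail that is absent
from the normal proteome: a frameshift neoantigen. Two facts make this
tractable at catalog scale:

1. **Frame-class collapse.** Two indels at the same tract whose net length
   changes are congruent modulo 3 place the downstream sequence in the same
   frame, and (because the content 3' of the tract is untouched) produce an
   identical downstream protein. The entire indel spectrum at one tract
   therefore collapses onto two classes — net shift ≡ 1 and ≡ 2 (mod 3) —
   which this package represents by one canonical deletion each: 2 bp
   (class 1, the "3n+1" series) and 1 bp (class 2, the "3n+2" series).
2. **Junction exclusion.** The amino acids spanning the wild-type/mutant
   boundary *inside* the tract do depend on the particular indel (size and
   position), not only on its class. The pipeline therefore discards the
   junction region and keeps only the peptide starting at the first mutant
   codon lying entirely 3' of the tract.

The pipeline: scan the genome for maximal microsatellite tracts; keep those
overlapping annotated CDS; emit the two canonical deletions per
(locus, transcript); translate the mutant transcript and record the
junction-excluded downstream peptide; deduplicate peptides by sequence;
enumerate fixed-length epitope windows; score windows against MHC allele
panels through a pluggable predictor contract; keep (epitope, allele) pairs
whose best IC50 over algorithms is below 50 nM; annotate with terminal
residues, GRAVY, evidence tables and differential-expression labels; persist
everything in a single-file store answering `search` and `best` queries.

## Microsatellite detection

`scan_sequence()` reports every **maximal** tract of a **primitive** motif
(one that is not itself a repetition of a shorter word) of length 1–5,
counting **whole units only**: a trailing partial unit is excluded from the
span. Defaults require more than five units for homopolymers
(`min_units["1"] == 6`) and at least three units for 2–5 bp motifs; all five
minima are configurable because repeat-catalog dialects differ (some count
homopolymers from five). Tracts containing N are never reported.

Determinism and tie-breaks: scanning is left-to-right per motif length; a
tract is anchored at its leftmost attainable start, and scanning for that
motif length resumes at the first base after an emitted tract, so
same-motif-length tracts never overlap. One practical consequence of
whole-unit trimming is that strand symmetry holds at the level of maximal
repeat *regions*, not trimmed spans: `ACACACA` scans to span 1–6 forward, and
its reverse complement's span mirrors to 2–7. The tests assert this
region-level covariance (counts, unit counts, and mirrored spans overlapping
by all but the partial-unit leftover).

A second, deliberately naive implementation (`scan_sequence_ref()`) walks
every start position and counts units by direct string comparison; the test
suite and the acceptance script require exact agreement between the two on
randomized sequences.

## Canonical variants and translation

For each (locus, transcript) pair whose in-CDS tract portion is at least
3 bases, `frameshift_variants()` deletes the last 1 and last 2 bases of the
tract in coding orientation. Position within the tract is irrelevant for the
peptide — that is exactly the frame-class property, and it is enforced by a
property test that applies every deletion and insertion of size 1–7 at every
in-tract position and demands the canonical peptide (or the wild-type
downstream peptide when the size is a multiple of 3). Insertions in that test
have *random* content: junction exclusion makes the downstream peptide
independent even of what was inserted.

VCF emission is independent of peptide generation: each deletion is
left-aligned against the plus strand of the genome (shift left while the base
preceding the deleted segment equals its last base) and written as an
anchored VCF 4.2 deletion record. A deletion whose bases straddle a splice
junction has no single-interval genomic representation; such variants keep
their peptides but are omitted from the VCF with a warning.

Translation (`translate_nt()`) uses the standard genetic code, proceeds codon
by codon from position 1, halts at the first stop, and ignores 1–2 trailing
bases. Mid-ORF semantics apply throughout: the first codon of a downstream
tail is never treated as an initiation codon (no TTG/CTG → M). Transcript
sequences are CDS plus any annotated 3' UTR, because frameshifts routinely
read through the annotated stop; a peptide whose translation reaches the
transcript end without a stop is kept and flagged `non_stop`.

**Junction stop codons.** `downstream_peptide()` starts translating *at* the
first fully post-tract codon; codons overlapping the tract are excluded
entirely and in particular are not scanned for stop codons. This is a
deliberate design choice: junction content varies with the specific indel
(a mono-T tract followed by `AA` yields a junction `TAA` after the 2-bp
deletion but not after a 1-bp insertion of the same class), so honoring
junction stops would make the catalog depend on which representative indel
was chosen — the opposite of what the two-deletion representation is for. A
variant whose *first post-tract codon* is itself a stop yields no record.

## Epitope enumeration, scoring and filtering

Window lengths default to 8–11 residues for MHC class I and 15 for class II,
the common lengths for the respective binding grooves; both are
configurable. The shipped allele panels contain 27 class I and 27 class II
high-population-frequency alleles (class II heterodimers written as
alpha/beta pairs joined by `-`); panels are plain-text, one allele per line.

Binding prediction is a plug-in contract: a predictor declares its supported
MHC classes and epitope lengths and returns one IC50 (nM, positive, finite)
per supported (epitope, allele) pair. Pairs a predictor does not support are
*missing*, never zero, and are excluded from aggregates rather than imputed.
The built-in `toy_predictor()` is a deterministic stand-in for desk-scale
runs: it hashes `epitope|allele|algorithm` (two independent 32-bit FNV-1a
passes) and maps the result log-uniformly onto [1, 50000] nM. Distinct
algorithm names give independent score surfaces, so aggregating over several
toy instances exercises the same code paths as a real multi-algorithm run.
Adapters that shell out to external predictors can be registered through the
same contract but are no part of the test surface.

The inclusion rule is *best-affinity*: a pair is retained when the minimum
IC50 over algorithms is below the threshold (default 50 nM). Best, median
and mean over the observed scores are stored per pair, so summaries using a
median cutoff (e.g. median < 500 nM, or the `best` query's median < 30 nM)
can be produced from the same store. Candidates are annotated with terminal
residues and the GRAVY score (arithmetic mean of Kyte–Doolittle hydropathy).

## Annotation and queries

Evidence joins are left joins keyed by normalized variant
(`chrom:pos:ref:alt`, aligned identically to the emitted VCF), exact peptide
string, or gene symbol; multiple matches concatenate deterministically
(sorted by source, key, payload). Differential expression between two sample
groups uses a two-sided Wilcoxon rank-sum test per gene with
Benjamini–Hochberg adjustment and an adjusted-p threshold of 0.05;
zero-variance genes are untested and unflagged. The rank-sum default is a
robustness choice — the upstream description fixes only the BH correction,
not the test. The top-expression filter ranks genes by mean (configurably
median) expression within a cohort and keeps the top fraction
(default 20%), retaining all ties at the cutoff value.

The store is a single file holding sorted relational tables (candidates,
peptides, variants, evidence, expression, samples); rebuilding from the same
inputs reproduces identical logical content. `neo_search()` combines all set
filters conjunctively and orders results by gene, epitope, allele;
`neo_best()` returns per-allele blocks under a statistic cutoff
(median by default, mirroring the worked query style), ranked ascending,
optionally intersected with the top-expression filter. Ascending-by-statistic
ranking and offset/limit pagination are this package's choices; nothing
upstream constrains them.

## Synthetic fixtures and what the tests do (and do not) show

`make_genome()` builds a small genome whose ground truth is exact: genes with
1–3 exons and a 3' UTR on both strands, planted coding, intronic and
intergenic tracts, and a background *purged* of accidental qualifying tracts
by targeted point mutations until a full scan reports exactly the planted
loci. Tract flanks are chosen so no planted tract can be extended by a whole
unit. The truth table lists, per planted coding tract and canonical deletion,
the expected downstream peptide computed by an independent literal
edit-and-translate oracle (`downstream_peptide_ref()`, which translates via
Biostrings rather than the package's own codon table). A random draw can be
infeasible — the frameshifted tail may stop at its very first post-junction
codon — and is then resampled from a derived sub-seed, so a given seed always
produces the same files. The small preset uses 2 chromosomes (~2.5 kb total),
6 genes, 6 coding + 2 intronic + 2 intergenic tracts; the expression design
is 50 genes × (20 normal + 20 tumor) samples, log-normal noise
(sdlog = 0.5), with 5 genes shifted 4-fold in tumor — an effect size at which
rank-sum recovery is essentially certain, chosen so fixture tests assert
recovery rather than power.

These fixtures validate *mechanics*, not biology: real genomes have
interrupted repeats, overlapping gene models, alternative biotypes and
chromosome-scale size, and real binding predictors have structured error the
toy hash does not emulate. Passing tests show the bookkeeping — coordinates,
strands, splicing, frames, dedup, filtering, joins, store round trips — is
exact at desk scale; they say nothing about predictor accuracy or about
genome-scale catalog counts.

## Numerical and degenerate-input choices

- Coordinates are 1-based fully closed internally; BED export is 0-based
  half-open.
- The annotated CDS is taken as-is (stop codon included in the fixture
  dialect); transcripts with CDS length not divisible by 3 are kept and
  flagged.
- CDS containing N is flagged untranslated and skipped with a warning;
  windows and tracts containing N are never produced.
- Deleting from a tract requires at least 3 in-CDS tract bases (a 2-bp
  deletion must leave one tract base); shorter overlaps are skipped with a
  warning.
- `bh_adjust()` validates inputs and delegates to `stats::p.adjust`;
  `label_de_genes()` uses the normal approximation (`exact = FALSE`) since
  expression values are continuous.
- Problem sizes in tests and the acceptance script (1000 random 300-mers for
  scanner equivalence, 200 random tracts × every indel of size 1–7 for the
  frame-class property, ≥10,000 scored pairs for filter semantics, 20 × 200
  genes for the BH null) are the package's chosen verification scale.

## Known limitations

- Only perfect (uninterrupted) repeats of motif length ≤ 5 are detected.
- Epitopes spanning the junction are excluded by design; users wanting them
  must model specific indels, not frame classes.
- The two-deletion representation cannot carry indel-specific population
  frequencies; evidence joins attach to the canonical keys only.
- The store is single-writer and loads tables into memory; it replaces a
  server database deliberately, trading concurrency for portability.
- Binding stability, proteasomal processing and foreignness are out of
  scope; columns for externally computed values can be joined as evidence.
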