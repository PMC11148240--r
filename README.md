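# msneoforge

Frameshift neoantigen discovery from coding microsatellites.

## The problem

Tumors with deficient DNA mismatch repair (dMMR / MSI-H) accumulate small
insertions and deletions in microsatellites — tandem repeats of 1–5 bp
motifs. An indel of size *s* with *s* mod 3 ≠ 0 inside a coding
microsatellite shifts the downstream reading frame, producing a mutant
protein tail absent from the normal proteome: a frameshift neoantigen, and a
natural target for immune interception in MSI cancers and Lynch syndrome.

Because indels whose sizes are congruent modulo 3 share a reading frame and
leave the sequence 3' of the tract untouched, the whole indel spectrum at one
tract collapses onto **two frame classes**, each representable by a single
canonical in-silico deletion:

- 2 bp deletion → net shift ≡ 1 (mod 3), the "3n+1" series
  (… −2, +1, +4 …);
- 1 bp deletion → net shift ≡ 2 (mod 3), the "3n+2" series
  (… −1, +2, +5 …).

msneoforge builds the catalog implied by this observation: it detects coding
microsatellites, emits the two canonical deletions per (locus, transcript)
as left-aligned VCF, translates the mutant transcripts into
**junction-excluded** downstream frameshift peptides (the peptide starts at
the first mutant codon lying fully 3' of the tract, because junction content
depends on the specific indel rather than on its class), deduplicates them,
enumerates MHC class I (8–11-mer) and class II (15-mer) epitope windows,
scores them through a pluggable binding-affinity predictor contract, keeps
pairs with best IC50 < 50 nM over algorithms, annotates candidates
(Kyte–Doolittle GRAVY, terminal residues, dbSNP/ClinVar/IEDB-style evidence,
Benjamini–Hochberg differential-expression labels), and serves
`search` / `best neoantigen` queries from a portable single-file store.

It is intended for methodologists and tool builders who need a transparent,
fully testable implementation of this pipeline at desk scale; everything runs
on synthetic genomes with planted ground truth, with no downloads.

## Worked example

Generate a small synthetic genome with planted microsatellites and run the
whole pipeline:

```r
library(msneoforge)

spec <- fixture_spec("small", seed = 1)
dir  <- file.path(tempdir(), "demo")
fx   <- make_genome(spec, dir)     # genome.fa, annotation.gtf, truth tables
res  <- run_all(dir)
res$counts
#>            n_loci    n_coding_pairs     n_coding_loci        n_variants
#>                10                 6                 6                12
#> n_unique_peptides         n_class_i        n_class_ii
#>                12              3314               390
```

Ten tracts were planted (6 coding, 2 intronic, 2 intergenic); the scan finds
exactly those ten, the six coding ones survive the CDS intersection, each
yields two canonical deletions, and the twelve mutant transcripts translate
into twelve distinct junction-excluded peptides:

```r
head(res$dedup[, c("peptide_id", "peptide", "gene_symbols", "non_stop")], 3)
#>   peptide_id         peptide gene_symbols non_stop
#> 1   FSP00001 AHGDSSTGCPSSNYA       GENE04    FALSE
#> 2   FSP00002             CYD       GENE05    FALSE
#> 3   FSP00003      GRSRLRFRVK       GENE03    FALSE
```

The 3,314 class I candidates are (epitope, allele) pairs over the shipped
27-allele panel whose best IC50 across the three deterministic toy scoring
algorithms is below 50 nM. Query the store for the best binders of two
alleles at a median-affinity cutoff of 30 nM:

```r
best <- neo_best(res$store, c("HLA-A*02:01", "HLA-B*07:02"), cutoff_nM = 30)
head(best[, c("epitope", "allele", "best", "median", "gravy")], 5)
#>       epitope      allele     best   median     gravy
#> 1 QDAPRLTMPRT HLA-A*02:01 1.016447 1.106105 -1.190909
#> 2    YNEPYQIK HLA-A*02:01 1.027144 1.117746 -1.762500
#> 3  NDLTHSDDCA HLA-A*02:01 1.029698 1.120524 -1.060000
#> 4 NEPYQIKTHRS HLA-A*02:01 1.053480 1.146405 -2.000000
#> 5   QAGLVSKVI HLA-A*02:01 1.078499 1.173631  1.100000
nrow(best)
#> [1] 211
```

Each row is one epitope–allele candidate ranked by median IC50 (nM, lower =
stronger predicted binding); `gravy` is the mean Kyte–Doolittle hydropathy.
Finally, every peptide in the fixture's truth table — computed by an
independent literal edit-and-translate oracle — is present in the store:

```r
coverage_check(res$store, fx$truth_peptides$peptide, where = "peptides")[1:2]
#> $n_present
#> [1] 12
#> $n_missing
#> [1] 0
```

A thin CLI over the same functions lives at `inst/cli/msneoforge.R`
(`fixtures`, `scan`, `run-all`, `search`, `best` subcommands).

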