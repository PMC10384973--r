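---
title: "ORF-centric classification of direct-RNA reads from adenovirus vector genomes"
author: "VectorTxAudit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ORF-centric classification of direct-RNA reads from adenovirus vector genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(VectorTxAudit)
```

## The problem

Adenovirus-vectored vaccines are E1-deleted viral genomes carrying a synthetic
transgene expression cassette in the deleted locus. Codon optimization and
sequence shuffling of the immunogen ORF can create unintended splice signals,
so a safety-relevant question is what the vector genome actually transcribes
in human cells: is the intended transgene mRNA dominant, is the cassette
spliced when it should not be, and is there any transcription from the E1
region (which would indicate replication-competent adenovirus, RCA, in the
stock)?

Nanopore direct RNA sequencing (dRNAseq) answers this at the level of single
native mRNA molecules. Each polyadenylated molecule is read from its polyA
tail towards the 5' end, preserving strand and full splice structure. The
characteristic artefact is 5'-end loss: the motor releases the molecule
before the last nucleotides are read, so reads systematically miss a few tens
of nucleotides of their true 5' end, while 3' ends are reliable.

`VectorTxAudit` implements the downstream analysis: spliced long-read
alignments against the annotated vector genome are canonicalized into
*transcript groups*, each group receives a *5'-proximal ORF* call, and from
these the package derives per-ORF gene transcription tables, a
transgene-cassette splice audit and an RCA screen. A synthetic read generator
with full ground truth makes every stage testable offline.

## The classification model

A read's spliced alignment is decoded into an exon chain (the `N` CIGAR
operation always opens a new exon; deletions up to `max_del = 30` nt are
absorbed, because aligner dialects differ on how small gaps are encoded).
The chain is then canonicalized against the feature catalog:

* **Junctions** — each junction end snaps independently to the nearest
  same-strand catalogued donor/acceptor within `junction_tol = 10` nt.
  A junction with either end unmatched is *novel*: a half-annotated junction
  flags cryptic-site usage, which is exactly the safety question, so it is
  never silently absorbed into a catalog junction.
* **TSS** — the observed 5' end is assigned to the nearest catalog
  transcription start site at or upstream of it, up to
  `tss_window = 100` nt downstream offset. The window is one-sided because
  dRNAseq truncates 5' ends but never extends them.
* **polyA** — the observed 3' end matches the nearest catalog
  polyadenylation site within `polya_tol = 30` nt on either side; 3' ends
  are read first by the pore and are trustworthy, hence the tight two-sided
  window.

The **transcript group** is the unit of quantification: all reads sharing
(strand, TSS assignment, snapped junction chain, polyA assignment). Reads
matching no TSS, no polyA and containing no junction are counted as
unclassifiable rather than forced into a group. 5' ends that match no TSS are
single-linkage clustered (`cluster_gap = 20` nt, `min_cluster_count = 10`)
into candidate novel promoters.

All tie-breaks (equidistant catalog features) resolve to the lower genomic
coordinate, so the classification is deterministic. Tolerances are exposed in
`groupingParams()` because no published values exist for them; the defaults
are sized to the known scale of nanopore coordinate wobble and 5' loss.

## The 5'-proximal ORF call

What protein a transcript "codes for" is decided the way a scanning ribosome
would: the first AUG of the mature mRNA. For each group the mRNA is rebuilt
from the representative exon chain **re-anchored at the assigned TSS** — not
at the observed read 5' end, since truncation would otherwise push the scan
past the true first AUG. If the first AUG's genomic position coincides
exactly with a catalogued ORF start codon (same strand), the group is
attributed to that ORF; near-cognate or out-of-frame matches are not
accepted, because the published categories are "known feature" versus "None
from the list" with no fuzzy matching. Otherwise the translated peptide is
reported (`none_from_list`) — this is how novel upstream promoters that
create previously undescribed proteins are surfaced — and AUG-less mRNAs are
`no_orf`.

Gene tables aggregate calls weighted by group read counts. The denominator
for percentages is declared explicitly in the output (classified reads, or a
caller-supplied total) because the published tables do not print theirs.
Percentages use half-up rounding (`percentOf()`), which reproduces the
published table arithmetic exactly; 2 decimal places are used automatically
whenever a nonzero row would round to 0.0 at 1.

## The splice audit and the RCA screen

The transgene cassette is designed intronless, so *any* junction in a group
assigned to the transgene promoter is an unintended splice. The audit
statistic is spliced reads per 100 *unspliced* reads from that promoter —
the published convention; because that denominator is unusual, a
conventional percentage of all promoter reads is available via
`denominator = "total"`. For an aberrant fraction *a* among
transgene-promoter transcripts the expected statistic is 100·a/(1−a). Every
junction with its donor inside the transgene ORF is listed individually.

The RCA screen counts vector reads whose ORF call carries the catalog tag
`E1`. The default threshold is zero: a single E1 transcript flips the verdict,
which is the appropriate semantics for a safety screen. Reads mapping to the
host cell's integrated E1 copy (E1-complementing production cells) are
reported separately and never affect the vector verdict.

## What the simulator emulates — and what it does not

`buildToyGenome()` lays out a deterministic ~35 kb vector analogue: a
transgene cassette (own promoter, 150 nt leader, intronless ORF, polyA site)
in the deleted-E1 locus; a pIX-like gene; a major-late-like unit whose
isoforms share a spliced tripartite leader; reverse-strand E2- and E4-like
units (the spliced E4 isoform's intron removes the unspliced isoform's start
codon, exercising the downstream-ORF call); an E1-like sentinel ORF that no
model expresses (for screen testing); and an aberrant transgene isoform whose
junction sits inside the transgene ORF at splice sites deliberately absent
from the catalog. Leaders are scrubbed of AUG so that every model's first AUG
is its annotated start codon; the construction is asserted before the object
is returned, and junction-straddling AUGs are repaired deterministically, so
any seed yields a valid layout.

`sampleReads()` draws a model per read from an abundance profile, applies
geometric 5' truncation (3' ends stay intact, as in the protocol), appends a
polyA tail and corrupts bases. The default `nonpermissiveProfile()` puts 0.86
of the reads on the transgene promoter, split 97:3 between the intended mRNA
and the aberrant isoform — so the expected audit statistic is
100·0.03/0.97 ≈ 3.09, inside the 2.4–3.4% range reported for real
nonpermissive/permissive data — with the remaining mass spread thinly over
the backbone. `permissiveProfile()` mimics E1-complementing cells: late units
dominate and the transgene drops to ~7.7%.

Numerical defaults and why:

| parameter | default | rationale |
|---|---|---|
| `truncation_mean` | 25 nt | typical scale of dRNAseq 5' loss; leaders are ≥150 nt so truncation rarely reaches a start codon |
| `sub/ins/del rate` | 3%/1%/1% | order of magnitude of nanopore RNA base error; classification reads the ground-truth SAM, so these only affect the FASTQ |
| `polya_len_mean` | 60 nt | typical enriched-polyA tail length |
| toy genome | 35,000 nt | the scale of an adenovirus vector genome |

The ground-truth SAM carries the *pre-error* truncated sequence (so CIGAR and
SEQ stay consistent) with the polyA tail as a soft clip; noisy FASTQ reads
are meant for an external spliced aligner (e.g. `minimap2 -ax splice -uf`).
The simulator does **not** model: signal-level (squiggle) behaviour, realistic
quality scores, alignment errors around junctions, template switching, or
internal priming. Passing tests therefore demonstrate the correctness of the
classification logic under truthful coordinates — not robustness to aligner
artefacts on real data, where junction wobble is absorbed only up to the
configured tolerances.

Simulation sizes used in the test-suite checks (5,000 reads per run, 20
sampling replicates for recovery statistics) were chosen so that binomial
sampling error is comfortably below the tolerances being checked
(SE of the transgene percentage at n = 5,000 is ≈0.5 points).

## Degenerate inputs and edge policies

* Empty FASTA, out-of-range or duplicate catalog rows, and a missing
  cassette row are validation errors that name the offending rows.
* Unmapped SAM records are skipped and counted; secondary/supplementary
  alignments are dropped (not stitched) by the default filter — conservative,
  and logged in `metadata()`.
* A truncation draw that would consume a whole transcript is clamped so at
  least 30 nt remain; `mapped_host` may be `NA` (percentage reported missing),
  and a zero denominator reports `NA` rather than a fabricated value.
* Reads are never re-oriented: dRNAseq is strand-faithful, so strand comes
  from the alignment flag alone.

## Worked example

```{r example, eval = FALSE}
cfg <- runConfig(outdir = "run1",
                 simulate = list(n_reads = 5000, profile = "nonpermissive"),
                 seed = 1)
res <- runPipeline(cfg)
head(res$gene_table)
res$splice_stats$pct_spliced_vs_unspliced
res$rca$verdict
```

The run directory contains the accounting, group, gene, splice-audit and
novel-end tables as TSV, the transcript models as BED12, and a manifest with
the config hash; re-running the same config reproduces every file bytewise.

## Known limitations

* One vector contig (plus an optional host-E1 contig); not a general genome
  annotation tool.
* Raw counts and percentages only — no length or depth normalization, mirroring
  the source tables.
* Chimeric/fused reads are dropped with the supplementary-alignment filter
  rather than reconstructed.
* The catalog TSV schema is this package's own reconstruction (the format of
  the original study's feature files is unpublished); a GFF3 reader maps
  standard types onto the same classes.
* Host-transcriptome mapping is accepted as an externally supplied count and
  never recomputed.
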