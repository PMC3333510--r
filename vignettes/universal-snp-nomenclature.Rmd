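---
title: "A position-based universal SNP nomenclature: model, aligner and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A position-based universal SNP nomenclature: model, aligner and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usnp)
```

## The naming model

A SNP is fully determined by four pivot features: the reference genome
build its coordinates refer to, the chromosome, the 1-based position, and
the observed alleles. The universal name is the concatenation of exactly
those features, `HG<build>.<chromosome>:<locus>:<alleles>`, so naming
requires no registry, no curation and no submission: anyone holding the
pivot features computes the same identifier, including for private or
unpublished variants. `usnp` implements this nomenclature with a strict
parser/validator and three conventions worth stating precisely.

**Coordinates are 1-based.** Public databases disagree here — some display
1-based positions while their dump files are 0-based — so the package
treats the off-by-one as an explicit, range-checked conversion
(`to_zero_based()`, `to_one_based()`) rather than an ambient assumption.
A cross-reference snapshot whose file declares `#coord=0based` is converted
once, at load time; everything downstream is 1-based.

**Indels occur *at* the stated position.** `HG19.1:1234:insT` writes `T`
at position 1234; the base formerly at 1234 now sits at 1235
(`displaced_reference_position()` returns exactly `locus + 1`, and `NA` for
substitutions and deletions, where the convention has no meaning).
`HG19.1:1234:delC` deletes the `C` at 1234. Only single-base events are in
scope: multi-base indels, ranges, rearrangements and CNVs are excluded by
design, as their naming raises consensus questions this nomenclature does
not attempt to settle.

**Allele order carries meaning but not certainty.** The leftmost allele
should be the major allele, which is normally the reference-genome base.
Allele frequency is population- and assay-dependent, so the package never
reorders alleles on its own authority: `canonicalize_alleles()` moves a
*supplied* reference base to the front (preserving the relative order of
the rest, idempotently), and if the supplied base is not among the recorded
alleles it leaves the name unchanged, attaches a `reference_mismatch` flag
and raises a warning rather than an error — a disagreement with the
reference is suspicious, not illegal. Substitutions may list up to four
distinct alleles (`A/C/G`), which is why the separator is `/` rather than
HGVS's `>`: "changed to" loses its clarity with more than two alleles. `N`
is accepted as an allele token (an unresolved base is better recorded than
dropped) but is non-canonical; parsing is case-insensitive while formatting
always emits upper-case bases with lower-case `ins`/`del`.

Every validation failure is a classed condition naming the offending field
(`usnp_locus_error`, `usnp_chromosome_error`, `usnp_allele_error`,
`usnp_allele_count_error`, `usnp_syntax_error`), so callers can dispatch on
the failure category; no failure is a bare string-matched error.

## Bridging to HGVS

A genomic-level HGVS name such as `NT_021937.19:g.7871183G>A` pins the
variant to an accessioned sequence, and one SNP commonly has several legal
HGVS names on different accessions. Translating between the two systems
therefore needs an accession→genome placement, which HGVS itself does not
carry. The package makes that mapping an explicit user input
(`accession_map()` / `read_accession_map()`): per `accession.version`, a
chromosome, the genome position of the accession's first base, a strand
and a length. On the minus strand the accession is the reverse complement
of its genome segment, so position `p` mirrors to
`genome_start + length − p` with bases complemented; an insertion shifts by
one more because the insertion gap flips sides under the mirror. The
translation is exactly invertible, and the test suite verifies the
round trip and the base-level identity on synthetic genomes. Coding
(`c.`), protein (`p.`) and multi-base forms are recognized and rejected
with a dedicated `hgvs_unsupported_error` — translating them would require
transcript models that are out of scope.

## Name mapping and the three negative outcomes

`map_name()` recognizes a namespace by pattern — `rs\d+`, `ss\d+`,
`IMS-JST\d+`, `HGVM\d+`, the universal grammar, PharmGKB's `rs#@chr:pos`
(resolved through the embedded rs#), and the lenient genome-browser style
`Chr19:11,087,877-11,087,877 G/T` (commas stripped, `chr` prefix dropped,
single-base ranges only) — then resolves against the snapshot. Position
lookup deliberately ignores alleles: cross-referencing asks whether *some*
SNP is recorded at the locus, since allele observations differ across
populations and assays. HapMap identifiers are stored in their own column
and never assumed equal to the rs# even though they usually are.

The package distinguishes three negative outcomes, rendered literally:

* `none` — a single database has no identifier for an otherwise resolved
  variant (per-field);
* `None` — the input name itself could not be recognized or resolved
  (whole-query);
* `Not Aligned` — a flanking read found no placement within the mismatch
  budget (aligner).

A record lacking allele information cannot yield a universal name (the
alleles are part of the name); `xref_usnp_name()` returns `NULL` and the
mapper reports `none` in the name column while still listing the
identifiers it did find.

## The aligner

Flanking-sequence localization is the route to a universal name when only
the surrounding sequence is known. Reads carry the variant site in the
bracket dialect used by dbSNP's rs_fasta dumps — `ACGT[G/A]TTCA`,
`[-/T]` for an insertion, `[T/-]` for a deletion — or, for FASTQ (whose
format cannot carry in-sequence markers), a `variant_at=<k>;alleles=<X/Y>`
annotation on the description line. Batch gates mirror the intended
service limits: extensions `fa/fas/fast/fasta/fq/fastq` only, 5 MB default
cap, queries up to 1024 bases.

The aligner is gapless seed-and-extend over a k-mer hash of the reference
(default `k = 12`), scoring placements by Hamming distance on both strands.
For a raw mismatch budget *b* the query contributes *b*+1 disjoint seeds;
by pigeonhole at least one seed is exact in any placement with ≤ *b*
mismatches, so the candidate set is provably complete whenever the query
length is at least (*b*+1)·*k*. Shorter queries fall back to an exhaustive
scan of every offset — at the package's intended reference scales (tens to
hundreds of kilobases) this costs milliseconds and keeps the completeness
guarantee unconditional. The test suite holds the aligner to *set equality*
with an independent exhaustive Hamming scan, not merely agreement on best
hits.

Numerical and convention choices:

* **Defaults `max_mismatch = 3`, `max_hits = 2`** — the standard short-read
  operating point for this task (report at most two best hits allowing
  three mismatches); both are arguments and CLI flags.
* **`N` matches nothing**, in query or reference, including `N` against
  `N`. The marked substitution site is written as `N` in the query and its
  position is excluded from the reported count, so the placeholder consumes
  no mismatch budget and a clean substitution read aligns with 0 counted
  mismatches. Internally the raw budget is therefore `max_mismatch` plus
  the number of excluded positions, which also sizes the seed count.
* **Gapless only.** Indel *variants* are handled by query construction —
  a deletion query carries the deleted base (present on the reference), an
  insertion query joins the two flanks (the inserted base is absent from
  the reference) — not by gapped dynamic programming. Gapped alignment
  would only matter for indel *sequencing errors*, which the fixture model
  does not generate.
* **Deterministic tie-breaking**: ascending mismatch count, then chromosome
  order as indexed, then leftmost start, then `+` before `−`. Ties are a
  real phenomenon (repeats); when two placements of equal quality project
  the variant to different loci the result is flagged `ambiguous` and both
  are reported, rather than silently picking one.
* **Locus projection**: on a `+` placement the variant locus is
  `start + |5′ flank|`; on `−` it mirrors through the placement
  (`start + L − 1 − offset`, and one further for insertions because the
  insertion gap flips sides), with alleles reverse-complemented. The
  reference base is then read off the genome and moved leftmost via
  `canonicalize_alleles()`; localization is invariant under
  reverse-complementing the input record, which the suite checks record by
  record.

## The fixture generator: what it emulates, and what it does not

`fixture_spec()` defines the study conditions used throughout the tests:
a uniform-random A/C/G/T genome (50 kb, one chromosome by default), 500
planted variants (10% single-base indels), read lengths 35/76/128/512 —
spanning the short-read regime from early NGS outputs to long fragments —
a 1% uniform per-base flank substitution error, and a 70% per-namespace
chance that a variant is recorded in the snapshot (so the `none` path is
exercised by construction). Reads are emitted from a uniformly random
strand. Everything is a pure function of the seed; file sets are
byte-identical across reruns.

Deliberate simplifications, and what they imply about the tests:

* **Uniform error model.** Real sequencing error is position- and
  chemistry-dependent; the generator applies i.i.d. substitution errors at
  a stated rate and no indel errors. Published accuracy figures obtained
  under realistic error models on the full human genome are therefore not
  reproduction targets here; what the tests *do* establish is exact
  recovery on error-free reads and placement precision under the stated
  uniform error.
* **Uniform base composition.** A random genome has essentially no repeat
  structure, so multi-hit ambiguity — pervasive in real genomes — arises
  only via the explicit `duplicate_segment_length` knob, which copies a
  segment to a second location to exercise the `ambiguous` flag. Passing
  tests on random genomes say nothing about mapping uniqueness in
  repeat-rich regions.
* **No population structure**: allele frequencies, linkage and quality
  scores are not modeled; the "major allele leftmost" recommendation is
  exercised only through the reference base.

**Accuracy definition.** Two quantities are reported at each read length.
On error-free reads, *recovery*: the fraction of all planted, untruncated
variants whose localized name equals the truth exactly — required to be
100% at every length. Under flank error with a fixed mismatch budget,
*placement precision*: among reads the aligner localizes at all, the
fraction placed at the exact truth locus. The distinction matters because
with an i.i.d. error rate the *number* of errors grows linearly with read
length (a 512 bp read at 1% carries ~5 expected errors), so the fraction of
reads that clear a fixed 3-mismatch budget necessarily falls with length —
a property of the error model, not of placement quality. Reads over budget
are honestly reported `Not Aligned`; among placed reads, precision is high
at 35 bp and non-decreasing through 512 bp, the expected behavior as longer
flanks make spurious placements ever less competitive.

**Problem sizes.** The suite runs oracle equivalence on a 10 kb genome
(200 reads across the four lengths, exhaustive scan as the reference),
localization at the default 50 kb / 500-variant conditions in both the
error-free and 1%-error regimes, and strand invariance over the full
500-read set — sizes chosen so the complete suite runs in minutes on one
CPU while every guarantee is exercised at, not below, its stated scope.

## Open design points, as resolved here

* The variant-site marker inside an uploaded sequence has no single
  standard; the bracket dialect was adopted because it is the de-facto
  convention of dbSNP flanking-sequence dumps, and it is part of this
  package's documented contract (`write_flanking()` emits it back).
* `N` in substitution pairs (`G/N`) and `insN` are accepted — `N` is a
  legal nucleotide token — but are non-canonical; strict consumers can
  reject them downstream.
* How equally-good placements should be resolved before database lookup is
  genuinely underdetermined; this implementation surfaces the ambiguity
  (`status = "ambiguous"`, both placements reported) instead of resolving
  it.
* The accession map is an explicit replacement for whatever internal
  contig-placement machinery a full-scale service would maintain; no
  network fetching of RefSeq placements is attempted, and cross-build
  liftover is out of scope (`HG19` is the only build bundled with
  fixtures).

## Limitations

Single-base variants only; gapless alignment (no tolerance for indel
sequencing errors); desk-scale reference genomes (the k-mer hash is an
in-memory R structure, not an FM-index — genome-scale indexing is a
non-goal); snapshots are static local files that must be regenerated when
the upstream databases change; no quality-aware scoring, paired reads or
compressed inputs.
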