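# usnp — universal SNP nomenclature, cross-database mapping and flanking-sequence localization

Single nucleotide polymorphisms accumulate names: a dbSNP `rs#`, a JSNP
`IMS-JST` accession, a HapMap entry, a GWAS/HGVbaseG2P `HGVM` id, several
legal HGVS names on different reference sequences, plus ad-hoc
genome-browser spellings like `Chr19:11,087,877 G/T`. None of these is
derivable from the variant itself, so cross-referencing a SNP across
databases — or recognizing that two papers describe the same variant — is
manual work. `usnp` implements a *position-based* universal nomenclature
that makes the name computable from the variant's pivot features alone:

```
HG<build>.<chromosome>:<locus>:<alleles>
```

* `HG19` — the human reference genome build the coordinates refer to.
* `<chromosome>` — `1`–`22`, `X` or `Y`.
* `<locus>` — the 1-based position of the variant.
* `<alleles>` — `G/A` (substitution; leftmost allele is the reference, more
  generally the major allele; up to four alleles), `insA` (single-base
  insertion), `delT` (single-base deletion).

So the variant known as `rs3737965` is simply `HG19.1:11789038:G/A`. For
indels the polymorphism occurs *at* the stated position: `1234insT` writes
`T` at position 1234 and displaces the former occupant of 1234 to 1235.

The package provides, entirely offline and testable on synthetic fixtures:

* **nomenclature** — strict parser, canonical formatter, descriptor
  validator, allele canonicalization, 0-based/1-based coordinate helpers
  (`parse_usnp`, `format_usnp`, `validate_descriptor`,
  `canonicalize_alleles`, `displaced_reference_position`,
  `to_zero_based`/`to_one_based`);
* **HGVS bridge** — translation to/from genomic-level (`g.`) HGVS names via
  a user-supplied accession map (`parse_hgvs_g`, `hgvs_to_usnp`,
  `usnp_to_hgvs`);
* **cross-reference store** — a TSV snapshot of per-position database
  identifiers with position lookup and name-to-name mapping (`load_xref`,
  `lookup_by_position`, `map_name`);
* **aligner** — a gapless, mismatch-tolerant k-mer seed-and-extend aligner
  that places flanking sequences with a marked variant site (bracket
  dialect `ACGT[G/A]TTCA`) on a reference genome and projects the site to a
  genomic coordinate (`build_index`, `align_read`, `localize_variant`,
  `align_batch`), with SAM export;
* **fixtures** — a seeded generator for random genomes, planted variants,
  cross-reference snapshots and simulated flanking reads (`fixture_spec`,
  `generate_genome`, `plant_snps`, `emit_flanking_reads`,
  `write_fixtures`);
* **CLI** — `name`, `map`, `align` and `fixtures` subcommands
  (`usnp_cli()`, or the `inst/exec/usnp` Rscript).

## Worked example

Generate a 20 kb synthetic genome with 100 planted variants, align the
simulated 76 bp flanking reads back, and cross-reference them:

```r
library(usnp)

spec  <- fixture_spec(genome_length = 20000, n_snps = 100, seed = 42)
paths <- write_fixtures(spec, "demo")

idx   <- build_index("demo/genome.fa")
store <- load_xref("demo/xref.tsv")
reads <- read_flanking("demo/reads_L76.fa")
res   <- align_batch(idx, reads, store = store)
head(res, 5)
```

```
     query_id chrom position strand mismatches alleles          usnp_id
 var00001_L76     1      604      +          0     C/T   HG19.1:604:C/T
 var00002_L76     1      698      +          2    insG  HG19.1:698:insG
 var00003_L76     1      917      +          0     C/A   HG19.1:917:C/A
 var00004_L76     1      964      +          1     A/T   HG19.1:964:A/T
 var00005_L76     1     1149      +          1    insC HG19.1:1149:insC
       rs          jsnp status
 rs911461 IMS-JST911461     ok
 rs872186 IMS-JST872186     ok
 rs427120          none     ok
 rs977533          none     ok
     none IMS-JST975973     ok
```

Each read is placed on the reference (strand, leftmost position, mismatch
count — the default budget is 3 mismatches, reporting at most the 2 best
hits), the marked site is projected to its 1-based locus, the universal
name is emitted with the reference allele leftmost, and every database
identifier recorded at that position is reported; `none` marks a database
with no record, `Not Aligned` a read with no placement within the budget.
The default reads carry a 1% simulated flank error, visible in the
`mismatches` column.

Mapping an existing name works from any namespace:

```r
map_name(store, "rs911461")
```

```
query: rs911461  [rs]
universal name: HG19.1:604:C/T
 chrom pos alleles           usnp       rs          jsnp hapmap gwas
     1 604     C/T HG19.1:604:C/T rs911461 IMS-JST911461   none none
```

An unrecognized or unknown name prints `None`. Name generation from pivot
features, and the insertion displacement rule:

```r
format_usnp(validate_descriptor(list(build = 19, chromosome = "1",
  locus = 11789038, variant_class = "substitution", alleles = c("G", "A"))))
#> "HG19.1:11789038:G/A"
displaced_reference_position(parse_usnp("HG19.1:1234:insT"))
#> 1235
```

The same operations are available from a shell:

```sh
usnp name --build 19 --chrom 1 --pos 11789038 --alleles G/A --xref xref.tsv
usnp map rs911461 --xref xref.tsv
usnp align reads.fa --reference genome.fa --xref xref.tsv --format both
usnp fixtures --out-dir demo --seed 42
```

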