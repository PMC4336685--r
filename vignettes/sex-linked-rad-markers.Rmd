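---
title: "Discovering sex-linked SNP markers from RAD sequencing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering sex-linked SNP markers from RAD sequencing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In a dioecious species with an unknown sex-determination system, a SNP that
sits in the non-recombining sex-determining region co-segregates perfectly
with sex in a full-sib family: under female heterogamety (ZW/ZZ) every
female — the heterogametic parent and every daughter — is heterozygous at
the marker and every male is homozygous, because the alternate allele rides
exclusively on the W chromosome. Under male heterogamety (XY/XX) the
pattern is mirrored. Screening a reduced-representation library of an F1
family for exactly this pattern therefore does two things at once: it
yields sex diagnostic markers usable for marker-assisted selection long
before plants flower, and the *polarity* of the pattern (which sex is
always heterozygous) identifies the heterogametic system.

`radsexr` implements that screen de novo — no reference genome — from
barcoded single-end RAD reads, together with a read-level simulator of the
underlying library so that every stage can be validated against a known
truth table.

## The data model

Reads are 90 nt: an 8-nt inline multiplex identifier (MID) followed by the
82-nt RAD tag that begins with `AATTC`, the residual of the EcoRI
recognition site `G/AATTC` after cleavage (the leading G stays on the other
fragment). All coordinates in the package are 1-based within the 82-nt tag,
position 1 being the leading A of `AATTC`. Only substitutions are modelled:
tags are fixed-length and indels are out of scope, consistent with a
SNP-only marker panel.

## Pipeline stages and their parameters

1. **Demultiplexing** (`demultiplex()`): a read is assigned when its first
   8 nt match a sample-sheet MID and nt 9–13 are `AATTC`; it is trimmed to
   the 82-nt tag. The default is exact barcode matching; a 1-mismatch
   rescue is available and is what `run_radsex_pipeline()` uses, because
   simulated MIDs are pairwise Hamming distance ≥ 3 apart, which makes
   single-error rescue unambiguous and avoids discarding ~4% of reads (at
   0.5% per-base error over 8 barcode bases) in a way that would thin
   coverage. Reads containing any non-ACGT character are discarded; the
   Hamming-based clustering downstream has no ambiguity handling.

2. **Stack building** (`build_stacks()`, per individual): unique read
   sequences, ordered by descending count, are clustered greedily — each
   unassigned sequence within Hamming distance 2 of the current founder
   joins its stack. Three refinements make the stacks usable for
   genotyping, all standard behaviour in stack-based RAD assemblers:

   * *Consensus-level merging.* Reads carrying a sequencing error on top
     of a minor allele can found a satellite cluster; satellites whose
     consensus is within the radius of a deeper cluster's consensus are
     folded in before genotyping, so minor-allele support is not
     fragmented.
   * *Secondary attachment.* Left-over sequences (from clusters below the
     depth threshold) within distance 4 (= radius + 2) of a stack
     consensus are re-admitted as members.
   * *Allele decomposition.* A heterozygous individual's two tag alleles
     usually differ by one or two substitutions and therefore share a
     stack. Columns where the second-most-supported base reaches
     `min_allele_depth` reads and `min_minor_ratio` of the leading base
     are treated as within-stack SNPs; member reads are grouped by their
     base tuple at those columns, and the two best-supported haplotypes
     become the stack's alleles.

   `min_stack_depth` (default 3 reads) suppresses singleton error
   sequences at the simulated 20–60× tag depths.

3. **Catalog construction** (`build_catalog()`): single-linkage merging of
   allele sequences across individuals at Hamming distance
   ≤ `catalog_mismatch` (default 2, mirroring the within-individual
   radius). Candidate pairs are generated by exact-match bucketing on
   three sequence chunks — two 82-mers within distance 2 must agree
   exactly on at least one third of their length — so no quadratic scan is
   needed. Loci where any individual contributes more than two distinct
   alleles are flagged repetitive (putative paralog collapse) and excluded
   from genotyping. Variant positions are the tag columns at which member
   alleles disagree.

4. **Genotyping** (`call_genotypes()`): per individual per locus, alleles
   with depth ≥ `min_allele_depth` (default 3) are credible. Two credible
   alleles with minor/major depth ratio ≥ `min_minor_ratio` (default 0.25)
   give a heterozygous call; a single credible allele gives a homozygous
   call (a sub-floor minor allele is logged and dropped — the signature of
   an error stack); two credible but strongly imbalanced alleles are
   *missing* with reason `allele_imbalance` rather than being forced to a
   call. The defaults are conventional stack-genotyping heuristics for
   ~20–60× tag depth; there is no likelihood model, and base qualities are
   unused (a deliberate extension point).

5. **Parent filter and sex screen** (`filter_parent_polymorphic()`,
   `screen_sex_association()`): only rows where both parents are called
   and differ are informative in an F1 pseudo-testcross. A row is a
   sex-marker candidate iff every female carries one identical het
   genotype and every male one identical hom genotype whose base belongs
   to the het pair, or the mirror. `max_missing` defaults to 0: with 18
   deeply covered individuals the screen is a perfect-information filter,
   and tolerating missing calls would quietly weaken the exact-match
   semantics. Candidates carry IUPAC codes and the 82-nt tag with the SNP
   bracketed, plus a reverse-complement rendering because assay primers
   are often read off the opposite strand (published marker tables mix the
   two strand conventions for exactly this reason).

6. **Inference and accounting** (`infer_sex_system()`,
   `radseq_summary_table()`): all-female-heterogametic candidates ⇒ ZW;
   all-male ⇒ XY; otherwise undetermined. The summary table reproduces the
   standard reduced-representation bookkeeping: total RAD sequence =
   reads × 82 bp, coverage depth = reads / tags, sequence coverage = total
   RAD sequence / genome size (default 660 Mbp, the flow-cytometry
   estimate for pistachio; simulated runs pass the simulated length), and
   bp-per-SNP densities. Group *subtotal* rows sum unrounded
   per-individual values and group *average* rows average them — means of
   ratios, not ratios of sums, which is how such tables are conventionally
   printed (the female mean depth of 50.2× differs from the pooled
   50.3×). Display rounding is half-up at one decimal for ×-columns.

## The simulator: what it emulates and what it does not

`simulate_genome()` plants a controllable number of EcoRI sites (spaced so
every tag window is complete and free of other sites, with accidental
`GAATTC` occurrences mutated away) and designates a sex-determining region
at the start of the sequence. `plant_variants()` places SNPs only inside
tag windows (positions 6–82, never in the `AATTC` motif) at ≤ 2 per tag,
so that the two alleles of any tag stay within the clustering radius.
`simulate_cross()` builds parent and progeny haplotypes: sex-linked
alternate alleles ride only on the W (or Y) haplotype; autosomal variants
segregate Mendelianly from drawn parental genotypes, with variants sharing
a tag co-phased and co-inherited and different tags assorting
independently. A ZW×ZZ cross structurally cannot emit a WW individual and
the generator asserts this. `simulate_reads()` draws Poisson(depth/2)
reads per haplotype per site, applies independent per-base substitution
errors, and writes FASTQ with constant Q30 qualities (the pipeline never
reads them).

Defaults mirror the balanced study design the screen is meant for: 8
female + 8 male F1 progeny plus both parents, 20× mean tag depth, 0.5%
per-base error. The demo genome is 100 kb with 150 sites — large enough
that 5 sex-linked plus 200 autosomal variants fit at ≤ 2 per tag, small
enough that the full pipeline runs in well under two minutes.

Deliberately *not* modelled: paired-end second reads (the analysis uses
only first reads), shearing and size selection (one tag per site, plus
strand), indels, PCR duplicates, quality-score structure, and paralogous
repeat families beyond the three-allele exclusion. Passing tests therefore
demonstrate the pipeline's correctness on data matching its model
assumptions, not robustness to the full messiness of a real library.

## What the stochastic checks can and cannot promise

At 20× tag depth each haplotype draws Poisson(10) reads. A heterozygote is
missed when either haplotype draws fewer than 3 surviving reads or the
depth ratio falls below 0.25; at the realized post-demultiplexing depth
this happens with probability ≈ 1% per carrier per locus, giving an
expected truth concordance of ≈ 99.3% (the suite asserts ≥ 99%). Recovery
of *all* planted sex-linked markers is a stricter event: with 5 markers
and 9 het carriers each, all-5 recovery has probability ≈ 0.6 per seed,
and a run in which one W haplotype draws 2 reads at one locus will report
4/5. This is a property of the calling thresholds at 20× depth, not of the
seed; deeper libraries (the upper end of the 20–60× design range) make the
event rate negligible.

The false-positive side is exact: an informative autosomal locus passes
the perfect screen with probability 2·(1/2)^(n_F+n_M) ≈ 3.05×10⁻⁵ for 8+8
progeny, and the Monte-Carlo calibration (10,000 informative loci) agrees
within three standard errors. No multiple-testing machinery is involved —
the screen is an exact-match filter, and the closed form is reported
alongside as context.

## Numerical and tie-breaking conventions

* Consensus ties are broken by the founding sequence's base (stacks) or
  the deepest allele's base (catalog); unique-sequence ordering is by
  descending count then lexicographic, making every run reproducible.
* Catalog locus ids are assigned in lexicographic order of allele
  sequence, so ids are stable for a given input set.
* All randomness flows from one run seed through fixed per-stage
  substreams (`seed + k·10007 mod 2³¹−1`).
* Het genotypes are unordered and always rendered alphabetically
  (`"A/G"`); missing is `"./."` with a reason in a side table.
* Half-up rounding is used wherever tables are printed; base R's
  round-half-even would differ at exact ties.

## Problem sizes used by the tests

The unit suite exercises a cached 12-kb, 20-site, 6-progeny error-free run
plus many sub-second constructed cases; the end-to-end checks run the full
100-kb demo (ZW and XY) once each; oracle equivalence uses 110 random
instances of ≤ 20 sequences against brute-force single linkage and row
enumeration; the calibration screens 10,000 simulated informative loci.

## Known limitations

* No gapped alignment or reference mapping; a tag disrupted by an indel is
  simply a different tag.
* The three-allele paralog guard is the only repeat handling; diverged
  paralogs merging within distance 2 would be flagged, closer ones would
  inflate het calls.
* Genotyping is threshold-based; a binomial-likelihood caller would
  recover part of the ~1% het loss at 20× depth.
* Per-individual SNP counts in the summary table depend on the thresholds
  above; they are internal accounting, not comparable across pipelines
  with different callers.
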