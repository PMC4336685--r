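# radsexr

De novo discovery of sex-linked SNP markers from restriction
site-associated DNA (RAD) sequencing of a full-sib family in a dioecious
species, with inference of the heterogametic sex-determination system
(ZW/ZZ vs XY/XX).

## The problem

Dioecious perennials such as pistachio flower only after years of
juvenility, so a seedling's sex cannot be selected on phenotype. A SNP
inside the non-recombining sex-determining region segregates perfectly
with sex in an F1 family: under female heterogamety every female —
heterogametic mother and every daughter — is heterozygous (the alternate
allele rides only on the W chromosome) and every male is homozygous;
under male heterogamety the pattern mirrors. Finding such SNPs in a
reduced-representation library simultaneously delivers sex-diagnostic
markers for marker-assisted selection and identifies which sex is
heterogametic.

## What the package does

Starting from 90-nt single-end reads (8-nt inline barcode + 82-nt EcoRI
tag beginning `AATTC`):

1. `demultiplex()` — assign reads to individuals by barcode, enforce the
   restriction motif, trim to the 82-nt tag;
2. `build_stacks()` — greedy 2-mismatch clustering of each individual's
   reads into tag stacks, with within-stack decomposition into haplotype
   alleles;
3. `build_catalog()` — single-linkage matching of alleles across
   individuals into catalog loci, with a paralog guard;
4. `call_genotypes()` — depth- and ratio-thresholded het/hom/missing
   calls at every variant position;
5. `filter_parent_polymorphic()` / `screen_sex_association()` — keep loci
   polymorphic between the parents, then demand a perfect sex split
   (every female one identical het genotype, every male one identical
   hom genotype from the het pair, or the mirror);
6. `infer_sex_system()` — ZW if all candidates are female-heterogametic,
   XY if all male, undetermined otherwise;
7. `radseq_summary_table()` / `bp_per_snp()` — the standard
   reduced-representation accounting (coverage depth = reads/tags,
   sequence coverage = reads × 82 bp / genome size, SNP densities).

A first-class simulator (`simulate_genome()`, `plant_variants()`,
`simulate_cross()`, `simulate_reads()`) generates an EcoRI RAD library
from a ZW (or XY) cross with planted sex-linked and autosomal SNPs and a
genotype truth table, so the whole pipeline is testable offline.
`run_radsex_pipeline()` orchestrates everything from one seeded
configuration; `inst/scripts/radsex.R` wraps it for the shell.

## Worked example

A small end-to-end run — 15-kb genome, 20 EcoRI sites, 3 female + 3 male
progeny plus parents, 2 planted sex-linked and 8 autosomal SNPs, 30× tag
depth, 0.2% error:

```r
library(radsexr)
run <- run_radsex_pipeline(radsex_config(
  genome_length = 15000, n_ecoRI_target = 20, sex_region_fraction = 0.25,
  n_female = 3, n_male = 3, n_sex_linked = 2, n_autosomal = 8,
  mean_depth_per_tag = 30, error_rate = 0.002, seed = 1), quiet = TRUE)

print(run)
#> radsex_run
#>   reads: 4955  loci: 20  variant rows: 10
#>   parent-polymorphic rows: 10  candidates: 2
#>   system: ZW  truth concordance: 1.0000

run$candidates[, c("marker_name", "position", "female_genotype",
                   "male_genotype", "iupac")]
#> # A tibble: 2 × 5
#>   marker_name    position female_genotype male_genotype iupac
#> 1 SNP-SIM-L00004       52 C/G             G/G           S
#> 2 SNP-SIM-L00018       52 G/T             T/T           K
```

Both planted sex-linked SNPs come back as candidates: all females
(mother + 3 daughters) are heterozygous, all males homozygous for one of
the het bases, so the system is called ZW with 2 female-heterogametic and
0 male-heterogametic loci, and every genotype call matches the
simulator's truth table (concordance 1.0). The probability that an
autosomal locus would pass the perfect screen by chance in this small
brood is `chance_cosegregation_probability(3, 3)` = 2·(1/2)⁶ ≈ 0.031 —
with only six progeny the screen needs the parents too, which is why
they are part of the pattern check; at the default 8+8 design the rate
falls to 3.05×10⁻⁵.

The coverage accounting for a sequenced family is reproduced from plain
counts:

```r
counts <- pistachio_radseq_counts()           # published 18-plant counts
rows <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i)
  summarize_individual(counts$individual_id[i], counts$read_number[i],
                       counts$n_rad_tags[i], genome_size = 660e6,
                       total_snp = counts$total_snp[i])))
radseq_summary_table(rows, counts$sex)        # per-individual + group rows
```

which yields, among others, a grand mean of 519,937 RAD tags, 47.3×
coverage depth and 3.1× sequence coverage per plant, and one SNP per
449 bp of tag sequence overall (568 bp in the male parent).

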