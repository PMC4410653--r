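# simval

Simulated diploid genomes with encoded ground truth, for benchmarking
read aligners and variant callers.

Benchmarking secondary analysis on real data founders on the absence of
ground truth. `simval` synthesizes the truth instead: it samples germline
(and optionally somatic) variants from a database VCF, applies them to a
reference to produce a **phased diploid genome** together with a **block
map** between perturbed and reference coordinates, simulates paired-end
reads whose true reference alignments are **encoded in the read names**,
and then validates whatever a pipeline produced:

* **Alignments** (SAM/BAM): a record is correct if it lies within a
  tolerance `W` of *any* of its true locations — a read straddling an
  inversion edge, say, has one true anchor per side. Accuracy is reported
  overall and per region class (`SEQ`, `DEL_GAP`, `INS_NOVEL`, `INV`,
  `DUP_COPY`).
* **Variant calls** (VCF): records are normalized to a canonical
  left-aligned form, matched one-to-one against the truth (exactly for
  small variants; by breakpoint distance ≤ 100 bp and size ratio ≥ 0.8
  for SVs), and scored as

  TPR = TP/(TP+FN), PPV = TP/(TP+FP), F1 = 2·TPR·PPV/(TPR+PPV),

  stratified by variant type and size bin (1, 2–5, …, >5000 bp).

A tumor/normal mode runs the simulation twice from one seed (so the two
genomes share a byte-identical germline), applies a somatic variant set on
top, and mixes reads at a chosen tumor fraction to model normal
contamination. Everything — including the synthetic reference, variant
database and insertion-donor pool — is generated by code, so the whole
pipeline runs with zero downloads, deterministically from a seed.

## Worked example

Simulate a 100 kb study, align the reads with `bwa mem`, and validate:

```r
library(simval)

fx    <- smoke_fixture(seed = 5)                       # reference, database, donor pool
ref   <- fx$reference$sequences
db    <- normalize_variants(fx$db, ref)
truth <- sample_truth(db, sampling_spec(n_snv = 50, n_indel = 20, n_sv = 5,
                                        seed = 5), ref, fx$pool)
dip   <- build_diploid(ref, truth)                     # two haplotypes + genome map
reads <- simulate_reads(dip$haplotypes, dip$map,
                        read_sim_params(coverage = 3, sub_error_rate = 0.001,
                                        seed = 5))
write_fasta(ref, "ref.fa"); write_fastq(reads, "reads")
```

```sh
bwa index ref.fa && bwa mem ref.fa reads_1.fq reads_2.fq > aln.sam
```

```r
rep <- validate_alignments("aln.sam", wiggle = 20)
tidy(rep)
#>   category      n correct incorrect_pos incorrect_chrom unmapped unknown fraction_correct
#> 1 ALL        6372    6153             0               0      219       0           0.9656
#> 2 DEL_GAP      56      56             0               0        0       0           1.0000
#> 3 DUP_COPY    177     177             0               0        0       0           1.0000
#> 4 INS_NOVEL   296      77             0               0      219       0           0.2601
#> 5 SEQ        6042    5997             0               0       45       0           0.9926
```

Every read bwa managed to place was placed correctly; the accuracy loss is
entirely unmapped reads, and the per-region breakdown shows why — reads
made of novel inserted sequence (`INS_NOVEL`) have nothing to align to in
the reference, while reads over deletions and duplications align fine.
That is the kind of conclusion the region labels exist for.

Validating a call set against the truth works the same way:

```r
cmp <- match_variants(truth, read_vcf("calls.vcf", ref))
glance(cmp)       # totals: tp, fn, fp, tpr, ppv, f1
stratify(cmp)     # per (type x size-bin) cells with marginals
autoplot(cmp)     # F1 heatmap over types and size bins
```

For a perfect caller (`calls = truth`) this prints
`75 TP, 0 FN, 0 FP (TPR 1.0000, PPV 1.0000, F1 1.0000)`.

A thin command-line front end covering the same steps ships at
`inst/cli/simval` (subcommands `fixture`, `sample`, `build`, `reads`,
`val-align`, `val-vcf`).

## Scope

Translocations, breakends, interspersed duplications, multi-sample VCFs,
per-variant subclonal fractions, learned sequencing-error profiles and
HTML reports are out of scope; see the methods vignette
(`vignettes/simulation-validation.Rmd`) for the model, parameter defaults
and design rationale.
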