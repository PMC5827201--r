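---
title: "Methods: strand-aware mitochondrial variant calling and heteroplasmy dynamics"
author: "mitovar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strand-aware mitochondrial variant calling and heteroplasmy dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitovar)
```

## The problem

Human mitochondrial DNA (mtDNA) is a 16,569 bp circular genome present in
hundreds to thousands of copies per cell, encoding 13 oxidative
phosphorylation subunits, 22 tRNAs and 2 rRNAs under the vertebrate
mitochondrial genetic code. Because many genome copies coexist, a variant
can occupy any fraction of them: a *heteroplasmy* (fractional) or a
*homoplasmy* (fixed). Deep sequencing of matched tumour–normal pairs makes
these fractions directly measurable as variant allele fractions (VAF) at
~2000x depth, and raises four linked questions that this package answers as
a pipeline:

1. which mtDNA variants are present in each tissue, and with what strand
   support (**variant calling**);
2. which constitutional variants are *private* — not explained by the
   carrier's haplogroup and not recurrent mutational hotspots
   (**haplogroup subtraction**);
3. how constitutional heteroplasmies shift between normal and tumour tissue
   (**heteroplasmy dynamics**);
4. what mutational process produced the variants, read from trinucleotide
   context and from the asymmetry between the light (L) and heavy (H)
   strands (**mutational spectra**).

## Variant calling model

Calling operates on per-position, strand-split allele counts, obtained
either from a text pileup (base qualities are applied at parse time) or
from a count table (assumed pre-filtered). A non-reference allele is called
constitutional when **all** of the following hold:

| filter | default | meaning |
|---|---|---|
| `min_baq` | 20 | Phred base quality floor, applied while parsing pileups |
| `min_mq` | 20 | mapping-quality floor; a contract of pileup generation, not re-checkable from a plain pileup |
| `min_depth` | 100 | total post-filter depth at the site |
| `min_vaf` | 0.02 | variant allele fraction |
| `min_vac` | 10 | variant allele count |
| `ci_confidence` | 0.99999 | exact (Clopper–Pearson) binomial interval on the variant fraction must exclude zero |
| `min_per_strand` | 5 | variant reads required on each strand |

A tumour allele is somatic when it passes the same cascade in the tumour,
the matched normal position has `min_depth` coverage, the tumour–normal
difference is at least 10 in allele count and 0.02 in allele fraction, and
the normal VAF falls outside the exact binomial interval of the tumour
count. Two choices here were genuinely open:

* **Count-difference normalisation.** With unequal depths, a raw count
  difference conflates fraction and depth; the default rescales the normal
  count to tumour depth (`normal_vaf * tumour_depth`). The raw difference
  is available via `vac_diff = "raw"`.
* **Interval construction.** The exact Clopper–Pearson interval
  (`qbeta`-based) is used because it is well defined at extreme counts
  (lower bound exactly 0 at count 0, upper bound exactly 1 at full count)
  and conservative at the 0.99999 level. Note that with `min_vac = 10` the
  zero-exclusion filter is implied by the count filter for the
  constitutional cascade; it binds in the somatic comparison against the
  normal VAF.

VAF threshold comparisons are computed on counts
(`vac >= min_vaf * depth` with a 1e-9 guard) rather than on the float ratio,
so decimal thresholds like 0.02 do not misclassify boundary counts through
binary rounding. Zygosity uses an inclusive heteroplasmy band
`[0.02, 0.98]`: the upper bound mirrors the calling floor symmetrically, as
no explicit homoplasmy cutoff is established for these data.

Read-linked artefact pairs (two alternative alleles that only ever co-occur
on the same reads, the signature of a systematic alignment artefact) are
flagged from read-level observations: among reads covering both positions,
the fraction carrying both alleles out of reads carrying either must reach
0.95, and the partner allele must be absent from reads lacking the first.

## Haplogroup subtraction

Haplogroups are assigned by maximising (path variants matched) − (path
variants missing) over all nodes of a phylotree-style table, with ties
going to the deeper node and then the lexicographically smaller label. This
is a deliberate simplification of rank-weighted matchers: it is exact,
auditable, and sufficient for subtracting lineage variants; externally
produced haplogroup calls can be supplied per sample to bypass it. Private
variants are then the constitutional set minus the assigned path and minus
the three mutational super-hotspots (A16182C, A16183C, T16519C), matched
exactly on (position, alternative allele) — a variant at a path position
with a *different* allele is retained, the most literal reading of
"accounted for by the haplogroup". The packaged tree is a ~20-node
synthetic fixture for testing; any table in the same schema can be used.

## Heteroplasmy dynamics

For each constitutional heteroplasmy, the tumour-side VAF and the
heteroplasmic fraction HF = min(VAF, 1 − VAF) are recomputed from raw
tumour counts with **no calling thresholds**: tracking loss of
heteroplasmy requires seeing tumour fractions below the 0.02 calling
floor, so a lost allele yields VAF 0 rather than a missing value. Shallow
tumour positions are flagged `low_confidence` but retained. Shifts are
tested with two paired t-tests:

* **HF test** (normal − tumour; positive t = loss of heteroplasmy). HF is
  a concave function of VAF, so *any* symmetric spreading of allele
  fractions — including pure neutral drift — reduces expected HF. A
  significant positive HF shift therefore indicates drift toward fixation
  or loss, not selection.
* **VAF test** (tumour − normal). Under neutrality the expected VAF change
  is zero regardless of spread; a significant VAF shift indicates the
  variant allele specifically is favoured or disfavoured.

The package's simulations reproduce this contrast: under the default
Wright–Fisher drift model the HF test rejects in roughly a third of
cohorts while the VAF test stays at its nominal 5% level.

## Mutational spectra and strand asymmetry

The 96-bin spectrum uses the standard pyrimidine-collapsed convention:
purine-reference substitutions are complemented together with their
trinucleotide context, taken circularly from the genome (nuclear variants
use linear contigs, dropping contig-edge positions). Strand-resolved
tallies exploit the fact that every substitution is a pyrimidine change on
exactly one strand: a forward G>A variant is C>T on the heavy strand, a
forward T>C variant is T>C on the light strand (equivalently A>G on the
heavy strand). mtDNA replication leaves the parental H-strand transiently
single-stranded, where spontaneous deamination (C→U, A→hypoxanthine)
enriches H-strand C>T and A>G transitions — the asymmetry the
`strand_asymmetry_analysis()` table quantifies, comparing consequence
composition and pathogenicity scores between H- and L-strand transition
groups. The two groups contain different variants, so the score comparison
is a two-sample t-test (pooled by default, Welch optional), not a paired
one. Pathogenicity scores and population frequencies are always inputs
(joined on position/ref/alt), never computed; frequency comparisons run on
raw fractions by default with a log10 flag, since the scale used for the
published comparison is unstated.

## Regional distribution test

The genome is partitioned into seven functional classes: non-coding, rRNA,
tRNA, and OxPhos complexes I (ND1–ND6, ND4L), III (CYB), IV (COI–COIII)
and V (ATP6, ATP8). Class lengths are summed gene spans; the non-coding
length is the remainder 16569 − Σ(gene lengths), which absorbs the
ATP8/ATP6 and ND4L/ND4 overlaps and is the only convention that reproduces
the published row values (1153/2513/1508/6356/1141/3010/888). Observed
variant counts are tested against length-proportional expectations with a
χ² goodness-of-fit statistic on 6 degrees of freedom (a two-sample
homogeneity variant is provided for comparing two variant sets). Applying
this construction to the published per-region private-variant counts gives
χ² = 73.04 (p ≈ 1e-13) — the same conclusion but not the same statistic as
the published 68.628, whose exact expected-proportion construction is
unstated; the package documents its own construction rather than forcing
agreement. The published somatic counts give p = 0.59, i.e. consistent
with chance placement, matching the published contrast.

## The synthetic cohort generator

`simulate_cohort()` emits tumour–normal pairs with a complete truth table.
Defaults are the study conditions the pipeline is validated under:

* depth ~ negative binomial with mean 2000 and size 4 (sd ≈ half the
  mean, matching the reported 2205 ± 1227 scale);
* per-base error 5e-4, spread uniformly over the three non-reference
  bases;
* per sample: haplogroup path variants as homoplasmies (drawn from the
  packaged toy tree), Poisson(3) private variants placed with 5x D-loop
  weighting (70% homoplasmic, the rest low-level heteroplasmies),
  Poisson(1) constitutional heteroplasmies with Beta(0.7, 6) VAFs
  truncated to [0.025, 0.95] (most mass below 0.10), and Poisson(1.5)
  somatic mutations, tumour-only, with Beta(1.2, 3) VAFs;
* somatic substitution classes drawn from a strand-labelled 12-class
  weight vector with H-strand C>T (0.35) and A>G (0.25) elevated;
* heteroplasmy drift between tissues via explicit Wright–Fisher
  bottleneck resampling (default 50 segregating units, 20 generations);
  the bottleneck mechanism is exact in distribution for the discrete
  model, preserves the mean, and its variance follows the closed form
  p(1−p)(1−(1−1/N)^g). The magnitude is not a claim about DLBCL — no
  quantitative drift size is established — but was fixed once to give
  visible losses and occasional fixations; a `directional(shift)`
  alternative moves each VAF toward its nearest boundary for power
  studies.
* allele counts are binomial at the true VAF, strands split binomially at
  0.5; optional read-linked artefact pairs emit matching read-level
  observations.

All randomness flows from one master seed with fixed per-pair substreams,
so individual pairs are reproducible in isolation. The generator writes
either count TSVs or pileup text (with qualities above the BAQ floor) to
exercise both input paths.

**What the simulator does not emulate** — and hence what green tests do
not show about real data: mapping artefacts and reference bias (NUMT
misalignment in particular), strand-biased sequencing error,
library-preparation 8-oxo-G damage, contamination between samples, indels,
and real phylogenetic structure (the toy tree has ~20 nodes). Threshold
behaviour on real data depends on exactly these processes; the simulator
validates the logic of the cascade, not its real-data operating point.

## Numerical and engineering choices

* Exact rational VAF comparisons (counts, not ratios) at filter
  boundaries; inclusive zygosity band ends.
* Consequence severity ordering stop-gain > non-synonymous > synonymous >
  tRNA > rRNA > non-coding; overlap positions are annotated against every
  covering gene with the most severe call reported as primary.
* Genes ending in incomplete stop codons (length not divisible by 3) are
  translated by padding with A, emulating polyadenylation completion.
* Haplogroup ties: deeper node, then lexicographic label.
* Degenerate statistics (zero-variance differences, empty groups) are
  reported as flagged degenerate results or skipped with a notice, never
  silently dropped.
* Problem sizes in the shipped tests and acceptance script: 20 simulated
  pairs at full genome scale for recovery, 500 replicate cohorts of 40
  heteroplasmies for test calibration, 500 planted somatic variants for
  spectrum recovery. These sizes give binomial standard errors small
  enough for 3-SE checks while keeping the default runs fast.

## The packaged reference is synthetic

The packaged gene coordinate table is the real, public rCRS annotation,
and everything that depends only on coordinates (region lengths, locate,
overlap handling) is exact. The packaged *sequence*
(`rcrs_synthetic.fa`, regenerable via `synthetic_mito_genome()`) is a
constructed stand-in, not the rCRS: a deterministic sequence with the
L-strand's base composition in which every protein gene is a valid
mitochondrial open reading frame (ATG start, no internal stops across
overlap frames, incomplete terminal codons where the real gene lengths
imply them), and with a valine codon placed at 11711 so the recurrent
G11711A substitution annotates as non-synonymous in ND4 as on the real
genome. Consequence logic, context extraction and spectra are fully
exercised against it, but base-level annotations of real variants require
supplying the real rCRS FASTA (`mito_genome(path = ...)`), which every
function accepts.

## Known limitations

* No indels, no genome builds other than rCRS coordinates, no hg18→rCRS
  conversion (inputs must already be on rCRS coordinates).
* The haplogroup matcher is unweighted; fine-grained assignments on real
  data should come from a dedicated tool and be passed in as overrides.
* Mapping quality cannot be enforced from plain pileups.
* The χ² regional test uses length-proportional expectations; mutational
  opportunity (base composition per region) is not modelled.
* Signature deconvolution (NMF/COSMIC fitting) is out of scope; spectra
  are descriptive.
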