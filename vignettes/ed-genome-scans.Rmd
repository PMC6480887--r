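---
title: "Euclidean-distance genome scans for two-pool bulked-segregant data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Euclidean-distance genome scans for two-pool bulked-segregant data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edscan)
```

## The mapping problem

Bulked-segregant analysis (BSA) locates trait-linked loci by sequencing
pooled DNA from two phenotypically extreme groups and scanning the genome
for sites where the pools' allele representation diverges.  The design
this package targets is the hardest variant: only **two pools** are
available — for example a multi-silique and a single-silique rapeseed
near-isogenic line (NIL) — with no parental genotypes, so SNP-index
methods (which need four samples) do not apply.  The informative signal
is the per-site difference between the pools' pooled allele depths.

## The ED statistic and its transform

At each variant site the pools' allele depths are converted to
frequencies and compared by the Euclidean Distance

$$
ED \;=\; \sqrt{\textstyle\sum_a \left(f_{a,\mathrm{pool1}} -
f_{a,\mathrm{pool2}}\right)^2},
$$

with the sum over alleles (the four bases at a SNP; ref/alt for an
InDel).  $ED$ ranges from 0 (identical pools) to $\sqrt 2$ (pools fixed
for disjoint alleles).  We compute ED on **frequencies** rather than raw
depths by default: raw base depths make the statistic scale with
coverage, whereas proportions bound it by $\sqrt 2$ and make sites
comparable; `on_frequencies = FALSE` preserves the literal depth-based
reading.

A single pooled site is noisy, so two denoising steps follow:

1. **Power transform** ($ED^k$, default $k = 5$): background chance
   differences are compressed toward 0 while near-maximal divergences
   are preserved, sharpening contrast before smoothing.
2. **Distance-weighted profile fit**: along each chromosome the powered
   values are smoothed by a kernel-weighted local average over a
   physical window (`bandwidth`, default 1 Mb), with tricube weights
   $(1-(d/h)^3)^3$.  The tricube kernel is the standard choice for
   distance-based local averaging; `uniform` and `triangular` kernels
   are available.  Each fitted value is a convex combination of raw
   values in its window, hence non-negative and bounded by the window's
   raw range.

SNP and InDel markers are scanned **independently** — they have
different error profiles and densities — and each class gets its own
threshold; agreement between the two scans is itself evidence, which is
why the final candidate set is the *intersection* of the two region
sets.

## The association threshold

Candidate regions are where the fitted profile exceeds
$\mathrm{center} + m \times \mathrm{spread}$ of the genome-wide fitted
values (multiplier $m = 3$ by default, the classical "ED + 3 SD" rule).

The choice of center/spread estimator matters more than it may appear.
The arithmetic mean and sample SD include the trait-linked plateaus
themselves, and a plateau at height $M$ occupying fraction $f$ of the
genome forces
$\mu + 3\sigma \approx fM + 3M\sqrt{f - f^2} > M$ once
$f \gtrsim 0.08$: on small scanned genomes (or strong, broad signals)
the classical threshold climbs **above the signal itself** and nothing
is called.  A real 10-Mb signal in an 850-Mb genome is $f
\approx 0.012$ and the classical rule works; a 3-Mb causal region with
2-Mb linkage decay on one 30-Mb chromosome is $f \approx 0.2$ and it
fails deterministically.  The default is therefore the robust pair
median and $1.4826 \times \mathrm{MAD}$, which coincides with
mean/SD under a pure-noise profile but has a 50% breakdown point;
`robust = FALSE` restores the literal mean + 3 SD formula.  The robust
threshold is deliberately liberal in the upper tail of a right-skewed
null field — its job is not to miss contaminated-scale signals — so on
pure-null data it flags slightly more isolated excursions than the
classical rule; the `min_markers` support filter absorbs these.

Two practical caveats, both visible in the package's own calibration
tests:

* The genome-wide spread is only estimable if the genome spans **many
  smoothing bandwidths** (the fitted field has roughly one independent
  value per bandwidth).  Scans of a region only a few bandwidths long
  have essentially undefined thresholds.
* The realized threshold is data-dependent.  Published values for this
  statistic (e.g. 0.26 for SNPs and 0.30 for InDels in the rapeseed
  multi-silique study) are properties of those data and are not
  reproducible from desk-scale simulations.

## Region calling and arithmetic

Maximal runs of consecutive markers at or above the threshold span
regions from their first to their last supporting marker; runs on the
same chromosome separated by at most `merge_gap` (default 200 kb,
matching the scale at which published nearby regions were reported as
distinct at 140 kb apart) are merged; regions with fewer than
`min_markers` supporting markers (default 10) are discarded — single
markers should never define a candidate region, though `min_markers =
1` reproduces pipelines that allowed 0.07-Mb regions.  Boundaries snap
outward to `bin_bp` bins (default 10 kb), reflecting the round
coordinates in which candidate regions are conventionally reported.

Regions are **half-open** `[start, end)` intervals, so the size of a
region is exactly `end - start` — the only convention under which
printed coordinates such as 28,990,000–33,790,000 reproduce their
printed 4.8 Mb size — and BED export writes coordinates verbatim.
Genes and variant sites stay 1-based inclusive; overlap logic converts
at the boundary and requires at least 1 bp of overlap, strand-agnostic.

Differential-expression integration is deliberately shallow: the DE
model fit happens upstream (DESeq-style); this package filters its
results table at $|FC| \ge 4$ and adjusted $p \le 0.01$ ("adjusted fold
change of 4" is read as a linear-scale fold-change bound,
$|\log_2 FC| \ge 2$, recorded in output metadata), splits genes by
region overlap, and summarizes direction percentages from counts.

## What the synthetic generator emulates

`simulation_config()` describes a two-NIL pooled re-sequencing
experiment scaled to desk size.  Defaults, chosen once to mirror the
study design the package targets:

| parameter | default | rationale |
|---|---|---|
| genome | one 30-Mb chromosome | desk-scale stand-in for one chromosome arm |
| causal region | 3 Mb at 13.5–16.5 Mb | one introgressed divergent segment |
| `divergence_d` | 1 | NILs are fixed for alternative alleles at the locus |
| `linkage_decay_bp` | 2 Mb | linear decay of divergence with distance |
| `mean_depth` | 40 | 40x average pool coverage, Poisson, truncated at 1 |
| `snp_density`, `indel_density` | 1/kb, 1/4 kb | ~4:1 SNP:InDel ratio of plant re-sequencing |
| `seq_error` | 0.005 | post-filter short-read error scale |
| `background_het` | 1 | marker ascertainment: retained markers segregate |
| `n_degs`, enrichment | 129, 39/129 | DE table of the emulated study |

The genetic model is the simplest one consistent with NILs: a fixed
shared background plus one divergent introgression.  At trait-linked
markers the single-silique pool's true alt frequency is 0 and the
multi-silique pool's is $d \cdot w$ with $w$ the linkage weight.
Background markers segregate at a frequency drawn uniformly in
(0.1, 0.9) **shared by both pools**: a marker table only contains sites
retained as informative after filtration, and shared residual
polymorphism sampled binomially in both pools is what null ED noise
actually is.  This matters statistically: if background sites were
noiseless (frequency 0 in both pools, as a fully literal NIL reading
would have it), the null fitted distribution would be degenerate and no
center + spread threshold would be defined; if only a small fraction
segregated, window means of the heavily skewed $ED^5$ would themselves
be skewed and the 3-SD rule miscalibrated.

The generator does **not** model pedigree structure, recombination
break points, mapping-function linkage decay (decay is linear), read
simulation, base-quality structure, or reference bias.  Passing the
recovery tests therefore demonstrates that the scan statistics and
calling logic behave as designed under the assumed noise model — not
that the pipeline is robust to artefacts of real short-read data.

## Numerical and degenerate-input choices

* `fit_profile` windows always contain the site itself, so weights never
  sum to 0; a single-site series returns its raw value.
* Zero-total-depth and missing-AD sites are dropped (and counted) at
  VCF read time; `depth_frequencies` refuses zero totals.
* Thresholds require at least 2 fitted values; direction percentages of
  an empty DEG set are `NA`, not 0.
* Ties at the threshold count as "above" (`fitted >= threshold`).
* Multiallelic sites keep their full allele-depth vectors; the ED
  formula consumes vectors of any length $\ge 2$.
* Sub-generators are seeded as `seed`, `seed + 1`, ... so a dataset is
  reproducible from one master seed, and every generator restores the
  caller's RNG state.

## Problem sizes used in validation

The packaged tests validate against brute-force oracles (direct
$O(n^2)$ summation for the fit, two-pass mean/SD for the threshold,
per-base membership for interval operations) at up to 1,000 sites and
10-kb toy chromosomes, and run seeded calibration studies at the study
scale the generator emulates: 20 null replicates of ~10,000 SNP sites
(no divergence) for threshold calibration, and 40 replicates of the
default 30-Mb / 3-Mb-causal configuration for recovery.  On the null
replicates fewer than 1% of fitted values exceed the classical
mean + 3 SD threshold and the median replicate calls no region; in the
recovery replicates the top-peak SNP region overlaps the true causal
interval and the SNP/InDel intersection is non-empty.

## Worked example

```{r example}
cfg <- simulation_config(chromosomes = c(A09 = 8e6),
                         causal_regions = data.frame(chrom = "A09",
                                                     start = 3e6,
                                                     end = 4.5e6),
                         linkage_decay_bp = 1e6,
                         n_genes = 800, n_degs = 40,
                         deg_enrichment_inside = 0.5, seed = 42)
dataset <- simulate_bsa_dataset(cfg, tempfile("edscan"))
report <- run_pipeline(dataset$vcf, dataset$gff3, dataset$deg,
                       bandwidth = 5e5)
report
```

```{r plot, fig.width = 6, fig.height = 4}
fit <- ed_scan(dataset$sites, bandwidth = 5e5)
plot(fit, class = "SNP")
```

## Known limitations

* No p-values: the ED scan is a descriptive threshold rule, not a
  calibrated test; permutation nulls are out of scope.
* The threshold is genome-wide per class; strong signals shift it
  (robust default mitigates, not eliminates).
* Variant-effect classes (non-synonymous, frame-shift) are consumed
  from annotations if present, never predicted.
* Upstream of the VCF (alignment, duplicate marking, calling) and the
  DE model fit are out of scope by design.
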