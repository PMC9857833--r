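---
title: "Euclidean-distance association mapping for two-bulk RNA-seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Euclidean-distance association mapping for two-bulk RNA-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edbsa)
```

## The method

Bulked segregant RNA-seq (BSR-seq) maps a quantitative trait by sequencing
pooled RNA from the two phenotypic extremes of a segregating population.
Away from the causal locus the two bulks are random draws from the same
population and their allele frequencies agree up to sampling noise; near the
causal locus, truncation selection on the trait drags the bulks' allele
frequencies apart. `edbsa` quantifies this per variant locus with the
Euclidean distance between the bulks' base-frequency vectors:

$$
\mathrm{ED} = \sqrt{(A_H - A_L)^2 + (C_H - C_L)^2 + (G_H - G_L)^2 + (T_H - T_L)^2},
$$

where $X_H$ and $X_L$ are the frequencies of base $X$ among the reads of the
high- and low-phenotype bulk. ED is 0 for identical pools and $\sqrt{2}$ at
full opposite fixation of a biallelic site. Indel loci, which have no
four-base frequency vector, use the same distance over their two-allele
$\{\mathrm{REF}, \mathrm{ALT}\}$ vectors; by default they are excluded from
the association profile but still counted when regions are annotated.

Raw ED values are raised to the fifth power (`k = 5`, configurable in
`ed_scores()`). Because $0 \le \mathrm{ED} \le \sqrt{2}$, the transform is
close to an indicator for large distances: for $0 < e_1 < e_2$,
$(e_2/e_1)^5 > e_2/e_1$, so background noise is compressed far more than
signal. The powered scores are then smoothed (`fit_profile()`) by averaging
over either all loci of a transcript (`per_feature` mode, natural when reads
were aligned to a transcriptome) or a sliding genomic window
(`sliding_window` mode, 1 Mb windows advanced by 100 kb by default —
candidate regions in this design are megabase-scale, and a 10:1
window-to-step ratio keeps region boundaries at 100 kb resolution).

The association threshold (`compute_threshold()`) is

$$ T = \mathrm{center}(\hat f) + m \cdot \mathrm{SD}(\hat f), $$

over the fitted values $\hat f$, with the median as the default center
(robust to the signal windows themselves; the mean is available), $m = 5$,
and the population standard deviation (divisor $n$). The threshold is
computed genome-wide rather than per chromosome: per-chromosome thresholds
would make a chromosome's own QTL inflate only its own null spread, which is
the less conservative choice with a handful of chromosomes. Maximal runs of
at-or-above-threshold entries (comparison is `>=` with no floating
tolerance, so results are deterministic) are merged across gaps up to one
window size and reported as candidate regions with their peak fitted value,
overlapping gene models (inclusive coordinates: a gene abutting a region
boundary counts), and SNP/indel tallies (`extract_regions()`,
`annotate_regions()`).

## Variant filtering

`filter_variants()` applies, in a fixed order so that removal reports are
reproducible: *missing* (zero depth in either bulk), *multi-allelic* (more
than one alternate allele), *depth* (either bulk below 5 reads, i.e. depth
must exceed 4), *support* (total depth across both bulks below 10), and
*non-polymorphic* (identical allele-frequency vectors; an L∞ tolerance is
configurable and defaults to 0 so any difference counts). Polymorphism is
decided on frequency vectors rather than called genotypes because the
statistic itself never calls genotypes. Note that with the default per-bulk
floor of 5, the total-support rule of 10 can only fire when its threshold is
raised — the two rules are stated separately because each is independently
configurable (`support_scope = "per_bulk"` switches the second to a
per-bulk reading). `intersect_caller_sets()` implements the two-caller
consensus step, keying loci on (chrom, pos, ref, alt-set) and keeping the
first caller's depths; the pipeline applies intersection before filtering,
so the filter report describes the consensus set.

## The simulator

`simulate_population()` emulates the study design the pipeline targets: a
single highly heterozygous, self-incompatible mother pollinated by unknown
donors, giving ~300 F1 half-sib progeny. Concretely:

* **Markers.** Uniformly placed SNPs (5,000 per chromosome on two 150 Mb
  chromosomes by default — chromosome arms of this size match the
  megabase-scale candidate intervals the method reports); the mother is
  heterozygous at a configurable fraction (default 0.8, reflecting a highly
  heterozygous outbred tree) and always at the causal locus.
* **Transmission.** Maternal gametes follow a Markov chain of haplotype
  origin with Haldane crossover probabilities at a fixed map density
  (default 2.5 cM/Mb); the alternate allele rides haplotype 1 at every
  heterozygous marker. Paternal alleles are independent Bernoulli draws at
  the donor-pool frequency (default 0.3): the donor pool is modelled as
  panmictic, without donor identity or donor-side linkage. An `"f2"` mode
  instead draws both gametes from heterozygous-parent chains.
* **Trait.** `seed_ratio = baseline + effect * (dose - E[dose]) + noise`,
  truncated to [0, 1], with baseline 0.34, additive effect 0.06 per
  alternate copy and environmental SD 0.05. The effect is centered at the
  expected dosage so that the population mean equals the baseline regardless
  of the QTL parameters — the baseline is the population's descriptive mean,
  not an ancestral-genotype value. With these defaults the population spans
  roughly 15–50% seed ratio and the QTL explains ~40% of the trait variance.
* **Correlated traits.** Fruit weight ($53 - 75(r - 0.34)$ g), pericarp
  thickness ($5.15 - 14(r - 0.34)$ cm) and seed number ($8 + 10(r - 0.34)$)
  are linear in the seed ratio plus independent noise, with loadings chosen
  once so that 20-plant extreme bulks reproduce the trait contrasts typical
  of this design (high bulk ≈ 44 g / 3.5 cm vs low bulk ≈ 62 g / 6.9 cm);
  seed weight is exactly `seed_ratio * fruit_weight`, which enforces the
  phenotype invariant and yields the expected sign pattern of correlations
  (+seed weight, +seed number, −fruit weight, −pericarp).
* **Sequencing.** For each marker and bulk the true pool frequency is the
  mean allele dosage of the bulk's plants over two; observed counts are
  Binomial(depth, frequency) at a fixed 100× depth, with a 0.001 per-read
  error rate re-assigning reads uniformly to the other three bases
  (implemented as exact multinomial sampling via sequential conditional
  binomials). Equal RNA contribution per plant is assumed — expression
  differences between genotypes, allele-specific expression, and
  depth variation across loci are *not* modelled.

What passing simulation-based tests shows, therefore, is that the chain
selection → linked allele-frequency divergence → ED profile → threshold →
region recovers a planted additive locus under idealised pooled sequencing.
It does not show robustness to expression-driven depth variation,
allele-specific expression, mis-alignment around indels, or reference bias,
all of which affect real RNA-seq bulks.

## Numerical and degenerate-input choices

* Frequencies at zero depth are an error, never silently 0; such loci must
  be removed by the missing-data filter, and `ed_scores()` refuses them.
* A removed locus is attributed to the first failing rule in the fixed
  order above, making filter reports order-independent of the input.
* Bulk selection breaks seed-ratio ties by plant id, and the low bulk is
  drawn from the plants left after the high bulk, so an exact half/half
  split partitions the population deterministically.
* Empty windows are omitted from profiles rather than reported as 0 — a
  windowed mean of nothing is undefined, and zeros would distort the
  threshold's center and SD.
* Internal coordinates are 1-based inclusive throughout (VCF/GFF3
  convention); conversion to 0-based half-open happens only when writing
  BED.
* Identical seeds give byte-identical pipeline outputs; every stage writes
  a run-metadata JSON with parameters, seed and input checksums.

## Known limitations

**The +5 SD threshold does not control the genome-wide null.** With
20-plant bulks, the bulk-composition component of an allele-frequency
difference has SD ≈ 0.11 and is shared along linked haplotype blocks, so
window means of powered ED form a long-range-correlated, heavy-tailed
random field with only a few dozen effectively independent values per
genome. In any finite sample the extreme can sit many sample-SDs above the
median (up to $\sqrt{n_\mathrm{eff}}$), and with the fifth-power transform
concentrating variance in the largest values it routinely does: simulations
with a zero-effect locus produce a small number of spurious
megabase-scale regions in most replicates rather than none. The
median + 5 SD rule should be read as a ranking device that isolates the
strongest peaks of a profile that does contain signal, not as a calibrated
significance test; candidate regions always require independent validation.
Permutation- or simulation-based thresholds are the principled alternative
and are out of scope here.

Other limitations: the statistic has no confidence intervals (no
G-statistic or Δ(SNP-index) machinery); no LOESS smoothing; expression
classification is descriptive, with no replication there is no
differential-expression test; and the simulator's donor pool ignores
population structure.

## Problem sizes used by the test-suite

Unit tests run on populations of 100 plants with 2 × 400–600 markers on
20–60 Mb chromosomes; end-to-end recovery checks use the full default
design (300 plants, 2 × 5,000 markers on 150 Mb chromosomes, 20-plant
bulks, 100× depth) across 20 seeded replicates each for a planted QTL
(effect 0.06) and a zero-effect control. These sizes were chosen as the
smallest that exercise each property cleanly.
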