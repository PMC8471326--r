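---
title: "Splicing-guided aggregation of low-frequency variants: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splicing-guided aggregation of low-frequency variants: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceagg)
```

## The problem

Low-frequency variants (minor allele frequency below 5%) are individually
too rare to test for molecular effects at attainable sample sizes. When the
phenotype of interest is the splicing of one exon, however, variants can be
pooled by *mechanism*: any variant predicted to destroy a splicing
regulatory element (SRE) in the region that controls that exon is a
candidate for the same downstream consequence, so carriers of *any* such
variant can be aggregated into one group. `spliceagg` implements this
splicing-guided aggregation end to end: SRE loss-of-function annotation,
percent-spliced-in (PSI) quantification from junction reads, a
permutation-validated regression of PSI on the aggregated carrier group,
and a downstream differential-expression contrast between high- and
low-skipping samples.

The motivating application is an exon that encodes a ligand-binding domain
of a microglial immune receptor and is skipped in a small fraction of
transcripts in the human frontal cortex, with cognitively normal (CN) and
Alzheimer's disease (AD) donors from two brain-bank cohorts covering three
brain regions. The package itself is generic: it takes any single-transcript
gene model, any internal exon, and user-supplied hexamer catalogues.

## The splicing unit and the functional-variant definition

For a target internal exon, the *splicing unit* is the genomic region in
which variants can plausibly act on that exon's splicing in cis: the exon
itself, its two flanking introns, and the two neighboring exons. Variant
positions inside the unit are classified exonic or intronic by the exon
intervals of the one transcript model in use.

SREs are modeled as exact hexamer motifs in three classes — exonic splicing
enhancers (ESE), exonic splicing silencers (ESS) and intronic splicing
enhancers (ISE). A single-nucleotide variant at position $p$ has up to six
reference 6-mers overlapping it (window starts $p-5, \dots, p$). The variant
is **functional** if for some window the reference 6-mer is a perfect member
of an applicable motif class (ESE or ESS for exonic positions, ISE for
intronic ones) while the same window carrying the alternative allele is not
a member of that class: the allele *loses* the SRE. Design choices worth
stating explicitly:

* **Loss only.** Motif gain (an alternative allele creating a motif) is not
  scored; functionality is defined solely as loss of a reference motif.
* **No directional sign.** ESE, ESS and ISE losses all count uniformly as
  "loss of SRE function"; the test downstream is two-sided.
* **Same-class membership.** The alternative hexamer is compared against
  the class set of the matched reference hexamer; membership in a different
  class does not rescue the loss.
* **SNVs only.** Hexamer windowing is undefined for indels; they are
  reported with a warning and marked non-functional.
* **Strand.** Motif matching happens in the sense of the pre-mRNA: for
  minus-strand genes the locus is reverse-complemented (and alleles
  complemented) before windowing. The suite verifies that annotating a
  minus-strand gene equals annotating the reverse-complemented locus as
  plus strand.

Motif catalogues ship as plain text (one 6-mer per line per class) and are
entirely user-configurable; the package does not bundle published
catalogues.

## PSI from junction reads

The exon's inclusion level per sample is estimated from junction-spanning
reads: `ijc` reads supporting the two inclusion junctions
(upstream–target and target–downstream) and `sjc` reads supporting the one
skipping junction. Because the inclusion isoform feeds two junctions and
the skipping isoform one, the default estimator length-normalizes:

$$\widehat{\psi} = \frac{ijc/2}{ijc/2 + sjc}.$$

The unnormalized form `ijc / (ijc + sjc)` is one flag away
(`length_normalize = FALSE`) since junction-counting conventions differ
between quantification tools. Samples with fewer than `min_reads` total
junction reads (default 10) are reported as missing; no coverage filter is
forced beyond that. The estimator is exact at the boundaries (all skipping
reads give 0, all inclusion reads give 1) and strictly monotone in each
count.

## Carrier aggregation and the association model

From the retained variants (polymorphic, MAF strictly below the threshold,
default 0.05; allele frequencies are computed from the combined cohort, and
missing genotypes leave the denominator and count as non-carrier), four
groups derive from two flags per sample:

* *variant group*: at least one ALT allele at at least one retained
  low-frequency variant; complement: *non-variant group*;
* *functional variant group*: at least one ALT allele at at least one
  functional variant; complement: *non-functional variant group* (which
  includes the non-variant samples).

The mega-analysis pools samples across regions and cohorts into one
ordinary least squares regression of PSI on the 0/1 group indicator, with
categorical covariates expanded to indicator sets. The default covariate is
`region`; in the emulated two-cohort design each cohort contributes
disjoint regions, so region indicators subsume cohort and including both
would be collinear (the fit detects and names collinear columns rather
than silently dropping them). Covariates constant within a stratum (e.g.
diagnosis inside the AD stratum) are dropped with a message. Without
covariates the fit reduces exactly to the pooled-variance two-sample
t-test, which the suite checks to 1e-10. P-values are two-sided throughout.
Samples appearing as multiple region-level rows are treated as independent
rows, matching a pooled mega-analysis; collapsing to one row per subject is
the caller's prerogative upstream.

**Permutation validation.** The observed analytic p-value is validated by
re-assigning the "functional" label at random *within the variant group*:
each of the `b` permutations (default 1000) draws, uniformly without
replacement, as many pseudo-functional samples from the variant group as
the observed functional group holds, refits the identical regression, and
records its p-value. Non-variant samples are never relabeled — the
permutation asks whether *which* variants a carrier has matters, given that
they carry something. The empirical p-value is $(r + 1)/(b + 1)$ with $r$
the count of permutations at or below the observed p (ties count as
extreme; the raw count is also reported). The additive smoothing avoids
zero p-values; the floor is $1/(b+1)$.

Stratified results (all samples, AD only, CN only) are reported as one row
per stratum; a stratum in which a group is empty is flagged not-testable
rather than raising.

## Downstream differential expression

Samples are split on PSI quartiles (linear interpolation, the default
empirical quantile): PSI strictly below the first quartile forms the
**high-skipping** group, PSI at or above the third quartile the
**low-skipping** group. Two deliberate choices: the naming follows PSI
semantics (low PSI = more skipping), and the top comparison is `>=`
because for a near-constitutive exon the third quartile typically equals
the maximum (PSI = 1), making a strict "greater than" empty.

Per gene, a Wilcoxon rank-sum test compares the two groups: exact two-sided
p-values when both groups have at most 8 samples and the values are
tie-free, otherwise the normal approximation with midrank tie correction
and continuity correction (genes with fully tied values carry no rank
information and get p = 1). Fold change is the ratio of linear-scale group
means stabilized by a pseudocount (default 1e-6), thresholded symmetrically
(> 2 or < 1/2). Significance requires Benjamini–Hochberg FDR q < 0.05 and
the fold-change criterion.

Gene-set over-representation is a one-sided hypergeometric upper-tail test
per set against the background of all genes in the expression matrix (an
external database's internal background would not be reproducible), BH
corrected across sets, significant at q < 0.05. Sets are read from GMT
files and intersected with the universe before testing.

## The synthetic-data generator

Every stage is testable without controlled-access data: the generator emits
a complete ground-truthed dataset (FASTA, GTF, VCF, junction counts,
phenotypes, expression, motif files, ground-truth JSON). What it emulates,
and the defaults chosen as the study conditions:

* a 5-exon gene (exons 150 bp, introns 300 bp) with the second exon as the
  skipping target;
* random disjoint hexamer catalogues (40 per class);
* 20 low-frequency SNVs in the splicing unit with MAFs uniform on
  0.001–0.05, of which 30% are planted to destroy an SRE hexamer
  (construction is verified by re-running the scanner: the planted
  functionality must be recovered exactly, or the generator aborts), plus
  2 common variants (MAF 0.10–0.30) so the frequency filter has work to do;
* Hardy–Weinberg genotypes with no linkage disequilibrium (the aggregation
  ignores LD); genotype vectors observed monomorphic are redrawn so every
  planted variant can define carriers, a slight upward bias on the smallest
  MAFs that is irrelevant to the analyses tested;
* latent PSI $\psi_s = \mathrm{clamp}(\psi_0 + \delta\,[\text{carrier} \times
  \text{gate}] + \varepsilon_s,\, 0, 1)$ with baseline $\psi_0 = 0.90$
  (the scale observed for a mostly included exon in frontal cortex), shift
  $\delta = -0.05$ in functional carriers, Gaussian noise
  $\sigma = 0.02$; the gate restricts the effect to all carriers, AD
  carriers only, or nobody (null data);
* junction reads: total $\sim$ Poisson(depth = 100); inclusion reads
  $\sim$ Binomial(total, $2\psi/(1+\psi)$), so the length-normalized
  estimator is unbiased for $\psi$;
* 1000 samples, 67% labeled AD, regions DLPFC/FP/IF at 56/23/21% with
  cohort determined by region;
* 2000 log-normal expression genes with 50 planted fold-4 DEGs in the
  high-skipping group.

Clamped Gaussian noise on latent PSI was chosen over a beta model for
transparency; at $\sigma = 0.02$ around 0.90 the clamp is essentially never
active. All outputs are pure functions of the configuration including its
seed; the suite asserts byte-identical regeneration.

What the generator does *not* emulate — and hence what passing tests do not
show about real data: read-level artifacts (mapping bias, duplicates),
linkage disequilibrium and population structure, overdispersed or
batch-confounded expression, repeated measures of one subject across
regions, and any realistic motif catalogue. The generator validates the
statistical machinery, not the biology of any particular locus.

## Numerical and degenerate-input choices

* Intervals are 1-based and closed throughout, the convention GTF, VCF and
  the Bioconductor ranges stack share, so no coordinate conversion happens
  at any boundary; the splicing-unit intervals provably tile the span.
* Multi-allelic VCF records are split into one variant per ALT allele,
  each annotated independently.
* Monomorphic variants are dropped by the frequency filter (they cannot
  define carriers); the filter is strict on both sides (0 < MAF <
  threshold).
* The regression requires at least two samples per group and errors with
  "degenerate grouping" otherwise; quartile grouping errors when either
  skipping group is empty (all PSI identical).
* Permutation draws use R's default generator; a fixed seed gives a
  bit-identical result object.
* The quantile type, pseudocount, thresholds, permutation count and
  coverage filter are all exposed as arguments with the defaults above.

## Problem sizes used by the test suite

The suite validates calibration and recovery by simulation at sizes chosen
to make the checks sharp yet quick on a single CPU: scanner-oracle
equivalence on 1000 random instances; null calibration on 500 datasets of
200 samples with 200 permutations each (rejection rate at 0.05 must sit
inside the binomial 95% CI for both the analytic and the empirical p);
parameter recovery over 100 replicates of 1000 samples with ~5% functional
carriers (95% CI coverage of the planted −0.05 in at least 90); and an
AD-only effect surfacing as a smaller AD-stratum p than CN-stratum p in at
least 95 of 100 replicates. Observed DE sensitivity under the planted
fold-4 signal is recorded as a suite baseline, not asserted against any
external number.

## Limitations

Perfect-match hexamers are a deliberately simple SRE model: no
position-specific scoring, no splice-site strength, no branch point, no RNA
secondary structure, no machine-learned splicing impact. Aggregation treats
all functional variants as exchangeable and ignores dosage (one ALT allele
suffices). The regression assumes independent rows and homoskedastic
errors; repeated brain regions per subject would call for a mixed model,
which is out of scope. PSI is estimated for one pre-specified event from
junction counts; event discovery and transcript-level deconvolution belong
to upstream tools.
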