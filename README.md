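# spliceagg

Splicing-guided aggregation of low-frequency variants for exon-skipping
analysis.

## The problem

Low-frequency variants (MAF < 5%) are individually too rare to associate
with molecular phenotypes at realistic sample sizes. When the phenotype is
the splicing of one exon, variants can instead be pooled by mechanism:
within the exon's *splicing unit* — the target exon, its flanking introns,
and the two neighboring exons — any variant whose alternative allele
destroys a splicing regulatory element (SRE) hexamer is a candidate for the
same splicing consequence. `spliceagg` aggregates carriers of at least one
such *functional* variant into a single group and tests the group's effect
on the exon's inclusion level. The motivating setting is an exon-skipping
event in a brain-expressed immune receptor gene in cognitively normal (CN)
and Alzheimer's disease (AD) donors across three frontal-lobe brain
regions from two cohorts; the package is generic over gene model, exon and
motif catalogues.

## What it computes

- **SRE loss-of-function annotation.** A SNV at position $p$ is functional
  iff some reference 6-mer overlapping $p$ (window starts $p-5,\dots,p$,
  oriented to the gene strand) perfectly matches a motif of the applicable
  class (ESE/ESS for exonic positions, ISE for intronic) while the same
  window with the alternative allele does not.
- **PSI quantification.** Percent spliced in from inclusion (`ijc`) and
  skipping (`sjc`) junction reads,
  $\widehat\psi = \frac{ijc/2}{ijc/2 + sjc}$ (inclusion supported by two
  junctions, skipping by one), missing below a coverage floor.
- **Aggregated association.** OLS mega-analysis of PSI on the
  functional-carrier indicator with categorical covariates, two-sided t
  p-values, diagnosis-stratified results, and a permutation validation that
  re-draws the functional label uniformly within the variant group
  ($\mathrm{empirical}\ p = (r+1)/(b+1)$).
- **Downstream DE.** High-/low-skipping groups from PSI quartiles
  (PSI < Q1 vs PSI ≥ Q3), per-gene Wilcoxon rank-sum tests, BH-FDR,
  fold-change filter, and hypergeometric gene-set over-representation
  against user-supplied GMT sets.
- **Ground-truthed simulation.** A generator emitting FASTA, GTF, VCF,
  junction counts, phenotypes, expression and motif files with planted,
  scanner-verified functional variants, a configurable latent PSI shift in
  carriers, and planted DEGs — so the whole pipeline is testable without
  controlled-access data.

## Worked example

```r
library(spliceagg)

cfg <- sim_config(seed = 42, n_samples = 400, n_genes_expr = 500,
                  n_planted_degs = 20)
paths <- write_dataset(simulate_dataset(cfg), "demo")

summary <- run_pipeline(list(
  fasta = paths$fasta, gtf = paths$gtf, vcf = paths$vcf,
  junctions = paths$junctions, samples = paths$samples, expr = paths$expr,
  motifs = list(ese = paths$ese, ess = paths$ess, ise = paths$ise),
  gene_id = "simGene", out_dir = "demo/out",
  seed = 42, permutations = 1000))

summary$association[, c("stratum", "n_group1", "n_group0", "beta", "se", "p_value")]
#>   stratum n_group1 n_group0    beta      se  p_value
#> 1     all      101      299 -0.0358 0.00535 7.62e-11
#> 2      AD       78      198 -0.0318 0.00605 2.88e-07
#> 3      CN       23      101 -0.0445 0.01123 1.25e-04
summary$permutation
#> $b           1000
#> $n_extreme   0
#> $empirical_p 0.000999001
summary$de$n_significant
#> [1] 20
```

Reading the output: of 400 samples, 101 carry at least one of the 4
planted SRE loss-of-function variants that survive the MAF filter. Their
mean PSI is 0.036 lower than the non-functional group's after adjusting
for brain region (the generator planted a −0.05 latent shift; junction
sampling attenuates the raw contrast), a difference that no random
re-assignment of the functional label within the variant group matched in
1000 permutations (empirical p = 1/1001). All 20 planted fold-4 DEGs are
recovered between the PSI-quartile skipping groups at FDR < 0.05. Stage
outputs (`annotations.tsv`, `groups.tsv`, `psi.tsv`, `association.tsv`,
`deg_results.tsv`, `summary.json`) land in `demo/out`.

A thin command-line wrapper is available at `inst/scripts/splag.R`
(`splag.R run --config run.yaml`, `splag.R simulate --seed 1 --out dir`).

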