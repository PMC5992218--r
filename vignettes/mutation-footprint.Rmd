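---
title: "Tracing the temporal footprint of POLE proofreading loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing the temporal footprint of POLE proofreading loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polefoot)
library(dplyr)
```

## The scientific problem

Tumours carrying mutations in the exonuclease (proofreading) domain of DNA
polymerase epsilon (*POLE*) — most prominently p.P286R and p.V411L — are
extreme hypermutators. Their mutational process is not only intense but
*biased*: it produces C>A transversions at TCT, C>T transitions at TCG and,
to a lesser degree, T>G at TTT. That bias is a clock of sorts. A gene that
was already mutated before proofreading failed carries ordinary
substitutions; a gene mutated after carries the biased footprint. Comparing
the footprint gene by gene therefore orders somatic events relative to the
moment proofreading was lost, turning an endpoint mutation catalog into a
partial timeline — evidence, for instance, that *POLE* and *PTEN* mutations
precede the hypermutation storm rather than follow it.

`polefoot` implements that analysis as a tested pipeline:

1. **Cohort classification.** Samples whose nonsynonymous SNV count strictly
   exceeds 500 are hypermutators; hypermutators whose spectrum is C>A-rich,
   C>G-poor and enriched for the propensity classes form the POLE category,
   the rest are common hypermutators. MSI-like common hypermutators can be
   flagged by refitting signature exposures (non-negative least squares
   against a user-supplied 96-context signature matrix; MSI-high when the
   MSI-like exposure exceeds 0.5).
2. **Pattern counting.** Every SNV is canonicalized into one of the 96
   pyrimidine-centred trinucleotide classes. *Propensity mutations* are
   `TCT>TAT` and `TCG>TTG`; `TTT>TGT`, although enriched, is excluded from
   scoring because T>G substitutions can also arise from dNTP-pool
   imbalance.
3. **The propensity score.** For a gene $g$ and tumour group $G$,

   $$\mathrm{FMP}_G(g) = \frac{\text{propensity mutations in } g \text{ across } G}
   {\text{all mutations in } g \text{ across } G} \times 100, \qquad
   \mathrm{PS}(g) = \mathrm{FMP}_{\text{POLE}}(g) - \mathrm{FMP}_{\text{common}}(g).$$

   Subtracting the common-hypermutator FMP removes the background rate at
   which propensity-class substitutions occur without a POLE mutant. PS is
   a ratio statistic, so it is independent of coding length.
4. **Gene selection.** Before scoring, genes with POLE-category-specific
   mutations are selected: a two-sided Fisher exact test on the per-gene
   2×2 table of mutated samples by group, Benjamini–Hochberg adjusted
   (q < 0.05), with enrichment required to point toward the POLE category;
   genes with fewer than 10 nonsynonymous SNVs in the POLE group are then
   removed as too thinly sampled.
5. **The inflection point.** The retained genes' PS values are plotted
   against standard-normal quantiles (a Q-Q plot). If every selected gene
   were equally susceptible the points would follow one line; instead a
   low-PS subpopulation bends the curve. A continuous one-breakpoint
   segmented regression, profiled over candidate breaks, locates the
   inflection point (IP); a Davies-type maximal-|t| test bounds the
   significance of the slope change; and a percentile bootstrap over genes
   yields a 99.999% confidence interval for the IP.
6. **Three periods.** Genes below the CI are POLE-*independent* (mutated
   before or regardless of proofreading loss), genes at or above its upper
   bound are POLE-*dependent*, and genes inside the CI are *indefinite* —
   the CI is deliberately used as a buffering border rather than a sharp
   threshold.
7. **Repair-pathway expression.** Homologous-recombination (BRCA1, RAD51,
   BRCA2, RAD54L, RAD52) and non-homologous end-joining (LIG4, PRKDC,
   XRCC4, XRCC6) signatures are scored as the mean normalized log
   expression of the member genes, compared between groups with Welch's
   t-test (Bonferroni-adjusted across signatures), and correlated with
   individual genes such as *TTK*.

## A worked run on a synthetic cohort

Everything below runs from the package's own generator; no external data
are needed.

```{r cohort}
cfg <- simulation_config()
sim <- simulate_cohort(cfg, seed = 1)
ann <- classify_samples(sim$catalog)
count(ann, group)
```

```{r ps}
sel <- select_pole_specific_genes(sim$catalog, ann)
genes <- filter_low_mutation_genes(sel, sim$catalog, ann)
ps_tab <- compute_ps_table(sim$catalog, ann, genes = genes)
ip <- bootstrap_ip_ci(ps_tab$ps, ps_tab$gene, n_boot = 500, seed = 2)
ip
periods <- assign_periods(ps_tab, ip)
count(periods, period)
```

```{r qqplot, fig.width = 6, fig.height = 4}
autoplot(ip)
```

Recovery against the generator's ground truth:

```{r recovery}
inner_join(periods, sim$truth$genes, by = "gene") |>
  count(class, period) |>
  tidyr::pivot_wider(names_from = period, values_from = n, values_fill = 0)
```

## What the generator emulates — and what it does not

The synthetic cohort reproduces the *statistical* structure the analysis
depends on, not genomic realism:

- **Two-tranche mutagenesis in POLE tumours.** Each POLE-category sample
  draws a clonal pre-onset tranche (10% of its mutations by default) from a
  background process, then a post-onset tranche from the POLE-like process.
  Pre-onset VAFs are Beta(8, 8) scaled by purity 0.8; post-onset Beta(2, 8),
  so the biased classes sit at lower allele fractions, mirroring their later
  acquisition.
- **Process spectra.** The background process is transition-dominant with a
  low C>G share; the POLE-like process adds `enrichment/96` (default
  enrichment 300) of probability mass split 0.60/0.25/0.15 over
  TCT>TAT/TCG>TTG/TTT>TGT; the MSI-like process concentrates C>T at NpCpG
  with little weight on TCG>TTG so that MSI does not mimic the propensity
  pattern. With these defaults the simulated POLE group has a propensity
  fraction near 0.5 and the common group near 0.035.
- **A susceptibility continuum.** Late genes carry a per-gene
  susceptibility λ ∈ [0.9, 1] (the fraction of their post-onset mutations
  drawn from the POLE-like process). A 260-gene *shoulder* subpopulation of
  the background universe has intermediate susceptibility, dense just below
  the late floor and thinning downward. This shoulder is what makes the PS
  Q-Q plot a smooth inflected curve rather than two disconnected clusters —
  the geometry the one-break segmented model describes and the indefinite
  buffer period exists for. Without it, no single-break continuous fit can
  place the inflection between the clusters.
- **A wide background universe.** 3000 background genes (lengths only, no
  bundled sequences) absorb untargeted mutations so Fisher-based gene
  selection has genuine negatives. Because this universe (~5 Mb) is much
  smaller than a real exome (~35 Mb), per-gene background mutation rates
  are inflated ~7×; the POLE-analog's coding length is set to 2 kb so its
  early-driver retention behaviour survives this compression.
- **Counts at study scale.** 10 POLE / 80 common / 10 non-hypermutator
  samples; per-sample nonsynonymous counts uniform on 1212–16632 (POLE)
  and 500–3000 (common); 414 focal genes with log-normal coding lengths
  (median 1.5 kb). Mutations on focal genes are placed on actual canonical
  motif sites of generated sequences, so motif-composition diagnostics are
  exercised honestly.
- **Paired expression.** Tumour/normal pairs share a per-gene baseline
  (N(8, 1) log2 units) with noise SD 0.5; HR genes are shifted by 1.0 (two
  noise SDs) in POLE tumours, restoration-panel genes by 0.8 of that, and
  the TTK row tracks the per-sample HR mean, producing the strong
  HR–TTK correlation the restoration analysis looks for.

What passing tests on this generator do *not* show: robustness to
variant-calling artefacts, copy-number and purity variation beyond a single
scalar, regional mutation-rate covariates (replication timing, expression),
or selection. The generator draws mutations independently given the gene
and process, so clustered or recurrent hotspot mutations are
under-represented.

## Numerical and design choices

- **Q-Q plotting positions** are `(i − 0.5)/n`; ties in PS are broken by
  gene symbol so coordinates are deterministic.
- **Breakpoint search** profiles the residual sum of squares over the
  observed quantiles between the 5th and 95th percentiles, with the
  continuous-at-the-break parameterisation solved in closed form from
  suffix sums (each candidate costs O(1) after an O(n) pass), which keeps
  the 500-resample bootstrap fast enough to run inside tests.
- **Davies-type test.** The maximal |t| for the slope-change term over the
  candidate grid, with the upper bound
  `2·Φ(−M) + V·exp(−M²/2)/√(8π)` (V the total variation of the t-process).
  The bound assumes iid regression errors; applied to Q-Q data (order
  statistics) the p-value is descriptive rather than calibrated, which is
  why calibration tests use paired regression data.
- **Bootstrap CI** is the percentile interval over gene resamples. At the
  99.999% level with 500–2000 resamples this is essentially the range of
  the bootstrap distribution and is known to under-cover; it is used as a
  buffering band, not a sharp inferential statement, and the level is
  configurable.
- **Period boundaries**: `ps < lower` → independent, `ps ≥ upper` →
  dependent, boundary equality with the upper bound counts as dependent.
- **FMP denominator.** The per-gene-within-group denominator is the
  default (`fmp_denominator = "gene"`); a group-wide denominator is
  available as a switch, since the defining text of the score admits both
  readings.
- **Fisher tables** count mutated samples (not mutation events; switchable)
  and use the two-sided exact p with enrichment toward the POLE category
  required — specific genes are enrichments, not depletions.
- **Test-selection flow**: Shapiro–Wilk on both samples (α = 0.05); if both
  accept, Welch; otherwise the F-test decides between Mann–Whitney (equal
  variances) and Brunner–Munzel (unequal). The mapping of the rank tests to
  the F-test outcome is a policy choice (Brunner–Munzel is designed for
  unequal variances) and is recorded in each result's notes.
- **Missing QC fields** never trigger a variant filter; each skipped
  criterion evaluation is counted and reported, because public or synthetic
  catalogs rarely carry read-level QC.
- **Exposure refitting** is a minimal NNLS fit against a user-supplied
  signature matrix — deliberately not a re-implementation of iterative
  signature-selection algorithms; it exists to flag MSI-like samples.

## Problem sizes used in the test-suite

The packaged tests run the full default cohort (414 focal + 3260 background
genes, ~300k records) three times for period recovery, 100 two-regime
cohorts of 414 genes at 500 bootstrap resamples for CI coverage, 200
replicates of n = 400 for breakpoint recovery, and 2000 null replicates per
statistical test for calibration; unit tests use a reduced cohort (8 POLE /
30 common samples, 60 focal genes). These sizes were chosen so the whole
suite exercises study-scale behaviour while remaining comfortable to run
repeatedly during development.

## Known limitations

- The inflection point of a segmented fit is an estimate of where the
  susceptible bulk begins, not of a biological change point; genes near the
  CI should be read as indefinite, which is the point of the buffer.
- PS requires both groups to have mutations in a gene; genes untouched in
  common hypermutators get `FMP_common = 0` rather than a shrunken
  estimate, so very sparsely mutated genes have noisy PS (hence the
  SNV ≥ 10 filter).
- The Davies p-value on Q-Q data over-rejects and should be treated as a
  descriptive index there.
- The CLI wrapper (`inst/scripts/polefoot.R`) is a thin convenience over
  `run_pipeline()`/`simulate_inputs()`; the R functions are the interface.
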