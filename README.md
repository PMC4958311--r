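# oncofunnel

Comparative oncogenomic driver discovery for murine mammary tumor models.

Murine *Trp53*-null transplant tumors recapitulate three aggressive human
breast cancer subtypes (basal-like, claudin-low, luminal).  `oncofunnel`
implements the analysis that turns multi-omic profiles of such a cohort —
expression microarrays, aCGH copy number, somatic mutations and structural
variants — together with a human segmented copy-number cohort and a pooled
shRNA dropout screen, into per-subtype candidate drug targets, by composing
five filters:

1. **Class-enriched copy-number regions.**  aCGH probes are filtered
   (control intensity > 10, data on > 70% of arrays), averaged in
   consecutive ten-probe windows per chromosome, and tested per subtype
   with a two-class SAM analysis,
   `d(i) = (x̄_in − x̄_out) / (s(i) + s0)`, calibrated by label permutation
   to a false discovery rate of 0%.
2. **Cis-correlation.**  A gene survives only if its expression tracks its
   own DNA copy number (Pearson r ≥ 0.5 across tumors).
3. **Amplifications only.**  Protein products of amplified genes are
   directly targetable; deletions are set aside.
4. **Human conservation.**  Orthologs are called amplified/deleted from SEG
   segmentation at a ±0.3 log2 threshold and tested (two-sided Fisher,
   p < 0.05) for enrichment in human basal-like versus non-basal tumors.
5. **Essentiality.**  A GARP-style score (mean of the two most-depleted
   shRNAs per gene and cell line, permutation p-value) must reach p < 0.05
   in at least 5% of the screen's 29 cell lines (≥ 2 lines).

Every stage logs a per-gene audit record, so each surviving or excluded
gene can be traced to the value that decided it.  The package also builds
subtype expression signatures (SAM FDR 0% up-genes), scores them across
cohorts and species through a homolog map, computes differentiation
scores (stem-like vs mature-luminal) with pooled-variance t-tests,
collapses mutations/SVs to gene level with Fisher subtype enrichment, and
ships a synthetic multi-omic cohort generator with planted drivers,
passengers and signatures that gives every stage a ground truth.

## Worked example

```r
library(oncofunnel)

co <- generate_cohort(cohort_config(seed = 1))
co
#> synthetic_cohort: 2000 genes x 24 murine tumors; 40 human samples; 29 screen lines
#>   planted drivers: 5

rep <- run_funnel(co, seed = 1)
rep
#> funnel_report (3 classes)
#>   BasalEx        20 in-region -> 3 cis -> 2 amplified -> 2 conserved -> 2 essential
#>     candidates: mG02.0103, mG02.0107
#>   ClaudinLowEx   0 in-region -> 0 cis -> 0 amplified -> 0 conserved -> 0 essential
#>   LuminalEx      10 in-region -> 2 cis -> 2 amplified -> 2 conserved -> 2 essential
#>     candidates: mG04.0203, mG04.0207

unlist(co$truth$expected_candidates)
#> mG02.0103 mG02.0107 mG04.0203 mG04.0207
```

The funnel narrows 20 in-region basal genes to exactly the two planted
basal drivers and the ten luminal in-region genes to the two planted
luminal drivers; the claudin-low class is copy-number neutral by
construction and drains at the first stage.  The audit shows *why* each
gene survived or fell — here the planted driver `mG02.0103` versus its
neighboring passenger `mG02.0104`:

```r
aud <- rep$classes$BasalEx$audit
aud[aud$gene %in% c("mG02.0103", "mG02.0104"),
    c("gene", "r", "pass_correlation", "conservation_p", "pass_essential")]
#>        gene      r pass_correlation conservation_p pass_essential
#> 3 mG02.0103 0.8804             TRUE       7.71e-07           TRUE
#> 4 mG02.0104 0.0307            FALSE             NA          FALSE
```

The driver's expression tracks its copy number (r = 0.88), its human
ortholog is basal-enriched (Fisher p ≈ 8e-7) and it is essential in 34% of
screen lines; the passenger sits in the same amplicon but its expression is
independent of dosage (r = 0.03), so it falls at the cis-correlation stage.

Differentiation scores recover the planted stem-to-luminal class ordering
(claudin-low < basal < luminal):

```r
sim <- simulate_differentiation_cohort(seed = 1)
compare_dscores(differentiation_score(sim$matrix, sim$centroids), sim$labels)
#>        class_a      class_b      t        p
#> 1      BasalEx ClaudinLowEx  10.70 4.02e-08
#> 2      BasalEx    LuminalEx  -8.04 1.29e-06
#> 3 ClaudinLowEx    LuminalEx -46.82 8.70e-17
```

## Layout

- `R/` — implementation: `io.R` (TSV/SEG/BED/MAF-lite readers and writers),
  `sam.R` (SAM statistic + permutation FDR), `signatures.R`, `somatic.R`,
  `cna.R` (aCGH pipeline), `human.R` (conservation), `screen.R`
  (essentiality), `funnel.R`, `synthetic.R` (cohort generator).
- `vignettes/driver-funnel.Rmd` — the methods vignette: model details,
  parameter rationale, what the generator does and does not emulate, known
  limitations.
- `tests/testthat/` — unit + property tests with independent brute-force
  oracles, and the end-to-end acceptance suite.
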