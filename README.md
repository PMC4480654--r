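# exonedge

Codon-counting molecular evolution pipeline for studying how **conservation at
exon edges** — the regions where exonic splicing enhancers (ESEs) concentrate —
biases per-gene estimates of dN/dS and the McDonald–Kreitman-style neutrality
index (NI), and how it shapes their correlations with gene expression.

## The problem

In compact, intron-rich plant genomes, most exons are short and a large
fraction of each coding sequence lies within a few dozen codons of an
exon–intron boundary. Splice enhancers make these exon edges unusually
conserved **at synonymous as well as non-synonymous sites**, violating the
assumption that synonymous changes are neutral. That inflates or deflates
per-gene dN/dS and NI, and can masquerade as (or mask) relationships between
evolutionary rate and gene-level covariates such as expression level,
expression breadth, or tissue specificity.

`exonedge` implements the full analysis as a tested, reusable package:

* **Pairwise dN/dS** — equal-weight Nei–Gojobori (1986) counting over gap-free
  codon columns with Jukes–Cantor correction
  `d = -(3/4) ln(1 - (4/3) p)`, the ≥150-aligned-base rule, and explicit
  validity flags (`min_aligned`, `saturated`, `dS_zero`, `internal_stop`).
* **Lineage-specific dN/dS** — per-branch rates on the unrooted three-taxon
  topology `((ingroup1, ingroup2), outgroup)` via most-parsimonious ancestral
  codons (ties averaged uniformly), with the standard branch filters
  `dS < 0.02`, `dS > 2`, `dN > 2`.
* **Neutrality index** — SNPs classified synonymous/non-synonymous against the
  reference CDS and
  `NI = log[(2Ds+1)(2Pn+1) / ((2Dn+1)(2Ps+1))]`
  (+1 pseudo-counts; NI > 0 purifying, NI < 0 positive selection).
* **Edge trimming and randomization tests** — removal of up to 30 codons from
  each edge of every fully aligned, in-frame exon, compared with matched
  random removal of the same number of codons; per-gene numerical P-values
  `p = (s - q + 1)/(s + 1)` over `s` randomizations, and the same test applied
  to cross-gene Spearman correlation strengths (attenuation test).
* **Expression covariates** — tissue-specificity `tau`, expression breadth,
  Z-scores.
* **Correlation battery** — Spearman, partial Spearman controlling for
  expression, Steiger's Fisher-z comparison of dependent correlations, a 2×2
  chi-square on the proportion of genes with dN/dS > 1, Kruskal–Wallis.
* **Splicing index** — alternative-splicing events normalised for transcript
  coverage: the mean event count over 100 random samples of 10 mapped ESTs.
* **Synthetic-data generator** — orthologue trios with exonic structure,
  attempt-and-accept substitution with per-site acceptance (stronger
  constraint within a configurable depth of exon edges), gene-level constraint
  `omega_g` coupled to a simulated expression level through a Gaussian copula,
  within-ingroup polymorphism, and EST chains — with a full ground-truth
  record, so every estimator is testable against known truth.

## Worked example

```r
library(exonedge)

ds <- simulate_dataset(sim_config(n_genes = 300), seed = 20260927)
res <- run_all(ds, "results/pipeline",
               pipeline_config(randomizations = 200), seed = 20260927)
```

prints (via the stage drivers in `analysis/`):

```
pairwise estimates: 278/300 genes valid
lineage ingroup1 branch: 278 genes pass the dS/dN filters
median pairwise omega: 0.171 | median NI: -0.037
```

278 of 300 simulated genes clear the 150-aligned-base rule; the median dN/dS
of 0.171 reflects the generating purifying constraint (median
`omega_g` = 0.2), and the median NI sits near 0 because the simulated
polymorphism experiences the same acceptance regime as divergence. Continuing
with the correlation stage:

```
rho(expression, omega): -0.534 (n=278) untrimmed, -0.311 (n=114) after k=30
expression vs pairwise omega rho=-0.534, vs lineage omega rho=-0.429
dependent-correlation test (steiger-fisher-z): t=-4.47, df=275, p=1.15e-05
attenuation test: |rho_sequential|=0.441 vs random removal, q=200/200, p=0.0050
```

Expression level predicts dN/dS strongly before trimming; removing 30 codons
from each exon edge attenuates the correlation (−0.534 → −0.311), and the
attenuation randomization test confirms the drop is specific to *edge* removal
(every one of 200 matched random removals left a stronger correlation,
p = 0.005). The lineage-specific estimate correlates significantly more weakly
with expression than the pairwise estimate — the dependent-correlation
comparison above.

The numbered drivers reproduce the whole analysis:

```sh
Rscript analysis/01_simulate.R       # writes results/data (FASTA + TSVs)
Rscript analysis/02_run_pipeline.R   # all stage tables -> results/pipeline
Rscript analysis/03_edge_effect.R    # sequential vs random removal summary
Rscript analysis/04_correlation_shift.R
Rscript analysis/05_splicing.R
```

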