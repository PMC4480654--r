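---
title: "Exon-edge conservation and rate estimation: models and methods"
author: "exonedge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exon-edge conservation and rate estimation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exonedge)
```

## Scope and model

`exonedge` estimates per-gene rates of protein-coding sequence evolution and
asks how conservation at exon edges — where exonic splicing enhancers
concentrate — distorts those estimates and their correlations with gene-level
covariates. The package works entirely in codon space: every coordinate is a
0-based, half-open codon index on the ungapped reference CDS, and alignment
construction (BLAST/Smith–Waterman/PRANK and transcript selection) is treated
as an upstream concern.

### Divergence estimators

**Pairwise dN/dS** uses equal-weight Nei–Gojobori counting. Each sense codon
contributes expected synonymous sites
$S(c) = \sum_{i=1}^{3} \tfrac{1}{3}\,\#\{\text{synonymous single-base changes at } i\}$
and $N(c) = 3 - S(c)$; mutations creating stop codons count as
non-synonymous sites. Differences between two codons are averaged over all
orderings of single-step mutational pathways, excluding pathways through stop
codons (if all pathways hit a stop, all are used, each step classified by the
code). Proportions $p_S = S_d/S$, $p_N = N_d/N$ are corrected with
Jukes–Cantor, $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$, and
$\omega = dN/dS$. This counting estimator replaces likelihood codon models
(yn00/codeml): it is fully specifiable and can be verified against exhaustive
enumeration, at the cost of ignoring transition/transversion and
codon-frequency effects. The estimator sits behind a narrow interface
(`estimate_pairwise()`), so a likelihood-based adapter could be swapped in.

**Lineage-specific dN/dS** polarises changes on the unrooted three-taxon
topology `((ingroup1, ingroup2), outgroup)`. The single internal node is
reconstructed per codon column by parsimony over the 61 sense codons (branch
cost = nucleotide Hamming distance); all tied most-parsimonious ancestors are
averaged with uniform weights when branch differences are counted. Replacing
ML ancestral reconstruction with parsimony is a deliberate simplification:
it is exact, desk-scale, and testable by exhaustive enumeration of all 61
candidate ancestors; its adequacy is assessed only on simulated data.

**Filters.** Genes need at least 150 aligned bases (after any trimming);
branches with $dS < 0.02$, $dS > 2$ or $dN > 2$ are flagged invalid
(unreliable ratios, non-orthologues, or saturation). Filters are applied
per branch, with reasons recorded; downstream correlation stages use genes
whose relevant branch is valid. Jukes–Cantor domain failures ($p \ge 3/4$)
invalidate the estimate rather than being clamped, and genes with an internal
stop codon in the reference are excluded from all estimators.

### Neutrality index

SNPs within the focal species are classified against the reference codon
(edits creating or destroying stops are unclassifiable; multiple SNPs in one
codon are classified independently, as haplotype phase is unavailable), and

$$NI = \log\frac{(2D_s + 1)(2P_n + 1)}{(2D_n + 1)(2P_s + 1)}$$

with divergence counts $D_s, D_n$ taken as the raw pathway-averaged
difference counts (not the Jukes–Cantor rates — the index compares counts,
and fractional counts from pathway averaging are admissible). The +1
pseudo-counts keep NI finite for all inputs. The logarithm base (natural by
default) only scales NI; every downstream use is rank- or sign-based and
therefore base-invariant.

### Edge trimming and the randomization test

Trimming operates on the concatenation of a gene's *eligible* exons — fully
aligned (no gap in any species), in frame, and a multiple of three in length —
so trimmed and untrimmed conditions always use the same exon set. The
sequential treatment removes $k$ codons from each edge of every eligible exon
(`both_edges`; an `internal_edges_only` mode exempts the gene's terminal
edges, since splice enhancers flank intron junctions — the choice between
these two readings of "exon edge" is genuinely open and both are provided).
The matched control removes the *same number* of codons uniformly at random
from the same eligible-exon concatenation; this paired design is what makes
the comparison interpretable as an edge effect rather than a length effect.

With $q$ the number of randomizations (out of $s$) in which the sequential
estimate exceeds the random-removal estimate (is lower, for NI; ties do not
count), the numerical P-value is

$$p = \frac{s - q + 1}{s + 1} \in \left[\tfrac{1}{s+1},\, 1\right].$$

One shared removal set per replicate is reused across statistics, so the dN,
dS, dN/dS and NI nulls are computed on identical removals. Replicates whose
estimate is invalid (e.g. the trimmed gene falls under 150 aligned bases) are
dropped from $s$; results with more than 10% invalid replicates are flagged
unreliable. The same machinery applies to cross-gene correlation strengths:
the attenuation test compares $|\rho|$ between a covariate and the
sequentially trimmed statistic against $|\rho|$ recomputed with every gene
randomly trimmed, one random trim per gene per replicate.

### Expression covariates and the correlation battery

Per-gene expression level defaults to the across-tissue mean (maximum
available as an option); breadth counts tissues above a configurable presence
threshold (default 0, i.e. any positive abundance); tissue specificity is
$\tau = \sum_i (1 - x_i/x_{\max}) / (n - 1)$; Z-scores allow cross-platform
comparison. Correlations are Spearman's rho on average ranks with the
t-approximation for p; partial correlations rank-transform all three
variables and apply the standard first-order partial-correlation formula.
Two dependent correlations sharing a variable are compared on Fisher-z
transformed values using Steiger's modification of the Hotelling–Williams
test with df = n − 3 (the specific variant is named in the output metadata,
since "a t-test on z-transformed rho" admits several forms). Missing data are
handled by pairwise-complete deletion, so each correlation reports its own n.
Raw p-values are reported without multiple-testing correction (the analysis
is descriptive; Benjamini–Hochberg q-values can be added by the user).

### Splicing index

Event detection among EST intron chains is deliberately minimal and fully
specified: an event signature is either (i) an unordered pair of distinct,
overlapping intron intervals observed in different chains (one alternative
boundary, counted once per interval pair), or (ii) an intron fully contained
in another chain's mapped extent with no intron of that chain overlapping it
(retention). Chains are compared only over overlapping mapped extents —
absence of an intron outside an EST's extent is not evidence. The
transcript-number normalisation — the step this module exists for — is exact:
the index is the mean event count over 100 random subsamples, without
replacement, of 10 mapped ESTs; genes with fewer than 10 ESTs are excluded.

## The synthetic-data generator

The generator produces the study conditions; it is not a tuning knob. Each
gene receives a geometric number of exons (mean 5) with log-normal codon
lengths (median 53 codons, truncated to [5, 250]) — echoing a compact,
intron-rich genome. A stop-free root CDS is drawn uniformly over sense
codons, and each branch of ((ingroup1, ingroup2), outgroup) evolves by
attempt-and-accept: substitution attempts arrive as a Poisson stream (defaults
0.12 attempts/site on each ingroup branch and 0.35 on the outgroup branch,
giving an ingroup–ingroup divergence in the range typical of congeneric plant
comparisons), each proposing a uniform alternative base; stop-creating
attempts are rejected; synonymous attempts are accepted with probability
$\phi(\text{site})$ and non-synonymous attempts with probability
$\omega_g \cdot \psi(\text{site})$. Within `edge_depth` (10) codons of an
exon edge, $\phi = \phi_{\text{edge}}^{u}$ and $\psi = \psi_{\text{edge}}^{u}$.
The attempt-and-accept process is not a rate-matrix exponential — it is exact
to bookkeep and entirely adequate at these divergences.

Defaults $\phi_{\text{edge}} = 0.5$, $\psi_{\text{edge}} = 0.15$ encode the
edge regime the analysis targets: both site classes are extra-constrained at
edges, non-synonymous changes more strongly — the configuration under which
edge removal raises dN, dS *and* dN/dS and weakens NI. With equal multipliers
the generating non-synonymous/synonymous ratio is identical at edge and
interior sites, so edge removal raises dN and dS but *cannot* raise their
ratio in expectation (Jukes–Cantor convexity in fact pushes it marginally the
other way); that regime is exercised in the tests as a documented limit.
When `edge_expression_link` is on, the exponent $u$ is the gene's expression
percentile, making edge constraint strongest in highly expressed genes — the
mechanism by which trimming attenuates the expression–dN/dS correlation.

Gene-level constraint $\omega_g$ (log-normal, median 0.2, truncated at 1.5)
and latent log-expression are drawn from a Gaussian copula with normal-scale
correlation $r = 2\sin(\pi\rho_s/6)$, hitting a target Spearman correlation
(default −0.4) exactly in distribution. Tissue abundances multiply the latent
level by a per-gene gamma profile normalised to mean 1 (so the across-tissue
mean preserves generating ranks exactly); tissues below 5% of the gene's mean
are silenced so that breadth varies. Polymorphism on the focal (ingroup1) tip
uses the same attempt-and-accept acceptance structure at rates
$\theta_s = \theta_n = 0.02$/site — equal attempt rates with
$\omega_g = 1$ and no edge constraint centre the median NI at 0, the neutral
calibration the tests verify. EST chains mix one or two isoforms (second
isoform: one intron boundary shifted 9 nt) 50/50 with full-extent mapping.

No indels are simulated (alignment construction is out of scope); a
`gap_fraction` switch corrupts a stated fraction of exon blocks with a gap
codon in one non-reference species to exercise eligibility flags. All
randomness flows from one master seed through per-gene derived streams, so any
gene can be regenerated independently of iteration order. The truth record
stores per-branch realized difference counts as pathway-averaged recounts
between the internal-node sequence and each tip (the same currency the
estimators use), plus raw accepted-attempt counts — under $\omega_g = 0$ the
accepted non-synonymous count is exactly 0, while the pathway recount can be
fractionally positive when two synonymous steps admit a path ordering through
a different amino acid.

**What passing tests do and do not show.** The generator emits pre-aligned,
indel-free, equal-rate-across-genes data with independent sites and no codon
usage bias, selection on silent sites outside edges, biased gene conversion,
or alignment error. Calibration and recovery results on these data validate
the *machinery* (estimators, tests, bookkeeping), not the biological
conclusions of any particular genome analysis.

## Numerical choices and problem sizes

* All arithmetic is double precision; output tables round to 6 significant
  digits (which also makes reruns byte-comparable).
* Randomization ties do not increment $q$ (conservative).
* Parsimony ancestor candidates are restricted to sense codons; columns with
  gaps, ambiguity or stops in any species are skipped and reported.
* The neutral mean omega sits near 0.95 rather than 1.00 because the
  generator rejects stop-creating mutations while the site counter charges
  stop-creating changes to the non-synonymous site total — a known,
  documented property of NG86-style counting under stop-free evolution.
* Test and acceptance runs use 120–500 genes per condition, s = 40–200
  randomizations per gene, and 20 replicate gene sets for the attenuation
  direction check; the per-gene randomization test in production use defaults
  to the conventional s = 1000. These sizes were chosen so each calibration
  has comfortable statistical resolution at desk scale; the null-calibration
  check of the attenuation test uses 60 gene sets of 40 genes at s = 79
  (yielding an exact 0.05 rejection level on the discrete p-grid).
* `estimate_pairwise` with dS = 0 yields an undefined omega and the gene is
  excluded (how likelihood tools handle this case is itself not standardised;
  exclusion is the conservative choice).
* The dN/dS > 1 proportion-shift test is a 2×2 chi-square without continuity
  correction, reported as not-applicable when a margin is zero.

## Known limitations

* Counting estimators underestimate rates at high divergence relative to
  likelihood methods and ignore transition/transversion bias; comparisons
  with yn00/codeml outputs on real data should expect systematic offsets.
* Parsimony ancestors bias branch assignment when branch lengths are very
  unequal; the outgroup branch here is ~3× the ingroup branches, which the
  recovery tests show is tolerable at these divergences.
* The splicing-event detector is a simplification of dedicated
  EST-classification methods; only the subsampling normalisation is claimed
  as faithful.
* Breadth's presence threshold and the choice of expression summary (mean vs
  max) matter on real data; both are configurable and default to the simplest
  reading.
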