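---
title: "Methods: expression profiling of injured retinal ganglion cells with rgcflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression profiling of injured retinal ganglion cells with rgcflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgcflow)
```

# The analysis

`rgcflow` analyses paired-end RNA-seq of FACS-sorted retinal ganglion cells
(RGCs) from a four-arm design: untreated animals (*non-treat*), NMDA-injected
animals given vehicle (*NMDA-saline*), and NMDA-injected animals given one of
two VCP-modulator compounds (*KUS121*, *KUS187*), three biological replicates
each. The question the pipeline answers is which transcriptional changes
induced by excitotoxic injury are reversed (or amplified) by treatment, and
which functional gene sets those changes implicate.

The stages run in a fixed order:

1. **Pair-validity filter.** A fragment is usable when both mates map to the
   same chromosome, in opposite orientation, with leftmost positions less
   than 500 kb apart. Every rejected pair is charged to exactly one reason,
   tested in the order *unmapped*, *different chromosome*, *same
   orientation*, *too far*; the filter therefore partitions the input and
   its statistics always sum to the total.
2. **Terminal-exon quantification.** Valid pairs are counted per gene when
   either mate's start falls inside the gene's terminal exon, once per pair.
   Counts become RPK10M: reads per kilobase of exon model per 10 million
   mapped reads,
   $\mathrm{RPK10M}_{gs} = c_{gs} / (L_g/10^3) / (M_s/10^7)$,
   where $L_g$ is the terminal-exon length and $M_s$ the sample's mapped-read
   total. Values are moved to $\log_2(\mathrm{RPK10M}+1)$.
3. **Expressed-gene filter.** A gene is kept when the maximum of its
   per-condition mean $\log_2$ values exceeds 3 (strictly).
4. **Quantile normalization.** Each sample is forced onto the common
   reference of across-sample rank means.
5. **ANOVA screen.** A per-gene one-way fixed-effects F test across the four
   conditions; genes with raw $p < 0.01$ proceed. No multiple-testing
   correction is applied: the screen is a feeder for clustering, not an
   inferential endpoint.
6. **Sample dendrogram with AU/BP support.** Samples are clustered on
   Euclidean distances (average linkage) over the screened genes, and clade
   support is estimated by multiscale bootstrap: BP is the plain bootstrap
   proportion, AU the approximately unbiased p-value from the
   signed-distance/curvature model (below).
7. **X-means clustering and hyper clusters.** Screened gene profiles are
   z-scored per gene (population SD) and clustered by x-means, a k-means
   variant that accepts a cluster split when the split's BIC beats the
   unsplit model's. With condition-center differences
   $d_1 = \bar z_{\text{NMDA-saline}} - \bar z_{\text{non-treat}}$,
   $d_2 = \bar z_{\text{KUS121}} - \bar z_{\text{NMDA-saline}}$,
   $d_3 = \bar z_{\text{KUS187}} - \bar z_{\text{NMDA-saline}}$,
   a cluster is **hyper cluster A** when $d_1 > 0.2$, $d_2 < -0.2$ and
   $d_3 < -0.2$ (injury-induced upregulation reversed by both compounds) and
   **hyper cluster B** when all three exceed $+0.2$ (strict inequalities
   throughout).
8. **Enrichment.** Hyper-cluster gene lists are tested against gene sets by
   the upper-tail hypergeometric probability $P(X \ge k)$ with
   over-representation fold $(k/n)/(K/N)$; fold-change gene lists
   ($\mathrm{fc} > 2$ or $< 0.5$ on differences of per-condition mean
   $\log_2$ values) are screened per pathway at raw $p < 0.05$; and the two
   three-comparison intersections are reported: pathways significant among
   injury-down *and* both-treatment-up lists (*restored up*), and the mirror
   (*restored down*).

# Parameters

| parameter | default | unit / scale | role |
|---|---|---|---|
| `max_distance` | 500000 | bp | strict mate-distance bound of the validity filter |
| `pseudocount` | 1 | linear RPK10M | added before $\log_2$; makes zero counts map to 0 |
| `expressed_threshold` | 3 | $\log_2$ RPK10M | strict lower bound on the per-condition mean maximum |
| `anova_alpha` | 0.01 | raw p | screen threshold (no correction) |
| `delta` | 0.2 | z-value | strict center-difference bound of the hyper-cluster rule |
| `fc_up`, `fc_down` | 2, 0.5 | linear fold | strict fold-change labels |
| `pathway_alpha` | 0.05 | raw p | pathway-screen threshold |
| `scales` | 0.5–1.4 step 0.1 | relative resample size | multiscale bootstrap grid (must contain 1) |
| `n_boot` | 1000 | resamples per scale | bootstrap effort |
| `k_min`, `k_max` | 2, 20 | clusters | x-means bounds |
| `linkage` | average | — | agglomeration method for the sample dendrogram |

The thresholds are the analysis constants of the study design; the bootstrap
and x-means settings are conventional values, configurable in every entry
point.

# The synthetic-data generator

The generator is first-class, tested code. It emulates, per seed and
byte-deterministically:

* an annotation of non-overlapping genes on at least two chromosomes, 1–4
  exons, terminal exons 200–2000 bp;
* a truth table assigning each gene a class — `hyperA` (up by
  `effect_log2` after injury, back down under both compounds), `hyperB`
  (up, then further up), or `null` — with per-condition true mean
  $\log_2$ abundances that satisfy the defining inequalities exactly;
  baselines are drawn uniformly on $\log_2$ 5–9, a 16-fold range
  representative of robustly expressed genes (the regime the analysis
  operates in after its expressed filter);
* per-sample SAM alignments: gene-level Poisson pair counts with
  expectations proportional to $2^{\mu + \varepsilon} L_g$
  ($\varepsilon \sim N(0, \texttt{noise\_sd\_log2})$, applied in log space
  to match the pipeline's log-scale analysis), pairs placed FR-oriented
  inside the terminal exon; plus injected invalid pairs carrying exactly
  one defect each (interchromosomal, same-orientation, or mates $\ge$
  500 kb apart), recorded in a manifest so the filter's rejections can be
  checked pair-for-pair;
* gene sets (GMT) with one planted set overlapping the hyperA genes and
  uniformly drawn decoys.

Default study conditions: 2000 genes, 3% hyperA, 0.75% hyperB, effect 1
$\log_2$ unit, replicate noise SD 0.25, 300{,}000 pairs per sample, and
invalid-pair fractions (0.15, 0.10, 0.139) whose sum leaves 61.1% of pairs
usable — the usable fraction typical of this library preparation. The
300k-pair library is a desk-scale stand-in for real libraries of tens of
millions of pairs; at this depth Poisson counting noise is visible for
short, low-abundance genes, which is realistic in kind if not in degree.

**What the generator does not emulate:** overdispersion beyond Poisson,
spliced alignments and CIGAR structure, multi-mapping ambiguity,
fragment-length distributions, correlated genes, batch effects, and GO-style
ontology structure (sets are flat). Passing tests on synthetic data
therefore demonstrate the pipeline's correctness and its behaviour under
the planted statistical structure, not robustness to every artefact of real
libraries.

# How recovery is measured

With three replicates, an effect of 1 $\log_2$ unit and replicate noise SD
0.25, the per-gene ANOVA screen has a hard power ceiling: the noncentrality
at these settings is $3 \times 0.75 / 0.0625 = 36$, giving power
$\approx 0.84$ at the $p<0.01$ cut even with noiseless counting. A planted
gene that the screen misses never reaches clustering. The package therefore
evaluates hyper-cluster recovery **on the screened population**: among
planted hyperA genes that pass the ANOVA screen, the fraction assigned to
clusters labelled A. The run report carries both this conditional fraction
and the unconditional one, so the screen's own sensitivity stays visible.

# Numerical choices

* **Terminal exon** = the 3'-most exon in gene orientation; for
  multi-transcript genes, the transcript with the longest terminal exon
  defines the model. Configurable to 5'.
* **Counting rule**: mate-start containment, once per pair per gene; a pair
  inside two genes' terminal exons increments both.
* **Mapped-read denominator**: all mapped mates count, including the mapped
  mate of a half-mapped pair, so the RPK10M denominator is distinct from
  (and at least twice) the valid-pair count.
* **Quantile-normalization ties**: a tie group receives the mean of the
  reference values at the sort positions it spans, keeping ties tied. With
  ties present, column value multisets after normalization can differ
  slightly by construction; exact idempotence holds on tie-free data.
* **Z-scores** use the population SD (divisor $n$), the common heatmap
  convention; constant rows are an error (they cannot survive the screen).
* **AU fitting**: $\Phi^{-1}(1-\mathrm{BP}_r) = v\sqrt{r} + c/\sqrt{r}$ is
  fit by weighted least squares with binomial variance weights
  $\mathrm{Var}(z_r) \approx \mathrm{BP}(1-\mathrm{BP}) /
  (B\,\varphi(z_r)^2)$; $\mathrm{AU} = 1 - \Phi(v - c)$. BP of 0 or 1 is
  clipped by $1/(2B)$ before the probit transform; clades observed never /
  always are flagged (`degenerate_low` / `degenerate_high`) with AU pinned
  to 0 / 1. At least two distinct scales are required.
* **X-means BIC**: spherical Gaussian with a common variance per model
  region, $\hat\sigma^2 = \mathrm{RSS}/(d(n-k))$ floored at $10^{-12}$,
  $k(d+1)$ free parameters; a split is accepted only when its BIC strictly
  exceeds the unsplit BIC, so identical points never split and total
  within-cluster variance never increases across accepted splits.
  Degenerate inputs `stats::kmeans` rejects (as many points as centers,
  fewer distinct points than centers) fall back to deterministic
  partitions.
* **Enrichment universe**: expressed genes carrying at least one gene-set
  annotation (so every set's $K$ is its intersection with the universe);
  the rule is echoed in every report. No multiple-testing correction in
  either enrichment stage, matching the screen-style, raw-p presentation.
* **Hierarchical clustering** delegates to `stats::hclust`, whose
  deterministic tie handling makes dendrograms reproducible for fixed
  input.

# Open design points, resolved

* Quantification is per gene (one terminal exon per gene); per-transcript
  quantification of isoform terminal exons is noted as the alternative but
  not implemented.
* Normalization runs after the expressed filter, matching the stage order
  stated for the study.
* X-means clusters per-sample z-score profiles; per-condition centers are
  computed from the assignment either way, and the hyper-cluster rule uses
  only those centers.
* Fold changes exponentiate differences of per-condition mean $\log_2$
  values (log-averaging), rather than averaging linear values.

# Problem sizes

The shipped tests run the generator at 80–300 genes and 8k–30k pairs per
sample for unit-level checks, and one full default-design run (2000 genes,
12 samples × 300k pairs) for end-to-end recovery; bootstrap support uses
100–1000 resamples per scale depending on the check. These sizes were chosen
so the whole suite exercises every stage at realistic shapes while staying
comfortably runnable on a laptop.

# Known limitations

* The pair filter treats alignments as fully aligned blocks (no CIGAR-aware
  splice handling); counting is mate-start containment, not overlap length.
* AU values inherit the asymptotic assumptions of the multiscale-bootstrap
  model; for clades near certainty the WLS fit is extrapolation and the
  degenerate flags should be trusted over the fitted number.
* X-means with a BIC of this form tends to over-split elongated or
  non-spherical clusters; `k_max` bounds the damage and the per-condition
  centers (what the hyper rule consumes) are robust to moderate
  over-splitting, since sub-clusters of a pattern inherit the pattern.
* Hypergeometric enrichment ignores gene-set overlap structure and GO
  ancestor propagation.
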