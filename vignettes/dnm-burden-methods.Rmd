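---
title: "Testing genes for coding and noncoding de novo mutation burden"
author: "DNMburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing genes for coding and noncoding de novo mutation burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DNMburden)
```

## The problem

De novo mutations (DNMs) — variants present in a child and absent from both
biological parents — are a major source of risk for severe neurodevelopmental
phenotypes. Whole-genome sequencing of parent–offspring trios makes the
noncoding portion of that signal accessible, but testing individual genes for
an excess of *noncoding* DNMs is much harder than for coding DNMs: the
noncoding target is vast, most noncoding sites are inert, and the background
mutation rate is strongly heterogeneous along the genome.

`DNMburden` implements a gene-level testing framework for this setting:

1. a **trio DNM caller** that applies a fixed eight-criterion filter chain to
   per-family VCFs;
2. a **region and consequence annotator** (a compact ANNOVAR-style
   classifier) plus per-site functional score attachment;
3. a **point-based case-only Poisson test** on likely-functional sites
   (deleteriousness score ≥ 15);
4. a **segment-based case-only Poisson test** on 1 kb windows with
   window-specific background rates derived from a genome-constraint map;
5. **case–control carrier burden** statistics, **Fisher combination** across
   variant classes and cohorts, and multiple-testing correction;
6. a fully self-contained **synthetic-cohort generator** that produces every
   input the pipeline consumes, with planted ground truth.

## Models and statistics

### Case-only Poisson tests

The number of DNMs per child is well approximated by a Poisson law, so the
per-gene count of DNMs across a cohort of $n$ trios is Poisson with a
gene-specific mean. For coding DNMs the expected count uses a precomputed
per-gene mutation probability $p_g$ (per chromosome per generation):

$$E_g^{\text{coding}} = p_g \times n \times 2,$$

the factor 2 counting the two transmitted autosomal chromosome copies. The
one-sided p-value for an observed count $k$ is the Poisson upper tail
$P(X \ge k) = \texttt{ppois}(k - 1, E_g, \text{lower.tail=FALSE})$
(`poissonCaseOnly()`).

For the **point-based noncoding test**, the gene's noncoding mutation rate is
assumed to track its coding rate, scaled by target size. The noncoding target
is the count of positions in the gene's noncoding footprint (transcript span
± 1 kb flank, minus CDS and canonical splice dinucleotides) whose
deleteriousness score is ≥ 15 — the effective target after the score filter:

$$E_g^{\text{noncoding}} = p_g \times n \times 2 \times
  \frac{L_g^{\text{noncoding,score} \ge 15}}{L_g^{\text{coding}}}.$$

Only score-qualifying noncoding DNMs are counted as observed. Intergenic
DNMs are tested separately through their nearest gene; the expected model
uses the count of score-qualifying positions in each gene's nearest-gene
territory (boundaries at midpoints between adjacent footprints). No
standard convention fixes the intergenic target length; this
midpoint-territory definition is the natural extension of the genic one
and is this package's design choice, as is the use of score-qualifying
*positions* (not observed variants) for the length — the raw-bp alternative
can be obtained by passing a permissive threshold to
`noncodingFunctionalLength()`.

### Segment-based test

Noncoding background mutation rates vary several-fold at kilobase scale. The
segment-based test tiles the genome into 1 kb bins; each bin carries an
expected rare-variant count from a population-scale constraint map, and

$$\beta_b = \frac{\text{expected}_b}{\overline{\text{expected}}}, \qquad
  E_b = \overline{c}_{1\text{kb}} \times \beta_b,$$

where $\overline{c}_{1\text{kb}}$ is the analyzed cohort's mean noncoding DNM
count per bin over the bin universe (`computeBackground()`). Genic bins
(overlapping a gene footprint but no CDS) map to every overlapping gene by
default; a single-assignment mode (longest overlap) is available, under
which per-gene expected counts exactly conserve the cohort total. Per gene,
observed is the DNM count in its bins, expected is $\sum_b E_b$, and the
same Poisson kernel applies. The segment test deliberately uses *all*
noncoding DNMs (no score filter) — it is the complementary, hypothesis-free
channel — with an optional score or Gnocchi-constraint restriction for
burden analyses of highly constrained windows.

One numerical subtlety: $\beta$ is normalized to unit mean over *all* bins,
but a genic-only (or intergenic-only) universe need not have unit mean
$\beta$. `runSegmentTest(rescaleBeta = TRUE)` (the default) rescales $\beta$
to unit mean over the analyzed universe so that expected counts conserve the
cohort total; `expectedBinCount()` itself remains the plain product.

### Case–control burden, combination, correction

Carrier-based 2×2 tables (a subject counts once per unit tested) feed a
one-sided Fisher exact test and a fold change of carrier fractions
(`geneSetBurden()`). Odds ratios add 0.5 to all four cells only when a cell
is zero (Haldane–Anscombe, `oddsRatioCorrected()`). Evidence across variant
classes and cohorts is merged with Fisher's method,
$X = -2\sum_i \ln p_i \sim \chi^2_{2k}$ (`fisherCombined()`): per gene, the
per-cohort coding p-values are combined, the per-cohort noncoding p-values
are combined, and the two family-level results are combined into one
gene-level p-value (`combineAcrossCohorts()`). Gene-level results are
corrected by Bonferroni over a declared universe (default 20,000 genes,
significance at raw $p < 2.5\times10^{-6}$) and by Benjamini–Hochberg FDR
over the same universe.

## Filter chain and its conventions

`applyDnmFilters()` evaluates **all** criteria and records every violation
(reason codes), enabling per-criterion accounting:

| criterion | rule | code |
|---|---|---|
| child alt depth | AD\_alt ≥ 6 | `ad_alt` |
| child genotype quality | GQ ≥ 25 | `child_gq` |
| parent genotype quality | both GQ ≥ 20 | `parent_gq` |
| parent depth | both DP > 8 (strict) | `parent_dp` |
| population frequency | AF < 0.001; missing = novel | `pop_af` |
| mappability | outside BED mask | `mappability` |
| allele balance | AD\_alt/(AD\_ref+AD\_alt) ∈ [0.25, 0.75] | `allele_balance` |
| difficult regions | gene prefix not HLA/MUC | `blacklist` |

Interpretation choices where the underlying convention is ambiguous: the
allelic-depth threshold applies to the *alternate* allele (a total-depth
reading would make the allele-balance filter redundant at low depth); the
allele-balance bounds are inclusive; parental thresholds apply to each parent
independently (the stricter reading); children homozygous for the alternate
allele are excluded as implausible de novo events (`child_hom_alt`). Within
100 bp in the same gene and child, transitively linked calls collapse to the
single most severe call (LGD > missense > other exonic > noncoding splicing
> UTR > intronic > flank > ncRNA), ties to the smaller position; the
transitive (single-linkage) reading is a design choice where a pairwise one
would be ambiguous for chains.

Coordinates are 1-based closed throughout the package (the
GenomicRanges/IRanges convention); BED input/output converts at the
boundary. Splicing is the 2 bp intron side of each exon boundary; flanks are
1 kb, matching the defaults of the annotation tool this classifier is
modeled on. When a gene's transcripts disagree, the union of exons and CDS
defines the gene-level model.

## The synthetic study

`simulateStudy()` generates a complete, self-contained study from one seed:
random reference sequences (default two 3 Mb chromosomes); 540
non-overlapping multi-exon genes (4% ncRNA, CDS length divisible by 3, ATG
and stop codons imprinted into the reference); a rate table proportional to
coding length times a log-normal gene factor (sd 0.25, giving a
length–rate correlation around 0.88, the regime reported for real rate
tables); a per-site score track with an exactly 1.8% probability of scoring
≥ 15 per site; 1 kb bins with gamma-distributed expected counts (shape 4,
scale 0.25 — unit mean with realistic heterogeneity); an intergenic
low-mappability mask; and per-family VCFs for 500 case and 500 control
trios with 90 DNMs per child on average, of which 1.27 are coding — the
per-child and per-class means mirror the cohort summaries of large published
trio studies.

Placement makes the coding test *exactly* calibrated: each DNM falls in gene
$g$'s coding target (CDS plus canonical splice dinucleotides — the same
definition the coding test counts) with probability $2 p_g m_g / R$, where
$R$ is the per-child mean and $m_g$ a case-only enrichment multiplier, so
per-gene coding counts are Poisson($2 p_g m_g n$) by Poisson thinning. The
remaining mass is spread over the noncoding genome proportionally to length
(enriched genes' footprints upweighted by $m_g$). The per-trio
noncoding/coding split therefore follows genomic footprint proportions — an
assumption, not an empirical calibration. Decoy records each violate exactly
one filter criterion (including detection-stage decoys: a parent carrying
the allele, a hom-alt child); inherited heterozygous background variants
exercise candidate detection. Blacklisted genes and masked windows are
excluded from clean placement so that the planted truth contract — every
clean DNM passes, every decoy fails with its own reason — is exact.

What passing tests on this generator do **not** show about real data:
mutational signatures and CpG context, read-level artifacts, sex-chromosome
inheritance, cohort relatedness and ancestry structure, and real
transcript complexity (overlapping genes, alternative isoforms) are all out
of scope; the generator validates the statistical machinery, not the
biology of any particular cohort.

## Calibration diagnostics and numerical choices

The Poisson tail p-value is discrete: under the null it is stochastically
*larger* than uniform (at expected counts near 1, a third of genes observe 0
and receive $p = 1$). Uniformity can therefore only be assessed through the
randomized probability integral transform
$p = P(X > k) + U \cdot P(X = k)$, which is exactly uniform under the null;
`randomizedPoissonP()` implements it for QQ/Kolmogorov–Smirnov diagnostics
and is never used for inference. On a null cohort of 500 case trios and
~515 rate-table genes the randomized p-values are KS-uniform and ~5% fall
below 0.05; genes planted at tenfold enrichment with expected ≥ 0.5 rank in
the point-test top 5 in ≥ 90% of replicates. These problem sizes (6 Mb
genome, 500 + 500 trios, 20 recovery replicates) are the package's chosen
simulation scale: large enough for stable calibration statistics while a
full run stays in the minutes range.

Other numerical conventions: p-values are clamped to $[10^{-300}, 1]$
before log transforms; `fisherCombined()` returns a single input unchanged;
an expected count of 0 with a positive observation reports the clamp floor;
zero-observed genes stay in the output (so FDR runs over the declared gene
universe, not just hit genes); nearest-gene ties go to the
lexicographically smaller id; and genes absent from the rate table are
reported without a p-value rather than silently dropped.

## Known limitations

* The noncoding point test inherits the assumption that a gene's noncoding
  mutation rate tracks its coding rate; genes in atypical sequence context
  will be mis-calibrated in both directions.
* Bins overlapping several genes are counted for each (marginal tests);
  under single-assignment the conservation identity holds but bin-sharing
  information is discarded.
* The caller takes genotypes as given: no re-genotyping, phasing, or mosaic
  detection.
* Scores are consumed as supplied tables; the package never computes
  deleteriousness, splice-impact or constraint scores itself.
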