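---
title: "Multi-resolution splice-QTL analysis: models, defaults and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-resolution splice-QTL analysis: models, defaults and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicedose)
library(dplyr)
```

## The problem

A common genetic variant near a cassette exon can shift how often that exon
is included in the mature transcript. Whole-gene expression analysis can be
blind to such an effect: total output stays flat while the isoform balance
moves. splicedose implements the multi-resolution strategy for detecting
this situation: the same genotype is tested against phenotypes quantified
at five levels — transcript, exonic part, exon–exon junction, splice site
and intron — and the *pattern of signs* across levels is read as the
fingerprint of a splicing effect. The motivating case is a 198-nt,
frame-preserving cassette exon whose inclusion is promoted by the minor
alleles of two linked SNPs, one exonic and one intronic, detectable as an
RT-PCR product pair of 740 nt (inclusive) and 542 nt (skipped).

## Gene-model layer

Internally every coordinate is 0-based half-open; GTF input/output converts
from the 1-based closed convention at the boundary, and BED export passes
through unchanged. From a set of transcripts the package derives:

* **Exonic parts** (`flatten_exonic_parts()`): the union of all exons is
  split at every exon boundary and runs with an identical set of supporting
  transcripts are merged, giving the maximal sub-intervals of constant
  transcript support (DEXSeq-style counting bins). Parts are numbered in
  ascending genomic coordinate on both strands; strand only affects
  donor/acceptor labelling.
* **Pseudo-transcript** (`build_pseudo_transcript()`): the merged union of
  all exons. Adjacent-but-not-overlapping exons are deliberately kept
  separate so that only genuine gaps become introns; zero-length introns
  are dropped.
* **Introns** (`derive_introns()`): the gaps between pseudo-exons. Together
  the pseudo-exons and introns tile the gene span with no overlap and no
  gap, a property the tests check on random gene models.
* **Junctions** (`enumerate_junctions()`): one per consecutive exon pair
  per transcript, stored as the intron interval and deduplicated across
  transcripts; a skipping isoform contributes the long junction over the
  cassette. On the minus strand the donor site is the junction endpoint
  with the larger coordinate (biological 5'→3' convention).

Primer anchors are coordinate-based (exon index plus offset in transcript
direction); `in_silico_amplicon()` measures a product on the spliced
molecule from the forward primer 5' end through the reverse primer 5' end
inclusive, and returns no product when an anchor's exon is absent from the
target isoform. Sequence-level primer matching is out of scope. The
packaged synthetic gene (`tyk2_like_gene()`, exon widths 430/198/320 nt)
is calibrated so the flanking primer pair yields exactly 740 and 542 nt on
the two isoforms; no real genomic sequence or coordinates are used.

```{r amplicon}
g <- tyk2_like_gene()
pr <- tyk2_like_primers()
in_silico_amplicon(g$transcripts[["TYK2L-201"]], pr$fwd, pr$rev)
in_silico_amplicon(g$transcripts[["TYK2L-204"]], pr$fwd, pr$rev,
                   reference = g$transcripts[["TYK2L-201"]])
```

## Quantification

Aligned reads enter as block lists (one row per aligned block); the gaps
between a read's blocks are its splices.

* **Junctions**: each gap is one observation, counted only when both
  flanking blocks align at least `min_overhang` nucleotides into their
  exons (default 6 nt — short overhangs are unreliably mapped). Counts are
  monotone in this filter.
* **Exonic parts and introns**: the union rule — a read increments every
  feature any of its blocks overlaps by ≥ 1 nt, once per feature. Several
  finer ambiguity policies exist in HTSeq-style counters; the union,
  count-per-feature rule is used uniformly here. A spliced block that jumps
  an intron does not touch it, so intron counts respond to intron retention
  and boundary-crossing only.
* **Splice-site activity**: a site's "activity" has no standard numeric
  definition in the field; splicedose defines it as
  the sum of counts of all junctions sharing the site. This makes total
  donor activity, total acceptor activity and total junction count
  identical — a conservation identity the tests enforce.
* **Normalisation**: RPKM (`count * 1e9 / (library_size * length)`) for
  length-bearing features (gene, exonic parts, introns, transcripts), RPM
  (`count * 1e6 / library_size`) for junctions and splice sites. Library
  size defaults to the total of counted reads per sample unless supplied.
* **PSI**: with upstream/downstream inclusion junction counts `c78`, `c89`
  and skipping count `c79`, inclusion evidence is `(c78 + c89)/2` (the two
  inclusion junctions measure the same molecules twice), and
  `psi = inclusion/(inclusion + skip)`; an all-zero denominator is
  reported as missing, never as 0.

### Isoform proportions by EM

Transcript-level abundances come from a small EM over junction
compatibility classes rather than a full fragment-level quantifier. A
molecule of isoform $k$ contributes junction reads in proportion to its
number of informative junctions $J_k$, so the probability that a junction
read falls in class $c$ is

$$P(c \mid \theta) = \frac{\sum_{k \in c} \theta_k J_k}{\sum_k \theta_k J_k},$$

and the weight $w_k = 1/J_k$ converts read shares back into molecule
proportions $\theta$. For the two-isoform cassette problem with 90
full-only and 10 skip-only reads this gives $\theta_{\text{full}} = 45/55
\approx 0.818$, which the tests verify against a grid-search maximiser of
the same likelihood. The EM starts uniform, stops when
$\max_k |\Delta\theta_k| < 10^{-8}$ or after 500 iterations, and is fully
deterministic; its log-likelihood is non-decreasing by construction.
Classes compatible with every isoform (shared exon-body reads) carry no
information about the mixture and are dropped.

## eQTL model

Each feature is tested with ordinary least squares,

$$y_i = \mu + \beta g_i + C_i \gamma + \varepsilon_i,$$

where $g_i \in \{0,1,2\}$ is the minor-allele dosage and $C$ holds the
covariates (in the synthetic study, population of origin). The test is a
two-sided t-test on $\beta$ with $n - k - 2$ residual degrees of freedom.
Phenotypes are analysed on the normalized RPKM/RPM scale by default; a
`log1p_transform` option exists. Choices worth knowing:

* Missing dosages, phenotypes or covariates are handled by listwise
  deletion; no imputation.
* A genotype constant after filtering, or too few complete cases, yields
  an explicit "untestable" record rather than an error, so multi-feature
  scans never die midway.
* A perfect fit reports the p-value at the smallest positive double
  rather than 0, keeping $p \in (0, 1]$.
* Rank-deficient covariates raise an error naming the offending column.
* Raw per-feature p-values are reported (the multi-level scan here tests a
  handful of features in one gene); `adjust_fdr()` provides
  Benjamini–Hochberg adjustment for users scanning many features, off by
  default.
* Mixed-model kinship correction is out of scope; the model is
  fixed-effects only.

**Conditional analysis** (`conditional_eqtl()`) appends a second SNP's
dosage to the covariates; a proxy whose association is pure linkage
disequilibrium collapses when its causal partner is conditioned on. Dosage
vectors correlated beyond $|r| > 0.999$ are flagged untestable rather than
inverted into a near-singular design.

**Direction pattern**: `cassette_direction_expectation()` packages the
signed fingerprint of an inclusion-promoting allele — skipping transcript
down, both inclusion junctions up, skipping junction down, the cassette's
flanking acceptor and donor activities up, both neighbouring introns down,
and no effect on total gene output. `direction_pattern()` scores
`sign(beta)` concordance over the eight signed features and reports the
null-expected gene-level feature separately (concordant when
non-significant at the chosen alpha).

## Band association and the exact test

The packaged table of 30 genotyped cell lines scores each line for the
presence of the skipped-exon RT-PCR product. Band absence coincides
exactly with minor-allele homozygosity at either SNP (12 absent: nine AA
at the exonic SNP only, one AA at the intronic SNP only, two AA at both);
`classify_band_rule()` encodes that recessive-style rule, stated, not
fitted. The association is tested with `fisher_exact_2x2()`, an exact
hypergeometric test built directly from binomial coefficients
(`lchoose`): conditional on the margins the top-left cell is
hypergeometric; one-sided p-values are tail sums and the two-sided
p-value sums all tables no more probable than the observed one (1e-7
relative tie tolerance, the usual convention). `stats::fisher.test` and a
full-enumeration oracle serve as independent cross-checks in the tests,
never as the implementation. The source table's header labels the band
"550nt" while its measured length is 542 nt; the package stores the text
value and keeps the header label in the fixture metadata.

## The synthetic study

`simulate_splicing_study()` generates the full data structure the analysis
assumes, with known truth. Its defaults *are* the study conditions used by
the calibration and recovery tests; they are set once and not tuned:

| parameter | default | meaning |
|---|---|---|
| `n` | 200 | individuals (the monocyte cohort scale) |
| `maf1`, `maf2` | 0.26, 0.17 | minor-allele frequencies, causal SNP and proxy |
| `r2` | 0.50 | target LD between the SNPs (European-like; the East-Asian-like setting uses MAFs ≈ 0.47 and r² = 0.9) |
| `alpha` | logit(0.85) | baseline inclusion: major-allele homozygotes already include the exon most of the time |
| `beta_g` | 1 | logit-PSI shift per causal minor allele — a testing convention, not a claim about any real gene |
| `sigma` | 0.3 | per-individual logit-PSI noise |
| `depth` | 100 | expected junction-informative reads per sample |
| `gamma_intron` | 0.5 | intron signal tracks `1 - PSI` |
| `pop_shift` | (0, 0.3) | two equal populations, additive baseline offset, mirrored by the `pop` covariate |

The generative chain: haplotype frequencies solved analytically from
(MAF₁, MAF₂, r²) with $D = \pm\sqrt{r^2\,p_1q_1p_2q_2}$ and an explicit
feasibility error quoting the attainable maximum; diploid genotypes by
drawing two haplotypes per individual (Hardy–Weinberg); inclusion by
$\mathrm{logit}(\psi_i) = \alpha + \beta_g g_{1i} + \text{pop}_i +
\varepsilon_i$; counts by Poisson — inclusion junctions at
$\text{depth}\cdot\psi$, the skipping junction at
$\text{depth}\cdot(1-\psi)$, introns at
$\text{depth}\cdot\gamma(1-\psi) + 1$, exonic parts proportional to part
length (the cassette part additionally scaled by $\psi$), and the gene
body at a constant rate *independent of genotype*, reflecting that
inclusion redistributes isoforms without changing total transcription.
Only SNP1 is causal; SNP2 associates purely through LD, which gives the
conditional analysis a ground truth. A single seed drives the whole run,
and identical configurations produce byte-identical output files.

What the generator does **not** emulate: negative-binomial overdispersion
is available (`overdispersion > 0`) but off by default; there is no
read-sequence simulation, mapping bias, GC or length bias, no relatedness
or population stratification beyond the additive mean shift, and counts
are generated directly at feature level (an optional block-list read
emitter exists for exercising the read counters). Passing tests therefore
demonstrate correctness of the statistical machinery under its own
assumptions — not robustness to the full mess of real RNA-seq.

```{r study}
sim <- simulate_splicing_study(sim_config(seed = 1))
res <- run_multilevel(
  sim$phenotypes,
  tibble::tibble(sample_id = sim$genotypes$sample_id,
                 dosage = sim$genotypes$dosage1),
  sim$covariates
)
direction_pattern(res)
```

## Validation design and problem sizes

The test suite pairs every non-trivial operation with an independent
oracle: exonic-part flattening against a per-coordinate sweep; junction
counting against a per-read loop; the EM against a 10⁻³ grid search of its
own likelihood; the exact test against full enumeration and
`fisher.test`; the OLS fit against explicit normal-equation solves. The
statistical acceptance checks run at fixed sizes chosen to keep the whole
suite in a few minutes on one core while leaving comfortable margins:
2000 null replicates for type-I calibration (expected rejection
0.05 ± 0.01), 100 simulation replicates for direction-pattern recovery
(≥ 7/8 sign concordance in ≥ 90% of replicates), 200 replicates for the
conditional-collapse check, and 10 draws of 5000 individuals for LD
recovery (|r̂² − 0.5| < 0.03).

## Known limitations

* The five-level quantification assumes a single gene model at a time; no
  genome-wide scan machinery (nor its multiple-testing consequences) is
  included.
* The EM treats junction reads only; exon-body evidence is deliberately
  uninformative, which is exact for the two-isoform cassette case but
  discards real information for complex loci.
* The splice-site activity definition (junction-count sum) is this
  package's reading of a quantity that has no standard numeric
  definition.
* OLS on RPKM/RPM scales is simple and transparent but not
  variance-stabilised; for heavily skewed phenotypes use
  `log1p_transform = TRUE` and judge residuals yourself.
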