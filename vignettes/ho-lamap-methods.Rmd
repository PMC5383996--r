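---
title: "Ho-index scans across biparental crosses: models, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ho-index scans across biparental crosses: models, parameters and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HoLAMap)
```

## The model

A quantitative trait locus that co-localizes in several biparental crosses
constrains the causal variant sharply: every cross that detected the QTL must
segregate at the causal site, so its founder and reference parents carry
different alleles there. Unlinked loci carry no such constraint — with
parental allele frequency $p$ a random parent pair is polymorphic with
probability $2p(1-p)$, at most $0.5$. The **Ho index** at a SNP is

$$\mathrm{Ho} = \frac{\#\{\text{detecting crosses with } g_F \neq g_R\}}
                      {\#\{\text{detecting crosses}\}},$$

with expectation 1 at the causal variant and about 0.5 at unlinked loci.
Because many non-causal variants can reach $\mathrm{Ho}=1$ by chance when few
crosses are available, the scan is intersected with per-SNP association
inside the QTL interval: a candidate must have $\mathrm{Ho} \ge 1$ **and**
$-\log_{10} p$ at or above the Bonferroni cutoff $-\log_{10}(\alpha/n)$.
`holamapScan()` ranks candidates by Ho (descending), then p-value, then
position.

### Assumptions

* **Inbred parents.** Accessions are treated as homozygous; "the cross is
  heterozygous at a SNP" means the F1 would be — the two parents carry
  different homozygous alleles. Residual heterozygous parent calls violate
  the assumption and are *uninformative* by default. A `lenient` policy
  compares dosages directly (het vs hom counts as polymorphic, equal hets as
  monomorphic) for panels with appreciable residual heterozygosity.
* **Correct detection flags.** The denominator counts crosses flagged as
  detecting the target QTL; flags come from upstream linkage mapping, which
  this package does not re-derive.
* **Shared causal allele.** All founder parents detecting the QTL carry the
  same functional allele; allelic heterogeneity breaks the Ho = 1 signature.

### Missing-data policies

The literal Ho definition divides by the number of detecting crosses
(`missingPolicy = "strict"`). A cross with a missing parent call at a SNP
then silently lowers Ho, biasing the scan against poorly covered sites, so
the default `"adjust"` policy drops uninformative crosses from numerator and
denominator ($\mathrm{Ho} = n_\text{polymorphic}/n_\text{informative}$) and
records Ho as undefined where no cross is informative. Both counts and the
detecting total are always reported, so either ratio can be recomputed from
the profile.

## Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `maxMissing` (variant filter) | 0.30 | fraction | keep variants with at most 30% missing calls; the boundary is inclusive (a 30% variant is kept) |
| `minMaf` | 0.05 | frequency | computed over non-missing calls only, inclusive |
| smoothing `window` | 2 | SNPs | moving average of two consecutive SNPs, shifted one SNP at a time; display only — candidate calling always uses raw Ho |
| `hoMin` | 1.0 | Ho | candidates are called at Ho = 1; equality is tested with tolerance $10^{-9}$, which only guards float storage since Ho values are exact small rationals |
| `promoterUpstream` | 2000 | bp | conventional promoter span upstream of the gene start (strand-aware); configurable because no single value is canonical |
| PCA covariates `k` | 3 | components | standard choice for structured crop panels with a handful of subpopulations; deterministic up to sign, fixed by making each component's largest-magnitude loading positive |
| `tailFraction` | 0.05 | fraction | tails of $\lceil f n \rceil$ samples by extreme phenotype; 0.10 and 0.15 give similar sweeps and remain available |
| cross numbers | 2–50 | crosses | range of the design curve; `crossNumberCurve()` also reports the smallest N reaching power 0.95 |
| `windowSpan` (π) | 10 000 | bp | non-overlapping windows; π is divided by the full span (invariant sites implicitly zero) unless `partialExact` |
| `flankSpan` | 20 000 | bp | flank width per side for the gene-vs-flank contrast |

## Association model

Per variant, least squares of trait on allele dosage (0/1/2), optionally
plus structure covariates; two-sided t test on the dosage coefficient with
$n_\text{used} - (2 + k)$ degrees of freedom. Complete cases are taken per
variant, so each SNP uses the maximum available data. Heterozygous samples
*are* used here (additive coding) even though the Ho computation ignores
them — association and Ho answer different questions. Monomorphic variants
yield `NA` rather than an error; collinear covariates are an error because
they silently change the meaning of the dosage coefficient. Structure
covariates replace externally estimated ancestry proportions with principal
components of the (mean-imputed, per-variant-centred) dosage matrix — a
deterministic, dependency-free stand-in that controls the same confounding
in a GLM; any full-rank covariate matrix can be supplied instead.

## Design simulations

`tailPower(pH, pL)` $= p_H(1-p_L) + (1-p_H)p_L$ is exactly the probability
that a random high-tail × low-tail parent pair is polymorphic, and equals
the brute-force fraction over all such pairs when frequencies are computed
from the same tails. The Monte-Carlo in `crossNumberPower()` splits the
panel by functional allele (heterozygotes belong to neither group), draws N
parents per group — by default *without* replacement within a replicate,
since an accession provides at most one parent per design; a
with-replacement mode exists and makes the analytic check
$\prod_j (1 - q_j^N)$ exact — and scores a replicate as success only when
the maximum-Ho set is exactly the functional variant. Ties count as
failure. Per-N substreams are derived from the base seed, so a curve is
reproducible and its entries independent.

## Nucleotide diversity

Per site, $\pi = 2 a r / (n_s (n_s - 1))$ with $a$ alternate and $r$
reference haplotypes among the $n_s$ non-missing calls — the unbiased mean
pairwise difference, in which missingness enters only through the per-site
sample size. Inbred accessions contribute one haplotype each (dosage 2 →
alternate, 0 → reference); heterozygous calls are excluded unless
`includeHet = TRUE`, in which case an het contributes one haplotype of each
allele. Windows tile the requested region from its start, so window
boundaries depend on the region anchor (documented deliberately: anchoring
at genome coordinate 0 would shift every boundary).

## The synthetic generator

`simulatePanel()` emulates the features the method actually relies on:

* subpopulation allele frequencies drawn around a shared ancestral frequency
  with a single Balding–Nichols-style divergence parameter (default 0.15,
  within the differentiation range of domesticated rice subspecies) — this
  is what creates structure confounding;
* inbred genotypes (dosage 0/2), optional residual heterozygosity and
  missingness;
* phenotype = causal effect + subpopulation shift + Gaussian noise, default
  effect 1.5 trait units at residual SD 1;
* the causal SNP's frequency held equal across subpopulations so the
  requested MAF (default 0.3) is realized up to binomial noise;
* optional perfect-LD copies flanking the causal SNP (exercises cluster
  calling) and an optional sweep region whose per-site heterozygosity in one
  subpopulation is scaled by a configured factor.

`simulateCrosses()` pairs high-tail founders with low-tail references and
flags a cross as detecting the QTL exactly when its parents segregate at
the causal SNP.

What the generator does **not** emulate: linkage disequilibrium decay and
recombination (no coalescent; LD exists only as exact copies), allelic
heterogeneity, genotyping error, multi-allelic sites, linked selection
outside the configured sweep, and real linkage mapping behind the detection
flags. Tests passing on these panels therefore demonstrate the estimators'
correctness and calibration, not performance under realistic LD structure.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere, matching VCF; variant
  positions must be sorted (non-decreasing; records produced by splitting a
  multi-allelic site share a position). Multi-allelic records are rejected
  by default and split to biallelic on request, with other-allele genotypes
  set missing.
* MAF uses non-missing calls only; the missing-rate filter handles
  missingness separately. Both filter bounds are inclusive; "less than 30%
  missing" vs "at most 30%" is not decidable from convention, and the
  inclusive reading is documented here once.
* Smoothed Ho values are reported at the leading variant and at the
  midpoint of the window's defined endpoints; undefined Ho values are
  skipped so windows span consecutive *defined* SNPs.
* In end-to-end fine-mapping experiments, structure covariates are computed
  from the whole panel rather than the candidate region: region-only PCs
  both absorb part of the causal signal and model structure poorly, which
  is also why genome-wide ancestry estimates are the field's practice.
* Perfect model fits (zero residual variance) report the smallest positive
  double rather than p = 0, keeping $-\log_{10} p$ finite.
* Problem sizes used by the test suite — e.g. 10,000 null variants on 300
  samples for calibration checks, 100 seeds of 500 × 200 panels for the
  recovery experiment, 10,000 Monte-Carlo replicates against the analytic
  cross-number oracle — were chosen so that sampling error is small relative
  to the tolerances asserted.

## Known limitations

* The Ho scan assumes biallelic SNPs; indels and multi-allelic sites must be
  normalized upstream.
* With few crosses the Ho = 1 set is rarely a singleton; the association
  intersection is load-bearing, and the cross-number simulation exists
  precisely to choose N.
* No mixed-model (kinship) association and no genome-wide scan
  orchestration: the association step here is candidate-region only, by
  scope.
* π per bp divides by the window span, treating unsequenced invariant sites
  as invariant; in panels with large callability gaps this understates π,
  and only the short terminal window can be rescaled (`partialExact`) since
  per-site callability is not tracked.
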