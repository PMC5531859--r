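---
title: "Detecting cancer genetic dependencies from loss-of-function screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cancer genetic dependencies from loss-of-function screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depscan)
```

## The model

A loss-of-function screen assigns each (cell line, gene target) pair a
quantitative sensitivity score; by field convention increasingly negative
scores mean greater inhibition of cell growth. Given a panel of cell lines
annotated for likely functional alterations in a driver gene, a *cancer
genetic dependency* (CGD) is an association in which the altered lines are
selectively sensitive to inhibition of a target gene.

The comparison is deliberately non-parametric. Screens from different
platforms use incommensurable scoring schemes (zGARP, ATARiS phenotype
scores, robust Z, CRISPR CS scores), none with a defensible distributional
model, so each driver/target/context combination is tested with a
one-sided Mann–Whitney U test: is the altered group stochastically more
sensitive (lower-scoring) than the wild-type group? Writing $n_1$ and
$n_2$ for the altered and wild-type group sizes,

$$U = \#\{(a, w): x_a < x_w\} + \tfrac12\,\#\{(a, w): x_a = x_w\},
\qquad \mathrm{CLES} = \frac{U}{n_1 n_2},$$

where the common-language effect size CLES is the probability that a
randomly chosen altered line is more sensitive than a randomly chosen
wild-type line — identical to the area under the ROC curve. Each record
also carries the difference of group medians in the screen's own score
units, as an interpretable magnitude.

Because the test is rank-based, CLES and p are invariant under any
strictly increasing rescaling of the scores; this is what makes one engine
applicable uniformly across heterogeneous screens.

### p-values

Two regimes are used, recorded per record in `p_method`:

- **Exact** (tie-free samples, $n_1+n_2 \le 30$): $P(U \ge u)$ is computed
  from the full null distribution of $U$, obtained by the standard count
  recursion $N(u; m, n) = N(u-n; m-1, n) + N(u; m, n-1)$. Counts up to
  $\binom{30}{15} \approx 1.6\times10^8$ are exactly representable in
  doubles, and the distribution is cached per $(n_1, n_2)$, so repeated
  tests at the same group sizes cost a single table lookup.
- **Normal approximation** (ties, or larger samples): mean $n_1 n_2/2$,
  the usual tie-corrected variance, and a continuity correction of $1/2$
  toward the null. When the pooled scores are all identical the variance
  is zero; the data carry no ordering information and the test reports
  p = 1 with a degenerate-data warning.

Both routes are checked in the test suite against two independent oracles:
brute-force enumeration of all $\binom{n_1+n_2}{n_1}$ group assignments,
and `stats::wilcox.test`.

## Functional alteration calling

Alterations are called per driver gene from two pre-processed inputs: a
mutation table (effect class plus the number of prior mutations of the
same site in a COSMIC-like catalogue) and a gene-level copy-number table
(minimum and maximum segment copy number over the coding sequence).
Variant-effect prediction and raw SNP-array segmentation are out of scope;
the tables are the contract.

| rule | criterion |
|---|---|
| recurrent mutation | missense or in-frame indel with site recurrence ≥ 3 |
| truncating (TSG only) | nonsense, frameshift or splice-site, unconditionally |
| amplification | minimum copy number over the CDS ≥ 8 ("entire coding sequence") |
| deletion | minimum copy number 0 ("any part of the coding sequence") |

Oncogenes with mode `both` are altered on amplification OR recurrent
mutation; tumor suppressors on deletion OR qualifying mutation. A small
set of oncogenes is restricted by mode: amplification-only (ERBB2, MYC,
MYCN) and mutation-only (KRAS, BRAF, NRAS, HRAS) — `defaultDrivers()`
ships exactly these seven, and every other driver is user configuration
with mode `both`, since the appropriate driver panel is study-specific.

Two modelling choices deserve note. First, cell lines whose alterations
fail the functional rules (say, a non-recurrent missense in a tumor
suppressor) are pooled into the wild-type group by default, because the
call matrix is binary; `scanDependencies(excludeNonFunctional = TRUE)`
instead drops such lines from the comparison, which is the conservative
reading of "no alteration in that gene". Second, splice-site recurrence is
ignored for tumor suppressors — the truncating rule lists splice-site
unconditionally.

## Scanning, filtering, de-duplication

Contexts are pan-cancer plus each tissue present in the shared panel
(the tissue is carried in the cell line name, `NAME_TISSUE`, and split at
the first underscore: harmonized names contain no underscore, tissues
may). Within each context a driver is testable when altered in at least 3
screened lines; the wild-type minimum is also 3 — the published rule
states only the altered-side minimum, and the symmetric default is chosen
so both medians are meaningful. Missing scores are dropped pairwise per
target, never imputed. Driver selection is applied per dataset and
context, and scan output is deterministically ordered (context, driver
entrez, target entrez, suffix), so identical inputs give byte-identical
results.

Retention uses the published thresholds exactly as printed: strict
p < 0.05 and inclusive CLES ≥ 0.65. Where a gene carries multiple score
solutions (ATARiS-style suffixed columns), the solution with the lowest
p-value is kept *before* filtering, so each gene is represented by its
best reagent solution; ties break by higher CLES, then lexicographically
smallest suffix. No multiple-testing correction is applied by default —
the resource design is nominal significance plus an effect-size floor —
but Benjamini–Hochberg q-values per (dataset, context) family are
available via `adjustPvalues(..., "benjamini_hochberg")`.

Z-score normalization (`zScoreNormalize`) standardizes to mean 0 and
sample sd 1 (n−1 denominator). The axis is a parameter because the
normalization's purpose — comparability of zGARP scores across cell
lines — does not pin it down: the default `per_cell_line` standardizes
each cell line's score vector, which directly equalizes per-line score
distributions; `per_target` is available and the choice is recorded in
the run manifest.

## Annotation

- **Functional interactions**: edges above combined score 0.4 (strict)
  are kept from a STRING-like edge list; 0–999 integer scores are
  auto-detected as the milli scale and divided by 1000. Tiers partition
  (0.4, 1]: medium ≤ 0.7 < high ≤ 0.9 < highest, configurable since the
  upstream conventions, not the method, define them. Self-edges are
  dropped, so a driver–driver dependency (oncogene addiction) annotates
  as `none` rather than trivially `highest`.
- **Inhibitors**: only `inhibitor` relationships are kept from a
  DGIdb-like table, and the MyCancerGenome / MyCancerGenomeClinicalTrial
  sources are excluded (they report drug–mutation efficacy, not direct
  target inhibition).
- **Multiple hits**: a (driver entrez, target entrez) pair retained in
  ≥ 2 distinct datasets is flagged in all of them. Matching ignores
  context and reagent suffix — cross-dataset replication is evidence
  about the gene pair, not about a particular reagent or tissue slice —
  and requires the pair to pass the filter in both datasets, not merely
  to have been tested.
- **Gene identity**: lookup resolves case-insensitively against primary
  symbols first, then synonyms, so a synonym shadowed by a real symbol
  (the HER2/ERBB2 situation) resolves to the primary gene; ambiguous
  synonyms are an error listing the candidates.

## The synthetic-data generator

`generateScreen()` emulates the statistical structure the test assumes:
independent per-target score vectors with a location shift between groups.
Background scores are standard normal — a convenience, not an assumption,
since the rank test never uses normality; a rescaled $t_3$ alternative
exercises heavy tails. The defaults are the package's reference
simulation conditions, fixed once: 30 cell lines (10 altered / 20
wild-type), 100 targets, planted mean shift −2, noise sd 1. These sizes
sit in the realistic range for a mid-size screen panel and give the
planted effect high but not saturating power, so regressions move the
measured rates.

`generateGenotype()` writes mutation/copy-number records that the calling
rules invert exactly, plus decoys one step below each rule boundary (site
recurrence 2, min copy number 7, min copy number 1) so that threshold
regressions change call counts. `generateAnnotationFixtures()` places
interaction scores at 0.35/0.45/0.75/0.95, straddling every tier
boundary.

What the generator deliberately does **not** model: correlation between
targets (seed-sequence off-target families), batch effects, panel
composition biases, or heteroscedastic noise across cell lines. Passing
tests therefore demonstrate the engine's correctness and calibration
under exchangeable noise, not robustness to the artifacts of real
screens — on real data the nominal false-positive rate should be read as
optimistic, which is exactly why the published design pairs nominal p
with an effect-size floor and cross-dataset replication flags.

## Calibration and power (computed by the test suite)

With no planted effect, the per-test retention rate of the joint
p < 0.05 ∧ CLES ≥ 0.65 filter over 200 replicate screens is compared to a
direct Monte-Carlo oracle of the same joint event (built from
`wilcox.test` plus an outer-product CLES) and must agree within 3
binomial standard errors. At 10/20 group sizes the CLES floor (U ≥ 130)
is weaker than the p threshold (U ≥ 138), so the joint null rate is just
below 0.05. With the planted −2 shift the pair must be recovered in
> 95% of 200 replicates while null targets stay at the calibrated null
rate. These checks run in `tests/testthat/test-acceptance.R` and are
recomputed from scratch by `scripts/acceptance.R`.

## Numerical and degenerate-input choices

- Scores are written with `%.17g`, so write → parse round-trips doubles
  exactly and a second write is byte-identical.
- Blank cells, `NA` and `NaN` all read as missing; missing is always
  written as a blank cell.
- Target labels parse as `SYMBOL_ENTREZID[_SUFFIX]`; the trailing segment
  is a suffix only when the second-to-last segment parses as an entrez
  id, and anything else fails loudly rather than guessing. A symbol that
  itself ends in `_<digits>` is inherently ambiguous in this dialect and
  will be read as entrez + suffix.
- Cell line harmonization (uppercase, strip punctuation) is idempotent;
  raw identifiers without a tissue part (e.g. bare COSMIC ids) must come
  with a rename map, there is no live lookup.
- An empty altered or wild-type group is a skip during scanning and an
  error in the bare statistics functions.
- Degenerate (all-tied) samples give p = 1 with a warning rather than an
  error, so one flat target cannot abort a scan.

## Known limitations

- The binary alteration matrix cannot express allelic dose or zygosity.
- Exact p-values are limited to tie-free samples; heavily tied score
  scales (integer-valued screens) always use the corrected normal
  approximation, which is anti-conservative below ~8 total lines —
  panels that small are already excluded by the 10-line minimum.
- Cross-dataset flags treat datasets as independent, which overstates
  replication when screens share cell lines and reagent libraries.
- The pipeline trusts the input effect classes; no VCF-level re-calling.
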