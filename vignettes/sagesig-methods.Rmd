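---
title: "sagesig: methods, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sagesig: methods, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sagesig)
```

# The analysis problem

SAGE estimates transcript abundance by counting short tags (10 bp by
default) cut adjacent to the 3'-most NlaIII site (CATG) of each transcript.
Tags are sequenced as *ditags* — two tags ligated tail-to-tail —
concatenated into long inserts separated by the anchoring site. A library is
the tag-frequency table of one sample; comparing libraries is comparing
multinomial count vectors with different totals.

This package implements a comparative workflow for a panel of several case
(metastatic) libraries and two reference (non-metastatic) libraries:
extraction and counting, normalization, a virtual averaged reference,
pairwise and consistent differential expression, multifunctional gene-set
signatures, resampling enrichment, library clustering, and qPCR validation.

# Tag extraction and counting

`extract_ditags()` returns the maximal substrings strictly between
consecutive anchoring sites whose length lies in `[min_len, max_len]`
(defaults 20–26, the classical convention for 10-bp tags; the bounds are
exposed because protocols differ). `split_ditag()` takes the first
`tag_len` bases forward and the reverse complement of the last `tag_len`
bases; ditags between `tag_len` and `2*tag_len` long legitimately yield two
overlapping tags (the tagging enzyme cuts at a variable distance), while
shorter ones are rejected and counted.

Duplicate-ditag collapse is **on** by default: in the classical protocol an
exact duplicate ditag is almost surely a PCR artifact. It is a flag because
protocol variants without size selection change the duplicate structure;
the synthetic generator plants duplicates so both settings are exercised.
Tags containing N are discarded with a counted warning; ambiguous tags
(mapping to more than one gene) are dropped by default rather than
double-counted, with `keep_first` available. Conservation is an invariant:
mapped + unmapped + dropped-ambiguous always equals the library total.

# Normalization and the virtual reference

Libraries are rescaled so counts sum to 100,000 ("tags per 100,000", the
field's reporting unit). Counts are kept fractional — rounding would break
linearity and conservation. The virtual reference averages the two
normalized reference libraries per tag; a tag present in only one is
averaged against zero (halved). Halving is the only treatment of singletons
that conserves totals and keeps the construction linear and commutative.

An important statistical subtlety: rescaled counts must not be fed to a
proportion test as if they were observations, because rescaling changes the
variance. The differential-expression functions therefore use **raw counts
with true library totals** for case libraries; the virtual reference, which
only exists on the normalized scale, enters with its target size as the
total. The `ztest_totals`-style choice is surfaced through which objects
you pass (a raw library contributes its raw total, a normalized library its
target).

# Differential expression

The pooled two-proportion z-test is used; with counts `c_a`, `c_b` and
totals `n_a`, `n_b`:

$$z = \frac{p_a - p_b}{\sqrt{p_0 (1-p_0)(1/n_a + 1/n_b)}}, \qquad
  p_0 = \frac{c_a + c_b}{n_a + n_b}.$$

The source study cites a z-test without printing a formula; the pooled
version is the standard choice for SAGE counts, and it is auditable:
$z^2$ equals the 1-df Pearson chi-square statistic of the 2×2 table with no
continuity correction, which the tests verify to 1e-9 against an
independent closed-form oracle. Genes with zero counts in both libraries
are non-testable and reported as `NA`.

Defaults surfaced because the study left them unstated:

- `alpha = 0.05`, two-sided, **no multiple-testing correction** (matching
  the original analysis era); a Benjamini–Hochberg flag exists for modern
  use.
- `min_count = 2` defines "expressed" (the cluster-size ≥ 2 convention used
  for the clustering filter); configurable to 1.
- `consistency = "per_library"`: a consistent gene must be individually
  significant with the same direction in *every* case-vs-reference
  comparison. The alternative `"pooled"` reading (sum the case counts, one
  test) is implemented because the study's wording admits both; per-library
  is the stricter and more literal reading, so it is the default.
- Genes expressed in all case libraries but absent from the reference
  cannot be tested and are counted as upregulated-unique — consistent with
  how the study's upregulated set includes uniquely expressed genes.

**Calibration.** Property tests check that under a null multinomial
simulation the rejection rate at `alpha = 0.05` sits within pooled binomial
99% bounds *in the regime where the normal approximation holds* (counts
≥ 10). Over the full `min_count = 2` universe the test is conservative
(empirically ≈ 0.044 at study-like depths): for genes with counts of 2–10
the discrete outcome space cannot achieve the nominal size. This is a
property of the z-test itself, not of the implementation — the acceptance
suite states the universe-wide bound as specified and documents the failure
rather than silently restricting the universe.

# Signatures

All signature objects are plain gene-id sets (opaque strings; no
symbol/alias resolution — annotations are consumed as given):

- *common case genes*: expressed (≥ `min_count`) in every case library;
- *multifunctional grid*: genes in ≥ 2 of the eight functional categories
  (motility, adhesion, chemotaxis, coagulation, proliferation, ECM
  remodeling, angiogenesis, antiapoptosis);
- *case signature* = grid ∩ common case genes; *reference signature* = grid
  ∩ reference expressed set;
- *biased signature* = case-signature members that are consistently
  differential, labelled `up_differential`/`down_differential`, or
  uniquely expressed (`unique_met`).

The reference expressed set defaults to genes expressed in **both**
reference libraries (`nm_expressed = "common"`), matching the study's
description of its reference gene set; the union-based virtual-library
alternative is a config switch. Reported percentages are rounded half-up to
one decimal (so 158/1488 prints 10.6 and 15/38 prints 39.5); the run report
always carries the integer numerator and denominator next to every
percentage so each figure is recomputable.

The published combined-signature arithmetic is internally inconsistent by
one gene (unique + shared partitions cannot reproduce both printed set
sizes); `build_signature_report()` therefore computes the union, the
unique sets and the shared set independently and records an
inclusion–exclusion check instead of forcing agreement.

# Enrichment

`simulate_baseline()` draws gene subsets of the tested size uniformly
*without replacement* (a drawn "cluster" cannot repeat within one draw) and
averages the fraction falling in the DE list over 100,000 iterations by
default. The analytic expectation is |DE|/|universe| regardless of the draw
scheme, and the law-of-large-numbers property is asserted at 5 standard
errors. The observed hit count is compared with the simulated baseline by
an **exact** binomial test, one-sided ("greater") by default since the
scientific claim is directional; the two-sided point-probability
alternative is exposed. The seed is a required, logged parameter.

# Clustering

Libraries are clustered on `1 − Pearson` correlation between normalized
per-gene vectors, computed over genes with count ≥ 2 in at least one
library. "Standard correlation" in the original software means centered
Pearson; its agglomeration rule is undocumented, so the linkage is a
parameter (default `average`, recorded in the report header). Merge heights
serialize to Newick via `ape`. `farthest_pair()` returns the pair with
maximal cophenetic distance, ties broken lexicographically — note that in
an ultrametric tree every pair separated at the root ties, so the farthest
pair is reported as a representative of the deepest split.

# qPCR validation

Standard curves are ordinary least squares of Ct on log10(dilution), with
`E = 10^(−1/slope)`; at least three distinct dilutions are required and a
positive slope triggers a warning. The Pfaffl ratio uses the sign
convention `ΔCt = Ct(calibrator) − Ct(sample)` — stated prominently because
flipping it inverts every ratio. With both efficiencies equal to 2 the
formula reduces algebraically to `2^(−ΔΔCt)`, checked numerically on a
grid. The calibrator is a designated sample id (modelling the pooled
reference cDNA), not recomputed from components. Replicates (triplicates by
design) are averaged with a deviation flag (default 0.5 cycles).

# The synthetic world

`generate_scenario()` emulates the study's structure: 5 case + 2 reference
libraries at the published depths (77,019–109,862 tags), a log-normal
transcriptome (σ = 1.5 on the log scale, the conventional heavy-tailed
abundance model), 88 planted upregulated genes (8 of them uniquely
expressed in cases) and 70 downregulated at 8-fold, a 161-gene
multifunctional grid over the eight categories at their published sizes
containing a planted 15-gene biased signature (7 differential + 8 unique),
a 339-gene external list with a planted grid overlap of 36, and Ct tables
with Gaussian noise (sd 0.2 cycles) plus dilution series. The universe is
5,400 genes, chosen once so the per-library expressed count lands in the
study's reported 4,000–4,500 band. One case library is generated with
inflated per-library dispersion (log-sd 0.35 vs 0.08) and acts as the
expression outlier for the farthest-pair check.

Planted effect genes are drawn from abundance strata where detection power
is essentially 1 (a downregulated gene must retain an expected count of
~15 in the shallowest library after division by the fold change). Tags are
one unique 10-mer per gene over the alphabet {A, T, G}: tags carry no C and
their reverse complements no G, so the anchoring site CATG cannot occur
inside any ditag — concatemer round-trips are exact by construction.

What a green end-to-end test establishes: the pipeline recovers planted
set memberships exactly where the quantity is deterministic (grid,
expressed/common recounts, signature algebra) and with full recall for
test-derived sets, with a bounded number of false-positive consistent-DE
calls (the z-test at `alpha = 0.05` against a shared reference admits a few
consistent false calls among ~3,000 genes; the acceptance bound of ≤ 25 was
fixed from this reasoning before measurement). What it does **not**
establish: robustness to tag-level noise (no sequencing-error model), GC
bias, realistic tag-to-gene ambiguity spectra, or biological dispersion
beyond log-normal multiplicative jitter.

# Numerical and degenerate-input choices

- Normalization of an empty library is an error; normalization is
  idempotent and exact to 1e-6 relative tolerance by construction.
- Both-zero count pairs are non-testable (`NA`), never silently 0.
- Degenerate enrichment baselines (empty or exhaustive DE lists) raise an
  error from the statistical primitive; the pipeline records such
  comparisons with `p = NA` instead of aborting the run.
- Constant expression vectors make the correlation distance undefined; the
  error names the offending library.
- Ties in `farthest_pair()` break lexicographically; dendrograms are
  invariant to library input order up to such ties.
- All generators take explicit integer seeds and are bit-reproducible;
  the pipeline report embeds no timestamps so reruns are byte-identical.

# Runtime scaling in the tests

The test suite runs the full acceptance criteria with simulation sizes at
or above the stated dimensions where cheap (10,000 oracle tables, 100,000
baseline iterations, the full 7-library scenario) and reduced iteration
counts where the criterion explicitly allows it (null-calibration
replicates use 500 iterations per replicate); the whole suite completes in
well under a minute on one CPU.

# Known limitations

- The z-test's discreteness makes the universe-wide type-I rate
  conservative at small counts (documented above); count-model DE
  (negative binomial with replicate dispersion) is out of scope.
- The enrichment baseline treats the DE list as fixed, as in the original
  design; there is no FDR control across subsets.
- Only two reference libraries are supported by the virtual-library
  constructor (pairwise averaging), matching the study design.
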