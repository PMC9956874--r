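---
title: "Exome matching: predicting dietary amino acid requirements from a transcriptome-weighted proteome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exome matching methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exomatch)
```

## The model

Many animals are protein limited, and for *Drosophila melanogaster* the
limitation acts through the single most under-supplied **essential** amino
acid (AA) in the diet. Exome matching predicts the dietary AA ratio an
organism needs from the AA composition its own genome encodes: if the
translated exome uses tryptophan rarely, the fly should need little dietary
tryptophan in molar terms.

The package implements three estimators of the demanded AA ratio, all
returning a 20-dimensional molar-fraction profile \(P(AA_i)\) with
\(\sum_i P(AA_i) = 1\):

1. **Protein-average** (the original exome match): compute each AA's
   relative abundance within every protein, then average those proportions
   with equal weight per protein. Protein length does not weight the
   average.
2. **Pooled**: sum raw residue counts over all isoforms and normalise once.
   This equals the weighted estimator with all weights equal, so comparing
   it with (3) isolates the effect of expression weighting.
3. **Transcriptome-weighted**: count the instances \(AA_{ij}\) of AA *i* in
   isoform *j*, weight by the isoform's transcript abundance \(E_j\) (FPKM),
   and normalise:
   \[ AA_i = \sum_j AA_{ij}\,E_j, \qquad P(AA_i) = \frac{AA_i}{\sum_i AA_i}. \]

The two unweighted conventions genuinely differ for length-heterogeneous
proteomes, which is why they are separate, explicitly named operations
rather than a default; conflating them silently changes results.

### Replicates

When several replicate transcriptomes are available, `weighted_profile()`
averages FPKM across replicate columns by default, while
`average_profiles()` supports the alternative route of building one profile
per replicate and averaging the profiles (reporting the per-AA standard
deviation for error bars). The two orders are near-equivalent; the
per-replicate-profile route is the one that reproduces replicate error
bars, so it is the one exposed for that purpose. Whether FPKM values should
be renormalised within a sample before cross-sample averaging is not
settled; the package uses raw FPKM, since the weighted estimator is
invariant to any global rescaling of a replicate and within-sample
renormalisation is exactly such a rescaling.

## Coverage and the limiting amino acid

Given a diet profile and a demand profile (both molar fractions), coverage
of AA *i* is \(100 \times \text{diet}_i / \text{demand}_i\) percent. The
essential AA with the lowest coverage is predicted limiting, and the
predicted relative gain from rebalancing the diet to the demand ratio at
fixed total AA is

\[ \text{gain} = 100\left(\frac{100}{\text{coverage}_{\text{limiting}}} - 1\right)\% . \]

Non-essential AAs get coverage values too (they are plotted in the tissue
panels) but are never selected as limiting, because the fly can synthesise
them. Ties in the minimal coverage are all flagged, with the alphabetically
first AA reported as primary — a determinism choice; real profiles at
double precision essentially never tie.

With the published diet ratios shipped in the package this machinery
reproduces the reference predictions: males fed the exome-matched ratio
(FLYAA) against the male transcriptome-weighted demand (MALEAA) are
tryptophan-limited at \(100 \times 0.010/0.012 = 83.3\%\) coverage
(predicted gain exactly 20%); females against FEMALEAA are lysine-limited
at 83.7% (gain 19.4%, printed as 20% at the tables' 3-decimal precision).

```{r}
d <- diet_profiles()
glance(aa_coverage(d$FLYAA, d$MALEAA))
glance(aa_coverage(d$FLYAA, d$FEMALEAA))
```

### Power analysis

Fecundity assays that test such predicted gains are sized with
\(n = (Z\sigma/E)^2\); `power_sample_size()` solves the relation for any of
its four quantities.

## The permutation null

Are observed profiles (FLYAA, MALEAA, FEMALEAA) unusual relative to what
arbitrary-but-realistic transcriptomes would produce? The null keeps the
proteome and the multiset of expression values fixed and randomly
reassigns the expression values to genes; each permutation yields a
weighted profile, and each profile's Euclidean distance to the
per-AA **median** permuted profile is recorded. An observed profile's
percentile is the percentage of permuted profiles strictly closer to the
median than it is.

Numerical choices, each of which alters results if made differently:

* **The median is not renormalised.** The component-wise median of unit-sum
  vectors does not itself sum to one; distances are measured to the raw
  median because renormalising would change every distance for no
  principled reason.
* **Gene level by default.** Expression is isoform-level FPKM but the null
  permutes gene labels. Genes differ in isoform count, so a literal swap of
  isoform expression vectors between genes is ill-defined. The package's
  semantics: each gene keeps its internal isoform-usage weights
  \(E_j / E_{\text{gene}}\) and the permutation shuffles gene **totals**
  across genes. This preserves the multiset of gene-level expression values
  exactly, moves all isoforms of a gene together, and reduces to plain
  isoform permutation when every gene has one isoform. `level = "isoform"`
  is available. Genes with zero total expression get equal within-gene
  weights (any weights would do — they multiply zero under the identity
  assignment, and under permutation only the composition vector matters).
* **Strict inequality for percentiles**, ties counting as not-exceeded,
  matching the "more distant than N% of permutations" reading.
* **Seeds are mandatory** and the RNG state of the calling session is left
  untouched.
* The default 20,000 permutations match the reference analysis; exhaustive
  enumeration of all \(n!\) assignments is available for up to 8 entities
  and is used to validate the sampler exactly.

Calibration: if the "observed" profile is itself produced by a random
reassignment, its percentile must be uniform on \([0, 100]\). The test
suite checks this with a Kolmogorov–Smirnov statistic over repeated trials
(300 trials x 200 permutations in the unit tests; 2,000 x 500 in the
acceptance checks, where the statistic stays below 0.05).

## Diet formulation

`formulate_diet()` turns a molar ratio plus a total AA concentration into a
wet-lab recipe. The total (default experiments use 10.7 g/L, with dilutions
at 5.4, 2.1 and 1.1 g/L) is interpreted as **free-base grams per litre**:
total moles \(N = \text{total} / \sum_i p_i M_i\), free-base grams
\(N p_i M_i\) for free molecular weight \(M_i\). Counter-ions of salt forms
(lysine and arginine monohydrochloride, the common commercial products) add
weigh-out mass — scaled by \(M^{salt}_i/M_i\) — but no amino acid, so
dilution series scale one profile linearly regardless of salt choice.
The free-base interpretation is also what the published stock-solution
gram amounts follow: recomputing them from the printed molar ratios at
10.7 g/L agrees within the rounding the 3-decimal ratios imply (the
coarsest, tryptophan at 0.010, carries 5% granularity), whereas
HCl-salt masses for lysine would overshoot the printed value by ~26%.

`split_stocks()` partitions a recipe across preparation stages following
standard holidic-food practice: isoleucine, leucine and tyrosine direct to
food before autoclaving (solubility), glutamate and cysteine as separate
post-autoclave solutions, the remaining essentials and non-essentials in
EAA/NEAA stocks. Splitting conserves every amount exactly. Non-AA diet
components (buffer, vitamins, lipids) are out of scope.

## The synthetic generator

`simulate_proteome()` emulates the statistical shape of the real inputs —
a multi-isoform proteome plus an isoform-by-replicate FPKM table — with
known ground truth:

* sequences are drawn residue-by-residue (multinomial) from a target
  profile. Real proteins have compositional autocorrelation, domain
  structure and biased length-composition coupling; none of that matters
  here because every downstream computation depends only on residue
  **counts**, which is exactly what the generator controls.
* expression is log-normal (`meanlog = 2`, `sdlog = 1.5`), giving the heavy
  right tail characteristic of FPKM tables, with multiplicative log-normal
  replicate noise (`sdlog = 0.2`); `uniform` and `point_mass` models support
  degenerate-case tests.
* the manifest records per-isoform counts and an **analytic**
  expression-weighted profile computed independently of the profile
  builders; the two must agree to 1e-12, which cross-validates generator
  and builders against each other.

What passing tests on such fixtures do *not* show: anything about FPKM
estimation quality, annotation errors, or isoform quantification ambiguity
in real data — the package consumes FPKM tables as given.

Test problem sizes were chosen to make the statistics decisive at desk
scale: the recovery check uses ~1.2e5 residues, where the per-AA
multinomial standard error is below \(0.5/\sqrt{N}\) so the \(3/\sqrt{N}\)
band is a ~6-sigma criterion; the unit-test calibration uses 300 trials of
200 permutations, where a miscalibrated percentile would exceed the KS
bound by an order of magnitude.

## Degenerate inputs and tolerances

* Profiles must sum to 1 within 1e-9 at construction (1e-6 after
  arithmetic chains); `normalize_counts()` refuses all-zero vectors and
  names the offending vector.
* Printed diet-ratio columns are accepted if they sum to within
  [0.98, 1.02] (rounding) and renormalised; anything outside is rejected as
  a probable unit mistake (e.g. a g/L column passed as ratios).
* Sequence cleaning drops non-canonical letters (X, U, B, ...) with a
  reported count rather than failing; records left empty are dropped with a
  warning. Stop symbols (`*`) are stripped silently.
* Isoforms in the proteome but missing from the expression table count as
  unexpressed (warning with a count); expression entries without a matching
  isoform are ignored (message). A fully unexpressed proteome is an error.
* Zero demand with nonzero supply yields infinite coverage, flagged and
  never limiting; zero demand and zero supply excludes the AA with a
  warning.

## Known limitations

* Single-AA limitation model: the predicted gain considers only the
  limiting AA; no co-limitation or substitution model.
* No modelling of translation efficiency, protein turnover, or body-protein
  AA retrieval; transcript abundance is taken as the demand weighting.
* Non-canonical amino acids are not profile dimensions.
* The package consumes translated proteomes and FPKM tables; it neither
  translates CDS nor quantifies reads.
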