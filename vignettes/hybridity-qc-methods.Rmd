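---
title: "Methods: marker-based QC of crossing blocks with hybriqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker-based QC of crossing blocks with hybriqc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybriqc)
```

## The model

`hybriqc` analyses biallelic SNP calls from a fixed QC panel genotyped on
the parents and putative F1 progenies of a manual crossing block. The core
assumption is the one that makes low-density hybridity testing work in a
self-pollinated crop: parental lines are (near-)homozygous inbreds, so at
any marker where the two parents of a cross are *opposite homozygotes* — an
informative locus — a genuine F1 is obligately heterozygous, while an
accidental self matches its female parent. Everything else in the package
is bookkeeping around that Mendelian fact: which loci are informative per
cross, how often each marker is informative across the cohort, and what
fraction of informative loci each F1 is heterozygous at.

Calls are normalised to four states against the panel definition — `HOM1`
(homozygous for panel allele 1), `HOM2`, `HET` (unordered: `T:C` ≡ `C:T`)
and missing. A call carrying an allele foreign to the marker's definition is
a validation error, not a genotype, because with KASP-style assays such a
call indicates a sample-tracking or assay problem that must surface, not be
absorbed.

## Per-marker statistics

Allele frequencies use gene counting: each homozygote contributes two copies
of its allele, each heterozygote one of each, missing calls are excluded
from the denominator. This is the population-genetics standard and the only
defensible choice when heterozygotes are present. From the frequencies,
PIC\(_j = 1 - \sum_i p_i^2\) (max 0.5 for a biallelic locus);
per-marker heterozygosity is the share of *non-missing* calls that are
`HET`, so that missingness does not dilute it; missingness is the share of
all calls.

Two panel-admission screens are applied per marker, mirroring how QC panels
are selected: a *bias* screen (either allele called more than 75% of the
time, i.e. MAF > 0.75, strict) and a *heterozygosity* screen (a passing
marker must show fewer than 4% heterozygous calls in an inbred reference
pool, so `pr_het >= 0.04` fails). Note the screens describe panel behaviour
in a *diverse, inbred* reference set; on a cohort that includes F1s or a
frequency-skewed breeding pool, failing the screen is informative output,
not an error.

## Filtering and fingerprints

Dataset filtering removes samples first (missingness strictly above the
threshold, default 10%), then markers (minor allele frequency strictly below
the floor, default 0.05), recomputed on the surviving samples. Samples
before markers mirrors the analysis sequence the statistics feed (parents
are dropped for relatedness before marker-level properties matter).
Thresholds phrased "more than X%" are implemented as strict inequalities
throughout (10% sample filter, 55% fingerprint-reliability rule). Filtering
twice with the same thresholds is a practical no-op on realistic data;
strictly speaking marker removal can alter sample missingness fractions, so
the idempotence property is exercised in the tests on a low-missingness
cohort rather than asserted universally.

A parental fingerprint is the ordered call string over the panel, rendered
with the panel alleles; profiles with more than 55% missing information are
flagged unreliable rather than dropped, since even a partial fingerprint
has identity value.

## Polymorphism and marker efficiency

Each cross's parental pair is scored per marker: 1 (opposite homozygotes),
0 (identical homozygotes), NA (either call missing). A *heterozygous parent
call also scores NA* under the default policy: the package's reading is
that hybridity at such a locus is undiagnosable — a het × hom cross produces
heterozygous and homozygous F1s in equal expectation, so the locus cannot
separate hybrid from self. The scoring convention itself only names missing
data as NA, so the het policy is configurable
(`het_policy = "zero"` treats het loci as simply not polymorphic).

Percent parental polymorphism is `100·Pm/Tm` with `Tm` the *evaluable*
(non-NA) markers of that pair, not the full panel size: the efficiency
formula explicitly excludes pairs with missing calls from its denominator,
and the same exclusion is applied per cross for coherence between the two
statistics. On complete data the two conventions coincide; on incomplete
data the evaluable-denominator version is the one for which the mean
identity (mean per-marker efficiency = mean per-cross polymorphism) holds,
which the tests exploit. Crosses that share a parent pair are scored
independently per cross ID, as they are distinct design rows.

## Hybridity classification

For each putative F1: informative loci are those scored 1 for its parents;
`L_het` counts informative loci at which the F1 is heterozygous; F1 calls
missing at informative loci are removed from both numerator and denominator;
hybridity is `100·L_het/(evaluable loci)`. Classification:

- `UNDETERMINED_NO_POLYMORPHISM` when the pair has no informative locus;
- `UNDETERMINED_MISSING` when fewer than `min_informative` informative loci
  are evaluable (default 1 — the weakest defensible rule, since the source
  convention for "undetermined due to missing data" is not quantified; a
  `low_power` flag marks crosses with fewer than 3 informative markers,
  where a single-locus call is fragile);
- otherwise `TRUE_HYBRID` iff hybridity ≥ 20%, else `SELF`. The boundary
  goes to `TRUE_HYBRID` because the selfing rule is phrased as "below 20%".

The threshold is a tube-mixup/genotyping-error guard: a true hybrid should
sit near 100%, a self near 0%, so 20% tolerates roughly one bad call in five
informative loci without flipping the class. Raising the threshold can only
move samples from `TRUE_HYBRID` to `SELF`, never the reverse (tested as a
monotonicity property).

An F1 that is the *male-allele homozygote* at an informative locus is
counted as non-heterozygous (evidence against hybridity) but separately
tallied in `n_male_hom`: that genotype is impossible under both selfing and
true hybridization, so it signals outcrossing by stray pollen or a sample
swap. No category is assigned to it — the cohort-level four-way
classification stays intact — but the flag is retained per F1.

Reported percentages are rounded half-up to integer percent for display
(`round()`'s half-even rule would disagree with conventional reporting at
.5 boundaries); unrounded values are always retained.

## Relatedness

Dosage encoding 0 / 0.5 / 1 with *unscaled* Euclidean distance over
pairwise-complete loci keeps distances interpretable: two fully homozygous
lines differing at k loci sit at exactly √k, the maximum over a 17-marker
panel is √17 ≈ 4.12, and sister lines sit at 0. `stats::dist` rescales sums
under pairwise deletion, which would break that closed form — hence the
in-package implementation.

Neighbor-Joining is implemented in-package (classic Saitou–Nei: join the
minimal-`Q` pair, standard branch-length and distance-update formulas) with
two contract details pinned down: ties on `Q` break to the lexicographically
smallest index pair, making output deterministic; and negative pendant
branch lengths — a known NJ artefact on non-additive inputs — are clamped to
zero with the deficit transferred to the sister branch, preserving the path
length between the joined nodes. Raw pre-clamp lengths are retained in the
`join_log` attribute. On additive matrices NJ is exact, which the tests
verify on 4- and 5-taxon trees against both the generating tree and
`ape::nj` as an independent oracle. Trees serialize to newick via `ape`.

PCA mean-imputes missing dosages per marker, centers without unit-variance
scaling (markers share a scale already; scaling would up-weight
near-monomorphic markers, the opposite of what a contribution analysis
wants), and uses `stats::prcomp`. Component signs are fixed by making each
loading vector's largest-magnitude entry positive, so runs are bit
reproducible. Marker contributions are squared loadings normalised per
component (summing to 100%), and the combined contribution over leading
components weights each component by its eigenvalue — an average that keeps
the 100% total, verified to 1e-9.

Cluster counts are deliberately not reported: cutting an NJ tree into "k
groups" requires a cut rule that is a user decision, not a property of the
data.

## The synthetic cohort generator

`sim_config()` defaults describe the reference crossing-block scenario the
package was designed around: 220 female parents in four source groups
(89/31/85/15), two genetically identical sister-line males, 225 crosses
(15 + 2 females crossed to the second male, 5 of them used with both males)
and 1,436 F1s allocated 428/214/637/157 across the groups; selfing rate
0.15; residual parental heterozygosity 0.02 per locus; per-call missingness
0.05; no genotyping error. Per-marker allele-1 frequencies default to an
even 0.53–0.99 gradient (mean 0.76), emulating a breeding pool in which a
nominally neutral panel drifts to a mean MAF near 0.76 with markers ranging
from nearly balanced to nearly fixed; `rep(0.5, 17)` gives the neutral
regime instead.

Generation draws true parental genotypes (HOM1 with probability `p_j`, then
HET at the residual rate), true F1s (a gamete from each parent for hybrids,
two female gametes for selfs — so a selfed heterozygous female locus
segregates 1:2:1, the biologically correct behaviour that stresses the
classifier the way residual heterozygosity does in practice), and only then
applies observation noise (missingness, and optionally a uniform
state-swap genotyping error) to the merged observed matrix. Gametes always
come from the uncorrupted parental genotypes, and truth labels are recorded
pre-corruption.

What the generator does **not** emulate, and hence what passing tests do
not show about real data: selfing events are independent per F1, whereas in
a real crossing block selfing clusters within crosses (an operator or
flower-timing effect), concentrating failures; this is why the simulated
percent-of-crosses-at-100%-success (≈35% under the defaults, with ~6 F1s
per cross and s = 0.15) is far below what a clustered-selfing cohort can
show even at the same overall selfing rate. Missingness is likewise
homogeneous per call, so the handful of catastrophically missing samples
real plates produce (>55% missing) are rare under the defaults. There is no
linkage or recombination model (irrelevant for single-locus QC scoring),
no pedigree structure among females, and no foreign-pollen outcross class.

## Numerical choices and degenerate inputs

- Allele-frequency sums are validated to 1e-9; the PIC identity
  `pic = 1 − maf² − mnaf²` holds to 1e-12.
- All-missing markers yield undefined (NA) frequencies/PIC and are flagged,
  not errored, at the table level; the scalar `allele_frequencies()` errors,
  naming the marker.
- A sample pair with zero shared non-missing loci has undefined distance
  (flagged); the pipeline only builds a tree when the distance matrix is
  complete.
- NJ for n = 2 returns the single edge split evenly; n = 3 uses the
  three-point closed form.
- Zero-variance matrices error in PCA rather than return a meaningless
  decomposition.
- The bundled panel reproduces its source table verbatim, including one
  marker whose printed position interval is inverted (end < start);
  `read_marker_panel()` warns rather than errors on that row.

## Problem sizes

The default end-to-end scenario (1,658 samples × 17 markers, 225 crosses,
relatedness over ~180 parents) runs the full pipeline in about two seconds;
the test suite uses cohorts between 2 and 2,000 samples, with the largest
classifier-recovery check at 1,000 F1s, chosen so the binomial
selfing-rate bound (3 standard errors at n = 1000, ±0.034) is a sharp test
while the suite stays fast.
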