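---
title: "Methods and design of the slinfer synthetic-lethality screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the slinfer synthetic-lethality screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slinfer)
```

# The inference problem

A synthetic lethal interaction (SLI) is a gene pair whose joint
inactivation is lethal while either single inactivation is viable. In
cancer, one member of such a pair is often already inactivated by mutation
or copy loss, making its partner a selective drug target. Direct
experimental mapping of SLIs in human cells is expensive, so computational
screens mine observational multi-omics data (tumor and cell-line
expression, copy number, mutations) and perturbation data (CRISPR/shRNA
gene-effect scores) for the statistical footprints such pairs leave behind.

`slinfer` implements three complementary inference strategies over plain
tabular inputs, plus the statistical kernels, molecular-state calling,
gene-set enrichment, synthetic-data generation and command-line plumbing
they need. This vignette records the models, the tunable parameters and
their defaults, the numerical choices, and the design decisions that were
genuinely open — together with what the synthetic benchmarks do and do not
demonstrate about behavior on real data.

# Statistical kernels

All workflow p-values come from five kernels, chosen so that each has a
small-sample regime verifiable by brute-force enumeration.

**Wilcoxon rank-sum** (`rankSumTest`). The statistic is the rank sum of the
first group in the pooled sample, with average ranks on ties. When the
pooled size is at most `exactLimit` (default 10, bounding enumeration at
choose(10, 5) = 252 assignments) the null distribution is enumerated over
all assignments of group labels to ranks, which is exact under ties as
well; otherwise a tie-corrected normal approximation with continuity
correction is used. One-sided p-values follow the standard convention
P(W ≤ w) / P(W ≥ w); the two-sided p is twice the smaller tail, capped at
1 (the convention of R's exact `wilcox.test`). A fully tied sample carries
no evidence and reports p = 1.

**Welch t-test** (`welchTTest`). Unequal-variance t with
Welch–Satterthwaite degrees of freedom; mutant groups in dependency screens
are small and have no reason to share the wild-type variance, which is why
the unequal-variance form was chosen over Student's t. Degenerate inputs
are results, not errors: both groups constant and equal gives t = 0,
p = 1; both constant but unequal is reported with p = 0 and a `degenerate`
flag so screens can surface rather than hide pathological columns.

**Spearman correlation** (`spearmanTest`). Rho is the Pearson correlation
of average ranks. For n ≤ 7 complete pairs without ties the p-value is
exact over all n! orderings; otherwise the t approximation with n − 2
degrees of freedom is used. Zero variance in either vector yields an
undefined-correlation result with a flag.

**Hypergeometric tail** (`hypergeomTail`) delegates to `phyper`, and
**Benjamini–Hochberg adjustment** (`bhAdjust`) to `p.adjust`, with NA
p-values propagated and excluded from the test count. BH was selected as
the FDR estimator because it is the field default for this kind of screen;
no permutation-based FDR or Bonferroni mode is provided. Enumeration uses
a 1e-9 tolerance when comparing tied rank sums or rhos, well below the
spacing of attainable values at enumerable sizes.

The test suite checks every kernel against an independently written
oracle: exhaustive label-assignment enumeration for the rank sum (all
pooled sizes up to 8, tied and untied), full permutation enumeration for
Spearman (n ≤ 6), direct mass summation for the hypergeometric tail (the
complete grid N ≤ 60), a literal step-up implementation for BH, and the
closed-form Welch formulas.

# Molecular-state calling

Every conditional test needs a binary notion of "query inactivated".

*Functional mutations.* A (sample, gene) cell is mutated when the mutation
table holds at least one record whose variant classification is in the
damaging set. The default set (`damagingClasses()`) contains the
non-silent, protein-altering MAF classes (nonsense, missense, frameshifts,
splice site, nonstop, start-codon changes); Silent/UTR/intron classes are
excluded. Whether every missense call should count is genuinely arguable —
no variant-effect scoring is attempted, and the set is fully overridable.

*Inactivation.* A gene is inactive in a sample when it is functionally
mutated, or when its expression falls strictly below the gene's
`exprPercentile` quantile (default 10, linear-interpolation quantiles,
R type 7) while its copy-number log2 ratio is below `cnMax` (default
−0.3). Percentiles are computed across the analyzed sample subset, not the
full cohort, so tissue-restricted runs are self-contained. Missing values
never satisfy a clause. *Overactivation* mirrors this: expression strictly
above the 100 − `exprPercentile` quantile and copy ratio above `cnMin`
(default +0.3). These thresholds are the long-standing defaults of
data-mining SL screens; they are exposed per run. A consequence worth
remembering: the expression clause can mark at most ~`exprPercentile`% of
samples per gene, which caps how much of a cohort omics-driven (as opposed
to mutation-driven) inactivation can ever cover.

# The DAISY-style screen

For each (query, partner) pair, each dataset contributes up to three
evidence rows:

* **SoF** — rank-sum test of the partner's copy number in query-inactive
  vs. remaining samples, alternative "greater". The direction encodes the
  survival-of-the-fittest argument: pairs whose co-loss kills the cell are
  depleted among surviving tumors, so where the query is lost the partner's
  copy number should sit *higher* than elsewhere. In SDL mode the
  conditioning switches to overactivation and the alternative flips.
* **FunEx** — rank-sum test of the partner's gene-effect score in
  query-inactive (SL) or query-overactive (SDL) lines, alternative "less".
* **Co-expression** — one-sided Spearman test for positive correlation.

Group-size minima (`minGroup` = 3 conditioned/unconditioned samples for the
rank-sum modules, `minPairs` = 10 complete pairs for co-expression) produce
*untestable* evidence rows rather than errors, mirroring how real cohorts
fail: a gene absent from a platform, a mutation too rare in a tissue.

q-values are computed within each (module, dataset) family — not pooled
across modules — because the three modules test different hypotheses on
different data; pooling would let a heavily-tested module dilute another's
FDR. A pair's module passes when any dataset reaches that module's q
cutoff (default 0.05 each, individually settable); the pair is a combined
prediction when all three modules pass. Untestable modules fail the
combination in strict mode (default); lenient mode skips them and flags
the prediction, supporting the common situation where only some layers
exist for a cohort.

# The MDSLP screen

`mdslpTest` compares the partner's gene-effect between functionally
mutated and wild-type lines with the two-sided Welch t-test and reports
Δ = mean(mutant) − mean(wild-type); Δ < 0 supports synthetic lethality.
Minimum group sizes default to 3 on both sides — Welch needs at least 2
per group for a variance, and 3 guards against degenerate estimates.
`mdslpScreen` crosses mutated genes, partners, gene-effect datasets
(shRNA- and CRISPR-derived matrices are interchangeable inputs
distinguished only by label) and contexts, then applies BH within each
(context, dataset) family. Whether the original formulations of this test
pooled contexts before correction is not documented anywhere we know of;
per-family correction was chosen and is reported per row, so a caller can
re-pool if desired. The default significance threshold is q ≤ 0.05, with
q ≤ 0.1 a common reporting convention for shRNA-derived screens.

# The CGI workflow

Yeast SGA screens score each double mutant with an ε value; negative ε
means the double mutant is less fit than the multiplicative expectation of
the single mutants, and strongly negative ε with small p is the yeast
definition of synthetic lethality. `filterNegativeInteractions` keeps
records with ε ≤ `epsMax` and p ≤ `pMax` (defaults −0.12 and 0.05, the
stringent convention for SGA data; a non-negative `epsMax` is rejected as
contradictory), keeping the most negative record per unordered pair.
`mapToHuman` strips allele suffixes (text after the first underscore —
arrays encode alleles, orthology is gene-level), expands each pair to the
cross product of its members' ortholog sets rather than picking a best
hit (the workflow is a candidate generator; downstream evidence filters),
drops unmapped members and post-mapping self-pairs, and merges provenance
for human pairs reached from several yeast pairs. Output ordering is
canonical (gene_a < gene_b, sorted), so runs are comparable byte for byte.

# Gene-set enrichment

`enrichGeneSets` applies the hypergeometric upper tail per set with BH
across sets. The universe defaults to the screened candidate space rather
than the whole genome: the query set was sampled from the genes the screen
actually tested, and using a larger universe would overstate significance.
Both p and q are reported, since display conventions differ on which to
threshold.

# The synthetic-cohort generator

`generateCohort` emulates a cell-line panel with planted SL pairs so that
every stage of the package can be tested end to end without external data.
Background structure, with fixed documented scales:

* expression: per-gene means ~ N(7, 1) (log2-like), unit noise;
* copy number: N(0, 0.15) plus a −0.8 shift on copy-loss events, drawn
  per cell with probability `lossRate`;
* lost genes also lose 1.5 expression units (dosage), so losses are
  visible to the expression clause of inactivation calling;
* gene effect: N(0, `noiseSd`), `noiseSd` = 0.3 by default;
* every gene is functionally mutated per cell with
  `backgroundMutationRate` = 0.05 (so non-planted query genes remain
  testable), classifications drawn from the damaging set; 5% of samples
  additionally receive a Silent decoy record to exercise the
  functional-mutation filter; cancer-type labels rotate round-robin over
  `nContexts` = 4.

For each planted pair (A, B), with A mutated at `mutationRate` = 0.2:

* in A-mutated samples, B's gene effect is shifted by
  −`dependencyShift` (default 1.0) — the FunEx/MDSLP signal;
* in A-mutated samples, B's loss probability is multiplied by
  1 − `coLossDepletion` (default 0.9) — the SoF signal;
* A and B share a latent factor: each gene's pre-dosage expression is
  √ρ·z + √(1−ρ)·ε with ρ = `coexpressionRho` = 0.7 — the co-expression
  signal. Because the independent loss-dosage term adds variance, the
  realized pair correlation is attenuated to approximately
  ρ / (1 + 1.5²·L(1−L)) ≈ 0.45 at the default loss rate L = 0.5; tests
  assert against this implied value, not the latent ρ.

Two generator choices deserve explanation. First, the planted effects
condition on A's *functional mutation* rather than on a broader
inactivation event: the mutation is the one planted state that every
detector (the MDSLP mutant group and the mutation clause of the DAISY
inactivation mask) observes directly, so the planted signal and the
measurable conditioning coincide and the benchmark measures detection
power rather than the overlap between two noisy state definitions. Second,
`lossRate` defaults to 0.5, emulating frequently lost loci of the kind SL
screens target. This is a power requirement one can compute: the SoF
rank-sum compares two mixtures that share their no-loss component, so its
separation (AUC) is capped near 0.5 + lossRate/2 even under total co-loss
depletion, and the 10th-percentile expression clause caps the
omics-driven part of the conditioning group at ~10% of samples. With rare
losses the depletion signal is simply not identifiable at cohort sizes of
a few hundred — real-world SoF analyses lean on tens of thousands of
tumors instead. At lossRate 0.5, depletion 0.9 and n = 500 the planted SoF
effect sits 5–6 null standard deviations from zero, which is what the
recovery benchmarks require.

`generateYeastScreen` emits one record per unordered gene pair: planted
negatives draw ε from N(`epsNegativeMean` = −0.25, 0.03) truncated below
−0.12 with p < 0.05, background pairs from N(0, 0.05) truncated above
−0.12 with uniform p. The truncation makes filter recovery exact by
construction — the generator plants an unambiguous ground truth rather
than a borderline one — so these benchmarks test the plumbing (filtering,
suffix stripping, ortholog expansion, deduplication), not threshold
sensitivity. Query and array identifiers carry `_sn`/`_dma` allele
suffixes to exercise stripping.

All randomness flows from one seeded Mersenne–Twister stream with fixed
normal/sample kinds, so cohorts are bit-reproducible across platforms, and
generators restore the caller's RNG state on exit.

## What the benchmarks do and do not show

The calibration and recovery checks run at deliberately modest sizes — the
package's own choices: null calibration on ten cohorts of 200 lines × 500
partner tests; recovery on twenty cohorts of 500 lines × 50 genes under
the strong-signal preset (shift 1.0 vs. noise 0.3, ρ 0.7, depletion 0.9);
CGI on a 100-gene screen with 20 planted negatives. Within those
conditions, MDSLP p-values are uniform under the null
(Kolmogorov–Smirnov), BH keeps the realized false-discovery proportion at
its nominal level, and all three workflows recover essentially all planted
pairs with at most a fraction of a false positive per run.

None of this transfers automatically to real cohorts. The generator draws
independent Gaussian backgrounds; real expression and dependency data have
heavy tails, batch structure, co-expression blocks among *non*-SL genes
and correlated copy-number segments, all of which inflate the effective
number of tests and can break FDR calibration. Mutation spectra are not
emulated (every damaging class is equally likely), platform discordance
between shRNA and CRISPR screens is a data property the package
deliberately does not model, and planted effect sizes are homogeneous
whereas real SLIs are context-dependent and usually weaker. The benchmarks
validate the statistics and the machinery, not biological discovery rates.

# Numerical and interface choices

Delimiters are auto-detected from the file extension (.tsv tab, .csv
comma) and overridable; missing values are "NA" or empty on read, empty on
write; numeric columns are written with 17 significant digits so write →
read round-trips are exact. Prediction tables sort by ascending q, then p,
then identifier columns, making outputs deterministic. Gene identifiers
are symbols and are never remapped — harmonization across platforms is the
caller's responsibility. The CLI writes a resolved `config.yaml` and a
`run.log` with md5 checksums of all file inputs next to every output, and
uses exit codes 0/2/3 (success / usage error / data error). Screens are
invariant to the ordering of query and partner lists, and a
tissue-restricted run equals a pan-cancer run on the pre-filtered cohort —
both properties are asserted in the test suite.

# Known limitations

Rank-sum enumeration above `exactLimit` falls back to a normal
approximation whose error (empirically < 0.02 for groups of 5–10) is
acceptable for screening but not for reporting extreme tail probabilities
from tiny cohorts; raise `exactLimit` where exactness matters. The
inactivation rule treats thresholds as hard cutoffs; samples at the
boundary move between groups under small data perturbations. One-to-many
orthology expansion deliberately over-generates CGI candidates, and no
conservation-confidence score is attached. The package predicts candidate
pairs; it does not rank drug targets or model clinical context.
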