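---
title: "Joint inclusive composite interval mapping for NAM populations: models and methods"
author: "jicim package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{JICIM models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jicim)
```

# The design and the problem

A nested association mapping (NAM) population crosses F founder lines to a
single common parent and derives a recombinant inbred line (RIL) family from
each cross. All families are genotyped on one consensus genetic map and
phenotyped for the same trait, and the F families are analysed jointly. The
joint analysis gains power from the total population size N = sum n_f while
keeping the clean linkage structure of biparental crosses, but it must deal
with three complications that single-family interval mapping does not have:
marker effects are founder-specific (each marker has F + 1 alleles: the
common parent's and one per founder), the residual variance differs between
families, and recombination fractions in a given interval differ between
families even though all families share one consensus map.

`jicim` implements joint inclusive composite interval mapping (JICIM) for
this design: a two-step procedure in which a fixed-effects marker model
first absorbs the genetic background, and a one-dimensional EM interval
scan then tests each genome position on background-adjusted phenotypes.
Single-family ICIM is the exact F = 1 special case (`icimScan()`).

# Step 1: stepwise selection of family-nested marker cofactors

The background model is

Y_i = mu + u_f(i) + sum_j x_ijf beta_jf + e_i,

where u_f is the cross (family) effect and x_ijf is +1 if line i of family
f carries the founder allele at marker j, -1 for the common-parent allele,
and 0 outside family f; the common-parent level is the reference. A marker
enters or leaves the model as a whole group of its F family-nested columns,
judged by a partial F-test with (up to) F numerator degrees of freedom:
one decision per marker, preserving the marker-by-family interaction
semantics. Defaults follow the residual-permutation calibration described
below: entry probability `pIn = 1e-4`, removal probability `pOut = 2e-4`.
Coefficients of unselected markers are exactly zero. Because every column
of the model is supported on a single family, the fit decomposes into
per-family ordinary least squares, which is how `stepwiseSelect()` computes
it; ties in the entry test are broken by the smallest marker index, and a
`maxTerms` cap (default N/10 marker groups) guards the degenerate
`pIn = pOut = 1` configuration.

## Phenotype adjustment and the choice of baseline

For a scan interval (k, k+1), the adjusted phenotype is

dY_i = y_i - b_f(i) - sum over selected markers j not in {k, k+1} of
x_ijf beta_jf,

so that the influence of QTL elsewhere in the genome is removed while the
effect of the flanking markers, which carry the local QTL signal, is
retained (the inclusive-cofactor convention). The subtracted family term
b_f is the family's *all-common baseline* - the fitted value of a
hypothetical line carrying the common-parent allele at every selected
marker (intercept minus the sum of the family's selected-marker
coefficients) - and not the family mean. This choice is deliberate and
matters for rare QTL. The step-2 mixture assigns the common QTL homozygote
one mean mu0 *shared across families*, matching the genotypic-value
convention used in the variance decomposition (0 for the common homozygote,
2 a_f for the founder homozygote of family f). Centring each family on its
mean would place a segregating family's common class at -a_f while
non-segregating families sit at 0, which contradicts the shared mu0 and
attenuates the joint LOD of QTL that segregate in few families; centring on
the all-common baseline aligns the common classes of all families at 0.
For F = 1, or when no markers are selected, the two conventions differ
only by a constant and the LOD is unchanged; with no selected markers the
adjustment reduces to family centring.

# The genetic model behind the scan

## Recombination scales

Selfed RILs accumulate recombination over generations, so the observed
recombinant fraction between two fixed loci is the Haldane-Waddington
function R = 2r/(1 + 2r) of the meiotic fraction r. Crossover counts in
RIL families therefore estimate R, not r; all data-facing quantities in
the package are on the RIL scale, and conversion to the meiotic scale
(`meioticScale()`) happens only inside composition (r12 = r1 + r2 - 2 r1 r2
under no interference) and interval splitting. The Haldane map function is
used throughout for the cM-to-fraction conversion. Morgan or Kosambi
variants are not offered: interval fractions are re-estimated from each
family's observed crossovers, so the map function only enters the
within-interval interpolation, where the difference between map functions
is second order at the 1-5 cM interval lengths the method is designed for,
and Kosambi's implied interference would contradict the no-interference
three-locus probabilities below.

## Per-family recombination on a consensus map

Recombination frequency varies across families. `estimateFamilyRecomb()`
estimates each family's interval fraction as its observed recombinant line
proportion, clamped to [1e-6, 0.5 - 1e-6]; a family with no informative
pair in an interval falls back to the consensus-map expectation. To place
a QTL at position x inside interval (k, k+1), the family fraction is
converted to a family-specific meiotic length, split at the consensus-map
proportion lambda = (x - pos_k)/(pos_{k+1} - pos_k), and the two
flank-to-QTL fractions are returned on the RIL scale
(`positionToIntervalRecomb()`). Meiotic lengths are additive under
Haldane, so the composition identity compose(r_left, r_right) =
r_interval holds exactly (tested to 1e-10).

## QTL genotype probabilities given flanking markers

Lines of a family fall into four classes by their flanking-marker
genotypes. The scan needs P(QfQf | class), which requires the joint
three-locus (marker, QTL, marker) distribution of a selfed RIL at
fixation. The package computes it in closed form from an autonomy
argument: each two-locus margin of the three-locus fixation distribution
is itself a two-locus selfing process, hence Haldane-Waddington with the
corresponding composed meiotic fraction. Writing R1, R2 for the flank-QTL
RIL fractions and R13 for the RIL fraction of the composed flank-to-flank
distance, the four symmetric haplotype-class probabilities solve a linear
system:

* double recombinant (flanks agree, QTL differs): q_d = (R1 + R2 - R13)/4
* recombination right of the QTL only: q_r = (R2 + R13 - R1)/4
* recombination left of the QTL only: q_l = (R1 + R13 - R2)/4
* parental: q_p = 1/2 - q_d - q_r - q_l

and the conditionals follow, e.g. p1 = P(QfQf | +,+) = q_p/(q_p + q_d).
The test suite verifies this against exact absorption probabilities of the
36-state selfing Markov chain to 1e-12; at the limits, a QTL on a marker
cosegregates with it (p1 = p2 = 1) and the interval midpoint gives
p2 = p3 = 1/2.

# Step 2: the EM interval scan

At each grid position (1 cM steps by default, the conventional choice),
line i of family f contributes

p_i N(dY_i; mu_f, s2_f) + (1 - p_i) N(dY_i; mu0, s2_f)

to the likelihood, where p_i is its class probability. The F + 1 means and
F variances are estimated by EM:

* E-step: posterior probability w_i of QfQf per line;
* M-step: mu_f is the posterior-weighted family mean; mu0 is the pooled
  mean of the complementary posteriors across families, weighted by the
  current precisions 1/s2_f (the ML update under heteroscedastic
  families); s2_f is the posterior-weighted second moment about the two
  means with divisor n_f.

Responsibilities are initialised from the marker-class priors and
variances from the per-family null fit - a deterministic start that equals
the null configuration perturbed by the marker-class means. Iteration
stops when the relative log-likelihood change falls below 1e-8 or after
200 iterations (the fit is then flagged unconverged); the log-likelihood
is non-decreasing across iterations and is computed in the log domain so
extreme class probabilities cannot underflow. Under the null the adjusted
phenotypes of each family follow one normal, fitted by per-family ML
(divisor n_f). The LOD score is (logLA - logL0)/ln 10, clamped at zero.
Variances are floored at 1e-12 of the squared data scale with the
likelihood's quadratic term written out explicitly, so a constant
phenotype yields LOD 0 rather than a 0/0 artefact.

Per-family additive effects are read off the fitted means as
a_f = (mu_f - mu0)/2, i.e. half the difference between the two homozygote
genotypic values. The scan kernel is implemented in C++ (Rcpp); all
genotype-dependent quantities (family interval fractions, class
probabilities per position, class membership per line) are precomputed
once per dataset, so permutation replicates and power-simulation
replicates only redo the phenotype-dependent work.

## Declaring QTL and support intervals

A QTL is declared at a local maximum of the LOD profile that exceeds the
threshold and decays by at least one LOD on both sides; its one-LOD
support interval is the maximal contiguous region around the peak with
LOD >= peak - 1. Two maxima sharing one support region merge into the
higher peak, which implements the decay rule: a secondary peak separated
by a valley shallower than one LOD is absorbed. At chromosome ends the
decay requirement is one-sided (the profile simply ends). Ties in the
peak position are broken by the leftmost grid point. These boundary and
merge conventions are the package's own; they are exercised directly by
the test suite on synthetic profiles.

# Variance explained

In a biparental RIL population the genetic variance of a QTL with additive
effect a is a^2, so PVE = 100 a^2 / V_P. In the NAM design the F + 1
genotypic values are 0 (common homozygote, frequency 1/2) and 2 a_f
(founder homozygote of family f, frequency n_f/2N); the genetic variance
is the variance of that discrete distribution, and the denominator is the
family-size-weighted mean of the family variances, V_P bar =
sum n_f V_Pf / N. With the ML divisor (n_f, the package default) V_P bar
equals the variance of the family-mean-centred phenotypes exactly -
between-family mean differences reflect cross effects, not QTL
segregation, and are excluded on purpose. The sample-variance divisor
(n_f - 1) is available by argument, at the cost of that exact identity.
Summed per-QTL variances need not equal a joint genetic variance when QTL
are linked; the package makes no additivity claim.

# Thresholds

Two permutation procedures are provided. `stepwisePThreshold()` calibrates
the step-1 entry probability: overall and family means are fitted, the
residuals are permuted globally across all lines (exchangeable under the
no-QTL null once family means are removed - permuting within families
would only shrink the permutation space), the smallest marker-association
P-value over all markers is recorded per replicate, and the threshold is
the empirical alpha-quantile of those minima. On the scale of the original
maize analysis this calibration motivates the default pIn = 1e-4.

`gwerThreshold()` controls the genome-wide k-error rate of the scan: per
permuted phenotype the full pipeline (stepwise selection, then the scan)
is rerun, peaks are collected with the same declaration rule as `callQTL()`
applied at threshold zero, and the per-replicate statistic is the
(k + 1)-th largest peak LOD (zero when there are fewer peaks); the
threshold is the empirical (1 - alpha) quantile over replicates (defaults:
1000 replicates, alpha 0.05). GWER(0) is the classical genome-wide
maximum-LOD permutation threshold; thresholds are non-increasing in k, and
scoring null scans at the GWER(2) threshold keeps the fraction of scans
declaring more than two QTL at the nominal level (both properties are
tested).

# The simulator and what it emulates

`simulateNAMGenotypes()` draws each line's chromosome as a first-order
Markov chain on the RIL scale: the first marker is common-parent or
founder with probability 1/2 and successive markers switch with
probability R = rilScale(haldane(spacing)). This matches the
no-interference multipoint model used by the class probabilities at the
two-locus level (verified against the enumeration oracle) and emulates the
structure of the motivating datasets: the default experiment geometry is
25 families x 200 RILs on ten 140 cM chromosomes with markers every
1.3 cM, and the nine published family phenotypic variances (2.61, 2.08,
7.85, 8.26, 9.82, 5.41, 9.17, 2.62, 5.59 days squared) are used for the
rare-QTL experiments, with their mean assigned to the remaining families.

Phenotypes come in three recipes. With a real phenotype vector available,
`phenotypeRealBackground()` adds a_f x_i to it. Without one,
`phenotypeNoiseBackground()` draws independent family noise: in `"noise"`
mode the family variances are error variances and the QTL variance comes
on top (so the rare-QTL family's total variance is V_Pf + a^2 - the
published description does not say whether its runs preserved the total
variance, and this reading is the conservative one for power: more total
variance, not less); in `"linked_pair"` mode the error variance is
V_Pf - sum a^2, preserving the total, and must be positive or the recipe
errors. QTL are placed either exactly on markers (genotype copied from the
marker) or at interval midpoints with the genotype copied from the left or
right flank by a fair coin - the hardest detection scenario.

The simulator does *not* emulate: real polygenic backgrounds and family
mean differences, segregation distortion, genotyping error, missing-data
patterns of real assays, heterozygosity residual in real RILs, or map
errors. Power estimated on the clean-noise background therefore shows the
method's behaviour under its own model assumptions; the published
real-background power numbers serve as qualitative anchors (power bounded
below by the clean-noise analogue) rather than as values reproduced
exactly.

# Missing genotypes

Before analysis, heterozygous calls become missing and markers that are
non-polymorphic within a family have that family's entries set to missing
(`preprocessGenotypes()`). `imputeMissing()` then assigns every missing
call to the homozygote with the higher posterior given the nearest
non-missing flanking markers of the same line, using the same
no-interference two-locus RIL probabilities on the family-estimated
recombination scale, with fractions composed across intervening intervals
on the meiotic scale. Exact ties (equidistant discordant flanks) are
broken by a seeded fair coin so the operation is deterministic given its
seed; a line missing an entire chromosome is assigned by seeded fair coins
with a warning. Observed calls are never altered and a second application
changes nothing. Single maximum-posterior imputation (rather than multiple
imputation or posterior-weighted scanning) keeps downstream estimators
deterministic; phenotypes are never imputed - lines without a phenotype
are dropped with a message.

# Power evaluation

`runPowerExperiment()` follows the placement-sweep convention: one
replicate is one QTL placement (at each marker, or at each interval
midpoint), and detection means a *declared* QTL - threshold plus decay
rule, not merely a high LOD - whose peak lies within a window of fixed
length (the support interval, SI) centred at the true position. When fewer
replicates than positions are requested the placements are a seeded random
subset without replacement - the desk-scale deviation from the full sweep.
Genotypes are simulated once per experiment and the phenotype is redrawn
per placement, mirroring the fixed-genotype design of the original
experiments and letting the scan reuse its genotype-dependent
precomputation. Detection windows are nested, so power is non-decreasing
in SI length by construction; monotonicity in effect size and the
on-marker >= mid-interval ordering are statistical properties and are
tested at matched seeds with a two-standard-error tolerance.
`runLinkedQTLExperiment()` and `linkedQTLSummary()` cover the linked-QTL
dissection setting: two QTL on one chromosome under the
variance-preserving recipe, summarised as position histograms and the
fraction of replicates that separate the pair properly (two declared
peaks, one within a stated window of each truth).

# Problem sizes and runtime choices

The bundled experiments use the full study geometry (25 x 200 lines, 1080
markers, 1 cM scan grid) with 100 seeded placements per power estimate,
1000 permutations for the single-family threshold, and 200 permutations /
200 null scans for the GWER calibration check; the unit suite runs on
smaller geometries (2-5 chromosomes, 40-60 cM, 60-300 lines) chosen so
each statistical check retains its discriminating power. These sizes are
package choices balancing Monte-Carlo error against desk-scale runs.

# Known limitations

* Additive effects in selfed-RIL (two-homozygote) families only: no
  dominance, no epistasis, no other mating designs.
* Effects at declared peaks are mildly overestimated by selection (the
  winner's curse), and closely linked QTL in repulsion or coupling can
  merge into a single call at an intermediate position with an effect
  near the sum - behaviour the linked-QTL experiment quantifies rather
  than corrects.
* The shared-mu0 mixture is the model's strength for rare QTL but assumes
  the step-1 adjustment has removed family-specific background at the
  common-genotype baseline; unselected small-effect background QTL leave
  a family-mean residue that slightly attenuates local signal.
* PVE denominators for rare QTL depend on whether the family or the whole
  population is the reference; the package reports both per-family PVE
  (100 a_f^2 / V_Pf) and NAM-level PVE and leaves the choice to the user.
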