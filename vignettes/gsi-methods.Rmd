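---
title: "Models and design choices in gsikit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in gsikit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gsikit)
```

`gsikit` turns a hierarchically sampled SNP baseline — individuals in
sites, sites in rivers, rivers in regions — into (i) a ranked locus
panel, (ii) a set of assignment units to which individual fish can be
assigned with at least 80% precision, and (iii) calibrated mixed-stock
estimates. This vignette explains the models behind each stage, the
parameters that matter, and the choices made where the design was
genuinely open.

## The assignment likelihood

Individual assignment uses the compound-Dirichlet (Rannala–Mountain)
predictive likelihood. For a biallelic locus with reference allele
counts $(x_A, x_B)$, $n = x_A + x_B$, and a per-allele prior of
$\lambda = 1/2$:

$$P(AA) = \frac{(x_A+\tfrac12)(x_A+\tfrac32)}{(n+1)(n+2)},\quad
P(AB) = \frac{2(x_A+\tfrac12)(x_B+\tfrac12)}{(n+1)(n+2)},$$

with $P(BB)$ symmetric. The three probabilities sum to one for any
counts, and an empty reference gives the prior predictive
$(3/8, 1/4, 3/8)$ — so unobserved alleles never produce zero
likelihoods and no ad-hoc constant is needed. Log-likelihoods are
summed over the individual's non-missing loci.

A fish is scored against **every baseline site**: per-site likelihoods
are normalized (in log space, with max-subtraction, so underflow cannot
occur) to scores summing to 100, and site scores are then summed within
each river or unit. Summation happens after normalization over sites,
not within rivers — a deliberate choice, exposed as the only
normalization offered, because site-level references keep within-river
heterogeneity while unit scores remain directly comparable to a cut-off
on a 0–100 scale. The default cut-off of 80 is illustrative, not
optimal; it trades the proportion of fish assigned against precision
and is configurable everywhere it appears.

Evaluation is leave-individual-out by construction: hold-out fish are
removed before training counts are formed, and each cross-validation
half is scored only against the other half's counts. The Monte-Carlo
exclusion test (simulate genotypes from a unit's posterior-mean
frequencies, compare likelihoods) is diagnostic output only and never
gates an assignment.

## Locus ranking

Per-locus Weir–Cockerham $\hat\theta = a/(a+b+c)$ is computed from the
1984 variance components over **rivers, pooling sites** — the samples
are collected by site, but ranking discriminatory power at the river
level matches the assignment target. The hierarchy is retained in the
data structures, so a three-level (site-within-river) estimator could
be added without changing any interface. Multi-locus summaries use the
ratio of sums $\sum a / \sum(a+b+c)$, the standard combination.
Negative single-locus estimates are kept as-is (they rank last);
monomorphic loci have undefined $\theta$ and are excluded from ranking.
Ties are broken by locus id, so rankings are bit-reproducible. Panels
are nested by construction; the default sizes (12, 24, 96, 192, 288,
384, 480) are subsets or multiples of 96-well genotyping platforms.

The F_ST-outlier screen is intentionally simple: $\theta_l (r-1) /
\bar F_{ST}$ is referred to a $\chi^2_{r-1}$ distribution, with
$\bar F_{ST}$ a 5%-trimmed mean, and Benjamini–Hochberg q-values
flagged at 0.05. It is a screen for the neutral-only pipeline variant,
not a replacement for full Bayesian outlier machinery; its false
positives are bounded in tests at twice the nominal FDR on null data.

## Quality control

Hardy–Weinberg conformity is tested exactly: conditional on observed
allele counts, the probability of $h$ heterozygotes is enumerated and
the two-sided p-value sums all outcomes no more probable than the
observed one (the standard exact-HWE convention; the enumeration is
checked to sum to one). Per site, per-locus p-values are combined with
Fisher's method; monomorphic site-loci contribute $p = 1$ rather than
being dropped, keeping degrees of freedom comparable across sites, and
are counted in the output. Sequential Bonferroni is implemented as Holm
applied across the per-site combined p-values.

## Distance geometry and clustering

Nei's $D_A$ is computed between sites from observed allele frequencies
(maximum likelihood, no prior). $D_A$ is symmetric but not a metric; it
is used only for ordination (classical Torgerson scaling via
`cmdscale`, negative eigenvalues reported but excluded from
coordinates). Outlier sites — which would distort locus ranking — are
flagged when their distance from the coordinate-wise median on axes 1–2
exceeds the median distance plus 3 MADs. The rule mechanizes what is
usually a visual judgement; borderline sites may differ from a human
call, which is why flags are reported, a manual list overrides them,
and flagged sites are returned to the data after ranking.

Regional structure comes from k-means on the leading principal
components of the mean-imputed dosage matrix (imputation is used for
PCA only, never in likelihoods), with
$BIC(k) = n\ln(WSS_k/n) + k\ln n$ and 20 seeded restarts per $k$. The
chosen $k$ is the smallest whose improvement to $k+1$ falls below 5% of
the scan's BIC range — a deterministic elbow; the full curve is always
reported and the choice can be overridden. On the default scenario the
scan recovers the 6 simulated regions.

## Assignment units

The unit-definition loop starts from one unit per river and applies
three ordered rules per iteration, using precision ("of fish assigned
to the unit, the fraction truly from it") from both evaluation methods:
both $\ge$ 0.80 keeps the river; both below merges it with the
admissible neighbour (same regional cluster, preferring geographic
adjacency) carrying the heaviest reciprocal-misassignment edge,
$w(u,v) = \overline{[m_{u\to v} + m_{v\to u}] / [n_u + n_v]}$ averaged
over the two methods on cut-off-filtered tables; a one-sided failure is
"case by case" — kept when the failing estimate is within 0.05 of the
threshold, merged otherwise, and always written to a decision ledger
that supports manual overrides and exact replay. The 0.05 margin
mechanizes judgement calls that, on real baselines, also weigh
geography; the override hook exists precisely because geography can
justify keeping a unit the margin rule would merge. Undefined precision
(no fish assigned to a unit) counts as failing. After any merge, loci
are re-ranked on the new units and the evaluation repeats; unit count is
non-increasing, so the loop terminates in at most one iteration per
river.

## Mixed-stock analysis

Mixture proportions are estimated by EM with baseline frequencies held
fixed (conditional maximum likelihood): genotype likelihoods per unit
from HWE at posterior-mean frequencies $(x_A+\tfrac12)/(n+1)$ —
consistent with the assignment prior — uniform start, proportions
updated as mean responsibilities, stopping at
$\max|\Delta\pi| < 10^{-8}$. The log-likelihood is non-decreasing by
construction and asserted in tests. Fish with zero likelihood in every
unit are excluded with a warning.

Baseline sampling uncertainty is propagated by parametric resampling:
each replicate draws unit frequencies from the Beta posterior
$\mathrm{Beta}(x_A+\tfrac12, x_B+\tfrac12)$, regenerates a baseline
sample of the same gene counts as the real data, and draws mixture
genotypes from an independent second posterior draw, so mixtures are
never estimated against frequencies fitted to their own realized
genotypes. Published resampling schemes for this step differ in detail
(with-replacement draws versus posterior draws); the Dirichlet-posterior
variant is this package's definition, chosen because it composes cleanly
with the Dirichlet machinery used everywhere else and shares the goal of
removing same-sample bias. Confidence intervals are 2.5/97.5 percentiles
over replicates; the SE of the mean is reported alongside. Default
designs are 1000 replicates of 200 fish (100% simulations) and 1000
fish (fishery simulations).

## The simulator

The generator is a nested Balding–Nichols model: each level draws a
daughter frequency from $\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$ around
its parent, so $F = 0$ copies the parent exactly and the hierarchy is
exactly nested. Ancestral frequencies are uniform on (0.1, 0.9) —
array-SNP panels are ascertained towards common variants, and the range
keeps Beta parameters well-conditioned at small $F$. The default
scenario ("demo18") is 6 regions × 3 rivers × 2 sites × 24 fish at 300
loci with $F_{region} = F_{river} = 0.03$, $F_{site} = 0.005$, 2%
missing calls and 16% MSV-3 loci — desk-scale numbers chosen to mirror
a national salmonid baseline qualitatively: tens of fish per site,
weak site-level and moderate river/region-level structure, a realized
multi-locus $\theta$ across rivers around 0.06. Simulator fidelity is
itself tested: at nominal $F_{river} = 0.10$ the realized multi-locus
$\theta$ lands within ±20%.

What the simulator does **not** emulate: linkage between loci,
selection, migration, family structure within sites (full-sib removal
is assumed done upstream), genotyping batch effects, and the
asymmetric, geographically continuous differentiation of real river
systems. Passing tests therefore demonstrate the correctness and
internal calibration of the machinery under the stated F-model, not
field performance on any real baseline — on real data, precision at a
given panel size will generally be lower and unit definitions coarser.

## Numerical and degenerate-input conventions

All likelihood aggregation is in log space with max-subtraction; scores
and simplex vectors are renormalized sums, asserted to 100 ± 1e−6 and
1 ± 1e−9 respectively. Exact-HWE tie comparison uses a relative
1e−10 tolerance. Genotype probabilities of exactly 0 (fixed frequencies
in toy problems) enter EM as a −10¹⁰ log-penalty rather than −∞ to keep
matrix products NaN-free; fish impossible everywhere are detected and
excluded. Empty groups yield zero counts, not errors; monomorphic loci
are excluded from ranking and uninformative in HWE ($p = 1$, flagged).
Ties anywhere (ranking, best unit, merge partners) break by id
ascending, and every stochastic operation takes an explicit seed.

## Problem sizes used in validation

The shipped tests and the acceptance script run on the default
scenario and scaled-down simulation designs (e.g. 50–200 mixture
replicates instead of 1000, 500-replicate calibration checks). These
sizes are the package's validation choices: large enough for the
Monte-Carlo tolerances asserted, small enough to run routinely on one
core. The full-size designs remain the function defaults.
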