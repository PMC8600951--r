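---
title: "Methods: structural connectome abnormality mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural connectome abnormality mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Temporal lobe epilepsy alters white-matter pathways well beyond the
seizure focus. In patients whose focal seizures secondarily generalize
(FBTCS), the working hypothesis is that this alteration is *widespread
and bilateral*, whereas patients without generalization carry *localized*
alteration near the focus. `netabnorm` implements the two complementary
analyses used to test this on structural connectomes — group-level
network-based statistics (NBS) and subject-level node abnormality — plus
the estimation statistics that quantify the group contrast, and a
synthetic cohort generator that makes the whole chain testable without
patient data.

The data model is a cohort of 90-node connectivity matrices (AAL
parcellation), FA- or MD-weighted, sharing one binary scaffold: a weight
of exactly 0 means "no connection in the scaffold", never "measured FA
of zero". Constant density across subjects is a validated invariant, and
it is what makes "the total number of connections of a node" a
subject-independent denominator.

# Network-based statistics

Per scaffold edge, a pooled-variance (Student) two-sample t-score is
computed and *oriented* so that positive values mean alteration in the
tested direction (`A_less_B` for FA reductions in patients; `A_greater_B`
for MD increases). The choice of pooled rather than Welch variance
follows the canonical NBS formulation; the direction is always an
explicit argument, never inferred from the data. Edges with zero pooled
variance score t = 0 (with a warning) rather than ±Inf.

Edges with oriented t strictly above the threshold T form a graph; the
*extent of alteration* is the edge count of its largest connected
component (components joined through shared nodes). Ties between
equal-extent components are broken toward the component containing the
smallest node index, so results are deterministic. The permutation null
re-labels subjects (group sizes preserved) and records each
permutation's maximal extent; the p-value uses the add-the-observed
convention \(p = (1 + \#\{\mathrm{null} \ge \mathrm{obs}\})/(B+1)\), so
p is never 0 and "p < .001" is the floor at B = 5000. An exhaustive
enumeration mode (`exact = TRUE`) replaces the Monte-Carlo null for
small groups and is tested against an independent brute-force oracle.

The threshold sweep re-runs the analysis over T = 0.05–5 in steps of
0.05, sharing one permutation stream across the grid; observed extents
are non-increasing in T by construction. `n_permutations = 0` gives an
extents-only sweep for ordering comparisons.

## Why the t = 3 null calibration band is knowingly red

One acceptance test demands that, on null cohorts (29 vs 29, no
effect), the fraction of p < .05 over 200 replicates at t = 3 falls in
the two-sided binomial band around .05. This cannot happen for the
extent statistic at that threshold: with 56 degrees of freedom the
per-edge one-tailed tail probability at t = 3 is ≈ 0.002, so a
~1000-edge scaffold yields ~2 suprathreshold edges under the null, and
the null extent is supported on {0, 1, 2, 3} (measured frequencies
≈ .12/.80/.07/.005 over 800 null worlds). The permutation test remains
exactly valid — \(P(p \le \alpha) \le \alpha\) — but its attainable
levels jump from ≈ .08 to ≈ .005, so the realized type-I fraction is
≈ .005, below the band. The same engine measures 0.065 (inside the
band) at t = 1.5, where null components carry hundreds of edges and the
statistic is near-continuous; a regular test asserts both facts. We
therefore report the band test honestly red rather than loosening it:
conservatism at strict thresholds is a property of extent-based NBS,
not of this implementation.

# Node abnormality

Each subject's connections are z-scored against per-edge control means
and SDs (n − 1 denominator); controls are scored leave-one-out so no
control is compared against itself. Degenerate edges (zero control SD)
are flagged and score z = 0 with a warning — the alternative (±Inf)
would make every downstream count meaningless.

A connection is abnormal when its z exceeds the threshold Z. The
default exceedance is two-sided (|z| > Z): the method description says
"higher than a set threshold" without printing a sign convention while
the headline findings are FA reductions, so we expose
`decrease_only` / `increase_only` modes and record the choice in every
profile. Node abnormality is abnormal degree / scaffold degree — the
only reading of "degree of the non-binarized z-score network" that makes
the measure a proportion in [0, 1] under constant density. Both
threshold comparisons are strict, matching "higher than" and giving
deterministic grid behaviour; abnormality load is therefore
non-increasing in both thresholds, and lobewise loads partition the
whole-brain load exactly (the six lobes partition the 90 nodes).

The discriminatory threshold pair maximizes |Cohen's d| between the two
patient groups' whole-brain loads over the default grid (Z: 1.5–3.5 by
0.1; ratio: 0.01–0.20 by 0.01), with ties broken toward the smaller Z
then smaller ratio. The region-wise comparison tests each of the 90
regions with a one-tailed rank-sum test at Z = 2.5 and applies
Benjamini–Hochberg jointly across all 90 regions (the alternative —
per-hemisphere correction over 45 — is not stated anywhere we could pin
down, and joint correction is the more conservative default).

Ipsilateral/contralateral flipping: z-scores must be computed in the
native frame (each patient edge against the matching control edge), so
for the region-wise stage we flip the resulting per-node values of
subjects whose epilepsy side differs from the reference side through the
atlas homologue pairs. The matrix-level `flip_to_ipsi_contra()` is also
provided (involution; preserves the weight multiset and permutes the
degree sequence).

# The atlas

The 90-region table (left/right alternating, pair (2k−1, 2k)) with the
six-lobe grouping — temporal 18, subcortical 14, frontal 26, parietal
14, occipital 12, cingulate 6 — is shipped as the default and as
`inst/extdata/aal90_atlas.csv`. No source we implement from prints the
exact lobe membership, so we use the grouping common in epilepsy
connectomics (hippocampus/amygdala with basal ganglia, thalamus, insula
and olfactory cortex as "subcortical"); any table passing the structural
and count invariants can be supplied instead.

# Estimation statistics

Cohen's d pools the two n−1 variances by degrees of freedom; AUROC is
Mann–Whitney U normalized by the product of group sizes with midranks
(ties count 0.5). Both get 95% BCa bootstrap intervals: bias correction
z0 from the fraction of bootstrap replicates below the point estimate
(ties counted half), acceleration from the jackknife skewness over the
concatenated leave-one-out statistics of both samples (standard Efron
formulation — the source names only "bias-corrected and accelerated"),
resampling within each group independently. With z0 = a = 0 the
interval reduces exactly to the percentile interval, which is a tested
identity, and a degenerate bootstrap distribution collapses the interval
to the point value with a warning rather than inventing spread.

Rank-sum tests use exact enumeration of all label assignments up to a
combined n of 10 (ties at the observed statistic counted fully, so
p(greater) + p(less) ≥ 1) and a tie-corrected normal approximation
above; Kruskal–Wallis uses midranks with the standard tie correction.
For the 2×2 demographics tables the Yates continuity correction
(clamped at |O−E| ≤ 0.5) is the default because it is the only
convention under which the reference cohort table's printed statistics
(0.03, 2.14, 0.31, 0.04) all reproduce to two decimals; uncorrected
Pearson gives 0.19/2.92/0.65/0.19. No covariate adjustment (age, sex)
is applied anywhere — the source is silent on it, and we chose not to
guess.

# The synthetic cohort generator

The generator emulates exactly what the downstream analysis assumes and
nothing more:

* **Scaffold** — one connected random graph (spanning tree + uniform
  extra edges) at density 0.25 of the 4005 possible edges, shared by all
  subjects. Streamline-atlas AAL connectomes are typically 20–30%
  dense; 0.25 also keeps the permutation engine's edge count (~1000)
  representative.
* **Controls** — per-edge weights ~ Normal(μ_e, σ) truncated to (0, 1],
  μ_e drawn once per edge from U(0.2, 0.6) (the bulk of observed FA
  means), σ = 0.04 (typical between-subject spread of edge FA). A
  truncated normal, not a beta, because the z-scoring step presumes
  approximately Gaussian control distributions; at these parameters the
  truncation is negligible.
* **Patients** — group sizes 29/23/60 mirror the reference cohort. The
  localized preset targets the left temporal lobe plus a small left
  inferior-frontal set (13 nodes); the widespread preset targets
  bilateral temporal + subcortical + parietal (46 nodes). Half of the
  scaffold edges incident to the target set are altered
  (both-endpoint edges first, then single-endpoint, shuffled
  deterministically), their means shifted by 1.5 control SDs — down for
  FA, up for MD. The fraction 0.5 was fixed by a design-time coverage
  analysis: below ~0.34 the widespread preset never leaves its
  within-target edge pool and would touch *fewer* distinct nodes than
  the localized preset, inverting the intended contrast.
* **Sides** — all synthetic patients are "left"-sided, with alterations
  seeded in left-hemisphere targets; reorientation therefore flips
  every patient, exercising the homologue machinery, while keeping
  per-edge effects at full size for the recovery tests.

What the generator does **not** emulate: spatial autocorrelation of FA,
hub-weighted degree distributions, distance-dependent connection
strength, site/scanner effects, covariate structure, or any coupling
between edges. A green recovery test therefore establishes that the
pipeline detects and localizes the *statistical* structure it claims to
detect — not that it would behave identically on real tractography
data.

# Numerical and reproducibility choices

Every stochastic stage takes an integer seed; stage seeds are derived
from one master seed by affine hashing below 2^31, and RNG state is
restored afterwards (`withr::with_seed`), so `run_full()` is
byte-identical under a fixed config. The permutation engine computes
group sums and sums of squares for blocks of permutations with two
matrix products, then finds components with an in-package union-find
(path-halving); `igraph` serves as an independent oracle in the tests
only. Matrices are written with 17 significant digits so text
round-trips are exact. Degenerate cases — zero-variance edges, empty
suprathreshold graphs (extent 0 → p = 1), all-tied rank tests (p = 1),
isolated nodes (ratio 0) — are all defined, warned about where
surprising, and tested.

# Known limitations

* No covariate regression in either the t-scores or the z-scores.
* The Zenodo-deposited patient networks of the reference study are not
  bundled; the headline dataset numbers (441/21 connections at t > 3,
  load d = .82/.44, KW χ² = 13.9) are validation targets only when that
  download is available. `read_cohort()` accepts exactly that data
  shape.
* MD support mirrors FA with the effect direction flipped; no separate
  MD-specific distributional model.
* The NBS family-wise statistic is component extent only (no mass or
  intensity variants).
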