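---
title: "Parentage, pollen dispersal and mating systems in a spaced-plant nursery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parentage, pollen dispersal and mating systems in a spaced-plant nursery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pollenkin)
```

## The analysis and its setting

pollenkin analyses progeny arrays collected from known mother plants in a
wind-pollinated, spaced-plant breeding nursery — the design used for
perennial outcrossing grasses such as intermediate wheatgrass, where
individually spaced genets (here on a 0.91 m grid, half-sib families of nine
planted adjacently) are genotyped with a few thousand biallelic SNPs. From
the genotypes of the candidate parents, the known mothers and their sampled
progeny, the package infers:

* **paternity** for each progeny, by categorical likelihood (LOD) assignment
  with simulation-calibrated confidence thresholds;
* **mating-system parameters**: the multilocus and single-locus outcrossing
  rates `t_m` and `t_s`, their difference (biparental inbreeding) and the
  correlated paternity `r_p`;
* **pollen dispersal**: realized mother–father distances, the axial
  dispersal standard deviation, direction sectors, and the dependence of
  pollination success on distance;
* **consequences of dispersal**: genetic diversity and genome-predicted
  trait values of progeny in 3 m pollination-distance bins.

Everything can be exercised against a forward simulator of the same nursery
design that records ground truth, so each stage is verifiable by parameter
recovery rather than by fiat.

## Genotype model

All genotypes are diploid biallelic dosages (0/1/2, `NA` missing). The crop
itself is hexaploid, but GBS genotype calls and all downstream parentage and
mating-system machinery treat loci as diploid SNPs, so the package models
exactly the data the analysis actually consumes. Missing calls are never
imputed: every likelihood simply skips loci with missing members
(conservative, and visible in the per-assignment `n_loci_compared`). Loci
are filtered at minor-allele frequency ≥ 3% (kept at the boundary) and
missingness ≤ 10% (discarded strictly above), with MAF computed on parents
and progeny pooled; a random subsample (default 2,500 loci) keeps the LOD
machinery well-conditioned.

Genotyping error is a symmetric dosage flip: a call is the true genotype
with probability `1 − ε` and each wrong dosage with probability `ε/2`. This
is the simplest model consistent with a stated overall mistyping proportion.
The paternity module defaults to `ε = 0.10`, mirroring the analysis
convention of setting the mistyping rate to the maximum tolerated missing
fraction — a deliberate conflation of mistyping and missingness that we
document rather than hide; the mating-system module has its own,
independent `ε` (default 0.01).

## Paternity by LOD

For progeny `o`, known mother `m` and candidate father `d`, each locus
contributes `ln P(o | m, d) − ln P(o | m, pollen pool)` where the pool
father contributes an allele drawn at the candidate-population frequency.
The error mixture is applied to offspring, mother and candidate calls. The
LOD of a candidate is the sum over loci at which all three are typed, and
assignments additionally require at least `min_loci` (default 300) compared
loci. The Δ statistic (the LOD gap between the two best candidates) is
deliberately not used for assignment: with nine half-sibs of each family
planted adjacently, near-ties between relatives are expected and Δ would
reject correct assignments.

Confidence thresholds are calibrated by simulation, in the spirit of the
classical parentage programs: 10,000 offspring are generated from random
parent pairs in the candidate pool, the true father is present in the
evaluated set with probability `prop_candidates_sampled` (default 749/771,
the genotyped fraction of planted genets), and the strict (95%) and relaxed
(80%) thresholds are the lowest LODs at which assignments above the
threshold are correct at the target rate. The mother herself is always a
candidate during assignment, so selfed progeny are detectable.

Numerical note: inside the dense matrix engine, `log(0)` terms (possible
only at `ε = 0`) are clamped at `log(1e-300)` so BLAS products stay finite;
the scalar `lod_score()` reports a true `−∞` for an opposing-homozygote
exclusion at zero error.

## Mixed-mating model

A progeny is selfed with probability `s`, otherwise outcrossed to a father
drawn from the pollen pool at the plug-in candidate allele frequencies:

```
P(progeny) = s · ∏_l T_self(g_l | mom_l)  +  (1 − s) · ∏_l T_out(g_l | mom_l, p_l)
```

The selfing indicator is shared across loci, which is what makes the
multilocus rate `t_m = 1 − ŝ` robust. The 1-D log-likelihood is concave in
`s`; it is maximized by Newton–Raphson safeguarded with bisection. The
single-locus rate `t_s` is one minus the mean of per-locus maximum-
likelihood selfing rates, solved by a vectorised Newton iteration across
loci. Spread comes from resampling maternal families with replacement
(default 1,000 bootstrap replicates, the convention for progeny-array
studies).

Two design choices deserve explanation:

* **Constraint.** With plug-in pollen frequencies the multilocus likelihood
  is *monotone* at the boundary whenever no progeny supports selfing, so an
  unconstrained maximizer runs to whatever lower bound is imposed on `s`.
  The default therefore constrains the multilocus `s` to [0, 1]
  (`constrain = FALSE` exposes the positivity-bounded unconstrained mode).
  Estimates of `t_m` slightly above 1, familiar from joint multi-parameter
  implementations, do not arise in this plug-in formulation. The *per-locus*
  estimates remain unconstrained within the positivity region of their
  likelihoods (capped at s ∈ [−0.5, 1.5]) so that their noise averages out
  and `t_s` — like published single-locus estimates — may exceed 1.
* **Known mothers.** Mothers are marked as known, and their genotypes are
  taken at face value in the mating model (`known_mother = TRUE`). Applying
  the error mixture to clean maternal genotypes measurably inflates the
  apparent selfing rate (we observe `t_s ≈ 0.98` instead of `1.00` on
  error-free-mother simulations); the full trio mixture remains available
  as a flag and is always used in the paternity LOD, where it matches the
  classical configuration.

Correlated paternity `r_p` — the probability that two outcrossed maternal
sibs share a father — is estimated by maximum likelihood on sib pairs under
the mixture `r_p · P(full sibs) + (1 − r_p) · P(half sibs)`. Treating pairs
as independent makes this a composite likelihood; its point estimate is
cross-validated against the direct identity-probability estimate
`Σ x_i(x_i − 1) / (n(n − 1))` over assigned fathers, and the reported
p-value for `r_p > 0` is a family-bootstrap percentile test, labelled as
such. Under spatially correlated paternity the independence model
slightly understates the outcross likelihood, giving `t_m` a small downward
bias (≈ 0.01–0.03 at 30% selfing in our recovery runs); this is inherent to
plug-in mixed-mating estimators and is stated here rather than corrected.

## Dispersal statistics

Realized dispersal is the Euclidean distance between a mother and the
assigned (strict-confidence) father. Selfing assignments are excluded from
distance summaries — a zero distance is a mating-system event, not a pollen
flight — and counted separately. The axial dispersal standard deviation is
`σ_pollen = sqrt(M/2)` with `M` the mean squared mother–father distance.
Bearings are measured clockwise from North and binned into sixteen
22.5° compass sectors; distance bins are left-closed, right-open
(`[0,3), [3,6), …`), a convention we fix because "0–3, 3–6" labels are
ambiguous at the boundaries, and we test it explicitly. A two-sample
Kolmogorov–Smirnov test compares realized distances against the distances
of all available donors, pooled across mothers (a per-mother option exists).

Per-bin diversity uses: mean pairwise identity-by-state dissimilarity
("genetic distance" is not a uniquely defined term, so we fix this
reading and expose an alternative), mean pairwise Nei distance among
progeny (individuals treated as populations of size one), and Shannon and
rarefaction indices computed on the per-assigned-father progeny counts
within the bin — the fathers-as-species reading under which a degenerate
far-distance bin with two fathers yields a rarefaction value of 2. The
rarefaction reference depth defaults to the smallest bin's progeny count.

**LSD tests.** Bin means are compared with Fisher's *protected* least
significant difference: pairwise LSD comparisons at `α = 0.05` are declared
only when the one-way ANOVA F test is itself significant. The protection
matters: with nine bins there are 36 pairwise comparisons, and an
unprotected LSD rejects somewhere far more often than `α` under a complete
null, which would make "no significant difference" unattainable even for
dispersal-independent traits. The unprotected variant remains available
(`protected = FALSE`). Letters are a standard compact letter display.

## Genomic prediction

Progeny trait values are predicted with single-environment GBLUP: ridge
regression on dosages centered at twice the training allele frequencies,
with the shrinkage level set by restricted maximum likelihood on the
spectral decomposition of the marker covariance. This is deliberately
simpler than the genotype-by-environment genomic-selection model used in
breeding practice: the module's role here is to supply progeny trait values
for the distance-bin comparison, not to reproduce a breeding program's
model. The marker-effect and relationship-matrix forms are algebraically
identical, and a test asserts their numerical agreement.

## The simulator: what it emulates, and what it does not

`simulate_nursery()` generates founder candidates (73 half-sib families of
9 sharing a simulated dam with independent sires — the adjacent-relative
structure of the real nursery without modelling the previous breeding cycle
— plus bi-parental F1 genets filling to 749), plants them row-major on a
0.91 m grid with family members adjacent, samples 15 mothers away from the
borders, and draws each progeny's father either as a selfing event (rate
`s`) or proportionally to a distance kernel (exponential with 3.5 m scale
by default — chosen once so that the simulated nursery reproduces the
"most pollination within 10 m" regime; exponential-power and uniform
kernels are available because the true kernel family of a real nursery is
unknown). Founder allele frequencies are uniform on [0.04, 0.25], the
a realistic post-filter MAF range for a GBS marker panel in this crop. Progeny calls receive the
symmetric error flips (default ε = 0.01) and missingness (default 5%,
comfortably under the 10% locus filter); founder genotypes are simulated
clean, which is a simplification relative to real GBS parents. Traits are
additive with i.i.d. normal marker effects and noise scaled to the target
heritability (`h² = 1` returns the genetic value exactly; `h² = 0` returns
pure unit-variance noise).

The simulator does **not** model pollen-cloud physics, wind direction,
flowering-phenology overlap, self-incompatibility loci, or the GBS read
level. Passing recovery tests therefore demonstrates that the estimators
recover the parameters of this generative model at the nursery design and
scale — not that real nurseries obey an exponential kernel or error-free
parents.

A single master seed drives every run; sub-stage seeds are derived
deterministically from it, so identical configurations are byte-identical.

## Problem sizes used in the shipped checks

The recovery tests and the acceptance script run the full study design —
749 candidates, 2,500 loci, 15 mothers × 56 progeny, 10,000 calibration
offspring — once, plus a second nursery at 30% selfing. Bootstrap spread in
the acceptance script uses 100 family resamples (the function default
remains 1,000); kernel-scale monotonicity uses 5 scales × 10 replicates of
a 144-candidate nursery; null calibrations use 400 LSD replicates, 2,500
HWE loci and 200 Nielsen replicates. These sizes are the package's chosen
desk scale: large enough that the binomial tolerances in the tests are
meaningful, small enough to run interactively.

## Known limitations

* The mixed-mating estimator assumes the pollen pool is the genotyped
  candidate set with plug-in frequencies; joint estimation of pool
  frequencies is noted as an extension.
* `t_s` estimates carry the finite-sample noise of per-locus likelihoods;
  with few loci (≲ 100) the multilocus rate is clearly superior, with
  thousands of loci the two are comparable on inbreeding-free data.
* The Nielsen effective-father number `1/Q̂` is unstable when most progeny
  have distinct fathers (Q̂ near or at zero is reported as unbounded with a
  flag).
* The per-bin Nei distance treats individuals as populations; other
  readings of per-bin diversity are possible and the choice is exposed as
  an option.
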