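---
title: "Crosslink-guided modeling of protein complexes: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crosslink-guided modeling of protein complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xltrap)
```

## The problem

Genetically encoded crosslinking amino acids let one map a protein-protein
interface in living cells: an electrophilic side chain such as
O-(2-bromoethyl)-tyrosine (BrEtY) placed in one partner reacts with a
cysteine thiol in the other only when the two come within the reach of the
resulting thioether adduct. Each reacting position pair is therefore a
distance restraint, and a panel of hundreds of tested pairs yields a sparse
distance map of the interface. `xltrap` implements the computational side of
such a study for a GPCR-arrestin complex: validating which pairs crosslink
significantly above background, turning the validated pairs into
yield-weighted distance restraints, scoring and optimizing rigid-body models
against those restraints, and analysing conformational ensembles
(orientation angles, distance traces, contact persistence).

## Crosslinking yields and the two-test filter

The crosslinking yield of a pair is the densitometric intensity of the
crosslinked band divided by the total intensity of the arrestin signal
(crosslinked plus free arrestin), a fraction in [0, 1]
(`crosslink_efficiency()`). A pair is validated when, over at least
`min_n = 3` replicates, its yields exceed a pooled background-noise control
by **both** a one-sided equal-variance t-test at p < 0.02 and a one-sided
Welch test at p < 0.05 (`validate_pairs()`).

Three choices here were genuinely open and are worth recording:

* **Sidedness.** Only signal *above* background is evidence of proximity,
  so both tests are one-sided (pair > control). A two-sided test would spend
  power on the uninterpretable direction.
* **Combination rule.** The two thresholds are combined by conjunction
  (both must pass). This is the conservative reading and makes the false
  positive rate of the combined filter at most the stricter of the two
  alphas; the test suite verifies this bound on 10,000 null pairs.
* **No multiplicity correction.** The thresholds are applied raw, matching
  how such screens are usually reported; the filter is a screen, not a
  confirmatory analysis.

When both samples are degenerate (zero variance) the t statistic is
undefined and the verdict falls back to an exact comparison of means.

## The restraint model

Each validated pair becomes a soft flat-bottom harmonic restraint on the
Cβ–Cβ distance $d$ of its residues (Cα for glycine, which has no Cβ),
weighted by the square root of its yield $B$:

$$E = \sqrt{B}\,\left[\max(d - 10.2,\; 0)^2 + \max(4.0 - d,\; 0)^2\right]$$

The upper wall, 10.2 Å, is the estimated maximal Cβ–Cβ span of the
BrEtY–Cys adduct; the lower wall, 4.0 Å, penalises atomic overlap. Inside
the flat bottom the penalty is exactly zero, outside it grows quadratically,
and it is continuous with continuous first derivative at both walls. There
is no force constant, so energies carry units of weighted Å². $B$ is stored
as a fraction; a percent convention would scale all energies by $\sqrt{100}$
but cannot change any ranking, which is why the package standardises on the
fraction.

`score_model()` reports per-restraint distances, penalties and satisfaction
at two cutoffs: 10.2 Å (the physical adduct span) and 15.0 Å, a margin that
allows for the conformational flexibility of the complex — systematic
studies of chemical crosslinks observe violations of roughly 3–6 Å over the
physical span in static models of flexible assemblies. `rank_models()`
orders candidate models by total restraint energy, breaking ties by the
satisfaction count at 10.2 Å and then by input order, so ranking is
deterministic.

## Crosslinker geometry

`max_span()` estimates the maximal anchor-to-anchor span of a probe by
building the adduct linker from an embedded ideal-geometry table, placing
the para-substituted ring as one rigid collinear segment (its exocyclic
bonds lie on the para axis), enumerating all rotatable torsions on a regular
grid (15° by default), discarding conformers in which atoms three or more
bonds apart come closer than 2.0 Å, and reporting the maximal span. The
geometry table for the built-in BrEtY–Cys probe uses bond lengths 1.51
(Cβ–Car), 2.79 (cross-ring), 1.37 (Car–O), 1.43 (O–CH2), 1.53 (CH2–CH2) and
1.81 Å (both C–S bonds), tetrahedral angles at sp3 carbons, 117° at the aryl
ether oxygen and 99° at the thioether sulfur — standard covalent values
chosen before any span was computed.

Two properties of this estimator are worth stating plainly. Because the
grid includes the all-anti conformer and the clash filter cannot reject an
extended chain, the enumeration returns a *geometric upper bound*: the span
of the fully extended linker, about 10.6 Å under this table. The published
10.2 Å estimate came from force-field conformational sampling, which visits
the fully extended state rarely if at all; an enumeration-based bound is
therefore expected to sit a few tenths of an Ångström above it, and no
physically defensible angle table brings the fully extended chain inside
10.2 ± 0.2 Å. The package keeps the transparent, reproducible bound rather
than tuning geometry toward the published number; the corresponding
acceptance test records the discrepancy. Refining the torsion grid can only
increase the estimate (nested grids), and the span can never exceed the sum
of the segment lengths — both are property-tested.

`monoisotopic_mass()` sums lightest-isotope atomic masses and subtracts one
electron mass per positive charge; for the protonated BrEtY cation
C11H15BrNO3⁺ this reproduces the published calculated m/z, 288.0230, to four
decimals.

## Rigid-body pose sampling

`mmc_optimize()` is a deliberately desk-scale stand-in for full
internal-coordinate optimization: the receptor is fixed and the mobile
partner's 6 rigid-body degrees of freedom are sampled by Metropolis Monte
Carlo under restraint energy plus a soft-sphere Cα clash term
(`clash_energy()`, wall 4.0 Å). Flexible-region remodeling is out of scope;
alternative loop conformations should enter as alternative input conformers.

Design choices:

* **Proposals.** One compound move per step: a rotation about the mobile
  partner's Cα centroid by a normally distributed angle (default sd 5°)
  around a uniformly random axis, plus an isotropic normal translation
  (default sd 0.5 Å per axis). An optional adaptive mode rescales both
  every 500 steps toward 30–50% acceptance.
* **Temperature.** Default kT = 1 in weighted-Å² units, chosen so that a
  unit-weight restraint violated by 1 Å beyond its wall (energy 1) is
  accepted with probability e⁻¹ ≈ 37%.
* **Seeds.** A seed is mandatory; trial *k* uses `seed + k - 1` and runs
  are bit-reproducible. There is no hidden global RNG state beyond R's
  seeded stream.
* **Point estimate.** With flat-bottom restraints the optimum is not a
  point but a plateau: every pose satisfying all restraints has exactly
  zero energy. The first zero-energy pose encountered lies at the edge of
  that plateau nearest the approach path and is a poor representative. The
  sampler therefore also returns `mean_pose`, the running average over all
  minimum-energy samples (rotation averaged and projected back onto the
  rotation group), which estimates the plateau centroid. Recovery
  experiments use `mean_pose`; `best_pose` (first minimum found) is kept
  for transparency.
* **Convergence.** No convergence criterion is claimed; the step budget is
  explicit configuration, and the thinned energy trace lets users judge
  plateaus themselves.

## Orientation analytics

Relative orientation is described with aircraft pitch/roll/yaw angles. Each
partner gets a right-handed frame from the principal components of its Cα
coordinates, eigenvalues descending: the longitudinal axis is PC1 signed
toward the centroid of configurable "nose" residues, the vertical axis is
PC2 signed toward a reference direction (the membrane normal; +z of the
input coordinates by default), and the transverse axis completes the frame.
Solving $X_{receptor} = R\,X_{arrestin}$ gives the rotation, from which

$$\beta = \mathrm{atan2}\!\left(-R_{31}, \sqrt{R_{11}^2 + R_{21}^2}\right),\quad
\gamma = \mathrm{atan2}\!\left(\tfrac{R_{32}}{\cos\beta}, \tfrac{R_{33}}{\cos\beta}\right),\quad
\alpha = \mathrm{atan2}\!\left(\tfrac{R_{21}}{\cos\beta}, \tfrac{R_{11}}{\cos\beta}\right)$$

are the pitch, roll and yaw, reported in degrees throughout. At gimbal lock
(|cos β| < 1e-8) the roll is set to zero, the residual rotation is folded
into the yaw and the result is flagged. Adjacent eigenvalues within 1% of
each other make the axis ordering unstable and raise a warning rather than
failing silently. For the receptor-arrestin system the published nose
conventions (arrestin residues K232–I233, V325–K326, A344–V345; receptor
helix-IV residues A333–V336) are construct-specific, so nose sets and the
membrane normal are plain configuration rather than constants.

`ensemble_orientation()` reports per-frame angles plus the arrestin Cα RMSD
from frame 1 after least-squares superposition of the receptor Cα onto
frame 1 (the fitting group is a documented choice). `distance_trace()`
summarises per-pair anchor distances over frames (min, quartiles, max,
fraction and ever-within flags at 10.2/15.0 Å); `contact_persistence()`
reports the fraction of frames with minimum heavy-atom distance below a
cutoff (default 4.0 Å, a common salt-bridge criterion), including an
any-of-group variant for interactions that switch between partners.

## Synthetic data: what it does and does not show

Every stage has a seeded generator so the full pipeline is testable with no
downloads, and each generator emits its ground truth:

* `make_toy_complex()` builds two pseudo-proteins (directionally persistent
  self-avoiding Cα walks, 3.8 Å spacing, ideal Cβ placement), docks them
  clash-free at a seed-determined pose and plants 12 restraints whose
  anchor distances spread across 6–9 Å, the middle of the flat bottom, with
  at most two restraints per residue so the anchors cover the interface.
  Yields follow `B = clip(0.6 − 0.04 (d − 4), 0.05, 0.6)` plus noise — a
  modeling choice loosely mimicking the observed decrease of yield with
  model distance, not a measured calibration.
* `simulate_blot_table()` draws replicate yields as
  `clip(true + N(0, sd), 0, 1)` (defaults: 3 replicates, sd 0.05) against a
  background control (mean 0.02, sd 0.01, n 20), matching the effect sizes
  the filter is meant to separate.
* `simulate_trajectory()` perturbs the mobile partner by per-frame normal
  pitch/roll/yaw deviations (defaults 4/5/7°, i.e. maximal deviations of
  roughly 13–25° over long trajectories, the scale seen in unbiased
  simulations of such complexes) plus translational noise, and returns the
  planted per-frame angles.

Passing recovery tests on these fixtures demonstrates that the estimators
are unbiased and exact on data satisfying their own assumptions: rigid
bodies, isotropic noise, well-separated principal components, authentic
flat-bottom geometry. They do not demonstrate robustness to features of
real data the generators omit: internal protein flexibility, correlated
replicate noise, non-Gaussian densitometry error, membrane anchoring, or
crosslinking "hub" residues whose many restraints cannot be satisfied by
one conformation. The test-suite problem sizes — 30-residue bodies, 10
trials of 50,000 Monte Carlo steps, 10,000 null pairs for filter
calibration, trajectories of 150–2,000 frames — were chosen as the smallest
sizes at which the statistical assertions are stable.

## Numerical choices and degenerate inputs

* Author residue numbering is used verbatim (no renumbering); insertion
  codes are part of the residue key.
* Alternate locations resolve to the highest occupancy, ties broken
  alphabetically; only the first model of a multi-model file is read by
  `parse_structure()` (use `read_ensemble()` for all models).
* A missing Cβ anchor is a hard error by default; `fallback_ca = TRUE`
  substitutes Cα with a warning. Glycine always anchors at Cα.
* `superpose()` uses the SVD-based least-squares fit with the determinant
  correction, so reflections are never returned; rank-deficient point
  spreads raise an error rather than producing an arbitrary axis.
* Distances at 0 and weights at 0 are legal restraint inputs; negative
  values are domain errors.
* Chain mapping of deposited models is never guessed: chains, nose residues
  and the membrane normal are user configuration.

## Limitations

The sampler is rigid-body only and its energy has no molecular-mechanics
terms beyond the soft clash wall, so it ranks and refines poses against
crosslinking data but does not produce physically relaxed structures. The
span estimator bounds, rather than reproduces, force-field conformational
sampling of the adduct. The significance filter treats replicates as
exchangeable and controls per-pair error only. Ensembles are read as
multi-model PDB; binary trajectory formats need external conversion.
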