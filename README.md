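# xltrap

Crosslink-guided analysis and modeling of protein complexes.

`xltrap` is an R package for studies that map a protein-protein interface
with genetically encoded crosslinking amino acids in live cells — the
motivating system is the complex between the parathyroid hormone 1 receptor
(PTH1R) and arrestin-2. An electrophilic residue such as
O-(2-bromoethyl)-tyrosine (BrEtY) placed in one partner forms a thioether
with a cysteine in the other only when the two side chains come within the
adduct's reach, so every reacting pair is a distance restraint on the
complex. The package covers the computational workflow end to end:

* **Validation** — crosslinking yields from band densitometry
  (band / total arrestin signal) and a two-test significance filter:
  a pair is validated when its yields over n ≥ 3 replicates beat a pooled
  background-noise control by both a one-sided equal-variance t-test
  (p < 0.02) and a one-sided Welch test (p < 0.05).
* **Restraints** — each validated pair with yield *B* becomes a
  yield-weighted flat-bottom harmonic penalty on the Cβ–Cβ distance
  *d* (Cα for glycine):

  E = √B · [ max(d − 10.2, 0)² + max(4.0 − d, 0)² ]

  zero anywhere between the 4.0 Å clash wall and the 10.2 Å adduct span,
  quadratic outside.
* **Scoring and sampling** — restraint reports and satisfaction counts at
  the 10.2 / 15.0 Å cutoffs, model ranking, and a seeded rigid-body
  Metropolis Monte Carlo sampler (restraint + soft Cα clash energy) that
  returns both the first minimum-energy pose and the minimum-plateau mean
  pose.
* **Ensemble analytics** — principal-axes pitch/roll/yaw orientation
  angles, per-pair distance statistics and contact persistence over
  multi-model PDB ensembles.
* **Crosslinker chemistry** — torsion-grid enumeration of the BrEtY–Cys
  adduct's maximal Cβ–Cβ span and monoisotopic mass utilities.
* **Synthetic data** — seeded generators (toy complexes with planted
  restraints, replicate blot tables, trajectories with planted angles) so
  every stage has a ground-truth recovery test.

## Worked example

```r
library(xltrap)

## a toy complex with 12 planted restraints, plus simulated blot replicates
toy <- make_toy_complex(seed = 7)
sim <- simulate_blot_table(setNames(toy$restraints$yield, paste0("pair", 1:12)),
                           seed = 7)
pairs <- validate_pairs(sim$table)
head(pairs[, c("pair_id", "n", "yield", "p_t", "p_welch", "verdict")], 4)
#>   pair_id n     yield          p_t      p_welch     verdict
#> 1   pair1 3 0.5680759 7.556428e-19 0.0048549267 significant
#> 2   pair2 3 0.4793064 1.367666e-25 0.0006504500 significant
#> 3   pair3 3 0.5706574 2.660165e-22 0.0020736024 significant
#> 4   pair4 3 0.4572582 7.249286e-28 0.0001260418 significant
dataset_summary(pairs)
#>      tested  detectable significant
#>          12          12          12
```

Every pair here was planted with a yield far above the background control
(mean 0.02), so all 12 pass both tests; `yield` is the restraint weight B.
Scoring the complex at its true pose satisfies every restraint exactly:

```r
score_model(toy$complex, toy$restraints)
#> xl_report: 12 restraints, total energy 0
#>   within 10.2 A: 12
#>   within 15.0 A: 12
```

Crosslinker utilities and pose recovery from a perturbed start:

```r
max_span(brety_cys_probe())                        # max Cβ–Cβ adduct span
#> [1] 10.59486
monoisotopic_mass("C11H15BrNO3", charge = 1)       # protonated BrEtY probe
#> [1] 288.023

start <- list(rotation = axis_rotation(c(0, 1, 0), 20),
              translation = c(10, 0, 0))            # 20° / 10 Å perturbation
res <- mmc_optimize(toy$receptor, toy$mobile, toy$restraints,
                    sampler_config(steps = 20000, trials = 2, seed = 1),
                    start_pose = start)
res
#> xl_sampling: 2 trial(s), best energy 0 (trial 1)
```

Both trials reach the zero-energy plateau; applying the plateau-mean pose of
the best trial puts the mobile partner 2.78 Å Cα-RMSD from the planted
truth. The span printed above is the fully extended adduct under ideal
covalent geometry — a geometric upper bound a few tenths of an Ångström
above the published force-field estimate of 10.2 Å (see the methods
vignette).

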