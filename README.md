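# cryoval

Per-particle 3D alignment quality scoring for cryo-EM single particle
analysis: soft-validation of a reconstructed density map against the
particle images that built it, score-based particle pruning, and
precision-only ranking of ab initio maps.

## The problem

A single-particle reconstruction assigns every experimental particle image
an orientation (three Euler angles and a 2D origin shift). Because the
images are extremely noisy, this 3D alignment is error prone, and a map can
look internally consistent while many of its particles are misaligned, are
pure noise, carry artifacts, or depict a different conformation. `cryoval`
quantifies, for each particle, two complementary properties of its
alignment against the final map:

- **Precision** — can the particle be assigned an orientation reproducibly?
  The particle is matched against projections of the map on a regular
  angular grid (normalized cross correlation after exhaustive 2D alignment),
  and the directions of its ξ most similar projections are collected. Their
  angular clusterability is

  α_m = Σ_{k≠n} w_n w_k arccos(p_n · p_k) / Σ_{k≠n} w_n w_k,

  the weighted mean pairwise geodesic distance on the projection sphere
  (weights w = NCC similarities). Tightly clustered matches (small α) mean a
  reliable orientation.

- **Accuracy** — does the refined orientation p̂_m agree with where the map
  itself would place the particle today? The accuracy statistic is

  χ_m = Σ_k w_k arccos(p̂_m · p_k) / Σ_k w_k,

  the weighted mean geodesic distance from the refined direction to the
  same ξ best matches found by an independent global search.

Both raw statistics are hard to interpret on their own, so each is
calibrated between two references: a **noise reference** (α̂_NOISE, χ̂_NOISE;
Monte-Carlo average over M draws of ξ uniform random orientations in the
asymmetric unit — the "every orientation equally likely" worst case) and a
per-particle **perfect reference** (the map projected at the particle's own
recorded orientation and shift, distorted by the same CTF, no noise, pushed
through an identical independent search). The quality scores are the
two-point linear maps

  q_m^p : α̂_NOISE ↦ 0, α_{m,good} ↦ 1 (evaluated at α_m),
  q_m^a : χ̂_NOISE ↦ 0, χ_{m,good} ↦ 1 (evaluated at χ_m),

deliberately not clamped to [0, 1]. A particle *aligns with precision*
(resp. accuracy) when its score is ≥ τ = 0.5 — closer to its perfect
counterpart than to noise. The global indicator

  Q = 100 · #\{q_m^p ≥ τ and q_m^a ≥ τ\} / N  (percent)

summarises map-particle consistency. This is *soft* validation: low Q
refutes a map; high Q is necessary, not sufficient. Typical parameter
defaults: ξ = 7, angular sampling Δ = 5°, M = 500, τ = 0.5.

Intended users: cryo-EM practitioners who want a per-particle quality
screen after (or during) refinement, and method developers who need a
self-contained, scriptable implementation with a synthetic ground-truth
generator.

## Worked example

Simulate a phantom dataset in which half of the recorded orientations have
been deliberately randomised, then validate it:

```r
library(cryoval)

vol <- make_phantom()                               # 32^3 blob phantom, 3 A/voxel
ds  <- simulate_dataset(vol, n = 50, snr = Inf,
                        corruption_fraction = 0.5, seed = 11)
rep <- validate_particles(vol, ds$stack, ds$records,
                          xi = 7, delta = 10, M = 200, rot_step = 5, seed = 3)
rep
#> ValidationReport: 50 particles, mode full
#>   Q = 64.0% (precise 96.0%, accurate 64.0%) at tau = 0.5

median(rep$scores$q_a[ds$corrupted])     #> -0.004
median(rep$scores$q_a[!ds$corrupted])    #> 1
keep <- prune(rep, tau = 0.5)            # indices passing both scores
```

Nearly every particle still *aligns with precision* (the images are clean
projections, so their matches cluster), but the corrupted half fails the
accuracy score — its refined orientations no longer agree with the global
search — and Q collapses towards the uncorrupted fraction. `write_report()` writes
the per-particle CSV/STAR tables, a JSON summary and a pruned STAR.

The same pipeline runs from the shell via the bundled front end:

```sh
Rscript inst/cli/cryoval simulate --out fix --n 50 --snr Inf --corrupt 0.5 --seed 11
Rscript inst/cli/cryoval validate --map fix_map.mrc --stack fix_particles.mrcs \
        --star fix_particles.star --out run --delta 10 --M 200 --seed 3
Rscript inst/cli/cryoval prune --scores run_scores.csv --star fix_particles.star \
        --out pruned.star --tau 0.5
```

Input formats: MRC/MRCS volumes and stacks, STAR particle tables (both the
legacy pixel-shift and the Angstrom-shift/optics-group dialects).

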