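---
title: "Scoring per-particle alignment precision and accuracy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring per-particle alignment precision and accuracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cryoval)
```

# The model

`cryoval` treats 3D alignment validation as a per-particle hypothesis test
against two calibrated extremes. For each experimental particle image $m$
the package runs a *global* projection-matching search: the input map is
projected on a near-uniform grid of directions over one asymmetric unit
(angular pitch $\Delta$), each grid projection is aligned to the particle
exhaustively over in-plane rotations and 2D shifts, and the $\xi$ grid
projections with the highest normalized cross correlation (NCC) are kept
with their similarity weights $w_{m,n}$ and directions
$\mathbf{p}_{m,n}$.

Two statistics are computed from this match set:

* **Clusterability** (precision)
  $$\alpha_m=\frac{\sum_{k}\sum_{n\neq k} w_{m,n}w_{m,k}\,
  \arccos(\mathbf p_{m,n}\!\cdot\!\mathbf p_{m,k})}
  {\sum_{k}\sum_{n\neq k} w_{m,n}w_{m,k}},$$
  the weighted mean pairwise geodesic distance among the match directions.
  A particle whose best matches agree on a small angular neighbourhood can
  be oriented reproducibly. The double sum confronts *every* match with
  every other one, so it remains sensitive when the matches split into two
  or more distinct clusters (a nearest-neighbour statistic would not).

* **Accuracy**
  $$\chi_m=\frac{\sum_k w_{m,k}\,\arccos(\hat{\mathbf p}_m\!\cdot\!
  \mathbf p_{m,k})}{\sum_k w_{m,k}},$$
  the weighted mean geodesic distance between the orientation
  $\hat{\mathbf p}_m$ assigned during refinement and the match directions
  of the fresh global search. Refinement pipelines narrow their angular
  searches as iterations progress, so an early misassignment is never
  revisited; $\chi_m$ re-examines every particle against the final map with
  no memory of that history.

All geodesic distances are minimised over the rotation operators of the
map's point group, so symmetry-equivalent directions count as identical.
Antipodal directions are *not* identified: a projection from $-\mathbf d$
is the mirror image of the projection from $\mathbf d$, and mirror matching
is deliberately outside the in-plane search.

## Calibration

Raw $\alpha_m$ and $\chi_m$ depend on symmetry, angular sampling and $\xi$,
so each is placed on a particle-specific scale with two references:

* **Noise reference.** The worst case is an orientation posterior that is
  uniform over the asymmetric unit. $\hat\alpha_{NOISE}$ is the average of
  $\alpha$ over $M$ draws of $\xi$ uniform random directions with *unit*
  weights (no NCC values exist for hypothetical random draws, and the
  weighting in $\alpha,\chi$ is defined only for real matches);
  $\hat\chi_{NOISE}$ likewise averages the distance from $\hat{\mathbf
  p}_m$ to uniform draws. $\hat\chi_{NOISE}$ is computed per particle at
  its own $\hat{\mathbf p}_m$: for non-trivial point groups the
  distance-to-uniform distribution depends on where in the asymmetric unit
  the direction sits, while for C1 the per-particle value simply
  reproduces the global constant.

* **Perfect reference.** Each particle gets a noise-free counterpart: the
  map projected at the particle's recorded orientation *and shift*,
  multiplied by the particle's own CTF, and pushed through an identical,
  fully independent global search, yielding $\alpha_{m,good}$ and
  $\chi_{m,good}$. This accounts for the fact that some views are
  intrinsically easier to align than others (signal concentration varies
  with direction), which a single global "good" value would ignore.

The quality scores are the unique straight lines through
$(\hat\alpha_{NOISE},0)$ and $(\alpha_{m,good},1)$, evaluated at
$\alpha_m$ (and the $\chi$ analogue). Scores are *not* clamped: values
slightly beyond 1 or below 0 occur legitimately because $\xi$ is small and
the grid is finite, and they are reported as-is. A particle aligns with
precision/accuracy when the score is $\ge\tau$; the default $\tau=0.5$
reads "closer to its perfect counterpart than to noise". The global
indicator $Q$ is the percentage of particles passing both thresholds.
$Q$ refutes when low and merely fails-to-refute when high: a wrong map can
still be self-consistent (soft validation).

Where the defining inequality of $Q$ is concerned, the package uses
$\ge\tau$ (not strict $>$): the two conventions differ only on the measure-
zero event of a score exactly at threshold, and $\ge$ matches the
"aligns with precision if $q\ge 0.5$" reading used everywhere else.

# Parameters

| parameter | default | units | role |
|---|---|---|---|
| $\xi$ | 7 | – | matches kept per particle; 1 + 6 neighbours of a grid node |
| $\Delta$ | 5 | degrees | angular pitch of the projection grid |
| $M$ | 500 | – | Monte-Carlo repeats for the noise references |
| $\tau$ | 0.5 | – | pass threshold on both scores |
| `rot_step` | $\Delta$ | degrees | in-plane search step |
| `max_shift` | box/8 | pixels | translational search bound |
| `sym` | C1 | – | point group of the map |

$\xi=7$ reflects that on a roughly hexagonal grid each direction has six
nearest neighbours, so a perfectly aligned particle's match set is one node
plus its ring. The NCC is computed under a circular mask of radius
$0.45\,N$ ($N$ = box size), which excludes the corner artifacts of in-plane
rotation while keeping nearly the whole particle. The in-plane search is
exhaustive at `rot_step` with an FFT translational scan per angle, followed
by separable three-point parabolic interpolation of the correlation peak;
without sub-pixel refinement the $\pm 0.5$ px quantisation error costs
enough NCC on smooth images to scramble the ranking of neighbouring
directions.

# What the synthetic generator emulates

`phantom_spec()`/`make_phantom()` build a deliberately asymmetric (C1)
cluster of twelve small Gaussian blobs of unequal weight in a $32^3$ box at
3 Å/voxel. Two properties drove this design, and both are *requirements of
the method*, not tuning: projections must carry enough fine, chiral
structure that (i) nearby viewing directions are distinguishable by NCC and
(ii) a view is distinguishable from its mirror — the antipodal view. Larger
smooth blobs fail both (their projections are nearly rotation invariant and
almost bilaterally symmetric), which makes even noiseless orientation
recovery ill-posed — a property of the object, not a defect of the scoring.
The 3 Å voxel also keeps the CTF adequately sampled in a 32-pixel box at
realistic defocus (0.5–2 µm); at finer pixel sizes the CTF oscillations
alias in small boxes.

`simulate_dataset()` draws uniform orientations in the asymmetric unit,
uniform in-plane angles, fractional shifts up to box/10, a uniform defocus
in 5000–20000 Å, applies the weak-phase CTF, and adds white Gaussian noise
at a target SNR defined as the masked signal-variance to noise-variance
ratio — measurable on the output, which the tests exploit. Contaminant
classes mirror the populations the scores are meant to flag: pure noise
(fails precision), bright-spot artifacts (5× signal RMS Gaussian spot) and
wrong-conformation particles from a perturbed phantom (fail accuracy), plus
a logged fraction of deliberately randomised recorded orientations
(precision without accuracy). Class counts use largest-remainder rounding
so they match the requested fractions exactly.

What the generator does **not** emulate: structured/coloured noise, CTF
envelopes and beam-induced motion, per-particle magnification errors,
overlapping neighbours, and continuous flexibility. Passing the simulation
experiments therefore demonstrates the statistical machinery (calibration,
discrimination, ranking) under the method's own assumptions, not
performance on any particular real dataset.

# Numerical choices

* Euler convention ZYZ, degrees in metadata, radians internally; the
  projection direction of $(\mathrm{rot},\mathrm{tilt},\psi)$ is
  $(\sin t\cos r,\sin t\sin r,\cos t)$, independent of $\psi$. The sign
  convention linking the Euler $\psi$ to the in-plane angle returned by the
  aligner is fixed by a constructed-transformation test.
* The canonical asymmetric unit is defined operationally: a direction's
  representative is its symmetry image with lexicographically largest
  $(z, x, y)$ (tolerance $10^{-9}$). Grid construction, membership tests
  and uniform sampling all share this definition, so they cannot disagree.
* The projection grid is an equal-area Fibonacci spiral filtered to the
  asymmetric unit; the point count targets a hexagonal-packing pitch of
  $\Delta$. Any near-uniform scheme satisfying the 1.5 Δ covering audit
  would do.
* Volume projection is real-space: trilinear sampling along the rotated
  viewing axis, summed; image rotation/shift is bilinear. Linearity and
  mass conservation are tested; interpolation error is the price of
  determinism and speed at validation resolution.
* `arccos` arguments are clipped to $[-1,1]$; NCC values to $[-1,1]$.
* Degenerate cases: constant images are flagged rather than normalised;
  particles whose two references coincide within $10^{-9}$ get `NA` scores,
  are flagged `degenerate-reference`, and count as *failing* in $Q$ — junk
  should not abort a run, and crediting it would inflate $Q$.
* Ties in the top-$\xi$ selection break towards the lower grid index;
  seeds: one run-level seed spawns per-particle substreams drawn up front,
  so results are independent of evaluation order and bitwise reproducible.
* FFTs go through FFTW3 with plans reused across the whole search; the
  correlation theorem supplies the shift scan, and wrap-around is bounded
  by `max_shift` ≤ box/8 under a mask of diameter 0.9 box.

# Design decisions on genuinely open points

* **Precision-only mode** (ranking ab initio maps, where no refined
  orientations exist): the perfect counterpart is anchored at the
  particle's *own best match* (rank-1 direction, in-plane angle and
  sub-pixel shift) from the global search. This is the only orientation
  estimate available, and for a good map it coincides with the particle's
  true view; accuracy is undefined and reported as `NA`. Both the mean
  precision score and the fraction of particles with $q^p\ge\tau$ are
  reported for each candidate map, since either aggregate supports a
  ranking.
* **Recorded shifts** are applied when building the perfect counterpart
  (the reference should be the particle the refinement claims it is,
  shift included).
* **Unit weights in the noise references**, as above.
* **Ranking aggregate.** Candidate maps are ordered by the fraction of
  particles with $q^p \ge \tau$, with the mean score reported alongside.
  Because scores are unclamped, a handful of particles with
  near-degenerate calibration ($\alpha_{m,good}\approx\hat\alpha_{NOISE}$,
  which featureless candidate maps produce in quantity) can move the mean
  arbitrarily, while the thresholded fraction is bounded and uses the same
  $\tau$ semantics as $Q$. When CTF metadata exists — in practice it is
  estimated long before any alignment — it is applied to the reference
  projections in precision-only mode too; matching contrast-inverted
  CTF particles against CTF-free references would penalise sharp maps more
  than blurred ones.

# Problem sizes used by the packaged experiments

The test-suite experiments run at desk scale, chosen once: angular pitch
$\Delta = 10°$ with `rot_step` 5° (the finer in-plane step costs little and
stabilises NCC ranking), $M = 500$, and $32^3$ phantoms for the noiseless
self-consistency, orientation-corruption and map-ranking experiments. The
signal-versus-noise discrimination experiment at SNR 0.1 uses the same blob
layout scaled into a $48^3$ box: the masked NCC at box 32 carries a noise
floor of $\approx 1/\sqrt{650}$ per hypothesis across a $\sim 3\times10^4$-
hypothesis search, which sits at the signal level at SNR 0.1 — at that box
size a substantial fraction of particles is genuinely unalignable
regardless of scoring. Box 48 triples the mask pixel count and restores the
regime the discrimination question is about.

# Known limitations

* The exhaustive search scales as (grid nodes) × (in-plane steps) ×
  (box² log box); validation of large boxes at Δ = 5° is compute-heavy.
  Evaluation is per-particle independent, so it parallelises trivially,
  but the packaged driver is serial.
* NCC under a fixed circular mask is the only similarity; no matched
  filtering, no mirror search, no local orientation refinement beyond the
  parabolic peak.
* Scores calibrated against a *wrong but self-consistent* map remain high:
  the method soft-validates alignment, never map correctness.
* For maps with near-degenerate projection directions (high symmetry or
  smooth featureless density) $\alpha_{m,good}$ approaches
  $\hat\alpha_{NOISE}$ and the precision score becomes unstable; such
  particles surface as flagged or extreme-valued scores rather than being
  silently clipped.
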