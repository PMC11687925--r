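---
title: "Multilevel Kapur-entropy thresholding with CIWP-PSO"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel Kapur-entropy thresholding with CIWP-PSO}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciwpso)
```

## The problem

Multilevel thresholding segments a grayscale image by choosing `n`
thresholds `th_1 < ... < th_n` that split the gray range `[0, L-1]` into
`n + 1` classes; every pixel is labeled by the class its gray value falls
into. For 8-bit images (`L = 256`) good thresholds can be found by
exhaustive search, but medical scanners commonly emit 12-bit data
(`L = 4096`), where the number of candidate threshold tuples
`choose(L-1, n)` explodes — at `n = 8` it is on the order of 10^25. The
package treats threshold selection as a stochastic global optimization
problem over that space, with a particle swarm variant tuned for the wide
search ranges that high bit depth creates.

## The objective: Kapur's maximum entropy

For a histogram with level probabilities `p_i`, a threshold set defines
classes `C_k` covering the level intervals `[th_k, th_{k+1} - 1]` (class 0
starts at level 0; the top class is closed at `L - 1`). Writing
`w_k = sum(p_i, i in C_k)` for the class probability, each class
contributes the Shannon entropy of its normalized distribution,

    H_k = - sum_{i in C_k} (p_i / w_k) * ln(p_i / w_k),

and the objective is `f(th) = sum_k H_k`, to be maximized. Natural
logarithms are used throughout. Two degenerate-case conventions keep the
objective finite for every candidate the optimizer can propose:
`0 * ln 0 := 0` for empty bins, and `H_k := 0` for an empty class. Both are
the information-theoretic limits, and they let the optimizer evaluate
rather than reject degenerate placements. `kapur_objective()` precomputes
the cumulative sums of `p` and `p ln p`, after which each evaluation is
O(n) via `H_k = ln(w_k) - S_k / w_k` with `S_k` the within-class sum of
`p ln p`.

Thresholds live in `[1, L-1]`, so no class is structurally empty at the
boundaries. On the uniform histogram with equal splits into `n + 1` classes
of `m` bins the objective equals `(n + 1) ln m` exactly, which the tests
use as a closed-form anchor.

## The optimizer

### Baseline PSO

`run_pso()` implements the classic swarm: particle `i` carries a position
`x_i` in `[1, L-1]^D` (`D` = number of thresholds), a velocity `v_i`, and a
personal best; each iteration

    v <- omega * v + c1 * r1 * (pbest - x) + c2 * r2 * (gbest - x)
    x <- x + v

with `r1, r2 ~ U[0,1]` drawn independently per particle *and per
dimension* (the canonical formulation; per-dimension draws explore better
in `D > 1`). Real-valued positions are decoded to integer thresholds by
rounding half-up, sorting, and repairing duplicates upward to the next free
integer (downward when the ceiling `L - 1` is hit), so every particle is
always evaluable — repair rather than rejection matches the unconditional
update loop of the swarm.

Two stabilizers are needed at 12-bit range and are deliberate design
choices: velocities are clamped to `v_max = 0.2 * (UB - LB)` (unclamped
velocities diverge over a 4095-wide box), and positions are clamped to the
bounds with the velocity left unchanged — the simplest bound-handling
contract, recorded so runs are reproducible.

### Pyramid layering and random opposition

`run_ciwp_pso()` ranks the swarm by current fitness each iteration and
splits it into three tiers: the single best particle (elite), the worst
`round((1 - rate) * N)` particles, and the middle. With the default
`rate = 0.9` and `N = 30` the worst tier holds 3 particles — within the
5–20% band the layering is designed for. The elite particle is frozen for
the iteration (elitism); it still steers everyone else through `gbest`.
Worst-tier particles are relocated by random opposition learning,

    P' = LB + UB - r * P,   r ~ U[0,1],

which teleports them toward the mirrored region of the search box —
cheap, aggressive diversification for exactly the particles whose gradient
information is worthless. `r` is drawn per dimension by default
(`rol_per_dim = FALSE` gives the scalar variant); per-dimension draws
increase diversity, which is the strategy's purpose. ROL replaces the
position only; velocity and personal-best history are kept.

### Complementary inertia weights

Middle-tier particles use a fitness-adaptive inertia weight *pair*. The
particle's fitness is mapped to `x in [-0.5, 0.5]` by

    x = (f - (f_best + f_worst)/2) / (f_best - f_worst),

where `f_best`/`f_worst` are the *current iteration's* swarm extremes (not
all-time records, so the map keeps adapting as the swarm converges; the
degenerate `f_best = f_worst` maps to `x = 0`). A scaled logit

    S(x) = ln((s_x * x + 0.5) / (0.5 - s_x * x)) / s_y,
    s_x = 0.96,  s_y = 7.8,

turns rank into weight: `omega = 0.7 + 0.4 * S(x)` and
`omega_reverse = 0.7 - 0.4 * S(x)` for the default range `[0.5, 0.9]`.
The pair is complementary (`omega + omega_reverse = omega_min + omega_max`
identically) and enters the update as

    v <- omega(f) * v + omega_reverse(f) * (c1 r1 (pbest - x) + c2 r2 (gbest - x)).

A fit particle gets high inertia and a small attraction step (exploit its
position); a poor one gets the reverse (abandon it). The logit's steep ends
concentrate the weight change on extreme ranks. `s_x = 0.96 < 1` keeps the
logit off its singularities, at the cost of a sub-0.001 endpoint gap:
`S(±0.5) = ±ln(49)/7.8 ≈ ±0.49895`, so the weights span
`[0.50042, 0.89958]` rather than exactly `[0.5, 0.9]`. The natural-log
reading of the basis function is the only one that makes it a scaled logit
spanning that range; a base-10 reading would compress the sweep to roughly
`[0.61, 0.79]` and defeat the design.

With the worst tier disabled (`rate = 1`) and the weight pair pinned
(`omega_min = omega_max`), the variant collapses onto baseline PSO with
elitism — the test suite verifies trajectory equality bitwise under a
shared seed, which pins down that the machinery adds nothing but the two
intended mechanisms. This is also why `swarm_config()` accepts
`omega_min = omega_max` rather than requiring a strict inequality.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `N` | 30 | swarm size |
| `T_max` | 100 | iterations |
| `c1`, `c2` | 1.5, 1.5 | cognitive / social acceleration |
| `omega` | 0.8 | fixed inertia (baseline PSO only) |
| `omega_min`, `omega_max` | 0.5, 0.9 | adaptive weight range (CIWP) |
| `rate` | 0.9 | middle-tier fraction; worst tier = `round((1-rate)N)` |
| `v_max_fraction` | 0.2 | velocity clamp, fraction of `UB - LB` |
| `LB`, `UB` | 1, `L-1` | threshold search box (gray levels) |

`rate` deserves a note: it is stated as 0.9 alongside a worst tier of
5–20% of the swarm; the two are reconciled by reading the worst-tier
fraction as `1 - rate`. Both are configurable.

## Synthetic images and the exhaustive oracle

`generate_synthetic_image()` draws each pixel independently from a
Gaussian mixture, rounded half-up and clipped to `[0, 2^n - 1]`. The
defaults target the regime the optimizer is built for: 12-bit depth,
256×256 pixels, and 2–5 well-separated modes producing smooth multimodal
histograms like those of mapped benchmark photographs and brain-MRI
scans. Mode SDs of 100–250 gray levels give histogram valleys wide enough
that the optimal thresholds are well-defined but not trivial. What the
generator does *not* emulate: spatial structure (pixels are i.i.d., real
tissue is correlated), scanner noise statistics (Rician in magnitude MRI),
partial-volume effects, and bias fields. Passing tests therefore certify
the optimizer and the objective on realistic *histograms*, not the
spatial metrics' behavior on real anatomy — which is also why the
quality metrics are validated separately against closed forms and an
independent reference implementation.

`exhaustive_optimal_thresholds()` enumerates every threshold tuple and
certifies the global optimum. It refuses beyond a tuple budget (default
10^7) instead of silently subsampling — certifiability over convenience.
At 12-bit depth the oracle becomes tractable through
`rebin_histogram()`, which merges adjacent bins (left-edge mapping back to
the original scale); `nTh = 1` and `nTh = 2` are additionally
special-cased with vectorized exact enumeration so the full 4095-level
pair search (~8.4M tuples) runs in about a second.

## Quality metrics

* **PSNR** uses `MAX = 2^n` (so 72.25 dB for a unit-difference 12-bit
  pair), which is the convention of the thresholding literature this
  package follows; `peak = "pow2m1"` switches to the conventional
  `2^n - 1`.
* **SSIM** follows the universal defaults: `C1 = (0.01 D)^2`,
  `C2 = (0.03 D)^2`, `C3 = C2/2` with `D = 2^n - 1`, an 11×11 Gaussian
  window (σ = 1.5, valid-mode, population moments), mean-pooled. A
  `window = "global"` mode computes one whole-image window so the value
  can be reproduced by scalar arithmetic in tests.
* **FSIM** needs a phase-congruency transform, implemented here from
  scratch on a log-Gabor filter bank (4 scales, 4 orientations, minimum
  wavelength 6, scale multiplier 2, `sigma_onf = 0.55`, Rayleigh noise
  floor at `k = 2` standard deviations, sigmoid frequency-spread weight),
  plus a Scharr gradient. Stabilizers are `T1 = 0.85` and `T2 = 160` at
  the 8-bit reference range; higher-bit-depth images are linearly
  rescaled by `255/(2^n - 1)` before the transform, which is equivalent
  to scaling the quadratic stabilizer `T2` by `((2^n - 1)/255)^2` and
  keeps both metrics' constants dimensionally consistent. Two identical
  constant images have no structure anywhere (`PC ≡ 0`); that case is
  defined to score 1.

The windowed SSIM and the full FSIM are checked in the test suite against
independently scripted reference implementations on a closed-form
sinusoidal fixture (agreement to 1e-9 and 1e-6 respectively).

## Numerical conventions

* Rounding is half-up (`floor(x + 0.5)`) everywhere a gray value is
  produced: decoding, rendering, synthesis.
* Partition ties break toward the lower particle index; exhaustive-search
  ties toward the lexicographically smallest tuple.
* The benchmark median of an even repeat count is the lower-middle order
  statistic, so the reported value always belongs to an actual run whose
  segmentation can be rendered and scored.
* All ratio denominators in the metrics carry small-epsilon guards; the
  weight map clamps `x` to `[-0.5, 0.5]` against round-off at the
  extremes.
* Per-case benchmark seeds are derived from a stable string hash of
  (image, nTh, algorithm, repeat), so adding an algorithm to a benchmark
  does not perturb the other algorithms' random streams.

## Problem sizes used by the shipped tests

The suite certifies optimizer-vs-oracle agreement on 256-level rebinned
histograms of 256×256 12-bit synthetic images (`nTh` 1–2, N = 30,
T = 100, 10 seeds per case), and CIWP-vs-baseline dominance on five
4-mode images at `nTh = 8` with 10 repeats per algorithm — the same
swarm-size and iteration budget as the defaults, with the image count and
repeat count chosen to keep a full test run comfortably fast while the
paired-seed design keeps the comparison sharp.

## Known limitations

* Only the Kapur objective is provided; Otsu's between-class variance is
  out of scope by design.
* The optimizer assumes a single-channel 2-D image; no color or volumetric
  support.
* FSIM internals (filter bank, gradient operator) follow the original
  reference settings, but published FSIM values computed with other
  implementations may differ in the third decimal — comparisons should
  use one implementation consistently.
* The synthetic generator's i.i.d. pixels make histogram-based results
  transfer to real images, but spatial metrics (SSIM/FSIM) on synthetic
  fixtures exercise correctness, not clinical realism.
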