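---
title: "Random-link Rouse models for homolog pairing dynamics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-link Rouse models for homolog pairing dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(homolink)
```

This vignette documents the model behind `homolink`, the estimator
conventions, the numerical choices, and what the package's green tests do
and do not establish. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The model

Each homolog is a single ideal (Gaussian) chain with Kuhn length $b$ and
linear compaction $c$ (nm of contour per bp), so a chromosome of $L$ bp
spans $N = Lc/b$ Kuhn segments and the tagged locus sits at $s = \ell c/b$.
The default compaction, $c = 0.0317$ nm/bp, follows from nucleosome
geometry: a 15-bp linker at the 0.34 nm/bp B-DNA rise plus 146 bp wrapped
into a nucleosome of zero net contour,
`compaction_from_nucleosome(15, 0.34, 146)`. Quoting compactions in bp/nm
(as interphase estimates usually are) requires passing the reciprocal to
`equivalent_kuhn_length()`; the function preserves Kuhn segments per bp, so
chain statistics are unchanged.

The medium is viscoelastic with exponent $\alpha$ (tracer MSD
$\sim t^\alpha$); a Rouse monomer then moves as $t^{\alpha/2}$. The default
$\alpha = 0.48$ corresponds to an observed single-cell MSCD exponent
$B = \alpha/2 = 0.24$. The subdiffusion prefactor $D_0$ is defined by the
**normalisation contract** early-time $\mathrm{MSCD}(t) = 6 D_0
t^{\alpha/2}$ ($D_0 t^{\alpha/2}$ per relative-coordinate axis, three axes,
two loci). Any other normalisation rescales $D_0$ only.

Three structural elements shape the long-time MSCD plateau:

1. **Nuclear confinement.** Both chains live in a sphere of radius $a$
   (default 1.59 µm) with telomeres pinned at independent uniform points on
   the surface.
2. **Rabl tethering.** With probability $p_\mathrm{rabl}(T) =
   e^{-k_\mathrm{rabl} t}$ (default $k_\mathrm{rabl} = 0.605\,h^{-1}$,
   mean detachment 1.65 h) both centromeres are co-anchored at one shared
   surface point, which tightens loci near the centromere.
3. **Random linkages.** A Poisson($\mu$) number of interhomolog linkages at
   i.i.d. uniform genomic positions, the same coordinate on both homologs.
   Linkages flanking the locus on one side make the locus pair an effective
   **linear** tether of $n_L = 2d$ Kuhn segments (locus → linkage →
   homologous locus), with plateau $2 b^2 n_L$; linkages on both sides make
   an effective **ring** with arms $n_1 = 2d_\mathrm{left}$, $n_2 =
   2d_\mathrm{right}$ and plateau $2 b^2 n_1 n_2/(n_1+n_2)$ — the exact
   harmonic composition of the two linear tethers, which the tests verify
   to machine precision.

A cell's plateau is the **minimum** of its tether plateau and the
confinement plateau. The min rule (rather than harmonic combination) keeps
the two regimes cleanly separated; the difference sits inside the 10%
Monte-Carlo band the confinement plateau itself carries.

## Confinement plateau: definition and sampling

Within one 25-min movie the anchor points are static, so the time-averaged
MSCD saturates at twice the *conditional* variance of the separation given
the anchors, averaged over cells:

$$\mathrm{MSCD}_\infty = 2\,E_\mathrm{anchors}\!\left[\operatorname{Var}
(\Delta \mathbf r \mid \mathrm{anchors})\right].$$

This quenched reading (rather than the annealed
$2\langle\Delta r^2\rangle$, which is ~50% larger) is a design decision;
the acceptance band of the 1.74 µm² reproduction covers the residual
ambiguity in how anchors are treated. The anchor-induced conditional means
are not discarded: their dispersion `offset_msq` feeds the synthetic
generator as a per-cell static separation offset, which is what makes
unlinked cells sit far apart on average and drives realistic
colocalization fractions.

Sampling is by rejection: chains are drawn bead-by-bead (1-Kuhn
discretisation, plus the exact locus and centromere coordinates) as
Brownian bridges between pins, abandoning a draw the moment a bead leaves
the sphere (compiled, `src/confined.cpp`). Acceptance for the default
geometry is ~0.1–1%, which the early-exit compiled loop makes cheap.
Halving the bead spacing moves the plateau by under 1%, so the 1-Kuhn grid
is kept. When a bisection probes a regime where acceptance collapses (e.g.
$a = 0.6$ µm at the bracket edge), the sampler falls back to an **exact
harmonic-well Gaussian solve** calibrated so a free monomer's radial
variance matches the uniform-sphere value $3a^2/5$. The fallback
over-confines long chains relative to the hard wall; it exists to keep
inversions bracketed, not to compute reported plateaus, and every reported
number in the acceptance report comes from the rejection sampler.

## Crossover family

The package provides two MSCD crossover families between $6 D_0
t^{\alpha/2}$ and the plateau $C$ (`mscd_theory_curve(form = ...)`):

- `"modesum"` (default): a superposition of odd Rouse modes with $1/p^2$
  amplitudes and stretched-exponential relaxation
  $\exp(-(t/\tau_p)^\alpha)$, $\tau_p = \tau_1 p^{-2/\alpha}$, with
  $\tau_1$ calibrated so the early asymptote is exactly $6 D_0
  t^{\alpha/2}$ (continuum prefactor $4/\pi^{3/2}$). The $t^{\alpha/2}$
  regime emerges from the mode superposition, as in the underlying polymer
  theory, and the local log-slope stays near $\alpha/2$ until close to the
  crossover.
- `"exponential"`: the single-exponential shortcut
  $C(1 - e^{-6 D_0 t^{\alpha/2}/C})$.

The exponential form was the originally sketched simplification, but its
bend starts at first order in $t^{\alpha/2}$: on the 50-frame movie grid it
depresses fitted single-cell exponents to a mean $B \approx 0.17$, which
would misrepresent a world generated at $\alpha = 0.48$. The mode-sum keeps
the generated world self-consistent (mean fitted $B \approx 0.22$, inside
the $0.24 \pm 0.05$ acceptance band; the residual deficit is genuine
crossover bending plus finite-movie fit noise, not a generator error). The
mode sum is truncated at $p \le 199$; the truncation only matters at lags
far below one frame.

The per-axis trajectory covariance is $K(t) = (C - \mathrm{MSCD}(t))/6$,
a positive mixture of stretched exponentials with exponent $\alpha \le 1$,
hence positive definite by construction; a jitter ladder exists as a
safety net and is not normally exercised.

## Synthetic data: what it emulates, what it does not

`simulate_trajectory()` draws the separation as a stationary, isotropic
Gaussian process sampled exactly on the frame grid (Cholesky of the
50×50 covariance), with variance $C/6$ per axis, plus the static anchor
offset for unlinked cells. There is no equilibration transient
(stationarity is assumed within a movie), no localization noise by default
(`localization_sd` exists but the experiment's noise is not modelled), no
point-spread-function rendering, no drift or stage registration, and no
crossover interference in linkage placement. Sister chromatids are not
resolved (each homolog is one chain). Frames with $|\Delta\mathbf r| <
250$ nm are flagged unresolved, their separations masked; they count as
colocalized for state analyses and are omitted from MSCD estimation.

Per-locus positions (for MSD analyses) decompose the pair as common mode
plus half the separation; the common mode reuses the same kernel family
with plateau $C_\mathrm{conf}/4$ and early slope $1.5 D_0 t^{\alpha/2}$,
so a single locus's MSD plateau stays at the confinement scale even for
tightly linked cells — which is exactly the MSCD-below-MSD signature of
linkage the tests assert.

The default stage schedule (T0–T5, hourly) uses the calibrated wild-type
linkage means for URA3 (0, 0, 0, 0.08, 1.27, 3.36), $p_\mathrm{rabl} =
e^{-0.605t}$, and stage diffusivities $D_0(T) = 0.015 + 0.005\,t$
µm²/s^0.24 — increasing through prophase, as reported qualitatively; the
magnitude was chosen once so that ensemble curves reach their plateaus
within the 25-min movie, and is not revisited. A `spo11` switch zeroes all
linkage means (recombination-null control). Generated colocalization
fractions are lower than experimental ones (~5–10% vs tens of percent):
the offset model spreads unlinked loci widely. Green tests therefore
establish the qualitative shapes (nonmonotonic wild-type fraction,
monotone null, plateau reduction after linkage onset), not the absolute
fractions.

## Estimators and fits

- **Time-averaged MSCD** (per cell): all ordered frame pairs
  $(\tau, \tau+t)$, overlapping windows included, both frames resolved; an
  exact match to a brute-force pair loop is part of the acceptance suite.
  **Ensemble MSCD**: pair-weighted pooling (each valid pair equal weight)
  is the default display estimator; `weighting = "cell"` with
  `censor_floor` implements the analysis-side convention of excluding
  per-cell MSCD values below $(0.25\,\mu m)^2 = 0.0625\,\mu m^2$ and
  weighting cells equally — the calibration chain runs on this censored,
  cell-weighted estimator.
- **Power-law/plateau fit** `min(A t^B, C)`: log–log least squares over
  breakpoint candidates; the power-law side needs ≥2 points and the
  plateau ≥2 points (a one-point plateau is reported as `no_plateau`
  instead); ties break toward the earliest breakpoint (longest plateau);
  all-equal curves return the degenerate $B = 0$ fit; negative slopes are
  clamped to 0 and flagged. `exponent_distribution()` keeps fits with
  ≥10 power-law points, following the published histogram convention.
- **Dwell times**: run-length encoding at the 30-s frame grid; the first
  and last runs of each movie are censored and excluded from distribution
  fits by default (`fraction_short_dwell(include_censored = TRUE)` exists
  because the published single-frame fraction may include them).
- **Dwell models**: kinetic = truncated exponential; diffusion and
  subdiffusion share the inverse-gamma-type form $t^{-p} e^{-\tau/t}$ on
  $[30\,s, \infty)$ with $p = 3/2$ (Brownian first return) and $p = 2 -
  B/2$ (fractional-Gaussian persistence, $\theta = 1 - B/2$). Note the
  exponents imply subdiffusion ($-1.88$ at $B = 0.24$) is *lighter*-tailed
  than diffusion ($-1.5$); the tests assert this exponent-consistent
  ordering. Likelihoods can be right-truncated at the movie length. The
  joint (timescale, $B$) likelihood of the subdiffusion model has a flat
  ridge, so fitted $B$ values are poorly identified even when the model is
  correctly *selected*; model selection (AIC) is the supported use.

## Calibration chain

The fit order mirrors the published procedure and its dependency
structure: $b$ from the T0 (Rabl-dominated) plateau; $k_\mathrm{rabl}$ and
$\mathrm{MSCD}_\infty(T_\infty)$ from recombination-null stage plateaus
(with $\mathrm{MSCD}_\infty(T_0)$ pinned to the T0 value); $a$ from
$\mathrm{MSCD}_\infty(T_\infty)$; stage-wise $\mu$ from wild-type
plateaus; $D_0$ last. All Monte-Carlo inversions bisect with **common
random numbers** (one seed per search, restored afterwards), making each
map deterministic and monotone during the search.

For $\mu$ the candidate-ensemble plateau can be computed two ways.
`method = "theory"` censors the exact per-cell curves at the floor — the
right comparison when the target is itself a theoretical quantity, and the
route used for the censored-vs-uncensored comparison (≤6% at $\mu \approx
3$). When the target plateau was *measured from movies*, detection
masking and finite-movie estimator noise inflate the measured censored
plateau by ~10–15% relative to exact curves, and censoring flattens the
$\mu$-to-plateau map enough that this mismatch becomes a >40% $\mu$ error.
`method = "simulate"` therefore realises each candidate ensemble as
simulated movies and measures them identically to the data, so estimator
biases cancel; a thinned linkage bank plus a fixed noise sub-seed keeps
candidates coupled. Because the censored map is shallow near $\mu \approx
3$, the inversion bank should be 2–4× the dataset size to keep its own
noise subdominant.

## Numerical choices

Internal units are µm and seconds (bp and nm at the boundary). Bisection
tolerances: 1 nm ($b$), 0.01 µm ($a$), 0.02–0.05 ($\mu$). Rejection
sampling uses 200 000 attempts per anchor before falling back. Confinement
statistics default to 100 anchors × 100 accepted configurations
(SEM ≈ 1–3% of the plateau). The RNG is R's global Mersenne-Twister
stream; every stochastic function documents that callers seed it, and
study generation derives independent per-stage sub-seeds from the master
seed so stages are reproducible in isolation.

## Known limitations

- The confinement plateau depends on the anchoring convention (independent
  uniform telomere anchors; one shared Rabl point); the true anchoring of
  the original analysis is not recoverable from the main text, hence the
  10% band on the 1.74 µm² reproduction.
- Absolute colocalization fractions are not calibrated to experiment (see
  above); only their stage profile shapes are.
- The mode-sum crossover uses stretched-exponential mode relaxation as a
  completely-monotone stand-in for Mittag-Leffler relaxation; the exact
  fractional kernel would slightly soften the approach to the plateau.
- Dwell-model densities implement the asymptotic tail forms with a
  short-time regulariser, not exact fractional first-passage solutions;
  only tail shape and model ranking are meaningful.
- The sequential calibration propagates no uncertainty between stages
  (matching the published procedure); there is no joint inference.
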