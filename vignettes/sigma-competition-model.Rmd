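---
title: "Modeling sigma factor competition for core RNA polymerase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling sigma factor competition for core RNA polymerase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigmacomp)
library(dplyr)
```

## The model and its assumptions

`sigmacomp` treats the partitioning of RNA polymerase core enzyme among
sigma factors as a quasi-steady-state (QSS) problem: binding reactions
equilibrate fast compared with changes in the totals, so at any moment
the pools satisfy coupled mass-action conservation laws rather than
differential equations. For N sigma species,

$$E_{free}\,\sigma_{i,free} = K_i \, E\sigma_i, \qquad
\sigma_{i,tot} = \sigma_{i,free} + E\sigma_i + \dots, \qquad
E_{tot} = E_{free} + \textstyle\sum_i E\sigma_i + \dots$$

The whole system collapses to a single scalar equation in the free core
concentration $x$: given $x$, every species' free sigma follows in
closed form (a quadratic when an anti-sigma factor competes for the same
sigma), and total core bound is monotone increasing in $x$. The root on
$[0, E_{tot}]$ is therefore unique and found by Brent's method
(`stats::uniroot`) at a relative tolerance of 1e-12 — robustness over
speed. A single species reduces to the familiar quadratic
$(c-h)(s-h) = Kh$, evaluated in the cancellation-free form
$h = 2cs/(b + \sqrt{b^2 - 4cs})$, $b = c+s+K$, which stays accurate for
$K$ ten orders of magnitude below the totals.

Internally everything is molar; copy numbers per cell are converted with
$n = C \cdot N_A V$ using the cell volume (default 1.32 fL, an average
fast-growing *E. coli* cell). Counts are the default reporting unit.

Key model layers, each optional:

* **Anti-sigma factors.** A species' sigma can be sequestered by a
  cognate anti-sigma with its own conservation law; the two-ligand
  equilibrium (core at fixed free concentration + anti-sigma) is a
  quadratic in free sigma solved inside the outer root-find, keeping the
  outer problem one-dimensional and provably bracketed.
* **Non-specific DNA binding.** Core and holoenzymes bind ~1.7 × 10⁷
  genomic sites (3.8 genome equivalents × 4.6 × 10⁶ bp) weakly
  (K_NS ≈ 1e-4 M). Because bound molecules never approach the site
  count, free sites ≈ total sites is hard-coded (excess-sites
  approximation). Equal non-specific affinities leave all *totals*
  exactly at their DNA-free values and simply rescale free pools by
  $p_{free} = 1/(1 + D/K_{NS})$; unequal affinities genuinely shift the
  competition. Free sigma factors do not bind DNA non-specifically —
  only core and holoenzymes do.
* **Transcription.** Initiation is Michaelis–Menten in the free cognate
  holoenzyme, $\alpha = k_{max} [P]\, h/(K_M + h)$; this is exact for
  the two-step scheme bind → initiate, with
  $K_M = (k_{off,p}+k_{init})/k_{on,p}$ (`mm_from_three_state()`).
  Promoters that bind a second, non-transcribing holoenzyme are
  repressed competitively:
  $rate \propto (h/K_M)/(1 + h/K_M + \sum_r r/K_{rep})$ — the standard
  single-site occupancy form, which unlike pure core competition also
  suppresses saturated promoters.
* **The sigma cycle.** Elongation sequesters core for
  $\tau_c = L_{op}/v$ and sigma for $\tau_\sigma = L_{ret}/v$
  (Little's law: a steady flux α holds $\alpha\tau$ molecules), and
  initiation actively separates sigma from core, giving the effective
  dissociation constant $K_{eff} = K + \alpha/(k_{on} h)$. With
  `release_mode = "holoenzyme_release"` the subunits leave the
  terminator together: $K_{eff} = K$ and sigma rides the whole operon.
  Stochastic sigma release is represented by its mean retention length
  only, consistent with the deterministic QSS treatment.

## Parameters that matter

| parameter | unit | default | rationale |
|---|---|---|---|
| cell volume | fL | 1.32 | average fast-growing cell |
| core RNAP / cell | count | 11400 | fast growth (2.5 dbl/h) |
| sigma70 / cell | count | 5700 | fast growth |
| kd_core | M | 1e-9 | strong sigma–core binding, nM scale |
| kon_core | /M/s | 1e8 | diffusion-limited association |
| K_NS (core, holo) | M | 1e-4 | weak, sequence-independent binding |
| promoters per class | count | 200 | typical cognate gene class |
| k_max | /s | 40/60 | maximal initiation 40/min |
| operon length | nt | 2000 | typical operon |
| retention length | nt | 300 | sigma release in early elongation |
| elongation speed | nt/s | 55 | fast-growth transcript elongation |

Two scenario-level choices deserve emphasis because the literature
constrains them only loosely:

* **Stringent-response dissociation constants.** The preset uses
  kd70 = 1 nM and kdAlt = 10 nM: both nanomolar (strong), with the
  housekeeping factor binding more strongly, following the measured
  binding hierarchy. They are plain arguments of `stringent_preset()`
  and worth varying — the peak response factor grows as binding
  strengthens and its location tracks the point where cores cover the
  housekeeping pool.
* **The cross-talk sign is a strong-binding effect.** The $K_{eff}$
  increment $\alpha/(k_{on}h)$ is *absolute*, so the relative weakening
  that active transcription imposes on a sigma species grows without
  bound as the equilibrium $K$ shrinks. In the symmetric two-class
  scenario, silencing the housekeeping class depresses alternative
  holoenzymes only when equilibrium binding is genuinely strong
  (K ≲ 0.01 nM at kon = 1e8 /M/s); at K = 1 nM the cores freed from
  housekeeping elongation outweigh the effect and both holoenzymes
  rise. The package's tests exercise the strong-binding regime.

## Numerical choices

* **Outer root-find** (all equilibrium levels): Brent on
  $[0, E_{tot}/(1+D/K_{NS,core})]$, relative tolerance 1e-12, ≤ 200
  iterations. The residual is monotone, so failure is essentially
  impossible for valid inputs; conservation is checked a posteriori and
  reported in `glance()`.
* **Cycle fixed point:** alternate (a) equilibrium partition of the
  *available* subunits (totals minus promoter-bound and elongating
  pools) at the current $K_{eff}$ with (b) recomputation of
  occupancies, fluxes and $K_{eff}$, with damping 0.5, until all pools
  change by < 1e-9 relative. Proposed occupancies are capped so they
  never demand more sigma or core than exists (raw Michaelis updates
  overshoot for scarce species). When a scarce species faces a heavy
  promoter load the fixed-point map's slope falls below −1 and a fixed
  damping oscillates; the solver detects the stall (no residual
  improvement over 30 iterations) and halves the damping, down to
  1e-3, before giving up with a diagnostic. A final re-partition at the
  converged sequestered pools guarantees the reported state satisfies
  conservation to the inner tolerance.
* **Pools far below one molecule** (< 1e-12 of the system scale) are
  compared absolutely in the convergence test, so femto-molecule noise
  cannot stall iteration.
* **Degenerate inputs:** zero sigma or zero core return the exact
  all-zero holoenzyme state; `kd = 0` is rejected (use
  `holoenzyme_strong_limit()` for the limit) to keep the ratio law
  well-defined.
* **Onset detection:** coarse scan (default 200 log-spaced points) to
  bracket the 5% crossing, then root bisection to relative 1e-6. The
  criterion is applied to free holoenzymes when DNA or the cycle is
  modeled and to totals otherwise, matching how the reduction is read
  off in each setting. The 5% threshold is an argument.
* **Response factors** are central differences in log–log space
  (one-sided at the ends); grids should be log-spaced so the derivative
  is a plain slope. `max_response()` refines the grid argmax by
  golden-section search on a local log-slope with half-width 1e-4 in
  log space.

## Fitting

Titration fits (binding curves, transcription curves, relative-Kd
hierarchies) run Levenberg–Marquardt (`minpack.lm`) on log-scale
parameters from a multi-start grid (Kd from 1e-12 to 1e-6 M), since the
saturating regime can trap a single start. The objective minimizes
*relative* residuals $(m - y)/m$: the measurement noise of gel-based
assays scales with signal, and under that multiplicative noise model
relative residuals are the natural Gauss–Newton objective — they leave
noiseless recovery exact and make the reported asymptotic standard
errors (delta method on log-parameters, rank-checked via SVD of the
numerical Jacobian) approximately calibrated, which plain unweighted
least squares is not. Exchangeable parameter pairs (e.g. Kd and K_M on
an uninformative design) are flagged `weakly-identifiable` rather than
reported with fictitious precision.

Equimolar mixes identify only the *ratios* of dissociation constants
once binding is strong: `fit_relative_kds()` pins the reference species
at 1 nM (deep strong binding against the 400 nM core of the classic
reconstitution design) and fits the remaining log-ratios against all
species' curves simultaneously. The gauge is exact only in the
$K \to 0$ limit — the titration knee softens on a
$\sqrt{K \cdot core}$ scale — which is why absolute constants from mix
data should not be trusted.

## The synthetic-data generator

`simulate_titration()` emulates equilibrium titration assays: fixed
core RNAP (default 400 nM, the classic holoenzyme-reconstitution
design), varied total sigma, response either the holoenzyme fraction of
the plateau (set by the core amount and computed from the model, never
fitted) or the normalized transcription rate. Noise is multiplicative
Gaussian, $y(1+\varepsilon)$, clipped at zero, with an explicit seed
that never touches the session RNG. It reproduces the *shape* and noise
character of such assays but not their real-world failure modes — no
baseline offsets, no plateau drift, no pipetting-correlated errors, no
partially active protein preparations. Passing recovery tests therefore
demonstrates that the estimator inverts the stated forward model at
realistic noise, not that any particular published constant is correct.

## Problem sizes and verification

The package's own verification pairs every solver with an independent
oracle: the explicit mass-action rate equations of the full reaction
scheme (binding, anti-sigma, non-specific sites, promoter binding,
elongation with delayed release) integrated to stationarity with
`deSolve`, on randomized small instances (1–4 species, 1–2 promoter
classes, totals 10⁻⁸–10⁻⁵ M). Equilibrium solutions agree to 1e-6
relative and cycle steady states to 1e-4. Analysis-level checks use
two-species scans of 100–400 grid points and fitting checks use
14-point titrations with 50 noise replicates — sizes chosen so the full
suite doubles as a quick regression run while still exercising every
regime (no-competition, sharp onset, deep competition, saturated and
unsaturated promoters).

## Known limitations

* Strictly steady-state: no pulsing, no time courses (the kinetic
  equations exist only as a test oracle).
* Repression at shared promoters affects rates but repressor
  holoenzymes are not themselves sequestered by those promoters in the
  cycle bookkeeping (their occupancy of a 200-copy class is negligible
  against 10³–10⁴ holoenzymes).
* The excess-sites approximation fails if bound molecules ever rival
  the ~10⁷ non-specific sites — impossible for realistic polymerase
  numbers.
* Sigma retained on an elongating complex is assumed inaccessible to
  anti-sigma capture.
* No polymerase traffic, collisions or premature termination.
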