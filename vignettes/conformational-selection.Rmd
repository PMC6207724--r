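---
title: "Dissecting an open/closed energy landscape: populations, binding kinetics, and coupled catalysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting an open/closed energy landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confsel)
```

# The system and the model

SHP2 is a nonreceptor protein tyrosine phosphatase whose catalytic (PTP)
domain is auto-inhibited by its N-terminal SH2 domain. The enzyme exchanges
between a *closed*, inactive conformation and an *open*, active one;
activating disease mutations (E76D, E76K) shift this equilibrium toward the
open state, and the allosteric inhibitor SHP099 binds only the closed
conformation. `confsel` implements the quantitative machinery for
dissecting such a two-state landscape from three kinds of measurements:

1. **NMR chemical-shift projection analysis** — the position of a
   fast-exchange-averaged cross peak along the line connecting the
   pure-open and pure-closed reference shifts gives a per-residue estimate
   of the closed fraction, pooled across residues by maximum likelihood.
2. **Stopped-flow conformational-selection kinetics** — relaxation rates of
   the three-state scheme open ⇌ closed, closed + L ⇌ closed·L give the
   microscopic rates (k_open, k_close, k_on, k_off) and, through
   K_D^obs = (K_open/close + 1)·k_off/k_on, the apparent drug affinity.
3. **Steady-state enzymology** — a two-site sequential substrate model with
   partial substrate inhibition describes the open catalytic engine, and a
   coupled exchange-plus-catalysis scheme predicts the activity and
   inhibitor response of any landscape.

Units are µM and seconds everywhere; fractions are dimensionless.

# Population estimation from chemical shifts

For residue *i* with query shift (δH, δN), open reference (δH_open,
δN_open) and closed reference (δH_closed, δN_closed), work in the
nitrogen-weighted plane (w = 0.15, the conventional down-weighting of the
¹⁵N axis; `NITROGEN_WEIGHT`, configurable in every function):

* axis **B** = scaled(closed − open), displacement **A** = scaled(query −
  open), θ = angle between them;
* fraction closed F = |A| cos θ / |B|.

**Orientation convention.** As commonly printed, the projection equations
measure the displacement from the *closed* reference, which makes F the
*negative of the open fraction* (−(1−F) here) for on-axis peaks and is
inconsistent with retaining residues with 0 ≤ F ≤ 1. We therefore measure
A from the *open* reference so that F is the closed fraction: F = 0 on the
open reference, F = 1 on the closed one. `project_residue(convention =
"printed")` exposes the other orientation for cross-checking; the filters
assume the default.

**Filters.** Residues are retained when collinear with the axis (θ ≤ 10°),
measurably displaced (|B| ≥ 0.03 ppm), inside the physical range (0 ≤ F ≤
1), and not on an a-priori exclusion list (residues near the drug pocket,
whose shifts respond to the ligand itself rather than the conformational
equilibrium; supplied by the user, e.g. everything within 15 Å of the
binding site). Each dropped residue records exactly one reason, checked in
the order exclusion list → |B| → angle → F range; the retained set is
independent of row order. The ±10° tolerance is applied to the angle
between the query displacement and the open→closed axis — under the
printed orientation this is equivalent to |180° − θ| ≤ 10°.

**Pooling.** With y_i = |A|_i cos θ_i and b_i = |B|_i, the model is y_i ~
N(b_i F, σ²) with a single noise scale σ per data set (the likelihood is
written per data set, so σ is per-protein, not shared across proteins).
The maximiser is closed-form,

$$\hat F = \frac{\sum_i b_i y_i}{\sum_i b_i^2},\qquad
\hat\sigma^2 = \frac1n\sum_i (b_i\hat F - y_i)^2,$$

and the variances come from the observed information (negative inverse
Hessian), whose cross-term vanishes at the optimum:
var(F̂) = σ̂²/Σb_i², var(σ̂) = σ̂²/(2n). The tests verify the closed form
against a dense grid-plus-refinement maximisation of the likelihood
surface (10⁻⁶) and verify the analytic Hessian against finite differences.
Per-residue F values are never clipped before pooling; only the filters
enforce the range, and a global F̂ outside [0, 1] is reported clipped with
a warning while the raw maximiser is retained (`f_hat_raw`). At least two
retained residues are required. A noiseless data set gives σ̂ = 0; its log
likelihood is reported as `Inf` and the variances as 0.

**Calibration.** Because the noise model (isotropic Gaussian peak
displacement) puts exactly N(0, σ²) noise on the axial component y_i, the
Hessian standard error should match the replicate-to-replicate spread of
F̂. The test suite checks this over 500 seeded replicates at the wild-type
design (n = 28 residues, closed fraction 0.90) and requires agreement
within 20%.

# Binding kinetics

The conformational-selection scheme (ligand binds only the closed state)
linearised at constant ligand L has two observable relaxation rates — the
magnitudes of the nonzero eigenvalues of the rate matrix, computed in
closed form by `eigen_rates()` from

$$\lambda_f + \lambda_s = k_{open} + k_{close} + k_{on}L + k_{off},\qquad
\lambda_f \lambda_s = k_{close}(k_{on}L + k_{off}) + k_{open} k_{off}.$$

(The product is the sum of the 2×2 principal minors; note that it carries
k_close, not k_open, against the binding term — the slow phase saturates
at the *closing* rate.) `simulate_scheme()` integrates the full nonlinear
mass-action system with ligand depletion (deSolve, lsoda, rtol 10⁻¹⁰) and
the tests require its long-time limit to match the algebraic three-state
equilibrium and its transients, fitted biexponentially, to match
`eigen_rates()` to 1% under pseudo-first-order conditions (ligand ≥ 10×
protein, the package's validity flag for the linearised analysis).

**Exponential fitting** uses variable projection: baseline, drift and
amplitudes are profiled out exactly by linear least squares at each trial
rate pair, and only the log-rates are optimised (Nelder–Mead, multi-start
from log-spaced decades bracketing the sampled time span). This makes the
noiseless round trip exact to numerical precision and needs no
user-supplied starting values. Phase-count selection is by AIC with a
resolvability guard (rates ≥ 3-fold apart, or the minor amplitude above 3×
the residual noise); a numerically perfect single-exponential fit
short-circuits to one phase. Replicate traces on a shared time base are
averaged before fitting (`average_traces()`), mirroring the usual
averaged-shots practice; fitting replicates individually and pooling is
equally possible with the same functions.

**The fast/slow-phase analysis equations are asymptotic.** The linear
fast-phase relation k_obs = k_on·L/(K_open/close + 1) + k_off is the
*slow* eigenvalue of the scheme in the pre-equilibrium (fast-exchange)
limit; used on the fast phase in the slow-exchange regime it carries a
persistent relative error of order p_open plus terms of order 1/ratio,
where ratio = (k_on L + k_off)/(k_open + k_close). The slow-phase
hyperbola (intercept k_off, plateau k_close) deviates from the exact slow
eigenvalue by a relative error of roughly (k_close − k_off)/(k_on L).
Consequently the property tests demonstrate convergence (< 5% at 10×
separation, < 0.5% at 100×) with a predominantly closed scheme whose
off-rate is comparable to its closing rate — the regime, identified
analytically, in which these published analysis equations are good
approximations — and the end-to-end noiseless round trip (ODE traces →
biexponential fits → fast/slow-phase chain) recovers the generative
closing rate within a 5% tolerance that covers this documented
finite-separation bias. The concentration grid for that round trip (10–100
µM at 0.05 µM protein) keeps binding faster than exchange at every point
so the phase assignment is unambiguous; at lower ligand the two
eigenvalues cross and "fast" no longer means "binding".

**Off-rate.** The dissociation experiment (pre-equilibrated complex
diluted 11-fold) is fitted single-exponentially. Rebinding is ignored by
default, matching the standard treatment; the fitted rate equals k_off
only when post-dilution concentrations are well below K_D^obs, and the
tests quantify the upward bias in the rebinding regime using the ODE
simulator. The fast-phase intercept also estimates k_off but is far less
reliable outside the pre-equilibrium regime; the pipeline therefore
prefers a dissociation-derived (or user-supplied) off-rate when available.

**Uncertainties** on K_D^obs are propagated to first order from the
standard errors of the four rates and cross-checked by seeded Monte-Carlo
resampling (agreement within 25% required at CVs ≤ 10%).

# Enzymology and the coupled model

The two-site sequential rate law

$$k_{obs}(S) = \frac{k_{cat,1}\,S/K_{D,1} + k_{cat,2}\,S^2/(K_{D,1}K_{D,2})}
{1 + S/K_{D,1} + S^2/(K_{D,1}K_{D,2})}$$

treats K_D,1 and K_D,2 as macroscopic sequential dissociation constants
(Adair–Pauling form, no statistical-factor correction) and shows partial
substrate inhibition exactly when k_cat,1 > k_cat,2: rise, single interior
maximum, plateau at k_cat,2. Fitting again uses variable projection (the
k_cats are linear given the K_Ds) with a nested Michaelis–Menten reduction
(K_D,2 → ∞) always fitted alongside; the reduction is preferred by AIC or
when the data show no descending branch. Dose–response data are fitted
with the four-parameter Boltzmann sigmoid in log₁₀-dose (asymptotes free
by default, since the printed analyses do not state whether they were
fixed; a 0/100-pinned two-parameter mode is provided), and
`restoration_concentration()` inverts any monotone activity-versus-dose
model by bisection, returning `Inf` when the target lies below the model's
floor.

The **coupled model** attaches the catalytic engine to the open state only
(the closed state is substrate-blind and catalytically silent — the
structural auto-inhibition mechanism) and the drug to the closed state
only. Substrate binding uses an association rate constant `kon_s` (default
100 µM⁻¹s⁻¹, fast enough that binding is effectively at equilibrium
relative to turnover; dissociation rates follow from the engine K_Ds). The
steady state of the resulting linear five-state scheme {closed·D, closed,
open, ES, ESS} is solved algebraically (null space of the rate matrix) and
by ODE relaxation; the two must agree to 10⁻⁶ and are further checked
against an independent closed-form Briggs–Haldane chain solution.

**A structural property worth knowing:** in this topology the closed state
touches the network through a single edge, so at steady state that edge
carries no net flux and the closed:free-open ratio equals its equilibrium
value *at any exchange rate*. Two consequences, both tested: (i) the
fold-suppression of activity relative to the fully open engine is bounded
by 1/p_open and approaches p_open × engine only at sub-saturating
substrate; (ii) steady-state activity depends on the exchange rates only
through their ratio. Reproducing suppressions larger than 1/p_open at
saturating substrate (as steady-state simulations with richer schemes can)
would require additional closed-state connectivity (e.g. closure of
substrate-bound enzyme), which this package deliberately does not model.

The inhibition curve re-solves the coupled steady state at each dose with
free-drug depletion handled by root-finding whenever the enzyme
concentration is non-negligible, and extracts the half-inhibition
concentration by bisection. When the enzyme is far below K_D^obs and
substrate load is light, the predicted IC50 equals K_D^obs (tested to 2%);
substrate and an open-state activator (thermodynamic linkage factor
`activator_shift()`: K_open/close × (1 + [act]/K_A)) both push it up.

Closing at the activity-assay temperature is taken as roughly twofold
faster than in the binding experiments (5.8 vs 2.9 s⁻¹); this is a config
default, not hard-coded. K_close/open versus K_open/close naming is
reconciled by storing one canonical `K_open_close` with its reciprocal
alongside.

# Synthetic data

The generators produce every input the pipeline consumes, under the
published study designs by default: closed fractions 0.896/0.770/0.042
(`confsel_preset("wt" | "e76d" | "e76k")` carries the landscapes and rate
constants), 28/13/22-residue peak sets, ligand grids within the published
0.5–100 µM span, five replicates, 2% trace noise, three activity
replicates at 5% CV. Peak noise is isotropic Gaussian in the
nitrogen-weighted plane; trace noise is additive Gaussian scaled to the
signal span with optional linear drift — the simplest models consistent
with averaged-replicate treatment. Axis lengths |B| are drawn log-uniform
over 0.05–0.6 ppm, a typical span for well-dispersed amide perturbations.
Fluorescence weights per species are free parameters (the real
quench/gain pattern is instrument- and construct-specific); defaults give
both phases nonzero amplitude. Every generator is bit-reproducible given
(scenario, seed), restores the caller's RNG state, and returns a `truth`
element the tests consume.

What the generators deliberately do not emulate: spectral lineshapes and
slow/fast NMR exchange-regime effects, minor-peak intensities,
instrument dead time, photobleaching beyond linear drift, and
inner-filter effects. Passing the round-trip tests therefore shows the
estimators are correct for the assumed noise models, not that those models
exhaust real-data pathologies.

# Numerical choices and problem sizes

* Optimisers: Nelder–Mead on log-transformed positive parameters with
  multi-start and a polish restart (reltol 10⁻¹⁵); Brent for
  one-dimensional searches. Linear sub-problems are always solved exactly.
* ODE integration: lsoda with rtol 10⁻¹⁰/atol 10⁻¹² for traces; steady
  states relaxed over 40 slowest-eigenvalue lifetimes at rtol 10⁻¹¹.
* Dual-solver agreement thresholds (10⁻⁶) and conservation checks (10⁻⁹
  relative) are asserted in the tests, not silently assumed.
* Degenerate inputs: a zero-length open↔closed axis raises a
  degenerate-axis error in single-residue projection and is routed to the
  |B| filter in batch mode; coincident exponential rates are rejected
  during search and flagged if fitted; flat slow-phase data raise an
  unidentifiability error; boundary closed fractions (0 or 1) are refused
  by `equilibrium_from_population()`.
* Test problem sizes are chosen to finish comfortably on one CPU while
  leaving Monte-Carlo margins: 300–500 replicates for calibration checks,
  40 random draws for dual-solver agreement, 8-concentration grids with
  2000-point traces for the kinetics round trip.

# Known limitations

* The package analyses a strictly two-state conformational equilibrium;
  intermediate or additional states (e.g. independent active-site loop
  dynamics) are outside the model and will surface as filter rejections or
  inflated σ̂.
* The fast-phase population correction and slow-phase hyperbola are
  asymptotic analysis equations; their documented biases at modest
  time-scale separation propagate into chain-derived constants (a few
  percent under the designs used here).
* The coupled model's dead-end topology bounds achievable activity
  suppression at 1/p_open; systems showing stronger suppression need
  richer schemes.
* Peak matching across spectra is by exact (residue, atom-group) keys;
  no automated peak tracking or assignment transfer is attempted, and
  unmatched residues are simply dropped with a count.
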