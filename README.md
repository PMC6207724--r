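# confsel

Quantitative dissection of a two-state (open/closed) conformational energy
landscape and its consequences for catalysis and allosteric drug binding —
the analysis chain developed around the SHP2 phosphatase, its activating
disease mutants (E76D, E76K), and the allosteric inhibitor SHP099, usable
for any enzyme regulated the same way.

SHP2's N-SH2 domain auto-inhibits its catalytic domain; the enzyme
exchanges between a closed, inactive and an open, active conformation, and
the inhibitor binds only the closed state (pure conformational selection).
Three quantitative questions follow, and the package answers each:

**1. Where does the equilibrium sit?** Fast-exchange-averaged amide cross
peaks lie on the line between the pure-open and pure-closed reference
shifts. In the ¹⁵N-weighted plane (w = 0.15), with axis **B** =
closed − open and displacement **A** = query − open,

    F = |A| cos θ / |B|        (fraction closed, per residue)

Residues are retained when collinear (θ ≤ 10°), measurable (|B| ≥ 0.03
ppm), physical (0 ≤ F ≤ 1) and away from the drug pocket; the global F̂
maximises the Gaussian likelihood Σᵢ N(yᵢ; bᵢF, σ²) in closed form with
observed-information variances.

**2. How fast, and how tightly does the drug bind?** For the scheme
open ⇌ closed (k_open, k_close), closed + L ⇌ closed·L (k_on, k_off), the
package simulates full mass-action traces, fits mono/bi-exponentials by
variable projection, extracts rates via the fast-phase line
k_obs = k_on·L/(K_open/close + 1) + k_off and the slow-phase hyperbola
(plateau k_close), and forms the apparent affinity

    K_D_obs = (K_open/close + 1) · k_off / k_on,   K_open/close = k_open/k_close

with first-order and Monte-Carlo error propagation.

**3. What does the landscape do to activity and potency?** The open
state carries a two-site sequential catalytic engine with partial
substrate inhibition,

    k_obs(S) = (kcat1·S/KD1 + kcat2·S²/(KD1·KD2)) / (1 + S/KD1 + S²/(KD1·KD2)),

and a coupled five-state steady-state model (closed·drug ⇌ closed ⇌ open ⇌
ES ⇌ ESS) predicts activity versus substrate, inhibition curves, IC50s,
and the drug concentration needed to push an activated mutant back to
wild-type basal activity. Boltzmann (four-parameter logistic) dose-response
fitting and an activator linkage shift complete the chain.

Seeded generators (`gen_peak_sets`, `gen_stopflow`, `gen_activity`,
`gen_dose_response`, presets `confsel_preset("wt"/"e76d"/"e76k")`) emulate
every input under the published study designs, so the entire pipeline is
testable without any external data.

## Worked example

Synthetic wild-type-like inputs ship with the package (28-residue peak
lists generated at closed fraction 0.896 with 0.003 ppm noise, and a
rate-versus-concentration table from the exact relaxation eigenvalues of
the wild-type scheme):

```r
library(confsel)

query  <- read_peak_list(system.file("extdata", "synthetic_query_wt.csv",  package = "confsel"), "query")
open_r <- read_peak_list(system.file("extdata", "synthetic_open_ref.csv",  package = "confsel"), "open_ref")
closed <- read_peak_list(system.file("extdata", "synthetic_closed_ref.csv", package = "confsel"), "closed_ref")

est <- estimate_population(filter_residues(project_peak_sets(query, open_r, closed)))
est
#> <population_estimate>
#>   fraction closed : 0.8952 +/- 0.0014 (n = 28 residues)
#>   fraction open   : 0.1048
#>   model noise     : 0.00256 ppm

Koc   <- equilibrium_from_population(est$f_hat)        # 0.1171
rates <- read_rate_table(system.file("extdata", "synthetic_rates_wt.csv", package = "confsel"))
fast  <- fit_fast_phase(rates, Koc)
slow  <- fit_slow_phase(rates, fast$k_on, 0.029)       # k_off from a dilution experiment
#> Warning: fitted half-saturation implies non-positive k_open
#> (expected here: the hyperbola constrains k_open only weakly, so the
#>  chain below derives it from the equilibrium constant instead)

scheme <- conf_sel_scheme(k_open = Koc * slow$k_close, k_close = slow$k_close,
                          k_on = fast$k_on, k_off = 0.029,
                          se = list(k_on = fast$k_on_se, k_off = 0.001))
apparent_kd(scheme, n_mc = 2000, seed = 1)$kd_obs
#> [1] 0.06638  # uM; the ~10% offset from the generative 0.074 is the
#>              # documented finite-separation bias of the fast-phase line

engine <- two_site_params(kcat1 = 300, kcat2 = 260, kd1 = 600, kd2 = 4000)
cfg <- coupled_config(engine, k_close = 5.8, p_open = 1 - est$f_hat,
                      drug = list(k_on = scheme$k_on, k_off = scheme$k_off),
                      enzyme_uM = 1e-5)
inhibition_curve(cfg, doses = c(0, 0.01, 0.1, 1), substrate = 500)
#> <inhibition_curve> basal 26.32 1/s at 500 uM substrate; IC50 = 0.07288 uM
```

Reading the numbers: the pooled projection recovers the closed fraction to
three decimals with a standard error from the likelihood curvature; the
kinetic chain turns the rate table into microscopic constants and an
apparent (population-diluted) affinity; and the coupled model shows the
mostly-closed landscape suppressing the ~143 s⁻¹ open engine to 26 s⁻¹ at
500 µM substrate while the drug half-inhibits near its apparent K_D. The
engine parameters here are illustrative, chosen to give open-variant-like
basal rates, not a reproduction of any published fit.

`run_pipeline()` chains the same stages from a single (YAML or in-memory)
config and serialises a provenance-bearing JSON report via
`write_report()`.

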