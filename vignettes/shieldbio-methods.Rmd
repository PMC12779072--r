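---
title: "Methods: photon shielding, docking thermodynamics and MIC statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: photon shielding, docking thermodynamics and MIC statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shieldbio)
```

shieldbio characterizes small-molecule drug candidates along three
independent axes that share nothing but the compound table: how well the
bulk material attenuates gamma radiation, how strongly the molecule binds
its protein targets in silico, and how its antimicrobial potency compares
across a candidate series. This vignette explains the models behind each
stage, the tunable parameters and their defaults, the numerical choices,
and what the synthetic-data module does and does not emulate.

## Photon attenuation

The density-independent interaction probability of a photon with a
compound is its mass attenuation coefficient (MAC, $\mu/\rho$, cm²/g),
obtained from elemental coefficients by the mixture rule

$$ (\mu/\rho)_{\mathrm{compound}}(E) \;=\; \sum_i W_i\,(\mu/\rho)_i(E), $$

where $W_i = n_i A_i / M$ are the elemental mass fractions computed from
the molecular formula ($n_i$ counts, $A_i$ standard atomic weights, $M$
the molecular weight). Atomic weights are a fixed IUPAC table shipped
with the package so that every environment computes identical fractions.

From the MAC and the mass density $\rho$ follow the linear attenuation
coefficient $\mu = \rho \cdot (\mu/\rho)$ (cm⁻¹), the half-value layer
$\mathrm{HVL} = \ln 2 / \mu$ and the mean free path
$\mathrm{MFP} = 1/\mu$. The exact $\ln 2$ is used throughout; the value
0.693 seen in print is a presentational rounding. Every emitted row
satisfies $\mathrm{HVL}\cdot\mu = \ln 2$ and $\mathrm{MFP}\cdot\mu = 1$
to floating-point precision, and the test suite asserts this.

**Interpolation.** Elemental cross sections are tabulated on discrete
energy grids; off-grid queries use log–log linear interpolation, the
standard choice for photon cross sections. It is exact at grid points and
exact on power-law curves, which gives the test suite a closed-form
oracle: synthetic tables generated as $\alpha E^{-\beta}$ must reproduce
the closed form to 10⁻¹⁰ through the whole pipeline. Extrapolation
beyond the grid is refused rather than attempted silently — silent
cross-section extrapolation is a classic source of wrong shielding
numbers.

**Densities.** The packaged candidate series (2a–2f) has published
linear attenuation coefficients but no published densities. Rather than
guess, the package treats density as a user input and provides
`infer_density()`, which back-solves $\rho = \mu / (\mu/\rho)$ at one
anchor energy. Anchoring at 662 keV and predicting the remaining
Compton-regime energies cross-validates the published table without
assuming anything not printed. The packaged table's 2a row repeats the
same value at 80 and 120 keV, which is physically implausible
(photoelectric absorption falls steeply over that range), so
cross-validation anchors in the Compton regime instead of at the low
energies.

**The packaged cross-section fixture.** Total mass attenuation
coefficients for H, C, N and O are transcribed from the standard
tabulation for these elements on a 26-point grid over 0.015–15 MeV. The
incoherent (Compton) channel is computed from the Klein–Nishina
per-electron cross section scaled by $N_A Z/A$. That model is accurate
in the Compton-dominated regime (above roughly 0.1 MeV for low-Z
elements) but overestimates the incoherent coefficient below ~50 keV,
where electron binding (the incoherent scattering function) suppresses
scattering. Consequences: mixture MACs and everything derived from them
use the total channel and are unaffected; Compton-to-total ratios (and
therefore equivalent atomic numbers) from this fixture are trustworthy
above ~0.1 MeV and indicative only below. All unit tests of the ratio
machinery run on synthetic two-channel tables with known closed forms,
not on this fixture.

## Equivalent atomic number and G-P buildup factors

Narrow-beam attenuation underestimates the photon field at depth because
scattered photons re-join the beam; buildup factors $B(E, x) \ge 1$
correct for this at penetration depth $x$ (measured in mean free paths).
The geometric-progression (G-P) representation parameterizes $B$ by five
coefficients $(b, c, a, X_k, d)$:

$$ K(E,x) = c\,x^a + d\,\frac{\tanh(x/X_k - 2) - \tanh(-2)}{1 - \tanh(-2)} $$

$$ B(E,x) = \begin{cases}
  1 + \dfrac{b-1}{K-1}\,(K^x - 1), & K \neq 1,\\[2mm]
  1 + (b-1)\,x, & K = 1,
\end{cases} $$

valid for $x \le 40$ mfp; the package enforces that domain and returns
$B(0)=1$ as the physical boundary condition. Near $K = 1$ the generic
branch is numerically singular ($0/0$), so the linear branch — its exact
limit — is used whenever $|K-1| < 10^{-8}$. The threshold was chosen so
that the switch error, bounded by $(b-1)x^2|K-1|/2 \le 3\times10^{-5}$
at the domain extremes, is far below any physical use of a buildup
factor, and the test suite checks continuity across the boundary.

A caution discovered while testing: $B$ is **not** guaranteed monotone
in depth for arbitrary parameter quintuples, because $K$ itself depends
on $x$ and the geometric branch changes character when $K(x)$ crosses 1.
Monotonicity is a theorem only for depth-independent $K$ ($a = d = 0$),
and that is what the property tests assert; tabulated physical parameter
sets do produce monotone curves in practice.

G-P parameters are tabulated per element; a compound is mapped to an
*equivalent atomic number* $Z_{eq}$ — the (real-valued) element whose
Compton-to-total attenuation ratio $R = (\mu/\rho)_C / (\mu/\rho)_T$
matches the compound's at the given energy — by logarithmic
interpolation between the bracketing tabulated elements:

$$ Z_{eq} = \frac{Z_1(\log R_2 - \log R) + Z_2(\log R - \log R_1)}
                 {\log R_2 - \log R_1}. $$

The implementation requires the elemental ratio table to be monotone in
$Z$ at the query energy (otherwise the bracket is ambiguous and the
function stops with a diagnostic), and refuses ratios outside the
tabulated span rather than clamping. The five G-P parameters are then
interpolated between the bracketing integer-$Z$ rows with the same
logarithmic-in-$Z$ weights — the convention of the buildup literature,
which the tests pin down exactly on synthetic parameter surfaces built
linear in $\log Z$. When a query energy falls between grid energies the
$Z$-interpolated parameters are interpolated log-linearly in energy,
exactly recovering tabulated values at grid energies.

Published buildup results for the packaged compound series report
EABF/EBF triplets at 10/20/40 mfp without stating the photon energy at
which they were read, so they cannot serve as numeric targets without
guessing; the package instead validates the buildup machinery by
property (bounds, continuity, endpoint identities, closed-form synthetic
surfaces). The default energy grid is 25 logarithmically spaced points
over 0.015–15 MeV, the standard G-P tabulation range and grid size; the
default depths are 10, 20 and 40 mfp.

## Docking thermodynamics

Docking engines print an inhibition constant next to each binding free
energy using

$$ K_i = \exp\!\left(\frac{\Delta G}{RT}\right), \qquad
   R = 1.98722\times10^{-3}\ \mathrm{kcal\,mol^{-1}K^{-1}},\quad
   T = 298.15\ \mathrm{K}, $$

and the package adopts exactly those constants: they reproduce all eight
packaged printed $K_i$ values from the printed $\Delta G$ within
rounding. Because $\Delta G$ is printed to two decimals, a ±0.005
kcal/mol grid step moves $K_i$ by about 0.85%; adding the rounding of
the printed $K_i$ itself motivates the 2% consistency tolerance used by
`dock_report()`. Printed constants that fail the check are flagged,
never overwritten — a disagreement is information about the source
table, not something to repair silently. Residual discrepancies at the
0.5% level (e.g. a printed 221.83 nM against a recomputed 220.99 nM) are
exactly what $\Delta G$ rounding predicts, so no alternative constants
were fitted.

MM/PBSA totals are the plain sum of the four end-point components (van
der Waals, electrostatic, polar solvation, nonpolar solvation); when
standard deviations accompany the components the reported total SD is
the root-sum-of-squares, a reporting convenience that ignores component
correlations. The packaged component table labels its polar term as
Generalized Born; the aggregator is agnostic and sums whatever polar
term is supplied.

## MIC statistics

Broth-microdilution MICs live on a two-fold concentration ladder, so two
analysis decisions had to be made that the source material leaves open:

* **Scale.** The default comparison runs on $\log_2$ MIC — dilution
  data are geometric, and one ladder step is then one unit. The raw
  scale remains available (`scale = "raw"`); on the packaged data both
  scales reject the null at $\alpha = 0.05$.
* **Replication.** One observation per tested (compound, organism)
  cell, organisms acting as replicates. Assay-level replicates are not
  published per cell, so this is the finest layout the data supports;
  it is recorded here as an assumption rather than asserted as the
  original computation.

The one-way ANOVA is the classical between/within decomposition
($F = \mathrm{MSB}/\mathrm{MSW}$, $p$ from the F distribution), written
out in the package and cross-checked in the tests against base R's
`aov()` on random layouts; the degenerate all-means-equal case returns
$F = 0$, $p = 1$. Tukey's HSD uses the Tukey–Kramer standard error
$\sqrt{\mathrm{MSW}(1/n_i + 1/n_j)/2}$ so unbalanced layouts (from
not-tested cells, which are excluded pairwise and never imputed) are
handled. Adjusted p-values come from the studentized range distribution
via base R's `ptukey` — a base distribution function of the language
runtime, not an optional dependency — and the test suite additionally
validates Tukey decisions against a 10⁶-draw Monte-Carlo simulation of
the studentized range null on three-group layouts, and the ANOVA's
type-I error rate against 10,000 null replicates.

Ladder membership is validated with a relative tolerance of 10⁻⁸, which
accepts the reporting convention that doubles 312 to 625 (a true ratio
of 2.003 between rungs, inside the declared [1.9, 2.1] band) while
catching genuinely off-ladder values.

## The synthetic-data module

Each generator emits a table with exactly the structure its consumer
assumes, plus the ground truth as attributes:

* `gen_xs_table()`: totals $\alpha_Z E^{-\beta_Z} + \gamma_Z$, Compton
  channel a $Z$-decreasing constant fraction of the total. With
  $\gamma_Z = 0$ log–log interpolation is exact, giving 10⁻¹⁰-level
  oracles; with the default small $\gamma_Z$ the curves are no longer
  pure power laws and only regression-level agreement is expected.
* `gen_gp_table()`: all five parameters linear in $\log Z$ at each grid
  energy with smooth coefficient curves, so interpolation has an exact
  closed form.
* `gen_docking_table()`: uniform $\Delta G$ on [−15, −5] kcal/mol (the
  favorable range of the packaged results); printed-style $K_i$ columns
  rounded to two decimals in their natural unit, falling back to four
  significant digits for sub-0.5 nM values where two-decimal rounding
  alone would exceed the 2% consistency tolerance.
* `gen_mic_matrix()`: true $\log_2$ MIC = baseline + compound effect +
  $N(0, 0.25^2)$ replicate noise, snapped to the nearest ladder rung
  with ties to the *lower* rung (the conservative call: ties read as
  less active). Defaults — ladder 78–1250 µg/mL, baseline 625 µg/mL,
  nine organisms, six compounds with effects (0, 0, 0, −1, +1, −2)
  log₂ units — mirror the packaged series, where two candidates are
  more active and one less.

A single root seed drives all four generators through fixed offsets, and
generation restores the caller's RNG state. What passing synthetic tests
demonstrate: the algebra, interpolation conventions, seed plumbing and
statistical machinery are correct against closed forms and known ground
truth. What they do not demonstrate: agreement with real photon physics
(the synthetic curves are smooth monotone stand-ins with no absorption
edges or pair-production rise), real docking score distributions, or
real inter-organism MIC correlation structure (organism effects are
i.i.d. noise here).

## Problem sizes and runtime

The test suite runs entirely from code-built fixtures: 26-point energy
grids, eight-record docking tables, 6 × 9 MIC matrices, 200–300
randomized parameter draws per property, a 10⁶-draw studentized-range
simulation, 10,000 null ANOVA replicates and 1,000 MIC power
replicates. These sizes keep the full suite under a minute on one CPU
while leaving the Monte-Carlo error of each stochastic check an order of
magnitude below its assertion tolerance.

## Known limitations

* The cross-section fixture's incoherent channel is Klein–Nishina, not
  a full incoherent-scattering-function tabulation (see above); Zeq from
  this fixture below ~0.1 MeV is indicative only.
* G-P parameter tables are inputs; the package does not generate them
  from transport calculations, and the shipped example table is
  synthetic (marked as such in its name and header).
* No photon transport, detector response, docking search, MD, or
  trajectory-based energy evaluation — the package post-processes
  tabular results of those computations.
* Effective atomic number Z_eff and electron density are out of scope;
  Zeq here is specifically the buildup-interpolation quantity.
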