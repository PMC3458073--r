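---
title: "Methods: structure-based folding simulations and two-state unfolding thermodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-based folding simulations and two-state unfolding thermodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fraxfold)
```

fraxfold studies how the non-canonical C-terminal region (CTR) of human
frataxin — roughly residues 196–210, which pack against helices α1/α2
without forming regular secondary structure — contributes to the stability
and folding cooperativity of the domain. The package combines three
computational layers that mirror how this question is attacked
experimentally and in silico: a coarse-grained structure-based (Gō-type)
folding model with WHAM thermodynamics, two-state equilibrium unfolding
fitters for chemical and thermal denaturation data, and analytic
hydrodynamic calculators. A synthetic-data layer generates every input the
pipeline needs with known ground truth, so all numerical machinery is
testable against closed forms.

## The structure-based model

Each residue is a single bead at its Cα position. The potential is the
standard Cα Gō form: harmonic bonds and angles about their native values,
1- and 3-fold cosine dihedrals, and a 10–12 Lennard-Jones well of depth ε
for every native contact,

$$V = \sum K_r (r - r_0)^2 + \sum K_\theta (\theta - \theta_0)^2 +
\sum \left[ K_\phi^{(1)} (1 - \cos\Delta\phi) +
K_\phi^{(3)} (1 - \cos 3\Delta\phi) \right] +
\sum_{\mathrm{native}} \varepsilon \left[ 5 \left(\tfrac{r_{0ij}}{r_{ij}}\right)^{12}
- 6 \left(\tfrac{r_{0ij}}{r_{ij}}\right)^{10} \right] + V_{\mathrm{rep}}$$

with $K_r = 100\,\varepsilon$, $K_\theta = 20\,\varepsilon$,
$K_\phi^{(1)} = \varepsilon$, $K_\phi^{(3)} = 0.5\,\varepsilon$. Native
contacts are Cα pairs with sequence separation $j \ge i+4$ and native
distance between 4.0 and 6.0 Å; closer-in-sequence pairs are already
restrained by the bonded terms. Units are reduced throughout: ε = 1,
k~B~ = 1, bead masses 1, lengths in Å.

**Excluded volume.** For non-native pairs ($j \ge i+4$, not in the contact
map) we use a smooth truncated wall,

$$V_{\mathrm{rep}}(r) = \varepsilon \left[ (\sigma_{ij}/r)^6 - 1 \right]^2
\quad (r < \sigma_{ij}), \qquad 0 \ \text{otherwise},$$

with $\sigma_{ij} = \min(4.0\,\text{Å}, r^{\mathrm{native}}_{ij})$. Three
properties motivated this choice over a bare $r^{-12}$ term. First, it
vanishes in both value and force at $\sigma_{ij}$, so the native structure
is *exactly* the global energy minimum and the native-state energy is
exactly $-\varepsilon N_{\mathrm{contacts}}$ — a property we use as a hard
regression anchor. Second, the continuity of the force matters for the
microcanonical (zero-friction) energy-conservation checks. Third, tying
$\sigma_{ij}$ to the native distance for natively-close pairs avoids
penalizing the reference geometry itself while still preventing chain
crossing. The leading hardness is still $r^{-12}$.

**Degenerate dihedrals.** A dihedral whose defining bond triple is
collinear in the native structure has no defined reference angle; such
dihedrals are disabled (zero force constant) with a warning. This arises
only in artificial test geometries — the toy generator adds a ±0.15 Å
alternation across its strands precisely so that all its dihedrals are
well-defined.

**Dynamics.** Constant-temperature runs use the BAOAB splitting of Langevin
dynamics (default timestep 0.0005 τ, friction 1 τ⁻¹ — the timestep is set
by the stiff $K_r = 100\,\varepsilon$ bonds, the friction by wanting
diffusive but fast-decorrelating sampling). With friction 0 the integrator
reduces to velocity Verlet, which is how the energy-conservation tests run.
Randomness comes from R's RNG, so a `set.seed()`-style integer seed makes
runs bit-reproducible; ladder runs derive per-run seeds as `seed + k`.

**Reaction coordinate.** Q is the fraction of native contacts formed, a
contact counting as formed when $r_{ij} < \gamma\, r_{0ij}$ with γ = 1.2.
An empty contact map yields Q = 1 by convention (with a warning) to avoid
0/0; this only occurs for degenerate inputs such as straight chains.

## WHAM, heat capacity and free-energy profiles

Multi-temperature runs are pooled by the weighted histogram analysis
method on joint (E, Q) bins (default 60 energy bins over the pooled range;
Q bins of width $1/N_{\mathrm{contacts}}$, capped at 50, since Q is
intrinsically discrete). The self-consistent equations are iterated
directly in log space with log-sum-exp stabilization until the per-run
shifts change by less than 1e-7 (cap 1e5 iterations; non-convergence is an
error that carries the residual history). Two numerical details matter:

* each bin's Boltzmann factor uses the *sample-mean* energy of the bin
  rather than the geometric bin center, which removes the leading
  discretization bias — on the analytic two-level benchmark this is the
  difference between recovering the Schottky heat capacity to a fraction
  of a percent versus a systematic ~3% error;
* the converged density of states is normalized to unit sum, making the
  result exactly invariant to run order.

Cv(T) is computed from reweighted moments, $(\langle E^2\rangle -
\langle E\rangle^2)/T^2$, on a 2001-point grid over the simulated bracket;
Tm is the Cv argmax (ties broken toward lower T), with the search window
shrunk by half the outermost ladder gaps: exactly at the coldest or
hottest run temperature the reweighting rests on a single histogram's
tails and the variance estimate spikes spuriously, so an extremal "peak"
there cannot be certified as a transition. Reweighting is refused
more than 20% outside the simulated temperature bracket. F(Q|T) =
−T ln P(Q|T) is reported with its minimum shifted to zero; empty interior
bins are masked with a warning. The barrier is the maximum of F between
the two deepest local minima, reported in units of k~B~T; when only one
minimum exists the barrier is an explicit `NULL` with a warning rather
than a number.

The WHAM layer is validated against a two-level system (level spacing 2 ε,
degeneracy 3) whose partition function is closed-form: the recovered
degeneracy ratio must be 3 within 5% and Cv(kT = 1) must match
$4p(1-p) \approx 0.8215$ within 3%.

## The toy fold and the CTR analogy

`make_helix_hairpin(n)` builds an analytic compact chain: two antiparallel
strands (3.8 Å backbone spacing, 5.0 Å between strands) joined by a turn
bead, plus a tail — the last ⌈0.15 n⌉ residues — lying along the groove
3.6 Å above the sheet, midway between the strands. All contact distances
are provable by enumeration; nothing is minimized or random. For n = 30
the map has 31 contacts, 20 of which involve the tail or its connector;
truncating the tail (the analogue of hFXN90–195) leaves 11.

The tail placement is the design decision that makes the toy a faithful
CTR analogue. Because each packed tail bead contacts *both* strands, its
contacts can only form when the core is folded — a conformational lock,
like the CTR packing against helices α1/α2. A tail packed against a
single strand fails qualitatively: strand 1 alone is just a chain
segment, so tail–strand contacts survive core unfolding, and truncating
such a tail removes more unfolded-state chain entropy than folded-state
enthalpy — *raising* the melting temperature, the opposite of the CTR
phenomenology. We verified both behaviors in equilibrium scans before
fixing the geometry.

The toy reproduces the topological situation — a peripheral segment whose
bridging contacts are lost on truncation — but not the size or contact
density of a real domain. Its transition is weakly first-order:
heat-capacity peaks are broad and F(Q) barriers are ~1 k~B~T rather than
the several k~B~T of a 120-residue domain. Passing the full-versus-
truncated comparison therefore demonstrates that the machinery resolves
the correct qualitative ordering (lower Tm, broader Cv peak, smaller
barrier after truncation), not that the toy is thermodynamically
equivalent to frataxin.

`thermo_scan()` runs the production protocol: an annealed temperature
ladder (each run starts from the final frame of the run below it, the
lowest from the native structure), WHAM pooling after discarding an
equilibration fraction of each run, then Cv, Tm and F(Q|Tm). Its
production timestep default is 0.002 τ, chosen from an explicit bias
scan: equilibrium mean Q and Cv at the transition agree across 0.0005,
0.002 and 0.003 τ but are visibly biased at 0.005 τ, where wall
collisions produce energy spikes. Problem sizes used in the shipped
tests: ladders of nine temperatures in steps of 0.1 bracketing each
variant's own transition (0.7–1.5 for the full toy, 0.5–1.3 for the
truncated one — the published analysis likewise evaluates each variant at
its own melting temperature), 3×10⁶ steps per temperature, frames every
250 steps, first 25% discarded. At these sizes the full toy shows an
interior Cv peak with an F(Q) profile carrying distinct basins near
Q ≈ 0.25 and Q ≈ 0.75, and the comparison against the truncated chain is
stable under the seeded protocol.

## Landscape decomposition and substates

`partition_contacts()` splits the contact map by a residue-id region (for
frataxin, the CTR 196–210 in author numbering; for the toy, its tail): a
contact is "CTR" when at least one partner lies in the region. Per frame,
each class's own formation fraction gives (Q_core, Q_CTR); the counting
identity $n_{\mathrm{core}} Q_{\mathrm{core}} + n_{\mathrm{ctr}}
Q_{\mathrm{ctr}} = n_{\mathrm{total}} Q$ holds exactly and is asserted in
tests. Joint (Q_core, Q_CTR) log-probability maps use a 25×25 grid over
[0,1]². Substate labels operationalize the native-ensemble split seen for
frataxin — N1 (core folded, CTR bound: Q_core ≥ 0.7 ∧ Q_CTR ≥ 0.5), N2
(core folded, CTR unbound: Q_core ≥ 0.7 ∧ Q_CTR < 0.5), U (Q_core ≤ 0.3),
else "other". The thresholds are declared package defaults, exposed as
arguments and recorded in the output attributes; they are not fitted to
anything. The transition-state ensemble selector takes frames with
|Q − 0.5| ≤ 0.05 at Tm; the half-width is configurable because "Q ≈ 0.5"
is a convention, not a measurement.

## Two-state unfolding fits

Chemical denaturation uses the Santoro–Bolen linear extrapolation model:
$\Delta G(x) = \Delta G^0 - m x$, linear baselines, signal =
population-weighted baseline average. Thermal denaturation uses the
Gibbs–Helmholtz free energy
$\Delta G(T) = \Delta H (1 - T/T_m) - \Delta C_p [(T_m - T) + T\ln(T/T_m)]$
with linear baselines in T. Both fitters are nonlinear least squares
(Levenberg–Marquardt via minpack.lm) with deterministic initialization:
end-segment baselines, midpoint from the mid-signal crossing, and for the
thermal fit a van 't Hoff estimate $\Delta H \approx 4 R T_m^2 \,
(\mathrm{d}f_U/\mathrm{d}T)|_{T_m}$. The m-value and ΔCp can each be held
fixed, matching the practice of fixing them at values predicted from chain
length. R = 1.9872×10⁻³ kcal mol⁻¹ K⁻¹; all fitting is internal to Kelvin
(°C ↔ K via 273.15); the default isothermal temperature is 293.15 K
(20 °C). Fluorescence and CD probes are fitted separately — no global
multi-probe fit.

`stability_curve()` evaluates ΔG(T) on a 0.1 K grid; with ΔCp > 0 its
interior maximum satisfies $\ln(T_m/T^*) = \Delta H/(T_m \Delta C_p)$, and
the grid answer is tested against that closed form. With ΔCp ≤ 0 the
maximum fields are NA with a warning.

The synthetic curve generators add Gaussian noise on the signal — matching
the least-squares error model — and are exact at zero noise, which is what
makes noiseless round trips a meaningful fitter test (recovery to ~4
significant figures). They do not emulate real-data pathologies such as
correlated drift, aggregation tails at high temperature, or incomplete
baselines, so passing round trips does not guarantee robustness to those.

## Hydrodynamics

Three analytic calculators: the empirical mass → Stokes-radius power law
$\log_{10} R_s[\text{Å}] = -0.254 + 0.369 \log_{10} MW[\text{Da}]$
(coefficients at their central values, uncertainties not propagated);
percent polydispersity as the mass-weighted coefficient of variation of a
size distribution; and the Svedberg ($M = s_0 R T / D_0 (1 - \bar v
\rho)$) and Stokes–Einstein ($R_s = k_B T / 6\pi\eta D_0$) conversions in
cgs units. For the truncated frataxin construct mass 11,923.2 Da the power
law gives 1.78 nm. For the full-length mass 13,605.1 Da direct evaluation
gives 1.87 nm, one hundredth above the 1.86 nm sometimes quoted for that
construct — possibly a rounding or a Met-cleaved-mass choice upstream; the
package reports the directly evaluated value.

## Known limitations

* The Gō model is topology-only: no sequence energetics, no non-native
  attraction, no solvent; temperatures are reduced and not mapped to
  Kelvin.
* The toy fold's weak cooperativity makes its Cv peak broad; Tm from the
  Cv argmax is meaningful only with adequate sampling (the annealed ladder
  protocol above).
* WHAM error bars are not computed (no autocorrelation analysis); the
  package reports point estimates and relies on the seeded protocol for
  reproducibility.
* The thermal and chemical estimates of ΔG need not agree for marginally
  stable constructs; the package reports both without reconciling them.
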