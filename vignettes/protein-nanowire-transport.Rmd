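---
title: "Methods: charge-transport analysis of conductive protein nanowires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: charge-transport analysis of conductive protein nanowires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piliwire)
```

## The problem

*Geobacter sulfurreducens* respires extracellular electron acceptors —
Fe(III) oxides, uranium, electrodes — through conductive type IV pili:
protein filaments a few nanometres wide and micrometres long, assembled
helically from a small pilin subunit.  Whether the protein fiber itself
carries respiratory current, and by what mechanism, is answered with
single-fiber electrical measurements and molecular models.  piliwire
implements the quantitative chain from those raw measurements to the
physical quantities the mechanistic argument rests on:

1. **Ohmic resistance** of a fiber from conductive-probe AFM (CP-AFM)
   current–voltage sweeps, and how it grows with probing distance.
2. **Conductivity, resistivity and electron transport rate**, under
   explicit fiber-diameter conventions.
3. **Space-charge-limited transport (SCLT)**: the ohmic-to-power-law
   crossover, carrier mobility and carrier concentration.
4. **Aromatic contacts** in fiber structural models — the putative
   hopping relays — under a carbon-pair distance criterion.
5. **STM spectroscopy**: differential conductance, band-gap detection and
   its temperature dependence, topographic periodicities, and
   tip-deconvolved diameter.
6. **Cofactor screening**: optical band signatures and elemental
   atoms-per-subunit stoichiometry, establishing that transport is not
   carried by metal or organic redox cofactors.

Every stage has a seeded synthetic-data generator with planted ground
truth, so the full chain is testable without instrument data.

## Ohmic fits and the distance law

A two-point CP-AFM sweep is fitted by ordinary least squares of current on
voltage inside a `|V| <= 0.6` V window, where single-fiber sweeps are
linear; the fiber resistance is the reciprocal slope.  The intercept is a
free parameter (it absorbs amplifier offset) rather than forcing the line
through the origin.  A non-positive slope — bare-substrate control sweeps —
is a flagged failure, not an exception, so batch processing survives
controls.

Resistance versus probing distance is fitted with two candidate laws:
linear `R(d) = R_c + s d` (an ohmic conductor in series with a contact
resistance `R_c`) and exponential `R(d) = A e^{kd}` (cumulative scattering
from charge traps).  The exponential fit is done by OLS on `ln R`, matching
the straight-line `R^2` reporting style of single-fiber work; both `R^2`
values are reported and the larger one selects the model, with ties going
to linear.  Non-positive resistances make the log fit undefined, so it is
skipped with a warning.  A negative fitted `R_c` is reported with a
warning, never clamped.

The along-fiber resistance of a length `L` is the slope times `L`; the
contact term can be included or excluded and both values are always
reported, since conventions differ on whether a quoted per-length
resistance contains the contact term.

## Diameter conventions and the geometry chain

Conductivity requires a cross-section, and pili have at least three
defensible diameters: the AFM height of the dried immobilized fiber
(2 nm), the solvated fiber core of molecular models (3.5 nm), and the
tip-deconvolved STM estimate including the C-terminal coil (4.7 nm).
`geometry_convention()` keeps these in a registry and every conductivity
or resistivity is labeled with its convention; `sigma = L/(R A)` with
`A = pi d^2/4`, and `rho = 1/sigma` exactly.  The electron transport rate
at bias `V` is `V/(R e)`; 100 mV is the default bias, the potential
available between the inner-membrane quinone pool and extracellular
Fe(III).  Rates are compared to the cellular Fe(III)-respiration rate in
`log10` orders of magnitude.

```{r geometry}
cond <- conductivity(7.3e8, 1000, geometry_convention("afm_height"))
unlist(cond[c("sigma_S_cm", "rho_ohm_cm")])
signif(electron_rate(7.3e8, 0.1), 3)
```

## The SCLT crossover and carrier characteristics

In thin wires, carrier depletion at the contact produces space-charge
limited injection above a crossover voltage `V_C`: the sweep turns from
`I ~ V` to `I = alpha V^b` with `b = 2` when trap-free and `b > 2` when
traps fill with injected charge.  `detect_crossover()` fits each polarity
on `(|V|, |I|)`: a grid search over candidate breakpoints (each sampled
voltage between the 20th and 90th percentile of `|V|`) combines a
through-origin line below with a log-log OLS power law above, minimizing
the summed current-space SSE.  The sweep is called crossover-free when the
single-line SSE is within 5% of the best two-segment SSE — an invented,
configurable tolerance; on a noisy but truly ohmic sweep the two-segment
model can still win this comparison by overfitting, but its exponent then
sits near 1 and `classify_transport()` places the curve back in the ohmic
class.  Classification uses an inclusive band `|b - 2| <= 0.25` for
trap-free SCLT.

Carrier mobility uses the thin-wire SCLT scaling `mu = alpha L G`.  The
geometric factor `G = 1/(2 pi eps0 eps_eff)` compresses the
wire-on-dielectric electrostatics into one effective permittivity;
`eps_eff = 15.3` is calibrated once so that a trap-free fiber probed at
1.6 um with `alpha = 1.7e-9 A/V^2` gives `mu = 3.2e-2 cm^2/Vs`, and the
same factor then reproduces the mutant-fiber mobility from its own
`(alpha, L)` without refitting.  Mobility *ratios* between fibers are
independent of `G` entirely, so the ~5x wild-type/mutant contrast is
calibration-free.  Carrier concentration is `n = sigma/(e mu)`; because
`sigma` carries a diameter convention, so does `n` (default
`solvated_core`), and with these conventions the result lands at the
`10^20 cm^-3` order.  The published concentrations were derived with
unpublished supplementary expressions, so order-of-magnitude agreement is
the intended check here, not digit-level reproduction.

## Aromatic contacts

Fast hopping requires aromatic side chains to approach each other; the
criterion implemented is *at least one carbon–carbon pair at 5 A or
less*, inclusive, regardless of ring orientation.  By default all carbon
atoms of the two residues enter the minimum (the literal reading);
`ring_only = TRUE` restricts to side-chain ring carbons.  Pairs within a
residue are excluded; no sequential-neighbor exclusion is applied.  The
census labels each pair intramolecular or intermolecular by chain
equality, and attributes contacts to subunits with a declared convention:
an intermolecular contact increments both subunits, an intramolecular one
its own subunit once.  Mean contacts per subunit per frame is then the
per-pilin statistic used to compare wild-type-like and
aromatic-deficient fibers.

The aromatic density map counts aromatic-residue atoms on a regular grid
(bounding box of the first frame padded by 2 A; atoms leaving the box in
later frames are dropped with a counted warning) and averages over
frames; `slice_density()` extracts planes at fractional offsets (defaults
0.30/0.50/0.70 of the box along the normal axis) for visual comparison of
aromatic distributions.

The synthetic fiber generator builds helical fibers whose aromatic side
chains are 6-carbon planar hexagons (1.4 A bond length) — the minimal
geometry that exercises a carbon-pair criterion.  `remove_ring_at`
replaces a residue's ring with a lone beta-carbon in every subunit,
emulating an aromatic-to-alanine mutation; deleting carbons can only
remove minima, so contact counts are provably non-increasing under this
operation, and the test suite asserts it against brute force.

## STM spectra and topography

Replicate tunneling sweeps are averaged pointwise (resampled by linear
interpolation onto the common grid when necessary).  dI/dV is computed by
Savitzky–Golay smoothing-differentiation (default window 9 points, order
2) on the uniform voltage grid; the filter half-width is trimmed from each
edge and recorded.  The raw current noise (estimated robustly from second
differences, which cancel the smooth signal) is propagated through the
known derivative kernel, giving an analytic dI/dV noise level — the
smoothed derivative itself is serially correlated, so estimating its noise
from the curve would bias the threshold.

A band gap is the largest contiguous interval with `|dI/dV|` at the noise
floor.  The auto threshold is 3x that propagated noise level, floored at
0.5% of the maximum `|dI/dV|` so noiseless spectra keep a usable
threshold; both terms scale with the data, making detection invariant
under current rescaling.  Two numerical details matter: noise exceedances
inside a gap arrive in clumps as wide as the filter window (correlated
smoothing), so above-threshold interruptions shorter than the window are
bridged; and a derivative filter of half-width `k` can only read zero
slope `k` samples inside a flat plateau, so the threshold-crossing edges
are expanded outward by the half-width.  With both corrections the
planted-gap recovery error stays within two grid steps across widths of
0.1–1.0 V at the calibrated noise.  Gaps below 50 mV are not reported
(single-point dropouts), sub-volt gaps classify as `gapped_conducting`
(the cryogenic redox-conductor signature), and gaps of a volt or more as
`insulating`.  `thermal_voltage()` supplies the `k_B T/e` scale (25 mV at
room temperature) against which a hundreds-of-millivolt gap is argued to
be thermally surmountable only at room temperature.

Topographic periodicity uses the autocorrelation of mean-subtracted
heights; local maxima above a normalized-autocorrelation threshold
(default 0.2) are reported as periods.  Mean subtraction makes the result
offset-invariant; harmonics of a strong fundamental do appear and are left
to the caller, since the fiber-relevant question is whether specific
periods (3–4 nm substructure, 14 nm repeat) are present.  Tip
deconvolution uses the spherical-tip/cylindrical-feature contact model
`W = 4 sqrt(R_tip r)`, inverted as `r = (W/4)^2/R_tip`; the exact
extrapolation used in the original supplementary material is unpublished,
so the contract here is the forward/inverse pair of a declared model, and
the 4–5 nm diameter band from an 8 nm apparent width is a consistency
check, not a reproduction.

## Cofactor screening

Peak detection uses topographic prominence (default 5% of the signal
range).  The band table encodes: tyrosine absorption ~270 nm or emission
~300 nm; tyrosinate emission ~340 nm; flavin absorption at ~360 *and*
~450 nm; oxidized c-type heme at 406 (Soret) *and* 528 nm.  Flavin and
heme require all their bands because the scientific claim is an absence
argument — a single coincidental band must not raise the flag.  The
quinone/flavin emission window is a configuration entry (default
400–550 nm) since its published bounds are in unpublished supplementary
material.  Band tolerance is ±10 nm, reflecting the "~" precision of the
quoted centers.  Flag assignment is monotone: adding peaks can only turn
flags on.

Elemental stoichiometry converts concentrations to a molar ratio:
`atoms/subunit = (ppm/M_element)/(protein/M_pilin)` with the pilin mass
6,568.51 Da (1.09e-14 ug).  Replicate ppm values propagate their standard
deviation linearly.  The conversion is dilution-invariant by construction.

## Synthetic-data conditions

The generators default to the measurement conditions of the study design
they emulate: ±1 V sweeps with 201 points; fiber resistances near
0.7–1 GOhm (wild-type-like) and 4 GOhm (mutant-like); distance series
spanning 50–950 nm; SCLT curves with `V_C = 0.5 V` and `b = 2` or 2.5;
STM gaps from hundreds of millivolts (cryogenic) to ~4 V
(insulator-like); topography with 3.5 and 14 nm periods.  The paper-scale
noise magnitudes of raw curves are not published; current noise is
calibrated with `iv_noise_for_r2()` so that in-window ohmic fits land in
the `R^2 = 0.98–0.99` band reported for the real sweeps, and 5e-12 A is
used where a visibly clean curve is wanted.  Noise is additive i.i.d.
Gaussian on current/height/signal — the simplest model consistent with
the scatter of the published fits; heavier-tailed noise is out of scope.
Synthetic SCLT curves are antisymmetric in V (single-polarity fits in the
source data make symmetry the neutral default).  All seeds are explicit
arguments; generators restore the caller's RNG state.

What the generators do *not* emulate: instrument drift, correlated (1/f)
noise, tip degradation, baseline slopes in optical spectra, and real MD
conformational dynamics (frames are i.i.d. jittered copies of one
geometry, with no force field, solvent or electrostatics).  Passing
round-trip tests therefore demonstrates correctness of the estimators
under the stated noise model, not robustness to every artifact of real
instrument data.

## Problem sizes and numerical choices

The test and acceptance workloads use desk-scale sizes chosen to exercise
every code path while keeping the whole suite fast: 100–201-point sweeps,
up to 200 seeded regression replicates, 100 seeded SCLT curves and 100
seeded gap fixtures, fibers of up to 8 subunits (~200 atoms) so the
brute-force contact oracle stays exact and cheap.  Physical constants are
CODATA 2018 fixed values.  Reported quantities are kept at full precision
internally; rounding to the printed precision (2 significant figures for
conductivities, 1 for the electron rate) happens only at the reporting
boundary.

## Known limitations

- The SCLT geometric factor is an effective-medium calibration, not a
  first-principles electrostatic solution for a wire on a dielectric
  substrate; absolute mobilities inherit it, ratios do not.
- Carrier concentrations reproduce the published values only to order of
  magnitude (see above).
- The crossover search assumes a single breakpoint per polarity.
- Contact statistics use no periodic boundary conditions (fibers are
  finite objects here; simulation boxes are out of scope).
- The per-pilin contact attribution is a declared convention; other
  conventions shift per-subunit means by bounded factors.
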