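---
title: "Methods: acid-base, CD and conformational analysis of polyamidoamino acids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: acid-base, CD and conformational analysis of polyamidoamino acids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paac)
```

## The system

Polyamidoamino acids (PAACs) are obtained by Michael-type polyaddition of an
alpha-amino acid with N,N'-methylenebisacrylamide. The amino acid's primary
amine becomes a tertiary amine in the main chain while its carboxyl group is
untouched, so every repeat unit carries one weakly acidic carboxyl and one
weakly basic tertiary amine: the polymer is an amphoteric polyelectrolyte.
Three homologues are built in (`default_polymer()`): the alanine-, valine-
and leucine-derived polymers, with repeat-unit masses 243.26, 271.32 and
285.34 g/mol (bisacrylamide 154.17 g/mol plus the residue).

Three experimental observables are modelled:

1. **Potentiometric titration.** Forward titration with NaOH from an
   acid-adjusted start crosses two buffering regions (carboxyl, then amine).
2. **Circular dichroism.** The polymers structure in water in a pH-dependent
   way; the differential molar ellipticity against a pH-3 reference follows
   a sigmoid in pH whose inflection sits at the amine half-ionization point.
3. **Chain conformation.** Descriptors of ten-repeat-unit oligomer
   geometries: end-to-end distance, radius of gyration, solvent-accessible
   surface area, dipole moment, and backbone torsion statistics.

## Ionization model

A single titratable group on a polyelectrolyte has an *apparent* pKa that
depends on its degree of dissociation $\alpha$. The plain
Henderson–Hasselbalch relation

$$\mathrm{pH} = pK_a - \log_{10}\frac{1-\alpha}{\alpha}$$

is inverted point-by-point by `apparent_pka()`. Away from $\alpha = 0.5$
polyelectrolytes follow the modified (Katchalsky–Spitnik) form

$$\mathrm{pH} = pK_a - \beta\,\log_{10}\frac{1-\alpha}{\alpha},$$

where $\beta$ absorbs interactions between neighbouring ionizable units;
$\beta = 1$ recovers the monomer-like case. `fit_katchalsky_spitnik()`
estimates $(pK_a, \beta)$ by ordinary least squares of pH on
$x = \log_{10}((1-\alpha)/\alpha)$; the intercept is the pKa and the slope
$-\beta$.

**Alpha window.** The regression is restricted to $\alpha \in [0.2, 0.8]$ by
default. The linearisation degenerates at the extremes ($x \to \pm\infty$),
and for this polymer family the carboxyl equilibrium is known to change
regime above $\alpha \approx 0.8$; the window is configurable.

**From curve to alpha.** `compute_alpha()` locates the two equivalence
volumes as maxima of the centred-difference derivative $d\mathrm{pH}/dV$
after 5-point moving-average smoothing (a Gran-plot extrapolation is the
fallback when a derivative peak is not resolved). Within each region the
degree of dissociation is the proton-balance-corrected titrant count

$$\alpha(V) = \frac{Q(V) - Q(V_{e1})}{n_{RU}} + c, \qquad
Q(V) = C\,V + \left([\mathrm{H^+}] - [\mathrm{OH^-}]\right)(V_0 + V),$$

with $c = 1$ in the carboxyl region (which ends at the first equivalence
volume $V_{e1}$) and $c = 0$ in the amine region. The free-proton term
matters here: with a carboxyl pKa near 2.3 the free acid at the bottom of
the curve is of the same order as 10% of the repeat units, and an
uncorrected titrant count would shift the inferred pKa by more than the
reading noise. Alphas are clamped to $(\epsilon, 1-\epsilon)$ with
$\epsilon = 0.01$ before any log transform.

**Half-neutralization.** `half_neutralization_ph()` returns the pH at
$\alpha = 0.5$, which equals the apparent pKa. When at least five points
fall in $\alpha \in [0.35, 0.65]$ it uses the intercept of the local
Katchalsky–Spitnik regression (under that model the intercept *is* the
half-neutralization pH, and the regression averages out reading noise);
with sparser data it falls back to linear interpolation.

**Speciation.** With the two groups parameterised as above,

$$f_{\mathrm{COO^-}} = \frac{1}{1 + 10^{(pK_{a1}-\mathrm{pH})/\beta_1}},
\qquad
f_{\mathrm{NH^+}} = \frac{1}{1 + 10^{(\mathrm{pH}-pK_{a2})/\beta_2}},$$

and `speciation()` forms the four repeat-unit microstates as products
(cationic COOH/NH⁺, zwitterionic COO⁻/NH⁺, uncharged COOH/NH, anionic
COO⁻/NH), assuming site independence — the $\beta$ exponents already carry
the nearest-neighbour coupling, and adding an explicit interaction term
would double-count it. Because $pK_{a1} \ll pK_{a2}$ the uncharged
microstate is numerically negligible, but it is kept so the four fractions
sum to one exactly; `net_neutral` lumps it with the zwitterion to give the
conventional three-state picture. The mean charge per repeat unit is
$f_{\mathrm{NH^+}} - f_{\mathrm{COO^-}}$, and `isoelectric_point()` locates
its root on (0, 14) with Brent's method at a 1e-6 pH tolerance.

## CD analysis

Raw ellipticities (mdeg) are divided by repeat-unit molar concentration and
path length (`to_molar_ellipticity()`, units mdeg M⁻¹ cm⁻¹); the molar
concentration follows from mass concentration over repeat-unit mass
(`repeat_unit_concentration()`, e.g. 0.5 mg/mL of the valine polymer is
1.843 mM). `differential_series()` subtracts the spectrum closest to pH 3
(required within ±0.2 pH, reflecting realistic pH-adjustment scatter),
evaluated at a fixed wavelength — by default each polymer's positive-band
maximum (228, 234, 231 nm for the three homologues) — or at the
per-spectrum detected peak.

`fit_sigmoid()` fits the 4-parameter base-10 logistic

$$\Delta\theta(\mathrm{pH}) = L + \frac{U - L}
{1 + 10^{\,m\,(\mathrm{pH}_{50} - \mathrm{pH})}}.$$

This functional form is chosen because it corresponds exactly to the
ionization model: if the structuring amplitude is proportional to the amine
deprotonation fraction, the differential series is this logistic with
$\mathrm{pH}_{50} = pK_{a2}$ and $m = 1/\beta_2$, so the fitted inflection
*is* the amine half-ionization pH with no approximation. The slope is left
free rather than tied to $\beta_2$, so the correspondence is a result, not
an assumption. Initialisation: plateaus from the 5th/95th percentiles,
$\mathrm{pH}_{50}$ from the mid-amplitude crossing, and a multi-start over
slopes $m_0 \in \{0.5, 1, 2\}$ with the lowest residual sum of squares
winning; the optimiser is Levenberg–Marquardt (`minpack.lm`). A constant
series raises a zero-amplitude error rather than returning an arbitrary
inflection. Plateau pH ranges are reported as the regions where
$|\Delta\theta - \text{plateau}| < 5\%$ of the fitted amplitude — the 5% is
a reporting convention, not part of the fit.

## Chain descriptors

`conformer()` carries elements, coordinates (Å), optional charges, Bondi
van der Waals radii and standard atomic masses (both overridable), and an
ordered backbone index. Structures load from PDB (via `bio3d`) or extended
XYZ with an optional per-atom charge column.

* `end_to_end()` — distance between the terminal backbone atoms, nm.
* `radius_of_gyration()` — mass-weighted by default, nm.
* `dipole_moment()` — $|\sum_i q_i (r_i - r_0)|$, converted at
  4.8032 D per e·Å. For net-neutral systems the value is
  origin-independent; for charged states the origin convention (centre of
  charge by default) is attached to the result, because quoting a dipole
  for an ion without its origin is meaningless.
* `sasa()` — Shrake–Rupley with a *deterministic* Fibonacci-lattice point
  set (960 points per atom by default; the 960 → 3840 refinement changes
  fixtures by under 0.5%), probe radius 0.14 nm (a water molecule).
  Exact duplicate atoms are collapsed first so they cannot double-count.
* `backbone_torsions()` — signed dihedrals in (−180°, 180°] for each four
  consecutive backbone atoms, following the right-handed convention used by
  `bio3d`; collinear triples yield `NA` rather than an arbitrary value.
* `transoid_fraction()` — share of torsions with $|\phi| \ge 150°$. The
  threshold splits the extended, hairpin-strand-like arrangements peaked at
  ±180° from turn conformations in the ±60–120° range; 150° is the midpoint
  gap between those two populations.

**Chain building.** `build_extended_chain()` generates the idealised
all-trans oligomer from internal coordinates by the natural-extension
reference frame construction. The 10-atom backbone repeat
N–C–C–C(O)–N–C–N–C(O)–C–C uses standard bond lengths (C–C 1.53 Å, C–N
1.47 Å, amide C–N 1.33 Å) and angles (tetrahedral 109.5°, trigonal 120°).
Side groups are coarse-grained: carbonyl oxygens plus one pseudo-atom per
repeat on the amine nitrogen standing in for the CH(R)COOH moiety — the
backbone dominates every descriptor of interest here, and full side-chain
geometry would require a force field, which is out of scope. Note that the
all-trans 10-mer built this way is an *idealised* elongated geometry;
software-built "fully elongated" starting structures in molecular modelling
typically measure somewhat shorter, so absolute end-to-end values should
not be compared across conventions.

## The synthetic generator

There are no deposited instrument data for these polymers, so the
generator produces inputs with the statistical structure the analysis
assumes; its defaults are the study conditions.

* `simulate_titration()` inverts the vessel's charge balance: at each pH on
  a grid (default 1.7–11.8, step 0.05) the added NaOH volume solves
  $n_{Na} + n_{H^+} + n_{RU} f_{\mathrm{NH^+}} = n_{Cl} + n_{OH^-} +
  n_{RU} f_{\mathrm{COO^-}}$ exactly (dilution included, $K_w = 10^{-14}$ at
  25 °C, activity coefficients unity — the experiments run at 0.1 M NaCl and
  no activity correction is invoked anywhere in the analysis). Defaults:
  0.05 M repeat units, 0.1 M titrant, start pre-adjusted to pH 1.7 by a
  strong-acid excess solved from the same balance. Noise is Gaussian on the
  pH readings (σ = 0.02 pH for "realistic" runs), volumes stay exact —
  burettes are far more precise than electrodes.
* `simulate_cd_series()` emits Gaussian bands: a positive band whose
  amplitude is proportional to the amine deprotonation fraction
  $1 - f_{\mathrm{NH^+}}$ (the structuring driver), and a weaker negative
  band at lower wavelength whose centre blue-shifts linearly below pH 5
  (2 nm per pH unit by default). Band centres use the per-polymer positive
  maxima; widths (10 and 8 nm) and the amplitude ratio are plausible band
  shapes, not measured values. The amplitude-to-deprotonation coupling is to
  the amine fraction, not to net charge, because the amine protonation state
  is the factor governing structuring. Noise is Gaussian on ellipticity,
  2% of the positive amplitude in the standard runs. Spectra are emitted in
  raw mdeg (the normalisation inverted), so the analysis path exercises the
  same steps an instrument file would.
* `make_coil()` redraws the backbone torsions of the extended chain from a
  mixture — 70% near-trans (|φ| = 180° − |N(0, 8°)|, random sign), 30% turn
  (uniform ±60–120°) — and rejects conformations with non-bonded backbone
  atoms closer than 2 Å. This emulates the hairpin-like folds' torsion
  statistics by construction; it is a geometric stand-in, not an energy
  model.

Every generator is deterministic given its seed, and regeneration is
bit-identical; the RNG state of the caller is left untouched.

**What passing tests do and do not show.** The generators share their
ionization model with the analysis (that is what makes exact round trips
possible), so recovery tests validate the inference machinery — equivalence
detection, proton-balance correction, regression, sigmoid fitting — under
known truth and realistic noise, not the physics of real PAAC solutions.
Real titrations add electrode drift, carbonate uptake and activity effects;
real CD spectra have non-Gaussian bands and baseline error; real coil
ensembles are Boltzmann-weighted. None of those are modelled.

## Problem sizes and numerics

The standard analyses run at desk scale: titration grids of ~200 points,
CD series of 33–41 pH values on a 1-nm wavelength grid, ten-repeat-unit
oligomers (~130 atoms with side pseudo-atoms), 960 SASA points per atom,
and 10–20 seeded replicates in the recovery studies. The sigmoid fit
tolerances are those of `minpack.lm` at its defaults (up to 200
iterations); the isoelectric root is bracketed on (0, 14) and solved to
1e-6 pH; alpha clamping at 0.01 bounds every log transform.

## Known limitations

* pKa1, β1 and the per-polymer β2 defaults are working fixture values for
  simulation; only the amine pKa2 values (8.1, 6.8, 7.3) and the band
  maxima are anchored to measurements of the real polymers.
* `compute_alpha()` assumes the two buffering regions are separable
  (pKa1 ≪ pKa2); strongly overlapping regions would need a global fit.
* Speciation is a two-site mean-field model; it cannot express microstate
  cooperativity beyond what β absorbs.
* The chain module computes descriptors of supplied or constructed
  geometries; it performs no dynamics, minimisation or solvation, so its
  outputs are compared as orderings and magnitudes, not as predictions of
  force-field values.
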