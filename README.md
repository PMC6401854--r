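# paac

Acid-base, circular-dichroism and conformational analysis of amphoteric
polyamidoamino acid (PAAC) polymers.

PAACs arise from Michael-type polyaddition of an alpha-amino acid with
N,N'-methylenebisacrylamide: every repeat unit keeps the amino acid's
carboxyl group and gains a tertiary amine, so the polymer is an amphoteric
polyelectrolyte whose charge state, solution structuring and chain
conformation are all driven by pH. This package provides the analysis
chain a solution physico-chemist needs to characterise such polymers:

* **Titration analysis** — degrees of dissociation from potentiometric
  curves (equivalence location by derivative maxima with a Gran-plot
  fallback, proton-balance-corrected titrant counts), apparent pKa via the
  Henderson–Hasselbalch relation
  `pH = pKa − log10((1−α)/α)`, and the Katchalsky–Spitnik cooperativity
  parameter β from its modified form
  `pH = pKa − β·log10((1−α)/α)` by linear regression.
* **Speciation** — pH-resolved fractions of the four repeat-unit
  microstates (cationic, zwitterionic, uncharged, anionic) from
  `(pKa1, β1, pKa2, β2)`, net charge per repeat unit, and the isoelectric
  point.
* **CD spectroscopy** — normalisation of raw mdeg spectra to repeat-unit
  molar ellipticity, differential series against a pH-3 reference, band
  peak extraction, and a 4-parameter logistic fit of the structuring
  transition `Δθ(pH) = L + (U−L)/(1 + 10^{m(pH₅₀−pH)})`, whose inflection
  pH₅₀ equals the amine half-ionization point when structuring tracks amine
  deprotonation.
* **Chain descriptors** — end-to-end distance, radius of gyration,
  Shrake–Rupley solvent-accessible surface area (0.14 nm probe,
  deterministic point set), dipole moment, backbone torsions and the
  transoid fraction, for structures from PDB/XYZ files or from the built-in
  internal-coordinate chain builder (all-trans extended chains and seeded
  random coils of the 10-atom PAAC backbone repeat).
* **Synthetic data** — titration curves by exact electroneutrality
  inversion, CD pH series coupled to amine deprotonation, and coil
  conformers, so every analysis can be exercised end-to-end with known
  ground truth.

## Worked example

Simulate the valine-derived polymer's forward titration and CD pH series,
then recover its acid-base constants and structuring transition:

```r
library(paac)
pol <- default_polymer("M-l-Val")   # pKa2 = 6.8, repeat unit 271.32 g/mol

## titration: 0.05 M repeat units, 0.1 M NaOH, 0.02 pH reading noise
proto <- titration_protocol(sample_conc = 0.05, ph_noise_sd = 0.02, seed = 1)
curve <- simulate_titration(pol, proto)
alpha <- compute_alpha(curve, pol)
half_neutralization_ph(alpha$carboxyl)   # 2.308  (apparent pKa1)
half_neutralization_ph(alpha$amine)      # 6.809  (apparent pKa2)
fit_katchalsky_spitnik(alpha$amine)
#> <ks_fit> pKa = 6.8150, beta = 1.1949 (R^2 = 0.99822, n = 29)
isoelectric_point(pol)                   # 4.100

## CD: 2% noise, differential vs pH 3 at the 234 nm band maximum
raw  <- simulate_cd_series(pol, cd_series_params(noise_sd = 0.02, seed = 1,
                                                 pos_center = 234))
norm <- lapply(raw, to_molar_ellipticity, pol$repeat_unit_mass)
fit_sigmoid(differential_series(norm, ref_ph = 3, wavelength = 234))
#> <sigmoid_fit> inflection pH 6.786, slope 0.774
#>   plateaus: 13.9 -> 1027.0 (RSS 1.25e+04, n = 33)
```

The titration recovers the generating pKa values (2.3 and 6.8) and β
(1.20); the CD sigmoid's inflection (6.786) lands on the amine
half-ionization pH within the reading noise — the central correspondence
this package quantifies.

Chain descriptors of the idealised extended 10-mer versus a seeded coil:

```r
describe_conformer(build_extended_chain(10))
#> <descriptor_set> Ree 12.096 nm, Rg 3.539 nm, SASA 32.61 nm^2
#>   97 torsions, transoid fraction 1.00
describe_conformer(make_coil(10, seed = 1))
#> <descriptor_set> Ree 7.665 nm, Rg 2.523 nm, SASA 32.04 nm^2
#>   97 torsions, transoid fraction 0.68
```

A YAML-driven pipeline (`run_pipeline()`, or the `inst/scripts/paac`
command-line wrapper) chains the stages and writes tidy CSV/JSON outputs
stamped with a configuration hash; see
`inst/extdata/example_config.yaml` and the methods vignette
(`vignettes/paac-methods.Rmd`) for the model details and design choices.

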