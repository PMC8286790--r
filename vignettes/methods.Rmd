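---
title: "Counting peptides per bacterium by SPR: models and assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting peptides per bacterium by SPR: models and assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sprcoat)
```

## The problem

Live bacterial vectors such as BCG (Bacillus Calmette-Guerin) can be coated
with tumour-antigen peptides carrying a cationic anchor (a hexalysine tail or
an HIV Tat-derived cell-penetrating peptide) that adsorbs to the negatively
charged mycobacterial outer membrane.  A key quality attribute of such a
vaccine platform is the *surface density of the cargo*: how many peptide
molecules ride on each bacterium.  `sprcoat` estimates this number from
label-free multi-parametric surface plasmon resonance (SPR) measurements in
which bacteria are first immobilized on the sensor and the peptide is then
flowed over them, with an uncoated reference channel run in parallel.

The estimate composes four models, each implemented and tested as a separate
module.

## 1. Optical model of the sensor

The sensor is a Kretschmann stack: coupling prism, thin metal film (with a
chromium adhesion layer), a silica top coat, and the aqueous running buffer.
For p-polarized light of vacuum wavelength $\lambda$ incident at internal
angle $\theta$, the reflectance of the stratified stack is computed with the
characteristic (transfer) matrix method.  Each interior layer $j$ of
thickness $d_j$ and complex index $n_j$ contributes

$$
M_j = \begin{pmatrix}
\cos\delta_j & -\tfrac{i}{q_j}\sin\delta_j\\
-i q_j \sin\delta_j & \cos\delta_j
\end{pmatrix},
\qquad
\delta_j = k_{z,j} d_j,\quad
q_j = k_{z,j}/n_j^2,
$$

with $k_{z,j} = \sqrt{k_0^2 n_j^2 - k_x^2}$ on the decaying branch
($\mathrm{Im}\,k_z \ge 0$; time convention $e^{-i\omega t}$, extinction as a
positive imaginary index part).  The reflectance $|r_p|^2$ shows the surface
plasmon resonance as a sharp dip; the dip angle is refined below the grid
spacing by parabolic interpolation through the minimum sample and its two
neighbours, with ties broken toward the lower angle.  The *angular response*
of an adsorbed layer is the dip shift it causes.  The test suite checks the
transfer matrix against an independently coded Parratt recursive-Fresnel
oracle to $10^{-10}$ on randomized stacks, the thin-film linear regime, the
saturation regime, and the exact zero cases (zero thickness, index-matched
layer — these short-circuit to exactly zero by construction).

### The default stack and its calibration

The exact layer recipe of the commercial Au-SiO2 slide is proprietary, so the
package ships a documented stand-in: BK7 prism ($n = 1.5151$ at 670 nm),
2 nm Cr ($3.0 + 3.5i$), 50 nm Au, 15 nm SiO2 ($n = 1.456$), PBS ambient
($n = 1.335$).  Published optical constants for gold at 670 nm vary
substantially between sources ($k \approx 3.4$–$3.8$); within that spread the
gold extinction was fixed once at $k = 3.515$ so that the reference
full-monolayer slab (next section) produces the instrument-modelled maximum
response of 2.28 degrees (the model gives 2.2785, i.e. 2.28 at printed
precision).  This is a one-time calibration of an underdetermined stack
constant against the published model output, not a tunable fit; every
constant remains overridable through `bcg_sensor_stack()` arguments or a
stack JSON file (`inst/extdata/bcg_sensor.json`).

## 2. Geometric model of the particle monolayer

A BCG bacillus of average length 2.36 um and width 0.47 um is represented by
the equal-volume sphere.  The canonical single-cell volume is taken directly
as 0.3887 um^3, giving an equivalent diameter

$$ d = \left(\frac{6V}{\pi}\right)^{1/3} = 905.5\ \mathrm{nm}. $$

None of the three standard rod idealizations reproduces 0.3887 exactly
(cylinder 0.409, spherocylinder 0.382, ellipsoid 0.273 um^3), so the volume
is treated as a direct input; `rod_volume()` provides the three shape models
for forward use.

A *full* monolayer is assumed hexagonally packed, occupying a fraction 0.74
of the sensor plane.  (0.74 is the 3-D close-packing fraction; 2-D hexagonal
disc packing would give 0.907.  The published procedure uses 0.74 and the
package follows it verbatim; both constants are configurable through
`packing_parameters()`.)  For the optical model, which assumes a homogeneous
slab, the packed spheres are collapsed by the volume fill factor 0.524
($\approx \pi/6$, the sphere-to-circumscribing-cube volume ratio):

$$ t_\mathrm{eff} = d \times 0.74 \times 0.524 = 351.1\ \mathrm{nm}. $$

With the particle index 1.35 this slab yields the maximum monolayer response
$R_\mathrm{max}^\mathrm{mono} = 2.28^\circ$ used as the coverage
denominator.  Each particle occupies a projected footprint
$\pi (d/2)^2 \approx 643{,}971$ nm^2.

## 3. The quantification chain

For each peptide, with the measured immobilization plateau $R_\mathrm{imm}$
and the reference-corrected peptide-binding plateau $R_\mathrm{bind}$ (both
in degrees):

1. coverage fraction $c = R_\mathrm{imm} / R_\mathrm{max}^\mathrm{mono}$
   (values above 1 violate the monolayer model and raise an error);
2. particle count $N_p = c \, A_\mathrm{spot} / A_\mathrm{footprint}$, with
   the detection spot a 1 mm diameter circle set by the instrument laser;
3. mass surface density $\Gamma = k \, R_\mathrm{bind}$ with
   $k = 600\ \mathrm{ng/cm^2}$ per degree, the standard proteinaceous-layer
   conversion for this instrument class (configurable; a de Feijter-style
   refractive-index-increment route would be a possible extension but is
   deliberately not implemented);
4. total mass $m = \Gamma A_\mathrm{spot}$;
5. molecule count $N = (m / M_w) N_A$ with the exact 2019 SI Avogadro
   constant;
6. molecules per particle $N / N_p$.

`run_chain()` executes the six steps and reports every intermediate;
`run_quantification()` does so for a whole configuration.  Counts are
carried at full precision and additionally reported as integers rounded
half-away-from-zero; rounding happens only at report time.

With the shipped three-peptide configuration the chain lands on
approximately $3.2\times10^5$ (6K-AH1), $4.4\times10^6$ (6K-TRP2) and
$1.8\times10^6$ (CPP-SIINFEKL) molecules per bacterium.  One comparison
subtlety is documented in the acceptance tests: the published per-bacterium
figure for CPP-SIINFEKL descends from an already-rounded molecule count
($2.4\times10^{11}$); the unrounded chain gives $1.75\times10^6$, which
agrees with the published figure at its two-significant-figure precision but
not within 2%.  The package reports the unrounded value.

## 4. Sensorgrams and the synthetic-data generator

Plateau extraction from a sensorgram is the mean over a user-chosen late
association window (default: the last quarter of the record), reported with
its standard deviation — the simplest defensible estimator, and explicit in
the report.  Whether a record was reference-corrected is recorded, since the
published procedure does not state it; both corrected and raw entry paths
are supported.

The generator emulates the assay design: a 12 min analyte injection followed
by a 3 min buffer wash at 100 uM analyte, two channels (active = Langmuir
1:1 binding + bulk refractive-index step; reference = bulk step only),
additive i.i.d. Gaussian noise (default 2% of $R_\mathrm{max}$), optional
linear drift, and a single seed governing all randomness with the global RNG
state restored on exit.  The Langmuir model is
$dR/dt = k_\mathrm{on} C (R_\mathrm{max} - R) - k_\mathrm{off} R$ with the
closed-form exponential phases; defaults $k_\mathrm{on} = 10^4$ /M/s,
$k_\mathrm{off} = 10^{-3}$ /s, $R_\mathrm{max} = 0.6^\circ$ put the
association half-time near 7 s and the plateau near the magnitude of the
measured peptide responses, typical of peptide-on-cell-surface interactions.

What the generator does *not* emulate: mass-transport limitation,
heterogeneous or bivalent binding, baseline jumps, spikes, or non-Gaussian
instrument noise.  A green parameter-recovery test therefore establishes
correctness of the estimator under the stated noise model, not robustness to
real-instrument artefacts.  `fit_langmuir()` exists to close this loop
(recovery within 5% median relative error at 2% noise); it performs no
affinity analysis of the single-concentration assay data, which would be
underdetermined.

## Numerical choices

* Angle scans default to 55–78 degrees at 0.005 degree steps, bracketing the
  dip for aqueous ambient on BK7; the dip must be an interior sample or an
  error asks for a wider range.
* Reflectance is clamped to [0, 1] against floating-point excursions at the
  last bit.
* The Langmuir fit works on log-scale rate constants, seeded from the tail
  decay and the plateau, Nelder-Mead followed by BFGS; a fitted amplitude
  below three residual standard deviations is flagged `low_signal`.
* Reports are byte-deterministic for a fixed configuration and seed; the
  configuration echo in `report.json` omits only the absolute config path.

## Known limitations

* The stand-in sensor stack reproduces the published monolayer response but
  is not the vendor's layer recipe; absolute dip positions (not shifts) may
  differ from the instrument.
* The monolayer model caps coverage at 100%; multilayer adsorption or
  aggregation on the sensor violates it and is reported as an error, not
  corrected for.
* The 600 ng/cm^2/degree mass conversion is treated as an instrument
  constant; its provenance (calibration vs literature) is not modelled.
* Particle size is monodisperse; no polydispersity or random-sequential
  adsorption coverage models.
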