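---
title: "Extracting complex refractive index spectra from uncollimated ATR-FTIR measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting complex refractive index spectra from uncollimated ATR-FTIR measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atrindex)
```

## The problem

Mid-infrared (2–15 µm) evanescent sensors for label-free clinical
diagnostics need the complex refractive index $n(\lambda) + ik(\lambda)$ of
the aqueous media they will probe: the evanescent penetration depth, and
therefore the device sensitivity, depends strongly on both components.
Transmission spectroscopy gives $k$ directly through the Beer–Lambert law,

$$k(\lambda) = \frac{\lambda\, a(\lambda)}{4 \pi d \,\log_{10} e},$$

with decadic absorbance $a = -\log_{10}(I/I_0)$ and path length $d$.  In an
attenuated-total-reflection (ATR) measurement there is no geometric path
length: the light samples the medium through an evanescent tail whose
effective thickness depends on wavelength, polarisation, the crystal and
sample indices, and — critically — the angle of incidence.  A benchtop FTIR
spectrometer delivers an *uncollimated, unpolarised* beam to the ATR
accessory, so the textbook single-angle (Harrick) effective-thickness model
cannot be evaluated: the angular distribution is unknown.

`atrindex` implements the empirical alternative: **calibrate the effective
path against water**.  Water's optical constants are known to high accuracy
from the literature, so measuring a pure-water absorbance $a_w$ on the same
element and inverting the Beer–Lambert relation for $d$ gives

$$d_{\mathrm{eff}}(\lambda) = \frac{\lambda\, a_w(\lambda)}
{4 \pi k_{\mathrm{ref}}(\lambda) \log_{10} e},$$

a single wavelength-dependent curve that absorbs the unknown angular
spread, polarisation mix, crystal dispersion and reflection count at once.
Any aqueous sample measured under the same conditions then yields
$k = \lambda a / (4\pi d_{\mathrm{eff}} \log_{10} e)$, valid as long as the
sample's index stays close to water's — which holds for blood, buffers and
dilute solutions, all dominated by their water content.

$d_{\mathrm{eff}}$ is stored as the *total* path over all $N$ reflections
(it scales down by $N$ for a single-reflection element).  Below 2.7 µm both
$a_w$ and $k_{\mathrm{ref}}$ are nearly zero and their ratio is noise, so
those points carry an explicit invalid flag; the flag propagates through
every later stage and masked values are never silently replaced by computed
numbers.

## Recovering the real part: Kramers–Kronig with extrapolation

Causality links the real and imaginary parts of any linear response
$\chi(\omega) = \chi_1(\omega) + i\chi_2(\omega)$ through the
principal-value pair

$$\chi_1(\omega) = \frac{1}{\pi}\, P \int_{-\infty}^{\infty}
\frac{\chi_2(\omega')}{\omega' - \omega}\, d\omega',$$

which for the refractive index (using the odd symmetry of $\chi_2$) becomes
the positive-frequency transform of $k$ into $n$ up to an additive
constant.  Numerically we use **Maclaurin's formula**: on an evenly spaced
frequency grid the integrand is summed at the grid points of *opposite
parity* to the evaluation point, with step $2h$, so the singular point is
never touched.  The scheme is robust for band-limited input and is linear,
which several tests exploit directly.  (An FFT-based Hilbert transform
would be faster but behaves worse at band edges; with the grid sizes used
here — a few thousand points — the $O(N^2)$ sum runs in about a second.)

Two practical obstacles and their treatment:

* **Band limitation.**  The integral formally needs $k$ at all
  frequencies.  Above the measured band (wavelengths below 1.67 µm) water
  and its solutes are featureless, so $k$ is padded with zeros up to twice
  the maximum measured wavenumber; this changes little.  Below the band the
  far-infrared absorption of water is enormous and ignoring it makes the
  computed $n$ diverge visibly *inside* the measured band.  We therefore
  splice the water standard's $k$ through 15–200 µm onto the measurement.
  The two curves are joined by a linear cross-fade over 14–15 µm: the
  splice the method prescribes does not specify a junction treatment, and a
  hard step would ring through the principal-value sum.  The fade (and the
  standard-$k$ substitution at masked points) feeds the transform integrand
  only — the $k$ reported to the user is always the measurement's own
  inversion.
* **The unknown constant.**  The transform fixes $n$ only up to an offset.
  We anchor at 2.0 µm, a low-loss wavelength where no depolarisation
  mechanism of dissolved analytes contributes, by adding
  $c = n_{\mathrm{ref}}(2\,\mu m) - n_{\mathrm{raw}}(2\,\mu m)$ everywhere.
  A single-point anchor is the simplest codification of "compare with the
  known index in a region of low loss"; an optional window-mean variant
  (`anchor_window_um`) is available if the single point sits on noise.

The package's standing self-test runs this whole chain on the water
standard's *own* $k$ over the measurement band: the recovered $n$ must
match the standard's $n$ table. Under the default synthetic conditions the
maximum error over 2–15 µm is about $2 \times 10^{-4}$ (tolerance 0.01),
while disabling the low-frequency extrapolation inflates the band-edge
deviation by four orders of magnitude relative to the anchor region.

## The differential pathway

For dilute analytes it is better to measure the solution against a
*water* reference: the instrument then reports the differential absorbance
of the analyte alone.  The same water-calibrated $d_{\mathrm{eff}}$ applies
— water still controls the evanescent field — so
$\Delta k = \lambda a_{\mathrm{diff}} / (4\pi d_{\mathrm{eff}}
\log_{10} e)$, and $\Delta n$ follows from the same transform with *zero*
extension (the increment vanishes outside the band; zero integrand
contributes nothing to the principal-value sum) and *no* offset step (the
water background is already removed).  A Savitzky–Golay filter (window 5,
cubic) is applied last to both $\Delta n$ and $\Delta k$; smoothing after
rather than before the transform is a choice — the transform is linear, so
for a symmetric kernel the difference is confined to edge effects — and
can be disabled.

## The synthetic ground truth

All tests run against a **Lorentz-oscillator** world:
$\varepsilon(\omega) = \varepsilon_\infty + \sum_j S_j /
(\omega_{0j}^2 - \omega^2 - i\gamma_j\omega)$, $n + ik = \sqrt\varepsilon$.
Lorentz models are causal by construction, so every Kramers–Kronig check
has a closed-form oracle.  The fixtures:

* **Pseudo-water** (`make_pseudo_water()`): three oscillators — O-H
  stretch at 3350 cm⁻¹ ($S = 9\times10^5$, $\gamma = 350$), H-O-H bend at
  1640 cm⁻¹ ($S = 6.5\times10^4$, $\gamma = 120$) and a broad libration
  band at 600 cm⁻¹ ($S = 1.8\times10^5$, $\gamma = 300$) — with
  $\varepsilon_\infty = 1.765$ so that $n(2\,\mu m) \approx 1.30$.  Peak
  $k$ values ($\approx 0.28$ at 3 µm, $\approx 0.13$ at 6.1 µm) sit close
  to liquid water's.  The same model provides both the "measured" truth and
  the "literature" standard table (50–6000 cm⁻¹ at 2 cm⁻¹), so the
  calibration self-consistency is exact by construction.
* **Blood-like** (`make_blood_like()`): pseudo-water plus amide I
  (6.05 µm) and amide II (6.49 µm) bands, the protein signature that
  distinguishes whole blood from water.
* **Dilute solute** (`make_dilute_solution()`): pseudo-water plus one weak
  band at 2250 cm⁻¹ (4.4 µm), $\gamma = 40$ cm⁻¹, strength chosen so the
  peak $\Delta k$ is 0.0020 — the first-order regime the differential
  pathway is designed for.  The band sits in a low-loss window of water
  deliberately: the leading bias of the differential route is the
  perturbation of $d_{\mathrm{eff}}$ by the analyte's own $\Delta n$, and
  that bias is proportional to the solvent's local absorption (roughly
  $3.3 \cdot k_w \cdot \Delta n$ for this geometry).  At 4.4 µm the
  recovery errors are below 2% (Δk) and 4% (Δn) of peak; moving the same
  band into the 8–10 µm diagnostic window, where water's libration tail is
  strong, degrades them to roughly 4–9%.  The package exposes this bias in
  simulation but, like the measurement method itself, does not correct it.

The forward simulator (`simulate_atr_absorbance()`) uses the
weak-absorption Harrick effective-thickness model per reflection — TE and
TM expressions averaged according to the polarisation fraction — times the
reflection count, averaged over a configurable angular distribution
(collimated delta, uniform, or truncated-Gaussian spread; deterministic
21-node Gauss–Legendre quadrature).  With a delta distribution the
empirical calibration must recover $N \times d_e(\theta_0)$ essentially
exactly (observed: $<10^{-12}$ relative; tolerance 0.5%); with a spread it
must land between the single-angle extremes.  What the simulator does
**not** emulate: detector noise (available but off by default, with an
explicit seed), atmospheric water-vapour lines, baseline drift beyond the
linear model, the microwave Debye relaxation of water below the tabulated
band, and the exact multilayer Fresnel response of strongly absorbing
samples — so a passing suite shows the *algorithms* are correct under the
stated model, not that instrument systematics are handled.

## Numerical choices and degenerate inputs

* Canonical internal unit: wavenumber (cm⁻¹), ascending; wavelength views
  are derived by $\lambda = 10^4/\tilde\nu$.  "Same grid" checks use a
  relative tolerance of $10^{-9}$ (file round trips keep 12 significant
  digits).
* Interpolation everywhere (standard lookups, resampling) is monotone-safe
  piecewise cubic (pchip) in wavenumber: it cannot overshoot near the sharp
  O-H bands, at the cost of $O(h^2)$ accuracy exactly at local extrema.
  Standard-table queries outside coverage are an error, never an
  extrapolation.
* Masking: calibration masks $\lambda < 2.7$ µm and points with
  $k_{\mathrm{ref}} < 10^{-4}$ (the ratio of two near-zeros); masks
  propagate; fully-masked calibrations raise a computation error rather
  than returning fiction.
* Baseline model: straight line in wavenumber through the mean of each
  anchor window (defaults 1.8–2.2 and 7.3–7.5 µm); idempotent by
  construction.  CO₂ excision bridges 4.20–4.35 µm linearly between the
  band-edge samples.  O-H normalization scales to the window *maximum*
  (2.85–3.15 µm); in the absolute pipeline both sample and water are scaled
  to the water measurement's own O-H peak, which cancels exactly in the
  calibrated inversion when sample and water coincide.
* Savitzky–Golay edges: the first and last two points are left unsmoothed
  rather than fabricating data at the band edges that would feed the
  transform.
* Errors are classed: `atr_argument_error` (bad inputs, raised before
  computation) vs `atr_computation_error` (degenerate results); the CLI
  maps them to exit codes 2 and 3.

## Problem sizes

The shipped checks run the measurement band 600–6000 cm⁻¹ at 4 cm⁻¹ (the
reference instrument resolution; 1351 points, extended grid ≈ 3000 points)
and at 2 cm⁻¹ for the differential study (2701 points, extended ≈ 6000),
sizes at which the full pipeline completes in seconds while resolving the
narrowest fixture band with ten points per half-width.

## Known limitations

* The water-calibrated $d_{\mathrm{eff}}$ applied to a sample whose index
  deviates appreciably from water incurs a bias the package measures (in
  simulation) but does not correct — see the dilute-solute discussion
  above.
* The phase-retrieval alternative (Kramers–Kronig on the ATR spectrum
  itself) is deliberately out of scope: it requires a collimated beam.
* The JCAMP-DX reader covers plain AFFN `(X++(Y..Y))` tables only.
* `k ≥ 0` is enforced for absolute spectra; noisy near-zero measurements
  are clipped at zero by the inversion rather than failing.
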