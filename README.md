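# ir2d

Kubo-model analysis of two-dimensional infrared (2D IR) spectra of protein
vibrational probes, with a response-function forward simulator for testing
every stage on synthetic data with known ground truth.

## The scientific problem

A localized vibrational probe — prototypically the heme-bound CO stretch of
cytochrome P450cam near 1930–1940 cm⁻¹ — reports on its protein
environment through its frequency fluctuations. Waiting-time-dependent 2D
IR spectra measure how fast those fluctuations randomize (spectral
diffusion); the linear absorption band measures their total amplitude.
Together they determine the frequency–frequency correlation function
(FFCF), modelled here with the Kubo form

    C(t) = δ(t)/T₂* + Δ₁² exp(−t/τ₁) + Δₛ²

— a motionally narrowed homogeneous term (Lorentzian FWHM
Γ* = 1/(π c T₂*)), an exponentially sampled inhomogeneous term (Δ₁, τ₁) and
a static term (Δₛ) for conformational substates sampled more slowly than
the experiment. When a sample populates **two** slowly interconverting
conformational states, the package implements the fixed-component analysis:
the band of the known state (e.g. the free enzyme's closed state) is pinned
to its separately measured FFCF, and the hidden state's center-line-slope
(CLS) decay and FFCF are extracted from the composite 2D data, along with
vibrational lifetimes, transition-dipole ratios and dipole-corrected state
populations.

The package is aimed at spectroscopists analysing CO (or similar narrow
carbonyl/nitrile) probes in proteins, and at method development: the
simulator generates purely absorptive 2D IR spectra, linear spectra and
pump–probe traces from Kubo parameters, so estimators can be validated
end-to-end.

## Worked example

Simulate the putidaredoxin-complex benchmark (two states: 25% closed-like
at 1936.8 cm⁻¹ with a 1.27-fold stronger transition dipole and a 16 ps
lifetime; 75% of the induced state at 1931.3 cm⁻¹ with 13 ps), then run
the full analysis:

```r
library(ir2d)

model  <- p450_fixture("pdx", noise_sd = 0)
series <- simulate_tw_series(model)                 # 9 waiting times, 0.25-44 ps
linear <- synth_linear_mixture(model)
analysis <- analyze_sample(series, linear)
analysis
#> 2D IR analysis: 2 component(s) (1-vs-2 F-test p = 5.86e-150)
#>   center  fwhm rel_area gamma_h delta_1 tau_1 delta_s t1_lifetime rel_pop
#> 1   1931 7.935    66.73   1.994   1.897 26.82   1.993       13.10   76.33
#> 2   1938 8.402    33.27   1.033   1.937 20.70   2.647       16.04   23.67
```

Reading the table: the composite is decomposed into two bands whose linear
areas split 67/33; correcting the high-frequency band's area by its fitted
squared dipole ratio gives populations 76/24 (injected: 75/25). The
low-frequency row carries the extracted FFCF of the hidden state
(injected Γ* = 2.2, Δ₁ = 2.0, τ₁ = 31.7, Δₛ = 1.8) and the global
lifetime fit returns 13.1/16.0 ps for the two bands.

Single-band samples go through the classic CLS/lineshape co-fit:

```r
decay <- cls_decay(simulate_tw_series(p450_fixture("wt", noise_sd = 0)))
decay
#> CLS decay over 9 waiting times (0.25-44 ps)
#>   fit: 0.307 * exp(-Tw/20.9 ps) + 0.591
fit_ffcf(decay, synth_linear_mixture(p450_fixture("wt", noise_sd = 0)),
         t1_lifetime = 16)
#> Kubo FFCF parameters
#>   Gamma* (homogeneous FWHM): 1.59 cm-1  (T2* = 6.68 ps)
#>   Delta_1: 2.98 cm-1   tau_1: 20.7 ps
#>   Delta_s: 4.08 cm-1   T1: 16 ps
```

(the generating parameters were Γ* = 1.6, Δ₁ = 3.0, τ₁ = 20.7, Δₛ = 4.1).

A thin command-line front end covering `simulate`, `fit-linear`, `cls`,
`lifetimes`, `decompose` and `report` lives at `inst/cli/ir2d.R`;
`vignettes/ir2d-methods.Rmd` documents the model, the estimators and their
design rationale.

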