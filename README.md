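# glycoforce

Quantitative analysis of AFM force spectroscopy on living cells, built for
studies of the endothelial glycocalyx: the brush-like, carbohydrate-rich
layer on the endothelial surface whose shortening is an early marker of
vascular dysfunction. The package decomposes force–distance curves into an
elastic cell response and a polymer-brush glycocalyx response, aggregates
force maps into per-cell summaries, and provides the companion
quantifications such studies lean on (corrected total cell fluorescence,
scratch-assay gap closure, differential-expression filtering and exact
set-overlap tests). A synthetic-data module generates every input with
planted ground truth, so the entire pipeline is testable end to end without
instrument data.

## The model

An approach curve records force F against piezo height z. After baseline
correction and contact-point estimation, each curve is modelled as the sum
of two regimes:

* **Elastic indentation.** For a spherical probe of radius R indenting an
  incompressible half-space by δ, the Hertz force is

      F = (4/3) · E/(1−ν²) · √R · δ^{3/2}

  with E the apparent Young's modulus and ν the Poisson ratio (0.5 by
  default). For pyramidal mapping tips the Hertz–Sneddon form
  F = E/(1−ν²) · (tan θ/√2) · δ² is used instead, with θ the face
  half-angle, fitted over a constant indentation window (δ ≤ 200 nm) to
  avoid substrate contributions.

* **Glycocalyx brush.** At tip–sample separation h, the Alexander–de
  Gennes steric repulsion of a grafted layer of length L and grafting
  density N compressed by a sphere is

      F(h) ≈ 50 · k_B T · R · N^{3/2} · L · exp(−2π h / L),

  nominally valid for 0.1 < h/L < 0.8, so ln F is affine in h with slope
  −2π/L.

The two-regime procedure fits the Hertz law in the deep-indentation window,
where the brush is almost fully squeezed (contributing only its saturated
prefactor, absorbed as a force offset), fits the brush law to the
long-range residual, and then refines contact point, modulus, brush length
and density jointly against the whole curve. The per-curve outputs E and L
feed the force-map summaries (whole cell versus its central region), the
cytochalasin-D before/after comparisons and the group statistics.

## Worked example

Simulate one noisy approach curve under the default acquisition conditions
(1.25 µm sphere, 0.02 N/m cantilever, 500 pN setpoint, 36.2 °C; planted
truth E = 2000 Pa, L = 300 nm, N = 1e14 m⁻²) and decompose it:

```r
library(glycoforce)
sim <- simulate_curve(sim_config(seed = 11))
dec <- decompose_curve(sim$curve)
dec
#> Two-regime force-curve decomposition
#>   E = 2001 Pa (z0 = 500.3 nm)
#>   glycocalyx L = 280.0 nm (N = 1.02e+14 m^-2)
coef(dec)
#>            E            L            N           z0
#> 2.001120e+03 2.799662e+02 1.016072e+14 5.002757e+02
```

The fitted modulus is within 0.1% of the planted 2000 Pa and the brush
length within 7% of the planted 300 nm on this single 3 pN-noise curve
(medians over ensembles land well under 1% and 2%; `plot(dec)` overlays the
fitted model on the data). Per-cell summaries compare groups with the
standard tests:

```r
set.seed(99)
L_values <- c(rnorm(16, 300, 40), rnorm(16, 180, 40)) # two cell lines
compare_groups(L_values, rep(c("control", "mutant"), each = 16))
#> Kruskal-Wallis test: statistic = 17.5, p = 2.87e-05
#>   group medians: control = 301.8, mutant = 194.4
```

The overlap of a differentially-expressed gene set with a putative-target
list is tested exactly:

```r
u <- as.character(1:10)
hypergeometric_overlap(u[1:5], u[2:5], u)
#> Set overlap: |universe| = 10, |A| = 5, |B| = 4, overlap = 4
#>   hypergeometric P(X >= 4) = 0.02381
```

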