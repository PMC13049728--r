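---
title: "Two-regime force-curve decomposition: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-regime force-curve decomposition: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoforce)
```

## The measurement and the model

An AFM force–distance approach curve records cantilever force $F$ (via the
deflection $d$ and spring constant $k$, $F = kd$) against piezo height $z$
as a probe approaches a living cell. On endothelial cells the curve carries
two superimposed signals: the long-range entropic repulsion of the
glycocalyx brush, and the elastic indentation of the cell body once the tip
makes contact. `glycoforce` separates them per curve.

With the contact point $z_0$ and the kinematic conventions

$$\delta = \max\{0,\,(z_0 - z) - d\}, \qquad h = (z - z_0) + d = -\,\delta_{\text{signed}},$$

(the piezo height decreases toward the surface; deflection is positive
under repulsive load, which pushes the tip away, so separation and
indentation are exact negatives of each other), the fitted model is

$$F(z) \;=\; C\,\delta^{p} \;+\; P\,e^{-2\pi h_+ / L},$$

where the elastic term is the Hertz sphere law ($p = 3/2$,
$C = \tfrac{4}{3}\,\frac{E}{1-\nu^2}\sqrt{R}$) or the Hertz–Sneddon
four-sided-pyramid law ($p = 2$, $C = \frac{E}{1-\nu^2}\tan\theta/\sqrt 2$),
and the brush term is the Alexander–de Gennes exponential with prefactor
$P = 50\,k_B T R N^{3/2} L$, saturating at $P$ under contact
($h_+ = \max\{h, 0\}$). The brush law is nominally valid for
$0.1 < h/L < 0.8$; its log-linearity in $h$ (slope $-2\pi/L$) is what the
initialisation exploits. Only $L$ is used downstream; $N$ is reported for
completeness.

## The estimator

The decomposition runs in stages, each of which is also exposed on its own:

1. **Baseline** (`correct_baseline`): a least-squares line over the
   farthest 30% of the approach is subtracted, removing deflection offset
   and drift. The window residual RMS doubles as the noise estimate for
   every later threshold. A straight line is the simplest model that
   removes drift without touching the brush regime; the fraction is a
   parameter.
2. **Contact scan** (`estimate_contact_point`): a piecewise model — zero
   force before a candidate $z_0$, a power law after — is profiled over the
   sampled grid and the total squared residual minimised. The scan is
   restricted to samples below a force cut (default 100 pN, i.e. the soft
   onset regime, well below the 500 pN setpoint): deep-indentation
   features, a stiff-substrate upturn in particular, would otherwise
   dominate the residual and can themselves mimic a power-law onset. A
   brush biases this scan outward by up to roughly one decay length; the
   `brush_suspected` flag marks that situation, and later stages correct
   for it.
3. **Deep-window Hertz fit** (`fit_hertz`): the contact law is fitted over
   the top $q = 0.4$ fraction of the indentation range — the regime where
   the glycocalyx is assumed almost squeezed — with the prefactor linear in
   the model and $z_0$ re-optimised by a grid-then-polish search. Inside the
   decomposition an additive force offset is co-fitted, absorbing the
   saturated brush force that underlies deep indentation; standalone fits
   default to no offset. For pyramidal mapping the window is instead a
   constant indentation cap (200 nm, about 10% of the cell height, avoiding
   the hard substrate), and two specifics apply: the candidate point set is
   frozen at the scan estimate before re-optimising $z_0$ (shifting the cap
   boundary with the candidate would otherwise reward pushing signal out of
   the window), and the non-contact side joins the objective, since a sharp
   tip without a brush should read zero force there.
4. **Brush fit** (`fit_brush`): the long-range residual on the non-contact
   side is regressed as $\ln F$ on $h$ — weighted by $F^2$, the
   delta-method variance stabiliser under additive force noise — then
   refined by Levenberg–Marquardt in force space, iterating the window into
   the $0.1 \le h/L \le 0.8$ validity band (at most 10 passes, converged at
   a 1% change in $L$). Detection is deliberately structural: the median
   force over the 16 non-contact samples nearest the surface must exceed 3
   noise RMS. A per-point count at a higher bar fails in both directions —
   a biased $z_0$ can hide a real brush, while i.i.d. noise essentially
   never lifts a 16-point median.
5. **Joint refinement**: all four parameters $(z_0, C, P, L)$ are refit
   against the whole curve. The $(z_0, L)$ plane is scanned on a coarse
   grid with both amplitudes profiled out by linear least squares, the best
   node is sharpened by three multi-resolution passes, and a bounded
   Levenberg–Marquardt polish finishes. The staged estimates above are
   good initialisers but leave $(z_0, C, P)$ weakly identified on noisy
   curves — the deep window alone carries little curvature contrast, and a
   70 nm contact-point error propagates into tens of percent on $E$ and
   contaminates the brush window with contact points. Profiling plus
   multi-resolution search makes the refinement global and deterministic;
   the far tail ($h > 1.5L$, where the brush force is below $10^{-4}$ of
   its prefactor) is excluded from the final polish so the positive-only
   model cannot chase noise. If the refined prefactor falls at noise level
   the initial brush detection is revoked — with $z_0$ now well determined,
   it was an artifact of the biased contact point.

Every stage failure is a documented quality flag (`no_contact`, `no_brush`,
`poor_hertz_fit`, `window_truncated`, `hertz_nonconverged`,
`brush_window_collapse`, `brush_refine_failed`, `joint_refine_failed`), never a
silent drop; a staged mishap that the joint refinement supersedes is
removed from the flags, which describe the returned result.

## Parameters that matter

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `poisson` | 0.5 | – | incompressible cell; never stated by typical instrument software, overridable |
| `hertz_q` | 0.4 | – | deep-window fraction ("close to maximal indentation") |
| cap | 200 | nm | pyramidal indentation cap (~10% of cell height) |
| `brush_window` | (0.1, 0.8) | h/L | Alexander–de Gennes validity band |
| `baseline_fraction` | 0.3 | – | far-end share used for the baseline line |
| `force_cut` | 100 | pN | contact-scan onset regime |
| spring constant | 0.02 | N/m | soft cantilever for glycocalyx work |
| probe radius | 1.25 | µm | colloidal sphere |
| face half-angle | 17.5 | ° | four-sided mapping pyramid |
| temperature | 309.35 | K | 36.2 °C liquid cell |

The pyramid front factor $\tan\theta/\sqrt2$ is the four-sided-pyramid
convention; vendor software varies, so the conical alternative
$(2/\pi)\tan\theta$ is selectable (`front_factor = "cone"`). The brush
prefactor constant (50) is likewise fixed in one place
(`glycoforce:::brush_prefactor`) so the round-trip property — generator and
fitter sharing the same closed form — is explicit.

## Force maps and group statistics

`fit_map` applies the decomposition (sphere) or the capped Sneddon fit
(pyramid) per pixel; `summarize_cell` aggregates valid pixels by median
(robust to occasional fit failures; mean selectable) over the whole cell
mask and over its central region. "Central" is defined here as the in-mask
pixels nearest the mask centroid covering half the mask area — a
reproducible, parameter-light proxy for the perinuclear region, since no
standard definition exists. Regions with fewer than 4 valid pixels are
reported absent rather than estimated. Cytochalasin-D experiments are
summarised by `percent_reduction` (positive = softer after treatment) and
compared with `compare_groups`, a thin wrapper over the Kruskal–Wallis and
unpaired t tests. Whether per-cell values should pool pixels or average
maps first is genuinely open; the package pools pixels per map and treats
each map as a cell.

## Image and table quantifications

CTCF follows the standard formula (integrated density − area × mean
background) exactly, with the background mean pooled across background
ROIs by default (per-ROI averaging selectable — the ImageJ convention is
ambiguous). Wound segmentation is texture-based: local variance over a
15 px window, Otsu threshold, morphological cleanup, largest low-texture
component; a frame whose two texture classes differ by less than a factor
4 in mean local variance is declared wound-free, which is what
distinguishes a closed wound from an arbitrary Otsu split. Gap closure is
$100\,(A_0 - A_t)/A_0$ on the open-area masks, all frames reported.

DEG filtering keeps $p_{adj} \le 0.105$ and fold change $> 1.5$ — the
0.105 cutoff is deliberately preserved as the default — applied to
$|FC| = 2^{|\log_2 FC|}$ symmetrically, since regulation in both directions
counts. DEP filtering keeps $p < 0.05$ (per-protein t-test, computable from
replicate intensities via `protein_ttest`) and $|FC| \ge 1.2$. The
hypergeometric overlap test sums exact point probabilities for
$P(X \ge k)$ — no normal approximation — and requires the universe
explicitly: the set of genes actually tested changes the answer, and a
silent default would hide that choice.

## The synthetic-data generator

`simulate_curve` draws the model itself plus an affine baseline artifact
and i.i.d. Gaussian force noise, emulating thermal-noise-dominated
soft-cantilever acquisition. Curves are sampled uniformly in the tip–sample
gap $g$ and mapped to piezo height through the exact force balance
$z = z_0 + g - F(g)/k$, so the planted $\delta$/$h$ bookkeeping is exact to
machine precision and the ramp is monotone for any stiffness; the piezo
spacing is then mildly non-uniform, which the curve container permits. The
approach is truncated where the noise-free force reaches the 500 pN
setpoint, as an instrument would stop, or at a configured indentation cap
for indentation-controlled mapping ramps. Default conditions: $E^* = 2$ kPa,
$L^* = 300$ nm, $N^* = 10^{14}\,\mathrm{m^{-2}}$, 3 pN noise, 512 samples
over a 2 µm non-contact range, 5 pN baseline offset, 0.005 pN/nm tilt.

`simulate_map` lays an elliptical cell phantom over a 7 × 7 grid (1.5 µm
step) with separately planted central and peripheral $(E, L)$ and optional
cytochalasin scaling of $E$; pyramid-mode maps use indentation-limited
ramps (220 nm) with an 800 nm non-contact range, the short-ramp regime of
mapping acquisition. For the cytochalasin simulations the planted modulus
is 8 kPa — a typical sharp-tip apparent modulus for endothelial cells — so
the post-treatment curves (0.4 ×) still clear the contact-detection
threshold comfortably. `simulate_fluor_image`, `simulate_scratch` and
`simulate_gene_table` plant disc-shaped cells with known integrated
signal over a flat background, a nested stripe closing at a constant rate,
and gene tables in which effects and p-values derive from one latent
z-score (effect + unit noise, two-sided normal p, Benjamini–Hochberg), so
fold-change and significance thresholds see internally consistent data.
Protein replicate noise (sd 0.19 log2 units, 3 vs 3 replicates) is chosen
so a 1.5-fold shift is detected with power ≈ 0.8 at α = 0.05, a
deliberately imperfect-recall regime.

What the generator does *not* emulate: real cell topography, viscoelastic
and adhesive responses, optical point-spread functions, sequencing-count
noise, spatially correlated drift. Passing round-trip tests therefore
demonstrates estimator correctness under the stated model, not robustness
to every artifact of real data — the usual caveat of simulation-based
validation.

## Numerical choices and degenerate inputs

Tolerances: the joint refinement's multi-resolution scan resolves $z_0$ to
~0.3 nm and $L$ to ~1.5% before the LM polish; window iteration converges
at 1% in $L$; fits with fewer than 8 points error (windows) or return
absent (regions). Ties in the central-region ranking and in top-k gene
ranking break deterministically (row-major order, lexicographic gene id).
Degenerate inputs have defined behaviour: flat curves raise a no-contact
error, brushless curves return `brush_detected = FALSE`, empty ROIs and
zero initial wound areas error by name, non-nested scratch masks warn.
Determinism is part of the contract: decomposing the same curve twice is
bitwise identical, and every generator is byte-reproducible under a fixed
seed.

## Problem sizes in the test-suite

The suite validates at sizes a laptop handles in seconds: 9 noiseless
grid points for the exact round trip, 200 noisy curves for the median
recovery (≈30 ms per decomposition), 20 simulated map pairs (7 × 7, ~30
in-cell pixels) for the cytochalasin comparison, 1000 null resamples for
the type-I calibration and 500 seeded tables for the null uniformity of
the overlap p-value. These sizes were chosen to keep Monte-Carlo error
well inside the asserted tolerances.

## Known limitations

* The decomposition is defined for the spherical-probe geometry; pyramidal
  curves get the capped Sneddon fit only (no brush), matching how such
  probes are used.
* Bottom-effect (finite cell thickness) corrections, viscoelastic models
  and retract-segment adhesion are out of scope.
* The brush model is the single-layer Alexander–de Gennes form; bimodal
  brushes and grafting-density biology are not addressed.
* $N$ is highly sensitive to the prefactor calibration and temperature;
  treat it as a relative quantity.
* The wound segmentation is a texture thresholder with two knobs; heavily
  textured debris inside a wound will fragment the mask.
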