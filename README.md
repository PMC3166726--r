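# perfkit

Deconvolution-based CT and MR brain perfusion analysis in R.

Dynamic contrast perfusion imaging — perfusion CT or dynamic
susceptibility contrast MR — tracks a contrast-agent bolus through brain
tissue and quantifies hemodynamics from the resulting time-concentration
curves. perfkit is for researchers and methods developers who need the
full measurement chain as inspectable, tested code: from raw 4D
attenuation/signal series to parameter maps of cerebral blood flow (CBF),
cerebral blood volume (CBV), mean transit time (MTT), time-to-maximum
(TMAX), time-to-peak (TTP), bolus arrival time (BAT), first moment (FM)
and peak concentration.

## The model in brief

Indicator-dilution theory for an intravascular tracer states

    c_voi(t) = CBF · ρ_voi · (c_art * r)(t) = (c_art * k)(t)

where `c_art` is the arterial input function (AIF), `r(t)` the residue
function (fraction of an instantaneous bolus still in the tissue at time
t; r(0) = 1, non-increasing) and `k(t) = CBF·ρ_voi·r(t)` the flow-scaled
residue. Recovering `k` from measured `c_art` and `c_voi` is a
deconvolution; then

    CBF = max(k)/ρ_voi,   CBV = ∫k/ρ_voi,   MTT = ∫k/max(k),
    TMAX = argmax_t k(t),

linked by the central volume theorem CBF = CBV/MTT. The discrete system
`A k = c` (lower-triangular Toeplitz or delay-insensitive block-circulant
`A` built from the AIF) is severely ill conditioned, so perfkit solves it
by SVD filtering — truncated SVD or Tikhonov
(`f_i = σ_i²/(σ_i²+λ²)`, `λ = λ_rel·σ_1`) — with λ chosen by a fixed
value (default `λ_rel = 0.2`), an oscillation-index threshold, or the
L-curve corner. A mathematically equivalent FFT path, a model-based
exponential-residue fit, the discrete Picard diagnostic, and
nondeconvolution estimators (maximum-slope CBF, AUC-/peak-ratio CBV) are
included, as are the preprocessing steps (HU/signal-to-concentration
conversion, hematocrit correction κ = 0.73, Gaussian smoothing, tissue
masking, automated AIF selection, partial-volume AIF rescaling, frame
removal) and a digital perfusion phantom with exact ground truth.

## Worked example

Render the reference phantom (8×8×2 voxels, 1 s frames; grey matter
CBF 60 mL/100 g/min, CBV 4 mL/100 g), convert to concentration, pick the
AIF automatically, and deconvolve one grey-matter voxel:

```r
library(perfkit)

ph   <- render_acquisition(reference_phantom())
conv <- ct_to_concentration(ph$series)
aif  <- auto_aif(conv$conc, array(TRUE, c(8, 8, 2)), conv$grid)$aif
cv   <- concentration_curve(conv$grid, conv$conc[6, 2, 1, ], "tissue")

A <- build_system_matrix(aif, "toeplitz")
k <- regularized_solution(A, cv, regularization_spec("tikhonov", 0.05))

cbf_from_k(k); cbv_from_k(k); mtt_from_k(k); tmax_of_k(k)
```

which prints

```
concentration_curve [arterial]: n = 40, dt = 1 s, peak = 294.9 at t = 10 s
system_matrix [toeplitz]: 40 x 40, rank 34, cond sigma1/sigmar = 4.56e+11
CBF = 57.0 mL/100 g/min
CBV = 4.02 mL/100 g
MTT = 4.23 s
TMAX = 0 s
```

The condition number shows why regularization is mandatory; the recovered
values sit within a few percent of the ground truth (60 / 4 / 4 / 0), the
residual gap being regularization smoothing plus discretization. Full
volumes go through `map_volume()` (one shared filtered pseudo-inverse for
all voxels) or the one-call pipeline `run_pipeline()`, which also
assembles a provenance report (effective config, hashes, selected λ_rel,
Picard flag, oscillation-index summary, per-voxel failure counts).

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/perfkit.R phantom --out ph/
Rscript inst/cli/perfkit.R run --in ph/dynamic.nii.gz --aif ph/aif.csv --out maps/
Rscript inst/cli/perfkit.R deconvolve --aif ph/aif.csv --curve tissue.csv \
    --matrix circulant --filter tikhonov --lambda-rel 0.2
```

Subcommands: `phantom`, `convert`, `deconvolve`, `curve-params`, `maps`,
`run`.

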