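---
title: "Deconvolution-based perfusion measurement: model, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolution-based perfusion measurement: model, algorithms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perfkit)
```

## The physiological model

perfkit implements the indicator-dilution model of cerebral
microcirculation for intravascular tracers. A tissue volume is fed by one
arterial inlet and drained by one venous outlet; a tracer particle
traverses the capillary bed with a random transit time drawn from a
stationary density $h(t)$. Three quantities follow from $h$:

* the **mean transit time** $\mathrm{MTT} = \int_0^\infty \tau h(\tau)\,d\tau$;
* the **residue function** $r(t) = 1 - \int_0^t h(\tau)\,d\tau$, the
  fraction of an idealized instantaneous bolus still inside the volume at
  time $t$ ($r(0) = 1$, non-increasing, and
  $\mathrm{MTT} = \int_0^\infty r$ by integration by parts);
* the measured tissue concentration
  $c_\mathrm{voi}(t) = \mathrm{CBF}\,\rho_\mathrm{voi}\,(c_\mathrm{art} * r)(t)$,
  where $c_\mathrm{art}$ is the arterial input function (AIF) and
  $\rho_\mathrm{voi}$ the mean tissue density.

The model assumes an intact blood–brain barrier (the tracer stays
intravascular), perfect mixing, and flow that is stationary over the scan.
Collecting the unknowns into the **flow-scaled residue**
$k(t) = \mathrm{CBF}\,\rho_\mathrm{voi}\,r(t)$ (units 1/s) turns the model
into $c_\mathrm{voi} = c_\mathrm{art} * k$, a deconvolution problem. From
the recovered $k$:

* $\mathrm{CBF} = \max_t k(t) / \rho_\mathrm{voi}$ — the maximum rather
  than $k(0)$, because bolus delay between the global AIF site and the
  tissue makes $k$ vanish at $t = 0$;
* $\mathrm{CBV} = \int_0^\infty k / \rho_\mathrm{voi}$;
* $\mathrm{MTT} = \int k / \max k$ (the central volume theorem
  $\mathrm{CBF} = \mathrm{CBV}/\mathrm{MTT}$ holds exactly by
  construction);
* $\mathrm{TMAX} = \arg\max_t k(t)$.

Curve-based parameters (TTP, $c_{\max}$, first moment, bolus arrival time)
and the nondeconvolution estimators (maximum slope CBF, AUC-ratio and
peak-ratio CBV) are computed directly from the measured curves.

## Discretization and the algebraic core

Curves are sampled uniformly, $t_j = (j-1)\Delta t$. The forward model is
the left-rectangle discrete convolution
$c_\mathrm{voi}(t_j) = \Delta t \sum_i c_\mathrm{art}(t_i)\,k(t_{j-i+1})$;
in matrix form $\mathbf{A}\mathbf{k} = \mathbf{c}$ with $\mathbf{A}$ the
lower-triangular Toeplitz matrix whose first column is
$\Delta t\,c_\mathrm{art}$. The **block-circulant** variant zero-pads both
curves to $L = 2N$ and embeds the convolution in a circulant matrix, which
makes the solution insensitive to bolus delay (a pure integer delay of the
tissue curve circularly shifts $k$ instead of attenuating it); the padding
length $2N$ prevents wrap-around of the causal convolution.

Two discretization rules coexist deliberately: the *system matrix* uses
the rectangle rule (so that an impulse AIF inverts exactly and the matrix
matches the printed construction), while all *parameter integrals*
(CBV, MTT, AUC ratios, first moment) use the trapezoid rule, which has
lower bias for smooth integrands. The rectangle rule overestimates the
area of a sampled decaying exponential by
$\frac{\Delta t / \tau}{1 - e^{-\Delta t/\tau}}$ — about 6% at
$\Delta t = 1$ s, MTT 4 s — so AUC identities are only met tightly on
finer grids; the worked examples in the tests use $\Delta t \le 0.1$ s
where this bias is below 1%.

The Toeplitz system is severely ill conditioned: the least-squares
solution $\mathbf{k}_\mathrm{ls} = \sum_i (u_i^\top c / \sigma_i) v_i$
amplifies noise catastrophically (on the noisy digital phantom its
amplitude exceeds physiology by several orders of magnitude). The
**discrete Picard diagnostic** tabulates $\sigma_i$, $|u_i^\top c|$ and
their ratio; the violation flag compares geometric-mean ratios over a
trailing versus a leading window (factor 10, window 5). Regularized
solutions filter the SVD sum with

* TSVD: $f_i = \mathbf{1}[\sigma_i \ge \lambda]$, or
* Tikhonov: $f_i = \sigma_i^2 / (\sigma_i^2 + \lambda^2)$, equivalent to
  minimizing $\|\mathbf{A}\mathbf{k}-\mathbf{c}\|_2^2 + \lambda^2\|\mathbf{k}\|_2^2$,

with $\lambda = \lambda_\mathrm{rel}\,\sigma_1$. The Fourier path
(`fft_deconvolve`) applies the Wiener filter
$\overline{\hat A}\hat C / (|\hat A|^2 + \tilde\lambda^2)$ with
$\tilde\lambda = \lambda_\mathrm{rel} \max |\hat A|$; because circulant
singular values are the moduli of the Fourier coefficients of the padded
AIF, this is *algebraically identical* to Tikhonov filtering of the
circulant SVD, and the test suite asserts agreement to 1e-6. A
model-based alternative (`model_fit_deconvolve`) restricts $k$ to
$a\,e^{-t/b}$, solving $a$ in closed form on a log grid over $b$ plus
local refinement — stable under noise, biased when the true residue shape
differs (the product $ab$, i.e. CBV, is largely preserved).

### Choosing the regularization parameter

Three selectors are provided. *Fixed*: $\lambda_\mathrm{rel} = 0.2$, the
typical fixed value in brain perfusion CT, is the shipped default.
*Oscillation index*: $\mathrm{OI} = \frac{1}{L\,\max k}\sum_j
|k_j - 2k_{j-1} + k_{j-2}|/2$ (zero for affine $k$); the selector walks a
50-point log grid over $\lambda_\mathrm{rel} \in [10^{-4}, 1]$ and stops
at the first solution with $\mathrm{OI}$ below the threshold (default
0.1). *L-curve*: the corner of the log–log plot of squared solution norm
versus squared residual norm, located as the point of maximum Menger
curvature over consecutive grid triples; ties break toward smaller
$\lambda$ and a collinear curve falls back to 0.2 with a warning.

Numerical details worth knowing: singular values below
$10^{-12}\sigma_1$ are treated as rank deficiency (leading zeros in a
baseline-subtracted AIF produce exactly this); `max(k)` ties break to the
first index, which defines TMAX on plateaus; negative $k$ samples — a
regularization artifact — are clipped to zero for the CBV/MTT integrals
only (configurable), never for $\max k$; integrals are truncated at the
grid end with a warning when $k$ has not decayed below 5% of its peak.

## Preprocessing

CT attenuation converts to concentration as
$c(t_j) = k_\mathrm{ct}(\mu(t_{j+B-1}) - \mu_0)$ with $\mu_0$ the mean of
the $B$ pre-bolus frames and $k_\mathrm{ct} = 1$ g/mL/HU (the constant
cancels in the deconvolution). MR signal converts as
$c(t_j) = -(k_\mathrm{mr}/TE)\ln(s(t_{j+B-1})/s_0)$; voxels with
non-positive signal are flagged invalid rather than clamped. Both
conversions consume the first $B-1$ frames and place $t = 0$ at the last
baseline frame — with $B = 1$ the first concentration sample is exactly
zero and the Toeplitz matrix becomes rank deficient. The hematocrit
factor $\kappa = 0.73$ multiplies tissue curves only (the tracer occupies
plasma, whose fraction differs between arteries and capillaries). MR
proportionality may differ between blood and tissue; separate
`k_mr_blood`/`k_mr_tissue` knobs default to equal.

The bolus-arrival detector declares BAT at the first sample where $m = 2$
consecutive values exceed $z = 3$ baseline noise standard deviations —
the threshold form is this package's choice, as is the automated AIF
heuristic: candidate voxels combine a top-percentile peak concentration
(widened to half the global maximum, so a partial-volume-attenuated
artery is not shadowed by a brighter vein) with bolus arrival at or below
the masked median; the AIF is the mean candidate curve. Partial-volume
attenuation of the AIF is repaired by rescaling to the trapezoid area of
a large venous vessel's curve. Frame removal (for reconstruction
artifacts) interpolates interior gaps linearly back onto the uniform grid
and truncates dropped end frames. Per-frame Gaussian smoothing is
separable, truncated at $3\sigma$, zero-padded, and mass-conserving away
from the volume boundary.

## The digital phantom

`reference_phantom()` renders an 8×8×2×43-frame CT acquisition
($\Delta t = 1$ s, $N = 40$ curve samples, $B = 4$ baseline frames,
35 HU tissue baseline) with grey matter (CBF 60 mL/100 g/min, CBV
4 mL/100 g, MTT 4 s), white matter (CBF 25, CBV 2, MTT 4.8 s), an
ischemic lesion (CBF 15, CBV 3, MTT 12 s, 2 s delay, 1.5 s dispersion),
an artery column and a vein column. Grey/white values sit at the standard
physiologic numbers for the healthy adult brain; the lesion values are
illustrative of hypoperfused tissue. The bolus is a gamma-variate
$A(t-t_0)^\alpha e^{-(t-t_0)/\beta}$ (onset 5 s, $\alpha = 3$,
$\beta = 1.5$ s, 300 HU-equivalent arterial peak — tissue enhancement
then sits an order of magnitude lower, as in real scans); the functional
form is this package's choice of bolus model. Residue shapes are
exponential by default; the gamma family (shape fixed at 4 unless
specified — only the mean is pinned by the physiology) is available for
model-mismatch experiments. Bolus dispersion uses a causal unit-area
exponential kernel $e^{-t/\tau}/\tau$, a standard vascular transport
model: it lowers $\max k$ (hence biases CBF down) while conserving the
area (CBV). Delays are rounded to the nearest sample so the forward model
stays exactly representable by the discrete convolution; sub-sample
delays are obtained by grid refinement, not interpolation.

Noise is additive Gaussian in the native signal domain (HU for CT,
fractional for MR) — where scanner noise lives — and requires an explicit
seed; rendering is bit-reproducible given the seed. The phantom
deliberately omits anatomy, beam hardening, motion, recirculation
modeling beyond the single-pass bolus, and spatial partial-volume
point-spread beyond a scalar vessel attenuation factor. Passing the
phantom suite therefore demonstrates correctness of the *mathematics* —
conversion inverses, convolution identities, recovery within
discretization error — not robustness to clinical artifacts.

## What the tests establish

On the noiseless reference phantom, tissue-class medians recover CBF
within 15%, CBV within 5% and MTT within 15% (single voxel:
59.7/4.02/4.04 against 60/4/4 at $\lambda_\mathrm{rel} = 0.01$). The
residual errors are regularization smoothing plus discretization; the
discretization component alone shrinks monotonically as $\Delta t$ drops
from 1 s to 0.25 s. The lesion's CBF is *under*estimated through
dispersion — the documented behavior of delay/dispersion on
deconvolution, not a defect — while its CBV (area-preserved) and TMAX
(≥ delay) remain informative. Problem sizes throughout the suite
($N \le 64$, 100-trial oracle sweeps, a 200-replicate arrival-time Monte
Carlo) were chosen so the whole suite documents the behavior at
interactive runtimes.

## Known limitations

* Intravascular-tracer model only: leaky capillaries (tumors, BBB
  breakdown) overestimate CBV; no multi-compartment extension.
* A fixed $\lambda_\mathrm{rel}$ trades bias for variance globally;
  CBF is systematically underestimated for large $\lambda_\mathrm{rel}$.
* No image registration or motion correction beyond frame removal.
* Absolute MR quantification inherits the unknown, tissue-dependent
  $k_\mathrm{mr}$; values are proportional unless calibrated.
* The maximum-slope CBF needs a no-venous-outflow bolus; at realistic
  MTT it underestimates deconvolution CBF (asserted, not hidden).
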