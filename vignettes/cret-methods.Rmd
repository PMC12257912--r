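---
title: "Continuous-representation fan-beam CT reconstruction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous-representation fan-beam CT reconstruction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The reconstruction model

Fan-beam CT measures line integrals $p(\beta, u)$ of the object's linear
attenuation $\mu$ along rays from a point source (azimuth $\beta$) to a flat
detector (lateral offset $u$). Classical filtered back-projection (FBP)
reconstructs

$$\hat y = A_{fb}^{T}\, C\, W_{\cos}\, p = A_{fb}^{T} z,$$

where $W_{\cos}$ is the flat-detector cosine weighting
$D/\sqrt{D^2+u^2}$ ($D$ the source-to-detector distance), $C$ the ramp
filter, and $A_{fb}^{T}$ back-projection. With linear interpolation, the
value at an output position $x_q$ is

$$\hat y(x_q) = \sum_{i=1}^{N} \frac{1}{L_{iq}^2}\,\frac{1}{l_i}
  \left( l_{i0}\, z_{i1} + l_{i1}\, z_{i0} \right),$$

where, in view $i$, $x_{iq}$ is the detector coordinate of the ray through
$x_q$, $z_{i0}, z_{i1}$ are the two nearest filtered samples, $l_{i0}, l_{i1}$
the distances from $x_{iq}$ to them ($l_i = l_{i0}+l_{i1}$ is one detector
pitch), and $L_{iq}$ the source-to-pixel distance. Note the cross weighting:
the *nearer* sample gets the *larger* weight because $l_{i0}$ multiplies
$z_{i1}$.

The package's continuous-representation extension (`cret_backproject()`)
replaces pure linear interpolation by linear interpolation *plus* a local
continuous model of the filtered sinogram between samples:

$$\hat y(x_q) = \sum_{i=1}^{N} \frac{1}{L_{iq}^2}\,\frac{1}{l_i}
  \left( l_{i0}\, f(z^*_{i1}, x_{iq}-x_{i1}) + l_{i1}\, f(z^*_{i0}, x_{iq}-x_{i0})
       + l_{i0}\, z_{i1} + l_{i1}\, z_{i0} \right),
  \qquad z^* = A_\gamma(E_\phi(S(z))),$$

where $S$ squeezes (and optionally unfolds) the sinogram around the region
of interest, $E_\phi$ is a small convolutional encoder, $A_\gamma$ a
$1\times1$ convolution matching the feature channels to the decoder
dimension, and $f$ is a *parameter-free* sinusoidal decoder:

$$f(z^*, x) = z^* \cdot \mathrm{PE}(x), \qquad
  \mathrm{PE}(x) = \left(1, \sqrt2\cos(\pi x), \sqrt2\sin(\pi x), \dots,
                   \sqrt2\cos(n\pi x), \sqrt2\sin(n\pi x)\right).$$

The basis is orthonormal under $\tfrac12\int_{-1}^{1} e_i e_j \,dx =
\delta_{ij}$ (`gram_matrix()` certifies this to $10^{-12}$), and the offsets
fed to $\mathrm{PE}$ are normalized by the detector pitch, so
$\Delta_0 = x_{iq}-x_{i0} \in [0,1]$ and $\Delta_1 \in [-1,0]$ always lie in
the orthogonality domain. The scaling of the constant term is the unique one
that makes the basis orthonormal, which `gram_matrix()` verifies rather than
assumes. Because the output is *FBP + a learned correction that is linear in
$z^*$*, a zero-initialized model reproduces plain FBP exactly; training can
only be asked to improve on that baseline. The same formula evaluates at any
output grid, so a region of interest can be rendered at arbitrary resolution
and from any detector binning scale with one model.

## Geometry conventions

World coordinates are mm with the isocenter at the origin, x right, y up;
the view angle is the source azimuth counter-clockwise from $+y$; the
detector is flat and equidistant with 0-based sample centers at
$u_k = (k - (D-1)/2)\,\mathrm{pitch}$; images are row-major with pixel
$(1,1)$ top-left and pixel centers on a symmetric grid. Window centering in
the squeezer rounds half away from zero; the fractional residual is carried
by the exact affine index map, so no information is lost to rounding.

## Sinogram squeezing and unfolding

Only a narrow band of each view contributes to a small patch. The squeezer
projects the patch center into every view (closed form), rounds the center
index, and copies a window of width $d$ (after conceptual zero padding by
`pad` cells, since windows near the detector edge may overhang). The stored
array is $N \times d$ instead of $N \times D$ — the memory ratio is exactly
$d/D$ — and the per-view integer offsets make the map between original and
squeezed detector coordinates exact, which is why squeezed-window FBP agrees
with full-sinogram FBP to better than $10^{-9}$ whenever every ray lands
inside the window (an invariant the tests check exhaustively).

Squeezing can distort neighborhoods across window rows, so the sinogram may
first be *unfolded*: the $3\times3$ neighborhood of every sample is stacked
as 9 channels, and the encoder's first layer becomes a $1\times1$
convolution with nine input channels. Contracting the 9 channels with
$1\times1$ weights is algebraically identical to a $3\times3$ convolution on
the unsqueezed sinogram (also a tested invariant), so no local context is
lost. Under the training protocol $d = 64/s$ and $\mathrm{pad} = 256/s$ at
binning scale $s$, which is sufficient for a $128\times128$-pixel patch in
the study geometry below.

## The learned components

The default encoder (`tiny_encoder()`) is deliberately small so that it
trains in minutes on one CPU: four convolutions with 32 channels, ReLU
activations, and a skip connection from the first activation to the output;
$1\times1\times9$ first layer for unfolded input, $3\times3\times1$
otherwise. The interface accepts externally defined encoders with the same
forward/backward contract, so larger super-resolution backbones can be
plugged in where the compute budget allows. Two fixed conditioning constants
keep Adam's geometry sane: the input scale (50) brings filtered-sinogram
values (order $10^{-2}$ mm$^{-1}$) to order one, and the feature scale
(`mu_water/1000`, i.e. one Hounsfield unit in attenuation units) maps the
order-one channel-matching outputs back to the physical scale of the decoder
coefficients. Neither is trained.

Training (`train_step1()`) minimizes the mean L1 discrepancy in HU between
the reconstructed patch and the ground-truth patch, with Adam, one sample
per iteration, and a learning rate that halves at 0.2/0.4/0.6/0.8 of the
run — the same *shape* of halving schedule used at full scale, scaled
proportionally to the shorter desk-scale run. Binning scales are mixed
within training ({1, 2, 4}), so a single model serves all scales. Gradients
flow through the back-projection via its exact adjoint
(`cret_backproject_grad()`); the convolution and channel-matching gradients
are hand-derived and verified against central differences to $10^{-4}$.

The optional restoration stage (`restorator()`, `train_step2_restorator()`)
is a 6-layer residual CNN on the reconstructed image, trained by transfer:
the reconstruction model is frozen, its outputs are paired with ground
truth, and only the restorator is updated. Its last layer is
zero-initialized, so an untrained restorator is the identity and the stage
is strictly plug-and-play.

## The synthetic study

No clinical data ship with the package; a phantom module generates
everything the tests need. Phantoms are sums of ellipses in HU (air
$-1000$): the standard modified Shepp-Logan table, or a water-equivalent
body ellipse with 3–8 random interior ellipses at $\pm150$ HU contrast.
Gaussian lesions ($\sigma = 0.75$ pixels, peak 100 HU — $\sigma$ is
interpreted in pixels of the ground-truth grid, as lesions are defined on
image patches) can be added. Sinograms are ray-driven line integrals (step
$\le$ ¼ pixel, bilinear sampling), corrupted by Poisson counting noise at
$I_0 = 10^6$ incident photons ($p' = -\ln(\max(N,1)/I_0)$; zero counts are
clipped to one photon), then detector-binned by averaging $s$ adjacent cells
(the mean convention keeps line-integral magnitudes scale-invariant; at
$p=0$ the noise variance is $1/I_0$, which the tests verify by Monte Carlo).

The desk-scale study conditions are: SID 600 mm, SDD 1000 mm, 240 views
over $2\pi$; $128\times128$ phantoms at 0.3 mm; $32\times32$ ground-truth
patches. Two detector layouts serve two different purposes:

* `desk_study_config()` (512 cells × 2 mm) makes the detector deliberately
  coarse relative to the image grid. This is the geometry of the
  squeeze-window protocol checks, where the $d = 64/s$ window must cover a
  $128\times128$-pixel patch — the window-sufficiency guarantee constrains
  how fine the detector may be relative to the patch, so demonstrating it
  requires this regime.
* `learning_study_config()` (1024 cells × 1 mm, iso-scaled pitch 0.6 mm =
  2 ground-truth pixels) is the geometry of the learning study: a scanner
  whose native sampling is comparable to the reconstruction grid, where
  *binning* is the resolution bottleneck the learned correction must undo.
  This matters for the out-of-range scale: at the coarse layout, a single
  $s=8$ cell (iso-scaled 9.6 mm) spans the entire patch, and no local
  correction can recover structure from one sample per view — trained
  models were indifferent or slightly harmful there. At the fine layout an
  $s=8$ cell spans a quarter of the patch and the correction learned at
  $s\in\{1,2,4\}$ transfers.

The training run uses 16 phantoms × 2 patches, 400 iterations at learning
rate $3\times10^{-3}$; evaluation uses 10 disjoint phantoms × 2 patches
per scale, including the binning scale $s=8$ that training never sees. The
learning rate, iteration count and encoder variant were selected on a
separate validation set of phantoms, never on the held-out set the tests
report.

What this synthetic study does *not* emulate: anatomical texture, scatter,
beam hardening, detector cross-talk, or the sheer diversity of clinical
data. Passing the learning test therefore shows that the training loop,
gradients, and cross-scale generalization mechanics work — not that the
tiny encoder rivals a full-scale model on real CT.

## Numerical choices

* **Ramp filter**: band-limited Ram-Lak kernel ($h_0 = 1/4\Delta^2$,
  $h_k = -1/(\pi k \Delta)^2$ for odd $k$) on the isocenter-scaled pitch
  $\Delta = \mathrm{pitch}\cdot\mathrm{SID}/\mathrm{SDD}$, evaluated by FFT
  with zero padding to the next power of two $\ge 2D$; optional Hann window.
  The filter window and padding are configuration, since reasonable
  implementations differ here.
* **Back-projection scaling**: $\Delta\beta/2 \cdot \mathrm{SID}^2$ per view
  ($\Delta\beta = 2\pi/N$, full-turn data counts each ray twice), so
  reconstructions approximate $\mu$ in mm$^{-1}$; the magnification weight
  follows the source-to-pixel distance $L_{iq}$. Against an independently
  written reference FBP this costs about 0.2 HU of interior RMSE on the
  Shepp-Logan benchmark (6.5 vs 6.25 HU at 720 views) — absolute calibration
  at the fraction-of-a-percent level, adequate since the comparisons the
  package reports (PSNR/SSIM between methods) are insensitive to a global
  affine map.
* **Window width at out-of-protocol scales**: the training protocol fixes
  $d = 64/s$; `prepare_sample()` floors the window at 8 columns so that
  interpolation neighbors always exist, and `min_window_width()` estimates
  the smallest sufficient window for any patch when the protocol value is
  overridden. Widening the $s=8$ window beyond the protocol value was
  tested and changed nothing measurable — the rays through a centered
  patch only ever touch the central columns.
* **Degenerate inputs**: rays outside the detector (or window) contribute
  zero and are counted per pixel in `meta$n_outside`; sinogram stages only
  advance forward (`raw` → `cos_weighted` → `filtered`), so weighting or
  filtering cannot be applied twice; accumulation is in double precision
  throughout.

## Known limitations

Curved detectors, cone-beam geometries, and iterative reconstruction are out
of scope. The Poisson model ignores electronic noise and detector blur. The
restorator improves L1/PSNR-type fidelity; task-based measures can rank it
differently, and it is therefore optional and applied last. Data
augmentation is exposed as a hook (`train_config(augment = )`) and defaults
to a no-op.
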