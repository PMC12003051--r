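---
title: "Methods: simulating dynamic speckle and quantifying contrast-implementation bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating dynamic speckle and quantifying contrast-implementation bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Laser speckle contrast imaging (LSCI) maps microcirculatory blood flow from
the blur of time-integrated speckle: the spatial speckle contrast
$K_s = \sigma/\langle I\rangle$, computed over small sliding windows
(typically $5\times5$ or $7\times7$ pixels), decreases as scatterer motion
decorrelates the field during the camera exposure $T$. Flow is summarized
either by the single-exposure asymptotic blood flow index
$\mathrm{BFI} = 1/(T K_s^2)$ (valid for $T/\tau_c > 100$) or, more robustly,
by fitting the multi-exposure (MESI) model to $K_s(T)$ to estimate the
decorrelation time $\tau_c$.

Different software stacks implement the sliding-window statistic
differently — square versus circular kernels, different border paddings,
population versus sample variance — and those numerical choices propagate
into $K_s$, and from there into $\tau_c$ and the flow index. This package
provides the machinery to quantify that propagation end to end on synthetic
data whose ground truth is known: a statistically faithful speckle
simulator, a nested-loop reference contrast estimator plus fast vectorized
variants, and the two $\tau_c$ estimators.

## The speckle simulator

A fully developed, polarized speckle field is drawn as a complex circular
Gaussian random field, band-limited in the spatial-frequency plane by a
circular pupil. We use the standard FFT-speckle convention that the speckle
grain size equals grid size divided by pupil diameter, i.e. a frequency
cutoff of $1/(2\,p)$ cycles/pixel for $p$ pixels per speckle; the intensity
autocorrelation FWHM this produces ($\approx 1.03\,p$) matches the nominal
ratio. A ratio $p \ge 2$ keeps the field below Nyquist; the default $p = 3$
samples the grains comfortably above it. Pixels point-sample the field, so
each raw frame's intensity is exponentially distributed and its global
contrast is 1 — the defining property of fully developed speckle (the
simulator emulates no camera noise, no static scatterers and no pixel-area
integration).

Temporal dynamics are imposed in the pupil plane by an autoregressive
update whose per-step coefficient is chosen so that the correlation between
any frame and the start of the sequence equals the prescribed field
autocorrelation $g_1(t)$. For the negative-exponential form
$g_1(\tau) = e^{-\tau/\tau_c}$ (multiple scattering in ordered flow, the
regime measured in rodent-brain arterioles and the default here) the update
is stationary and *every pairwise* lag obeys $g_1$ exactly, so the
intensity correlation satisfies the Siegert relation
$g_2(\tau) - 1 = |g_1(\tau)|^2$ by construction — this is verified
empirically in the test suite. For the Gaussian and square-root-exponential
forms the update reproduces the correlation with the sequence start
exactly, while pairwise correlations between interior frames are
approximated by the ratio $g_1(t_2)/g_1(t_1)$; these forms are provided for
exploration, not used in the headline comparisons.

Time integration averages $n = \lceil T/\mathrm{d}t\rceil$ consecutive
frames with $\mathrm{d}t = \tau_c/20$ by default. At that step the residual
discretization error of $K(T)$ is below 0.1%: the discrete double sum over
sub-frame pairs differs from the continuous integral by a factor
$\tanh^{-1}$-like correction of order $(\mathrm{d}t/\tau_c)^2$. A safety
cap (`max_subframes`, default 20 000) turns pathological requests into an
explicit error rather than silent subsampling. Each exposure of a MESI
ladder uses an independent random stream derived deterministically from one
master seed, so stacks are bit-reproducible.

### Quantization

Camera-like stacks are quantized to 12 bits with the frame mean placed at a
quarter of full scale. For exponentially distributed intensities this
leaves $P(X > 4\mu) = e^{-4} \approx 1.8\%$ of pixels saturated in the
high-contrast (short-exposure) frames. That tail clipping measurably skews
the short-exposure contrast downward and inflates a subsequent MESI
$\tau_c$ fit by roughly 4–6% at $\tau_c = 0.1$ ms. The comparison pipeline
therefore computes contrast on the noise-free floating-point intensities by
default settings of the acceptance analysis, while quantization remains
available (and is the default when writing camera-like stacks) for studies
of bit-depth effects.

## Contrast engines

`contrast_direct()` is the reference: an explicit nested loop over interior
pixels applying the textbook definitions of mean and variance to the
window's member pixels. It is deliberately naive — its only job is to be
unambiguous. The vectorized engines compute local sums of $I$ and $I^2$ via
cumulative sums along rows (each window row is a contiguous chord for both
square and disc kernels) and form
$K_s = \sqrt{\max(E[I^2] - E[I]^2,\,0)}/E[I]$. All accumulation is in
double precision — squared 12-bit values overflow 32-bit accumulators on
large kernels — and the rare negative variances produced by cancellation
are clamped to zero and counted on the returned map. On the valid interior
the sums engines agree with the reference to better than $10^{-9}$, which
the test suite checks property-style over seeded random images.

Border handling follows the conventions of the common implementations:
`reflect` (edge pixel duplicated), `symmetric` (mirrored without
duplication), `constant_zero`, or `none_crop` (border left undefined).
Padding can only affect pixels within $\lfloor\text{size}/2\rfloor$ of the
border, so every analysis here crops that margin before averaging — after
cropping, all square-kernel engines agree with the reference exactly, and
any residual differences between variants are genuine kernel-membership
effects, not edge artifacts.

Two disc-membership rules are provided. The Euclidean rule ($d \le r$)
gives 13 member pixels at diameter 5 and 29 at diameter 7 and is the
package default. The `inclusive` rule ($d^2 \le r^2 + 1$) reproduces the
mask that ImageJ's built-in circular rank filters actually apply — 21 and
37 members for radii 2 and 3. The distinction matters: with only 13
members the circular estimator sits about 12% below the square-5 reference
on correlated speckle at 3 px/speckle, whereas the 21-member ImageJ-style
mask stays within about 4%, the behavior reported for circular-kernel
implementations in practice. Window-size bias is the dominant effect
throughout: smaller windows undersample the speckle statistics and
systematically underestimate $K_s$, which is why $7\times7$ means exceed
$5\times5$ means at every exposure.

The variance divisor defaults to the population convention ($\sigma$ as the
plain RMS deviation), matching the definition $K_s = \sigma/\langle
I\rangle$; the sample ($N-1$) convention is exposed as an option and
relates to it by the exact factor $\sqrt{N/(N-1)}$.

## Flow models

The MESI model implemented is
$$K(T) = \left\{\beta\rho^2\,\frac{e^{-2x} - 1 + 2x}{2x^2}
 + 4\beta\rho(1-\rho)\,\frac{e^{-x} - 1 + x}{x^2}
 + v_{ne} + v_{noise}\right\}^{1/2},\qquad x = T/\tau_c,$$
the canonical normalization in which $K \to \sqrt{\beta}$ as $x \to 0$ for
a fully dynamic field ($\rho = 1$, $v = 0$). The kernel
$h(u) = (e^{-u} - 1 + u)/u^2$ is evaluated through `expm1` with a series
branch below $u = 0.01$, keeping the model stable from $x < 10^{-6}$ to
$x > 10^{3}$ (branch agreement is checked to $10^{-12}$).

`fit_mesi()` minimizes squared residuals in $K$ — the measured observable;
fitting $K^2$ would silently reweight the exposures — with bounded
Levenberg–Marquardt (minpack.lm) restarted from eight log-spaced $\tau_c$
values in [0.01, 10] ms, because the objective has shallow valleys in the
$(\beta, \tau_c)$ plane. The fit is deterministic given the data and start
grid, and refitting from a previous solution reproduces it to solver
tolerance.

Default box bounds are mode-dependent. Experimental mode uses
$0.05 < \beta < 0.5$, $0.1 \le \rho \le 1$, $0 < \tau_c < 10$ ms,
$0 \le v_{noise} < 0.3$ — the instrument-typical ranges for in vivo MESI,
where speckle-to-pixel sampling and depolarization keep $\beta$ well below
1, and where the nonergodic term is pooled into $v_{noise}$. Simulation
mode relaxes only the $\beta$ ceiling to its physical maximum of 1: a
point-sampled 3 px/speckle simulation has an effective
$\beta \approx 0.62$–$0.74$ (set purely by spatial sampling and the
finite-window estimator), and clamping it at 0.5 forces the fit to inflate
$\tau_c$ by tens of percent to compensate — an artifact of the bound, not
of the data. Both bound sets are plain defaults and can be overridden.

The asymptotic single-exposure estimator inverts
$K_s^2 = \beta\tau_c/T$ as $\hat\tau_c = T K_s^2/\beta$, normalized by a
caller-supplied $\beta$ — in the comparison pipeline, each variant's own
fitted $\beta$, since the estimate is meaningless without stating its
normalization. Estimates are flagged unreliable when $T/\hat\tau_c < 100$.
Composed with the exact model, the estimator's intrinsic bias at
$x = 600$ is $-0.08\%$; on finite windows the per-exposure estimates climb
monotonically toward their large-$T$ plateau, and that plateau sits at
$(\beta_{\mathrm{eff}}/\hat\beta)\,\tau_c$ — a reminder that single-exposure
LSCI inherits every bias of both the contrast estimator and the
normalization, which is the argument for MESI.

## The comparison pipeline

`run_simulated_comparison()` reproduces the study design: per exposure it
simulates one integrated frame, computes every variant's cropped contrast
map and its spatial mean, and references each variant against the direct
square kernel of the same size and divisor. Because the sums engine equals
the nested-loop reference to $10^{-9}$ on the cropped region, the reference
is evaluated with the sums engine by default (the literal loop is a flag
away). Each variant's $K_s(T)$ is then fitted in simulation mode with
$\rho = 1$ and $v_{ne} = v_{noise} = 0$, the conditions of a noise-free,
fully dynamic field.

For exposure-cycled acquisitions (e.g. 774 frames cycling through 6
exposures, i.e. 129 sequences per exposure), `average_mesi_sequences()`
averages *contrast maps*, never raw frames — contrast first, then
averaging, preserving the per-frame statistics — and `roi_mean_contrast()`
reduces the averaged maps over named ROI masks, feeding per-ROI MESI fits.

## Problem sizes and what the tests show

The packaged analyses run at $256\times256$ pixels (tests use smaller
frames down to $48\times48$ where only exactness, not statistics, is at
stake). Mean-$K_s$ statistics are essentially size-independent — the mean
over a cropped $250\times250$ map already averages several thousand
independent speckle grains, giving sub-percent Monte-Carlo error — so
conclusions transfer to larger fields unchanged.

Under these conditions the pipeline recovers $\tau_c$ from the square
$7\times7$ estimator to within about 2–7% of truth (slightly above truth at
$\tau_c = 0.1$ ms, essentially unbiased at $\tau_c = 1$ ms), with the
$5\times5$ estimator a few percent further off in the same direction, and
the ImageJ-style circular kernel within 4% of the square reference at every
exposure. The residual positive bias at $\tau_c = 0.1$ ms is the
finite-window sampling bias of $K_s$ interacting with the fit; it shrinks
with kernel size, which is precisely the paper-scale effect this package
exists to expose.

What passing tests do *not* show: real data add camera noise, static
scatterers ($\rho < 1$), pixel-area integration, depolarization and
heterogeneous fields, all of which move $\beta$, add variance offsets and
change the error budget of single-exposure LSCI. The simulator is a
ground-truth instrument for isolating numerical-implementation effects,
not a forward model of any particular camera.

## Known limitations

* Only the exponential-$g_1$ MESI kernel is fitted; speckle-visibility
  estimators and other $g_1$ forms inside the fit are out of scope.
* Non-exponential decorrelation forms are exact only against the sequence
  start (see above).
* The in vivo arm of the original study (hand-drawn ROIs over mouse cortex)
  requires external data; the package ships the machinery (cycle averaging,
  ROI reduction, experimental-mode fits) and validates it on composite
  synthetic stacks with two embedded $\tau_c$ regions.
* Exact byte-level emulation of any third-party library's border
  arithmetic is a non-goal; border modes are modelled as the configurable
  padding variants described above.
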