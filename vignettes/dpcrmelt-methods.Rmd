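---
title: "Methods: droplet dPCR quantification with stepwise melting multiplexing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: droplet dPCR quantification with stepwise melting multiplexing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpcrmelt)
```

## The measurement model

Digital PCR partitions a sample into many nanoliter droplets, amplifies, and
counts which droplets light up. If a target is present at concentration $c$
copies/µL and a droplet holds volume $v$ nL, the number of copies it receives
is Poisson with mean $\lambda = c \, v \times 10^{-3}$. The whole
quantification rests on the fraction of *negative* droplets: with $N$
analyzed droplets of which $n_{neg}$ are negative,

$$\hat\lambda = -\ln\frac{n_{neg}}{N}, \qquad
  \mathrm{SE}(\hat\lambda) = \sqrt{\frac{N - n_{neg}}{N\, n_{neg}}},$$

the delta-method standard error of the log-transformed binomial fraction.
`lambda_hat()` implements this with a 95% CI $\hat\lambda \pm 1.96\,
\mathrm{SE}$; when fewer than 10 negatives or 10 positives remain, the CI is
instead a Wilson interval on the negative fraction pushed through $-\ln$,
which stays finite and asymmetric where the normal approximation fails. A
well with no negatives cannot be quantified, only bounded: it is flagged
`saturated` and reports the lower bound $-\ln\{1/(N+1)\}$. A well with no
positives is flagged `empty`. Concentration follows as
$c = \hat\lambda / (v \times 10^{-3})$, multiplied by the dilution factor
$D$ for the sample-level value; $D$ is always an explicit input because the
droplet phase is what the instrument sees.

Derived statistics reuse this core. The copy-number ratio of a target gene
against a centromeric reference is $R = c_t / c_r$ with a delta-method CI on
$\ln R$, $\operatorname{var}(\ln R) = (\mathrm{SE}_t/\lambda_t)^2 +
(\mathrm{SE}_r/\lambda_r)^2$; calls use the clinical thresholds $R \ge 2$
amplified, $R < 1.5$ normal, and the gap $[1.5, 2)$ is surfaced as
*equivocal* rather than silently rounded to either side. The variant allele
frequency is $f = 100\, c_{mut}/c_{tot}$ percent with the analogous CI.
Mutation *detection* is a separate, deliberately frequentist rule
(`detect_call()`): at least $k_{min} = 3$ mutant-positive droplets and a
clean no-template control; a single NTC positive vetoes the call and raises
a contamination flag.

## Stepwise melting multiplexing (dSMA)

Targets sharing one fluorophore can be separated by the melting temperature
of their probe–amplicon duplex: the duplex fluoresces only at imaging
temperatures strictly *below* its Tm. Imaging the same droplet array at
ascending temperatures $t_1 < \dots < t_J$, one Tm class per step, gives
cumulative loads $\lambda_{cum}(t_j) = -\ln\{n_{neg}(t_j)/N\}$ that sum the
classes still annealed at $t_j$. Per-class loads follow by differencing,
$\lambda_j = \lambda_{cum}(t_j) - \lambda_{cum}(t_{j+1})$ with
$\lambda_J = \lambda_{cum}(t_J)$, so the unclamped class loads sum to the
cumulative load at the lowest temperature by construction. Near
$\lambda_j \approx 0$ sampling noise can push a difference slightly
negative; `dsma_deconvolve()` clamps it to zero and sets a `clamped` flag
instead of erroring, because small negatives are the expected behaviour of
an unbiased estimator at the boundary.

Because all temperatures are imaged on the *same* droplets, the cumulative
estimates are strongly dependent and closed-form per-class SEs would be
wrong. SEs come from a seeded parametric bootstrap over droplets
($B = 200$): per-class positivity is independent Bernoulli with
$p_j = 1 - e^{-\hat\lambda_j}$, and each replicate resamples the droplet
field via a multinomial over the $2^J$ class-status combinations — exactly
the joint law the estimator assumes, at negligible cost.

This arithmetic requires one common denominator $N$ across temperatures,
which the registration stage guarantees (below). The encoding capacity of
the scheme is the product of fluorophores and Tm classes
(`encoding_capacity()`): four probes at two temperatures give 8 codes, i.e.
7 variants alongside one reference.

## The synthetic well generator

Every downstream stage is testable without instrument data because the
`simulate` functions generate droplet-level truth and rendered images.

* **Occupancies** (`draw_occupancies()`): volumes are log-normal with mean
  1.010 nL and CV 3.46% — the measured dispersion of the droplet printer the
  package models; a log-normal is used because only mean and CV are known
  and positivity must be guaranteed. Copies per target are independent
  Poisson draws with mean $c_t v_i 10^{-3}$. Default well size is 20 000
  droplets.
* **Melting rule** (`true_calls()`): a channel is truly positive iff the
  droplet carries a target on that channel with `tm` strictly above the
  imaging temperature. The default synthetic Tm ladder is {63, 73} °C imaged
  at {58, 68} °C. The real assays' probe Tm values are not published; this
  ladder is a stand-in that preserves the decisive property (one class
  quenched between the two imaging points).
* **Rendering** (`render_well()`): droplets become non-overlapping disks
  (sphere-equivalent diameter, $d = (6v/\pi)^{1/3}$; 124.07 µm ≈ 31 px at
  the default 4 µm/px) on a jittered hexagonal lattice with a 2 px minimum
  gap — close-packed but resolvable, like a settled monolayer. Pixel values
  are the droplet's population mean (negative ~N(2000, 100), positive
  ~N(8000, 300) ADU per channel by default) plus additive Gaussian pixel
  noise, clipped to the 16-bit range. Per-(channel, temperature) pages apply
  a configurable integer or subpixel translation, emulating the pixel
  shifts real filter wheels introduce. A 20 000-droplet well does not fit a
  2048² frame at 4 µm/px; it is simulated as four ~5000-droplet tiles, or at
  the occupancy level when no image is needed.
* **Artifacts** (`inject_artifacts()`): coalesced droplets (single disks of
  volume $2v$, diameter $2^{1/3} \approx 1.26\times$), debris (4:1
  high-eccentricity blobs, mask circularity ≈ 0.5), and edge-clipped disks.
  Because close packing leaves no free interior space, the renderer reserves
  spare lattice sites for planned artifacts at render time.
* **Seeds**: one master seed per well; sub-stages derive fixed offsets
  (occupancies +1, placement +2, intensity populations +3, pixel noise +4
  per page, artifacts +5), so every object is bit-reproducible.
* The fixture SNR is defined as (negative-droplet mean − background) /
  pixel-noise SD — the contrast of the *hardest* objects to find.

What the generator does **not** emulate: optical point-spread functions,
illumination shading, spectral crosstalk between channels, intensity "rain"
(present as an option but off by default), droplet drift between pages
beyond rigid translation, and non-Gaussian camera noise. Passing tests
therefore demonstrate the correctness of the algorithms under the stated
model, not instrument-grade performance on real images.

## Droplet detection and QC

The reference detector (`detect()`) is classical and fully deterministic so
it can serve as a reproducible oracle: Gaussian prefilter (σ = 2 px) →
global threshold → fill holes → distance transform → watershed split with
seed separation 0.6× the expected diameter → equivalent-diameter gate. A
learned segmenter can be plugged in behind the same contract and is held to
the same fixture metrics.

Two numerical choices deserve explanation:

* **Global threshold.** Droplet-array histograms are typically *trimodal*
  (background, negative droplets, positive droplets). Plain Otsu, which
  assumes two classes, reproducibly splits negatives from positives and
  loses every negative droplet. The detector instead thresholds at the
  midpoint between the background mode and the next population mode of the
  pixel-density estimate; a Gaussian-blurred step edge crosses that midpoint
  exactly at the true boundary, so the mask is unbiased for the dominant
  (negative) population. Otsu remains the fallback for unimodal images.
* **Per-object sizing.** A single global threshold still biases sizes of
  objects away from the population level: bright positives cross it far out
  on their edge profile and measure oversized, objects dimmer than typical
  get clipped. The measured equivalent radius is therefore debiased
  analytically by inverting the Gaussian edge profile: an object of plateau
  $V$ over background $B$, blurred with the prefilter's $\sigma$, crosses
  the threshold $t$ at radius $r_0 - \sigma\,\Phi^{-1}\{(t-B)/(V-B)\}$, so
  $r_0 = r_{mask} + \sigma\,\Phi^{-1}\{(t-B)/(V-B)\}$ (the $z$-score is
  clamped to $\pm 2.5$). This keeps the equivalent diameter unbiased for
  every intensity class, which matters because the oversize QC gate at
  1.25× the median diameter must reliably catch coalesced droplets at
  1.26×: a 1% decision margin leaves no room for systematic size bias.

Circularity is $4\pi A / P^2$ with the perimeter taken from the traced
8-connected contour chain; on discrete disks ≥ 20 px this measures 0.91–0.98
(the usual discretization excess above/below 1 is clipped at 1.1), and on
4:1 blobs ≈ 0.5, so the 0.85 irregularity gate separates them cleanly. QC
reasons are assigned with priority oversized > undersized > irregular >
overlap > edge; the overlap rule rejects both members of a pair closer than
0.9× the sum of radii (tangency is normal in a monolayer and passes), and
the edge margin defaults to one expected radius.

## Registration across pages

Filter changes shift the whole field by a few pixels. Rather than resampling
images, the pipeline registers *records*: each page is detected
independently, the translation between a reference page and every other page
is the component-wise median of nearest-neighbour displacement vectors
(two matching passes, the second with the first estimate applied — exact for
integer shifts of identical sets), and droplets are greedily matched
one-to-one within 0.5× the median droplet radius, below the close-packing
distance so a neighbour cannot capture a shifted droplet. Only droplets
matched on *every* required page are retained (`build_call_table()`), giving
the single denominator $N$ that the melting arithmetic requires; the dropped
fraction is reported. A translation-only model is used because pages come
from one fixed camera.

## Thresholding and calling

Per-channel thresholds are estimated on the lowest-temperature page — in a
melting design that is where all populations fluoresce — and reused across
that channel's temperatures, since annealed probes of one channel are the
same fluorophore at every step. The estimator (`auto_threshold()`) tries, in
order: the KDE valley between the two highest modes (Silverman bandwidth,
modes below 5% of the main peak ignored); the two-means midpoint when the
clusters separate by more than 4 pooled SDs (this path catches wells with
rare positives whose mode is invisible to the KDE); and otherwise a robust
single-population guard, median + 5·MAD, which deliberately declares the
well all-negative rather than hallucinating positives in NTC wells.
Positivity is strictly greater-than, so boundary values are negative —
conservative toward false positives. Droplets positive at a higher
temperature but negative at a lower one violate melting physics; the
monotone filter drops them entirely (decrementing $N$ consistently) and
reports the inconsistency fraction.

## Known limitations

* **Drop-off assays at high template load.** A drop-off mutant call requires
  the droplet to contain a mutant *and no wildtype* template. At a wildtype
  load of $\lambda_{wt} \approx 3$ per droplet only $e^{-3} \approx 5\%$ of
  mutant droplets are wildtype-free, so the expected countable mutant
  droplets at 0.1% VAF in a 20 000-droplet well is ≈ 3 — exactly at the
  detection rule's boundary. Direct-channel variants do not suffer this
  coincidence loss; at realistic loads the drop-off route needs either
  dilution or larger wells. The limit-of-detection simulation therefore
  evaluates the spiked direct-channel variant.
* The simulator's positives are well separated from negatives by default;
  real chemistries produce rain and partial quenching the thresholds may
  handle less cleanly.
* Registration assumes pure translation; rotation or scale drift between
  pages is out of scope.
* The Tm ladder {63, 73} °C is a stand-in for unpublished probe Tms.

## Problem sizes used by the test-suite

Image-based tests run single-channel wells of 120–500 droplets at roughly
650–750 px square (the geometry of one tile at 4 µm/px), which exercises the
full detection/QC/registration chain in seconds. Statistical property tests
run at the occupancy level, where wells of $N = 20\,000$ are cheap: 200
wells per λ for estimator bias, 500 replicates per λ for CI coverage,
100 seeds for the two-class melting recovery, and 200 bootstrap replicates
inside each deconvolution. These sizes were chosen so each property is
resolved with Monte-Carlo error well below its tolerance band.

## A compact worked example

```{r example}
panel <- assay_panel(
  rbind(target_spec("T790M", "FAM", 73), target_spec("L858R", "FAM", 63)),
  channels = "FAM", temperatures = c(58, 68)
)
cfg <- sim_config(c(T790M = 500, L858R = 500), n_droplets = 20000, seed = 7)
occ <- draw_occupancies(panel, cfg)
counts <- purrr::map_dfr(panel$temperatures, function(temp) {
  calls <- true_calls(occ, panel, temp)$FAM
  partition_counts(length(calls), sum(!calls), temperature = temp)
})
dsma_deconvolve(counts, tm_ladder = c(63, 73), seed = 1) |> tidy()
```

Both classes were simulated at 500 copies/µL (λ ≈ 0.5 each after the 1.010
nL mean volume); the deconvolution recovers them with bootstrap SEs of the
right magnitude, and the two cumulative loads behave as the melting rule
dictates.
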