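---
title: "Methods: quantitative phenotyping of a calmodulinopathy mouse model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative phenotyping of a calmodulinopathy mouse model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calmquant)
```

# The scientific problem

Calmodulin (CALM) is encoded by three genes — *Calm1*, *Calm2*, *Calm3* —
whose transcripts differ but whose protein product is identical. An
arrhythmogenic missense mutation (here, N98S) therefore arrives as one
mutant allele among six, and its phenotypic leverage depends on a chain of
quantitative ratios: the mutant allele's share of *Calm1* transcripts, that
gene's share of the pooled Calm transcript output, the mutant protein's
share of total CALM (which turns out to be far larger than the transcript
share predicts), protein turnover differences that could explain the
discrepancy, and the downstream electrophysiological consequences —
weakened Ca^2+^/CaM-dependent inactivation (CDI) of L-type current, action
potential and QT prolongation, conduction slowing, and ventricular
arrhythmia. `calmquant` implements each of those quantifications as a small,
tested operation, together with generators that produce synthetic inputs
with the same statistical structure, so the whole chain can be validated by
parameter recovery.

# Transcript quantification

**FPKM.** Expression is normalised per kilobase of transcript and per
million mapped fragments: `fpkm = count / (length_kb * library_millions)`.
Isoform counts are pooled per gene before the call. Zero transcript length
or an empty library is rejected rather than propagated as `Inf`.

**Allele fractions.** At a heterozygous tag position, reads carrying each
nucleotide are counted; `allele_fractions()` returns the two fractions and
the reference/alternate fold. When only a fold ratio is reported,
`allele_fraction_from_fold()` inverts it (`1 / (1 + fold)`), e.g. a
2.34-fold excess of wild-type reads implies a mutant fraction of
`r round(allele_fraction_from_fold(2.34), 4)` — approximately 30%.

**Mutant transcript share.** Because the three genes encode one protein,
the functionally relevant quantity is
`alt_fraction * FPKM_Calm1 / sum(FPKM_Calm1..3)`. Shares are reported
rounded to one decimal (the raw value is kept as an attribute); the raw
per-gene shares always total exactly 100%, while three one-decimal
roundings can shift the printed total by up to 0.15.

**2^-ddCt chamber estimates.** Absolute transcript levels in chambers
without RNA-seq are estimated by qPCR relative quantification: per
replicate, dCt = Ct(gene) − Ct(Gapdh); ddCt is the difference of tissue
means; the fold change `2^-ddCt` scales the calibrator chamber's FPKM.
Error margins use `2^-(ddCt ∓ SEM)` with the SEM of the target-tissue dCt
mean — a deliberate convention, since pooling the calibrator SEM is equally
defensible but produces a wider band than the single ± band this estimate
is meant to mirror. The reference gene is a column of the input table
(single reference; no multi-gene geometric mean).

# Protein quantification (stable-isotope dilution)

A synthetic peptide carrying a heavy leucine (six ^13^C, one ^15^N) is
spiked at a known amount; the mass shift is
`6 × 1.003355 + 1 × 0.997035 = 7.017` Da (reported as 7 Da). Quantification
is single-point internal-standard calibration:
`amount = spike * light_area / heavy_area`, which cancels any common
detector gain. Amounts are normalised to total protein (fmol/µg) and
summarised per genotype by median and range, with the even-*n* median
convention (midpoint of the two central values) stated explicitly because
the cohorts have four animals per genotype. The mutant fraction
`100 * mut / (wt + mut)` and its complement always total exactly 100 before
rounding.

# Protein turnover

Cycloheximide-chase densitometry is normalised twice: each band to its
loading control (GAPDH by convention), then to the normalised time-0 value,
making `percent_remaining()` invariant to lane-wise rescaling. A decay fit
(`100 · 2^(−t/half_life)`, Levenberg–Marquardt least squares started from
the log-linear slope) summarises the series; a series with no decreasing
trend is reported as stable (`rate = 0`, infinite half-life) rather than
fitted to a meaningless positive rate. Proteasome-inhibitor experiments are
reduced to fold changes of normalised intensity over vehicle. Biological
replicates should be averaged from technical replicates before fitting;
the two antibody channels (anti-CALM vs anti-HA) are analysed separately
and never reconciled, since their late-time discrepancy is a biological
question, not a computational one.

# ECG phenotype

**Signal averaging** aligns beats at the QRS maximum (or minimum) and takes
the pointwise mean over the common overlap, attenuating independent noise
by ≈ 1/√N. Interval measurement on the averaged complex is manual in
practice and out of scope; interval tables are the input from here on.

**Rate correction.** The exponent *n* of `QT = a · (RR/RR_ref)^n` is fitted
by OLS of ln QT on ln(RR/RR_ref). The reference RR defaults to the series
mean; when pooling a cohort, the cohort mean of per-animal 24-hour average
RR should be passed explicitly. `qtc()` applies
`QTc = QT / (RR/RR_ref)^n`; on noiseless power-law beats the corrected
series is constant to numerical precision, which is the test of the whole
construction. The classical fixed 100 ms normalisation can be emulated by
passing `rr_reference = 100`.

**Arrhythmia scoring** implements the worst-event rubric: 1 none/isolated
PVCs; 2 bigeminy or > 10 PVCs/min; 3 couplet; 4 NSVT of 3–15 s. Sustained
VT (> 15 s) does not raise the score past 4 but is flagged. The score is
monotone under event addition by construction. BVT incidence counts
animals with at least one episode longer than 3 s, not episodes.

# Cellular electrophysiology (CDI)

`r50()` is the fraction of peak current magnitude remaining 50 ms after the
peak, interpolated linearly between samples (the nearest-sample convention
is the obvious alternative; interpolation was chosen and is stated). The
peak is sought in a 2–100 ms window after step onset to skip the capacitive
transient — the window is a convention, configurable, not a reproduction of
an unstated original. `f50 = (r50_Ca − r50_Ba)/r50_Ba` isolates CDI because
Ba^2+^ supports only voltage-dependent inactivation. In the generator's
product-of-exponentials model, `f50 = exp(−50/τ_CDI) − 1` independent of
the VDI time constant, which provides the analytic oracle for the
monotonicity sweep and the cohort decrement test.

# Optical mapping

The per-pixel trace model is a half-cosine upstroke (duration 1 ms) with
exponential repolarisation; level-crossing times are then closed-form,
which is why this template was chosen for the generator. Activation is the
time of maximal dF/dt, parabolic-refined to sub-frame precision; a pixel is
masked when the maximal derivative does not exceed 5× the baseline
derivative SD (a stated convention — the original operational definitions
are not public). APD at level L runs from activation to the first
interpolated crossing of (100−L)% of the amplitude above baseline, so
APD30 ≤ APD50 ≤ APD80 on every valid pixel.

Conduction velocity uses a local 5×5 plane fit of activation time
(gradient → per-pixel velocity vector, speed `1/|∇t|`, degenerate flat
gradients excluded), then bins vectors by direction modulo 180° (10° bins)
and takes bin medians; CV~max~ and CV~min~ are the extreme bin medians and
the fast axis the fastest bin. This reduces correctly in both limits: a
plane wave puts every vector in one bin (CV~max~ = CV~min~), and an
elliptical wavefront spans all bins with medians running from the
transverse to the longitudinal speed.

Default simulated geometry: 41×41 pixels at 0.1 mm pitch, 0.2 ms frames,
speeds 0.6/0.3 mm/ms and APD80 = 40 ms — a realistic mouse epicardial
field of view that resolves the upstroke while keeping a movie at a few
megabytes. On this geometry both speeds are recovered within ~5%;
curvature near the pacing origin biases the plane fit, which is why very
small grids degrade first.

# Histology imaging

Fibrosis is quantified exactly as a colour-threshold method: the fibrotic
mask is a threshold on the blue-minus-red difference image (positive for
trichrome-blue collagen; the sign is configurable for other stains), the
tissue mask a threshold on the unweighted channel-mean grayscale, and the
output `100 · |fibrotic ∩ tissue| / |tissue|`. Thresholds default to Otsu's
method, making the fraction invariant to uniform brightness scaling; fixed
thresholds may be supplied. Whether the original analysis thresholded R−B
or B−R, and at what value, is not stated anywhere public — both directions
are exposed and the default is the one that makes collagen positive.

Striation analysis samples the image along a user-drawn line with a
50-pixel averaging band perpendicular to it (bilinear interpolation), then
detects peaks with prominence ≥ 10% of the profile's dynamic range and
reports the mean peak-to-peak distance, in µm when a pixel scale is given.

# Cohort statistics

Mendelian segregation is tested by chi-square against a 1:2:1 ratio with
expected counts from the observed total (delegated to `chisq.test`, with a
hand-computed oracle in the tests); a zero expected class is rejected.
"Percent of expected" supports both the total-anchored convention and a
wild-type-anchored one, because deficit statements in intercross data are
often anchored on the unaffected class; total-anchored is the default.
The differential-protein filter is the strict rule |log2FC| > 0.5 and
raw P < 0.05 — no multiple-testing correction, matching the filter it
implements.

# What the generators do and do not emulate

Each generator uses a standard positive/count noise model — binomial for
allelic reads, Poisson for fragment counts, multiplicative lognormal (unit
median) for areas, densitometry and QT noise, additive Gaussian for images
and movies — and returns its own ground truth so recovery tests need no
external data. Study-condition defaults are fixed once: sequencing depth
and fractions as printed; chase design 0/6/12/24/36 h; RR range 90–140 ms
for ambulatory mice; 4 animals per genotype and cell counts 21/16/14 where
cohort structure matters.

Passing recovery tests therefore shows the estimators are consistent under
these noise models at realistic sizes — not that real data are this clean.
Real chromatograms have integration errors correlated between channels,
real ECGs have annotation error and circadian structure, real optical maps
have motion artefact and spatially correlated noise, and real trichrome
sections have stain gradients; none of these are simulated, and all are
listed as out of scope of the module surfaces (e.g. no leak subtraction,
no ratiometry, no stain normalisation).

# Numerical choices and degenerate inputs

Fractions and folds reject undefined denominators (zero totals, zero heavy
area, zero vehicle, zero r50_Ba) with explicit messages instead of
returning NaN. Reported percentages are rounded to one decimal only at the
reporting boundary; raw values are always retained. The decay fit treats a
non-decreasing series as a stable protein; the exponent fit refuses a
series without RR variation. Optical-map pixels fail softly (masked `NA`)
because a partial map is useful, whereas scalar statistics fail loudly.
Monte-Carlo tolerances in the test suite are derived from the noise budget
(e.g. a cv = 0.1 light/heavy ratio gives a per-sample fraction SD of about
3.4 points, hence a 5-point budget on a 4-animal median) and are fixed
before use.

# Known limitations

Published correction factors and cohort medians depend on per-animal raw
data that are not redistributable, so those quantities are validated by
construction and recovery rather than reproduction. The CV estimator's
direction-binned medians assume the mapped field samples a reasonable
spread of propagation directions; a heavily cropped field with one
direction collapses CV~max~ and CV~min~ to the same bin, which is correct
for a plane wave but uninformative about anisotropy. The arrhythmia score
consumes annotated event logs; detecting events from raw ECG is expressly
not implemented.
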