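---
title: "From expression matrices to melodies: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From expression matrices to melodies: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonifex)
```

## The model

sonifex maps a probe-set × sample matrix of log2 signal intensities onto
melodies. Three ideas carry the method:

1. **Pitch is scaled intensity.** Each sample is projected onto a virtual
   equal-temperament keyboard. With $SI_{\max}(k)$ the maximal intensity of
   the analysed probe sets of sample $k$, $N$ keys, minimal frequency
   $f_{\min}$ and $step$ tone steps per octave,
   $$\mathrm{key}(i,k) = \left\lceil \frac{SI(i,k)}{SI_{\max}(k)/N} \right\rceil,
   \qquad f(i,k) = f_{\min}\, 2^{(\mathrm{key}(i,k)-1)/step}.$$
   Because the intensities are already log-scale and keys are log-scale
   frequencies, $\log_2 f$ is an affine, stepwise-constant, non-decreasing
   function of the intensity. Per-sample maximum scaling means every sample
   uses the full keyboard regardless of its global signal level; it also
   means the mapping is *relative* — a probe's pitch is only comparable
   across samples to the extent that the samples' maxima are comparable
   (see the generator notes below).

2. **Duration is quantized variance.** The sample variance $s^2(i)$
   (divisor $n-1$; the median pseudo-sample is excluded) of a probe's
   frequencies across samples is mapped to classical note values. With
   minimal length $m$ (fraction of a whole note) and the variance range
   $[s^2_{\min}, s^2_{\max}]$ of the selection context:
   $$val = \left\lceil \frac{s^2}{(s^2_{\max}-s^2_{\min})\,m} \right\rceil,\quad
   unit = \min\left(2^{\lceil \log_2 val \rceil},\, 1/m\right),\quad
   \text{principal} = unit \cdot m,$$
   $$da = \left\lceil \frac{s^2}{(s^2_{\max}/3)\,m} \right\rceil,\qquad
   dots = da \bmod 3,$$
   and the sounded duration is principal × (1, 1.5, 1.75) for 0, 1, 2
   dots. $s^2_{\min}$ is the variance of the $(k{+}1)$-th ranked probe, so
   every *selected* probe sits strictly above it and $val \ge 1$.

3. **The median pseudo-sample is the reference.** Per-probe medians across
   samples (even counts: mean of the two central order statistics) are
   themselves transformed into frequencies, with their own maximum as
   scaling anchor. All melodies are jointly sorted by ascending median
   frequency, so the reference melody rises monotonically and probes
   over-expressed in an outlier sample relative to the cohort surface at
   the start of the piece. The median channel never contributes to
   variances or to the scaling of real samples: it is a sorting and
   comparison reference only.

Diagnostics follow from the aligned structure: per-note absolute
divergence $|f_{\text{sample}} - f_{\text{median}}|$ with an OLS trend
over onset time, and per-probe counts of samples sounding above an
absolute threshold (987 Hz, B5, by default) or at least one octave above
the median.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| `f_min` | 27.5 | Hz | lowest key of a standard 88-key piano (A0) |
| `n_keys` | 88 | keys | full piano compass; key 49 = 440 Hz |
| `steps_per_octave` | 12 | steps | semitone scale; 24 (quarter-tone) and 6 (whole-tone) are supported |
| `min_length` | 1/8 | whole notes | four principal lengths {1/8 … 1}; enters the tone-count rule |
| tone count `k` | `12 × 4 × n_samples` | probes | one octave's worth of steps × principal lengths per sample |
| `seconds_per_whole_note` | 1 (standard), 4 (recalibrated) | s | whole note ≈ 1 s; in template mode the crotchet is the 1 s unit |
| `sample_rate`, `amplitude`, `fade_ms` | 44100, 0.8, 5 | Hz, —, ms | CD-rate PCM; headroom against clipping; click-free note joins |

## Numerical choices and edge cases

* **Non-positive intensities** clamp to key 1 (the raw formula would give
  key ≤ 0); this keeps every probe audible and the mapping monotone.
* **Key-edge boundaries**: an intensity exactly on a key edge takes the
  ceiling of an integer — no epsilon nudging.
* **`frequency_to_key`** picks the nearest key in log-frequency distance;
  exact half-step ties resolve to the upper key; out-of-range frequencies
  clamp to the keyboard edges with a warning (relevant only for
  recalibrated melodies, whose frequencies are continuous).
* **Percentiles** in the group-specificity filter interpolate linearly
  between order statistics (R's type-7 quantile), and the fold-change cut
  is a *strict* inequality evaluated as a log2 difference.
* **Stable sorts everywhere**: variance ranking and median sorting break
  ties by input order, so results are permutation-stable and reproducible.
* **Degenerate variance range** ($s^2_{\max} \le s^2_{\min}$, e.g. all
  samples identical): every probe is assigned the minimal length with a
  warning rather than an error.
* **The dot rule is cyclic, not monotone.** $dots = da \bmod 3$ makes the
  *total* duration non-monotone in $s^2$ at dot-cycle boundaries even
  though the principal length is non-decreasing. We regard the principal
  length as the monotone carrier of "information content" and the dots as
  a finer, cyclic embellishment; tests assert monotonicity of the
  principal.
* **Audio determinism**: pure sine synthesis with linear fades, 16-bit
  PCM; identical inputs give byte-identical files. Peak amplitude respects
  the configured headroom up to one quantization LSB.

## Recalibration

For a template of $M$ notes, the top-$M$ variance probes are melodized as
usual, then the median channel is replaced note-for-note by the template
(in melody order along the sorted probe sequence) and each sample is
rescaled multiplicatively:
$$f_{\text{new}}(i,k) = f_{\text{template}}(i)\,
\frac{f_{\text{old}}(i,k)}{f_{\text{old}}(i,\text{med})}.$$
This is the only rescaling under which each sample's frequency *ratios* to
the reference — the audible dissonances — survive the change of tune, and
it preserves the sample ranking by mean $|\log_2 f - \log_2 f_{\text{med}}|$.
Recalibrated frequencies are left continuous for audio; score export snaps
them to the nearest key. Template durations are taken verbatim (crotchet =
1 time unit = 1 s). The two bundled templates are approximate
transcriptions with the conventional lengths (63 and 86 notes) and are
labelled as such; they are fixtures for testing and demonstration, not
critical editions.

## What the synthetic generator emulates — and what it does not

`simulate_matrix()` draws a per-probe baseline $\mathcal N(7, 2^2)$ on the
log2 scale, adds i.i.d. normal noise (sd 0.3), and plants sample-specific
markers of effect +4 log2 units. Two structural choices matter:

* **Up-markers live on low-baseline probes; the outlier's down-markers on
  high-baseline probes.** A sample-specific transcript is silent in the
  other samples; a transcript silenced *only* in the outlier is, by
  construction, constitutively expressed elsewhere. This also keeps the
  top of the intensity range occupied by shared high-expressors, so the
  per-sample maximum — the key-scaling anchor — is stable across samples
  and for the median profile, as in real normalized array data. Without
  this, scaling mismatch (not biology) dominates the divergence signal.
* **Marker density matches the selected set.** Defaults plant 30 markers
  per regular sample and 90 (half up, half down) for the outlier, so with
  4 samples the planted discriminating probes essentially fill the default
  192-tone selection — mirroring data sets in which the top-variance
  selection consists of sample-discriminating probes.

The generator does **not** emulate probe-level effects, intensity-dependent
(heteroscedastic) noise, correlated gene modules, batch effects, or
exon-array probe multiplicity. Passing the recovery tests therefore shows
that the pipeline orders, scales and diverges as designed under its own
assumptions — not that any particular real data set will separate
audibly.

## Problem sizes used in the test suite

Tests run on matrices of 10–400 probes and 2–7 samples; the parameter
recovery study uses 20 seeded simulations of the default 400 × 4 design
(about a minute in total), and oracle-equivalence checks use 100-point
variance grids and 10-probe toys. These sizes were chosen to exercise every
code path, including the `k+1` boundary and degenerate inputs, while
keeping the default suite fast.

## Known limitations

* Frequency variance is computed in Hz, so high-register probes carry more
  weight than low-register ones at equal log-scale variability; the method
  deliberately over-represents highly expressed genes.
* Score export requires 12 steps per octave; quarter- and whole-tone
  tunings render to audio and plots only.
* The stereo scheme is strictly sample-vs-median; free combinations of
  samples are out of scope, as are MP3 encoding, MIDI and real-time
  playback.
* No statistical significance is attached to divergence slopes or
  high-pitch counts; they are descriptive diagnostics.
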