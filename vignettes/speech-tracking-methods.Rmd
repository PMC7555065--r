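---
title: "Methods: neural tracking of perceived speech on synthetic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neural tracking of perceived speech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(speechtrack)
```

# The problem

Dorsal precentral cortex is classically a motor territory, yet
high-density intracranial recordings show that part of it follows the
acoustics of *heard* speech: its high-frequency-band amplitude (HFB,
65–125 Hz, a proxy for local population firing) co-varies with the
speech spectral envelope at a positive lag of a few hundred
milliseconds, follows the phrasal ON/OFF rhythm of continuous speech,
and prefers clean speech over speech mixed with background sound.
Testing an analysis chain that makes such claims is hard precisely
because the interesting datasets cannot be shared. `speechtrack`
therefore implements the full chain *and* a generator of synthetic
audio-plus-neural data with known ground truth, so that every stage can
be validated by planted-effect recovery and null calibration instead of
by eyeballing irreplaceable recordings.

# The model and its assumptions

## Measurement model (what the generator inverts)

For a tracking channel $e$ with coupling gain $g_e$ and lag $\ell_e$,
the raw signal is

$$ s_e(t) = a_e(t)\, c_e(t) + n_e(t) + 0.5\,\sigma_e \sin(2\pi f_{line} t), \qquad
   a_e(t) = \max\{1 + g_e\, \tilde{x}(t - \ell_e),\, 0\}, $$

where $c_e$ is unit-variance noise band-limited to 65–125 Hz,
$\tilde{x}$ is the speech spectral envelope scaled to unit SD, $n_e$ is
pink ($1/f$ amplitude) noise with SD $\sigma_e$, and $f_{line}$ = 50 Hz.
`onoff_only` channels replace $\tilde{x}$ by the binary speech ON/OFF
vector; `unresponsive` channels have $g_e = 0$. The analysis chain never
sees $a_e$; it must recover $g_e > 0$ channels and their lags from
$s_e$ alone. Because HFB amplitude is what carries the signal, the
preprocessing stage (notch, common average reference, Gabor modulus,
frame averaging) is exercised realistically, including its failure
modes.

## Analysis model

Per electrode and 4-s fragment, tracking is the maximum over lags
$k \in [-100, 500]$ ms (10 ms grid) of the Spearman correlation between
the envelope and the HFB frames, with positive $k$ meaning audio leads.
Maxima are Fisher-transformed, $z = \tfrac12 \log\frac{1+\rho}{1-\rho}$,
and contrasted between conditions with Student t tests
(pooled-variance independent for speech vs nonspeech, paired for
isolated vs mixed tracks), Bonferroni-corrected over the electrode
family under test. Rank correlation is used because both audio and
neural amplitude distributions are strongly right-skewed; a
log-transform + Pearson variant is available behind a flag.

The phrasal-rhythm stage regresses lag-aligned, concatenated HFB frames
on the binary speech ON/OFF vector by OLS (one model over all
fragments, intercept included even though z-scored responses make it
nearly zero — it keeps residuals exactly orthogonal to the design).
Significance comes from a fragment-permutation null: the order of the
fragments is shuffled in the design 10,000 times while responses stay
fixed, and the observed F is compared with the empirical
$(1-\alpha)$ percentile. The published description equates the
"99.999th percentile" with a chance level of .001; those are not the
same number, and this package implements the $(1-\alpha)$ percentile
with $\alpha = 0.001$ (i.e. the 99.9th) as the internally consistent
reading.

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `fragment_duration` | 4 | s | analysis window; 400 frames at 100 Hz |
| `pause_range` | 0.12–0.5 | s | phrasal pauses: ≥120 ms perceptually, ≤500 ms to stay one fragment |
| band | 65–125 | Hz | HFB; bins at 1 Hz, Gabor FWHM = 4 cycles |
| lag window | −100…500 | ms | biologically plausible audio→neural lags |
| lag step | 10 | ms | the 100 Hz frame grid; finer steps are not identifiable |
| `min_overlap` | 300 | frames | rank correlations on fewer frames are too unstable |
| `snr_noisy_db` | 0 | dB | speech/background power in noisy fragments |
| `margin_db` | 35 | dB | sound ON/OFF threshold below the intensity maximum |
| pitch floor/ceiling | 75 / 600 | Hz | autocorrelation search range (standard defaults) |
| `voicing_threshold` | 0.45 | – | minimum normalized autocorrelation for voiced |
| `octave_cost` | 0.02 | per octave | favours the shorter lag among near-equal peaks |
| `alpha` | 0.05 | – | family-wise level, Bonferroni over electrodes |
| `n_perm` / `perm_alpha` | 10,000 / 0.001 | – | permutation null resolution |

# What the generator emulates — and what it does not

Emulated: fragment statistics (counts, durations, pause structure), a
voiced source with pitch contour and syllabic envelope, matched sound
intensity between speech and nonspeech fragments (so the intensity
control t test is null by construction, up to ~10% per-scene jitter),
background at controlled SNR with the clean track retained, neural
channels at 2000 Hz and 512 Hz with line noise and pink noise, and hand
labels drawn independently of condition (so the speech-by-hand
contingency null holds; a dependence knob exists for power studies).

Deliberately not emulated: real music; semantics or phonotactics;
articulatory detail; epileptic or movement artifacts; volume conduction
between channels. A green test on this world therefore establishes that
the *statistics recover what the measurement model plants* — it cannot
establish that real dPCC behaves this way, nor validate artifact
rejection, which the package does not attempt.

Two behaviours of the synthetic world are worth knowing:

* **CAR leakage on small montages.** Common average referencing is
  applied per grid. With only a handful of channels, subtracting the
  grid mean injects a fraction of every responsive channel's
  speech-locked power into every other channel of that grid, and since
  band-limited amplitudes add incoherently this *raises* HFB during
  speech on unresponsive channels. On 128-channel grids the leakage is
  1/128 and negligible; on a 4–8 channel fixture it is visible, and the
  type-I calibration therefore uses all-gain-zero worlds, where CAR is
  exactly harmless.
* **Prosodic f0–intensity coupling.** The speech source scales its
  fundamental by $0.85 + 0.25\,\mathrm{AM}(t)$, so louder syllables are
  higher-pitched, as in natural speech. Without this, pitch would
  relate to the envelope *only* through the voicing gate, which breaks
  the partial-correlation analysis in a way real speech does not (next
  section).

# Numerical choices

* **Gabor atoms**: Gaussian amplitude envelope with FWHM equal to
  4 periods of the centre frequency ($\sigma = \mathrm{FWHM}/2\sqrt{2\ln 2}$),
  truncated at $\pm 4\sigma$, normalized so a unit sinusoid at centre
  frequency has modulus 1; convolution by FFT with reflection padding;
  frames whose wavelet support touches an edge are flagged.
* **Downsampling to 100 Hz** by averaging the (smooth) amplitude within
  10 ms frames — sample-count-based grouping, so 512 Hz (non-integer
  samples per frame) is handled exactly; no phase distortion, and
  fragment means are conserved to <1% versus native rate.
* **Notch**: RBJ biquad, −3 dB width 4 Hz, run forward–backward
  (zero phase) with reflection padding.
* **Cochlear spectrogram**: Hann STFT (32 ms window, 8 ms hop) whose
  magnitude bins are pooled onto 128 log-spaced constant-Q Gaussian
  channels over 180–7200 Hz. Each STFT magnitude bin is the modulus of
  a band-passed analytic signal — i.e. a rectified, smoothed band-pass
  output — so this is an $O(N\log N)$ equivalent of a 128-filter bank
  for the only quantity consumed downstream (the bin-averaged
  envelope), and it is exactly linear in input amplitude. The auditory
  model's nonlinear stages are deliberately omitted.
* **Pitch**: window-corrected normalized autocorrelation per 40 ms
  frame; candidate peaks refined by sinc interpolation (parabolic
  interpolation underestimates the cusp-shaped true-period peak and
  then loses to its on-sample integer multiples); heights clamped at 1;
  octave cost 0.02/octave; unvoiced coded 0 so the series is defined
  everywhere. 0.02 rather than Praat's 0.01 because decisions here are
  per-frame (no Viterbi path smoothing).
* **Ties and degeneracies**: lag ties break toward the smallest |lag|;
  Kruskal–Wallis returns H = 0 when all values tie; paired t on
  identical vectors reports t = 0, p = 1 instead of erroring;
  per-fragment envelope–pitch correlations are skipped (flagged) when a
  fragment has no voicing.
* **Negative best-lags** are clamped to 0 before lag alignment (the
  procedure is defined as a positive shift of up to 500 ms); the count
  of clamped fragments is reported.

# Open design points, resolved

* 2×2 contingency tests use the Yates continuity correction; larger
  tables use none. This is also the only combination consistent with
  the published pair of statistics (1.31 uncorrected 2×3; 0.97
  corrected 2×2). The published df annotation "(2, 609)" for the 2×2
  test is reported here as df = 1, as computed from the table.
* Dunn post hoc p values are Holm-adjusted (no method is named in the
  source description; Holm is uniformly more powerful than Bonferroni
  at the same family-wise guarantee).
* The hand covariate enters the control regression as one ordinal
  column (0/1/2); dummy coding is available behind a flag.
* Fragment selection is greedy earliest-fit within maximal speech runs
  (any deterministic rule is a choice; greedy is reproducible and
  matches the published fragment arithmetic).
* Degrees of freedom are always computed from the actual design rather
  than copied from published tables, whose df bookkeeping is not fully
  reconstructible.
* "Intensity" for the loudness control is mean absolute amplitude;
  RMS is available via `method = "rms"`.

# A knowingly unmet acceptance check

The partial-correlation stage asks that envelope-coupled channels show
significant partial-ρ(envelope | pitch) — they do, ≈ +0.4 — and
*non-significant* partial-ρ(pitch | envelope). In this synthetic world
the second half fails: the pitch partial is ≈ −0.14 and consistently
so across fragments. The cause is structural. Pitch is exactly zero
whenever unvoiced, so rank(pitch) depends on rank(envelope) through a
hard gate; partial Spearman removes only the least-squares *linear*
component in rank space, and the left-over gate nonlinearity is
anti-correlated with the envelope once the ON/OFF offset has been
regressed out of the response. Real speech data evidently sit close to
the linear-copula regime where the published ≈ +0.01 obtains; a
synthetic voiced/unvoiced source with 10 ms frames does not, even with
prosodic f0–intensity coupling. The options — computing partials within
voiced frames only, or relaxing the significance clause — would change
the method or weaken the test, so the check is left failing and
documented here instead. The directional claim (envelope tracking ≫
pitch tracking on residuals) holds and is asserted.

# Known limitations

* Pure R; the Gabor stage is FFT-based but still the slowest step
  (~10 s per channel-minute at 2000 Hz with 61 bins).
* The permutation F test exploits the single-regressor closed form for
  speed when all fragments have equal length; the generic refit path is
  used (and tested equal) otherwise.
* EDF input is not implemented (no reader available in the target
  environment); the neural container is a documented float32 binary
  with a JSON sidecar, plus WAV/TextGrid/TSV for audio and annotations.
* Electrode localization, anatomical labeling and brain-surface
  rendering are out of scope; anatomical labels are metadata supplied
  by the caller or the generator.
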