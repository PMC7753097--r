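---
title: "Linking whole-report processing speed to EEG alpha attenuation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking whole-report processing speed to EEG alpha attenuation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvalpha)
```

## The scientific question

Habitual video gaming — action gaming in particular — has repeatedly been
associated with faster visual information processing. One candidate neural
substrate is the modulation of posterior EEG alpha power (8–14 Hz) after a
visual stimulus has been processed: a post-stimulus *decrease* in alpha power
(event-related desynchronisation, ERD) is read as disinhibited, engaged
processing, an *increase* (ERS) as inhibition. `tvalpha` implements a complete
analysis chain that quantifies both sides of this relationship — visual
processing speed from behaviour and alpha attenuation from the EEG — and the
group-level inference connecting them, together with a synthetic-cohort
generator so that every stage can be validated end to end without access to
participant data.

## The whole-report task and its design arithmetic

Participants fixate centrally; six of ten geometric shapes appear on an
invisible circle (polar angles 30°–330° in 60° steps) for one of six brief
exposures, are masked, and the participant reports every shape they are
confident they saw. There are `choose(10, 6) = 210` distinct displays
(`enumerate_displays()`); a session (`build_schedule()`) comprises a 24-trial
training block and two experimental blocks of 210 trials in which every
display occurs exactly once and each exposure duration exactly 35 times —
444 trials in total. Because a 60 Hz monitor under a non-real-time OS cannot
hit the requested exposures exactly, measured deviations are logged per
nominal duration and each nominal value is corrected by the mode of its
deviation distribution (`correct_durations()`). Deviations are binned to
0.1 ms *before* taking the mode — the mode of a continuous measurement is
otherwise ill-defined — and ties are broken toward the smallest absolute
deviation. With the default timing-log offsets this turns the nominal
16.7–200.4 ms set into 17.8, 35.6, 53.4, 89, 144.6 and 198 ms.

Gaming groups come from self-reported weekly play hours per genre
(`classify_gamer()`): action video gamers (AVGs) play shooter plus
action-RPG/adventure titles for at least 5 h/week combined; non-video gamers
(NVGs) stay within 1 h for each action-style genre, 3 h for each remaining
genre, and 5 h overall; everyone else is a non-action video gamer (NAVG).
The AVG rule is evaluated first. Whether the 5 h threshold is combined across
the two action genres or applies per genre is not uniquely determined by the
questionnaire wording; we default to the combined reading (the genres are
listed jointly) and expose `action_rule = "per_genre"` as the alternative.

## The TVA observer model

In the Theory of Visual Attention, all displayed items race in parallel for a
limited short-term store. Item $x$ is processed at exponential rate

$$v_x = C \, \frac{w_x}{\sum_{z \in S} w_z},$$

so the rates always sum to the total processing capacity $C$ (items/s). With
the uniform attentional weights appropriate for this unstructured task, each
of the $n = 6$ items finishes within an exposure of $t$ ms with probability

$$p(t) = 1 - \exp\!\left(-\frac{C}{n}\,\frac{\max(0,\, t - t_0)}{1000}\right),$$

where $t_0$ is the perceptual threshold below which nothing is encoded. The
number of finished items $B$ is Binomial$(n, p(t))$; the store admits at most
$K_r$ of them, so the reported score is $S = \min(K_r, B)$. A real-valued
capacity $K$ is realised per trial as a two-point mixture on
$\lfloor K \rfloor$ and $\lceil K \rceil$ with weight $K - \lfloor K \rfloor$
on the larger value — the simplest distribution whose long-exposure mean-score
asymptote equals $K$ exactly. `score_pmf()` evaluates this distribution in
closed form (Poisson-binomial convolution for non-uniform weights), and the
mean-score curve (`expected_score_curve()`) rises from $t_0$ with initial
slope $C/1000$ items per ms toward the asymptote $\min(K, n)$ — the geometry
that makes $C$, $K$ and $t_0$ jointly identifiable from accuracy alone.

### Maximum-likelihood estimation

`fit_tva()` maximises the trial log-likelihood over $(C, K, t_0)$, with $C$
on the log scale, by L-BFGS-B from eight fixed diverse starts (one with
$K = 0.5$ so that degenerate all-zero data can reach the lower bound).
Bounds default to $C \in [0.5, 500]$ items/s, $K \in [0, 6]$ items,
$t_0 \in [0, 40]$ ms. The likelihood is computed on the 6 × 7 table of
(duration, score) counts, so fitting is fast and duplicating a data set
cannot change the maximiser. $t_0$ is estimated by default: the task
description implies an origin offset of the exponential curve even though no
threshold parameter is quoted; `estimate_t0 = FALSE` fixes it at 0. Scoring
counts only correctly reported shapes — participants are instructed not to
guess, so reported-but-absent shapes are not penalised. Roughly 192 trials
covering all six durations are needed for stable estimates; the full design
provides 210 per block, and per-block fits (`per_block = TRUE`) feed the
time-on-task analyses. Parameter recovery at the study's own scale
(420 trials, $C = 30$, $K = 3.5$, $t_0 = 10$) places $\hat C$ within ±15 %
and $\hat K$ within ±0.4 in well over 90 % of simulated observers (see the
test suite), and the estimation error shrinks as trials accumulate.

## The EEG alpha-ratio chain

Alpha attenuation is quantified without touching the stimulus interval
itself (whose duration varies by condition and would contaminate the
spectra): a 500 ms window *ending at stimulus onset* is compared with a
500 ms window *anchored at the mask*. Per subject, block, exposure duration
and band, the statistic is

$$\text{alpha ratio} = \log_{10}
  \frac{\overline{P}_{\text{pre-stimulus}}}{\overline{P}_{\text{post-mask}}},$$

with trial-averaged power spectra $\overline P$ first averaged over the
posterior ROI (17 occipital/parietal/parieto-occipital channels) and the
band bins. Positive values indicate ERD, negative ERS. The processing order
is fixed: trial-average spectra → pre/post ratio → ROI/band mean → log10.

Concrete numerical choices:

* **Preprocessing** (`preprocess_eeg()`): 0.1–120 Hz band-pass and 50 Hz
  notch, then common-average re-reference over scalp channels, then
  resampling to 1024 Hz. The filters are zero-phase frequency-domain filters
  (Butterworth-magnitude band-pass, Gaussian notch) applied in a single FFT
  round trip per recording with two real channels packed per complex
  transform; this gives no phase distortion by construction, attenuates
  50 Hz by far more than 20 dB while changing an 11 Hz signal by under
  1 dB, and is an order of magnitude faster at 62 channels than per-channel
  time-domain forward-backward filtering, which is numerically fragile for
  a 0.1 Hz high-pass.
* **Windows and grid**: 500 ms at 1024 Hz = 512 samples, hence an exact
  2 Hz frequency grid. *Medium* alpha uses the 10 and 12 Hz bins, *upper*
  alpha the 12 and 14 Hz bins; the shared 12 Hz bin mirrors the overlapping
  10–12 / 12–14 Hz band edges.
* **Taper**: a Hann window with power normalisation by default
  (`taper = "none"` available). The pre/post *ratio* is essentially
  taper-invariant; the taper only controls leakage.
* **Post-window anchor**: the mask lasts 501 ms, and "after the mask
  display" is ambiguous between its onset and offset. We anchor at mask
  *onset* by default — that window covers the period directly following
  stimulus processing, which is the quantity of interest — and expose
  `post_anchor = "mask_offset"`.
* **Degenerate spectra**: zero-power denominator bins are replaced by
  $10^{-12}\,\mu V^2$ and counted in an attribute.
* Trials whose windows would leave the recording are dropped and counted;
  ratio estimates are treated as stable from about 15 trials per cell
  (35 are available in the full design).

Per-subject *average* ratios — the quantities correlated with $C$ and $K$ —
are unweighted means of the 12 block × duration cells per band, computed on
the log scale (the transform precedes averaging; both orderings were
defensible and this one matches treating the log-ratio as the analysis
variable throughout).

## The inferential chain

`run_pipeline()` reproduces the full chain on a cohort table:

1. **Correlations** (`correlate_tva_alpha()`): four one-tailed Pearson tests
   (average medium/upper ratio × $C$/$K$), directional because stronger ERD
   is expected to accompany faster processing; Bonferroni adjustment with
   family size 4.
2. **Mixed ANOVAs** (`mixed_anova()`): GROUP × TIME-ON-TASK × EXPOSURE
   DURATION on the alpha ratios per band, and GROUP × TIME-ON-TASK on the
   per-block $C$ and $K$ estimates. Type II sums of squares throughout (the
   group sizes 14/15/9 are unbalanced), Mauchly's test per within effect
   with more than one numerator df, Greenhouse–Geisser correction of df and
   p when Mauchly rejects at 0.05 (Huynh–Feldt behind an option), and
   generalized eta squared in the observed-measure formulation
   $\eta^2_G = SS_\text{effect} / (SS_\text{effect} + \sum SS_\text{error})$
   summing the error SS of all strata — the standard choice when all
   factors are observed rather than manipulated measures. The
   GROUP × TIME interaction for 38 subjects in 3 groups has error df
   $N - g = 35$ by design.
3. **Difference regression** (`difference_values()`, `cooks_screen()`,
   `dummy_regression()`): per subject, the block-2 minus block-1 change in
   $C$ (criterion) and in the per-block mean medium ratio (predictor);
   subjects are screened by Cook's distance on the full dummy-coded model
   (threshold 4/n by default — the conventional rule; the threshold is
   configurable since no specific value is canonical), and the reported
   model is
   $Y_i = \alpha + \beta_1 X_i + \beta_2 D_{i,\text{NAVG}} + \beta_3
   D_{i,\text{AVG}} + \beta_4 X_i D_{i,\text{NAVG}} + \beta_5 X_i
   D_{i,\text{AVG}} + \varepsilon_i$ with NVGs as reference. Only the
   whole-model $F(5, n-6)$ is meant for inference; per-group lines are
   recoverable from the coefficients.
4. **Assumption checks** (`assumption_checks()`): Shapiro–Wilk per group and
   Levene across groups, reported but never blocking — the ANOVA is robust
   to the mild normality violations typical here.

Bayes factors and the demographic comparisons are out of scope: they are
prior- and package-dependent and add nothing to the frequentist chain the
package reproduces.

## The synthetic cohort generator

`generate_cohort()` draws 38 subjects (14 NVGs, 15 NAVGs, 9 AVGs) with
per-block true parameters; `generate_behavior()` simulates their 420
experimental trials through the race model; `generate_eeg()` synthesises a
62-channel recording per subject in which posterior-ROI channels carry an
ongoing 11 Hz oscillation whose amplitude drops by the factor $10^{-d/2}$
from the pre-stimulus to the post-mask window — so the band log-ratio equals
the programmed attenuation $d$ exactly in the noise-free limit — on top of
AR(1) background noise on all channels; `generate_timing_log()` emits
deviation samples whose binned mode reproduces the corrected-duration set.

The defaults encode the structure the analysis is designed to detect, chosen
once as plausible magnitudes for this kind of study (no raw group means are
published to copy):

* Group × block mean $C$ (items/s): NVG 44 → 42, NAVG 39 → 45, AVG 38 → 52 —
  NVGs fastest in block 1, gamers overtaking in block 2, AVGs with the
  largest gain; between-subject SD 7, block-level SD 2.5.
* $K \sim N(3.3, 0.5)$ clipped to $[1, 6]$; $t_0 = 15$ ms.
* Attenuation $d$ (log10 scale): NVG 0.04 → 0.05, NAVG 0.04 → 0.08,
  AVG 0.04 → 0.13 across blocks; between-subject SD 0.03, block-level SD
  0.02; an inverted-U duration profile (0.5, 0.7, 0.85, 1.0, 1.15, 0.9)
  peaking at 144.6 ms.
* A latent factor correlates a subject's $C$ level with their attenuation
  level at 0.55, and within AVGs the idiosyncratic block-2 attenuation gain
  feeds into the block-2 $C$ gain with slope 150 items/s per log10 unit —
  producing the positive overall correlation and the strongly positive
  AVG-specific difference-regression slope the analysis should recover.
* EEG: alpha amplitude 20 µV (±20 % per-channel jitter), AR(1) noise with
  SD 4 µV and coefficient 0.95, sampling rate 1024 Hz.
* Questionnaire hours are drawn inside the classification region of each
  subject's group, so `classify_gamer()` round-trips the labels exactly.

What the generator deliberately does **not** emulate: ocular and muscle
artifacts, volume conduction, bad channels, non-stationary alpha peak
frequency, response errors (false reports) and attentional-weight
asymmetries. Passing the end-to-end tests therefore demonstrates that the
pipeline is correct and well-calibrated *given the model assumptions*, not
that those assumptions exhaust real EEG; the artifact-handling steps the
original recordings required (manual inspection, ocular ICA, channel
interpolation) are intentionally out of scope, and the readers accept
pre-cleaned data.

## Problem sizes used in the automated checks

Simulation-based checks run at sizes chosen to make their statistical
targets sharp while keeping the suite practical: score-distribution
simulations use $10^5$ trials (three Monte-Carlo standard errors),
parameter recovery uses 50 observers at the full 420-trial design, null
calibration uses 1000 replicates of the 38-subject design, and the
end-to-end replicates run the complete chain — EEG synthesis included — at
the generator's default effect sizes with 10 EEG trials per
block × duration cell (the alpha-ratio estimation error at 10 trials is
already an order of magnitude below the between-subject attenuation spread,
so cell count, not effect size, is the only thing scaled). One full
35-trials-per-cell subject is exercised separately to pin the study-scale
estimation error.

## Known limitations

* The likelihood is the package's own reading of the whole-report model
  (exponential race, binomial encoding, floor/ceiling capacity mixture);
  published TVA toolboxes implement richer response models (error-aware
  report distributions, alternative $K$ distributions) whose exact form is
  not reproducible from the task description alone.
* Filtering and pigeonholing biases (sensory evidence, category bias,
  pertinence weights) are documented theory context only; estimation beyond
  the uniform-weight special case is out of scope.
* EDF files are not read or written; BrainVision triplets and a plain
  binary + JSON fallback cover file exchange.
* With 9 subjects in the smallest group, the difference-regression slopes
  are descriptive; only the whole-model F is stable — a limitation inherited
  from the design, not the implementation.
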