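---
title: "Scoring spore germination from segmented time-lapse microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring spore germination from segmented time-lapse microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germlapse)
```

## The measurement problem

Fission yeast (*Schizosaccharomyces pombe*) ascospores germinate in three
morphologically distinct stages: a dormant spore is nearly round; it first
swells isotropically (area increases, shape stays circular); it then breaks
symmetry and extends a polarized germ tube; and finally it performs its first
cell division. Time-lapse brightfield imaging (typically one frame every 10
minutes for 1,200 minutes) captures all of this, and modern segmentation
tools turn each frame into an integer *label mask* in which every connected
object carries a positive id. `germlapse` starts where the segmenter stops:
it turns stacks of label masks into quantitative germination statistics.

The package deliberately treats segmentation as pluggable. Any segmenter
(deep-learning or classical) that produces label masks can feed the pipeline;
a minimal Otsu-threshold fallback (`segment_threshold()`) is bundled for
grayscale input, but it is a convenience, not the intended front end.

## Morphometry and the aspect-ratio criteria

Each object is summarized by the ellipse with the same normalized second
central moments as its pixel set. With pixels modeled as unit squares, the
covariance of the pixel centers plus $1/12$ per axis gives eigenvalues
$\lambda_1 \ge \lambda_2$; the axes are $4\sqrt{\lambda_i}$ and the aspect
ratio is

$$\mathrm{AR} = \sqrt{\lambda_1/\lambda_2} \ge 1 .$$

The unit-square correction matters: it makes a solid axis-aligned rectangle's
AR equal its side ratio exactly and gives a single pixel AR $=1$, so the
statistic degrades gracefully. Two AR thresholds drive the scoring:

* **Spore selection.** Only tracks present at time point zero with
  $\mathrm{AR} < 1.4$ there are scored — these are circular and therefore
  likely spores. Strictness at the boundary follows the published rule.
* **First division.** The first frame at which a track's AR strictly exceeds
  $3.0$ is called the time of first division; germinating cells reach an
  average AR of about 3.1 when they divide. Division times are quantized to
  frame times (no sub-frame interpolation), matching the 10-minute sampling
  of the source assay.

One addition is ours: a configurable starting-area floor
(`min_spore_area_um2`, default 3 µm², far below the 7–9 µm² of real spores)
so that small round debris at frame 0 is not scored as a spore. Set it to 0
to recover the pure AR rule.

## Tracking and focus loss

Objects are linked frame to frame by greedy maximal intersection-over-union;
spores barely move between 10-minute frames, so overlap matching suffices
(matches below `iou_min = 0.3` are rejected). When a mask splits — a
division — the fragment containing the parent's last centroid inherits the
track identity and the split (frame, fragment count) is recorded; this keeps
the AR series continuous through division, which the division-calling rule
requires.

Transient focus failures make every object's apparent area dip or spike in
the same frames. Detection therefore uses a population statistic, the median
over tracks of the per-frame relative area deviation, which is robust to
genuine single-cell events (explosions, divisions). Two tests run in
sequence:

1. *Exclusion*: each frame is compared with the midpoint of the track's
   areas `focus_max_run + 1` frames away on either side — anchors a
   tolerable outage can never contaminate on both sides at once. If frames
   whose median deviation exceeds `focus_rel_dev_max = 0.3` form a run longer
   than `focus_max_run = 5`, focus was lost for more than five time points
   and the stack is excluded from analysis.
2. *Repair*: remaining glitches are found against a per-track running median
   over the surrounding frames (excluding the frame itself), replaced by
   linear interpolation, and recorded as gaps.

We first tried a greedy "peel the worst frame" scheme against
nearest-unflagged-neighbor interpolation; it mis-attributes deviations when a
run's neighbors are themselves corrupted, so it was replaced by the two-test
design above, which handles both a single corrupted frame (flagging exactly
that frame) and sustained outages.

## Swelling windows

Swelling is an increase in area without an increase in AR. The source assay
read swelling windows off population plots by eye; `detect_swelling_window()`
algorithmizes this per spore: after a centered moving average of width
`swell_smooth_frames = 5`, a frame qualifies when the smoothed area slope
exceeds 0.5% of the starting area per frame while the smoothed AR slope stays
below 0.005 per frame; the longest qualifying run of at least 3 frames is the
window, clamped to end no later than the called division. A centered filter
anticipates one-sided ramps by about half its width, so the window endpoints
are shifted by `floor(w/2) - 1` (start) and `floor(w/2) + 1` (end) frames:
the start detector is a threshold *crossing* (it fires about one frame late
relative to the raw anticipation), while the end detector is a threshold
*violation* (it fires as soon as any AR rise enters the look-ahead, about one
frame early). With these shifts, recovered endpoints sit within two frames of
the generator's true phase boundaries on noise-free cohorts; both slope
thresholds and the filter width are configurable.

## Phenotype classification

The source study classified outgrowth phenotypes by eye. The package
operationalizes the five categories with explicit geometry, applied in a
fixed order so the labels are mutually exclusive (and the published
"bipolar beats elongated" tie-break is enforced structurally):

1. **exploded** — the track's area collapses by more than 50% within two
   frames and the object disappears or fragments into more than two pieces;
2. **bipolar** — at least two outgrowths whose directions are separated by
   more than 120°;
3. **bubble** — the mask splits while the cell is still circular
   (AR at division < 1.6);
4. **elongated** — maximal outgrowth length strictly above 6 µm
   (normal outgrowths are ~4.5 µm before division);
5. **normal** — any other completed attempt.

Outgrowth geometry comes from fitting the spore body as the maximal disc
centered on the frame-0 centroid that fits inside the mask; everything else
is outgrowth, split into connected components with a length and a direction.
Components shorter than 1 µm or smaller than 5 px are rasterization slivers
and are dropped. All five numeric cut-offs (50%, 120°, 1.6, 6 µm, the
sliver floors) are package choices validated against the synthetic
generator's ground truth — there is no claim that they reproduce any
particular human rater. A spore whose mask splits before its AR ever exceeds
3.0 (the bubble morphology) is *not* counted as germinated by the AR rule;
it still counts as a germination attempt for phenotype fractions, which are
reported over attempts (completed divisions, bubble splits and explosions)
and sum to 100%.

## Vacuole partitioning

For FM4-64 time-lapses, `partition_signal()` measures, at the frame of first
division, the fraction of total in-object fluorescence retained in the spore
body versus the germ tube. The body is the same fitted disc used by the
phenotype rules; background is the median intensity outside all objects,
subtracted with clamping at zero. Subtracting the outside median makes the
fraction exactly invariant to a spatially constant offset, and it is
trivially invariant to gain; both invariances are asserted in the tests.
Whether to sum raw or background-subtracted intensities was an open choice;
background-subtracted was chosen because it makes the statistic independent
of camera offset.

## Longevity and stress statistics

Colony-forming-unit (CFU) tables are normalized per replicate: counts are
dilution-corrected and divided by that replicate's own day-0 value, so
viability at day 0 is exactly 1 and replicate independence is preserved for
the downstream t-test (values above 1 at later days are counting noise and
are not clipped). Longevity is compared by the trapezoidal area under the
viability curve, $\sum_i (v_i + v_{i+1})/2 \cdot (d_{i+1} - d_i)$, with a
two-sided pooled-variance t-test on per-replicate AUCs (Welch available by
flag; pooled is the sensible default at three replicates per group).
Germination-efficiency contrasts use Fisher's exact test — implemented by
direct enumeration of the conditional hypergeometric support under the
standard "sum of probabilities ≤ observed" two-sided rule, with a $1+10^{-7}$
relative tie guard; other two-sided conventions can differ in the third
decimal. Multi-group comparisons use one-way ANOVA with post hoc pairwise
pooled t-tests, reported uncorrected (a Bonferroni column is optional).
Acute-stress assays report percent survival, $100 \times$ treated/untreated
CFUs per replicate, averaged over replicates; replicates with zero untreated
counts are dropped with a warning. An exponential decay rate per storage
condition can be recovered with a Poisson log-linear GLM on raw counts
(`fit_decay_rate()`), which handles zero counts that a log-transform
regression cannot.

## What the synthetic generator emulates

`generate_timelapse()` produces label-mask stacks with full ground truth.
Kinematics are continuous in time and only sampled and rasterized at frame
times, so the truth is independent of the pixel grid; truth aspect ratios
come from one-dimensional quadrature of the continuous shape's half-width
profile. A germinating cell is a swollen disc body of radius $r_s$ plus an
axial tube of half-width $r_o$ with a hemispherical cap; the tube elongates
linearly, the true division time is where the continuous AR crosses 3.0, and
the mask physically splits near AR 3.1 — at least two frames after the
crossing, so the crossing is always observable on whole masks.

Key defaults and their anchors:

| parameter | default | anchor |
|---|---|---|
| frame interval / movie length | 10 min / 120 frames | the source imaging protocol |
| starting area | $\mathcal{N}(8, 0.8^2)$ µm² | true spore areas ~7–9 µm² |
| pixel size | 0.18 µm/px | 60× objective with an 11 µm camera pixel |
| tube half-width | ~1.0 µm | gives outgrowth ≈ 4.7–5.2 µm at the AR-3 crossing, matching the ~4.5 µm seen before first division |
| elongated cells | full-width tube | AR-3 crossing at 7.4–8.4 µm > 6 µm, with late splits up to 20 µm |
| division AR target | 3.1 | mean AR at division |
| dormancy lag | lognormal, median 150 min, sdlog 0.35 | divisions cluster near 500–650 min |
| swelling | +0.02 µm²/min for 180 min | area grows ~45% before polarization |
| vacuole body fraction | 0.64 | body retention in young healthy spores |
| CFU decay | $S(10)=0.5$ (37 °C analog), $S(80)=0.5$ (4 °C analog) | viability half-lives by storage temperature |
| replicates | 3 (CFU), 5 (stress) | the assay designs |

`efficiency` (default 0.9) is the probability that a spore completes the
first division. Because bubble and exploded cells attempt germination but
never reach AR 3, a spore attempts with probability
`efficiency / P(normal ∪ elongated ∪ bipolar)` and the attempt's class
follows `phenotype_probs`; this makes phenotype fractions among attempts
exactly multinomial and the divided fraction exactly `efficiency` in
expectation — both recovery checks rely on it. A consequence is that
`efficiency` cannot exceed the summed probability of the division-completing
classes; the constructor enforces this.

A default field holds 25 spores in a 896×896 px frame; larger cohorts are
generated as multiple fields with consecutive sub-seeds and pooled, exactly
as real experiments image multiple positions. Placement is rejection
sampling on each spore's own final spatial extent, so masks never touch —
the tracker does not handle merging cells, a documented limitation. Debris
specks appear and disappear at random frames (from frame 1 by default).

What the generator does **not** emulate: touching or crowded cells,
segmentation errors other than uniform boundary jitter, uneven illumination,
photobleaching, focus drift (focus loss is tested by perturbing stacks
directly), motile cells, second and later divisions, and any optics/PSF
model. Passing the recovery tests therefore demonstrates that the scoring
rules invert the generative model faithfully — not that they are robust to
every artifact of real microscopy. The CFU generator's exponential decay is
likewise the simplest monotone model, not a claim about true spore-death
kinetics.

## Numerical choices and degenerate inputs

* Ties in tracking are resolved by IoU order; split inheritance falls back
  to the nearest fragment centroid if the parent centroid lands in the gap.
* A single-pixel object has AR exactly 1; absent labels raise errors rather
  than returning NA.
* `compare_auc` with zero variance in both groups returns $p = 1$ for equal
  means and $p = 0$ (infinite $|t|$) otherwise, by convention.
* Fisher's test uses the $\le$-observed rule with a $1+10^{-7}$ tie guard —
  the same guard an enumeration oracle must apply.
* All times are minutes, lengths µm, areas µm²; nothing returns pixel units.
* CSV/JSON writers use fixed number formatting so identical inputs give
  byte-identical outputs; the generator consumes randomness in a fixed
  order from a single seed, so equal seed + config is bit-reproducible.

## Problem sizes used in the checks

The bundled test suite validates morphometry on 100 random blobs against a
brute-force covariance oracle; division-call and efficiency recovery on a
200-spore noise-free cohort (8 fields); phenotype recovery on a 400-spore
cohort (16 fields) with probabilities (0.7, 0.1, 0.1, 0.05, 0.05); vacuole
recovery on 40 spores; t-test calibration on 2,000 null simulations; decay
recovery on 2,000 seeded CFU datasets and its power companion on 500. These
sizes were chosen to make the binomial/multinomial error bounds meaningful
while keeping a full run of the suite in a few minutes on one core.

## Limitations

Beyond the generator's idealizations listed above: the pipeline scores only
the first division (no lineages); the body/outgrowth boundary is a fitted
disc, which under-measures bodies that deform during outgrowth; phenotype
thresholds are geometric surrogates for human judgment and should be
re-validated before applying them to a new strain or imaging setup; and the
focus-loss exclusion rule assumes at least a handful of tracked objects per
frame for the population median to be meaningful.
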