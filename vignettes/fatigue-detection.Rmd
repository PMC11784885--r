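---
title: "Landmark-based fatigue detection: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-based fatigue detection: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perclos)
```

## The detection model

Driver drowsiness shows up in two facial behaviours that a landmark mesh
captures well: eyelid closure and yawning. Given a 468-point facial mesh per
video frame, the package quantifies both with two dimensionless ratios.

The **eye aspect ratio** (EAR) of one eye is the sum of three eyelid
vertical separations over three times the eye-corner width; the frame's EAR
averages the left and right eyes:

$$\mathrm{EAR}_{right} = \frac{|Y_{384}-Y_{381}| + |Y_{386}-Y_{374}| +
|Y_{388}-Y_{390}|}{3\,|X_{362}-X_{263}|}, \qquad
\mathrm{EAR} = \tfrac12(\mathrm{EAR}_{left} + \mathrm{EAR}_{right}).$$

The **mouth aspect ratio** (MAR) is built the same way from eight points on
the *outer* lip contour (inner-contour points are frequently lost across
speakers), corners 61/291 and vertical pairs (39,181), (0,17), (269,405).
Both ratios are quotients of absolute coordinate differences, so they are
invariant under translation, uniform scaling and reflection of the frame —
head distance and image resolution drop out. Only x and y enter; a z
coordinate is carried but ignored, because the formulas are strictly planar.

Per frame, strict comparisons give boolean states: eyes closed iff
EAR $<$ 0.02 (closure drives EAR toward 0), yawning iff MAR $>$ 0.65
(closed mouths rest in the 0.2–0.3 band, yawns plateau near 1.1). When a
face-feature detector supplies per-frame class labels, the combined rule is
applied literally: yawning requires `o_mouth` **and** the MAR test; closed
eyes accept `c_eyes` **or** the EAR test. The asymmetry (AND for the mouth,
OR for the eyes) is kept as specified rather than harmonized.

Maximal runs of in-state frames become **episodes**, reported half-open
(`start`, `end`, `duration = end - start`), so a 20-frame closure has
duration exactly 20 — the half-open convention resolves the off-by-one that
an inclusive end frame would introduce into the run-length difference
`F_e = F_ej - F_ei`.

Within each **unit cycle** of $F_0 = 150$ frames (about 6.5 s at ~23 fps),
four statistics are computed: the PERCLOS scores
$P_{eyes} = \sum (F_{ej}-F_{ei}) / F_0$ and its mouth analogue $P_{mouth}$,
and the longest consecutive runs $F_e$ and $F_m$. The cycle is **fatigued**
iff any enabled criterion holds (inclusive comparisons):

$$P_{eyes} \ge 0.15 \;\lor\; P_{mouth} \ge 0.15 \;\lor\; F_e \ge 20
\;\lor\; F_m \ge 30.$$

Two readings were genuinely open here. First, the printed rule's line
"$P_{eyes} = P_{mouth} \ge 0.15$" could demand both scores at once; we read
it disjunctively — either score suffices — consistent with the surrounding
prose that lists the conditions as alternatives. Second, the prose says
frames "exceed 20" / "surpass 30" while the displayed rule prints $\ge$; the
inclusive form is adopted, so the decision boundaries sit exactly at 20 and
30 frames. Both choices are observable through `cycle_config()` if a user
wants the other convention (`fe_threshold = 21` etc.).

## Windowing and border effects

Cycles tile the sequence at `stride = f0` by default (non-overlapping unit
cycles); a smaller stride slides the window for streaming use. A trailing
partial window is evaluated with $F_0$ as the PERCLOS divisor and flagged
`partial`; the overall verdict is taken over complete cycles, falling back
to partials only when the input is shorter than one cycle. An episode that
straddles a window border contributes its *clipped* overlap to PERCLOS
(PERCLOS is a property of the window) but its *full* duration to
$F_e$/$F_m$ (a sustained closure is a property of the behaviour, not of the
tiling). This means a 25-frame closure centred on a border still trips the
$F_e \ge 20$ criterion in both windows it touches.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `ear_closed` | 0.02 | – | EAR below which eyes count as closed (strict) |
| `mar_yawn` | 0.65 | – | MAR above which the mouth counts as yawning (strict) |
| `f0` | 150 | frames | unit-cycle length (~6.5 s at 23 fps) |
| `perclos_threshold` | 0.15 | – | PERCLOS level that marks fatigue (inclusive) |
| `fe_threshold` | 20 | frames | fatigued consecutive eye-closure run |
| `fm_threshold` | 30 | frames | fatigued consecutive yawn run |
| `stride` | `f0` | frames | window stride |
| `gap_tolerance` | 0 | frames | episode merge gap (`find_episodes()`) |

`gap_tolerance` defaults to 0 because the consecutive-frame statistics are
defined over uninterrupted runs; merging, when requested, affects only run
continuity, never the PERCLOS sums (which always use the raw runs).

Coordinates must be in one isotropic unit — pixels recommended. Mesh
extractors often emit per-axis normalized coordinates, which distort x/y
quotients on non-square images; `read_landmark_table(coords = "normalized",
image_dims = c(w, h))` rescales on read. Whether the 362/263 eye is the
anatomical right or a mirrored image's left cannot be settled from the
index list alone; the package follows the published labels, and since the
verdict uses only the two-eye mean, the choice cannot affect any decision.

## The synthetic generator

`simulate_face()` animates a canonical 640-unit-wide face template (eye
width 80, mouth width 160 units; filler landmarks on an ellipse) through
blink, sustained-closure and yawn events. Defaults encode the regime the
detector assumes: resting EAR 0.10, closed-plateau EAR 0.005, resting MAR
0.25, yawn-plateau MAR 1.1, 23 fps, and a 10-frame linear attack/release
ramp. The resting EAR of 0.10 is a generator choice — published traces show
open-eye EAR comfortably above the closure threshold without quantifying
it — and is freely configurable.

Kinematics are linear attack / plateau / release: the simplest shape that
realizes the stated plateaus. One deliberate detail: ramps interpolate from
the baseline toward the decision threshold over `ramp + 1` steps, so ramp
frames approach but never reach it, the final closing motion happening
within one frame. Sub-threshold frames are therefore *exactly* the plateau
frames, making ground truth unambiguous (truth marks a frame closed/yawning
iff its noiseless EAR/MAR crosses the default thresholds) and letting tests
assert exact event-boundary recovery. Noise is isotropic Gaussian per
coordinate, independent across frames — real landmark jitter is temporally
correlated and anisotropic, so noise-robustness results here are
optimistic in that respect. The generator also cannot emulate head
rotation, occlusion (eyeglasses) or extractor dropouts; a pipeline that
passes every synthetic test has demonstrated its *arithmetic and decision
logic*, not robustness to those real-world failure modes.

With a seed the generator is bit-reproducible, and it restores the caller's
RNG state.

## Detection evaluation

`ciou()` decomposes the complete-IoU score,
$\mathrm{CIoU} = \mathrm{IoU} - \rho^2/c^2 - \alpha v$ and its loss form
$L_{CIoU} = 1 - \mathrm{IoU} + \rho^2/c^2 + \alpha v$, with
$v = \frac{4}{\pi^2}(\arctan\frac{\omega^{gt}}{h^{gt}} -
\arctan\frac{\omega}{h})^2$ and $\alpha = v/(1-\mathrm{IoU}+v)$. At perfect
overlap $\alpha$ is the 0/0 limit; it is defined as 0 there (continuous,
standard practice). Although the formula assigns the two boxes distinct
roles, the squared arctan difference makes $v$ — and hence the score —
numerically symmetric under argument swap; the tests pin that down so the
roles cannot silently drift.

AP uses **all-point interpolation**: the precision envelope (maximum
precision at each recall or higher) integrated over recall — the step-form
of $AP = \int_0^1 P(R)\,dR$ — rather than 11-point sampling, because the
definition is a true integral. Matching is greedy in descending confidence
(ties keep input order) against the highest-IoU unmatched ground truth at
IoU $\ge$ 0.5 by default; the matching rule and the operating IoU are
configurable since neither is dictated by the metric's definition. mAP
averages per-class APs over the five face-feature classes; classes with no
ground truth are excluded with a warning rather than contributing a
meaningless 0.

## Numerical choices and degenerate inputs

* Threshold comparisons are strict for per-frame states and inclusive for
  cycle criteria, exactly as printed; boundary frames (EAR = 0.02,
  MAR = 0.65) are in the normal state, boundary cycles
  (PERCLOS = 0.15, $F_e$ = 20, $F_m$ = 30) are fatigued.
* Zero eye or mouth width makes a ratio undefined: the frame is flagged
  `valid = FALSE` (neither closed nor yawning downstream) rather than
  aborting the run or silently zeroing; a missing or non-finite required
  landmark, by contrast, is a structural error naming the frame and index.
* Episode merging ties: runs separated by exactly `gap_tolerance` false
  frames merge; the merged duration is the full span including the gap.
* All test and acceptance computations run on 150–300-frame sequences —
  one to two unit cycles — which is the natural problem size for a decision
  whose every statistic is defined within a 150-frame window.

## Worked example

```{r example}
sim <- simulate_face(simulation_config(
  n_frames = 150,
  events = list(event_spec("closure", onset = 60, duration = 25))))
report <- classify_sequence(sim$frames)
summary(report)
report$cycles
```

The 25-frame closure gives $F_e = 25 \ge 20$ and PERCLOS
$25/150 \approx 0.167 \ge 0.15$: both criteria fire and the cycle is
fatigued. Five scattered 5-frame closures instead trigger PERCLOS alone:

```{r example-perclos}
five <- simulate_face(simulation_config(
  n_frames = 150,
  events = lapply(c(5, 35, 65, 95, 125),
                  function(o) event_spec("closure", o, 5))))
classify_sequence(five$frames)$cycles[, c("p_eyes", "fe", "triggered", "verdict")]
```

## Known limitations

The detector inherits every upstream weakness of the landmark extractor —
head pose, occlusion, low light — and makes no attempt to compensate
(no smoothing beyond the validity flag, no pose normalization, by design).
The P80 blink-ratio variant of PERCLOS (per-blink openness fractions) is
not computed; the package's PERCLOS is the frame-count fraction within the
unit cycle. Verdicts are per-cycle and per-sequence; no attempt is made to
persist state across separate calls.
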