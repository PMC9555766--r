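---
title: "Methods: vector coding, segment dominancy and step-to-step coordination statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vector coding, segment dominancy and step-to-step coordination statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sprintcoord)
```

# The analysis in brief

`sprintcoord` quantifies how pairs of body segments coordinate during the
first steps of a sprint from blocks. The inputs are sagittal-plane segment
angle time series (trunk, both thighs, shanks and feet, in degrees) together
with gait event annotations (toe-offs and touchdowns with limb side). The
pipeline is:

1. **Filter** each angle series with a zero-phase low-pass Butterworth
   (default 15 Hz cutoff, order 4 per pass).
2. **Segment** the trial into steps: a step runs from one toe-off to the next
   toe-off of the contralateral leg, starting at front-foot block clearance
   (`TO_0`). Flight time is toe-off to the contralateral touchdown; contact
   time is touchdown to the closing toe-off. The swing leg at the opening
   toe-off is *leading*, the stance leg *trailing*; roles alternate every
   step.
3. **Time-normalize** every segment over every step window to 101 points by
   linear interpolation, yielding 100 analysis intervals per step.
4. **Vector coding**: for a segment coupling with proximal angle $\theta_P$
   and distal angle $\theta_D$, the coupling angle at interval $i$ is
   $$\gamma_i = \operatorname{atan2}\!\left(\Delta\theta_{D,i},\,
     \Delta\theta_{P,i}\right) \bmod 360^\circ ,$$
   the direction of the step between adjacent points of the angle–angle
   diagram, measured from the right horizontal.
5. **Classification**: the four quadrants of $\gamma$ encode in-phase (+),
   anti-phase (distal rotating +), in-phase (−) and anti-phase (proximal
   rotating +); each quadrant splits into two 45° bins by dominant segment,
   giving eight coordination bins.
6. **Dominancy**: folding $\gamma$ into $[0^\circ, 90^\circ]$ and converting
   to gradians ($90^\circ = 100$ gon) expresses the distal segment's share of
   the rotation as a percentage; the reported magnitude is the dominant
   segment's share, constrained to $[50, 100]$. $100\%$ means the
   non-dominant segment was stationary over the interval, $50\%$ equal
   rotation.
7. **Group statistics**: pointwise circular means and mean resultant lengths
   $r$ across participants, between-individual variation as a circular SD,
   per-step bin frequencies, and the step-to-step similarity score CA\_Diff.
8. **Inference**: one-way repeated-measures ANOVA (Mauchly sphericity check,
   Greenhouse–Geisser correction, partial $\eta^2$) for discrete
   touchdown/toe-off angles, Friedman tests for bin frequencies, Wilcoxon
   signed-rank pairwise tests, Bonferroni adjustment.

The three supported couplings use a proximal–distal convention: thigh–thigh
(proximal = trailing thigh, distal = leading thigh), trunk–shank (proximal =
trunk) and shank–foot (proximal = shank). Intra-limb couplings use the limb
in stance during the step — the leading limb, since it touches down within
the step. This is the reading most consistent with stance-phase
interpretation of the profiles (e.g. dorsiflexion after touchdown); the
alternative (trailing limb) would describe a limb that is airborne for the
whole step.

# Conventions and tunable parameters

**Angle sign convention.** Angles are measured anticlockwise-positive as
viewed from the athlete's right with motion left-to-right, so clockwise
rotation (forward lean of trunk or shank, plantarflexion of the foot as the
heel rises) decreases the angle. An upright trunk or shank sits near 90° from
the right horizontal; a flat foot near 0°. Only increments enter the coupling
angle, so any constant offset per segment is immaterial to the coordination
results; the convention matters only for interpreting direction (+/−) labels.

**Time base.** Seconds from recording start. Events carry times, not frame
numbers; converting from a 120 Hz video frame index is the caller's job.

The parameters that matter, with defaults (see `analysis_config()`):

| parameter | default | units | why |
|---|---|---|---|
| `n_norm_points` | 101 | points | 100 intervals per step; standard normalization for gait cycles |
| `lowpass_cutoff` | 15 | Hz | matches the customary low-pass for sprint kinematics at 200 Hz; `NA` disables |
| `filter_order` | 4 | — | per pass; applied forward–backward for zero phase |
| `circular_sd_formula` | `"angular_deviation"` | — | $\sqrt{2(1-r)}$, in degrees; `"log"` gives $\sqrt{-2\ln r}$ |
| `bin_boundary_rule` | `"distal"` | — | see below |

# Numerical choices, boundaries and degenerate inputs

**Interval attribution.** 101 normalized points give 100 coupling angles;
interval $i$ is plotted at normalized time $i\%$. Touchdown percentage is
computed from raw event times, not snapped to the normalized grid.

**Bin boundaries.** Bins are half-open $[\ell, \ell + 45^\circ)$ sectors,
with one deliberate exception. On an exact quadrant diagonal (45°, 135°,
225°, 315°) the two segments rotate equally and dominancy is exactly 50%: a
tie. We assign ties to the *distal* segment, and therefore assign the
boundary angle to the distal-dominant bin of its quadrant, so that
`classify_bin()` and `dominancy()` can never disagree about which segment
dominates. At 135° and 315° this differs from the plain half-open rule
(there the upper sector is the proximal-dominant one); `bin_boundary_rule =
"lower"` restores plain half-open sectors for users who prefer strict
sector arithmetic. On real (continuous, noisy) data exact diagonals have
measure zero, so the choice is invisible; it only matters for constructed
inputs and grid sweeps.

**Undefined coupling angles.** When both increments are exactly zero the
direction is undefined. Such intervals inherit the previous defined bin when
one exists (flagged `inherited` in the profile), otherwise they stay
undefined and are excluded from bin frequencies and from both numerator and
denominator of CA\_Diff. Recorded data never hits this; synthetic or
resting-segment data can.

**Circular SD.** The between-individual variation is the angular deviation
$\sqrt{2(1-r)}$ (in radians, reported in degrees), with
$\sqrt{-2\ln r}$ selectable. Both are standard in the vector-coding
literature; they agree closely for moderate dispersion and diverge as
$r \to 0$ (the angular deviation is bounded at $\sqrt 2$ rad ≈ 81°, the log
form is unbounded). The mean profile's displayed bin and dominancy are
classified from the circular-mean coupling angle, matching how mean
coordination profiles are coloured.

**CA\_Diff.** Bins are compared on the 8-ring: distance
$d = \min(|a-b|, 8-|a-b|) \in \{0..4\}$ per interval, summed and expressed as
a percentage of the maximum ($4$ per compared interval). 0% means identical
bin sequences; 100% means diametrically opposite everywhere.

**Sphericity.** Mauchly's test runs on the orthonormal-contrast covariance;
the Greenhouse–Geisser $\hat\varepsilon$ (lower-bounded at $1/(k-1)$)
corrects degrees of freedom and p only when Mauchly p < 0.05, mirroring
common applied practice of correcting only violators. Effect size is partial
$\eta^2 = SS_{\text{effect}} / (SS_{\text{effect}} + SS_{\text{error}})$.
The Wilcoxon signed-rank p is exact (full enumeration) for $n \le 25$
without ties, else a tie-corrected normal approximation with continuity
correction. The Friedman statistic uses mid-ranks with the tie-corrected
denominator; an exact permutation p (full $k!^n$ enumeration) is available
for small designs. The chi-squared approximation is accurate in the
rejection tail but can deviate from the exact distribution by more than 0.1
mid-distribution at $n = 6, k = 3$ — a known small-sample property worth
remembering when quoting non-significant Friedman p-values from small
cohorts.

# What the synthetic generator emulates — and what it does not

`generate_trial()` builds seven smooth angle series plus a consistent event
list from piecewise cosine-ease segments anchored at event-time targets:

- **Thighs**: anti-phase oscillation. Within each step both thighs follow a
  single shared ease shape; the trailing thigh rotates forward by
  `thigh_rise` degrees while the leading thigh retracts by
  `thigh_rise / thigh_ratio`. Because the shape is shared, the increment
  ratio — hence the coupling angle and dominancy — is *exactly* constant
  within the step: $\gamma = \operatorname{atan2}(-1/\rho,\,1)$ for ratio
  $\rho$, the anti-phase trailing (+) bin for $\rho > 1$. The default
  $\rho = 1.45$ yields ≈62% trailing dominancy, in the range reported for
  accelerating sprinters. The price of an exactly constant within-step ratio
  is a slow upward drift of the thigh oscillation midline across steps
  (rise ≠ drop); over four steps this stays within physiological angles and
  is accepted as a deliberate simplification.
- **Trunk**: clockwise rotation (decreasing angle) during flight, reversal
  at touchdown, anticlockwise rise through stance, with a per-step
  verticalization increment (default 6°/step) — the step effect the
  repeated-measures ANOVA power checks target.
- **Shank/foot** (stance limb): shank rotates forward (clockwise) over the
  foot through stance from a touchdown angle that verticalizes across steps;
  the foot lands steeply in step 1 and flatter later, rises toward flat in
  early stance (dorsiflexion, anti-phase with the shank) and plantarflexes
  sharply into toe-off.
- **Noise**: additive, band-limited below 30 Hz so the 15 Hz analysis
  low-pass meaningfully attenuates it; applied in angle space before any
  filtering. Between-participant structure comes from jittered timing,
  ratio, rise and anchor targets.

Event times are snapped to the sampling grid. This guarantees that no
sampling interval straddles a step boundary, so the generator's within-step
increment ratios survive sampling and linear time-normalization exactly —
that is what makes the closed-form ground-truth recovery tests exact rather
than approximate.

What the generator does **not** emulate: soft-tissue artifact and sensor
fusion error (the noise is smooth and stationary), inter-segmental dynamics
(no physics — anchor targets are chosen, not computed), asymmetries between
left and right beyond role alternation, step-length/velocity coupling, and
every nuance of real profiles (e.g. the brief in-phase periods around
touchdown seen in some athletes arise only partially from the default
anchors). A green ground-truth test therefore establishes that the
*pipeline* is faithful to the vector-coding definitions, not that the
generator reproduces any particular athlete's data.

# Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_participants = 5, rng_seed = 1)
cohort <- generate_cohort(cfg)

profiles <- unlist(lapply(cohort, trial_profiles, coupling = "thigh_thigh"),
                   recursive = FALSE)
bin_frequencies(profiles[[1]])
attr(ca_diff_table(profiles), "summary")

gp <- group_profile(Filter(function(p) p$step_index == 1, profiles))
head(gp[, c("pct", "mean_deg", "r", "sd_deg", "mean_bin_label")])
```

# Known limitations

- Joint angles (hip, knee, ankle) are not computed: the input contract
  carries segment angles only, and joint conventions vary; discrete
  kinematics are reported for trunk and the stance-limb thigh/shank/foot.
- The inferential layer assumes complete participant × step matrices
  (listwise completeness), as the analyses it mirrors did.
- The exact Friedman permutation test is limited by full enumeration
  (`factorial(k)^n` arrangements); it refuses rather than approximates.
- Circular inferential tests (e.g. Watson–Williams) are out of scope; group
  inference runs on frequencies and discrete angles.
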