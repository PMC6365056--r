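---
title: "Decision bias, evidence accumulation and neural response gain: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision bias, evidence accumulation and neural response gain: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(driftgain)
```

# The scientific problem

In a go/no-go visual detection task, observers can be pushed toward a
liberal or a conservative response policy by instructions and asymmetric
penalties. Signal detection theory summarises such a policy shift as a
movement of the criterion *c*, but says nothing about *how* the decision
process changes over time. Two dynamic accounts are distinguishable with a
drift-diffusion model (DDM): the accumulator may start closer to one
decision bound (a starting-point bias, *z*), or the rate of accumulation
itself may be biased toward a bound by a stimulus-independent constant
added to the drift (a drift bias, *db*). The two accounts make different
predictions about the shape of the response-time distribution, so they can
be told apart by fitting both model variants and comparing fit quality.
`driftgain` implements that comparison, the signal-detection summaries, the
EEG-style spectral statistics that accompany it (pre-stimulus alpha,
stimulus-induced gamma, frontal theta, cluster-based permutation
inference), the sigmoidal response-gain model connecting alpha to gamma,
and the repeated-measures correlation connecting gamma to drift bias — all
exercised end to end on synthetic data from the package's own generator.

# The go/no-go diffusion model

A decision variable starts at $z = z_{frac} \cdot a$ between an absorbing
lower bound $0$ and upper bound $a$, and evolves as

$$dy = (\pm v + db)\,dt + s\,dW,$$

with drift $+v$ for targets, $-v$ for nontargets, drift bias $db$ added in
either case, and Gaussian increment noise of scale $s$ (fixed at $s = 1$;
all parameter magnitudes are interpreted under this scaling convention).
An upper-bound crossing produces a button press at the crossing time plus
the non-decision time $t_{nd}$ (encoding plus motor latency, a single
summed parameter); presses later than the 0.84 s response deadline are
censored into the no-response category, mirroring the task's response
window. A lower-bound crossing is an *implicit* target-absent decision:
no overt response is recorded.

Simulation is Euler–Maruyama in compiled code. The step `dt = 1e-3` s is
the generator default; `1e-4` s is used wherever a simulation serves as a
numerical oracle, because the boundary-crossing bias of the Euler scheme
scales with $\sqrt{dt}$.

## Quantile G-square fitting

Press-trial RT distributions are summarised by their 0.1/0.3/0.5/0.7/0.9
quantiles (type-7 empirical quantiles; ties broken by stable sort; press
RTs below the 200 ms cutoff are discarded), giving six RT bins with
expected proportions (.1, .2, .2, .2, .2, .1), plus a single bin counting
no-response trials. For each condition-by-stimulus cell the model's bin
probabilities come from the Wiener first-passage density through the upper
bound, computed with the classic dual (small-time / large-time) series
representation, whichever converges faster at the requested tolerance, and
integrated with composite Gauss–Legendre panels. Sub-cutoff press
probability mass is truncated and renormalised symmetrically with the
observed counts; expected probabilities are floored at $10^{-10}$ and
renormalised so the objective stays finite. The objective is the
multinomial deviance

$$G^2 = 2 \sum_i O_i \ln \frac{O_i}{N p_i},$$

summed over cells. Cells with fewer than 10 retained presses collapse to
median-only binning and are flagged; all-no-response cells degenerate to a
single bin and are flagged.

## The three bias variants and BIC

Drift rate, boundary separation and non-decision time are free per
condition in all variants. The *fixed* variant shares both $z_{frac}$ and
$db$ across conditions; *starting_point* frees $z_{frac}$ per condition;
*drift_bias* frees $db$ per condition. The two bias variants therefore
have equal parameter counts and their BIC difference reduces to their
$G^2$ difference. We rank models by $BIC = G^2 + k \ln N$: because $G^2$
is a deviance against the saturated multinomial, BIC *differences* match
differences of $-2\ln L + k \ln N$, which is all that ranking needs. The
convention is recorded in the fit object.

## Optimisation

The conditions share only the bias parameter(s) a variant keeps fixed, so
the fit is organised as a profile search: the shared parameter is scanned
over a coarse grid (centre-out), each grid point solving two independent
4-parameter (3 for the fixed variant) bounded Nelder–Mead problems that
warm-start from the nearest already-evaluated grid point, with jittered
random restarts at the first (central) point and a data-informed start
(unit boundary, moderate drift, $t_{nd}$ just below the earliest observed
quantile) everywhere. The incumbent region is refined twice and finished
with quadratic interpolation through the bracketing profile points. Every
evaluation stores its solution, so the procedure is deterministic given
the seed. Bounds are enforced by penalty (box: $v \in [-6, 6]$,
$a \in [0.3, 4]$, $z_{frac} \in [0.05, 0.95]$, $db \in [-6, 6]$,
$t_{nd} \in [0.05, 0.6]$ s). This profile design replaced a raw
9-dimensional simplex during development because the joint objective has a
pronounced $z$–$db$ ridge on which a single simplex stalls
unpredictably; the profile search converged to the same optima where the
simplex succeeded and rescued the cases where it failed.

## Bin-wise refits

For the alpha-binned analyses the drift bias is re-estimated per alpha bin
as a one-dimensional profile refit: the non-bias parameters stay at the
subject's condition-level estimates and each bin's $db$ minimises that
bin's $G^2$. Bin-wise starting points come from the analogous refit of the
starting-point variant. A full joint fit freeing 20 bin-wise parameters at
once would be slower and far less stable with no benefit at the bin sizes
involved.

# Signal-detection summaries

$d' = Z(H) - Z(FA)$ and $c = -\tfrac12 [Z(H) + Z(FA)]$ with $Z$ the
inverse standard normal; positive $c$ is conservative. Rates of exactly 0
or 1 are corrected by the log-linear rule, $(k + 0.5)/(n + 1)$, applied
only to the offending rate and flagged in the output (the correction is
configurable because no specific rule is canonical). Sessions are pooled
within subject and condition before computing rates.

# Spectral estimation

Three presets mirror the analysis settings: a sliding 0.4 s Hann window
(50 ms steps) on a 1 Hz bin grid for 3–35 Hz; a five-taper DPSS multitaper
estimate at ±8 Hz nominal smoothing on a 2 Hz grid for 36–100 Hz (the
time-bandwidth product $2 \cdot 0.4 \cdot 8 - 1 = 5.4$ admits five
tapers); and a single 1 s window centred 0.5 s before trial onset on a
0.5 Hz grid for 1–35 Hz. Finer-than-native frequency grids are reached by
zero-padding, declared in the cube metadata. DPSS tapers are computed from
the standard symmetric tridiagonal eigenproblem. Power is scaled
one-sided, $2|X|^2 / f_s$, with unit-energy tapers; since every statistic
downstream is a ratio (percent modulation) or a comparison, only relative
power matters and the absolute normalisation is a recorded convention.
The nominal "4.5 Hz smoothing" of the single-Hann mode is metadata only:
actual smoothing is determined by the window length.

Percent modulation is $(x - b)/b \times 100$ with $b$ the mean baseline
power (−0.4 to 0 s) per frequency, channel and *condition*. Trial alpha is
the mean raw 8–12 Hz power over −0.8 to −0.2 s (staying half a window from
onset) over a posterior electrode pool, with a per-subject ±3 SD exclusion
mask; trial gamma is the mean modulation over 59–100 Hz, 0.2–0.6 s, same
pool. Pools are label-driven (posterior: Oz, POz, Pz, PO3, PO4, P1–P6;
frontal: Fz, Cz, FC1, FC2; ERP channel C4) and overridable. The ERP is a
zero-phase 4th-order Butterworth low-pass at 8 Hz followed by trial
averaging.

# Cluster-based permutation inference

Per-bin paired t statistics against zero across subjects are thresholded
at two-sided $p < 0.05$; supra-threshold bins of equal sign are joined
under 4-connectivity in the time-frequency plane plus a user-supplied
channel adjacency (a ring by default for synthetic grids). The cluster
statistic is the summed t (maxsum). The null is the maximum |mass| over
subject-level sign flips (1000 by default), which controls the two-sided
family-wise error without doubling; corrected
$p = (1 + \#\{null \ge obs\})/(1 + n_{perm})$. When $2^{N}$ does not
exceed the permutation budget the flips are enumerated exactly and the
result says so. Scalar condition contrasts use the same sign-flip logic as
a paired two-sided permutation test (10,000 permutations), exact when
feasible.

# The response-gain model

Population output is a logistic function of total synaptic input
$S = S_x + S_N$:

$$O(S) = \frac{A}{1 + e^{-k (S - S_0)}}, \qquad
g(S) = \frac{dO}{dS} = \frac{k\,O\,(A - O)}{A},$$

bell-shaped in $S$ with peak $kA/4$ at $S_0$. The response-gain literature
this analysis follows does not commit to a specific sigmoid; the logistic
is this package's default and the form is configurable. Endogenous input $S_N$ falls monotonically with pre-stimulus
alpha (lower alpha = higher excitability); the default mapping is linear,
$S = (\alpha_0 - \alpha)/\alpha_{scale}$. A condition-specific amplitude
$A$ (liberal ≥ conservative) raises the whole gain curve, which is the
model's account of the stronger stimulus-induced gamma under a liberal
policy.

Trials are sorted by alpha per subject and condition into 10 equal-count
core bins whose membership windows extend half a core width into each
neighbour (edge bins extend inward only), one concrete reading of "50%
range overlap" that is pinned down by an enumeration test (n = 100 gives
bin sizes 15, 20 × 8, 15). Binning is rank-based, hence invariant to
affine rescaling of alpha. The inverted-U test uses the ten-bin Gaussian
contrast weights (−1000, −991, −825, 295, 2521, 2521, 295, −825, −991,
−1000; they sum to zero): each subject's profile is reduced to a contrast
score and scored against zero with a one-sample test reported as
$F(1, N-1) = t^2$ — exactly the single-degree-of-freedom contrast of the
repeated-measures ANOVA, without the full mixed-model machinery. The
condition × bin interaction applies the same test to
liberal-minus-conservative profiles. Error bars for within-subject designs
remove each subject's mean before computing the SEM.

# Repeated-measures correlation and controls

rmcorr is the analysis-of-covariance formulation: subject as factor, a
common slope for the covariate; $r$ carries the slope's sign and magnitude
$\sqrt{SS_x / (SS_x + SS_{err})}$, with $df = N_{obs} - N_{subjects} - 1$
(125 for 14 subjects × 10 bins) and the p-value from the common slope's
$F(1, df)$. Robustness refits exclude observations whose Cook's distance
exceeds five times the average and recompute the correlation with df
reduced accordingly. The joint control regresses gamma on bin-wise drift
bias *and* starting point together (subject-centred), reporting each
predictor's partial F. The theta control regresses each subject's bin-wise
drift bias on standardised theta, gamma and their product and tests each
coefficient across subjects ($F(1, N-1) = t^2$); this matches the reference analysis's
degrees of freedom of the original two-way repeated-measures formulation,
which is inconsistent with a 10-level factorial ANOVA and is therefore
interpreted here as a within-subject regression.

# The synthetic-study generator

The generator is first-class, tested code; it emulates the study's
conditions rather than any particular recording:

* **Design.** Blocks of 240 trials with exactly 180 targets and 60
  nontargets (exact counts, not binomial draws), liberal and conservative
  blocks alternating (first block counterbalanced across subjects), ITI
  uniform on 0.3–2.2 s (generated for epoch realism, unused by the
  statistics), response deadline 0.84 s. Default 14 subjects × 6 blocks
  per condition.
* **Behaviour.** Choices/RTs from the go/no-go DDM at the reference
  group-mean parameters: liberal $v = 2.39$, $db = 2.08$; conservative
  $v = 3.06$, $db = -0.04$; shared $z_{frac} = 0.24$. Boundary separation
  and non-decision time are not part of the reference parameter set; $a = 1.0$ and
  $t_{nd} = 0.28/0.32$ s (liberal shorter, matching its reference
  direction) were calibrated from the closed-form press probabilities so
  the synthetic hit/false-alarm rates land near the reference median
  counts (liberal ≈ .87/.16, conservative ≈ .70/.02). Between-subject
  jitter: v sd 0.4, db sd 0.35, z sd 0.03, a sd 0.08. In the *coupled*
  study the trial-level drift-bias variability (below) adds
  response-rate spread, so $a = 1.0$ reproduces the reference rates; the
  single-subject recovery harness has no such variability and uses
  $a = 0.8$, calibrated against the same counts without it (conservative
  H ≈ .71 / FA ≈ .014, liberal H ≈ .84 / FA ≈ .20). The distinction
  matters for identifiability: with too large a boundary the conservative
  condition yields almost no false alarms, and an empty false-alarm cell
  leaves the conservative drift bias unidentified along a v–db ridge.
* **Scalars.** Alpha is log-normal (positive support by construction) with
  condition-specific log-median ($\ln 17$ liberal vs $\ln 20$
  conservative, sd-log 0.35 — arbitrary units; the study reports no
  distribution, so a right-skewed positive law was chosen as typical for
  band power). Gamma modulation is the subject's condition gain curve
  evaluated at the trial's alpha plus Gaussian noise (sd 10 percent —
  single-trial EEG gamma is far noisier than its mean; this choice makes
  bin means informative at study-scale trial counts without making single
  trials so). Amplitudes $A$ = 12 (liberal) vs 8 (conservative), ratio
  1.5, CV 25% across subjects; $k = 1.5$, $S_0 = 2.3$,
  $\alpha_0 = 30$, $\alpha_{scale} = 5$, placing the gain peak near alpha
  ≈ 18.5, interior to both conditions' bin ranges. Theta is a condition
  mean (2.0 liberal vs 1.6 conservative) plus noise (sd 0.4).
* **Coupling.** In the full coupled simulation the trial's drift bias is
  the condition value plus 0.15 × the subject-and-condition-centred gamma
  modulation, so bin-wise drift bias rises with bin gamma — the structure
  the rmcorr stage is supposed to recover.
* **Raw epochs.** −1.0 to +1.25 s at ≥256 Hz: posterior channels carry a
  25 Hz frame-locked pulse train (25% duty, so the 50 Hz first harmonic is
  present, as a non-sinusoidal drive implies) after onset and a
  condition-amplitude 10 Hz pre-stimulus oscillation; frontal channels a
  2–6 Hz component; all channels 1/f-shaped background noise.

What the generator does *not* emulate: texture content and masking, eye
movements and artifacts, volume conduction and electrode geometry,
session/block nonstationarities, or any neural dynamics beyond the scalar
statistical structure above. Passing tests therefore show that the
analysis chain recovers the structure it assumes, at realistic effect
sizes and trial counts — not that it would survive the artifact load of
real recordings, which the original preprocessing (excluded here by
design) exists to handle.

# Numerical choices and degenerate inputs

* First-passage series tolerance $10^{-10}$, error if not reachable within
  1000 terms; quadrature panels capped at 0.05 s (16-point Gauss–Legendre
  is accurate to ~$10^{-12}$ at that width).
* Expected-bin floor $10^{-10}$ with renormalisation.
* All randomness flows from one master seed through named substreams
  (`child_seed`), so stages re-run identically in isolation.
* Degenerate cells (no presses, or fewer than 10) collapse with flags
  rather than failing; p_target of 0 or 1 and non-integer per-block target
  counts are rejected at configuration time.
* Permutation p-values are never 0: the +1 convention bounds them below by
  $1/(1 + n_{perm})$ (exact enumeration bounds them by $1/2^N$).

# Problem sizes used by the test-suite studies

The simulation studies in the package's checks use: ~1440 liberal and
~1920 conservative trials per synthetic subject (6 and 8 blocks — the
study's per-condition totals); 10 seeds for the fit-replicate SD; 20
datasets per generating variant for model recovery with 3 optimisation
restarts per fit; a 3 × 3 (v × z) grid at $n = 10^5$, $dt = 10^{-4}$ for
the simulator-versus-analytic check; 200 null datasets × 200 permutations
(15 subjects, 8 × 20 × 30 grid) for the family-wise error rate; and 50
replicates at N = 14 subjects for the Gaussian-contrast power check.
These sizes were chosen as the smallest at which the corresponding
statistics are stable.

# Known limitations

* The G-square/BIC convention differs from the original custom code's
  (unstated) likelihood convention, so absolute BIC magnitudes are not
  comparable to the reference implementation's; only model rankings are.
* The profile optimiser assumes the profile over the shared bias parameter
  is well-behaved (one significant basin after the grid scan); pathological
  multi-basin profiles would need a denser scan.
* Bin-wise bias refits condition on the subject-level non-bias parameters;
  uncertainty in those parameters is not propagated into bin-wise
  estimates.
* The spectral path assumes clean, artifact-free input; no ICA,
  muscle-artifact rejection or current-source-density transform is
  provided.
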