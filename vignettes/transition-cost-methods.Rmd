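---
title: "Measuring brain state-transition cost from EEG microstates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring brain state-transition cost from EEG microstates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Cognitive work leaves a trace in the spatio-temporal organisation of brain
activity: moving from rest into a demanding task requires reconfiguring the
ongoing dynamics, and the effort of that reconfiguration is of direct
interest in the study of cognitive control. msbridge quantifies this effort
from multichannel EEG in three steps:

1. reduce the continuous EEG to a sequence of discrete **microstates** —
   quasi-stable scalp topographies that the signal revisits on a scale of
   tens of milliseconds;
2. characterise the resting dynamics by the **coverage distribution**
   $\pi^0$ (fraction of time in each state) and the **two-step joint
   matrix** $Q_{ij} = \Pr[k_{t-1}=i,\,k_t=j]$, and each task condition by
   its coverage $\pi^T$;
3. compute the **transition cost** as the solution of a discrete
   Schrödinger bridge problem: the Kullback–Leibler divergence between the
   resting reference dynamics and the closest coupling that moves
   $\pi^0$ into $\pi^T$,

$$
\mathrm{Cost} \;=\; \min_{P \in U} D_{KL}(P \,\|\, Q)
           \;=\; \min_{P \in U} \sum_{ij} C_{ij} P_{ij} - H(P),
\qquad C_{ij} = -\log Q_{ij},
$$

with $U = \{P > 0,\ \sum_{ij} P_{ij} = 1,\ \sum_j P_{ij} = \pi^0_i,\
\sum_i P_{ij} = \pi^T_j\}$ and $H$ the Shannon entropy of the plan. The
cost matrix $-\log Q$ makes transitions that are common at rest cheap: the
bridge measures how far the brain must bend its spontaneous dynamics, not
merely how different two histograms are. This is an entropy-regularised
optimal transport problem whose Gibbs kernel is exactly $Q$; the
regularisation weight is fixed by the problem itself, so no $\varepsilon$
knob is exposed. Strict convexity guarantees a unique optimum, found by
Sinkhorn's alternating diagonal scaling.

## Microstate extraction

**Preprocessing.** Recordings are zero-phase bandpass filtered (defaults
1–40 Hz: order-2 Butterworth high-pass and low-pass, each run
forward–backward) and decimated to 250 Hz. The decimation factor must be
an integer and the upper band edge must sit below the target Nyquist, so
the bandpass itself anti-aliases. Zero-phase filtering uses odd-reflection
padding of three time constants of the slowest pole, which keeps edge
transients below $10^{-6}$ of the signal scale. All maps are
average-referenced; for zero-mean maps the Pearson spatial correlation
coincides with the cosine similarity, which is used throughout.

**GFP peaks.** Global field power is the population (divide-by-$N$)
standard deviation of the instantaneous map across channels. Topographies
at strict local GFP maxima have the highest signal-to-noise ratio and are
the clustering input; up to 10000 peaks are drawn uniformly without
replacement per subject (seeded). Peak thinning (`minSeparation`) is off
by default.

**Modified k-means.** The clustering is polarity-invariant: map $v_i$ is
assigned to the template maximising $(a_k \cdot v_i)^2$, and each template
is updated to the principal eigenvector of its cluster's scatter matrix
$\sum_i v_i v_i^\top$ — the direction maximising sign-blind explained
variance. Convergence is declared when the relative change in global
explained variance (GEV),
$\mathrm{GEV} = \sum_i (v_i \cdot a_{L_i})^2 / \sum_i \|v_i\|^2$,
falls below `tol` ($10^{-6}$); the best of `restarts` (50) random
initialisations by GEV wins. Assignment ties and the CV minimiser tie
break to the lowest index; an emptied cluster is re-seeded from the
worst-fit map; template signs follow a fixed convention (largest-magnitude
channel positive), making fits bit-reproducible under fixed seeds.

**Choosing K.** For each candidate K the two-level fit (subject-level
clustering, pooling of subject templates, group-level clustering, same K
at both levels) is scored on the pooled peak maps by the residual noise
$\hat\sigma^2 = \sum_i (\|v_i\|^2 - (a_{L_i}\cdot v_i)^2)/(n(C-1))$ and
the cross-validation criterion
$\mathrm{CV} = \hat\sigma^2\,[(C-1)/(C-1-K)]^2$, with $C$ the channel
count; the selected K minimises CV. K $\ge C-1$ leaves CV undefined and is
skipped with a warning. Template labels are fit-internal (1..K); matching
to the literature's canonical A–G maps is cosmetic and out of scope.

**Back-fitting.** Every sample of the continuous recording is labeled with
the template of highest absolute spatial correlation (equivalent to
minimum polarity-blind Euclidean distance), with no temporal smoothing.

## Sequence statistics

Rest is cut into consecutive non-overlapping 2-s windows — the duration of
one task trial — so that rest and task estimates share the same segment
geometry; a trailing partial window is dropped. Coverage pools samples over
all segments of a condition after discarding each segment's first and last
maximal same-label run ("boundary microstates"): runs truncated by a
segment edge have unreliable duration. A segment consisting of a single
run is entirely boundary and contributes nothing; if a condition loses
all samples this way a degenerate-distribution error is raised. The joint
matrix $Q$ counts ordered consecutive pairs strictly within segments
(never across a window boundary) and is estimated from rest only.
Boundary exclusion applies to coverage, not to $Q$, by default — dropping
runs before pairing would delete genuine transitions — though both
estimators expose the flag.

Because boundary dropping perturbs the empirical coverage slightly
relative to $Q$'s own marginals, the resting $\pi^0$ entering the bridge
is the coverage-based estimate with the same exclusion flags as the task
side, feasibility-checked against $Q$'s support. Transition asymmetry
(the directionality of resting dynamics) is tested per unordered state
pair by a paired two-tailed t-test of $Q_{ij} - Q_{ji}$ across subjects;
a zero-variance, zero-mean difference is reported as undefined rather
than significant, and a zero-variance, nonzero-mean difference as
$p \to 0$.

## Solver numerics

Sinkhorn iterates $u \leftarrow \pi^0 \oslash Qv$,
$v \leftarrow \pi^T \oslash Q^\top u$ on the support of the marginals
until the worst absolute marginal violation of
$P = \mathrm{diag}(u)\,Q\,\mathrm{diag}(v)$ drops below `tol`
($10^{-10}$; `maxIter` $10^5$). If any scaling exceeds $10^{30}$ the
solver switches to log-domain updates (log-sum-exp), which is exact and
cheap at microstate dimensions. States with zero marginal mass are
excluded from the active support; mass required across zero-support rows
or columns of $Q$ raises an infeasibility error that suggests Laplace
smoothing (`pseudocount`), available as
$(\mathrm{counts}+\lambda)/(n+K^2\lambda)$ but off by default — a dense
7-state resting $Q$ does not need it. Costs are reported in nats. On
every solve the objective identity
$\sum C_{ij}P_{ij} - H(P) = D_{KL}(P\|Q)$ holds to $10^{-10}$, and the
baseline divergence $D_{KL}(\pi_{task}\|\pi_{rest})$ is available for
comparison; the divergence direction is task-from-rest, with both
directions computable by swapping arguments.

## The synthetic cohort generator

The generator produces the study design as ground truth: 44 subjects,
64 channels at 500 Hz, a 4-minute resting session (the Methods value;
rest duration is otherwise data-driven), and six task conditions —
congruency (incongruent/congruent, coded $-.5/+.5$) crossed with the
proportion of congruency (PC25/PC50/PC75, coded $-.5/0/+.5$) — of 48
2-second trials each, separated by noise-only inter-trial gaps that
exercise the exclusion path.

Labels follow a metastable chain
$T = p_{stay} I + (1-p_{stay})\,\mathbf{1}\pi^\top$: with probability
$p_{stay}$ (0.9) the state persists, otherwise it redraws from $\pi$, so
the stationary law is exactly $\pi$ and mean dwell times (~10 samples,
i.e. ~40 ms at 250 Hz) sit in the physiological microstate range.
Condition effects shift the stationary distribution in logit space with
$p_{stay}$ held fixed, moving coverage while keeping metastability
constant; default magnitudes produce coverage changes of a few percent,
the scale reported for task modulations of microstate coverage. EEG is
rendered as $v_t = s_t\,\sigma_t\, a_{k_t} + \eta_t$ with random
per-sample polarity flips $\sigma_t$, iid Gaussian channel noise scaled
so the mean amplitude-to-noise ratio equals `snr`, and an alpha-like
envelope $s_t = 0.25 + |\sin(2\pi\,10\,t)|$. The floor is a deliberate
departure from a pure rectified sinusoid: at an envelope zero the label
is unidentifiable at any SNR, which would make exact label recovery
unattainable by construction rather than informative.

What the generator does **not** emulate: volume-conduction forward
physics, spatially correlated noise, artifacts (blinks, muscle), 1/f
spectra, or inter-subject topography variability. Passing recovery tests
therefore demonstrates correctness of the estimators under the stated
model, not robustness to real-world EEG nuisance structure.

## Sampling bounds used in the recovery checks

Two chain-statistics facts shape the test tolerances. First, diagonal
entries of $\hat Q$ count events that repeat through entire dwell runs,
so their variance exceeds the binomial $Q(1-Q)/n$ by the integrated
autocorrelation time $(1+a)/(1-a)$ at effective self-transition $a$
(~26x at $a = 0.925$); off-diagonal pair events cannot repeat at
consecutive steps and keep the binomial scale. Recovery checks therefore
use the binomial standard error off-diagonal and the inflated one on the
diagonal. Second, the cost of a null design (task distribution equal to
rest) is not zero but a chi-square-style functional of the marginal
estimation errors with expectation about
$\tfrac{K-1}{2}\,\tau\,(1/n_{task} + 1/n_{rest})$,
$\tau = (1+p_{stay})/(1-p_{stay})$; the null-cohort check allows five
times this scale to cover higher-order KL terms and cohort spread.

## Problem sizes

The shipped checks run at desk scale, chosen once: template/K/label
recovery on 6 subjects, 32 channels, 48 s rest at 250 Hz, restarts 10,
K searched over 2–8; effect-ordering on label-level cohorts of 8 subjects
with 20 trials per condition over three cohort seeds; asymmetry power on
30-subject cohorts of 1000-sample chains over 200 replicates (100 in the
acceptance script). Oracle equivalence solves 100 random bridge problems
at K = 2 and 3 against brute-force minimisers over the transportation
polytope (golden-section on the single free parameter at K = 2,
penalised Nelder–Mead over the free 2x2 block at K = 3).

## Known limitations

- Input formats are CSV matrix + JSON sidecar; EDF is not read.
- The full random-slope mixed-effects inference of the per-microstate and
  cost models is delegated to external tooling via the long-format
  export; the package owns design coding, the chance-level t-test,
  BH-FDR over the 28-effect family, Stroop contrasts and pooled OLS
  slope summaries.
- No temporal smoothing or minimum-duration merging of label sequences;
  no polarity-sensitive clustering; no canonical template naming.
- Coverage/cost estimates assume approximate stationarity within
  condition segments.

## A minimal run

```r
library(msbridge)

cfg <- syntheticConfig(nChannels = 16, KTrue = 4, nSubjects = 3,
                       srate = 250, restDurationS = 24,
                       nTrialsPerCondition = 10, seed = 1)
coh <- generateCohort(cfg, render = FALSE)
sq  <- coh$sequences[[1]]
task <- setdiff(unique(segments(sq)$condition), "rest")
transitionCostPerCondition(sq, lapply(task, function(cd) coverage(sq, cd)))
```

The same pipeline runs from the shell via `inst/cli/msbridge`
(`simulate`, `fit-microstates`, `backfit`, `coverage`, `transition-cost`,
`stats`, `report`), with every stage seeded from one root seed and a
manifest recording the configuration of each step.
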