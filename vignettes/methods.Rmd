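---
title: "Models, null distributions and design choices in subnetdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, null distributions and design choices in subnetdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

subnetdyn implements a multimodal network-neuroscience pipeline around one
scientific question: can a task-control system (the frontoparietal system,
FP) be split into two subnetworks whose relative activity governs the
functional coupling between FP and the default-mode (DM) and
dorsal-attention (DA) systems, with consequences for working-memory
performance? The package provides the statistical machinery for each step,
and a synthetic cohort generator whose planted effects make every estimator
testable end to end.

## The weighted stochastic block model

The FP subgraph of a functional connectivity matrix (Pearson correlations
between regional BOLD timeseries) is partitioned with a weighted stochastic
block model with normally distributed edge weights: nodes receive labels
$z_i \in \{1..K\}$ and an edge between blocks $(z_i, z_j)$ is modeled as
$N(\mu_{z_i z_j}, \sigma^2_{z_i z_j})$. `wsbm_loglik()` exposes the
generative exponent
$C\mu/\sigma^2 - C^2/(2\sigma^2) - \mu^2/(2\sigma^2) = -(C-\mu)^2/(2\sigma^2)$
summed over unordered off-diagonal pairs; symmetric matrices make the
ordered-pair sum exactly twice this, and diagonal self-correlations are
uninformative, so the unordered convention is used throughout.

One numerical fact shapes the implementation: at the blockwise
maximum-likelihood parameters, the exponent-only objective equals $-P/2$
for *every* partition ($P$ = number of pairs), because each pair's squared
standardized residual averages to one within its own block. The
exponent-only form is therefore useless for fitting or for comparing block
counts. Fitting, the permutation null, and `compare_k()` all use the full
Gaussian log-density (exponent plus $-\tfrac12\log 2\pi\sigma^2$), available
as `wsbm_loglik(..., full = TRUE)`.

`fit_wsbm()` is a greedy alternating maximizer: blockwise sample
mean/variance given labels, then sequential label sweeps maximizing the full
log-density given parameters, best of `restarts` (default 20) random
initializations, variance floor `1e-6`, canonical relabeling (the block of
the lowest-index node is 1). Because both phases are exact coordinate
ascents on the same objective, the log-likelihood trace is non-decreasing
— a tested invariant. A consequence of maximum likelihood is that
$K = 3$ fits never have lower log-likelihood than $K = 2$ on the same data
(nesting); the bootstrap comparison against $K = 1$ is therefore the
meaningful one, and the $K = 3$ tail is reported without assertion.

Partition agreement uses the z-scored Rand coefficient: the number of node
pairs co-clustered in both partitions, centered and scaled by its exact
mean and variance under random relabeling (derived from falling-factorial
counts of the group sizes; checked against a permutation oracle).
`consensus_partition()` returns the input partition with the highest mean
z-Rand to the rest. The permutation null for the consensus refits the block
parameters per subject under a size-preserving random relabeling — the
label-permutation scheme is an assumption, since the source procedure does
not state whether block sizes are preserved.

## Boundary control

From a normalized structural (tractography) matrix, a region's boundary
control with respect to two target systems J and L is computed from its
total strength $k_i$ and its strengths into the two systems:
$1 - (k_i(J)/k_i)^2 - (k_i(L)/k_i)^2$ when $k_i(J) + k_i(L) = k_i$ (relative
tolerance $10^{-9}$; real-valued strengths almost never hit the equality
branch), else $(k_i(J)/k_i)^2 + (k_i(L)/k_i)^2$. The statistic is
scale-invariant and bounded in [0, 1]. System-level strengths are the only
reading under which "regional boundary control with respect to two systems"
is a single per-region number; a region's own intra-FP connections count
toward $k_i$ but not toward $k_i(J)$ or $k_i(L)$.

Enrichment of the top-5% controllers (exactly 20 regions at $N = 400$,
index-ordered tie-break) in the FP system is tested two ways on purpose:
a label-permutation p-value, and the exact hypergeometric tail as an
internal oracle (for 9/20 hits against 61 of 400, the exact tail is
$\approx 1.08\times10^{-3}$). The two must agree within Monte-Carlo error;
the source study's reported p = 0.0019 for this configuration cannot be
reconciled exactly with the exchangeable-label null, so both numbers are
reported and neither is asserted as ground truth.

## Gene coexpression

Probe-level expression is aggregated by centering each probe across parcels
and averaging per (parcel, gene). Centering annihilates any component
constant across parcels — which is why the synthetic generator plants its
FP-wide baseline as a *parcel-varying* latent profile (present only in FP
parcels, absent elsewhere): after centering across all parcels, FP pairs
keep a positive shared coexpression baseline, as in real cortical data where
the FP parcels are a subset of the full set. On top of it, each subnetwork
loads on its own latent profile with weight `margin` (default 0.3).

The test statistic is the ratio of within- to between-subnetwork mean
coexpression. Each bootstrap resamples genes with replacement at full size
(the standard bootstrap reading of "a bootstrap sample of all genes"; a
config flag switches to without-replacement), recomputes the ratio, and
subtracts the mean ratio over label permutations (permuting only the
labeled FP parcels — the scope of the permutation is another undocumented
choice, made here and flagged). The p-value is the fraction of bootstrap
indices below zero, computed per subnetwork, matching the two reported
p-values in the source analysis. Desk defaults are 1000 bootstraps and 200
permutations; paper scale (10000/1000, 16699 genes, 338 parcels) is
reachable by configuration.

## The Hopf oscillator network

Each unit follows the Stuart-Landau normal form: for bifurcation parameter
$a < 0$ a noisy low-activity fixed point, for $a > 0$ a limit cycle of
radius $\sqrt a$ (so RMS of the real part is $\sqrt{a/2}$ — both closed
forms are 1%-level integration checks). Units are diffusively coupled
through $G\sum_i D_{ij}(x_i - x_j)$ and its $y$ analog, integrated by
Euler-Maruyama at dt = 0.01 s for 6 simulated minutes, with noise
$\xi\sqrt{dt}\,N(0,1)$ drawn independently for the $x$ and $y$ updates
(the $\sqrt{dt}$ scaling is the standard additive-SDE convention; whether
the noise is shared between the two equations is unstated, and independent
draws are chosen). The integrator is compiled (Rcpp) and uses R's RNG, so
`set.seed` governs reproducibility. A 20 s transient is discarded before
any summary (settling time at $|a| \approx 0.075$ is below 10 s).
Frequencies are drawn per initialization from a truncated normal with mean
0.04 Hz and SD 0.01 Hz, inside the 0.009-0.08 Hz band of interest.
Synchrony is the time-mean Kuramoto order parameter over instantaneous
phases from an FFT-based analytic signal.

The group-level coupling matrix D is not printed in the source study (it
was an empirical tractography average), so the simulator uses the planted
structural motif (A-DM 2.07, B-DM 0.676, A-DA 1.03, B-DA 1.54; the
unreported A-B and DM-DA entries fixed at 1.0 and 0.5). Its absolute scale
is the one genuinely free quantity: normalized to unit mean coupling the
4-unit system globally synchronizes at the working point (a = -0.075,
G = 0.1) and amplitude manipulations stop moving inter-system coupling.
Following the same logic the source used to pick its working point —
sweep, then choose intermediate synchrony — the motif is normalized so its
maximum entry is 0.5, i.e. $G D_{max} = 0.05 < |a|$, which puts the
strongest pair at partial entrainment and mean R near 0.55. This was fixed
once from the regime analysis, before the sign tests were run at their
final seeds.

In the amplitude experiment, the target subnetwork's $a$ is varied while
all other units stay at the base value; the FP signal is the mean of the
SN-A and SN-B group signals (mean rather than sum — identical up to scale
for correlations), and the overall mean system coupling (mean of the six
pairwise core-group correlations in that run) is subtracted from
r(FP, DM). The tested claims are signs only: raising SN-A's amplitude
raises corrected FP-DM coupling, raising SN-B's lowers it, and zeroing D
abolishes both. One stated qualitative result is *not* reproducible in
this synthetic world: near-universal anticorrelation of the two subnetwork
signals across initializations. Nonnegative diffusive coupling biases every
pairwise correlation positive, so the anticorrelation census sits near or
below chance for any scale of the motif; the census function is provided
and tested against its exact binomial behavior at D = 0.

At 192/400 units the group matrix is expanded so the *summed* inter-group
coupling matches the group-level entry (edge weight $D_{gh}/(n_g n_h)$);
per-oscillator influence then shrinks with group size, which preserves the
bookkeeping contract but weakens per-unit coupling at scale — group signals
are unweighted means of member $x$ series.

## Multilevel statistics

Two scans nested in each subject make observations non-exchangeable, so all
cohort inferences use a random-intercept model fit by marginal maximum
likelihood, implemented directly: the per-subject covariance
$\sigma_e^2 (I + \lambda J)$ has closed-form inverse and determinant, and
the profile likelihood is optimized over $\log\lambda$ with an explicit
boundary check at $\lambda = 0$ (where the fit collapses to pooled OLS
exactly). The fit is verified in the test suite against two independent
oracles: a dense-matrix numerical maximization of the same marginal
likelihood, and lme4's ML fit. Wald tests use
df = n_obs - n_fixed - n_subjects + 1; Satterthwaite-style corrections are
out of scope and the source's df convention is not asserted. The robust
option runs observation-level Huber weights (tuning constant 1.345) on
standardized marginal residuals inside an IRLS loop around the ML fit — an
approximation to a dedicated robust multilevel estimator, adequate for
downweighting gross outliers.

The repeated-measures correlation is the ANCOVA form: subject fixed
effects absorb between-person variance, a common slope is fit to the
within-subject-centered covariate, and $r_{rm}$ is the signed square root
of the partial variance explained (equal, on balanced designs, to the
correlation of within-subject-centered variables — the brute-force oracle
in the tests). The paired-swap permutation test flips each paired
difference's sign with probability 1/2; the one-sided p (proportion of
null mean differences at or above the observed) is the default, matching
the source convention, with a two-sided option.

## The synthetic cohort

The generator is a stated world, not a fitting device. Eight systems carry
independent unit-variance Gaussian latents per run; the subnetwork latents
are linear combinations of the DM and DA latents,
$s_A = g_A(c_1 s_{DM} - c_2 s_{DA}) + \sigma_A e_A$ and
$s_B = g_B(-c_3 s_{DM} + c_4 s_{DA}) + \sigma_B e_B$, with subject
amplitude factors $g \sim N(1, 0.3)$ (the between-subject spread is
unreported in the source and 0.3 is this package's one free choice of
individual-difference magnitude). Regional signals are latent plus
independent noise of SD $\nu = \sqrt{1/w - 1}$, with within-subnetwork
regional correlation $w = 0.9$ by default; subnetwork regions are
additionally scaled by $g$. The two appearances of $g$ are deliberate:
inside the latent it makes *coupling* grow with the subject's amplitude
factor, as the mechanism under study requires, and as an overall regional
scale it makes *RMS activity* track $g$ without touching any correlation.
With either link alone, the RMS-to-coupling and RMS-to-behavior sign
checks would be statistically invisible at desk scale.

Coupling calibration: the region-pair estimator attenuates the latent
correlation by $w$, while the subnetwork-mean estimator attenuates it by
$\approx 1$; coefficients are inflated by $1/\sqrt w$ so the two estimators
straddle each target symmetrically, both within the stated $\pm 0.02$ band
(cohort-mean Monte-Carlo error shrinks as $1/\sqrt n$). Defaults are the
four empirical couplings (0.042, -0.082, -0.014, 0.12), 50 subjects, two
runs, 405 timepoints at TR 0.72 s. Structural networks are independent
gamma draws (shape 4) around the four planted block means with a 0.3
background; behavior is
intercept $- \beta_A g_A + \beta_B g_B - \beta_{FC}\,FC_{FP,DM}$ + subject
intercept + noise, clipped to [0, 1] like an accuracy.

What the generator does not emulate: BOLD autocorrelation, motion and
scanner artifacts, tractography distance biases, empirical DM-DA
anticorrelation, and spatial autocorrelation of gene expression. A green
end-to-end test therefore establishes that the estimators recover planted
second-order structure at realistic effect sizes — not that the pipeline is
robust to real-data nuisances that are out of scope here.

## Numerical conventions

Tie-breaks are deterministic everywhere (ascending edge order in structural
thresholding, region index in top-percentile selection, lowest subject
index in consensus). All stage seeds derive from one master seed through a
documented hash-counter scheme, so identical configuration yields
byte-identical study reports. Matrices travel as TSV with 17-significant-
digit values, which round-trips doubles exactly.
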