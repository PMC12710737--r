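---
title: "Semantic encoding of naturalistic movie fMRI: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic encoding of naturalistic movie fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis in one paragraph

`semcine` implements a brain–AI alignment analysis for naturalistic
movie-watching fMRI. A continuous movie session, organized as runs of movie
segments separated by 20-s fixation blocks, is segmented into overlapping
clips of 16–20 s. Each clip carries a vector of eleven interpretable
semantic scores in $[0,1]$ (motion intensity, scene brightness, people
presence, faces close-up, social interaction, dialogue, music, valence,
arousal, threat, narrative progress), consumed as a CSV — in the motivating
study these come from a multimodal language model annotating the same
clips. On the brain side, parcel-averaged BOLD time series (360 cortical
parcels) are z-scored on non-rest frames, cleaned of the frame-wise global
mean, and averaged over each clip's hemodynamically lagged window, giving a
clips × parcels response matrix $Y$ per subject and a trimmed-mean group
matrix. For each parcel, ridge regression with leave-one-out
cross-validation predicts the clip responses from the feature matrix $X$
(clips × 11); the pooled held-out $R^2$ per parcel is the *semantic
explainability* map. Individual differences in these maps are then related
to (a) resting-state nodewise connectivity strength through behavioral PLS
with permutation and bootstrap inference, and (b) seven age-adjusted
cognitive scores through cross-subject Spearman correlation with pooled
Benjamini–Hochberg FDR control.

## Models and estimators

### Segmentation

Within each movie interval $[a, b)$, the usable window is
$[a,\, b - \text{end\_buffer})$ with a 5-s buffer: the buffer guarantees
that the 5-s lagged BOLD window of every clip stays inside the movie
interval. Candidate onsets advance in 10-s steps from $a$; a candidate
spans $\min(20,\ \text{usable end} - \text{start})$ s and is kept iff at
least 16 s long; enumeration halts at the first rejected candidate, so at
most one shortened tail clip is emitted per segment. The source study does
not state what happens after a first sub-minimum candidate; halting is this
package's deterministic reading, and anyone reconciling clip counts against
an official manifest should check that rule first.

### Clip responses

A TR belongs to a window iff its onset lies in the half-open window — the
one rule that stays unambiguous for non-integer lags and TR ≠ 1 s.
Standardization uses non-rest frames only, with the $n-1$ SD denominator
everywhere in the package; constant parcels are zeroed and flagged rather
than propagating NaNs. The order is fixed: z-score, then frame-wise
global-mean removal (the order the source pipeline states). Group
aggregation trims `floor(trim_fraction * N)` subjects per tail
(5% per tail by default — the literal reading of "trimming 5% of the
highest and lowest values"; the 2.5%-per-tail alternative is a one-line
config change).

### Encoding

Ridge regression with the penalty on the standardized scale and no
intercept (data centered):
$\hat\beta = (X_s^\top X_s + \lambda I)^{-1} X_s^\top y_s$, $\lambda = 1$
by default. Cross-validation is leave-one-clip-out with strict fold
hygiene: fold statistics come from the training clips only and are applied
to the held-out clip, and predictions are back-transformed to the original
response scale. Explainability is
$R^2 = 1 - \mathrm{SS}_{res}/\mathrm{SS}_{tot}$ over the pooled held-out
predictions around the grand observed mean — *not* a squared correlation —
because only this definition can go negative when the model underperforms
a mean-only baseline, which the motivating results explicitly report.
Reported coefficient maps come from the all-clip standardized fit (the
fold-averaged coefficients are retained for diagnostics); the source does
not state which of the two it maps, and this choice is flagged here.
Internally the fold loop uses leave-one-out downdates of the full-data
sums; tests verify it against a from-scratch fold implementation at
`1e-10`.

Feature importance is summarized two ways: the mean of $|\beta|$ across
parcels, and an $R^2$-weighted mean with weights
$\max(R^2_i, 0) / \sum_j \max(R^2_j, 0)$, so negative-$R^2$ parcels carry
no weight.

### Connectivity strength

Pearson correlations between parcel time series are clipped to
$|r| \le 1 - 10^{-7}$ before Fisher $z = \operatorname{atanh}(r)$, so
duplicated or degenerate parcels cannot inject infinities. Strength is the
mean over $j \ne i$ of $\max(z_{ij}, 0)$ (negative edges zeroed, diagonal
excluded). Whether the source applies global-mean removal before rest FC
is not explicit; this package correlates z-scored series without
global-mean removal and exposes the alternative as a switch.

### PLS

Behavioral (cross-covariance SVD) flavor: both subject × parcel blocks are
column z-scored, $C = \tilde X^\top \tilde Y/(n-1)$ is decomposed, paired
singular vectors are the saliences, block scores are the projections.
Column z-scoring (rather than centering only) is the default because the
two blocks live on incomparable scales ($R^2$ vs Fisher-z strength);
center-only is available. Significance: permute subject rows of $Y$ only,
recompute the full SVD, $p_k = (1 + \#\{\sigma^{perm}_k \ge
\sigma^{obs}_k\})/(n_{perm}+1)$. Stability: bootstrap subjects with
replacement, sign-align each draw's saliences to the originals by dot
product, and report the bootstrap ratio (original salience / bootstrap SD).
Variance explained is reported both as the covariance fraction
$\sigma_k^2/\sum \sigma^2$ and as per-block score-variance fractions,
because the source shows per-block percentages without defining a formula.
Published loading ranges suggest the source may plot bootstrap ratios
rather than unit-norm saliences; this package reports both separately
rather than guessing.

### Cognition coupling

Cross-subject Spearman correlation (Pearson on average ranks) between each
parcel's subject-wise $R^2$ and each of seven scores, p-values from the
t approximation with $n-2$ df (standard at the study's $n = 176$; an exact
permutation option would only matter at small $n$). All finite p-values
are pooled into a single vector for the Benjamini–Hochberg step-up rule at
$q = 0.05$; parcels flagged degenerate upstream are excluded so $m$ counts
tested hypotheses only. The source text mentions a "360 × 11" correlation
matrix while listing seven cognitive measures; this package implements the
named list of seven and documents the discrepancy.

## The synthetic world

The generator exists so that every stage is testable by parameter
recovery; its defaults are a stated world, chosen once:

- **Schedule**: 4 runs × 6 segments of 60 s separated by 20-s fixation,
  TR = 1 s — matching the rhythm of the motivating dataset at desk scale;
  24 subjects by default, scalable to the study's ~176.
- **Latent semantic courses**: Gaussian-kernel-smoothed white noise
  (SD 8 s), re-standardized, squashed to $[0,1]$ by a logistic
  (steepness 1.7), zeroed at rest. Clip scores are defined as the window
  means of these courses, so the encoding model is correctly specified at
  the clip level by construction; misspecification experiments are an
  option, not the default. When all runs share an interval layout (the
  default), one latent realization is reused across runs. This is
  deliberate: per-run z-scoring divides each parcel by its run-wise sample
  SD, and with independent latent draws those SDs differ by a few percent,
  making pooled responses only piecewise-affine in the clip scores and
  capping noiseless recovery near $R^2 \approx 0.95$. Shared layouts make
  the per-run standardization a fixed linear map, so the noiseless
  pipeline is exactly linear and recovery tests are sharp. Real sessions
  do differ across runs — this is a verifiability choice, not a realism
  claim.
- **Encoding truth** $B$ (parcels × 11): 30% of parcels active
  (block-sparse), weights $\mathcal N(0, 1)$, with the `dialogue` column
  scaled 2.5× so importance metrics have a known winner. Movie BOLD:
  $y_{i,t} = a_{s,i} \sum_f B_{if}(L_{f,t-\text{lag}} - \bar L_f) +
  \varepsilon$, $\varepsilon \sim \mathcal N(0, \sigma^2)$ iid, rest TRs
  noise-only. No HRF convolution — like the source, only a fixed 5-s
  shift. Default $\sigma = 0.3$, on the order of the noise-free signal SD
  at these defaults (SNR near 1); tests that need a specific SNR compute
  the signal SD explicitly via `signal_sd()`. Within a run the eleven
  courses are linearly recombined so that their clip-window means are
  exactly uncorrelated with equal SDs, and mapped to $[0,1]$ by one
  shared affine map: with strong smoothing and few segments, raw draws
  carry chance feature correlations of 0.4–0.7 that confound
  coefficient-recovery tests; the independence the world *states* is
  enforced where the encoding model actually looks.
- **Subject structure**: gain $a_s = \exp(0.4 z_1)$ scales the evoked
  signal (globally on active parcels, or only on designated parcels in
  `"localized"` mode for spatially specific cognition coupling); trait
  $u_s = z_2$ drives the connectivity axis; $(z_1, z_2)$ are bivariate
  normal with correlation $\rho_{axis}$ (default 0.6) — the single dial
  for the PLS effect size.
- **Rest runs**: one shared factor with parcel loadings
  $\lambda_i = \sqrt{0.6 + 0.8\, u_s w_i}$ (floored at 0.05) plus unit
  white noise, 1200 TRs. The factor is normalized to exact zero mean and
  unit sample variance per subject: its realized variance would otherwise
  shift every pairwise correlation of that subject coherently, adding a
  subject-level common mode to the strength profiles that masks the
  planted axis. The axis loading $w$ is nonzero on 40 parcels with
  equal-magnitude balanced signs ($\pm 1/\sqrt{40}$, half positive):
  balanced signs keep the trait from shifting the global mean loading,
  and equal magnitudes keep the strength-vs-trait correlation profile
  proportional to $w$ (unequal loadings saturate at different rates and
  distort the recoverable pattern). These three choices — shared latent,
  normalized factor, balanced equal-magnitude loading — were fixed by
  requiring the generator to satisfy its own stated recovery properties,
  not by reference to any empirical result.
- **Cognition**: each score is `strength · trait + noise`, z-scored. The
  fluid/crystallized composites and fluid intelligence link to the gain
  trait at 0.5, the memory scores at 0.3, the speeded executive measures
  not at all — mirroring the qualitative pattern the motivating study
  reports, with noise SDs chosen so each score has unit variance.

What a green test does *not* establish: the generator has no spatial
autocorrelation on the cortex, no hemodynamic response function, no
scanner drift or motion artifacts, Gaussian noise only, and feature
courses independent by construction. Recovery on this world validates the
estimators' algebra and calibration, not their behavior under real fMRI
artifacts.

## Numerical choices

- SDs use the $n-1$ denominator everywhere (z-scoring, correlations,
  importance); tolerance for "zero variance" is $10^{-12}$, and flagged
  entities are excluded rather than imputed.
- Correlation clipping at $1 - 10^{-7}$ before `atanh`.
- Permutation p-values use the $+1$ correction and can never be 0.
- Salience sign convention: the largest-magnitude entry of each original
  salience column is positive; bootstrap draws are aligned by dot-product
  sign, so the convention cannot affect $|$bootstrap ratio$|$.
- All generators restore the caller's RNG state; derived seeds stay within
  32-bit range.
- The BH step-up is implemented directly from the definition and tested
  against a brute-force oracle; it is monotone in $q$ by construction.

## Known limitations

- No neuroimaging-format I/O (NIfTI/CIFTI/GIFTI): parcel matrices must be
  exported upstream; the readers define a plain-TSV contract with explicit
  subject/run/TR headers.
- The published clip count (293) can only be reproduced with the official
  restricted-access timing tables; the packaged worked examples are
  hand-enumerable schedules.
- Single fixed $\lambda$; no hyperparameter search, by design.
- The PLS reports one latent variable by default; higher components are
  available but the planted world only defines one axis.
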