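---
title: "Methods: thermal imaging of social events in wild primates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal imaging of social events in wild primates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(thermosocial)
```

## The problem

Peri-nasal skin temperature tracks autonomic state: sympathetic
vasoconstriction under stress cools the nose within seconds, parasympathetic
vasodilation warms it. Functional infrared thermography therefore offers a
non-invasive window on how free-ranging animals appraise social events.
`thermosocial` implements the full analysis chain for such a field study on
adult male chimpanzees: picture-level nose temperatures taken during
ordinary social events, long-term dyadic interaction logs, and event-level
audience metadata go in; corrected event temperatures, social indices, a
thermal clustering of event types, and audience-effect model selections come
out.

Because the original field data are held externally, the package ships a
first-class synthetic-data generator with known ground truth. Every stage is
validated by parameter recovery against that truth.

## Angle-bias correction

Chimpanzees rarely face the camera, and the view angle biases the apparent
nose temperature. Pictures are coded into seven angle categories (`facing`
is the reference). For each event we average pictures per angle, giving an
event-by-angle matrix with missing cells, and complete it by regularized
iterative PCA (EM-PCA):

1. initialize missing cells with column means;
2. center columns, take the SVD, reconstruct with the top `rank` components,
   shrinking each retained singular value $s$ to $(s^2-\hat\sigma^2)/s$,
   where $\hat\sigma^2$ is the mean of the discarded squared singular values
   over the residual dimensions;
3. overwrite missing cells with the reconstruction; iterate until the sum of
   squared changes in the imputed cells falls below `tol` (default `1e-6`,
   `max_iter = 1000`).

Events with an observed facing cell use its mean directly; the rest use the
imputed facing value (`was_imputed` flags them, and the imputed fraction is
reported — about 46–48% under the generator defaults, matching the scale of
correction the field protocol implies). The corrected temperature is
log-transformed (natural log, the usual choice for multiplicative
physiological effects) before modelling.

Numerical notes, found worth documenting:

* The angle offsets are additive, so the *centered* matrix is rank one. With
  `rank` larger than the true rank and little noise, the spare components
  can park arbitrary structure in the missing cells without any penalty on
  observed ones — the classic EM-PCA overfit. The shrinkage step suppresses
  this whenever real picture noise is present (the default `rank = 2` is
  then safe), and `select_rank_cv()` offers a cross-validated rank choice
  that identifies the additive structure. Observed cells are never altered,
  exactly.
* The plain EM objective decreases monotonically (up to numerical jitter);
  re-estimating $\hat\sigma^2$ each iteration makes the regularized trace
  only *approximately* monotone. Tests assert strict monotonicity for the
  plain scheme and bounded transients for the regularized one.
* Pictures outside the 15–300 s post-event window, or outside 20–42 °C, are
  dropped before matrix construction; imputed values outside those bounds
  are excluded with a flag.

## Social indices

**Composite Relationship Index.** For focal $f$ and partner $j$,
$$\mathrm{CRI}=\frac{G_{fj}+R_{fj}-5\,A_{fj}}{T_f},$$
with $G$ grooming occurrences (any direction), $R$ resting within 5 m
(15-min occurrence counts), $A$ aggressions in either direction with severe
aggressions counted twice, and $T$ the focal's total 15-min observation
occurrences; the factor 5 rebalances event counts against occurrence
counts. Bond partners are the focal's top-3 positive-CRI partners; non-bond
partners the bottom-3 negative. Ties are broken by interaction volume, then
partner id, for determinism.

**Elo rating.** Severe aggressions, chases and threats (aggressor wins) and
pant-grunts (the unidirectional submissive call — receiver wins) update
ratings sequentially: the winner gains $k\,(1-p)$ with
$p = 1/(1+10^{(r_L-r_W)/400})$, the loser loses the same, so rating mass is
conserved exactly. Defaults `k_factor = 100`, `start_rating = 1000` are the
conventional constants for the continuous-update method; final scores are
standardized (z-scores) for modelling. `elo_stability()` reports the
Spearman correlation between first- and second-half ratings (a stable
hierarchy gives values near 1; reported, not enforced).

## Event-type clustering

Each of the 13 social event types gets a thermal-signature feature vector:
per-subject means of residual log temperatures (log temperature minus the
baseline-calibrated ambient and movement adjustments), plus the type's
overall mean and SD; features are standardized before Euclidean distances.
Empty subject-by-type cells are filled with the subject's grand mean so
vectors stay comparable. The baseline is excluded — it is the comparison
level of the downstream model, not a clustered type. Ward's minimum-variance
linkage (`hclust`, `ward.D2`) builds the tree; the number of clusters is the
mean-silhouette maximizer over `k_range` (default 2–6), ties toward smaller
`k`; singleton silhouettes are 0 by the usual convention. Cophenetic
correlations for Ward and single linkage are reported as a faithfulness
check. Feature construction was the genuinely open design point: per-subject
residual profiles are robust to unequal event counts and preserve subject
structure; distances between per-type temperature *distributions* would be a
reasonable alternative and are deliberately out of scope.

## Mixed models and model selection

All models are Gaussian linear mixed models: log corrected nose temperature
as the response, random intercepts for subject identity and prior movement
(three levels — kept as a random factor deliberately, matching the study
design it emulates), and centered ambient temperature as a control covariate
present in *every* model including nulls. Confound calibration fits one
model per candidate confound (ambient temperature, humidity, camera
distance, prior movement) on resting-baseline events only and flags those
with Wald $p<0.05$ for control downstream.

Model selection enumerates all marginality-respecting subsets of the
candidate audience terms, fits each by **ML**, and ranks by
$$\mathrm{AICc}=-2\ell+2k+\frac{2k(k+1)}{n-k-1},$$
with $k$ counting fixed coefficients *plus* variance components plus the
residual variance. ML is used for AICc and likelihood-ratio tests; the
selected model is refit by REML for reported coefficients — the standard
division of labour in mixed-model selection. The LRT against the null
(random factors + control only) uses $\chi^2 = 2\Delta\ell$ with df equal to
the difference in fixed-coefficient counts. Per-term tests are Type-II Wald
chi-squares; post-hoc contrasts are estimated marginal means with Tukey
adjustment and residual degrees of freedom $n-\mathrm{rank}(X)$ (simple and
transparent; Satterthwaite or Kenward–Roger approximations would give
slightly different dfs and are out of scope).

Candidate term lists cover every audience variable observable in the event
schema: alpha-male and mother presence at 10 m and 35 m, male and female
counts at both radii, and the subject's standardized Elo rating; the
grooming model adds the subject's grooming role, whether the partner is the
alpha, and their interaction.

## The synthetic-data generator

The generator draws a complete field season: 9 focal males, 13 social event
types (65 events each by default) plus 392 resting-baseline events, 1–13
pictures per event, and 6 months of interaction logs. The event-level
expected temperature is

> group intercept + group-specific subject signature + subject intercept +
> movement offset + 0.2 °C/°C × (ambient − 25) + audience terms,

with audience terms applying only where they biologically act: alpha-male
presence within 35 m lowers cooperative-event temperatures (−0.5 °C),
each female within 10 m raises competitive-event temperatures (+0.2 °C),
and copulations respond to the number of males within 10 m (+0.3 °C each)
and to mother presence (−2.1 °C). Pictures add the angle bias of their view
category plus 0.3 °C i.i.d. noise; 46% of events lack a facing picture.

Two calibration decisions matter for interpreting the defaults:

* The per-group means and SDs a field study reports are *marginal*
  quantities. The config's `cluster_means` and `cluster_sds` are therefore
  intercepts and residual SDs chosen (by a one-off variance-budget
  calculation) so that the *marginal* group means and SDs land at about
  33.6 ± 1.66 °C (cooperative), 32.8 ± 2.10 (competitive), 33.6 ± 1.45
  (mixed) and 33.1 ± 2.16 (baseline) — the scale of real chimpanzee nose
  temperatures. Using the printed values directly as residual SDs would
  double-count variance already contributed by subjects, movement, ambient
  and audience terms.
* Each non-baseline group carries a deterministic per-subject response
  signature: a fixed near-orthogonal ±1 pattern scaled by
  `cluster_profile_sd` (1.0 °C). This encodes that functional classes of
  events engage individuals in distinct ways — the feature that makes the
  three-group structure detectable at all, since the cooperative and mixed
  groups share the same mean. Random Gaussian signatures would make the
  planted separation itself a lottery across seeds; fixed patterns keep the
  study conditions constant. The largest pattern separation goes to the
  A–C pair (equal means).

Interaction logs encode a planted hierarchy (logistic win probability with
steepness 0.7 per rank difference; pant-grunts always flow up the planted
order with the same logistic) and a planted symmetric bond graph of degree
≤ 3 (bond dyads groom and rest together at 4× the baseline rate; planted
rival dyads at 8× aggression and 0.1× affiliation provide the negative-CRI
partners). The degree cap matches what top-3 CRI selection can recover.
Focal observation effort is 60 occurrences per subject per month. Ambient
temperature is uniform on 20–30 °C, humidity 40–90%, camera distance
7–15 m; audience counts are truncated Poissons (females mean 4 within 35 m,
males mean 2, 40% of the 35 m party within 10 m); mother presence (5 of 9
subjects have a living mother) is 20% of events. None of these field
distributions is reported for the real study; the values are plausible
placeholders, not estimates, and live in the config.

What the generator does *not* emulate: temporal autocorrelation within
follows, weather trends, party-composition dynamics, demographic structure
beyond adult males, and type-specific idiosyncrasies within a functional
group. Passing recovery tests therefore show the pipeline recovers the
structure *this* generative model plants — a necessary check of the
machinery, not evidence about real chimpanzees.

## Problem sizes used in validation

The shipped validation suite uses: the full-scale generator (about 1240
events, 8600 pictures) for cluster-structure and audience-effect recovery
across 10 seeds; 200 simulated datasets of n = 500 for coefficient
coverage; 1000 null simulations of n = 300 for test calibration; and
exact small fixtures for every printed-formula check. These sizes were
chosen to keep Monte-Carlo error comfortably below the margins being
tested.

## Known limitations

* The movement random factor has three levels; its variance component is
  weakly identified and fits are routinely singular — harmless for the fixed
  effects of interest, and flagged.
* Contrast dfs use the residual rule; printed dfs from other df
  approximations will differ slightly.
* AICc-minimization with many candidates admits spurious companions to true
  effects in the best model; recovery criteria therefore test containment
  of the planted term, not exact model identity.
* The imputation assumes angle biases are additive and shared across
  events; angle-by-individual interactions would need a richer model.
* Constant-`k` Elo updates keep a noise floor: because late interactions
  move ratings by up to `k/2` points regardless of how much history exists,
  two adjacent-ranked individuals can end slightly swapped even under a
  strictly transitive planted hierarchy. Exact-ordering recovery is
  therefore high but not guaranteed; rank correlation with the truth stays
  ≥ 0.97. A decaying `k` schedule would remove this at the cost of leaving
  the conventional method.
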