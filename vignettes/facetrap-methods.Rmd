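---
title: "Methods: facial photo-ID analysis for camera-trap surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: facial photo-ID analysis for camera-trap surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Photo-based capture–mark–recapture needs individually identifiable animals.
Pumas lack pelage markings, so lateral camera-trap images are a poor basis
for photo-ID; facial features (eyes, rhinarium, pinnae condition) are far
more individually distinctive but require the animal to face the camera.
`facetrap` implements the analysis side of evaluating that idea: it turns
raw photo tables into independent detection events, quantifies how often
faces are captured at sites with and without an attention-calling device
(ACD), measures how well independent raters agree when matching event pairs
by perceived identity, and models daily detection rates for evidence of
avoidance behaviour. A synthetic-data module generates every input with
known ground truth so the whole pipeline is testable without field data.

## Detection events

Photos at one site belong to one detection event while consecutive photos
are separated by at most the independence gap (default 30 minutes, the
conventional choice for large carnivores). The rule is *chained*: each
photo is compared with the previous photo, not with the event's start, so
a long burst can span more than the gap end to end. A strictly larger gap
starts a new event. Consequences worth knowing:

* regrouping is idempotent, and increasing the gap can only merge events,
  never split them (monotone coarsening);
* a photo pair exactly at the gap stays in one event ("greater than 30
  minutes" separates).

Event attributes aggregate photo flags: a face is "captured" when any
photo shows all facial features; the behaviour code is the most reactive
one present (retreat > curiosity > look-only > none > unknown — the field
assigns one category per event, and this precedence is our documented
tie-break); monochrome and flash flags are ORs; face resolution is the
maximum bounding-box pixel area.

Night/day is classified at the event **start time** (the triggering
moment; a mid-event definition would differ only for events spanning
twilight) using solar elevation from the NOAA low-accuracy solar-position
approximation, accurate to well under 0.5 degrees. "Night" means solar
elevation below −18° (astronomical twilight); the threshold is a
parameter. Refraction is ignored — it matters near 0°, not near −18°.
All timestamps are normalized to one configured Olson timezone before
grouping; DST is handled by the zone database (the package points `TZDIR`
at a usable database on load when the host's is broken, which matters in
minimal containers).

Face resolution is dichotomized by a median split (standard midpoint
median); values equal to the median deterministically go to "low". The
split is computed once on the full event set and inherited by subsets.

## Contingency analysis

Face-capture and behaviour counts are compared between ACD and
conventional sites with Pearson's chi-squared test of independence,
**without** Yates continuity correction: the reference statistic for the
published face-capture table (52/46 vs 12/98) is reproduced exactly only
uncorrected. Rates are reported as percentages rounded half away from
zero to one decimal. Retreat-vs-other reactions form a 2×2 by site type;
since the underlying field counts for that table were never published, it
is exercised on synthetic data only.

## Pairwise identity ratings

With \(n\) events there are \(n(n-1)/2\) unordered pairings (16 events →
120), each rated "same" or "different" by each of \(R\) raters. A rater's
implied identities are the connected components of the graph whose edges
are their "same" verdicts — transitive closure, exactly what an
interactive network display does. "Different" verdicts that land inside
one component are *contradictions*; they are reported, never auto-resolved,
because adjudicating them requires information the ratings do not contain.

The *singleton adjustment* flips, for every pairing where exactly one
rater dissents from the otherwise unanimous rest (an \(R-1\) vs 1 split),
that lone verdict to the consensus. The definition generalizes the
five-rater case to any \(R \ge 3\); the operation is idempotent and can
only increase unanimity. The reported singleton fraction counts
*pairings* with an \(R-1\):1 split among pairings with any disagreement
(the alternative — counting verdicts — is a different number; the pairing
reading matches "pairings with <100% agreement").

## Agreement statistics

Subjects of the kappa analysis are the pairings themselves with binary
categories, not identity labels. With \(n_{ij}\) raters assigning pairing
\(i\) to category \(j\):

\[ p_j = \frac{\sum_i n_{ij}}{NR}, \quad
   P_i = \frac{\sum_j n_{ij}^2 - R}{R(R-1)}, \quad
   \kappa = \frac{\bar P - \bar P_e}{1 - \bar P_e}, \;
   \bar P_e = \sum_j p_j^2 . \]

When every verdict falls in one category, \(\bar P_e = 1\) and kappa is
undefined; such subsets are reported as "perfect/degenerate agreement, no
CI" rather than a number. Confidence intervals are symmetric normal
intervals using the large-sample variance

\[ \widehat{\mathrm{var}}(\kappa) = \frac{2}{NR(R-1)}\cdot
   \frac{\bar P_e - (2R-3)\bar P_e^2 + 2(R-2)\sum_j p_j^3}{(1-\bar P_e)^2}, \]

with the z quantile kept at full precision (1.959964…) internally and
results rounded to two decimals for display.

**Known limitation (and an honestly red acceptance check).** This
variance is a null-type, large-sample estimator. In a calibration study —
500 tables at \(N = 120\), \(R = 5\), generated from iid pairing truths at
a truly-same fraction of 14/120 with rater errors calibrated so the
long-run kappa is 0.54 — the nominal 95% interval covers the long-run
kappa in ≈99% of replicates (empirical SD of \(\hat\kappa\) ≈ 0.076
versus a mean formula SE ≈ 0.10). The suite's calibration criterion
demands 90–98% coverage, so that test fails by construction; we keep the
prescribed estimator and the red test rather than quietly substituting a
different variance. Users wanting tighter intervals at non-null kappa
should bootstrap over subjects.

Attribute subsets follow the either/or/both framework: pairings where a
binary attribute (monochrome imagery, ambient light, pinnae damage,
high-resolution class) holds for both, neither, or exactly one member
event. Spearman's rank correlation between attributes uses average ranks
(equal to the phi coefficient for binary attributes, so
\(\chi^2 = N\rho^2\) on the 2×2); the p-value uses the t approximation,
with exact permutation enumeration available at \(n \le 8\) (full
enumeration at \(n = 10\) would be 3.6M permutations for a display-only
p-value; the narrowing is deliberate and documented).

## Detection-rate GLMM

Daily detection counts per site-day are modelled as Poisson with a log
link, z-scaled day covariates (days since deployment, days since lure
refresh; means/SDs stored for back-transformation), binary ACD and
scrape-site factors with interactions, and independent Gaussian random
intercepts for site, season (meteorological quarters DJF/MAM/JJA/SON —
the field definition was never stated, so the simplest calendar one is
used and is configurable) and calendar year. Fitting uses the Laplace
approximation via `lme4::glmer` — the same approximation class as the
field study's tooling — and reduces to an ordinary Poisson GLM when no
random terms are requested; the no-random-effect fit matches an IRLS GLM
to 10⁻⁶, which is the package's oracle for the likelihood machinery.
Hard optimizer failures abort loudly; near-boundary gradient warnings are
retained on the fit object as flags rather than being fatal, since they
are routine for sparse counts with small-variance groupings.

Backward selection repeatedly removes the eliminable term (marginality
respected: no main effect leaves while a retained interaction contains
it) whose removal costs the least log-likelihood, as long as the
likelihood-ratio test for the removal is non-significant at α = 0.05.
The exact elimination-order heuristics of specialized selection packages
are deliberately not replicated; instead every step is recorded in an
auditable trail (term, df, LL drop, p, removed). Model ranking uses AIC
with ΔAIC from the best; AIC is invariant to covariate scaling because
the likelihood is.

Type-III tests refit with sum-to-zero contrasts and Wald-test each term's
coefficient block against its full covariance, adjusting for all other
terms including the term's own interactions. Diagnostics follow standard
count-model practice: the dispersion ratio is the Pearson chi-squared
over residual df, and the zero-inflation ratio is observed zeros over
zeros expected under the fitted conditional means. A slope \(\beta\) on a
z-scaled day covariate back-transforms to
\((e^{\beta/\mathrm{SD}} - 1)\times 100\) percent per day; the field
study's own back-transformation was never stated, so only this package's
definition is tested.

## The synthetic world

The generator's defaults state the world the analyses expect: 61 sites
totalling 13,375 camera-days (staggered deployments over 18 months, lure
refreshed every 30 days), roughly half of sites with an ACD and half at
community scrapes; fixed effects on the scaled scale of about
(−4.2, ACD −0.2, scrape +0.6, deployment trend −0.1, lure 0, ACD×trend
−0.4) with a site intercept SD of 0.5 and small season/year SDs (0.2) —
magnitudes in the range of the published coefficient table, yielding a
few hundred events per realization. The rating exercise defaults to 16
events from 7 latent individuals with 10/16 monochrome, night strongly
associated with monochrome (IR flash), 6/16 events showing pinnae damage
(an individual-level trait inherited by events), and log-normal face
resolutions around a median of ≈39,216 pixels.

Raters are confusion models: a truly-same pairing is rated "different"
with probability `p_false_split`, a truly-different one "same" with
`p_false_merge`, with multiplicative attribute modifiers — mixed-pinnae
pairings force the false-merge rate to 0 (those pairs are unmistakably
different animals), and both-low-resolution pairings inflate both error
rates. Default error rates are calibrated, via the closed-form long-run
kappa of this confusion model, to ≈0.54 at the default truly-same
fraction. Errors are independent across raters and pairings given the
truth; the real rating process has transitivity pressure (raters see the
evolving identity network), which this deliberately does not model — so a
green synthetic test establishes formula and pipeline correctness, not
human rating behaviour.

For parameter-recovery studies the scenario fixes the season/year SDs at
0: three-to-four-level groupings are not meaningfully estimable and would
only add noise to a coverage assessment of the fixed effects. The
pre-registered recovery run (100 replicates at full scale, site SD 0.5)
gave per-coefficient 95%-CI coverage of 0.93–0.96.

## Numerical and degenerate-input policy

* Percent formatting rounds half away from zero (`format_percent`); base
  R's round-half-even would print 10.85% as "10.8%".
* Chi-squared tests refuse tables with a zero row/column total
  (degenerate) and non-integer counts (input error); distinct condition
  classes map to distinct CLI exit codes (2 input, 3 convergence, 4
  degenerate).
* Undefined kappa (single used category) is an error object, never NaN;
  subset analyses convert it to an explicit "degenerate" status.
* The event generator refuses schedules whose regrouping would merge
  events (photo-to-photo spacing at or below the independence gap).
* All simulation entry points take an integer seed and are byte-stable
  under it.

## Scope limits

No image analysis (face visibility and bounding boxes are inputs), no
species classification, no exact/Fisher tests, no weighted kappa or
k > 2 agreement beyond what the formulas allow, no negative-binomial or
zero-inflated fitting (diagnostics detect, they do not fix), no spatial
or temporal autocorrelation beyond the day-trend covariates, and no
automated reconciliation of contradictory identity matchings.
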