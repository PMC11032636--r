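---
title: "Form typicality for semantic size: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Form typicality for semantic size: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sizeform)
library(dplyr)
```

## The problem

Vocabularies carry statistical regularities between how words sound and what
they mean. For semantic *size*, the classic observation is that high front
vowels (as in *teensy*) pattern with small referents and low back vowels (as
in *tall*) with large ones; but such resemblance-based sound symbolism is
only one facet. Distributed *systematicity* — weak, vocabulary-wide
correlations between many surface-form properties and a meaning dimension —
can be quantified by regressing a semantic rating on a large battery of form
variables and scoring each word by its fitted value. `sizeform` implements
that measure, called **form typicality**, end to end:

1. derive 60 surface-form variables from ARPAbet pronunciations;
2. remove exactly collinear variables;
3. select the best predictive subset under Mallow's $C_p$;
4. z-score the fitted sizes: a word's typicality is how "large-sounding"
   its form is relative to the lexicon;
5. test whether typicality differs across lexical categories
   (Welch ANOVA, Games–Howell);
6. ask whether typicality predicts item-level behaviour (lexical decision,
   reading aloud, semantic decision, recognition memory) over and above
   standard lexical/semantic controls, via three-step hierarchical
   regressions with heteroskedasticity-consistent standard errors.

A seeded synthetic-data module generates lexicons, rater-level Likert
ratings and megastudy-style outcome tables with *known* planted parameters,
so every stage is verifiable without any external download.

## The form variables

Each pronunciation is a sequence of ARPAbet symbols with stress digits on
vowels. A fixed decision table (`arpabet_feature_table()`) classifies all
39 symbols: consonants by place (bilabial, labiodental, linguodental,
alveolar, palatal, velar, glottal), manner (stop, fricative, affricate,
nasal, liquid, glide) and voicing; vowels by height (high, mid, low) and
frontness (front, central, back), with diphthongs classified by their
nucleus and /ɔ/ (`AO`, the *tall* vowel) treated as low back. The table is
data, not code: any cell can be overridden by passing a modified table.

The 60 variables per word are: three lengths (letters, phonemes,
syllables); 21 class counts (3 heights, 3 frontness classes, 7 places, 6
manners, 2 voicing classes); 16 indicators each for the first and final
phoneme (vowel flag, 7 places, 6 manners, 2 voicing flags); and 4
primary-stress position indicators (initial, final, medial, multiple).
Syllable count is the vowel-phoneme count — a standard proxy that avoids a
syllabification algorithm. Monosyllables are coded `stress_initial`; words
with two or more primary-stress digits are `stress_multiple`; a word with
no primary-stress digit (as in some function words) is coded
`stress_initial` as well, which keeps the coding exactly invariant to
secondary-stress digits. An external stress table can override the
digit-derived coding when a separate stress database is preferred.

## Pruning exact collinearity

The 60 variables satisfy partition identities (heights sum to syllables,
places and manners each sum to the consonant count, voicing sums to the
phoneme count, each indicator block sums to one), so the matrix is rank
deficient by construction. `find_linear_combos()` walks the columns left to
right and drops any column lying in the span of the retained earlier ones
(two-pass Gram–Schmidt, relative tolerance `1e-8`), so the later-ordered
member of each identity is removed and the canonical column order is part
of the contract. By default the constant vector is included in the spanning
set (but never removable): sum-to-one identities such as the four stress
indicators alias the intercept of any downstream regression, and
matrix-only pruning would leave them in place. `intercept = FALSE` gives
the matrix-only behaviour for comparison with generic collinearity
filters.

## Best-subset selection under Mallow's $C_p$

With $\hat\sigma^2$ the residual variance of the model containing every
(pruned) variable and $p$ the parameter count including the intercept,

$$C_p = \frac{RSS_p}{\hat\sigma^2} + 2p - n,$$

so the full model has $C_p = p$ exactly — a property the tests assert. The
criterion is equivalent to AIC for linear models and estimates predictive
accuracy, which is the right target when the fitted values themselves (the
typicality scores) are the quantity of interest.

`best_subset_cp()` finds the *exact* minimizer over all subsets up to
`max_features`. The search is a branch-and-bound over include/exclude
decisions, implemented in C++ on a sweep-operator tableau of the centred,
column-standardized Gram matrix ($O(k^2)$ per node). Each node bounds its
completions by combining two valid lower bounds on the residual-sum
increase of dropping $m$ free variables: the $m$-th smallest single-drop
cost (any dropped set contains a variable at least that expensive, and
dropping a superset can only raise RSS), and an eigenvalue bound
$\lambda_{\min}(G)\sum_{j}\beta_j^2$ from interlacing. A forward-selection
warm start seeds the incumbent. Ties in $C_p$ (tolerance $10^{-7}$) go to
the smaller subset, then to the lexicographically earlier column set, so
output is deterministic. An exhaustive enumeration mode exists up to 25
columns; the test suite verifies branch-and-bound against independent
enumeration on hundreds of random problems. Candidate incumbents are
re-evaluated with a fresh factorization so sweep round-off never
contaminates the reported optimum.

Typicality is the selected model's fitted value, z-scored with the fitting
set's mean and SD; the constants are stored on the model (and in its JSON
serialization), so new words are scored on the same scale and scoring is
reproducible bit for bit.

## Group comparisons

Typicality rarely satisfies variance homogeneity across lexical categories,
so the workflow is: Bartlett's test (`stats::bartlett.test`) as the
diagnostic, Welch's ANOVA (`stats::oneway.test`) as the omnibus test, and
Games–Howell pairwise post hocs. The effect size reported with the Welch F
is $\hat\omega^2 = \frac{df_1(F-1)}{df_1(F-1)+N}$ — the conventional
approximation in this literature, documented as approximate. Games–Howell
uses per-pair Welch standard errors and Satterthwaite degrees of freedom
with $q = |\bar x_i - \bar x_j|\sqrt{2}/SE$ referred to the studentized
range distribution with the full number of groups (`stats::ptukey`). With
two groups it reduces exactly to the Welch t-test; under homogeneity with
large equal groups it tracks Tukey's HSD to within a couple of percentage
points on the probability scale. (Agreement in *relative* terms is not a
meaningful target for tail p-values: p depends exponentially on the
sample-variance-based q statistic, so even exact implementations differ by
tens of percent on very small p's.)

## Hierarchical regressions with robust errors

`fit_hierarchical()` fits cumulative OLS models: controls in step 1, size
ratings in step 2, typicality in step 3 (any block structure is allowed).
Predictors are mean-centred by default, which provably changes only the
intercept. Coefficient covariance uses the HC2 sandwich estimator by
default (`sandwich::vcovHC`; HC0/HC1/HC3 selectable), and the package
refuses HC2/HC3 when an observation has leverage 1, naming it. ΔR² is
reported on unadjusted R² (adjusted R² may decrease and is tabulated
separately). The significance of each increment is a robust Wald χ² on the
newly added block's coefficients using the same sandwich covariance — a
deliberate choice documented here: pairing ΔR² with a classical F would
contradict the robust fitting, and the Wald form holds its nominal size
under the heteroskedastic null in the calibration tests. Missing data are
handled by listwise deletion with a recorded count.

## What the synthetic generator emulates

`generate_lexicon()` builds words from (onset)(vowel)(coda) syllable
templates with syllable-count probabilities (.33, .42, .18, .06, .01 for
1–5 syllables) matching a large English norms set, one primary stress per
word (2% carry two, emulating even stress), secondary-stress digits on 15%
of unstressed syllables, and orthography derived deterministically from
phonemes through a grapheme map, so letter length correlates naturally
with phonological length. All 24 consonants are available in onset *and*
coda: phonotactic realism is explicitly not a goal — spanning every
decision-table category is, so that every one of the 60 variables (and the
rank structure of their matrix) is exercised. Real English data differ in
ways that matter for interpretation: no glottal/glide codas (which changes
*which* columns are exactly collinear), Zipfian rather than uniform phoneme
frequencies, and correlated covariates. Passing tests on synthetic data
therefore validate the machinery and its statistical properties, not any
claim about English.

`generate_size_ratings()` plants the ground truth: latent size = intercept
3.017 + 18 nonzero slopes on form variables (e.g. +0.361 per syllable,
−0.113 per high vowel, +0.239 for final stress), word-level noise, then 30
simulated raters each reporting the latent value plus unit-SD rater noise
rounded and clamped to the 1–7 scale. The word-noise SD default of 1.30
was calibrated once against the measured planted-signal variance (0.433)
so that refitting on rating means yields an adjusted R² near .20 at
n ≈ 2,900 — the regime the measure is designed for; the 100-seed
validation run asserts the refit adjusted R² stays inside [.15, .25] on
every seed. Heterogeneous rater SDs (`sd_rater_spread`)
produce words exceeding the 1.5 rating-SD exclusion cutoff when the filter
itself is under test.

`generate_outcomes()` plants behavioural effects by target ΔR²: the latent
outcome is built from three sample-orthogonalized standardized components
(a weighted controls index; size residualized on controls; typicality
residualized on controls and size) with slopes solved from the requested
cumulative R² targets, plus unit noise. Defaults plant a step-3 typicality
increment of .005 on zRT with a negative (facilitatory) sign, .002 for
step 2. zRT is standardized across items; accuracy and corrected hit
probability are clamped affine maps into [0, 1] and [−1, 1].

## Problem sizes and numerical choices

The heavy validation runs use n = 2,900 words with 100 seeded replicates
for end-to-end recovery, 10,000 replicates for Welch type-I calibration,
2,000 for the robust increment tests, and 200 random problems (≤ 12
features) for exact-search verification — sizes chosen so the full suite
completes comfortably on a single core while leaving the binomial noise on
every calibrated rate well inside its acceptance band. Seeds fan out from
one integer to per-stage child seeds so stages can be regenerated
independently. Key tolerances: pruning `1e-8` (scaled), $C_p$ ties `1e-7`,
z-score identities asserted at `1e-10`.

## Known limitations

* **Selection is not consistent at small effect sizes.** Five of the 18
  planted slopes have true |t| near 2 at n = 2,900; a $C_p$/AIC-type
  criterion includes such variables with probability well below 1, so the
  *entire* planted set survives selection only rarely, even though the
  full-design refit covers every planted coefficient within 3 SEs and the
  typicality scores themselves are stable (fitted values are far less
  sensitive than subset membership). Users comparing selected subsets
  across samples should expect membership churn among marginal variables.
* The ω² formula applied to the Welch F is an approximation; it can be
  slightly negative under the null.
* Default synthetic covariates are independent normals; the strong
  length–neighbourhood–typicality collinearity of real lexicons appears
  only when a correlation structure is supplied.
* The 60-variable inventory is one defensible reconstruction of this
  family of measures; frontness counts and the monosyllable stress
  convention are choices documented above, validated through internal
  consistency (partition identities, pruning structure), not against any
  external variable list.
* Grapheme-to-phoneme conversion, syllabification and non-English
  inventories are out of scope.
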