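---
title: "Measuring session-level linguistic synchrony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring session-level linguistic synchrony}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lingsync)
```

## The measurement model

Interpersonal synchrony — the alignment of responses between interactants —
has a linguistic face: speakers who are "in tune" tend to adopt similar
linguistic stances. lingsync operationalizes linguistic synchrony at the
level psychotherapists and clients actually experience and recall: the
**session**. The unit of measurement is the *sub-transcript*, all of one
speaker's language within one session. A dyad with $n$ sessions yields $2n$
sub-transcripts, labelled $C_1 \dots C_n$ (client) and $T_1 \dots T_n$
(therapist).

Each sub-transcript is summarized by four 0–100 composites of word-category
percentages, in the tradition of dictionary-based text analysis:

* **analytic thinking** — formal, logical style (articles, prepositions)
  versus narrative, here-and-now style (pronouns, auxiliaries, conjunctions,
  adverbs, negations);
* **clout** — confident, other-focused stance (*we*, *you*) versus
  tentativeness (*maybe*, *perhaps*);
* **authenticity** — disclosing, personal language (first-person singular
  and third-person pronouns, exclusive words) versus guarded language
  (negative-emotion words, motion verbs);
* **emotional tone** — positive- minus negative-emotion words, with 50 as
  the "no emotionality" anchor.

The dyad's $2n \times 4$ profile matrix is z-scored per variable (pooled
over both speakers, so scores are relative to *that dyad's* average) and
clustered with k-means at an elbow-selected $k$. The synchrony rule is
**co-membership**: session $x$ is synchronized iff $T_x$ and $C_x$ land in
the same cluster — therapist and client language within a synchronized
session is more similar to each other than to the rest of the treatment.
The dyad-level outcomes are (i) which sessions are synchronized, (ii) the
percentage of synchronized sessions, and (iii) their distribution across
the treatment span (contiguous blocks versus intermittent singletons),
computed by `session_synchrony()` and `distribution_summary()`.

```{r pipeline}
res <- dyad_synchrony(dyad_profiles("B"))
glance(res)
```

## Scoring: what is (and is not) reproduced

The four summary variables of the commercial LIWC program are defined up to
sign structure in the published literature, but their exact standardization
against LIWC's norming corpora is proprietary. `summary_variable()`
therefore implements the documented *signed composition*

$$\mathrm{score} = \mathrm{offset} + \sum_{c \in \mathrm{pos}} p_c -
  \sum_{c \in \mathrm{neg}} p_c, \qquad \text{clamped to } [0, 100],$$

where $p_c$ is the percentage of tokens matching category $c$ and the
offset defaults to 50, the scale midpoint. Scores from this open
composition are internally consistent and monotone in the right categories,
but are **not** numerically comparable with LIWC output. For that reason
the pipeline also accepts precomputed score tables (`read_profiles()`), and
the bundled three-dyad dataset ships LIWC-scored values directly; the
clustering and synchrony stages are agnostic about where the four numbers
came from.

Other scoring conventions: matching is case-insensitive; a trailing-`*`
pattern is a prefix match of at least the stem length; a token counts once
per category however many patterns of that category it matches; tokens are
maximal alphanumeric runs with internal apostrophes (contractions are one
token). Empty sub-transcripts score a flagged (50, 50, 50, 50) — the scale
midpoint — and can be excluded with `drop_degenerate = TRUE`.

## Choosing k: the elbow rule and its override

Distortion (the k-means objective, the total squared distance of objects to
their assigned centers) decreases monotonically in $k$, reaching 0 at
$k = 2n$; the elbow is the point after which further clusters stop paying
for their loss of parsimony. `elbow_scan()` operationalizes the visual
elbow as the $k$ maximizing the discrete curvature
$d(k{-}1) - 2d(k) + d(k{+}1)$, ties going to the smaller $k$.

A numerical rule cannot fully substitute for reading the plot: adjacent
curvatures can be close, and an analyst reading the curve may defensibly
pick the next $k$. This happens with bundled Dyad A, where the curvature
rule picks $k = 2$ while the dataset's reference analysis reads the elbow
at $k = 3$; `dyad_synchrony(, k = )` exists precisely for this documented
override, and the report records both the scan and the $k$ actually used.
At the reference $k$ the co-membership outcomes of all three bundled dyads
are stable across seeds.

Two degenerate situations are flagged rather than hidden: a distortion
curve with no pronounced elbow (near-zero maximum curvature) warns that the
chosen $k$ is unreliable, and a $k = 1$ solution warns that co-membership
synchrony is degenerately 100%.

Numerical choices: distortion is the *squared*-distance sum, the objective
Lloyd's algorithm actually minimizes (the unsquared sum is also reported
for plotting); initialization is k-means++ with 50 restarts and a fixed
seed by default, so reported solutions are reproducible bit for bit;
iterations run to an assignment fixpoint (cap 300); an emptied cluster is
reseeded at the point farthest from its center; if a scanned distortion
ever exceeds its predecessor (restart underspend) that $k$ is refit with
5× restarts. On instances small enough to enumerate, the restarted fits
attain the exact partition optimum (`brute_force_kmeans()` is the test
oracle, and base R's `stats::kmeans()` an independent cross-check).

## Preprocessing choices

Z-scoring uses the sample SD (denominator $n-1$); the population-SD variant
is available via `sd_type` and, being a per-column rescaling by a common
factor, does not change cluster assignments. Optional per-speaker
mean-centering (`mean_center_by_speaker()`) subtracts each speaker's own
variable means before standardizing, for analysts who want within-person
variation isolated from between-person offsets; it is **off** by default,
and the package deliberately reports rather than asserts its effect, since
centering can but need not alter clustering outcomes.

## What the simulator emulates

`simulate_profiles()` generates the statistical structure the co-membership
measure assumes, with known ground truth. Each session is independently
synchronized with probability `planted_rate`. A synchronized session has a
*single shared linguistic profile*: one draw from an isotropic Gaussian
around the synchronized-session center, used for both rows (an optional
within-pair jitter `pair_sd` softens this; its default 0 is the
perfect-synchrony limit, in which the two rows of a synchronized session
coincide and co-cluster at any $k$). An asynchronized session draws its
therapist and client rows independently around role-specific centers.

The default geometry places the therapist and client centers at
$\pm\,\mathrm{separation}/2$ noise-SD units on *every* variable
(`separation = 6`, i.e. a 6-SD per-variable gap and a 12-SD Euclidean gap),
with the synchronized-session center equidistant (about 8.5 SD) from both.
These are deliberately well-separated regimes: role polarization of the
size seen in real guidance-style dyads, scaled so that cluster
misassignment is a $\Phi(-4)$-or-rarer event and recovery error reflects
the measure, not boundary noise. Under this design the pipeline recovers
the realized planted rate exactly across the {0, 0.25, 0.5, 1} range
(verified over 50 seeds per rate at 50 sessions in the test suite, with an
elbow scan over $k \le 6$ and 10 restarts — ample for such separated
structure).

What the simulator does *not* emulate: correlated variables (unless you
pass a `sigma` covariance), session-to-session autocorrelation, gradual
drift in stance over treatment, and any real English discourse structure —
`simulate_token_stream()` draws tokens i.i.d. from category
representatives plus filler and is meant to validate the scorer's
percentage arithmetic, not to look like speech. Passing tests on this
synthetic structure shows the *measurement machinery* is correct; it does
not validate the construct on real therapy talk.

## Limitations

* The synchrony percentage depends on the chosen $k$; the elbow is
  sometimes genuinely ambiguous, which is why the report always carries the
  full scan and configuration.
* No null model is attached to a dyad's percentage; a within-role
  permutation test would be a natural extension.
* Scores from the open composition and from LIWC are on different scales;
  do not mix them within one dyad.
* The bundled dataset is three dyads — an illustration, not a sample;
  nothing here licenses claims linking synchrony to treatment outcome.
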