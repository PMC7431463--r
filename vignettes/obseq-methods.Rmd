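---
title: "Analyzing coded interaction sequences: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing coded interaction sequences: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(obseq)
```

## The data model

`obseq` works on *multi-event sequence data*: an ordered list of
observation units, where each unit is a set of co-occurring categorical
codes — typically one speaker (turn) code plus the communication
strategies coded for that conversational turn. The codes come from an
*observation instrument*: a field format combined with category systems,
i.e. a set of named dimensions each holding a closed, mutually
exclusive, exhaustive category set. Units carry no durations; order is
the clock, and the internal time of record *i* is simply its 0-based
index. This is the weakest — and most robust — temporal assumption one
can make about transcribed conversation, and all three analyses below
are formulated directly on it.

The packaged instrument (`study_instrument()`) codes group-psychotherapy
conversation: 13 content dimensions totalling 28 communication-strategy
codes (questioning `QA`, paraphrasing `RP`, mentalization `MNT`,
expressivity codes `RA`/`EC`/`CD`/`RB`, laughter `R`, and so on) plus a
turn dimension of speaker codes. One wrinkle is worth documenting: the
printed declaration block for this instrument lists seven speaker codes
but the accompanying record rows also use `T` for the lead therapist.
`study_instrument()` therefore adds `T` by default (eight speakers);
`study_instrument(add_therapist = FALSE)` returns the declaration block
verbatim.

Two text dialects are supported. The native multi-event dialect declares
the instrument in a `($NAME = code ...)` block ending in `;`, then one
row per unit ending in `.`, with `/` closing the session. The THEME
dialect splits the same information into a `.vvt` category file and an
`.rdt` record file whose rows are stamped at a conventional constant
increment (`time_step`, default 5) because event-based data have no real
times; `write_theme()` and `read_theme_rdt()` round-trip this exactly.
Code matching is case-insensitive on read and canonicalized to upper
case, because the two dialects disagree on case in circulating material.

## Interobserver reliability

`cohens_kappa()` computes the standard chance-corrected agreement
between two aligned codings, with Landis–Koch qualitative bands
(`landis_koch_band()`). `session_agreement()` compares two codings of
one session *per dimension*, scoring the absence of any code of a
dimension as an explicit `"<none>"` pseudo-category — so coders disagree
when one of them saw nothing to code — and also reports a pooled kappa
over the concatenated dimension-wise codings. Published reliability
figures for this kind of material rarely state whether they are
per-dimension or pooled, which is why both are always reported. The
degenerate case (both coders constant and identical, expected agreement
1) returns kappa 1 by convention, flagged.

## Lag sequential analysis

For a *given* (criterion) behavior and a *conditional* behavior at lag
*k*, the unit of evidence is the 2×2 table over all record pairs
(*i*, *i + k*): given present/absent at *i* against conditional
present/absent at *i + k*. With joint count *x*, margins *r* and *c*,
and *N = n − |k|* pairs, the Allison–Liker adjusted residual is

$$z = \frac{x - rc/N}{\sqrt{(rc/N)\,(1 - r/N)\,(1 - c/N)}},$$

asymptotically standard normal under no sequential association.
`|z| > 1.96` marks activation (`z > 0`) or inhibition (`z < 0`) at
alpha = 0.05; the threshold is `qnorm(1 - alpha/2)` and alpha is
configurable. Degenerate margins (a behavior never or always present
among the paired records) leave *z* undefined and are reported as
missing, never as zero — silently zero-filling would bias every
aggregate built on top.

Design choices that were genuinely open:

* **The 30-record floor.** Sequential statistics on shorter sessions
  are too unstable to interpret; `residual_matrix()` refuses sessions
  under 30 records unless `allow_short = TRUE` downgrades the refusal
  to a warning.
* **Lag-0 entries** are computed only across dimensions: two codes of
  one dimension are mutually exclusive by construction, so their lag-0
  association is structurally degenerate and is reported as undefined.
* **Pattern construction stop rules.** `construct_pattern()` walks
  outward from lag 0 and collects significant conditionals per lag.
  A direction stops when (a) it holds no further significant behaviors,
  or (b) two consecutive empty lags follow at least one contributing
  lag. A third convention — stop after the nearer of two consecutive
  significant lags, the "MAX LAG" — is interpretive rather than
  statistical, and is only applied behind `strict_maxlag = TRUE`.
  Undefined residuals count as empty lags.

## Polar coordinate analysis

Polar coordinate analysis condenses the residuals around one *focal*
behavior into one vector per conditional behavior. Cochran's reduction
$Z_{sum} = \sum z_i / \sqrt{n}$ aggregates the residuals at lags
+1..+`n_lags` into a prospective score and those at −1..−`n_lags` into a
retrospective score; each pair becomes a vector with

$$\mathrm{length} = \sqrt{Z_{sum,p}^2 + Z_{sum,r}^2}, \qquad
  \varphi_0 = \arcsin\!\left(\frac{|Z_{sum,r}|}{\mathrm{length}}\right),$$

plotted with prospective on the x-axis and retrospective on the y-axis.
The sign pair fixes the quadrant — (+,+) mutual activation, (−,+) focal
inhibits/is activated, (−,−) mutual inhibition, (+,−) focal activates/is
inhibited — and the arcsin is corrected into the quadrant's arc
(I: φ₀, II: 180−φ₀, III: 180+φ₀, IV: 360−φ₀). The raw arcsin alone
cannot exceed 90°, so the correction is forced by any vector outside
quadrant I. Zeros are treated as positive for quadrant assignment;
a zero-length vector has no direction and is returned flagged
`degenerate` rather than assigned an arbitrary angle. Five prospective
and five retrospective lags are the conventional minimum, and the
default.

Two retrospectivity conventions are exposed. *Classic* retrospectivity
reads the negative-lag residuals forward. *Genuine* retrospectivity
(the default) feeds backward in time — operationally, the prospective
analysis of the time-reversed session. For the adjusted residual these
coincide exactly: the 2×2 lagged table is invariant under reversing the
session and flipping the lag sign, a property the test suite asserts.
Both code paths are kept because the two conventions differ for
statistics that are *not* symmetric in this way, and because users
expect to state which convention a result used. Lags whose residual is
undefined are dropped from the Zsum and the divisor √n reduced, with a
warning — zero-filling would shrink vectors toward the origin by an
arbitrary amount.

**A calibration caveat.** The conventional significance rule marks a
vector when its *length* exceeds 1.96. Under a null with independent
approximately standard-normal Zsums, the squared length is χ² with two
degrees of freedom, so the rule flags ≈ e^(−1.96²/2) ≈ 14.6% of null
vectors — roughly three times the nominal 5% of the per-residual rule.
Monte-Carlo runs in the test suite reproduce rates of 12–15% across
alphabet sizes. The package keeps the conventional threshold because it
is what published tables mark with "(*)" — but maps and tables should be
read with this anticonservatism in mind; a two-dimensional 5% criterion
would put the circle at √χ²₂(0.95) ≈ 2.45 instead.

## T-pattern detection

A T-pattern is a recurrent, hierarchically nested sequence of
event-types whose inter-component distances fall within statistically
significant *critical intervals*. `session_to_series()` converts a
session into point processes on the record-index timeline: every code
becomes an event-type, and each observed turn-by-content co-occurrence
(e.g. `T,QA` — "the therapist asks a question") becomes an additional
composite event-type. Full power-set expansion of co-occurrences is
deliberately not done: it is combinatorially explosive and the
turn-by-content pairs are the units of interest in conversation data.

The pair test: under the null, occurrences of B fall independently per
time unit at rate λ = N_B/T, so an A-occurrence has probability
p₀ = 1 − (1 − λ)^w of being followed by at least one B in a w-unit
window. The p-value is the upper binomial tail P(X ≥ C) for
X ~ Binomial(N_A, p₀), where C counts A-occurrences actually followed by
a B in the window (several Bs in one window count once). This null is
deliberately simple and slightly conservative on sequences with strong
autocorrelation; the suite verifies rejection at or below the nominal
rate on shuffled data.

Detection is level-wise and bottom-up (`detect_tpatterns()`): level 1
tests all ordered pairs of distinct event-types; significant pairs
(p < alpha) whose greedily matched, non-overlapping occurrences number
at least `min_occ` become patterns; later levels treat patterns as units
(occurrence time = first terminal's time) and pair them with units whose
terminal sets are disjoint. Defaults follow the established practice for
event-based data: window fixed to [1, 1] (temporal distance of one
observation unit), `min_occ = 30`, `alpha = 0.005`. A free-interval
search (smallest binomial tail over windows [1, d], d ≤ `max_interval`)
is available behind `free_interval = TRUE`; it is uncorrected for the
selection over windows, as in the original software tradition, and the
number of candidate windows tried is recorded on each pattern for
transparency. Redundancy reduction drops a pattern when another detected
pattern contains it as a subtree occurring at exactly the same set of
start times — an operational stand-in for the proprietary "completeness
competition" of the reference implementation.

## The synthetic session generator

Real transcripts of this kind are rarely shareable, so the package
ships a seeded generator (`generate_session()`) whose output has the
statistical structure the analyses assume: a Markov chain over speakers
(turn-taking), a per-speaker emission distribution over content codes,
optional *lag rules* that plant sequential dependencies (after a
trigger at row *i*, the content of row *i + lag* is overwritten with a
response with stated probability), and optional recurring patterns
written at fixed gaps into non-overlapping anchor rows
(rejection-sampled, capacity-checked). Rules apply in declaration
order, later rules may overwrite earlier responses, and generation is
fully deterministic given the seed; the caller's RNG stream is left
untouched.

`study_like_config()` is the package's reference condition: eight
speakers; turn-taking that returns to the therapist about half the
time; a therapist emission mix with 25% questioning, 15% mentalization
and 10% paraphrasing — matching the intervention shares the worked
examples report — and adolescent speakers dominated by topic
continuation and answers; 600 rows by default, comfortably above the
30-row validity floor and long enough for `min_occ = 30` pattern
detection to be meaningful.

What the generator does *not* emulate: session-phase drift in code
mixes, speaker-specific reply latencies beyond lag-1 rules, and the
within-row multiplicity of real codings (generated rows carry exactly
one turn and one content code, where real rows may carry several
content codes). Tests passing on generated data therefore demonstrate
the statistical machinery under its stated assumptions, not fidelity to
any particular clinical corpus.

## Numerical and scale choices

* Residual-vs-brute-force equivalence is asserted to 1e−12 on random
  sessions up to 50 rows; vector angle/length round-trips to 1e−9.
* Null calibration in the test suite uses 1000 i.i.d. 4-code sessions
  of 200 rows — the 4-code uniform alphabet keeps expected joint counts
  near 12, large enough for the residual's normal approximation to
  hold, which is the same adequacy logic behind the 30-record floor.
  The planted-effect power checks use 100 seeds of 600-row sessions.
* Published polar worked examples are reproduced from their printed
  two-decimal Zsum inputs; lengths agree within ±0.02 and angles within
  ±0.3°, the discrepancy budget implied by the rounding of the inputs.
  One published table prints quadrant III for a vector whose two Zsums
  are positive; the package derives quadrants from signs and does not
  special-case such rows (the accompanying figure and text agree with
  the sign-derived quadrant I).
* Ties and zeros: a Zsum of exactly 0 counts as positive for quadrant
  assignment; band boundaries in `landis_koch_band()` carry a 1e−9
  epsilon so ratio arithmetic cannot tip a value across a printed cut
  point.

## Worked example

```{r example}
ses <- study_session("early")
ses
code_frequencies(ses, within_turn = "T")

inputs <- study_polar_inputs()
polar_vector(inputs$zsum_prospective[2], inputs$zsum_retrospective[2])
```

```{r simulated}
cfg <- study_like_config(
  seed = 42, n_rows = 600,
  lag_rules = data.frame(trigger = "QA", response = "RA", lag = 1, prob = 0.9))
sim <- generate_session(cfg)
rm <- residual_matrix(sim, "QA", c("RA", "EC", "RP"), -2:2)
subset(as.data.frame(rm), significant)
```
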