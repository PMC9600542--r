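---
title: "Disproportionality-based signal detection on spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality-based signal detection on spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous pharmacovigilance databases collect individual case safety
reports (ICSRs): one report describes one patient, one or more suspected
drugs, and one or more adverse events coded as MedDRA-style preferred
terms (PTs). Because there is no denominator of exposed patients,
associations are sought by *disproportionality*: a drug–event pair is
interesting when the pair is reported more often than the drug's and the
event's overall reporting rates would predict. pvsignal implements this
screen end to end — contingency tables, the three standard statistics, a
composite signal criterion, roll-up of signal PTs to primary system organ
classes (SOCs), demographic summaries, and a treemap of the signal
profile — together with a synthetic report generator that provides ground
truth for validating every stage. The motivating use case is the safety
profile of biologics for severe asthma (omalizumab and the other
anti-IgE/IL-5/IL-4R antibodies), where ear-and-labyrinth and
eosinophil-related reporting patterns are of clinical interest because of
eosinophilic otitis media, but the machinery is generic.

## The model

For a target drug $D$ and event $E$, reports are cross-classified at the
case level into the two-by-two table

|              | event $E$ | other events |
|--------------|-----------|--------------|
| drug $D$     | $a$       | $b$          |
| other drugs  | $c$       | $d$          |

with $n = a+b+c+d$ the size of the background universe. Each report
falls in exactly one cell; listing a drug or event twice in one report
counts once (drugs and events are sets per report).

The statistics are

* proportional reporting ratio
  $\mathrm{PRR} = \dfrac{a/(a+b)}{c/(c+d)}$,
* reporting odds ratio
  $\mathrm{ROR} = \dfrac{a/b}{c/d} = \dfrac{ad}{bc}$,
* shrinkage information component
  $\mathrm{IC} = \log_2 \dfrac{a + 1/2}{E + 1/2}$, where
  $E = (a+b)(a+c)/n$ is the count expected under independence.

The $+1/2$ terms pull rare pairs toward $\mathrm{IC} = 0$; for large
counts the IC converges to the plain $\log_2(a/E)$, the log observed-to-
expected joint reporting ratio. PRR and ROR use the raw cells with no
continuity correction. Statistics whose denominators vanish are
*undefined* and returned as `NA` — never clamped to $0$ or $\infty$ —
and an undefined statistic fails the signal criterion. This avoids
spurious infinite RORs when $d = 0$.

A pair is flagged as a **signal** when all of the following hold
(`signal_criteria()`): at least 3 reports ($a \ge 3$),
$\mathrm{PRR} \ge 2$, $\mathrm{ROR} \ge 2$, and the lower 95% credibility
bound of the IC above 0. The IC comparison is strict (`> 0`) by default
with a flag to relax to `>= 0`; the count/PRR/ROR thresholds are
conventional in routine signal detection and all four are tunable.

### The IC credibility bound

`ic025()` offers two routes to the lower bound:

* `method = "approx"` (default): the published closed form
  $\mathrm{IC}_{025} = \mathrm{IC} - 3.3\,(a+1/2)^{-1/2} -
  2.4\,(a+1/2)^{-3/2}$.
* `method = "mc"`: the 2.5th percentile of
  $\log_2\!\big(G/(E+1/2)\big)$ over draws
  $G \sim \mathrm{Gamma}(a + 1/2,\ \mathrm{rate} = 1)$, the posterior of
  the observed count under the shrinkage model.

The two do not coincide exactly: the closed form is an approximation
whose documented accuracy is about $0.1$ on the IC scale. The package's
own measurements (see `tests/testthat/`) put the deterministic gap at
$\approx 0.08$ for $a = 3$, $\approx 0.06$ at $a = 10$, and below
$0.05$ only from roughly $a \approx 40$ upward; Monte-Carlo noise at
$10^6$ draws adds $\pm 0.003$. The closed form is the default because it
is deterministic and fast at database scale; the gamma-posterior MC is
retained as the validation oracle. Since the closed-form penalty is
always positive, $\mathrm{IC}_{025} < \mathrm{IC}$ for every table.

### Choice of background universe

`build_table()` supports two comparator universes. `all_reports`
(default) uses every report in the dataset, matching the "all other
drugs" reading of the contingency table. `listed_drugs_only` restricts
the universe to reports listing at least one drug from an explicit
comparator set, for within-class comparisons. The package asserts
neither as the "correct" choice; published analyses are often ambiguous
on this point, and the two can differ materially (see the degenerate
regime below).

## The synthetic-report generator

`generate_reports()` draws, per report:

1. **drugs** — independent Bernoulli per catalog drug with its marginal
   probability, re-drawn until at least one drug is listed;
2. **events** — independent Bernoulli per catalog PT with probability
   $\min(1, \text{baseline} \times \rho)$, where $\rho$ is the largest
   planted relative reporting ratio among the report's listed drugs for
   that PT (1 if none), re-drawn until non-empty;
3. **demographics** — independent draws from per-field marginals.

Taking the maximum $\rho$ across a report's drugs (rather than a
product) keeps the per-pair marginal interpretable: the in-drug event
rate for a planted pair is baseline × ρ regardless of co-medication.
Conditioning on non-empty drug and event sets reflects that a
spontaneous report exists only as a drug–AE record; under the null it
inflates all event rates by a common factor and leaves drug–event
independence — hence PRR = ROR = 1 and IC = 0 in expectation — intact.
Ground truth labels pairs planted with $\rho \ge 2$ as true
associations; everything else in the catalog cross-product is a null
pair.

The default demographic marginals (`demographic_defaults()`) reproduce
the demographic mix published for omalizumab reports in a global
database: 78.2% of reports from the Americas, 64.6% female, 50.9%
serious, age unknown in 47% of reports. They are renormalized to sum to
one per field and drawn independently of drugs and events, since only
marginals (not joint distributions) are published.

### Default catalogs and the degenerate-share regime

The default catalogs (`demo_config()`) emulate a whole-database universe
containing the five asthma biologics. Their marginal probabilities keep
the published report-volume ratios (32,618 : 7,344 : 2,387 : 315 :
20,559) but are scaled so the five drugs jointly cover about a tenth of
reports, with five common asthma co-medications supplying the
background. This is a deliberate design choice: if the universe were
the five biologics alone, omalizumab would account for ~52% of all
reports, and the shrinkage IC — bounded above by $\log_2(1/\text{drug
share})$ — could never materially exceed 0.95, making the
$\mathrm{IC}_{025} > 0$ criterion nearly unattainable for omalizumab no
matter how strong the association. Published whole-database analyses do
not face this because any single drug is a tiny share of the database;
the default catalogs reproduce that regime.

Planted relative reporting ratios are the published disproportionality
strengths for these drugs: all seventeen ear-and-labyrinth and eight
eosinophil-related PRRs of omalizumab, the three ear and two eosinophil
signals of mepolizumab, and one abnormal-eosinophil-count association
each for benralizumab and dupilumab. Baseline event probabilities were
chosen once as field-realistic values — common complaints (drug
ineffective, headache, dyspnoea, injection-site reactions, …) dominate
with roughly two events per report before conditioning, while ear and
eosinophil terms are rare — sized so planted pairs have expected
co-report counts of roughly 8–50 at the default 60,000 reports. At that
size a typical run recovers 80–95% of planted pairs and falsely flags
under 1% of null pairs, with the ear-and-labyrinth SOC dominating the
signal treemap, qualitatively matching the published signal profile.

### What the generator does *not* emulate

Duplicate reports, temporal reporting dynamics (notoriety and
stimulated-reporting waves), co-prescription structure, dependence of
demographics on drugs or events, and masking by competing signals are
all absent. Passing tests on synthetic data therefore demonstrate that
the statistics and plumbing are correct under the stated generative
model — not that the thresholds have any particular sensitivity or
specificity on real spontaneous-reporting data, where these biases are
the main analytic difficulty.

## Numerical and interface choices

* **Percentages** in summary tables are rounded half-up to two decimals
  (`round_half_up()`), matching the convention of published report
  tables; base R's round-half-to-even disagrees on exact ties.
* **Orderings** are deterministic everywhere: screen results by drug,
  descending report count, then PT; roll-ups by descending signal count;
  all string sorts under C collation, independent of the session locale.
* **Interchange** is UTF-8 RFC-4180 CSV with a fixed field order and a
  canonical row order, so equal datasets serialize byte-identically and
  `read_icsr_table(write_icsr_table(d))` recovers `d` exactly.
* **Eosinophil filter**: the case-insensitive singular substring
  `"eosinophil"` is used, since terms like "Eosinophilia" and
  "Eosinophil count increase" do not contain the plural form.
* **Empty margins**: a drug or event absent from the dataset yields a
  table with an empty margin and undefined statistics, not an error.
* **Age bands**: the demographic bands include textually overlapping
  "45–65 years" / "65–74 years" labels as published; the generator
  treats them as disjoint with age 65 in the younger band.
* **Seeds**: every stochastic routine (generator, MC bound) takes an
  explicit seed and restores the caller's RNG state.

## Validation problem sizes

The shipped test-and-acceptance suite exercises the pipeline at sizes
chosen to make sampling noise negligible relative to the effects under
test while keeping a full run in the low minutes: a 60,000-report
demonstration universe, a 200,000-report null database for the
false-flag rate, 100 independent 50,000-report runs for planted-pair
recovery (a $\rho = 5$ pair with expected count 50), and 50 random
tables × $10^6$ gamma draws for the IC025 oracle comparison.

## Known limitations

No multiple-testing adjustment is applied — threshold-based signal
detection conventionally screens thousands of pairs and treats the
output as hypotheses, not confirmed associations. A signal is a
statistical reporting association, never a demonstrated causal adverse
reaction. EBGM/MGPS-style empirical-Bayes scores, regression-based
methods, stratified tables, duplicate detection and HLT/HLGT-level
roll-ups are out of scope. The shipped PT→SOC dictionary is a small
synthetic stand-in, not licensed MedDRA content.
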