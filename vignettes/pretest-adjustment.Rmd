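---
title: "Encoding clinical intuition as a pretest-probability boost in likelihood-ratio disease ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Encoding clinical intuition as a pretest-probability boost in likelihood-ratio disease ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenolr)
```

## The model

Phenotype-driven prioritization of Mendelian diseases scores each candidate
disease $D$ against the phenotype terms observed in (or explicitly excluded
from) a patient. For each term $x$ the likelihood ratio

$$\mathrm{LR}(x) = \frac{\Pr(x \mid D)}{\Pr(x \mid \neg D)}$$

compares the term's frequency in the disease to its background frequency
across all diseases. Under an independence assumption the per-term ratios
multiply into a composite $\mathrm{LR}(X)$ for the whole profile $X$, and
Bayes' rule in odds form converts a pretest probability $p$ into a posttest
probability

$$\Pr(D \mid X) = \frac{p\,\mathrm{LR}(X)}{1 - p + p\,\mathrm{LR}(X)}.$$

Absent other information every one of the $N$ catalogued diseases gets the
uniform pretest $p = 1/N$. But clinicians rarely start from ignorance: a
skeletal-dysplasia clinic sees skeletal dysplasias, and a patient with situs
inversus and agenesis of the corpus callosum makes a ciliopathy far more
likely than chance. This package encodes that intuition as a *pretest
adjustment*: the user selects a disease-group term from a disease ontology
(Mondo), the group is expanded to its descendant terms and, via
cross-references, to the $k$ flat (OMIM-style) disease identifiers of the
annotation corpus, and each of those $k$ diseases has its pretest
probability raised from $1/N$ to $(1+a)/N$ before renormalization. In
closed form,

$$p_a(d) = \frac{1+a}{N + ka} \;\;\text{(boosted)}, \qquad
  \frac{1}{N + ka} \;\;\text{(non-boosted)},$$

so the boosted-to-non-boosted ratio is exactly $1+a$, and $a = 0$ reproduces
the uniform distribution bit for bit. We use the exact form rather than the
$\approx (1+a)/N$ small-$k$ approximation throughout; both agree with the
two-significant-figure worked example ($N = 8307$, $k = 2$, $a = 5$ giving
$6/8317 \approx 7.2\times10^{-4}$), and exactness costs nothing.

```{r worked}
ids <- sprintf("OMIM:%06d", seq_len(8307))
adjust_pretest(ids, ids[1:2], a = 5)$probs[[1]]
```

Only one group is boosted per run, mirroring a single intuition. If callers
compose distributions themselves, note that boosting two overlapping groups
additively would break the ratio contract; the intended semantics for
overlap is that the largest applicable multiplier wins.

## The per-term likelihood-ratio model

The published contribution this package centres on is the pretest
adjustment, which is agnostic to how the per-term LRs are produced — it only
needs positive, finite ratios that are monotone in annotation strength. The
matching model here is therefore a deliberately simple reconstruction,
with every constant exposed in `lr_options()`:

* **Exact match** — the disease is annotated with the observed term at
  frequency $f$: numerator $f$.
* **Annotated ancestor** (the patient's term is more specific): numerator
  $f \cdot 0.5$; the factor (default 0.5) discounts for the ambiguity of
  which specific presentation an unspecific annotation covers.
* **Annotated descendant** (the patient's term is less specific): numerator
  $f$ of the descendant.
* **No related annotation**: the LR is pinned to `no_match_lr`
  (default 0.01) — a strong but bounded penalty, so a single noisy term
  cannot zero out a candidate.
* **Excluded term, disease annotated** ("violated"): $(1-f)$ over
  $\max(1-\mathrm{bg}, 1/(2N))$.
* **Excluded term, disease not annotated** ("confirmed"):
  $1/(1-\mathrm{bg})$, capped at `excluded_cap` (default 2) so that
  confirming the absence of a common finding is rewarded, but never as
  strongly as observing a specific one.

When several annotations match, the one yielding the highest LR wins, with
ties broken by the smallest term identifier so results are deterministic.

The denominator $\Pr(x \mid \neg D)$ is estimated from the corpus itself:
the fraction of diseases annotated with the term or any descendant of it,
floored at $1/(2N)$ so no ratio is infinite. This floor, together with the
propagation, makes background frequencies monotone along the ontology
(ancestors are at least as frequent as their descendants) and exactly 1 at
the phenotype root.

These choices do not claim fidelity to any particular production scoring
engine's internal distributions; the benchmark results below should be read
as properties of *pretest adjustment under a reasonable LR engine*, not of
a specific engine.

## Numerical choices

* Composite LRs are accumulated in log space; on toy inputs the result
  equals the naive product to $10^{-9}$ relative. Posttest probabilities
  used for ranking are computed through log-odds (`plogis`), which stays
  exact when the composite LR is astronomically large and the naive formula
  would return `Inf/Inf`.
* Ranking sorts by posttest probability, breaking ties by composite LR and
  then lexicographic disease id; the benchmark statistic is the competition
  ("1224") rank of the true diagnosis, so ties share the best rank of
  their block.
* The boosted/non-boosted ratio equals $1+a$ to machine precision
  (about $10^{-16}$ relative); binary floating point does not allow bitwise
  equality here, and tests assert the ratio at a few ulps.
* Probability sums are validated at $10^{-12}$; pretest files that fail a
  looser $10^{-9}$ check on load are rejected as corrupt.
* HPOA frequency fields accept HPO frequency terms (mapped to the midpoints
  of their defined ranges: obligate 1.0, very frequent 0.895, frequent
  0.545, occasional 0.17, very rare 0.025), $m/n$ ratios and percentages.
  An empty field defaults to 1.0 — the presence of an annotation asserts a
  characteristic feature. A frequency of exactly zero is interpreted as an
  absence assertion and moved to the excluded set, keeping annotation
  frequencies in $(0, 1]$. If a term is asserted both present and absent,
  absence wins with a warning.
* Ontology cross-references are accepted for a configurable set of prefixes
  (default OMIM) regardless of the xref predicate used; finer predicate
  semantics (e.g. exact-match-only) are a known fidelity gap.

The annotated corpus size is reported as published in two slightly
different states ($N = 8297$ diseases in the data description, $N = 8307$
in the worked example); the package takes $N$ from whatever corpus it is
given and the tests exercise both constants as printed.

## What the synthetic data emulates

Real evaluations of this method used hundreds of curated case reports
against the full HPO/Mondo releases — inputs far too large to ship or
regenerate in a test suite. The generator in `synth_config()` /
`make_ontologies()` / `make_corpus()` / `simulate_patient()` reproduces the
*structure* those inputs have, at desk scale, and emits the same file
dialects (OBO-Graph JSON, HPOA TSV, Phenopacket v2 JSON) so that every test
exercises the real parsers.

Defaults (all overridable, chosen once as the package's study conditions):

* a 40-term phenotype DAG of depth 4 with at least one diamond
  (multiple inheritance), so closure code cannot get away with tree
  assumptions;
* 50 diseases with 8 annotated terms each, frequencies drawn from the HPO
  frequency-term midpoints;
* three nested group chains (3 within 10, 4 within 12, 5 within 15
  diseases) whose members share half their annotated terms through a group
  core — disease families are phenotypically coherent, which is exactly why
  a group-level boost is clinically meaningful and why it cannot help
  against within-group competitors;
* patient simulation observes each annotated term with probability equal to
  its frequency, records two observed terms imprecisely as a parent term,
  and swaps each observed term for a random one with probability 0.2.

The noise settings were fixed so that the uniform-pretest baseline behaves
like a diagnostically ambiguous cohort — the true disease usually lands
near, but not at, the top (mean baseline rank around 8, roughly 40% at
rank 1 under the default seed-scale). A cleaner corpus would leave the
boost nothing to improve; a much noisier one would swamp the phenotype
signal entirely. This choice was made from the baseline rank distribution,
before any improvement statistics were computed.

What the generator does **not** emulate: realistic human phenotype
frequencies and co-occurrence, ontology depth heterogeneity, shared terms
between unrelated disease families, curation bias in case reports, and any
genotype information. Passing tests therefore demonstrate the method's
internal contracts and qualitative behavior (boost helps when the intuition
is right, narrow beats broad, wrong intuition hurts), not clinical
performance on real data.

## Benchmarking design

`run_benchmark()` ranks each case's true diagnosis under the uniform
pretest and under group-boosted pretests for each adjustment value in the
sweep (default 1, 5, 10, 15, 20) and both intuition widths: *narrow* (a
small group closely related to the diagnosis) and *broad* (a larger
umbrella group containing it). The composite LR of a case does not depend
on the pretest, so it is computed once per case and reused across the
sweep. Improvement is uniform rank minus adjusted rank; positive is better.

Rank improvements per (width, adjustment) cell are tested with a one-sided
Wilcoxon signed-rank test, alternative: ranks improve. Policy: zero
differences are dropped; tied absolute differences get mid-ranks; the exact
null distribution (all $2^n$ sign assignments, computed by convolution) is
used for $n \le 12$, where it is instantaneous even with ties; above that,
a tie-corrected normal approximation with continuity correction. All
differences zero yields a degenerate result with $p = 1$. Signed-rank on
paired ranks was chosen over rank-sum because each case serves as its own
control across the two pretest configurations.

Cases whose true diagnosis is missing from the corpus are excluded with a
logged count (a known failure mode of cross-nomenclature mapping), as are
cases, per width, whose group term maps to no corpus disease.

The shipped acceptance checks run this design on a seeded 50-disease /
200-patient synthetic cohort — small enough to run in seconds, large enough
for the Wilcoxon tests to resolve the effect. At that scale the qualitative
published pattern reproduces: positive mean improvement at every adjustment
value, narrow at least as good as broad, and p-values shrinking as the
adjustment grows. The published full-scale p-values themselves are not
reproducible without the original curated case collection and ontology
releases, and no attempt is made to match them numerically.

## Limitations

* The LR engine is a reconstruction; absolute posttest probabilities are
  only as meaningful as its simplified distributions.
* A wrong intuition (boosting a group that does not contain the true
  diagnosis) demotes the correct answer — by design, and demonstrably in
  the test suite. Users should try $a = 0$ when no candidate convinces.
* Group expansion inherits every gap of the disease-ontology
  cross-references; empty mappings warn and fall back to uniform rather
  than failing.
* Only `is_a` edges are traversed; other ontology relations are ignored,
  matching the subclass-based notion of a disease group.
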