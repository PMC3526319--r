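---
title: "Methods: isoform-ratio quantification, dosage-series target calling and RIP-qPCR in ASpanel"
author: "ASpanel authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isoform-ratio quantification, dosage-series target calling and RIP-qPCR in ASpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ASpanel)
```

# Scope and data model

`ASpanel` analyzes high-resolution RT-PCR alternative-splicing panels: each
panel event is one primer pair amplifying all splice isoforms of one known
AS event, read out as sized fluorescent peaks on a capillary sequencer. The
package consumes *peak tables* (sample, primer pair, fragment size in bp,
peak area), not raw electropherograms; size-standard calibration and
dye-channel handling are upstream of its scope.

Two S4 classes carry the data. `SplicingPanel` is the validated panel
definition: expected product sizes per event (strictly increasing integers),
the *relevant* isoform subset that enters ratio computation, and the
*designated* isoform whose percentage defines the direction of change — by
convention the smaller product of the considered pair. The panel file is the
single source of truth for these designations; nothing is inferred from the
data, mirroring how panel studies mark the considered isoform pair in their
tables. `IsoformExperiment` extends `SummarizedExperiment` with rows =
(event, isoform size) and assays `area` and `percent`, so the usual
Bioconductor subsetting and metadata machinery applies.

# Peak assignment

Each expected size is matched to the observed peak within a tolerance window
(default **1.0 bp**: capillary sizing at these product lengths resolves
single bases, and sub-bp sizing error is well below ±1). Among several
qualifying peaks the nearest wins; exact ties go to the larger area (the
smaller co-migrating peak is more plausibly noise). If one observed peak
falls inside the windows of two expected sizes the assignment errors and
advises a smaller tolerance, rather than guessing. An expected isoform with
no qualifying peak gets **area 0 with a missing flag** instead of being
dropped: downstream percentages stay computable (the other isoform is then
100%) while the gap remains traceable. Peaks matching nothing are reported
as unmatched — the package deliberately exposes them instead of silently
filtering possible nonspecific products.

# Isoform percentages and replicate summaries

For relevant isoforms of one event in one sample,
$\mathrm{pct}_i = 100\,A_i / \sum_{j \in \mathrm{relevant}} A_j$.
Non-relevant isoforms are excluded from the denominator and reported as NA.
If the total relevant area is zero the profile is *undefined*: flagged,
excluded from summaries and tests, and listed in the object metadata.
Replicate summaries report mean, SD and SEM per genotype; SEM uses the
sample SD (n−1 denominator) — the convention is stated because with n = 3 it
matters. Genotypes with a single defined replicate are descriptive only and
barred from testing.

Total transcript level is the summed relevant area normalized to a reference
transcript's area. Both panel references (ACTIN11, RPL12c) are always
computed and shown side by side; when the two disagree on the 2-fold
abundance call the event is flagged rather than arbitrated, since there is
no principled way to prefer one housekeeping gene after the fact.

# Differential splicing

Contrasts are tested per event on the designated isoform's per-replicate
percentages with a two-sided t-test. **Welch is the default**: with n = 3
per group, variance heterogeneity between genotypes is common and the Welch
form is safer; the pooled Student form is available (`varEqual = TRUE`) for
exact replication of classical analyses, and the two coincide for balanced
equal-variance groups. Degenerate inputs are defined explicitly: two
constant equal groups give t = 0, p = 1; constant unequal groups give p = 0
with a degenerate flag.

Tiers combine effect size and significance on **unrounded** means:
*primary* |Δ| ≥ 5 points with p ≤ 0.05, *secondary* 3 ≤ |Δ| < 5 with
p ≤ 0.05. The 5-point threshold reflects what such assays call a robust
ratio change; the secondary band exists because technical replication shows
a SEM of up to ~3 points, so smaller significant shifts are reportable but
second-class. Both cutoffs are inclusive (≥, ≤) and configurable. No
multiple-testing correction is applied to the tiering — matching how panel
studies report per-event calls — but a Benjamini–Hochberg column is emitted
for information. Abundance changes use an inclusive 2-fold rule
(fold ≥ 2 or ≤ 0.5) under at least one reference.

# Event-class enrichment

Enrichment of an event type among changed events uses the hypergeometric
distribution with population N = panel events (references excluded),
successes K = events of that type, draws n = changed events. Two
probabilities are reported: the **point mass** P(X = k), computed in log
space via `lchoose` — this is the spreadsheet HYPGEOMDIST convention that
panel studies conventionally print as "hypergeometric test" — and the proper
one-sided **tail** in the direction of departure from the expectation nK/N.
Reports carry both: the tail as the statistically meaningful p-value, the
point form for concordance with the literature. The implementation is
cross-checked in the tests against `dhyper`/`phyper` and against exhaustive
enumeration of all draws for every instance with N ≤ 20.

# Dosage-series direct-target classification

A direct target of a dosage-varied splicing regulator should respond to loss
of the protein in the direction opposite to its over-expression. With
contrasts wt→ox (two independent backgrounds) and wt→knockdown:
`direct_strong` requires all three contrasts primary-tier with the knockdown
delta opposite in sign to both (equal-signed) over-expression deltas;
`direct_weak` relaxes only the knockdown to the secondary tier, capturing
smaller-but-significant opposite shifts (the 3–5-point band; with
integer-printed tables a true change of ~4.75 rounds to 5, so tier
assignment should always use unrounded means where available);
`same_direction` marks significant co-directional knockdown responses
(suggesting action within a complex); `ox_specific` marks events silent in
the knockdown. The call is invariant to swapping the two over-expression
contrasts, and a knockdown delta of exactly 0 — which can never be
significant — lands in `ox_specific` or `unchanged`. With a single
over-expression line the same rules apply to the one available contrast.

# RIP-qPCR

Quantification uses the ΔCt model with amplification efficiency fixed at
**2** (perfect doubling; a per-target efficiency argument exists but
protocols rarely calibrate it): `level = 2^−(Ct_target − Ct_PP2A)`.
Technical duplicates are averaged **on the Ct scale** (the scale on which
qPCR noise is approximately Gaussian); biological replicates are combined on
the ratio scale. Levels are expressed relative to the input fraction, which
is therefore 1 by construction; levels above input are allowed — higher
extraction/amplification efficiency from precipitates than from whole
extract is a known effect, so no capping is applied. Enrichment is
mean(IP+)/mean(IP−), tested with the classical pooled Student's t-test
(the convention for such assays; Welch is available), starred at p < 0.05
and p < 0.005. When the mock precipitate is undetected in every replicate no
test is applied; the enrichment is reported as a **lower bound** against the
detection floor (default Ct 40, configurable). An undetected reference
transcript is an error, not an imputation.

# The synthetic-data generator

`simulatePanel()` emulates the study conditions: a 288-event panel with the
published census composition (~47% alt 3′SS, 23% alt 5′SS, 17% intron
retention, 12% exon skipping, 1% cryptic intron), two reference transcripts,
three biological replicates, and the five-genotype dosage series. Per
replicate, each isoform's true percentage is perturbed by independent
Gaussian noise of SD `noiseSD` (default 3 points), clipped to [0, 100] and
renormalized to sum to 100; peak areas are percentages scaled by a
log-normally noisy expression level, and fragment sizes get sub-bp jitter
within the matching tolerance. Two consequences of this noise model are
worth stating. First, renormalization shrinks the realized SD of a
two-isoform percentage by $\sqrt{p^2+q^2}/100$, so at `noiseSD = 3` the mean
per-event replicate SEM is ≈1.1–1.2 points — comfortably inside the ≤3-point
technical envelope such assays report; the unit tests pin the generator to
an independent Monte-Carlo computation of this same process rather than to
a nominal SD/√n value. Second, planted strong direct targets shift the
designated isoform by the full ±`effectSize` (default 15 points) in *both*
directions of the series — over-expression up, knockdown down (or the
mirror). An a-priori power calculation fixed this choice: at n = 3 and
5-point/0.05 thresholds, a knockdown shift of half the effect would be
detected in only ~50–80% of events, making reliable three-contrast recovery
impossible; the biological observation that loss-of-function affects fewer
events than over-expression is represented by the `direct_weak`,
`same_direction` and null classes rather than by halving the knockdown
magnitude. Weak targets use `weakEffect` (default 4 points) in the
knockdown; same-direction events move half the effect with the ox sign.

`simulateRip()` models concentrations relative to the reference (fixed at 1
in every fraction): bound targets are captured at `ripEnrichment` (default
10×) in IP+ and `ripBackground` (default 0.1×) in IP−, so the planted
IP+/IP− contrast is their ratio; Ct values are
`ctReference − log2(conc) + N(0, ctNoise)` (default noise 0.2 cycles) in
technical duplicates, with configurable targets whose mock signal lies below
the detection limit (emitted as n.d.). All randomness in both generators
flows from the single config seed.

What the generator does **not** emulate: ecotype-specific baseline splicing
differences (both wild types share true fractions), primer-specific
amplification bias, co-migrating nonspecific products, partially degraded
RNA, and correlated replicate effects (growth batches). Passing the recovery
tests therefore demonstrates that the statistical machinery is correct under
the stated noise model, not that the thresholds are optimal for any
particular real dataset.

# Test problem sizes

The simulation-based checks use sizes chosen to make their Monte-Carlo error
small relative to the asserted margins: 250 events (a quarter planted as
strong targets) for dosage-series recovery, 2000 null events for the
false-positive calibration of the joint |Δ| ≥ 5 & p ≤ 0.05 criterion, and
500 seeded RIP simulations for binding detection, all with three replicates
and the default noise levels.

# Known limitations

* The two-isoform case is the generator's default; multi-isoform events are
  fully supported in quantification (non-relevant isoforms excluded from
  denominators) but planted effects are two-isoform.
* Classification requires the knockdown and first over-expression contrast
  to share the wild type; a knockdown in a different background would need
  its own baseline.
* The hypergeometric census treats events as exchangeable; events on the
  same transcript (shared primer targets) are counted independently, as in
  the source analyses.
* Printed integer tables carry a ±0.5-point rounding band, so threshold
  decisions at exactly 5 points are not reproducible from published means
  alone — tiering should always run on unrounded values.
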