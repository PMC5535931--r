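---
title: "Semi-quantitative AP-MS analysis with apmsq: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-quantitative AP-MS analysis with apmsq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apmsq)
```

# The analysis problem

Affinity-purification mass spectrometry (AP-MS) pulls down a bait protein
(here the EZH2 methyltransferase in acute myeloid leukaemia cells) with an
antibody and identifies the co-purifying prey proteins. Spectral counts -
the number of MS/MS spectra matched to each protein - serve as a
semi-quantitative abundance proxy. Three questions drive the pipeline:

1. **Which preys interact with the bait?** Abundance in bait
   immunoprecipitations (IPs) relative to isotype (IgG) control IPs, with
   probabilistic confidence scoring and contaminant filtering.
2. **Which interactions change with treatment?** A staged cascade
   comparing bait IPs across a differentiation stimulus, with matched
   biological pairs guarding against false direction calls.
3. **Which preys are enzymatic (methylation) substrates?** Methyl-site
   calling from peptide evidence with per-condition occupancy, and
   triangulation against a pan-methyl-lysine IP.

The package ingests post-database-search tables only (protein-level count
matrices and peptide-level evidence); raw spectra, search engines and
external web services are out of scope.

# Quantitation model

## Floored fold change

For protein $i$, let $\bar{x}_i^{\mathrm{bait}}$ and
$\bar{x}_i^{\mathrm{ctrl}}$ be the mean spectral count over bait and
control samples. The fold change is

$$\mathrm{FC}_i \;=\; \frac{\max(\bar{x}_i^{\mathrm{bait}},\, f)}
                           {\max(\bar{x}_i^{\mathrm{ctrl}},\, f)},
  \qquad f = 0.1 ,$$

so a protein never seen in the IgG controls still gets a finite ratio
(e.g. bait mean 10, control mean 0 gives $10/0.1 = 100$). Means rather
than sums are used so the unequal group sizes of the emulated design
(7 bait IPs versus 5 IgG controls) do not bias the ratio; the floor is
applied to the aggregated mean, not to individual samples.

## Exact-test screening

Each protein's summed spectra are contrasted against the spectra of all
other proteins, in the bait versus the control group, in a 2x2 table. The
reported p-value is the one-sided (enrichment in bait) hypergeometric
upper tail; sidedness is a design choice - the screen only cares about
enrichment over background, never depletion. How the 2x2 table should be
constructed from spectral counts is genuinely underdetermined; per-group
summed totals across all quantified proteins are used and the table
entries are reported alongside the p-value so the construction is
auditable. q-values are Benjamini-Hochberg across all tested proteins
(`bh_adjust()`, a validated wrapper over `stats::p.adjust`).

## Exclusive spectrum counts

Spectra from peptides shared between protein groups are ambiguous;
`compute_exclusive_counts()` drops them. The minimal protein-inference
rule needed to define "exclusive" is applied first: proteins with
identical peptide sets merge into one group (id = member ids joined with
`+`), and a protein whose peptide set is strictly contained in another's
merges into that superset's group. A peptide then counts only if every
protein carrying it belongs to one group.

# Interaction confidence score

`score_interactions()` is a self-contained two-component Poisson mixture
in the spirit of SAINT-style scoring. Per protein,
$\lambda_0 = \max(\bar{x}^{\mathrm{ctrl}}, f)$ is the background rate and
$\lambda_1 = \max(\bar{x}^{\mathrm{bait}}, \lambda_0)$ the interaction
rate (clamped so the interaction component never sits below background).
Each bait replicate count $x_j$ yields a posterior probability of coming
from the interaction component,

$$r_j = \frac{\pi\,\mathrm{Pois}(x_j;\lambda_1)}
             {\pi\,\mathrm{Pois}(x_j;\lambda_1) +
              (1-\pi)\,\mathrm{Pois}(x_j;\lambda_0)},$$

with prior $\pi = 0.5$, and the confidence score is the plain mean of
$r_j$ over bait replicates (top-$k$ aggregation is deliberately not used;
every replicate votes). The default gate is score $\ge 0.8$ together with
fold change $\ge 2$.

Two properties of this model are worth knowing:

* **Clamping makes the score bottom out at the prior.** When the bait
  mean does not exceed the control mean, $\lambda_1 = \lambda_0$, every
  likelihood ratio is 1 and the score equals $\pi$ exactly - absence of
  bait counts is "no evidence", never "evidence against".
* **Monotonicity holds at fixed rates, not under re-estimation.** At
  fixed $(\lambda_0, \lambda_1)$ the posterior is nondecreasing in each
  count (monotone likelihood ratio). Because $\lambda_1$ is re-estimated
  from the bait mean, however, raising one already-high replicate also
  raises $\lambda_1$ and can lower the other replicates' posteriors;
  `score_interactions()` therefore accepts explicit `lambda0`/`lambda1`
  overrides, and the test suite checks monotonicity in that regime.
* **Condition-specific partners are penalized.** A prey that binds the
  bait only in one condition has low counts in the other condition's
  replicates; under the single shared $\lambda_1$ those replicates score
  near zero, capping the mean score around (detected replicates)/(all
  replicates) - e.g. ~5/7 with 7 bait IPs. Such preys are the subject of
  the differential cascade, not the high-confidence interactome gate;
  interpret the two outputs together.

# Contaminant filtering

Frequent fliers are flagged against a reference profile of control AP-MS
runs (a CRAPome-style export) by a deliberate two-clause rule: flagged iff
detected in more than half the reference experiments **and** not
differentially enriched (floored bait mean below 2x the profile's
expected count). Genuinely enriched frequent binders therefore survive;
proteins absent from the profile are never flagged.

# Differential-interaction cascade

Four gates in fixed order, recording the first failure per protein:

| stage | rule | default |
|---|---|---|
| `igg_gate` | floored bait mean / floored IgG mean | $\ge 1.5$ |
| `ratio_gate` | untreated/treated floored means, either direction | $\ge 2$ or $\le 0.5$ |
| `consistency_gate` | every detected matched pair agrees with the global direction | - |
| `presence_gate` | bait samples with count > 0 | $> 1$ |

"2-fold change in either direction" is interpreted symmetrically on
floored group means. Matched-pair direction uses floored per-pair ratios
with a dead zone: a pair ratio inside $(0.83, 1.2)$ counts as
`not_detected` and does not vote, since direction is only meaningful for
proteins already showing a clear change; the bounds are configuration
keys. Unpaired bait samples contribute to the group means but not to the
consistency gate; with no pairs at all the gate is skipped with a warning.

The cascade is a screen, not an error-controlled test: on synthetic data
it recovers essentially all planted condition-specific interactors but
also passes background proteins whose counts drift by chance (the
false-discovery proportion is reported by `scripts/acceptance.R` rather
than bounded). In practice its output is read jointly with the
high-confidence interactome.

# Methyl-site calling and occupancy

Peptide coordinates are 1-based and inclusive with the initiator
methionine counted, so a modification at peptide offset $o$ in a peptide
starting at residue $s$ sits at absolute position $s + o - 1$. Published
site tables contain formatting artefacts - bolding asterisks and
line-break hyphens inside sequences - which the reader strips before any
length or residue check. Records whose stated start/stop span disagrees
with the sequence length are retained with `coord_consistent = FALSE` and
excluded from site calling only; the bundled example table contains
exactly one such histone H3.1 record. Where a published site name
disagrees with the computed position (the bundled example has three such
cases), the computed position is authoritative and the stated name is
kept as an `author_label` annotation - the source's residue-numbering
convention cannot be reconstructed.

Evidence passes two inclusive identification gates, protein probability
$\ge 0.999$ and peptide probability $\ge 0.80$; the peptide default sits
at the permissive end of the conventional 80-95% range and is a single
configurable value. Modified and covering spectra are summed per
(protein, position, state, condition); occupancy is

$$\mathrm{occ} = 100 \cdot n_{\mathrm{mod}} / n_{\mathrm{total}},$$

rounded **half away from zero** to one decimal (base R's round-half-even
would print 7/32 as 21.8 rather than the conventional 21.9), with
integer-valued percents printed without a decimal (`5%`, `50%`) and
`ND` when no covering spectra exist. A site is dropped only if it is ND
in every condition. Per-sample occupancies are available via
`by_sample = TRUE` for transparency. Of the 38 per-condition cells in the
bundled example table, 36 reproduce the published labels exactly; two
published cells (4/21 and 1/19) are arithmetically inconsistent with
their own printed counts and are reproduced at the computed value.

## Substrate triangulation

A prey is a candidate direct methylation substrate iff three independent
evidence streams agree: co-IP with the bait in at least two distinct MS
experiments (distinct `run_id`s with nonzero counts), enrichment in the
pan-methyl-lysine IP (mean counts at least 1.5x the floored pooled IgG
mean - inclusive, and pooled rather than per-matched-run, a documented
choice), and at least one called methyl site.

# Network module

`mcl_cluster()` is a from-scratch Markov clustering implementation (no
installed package provides MCL): self-loops are added with weight equal
to the node's maximum incident edge weight (common MCL practice, keeps
the walk aperiodic without drowning the signal of weakly connected
nodes), columns are normalized, and expansion (power 2) alternates with
inflation (elementwise power 2, renormalize), pruning entries below
1e-5, until the maximum column change drops below 1e-6. Clusters are the
attractor systems of the limit matrix; a node attracted to several
systems joins the one attracting it most strongly, ties broken by
lexicographically smallest attractor id so results are deterministic.
Columns emptied by pruning restart as self-loops (degenerate-input
guard).

`term_enrichment()` is the exact upper-tail hypergeometric test of a
cluster against GMT annotations; it equals a one-sided Fisher test on the
corresponding 2x2 table, which the test suite uses as a cross-check. The
universe defaults to the interactome result, not the whole annotation
file - a deliberate, logged choice, since it changes every p-value.
Zero-overlap terms are reported with their computed p, not skipped.

# Synthetic studies and what they do (not) show

`generate_study()` emulates the study design end to end: 4 untreated +
3 treated bait IPs with 2 matched pairs, 5 IgG controls, 1 pan-methyl IP.
Background counts are negative-binomial - spectral counts are
overdispersed relative to Poisson - with mean 2 and size 8, typical of
low-level nonspecific binding in IgG controls (size -> infinity recovers
Poisson, so the dispersion is a knob). True interactors are elevated
8-fold in bait IPs, reflecting the strong enrichment of genuine complex
members over isotype background; condition-specific interactors gain a
further 4-fold in their favoured condition; contaminants are elevated
5-fold in *all* samples including controls and are simultaneously written
into the contaminant profile, so the two-clause filter is exercised
end to end. Methyl-site occupancies are Beta(2, 8) (right-skewed, mostly
sub-stoichiometric, as observed for non-histone methylation) and modified
spectra are binomial draws. All randomness flows through one seed;
identical configurations reproduce byte-identical tables and the
caller's RNG stream is left untouched.

Problem sizes used by the test suite and acceptance script - 500
proteins, 20 true interactors, 100 planted methyl sites at a mean
coverage of 400 spectra per site for occupancy recovery, 20 replicate
null studies - are chosen so every check runs comfortably on a laptop
while the law-of-large-numbers margins still hold; at a mean coverage of
200 the binomial sampling error alone (~2.2 points mean absolute error
for Beta(2, 8) occupancies) would exceed the 2-point recovery target, so
recovery is assessed at deeper coverage where the expected error is ~1.5
points.

What passing on synthetic data does **not** show: the generator draws
independent counts per protein (no co-eluting complexes, no
protein-length or abundance biases, no run-to-run batch effects), plants
methyl evidence only on true interactors, and simulates neither retention
time nor search-engine score distributions. Real AP-MS data will violate
all of these in degree; the synthetic checks validate the arithmetic and
the gate logic, not field performance.

# Numerical and degenerate-input conventions

* Missing count cells read as 0 - in spectral counting, absence of
  spectra is an observation, not missing data.
* All probability gates are inclusive (`>=`), including the score, the
  identification probabilities and the pan-methyl ratio ("at least").
* An all-zero count matrix, an empty sample subset, an empty universe, a
  manifest without the required antibody classes, and a pair with other
  than two members are errors, reported before any computation.
* Tables are written with a deterministic column order and rows sorted
  lexicographically over all columns, so reruns are byte-identical and
  diffable.

# Known limitations

* The confidence score is a simplified stand-in for full
  interactome-scoring models: no replicate order statistics, no bait-level
  normalization, Poisson rather than negative-binomial components. Its
  operating characteristics on the synthetic studies (sensitivity ~0.95,
  FDP ~0.05 at defaults) are measured, not guaranteed.
* The differential cascade controls direction consistency and presence,
  not the false-discovery rate.
* Site localization within a peptide is taken from the search-engine
  annotation as given; no localization scoring is performed.
* GO-style annotations are used as flat sets; no ontology propagation.
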