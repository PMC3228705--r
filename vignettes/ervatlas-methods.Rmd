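---
title: "Cataloging and dating HML-2 endogenous retroviruses with ervatlas"
author: "ervatlas authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cataloging and dating HML-2 endogenous retroviruses with ervatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ervatlas)
```

## The scientific problem

HERV-K (HML-2) is the youngest clade of human endogenous retroviruses: a
set of proviruses — integrated retroviral genomes with the structure
5'&nbsp;LTR – *gag/pro/pol/env* – 3'&nbsp;LTR — plus several hundred solo
LTRs left behind when recombination between a provirus's two LTRs deletes
the internal genes. Because the two long terminal repeats (LTRs) of a
provirus are created as identical copies at integration and then evolve
independently at the neutral host rate, the sequence divergence between
cognate LTRs is a molecular clock for the insertion, and departures from
the expected cognate pairing reveal post-integration recombination and
gene conversion. `ervatlas` implements the full characterization workflow
around these ideas, together with a seeded synthetic generator that plants
every quantity of interest as ground truth.

## Element calling from repeat annotations

`readRepeatAnnotation()` ingests RepeatMasker `.out` tables (1-based
inclusive, `C` meaning the minus strand) or BED6 (0-based half-open,
converted on input). All coordinates inside the package and in its output
follow the 1-based inclusive convention of `GRanges` and of genome-browser
displays.

`callProviruses()` chains same-strand hits separated by at most `maxGap`
(default 1,000 bp, a typical inter-fragment gap in repeat annotations;
RepeatMasker linking IDs additionally merge fragments when present) and
calls a provirus when the chain contains an LTR hit together with internal
coding sequence, or — with no LTR — two internal hits each covering more
than half of a full gene. The gene-length yardsticks ship as a config
(`defaultGeneLengths()`) and should be replaced when a different reference
annotation is in play. `callSoloLtrs()` keeps LTR hits of at least 750 bp
(the intactness cutoff used for solo-LTR catalogs) that are neither
provirus components nor within an exclusion window of same-strand internal
sequence. `writeCatalog()`/`readCatalog()` round-trip the catalog as a TSV
in the published table layout.

## Classification

**Type 1 vs type 2.** Type 1 proviruses carry a 292-bp deletion at the
*pol*–*env* junction; type 2 proviruses do not (type 2 encodes Rec, type 1
Np9). The published description does not fix alignment coordinates for the
deletion window, so the window is configuration: either supplied
explicitly or recovered with `findDeletionWindow()` as the longest gap
block shared by known type-1 rows where the reference retains sequence.
`classifyType()` then calls type 1 when at least 90% of the window is
gapped while both 100-column flanks retain sequence, type 2 when at most
10% is gapped, and undetermined otherwise — deliberately including
elements whose larger deletions span the window and its flanks, which
cannot be typed by this feature. The 90/10/flank thresholds make a
previously by-eye call deterministic and are exposed as arguments.

**LTR subgroups.** The LTR5Hs, LTR5A and LTR5B subgroups are distinguished
by short diagnostic insertions at fixed alignment columns: one shared by
essentially all 5A and 5B (and absent from all 5Hs), one unique to 5A, and
one carried by most (but only most) 5Hs. `classifySubgroup()` therefore
uses the shared insertion as the primary discriminator (present →
5A if the 5A-unique insertion is also present, else 5B; absent → 5Hs)
and records the 5Hs-associated insertion as supporting evidence only.
Presence means at least half of the insertion's columns carry bases, and a
row with no aligned sequence around the diagnostic columns is
undetermined rather than 5Hs — a deletion and missing data must not be
conflated. For proviruses both cognate copies of each insertion vote,
which makes the call robust to a deletion clipping one LTR.

**ORFs.** `callOrfs()` degaps each gene region, scans the three forward
frames for the longest stop-free stretch, and calls the gene intact when
that stretch reaches 95% of the degapped reference length. No splice
isoforms are modeled.

## Divergence counting and distances

`countDivergence()` compares base-vs-base columns one by one and scores
each maximal run of gap-vs-base columns as a single substitution event
contributing one unit to the comparable length — the standard LTR-dating
convention for insertions/deletions. The published rule explicitly treats
runs longer than 2 bp as single substitutions but is silent on 1–2 bp
indels; we count every maximal run as one event for uniformity and expose
`indelMode = "strict"` (short runs counted per column) for sensitivity
analysis. Columns where both rows are gapped, or where either row is N,
are excluded from both numerator and denominator: ambiguity must not
inflate divergence.

`consensusDistance()` corrects the raw proportion for multiple hits:
Jukes–Cantor uses the full proportion (indel events included, matching the
divergence count), while the Kimura 2-parameter correction — a
base-substitution concept — estimates its transition and transversion
proportions over base-vs-base columns only. The transition/transversion
ratio κ = 2 is carried as metadata (and drives the simulator's
substitution process); the K2P estimator itself takes P and Q from the
data. Saturated inputs (log arguments ≤ 0, or raw p ≥ 0.75 for JC) raise
errors rather than returning fiction.

`buildConsensus()` takes the strict per-column majority over A/C/G/T/gap
(N casts no vote), breaking ties deterministically: bases beat the gap,
and tied bases resolve alphabetically — biased toward retaining sequence.

## Age estimation

**Paired-LTR clock.** With divergence proportion *p* between cognate LTRs,
`estimateProvirusAge()` reports the age interval
100·*p*/0.45 to 100·*p*/0.24 Myr, using the neutral band of
0.24–0.45% divergence per Myr. The ratio of the bounds is therefore
exactly 1.875 for every dated element. Estimates whose lower bound falls
under 2 Myr are formatted as "&lt;&nbsp;2" — recent integrations carry too
few substitutions to date — while the numeric values are retained
internally.

**Solo-LTR consensus distance.** Solo LTRs (and single-LTR proviruses)
have no cognate partner, so their age comes from the distance to their
subgroup consensus: the mean of the JC and K2P distances, divided by an
average rate of 0.34 %/Myr. Part of that distance accrued before
integration (during viral replication) and part reflects the distance
between the element's true ancestor and the subgroup consensus, so the raw
value is biased; `calibrateCorrectionFactor()` regresses paired-LTR ages
on consensus-method ages through the origin over two-LTR proviruses
(slope = Σxy/Σx²) and the slope — with its 95% confidence slopes for the
age bounds — rescales the solo estimates (`applyCalibration()`,
`estimateSoloAge()`). The method remains noisy at the individual-element
level (the correlation between solo estimate and truth on synthetic data
is ~0.45); what the calibration guarantees, and what the tests check, is
an unbiased age *scale*: the through-origin slope of estimate against
truth lands in [0.8, 1.2].

## Recombination detection

**Non-paired cognate LTRs.** Each provirus's two LTRs should be mutual
nearest neighbors in a K2P distance matrix over all provirus LTRs (rows
with fewer than 250 aligned bases are excluded as uninformative).
`detectUnpairedLtrs()` flags a provirus when another LTR beats the cognate
by more than a noise floor of 0.015 substitutions/site and, when a tree is
supplied, the NJ tree does not show the cognates as sisters. Both guards
are deliberate: distance differences of a few substitutions are sampling
noise at 1-kb LTR length, whereas a real conversion leaves a
near-identical twin of the converted LTR elsewhere in the genome — a
signal of several percent — and the cherry test adds the global evidence
the original tree-based analysis relied on. A conversion event marks
*both* partners: the recipient's cognate distance explodes and the donor's
3' LTR acquires a closer twin.

**Trees.** `buildNjTree()` is a from-scratch neighbor-joining
implementation (Saitou–Nei Q-criterion, deterministic lowest-index
tie-break) returning a standard `phylo` object; on additive matrices it
reproduces the generating tree exactly, which the tests verify against an
independent implementation.

**Breakpoint scanning.** `scanBreakpoints()` slides a window (default 500
columns, step 100) along a provirus, assigns each window to the subgroup
consensus with the highest identity when the margin over the runner-up
exceeds 1 percentage point (subgroup consensuses are >95% identical;
smaller margins are noise — ambiguous windows inherit the previous call),
and merges same-call windows into segments that tile the scanned range,
with boundaries midway between adjacent window centers. A chimeric element
is localized to within one window of its true junction.

## Chromosomal distribution

`fitNbRegression()` fits element counts per chromosome against chromosome
length or gene count with a log-link negative-binomial model
(variance μ + αμ², dispersion by maximum likelihood via `MASS::glm.nb`),
reports the likelihood-ratio statistic −2(ℓ~null~ − ℓ~full~) against
χ²(1), and builds a 95% mean-prediction band by the delta method on the
linear predictor; `flagOutliers()` reports chromosomes outside the band,
the graphical criterion of the original analysis. `fitAllNbRegressions()`
runs the nine response×predictor panels. `geneProximitySummary()` counts
elements within 30 kb of genes, inside genes (intronic when exon intervals
are available to exclude), and the antisense fraction of those — the
orientation-bias signal of selection against sense-strand insertions.

## The synthetic generator and what it does (not) show

`simulateCatalog()` emulates the study conditions with known ground truth:

- **Clock.** Cognate-LTR divergence accrues at 0.345 %/Myr (the midpoint
  of the 0.24–0.45 band, consistent with the 0.34 solo rate, so the two
  dating methods are mutually consistent by construction), as a K2P
  process with κ = 2 collapsed to one binomial draw per branch — an
  approximation documented as valid below ~5% per-branch divergence.
  Deletions occur at 10⁻⁵ events/site/Myr.
- **Integration history.** Integrations sample an evolving per-subgroup
  viral source lineage (0.35 %/Myr between integration events) and each
  integrating virion carries a private replication-burst divergence of
  0.5%. This ladder structure is what makes cognate-LTR pairing hold for
  clean simulations: proviruses integrated far apart in time are
  proportionally farther from each other than from their own cognate
  copies. A generator that draws every provirus from one fixed ancestor
  breaks the pairing property for old elements regardless of the
  detector — the property belongs to the history, not the algorithm.
- **Composition.** Subgroup proportions 50/24/26 (5Hs/5A/5B), ages
  uniform on 1–30 Myr, the 292-bp deletion applied to 44% of 5Hs
  proviruses (type 1 is a 5Hs feature), optional conversion events
  (recent, donor chosen at maximal age gap).
- **Genome layout.** Twelve synthetic chromosomes (18–60 Mb, 60–520
  genes) with per-chromosome element counts drawn from the
  negative-binomial placement model (β₁ = 0.5 on scaled gene count,
  dispersion 0.3), so the distribution regression has planted truth.

`simulateReferenceComposition()` additionally plants the published
catalog's composition — 91 proviruses with 20/55/16 types, 45/21/23
subgroups, three conversion events (six involved elements), and an LTR5A
duplication clade of seven with a >99.9%-identical triplet (whole-provirus
copies; such elements share their LTR histories and are excluded from the
pairing analysis, as their curation history requires; its per-integration
burst is 1%, the inter-element divergence floor seen among human-specific
elements).

What passing these tests shows: the formulas, classifiers and detectors
recover what was planted under the stated evolutionary model at realistic
sizes. What they do not show: performance on real annotation mess
(assembly gaps, nested repeats, segmental duplications beyond the planted
clade), on alignments with the distinctive error modes of real MSA tools,
or on genuinely unknown rate variation between lineages. The published
catalog numbers that depend on a specific genome build and manual curation
are not reproducible from synthetic data and are not claimed.

## Numerical and design choices

- Problem sizes in the tests (e.g. 200 proviruses for interval coverage,
  500 null replicates for the regression's type-I error, 300 LTRs for
  classification accuracy) are chosen so each property is measured with
  comfortable binomial resolution while the whole suite stays quick.
- All randomness flows from a single integer seed per simulation;
  identical seeds give bit-identical outputs.
- Degenerate inputs error loudly: empty overlaps, saturated distances,
  all-zero counts, fewer than three calibration pairs.
- Young-provirus formatting applies only at output; numeric estimates are
  never truncated internally.
- Elements dated by both methods use the paired result; single-LTR
  proviruses fall back to the solo-consensus method.

## Reproducing the headline numbers

`scripts/acceptance.R --seed <int> --out <path>` regenerates every
quantity discussed here from scratch — planted-composition recovery,
formula identities, coverage, calibration, regression calibration,
detection sensitivity and specificity, and calling recovery — and writes
them as JSON. The test suite asserts the same properties at fixed seeds.
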