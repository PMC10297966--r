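---
title: "Methods: simulating and reading out single-molecule telomere optical maps"
author: "telomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and reading out single-molecule telomere optical maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The assay being modelled

Single-molecule telomere analysis via optical mapping images long (>150 kb)
DNA fibers carrying two label channels: genome-wide nick labels (Nt.BspQI
sites, GCTCTTC) whose interval pattern identifies the subtelomere of a
chromosome arm against an hg38-derived arm map, and telomere-specific
labels whose total fluorescence intensity is proportional to telomere
length. A molecule whose nick pattern aligns to an arm's subtelomeric map
with the arm's terminal label covered ("end-anchored") is a sighting of
that chromosome end, and falls into one of four classes:

* **END_TEL** — a terminal telomere signal beyond the last nick label;
* **TFE** (telomere-free end) — the subtelomere aligns but no telomere
  signal is detectable; recorded as 0 kb;
* **fusion/ITS+** — the arm's end continues into an additional fragment,
  with an internal telomere-like signal at the junction;
* **fusion/ITS−** — the same, with no detectable junction telomere;
  recorded as 0 kb.

Telomere-only fibers with no alignable nick pattern are extrachromosomal
telomeric repeats (**ECTR**), counted separately. Five genome-wide
readouts — fusion/ITS+ %, fusion/ITS− %, TFE %, the super-long telomere
fraction (>15 kb), and the coefficient of variation (CV = sd/mean) of the
pooled telomere lengths — separate ALT-positive from telomerase-positive
cells, and `call_alt()` turns them into a 3-of-5 vote.

This package implements the full readout side of the assay plus a
synthetic-data generator with packaged profiles for the six published cell
lines (U2OS, Saos-2, SK-MEL-2 — ALT+; UMUC3, LNCaP — TEL+; IMR90-S —
senescent control).

## The synthetic-data generator

### Reference arm maps

`make_reference()` builds 41 arm maps (all human arms except the five
acrocentric p-arms, which the assay cannot measure) of 300 kb each, with
nick labels placed by a shifted-exponential interval model: gaps are
`min_spacing + Exp(mean − min_spacing)`, so the mean inter-label spacing is
exactly the configured 9 kb while respecting a 1.5 kb minimum resolvable
spacing. These defaults approximate Nt.BspQI label density; no published
per-arm maps are shipped, so the maps are synthetic but structurally
faithful. Each arm's distal-most label is anchored 6–18 kb from the
chromosome terminus. This is a deliberate design constraint: the
classifier's telomere-free-end test needs a measurable unlabeled overhang
(≥5 kb) and its end-anchorage test needs the terminal label within 20 kb of
the terminus; pure Poisson placement would leave ~40% of arms with a
terminal gap below 5 kb, making simulated TFEs undecidable by geometry
rather than by biology.

### Molecule construction

Per arm, `Poisson(30)` molecules are drawn (the published coverage is
"around 30 molecules with telomeres per arm"). Each draws a category from
the profile's mixture and a subtelomere window of Uniform(150, 300) kb —
fibers below 150 kb are not loaded. END_TEL molecules append a telomere
tract of length `T` sampled from the profile's end-telomere distribution,
represented as one telomere-channel label of intensity `k·T` at the tract
midpoint (`k` = 1000 units/kb by default; the constant is arbitrary since
only the product is observable, and it is recorded in the calibration model
so the length readout is exactly invertible). Fusions append a partner
fragment beyond the terminus: with probability 0.5 another arm's reversed
subtelomere (its own terminus faces the junction, as end-to-end fusions
do — occasionally the same arm, reproducing same-arm fusion pairs), else a
short uncharacterized fragment whose ≤7 labels sit below the aligner's
8-label acceptance floor. ITS+ junctions carry the internal telomere
cluster with ≥10 kb of labeled DNA on both sides, guaranteeing "internal"
under the classifier's flank threshold. ECTR fibers are telomere-only
molecules (mean 11 kb, emitted at 20 per 100 arm-anchored molecules in ALT
profiles, absent otherwise). Half of all fibers are reversed end-to-end,
since imaging has no preferred orientation.

### Length distributions and Table-style calibration

Telomere lengths follow a two-component lognormal mixture: a body matched
by moments to the published mean ± sd, plus a heavy "super-long" tail
(median 20 kb, log-sd 0.6) whose weight `calibrate_tail()` sets by monotone
bisection so the analytic P(length > 15 kb) of the measured-telomere
mixture (end telomeres and ITS+ junctions, weighted by their category
fractions) equals the published super-long fraction. Three numerical
choices deserve note:

* **The mean is preserved, the sd is emergent.** The published end-telomere
  moments and super-long fractions are mutually inconsistent for the ALT
  lines: a distribution with mean 5.0 and sd 2.2 kb cannot put ~5% of its
  mass above 15 kb (Cantelli's inequality caps it at 4.6%). The mixture
  therefore recentres its body as tail weight grows so that the *mean*
  stays exactly at the published value — the mean feeds the pooled-mean
  identity that links the category table to the overall mean — while the
  realized sd exceeds the printed one and the genome-wide CV is treated as
  an emergent, checked property rather than an imposed parameter.
* **Tail weight can only add mass.** For SK-MEL-2 (and the control lines)
  the lognormal body alone already exceeds the published >15 kb fraction,
  so the calibrated tail weight clamps to zero and the realized super-long
  fraction is the body's own.
* **Bounded controls.** The published data record each line's longest
  telomere (UMUC3 14.75 kb, LNCaP 23.5 kb, IMR90-S 16.4 kb) and CVs below
  1; an unbounded lognormal tail instead lets a single ~50 kb draw among
  ~1000 molecules push a control line's sample CV past 1. The TEL+ and
  senescent profiles therefore truncate at their published maxima; the ALT
  profiles stay unbounded, super-long tails being their defining feature.

All category length draws are conditioned on exceeding the 0.1 kb
detection floor: published length tables describe *detected* telomeres,
and a sub-floor ITS+ draw would emit no label and be structurally an ITS−
molecule.

### Noise model

Defaults (all configurable, zeroed by `noise_off()`): nick-label sizing
jitter sd 250 bp, label dropout 10%, spurious labels at 1 per 100 kb,
multiplicative telomere-intensity noise with CV 0.10, detection floor
0.1 kb. The magnitudes are typical optical-map error scales chosen by
judgment; no published single-molecule error model exists for the emulated
datasets. These are the study conditions for every noisy test in the
package and are not tuned per experiment.

## Alignment

Arms are identified by *interval agreement*: successive label gaps on the
molecule are compared with successive gaps on the reference, which is
invariant to the unknown offset of a molecule within an arm — the standard
approach for optical maps. A dynamic program over (molecule label,
reference label) pairs scores +3 per matched pair, −1 per skipped label on
either track between consecutive matches, with free ends; a consecutive
pair is admissible when `|Δref − Δmol| ≤ max(500 bp, 0.12·Δref)`. Within
the gate a small graded cost (10⁻⁴ per bp of deviation) makes exact
geometry beat coincidental within-tolerance matches on otherwise tied
matchings — without it, ties at an arm's terminal label can resolve onto a
fusion partner's label and flip end-anchorage. Alignments are accepted at
≥8 matched labels and score ≥20; both floors are configurable, and the
score floor is exposed rather than inferred since no published confidence
threshold exists. The DP equals exhaustive enumeration over all monotone
matchings on small instances (a tested property); for speed, candidate
arms are ranked by a score-only scan with a tighter skip window
(`scan_max_skip = 2`, tolerating two consecutive dropouts) and only the
winner is re-aligned with the full window.

Fusion molecules get a greedy split alignment: the best accepted alignment
is found over all arms and both orientations, its molecule span is masked,
and each flank is re-scanned once — at most two segments, matching the
two-part geometry of end-to-end fusions. Ties between arms break by score,
then lexicographic arm id.

## Classification

A segment provides end-anchored context when its distal matched label lies
within 20 kb of the arm terminus (`end_window_bp`); requiring the literal
terminal reference label instead would let a single dropped label
unclassify an otherwise terminal molecule, and since end telomeres and
TFEs carry one anchor while fusions effectively carry two, that loss is
differential and would bias the recovered fusion percentages upward. Each
end-anchored segment is examined in the direction its chromosome end
points, over the molecule region distal to its distal matched label:

* a telomere cluster there (labels merged within 3 kb, undetectable
  clusters discarded) with ≥10 kb of molecule *and* ≥2 nick labels beyond
  it → **fusion/ITS+**; with less beyond it → **END_TEL**;
* no cluster, ≥2 nick labels over ≥10 kb → **fusion/ITS−**;
* no cluster and fewer than 2 nick labels, with ≥5 kb of overhang →
  **TFE**; a shorter overhang is a truncated fiber and stays unclassified
  rather than inflating the TFE percentage, which is the assay's key
  zero-versus-nonzero discriminator.

The 2-label partner requirement (instead of 1) guards the rare-event
readouts: at the default false-label rate, a single spurious label lands in
a TFE's terminal overhang in roughly 10% of TFE molecules, which would
otherwise leak TFE → ITS− and double a 0.5% ITS− readout; genuine fusion
partners always carry at least 2 labels. Molecules with no accepted
alignment but a telomere cluster are **ECTR**; everything else is
**UNCLASSIFIED**. TFE and ITS− lengths are set to 0 kb structurally (in the
classified-molecule constructor), not by downstream bookkeeping.

### Counting conventions

A fusion whose two segments end-anchor on two arms is a sighting of both
chromosome ends: per-arm tables count it once under each arm (twice under
the same arm for same-arm fusions). Genome-wide percentages instead count
every molecule exactly once — a fusion of arms A and B is one molecule of
the cell line — otherwise recovered fusion percentages would be inflated by
~50% of the both-anchored fusion share relative to the mixture that
generated them. Both conventions are implemented (`arm_stats()` vs
`genome_summary()`); the per-sighting choice for arm tables is the one a
per-arm appendix table implies, and the once-per-molecule choice is the
one the genome-wide summary table implies.

The end-telomere mean excludes TFE and ITS− (their zeros) *and* ITS+
junction lengths: the pooled-mean identity
`overall ≈ f_end·mean_end + f_ITS+·mean_ITS+` reproduces the published
overall means only under that reading, which settles a textual ambiguity
in favour of END_TEL-only.

## Statistics and the ALT call

Per-arm tables carry counts, category percentages, means ± sample (n−1)
standard deviations, the arm's longest telomere, and the per-arm CV
(undefined when the arm's mean is 0, e.g. an all-fusion/ITS− arm; such arms
contribute no CV to the median). Between-line comparisons use two-tailed
unequal-variance (Welch) t-tests on per-arm metric vectors restricted to
arms analyzed in both lines, with Welch–Satterthwaite degrees of freedom;
identical degenerate samples (e.g. two all-zero TFE vectors) return p = 1
by convention. The Welch flavour is used throughout — the assay's
published arm-level tests do not distinguish pooled from unpooled, and
unequal variances are the safe default. No multiple-testing correction is
applied, matching the published analysis.

`call_alt()` flags ITS+ ≥ 1%, ITS− ≥ 0.25%, TFE ≥ 1%, CV ≥ 1, and
super-long (>15 kb) ≥ 0.5%, calling ALT-positive on ≥3 of 5. The
thresholds sit between the published ALT minima (ITS+ 8.6, ITS− 0.5, TFE
6.3, CV 1.1, >15 kb 1.0%) and the TEL+/senescent maxima (fusions and TFE
absent, CV ≤ 0.8, >15 kb ≤ 0.4%); the 3-of-5 vote keeps one noisy readout
from flipping the call. Published CV rows are not exactly sd/mean of the
published moment rows (rounding), so tests assert the CV > 1 / CV < 1
separation rather than exact CV equality.

## Problem sizes used by the test suite

Unit and property tests run at deliberately small scale: DP-versus-brute
enumeration on ≤8×8 label instances; noise-free round trips on 500
molecules per profile (100% category agreement required); recovery of
published percentages at the study scale of ~2000 arm-anchored molecules
(48 per arm over 41 arms) within 3 binomial standard errors; CV separation
and end-to-end ALT calls over 20 seeds per cell line at the default
coverage (~1200 arm-anchored molecules per run). The acceptance script
(`scripts/acceptance.R`) re-runs the ~2000-molecule pipelines and the
noiseless worked fixtures from scratch at every invocation.

## What passing tests do and do not show

The generator emulates the *statistical structure* the readouts rest on:
category mixtures, heavy-tailed length distributions, label geometry,
coverage, and measurement noise. It does not emulate raw fluorescence
images, nanochannel physics, replication dynamics, sequence-level
subtelomere homology, or real hg38 label maps; arm-assignment accuracy
against synthetic Poisson-pattern references does not bound accuracy
against real subtelomeres, whose label patterns can share homologous
blocks. Fusion partner geometry is simplified to two-part molecules, so
chimeras of three or more fragments are out of scope (alignments stop at
two segments). The assay itself cannot distinguish circular from linear or
single- from double-stranded ECTRs, and neither does the simulation.
Per-arm length noise on real data is unpublished; the defaults here are
judgment calls exposed in the configuration.
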