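---
title: "Screening assigned molecular formulas for toxic compounds with toxscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening assigned molecular formulas for toxic compounds with toxscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toxscreen)
```

## The screening problem

Non-targeted LC/MS screening of candidate foods — leaf protein concentrate
and other alternative food fractions — produces, after peak picking and
molecular-formula assignment, a table of neutral molecular formulas with
masses, abundances and retention times, one per monoisotopic feature, for
each electrospray-ionization polarity. Purchasing reference standards for
every conceivable phytotoxin is not realistic (the Toxic Plants–PhytoToxins
database alone lists over 1500), so the screening question is inverted:
which of the *assigned formulas* coincide with compounds that a chemical
hazards database already flags? `toxscreen` implements that filtering stage:

1. **Formula matching** — assigned formulas are matched by exact elemental
   composition against a local table of candidate toxic compounds (an
   OpenFoodTox/TPPT-style extract: name, formula, monoisotopic mass,
   source).
2. **Record retrieval** — each matched candidate name is resolved to
   compound identifiers (CIDs) and its full hierarchical record is
   retrieved, from a local JSON store by default or from a live HTTP
   provider.
3. **Hazard classification** — each record is scanned for toxicity and
   food-safety fields, GHS hazard-statement codes (H-numbers) are extracted,
   and the compound is placed into one of five severity-ordered categories.
4. **Merging** — per-mode results are combined per sample, and per-sample
   toxic, unfound and unchecked tables are each merged across samples (three
   merge passes), with a final formatting pass over the merged toxic table.

The result partitions every matched candidate into **toxic** (classified),
**unchecked** (record exists but carries no toxicity or food-safety field),
**unfound** (no retrievable record), or **locally matched** (resolved from a
local table of previously hand-checked names).

## Formula matching

Formulas are canonicalized to Hill notation (C, H, then other elements
alphabetically; supported elements C, H, N, O, S, P, Cl) and compared by
exact element-count equality. Two decisions here were genuinely open:

* **No mass-tolerance fallback.** The upstream assignment stage has already
  resolved accurate mass to a formula under its own error model (typically
  1–3 ppm), so re-matching by mass would only re-introduce ambiguity the
  assignment just removed. Matching is therefore purely compositional. The
  reader still cross-checks each row's stated mass against the mass computed
  from its formula (default tolerance 3 ppm, mirroring the usual assignment
  error bound) and *flags* inconsistent rows rather than dropping them,
  since matching never uses the stated mass.
* **Isomers are all retained.** A formula matching *k* table entries yields
  one match with *k* candidates, every one of which proceeds independently
  to record retrieval. Without structural information (fragmentation,
  retention-time standards) every formula match is tentative, so discarding
  isomers would silently hide hazards; the worked validation set contains
  exactly such a pair (3- and 4-methoxybenzaldehyde, both C8H8O2, one an
  irritant and one acutely toxic).

Inputs are treated as neutral formulas. For users feeding raw ion formulas
an optional adjustment (`ionAdjust = "deprotonated"` / `"protonated"`) adds
or removes one hydrogen before matching; it defaults off.

## Record retrieval

The default provider is a directory of JSON records (`loadFixtureStore`),
one file per compound, mirroring a hierarchical Record → Section →
Information layout so that records downloaded from a real service can be
dropped in unchanged. The name index is case-insensitive and also keyed on
stereo-prefix-stripped names (`L-`, `D-`, `DL-`, `(+)-`, `(-)-`), because
food-safety databases and chemical-record databases systematically disagree
on stereo-descriptors ("L-glutamic acid" vs "glutamic acid").

A name can resolve to several CIDs; the provider fetches up to `cid_cap`
(default 3) records and classification keeps the maximum severity over all
of them, the conservative choice when no selection rule is defined.

The live client (`liveProvider`) enforces a minimum interval of 0.2 s — a
fifth of a second — between consecutive requests, retries transient
transport failures three times with growing backoff, and only then surfaces
an error. *Not found* and *transport error* are distinct conditions: only
the former routes a compound to the unfound partition for local matching;
the latter is recorded as an error note (still conservatively binned as
unfound, never aborting a run). The limiter's clock and sleep function and
the client's transport are injectable, so the spacing and retry contracts
are tested with a fake clock and stubbed transport; the test suite never
touches the network.

## Hazard classification

Record sections whose headings contain (case-insensitive substring) one of
the toxicity keywords — defaults `toxic`, `ghs`, `hazard`, `safety` — or the
food keyword `food` are collected depth-first. Hazard-statement codes are
extracted from toxicity-section content as `H` followed by exactly three
digits. Classification then maps codes to five severity-ordered families:

| Codes | Family, level | Label |
|---|---|---|
| H300/H310/H330 | Acute toxic 2 | "Acute toxic 2" |
| H301/H311/H331 | Acute toxic 3 | "Acute toxic 3" |
| H302/H312/H332 | Acute toxic 4 | "Acute toxic 4" |
| H303/H313/H333 | Acute toxic 5 | "Acute toxic 5" |
| H315 | Skin irritant 2 | "Skin irritant 2" |
| H318 / H319 | Eye irritant 1 / 2 | "Eye irritant 1/2" |
| H315 ∧ H319 | Skin and eye irritant | combined family |
| none mapped | Potentially toxic | "Potentially toxic" |

Decisions worth recording:

* The five families are reverse-engineered from the labels the method is
  expected to produce ("Acute toxic 4", "Skin and eye irritant 2", "Eye
  irritant 2", "Potentially toxic"); the combined skin-and-eye family is
  what distinguishes a compound carrying both H315 and H319 from one
  carrying H319 alone.
* H300-type codes span GHS categories 1–2; the less extreme category (2) is
  reported. Oral, dermal and inhalation routes collapse to one acute level
  per position because the output labels carry no exposure route.
* When both a skin and an eye code are present the combined family takes
  the more severe of the two levels (so H318 + H315 gives "Skin and eye
  irritant 1"); this is what keeps the classifier monotone — adding a code
  can never lower the severity — a property the tests verify exhaustively
  against a brute-force oracle over all subsets of a 12-code set.
* Food-safety sections are carried as evidence only and never escalate
  severity: an escalation rule would have to invent hazard levels that food
  legislation sections do not encode.
* An empty code set with a non-empty toxicity field set classifies as
  "Potentially toxic": the record talks about toxicity but carries no
  harmonized statement, so the compound is flagged for human follow-up
  rather than silently passed.

The total severity order is Acute toxic 1 > … > Acute toxic 5 > Skin and
eye irritant > Eye irritant > Skin irritant > Potentially toxic
(`severityRank`); all reports sort by it.

## Merging

Per-mode tables are unioned by normalized compound name into per-sample
tables (`combineModes`), then per-sample tables into cross-sample reports
(`mergeSamples`), once each for toxic, unfound and unchecked. The merge is
an **outer (union) join** on the one shared column, the normalized name: a
merged report meant to guide the choice of confirmation standards is only
useful if no sample's compounds are dropped. An intersection variant is
available (`how = "intersection"`) but is not the default. Classification
conflicts across modes or samples resolve to the higher severity with a
logged warning. The merge is commutative, associative and idempotent up to
row order, which the tests check on randomized inputs.

## Synthetic data

The generators (`fixtureSpec`, `genToxicTable`, `genSample`,
`genRecordStore`) emulate the interchange artifacts of the surrounding
toolchain, not the physics upstream of them:

* background formulas are random CHNO compositions with H/C between 0.3 and
  3.0 (the plausibility window the assignment stage itself enforces), with
  C 5–30, O ≥ 1;
* masses are *computed* from element counts using one embedded monoisotopic
  mass table shared with the consistency checker, never sampled, so every
  generated row passes the 3 ppm check by construction;
* abundances are log-uniform over 10^4–10^8 (the dynamic range typical of
  Orbitrap peak areas) and retention times uniform on [0, 70] min, the span
  of the 70-minute chromatographic gradient the interchange format
  originates from;
* decoy toxic-table entries are rejection-sampled so they collide with
  neither planted nor background formulas. Planted-compound recovery is
  therefore exact with zero false positives *by construction* — passing
  that test demonstrates the bookkeeping (matching, partitioning, merging)
  is lossless, not that the method separates toxins from matrix in real
  data, where the toxic table is incomplete and isomeric collisions with
  benign compounds are common.

The generators do not simulate raw spectra, isotope patterns, adducts,
chromatographic noise or assignment errors; those belong to the upstream
peak-picking and assignment tools.

`validationFixture()` bundles the eight-compound worked example (coumarin,
3-/4-methoxybenzaldehyde, glutamic and aspartic acid, phenylalanine, citric
acid, naringin) with their actual harmonized GHS statements; the pipeline
reproduces the expected classification column exactly:

```{r validation}
fx <- validationFixture(file.path(tempdir(), "val"))
res <- runPipeline(list(samples = fx$sampleDir, toxic_table = fx$toxicTable,
                        store = fx$store, output = file.path(tempdir(), "valout")))
mergedReports(res)$toxic[, c("name", "classification", "evidence")]
```

## Numerical and degenerate-input choices

* CSV dialect is fixed: comma separator, UTF-8, header required — no
  sniffing. The strict feature-table contract accepts exactly the column
  order `row m/z, peak area, row retention time` and rejects the other five
  permutations.
* Report rows sort by severity rank descending then normalized name;
  deterministic output is what makes fixture-provider reruns byte-identical
  (the run log deliberately contains counts only, no timestamps).
* Empty inputs are legal everywhere: header-only feature tables, empty
  toxic tables, samples matching nothing, empty merged reports all produce
  header-only outputs rather than errors.
* Seeds: every generator derives per-purpose seeds from the spec seed and
  restores the caller's RNG state, so fixture generation never perturbs a
  surrounding simulation.
* Test problem sizes are deliberately modest — exhaustive classifier checks
  over 2^12 code subsets, 100-iteration randomized partition checks,
  two-sample pipeline runs with 15–25 background formulas — chosen to probe
  the combinatorics that matter while keeping a full suite run around a
  minute.

## Known limitations

* A compound must be present in the local toxic table to be screened at
  all; compounds not already known to be hazardous are invisible to this
  design (the trade-off for never needing structural identification).
* Formula matches are tentative: no structural evidence is used, so every
  toxic row is a candidate for confirmation against standards, not a
  finding.
* The classifier only reads harmonized hazard statements; dose descriptors
  (LD50), reference values (ADI/TDI) and chronic endpoints are out of
  scope.
* Name-based record resolution inherits the naming mismatches between
  databases; stereo-prefix stripping covers the common cases, the local
  table covers the rest by hand.
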