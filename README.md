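# toxscreen

Non-targeted toxin screening of assigned molecular formulas from LC/MS
experiments.

## What it does and for whom

Labs evaluating unconventional food sources (leaf protein concentrate,
agricultural residues, novel fermentation products) need to know whether a
sample contains known hazardous compounds without buying reference standards
for every conceivable phytotoxin. After peak picking and molecular-formula
assignment, a non-targeted LC/MS run reduces to a table of neutral formulas
with masses, abundances and retention times per electrospray-ionization
mode. `toxscreen` filters those tables against chemical-hazard knowledge:

1. **match** — exact element-count matching of assigned formulas (canonical
   Hill notation) against a local table of candidate toxic compounds
   (OpenFoodTox/TPPT-style: name, formula, monoisotopic mass, source);
   all isomeric candidates are retained;
2. **retrieve** — each candidate name is resolved to compound identifiers
   (CIDs) and its full hierarchical record fetched, from a local JSON store
   (default) or a live HTTP provider that spaces requests ≥ 0.2 s apart;
3. **classify** — records are scanned for toxicity/food-safety sections,
   GHS hazard-statement codes (`H<3 digits>`) are extracted and each
   compound lands in one of five severity-ordered categories:
   Acute toxic (GHS 1–5) > Skin and eye irritant > Eye irritant >
   Skin irritant > Potentially toxic, keeping the maximum severity;
4. **merge** — modes are combined per sample and the per-sample toxic,
   unfound and unchecked tables are each merged across samples (union join
   on normalized compound name), with a final formatting pass grouping the
   merged toxic table by category.

Every matched candidate ends up in exactly one partition: *toxic*,
*unchecked* (record without toxicity fields), *unfound* (no record), or
*locally matched* (resolved from a local table of previously hand-checked
names).

## Worked example

The bundled validation fixture holds the eight compounds recovered when this
screening design was validated against a proprietary-software workflow on
red maple leaf concentrate, with their harmonized GHS hazard statements:

```r
library(toxscreen)
fx  <- validationFixture(tempfile("val"))
res <- runPipeline(list(samples = fx$sampleDir, toxic_table = fx$toxicTable,
                        store = fx$store, output = tempfile("out")))
mergedReports(res)$toxic[, c("name", "classification", "evidence")]
```

prints

```
                   name          classification  evidence
1 4-methoxybenzaldehyde           Acute toxic 4      H302
2              coumarin           Acute toxic 4      H302
3 3-methoxybenzaldehyde Skin and eye irritant 2 H315;H319
4           citric acid Skin and eye irritant 2 H315;H319
5              naringin Skin and eye irritant 2 H315;H319
6         phenylalanine          Eye irritant 2      H319
7         aspartic acid       Potentially toxic          
8         glutamic acid       Potentially toxic          
```

Reading the rows: coumarin and 4-methoxybenzaldehyde carry H302 ("harmful
if swallowed"), GHS acute oral category 4; the three H315+H319 compounds are
combined skin-and-eye irritants at category 2; phenylalanine carries H319
alone; the two amino acids have toxicity fields but no harmonized statement,
so they are flagged "Potentially toxic" for human follow-up. Note that 3-
and 4-methoxybenzaldehyde share the formula C8H8O2 — one assigned formula,
two retained isomeric candidates with different hazard outcomes — and that
the amino acids were listed in the toxic table under their stereo-prefixed
names (L-phenylalanine, ...) and resolved to prefix-free record names by
name normalization.

A command-line front end is installed with the package
(`inst/scripts/toxscreen`): `toxscreen run --config run.yaml`,
`toxscreen validate-input FILE` (feature-table column contract:
`row m/z, peak area, row retention time`), and
`toxscreen gen-fixtures --spec spec.yaml --out DIR`.

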