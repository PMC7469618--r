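---
title: "The LEAP model: linked entity-attribute-pair stores for terminology crosswalks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The LEAP model: linked entity-attribute-pair stores for terminology crosswalks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leapr)
```

## The problem

Mapping records between two living classification systems — the motivating
case is OncoTree, the cancer-type ontology used for tumor-sample annotation,
against the seven ICD-O-3-based diagnosis elements a genomic data repository
requires (primary diagnosis, tissue or organ of origin, tumor grade,
morphology, site of resection or biopsy, primary site, disease type) — is
usually done in a denormalized spreadsheet: one row per code and sample type,
one column per target field. That layout copies every shared description into
every row that uses it. When a description changes upstream, dozens of cells
must be edited by hand; when a cell is mistyped, nothing catches it. The
defects that result fall into a small taxonomy: terms that are not in the
target system's data dictionary at all (overwhelmingly mere capitalization
differences), values that are individually legal but inconsistent with a
related field (a morphology code paired with the wrong diagnosis text), and
mappings that are syntactically valid but semantically wrong, which only an
expert can judge.

`leapr` implements a store designed around that failure mode.

## The model

The store normalizes data into six relations:

* **entity types** — "OncoTree code", "GDC morphology", "GENIE mapping", ...
* **entities** — one row per thing, identified by `(type, label)`;
* **attributes** — field names;
* **pairs** — reusable `attribute:value` combinations;
* **facts** — the join table assigning a pair to an entity, by numeric ids
  only (the entity-type reference lives on the entity, not on the fact);
* **links** — directed entity-to-entity edges.

The first five are a hybrid entity–attribute–value (EAV) layout: values are
normalized out of the fact table into shared pair rows, so a description used
by thirty mappings exists exactly once. The links are the distinctive part:
an entity *inherits* every attribute it does not set directly from the
entities it links to, transitively. A mapping entity for `(MYEC, primary)`
links to the morphology entity `8982/3` and carries no diagnosis text of its
own; `leap_resolve()` fills in the text from the morphology entity. When the
upstream description changes, `leap_update_pair_value()` touches exactly one
pair row and the change cascades to every inheritor — the package reports the
affected set rather than requiring the caller to enumerate it.

```{r}
st <- leap_store(actor = "vignette")
ot <- leap_add_entity_type(st, "OncoTree code")
gm <- leap_add_entity_type(st, "GDC morphology")
myec <- leap_add_entity(st, ot, "MYEC")
stmyec <- leap_add_entity(st, ot, "STMYEC")
morph <- leap_add_entity(st, gm, "8982/3")
leap_add_attribute(st, "primary_diagnosis")
leap_set_fact(st, morph, "primary_diagnosis", "Malignant myoepithelioma")
leap_add_link(st, myec, morph)
leap_add_link(st, stmyec, morph)

pair <- leap_get_pair(st, "primary_diagnosis", "Malignant myoepithelioma")
leap_update_pair_value(st, pair, "myoepithelioma, malignant")
leap_resolve(st, myec)
```

### Resolution semantics

Three rules, chosen to surface defects rather than hide them:

1. a direct fact always beats an inherited one;
2. among inherited providers the nearest (shortest link path) wins — a
   mapping's own OncoTree code entity overrides the same field on that
   code's parent;
3. if two providers at the same shortest distance disagree, resolution fails
   with a `leap_conflict_error` naming the attribute, both values and both
   paths. Equal-distance disagreement is exactly the situation in which a
   silent tie-break would bury an error, so there is no silent tie-break.

Links are transitive because classification chains are: a mapping entity
reaches descriptive pairs through a morphology entity one hop away, and a
code entity reaches nothing its own facts do not already cover, so deep
chains stay cheap. The link digraph must be acyclic; `leap_add_link()`
rejects any edge that would close a cycle, naming the path. Links may carry
a free-text `role` ("parent", "morphology"); the role is annotation only and
never affects resolution.

Values are compared byte-for-byte in the core. Case-insensitive matching
happens only in the validator, because a capitalization difference is a
defect to *report*, not to auto-repair.

## History and as-of reconstruction

Every mutation passes through one interception layer that enforces
referential integrity, uniqueness and acyclicity and appends exactly one
change record — sequence number, relation, row id, operation, full old and
new row images, a strictly monotone UTC timestamp (microsecond precision,
ties broken by forcing the clock forward), and an actor string. There is no
second write path, so no mutation can bypass history capture; multi-row
imports run inside a snapshot/rollback wrapper so a failed import leaves no
partial state.

The change log is the database: the live relations are the fold of the log,
`leap_as_of(store, t)` is the fold of the prefix up to `t` (returned
read-only), and the single-file JSON store format is simply the serialized
log. Full row images rather than deltas are stored; at the tens-of-megabytes
scale this store targets, the simplicity is worth more than the space.
Saving writes a temporary file and renames it into place, so a crashed save
never corrupts the store; a truncated or foreign file is refused with a
clean error on open. Single-writer, multiple-reader semantics are assumed
throughout — this is a curation tool, not a server.

## Ingest and the dynamic pivot

`leap_load_classification()` loads one version of a classification table
(fields: code, name, main type, tissue, optional parent) as one entity per
code with three facts and a link to its parent. `leap_load_mapping_sheet()`
inverts the denormalized spreadsheet: a **link spec** declares which sheet
columns identify linked entities (by default `oncotree_code`, `morphology`,
and `tissue_or_organ_of_origin`, targeting the code, morphology and
topography entity types) and which columns ride along as facts *on those
target entities*. Only the identifying columns (`oncotree_code`,
`sample_type`) become facts on the mapping entity itself, so descriptive
values are inherited, never copied. Contradictory carried values — two rows
claiming different diagnoses for one morphology — abort the import, listing
the rows.

`leap_export_denormalized()` is the inverse pivot: columns are discovered
from the resolved sets at run time (entity label plus the union of attribute
names, first-seen order), never hard-coded. Export and re-import are exact
inverses on every generated fixture, and the exported table reproduces the
13-column layout of the motivating spreadsheet: a mapping label, the two
identifying fields, the three OncoTree descriptive fields, and the seven
GDC diagnosis elements. That 13-column set is a reconstruction — the
original sheet's layout is configuration, not contract, and both the link
spec and the column order can be overridden.

Delimited-text I/O keeps every cell as verbatim UTF-8 text (no type
guessing), quotes embedded delimiters, accepts CRLF and LF alike, and
rejects ragged rows with the line number.

## Validation

`leap_validate()` checks the resolved (inheritance-inclusive) values of one
entity type against a data dictionary of allowable values plus pairwise
dependency rules, and classifies findings into four mutually exclusive
categories per `(entity, attribute)`:

* `UNKNOWN_TERM` — no allowable value matches, even case-folded; the detail
  suggests the nearest allowable value by edit distance;
* `CAPITALIZATION_MISMATCH` — a match exists after trimming outer
  whitespace and Unicode case folding; the detail gives the dictionary form;
* `DEPENDENT_FIELD_MISMATCH` — both values are allowable but their
  combination violates a declared rule (e.g. morphology determines the
  admissible primary diagnoses); the detail cites the rule and expectation;
* `ANNOTATED_INACCURATE` — a human judgment recorded with
  `leap_annotate_inaccurate()`. Semantically wrong but syntactically valid
  mappings cannot be detected mechanically, so the package carries the
  expert's verdict through reports instead of guessing.

A value-level defect on either side of a dependency rule suppresses the
dependent-field check for that entity: a pair containing an unknown term is
unassessable, and reporting it twice under two categories would double-count
one underlying defect. This is what makes the categories a partition.
Attributes the dictionary does not declare, and entities resolving only one
side of a rule, are reported as metadata, not findings. Validation is
read-only and its report order (entity label, then attribute) is
deterministic so that reports diff cleanly.

## Version diffing

`leap_diff_classifications()` keys on the code: `added`, `removed`, and for
codes present in both versions `renamed` / `reparented` / `refielded`
(tissue or main-type changes). Codes are treated as stable identifiers — a
code renaming itself is indistinguishable from a remove-plus-add without an
alias table, which the input format does not provide.
`leap_flag_for_review()` then lists every mapping whose code was removed or
changed in place, plus added codes with no mapping yet; it deliberately
never re-maps anything. `leap_summarize_diff()` groups additions by a
classification field and reports whole-percent shares rounded half-up; note
that half-up rounding of a share just above .5 (e.g. 30/146 = 20.55%) gives
21 where truncation would give 20.

## The synthetic world generator

Tests and the acceptance checks run against `leap_generate_world()`, which
emulates the study's inputs without any download. Its defaults are fixed at
the conditions the package is built around:

* **286 codes × 3 sample types**, giving the 858-row, 13-column mapping
  sheet shape of the motivating submission;
* ten tissue groups headed by *myeloid* and *lymphoid*;
* shared vocabularies of ~40 morphology entities (codes shaped `NNNN/3`)
  and ~15 topography entities (codes shaped `CNN.N`), so that many mappings
  inherit from each vocabulary entity, as in real data;
* a dictionary covering the seven GDC attributes plus one
  morphology→primary-diagnosis dependency rule;
* defect rates shaped like the observed error profile: capitalization
  defects dominating the unknown-term class (rate 0.07 of vocabulary
  entities, vs 0.02 for true unknown terms), dependent-field mismatches at
  0.06 of morphology entities, and reviewer annotations on 0.11 of mapping
  rows. Value defects are injected at the *vocabulary entity* level — every
  row sharing the corrupted entity sees the corrupted value, which is how a
  shared-sheet error actually propagates — and never into the link-key
  columns, whose errors are the expert-judged class. Rates are fractions of
  eligible targets, realized as exact counts (at least one when the rate is
  positive), so every category is present at every seed.
* a release-style edit script for version 2: 146 additions concentrated in
  the first two tissue groups (75 and 30), plus a dozen renames, a few
  reparentings, field revisions, and leaf removals.

Generation is a pure function of the spec: the RNG kind is pinned
(Mersenne-Twister, rejection sampling) and the caller's RNG state is
restored afterwards, so written fixture files are byte-identical across
runs. The ground truth enumerates every seeded defect expanded to the
mapping rows it reaches, the realized edit script, and the link topology;
the validator is scored against it by exact set equality on
`(entity, attribute, category)`.

What the generator does *not* emulate: real OncoTree content or real GDC
allowable values, multi-valued or typed attributes, near-miss semantic
errors (the annotated class is sampled uniformly, not adversarially), and
vocabulary-level churn between versions. A clean pass on these fixtures
demonstrates the mechanics — inheritance, cascade, history, detection,
diffing — not recall on any particular real dictionary release.

## Problem sizes and numerical choices

The test suite resolves stores of up to ~1 200 entities and ~7 700 change
records (the 286-code world) in a few seconds each; the property suite runs
200 randomized DAG stores (≤ 12 entities) against a brute-force resolution
oracle, 55-step mutation scripts against capture-and-replay, and 20
generator seeds against ground truth. Identifiers are store-issued
monotonically increasing integers, never reused after deletion. Timestamps
are numeric UTC seconds; equal-timestamp ties cannot occur by construction.
Percentages are rounded half away from zero. String ordering everywhere
uses radix (C-locale) sorting so reports and exports are locale-independent.

## Design choices that were genuinely open

* **Pair-value collisions on update**: if the corrected value already exists
  as a pair of the same attribute, the default merges the facts onto the
  existing pair (preserving the one-update cascade) rather than rejecting;
  `on_collision = "reject"` is available where vocabulary identity matters.
* **Sample type** is modeled as a direct fact on a per-`(code, sample_type)`
  mapping entity — three mapping entities per fully mapped code — rather
  than as a link role or a separate entity; it is identifying, not
  descriptive.
* **Link roles** are stored but ignored by resolution; nothing in the data
  model requires role-sensitive inheritance, and adding it would complicate
  the conflict rule.
* **Annotations** live on a reserved attribute (`flagged_inaccurate`) so
  they flow through history and snapshots like any fact, but the exporter
  excludes the reserved attribute by default: it is workflow metadata, not
  mapping content, and including it would perturb the sheet layout.
* **One allowable set per attribute**: the dictionary does not distinguish
  deprecated from current values; model a deprecation by removing the value
  and letting the validator flag the survivors.

## Known limitations

Single-valued attributes only; pairwise dependency rules only (no joint
constraints over three or more fields); no automatic re-mapping after a
version diff; no semantic mapping suggestions; single-writer persistence
with whole-store reads — none of which bind at the tens-of-megabytes scale
the design targets.
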