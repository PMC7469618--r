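# leapr

Harmonizing records between two living classification systems — for example
OncoTree cancer-type codes against the seven diagnosis elements a genomic
repository requires on an ICD-O-3 basis (primary diagnosis, tissue or organ
of origin, tumor grade, morphology, site of resection or biopsy, primary
site, disease type) — is usually managed in a denormalized spreadsheet that
copies every shared description into every row. Shared values drift, case
errors creep in, and an upstream change means editing dozens of cells by
hand.

`leapr` replaces the spreadsheet with a **linked entity–attribute–pair
store**: a hybrid EAV database in which

* entities, attributes and reusable `attribute:value` **pairs** live in
  separate relations, joined by a numeric-keyed **fact** table, and
* directed **links** let an entity inherit every attribute it does not set
  directly from the entities it links to, transitively.

A mapping row for `(MYEC, primary)` therefore carries only its identifying
facts and a link to the morphology entity `8982/3`; the diagnosis text
exists once, on the morphology entity. Correcting it is one pair update:

```
resolve(e) = direct facts of e
           ∪ { nearest-provider facts over links, per attribute }
```

with direct-over-inherited precedence, nearest-provider-wins, and a hard
conflict error (never a silent tie-break) when equally distant providers
disagree. Every mutation appends one full-image change record to an
append-only history, so any past state can be reconstructed (`leap_as_of`).
On top of the core sit a data-dictionary validator with a four-way defect
taxonomy (unknown term / capitalization mismatch / dependent-field mismatch
/ annotated-inaccurate), a dynamic-pivot exporter whose columns are
discovered rather than hard-coded, a classification version differ with
re-review flagging, and a deterministic synthetic-world generator with
seeded defects and exhaustive ground truth.

## Worked example

```r
library(leapr)

st <- leap_store(actor = "curator")
ot <- leap_add_entity_type(st, "OncoTree code")
gm <- leap_add_entity_type(st, "GDC morphology")
myec   <- leap_add_entity(st, ot, "MYEC")    # myoepithelial carcinoma, salivary gland
stmyec <- leap_add_entity(st, ot, "STMYEC")  # soft tissue myoepithelial carcinoma
morph  <- leap_add_entity(st, gm, "8982/3")
leap_add_attribute(st, "primary_diagnosis")
leap_set_fact(st, morph, "primary_diagnosis", "Malignant myoepithelioma")
leap_add_link(st, myec, morph)    # both codes inherit the morphology's
leap_add_link(st, stmyec, morph)  # descriptive attributes through links

leap_resolve(st, myec)
#> <leap_resolved> entity 'MYEC' (1 attributes)
#>   primary_diagnosis = 'Malignant myoepithelioma'  [via 8982/3]

# the repository rewords the description: one pair update, cascaded
pair <- leap_get_pair(st, "primary_diagnosis", "Malignant myoepithelioma")
leap_update_pair_value(st, pair, "myoepithelioma, malignant")
#> <leap_change_summary> rows_updated = 1
#>   affected entities: 8982/3, MYEC, STMYEC

leap_resolve(st, stmyec)
#> <leap_resolved> entity 'STMYEC' (1 attributes)
#>   primary_diagnosis = 'myoepithelioma, malignant'  [via 8982/3]
```

`rows_updated = 1` is the point of the design: one row changed, and both
linked codes now resolve to the new description. The same store supports
history (`leap_entity_history(st, myec)` shows the pair UPDATE arriving
through the link) and time travel (`leap_as_of` reconstructs the
pre-update state).

End-to-end, a denormalized mapping sheet is loaded with
`leap_load_mapping_sheet()` (links inherit the descriptive fields instead
of copying them), validated with `leap_validate()` against a JSON data
dictionary, and re-exported with `leap_export_denormalized()`; a new
classification release is compared with `leap_diff_classifications()` and
affected mappings flagged with `leap_flag_for_review()`. The
`leap_generate_world()` fixture generator produces a full synthetic study —
two classification versions, dictionary, an 858-row × 13-column mapping
sheet, seeded defects, ground truth — from a single seed.

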