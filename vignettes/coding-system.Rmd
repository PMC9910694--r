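---
title: "The animal-model coding system: design, registry and retrieval benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The animal-model coding system: design, registry and retrieval benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amrcode)
```

## The coding model

`amrcode` implements a layered classification-and-coding scheme for
human-disease animal-model resources. A record is classified independently
along three hierarchical *trunk* dimensions — system disease (A), animal
species (B), modeling method (C) — and one parallel *branch* of essential
attributes (D). Each classified layer contributes a fixed-width, zero-padded
digit group to the canonical code

```
CSTR09:A<major><intermediate>[<minor>]B<major><species><strain>C<category>[<subcat>]D<coop><share><pres>
```

The fixed `CSTR09` prefix marks the record as a Chinese
science-and-technology "experimental material" resource, keeping these
codes embeddable in the national resource-identifier ecosystem; the
platform-level identifiers themselves
(`CSTR:16397.09.0C01001234`, component widths 4/5/2/10) are parsed by
`parse_national_identifier()` and treated as opaque beyond their widths.

Two structural rules drive everything else:

* **Supplementary zeros.** The all-zeros code of a layer (`00`, `000`,
  digit `0`) stands for "empty layer" or "attribute missing". It can never
  be assigned to a labeled node, so a code is always unambiguous about what
  is *not* recorded.
* **Incremental sequence codes.** Within a parent, labeled children receive
  the smallest unused nonzero code (`assign_next_code()`). Vocabularies
  therefore grow append-only: new intermediate categories or strains get
  fresh codes without disturbing existing ones.

The rationale for the layering is combinatorial. A flat three-way
classification with 10, 6 and 3 categories per dimension yields at most
`combinatorial_capacity(c(10, 6, 3))` = 180 cells — far too coarse for
thousands of models, so most cells would hold many records and retrieval
would still end in a visual scan. Subdividing each dimension into layers
multiplies the cell count (the bundled vocabulary alone spans 16 × 4 × 3 =
192 major-level cells before strains and intermediates are counted), which
is what makes one-shot retrieval plausible.

### Profiles

Two code profiles are supported. The *paper* profile encodes A as
major+intermediate (4 digits), B fully (7 digits), C as category (2
digits); this matches every printed reference code. The *extended* profile
adds the optional disease-minor and method-subcategory layers (A = 6, C = 4
digits), zero-filled when absent. Decoding auto-detects the profile from
segment widths; an extended code whose extra layers are all zeros decodes
cleanly against a paper-profile registry, while nonzero extra layers are an
error — silent truncation would change meaning.

## The bundled registry and its provenance

`amr_fixture_registry()` loads the vocabulary that the published reference
material states directly: the 16 disease majors in their printed order, the
eight cardiovascular intermediates (myocarditis `01` … atherosclerosis
`08`), laboratory animal `11`, species mouse `11` / rat `13` / guinea pig
`15` / rabbit `27`, the named strains, the three modeling methods, and the
attribute digit vocabularies. Three nodes are *inferred* from printed full
codes rather than stated as table rows — rabbit `27` (from `B1127001`),
the ICR-Tg(hACE2) strain `017` and the SARS-CoV-2 intermediate `12` (both
from the worked example `A0312B1111017C02D201`) — and carry
`provenance = "inferred"` in the fixture so the distinction is queryable.
Gaps are left unassigned (mouse strains `004`–`016` are reserved), since
inventing entries would collide with the append-only assignment rule. One
source conflict is resolved in favour of the prose: species `15` is
recorded as guinea pig, not pig. The full national taxonomy (118 disease
intermediates, complete strain lists) is unpublished and deliberately not
reconstructed.

The registry serializes as a flat TSV (`dimension`, `layer`, `parent_path`,
`label`, `code`, `provenance`) and an equivalent YAML row list; parents are
referenced by `/`-joined label paths. Because labels themselves may contain
`/` (BALB/c), the registry keeps the resolved label *vector* per node
internally and never re-splits path strings.

## Retrieval: code patterns vs the keyword baseline

`search_by_code_pattern()` matches per-digit: a query constrains each
segment with literal digits, `?` (any digit at one position) or `*` (whole
segment). This grammar is a design choice of the package — partial-code
retrieval is demonstrated in the reference material only by example. Two
invariants pin the semantics: results always equal a naive per-record regex
scan (tested against an independent oracle), and refining a pattern with a
literal digit never enlarges the result set.

`neighbor_expansion()` implements relevance search — "models like this one,
but varying these layers" — by wildcarding the chosen layers of a base code
and excluding the base code itself. It is defined *as* the equivalent
pattern search, so the same oracle covers it.

`keyword_search()` reproduces the baseline the code method competes with:
field-AND matching, substrings for the three long text fields (`name`,
`english_name`, `disease_description`), whole-value equality for the three
short ones (`cooperation`, `date`, `preservation`). Matching is
case-sensitive on trimmed values; no stemming, ranking or refinement —
deliberately, since the baseline's inability to refine a 171-name candidate
list is precisely the inefficiency being measured.

`benchmark_one_shot()` scores both methods per query by whether the result
set equals exactly the target record — the strictest reading of "retrieved
at one time" — plus the mean and maximum candidate-list sizes. Ties among
equal matches are avoided by fixed deterministic ordering (code, then
record id), so results are byte-stable across runs.

## The synthetic catalog generator

Real catalog contents are not redistributable, so benchmarks run on
generated catalogs (`generate_catalog()`). The generator emulates the one
structural fact that matters for retrieval efficiency: *skewed cell
occupancy*. Records are assigned to (disease-leaf × species-leaf × method)
cells by a categorical distribution in which a few hotspot cells carry
fixed large weights and the remaining mass is spread by a symmetric
Dirichlet draw.

Defaults, chosen once as a realistic emulation and documented as fictional:

* `total_records = 865` — the size of the national collection the scheme
  was developed against;
* hotspots: tumor × C57 mouse × {induced, genetic engineering} with
  combined weight 181/865 ≈ 0.21, mirroring the anecdotal mouse-tumor
  concentration in that collection (the real per-cell distribution is
  unpublished);
* `cell_skew = 0.5` — a sub-uniform Dirichlet concentration giving a long
  tail of sparse cells next to the hotspots;
* `attribute_missing_rate = 0.1` per attribute, reflecting patchy
  administrative metadata.

Each record draws attributes independently, is encoded through
`encode_record()` (so every generated code is valid by construction — and
re-validated in tests), and gets label-derived English metadata plus a
unique noise token, e.g. `"C57 tumor induced model lot-28997"`. The
generator is deterministic given its seed, restores the caller's RNG
state, and exposes the drawn cell distribution as the `cell_weights`
attribute so goodness-of-fit can be checked (a pooled chi-square test at
n = 10,000 is part of the suite).

What the generator does **not** emulate: bilingual (Chinese/English)
metadata, realistic prose descriptions, inter-field correlations beyond the
cell structure, or the real database's actual contents. Benchmark results
on synthetic catalogs therefore demonstrate the *mechanism* of the
efficiency gain — unique-enough codes versus unrefinable keyword lists —
not a measurement of any live system.

`make_query_set()` builds paired queries: for each sampled target, the
keyword method gets one word drawn from the target's own name (guaranteed
to match it, usually among many others), the code method gets the target's
fully literal pattern. This is intentionally generous to the baseline —
a human would rarely guess even one exact token of the stored name.

## Numerical and edge-case choices

* **Canonical form.** No whitespace after the colon, upper-case letters;
  printed forms with a space and lower-case input are accepted and
  normalized. Canonicalization is idempotent and performs no structural
  validation.
* **`00–99` ranges** are read as: `00` reserved, `01`–`99` assignable.
  Capacity exhaustion under a parent is a hard error, not a silent wrap.
* **Attribute semantics are positional** (cooperation, sharing,
  preservation after `D`); every printed full code confirms this reading,
  and the brute-force enumeration of valid D-parts (36 codes, maximum 322)
  is asserted in the suite.
* **Validation returns data, not errors** (`validate_code()`): a data frame
  of located violations, so batch ingestion can report everything at once.
  `decode_code()` raises the first problem as an error instead, which fits
  interactive use.
* **One-shot success** requires result set == {target}; returning the
  target plus one sibling counts as a miss for both methods.
* **Degenerate inputs**: empty registries report zero counts; empty
  catalogs search to empty results; an empty query set yields `NA` rates
  rather than fabricated zeros.

## Problem sizes in the test suite

The suite exercises the decode∘encode identity over every fixture leaf
cell with rotating attribute triples plus one cell × all 36 triples
(~1.7k round trips), the search oracle on a 10,000-record catalog, and
benchmarks on the 865-record default; the full suite runs in well under a
minute on one CPU. These sizes were chosen to cover every code path and
the claimed scale of the motivating collection while keeping the suite
fast to iterate.

## Known limitations

* The bundled vocabulary is the published condensed template, not the full
  national taxonomy; counts that depend on the unpublished remainder (118
  disease intermediates, live-database hit counts) are out of reach by
  construction.
* Keyword matching is byte-level on trimmed UTF-8; no Unicode
  normalization or CJK tokenization is attempted, consistent with the
  English-only synthetic metadata.
* The CLI encodes label paths with `/` as separator, so labels containing
  `/` (BALB/c) must be supplied via input files rather than flags.
* Codes are categories, not identifiers: several records may share one
  code, and the benchmark treats that honestly (the code method's one-shot
  rate drops below 1 exactly where cells × attributes collide).
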