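---
title: "Registry construction and quality assessment: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registry construction and quality assessment: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allregistry)
```

This vignette explains what the package computes, the assumptions behind
each stage, the parameters that matter and why their defaults were chosen,
and what the synthetic-data tests do and do not demonstrate about real
hospital data.

## The pipeline

A registry build runs in stages, each usable on its own:

1. **Table specification** (`load_schema`). The registry is defined by a
   versionable config document: tables grouped into seven categories
   (Person, Diagnosis, Laboratory, Drug, Surgery, HSCT, Visit), each element
   with a data type, maximum length, NOT NULL status and optional value
   domain, plus primary and foreign keys. Validation is structural and
   complete before any data is touched: primary keys must exist and be NOT
   NULL, foreign keys must resolve to a declared table's primary key, and
   element identifiers are unique across the whole schema (which is why the
   packaged schemas use table-prefixed ids).

2. **Cohort selection** (`select_patients`). Included patients have at
   least one C91.0 diagnosis dated January 1990–December 2023, are aged
   under 18 in completed years *at the first C91.0 diagnosis date* (the
   eligibility time point had to be fixed somewhere; diagnosis date is the
   clinically natural choice), and carry confirmatory evidence — a
   bone-marrow blast percentage of at least 20, or an immunophenotype
   recoverable from flow-cytometry results. Patients with another
   malignancy code predating the first ALL code are *flagged for review*,
   never auto-excluded: distinguishing a true prior malignancy from
   miscoding needs a clinician.

3. **Transforms** (`build_registry`). Three automatable kinds:
   *direct* (column copy, optionally through a named recoding such as
   `sex_code`), *multivariate* (currently the nearest-qualifying-lab
   transform: the value of the requested lab type within the closed window
   `[anchor, anchor + 7]` days, ties broken by smallest absolute distance,
   then earlier date, then stable input order — every tie-break is explicit
   because "the nearest WBC" is otherwise ambiguous), and *nlp* (a named
   parser applied to the narrative column, falling back to the structured
   column for rows a tabular CDW stores discretely). Values that fail type
   coercion — an impossible calendar date, a non-numeric count — are kept
   verbatim and surfaced to the quality engine as format candidates rather
   than silently dropped: the quality report must see the data as loaded.
   Dates are calendar dates at day resolution, ISO-8601 throughout.

4. **Rule-based NLP** (`parse_fish`, `parse_karyotype`,
   `parse_immunophenotype`). Deliberately regular-expression based — the
   report fields are semi-structured, and deterministic rules keep every
   extracted value auditable. The parsers are *total*: no input string
   raises; anything unparseable becomes an explicit indeterminate finding
   retaining the raw text. Design decisions worth stating:
   - The trailing `(a/b)` after a `nuc ish` clause is read as
     abnormal-cells / cells-scored, the ISCN scoring convention.
   - A deletion call requires a probe copy number below 2, with no minimum
     cell-fraction cutoff; none is defined for the assay as modelled, and a
     threshold would silently change calls.
   - Ploidy thresholds default to hypodiploid < 44, normal range 44–50,
     hyperdiploid > 50 — the common pediatric-ALL convention — and are
     configurable because laboratories differ.
   - Only the modal chromosome count is extracted from karyotypes; a full
     ISCN grammar (derivatives, breakpoints, clones) is out of scope.
   - Flow-cytometry lineage comes from a configurable marker→lineage
     lexicon; markers count as evidence only when reported positive, and
     token boundaries prevent CD3 matching inside CD30.

5. **ADE assessment** (`classify_elements`, `ade_report`). Classification
   is *design-time*: it derives from the mapping configuration plus the
   institution's field inventory, not from attempted extraction — an
   element whose source field the CDW lacks is `unavailable` no matter what
   transform was declared. Percentages are displayed half-up to one decimal
   with the raw ratio always retained (117/138 is 84.78…%, which prints as
   84.8 under half-up rounding but is sometimes quoted as 84.7; keeping the
   raw ratio avoids arguing with either).

6. **Quality engine** (`evaluate_quality`, `remediate`, `grade`). Rules are
   declarative config, one of eight check kinds, each legal only under its
   dimension (validity → range/format; accuracy → timeline/business rule;
   consistency → relationship). The *checked-unit* question — what is the
   denominator of an error rate? — is answered per rule kind and is the
   package's own definition, since error rates are meaningless without one:
   cells in scope for completeness/validity rules, event rows with a death
   date on file for timeline rules, trigger prescriptions for business
   rules, keys for uniqueness, non-missing references for consistency.
   The quality value is `100 − overall error rate`, mapped onto five level
   bands with Level 5 (quality value 85–100, inclusive lower bound) as the
   minimum standard.

7. **Remediation.** Policies per rule: `mark_na` and `exclude_invalid`
   replace the offending cell with the explicit `"NA"` marker (an
   acknowledged missing value, which completeness rules accept — this is
   what distinguishes "checked and absent" from "never filled");
   `drop_record` and `reload_dedupe` remove rows; `reindex_fk` blanks a
   dangling reference; `verify_date` restores the patient's death date from
   a trusted certificate relation and removes event records that still
   conflict afterwards. Business rules are always `flag_only`: a leucovorin
   prescription without methotrexate in the prior seven days is flagged,
   but whether it is an error requires clinical context, so the engine
   never touches it. Re-evaluating a remediated registry therefore yields
   findings only for flag-only rules, and a second remediation is a no-op.
   When several cell policies collide the precedence is
   `drop_record > exclude_invalid > mark_na`.

## The synthetic CDW generator

No patient data ships with the package; the generator
(`generate_cohort`) emulates the *structural* features the pipeline
consumes, in two dialects: `narrative_heavy` (coverage from 2000, 80% of
cytogenetic/flow results as free text) and `tabular` (coverage from 2009,
fully discrete). Per patient it produces a C91.0 diagnosis inside the study
window, an age under 18 at that date, a marrow blast percentage of 20–98,
WBC measurements around and after diagnosis, karyotype/FISH/flow results
rendered through the same template grammars the parsers are tested against
(with controlled noise: `x` vs `×`, variable spacing, trailing ellipses),
one methotrexate–leucovorin pair, visits with department codes in the valid
1–26 domain, HSCT events for 22% and death dates for 15% of eligible
patients, each death postdating every generated event. A configurable 20%
of patients are decoys violating exactly one eligibility criterion.
Defaults were chosen once as plausible for a pediatric-ALL population
(median cohort age under 10, HSCT in roughly a fifth) and are not tuned.

`inject_errors` corrupts exactly the requested number of cells per quality
dimension and writes a ledger with both the source location and the
registry location where the engine must flag it. Two targeting constraints
are deliberate generator design: injections land only on rows of
non-decoy patients (a defect on a row that cohort selection removes could
never be detected, so it would make the recall oracle vacuous), and never
on cells that determine eligibility. Relationship defects are injected on
the lab→visit foreign key rather than the patient key for the same reason:
patient-key orphans would be silently filtered out before quality
evaluation ever ran.

**What the synthetic tests show — and what they do not.** Perfect recall
and precision on injected data show that the rule engine detects exactly
the defect classes it has rules for, with correct denominators and
locations. They do not show that real CDW extracts contain only these
defect classes, that real missingness rates resemble the synthetic ones
(real per-field missingness is not modelled at all), or that the parsers
cover the full variety of real-world report prose — the grammars mirror the
parsers by construction, so round-trip success is a consistency check, not
a field validation.

## Numerical choices

- Display rounding is half-up (one decimal for proportions, three for
  error rates); raw ratios are always carried alongside.
- Degenerate inputs fail loudly: an error rate with zero checked units, a
  proportion over an empty scope, and errors exceeding the checked count
  are errors, not zeros.
- Every ordering is made deterministic (stable radix sorts, explicit
  tie-breaks), so identical inputs give byte-identical registries, and a
  run manifest (config hash + seed) reproduces a pipeline run exactly.
- Problem sizes in the tests and the acceptance script — cohorts of 500
  patients over three seeds, a thousand round-trip report strings — were
  chosen as the scale at which every property has comfortably outgrown
  small-sample flukes while a full run stays interactive.

## Known limitations

- The packaged 184-element registry specification reproduces the published
  per-table counts, but most element *names* are placeholders: the source
  catalogue is not public. Twenty subcategory tables are modelled; the
  published description of the same inventory gives the subcategory count
  as 18 without enumerating the grouping, so the table-level tally was
  taken from the per-table count breakdown, which is internally consistent.
- The quality rule pack shipped for the demo registry covers every
  dimension and the canonical worked rules, but is illustrative: a real
  deployment would grow site-specific rules (the count of rules is
  configuration, not a claim).
- The engine clears remediable timeline findings by construction; in a real
  deployment, death dates verified as *correct* against certificates leave
  genuine conflicts standing, which is one reason flag-only categories
  exist.
- No SQL execution, no DDL generation, no live database connectivity, no
  statistical NLP: the package operates on delimited extracts and config.
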