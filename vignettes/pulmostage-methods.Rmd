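---
title: "Rule-based pulmonary T-staging from free-text reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based pulmonary T-staging from free-text reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulmostage)
```

## The problem

Staging a lung tumor under the TNM system requires three kinds of evidence
about the primary tumor, all of which radiologists routinely dictate in
free text: its largest dimension, whether it directly invades named
thoracic structures, and a small set of non-size findings (post-obstructive
atelectasis, satellite nodules, nodules in other ipsilateral lobes).
`pulmostage` extracts these three items from English chest CT / PET-CT
staging reports with deterministic rules and composes them into a T
substage. A rule-based design was chosen deliberately: every label comes
with a human-readable rationale and token-level highlights, the behavior is
configurable (lexicons, modifier inventory, section policy and decision
table are all editable plain-text resources), and no protected clinical
training data are needed.

## Pipeline

A report passes through five stages, each consuming and returning the same
token-level standoff document, so the stages can run fused in one process
or chained through the JSON interchange format:

1. **Preprocess.** Line endings, non-breaking spaces, tabs and stray
   control characters are normalized *length-preservingly*, so every
   annotation span indexes the original text directly and the offset map is
   the identity. We chose in-place normalization over whitespace-run
   collapsing precisely so that a GUI can highlight spans on the text the
   radiologist wrote without coordinate translation. Sections are opened by
   subheadings matched at line starts only (optionally followed by `:`), so
   a mid-sentence "chest" never opens a section; text before the first
   heading, or a report without headings, is a single in-scope `other`
   section. Sentences are split at newlines and at whitespace after
   terminal punctuation — a decimal point inside `3.1 cm` is never followed
   by whitespace, so measurements cannot be split. Tokens cover all
   non-whitespace characters; decimal-comma numbers (`8,6`) stay single
   tokens.

2. **Concept matching.** Each lexicon entry is one case-insensitive,
   word-boundary-anchored pattern carrying a SNOMED-CT code and a category
   (tumor mass, lymph node, involvement target, presence finding, anatomic
   location, blacklist term). Longest match wins among overlapping hits of
   the same category. A tumor lexeme accompanied in-sentence by an explicit
   nodal lexeme (`lymph`, `node`, `nodal`) is recategorized as a lymph
   node — "a (lymphnodal) subcarinal mass" describes a node — whereas a
   nodal-*station* word alone does not flip it, because "a perihilar mass"
   is usually the tumor. This keeps both of the hard hilar cases nearly
   right but cannot resolve the ambiguity entirely; it remains the
   dominant error mode of this class of algorithm.

3. **Context validation.** A ConText/NegEx-style engine: negation,
   uncertainty and historical triggers carry a direction (forward,
   backward, bidirectional); their scope runs to the sentence boundary,
   truncated at the nearest termination trigger (`but`, `however`, `;`,
   ...) or at the next flag-bearing trigger. Pseudo triggers (`no change`)
   swallow the shorter true triggers they contain and flag nothing. Scope
   is purely positional: there is no dependency parsing, so a modifier can
   in principle attach to the wrong concept in convoluted sentences. That
   limitation is retained by design — the point of this component is the
   simple, auditable rule. Flags are monotone, and blacklist mentions never
   carry flags. Uncertainty phrasing such as "abutting" or "extending
   towards" *excludes* a concept from staging by default, implementing the
   convention that involvement is only scored when stated as certain; the
   inventory is a TSV resource, so counting uncertain involvement instead
   is a one-line configuration change.

4. **Measurements and findings.** A size must carry a unit (`mm`/`cm`) to
   exist; `14` alone is never a measurement, and a tumor described only as
   "large" yields no size. The grammar accepts decimal points and commas,
   two/three-dimension tuples sharing one trailing unit, and axis-labelled
   tuples (`2.1 (AP) × 3.0 (TVR) × 1.8 (SI) cm`); ranges (`1-2 cm`) are
   skipped as ambiguous. The largest dimension is normalized to mm (exact
   ×10 for cm). Each measurement links to the nearest preceding unflagged
   tumor/node/involvement mention in its sentence (falling back to the
   nearest following), and takes laterality/lobe from the nearest anatomic
   location mention. Sizes linked to lymph nodes or involvement targets
   (e.g. "pleural thickening of 8,6 cm") never become tumor sizes.
   Suppression happens sentence-wise before linking: a sentence containing
   a blacklist term (kidney, liver, cyst, adrenal, ...) or lying in an
   out-of-scope section (history, abdomen, bones, ...) loses its tumor-mass
   and size candidates, while involvement mentions survive. Generic
   "atelectasis" is only a presence finding when the sentence carries no
   gravity-type adjective (basal, bibasilar, bilateral, subsegmental,
   dependent, ...); an explicitly post-obstructive phrase always counts.

5. **Classification.** Consolidation chooses the largest linked tumor size
   as the primary. A second sized tumor mention in the same lobe (or with
   unknown site) is treated as a *repeated description of the same tumor*:
   the larger size is kept and a warning logged. We resolved this
   deliberately against the alternative reading (same-lobe second mention =
   satellite nodule) because duplicate dictation of one tumor's size is a
   documented reporter behavior, while satellite nodules are reliably
   announced with the word "satellite", which the lexicon catches as a
   presence finding. A sized tumor in a different ipsilateral lobe becomes
   a T4-eligible nodule when above the minimum size; contralateral nodules
   are outside the T domain and only logged. The label is the maximum of
   the three components under
   `Tx < T1a < T1b < T1c < T2 < T2a < T2b < T3 < T4`.

## The decision table

The size/involvement/presence rules live in a versioned YAML resource
(`inst/extdata/tnm_ajcc8.yaml`) so that future editions can be swapped in
for restaging historical reports. Numerical conventions:

* Size classes are "> lower, ≤ upper": 10 mm is T1a, 30 mm is T1c,
  boundary values inclusive on the lower class.
* The classification itself does not state a minimum size for a nodule in a
  different ipsilateral lobe; `nodule_min_size_mm` (default 10, i.e.
  "> 1 cm") makes that threshold explicit and configurable. A nodule at or
  below the threshold, or without a size, contributes nothing and the
  rationale says so.
* A satellite nodule in the same lobe has *no* minimum size — the
  explicit threshold applies only to the different-lobe rules.
* A bare T2 criterion (e.g. main-bronchus involvement) with a known size
  resolves to T2a (≤ 40 mm) or T2b (≤ 50 mm); with no size the distinct
  label `T2` stands. `Tx` is this package's convention for "no tumor
  evidence extracted"; it is not part of the descriptor table.
* Degenerate inputs: non-positive sizes are input errors; an involvement
  structure unknown to the table is a configuration error (the lexicon and
  table must agree); all-absent components give Tx, never an error.

## The synthetic corpus

The 425-report clinical corpus behind this method is not publicly
available, so the package ships a seeded generator that emulates its three
report formats — a plain CT report with History / Comparison / Technique /
Findings / Chest / Mediastinum / Abdomen / Bones subheadings, a blended
PET-CT narrative in a single Findings section, and a sectioned PET-CT
format with separate CT and PET findings. Defaults are fixed, not tuned:
the substage weights follow a staging cohort's composition (T1a and bare
T2 rare; T1c, T2a, T3 common), the format mix is roughly 53/39/9
CT/PET/PET-CT, and distractor rates (benign kidney cysts with sizes 30%,
gravity atelectasis 35%, negated involvement 25%, uncertain involvement
25%, nodal-station lymph nodes with sizes 40%, unitless sizes 15%) and
dialect rates (decimal commas 20%, three-dimension tuples 30%, axis labels
10%) were chosen once as plausible dictation frequencies. Every gold record
is self-consistent by construction: the generator classifies its own
planted findings and aborts on an infeasible plan, so a gold label can
never disagree with the rules it is meant to test.

The generator is a template grammar with lexical variation sampled from the
concept lexicon itself. That guarantees computable gold labels, but it also
bounds what passing tests can show: the pipeline is exercised against the
grammar's phrasings and the planted distractor constructs, **not** against
out-of-grammar clinical language, speech-recognition artifacts, or the full
variability of real reports. Perfect recovery on the synthetic corpus is a
correctness statement about the rules, not an accuracy claim about clinical
text.

## Verification

Problem sizes were chosen to make the checks exhaustive where that is cheap
and generously sized where it is not: the classifier is compared with an
independently written brute-force transcription of the decision rules over
all sizes 1–100 mm plus absent × all 1024 subsets of a ten-structure
involvement inventory × cycled presence combinations (~10^5 cases); the
clean and adversarial corpora use n = 200 documents each; scope assignment
is compared against a literal pairwise oracle over every generated
sentence plus a hand-built trace table (which caught a boundary bug the
generated oracle shared with the implementation — a reminder that oracles
derived from the same reading of a rule are weaker than independently
constructed cases); determinism is verified by byte-comparing two seeded
runs end to end. The scripts/acceptance.R entry point recomputes all of
this from scratch.

## Known limitations

* The `cyst` blacklist term suppresses cystic *lung* tumors — the
  documented trade-off of blacklisting renal cysts is reproduced, not
  fixed.
* Hilar mass-versus-node ambiguity is reduced by the nodal-lexeme rule but
  not eliminated.
* No dependency parsing: context scope is positional within the sentence.
* Involvement is detected from the structure word with context flags, not
  from verified invasion semantics; a sentence like "the mediastinum is
  unremarkable" would count as involvement unless negated — in practice
  such sentences are negated ("no ...") or absent, but this is a real
  false-positive surface on free text.
* N and M staging are out of scope; the interchange format reserves no
  more than the T result.
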