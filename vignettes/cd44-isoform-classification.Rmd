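---
title: "Classifying CD44 protein isoforms by exon composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying CD44 protein isoforms by exon composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cd44iso)
```

## The problem

Human CD44 is a type-I transmembrane glycoprotein whose gene comprises 19
exons, nine of which (the variable exons V2–V10) are subject to alternative
splicing. Protein databases hold dozens of deposited CD44 sequences under
inconsistent names and accessions: the same isoform may appear under an NCBI
and a UniProt entry, under a historical abbreviation (CD44s, CD44E, epican,
Hermes), or with no name at all, and entries within one splice form differ
further by benign point substitutions, single-residue indels, or C-terminal
truncation. `cd44iso` makes this corpus tractable by expressing every
deposited sequence as a set of edits against one fixed reference — the
742-residue canonical isoform carrying all nine variable exons — and then
classifying those edits.

The pipeline is: global alignment of each isoform to the canonical →
conversion of the alignment into HGVS p.-level variant descriptors →
matching of descriptors against a catalogue of known exon-splice events →
classification of the C-terminus → grouping of isoforms by exon
composition. A separate module scans genomic exon sequence for the
alternative AG/GT splice sites that microexon variants imply.

## Coordinates and descriptors

All positions are 1-based and inclusive on the canonical sequence, matching
the HGVS protein convention; no 0-based or half-open interface is exposed.
Four descriptor kinds cover everything observed in the corpus:

* substitution — `p.K417R`
* deletion — `p.A428del`, `p.G266_S273del` (named form, one-letter codes)
* insertion — `p.345_346insA` (flanking positions)
* deletion–insertion (delins) — `p.385_428delinsT`

A delins is the protein-level footprint of splicing out exons: the splice
junction fuses a hybrid codon, so a replaced canonical range plus a short
junction insert (often a single residue) is exactly what the protein
records. The packaged event catalogue stores each recognised splice pattern
as such a `(replaced range, insert)` pair; exon labels (V2, V6, …) are
display metadata, not coordinates, because exon boundaries are only defined
here through the descriptors themselves. Only one-letter amino-acid codes
are emitted or parsed; three-letter HGVS forms and nucleotide-level
descriptors (c./g./r.) are out of scope, as are frameshift/extension forms,
which do not occur in this corpus.

### Normalization: `hgvs3` versus `as-deposited`

An edit inside a repeat run has several equivalent spellings: deleting any
one alanine of the canonical A427–A429 run yields the same protein. Mode
`"hgvs3"` (the default) rewrites each descriptor as the
highest-coordinate representative of its equivalence class — two
descriptors are equivalent exactly when applying them gives identical
strings, and normalization maps each class to one member (the deletion
above becomes `p.A429del`). Mode `"as-deposited"` leaves descriptors
untouched; it exists because databases print `p.A428del`, and a fixture
transcribed from deposited records should round-trip byte-identically.
The implementation derives the normal form by maximising the common prefix
between the reference and the edited sequence, then the common suffix —
maximising the prefix first is what pushes the edit to its most C-terminal
spelling. The single-residue insertion between positions 345/346 sits in a
non-repetitive context (`…MTD…`), so both modes print the same form for it.

## The aligner

Alignment is global Needleman–Wunsch with affine gap runs (Gotoh
recursion), implemented in compiled code. The scoring defaults are:

| parameter | default | why |
|---|---|---|
| match | +2 | identity scoring; all inputs are isoforms of one gene |
| mismatch | −3 | point substitutions should cost little and align as mismatch columns, never as gap pairs |
| gap open | −12 | steep opening cost makes one long gap beat scattered short gaps, so a spliced-out multi-exon block appears as a single contiguous run |
| gap extend | −0.5 | shallow extension keeps a 380-residue splice-out affordable |

A substitution matrix (BLOSUM-style) is deliberately not used: residue
similarity between isoforms of the same gene is noise for this task.
`X` never counts as a match anywhere — in scoring, extraction, or event
verification. End gaps are charged normally (the alignment is fully
global); partial records are instead detected downstream from coverage,
which keeps the alignment model simple and pushes the partial/complete
decision to a single interpretable threshold.

All four default scores are dyadic rationals, so alignment scores are exact
in floating point and traceback tie detection uses exact equality. Among
co-optimal alignments the traceback prefers gap states over match states
and gap-run extension over re-opening, which places gap runs at the highest
(most C-terminal) reference coordinates — descriptor extraction therefore
lands on 3'-normalized coordinates directly in most cases, and the
normalization pass only has work to do in genuine repeat contexts.

### Extraction and the merge rule

Alignment columns are partitioned into maximal blocks of non-identity
columns; a block is a run of gap columns together with any mismatch columns
*strictly contiguous* to it. Each block becomes one descriptor. The
strict-contiguity rule is load-bearing: a substitution two residues away
from a splice event (such as the recurrent `p.I479T` near the V6 event)
stays a separate residual, while a substitution flush against an event
boundary is absorbed into the delins. The absorbed case is irreducible —
under affine scoring, a point edit separated from an event block by `k`
match columns is only representable separately when the rescued matches
outweigh a second gap opening (`5k > 12`, i.e. `k ≥ 3`) — so the package
treats it as a property of the representation, not an error, and the
synthetic generator's default mode keeps planted point edits at least four
residues clear of event boundaries so that ground truth stays unambiguous.
An adversarial generator mode plants flush substitutions deliberately; the
tests assert that extraction then re-segments the edit but still
reconstructs the sequence byte-exactly.

### Whole-tail replacements

Events that replace everything from some position to the C-terminus with
an insert of two or more residues (`p.78_742delinsSST`, the soluble-form
67-residue tail, `p.23_742delinsGVGRRKS`, the 18-residue V7–19 ending) do
not survive naive global alignment as one block: within a replaced span of
hundreds of residues, a short insert almost always finds three or more
spurious consecutive matches, which is enough to split the gap run. These
endings are exactly the ones that do not align to the canonical tail in
the first place, so `classify_isoform` handles them the way the corpus
does: when a query ends with such an event's insert, the remaining prefix
is aligned against the canonical truncated at the event start, and the
decomposition is kept only if re-applying it reproduces the query
byte-exactly; otherwise the plain global alignment is used. Novel
(uncatalogued) whole-tail replacements fall back to the plain path and may
extract as more than one block — a known limitation.

## Event matching and grouping

A descriptor matches a catalogue event only when its `(start, end, insert)`
triple equals the entry exactly, after both sides are put in the same
normalization mode. Fuzzy matching is deliberately absent: the microexon
events (partial exon 5, `p.192_223delinsA`; partial V3, the 266–273
deletion) differ from full-exon events only in their boundaries, so a
tolerant matcher would erase precisely the distinction that motivates the
catalogue. Boundaries off by at most two residues raise a warning instead.
Unmatched delins descriptors replacing at least 8 residues are reported as
*novel* events — 8 is the size of the smallest catalogued non-point event,
which sets the scale separating putative unannotated splicing from noise.
Everything else is a residual variant.

Isoforms are grouped by `group_key`, a pure function of matched and novel
events: entries sharing a splice pattern form one group regardless of
residual point variants. This mirrors how the corpus itself is organised —
the full-length pattern, for instance, holds the canonical alongside
743- and 741-residue entries that differ from it only by `p.345_346insA`
or an alanine deletion. Novel events enter the key so unknown splice
patterns found their own groups rather than polluting residual columns.
Records flagged `partial` are excluded from grouping and reported
separately, never silently classified.

The deposited corpus lists some 37 exon-composition groups across both
databases; verifying that count requires the full isoform listings
(including appendix-only entries), which are not shipped here. The package
verifies the grouping logic itself on reconstructed and synthetic corpora
instead.

## The C-terminus

The canonical cytoplasmic long tail occupies positions 675–742 and begins
after the `…RRR` motif at the end of the transmembrane-adjacent segment.
Four classes are assigned:

* **long** — no event-scale edit touches 675–742 (point variants inside
  the tail, such as `p.S697I`, do not change the class);
* **short** — the catalogued replacement of 675–742 by a single serine,
  producing the `…RRS` short-tail ending;
* **alternative** — the sequence ends in a novel suffix: one of the known
  alternative endings (shipped as a catalogue) or an unalignable
  replacement, which is returned as the `c_terminal_segment`;
* **truncated** — the sequence simply stops early with no novel residues.

Because the corpus distinguishes short from long tails only at the protein
level (the differentiating exon carries no coding sequence), the class is
decided purely from the protein ending; transcript-level disambiguation is
impossible at this layer. One catalogued row (the soluble form) prints a
deposited length inconsistent with its own descriptor arithmetic by five
residues; the catalogue stores the row as deposited and flags the
discrepancy in its `source_note` rather than resolving it.

## Partials and coverage

A record is flagged `partial` when its length covers less than 95% of the
span expected after accounting for its matched and novel events. The 0.95
default separates the two populations cleanly in the emulated corpus:
genuine deposits within a splice form differ by single residues (coverage
≈ 0.999), while truncated deposits lose at least several percent of the
protein. A second flag, `low-coverage`, marks sequences whose aligned
fraction is below 0.5 — significantly divergent records that should be
inspected one-to-one rather than trusted in bulk.

## The splice-site scanner

Microexon variants imply that an alternative splice acceptor (intron-final
`AG`) or donor (intron-initial `GT`) competes with the annotated site
inside the exon body. The scanner implements only the minimal dinucleotide
rule — every internal `AG` immediately 5' of a candidate new exon start,
every internal `GT` immediately 3' of a candidate new exon end — with
explicit phase bookkeeping: a candidate is *consistent* only when the
trimmed nucleotides divide into whole codons matching the protein-level
trim; fractional-codon candidates are reported as *phase-shift*, never
silently dropped. No position-weight matrices or MaxEnt scores are
computed: the biological claim such a scan can support is the bare
existence of a competing site, and anything stronger needs experimental
confirmation. Coordinates are local to the supplied fragment; the flanking
intron context defaults to 20 nt (an assumption, configurable), and at
least 2 nt are required so the canonical boundary dinucleotides are
visible. Candidates never fall inside the flank.

## The synthetic generator

`generate_isoform_set()` emulates the structure of the deposited corpus:
isoforms carrying catalogued event combinations (the default pattern list
mirrors the recognised combinations, including double-event forms such as
standard + short tail and microexon + V6), point substitutions at
5 × 10⁻³ per residue and single-residue indels at 10⁻³ per residue
(matching the "one or two benign changes per entry" character of real
deposits), byte-identical duplicates under second accessions (5%), and
C-terminally truncated partials (5%, retaining 30–90% of the protein).
Indels are planted only where they are their own 3'-normal form, inserted
residues differ from both flanks, and point edits keep four residues clear
of event boundaries and of each other — so the planted truth is exactly
recoverable, which is what makes 100%-recovery assertions meaningful.
Two stress modes relax this deliberately (`adversarial` plants flush
boundary substitutions; `repeat_stress` allows repeat-context insertions).

What the generator does **not** emulate: sequencing-error compositional
bias, N-terminal truncation (off by default), correlated variants,
nucleotide-level splicing, and novel uncatalogued splice events. Passing
the recovery suites therefore demonstrates correctness of the
representation and matching machinery under corpus-like conditions, not
robustness to arbitrary real-world artefacts.

`generate_genomic_fixture()` builds exon bodies free of `AG`/`GT` (so the
only candidates are planted ones), joined by intron stubs with canonical
`GT…AG` boundaries, and plants requested internal sites at exact offsets,
erroring when two requests collide.

## Numerical and testing choices

Problem sizes in the shipped test-suite were chosen to exercise every code
path at full scale while staying quick on one CPU: the alignment oracle
compares against exhaustive enumeration of all global alignments up to
length 5 and against an independently formulated memoized recursion up to
length 8 (1000 sampled pairs); the end-to-end recovery suite runs 500+
isoforms under the rates above; the splice scanner is checked against a
brute-force scan on 100 seeded 300-nt fixtures. All randomness is seeded;
generation is integer-RNG based and byte-deterministic across platforms.

Degenerate inputs are hard errors with context (empty sequences, residues
outside the 20 standard codes plus `X`, out-of-range or duplicate
catalogue rows, overlapping descriptors, reference mismatches); `U`, `B`,
and `Z` are rejected because the corpus contains none, and accepting them
silently would mask upstream problems.

## Limitations

* Exon boundaries are never inferred from protein data; the catalogue is
  the single source of event coordinates.
* Novel whole-tail replacements (not in the catalogue) may extract as
  multiple descriptors rather than one.
* The group count of the full deposited corpus cannot be verified without
  the complete listings; only grouping behaviour is tested.
* The scanner's dinucleotide rule deliberately over-reports: most internal
  `AG`/`GT` sites are not used by the spliceosome.
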