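---
title: "Designing stop-codon base-editing guides with sgstop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing stop-codon base-editing guides with sgstop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgstop)
```

## The problem

Cytosine base editors such as Target-AID (a catalytically dead SpCas9 fused
to a cytidine deaminase) convert C to T within a narrow window of the
protospacer without a double-strand break. In bacteria like
*Agrobacterium*, which lack non-homologous end joining and tolerate DSBs
poorly, this is the practical route to gene knockout: convert a codon into
a premature stop. Not every dCas9 binding site can do this — the editing
window must cover a cytosine whose conversion creates an in-frame stop.
`sgstop` automates that filter: enumerate every PAM-adjacent candidate
guide over an annotated CDS, keep exactly those that can install a
premature stop, annotate the predicted protein change and bystander edits,
screen off-targets against a genome, rank, and emit cloning-ready oligos.

## The model

Under the standard/bacterial genetic code, single-base C→T conversions can
create a stop codon from exactly four sense codons:

* `CAA → TAA`, `CAG → TAG`, `CGA → TGA` — the cytosine is on the coding
  strand, so a **plus-strand** guide (window over the C) works;
* `TGG → TGA/TAG/TAA` — tryptophan has no C on the coding strand, but its
  opposite-strand triplet `CCA` has two; a **minus-strand** guide edits
  them (read on the coding strand as G→A).

`build_stop_rule_table()` derives this set by exhaustive enumeration over
all 64 codons × all nonempty C-subsets, rather than hard-coding it; with a
different `editor_architecture()` conversion chemistry or genetic code the
same machinery derives the corresponding table. The filter itself
(`is_viable()`) is simulation-driven — it tries every mask of window
cytosines and checks the translated consequence — with the rule table used
as an independent cross-check in the test suite. Because edits in
different codons are independent, the per-codon subset search is exactly
equivalent to searching all masks.

A guide is **viable** when some nonempty subset of its editable window
positions creates a stop strictly before the native stop codon. Guides
whose only "stop" lands on the native stop codon are rejected as not
premature. Truncation is summarized as
`(nonsense_codon_number − 1) / (protein length)`, the fraction of residues
retained, so smaller is a more complete knockout.

## Parameters that matter

* **PAM** (`pam`, default `NGG`): IUPAC pattern matched immediately 3' of
  the protospacer; ambiguity letters in the *input sequence* never satisfy
  a PAM letter (conservative on draft assemblies).
* **Spacer length** (`spacer_length`, default 20 nt).
* **Editing window** (`window_start`–`window_end`, default 2–4): 1-based
  from the PAM-distal 5' end of the spacer, the dominant convention in the
  base-editing literature. Published Target-AID windows vary between
  roughly positions 2–4 and 2–6 depending on assay; 2–4 is the
  conservative core of the reported activity and is the default here. It
  is configurable and recorded in every report header, because widening
  the window can only add viable guides (a property the tests assert).
* **Genetic code** (`genetic_code_table`, default NCBI table 11,
  bacterial). Codon numbering is 1-based from the annotated start codon,
  matching knockout genotype labels such as `Q151*`.
* **Bystander policy**: viability requires only that *some* mask creates a
  stop. The reported representative edit is the **maximal mask** — every
  window cytosine converted — because deaminases edit promiscuously within
  the window; within the stop-gaining codon the largest stop-yielding
  subset is used. Bystander consequences (silent/missense) are listed, not
  used to disqualify; `require_clean = TRUE` additionally demands that the
  fully maximal edit still yields the stop with no missense bystander.
* **Off-targets** (`max_mismatch`, default 3): plain Hamming distance over
  the spacer with an exactly matching PAM, reported as `m0..m3` tallies.
  No CFD/MIT-style weighting is attempted — the contract is transparent
  and oracle-checkable, and the counts feed a lexicographic ranking
  (fewest hits beyond the guide's own site, then earliest stop, then
  highest external on-target score, then position).

## A worked example

```{r example}
fx <- generate_locus(synthetic_locus_spec(
  264, planted = list(c(151, "CAG")), decoys = 3, seed = 42))
design <- design_guides(fx$locus,
                        genome = setNames(locus_seq(fx$locus), "self"))
design$reports[, c("rank", "spacer", "strand", "protein_change",
                   "truncation_fraction", "m0", "m1")]
```

Every reported guide converts the planted codon-151 `CAG` to `TAG`
(`Q151*`), and scanning the locus itself yields each guide's own site as
the single 0-mismatch hit.

## The synthetic-locus generator

`generate_locus()` is first-class, tested code, not a stored fixture. It
emulates the situation the tool is used in — a bacterial CDS containing a
handful of knockout-amenable codons — while making the truth knowable:

* background codons are drawn only from codons that **no** C→T edit can
  turn into a stop, so planted sites are the only true positives;
* each planted codon gets a supporting PAM forced into place (sense codons
  a downstream `NGG` for a plus-strand guide; `TGG` an upstream `CC` so a
  minus-strand guide's window reaches an opposite-strand cytosine);
* decoy PAMs over non-amenable background exercise the rejection path;
* every attempt is validated (planted codons intact, start codon intact,
  terminal codon still a stop, no background codon amenable) and redrawn
  on failure, bounded and seed-reproducible. A PAM force is allowed to
  overlap the terminal stop codon, which is then permitted to be any of
  TAA/TAG/TGA — otherwise sites 6–7 codons before the stop would be
  geometrically impossible to plant.

What the generator does *not* emulate: real codon-usage bias, repeated or
low-complexity sequence, GC skew, and real off-target landscapes. Passing
the planted-recovery tests therefore demonstrates correctness of the
filter logic, not performance claims about any particular genome; the
off-target module is validated separately against a naive rescan oracle on
random 50-kb contigs.

## Numerical and design choices

* Coordinates are 0-based half-open internally; GFF3 (1-based inclusive)
  and BED (0-based half-open) convert at the export boundary only.
* Ordering of candidates, ranking tie-breaks, and export field order are
  all fully deterministic; two runs on the same inputs are byte-identical.
* CDS sanity problems (non-ATG start, internal stop, missing terminal
  stop) warn rather than fail, so GTG/TTG starts and partial annotations
  load; `strict = TRUE` upgrades them to errors.
* Multi-exon (joined) CDS annotations are rejected rather than silently
  spliced: this is a bacterial tool.
* Degenerate inputs: a locus with no PAM yields an empty candidate list,
  an empty result set exports a valid header-only report, and a guide
  paired with the wrong locus raises an integrity error rather than
  returning coordinates in the wrong frame.
* On-target efficiency scores are deliberately *not* computed: they join
  from an external TSV keyed by spacer sequence, since established scoring
  models are trained and computed elsewhere; unmatched spacers get an
  absent score and a warning.
* Cloning oligos are `arm + spacer + arm` (19-nt arms by default, 58-nt
  oligo for a 20-nt spacer); the shipped arms are labelled PLACEHOLDER
  because real arms are backbone-specific.

## Problem sizes used in validation

The test suite checks the filter against an exhaustive-mask brute-force
oracle on 200 random loci of 60–600 codons with 30-nt flanks, recovers
planted sites with sensitivity 1.0 and zero false positives over 50 seeded
fixtures, and validates the off-target scanner position-by-position on
random 50-kb contigs at 0–3 mismatches — sizes chosen so the whole suite
runs comfortably on a laptop while exercising every code path at realistic
bacterial-gene scale.

## Known limitations

* No per-position editing-efficiency weighting inside the window; all
  window cytosines are treated as editable.
* 3'-PAM architectures only (no Cas12a-style 5' PAMs).
* Off-target search is ungapped Hamming with exact-PAM (optionally NAG)
  matching; bulges and editing-window-aware off-target edit prediction are
  out of scope.
* Single-CDS, bacterial scope: no splicing, one locus per run.
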