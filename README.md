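# sgstop

Guide-RNA design for **cytosine base-editor gene knockout** in bacteria.

Cytosine base editors such as Target-AID (dCas9 fused to a cytidine
deaminase) convert C→T inside a small window of the protospacer without a
double-strand break — the practical route to gene knockout in organisms
like *Agrobacterium* that do not tolerate DSBs. Knockout works by turning
a codon into a premature stop, and under the bacterial genetic code only
four sense codons are amenable:

| codon | edit | result | guide strand |
|-------|------|--------|--------------|
| `CAA` | C→T  | `TAA`  | + (C on coding strand) |
| `CAG` | C→T  | `TAG`  | + |
| `CGA` | C→T  | `TGA`  | + |
| `TGG` | opposite-strand `CCA`, C→T (G→A on coding strand) | `TGA`/`TAG`/`TAA` | − |

`sgstop` enumerates every PAM-adjacent candidate guide over an annotated
coding sequence (both strands, flanks included), keeps exactly those whose
editing-window conversions can install an in-frame premature stop,
simulates the edit (protein-change label such as `Q151*`, truncation
fraction, bystander consequences), counts Hamming-distance off-target
sites in a genome FASTA, ranks the survivors, exports GFF3/BED/TSV
annotations, and assembles cloning-ready oligos for Golden-Gate insertion
into single-component editor backbones. The editable-codon set is not
hard-coded: it is derived by exhaustive enumeration from the configured
genetic code and conversion chemistry, so other editor architectures
(different PAM, window, or base conversion) are a constructor call away.

Intended users: microbial genome engineers designing knockout guides for
base-editing workflows, and anyone needing a transparent, testable stop
filter behind a plasmid-design GUI.

## Worked example

Design guides against a synthetic thymidylate-synthase-like locus with an
editable `CAG` at codon 151 (the generator plants the codon plus a
supporting PAM and records the ground truth):

```r
library(sgstop)

fx <- generate_locus(synthetic_locus_spec(
  264, planted = list(c(151, "CAG")), decoys = 3, seed = 42))
design <- design_guides(fx$locus,
                        genome = setNames(locus_seq(fx$locus), "self"))
#> 111 candidate guide(s) enumerated
#> 2 viable (premature-stop) guide(s)
#> off-target scan complete (2 spacers)
#> 2 guide(s) exported to report

design$reports[, c("rank", "spacer", "strand", "protein_change",
                   "truncation_fraction", "m0", "m1")]
#>   rank               spacer strand protein_change truncation_fraction m0 m1
#> 1    1 CGTCAGACCACTCACCCTTC      +          Q151*           0.5703422  1  0
#> 2    2 GTCAGACCACTCACCCTTCA      +          Q151*           0.5703422  1  0
```

Of 111 PAM-adjacent candidates, exactly two can convert codon 151 `CAG`
to `TAG` — both labeled `Q151*` (glutamine 151 to stop). The truncation
fraction 0.57 means the edit keeps 57% of the protein before the new
stop; `m0 = 1` is each guide's own site in the scanned sequence, with no
additional 0–3-mismatch matches. Reports export to standard formats and
feed oligo assembly:

```r
export_annotations(design$reports, fx$locus, "gff3", path = "guides.gff3")
make_cloning_oligo(design$reports[1, ])
#> "ACGTACGTACGTACGTACGCGTCAGACCACTCACCCTTCTACGATCGATCGATCGATC"  # 58 nt
```

(The default 19-nt arms are placeholders — substitute the
overhang-complementary arms of your BsaI-digested backbone.)

Input loci can also come from files: GenBank flat files, FASTA + GFF3, or
a bare in-frame FASTA CDS, via `load_locus()`; `run_pipeline()` wires
loading, design and export together, and `inst/scripts/sgstop-cli.R` is a
thin command-line wrapper with `design` / `enumerate` / `filter` /
`offtarget` / `fixture` subcommands.

See the vignette (`vignettes/guide-design-methods.Rmd`) for the model,
parameter defaults (editing window, bystander policy, off-target
contract) and the generator's scope.

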