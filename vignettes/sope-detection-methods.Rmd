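---
title: "Detecting sensory organ precursor enhancers and classifying achaete-scute genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sensory organ precursor enhancers and classifying achaete-scute genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sopescan)
```

## The biological problem

Genes of the achaete-scute family endow ectodermal cells with neural
potential. Within the family two functional classes exist in arthropods:
proneural *ASH* genes, expressed in broad proneural domains, and
precursor-specific *ase*-like genes, expressed only in sensory organ
precursors (SOPs) after lateral inhibition has singled them out.
Two independent kinds of sequence evidence separate the classes:

1. **Protein motifs.** ASH proteins carry a 16-residue C-terminal domain
   (reference `PDDEELLDYISWWQQQ`) that is poorly conserved in Ase
   proteins (50% identity or less), while Ase proteins carry a
   diagnostic five-residue motif, hydrophobic–Lys–polar–Glu–hydrophobic,
   absent from non-dipteran ASH proteins.
2. **A regulatory element.** The SOP enhancer (SOPE) — a cluster of
   binding sites for four factor classes (E boxes for bHLH proteins,
   α boxes for NF-κB/Dorsal-class factors, AT-rich β boxes of unknown
   function, and N boxes for the Hairy/Enhancer-of-split repressors) —
   sits in the UTR of *ase*-like transcripts but not of proneural *ASH*
   transcripts.

`sopescan` turns both lines of evidence into automated, testable
measurements: a double-stranded degenerate-consensus scanner, a
heterotypic cluster caller with ORF-relative localization, exact protein
motif measurements, logo/conservation statistics for pooled sites, and a
seeded synthetic-data generator that provides planted ground truth for
every stage.

## Box models

Each binding-site class is a `box_definition`, either a degenerate IUPAC
consensus or an AT-rich window rule:

| box | default | kind | strands |
|-----|---------------------------|------------------|---------|
| E   | `CANNTG`                  | IUPAC consensus  | both    |
| α   | `GGGWWWNCC`               | IUPAC consensus  | both    |
| β   | width 8, ≥ 0.85 AT        | AT-rich window   | strandless |
| N   | `CACNAG`                  | IUPAC consensus  | both    |

The E-box default is the canonical bHLH site; the pooled arthropod logo
`CAGCTG` is one of its instances. The N-box default is the canonical
Hairy/E(spl) repressor site. The α box is the most degenerate of the
four classes, with conservation limited to the central part of the
NF-κB site; we default to the NF-κB/Dorsal-class consensus `GGGWWWNCC`.
No β-box consensus is known, so β boxes are modelled as AT-rich windows.
All four definitions are configuration-overridable, because the exact
site alignments behind the published arrangements are not recoverable
from the text; the defaults are canonical literature consensus choices.

Matching uses a **subset rule**: a sequence letter matches a pattern
letter only if its base set is contained in the pattern letter's base
set. An `N` run in a draft genome therefore never produces hits (an
undetermined base is not evidence for a site); a policy flag
(`ambiguity = "wildcard"`) relaxes this to base-set intersection.
A locus whose matched site is its own reverse complement is reported
once, on the forward strand, so palindromic E boxes are not counted
twice. Overlapping hits of the same class at different offsets are all
reported: the cluster caller, not the scanner, decides relevance.

```{r}
scan_boxes("TTCAGCTGTTATATATATTGG", default_box_set())
```

## Cluster calling and localization

A SOPE candidate is a single-linkage chain of box hits: consecutive hits
(by start) stay in one chain while the gap from the chain's rightmost
end to the next hit is at most `gap_max`. Chains must contain at least
`min_boxes` hits of at least `min_types` distinct classes; a merged
AT-rich region counts as one box. The defaults —

* `gap_max` = 450 bp,
* `min_boxes` = 4,
* `min_types` = 3

— were chosen so that all five published arthropod SOPEs (5–13 boxes of
3–4 classes over 246–1,052 bp) pass while isolated hits do not.
Scanning is per-UTR by default (hits inside the ORF are excluded), with
a switch to scan the whole transcript.

Coordinates are 0-based half-open internally; all human-readable output
is 1-based or expressed as distances. Distances use the gap convention
(bases strictly between the element and the codon): a cluster
`[10, 156)` with an ORF starting at 300 is "144 bp upstream of the
start codon", and a cluster `[503, 749)` with an ORF ending at 500 lies
"between 3 bp and 249 bp downstream of the stop codon" — the published
phrasing for the fly and spider elements, which calibrates the
convention.

ORF inference (used when gene models supply no coordinates) takes the
longest forward-strand `ATG`…stop frame, ties broken toward the
smallest start; codons containing ambiguity codes are never accepted as
start or stop. Both routes — provided and inferred coordinates — are
exposed, since published UTR boundaries are not always stated to be
model-derived.

## Protein classification

`cterm_identity()` slides a 16-residue window over the final 40 residues
(ungapped — the domain is C-terminal, and an ungapped comparison makes
the identity fraction well defined over exactly 16 positions), keeping
the best window with ties resolved toward the C-terminus. Display
percentages truncate toward zero, so 10/16 prints as 62%, matching the
printed convention for this domain. `find_ase_motif()` reports every
window matching `[hydrophobic] K [polar] E [hydrophobic]`; the class
sets default to standard biochemical groupings (hydrophobic
A,V,L,I,M,F,W,Y,C; polar S,T,N,Q,Y,C,G,H — Y and C deliberately sit in
both) and are overridable, since the motif's class membership is named,
not defined, in the literature.

Classification: any Ase-motif hit ⇒ `ase`; otherwise C-terminal
identity ≥ 0.5 ⇒ `ASH` (the 0.5 default comes from the published "50%
identity or less" boundary for Ase proteins); otherwise
`indeterminate` — a degraded C-terminal domain alone does not establish
an *ase* orthologue. bHLH detection is deliberately **not** a criterion:
the bHLH domain identifies family members but does not separate the two
classes.

Gene-level integration treats a UTR SOPE as a second, independent
feature: protein `ase` or `indeterminate` + SOPE ⇒ `ase_like`;
`ASH` + SOPE ⇒ `ancestral_ASH_ase_like` (one gene carrying both
functions, the inferred ancestral state seen in myriapods);
`ASH` alone ⇒ `proneural_ASH`; `ase` alone ⇒ `ase_like`.

## Logos and flank conservation

Aligned box instances are tallied into a position frequency matrix
(sites containing ambiguity codes are excluded entirely rather than
fractionally counted, keeping tallies exact integers). Information
content per column is $2 - H$ bits. The small-sample correction
$e(n) = 3/(2 \ln 2\, n)$ is available but off by default: the pooled
arthropod site sets are tiny (5–17 sites) and the published logos'
correction status is unknown, so both variants are exposed.

The consensus rule is deterministic: a single base when its frequency is
≥ 0.75 and the column carries ≥ 1 bit, otherwise the minimal IUPAC code
covering all bases at frequency ≥ 0.25. The thresholds are this
package's choices (the published record contains only logo pictures);
they recover `CAGCTG` from pooled clean E boxes and degrade gracefully
to degenerate codes.

Whether nucleotides *flanking* the boxes are conserved is made
operational as a permutation test (the published claim of "no
significant conservation" names no test): the statistic is the mean
information content over flank columns; the null redistributes the
pooled flank letters uniformly over the flank positions. Under an
i.i.d. flank model all arrangements of the pool are exchangeable, so
the test is exact and its p-values are reproducible bit-for-bit given
`(alignment, n_perm, seed)`.

## The synthetic-data generator

The generator is first-class, tested code — it defines the conditions
under which every stage is validated:

* `random_dna(length, gc, seed)` — i.i.d. backgrounds; the default UTR
  composition is GC = 0.45, reflecting the AT-leaning UTRs of the
  species involved and deliberately exercising β-box false-positive
  behaviour.
* `synth_transcript()` — `[5' UTR][ORF][3' UTR]` with planted box
  instances at known offsets; the ORF contains no internal in-frame
  stops, and backgrounds in which the planted ORF is not the unique
  longest ORF are rejected (at most 100 redraws, then an error — a
  deterministic bound on work).
* `synth_protein()` — the C-terminal tail is `[filler × 24][16-mer]`,
  the 16-mer matching the reference at exactly *k* chosen positions and
  every mismatch/filler position set to arginine, which matches the
  reference nowhere and belongs to neither motif class. Every window the
  search examines then matches at ≤ *k* positions, so the measured
  identity equals *k*/16 exactly, by construction rather than by
  rejection. Motif presence/absence in the body is verified by scanning.
* `benchmark_recovery()` — plants one five-box, four-class cluster per
  transcript (concrete instances drawn uniformly from the consensus
  degeneracies, seeded), runs the full scan + call pipeline, and reports
  recall (a call must cover ≥ 90% of the planted span — coverage rather
  than Jaccard, because nearby background hits legitimately extend a
  called cluster under `gap_max` = 450), precision, and per-pattern
  background match counts against the analytic per-window probability.
* `simulate_arthropod_five()` — a five-gene bundle reproducing the published
  five-species configuration of box compositions, spans, UTR sides and
  protein classes, used for end-to-end determinism checks. Where the
  published record gives two conflicting spans for one species, the
  prose location is used and the discrepancy left alone; the pipeline
  always reports its own measured spans.

What the generator does **not** emulate: phylogenetic correlation among
sites, compositional heterogeneity along real UTRs (isochores, repeats),
enhancer turnover, and splicing. Passing recovery tests therefore shows
the machinery is correct on the stated model, not that the defaults are
optimal for any particular genome.

## Numerical and design choices

* Coordinates: 0-based half-open internally, 1-based inclusive in
  reports; distances use the gap convention calibrated above.
* Scanner ties/duplicates: hits are unique under (class, region,
  strand); palindromic double-strand matches collapse to one `+` hit.
* `cterm_identity` ties go to the most C-terminal window.
* Permutation p-values use the add-one estimator
  $(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_{perm})$, which never
  returns 0 and keeps the test valid.
* Stop codons are the standard three; non-standard genetic codes are
  out of scope.
* All randomness flows through explicit integer seeds; generators
  save and restore the caller's RNG state.

Problem sizes used by the test suite and the acceptance script — 200
random sequences (≤ 1 kb) for scanner–oracle equivalence, 100 transcripts
for planted recovery, the full 17 × 2 × 10 protein grid, and 500
simulated alignments at 199 permutations each for the type-I study
(199 suffices because the permutation test is exact; the 1000-permutation
default is used for single-alignment calls) — are the package's chosen
validation sizes and complete in well under a minute each on one CPU.

## Worked example

```{r}
bundle <- simulate_arthropod_five(seed = 1)
report <- run_pipeline(bundle$transcripts, bundle$proteins,
                       run_config(pairing = bundle$pairing,
                                  orf_table = bundle$orf_table, seed = 1))
report
report$genes[, c("protein_id", "protein_label", "cterm_percent",
                 "utr_side", "gene_label")]
```

The three motif-bearing proteins come out `ase_like`; the indeterminate
spider-like protein is rescued to `ase_like` by its 3' UTR SOPE; and the
centipede-like gene — an ASH protein whose transcript nevertheless
carries a 5' UTR SOPE — is flagged `ancestral_ASH_ase_like`, the
single-gene state from which the two classes are inferred to have
diverged.

## Known limitations

* The α- and β-box defaults stand in for unrecoverable published
  alignments; results for those classes depend on the configured
  consensus more than for E and N boxes.
* Cluster spans absorb nearby background hits by design; reported spans
  are therefore upper bounds on the planted/true element under
  permissive `gap_max`.
* No statistical enrichment score is attached to a called cluster; the
  caller is a deterministic rule, not a classifier with a false
  discovery rate.
* Only forward-strand, unspliced transcript coordinates are supported;
  genome-scale annotation and multi-exon models are out of scope.
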