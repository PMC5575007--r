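---
title: "Methods: exact (ARN)X motif scanning, seed search and architecture mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact (ARN)X motif scanning, seed search and architecture mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arnscan)
```

## The model

Hfq's distal face binds A-rich RNA in three-nucleotide registers.  We
formalise one register as an *ARN triplet*: position 1 must be `A`
(A-site), position 2 must be `A` or `G` (R-site), position 3 is free
(N-site — the base points away from the protein).  A 3-mer failing these
constraints is *non-functional* (NF).  The abasic residue `0` (a backbone
position with no base, used in probes that delete N-site bases) is
accepted at the N position only; at the A or R position it fails the
triplet, because those bases contact the protein.

An *(ARN)X motif match* is an exact combinatorial object, not a score: an
ordered tiling of ARN triplets, NF triplets and single-nucleotide gaps
that

* opens and closes on an ARN triplet,
* contains at least `n_arn_min` ARN triplets (default 4),
* contains at most `max_nf` NF triplets (default 2), no two abutting,
* contains at most `max_gaps` single gaps (default 2), no two abutting,
* spans at most `window_nt` nucleotides (default 20).

The defaults make the window exactly saturable, `4*3 + 2*3 + 2*1 = 20`,
which is asserted as a test invariant.  There are no p-values anywhere:
the screen is deliberately exact, and a shuffle-based background rate
(`shuffle_hit_rate()`) is offered as a *measurement*, not a test.

### Why "non-adjacent" means "not abutting"

The constraint on NF triplets and on gaps is stated as non-adjacency.  We
interpret it as *not directly abutting in sequence*: `NF·GAP·NF` is legal
(the gap restores a backbone spacer between the two weak registers),
`NF·NF` is not.  The constraint is on the offending elements themselves,
and a single-nucleotide spacer already breaks the run.  The same reading
applies to gaps.

### Matching by compiled pattern sets

`enumerate_layouts()` generates every distinct ordering of a given number
of ARN, NF and gap elements satisfying the rules above — the permutation
machinery that turns one pattern *definition* into a comprehensive pattern
*set*.  `find_matches()` compiles the union of all layouts consistent with
the active parameters (for the defaults: every layout with 4–6 ARN
triplets, 0–2 NF, 0–2 gaps fitting in 20 nt) and slides each layout over
the sequence with vectorised position tests.  Matches are reported
*maximally*: an interval is dropped if some valid match strictly contains
it, since merging makes sub-matches redundant.  Where several tilings
produce the same interval, the reported element breakdown prefers more ARN
triplets, then fewer gaps, then the lexicographically earliest element
string; the interval never depends on this tie-break.

The test suite validates the compiled-pattern route against an
*independent exhaustive DFS* that enumerates every legal tiling from every
ARN-opening position (set equality of maximal matches on 1,000 seeded
random sequences), and validates `enumerate_layouts()` counts against a
position-combination brute force for all element counts up to (6, 2, 2).

### Merging and the 20-nt window

The window bounds a *single match*, not a motif region.  Overlapping
matches (≥ 1 nt shared) merge into one region; book-ended matches do not
(cohort reports list several distinct regions per sequence, so proximity
alone cannot merge).  Long regions therefore arise only through merging:
on the OxyS oligonucleotide (nucleotides 57–86 of the full-length sRNA),
three maximal ≤ 20-nt matches merge into the single region 59–86, and no
match can open at 57 or 58 because `UC` cannot begin an ARN triplet.

```{r}
merge_matches(find_matches(printed_oligos()$oxyS_arn))
```

mRNA 5′ windows conventionally use a relaxed `n_arn_min = 3`: mRNA-side
(ARN)X regions are shorter and were historically located by inspection,
so the stricter sRNA default misses them.  This relaxation is a stand-in
for a visual criterion and is surfaced as an explicit parameter, never a
hidden default: the printed fhlA fusion oligonucleotide, for example,
contains *no* valid 4-triplet match (verified by exhaustive enumeration)
but exactly one merged region at the 3-triplet threshold.

## Coordinates

Everything is 1-based inclusive internally; only BED export converts to
0-based half-open.  Two conventions from the field are honoured exactly:

* **Offsets** — an excised oligonucleotide carries the native coordinate
  of its first residue (FASTA header token `offset=57`), so reports use
  full-length numbering.
* **No position 0** — mRNA windows number positions relative to the start
  codon, −1 abutting +1.  `to_native()` and `native_gap()` implement the
  coordinate walk; the spacing between regions at (−70, −55) and
  (−10, +5) is 44 nt, counted over the line `..., −11, ..., −54`.

## Seed regions

A minimal seed is 7 consecutive Watson–Crick pairs, or 6 pairs + a single
bulged nucleotide + 2 pairs.  Since duplex complementarity is symmetric
and neither the bulged strand nor the reading order is fixed by the
definition, `find_seeds()` searches the bulge on either strand and the
6+gap+2 layout in both orders; both choices are parameters, and the
output records which applied (`gap_strand`).  G:U wobble is off by
default — the definition says *complementary*, and wobble is a flag.

Perfect hits report the maximal duplex (a flag restores all minimal 7-bp
windows).  Bulged hits are assembled from two *maximal* complementary
runs on adjacent pairing diagonals separated by exactly one bulged
nucleotide; run-maximality guarantees the bulge genuinely cannot pair in
place, so no bulged hit is a redundant re-description of a perfect
duplex.  One consequence worth knowing: a homopolymeric duplex (poly(G)
against poly(C)) legitimately pairs in every register and yields one
maximal duplex per diagonal with ≥ 7 pairs.  The implementation is tested
for set equality against an exhaustive enumeration of interval pairs with
at most one bulge and explicit non-extension checks at all four segment
boundaries, on 200 seeded random pairs.

## Architecture mapping

Secondary structure is *consumed*, never computed: the package parses
dot-bracket strings from external folding engines and can emit
Vienna-style constraint strings (`x` over motif positions) so those
engines keep (ARN)X motifs unpaired.  `find_hairpins()` reports innermost
hairpins (a stacked helix whose enclosed region contains no brackets);
`motif_context()` classifies a region as *embraced* when a hairpin lies
entirely on each side — the arrangement shared by OxyS-like sRNAs — and
reports the fraction of unpaired region positions (threshold 0.9).

The 3′ poly(U) tail is operationalised as ≥ 4 consecutive U beginning
within the 3′-terminal 15 nt (both configurable; Rho-independent
terminator tails are not quantitatively defined in the literature, so
these are package choices).  The motif-to-tail distance counts the
nucleotides between region end and the first U of the terminal run; the
20–40 nt band observed for OxyS-like sRNAs is the generator's default
spacing, never a filter.  Likewise the ~60-nt spacing between the two
mRNA-side (ARN)X regions is treated as a configurable *candidate* band
(40–80 nt) in `bipartite_regions()` — it flags, it does not filter.

Conservation of a motif across homologs is summarised at the positions
the motif actually constrains: per A-site column the fraction of rows
carrying `A`, per R-site column the fraction carrying `A`/`G`, plus a
row-level *persistence* (fraction of rows satisfying every A/R constraint
in the region).  Rows fully gapped over the region leave the persistence
denominator; columns where all non-reference rows are gapped are flagged
rather than dropped.  The 0.8 "conserved" threshold is presentation only.

## The synthetic-data generator

The generator emulates exactly the statistical structure the analysis
assumes, with complete ground truth:

* `plant_motif()` — background of configurable composition (default
  A = 0.2; an A-depleted 0.1 option exists because A-rich background
  spawns spurious motifs — itself a reportable behaviour) with one
  embedded motif drawn from a `motif_spec()`: `A` at A-sites, `A` with
  probability 0.8 else `G` at R-sites (the A-preference seen in conserved
  motifs), free N-sites, rejection-sampled genuine NF triplets.  Planted
  motifs satisfy the refined pattern *by construction*, so exact matching
  recovers 100 % of them — asserted over 500 seeded plants.
* `make_srna()` — leader | stem-loop | motif | stem-loop | filler |
  poly(U), with the motif-end-to-tail spacing drawn uniformly from
  20–40 nt by default.  Stem arms avoid `A` (their complements therefore
  avoid 3′ U-runs) and the pre-tail filler avoids `U`, so the planted
  tail is the only qualifying U-run near the 3′ end and
  `polyU_distance()` returns the planted spacing exactly; seeds embedded
  in loops may contain any residues, so a U-rich seed placed very close
  to the 3′ end could in principle confound the tail call — the defaults
  keep loops well upstream.
* `shuffle_null()` — mononucleotide permutation, or an Eulerian-path
  (random-arborescence) dinucleotide shuffle preserving all 16
  dinucleotide counts and both terminal residues.
* `make_alignment()` — i.i.d. per-position substitutions with an optional
  reduced rate at protected motif sites, emulating purifying selection.

Every generator requires an explicit integer seed and restores the global
RNG state, so runs are reproducible and side-effect free.

What passing tests on this generator *do not* show: real sRNAs have
correlated composition, structured backgrounds and imperfect annotations;
the generator demonstrates correctness of the machinery, not cohort-level
biology.  Reproducing the published 67-sRNA screen requires the original
sequence set, which is not redistributed; given that FASTA, `scan_set()`
reproduces the cohort histogram directly, and sequence-source drift is
the expected cause of any count perturbation.

## Numerical and design choices

* Degenerate inputs: sequences shorter than `3 * n_arn_min` scan to an
  empty result (not an error); out-of-range layout placements are
  `FALSE`; empty region sets write header-only reports.
* Gaps are forbidden at layout boundaries in every ambiguity class (a
  boundary gap adds no binding content and would blur printed
  coordinates).
* Maximum gap count defaults to 2: the explorative pattern ladder uses
  one or two single gaps, and two is exactly what saturates the 20-nt
  window alongside four ARN and two NF elements.  It is a parameter.
* Merging requires ≥ 1 nt overlap; abutting regions stay separate.
* The problem sizes in the test suite (1,000 random sequences ≤ 40 nt for
  the motif oracle, 200 pairs ≤ 30 nt for the duplex oracle, 500 planted
  motifs, 100 planted architectures) were chosen to exercise every code
  path of the combinatorics at desk scale; the matchers themselves are
  exact, so larger random panels add coverage, not information.

## Limitations

* The scanner is exact by design: it cannot rank near-misses or quantify
  motif strength; a probabilistic model (PWM/HMM) is out of scope.
* Seed search is purely combinatorial — no thermodynamics, no
  accessibility; it finds candidate complementarity, not binding energy.
* Folding is delegated to external engines; the package only constrains
  and consumes their output.
* mRNA-side motif calling inherits the relaxed-threshold convention and
  should be read as "candidate region", mirroring the visual criterion it
  stands in for.
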