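# arnscan — scanning bacterial RNAs for Hfq distal-site (ARN)ₓ motifs

Bacterial small regulatory RNAs (sRNAs) and the 5′ regions of their target
mRNAs are matched up by the RNA chaperone Hfq, a homo-hexamer whose *distal*
face binds A-rich sequence in three-nucleotide registers.  Each register —
an **ARN triplet** — has an A-site that accepts only adenine, an R-site that
accepts either purine (adenine preferred), and an N-site whose base flips
away from the protein and is unconstrained.  Runs of such triplets,
**(ARN)ₓ motifs**, mark Hfq binding sites in sRNAs such as OxyS and in mRNA
5′ UTRs such as *fhlA*.

`arnscan` implements the combinatorial machinery for working with these
motifs, for RNA bioinformaticians who want the screen to be exact,
reproducible and testable rather than ad hoc:

* **Permuted pattern sets** (`enumerate_layouts()`, `pattern_set()`) —
  every ordering of ARN triplets, bounded "non-functional" (non-ARN)
  triplets and single-nucleotide gaps satisfying the layout rules
  (boundary triplets are ARN; NF triplets never abut; gaps never abut).
* **The refined motif scan** (`find_matches()`, `merge_matches()`,
  `scan_set()`) — a match is at least 4 ARN triplets within a 20-nt span,
  with at most 2 non-adjacent NF triplets and at most 2 separated gaps
  (defaults; all configurable).  Overlapping matches merge into motif
  regions; a cohort scan tabulates regions per sequence (0, 1, 2, 3, 4, 5+).
* **Seed complementarity search** (`find_seeds()`) — minimal sRNA–mRNA
  seed duplexes: 7 consecutive Watson–Crick pairs, or 6 pairs + a
  one-nucleotide bulge on either strand + 2 pairs; G:U wobble optional.
* **Architecture mapping** (`find_hairpins()`, `motif_context()`,
  `polyU_distance()`, `mrna_window()`, `bipartite_regions()`,
  `conservation_profile()`, `folding_constraints()`) — motif regions
  against hairpins from dot-bracket structures, 3′ poly(U) tails, mRNA 5′
  windows with UTR numbering (no position 0), alignment conservation, and
  Vienna-style constraint strings that keep motifs unpaired during folding.
* **Synthetic data with ground truth** (`plant_motif()`, `make_srna()`,
  `make_target_mrna()`, `shuffle_null()`, `make_alignment()`) — planted
  motifs, OxyS-like stem-loop|motif|stem-loop|poly(U) architectures,
  embedded seeds, dinucleotide-preserving shuffles and simulated homolog
  alignments, so every stage is verifiable offline.

Coordinates are 1-based inclusive throughout (BED export alone is 0-based
half-open), sequences use the alphabet `A C G U` plus `0` for an abasic
residue, and an `offset=<int>` FASTA header token lets an excised
oligonucleotide report matches in full-length numbering.

## Worked example

The classic worked example is the 30-nt oligonucleotide comprising
nucleotides 57–86 of the *E. coli* sRNA OxyS, which the package ships as a
built-in input:

```r
library(arnscan)

oligo <- printed_oligos()$oxyS_arn   # offset 57: full-length numbering
matches <- find_matches(oligo)
as.data.frame(matches)[, c("start", "end", "n_arn", "elements")]
#>   start end n_arn                  elements
#> 1    59  76     4     ARN|NF|ARN|ARN|NF|ARN
#> 2    65  80     4    ARN|ARN|GAP|ARN|NF|ARN
#> 3    68  86     4 ARN|GAP|ARN|NF|ARN|NF|ARN

merge_matches(matches)[, c("seq_id", "start", "end", "n_matches")]
#>     seq_id start end n_matches
#> 1 oxyS_arn    59  86         3
```

Three maximal ≤20-nt matches tile the A-rich core of the oligo; because
they overlap they merge into the single motif region 59–86 — the region a
cohort report lists for OxyS.  The motif cannot open before 59: the two
residues 5′ of it (UC) cannot begin an ARN triplet.  A small cohort scan:

```r
scan <- scan_set(list(printed_oligos()$A20,
                      rna_seq("c20", strrep("C", 20)),
                      oligo))
scan
#> <arn_scan> 3 sequences, 2 merged (ARN)X regions
#> regions per sequence:
#>  0  1  2  3  4 5+
#>  1  2  0  0  0  0
```

Poly(A)₂₀ carries one full-length region (any reading frame of poly(A) is
an ARN triplet), poly(C)₂₀ none (no A-site anywhere).

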