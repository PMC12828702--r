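---
title: "Designing, simulating and QC-ing Golden Gate gRNA arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing, simulating and QC-ing Golden Gate gRNA arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guidearray)
```

`guidearray` models one specific multiplexed-CRISPR construction strategy:
every guide RNA (gRNA) expression unit is produced by polymerase cycling
assembly (PCA) from a double-stranded U6 promoter fragment, one single-stranded
59-nt spacer oligo, and a double-stranded scaffold-terminator fragment; a
position-specific primer pair then equips the unit with a type IIS (BsaI)
recognition site and a 4-bp junction overhang at each end, so that one-pot
Golden Gate digestion/ligation assembles the units into the destination vector
in a fixed order. This vignette explains the models behind each stage, the
parameters that matter, and the choices made where the design space was
genuinely open.

## The sequence model

A unit's PCA product is laid out as

```
[pad][GGTCTC][N][left overhang][U6 promoter][spacer][scaffold][right overhang][N'][GAGACC][pad']
```

BsaI is modelled generically as a type IIS descriptor (recognition `GGTCTC`,
1-nt cut spacer, 4-nt 5′ overhang; see `bsai()` and `type2s_enzyme()` for
other enzymes). Digestion removes the primer tails and exposes the two
overhangs; ligation joins fragments that share a junction overhang, each
junction counted once. With the packaged default fixtures the PCA product is
433 bp, the digested fragment 415 bp, and a *k*-unit insert is `411·k + 4` bp
(4114 bp for ten units, the familiar ~4 kb excised-array band). All internal
coordinates are 0-based half-open; overhangs are always written as top-strand
5′→3′; the GenBank writer converts to that format's 1-based inclusive
convention.

Two conventions are worth making explicit:

* **Primer-tail regions include the annealing footprint.** Mutations are
  classified as *deleterious* only inside the parts of the promoter, spacer
  and scaffold that no primer covers; anything under a primer footprint
  (5′ tail, overhang, or annealing region) is *inconsequential*, because those
  bases only serve unit amplification and are resynthesised every cycle. The
  unit region map therefore tiles each unit as
  `primer_tail_left | u6_promoter | spacer | scaffold | primer_tail_right`,
  with each internal junction overhang assigned to the downstream unit's left
  tail.
* **Homology arm split.** The spacer oligo totals 59 nt: a 20-nt arm matching
  the promoter's 3′ end, the 20-nt spacer, and a 19-nt arm matching the
  scaffold's 5′ start. Only the total is externally constrained; the
  near-symmetric 20/19 split is this package's default and both arms are
  configurable (`up_arm_len`, `down_arm_len`, minimum 12 nt for reliable
  annealing).

## Junction overhangs

Assembly order is enforced entirely by the overhang set, so
`select_overhang_set()` enforces the properties that make a Golden Gate
junction set high-fidelity: pairwise distinct 4-mers, no palindromes (a
self-complementary overhang ligates to itself), no cross-complementary pairs
(which would scramble order), GC content between 1 and 3 of 4 bases, and a
minimum pairwise Hamming distance of 2 to suppress single-mismatch ligation.
Selection is a greedy scan over a fixed candidate ordering (a maximal
Hamming-distance-2 code first), so results are deterministic. Empirical
ligation-fidelity matrices are deliberately out of scope; the constraint set
reproduces the guarantees such tools aim for without proprietary data.

Capacity under the default constraints is 48 overhangs, comfortably covering
the default 20-unit maximum (21 junctions). The hard ceiling of 52 units
(53 junctions) is reachable only with `min_hamming = 1`; requests beyond the
default capacity fail with the violated constraint named, and designs above
20 units warn that assembly efficiency is expected to degrade.

## Synthetic fixtures

Real workflows load the promoter, scaffold and vector flanks from FASTA
(`read_fixtures()`). For self-contained design and testing the package ships
a synthetic stand-in set (`default_fixtures()`, regenerable with
`make_fixtures()`): random sequences sized so the default PCA unit is exactly
433 bp (265-nt promoter stand-in, 122-nt scaffold stand-in, 200-nt flanks),
rejection-sampled until (a) no sequence contains a recognition site on either
strand and (b) no junction or primer-tail context can form one with *any*
candidate overhang. These stand-ins reproduce the lengths, layout and
enzyme-safety properties of the real sequences — not their biology; passing
tests on them demonstrates the design arithmetic and the QC pipeline, not
promoter activity.

## The assembly simulator

The simulator is the package's test bed and calibration tool
(`sim_params()`):

* **Truncation.** Ligation is modelled as failing independently at each of
  the `k − 1` internal junctions with probability `q`
  (`junction_failure_prob`), truncating the molecule at the first failure, so
  the full-length fraction is `(1 − q)^(k−1)`. The outcome distribution is
  what is observable; per-junction independence is the simplest mechanism
  consistent with it, and an explicit unit-count distribution
  (`unit_count_probs`) is available when an exact histogram must be planted.
* **Mutations.** At most one deleterious and one primer-tail mutation per
  unit per molecule, placed uniformly within the region class, substitution
  vs 1-nt indel controlled by `sub_indel_ratio`. This matches the per-unit
  binary statistic the QC reports ("one or more deleterious mutation").
* **Reads.** Whole-plasmid reads are the molecule wrapped in the vector
  flanks, with uniform per-base errors (`read_error_rate`), optional
  reverse-complementing, and optional flank loss (`incomplete_prob`)
  emulating incomplete plasmid reads. No homopolymer-aware nanopore error
  model is attempted — uniform errors suffice to stress the approximate
  matching — and FASTQ qualities are a constant Phred score consistent with
  the error rate, since the pipeline ignores them. Whether reads stand for
  raw reads or per-clone consensus is a matter of the error rate chosen
  (2% vs 0).

Every stage is fully determined by `seed`; molecule and read generation use
distinct sub-streams derived from it.

## The QC pipeline

* **Extraction** (`extract_inserts()`): each read is searched on both strands
  for the upstream then the downstream backbone flank; each flank must match
  within `max_error_rate` (default 0.2) of its length in edits. Defaults use
  30-nt flanks — tolerant of nanopore error rates while keeping spurious
  localisation negligible (an unrelated 30-mer at ≤ 6 edits is vanishingly
  unlikely). Reads lacking either flank are discarded and counted, mirroring
  how incomplete plasmid reads are handled in practice; inserts are reported
  in design orientation with per-flank error counts.
* **Binning** (`bin_by_length()`): an insert joins the unit count whose
  expected length is nearest, provided the residual is under half the
  per-unit increment (205 bp by default); anything else is reported
  `unbinned` rather than forced into a bin.
* **Mutation profiling** (`profile_mutations()`): global alignment against
  the expected array (match +1, mismatch −1, gap open −2, gap extend −1 —
  conventional edit-distance-like scores, configurable via
  `alignment_scoring()`), each non-match column becoming a call located in
  the region map, with adjacent gap columns merged into a single indel call.
  Inserts under 80% alignment identity are flagged unalignable and excluded
  from the statistics rather than contributing nonsense calls.
* **Spacer mapping** (`map_spacers()`): each full-length insert's spacer
  windows are projected through the alignment and compared to every pool
  member by normalised edit-distance similarity; assignment requires a unique
  best member at ≥ 0.8 similarity, and exact ties are always `unassigned`,
  never broken arbitrarily. Column sums of the resulting position × member
  matrix equal the number of full-length inserts by construction.

## Planning statistics

`picking_probability()` evaluates the chain
`p(G) = 1 − p(M)`, `p(A) = p(G)^k`, `p(C) = p(A)·p(F)`,
`p(U) = 1 − (1 − p(C))^n`, assuming units mutate independently (they are
synthesised in separate PCAs) and colonies are independent transformants.
`estimate_proportions()` turns QC outputs into point estimates with Wilson
score intervals — chosen over the normal approximation for sane behaviour at
small counts and proportions near 0 or 1, and cross-checked in the tests
against an independent implementation. `library_diversity()` multiplies pool
sizes in exact schoolbook big-integer arithmetic, so counts like 10^10 (ten
pools of ten) or beyond double precision are exact digit strings.

## Verification scale and limitations

The test-suite simulations use problem sizes chosen to make the statistical
checks sharp at desk scale: truncation calibration at 10,000 molecules
(3 binomial standard errors), library uniformity at 20,000 molecules
(chi-square at α = 0.001 per position), full-length recovery at 3 × 1000
read pools, and mutation-rate recovery at 28 clones × 10 units (the 99%
binomial interval for 280 trials), each under fixed seeds.

Known limitations: no thermodynamic primer optimisation (annealing regions
are fixed-length fixture substrings, as in the underlying protocol); no
empirical ligation-fidelity scoring; no model of recombination between the
repetitive units in bacteria or during lentiviral delivery; and uniform read
errors rather than a sequencer-specific error profile. Passing the simulator
round-trips therefore demonstrates correctness of the design arithmetic and
the QC logic, not performance on any particular sequencing chemistry.
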