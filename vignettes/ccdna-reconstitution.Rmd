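---
title: "Reconstituted promoters and ORFs in concatemeric cDNA: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstituted promoters and ORFs in concatemeric cDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoscan)
```

## The system

DRT2-type phage-defence systems pair a reverse transcriptase (RT) with a
~280-nt non-coding RNA (ncRNA). Upon infection the RT rolls over a ~120-nt
central *template region* of the ncRNA, producing a concatemeric cDNA
(ccDNA) of tandem template repeats. Two features only exist on the
*concatemer*, never in the genome or in a single repeat:

* **A sigma-70 promoter.** Within one repeat the -10 (TATAAT) and -35
  (TTGACA) hexamers sit out of order, separated by a 91-bp gap. Adjacent
  repeats juxtapose the -10 of one repeat with the -35 of the next at
  exactly 17 bp — the consensus spacer. For a repeat of length $L$ with
  in-repeat gap $g$ and 6-bp motifs, the junction spacer is $L - g - 12$;
  with $L = 120$ and $g = 91$ that is 17, independent of where the repeat
  boundary is drawn.
* **A junction-spanning, stop-free ORF.** Repeat lengths divisible by three
  preserve reading frame across junctions; a frameshifting length would
  place a stop codon within two repeats with near certainty.

`neoscan` implements (i) reconstruction of theoretical ccDNA from ncRNA
sequences and detection of these reconstituted features, (ii) exact k-mer
segmentation of long sequencing reads with template-jump quantification,
and (iii) a mechanistic simulator of rolling reverse transcription that
provides ground truth for every analysis.

## Locus geometry and the unique reading frame

The synthetic locus generator (`make_locus()`) embeds, in ccDNA repeat
coordinates (repeat = reverse complement of the template):

| element | position | note |
|---|---|---|
| junction `TA` | 1–2 | with the repeat-terminal `TGT` forms the `TGTTA` junction |
| `GATAT` | 3–7 | reverse complement of the primer-binding site (ncRNA 142–146) |
| `TATAAT` (-10) | 13–18 | |
| `GAG` (RBS) | 24–26 | |
| `ATG` (start) | 32–34 | 13 nt downstream of the -10 end |
| `GAATC` (HinfI) | 40–44 | exactly one GANTC per repeat |
| `TTGACA` (-35) | $L-10$ – $L-5$ | junction spacer 17 for any $L$ |
| `TGT` | $L-2$ – $L$ | reverse complement of the leading `ACA` bracket |

On the ncRNA, the template occupies bases 29 to $28 + L$, beginning with
the first `ACA` bracket and followed immediately by the second; the PBS
(bases $22+L$ to $26+L$) reverse-complements to the `GATAT` primer that is
covalently attached after the final ncRNA base.

These constraints pin the reading frame. With `TAGATAT` forced at repeat
positions 1–7 and the promoter hexamers at 13–18 and $L-10$ – $L-5$,
codons starting at positions $\equiv 2 \pmod 3$ are the only frame in
which no fixed element contains a stop (frames 0 and 2 hit `TAG` and `TAA`
inside fixed sequence). The generator therefore fills all free positions
with sense codons in that cyclic frame, drawing each partially constrained
codon uniformly from the sense codons compatible with its fixed bases.
Candidate loci are resampled until: each motif and the GANTC site occur
exactly once per repeat; no decoy `ACA` falls inside the bracket-search
band; every 11-mer across both strands is unique; and the chimeric
junction windows behave as described in the next section.

## Jump detection and junction micro-homology

Reads are segmented into all overlapping k-mers (default $k = 11$, the
minimum unique length for a 280-nt ncRNA), each assigned the ncRNA
position of its first base and a strand (minus = antisense, the
orientation of first-strand cDNA). A *jump* is a non-adjacent mapping of
adjacent windows; jump coordinates follow the jump-map convention (from:
3' base of the 5' window; to: 5' base of the 3' window). Categories follow
the strand pair: 1 minus→minus (tandem repeats), 2 minus→plus (reversal
into second-strand synthesis), 3 plus→plus (second-strand repeats), 4
plus→minus (read-through from the primer into the ncRNA 3' domain).

A geometric subtlety: because the template begins with the `ACA` bracket
and the second bracket follows the template end directly, the first three
bases written after a tandem jump (`TGT`) are *identical* to the reverse
complement of the second bracket. Windows therefore map straight through a
junction, three bases into the bracket — the same alignment-region logic
by which telomerase repositions its template. A naive detector reports the
canonical tandem jump as 29→151 rather than the mechanistic 29→148. Since
the breakpoint is genuinely unidentifiable inside the voided window run
(homology extends runs by up to $k-1$; sequencing errors truncate them by
up to the void length), `quantify_jumps()` snaps each endpoint of a
same-strand jump to its template boundary whenever the extrapolated
diagonal reaches the boundary within that slack. Strand-change jumps
(categories 2 and 4) are never snapped, so the reversal (31→34) and
read-through (146→280) coordinates are reported exactly; the locus
generator verifies that those junctions carry no accidental homology.

Two related defaults:

* `diagonal_tolerance` — 0 for error-free analysis; about 3 for
  error-bearing reads (small same-strand slips from indels are not jumps).
* `max_skip = 3k` — a junction voids $k-1-3$ windows and each nearby error
  up to $k$ more, so bridging must tolerate a junction flanked by two
  clustered errors; at $2k$ such reads split and true jumps are lost
  (measured recall 0.89 versus 0.965 at $3k$, precision 0.978, on 1,500
  simulated reads at substitution/insertion/deletion rates
  0.02/0.01/0.01).

## The simulator

`simulate_synthesis()` writes each molecule 5'→3' as the RT would:
`GATAT` primer, template copied from base 141 down to 29, then per
junction a Category-1 jump back to base 148. Repeat counts follow a
zero-truncated geometric law parameterised by its mean (default 5, the
modal count reported for in vivo ccDNA; the law's own mode is 1 and the
very long observed tail — beyond 100 repeats — is not modelled). Reversal
is evaluated once per molecule at the terminal junction (default
probability 0.4), absorbing the per-junction hazard into the repeat-count
law; on reversal the final minus repeat stops at base 31, the RT turns
onto its own nascent strand (Category 2, resuming at plus base 34) and
copies back, producing $y$ plus-strand repeats with $y$ drawn uniformly on
$1..x$ — so $y \le x$ holds mechanically, not by filtering. If the second
strand reaches the primer ($y = x$), read-through into the ncRNA 3' domain
(Category 4) occurs with probability 0.5. Under this model the expected
per-molecule category counts are closed-form: $E[c_1] = m - 1$,
$E[c_2] = r$, $E[c_3] = r\,(m-1)/2$, $E[c_4] = r\,q\,E[1/x]$ (mean $m$,
reversal $r$, read-through $q$), which the test suite checks against
10,000 simulated molecules.

`sequence_reads()` applies independent per-base substitution, insertion
and deletion (defaults 0.02/0.01/0.01, Nanopore-like), logs every error
position, and uses constant placeholder qualities; there is no
homopolymer-specific error model. `simulate_shortreads()` emulates the two
short-read protocols at the level the analyses need: random fragments with
strand labels, an untreated variant that can only sample single-stranded
(reversal-free) molecules, an S1-style variant that opens hairpins so both
strand blocks are sampled, and a configurable count of spike-control reads
for normalisation (`normalized = raw / (spike × volume)`).

The ortholog family generator (`make_family()`) derives members from a
reference locus by resizing a three-codon variable zone (template lengths
111/117/120/129 with weights 0.1/0.6/0.2/0.1, matching the reported
length distribution with 117 modal), swapping free template codons with
probability 0.3 and scaffold bases with probability 0.05. Fixed elements
are never mutated, so conservation profiles dip across the template's
free codons while the brackets, promoter motifs and scaffold stay high —
the qualitative structure the conservation analysis assumes. The
alignment is emitted by construction (gap padding at the variable zone),
not recomputed by an aligner.

## Numerical choices and edge cases

* **Coordinates** are 1-based inclusive at every interface.
* **Conservation** is $2 - H$ bits per column over A/C/G/T frequencies;
  gaps are excluded from the frequencies and columns with more than 50%
  gaps are reported missing, keeping the 2-bit ceiling interpretable. The
  smoothed track is a centred moving average (default window 10) with
  shrinking windows at the edges.
* **Promoter matching** is exact consensus by default (`max_mismatch = 0`),
  configurable; spacer range 15–19 bp.
* **ACA-bracket extraction** takes the nearest `ACA` at or left of an
  approximate start, then the nearest downstream `ACA` whose implied
  template length falls in a band (default 90–150 nt, covering the
  observed 111–129).
* **"13 nt downstream of the -10"** is read as a 13-nt gap between the
  motif end and the reported window, which in the reference geometry puts
  the start codon at repeat position 32 and the `GAG` RBS between the
  -10 and the start; both are reported, since the anchor of the printed
  offset is ambiguous.
* **Digest** cuts `cut_offset` bases into each IUPAC site occurrence
  (G^ANTC by default); fragment lengths always sum to the input length. A
  single-repeat hairpin does *not* release a repeat-length fragment (its
  two sites are mirror-symmetric about the loop), so digest claims are
  assessed on molecules of three or more repeats.
* **Layout ties** between equal longest runs go to the leftmost run.
* **Ambiguous k-mers** are excluded from mapping rather than placed
  randomly; segmentation reports them as unmapped.

## Problem sizes

The shipped tests run the full pipeline (simulate → segment → quantify →
classify) on 300 zero-error reads for exact truth equivalence, 1,500
error-bearing reads for the recall/precision bound, and 10,000 truth-level
molecules (no sequencing step) for distributional checks; these sizes give
stable statistics at interactive runtimes.

## Limitations

The simulator does not model per-base reversal within a repeat, kinetic or
nucleotide-dependence of the RT, the heavy tail of in vivo repeat counts,
or sequence-dependent (homopolymer) sequencing error. Promoter detection
is consensus matching, not a strength model; no thermodynamics or PWM
scoring is attempted. Passing tests demonstrate recovery of the simulator's
statistical structure, not performance on real Nanopore data, whose error
and length distributions are richer.
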