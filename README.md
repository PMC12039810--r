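# neoscan

Analysis of concatemeric cDNA (ccDNA) produced by rolling reverse
transcription of a non-coding RNA, as in DRT2-type bacterial phage-defence
systems, for researchers studying RT-based defence, tandem-repeat DNA
synthesis, or template jumping in long reads.

Upon phage infection, the DRT2 reverse transcriptase repeatedly copies a
~120-nt template region of its ~280-nt ncRNA into tandem repeats. The
repeats reconstitute two features that exist only on the concatemer:

* a **sigma-70 promoter** — within one repeat the -10 (`TATAAT`) and -35
  (`TTGACA`) hexamers are out of order with a 91-bp gap, but adjacent
  repeats juxtapose the -10 of one repeat with the -35 of the next at the
  consensus 17-bp spacing (for repeat length *L* and in-repeat gap *g*,
  the junction spacer is *L − g − 12*; 120 − 91 − 12 = 17);
* a **junction-spanning, stop-free ORF** (a "nearly endless" ORF) — repeat
  lengths divisible by three preserve frame across junctions, and the
  encoded repetitive protein is strongly hydrophobic and toxic.

The package provides three layers:

1. **reconstitute** — extract the ACA-bracketed template from an ncRNA,
   build theoretical ccDNA (`concatemerize()`), scan promoters
   (`scan_promoters()`), reading frames (`scan_orfs()`), RBS/start codons
   (`locate_rbs()`), restriction digests (`digest_sequence()`),
   alignment conservation in bits (`conservation_profile()`), randomized
   repeat nulls over the 61 sense codons (`random_repeat()`) and protein
   hydropathy (`protein_properties()`);
2. **jumpmap** — exact 11-mer segmentation of long reads against the ncRNA
   (`kmer_index()`, `segment_read()`), template-jump quantification and
   four-way mechanistic classification (`quantify_jumps()`,
   `classify_jumps()`, `jump_map()`), per-read repeat structure including
   hairpin (x, y) counts (`read_structure()`), 3'-extension consensus
   (`detect_3prime_extension()`), chimeric-read layouts and spike-in
   normalisation;
3. **synthetic data** — a mechanistic simulator of rolling reverse
   transcription with per-molecule ground truth (`make_locus()`,
   `make_family()`, `simulate_synthesis()`, `sequence_reads()`,
   `simulate_shortreads()`).

## Worked example

```r
library(neoscan)

locus <- make_locus(seed = 42)          # synthetic locus, reference geometry
locus
#> <ncrna_locus> synthetic_locus: 280 nt, template 29-148 (120 nt), PBS 142-146, primer GATAT

tpl <- extract_template(locus, "aca_motif")   # template between the ACA brackets
cc  <- concatemerize(tpl$template, 2)         # two-repeat theoretical ccDNA
scan_promoters(cc)
#>   minus35_start minus35_end minus10_start minus10_end spacer_bp spans_junction arrangement
#> 1           110         115           133         138        17           TRUE   canonical
```

One canonical promoter: the -35 from repeat 1 (110–115) pairs with the -10
from repeat 2 (133–138) across the junction with a 17-bp spacer. A single
repeat instead reports the out-of-order arrangement with its 91-bp gap.

```r
scan_orfs(cc)[, c("frame", "start_position", "n_stops", "stop_free", "spans_junction")]
#>   frame start_position n_stops stop_free spans_junction
#> 1     0             NA       4     FALSE          FALSE
#> 2     1             32       0      TRUE           TRUE
#> 3     2             69      12     FALSE          FALSE
```

Exactly one reading frame is stop-free and spans the junction; its start
codon sits 13 nt downstream of the -10 motif. An in-silico HinfI digest of
a four-repeat concatemer releases the repeat unit:

```r
digest_sequence(concatemerize(tpl$template, 4)$sequence)
#> [1]  40 120 120 120  80
```

Jump analysis of a simulated molecule recovers the simulator's ground
truth — here a three-repeat molecule with two tandem (Category 1) jumps
from minus-strand base 29 back to base 148:

```r
sim <- simulate_synthesis(sim_config(locus, n_reads = 500, seed = 43))
asn <- segment_read(sim$molecules[[1]], kmer_index(locus), read_id = "mol_00001")
classify_jumps(quantify_jumps(asn, template_interval = c(29, 148)))$jumps
#>     read_id from_position from_strand to_position to_strand category
#> 1 mol_00001            29       minus         148     minus        1
#> 2 mol_00001            29       minus         148     minus        1
```

See the vignette (`vignettes/ccdna-reconstitution.Rmd`) for the models,
the junction micro-homology handling, and every tunable default.

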