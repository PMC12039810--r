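test_that("3' extension consensus recovers the GATAT primer", {
  loc <- ref_locus()
  reads <- rep(paste0(substr(loc$sequence, 180, 280), loc$primer), 25)
  ext <- detect_3prime_extension(reads, loc)
  expect_identical(ext$consensus, "GATAT")
  expect_equal(ext$n_anchored, 25)
  expect_equal(ncol(ext$pfm), 5)
  expect_equal(unname(ext$pfm["G", 1]), 25)
})

test_that("RT-dead reads give an empty consensus; PBS mutants complement their PBS", {
  loc <- ref_locus()
  ## no extension past the ncRNA terminus
  dead <- rep(substr(loc$sequence, 180, 280), 10)
  ext0 <- detect_3prime_extension(dead, loc)
  expect_identical(ext0$consensus, "")

  ## mutate the PBS: the extension is its reverse complement
  mut_seq <- loc$sequence
  substr(mut_seq, 142, 146) <- "CCGGA"
  mut_locus <- ncrna_locus("pbs_mut", mut_seq, aca_positions = loc$aca_positions,
                           pbs_interval = c(142, 146), primer = "TCCGG")
  reads <- rep(paste0(substr(mut_seq, 180, 280), revcomp("CCGGA")), 12)
  ext <- detect_3prime_extension(reads, mut_locus)
  expect_identical(ext$consensus, revcomp("CCGGA"))

  ## reads that never reach the terminus anchor nowhere
  expect_warning(none <- detect_3prime_extension(rep("ACGTACGTACGTACGTACGT", 3), loc),
                 "no reads anchored")
  expect_equal(none$n_anchored, 0)
})

test_that("chimeric-read layout anchors each read on its longest consecutive run", {
  idx <- ref_index()
  loc <- ref_locus()
  ## fully contiguous plus-strand read: every window sits at its own position
  contig <- substr(loc$sequence, 50, 120)
  lay <- layout_chimeric_reads(list(segment_read(contig, idx, "contig")))
  segs <- lay$segments
  expect_true(all(segs$in_run))
  expect_equal(segs$x, segs$color_position)
  expect_equal(lay$n_excluded, 0)

  ## two-repeat chimeric read: out-of-run windows are placed at run-relative
  ## coordinates, giving the disjunct layout
  chim <- concatemerize(ref_template(), 2)$sequence
  lay2 <- layout_chimeric_reads(list(segment_read(chim, idx, "chim")))
  s2 <- lay2$segments
  expect_true(any(!s2$in_run))
  off_run <- s2[!s2$in_run & !is.na(s2$color_position), ]
  expect_true(all(off_run$x != off_run$color_position))

  ## unmappable read is excluded but counted
  set.seed(11)
  junk <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE), collapse = "")
  lay3 <- layout_chimeric_reads(list(segment_read(junk, idx, "junk"),
                                     segment_read(contig, idx, "contig")))
  expect_equal(lay3$n_excluded, 1)
  expect_equal(unique(lay3$segments$read_id), "contig")
})

test_that("equal-length runs break ties to the leftmost", {
  idx <- ref_index()
  loc <- ref_locus()
  set.seed(13)
  spacer <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
  a <- substr(loc$sequence, 40, 61)    # 22 nt -> 12 windows
  b <- substr(loc$sequence, 200, 221)  # 22 nt -> 12 windows
  asn <- segment_read(paste0(a, spacer, b), idx, "tie")
  ## verify the fixture really has two equal maximal runs
  mapped_runs <- rle(asn$strand != "unmapped")
  expect_equal(sum(mapped_runs$lengths[mapped_runs$values] == 12), 2)
  lay <- layout_chimeric_reads(list(asn))
  run_offsets <- lay$segments$read_offset[lay$segments$in_run]
  expect_equal(min(run_offsets), 0)    # leftmost run chosen
})

test_that("spike-in normalization divides by spike reads and volume", {
  sc <- strand_counts(template_minus = 100, spike_reads = 10,
                      volume_equivalents = 2)
  norm <- normalize_strand_counts(sc)
  expect_equal(unname(norm$normalized["template_minus"]), 5)

  ## doubling the spike halves every normalized count
  sc2 <- strand_counts(template_minus = 100, template_plus = 40,
                       spike_reads = 20, volume_equivalents = 2)
  norm2 <- normalize_strand_counts(sc2)
  expect_equal(unname(norm2$normalized["template_minus"]), 2.5)
  expect_equal(norm2$normalized, normalize_strand_counts(
    strand_counts(template_minus = 100, template_plus = 40, spike_reads = 10,
                  volume_equivalents = 2))$normalized / 2)

  expect_error(normalize_strand_counts(strand_counts(spike_reads = 0)),
               "spike_reads")
})

test_that("plus-strand junction reads appear only after hairpins are opened", {
  loc <- ref_locus()
  idx <- ref_index()
  ## untreated library on single-stranded (no reversal) molecules
  sim_ss <- simulate_synthesis(sim_config(loc, n_reads = 40, p_reversal = 0,
                                          seed = 41))
  un <- simulate_shortreads(sim_ss, "strand_specific", s1_treated = FALSE,
                            n_fragments = 120, frag_len = c(150, 250),
                            spike_count = 30, seed = 42)
  frags <- un$reads[un$reads$source == "fragment", ]
  expect_true(all(frags$strand_label == "minus"))
  t_un <- tally_strand_reads(frags$sequence, frags$strand_label, idx, loc,
                             spike_reads = un$spike_reads)
  expect_equal(unname(t_un$raw["junction_plus"]), 0)
  expect_gt(unname(t_un$raw["junction_minus"]), 0)

  ## S1-treated library on hairpin molecules samples both strands
  sim_hp <- simulate_synthesis(sim_config(loc, n_reads = 40, p_reversal = 1,
                                          seed = 43))
  s1 <- simulate_shortreads(sim_hp, "strand_specific", s1_treated = TRUE,
                            n_fragments = 250, frag_len = c(150, 250),
                            spike_count = 30, seed = 44)
  f1 <- s1$reads[s1$reads$source == "fragment" &
                   s1$reads$strand_label %in% c("plus", "minus"), ]
  t_s1 <- tally_strand_reads(f1$sequence, f1$strand_label, idx, loc,
                             spike_reads = s1$spike_reads)
  expect_gt(unname(t_s1$raw["junction_plus"]), 0)
  expect_gt(unname(t_s1$raw["junction_minus"]), 0)
})
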