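test_that("coordinate extraction returns the annotated 120-nt template", {
  tpl <- extract_template(ref_locus(), "coordinates")
  expect_equal(nchar(tpl$template), 120)
  expect_equal(c(tpl$start, tpl$end), c(29, 148))
  expect_identical(substr(tpl$template, 1, 3), "ACA")
})

test_that("ACA-bracket extraction finds the template between the brackets", {
  ## toy ncRNA: ACA at 3 and 12, template = positions 3-11
  toy <- "GGACAGGGTTTACAGG"
  tpl <- extract_template(toy, "aca_motif", approx_start = 3,
                          length_band = c(5, 20))
  expect_identical(tpl$template, "ACAGGGTTT")
  expect_equal(c(tpl$start, tpl$end), c(3, 11))

  ## no second bracket
  expect_error(extract_template("GGACAGGGTTT", "aca_motif", approx_start = 3,
                                length_band = c(5, 20)),
               "bracket-not-found")
  ## no bracket left of the hint
  expect_error(extract_template("GGGGTTTACAGG", "aca_motif", approx_start = 3,
                                length_band = c(5, 20)),
               "bracket-not-found")
  ## on the reference locus the bracket rule recovers the annotation
  tpl2 <- extract_template(ref_locus(), "aca_motif")
  expect_equal(c(tpl2$start, tpl2$end), c(29, 148))
})

test_that("locus construction rejects out-of-bounds coordinates", {
  expect_error(ncrna_locus("x", "ACGTACGT", template_start = 2,
                           template_end = 50),
               "outside sequence")
})

test_that("concatemerization reverse-complements and repeats the template", {
  cc <- concatemerize("ACAGTT", 3)
  expect_identical(cc$sequence, "AACTGTAACTGTAACTGT")
  expect_identical(cc$repeat_unit, "AACTGT")
  expect_equal(cc$junction_positions, c(6, 12))

  cc2 <- concatemerize(ref_template(), 2)
  expect_equal(nchar(cc2$sequence), 240)
  expect_equal(length(cc2$junction_positions), 1)

  cc1 <- concatemerize("ACAGTT", 1)
  expect_identical(cc1$sequence, cc1$repeat_unit)
  expect_length(cc1$junction_positions, 0)

  expect_error(concatemerize("ACAGTT", 0), "positive integer")
  expect_error(concatemerize("ACAGXT", 2), "outside")
})

test_that("reverse-complement involution holds for generated templates", {
  set.seed(42)
  for (i in 1:20) {
    tpl <- paste(sample(c("A", "C", "G", "T"), sample(10:60, 1),
                        replace = TRUE), collapse = "")
    expect_identical(revcomp(concatemerize(tpl, 1)$sequence), tpl)
  }
})

test_that("promoter scan reconstitutes the 17-bp-spacer promoter only across junctions", {
  cc2 <- concatemerize(ref_template(), 2)
  calls <- scan_promoters(cc2)
  canon <- calls[calls$arrangement == "canonical", ]
  expect_equal(nrow(canon), 1)
  expect_equal(canon$spacer_bp, 17)
  expect_true(canon$spans_junction)
  expect_equal(canon$minus35_start, 110)
  expect_equal(canon$minus10_start, 133)

  ## single repeat: motifs out of order, 91-bp gap, no canonical call
  calls1 <- scan_promoters(concatemerize(ref_template(), 1))
  expect_false(any(calls1$arrangement == "canonical"))
  expect_equal(calls1$spacer_bp[calls1$arrangement == "out_of_order"], 91)
  expect_false(calls1$spans_junction[1])

  ## -10 knocked out (TATAAT -> CGCGGC): nothing canonical remains
  mut_repeat <- sub("TATAAT", "CGCGGC", concatemerize(ref_template(), 1)$sequence)
  mut2 <- scan_promoters(strrep(mut_repeat, 2))
  expect_false(any(mut2$arrangement == "canonical"))
})

test_that("an n-repeat construct yields exactly n-1 junction-spanning promoters", {
  for (n in 2:5) {
    calls <- scan_promoters(concatemerize(ref_template(), n))
    canon <- calls[calls$arrangement == "canonical", ]
    expect_equal(nrow(canon), n - 1)
    expect_true(all(canon$spans_junction))
    expect_true(all(canon$spacer_bp == 17))
  }
})

test_that("ORF scan finds the junction-spanning stop-free frame", {
  ## toy: repeat ATGGCTGCT, frame 0 translates to MAAMAA
  cc <- concatemerize(revcomp("ATGGCTGCT"), 2)
  expect_identical(cc$repeat_unit, "ATGGCTGCT")
  orfs <- scan_orfs(cc)
  f0 <- orfs[orfs$frame == 0, ]
  expect_true(f0$stop_free)
  expect_identical(f0$translation, "MAAMAA")
  expect_equal(f0$start_position, 1)
  expect_true(all(orfs$frame_preserving))

  ## reference repeat (length 120): exactly one stop-free frame, spans junctions
  orfs3 <- scan_orfs(concatemerize(ref_template(), 3))
  sf <- orfs3[orfs3$stop_free, ]
  expect_equal(nrow(sf), 1)
  expect_true(sf$spans_junction)
  expect_true(sf$frame_preserving)
  expect_false(grepl("\\*", sf$translation))

  expect_error(scan_orfs("AC"), "codon")
})

test_that("a 119-nt repeat frameshifts at every junction and stops appear in all frames", {
  loc119 <- make_locus(seed = 202, template_length = 119)
  tpl <- extract_template(loc119, "coordinates")$template
  expect_equal(nchar(tpl), 119)
  orfs <- scan_orfs(concatemerize(tpl, 3))
  expect_false(any(orfs$frame_preserving))
  ## brute-force oracle: count stop codons per frame directly
  s <- concatemerize(tpl, 3)$sequence
  for (f in 0:2) {
    starts <- seq(1 + f, nchar(s) - 2, by = 3)
    stops <- sum(substring(s, starts, starts + 2) %in% c("TAA", "TAG", "TGA"))
    expect_equal(orfs$n_stops[orfs$frame == f], stops)
    expect_gt(stops, 0)
  }
})

test_that("RBS and start codon sit 13 nt downstream of the junction -10", {
  cc2 <- concatemerize(ref_template(), 2)
  canon <- scan_promoters(cc2)
  canon <- canon[canon$arrangement == "canonical", ][1, , drop = FALSE]
  rbs <- locate_rbs(cc2, canon)
  expect_equal(rbs$window[1], canon$minus10_end + 14)
  expect_equal(rbs$start_codon, 152)          # repeat position 32, second repeat
  expect_equal(rbs$rbs, 144)                  # GAG at repeat position 24
  expect_identical(substr(cc2$sequence, rbs$start_codon, rbs$start_codon + 2), "ATG")
  expect_identical(substr(cc2$sequence, rbs$rbs, rbs$rbs + 2), "GAG")
  expect_false(rbs$truncated)

  ## start codon removed: no ATG reported
  seq_noatg <- cc2$sequence
  substr(seq_noatg, 152, 154) <- "CCC"
  rbs2 <- locate_rbs(seq_noatg, canon)
  expect_true(is.na(rbs2$start_codon))

  ## window running past the sequence end is truncated with a warning
  expect_warning(r3 <- locate_rbs("ACGTACGTACGT", 1, offset = 2, window = 50),
                 "truncated")
  expect_true(r3$truncated)
  expect_error(locate_rbs("ACGT", 10, offset = 13), "past the sequence end")
})

test_that("in-silico digest cuts G^ANTC and conserves total length", {
  expect_equal(digest_sequence("AAGAATCAA"), c(3, 6))
  expect_equal(digest_sequence("ACGTACGTAA"), 10)

  cc4 <- concatemerize(ref_template(), 4)
  frags <- digest_sequence(cc4$sequence)
  expect_length(frags, 5)
  expect_equal(unique(frags[2:4]), 120)
  expect_equal(sum(frags), nchar(cc4$sequence))

  set.seed(7)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
    expect_equal(sum(digest_sequence(s)), 200)
  }
})

test_that("protein properties follow the Kyte-Doolittle scale", {
  expect_equal(protein_properties("IIII")$gravy, 4.5)
  expect_equal(protein_properties("RRRR")$gravy, -4.5)
  p <- protein_properties("AIRK")
  expect_equal(p$hydrophobic_fraction, 0.5)
  expect_equal(p$length, 4)
  expect_error(protein_properties(""), "non-empty")
  expect_error(protein_properties("AIX2"), "unknown residue")
})
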