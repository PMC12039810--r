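test_that("a contiguous read yields zero jumps", {
  asn <- segment_read(concatemerize(ref_template(), 1)$sequence, ref_index())
  expect_equal(nrow(quantify_jumps(asn, template_interval = ref_interval())), 0)
})

test_that("a read crossing one tandem junction jumps from minus 29 to minus 148", {
  read <- concatemerize(ref_template(), 2)$sequence
  asn <- segment_read(read, ref_index())
  j <- quantify_jumps(asn, template_interval = ref_interval())
  expect_equal(nrow(j), 1)
  expect_equal(j$from_position, 29)
  expect_equal(j$to_position, 148)
  expect_identical(c(j$from_strand, j$to_strand), c("minus", "minus"))

  ## without the template interval the breakpoint sits at the 3-nt bracket
  ## micro-homology (alignment region) instead
  raw <- quantify_jumps(asn)
  expect_equal(raw$from_position, 29)
  expect_equal(raw$to_position, 151)
})

test_that("strand pairs classify into categories 1-4 with fractions over all jumps", {
  jumps <- data.frame(
    read_id = "r",
    from_position = c(29, 31, 148, 146),
    from_strand = c("minus", "minus", "plus", "plus"),
    to_position = c(148, 34, 29, 280),
    to_strand = c("minus", "plus", "plus", "minus"))
  cls <- classify_jumps(jumps)
  expect_equal(cls$jumps$category, 1:4)
  expect_equal(unname(cls$fractions), rep(0.25, 4))
})

test_that("the jump map conserves counts and is dominated by the tandem junction", {
  sim <- ref_sim()
  idx <- ref_index()
  all_jumps <- do.call(rbind, lapply(seq_len(100), function(i) {
    asn <- segment_read(sim$molecules[[i]], idx,
                        read_id = names(sim$molecules)[i])
    quantify_jumps(asn, template_interval = ref_interval())
  }))
  cls <- classify_jumps(all_jumps)
  map <- jump_map(cls$jumps)
  expect_equal(sum(map$n), nrow(all_jumps))
  top <- map[1, ]
  expect_equal(c(top$from_position, top$to_position), c(29, 148))
  expect_identical(c(top$from_strand, top$to_strand), c("minus", "minus"))
  expect_equal(top$category, 1)
  ## empty input gives an empty table
  expect_equal(nrow(jump_map(all_jumps[0, ])), 0)
})

test_that("read structure counts repeats from junction jumps", {
  ## pure minus-strand concatemer: x repeats, no second strand
  read <- concatemerize(ref_template(), 5)$sequence
  asn <- segment_read(read, ref_index())
  rs <- read_structure(asn, ref_locus())
  expect_equal(rs$n_minus_repeats, 5)
  expect_equal(rs$n_plus_repeats, 0)
  expect_equal(rs$total_repeats, 5)
  expect_false(rs$readthrough)

  ## no mapped windows
  set.seed(77)
  junk <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  rs0 <- read_structure(segment_read(junk, ref_index()), ref_locus())
  expect_equal(rs0$total_repeats, 0)
  expect_true(is.na(rs0$start_position))
})

test_that("hairpin molecules are recovered as (x, y) with primer starts", {
  sim <- simulate_synthesis(sim_config(ref_locus(), n_reads = 80,
                                       p_reversal = 1, seed = 31))
  idx <- ref_index()
  for (i in seq_len(40)) {
    tr <- sim$truth_reads[i, ]
    asn <- segment_read(sim$molecules[[i]], idx, read_id = tr$read_id)
    rs <- read_structure(asn, ref_locus())
    expect_equal(rs$n_minus_repeats, tr$x)
    expect_equal(rs$n_plus_repeats, tr$y)
    expect_equal(rs$readthrough, tr$readthrough)
    expect_true(rs$has_primer_start)
    expect_equal(rs$start_position, ref_locus()$pbs_interval[2])
  }
})

test_that("reads split across voids longer than max_skip", {
  set.seed(55)
  insert <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = "")
  half <- substr(ref_locus()$sequence, 40, 100)
  read <- paste0(half, insert, substr(ref_locus()$sequence, 200, 260))
  asn <- segment_read(read, ref_index())
  j <- quantify_jumps(asn, max_skip = 33, template_interval = ref_interval())
  expect_equal(nrow(j), 0)  # void of ~90 windows exceeds max_skip: no bridge
  j2 <- quantify_jumps(asn, max_skip = 200, template_interval = ref_interval())
  expect_equal(nrow(j2), 1) # bridged when allowed
})
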