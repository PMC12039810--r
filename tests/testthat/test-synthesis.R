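test_that("parameter limits produce pure minus-strand concatemers", {
  sim <- simulate_synthesis(sim_config(ref_locus(), n_reads = 60,
                                       p_reversal = 0, p_readthrough = 0,
                                       seed = 5))
  expect_true(all(sim$truth_jumps$category == 1))
  expect_true(all(sim$truth_reads$y == 0))
  expect_false(any(sim$truth_reads$readthrough))
  ## every molecule starts with the GATAT primer sequence
  expect_true(all(startsWith(unname(sim$molecules), "GATAT")))
})

test_that("the hairpin constraint y <= x holds mechanically for every molecule", {
  sim <- simulate_synthesis(sim_config(ref_locus(), n_reads = 400,
                                       p_reversal = 1, seed = 19))
  expect_true(all(sim$truth_reads$y >= 1))
  expect_true(all(sim$truth_reads$y <= sim$truth_reads$x))
})

test_that("repeat counts follow the zero-truncated geometric law", {
  sim <- simulate_synthesis(sim_config(ref_locus(), n_reads = 10000, seed = 23))
  x <- sim$truth_reads$x
  se <- stats::sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 5), 3 * se)
  ## the configured law's mode
  expect_equal(as.integer(names(which.max(table(x)))), 1)
  ## reversal fraction estimates p_reversal
  rev_frac <- mean(sim$truth_reads$y > 0)
  se_rev <- sqrt(rev_frac * (1 - rev_frac) / length(x))
  expect_lt(abs(rev_frac - 0.4), 3 * se_rev)
})

test_that("truth category counts match closed-form expectations", {
  n <- 10000
  sim <- simulate_synthesis(sim_config(ref_locus(), n_reads = n, seed = 29))
  counts <- sapply(1:4, function(cat) {
    per_read <- table(factor(sim$truth_jumps$read_id[sim$truth_jumps$category == cat],
                             levels = sim$truth_reads$read_id))
    as.vector(per_read)
  })
  ## closed forms under the simulator model (mean m, reversal r, read-through q):
  ## E[cat1] = m - 1; E[cat2] = r; E[cat3] = r (m - 1) / 2; E[cat4] = r q E[1/x]
  m <- 5; r <- 0.4; q <- 0.5; p <- 1 / m
  e_inv_x <- sum((1 / (1:5000)) * p * (1 - p)^(0:4999))
  expected <- c(m - 1, r, r * (m - 1) / 2, r * q * e_inv_x)
  for (cat in 1:4) {
    se <- stats::sd(counts[, cat]) / sqrt(n)
    expect_lt(abs(mean(counts[, cat]) - expected[cat]), 3 * se)
  }
})

test_that("zero-error sequencing reproduces molecules, with adapters where asked", {
  sim <- simulate_synthesis(sim_config(ref_locus(), n_reads = 20, seed = 3))
  reads <- sequence_reads(sim, error_rates = c(sub = 0, ins = 0, del = 0),
                          seed = 4)
  expect_identical(reads$reads$sequence, unname(sim$molecules))
  expect_equal(nrow(reads$errors), 0)

  with_ad <- sequence_reads(sim, error_rates = c(sub = 0, ins = 0, del = 0),
                            adapter5 = "AATGTACTT", adapter3 = "GCAAT", seed = 4)
  expect_identical(with_ad$reads$sequence,
                   paste0("AATGTACTT", unname(sim$molecules), "GCAAT"))
  expect_equal(nchar(with_ad$reads$quality), nchar(with_ad$reads$sequence))
})

test_that("substitution counts match the binomial expectation", {
  sim <- simulate_synthesis(sim_config(ref_locus(), n_reads = 200, seed = 13))
  reads <- sequence_reads(sim, error_rates = c(sub = 0.02, ins = 0, del = 0),
                          seed = 14)
  n_bases <- sum(nchar(sim$molecules))
  n_sub <- sum(reads$errors$type == "sub")
  expect_lt(abs(n_sub - 0.02 * n_bases), 3 * sqrt(n_bases * 0.02 * 0.98))
})

test_that("sequencing is byte-deterministic given the seed", {
  sim <- simulate_synthesis(sim_config(ref_locus(), n_reads = 30, seed = 2))
  a <- sequence_reads(sim, seed = 9)
  b <- sequence_reads(sim, seed = 9)
  expect_identical(a, b)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(a$reads, f1); write_fastq(b$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("short-read libraries label strands and emit the configured spike", {
  sim <- simulate_synthesis(sim_config(ref_locus(), n_reads = 30,
                                       p_reversal = 0, seed = 51))
  sr <- simulate_shortreads(sim, "strand_specific", n_fragments = 150,
                            spike_count = 37, seed = 52)
  expect_equal(sum(sr$reads$source == "spike"), 37)
  expect_equal(sr$spike_reads, 37)
  frag <- sr$reads[sr$reads$source == "fragment", ]
  expect_equal(nrow(frag), 150)
  expect_true(all(frag$strand_label == "minus"))

  tag <- simulate_shortreads(sim, "tagmentation", n_fragments = 50,
                             spike_count = 0, seed = 53)
  expect_true(all(is.na(tag$reads$strand_label)))
})
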