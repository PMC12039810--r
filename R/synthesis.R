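#' Configuration for the rolling reverse-transcription simulator
#'
#' Defaults encode the study conditions: a modal repeat count of 5 via a
#' zero-truncated geometric law, reversal to second-strand synthesis only at
#' repeat junctions with the number of plus-strand repeats y drawn uniformly
#' on 1..x (so y <= x holds mechanically), optional read-through from the
#' primer into the ncRNA 3' domain, and Nanopore-like error rates
#' (substitution 0.02, insertion 0.01, deletion 0.01).
#'
#' @param locus An [ncrna_locus()], typically from [make_locus()].
#' @param n_reads Number of molecules/reads (default 1000).
#' @param repeat_mean Mean of the zero-truncated geometric repeat-count law
#'   (default 5; its mode is 1..5-region heavy with mean 5 and the law is
#'   parameterised so `P(x = k) = p (1 - p)^(k - 1)`, `p = 1/mean`).
#' @param p_reversal Probability that a molecule reverses into second-strand
#'   synthesis at its final junction (default 0.4).
#' @param p_readthrough Probability of primer read-through into the ncRNA 3'
#'   domain given the second strand reaches the primer (y = x) (default 0.5).
#' @param error_rates Named vector `c(sub=, ins=, del=)` (defaults
#'   0.02/0.01/0.01).
#' @param adapter5,adapter3 Adapter sequences added by [sequence_reads()]
#'   (defaults empty).
#' @param seed Integer seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(locus, n_reads = 1000L, repeat_mean = 5,
                       p_reversal = 0.4, p_readthrough = 0.5,
                       error_rates = c(sub = 0.02, ins = 0.01, del = 0.01),
                       adapter5 = "", adapter3 = "", seed = NULL) {
  stopifnot(inherits(locus, "ncrna_locus"))
  probs <- c(p_reversal, p_readthrough, unname(error_rates))
  if (any(probs < 0 | probs > 1) || any(is.na(probs)))
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  if (repeat_mean < 1) stop("repeat_mean must be >= 1", call. = FALSE)
  structure(list(locus = locus, n_reads = as.integer(n_reads),
                 repeat_mean = repeat_mean, p_reversal = p_reversal,
                 p_readthrough = p_readthrough,
                 error_rates = c(sub = unname(error_rates["sub"]),
                                 ins = unname(error_rates["ins"]),
                                 del = unname(error_rates["del"])),
                 adapter5 = adapter5, adapter3 = adapter3, seed = seed),
            class = "sim_config")
}

## One molecule of rolling reverse transcription, as ordered synthesis runs.
## Minus-strand synthesis starts from the GATAT primer at the PBS, descends
## the template, jumps back to the template end at each junction (Category
## 1). On reversal the final minus repeat stops 2 nt into the template
## (base 31 for the reference), the RT turns onto the nascent strand
## (Category 2, to plus base 34) and ascends, jumping across second-strand
## junctions (Category 3). If the second strand reaches the primer (y = x)
## it may read through into the ncRNA 3' domain (Category 4, to the ncRNA
## terminal base).
sim_molecule <- function(locus, repeat_mean, p_reversal, p_readthrough,
                         rc_nc = revcomp(locus$sequence)) {
  nc <- locus$sequence
  ts <- locus$template_start; te <- locus$template_end
  pbs_hi <- locus$pbs_interval[2]
  nlen <- nchar(nc)
  rev_from <- ts + 2L; rev_to <- ts + 5L
  ## minus-sense emission of ncRNA [lo, hi] as a slice of the precomputed
  ## reverse complement
  minus_seg <- function(lo, hi) substr(rc_nc, nlen - hi + 1L, nlen - lo + 1L)

  x <- stats::rgeom(1L, 1 / repeat_mean) + 1L
  reversal <- stats::runif(1) < p_reversal
  y <- if (reversal) sample.int(x, 1L) else 0L
  readthrough <- reversal && y == x && stats::runif(1) < p_readthrough

  parts <- character(); blocks <- c(minus = 0L, plus = 0L, rt = 0L)
  j_from <- integer(); j_to <- integer(); j_cat <- integer()
  for (i in seq_len(x)) {
    hi <- if (i == 1L) pbs_hi else te
    lo <- if (i == x && reversal) rev_from else ts
    parts <- c(parts, minus_seg(lo, hi))
    if (i < x) {
      j_from <- c(j_from, ts); j_to <- c(j_to, te); j_cat <- c(j_cat, 1L)
    }
  }
  blocks["minus"] <- sum(nchar(parts))
  if (reversal) {
    j_from <- c(j_from, rev_from); j_to <- c(j_to, rev_to); j_cat <- c(j_cat, 2L)
    plus_parts <- character()
    for (i in seq_len(y)) {
      lo <- if (i == 1L) rev_to else ts
      hi <- if (i == y && y == x) pbs_hi else te
      plus_parts <- c(plus_parts, substr(nc, lo, hi))
      if (i < y) {
        j_from <- c(j_from, te); j_to <- c(j_to, ts); j_cat <- c(j_cat, 3L)
      }
    }
    blocks["plus"] <- sum(nchar(plus_parts))
    parts <- c(parts, plus_parts)
    if (readthrough) {
      j_from <- c(j_from, pbs_hi); j_to <- c(j_to, nlen); j_cat <- c(j_cat, 4L)
      rt_part <- minus_seg(te + 1L, nlen)
      blocks["rt"] <- nchar(rt_part)
      parts <- c(parts, rt_part)
    }
  }
  strands <- rbind(c("minus", "minus"), c("minus", "plus"),
                   c("plus", "plus"), c("plus", "minus"))
  list(sequence = paste(parts, collapse = ""),
       j_from = j_from, j_to = j_to, j_cat = j_cat,
       j_from_strand = strands[j_cat, 1], j_to_strand = strands[j_cat, 2],
       x = x, y = y, start_position = pbs_hi, readthrough = readthrough,
       blocks = blocks)
}

#' Simulate ccDNA molecules with ground truth
#'
#' Runs the rolling reverse-transcription model of [sim_config()] and emits
#' each molecule's DNA sequence together with its full construction trace:
#' every template jump (position, strand, category, in order of synthesis)
#' and the per-molecule repeat structure. The truth log is exactly what
#' error-free k-mer jump analysis of the molecules should recover.
#'
#' @param config A [sim_config()].
#' @return Object of class `ccdna_simulation`: `molecules` (named character
#'   vector), `truth_jumps` (data.frame: `read_id`, `event_index`,
#'   `from_position`, `from_strand`, `to_position`, `to_strand`,
#'   `category`), `truth_reads` (data.frame: `read_id`, `x`, `y`,
#'   `start_position`, `readthrough`, block lengths), `locus`, `config`.
#' @export
simulate_synthesis <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_reads
    ids <- if (n > 0) sprintf("mol_%05d", seq_len(n)) else character()
    mols <- stats::setNames(character(n), ids)
    rc_nc <- revcomp(config$locus$sequence)
    per <- vector("list", n)
    for (i in seq_len(n)) {
      m <- sim_molecule(config$locus, config$repeat_mean,
                        config$p_reversal, config$p_readthrough, rc_nc = rc_nc)
      mols[i] <- m$sequence
      per[[i]] <- m
    }
    nj <- vapply(per, function(m) length(m$j_cat), integer(1))
    truth_jumps <- data.frame(
      read_id = rep(ids, nj),
      event_index = unlist(lapply(nj, seq_len), use.names = FALSE),
      from_position = unlist(lapply(per, `[[`, "j_from"), use.names = FALSE),
      from_strand = unlist(lapply(per, `[[`, "j_from_strand"), use.names = FALSE),
      to_position = unlist(lapply(per, `[[`, "j_to"), use.names = FALSE),
      to_strand = unlist(lapply(per, `[[`, "j_to_strand"), use.names = FALSE),
      category = unlist(lapply(per, `[[`, "j_cat"), use.names = FALSE))
    if (n == 0)
      truth_jumps <- data.frame(read_id = character(), event_index = integer(),
                                from_position = integer(),
                                from_strand = character(),
                                to_position = integer(),
                                to_strand = character(), category = integer())
    truth_reads <- data.frame(
      read_id = ids,
      x = vapply(per, `[[`, integer(1), "x"),
      y = vapply(per, `[[`, integer(1), "y"),
      start_position = vapply(per, `[[`, integer(1), "start_position"),
      has_primer_start = rep(TRUE, n),
      readthrough = vapply(per, `[[`, logical(1), "readthrough"),
      minus_len = vapply(per, function(m) unname(m$blocks["minus"]), integer(1)),
      plus_len = vapply(per, function(m) unname(m$blocks["plus"]), integer(1)),
      rt_len = vapply(per, function(m) unname(m$blocks["rt"]), integer(1)))
    structure(list(molecules = mols, truth_jumps = truth_jumps,
                   truth_reads = truth_reads,
                   locus = config$locus, config = config),
              class = "ccdna_simulation")
  })
}

#' @export
print.ccdna_simulation <- function(x, ...) {
  cat(sprintf("<ccdna_simulation> %d molecules, %d truth jumps, locus %s\n",
              length(x$molecules), nrow(x$truth_jumps), x$locus$id))
  invisible(x)
}

## Per-base substitution/insertion/deletion with logged positions
## (coordinates on the input molecule).
apply_errors <- function(seq, sub, ins, del) {
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  u_del <- stats::runif(n) < del
  u_sub <- !u_del & stats::runif(n) < sub
  u_ins <- stats::runif(n) < ins
  for (i in which(u_sub)) b[i] <- sample(setdiff(DNA_BASES, b[i]), 1L)
  pieces <- b
  pieces[u_del] <- ""
  ins_at <- which(u_ins)
  if (length(ins_at))
    pieces[ins_at] <- paste0(pieces[ins_at],
                             sample(DNA_BASES, length(ins_at), replace = TRUE))
  err <- rbind(
    if (any(u_sub)) data.frame(position = which(u_sub), type = "sub"),
    if (any(u_ins)) data.frame(position = ins_at, type = "ins"),
    if (any(u_del)) data.frame(position = which(u_del), type = "del"))
  list(sequence = paste(pieces, collapse = ""),
       errors = if (is.null(err)) data.frame(position = integer(), type = character()) else err)
}

#' Turn simulated molecules into sequencing reads
#'
#' Applies per-base substitution/insertion/deletion errors (positions
#' logged), prepends/appends adapters, and attaches a constant placeholder
#' quality string. Deterministic given the seed.
#'
#' @param sim A [simulate_synthesis()] result, or a named character vector
#'   of molecule sequences.
#' @param error_rates Named vector `c(sub=, ins=, del=)`; defaults to the
#'   simulation config's rates (or zero for a bare character vector).
#' @param adapter5,adapter3 Adapter sequences (defaults from the config).
#' @param seed Integer seed.
#' @param quality_char Constant FASTQ quality character (default `"I"`).
#' @return List: `reads` (data.frame `read_id`, `sequence`, `quality`) and
#'   `errors` (data.frame `read_id`, `position`, `type`; molecule
#'   coordinates).
#' @export
sequence_reads <- function(sim, error_rates = NULL, adapter5 = NULL,
                           adapter3 = NULL, seed = NULL, quality_char = "I") {
  if (inherits(sim, "ccdna_simulation")) {
    mols <- sim$molecules
    if (is.null(error_rates)) error_rates <- sim$config$error_rates
    if (is.null(adapter5)) adapter5 <- sim$config$adapter5
    if (is.null(adapter3)) adapter3 <- sim$config$adapter3
  } else {
    mols <- sim
    if (is.null(error_rates)) error_rates <- c(sub = 0, ins = 0, del = 0)
    if (is.null(adapter5)) adapter5 <- ""
    if (is.null(adapter3)) adapter3 <- ""
  }
  if (any(error_rates < 0 | error_rates >= 1))
    stop("error rates must lie in [0, 1)", call. = FALSE)
  with_seed(seed, {
    ids <- names(mols)
    if (is.null(ids)) ids <- sprintf("read_%05d", seq_along(mols))
    seqs <- character(length(mols))
    errs <- vector("list", length(mols))
    for (i in seq_along(mols)) {
      r <- apply_errors(mols[[i]], error_rates["sub"], error_rates["ins"],
                        error_rates["del"])
      seqs[i] <- paste0(adapter5, r$sequence, adapter3)
      if (nrow(r$errors)) errs[[i]] <- cbind(read_id = ids[i], r$errors)
    }
    errs <- errs[!vapply(errs, is.null, logical(1))]
    list(reads = data.frame(read_id = ids, sequence = seqs,
                            quality = strrep(quality_char, nchar(seqs))),
         errors = if (length(errs)) do.call(rbind, errs) else
           data.frame(read_id = character(), position = integer(),
                      type = character()))
  })
}

#' Simulate short-read libraries from ccDNA molecules
#'
#' Random fragmentation of simulated molecules. In `"strand_specific"` mode
#' each fragment is labelled with the strand block it derives from
#' (minus-strand block, plus-strand block, or the read-through block, which
#' is minus-sense); untreated libraries (`s1_treated = FALSE`) sample only
#' single-stranded molecules (no second strand), whereas the S1-treated
#' variant opens the hairpins so both strand blocks are sampled. In
#' `"tagmentation"` mode fragments come from all molecules in random
#' orientation without labels. A configurable number of reads of a fixed
#' single-strand spike control is appended.
#'
#' @param sim A [simulate_synthesis()] result.
#' @param mode `"tagmentation"` or `"strand_specific"`.
#' @param s1_treated Logical; open hairpins (strand_specific mode).
#' @param n_fragments Number of fragment reads (default 500).
#' @param frag_len Inclusive fragment-length range (default `c(50, 200)`).
#' @param spike_count Number of spike-control reads (default 100).
#' @param spike_len Spike sequence length (default 200).
#' @param seed Integer seed.
#' @return List: `reads` (data.frame `read_id`, `sequence`, `strand_label`,
#'   `source`), `spike_reads`, `spike_sequence`, `mode`, `s1_treated`.
#' @export
simulate_shortreads <- function(sim, mode = c("tagmentation", "strand_specific"),
                                s1_treated = FALSE, n_fragments = 500L,
                                frag_len = c(50L, 200L), spike_count = 100L,
                                spike_len = 200L, seed = NULL) {
  stopifnot(inherits(sim, "ccdna_simulation"))
  mode <- match.arg(mode)
  with_seed(seed, {
    tr <- sim$truth_reads
    eligible <- if (mode == "strand_specific" && !s1_treated)
      which(tr$plus_len == 0L) else seq_len(nrow(tr))
    if (length(eligible) == 0)
      stop("no molecules eligible for an untreated single-strand library", call. = FALSE)
    lens <- nchar(sim$molecules[eligible])
    rows <- vector("list", n_fragments)
    for (i in seq_len(n_fragments)) {
      j <- eligible[sample.int(length(eligible), 1L, prob = lens)]
      mol <- sim$molecules[[j]]
      L <- nchar(mol)
      fl <- min(L, sample(frag_len[1]:frag_len[2], 1L))
      start <- sample.int(L - fl + 1L, 1L)
      end <- start + fl - 1L
      frag <- substr(mol, start, end)
      m_end <- tr$minus_len[j]; p_end <- m_end + tr$plus_len[j]
      label <- if (end <= m_end || start > p_end) "minus"
               else if (start > m_end && end <= p_end) "plus"
               else "spanning"
      if (mode == "tagmentation") {
        if (stats::runif(1) < 0.5) frag <- revcomp(frag)
        label <- NA_character_
      }
      rows[[i]] <- data.frame(read_id = sprintf("frag_%05d", i), sequence = frag,
                              strand_label = label, source = "fragment")
    }
    spike_sequence <- random_dna(spike_len)
    spikes <- if (spike_count > 0)
      data.frame(read_id = sprintf("spike_%05d", seq_len(spike_count)),
                 sequence = spike_sequence, strand_label = NA_character_,
                 source = "spike") else NULL
    list(reads = rbind(do.call(rbind, rows), spikes),
         spike_reads = as.integer(spike_count),
         spike_sequence = spike_sequence, mode = mode, s1_treated = s1_treated)
  })
}
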