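#' Extract the reverse-transcribed template region from an ncRNA
#'
#' In `"coordinates"` mode the annotated `template_start`/`template_end`
#' interval is returned. In `"aca_motif"` mode the template is located by its
#' conserved "ACA" brackets: the first bracket is the nearest ACA at or left
#' of `approx_start` (the first bracket is part of the template itself), and
#' the second bracket is the nearest downstream ACA whose implied template
#' length falls within `length_band`. The template runs from the first
#' bracket (inclusive) to the base immediately before the second bracket.
#'
#' @param locus An [ncrna_locus()] (or a plain DNA string in `aca_motif` mode).
#' @param mode `"coordinates"` or `"aca_motif"`.
#' @param approx_start Approximate 1-based template start used to pick the
#'   first bracket in `aca_motif` mode (default: the annotated start).
#' @param length_band Acceptable template lengths for the second bracket
#'   (default `c(90, 150)`, covering the observed ortholog range 111-129).
#'
#' @return List with `template` (DNA string), `start`, `end` (1-based
#'   inclusive interval on the ncRNA).
#' @export
#' @examples
#' loc <- ncrna_locus("toy", "GGACAGGGTTTACAGG", template_start = 3,
#'                    template_end = 11, pbs_interval = c(5, 9))
#' extract_template(loc, "aca_motif", approx_start = 3, length_band = c(5, 20))
extract_template <- function(locus, mode = c("coordinates", "aca_motif"),
                             approx_start = NULL, length_band = c(90, 150)) {
  mode <- match.arg(mode)
  if (is.character(locus)) {
    sequence <- assert_dna(locus, "locus")
    if (mode == "coordinates")
      stop("coordinates mode requires an ncrna_locus object", call. = FALSE)
    if (is.null(approx_start)) approx_start <- 1L
  } else {
    stopifnot(inherits(locus, "ncrna_locus"))
    sequence <- locus$sequence
    if (is.null(approx_start)) approx_start <- locus$template_start
  }

  if (mode == "coordinates") {
    s <- locus$template_start; e <- locus$template_end
    return(list(template = substr(sequence, s, e), start = s, end = e))
  }

  aca <- find_motif(sequence, "ACA")
  first <- aca[aca <= approx_start]
  if (length(first) == 0)
    stop("bracket-not-found: no ACA at or left of position ", approx_start, call. = FALSE)
  first <- max(first)
  cand <- aca[aca > first]
  cand <- cand[(cand - first) >= length_band[1] & (cand - first) <= length_band[2]]
  if (length(cand) == 0)
    stop("bracket-not-found: no downstream ACA with implied template length in [",
         length_band[1], ",", length_band[2], "]", call. = FALSE)
  second <- min(cand)
  list(template = substr(sequence, first, second - 1L),
       start = first, end = second - 1L)
}

#' Build theoretical concatemeric cDNA from a template
#'
#' Reverse-complements the template (first-strand cDNA orientation) and
#' concatenates `n` copies, recording the repeat junction positions. This is
#' the in-silico equivalent of rolling reverse transcription producing tandem
#' repeats of the template.
#'
#' @param template DNA string over A/C/G/T (the ncRNA template region, sense
#'   orientation), or the result of [extract_template()].
#' @param n Positive integer number of repeats.
#'
#' @return A `ccdna_construct`: list with `repeat_unit`, `n_repeats`,
#'   `sequence` and `junction_positions` (the last base of each repeat except
#'   the final one; the boundary lies between `j` and `j + 1`).
#' @export
#' @examples
#' concatemerize("ACAGTT", 3)$sequence  # "AACTGTAACTGTAACTGT"
concatemerize <- function(template, n) {
  if (is.list(template)) template <- template$template
  assert_dna(template, "template")
  if (length(n) != 1 || is.na(n) || n < 1 || n != as.integer(n))
    stop("n must be a positive integer", call. = FALSE)
  n <- as.integer(n)
  unit <- revcomp(template)
  L <- nchar(unit)
  structure(
    list(repeat_unit = unit, n_repeats = n,
         sequence = strrep(unit, n),
         junction_positions = if (n > 1) L * seq_len(n - 1L) else integer()),
    class = "ccdna_construct"
  )
}

#' @export
print.ccdna_construct <- function(x, ...) {
  cat(sprintf("<ccdna_construct> %d x %d nt repeat (%d nt, %d junctions)\n",
              x$n_repeats, nchar(x$repeat_unit), nchar(x$sequence),
              length(x$junction_positions)))
  invisible(x)
}

as_ccdna <- function(x) {
  if (inherits(x, "ccdna_construct")) return(x)
  assert_dna(x, "ccdna")
  structure(list(repeat_unit = x, n_repeats = 1L, sequence = x,
                 junction_positions = integer()),
            class = "ccdna_construct")
}

#' Scan ccDNA for sigma-70 promoters
#'
#' Finds canonical promoter calls: a -35 element upstream of a -10 element
#' with a spacer within `spacer_range` (the sigma-70 consensus spacing is
#' 17 bp). Within a single repeat of DRT2-type ccDNA the two hexamers are out
#' of order with a 91-bp gap, so a canonical promoter only appears when
#' adjacent repeats juxtapose the -10 of one repeat with the -35 of the next.
#' When no canonical call exists, out-of-order arrangements (-10 upstream of
#' -35) are reported as diagnostics with their observed gap.
#'
#' @param ccdna A `ccdna_construct` (from [concatemerize()]) or DNA string.
#' @param minus10_motif,minus35_motif Consensus hexamers (defaults TATAAT and
#'   TTGACA).
#' @param spacer_range Inclusive spacer bounds for a canonical call
#'   (default `c(15, 19)`).
#' @param max_mismatch Allowed mismatches per motif (default 0: exact
#'   consensus).
#'
#' @return data.frame with one row per call: motif intervals, `spacer_bp`,
#'   `spans_junction` and `arrangement` (`"canonical"` or `"out_of_order"`).
#'   Zero rows is a valid result.
#' @export
scan_promoters <- function(ccdna, minus10_motif = "TATAAT",
                           minus35_motif = "TTGACA",
                           spacer_range = c(15, 19), max_mismatch = 0) {
  cc <- as_ccdna(ccdna)
  seqs <- cc$sequence
  m10 <- find_motif(seqs, minus10_motif, max_mismatch)
  m35 <- find_motif(seqs, minus35_motif, max_mismatch)
  w10 <- nchar(minus10_motif); w35 <- nchar(minus35_motif)
  junc <- cc$junction_positions

  spans <- function(a, b) vapply(seq_along(a), function(i)
    any(junc >= a[i] & junc < b[i]), logical(1))

  calls <- data.frame(minus35_start = integer(), minus35_end = integer(),
                      minus10_start = integer(), minus10_end = integer(),
                      spacer_bp = integer(), spans_junction = logical(),
                      arrangement = character())
  if (length(m10) && length(m35)) {
    grid <- expand.grid(p35 = m35, p10 = m10)
    grid$spacer <- grid$p10 - (grid$p35 + w35 - 1L) - 1L
    canon <- grid[grid$spacer >= spacer_range[1] & grid$spacer <= spacer_range[2], ]
    if (nrow(canon)) {
      calls <- data.frame(
        minus35_start = canon$p35, minus35_end = canon$p35 + w35 - 1L,
        minus10_start = canon$p10, minus10_end = canon$p10 + w10 - 1L,
        spacer_bp = as.integer(canon$spacer),
        spans_junction = spans(canon$p35, canon$p10 + w10 - 1L),
        arrangement = "canonical")
      calls <- calls[order(calls$minus35_start), , drop = FALSE]
      rownames(calls) <- NULL
      return(calls)
    }
  }
  ## no canonical call: report out-of-order arrangements (-10 before -35)
  if (length(m10) && length(m35)) {
    rows <- lapply(m10, function(p10) {
      after <- m35[m35 > p10 + w10 - 1L]
      if (!length(after)) return(NULL)
      p35 <- min(after)
      data.frame(minus35_start = p35, minus35_end = p35 + w35 - 1L,
                 minus10_start = p10, minus10_end = p10 + w10 - 1L,
                 spacer_bp = p35 - (p10 + w10 - 1L) - 1L,
                 spans_junction = any(junc >= p10 & junc < p35 + w35 - 1L),
                 arrangement = "out_of_order")
    })
    rows <- do.call(rbind, rows)
    if (!is.null(rows)) {
      rownames(rows) <- NULL
      return(rows)
    }
  }
  calls
}

#' Scan reading frames of a ccDNA concatemer
#'
#' For each frame offset 0-2 of the full concatemer, reports stop-codon
#' positions, the first start codon, whether the repeat length preserves
#' frame across junctions (length divisible by three) and, for stop-free
#' frames in multi-repeat constructs, the junction-spanning flag and the
#' translated protein. A repeat length not divisible by three shifts frame at
#' every junction, so stop-free junction-spanning frames essentially require
#' the mod-3 rule.
#'
#' @param ccdna A `ccdna_construct` or DNA string.
#' @return data.frame with one row per frame: `frame` (0-2), `start_position`
#'   (first in-frame ATG, NA if none), `n_stops`, `stop_positions` (list
#'   column of 1-based codon starts), `frame_preserving`, `stop_free`,
#'   `spans_junction`, `translation` (NA unless stop-free).
#' @export
scan_orfs <- function(ccdna) {
  cc <- as_ccdna(ccdna)
  s <- cc$sequence
  n <- nchar(s)
  if (n < 3) stop("sequence shorter than one codon", call. = FALSE)
  fp <- nchar(cc$repeat_unit) %% 3L == 0L
  rows <- lapply(0:2, function(f) {
    starts <- seq.int(1L + f, n - 2L, by = 3L)
    codons <- substring(s, starts, starts + 2L)
    stop_pos <- starts[codons %in% STOP_CODONS]
    atg <- starts[codons == "ATG"]
    stop_free <- length(stop_pos) == 0L
    data.frame(frame = f,
               start_position = if (length(atg)) atg[1] else NA_integer_,
               n_stops = length(stop_pos),
               frame_preserving = fp,
               stop_free = stop_free,
               spans_junction = stop_free && cc$n_repeats >= 2L,
               translation = if (stop_free)
                 translate_dna(substr(s, 1L + f, n)) else NA_character_)
  })
  out <- do.call(rbind, rows)
  out$stop_positions <- lapply(0:2, function(f) {
    starts <- seq.int(1L + f, n - 2L, by = 3L)
    starts[substring(s, starts, starts + 2L) %in% STOP_CODONS]
  })
  out[, c("frame", "start_position", "n_stops", "stop_positions",
          "frame_preserving", "stop_free", "spans_junction", "translation")]
}

#' Locate the ribosome-binding site and start codon downstream of a promoter
#'
#' Reports the window beginning `offset` nt after the end of the -10 motif of
#' a canonical promoter call, the first ATG within that window, and any RBS
#' motif (default "GAG") between the -10 element and the start codon.
#'
#' @param ccdna A `ccdna_construct` or DNA string.
#' @param promoter One canonical row from [scan_promoters()].
#' @param offset Gap in nt between the -10 motif end and the window start
#'   (default 13, matching the conserved start-codon placement).
#' @param window Window length in nt (default 15).
#' @param rbs_motif RBS consensus to search for (default `"GAG"`).
#'
#' @return List: `window` (start, end; possibly truncated with a warning),
#'   `start_codon` (1-based ATG position or NA), `rbs` (1-based motif
#'   position or NA), `truncated` flag.
#' @export
locate_rbs <- function(ccdna, promoter, offset = 13, window = 15,
                       rbs_motif = "GAG") {
  cc <- as_ccdna(ccdna)
  if (is.data.frame(promoter)) {
    if (nrow(promoter) != 1)
      stop("promoter must be a single call (one row)", call. = FALSE)
    if (promoter$arrangement != "canonical")
      stop("promoter must be a canonical call", call. = FALSE)
    m10_end <- promoter$minus10_end
  } else m10_end <- as.integer(promoter)
  n <- nchar(cc$sequence)
  win_start <- m10_end + offset + 1L
  win_end <- win_start + window - 1L
  truncated <- FALSE
  if (win_start > n)
    stop("window lies entirely past the sequence end", call. = FALSE)
  if (win_end > n) {
    warning("window truncated at sequence end")
    win_end <- n
    truncated <- TRUE
  }
  win_seq <- substr(cc$sequence, win_start, win_end)
  atg <- find_motif(win_seq, "ATG")
  start_codon <- if (length(atg)) win_start + atg[1] - 1L else NA_integer_
  rbs_end <- if (!is.na(start_codon)) start_codon - 1L else win_end
  rbs_region <- substr(cc$sequence, m10_end + 1L, rbs_end)
  rbs_hits <- find_motif(rbs_region, rbs_motif)
  rbs <- if (length(rbs_hits)) m10_end + rbs_hits[length(rbs_hits)] else NA_integer_
  list(window = c(win_start, win_end), start_codon = start_codon,
       rbs = rbs, truncated = truncated)
}

#' In-silico restriction digest
#'
#' Cuts a sequence at every occurrence of an IUPAC site pattern,
#' `cut_offset` bases into the site (default `G^ANTC`, the HinfI cut), and
#' returns ordered fragment lengths. Fragment lengths always sum to the input
#' length. Each ccDNA repeat of the reference locus contains one GANTC site,
#' so a digest of multi-repeat ccDNA yields internal fragments of exactly the
#' repeat length.
#'
#' @param sequence DNA string.
#' @param site IUPAC site pattern (default `"GANTC"`, HinfI).
#' @param cut_offset Bases into the site after which the cut occurs
#'   (default 1: after the G).
#' @return Integer vector of fragment lengths, 5' to 3'.
#' @export
#' @examples
#' digest_sequence("AAGAATCAA")  # 3, 6
digest_sequence <- function(sequence, site = "GANTC", cut_offset = 1) {
  assert_dna(sequence)
  starts <- find_iupac(sequence, site)
  cuts <- sort(unique(starts + cut_offset - 1L))
  cuts <- cuts[cuts >= 1 & cuts < nchar(sequence)]
  as.integer(diff(c(0L, cuts, nchar(sequence))))
}
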