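#' Quantify template jumps from window assignments
#'
#' A jump is a non-adjacent mapping of adjacent k-mers: for each pair of
#' successive mapped windows the expected next anchor is the current anchor
#' plus one (plus strand) or minus one (minus strand) per window step; any
#' same-strand deviation beyond `diagonal_tolerance`, or any strand change,
#' is emitted as a jump. Unmapped windows are skipped, and a pair is only
#' evaluated when at most `max_skip` unmapped windows separate it (a single
#' base error voids k windows; a repeat junction voids k - 1 minus the
#' junction micro-homology, so the default of 3k tolerates a junction with
#' two clustered flanking errors without splitting the read).
#'
#' Jump coordinates follow the jump-map convention: `from_position` is the
#' mapped position of the 3' base of the 5' window (minus strand: anchor
#' minus k - 1; plus strand: anchor plus k - 1) and `to_position` is the
#' mapped position of the 5' base of the 3' window (its anchor). A read
#' crossing one tandem-repeat junction of the reference locus therefore
#' yields a jump from minus-strand base 29 to minus-strand base 148.
#'
#' Junction breakpoints can carry micro-homology: the template starts with
#' the leading ACA bracket and is followed immediately by the second
#' bracket, so the first bases synthesized after a tandem jump (TGT, the
#' reverse complement of ACA) are identical to the bracket region just past
#' the template end, and windows spanning the junction map a few bases into
#' the bracket (the telomerase-like alignment region). Sequencing errors
#' have the opposite effect, truncating the flanking runs. When
#' `template_interval` is supplied, each endpoint of a same-strand jump is
#' therefore snapped to its template boundary whenever its extrapolated
#' diagonal reaches the boundary within the voided run, recovering the
#' mechanistic coordinates (e.g. 29 to 148 rather than 29 to 151);
#' strand-change jumps are never snapped.
#'
#' @param assignments data.frame from [segment_read()] (one read).
#' @param k Window length used for segmentation (default 11).
#' @param diagonal_tolerance Maximum same-strand deviation from the expected
#'   position that is still called contiguous (default 0; use about 3 for
#'   error-bearing reads).
#' @param max_skip Maximum run of unmapped windows across which a pair is
#'   still evaluated (default `3 * k`).
#' @param template_interval Optional `c(start, end)` of the template on the
#'   ncRNA, enabling micro-homology canonicalization of breakpoints.
#' @return data.frame with columns `read_id`, `from_position`, `from_strand`,
#'   `to_position`, `to_strand` (zero rows if the read is contiguous).
#' @export
quantify_jumps <- function(assignments, k = 11L, diagonal_tolerance = 0,
                           max_skip = 3L * k, template_interval = NULL) {
  empty <- data.frame(read_id = character(), from_position = integer(),
                      from_strand = character(), to_position = integer(),
                      to_strand = character())
  keep <- assignments$strand != "unmapped" & !is.na(assignments$position)
  off <- assignments$read_offset[keep]
  pos <- assignments$position[keep]
  strand <- assignments$strand[keep]
  n <- length(off)
  if (n < 2) return(empty)

  ia <- seq_len(n - 1L); ib <- ia + 1L
  gap <- off[ib] - off[ia]                         # window step, >= 1
  dir_a <- ifelse(strand[ia] == "plus", 1L, -1L)
  dir_b <- ifelse(strand[ib] == "plus", 1L, -1L)
  expected <- pos[ia] + dir_a * gap
  is_jump <- (gap - 1L <= max_skip) &              # beyond max_skip: split, no call
    (strand[ia] != strand[ib] | abs(pos[ib] - expected) > diagonal_tolerance)
  if (!any(is_jump)) return(empty)
  ia <- ia[is_jump]; ib <- ib[is_jump]
  gap <- gap[is_jump]; dir_a <- dir_a[is_jump]; dir_b <- dir_b[is_jump]

  from_pos <- pos[ia] + dir_a * (k - 1L)           # 3' base of the 5' window
  to_pos <- pos[ib]                                # 5' base of the 3' window
  if (!is.null(template_interval)) {
    ## Junction breakpoints are unidentifiable inside the voided window run
    ## (micro-homology lets windows over-run into the bracket by up to
    ## k - 1 bases; errors truncate runs by up to the void length g). Snap
    ## each endpoint of a same-strand jump to its template boundary when
    ## its diagonal, extrapolated through the void, reaches the boundary
    ## within that slack; this recovers the mechanistic coordinates
    ## (29 -> 148 on the minus strand, 148 -> 29 on the plus strand).
    g <- gap - 1L                                  # voided windows
    ts <- template_interval[1]; te <- template_interval[2]
    same <- strand[ia] == strand[ib]
    b_pre <- ifelse(dir_a > 0, te, ts)
    b_post <- ifelse(dir_b > 0, ts, te)
    rem_pre <- dir_a * (b_pre - from_pos)
    rem_post <- dir_b * (to_pos - b_post)
    snap_pre <- same & rem_pre >= -(k - 1L) & rem_pre <= g
    snap_post <- same & rem_post >= -(k - 1L) & rem_post <= g
    from_pos[snap_pre] <- b_pre[snap_pre]
    to_pos[snap_post] <- b_post[snap_post]
  }
  data.frame(read_id = assignments$read_id[keep][ia],
             from_position = as.integer(from_pos),
             from_strand = strand[ia],
             to_position = as.integer(to_pos),
             to_strand = strand[ib])
}

#' Classify template jumps into mechanistic categories
#'
#' Categories follow the strand pair of each jump: Category 1 are
#' minus-to-minus jumps (tandem-repeat synthesis, canonically from the
#' template start back to its end); Category 2 are minus-to-plus reversals
#' (the RT switching to second-strand synthesis); Category 3 are
#' plus-to-plus jumps across repeat junctions (second-strand tandem
#' repeats); Category 4 are plus-to-minus jumps (read-through from the
#' primer-binding site into the ncRNA 3' domain).
#'
#' @param jumps data.frame from [quantify_jumps()] (any number of reads).
#' @param locus Optional [ncrna_locus()]; currently informational only, the
#'   classification is fully determined by the strand pair.
#' @return List: `jumps` (input with an integer `category` column) and
#'   `fractions` (named fractions of categories 1-4 over all off-diagonal
#'   jumps).
#' @export
classify_jumps <- function(jumps, locus = NULL) {
  cat_of <- function(from, to) {
    ifelse(from == "minus" & to == "minus", 1L,
    ifelse(from == "minus" & to == "plus", 2L,
    ifelse(from == "plus" & to == "plus", 3L, 4L)))
  }
  jumps$category <- if (nrow(jumps)) cat_of(jumps$from_strand, jumps$to_strand) else integer()
  counts <- tabulate(jumps$category, nbins = 4)
  fractions <- if (sum(counts) > 0) counts / sum(counts) else rep(NA_real_, 4)
  names(fractions) <- paste0("category", 1:4)
  list(jumps = jumps, fractions = fractions)
}

#' Aggregate jumps into a jump-map count table
#'
#' Counts jumps by their (from, to) signed coordinates, the table plotted as
#' a jump map (y: 3' base of the 5' window; x: 5' base of the 3' window).
#' The table total equals the number of jump pairs counted.
#'
#' @param jumps data.frame from [quantify_jumps()] or
#'   `classify_jumps()$jumps`.
#' @return data.frame with `from_position`, `from_strand`, `to_position`,
#'   `to_strand` (and `category` if present) plus a count column `n`, sorted
#'   by decreasing count.
#' @export
jump_map <- function(jumps) {
  keys <- intersect(c("from_position", "from_strand", "to_position",
                      "to_strand", "category"), names(jumps))
  if (nrow(jumps) == 0) {
    out <- jumps[, keys, drop = FALSE]
    out$n <- integer()
    return(out)
  }
  agg <- stats::aggregate(list(n = rep(1L, nrow(jumps))), jumps[keys], sum)
  agg[order(-agg$n), , drop = FALSE]
}

#' Per-read repeat structure
#'
#' Derives the (x, y) repeat structure of a read from its window assignments:
#' x minus-strand repeats (Category-1 junction jumps plus one, when any
#' minus-strand windows exist) followed by y plus-strand repeats (Category-3
#' jumps plus one). Hairpin reads produced by reversal onto the nascent
#' strand satisfy y <= x mechanistically. Also reports the mapped position
#' of the first window, whether the read starts at the primer (first window
#' mapped to the minus strand at the primer-binding-site end) and whether
#' any Category-4 read-through jump is present.
#'
#' @param assignments data.frame from [segment_read()] (one read, adapters
#'   trimmed).
#' @param locus [ncrna_locus()] providing the PBS interval.
#' @param k,diagonal_tolerance,max_skip Passed to [quantify_jumps()].
#' @return One-row data.frame: `read_id`, `n_minus_repeats`,
#'   `n_plus_repeats`, `total_repeats`, `start_position`, `start_strand`,
#'   `has_primer_start`, `readthrough`.
#' @export
read_structure <- function(assignments, locus, k = 11L,
                           diagonal_tolerance = 0, max_skip = 3L * k) {
  jumps <- classify_jumps(quantify_jumps(
    assignments, k = k, diagonal_tolerance = diagonal_tolerance,
    max_skip = max_skip,
    template_interval = c(locus$template_start, locus$template_end)))$jumps
  mapped <- assignments[assignments$strand != "unmapped", , drop = FALSE]
  read_id <- if (nrow(assignments)) assignments$read_id[1] else NA_character_
  if (nrow(mapped) == 0) {
    return(data.frame(read_id = read_id, n_minus_repeats = 0L,
                      n_plus_repeats = 0L, total_repeats = 0L,
                      start_position = NA_integer_, start_strand = NA_character_,
                      has_primer_start = FALSE, readthrough = FALSE))
  }
  x <- sum(jumps$category == 1L) + as.integer(any(mapped$strand == "minus"))
  y <- sum(jumps$category == 3L) + as.integer(any(mapped$strand == "plus"))
  first <- mapped[1, ]
  data.frame(read_id = read_id,
             n_minus_repeats = x, n_plus_repeats = y, total_repeats = x + y,
             start_position = first$position, start_strand = first$strand,
             has_primer_start = first$read_offset == 0L &&
               first$strand == "minus" &&
               first$position == locus$pbs_interval[2],
             readthrough = any(jumps$category == 4L))
}
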