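#' Profile bases appended after the ncRNA 3' end
#'
#' Anchors each read at the ncRNA 3' terminus by exact match of the ncRNA's
#' terminal `anchor_len` bases, collects the bases appended after the
#' terminus, and returns a position frequency matrix plus the majority-rule
#' consensus. For the reference RNP the consensus of the appended bases is
#' the DNA primer "GATAT" directly after the final ncRNA base; a
#' primer-binding-site mutant yields the reverse complement of its mutant
#' PBS, and an RT-dead preparation yields an empty consensus.
#'
#' @param reads Character vector of read sequences covering the ncRNA 3'
#'   terminus.
#' @param locus [ncrna_locus()].
#' @param anchor_len Length of the exact terminal match used to anchor reads
#'   (default 15).
#' @param max_positions Maximum number of appended positions profiled
#'   (default 10).
#' @param min_frac Minimum fraction of anchored reads that must cover a
#'   position (and agree by plurality) for it to enter the consensus
#'   (default 0.5).
#' @return List: `pfm` (4 x positions base count matrix), `consensus`
#'   (character string, possibly empty), `n_anchored`.
#' @export
detect_3prime_extension <- function(reads, locus, anchor_len = 15L,
                                    max_positions = 10L, min_frac = 0.5) {
  ncrna <- locus$sequence
  n <- nchar(ncrna)
  anchor <- substr(ncrna, n - anchor_len + 1L, n)
  tails <- character()
  for (r in reads) {
    hit <- regexpr(anchor, r, fixed = TRUE)
    if (hit == -1) next
    tails <- c(tails, substr(r, hit + anchor_len, nchar(r)))
  }
  if (length(tails) == 0) {
    warning("no reads anchored at the ncRNA 3' terminus")
    return(list(pfm = matrix(0L, 4, 0, dimnames = list(DNA_BASES, NULL)),
                consensus = "", n_anchored = 0L))
  }
  width <- min(max(nchar(tails)), max_positions)
  pfm <- matrix(0L, nrow = 4, ncol = width,
                dimnames = list(DNA_BASES, seq_len(width)))
  if (width > 0) {
    for (j in seq_len(width)) {
      b <- substr(tails, j, j)
      tab <- table(factor(b[b %in% DNA_BASES], levels = DNA_BASES))
      pfm[, j] <- as.integer(tab)
    }
  }
  consensus <- character()
  for (j in seq_len(ncol(pfm))) {
    col <- pfm[, j]
    if (sum(col) < min_frac * length(tails)) break
    top <- which.max(col)
    if (col[top] < min_frac * sum(col)) break
    consensus <- c(consensus, DNA_BASES[top])
  }
  list(pfm = pfm, consensus = paste(consensus, collapse = ""),
       n_anchored = length(tails))
}

#' Layout table for chimeric-read visualisation
#'
#' For each read, finds the longest run of consecutively mapping windows
#' (same strand, anchors stepping by one per window; leftmost run on ties).
#' Windows in the run take their mapped positions as x coordinates; all
#' other windows are placed at read-relative offsets extrapolated from the
#' run, so chimeric reads show disjunct segments extending past the template
#' boundary. Each segment is coloured by its own mapped position.
#'
#' @param assignment_list List of data.frames from [segment_read()], one per
#'   read.
#' @return List: `segments` data.frame (`read_id`, `y` read rank,
#'   `read_offset`, `x`, `color_position`, `in_run`) and `n_excluded`, the
#'   number of reads with no mapped windows (excluded from the layout).
#' @export
layout_chimeric_reads <- function(assignment_list) {
  segs <- list()
  n_excluded <- 0L
  rank <- 0L
  for (asn in assignment_list) {
    mapped_idx <- which(asn$strand != "unmapped")
    if (length(mapped_idx) == 0) { n_excluded <- n_excluded + 1L; next }
    rank <- rank + 1L
    run <- longest_consecutive_run(asn)
    a <- asn[run[1], ]
    dir <- if (a$strand == "plus") 1L else -1L
    x <- a$position + dir * (asn$read_offset - a$read_offset)
    x[run] <- asn$position[run]
    segs[[rank]] <- data.frame(read_id = asn$read_id[1], y = rank,
                               read_offset = asn$read_offset, x = x,
                               color_position = asn$position,
                               in_run = seq_len(nrow(asn)) %in% run)
  }
  segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(read_id = character(), y = integer(), read_offset = integer(),
               x = integer(), color_position = integer(), in_run = logical())
  rownames(segments) <- NULL
  list(segments = segments, n_excluded = n_excluded)
}

## indices (rows of `asn`) of the longest run of consecutively mapping
## windows; leftmost run wins ties
longest_consecutive_run <- function(asn) {
  n <- nrow(asn)
  best <- integer(); cur <- integer()
  for (i in seq_len(n)) {
    if (asn$strand[i] == "unmapped") {
      if (length(cur) > length(best)) best <- cur
      cur <- integer()
      next
    }
    extends <- length(cur) > 0 && {
      j <- cur[length(cur)]
      step <- if (asn$strand[j] == "plus") 1L else -1L
      asn$strand[i] == asn$strand[j] &&
        asn$read_offset[i] == asn$read_offset[j] + 1L &&
        asn$position[i] == asn$position[j] + step
    }
    cur <- if (extends) c(cur, i) else i
    if (length(cur) > length(best)) best <- cur
  }
  best
}

#' Strand-specific read counts with spike-in normalization
#'
#' Raw plus/minus read counts for template-mapping reads (any read mapping
#' within the template region) and junction-containing reads (any read
#' containing juxtaposed template regions, i.e. a repeat-junction jump),
#' together with the spike-in read count and the culture-volume equivalents
#' of the library input.
#'
#' @param template_plus,template_minus,junction_plus,junction_minus Raw read
#'   counts.
#' @param spike_reads Reads mapping to the single-strand DNA control.
#' @param volume_equivalents Culture-volume scale factor (default 1).
#' @return Object of class `strand_counts`.
#' @export
strand_counts <- function(template_plus = 0, template_minus = 0,
                          junction_plus = 0, junction_minus = 0,
                          spike_reads = 0, volume_equivalents = 1) {
  structure(list(raw = c(template_plus = unname(template_plus),
                         template_minus = unname(template_minus),
                         junction_plus = unname(junction_plus),
                         junction_minus = unname(junction_minus)),
                 spike_reads = spike_reads,
                 volume_equivalents = volume_equivalents,
                 normalized = NULL),
            class = "strand_counts")
}

#' Normalize strand-specific counts by spike-in and volume
#'
#' `normalized = raw / (spike_reads * volume_equivalents)`; doubling the
#' spike count halves every normalized count (scale equivariance).
#'
#' @param counts A [strand_counts()].
#' @return The input with its `normalized` field filled.
#' @export
#' @examples
#' normalize_strand_counts(strand_counts(template_minus = 100,
#'   spike_reads = 10, volume_equivalents = 2))$normalized["template_minus"]
normalize_strand_counts <- function(counts) {
  stopifnot(inherits(counts, "strand_counts"))
  if (counts$spike_reads <= 0)
    stop("normalization error: spike_reads must be > 0", call. = FALSE)
  if (counts$volume_equivalents <= 0)
    stop("normalization error: volume_equivalents must be > 0", call. = FALSE)
  counts$normalized <- counts$raw / (counts$spike_reads * counts$volume_equivalents)
  counts
}

#' Tally strand-specific short reads into raw counts
#'
#' Segments each read against the ncRNA k-mer index; a read is
#' template-mapping when any window maps within the template interval and
#' junction-containing when it additionally carries a same-strand
#' repeat-junction jump. Counts are split by the supplied strand labels.
#'
#' @param reads Character vector of read sequences.
#' @param strand_label Character vector (`"plus"`/`"minus"`) per read.
#' @param index [kmer_index()] of the locus.
#' @param locus [ncrna_locus()].
#' @param spike_reads,volume_equivalents Passed through to [strand_counts()].
#' @param diagonal_tolerance Passed to [quantify_jumps()].
#' @return A [strand_counts()] object.
#' @export
tally_strand_reads <- function(reads, strand_label, index, locus,
                               spike_reads = 1, volume_equivalents = 1,
                               diagonal_tolerance = 0) {
  counts <- c(template_plus = 0, template_minus = 0,
              junction_plus = 0, junction_minus = 0)
  for (i in seq_along(reads)) {
    asn <- segment_read(reads[i], index, read_id = paste0("r", i))
    mapped <- asn[asn$strand != "unmapped", , drop = FALSE]
    in_template <- mapped$position >= locus$template_start &
      mapped$position <= locus$template_end
    if (!any(in_template)) next
    lab <- strand_label[i]
    counts[paste0("template_", lab)] <- counts[paste0("template_", lab)] + 1
    jj <- classify_jumps(quantify_jumps(asn, k = index$k,
                                        diagonal_tolerance = diagonal_tolerance))$jumps
    if (any(jj$category %in% c(1L, 3L)))
      counts[paste0("junction_", lab)] <- counts[paste0("junction_", lab)] + 1
  }
  strand_counts(counts["template_plus"], counts["template_minus"],
                counts["junction_plus"], counts["junction_minus"],
                spike_reads = spike_reads,
                volume_equivalents = volume_equivalents)
}
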