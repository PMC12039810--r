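#' Build an exact k-mer index of an ncRNA
#'
#' Indexes every k-mer of the ncRNA coding strand ("plus") and of its reverse
#' complement ("minus", the orientation of first-strand cDNA). The stored
#' position is the ncRNA coordinate of the k-mer's first base in read
#' orientation: a plus-strand k-mer starting at ncRNA position `p` is
#' anchored at `p`; the minus-strand k-mer covering the same bases is
#' anchored at `p + k - 1` (its first base pairs with that coordinate).
#' K-mers occurring more than once across the union of both strands are
#' recorded as ambiguous and excluded from mapping, since jump analysis
#' relies on unique hashing. The index also reports `min_unique_k`, the
#' smallest k at which every k-mer across both strands is unique (NA if none
#' exists, e.g. for a perfect palindrome).
#'
#' @param ncrna DNA string or [ncrna_locus()].
#' @param k Window length (default 11, the minimum unique length for the
#'   reference 280-nt ncRNA).
#' @return Object of class `kmer_index`.
#' @export
#' @examples
#' kmer_index("AAAAC", k = 4)$min_unique_k  # 4
kmer_index <- function(ncrna, k = 11L) {
  if (inherits(ncrna, "ncrna_locus")) ncrna <- ncrna$sequence
  assert_dna(ncrna, "ncrna")
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  n <- nchar(ncrna)
  if (n < k) stop("sequence shorter than k", call. = FALSE)

  plus <- kmers_of(ncrna, k)
  minus <- revcomp(plus)
  kmer <- c(plus, minus)
  pos <- c(seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  strand <- rep(c("plus", "minus"), each = n - k + 1L)
  dup <- kmer[duplicated(kmer)]
  ambiguous <- unique(dup)
  keep <- !(kmer %in% ambiguous)

  min_unique_k <- NA_integer_
  for (kk in seq_len(n)) {
    u <- kmers_of(ncrna, kk)
    all_k <- c(u, revcomp(u))
    if (!anyDuplicated(all_k)) { min_unique_k <- kk; break }
  }

  structure(list(k = k, kmer = kmer[keep], pos = pos[keep],
                 strand = strand[keep], ambiguous = ambiguous,
                 min_unique_k = min_unique_k, ncrna_length = n),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k=%d over %d nt: %d unique k-mers, %d ambiguous, min_unique_k=%s\n",
              x$k, x$ncrna_length, length(x$kmer), length(x$ambiguous),
              ifelse(is.na(x$min_unique_k), "NA", x$min_unique_k)))
  invisible(x)
}

#' Segment a read into consecutive k-mer window assignments
#'
#' Slides a k-length window along the read one base at a time and assigns
#' each window its mapped ncRNA position and strand from the index, or
#' `"unmapped"` for windows absent from the index (sequencing errors,
#' adapters, junction-spanning chimeric windows) or ambiguous.
#'
#' @param read DNA string.
#' @param index A [kmer_index()].
#' @param read_id Optional identifier carried into the output.
#' @return data.frame with columns `read_id`, `read_offset` (0-based window
#'   start in the read), `position` (1-based ncRNA anchor coordinate or NA),
#'   `strand` (`"plus"`, `"minus"` or `"unmapped"`). Mapped plus unmapped
#'   window counts always equal `nchar(read) - k + 1`.
#' @export
segment_read <- function(read, index, read_id = "read") {
  stopifnot(inherits(index, "kmer_index"))
  k <- index$k
  n <- nchar(read)
  if (n < k) {
    warning("read shorter than k; empty segmentation")
    return(data.frame(read_id = character(), read_offset = integer(),
                      position = integer(), strand = character()))
  }
  km <- kmers_of(read, k)
  hit <- match(km, index$kmer)
  data.frame(read_id = read_id,
             read_offset = 0:(n - k),
             position = ifelse(is.na(hit), NA_integer_, index$pos[hit]),
             strand = ifelse(is.na(hit), "unmapped", index$strand[hit]))
}
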