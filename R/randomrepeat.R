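#' Specification for randomized ccDNA repeats
#'
#' Describes the fixed sequence elements of a ccDNA repeat whose positions
#' are conserved in the randomized null: the internal -10 element (TATAAT),
#' -35 element (TTGACA), repeat junction pentamer (TGTTA, wrapping the repeat
#' boundary) and ribosome-binding site (GAG). All other positions are filled
#' with codons drawn uniformly from the 61 sense codons. The null controls
#' for nucleotide-level selection when assessing amino-acid properties of the
#' encoded repeat protein.
#'
#' @param repeat_length Repeat unit length (default 120).
#' @param fixed_elements Named list of `list(seq =, pos =)` entries; element
#'   positions are 1-based repeat coordinates and may wrap cyclically past
#'   the repeat end (the junction does). Defaults follow the reference
#'   repeat geometry: -10 at 13, RBS at 24, -35 at `repeat_length - 10`,
#'   junction TGTTA at `repeat_length - 2`.
#' @param n_concat Number of repeats concatemerized before translation
#'   (default 20).
#' @param seed Integer seed; the generated repeat is deterministic given the
#'   seed.
#' @return Object of class `random_repeat_spec`.
#' @export
random_repeat_spec <- function(repeat_length = 120L, fixed_elements = NULL,
                               n_concat = 20L, seed = NULL) {
  repeat_length <- as.integer(repeat_length)
  if (is.null(fixed_elements)) {
    fixed_elements <- list(
      minus10  = list(seq = "TATAAT", pos = 13L),
      rbs      = list(seq = "GAG",    pos = 24L),
      minus35  = list(seq = "TTGACA", pos = repeat_length - 10L),
      junction = list(seq = "TGTTA",  pos = repeat_length - 2L)
    )
  }
  occupied <- integer()
  for (el in fixed_elements) {
    idx <- ((el$pos - 1L) + seq_len(nchar(el$seq)) - 1L) %% repeat_length + 1L
    if (any(idx %in% occupied))
      stop("layout error: fixed elements overlap", call. = FALSE)
    occupied <- c(occupied, idx)
  }
  structure(list(repeat_length = repeat_length,
                 fixed_elements = fixed_elements,
                 codon_alphabet = sense_codons(),
                 n_concat = as.integer(n_concat), seed = seed),
            class = "random_repeat_spec")
}

#' Generate a randomized ccDNA repeat and its concatemer translation
#'
#' Places the fixed elements of `spec` at their conserved positions and fills
#' every gap with codons sampled uniformly (with replacement) from the 61
#' sense codons, truncating the final codon of each gap to fit. The repeat is
#' concatemerized `n_concat` times and translated (frame offset 1, the
#' reading frame compatible with the fixed-element layout; stop codons appear
#' as `*` since random fill does not preserve an open frame).
#'
#' @param spec A [random_repeat_spec()].
#' @return List: `repeat_unit`, `concatemer` (a `ccdna_construct`),
#'   `translation`, `codon_alphabet`.
#' @export
random_repeat <- function(spec = random_repeat_spec()) {
  stopifnot(inherits(spec, "random_repeat_spec"))
  with_seed(spec$seed, {
    L <- spec$repeat_length
    chars <- rep(NA_character_, L)
    for (el in spec$fixed_elements) {
      idx <- ((el$pos - 1L) + seq_len(nchar(el$seq)) - 1L) %% L + 1L
      chars[idx] <- strsplit(el$seq, "")[[1]]
    }
    free <- which(is.na(chars))
    if (length(free)) {
      runs <- split(free, cumsum(c(1L, diff(free) != 1L)))
      for (run in runs) {
        need <- length(run)
        codons <- sample(spec$codon_alphabet, ceiling(need / 3), replace = TRUE)
        fill <- strsplit(paste(codons, collapse = ""), "")[[1]][seq_len(need)]
        chars[run] <- fill
      }
    }
    unit <- paste(chars, collapse = "")
    cc <- concatemerize(revcomp(unit), spec$n_concat)  # unit is already ccDNA-sense
    list(repeat_unit = unit,
         concatemer = cc,
         translation = translate_dna(substr(cc$sequence, 2, nchar(cc$sequence))),
         codon_alphabet = spec$codon_alphabet)
  })
}
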