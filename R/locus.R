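#' ncRNA locus with annotated template interval
#'
#' Container for a non-coding RNA locus of a DRT2-type defence system, stored
#' as its coding-strand DNA. The locus records the reverse-transcribed
#' template interval, the positions of the "ACA" bracket motifs that flank
#' the template (the first of which is part of the template), the
#' primer-binding site (PBS) and the short DNA primer covalently appended to
#' the ncRNA 3' end. All coordinates are 1-based inclusive.
#'
#' @param id Character label.
#' @param sequence DNA string (A/C/G/T) of the ncRNA coding strand.
#' @param template_start,template_end 1-based inclusive template interval
#'   (defaults 29 and `template_start + 119`, i.e. a 120-nt template).
#' @param aca_positions Integer vector of 1-based start positions of "ACA"
#'   bracket motifs (typically the template start and the position just after
#'   the template end).
#' @param pbs_interval 1-based inclusive interval of the primer-binding site;
#'   must lie within the template. Default: the 5 bases ending 2 nt before the
#'   template end, matching the reference geometry (bases 142-146 for a
#'   29-148 template).
#' @param primer DNA primer appended 3' of the ncRNA (default `"GATAT"`).
#' @param elements Optional named list describing fixed sequence elements of
#'   the repeat unit in repeat coordinates (used by the simulator).
#'
#' @return An object of class `ncrna_locus`.
#' @export
ncrna_locus <- function(id, sequence, template_start = 29L,
                        template_end = template_start + 119L,
                        aca_positions = integer(),
                        pbs_interval = NULL,
                        primer = "GATAT",
                        elements = NULL) {
  assert_dna(sequence)
  n <- nchar(sequence)
  template_start <- as.integer(template_start)
  template_end <- as.integer(template_end)
  if (template_start < 1 || template_end > n || template_start > template_end)
    stop("template interval [", template_start, ",", template_end,
         "] outside sequence of length ", n, call. = FALSE)
  if (is.null(pbs_interval))
    pbs_interval <- c(template_end - 6L, template_end - 2L)
  pbs_interval <- as.integer(pbs_interval)
  if (pbs_interval[1] < template_start || pbs_interval[2] > template_end)
    stop("pbs_interval must lie within the template interval", call. = FALSE)
  if (nchar(primer) > 0) assert_dna(primer, "primer")
  structure(
    list(id = id, sequence = sequence,
         template_start = template_start, template_end = template_end,
         aca_positions = as.integer(aca_positions),
         pbs_interval = pbs_interval, primer = primer,
         elements = elements),
    class = "ncrna_locus"
  )
}

#' @export
print.ncrna_locus <- function(x, ...) {
  cat(sprintf("<ncrna_locus> %s: %d nt, template %d-%d (%d nt), PBS %d-%d, primer %s\n",
              x$id, nchar(x$sequence), x$template_start, x$template_end,
              x$template_end - x$template_start + 1L,
              x$pbs_interval[1], x$pbs_interval[2], x$primer))
  invisible(x)
}

template_length <- function(locus) locus$template_end - locus$template_start + 1L
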