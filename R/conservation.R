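#' Alignment-column conservation profile
#'
#' Conservation is the difference between maximum entropy and the observed
#' Shannon entropy of each alignment column: `2 - H(column)` bits, with `H`
#' computed over A/C/G/T frequencies. An invariant column scores exactly
#' 2 bits; an equifrequent A/C/G/T column scores 0. Gaps are excluded from
#' the column frequencies; columns with more than `max_gap_frac` gaps are
#' reported as missing (NA). A centred moving average (window shrinking at
#' the edges) provides the smoothed track.
#'
#' @param alignment Character vector of equal-length gapped sequences (gap
#'   character `-`), or a list/`DNAStringSet` coercible to one.
#' @param window Smoothing window length in alignment columns (default 10).
#' @param max_gap_frac Columns with a higher gap fraction are set to NA
#'   (default 0.5).
#'
#' @return Object of class `conservation_profile`: list with `per_position`
#'   (bits), `smoothed`, `window`, `n_sequences`.
#' @export
conservation_profile <- function(alignment, window = 10, max_gap_frac = 0.5) {
  alignment <- toupper(as.character(alignment))
  if (length(alignment) < 2)
    stop("need at least 2 aligned sequences", call. = FALSE)
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1)
    stop("ragged alignment: sequences have unequal lengths", call. = FALSE)
  mat <- do.call(rbind, strsplit(alignment, ""))
  ncol_aln <- ncol(mat)
  per <- vapply(seq_len(ncol_aln), function(j) {
    col <- mat[, j]
    bases <- col[col %in% DNA_BASES]
    if (length(col) - length(bases) > max_gap_frac * length(col) ||
        length(bases) == 0) return(NA_real_)
    p <- table(factor(bases, levels = DNA_BASES)) / length(bases)
    p <- p[p > 0]
    2 - sum(-p * log2(p))
  }, numeric(1))
  smoothed <- moving_average(per, window)
  structure(list(per_position = per, smoothed = smoothed,
                 window = window, n_sequences = length(alignment)),
            class = "conservation_profile")
}

## centred moving average with shrinking windows at the edges; NAs ignored
moving_average <- function(x, window) {
  half_lo <- floor((window - 1) / 2)
  half_hi <- ceiling((window - 1) / 2)
  n <- length(x)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half_lo); hi <- min(n, i + half_hi)
    v <- x[lo:hi]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("<conservation_profile> %d columns, %d sequences, window %d; mean %.2f bits\n",
              length(x$per_position), x$n_sequences, x$window,
              mean(x$per_position, na.rm = TRUE)))
  invisible(x)
}

#' Theoretical protein properties
#'
#' GRAVY (grand average of hydropathy; mean Kyte-Doolittle hydropathy over
#' all residues) and the fraction of hydrophobic residues
#' (A, I, L, M, F, W, V), as used to characterise the strongly hydrophobic
#' repetitive Neo protein.
#'
#' @param aa_sequence Amino-acid string over the standard 20-letter alphabet.
#' @return List with `gravy`, `hydrophobic_fraction`, `length`.
#' @export
#' @examples
#' protein_properties("IIII")$gravy  # 4.5
protein_properties <- function(aa_sequence) {
  if (length(aa_sequence) != 1 || is.na(aa_sequence) || nchar(aa_sequence) == 0)
    stop("aa_sequence must be a single non-empty string", call. = FALSE)
  aa <- strsplit(toupper(aa_sequence), "")[[1]]
  bad <- setdiff(aa, names(KYTE_DOOLITTLE))
  if (length(bad))
    stop("unknown residue(s): ", paste(unique(bad), collapse = ","), call. = FALSE)
  list(gravy = mean(KYTE_DOOLITTLE[aa]),
       hydrophobic_fraction = mean(aa %in% HYDROPHOBIC_AA),
       length = length(aa))
}
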