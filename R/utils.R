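#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' The 61 sense codons of the standard genetic code
#'
#' All 64 trinucleotides minus the three stop codons (TAA, TAG, TGA).
#' This is the codon alphabet used by [random_repeat()] and by the
#' synthetic-locus generators when filling unconstrained positions.
#'
#' @return Character vector of 61 codons.
#' @export
#' @examples
#' length(sense_codons())
sense_codons <- function() {
  all64 <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0), DNA_BASES, paste0))
  sort(setdiff(all64, STOP_CODONS))
}

## Kyte-Doolittle hydropathy scale (ProtParam GRAVY convention)
KYTE_DOOLITTLE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

HYDROPHOBIC_AA <- c("A", "I", "L", "M", "F", "W", "V")

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] returning
#' plain character vectors.
#'
#' @param x Character vector of DNA sequences (A/C/G/T).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

assert_dna <- function(x, arg = deparse(substitute(x))) {
  if (length(x) != 1 || is.na(x) || !is.character(x) || nchar(x) == 0)
    stop(sprintf("'%s' must be a single non-empty DNA string", arg), call. = FALSE)
  if (grepl("[^ACGT]", x))
    stop(sprintf("'%s' contains characters outside {A,C,G,T}", arg), call. = FALSE)
  invisible(x)
}

## Run `code` under a temporary RNG state seeded with `seed`; restores the
## caller's stream afterwards so seeded helpers compose without interference.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

## Exact motif occurrences (1-based starts); max_mismatch allows Hamming slack.
find_motif <- function(sequence, motif, max_mismatch = 0) {
  n <- nchar(sequence)
  m <- nchar(motif)
  if (m > n) return(integer())
  if (max_mismatch == 0) {
    hits <- gregexpr(motif, sequence, fixed = TRUE)[[1]]
    if (hits[1] == -1) return(integer())
    return(as.integer(hits))
  }
  seq_chr <- strsplit(sequence, "")[[1]]
  mot_chr <- strsplit(motif, "")[[1]]
  starts <- seq_len(n - m + 1)
  mism <- vapply(starts, function(s) sum(seq_chr[s:(s + m - 1)] != mot_chr), integer(1))
  starts[mism <= max_mismatch]
}

IUPAC_REGEX <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
  B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]"
)

iupac_to_regex <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_REGEX))
  if (length(bad))
    stop("site pattern contains non-IUPAC characters: ", paste(bad, collapse = ","), call. = FALSE)
  paste(IUPAC_REGEX[chars], collapse = "")
}

## All occurrences of an IUPAC pattern (overlapping), 1-based starts.
find_iupac <- function(sequence, pattern) {
  rx <- iupac_to_regex(pattern)
  hits <- integer()
  from <- 1L
  repeat {
    m <- regexpr(rx, substr(sequence, from, nchar(sequence)), perl = TRUE)
    if (m == -1) break
    hit <- from + as.integer(m) - 1L
    hits <- c(hits, hit)
    from <- hit + 1L
  }
  hits
}

translate_dna <- function(seq) {
  n <- nchar(seq) - nchar(seq) %% 3
  if (n < 3) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(seq, 1, n)),
                                     if.fuzzy.codon = "X"))
}

kmers_of <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  substring(seq, 1:(n - k + 1), k:n)
}
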