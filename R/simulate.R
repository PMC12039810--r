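## Synthetic locus and ortholog-family generators.
##
## The generated locus reproduces the geometry the analyses assume:
## a 280-nt ncRNA whose central template (default 120 nt, starting at base
## 29) begins with the leading ACA bracket and is followed immediately by
## the second bracket; a primer-binding site whose reverse complement is the
## 5-nt DNA primer GATAT; and, on the ccDNA (reverse-complement) strand, the
## -10/-35 promoter hexamers in the out-of-order single-repeat arrangement
## that reconstitutes a canonical 17-bp-spacer promoter across repeat
## junctions, plus an RBS, start codon and a single HinfI (GANTC) site per
## repeat. Free positions are filled with sense codons in the one reading
## frame the fixed elements leave open (codons starting at repeat position
## 2), so concatemers carry a stop-free junction-spanning ORF whenever the
## repeat length is divisible by three.

repeat_layout <- function(L) {
  if (L < 60) stop("template_length too short for the fixed-element layout", call. = FALSE)
  list(
    junction_tail = list(seq = "TA",     pos = 1L),
    primer_rc     = list(seq = "GATAT",  pos = 3L),
    minus10       = list(seq = "TATAAT", pos = 13L),
    rbs           = list(seq = "GAG",    pos = 24L),
    start_codon   = list(seq = "ATG",    pos = 32L),
    hinfi         = list(seq = "GAATC",  pos = 40L),
    minus35       = list(seq = "TTGACA", pos = L - 10L),
    junction_head = list(seq = "TGT",    pos = L - 2L)
  )
}

layout_mask <- function(layout, L) {
  chars <- rep(NA_character_, L)
  for (el in layout) {
    idx <- (el$pos - 1L + seq_len(nchar(el$seq)) - 1L) %% L + 1L
    chars[idx] <- strsplit(el$seq, "")[[1]]
  }
  chars
}

## Fill free positions with sense codons in the cyclic frame with codon
## starts at positions 2, 5, ... (mod repeat length). Partially fixed codons
## are drawn from the sense codons consistent with their fixed bases.
fill_repeat <- function(L, layout = repeat_layout(L)) {
  chars <- layout_mask(layout, L)
  codons <- sense_codons()
  codon_mat <- do.call(rbind, strsplit(codons, ""))
  if (L %% 3L == 0L) {
    starts <- seq.int(2L, L - 1L, by = 3L)
  } else {
    starts <- seq.int(2L, L - 2L, by = 3L)
  }
  for (s in starts) {
    idx <- (s - 1L + 0:2) %% L + 1L
    pat <- chars[idx]
    if (!anyNA(pat)) next
    ok <- rep(TRUE, length(codons))
    for (j in 1:3) if (!is.na(pat[j])) ok <- ok & codon_mat[, j] == pat[j]
    if (!any(ok)) stop("layout error: no sense codon fits fixed bases", call. = FALSE)
    pick <- sample(which(ok), 1L)
    chars[idx] <- codon_mat[pick, ]
  }
  left <- which(is.na(chars))
  if (length(left)) chars[left] <- sample(DNA_BASES, length(left), replace = TRUE)
  paste(chars, collapse = "")
}

## Simulability checks: motif uniqueness in the 2-repeat concatemer, no
## decoy ACA bracket inside the length band, unique 11-mers across both
## strands of the ncRNA, and no chimeric junction 11-mer colliding with the
## index (so jump detection is exact at zero error). Tandem junctions carry
## a forced 3-nt micro-homology with the bracket (junction TGT = revcomp of
## the second ACA), so windows spanning a tandem junction by up to
## k - 1 - 3 bases must be unmapped while the bracket-homology windows map
## by construction; reversal and read-through junctions must have no
## homology mapping at all.
locus_valid <- function(ncrna, rep_unit, L, k = 11L, band_lo = 90L) {
  rep2 <- strrep(rep_unit, 2L)
  if (length(find_motif(rep2, "TATAAT")) != 2L) return(FALSE)
  if (length(find_motif(rep2, "TTGACA")) != 2L) return(FALSE)
  if (length(find_iupac(rep2, "GANTC")) != 2L) return(FALSE)

  ts <- 29L; te <- 28L + L; n <- nchar(ncrna)
  aca <- find_motif(ncrna, "ACA")
  decoys <- aca[aca >= ts + band_lo & aca < ts + L]
  if (length(decoys)) return(FALSE)

  all_k <- c(kmers_of(ncrna, k), revcomp(kmers_of(ncrna, k)))
  if (anyDuplicated(all_k)) return(FALSE)

  chim <- c(
    substr(rep2, L - k + 2L, L + k - 4L),                                  # tandem junction, past the 3-nt bracket homology
    paste0(revcomp(substr(ncrna, ts + 2L, ts + k)),
           substr(ncrna, ts + 5L, ts + 3L + k)),                           # reversal turn
    paste0(substr(ncrna, te - k, te - 2L),
           revcomp(substr(ncrna, n - k + 2L, n)))                          # primer read-through
  )
  chim_k <- unlist(lapply(chim, kmers_of, k = k))
  !any(chim_k %in% all_k)
}

#' Generate a synthetic ncRNA locus
#'
#' Draws a random ncRNA realising the reference locus geometry (see the
#' package vignette): template at bases 29 to `28 + template_length`, ACA
#' brackets at the template start and immediately after its end, PBS whose
#' reverse complement is the primer `GATAT`, and a ccDNA repeat carrying the
#' promoter/RBS/start/HinfI layout with sense-codon fill. Candidate loci are
#' resampled until the locus is cleanly analysable: one promoter motif and
#' one GANTC site per repeat, no decoy ACA bracket, all 11-mers unique
#' across both strands, and no junction-spanning chimeric 11-mer colliding
#' with the ncRNA index.
#'
#' @param seed Integer seed (optional; the caller's RNG stream is restored).
#' @param template_length Template length in nt; 120 is the reference,
#'   111/117/129 occur among orthologs, 119 gives a frame-breaking negative
#'   control (default 120).
#' @param ncrna_length Total ncRNA length (default 280).
#' @param id Locus identifier.
#' @param max_tries Resampling budget (default 500).
#' @return An [ncrna_locus()] with the repeat-element layout attached
#'   (`$elements`, repeat coordinates) and the repeat unit (`$repeat_unit`).
#' @export
make_locus <- function(seed = NULL, template_length = 120L, ncrna_length = 280L,
                       id = "synthetic_locus", max_tries = 500L) {
  L <- as.integer(template_length)
  tail_len <- ncrna_length - (28L + L + 3L)
  if (tail_len < 30)
    stop("ncrna_length too short for template_length plus the 3' domain", call. = FALSE)
  with_seed(seed, {
    layout <- repeat_layout(L)
    for (try in seq_len(max_tries)) {
      rep_unit <- fill_repeat(L, layout)
      ncrna <- paste0(random_dna(28L), revcomp(rep_unit), "ACA", random_dna(tail_len))
      if (!locus_valid(ncrna, rep_unit, L)) next
      loc <- ncrna_locus(id, ncrna,
                         template_start = 29L, template_end = 28L + L,
                         aca_positions = c(29L, 29L + L),
                         pbs_interval = c(22L + L, 26L + L),
                         primer = "GATAT", elements = layout)
      loc$repeat_unit <- rep_unit
      return(loc)
    }
    stop("failed to generate a valid locus in ", max_tries, " tries", call. = FALSE)
  })
}

revcomp_gapped <- function(x) {
  chars <- rev(strsplit(x, "")[[1]])
  nb <- chars != "-"
  chars[nb] <- strsplit(chartr("ACGT", "TGCA", paste(chars[nb], collapse = "")), "")[[1]]
  paste(chars, collapse = "")
}

#' Generate an aligned family of ortholog ncRNA loci
#'
#' Members derive from a common reference locus (template length 120) by
#' resizing a variable codon zone in the middle of the repeat (template
#' lengths drawn from `lengths`, the ortholog length distribution), swapping
#' free template codons for random sense codons with probability
#' `template_mut_prob`, and mutating scaffold bases (5' handle and 3'
#' domain) with probability `scaffold_mut_prob`. Fixed elements (brackets,
#' promoter motifs, junction, RBS, PBS) are never mutated, so conservation
#' is high at fixed elements and low at free template codons, and every
#' member with a length divisible by three keeps a stop-free
#' junction-spanning frame in its concatemers. The alignment is emitted by
#' construction (gap padding at the variable zone).
#'
#' @param seed Integer seed.
#' @param n_members Number of family members (default 42).
#' @param lengths Template lengths sampled for members (default
#'   `c(111, 117, 120, 129)`).
#' @param length_probs Sampling weights (default favouring 117, the modal
#'   ortholog length).
#' @param template_mut_prob Per-free-codon substitution probability
#'   (default 0.3).
#' @param scaffold_mut_prob Per-base scaffold substitution probability
#'   (default 0.05).
#' @return Object of class `ncrna_family`: `sequences` (ungapped ncRNAs),
#'   `alignment` (equal-length gapped ncRNAs), `template_lengths`,
#'   `reference` (the reference [ncrna_locus()]).
#' @export
make_family <- function(seed = NULL, n_members = 42L,
                        lengths = c(111L, 117L, 120L, 129L),
                        length_probs = c(0.1, 0.6, 0.2, 0.1),
                        template_mut_prob = 0.3, scaffold_mut_prob = 0.05) {
  if (n_members < 2) stop("n_members must be >= 2", call. = FALSE)
  if (any(lengths %% 3L != 0L))
    warning("some template lengths are not divisible by 3; their concatemers will frameshift")
  with_seed(seed, {
    ref <- make_locus(template_length = 120L)
    ref_rep <- strsplit(ref$repeat_unit, "")[[1]]
    mask <- layout_mask(ref$elements, 120L)
    zone <- 62:70                          # three free codons, resized per member
    codon_starts <- seq.int(2L, 119L, by = 3L)
    free_codons <- Filter(function(s) {
      idx <- (s - 1L + 0:2) %% 120L + 1L
      all(is.na(mask[idx])) && !any(idx %in% zone)
    }, codon_starts)
    pre_ref <- substr(ref$sequence, 1, 28)
    tail_ref <- substr(ref$sequence, 152, nchar(ref$sequence))
    codons <- sense_codons()

    Ls <- lengths[sample.int(length(lengths), n_members, replace = TRUE,
                             prob = length_probs)]
    Ls[1] <- 120L                          # reference-like first member
    maxz <- max(Ls) - 111L

    mutate_bases <- function(s, p) {
      chars <- strsplit(s, "")[[1]]
      hit <- stats::runif(length(chars)) < p
      chars[hit] <- vapply(chars[hit],
                           function(b) sample(setdiff(DNA_BASES, b), 1L), "")
      paste(chars, collapse = "")
    }

    aligned <- character(n_members)
    seqs <- character(n_members)
    for (m in seq_len(n_members)) {
      L <- Ls[m]; z <- L - 111L
      chars <- ref_rep
      for (s in free_codons) {
        if (stats::runif(1) < template_mut_prob) {
          idx <- (s - 1L + 0:2) %% 120L + 1L
          chars[idx] <- strsplit(sample(codons, 1L), "")[[1]]
        }
      }
      ## variable zone: reference codons resized to the member's length,
      ## then mutated like any other free codon
      zone_codons <- substring(paste(chars[zone], collapse = ""),
                               c(1, 4, 7), c(3, 6, 9))
      if (z < 9L) zone_codons <- zone_codons[seq_len(z / 3L)]
      if (z > 9L) zone_codons <- c(zone_codons,
                                   sample(codons, (z - 9L) / 3L, replace = TRUE))
      mut <- stats::runif(length(zone_codons)) < template_mut_prob
      zone_codons[mut] <- sample(codons, sum(mut), replace = TRUE)
      zone_seq <- paste(zone_codons, collapse = "")
      rep_m <- paste0(paste(chars[1:61], collapse = ""), zone_seq,
                      paste(chars[71:120], collapse = ""))
      rep_aln <- paste0(paste(chars[1:61], collapse = ""), zone_seq,
                        strrep("-", maxz - z),
                        paste(chars[71:120], collapse = ""))
      pre <- mutate_bases(pre_ref, scaffold_mut_prob)
      tl <- mutate_bases(tail_ref, scaffold_mut_prob)
      seqs[m] <- paste0(pre, revcomp(rep_m), "ACA", tl)
      aligned[m] <- paste0(pre, revcomp_gapped(rep_aln), "ACA", tl)
    }
    names(seqs) <- names(aligned) <- sprintf("ortholog_%02d", seq_len(n_members))
    structure(list(sequences = seqs, alignment = aligned,
                   template_lengths = Ls, reference = ref),
              class = "ncrna_family")
  })
}

#' @export
print.ncrna_family <- function(x, ...) {
  cat(sprintf("<ncrna_family> %d members, template lengths %s, alignment width %d\n",
              length(x$sequences),
              paste(sort(unique(x$template_lengths)), collapse = "/"),
              nchar(x$alignment[1])))
  invisible(x)
}
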