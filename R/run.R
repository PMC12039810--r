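## Pipeline runners behind the command-line entry point. Each run writes a
## config echo (including the seed) next to its outputs for reproducibility.

echo_config <- function(out_dir, params) {
  jsonlite::write_json(params, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Reconstitute theoretical ccDNA from an ncRNA and report its features
#'
#' Reads ncRNA sequences from FASTA, extracts each template, builds an
#' n-repeat theoretical ccDNA and writes promoter calls, reading-frame
#' scans, restriction fragments, an optional conservation profile and a
#' JSON summary per locus.
#'
#' @param ncrna_fasta Path to the ncRNA FASTA.
#' @param out_dir Output directory (created if missing).
#' @param n_repeats Repeats in the theoretical concatemer (default 5).
#' @param mode Template extraction mode (`"coordinates"` or `"aca_motif"`).
#' @param template_start,template_end Template interval for coordinates mode
#'   (defaults 29/148).
#' @param length_band ACA-bracket length band for aca_motif mode.
#' @param alignment_fasta Optional aligned FASTA of ortholog ncRNAs for the
#'   conservation profile.
#' @param digest_site IUPAC restriction site (default `"GANTC"`, HinfI).
#' @return Invisibly, a list of result tables per locus.
#' @export
run_reconstitute <- function(ncrna_fasta, out_dir, n_repeats = 5L,
                             mode = "coordinates", template_start = 29L,
                             template_end = 148L, length_band = c(90, 150),
                             alignment_fasta = NULL, digest_site = "GANTC") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- read_sequences(ncrna_fasta)
  results <- list()
  for (nm in names(seqs)) {
    locus <- ncrna_locus(nm, unname(seqs[nm]),
                         template_start = template_start,
                         template_end = min(template_end, nchar(seqs[nm])))
    tpl <- extract_template(locus, mode, length_band = length_band)
    cc <- concatemerize(tpl$template, n_repeats)
    promoters <- scan_promoters(cc)
    orfs <- scan_orfs(cc)
    fragments <- digest_sequence(cc$sequence, site = digest_site)
    canonical <- promoters[promoters$arrangement == "canonical" &
                             promoters$spans_junction, , drop = FALSE]
    rbs <- if (nrow(canonical)) locate_rbs(cc, canonical[1, , drop = FALSE]) else NULL
    prefix <- file.path(out_dir, nm)
    write_tsv(promoters, paste0(prefix, "_promoters.tsv"))
    write_tsv(orfs[, setdiff(names(orfs), "translation")],
              paste0(prefix, "_orfs.tsv"))
    write_tsv(data.frame(fragment = seq_along(fragments), length = fragments),
              paste0(prefix, "_digest.tsv"))
    stop_free <- orfs[orfs$stop_free, , drop = FALSE]
    summary <- list(
      id = nm, template_start = tpl$start, template_end = tpl$end,
      template_length = nchar(tpl$template), n_repeats = n_repeats,
      n_junction_promoters = sum(promoters$arrangement == "canonical" &
                                   promoters$spans_junction),
      junction_spacer_bp = if (nrow(canonical)) canonical$spacer_bp[1] else NA,
      stop_free_frames = stop_free$frame,
      frame_preserving = nchar(cc$repeat_unit) %% 3 == 0,
      start_codon = if (!is.null(rbs)) rbs$start_codon else NA,
      rbs = if (!is.null(rbs)) rbs$rbs else NA,
      digest_internal_bp = if (length(fragments) > 2)
        unique(fragments[-c(1, length(fragments))]) else NA)
    jsonlite::write_json(summary, paste0(prefix, "_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    results[[nm]] <- list(promoters = promoters, orfs = orfs,
                          fragments = fragments, summary = summary)
  }
  if (!is.null(alignment_fasta)) {
    aln <- read_sequences_aligned(alignment_fasta)
    prof <- conservation_profile(aln)
    write_tsv(data.frame(position = seq_along(prof$per_position),
                         conservation_bits = prof$per_position,
                         smoothed = prof$smoothed),
              file.path(out_dir, "conservation.tsv"))
    results$conservation <- prof
  }
  echo_config(out_dir, list(command = "reconstitute", ncrna_fasta = ncrna_fasta,
                            n_repeats = n_repeats, mode = mode,
                            template_start = template_start,
                            template_end = template_end,
                            digest_site = digest_site))
  invisible(results)
}

## aligned FASTA (keeps gaps; plain parser since Biostrings DNAStringSet
## would also accept gaps but we avoid alphabet surprises)
read_sequences_aligned <- function(path) {
  lines <- readLines(path)
  headers <- grep("^>", lines)
  ids <- sub("^>\\s*", "", lines[headers])
  ids <- sub("\\s.*$", "", ids)
  starts <- headers + 1L
  ends <- c(headers[-1] - 1L, length(lines))
  seqs <- vapply(seq_along(headers), function(i)
    paste(lines[starts[i]:ends[i]], collapse = ""), "")
  names(seqs) <- ids
  toupper(seqs)
}

#' Run the k-mer jump-mapping pipeline on long reads
#'
#' Segments each read into consecutive k-mers mapped to the ncRNA, writes
#' the jump table, per-read structures, the aggregated jump map and a JSON
#' summary with category fractions.
#'
#' @param reads_path FASTQ/FASTA of reads.
#' @param locus_fasta ncRNA FASTA (first record used).
#' @param locus_json Optional JSON annotation (template interval, PBS,
#'   primer) as written by [run_simulate()].
#' @param k Window length (default 11).
#' @param tolerance Diagonal tolerance for jump calls (default 0; use ~3 for
#'   error-bearing reads).
#' @param max_skip Maximum unmapped-window run bridged when pairing windows
#'   (default `3 * k`).
#' @param out_dir Output directory.
#' @return Invisibly, list with `jumps`, `structures`, `map`, `fractions`.
#' @export
run_jumpmap <- function(reads_path, locus_fasta, locus_json = NULL, k = 11L,
                        tolerance = 0, max_skip = 3L * k, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  locus <- locus_from_files(locus_fasta, locus_json)
  index <- kmer_index(locus, k = k)
  reads <- read_sequences(reads_path)
  jumps <- list(); structures <- list()
  short <- 0L
  for (i in seq_along(reads)) {
    id <- names(reads)[i]
    if (nchar(reads[i]) < k) { short <- short + 1L; next }
    asn <- segment_read(unname(reads[i]), index, read_id = id)
    j <- quantify_jumps(asn, k = k, diagonal_tolerance = tolerance,
                        max_skip = max_skip,
                        template_interval = c(locus$template_start,
                                              locus$template_end))
    if (nrow(j)) jumps[[id]] <- j
    structures[[id]] <- read_structure(asn, locus, k = k,
                                       diagonal_tolerance = tolerance,
                                       max_skip = max_skip)
  }
  if (short) message(short, " read(s) shorter than k skipped")
  jumps <- if (length(jumps)) do.call(rbind, jumps) else
    data.frame(read_id = character(), from_position = integer(),
               from_strand = character(), to_position = integer(),
               to_strand = character())
  rownames(jumps) <- NULL
  cls <- classify_jumps(jumps, locus)
  structures <- if (length(structures)) do.call(rbind, structures) else
    data.frame()
  map <- jump_map(cls$jumps)
  write_tsv(cls$jumps, file.path(out_dir, "jumps.tsv"))
  write_tsv(structures, file.path(out_dir, "read_structure.tsv"))
  write_tsv(map, file.path(out_dir, "jump_map.tsv"))
  jsonlite::write_json(list(n_reads = length(reads), n_jumps = nrow(cls$jumps),
                            category_fractions = as.list(cls$fractions),
                            min_unique_k = index$min_unique_k),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  echo_config(out_dir, list(command = "jumpmap", reads = reads_path,
                            locus = locus_fasta, k = k, tolerance = tolerance,
                            max_skip = max_skip))
  invisible(list(jumps = cls$jumps, structures = structures, map = map,
                 fractions = cls$fractions))
}

#' Simulate a full ccDNA sequencing dataset
#'
#' Generates a synthetic locus, simulates rolling reverse transcription and
#' long-read sequencing, and writes the read FASTQ, ground-truth tables,
#' locus FASTA/JSON and a config echo. All randomness flows from `seed`.
#'
#' @param out_dir Output directory.
#' @param seed Integer master seed (default 1).
#' @param n_reads Number of reads (default 1000).
#' @param template_length Template length (default 120).
#' @param repeat_mean,p_reversal,p_readthrough,error_rates,adapter5,adapter3
#'   Passed to [sim_config()].
#' @return Invisibly, list with the simulation and read objects and file
#'   paths.
#' @export
run_simulate <- function(out_dir, seed = 1L, n_reads = 1000L,
                         template_length = 120L, repeat_mean = 5,
                         p_reversal = 0.4, p_readthrough = 0.5,
                         error_rates = c(sub = 0.02, ins = 0.01, del = 0.01),
                         adapter5 = "", adapter3 = "") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  locus <- make_locus(seed = seed, template_length = template_length)
  cfg <- sim_config(locus, n_reads = n_reads, repeat_mean = repeat_mean,
                    p_reversal = p_reversal, p_readthrough = p_readthrough,
                    error_rates = error_rates, adapter5 = adapter5,
                    adapter3 = adapter3, seed = seed + 1L)
  sim <- simulate_synthesis(cfg)
  reads <- sequence_reads(sim, seed = seed + 2L)
  paths <- list(
    fastq = file.path(out_dir, "reads.fastq"),
    truth_jumps = file.path(out_dir, "truth_jumps.tsv"),
    truth_reads = file.path(out_dir, "truth_reads.tsv"),
    locus_fasta = file.path(out_dir, "locus.fasta"),
    locus_json = file.path(out_dir, "locus.json"))
  write_fastq(reads$reads, paths$fastq)
  write_tsv(sim$truth_jumps, paths$truth_jumps)
  write_tsv(sim$truth_reads, paths$truth_reads)
  write_fasta(stats::setNames(locus$sequence, locus$id), paths$locus_fasta)
  locus_to_json(locus, paths$locus_json)
  echo_config(out_dir, list(command = "simulate", seed = seed,
                            n_reads = n_reads,
                            template_length = template_length,
                            repeat_mean = repeat_mean,
                            p_reversal = p_reversal,
                            p_readthrough = p_readthrough,
                            error_rates = as.list(error_rates),
                            adapter5 = adapter5, adapter3 = adapter3))
  invisible(list(sim = sim, reads = reads, paths = paths))
}
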