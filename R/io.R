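## File IO helpers: FASTA/FASTQ via Biostrings, plain TSV tables.

#' Read sequences from FASTA/FASTQ
#'
#' @param path File path; format guessed from the extension (`.fq`/`.fastq`
#'   read as FASTQ, anything else as FASTA).
#' @return Named character vector of sequences.
#' @export
read_sequences <- function(path) {
  fmt <- if (grepl("\\.f(ast)?q$", path, ignore.case = TRUE)) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(gsub("-", "", seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

write_fasta_aligned <- function(seqs, path) {
  lines <- as.vector(rbind(paste0(">", names(seqs)), unname(seqs)))
  writeLines(lines, path)
  invisible(path)
}

#' Write reads to FASTQ
#'
#' @param reads data.frame with `read_id`, `sequence`, `quality` (as from
#'   [sequence_reads()]).
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  lines <- if (nrow(reads) == 0) character() else
    as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                    rep("+", nrow(reads)), reads$quality))
  writeLines(lines, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  list_cols <- vapply(df, is.list, logical(1))
  for (j in which(list_cols))
    df[[j]] <- vapply(df[[j]], function(v) paste(v, collapse = ","), "")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

locus_to_json <- function(locus, path) {
  jsonlite::write_json(list(
    id = locus$id,
    template_start = locus$template_start, template_end = locus$template_end,
    aca_positions = locus$aca_positions, pbs_interval = locus$pbs_interval,
    primer = locus$primer), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

locus_from_files <- function(fasta_path, json_path = NULL) {
  seqs <- read_sequences(fasta_path)
  ann <- if (!is.null(json_path) && file.exists(json_path))
    jsonlite::read_json(json_path, simplifyVector = TRUE) else list()
  ncrna_locus(
    id = if (!is.null(ann$id)) ann$id else names(seqs)[1],
    sequence = unname(seqs[1]),
    template_start = if (!is.null(ann$template_start)) ann$template_start else 29L,
    template_end = if (!is.null(ann$template_end)) ann$template_end else 148L,
    aca_positions = if (!is.null(ann$aca_positions)) ann$aca_positions else integer(),
    pbs_interval = if (!is.null(ann$pbs_interval)) ann$pbs_interval else NULL,
    primer = if (!is.null(ann$primer)) ann$primer else "GATAT")
}
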