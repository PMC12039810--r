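## Shared fixtures, generated once per test run. Seeds are fixed so every
## fixture is reproducible; nothing is stored on disk.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

ref_locus <- function() memo("locus", make_locus(seed = 101))
ref_index <- function() memo("index", kmer_index(ref_locus()))
ref_template <- function()
  memo("template", extract_template(ref_locus(), "coordinates")$template)
ref_interval <- function() c(ref_locus()$template_start, ref_locus()$template_end)

## small zero-error simulation shared by pipeline tests
ref_sim <- function()
  memo("sim", simulate_synthesis(sim_config(ref_locus(), n_reads = 300, seed = 7)))

## greedy one-to-one jump matching: same strand pair, both endpoints within
## `window` bases; used by the error-robustness checks
match_jumps <- function(detected, truth, window = 11) {
  used <- rep(FALSE, nrow(truth))
  tp <- 0L; fp <- 0L
  for (r in seq_len(nrow(detected))) {
    m <- which(!used &
                 truth$from_strand == detected$from_strand[r] &
                 truth$to_strand == detected$to_strand[r] &
                 abs(truth$from_position - detected$from_position[r]) <= window &
                 abs(truth$to_position - detected$to_position[r]) <= window)
    if (length(m)) { used[m[1]] <- TRUE; tp <- tp + 1L } else fp <- fp + 1L
  }
  c(tp = tp, fp = fp, fn = sum(!used))
}

## jump rows as order-independent multiset keys
jump_keys <- function(df)
  sort(paste(df$from_position, df$from_strand, df$to_position, df$to_strand))
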