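# shared fixtures built in code

random_seq <- function(L, freqs = yeast_aa_freqs()) {
  paste(sample(names(freqs), L, replace = TRUE, prob = freqs), collapse = "")
}

# independent oracle: per-window brute-force sums (no rolling arithmetic)
brute_window_charges <- function(sequence, table = charge_table(), W = 30L) {
  rc <- residue_charges(sequence, table)
  vapply(seq_len(nchar(sequence) - W + 1L),
         function(i) sum(rc[i:(i + W - 1L)]), numeric(1))
}

make_proteome <- function(seqs, ids = sprintf("P%04d", seq_along(seqs))) {
  proteome(ids, seqs)
}

# a 30-residue window with exact rounded net charge q, starting with M
nterm_window <- function(q) {
  win <- rep("A", 30)
  win[1] <- "M"
  if (q != 0) win[2:(abs(q) + 1)] <- if (q > 0) "K" else "E"
  paste(win, collapse = "")
}
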