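# Shared fixture builders. Everything is generated in code; small sizes,
# fixed seeds.

tiny_ref <- function(n = 3, len = c(300, 400), vector_len = 0, seed = 3) {
  generate_reference(n, len, vector_len = vector_len, gc_fraction = 0.5, seed = seed)
}

# perfectly calibrated single-quality model
flat_model <- function(q = 30, read_len = 50) {
  error_model(read_len = read_len, q_levels = q)
}

# one hand-built read: forward, aligned at `start` on record `rec`
manual_read <- function(ref, seq, qual, rec = 1L, start = 0L, rev = FALSE,
                        read_group = "RG1") {
  v <- spikecal:::dna_int(seq)
  L <- length(v)
  S <- matrix(v, 1L, L)
  if (rev) S <- matrix(spikecal:::comp_int(rev(v)), 1L, L)
  structure(list(
    ref_ids = ref$records$id, rec = rec, start = as.integer(start),
    rev = rev, mate = 1L, seq = S,
    qual = matrix(as.integer(qual), 1L, L, byrow = TRUE),
    read_group = read_group, read_len = L,
    truth = data.frame(read = integer(), cycle = integer(), ref_id = character(),
                       ref_pos = integer(), type = character())
  ), class = "aligned_reads")
}

# substring of a reference record (0-based half-open)
ref_substr <- function(ref, rec, from, to) {
  substr(ref$sequences[[rec]], from + 1L, to)
}

# central 99% binomial interval
binom_ci99 <- function(n, p) stats::qbinom(c(0.005, 0.995), n, p)
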