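# fixtures are generated in code; nothing is read from disk

random_dna <- function(n, len, seed = NULL) {
  gen <- function() {
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    }, character(1))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# identity channel: every stage configured to pass molecules through
identity_config <- function(depth = 10, reads = 5) {
  channel_config(
    synthesis = list(mean_depth = depth, prob = 1, rates = error_rates()),
    decay = list(survival_prob = 1, rates = error_rates()),
    pcr = list(cycles = 0L),
    sampling = list(ratio = 1),
    sequencing = list(depth = reads, rates = error_rates())
  )
}

# small but otherwise default-shaped channel for fast stochastic tests
small_config <- function(...) {
  channel_config(
    synthesis = list(mean_depth = 200, rates = error_rates(sub = 0.002,
                                                           del = 0.001)),
    decay = list(survival_prob = 0.95),
    pcr = list(cycles = 4L, efficiency = 0.8, bias_sigma = 0.03),
    sampling = list(ratio = 0.1),
    sequencing = list(depth = 15),
    ...
  )
}

# independent chunk-splitting oracle (zero-padded column matrix of bytes)
split_chunks_oracle <- function(data, chunk_size) {
  M <- ceiling(length(data) / chunk_size)
  padded <- c(data, raw(M * chunk_size - length(data)))
  matrix(as.integer(padded), nrow = chunk_size)
}

# hand-built read_set around given references
make_read_set <- function(references, reads_tbl) {
  pool <- seq_pool(references, counts = 0 * seq_along(references) + 1)
  rs <- reads_tbl
  attr(rs, "references") <- references
  attr(rs, "ref_ids") <- paste0("seq_", seq_along(references))
  class(rs) <- c("read_set", class(tibble::tibble()))
  rs
}
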