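#' Deterministic pseudo-random test file
#'
#' Generates `size_bytes` of seeded pseudo-random bytes, standing in for a
#' stored file (the experiments here use a 9 KB payload).
#'
#' @param size_bytes File size (>= 1).
#' @param seed Integer seed.
#' @return A raw vector.
#' @examples
#' identical(generate_file(16, 1), generate_file(16, 1))
#' @export
generate_file <- function(size_bytes, seed = 1L) {
  stopifnot(size_bytes >= 1)
  withr::with_seed(as.integer(seed),
                   as.raw(sample.int(256L, size_bytes, replace = TRUE) - 1L))
}

#' Robust soliton degree distribution
#'
#' The standard Luby-transform degree law: ideal soliton `rho` plus the
#' spike/tail correction `tau` parameterized by `c` and `delta`, normalized
#' to a pmf on `1..M`.
#'
#' @param M Number of chunks.
#' @param c,delta Robust soliton parameters.
#' @return Numeric pmf of length `M`.
#' @export
robust_soliton <- function(M, c = 0.03, delta = 0.3) {
  stopifnot(M >= 1)
  if (M == 1L) return(1)
  rho <- c(1 / M, 1 / ((2:M) * (1:(M - 1))))
  R <- c * log(M / delta) * sqrt(M)
  tau <- numeric(M)
  if (R > 1) {
    kk <- floor(M / R)
    d <- seq_len(max(min(kk - 1, M), 0))
    tau[d] <- R / (d * M)
    if (kk >= 1 && kk <= M) tau[kk] <- R * log(R / delta) / M
  }
  p <- rho + tau
  p / sum(p)
}

split_chunks <- function(data, chunk_size) {
  stopifnot(is.raw(data), chunk_size >= 1)
  M <- ceiling(length(data) / chunk_size)
  padded <- c(data, raw(M * chunk_size - length(data)))
  matrix(as.integer(padded), nrow = chunk_size)   # chunk_size x M, int 0..255
}

#' Luby-transform fountain encoding
#'
#' Splits `data` into `M` equal chunks (zero-padded) and emits
#' `n_droplets` droplets. Each droplet is fully determined by its own
#' 32-bit seed (derived from `seed` and the droplet index with
#' [derive_seed()]): under that seed, the degree is drawn from the robust
#' soliton law and the member chunks uniformly without replacement; the
#' payload is the bytewise XOR of the member chunks. A decoder therefore
#' only needs `(seed, payload)` pairs.
#'
#' @param data Raw vector.
#' @param chunk_size Chunk length in bytes (20 by default, giving 104 nt
#'   strands under the standard layout, see [droplets_to_dna()]).
#' @param n_droplets Number of droplets to emit.
#' @param seed Integer base seed.
#' @param c,delta Robust soliton parameters.
#' @return A `droplet_set` tibble: `index`, `seed`, `degree`, `members`
#'   (list of integer vectors), `payload` (list of raw vectors); chunk
#'   count `M`, `chunk_size` and soliton parameters as attributes.
#' @export
lt_encode <- function(data, chunk_size = 20L, n_droplets, seed = 1L,
                      c = 0.03, delta = 0.3) {
  chunks <- split_chunks(data, chunk_size)
  M <- ncol(chunks)
  pmf <- robust_soliton(M, c, delta)
  dseed <- vapply(seq_len(n_droplets), function(i) derive_seed(seed, "droplet", i),
                  integer(1))
  members <- vector("list", n_droplets)
  degree <- integer(n_droplets)
  payload <- vector("list", n_droplets)
  for (i in seq_len(n_droplets)) {
    withr::with_seed(dseed[i], {
      d <- sample.int(M, 1L, prob = pmf)
      mem <- sort(sample.int(M, d))
    })
    degree[i] <- d
    members[[i]] <- mem
    pl <- chunks[, mem[1]]
    for (m in mem[-1]) pl <- bitwXor(pl, chunks[, m])
    payload[[i]] <- as.raw(pl)
  }
  out <- tibble(index = seq_len(n_droplets), seed = dseed, degree = degree,
                members = members, payload = payload)
  attr(out, "M") <- M
  attr(out, "chunk_size") <- as.integer(chunk_size)
  attr(out, "soliton") <- c(c = c, delta = delta)
  class(out) <- c("droplet_set", class(tibble()))
  out
}

# incremental peeling decoder used by lt_decode / lt_min_droplets
new_peeler <- function(M, chunk_size) {
  env <- new.env(parent = emptyenv())
  env$decoded <- vector("list", M)
  env$n_resolved <- 0L
  env$pending_members <- list()
  env$pending_payload <- list()
  env$chunk_index <- vector("list", M)   # chunk -> pending droplet ids
  env$M <- M
  env
}

peel_resolve <- function(env, chunk, payload) {
  queue_c <- chunk; queue_p <- list(payload)
  while (length(queue_c) > 0L) {
    ch <- queue_c[[1L]]; pl <- queue_p[[1L]]
    queue_c <- queue_c[-1L]; queue_p <- queue_p[-1L]
    if (!is.null(env$decoded[[ch]])) next
    env$decoded[[ch]] <- pl
    env$n_resolved <- env$n_resolved + 1L
    for (did in env$chunk_index[[ch]]) {
      mem <- env$pending_members[[did]]
      if (is.null(mem) || !(ch %in% mem)) next
      mem <- mem[mem != ch]
      pp <- bitwXor(env$pending_payload[[did]], pl)
      if (length(mem) == 1L) {
        env$pending_members[did] <- list(NULL)
        queue_c <- c(queue_c, mem)
        queue_p <- c(queue_p, list(pp))
      } else if (length(mem) == 0L) {
        env$pending_members[did] <- list(NULL)
      } else {
        env$pending_members[[did]] <- mem
        env$pending_payload[[did]] <- pp
      }
    }
    env$chunk_index[[ch]] <- integer(0)
  }
  invisible(env)
}

peel_add <- function(env, members, payload) {
  pl <- as.integer(payload)
  known <- !vapply(env$decoded[members], is.null, logical(1))
  for (m in members[known]) pl <- bitwXor(pl, as.integer(env$decoded[[m]]))
  mem <- members[!known]
  if (length(mem) == 0L) return(invisible(env))
  if (length(mem) == 1L) {
    peel_resolve(env, mem, pl)
  } else {
    did <- length(env$pending_members) + 1L
    env$pending_members[[did]] <- mem
    env$pending_payload[[did]] <- pl
    for (m in mem) env$chunk_index[[m]] <- c(env$chunk_index[[m]], did)
  }
  invisible(env)
}

#' Peeling (belief-propagation) fountain decoding
#'
#' `lt_decode()` feeds all droplets to a peeling decoder and returns the
#' recovered data. `lt_min_droplets()` feeds droplets one by one and
#' returns the count at which all `M` chunks resolve - one sample of the
#' droplets-needed variable `(1 + beta) M`. Peeling-only decoding (no
#' Gaussian elimination) is used, as in standard Luby-transform practice,
#' so droplets-needed samples are slightly larger than an
#' elimination-based decoder would give.
#'
#' @param droplets A `droplet_set` from [lt_encode()].
#' @param M Chunk count (defaults to the attribute on `droplets`).
#' @return `lt_decode()`: raw vector of the decoded (padded) data;
#'   `lt_min_droplets()`: integer count. Both raise a condition carrying
#'   the number of resolved chunks if the stream is exhausted first.
#' @export
lt_min_droplets <- function(droplets, M = attr(droplets, "M")) {
  cs <- attr(droplets, "chunk_size")
  env <- new_peeler(M, cs)
  for (i in seq_len(nrow(droplets))) {
    peel_add(env, droplets$members[[i]], droplets$payload[[i]])
    if (env$n_resolved == M) return(i)
  }
  abort(sprintf("Droplet stream exhausted with %d of %d chunks resolved.",
                env$n_resolved, M),
        class = "dnachannel_error_decode", resolved = env$n_resolved)
}

#' @rdname lt_min_droplets
#' @export
lt_decode <- function(droplets, M = attr(droplets, "M")) {
  cs <- attr(droplets, "chunk_size")
  env <- new_peeler(M, cs)
  for (i in seq_len(nrow(droplets))) {
    peel_add(env, droplets$members[[i]], droplets$payload[[i]])
    if (env$n_resolved == M) break
  }
  if (env$n_resolved < M) {
    abort(sprintf("Droplet stream exhausted with %d of %d chunks resolved.",
                  env$n_resolved, M),
          class = "dnachannel_error_decode", resolved = env$n_resolved)
  }
  as.raw(unlist(env$decoded))
}

#' Sample the droplets-needed distribution
#'
#' Convenience wrapper running `n` independent encode/decode experiments on
#' the same data and returning the droplets-needed counts, the raw material
#' for [fit_permitted()].
#'
#' @param data Raw vector to encode.
#' @param n Number of experiments.
#' @param base_seed Base seed; experiment `i` uses
#'   `derive_seed(base_seed, "needed", i)`.
#' @inheritParams lt_encode
#' @param max_overhead Stream length as a multiple of `M`.
#' @return Integer vector of length `n`.
#' @export
lt_needed_samples <- function(data, n, base_seed = 1L, chunk_size = 20L,
                              c = 0.03, delta = 0.3, max_overhead = 3) {
  vapply(seq_len(n), function(i) {
    M <- ceiling(length(data) / chunk_size)
    dr <- lt_encode(data, chunk_size, n_droplets = ceiling(max_overhead * M),
                    seed = derive_seed(base_seed, "needed", i),
                    c = c, delta = delta)
    lt_min_droplets(dr)
  }, integer(1))
}

# ---- byte <-> DNA mapping (2 bits/base, A=00 C=01 G=10 T=11) -------------

QUADS <- local({
  b <- c("A", "C", "G", "T")
  v <- character(256)
  for (x in 0:255) {
    v[x + 1] <- paste0(b[bitwAnd(bitwShiftR(x, 6), 3L) + 1L],
                       b[bitwAnd(bitwShiftR(x, 4), 3L) + 1L],
                       b[bitwAnd(bitwShiftR(x, 2), 3L) + 1L],
                       b[bitwAnd(x, 3L) + 1L])
  }
  v
})

#' Map bytes to DNA and back
#'
#' Two bits per base, most significant bits first: `A = 00`, `C = 01`,
#' `G = 10`, `T = 11`; each byte becomes 4 nt (`0x1B` -> `"ACGT"`).
#'
#' @param bytes Raw vector.
#' @param dna DNA string of length divisible by 4.
#' @return `bytes_to_dna()`: a DNA string; `dna_to_bytes()`: a raw vector.
#' @examples
#' bytes_to_dna(as.raw(0x1B))
#' dna_to_bytes("ACGT")
#' @export
bytes_to_dna <- function(bytes) {
  stopifnot(is.raw(bytes))
  paste(QUADS[as.integer(bytes) + 1L], collapse = "")
}

#' @rdname bytes_to_dna
#' @export
dna_to_bytes <- function(dna) {
  stopifnot(nchar(dna) %% 4 == 0)
  v <- match(strsplit(dna, "", fixed = TRUE)[[1]], DNA_BASES) - 1L
  if (anyNA(v)) {
    abort("Non-ACGT character in DNA string.",
          class = "dnachannel_error_validation")
  }
  m <- matrix(v, nrow = 4L)
  as.raw(m[1, ] * 64L + m[2, ] * 16L + m[3, ] * 4L + m[4, ])
}

#' Map droplets to DNA strands
#'
#' Lays each droplet out as `seed (4 bytes, big-endian) | payload |
#' L_RS parity bytes` and maps it 2 bits/base; with the default 20-byte
#' payload and `L_RS = 2` this yields 104 nt strands. The parity bytes are
#' an interleaved XOR fold of the message bytes - placeholder check bytes
#' standing in for Reed-Solomon codewords, whose correction capacity is
#' modeled by counting ([rs_recoverable()]), not by finite-field decoding.
#'
#' @param droplets A `droplet_set`.
#' @param L_RS Parity bytes appended per strand.
#' @return Tibble with `id` and `seq`, ready for [run_channel()] or
#'   [write_fasta()].
#' @export
droplets_to_dna <- function(droplets, L_RS = 2L) {
  stopifnot(inherits(droplets, "droplet_set"), L_RS >= 0)
  seqs <- vapply(seq_len(nrow(droplets)), function(i) {
    sd <- droplets$seed[i]
    seed_bytes <- as.raw(c(bitwAnd(bitwShiftR(sd, 24), 255L),
                           bitwAnd(bitwShiftR(sd, 16), 255L),
                           bitwAnd(bitwShiftR(sd, 8), 255L),
                           bitwAnd(sd, 255L)))
    msg <- c(seed_bytes, droplets$payload[[i]])
    parity <- raw(0)
    if (L_RS > 0) {
      lanes <- (seq_along(msg) - 1L) %% L_RS
      parity <- as.raw(vapply(0:(L_RS - 1L), function(l) {
        Reduce(bitwXor, as.integer(msg[lanes == l]), accumulate = FALSE)
      }, integer(1)))
    }
    bytes_to_dna(c(msg, parity))
  }, character(1))
  tibble(id = paste0("droplet_", droplets$index), seq = seqs)
}

#' Byte-error count between a consensus and its reference
#'
#' Maps base positions to bytes (4 nt per byte under the 2-bit code) and
#' counts bytes containing at least one mismatching base - the unit the
#' Reed-Solomon capacity rule works in.
#'
#' @param consensus,reference Equal-length DNA strings.
#' @param nt_per_byte Bases per byte (4 for the 2-bit code).
#' @return Integer byte-error count (`NA` on length mismatch).
#' @export
byte_errors <- function(consensus, reference, nt_per_byte = 4L) {
  if (nchar(consensus) != nchar(reference)) return(NA_integer_)
  mism <- which(utf8ToInt(consensus) != utf8ToInt(reference))
  length(unique((mism - 1L) %/% nt_per_byte))
}

#' Is a consensus recoverable by the Reed-Solomon budget?
#'
#' `TRUE` iff the byte-error count is at most the correction capacity
#' `floor(L_RS / 2)`. Length mismatches (possible only under non-default
#' voting modes) are unrecoverable and flagged via attribute
#' `"length_mismatch"`.
#'
#' @param read Consensus (or read) string.
#' @param reference Reference string.
#' @param L_RS Parity bytes.
#' @return Logical.
#' @export
rs_recoverable <- function(read, reference, L_RS) {
  stopifnot(L_RS >= 0)
  if (nchar(read) != nchar(reference)) {
    out <- FALSE
    attr(out, "length_mismatch") <- TRUE
    return(out)
  }
  byte_errors(read, reference) <= L_RS %/% 2
}

#' Serialize droplets to a plain-text TSV
#'
#' A droplet is fully determined by its seed given `M` and the soliton
#' parameters, so the TSV stores `index`, `seed` and the payload as
#' lowercase hex, with a `#`-prefixed header line recording `M`,
#' `chunk_size`, `c` and `delta`. `read_droplets()` re-derives each
#' droplet's degree and member set from its seed, exactly as [lt_encode()]
#' drew them.
#'
#' @param droplets A `droplet_set`.
#' @param path File path.
#' @return `write_droplets()` returns `path` invisibly; `read_droplets()`
#'   returns a `droplet_set`.
#' @export
write_droplets <- function(droplets, path) {
  stopifnot(inherits(droplets, "droplet_set"))
  sol <- attr(droplets, "soliton")
  hdr <- sprintf("# M=%d chunk_size=%d c=%g delta=%g",
                 attr(droplets, "M"), attr(droplets, "chunk_size"),
                 sol[["c"]], sol[["delta"]])
  hex <- vapply(droplets$payload,
                function(p) paste(sprintf("%02x", as.integer(p)),
                                  collapse = ""),
                character(1))
  lines <- c(hdr, "index\tseed\tpayload",
             paste(droplets$index, droplets$seed, hex, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_droplets
#' @export
read_droplets <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  m <- regmatches(hdr, regexec(
    "^# M=([0-9]+) chunk_size=([0-9]+) c=([0-9.eE+-]+) delta=([0-9.eE+-]+)$",
    hdr))[[1]]
  if (length(m) == 0L) {
    abort("Missing droplet TSV header line.",
          class = "dnachannel_error_validation")
  }
  M <- as.integer(m[2]); cs <- as.integer(m[3])
  cc <- as.numeric(m[4]); dd <- as.numeric(m[5])
  body <- utils::read.table(text = lines[-(1:2)], sep = "\t",
                            col.names = c("index", "seed", "payload"),
                            colClasses = c("integer", "integer", "character"))
  pmf <- robust_soliton(M, cc, dd)
  members <- vector("list", nrow(body))
  degree <- integer(nrow(body))
  payload <- vector("list", nrow(body))
  for (i in seq_len(nrow(body))) {
    withr::with_seed(body$seed[i], {
      d <- sample.int(M, 1L, prob = pmf)
      mem <- sort(sample.int(M, d))
    })
    degree[i] <- d
    members[[i]] <- mem
    bytes <- body$payload[i]
    payload[[i]] <- as.raw(strtoi(substring(bytes,
                                            seq(1, nchar(bytes), 2),
                                            seq(2, nchar(bytes), 2)),
                                  base = 16L))
  }
  out <- tibble(index = body$index, seed = body$seed, degree = degree,
                members = members, payload = payload)
  attr(out, "M") <- M
  attr(out, "chunk_size") <- cs
  attr(out, "soliton") <- c(c = cc, delta = dd)
  class(out) <- c("droplet_set", class(tibble()))
  out
}
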