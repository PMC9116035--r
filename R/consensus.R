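#' Positional majority voting
#'
#' Combines the reads of one reference into a consensus by per-position
#' plurality. Only reads whose length equals the reference length enter the
#' tally: positional voting is ill-defined across lengths, so indel-carrying
#' reads are excluded by default (`mode = "strict"`). With `mode = "length"`
#' the tally instead runs at the plurality read length, accepting consensus
#' sequences that differ in length from the reference. If no read qualifies
#' the sequence is LOST (`NA`).
#'
#' Ties are broken by a fixed, documented-as-arbitrary base order
#' (default `A < C < G < T`) so runs are replayable.
#'
#' @param reads Character vector of read sequences, or a tibble with `seq`
#'   and `mult` columns (a [read_set] subset).
#' @param reference_length Length of the originating reference (>= 1).
#' @param mult Read multiplicities (recycled; ignored when `reads` is a
#'   tibble carrying its own).
#' @param tie_order Base order used to break positional ties.
#' @param mode `"strict"` (default) or `"length"`, see above.
#' @return The consensus string, or `NA_character_` when lost. The number of
#'   contributing reads is attached as attribute `"contributing"`.
#' @examples
#' vote(c("ACGT", "AGGT", "AGGT"), 4)            # "AGGT"
#' vote(c("ACGT", "ACGT", "AGGT", "AGGT"), 4)    # tie at pos 1 -> "ACGT"
#' vote(character(0), 4)                         # NA: lost
#' @export
vote <- function(reads, reference_length, mult = 1,
                 tie_order = c("A", "C", "G", "T"),
                 mode = c("strict", "length")) {
  mode <- match.arg(mode)
  stopifnot(reference_length >= 1)
  if (is.data.frame(reads)) {
    mult <- reads$mult
    reads <- reads$seq
  }
  mult <- rep_len(as.numeric(mult), length(reads))
  len <- reference_length
  if (mode == "length" && length(reads) > 0L) {
    # plurality read length, ties toward the reference length
    lens <- nchar(reads)
    tl <- rowsum(mult, lens)
    cand <- as.integer(rownames(tl))
    best <- tl[, 1L] == max(tl[, 1L])
    len <- if (any(cand[best] == reference_length)) reference_length
           else min(cand[best])
  }
  qual <- nchar(reads) == len
  if (!any(qual)) {
    out <- NA_character_
    attr(out, "contributing") <- 0
    return(out)
  }
  seqs <- reads[qual]
  w <- mult[qual]
  chars <- matrix(match(unlist(strsplit(seqs, "", fixed = TRUE)),
                        tie_order),
                  nrow = len)
  tall <- vapply(seq_along(tie_order),
                 function(b) as.numeric((chars == b) %*% w),
                 numeric(len))
  if (len == 1L) tall <- matrix(tall, nrow = 1L)
  winner <- max.col(tall, ties.method = "first")
  out <- paste(tie_order[winner], collapse = "")
  attr(out, "contributing") <- sum(w)
  out
}

#' Count voting errors against the reference
#'
#' Hamming distance when lengths match (the only case under strict voting);
#' unit-cost edit distance otherwise.
#'
#' @param consensus Consensus string (not `NA`).
#' @param reference Reference string.
#' @return Integer error count.
#' @export
count_voting_errors <- function(consensus, reference) {
  stopifnot(!is.na(consensus))
  if (nchar(consensus) == nchar(reference)) {
    sum(utf8ToInt(consensus) != utf8ToInt(reference))
  } else {
    as.integer(attr(seq_diff(reference, consensus), "cost"))
  }
}

#' Call consensus sequences for every reference of a read set
#'
#' @param reads A [read_set] (or a `channel_run` holding one).
#' @inheritParams vote
#' @return Tibble with one row per reference: `ref`, `id`, `consensus`
#'   (`NA` = lost), `contributing`, `n_err` (positional voting errors) and
#'   `byte_err` (byte errors at 4 nt per byte, see [byte_errors()]).
#' @export
consensus_calls <- function(reads, tie_order = c("A", "C", "G", "T"),
                            mode = c("strict", "length")) {
  mode <- match.arg(mode)
  if (inherits(reads, "channel_run")) reads <- reads$reads
  refs <- attr(reads, "references")
  ids <- attr(reads, "ref_ids")
  by_ref <- split(seq_len(nrow(reads)), factor(reads$ref,
                                               levels = seq_along(refs)))
  res <- purrr::map(seq_along(refs), function(r) {
    rows <- by_ref[[r]]
    v <- vote(reads[rows, ], nchar(refs[r]), tie_order = tie_order,
              mode = mode)
    if (is.na(v)) {
      list(consensus = NA_character_, contributing = 0,
           n_err = NA_integer_, byte_err = NA_integer_)
    } else {
      list(consensus = as.character(v),
           contributing = attr(v, "contributing"),
           n_err = count_voting_errors(as.character(v), refs[r]),
           byte_err = byte_errors(as.character(v), refs[r]))
    }
  })
  tibble(ref = seq_along(refs), id = ids,
         consensus = purrr::map_chr(res, "consensus"),
         contributing = purrr::map_dbl(res, "contributing"),
         n_err = purrr::map_int(res, "n_err"),
         byte_err = purrr::map_int(res, "byte_err"))
}

#' Summarize a channel run
#'
#' Votes consensus sequences and assembles the run's noise profile: the lost
#' count `N_l` (references with no qualifying reads), the error-number
#' histogram `N_e(i)` (references with exactly `i` positional voting
#' errors), the byte-error histogram used by the redundancy design, mean
#' sequencing depth, and the per-stage copy-number snapshots. The exact
#' partition `sum_i N_e(i) + N_l = M` holds on every run and is asserted.
#'
#' @param run A `channel_run` (from [run_channel()]) or a [read_set].
#' @inheritParams vote
#' @return A `channel_summary` list with elements `M`, `N_l`, `calls`
#'   (per-reference tibble), `N_e` (tibble `errors`, `n_seq`), `byte_hist`
#'   (tibble `errors`, `n_seq`), `mean_depth`, `snapshots`.
#' @export
summarize_run <- function(run, tie_order = c("A", "C", "G", "T"),
                          mode = c("strict", "length")) {
  reads <- if (inherits(run, "channel_run")) run$reads else run
  if (is.null(reads)) {
    abort("This run has no reads; execute the sequencing stage first.",
          class = "dnachannel_error_validation")
  }
  calls <- consensus_calls(reads, tie_order = tie_order, mode = mode)
  M <- nrow(calls)
  N_l <- sum(is.na(calls$consensus))
  ne <- table(calls$n_err[!is.na(calls$consensus)])
  N_e <- tibble(errors = as.integer(names(ne)), n_seq = as.integer(ne))
  stopifnot(sum(N_e$n_seq) + N_l == M)
  bh <- table(calls$byte_err[!is.na(calls$consensus)])
  byte_hist <- tibble(errors = as.integer(names(bh)), n_seq = as.integer(bh))
  structure(list(
    M = M, N_l = N_l, calls = calls, N_e = N_e, byte_hist = byte_hist,
    mean_depth = mean(read_depths(reads)$reads),
    snapshots = if (inherits(run, "channel_run")) run$snapshots else NULL,
    seed = if (inherits(run, "channel_run")) run$seed else NA_integer_
  ), class = "channel_summary")
}

#' @export
print.channel_summary <- function(x, ...) {
  cat(sprintf("<channel_summary> M = %d | lost N_l = %d (%.2f%%) | mean depth %.1f\n",
              x$M, x$N_l, 100 * x$N_l / x$M, x$mean_depth))
  err <- x$N_e[x$N_e$errors > 0, ]
  cat(sprintf("  sequences with voting errors: %d (%.2f%%)\n",
              sum(err$n_seq), 100 * sum(err$n_seq) / x$M))
  invisible(x)
}

#' Export a summary as JSON / TSV
#'
#' @param x A `channel_summary`.
#' @param path Output file (`.json` for the full summary, or a TSV path for
#'   the histograms).
#' @export
write_summary <- function(x, path) {
  stopifnot(inherits(x, "channel_summary"))
  obj <- list(M = x$M, N_l = x$N_l, mean_depth = x$mean_depth,
              N_e = setNames(as.list(x$N_e$n_seq), x$N_e$errors),
              byte_errors = setNames(as.list(x$byte_hist$n_seq),
                                     x$byte_hist$errors))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_summary
#' @param snapshots Snapshot tibble from a `channel_run`.
#' @export
write_snapshots <- function(snapshots, path) {
  utils::write.table(as.data.frame(snapshots), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
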