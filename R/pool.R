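#' Oligo pools as variant tables
#'
#' A `seq_pool` is the state passed between channel stages: a tibble with one
#' row per *error type* (variant) of a reference sequence, holding
#'
#' * `ref`   - integer index of the reference sequence,
#' * `edits` - canonical edit string identifying the variant (`""` =
#'   error-free type; see [parse_edits()]),
#' * `count` - copy number of that variant (stored as double; PCR counts
#'   overflow integers).
#'
#' The reference sequences themselves, their ids and a free-text stage label
#' travel as attributes. A reference whose total copy number is zero has no
#' rows and is *lost*; [pool_totals()] reports totals and lost flags.
#'
#' @param references Character vector of DNA strings (or a tibble with `id`
#'   and `seq` columns as returned by [read_fasta()]).
#' @param counts Initial copy number per reference (recycled; default 1).
#' @param ids Reference ids; default `seq_1`, `seq_2`, ...
#' @param stage Stage label recorded on the pool.
#' @return A `seq_pool` tibble.
#' @examples
#' p <- seq_pool(c("ACGTACGT", "TTGGCCAA"), counts = 100)
#' pool_totals(p)
#' @export
seq_pool <- function(references, counts = 1, ids = NULL, stage = "input") {
  if (is.data.frame(references)) {
    ids <- ids %||% references$id
    references <- references$seq
  }
  stopifnot(is.character(references), length(references) >= 1L,
            all(nzchar(references)))
  if (any(grepl("[^ACGT]", references))) {
    abort("References must be strings over A, C, G, T.",
          class = "dnachannel_error_validation")
  }
  M <- length(references)
  counts <- rep_len(as.numeric(counts), M)
  if (any(counts < 0)) {
    abort("Copy numbers must be non-negative.",
          class = "dnachannel_error_validation")
  }
  ids <- ids %||% paste0("seq_", seq_len(M))
  variants <- tibble(ref = seq_len(M), edits = "", count = counts)
  variants <- variants[variants$count > 0, ]
  new_seq_pool(variants, references, ids, stage)
}

new_seq_pool <- function(variants, references, ids, stage) {
  stopifnot(all(c("ref", "edits", "count") %in% names(variants)))
  out <- as_tibble(variants[, c("ref", "edits", "count")])
  attr(out, "references") <- references
  attr(out, "ref_ids") <- ids
  attr(out, "stage") <- stage
  class(out) <- c("seq_pool", class(tibble()))
  out
}

#' @rdname seq_pool
#' @param pool A `seq_pool`.
#' @export
pool_references <- function(pool) attr(pool, "references")

#' @rdname seq_pool
#' @export
pool_stage <- function(pool) attr(pool, "stage")

#' @rdname seq_pool
#' @export
pool_totals <- function(pool) {
  refs <- pool_references(pool)
  tot <- numeric(length(refs))
  agg <- rowsum(pool$count, pool$ref)
  tot[as.integer(rownames(agg))] <- agg[, 1L]
  tibble(ref = seq_along(refs), id = attr(pool, "ref_ids"),
         total = tot, lost = tot == 0)
}

#' @export
print.seq_pool <- function(x, ...) {
  tot <- pool_totals(x)
  cat(sprintf(
    "<seq_pool> %d references, %d variant rows, %.4g molecules (%d lost) [stage: %s]\n",
    length(pool_references(x)), nrow(x), sum(x$count), sum(tot$lost),
    pool_stage(x)))
  NextMethod()
}

# re-aggregate identical (ref, edits) variants and drop zero counts
consolidate_pool <- function(variants, pool, stage = pool_stage(pool)) {
  dt <- as.data.table(variants)[count > 0]
  dt <- dt[, list(count = as.numeric(sum(count))), by = list(ref, edits)]
  setorder(dt, ref, edits)
  new_seq_pool(as_tibble(dt), pool_references(pool), attr(pool, "ref_ids"),
               stage)
}

#' Serialize a variant table
#'
#' Writes/reads the variant table of a pool as TSV with columns
#' `reference_id`, `edits` (canonical edit string) and `count`. The edit
#' string grammar is documented in [parse_edits()] and round-trips
#' bit-exactly.
#'
#' @param pool A `seq_pool`.
#' @param path File path.
#' @param references Reference sequences (needed to rebuild a pool when
#'   reading).
#' @return `write_variants()` returns `path` invisibly; `read_variants()`
#'   returns a `seq_pool`.
#' @export
write_variants <- function(pool, path) {
  ids <- attr(pool, "ref_ids")
  df <- data.frame(reference_id = ids[pool$ref], edits = pool$edits,
                   count = format(pool$count, scientific = FALSE, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_variants
#' @param ids Reference ids matching `references`.
#' @param stage Stage label for the rebuilt pool.
#' @export
read_variants <- function(path, references, ids = NULL, stage = "imported") {
  if (is.data.frame(references)) {
    ids <- ids %||% references$id
    references <- references$seq
  }
  ids <- ids %||% paste0("seq_", seq_along(references))
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "numeric"),
                          na.strings = NULL)
  ref <- match(df$reference_id, ids)
  if (anyNA(ref)) {
    abort("Variant table refers to unknown reference ids.",
          class = "dnachannel_error_validation")
  }
  v <- tibble(ref = ref, edits = df$edits, count = df$count)
  consolidate_pool(v, new_seq_pool(v, references, ids, stage))
}

#' Turn a pool's variants into actual sequences
#'
#' Materializes every variant row of a pool (or any tibble with `ref` and
#' `edits` columns) against its reference.
#'
#' @param pool A `seq_pool`.
#' @return The pool tibble with a `seq` column appended.
#' @export
materialize_pool <- function(pool) {
  refs <- pool_references(pool)
  out <- as_tibble(pool)
  key <- paste(out$ref, out$edits)
  uk <- which(!duplicated(key))
  # one vectorized token parse over all distinct variants, then a light
  # per-variant application (the exported materialize() revalidates; this
  # internal path trusts canonical strings the simulator built itself)
  toks <- strsplit(out$edits[uk], ";", fixed = TRUE)
  nt <- lengths(toks)
  tk <- unlist(toks, use.names = FALSE)
  pos <- as.integer(sub("[SDI].*$", "", tk))
  op <- sub("^[0-9]+([SDI]).*$", "\\1", tk)
  base <- sub("^[0-9]+[SDI]", "", tk)
  ends <- cumsum(nt)
  starts <- ends - nt + 1L
  ref_chars <- strsplit(refs, "", fixed = TRUE)
  useq <- character(length(uk))
  for (i in seq_along(uk)) {
    if (nt[i] == 0L || !nzchar(out$edits[uk[i]])) {
      useq[i] <- refs[out$ref[uk[i]]]
      next
    }
    sl <- starts[i]:ends[i]
    useq[i] <- apply_tokens(ref_chars[[out$ref[uk[i]]]],
                            pos[sl], op[sl], base[sl])
  }
  out$seq <- useq[match(key, key[uk])]
  out
}

# tokens must be in canonical order (pos asc, S < D < I, insertions
# left-to-right within a position)
apply_tokens <- function(chars, pos, op, base) {
  L <- length(chars)
  s <- op == "S"
  if (any(s)) chars[pos[s] + 1L] <- base[s]
  d <- op == "D"
  if (any(d)) chars[pos[d] + 1L] <- ""
  ins <- which(op == "I")
  if (length(ins) > 0L) {
    pre <- character(L + 1L)
    for (ii in ins) {
      p <- pos[ii] + 1L
      pre[p] <- paste0(pre[p], base[ii])
    }
    paste0(paste0(pre[seq_len(L)], chars, collapse = ""), pre[L + 1L])
  } else {
    paste0(chars, collapse = "")
  }
}
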