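#' Edit strings
#'
#' A variant (error type) of a reference sequence is identified by a canonical
#' edit string: semicolon-joined tokens, each `"<pos>S<base>"` (substitution),
#' `"<pos>D"` (deletion) or `"<pos>I<base>"` (insertion), with `pos` a 0-based
#' offset into the *original* reference. The empty string is the error-free
#' type. Tokens are sorted by position, then by operation (`S` < `D` < `I`),
#' so equal variants compare equal as strings. Insertions are placed before
#' the base at `pos`; `pos` equal to the reference length appends at the end.
#'
#' Keeping all coordinates in original-reference space makes edit application
#' order-independent: substitutions are applied first, then deletions, then
#' insertions, and the result does not depend on the order tokens were
#' acquired.
#'
#' @param edits An edit string, or a data frame with columns `pos`, `op`,
#'   `base` as returned by `parse_edits()`.
#' @return `parse_edits()` returns a tibble with columns `pos` (integer),
#'   `op` (`"S"`, `"D"` or `"I"`) and `base` (`NA` for deletions);
#'   `format_edits()` returns the canonical edit string.
#' @examples
#' parse_edits("1SG;2D;4IA")
#' format_edits(parse_edits("2D;1SG"))  # canonical order restored
#' @name edit-strings
NULL

OP_LEVELS <- c("S", "D", "I")

#' @rdname edit-strings
#' @export
parse_edits <- function(edits) {
  if (is.data.frame(edits)) {
    ed <- as_tibble(edits)
  } else {
    stopifnot(is.character(edits), length(edits) == 1L)
    if (!nzchar(edits)) {
      return(tibble(pos = integer(), op = character(), base = character()))
    }
    toks <- strsplit(edits, ";", fixed = TRUE)[[1]]
    m <- regmatches(toks, regexec("^([0-9]+)([SDI])([ACGT]?)$", toks))
    bad <- lengths(m) == 0L
    if (any(bad)) {
      abort(sprintf("Malformed edit token(s): %s",
                    paste(toks[bad], collapse = ", ")),
            class = "dnachannel_error_validation")
    }
    ed <- tibble(
      pos  = as.integer(vapply(m, `[`, character(1), 2L)),
      op   = vapply(m, `[`, character(1), 3L),
      base = vapply(m, `[`, character(1), 4L)
    )
    ed$base[ed$base == ""] <- NA_character_
  }
  if (any(ed$op %in% c("S", "I") & is.na(ed$base))) {
    abort("Substitutions and insertions require a base.",
          class = "dnachannel_error_validation")
  }
  if (any(ed$op == "D" & !is.na(ed$base))) ed$base[ed$op == "D"] <- NA_character_
  arrange(ed, pos, match(op, OP_LEVELS))
}

#' @rdname edit-strings
#' @export
format_edits <- function(edits) {
  ed <- parse_edits(edits)
  if (nrow(ed) == 0L) return("")
  paste0(ed$pos, ed$op, ifelse(is.na(ed$base), "", ed$base), collapse = ";")
}

#' Apply an edit list to a reference sequence
#'
#' Materializes a variant: substitutions are applied first, then deletions,
#' then insertions, all in original-reference coordinates. An insertion at
#' position `pos` lands before the reference base at `pos`; `pos` equal to
#' the reference length appends.
#'
#' @param reference A DNA string over `ACGT`.
#' @param edits Edit string or parsed edit table (see [parse_edits()]).
#' @return The edited DNA string.
#' @examples
#' materialize("ACGT", "")            # "ACGT"
#' materialize("ACGT", "1SG")         # "AGGT"
#' materialize("ACGT", "2D")          # "ACT"
#' materialize("ACGT", "2IT")         # "ACTGT"
#' @seealso [seq_diff()] for the inverse operation.
#' @export
materialize <- function(reference, edits) {
  stopifnot(is.character(reference), length(reference) == 1L, nzchar(reference))
  ed <- parse_edits(edits)
  chars <- strsplit(reference, "", fixed = TRUE)[[1]]
  L <- length(chars)
  if (nrow(ed) == 0L) return(reference)
  if (any(ed$pos < 0L) || any(ed$pos > L) ||
      any(ed$pos == L & ed$op != "I")) {
    abort("Edit position out of range for this reference.",
          class = "dnachannel_error_coordinate")
  }
  subs <- ed[ed$op == "S", ]
  if (nrow(subs) > 0L) {
    if (any(chars[subs$pos + 1L] == subs$base)) {
      abort("Substitution equal to the reference base.",
            class = "dnachannel_error_validation")
    }
    chars[subs$pos + 1L] <- subs$base
  }
  out <- chars
  del <- ed$pos[ed$op == "D"]
  if (length(del) > 0L) out[del + 1L] <- ""
  ins <- ed[ed$op == "I", ]
  if (nrow(ins) > 0L) {
    pre <- character(L + 1L)
    for (i in seq_len(nrow(ins))) {
      p <- ins$pos[i] + 1L
      pre[p] <- paste0(pre[p], ins$base[i])
    }
    paste0(paste0(pre[seq_len(L)], out, collapse = ""), pre[L + 1L])
  } else {
    paste0(out, collapse = "")
  }
}

#' Minimum edit script between a reference and a read
#'
#' Unit-cost global alignment (Needleman-Wunsch over substitutions,
#' deletions and insertions) returning a canonical edit string whose
#' [materialize()] reproduces the read. Ties are broken deterministically:
#' matches are consumed from the right, and otherwise substitution is
#' preferred over deletion over insertion, which shifts indels to the
#' leftmost equivalent position.
#'
#' @param reference,read Non-empty DNA strings.
#' @return Canonical edit string; its edit distance is attached as the
#'   `"cost"` attribute.
#' @examples
#' seq_diff("ACGT", "ACGT")   # ""
#' seq_diff("ACGT", "AGGT")   # "1SG"
#' materialize("ACGT", seq_diff("ACGT", "ATTACGT"))
#' @export
seq_diff <- function(reference, read) {
  stopifnot(nzchar(reference), nzchar(read))
  a <- strsplit(reference, "", fixed = TRUE)[[1]]
  b <- strsplit(read, "", fixed = TRUE)[[1]]
  n <- length(a); m <- length(b)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1L] <- 0:n
  D[1L, ] <- 0:m
  for (i in seq_len(n)) {
    same <- a[i] == b
    prev <- D[i, ]
    cur <- D[i + 1L, ]
    # row-wise DP; inner loop unavoidable for the running minimum
    for (jj in seq_len(m)) {
      cur[jj + 1L] <- min(prev[jj] + !same[jj],   # diag
                          prev[jj + 1L] + 1L,     # deletion
                          cur[jj] + 1L)           # insertion
    }
    D[i + 1L, ] <- cur
  }
  # traceback with canonical preference: match > sub > del > ins
  i <- n; j <- m
  pos <- integer(0); op <- character(0); base <- character(0)
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L && a[i] == b[j] && D[i + 1L, j + 1L] == D[i, j]) {
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && j > 0L && D[i + 1L, j + 1L] == D[i, j] + 1L) {
      pos <- c(pos, i - 1L); op <- c(op, "S"); base <- c(base, b[j])
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && D[i + 1L, j + 1L] == D[i, j + 1L] + 1L) {
      pos <- c(pos, i - 1L); op <- c(op, "D"); base <- c(base, NA_character_)
      i <- i - 1L
    } else {
      pos <- c(pos, i); op <- c(op, "I"); base <- c(base, b[j])
      j <- j - 1L
    }
  }
  # collected right-to-left; reverse so same-position insertions keep
  # left-to-right order (the stable canonical sort preserves it)
  out <- format_edits(tibble(pos = rev(pos), op = rev(op), base = rev(base)))
  attr(out, "cost") <- D[n + 1L, m + 1L]
  out
}
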