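#' Error-generation primitive (E step)
#'
#' Pushes every molecule of a pool through a stochastic mutation process:
#' each molecule independently acquires new substitutions, deletions and
#' insertions at the per-base probabilities in `rates`. Molecules that
#' acquire no new edit stay in their parent variant; molecules that do move
#' to new (or merged) variants carrying the parent's edits plus the new
#' ones. Total copy number per reference is conserved exactly, and this is
#' asserted on every call.
#'
#' The implementation never touches unaffected molecules: for each variant
#' of count `n` the number of molecules with at least one new edit is a
#' single binomial draw with success probability `1 - (1 - p)^L`, where `p`
#' is the mean per-position event probability for that reference
#' (substitution + deletion + insertion mass). Each affected molecule then
#' draws its number of edited positions from the truncated binomial
#' `Bin(L, p) | >= 1`, positions uniformly without replacement, and the
#' event type at a position by the normalized mass
#' `(T_sub row of the base, P_del, P_ins)`. For flat (preset) rates this is
#' distributionally identical to naive per-molecule simulation; for
#' base-dependent substitution matrices the position choice is homogenized
#' over the reference composition.
#'
#' New-edit coordinates live in original-reference space. When a new edit
#' collides with an inherited one the newest substitution wins, a deletion
#' beats a substitution, and at most one insertion is kept per position.
#'
#' @param pool A [seq_pool()].
#' @param rates An [error_rates()] object.
#' @param seed Optional integer seed (otherwise the current RNG stream is
#'   used).
#' @return A `seq_pool` with the same per-reference totals.
#' @examples
#' p <- seq_pool(c("ACGTACGTAC"), counts = 1000)
#' generate_errors(p, error_rates(sub = 0.01, del = 0.01), seed = 1)
#' @export
generate_errors <- function(pool, rates, seed = NULL) {
  validate_rates(rates)
  if (nrow(pool) == 0L) return(pool)
  with_seed_maybe(seed, generate_errors_impl(pool, rates))
}

generate_errors_impl <- function(pool, rates) {
  refs <- pool_references(pool)
  L <- nchar(refs)
  psub <- sub_prob_by_base(rates)         # by base A C G T
  p_evt <- rates$P_del + rates$P_ins      # base-independent part

  # per-reference mean per-position event probability
  ref_chars <- strsplit(refs, "", fixed = TRUE)
  base_idx <- lapply(ref_chars, match, DNA_BASES)
  pbar <- vapply(base_idx, function(bi) mean(psub[bi]) + p_evt, numeric(1))
  if (all(pbar == 0)) return(pool)
  p_any <- 1 - (1 - pbar)^L

  counts0 <- pool_totals(pool)$total

  # molecules leaving their parent variant: one binomial per variant row
  m <- rbinom(nrow(pool), pool$count, p_any[pool$ref])
  A <- sum(m)
  if (A == 0) return(pool)

  parent_row <- rep.int(seq_len(nrow(pool)), m)       # affected molecule -> row
  mref <- pool$ref[parent_row]
  Lm <- L[mref]
  # edited positions per affected molecule: Bin(L, pbar) truncated at >= 1
  pb <- pbar[mref]
  kk <- qbinom(runif(A, pbinom(0, Lm, pb), 1), Lm, pb)
  kk[kk < 1L] <- 1L   # numeric safety at tiny probabilities

  ev_mol <- rep.int(seq_len(A), kk)
  ev_ref <- mref[ev_mol]
  E <- length(ev_mol)
  ev_pos <- as.integer(floor(runif(E) * L[ev_ref]))    # 0-based
  # resample duplicate (molecule, position) pairs: positions are drawn
  # without replacement within a molecule
  repeat {
    key <- ev_mol * 2^16 + ev_pos
    dup <- duplicated(key)
    if (!any(dup)) break
    ev_pos[dup] <- as.integer(floor(runif(sum(dup)) * L[ev_ref[dup]]))
  }

  # event type by normalized (sub mass at base, P_del, P_ins)
  offsets <- c(0L, cumsum(nchar(refs)))
  all_bases <- unlist(base_idx, use.names = FALSE)
  ev_base <- all_bases[offsets[ev_ref] + ev_pos + 1L]  # base index 1..4
  w_sub <- psub[ev_base]
  tot_w <- w_sub + rates$P_del + rates$P_ins
  u <- runif(E) * tot_w
  is_sub <- u < w_sub
  is_del <- !is_sub & u < w_sub + rates$P_del
  is_ins <- !is_sub & !is_del

  tok <- character(E)
  if (any(is_sub)) {
    # target base from the normalized off-diagonal row of T_sub
    Toff <- rates$T_sub; diag(Toff) <- 0
    Tn <- Toff / rowSums(Toff)
    cum <- t(apply(Tn, 1, cumsum))
    r <- runif(sum(is_sub))
    bi <- ev_base[is_sub]
    newb <- 1L + (r > cum[cbind(bi, 1)]) + (r > cum[cbind(bi, 2)]) +
      (r > cum[cbind(bi, 3)])
    tok[is_sub] <- paste0(ev_pos[is_sub], "S", DNA_BASES[newb])
  }
  if (any(is_del)) tok[is_del] <- paste0(ev_pos[is_del], "D")
  if (any(is_ins)) {
    tok[is_ins] <- paste0(ev_pos[is_ins], "I",
                          DNA_BASES[sample.int(4L, sum(is_ins), replace = TRUE)])
  }

  new_edits <- compose_edits(pool$edits[parent_row],
                             data.table(mol = ev_mol, pos = ev_pos,
                                        op = ifelse(is_sub, "S",
                                                    ifelse(is_del, "D", "I")),
                                        tok = tok))

  out <- data.table(ref = mref, edits = new_edits, count = 1)
  stay <- data.table(ref = pool$ref, edits = pool$edits,
                     count = pool$count - m)
  res <- consolidate_pool(rbind(stay, out), pool)

  counts1 <- pool_totals(res)$total
  stopifnot(identical(counts0, counts1))   # E steps conserve molecules
  res
}

# merge per-molecule new edit tokens with inherited parent edit strings,
# applying the collision rules (newest S wins, D beats S, one I per pos)
compose_edits <- function(parent_edits, ev) {
  A <- length(parent_edits)
  has_parent <- nzchar(parent_edits)
  if (any(has_parent)) {
    pidx <- which(has_parent)
    ptoks <- strsplit(parent_edits[pidx], ";", fixed = TRUE)
    pn <- lengths(ptoks)
    ptok <- unlist(ptoks, use.names = FALSE)
    pdt <- data.table(
      mol = rep.int(pidx, pn),
      pos = as.integer(sub("[SDI].*$", "", ptok)),
      op  = sub("^[0-9]+([SDI]).*$", "\\1", ptok),
      tok = ptok, ord = 0L
    )
    ev[, ord := 1L]
    ev <- rbind(pdt, ev)
  } else {
    ev[, ord := 1L]
  }
  # substitutions/deletions share a position slot; insertions have their own
  cls <- as.integer(ev$op == "I")
  key <- ev$mol * 262144 + ev$pos * 2 + cls
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    # rare: a molecule holds an inherited and a new token at one position
    dd <- ev[dup][order(mol, pos, ord)]
    dd <- dd[, {
      if (any(op == "D")) list(op = "D", tok = paste0(pos[1L], "D"), ord = 0L)
      else list(op = op[.N], tok = tok[.N], ord = 0L)
    }, by = list(mol, pos)]
    data.table::setcolorder(dd, names(ev))
    ev <- rbind(ev[!dup], dd)
  }
  # canonical order, then one vectorized collapse per group size
  ord2 <- order(ev$mol, ev$pos, match(ev$op, OP_LEVELS))
  out <- character(A)
  grp <- collapse_tokens(ev$mol[ord2], ev$tok[ord2])
  out[grp$mol] <- grp$edits
  none <- !nzchar(out)
  out[none] <- parent_edits[none]
  out
}

# collapse sorted (mol, tok) pairs into one ";"-joined string per molecule;
# vectorized over groups of equal size (sizes are small and bounded)
collapse_tokens <- function(mol, tok) {
  r <- rle(mol)
  sizes <- r$lengths
  starts <- cumsum(sizes) - sizes + 1L
  out <- character(length(sizes))
  for (s in sort(unique(sizes))) {
    gi <- which(sizes == s)
    if (s == 1L) {
      out[gi] <- tok[starts[gi]]
    } else {
      parts <- lapply(seq_len(s) - 1L, function(o) tok[starts[gi] + o])
      out[gi] <- do.call(paste, c(parts, sep = ";"))
    }
  }
  list(mol = r$values, edits = out)
}
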