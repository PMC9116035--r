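#' Per-base error rates for one channel stage
#'
#' The stochastic mutation model of a stage is parameterized by a 4x4 base
#' substitution matrix `T_sub` (row = original base, column = new base,
#' diagonal = no-change mass), a per-base deletion probability `P_del` and a
#' per-position insertion probability `P_ins`.
#'
#' `error_rates(sub = s)` builds a uniform substitution matrix in which each
#' base mutates with total probability `s`, split equally over the three
#' other bases. A custom `sub_matrix` may instead give relative off-diagonal
#' weights per row (rows are normalized to sum to `sub`), e.g. to weight
#' deamination-like C->T / G->A transitions.
#'
#' @param sub Total per-base substitution probability.
#' @param del Per-base deletion probability.
#' @param ins Per-position insertion probability.
#' @param sub_matrix Optional 4x4 matrix of relative substitution weights
#'   (diagonal ignored), rows/cols ordered A, C, G, T.
#' @return An `error_rates` object (list with `T_sub`, `P_del`, `P_ins`).
#' @examples
#' error_rates(sub = 0.003, del = 0.0015, ins = 5e-4)
#' ngs_rates()
#' nanopore_rates()
#' @export
error_rates <- function(sub = 0, del = 0, ins = 0, sub_matrix = NULL) {
  check_prob(sub, "sub"); check_prob(del, "del"); check_prob(ins, "ins")
  if (is.null(sub_matrix)) {
    W <- matrix(1, 4, 4); diag(W) <- 0
  } else {
    stopifnot(is.matrix(sub_matrix), all(dim(sub_matrix) == c(4, 4)),
              all(sub_matrix >= 0))
    W <- sub_matrix
    diag(W) <- 0
    if (any(rowSums(W) == 0) && sub > 0) {
      abort("Each row of `sub_matrix` needs a positive off-diagonal weight.",
            class = "dnachannel_error_validation")
    }
  }
  T_sub <- W / ifelse(rowSums(W) > 0, rowSums(W), 1) * sub
  diag(T_sub) <- 1 - rowSums(T_sub)
  dimnames(T_sub) <- list(DNA_BASES, DNA_BASES)
  structure(list(T_sub = T_sub, P_del = del, P_ins = ins),
            class = "error_rates")
}

validate_rates <- function(rates) {
  if (!inherits(rates, "error_rates")) {
    abort("`rates` must be an `error_rates` object.",
          class = "dnachannel_error_validation")
  }
  Ts <- rates$T_sub
  off <- Ts; diag(off) <- 0
  if (any(Ts < -1e-12) || any(Ts > 1 + 1e-12) || any(rowSums(off) > 1 + 1e-12)) {
    abort("Invalid substitution matrix.", class = "dnachannel_error_validation")
  }
  check_prob(rates$P_del, "P_del"); check_prob(rates$P_ins, "P_ins")
  invisible(rates)
}

#' @export
print.error_rates <- function(x, ...) {
  off <- x$T_sub; diag(off) <- 0
  cat(sprintf("<error_rates> sub per base: %s | del: %g | ins: %g\n",
              paste(format(rowSums(off), digits = 3), collapse = "/"),
              x$P_del, x$P_ins))
  invisible(x)
}

# per-base total substitution probability, in base order A C G T
sub_prob_by_base <- function(rates) {
  off <- rates$T_sub; diag(off) <- 0
  rowSums(off)
}

#' @rdname error_rates
#' @export
ngs_rates <- function() error_rates(sub = 0.001, del = 1e-4, ins = 1e-4)

#' @rdname error_rates
#' @export
nanopore_rates <- function() error_rates(sub = 0.03, del = 0.02, ins = 0.015)

#' @rdname error_rates
#' @export
synthesis_rates <- function() error_rates(sub = 0.003, del = 0.0015, ins = 5e-4)

#' @rdname error_rates
#' @export
decay_rates <- function() {
  # deamination-weighted damage: C->T and G->A dominate
  W <- matrix(1, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  W["C", "T"] <- 8; W["G", "A"] <- 8
  error_rates(sub = 0.001, sub_matrix = W)
}
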