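#' Distribution-change primitive (D step)
#'
#' Replaces every variant's copy number by an independent draw from a
#' count-conditional distribution: `n'_ij ~ sampler(n_ij)`. Variants whose
#' new count is zero are dropped; references whose total drops to zero are
#' thereby lost. This is the primitive behind synthesis copy draws, decay,
#' PCR growth, sub-sampling and read allocation.
#'
#' @param pool A [seq_pool()].
#' @param sampler Function taking the vector of current counts and returning
#'   a same-length vector of new non-negative counts.
#' @param ... Passed on to `sampler`.
#' @param seed Optional integer seed.
#' @param stage Stage label for the returned pool.
#' @return A `seq_pool`.
#' @examples
#' p <- seq_pool(c("ACGT", "TTAA"), counts = 1000)
#' change_distribution(p, function(n) rbinom(length(n), n, 0.5), seed = 1)
#' thin_pool(p, 0.25, seed = 1)
#' @export
change_distribution <- function(pool, sampler, ..., seed = NULL,
                                stage = pool_stage(pool)) {
  new_counts <- with_seed_maybe(seed, sampler(pool$count, ...))
  if (length(new_counts) != nrow(pool)) {
    abort("`sampler` must return one count per variant.",
          class = "dnachannel_error_contract")
  }
  if (any(is.na(new_counts)) || any(new_counts < 0)) {
    abort("`sampler` returned negative or missing counts.",
          class = "dnachannel_error_contract")
  }
  out <- tibble(ref = pool$ref, edits = pool$edits, count = new_counts)
  consolidate_pool(out, pool, stage = stage)
}

#' @rdname change_distribution
#' @param prob Binomial thinning probability: each molecule survives
#'   independently with probability `prob`.
#' @export
thin_pool <- function(pool, prob, seed = NULL, stage = pool_stage(pool)) {
  check_prob(prob, "prob")
  change_distribution(pool, function(n) rbinom(length(n), n, prob),
                      seed = seed, stage = stage)
}
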