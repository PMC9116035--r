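#' Channel stages
#'
#' The five stage models of the storage channel, each built from the two
#' primitives ([generate_errors()], [change_distribution()]) and chainable
#' with the pipe:
#'
#' * `synthesis()` draws the initial copy number of every designed sequence
#'   i.i.d. from the configured count distribution (binomial by default,
#'   reflecting the coupling-efficiency stochasticity of array synthesis),
#'   then applies synthesis errors.
#' * `decay()` thins every variant binomially by the survival probability and
#'   applies damage substitutions.
#' * `pcr()` draws one amplification efficiency per reference (truncated
#'   normal, giving persistent between-sequence amplification bias) and grows
#'   each variant per cycle as `n <- n + Binomial(n, efficiency)`; with
#'   `dilute = TRUE` the amplified pool is then thinned back to its input
#'   molecule count, like the post-PCR aliquot of a real protocol.
#' * `sample_pool()` binomially thins every variant by the sampling ratio.
#' * `sequence_pool()` allocates a total read budget of
#'   `depth * (number of surviving references)` multinomially across all
#'   molecules (so coverage inherits the pool's copy-number skew), applies
#'   platform errors to the drawn reads, and returns a [read_set].
#'
#' @param references Character vector or `tibble(id, seq)` of designed
#'   sequences.
#' @param pool A [seq_pool()].
#' @param config A [channel_config()].
#' @param seed Optional integer seed for the stage.
#' @return A `seq_pool`, or a `read_set` for `sequence_pool()`.
#' @examples
#' cfg <- channel_config(synthesis = list(mean_depth = 50),
#'                       sampling = list(ratio = 0.5))
#' refs <- c("ACGTACGTACGTACGT", "TTGGCCAATTGGCCAA")
#' synthesis(refs, cfg, seed = 1) |>
#'   decay(cfg, seed = 2) |>
#'   sample_pool(cfg, seed = 3)
#' @name channel-stages
NULL

#' @rdname channel-stages
#' @export
synthesis <- function(references, config = channel_config(), seed = NULL) {
  validate_config(config)
  if (is.data.frame(references)) {
    ids <- references$id; references <- references$seq
  } else ids <- NULL
  if (length(references) == 0L) {
    abort("Empty reference set.", class = "dnachannel_error_validation")
  }
  cs <- config$synthesis
  with_seed_maybe(seed, {
    M <- length(references)
    counts <- switch(
      cs$count_distribution,
      binomial = rbinom(M, size = round(cs$mean_depth / cs$prob), prob = cs$prob),
      negative_binomial = rnbinom(M, mu = cs$mean_depth, size = cs$size),
      abort("Unknown count distribution.", class = "dnachannel_error_validation")
    )
    pool <- seq_pool(references, counts = counts, ids = ids,
                     stage = "synthesis")
    generate_errors(pool, cs$rates)
  })
}

#' @rdname channel-stages
#' @export
decay <- function(pool, config = channel_config(), seed = NULL) {
  validate_config(config)
  cd <- config$decay
  with_seed_maybe(seed, {
    out <- thin_pool(pool, cd$survival_prob, stage = "decay")
    generate_errors(out, cd$rates)
  })
}

#' @rdname channel-stages
#' @export
pcr <- function(pool, config = channel_config(), seed = NULL) {
  validate_config(config)
  cp <- config$pcr
  if (cp$cycles == 0L) return(new_seq_pool(pool, pool_references(pool),
                                           attr(pool, "ref_ids"), "pcr"))
  with_seed_maybe(seed, {
    M <- length(pool_references(pool))
    eff <- pmin(pmax(rnorm(M, cp$efficiency, cp$bias_sigma), 0), 1)
    n_in <- sum(pool$count)
    counts <- pool$count
    p <- eff[pool$ref]
    capped <- FALSE
    for (cyc in seq_len(cp$cycles)) {
      counts <- counts + rbinom(length(counts), counts, p)
      over <- counts > cp$ceiling
      if (any(over)) {
        counts[over] <- cp$ceiling
        capped <- TRUE
      }
    }
    if (capped) {
      warn("PCR counts reached the configured ceiling and were capped.",
           class = "dnachannel_warn_overflow")
    }
    out <- consolidate_pool(
      tibble(ref = pool$ref, edits = pool$edits, count = counts),
      pool, stage = "pcr")
    if (isTRUE(cp$dilute) && sum(out$count) > n_in) {
      out <- thin_pool(out, n_in / sum(out$count), stage = "pcr")
    }
    out
  })
}

#' @rdname channel-stages
#' @export
sample_pool <- function(pool, config = channel_config(), seed = NULL) {
  validate_config(config)
  with_seed_maybe(seed, thin_pool(pool, config$sampling$ratio,
                                  stage = "sampling"))
}

#' @rdname channel-stages
#' @export
sequence_pool <- function(pool, config = channel_config(), seed = NULL) {
  validate_config(config)
  cq <- config$sequencing
  refs <- pool_references(pool)
  with_seed_maybe(seed, {
    surviving <- sum(pool_totals(pool)$total > 0)
    total_reads <- round(cq$depth * surviving)
    if (total_reads == 0 || nrow(pool) == 0L) {
      empty <- tibble(ref = integer(), edits = character(), count = numeric())
      new_read_set(empty, pool)
    } else {
      alloc <- as.numeric(rmultinom(1, total_reads, prob = pool$count))
      rp <- consolidate_pool(
        tibble(ref = pool$ref, edits = pool$edits, count = alloc),
        pool, stage = "sequencing")
      rp <- generate_errors(rp, cq$rates)
      new_read_set(rp, pool)
    }
  })
}

#' Sequencing readouts grouped by originating reference
#'
#' A `read_set` keeps the pool representation for reads: a tibble with one
#' row per distinct read sequence per reference (`ref`, `edits`, `seq`,
#' `mult`), with ground-truth linkage to the originating reference retained
#' (no clustering is performed, matching the simulation's output contract).
#'
#' @param x A `read_set`.
#' @return `read_lost()` returns the per-reference lost flag (zero reads of
#'   any length); `read_depths()` the per-reference read totals.
#' @name read_set
NULL

new_read_set <- function(read_pool, pool) {
  tb <- materialize_pool(new_seq_pool(read_pool, pool_references(pool),
                                      attr(pool, "ref_ids"), "reads"))
  out <- tibble(ref = tb$ref, edits = tb$edits, seq = tb$seq, mult = tb$count)
  attr(out, "references") <- pool_references(pool)
  attr(out, "ref_ids") <- attr(pool, "ref_ids")
  class(out) <- c("read_set", class(tibble()))
  out
}

#' @rdname read_set
#' @export
read_depths <- function(x) {
  refs <- attr(x, "references")
  tot <- numeric(length(refs))
  if (nrow(x) > 0L) {
    agg <- rowsum(x$mult, x$ref)
    tot[as.integer(rownames(agg))] <- agg[, 1L]
  }
  tibble(ref = seq_along(refs), id = attr(x, "ref_ids"), reads = tot)
}

#' @rdname read_set
#' @export
read_lost <- function(x) read_depths(x)$reads == 0

#' @export
print.read_set <- function(x, ...) {
  d <- read_depths(x)
  cat(sprintf("<read_set> %d references, %.0f reads (%d with zero reads)\n",
              nrow(d), sum(d$reads), sum(d$reads == 0)))
  NextMethod()
}

#' Run the full channel
#'
#' Executes synthesis -> decay -> PCR -> sampling -> sequencing with
#' deterministically derived per-stage child seeds, capturing a per-stage
#' snapshot of the copy-number distribution (per-reference totals only, to
#' bound memory). Stages listed in `skip` are identity-passed, supporting
#' single-stage study; `through` stops the channel early (e.g.
#' `through = "sampling"` returns the pool prepared for sequencing, which can
#' then be read out at several depths with [sequence_pool()]).
#'
#' @param references Designed sequences (character vector or
#'   `tibble(id, seq)`).
#' @param config A [channel_config()].
#' @param seed Integer base seed; per-stage seeds are derived with
#'   [derive_seed()], so a run is byte-identical under the same seed.
#' @param skip Character vector of stage names to pass through unchanged
#'   (among `"decay"`, `"pcr"`, `"sampling"`).
#' @param through Last stage to execute (default `"sequencing"`).
#' @return A `channel_run` list: `reads` (a [read_set], or `NULL` if the run
#'   stopped early), `pool` (the final `seq_pool`), `snapshots` (tibble of
#'   per-stage per-reference molecule totals), `config`, `seed`.
#' @examples
#' cfg <- channel_config(synthesis = list(mean_depth = 30),
#'                       sampling = list(ratio = 0.5),
#'                       sequencing = list(depth = 10))
#' run <- run_channel(c("ACGTACGTACGTACGT", "TTGGCCAATTGGCCAA"), cfg, seed = 1)
#' run$snapshots
#' @export
run_channel <- function(references, config = channel_config(), seed = 1L,
                        skip = character(),
                        through = c("sequencing", "sampling", "pcr", "decay",
                                    "synthesis")) {
  validate_config(config)
  through <- match.arg(through)
  stages <- c("synthesis", "decay", "pcr", "sampling", "sequencing")
  todo <- stages[seq_len(match(through, stages))]
  bad <- setdiff(skip, c("decay", "pcr", "sampling"))
  if (length(bad) > 0L) {
    abort(sprintf("Cannot skip stage(s): %s", paste(bad, collapse = ", ")),
          class = "dnachannel_error_validation")
  }
  snapshots <- list()
  take <- function(pool, st) {
    tt <- pool_totals(pool)
    snapshots[[st]] <<- tibble(stage = st, ref = tt$ref, total = tt$total)
    pool
  }
  wrap <- function(st, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Channel failed in stage '%s': %s", st,
                    conditionMessage(e)),
            class = "dnachannel_error_stage", parent = e)
    })
  }
  pool <- wrap("synthesis",
               synthesis(references, config, derive_seed(seed, "synthesis")))
  pool <- take(pool, "synthesis")
  reads <- NULL
  for (st in setdiff(todo, "synthesis")) {
    if (st %in% skip) next
    sseed <- derive_seed(seed, st)
    if (st == "sequencing") {
      reads <- wrap(st, sequence_pool(pool, config, sseed))
      snapshots[["sequencing"]] <-
        tibble(stage = "sequencing", ref = read_depths(reads)$ref,
               total = read_depths(reads)$reads)
    } else {
      pool <- wrap(st, switch(st,
                              decay = decay(pool, config, sseed),
                              pcr = pcr(pool, config, sseed),
                              sampling = sample_pool(pool, config, sseed)))
      pool <- take(pool, st)
    }
  }
  structure(list(reads = reads, pool = pool,
                 snapshots = bind_rows(snapshots),
                 references = pool_references(pool),
                 ref_ids = attr(pool, "ref_ids"),
                 config = config, seed = seed),
            class = "channel_run")
}

#' @export
print.channel_run <- function(x, ...) {
  cat(sprintf("<channel_run> %d references, seed %d, stages: %s\n",
              length(x$references), x$seed,
              paste(unique(x$snapshots$stage), collapse = " -> ")))
  if (!is.null(x$reads)) print(read_depths(x$reads))
  invisible(x)
}
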