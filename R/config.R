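#' Channel configuration
#'
#' Bundles all stage parameters of the storage channel. Every element has a
#' default so `channel_config()` is a complete, runnable configuration; any
#' stage can be overridden piecemeal, e.g.
#' `channel_config(sampling = list(ratio = 0.01))`.
#'
#' Stage parameters:
#'
#' * `synthesis`: `mean_depth` (expected copies per designed sequence),
#'   `count_distribution` (`"binomial"`, with success probability `prob`, or
#'   `"negative_binomial"` with dispersion `size`), and an [error_rates()]
#'   object for synthesis errors.
#' * `decay`: `survival_prob` (per-molecule survival through storage) and
#'   damage `rates` (deamination-weighted substitutions by default).
#' * `pcr`: `cycles`, `efficiency` (mean per-cycle duplication probability),
#'   `bias_sigma` (between-sequence SD of the per-sequence efficiency,
#'   drawn once per reference and truncated to `[0, 1]`), `dilute` (when
#'   `TRUE`, the amplified pool is thinned back to its pre-PCR molecule
#'   count, mirroring the aliquot taken after amplification) and `ceiling`
#'   (overflow guard on per-variant counts).
#' * `sampling`: `ratio`, the fraction of the physical pool carried into
#'   sequencing preparation.
#' * `sequencing`: `depth` (mean reads per surviving reference) and platform
#'   `rates` ([ngs_rates()] by default, [nanopore_rates()] as the high-error
#'   preset).
#'
#' @param synthesis,decay,pcr,sampling,sequencing Named lists overriding the
#'   defaults above.
#' @return A `channel_config` object.
#' @examples
#' cfg <- channel_config(sequencing = list(depth = 50))
#' cfg$sequencing$depth
#' @export
channel_config <- function(synthesis = list(), decay = list(), pcr = list(),
                           sampling = list(), sequencing = list()) {
  defaults <- list(
    synthesis = list(mean_depth = 5000, count_distribution = "binomial",
                     prob = 0.5, size = 10, rates = synthesis_rates()),
    decay = list(survival_prob = 0.99, rates = decay_rates()),
    pcr = list(cycles = 10L, efficiency = 0.8, bias_sigma = 0.03,
               dilute = TRUE, ceiling = 1e12),
    sampling = list(ratio = 0.001),
    sequencing = list(depth = 30, rates = ngs_rates())
  )
  override <- list(synthesis = synthesis, decay = decay, pcr = pcr,
                   sampling = sampling, sequencing = sequencing)
  cfg <- purrr::map2(defaults, override, utils::modifyList)
  structure(cfg, class = "channel_config")
}

validate_config <- function(cfg) {
  if (!inherits(cfg, "channel_config")) {
    abort("`config` must be a `channel_config` object.",
          class = "dnachannel_error_validation")
  }
  stopifnot(cfg$synthesis$mean_depth >= 0, cfg$pcr$cycles >= 0,
            cfg$sequencing$depth >= 0)
  check_prob(cfg$decay$survival_prob, "survival_prob")
  check_prob(cfg$sampling$ratio, "ratio")
  check_prob(cfg$pcr$efficiency, "efficiency")
  validate_rates(cfg$synthesis$rates)
  validate_rates(cfg$decay$rates)
  validate_rates(cfg$sequencing$rates)
  invisible(cfg)
}

#' @export
print.channel_config <- function(x, ...) {
  cat("<channel_config>\n")
  cat(sprintf("  synthesis:  mean_depth %g (%s)\n", x$synthesis$mean_depth,
              x$synthesis$count_distribution))
  cat(sprintf("  decay:      survival %g\n", x$decay$survival_prob))
  cat(sprintf("  pcr:        %d cycles, efficiency %g, bias_sigma %g%s\n",
              x$pcr$cycles, x$pcr$efficiency, x$pcr$bias_sigma,
              if (isTRUE(x$pcr$dilute)) ", diluted" else ""))
  cat(sprintf("  sampling:   ratio %g\n", x$sampling$ratio))
  cat(sprintf("  sequencing: depth %g\n", x$sequencing$depth))
  invisible(x)
}

rates_to_list <- function(r) {
  list(sub_matrix = unname(apply(r$T_sub, 1, as.numeric, simplify = FALSE)),
       del = r$P_del, ins = r$P_ins)
}

rates_from_list <- function(l) {
  W <- do.call(rbind, l$sub_matrix)
  off <- W; diag(off) <- 0
  er <- error_rates(sub = max(rowSums(off)), del = l$del, ins = l$ins)
  er$T_sub <- W
  dimnames(er$T_sub) <- list(DNA_BASES, DNA_BASES)
  validate_rates(er)
}

#' Read and write channel configurations as YAML
#'
#' The on-disk schema mirrors [channel_config()]: one top-level key per
#' stage, with `rates` expanded into a `sub_matrix` (4 rows of 4
#' probabilities, diagonal = no-change mass), `del` and `ins`. Reading is
#' tolerant to key order; [config_hash()] is invariant to it.
#'
#' @param cfg A `channel_config`.
#' @param path YAML file path.
#' @return `read_channel_config()` returns a `channel_config`;
#'   `write_channel_config()` returns `path` invisibly.
#' @export
write_channel_config <- function(cfg, path) {
  validate_config(cfg)
  out <- unclass(cfg)
  for (st in c("synthesis", "decay", "sequencing")) {
    out[[st]]$rates <- rates_to_list(out[[st]]$rates)
  }
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname write_channel_config
#' @export
read_channel_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (st in c("synthesis", "decay", "sequencing")) {
    if (!is.null(raw[[st]]$rates)) {
      raw[[st]]$rates <- rates_from_list(raw[[st]]$rates)
    }
  }
  cfg <- channel_config(synthesis = raw$synthesis %||% list(),
                        decay = raw$decay %||% list(),
                        pcr = raw$pcr %||% list(),
                        sampling = raw$sampling %||% list(),
                        sequencing = raw$sequencing %||% list())
  validate_config(cfg)
  cfg
}

#' @rdname write_channel_config
#' @details `config_hash()` canonicalizes the configuration (keys sorted
#'   recursively, numbers at 15 significant digits) before hashing, so
#'   reordering keys in a YAML file does not change the hash.
#' @export
config_hash <- function(cfg) {
  canon <- function(x) {
    if (inherits(x, "error_rates")) x <- rates_to_list(x)
    if (is.list(x)) {
      if (!is.null(names(x))) x <- x[order(names(x))]
      lapply(x, canon)
    } else if (is.numeric(x)) {
      signif(x, 10)   # robust to serialization round-trips
    } else x
  }
  js <- jsonlite::toJSON(canon(unclass(cfg)), auto_unbox = TRUE, digits = 15)
  h <- 17
  for (b in utf8ToInt(as.character(js))) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
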