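#' FASTA / FASTQ input and output
#'
#' Thin wrappers over Biostrings giving the package's tabular interface:
#' sequences travel as `tibble(id, seq)`. `write_fastq()` expands read
#' multiplicities into individual records with suffixed ids
#' (`<id>_read1`, `_read2`, ...) and a constant quality placeholder, since
#' the simulator does not model per-base qualities.
#'
#' @param path File path.
#' @param records `tibble(id, seq)`.
#' @param reads A [read_set].
#' @param quality Constant quality character for FASTQ output.
#' @return `read_fasta()` returns `tibble(id, seq)`; writers return `path`
#'   invisibly.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  tibble(id = names(x), seq = as.character(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(records, path) {
  x <- Biostrings::DNAStringSet(setNames(records$seq, records$id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname read_fasta
#' @export
write_fastq <- function(reads, path, quality = "I") {
  stopifnot(inherits(reads, "read_set"))
  ids <- attr(reads, "ref_ids")
  if (nrow(reads) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  rep_idx <- rep.int(seq_len(nrow(reads)), reads$mult)
  seqs <- reads$seq[rep_idx]
  base_id <- ids[reads$ref][rep_idx]
  within_ref <- stats::ave(seq_along(base_id), base_id, FUN = seq_along)
  recs <- paste0("@", base_id, "_read", within_ref, "\n", seqs, "\n+\n",
                 strrep(quality, nchar(seqs)))
  writeLines(recs, path)
  invisible(path)
}

#' Run replicated channel experiments
#'
#' Executes the full channel + voting + total-lost accounting `n_replicates`
#' times with independently derived child seeds
#' (`derive_seed(base_seed, "replicate", i)`), returning one row per
#' replicate ready for the distribution fits of the redundancy design.
#'
#' @param references Designed sequences (`tibble(id, seq)` or character).
#' @param config A [channel_config()].
#' @param n_replicates Number of replicates (>= 1).
#' @param base_seed Base seed.
#' @param L_RS Reed-Solomon parity bytes used for the `N_tl` column
#'   (`NULL` to omit).
#' @param keep_summaries Keep the full [summarize_run()] objects as a list
#'   column (needed by [redundancy_plan()]).
#' @return Tibble with `replicate`, `seed`, `N_l`, `n_err_seqs`,
#'   `mean_depth`, `N_tl` (when `L_RS` is given) and `summary` (when kept).
#' @export
run_replicates <- function(references, config = channel_config(),
                           n_replicates = 10L, base_seed = 1L, L_RS = NULL,
                           keep_summaries = TRUE) {
  stopifnot(n_replicates >= 1)
  rows <- purrr::map(seq_len(n_replicates), function(i) {
    sd_i <- derive_seed(base_seed, "replicate", i)
    res <- tryCatch({
      run <- run_channel(references, config, seed = sd_i)
      summarize_run(run)
    }, error = function(e) {
      abort(sprintf("Replicate %d (seed %d) failed: %s", i, sd_i,
                    conditionMessage(e)),
            class = "dnachannel_error_replicate", parent = e)
    })
    tibble(replicate = i, seed = sd_i, M = res$M, N_l = res$N_l,
           n_err_seqs = sum(res$N_e$n_seq[res$N_e$errors > 0]),
           mean_depth = res$mean_depth,
           N_tl = if (is.null(L_RS)) NA_real_
                  else total_lost(res, L_RS),
           summary = if (keep_summaries) list(res) else list(NULL))
  })
  out <- bind_rows(rows)
  if (is.null(L_RS)) out$N_tl <- NULL
  if (!keep_summaries) out$summary <- NULL
  out
}

#' Write a run's outputs plus a manifest
#'
#' Persists a `channel_run`: reads as FASTQ, consensus as FASTA, snapshots
#' and summary, plus a JSON manifest recording the configuration hash,
#' seed, stage list, output paths and wall time, so a run directory is
#' self-describing and replayable.
#'
#' @param run A `channel_run` with reads.
#' @param dir Output directory (created if needed).
#' @return The manifest (invisibly).
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "channel_run"), !is.null(run$reads))
  t0 <- Sys.time()
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(reads = file.path(dir, "reads.fastq"),
                consensus = file.path(dir, "consensus.fasta"),
                snapshots = file.path(dir, "snapshots.tsv"),
                summary = file.path(dir, "summary.json"))
  write_fastq(run$reads, paths$reads)
  s <- summarize_run(run)
  ok <- !is.na(s$calls$consensus)
  write_fasta(tibble(id = s$calls$id[ok], seq = s$calls$consensus[ok]),
              paths$consensus)
  write_snapshots(run$snapshots, paths$snapshots)
  write_summary(s, paths$summary)
  manifest <- list(config_hash = config_hash(run$config), seed = run$seed,
                   stages = unique(run$snapshots$stage),
                   paths = paths,
                   wall_time_s = as.numeric(difftime(Sys.time(), t0,
                                                     units = "secs")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
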