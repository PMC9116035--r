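#' Error profile of a simulated channel
#'
#' The inputs of the redundancy design: the number of data chunks `N`, the
#' per-sequence payload length `L_d` (bytes), the fountain decoding overhead
#' `beta`, the lost-sequence count `N_l` and the byte-error histogram
#' `N_e(i)` (sequences whose voted consensus carries exactly `i` byte
#' errors).
#'
#' All terms of the density expression must share one scale: droplets
#' needed are counted per `N` chunks, so losses must be too. When the
#' profile is built from a simulated pool of `pool_size` sequences
#' (default: the summary's `M`), `N_l` and `N_e` counts are rescaled by
#' `n_chunks / pool_size`, i.e. they enter as per-sequence rates times
#' `N`. Directly supplied `N_l`/`N_e` without a `pool_size` are taken as
#' already commensurate with `n_chunks`.
#'
#' @param summary A [summarize_run()] result, or `NULL` when `N_l`/`N_e` are
#'   given directly.
#' @param n_chunks Number of data chunks `N` (= `M` of the fountain code).
#' @param payload_bytes Payload length `L_d` in bytes.
#' @param beta Fountain decoding overhead (droplets needed `= (1+beta)N`).
#' @param N_l,N_e Direct inputs when no summary is given: lost count and a
#'   tibble/data.frame with `errors`, `n_seq` columns (byte errors).
#' @param pool_size Number of sequences the counts were measured on (for
#'   rescaling, see Details).
#' @return An `error_profile` object.
#' @export
error_profile <- function(summary = NULL, n_chunks, payload_bytes, beta,
                          N_l = NULL, N_e = NULL, pool_size = NULL) {
  if (!is.null(summary)) {
    stopifnot(inherits(summary, "channel_summary"))
    N_l <- summary$N_l
    N_e <- summary$byte_hist
    pool_size <- pool_size %||% summary$M
  }
  n_chunks <- as.integer(n_chunks)
  payload_bytes <- as.integer(payload_bytes)
  N_e <- as_tibble(N_e)
  if (!is.null(pool_size)) {
    stopifnot(pool_size >= 1)
    f <- n_chunks / pool_size
    N_l <- N_l * f
    N_e$n_seq <- N_e$n_seq * f
  }
  stopifnot(all(c("errors", "n_seq") %in% names(N_e)),
            N_l >= 0, all(N_e$n_seq >= 0), n_chunks >= 1, payload_bytes >= 1,
            beta >= 0)
  structure(list(N = n_chunks, L_d = payload_bytes, beta = beta,
                 N_l = N_l, N_e = N_e),
            class = "error_profile")
}

#' @export
print.error_profile <- function(x, ...) {
  cat(sprintf(
    "<error_profile> N = %d chunks, L_d = %d bytes, beta = %.3f, N_l = %.4g, %.4g sequences with byte errors\n",
    x$N, x$L_d, x$beta, x$N_l, sum(x$N_e$n_seq[x$N_e$errors > 0])))
  invisible(x)
}

profile_tail <- function(profile, k, tail = c("capacity", "printed")) {
  tail <- match.arg(tail)
  lo <- if (tail == "capacity") k + 1L else pmax(k, 1L)
  vapply(lo, function(l) sum(profile$N_e$n_seq[profile$N_e$errors >= l]),
         numeric(1))
}

#' Information density under a Reed-Solomon budget
#'
#' Estimated bits-per-base efficiency of the full code when the
#' Reed-Solomon parity corrects up to `k` byte errors (`L_RS = 2k` parity
#' bytes): the product of the within-sequence density `L_d / (L_d + 2k)`
#' and the across-sequence density
#' `N / ((1 + beta) N + N_l + T(k))`, where `T(k)` counts the sequences
#' whose byte errors exceed the correction capacity and which are therefore
#' discarded, acting like additional losses.
#'
#' With `tail = "capacity"` (default) a sequence is discarded when its byte
#' errors exceed `floor(L_RS / 2) = k`; `tail = "printed"` discards already
#' at `k` errors, the more conservative reading.
#'
#' @param profile An [error_profile()].
#' @param k Correctable byte errors (vectorized); `L_RS = 2k`.
#' @param tail Tail convention, see above.
#' @return Numeric vector of densities in `(0, 1]`.
#' @examples
#' pr <- error_profile(n_chunks = 100, payload_bytes = 32, beta = 0.05,
#'                     N_l = 3,
#'                     N_e = data.frame(errors = c(0, 2), n_seq = c(90, 7)))
#' information_density(pr, k = 2)   # (32/36) * (100/115)
#' @export
information_density <- function(profile, k, tail = c("capacity", "printed")) {
  stopifnot(inherits(profile, "error_profile"), all(k >= 0))
  tail <- match.arg(tail)
  tl <- profile_tail(profile, as.integer(k), tail)
  (profile$L_d / (profile$L_d + 2 * k)) *
    (profile$N / ((1 + profile$beta) * profile$N + profile$N_l + tl))
}

#' Scan Reed-Solomon lengths and pick the densest
#'
#' `density_table()` evaluates [information_density()] on `k = 0..k_max`;
#' `choose_rs_length()` returns `L_RS = 2 * argmax_k D(k)` (smallest `k` on
#' ties).
#'
#' @inheritParams information_density
#' @param k_max Largest correction capacity scanned.
#' @return `density_table()`: tibble with `k`, `L_RS`, `density`;
#'   `choose_rs_length()`: integer `L_RS` with the table attached as
#'   attribute `"density_table"`.
#' @export
density_table <- function(profile, k_max = 8L, tail = c("capacity", "printed")) {
  tail <- match.arg(tail)
  k <- 0:k_max
  tibble(k = k, L_RS = 2L * k,
         density = information_density(profile, k, tail = tail))
}

#' @rdname density_table
#' @export
choose_rs_length <- function(profile, k_max = 8L,
                             tail = c("capacity", "printed")) {
  tb <- density_table(profile, k_max, tail)
  L <- tb$L_RS[which.max(tb$density)]   # which.max takes the smallest k on ties
  attr(L, "density_table") <- tb
  L
}

#' Total lost count under a Reed-Solomon budget
#'
#' Lost sequences plus sequences whose byte errors exceed the correction
#' capacity `floor(L_RS / 2)` and are discarded before fountain decoding.
#'
#' @param summary A [summarize_run()] result (or an [error_profile()]).
#' @param L_RS Reed-Solomon parity bytes per sequence.
#' @return Integer `N_tl`.
#' @export
total_lost <- function(summary, L_RS) {
  stopifnot(L_RS >= 0)
  cap <- L_RS %/% 2
  if (inherits(summary, "channel_summary")) {
    N_l <- summary$N_l
    hist <- summary$byte_hist
  } else {
    stopifnot(inherits(summary, "error_profile"))
    N_l <- summary$N_l
    hist <- summary$N_e
  }
  N_l + sum(hist$n_seq[hist$errors > cap])
}

#' Fit the total-lost distribution
#'
#' Total lost counts over repeated runs behave like a sum of many rare
#' independent loss events, so a Poisson law is fitted; the MLE of its rate
#' is the sample mean. An Anderson-Darling-type statistic against the
#' fitted distribution is attached as a goodness-of-fit measure.
#'
#' @param samples Non-negative integer `N_tl` values from repeated runs
#'   (>= 2).
#' @return A `lost_fit` object (fields `lambda`, `n`, `ad`).
#' @examples
#' fit_lost(c(2, 4, 3, 3))$lambda  # 3
#' @export
fit_lost <- function(samples) {
  if (length(samples) < 2L) {
    abort("Need at least 2 samples.", class = "dnachannel_error_validation")
  }
  if (any(samples < 0) || any(is.na(samples))) {
    abort("Lost counts must be non-negative.",
          class = "dnachannel_error_validation")
  }
  lambda <- mean(samples)
  ad <- if (lambda > 0) ad_statistic(samples, function(q) ppois(q, lambda))
        else NA_real_
  structure(list(lambda = lambda, n = length(samples), ad = ad),
            class = "lost_fit")
}

#' @export
print.lost_fit <- function(x, ...) {
  cat(sprintf("<lost_fit> Poisson lambda = %.4g (n = %d, AD = %.3g)\n",
              x$lambda, x$n, x$ad))
  invisible(x)
}

#' Anderson-Darling statistic against a fitted distribution
#'
#' The classical A-squared statistic
#' `-n - (1/n) * sum (2i - 1) (log F(x_(i)) + log(1 - F(x_(n+1-i))))`
#' computed for an arbitrary CDF. Used here to compare candidate families
#' (e.g. Gumbel vs normal) for the droplets-needed samples; for discrete
#' fits it is reported as a descriptive measure, not a formal test.
#'
#' @param x Samples.
#' @param cdf Vectorized cumulative distribution function.
#' @return The A-squared value.
#' @export
ad_statistic <- function(x, cdf) {
  n <- length(x)
  u <- pmin(pmax(cdf(sort(x)), 1e-12), 1 - 1e-12)
  i <- seq_len(n)
  -n - mean((2 * i - 1) * (log(u) + log(1 - rev(u))))
}

# ---- Gumbel (max-type, right-skewed) ------------------------------------

pgumbel <- function(q, loc, scale) exp(-exp(-(q - loc) / scale))

dgumbel <- function(x, loc, scale) {
  z <- (x - loc) / scale
  exp(-z - exp(-z)) / scale
}

qgumbel <- function(p, loc, scale) loc - scale * log(-log(p))

#' Fit the droplets-needed (permitted-lost) distribution
#'
#' The number of droplets a fountain decoder needs, `(1 + beta) M`, is
#' right-skewed over repeated decodings; a Gumbel location-scale family is
#' fitted by maximum likelihood (moment-based start, Nelder-Mead refine).
#' The permitted-lost variable at overhead `alpha` is its reflection
#' `(alpha - beta) M = (1 + alpha) M - (1 + beta) M`, whose discretized pmf
#' [permitted_pmf()] derives per `alpha` from this one fit. The
#' Anderson-Darling statistic of the fit is attached; degenerate samples
#' fall back to a point mass with a warning.
#'
#' @param samples Droplets-needed counts from repeated decodings (>= 5).
#' @param M Number of data chunks.
#' @return A `permitted_fit` object (fields `loc`, `scale`, `M`, `beta_hat`,
#'   `ad`, `degenerate`).
#' @export
fit_permitted <- function(samples, M) {
  if (length(samples) < 5L) {
    abort("Need at least 5 samples.", class = "dnachannel_error_validation")
  }
  stopifnot(M >= 1)
  M <- as.integer(M)
  if (sd(samples) == 0) {
    warn("Degenerate droplets-needed samples; using a point mass.",
         class = "dnachannel_warn_degenerate")
    return(structure(list(loc = samples[1], scale = 0, M = M,
                          beta_hat = samples[1] / M - 1,
                          ad = NA_real_, degenerate = TRUE),
                     class = "permitted_fit"))
  }
  fit <- fit_gumbel(samples)
  structure(list(loc = fit$loc, scale = fit$scale, M = M,
                 beta_hat = mean(samples) / M - 1,
                 ad = ad_statistic(samples,
                                   function(q) pgumbel(q, fit$loc, fit$scale)),
                 degenerate = FALSE),
            class = "permitted_fit")
}

#' @rdname fit_permitted
#' @details `fit_gumbel()` is the bare location/scale MLE, exposed for
#'   model-comparison use.
#' @export
fit_gumbel <- function(samples) {
  s0 <- sd(samples) * sqrt(6) / pi
  l0 <- mean(samples) - 0.5772156649 * s0
  nll <- function(par) {
    if (par[2] <= 0) return(Inf)
    -sum(log(dgumbel(samples, par[1], par[2])))
  }
  opt <- optim(c(l0, s0), nll, method = "Nelder-Mead")
  list(loc = opt$par[1], scale = opt$par[2])
}

#' @export
print.permitted_fit <- function(x, ...) {
  cat(sprintf(
    "<permitted_fit> Gumbel(loc = %.2f, scale = %.2f), M = %d, beta_hat = %.3f (AD = %.3g)\n",
    x$loc, x$scale, x$M, x$beta_hat, x$ad))
  invisible(x)
}

#' Discretized permitted-lost pmf at a given overhead
#'
#' The permitted-lost count at fountain overhead `alpha` is
#' `J = (1 + alpha) M - D` with `D` the fitted droplets-needed variable.
#' Its pmf is obtained by half-integer discretization of the fitted
#' (reflected) Gumbel, `pmf(j) = F_J(j + 0.5) - F_J(j - 0.5)`, renormalized
#' on `[0, t_max]`; mass of `J < 0` (more droplets needed than exist) is
#' reported as attribute `"p_negative"` and counts as certain failure in
#' [failure_probability()].
#'
#' @param fit A [fit_permitted()] object.
#' @param alpha Fountain overhead.
#' @param t_max Truncation bound; default the `1 - 1e-6` quantile of `J`.
#' @return Tibble with `j`, `p`; attributes `p_negative`, `t_max`.
#' @export
permitted_pmf <- function(fit, alpha, t_max = NULL) {
  stopifnot(inherits(fit, "permitted_fit"), alpha >= 0)
  top <- (1 + alpha) * fit$M
  # J = top - D;  F_J(j) = P(D >= top - j) = 1 - F_D(top - j) (continuous D)
  cdf_J <- function(j) {
    if (fit$degenerate) as.numeric(top - fit$loc <= j)
    else 1 - pgumbel(top - j, fit$loc, fit$scale)
  }
  if (is.null(t_max)) {
    t_max <- if (fit$degenerate) max(0, ceiling(top - fit$loc))
             else ceiling(top - qgumbel(1e-6, fit$loc, fit$scale))
    t_max <- max(t_max, 0)
  }
  stopifnot(t_max >= 0)
  j <- 0:t_max
  p <- cdf_J(j + 0.5) - cdf_J(j - 0.5)
  p_neg <- cdf_J(-0.5)
  resid <- 1 - cdf_J(t_max + 0.5)
  if (resid > 1e-4) {
    warn(sprintf("Truncation at t_max = %d leaves %.3g probability mass.",
                 as.integer(t_max), resid),
         class = "dnachannel_warn_truncation")
  }
  # renormalize the non-negative part so pmf + p_negative sum to one
  keep <- sum(p)
  if (keep > 0) p <- p * (1 - p_neg) / keep
  out <- tibble(j = j, p = p)
  attr(out, "p_negative") <- p_neg
  attr(out, "t_max") <- t_max
  out
}

#' Decoding failure probability
#'
#' Decoding fails when the total lost count exceeds the permitted lost
#' count: `p_f = P(N_tl > J)`, evaluated as
#' `sum_j f_J(j) P(N_tl > j)` over the discretized permitted-lost pmf, plus
#' the mass of `J < 0`. `lost` may be a fitted Poisson ([fit_lost()]) or a
#' finite pmf (named numeric vector, names = support), and `permitted`
#' either a [fit_permitted()] object (then `alpha` is required) or a finite
#' pmf; finite pmfs make the computation an exact enumeration, which is the
#' test oracle for the fitted path.
#'
#' @param lost `lost_fit` or named numeric pmf of `N_tl`.
#' @param permitted `permitted_fit` or named numeric pmf of the permitted
#'   lost count.
#' @param alpha Fountain overhead (needed with a `permitted_fit`).
#' @param t_max Truncation bound for the permitted pmf.
#' @return Failure probability in `[0, 1]`.
#' @examples
#' failure_probability(lost = c(`0` = .5, `2` = .5),
#'                     permitted = c(`1` = .5, `3` = .5))   # 0.25
#' @export
failure_probability <- function(lost, permitted, alpha = NULL, t_max = NULL) {
  if (inherits(permitted, "permitted_fit")) {
    stopifnot(!is.null(alpha))
    pj <- permitted_pmf(permitted, alpha, t_max)
    jj <- pj$j; pp <- pj$p
    p_neg <- attr(pj, "p_negative")
  } else {
    jj <- as.numeric(names(permitted))
    pp <- as.numeric(permitted)
    stopifnot(abs(sum(pp) - 1) < 1e-8, all(pp >= 0))
    p_neg <- sum(pp[jj < 0])
    pp <- pp[jj >= 0]; jj <- jj[jj >= 0]
  }
  surv <- if (inherits(lost, "lost_fit")) {
    1 - ppois(jj, lost$lambda)
  } else {
    xs <- as.numeric(names(lost))
    ps <- as.numeric(lost)
    stopifnot(abs(sum(ps) - 1) < 1e-8, all(ps >= 0))
    vapply(jj, function(j) sum(ps[xs > j]), numeric(1))
  }
  min(max(p_neg + sum(pp * surv), 0), 1)
}

#' Scan fountain overheads for a target success probability
#'
#' Computes `p_f(alpha)` on a grid, rescaling the Poisson total-lost rate
#' per overhead as `lambda = p_tl (1 + alpha) N` (more encoded sequences
#' mean proportionally more losses) and re-deriving the permitted-lost pmf
#' from the one droplets-needed fit. Returns the contiguous range of
#' overheads meeting `p_f <= 1 - target_success`.
#'
#' @param p_tl Per-sequence total-loss probability (e.g.
#'   `mean(N_tl) / n_sequences` over replicates).
#' @param permitted A [fit_permitted()] object.
#' @param target_success Required decoding success probability.
#' @param alpha_grid Candidate overheads (ascending).
#' @param N Number of data chunks; defaults to the fit's `M`.
#' @return An `alpha_scan` tibble (`alpha`, `lambda`, `p_f`) with
#'   attributes `alpha_min`, `alpha_max`, `target`.
#' @export
choose_alpha <- function(p_tl, permitted, target_success = 0.99,
                         alpha_grid = seq(0.01, 1, by = 0.01), N = NULL) {
  stopifnot(inherits(permitted, "permitted_fit"),
            target_success > 0, target_success < 1, p_tl >= 0, p_tl <= 1)
  N <- N %||% permitted$M
  alpha_grid <- sort(alpha_grid)
  lam <- p_tl * (1 + alpha_grid) * N
  pf <- vapply(seq_along(alpha_grid), function(i) {
    failure_probability(structure(list(lambda = lam[i]), class = "lost_fit"),
                        permitted, alpha = alpha_grid[i])
  }, numeric(1))
  ok <- pf <= (1 - target_success)
  out <- tibble(alpha = alpha_grid, lambda = lam, p_f = pf)
  if (!any(ok)) {
    inform(sprintf(
      "No overhead on the grid meets the %.3g target (min p_f = %.3g at alpha = %.3g).",
      1 - target_success, min(pf), alpha_grid[which.min(pf)]))
    amin <- NA_real_; amax <- NA_real_
  } else {
    first <- which(ok)[1]
    run_end <- which(!ok & seq_along(ok) > first)
    amin <- alpha_grid[first]
    amax <- alpha_grid[if (length(run_end) > 0) run_end[1] - 1 else length(ok)]
  }
  attr(out, "alpha_min") <- amin
  attr(out, "alpha_max") <- amax
  attr(out, "target") <- target_success
  class(out) <- c("alpha_scan", class(tibble()))
  out
}

#' @export
print.alpha_scan <- function(x, ...) {
  cat(sprintf("<alpha_scan> target success %.3g: alpha in [%s, %s]\n",
              attr(x, "target"),
              format(attr(x, "alpha_min")), format(attr(x, "alpha_max"))))
  NextMethod()
}

#' Full redundancy design from simulation replicates
#'
#' Runs the redundancy-design procedure end to end from replicate summaries
#' and droplets-needed samples: builds the pooled error profile, scans
#' Reed-Solomon lengths for the densest choice, fits the Poisson total-lost
#' and Gumbel droplets-needed laws, and scans fountain overheads for the
#' target success probability.
#'
#' @param summaries List of [summarize_run()] results (replicates).
#' @param droplet_samples Droplets-needed counts from repeated fountain
#'   decodings.
#' @param n_chunks Data chunks `N` (= fountain `M`).
#' @param payload_bytes Payload bytes per sequence `L_d`.
#' @param target_success Required decoding success probability.
#' @param k_max Largest Reed-Solomon capacity scanned.
#' @param alpha_grid Candidate fountain overheads.
#' @param beta Decoding overhead; default estimated as
#'   `mean(droplet_samples) / n_chunks - 1`.
#' @return A `redundancy_plan` with the profile, density table, chosen
#'   `L_RS`, both fits, the `p_f(alpha)` scan and the selected alpha range.
#' @export
redundancy_plan <- function(summaries, droplet_samples, n_chunks,
                            payload_bytes, target_success = 0.99,
                            k_max = 8L, alpha_grid = seq(0.01, 1, 0.01),
                            beta = NULL) {
  stopifnot(length(summaries) >= 1)
  beta <- beta %||% (mean(droplet_samples) / n_chunks - 1)
  # pooled byte-error histogram across replicates (averaged counts)
  all_h <- bind_rows(lapply(summaries, function(s) s$byte_hist))
  hist <- all_h |> group_by(errors) |>
    summarise(n_seq = sum(n_seq) / length(summaries), .groups = "drop")
  N_l <- mean(vapply(summaries, function(s) s$N_l, numeric(1)))
  profile <- error_profile(n_chunks = n_chunks, payload_bytes = payload_bytes,
                           beta = beta, N_l = N_l, N_e = hist,
                           pool_size = summaries[[1]]$M)
  tb <- density_table(profile, k_max)
  L_RS <- tb$L_RS[which.max(tb$density)]
  ntl <- vapply(summaries, total_lost, numeric(1), L_RS = L_RS)
  n_sequences <- summaries[[1]]$M
  lost <- if (length(ntl) >= 2L) fit_lost(ntl) else
    structure(list(lambda = ntl, n = 1L, ad = NA_real_), class = "lost_fit")
  p_tl <- mean(ntl) / n_sequences
  permitted <- fit_permitted(droplet_samples, n_chunks)
  scan <- choose_alpha(p_tl, permitted, target_success,
                       alpha_grid = alpha_grid, N = n_chunks)
  structure(list(profile = profile, density = tb, L_RS = L_RS,
                 peak_density = max(tb$density), N_tl = ntl, p_tl = p_tl,
                 lost = lost, permitted = permitted, alpha_scan = scan,
                 alpha_min = attr(scan, "alpha_min"),
                 alpha_max = attr(scan, "alpha_max"),
                 target_success = target_success),
            class = "redundancy_plan")
}

#' @export
print.redundancy_plan <- function(x, ...) {
  cat("<redundancy_plan>\n")
  cat(sprintf("  L_RS = %d bytes (peak information density %.1f%%)\n",
              x$L_RS, 100 * x$peak_density))
  cat(sprintf("  total lost: Poisson lambda = %.2f (p_tl = %.4f)\n",
              x$lost$lambda, x$p_tl))
  cat(sprintf("  droplets needed: Gumbel(%.1f, %.2f), beta_hat = %.3f\n",
              x$permitted$loc, x$permitted$scale, x$permitted$beta_hat))
  cat(sprintf("  alpha range for %.0f%% success: [%s, %s]\n",
              100 * x$target_success, format(x$alpha_min),
              format(x$alpha_max)))
  invisible(x)
}

#' @rdname redundancy_plan
#' @param plan A `redundancy_plan`.
#' @param path Output JSON path.
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "redundancy_plan"))
  obj <- list(
    L_RS = plan$L_RS, peak_density = plan$peak_density,
    density = as.list(setNames(plan$density$density, plan$density$k)),
    lambda = plan$lost$lambda, p_tl = plan$p_tl,
    gumbel = list(loc = plan$permitted$loc, scale = plan$permitted$scale,
                  beta_hat = plan$permitted$beta_hat),
    alpha_min = plan$alpha_min, alpha_max = plan$alpha_max,
    target_success = plan$target_success,
    pf_curve = as.list(setNames(plan$alpha_scan$p_f, plan$alpha_scan$alpha))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
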