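#' Broom-style tidiers
#'
#' `tidy()` returns the per-term / per-row content of a fitted object as a
#' tibble; `glance()` returns a one-row summary. Available for
#' [fit_lost()], [fit_permitted()], [choose_alpha()] scans,
#' [redundancy_plan()]s and [summarize_run()] summaries.
#'
#' @param x A fitted object from this package.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname tidiers
#' @export
tidy.lost_fit <- function(x, ...) {
  tibble(term = "lambda", estimate = x$lambda,
         std.error = sqrt(x$lambda / x$n))
}

#' @rdname tidiers
#' @export
glance.lost_fit <- function(x, ...) {
  tibble(lambda = x$lambda, n = x$n, ad = x$ad)
}

#' @rdname tidiers
#' @export
tidy.permitted_fit <- function(x, ...) {
  tibble(term = c("location", "scale"), estimate = c(x$loc, x$scale))
}

#' @rdname tidiers
#' @export
glance.permitted_fit <- function(x, ...) {
  tibble(location = x$loc, scale = x$scale, beta_hat = x$beta_hat,
         M = x$M, ad = x$ad, degenerate = x$degenerate)
}

#' @rdname tidiers
#' @export
tidy.alpha_scan <- function(x, ...) as_tibble(x)

#' @rdname tidiers
#' @export
glance.alpha_scan <- function(x, ...) {
  tibble(alpha_min = attr(x, "alpha_min"), alpha_max = attr(x, "alpha_max"),
         target_success = attr(x, "target"))
}

#' @rdname tidiers
#' @export
tidy.redundancy_plan <- function(x, ...) x$density

#' @rdname tidiers
#' @export
glance.redundancy_plan <- function(x, ...) {
  tibble(L_RS = x$L_RS, peak_density = x$peak_density,
         lambda = x$lost$lambda, p_tl = x$p_tl,
         beta_hat = x$permitted$beta_hat,
         alpha_min = x$alpha_min, alpha_max = x$alpha_max,
         target_success = x$target_success)
}

#' @rdname tidiers
#' @export
tidy.channel_summary <- function(x, ...) x$calls

#' @rdname tidiers
#' @export
glance.channel_summary <- function(x, ...) {
  tibble(M = x$M, N_l = x$N_l,
         n_err_seqs = sum(x$N_e$n_seq[x$N_e$errors > 0]),
         mean_depth = x$mean_depth)
}
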