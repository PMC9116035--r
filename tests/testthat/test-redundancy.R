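test_that("information density follows the two-factor formula", {
  pr <- error_profile(n_chunks = 100, payload_bytes = 32, beta = 0.05,
                      N_l = 3,
                      N_e = data.frame(errors = c(0, 3), n_seq = c(90, 7)))
  # k = 2 corrects 2 byte errors; the 7 three-error sequences are discarded
  expect_equal(information_density(pr, 2), (32 / 36) * (100 / 115))
  # perfect channel, no overhead: density 1 at k = 0
  perfect <- error_profile(n_chunks = 50, payload_bytes = 20, beta = 0,
                           N_l = 0,
                           N_e = data.frame(errors = 0, n_seq = 50))
  expect_equal(information_density(perfect, 0), 1)
  # strictly decreasing in N_l
  worse <- error_profile(n_chunks = 100, payload_bytes = 32, beta = 0.05,
                         N_l = 10,
                         N_e = data.frame(errors = c(0, 3), n_seq = c(90, 7)))
  expect_lt(information_density(worse, 2), information_density(pr, 2))
  # printed-tail mode also discards exactly-k-error sequences
  pr2 <- error_profile(n_chunks = 100, payload_bytes = 32, beta = 0.05,
                       N_l = 3,
                       N_e = data.frame(errors = c(0, 2), n_seq = c(90, 7)))
  expect_equal(information_density(pr2, 2, tail = "printed"),
               (32 / 36) * (100 / 115))
  expect_equal(information_density(pr2, 2), (32 / 36) * (100 / 108))
})

test_that("density is invariant to scaling counts together", {
  pr1 <- error_profile(n_chunks = 100, payload_bytes = 20, beta = 0.1,
                       N_l = 4,
                       N_e = data.frame(errors = c(0, 1, 2),
                                        n_seq = c(80, 12, 4)))
  pr10 <- error_profile(n_chunks = 1000, payload_bytes = 20, beta = 0.1,
                        N_l = 40,
                        N_e = data.frame(errors = c(0, 1, 2),
                                         n_seq = c(800, 120, 40)))
  expect_equal(information_density(pr1, 0:4), information_density(pr10, 0:4))
})

test_that("profiles built from a pool rescale losses to the chunk scale", {
  prof_direct <- error_profile(n_chunks = 100, payload_bytes = 20, beta = 0.1,
                               N_l = 4,
                               N_e = data.frame(errors = c(0, 1),
                                                n_seq = c(380, 16)),
                               pool_size = 400)
  expect_equal(prof_direct$N_l, 1)
  expect_equal(prof_direct$N_e$n_seq, c(95, 4))
})

test_that("choose_rs_length maximizes density (ties to the smallest k)", {
  clean <- error_profile(n_chunks = 100, payload_bytes = 20, beta = 0,
                         N_l = 0, N_e = data.frame(errors = 0, n_seq = 100))
  expect_equal(choose_rs_length(clean), 0L, ignore_attr = TRUE)
  # discarding the 30 single-error sequences costs more than 2 parity bytes:
  # D(0) = 100/130 = 0.769 < D(1) = (20/22)*1 = 0.909 > D(2) = 20/24
  burdened <- error_profile(n_chunks = 100, payload_bytes = 20, beta = 0,
                            N_l = 0,
                            N_e = data.frame(errors = c(0, 1),
                                             n_seq = c(70, 30)))
  expect_equal(choose_rs_length(burdened), 2L, ignore_attr = TRUE)
  tb <- attr(choose_rs_length(burdened), "density_table")
  expect_equal(tb$density[tb$k == 1], 20 / 22)
  # scale invariance of the argmax
  big <- error_profile(n_chunks = 300, payload_bytes = 20, beta = 0,
                       N_l = 0,
                       N_e = data.frame(errors = c(0, 1),
                                        n_seq = c(210, 90)))
  expect_equal(choose_rs_length(big), 2L, ignore_attr = TRUE)
})

test_that("total_lost adds lost and uncorrectable sequences", {
  pr <- error_profile(n_chunks = 100, payload_bytes = 20, beta = 0,
                      N_l = 4,
                      N_e = data.frame(errors = c(1, 2), n_seq = c(10, 3)))
  expect_equal(total_lost(pr, 0), 17)
  expect_equal(total_lost(pr, 2), 4 + 3)   # corrects 1 byte error
  expect_equal(total_lost(pr, 4), 4)
  # non-increasing in L_RS
  tl <- vapply(c(0, 2, 4, 6), total_lost, numeric(1), summary = pr)
  expect_true(all(diff(tl) <= 0))
  clean <- error_profile(n_chunks = 10, payload_bytes = 20, beta = 0,
                         N_l = 0, N_e = data.frame(errors = 0, n_seq = 10))
  expect_equal(total_lost(clean, 0), 0)
})

test_that("the Poisson total-lost fit is the sample mean", {
  expect_equal(fit_lost(c(2, 4, 3, 3))$lambda, 3)
  expect_equal(fit_lost(c(0, 0, 0))$lambda, 0)
  expect_error(fit_lost(c(3)), class = "dnachannel_error_validation")
  expect_error(fit_lost(c(2, -1)), class = "dnachannel_error_validation")
  # estimator recovery at n = 200 within 3 standard errors
  x <- withr::with_seed(41, rpois(200, 8))
  expect_lt(abs(fit_lost(x)$lambda - 8), 3 * sqrt(8 / 200))
})

test_that("Gumbel fitting recovers known parameters within 5% RMS at n = 500", {
  rgumbel <- function(n, loc, scale) loc - scale * log(-log(runif(n)))
  loc <- 520; scale <- 18
  rel <- withr::with_seed(43, {
    vapply(1:50, function(i) {
      x <- rgumbel(500, loc, scale)
      f <- fit_gumbel(x)
      c((f$loc - loc) / loc, (f$scale - scale) / scale)
    }, numeric(2))
  })
  expect_lt(sqrt(mean(rel[1, ]^2)), 0.05)
  expect_lt(sqrt(mean(rel[2, ]^2)), 0.05)
})

test_that("the AD statistic prefers Gumbel over normal on skewed data", {
  rgumbel <- function(n, loc, scale) loc - scale * log(-log(runif(n)))
  wins <- withr::with_seed(44, {
    vapply(1:50, function(i) {
      x <- rgumbel(300, 100, 12)
      g <- fit_gumbel(x)
      ad_g <- ad_statistic(x, function(q) dnachannel:::pgumbel(q, g$loc,
                                                              g$scale))
      ad_n <- ad_statistic(x, function(q) pnorm(q, mean(x), sd(x)))
      ad_g < ad_n
    }, logical(1))
  })
  expect_gt(mean(wins), 0.5)
})

test_that("degenerate droplets-needed samples fall back to a point mass", {
  expect_warning(f <- fit_permitted(rep(120, 6), M = 100),
                 class = "dnachannel_warn_degenerate")
  expect_true(f$degenerate)
  # permitted lost at alpha is exactly (1+alpha)M - c
  pm <- permitted_pmf(f, alpha = 0.5)
  expect_equal(pm$j[pm$p > 0.5], 150 - 120)
})

test_that("failure probability matches exhaustive enumeration on finite pmfs", {
  enum_oracle <- function(lost, permitted) {
    li <- as.numeric(names(lost)); pj <- as.numeric(names(permitted))
    total <- 0
    for (a in seq_along(li)) for (b in seq_along(pj)) {
      if (li[a] > pj[b]) total <- total + lost[[a]] * permitted[[b]]
    }
    unname(total)
  }
  expect_equal(failure_probability(lost = c(`0` = 1), permitted = c(`0` = 1)),
               0)
  expect_equal(failure_probability(lost = c(`5` = 1), permitted = c(`3` = 1)),
               1)
  expect_equal(failure_probability(lost = c(`0` = .5, `2` = .5),
                                   permitted = c(`1` = .5, `3` = .5)), 0.25)
  withr::with_seed(45, {
    for (i in 1:20) {
      ls <- sample(0:12, sample(2:6, 1))
      lp <- runif(length(ls)); lp <- lp / sum(lp)
      lost <- setNames(as.list(lp), ls)
      ps <- sample(0:12, sample(2:6, 1))
      pp <- runif(length(ps)); pp <- pp / sum(pp)
      perm <- setNames(as.list(pp), ps)
      expect_equal(
        failure_probability(lost = unlist(lost), permitted = unlist(perm)),
        enum_oracle(lost, perm))
    }
  })
})

test_that("the fitted path agrees with enumeration over its own discretized pmf", {
  rgumbel <- function(n, loc, scale) loc - scale * log(-log(runif(n)))
  x <- withr::with_seed(46, rgumbel(50, 115, 6))
  f <- fit_permitted(x, M = 100)
  lost <- fit_lost(withr::with_seed(47, rpois(10, 4)))
  alpha <- 0.4
  pm <- permitted_pmf(f, alpha)
  manual <- attr(pm, "p_negative") +
    sum(pm$p * (1 - ppois(pm$j, lost$lambda)))
  expect_equal(failure_probability(lost, f, alpha = alpha), manual)
})

test_that("p_f(alpha) is non-increasing and the scan finds the crossing", {
  rgumbel <- function(n, loc, scale) loc - scale * log(-log(runif(n)))
  x <- withr::with_seed(48, rgumbel(40, 112, 5))
  f <- fit_permitted(x, M = 100)
  scan <- choose_alpha(p_tl = 0.03, permitted = f, target_success = 0.99,
                       alpha_grid = seq(0.01, 1, 0.01))
  expect_true(all(diff(scan$p_f) <= 1e-9))
  amin <- attr(scan, "alpha_min")
  expect_false(is.na(amin))
  # brute-force refinement: the coarse answer is the first grid point at or
  # past the dense-grid crossing
  dense <- choose_alpha(p_tl = 0.03, permitted = f, target_success = 0.99,
                        alpha_grid = seq(0.001, 1, 0.001))
  cross <- attr(dense, "alpha_min")
  expect_equal(amin, seq(0.01, 1, 0.01)[which(seq(0.01, 1, 0.01) >= cross - 1e-9)[1]])
  # with no losses the minimum feasible overhead is decoding overhead alone
  f0 <- suppressWarnings(fit_permitted(rep(100, 6), M = 100))
  scan0 <- choose_alpha(p_tl = 0, permitted = f0, target_success = 0.99,
                        alpha_grid = seq(0.01, 1, 0.01))
  expect_equal(attr(scan0, "alpha_min"), 0.01)
})

test_that("redundancy_plan assembles the full design from replicates", {
  refs <- c("ACGTACGTACGTACGT", "TTGGCCAATTGGCCAA", "AACCGGTTAACCGGTT")
  mk_summary <- function(seed) {
    run <- run_channel(refs, identity_config(depth = 20, reads = 40),
                       seed = seed)
    summarize_run(run)
  }
  sums <- lapply(1:3, mk_summary)
  rgumbel <- function(n, loc, scale) loc - scale * log(-log(runif(n)))
  needed <- withr::with_seed(49, round(rgumbel(10, 3.3, 0.2)))
  plan <- redundancy_plan(sums, needed, n_chunks = 3, payload_bytes = 4,
                          target_success = 0.99)
  expect_s3_class(plan, "redundancy_plan")
  expect_equal(plan$L_RS, 0L)      # error-free channel needs no parity
  expect_equal(plan$p_tl, 0)
  expect_equal(nrow(tidy(plan)), 9L)
  expect_true(all(c("L_RS", "alpha_min") %in% names(glance(plan))))
})
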