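test_that("synthesis draws configured copy numbers and conserves them under errors", {
  refs <- random_dna(500, 20, seed = 1)
  cfg0 <- channel_config(synthesis = list(mean_depth = 200,
                                          rates = error_rates()))
  p0 <- synthesis(refs, cfg0, seed = 2)
  tt <- pool_totals(p0)$total
  expect_equal(mean(tt), 200, tolerance = 0.01)
  expect_true(all(p0$edits == ""))
  # same seed, nonzero rates: totals identical (errors conserve counts)
  cfg1 <- channel_config(synthesis = list(mean_depth = 200,
                                          rates = error_rates(sub = 0.01)))
  p1 <- synthesis(refs, cfg1, seed = 2)
  expect_identical(pool_totals(p1)$total, tt)
  # zero depth loses everything
  pz <- synthesis(refs, channel_config(synthesis = list(mean_depth = 0)),
                  seed = 3)
  expect_true(all(pool_totals(pz)$lost))
  expect_error(synthesis(character(0), cfg0),
               class = "dnachannel_error_validation")
})

test_that("decay thins by the survival probability", {
  refs <- random_dna(200, 15, seed = 4)
  p <- seq_pool(refs, counts = 400)
  id <- decay(p, channel_config(decay = list(survival_prob = 1,
                                             rates = error_rates())), seed = 5)
  expect_identical(as.data.frame(id)[c("ref", "count")],
                   as.data.frame(p)[c("ref", "count")])
  gone <- decay(p, channel_config(decay = list(survival_prob = 0)), seed = 6)
  expect_true(all(pool_totals(gone)$lost))
  half <- decay(p, channel_config(decay = list(survival_prob = 0.5,
                                               rates = error_rates())),
                seed = 7)
  # P[Binomial(400, .5) = 0] ~ 0: no reference should be lost
  expect_equal(sum(pool_totals(half)$lost), 0)
  expect_equal(mean(pool_totals(half)$total), 200, tolerance = 0.02)
})

test_that("pcr grows counts per cycle and reproduces amplification bias", {
  refs <- random_dna(200, 15, seed = 8)
  p <- seq_pool(refs, counts = 100)
  p0 <- pcr(p, channel_config(pcr = list(cycles = 0L)), seed = 9)
  expect_identical(as.data.frame(p0)[c("ref", "edits", "count")],
                   as.data.frame(p)[c("ref", "edits", "count")])
  # efficiency 1, no bias, no dilution: exact doubling
  cfgd <- channel_config(pcr = list(cycles = 3L, efficiency = 1,
                                    bias_sigma = 0, dilute = FALSE))
  dbl <- pcr(p, cfgd, seed = 10)
  expect_true(all(dbl$count == 800))
  # per-sequence bias inflates the between-reference CV (paired seeds)
  cv <- function(x) sd(x) / mean(x)
  cfg_b <- channel_config(pcr = list(cycles = 10L, efficiency = 0.9,
                                     bias_sigma = 0.05, dilute = FALSE))
  cfg_n <- channel_config(pcr = list(cycles = 10L, efficiency = 0.9,
                                     bias_sigma = 0, dilute = FALSE))
  cv_b <- cv(pool_totals(pcr(p, cfg_b, seed = 11))$total)
  cv_n <- cv(pool_totals(pcr(p, cfg_n, seed = 11))$total)
  expect_gt(cv_b, cv_n)
  # dilution restores the input scale
  dil <- pcr(p, channel_config(pcr = list(cycles = 6L, efficiency = 0.9,
                                          bias_sigma = 0.03, dilute = TRUE)),
             seed = 12)
  expect_equal(sum(dil$count), sum(p$count), tolerance = 0.02)
})

test_that("sampling matches the Poisson limit at small ratios", {
  refs <- random_dna(1000, 12, seed = 13)
  p <- seq_pool(refs, counts = 5000)
  expect_identical(
    as.data.frame(sample_pool(p, channel_config(sampling = list(ratio = 1)),
                              seed = 14))[c("ref", "count")],
    as.data.frame(p)[c("ref", "count")])
  expect_true(all(pool_totals(
    sample_pool(p, channel_config(sampling = list(ratio = 0)), seed = 15))$lost))
  s <- sample_pool(p, channel_config(sampling = list(ratio = 0.001)),
                   seed = 16)
  tt <- pool_totals(s)
  expect_equal(mean(tt$total), 5, tolerance = 0.06)
  # lost fraction ~ e^-5 ~ 0.0067
  expect_lt(abs(mean(tt$lost) - exp(-5)), 0.01)
})

test_that("sequencing allocates the read budget and keeps linkage", {
  refs <- random_dna(100, 20, seed = 17)
  p <- seq_pool(refs, counts = 50)
  rs0 <- sequence_pool(p, channel_config(sequencing = list(depth = 0)),
                       seed = 18)
  expect_true(all(read_lost(rs0)))
  # single surviving reference, error-free sequencing: identical reads
  one <- seq_pool(refs[1], counts = 10)
  rs1 <- sequence_pool(one, channel_config(
    sequencing = list(depth = 30, rates = error_rates())), seed = 19)
  expect_equal(sum(rs1$mult), 30)
  expect_true(all(rs1$seq == refs[1]))
  # total reads = depth x surviving references, exactly as budgeted
  rs <- sequence_pool(p, channel_config(sequencing = list(depth = 20)),
                      seed = 20)
  expect_equal(sum(rs$mult), 20 * 100)
})

test_that("an identity-configured channel reproduces the references", {
  refs <- random_dna(20, 30, seed = 21)
  run <- run_channel(refs, identity_config(depth = 10, reads = 30), seed = 22)
  s <- summarize_run(run)
  expect_equal(s$N_l, 0)
  expect_equal(s$N_e$errors, 0L)
  expect_equal(s$N_e$n_seq, 20L)
  expect_true(all(run$reads$seq == refs[run$reads$ref]))
})

test_that("runs are byte-identical under the same seed", {
  refs <- random_dna(30, 25, seed = 23)
  cfg <- small_config()
  a <- run_channel(refs, cfg, seed = 77)
  b <- run_channel(refs, cfg, seed = 77)
  expect_identical(as.data.frame(a$reads), as.data.frame(b$reads))
  expect_identical(a$snapshots, b$snapshots)
  c_ <- run_channel(refs, cfg, seed = 78)
  expect_false(identical(as.data.frame(a$reads), as.data.frame(c_$reads)))
})

test_that("stage snapshots show PCR bias widening the distribution", {
  refs <- random_dna(150, 20, seed = 24)
  cfg <- channel_config(
    synthesis = list(mean_depth = 300, rates = error_rates()),
    decay = list(survival_prob = 1, rates = error_rates()),
    pcr = list(cycles = 10L, efficiency = 0.8, bias_sigma = 0.05,
               dilute = TRUE),
    sampling = list(ratio = 1))
  run <- run_channel(refs, cfg, seed = 25, through = "sampling")
  sn <- run$snapshots
  v_syn <- var(sn$total[sn$stage == "synthesis"])
  v_pcr <- var(sn$total[sn$stage == "pcr"])
  expect_gt(v_pcr, v_syn)
})

test_that("stages can be skipped and the channel stopped early", {
  refs <- random_dna(10, 20, seed = 26)
  run <- run_channel(refs, identity_config(), seed = 27, skip = c("pcr"),
                     through = "sampling")
  expect_false("pcr" %in% run$snapshots$stage)
  expect_null(run$reads)
  expect_s3_class(run$pool, "seq_pool")
  expect_error(run_channel(refs, identity_config(), seed = 1,
                           skip = "synthesis"),
               class = "dnachannel_error_validation")
})

test_that("lost counts fall with sampling ratio and sequencing depth, and converge", {
  refs <- random_dna(300, 24, seed = 28)
  base <- list(synthesis = list(mean_depth = 3000, rates = error_rates()),
               decay = list(survival_prob = 1, rates = error_rates()),
               pcr = list(cycles = 0L))
  mean_lost <- function(ratio, depth, seeds = 1:6) {
    mean(vapply(seeds, function(s) {
      cfg <- channel_config(synthesis = base$synthesis, decay = base$decay,
                            pcr = base$pcr,
                            sampling = list(ratio = ratio),
                            sequencing = list(depth = depth,
                                              rates = error_rates()))
      run <- run_channel(refs, cfg, seed = 100 + s)
      sum(read_lost(run$reads))
    }, numeric(1)))
  }
  l_d2 <- mean_lost(0.001, 2)
  l_d10 <- mean_lost(0.001, 10)
  l_d40 <- mean_lost(0.001, 40)
  expect_true(l_d2 >= l_d10 && l_d10 >= l_d40)
  # converged value equals the post-sampling lost count
  post_sampling <- mean(vapply(1:6, function(s) {
    cfg <- channel_config(synthesis = base$synthesis, decay = base$decay,
                          pcr = base$pcr, sampling = list(ratio = 0.001))
    run <- run_channel(refs, cfg, seed = 100 + s, through = "sampling")
    sum(pool_totals(run$pool)$lost)
  }, numeric(1)))
  expect_lt(abs(l_d40 - post_sampling), 0.15 * max(post_sampling, 1) + 1)
  # deeper sampling loses fewer sequences
  expect_gt(mean_lost(0.001, 10), mean_lost(0.01, 10))
})
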