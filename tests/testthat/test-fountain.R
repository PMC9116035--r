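test_that("generate_file is deterministic in its seed", {
  expect_identical(generate_file(16, 1), generate_file(16, 1))
  expect_equal(length(generate_file(9216, 2)), 9216)
  expect_false(identical(generate_file(64, 1), generate_file(64, 2)))
})

test_that("robust soliton is a pmf with the expected spike", {
  for (M in c(2, 10, 461)) {
    p <- robust_soliton(M)
    expect_equal(sum(p), 1)
    expect_true(all(p >= 0))
  }
  # degree histogram matches the pmf (chi-squared sanity)
  M <- 50
  pmf <- robust_soliton(M, 0.05, 0.05)
  file <- generate_file(M * 4, seed = 3)
  dr <- lt_encode(file, chunk_size = 4, n_droplets = 20000, seed = 4,
                  c = 0.05, delta = 0.05)
  obs <- tabulate(dr$degree, nbins = M)
  keep <- pmf * 20000 >= 5
  chi <- suppressWarnings(
    stats::chisq.test(obs[keep], p = pmf[keep] / sum(pmf[keep])))
  expect_gt(chi$p.value, 1e-4)
})

test_that("degenerate encodings behave: M = 1 and degree-1 droplets", {
  file <- generate_file(8, seed = 5)
  dr <- lt_encode(file, chunk_size = 8, n_droplets = 5, seed = 6)
  expect_true(all(dr$degree == 1))
  expect_true(all(vapply(dr$payload, identical, logical(1), file)))
  expect_equal(lt_min_droplets(dr), 1L)
  # a degree-1 droplet's payload equals its member chunk
  big <- lt_encode(generate_file(100, 7), chunk_size = 10, n_droplets = 200,
                   seed = 8)
  d1 <- which(big$degree == 1)[1]
  chunk <- split_chunks_oracle(generate_file(100, 7), 10)
  expect_identical(big$payload[[d1]],
                   as.raw(chunk[, big$members[[d1]]]))
})

test_that("a hand-crafted peeling chain resolves in order", {
  # droplets {1}, {1,2}, {1,2,3}: all three needed, chain peels completely
  chunks <- lapply(1:3, function(i) as.raw(c(i, i + 10)))
  xor_raw <- function(a, b) as.raw(bitwXor(as.integer(a), as.integer(b)))
  dr <- tibble::tibble(
    index = 1:3, seed = 1:3, degree = 1:3,
    members = list(1L, 1:2, 1:3),
    payload = list(chunks[[1]],
                   xor_raw(chunks[[1]], chunks[[2]]),
                   xor_raw(xor_raw(chunks[[1]], chunks[[2]]), chunks[[3]])))
  attr(dr, "M") <- 3L
  attr(dr, "chunk_size") <- 2L
  class(dr) <- c("droplet_set", class(tibble::tibble()))
  expect_equal(lt_min_droplets(dr), 3L)
  expect_identical(lt_decode(dr), as.raw(unlist(chunks)))
})

test_that("decoded chunks XOR-verify against the original file", {
  file <- generate_file(600, seed = 9)
  dr <- lt_encode(file, chunk_size = 20, n_droplets = 150, seed = 10)
  dec <- lt_decode(dr)
  expect_identical(dec[seq_along(file)], file)
})

test_that("droplets-needed samples respect the information bound and skew right", {
  file <- generate_file(200 * 4, seed = 11)
  needed <- vapply(1:120, function(i) {
    dr <- lt_encode(file, chunk_size = 4,
                    n_droplets = 900, seed = derive_seed(12, "rep", i))
    lt_min_droplets(dr)
  }, integer(1))
  expect_true(all(needed >= 200))
  skew <- mean((needed - mean(needed))^3) / sd(needed)^3
  expect_gt(skew, 0)
})

test_that("stream exhaustion reports the resolved-chunk count", {
  file <- generate_file(400, seed = 13)
  dr <- lt_encode(file, chunk_size = 4, n_droplets = 30, seed = 14)
  err <- tryCatch(lt_min_droplets(dr), error = function(e) e)
  expect_s3_class(err, "dnachannel_error_decode")
  expect_true(err$resolved < 100)
})

test_that("bytes map to DNA at 2 bits per base and back", {
  expect_identical(bytes_to_dna(as.raw(0x1B)), "ACGT")
  expect_identical(dna_to_bytes("ACGT"), as.raw(0x1B))
  b <- generate_file(64, seed = 15)
  expect_identical(dna_to_bytes(bytes_to_dna(b)), b)
  expect_error(dna_to_bytes("ACGN"), class = "dnachannel_error_validation")
})

test_that("droplets map to strands of the standard layout", {
  file <- generate_file(9216, seed = 16)
  dr <- lt_encode(file, chunk_size = 20, n_droplets = 10, seed = 17)
  strands <- droplets_to_dna(dr, L_RS = 2)
  # 4 seed + 20 payload + 2 parity bytes = 26 bytes = 104 nt
  expect_true(all(nchar(strands$seq) == 104))
  # seed recoverable from the strand prefix
  b <- dna_to_bytes(substr(strands$seq[1], 1, 16))
  seed_back <- sum(as.integer(b) * c(2^24, 2^16, 2^8, 1))
  expect_equal(seed_back, dr$seed[1])
})

test_that("rs_recoverable applies the floor(L_RS/2) capacity rule", {
  ref <- strrep("ACGT", 6)
  expect_true(rs_recoverable(ref, ref, 0))
  one_err <- paste0("G", substr(ref, 2, 24))
  expect_true(rs_recoverable(one_err, ref, 2))
  two_err <- paste0("GG", substr(ref, 3, 24))  # two bases, same byte
  expect_equal(byte_errors(two_err, ref), 1L)
  two_bytes <- paste0("G", substr(ref, 2, 8), "T", substr(ref, 10, 24))
  expect_equal(byte_errors(two_bytes, ref), 2L)
  expect_false(rs_recoverable(two_bytes, ref, 2))
  expect_false(rs_recoverable(substr(ref, 1, 20), ref, 2))
})

test_that("droplets round-trip through the TSV serialization", {
  file <- generate_file(120, seed = 18)
  dr <- lt_encode(file, chunk_size = 12, n_droplets = 25, seed = 19)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_droplets(dr, path)
  back <- read_droplets(path)
  expect_identical(back$seed, dr$seed)
  expect_identical(back$degree, dr$degree)
  expect_identical(back$members, dr$members)
  expect_identical(back$payload, dr$payload)
  expect_identical(lt_decode(back), lt_decode(dr))
})
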