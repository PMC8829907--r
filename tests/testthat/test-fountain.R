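test_that("chunking pads to whole chunks and records the original length", {
  o <- chunk_data(as.raw(1:10), 4L)
  expect_equal(o$k, 3L)                       # ceil(10/4)
  expect_equal(length(o$payload), 12L)        # 2 padding bytes
  expect_equal(o$originalLength, 10L)
  expect_equal(chunk_data(as.raw(1:8), 4L)$k, 2L)   # no padding
  o1 <- chunk_data(as.raw(7), 4L)
  expect_equal(o1$k, 1L)
  expect_equal(length(o1$payload), 4L)
  expect_error(chunk_data(raw(0), 4L), "non-empty")
})

test_that("the bit-to-base mapping reproduces the printed examples and inverts", {
  expect_equal(bits_to_dna("0110100011"), "TCCAG")
  expect_equal(bits_to_dna("0000000000"), "AAAAA")
  expect_equal(dna_to_bits("TCCAG"), "0110100011")
  expect_equal(dna_to_bits("AAAAA"), "0000000000")
  expect_error(bits_to_dna("011"), "even")
  expect_error(bits_to_dna("01a0"))
  set.seed(51)
  for (i in 1:25) {
    n <- 2 * sample(1:40, 1)
    bits <- paste(sample(0:1, n, replace = TRUE), collapse = "")
    expect_identical(dna_to_bits(bits_to_dna(bits)), bits)
    s <- random_dna(sample(1:40, 1))
    expect_equal(nchar(dna_to_bits(s)), 2 * nchar(s))
  }
})

test_that("symbol generation is non-systematic, deterministic and esi-reproducible", {
  fp <- fountain_params(chunkSize = 4L, seed = 7L)
  obj <- chunk_data(as.raw(1:32), 4L)  # k = 8
  expect_error(encode_symbol(obj, 3L, fp), class = "dnakv_systematic_esi")
  expect_error(encode_symbol(obj, obj$k - 1L, fp), class = "dnakv_systematic_esi")
  p1 <- encode_symbol(obj, 8L, fp)
  p2 <- encode_symbol(obj, 8L, fp)
  expect_identical(p1, p2)
  expect_equal(nchar(p1$dna), packet_dna_length(fp))
  # DNA form alone reconstructs (esi, bytes)
  back <- parse_packet_dna(p1$dna, fp)
  expect_equal(back$esi, 8L)
  expect_equal(back$bytes, p1$bytes)
  expect_error(parse_packet_dna(substr(p1$dna, 1, 10), fp),
               class = "dnakv_packet_truncated")
})

test_that("LT XOR algebra: degree-1 packets are chunks, XOR is self-inverse", {
  fp <- fountain_params(chunkSize = 4L, backend = "lt", seed = 9L)
  obj <- chunk_data(as.raw(c(1:16)), 4L)  # k = 4
  # scan repair symbols for a degree-1 packet; its bytes equal that chunk
  found <- FALSE
  for (esi in 4:200) {
    co <- dnakv:::symbol_coeffs(esi, obj$k, fp)
    if (sum(co) == 1) {
      pkt <- encode_symbol(obj, esi, fp, as_dna = FALSE)
      expect_equal(pkt$bytes, obj$chunks[which(co == 1), ])
      found <- TRUE
      break
    }
  }
  expect_true(found)
  # xor(chunk0, chunk1) xor chunk1 == chunk0
  x01 <- bitwXor(obj$chunks[1, ], obj$chunks[2, ])
  expect_equal(bitwXor(x01, obj$chunks[2, ]), unname(obj$chunks[1, ]))
})

test_that("decoding fails below rank k and succeeds with enough symbols", {
  for (backend in c("gf256", "lt")) {
    fp <- fountain_params(chunkSize = 4L, backend = backend, seed = 13L)
    payload <- as.raw(c(255, 0, 1:30))
    obj <- chunk_data(payload, 4L)  # k = 8
    pk <- lapply(8:40, function(e) encode_symbol(obj, e, fp, as_dna = FALSE))
    # k - 1 packets can never decode (information-theoretic bound)
    dec_few <- fountain_decode(pk[1:(obj$k - 1)], obj$k, obj$originalLength, fp)
    expect_false(dec_few$success)
    expect_lt(dec_few$rank, obj$k)
    # a generous set decodes byte-exactly
    dec <- fountain_decode(pk, obj$k, obj$originalLength, fp)
    expect_true(dec$success)
    expect_identical(dec$payload, payload)
  }
})

test_that("degenerate payloads (all-zero / all-one) round-trip", {
  for (backend in c("gf256", "lt")) {
    fp <- fountain_params(chunkSize = 4L, backend = backend, seed = 15L)
    for (payload in list(raw(24), as.raw(rep(255L, 24)))) {
      obj <- chunk_data(payload, 4L)
      pk <- lapply(obj$k:(obj$k + 19), function(e) encode_symbol(obj, e, fp, as_dna = FALSE))
      dec <- fountain_decode(pk, obj$k, obj$originalLength, fp)
      expect_true(dec$success)
      expect_identical(dec$payload, payload)
    }
  }
})

test_that("packet whitening keeps DNA non-degenerate for constant payloads", {
  fp <- fountain_params(chunkSize = 4L, seed = 17L)
  obj <- chunk_data(raw(32), 4L)  # all-zero message: all symbols are zero
  pkt <- encode_symbol(obj, 10L, fp)
  expect_true(all(pkt$bytes == 0L))        # the code is linear
  expect_gt(length(unique(strsplit(pkt$dna, "")[[1]])), 1)  # DNA is not
  expect_lt(max_homopolymer_run(pkt$dna), nchar(pkt$dna))
})

test_that("conflicting duplicate packets raise an integrity error", {
  fp <- fountain_params(chunkSize = 4L, seed = 19L)
  obj <- chunk_data(as.raw(1:16), 4L)
  pk <- lapply(4:9, function(e) encode_symbol(obj, e, fp, as_dna = FALSE))
  bad <- pk[[1]]
  bad$bytes <- bitwXor(bad$bytes, 1L)
  expect_error(fountain_decode(c(pk, list(bad)), obj$k, obj$originalLength, fp),
               class = "dnakv_integrity")
  # an identical duplicate is merely deduplicated
  dec <- fountain_decode(c(pk, pk[1]), obj$k, obj$originalLength, fp)
  expect_true(dec$success)
})

test_that("gf256 backend meets the dense-code rank expectations at small scale", {
  fp <- fountain_params(chunkSize = 2L, seed = 21L)
  payload <- as.raw(1:16)
  obj <- chunk_data(payload, 2L)  # k = 8
  # exactly k random repair symbols succeed in the vast majority of trials
  succ <- 0L
  for (trial in 1:200) {
    esis <- dnakv:::with_seed(trial, sample(8:5000, 8))
    pk <- lapply(esis, function(e) encode_symbol(obj, e, fp, as_dna = FALSE))
    dec <- fountain_decode(pk, obj$k, obj$originalLength, fp)
    succ <- succ + (dec$success && identical(dec$payload, payload))
  }
  # full-rank probability of a random 8x8 GF(256) matrix is ~0.996
  expect_gte(succ, 190L)
})

test_that("decode success is monotone in the number of received symbols", {
  fp <- fountain_params(chunkSize = 2L, backend = "lt", seed = 23L)
  payload <- as.raw(1:12)
  obj <- chunk_data(payload, 2L)  # k = 6
  rates <- vapply(c(0L, 2L, 6L), function(extra) {
    succ <- 0L
    for (trial in 1:120) {
      esis <- dnakv:::with_seed(trial * 7L, sample(6:4000, 6 + extra))
      pk <- lapply(esis, function(e) encode_symbol(obj, e, fp, as_dna = FALSE))
      succ <- succ + fountain_decode(pk, obj$k, obj$originalLength, fp)$success
    }
    succ / 120
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("can_decode enforces rank plus erasure tolerance", {
  fp <- fountain_params(chunkSize = 4L, seed = 25L)
  obj <- chunk_data(as.raw(1:16), 4L)  # k = 4
  esis <- 4:7
  expect_true(can_decode(esis, obj$k, fp, epsilon = 0L))
  expect_false(can_decode(esis, obj$k, fp, epsilon = 1L))    # too few symbols
  expect_false(can_decode(4:5, obj$k, fp, epsilon = 0L))
  expect_true(can_decode(4:9, obj$k, fp, epsilon = 2L))
  # a set that tolerates one erasure decodes after dropping any packet
  esis5 <- 4:8
  if (can_decode(esis5, obj$k, fp, epsilon = 1L)) {
    for (drop in seq_along(esis5)) {
      pk <- lapply(esis5[-drop], function(e) encode_symbol(obj, e, fp, as_dna = FALSE))
      expect_true(fountain_decode(pk, obj$k, obj$originalLength, fp)$success)
    }
  }
})
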