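test_that("encoder configuration validates its invariants", {
  expect_error(encoder_config(minDist = 0), "\\(0, 1\\)")
  expect_error(encoder_config(strandLshK = 5L,
                              lsh = lsh_params(kmerK = 4L)), "kmerK")
  cfg <- encoder_config()
  expect_equal(cfg$lsh$kmerK, 5L)
})

test_that("admissible packets pass per-packet constraints including junctions", {
  cfg <- encoder_config(fountain = fountain_params(chunkSize = 4L, seed = 61L),
                        seed = 61L)
  probeIdx <- lsh_index(cfg$lsh)
  strandIdx <- lsh_index(cfg$lsh)
  st <- dnakv:::new_encoder_state(as.raw(1:32), cfg, prefix = "")
  for (i in 1:6) {
    pkt <- next_dna_packet(st, cfg, probeIdx, strandIdx)
    gc <- gc_content(pkt$dna)
    expect_true(gc >= 0.4 && gc <= 0.6)
    expect_lte(oracle_max_run(paste0(st$valueDna, pkt$dna)), 5L)
    st$valueDna <- paste0(st$valueDna, pkt$dna)
  }
  # rejected ESIs are skipped permanently: the stream advanced monotonically
  expect_gte(st$nextEsi, 8L + 6L)
})

test_that("an adversarial probe built from a packet's subsequence forces rejection", {
  cfg <- encoder_config(fountain = fountain_params(chunkSize = 16L, seed = 62L),
                        seed = 62L)
  emptyIdx <- lsh_index(cfg$lsh)
  st0 <- dnakv:::new_encoder_state(as.raw(1:64), cfg, prefix = "")
  first <- next_dna_packet(st0, cfg, emptyIdx, lsh_index(cfg$lsh))
  # plant the accepted packet's own DNA as a "probe": similarity 1 > maxSim
  probeIdx <- lsh_index(cfg$lsh)
  lsh_insert(probeIdx, "adv", first$dna)
  st1 <- dnakv:::new_encoder_state(as.raw(1:64), cfg, prefix = "")
  alt <- next_dna_packet(st1, cfg, probeIdx, lsh_index(cfg$lsh))
  expect_gt(alt$esi, first$esi)  # the planted candidate was skipped
  expect_lte(jaccard_similarity(alt$dna, first$dna, 5), 1 - cfg$minDist)
})

test_that("encoded objects round-trip and carry the promised structure", {
  fx <- fixture_library()
  lib <- fx$lib
  expect_length(lib$strands, 15L)
  plen <- packet_dna_length(fx$cfg$fountain)
  for (s in lib$strands) {
    expect_equal(nchar(s$seq), nchar(s$probeSeq) + s$packetCount * plen)
    expect_identical(substr(s$seq, 1, nchar(s$probeSeq)), s$probeSeq)
    # strip the probe, split at fixed packet length, decode
    body <- substr(s$seq, nchar(s$probeSeq) + 1, nchar(s$seq))
    pieces <- substring(body, seq(1, nchar(body), by = plen),
                        seq(plen, nchar(body), by = plen))
    pk <- lapply(pieces, parse_packet_dna, params = fx$cfg$fountain)
    dec <- fountain_decode(pk, s$k, s$originalLength, fx$cfg$fountain)
    expect_true(dec$success)
    i <- which(vapply(fx$objects, function(o) o$doi == s$doi, logical(1)))
    expect_identical(dec$payload, fx$objects[[i]]$payload)
  }
})

test_that("every emitted strand passes the independent constraint audit", {
  fx <- fixture_library()
  seqs <- vapply(fx$lib$strands, function(s) s$seq, character(1))
  probes <- fixture_probes()$probes$seq
  for (s in seqs) {
    expect_lte(oracle_max_run(s), 5L)
    expect_false(oracle_hairpin(s, 6L, 3L, 8L))
  }
  # pairwise strand distance and strand-to-probe distance at k = 5
  n <- length(seqs)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    expect_gte(1 - oracle_jaccard(seqs[i], seqs[j], 5), 0.3)
  }
  for (i in seq_len(n)) {
    own <- fx$lib$strands[[i]]$probeSeq
    for (p in probes) {
      if (identical(p, own)) next  # the key is a subsequence of its own strand
      expect_gte(1 - oracle_jaccard(seqs[i], p, 5), 0.3)
    }
  }
})

test_that("overhead adds spare packets beyond the minimal decodable set", {
  objs <- generate_fixtures(3, 16, "random", seed = 63)  # k = 4 at chunkSize 4
  ps <- fixture_probes()
  mk <- function(eps) {
    cfg <- encoder_config(fountain = fountain_params(chunkSize = 4L,
                                                     epsilon = eps, seed = 64L),
                          seed = 64L)
    encode_library(objs, ps, cfg)
  }
  lib0 <- mk(0L)
  lib2 <- mk(2L)
  for (i in 1:3) {
    expect_gte(lib2$strands[[i]]$packetCount, lib0$strands[[i]]$packetCount + 2L)
    # roundtrip still intact with overhead
    expect_identical(random_read(lib2, lib2$mapping, objs[[i]]$doi),
                     objs[[i]]$payload)
  }
})

test_that("identical payloads under different probes give distinct decodable strands", {
  # two strands sharing all their Info-DNA differ only in the probe, which
  # leaves their Jaccard similarity around 0.6; a distance floor above that
  # makes the strand-dissimilarity check force different ESIs for the twin
  payload <- as.raw(rep(c(7L, 77L), 16))
  objs <- list(list(doi = 0L, payload = payload), list(doi = 1L, payload = payload))
  # m = 5 banding: near-certain band collision at similarity ~0.6, so the
  # duplicate Info-DNA is reliably proposed and rejected
  cfg <- encoder_config(fountain = fountain_params(chunkSize = 4L, seed = 65L),
                        minDist = 0.4, seed = 65L,
                        lsh = lsh_params(r = 200L, b = 40L, kmerK = 5L, seed = 65L))
  lib <- encode_library(objs, fixture_probes(), cfg)
  s1 <- lib$strands[[1]]$seq
  s2 <- lib$strands[[2]]$seq
  expect_false(identical(substr(s1, 61, nchar(s1)), substr(s2, 61, nchar(s2))))
  expect_gte(1 - oracle_jaccard(s1, s2, 5), 0.4)
  expect_identical(random_read(lib, lib$mapping, 0L), payload)
  expect_identical(random_read(lib, lib$mapping, 1L), payload)
})

test_that("library encoding is deterministic and rejects probe exhaustion upfront", {
  objs <- generate_fixtures(4, 16, "random", seed = 66)
  cfg <- encoder_config(fountain = fountain_params(chunkSize = 4L, seed = 67L),
                        seed = 67L)
  a <- encode_library(objs, fixture_probes(), cfg)
  b <- encode_library(objs, fixture_probes(), cfg)
  expect_identical(lapply(a$strands, `[[`, "seq"), lapply(b$strands, `[[`, "seq"))
  expect_identical(a$mapping$entries, b$mapping$entries)
  few <- fixture_probes()$probes[1:2, ]
  expect_error(encode_library(objs, few, cfg), class = "dnakv_probe_exhaustion")
})

test_that("shared keys (1:n mode) map one probe to several objects", {
  objs <- generate_fixtures(6, 16, "random", seed = 68)
  cfg <- encoder_config(fountain = fountain_params(chunkSize = 4L, seed = 69L),
                        seed = 69L)
  lib <- encode_library(objs, fixture_probes(), cfg, probesPerKey = 3L)
  tab <- table(lib$mapping$entries$probe_id)
  expect_equal(length(tab), 2L)
  expect_true(all(tab == 3L))
})

test_that("mapping tables round-trip through JSON", {
  fx <- fixture_library()
  path <- withr::local_tempfile(fileext = ".json")
  write_mapping(fx$lib$mapping, path)
  back <- read_mapping(path)
  expect_equal(back$entries, fx$lib$mapping$entries)
  expect_equal(back$config$fountain$chunkSize, fx$cfg$fountain$chunkSize)
  # a reread table drives a correct read
  expect_identical(random_read(fx$lib, back, fx$objects[[2]]$doi),
                   fx$objects[[2]]$payload)
})
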