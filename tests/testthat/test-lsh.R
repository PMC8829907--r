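test_that("lsh parameters enforce the banding arithmetic", {
  p <- lsh_params(r = 200L, b = 20L, kmerK = 4L, seed = 1L)
  expect_equal(p$m, 10L)
  expect_error(lsh_params(r = 200L, b = 21L), "divisible")
  expect_error(lsh_params(r = 200L, b = 20L, kmerK = 12L))
  expect_error(lsh_params(t = 0), "\\(0, 1\\)")
  expect_error(lsh_params(c = 1))
})

test_that("minhash signatures are deterministic and seed-dependent", {
  p1 <- lsh_params(r = 40L, b = 8L, kmerK = 3L, seed = 5L)
  p2 <- lsh_params(r = 40L, b = 8L, kmerK = 3L, seed = 6L)
  s <- "ACTACCGGATTACA"
  expect_identical(minhash_signature(s, p1), minhash_signature(s, p1))
  expect_equal(length(minhash_signature(s, p1)), 40L)
  expect_false(identical(minhash_signature(s, p1), minhash_signature(s, p2)))
  expect_error(minhash_signature("AC", p1), class = "dnakv_invalid_k")
})

test_that("matching-position fraction estimates exact Jaccard, tightening with r", {
  set.seed(21)
  for (trial in 1:10) {
    base <- random_dna(200)
    # perturb to produce a mid-range similarity
    mutated <- strsplit(base, "")[[1]]
    pos <- sample(200, 30)
    mutated[pos] <- sample(c("A", "C", "G", "T"), 30, replace = TRUE)
    other <- paste(mutated, collapse = "")
    exact <- jaccard_similarity(base, other, 4)
    for (r in c(200L)) {
      p <- lsh_params(r = r, b = 20L, kmerK = 4L, seed = trial)
      est <- mean(minhash_signature(base, p) == minhash_signature(other, p))
      expect_lt(abs(est - exact), 0.1)
    }
  }
})

test_that("the analytic S-curve is correct, bounded and monotone", {
  expect_equal(collision_probability(1, 10, 20), 1)
  expect_equal(collision_probability(0, 10, 20), 0)
  # frozen from independent evaluation of 1 - (1 - 0.8^10)^20
  expect_equal(collision_probability(0.8, 10, 20), 0.8968691, tolerance = 1e-6)
  s <- seq(0, 1, by = 0.01)
  cp <- collision_probability(s, 10, 20)
  expect_true(all(diff(cp) >= 0))
  expect_true(all(cp >= 0 & cp <= 1))
  expect_error(collision_probability(1.2, 10, 20))
})

test_that("empirical band-collision frequency follows 1-(1-s^m)^b", {
  # fixed sequence pairs at low/mid/high similarity; collision frequency over
  # independent hash families must match the S-curve within binomial error
  set.seed(22)
  m <- 5L; b <- 8L; r <- m * b
  make_pair <- function(nmut) {
    a <- random_dna(120)
    ch <- strsplit(a, "")[[1]]
    pos <- sample(120, nmut)
    ch[pos] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
    list(a = a, b = paste(ch, collapse = ""))
  }
  nseeds <- 150L
  for (nmut in c(40L, 12L, 4L)) {
    pr <- make_pair(nmut)
    s <- jaccard_similarity(pr$a, pr$b, 4)
    hits <- 0L
    for (seed in seq_len(nseeds)) {
      p <- lsh_params(r = r, b = b, kmerK = 4L, seed = seed)
      sa <- minhash_signature(pr$a, p)
      sb <- minhash_signature(pr$b, p)
      band_eq <- vapply(seq_len(b), function(i) {
        idx <- ((i - 1) * m + 1):(i * m)
        all(sa[idx] == sb[idx])
      }, logical(1))
      hits <- hits + any(band_eq)
    }
    expected <- collision_probability(s, m, b)
    tol <- 3 * sqrt(max(expected * (1 - expected), 0.25 / nseeds) / nseeds)
    expect_lt(abs(hits / nseeds - expected), tol + 1e-9)
  }
})

test_that("index insert/query respects band structure and duplicates", {
  p <- lsh_params(r = 40L, b = 8L, kmerK = 4L, seed = 9L)
  idx <- lsh_index(p)
  expect_equal(length(lsh_query(idx, random_dna(30))), 0L)  # empty index
  s <- random_dna(60)
  lsh_insert(idx, "x", s)
  expect_error(lsh_insert(idx, "x", s), "already present")
  # self-collision in every band -> returned as candidate
  expect_true("x" %in% lsh_query(idx, s))
  # identical sequence under a second id -> both returned
  lsh_insert(idx, "y", s)
  expect_setequal(lsh_query(idx, s), c("x", "y"))
  # each insertion lands in exactly b band buckets
  idx2 <- lsh_index(p)
  set.seed(23)
  for (i in 1:20) lsh_insert(idx2, i, random_dna(60))
  n_entries <- sum(lengths(as.list(idx2$tables)))
  expect_equal(n_entries, 20L * p$b)
})

test_that("near-duplicates are found and verified similarity has no false positives", {
  p <- lsh_params(r = 200L, b = 20L, kmerK = 4L, seed = 31L)
  set.seed(24)
  idx <- lsh_index(p)
  stored <- replicate(120, random_dna(60))
  for (i in seq_along(stored)) lsh_insert(idx, i, stored[i])
  # single-base variant of a stored sequence: high similarity, must be caught
  found <- 0L
  for (trial in 1:20) {
    i <- sample(120, 1)
    ch <- strsplit(stored[i], "")[[1]]
    pos <- sample(60, 1)
    ch[pos] <- sample(setdiff(c("A", "C", "G", "T"), ch[pos]), 1)
    q <- paste(ch, collapse = "")
    found <- found + (i %in% lsh_query(idx, q))
  }
  expect_gte(found, 19L)  # collision probability at this similarity is ~1

  # a stored sequence always matches itself for any cutoff below 1
  for (i in sample(120, 10)) {
    expect_true(lsh_has_similar(idx, stored[i], 0.6))
  }
  # a sequence dissimilar to everything: verified check must say FALSE even
  # if banding proposed candidates (no false positives after verification)
  q <- strrep("ACGT", 15)
  max_exact <- max(vapply(stored, function(s) oracle_jaccard(q, s, 4), numeric(1)))
  if (max_exact <= 0.6) expect_false(lsh_has_similar(idx, q, 0.6))
  expect_false(lsh_has_similar(lsh_index(p), random_dna(60), 0.6))  # empty index
})

test_that("index persistence round-trips through JSON", {
  p <- lsh_params(r = 40L, b = 8L, kmerK = 4L, seed = 12L)
  idx <- lsh_index(p)
  set.seed(25)
  seqs <- replicate(10, random_dna(60))
  for (i in 1:10) lsh_insert(idx, paste0("s", i), seqs[i])
  path <- withr::local_tempfile(fileext = ".json")
  lsh_save(idx, path)
  idx2 <- lsh_load(path)
  expect_equal(idx2$n, 10L)
  expect_identical(sort(names(as.list(idx2$store))), sort(names(as.list(idx$store))))
  q <- seqs[3]
  expect_setequal(lsh_query(idx2, q), lsh_query(idx, q))
  expect_identical(lsh_has_similar(idx2, seqs[5], 0.6),
                   lsh_has_similar(idx, seqs[5], 0.6))
})
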