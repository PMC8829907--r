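# Independent brute-force oracles and fixture builders. Tests audit package
# output with these, never with the package's own fast paths.

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Naive k-mer Jaccard via character sets.
oracle_jaccard <- function(a, b, k) {
  ka <- unique(substring(a, seq_len(nchar(a) - k + 1), k:nchar(a)))
  kb <- unique(substring(b, seq_len(nchar(b) - k + 1), k:nchar(b)))
  length(intersect(ka, kb)) / length(union(ka, kb))
}

# Exhaustive O(L^2) stem-loop scan over all window pairs.
oracle_hairpin <- function(seq, stemMin, loopMin, loopMax) {
  L <- nchar(seq)
  rc <- function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      gap <- j - (i + stemMin - 1) - 1
      if (gap < loopMin || gap > loopMax) next
      if (j + stemMin - 1 > L) next
      if (substr(seq, j, j + stemMin - 1) == rc(substr(seq, i, i + stemMin - 1))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Naive longest-run scan.
oracle_max_run <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  best <- 1L
  cur <- 1L
  for (i in seq_along(ch)[-1]) {
    cur <- if (ch[i] == ch[i - 1]) cur + 1L else 1L
    best <- max(best, cur)
  }
  best
}

# Small shared fixtures: a probe set and an encoded library, built once per
# test run (deterministic seeds).
fixture_probes <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_probe_set(25, probe_config(seed = 301))
    }
    cache
  }
})

fixture_library <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      objs <- generate_fixtures(15, 32, "random", seed = 302)
      cfg <- encoder_config(fountain = fountain_params(chunkSize = 4L,
                                                       epsilon = 0L,
                                                       seed = 303),
                            seed = 303)
      cache <<- list(objects = objs,
                     lib = encode_library(objs, fixture_probes(), cfg),
                     cfg = cfg)
    }
    cache
  }
})
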