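# lsh: MinHash signatures over k-mer sets and a banded OR-construction index.
# Two sequences become candidates when all m hash values of at least one of
# the b bands agree; every candidate is then verified with the exact Jaccard
# similarity, so the index can produce false positives but the two-stage
# filter never reports one.

LSH_PRIME <- 2147483647  # 2^31 - 1, Mersenne prime for the universal family

#' MinHash / banded LSH parameters
#'
#' `r` universal hash functions are split into `b` bands of `m = r/b` rows.
#' With exact Jaccard similarity `s`, the probability that two sequences
#' collide in at least one band is the S-curve `1 - (1 - s^m)^b` (see
#' [collision_probability()]). `t` and `c` document the distance threshold
#' and approximation factor the index is operated at; the hash family is
#' drawn deterministically from `seed`.
#'
#' @param r total number of hash functions; must equal `b * m` exactly.
#' @param b number of bands.
#' @param kmerK shingle length in bp (`<= 11`).
#' @param seed RNG seed for the hash family.
#' @param t distance threshold in `(0, 1)`.
#' @param c approximation factor `> 1`.
#' @return An object of class `lsh_params`.
#' @export
lsh_params <- function(r = 200L, b = 20L, kmerK = 4L, seed = 1L, t = 0.4, c = 2) {
  if (!is_count(r) || !is_count(b)) stopf("r and b must be positive integers")
  if (r %% b != 0) stopf("r = %d is not divisible by b = %d (need r = b * m)", r, b)
  if (!is_count(kmerK) || kmerK > 11) stopf("kmerK must be an integer in [1, 11]")
  if (!is_fraction(t) || t <= 0 || t >= 1) stopf("t must lie in (0, 1)")
  if (!is.numeric(c) || c <= 1) stopf("c must be > 1")
  structure(list(r = as.integer(r), b = as.integer(b), m = as.integer(r / b),
                 kmerK = as.integer(kmerK), t = t, c = c,
                 seed = as.integer(seed)),
            class = "lsh_params")
}

# (a_i * x + c_i) mod p coefficients for the r-member hash family.
hash_family <- function(params) {
  with_seed(derive_seed(params$seed, 7901L), {
    list(a = sample(LSH_PRIME - 1, params$r, replace = TRUE),
         c = sample(LSH_PRIME, params$r, replace = TRUE) - 1)
  })
}

#' MinHash signature of a sequence
#'
#' Entry `i` is the minimum of `h_i(x) = (a_i * x + c_i) mod p` over the
#' 2-bit-packed k-mers `x` of the sequence; identical
#' `(sequence, params)` always yield the identical signature.
#'
#' @param seq DNA sequence string of length `>= kmerK`.
#' @param params an [lsh_params()] object.
#' @param fam optional precomputed hash family (internal reuse).
#' @return Numeric vector of `r` minimum hash values.
#' @export
minhash_signature <- function(seq, params, fam = NULL) {
  x <- kmer_ints(seq, params$kmerK)
  fam <- fam %||% hash_family(params)
  # r x n matrix of hash values; products stay below 2^53 because
  # a_i < 2^31 and x < 4^11.
  M <- (fam$a %o% x + fam$c) %% LSH_PRIME
  M[cbind(seq_len(params$r), max.col(-M, ties.method = "first"))]
}

#' Analytic banded-LSH collision probability
#'
#' Probability that two sequences with Jaccard similarity `s` share all `m`
#' MinHash values in at least one of `b` bands: `1 - (1 - s^m)^b`, monotone
#' increasing in `s`.
#'
#' @param s similarity fraction(s) in `[0, 1]`.
#' @param m rows per band.
#' @param b number of bands.
#' @return Collision probability, vectorized over `s`.
#' @export
collision_probability <- function(s, m, b) {
  if (any(s < 0 | s > 1)) stopf("s must lie in [0, 1]")
  1 - (1 - s^m)^b
}

band_keys <- function(sig, params) {
  paste0(seq_len(params$b), "|",
         vapply(seq_len(params$b), function(i) {
           paste(sig[((i - 1) * params$m + 1):(i * params$m)], collapse = ",")
         }, character(1)))
}

#' Create a banded MinHash index
#'
#' The index is a mutable reference object (an environment): [lsh_insert()]
#' updates it in place and also returns it, so both the imperative and the
#' pipe style work. It keeps the original sequences in `store` so that every
#' candidate can be verified with the exact Jaccard similarity.
#'
#' @param params an [lsh_params()] object.
#' @return An object of class `lsh_index`.
#' @export
lsh_index <- function(params = lsh_params()) {
  stopifnot(inherits(params, "lsh_params"))
  idx <- new.env(parent = emptyenv())
  idx$params <- params
  idx$fam <- hash_family(params)
  idx$tables <- new.env(parent = emptyenv())
  idx$store <- new.env(parent = emptyenv())
  idx$n <- 0L
  class(idx) <- "lsh_index"
  idx
}

#' @export
print.lsh_index <- function(x, ...) {
  cat(sprintf("banded MinHash index: %d sequence(s), r=%d b=%d m=%d k=%d\n",
              x$n, x$params$r, x$params$b, x$params$m, x$params$kmerK))
  invisible(x)
}

#' Insert a sequence into an LSH index
#'
#' Registers the sequence under `id` in all `b` band tables. Duplicate ids
#' are rejected; inserting the same sequence under two ids is allowed (both
#' will be returned by matching queries).
#'
#' @param idx an [lsh_index()] object (modified in place).
#' @param id unique identifier (coerced to character).
#' @param seq DNA sequence string.
#' @return The index, invisibly.
#' @export
lsh_insert <- function(idx, id, seq) {
  stopifnot(inherits(idx, "lsh_index"))
  id <- as.character(id)
  if (!is.null(idx$store[[id]])) stopf("id '%s' already present in index", id)
  s <- as_dna(seq)
  sig <- minhash_signature(s, idx$params, idx$fam)
  for (key in band_keys(sig, idx$params)) {
    idx$tables[[key]] <- c(idx$tables[[key]], id)
  }
  idx$store[[id]] <- s
  idx$n <- idx$n + 1L
  invisible(idx)
}

#' Candidate ids sharing at least one band with a query sequence
#'
#' May contain false positives (sequences whose true similarity is low);
#' never drops a band match. Use [lsh_has_similar()] for the verified
#' two-stage check.
#'
#' @inheritParams lsh_insert
#' @param seq query DNA sequence.
#' @return Character vector of candidate ids (possibly empty).
#' @export
lsh_query <- function(idx, seq) {
  stopifnot(inherits(idx, "lsh_index"))
  if (idx$n == 0L) return(character())
  sig <- minhash_signature(as_dna(seq), idx$params, idx$fam)
  keys <- band_keys(sig, idx$params)
  unique(unlist(lapply(keys, function(k) idx$tables[[k]]), use.names = FALSE))
}

#' Verified similarity check against an index
#'
#' Two-stage filter: band candidates from [lsh_query()] are verified with the
#' exact k-mer Jaccard similarity, so the result has no false positives
#' relative to exact verification.
#'
#' @inheritParams lsh_query
#' @param maxSim similarity cutoff in `(0, 1)`.
#' @return `TRUE` iff some stored sequence has exact similarity `> maxSim`.
#' @export
lsh_has_similar <- function(idx, seq, maxSim) {
  if (!is_fraction(maxSim) || maxSim <= 0 || maxSim >= 1) {
    stopf("maxSim must lie in (0, 1)")
  }
  s <- as_dna(seq)
  for (id in lsh_query(idx, s)) {
    if (jaccard_similarity(s, idx$store[[id]], idx$params$kmerK) > maxSim) {
      return(TRUE)
    }
  }
  FALSE
}

#' Persist / restore an LSH index
#'
#' Writes a single self-describing JSON file holding the parameters, the band
#' tables and the sequence store, so probe indexes can be reused across runs;
#' `lsh_load()` restores an equivalent index (signatures are deterministic in
#' the stored seed).
#'
#' @param idx an [lsh_index()] object.
#' @param path file path for the JSON index.
#' @return `lsh_save()` returns `path` invisibly; `lsh_load()` returns the
#'   restored index.
#' @export
lsh_save <- function(idx, path) {
  stopifnot(inherits(idx, "lsh_index"))
  obj <- list(
    format = "dnakv-lsh-index",
    version = 1L,
    params = unclass(idx$params),
    store = as.list(idx$store),
    tables = as.list(idx$tables)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname lsh_save
#' @export
lsh_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "dnakv-lsh-index")) stopf("not a dnakv LSH index file")
  p <- obj$params
  idx <- lsh_index(lsh_params(r = p$r, b = p$b, kmerK = p$kmerK, seed = p$seed,
                              t = p$t, c = p$c))
  for (id in names(obj$store)) idx$store[[id]] <- obj$store[[id]]
  for (key in names(obj$tables)) idx$tables[[key]] <- as.character(obj$tables[[key]])
  idx$n <- length(obj$store)
  idx
}
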