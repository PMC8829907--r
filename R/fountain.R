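# fountain: rateless erasure codes and the bit<->base mapping.
#
# Two backends behind one interface:
#  * "gf256" - a dense random linear fountain code over GF(256): every repair
#    symbol is a pseudo-random GF(256) combination of all k source chunks,
#    with coefficients derived deterministically from (seed, esi). Its
#    decode-failure probability at k+e received symbols is ~256^-(e+1),
#    which realizes the RaptorQ-class recovery guarantees (>99% at e = 0,
#    >99.99% at e = 1) that systems in this field rely on.
#  * "lt" - a Luby-transform code with the robust soliton degree
#    distribution, decoded by belief-propagation peeling with Gaussian
#    elimination over GF(2) on a stall.
#
# Both are non-systematic by contract: only symbols with esi >= k (repair
# symbols) may be emitted, so raw payload bit patterns - e.g. the all-zero
# bytes that would map to a homopolymer - never appear verbatim in DNA.

#' Fountain-code parameters
#'
#' @param chunkSize bytes per source chunk.
#' @param epsilon decode overhead: number of spare decodable symbols a strand
#'   must carry beyond the minimum.
#' @param backend `"gf256"` (dense random linear code over GF(256), the
#'   default) or `"lt"` (Luby transform with robust soliton distribution).
#' @param solC,solDelta robust-soliton parameters (LT backend only).
#' @param headerBits width of the big-endian encoding-symbol-identifier
#'   header prepended to each packet before DNA mapping.
#' @param seed RNG seed; together with an `esi` it fully determines a symbol.
#' @return An object of class `fountain_params`.
#' @export
fountain_params <- function(chunkSize = 4L, epsilon = 0L,
                            backend = c("gf256", "lt"),
                            solC = 0.1, solDelta = 0.05,
                            headerBits = 16L, seed = 1L) {
  backend <- match.arg(backend)
  if (!is_count(chunkSize)) stopf("chunkSize must be an integer >= 1")
  if (!is_count(epsilon, min = 0)) stopf("epsilon must be an integer >= 0")
  if (!is_count(headerBits, min = 8) || headerBits %% 2 != 0 || headerBits > 30) {
    stopf("headerBits must be an even integer in [8, 30]")
  }
  structure(list(chunkSize = as.integer(chunkSize), epsilon = as.integer(epsilon),
                 backend = backend, solC = solC, solDelta = solDelta,
                 headerBits = as.integer(headerBits), seed = as.integer(seed)),
            class = "fountain_params")
}

#' Split a payload into equally sized source chunks
#'
#' Zero-pads the payload to a multiple of `chunkSize`; the original byte
#' length is recorded so decoding can truncate the padding again (the pad is
#' never stored in DNA).
#'
#' @param payload non-empty raw vector.
#' @param chunkSize bytes per chunk.
#' @return An object of class `source_object` with fields `payload`
#'   (padded), `k`, `chunkSize`, `originalLength` and `chunks` (a
#'   `k x chunkSize` integer matrix of byte values).
#' @export
chunk_data <- function(payload, chunkSize) {
  if (!is.raw(payload)) stopf("payload must be a raw vector")
  if (length(payload) == 0) stopf("payload must be non-empty")
  if (!is_count(chunkSize)) stopf("chunkSize must be an integer >= 1")
  n0 <- length(payload)
  k <- ceiling(n0 / chunkSize)
  padded <- c(payload, raw(k * chunkSize - n0))
  chunks <- matrix(as.integer(padded), nrow = k, ncol = chunkSize, byrow = TRUE)
  structure(list(payload = padded, k = as.integer(k),
                 chunkSize = as.integer(chunkSize),
                 originalLength = as.integer(n0), chunks = chunks),
            class = "source_object")
}

# ---- bit <-> byte <-> base plumbing -----------------------------------------

# MSB-first bit string of a byte-value integer vector.
bytes_to_bits <- function(bytes) {
  if (length(bytes) == 0) return("")
  m <- vapply(7:0, function(s) bitwAnd(bitwShiftR(as.integer(bytes), s), 1L),
              integer(length(bytes)))
  paste(t(matrix(m, nrow = length(bytes))), collapse = "")
}

bits_to_bytes <- function(bits) {
  n <- nchar(bits)
  if (n %% 8 != 0) stopf("bit string length %d is not a multiple of 8", n)
  v <- as.integer(strsplit(bits, "", fixed = TRUE)[[1]])
  m <- matrix(v, nrow = 8)
  as.integer(2^(7:0) %*% m)
}

int_to_bits <- function(x, width) {
  paste(bitwAnd(bitwShiftR(as.integer(x), (width - 1):0), 1L), collapse = "")
}

bits_to_int <- function(bits) {
  v <- as.integer(strsplit(bits, "", fixed = TRUE)[[1]])
  as.integer(sum(v * 2^((length(v) - 1):0)))
}

#' Map a bit string to DNA and back
#'
#' The fixed 2-bits-per-base table `00 -> A`, `01 -> T`, `10 -> C`,
#' `11 -> G`; `dna_to_bits()` is its exact inverse, so
#' `dna_to_bits(bits_to_dna(x)) == x` for every even-length bit string.
#'
#' @param bits character scalar over `{0,1}` of even length.
#' @param seq DNA sequence string.
#' @return `bits_to_dna()` a DNA string of half the bit length;
#'   `dna_to_bits()` a bit string of twice the base length.
#' @export
#' @examples
#' bits_to_dna("0110100011") # "TCCAG"
bits_to_dna <- function(bits) {
  if (!is.character(bits) || length(bits) != 1) stopf("bits must be a single string")
  n <- nchar(bits)
  if (n == 0 || n %% 2 != 0) stopf("bit string must have positive even length, got %d", n)
  if (grepl("[^01]", bits)) stopf("bit string may contain only 0 and 1")
  v <- as.integer(strsplit(bits, "", fixed = TRUE)[[1]])
  idx <- 2L * v[seq(1, n, by = 2)] + v[seq(2, n, by = 2)]
  paste(c("A", "T", "C", "G")[idx + 1L], collapse = "")
}

#' @rdname bits_to_dna
#' @export
dna_to_bits <- function(seq) {
  s <- as_dna(seq)
  idx <- match(strsplit(s, "", fixed = TRUE)[[1]], c("A", "T", "C", "G")) - 1L
  paste(rbind(bitwShiftR(idx, 1L), bitwAnd(idx, 1L)), collapse = "")
}

# ---- symbol generation ------------------------------------------------------

# Robust soliton degree distribution for message length k.
robust_soliton <- function(k, c = 0.1, delta = 0.05) {
  rho <- c(1 / k, 1 / ((2:k) * (1:(k - 1))))
  R <- c * log(k / delta) * sqrt(k)
  tau <- numeric(k)
  cap <- max(1L, min(k, floor(k / R)))
  if (cap > 1) tau[1:(cap - 1)] <- R / ((1:(cap - 1)) * k)
  tau[cap] <- R * log(R / delta) / k
  tau[tau < 0] <- 0
  p <- rho + tau
  p / sum(p)
}

# Deterministic coefficient row for one encoding symbol. For gf256 a dense
# byte vector (never all zero); for lt a 0/1 membership vector with degree
# drawn from the robust soliton distribution.
symbol_coeffs <- function(esi, k, params) {
  with_seed(derive_seed(params$seed, 1009L, esi), {
    if (params$backend == "gf256") {
      repeat {
        co <- sample.int(256L, k, replace = TRUE) - 1L
        if (any(co != 0L)) return(co)
      }
    } else {
      p <- robust_soliton(k, params$solC, params$solDelta)
      d <- sample.int(k, 1L, prob = p)
      sel <- sample.int(k, d)
      co <- integer(k)
      co[sel] <- 1L
      co
    }
  })
}

#' Generate one repair symbol (packet)
#'
#' Only repair symbols may be emitted (`esi >= k`); requesting a systematic
#' symbol is an error. A packet is fully reproducible from `(seed, esi)`
#' alone: the same pair always yields bit-identical packets.
#'
#' @param obj a [chunk_data()] source object.
#' @param esi encoding-symbol identifier, `k <= esi < 2^headerBits`.
#' @param params a [fountain_params()] object.
#' @param as_dna also attach the packet's DNA form (header + payload mapped
#'   2 bits per base).
#' @return An object of class `dna_packet`: list with `esi`, `bytes`
#'   (integer byte values, length `chunkSize`) and `dna` (or `NULL`).
#' @export
encode_symbol <- function(obj, esi, params, as_dna = TRUE) {
  stopifnot(inherits(obj, "source_object"), inherits(params, "fountain_params"))
  if (!is_count(esi, min = 0)) stopf("esi must be a non-negative integer")
  if (esi < obj$k) {
    stopf("esi %d < k = %d: systematic symbols are forbidden (non-systematic contract)",
          esi, obj$k, class = "dnakv_systematic_esi")
  }
  if (esi >= 2^params$headerBits) {
    stopf("esi %d does not fit the %d-bit header", esi, params$headerBits)
  }
  co <- symbol_coeffs(esi, obj$k, params)
  bytes <- if (params$backend == "gf256") {
    as.integer(gf256_matmul_cpp(matrix(co, nrow = 1), obj$chunks))
  } else {
    sel <- which(co == 1L)
    out <- integer(obj$chunkSize)
    for (j in sel) out <- bitwXor(out, obj$chunks[j, ])
    out
  }
  dna <- if (as_dna) packet_dna(esi, bytes, params) else NULL
  structure(list(esi = as.integer(esi), bytes = bytes, dna = dna),
            class = "dna_packet")
}

# Pseudorandom whitening mask for a packet's payload bytes. The code is
# linear, so a low-entropy message (e.g. all zero bytes) yields low-entropy
# repair symbols; XORing a mask derived from (seed, esi) into the serialized
# payload keeps the DNA form pseudorandom for every message while the
# decoder, which removes the mask before solving, is unaffected.
packet_mask <- function(esi, nBytes, params) {
  with_seed(derive_seed(params$seed, 7451L, esi), {
    sample.int(256L, nBytes, replace = TRUE) - 1L
  })
}

# Fixed seed-derived permutation interleaving header and payload bits. The
# ESI header is low-entropy (small identifiers share long runs of zero
# bits); spreading its bits among the whitened payload bits prevents any
# positional low-entropy region - homopolymer headers, shared packet
# prefixes - from ever reaching the DNA.
packet_bit_perm <- function(params) {
  nbits <- params$headerBits + 8L * params$chunkSize
  with_seed(derive_seed(params$seed, 5077L), sample.int(nbits))
}

#' Packet DNA geometry and (de)serialization
#'
#' A packet is serialized as the `headerBits`-bit big-endian ESI followed by
#' the payload bytes XOR a pseudorandom whitening mask keyed by
#' `(seed, esi)`; the combined bit vector is then interleaved by a fixed
#' seed-derived permutation and mapped 2 bits per base. Every packet
#' occupies exactly `packet_dna_length(params)` bases, which is how the
#' decoder splits a strand back into packets; `parse_packet_dna()` inverts
#' the permutation and removes the mask, so the DNA form alone round-trips
#' to `(esi, bytes)` exactly. Whitening plus interleaving keep packet DNA
#' pseudorandom even for degenerate messages (all-zero or all-one bytes,
#' for which the repair symbols of any linear code are themselves constant)
#' and for small ESIs whose plain headers would carry long zero runs.
#'
#' @param esi encoding-symbol identifier.
#' @param bytes integer byte values of the packet payload.
#' @param params a [fountain_params()] object.
#' @return `packet_dna()` the packet's DNA string; `parse_packet_dna()` a
#'   list `(esi, bytes)`; `packet_dna_length()` the fixed length in bases.
#' @export
packet_dna <- function(esi, bytes, params) {
  masked <- bitwXor(as.integer(bytes), packet_mask(esi, length(bytes), params))
  bits <- paste0(int_to_bits(esi, params$headerBits), bytes_to_bits(masked))
  v <- strsplit(bits, "", fixed = TRUE)[[1]]
  bits_to_dna(paste(v[packet_bit_perm(params)], collapse = ""))
}

#' @rdname packet_dna
#' @param dna DNA string of exactly `packet_dna_length(params)` bases.
#' @export
parse_packet_dna <- function(dna, params) {
  expect_len <- packet_dna_length(params)
  if (nchar(dna) != expect_len) {
    stopf("packet DNA has %d bases, expected %d", nchar(dna), expect_len,
          class = "dnakv_packet_truncated")
  }
  shuffled <- strsplit(dna_to_bits(dna), "", fixed = TRUE)[[1]]
  v <- character(length(shuffled))
  v[packet_bit_perm(params)] <- shuffled
  bits <- paste(v, collapse = "")
  esi <- bits_to_int(substr(bits, 1, params$headerBits))
  masked <- bits_to_bytes(substr(bits, params$headerBits + 1, nchar(bits)))
  list(esi = esi, bytes = bitwXor(masked, packet_mask(esi, length(masked), params)))
}

#' @rdname packet_dna
#' @export
packet_dna_length <- function(params) {
  as.integer((params$headerBits + 8L * params$chunkSize) / 2L)
}

# ---- decoding ---------------------------------------------------------------

# Deduplicate packets by esi; packets repeating an esi with different bytes
# are an integrity error (one of them is corrupt).
dedupe_packets <- function(packets) {
  esis <- vapply(packets, function(p) p$esi, integer(1))
  keep <- !duplicated(esis)
  for (i in which(duplicated(esis))) {
    first <- packets[[match(esis[i], esis)]]
    if (!identical(first$bytes, packets[[i]]$bytes)) {
      stopf("packets with esi %d carry different payloads (integrity error)",
            esis[i], class = "dnakv_integrity")
    }
  }
  packets[keep]
}

#' Decode a set of fountain packets
#'
#' Rebuilds each packet's coefficient row from its ESI and solves for the
#' source chunks. The LT backend peels degree-1 equations first
#' (belief propagation) and falls back to Gaussian elimination over GF(2) on
#' a stall; the gf256 backend solves directly over GF(256). Failure
#' (insufficient rank) is explicit - the decoder never silently returns a
#' corrupted payload for a rank-deficient system.
#'
#' @param packets list of `dna_packet` objects (or lists with `esi`,
#'   `bytes`).
#' @param k number of source chunks.
#' @param originalLength pre-padding payload length in bytes.
#' @param params the [fountain_params()] used at encode time.
#' @return List with `success` (logical), `payload` (raw vector or `NULL`)
#'   and `rank` (achieved coefficient rank).
#' @export
fountain_decode <- function(packets, k, originalLength, params) {
  stopifnot(inherits(params, "fountain_params"))
  if (!is_count(k)) stopf("k must be an integer >= 1")
  if (length(packets) == 0) {
    return(list(success = FALSE, payload = NULL, rank = 0L))
  }
  packets <- dedupe_packets(packets)
  n <- length(packets)
  A <- do.call(rbind, lapply(packets, function(p) symbol_coeffs(p$esi, k, params)))
  Y <- do.call(rbind, lapply(packets, function(p) as.integer(p$bytes)))
  sol <- if (params$backend == "gf256") {
    gf256_solve_cpp(A, Y)
  } else {
    lt_decode(A, Y)
  }
  if (!isTRUE(sol$ok)) {
    return(list(success = FALSE, payload = NULL, rank = sol$rank))
  }
  padded <- as.raw(as.integer(t(sol$x)))
  if (originalLength > length(padded)) {
    return(list(success = FALSE, payload = NULL, rank = sol$rank))
  }
  list(success = TRUE, payload = padded[seq_len(originalLength)], rank = sol$rank)
}

# Peeling (belief-propagation) decoder with GF(2) elimination fallback.
lt_decode <- function(A, Y) {
  n <- nrow(A); k <- ncol(A); L <- ncol(Y)
  A <- A != 0L
  Y <- Y
  x <- matrix(NA_integer_, nrow = k, ncol = L)
  solved <- logical(k)
  repeat {
    deg <- rowSums(A)
    ones <- which(deg == 1L)
    if (length(ones) == 0) break
    progressed <- FALSE
    for (i in ones) {
      j <- which(A[i, ])
      if (length(j) != 1) next   # row consumed earlier in this sweep
      yi <- Y[i, ]
      x[j, ] <- yi
      solved[j] <- TRUE
      hit <- which(A[, j])
      for (h in hit) {
        Y[h, ] <- bitwXor(Y[h, ], yi)
        A[h, j] <- FALSE
      }
      # the resolving row itself went to degree 0 via the loop above
      progressed <- TRUE
    }
    if (!progressed) break
    if (all(solved)) break
  }
  if (all(solved)) {
    return(list(ok = TRUE, rank = k, x = x))
  }
  # stall: eliminate the residual system over the unsolved columns
  un <- which(!solved)
  live <- which(rowSums(A) > 0)
  if (length(live) == 0) {
    return(list(ok = FALSE, rank = sum(solved), x = NULL))
  }
  sub <- gf2_solve_cpp(matrix(as.integer(A[live, un, drop = FALSE]),
                              nrow = length(live)),
                       Y[live, , drop = FALSE])
  if (!isTRUE(sub$ok)) {
    return(list(ok = FALSE, rank = sum(solved) + sub$rank, x = NULL))
  }
  x[un, ] <- sub$x
  list(ok = TRUE, rank = k, x = x)
}

#' Does a packet set decode with the required overhead?
#'
#' A set satisfies overhead `epsilon` when it is decodable (coefficient rank
#' `k`) and *remains* decodable after the removal of any `epsilon` of its
#' packets - i.e. it tolerates `epsilon` erasures. All removal subsets are
#' checked exactly (desk-scale `epsilon` keeps the combinatorics tiny).
#'
#' @param esis integer vector of the packets' encoding-symbol identifiers.
#' @param k number of source chunks.
#' @param params a [fountain_params()] object.
#' @param epsilon required erasure tolerance (defaults to
#'   `params$epsilon`).
#' @return `TRUE` iff the rank condition holds for every removal subset.
#' @export
can_decode <- function(esis, k, params, epsilon = params$epsilon) {
  n <- length(esis)
  if (n < k + epsilon) return(FALSE)
  A <- do.call(rbind, lapply(esis, function(e) symbol_coeffs(e, k, params)))
  rank_fun <- if (params$backend == "gf256") gf256_rank_cpp else gf2_rank_cpp
  if (rank_fun(A) < k) return(FALSE)
  if (epsilon == 0) return(TRUE)
  drops <- combn(n, epsilon)
  for (j in seq_len(ncol(drops))) {
    if (rank_fun(A[-drops[, j], , drop = FALSE]) < k) return(FALSE)
  }
  TRUE
}
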