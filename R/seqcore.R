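# seqcore: DNA string primitives, biochemical constraint checks, k-mer
# shingling and exact Jaccard similarity (the brute-force reference that the
# LSH layer is always verified against).

DNA_BASES <- c("A", "C", "G", "T")

#' Validate a DNA sequence
#'
#' Coerces a character scalar to an upper-case DNA string over `{A,C,G,T}`.
#' Any other symbol (including `U` and IUPAC ambiguity codes) is rejected with
#' the position of the first offending character.
#'
#' @param x character scalar.
#' @return The validated upper-case sequence string.
#' @export
#' @examples
#' as_dna("acgt")
as_dna <- function(x) {
  if (!is.character(x) || length(x) != 1 || is.na(x)) {
    stopf("a DNA sequence must be a single character string", class = "dnakv_invalid_dna")
  }
  s <- toupper(x)
  if (nchar(s) < 1) {
    stopf("a DNA sequence must have length >= 1", class = "dnakv_invalid_dna")
  }
  bad <- regexpr("[^ACGT]", s)
  if (bad > 0) {
    stopf("invalid symbol '%s' at position %d (alphabet is A, C, G, T)",
          substr(s, bad, bad), bad, class = "dnakv_invalid_dna")
  }
  s
}

#' Position-wise complement of a DNA sequence
#'
#' Swaps `A<->T` and `C<->G` at each position, preserving order. This is the
#' convention used to derive microarray probes from target subsequences (a
#' target `TGAC` gives the probe `ACTG`); it is *not* the reverse complement,
#' for which see [reverse_complement()].
#'
#' @param seq DNA sequence string.
#' @return The complemented sequence, same length.
#' @export
#' @examples
#' complement("TGAC") # "ACTG"
complement <- function(seq) {
  chartr("ACGT", "TGCA", as_dna(seq))
}

#' Reverse complement of a DNA sequence
#'
#' The biochemical antiparallel complement: complement each base and reverse
#' the order. Used by the hairpin scanner, where a downstream window must
#' fold back onto an upstream window.
#'
#' @inheritParams complement
#' @return The reverse-complemented sequence.
#' @export
reverse_complement <- function(seq) {
  s <- complement(seq)
  paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
}

#' k-mer set of a sequence
#'
#' All distinct contiguous length-`k` subsequences, in order of first
#' appearance. `ACTACC` with `k = 3` yields `{ACT, CTA, TAC, ACC}`.
#'
#' @param seq DNA sequence string.
#' @param k shingle length in bp; must satisfy `1 <= k <= nchar(seq)`.
#' @return Character vector of distinct k-mers.
#' @export
kmer_set <- function(seq, k) {
  s <- as_dna(seq)
  L <- nchar(s)
  if (!is_count(k) || k > L) {
    stopf("k must be an integer in [1, %d] for a sequence of length %d", L, L,
          class = "dnakv_invalid_k")
  }
  unique(substring(s, seq_len(L - k + 1), k:L))
}

# k-mers as 2-bit packed integers (A=0, C=1, G=2, T=3, first base most
# significant); distinct values only. Requires k <= 11 so products with
# 31-bit hash coefficients stay exact in doubles.
kmer_ints <- function(seq, k) {
  s <- as_dna(seq)
  L <- nchar(s)
  if (!is_count(k) || k > L) {
    stopf("k must be an integer in [1, %d] for a sequence of length %d", L, L,
          class = "dnakv_invalid_k")
  }
  if (k > 11) stopf("k-mer packing supports k <= 11, got %d", k)
  code <- match(strsplit(s, "", fixed = TRUE)[[1]], DNA_BASES) - 1
  if (k == 1) return(unique(code))
  # embed() row i is c(code[i+k-1], ..., code[i]): weight it little-endian to
  # make the first base of the window most significant.
  vals <- as.vector(embed(code, k) %*% 4^(0:(k - 1)))
  unique(vals)
}

#' Exact Jaccard similarity of two sequences' k-mer sets
#'
#' `|S_k(q1) n S_k(q2)| / |S_k(q1) u S_k(q2)|`: 1 for identical k-mer sets, 0
#' for disjoint ones. This is the exact (brute-force) similarity that the LSH
#' index approximates and against which every LSH candidate is verified.
#'
#' @param q1,q2 DNA sequence strings.
#' @param k shingle length in bp.
#' @return Similarity in `[0, 1]`.
#' @export
#' @examples
#' jaccard_similarity("ACTACC", "ACTACG", 3) # 0.6
jaccard_similarity <- function(q1, q2, k) {
  a <- kmer_ints(q1, k)
  b <- kmer_ints(q2, k)
  ni <- sum(a %in% b)
  ni / (length(a) + length(b) - ni)
}

#' @rdname jaccard_similarity
#' @export
jaccard_distance <- function(q1, q2, k) 1 - jaccard_similarity(q1, q2, k)

#' All-pairs exact Jaccard similarity matrix
#'
#' Computes the exact k-mer Jaccard similarity for every pair of sequences by
#' dense set-membership algebra (`|A n B|` via a 0/1 membership matrix cross
#' product), independent of any LSH machinery. Intended as the brute-force
#' audit for generated probe sets and strand libraries.
#'
#' @param seqs character vector of DNA sequences.
#' @param k shingle length in bp (`k <= 11`).
#' @return A symmetric `length(seqs)` square matrix of similarities with unit
#'   diagonal.
#' @export
pairwise_jaccard <- function(seqs, k) {
  n <- length(seqs)
  if (n < 1) stopf("need at least one sequence")
  if (!is_count(k) || k > 11) stopf("k must be an integer in [1, 11]")
  M <- matrix(0L, nrow = n, ncol = 4^k)
  for (i in seq_len(n)) {
    M[i, kmer_ints(seqs[[i]], k) + 1L] <- 1L
  }
  inter <- tcrossprod(M)
  sizes <- diag(inter)
  uni <- outer(sizes, sizes, "+") - inter
  sim <- inter / uni
  dimnames(sim) <- list(names(seqs), names(seqs))
  sim
}

#' GC content of a sequence
#'
#' Fraction of `G` and `C` bases; around 0.5 gives the most stable DNA.
#'
#' @inheritParams complement
#' @return Fraction in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  s <- as_dna(seq)
  1 - nchar(gsub("[GC]", "", s)) / nchar(s)
}

#' Longest homopolymer run
#'
#' Length (bp) of the longest run of one repeated base. Long runs are
#' error-prone to synthesize and sequence, so encoders cap them.
#'
#' @inheritParams complement
#' @return Run length in bp (>= 1).
#' @export
max_homopolymer_run <- function(seq) {
  s <- as_dna(seq)
  max(rle(strsplit(s, "", fixed = TRUE)[[1]])$lengths)
}

#' Stem-loop structure parameters
#'
#' Parameters of the hairpin model used by [has_complex_structure()]: a
#' hairpin is two disjoint windows of at least `stemMin` bp where the
#' downstream window is the reverse complement of the upstream one, separated
#' by a loop of `loopMin` to `loopMax` unpaired bases.
#'
#' @param stemMin minimum self-complementary stem length in bp (>= 2).
#' @param loopMin,loopMax hairpin loop size bounds in bp.
#' @return An object of class `structure_params`.
#' @export
structure_params <- function(stemMin = 6L, loopMin = 3L, loopMax = 8L) {
  if (!is_count(stemMin, min = 2)) stopf("stemMin must be an integer >= 2")
  if (!is_count(loopMin, min = 0) && loopMin != 0) stopf("loopMin must be an integer >= 0")
  if (!is_count(loopMax, min = 0) || loopMax < loopMin) {
    stopf("loopMax must be an integer >= loopMin")
  }
  structure(list(stemMin = as.integer(stemMin), loopMin = as.integer(loopMin),
                 loopMax = as.integer(loopMax)),
            class = "structure_params")
}

#' Detect hairpin-forming secondary structure
#'
#' Scans for a stem-loop: an upstream window of `stemMin` bp whose reverse
#' complement occurs downstream after a gap of `loopMin` to `loopMax` bases.
#' Any stem of length `>= stemMin` necessarily contains a stem of exactly
#' `stemMin`, so only windows of that length are scanned. Sequences too short
#' to host a stem-loop (`L < 2*stemMin + loopMin`) are trivially structure
#' free.
#'
#' @param seq DNA sequence string.
#' @param sp a [structure_params()] object.
#' @return `TRUE` if a hairpin under the model exists.
#' @export
has_complex_structure <- function(seq, sp = structure_params()) {
  s <- as_dna(seq)
  stopifnot(inherits(sp, "structure_params"))
  L <- nchar(s)
  st <- sp$stemMin
  if (L < 2 * st + sp$loopMin) return(FALSE)
  comp <- chartr("ACGT", "TGCA", s)
  revs <- paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  for (g in sp$loopMin:sp$loopMax) {
    nst <- L - 2 * st - g + 1
    if (nst < 1) next
    i <- seq_len(nst)
    up <- substring(comp, i, i + st - 1)                # complement of upstream stem
    j <- i + st + g                                     # downstream stem start
    down_rev <- substring(revs, L - (j + st - 1) + 1, L - j + 1) # downstream stem, reversed
    if (any(up == down_rev)) return(TRUE)
  }
  FALSE
}

#' Biochemical constraint configuration
#'
#' Bundles the constraint thresholds applied to probes, packets and strands:
#' GC-content bounds, the homopolymer cap, the hairpin model, and sequences
#' (typically the library's single primer pair) whose k-mer overlap must stay
#' below `forbiddenMaxSim`.
#'
#' @param gcMin,gcMax GC-fraction bounds in `[0, 1]`.
#' @param maxHomopolymer maximum allowed single-base run in bp.
#' @param probeLen nominal probe length in bp (recorded for consumers).
#' @param struct a [structure_params()] object.
#' @param forbidden character vector of sequences to avoid (primer pair).
#' @param forbiddenMaxSim maximum tolerated Jaccard similarity to a forbidden
#'   sequence.
#' @param forbiddenK shingle length for the forbidden-overlap check.
#' @param checkStructure apply the hairpin check (disabled for per-packet
#'   checks, where structure is only meaningful on the assembled strand).
#' @return An object of class `constraint_config`.
#' @export
constraint_config <- function(gcMin = 0.4, gcMax = 0.6, maxHomopolymer = 5L,
                              probeLen = 60L, struct = structure_params(),
                              forbidden = character(), forbiddenMaxSim = 0.6,
                              forbiddenK = 4L, checkStructure = TRUE) {
  if (!is_fraction(gcMin) || !is_fraction(gcMax) || gcMin > gcMax) {
    stopf("need 0 <= gcMin <= gcMax <= 1")
  }
  if (!is_count(maxHomopolymer)) stopf("maxHomopolymer must be an integer >= 1")
  if (!is_count(probeLen)) stopf("probeLen must be an integer >= 1")
  stopifnot(inherits(struct, "structure_params"))
  if (!is_fraction(forbiddenMaxSim)) stopf("forbiddenMaxSim must be in [0, 1]")
  forbidden <- vapply(forbidden, as_dna, character(1), USE.NAMES = FALSE)
  structure(list(gcMin = gcMin, gcMax = gcMax,
                 maxHomopolymer = as.integer(maxHomopolymer),
                 probeLen = as.integer(probeLen), struct = struct,
                 forbidden = forbidden, forbiddenMaxSim = forbiddenMaxSim,
                 forbiddenK = as.integer(forbiddenK),
                 checkStructure = isTRUE(checkStructure)),
            class = "constraint_config")
}

#' Check a sequence against all configured constraints
#'
#' Applies the GC-range check (C1), the homopolymer cap (C2), the hairpin
#' model (C6) and the forbidden-sequence overlap check (primer avoidance),
#' collecting *all* violations rather than stopping at the first.
#'
#' @param seq DNA sequence string.
#' @param cfg a [constraint_config()] object.
#' @return A list of class `constraint_report` with elements `passed`
#'   (logical) and `violations` (data frame with columns `constraint`,
#'   `observed`, `message`).
#' @export
check_constraints <- function(seq, cfg = constraint_config()) {
  s <- as_dna(seq)
  stopifnot(inherits(cfg, "constraint_config"))
  v <- list()
  gc <- gc_content(s)
  if (gc < cfg$gcMin || gc > cfg$gcMax) {
    v[[length(v) + 1]] <- data.frame(
      constraint = "C1", observed = gc,
      message = sprintf("GC content %.3f outside [%.2f, %.2f]", gc, cfg$gcMin, cfg$gcMax))
  }
  run <- max_homopolymer_run(s)
  if (run > cfg$maxHomopolymer) {
    v[[length(v) + 1]] <- data.frame(
      constraint = "C2", observed = run,
      message = sprintf("homopolymer run %d exceeds cap %d", run, cfg$maxHomopolymer))
  }
  if (cfg$checkStructure && has_complex_structure(s, cfg$struct)) {
    v[[length(v) + 1]] <- data.frame(
      constraint = "C6", observed = 1,
      message = sprintf("stem-loop with stem >= %d bp detected", cfg$struct$stemMin))
  }
  for (f in cfg$forbidden) {
    k <- min(cfg$forbiddenK, nchar(s), nchar(f))
    sim <- jaccard_similarity(s, f, k)
    if (sim > cfg$forbiddenMaxSim) {
      v[[length(v) + 1]] <- data.frame(
        constraint = "C4", observed = sim,
        message = sprintf("similarity %.3f to forbidden sequence exceeds %.2f",
                          sim, cfg$forbiddenMaxSim))
    }
  }
  violations <- if (length(v)) do.call(rbind, v) else
    data.frame(constraint = character(), observed = numeric(), message = character())
  structure(list(passed = nrow(violations) == 0, violations = violations),
            class = "constraint_report")
}

#' @export
print.constraint_report <- function(x, ...) {
  if (x$passed) cat("constraint report: passed\n")
  else {
    cat(sprintf("constraint report: %d violation(s)\n", nrow(x$violations)))
    print(x$violations, row.names = FALSE)
  }
  invisible(x)
}

#' Read and write DNA FASTA files
#'
#' Thin wrappers around Biostrings I/O keeping sequences as plain named
#' character vectors; records are wrapped at 80 columns and record IDs kept
#' verbatim.
#'
#' @param path file path.
#' @param seqs named character vector of DNA sequences.
#' @return `read_fasta()` returns a named character vector; `write_fasta()`
#'   returns `path` invisibly.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs) %||% as.character(seq_along(seqs))
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}
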