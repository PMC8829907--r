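# probegen: stochastic generation of fixed-length probes (barcodes) with
# exact GC-count placement, constraint filtering and LSH-enforced mutual
# dissimilarity. Probes are the keys of the DNA key-value store.

#' Probe-generation configuration
#'
#' Defaults follow the published operating point for 60 bp probes: GC content
#' in 40-60%, homopolymer runs capped at 5 bp, pairwise k-mer (k = 4) Jaccard
#' similarity at most 60%, and a banded MinHash index with r = 200, b = 20
#' backing the dissimilarity checks.
#'
#' @param probeLen probe length in bp.
#' @param gcMin,gcMax GC-fraction bounds the probe is sampled in.
#' @param maxHomopolymer maximum allowed single-base run in bp.
#' @param maxSim pairwise similarity cutoff in `(0, 1)`; candidates whose
#'   exact Jaccard similarity to any accepted probe exceeds it are discarded.
#' @param maxAttempts retry cap per probe before an explicit failure is
#'   raised (an over-constrained configuration would otherwise loop forever).
#' @param seed RNG seed; the full probe set is deterministic in it.
#' @param struct hairpin model, see [structure_params()].
#' @param forbidden primer pair (or other sequences) the probes must not
#'   overlap with.
#' @param lsh [lsh_params()] for the probe index.
#' @return An object of class `probe_config`.
#' @export
probe_config <- function(probeLen = 60L, gcMin = 0.4, gcMax = 0.6,
                         maxHomopolymer = 5L, maxSim = 0.6,
                         maxAttempts = 10000L, seed = 1L,
                         struct = structure_params(),
                         forbidden = character(),
                         lsh = lsh_params(r = 200L, b = 20L, kmerK = 4L,
                                          seed = seed)) {
  if (!is_fraction(maxSim) || maxSim <= 0 || maxSim >= 1) {
    stopf("maxSim must lie in (0, 1)")
  }
  if (!is_count(maxAttempts)) stopf("maxAttempts must be an integer >= 1")
  constraint <- constraint_config(gcMin = gcMin, gcMax = gcMax,
                                  maxHomopolymer = maxHomopolymer,
                                  probeLen = probeLen, struct = struct,
                                  forbidden = forbidden,
                                  forbiddenMaxSim = maxSim,
                                  forbiddenK = lsh$kmerK)
  structure(list(probeLen = as.integer(probeLen), gcMin = gcMin, gcMax = gcMax,
                 maxSim = maxSim, maxAttempts = as.integer(maxAttempts),
                 seed = as.integer(seed), constraint = constraint, lsh = lsh),
            class = "probe_config")
}

#' Draw one raw probe candidate
#'
#' Implements the exact-GC sampling scheme: a GC count is drawn uniformly
#' from the integer range implied by `[gcMin * probeLen, gcMax * probeLen]`,
#' that many positions are chosen uniformly without replacement and filled
#' with G or C (equiprobable), and the remaining positions are filled with A
#' or T (equiprobable). This is one raw draw *before* any constraint
#' filtering; it consumes the caller's RNG stream.
#'
#' @param cfg a [probe_config()] object.
#' @return A DNA sequence string of length `probeLen`.
#' @export
sample_probe <- function(cfg) {
  len <- cfg$probeLen
  lo <- ceiling(cfg$gcMin * len)
  hi <- floor(cfg$gcMax * len)
  if (lo > hi) stopf("GC bounds [%g, %g] admit no integer GC count at length %d",
                     cfg$gcMin, cfg$gcMax, len)
  gcCount <- if (lo == hi) lo else sample(lo:hi, 1L)
  p <- character(len)
  gcPos <- sample.int(len, gcCount)
  atPos <- setdiff(seq_len(len), gcPos)
  p[gcPos] <- sample(c("G", "C"), gcCount, replace = TRUE)
  p[atPos] <- sample(c("A", "T"), length(atPos), replace = TRUE)
  paste(p, collapse = "")
}

#' Generate one accepted probe
#'
#' Rejection-samples [sample_probe()] until the candidate passes all
#' biochemical constraints and has no verified similarity above `maxSim` to
#' any probe already in the index; the accepted probe is inserted into the
#' index before returning. Fails explicitly after `maxAttempts` rejected
#' candidates, naming the most frequent violated constraint so an
#' over-constrained configuration is diagnosable.
#'
#' @param cfg a [probe_config()] object.
#' @param index an [lsh_index()] holding all previously accepted probes
#'   (updated in place).
#' @param id identifier for the accepted probe.
#' @return List with `id`, `seq` and `attempts` (candidates drawn, including
#'   the accepted one).
#' @export
generate_probe <- function(cfg, index, id = index$n + 1L) {
  stopifnot(inherits(cfg, "probe_config"), inherits(index, "lsh_index"))
  tally <- c(C1 = 0L, C2 = 0L, C4 = 0L, C6 = 0L, similar = 0L)
  for (attempt in seq_len(cfg$maxAttempts)) {
    p <- sample_probe(cfg)
    rep <- check_constraints(p, cfg$constraint)
    if (!rep$passed) {
      for (ct in rep$violations$constraint) tally[ct] <- tally[ct] + 1L
      next
    }
    if (lsh_has_similar(index, p, cfg$maxSim)) {
      tally["similar"] <- tally["similar"] + 1L
      next
    }
    lsh_insert(index, id, p)
    return(list(id = id, seq = p, attempts = attempt))
  }
  worst <- names(tally)[which.max(tally)]
  stopf(paste0("no admissible probe found in %d attempts; most frequent ",
               "rejection: %s (%d times) - configuration is over-constrained"),
        cfg$maxAttempts, worst, max(tally), class = "dnakv_probe_exhausted")
}

#' Generate a set of mutually dissimilar probes
#'
#' Repeats [generate_probe()] until `n` probes are accepted. The result is
#' fully deterministic in `cfg$seed` (including acceptance order), every
#' probe satisfies the constraint configuration, and all pairs have exact
#' Jaccard similarity at most `maxSim`.
#'
#' @param n number of probes.
#' @param cfg a [probe_config()] object.
#' @param verbose print progress every 100 probes.
#' @return An object of class `probe_set`: list with `probes` (data frame
#'   `id`, `seq`, `attempts`), `index` (the populated [lsh_index()]) and
#'   `config`.
#' @export
generate_probe_set <- function(n, cfg = probe_config(), verbose = FALSE) {
  if (!is_count(n)) stopf("n must be an integer >= 1")
  index <- lsh_index(cfg$lsh)
  rows <- vector("list", n)
  with_seed(derive_seed(cfg$seed, 17L), {
    for (i in seq_len(n)) {
      pr <- generate_probe(cfg, index, id = i)
      rows[[i]] <- data.frame(id = i, seq = pr$seq, attempts = pr$attempts)
      if (verbose && i %% 100L == 0L) {
        message(sprintf("probe %d/%d (attempts so far: %d)", i, n,
                        sum(vapply(rows[seq_len(i)], function(r) r$attempts, numeric(1)))))
      }
    }
  })
  structure(list(probes = do.call(rbind, rows), index = index, config = cfg),
            class = "probe_set")
}

#' @export
print.probe_set <- function(x, ...) {
  cat(sprintf("probe set: %d probes of %d bp (GC %.0f-%.0f%%, maxSim %.0f%%, mean attempts %.2f)\n",
              nrow(x$probes), x$config$probeLen, 100 * x$config$gcMin,
              100 * x$config$gcMax, 100 * x$config$maxSim,
              mean(x$probes$attempts)))
  invisible(x)
}

#' Write a probe set to FASTA
#'
#' Record id is the probe's ordinal identifier.
#'
#' @param ps a `probe_set` or a data frame with columns `id`, `seq`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_probes <- function(ps, path) {
  df <- if (inherits(ps, "probe_set")) ps$probes else ps
  write_fasta(setNames(df$seq, df$id), path)
}
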