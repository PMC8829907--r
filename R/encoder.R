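# encoder: the probe-aware encoding pipeline. For each data object it walks
# the fountain code's unbounded repair-symbol stream, keeps only packets
# whose DNA passes the per-packet constraints and dissimilarity checks,
# assembles them into a decodable Info-DNA strand, anneals the probe (key)
# to its 5' end and records the DOI -> probe mapping.

#' Encoder configuration
#'
#' Defaults follow the published strand settings: k-mer length 5 for all
#' strand-level similarity checks, a minimum pairwise Jaccard distance of
#' 30% between every pair of final sequences, GC content checked per packet
#' (which keeps the distribution uniform along the strand) and homopolymer
#' runs capped across packet junctions.
#'
#' @param constraint a [constraint_config()] object; its GC bounds and
#'   homopolymer cap are applied per packet, its hairpin model to the
#'   assembled strand only.
#' @param fountain a [fountain_params()] object.
#' @param minDist minimum Jaccard distance in `(0, 1)` required between a new
#'   sequence and every probe, primer and previously encoded strand;
#'   similarity above `1 - minDist` causes rejection.
#' @param strandLshK shingle length in bp for strand-level checks.
#' @param maxPacketTries candidate-symbol budget per packet slot.
#' @param strandRetries whole-strand retry budget after a strand-level
#'   constraint failure.
#' @param seed seed recorded for the run (symbol generation derives all of
#'   its randomness from `fountain$seed` and the ESI, so encoding is
#'   deterministic).
#' @param lsh [lsh_params()] for the probe and strand indexes used during
#'   encoding.
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(constraint = constraint_config(),
                           fountain = fountain_params(),
                           minDist = 0.3, strandLshK = 5L,
                           maxPacketTries = 5000L, strandRetries = 25L,
                           seed = 1L,
                           lsh = lsh_params(r = 200L, b = 20L,
                                            kmerK = strandLshK, seed = seed)) {
  stopifnot(inherits(constraint, "constraint_config"),
            inherits(fountain, "fountain_params"))
  if (!is_fraction(minDist) || minDist <= 0 || minDist >= 1) {
    stopf("minDist must lie in (0, 1)")
  }
  if (!is_count(maxPacketTries) || !is_count(strandRetries)) {
    stopf("maxPacketTries and strandRetries must be positive integers")
  }
  if (lsh$kmerK != strandLshK) stopf("lsh$kmerK must equal strandLshK")
  structure(list(constraint = constraint, fountain = fountain,
                 minDist = minDist, strandLshK = as.integer(strandLshK),
                 maxPacketTries = as.integer(maxPacketTries),
                 strandRetries = as.integer(strandRetries),
                 seed = as.integer(seed), lsh = lsh),
            class = "encoder_config")
}

# Similarity ceiling implied by the distance floor.
encoder_max_sim <- function(cfg) 1 - cfg$minDist

new_encoder_state <- function(payload, cfg, prefix = "") {
  st <- new.env(parent = emptyenv())
  st$obj <- chunk_data(payload, cfg$fountain$chunkSize)
  st$nextEsi <- st$obj$k
  st$prefix <- prefix   # annealed upstream sequence (the probe); junction-checked
  st$valueDna <- ""
  st$rejections <- c(C1 = 0L, C2 = 0L, C4 = 0L, C5 = 0L, C7 = 0L)
  st
}

# Exact-Jaccard check of a candidate against the primer pair; k shrinks to
# the shortest sequence so very short primers are still comparable.
primer_conflict <- function(dna, cfg) {
  for (f in cfg$constraint$forbidden) {
    k <- min(cfg$strandLshK, nchar(dna), nchar(f))
    if (jaccard_similarity(dna, f, k) > encoder_max_sim(cfg)) return(TRUE)
  }
  FALSE
}

#' Produce the next admissible DNA packet for an object
#'
#' Advances the encoding-symbol identifier monotonically (rejected ESIs are
#' skipped permanently), maps each candidate repair symbol to DNA, and
#' returns the first candidate that passes the per-packet GC check (C1), the
#' homopolymer cap including the junction with the strand assembled so far
#' (C2), primer avoidance (C3/C4), and the verified LSH dissimilarity checks
#' against the probe set (C7) and previously encoded strands (C5).
#'
#' @param state per-object encoder state created internally by
#'   [encode_object()].
#' @param cfg an [encoder_config()] object.
#' @param probeIdx [lsh_index()] over the probe set.
#' @param strandIdx [lsh_index()] over previously accepted strands.
#' @return A `dna_packet` (see [encode_symbol()]).
#' @export
next_dna_packet <- function(state, cfg, probeIdx, strandIdx) {
  maxSim <- encoder_max_sim(cfg)
  maxHP <- cfg$constraint$maxHomopolymer
  sofar <- paste0(state$prefix, state$valueDna)
  tail_len <- min(nchar(sofar), maxHP)
  tail <- substr(sofar, nchar(sofar) - tail_len + 1, nchar(sofar))
  for (try in seq_len(cfg$maxPacketTries)) {
    esi <- state$nextEsi
    if (esi >= 2^cfg$fountain$headerBits) {
      stopf("encoding-symbol identifiers exhausted (header width %d bits)",
            cfg$fountain$headerBits, class = "dnakv_esi_exhausted")
    }
    state$nextEsi <- esi + 1L
    pkt <- encode_symbol(state$obj, esi, cfg$fountain, as_dna = TRUE)
    d <- pkt$dna
    gc <- gc_content(d)
    if (gc < cfg$constraint$gcMin || gc > cfg$constraint$gcMax) {
      state$rejections["C1"] <- state$rejections["C1"] + 1L
      next
    }
    if (max_homopolymer_run(paste0(tail, d)) > maxHP) {
      state$rejections["C2"] <- state$rejections["C2"] + 1L
      next
    }
    if (primer_conflict(d, cfg)) {
      state$rejections["C4"] <- state$rejections["C4"] + 1L
      next
    }
    if (lsh_has_similar(probeIdx, d, maxSim)) {
      state$rejections["C7"] <- state$rejections["C7"] + 1L
      next
    }
    if (lsh_has_similar(strandIdx, d, maxSim)) {
      state$rejections["C5"] <- state$rejections["C5"] + 1L
      next
    }
    return(pkt)
  }
  worst <- names(state$rejections)[which.max(state$rejections)]
  stopf(paste0("no admissible packet in %d candidate symbols; dominant ",
               "rejection: %s (%d times)"),
        cfg$maxPacketTries, worst, max(state$rejections),
        class = "dnakv_packet_exhausted")
}

#' Encode one data object into an Info-DNA strand
#'
#' Appends admissible DNA packets until the accumulated set is decodable and
#' tolerates `epsilon` erasures (see [can_decode()]), then applies the
#' whole-strand checks - homopolymer runs across the probe junction, the
#' hairpin model (C6, evaluated only on the assembled strand), primer
#' avoidance, and verified dissimilarity to all probes and strands. On a
#' whole-strand failure the packets are discarded and assembly restarts with
#' fresh ESIs, up to `strandRetries` times. On success the probe is
#' prepended, the strand registered in the strand index, and the strand
#' returned.
#'
#' @param doi data-object identifier.
#' @param payload raw vector.
#' @param probe list (or one-row data frame) with `id` and `seq`.
#' @param cfg an [encoder_config()] object.
#' @param probeIdx,strandIdx LSH indexes over probes and accepted strands
#'   (`strandIdx` is updated in place).
#' @return An object of class `info_strand`: list with `doi`, `probeId`,
#'   `probeSeq`, `seq` (full strand), `esis`, `packetCount`, `k`,
#'   `chunkSize`, `originalLength`, `epsilon` and `rejections`.
#' @export
encode_object <- function(doi, payload, probe, cfg, probeIdx, strandIdx) {
  stopifnot(inherits(cfg, "encoder_config"))
  probeSeq <- as_dna(probe$seq)
  state <- new_encoder_state(payload, cfg, prefix = probeSeq)
  k <- state$obj$k
  eps <- cfg$fountain$epsilon
  maxSim <- encoder_max_sim(cfg)
  esi_jump <- function(retry) {
    # jump the monotone ESI stream ahead so the next assembly sees packets
    # with genuinely different identifier bits
    jump <- as.integer(min(2^cfg$fountain$headerBits - 2,
                           retry * (2^cfg$fountain$headerBits %/% cfg$strandRetries)))
    state$nextEsi <- max(state$nextEsi, jump)
  }
  for (retry in seq_len(cfg$strandRetries)) {
    state$valueDna <- ""
    esis <- integer()
    assembled <- tryCatch({
      repeat {
        pkt <- next_dna_packet(state, cfg, probeIdx, strandIdx)
        state$valueDna <- paste0(state$valueDna, pkt$dna)
        esis <- c(esis, pkt$esi)
        if (length(esis) >= k + eps && can_decode(esis, k, cfg$fountain, eps)) break
      }
      TRUE
    }, dnakv_packet_exhausted = function(e) {
      if (retry == cfg$strandRetries) stop(e)
      FALSE
    })
    if (!assembled) {
      esi_jump(retry)
      next
    }
    full <- paste0(probeSeq, state$valueDna)
    ok <- max_homopolymer_run(full) <= cfg$constraint$maxHomopolymer &&
      !(cfg$constraint$checkStructure &&
          has_complex_structure(full, cfg$constraint$struct)) &&
      !primer_conflict(full, cfg) &&
      !lsh_has_similar(probeIdx, full, maxSim) &&
      !lsh_has_similar(strandIdx, full, maxSim)
    if (ok) {
      lsh_insert(strandIdx, doi, full)
      return(structure(list(
        doi = doi, probeId = probe$id, probeSeq = probeSeq, seq = full,
        esis = esis, packetCount = length(esis), k = k,
        chunkSize = state$obj$chunkSize,
        originalLength = state$obj$originalLength, epsilon = eps,
        rejections = state$rejections), class = "info_strand"))
    }
    esi_jump(retry)
  }
  stopf("object %s: whole-strand constraints failed in %d assembly attempts",
        as.character(doi), cfg$strandRetries, class = "dnakv_strand_exhausted")
}

#' @export
print.info_strand <- function(x, ...) {
  cat(sprintf("info strand doi=%s: %d bp = probe %d bp + %d packets (k=%d, eps=%d)\n",
              as.character(x$doi), nchar(x$seq), nchar(x$probeSeq),
              x$packetCount, x$k, x$epsilon))
  invisible(x)
}

#' Encode a library of data objects
#'
#' Assigns probes to objects (one probe per object by default; with
#' `probesPerKey = n` each probe addresses `n` consecutive objects), builds
#' fresh probe and strand LSH indexes at the strand shingle length, encodes
#' every object with [encode_object()], and assembles the mapping table.
#' Probe exhaustion is rejected before any encoding starts. The result is
#' deterministic in the configuration and input order.
#'
#' @param objects list of `list(doi =, payload =)` entries (see
#'   [generate_fixtures()]).
#' @param probes a `probe_set` or data frame with columns `id`, `seq`.
#' @param cfg an [encoder_config()] object.
#' @param probesPerKey objects addressed per probe (1 = unique key per
#'   object).
#' @return An object of class `dna_library`: list with `strands` (list of
#'   `info_strand`), `mapping` (a `mapping_table`), `probeIndex` and
#'   `strandIndex`.
#' @export
encode_library <- function(objects, probes, cfg = encoder_config(),
                           probesPerKey = 1L) {
  if (!is_count(probesPerKey)) stopf("probesPerKey must be an integer >= 1")
  pdf <- if (inherits(probes, "probe_set")) probes$probes else probes
  n <- length(objects)
  needed <- ceiling(n / probesPerKey)
  if (nrow(pdf) < needed) {
    stopf("probe exhaustion: %d objects at %d per key need %d probes, have %d",
          n, probesPerKey, needed, nrow(pdf), class = "dnakv_probe_exhaustion")
  }
  probeIdx <- lsh_index(cfg$lsh)
  for (i in seq_len(nrow(pdf))) lsh_insert(probeIdx, paste0("p", pdf$id[i]), pdf$seq[i])
  strandIdx <- lsh_index(cfg$lsh)
  strands <- vector("list", n)
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    ob <- objects[[i]]
    prow <- pdf[(i - 1) %/% probesPerKey + 1, ]
    st <- encode_object(ob$doi, ob$payload, list(id = prow$id, seq = prow$seq),
                        cfg, probeIdx, strandIdx)
    strands[[i]] <- st
    entries[[i]] <- data.frame(
      doi = as.character(ob$doi), probe_id = as.character(prow$id),
      probe_seq = prow$seq, k = st$k, chunk_size = st$chunkSize,
      original_length = st$originalLength, packet_count = st$packetCount,
      epsilon = st$epsilon)
  }
  mapping <- structure(list(
    config = list(fountain = unclass(cfg$fountain),
                  probeLen = nchar(pdf$seq[1]),
                  strandLshK = cfg$strandLshK, minDist = cfg$minDist),
    entries = do.call(rbind, entries)), class = "mapping_table")
  structure(list(strands = strands, mapping = mapping,
                 probeIndex = probeIdx, strandIndex = strandIdx),
            class = "dna_library")
}

#' @export
print.dna_library <- function(x, ...) {
  lens <- vapply(x$strands, function(s) nchar(s$seq), numeric(1))
  cat(sprintf("DNA library: %d strand(s), mean length %.1f bp\n",
              length(x$strands), mean(lens)))
  invisible(x)
}

#' Mapping-table and strand-library serialization
#'
#' The mapping table is the in-silico half of the store: the DOI -> probe
#' association plus the per-object decode metadata (k, chunk size, original
#' length, packet count, overhead) and the fountain parameters. The JSON
#' file alone is sufficient to drive random access over a strand FASTA.
#'
#' @param mapping a `mapping_table`.
#' @param path output path.
#' @return `write_mapping()` returns `path` invisibly; `read_mapping()` the
#'   restored `mapping_table`.
#' @export
write_mapping <- function(mapping, path) {
  stopifnot(inherits(mapping, "mapping_table"))
  obj <- list(format = "dnakv-mapping", version = 1L,
              config = mapping$config, entries = mapping$entries)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mapping
#' @export
read_mapping <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "dnakv-mapping")) stopf("not a dnakv mapping file")
  fp <- obj$config$fountain
  obj$config$fountain <- unclass(fountain_params(
    chunkSize = fp$chunkSize, epsilon = fp$epsilon, backend = fp$backend,
    solC = fp$solC, solDelta = fp$solDelta, headerBits = fp$headerBits,
    seed = fp$seed))
  structure(list(config = obj$config, entries = obj$entries),
            class = "mapping_table")
}

#' Write a strand library to FASTA
#'
#' Record id is the DOI; the description carries the probe id and packet
#' count.
#'
#' @param lib a `dna_library` or list of `info_strand` objects.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_strands <- function(lib, path) {
  strands <- if (inherits(lib, "dna_library")) lib$strands else lib
  seqs <- vapply(strands, function(s) s$seq, character(1))
  names(seqs) <- vapply(strands, function(s) {
    sprintf("%s probe=%s packets=%d", as.character(s$doi),
            as.character(s$probeId), s$packetCount)
  }, character(1))
  write_fasta(seqs, path)
}
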