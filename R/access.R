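# access: in-silico microarray random access. A read prints the requested
# DOIs' probes onto a (virtual) array, hybridizes the whole library against
# it, optionally corrupts the selected strand through an error channel,
# splits the Info-DNA back into packets and fountain-decodes the payload.

#' Print probes onto a microarray
#'
#' Looks each requested DOI up in the mapping table and immobilizes
#' ("downloads") the corresponding probes onto a virtual microarray;
#' duplicate probes (several DOIs sharing one key) are printed once.
#'
#' @param mapping a `mapping_table` (see [encode_library()]).
#' @param dois vector of data-object identifiers; must be non-empty and all
#'   present in the table.
#' @return An object of class `microarray` holding the printed probe
#'   sequences.
#' @export
print_array <- function(mapping, dois) {
  stopifnot(inherits(mapping, "mapping_table"))
  if (length(dois) == 0) stopf("no DOIs requested", class = "dnakv_not_found")
  dois <- as.character(dois)
  hit <- match(dois, mapping$entries$doi)
  if (anyNA(hit)) {
    stopf("unknown DOI(s): %s", paste(dois[is.na(hit)], collapse = ", "),
          class = "dnakv_not_found")
  }
  structure(list(probes = unique(mapping$entries$probe_seq[hit])),
            class = "microarray")
}

#' @export
print.microarray <- function(x, ...) {
  cat(sprintf("microarray: %d printed probe(s) of %d bp\n",
              length(x$probes), nchar(x$probes[1])))
  invisible(x)
}

hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Hybridize a strand library against a microarray
#'
#' A strand is selected iff its key region (the probe-length prefix) matches
#' some printed probe within Hamming distance `tolerance`; selection returns
#' whole strands, emulating wash stringency with the mismatch tolerance
#' (tolerance 0 = perfectly stringent washing). Because the simulated pool is
#' conceptually double-stranded - each strand carries its probe's complement
#' as well - the match is performed directly between the stored probe and the
#' key prefix, with no complementation step.
#'
#' @param library a `dna_library`, a list of `info_strand` objects, or a
#'   named character vector of strand sequences (names = DOIs).
#' @param array a [print_array()] microarray.
#' @param tolerance maximum number of mismatches in the key region.
#' @return Named character vector of the selected whole strands (names =
#'   DOIs); empty when nothing hybridizes.
#' @export
hybridize <- function(library, array, tolerance = 0L) {
  stopifnot(inherits(array, "microarray"))
  if (!is_count(tolerance, min = 0)) stopf("tolerance must be an integer >= 0")
  seqs <- library_seqs(library)
  if (length(seqs) == 0) return(character())
  plen <- nchar(array$probes[1])
  keys <- substr(seqs, 1, plen)
  sel <- vapply(keys, function(key) {
    any(vapply(array$probes, function(p) hamming(key, p) <= tolerance, logical(1)))
  }, logical(1), USE.NAMES = FALSE)
  seqs[sel]
}

# Normalize the accepted library representations to a DOI-named vector.
library_seqs <- function(library) {
  if (inherits(library, "dna_library")) library <- library$strands
  if (is.character(library)) {
    if (length(library) == 0) return(setNames(character(), character()))
    if (is.null(names(library))) stopf("a character library must be DOI-named")
    return(library)
  }
  setNames(vapply(library, function(s) s$seq, character(1)),
           vapply(library, function(s) as.character(s$doi), character(1)))
}

#' Error channel for synthesis/sequencing noise
#'
#' Independent per-base substitution, insertion and deletion probabilities; a
#' substitution always changes the base, an insertion places one uniform base
#' before a position (or at the 3' end).
#'
#' @param subRate,insRate,delRate per-base probabilities in `[0, 1]`.
#' @param seed optional seed making the channel deterministic; without it the
#'   caller's RNG stream is used.
#' @return An object of class `error_channel`.
#' @export
error_channel <- function(subRate = 0, insRate = 0, delRate = 0, seed = NULL) {
  for (r in c(subRate, insRate, delRate)) {
    if (!is_fraction(r)) stopf("error rates must lie in [0, 1]")
  }
  structure(list(subRate = subRate, insRate = insRate, delRate = delRate,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "error_channel")
}

#' Corrupt a DNA sequence through an error channel
#'
#' @param seq DNA sequence string (or an `info_strand`, whose `seq` is
#'   taken).
#' @param ch an [error_channel()].
#' @return The corrupted raw sequence; structural guarantees of the input no
#'   longer hold.
#' @export
corrupt <- function(seq, ch) {
  stopifnot(inherits(ch, "error_channel"))
  if (inherits(seq, "info_strand")) seq <- seq$seq
  s <- as_dna(seq)
  run <- function() {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- length(chars)
    keep <- runif(n) >= ch$delRate
    sub <- runif(n) < ch$subRate
    for (i in which(sub & keep)) {
      chars[i] <- sample(setdiff(DNA_BASES, chars[i]), 1L)
    }
    ins <- runif(n + 1) < ch$insRate
    ins_base <- character(n + 1)
    if (any(ins)) ins_base[ins] <- sample(DNA_BASES, sum(ins), replace = TRUE)
    out <- character(0)
    for (i in seq_len(n)) {
      if (ins[i]) out <- c(out, ins_base[i])
      if (keep[i]) out <- c(out, chars[i])
    }
    if (ins[n + 1]) out <- c(out, ins_base[n + 1])
    paste(out, collapse = "")
  }
  if (is.null(ch$seed)) run() else with_seed(ch$seed, run())
}

#' Randomly access one stored object
#'
#' The full read path: look the DOI's probe up in the mapping table, print it
#' onto an array, hybridize the library, optionally corrupt the selected
#' strand, strip the key region, split the Info-DNA at the fixed packet
#' length, discard faulty packets (truncated tails, ESI headers outside the
#' valid range), and fountain-decode. Errors are explicit: a
#' `dnakv_not_found` condition when no strand hybridizes and a
#' `dnakv_recovery_error` (naming the surviving packet count) when the
#' surviving packets cannot decode.
#'
#' @param library a strand library (see [hybridize()] for accepted forms).
#' @param mapping the `mapping_table` for the library.
#' @param doi one data-object identifier.
#' @param ch optional [error_channel()] applied to the selected strand.
#' @param tolerance hybridization mismatch tolerance.
#' @return The recovered payload as a raw vector.
#' @export
random_read <- function(library, mapping, doi, ch = NULL, tolerance = 0L) {
  stopifnot(inherits(mapping, "mapping_table"))
  if (length(doi) != 1) stopf("random_read() reads one DOI; use parallel_read() for several")
  doi <- as.character(doi)
  entry <- mapping$entries[mapping$entries$doi == doi, ]
  if (nrow(entry) == 0) stopf("unknown DOI: %s", doi, class = "dnakv_not_found")
  array <- print_array(mapping, doi)
  sel <- hybridize(library, array, tolerance)
  if (!(doi %in% names(sel))) {
    stopf("no strand hybridized for DOI %s", doi, class = "dnakv_not_found")
  }
  seq <- sel[[doi]]
  if (!is.null(ch)) seq <- corrupt(seq, ch)
  fp <- do.call(fountain_params, mapping$config$fountain)
  decode_strand(seq, entry, fp)
}

# Strip the key region, split into fixed-length packets, drop faulty ones,
# decode.
decode_strand <- function(seq, entry, fp) {
  plen <- nchar(entry$probe_seq)
  tail <- substr(seq, plen + 1, nchar(seq))
  plen_pkt <- packet_dna_length(fp)
  n_whole <- nchar(tail) %/% plen_pkt
  packets <- list()
  for (i in seq_len(n_whole)) {
    piece <- substr(tail, (i - 1) * plen_pkt + 1, i * plen_pkt)
    pk <- tryCatch(parse_packet_dna(piece, fp), error = function(e) NULL)
    if (is.null(pk)) next
    if (pk$esi < entry$k || pk$esi >= 2^fp$headerBits) next  # faulty header
    packets[[length(packets) + 1]] <- pk
  }
  dec <- tryCatch(
    fountain_decode(packets, entry$k, entry$original_length, fp),
    dnakv_integrity = function(e) list(success = FALSE, payload = NULL, rank = NA))
  if (!dec$success) {
    stopf("recovery failed for DOI %s: %d surviving packet(s), need rank %d",
          entry$doi, length(packets), entry$k, class = "dnakv_recovery_error")
  }
  dec$payload
}

#' Read several objects in one hybridization
#'
#' Prints all requested probes on one array, hybridizes once, and decodes
#' each object from its selected strand; equivalent to independent
#' [random_read()] calls on a clean channel.
#'
#' @inheritParams random_read
#' @param dois vector of data-object identifiers.
#' @return Named list of raw payloads keyed by DOI.
#' @export
parallel_read <- function(library, mapping, dois, ch = NULL, tolerance = 0L) {
  array <- print_array(mapping, dois)
  sel <- hybridize(library, array, tolerance)
  fp <- do.call(fountain_params, mapping$config$fountain)
  out <- vector("list", length(dois))
  names(out) <- as.character(dois)
  for (doi in as.character(dois)) {
    if (!(doi %in% names(sel))) {
      stopf("no strand hybridized for DOI %s", doi, class = "dnakv_not_found")
    }
    seq <- sel[[doi]]
    if (!is.null(ch)) seq <- corrupt(seq, ch)
    entry <- mapping$entries[mapping$entries$doi == doi, ]
    out[[doi]] <- decode_strand(seq, entry, fp)
  }
  out
}
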