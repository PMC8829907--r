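# cli_io: fixture generation, the end-to-end pipeline (probes -> encode ->
# verify), the independent audit, configuration parsing and the run
# manifest. A thin command-line front-end over these functions is installed
# as `exec/dnakv`.

#' Generate synthetic payload objects
#'
#' Stands in for an external dataset: a deterministic list of byte payloads
#' with gapless DOIs `0..n-1`. The `all-zero` and `all-one` classes exist
#' specifically to stress the non-systematic encoding argument - mapped
#' verbatim, such payloads would become pure homopolymers.
#'
#' @param nObjects number of objects.
#' @param objectSize bytes per object.
#' @param payloadClass `"random"` (uniform bytes), `"text"` (printable ASCII
#'   words), `"all-zero"` (0x00) or `"all-one"` (0xFF).
#' @param seed RNG seed; identical spec always yields identical payloads.
#' @return List of `list(doi =, payload =)` entries, payloads as raw
#'   vectors.
#' @export
generate_fixtures <- function(nObjects, objectSize,
                              payloadClass = c("random", "text", "all-zero", "all-one"),
                              seed = 1L) {
  payloadClass <- match.arg(payloadClass)
  if (!is_count(nObjects) || !is_count(objectSize)) {
    stopf("nObjects and objectSize must be positive integers")
  }
  with_seed(derive_seed(seed, 4099L), {
    lapply(seq_len(nObjects) - 1L, function(doi) {
      payload <- switch(payloadClass,
        "random" = as.raw(sample.int(256L, objectSize, replace = TRUE) - 1L),
        "text" = charToRaw(paste(sample(c(letters, LETTERS, " "), objectSize,
                                        replace = TRUE), collapse = "")),
        "all-zero" = raw(objectSize),
        "all-one" = as.raw(rep(255L, objectSize)))
      list(doi = doi, payload = payload)
    })
  })
}

#' Independent audit of probes and strands
#'
#' Recomputes every guarantee with the exact brute-force primitives only -
#' GC content, homopolymer runs, the hairpin scan, and all-pairs Jaccard
#' similarities - never trusting the generator's or encoder's internal
#' (LSH-based) checks.
#'
#' @param probes character vector of probe sequences.
#' @param strands character vector of final strand sequences (optional).
#' @param probeCfg the [probe_config()] the probes were generated under.
#' @param encCfg the [encoder_config()] the strands were encoded under
#'   (required when `strands` given).
#' @return List of class `dnakv_audit` with the measured extremes, the
#'   per-constraint violation counts and `violations` (their total).
#' @export
audit_library <- function(probes, strands = NULL, probeCfg = probe_config(),
                          encCfg = NULL) {
  gc <- vapply(probes, gc_content, numeric(1), USE.NAMES = FALSE)
  runs <- vapply(probes, max_homopolymer_run, numeric(1), USE.NAMES = FALSE)
  hairpins <- vapply(probes, has_complex_structure, logical(1),
                     sp = probeCfg$constraint$struct, USE.NAMES = FALSE)
  sim <- pairwise_jaccard(probes, probeCfg$lsh$kmerK)
  maxPairSim <- if (length(probes) > 1) max(sim[upper.tri(sim)]) else 0
  out <- list(
    nProbes = length(probes),
    probeGcMin = min(gc), probeGcMax = max(gc),
    probeMaxRun = max(runs),
    probeMaxPairSim = maxPairSim,
    counts = c(
      C1 = sum(gc < probeCfg$gcMin | gc > probeCfg$gcMax),
      C2 = sum(runs > probeCfg$constraint$maxHomopolymer),
      C6 = sum(hairpins),
      C3 = if (length(probes) > 1) sum(sim[upper.tri(sim)] > probeCfg$maxSim) else 0L
    ))
  if (!is.null(strands)) {
    stopifnot(!is.null(encCfg))
    d <- 1 - pairwise_jaccard(strands, encCfg$strandLshK)
    out$nStrands <- length(strands)
    out$strandMinPairDist <- if (length(strands) > 1) min(d[upper.tri(d)]) else 1
    sruns <- vapply(strands, max_homopolymer_run, numeric(1), USE.NAMES = FALSE)
    shp <- vapply(strands, has_complex_structure, logical(1),
                  sp = encCfg$constraint$struct, USE.NAMES = FALSE)
    out$counts <- c(out$counts,
      strandC2 = sum(sruns > encCfg$constraint$maxHomopolymer),
      strandC6 = sum(shp),
      strandC5 = if (length(strands) > 1)
        sum(d[upper.tri(d)] < encCfg$minDist) else 0L)
  }
  out$violations <- sum(out$counts)
  class(out) <- "dnakv_audit"
  out
}

#' @export
print.dnakv_audit <- function(x, ...) {
  cat(sprintf("audit: %d probe(s), GC %.1f-%.1f%%, max run %d, max pair sim %.3f\n",
              x$nProbes, 100 * x$probeGcMin, 100 * x$probeGcMax,
              x$probeMaxRun, x$probeMaxPairSim))
  if (!is.null(x$nStrands)) {
    cat(sprintf("       %d strand(s), min pair dist %.3f\n",
                x$nStrands, x$strandMinPairDist))
  }
  cat(sprintf("       total violations: %d\n", x$violations))
  invisible(x)
}

#' Default pipeline configuration
#'
#' One declarative list for all stages, encoding the reference operating
#' point: 60 bp probes with GC 40-60%, homopolymer cap 5, probe similarity
#' cutoff 60% at k = 4, strand minimum distance 30% at k = 5, LSH r = 200,
#' b = 20.
#'
#' @param nObjects,objectSize,payloadClass,seed fixture settings, see
#'   [generate_fixtures()].
#' @param nProbes probes to generate (defaults to the number of keys
#'   needed).
#' @param probesPerKey objects addressed per probe.
#' @param probeLen probe length in bp.
#' @param chunkSize,epsilon,backend fountain settings.
#' @param ... overrides merged into the list.
#' @return A named list understood by [run_pipeline()].
#' @export
pipeline_config <- function(nObjects = 50L, objectSize = 32L,
                            payloadClass = "random", seed = 1L,
                            nProbes = NULL, probesPerKey = 1L, probeLen = 60L,
                            chunkSize = 4L, epsilon = 0L, backend = "gf256",
                            ...) {
  base <- list(
    nObjects = nObjects, objectSize = objectSize,
    payloadClass = payloadClass, seed = seed,
    nProbes = nProbes %||% ceiling(nObjects / probesPerKey),
    probesPerKey = probesPerKey, probeLen = probeLen,
    gcMin = 0.4, gcMax = 0.6, maxHomopolymer = 5L, probeMaxSim = 0.6,
    probeKmerK = 4L, minDist = 0.3, strandLshK = 5L,
    lshR = 200L, lshB = 20L,
    chunkSize = chunkSize, epsilon = epsilon, backend = backend,
    primers = character())
  modifyList(base, list(...))
}

#' Read a pipeline configuration file
#'
#' YAML or JSON (decided by extension); fields are validated and completed
#' with the [pipeline_config()] defaults.
#'
#' @param path configuration file path.
#' @return A validated configuration list.
#' @export
read_config <- function(path) {
  cfg <- if (grepl("[.]ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, cfg)
}

# Build the stage configurations, validating cross-field invariants early.
pipeline_setup <- function(cfg) {
  if (cfg$lshR %% cfg$lshB != 0) {
    stopf("invalid configuration: lshR = %d is not divisible by lshB = %d",
          cfg$lshR, cfg$lshB)
  }
  pc <- probe_config(
    probeLen = cfg$probeLen, gcMin = cfg$gcMin, gcMax = cfg$gcMax,
    maxHomopolymer = cfg$maxHomopolymer, maxSim = cfg$probeMaxSim,
    seed = derive_seed(cfg$seed, 1L), forbidden = cfg$primers,
    lsh = lsh_params(r = cfg$lshR, b = cfg$lshB, kmerK = cfg$probeKmerK,
                     seed = derive_seed(cfg$seed, 1L)))
  ec <- encoder_config(
    constraint = constraint_config(gcMin = cfg$gcMin, gcMax = cfg$gcMax,
                                   maxHomopolymer = cfg$maxHomopolymer,
                                   probeLen = cfg$probeLen,
                                   forbidden = cfg$primers,
                                   forbiddenMaxSim = 1 - cfg$minDist,
                                   forbiddenK = cfg$strandLshK),
    fountain = fountain_params(chunkSize = cfg$chunkSize,
                               epsilon = cfg$epsilon, backend = cfg$backend,
                               seed = derive_seed(cfg$seed, 2L)),
    minDist = cfg$minDist, strandLshK = cfg$strandLshK,
    seed = derive_seed(cfg$seed, 2L),
    lsh = lsh_params(r = cfg$lshR, b = cfg$lshB, kmerK = cfg$strandLshK,
                     seed = derive_seed(cfg$seed, 2L)))
  list(probe = pc, encoder = ec)
}

#' Run the full workflow: probes, encoding, verification, audit
#'
#' Executes the three stages end-to-end on synthetic payloads - probe
#' generation, probe-aware encoding, and a verification pass that reads
#' every object back through the clean access path - then audits all
#' outputs with the brute-force primitives and writes `probes.fasta`,
#' `library.fasta`, `mapping.json`, `manifest.json` and `audit.json` to
#' `outDir`. Any stage failure aborts with the stage name. Reruns with the
#' same configuration produce byte-identical FASTA outputs.
#'
#' @param config a [pipeline_config()] list or a path to a YAML/JSON file.
#' @param outDir output directory (created if missing).
#' @param verbose print stage progress.
#' @return Invisibly, a list with `probes`, `library`, `audit`, `manifest`
#'   and `recovered` (count of byte-exact recoveries).
#' @export
run_pipeline <- function(config, outDir, verbose = FALSE) {
  cfg <- if (is.character(config)) read_config(config) else
    do.call(pipeline_config, config)
  setup <- pipeline_setup(cfg)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  if (verbose) message("stage fixtures")
  objects <- stage("fixtures", generate_fixtures(
    cfg$nObjects, cfg$objectSize, cfg$payloadClass, seed = cfg$seed))
  if (verbose) message("stage gen-probes")
  ps <- stage("gen-probes", generate_probe_set(cfg$nProbes, setup$probe))
  if (verbose) message("stage encode")
  lib <- stage("encode", encode_library(objects, ps, setup$encoder,
                                        probesPerKey = cfg$probesPerKey))
  if (verbose) message("stage verify")
  recovered <- stage("verify", {
    ok <- 0L
    for (ob in objects) {
      got <- random_read(lib, lib$mapping, ob$doi)
      if (identical(got, ob$payload)) ok <- ok + 1L
    }
    ok
  })
  if (recovered < length(objects)) {
    stopf("pipeline stage 'verify' failed: only %d/%d objects recovered",
          recovered, length(objects))
  }
  if (verbose) message("stage audit")
  audit <- stage("audit", audit_library(
    ps$probes$seq, vapply(lib$strands, function(s) s$seq, character(1)),
    probeCfg = setup$probe, encCfg = setup$encoder))
  manifest <- list(
    tool = "dnakv", version = as.character(utils::packageVersion("dnakv")),
    config = cfg,
    counters = list(
      probeAttempts = sum(ps$probes$attempts),
      packetRejections = Reduce(`+`, lapply(lib$strands, function(s) s$rejections)),
      packetCounts = vapply(lib$strands, function(s) s$packetCount, integer(1)),
      recovered = recovered))
  write_probes(ps, file.path(outDir, "probes.fasta"))
  write_strands(lib, file.path(outDir, "library.fasta"))
  write_mapping(lib$mapping, file.path(outDir, "mapping.json"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(unclass(audit), file.path(outDir, "audit.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(probes = ps, library = lib, audit = audit,
                 manifest = manifest, recovered = recovered))
}
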