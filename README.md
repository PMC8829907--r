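# dnakv — a probe-addressed key-value store on synthetic DNA

DNA storage systems usually address data with PCR primers, which limits a
pool to roughly ten directly accessible objects. `dnakv` implements and
simulates, end to end, an architecture that scales the address space to
thousands–millions of objects: every stored object is one strand
`probe (key) ++ Info-DNA (value)`, where the probe is a short microarray
barcode and the Info-DNA is a fountain-coded encoding of the object's bytes.
Random access is a microarray selection: look the object's probe up in an
in-silico mapping table, print it on the array, hybridize the pool, sequence
the selected strand, decode.

The package is aimed at people studying the coding layer of DNA storage —
it lets you generate large constraint-satisfying probe sets, encode
arbitrary payloads into biochemically well-behaved strands, and verify
recovery in simulation, all deterministically from a seed.

## What is inside

* **Sequence core** — validated DNA strings; GC content; homopolymer runs;
  a stem-loop (hairpin) scanner; exact k-mer Jaccard similarity
  `sim_k(q1,q2) = |S_k(q1) ∩ S_k(q2)| / |S_k(q1) ∪ S_k(q2)|`
  and an all-pairs brute-force audit.
* **MinHash LSH** — banded signatures (r = 200 hash functions, b = 20 bands
  of m = 10 by default) with the analytic band-collision S-curve
  `P(collide) = 1 − (1 − s^m)^b`; every candidate is verified with the
  exact Jaccard similarity, so dissimilarity checks scale without false
  positives.
* **Probe generator** — rejection sampling with exact GC-count placement;
  constraints: GC in 40–60%, homopolymer runs ≤ 5 bp, no hairpins, pairwise
  similarity ≤ 60% (k = 4), primer avoidance.
* **Fountain codec** — non-systematic repair symbols only; a dense GF(256)
  random-linear backend (decode success > 99% from exactly k symbols,
  > 99.99% from k+1) and a Luby-transform backend (robust soliton, peeling
  decoder with GF(2) elimination fallback); fixed bit↔base mapping
  `00→A, 01→T, 10→C, 11→G` with per-packet whitening and bit interleaving.
* **Probe-aware encoder** — walks the repair-symbol stream, keeps packets
  that pass per-packet GC/run/primer/dissimilarity checks, assembles a
  strand that decodes with a configurable erasure overhead ε, anneals the
  probe, maintains the DOI → probe mapping table.
* **Access simulator** — probe printing, Hamming-tolerance hybridization,
  an iid substitution/insertion/deletion error channel, and full decode.
* **Pipeline & CLI** — `run_pipeline()` (fixtures → probes → encode →
  verify → audit) plus a thin `exec/dnakv` command-line front-end
  (`gen-probes`, `encode`, `access`, `fixtures`, `pipeline`).

## Worked example

```r
library(dnakv)

ps   <- generate_probe_set(5, probe_config(seed = 1))
ps
#> probe set: 5 probes of 60 bp (GC 40-60%, maxSim 60%, mean attempts 1.00)

objs <- generate_fixtures(3, 32, "text", seed = 2)
rawToChar(objs[[1]]$payload)
#> [1] "ljmjzJLNhBKThzDPRoajIcGdRMNvVbaP"

cfg <- encoder_config(fountain = fountain_params(chunkSize = 4, epsilon = 1,
                                                 seed = 3), seed = 3)
lib <- encode_library(objs, ps, cfg)
lib$strands[[1]]
#> info strand doi=0: 276 bp = probe 60 bp + 9 packets (k=8, eps=1)

rawToChar(random_read(lib, lib$mapping, 0L))
#> [1] "ljmjzJLNhBKThzDPRoajIcGdRMNvVbaP"
```

The 32-byte object became 8 source chunks (k = 8); with overhead ε = 1 the
strand carries 9 packets of 24 bp each (16-bit symbol identifier + 4 payload
bytes, 2 bits per base), appended to the 60 bp probe: 276 bp in total. The
overhead is a real erasure guarantee — delete a whole packet from the strand
and the read still returns the exact bytes:

```r
plen <- packet_dna_length(cfg$fountain)   # 24 bases
seqs <- setNames(vapply(lib$strands, function(x) x$seq, character(1)),
                 vapply(lib$strands, function(x) as.character(x$doi), character(1)))
body <- substr(seqs[["0"]], 61, nchar(seqs[["0"]]))
seqs[["0"]] <- paste0(substr(seqs[["0"]], 1, 60),       # drop first packet
                      substr(body, plen + 1, nchar(body)))
identical(random_read(seqs, lib$mapping, 0L), objs[[1]]$payload)
#> [1] TRUE
```

See `vignette("dna-key-value-storage", package = "dnakv")` for the model,
the parameter meanings, and the design decisions.

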