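---
title: "A probe-addressed key-value store on synthetic DNA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A probe-addressed key-value store on synthetic DNA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnakv)
```

## The storage model

`dnakv` simulates a DNA storage architecture in which every stored object is
one synthetic strand of the form

```
strand  =  probe (key)  ++  Info-DNA (value)
```

The *probe* is a short barcode (60 bp by default) immobilizable on a
microarray; it addresses the strand the way a key addresses a value. The
*Info-DNA* is a fountain-coded encoding of the object's bytes. An in-silico
*mapping table* associates each data-object identifier (DOI) with its probe,
so a random read is: look up the probe, print it on a (virtual) array,
hybridize the pool, sequence the selected strand, decode. Because a
microarray carries up to millions of distinct spots, this scales the address
space far beyond the ~10 objects per pool that PCR primers allow.

Everything here is simulated: no synthesis, sequencing, array physics or
fluorescence model is included. What the package does let you verify is the
*coding* layer — that large probe sets with guaranteed mutual dissimilarity
exist and can be generated quickly, that arbitrary bytes can be encoded into
biochemically well-behaved strands, and that selection-plus-decoding recovers
every object exactly, including under an injected error channel.

## Biochemical constraints

All generated sequences respect a configurable constraint set
(`constraint_config()`):

* **GC content** within `[gcMin, gcMax]` (default 40–60%) — GC balance
  correlates with synthesis/sequencing fidelity and duplex stability.
* **Homopolymer cap** (default 5 bp) — long single-base runs are the
  dominant sequencing-error mode.
* **Hairpin avoidance** — strands should not fold on themselves.
* **Dissimilarity** — probes vs probes, strands vs strands, strands vs
  probes, and everything vs the library's single primer pair, measured as
  Jaccard similarity of k-mer sets.

### The hairpin model

No specific secondary-structure predictor is mandated by the architecture,
so the package uses a deterministic stem-loop scanner: a sequence is flagged
when some window of `stemMin` bases (default 6) reappears downstream as its
reverse complement after a gap of `loopMin`–`loopMax` bases (default 3–8),
i.e. when a fold with a ≥6 bp stem and a plausible loop exists. The scanner
is exact for its model (`has_complex_structure()` agrees with an exhaustive
O(L²) window-pair search in the property tests) and cheap enough to run on
every candidate. It is not a thermodynamic folder: it knows nothing of
wobble pairs, bulges, or melting temperature, and a sequence it passes could
still fold weakly. Users who need ensemble predictions can post-filter
sequences with an external folder; the stem-loop model is the package's
operating definition of "complex structure".

### Similarity and its approximation

Exact similarity is the Jaccard index of k-mer sets,
`sim_k(q1,q2) = |S_k(q1) ∩ S_k(q2)| / |S_k(q1) ∪ S_k(q2)|`
(`jaccard_similarity()`; `k = 4` for probes, `k = 5` for strands). Checking
a candidate against a million accepted sequences exactly is quadratic and
infeasible, so candidates are screened with MinHash LSH: `r = 200` universal
hash functions over 2-bit-packed k-mers, split into `b = 20` bands of
`m = 10` rows. Two sequences collide when all `m` minima agree in at least
one band, which happens with probability `1 − (1 − s^m)^b` at similarity `s`
(`collision_probability()`). Every band candidate is then *verified* with
the exact Jaccard similarity, so the two-stage filter (`lsh_has_similar()`)
has no false positives; false negatives are possible exactly where the
S-curve is low, which is the designed behaviour — near-threshold pairs are
caught with the probability the banding implies, far-above-threshold pairs
essentially always. The hash family is `h_i(x) = (a_i·x + c_i) mod p` with
`p = 2³¹ − 1` and `(a_i, c_i)` drawn from a seeded RNG; band keys are the
tuple of raw minima. Neither the family nor the band-combination rule is
canonical; both choices are deterministic, seed-reproducible and satisfy the
MinHash estimator property (signature agreement is an unbiased estimate of
`s`, checked in the tests at `r = 40` and `r = 200`).

## Probe generation

`generate_probe_set()` rejection-samples probes with exact GC placement: a
GC count is drawn uniformly from the integer interval implied by the GC
bounds, that many positions receive G or C (equiprobable), the rest A or T.
Uniform placement is the least-informative choice consistent with "sample in
the GC range"; the audits therefore bound the GC *range*, not its shape.
Each candidate must pass all constraints and must not exceed the similarity
cutoff (default 60%) against any accepted probe, enforced through the
LSH index and exact verification. Accepted probes enter the index before the
next draw, so the set is mutually dissimilar by construction; the test suite
nevertheless re-audits finished sets brute-force (all-pairs exact Jaccard
via `pairwise_jaccard()`), never trusting the generator's own filter. A
retry cap (default 10,000 attempts per probe) turns an over-constrained
configuration into a diagnosable error naming the dominant rejected
constraint, instead of a silent infinite loop.

## The fountain-code layer

Objects are zero-padded and split into `k` chunks of `chunkSize` bytes
(default 4). The codec interface is rateless: any encoding-symbol identifier
(ESI) maps deterministically — given the codec seed — to one repair symbol.
Two backends implement it:

* **`gf256`** (default): each repair symbol is a dense pseudo-random GF(256)
  linear combination of all `k` chunks, with coefficients derived from
  `(seed, esi)`; decoding is Gaussian elimination over GF(256) (compiled
  code). A random square GF(256) system is nonsingular with probability
  `∏_{i≥1}(1 − 256^{-i}) ≈ 0.996`, so decoding from exactly `k` received
  symbols succeeds >99% of the time, from `k+1` symbols >99.99%, and each
  extra symbol divides the failure rate by roughly 256. These are the
  recovery guarantees of the RaptorQ class of codes; the package implements
  them with the dense random linear construction rather than the RFC 6330
  schedule (systematic indices, LDPC/HDPC precode), whose complexity buys
  linear-time decoding that desk-scale simulation does not need.
* **`lt`**: a classical Luby-transform code with robust soliton degree
  distribution (`c = 0.1`, `δ = 0.05`), decoded by belief-propagation
  peeling with a GF(2) Gaussian-elimination fallback on a stall. At small
  `k` an LT code needs noticeably more than `k` symbols; it is included as
  the canonical reference point of the code family and for its XOR-algebra
  transparency.

Both backends are *non-systematic by contract*: only ESIs `≥ k` (repair
symbols) may be emitted, so no source chunk ever appears verbatim as DNA.

### Packet serialization

A packet's DNA form must be self-describing, so a `headerBits`-wide
big-endian ESI (default 16 bits) is attached to the payload, and the whole
bit vector is mapped two bits per base (`00→A, 01→T, 10→C, 11→G` — the
fixed mapping table, exactly inverted by `dna_to_bits()`). Two
transformations are applied first, both invisible to the decoder:

* **Whitening.** Any linear code maps a low-entropy message to low-entropy
  repair symbols — an all-zero object yields all-zero symbols, which the
  base mapping would turn into pure poly-A. The payload bytes are therefore
  XORed with a pseudo-random mask derived from `(seed, esi)` before
  mapping; `parse_packet_dna()` removes it again. This keeps packet DNA
  pseudo-random for *every* payload class, which the all-zero/all-one
  fixture classes exercise end to end.
* **Bit interleaving.** Small ESIs share long runs of zero bits, so a plain
  header would give every early packet an identical `AAAA…` prefix —
  creating homopolymers at junctions and shared subsequences across
  strands. A fixed seed-derived permutation interleaves header and payload
  bits before the base mapping, dissolving any positional low-entropy
  region.

Packets have a fixed DNA length (`packet_dna_length()`), which is how the
reader splits a strand; no checksum is added, so a substitution inside a
packet's payload region silently corrupts that packet and recovery then
relies on the overhead. A corrupted ESI header is usually detected (the
value falls outside `[k, 2^headerBits)`) and the packet discarded.

## The probe-aware encoding pipeline

`encode_object()` walks the ESI stream monotonically; rejected ESIs are
skipped permanently, which realizes the "choose a decodable subsequence of
the symbol stream" contract with minimal state. Each candidate packet must
pass, at packet level: GC bounds (checking GC per packet rather than per
strand keeps the content uniform along the strand), the homopolymer cap
*including the junction* with everything already assembled (probe suffix
plus previous packets), primer avoidance, and verified dissimilarity to all
probes and all previously accepted strands. Hairpin structure is evaluated
only on the assembled strand — individual packets are too short for the
stem-loop geometry to be meaningful.

Packets are appended until `can_decode()` holds: the set decodes *and*
remains decodable after removal of any `ε` packets, checked exactly over all
removal subsets (at desk scale `ε ≤ 2`, so the combinatorics are trivial).
This operationalizes "decodable with a certain overhead" as erasure
tolerance, which is the property the access layer actually uses. The
assembled strand then faces the whole-strand checks (junction runs, hairpin,
primers, dissimilarity); on failure the packets are discarded and assembly
restarts — with the ESI stream jumped forward, because a whole-strand
failure is often driven by the probe interacting with the shared identifier
bits of nearby ESIs and would otherwise recur identically. The strand-level
retry budget (default 25) and per-packet candidate budget (default 5,000)
convert a too-strict configuration into an explicit error.

Encoding consumes no RNG stream: symbols, masks and permutations are all
keyed by `(seed, esi)`, so a library is bit-reproducible from its
configuration, including acceptance order.

## Random access

`random_read()` simulates the microarray path. Hybridization is modeled as
an exact-prefix match: a strand is selected when its key region (probe-length
prefix) is within Hamming distance `tolerance` (default 0) of a printed
probe; the tolerance knob abstracts wash stringency. Since the pool is
conceptually double-stranded — each strand carries both the probe and its
complement — the simulator compares the stored probe sequence directly with
the key prefix and performs no complementation. The probe-set dissimilarity
guarantee is what makes tolerance-0 selection exact across the library (no
false positives in a 1,000-strand pool, tested). In shared-key mode (one
probe addressing several objects) a read returns all strands under that key;
the simulator disambiguates by the strand's recorded identity, which stands
in for content-level disambiguation a deployment would use.

An `error_channel()` injects iid per-base substitutions, insertions and
deletions after selection, standing in for synthesis and sequencing noise.
It is deliberately simple plumbing — real error processes are bursty and
sequence-context-dependent — but suffices to demonstrate the designed
monotone trade: recovery probability decreases with the error rate and
increases with the overhead `ε`, and a strand encoded with `ε = 2` survives
the deletion of a full packet.

## What the synthetic data does and does not show

`generate_fixtures()` produces the study payloads: uniform random bytes
(the hard case for dissimilarity, since all strands draw from the same
distribution), printable text (realistic entropy), and the all-zero /
all-one classes that stress the non-systematic and whitening arguments.
Default problem sizes — 1,000 probes for the probe audit, 200 objects of 32
bytes for the library audit, 2,000 and 100,000 Monte-Carlo trials for the
recovery rates at `k` and `k+1` — are chosen so every guarantee is measured
with meaningful resolution on a single CPU; they are scaled-down analogues
of the million-probe and million-object settings the architecture targets,
and nothing in the implementation depends on the scale. What passing tests
do *not* show: behaviour under real synthesis/sequencing error profiles,
thermodynamic hybridization specificity, or array physics — the simulation
abstracts all three.

## Numerical and design choices

* Probe complement convention: probes are derived by position-wise
  complement (`complement()`, A↔T / C↔G in place), the convention of the
  worked probe-design example; `reverse_complement()` exists separately and
  drives the hairpin scanner. The hybridization simulator matches stored
  probes directly, so the convention does not affect selection results.
* k-mer packing uses 2 bits per base, restricting `k ≤ 11` so hash products
  stay exact in doubles; defaults use `k = 4` and `k = 5`.
* `gcCount` sampling is uniform on the closed integer interval
  `[⌈gcMin·len⌉, ⌊gcMax·len⌋]`; ties (`gcMin = gcMax`) force the count.
* `can_decode()` checks all `C(n, ε)` removal subsets exactly rather than a
  greedy approximation; with the gf256 backend virtually any `k` of the
  packets decode, so accepted strands contain `k + ε` packets almost
  always.
* Duplicate ESIs in a decode set are deduplicated; duplicates with
  conflicting payloads raise an integrity error rather than silently
  entering elimination.
* The LSH index is a reference object (environment): inserts mutate in
  place, matching its role as shared state between generator and encoder;
  single-threaded execution makes the behave-as-serialized contract
  trivial.

## Known limitations

* The stem-loop scanner is a combinatorial, not thermodynamic, structure
  model.
* The gf256 backend's decoder is cubic-time Gaussian elimination — ample
  for desk-scale `k`, not for streaming gigabytes.
* The error channel is iid; no burst or context model.
* One object maps to one strand; sharding large objects across strands is
  out of scope, so practical object sizes are tens to hundreds of bytes.
* Hybridization is a Hamming-threshold abstraction; no quantitative
  stringency (temperature, salt) is modeled.

## Reproducing the measurements

`scripts/acceptance.R --seed <int> --out <path>` regenerates every headline
number from scratch: the 1,000-probe audit (max pairwise similarity, GC
range, run lengths), the 200-object strand-distance audit, and the
Monte-Carlo recovery rates at `k` and `k+1` received symbols. The test suite
(`testthat::test_dir("tests/testthat")`) re-derives the same guarantees at
smaller scale alongside the per-module unit and property tests.
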